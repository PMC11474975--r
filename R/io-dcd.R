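##
## CHARMM/NAMD DCD binary trajectory format (little-endian, Fortran records).
## Coordinates on disk are Angstrom single precision; the frame interval is
## stored once (AKMA time units), so DCD can only carry uniform time spacing.
##

.akma_ps <- 0.04888821  # 1 AKMA time unit in ps

read_fortran_record <- function(con, what, size, n = NULL) {
  len <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!length(len)) return(NULL)
  payload <- switch(what,
    raw = readBin(con, "raw", len),
    integer = readBin(con, "integer", len / size, size = size,
                      endian = "little"),
    double = readBin(con, "double", len / size, size = size,
                     endian = "little")
  )
  tail <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!length(tail) || tail != len) return(NULL)  # truncated record
  payload
}

write_fortran_record <- function(con, payload, what, size) {
  len <- switch(what,
    raw = length(payload),
    integer = length(payload) * size,
    double = length(payload) * size
  )
  writeBin(as.integer(len), con, size = 4, endian = "little")
  switch(what,
    raw = writeBin(payload, con),
    integer = writeBin(as.integer(payload), con, size = size,
                       endian = "little"),
    double = writeBin(as.double(payload), con, size = size, endian = "little")
  )
  writeBin(as.integer(len), con, size = 4, endian = "little")
}

read_dcd <- function(path, top) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- read_fortran_record(con, "raw", 1)
  if (is.null(hdr) || length(hdr) != 84 ||
      rawToChar(hdr[1:4]) != "CORD") {
    stop_pd("read_trajectory(): %s is not a DCD file", path)
  }
  icntrl <- readBin(hdr[5:84], "integer", 20, size = 4, endian = "little")
  istart <- icntrl[2]; nsavc <- max(icntrl[3], 1L)
  delta <- readBin(hdr[(4 + 9 * 4 + 1):(4 + 10 * 4)], "double", 1, size = 4,
                   endian = "little")
  has_cell <- icntrl[11] == 1L
  invisible(read_fortran_record(con, "raw", 1))        # title block
  nat <- read_fortran_record(con, "integer", 4)
  if (is.null(nat)) stop_pd("truncated DCD header in %s", path)
  if (nat != n_atoms(top)) {
    stop_pd("read_trajectory(): DCD has %d atoms, topology has %d",
            nat, n_atoms(top))
  }
  frames <- list(); f <- 0L
  repeat {
    if (has_cell) {
      cell <- read_fortran_record(con, "double", 8)
      if (is.null(cell)) break
    }
    x <- read_fortran_record(con, "double", 4)
    y <- read_fortran_record(con, "double", 4)
    z <- read_fortran_record(con, "double", 4)
    if (is.null(x) || is.null(y) || is.null(z) ||
        length(x) != nat || length(y) != nat || length(z) != nat) {
      if (!is.null(x)) warn_pd("truncated DCD %s: stopping after frame %d",
                               path, f)
      break
    }
    f <- f + 1L
    frames[[f]] <- cbind(x, y, z)
  }
  if (!f) stop_pd("no complete frames in DCD file %s", path)
  dt_ns <- delta * nsavc * .akma_ps / 1000
  t0 <- istart * delta * .akma_ps / 1000
  trajectory(top, frames, time = t0 + (seq_len(f) - 1) * dt_ns)
}

write_dcd <- function(traj, frame_indices, path) {
  nf <- length(frame_indices)
  tms <- traj$time[frame_indices]
  dt_ns <- if (nf > 1) tms[2] - tms[1] else 0.001
  if (dt_ns <= 0) dt_ns <- 0.001
  delta <- dt_ns * 1000 / .akma_ps
  istart <- as.integer(round(tms[1] / dt_ns))
  con <- file(path, "wb")
  on.exit(close(con))
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- istart; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[20] <- 24L  # CHARMM-format flag
  hdr <- c(charToRaw("CORD"), writeBin(icntrl, raw(), size = 4,
                                       endian = "little"))
  ## splice the float32 delta into icntrl slot 10
  hdr[(4 + 9 * 4 + 1):(4 + 10 * 4)] <- writeBin(delta, raw(), size = 4,
                                                endian = "little")
  write_fortran_record(con, hdr, "raw", 1)
  title <- sprintf("%-80s", "pocketdyn trajectory")
  write_fortran_record(con, c(writeBin(1L, raw(), size = 4, endian = "little"),
                              charToRaw(title)), "raw", 1)
  write_fortran_record(con, n_atoms(traj$topology), "integer", 4)
  for (f in frame_indices) {
    xyz <- traj$frames[[f]]
    write_fortran_record(con, xyz[, 1], "double", 4)
    write_fortran_record(con, xyz[, 2], "double", 4)
    write_fortran_record(con, xyz[, 3], "double", 4)
  }
}
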