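##
## GROMACS GRO format (fixed-column, nm on disk -> Angstrom in memory).
## GRO carries no chain ids; all atoms land in chain "A".
##

parse_gro_block <- function(lines, path) {
  if (length(lines) < 3) stop_pd("truncated GRO file: %s", path)
  nat <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(nat)) stop_pd("malformed GRO atom count line in %s: '%s'",
                          path, lines[2])
  if (length(lines) < nat + 3) stop_pd("truncated GRO file %s: expected %d atom lines",
                                       path, nat)
  al <- lines[3:(nat + 2)]
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(substr(al, from, to)))
    if (anyNA(v)) stop_pd("malformed GRO line in %s (bad %s): '%s'",
                          path, what, al[which(is.na(v))[1]])
    v
  }
  tm <- regmatches(lines[1], regexpr("t=\\s*[-0-9.eE+]+", lines[1]))
  time_ps <- if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) else NA_real_
  list(
    n = nat,
    residue_number = as.integer(num(1, 5, "residue number")),
    residue_name = trimws(substr(al, 6, 10)),
    atom_name = trimws(substr(al, 11, 15)),
    coords = cbind(num(21, 28, "x"), num(29, 36, "y"), num(37, 44, "z")) * 10,
    time_ns = time_ps / 1000,
    used = nat + 3L
  )
}

read_gro_topology <- function(path, water_resnames = .water_resnames) {
  b <- parse_gro_block(readLines(path, warn = FALSE), path)
  atoms <- data.frame(
    atom_name = b$atom_name, residue_name = b$residue_name,
    residue_number = b$residue_number, chain_id = "A",
    stringsAsFactors = FALSE
  )
  top <- topology(atoms, water_resnames)
  attr(top, "coords") <- b$coords
  top
}

read_gro_trajectory <- function(path, top) {
  lines <- readLines(path, warn = FALSE)
  frames <- list(); time <- numeric(0); at <- 1L; f <- 0L
  while (at + 2L <= length(lines)) {
    b <- parse_gro_block(lines[at:length(lines)], path)
    if (b$n != n_atoms(top)) {
      stop_pd("read_trajectory(): GRO frame has %d atoms, topology has %d",
              b$n, n_atoms(top))
    }
    f <- f + 1L
    frames[[f]] <- b$coords
    time <- c(time, if (is.na(b$time_ns)) f - 1 else b$time_ns)
    at <- at + b$used
  }
  if (!length(frames)) stop_pd("no frames in GRO file %s", path)
  trajectory(top, frames, time = time)
}

write_gro <- function(traj, frame_indices, path) {
  a <- traj$topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frame_indices) {
    writeLines(sprintf("frame t= %.6f", traj$time[f] * 1000), con)  # ps
    writeLines(sprintf("%5d", nrow(a)), con)
    xyz <- traj$frames[[f]] / 10  # nm
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       a$residue_number %% 100000,
                       substr(a$residue_name, 1, 5),
                       substr(a$atom_name, 1, 5),
                       a$atom_index %% 100000 + 1L,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines("   10.00000   10.00000   10.00000", con)
  }
}
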