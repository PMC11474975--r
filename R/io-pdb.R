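##
## PDB (v3.3 fixed-column) reading and writing.
##

#' Read a topology from a structure file
#'
#' @param path file path.
#' @param format \code{"pdb"} or \code{"gro"}; guessed from the extension when
#'   missing.
#' @param water_resnames residue names recognised as water.
#' @return a topology.  Coordinates of the first frame/model are attached as
#'   attribute \code{"coords"} (N x 3, Angstrom).
#' @export
read_topology <- function(path, format = NULL,
                          water_resnames = .water_resnames) {
  if (!file.exists(path)) stop_pd("read_topology(): no such file: %s", path)
  format <- format %||% tolower(tools::file_ext(path))
  switch(format,
    pdb = read_pdb_topology(path, water_resnames),
    gro = read_gro_topology(path, water_resnames),
    stop_pd("read_topology(): unknown format '%s'", format)
  )
}

parse_pdb_atom_lines <- function(lines, path) {
  n <- length(lines)
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(substr(lines, from, to)))
    if (anyNA(v)) {
      stop_pd("malformed PDB line in %s (bad %s): '%s'", path, what,
              lines[which(is.na(v))[1]])
    }
    v
  }
  list(
    atom_name = trimws(substr(lines, 13, 16)),
    altloc = substr(lines, 17, 17),
    residue_name = trimws(substr(lines, 18, 21)),
    chain_id = substr(lines, 22, 22),
    residue_number = as.integer(num(23, 26, "residue number")),
    x = num(31, 38, "x"), y = num(39, 46, "y"), z = num(47, 54, "z"),
    element = trimws(substr(lines, 77, 78))
  )
}

read_pdb_topology <- function(path, water_resnames = .water_resnames) {
  lines <- readLines(path, warn = FALSE)
  atom <- lines[startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")]
  ## single model only for the topology
  endmdl <- which(startsWith(lines, "ENDMDL"))
  if (length(endmdl)) {
    first_block <- lines[seq_len(endmdl[1])]
    atom <- first_block[startsWith(first_block, "ATOM  ") |
                          startsWith(first_block, "HETATM")]
  }
  if (!length(atom)) stop_pd("no ATOM/HETATM records in %s", path)
  p <- parse_pdb_atom_lines(atom, path)
  keep <- p$altloc %in% c(" ", "", "A")
  atoms <- data.frame(
    atom_name = p$atom_name[keep], residue_name = p$residue_name[keep],
    residue_number = p$residue_number[keep], chain_id = p$chain_id[keep],
    element = p$element[keep], stringsAsFactors = FALSE
  )
  chain_blank <- atoms$chain_id == " " | atoms$chain_id == ""
  atoms$chain_id[chain_blank] <- "A"
  top <- topology(atoms, water_resnames)
  attr(top, "coords") <- cbind(p$x[keep], p$y[keep], p$z[keep])
  top
}

read_pdb_models <- function(path, top) {
  lines <- readLines(path, warn = FALSE)
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  frames <- list()
  if (!length(model_starts)) {
    p <- parse_pdb_atom_lines(lines[is_atom], path)
    frames[[1]] <- cbind(p$x, p$y, p$z)
  } else {
    bounds <- c(model_starts, length(lines) + 1L)
    for (m in seq_along(model_starts)) {
      blk <- lines[bounds[m]:(bounds[m + 1] - 1L)]
      al <- blk[startsWith(blk, "ATOM  ") | startsWith(blk, "HETATM")]
      if (!length(al)) next
      p <- parse_pdb_atom_lines(al, path)
      frames[[length(frames) + 1L]] <- cbind(p$x, p$y, p$z)
    }
  }
  nc <- vapply(frames, nrow, integer(1))
  if (any(nc != n_atoms(top))) {
    stop_pd("read_trajectory(): PDB model has %d atoms, topology has %d",
            nc[which(nc != n_atoms(top))[1]], n_atoms(top))
  }
  trajectory(top, frames, time = seq_along(frames) - 1)
}

pdb_atom_line <- function(serial, name, resname, chain, resnum, xyz, element,
                          occupancy = 1.00, bfactor = 0.00) {
  ## atom-name column convention: 1-3 char names start in column 14
  nm <- ifelse(nchar(name) >= 4, substr(name, 1, 4),
               paste0(" ", formatC(name, width = -3)))
  sprintf("ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000, nm, substr(resname, 1, 4), substr(chain, 1, 1),
          resnum %% 10000, xyz[1], xyz[2], xyz[3], occupancy, bfactor,
          substr(element, 1, 2))
}

write_pdb_models <- function(traj, frame_indices, path) {
  a <- traj$topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(frame_indices)) {
    f <- frame_indices[m]
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- traj$frames[[f]]
    lines <- vapply(seq_len(nrow(a)), function(i) {
      pdb_atom_line(i, a$atom_name[i], a$residue_name[i], a$chain_id[i],
                    a$residue_number[i], xyz[i, ], a$element[i])
    }, character(1))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}
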