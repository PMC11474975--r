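##
## Trajectory: an ordered set of coordinate frames over one topology.
## Coordinates are N x 3 matrices in Angstrom; times in ns.
##

#' Construct a trajectory
#'
#' @param top a topology.
#' @param frames list of N x 3 coordinate matrices (Angstrom).
#' @param time numeric vector of frame times (ns), non-decreasing.
#' @param box optional list of 3 x 3 box matrices (Angstrom) or NULL.
#' @param provenance optional data.frame (replicate id, original time) kept
#'   through trimming/concatenation.
#' @return object of class \code{"trajectory"}.
#' @export
trajectory <- function(top, frames, time = NULL, box = NULL,
                       provenance = NULL) {
  stopifnot(inherits(top, "topology"), is.list(frames), length(frames) >= 1)
  n <- n_atoms(top)
  ok <- vapply(frames, function(f) is.matrix(f) && nrow(f) == n &&
                 ncol(f) == 3, logical(1))
  if (!all(ok)) {
    stop_pd("trajectory(): frame %d has wrong shape (need %d x 3)",
            which(!ok)[1], n)
  }
  nf <- length(frames)
  if (is.null(time)) time <- seq_len(nf) - 1
  if (length(time) != nf) stop_pd("trajectory(): time length != frame count")
  if (is.unsorted(time)) stop_pd("trajectory(): frame times must be non-decreasing")
  if (is.null(provenance)) {
    provenance <- data.frame(replicate = rep(1L, nf), original_time = time)
  }
  structure(list(topology = top, frames = frames, time = as.numeric(time),
                 box = box, provenance = provenance),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms, t = %.4g..%.4g ns\n",
              n_frames(x), n_atoms(x$topology), min(x$time), max(x$time)))
  invisible(x)
}

#' Number of frames
#' @param traj a trajectory.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Read a trajectory file
#'
#' Supported formats: \code{"dcd"} (CHARMM/NAMD binary, Angstrom),
#' \code{"pdb_models"} (multi-MODEL PDB) and \code{"gro"} (possibly
#' multi-frame).  Coordinates are returned in Angstrom and times in ns
#' regardless of the on-disk unit.  XTC is not supported (no R codec for its
#' compressed coordinate format); convert to DCD upstream.
#'
#' @param path file path.
#' @param top topology with matching atom count.
#' @param format one of \code{"dcd"}, \code{"pdb_models"}, \code{"gro"};
#'   guessed from the extension when missing.
#' @return a trajectory.
#' @export
read_trajectory <- function(path, top, format = NULL) {
  if (!file.exists(path)) stop_pd("read_trajectory(): no such file: %s", path)
  format <- format %||% guess_format(path)
  if (identical(format, "xtc")) {
    stop_pd("read_trajectory(): XTC is not supported (compressed xdr codec); use DCD, multi-model PDB or GRO")
  }
  switch(format,
    dcd = read_dcd(path, top),
    pdb_models = read_pdb_models(path, top),
    gro = read_gro_trajectory(path, top),
    stop_pd("read_trajectory(): unknown format '%s'", format)
  )
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, dcd = "dcd", pdb = "pdb_models", gro = "gro", xtc = "xtc",
         stop_pd("cannot guess trajectory format from extension '.%s'", ext))
}

#' Trim equilibration and concatenate replicate trajectories
#'
#' Removes frames earlier than \code{discard_before} ns from each replicate
#' (the usual discard of the equilibration leg of each run), then concatenates
#' the remainders in input order.  Per-frame provenance (replicate number and
#' original time) is retained; output times are the original times.
#'
#' @param trajectories list of trajectories sharing one topology.
#' @param discard_before ns; frames with \code{time < discard_before} dropped.
#' @return a trajectory.
#' @export
concatenate_trim <- function(trajectories, discard_before = 0) {
  stopifnot(is.list(trajectories), length(trajectories) >= 1)
  n0 <- n_atoms(trajectories[[1]]$topology)
  nm0 <- trajectories[[1]]$topology$atoms$atom_name
  frames <- list(); time <- numeric(0); prov <- NULL
  for (i in seq_along(trajectories)) {
    tr <- trajectories[[i]]
    if (n_atoms(tr$topology) != n0 ||
        !identical(tr$topology$atoms$atom_name, nm0)) {
      stop_pd("concatenate_trim(): trajectory %d has an incompatible topology", i)
    }
    keep <- which(tr$time >= discard_before)
    if (!length(keep)) next
    frames <- c(frames, tr$frames[keep])
    time <- c(time, tr$time[keep])
    prov <- rbind(prov, data.frame(replicate = i, original_time = tr$time[keep]))
  }
  if (!length(frames)) stop_pd("concatenate_trim(): no frames remain after discarding t < %g ns",
                               discard_before)
  structure(list(topology = trajectories[[1]]$topology, frames = frames,
                 time = time, box = NULL, provenance = prov),
            class = "trajectory")
}

#' Write trajectory frames to a file
#'
#' @param traj a trajectory.
#' @param frame_indices 1-based frame indices to write, in order.
#' @param path output path.
#' @param format one of \code{"pdb_models"}, \code{"dcd"}, \code{"gro"};
#'   guessed from the extension when missing.
#' @return \code{path}, invisibly.
#' @export
write_frames <- function(traj, frame_indices = seq_len(n_frames(traj)), path,
                         format = NULL) {
  if (!length(frame_indices)) stop_pd("write_frames(): empty frame index list")
  if (any(frame_indices < 1 | frame_indices > n_frames(traj))) {
    stop_pd("write_frames(): frame index out of range 1..%d", n_frames(traj))
  }
  format <- format %||% guess_format(path)
  switch(format,
    pdb_models = write_pdb_models(traj, frame_indices, path),
    dcd = write_dcd(traj, frame_indices, path),
    gro = write_gro(traj, frame_indices, path),
    stop_pd("write_frames(): unsupported output format '%s'", format)
  )
  invisible(path)
}

## stack selected atoms of all frames into a frames x (3m) matrix
frames_matrix <- function(traj, sel = NULL) {
  rows <- if (is.null(sel)) seq_len(n_atoms(traj$topology)) else sel_rows(sel)
  nf <- n_frames(traj)
  out <- matrix(0, nf, 3L * length(rows))
  for (f in seq_len(nf)) out[f, ] <- as.vector(t(traj$frames[[f]][rows, , drop = FALSE]))
  out
}
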