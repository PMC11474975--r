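##
## Least-squares (Kabsch) superposition and RMSD/RMSF metrics.
##

#' Kabsch least-squares fit
#'
#' Finds the proper rotation and translation minimising the (optionally
#' weighted) squared deviation of \code{mobile} from \code{reference}.
#' Reflections are corrected so \code{det(rotation) = +1}.
#'
#' @param mobile,reference n x 3 coordinate matrices (Angstrom), n >= 3.
#' @param weights optional per-atom weights (e.g. masses); uniform when NULL.
#' @return list of class \code{"rigid_transform"} with \code{rotation}
#'   (3 x 3) and \code{translation} (length 3); apply as
#'   \code{coords \%*\% rotation + translation} via
#'   \code{\link{apply_transform}}.
#' @export
kabsch_fit <- function(mobile, reference, weights = NULL) {
  stopifnot(is.matrix(mobile), is.matrix(reference),
            ncol(mobile) == 3, ncol(reference) == 3)
  n <- nrow(mobile)
  if (nrow(reference) != n) stop_pd("kabsch_fit(): atom count mismatch (%d vs %d)",
                                    n, nrow(reference))
  if (n < 3) stop_pd("kabsch_fit(): need at least 3 atoms")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  w <- w / sum(w)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  mm <- sweep(mobile, 2, cm)
  rr <- sweep(reference, 2, cr)
  h <- t(mm * w) %*% rr
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) stop_pd("kabsch_fit(): degenerate geometry (collinear atoms)")
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  ## x_fit = (x - cm) %*% t(rot) + cr  ==  x %*% rotation + translation
  rotation <- t(rot)
  translation <- as.numeric(cr - cm %*% rotation)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#' @param coords n x 3 matrix.
#' @param tf a \code{"rigid_transform"}.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(coords, tf) {
  sweep(coords %*% tf$rotation, 2, tf$translation, `+`)
}

## Fit frame onto reference using the atoms in fit_rows, return whole frame
## transformed.
fit_frame <- function(frame, reference, fit_rows, weights = NULL) {
  tf <- kabsch_fit(frame[fit_rows, , drop = FALSE],
                   reference[fit_rows, , drop = FALSE], weights)
  apply_transform(frame, tf)
}

rmsd_value <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Per-frame RMSD after superposition
#'
#' For each frame, superposes \code{fit_selection} atoms onto the reference
#' (least squares, unweighted by default, mass-weighted on request) and
#' measures RMSD over \code{measure_selection}.
#'
#' @param traj a trajectory.
#' @param reference N x 3 reference coordinates (defaults to frame 1).
#' @param fit_selection,measure_selection atom selections; measure defaults
#'   to the fit selection.
#' @param fit superpose before measuring (TRUE) or measure in place.
#' @param mass_weighted mass-weight the fit.
#' @return data.frame with \code{frame}, \code{time} (ns), \code{rmsd}
#'   (Angstrom).
#' @export
rmsd_series <- function(traj, reference = NULL, fit_selection,
                        measure_selection = fit_selection, fit = TRUE,
                        mass_weighted = FALSE) {
  reference <- reference %||% traj$frames[[1]]
  if (nrow(reference) != n_atoms(traj$topology)) {
    stop_pd("rmsd_series(): reference has %d atoms, topology %d",
            nrow(reference), n_atoms(traj$topology))
  }
  fr <- sel_rows(fit_selection)
  mr <- sel_rows(measure_selection)
  w <- if (mass_weighted) traj$topology$atoms$mass[fr] else NULL
  ref_m <- reference[mr, , drop = FALSE]
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    x <- traj$frames[[f]]
    if (fit) x <- fit_frame(x, reference, fr, w)
    rmsd_value(x[mr, , drop = FALSE], ref_m)
  }, numeric(1))
  data.frame(frame = seq_len(n_frames(traj)), time = traj$time, rmsd = vals)
}

#' Root-mean-square fluctuation
#'
#' RMSF_i = sqrt(<|x_i - <x_i>|^2>) after superposing each frame onto the
#' reference on \code{fit_selection}.  With \code{per_residue = TRUE} atomic
#' values are averaged over each residue's atoms in the measure selection.
#'
#' @inheritParams rmsd_series
#' @param per_residue average per residue.
#' @return data.frame of class \code{"fluctuation_profile"}: per-atom rows
#'   (\code{atom_index}, \code{residue_index}, \code{residue_number},
#'   \code{rmsf}) or per-residue rows.
#' @export
rmsf <- function(traj, fit_selection, measure_selection = fit_selection,
                 reference = NULL, per_residue = FALSE,
                 mass_weighted = FALSE) {
  if (n_frames(traj) < 2) stop_pd("rmsf(): need at least 2 frames")
  reference <- reference %||% traj$frames[[1]]
  fr <- sel_rows(fit_selection)
  mr <- sel_rows(measure_selection)
  w <- if (mass_weighted) traj$topology$atoms$mass[fr] else NULL
  nf <- n_frames(traj)
  ## two passes: mean first, then squared deviations (numerically stable)
  fitted <- lapply(seq_len(nf), function(f) {
    fit_frame(traj$frames[[f]], reference, fr, w)[mr, , drop = FALSE]
  })
  mean1 <- Reduce(`+`, fitted) / nf
  msf <- numeric(length(mr))
  for (f in seq_len(nf)) msf <- msf + rowSums((fitted[[f]] - mean1)^2)
  msf <- msf / nf
  a <- traj$topology$atoms[mr, ]
  out <- data.frame(atom_index = a$atom_index,
                    residue_index = a$residue_index,
                    residue_number = a$residue_number,
                    residue_name = a$residue_name,
                    chain_id = a$chain_id,
                    rmsf = sqrt(msf))
  if (per_residue) {
    agg <- stats::aggregate(rmsf ~ residue_index + residue_number +
                              residue_name + chain_id, data = out, FUN = mean)
    out <- agg[order(agg$residue_index), ]
    rownames(out) <- NULL
  }
  class(out) <- c("fluctuation_profile", "data.frame")
  out
}
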