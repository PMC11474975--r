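##
## Essential-dynamics PCA: eigendecomposition of the (optionally
## mass-weighted) covariance of superposed coordinates, projections,
## PC overlap between ensembles, and extreme-motion interpolation.
##

#' Fit a conformational PCA model
#'
#' Each frame is least-squares superposed onto \code{reference} on the
#' selection, coordinates are (optionally) weighted by sqrt(mass), and the
#' covariance of the flattened 3M-dimensional coordinates is
#' eigendecomposed.  For large selections (3M > 5000) the frame-space dual
#' (Gram) decomposition is used; the spectra agree to numerical precision.
#'
#' @param traj a trajectory.
#' @param selection atom selection the PCA is built on (e.g. main chain).
#' @param mass_weighted weight coordinates by sqrt(mass) (units of the
#'   eigenvalues become Angstrom^2 amu).
#' @param reference N x 3 reference coordinates; defaults to frame 1.
#' @param n_components number of eigenvectors to keep; NULL keeps all.
#' @return object of class \code{"pca_model"}: \code{mean} (3M, weighted
#'   coordinates), \code{eigenvectors} (3M x K, orthonormal columns),
#'   \code{eigenvalues} (non-increasing, clipped at 0), \code{weights}
#'   (per-atom), \code{trace} of the covariance, plus the selection and
#'   reference needed to project external structures.
#' @export
fit_pca <- function(traj, selection, mass_weighted = TRUE, reference = NULL,
                    n_components = NULL) {
  if (n_frames(traj) < 2) stop_pd("fit_pca(): need at least 2 frames")
  reference <- reference %||% traj$frames[[1]]
  rows <- sel_rows(selection)
  w_atom <- if (mass_weighted) traj$topology$atoms$mass[rows] else rep(1, length(rows))
  sw <- sqrt(rep(w_atom, each = 3))
  nf <- n_frames(traj)
  m3 <- 3L * length(rows)
  y <- matrix(0, nf, m3)
  for (f in seq_len(nf)) {
    x <- fit_frame(traj$frames[[f]], reference, rows)[rows, , drop = FALSE]
    y[f, ] <- as.vector(t(x)) * sw
  }
  mu <- colMeans(y)
  yc <- sweep(y, 2, mu)
  tr <- sum(yc * yc) / nf
  if (m3 <= 5000) {
    cv <- crossprod(yc) / nf
    ed <- eigen(cv, symmetric = TRUE)
    vals <- ed$values
    vecs <- ed$vectors
  } else {
    g <- tcrossprod(yc) / nf            # frames x frames Gram
    ed <- eigen(g, symmetric = TRUE)
    pos <- ed$values > 1e-12 * max(ed$values, 1e-300)
    vals <- ed$values[pos]
    vecs <- t(yc) %*% ed$vectors[, pos, drop = FALSE]
    vecs <- sweep(vecs, 2, sqrt(nf * vals), `/`)
  }
  vals <- pmax(vals, 0)
  if (!is.null(n_components)) {
    k <- min(n_components, length(vals))
    vals <- vals[seq_len(k)]
    vecs <- vecs[, seq_len(k), drop = FALSE]
  }
  ## sign convention: largest-magnitude component positive
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  structure(list(mean = mu, eigenvectors = vecs, eigenvalues = vals,
                 weights = w_atom, trace = tr, mass_weighted = mass_weighted,
                 selection = if (inherits(selection, "atom_selection"))
                   selection else structure(list(indices = rows - 1L,
                                                 label = "indices"),
                                            class = "atom_selection"),
                 reference = reference),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  k <- min(3, length(x$eigenvalues))
  cat(sprintf("pca_model: %d dof, %d components (trace %.4g)\n",
              length(x$mean), length(x$eigenvalues), x$trace))
  cat("  leading eigenvalues:",
      paste(signif(x$eigenvalues[seq_len(k)], 4), collapse = ", "), "\n")
  invisible(x)
}

## weighted flattened coordinates of one frame on the model's selection,
## after superposition to the model reference
model_coords <- function(model, frame) {
  rows <- sel_rows(model$selection)
  x <- fit_frame(frame, model$reference, rows)[rows, , drop = FALSE]
  as.vector(t(x)) * sqrt(rep(model$weights, each = 3))
}

#' Project coordinates or a trajectory onto PCA eigenvectors
#'
#' External single structures are superposed to the model's reference on the
#' model's selection before projecting.
#'
#' @param model a \code{pca_model}.
#' @param x a trajectory or an N x 3 coordinate matrix.
#' @param n_components number of components to return.
#' @return frames x K matrix of class \code{"pca_projection"} (a single
#'   structure gives 1 row).
#' @export
project_pca <- function(model, x, n_components = 3) {
  k <- min(n_components, ncol(model$eigenvectors))
  v <- model$eigenvectors[, seq_len(k), drop = FALSE]
  if (inherits(x, "trajectory")) {
    out <- matrix(0, n_frames(x), k)
    for (f in seq_len(n_frames(x))) {
      out[f, ] <- (model_coords(model, x$frames[[f]]) - model$mean) %*% v
    }
  } else {
    if (!is.matrix(x) || ncol(x) != 3) stop_pd("project_pca(): x must be a trajectory or an N x 3 matrix")
    out <- matrix((model_coords(model, x) - model$mean) %*% v, 1, k)
  }
  colnames(out) <- paste0("PC", seq_len(k))
  class(out) <- c("pca_projection", class(out))
  out
}

#' Reconstruct Cartesian coordinates from PC scores
#'
#' @param model a \code{pca_model}.
#' @param scores length-K numeric vector of PC values.
#' @return M x 3 coordinate matrix (Angstrom) over the model's selection.
#' @export
reconstruct_pca <- function(model, scores) {
  k <- length(scores)
  y <- model$mean + as.numeric(model$eigenvectors[, seq_len(k), drop = FALSE]
                               %*% scores)
  y <- y / sqrt(rep(model$weights, each = 3))
  matrix(y, ncol = 3, byrow = TRUE)
}

#' Negate one principal component of a projection
#'
#' The eigenvector sign is arbitrary; published plots sometimes flip a PC for
#' visual comparison between species.  Flipping changes no cluster structure.
#'
#' @param projection a projection matrix.
#' @param component column to negate (1-based).
#' @return the projection with that column negated.
#' @export
flip_pc_sign <- function(projection, component) {
  if (component > ncol(projection)) stop_pd("flip_pc_sign(): component %d > %d",
                                            component, ncol(projection))
  projection[, component] <- -projection[, component]
  projection
}

#' Overlap (inner product) of corresponding PCs of two models
#'
#' Measures conservation of a collective motion between two ensembles as the
#' inner product of the unit eigenvectors.  Sign is retained; report
#' \code{abs()} for magnitude.
#'
#' @param model_a,model_b \code{pca_model}s built on identical selections.
#' @param component which PC (1-based).
#' @return correlation in [-1, 1].
#' @export
pc_overlap <- function(model_a, model_b, component = 1) {
  if (length(model_a$mean) != length(model_b$mean)) {
    stop_pd("pc_overlap(): models have different dimension (%d vs %d)",
            length(model_a$mean), length(model_b$mean))
  }
  va <- model_a$eigenvectors[, component]
  vb <- model_b$eigenvectors[, component]
  sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
}

#' Interpolate conformations between the extremes of one PC
#'
#' Reconstructs \code{n} conformations mean + t v along the chosen component,
#' t scanning linearly over the observed projection range, and returns them
#' as a trajectory over the model's selection atoms (Cartesian Angstrom,
#' weights un-applied) -- the standard way to visualise a collective motion.
#'
#' @param model a \code{pca_model}.
#' @param projection projection matrix of the trajectory on the model.
#' @param component PC to scan.
#' @param n number of conformations (>= 2).
#' @param top topology the model selection refers to.
#' @return a trajectory of \code{n} frames over the selection atoms.
#' @export
interpolate_extremes <- function(model, projection, component, n = 100,
                                 top = NULL) {
  if (n < 2) stop_pd("interpolate_extremes(): n must be >= 2")
  if (model$eigenvalues[component] <= 1e-12) {
    stop_pd("interpolate_extremes(): degenerate PC %d (zero variance)",
            component)
  }
  rng <- range(projection[, component])
  ts <- seq(rng[1], rng[2], length.out = n)
  frames <- lapply(ts, function(t) {
    s <- numeric(component); s[component] <- t
    reconstruct_pca(model, s)
  })
  sub <- subset_topology(top %||% attr(model, "topology"), model$selection)
  trajectory(sub, frames, time = seq_len(n) - 1)
}

## topology restricted to a selection (for writing PCA motions etc.)
subset_topology <- function(top, sel) {
  if (is.null(top)) stop_pd("a topology is required to build the output trajectory")
  a <- top$atoms[sel_rows(sel), ]
  a$atom_index <- NULL; a$residue_index <- NULL
  rownames(a) <- NULL
  topology(a)
}
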