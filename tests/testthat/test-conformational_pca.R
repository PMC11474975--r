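## shared small ensemble for several blocks
make_ensemble <- function(n_frames = 60, n_atoms = 8, sd = 0.4, seed = 21) {
  h <- make_harmonic(n_atoms = n_atoms, n_frames = n_frames, sigma = sd,
                     seed = seed)
  h$traj
}

test_that("fit_pca satisfies rank, trace and orthonormality identities", {
  traj <- make_ensemble(n_frames = 500, n_atoms = 10)
  sel <- select_atoms(traj$topology, "calpha")
  m <- fit_pca(traj, sel, mass_weighted = TRUE)
  ## trace identity
  expect_lt(abs(sum(m$eigenvalues) - m$trace) / m$trace, 1e-8)
  ## orthonormal eigenvectors
  vtv <- crossprod(m$eigenvectors)
  expect_lt(max(abs(vtv - diag(ncol(vtv)))), 1e-8)
  ## non-increasing spectrum
  expect_true(all(diff(m$eigenvalues) <= 1e-10))

  ## rank-1 ensemble: one (deformation-only) displacement direction ->
  ## exactly one nonzero eigenvalue
  base <- toy_peptide_coords(3)
  top <- toy_peptide(3)
  set.seed(33)
  dirv <- remove_rigid_modes(base, matrix(rnorm(length(base)),
                                          nrow(base), 3))
  frames <- lapply(seq(-0.2, 0.2, length.out = 20),
                   function(t) base + t * dirv)
  m1 <- fit_pca(trajectory(top, frames),
                select_atoms(top, "heavy"), mass_weighted = FALSE,
                reference = base)
  expect_equal(sum(m1$eigenvalues > 1e-6 * m1$eigenvalues[1]), 1)

  expect_error(fit_pca(trajectory(top, list(base)),
                       select_atoms(top, "heavy")), "2 frames")
})

test_that("mass weighting is a no-op for homogeneous masses", {
  traj <- make_ensemble(n_frames = 80)   # all-carbon system
  sel <- select_atoms(traj$topology, "calpha")
  mw <- fit_pca(traj, sel, mass_weighted = TRUE)
  uw <- fit_pca(traj, sel, mass_weighted = FALSE)
  for (k in 1:3) {
    expect_equal(abs(sum(mw$eigenvectors[, k] * uw$eigenvectors[, k])), 1,
                 tolerance = 1e-8)
  }
  expect_equal(mw$eigenvalues / mw$weights[1], uw$eigenvalues,
               tolerance = 1e-8)
})

test_that("projection identities: zero at the mean, decorrelated scores, exact reconstruction", {
  traj <- make_ensemble(n_frames = 120, n_atoms = 6)
  sel <- select_atoms(traj$topology, "calpha")
  m <- fit_pca(traj, sel, mass_weighted = TRUE)

  ## projecting the reconstruction of the mean gives zeros
  mean_coords <- reconstruct_pca(m, numeric(3))
  expect_lt(max(abs(project_pca(m, mean_coords))), 1e-6)

  ## PC scores decorrelate
  pr <- project_pca(m, traj, n_components = 3)
  cv <- stats::cov(unclass(pr))
  off <- abs(cv[upper.tri(cv)])
  expect_lt(max(off) / max(diag(cv)), 1e-6)

  ## full-rank reconstruction is exact
  full <- project_pca(m, traj, n_components = length(m$eigenvalues))
  f3 <- fit_frame(traj$frames[[3]], m$reference, sel$indices + 1)
  rec <- reconstruct_pca(m, full[3, ])
  expect_lt(max(abs(rec - f3[sel$indices + 1, ])), 1e-8)

  expect_error(project_pca(m, matrix(0, 2, 3)))  # dimension mismatch
})

test_that("pc_overlap is 1 on itself, 0 for orthogonal planted modes, high for a shared mode", {
  traj <- make_ensemble(n_frames = 100)
  sel <- select_atoms(traj$topology, "calpha")
  m <- fit_pca(traj, sel)
  expect_equal(pc_overlap(m, m, 1), 1.0, tolerance = 1e-12)

  ## orthogonal leading eigenvectors -> overlap exactly 0
  mk_model <- function(v) {
    structure(list(mean = numeric(length(v)),
                   eigenvectors = matrix(v / sqrt(sum(v^2))),
                   eigenvalues = 1), class = "pca_model")
  }
  e1 <- c(1, 0, 0, 0, 0, 0); e2 <- c(0, 0, 1, 0, 0, 0)
  expect_lt(abs(pc_overlap(mk_model(e1), mk_model(e2), 1)), 1e-10)
  expect_error(pc_overlap(mk_model(e1), mk_model(c(1, 0, 0)), 1),
               "dimension")

  ## two ensembles sharing a planted collective mode overlap >= 0.99
  h1 <- make_harmonic(n_atoms = 40, n_frames = 1500, sigma = 0.1,
                      mode = "bend", mode_amplitude = 3, seed = 31)
  h2 <- make_harmonic(n_atoms = 40, n_frames = 1500, sigma = 0.1,
                      mode = "bend", mode_amplitude = 3, seed = 77)
  sel40 <- select_atoms(h1$traj$topology, "calpha")
  ma <- fit_pca(h1$traj, sel40, reference = h1$base)
  mb <- fit_pca(h2$traj, sel40, reference = h1$base)
  expect_gte(abs(pc_overlap(ma, mb, 1)), 0.99)
  ## and PC1 recovers the planted mode itself
  planted <- as.vector(t(h1$mode)) * sqrt(rep(ma$weights, each = 3))
  planted <- planted / sqrt(sum(planted^2))
  expect_gte(abs(sum(planted * ma$eigenvectors[, 1])), 0.99)
})

test_that("flip_pc_sign is an involution and does not change cluster populations", {
  pr <- matrix(c(1, 2, -3, 4), 2, 2, byrow = TRUE)
  expect_equal(flip_pc_sign(pr, 1), matrix(c(-1, 2, 3, 4), 2, 2,
                                           byrow = TRUE))
  expect_equal(flip_pc_sign(flip_pc_sign(pr, 2), 2), pr)

  set.seed(3)
  x <- rbind(matrix(rnorm(300), 100, 3),
             sweep(matrix(rnorm(300), 100, 3), 2, c(15, 0, 0), `+`))
  a <- elbow_kmeans(x, k_max = 5, seed = 11)
  b <- elbow_kmeans(flip_pc_sign(x, 1), k_max = 5, seed = 11)
  expect_equal(sort(a$populations), sort(b$populations))
  expect_equal(a$k, b$k)
})

test_that("interpolate_extremes scans linearly between the observed extremes", {
  h <- make_harmonic(n_atoms = 10, n_frames = 200, sigma = 0.05,
                     mode = "bend", mode_amplitude = 2, seed = 5)
  sel <- select_atoms(h$traj$topology, "calpha")
  m <- fit_pca(h$traj, sel, reference = h$base)
  pr <- project_pca(m, h$traj, 3)
  tr <- interpolate_extremes(m, pr, component = 1, n = 100,
                             top = h$traj$topology)
  expect_equal(n_frames(tr), 100)
  ## endpoints equal the reconstructions at the observed extremes
  expect_equal(tr$frames[[1]], reconstruct_pca(m, c(min(pr[, 1]), 0, 0)),
               tolerance = 1e-10)
  expect_equal(tr$frames[[100]], reconstruct_pca(m, c(max(pr[, 1]), 0, 0)),
               tolerance = 1e-10)
  ## successive-step RMSD is constant (linearity)
  steps <- vapply(1:99, function(i) {
    sqrt(mean(rowSums((tr$frames[[i + 1]] - tr$frames[[i]])^2)))
  }, numeric(1))
  expect_lt(diff(range(steps)), 1e-6)
  ## degenerate PC errors out
  expect_error(interpolate_extremes(m, pr, component = length(m$eigenvalues),
                                    top = h$traj$topology), "degenerate")
})

test_that("elbow_kmeans recovers planted cluster structure", {
  ## structureless (zero-variance) projection -> a single trivial cluster
  x0 <- matrix(1, 50, 3)
  expect_equal(elbow_kmeans(x0, k_max = 6, seed = 2)$k, 1)

  ## 4 well-separated Gaussians -> k = 4, populations 0.25 +/- 0.02
  centers <- rbind(c(0, 0, 0), c(20, 0, 0), c(0, 20, 0), c(0, 0, 20))
  x4 <- do.call(rbind, lapply(1:4, function(i) {
    sweep(matrix(rnorm(1500), 500, 3), 2, centers[i, ], `+`)
  }))
  truth <- rep(1:4, each = 500)
  res <- elbow_kmeans(x4, k_max = 8, seed = 7)
  expect_equal(res$k, 4)
  expect_equal(res$populations, rep(0.25, 4), tolerance = 0.02 / 0.25)
  expect_gte(adjusted_rand_index(res$labels, truth), 0.95)
  ## SSR/SST non-increasing, determinism, label-permutation safety
  expect_true(all(diff(res$ssr_sst) <= 1e-10))
  res2 <- elbow_kmeans(x4, k_max = 8, seed = 7)
  expect_identical(res$labels, res2$labels)
  expect_equal(sum(res$populations), 1, tolerance = 1e-12)
  expect_error(elbow_kmeans(x4, k_max = 1, seed = 1), "k_max")
})
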