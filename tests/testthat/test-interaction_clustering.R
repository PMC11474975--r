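test_that("default_fragments cuts acyclic linkers and keeps rings whole", {
  ## biphenyl-like: two 3-rings joined by one cuttable bond -> 2 fragments
  mk_lig <- function(n_frag) {
    xyz <- pocketdyn:::ligand_rod_coords(n_frag)
    top <- topology(data.frame(
      atom_name = paste0("C", seq_len(nrow(xyz))), residue_name = "LIG",
      residue_number = 1, chain_id = "L", element = "C"
    ))
    list(top = top, xyz = xyz)
  }
  l2 <- mk_lig(2)
  expect_length(default_fragments(l2$top, l2$xyz)$fragments, 2)

  ## single ring -> 1 fragment (no acyclic bonds to cut)
  phi <- 2 * pi * (0:5) / 6
  ring <- cbind(1.4 * cos(phi), 1.4 * sin(phi), 0)
  rtop <- topology(data.frame(atom_name = paste0("C", 1:6),
                              residue_name = "LIG", residue_number = 1,
                              chain_id = "L", element = "C"))
  expect_length(default_fragments(rtop, ring)$fragments, 1)

  ## rod of 3 linked rings -> 3 fragments matching the construction
  ps0 <- make_pose_trajectory(n_frames = 2, noise_sigma = 0, seed = 1)
  fs <- default_fragments(ps0$traj$topology, ps0$traj$frames[[1]],
                          atom_rows = ps0$ligand_rows)
  got <- unname(lapply(fs$fragments, function(f) sort(unname(f$atom_rows))))
  want <- unname(lapply(ps0$fragments$fragments,
                        function(f) sort(unname(f$atom_rows))))
  expect_equal(got, want)
})

test_that("min_distance_matrix is exact and bit-equal to the naive loop", {
  ## closed form: residue atom at origin, fragment at 3 and 5 A
  top <- topology(data.frame(
    atom_name = c("CA", "C1", "C2"), residue_name = c("ALA", "LIG", "LIG"),
    residue_number = c(1, 2, 2), chain_id = c("A", "L", "L"),
    element = "C"
  ))
  xyz <- rbind(c(0, 0, 0), c(3, 0, 0), c(5, 0, 0))
  tr <- trajectory(top, list(xyz))
  fr <- fragment_scheme(list(F1 = 2:3))
  d <- min_distance_matrix(tr, residue_groups = list(`0` = 1L),
                           fragments = fr)
  expect_equal(as.numeric(d), 3.0)

  ## brute-force oracle: bit-equal on random frames
  ps <- make_pose_trajectory(n_frames = 50, seed = 9)
  groups <- pocketdyn:::residue_heavy_groups(ps$traj$topology)
  fast <- min_distance_matrix(ps$traj, groups, ps$fragments)
  slow <- pocketdyn:::min_distance_brute(ps$traj, groups, ps$fragments)
  expect_identical(unname(unclass(fast)[, ]), slow)

  ## isometry invariance
  rot <- random_rotation()
  moved <- trajectory(ps$traj$topology,
                      lapply(ps$traj$frames[1:10], function(f) {
                        sweep(f %*% t(rot), 2, c(7, -3, 11), `+`)
                      }))
  d2 <- min_distance_matrix(moved, groups, ps$fragments)
  expect_equal(unclass(d2)[, ], unclass(fast)[1:10, ], tolerance = 1e-9)

  expect_error(min_distance_matrix(tr, residue_groups = list(`0` = integer(0)),
                                   fragments = fr), "empty")
})

test_that("reciprocal_features floors at contact and preserves distance order", {
  d <- matrix(c(2, 0, 0.4, 10), 1, 4)
  f <- reciprocal_features(d, distance_floor = 0.5)
  expect_equal(as.numeric(f), c(0.5, 2.0, 2.0, 0.1))
  ## monotone: larger distance, smaller (or equal) feature
  d1 <- matrix(seq(0, 8, by = 0.25), 1)
  f1 <- as.numeric(reciprocal_features(d1))
  expect_true(all(diff(f1) <= 0))
  expect_true(all(f1 > 0 & f1 <= 2))
})

test_that("feature_pca separates planted two-state patterns on PC1", {
  set.seed(6)
  a <- rep(c(2, 0.3), 10); b <- rep(c(0.3, 2), 10)
  x <- rbind(
    matrix(rep(a, 40), 40, byrow = TRUE) + matrix(rnorm(800, sd = 0.05), 40),
    matrix(rep(b, 60), 60, byrow = TRUE) + matrix(rnorm(1200, sd = 0.05), 60)
  )
  fp <- feature_pca(x, 3)
  pc1 <- fp$projection[, 1]
  expect_true(max(pc1[1:40]) < min(pc1[41:100]) ||
                min(pc1[1:40]) > max(pc1[41:100]))
  ## trace identity and centered projection
  expect_lt(abs(sum(fp$model$eigenvalues) - fp$model$trace) /
              fp$model$trace, 1e-8)
  expect_lt(max(abs(colMeans(fp$projection))), 1e-10)
  ## constant matrix warns and projects to zero
  expect_warning(fp0 <- feature_pca(matrix(1, 10, 4), 2), "constant")
  expect_equal(max(abs(fp0$projection)), 0)
})

test_that("cluster_poses recovers planted poses with the Silhouette/DB rule", {
  ps <- make_pose_trajectory(n_frames = 800, seed = 7)
  dm <- min_distance_matrix(ps$traj, fragments = ps$fragments)
  fp <- feature_pca(reciprocal_features(dm), 3)
  res <- cluster_poses(fp$projection, 2:6, seed = 7)
  expect_equal(res$k, 3)
  expect_gte(adjusted_rand_index(res$labels, ps$labels), 0.95)
  ## the chosen k ranks first or second on Davies-Bouldin
  db_rank <- rank(res$metrics$davies_bouldin, ties.method = "min")
  expect_lte(db_rank[res$metrics$k == res$k], 2)
  ## determinism
  res2 <- cluster_poses(fp$projection, 2:6, seed = 7)
  expect_identical(res$labels, res2$labels)

  ## 80/20 occupancies recovered within 0.03
  ps2 <- make_pose_trajectory(n_frames = 1000, occupancies = c(0.8, 0.2),
                              seed = 12)
  dm2 <- min_distance_matrix(ps2$traj, fragments = ps2$fragments)
  fp2 <- feature_pca(reciprocal_features(dm2), 3)
  res2 <- cluster_poses(fp2$projection, 2:5, seed = 12)
  expect_equal(res2$k, 2)
  expect_equal(sort(res2$populations), c(0.2, 0.8), tolerance = 0.03 / 0.2)

  expect_error(cluster_poses(fp$projection, 1:3, seed = 1), "k candidates")
})

test_that("featurization clustering agrees with ligand-RMSD linkage clustering", {
  ps <- make_pose_trajectory(n_frames = 240, seed = 19)
  dm <- min_distance_matrix(ps$traj, fragments = ps$fragments)
  fp <- feature_pca(reciprocal_features(dm), 3)
  res <- cluster_poses(fp$projection, 2:5, seed = 19)

  ## oracle: superpose on protein, all-vs-all ligand RMSD, average linkage
  prot <- select_atoms(ps$traj$topology, "protein and heavy")
  ref <- ps$traj$frames[[1]]
  lig <- lapply(ps$traj$frames, function(f) {
    pocketdyn:::fit_frame(f, ref, prot$indices + 1)[ps$ligand_rows, ]
  })
  n <- length(lig)
  dmat <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dmat[i, j] <- dmat[j, i] <- sqrt(mean(rowSums((lig[[i]] - lig[[j]])^2)))
    }
  }
  hc <- stats::hclust(stats::as.dist(dmat), method = "average")
  oracle_labels <- stats::cutree(hc, k = res$k)
  expect_gte(adjusted_rand_index(res$labels, oracle_labels), 0.9)
})

test_that("silhouette implementation matches cluster::silhouette", {
  skip_if_not_installed("cluster")
  set.seed(14)
  x <- rbind(matrix(rnorm(90), 30, 3),
             sweep(matrix(rnorm(90), 30, 3), 2, c(6, 0, 0), `+`))
  labels <- rep(1:2, each = 30)
  ours <- pocketdyn:::silhouette_score(x, labels)
  ref <- mean(cluster::silhouette(labels, stats::dist(x))[, "sil_width"])
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("extract_representatives orders members and truncates correctly", {
  set.seed(2)
  x <- rbind(matrix(rnorm(30, sd = 0.1), 10, 3),
             sweep(matrix(rnorm(60, sd = 0.1), 20, 3), 2, c(9, 0, 0), `+`))
  res <- cluster_poses(x, 2:3, seed = 5)
  reps <- extract_representatives(res, x, n = 1000)
  ## small cluster returns all members
  expect_setequal(lengths(lapply(reps, `[[`, "representatives")),
                  c(10, 20))
  for (r in reps) {
    expect_true(all(diff(r$distance) >= 0))
    expect_equal(r$central, r$representatives[1])
  }
  ## symmetric 2-point cluster: tie broken toward the lower frame index
  res1 <- structure(list(labels = c(1L, 1L), k = 1L,
                         centers = matrix(c(0.5, 0, 0), 1)),
                    class = "pose_clusters")
  x2 <- rbind(c(0, 0, 0), c(1, 0, 0))
  reps1 <- extract_representatives(res1, x2, n = 2)
  expect_equal(reps1[[1]]$central, 1)
  ## truncation to n
  reps_n <- extract_representatives(res, x, n = 5)
  expect_true(all(lengths(lapply(reps_n, `[[`, "representatives")) <= 5))
})

test_that("pose featurization never builds a frames x frames object", {
  ## memory property at reduced scale: features stay O(frames x P)
  ps <- make_pose_trajectory(n_frames = 400, seed = 3)
  dm <- min_distance_matrix(ps$traj, fragments = ps$fragments)
  expect_equal(dim(dm), c(400, 20 * 3))
  fe <- reciprocal_features(dm)
  expect_equal(dim(fe), dim(dm))
  expect_true(all(fe > 0 & fe <= 2))
  expect_equal(nrow(attr(fe, "column_key")), ncol(fe))
})
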