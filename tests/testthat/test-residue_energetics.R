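## two-particle system with controllable parameters
two_atoms <- function(q = c(1, 1), sigma = c(0.3, 0.3), eps = c(0.5, 0.5),
                      r_nm = 1.0) {
  top <- topology(data.frame(
    atom_name = c("C1", "CA"), residue_name = c("LIG", "ALA"),
    residue_number = 1:2, chain_id = c("L", "A"), element = "C"
  ))
  top <- set_ff_params(top, q, sigma, eps)
  list(top = top, xyz = rbind(c(0, 0, 0), c(r_nm * 10, 0, 0)))
}

test_that("mm_interaction reproduces Coulomb and Lennard-Jones closed forms", {
  s <- two_atoms(q = c(1, 1), eps = c(0, 0), r_nm = 1.0)
  e <- mm_interaction(s$xyz, s$top, 0L, 1L)
  expect_equal(e[["coulomb"]], 138.935458, tolerance = 1e-9)
  expect_equal(e[["lj"]], 0)

  ## q-squared and 1/r scaling
  s2 <- two_atoms(q = c(2, 2), eps = c(0, 0), r_nm = 1.0)
  expect_equal(mm_interaction(s2$xyz, s2$top, 0L, 1L)[["coulomb"]],
               4 * e[["coulomb"]], tolerance = 1e-12)
  s3 <- two_atoms(q = c(1, 1), eps = c(0, 0), r_nm = 2.0)
  expect_equal(mm_interaction(s3$xyz, s3$top, 0L, 1L)[["coulomb"]],
               e[["coulomb"]] / 2, tolerance = 1e-12)

  ## LJ: zero at r = sigma, minimum -eps at r = 2^(1/6) sigma
  s4 <- two_atoms(q = c(0, 0), sigma = c(0.3, 0.3), eps = c(0.5, 0.5),
                  r_nm = 0.3)
  expect_equal(mm_interaction(s4$xyz, s4$top, 0L, 1L)[["lj"]], 0,
               tolerance = 1e-12)
  s5 <- two_atoms(q = c(0, 0), sigma = c(0.3, 0.3), eps = c(0.5, 0.5),
                  r_nm = 2^(1 / 6) * 0.3)
  expect_equal(mm_interaction(s5$xyz, s5$top, 0L, 1L)[["lj"]], -0.5,
               tolerance = 1e-12)

  ## clash and missing-parameter errors
  s6 <- two_atoms(r_nm = 0.04)
  expect_error(mm_interaction(s6$xyz, s6$top, 0L, 1L), "clash")
  s7 <- two_atoms(); s7$top$atoms$charge[2] <- NA
  expect_error(mm_interaction(s7$xyz, s7$top, 0L, 1L), "missing charge/LJ")
})

test_that("per-residue decomposition sums to the whole-interface MM energy", {
  ps <- make_pose_trajectory(n_frames = 5, seed = 7)
  top <- ps$traj$topology
  a <- top$atoms
  q <- numeric(nrow(a))
  q[a$molecule_tag == "protein" & a$atom_name == "CB"] <- 0.3
  q[a$molecule_tag == "protein" & a$atom_name == "CG"] <- -0.3
  q[a$molecule_tag != "protein"] <- rep_len(c(-0.15, -0.15, 0.3), 9)
  top <- set_ff_params(top, q, 0.25, 0.5)
  lig <- ps$ligand_rows - 1L
  frame <- ps$traj$frames[[1]]

  per_res <- vapply(0:19, function(r) {
    sum(mm_interaction(frame, top, lig, r))
  }, numeric(1))

  ## whole-interface double loop oracle
  f_c <- 138.935458
  lr <- ps$ligand_rows
  pr <- which(a$molecule_tag == "protein")
  total <- 0
  for (i in lr) for (j in pr) {
    r <- sqrt(sum((frame[i, ] - frame[j, ])^2)) / 10
    sig <- (top$atoms$lj_sigma[i] + top$atoms$lj_sigma[j]) / 2
    epsij <- sqrt(top$atoms$lj_epsilon[i] * top$atoms$lj_epsilon[j])
    sr6 <- (sig / r)^6
    total <- total + f_c * top$atoms$charge[i] * top$atoms$charge[j] / r +
      4 * epsij * (sr6^2 - sr6)
  }
  expect_equal(sum(per_res), total, tolerance = 1e-9)
  expect_lt(abs(sum(per_res) - total) / abs(total), 1e-6)
})

test_that("select_energy_frames enforces the nearest-first minimum-separation rule", {
  set.seed(7)
  ## 1000 consecutive frames in one cluster
  members <- 1:1000
  distance <- abs(members - 500) / 1000 + stats::runif(1000, 0, 1e-4)
  got <- select_energy_frames(members, distance, stride = 20, count = 20)
  expect_length(got, 20)
  expect_true(all(abs(outer(got, got, `-`))[lower.tri(matrix(0, 20, 20))] >=
                    20))
  ## nearest-first: the closest member is always taken
  expect_equal(got[1], members[which.min(distance)])

  ## tiny cluster returns everything admissible with a warning
  five <- c(10L, 50L, 90L, 130L, 170L)
  expect_warning(all5 <- select_energy_frames(five, c(3, 1, 2, 5, 4),
                                              stride = 20, count = 20),
                 "only 5")
  expect_setequal(all5, five)
  ## consecutive frames collapse to one representative under the stride
  expect_warning(one <- select_energy_frames(1:5, c(3, 1, 2, 5, 4),
                                             stride = 20, count = 20),
                 "only 1")
  expect_equal(one, 2L)

  ## stride 1 degenerates to the 20 nearest
  d <- stats::runif(100)
  near <- select_energy_frames(1:100, d, stride = 1, count = 20)
  expect_equal(sort(near), sort(order(d)[1:20]))

  ## determinism
  expect_identical(select_energy_frames(members, distance, 20, 20), got)
})

test_that("decompose_clusters isolates planted interactions and scales linearly", {
  ## ligand close to exactly one residue: everything else ~ 0
  atoms <- rbind(
    data.frame(atom_name = "CG", residue_name = "ALA",
               residue_number = 1:6, chain_id = "A", element = "C"),
    data.frame(atom_name = "C1", residue_name = "LIG", residue_number = 10,
               chain_id = "L", element = "C")
  )
  top <- topology(atoms)
  ## residue 1 charged, all others neutral; ligand charged
  top <- set_ff_params(top, c(-0.3, 0, 0, 0, 0, 0, 0.3), 0.25, c(rep(0, 6), 0))
  xyz <- rbind(cbind(seq(0, 100, by = 20), 0, 0), c(3, 0, 0))
  tr <- trajectory(top, list(xyz, xyz, xyz))
  res <- structure(list(labels = c(1L, 1L, 1L), k = 1L,
                        centers = matrix(0, 1, 3), populations = 1,
                        status = "ok"),
                   class = "pose_clusters")
  proj <- matrix(0, 3, 3)
  dec <- suppressWarnings(
    decompose_clusters(tr, res, proj, 6L, stride = 1, count = 3)
  )
  tab <- dec$table
  expect_lt(max(abs(tab$total[tab$residue_number != 1])), 0.01)
  expect_lt(tab$total[tab$residue_number == 1], -30)
  ## total = coulomb + lj identity
  expect_equal(tab$total, tab$coulomb + tab$lj, tolerance = 1e-9)

  ## doubling ligand charges doubles every Coulomb contribution
  top2 <- top; top2$atoms$charge[7] <- 0.6
  tr2 <- tr; tr2$topology <- top2
  dec2 <- suppressWarnings(
    decompose_clusters(tr2, res, proj, 6L, stride = 1, count = 3)
  )
  expect_equal(dec2$table$coulomb, 2 * tab$coulomb, tolerance = 1e-12)
})

test_that("a planted tight binder shows several favourable residues; filtering bands them", {
  ## 4 residues ringed about a central charged ligand atom at 3 A
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 0, 1), c(0, 0, -1))
  atoms <- rbind(
    data.frame(atom_name = "CG", residue_name = "ALA",
               residue_number = 1:6, chain_id = "A", element = "C"),
    data.frame(atom_name = "C1", residue_name = "LIG", residue_number = 10,
               chain_id = "L", element = "C")
  )
  top <- topology(atoms)
  top <- set_ff_params(top, c(rep(-0.25, 4), 0, 0, 0.25), 0.25, 0.3)
  xyz <- rbind(3 * dirs, c(40, 0, 0), c(45, 0, 0), c(0, 0, 0))
  tr <- trajectory(top, list(xyz, xyz))
  res <- structure(list(labels = c(1L, 1L), k = 1L,
                        centers = matrix(0, 1, 3), populations = 1,
                        status = "ok"),
                   class = "pose_clusters")
  dec <- suppressWarnings(
    decompose_clusters(tr, res, matrix(0, 2, 3), 6L, stride = 1, count = 2)
  )
  strong <- filter_contributors(dec, threshold = -4)
  expect_gte(sum(strong$noncharged$total <= -5), 4)

  ## boundary: exactly -4 is included; bands follow the -10 / -5 rule
  fake <- structure(list(table = data.frame(
    cluster = 1, residue_index = 0:3, residue_number = 1:4,
    residue_name = c("ALA", "SER", "ASP", "TRP"),
    coulomb = c(-4, -11, -20, 2), lj = 0,
    total = c(-4, -11, -20, 2),
    charge_class = c("noncharged", "noncharged", "charged", "noncharged")
  )), class = "energy_decomposition")
  rep_ <- filter_contributors(fake, threshold = -4)
  expect_equal(rep_$noncharged$residue_name, c("SER", "ALA"))
  expect_equal(rep_$noncharged$band, c("strong", "weak"))
  ## charged residues are reported, never dropped
  expect_equal(rep_$charged$residue_name, "ASP")
  ## all-positive decomposition -> empty report
  fake2 <- fake
  fake2$table$total <- abs(fake2$table$total)
  expect_equal(nrow(filter_contributors(fake2)$noncharged), 0)
})
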