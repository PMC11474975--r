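## Shared fixture builders for the test suite.  Everything is generated in
## code; no binary fixtures on disk.

## minimal peptide topology: n_res alanine-like residues, backbone + CB
toy_peptide <- function(n_res = 2, chain = "A") {
  atoms <- do.call(rbind, lapply(seq_len(n_res), function(i) {
    data.frame(
      atom_name = c("N", "CA", "C", "O", "CB"),
      residue_name = "ALA", residue_number = i, chain_id = chain,
      element = c("N", "C", "C", "O", "C")
    )
  }))
  topology(atoms)
}

toy_peptide_coords <- function(n_res = 2) {
  do.call(rbind, lapply(seq_len(n_res), function(i) {
    base <- c(3.8 * i, 0, 0)
    rbind(base + c(0, 0, 0), base + c(1.4, 0, 0), base + c(2.1, 1.2, 0),
          base + c(2.1, 2.4, 0), base + c(1.4, -1.0, 1.0))
  }))
}

## single water molecule topology
toy_water <- function() {
  topology(data.frame(
    atom_name = c("OW", "HW1", "HW2"), residue_name = "SOL",
    residue_number = 1, chain_id = "W", element = c("O", "H", "H")
  ))
}

random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

## brute-force rotation search: best RMSD over an Euler-angle grid, refined
## twice around the incumbent; independent oracle for the Kabsch fit
grid_search_rmsd <- function(mobile, reference) {
  cm <- colMeans(mobile); cr <- colMeans(reference)
  mm <- sweep(mobile, 2, cm); rr <- sweep(reference, 2, cr)
  rot_zyz <- function(a, b, g) {
    rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0,
                               0, 0, 1), 3, 3, byrow = TRUE)
    ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0,
                               -sin(t), 0, cos(t)), 3, 3, byrow = TRUE)
    rz(a) %*% ry(b) %*% rz(g)
  }
  eval_rmsd <- function(a, b, g) {
    sqrt(mean(rowSums((mm %*% t(rot_zyz(a, b, g)) - rr)^2)))
  }
  best <- c(0, 0, 0); best_r <- eval_rmsd(0, 0, 0)
  step <- pi / 12                      # 15 degrees
  grid <- list(a = seq(-pi, pi, by = step),
               b = seq(0, pi, by = step),
               g = seq(-pi, pi, by = step))
  for (a in grid$a) for (b in grid$b) for (g in grid$g) {
    r <- eval_rmsd(a, b, g)
    if (r < best_r) { best_r <- r; best <- c(a, b, g) }
  }
  for (step in c(pi / 72, pi / 360)) { # 2.5 then 0.5 degrees
    rng <- seq(-6 * step, 6 * step, by = step)
    cur <- best
    for (da in rng) for (db in rng) for (dg in rng) {
      r <- eval_rmsd(cur[1] + da, cur[2] + db, cur[3] + dg)
      if (r < best_r) { best_r <- r; best <- cur + c(da, db, dg) }
    }
  }
  best_r
}
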