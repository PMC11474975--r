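##
## Deterministic synthetic systems: the test bed standing in for MD data.
## Each generator returns an in-memory trajectory plus machine-readable
## ground truth; identical (parameters, seed) give bit-identical output.
##

#' Attach force-field parameters to a topology
#'
#' @param top a topology.
#' @param charge per-atom charges (e).
#' @param lj_sigma per-atom LJ sigma (nm).
#' @param lj_epsilon per-atom LJ epsilon (kJ/mol).
#' @return the topology with parameter columns set.
#' @export
set_ff_params <- function(top, charge, lj_sigma, lj_epsilon) {
  n <- n_atoms(top)
  top$atoms$charge <- rep_len(charge, n)
  top$atoms$lj_sigma <- rep_len(lj_sigma, n)
  top$atoms$lj_epsilon <- rep_len(lj_epsilon, n)
  top
}

#' Project out rigid-body components of a displacement field
#'
#' Removes the components of \code{v} along the 3 translations and the 3
#' infinitesimal rotations about the centroid of \code{base}, leaving a pure
#' deformation.  Useful for planting collective modes that superposition
#' fitting cannot absorb.
#'
#' @param base n x 3 reference coordinates.
#' @param v n x 3 displacement field.
#' @return n x 3 displacement with rigid components removed.
#' @export
remove_rigid_modes <- function(base, v) {
  n <- nrow(base)
  ctr <- sweep(base, 2, colMeans(base))
  rigid <- cbind(
    as.vector(t(cbind(rep(1, n), 0, 0))),
    as.vector(t(cbind(0, rep(1, n), 0))),
    as.vector(t(cbind(0, 0, rep(1, n)))),
    as.vector(t(cbind(0, -ctr[, 3], ctr[, 2]))),   # rotation about x
    as.vector(t(cbind(ctr[, 3], 0, -ctr[, 1]))),   # rotation about y
    as.vector(t(cbind(-ctr[, 2], ctr[, 1], 0)))    # rotation about z
  )
  q <- qr.Q(qr(rigid))
  vf <- as.vector(t(v))
  vf <- vf - q %*% crossprod(q, vf)
  matrix(vf, ncol = 3, byrow = TRUE)
}

## ligand template: n_frag triangle rings (3 atoms, side 1.5 A) linked by
## single 1.5 A bonds -> default_fragments recovers exactly n_frag fragments
ligand_rod_coords <- function(n_frag = 3) {
  v <- rbind(c(-0.75, 0, -0.433), c(0.75, 0, -0.433), c(0, 0, 0.866))
  do.call(rbind, lapply(seq_len(n_frag) - 1, function(i) {
    sweep(v, 2, c(3 * i, 0, 0), `+`)
  }))
}

#' Planted-pose protein-ligand trajectory
#'
#' A toy receptor -- \code{n_residues} residues on a ring (backbone N/CA/C/O
#' plus two inward-pointing side-chain carbons) -- with a rod ligand of
#' \code{n_fragments} linked 3-atom rings.  Each frame sits in one of
#' \code{length(occupancies)} planted poses: the ligand is placed against
#' that pose's arc of contact residues (side-chain distances < 4 Angstrom)
#' and > 8 Angstrom from all other residues.  The pose sequence is built
#' from dwell blocks with exact per-pose block counts, shuffled under the
#' seed, so the label histogram matches the occupancies up to block
#' granularity.  Gaussian coordinate noise of sd \code{noise_sigma} is added
#' everywhere.
#'
#' @param n_frames frames to generate.
#' @param occupancies per-pose fractions, summing to 1.
#' @param noise_sigma Angstrom.
#' @param n_residues receptor size (>= 4 * poses recommended).
#' @param n_fragments ligand fragments.
#' @param dwell frames per dwell block.
#' @param seed RNG seed.
#' @return list: \code{traj}, \code{labels} (planted pose per frame),
#'   \code{fragments} (ground-truth \code{fragment_scheme}),
#'   \code{contact_residues} (list of residue_index vectors per pose),
#'   \code{ligand_rows} (1-based atom rows of the ligand).
#' @export
make_pose_trajectory <- function(n_frames = 3000,
                                 occupancies = c(1, 1, 1) / 3,
                                 noise_sigma = 0.2, n_residues = 20,
                                 n_fragments = 3, dwell = 10, seed = 7) {
  if (abs(sum(occupancies) - 1) > 1e-9 || any(occupancies <= 0)) {
    stop_pd("make_pose_trajectory(): occupancies must be positive and sum to 1")
  }
  n_poses <- length(occupancies)
  ring_r <- 25
  theta <- 2 * pi * (seq_len(n_residues) - 1) / n_residues
  ## backbone + side chain, all in the ring plane (y = 0), side chain inward
  res_atoms <- function(i) {
    u <- c(cos(theta[i]), 0, sin(theta[i]))
    ca <- ring_r * u
    rbind(ca + c(0, 1.2, 0),       # N
          ca,                      # CA
          ca + c(0, -1.2, 0),      # C
          ca + c(0, -2.4, 0),      # O
          (ring_r - 2) * u,        # CB
          (ring_r - 3.5) * u)      # CG
  }
  prot_xyz <- do.call(rbind, lapply(seq_len(n_residues), res_atoms))
  prot_atoms <- data.frame(
    atom_name = rep(c("N", "CA", "C", "O", "CB", "CG"), n_residues),
    residue_name = "ALA",
    residue_number = rep(seq_len(n_residues), each = 6),
    chain_id = "A",
    element = rep(c("N", "C", "C", "O", "C", "C"), n_residues)
  )
  lig0 <- ligand_rod_coords(n_fragments)
  lig_atoms <- data.frame(
    atom_name = paste0("C", seq_len(nrow(lig0))),
    residue_name = "LIG", residue_number = 1, chain_id = "L", element = "C"
  )
  top <- topology(rbind(prot_atoms, lig_atoms))
  lig_rows <- nrow(prot_atoms) + seq_len(nrow(lig0))
  ## contact arcs: 3 consecutive residues per pose, arcs spread evenly
  arc_start <- floor((seq_len(n_poses) - 1) * n_residues / n_poses) + 1L
  contacts <- lapply(arc_start, function(s) ((s - 1):(s + 1)) %% n_residues + 1L)
  if (anyDuplicated(unlist(contacts))) {
    stop_pd("make_pose_trajectory(): contact arcs overlap; increase n_residues")
  }
  ## ligand placement per pose: centered on the arc's middle residue, rod
  ## tangential, pulled in just inside the CG shell
  pose_coords <- lapply(seq_len(n_poses), function(p) {
    mid <- contacts[[p]][2]
    u <- c(cos(theta[mid]), 0, sin(theta[mid]))     # radial
    tangent <- c(-sin(theta[mid]), 0, cos(theta[mid]))
    center <- (ring_r - 7) * u
    span <- lig0[, 1] - mean(lig0[, 1])
    sweep(outer(span, tangent) + lig0[, 2] %o% c(0, 1, 0) +
            lig0[, 3] %o% u, 2, center, `+`)
  })
  ## exact-count dwell blocks, shuffled
  n_blocks <- ceiling(n_frames / dwell)
  counts <- floor(occupancies * n_blocks)
  rem <- n_blocks - sum(counts)
  if (rem > 0) {
    top_up <- order(occupancies * n_blocks - counts, decreasing = TRUE)
    counts[top_up[seq_len(rem)]] <- counts[top_up[seq_len(rem)]] + 1L
  }
  with_seed(seed, {
    blocks <- sample(rep(seq_len(n_poses), counts))
    labels <- rep(blocks, each = dwell)[seq_len(n_frames)]
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      xyz <- rbind(prot_xyz, pose_coords[[labels[f]]])
      frames[[f]] <- xyz + matrix(stats::rnorm(length(xyz),
                                               sd = noise_sigma),
                                  nrow(xyz), 3)
    }
  })
  frag_groups <- split(lig_rows, rep(seq_len(n_fragments), each = 3))
  list(traj = trajectory(top, frames, time = (seq_len(n_frames) - 1) * 0.1),
       labels = labels,
       fragments = fragment_scheme(frag_groups),
       contact_residues = lapply(contacts, function(x) x - 1L),
       ligand_rows = lig_rows)
}

#' Analytic channel trajectory
#'
#' Atom rings are placed on the envelope of the inscribed spheres of radius
#' R(y) + vdW centered on the Y axis (ring height t - F F', ring radius
#' F sqrt(1 - F'^2) with F = R + vdW), so the largest sphere that fits at
#' height y without touching any atom's van der Waals surface has radius
#' exactly R(y) -- for a cylinder this reduces to rings of radius R + vdW.
#' Requires |R'(y)| < 1.  Optional breathing: R(y, t) = R(y) + amplitude *
#' sin(2 pi t / period).
#'
#' @param radius_fun function(y) -> pore radius (Angstrom), positive on the
#'   range.
#' @param axis_range c(lo, hi) Angstrom; rings extend one spacing beyond.
#' @param ring_spacing axial ring separation (Angstrom).
#' @param vdw atom van der Waals radius (Angstrom).
#' @param n_frames frames.
#' @param breathing_amplitude,breathing_period optional time modulation
#'   (Angstrom, frames).
#' @return list: \code{traj} (atoms carry \code{vdw_radius}),
#'   \code{radius_fun}, and \code{radius_at(y, frame)} giving the analytic
#'   truth per frame.
#' @export
make_channel <- function(radius_fun, axis_range = c(2.5, 20),
                         ring_spacing = 1, vdw = 1.5, n_frames = 1,
                         breathing_amplitude = 0, breathing_period = 10) {
  ys <- seq(axis_range[1] - ring_spacing, axis_range[2] + ring_spacing,
            by = ring_spacing)
  if (any(vapply(ys, radius_fun, numeric(1)) <= 0)) {
    stop_pd("make_channel(): radius function must be positive on the range")
  }
  rmod <- function(y, f) {
    radius_fun(y) + breathing_amplitude *
      sin(2 * pi * (f - 1) / breathing_period)
  }
  ## envelope ring geometry at sphere parameter t for frame f
  ring_geom <- function(t, f) {
    h <- 1e-4
    fv <- rmod(t, f) + vdw
    fp <- (rmod(t + h, f) - rmod(t - h, f)) / (2 * h)
    if (abs(fp) >= 1) stop_pd("make_channel(): |R'(y)| must be < 1")
    c(y = t - fv * fp, rho = fv * sqrt(1 - fp^2))
  }
  ## atom count per ring fixed across frames (sized for the widest breath)
  n_per_ring <- vapply(ys, function(t) {
    rho_max <- ring_geom(t, 1)["rho"] + abs(breathing_amplitude)
    max(8, ceiling(2 * pi * rho_max))   # <= 1 A arc spacing
  }, numeric(1))
  build <- function(f) {
    do.call(rbind, lapply(seq_along(ys), function(i) {
      g <- ring_geom(ys[i], f)
      phi <- 2 * pi * (seq_len(n_per_ring[i]) - 1) / n_per_ring[i]
      cbind(g["rho"] * cos(phi), g["y"], g["rho"] * sin(phi))
    }))
  }
  xyz0 <- build(1)
  atoms <- data.frame(
    atom_name = "C", residue_name = "ALA",
    residue_number = rep(seq_along(ys), n_per_ring),
    chain_id = "A", element = "C"
  )
  atoms$vdw_radius <- vdw
  top <- topology(atoms)
  frames <- lapply(seq_len(n_frames), function(f) {
    if (breathing_amplitude == 0 && f > 1) return(xyz0)
    build(f)
  })
  list(traj = trajectory(top, frames),
       radius_fun = radius_fun,
       radius_at = rmod)
}

#' Water box with scheduled site occupancy
#'
#' One site atom (a tyrosine hydroxyl oxygen at the origin) surrounded by
#' \code{n_waters} three-site waters.  Per frame, the schedule places
#' \code{inner[f]} water oxygens strictly inside the lower cutoff and
#' \code{mid[f]} between the cutoffs; the rest sit outside the upper cutoff.
#' A 0.2 Angstrom guard band keeps jittered oxygens away from both cutoffs,
#' so the expected occupancy table is exact.
#'
#' @param n_frames frames.
#' @param n_waters waters in the box.
#' @param inner,mid per-frame counts (recycled) inside the lower cutoff and
#'   between the cutoffs.
#' @param cutoffs two ascending cutoffs (Angstrom), default c(3.0, 3.5).
#' @param seed RNG seed.
#' @return list: \code{traj}, \code{site} ("A:1:OH"), \code{expected}
#'   (data.frame site, cutoff, mean), \code{cutoffs}.
#' @export
make_waterbox <- function(n_frames = 100, n_waters = 20, inner = 1, mid = 0,
                          cutoffs = c(3.0, 3.5), seed = 11) {
  guard <- 0.2
  inner <- rep_len(inner, n_frames)
  mid <- rep_len(mid, n_frames)
  if (any(inner + mid > n_waters)) stop_pd("make_waterbox(): schedule exceeds n_waters")
  bands <- rbind(c(2.4, cutoffs[1] - guard),
                 c(cutoffs[1] + guard, cutoffs[2] - guard),
                 c(cutoffs[2] + guard, 9.0))
  if (any(bands[, 2] <= bands[, 1])) stop_pd("make_waterbox(): cutoffs leave no room for the guard band")
  site_atoms <- data.frame(atom_name = "OH", residue_name = "TYR",
                           residue_number = 1, chain_id = "A", element = "O")
  wat_atoms <- data.frame(
    atom_name = rep(c("OW", "HW1", "HW2"), n_waters),
    residue_name = "SOL",
    residue_number = rep(seq_len(n_waters) + 1L, each = 3),
    chain_id = "W",
    element = rep(c("O", "H", "H"), n_waters)
  )
  top <- topology(rbind(site_atoms, wat_atoms))
  with_seed(seed, {
    frames <- lapply(seq_len(n_frames), function(f) {
      band_of <- rep(3L, n_waters)
      if (inner[f] > 0) band_of[seq_len(inner[f])] <- 1L
      if (mid[f] > 0) band_of[inner[f] + seq_len(mid[f])] <- 2L
      xyz <- matrix(0, 1 + 3 * n_waters, 3)
      for (w in seq_len(n_waters)) {
        b <- bands[band_of[w], ]
        r <- stats::runif(1, b[1], b[2])
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        o <- r * u
        rows <- 1 + (w - 1) * 3 + 1:3
        xyz[rows[1], ] <- o
        xyz[rows[2], ] <- o + c(0.96, 0, 0)
        xyz[rows[3], ] <- o + c(-0.24, 0.93, 0)
      }
      xyz
    })
  })
  expected <- data.frame(
    site = "A:1:OH",
    cutoff = cutoffs,
    mean = round(c(mean(inner), mean(inner + mid)), 2)
  )
  list(traj = trajectory(top, frames), site = "A:1:OH", expected = expected,
       cutoffs = cutoffs)
}

#' Harmonic ensemble with known fluctuations
#'
#' Atoms (one CA per residue, on a helix) jitter isotropically about fixed
#' positions with per-atom sd \code{sigma}; expected RMSF_i = sqrt(3) *
#' sigma_i.  Optionally a planted collective mode: frame displacements
#' a_f * v with a_f ~ N(0, mode_amplitude^2), for PCA-recovery tests.
#'
#' @param n_atoms atoms.
#' @param n_frames frames.
#' @param sigma per-atom jitter sd (Angstrom), recycled.
#' @param mode optional unit 3N displacement vector (matrix n_atoms x 3 or
#'   NULL); \code{"bend"} builds one.
#' @param mode_amplitude sd of the mode coordinate (Angstrom).
#' @param seed RNG seed.
#' @return list: \code{traj}, \code{expected_rmsf} (per atom, isotropic part
#'   only), \code{mode} (unit n_atoms x 3 matrix or NULL), \code{base}.
#' @export
make_harmonic <- function(n_atoms = 50, n_frames = 2000, sigma = 0.5,
                          mode = NULL, mode_amplitude = 0, seed = 3) {
  sigma <- rep_len(sigma, n_atoms)
  t_ <- seq_len(n_atoms)
  base <- cbind(4 * cos(t_ / 2), 1.5 * t_, 4 * sin(t_ / 2))
  if (identical(mode, "bend")) {
    mode <- cbind(sin(pi * t_ / n_atoms), 0 * t_,
                  cos(pi * t_ / n_atoms) - 0.5)
  }
  if (!is.null(mode)) {
    ## make the planted mode orthogonal to the 6 rigid-body motions so
    ## least-squares fitting leaves it intact and PCA can recover it exactly
    mode <- remove_rigid_modes(base, mode)
    mode <- mode / sqrt(sum(mode^2))
  }
  atoms <- data.frame(atom_name = "CA", residue_name = "ALA",
                      residue_number = t_, chain_id = "A", element = "C")
  top <- topology(atoms)
  with_seed(seed, {
    amps <- if (is.null(mode)) numeric(n_frames)
            else stats::rnorm(n_frames, sd = mode_amplitude)
    frames <- lapply(seq_len(n_frames), function(f) {
      base + (if (is.null(mode)) 0 else amps[f] * mode) +
        matrix(stats::rnorm(3 * n_atoms), n_atoms, 3) * sigma
    })
  })
  list(traj = trajectory(top, frames),
       expected_rmsf = sqrt(3) * sigma, mode = mode, base = base)
}
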