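##
## HOLE-style channel-radius profiling: per-slice largest inscribed sphere
## along a fixed axis (canonical Y), found by an annealed Monte-Carlo search
## in each slice plane, marching outward from a seed point.
##

## Bondi van der Waals radii (Angstrom); HOLE's AMBER-derived defaults differ
## slightly -- documented deviation.
.bondi_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
                  F = 1.47, CL = 1.75, BR = 1.85, SE = 1.90)

vdw_radii_for <- function(top, rows, table = .bondi_radii) {
  a <- top$atoms
  r <- if (!is.null(a$vdw_radius)) a$vdw_radius[rows] else rep(NA_real_, length(rows))
  miss <- is.na(r)
  r[miss] <- table[a$element[rows][miss]]
  if (anyNA(r)) stop_pd("no van der Waals radius for element '%s'",
                        a$element[rows][is.na(r)][1])
  unname(r)
}

## rotation matrix sending unit vector a onto unit vector b (Rodrigues)
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (abs(c_ + 1) < 1e-12) {           # antiparallel: rotate pi about any normal
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * a) * a; v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Reorient a trajectory so a channel axis is parallel to Y
#'
#' Rotates the reference so \code{axis_hint} becomes the +Y direction, then
#' Kabsch-fits every frame onto the reoriented reference on C-alpha atoms
#' (whole-frame transform).
#'
#' @param traj a trajectory.
#' @param reference N x 3 reference coordinates; defaults to frame 1.
#' @param axis_hint length-3 vector, or 2 x 3 matrix of two points (bottom,
#'   top) defining the channel axis.
#' @param fit_selection selection used for the per-frame fit; default C-alpha
#'   (falls back to all atoms when the system has no CA, e.g. synthetic
#'   channels).
#' @return the aligned trajectory; the rotated reference is attached as
#'   attribute \code{"reference"}.
#' @export
align_gorge_axis <- function(traj, reference = NULL, axis_hint,
                             fit_selection = NULL) {
  reference <- reference %||% traj$frames[[1]]
  if (is.matrix(axis_hint)) axis_hint <- axis_hint[2, ] - axis_hint[1, ]
  if (sqrt(sum(axis_hint^2)) < 1e-12) stop_pd("align_gorge_axis(): zero-length axis hint")
  rot <- rotation_between(axis_hint, c(0, 1, 0))
  ref_rot <- reference %*% t(rot)
  if (is.null(fit_selection)) {
    ca <- which(traj$topology$atoms$atom_name == "CA" &
                  traj$topology$atoms$molecule_tag == "protein")
    rows <- if (length(ca) >= 3) ca else seq_len(n_atoms(traj$topology))
  } else {
    rows <- sel_rows(fit_selection)
  }
  frames <- lapply(traj$frames, fit_frame, reference = ref_rot,
                   fit_rows = rows)
  out <- trajectory(traj$topology, frames, time = traj$time,
                    provenance = traj$provenance)
  attr(out, "reference") <- ref_rot
  out
}

## annealed MC maximisation of the pore radius in one slice plane.
## Returns c(radius, x, z).  step halves after 50 consecutive rejections.
mc_slice_search <- function(xz0, y, xyz, vdw, mc_steps, step_size) {
  dy2 <- (xyz[, 2] - y)^2
  pore <- function(x, z) {
    min(sqrt((xyz[, 1] - x)^2 + dy2 + (xyz[, 3] - z)^2) - vdw)
  }
  cx <- xz0[1]; cz <- xz0[2]
  best <- pore(cx, cz)
  rej <- 0L; step <- step_size
  prop <- matrix(stats::rnorm(2L * mc_steps, sd = 1), mc_steps, 2)
  for (s in seq_len(mc_steps)) {
    r <- pore(cx + prop[s, 1] * step, cz + prop[s, 2] * step)
    if (r > best) {
      best <- r; cx <- cx + prop[s, 1] * step; cz <- cz + prop[s, 2] * step
      rej <- 0L
    } else {
      rej <- rej + 1L
      if (rej >= 50L) { step <- step / 2; rej <- 0L }
    }
  }
  c(best, cx, cz)
}

#' Per-slice channel radius of one frame
#'
#' Divides \code{axis_range} along Y into slices of \code{slice_thickness}
#' and, for each slice, maximises the pore radius r(c) = min_atoms(|c - atom|
#' - vdW) over the slice plane with an annealed Monte-Carlo walk
#' (\code{mc_steps} Gaussian proposals, accept on improvement, step halved
#' after 50 consecutive rejections).  Slices are processed marching outward
#' from the slice containing \code{seed_point}, each initialised at the
#' previous slice's optimum.
#'
#' @param coords N x 3 coordinates of the blocking atoms (Angstrom).
#' @param vdw per-atom van der Waals radii (Angstrom).
#' @param seed_point length-3 start point inside the channel.
#' @param axis_range c(lo, hi) along Y (Angstrom).
#' @param slice_thickness Angstrom.
#' @param mc_steps Monte-Carlo proposals per slice.
#' @param mc_step_size initial proposal standard deviation (Angstrom).
#' @param rng_seed seed for the proposal stream.
#' @param init_centers optional n_slices x 2 matrix of (x, z) starts per
#'   slice, replacing the outward march (used to warm-start from a previous
#'   profile, which makes the estimate monotone under atom deletion).
#' @return data.frame: \code{slice_center} (Y, Angstrom), \code{radius}
#'   (Angstrom, negative clamped to 0), \code{center_x}, \code{center_z}.
#' @export
slice_radius <- function(coords, vdw, seed_point, axis_range = c(2.5, 20),
                         slice_thickness = 0.5, mc_steps = 2000,
                         mc_step_size = 0.1, rng_seed = 1,
                         init_centers = NULL) {
  n_slices <- floor(round((axis_range[2] - axis_range[1]) / slice_thickness,
                          9))
  centers <- axis_range[1] + (seq_len(n_slices) - 0.5) * slice_thickness
  seed_slice <- which.min(abs(centers - seed_point[2]))
  out_r <- numeric(n_slices); out_c <- matrix(0, n_slices, 2)
  with_seed(rng_seed, {
    if (!is.null(init_centers)) {
      ## explicit per-slice starts (e.g. a previous run's optima)
      for (i in seq_len(n_slices)) {
        res <- mc_slice_search(init_centers[i, ], centers[i], coords, vdw,
                               mc_steps, mc_step_size)
        out_r[i] <- res[1]; out_c[i, ] <- res[2:3]
      }
    } else {
      prev_up <- c(seed_point[1], seed_point[3])
      for (i in seed_slice:n_slices) {
        res <- mc_slice_search(prev_up, centers[i], coords, vdw, mc_steps,
                               mc_step_size)
        out_r[i] <- res[1]; out_c[i, ] <- res[2:3]; prev_up <- res[2:3]
      }
      if (seed_slice > 1) {
        prev_dn <- out_c[seed_slice, ]
        for (i in (seed_slice - 1):1) {
          res <- mc_slice_search(prev_dn, centers[i], coords, vdw, mc_steps,
                                 mc_step_size)
          out_r[i] <- res[1]; out_c[i, ] <- res[2:3]; prev_dn <- res[2:3]
        }
      }
    }
  })
  if (out_r[seed_slice] < 0) warn_pd("slice_radius(): channel blocked at the seed slice; radius recorded as 0")
  data.frame(slice_center = centers, radius = pmax(out_r, 0),
             center_x = out_c[, 1], center_z = out_c[, 2])
}

#' Channel-radius profile of a trajectory
#'
#' Runs \code{\link{slice_radius}} on every frame (with a per-frame RNG
#' substream derived from \code{seed}) of a trajectory already aligned by
#' \code{\link{align_gorge_axis}}.  Blocking atoms default to protein atoms;
#' waters, ions and the ligand are excluded.
#'
#' @param traj aligned trajectory.
#' @param seed_atom either a length-3 point or a string
#'   \code{"chain:resnum:atomname"} (e.g. \code{"A:122:HA"}) naming the seed
#'   atom, whose reference-frame position seeds the search.
#' @param axis_range,slice_thickness,mc_steps,mc_step_size see
#'   \code{\link{slice_radius}}.
#' @param seed master RNG seed.
#' @param atom_rows 1-based rows of the blocking atoms; default protein.
#' @param vdw_table named per-element radii (Angstrom).
#' @return object of class \code{"gorge_profile"}: \code{radii} (frames x
#'   slices), \code{slice_center}, \code{centers} (list of per-frame slice
#'   center paths), plus the parameters.
#' @export
profile_trajectory <- function(traj, seed_atom, axis_range = c(2.5, 20),
                               slice_thickness = 0.5, mc_steps = 2000,
                               mc_step_size = 0.1, seed = 1,
                               atom_rows = NULL, vdw_table = .bondi_radii) {
  top <- traj$topology
  atom_rows <- atom_rows %||% which(top$atoms$molecule_tag == "protein")
  if (!length(atom_rows)) stop_pd("profile_trajectory(): no blocking atoms")
  vdw <- vdw_radii_for(top, atom_rows, vdw_table)
  if (is.character(seed_atom)) {
    parts <- strsplit(seed_atom, ":")[[1]]
    if (length(parts) != 3) stop_pd("seed_atom string must be 'chain:resnum:atomname'")
    hit <- which(top$atoms$chain_id == parts[1] &
                   top$atoms$residue_number == as.integer(parts[2]) &
                   top$atoms$atom_name == toupper(parts[3]))
    if (!length(hit)) stop_pd("profile_trajectory(): seed atom %s not found", seed_atom)
    seed_point <- traj$frames[[1]][hit[1], ]
  } else {
    seed_point <- as.numeric(seed_atom)
  }
  nf <- n_frames(traj)
  radii <- NULL; centers <- vector("list", nf)
  for (f in seq_len(nf)) {
    sr <- slice_radius(traj$frames[[f]][atom_rows, , drop = FALSE], vdw,
                       seed_point, axis_range, slice_thickness, mc_steps,
                       mc_step_size, rng_seed = subseed(seed, f))
    if (is.null(radii)) radii <- matrix(0, nf, nrow(sr))
    radii[f, ] <- sr$radius
    centers[[f]] <- cbind(sr$center_x, sr$center_z)
  }
  structure(list(radii = radii, slice_center = sr$slice_center,
                 centers = centers, axis_range = axis_range,
                 slice_thickness = slice_thickness, seed_point = seed_point,
                 atom_rows = atom_rows, vdw = vdw),
            class = "gorge_profile")
}

#' @export
print.gorge_profile <- function(x, ...) {
  cat(sprintf("gorge_profile: %d frames x %d slices, Y %.1f..%.1f A, radii %.2f..%.2f A\n",
              nrow(x$radii), ncol(x$radii), x$axis_range[1], x$axis_range[2],
              min(x$radii), max(x$radii)))
  invisible(x)
}

#' Per-slice radius percentiles
#' @param profile a \code{gorge_profile}.
#' @param probs percentiles.
#' @return data.frame of slice centers and radius quantiles.
#' @export
profile_percentiles <- function(profile, probs = c(0.05, 0.25, 0.5, 0.75,
                                                   0.95)) {
  q <- t(apply(profile$radii, 2, stats::quantile, probs = probs))
  out <- data.frame(slice_center = profile$slice_center, q)
  names(out)[-1] <- paste0("p", probs * 100)
  out
}

#' Axial position distribution of channel-lining residues
#'
#' A residue lines the channel surface in slice i of frame f when any of its
#' heavy atoms lies within (radius + vdW + contact_margin) of that slice's
#' optimal sphere center.  Returns hit counts per residue and slice, pooled
#' over frames.
#'
#' @param profile a \code{gorge_profile} from the same trajectory.
#' @param traj the aligned trajectory.
#' @param contact_margin Angstrom.
#' @return data.frame: residue_index, residue_number, residue_name,
#'   slice_center (axial position), count.
#' @export
residue_surface_positions <- function(profile, traj, contact_margin = 1.0) {
  top <- traj$topology
  rows <- profile$atom_rows
  ri <- top$atoms$residue_index[rows]
  hits <- list()
  for (f in seq_len(nrow(profile$radii))) {
    xyz <- traj$frames[[f]][rows, , drop = FALSE]
    for (i in seq_along(profile$slice_center)) {
      cen <- c(profile$centers[[f]][i, 1], profile$slice_center[i],
               profile$centers[[f]][i, 2])
      reach <- profile$radii[f, i] + profile$vdw + contact_margin
      d <- sqrt(rowSums(sweep(xyz, 2, cen)^2))
      res <- unique(ri[d <= reach])
      if (length(res)) {
        hits[[length(hits) + 1L]] <-
          data.frame(residue_index = res,
                     slice_center = profile$slice_center[i])
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(residue_index = integer(0), residue_number = integer(0),
                      residue_name = character(0), slice_center = numeric(0),
                      count = integer(0)))
  }
  all <- do.call(rbind, hits)
  agg <- stats::aggregate(cbind(count = rep(1L, nrow(all))) ~ residue_index +
                            slice_center, data = all, FUN = sum)
  a <- top$atoms[!duplicated(top$atoms$residue_index), ]
  agg$residue_number <- a$residue_number[match(agg$residue_index,
                                               a$residue_index)]
  agg$residue_name <- a$residue_name[match(agg$residue_index,
                                           a$residue_index)]
  agg[order(agg$residue_index, agg$slice_center),
      c("residue_index", "residue_number", "residue_name", "slice_center",
        "count")]
}
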