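##
## Molecular-mechanics protein-ligand interaction energies, decomposed per
## residue.  Only the vacuum MM terms (Coulomb + Lennard-Jones) are computed;
## Poisson-Boltzmann and surface-area solvation belong to an external solver
## and are out of scope, so the numbers here are "MM term" contributions,
## not full MM-PBSA binding energies.
##

.coulomb_f <- 138.935458  # kJ mol^-1 nm e^-2

.charged_resnames <- c("ASP", "GLU", "LYS", "ARG", "HIP")

check_params <- function(top, rows, what) {
  a <- top$atoms
  bad <- rows[is.na(a$charge[rows]) | is.na(a$lj_sigma[rows]) |
                is.na(a$lj_epsilon[rows])]
  if (is.null(a$charge) || is.null(a$lj_sigma) || is.null(a$lj_epsilon) ||
      length(bad)) {
    stop_pd("mm_interaction(): missing charge/LJ parameters for %s atoms (e.g. atom_index %s)",
            what, if (length(bad)) bad[1] - 1L else "all")
  }
}

#' MM interaction energy between a ligand and one residue
#'
#' Coulomb = f * sum q_i q_j / r_ij with f = 138.935458 kJ mol^-1 nm e^-2
#' and r in nm (vacuum dielectric); LJ = sum 4 eps_ij [(sig_ij/r)^12 -
#' (sig_ij/r)^6] with Lorentz-Berthelot combination (sigma arithmetic,
#' epsilon geometric mean).  All intermolecular pairs, no cutoff.
#'
#' @param frame N x 3 coordinates (Angstrom).
#' @param top topology carrying \code{charge} (e), \code{lj_sigma} (nm),
#'   \code{lj_epsilon} (kJ/mol).
#' @param ligand_sel atom selection (or 0-based indices) of the ligand.
#' @param residue residue_index (0-based) of the protein residue.
#' @return named numeric \code{c(coulomb = , lj = )} in kJ/mol.
#' @export
mm_interaction <- function(frame, top, ligand_sel, residue) {
  lig <- sel_rows(ligand_sel)
  res <- which(top$atoms$residue_index == residue)
  res <- setdiff(res, lig)
  if (!length(res)) stop_pd("mm_interaction(): residue_index %d has no atoms", residue)
  check_params(top, c(lig, res), "involved")
  a <- top$atoms
  ## r in nm
  pl <- frame[lig, , drop = FALSE] / 10
  pr <- frame[res, , drop = FALSE] / 10
  d2 <- outer(rowSums(pl^2), rowSums(pr^2), `+`) - 2 * tcrossprod(pl, pr)
  d2[d2 < 0] <- 0
  r <- sqrt(d2)
  if (any(r < 0.05)) stop_pd("mm_interaction(): clash (pair distance < 0.05 nm)")
  qq <- outer(a$charge[lig], a$charge[res])
  coulomb <- .coulomb_f * sum(qq / r)
  sig <- outer(a$lj_sigma[lig], a$lj_sigma[res], `+`) / 2
  eps <- sqrt(outer(a$lj_epsilon[lig], a$lj_epsilon[res]))
  sr6 <- (sig / r)^6
  lj <- sum(4 * eps * (sr6^2 - sr6))
  c(coulomb = coulomb, lj = lj)
}

#' Select energy frames from a pose cluster
#'
#' Walks the cluster members ranked by feature-space distance to the cluster
#' center and takes a member only if its trajectory index differs by at least
#' \code{stride} frames from every member already taken, stopping at
#' \code{count} -- the "closest to the central structure, evenly spaced"
#' rule for picking conformers that represent a local free-energy minimum
#' without sampling near-duplicates.
#'
#' @param members cluster member frame indices.
#' @param distance feature-space distance of each member to the center
#'   (same order).
#' @param stride minimum index separation between chosen frames.
#' @param count frames wanted.
#' @return integer frame indices, nearest-first; fewer than \code{count}
#'   (with a warning) when the cluster is too small.
#' @export
select_energy_frames <- function(members, distance, stride = 20, count = 20) {
  stopifnot(length(members) == length(distance), length(members) >= 1)
  ord <- order(distance, members)
  taken <- integer(0)
  for (i in ord) {
    if (all(abs(members[i] - taken) >= stride)) {
      taken <- c(taken, members[i])
      if (length(taken) == count) break
    }
  }
  if (length(taken) < count) {
    warn_pd("select_energy_frames(): only %d of %d frames available under the stride-%d rule",
            length(taken), count, stride)
  }
  taken
}

#' Per-residue MM energy decomposition over pose clusters
#'
#' For each cluster, averages \code{\link{mm_interaction}} over the frames
#' chosen by \code{\link{select_energy_frames}} for every protein residue.
#'
#' @param traj a trajectory.
#' @param result a \code{"pose_clusters"} with labels.
#' @param projection the feature-PC projection used for clustering.
#' @param ligand_sel ligand atom selection.
#' @param stride,count frame-selection parameters.
#' @param residues residue_index values to decompose; default all protein
#'   residues.
#' @return object of class \code{"energy_decomposition"}: data.frame
#'   \code{table} with cluster, residue_index, residue_number, residue_name,
#'   coulomb, lj, total (kJ/mol, means over selected frames), charge_class;
#'   \code{frames} (per-cluster frame lists); \code{per_frame} (list of
#'   per-cluster residue x frame total-energy matrices).
#' @export
decompose_clusters <- function(traj, result, projection, ligand_sel,
                               stride = 20, count = 20, residues = NULL) {
  if (is.null(result$labels)) stop_pd("decompose_clusters(): clustering has no labels")
  top <- traj$topology
  a <- top$atoms
  residues <- residues %||%
    sort(unique(a$residue_index[a$molecule_tag == "protein"]))
  reps <- extract_representatives(result, projection, n = length(result$labels))
  rows <- list(); frames_used <- list(); per_frame <- list()
  first <- a[!duplicated(a$residue_index), ]
  for (cl in seq_len(result$k)) {
    fr <- select_energy_frames(reps[[cl]]$representatives,
                               reps[[cl]]$distance, stride, count)
    frames_used[[cl]] <- fr
    mat_c <- matrix(0, length(residues), length(fr))
    mat_l <- matrix(0, length(residues), length(fr))
    for (j in seq_along(fr)) {
      for (i in seq_along(residues)) {
        e <- mm_interaction(traj$frames[[fr[j]]], top, ligand_sel,
                            residues[i])
        mat_c[i, j] <- e["coulomb"]; mat_l[i, j] <- e["lj"]
      }
    }
    rn <- first$residue_name[match(residues, first$residue_index)]
    rows[[cl]] <- data.frame(
      cluster = cl, residue_index = residues,
      residue_number = first$residue_number[match(residues,
                                                  first$residue_index)],
      residue_name = rn,
      coulomb = rowMeans(mat_c), lj = rowMeans(mat_l),
      total = rowMeans(mat_c) + rowMeans(mat_l),
      charge_class = ifelse(rn %in% .charged_resnames, "charged",
                            "noncharged")
    )
    per_frame[[cl]] <- mat_c + mat_l
  }
  structure(list(table = do.call(rbind, rows), frames = frames_used,
                 per_frame = per_frame,
                 populations = result$populations),
            class = "energy_decomposition")
}

#' @export
print.energy_decomposition <- function(x, ...) {
  cat(sprintf("energy_decomposition: %d clusters x %d residues\n",
              length(x$frames), length(unique(x$table$residue_index))))
  top <- x$table[order(x$table$total), ][seq_len(min(5, nrow(x$table))), ]
  print(top[, c("cluster", "residue_name", "residue_number", "coulomb",
                "lj", "total")], row.names = FALSE)
  invisible(x)
}

#' Filter energetically important residues
#'
#' Noncharged residues with mean total contribution at or below
#' \code{threshold} (default -4 kJ/mol), sorted most favourable first, with
#' interaction-strength bands: "strong" at or below -10 kJ/mol, "favorable"
#' at or below -5.  Charged residues are reported separately (their Coulomb
#' terms are unreliable without the solvation screening that is out of
#' scope), never silently dropped.
#'
#' @param decomp an \code{energy_decomposition}.
#' @param threshold kJ/mol (inclusive).
#' @return list: \code{noncharged} (filtered, with \code{band}),
#'   \code{charged} (all charged residues, unfiltered).
#' @export
filter_contributors <- function(decomp, threshold = -4) {
  tab <- decomp$table
  nc <- tab[tab$charge_class == "noncharged" & tab$total <= threshold, ]
  nc <- nc[order(nc$total), ]
  nc$band <- ifelse(nc$total <= -10, "strong",
                    ifelse(nc$total <= -5, "favorable", "weak"))
  ch <- tab[tab$charge_class == "charged", ]
  rownames(nc) <- NULL; rownames(ch) <- NULL
  list(noncharged = nc, charged = ch[order(ch$total), ])
}
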