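##
## Hydration-site water occupancy: waters counted at hydrogen-bonding
## distances (< 3.5 / < 3.0 Angstrom, strictly) of selected site atoms,
## averaged over a trajectory.  A water's position is its oxygen.
##

## resolve "chain:resnum:atomname" to a 1-based atom row
resolve_site_atom <- function(top, site) {
  if (is.numeric(site)) return(as.integer(site))
  parts <- strsplit(site, ":")[[1]]
  if (length(parts) != 3) stop_pd("site must be 'chain:resnum:atomname', got '%s'", site)
  hit <- which(top$atoms$chain_id == parts[1] &
                 top$atoms$residue_number == as.integer(parts[2]) &
                 top$atoms$atom_name == toupper(parts[3]))
  if (!length(hit)) stop_pd("site atom %s not found in topology", site)
  hit[1]
}

water_oxygen_rows <- function(top) {
  which(top$atoms$molecule_tag == "water" & top$atoms$element == "O")
}

#' Count waters near a site atom in one frame
#'
#' Number of distinct water molecules whose oxygen lies strictly closer than
#' \code{cutoff} to the site atom.  A coarse bounding-box prefilter is
#' applied before the exact distance test, so the count is bit-equal to the
#' naive loop.
#'
#' @param frame N x 3 coordinates (Angstrom).
#' @param top topology with waters tagged.
#' @param site atom row (1-based) or \code{"chain:resnum:atomname"}.
#' @param cutoff Angstrom (strict \code{<}).
#' @return integer count.
#' @export
count_waters <- function(frame, top, site, cutoff = 3.5) {
  wo <- water_oxygen_rows(top)
  if (!length(wo)) {
    warn_pd("count_waters(): no waters in the system")
    return(0L)
  }
  s <- resolve_site_atom(top, site)
  p <- frame[s, ]
  ox <- frame[wo, , drop = FALSE]
  ## prefilter: axis-aligned box of half-width cutoff
  near <- abs(ox[, 1] - p[1]) < cutoff & abs(ox[, 2] - p[2]) < cutoff &
    abs(ox[, 3] - p[3]) < cutoff
  if (!any(near)) return(0L)
  d2 <- rowSums(sweep(ox[near, , drop = FALSE], 2, p)^2)
  sum(d2 < cutoff^2)
}

## naive oracle for the tests
count_waters_brute <- function(frame, top, site, cutoff = 3.5) {
  wo <- water_oxygen_rows(top)
  s <- resolve_site_atom(top, site)
  n <- 0L
  for (w in wo) {
    if (sqrt(sum((frame[w, ] - frame[s, ])^2)) < cutoff) n <- n + 1L
  }
  n
}

#' Water occupancy table over a trajectory
#'
#' Mean number of waters within each cutoff of each site atom, averaged over
#' frames; per-frame counts are retained.
#'
#' @param traj a trajectory.
#' @param sites character vector of \code{"chain:resnum:atomname"} site
#'   atoms (optionally named with labels) or integer atom rows.
#' @param cutoffs Angstrom, positive ascending (default c(3.0, 3.5)).
#' @return object of class \code{"occupancy_table"}: data.frame
#'   \code{summary} (site, cutoff, mean rounded to 2 decimals) and
#'   \code{counts} (frames x (site, cutoff) integer matrix).
#' @export
occupancy_table <- function(traj, sites, cutoffs = c(3.0, 3.5)) {
  stopifnot(n_frames(traj) >= 1, all(diff(cutoffs) > 0), all(cutoffs > 0))
  top <- traj$topology
  labels <- names(sites) %||% as.character(sites)
  labels[!nzchar(labels)] <- as.character(sites)[!nzchar(labels)]
  rows <- vapply(sites, resolve_site_atom, integer(1), top = top)
  nf <- n_frames(traj)
  counts <- matrix(0L, nf, length(sites) * length(cutoffs))
  cn <- character(0)
  col <- 0
  for (i in seq_along(sites)) {
    for (cu in cutoffs) {
      col <- col + 1
      counts[, col] <- vapply(seq_len(nf), function(f) {
        count_waters(traj$frames[[f]], top, rows[i], cu)
      }, integer(1))
      cn <- c(cn, sprintf("%s@%.1f", labels[i], cu))
    }
  }
  colnames(counts) <- cn
  summary <- data.frame(
    site = rep(labels, each = length(cutoffs)),
    cutoff = rep(cutoffs, length(sites)),
    mean = round(colMeans(counts), 2)
  )
  structure(list(summary = summary, counts = counts),
            class = "occupancy_table")
}

#' @export
print.occupancy_table <- function(x, ...) {
  cat("occupancy_table:\n")
  print(x$summary)
  invisible(x)
}

#' Percent change in water occupancy between two tables
#'
#' change = (other - reference) / reference x 100 per (site, cutoff); a zero
#' reference yields NA with \code{undefined = TRUE} rather than an error.
#'
#' @param reference,other \code{occupancy_table}s sharing sites and cutoffs.
#' @return data.frame: site, cutoff, reference mean, other mean,
#'   percent_change, undefined flag.
#' @export
compare_occupancy <- function(reference, other) {
  a <- reference$summary; b <- other$summary
  if (!identical(a$site, b$site) || !identical(a$cutoff, b$cutoff)) {
    stop_pd("compare_occupancy(): tables have different sites or cutoffs")
  }
  undef <- a$mean == 0
  pc <- ifelse(undef, NA_real_, (b$mean - a$mean) / a$mean * 100)
  data.frame(site = a$site, cutoff = a$cutoff, reference = a$mean,
             other = b$mean, percent_change = pc, undefined = undef)
}
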