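##
## Binding-pose clustering from reciprocal residue-fragment minimum
## distances: the fast, superposition-free featurization of protein-ligand
## conformers.  Features are internal coordinates (1/min-distance, 1/Angstrom)
## so no fitting or RMSD matrix is ever needed; memory stays O(frames x P).
##

#' Fragment a ligand by cutting acyclic linker bonds
#'
#' Bonds are perceived by distance (heavy-heavy < 1.85 Angstrom, 2.1 to
#' S/Cl/Br), rings detected on the bond graph, and fragments are the
#' connected components left after cutting every acyclic single bond joining
#' two non-terminal heavy atoms where at least one side carries a ring or
#' >= 3 atoms.  Fragments are named F1..Fn in atom order.
#'
#' @param top ligand topology (or full topology; only \code{atom_rows} used).
#' @param coords N x 3 coordinates of the same atoms (Angstrom).
#' @param atom_rows 1-based rows of the ligand's heavy atoms; default: all
#'   non-hydrogen atoms of \code{top}.
#' @return object of class \code{"fragment_scheme"}: list \code{fragments} of
#'   (name, atom_rows), covering all ligand heavy atoms, pairwise disjoint.
#' @export
default_fragments <- function(top, coords, atom_rows = NULL) {
  heavy <- which(!is_hydrogen(top))
  atom_rows <- atom_rows %||% heavy
  if (length(atom_rows) < 2) stop_pd("default_fragments(): need >= 2 heavy atoms")
  xyz <- coords[atom_rows, , drop = FALSE]
  el <- top$atoms$element[atom_rows]
  n <- length(atom_rows)
  d <- as.matrix(stats::dist(xyz))
  cut_len <- matrix(1.85, n, n)
  soft <- el %in% c("S", "CL", "BR")
  cut_len[soft, ] <- 2.1
  cut_len[, soft] <- pmax(cut_len[, soft], 2.1)
  adj <- d < cut_len & upper.tri(d)
  edges <- which(adj, arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  if (igraph::components(g)$no > 1) {
    warn_pd("default_fragments(): ligand graph is disconnected; fragmenting components independently")
  }
  ## ring bonds = edges not bridges; cuttable = bridge between two
  ## non-terminal atoms where a side has a ring or >= 3 atoms
  bridges <- igraph::bridges(g)
  deg <- igraph::degree(g)
  cut <- integer(0)
  for (e in bridges) {
    vs <- igraph::ends(g, e)[1, ]
    if (any(deg[vs] < 2)) next
    g2 <- igraph::delete_edges(g, e)
    comp <- igraph::components(g2)
    side_sizes <- comp$csize[comp$membership[vs]]
    has_ring <- vapply(vs, function(v) {
      memb <- comp$membership == comp$membership[v]
      sub <- igraph::induced_subgraph(g2, which(memb))
      igraph::ecount(sub) >= igraph::vcount(sub)  # cycle present
    }, logical(1))
    if (any(has_ring) || any(side_sizes >= 3)) cut <- c(cut, e)
  }
  gf <- igraph::delete_edges(g, cut)
  memb <- igraph::components(gf)$membership
  ids <- unique(memb)  # in atom order
  frags <- lapply(seq_along(ids), function(i) {
    list(name = paste0("F", i), atom_rows = atom_rows[memb == ids[i]])
  })
  structure(list(fragments = frags), class = "fragment_scheme")
}

#' @export
print.fragment_scheme <- function(x, ...) {
  sizes <- vapply(x$fragments, function(f) length(f$atom_rows), integer(1))
  cat(sprintf("fragment_scheme: %d fragments (%s atoms)\n",
              length(x$fragments), paste(sizes, collapse = "/")))
  invisible(x)
}

#' Build a fragment scheme from explicit atom groups
#' @param groups named list of 1-based atom row vectors.
#' @return a \code{"fragment_scheme"}.
#' @export
fragment_scheme <- function(groups) {
  stopifnot(length(groups) >= 1, all(lengths(groups) > 0))
  if (anyDuplicated(unlist(groups))) stop_pd("fragment_scheme(): fragments must be disjoint")
  nms <- names(groups) %||% paste0("F", seq_along(groups))
  structure(list(fragments = Map(function(n, a) list(name = n, atom_rows = a),
                                 nms, groups)),
            class = "fragment_scheme")
}

## per-residue heavy-atom groups for the protein (1-based rows)
residue_heavy_groups <- function(top, residue_indices = NULL,
                                 atom_set = c("heavy", "main_chain")) {
  atom_set <- match.arg(atom_set)
  a <- top$atoms
  keep <- a$molecule_tag == "protein" &
    (if (atom_set == "heavy") a$element != "H"
     else a$atom_name %in% c("N", "CA", "C", "O"))
  ri <- sort(unique(a$residue_index[keep]))
  if (!is.null(residue_indices)) ri <- intersect(ri, residue_indices)
  groups <- lapply(ri, function(r) which(keep & a$residue_index == r))
  empty <- lengths(groups) == 0
  if (any(empty)) stop_pd("min_distance_matrix(): residue %d has no atoms in the '%s' set",
                          ri[empty][1], atom_set)
  names(groups) <- ri
  groups
}

#' Residue-fragment minimum-distance matrix
#'
#' For every frame, the minimum Euclidean distance between each residue group
#' (heavy atoms by default) and each ligand fragment.  Exact: the blocked
#' evaluation is bit-equal to the naive double loop.
#'
#' @param traj a trajectory.
#' @param residue_groups named list of 1-based atom row vectors per residue
#'   (see \code{residue_heavy_groups}); default: all protein residues, heavy
#'   atoms.
#' @param fragments a \code{"fragment_scheme"}.
#' @return frames x P matrix (Angstrom) with columns named
#'   \code{<residue>|<fragment>}; attribute \code{"column_key"} is a
#'   data.frame (residue_index, fragment).
#' @export
min_distance_matrix <- function(traj, residue_groups = NULL, fragments) {
  residue_groups <- residue_groups %||% residue_heavy_groups(traj$topology)
  if (any(lengths(residue_groups) == 0)) {
    stop_pd("min_distance_matrix(): empty residue group '%s'",
            names(residue_groups)[lengths(residue_groups) == 0][1])
  }
  frs <- fragments$fragments
  nr <- length(residue_groups); nf <- length(frs)
  lig_rows <- unlist(lapply(frs, `[[`, "atom_rows"))
  frag_of <- rep(seq_len(nf), vapply(frs, function(f) length(f$atom_rows),
                                     integer(1)))
  res_rows <- unlist(residue_groups)
  res_of <- rep(seq_len(nr), lengths(residue_groups))
  out <- matrix(0, n_frames(traj), nr * nf)
  res_split <- split(seq_along(res_rows), res_of)
  for (f in seq_len(n_frames(traj))) {
    xyz <- traj$frames[[f]]
    a <- xyz[res_rows, , drop = FALSE]
    ## squared distances one ligand atom at a time; the per-pair arithmetic
    ## (component differences squared, summed x,y,z) matches the naive loop
    ## exactly, and min() aggregation is order-free, so the result is
    ## bit-equal to brute force
    d2 <- matrix(0, length(res_rows), length(lig_rows))
    for (j in seq_along(lig_rows)) {
      b <- xyz[lig_rows[j], ]
      d2[, j] <- (a[, 1] - b[1])^2 + (a[, 2] - b[2])^2 + (a[, 3] - b[3])^2
    }
    grp <- matrix(0, length(res_rows), nf)
    for (j in seq_len(nf)) {
      cols <- which(frag_of == j)
      grp[, j] <- do.call(pmin, as.data.frame(d2[, cols, drop = FALSE]))
    }
    dmin <- matrix(Inf, nr, nf)
    for (i in seq_len(nr)) {
      dmin[i, ] <- apply(grp[res_split[[i]], , drop = FALSE], 2, min)
    }
    out[f, ] <- sqrt(as.vector(t(dmin)))
  }
  key <- data.frame(
    residue = rep(names(residue_groups), each = nf),
    fragment = rep(vapply(frs, `[[`, character(1), "name"), nr)
  )
  colnames(out) <- paste(key$residue, key$fragment, sep = "|")
  attr(out, "column_key") <- key
  out
}

## naive oracle used by the tests: explicit loops over pairs
min_distance_brute <- function(traj, residue_groups, fragments) {
  frs <- fragments$fragments
  nr <- length(residue_groups); nf <- length(frs)
  out <- matrix(0, n_frames(traj), nr * nf)
  for (f in seq_len(n_frames(traj))) {
    xyz <- traj$frames[[f]]
    col <- 0
    for (i in seq_len(nr)) {
      for (j in seq_len(nf)) {
        col <- col + 1
        a <- xyz[residue_groups[[i]], , drop = FALSE]
        b <- xyz[frs[[j]]$atom_rows, , drop = FALSE]
        best <- Inf
        for (p in seq_len(nrow(a))) {
          for (q in seq_len(nrow(b))) {
            dd <- (a[p, 1] - b[q, 1])^2 + (a[p, 2] - b[q, 2])^2 +
              (a[p, 3] - b[q, 3])^2
            if (dd < best) best <- dd
          }
        }
        out[f, col] <- sqrt(best)
      }
    }
  }
  out
}

#' Reciprocal-distance features
#'
#' 1/max(d, floor): reciprocating shrinks the signal of residues far from the
#' ligand and amplifies contacts, so pose changes dominate the feature
#' variance.  The floor bounds features when atoms touch.
#'
#' @param distances frames x P minimum-distance matrix (Angstrom).
#' @param distance_floor Angstrom; distances below it are clamped.
#' @return object of class \code{"feature_matrix"}: frames x P matrix in
#'   1/Angstrom, same column key, \code{distance_floor} attribute.
#' @export
reciprocal_features <- function(distances, distance_floor = 0.5) {
  stopifnot(all(distances >= 0))
  out <- 1 / pmax(distances, distance_floor)
  attr(out, "column_key") <- attr(distances, "column_key")
  attr(out, "distance_floor") <- distance_floor
  class(out) <- c("feature_matrix", class(out))
  out
}

#' PCA of a feature matrix
#'
#' Column-mean-centered, unweighted covariance of the reciprocal-distance
#' features.  Features are internal coordinates, so no superposition is
#' applied.
#'
#' @param features frames x P feature matrix.
#' @param n_components components to keep in the returned projection.
#' @return list with \code{model} (\code{pca_model}-like: mean,
#'   eigenvectors, eigenvalues, trace) and \code{projection} (frames x K).
#' @export
feature_pca <- function(features, n_components = 3) {
  x <- unclass(features)
  attr(x, "column_key") <- NULL; attr(x, "distance_floor") <- NULL
  nf <- nrow(x)
  if (nf <= n_components) stop_pd("feature_pca(): need more frames than components")
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  tr <- sum(xc * xc) / nf
  if (tr == 0) warn_pd("feature_pca(): constant feature matrix; projections are all zero")
  if (ncol(x) <= 5000 || ncol(x) <= nf) {
    ed <- eigen(crossprod(xc) / nf, symmetric = TRUE)
    vals <- pmax(ed$values, 0); vecs <- ed$vectors
  } else {
    g <- tcrossprod(xc) / nf
    ed <- eigen(g, symmetric = TRUE)
    pos <- ed$values > 1e-12 * max(ed$values, 1e-300)
    vals <- ed$values[pos]
    vecs <- sweep(t(xc) %*% ed$vectors[, pos, drop = FALSE], 2,
                  sqrt(nf * vals), `/`)
  }
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  model <- structure(list(mean = mu, eigenvectors = vecs,
                          eigenvalues = vals, weights = rep(1, ncol(x)),
                          trace = tr, mass_weighted = FALSE,
                          selection = NULL, reference = NULL),
                     class = "pca_model")
  k <- min(n_components, ncol(vecs))
  proj <- xc %*% vecs[, seq_len(k), drop = FALSE]
  colnames(proj) <- paste0("PC", seq_len(k))
  list(model = model, projection = proj)
}

#' Cluster binding poses in feature-PC space
#'
#' K-means over candidate k with model selection by Silhouette score under a
#' Davies-Bouldin constraint: the chosen k maximises the Silhouette score
#' among candidates whose Davies-Bouldin index ranks lowest or second lowest;
#' ties go to the smaller k.  The Silhouette is computed on a fixed-seed
#' subsample above 5000 frames, the DB index always on all frames.
#'
#' @param projection frames x 3 feature-PC matrix.
#' @param k_candidates integer vector of candidate cluster counts (>= 2).
#' @param seed RNG seed.
#' @return object of class \code{"pose_clusters"}: \code{labels}, \code{k},
#'   \code{metrics} (k, silhouette, davies_bouldin, ssr_sst),
#'   \code{populations}, \code{central_frame}, \code{status} ("ok" or
#'   "no_admissible_k" with all metrics and NULL labels).
#' @export
cluster_poses <- function(projection, k_candidates = 2:10, seed = 1) {
  x <- as.matrix(projection)
  if (any(k_candidates < 2) || any(k_candidates >= nrow(x))) {
    stop_pd("cluster_poses(): k candidates must lie in [2, frames-1]")
  }
  k_candidates <- sort(unique(as.integer(k_candidates)))
  fits <- list(); met <- NULL
  for (k in k_candidates) {
    fit <- kmeans_pp(x, k, seed = subseed(seed, k))
    fits[[as.character(k)]] <- fit
    met <- rbind(met, data.frame(
      k = k,
      silhouette = silhouette_score(x, fit$cluster,
                                    subsample_seed = subseed(seed, 1000 + k)),
      davies_bouldin = davies_bouldin(x, fit$cluster),
      ssr_sst = fit$tot_withinss / fit$totss
    ))
  }
  db_rank <- rank(met$davies_bouldin, ties.method = "min")
  admissible <- which(db_rank <= 2)
  if (!length(admissible)) {
    return(structure(list(labels = NULL, k = NA_integer_, metrics = met,
                          populations = NULL, central_frame = NULL,
                          status = "no_admissible_k"),
                     class = "pose_clusters"))
  }
  best <- admissible[order(-met$silhouette[admissible],
                           met$k[admissible])][1]
  k <- met$k[best]
  fit <- fits[[as.character(k)]]
  pops <- as.numeric(table(factor(fit$cluster, levels = seq_len(k)))) / nrow(x)
  structure(list(labels = fit$cluster, k = k, metrics = met,
                 populations = pops, centers = fit$centers,
                 central_frame = central_frames(x, fit$cluster, fit$centers),
                 status = "ok"),
            class = "pose_clusters")
}

#' @export
print.pose_clusters <- function(x, ...) {
  if (identical(x$status, "no_admissible_k")) {
    cat("pose_clusters: no admissible k (see $metrics)\n")
  } else {
    cat(sprintf("pose_clusters: k = %d, populations %s\n", x$k,
                paste(sprintf("%.1f%%", 100 * x$populations),
                      collapse = "/")))
  }
  invisible(x)
}

#' Central and representative frames per pose cluster
#'
#' The central structure is the frame nearest its cluster centroid in
#' feature-PC space; representatives are the up-to-\code{n} nearest cluster
#' members in ascending feature-space distance.
#'
#' @param result a \code{"pose_clusters"} with labels.
#' @param projection the frames x 3 projection clustering was run on.
#' @param n maximum representatives per cluster.
#' @return list per cluster: \code{central} (frame index),
#'   \code{representatives} (ordered frame indices), \code{distance}
#'   (matching feature-space distances).
#' @export
extract_representatives <- function(result, projection, n = 1000) {
  if (is.null(result$labels)) stop_pd("extract_representatives(): clustering has no labels")
  x <- as.matrix(projection)
  lapply(seq_len(result$k), function(cl) {
    members <- which(result$labels == cl)
    cen <- result$centers[cl, ]
    d <- sqrt(rowSums(sweep(x[members, , drop = FALSE], 2, cen)^2))
    ord <- order(d, members)
    take <- ord[seq_len(min(n, length(members)))]
    list(central = members[ord[1]], representatives = members[take],
         distance = d[take])
  })
}
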