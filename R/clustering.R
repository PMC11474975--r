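##
## Clustering machinery shared by the conformational (elbow) and pose
## (Silhouette / Davies-Bouldin) pipelines: k-means++ K-means with restarts,
## quality indices, and the elbow rule on the SSR/SST curve.
##

## k-means++ seeding (Arthur & Vassilvitskii): first center uniform, later
## centers sampled with probability proportional to squared distance to the
## nearest chosen center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  i <- sample.int(n, 1)
  centers[1, ] <- x[i, ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  if (k > 1) {
    for (j in 2:k) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      i <- sample.int(n, 1, prob = p)
      centers[j, ] <- x[i, ]
      d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
    }
  }
  centers
}

## Deterministic K-means: k-means++ init, n_restarts restarts under a fixed
## seed, best total within-cluster sum of squares wins.
kmeans_pp <- function(x, k, seed, n_restarts = 10, iter_max = 100) {
  x <- as.matrix(x)
  if (k == 1) {
    ctr <- matrix(colMeans(x), 1)
    ss <- sum(sweep(x, 2, ctr[1, ])^2)
    return(list(cluster = rep(1L, nrow(x)), centers = ctr,
                tot_withinss = ss, totss = ss))
  }
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      init <- kmeanspp_centers(x, k)
      km <- suppressWarnings(
        stats::kmeans(x, centers = init, iter.max = iter_max,
                      algorithm = "Lloyd")
      )
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    list(cluster = best$cluster, centers = best$centers,
         tot_withinss = best$tot.withinss, totss = best$totss)
  })
}

## mean Silhouette width; own implementation (O(n^2)), cross-checked against
## cluster::silhouette in the tests.  Subsampled above max_n points.
silhouette_score <- function(x, labels, max_n = 5000, subsample_seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (length(unique(labels)) < 2) return(NA_real_)
  if (n > max_n) {
    idx <- with_seed(subsample_seed, sort(sample.int(n, max_n)))
    x <- x[idx, , drop = FALSE]
    labels <- labels[idx]
    if (length(unique(labels)) < 2) return(NA_real_)
  }
  d <- as.matrix(stats::dist(x))
  labs <- sort(unique(labels))
  sil <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    same <- labels == labels[i]
    ni <- sum(same)
    a <- if (ni > 1) sum(d[i, same]) / (ni - 1) else NA
    b <- min(vapply(labs[labs != labels[i]],
                    function(l) mean(d[i, labels == l]), numeric(1)))
    sil[i] <- if (ni > 1) (b - a) / max(a, b) else 0
  }
  mean(sil)
}

## Davies-Bouldin index: mean over clusters of the worst (s_i+s_j)/d_ij,
## s = mean distance to centroid, d = centroid separation.  Lower is better.
davies_bouldin <- function(x, labels) {
  x <- as.matrix(x)
  labs <- sort(unique(labels))
  k <- length(labs)
  if (k < 2) return(NA_real_)
  cen <- t(vapply(labs, function(l) colMeans(x[labels == l, , drop = FALSE]),
                  numeric(ncol(x))))
  s <- vapply(seq_len(k), function(i) {
    xi <- x[labels == labs[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(xi, 2, cen[i, ])^2)))
  }, numeric(1))
  dij <- as.matrix(stats::dist(cen))
  mean(vapply(seq_len(k), function(i) {
    max(vapply(seq_len(k)[-i], function(j) (s[i] + s[j]) / dij[i, j],
               numeric(1)))
  }, numeric(1)))
}

## frame nearest (Euclidean) to each cluster centroid; ties -> lower index
central_frames <- function(x, labels, centers) {
  labs <- sort(unique(labels))
  vapply(seq_along(labs), function(i) {
    members <- which(labels == labs[i])
    d2 <- rowSums(sweep(x[members, , drop = FALSE], 2, centers[i, ])^2)
    members[which.min(d2)]
  }, integer(1))
}

#' Conformational-state clustering with the elbow criterion
#'
#' Runs K-means (k-means++ initialisation, 10 restarts, fixed seed) on the
#' first \code{n_components} PCs for k = 1..k_max and picks the smallest k at
#' which the SSR/SST curve (within-cluster over total sum of squares) drops
#' by less than \code{threshold} when moving to k+1 -- the elbow rule with a
#' 2.5\% default threshold.
#'
#' @param projection frames x K projection matrix (first 3 PCs used by
#'   default).
#' @param n_components number of leading PCs used as features.
#' @param threshold elbow threshold on consecutive SSR/SST improvement.
#' @param k_max largest k examined.
#' @param seed RNG seed for K-means restarts.
#' @return object of class \code{"conf_clusters"}: \code{labels}, \code{k},
#'   \code{ssr_sst} (per-k curve), \code{populations}, \code{central_frame}.
#' @export
elbow_kmeans <- function(projection, n_components = 3, threshold = 0.025,
                         k_max = 10, seed = 1) {
  x <- as.matrix(projection)[, seq_len(min(n_components, ncol(projection))),
                             drop = FALSE]
  if (nrow(x) < k_max) stop_pd("elbow_kmeans(): fewer frames (%d) than k_max (%d)",
                               nrow(x), k_max)
  if (k_max < 2) stop_pd("elbow_kmeans(): k_max must be >= 2")
  one <- kmeans_pp(x, 1, seed = subseed(seed, 1))
  if (one$totss <= 1e-12) {
    ## zero-variance projection: a single trivial cluster
    return(structure(list(labels = rep(1L, nrow(x)), k = 1L,
                          ssr_sst = c(0, rep(NA_real_, k_max - 1)),
                          populations = 1, central_frame = 1L),
                     class = "conf_clusters"))
  }
  fits <- vector("list", k_max)
  ratio <- numeric(k_max)
  for (k in seq_len(k_max)) {
    fits[[k]] <- kmeans_pp(x, k, seed = subseed(seed, k))
    ratio[k] <- fits[[k]]$tot_withinss / fits[[1]]$totss
  }
  chosen <- k_max
  for (k in seq_len(k_max - 1)) {
    if (ratio[k] - ratio[k + 1] < threshold) { chosen <- k; break }
  }
  fit <- fits[[chosen]]
  pops <- as.numeric(table(factor(fit$cluster, levels = seq_len(chosen)))) /
    nrow(x)
  structure(list(labels = fit$cluster, k = chosen, ssr_sst = ratio,
                 populations = pops,
                 central_frame = central_frames(x, fit$cluster, fit$centers)),
            class = "conf_clusters")
}

#' @export
print.conf_clusters <- function(x, ...) {
  cat(sprintf("conf_clusters: k = %d, populations %s\n", x$k,
              paste(sprintf("%.1f%%", 100 * x$populations), collapse = "/")))
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions, used to score planted
#' cluster recovery; 1 = identical partitions up to relabeling.
#'
#' @param a,b integer label vectors of equal length.
#' @return adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
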