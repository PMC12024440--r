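# k-means edge community detection on rows of the eFC matrix.
#
# "Standardized Euclidean distance" is realized as feature standardization:
# each eFC column is centered and scaled to unit (sample) variance, then
# ordinary Euclidean k-means runs on the standardized rows. Weighted-distance
# k-means has no standard centroid update; rescaling the feature space is the
# conventional equivalent and leaves the assignment geometry identical.
# Lloyd's algorithm with k-means++ initialization; across restarts the
# partition with minimum inertia wins (ties -> first restart).

#' Cluster edges by k-means on eFC rows
#'
#' Each of the M rows of the eFC matrix (the full connectivity profile of
#' one edge) is one observation. Features are standardized, k-means++ seeds
#' the centroids, Lloyd iterations run to convergence, and the best of
#' `n_restarts` random restarts (minimum within-cluster sum of squared
#' distances, "inertia") is returned. Deterministic given
#' `(efc, k, n_restarts, seed)`.
#'
#' A restart that produces an empty cluster re-seeds the offending centroid
#' at the point farthest from its current centroid; after 10 such repairs in
#' one restart the restart errors out.
#'
#' @param efc an `efc_matrix`.
#' @param k number of communities, 2 <= k <= M.
#' @param n_restarts random restarts (study-scale default 250).
#' @param seed master seed; per-restart seeds are derived from it.
#' @param max_iter Lloyd iteration cap per restart.
#' @param standardize standardize features before clustering (default TRUE).
#' @return An object of class `edge_partition`: `labels` (length M, values
#'   1..k), `k`, `inertia`, `restart_seed` (seed of the winning restart),
#'   `restart_inertias`, `n_reinit` (empty-cluster repairs), `edge_index`,
#'   `n_nodes`, `subject_id`.
#' @export
cluster_edges <- function(efc, k, n_restarts = 250, seed = 1L,
                          max_iter = 100L, standardize = TRUE) {
  stopifnot(inherits(efc, "efc_matrix"))
  x <- efc$values
  m <- nrow(x)
  if (k < 2 || k > m) stop_fc("k must satisfy 2 <= k <= M = %d, got %s", m, k)
  if (standardize) {
    mu <- colMeans(x)
    sdv <- apply(x, 2, stats::sd)
    sdv[sdv == 0] <- 1  # constant feature: carries no distance information
    x <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  }
  # n_restarts = 1 runs the seed directly, so any partition can be
  # reproduced bit-identically from its recorded restart_seed
  restart_seeds <- if (n_restarts == 1) as.integer(seed) else
    derive_seeds(seed, n_restarts)
  best <- NULL
  inertias <- numeric(n_restarts)
  n_reinit_total <- 0L
  row_sq <- rowSums(x^2)
  for (r in seq_len(n_restarts)) {
    res <- kmeans_once(x, k, restart_seeds[r], max_iter, row_sq)
    inertias[r] <- res$inertia
    n_reinit_total <- n_reinit_total + res$n_reinit
    if (is.null(best) || res$inertia < best$inertia) {
      best <- res
      best$restart_seed <- restart_seeds[r]
    }
  }
  structure(list(labels = best$labels, k = as.integer(k),
                 inertia = best$inertia, restart_seed = best$restart_seed,
                 restart_inertias = inertias, n_reinit = n_reinit_total,
                 edge_index = efc$edge_index, n_nodes = efc$n_nodes,
                 subject_id = efc$subject_id),
            class = "edge_partition")
}

# One seeded k-means++ / Lloyd run on pre-standardized data.
kmeans_once <- function(x, k, seed, max_iter, row_sq = rowSums(x^2)) {
  m <- nrow(x)
  set.seed(seed)
  centers <- x[kmeanspp_pick(x, k, row_sq), , drop = FALSE]
  labels <- integer(m)
  n_reinit <- 0L
  for (iter in seq_len(max_iter)) {
    d2 <- dist2_to_centers(x, centers, row_sq)
    new_labels <- max.col(-d2, ties.method = "first")
    # empty-cluster repair: move the centroid to the farthest observation
    repair <- 0L
    while (length(miss <- setdiff(seq_len(k), unique(new_labels))) > 0) {
      repair <- repair + 1L
      if (repair > 10L) stop_fc("k-means: cluster stayed empty after 10 re-seeds (k = %d)", k)
      far <- which.max(d2[cbind(seq_len(m), new_labels)])
      centers[miss[1], ] <- x[far, ]
      d2 <- dist2_to_centers(x, centers, row_sq)
      new_labels <- max.col(-d2, ties.method = "first")
      n_reinit <- n_reinit + 1L
    }
    if (identical(new_labels, labels)) break
    labels <- new_labels
    for (c0 in seq_len(k)) {
      centers[c0, ] <- colMeans(x[labels == c0, , drop = FALSE])
    }
  }
  d2 <- dist2_to_centers(x, centers, row_sq)
  inertia <- sum(d2[cbind(seq_len(m), labels)])
  list(labels = labels, inertia = inertia, n_reinit = n_reinit)
}

# Squared Euclidean distance of every row of x to every center row.
dist2_to_centers <- function(x, centers, row_sq) {
  d2 <- row_sq - 2 * x %*% t(centers) +
    rep(rowSums(centers^2), each = nrow(x))
  d2[d2 < 0] <- 0
  d2
}

# k-means++ seeding: first center uniform, then prob proportional to the
# squared distance to the nearest chosen center.
kmeanspp_pick <- function(x, k, row_sq) {
  m <- nrow(x)
  picks <- integer(k)
  picks[1] <- sample.int(m, 1)
  d2 <- drop(dist2_to_centers(x, x[picks[1], , drop = FALSE], row_sq))
  for (c0 in seq_len(k - 1)) {
    if (all(d2 == 0)) {
      picks[c0 + 1] <- sample.int(m, 1)
    } else {
      picks[c0 + 1] <- sample.int(m, 1, prob = d2)
    }
    d2 <- pmin(d2, drop(dist2_to_centers(x, x[picks[c0 + 1], , drop = FALSE],
                                         row_sq)))
  }
  picks
}

#' Sweep the number of communities
#'
#' Runs [cluster_edges()] for every k in `k_range` (study-scale default
#' 2..10, 250 restarts per k) and collects the best partition and the
#' restart inertia list per k, plus an inertia curve to aid choosing k.
#'
#' @param efc an `efc_matrix`.
#' @param k_range integer vector of k values.
#' @param n_restarts restarts per k.
#' @param seed master seed; per-k seeds are derived from it.
#' @inheritParams cluster_edges
#' @return An object of class `ksweep_result`: `partitions` (named list,
#'   one `edge_partition` per k), `inertia_curve` (data.frame k, inertia),
#'   `restart_inertias` (list), `k_range`, `n_restarts`.
#' @export
sweep_k <- function(efc, k_range = 2:10, n_restarts = 250, seed = 1L,
                    max_iter = 100L, standardize = TRUE) {
  stopifnot(length(k_range) >= 1, all(k_range >= 2))
  k_range <- as.integer(k_range)
  k_seeds <- derive_seeds(seed, length(k_range))
  parts <- vector("list", length(k_range))
  names(parts) <- as.character(k_range)
  for (a in seq_along(k_range)) {
    parts[[a]] <- cluster_edges(efc, k_range[a], n_restarts = n_restarts,
                                seed = k_seeds[a], max_iter = max_iter,
                                standardize = standardize)
  }
  curve <- data.frame(k = k_range,
                      inertia = vapply(parts, function(p) p$inertia, 0))
  structure(list(partitions = parts, inertia_curve = curve,
                 restart_inertias = lapply(parts, function(p) p$restart_inertias),
                 k_range = k_range, n_restarts = as.integer(n_restarts)),
            class = "ksweep_result")
}

#' Pick k at the inertia elbow
#'
#' The elbow is the k with the largest relative inertia drop from its
#' predecessor, (I(k-1) - I(k)) / I(k-1). The choice of k is reported, never
#' silently assumed: downstream tables carry the k they were computed at.
#'
#' @param sweep a `ksweep_result` with at least two k values.
#' @return The selected k (integer).
#' @export
choose_k_elbow <- function(sweep) {
  stopifnot(inherits(sweep, "ksweep_result"))
  cv <- sweep$inertia_curve
  if (nrow(cv) < 2) return(cv$k[1])
  drop_rel <- (cv$inertia[-nrow(cv)] - cv$inertia[-1]) / cv$inertia[-nrow(cv)]
  cv$k[which.max(drop_rel) + 1L]
}

#' @export
print.edge_partition <- function(x, ...) {
  cat(sprintf("edge_partition '%s': %d edges, k = %d, inertia = %.4g (seed %d)\n",
              x$subject_id, length(x$labels), x$k, x$inertia, x$restart_seed))
  invisible(x)
}

#' Write a partition as a delimited table plus JSON metadata
#'
#' @param partition an `edge_partition`.
#' @param path output path for the table (edge, i, j, community).
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "edge_partition"))
  df <- partition$edge_index
  df$community <- partition$labels
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(subject_id = partition$subject_id, k = partition$k,
               inertia = partition$inertia,
               restart_seed = partition$restart_seed,
               n_restarts = length(partition$restart_inertias),
               n_reinit = partition$n_reinit)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
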