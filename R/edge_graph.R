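# Edge graph construction: co-fluctuation edge time series and the edge
# functional connectivity (eFC) matrix.
#
# Canonical edge order is row-major over the strict upper triangle:
# (1,2), (1,3), ..., (1,N), (2,3), ..., (N-1,N). Positions are 1-based.
# All downstream tables (partitions, participation, similarity) inherit it.

#' Canonical edge index for N nodes
#'
#' @param n_nodes number of nodes N (>= 2).
#' @return data.frame with columns `edge` (1..M), `i`, `j` (i < j), in
#'   row-major upper-triangle order; M = N(N-1)/2.
#' @export
edge_index <- function(n_nodes) {
  stopifnot(n_nodes >= 2)
  i <- rep.int(seq_len(n_nodes - 1), times = (n_nodes - 1):1)
  j <- unlist(lapply(seq_len(n_nodes - 1), function(a) (a + 1):n_nodes),
              use.names = FALSE)
  data.frame(edge = seq_along(i), i = i, j = j)
}

#' Map a node pair to its canonical edge position
#'
#' Closed-form inverse pair of [edge_to_pair()]; `i < j` required.
#'
#' @param i,j node indices (vectors allowed), 1 <= i < j <= N.
#' @param n_nodes number of nodes.
#' @return integer edge positions in 1..M.
#' @export
pair_to_edge <- function(i, j, n_nodes) {
  stopifnot(all(i >= 1), all(j <= n_nodes), all(i < j))
  as.integer((i - 1) * (2 * n_nodes - i) / 2 + (j - i))
}

#' Map canonical edge positions back to node pairs
#'
#' @param e edge positions in 1..M.
#' @param n_nodes number of nodes.
#' @return data.frame with columns `i`, `j`.
#' @export
edge_to_pair <- function(e, n_nodes) {
  m <- n_nodes * (n_nodes - 1) / 2
  stopifnot(all(e >= 1), all(e <= m))
  # smallest i with cumulative count >= e
  cum <- cumsum((n_nodes - 1):1)
  i <- findInterval(e - 1, c(0, cum), rightmost.closed = FALSE)
  j <- e - c(0, cum)[i] + i
  data.frame(i = as.integer(i), j = as.integer(j))
}

#' Build the co-fluctuation edge time series
#'
#' For a z-scored panel, edge (i, j) at timepoint t is the product
#' z_i(t) * z_j(t): positive when both components deviate from baseline in
#' the same direction, negative when they move oppositely. Under the
#' population z-scoring convention the time average of each edge row equals
#' the Pearson correlation of its two components.
#'
#' @param panel a z-scored `ts_panel`.
#' @return An object of class `edge_ts`: list with `values` (M x T matrix),
#'   `edge_index`, `subject_id`, `n_nodes`.
#' @export
build_edge_timeseries <- function(panel) {
  stopifnot(inherits(panel, "ts_panel"))
  if (!panel$zscored) stop_fc("panel '%s' must be z-scored first", panel$subject_id)
  z <- panel$values
  idx <- edge_index(nrow(z))
  vals <- z[idx$i, , drop = FALSE] * z[idx$j, , drop = FALSE]
  rownames(vals) <- paste(panel$component_ids[idx$i],
                          panel$component_ids[idx$j], sep = "~")
  structure(list(values = vals, edge_index = idx,
                 subject_id = panel$subject_id, n_nodes = nrow(z),
                 component_ids = panel$component_ids),
            class = "edge_ts")
}

#' @export
print.edge_ts <- function(x, ...) {
  cat(sprintf("edge_ts '%s': %d edges (N = %d) x %d timepoints\n",
              x$subject_id, nrow(x$values), x$n_nodes, ncol(x$values)))
  invisible(x)
}

#' Compute the edge functional connectivity matrix
#'
#' Entry (e, f) is the uncentered cosine similarity of the two edge rows,
#' sum_t c_e(t) c_f(t) / sqrt(sum_t c_e(t)^2 * sum_t c_f(t)^2). No mean
#' removal is applied to the edge rows: the similarity is computed exactly
#' as the uncentered formula reads. The result is symmetric with unit
#' diagonal and entries in [-1, 1].
#'
#' For N = 200 components M = 19900 and the dense double matrix is ~3 GB;
#' `block_size` evaluates the Gram product in row blocks to bound the
#' working set of the multiplication. Desk-scale analyses use N <= 40.
#'
#' @param ets an `edge_ts`.
#' @param block_size rows per block for the Gram product; `NULL` (default)
#'   computes it in one `tcrossprod`.
#' @return An object of class `efc_matrix`: list with `values` (M x M),
#'   `edge_index`, `n_nodes`, `subject_id`.
#' @export
compute_efc <- function(ets, block_size = NULL) {
  stopifnot(inherits(ets, "edge_ts"))
  x <- ets$values
  m <- nrow(x)
  if (m < 2) stop_fc("need at least 2 edges, got %d", m)
  sq <- rowSums(x^2)
  if (any(sq == 0)) {
    e0 <- which(sq == 0)[1]
    stop_fc("edge (%d,%d) has an all-zero co-fluctuation series: eFC denominator is zero",
            ets$edge_index$i[e0], ets$edge_index$j[e0])
  }
  if (is.null(block_size)) {
    g <- tcrossprod(x)
  } else {
    stopifnot(block_size >= 1)
    g <- matrix(0, m, m)
    starts <- seq(1, m, by = block_size)
    for (s in starts) {
      rows <- s:min(s + block_size - 1, m)
      g[rows, ] <- x[rows, , drop = FALSE] %*% t(x)
    }
  }
  d <- sqrt(sq)
  v <- g / tcrossprod(d)
  v <- (v + t(v)) / 2   # enforce exact symmetry against FP round-off
  diag(v) <- 1
  dimnames(v) <- list(rownames(x), rownames(x))
  structure(list(values = v, edge_index = ets$edge_index,
                 n_nodes = ets$n_nodes, subject_id = ets$subject_id),
            class = "efc_matrix")
}

#' @export
print.efc_matrix <- function(x, ...) {
  cat(sprintf("efc_matrix '%s': %d x %d (N = %d nodes)\n",
              x$subject_id, nrow(x$values), ncol(x$values), x$n_nodes))
  invisible(x)
}

#' Conventional node functional connectivity
#'
#' Pearson correlation between all component pairs of a z-scored panel;
#' equals the time average of the corresponding edge co-fluctuation series.
#' Provided as the node-centric reference alongside the edge-centric view.
#'
#' @param panel a z-scored `ts_panel`.
#' @return Symmetric N x N correlation matrix with unit diagonal.
#' @export
compute_nfc <- function(panel) {
  stopifnot(inherits(panel, "ts_panel"))
  if (!panel$zscored) stop_fc("panel '%s' must be z-scored first", panel$subject_id)
  z <- panel$values
  v <- tcrossprod(z) / ncol(z)
  v <- (v + t(v)) / 2
  diag(v) <- 1
  dimnames(v) <- list(panel$component_ids, panel$component_ids)
  v
}

#' Write a square matrix with a JSON sidecar
#'
#' Matrices persist as plain delimited text plus `<path>.json` recording the
#' subject, node count and canonical edge-index provenance, so any stage can
#' be re-run from persisted intermediates.
#'
#' @param obj an `efc_matrix` or `edge_ts`.
#' @param path output path for the matrix body.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(obj, path) {
  stopifnot(inherits(obj, c("efc_matrix", "edge_ts")))
  utils::write.table(fmt_mat(obj$values), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  meta <- list(class = class(obj)[1], subject_id = obj$subject_id,
               n_nodes = obj$n_nodes, n_edges = nrow(obj$values),
               edge_order = "row-major upper triangle, i < j, 1-based")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

fmt_mat <- function(m) {
  matrix(fmt_num(m), nrow = nrow(m))
}
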