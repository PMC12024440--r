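# Community overlap metrics: node participation across edge communities,
# normalized Shannon entropy at the component and network level, and
# node-pair community similarity. All metrics are invariant under community
# relabeling.

#' Node participation across edge communities
#'
#' Row i gives the fraction of node i's N - 1 incident edges assigned to
#' each community: p_ic = (1/(N-1)) * sum_{j != i} delta(g_ij, c). Rows sum
#' to one by construction.
#'
#' @param partition an `edge_partition`.
#' @param n_nodes number of nodes N; defaults to the partition's.
#' @return N x k numeric matrix of participation probabilities.
#' @export
participation <- function(partition, n_nodes = partition$n_nodes) {
  stopifnot(inherits(partition, "edge_partition"))
  m_expected <- n_nodes * (n_nodes - 1) / 2
  if (length(partition$labels) != m_expected) {
    stop_fc("partition covers %d edges but N = %d requires %d",
            length(partition$labels), n_nodes, m_expected)
  }
  k <- partition$k
  idx <- partition$edge_index
  counts <- matrix(0, n_nodes, k)
  node <- c(idx$i, idx$j)
  lab <- rep(partition$labels, 2)
  for (r in seq_along(node)) counts[node[r], lab[r]] <- counts[node[r], lab[r]] + 1
  counts / (n_nodes - 1)
}

#' Shannon entropy of participation profiles
#'
#' h_i = -sum_c p_ic log2 p_ic, with the convention 0 log 0 = 0. With
#' `normalize = TRUE` the entropy is divided by log2(k), where k is the
#' number of communities requested (profile columns), so a node whose edges
#' all share one community scores 0 and a node spread uniformly over all k
#' communities scores 1.
#'
#' @param profile N x k participation matrix (rows sum to 1).
#' @param normalize divide by log2(k) (default TRUE).
#' @return numeric vector of N entropies (bits if unnormalized).
#' @export
node_entropy <- function(profile, normalize = TRUE) {
  profile <- as.matrix(profile)
  if (any(profile < 0) || any(profile > 1)) {
    stop_fc("participation entries must lie in [0, 1]")
  }
  if (any(abs(rowSums(profile) - 1) > 1e-8)) {
    stop_fc("participation rows must sum to 1")
  }
  k <- ncol(profile)
  plogp <- profile * log2(profile)
  plogp[profile == 0] <- 0
  h <- -rowSums(plogp)
  if (normalize) {
    if (k == 1) stop_fc("normalized entropy undefined for k = 1 (log2 1 = 0)")
    h <- h / log2(k)
  }
  h
}

#' Network-level entropy
#'
#' Aggregates component-level entropies into one value per network. The
#' default is the unweighted mean over member components; `weights` (a
#' named numeric vector over components) enables a weighted mean.
#'
#' @param entropies numeric vector named by component id.
#' @param atlas a `network_atlas` covering every component.
#' @param weights optional named numeric weights per component.
#' @return numeric vector named by network, in `atlas$network_order`.
#' @export
network_entropy <- function(entropies, atlas, weights = NULL) {
  stopifnot(inherits(atlas, "network_atlas"))
  ids <- names(entropies)
  if (is.null(ids)) stop_fc("entropies must be named by component id")
  check_atlas_covers(atlas, ids)
  nets <- atlas$mapping[ids]
  out <- vapply(atlas$network_order, function(nw) {
    memb <- ids[nets == nw]
    if (!length(memb)) stop_fc("network '%s' has no components in the panel", nw)
    if (is.null(weights)) {
      mean(entropies[memb])
    } else {
      w <- weights[memb]
      sum(w * entropies[memb]) / sum(w)
    }
  }, 0)
  out
}

#' Node-pair community similarity
#'
#' For nodes i and j, the fraction of the N - 2 third-party nodes u whose
#' edges (i,u) and (j,u) carry the same community label:
#' s_ij = (1/(N-2)) * sum_{u != i,j} delta(g_iu, g_ju). The diagonal is
#' stored as 1 by convention and excluded from statistics.
#'
#' @param partition an `edge_partition`.
#' @param n_nodes number of nodes N (>= 3).
#' @return Symmetric N x N matrix with entries in [0, 1].
#' @export
community_similarity <- function(partition, n_nodes = partition$n_nodes) {
  stopifnot(inherits(partition, "edge_partition"))
  if (n_nodes < 3) stop_fc("community similarity needs N >= 3 (denominator N - 2)")
  idx <- partition$edge_index
  lab <- matrix(NA_integer_, n_nodes, n_nodes)
  lab[cbind(idx$i, idx$j)] <- partition$labels
  lab[cbind(idx$j, idx$i)] <- partition$labels
  s <- matrix(1, n_nodes, n_nodes)
  for (i in seq_len(n_nodes - 1)) {
    for (j in (i + 1):n_nodes) {
      u <- setdiff(seq_len(n_nodes), c(i, j))
      s[i, j] <- s[j, i] <- mean(lab[i, u] == lab[j, u])
    }
  }
  s
}

#' Build a long-format entropy table for a set of subjects
#'
#' One row per (subject, level, unit): component-level normalized entropy
#' for every component and network-level entropy for every network, at the
#' partition's k. This long table is the unit of group statistics.
#'
#' @param partitions named list of `edge_partition`, one per subject id.
#' @param atlas a `network_atlas`; names must match the panels' component
#'   ids in panel order.
#' @param component_ids character vector of component ids in node order.
#' @param normalize passed to [node_entropy()].
#' @return data.frame with columns subject_id, level ("component" or
#'   "network"), unit, k, entropy.
#' @export
entropy_table <- function(partitions, atlas, component_ids, normalize = TRUE) {
  stopifnot(length(partitions) >= 1, !is.null(names(partitions)))
  check_atlas_covers(atlas, component_ids)
  rows <- lapply(names(partitions), function(sid) {
    p <- partitions[[sid]]
    prof <- participation(p)
    h <- stats::setNames(node_entropy(prof, normalize = normalize), component_ids)
    hn <- network_entropy(h, atlas)
    rbind(
      data.frame(subject_id = sid, level = "component", unit = names(h),
                 k = p$k, entropy = unname(h)),
      data.frame(subject_id = sid, level = "network", unit = names(hn),
                 k = p$k, entropy = unname(hn))
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
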