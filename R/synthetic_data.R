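# Latent-factor synthetic cohorts with known edge-community structure.
#
# Generative model: k* independent standard-normal latent community signals
# s_c(t); node i observes x_i(t) = sum_c w_ic s_c(t) + noise_sd * eps_i(t)
# with nonnegative mixing weights w_i summing to 1. The model is chosen
# because it gives analytically known ground truth, not as a claim about
# BOLD physiology:
#   * planted edge label for (i,j) = argmax_c w_ic * w_jc (ties -> lowest c),
#   * planted node overlap = normalized entropy of the loading row,
#   * nodal covariance converges to W W' + noise_sd^2 I as T grows.
# Group 2 can override designated networks' loadings toward the uniform
# mixture, planting higher community overlap there.

#' Describe a synthetic cohort design
#'
#' Defaults mirror the emulated study scale where desk-feasible: 32
#' components over the 16 canonical intrinsic connectivity networks (2
#' each), T = 230 usable volumes (240 acquired minus 10 discarded), and
#' cohorts of 33 ("patient") and 44 ("control") subjects. Latent structure
#' defaults to k* = 4 communities with networks assigned round-robin;
#' loadings put `loading_primary` on the own community and spread the rest
#' over the other communities in cyclic order with geometric decay
#' `loading_decay`, so every edge has a unique dominant community (no
#' argmax ties).
#'
#' @param n_components number of components N (multiple of `n_networks`).
#' @param n_networks number of named networks.
#' @param network_names character vector of network names; defaults to the
#'   16 canonical intrinsic-network labels.
#' @param t_len timepoints per subject.
#' @param k_latent number of latent communities k* (>= 2).
#' @param loading_primary weight on the own community, in (0, 1].
#' @param loading_decay geometric decay of the off-community weights.
#' @param noise_sd observation noise standard deviation (>= 0).
#' @param n_group1,n_group2 cohort sizes.
#' @param group_labels two cohort labels (group 1 first).
#' @param target_networks networks whose loadings group 2 overrides.
#' @param override_mix mixing toward uniform in group 2's target networks:
#'   w' = (1 - mix) w + mix / k*. 1 = fully uniform rows.
#' @param mixing per-network mixing toward the uniform loading, in \[0, 1\]
#'   (recycled over networks): component rows become
#'   (1 - mixing) w + mixing / k*. A heterogeneous profile (e.g.
#'   `seq(0, 0.75, length.out = 16)`) plants a graded population of
#'   community overlap across networks, which is what makes recovered
#'   entropy respond to planted overlap; a scalar 0 (default) leaves the
#'   base scheme untouched.
#' @param loadings optional explicit N x k* loading matrix (rows sum to 1);
#'   overrides the default scheme (`mixing` still applies on top).
#' @return An object of class `sim_design`.
#' @export
simulation_design <- function(n_components = 32, n_networks = 16,
                              network_names = NULL, t_len = 230,
                              k_latent = 4, loading_primary = 0.85,
                              loading_decay = 0.4, noise_sd = 0.5,
                              n_group1 = 33, n_group2 = 44,
                              group_labels = c("patient", "control"),
                              target_networks = character(0),
                              override_mix = 1, mixing = 0,
                              loadings = NULL) {
  if (is.null(network_names)) {
    canon <- c("VisCent", "VisPeri", "SomMotA", "SomMotB", "DorsAttnA",
               "DorsAttnB", "SalVentAttnA", "SalVentAttnB", "Limbic",
               "ContA", "ContB", "ContC", "DefaultA", "DefaultB",
               "DefaultC", "TempPar")
    if (n_networks > length(canon)) {
      network_names <- sprintf("Net%02d", seq_len(n_networks))
    } else {
      network_names <- canon[seq_len(n_networks)]
    }
  }
  stopifnot(length(network_names) == n_networks,
            n_components %% n_networks == 0,
            k_latent >= 2, noise_sd >= 0, t_len >= 2,
            loading_primary > 0, loading_primary <= 1,
            override_mix >= 0, override_mix <= 1,
            n_group1 >= 2, n_group2 >= 2,
            length(group_labels) == 2, !anyDuplicated(group_labels))
  miss <- setdiff(target_networks, network_names)
  if (length(miss)) stop_fc("target network '%s' not among network names", miss[1])
  per_net <- n_components / n_networks
  net_of_comp <- rep(network_names, each = per_net)
  community_of_net <- ((seq_len(n_networks) - 1) %% k_latent) + 1
  community_of_comp <- rep(community_of_net, each = per_net)
  if (is.null(loadings)) {
    loadings <- t(vapply(community_of_comp, function(a) {
      w <- numeric(k_latent)
      w[a] <- loading_primary
      rest <- 1 - loading_primary
      if (rest > 0 && k_latent > 1) {
        others <- ((a - 1 + seq_len(k_latent - 1)) %% k_latent) + 1
        dec <- loading_decay^(seq_len(k_latent - 1) - 1)
        w[others] <- rest * dec / sum(dec)
      }
      w
    }, numeric(k_latent)))
  } else {
    loadings <- as.matrix(loadings)
    stopifnot(nrow(loadings) == n_components, ncol(loadings) == k_latent)
  }
  stopifnot(all(mixing >= 0), all(mixing <= 1),
            length(mixing) %in% c(1L, n_networks))
  lam <- rep(rep_len(mixing, n_networks), each = per_net)
  loadings <- (1 - lam) * loadings + lam / k_latent
  if (any(loadings < 0) || any(abs(rowSums(loadings) - 1) > 1e-8)) {
    stop_fc("loading rows must be nonnegative and sum to 1")
  }
  component_ids <- sprintf("IC%03d", seq_len(n_components))
  rownames(loadings) <- component_ids
  structure(list(n_components = n_components, n_networks = n_networks,
                 network_names = network_names, t_len = t_len,
                 k_latent = as.integer(k_latent), noise_sd = noise_sd,
                 loadings = loadings, component_ids = component_ids,
                 net_of_comp = net_of_comp,
                 n_group1 = n_group1, n_group2 = n_group2,
                 group_labels = group_labels,
                 target_networks = target_networks,
                 override_mix = override_mix,
                 mixing = rep_len(mixing, n_networks)),
            class = "sim_design")
}

# Loading matrix seen by a subject of the given group.
group_loadings <- function(design, group = 1L) {
  w <- design$loadings
  if (group == 2L && length(design$target_networks)) {
    sel <- design$net_of_comp %in% design$target_networks
    mix <- design$override_mix
    w[sel, ] <- (1 - mix) * w[sel, , drop = FALSE] + mix / design$k_latent
  }
  w
}

# Ground truth implied by a loading matrix.
#
# Two planted edge labelings are reported:
#  * edge_labels: argmax_c w_ic * w_jc, ties -> lowest c. This scores an
#    edge by its shared single-community content only.
#  * edge_pair_labels: argmax over the symmetrized latent-pair coefficients
#    of the product series, A_(c,d) = w_ic w_jd + w_id w_jc (c < d) and
#    A_(c,c) = w_ic w_jc. The co-fluctuation of edge (i,j) is
#    sum_(c<=d) A_(c,d) s_c s_d-like, so the dominant pair coefficient is
#    the community the eFC matrix actually expresses: edges between two
#    communities are dominated by the s_c s_d interaction term and form
#    their own eFC block, which the single-community argmax cannot name.
#    Labels index the pairs (1,1), (1,2), ..., (k,k) in row-major
#    upper-triangle order; with k* = 2 latent communities this plants
#    exactly three edge communities.
loading_truth <- function(w) {
  n <- nrow(w); k <- ncol(w)
  idx <- edge_index(n)
  wi <- w[idx$i, , drop = FALSE]
  wj <- w[idx$j, , drop = FALSE]
  prod_w <- wi * wj
  edge_labels <- max.col(prod_w, ties.method = "first")
  cc <- rep(seq_len(k), times = k:1)
  dd <- unlist(lapply(seq_len(k), function(a) a:k), use.names = FALSE)
  pairs <- data.frame(c = cc, d = dd)  # (1,1), (1,2), ..., (k,k)
  coef <- vapply(seq_len(nrow(pairs)), function(r) {
    c0 <- pairs$c[r]; d0 <- pairs$d[r]
    if (c0 == d0) wi[, c0] * wj[, c0]
    else wi[, c0] * wj[, d0] + wi[, d0] * wj[, c0]
  }, numeric(nrow(idx)))
  edge_pair_labels <- max.col(coef, ties.method = "first")
  wl <- w * log2(w)
  wl[w == 0] <- 0
  node_overlap <- -rowSums(wl) / log2(k)
  list(edge_labels = edge_labels, edge_pair_labels = edge_pair_labels,
       node_overlap = unname(node_overlap))
}

#' Simulate one subject's panel with ground truth
#'
#' @param design a `sim_design`.
#' @param seed subject-level seed.
#' @param group 1 or 2 (group 2 applies the loading override).
#' @param subject_id subject label.
#' @return list with `panel` (raw `ts_panel`), `edge_labels` (planted
#'   single-community argmax label of every canonical edge),
#'   `edge_pair_labels` (planted label by dominant latent-pair coefficient,
#'   the partition the eFC matrix geometrically expresses — use this as the
#'   recovery benchmark), `node_overlap` (planted normalized loading entropy
#'   per component) and `loadings`.
#' @export
simulate_panel <- function(design, seed, group = 1L, subject_id = "sim") {
  stopifnot(inherits(design, "sim_design"), group %in% c(1L, 2L))
  w <- group_loadings(design, group)
  set.seed(as.integer(seed))
  s <- matrix(stats::rnorm(design$k_latent * design$t_len),
              design$k_latent, design$t_len)
  eps <- matrix(stats::rnorm(design$n_components * design$t_len),
                design$n_components, design$t_len)
  x <- w %*% s + design$noise_sd * eps
  truth <- loading_truth(w)
  list(panel = ts_panel(x, subject_id = subject_id,
                        component_ids = design$component_ids),
       edge_labels = truth$edge_labels,
       edge_pair_labels = truth$edge_pair_labels,
       node_overlap = truth$node_overlap,
       loadings = w)
}

#' Simulate a two-cohort synthetic study
#'
#' Subject seeds are derived from the master seed by a fixed rule, so the
#' whole cohort is reproducible bit-for-bit. Covariates emulate the
#' demographic profile of the emulated study: age is group-matched, sex
#' code (1 = female) differs mildly in proportion, and education and a
#' symptom score carry genuine group mean shifts, so residualization has
#' real confounding to remove.
#'
#' @param design a `sim_design`.
#' @param seed master seed.
#' @return An object of class `synthetic_cohort`: `panels` (named list of
#'   raw `ts_panel`), `subjects` (`subject_table`), `atlas`
#'   (`network_atlas`), `truth` (per-group planted edge labels and node
#'   overlap), `design`, `seed`.
#' @export
simulate_cohort <- function(design, seed) {
  stopifnot(inherits(design, "sim_design"))
  n1 <- design$n_group1; n2 <- design$n_group2
  n_sub <- n1 + n2
  seeds <- derive_seeds(seed, n_sub + 1L)
  ids <- sprintf("S%03d", seq_len(n_sub))
  grp_num <- rep(c(1L, 2L), c(n1, n2))
  grp_lab <- design$group_labels[grp_num]
  panels <- vector("list", n_sub)
  names(panels) <- ids
  for (a in seq_len(n_sub)) {
    panels[[a]] <- simulate_panel(design, seeds[a], group = grp_num[a],
                                  subject_id = ids[a])$panel
  }
  set.seed(seeds[n_sub + 1L])
  age <- round(stats::rnorm(n_sub, 21.5, 6.5), 1)
  sex <- stats::rbinom(n_sub, 1, ifelse(grp_num == 1L, 9 / 33, 20 / 44))
  education <- round(ifelse(grp_num == 1L,
                            stats::rnorm(n_sub, 11.2, 1.4),
                            stats::rnorm(n_sub, 13.9, 4.2)), 1)
  symptom <- round(ifelse(grp_num == 1L,
                          stats::rnorm(n_sub, 12.3, 6.5),
                          stats::rnorm(n_sub, 11.3, 5.4)), 1)
  subjects <- subject_table(data.frame(
    subject_id = ids, group = grp_lab, age = age, sex = sex,
    education = education, symptom = symptom, stringsAsFactors = FALSE))
  atlas <- network_atlas(design$component_ids, design$net_of_comp)
  truth <- list(
    group1 = loading_truth(group_loadings(design, 1L)),
    group2 = loading_truth(group_loadings(design, 2L)),
    component_ids = design$component_ids,
    edge_order = "row-major upper triangle, i < j, 1-based")
  structure(list(panels = panels, subjects = subjects, atlas = atlas,
                 truth = truth, design = design, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d + %d subjects, N = %d, T = %d, k* = %d (seed %s)\n",
              x$design$n_group1, x$design$n_group2, x$design$n_components,
              x$design$t_len, x$design$k_latent, x$seed))
  invisible(x)
}

#' Entropy table for an in-memory cohort
#'
#' Runs the analysis core (z-score, edge time series, eFC, k-means at every
#' k in `k_range`, participation entropy) on every subject of a cohort
#' without touching disk — the workhorse for simulation studies. Per-subject
#' clustering seeds are derived from `seed`.
#'
#' @param cohort a `synthetic_cohort` (or any named list of raw `ts_panel`
#'   plus an `atlas` field).
#' @param k_range integer vector of community counts.
#' @param n_restarts k-means restarts per k.
#' @param seed master seed for the clustering stage.
#' @param normalize passed to [node_entropy()].
#' @return Long-format entropy data.frame as [entropy_table()], stacked
#'   over all k in `k_range`.
#' @export
cohort_entropy <- function(cohort, k_range = 2:10, n_restarts = 250,
                           seed = 1L, normalize = TRUE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  seeds <- derive_seeds(seed, length(cohort$panels))
  comp_ids <- cohort$design$component_ids
  tabs <- vector("list", length(cohort$panels))
  for (a in seq_along(cohort$panels)) {
    z <- zscore_panel(cohort$panels[[a]])
    efc <- compute_efc(build_edge_timeseries(z))
    sw <- sweep_k(efc, k_range, n_restarts = n_restarts, seed = seeds[a])
    parts <- lapply(sw$partitions, function(p) {
      p$subject_id <- names(cohort$panels)[a]; p
    })
    tabs[[a]] <- do.call(rbind, lapply(parts, function(p) {
      entropy_table(stats::setNames(list(p), p$subject_id), cohort$atlas,
                    comp_ids, normalize = normalize)
    }))
  }
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}

#' Write a synthetic cohort to disk
#'
#' Panels, atlas and subject table are written in exactly the formats the
#' readers consume (`panels/<id>.tsv` with a component-id header row,
#' components in columns; `atlas.tsv`; `subjects.tsv`). Ground truth goes
#' to a separate `truth.json` that the analysis pipeline never reads.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(file.path(dir, "panels"), recursive = TRUE, showWarnings = FALSE)
  for (sid in names(cohort$panels)) {
    write_panel(cohort$panels[[sid]], file.path(dir, "panels", paste0(sid, ".tsv")))
  }
  utils::write.table(
    data.frame(component_id = names(cohort$atlas$mapping),
               network = unname(cohort$atlas$mapping)),
    file.path(dir, "atlas.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(as.data.frame(cohort$subjects),
                     file.path(dir, "subjects.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
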