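# End-to-end orchestration: read -> z-score -> edge time series -> eFC ->
# k sweep -> entropy / similarity -> group statistics, from a single config,
# with stage logging and a JSON run manifest. All tables are delimited text
# so every stage can be re-run and compared byte-for-byte.

pipeline_defaults <- function() {
  list(
    panels = NULL, atlas = NULL, subjects = NULL, out_dir = NULL,
    delimiter = "\t", orientation = "columns", header = "auto",
    k_range = 2:10, n_restarts = 250, seed = 1,
    k_select = "elbow",          # "elbow" or an integer k
    clustering = "subject",      # "subject" or "pooled" (group-mean eFC)
    covariates = character(0), alpha = 0.05,
    stat_level = "network", welch = FALSE,
    write_partitions = TRUE, write_similarity = TRUE, write_efc = FALSE,
    verbose = TRUE
  )
}

#' Read a pipeline run configuration from JSON
#'
#' Unknown keys are rejected; omitted keys take package defaults.
#'
#' @param path path to a JSON config file.
#' @return A complete config list for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_fc("config file not found: %s", path)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  defs <- pipeline_defaults()
  unknown <- setdiff(names(user), names(defs))
  if (length(unknown)) stop_fc("unknown config key(s): %s",
                               paste(unknown, collapse = ", "))
  utils::modifyList(defs, user)
}

#' Run the full edge-centric analysis pipeline
#'
#' Stages: pre-flight validation of all referenced paths; panel reading and
#' z-scoring; per-subject edge time series and eFC; a k-means sweep over
#' `k_range` with `n_restarts` restarts (per-subject seeds derived from the
#' master seed); entropy tables over every k in the sweep; community
#' similarity at the selected k; covariate-adjusted group comparison at the
#' selected k with Bonferroni control. `clustering = "pooled"` clusters the
#' cohort-mean eFC once instead (every subject then shares the partition;
#' group statistics are skipped because between-subject variance is zero by
#' construction).
#'
#' The selected k defaults to the elbow (largest relative drop) of the
#' cohort-mean normalized inertia curve and is recorded prominently in the
#' manifest; pass an integer `k_select` to fix it.
#'
#' @param config a config list (see [pipeline_defaults] keys) or path to a
#'   JSON config.
#' @return Invisibly, a list with the entropy table, group comparison (or
#'   NULL), selected k, and the manifest. Side effect: tables and
#'   `manifest.json` under `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- read_run_config(config)
  }
  cfg <- utils::modifyList(pipeline_defaults(), config)
  say <- function(...) if (isTRUE(cfg$verbose)) message(sprintf(...))
  t0 <- Sys.time()

  # -- pre-flight -----------------------------------------------------------
  for (key in c("panels", "atlas", "subjects", "out_dir")) {
    if (is.null(cfg[[key]])) stop_fc("[preflight] config key '%s' is required", key)
  }
  if (!dir.exists(cfg$panels)) stop_fc("[preflight] panels directory not found: %s", cfg$panels)
  panel_files <- sort(list.files(cfg$panels, pattern = "\\.(tsv|csv|txt)$",
                                 full.names = TRUE))
  if (!length(panel_files)) stop_fc("[preflight] no panel files under %s", cfg$panels)
  if (!file.exists(cfg$atlas)) stop_fc("[preflight] atlas file not found: %s", cfg$atlas)
  if (!file.exists(cfg$subjects)) stop_fc("[preflight] subject table not found: %s", cfg$subjects)
  cfg$k_range <- as.integer(cfg$k_range)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  # -- read & z-score -------------------------------------------------------
  say("[read] %d panels, atlas %s, subjects %s", length(panel_files),
      cfg$atlas, cfg$subjects)
  atlas <- read_atlas(cfg$atlas, delimiter = cfg$delimiter)
  subjects <- read_subjects(cfg$subjects, delimiter = cfg$delimiter)
  panels <- lapply(panel_files, read_panel, delimiter = cfg$delimiter,
                   orientation = cfg$orientation, header = cfg$header)
  names(panels) <- vapply(panels, function(p) p$subject_id, "")
  if (anyDuplicated(names(panels))) stop_fc("[read] duplicate panel subject ids")
  miss <- setdiff(names(panels), subjects$subject_id)
  if (length(miss)) stop_fc("[read] panel subject '%s' has no subject-table row", miss[1])
  comp_ids <- panels[[1]]$component_ids
  for (p in panels) {
    if (!identical(p$component_ids, comp_ids)) {
      stop_fc("[read] subject '%s' has different component ids", p$subject_id)
    }
  }
  check_atlas_covers(atlas, comp_ids)
  panels <- lapply(panels, zscore_panel)

  # -- edge graphs ----------------------------------------------------------
  say("[efc] building edge time series and eFC for %d subjects", length(panels))
  efcs <- lapply(panels, function(p) compute_efc(build_edge_timeseries(p)))
  if (isTRUE(cfg$write_efc)) {
    dir.create(file.path(cfg$out_dir, "efc"), showWarnings = FALSE)
    for (sid in names(efcs)) {
      write_matrix(efcs[[sid]], file.path(cfg$out_dir, "efc", paste0(sid, ".tsv")))
    }
  }

  # -- clustering -----------------------------------------------------------
  pooled <- identical(cfg$clustering, "pooled")
  sub_seeds <- derive_seeds(cfg$seed, length(efcs) + 1L)
  if (pooled) {
    say("[cluster] pooled mode: clustering the cohort-mean eFC, k in {%s}, %d restarts",
        paste(cfg$k_range, collapse = ","), cfg$n_restarts)
    mean_vals <- Reduce(`+`, lapply(efcs, `[[`, "values")) / length(efcs)
    mean_efc <- structure(list(values = mean_vals,
                               edge_index = efcs[[1]]$edge_index,
                               n_nodes = efcs[[1]]$n_nodes,
                               subject_id = "pooled"),
                          class = "efc_matrix")
    pooled_sweep <- sweep_k(mean_efc, cfg$k_range, cfg$n_restarts,
                            seed = sub_seeds[length(efcs) + 1L])
    sweeps <- lapply(names(efcs), function(sid) pooled_sweep)
    names(sweeps) <- names(efcs)
  } else {
    say("[cluster] per-subject k sweep, k in {%s}, %d restarts",
        paste(cfg$k_range, collapse = ","), cfg$n_restarts)
    sweeps <- vector("list", length(efcs))
    names(sweeps) <- names(efcs)
    for (a in seq_along(efcs)) {
      sweeps[[a]] <- sweep_k(efcs[[a]], cfg$k_range, cfg$n_restarts,
                             seed = sub_seeds[a])
      sweeps[[a]]$partitions <- lapply(sweeps[[a]]$partitions, function(p) {
        p$subject_id <- names(efcs)[a]; p
      })
      say("[cluster]   %s done (%d/%d)", names(efcs)[a], a, length(efcs))
    }
  }
  curves <- do.call(rbind, lapply(names(sweeps), function(sid) {
    cv <- sweeps[[sid]]$inertia_curve
    data.frame(subject_id = sid, k = cv$k, inertia = cv$inertia)
  }))
  utils::write.table(curves, file.path(cfg$out_dir, "inertia_curves.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  # -- k selection ----------------------------------------------------------
  if (identical(cfg$k_select, "elbow")) {
    if (length(cfg$k_range) < 2) {
      k_sel <- cfg$k_range[1]
    } else {
      norm_curves <- vapply(sweeps, function(sw) {
        cv <- sw$inertia_curve$inertia
        cv / cv[1]
      }, numeric(length(cfg$k_range)))
      mean_curve <- rowMeans(as.matrix(norm_curves))
      dr <- (mean_curve[-length(mean_curve)] - mean_curve[-1]) /
        mean_curve[-length(mean_curve)]
      k_sel <- cfg$k_range[which.max(dr) + 1L]
    }
    say("[select-k] elbow of the cohort-mean inertia curve selects k = %d (report all k!)", k_sel)
  } else {
    k_sel <- as.integer(cfg$k_select)
    if (!k_sel %in% cfg$k_range) stop_fc("[select-k] k_select = %d not in k_range", k_sel)
    say("[select-k] fixed k = %d from config", k_sel)
  }

  # -- entropy over every k -------------------------------------------------
  say("[entropy] component- and network-level entropy for every k in the sweep")
  ent_list <- lapply(cfg$k_range, function(kk) {
    parts <- lapply(sweeps, function(sw) sw$partitions[[as.character(kk)]])
    entropy_table(parts, atlas, comp_ids)
  })
  entropy <- do.call(rbind, ent_list)
  utils::write.table(entropy, file.path(cfg$out_dir, "entropy.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  if (isTRUE(cfg$write_partitions)) {
    dir.create(file.path(cfg$out_dir, "partitions"), showWarnings = FALSE)
    for (sid in names(sweeps)) {
      for (kk in cfg$k_range) {
        write_partition(sweeps[[sid]]$partitions[[as.character(kk)]],
                        file.path(cfg$out_dir, "partitions",
                                  sprintf("%s_k%02d.tsv", sid, kk)))
      }
    }
  }
  if (isTRUE(cfg$write_similarity)) {
    dir.create(file.path(cfg$out_dir, "similarity"), showWarnings = FALSE)
    for (sid in names(sweeps)) {
      s <- community_similarity(sweeps[[sid]]$partitions[[as.character(k_sel)]])
      utils::write.table(fmt_mat(s),
                         file.path(cfg$out_dir, "similarity",
                                   sprintf("%s_k%02d.tsv", sid, k_sel)),
                         sep = "\t", row.names = FALSE, col.names = FALSE,
                         quote = FALSE)
    }
  }

  # -- group statistics -----------------------------------------------------
  comparison <- NULL
  if (pooled) {
    say("[stats] pooled clustering shares one partition across subjects; group statistics skipped")
  } else {
    say("[stats] %s-level comparison at k = %d, covariates: %s",
        cfg$stat_level, k_sel,
        if (length(cfg$covariates)) paste(cfg$covariates, collapse = ", ") else "(none)")
    comparison <- compare_groups(entropy, subjects, level = cfg$stat_level,
                                 k = k_sel, covariates = cfg$covariates,
                                 alpha = cfg$alpha, welch = isTRUE(cfg$welch))
    utils::write.table(as.data.frame(comparison),
                       file.path(cfg$out_dir, sprintf("group_stats_k%02d.tsv", k_sel)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  manifest <- list(
    package = "edgefc", version = as.character(utils::packageVersion("edgefc")),
    config = cfg[setdiff(names(cfg), "verbose")],
    n_subjects = length(panels), n_components = length(comp_ids),
    n_edges = nrow(efcs[[1]]$values),
    selected_k = k_sel, k_selection_rule = if (identical(cfg$k_select, "elbow"))
      "largest relative drop of the cohort-mean normalized inertia curve" else "fixed by config",
    family_size = if (!is.null(comparison)) attr(comparison, "family_size") else NULL,
    bonferroni_threshold = if (!is.null(comparison))
      attr(comparison, "alpha") / attr(comparison, "family_size") else NULL,
    groups = attr(subjects, "groups"),
    subject_seeds = sub_seeds,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  say("[done] outputs in %s (%.1f s)", cfg$out_dir, manifest$elapsed_sec)
  invisible(list(entropy = entropy, comparison = comparison, k = k_sel,
                 manifest = manifest))
}
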