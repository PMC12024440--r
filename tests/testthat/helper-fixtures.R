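# Shared fixtures: everything is generated in code at test time.

rand_panel <- function(n = 5, t_len = 50, seed = 1, zscore = FALSE) {
  set.seed(seed)
  p <- ts_panel(matrix(rnorm(n * t_len), n, t_len),
                subject_id = sprintf("fix%d", seed))
  if (zscore) zscore_panel(p) else p
}

# Hand-built partition over the canonical edge order.
make_partition <- function(labels, n_nodes, k = max(labels)) {
  structure(list(labels = as.integer(labels), k = as.integer(k),
                 inertia = 0, restart_seed = 0L,
                 restart_inertias = numeric(0), n_reinit = 0L,
                 edge_index = edge_index(n_nodes), n_nodes = n_nodes,
                 subject_id = "hand"),
            class = "edge_partition")
}

# Synthetic eFC-like object from an arbitrary square matrix.
make_efc <- function(values, n_nodes) {
  structure(list(values = values, edge_index = edge_index(n_nodes),
                 n_nodes = n_nodes, subject_id = "hand"),
            class = "efc_matrix")
}

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# The planted three-edge-community benchmark design: two latent communities,
# strong primary loads; eFC then holds exactly three blocks (within-1,
# within-2, cross).
three_community_design <- function(n = 24, t_len = 400, noise_sd = 0.5) {
  simulation_design(n_components = n, n_networks = 2, k_latent = 2,
                    t_len = t_len, loading_primary = 0.9,
                    noise_sd = noise_sd, n_group1 = 2, n_group2 = 2)
}

# Heterogeneous-overlap cohort world used by the group-level benchmarks:
# one component per canonical network, mixing graded across networks.
cohort_world <- function(target = character(0), mixing_max = 0.75) {
  simulation_design(n_components = 16, n_networks = 16, t_len = 230,
                    k_latent = 3, loading_primary = 1, noise_sd = 0.5,
                    mixing = seq(0, mixing_max, length.out = 16),
                    target_networks = target, override_mix = 1)
}
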