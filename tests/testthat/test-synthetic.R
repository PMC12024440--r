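test_that("simulation_design validates inputs and builds loadings", {
  d <- simulation_design()
  expect_equal(dim(d$loadings), c(32L, 4L))
  expect_lt(max(abs(rowSums(d$loadings) - 1)), 1e-12)
  expect_equal(length(d$network_names), 16)
  expect_error(simulation_design(n_components = 30, n_networks = 16),
               "n_components")
  expect_error(simulation_design(target_networks = "Nope"),
               "'Nope' not among")
  bad <- matrix(1, 32, 4)
  expect_error(simulation_design(loadings = bad), "sum to 1")
  # mixing pulls rows toward the uniform mixture
  dm <- simulation_design(mixing = 1)
  expect_true(all(abs(dm$loadings - 0.25) < 1e-12))
})

test_that("planted ground truth matches hand calculations", {
  # 3 nodes, 2 latents, one-hot communities (1, 1, 2)
  W <- rbind(c(1, 0), c(1, 0), c(0, 1))
  d <- simulation_design(n_components = 3, n_networks = 3, k_latent = 2,
                         t_len = 50, noise_sd = 0, loadings = W,
                         n_group1 = 2, n_group2 = 2)
  sp <- simulate_panel(d, seed = 1)
  # edges (1,2), (1,3), (2,3); single-community argmax with tie -> lowest
  expect_equal(sp$edge_labels, c(1L, 1L, 1L))
  # latent-pair labels over (1,1), (1,2), (2,2)
  expect_equal(sp$edge_pair_labels, c(1L, 2L, 2L))
  expect_equal(sp$node_overlap, c(0, 0, 0))
  # mixed rows: normalized loading entropy
  W2 <- rbind(c(0.7, 0.3), c(1, 0), c(0.5, 0.5))
  d2 <- simulation_design(n_components = 3, n_networks = 3, k_latent = 2,
                          t_len = 50, noise_sd = 0.1, loadings = W2,
                          n_group1 = 2, n_group2 = 2)
  sp2 <- simulate_panel(d2, seed = 1)
  h07 <- -(0.7 * log2(0.7) + 0.3 * log2(0.3))
  expect_equal(sp2$node_overlap, c(h07, 0, 1))
})

test_that("one-hot loadings with zero noise give identical block series", {
  d <- simulation_design(n_components = 8, n_networks = 2, k_latent = 2,
                         t_len = 100, loading_primary = 1, noise_sd = 0,
                         n_group1 = 2, n_group2 = 2)
  sp <- simulate_panel(d, seed = 5)
  v <- sp$panel$values
  expect_equal(v[1, ], v[2, ])   # same block, same latent
  expect_false(isTRUE(all.equal(v[1, ], v[5, ])))
  # within-block edges have eFC exactly 1
  efc <- compute_efc(build_edge_timeseries(zscore_panel(sp$panel)))
  e12 <- pair_to_edge(1, 2, 8); e23 <- pair_to_edge(2, 3, 8)
  expect_equal(efc$values[e12, e23], 1)
})

test_that("separable loadings at zero noise are recovered exactly", {
  d <- simulation_design(n_components = 12, n_networks = 2, k_latent = 2,
                         t_len = 150, loading_primary = 1, noise_sd = 0,
                         n_group1 = 2, n_group2 = 2)
  sp <- simulate_panel(d, seed = 6)
  efc <- compute_efc(build_edge_timeseries(zscore_panel(sp$panel)))
  # three planted edge communities: within-1, within-2, cross
  p <- cluster_edges(efc, k = 3, n_restarts = 10, seed = 7)
  expect_equal(adjusted_rand_index(p$labels, sp$edge_pair_labels), 1)
})

test_that("empirical correlations converge to the design-implied form", {
  d200 <- simulation_design(n_components = 12, n_networks = 4, k_latent = 3,
                            t_len = 200, noise_sd = 0.5,
                            n_group1 = 2, n_group2 = 2)
  d2000 <- simulation_design(n_components = 12, n_networks = 4, k_latent = 3,
                             t_len = 2000, noise_sd = 0.5,
                             n_group1 = 2, n_group2 = 2)
  implied <- function(d) {
    cv <- d$loadings %*% t(d$loadings) + diag(d$noise_sd^2, d$n_components)
    stats::cov2cor(cv)
  }
  dev <- function(d, seed) {
    sp <- simulate_panel(d, seed)
    max(abs(cor(t(sp$panel$values)) - implied(d)))
  }
  devs200 <- sapply(1:3, function(s) dev(d200, s))
  devs2000 <- sapply(1:3, function(s) dev(d2000, s))
  expect_lt(mean(devs2000), mean(devs200))
  expect_lt(mean(devs2000), 0.1)
})

test_that("cohorts are deterministic and carry per-group truth", {
  d <- simulation_design(n_components = 6, n_networks = 3, k_latent = 2,
                         t_len = 40, n_group1 = 3, n_group2 = 4,
                         target_networks = "SomMotA", override_mix = 1)
  co1 <- simulate_cohort(d, 123)
  co2 <- simulate_cohort(d, 123)
  expect_identical(co1$panels[["S005"]]$values, co2$panels[["S005"]]$values)
  expect_identical(as.data.frame(co1$subjects), as.data.frame(co2$subjects))
  expect_equal(nrow(co1$subjects), 7)
  expect_equal(sort(unique(co1$subjects$group)), c("control", "patient"))
  # the override touches only the target network's components in group 2
  ov <- co1$truth$group2$node_overlap - co1$truth$group1$node_overlap
  target_comps <- which(d$net_of_comp == "SomMotA")
  expect_true(all(ov[target_comps] > 0))
  expect_true(all(ov[-target_comps] == 0))
  # a different master seed changes the data
  co3 <- simulate_cohort(d, 124)
  expect_false(identical(co1$panels[["S001"]]$values,
                         co3$panels[["S001"]]$values))
})

test_that("write_cohort emits files the readers consume, byte-stably", {
  d <- simulation_design(n_components = 6, n_networks = 3, k_latent = 2,
                         t_len = 30, n_group1 = 3, n_group2 = 3)
  co <- simulate_cohort(d, 55)
  dir1 <- file.path(tempfile(), "a"); dir2 <- file.path(tempfile(), "b")
  write_cohort(co, dir1)
  write_cohort(simulate_cohort(d, 55), dir2)
  f1 <- list.files(dir1, recursive = TRUE)
  expect_true(all(c("atlas.tsv", "subjects.tsv", "truth.json",
                    "panels/S001.tsv") %in% f1))
  for (f in f1) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), label = f)
  }
  # round-trip through the readers
  p <- read_panel(file.path(dir1, "panels", "S002.tsv"),
                  orientation = "columns")
  expect_equal(unname(p$values), unname(co$panels[["S002"]]$values),
               tolerance = 1e-12)
  atlas <- read_atlas(file.path(dir1, "atlas.tsv"))
  expect_identical(atlas$mapping, co$atlas$mapping)
  subj <- read_subjects(file.path(dir1, "subjects.tsv"))
  expect_equal(subj$group, co$subjects$group)
})

test_that("cohort_entropy returns a complete long table", {
  d <- simulation_design(n_components = 6, n_networks = 3, k_latent = 2,
                         t_len = 60, n_group1 = 2, n_group2 = 2)
  co <- simulate_cohort(d, 9)
  tbl <- cohort_entropy(co, k_range = 2:3, n_restarts = 2, seed = 10)
  expect_equal(nrow(tbl), 4 * 2 * (6 + 3))  # subjects x k x (comps + nets)
  expect_true(all(tbl$entropy >= 0 & tbl$entropy <= 1))
  expect_setequal(unique(tbl$k), 2:3)
})
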