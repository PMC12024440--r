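make_subjects <- function(n1 = 6, n2 = 6, seed = 1) {
  set.seed(seed)
  subject_table(data.frame(
    subject_id = sprintf("s%02d", seq_len(n1 + n2)),
    group = rep(c("patient", "control"), c(n1, n2)),
    age = round(rnorm(n1 + n2, 25, 5), 1),
    education = round(rnorm(n1 + n2, 13, 2), 1)))
}

test_that("residualize reduces to centering and absorbs exact fits", {
  subj <- make_subjects()
  v <- rnorm(12)
  expect_equal(residualize(v, subj), v - mean(v))
  # metric exactly linear in a covariate
  v2 <- 3 + 0.5 * subj$education
  expect_lt(max(abs(residualize(v2, subj, "education"))), 1e-10)
  # named values are aligned by subject id
  v3 <- stats::setNames(v, rev(subj$subject_id))
  expect_equal(residualize(v3, subj), rev(v) - mean(v))
  # collinear design errors with the offending column
  subj$edu2 <- subj$education * 2
  subj <- subject_table(as.data.frame(subj))
  expect_error(residualize(v, subj, c("education", "edu2")),
               "collinear.*edu2")
})

test_that("residualization recovers a planted group effect", {
  set.seed(77)
  n1 <- 40; n2 <- 50
  # education varies but is group-balanced: residualization removes its
  # contribution without absorbing the group effect (the group label is
  # never in the design, so a group-shifted covariate would attenuate it)
  subj <- subject_table(data.frame(
    subject_id = sprintf("s%03d", 1:(n1 + n2)),
    group = rep(c("a_grp", "b_grp"), c(n1, n2)),
    education = rnorm(n1 + n2, 13, 2.5)))
  planted <- 1.0
  metric <- planted * (subj$group == "b_grp") + 0.5 * subj$education +
    rnorm(n1 + n2, 0, 0.3)
  raw_diff <- mean(metric[subj$group == "b_grp"]) -
    mean(metric[subj$group == "a_grp"])
  adj <- residualize(metric, subj, "education")
  diff_adj <- mean(adj[subj$group == "b_grp"]) - mean(adj[subj$group == "a_grp"])
  expect_lt(abs(diff_adj - planted), 0.2)
  # and the adjustment shrinks the residual variance
  expect_lt(var(adj), var(metric - mean(metric)))
  # residualize -> t is invariant to affine covariate rescaling
  subj2 <- subj
  subj2$education <- subj2$education * 3.7 - 12
  subj2 <- subject_table(as.data.frame(subj2))
  t1 <- two_sample_t(residualize(metric, subj, "education"), subj$group)
  t2 <- two_sample_t(residualize(metric, subj2, "education"), subj2$group)
  expect_equal(t1$t, t2$t, tolerance = 1e-10)
})

test_that("two_sample_t matches the classical pooled formula", {
  x1 <- c(3.1, 2.8, 3.5, 3.0, 2.9, 3.3)
  x2 <- c(3.9, 4.2, 3.7, 4.0, 4.4, 3.8)
  res <- two_sample_t(c(x1, x2), rep(c("a", "b"), each = 6))
  # independent oracle: stats::t.test with equal variances
  or <- t.test(x2, x1, var.equal = TRUE)
  expect_equal(res$t, unname(or$statistic), tolerance = 1e-12)
  expect_equal(res$df, unname(or$parameter))
  expect_equal(res$p, or$p.value, tolerance = 1e-12)
  # identical distributions
  same <- two_sample_t(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # label swap negates t, keeps p
  sw <- two_sample_t(c(x1, x2), rep(c("b", "a"), each = 6))
  expect_equal(sw$t, -res$t)
  expect_equal(sw$p, res$p)
  # Welch variant against its oracle
  resw <- two_sample_t(c(x1, x2 * 3), rep(c("a", "b"), each = 6), welch = TRUE)
  orw <- t.test(x2 * 3, x1)
  expect_equal(resw$t, unname(orw$statistic), tolerance = 1e-12)
  expect_equal(resw$df, unname(orw$parameter), tolerance = 1e-10)
})

test_that("bonferroni is alpha over n", {
  expect_equal(bonferroni(0.05, 16), 0.003125)
  expect_equal(bonferroni(0.05, 1), 0.05)
  expect_equal(bonferroni(0.05, 9), 0.05 / 9)
  expect_error(bonferroni(0.05, 0), ">= 1")
})

test_that("chi_square_counts matches closed forms and the study's sex table", {
  prop <- matrix(c(10, 20, 5, 10), 2)  # perfectly proportional
  res <- chi_square_counts(prop)
  expect_equal(res$chisq, 0)
  expect_equal(res$p, 1)
  diag20 <- chi_square_counts(matrix(c(10, 0, 0, 10), 2))
  expect_equal(diag20$chisq, 20)
  expect_error(chi_square_counts(matrix(c(0, 0, 5, 10), 2)), "marginal")
  # independent oracle
  tab <- matrix(c(12, 5, 7, 9), 2)
  expect_equal(chi_square_counts(tab)$chisq,
               unname(suppressWarnings(chisq.test(tab, correct = FALSE))$statistic),
               tolerance = 1e-12)
  # 24M/9F vs 24M/20F: non-significant sex difference, p near 0.103
  sex <- chi_square_counts(matrix(c(24, 24, 9, 20), 2))
  expect_gt(sex$p, 0.05)
  expect_lt(sex$p, 0.2)
  # Yates correction shrinks the statistic
  expect_lt(chi_square_counts(tab, correct = TRUE)$chisq,
            chi_square_counts(tab)$chisq)
})

test_that("compare_groups flags separated units and keeps bookkeeping", {
  subj <- make_subjects(5, 5)
  g2 <- subj$group == sort(unique(subj$group))[2]
  ent <- rbind(
    data.frame(subject_id = subj$subject_id, level = "network", unit = "sep",
               k = 4, entropy = ifelse(g2, 0.9, 0.1) + seq(0, 0.009, length.out = 10)),
    data.frame(subject_id = subj$subject_id, level = "network", unit = "null",
               k = 4, entropy = rep(c(0.4, 0.5), 5)))
  res <- compare_groups(ent, subj, level = "network", alpha = 0.05)
  df <- as.data.frame(res)
  expect_equal(attr(res, "family_size"), 2)
  expect_equal(df$threshold, rep(0.025, 2))
  expect_true(df$significant[df$unit == "sep"])
  expect_false(df$significant[df$unit == "null"])
  expect_equal(df$significant, df$p_raw < df$threshold)
  # direction is group2 - group1, alphabetical groups
  expect_gt(df$t[df$unit == "sep"], 0)
  expect_match(df$direction[df$unit == "sep"], ">")
  # multiple k without an explicit k errors
  ent2 <- rbind(ent, transform(ent, k = 5))
  expect_error(compare_groups(ent2, subj), "multiple k")
  # sweep-mean aggregation works over the same table
  resm <- compare_groups(ent2, subj, k = "mean")
  expect_equal(attr(resm, "family_size"), 2)
  # a subject missing at the requested level errors
  expect_error(compare_groups(ent[ent$subject_id != "s01", ], subj),
               "missing from entropy")
})
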