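# Covariate-adjusted two-group comparisons with Bonferroni control.
#
# Confounders are handled by pooled OLS residualization: the metric is
# regressed on an intercept plus the named covariates over the pooled
# sample (the group label is never in the design), and the residuals enter
# a classical two-sample t test. Direction of effect is reported as
# group2 - group1 where group1 < group2 alphabetically.

#' Residualize a metric on covariates
#'
#' Ordinary least squares of `values` on an intercept plus the named
#' covariate columns of `subjects`, fitted on the pooled sample; returns the
#' residuals. With zero covariates this is mean-centering. The group label
#' is deliberately excluded from the design so group differences survive
#' adjustment.
#'
#' @param values numeric vector, one value per subject (named by subject_id
#'   or aligned with `subjects` rows).
#' @param subjects a `subject_table`.
#' @param covariates character vector of covariate column names (may be
#'   empty).
#' @return numeric vector of residuals, aligned with `subjects`.
#' @export
residualize <- function(values, subjects, covariates = character(0)) {
  stopifnot(inherits(subjects, "subject_table"))
  if (!is.null(names(values))) {
    miss <- setdiff(subjects$subject_id, names(values))
    if (length(miss)) stop_fc("no metric value for subject '%s'", miss[1])
    values <- values[subjects$subject_id]
  }
  if (length(values) != nrow(subjects)) {
    stop_fc("values length %d != %d subjects", length(values), nrow(subjects))
  }
  if (!length(covariates)) return(unname(values - mean(values)))
  miss <- setdiff(covariates, names(subjects))
  if (length(miss)) stop_fc("covariate column '%s' not in subject table", miss[1])
  x <- cbind(`(Intercept)` = 1,
             as.matrix(as.data.frame(subjects)[, covariates, drop = FALSE]))
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dropped <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop_fc("rank-deficient covariate design; collinear column(s): %s",
            paste(dropped, collapse = ", "))
  }
  unname(qr.resid(qx, values))
}

#' Classical two-sample t test
#'
#' Pooled-variance (equal-variance) two-sample t by default, matching the
#' textbook "two-sample independent t test"; `welch = TRUE` switches to the
#' Welch unequal-variance form. Two-sided p. The statistic is computed on
#' group2 - group1 with groups in alphabetical order.
#'
#' @param values numeric vector.
#' @param groups vector with exactly two distinct labels, same length.
#' @param welch use the Welch correction (default FALSE).
#' @return list with `t`, `df`, `p`, `group1`, `group2`, and per-group
#'   `mean` and `sd`.
#' @export
two_sample_t <- function(values, groups, welch = FALSE) {
  groups <- as.character(groups)
  g <- sort(unique(groups))
  if (length(g) != 2) stop_fc("need exactly 2 groups, found %d", length(g))
  x1 <- values[groups == g[1]]
  x2 <- values[groups == g[2]]
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 2 || n2 < 2) stop_fc("each group needs >= 2 subjects")
  v1 <- stats::var(x1); v2 <- stats::var(x2)
  if (v1 == 0 && v2 == 0 && mean(x2) == mean(x1)) {
    tt <- 0
    df <- n1 + n2 - 2
  } else if (welch) {
    se2 <- v1 / n1 + v2 / n2
    tt <- (mean(x2) - mean(x1)) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tt <- (mean(x2) - mean(x1)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df),
       group1 = g[1], group2 = g[2],
       mean1 = mean(x1), sd1 = stats::sd(x1),
       mean2 = mean(x2), sd2 = stats::sd(x2))
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error level (default 0.05).
#' @param n number of comparisons in the family (>= 1).
#' @return alpha / n.
#' @export
bonferroni <- function(alpha = 0.05, n) {
  if (n < 1) stop_fc("Bonferroni family size must be >= 1, got %s", n)
  alpha / n
}

#' Pearson chi-square test on a 2x2 count table
#'
#' Pearson's statistic without continuity correction by default (the
#' `correct` switch enables Yates). A zero row or column marginal makes the
#' expected counts degenerate and errors.
#'
#' @param counts 2x2 matrix of nonnegative integer counts.
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return list with `chisq`, `df`, `p`.
#' @export
chi_square_counts <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) stop_fc("counts must be a 2x2 table")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_fc("counts must be nonnegative integers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop_fc("chi-square undefined: a row or column marginal is zero")
  }
  n <- sum(counts)
  expected <- outer(rowSums(counts), colSums(counts)) / n
  dev <- abs(counts - expected)
  if (correct) dev <- pmax(dev - 0.5, 0)
  chisq <- sum(dev^2 / expected)
  list(chisq = chisq, df = 1,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Covariate-adjusted group comparison of entropy
#'
#' For every unit (network or component) at the requested k: residualize the
#' per-subject entropy on the covariates ([residualize()]), run the
#' two-sample t test between cohorts, and apply Bonferroni control over the
#' family of units. The family size n equals the number of units tested and
#' is recorded in the result. Effects are signed group2 - group1 with groups
#' sorted alphabetically.
#'
#' @param entropy long-format entropy table ([entropy_table()]).
#' @param subjects a `subject_table` covering every subject in `entropy`.
#' @param level "network" (default) or "component".
#' @param k which partition k to test (default: the single k present), or
#'   `"mean"` to test each subject's entropy averaged over every k in the
#'   table — the sweep-level overlap summary used when no single k is
#'   privileged.
#' @param covariates covariate column names to residualize on.
#' @param alpha family-wise error level.
#' @param welch use Welch's t.
#' @return An object of class `group_comparison`: a data.frame (one row per
#'   unit, sorted by raw p) with columns unit, t, df, p_raw, threshold,
#'   significant, mean_g1, sd_g1, mean_g2, sd_g2, direction; attributes
#'   record the family size, alpha, k, groups and covariates.
#' @export
compare_groups <- function(entropy, subjects, level = c("network", "component"),
                           k = NULL, covariates = character(0), alpha = 0.05,
                           welch = FALSE) {
  level <- match.arg(level)
  stopifnot(inherits(subjects, "subject_table"))
  sub <- entropy[entropy$level == level, , drop = FALSE]
  if (is.null(k)) {
    ks <- unique(sub$k)
    if (length(ks) != 1) {
      stop_fc("entropy table holds multiple k (%s); pass k explicitly",
              paste(ks, collapse = ", "))
    }
    k <- ks
  }
  if (identical(k, "mean")) {
    agg <- stats::aggregate(entropy ~ subject_id + unit, data = sub, FUN = mean)
    agg$level <- level
    agg$k <- 0L   # sentinel: sweep-mean, recorded in attributes
    sub <- agg
  } else {
    sub <- sub[sub$k == k, , drop = FALSE]
  }
  if (!nrow(sub)) stop_fc("no %s-level entropy rows at k = %s", level, k)
  miss <- setdiff(subjects$subject_id, unique(sub$subject_id))
  if (length(miss)) stop_fc("subject '%s' missing from entropy table at k = %s",
                            miss[1], k)
  units <- unique(sub$unit)
  n_family <- length(units)
  thr <- bonferroni(alpha, n_family)
  grp <- stats::setNames(subjects$group, subjects$subject_id)
  rows <- lapply(units, function(u) {
    du <- sub[sub$unit == u, , drop = FALSE]
    vals <- stats::setNames(du$entropy, du$subject_id)
    adj <- residualize(vals, subjects, covariates)
    tt <- two_sample_t(adj, grp[subjects$subject_id], welch = welch)
    raw <- vals[subjects$subject_id]
    g <- sort(unique(subjects$group))
    data.frame(unit = u, t = tt$t, df = tt$df, p_raw = tt$p, threshold = thr,
               significant = tt$p < thr,
               mean_g1 = mean(raw[subjects$group == g[1]]),
               sd_g1 = stats::sd(raw[subjects$group == g[1]]),
               mean_g2 = mean(raw[subjects$group == g[2]]),
               sd_g2 = stats::sd(raw[subjects$group == g[2]]),
               direction = ifelse(tt$t >= 0, sprintf("%s>%s", g[2], g[1]),
                                  sprintf("%s<%s", g[2], g[1])))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_raw), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "family_size") <- n_family
  attr(out, "alpha") <- alpha
  attr(out, "k") <- k
  attr(out, "level") <- level
  attr(out, "covariates") <- covariates
  attr(out, "groups") <- sort(unique(subjects$group))
  class(out) <- c("group_comparison", "data.frame")
  out
}
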