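# Nonparametric group comparisons over per-animal TBR values: the
# Kruskal-Wallis ANOVA on ranks with Dunn's post hoc pairwise analysis for
# the multi-group design, and the Mann-Whitney rank sum test for two-group
# contrasts. All tests are two-sided; ties are handled by mid-ranks with
# the usual variance correction.

as_groups <- function(groups) {
  if (is.data.frame(groups))
    groups <- split(groups$value, groups$group)
  if (!is.list(groups) || length(groups) < 1)
    ebtbr_error("groups must be a named list of numeric vectors",
                "ebtbr_parameter_error")
  labs <- names(groups) %||% as.character(seq_along(groups))
  if (is.null(names(groups))) names(groups) <- labs
  for (g in groups) {
    if (length(g) < 1 || !all(is.finite(g)))
      ebtbr_error("each group needs >= 1 finite observation",
                  "ebtbr_parameter_error")
  }
  groups
}

check_not_degenerate <- function(groups) {
  pooled <- unlist(groups, use.names = FALSE)
  if (length(unique(pooled)) == 1)
    ebtbr_error("all observations are identical; rank tests are undefined",
                "ebtbr_degenerate_error")
}

#' Median and quartile summary per group
#'
#' The reporting convention used alongside the rank tests: median with
#' first and third quartiles.
#'
#' @param groups named list of numeric vectors (one per group), or a
#'   data.frame with columns `value` and `group`.
#' @return data.frame with columns `label`, `n`, `q1`, `median`, `q3`.
#' @export
group_summary <- function(groups) {
  groups <- as_groups(groups)
  do.call(rbind, lapply(names(groups), function(nm) {
    q <- stats::quantile(groups[[nm]], c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(label = nm, n = length(groups[[nm]]),
               q1 = q[1], median = q[2], q3 = q[3],
               stringsAsFactors = FALSE)
  }))
}

# H statistic from per-group rank sums, with tie correction.
kw_H <- function(rank_sums, ns, N, tie_corr) {
  H <- 12 / (N * (N + 1)) * sum(rank_sums^2 / ns) - 3 * (N + 1)
  H / tie_corr
}

kw_tie_correction <- function(pooled) {
  t <- table(pooled)
  1 - sum(t^3 - t) / (length(pooled)^3 - length(pooled))
}

# Exact permutation p-value for the Kruskal-Wallis H: enumerate every
# distinct assignment of the pooled observations to groups of the observed
# sizes (equivalent to full permutation enumeration, since within-group
# order does not change H) and count assignments with H >= observed.
kw_exact_p <- function(pooled, ns, H_obs) {
  N <- length(pooled)
  ranks <- rank(pooled)
  tie_corr <- kw_tie_correction(pooled)
  if (tie_corr <= 0)
    ebtbr_error("all observations are identical; rank tests are undefined",
                "ebtbr_degenerate_error")
  k <- length(ns)
  count <- 0
  total <- 0
  recurse <- function(avail, gi, sums) {
    if (gi == k) {
      sums[k] <- sum(ranks[avail])
      H <- kw_H(sums, ns, N, tie_corr)
      total <<- total + 1
      if (H >= H_obs - 1e-9) count <<- count + 1
      return(invisible())
    }
    cmb <- utils::combn(avail, ns[gi])
    for (j in seq_len(ncol(cmb))) {
      sums[gi] <- sum(ranks[cmb[, j]])
      recurse(setdiff(avail, cmb[, j]), gi + 1L, sums)
    }
  }
  recurse(seq_len(N), 1L, numeric(k))
  count / total
}

#' Kruskal-Wallis ANOVA on ranks
#'
#' Tie-corrected H statistic with the chi-square approximation
#' (df = k - 1). For small samples (total n <= 12) an exact permutation
#' p-value can be requested, computed by exhaustive enumeration of group
#' assignments.
#'
#' @param groups named list of numeric vectors (one per group), or a
#'   data.frame with columns `value` and `group`.
#' @param exact also compute the exact permutation p-value?
#' @return an object of class `test_report` with `statistic` (H), `df`,
#'   `p_value` (chi-square approximation) and, if requested, `p_exact`.
#' @export
kruskal_wallis <- function(groups, exact = FALSE) {
  groups <- as_groups(groups)
  if (length(groups) < 2)
    ebtbr_error("kruskal_wallis needs >= 2 groups", "ebtbr_parameter_error")
  pooled <- unlist(groups, use.names = FALSE)
  if (length(pooled) < 3)
    ebtbr_error("kruskal_wallis needs total n >= 3", "ebtbr_parameter_error")
  check_not_degenerate(groups)
  labels <- factor(rep(names(groups), lengths(groups)),
                   levels = names(groups))
  kt <- stats::kruskal.test(pooled, labels)
  report <- structure(list(test_name = "Kruskal-Wallis ANOVA on ranks",
                           statistic = unname(kt$statistic),
                           df = unname(kt$parameter),
                           p_value = kt$p.value,
                           groups = group_summary(groups),
                           pairwise = NULL),
                      class = "test_report")
  if (exact) {
    if (length(pooled) > 12)
      ebtbr_error("exact Kruskal-Wallis enumeration limited to total n <= 12",
                  "ebtbr_parameter_error")
    report$p_exact <- kw_exact_p(pooled, lengths(groups), report$statistic)
  }
  report
}

#' Dunn's post hoc pairwise comparisons
#'
#' After a significant Kruskal-Wallis result, compares every pair of
#' groups via z statistics on mean ranks of the pooled sample, with
#' tie-corrected pooled variance and (by default) Bonferroni adjustment
#' over the k(k-1)/2 comparisons, flagging pairs significant at `alpha`.
#'
#' @inheritParams kruskal_wallis
#' @param alpha significance level for the flags.
#' @param adjust `"bonferroni"` (Dunn's classical multiplicity control) or
#'   `"none"`.
#' @return a `test_report` whose `pairwise` data.frame has one row per
#'   pair: `group1`, `group2`, `z`, `p_raw`, `p_adjusted`, `significant`.
#' @export
dunn_posthoc <- function(groups, alpha = 0.05,
                         adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  groups <- as_groups(groups)
  if (length(groups) < 3)
    ebtbr_error("dunn_posthoc needs >= 3 groups (use mann_whitney for 2)",
                "ebtbr_parameter_error")
  check_not_degenerate(groups)
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  rk <- rank(pooled)
  labels <- rep(names(groups), lengths(groups))
  mean_ranks <- tapply(rk, labels, mean)
  ns <- lengths(groups)
  t <- table(pooled)
  tie_term <- sum(t^3 - t) / (12 * (N - 1))
  sigma2 <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(names(groups), 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    se <- sqrt(sigma2 * (1 / ns[[g1]] + 1 / ns[[g2]]))
    z <- (mean_ranks[[g1]] - mean_ranks[[g2]]) / se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group1 = g1, group2 = g2, z = z, p_raw = p,
               stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, rows)
  pw$p_adjusted <- if (adjust == "bonferroni") pmin(1, pw$p_raw * m)
                   else pw$p_raw
  pw$significant <- pw$p_adjusted < alpha
  structure(list(test_name = sprintf("Dunn's post hoc test (%s)", adjust),
                 statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                 alpha = alpha,
                 groups = group_summary(groups),
                 pairwise = pw),
            class = "test_report")
}

#' Mann-Whitney rank sum test
#'
#' Two-sided U test. The p-value is exact (from the full permutation
#' distribution of U) when the smaller sample has at most 8 observations
#' and there are no ties; otherwise the normal approximation with
#' mid-ranks, tie-corrected variance and continuity correction is used.
#'
#' @param a,b numeric vectors of observations for the two groups.
#' @return a `test_report` with `statistic` (U for `a` vs `b`), `p_value`
#'   and `exact` (logical).
#' @export
mann_whitney <- function(a, b) {
  if (length(a) < 1 || length(b) < 1 || !all(is.finite(c(a, b))))
    ebtbr_error("both samples need >= 1 finite observation",
                "ebtbr_parameter_error")
  check_not_degenerate(list(a = a, b = b))
  has_ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- min(length(a), length(b)) <= 8 && !has_ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE))
  structure(list(test_name = "Mann-Whitney rank sum test",
                 statistic = unname(wt$statistic),
                 df = NA_real_,
                 p_value = wt$p.value,
                 exact = use_exact,
                 groups = group_summary(list(a = a, b = b)),
                 pairwise = NULL),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("<test_report> %s\n", x$test_name))
  if (is.finite(x$statistic))
    cat(sprintf("  statistic = %.4f%s, p = %.4g%s\n", x$statistic,
                if (is.finite(x$df %||% NA)) sprintf(" (df = %g)", x$df)
                else "",
                x$p_value,
                if (!is.null(x$p_exact))
                  sprintf(" (exact permutation p = %.4g)", x$p_exact)
                else ""))
  if (!is.null(x$pairwise)) {
    cat(sprintf("  pairwise comparisons (alpha = %.3g):\n", x$alpha))
    for (j in seq_len(nrow(x$pairwise))) {
      r <- x$pairwise[j, ]
      cat(sprintf("    %s vs %s: z = %+.3f, adj. p = %.4g%s\n",
                  r$group1, r$group2, r$z, r$p_adjusted,
                  if (r$significant) " *" else ""))
    }
  }
  invisible(x)
}
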