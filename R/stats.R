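#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Two-sided two-sample KS test (sup distance between the empirical
#' CDFs) with asymptotic p-value, as used to compare pooled per-molecule
#' diffusion-coefficient distributions between conditions.
#'
#' @param sample_a,sample_b numeric vectors (n >= 10 each).
#' @param label_a,label_b group labels for the report.
#' @return A `comparison_result` list: `test`, `groups`, `statistic`,
#'   `p_value`, and per-group `mean`, `sd`, `n`.
#' @export
ks_compare <- function(sample_a, sample_b, label_a = "a", label_b = "b") {
  if (!length(sample_a) || !length(sample_b)) stop("empty sample")
  if (length(sample_a) < 10 || length(sample_b) < 10)
    warning("fewer than 10 observations in a group")
  kt <- suppressWarnings(ks.test(sample_a, sample_b, exact = FALSE))
  structure(list(test = "KS", groups = c(label_a, label_b),
                 statistic = unname(kt$statistic),
                 p_value = unname(kt$p.value),
                 group_stats = data.frame(
                   group = c(label_a, label_b),
                   mean = c(mean(sample_a), mean(sample_b)),
                   sd = c(sd(sample_a), sd(sample_b)),
                   n = c(length(sample_a), length(sample_b)))),
            class = "comparison_result")
}

#' Per-cell group comparisons (t-test / ANOVA + Bonferroni)
#'
#' Compares per-cell summary values (bound fractions, diffusion
#' coefficients) between conditions: a two-tailed unpaired t-test for a
#' pair of groups, or one-way ANOVA followed by all pairwise t-tests with
#' Bonferroni adjustment (`p_adj = min(1, p * m)`, `m` = number of
#' pairs) for more than two groups.
#'
#' @param groups named list of numeric per-cell vectors (>= 2 cells
#'   each).
#' @param test `"ttest"` (2 groups) or `"anova_bonferroni"`.
#' @return List of `comparison_result`s, one per pair; for ANOVA the
#'   overall F-test is attached as attribute `"anova"`.
#' @export
percell_compare <- function(groups, test = c("ttest", "anova_bonferroni")) {
  test <- match.arg(test)
  if (length(groups) < 2) stop("need at least two groups")
  if (any(lengths(groups) < 2)) stop("need >= 2 cells per group")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  m <- length(pairs)
  mk <- function(a, b, stat, p, p_adj, lab) {
    structure(list(test = lab, groups = c(a, b), statistic = stat,
                   p_value = p_adj, p_raw = p,
                   group_stats = data.frame(
                     group = c(a, b),
                     mean = c(mean(groups[[a]]), mean(groups[[b]])),
                     sd = c(sd(groups[[a]]), sd(groups[[b]])),
                     n = c(length(groups[[a]]), length(groups[[b]])))),
              class = "comparison_result")
  }
  if (test == "ttest") {
    if (length(groups) != 2)
      stop("ttest requires exactly two groups; use anova_bonferroni")
    a <- names(groups)[1]; b <- names(groups)[2]
    tt <- t.test(groups[[a]], groups[[b]], var.equal = TRUE)
    return(list(mk(a, b, unname(tt$statistic), tt$p.value, tt$p.value,
                   "t-test")))
  }
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups), lengths(groups))))
  an <- aov(value ~ group, data = df)
  out <- lapply(pairs, function(pr) {
    tt <- t.test(groups[[pr[1]]], groups[[pr[2]]], var.equal = TRUE)
    mk(pr[1], pr[2], unname(tt$statistic), tt$p.value,
       min(1, tt$p.value * m), "ANOVA+Bonferroni")
  })
  attr(out, "anova") <- summary(an)
  out
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<%s> %s vs %s: statistic %.4g, p %.3g\n", x$test,
              x$groups[1], x$groups[2], x$statistic, x$p_value))
  invisible(x)
}
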