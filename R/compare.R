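# Group summaries and the comparison statistics used for motility and
# density data: two-tailed unpaired t-test for two groups, Kruskal-Wallis
# followed by Dunn's multiple-comparison z-tests for three or more.

#' Per-group mean, SD and SEM
#'
#' @param values Numeric vector of observations.
#' @param groups Vector of group keys, same length as `values`.
#' @return A `data.frame` per group: `group`, `n`, `mean`, `sd`, `sem`,
#'   `single_observation`. A group of one observation has no sample SD;
#'   it is reported as 0 with the flag set.
#' @examples
#' summarize_groups(c(2, 4, 10, 12, 14), c("a", "a", "b", "b", "b"))
#' @export
summarize_groups <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  if (length(values) == 0L) stop("no observations", call. = FALSE)
  g <- factor(groups, levels = unique(as.character(groups)))
  out <- do.call(rbind, lapply(split(as.numeric(values), g), function(v) {
    s <- if (length(v) > 1L) stats::sd(v) else 0
    data.frame(n = length(v), mean = mean(v), sd = s,
               sem = s / sqrt(length(v)),
               single_observation = length(v) == 1L)
  }))
  data.frame(group = levels(g), out, row.names = NULL,
             stringsAsFactors = FALSE)
}

significance_band <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "ns")))
}

#' Dunn's multiple-comparison z-tests
#'
#' Post-hoc pairwise comparisons after Kruskal-Wallis, on the pooled
#' mid-ranks with tie correction. The default multiplicity adjustment is
#' Bonferroni over all pairs (the common Prism convention); `"holm"` and
#' `"none"` are available.
#'
#' @param values Numeric observations.
#' @param groups Group keys.
#' @param p_adjust `"bonferroni"` (default), `"holm"` or `"none"`.
#' @return A `data.frame` per pair: `group1`, `group2`, `z`, `p_raw`,
#'   `p_adj`, `band`.
#' @export
dunn_test <- function(values, groups, p_adjust = "bonferroni") {
  p_adjust <- match.arg(p_adjust, c("bonferroni", "holm", "none"))
  g <- factor(groups, levels = unique(as.character(groups)))
  x <- as.numeric(values)
  N <- length(x)
  r <- rank(x)                                  # mid-ranks
  rbar <- tapply(r, g, mean)
  n <- tabulate(g)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_corr
  lev <- levels(g)
  pairs <- utils::combn(seq_along(lev), 2L)
  z <- apply(pairs, 2L, function(ij) {
    (rbar[ij[1]] - rbar[ij[2]]) /
      sqrt(s2 * (1 / n[ij[1]] + 1 / n[ij[2]]))
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  p_adj <- stats::p.adjust(p_raw, method = if (p_adjust == "none")
    "none" else p_adjust)
  data.frame(group1 = lev[pairs[1L, ]], group2 = lev[pairs[2L, ]],
             z = as.numeric(z), p_raw = p_raw, p_adj = p_adj,
             band = significance_band(p_adj),
             stringsAsFactors = FALSE)
}

#' Compare observation groups
#'
#' Two groups: two-tailed unpaired t-test. Three or more: Kruskal-Wallis
#' (mid-ranks, tie-corrected) followed by [dunn_test()]. Significance
#' bands: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001.
#'
#' @inheritParams dunn_test
#' @param var_equal Pool variances in the two-group t-test (default
#'   `TRUE`, the classical unpaired t-test).
#' @return A `comparison_result` list: `test`, `statistic`, `p_value`,
#'   `pairwise` (a data frame of pairs with adjusted p and band).
#' @examples
#' compare_groups(c(1, 2, 3, 14, 15, 16), rep(c("pbs", "ctx"), each = 3))
#' @export
compare_groups <- function(values, groups, p_adjust = "bonferroni",
                           var_equal = TRUE) {
  stopifnot(length(values) == length(groups))
  g <- factor(groups, levels = unique(as.character(groups)))
  x <- as.numeric(values)
  n <- tabulate(g)
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  small <- levels(g)[n < 2L]
  if (length(small))
    stop("group(s) with fewer than 2 observations: ",
         paste(small, collapse = ", "), call. = FALSE)
  if (nlevels(g) == 2L) {
    tt <- stats::t.test(x[g == levels(g)[1]], x[g == levels(g)[2]],
                        var.equal = var_equal)
    pairwise <- data.frame(group1 = levels(g)[1], group2 = levels(g)[2],
                           z = unname(tt$statistic),
                           p_raw = tt$p.value, p_adj = tt$p.value,
                           band = significance_band(tt$p.value),
                           stringsAsFactors = FALSE)
    res <- list(test = "two-tailed unpaired t-test",
                statistic = unname(tt$statistic), p_value = tt$p.value,
                pairwise = pairwise)
  } else {
    kw <- stats::kruskal.test(x, g)
    res <- list(test = "Kruskal-Wallis + Dunn's multiple comparisons",
                statistic = unname(kw$statistic), p_value = kw$p.value,
                pairwise = dunn_test(x, g, p_adjust = p_adjust))
  }
  structure(res, class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s\n  global statistic %.4g, p = %.4g\n",
              x$test, x$statistic, x$p_value))
  pw <- x$pairwise
  for (i in seq_len(nrow(pw)))
    cat(sprintf("  %s vs %s: adjusted p = %.4g %s\n",
                pw$group1[i], pw$group2[i], pw$p_adj[i], pw$band[i]))
  invisible(x)
}

#' Fold change between two positive quantities
#'
#' @param a,b Positive values; the ratio `a / b` is returned.
#' @return `a / b`.
#' @examples
#' fold_change(4.92, 2.07) # ~2.4-fold
#' @export
fold_change <- function(a, b) {
  if (any(b <= 0)) stop("reference value must be > 0", call. = FALSE)
  a / b
}
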