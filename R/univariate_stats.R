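#' Mann-Whitney U test for two groups
#'
#' Reports the U statistic of the first group
#' (`U1 = sum(ranks of x) - n1(n1+1)/2`) with a two-sided p-value: exact when
#' `n1*n2 <= 400` and there are no ties, normal approximation with tie
#' correction (no continuity correction) otherwise.
#'
#' @param x,y non-empty numeric vectors (first and second group).
#' @param variable optional variable name carried into the result.
#' @return An object of class `group_test_result` with fields `variable`,
#'   `test` ("U"), `statistic` (U1), `p`, `exact`, and per-group mean/SD.
#' @export
mann_whitney_u <- function(x, y, variable = deparse(substitute(x))) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) stopf("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- length(x) * length(y) <= 400 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = FALSE)
  )
  structure(list(variable = variable, test = "U",
                 statistic = unname(wt$statistic), p = wt$p.value,
                 exact = exact,
                 group1 = c(mean = mean(x), sd = stats::sd(x), n = length(x)),
                 group2 = c(mean = mean(y), sd = stats::sd(y), n = length(y))),
            class = "group_test_result")
}

#' Pearson chi-square test for a 2x2 table
#'
#' Uncorrected (no Yates continuity correction) Pearson statistic, equal to
#' the closed form `N*(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, with df = 1.
#'
#' @param table 2x2 matrix of non-negative counts with positive margins.
#' @param variable optional variable name.
#' @return A `group_test_result` with `test` = "chi2".
#' @export
chi_square_2x2 <- function(table, variable = "table") {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stopf("need a 2x2 table")
  if (any(tab < 0)) stopf("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) stopf("zero margin")
  n <- sum(tab)
  stat <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
    prod(rowSums(tab), colSums(tab))
  structure(list(variable = variable, test = "chi2",
                 statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 exact = FALSE, group1 = tab[, 1], group2 = tab[, 2]),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("%s: %s = %.4g, p = %.3g%s\n", x$variable,
              if (x$test == "U") "U" else "chi-square", x$statistic, x$p,
              if (isTRUE(x$exact)) " (exact)" else ""))
  invisible(x)
}

#' Per-feature univariate group screen
#'
#' Runs a Mann-Whitney U test (positive group first) for every feature and
#' applies Benjamini-Hochberg FDR correction across the whole feature family
#' at threshold `q`. On cohorts with sparse moderate multivariate effects at
#' small n this screen is expected to flag nothing - the regime in which only
#' the multivariate classifier detects the group difference.
#'
#' @param ft labeled [feature_table()].
#' @param q FDR threshold (default 0.05).
#' @return data.frame with one row per feature: `feature`, `u`, `p`, `p_adj`,
#'   `significant`, plus group means; `n_significant` attribute gives the
#'   flagged count.
#' @export
group_screen <- function(ft, q = 0.05) {
  stopifnot(inherits(ft, "feature_table"))
  if (is.null(ft$labels)) stopf("group screen needs a labeled table")
  pos <- ft$labels == 1L
  res <- lapply(seq_along(ft$feature_names), function(j) {
    r <- mann_whitney_u(ft$values[pos, j], ft$values[!pos, j],
                        variable = ft$feature_names[j])
    data.frame(feature = r$variable, u = r$statistic, p = r$p,
               mean_pos = r$group1[["mean"]], mean_neg = r$group2[["mean"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  fdr <- bh_fdr(out$p, q)
  out$p_adj <- fdr$adjusted
  out$significant <- fdr$significant
  attr(out, "n_significant") <- sum(out$significant)
  out
}
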