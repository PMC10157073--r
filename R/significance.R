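#' Permutation test of cross-validated balanced accuracy
#'
#' Reruns the entire nested cross-validation pipeline (wrapper selection and
#' penalty search included) on label-permuted copies of the data, and compares
#' the observed cross-validated balanced accuracy against the resulting null
#' distribution. The p-value uses the add-one correction
#' `p = (1 + #(null >= observed)) / (1 + n_perm)`, so it lies in `(0, 1]`.
#'
#' @param ft labeled [feature_table()].
#' @param n_perm number of label permutations (>= 1).
#' @param seed master seed governing permutations and every nested-CV rerun.
#' @param ... pipeline arguments forwarded to [run_nested_cv()]
#'   (`outer_k`, `inner_k`, `C_grid`, ...).
#' @return An object of class `permutation_result`: `observed_bac`,
#'   `null_bac`, `p_value`, `n_perm`.
#' @export
permutation_test <- function(ft, n_perm = 200, seed = 1, ...) {
  stopifnot(inherits(ft, "feature_table"))
  if (is.null(ft$labels)) stopf("permutation test needs a labeled table")
  if (n_perm < 1L) stopf("n_perm must be >= 1")
  observed <- run_nested_cv(ft, seed = seed, ...)$confusion$bac
  null_bac <- vapply(seq_len(n_perm), function(i) {
    ft_i <- generate_null_labels(ft, seed = derive_seed(seed, 3L, i))
    run_nested_cv(ft_i, seed = derive_seed(seed, 4L, i), ...)$confusion$bac
  }, numeric(1))
  structure(list(observed_bac = observed, null_bac = null_bac,
                 p_value = (1 + sum(null_bac >= observed)) / (1 + n_perm),
                 n_perm = as.integer(n_perm)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("observed BAC = %.3f; P_%d = %.4g (null mean %.3f)\n",
              x$observed_bac, x$n_perm, x$p_value, mean(x$null_bac)))
  invisible(x)
}

ensemble_weight_matrix <- function(x) {
  if (inherits(x, "nested_cv_result")) x <- x$ensemble
  if (inherits(x, "svm_ensemble")) {
    w <- do.call(rbind, lapply(x$members, `[[`, "w_full"))
    colnames(w) <- x$feature_names
    return(w)
  }
  as.matrix(x)
}

#' Cross-validation ratio of feature weights
#'
#' The CVR of a feature is its mean weight across the models in which the
#' wrapper selected it, divided by the standard error of that mean
#' (`SD/sqrt(m)`, `m` = number of selecting models) - a Z-score-like index of
#' how stably the feature was weighted throughout the cross-validation
#' structure. Never-selected features get `NA`; zero spread (including
#' single-model selection) yields a signed infinite sentinel with a warning.
#' A plain-SD denominator is available via `denominator = "sd"`.
#'
#' @param x an `svm_ensemble`, a `nested_cv_result`, or a models-by-features
#'   weight matrix with zeros for unselected features.
#' @param denominator `"se"` (default) or `"sd"`.
#' @return data.frame with `feature`, `m`, `mean_w`, `sd_w`, `cvr`.
#' @export
compute_cvr <- function(x, denominator = c("se", "sd")) {
  denominator <- match.arg(denominator)
  w <- ensemble_weight_matrix(x)
  if (nrow(w) < 2L) stopf("need weight records from at least 2 models")
  zero_spread <- character(0)
  res <- lapply(seq_len(ncol(w)), function(j) {
    wi <- w[w[, j] != 0, j]
    m <- length(wi)
    if (m == 0L) {
      return(data.frame(m = 0L, mean_w = NA_real_, sd_w = NA_real_,
                        cvr = NA_real_))
    }
    mu <- mean(wi)
    sdw <- if (m >= 2L) stats::sd(wi) else 0
    den <- if (denominator == "se") sdw / sqrt(m) else sdw
    cvr <- if (mu == 0) 0 else if (den == 0) {
      zero_spread <<- c(zero_spread, colnames(w)[j] %||% as.character(j))
      sign(mu) * Inf
    } else {
      mu / den
    }
    data.frame(m = m, mean_w = mu, sd_w = sdw, cvr = cvr)
  })
  if (length(zero_spread)) {
    warnf("zero weight spread for %d feature(s) (e.g. %s); CVR set to signed Inf",
          length(zero_spread), zero_spread[1])
  }
  cbind(data.frame(feature = colnames(w) %||% paste0("feature_", seq_len(ncol(w))),
                   stringsAsFactors = FALSE),
        do.call(rbind, res))
}

#' Sign-based consistency of feature weights
#'
#' For each feature, tests whether the sign of its weight across the models
#' that selected it departs from a fair coin: a two-sided exact binomial test
#' of the positive-sign count against 0.5, followed by Benjamini-Hochberg
#' FDR correction across all evaluated features at threshold `q`.
#'
#' @inheritParams compute_cvr
#' @param q FDR threshold (default 0.05).
#' @return data.frame with `feature`, `m`, `n_pos_sign`, `p_sign`, `p_adj`,
#'   `significant`.
#' @export
sign_consistency <- function(x, q = 0.05) {
  w <- ensemble_weight_matrix(x)
  m <- colSums(w != 0)
  npos <- colSums(w > 0)
  p <- rep(NA_real_, ncol(w))
  for (j in which(m > 0)) {
    p[j] <- stats::binom.test(npos[j], m[j], p = 0.5,
                              alternative = "two.sided")$p.value
  }
  adj <- rep(NA_real_, length(p))
  flag <- rep(NA, length(p))
  ev <- !is.na(p)
  if (any(ev)) {
    fdr <- bh_fdr(p[ev], q)
    adj[ev] <- fdr$adjusted
    flag[ev] <- fdr$significant
  }
  data.frame(feature = colnames(w) %||% paste0("feature_", seq_len(ncol(w))),
             m = as.integer(m), n_pos_sign = as.integer(npos),
             p_sign = p, p_adj = adj, significant = flag,
             stringsAsFactors = FALSE)
}

#' Combined feature-stability table
#'
#' Joins [compute_cvr()] and [sign_consistency()] into the per-feature
#' stability report used to interpret the discriminative pattern.
#'
#' @inheritParams sign_consistency
#' @param denominator forwarded to [compute_cvr()].
#' @return data.frame with columns `feature`, `m`, `mean_w`, `sd_w`, `cvr`,
#'   `n_pos_sign`, `p_sign`, `p_adj`, `significant`.
#' @export
feature_stability <- function(x, q = 0.05, denominator = "se") {
  cvr <- compute_cvr(x, denominator = denominator)
  sgn <- sign_consistency(x, q = q)
  cbind(cvr, sgn[, c("n_pos_sign", "p_sign", "p_adj", "significant")])
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Standard step-up procedure at threshold `q`; returns both adjusted
#' p-values and significance flags (a flagged p-value is one whose BH-adjusted
#' value is at most `q`).
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param q FDR threshold.
#' @return List with `adjusted` and logical `significant`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stopf("p-values must be in [0, 1] and non-missing")
  }
  adjusted <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adjusted, significant = adjusted <= q)
}
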