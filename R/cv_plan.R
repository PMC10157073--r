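#' Build a repeated stratified cross-validation plan
#'
#' Assigns every subject to one test fold per repeat, stratified by class so
#' each fold contains at least one subject of each class whenever `k` does not
#' exceed the minority-class count. With `k` equal to the sample size the plan
#' degenerates to leave-one-out and stratification is waived with a warning.
#'
#' @param labels vector in `{+1, -1}`.
#' @param k number of folds per repeat (default 10).
#' @param repeats number of repeats (default 10).
#' @param seed integer master seed; identical inputs give identical plans.
#' @return An object of class `cv_plan`: list with `folds` (repeats x subjects
#'   integer matrix of fold ids), `k`, `repeats`, `seed`, `n`.
#' @export
build_cv_plan <- function(labels, k = 10, repeats = 10, seed = 1) {
  if (!all(labels %in% c(-1, 1))) stopf("labels must be +1 or -1")
  n <- length(labels)
  n_min <- min(sum(labels == 1), sum(labels == -1))
  if (n_min == 0L) stopf("both classes must be present")
  if (k < 2L) stopf("k must be >= 2")
  loo <- k == n
  if (!loo && k > n_min) {
    stopf("k = %d exceeds the minority-class count %d; stratified folds infeasible - use k <= %d (or k = n for leave-one-out)",
          k, n_min, n_min)
  }
  if (loo && k > n_min) warnf("leave-one-out plan: stratification waived")
  folds <- matrix(0L, nrow = repeats, ncol = n)
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      if (loo) {
        folds[r, ] <- sample.int(n)
      } else {
        # per-class counts differ by <= 1 across folds; the leftover subjects
        # of the second class go to the folds currently smallest, keeping
        # total fold sizes within +/-1 of n/k
        idx_pos <- which(labels == 1)
        idx_neg <- which(labels == -1)
        pos_counts <- rep(length(idx_pos) %/% k, k)
        extra_pos <- sample.int(k, length(idx_pos) %% k)
        pos_counts[extra_pos] <- pos_counts[extra_pos] + 1L
        neg_counts <- rep(length(idx_neg) %/% k, k)
        n_extra <- length(idx_neg) %% k
        if (n_extra > 0L) {
          extra_neg <- order(pos_counts + neg_counts, stats::runif(k))[seq_len(n_extra)]
          neg_counts[extra_neg] <- neg_counts[extra_neg] + 1L
        }
        folds[r, sample(idx_pos)] <- rep(seq_len(k), pos_counts)
        folds[r, sample(idx_neg)] <- rep(seq_len(k), neg_counts)
      }
    }
  })
  structure(list(folds = folds, k = as.integer(k), repeats = as.integer(repeats),
                 seed = as.integer(seed), n = n),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("cv_plan: %d subjects, %d folds x %d repeats (seed %d)\n",
              x$n, x$k, x$repeats, x$seed))
  invisible(x)
}

#' Fit a per-feature min-max scaler on training data
#'
#' @param train_matrix numeric training matrix.
#' @return Scaler state: list with per-feature `min`, `range`, and a logical
#'   `constant` mask for features with zero training range (mapped to 0.5).
#' @export
fit_scaler <- function(train_matrix) {
  if (nrow(train_matrix) == 0L) stopf("empty training matrix")
  mins <- apply(train_matrix, 2, min)
  maxs <- apply(train_matrix, 2, max)
  rng <- maxs - mins
  constant <- rng == 0
  rng[constant] <- 1  # avoid 0/0; constant columns handled explicitly
  list(min = mins, range = rng, constant = constant)
}

#' Apply a fitted min-max scaler
#'
#' Rescales to `(x - min)/(max - min)` using the training extrema only; values
#' outside the training range (possible on test data) are clipped to
#' `[0, 1]`; features constant in training map to 0.5.
#'
#' @param state output of [fit_scaler()].
#' @param matrix numeric matrix with the same columns as the training matrix.
#' @return Rescaled matrix in `[0, 1]`.
#' @export
apply_scaler <- function(state, matrix) {
  x <- sweep(sweep(matrix, 2, state$min, `-`), 2, state$range, `/`)
  x[x < 0] <- 0
  x[x > 1] <- 1
  if (any(state$constant)) x[, state$constant] <- 0.5
  x
}

#' Train a linear maximum-margin classifier
#'
#' Thin wrapper around the libsvm C-classification solver (linear kernel,
#' hinge loss, penalty `C`) that extracts the primal weight vector and bias
#' oriented so a positive decision score `sum(w*x) + b` predicts the positive
#' class (+1). Deterministic for fixed input.
#'
#' @param x rescaled training matrix.
#' @param y labels in `{+1, -1}`, both classes present.
#' @param C penalty constant.
#' @return List with `w` (weights), `b` (bias), `C`.
#' @export
train_linear_svm <- function(x, y, C = 1) {
  if (length(unique(y)) < 2L) stopf("single-class training fold")
  fit <- e1071::svm(x, factor(y, levels = c(-1, 1)), kernel = "linear",
                    cost = C, scale = FALSE, fitted = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # libsvm orients decision values toward the class of the first training row
  if (fit$levels[fit$labels[1]] != "1") {
    w <- -w
    b <- -b
  }
  list(w = unname(w), b = unname(b), C = C)
}

svm_decision <- function(model, x) drop(x %*% model$w) + model$b
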