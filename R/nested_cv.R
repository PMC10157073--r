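#' Default penalty grid
#'
#' Logarithmic grid `2^(-6..4)` spanning under- to over-regularized regimes
#' for min-max rescaled features.
#'
#' @return Numeric vector of 11 penalty constants.
#' @export
default_C_grid <- function() 2^(-6:4)

fold_bac <- function(pred, truth) {
  (mean(pred[truth == 1] == 1) + mean(pred[truth == -1] == -1)) / 2
}

# Mean validation BAC of a feature subset + penalty over a list of inner folds.
eval_subset_bac <- function(x, y, cols, C, fold_list) {
  tot <- 0
  for (fd in fold_list) {
    xtr <- x[fd$tr, cols, drop = FALSE]
    sc <- fit_scaler(xtr)
    m <- train_linear_svm(apply_scaler(sc, xtr), y[fd$tr], C)
    s <- drop(apply_scaler(sc, x[fd$va, cols, drop = FALSE]) %*% m$w) + m$b
    tot <- tot + fold_bac(ifelse(s > 0, 1, -1), y[fd$va])
  }
  tot / length(fold_list)
}

#' Greedy forward wrapper feature selection
#'
#' Starts from the empty set (baseline balanced accuracy 0.5) and repeatedly
#' adds the feature/penalty pair maximizing mean inner cross-validated
#' balanced accuracy, stopping when no candidate improves it by more than
#' `epsilon`. Ties are broken toward the lower feature index and the smaller
#' (more regularized) penalty; the stopping rule itself prefers fewer
#' features.
#'
#' @param x raw (unscaled) training matrix; scaling is refit inside every
#'   inner training fold.
#' @param y labels in `{+1, -1}`.
#' @param C_grid candidate penalty constants.
#' @param inner_k,inner_repeats inner cross-validation plan dimensions.
#' @param seed seed for the inner fold assignments.
#' @param epsilon minimum balanced-accuracy improvement to continue.
#' @param max_features optional cap on the selected subset size.
#' @return List with `selected` (feature indices in selection order), `C`
#'   (penalty of the final accepted step), `bac` (final inner validation
#'   balanced accuracy), `trace` (one row per accepted step).
#' @export
greedy_forward_select <- function(x, y, C_grid = default_C_grid(),
                                  inner_k = 10, inner_repeats = 10, seed = 1,
                                  epsilon = 1e-6, max_features = Inf) {
  p <- ncol(x)
  if (p < 1L) stopf("need at least one feature")
  plan <- build_cv_plan(y, k = inner_k, repeats = inner_repeats, seed = seed)
  fold_list <- list()
  for (r in seq_len(plan$repeats)) {
    for (f in seq_len(plan$k)) {
      va <- which(plan$folds[r, ] == f)
      fold_list[[length(fold_list) + 1L]] <- list(tr = which(plan$folds[r, ] != f), va = va)
    }
  }
  selected <- integer(0)
  best_bac <- 0.5
  best_C <- C_grid[1]
  trace <- list()
  first_candidate <- NULL
  while (length(selected) < min(p, max_features)) {
    cand_feat <- NA_integer_; cand_C <- NA_real_; cand_bac <- -Inf
    for (j in setdiff(seq_len(p), selected)) {
      cols <- c(selected, j)
      for (C in C_grid) {
        bac <- eval_subset_bac(x, y, cols, C, fold_list)
        if (bac > cand_bac) {  # strict: earlier feature / smaller C wins ties
          cand_bac <- bac; cand_feat <- j; cand_C <- C
        }
      }
    }
    if (length(selected) == 0L) {
      first_candidate <- list(feature = cand_feat, C = cand_C, bac = cand_bac)
    }
    if (cand_bac <= best_bac + epsilon) break
    selected <- c(selected, cand_feat)
    best_bac <- cand_bac
    best_C <- cand_C
    trace[[length(trace) + 1L]] <- data.frame(step = length(selected),
                                              feature = cand_feat, C = cand_C,
                                              bac = cand_bac)
  }
  list(selected = selected, C = best_C, bac = best_bac,
       first_candidate = first_candidate,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(step = integer(), feature = integer(), C = numeric(),
                    bac = numeric()))
}

#' Run the repeated nested cross-validation pipeline
#'
#' For every outer training partition the inner cycle (greedy wrapper
#' selection plus penalty search) picks a winning configuration, which is
#' refit on the full outer-training data (min-max scaler refit included) and
#' applied to the held-out outer fold. Out-of-fold decision scores are pooled
#' per subject across repeats; a subject's cross-validated prediction is the
#' sign of its mean out-of-fold score (ties predict the negative class).
#' The refit fold-level models are retained as an ensemble for external use.
#'
#' @param ft labeled [feature_table()].
#' @param outer_k,outer_repeats outer cross-validation plan dimensions.
#' @param inner_k,inner_repeats inner plan dimensions used by the wrapper.
#' @param C_grid penalty grid.
#' @param seed master seed; fold assignments and all member models are
#'   deterministic given it.
#' @param plan optional pre-built outer [build_cv_plan()] (its dimensions
#'   override `outer_k`/`outer_repeats`).
#' @param epsilon,max_features forwarded to [greedy_forward_select()].
#' @return An object of class `nested_cv_result`: `ensemble` (class
#'   `svm_ensemble`), `scores` (subjects x repeats out-of-fold decision
#'   scores), `mean_scores`, `predictions`, `confusion` (with AUC from the
#'   mean scores), `plan`.
#' @export
run_nested_cv <- function(ft, outer_k = 10, outer_repeats = 10,
                          inner_k = 10, inner_repeats = 10,
                          C_grid = default_C_grid(), seed = 1, plan = NULL,
                          epsilon = 1e-6, max_features = Inf) {
  stopifnot(inherits(ft, "feature_table"))
  if (is.null(ft$labels)) stopf("nested CV needs a labeled table")
  x <- ft$values
  y <- ft$labels
  if (is.null(plan)) {
    plan <- build_cv_plan(y, k = outer_k, repeats = outer_repeats,
                          seed = derive_seed(seed, 1L))
  }
  n <- nrow(x)
  scores <- matrix(NA_real_, n, plan$repeats,
                   dimnames = list(ft$subject_ids, NULL))
  members <- list()
  for (r in seq_len(plan$repeats)) {
    for (f in seq_len(plan$k)) {
      te <- plan$folds[r, ] == f
      tr <- !te
      if (!any(te)) next
      sel <- greedy_forward_select(x[tr, , drop = FALSE], y[tr],
                                   C_grid = C_grid, inner_k = inner_k,
                                   inner_repeats = inner_repeats,
                                   seed = derive_seed(seed, 2L, r, f),
                                   epsilon = epsilon,
                                   max_features = max_features)
      # empty selection (nothing beat the chance baseline, e.g. pure-noise
      # training data) falls back to the best single-feature candidate so a
      # fold-level model always exists
      if (length(sel$selected)) {
        cols <- sel$selected
        C_win <- sel$C
      } else {
        cols <- sel$first_candidate$feature
        C_win <- sel$first_candidate$C
      }
      xtr <- x[tr, cols, drop = FALSE]
      sc <- fit_scaler(xtr)
      m <- train_linear_svm(apply_scaler(sc, xtr), y[tr], C_win)
      w_full <- numeric(ncol(x))
      w_full[cols] <- m$w
      members[[length(members) + 1L]] <- list(
        repeat_id = r, fold_id = f, selected = cols, C = C_win,
        w = m$w, b = m$b, w_full = w_full, scaler = sc,
        selected_empty = length(sel$selected) == 0L,
        inner_bac = sel$bac)
      scores[te, r] <- drop(apply_scaler(sc, x[te, cols, drop = FALSE]) %*% m$w) + m$b
    }
  }
  if (anyNA(scores)) stopf("internal error: incomplete out-of-fold score matrix")
  mean_scores <- rowMeans(scores)
  predictions <- ifelse(mean_scores > 0, 1L, -1L)
  ensemble <- structure(list(members = members,
                             feature_names = ft$feature_names,
                             aggregation = "mean"),
                        class = "svm_ensemble")
  structure(list(ensemble = ensemble, scores = scores,
                 mean_scores = mean_scores, predictions = predictions,
                 confusion = confusion_from_predictions(y, predictions, mean_scores),
                 labels = y, subject_ids = ft$subject_ids, plan = plan,
                 seed = seed),
            class = "nested_cv_result")
}

#' @export
print.nested_cv_result <- function(x, ...) {
  cat(sprintf("nested_cv_result: %d subjects, %d ensemble members\n",
              length(x$mean_scores), length(x$ensemble$members)))
  print(x$confusion)
  invisible(x)
}

#' Apply a trained ensemble to an external cohort
#'
#' Features are matched by name (column order of the external table is
#' irrelevant); every member applies its own training scaler and weights, and
#' the ensemble decision score is the mean of member scores. When the cohort
#' is declared all-negative the achieved specificity is reported.
#'
#' @param ensemble an `svm_ensemble` from [run_nested_cv()].
#' @param ft external [feature_table()].
#' @param all_negative declare the cohort all-negative (e.g. an external
#'   healthy-control sample) to obtain a specificity estimate.
#' @return List with `scores` (mean decision score per subject),
#'   `predictions`, `member_scores` (subjects x members), and `specificity`
#'   (or `NA`).
#' @export
apply_ensemble <- function(ensemble, ft, all_negative = FALSE) {
  stopifnot(inherits(ensemble, "svm_ensemble"), inherits(ft, "feature_table"))
  missing <- setdiff(ensemble$feature_names, ft$feature_names)
  if (length(missing)) {
    stopf("external table lacks %d training feature(s), e.g. %s",
          length(missing), missing[1])
  }
  x <- ft$values[, ensemble$feature_names, drop = FALSE]
  ms <- vapply(ensemble$members, function(m) {
    drop(apply_scaler(m$scaler, x[, m$selected, drop = FALSE]) %*% m$w) + m$b
  }, numeric(nrow(x)))
  if (is.null(dim(ms))) ms <- matrix(ms, nrow = nrow(x))
  scores <- rowMeans(ms)
  predictions <- ifelse(scores > 0, 1L, -1L)
  spec <- NA_real_
  if (all_negative || (!is.null(ft$labels) && all(ft$labels == -1L))) {
    spec <- mean(predictions == -1L)
  }
  list(scores = stats::setNames(scores, ft$subject_ids),
       predictions = stats::setNames(predictions, ft$subject_ids),
       member_scores = ms, specificity = spec)
}
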