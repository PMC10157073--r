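test_that("min-max scaler rescales, clips, and centers constant features", {
  tr <- cbind(a = c(2, 4, 6), b = c(5, 5, 5))
  sc <- fit_scaler(tr)
  expect_equal(unname(apply_scaler(sc, tr)[, 1]), c(0, 0.5, 1))
  expect_equal(unname(apply_scaler(sc, tr)[, 2]), rep(0.5, 3))
  te <- cbind(a = c(8, 1), b = c(9, 9))
  expect_equal(unname(apply_scaler(sc, te)[, 1]), c(1, 0))  # clipped
  expect_equal(unname(apply_scaler(sc, te)[, 2]), c(0.5, 0.5))
  # invariant to the constant's value
  sc2 <- fit_scaler(cbind(a = c(2, 4, 6), b = c(-3, -3, -3)))
  expect_equal(apply_scaler(sc2, te), apply_scaler(sc, te))
})

test_that("linear SVM places the boundary midway on a symmetric pair", {
  x <- matrix(c(0, 1), 2, 1)
  m <- train_linear_svm(x, c(-1, 1), C = 1000)
  expect_equal(-m$b / m$w, 0.5, tolerance = 1e-6)
  expect_gt(m$w, 0)  # positive class on the high side
  expect_error(train_linear_svm(x, c(1, 1), 1), "single-class")
})

test_that("weight norm shrinks monotonically as C decreases", {
  set.seed(8)
  x <- matrix(runif(40), 20, 2)
  y <- rep(c(1, -1), 10)  # contradictory-ish labels on random data
  norms <- vapply(2^(3:-5), function(C) sqrt(sum(train_linear_svm(x, y, C)$w^2)),
                  numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("decision scores reproduce the libsvm decision values", {
  set.seed(9)
  x <- matrix(rnorm(60), 20, 3)
  y <- rep(c(1, -1), 10)
  m <- train_linear_svm(x, y, C = 2)
  fit <- e1071::svm(x, factor(y, levels = c(-1, 1)), kernel = "linear", cost = 2,
                    scale = FALSE)
  dv <- drop(attr(predict(fit, x, decision.values = TRUE), "decision.values"))
  ours <- drop(x %*% m$w) + m$b
  flip <- if (colnames(attr(predict(fit, x, decision.values = TRUE),
                            "decision.values")) == "1/-1") 1 else -1
  expect_equal(ours, unname(flip * dv), tolerance = 1e-10)
})

test_that("cross-validation plans stratify, partition, and are deterministic", {
  labels <- rep(c(1, -1), c(14, 15))
  p1 <- build_cv_plan(labels, k = 10, repeats = 10, seed = 5)
  p2 <- build_cv_plan(labels, k = 10, repeats = 10, seed = 5)
  expect_identical(p1$folds, p2$folds)
  for (r in seq_len(10)) {
    sizes <- table(p1$folds[r, ])
    expect_length(sizes, 10L)
    expect_true(all(sizes %in% 2:3))
    for (f in 1:10) {
      fold_labels <- labels[p1$folds[r, ] == f]
      expect_true(all(c(1, -1) %in% fold_labels))
    }
  }
  expect_error(build_cv_plan(labels, k = 15, repeats = 1, seed = 1), "minority")
  expect_warning(p_loo <- build_cv_plan(labels, k = 29, repeats = 1, seed = 1),
                 "leave-one-out")
  expect_equal(sort(p_loo$folds[1, ]), 1:29)
})

test_that("greedy selection finds the informative feature and follows the ties rule", {
  ft <- make_separable_table(n_per_class = 6, n_noise = 3)
  sel <- greedy_forward_select(ft$values, ft$labels, C_grid = 1, inner_k = 3,
                               inner_repeats = 2, seed = 2)
  expect_equal(sel$selected[1], 1L)
  expect_gt(sel$bac, 0.9)

  # brute force over all non-empty subsets at each cardinality along the
  # greedy path, scored by the same inner-validation criterion
  plan <- build_cv_plan(ft$labels, k = 3, repeats = 2, seed = 2)
  folds <- list()
  for (r in 1:2) for (f in 1:3) {
    folds[[length(folds) + 1]] <- list(tr = which(plan$folds[r, ] != f),
                                       va = which(plan$folds[r, ] == f))
  }
  score_subset <- function(cols) {
    mean(vapply(folds, function(fd) {
      sc <- fit_scaler(ft$values[fd$tr, cols, drop = FALSE])
      m <- train_linear_svm(apply_scaler(sc, ft$values[fd$tr, cols, drop = FALSE]),
                            ft$labels[fd$tr], 1)
      s <- drop(apply_scaler(sc, ft$values[fd$va, cols, drop = FALSE]) %*% m$w) + m$b
      pred <- ifelse(s > 0, 1, -1)
      truth <- ft$labels[fd$va]
      (mean(pred[truth == 1] == 1) + mean(pred[truth == -1] == -1)) / 2
    }, numeric(1)))
  }
  all_singletons <- vapply(1:4, function(j) score_subset(j), numeric(1))
  expect_equal(sel$selected[1], which.max(all_singletons))
  if (length(sel$selected) >= 2) {
    pairs <- setdiff(1:4, sel$selected[1])
    pair_scores <- vapply(pairs, function(j) score_subset(c(sel$selected[1], j)),
                          numeric(1))
    expect_equal(sel$selected[2], pairs[which.max(pair_scores)])
  }

  # duplicated informative column: the lower index wins the tie
  dup <- cbind(ft$values[, 1], ft$values[, 1], ft$values[, 2])
  colnames(dup) <- c("d1", "d2", "n1")
  ft_dup <- feature_table(dup, ft$subject_ids, labels = ft$labels)
  sel_dup <- greedy_forward_select(ft_dup$values, ft_dup$labels, C_grid = 1,
                                   inner_k = 3, inner_repeats = 2, seed = 2)
  expect_equal(sel_dup$selected[1], 1L)
  expect_false(2L %in% sel_dup$selected)
})

test_that("greedy terminates quickly on pure noise", {
  ft <- make_null_table(n_pos = 8, n_neg = 8, p = 5, seed = 10)
  sel <- greedy_forward_select(ft$values, ft$labels, C_grid = 1, inner_k = 4,
                               inner_repeats = 2, seed = 3)
  expect_lte(length(sel$selected), 3L)
})

test_that("nested CV is deterministic and scores every subject once per repeat", {
  ft <- make_separable_table()
  r1 <- quick_cv(ft, seed = 7)
  r2 <- quick_cv(ft, seed = 7)
  expect_identical(r1$scores, r2$scores)
  expect_identical(r1$predictions, r2$predictions)
  expect_equal(ncol(r1$scores), 2L)          # one out-of-fold score per repeat
  expect_false(anyNA(r1$scores))
  expect_gt(r1$confusion$bac, 0.9)            # separable data classified cleanly
  r3 <- quick_cv(ft, seed = 8)
  expect_false(identical(r1$scores, r3$scores))
})

test_that("leave-one-out on trivially separable 1-feature data is exact", {
  x <- matrix(c(1:6, 101:106), ncol = 1)
  colnames(x) <- "f1"
  ft <- feature_table(x, sprintf("S%02d", 1:12), labels = rep(c(-1, 1), each = 6))
  plan <- suppressWarnings(build_cv_plan(ft$labels, k = 12, repeats = 1, seed = 1))
  res <- run_nested_cv(ft, plan = plan, inner_k = 3, inner_repeats = 1,
                       C_grid = 10, seed = 4)
  expect_equal(res$confusion$bac, 1)
})

test_that("training never touches outer-test labels (no-leakage checksum)", {
  ft <- make_separable_table()
  plan <- build_cv_plan(ft$labels, k = 3, repeats = 2, seed = 21)
  res <- run_nested_cv(ft, plan = plan, inner_k = 2, inner_repeats = 2,
                       C_grid = 1, seed = 21)
  victim <- 1L
  ft_bad <- ft
  ft_bad$labels[victim] <- -ft_bad$labels[victim]
  res_bad <- run_nested_cv(ft_bad, plan = plan, inner_k = 2, inner_repeats = 2,
                           C_grid = 1, seed = 21)
  for (r in seq_len(plan$repeats)) {
    f <- plan$folds[r, victim]
    pick <- function(x) Filter(function(m) m$repeat_id == r && m$fold_id == f,
                               x$ensemble$members)[[1]]
    m_good <- pick(res); m_bad <- pick(res_bad)
    expect_identical(m_good$w_full, m_bad$w_full)
    expect_identical(m_good$b, m_bad$b)
    expect_identical(m_good$selected, m_bad$selected)
    expect_identical(m_good$scaler, m_bad$scaler)
  }
})

test_that("ensembles apply by feature name, not column position", {
  ft <- make_separable_table()
  res <- quick_cv(ft, seed = 13)
  straight <- apply_ensemble(res$ensemble, ft)
  perm <- sample(ncol(ft$values))
  ft_perm <- feature_table(ft$values[, perm], ft$subject_ids,
                           ft$feature_names[perm], ft$labels)
  permuted <- apply_ensemble(res$ensemble, ft_perm)
  expect_identical(straight$scores, permuted$scores)
  # identity input reproduces the same mean score on every call
  expect_identical(straight$scores, apply_ensemble(res$ensemble, ft)$scores)
  # missing feature is a hard error
  ft_short <- feature_table(ft$values[, -2], ft$subject_ids,
                            ft$feature_names[-2], ft$labels)
  expect_error(apply_ensemble(res$ensemble, ft_short), "lacks")
})

test_that("external all-negative cohorts yield a specificity estimate", {
  co <- generate_cohort(synthetic_spec(n_pos = 8, n_neg = 8, n_features = 6,
                                       effect_vector = c(1.5, -1.5, 1, 0, 0, 0),
                                       seed = 31))
  res <- run_nested_cv(co$features, outer_k = 4, outer_repeats = 2, inner_k = 2,
                       inner_repeats = 2, C_grid = 1, seed = 31)
  ext <- generate_cohort(synthetic_spec(n_pos = 0, n_neg = 30, n_features = 6,
                                        effect_vector = c(1.5, -1.5, 1, 0, 0, 0),
                                        seed = 32))
  out <- apply_ensemble(res$ensemble, ext$features, all_negative = TRUE)
  expect_length(out$scores, 30L)
  expect_false(is.na(out$specificity))
  expect_gte(out$specificity, 0.5)
})
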