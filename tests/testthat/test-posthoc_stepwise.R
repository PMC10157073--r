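test_that("stepwise regression recovers a planted single-predictor model", {
  set.seed(21)
  n <- 14
  cand <- as.data.frame(matrix(rnorm(n * 5), n, 5))
  names(cand) <- paste0("z", 1:5)
  y <- 3 * cand$z1 + rnorm(n, sd = 0.1)
  fit <- stepwise_fit(y, cand)
  expect_identical(fit$terms, "z1")
  row <- fit$coefficients[fit$coefficients$term == "z1", ]
  expect_gt(3, row$ci_lower)
  expect_lt(3, row$ci_upper)
  expect_gt(fit$adj_r_squared, 0.95)
})

test_that("pure-noise candidates usually yield the empty model", {
  set.seed(22)
  sizes <- vapply(1:60, function(i) {
    cand <- as.data.frame(matrix(rnorm(20 * 4), 20, 4))
    length(stepwise_fit(rnorm(20), cand)$terms)
  }, numeric(1))
  expect_equal(median(sizes), 0)
})

test_that("stepping path matches an exhaustive oracle on <= 4 candidates", {
  # oracle: replay the same entry/removal rules using add1/drop1 F tests,
  # enumerating every candidate move from scratch
  oracle_stepwise <- function(y, cand, p_enter = 0.05, p_remove = 0.10) {
    dat <- cbind(cand, .y = y)
    included <- character(0)
    repeat {
      moved <- FALSE
      fit <- lm(if (length(included)) reformulate(included, ".y") else .y ~ 1,
                data = dat)
      pool <- setdiff(names(cand), included)
      if (length(pool)) {
        a1 <- add1(fit, scope = reformulate(c(included, pool)), test = "F")
        pe <- setNames(a1[["Pr(>F)"]][-1], rownames(a1)[-1])
        pe <- pe[!is.na(pe)]
        if (length(pe) && min(pe) < p_enter) {
          included <- c(included, names(pe)[which.min(pe)])
          moved <- TRUE
        }
      }
      if (length(included)) {
        fit <- lm(reformulate(included, ".y"), data = dat)
        d1 <- drop1(fit, test = "F")
        pr <- setNames(d1[["Pr(>F)"]][-1], rownames(d1)[-1])
        if (max(pr) > p_remove) {
          included <- setdiff(included, names(pr)[which.max(pr)])
          moved <- TRUE
        }
      }
      if (!moved) break
    }
    sort(included)
  }
  set.seed(23)
  for (i in 1:20) {
    n <- 16
    cand <- as.data.frame(matrix(rnorm(n * 4), n, 4))
    names(cand) <- paste0("v", 1:4)
    beta <- sample(c(0, 0, 1.5, -2), 4)
    y <- as.matrix(cand) %*% beta + rnorm(n)
    fit <- stepwise_fit(as.numeric(y), cand)
    expect_identical(sort(fit$terms), oracle_stepwise(as.numeric(y), cand))
  }
})

test_that("forced-out candidates give an intercept-only fit with R^2 = 0", {
  set.seed(24)
  cand <- data.frame(a = rnorm(12), b = rnorm(12))
  fit <- stepwise_fit(rnorm(12), cand, p_enter = 1e-12, p_remove = 2e-12)
  expect_length(fit$terms, 0L)
  expect_equal(fit$r_squared, 0)
  expect_equal(nrow(fit$coefficients), 1L)  # intercept row only
})

test_that("refitting the final term set reproduces the stepwise table", {
  set.seed(25)
  n <- 20
  cand <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- 2 * cand$a - 1.5 * cand$b + rnorm(n, sd = 0.5)
  fit <- stepwise_fit(y, cand)
  direct <- lm(reformulate(fit$terms, "y"), data = cbind(cand, y = y))
  expect_equal(fit$coefficients$estimate,
               unname(coef(direct)[fit$coefficients$term]), tolerance = 1e-10)
  expect_equal(fit$coefficients$se,
               unname(summary(direct)$coefficients[fit$coefficients$term, "Std. Error"]),
               tolerance = 1e-10)
  # CI identity: estimate +/- t * SE
  tq <- qt(0.975, fit$df_residual)
  expect_equal(fit$coefficients$ci_upper,
               fit$coefficients$estimate + tq * fit$coefficients$se,
               tolerance = 1e-10)
  # adjusted R^2 identity
  k <- length(fit$terms)
  expect_equal(fit$adj_r_squared,
               1 - (1 - fit$r_squared) * (n - 1) / (n - k - 1), tolerance = 1e-12)
})

test_that("post-hoc inputs pair scores with covariates for the positive class", {
  co <- generate_cohort(synthetic_spec(n_pos = 6, n_neg = 6, n_features = 4,
                                       effect_vector = c(1.5, -1, 0, 0), seed = 41))
  res <- run_nested_cv(co$features, outer_k = 3, outer_repeats = 1, inner_k = 2,
                       inner_repeats = 1, C_grid = 1, seed = 41)
  inp <- assemble_posthoc_inputs(res, co$covariates)
  expect_length(inp$response, 6L)
  expect_identical(inp$subject_ids, res$subject_ids[res$labels == 1L])
  # subject with a missing covariate is dropped with a warning
  cov_na <- co$covariates
  cov_na$data$age[1] <- NA
  expect_warning(inp2 <- assemble_posthoc_inputs(res, covariate_table(cov_na$data, cov_na$subject_ids)),
                 "missing covariates")
  expect_length(inp2$response, 5L)
  # no overlap is an error
  cov_other <- covariate_table(data.frame(age = c(1, 2)), c("X1", "X2"))
  expect_error(assemble_posthoc_inputs(res, cov_other), "no usable subjects")
})
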