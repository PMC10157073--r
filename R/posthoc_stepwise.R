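#' Forward-backward stepwise linear regression
#'
#' Classical p-value stepping on partial F tests (for a single added or
#' removed term the partial F equals the squared coefficient t statistic, so
#' the entry/removal p-values are the usual t-test p-values): starting from
#' the intercept-only model, repeatedly enter the candidate with the smallest
#' p-value below `p_enter`, then remove any included term whose p-value rises
#' above `p_remove`, until no move is possible. The final term set is refit by
#' ordinary least squares and reported with a full coefficient table.
#'
#' @param response numeric response vector (e.g. per-subject ensemble decision
#'   scores).
#' @param candidates data.frame of numeric candidate predictors (main effects
#'   only; raw scales).
#' @param p_enter entry threshold (default 0.05).
#' @param p_remove removal threshold (default 0.10; must exceed `p_enter`).
#' @return An object of class `stepwise_fit`: `terms` (included names, in
#'   entry order), `coefficients` (estimate, 95% CI, SE, T, p; intercept row
#'   first), `r_squared`, `adj_r_squared`, `f_statistic`, `f_p`, `df_residual`,
#'   `trace` (step-by-step actions), `model` (the final `lm`).
#' @export
stepwise_fit <- function(response, candidates, p_enter = 0.05, p_remove = 0.10) {
  candidates <- as.data.frame(candidates)
  if (ncol(candidates) == 0L) stopf("empty candidate set")
  if (p_enter >= p_remove) stopf("p_enter must be smaller than p_remove")
  keep <- stats::complete.cases(candidates) & !is.na(response)
  if (sum(!keep)) warnf("dropping %d subject(s) with missing data", sum(!keep))
  y <- response[keep]
  dat <- candidates[keep, , drop = FALSE]
  n <- length(y)
  if (n <= 2L) stopf("need more than 2 complete subjects")
  dat$.y <- y

  term_p <- function(terms) {
    # p-value of each term in the model containing exactly `terms`
    fml <- stats::reformulate(terms, response = ".y")
    fit <- stats::lm(fml, data = dat)
    cf <- summary(fit)$coefficients
    stats::setNames(cf[match(terms, rownames(cf)), "Pr(>|t|)"], terms)
  }
  entry_p <- function(included, cand) {
    if (n <= length(included) + 2L) return(NA_real_)  # guard: no residual df
    fit <- stats::lm(stats::reformulate(c(included, cand), response = ".y"), data = dat)
    cf <- summary(fit)$coefficients
    if (!cand %in% rownames(cf)) return(NA_real_)      # rank-deficient: skip
    cf[cand, "Pr(>|t|)"]
  }

  included <- character(0)
  trace <- list()
  repeat {
    moved <- FALSE
    pool <- setdiff(names(candidates), included)
    if (length(pool)) {
      pe <- vapply(pool, function(cand) entry_p(included, cand), numeric(1))
      if (any(is.na(pe))) {
        skipped <- pool[is.na(pe)]
        if (length(skipped)) warnf("skipping rank-deficient/insufficient-df term(s): %s",
                                   paste(skipped, collapse = ", "))
      }
      pe <- pe[!is.na(pe)]
      if (length(pe) && min(pe) < p_enter) {
        add <- names(pe)[which.min(pe)]
        included <- c(included, add)
        trace[[length(trace) + 1L]] <- data.frame(step = length(trace) + 1L,
                                                  action = "add", term = add,
                                                  p = min(pe))
        moved <- TRUE
      }
    }
    if (length(included)) {
      pr <- term_p(included)
      if (max(pr) > p_remove) {
        drop_term <- names(pr)[which.max(pr)]
        included <- setdiff(included, drop_term)
        trace[[length(trace) + 1L]] <- data.frame(step = length(trace) + 1L,
                                                  action = "remove",
                                                  term = drop_term, p = max(pr))
        moved <- TRUE
      }
    }
    if (!moved) break
  }

  fml <- if (length(included)) stats::reformulate(included, response = ".y") else
    stats::as.formula(".y ~ 1")
  fit <- stats::lm(fml, data = dat)
  sm <- summary(fit)
  cf <- sm$coefficients
  ci <- stats::confint(fit, level = 0.95)
  coefficients <- data.frame(term = rownames(cf),
                             estimate = cf[, "Estimate"],
                             ci_lower = ci[, 1], ci_upper = ci[, 2],
                             se = cf[, "Std. Error"],
                             t = cf[, "t value"],
                             p = cf[, "Pr(>|t|)"],
                             row.names = NULL, stringsAsFactors = FALSE)
  fstat <- sm$fstatistic
  structure(list(terms = included, coefficients = coefficients,
                 r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
                 f_statistic = if (is.null(fstat)) NA_real_ else unname(fstat[1]),
                 f_p = if (is.null(fstat)) NA_real_ else
                   unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
                 df_residual = fit$df.residual,
                 n = n,
                 trace = if (length(trace)) do.call(rbind, trace) else
                   data.frame(step = integer(), action = character(),
                              term = character(), p = numeric()),
                 model = fit),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat(sprintf("stepwise_fit: %d term(s), n = %d, adj R^2 = %.3f\n",
              length(x$terms), x$n, x$adj_r_squared))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Assemble the post-hoc regression inputs
#'
#' Pairs per-subject mean out-of-fold decision scores with covariates,
#' restricted to a label subset (study usage: the positive class, for which
#' forensic covariates exist). Subjects with any missing covariate are
#' dropped listwise with a warning naming the count.
#'
#' @param result a `nested_cv_result`.
#' @param cov a [covariate_table()].
#' @param subset `"positive"` (default), `"negative"`, or `"all"`.
#' @return List with `response` (decision scores), `candidates` (covariate
#'   data.frame), `subject_ids`.
#' @export
assemble_posthoc_inputs <- function(result, cov, subset = c("positive", "negative", "all")) {
  stopifnot(inherits(result, "nested_cv_result"), inherits(cov, "covariate_table"))
  subset <- match.arg(subset)
  want <- switch(subset,
                 positive = result$subject_ids[result$labels == 1L],
                 negative = result$subject_ids[result$labels == -1L],
                 all = result$subject_ids)
  ids <- want[want %in% cov$subject_ids]
  if (length(ids) == 0L) stopf("no usable subjects (no covariate overlap with '%s' subset)", subset)
  if (length(ids) < length(want)) {
    warnf("%d subject(s) without covariates excluded from the post-hoc stage",
          length(want) - length(ids))
  }
  cand <- cov$data[ids, , drop = FALSE]
  complete <- stats::complete.cases(cand)
  if (any(!complete)) {
    warnf("dropping subject(s) with missing covariates: %s",
          paste(ids[!complete], collapse = ", "))
    ids <- ids[complete]
    cand <- cand[complete, , drop = FALSE]
  }
  if (length(ids) == 0L) stopf("no subjects with complete covariates")
  list(response = result$mean_scores[ids], candidates = cand, subject_ids = ids)
}
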