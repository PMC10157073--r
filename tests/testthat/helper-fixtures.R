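# Small fixtures built in code, shared across test files.

# A tiny labeled table with a cleanly separable first feature.
make_separable_table <- function(n_per_class = 6, n_noise = 3, seed = 42) {
  n <- 2 * n_per_class
  set.seed(seed)
  x <- cbind(c(rnorm(n_per_class, 3, 0.3), rnorm(n_per_class, -3, 0.3)),
             matrix(rnorm(n * n_noise), n, n_noise))
  colnames(x) <- paste0("f", seq_len(n_noise + 1))
  feature_table(x, sprintf("S%02d", seq_len(n)),
                labels = rep(c(1, -1), each = n_per_class))
}

# Pure-noise labeled table.
make_null_table <- function(n_pos = 6, n_neg = 6, p = 4, seed = 42) {
  n <- n_pos + n_neg
  set.seed(seed)
  feature_table(matrix(rnorm(n * p), n, p,
                       dimnames = list(NULL, paste0("f", seq_len(p)))),
                sprintf("S%02d", seq_len(n)),
                labels = rep(c(1, -1), c(n_pos, n_neg)))
}

# Quick pipeline settings used wherever a full nested-CV run is needed.
quick_cv <- function(ft, seed = 1, ...) {
  run_nested_cv(ft, outer_k = 3, outer_repeats = 2, inner_k = 2,
                inner_repeats = 2, C_grid = 1, seed = seed, ...)
}
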