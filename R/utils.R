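#' Bonferroni-corrected per-test threshold
#'
#' Family-wise alpha divided by the number of tests in the family, e.g.
#' 0.05/84 = 5.95e-4 for a scan over 84 cell populations and 0.05/20 = 0.0025
#' for 20 GO terms.
#'
#' @param n_tests number of tests in the family.
#' @param alpha family-wise error rate (default 0.05).
#' @return per-test significance threshold.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  stopifnot(is.numeric(n_tests), length(n_tests) == 1L, n_tests >= 1)
  alpha / n_tests
}

# run expr under a fixed seed without touching the caller's RNG state
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 ||
      x != floor(x)) {
    stop("configuration error: '", name, "' must be a positive integer",
         call. = FALSE)
  }
  invisible(as.integer(x))
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
    stop("configuration error: '", name, "' must lie in (0, 1)",
         call. = FALSE)
  }
  invisible(as.numeric(x))
}

autosome_labels <- function() paste0("chr", 1:22)
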