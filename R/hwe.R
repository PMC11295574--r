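#' Hardy-Weinberg equilibrium exact test
#'
#' Exact test conditional on the observed allele counts: enumerates every
#' heterozygote count of the same parity as the minor-allele count, computes
#' each configuration's probability under the standard conditional
#' distribution (normalized log-probabilities), and sums the probabilities of
#' all configurations no more probable than the observed one.
#'
#' @param n_homref,n_het,n_homalt genotype counts (total > 0).
#' @return exact two-sided p-value in (0, 1].
#' @export
hwe_exact <- function(n_homref, n_het, n_homalt) {
  stopifnot(n_homref >= 0, n_het >= 0, n_homalt >= 0)
  n <- n_homref + n_het + n_homalt
  if (n == 0) stop("empty genotype table", call. = FALSE)
  n_alt <- 2 * n_homalt + n_het
  n_minor <- min(n_alt, 2 * n - n_alt)
  if (n_minor == 0) return(1)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  # log P(het = h | n, n_minor), up to a constant:
  # P(h) = n! 2^h / (homref(h)! h! homalt(h)!) * minor! major! / (2n)!
  logp <- vapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    lgamma(n + 1) - lgamma(hom_min + 1) - lgamma(h + 1) -
      lgamma(hom_maj + 1) + h * log(2)
  }, 0)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- which(hets == n_het)
  if (length(obs) != 1L)
    stop("genotype counts inconsistent with allele counts", call. = FALSE)
  min(sum(prob[prob <= prob[obs] * (1 + 1e-12)]), 1)
}
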