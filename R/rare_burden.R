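#' Sample quality control for case-control exome data
#'
#' Removes one member of each related pair (kinship coefficient strictly
#' greater than 0.177, which also covers duplicates at > 0.354), preferring
#' to drop the sample involved in the most remaining pairs (ties broken by
#' ascending sample id) so that a chain A-B, B-C loses only B. Also removes
#' ancestry-flagged samples and samples with mean genotype depth below
#' `min_depth` (strict).
#'
#' @param samples sample table (sample_id, status, mean_depth, ancestry_flag,
#'   covariates).
#' @param kinship data.frame with columns id1, id2, coef (symmetric pairs
#'   listed once).
#' @param kin_threshold relatedness cutoff (strict >; default 0.177,
#'   first-degree relatives).
#' @param min_depth minimum mean genotype depth (default 20).
#' @return the filtered sample table.
#' @export
sample_qc <- function(samples, kinship = NULL, kin_threshold = 0.177,
                      min_depth = 20) {
  drop <- character(0)
  if (!is.null(kinship) && nrow(kinship) > 0) {
    pairs <- kinship[kinship$coef > kin_threshold, c("id1", "id2"),
                     drop = FALSE]
    while (nrow(pairs) > 0) {
      deg <- sort(table(c(pairs$id1, pairs$id2)), decreasing = TRUE)
      top <- names(deg)[deg == max(deg)]
      victim <- sort(top)[1]
      drop <- c(drop, victim)
      pairs <- pairs[pairs$id1 != victim & pairs$id2 != victim, ,
                     drop = FALSE]
    }
  }
  keep <- !(samples$sample_id %in% drop) &
    !samples$ancestry_flag &
    samples$mean_depth >= min_depth
  samples[keep, , drop = FALSE]
}

#' Genotype-level quality control
#'
#' Sets to missing every genotype failing any of: depth >= 10, genotype
#' quality >= 30, allele balance <= 0.1 for hom-ref and >= 0.9 for hom-alt,
#' and allele balance in [0.25, 0.75] for heterozygotes (all boundaries
#' inclusive as printed). Idempotent.
#'
#' @param vt a `variant_table`.
#' @return the table with failing genotypes set to NA and the genotype-QC
#'   flag recorded (required by [variant_qc()]).
#' @export
genotype_qc <- function(vt) {
  stopifnot(inherits(vt, "variant_table"))
  g <- vt$geno
  bad <- vt$dp < 10 | vt$gq < 30
  bad <- bad | (!is.na(g) & g == 0L & vt$ab > 0.1)
  bad <- bad | (!is.na(g) & g == 1L & (vt$ab < 0.25 | vt$ab > 0.75))
  bad <- bad | (!is.na(g) & g == 2L & vt$ab < 0.9)
  g[bad] <- NA_integer_
  vt$geno <- g
  vt$qc$genotype <- TRUE
  vt
}

#' Variant-level quality control
#'
#' Removes variants that fail VQSR, have post-genotype-QC call rate below
#' `min_call_rate` (strict <), fail the Hardy-Weinberg exact test at
#' `hwe_alpha` (strict <), or are flagged low-complexity. Requires
#' [genotype_qc()] to have been applied (call rate is computed on post-QC
#' missingness).
#'
#' @param vt a genotype-QC'd `variant_table`.
#' @param min_call_rate call-rate exclusion threshold (default 0.9).
#' @param hwe_alpha HWE exact-test exclusion threshold (default 1e-8).
#' @return the filtered table with the variant-QC flag recorded.
#' @export
variant_qc <- function(vt, min_call_rate = 0.9, hwe_alpha = 1e-8) {
  stopifnot(inherits(vt, "variant_table"))
  if (!isTRUE(vt$qc$genotype))
    stop("genotype_qc() must be applied before variant_qc()", call. = FALSE)
  g <- vt$geno
  call_rate <- 1 - rowMeans(is.na(g))
  hwe_p <- vapply(seq_len(nrow(g)), function(i) {
    gi <- g[i, ]
    hwe_exact(sum(gi == 0L, na.rm = TRUE), sum(gi == 1L, na.rm = TRUE),
              sum(gi == 2L, na.rm = TRUE))
  }, 0)
  keep <- vt$info$vqsr_pass & !vt$info$low_complexity &
    !(call_rate < min_call_rate) & !(hwe_p < hwe_alpha)
  for (fld in c("geno", "dp", "gq", "ab")) {
    vt[[fld]] <- vt[[fld]][keep, , drop = FALSE]
  }
  vt$info <- vt$info[keep, , drop = FALSE]
  vt$qc$variant <- TRUE
  vt
}

#' Define qualifying singleton protein-truncating variants
#'
#' Keeps variants whose consequence is stop-gain, frameshift, or splice
#' donor/acceptor, carried heterozygously by exactly one retained sample
#' (with no homozygous-alternative genotypes), and absent from the external
#' reference cohort. Requires [variant_qc()] first.
#'
#' @param vt a variant-QC'd `variant_table`.
#' @param sample_ids retained samples over which carriers are counted
#'   (default: all samples in the table).
#' @return character vector of qualifying variant ids.
#' @export
define_ptv_singletons <- function(vt, sample_ids = colnames(vt$geno)) {
  stopifnot(inherits(vt, "variant_table"))
  if (!isTRUE(vt$qc$variant))
    stop("variant_qc() must be applied before defining PTV singletons",
         call. = FALSE)
  ptv_classes <- c("stop_gained", "frameshift", "splice_donor",
                   "splice_acceptor")
  g <- vt$geno[, sample_ids, drop = FALSE]
  n_het <- rowSums(g == 1L, na.rm = TRUE)
  n_homalt <- rowSums(g == 2L, na.rm = TRUE)
  keep <- vt$info$consequence %in% ptv_classes &
    n_het == 1L & n_homalt == 0L & !vt$info$in_external_ref
  vt$info$variant_id[keep]
}

#' Rare-PTV burden test (Firth penalized logistic regression)
#'
#' Counts qualifying PTVs per sample within `gene_set` and fits a Firth
#' logistic regression of case status on that count plus covariates (10
#' principal components, synonymous burden, platform, sex), optionally also
#' adjusting for the sample's total qualifying-PTV burden across all
#' expressed genes (`background_covariate = "all_expressed"`), so that
#' set-specific enrichment is tested above the tissue-wide background rate.
#' The p-value is one-tailed for greater burden in cases.
#'
#' @param vt a variant-QC'd `variant_table`.
#' @param qualifying qualifying variant ids from [define_ptv_singletons()].
#' @param gene_set gene ids whose burden is tested.
#' @param samples sample table (possibly [sample_qc()]-filtered); must carry
#'   status, sex, platform, syn_burden and PC1..PC10.
#' @param background_covariate "none" or "all_expressed".
#' @param expressed_genes gene ids defining the background burden (required
#'   when `background_covariate = "all_expressed"`).
#' @return data.frame: set, or, coef, se, p (one-tailed), n_cases,
#'   n_controls, n_qualifying (a BurdenResult).
#' @export
burden_test <- function(vt, qualifying, gene_set, samples = vt$samples,
                        background_covariate = c("none", "all_expressed"),
                        expressed_genes = NULL) {
  background_covariate <- match.arg(background_covariate)
  stopifnot(inherits(vt, "variant_table"))
  if (!isTRUE(vt$qc$variant))
    stop("variant_qc() must be applied before burden testing", call. = FALSE)
  if (length(qualifying) == 0L) stop("no qualifying variants", call. = FALSE)
  sid <- samples$sample_id
  count_in <- function(genes) {
    rows <- vt$info$variant_id %in% qualifying & vt$info$gene_id %in% genes
    if (!any(rows)) return(numeric(length(sid)))
    colSums(vt$geno[rows, sid, drop = FALSE] == 1L, na.rm = TRUE)
  }
  burden <- count_in(gene_set)
  if (sum(burden) == 0) stop("zero total burden in the gene set",
                             call. = FALSE)
  X <- cbind(intercept = 1, burden = burden,
             as.matrix(samples[, paste0("PC", 1:10)]),
             syn = samples$syn_burden,
             platform = as.numeric(factor(samples$platform)) - 1,
             sex = samples$sex - 1)
  if (background_covariate == "all_expressed") {
    if (is.null(expressed_genes))
      stop("background_covariate = 'all_expressed' needs 'expressed_genes'",
           call. = FALSE)
    X <- cbind(X, background = count_in(expressed_genes))
  }
  fit <- firth_logistic(samples$status, X)
  b <- fit$coef["burden"]
  se <- fit$se["burden"]
  data.frame(set = "gene_set", or = exp(unname(b)), coef = unname(b),
             se = unname(se),
             p = pnorm(unname(b / se), lower.tail = FALSE),
             n_cases = sum(samples$status == 1),
             n_controls = sum(samples$status == 0),
             n_qualifying = length(qualifying),
             stringsAsFactors = FALSE)
}
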