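#' Extend gene boundaries into analysis windows
#'
#' Strand-aware extension of gene intervals: a plus-strand gene `[s, e]`
#' becomes `[s - upstream, e + downstream]` and a minus-strand gene
#' `[s - downstream, e + upstream]`, floored at position 1. The defaults
#' (35 kb upstream, 10 kb downstream) are the windows conventionally used to
#' assign GWAS SNPs to genes for gene-level association.
#'
#' @param genes gene-model table (gene_id, chr, start, end, strand).
#' @param upstream,downstream extension in bp (>= 0).
#' @param strand_aware if FALSE, extend `upstream` before start and
#'   `downstream` after end regardless of strand.
#' @return data.frame gene_id, chr, start, end of the windows.
#' @export
extend_gene_windows <- function(genes, upstream = 35000L,
                                downstream = 10000L, strand_aware = TRUE) {
  stopifnot(upstream >= 0, downstream >= 0)
  minus <- strand_aware & genes$strand == "-"
  lead <- ifelse(minus, downstream, upstream)
  trail <- ifelse(minus, upstream, downstream)
  data.frame(gene_id = genes$gene_id, chr = genes$chr,
             start = pmax(1, genes$start - lead),
             end = genes$end + trail,
             stringsAsFactors = FALSE)
}

#' Assign SNPs to gene windows
#'
#' Each SNP is assigned to every window whose closed interval contains its
#' position, so a SNP may belong to several genes. Genes whose windows
#' contain no SNPs are dropped (a count is reported via message).
#'
#' @param sumstats summary-statistics table (SNP, CHR, BP, ...).
#' @param windows interval table from [extend_gene_windows()].
#' @return named list: gene id -> character vector of SNP ids.
#' @export
assign_snps <- function(sumstats, windows) {
  pairs <- overlap_pairs(sumstats$CHR, sumstats$BP, sumstats$BP,
                         windows$chr, windows$start, windows$end)
  out <- split(sumstats$SNP[pairs[, "query"]],
               windows$gene_id[pairs[, "subject"]])
  n_empty <- nrow(windows) - length(out)
  if (n_empty > 0)
    message(n_empty, " gene window(s) contained no SNPs and were dropped")
  out
}

#' LD correlation matrix for a set of SNPs
#'
#' Pearson correlation of reference-panel dosages, symmetrized, with unit
#' diagonal. Monomorphic SNPs get zero off-diagonal correlation (with a
#' warning) so they behave as independent chi-square(1) terms in the null.
#'
#' @param panel `reference_panel` (genotype dosages individuals x SNPs).
#' @param snps SNP ids, all present in the panel.
#' @return correlation matrix in SNP order.
#' @export
ld_correlation <- function(panel, snps) {
  idx <- match(snps, panel$snps$snp)
  if (anyNA(idx))
    stop("SNP(s) absent from panel: ",
         paste(head(snps[is.na(idx)]), collapse = ", "), call. = FALSE)
  g <- panel$genotypes[, idx, drop = FALSE]
  sds <- apply(g, 2, sd)
  mono <- sds == 0
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP(s); treated as uncorrelated")
    g[, mono] <- rnorm(nrow(g)) # placeholder; rows reset below
  }
  r <- cor(g)
  if (any(mono)) {
    r[mono, ] <- 0
    r[, mono] <- 0
  }
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- list(snps, snps)
  r
}

#' Gene-level association under the SNP-wise mean model
#'
#' Converts SNP p-values to chi-square(1) statistics, averages them over the
#' gene window, and evaluates the mean against its LD-aware null: with `R`
#' the SNP correlation matrix and `lambda` its eigenvalues, the null of
#' `m * T` is `sum_j lambda_j chisq_1`, whose tail is computed by Imhof
#' inversion ([quadform_pvalue()]). The gene z-score is the upper-tail probit
#' of the gene p-value.
#'
#' @param snp_p SNP p-values in window order (length = `nrow(R)`).
#' @param R SNP correlation matrix from [ld_correlation()].
#' @param N GWAS sample size (carried into the output).
#' @param method tail method passed to [quadform_pvalue()].
#' @return list: `statistic` (mean chi-square), `p`, `z`, `n_snps`, `method`.
#' @export
gene_score <- function(snp_p, R, N = NA_real_,
                       method = c("imhof", "satterthwaite")) {
  method <- match.arg(method)
  stopifnot(length(snp_p) == nrow(R), nrow(R) == ncol(R))
  if (any(snp_p <= 0 | snp_p > 1)) stop("p-values must lie in (0, 1]",
                                        call. = FALSE)
  q <- qchisq(snp_p, df = 1, lower.tail = FALSE)
  stat <- mean(q)
  lambda <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  p <- quadform_pvalue(length(q) * stat, lambda, method = method)
  list(statistic = stat, p = p, z = qnorm(p, lower.tail = FALSE),
       n_snps = length(q), N = N, method = method)
}

#' Gene score table for all genes
#'
#' Runs [gene_score()] for every gene window with at least one SNP, using
#' per-gene LD from the reference panel. SNPs absent from the panel are
#' dropped from the gene (a count is reported).
#'
#' @param sumstats summary statistics (SNP, CHR, BP, A1, A2, P, N).
#' @param panel reference panel.
#' @param genes gene-model table.
#' @param upstream,downstream window extension in bp (defaults 35 kb / 10 kb).
#' @param method tail method for [gene_score()].
#' @return data.frame: gene_id, n_snps, statistic, p, z, length (window bp),
#'   log_length, log_nsnps.
#' @export
gene_score_table <- function(sumstats, panel, genes, upstream = 35000L,
                             downstream = 10000L,
                             method = c("imhof", "satterthwaite")) {
  method <- match.arg(method)
  windows <- extend_gene_windows(genes, upstream, downstream)
  snp_map <- assign_snps(sumstats, windows)
  p_lookup <- setNames(sumstats$P, sumstats$SNP)
  win_len <- setNames(windows$end - windows$start + 1, windows$gene_id)
  n_dropped <- 0L
  rows <- lapply(names(snp_map), function(g) {
    snps <- snp_map[[g]]
    keep <- snps %in% panel$snps$snp
    n_dropped <<- n_dropped + sum(!keep)
    snps <- snps[keep]
    if (length(snps) == 0L) return(NULL)
    R <- ld_correlation(panel, snps)
    gs <- gene_score(p_lookup[snps], R, N = sumstats$N[1], method = method)
    data.frame(gene_id = g, n_snps = gs$n_snps, statistic = gs$statistic,
               p = gs$p, z = gs$z, length = unname(win_len[g]),
               stringsAsFactors = FALSE)
  })
  if (n_dropped > 0)
    message(n_dropped, " SNP assignment(s) dropped: absent from panel")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$log_length <- log(out$length)
  out$log_nsnps <- log(out$n_snps)
  out
}
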