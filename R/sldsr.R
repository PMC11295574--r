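#' Convert a gene set to a SNP annotation column
#'
#' Marks a SNP 1 if it lies within any set gene's interval extended by
#' `window` bp on both sides (strand-ignored, as conventional for
#' heritability-partitioning annotations; default 100 kb), else 0.
#'
#' @param set gene ids.
#' @param genes gene-model table.
#' @param window bp extension on both sides (>= 0).
#' @param snps SNP table with CHR and BP columns (e.g. summary statistics).
#' @return numeric 0/1 vector aligned to `snps` rows.
#' @export
genes_to_annotation <- function(set, genes, window = 100000L, snps) {
  stopifnot(window >= 0)
  g <- genes[genes$gene_id %in% set, , drop = FALSE]
  if (nrow(g) == 0L) {
    warning("empty gene set: all-zero annotation")
    return(numeric(nrow(snps)))
  }
  as.numeric(overlaps_any(snps$CHR, snps$BP, snps$BP,
                          g$chr, pmax(1, g$start - window), g$end + window))
}

#' Per-annotation LD scores
#'
#' For SNP j and annotation c, `l(j, c) = sum_k a_kc * rtilde2_jk` over SNPs
#' k within `window_cm` centimorgans of j, where `rtilde2 = r2 - (1 - r2) /
#' (n - 2)` is the bias-corrected squared dosage correlation (so SNPs in
#' linkage equilibrium contribute 0 in expectation and a lone SNP's base LD
#' score is ~1 from its self term).
#'
#' @param panel `reference_panel` with genetic-map positions (`cm`).
#' @param annot SNPs x annotations matrix (must include a base column of 1s
#'   for downstream regression; not checked here).
#' @param window_cm window half-width in cM (> 0).
#' @param chunk internal chunk size for the blocked computation.
#' @return object of class `annotation_ldscores`: list with `scores`
#'   (SNPs x annotations), `snps` metadata, and `window_cm`.
#' @export
compute_ld_scores <- function(panel, annot, window_cm = 1.0, chunk = 500L) {
  n <- nrow(panel$genotypes)
  if (n <= 2) stop("need more than 2 panel individuals", call. = FALSE)
  stopifnot(window_cm > 0)
  annot <- as.matrix(annot)
  m <- ncol(panel$genotypes)
  stopifnot(nrow(annot) == m)
  g <- panel$genotypes
  mu <- colMeans(g)
  sdv <- sqrt(colMeans(g^2) - mu^2) * sqrt(n / (n - 1))
  z <- sweep(sweep(g, 2, mu), 2, pmax(sdv, .Machine$double.eps), `/`)
  z[, sdv == 0] <- 0

  scores <- matrix(0, m, ncol(annot),
                   dimnames = list(panel$snps$snp, colnames(annot)))
  cm <- panel$snps$cm
  for (ch in unique(panel$snps$chr)) {
    on_chr <- which(panel$snps$chr == ch)
    starts <- seq(1L, length(on_chr), by = chunk)
    for (s in starts) {
      j <- on_chr[s:min(s + chunk - 1L, length(on_chr))]
      win <- on_chr[cm[on_chr] >= min(cm[j]) - window_cm &
                      cm[on_chr] <= max(cm[j]) + window_cm]
      r <- crossprod(z[, win, drop = FALSE], z[, j, drop = FALSE]) / (n - 1)
      r2 <- r^2
      rt <- r2 - (1 - r2) / (n - 2)
      rt[abs(outer(cm[win], cm[j], `-`)) > window_cm] <- 0
      scores[j, ] <- scores[j, ] +
        crossprod(rt, annot[win, , drop = FALSE])
    }
  }
  structure(list(scores = scores, snps = panel$snps, window_cm = window_cm),
            class = "annotation_ldscores")
}

#' Stratified LD-score regression with block-jackknife inference
#'
#' Regresses per-SNP GWAS chi-squares on `N * l(j, c)` across annotations
#' with an intercept. A first unweighted pass estimates the base coefficient,
#' from which heteroskedasticity weights `1 / (l_base * 2 * (1 + N *
#' tau_base * l_base)^2)` are formed for the weighted fit. Standard errors
#' come from a delete-one block jackknife over `n_blocks` contiguous SNP
#' blocks; each annotation's one-tailed p tests `tau > 0` against the
#' standard normal.
#'
#' @param sumstats summary statistics (SNP, P, N), aligned by SNP id to the
#'   LD scores.
#' @param ldscores an `annotation_ldscores` object.
#' @param n_blocks jackknife blocks (>= 2; default 200).
#' @return object of class `sldsr_result`: data.frame with one row per
#'   annotation (plus the intercept): annotation, tau, se, z, p, n_blocks.
#' @export
sldsr_fit <- function(sumstats, ldscores, n_blocks = 200L) {
  stopifnot(inherits(ldscores, "annotation_ldscores"), n_blocks >= 2)
  idx <- match(sumstats$SNP, ldscores$snps$snp)
  if (anyNA(idx))
    stop("summary-statistic SNP(s) absent from LD scores", call. = FALSE)
  L <- ldscores$scores[idx, , drop = FALSE]
  m <- nrow(L)
  if (m < n_blocks) stop("fewer SNPs than jackknife blocks", call. = FALSE)
  chi2 <- qchisq(sumstats$P, df = 1, lower.tail = FALSE)
  N <- sumstats$N
  X <- cbind(intercept = 1, N * L)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient annotation design (duplicated annotation?)",
         call. = FALSE)
  base_col <- if ("base" %in% colnames(L)) "base" else colnames(L)[1]

  # first pass: unweighted, to estimate the base coefficient for weighting
  tau_base <- qr.coef(qr(X), chi2)[base_col]
  lb <- pmax(L[, base_col], 1)
  w <- 1 / (lb * 2 * (1 + N * max(tau_base, 0) * lb)^2)

  # weighted fit via per-block sufficient statistics (fast jackknife)
  block <- ceiling(seq_len(m) / (m / n_blocks))
  k <- ncol(X)
  Xw <- X * sqrt(w)
  yw <- chi2 * sqrt(w)
  xtx_b <- array(0, c(k, k, n_blocks))
  xty_b <- matrix(0, k, n_blocks)
  for (b in seq_len(n_blocks)) {
    rows <- which(block == b)
    xb <- Xw[rows, , drop = FALSE]
    xtx_b[, , b] <- crossprod(xb)
    xty_b[, b] <- crossprod(xb, yw[rows])
  }
  xtx <- apply(xtx_b, c(1, 2), sum)
  xty <- rowSums(xty_b)
  tau <- solve(xtx, xty)
  jk <- vapply(seq_len(n_blocks), function(b) {
    solve(xtx - xtx_b[, , b], xty - xty_b[, b])
  }, numeric(k))
  jk_mean <- rowMeans(jk)
  se <- sqrt((n_blocks - 1) / n_blocks * rowSums((jk - jk_mean)^2))
  z <- tau / se
  out <- data.frame(annotation = colnames(X), tau = unname(tau),
                    se = unname(se), z = unname(z),
                    p = pmax(pnorm(unname(z), lower.tail = FALSE),
                             .Machine$double.xmin),
                    n_blocks = n_blocks, stringsAsFactors = FALSE)
  class(out) <- c("sldsr_result", "data.frame")
  out
}
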