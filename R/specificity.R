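#' Remove cell clusters with too few cells
#'
#' Clusters below `min_cells` cannot give representative mean expression and
#' are dropped before specificity scoring (in the motivating dataset this
#' removed two oligodendrocyte clusters of 7 and 3 cells, leaving 84 of 86).
#'
#' @param ann cell annotation data.frame (cell_id, cluster, donor, stage).
#' @param min_cells minimum cluster size retained (boundary kept; default 10).
#' @return the annotation restricted to surviving clusters.
#' @export
filter_clusters <- function(ann, min_cells = 10L) {
  stopifnot(min_cells >= 1)
  sizes <- table(ann$cluster)
  keep <- names(sizes)[sizes >= min_cells]
  if (length(keep) == 0L) stop("no clusters survive", call. = FALSE)
  ann[ann$cluster %in% keep, , drop = FALSE]
}

#' Filter genes before specificity scoring
#'
#' Removes, in order: genes on non-autosomes (sex-chromosome genes can
#' introduce donor sex bias), genes overlapping the extended MHC region
#' (default chr6:25,000,000-35,000,000, closed interval, any base overlap;
#' its extensive LD confounds enrichment), genes expressed in fewer than
#' `min_cells_expressing` cells, and uninformative genes whose one-way
#' variance test across cell types (on log-CP10K values) is not significant
#' at BH-adjusted `alpha_uninformative`.
#'
#' @param counts genes x cells count matrix (rownames = gene ids).
#' @param genes gene-model table covering all count-matrix genes.
#' @param ann cell annotation (already cluster-filtered); only its cells are
#'   used and its clusters define the variance-test groups.
#' @param mhc list(chr, start, end) for the excluded region.
#' @param min_cells_expressing minimum number of cells with a nonzero count.
#' @param alpha_uninformative BH-adjusted significance cutoff for the
#'   between-type variance test.
#' @return the filtered count matrix (columns restricted to `ann$cell_id`).
#' @export
filter_genes <- function(counts, genes, ann,
                         mhc = list(chr = "chr6", start = 25e6, end = 35e6),
                         min_cells_expressing = 10L,
                         alpha_uninformative = 0.05) {
  gid <- rownames(counts)
  gi <- genes[match(gid, genes$gene_id), ]
  if (anyNA(gi$gene_id))
    stop("gene models missing for: ",
         paste(head(gid[is.na(gi$gene_id)]), collapse = ", "), call. = FALSE)
  known <- c(autosome_labels(), "chrX", "chrY", "chrM")
  if (any(bad <- !gi$chr %in% known))
    stop("unknown chromosome label for gene ",
         paste(head(gi$gene_id[bad]), collapse = ", "), call. = FALSE)

  keep <- gi$chr %in% autosome_labels()
  keep <- keep & !overlaps_any(gi$chr, gi$start, gi$end,
                               mhc$chr, mhc$start, mhc$end)
  counts <- counts[keep, ann$cell_id, drop = FALSE]
  counts <- counts[rowSums(counts > 0) >= min_cells_expressing, ,
                   drop = FALSE]
  if (nrow(counts) == 0L) stop("no genes survive filtering", call. = FALSE)

  # vectorized one-way ANOVA across cell types on normalized values
  x <- normalize_counts(counts, "log_cp10k")
  f <- factor(ann$cluster)
  k <- nlevels(f)
  nc <- as.numeric(table(f))
  n <- ncol(x)
  ind <- stats::model.matrix(~ f - 1)
  gm <- (x %*% ind) / rep(nc, each = nrow(x))
  grand <- rowMeans(x)
  ssb <- as.numeric((gm - grand)^2 %*% nc)
  ssw <- rowSums(x^2) - as.numeric(gm^2 %*% nc)
  fstat <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- pf(fstat, k - 1, n - k, lower.tail = FALSE)
  # flat genes: between-type variation indistinguishable from rounding
  # noise on the gene's own scale (covers the 0/0 F statistic too)
  flat <- is.nan(fstat) | ssb <= 1e-10 * pmax(rowSums(x^2), 1e-300)
  p[flat] <- 1
  informative <- p.adjust(p, "BH") <= alpha_uninformative
  counts[informative, , drop = FALSE]
}

#' Normalize a count matrix
#'
#' `log_cp10k` is `ln(1 + 1e4 * count / cell_total)` (invariant to scaling a
#' cell's counts). `pearson_residual` is `(count - mu) / sqrt(mu + mu^2 /
#' theta)` with `mu = gene mean x cell size factor` and a fixed dispersion
#' `theta`, clipped at `+/- sqrt(n_cells)` — a deterministic approximation to
#' regularized-NB normalization that preserves the mean-ratio structure the
#' specificity score needs.
#'
#' @param counts genes x cells count matrix.
#' @param method "log_cp10k" (default) or "pearson_residual".
#' @param theta fixed NB dispersion for Pearson residuals.
#' @return real matrix, same dimensions and dimnames.
#' @export
normalize_counts <- function(counts,
                             method = c("log_cp10k", "pearson_residual"),
                             theta = 100) {
  method <- match.arg(method)
  tot <- colSums(counts)
  if (any(tot == 0))
    stop("cell with zero total count: ",
         paste(head(colnames(counts)[tot == 0]), collapse = ", "),
         call. = FALSE)
  if (method == "log_cp10k") {
    log1p(sweep(counts, 2, 1e4 / tot, `*`))
  } else {
    sf <- tot / mean(tot)
    mu <- rowMeans(counts) %o% sf
    r <- (counts - mu) / sqrt(mu + mu^2 / theta)
    clip <- sqrt(ncol(counts))
    pmin(pmax(r, -clip), clip)
  }
}

#' Expression specificity matrix
#'
#' For each retained gene, its mean expression in each cell type divided by
#' the sum of its mean expression over all cell types, so each row is a
#' probability vector over cell types. Genes with zero mean everywhere are
#' dropped.
#'
#' @param normalized genes x cells normalized expression matrix.
#' @param ann cell annotation with `cell_id` and `cluster` (>= 2 clusters).
#' @return genes x cell-types matrix of specificity scores; rows sum to 1.
#' @export
specificity_matrix <- function(normalized, ann) {
  f <- factor(ann$cluster)
  if (nlevels(f) < 2)
    stop("need at least two cell types", call. = FALSE)
  x <- normalized[, ann$cell_id, drop = FALSE]
  ind <- stats::model.matrix(~ f - 1)
  colnames(ind) <- levels(f)
  means <- (x %*% ind) / rep(as.numeric(table(f)), each = nrow(x))
  tot <- rowSums(means)
  means <- means[tot > 0, , drop = FALSE]
  spec <- means / rowSums(means)
  as.matrix(spec)
}

#' Top-specificity gene set for one cell type
#'
#' Ranks genes by specificity for `cell_type` (descending; ties broken by
#' ascending gene id, so the set is deterministic) and returns the top
#' decile-style fraction or a fixed top-N. An optional biotype filter
#' (protein_coding / noncoding) is applied before ranking.
#'
#' @param spec specificity matrix from [specificity_matrix()].
#' @param cell_type a column name of `spec`.
#' @param fraction top fraction in (0, 1], e.g. 0.1 for the top decile
#'   (set size is `ceiling(fraction * n_genes)`); give either this or `n`.
#' @param n fixed set size (e.g. 2000); errors if larger than the ranked
#'   gene count unless `allow_short = TRUE`.
#' @param biotype_filter "all", "protein_coding" or "noncoding".
#' @param genes gene-model table (required for biotype filtering).
#' @param allow_short return all genes when `n` exceeds the available count.
#' @return character vector of gene ids.
#' @export
top_fraction_set <- function(spec, cell_type, fraction = NULL, n = NULL,
                             biotype_filter = c("all", "protein_coding",
                                                "noncoding"),
                             genes = NULL, allow_short = FALSE) {
  biotype_filter <- match.arg(biotype_filter)
  if (!cell_type %in% colnames(spec))
    stop("unknown cell type: ", cell_type, call. = FALSE)
  s <- spec[, cell_type]
  ids <- rownames(spec)
  if (biotype_filter != "all") {
    if (is.null(genes))
      stop("biotype filtering needs the gene-model table", call. = FALSE)
    bt <- genes$biotype[match(ids, genes$gene_id)]
    keep <- if (biotype_filter == "protein_coding") bt == "protein_coding"
            else bt != "protein_coding"
    s <- s[keep]
    ids <- ids[keep]
  }
  if (is.null(fraction) == is.null(n))
    stop("give exactly one of 'fraction' or 'n'", call. = FALSE)
  if (!is.null(fraction)) {
    if (fraction <= 0 || fraction > 1)
      stop("'fraction' must lie in (0, 1]", call. = FALSE)
    size <- ceiling(fraction * length(ids))
  } else {
    if (n > length(ids) && !allow_short)
      stop("requested top ", n, " of only ", length(ids), " genes",
           call. = FALSE)
    size <- min(n, length(ids))
  }
  ord <- order(-s, ids)
  ids[ord][seq_len(size)]
}

#' Jaccard index of two gene sets
#'
#' @param a,b character vectors of gene ids.
#' @return |intersection| / |union|; 0 when both sets are empty.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}
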