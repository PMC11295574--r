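# Readers/writers for the plain-text interchange formats the pipeline uses.
# Coordinates are 1-based inclusive throughout; sumstats are whitespace
# delimited with header SNP CHR BP A1 A2 P N.

#' Write gene sets in GMT format
#'
#' @param sets named list: set name -> gene ids.
#' @param path output file.
#' @param description optional per-set description (recycled).
#' @export
write_gmt <- function(sets, path, description = "celltrait") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from GMT format
#'
#' @param path GMT file (set name, description, then gene ids, tab-separated).
#' @return named list: set name -> gene ids (duplicates removed).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(out) <- vapply(parts, `[[`, "", 1)
  out
}

#' Write GWAS summary statistics
#'
#' Whitespace-delimited text with header `SNP CHR BP A1 A2 P N`.
#'
#' @param sumstats summary-statistics data.frame.
#' @param path output file.
#' @export
write_sumstats <- function(sumstats, path) {
  write.table(sumstats[, c("SNP", "CHR", "BP", "A1", "A2", "P", "N")],
              path, quote = FALSE, row.names = FALSE, sep = " ")
  invisible(path)
}

#' Read GWAS summary statistics
#'
#' @param path whitespace-delimited file with header `SNP CHR BP A1 A2 P N`.
#' @return validated data.frame.
#' @export
read_sumstats <- function(path) {
  x <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("SNP", "CHR", "BP", "A1", "A2", "P", "N")
  if (!all(need %in% names(x)))
    stop("sumstats must have columns ", paste(need, collapse = " "),
         call. = FALSE)
  if (any(x$P <= 0 | x$P > 1)) stop("p-values must lie in (0, 1]",
                                    call. = FALSE)
  if (any(x$BP <= 0)) stop("positions must be positive", call. = FALSE)
  if (anyDuplicated(x$SNP)) stop("duplicate SNP ids", call. = FALSE)
  x
}

#' Write a count matrix as MatrixMarket plus gene/cell TSVs
#'
#' @param counts genes x cells count matrix.
#' @param dir output directory (created if needed); writes `counts.mtx`,
#'   `genes.tsv`, `cells.tsv`.
#' @export
write_counts_mtx <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
                  file.path(dir, "counts.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' Read a count matrix written by [write_counts_mtx()]
#'
#' @param dir directory containing `counts.mtx`, `genes.tsv`, `cells.tsv`.
#' @return dense genes x cells integer matrix.
#' @export
read_counts_mtx <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "counts.mtx")))
  dimnames(m) <- list(readLines(file.path(dir, "genes.tsv")),
                      readLines(file.path(dir, "cells.tsv")))
  storage.mode(m) <- "integer"
  m
}

#' Write the gene-model table as TSV (1-based inclusive coordinates)
#'
#' @param genes gene-model table.
#' @param path output file.
#' @export
write_gene_models <- function(genes, path) {
  write.table(genes, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Read a gene-model TSV written by [write_gene_models()]
#' @param path input file.
#' @return gene-model data.frame.
#' @export
read_gene_models <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write a specificity matrix as TSV
#'
#' @param spec specificity matrix.
#' @param path output file (gene ids in the first column).
#' @export
write_specificity <- function(spec, path) {
  df <- data.frame(gene_id = rownames(spec), as.data.frame(spec),
                   check.names = FALSE)
  write.table(df, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Write per-SNP annotation LD scores as TSV
#'
#' Conventional layout: SNP, CHR, BP, then one column per annotation.
#'
#' @param ldscores an `annotation_ldscores` object.
#' @param path output file.
#' @export
write_ldscores <- function(ldscores, path) {
  df <- data.frame(SNP = ldscores$snps$snp, CHR = ldscores$snps$chr,
                   BP = ldscores$snps$bp,
                   as.data.frame(ldscores$scores), check.names = FALSE)
  write.table(df, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Write synthetic ground truth as JSON
#'
#' @param truth truth list from the generators.
#' @param path output file.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write a variant table as VCF
#'
#' Minimal VCF 4.2 with FORMAT fields GT:DP:GQ:AD (AD derived from DP and
#' allele balance) and INFO tags CSQ (consequence class), EXT (present in the
#' external reference), and LC (low-complexity region).
#'
#' @param vt a `variant_table`.
#' @param path output file (plain text).
#' @export
write_variant_vcf <- function(vt, path) {
  info <- vt$info
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=EXT,Number=0,Type=Flag,Description=\"In external reference\">",
    "##INFO=<ID=LC,Number=0,Type=Flag,Description=\"Low-complexity region\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene id\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=AD,Number=2,Type=Integer,Description=\"Allele depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(vt$geno)), collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (i in seq_len(nrow(info))) {
    g <- vt$geno[i, ]
    ad_alt <- round(vt$dp[i, ] * vt$ab[i, ])
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    fmt <- paste0(gt, ":", vt$dp[i, ], ":", vt$gq[i, ], ":",
                  vt$dp[i, ] - ad_alt, ",", ad_alt)
    tags <- paste0("CSQ=", info$consequence[i], ";GENE=", info$gene_id[i],
                   if (info$in_external_ref[i]) ";EXT" else "",
                   if (info$low_complexity[i]) ";LC" else "")
    writeLines(paste(c(info$chr[i], info$pos[i], info$variant_id[i],
                       info$ref[i], info$alt[i], ".",
                       if (info$vqsr_pass[i]) "PASS" else "VQSR",
                       tags, "GT:DP:GQ:AD", fmt), collapse = "\t"), con)
  }
  invisible(path)
}
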