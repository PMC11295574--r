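#' Pipeline run configuration
#'
#' Validated bundle of the thresholds used across the pipeline. Defaults are
#' the conventional analysis settings: cluster-size minimum 10, top
#' specificity decile (fraction 0.1) or fixed top-2000 sets, 35 kb / 10 kb
#' gene-window extension for gene scores, 100 kb annotation windows and 1 cM
#' LD-score windows for heritability partitioning, 200 jackknife blocks, HWE
#' exclusion at 1e-8 and call-rate exclusion at 0.9. Unknown keys are
#' rejected.
#'
#' @param ... overrides of the defaults below.
#' @return a validated `run_config` list.
#' @export
run_config <- function(...) {
  defaults <- list(min_cells = 10L, fraction = 0.1, top_n = 2000L,
                   magma_up = 35000L, magma_down = 10000L,
                   sldsr_window = 100000L, window_cm = 1.0,
                   n_blocks = 200L, hwe_alpha = 1e-8, call_rate = 0.9,
                   min_cells_expressing = 10L, alpha_uninformative = 0.05,
                   biotype = "all", seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, over)
  for (nm in c("min_cells", "top_n", "magma_up", "magma_down",
               "sldsr_window", "n_blocks", "min_cells_expressing")) {
    if (cfg[[nm]] < 0) stop("'", nm, "' must be non-negative", call. = FALSE)
  }
  if (cfg$fraction <= 0 || cfg$fraction > 1)
    stop("'fraction' must lie in (0, 1]", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Cell-population scan: dual gene-set and heritability enrichment
#'
#' Runs the full common-variant scan on one dataset: cluster and gene
#' filtering, specificity scoring, gene-level association scores, and per
#' cell type both (i) competitive enrichment of the top-specificity gene set
#' and (ii) stratified LD-score regression of the matching SNP annotation
#' conditional on the baseline annotations. A population is flagged
#' dual-significant when both one-tailed p-values fall below the Bonferroni
#' threshold `0.05 / n_celltypes`.
#'
#' @param counts genes x cells count matrix.
#' @param ann cell annotation table.
#' @param genes gene-model table.
#' @param sumstats GWAS summary statistics.
#' @param panel LD reference panel.
#' @param config a [run_config()].
#' @param baseline optional extra baseline annotation columns
#'   (SNPs x annotations, aligned to `sumstats` rows) for the conditional
#'   heritability fit.
#' @return list: `table` (per cell type: set size, enrichment beta/p,
#'   tau/z/p, dual_significant), `bonferroni`, `spec`, `scores`, and the drop
#'   log `log`.
#' @export
run_celltype_scan <- function(counts, ann, genes, sumstats, panel,
                              config = run_config(), baseline = NULL) {
  stopifnot(inherits(config, "run_config"))
  log <- list(n_cells_in = nrow(ann), n_genes_in = nrow(counts))
  ann <- filter_clusters(ann, config$min_cells)
  log$n_clusters <- length(unique(ann$cluster))
  counts <- filter_genes(counts, genes, ann,
                         min_cells_expressing = config$min_cells_expressing,
                         alpha_uninformative = config$alpha_uninformative)
  log$n_genes_retained <- nrow(counts)
  spec <- specificity_matrix(normalize_counts(counts, "log_cp10k"), ann)
  scores <- gene_score_table(sumstats, panel, genes,
                             upstream = config$magma_up,
                             downstream = config$magma_down)
  log$n_genes_scored <- nrow(scores)

  cell_types <- colnames(spec)
  sets <- lapply(cell_types, function(ct) {
    top_fraction_set(spec, ct, fraction = config$fraction,
                     biotype_filter = config$biotype, genes = genes)
  })
  names(sets) <- cell_types

  annot <- cbind(base = rep(1, nrow(sumstats)))
  if (!is.null(baseline)) annot <- cbind(annot, baseline)
  set_cols <- vapply(sets, function(s) {
    genes_to_annotation(s, genes, window = config$sldsr_window, snps = sumstats)
  }, numeric(nrow(sumstats)))
  ld <- compute_ld_scores(panel, cbind(annot, set_cols),
                          window_cm = config$window_cm)
  base_cols <- seq_len(ncol(annot))

  rows <- lapply(cell_types, function(ct) {
    enr <- competitive_enrichment(scores, sets[[ct]], name = ct)
    ld_ct <- ld
    ld_ct$scores <- ld$scores[, c(colnames(annot), ct), drop = FALSE]
    sl <- sldsr_fit(sumstats, ld_ct, n_blocks = config$n_blocks)
    tau_row <- sl[sl$annotation == ct, ]
    data.frame(cell_type = ct, n_set = enr$n_set, magma_beta = enr$beta,
               magma_p = enr$p, sldsr_tau = tau_row$tau,
               sldsr_z = tau_row$z, sldsr_p = tau_row$p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  thr <- bonferroni_threshold(length(cell_types))
  tab$dual_significant <- tab$magma_p < thr & tab$sldsr_p < thr
  list(table = tab, bonferroni = thr, spec = spec, scores = scores,
       log = log)
}

#' Dot-plot of a cell-population scan
#'
#' Draws -log10 one-tailed p-values per cell population for both enrichment
#' routes, with the nominal (0.05, dotted) and Bonferroni (dashed)
#' thresholds. Requires ggplot2.
#'
#' @param scan_table the `table` element of [run_celltype_scan()].
#' @param bonferroni the family-wise threshold to draw.
#' @return a ggplot object.
#' @export
plot_scan <- function(scan_table, bonferroni = 0.05 / nrow(scan_table)) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_scan() needs ggplot2", call. = FALSE)
  df <- rbind(
    data.frame(cell_type = scan_table$cell_type, method = "gene-set",
               logp = -log10(scan_table$magma_p)),
    data.frame(cell_type = scan_table$cell_type, method = "heritability",
               logp = -log10(scan_table$sldsr_p)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell_type, y = .data$logp,
                                   colour = .data$method)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dotted") +
    ggplot2::geom_hline(yintercept = -log10(bonferroni),
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = expression(-log[10](italic(p))),
                  colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

# deterministic short hash of an R object (config fingerprinting)
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

#' Plain-text run report
#'
#' Renders a deterministic text report (no timestamps) of a results bundle:
#' run metadata (seed, configuration hash), each stage's table, and the
#' multiple-testing threshold each table was judged against.
#'
#' @param bundle named list of stage results (data.frames, each optionally
#'   carrying a `bonferroni` attribute).
#' @param config the [run_config()] used.
#' @return character vector of report lines (invisibly printable via `cat`).
#' @export
report <- function(bundle, config = run_config()) {
  if (length(bundle) == 0L) stop("empty results bundle", call. = FALSE)
  lines <- c("celltrait run report",
             paste0("seed: ", config$seed),
             paste0("config hash: ", config_hash(unclass(config))), "")
  for (nm in names(bundle)) {
    x <- bundle[[nm]]
    lines <- c(lines, paste0("== ", nm, " =="))
    thr <- attr(x, "bonferroni")
    if (!is.null(thr))
      lines <- c(lines, paste0("bonferroni threshold: ", signif(thr, 3)))
    if (is.data.frame(x)) {
      lines <- c(lines, utils::capture.output(print(x, digits = 4)))
    } else {
      lines <- c(lines, utils::capture.output(utils::str(x)))
    }
    lines <- c(lines, "")
  }
  lines
}
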