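#' Per-cell trait-association score
#'
#' Regresses gene-level GWAS statistics on the cell's normalized expression,
#' adjusting for each gene's dataset-average expression:
#' `gene_stat ~ intercept + cell_expr + avg_expr` over all genes in the
#' design. The score is the t-statistic of the `cell_expr` coefficient, so a
#' positive score means trait-associated genes are preferentially expressed
#' in this cell relative to the dataset average.
#'
#' @param cell_expr normalized expression of one cell (per gene).
#' @param gene_stat per-gene association statistic (z by default upstream).
#' @param avg_expr per-gene dataset mean of normalized expression.
#' @return list: `score` (t-statistic; 0 with `flag = "degenerate"` when the
#'   cell's expression is constant or collinear with the average) and `flag`.
#' @export
cell_score <- function(cell_expr, gene_stat, avg_expr) {
  ok <- complete.cases(cell_expr, gene_stat, avg_expr)
  if (sum(ok) < 30)
    stop("need >= 30 genes with expression, average, and statistic",
         call. = FALSE)
  X <- cbind(1, cell = cell_expr[ok], avg = avg_expr[ok])
  y <- gene_stat[ok]
  if (qr(X)$rank < ncol(X))
    return(list(score = 0, flag = "degenerate"))
  fit <- lm.fit(X, y)
  df <- length(y) - ncol(X)
  rss <- sum(fit$residuals^2)
  if (rss <= 0 || df <= 0) return(list(score = 0, flag = "degenerate"))
  xtxi <- chol2inv(qr.R(fit$qr))
  tstat <- fit$coefficients["cell"] / sqrt(rss / df * xtxi[2, 2])
  list(score = unname(tstat), flag = "")
}

#' Trait-association scores for every cell
#'
#' Applies [cell_score()] to each column of a normalized expression matrix.
#'
#' @param expr genes x cells normalized expression matrix.
#' @param gene_stat data.frame with `gene_id` and a statistic column.
#' @param stat which gene statistic to regress: the gene z-score (default) or
#'   `-log10(p)`.
#' @param ann optional cell annotation supplying `donor` (and `pseudotime`)
#'   columns, matched by cell_id.
#' @param pseudotime optional per-cell pseudotime vector (overrides `ann`).
#' @return data.frame: cell_id, score, flag, plus donor/pseudotime when
#'   available (a `CellTraitScores` table).
#' @export
cell_scores <- function(expr, gene_stat, stat = c("z", "neglog10p"),
                        ann = NULL, pseudotime = NULL) {
  stat <- match.arg(stat)
  common <- intersect(rownames(expr), gene_stat$gene_id)
  if (length(common) < 30)
    stop("need >= 30 genes shared between expression and gene statistics",
         call. = FALSE)
  expr <- expr[common, , drop = FALSE]
  gs <- gene_stat[match(common, gene_stat$gene_id), ]
  y <- if (stat == "z") gs$z else -log10(gs$p)
  avg <- rowMeans(expr)
  res <- lapply(seq_len(ncol(expr)),
                function(j) cell_score(expr[, j], y, avg))
  out <- data.frame(cell_id = colnames(expr),
                    score = vapply(res, `[[`, 0, "score"),
                    flag = vapply(res, `[[`, "", "flag"),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(ann)) {
    i <- match(out$cell_id, ann$cell_id)
    if ("donor" %in% names(ann)) out$donor <- ann$donor[i]
    if ("pseudotime" %in% names(ann)) out$pseudotime <- ann$pseudotime[i]
  }
  if (!is.null(pseudotime)) out$pseudotime <- pseudotime
  out
}

#' Filter and log-normalize trajectory expression
#'
#' Removes genes with nonzero counts in fewer than `min_cells` cells
#' (default 10), then log-CP10K normalizes.
#'
#' @param counts genes x cells count matrix for the trajectory cells.
#' @param min_cells minimum number of expressing cells (boundary kept).
#' @return normalized expression matrix.
#' @export
filter_trajectory_genes <- function(counts, min_cells = 10L) {
  stopifnot(min_cells >= 1)
  keep <- rowSums(counts > 0) >= min_cells
  if (!any(keep)) stop("no genes survive the trajectory filter",
                       call. = FALSE)
  normalize_counts(counts[keep, , drop = FALSE], "log_cp10k")
}

#' Regression of cell-trait scores on pseudotime
#'
#' Regresses the z-scored cell score on z-scored pseudotime, so the
#' coefficient is the standardized beta (the Pearson correlation for this
#' single-predictor model), with its two-sided p-value.
#'
#' @param scores `CellTraitScores` data.frame with `score` and `pseudotime`.
#' @return data.frame: beta (standardized), p, n_cells (a TrajectoryResult).
#' @export
trajectory_test <- function(scores) {
  ok <- complete.cases(scores$score, scores$pseudotime)
  s <- scores[ok, , drop = FALSE]
  if (nrow(s) < 10)
    stop("need >= 10 cells with pseudotime", call. = FALSE)
  if (sd(s$pseudotime) == 0)
    stop("pseudotime is constant", call. = FALSE)
  if (sd(s$score) == 0) return(data.frame(beta = 0, p = 1,
                                          n_cells = nrow(s)))
  # both variables z-scored, single predictor: beta is the Pearson r
  n <- nrow(s)
  r <- cor(s$score, s$pseudotime)
  r <- min(max(r, -1), 1)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.xmin))
  p <- max(2 * pt(-abs(tstat), df = n - 2), .Machine$double.xmin)
  data.frame(beta = r, p = p, n_cells = n)
}

#' Leave-one-donor-out trajectory robustness
#'
#' Repeats [trajectory_test()] excluding each donor's cells in turn; a donor
#' owning all cells yields a flagged row instead of a test.
#'
#' @param scores `CellTraitScores` with `score`, `pseudotime`, `donor`.
#' @return data.frame: excluded_donor, beta, p, n_cells, flag.
#' @export
leave_one_donor_out <- function(scores) {
  donors <- unique(scores$donor)
  if (length(donors) < 2) stop("need >= 2 donors", call. = FALSE)
  rows <- lapply(donors, function(d) {
    rest <- scores[scores$donor != d, , drop = FALSE]
    if (nrow(rest) == 0L)
      return(data.frame(excluded_donor = d, beta = NA_real_, p = NA_real_,
                        n_cells = 0L, flag = "donor_owns_all_cells"))
    r <- tryCatch(trajectory_test(rest), error = function(e) NULL)
    if (is.null(r))
      return(data.frame(excluded_donor = d, beta = NA_real_, p = NA_real_,
                        n_cells = nrow(rest), flag = "untestable"))
    data.frame(excluded_donor = d, beta = r$beta, p = r$p,
               n_cells = r$n_cells, flag = "")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' First-principal-component pseudotime
#'
#' A deliberately simple stand-in ordering for graph-based trajectory
#' inference, used so synthetic runs are self-contained: the first principal
#' component of the (log-normalized) expression matrix, oriented so that the
#' root cells take the smallest values, min-max scaled to [0, 1]. Real
#' analyses should supply externally computed pseudotime as an input column.
#'
#' @param expr genes x cells normalized expression matrix (>= 3 cells).
#' @param root_cells cell ids anchoring the start of the trajectory.
#' @return named numeric vector of pseudotime values in [0, 1].
#' @export
simple_pseudotime <- function(expr, root_cells) {
  if (ncol(expr) < 3) stop("need >= 3 cells", call. = FALSE)
  x <- t(expr)
  x <- sweep(x, 2, colMeans(x))
  sv <- svd(x, nu = 1, nv = 0)
  if (sv$d[1] <= .Machine$double.eps * max(dim(x)))
    stop("expression matrix has rank 0", call. = FALSE)
  pc1 <- sv$u[, 1] * sv$d[1]
  names(pc1) <- colnames(expr)
  root <- names(pc1) %in% root_cells
  if (!any(root)) stop("no root cells found in the matrix", call. = FALSE)
  if (mean(pc1[root]) > mean(pc1)) pc1 <- -pc1
  (pc1 - min(pc1)) / (max(pc1) - min(pc1))
}
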