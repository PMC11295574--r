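#' Competitive gene-set enrichment of gene-level association statistics
#'
#' Regresses gene z-scores on a set-membership indicator plus technical
#' covariates (default: log window length and log SNP count), and reports a
#' one-tailed p-value for the set mean being *greater* than the background
#' (all enrichment p-values in this pipeline are one-tailed). Gene-gene LD
#' correlation is not modeled in the default regression; results state this
#' in the `model` field.
#'
#' @param scores gene score table ([gene_score_table()]: gene_id, z, plus
#'   covariate columns).
#' @param set character vector of gene ids.
#' @param covariates covariate column names in `scores` (may be empty).
#' @param name label for the result row.
#' @return one-row data.frame: set, beta, se, p (one-tailed), n_set,
#'   n_background, flag, model.
#' @export
competitive_enrichment <- function(scores, set,
                                   covariates = c("log_length", "log_nsnps"),
                                   name = "set") {
  member <- scores$gene_id %in% set
  if (sum(member) < 2 || sum(!member) < 2)
    stop("need >= 2 set genes and >= 2 background genes with scores",
         call. = FALSE)
  covs <- as.matrix(scores[, covariates, drop = FALSE])
  X <- cbind(1, member = as.numeric(member), covs)
  y <- scores$z
  flag <- ""
  if (sd(y) == 0 || qr(X)$rank < ncol(X)) {
    beta <- 0; se <- NA_real_; p <- 0.5
    flag <- "degenerate"
  } else {
    fit <- lm.fit(X, y)
    df <- length(y) - ncol(X)
    rss <- sum(fit$residuals^2)
    if (rss <= .Machine$double.eps * sum(y^2) || df <= 0) {
      beta <- unname(fit$coefficients["member"]); se <- NA_real_; p <- 0.5
      flag <- "degenerate"
    } else {
      sigma2 <- rss / df
      xtxi <- chol2inv(qr.R(fit$qr))
      beta <- unname(fit$coefficients["member"])
      se <- sqrt(sigma2 * xtxi[2, 2])
      p <- pt(beta / se, df = df, lower.tail = FALSE)
    }
  }
  data.frame(set = name, beta = beta, se = se, p = p,
             n_set = sum(member), n_background = sum(!member),
             flag = flag, model = "ols_no_gene_correlation",
             stringsAsFactors = FALSE)
}

#' GO-style over-representation analysis
#'
#' One-sided hypergeometric test per term for over-representation of `set`
#' genes among term genes, within `background`, with BH adjustment across
#' terms. Terms with no background genes are skipped with a warning.
#'
#' @param set gene ids (must be a subset of `background`).
#' @param annotation named list: term id -> gene ids.
#' @param background gene ids defining the universe (e.g. all genes detected
#'   in the cell population).
#' @return data.frame: term, overlap, expected, fold, p, p_adj, n_term,
#'   ordered by p.
#' @export
go_overrepresentation <- function(set, annotation, background) {
  set <- unique(set); background <- unique(background)
  if (!all(set %in% background))
    stop("'set' must be contained in 'background'", call. = FALSE)
  n_bg <- length(background)
  n_set <- length(set)
  rows <- lapply(names(annotation), function(term) {
    term_genes <- intersect(unique(annotation[[term]]), background)
    k <- length(term_genes)
    if (k == 0L) {
      warning("term '", term, "' has no background genes; skipped")
      return(NULL)
    }
    ov <- length(intersect(set, term_genes))
    expected <- n_set * k / n_bg
    p <- if (ov == 0L) 1 else
      phyper(ov - 1, k, n_bg - k, n_set, lower.tail = FALSE)
    data.frame(term = term, overlap = ov, expected = expected,
               fold = if (expected > 0) ov / expected else 0,
               p = p, n_term = k, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable terms", call. = FALSE)
  out$p_adj <- pmax(p.adjust(out$p, "BH"), out$p)
  out[order(out$p, out$term), ]
}

#' Test GWAS enrichment within decile-by-GO intersection sets
#'
#' For each of the `top_k` most over-represented terms, intersects the term's
#' genes with the top-specificity-decile set and runs
#' [competitive_enrichment()] on the intersection. Intersections with fewer
#' than 2 genes are flagged untestable (p = NA). The Bonferroni threshold
#' `0.05 / top_k` is attached as attribute `bonferroni`.
#'
#' @param decile_set gene ids of the top specificity decile.
#' @param annotation named list: term id -> gene ids.
#' @param top_k number of top terms to test (ranked by `ora` if given,
#'   otherwise taken in list order).
#' @param scores gene score table for the competitive regression.
#' @param ora optional result of [go_overrepresentation()] used to rank terms.
#' @param covariates passed to [competitive_enrichment()].
#' @return data.frame of enrichment results, one row per term.
#' @export
intersect_and_test <- function(decile_set, annotation, top_k = 20L, scores,
                               ora = NULL,
                               covariates = c("log_length", "log_nsnps")) {
  stopifnot(top_k >= 1)
  terms <- if (!is.null(ora)) ora$term else names(annotation)
  terms <- head(terms, top_k)
  rows <- lapply(terms, function(term) {
    inter <- intersect(decile_set, annotation[[term]])
    if (length(inter) < 2 ||
        sum(scores$gene_id %in% inter) < 2 ||
        sum(!scores$gene_id %in% inter) < 2) {
      return(data.frame(set = term, beta = NA_real_, se = NA_real_,
                        p = NA_real_, n_set = length(inter),
                        n_background = NA_integer_, flag = "untestable",
                        model = "ols_no_gene_correlation",
                        stringsAsFactors = FALSE))
    }
    competitive_enrichment(scores, inter, covariates, name = term)
  })
  out <- do.call(rbind, rows)
  attr(out, "bonferroni") <- bonferroni_threshold(length(terms))
  out
}
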