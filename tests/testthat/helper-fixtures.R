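# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# small expression fixture: genes, counts, annotation, truth
fx_counts <- function() fixture("counts", function() {
  cfg <- sim_config(seed = 101, n_genes = 300, n_cell_types = 5,
                    cells_per_type = 60, marker_fold = 12)
  genes <- gen_gene_models(cfg)
  c(list(cfg = cfg, genes = genes), gen_counts(cfg, genes))
})

# mid-size GWAS fixture under the null (no planted effect)
fx_gwas_null <- function() fixture("gwas_null", function() {
  cfg <- sim_config(seed = 202, n_genes = 300, n_snps = 6000,
                    n_ld_blocks = 60)
  genes <- gen_gene_models(cfg)
  truth <- gen_counts(cfg, genes)$truth
  c(list(cfg = cfg, genes = genes, truth = truth),
    gen_panel_and_sumstats(cfg, genes, truth))
})

# gene score table on the null GWAS fixture
fx_gene_scores <- function() fixture("gene_scores", function() {
  g <- fx_gwas_null()
  suppressMessages(gene_score_table(g$sumstats, g$panel, g$genes))
})

# LD-score fixture on the null GWAS panel (base + planted-set annotations)
fx_ldscores <- function() fixture("ldscores", function() {
  g <- fx_gwas_null()
  a_set <- genes_to_annotation(g$truth$enriched_gene_set, g$genes,
                               window = 0, snps = g$sumstats)
  annot <- cbind(base = rep(1, nrow(g$sumstats)), set = a_set)
  list(ld = compute_ld_scores(g$panel, annot), annot = annot, gwas = g)
})

# independent enumeration oracle for the one-sided Wilcoxon rank-sum test:
# P(targets' rank-sum >= observed) over all choose(n1+n2, n1) assignments
wilcox_enum_oracle <- function(x_target, x_other) {
  pooled <- c(x_target, x_other)
  n1 <- length(x_target)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  sets <- utils::combn(length(pooled), n1)
  sums <- colSums(matrix(r[sets], nrow = n1))
  mean(sums >= obs - 1e-9)
}

# independent enumeration oracle for the HWE exact test: direct factorial
# products over all heterozygote counts consistent with the allele counts
hwe_enum_oracle <- function(n_homref, n_het, n_homalt) {
  n <- n_homref + n_het + n_homalt
  na <- 2 * n_homalt + n_het
  nmin <- min(na, 2 * n - na)
  if (nmin == 0) return(1)
  hets <- seq(nmin %% 2, nmin, by = 2)
  prob <- vapply(hets, function(h) {
    hom_min <- (nmin - h) / 2
    hom_maj <- n - h - hom_min
    factorial(n) / (factorial(hom_min) * factorial(h) * factorial(hom_maj)) *
      2^h
  }, 0)
  prob <- prob / sum(prob)
  obs <- prob[hets == n_het]
  sum(prob[prob <= obs * (1 + 1e-12)])
}
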