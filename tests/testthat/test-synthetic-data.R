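test_that("config validation rejects bad values", {
  expect_error(sim_config(n_genes = 0), "positive integer")
  expect_error(sim_config(marker_fraction = 1.2), "\\(0, 1\\)")
  expect_error(sim_config(ld_rho = 1), "\\[0, 1\\)")
  expect_error(sim_config(planted_burden_or = 0.5), ">= 1")
  expect_error(gen_gene_models(sim_config(n_genes = 11)), NA)
})

test_that("gene models place genes on chrX and in the MHC, deterministically", {
  cfg <- sim_config(seed = 1, n_genes = 100)
  g1 <- gen_gene_models(cfg)
  expect_equal(nrow(g1), 100)
  expect_gte(sum(g1$chr == "chrX"), 1)
  expect_gte(sum(g1$chr == "chr6" & g1$start >= 25e6 & g1$end <= 35e6), 1)
  expect_true(all(g1$start >= 1 & g1$end >= g1$start))
  # non-overlapping within chromosome
  for (ch in unique(g1$chr)) {
    gg <- g1[g1$chr == ch, ]
    gg <- gg[order(gg$start), ]
    if (nrow(gg) > 1) expect_true(all(gg$start[-1] > gg$end[-nrow(gg)]))
  }
  expect_identical(g1, gen_gene_models(cfg))
  g2 <- gen_gene_models(sim_config(seed = 2, n_genes = 100))
  expect_false(identical(g1$start, g2$start))
})

test_that("counts carry planted markers, tiny clusters, round-robin donors", {
  fx <- fx_counts()
  expect_equal(length(unique(fx$ann$cluster)), fx$cfg$n_cell_types + 2)
  sizes <- table(fx$ann$cluster)
  expect_setequal(as.integer(sizes[c("TinyA", "TinyB")]), c(7L, 3L))
  expect_equal(sort(unique(fx$ann$donor)),
               sprintf("D%02d", 1:fx$cfg$n_donors))
  expect_true(all(fx$counts >= 0))
  expect_true(all(unlist(fx$truth$marker_genes) %in% fx$genes$gene_id))
  expect_true(all(fx$truth$enriched_gene_set %in% fx$genes$gene_id))
  # determinism
  again <- gen_counts(fx$cfg, fx$genes)
  expect_identical(fx$counts, again$counts)
})

test_that("with unit marker fold no type is preferred beyond noise", {
  cfg <- sim_config(seed = 7, n_genes = 200, n_cell_types = 4,
                    cells_per_type = 100, marker_fold = 1)
  genes <- gen_gene_models(cfg)
  gc1 <- gen_counts(cfg, genes)
  ann <- filter_clusters(gc1$ann)
  spec <- specificity_matrix(normalize_counts(gc1$counts[, ann$cell_id]), ann)
  # mean specificity of "marker" genes in their own type ~ 1/k
  own <- vapply(names(gc1$truth$marker_genes), function(t) {
    mean(spec[intersect(gc1$truth$marker_genes[[t]], rownames(spec)), t])
  }, 0)
  expect_true(all(abs(own - 1 / 4) < 0.05))
})

test_that("planted markers reach their type's top decile across seeds", {
  hits <- vapply(1:50, function(s) {
    cfg <- sim_config(seed = 300 + s, n_genes = 200, n_cell_types = 4,
                      cells_per_type = 40, marker_fraction = 0.05,
                      marker_fold = 20, nb_dispersion = 10)
    genes <- gen_gene_models(cfg)
    gc1 <- gen_counts(cfg, genes)
    ann <- filter_clusters(gc1$ann)
    spec <- specificity_matrix(
      normalize_counts(gc1$counts[, ann$cell_id]), ann)
    top <- top_fraction_set(spec, "CT01", fraction = 0.1)
    mk <- intersect(gc1$truth$marker_genes$CT01, rownames(spec))
    all(mk %in% top)
  }, NA)
  expect_gte(mean(hits), 0.95)
})

test_that("null sumstats are uniform and LD structure matches construction", {
  g <- fx_gwas_null()
  expect_gt(ks.test(g$sumstats$P, "punif")$p.value, 0.01)
  # adjacent within-block dosage correlation ~ ld_rho
  geno <- g$panel$genotypes
  blk <- g$panel$snps$block
  idx <- which(blk[-1] == blk[-length(blk)])[1:300]
  r_adj <- vapply(idx, function(j) cor(geno[, j], geno[, j + 1]), 0)
  expect_lt(abs(mean(r_adj) - g$cfg$ld_rho), 0.03)
  # determinism
  again <- gen_panel_and_sumstats(g$cfg, g$genes, g$truth)
  expect_identical(g$sumstats, again$sumstats)
  expect_identical(g$panel$genotypes, again$panel$genotypes)
})

test_that("ld_rho = 0 yields near-zero adjacent r-squared", {
  cfg <- sim_config(seed = 11, n_snps = 2000, n_ld_blocks = 20, ld_rho = 0)
  genes <- gen_gene_models(cfg)
  truth <- gen_counts(cfg, genes)$truth
  ps <- gen_panel_and_sumstats(cfg, genes, truth)
  geno <- ps$panel$genotypes
  r2 <- vapply(seq_len(500), function(j) cor(geno[, j], geno[, j + 1])^2, 0)
  # E[r^2] ~ 1/n for independent SNPs
  n <- nrow(geno)
  expect_lt(mean(r2), 2 / n + 3 * sd(r2) / sqrt(length(r2)))
})

test_that("planted set effect inflates mean chi-square by its stated amount", {
  cfg <- sim_config(seed = 12, n_snps = 8000, n_ld_blocks = 80,
                    planted_set_effect = 0.8)
  genes <- gen_gene_models(cfg)
  truth <- gen_counts(cfg, genes)$truth
  ps <- gen_panel_and_sumstats(cfg, genes, truth)
  chi2 <- qchisq(ps$sumstats$P, 1, lower.tail = FALSE)
  eg <- genes[genes$gene_id %in% truth$enriched_gene_set, ]
  inset <- celltrait:::overlaps_any(ps$sumstats$CHR, ps$sumstats$BP,
                                    ps$sumstats$BP, eg$chr, eg$start, eg$end)
  m <- sum(inset)
  se <- sd(chi2[inset]) / sqrt(m)
  # LD inflates the effective SE; allow 3x the iid bound times sqrt(5)
  expect_lt(abs(mean(chi2[inset]) - (1 + 0.8)), 3 * se * sqrt(5))
  expect_lt(abs(mean(chi2[!inset]) - 1), 0.1)
})

test_that("trajectory pseudotime is in [0,1] and increasing with cell index", {
  fx <- fx_counts()
  gs <- data.frame(gene_id = fx$genes$gene_id, z = rnorm(nrow(fx$genes)))
  tr <- gen_trajectory(fx$cfg, gs, n_cells = 100, slope = 0.5)
  expect_true(all(tr$pseudotime >= 0 & tr$pseudotime <= 1))
  expect_true(all(diff(tr$pseudotime) > 0))
  expect_equal(ncol(tr$counts), 100)
  expect_error(gen_trajectory(fx$cfg, gs[1:10, ]), ">= 50")
})

test_that("rare-variant table plants QC violations and singleton PTVs", {
  fx <- fx_counts()
  cfg <- sim_config(seed = 15, n_cases = 150, n_controls = 150)
  vt <- gen_rare_variants(cfg, fx$genes, fx$truth)
  expect_false(all(vt$info$vqsr_pass))
  expect_true(any(vt$info$low_complexity))
  expect_true(any(vt$dp < 10))
  # at least one variant fails HWE and one fails call rate after genotype QC
  vtq <- genotype_qc(vt)
  cr <- 1 - rowMeans(is.na(vtq$geno))
  expect_true(any(cr < 0.9))
  hwe_p <- vapply(seq_len(nrow(vtq$geno)), function(i) {
    g <- vtq$geno[i, ]
    hwe_exact(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
              sum(g == 2, na.rm = TRUE))
  }, 0)
  expect_true(any(hwe_p < 1e-8))
  # planted singleton PTVs in burden genes survive the full QC chain
  qual <- define_ptv_singletons(variant_qc(vtq))
  in_burden <- vt$info$variant_id %in% qual &
    vt$info$gene_id %in% fx$truth$burden_genes
  expect_gt(sum(in_burden), 0)
})
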