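make_ann <- function(sizes) {
  data.frame(cell_id = sprintf("c%03d", seq_len(sum(sizes))),
             cluster = rep(names(sizes), sizes),
             donor = "D01", stage = "adult", stringsAsFactors = FALSE)
}

test_that("cluster filter drops small clusters with the documented boundary", {
  sizes <- setNames(c(rep(20L, 84), 7L, 3L), sprintf("cl%02d", 1:86))
  ann <- make_ann(sizes)
  kept <- filter_clusters(ann, min_cells = 10)
  expect_equal(length(unique(kept$cluster)), 84)
  expect_identical(filter_clusters(ann, min_cells = 1), ann)
  ann2 <- make_ann(c(a = 10L, b = 9L))
  expect_equal(unique(filter_clusters(ann2, 10)$cluster), "a")
  expect_error(filter_clusters(ann2, 100), "no clusters survive")
})

test_that("gene filter removes non-autosomal, MHC, sparse and flat genes", {
  genes <- data.frame(
    gene_id = c("gA", "gX", "gMHC", "gEdge", "gFlat", "gSparse", "gFill"),
    chr = c("chr1", "chrX", "chr6", "chr6", "chr2", "chr2", "chr2"),
    start = c(1e6, 1e6, 26e6, 24999000, 2e6, 3e6, 4e6),
    end = c(1.01e6, 1.01e6, 26.01e6, 25000500, 2.01e6, 3.01e6, 4.01e6),
    strand = "+", biotype = "protein_coding", stringsAsFactors = FALSE)
  n_cells <- 60
  ann <- make_ann(c(t1 = 30L, t2 = 30L))
  counts <- matrix(5L, 7, n_cells,
                   dimnames = list(genes$gene_id, ann$cell_id))
  counts["gA", ] <- ifelse(ann$cluster == "t1", 50L, 5L)  # informative
  counts["gFlat", ] <- 7L                                 # flat everywhere
  counts["gSparse", ] <- 0L
  counts["gSparse", 1:5] <- 3L                 # expressed in only 5 cells
  # filler keeps every cell's total identical after the sparse gene is
  # dropped, so normalization leaves a flat gene flat
  counts["gFill", ] <- 100L - colSums(counts[c("gA", "gFlat"), ])
  out <- filter_genes(counts, genes, ann, min_cells_expressing = 10)
  expect_false("gX" %in% rownames(out))       # non-autosomal
  expect_false("gMHC" %in% rownames(out))     # inside the MHC window
  expect_false("gEdge" %in% rownames(out))    # overlaps window boundary
  expect_false("gSparse" %in% rownames(out))  # too few expressing cells
  expect_false("gFlat" %in% rownames(out))    # no between-type variance
  expect_true("gA" %in% rownames(out))
  bad <- genes; bad$chr[1] <- "chr_odd"
  expect_error(filter_genes(counts, bad, ann), "chromosome")
})

test_that("log-CP10K is cell-scaling invariant and Pearson residuals match hand values", {
  counts <- matrix(c(0L, 2L, 4L, 1L, 3L, 5L), nrow = 3,
                   dimnames = list(paste0("g", 1:3), c("c1", "c2")))
  norm <- normalize_counts(counts, "log_cp10k")
  expect_equal(norm[1, 1], 0)
  doubled <- counts; doubled[, 1] <- doubled[, 1] * 2L
  expect_equal(normalize_counts(doubled, "log_cp10k")[, 1], norm[, 1])
  # hand-computed Pearson residuals, theta = 100
  tot <- colSums(counts); sf <- tot / mean(tot)
  mu <- rowMeans(counts) %o% sf
  hand <- (counts - mu) / sqrt(mu + mu^2 / 100)
  clip <- sqrt(2)
  hand <- pmin(pmax(hand, -clip), clip)
  expect_equal(normalize_counts(counts, "pearson_residual"), hand)
  zero <- counts; zero[, 2] <- 0L
  expect_error(normalize_counts(zero), "zero total")
})

test_that("specificity rows are probability vectors with the exact ratios", {
  ann <- make_ann(c(A = 2L, B = 2L, C = 2L))
  x <- matrix(0, 3, 6, dimnames = list(paste0("g", 1:3), ann$cell_id))
  x[1, 1:2] <- 5                      # expressed only in A
  x[2, ] <- 4                         # equal everywhere
  x[3, ] <- rep(c(2, 1, 1), each = 2) # means 2,1,1
  spec <- specificity_matrix(x, ann)
  expect_equal(rowSums(spec), setNames(rep(1, 3), paste0("g", 1:3)))
  expect_equal(unname(spec["g1", ]), c(1, 0, 0))
  expect_equal(unname(spec["g2", ]), rep(1 / 3, 3))
  expect_equal(unname(spec["g3", ]), c(0.5, 0.25, 0.25))
  expect_error(specificity_matrix(x, make_ann(c(A = 6L))), "two cell types")
  # permuting cell order leaves the matrix unchanged
  perm <- sample(nrow(ann))
  expect_equal(specificity_matrix(x[, perm], ann[perm, ]), spec)
})

test_that("specificity is invariant to scaling one cell's counts (log-CP10K)", {
  fx <- fx_counts()
  ann <- filter_clusters(fx$ann)
  counts <- fx$counts[, ann$cell_id]
  s1 <- specificity_matrix(normalize_counts(counts), ann)
  counts[, 5] <- counts[, 5] * 3L
  s2 <- specificity_matrix(normalize_counts(counts), ann)
  expect_equal(s1, s2)
})

test_that("top-fraction sets rank correctly, break ties by gene id, respect biotype", {
  spec <- matrix(c(seq(0.99, 0.01, length.out = 99), 0.5), 100, 1,
                 dimnames = list(sprintf("g%03d", 1:100), "A"))
  spec <- cbind(spec, B = 1 - spec[, 1]); spec <- spec / rowSums(spec)
  top <- top_fraction_set(spec, "A", fraction = 0.1)
  expect_length(top, 10)
  expect_true(min(spec[top, "A"]) >= max(spec[setdiff(rownames(spec), top), "A"]))
  expect_error(top_fraction_set(spec, "A", n = 2000), "of only")
  expect_length(top_fraction_set(spec, "A", n = 2000, allow_short = TRUE), 100)
  expect_error(top_fraction_set(spec, "A", fraction = 1.5), "\\(0, 1\\]")
  # ties at the boundary: deterministic by ascending gene id
  tie <- matrix(0.5, 10, 2, dimnames = list(sprintf("t%02d", 10:1),
                                            c("A", "B")))
  expect_equal(top_fraction_set(tie, "A", fraction = 0.3),
               sprintf("t%02d", 1:3))
  # biotype filter applied before ranking
  genes <- data.frame(gene_id = rownames(spec),
                      biotype = rep(c("protein_coding", "noncoding"), 50))
  pc <- top_fraction_set(spec, "A", fraction = 0.1,
                         biotype_filter = "protein_coding", genes = genes)
  expect_length(pc, 5)
  expect_true(all(genes$biotype[match(pc, genes$gene_id)] == "protein_coding"))
})

test_that("jaccard index handles the standard cases", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard("a", "b"), 0)
  expect_equal(jaccard(c("1", "2", "3"), c("2", "3", "4")), 0.5)
  expect_equal(jaccard(character(0), character(0)), 0)
})
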