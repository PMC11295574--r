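toy_samples <- function(n, status = rep(0:1, n / 2), seed = 1) {
  withr::with_seed(seed, {
    s <- data.frame(sample_id = sprintf("S%04d", 1:n), status = status,
                    sex = sample(1:2, n, TRUE),
                    platform = sample(c("A", "B"), n, TRUE),
                    mean_depth = 40, ancestry_flag = FALSE,
                    syn_burden = rpois(n, 30), stringsAsFactors = FALSE)
    for (k in 1:10) s[[paste0("PC", k)]] <- rnorm(n)
    s
  })
}

test_that("sample QC removes relatives greedily, plus ancestry and low depth", {
  s <- toy_samples(6)
  s$ancestry_flag[5] <- TRUE
  s$mean_depth[6] <- 15
  kin <- data.frame(id1 = c("S0001", "S0002", "S0003"),
                    id2 = c("S0002", "S0003", "S0004"),
                    coef = c(0.2, 0.25, 0.2))
  out <- sample_qc(s, kin)
  # chain S1-S2, S2-S3, S3-S4: S2 and S3 have degree 2; S2 removed first
  # (tie broken by id), then S3-S4 remains so S3 goes too
  expect_false(any(c("S0002", "S0003") %in% out$sample_id))
  expect_true(all(c("S0001", "S0004") %in% out$sample_id))
  expect_false("S0005" %in% out$sample_id)  # ancestry flag
  expect_false("S0006" %in% out$sample_id)  # depth < 20
  # boundary: kinship exactly 0.177 keeps both; a simple chain loses only
  # the middle sample
  kin2 <- data.frame(id1 = "S0001", id2 = "S0002", coef = 0.177)
  expect_true(all(c("S0001", "S0002") %in% sample_qc(s[1:4, ], kin2)$sample_id))
  kin3 <- data.frame(id1 = c("S0001", "S0002"), id2 = c("S0002", "S0003"),
                     coef = 0.2)
  out3 <- sample_qc(s[1:4, ], kin3)
  expect_setequal(out3$sample_id, c("S0001", "S0003", "S0004"))
  # a single related pair loses exactly one member
  kin4 <- data.frame(id1 = "S0001", id2 = "S0003", coef = 0.2)
  expect_equal(nrow(sample_qc(s[1:4, ], kin4)), 3)
})

make_vt <- function(geno, dp = NULL, gq = NULL, ab = NULL,
                    consequence = rep("stop_gained", nrow(geno)),
                    in_ext = rep(FALSE, nrow(geno)),
                    vqsr = rep(TRUE, nrow(geno)),
                    lc = rep(FALSE, nrow(geno))) {
  m <- nrow(geno); n <- ncol(geno)
  if (is.null(dp)) dp <- matrix(50L, m, n)
  if (is.null(gq)) gq <- matrix(99L, m, n)
  if (is.null(ab)) {
    ab <- matrix(0.02, m, n)
    ab[geno == 1L] <- 0.5
    ab[geno == 2L] <- 0.98
  }
  dimnames(geno) <- list(sprintf("v%03d", 1:m), sprintf("S%04d", 1:n))
  structure(list(geno = geno, dp = dp, gq = gq, ab = ab,
                 info = data.frame(variant_id = rownames(geno),
                                   gene_id = sprintf("gene%02d", 1:m),
                                   consequence = consequence,
                                   in_external_ref = in_ext,
                                   vqsr_pass = vqsr, low_complexity = lc,
                                   stringsAsFactors = FALSE),
                 samples = toy_samples(n),
                 qc = list(genotype = FALSE, variant = FALSE)),
            class = "variant_table")
}

test_that("genotype QC applies every printed boundary, inclusively", {
  geno <- rbind(v1 = c(1L, 1L, 1L, 0L, 0L, 0L),
                v2 = c(2L, 2L, 1L, 1L, 0L, 2L))
  vt <- make_vt(geno)
  vt$dp[1, 1] <- 9L       # het, low depth: missing
  vt$gq[1, 2] <- 29L      # het, low GQ: missing
  vt$ab[1, 3] <- 0.25     # het at the inclusive lower boundary: kept
  vt$ab[1, 4] <- 0.10     # hom-ref at the boundary: kept
  vt$ab[1, 5] <- 0.11     # hom-ref above the boundary: missing
  vt$ab[2, 1] <- 0.90     # hom-alt at the boundary: kept
  vt$ab[2, 2] <- 0.89     # hom-alt below the boundary: missing
  vt$ab[2, 3] <- 0.76     # het above the band: missing
  vt$ab[2, 4] <- 0.75     # het at the inclusive upper boundary: kept
  out <- genotype_qc(vt)
  expect_true(is.na(out$geno[1, 1]))
  expect_true(is.na(out$geno[1, 2]))
  expect_false(is.na(out$geno[1, 3]))
  expect_false(is.na(out$geno[1, 4]))
  expect_true(is.na(out$geno[1, 5]))
  expect_false(is.na(out$geno[2, 1]))
  expect_true(is.na(out$geno[2, 2]))
  expect_true(is.na(out$geno[2, 3]))
  expect_false(is.na(out$geno[2, 4]))
  # idempotent
  expect_identical(genotype_qc(out)$geno, out$geno)
})

test_that("HWE exact test matches brute-force enumeration and normalizes", {
  expect_equal(hwe_exact(5, 0, 5), hwe_enum_oracle(5, 0, 5),
               tolerance = 1e-12)
  expect_equal(hwe_exact(10, 0, 0), 1)
  set.seed(41)
  for (i in 1:50) {
    n <- sample(3:50, 1)
    nab <- sample(0:n, 1)
    naa <- sample(0:(n - nab), 1)
    nbb <- n - nab - naa
    expect_equal(hwe_exact(naa, nab, nbb), hwe_enum_oracle(naa, nab, nbb),
                 tolerance = 1e-10,
                 label = sprintf("(%d,%d,%d)", naa, nab, nbb))
  }
})

test_that("variant QC removes exactly the rule violations, strict boundaries", {
  n <- 200
  geno <- rbind(clean = rep(c(0L, 1L), c(n - 2, 2)),
                vqsr = rep(c(0L, 1L), c(n - 1, 1)),
                lc = rep(c(0L, 1L), c(n - 1, 1)),
                lowcall = rep(c(0L, 1L), c(n - 1, 1)),
                hwe = rep(c(0L, 1L), c(0.4 * n, 0.6 * n)))
  vt <- make_vt(geno, vqsr = c(TRUE, FALSE, TRUE, TRUE, TRUE),
                lc = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  vt$dp[4, 1:30] <- 5L  # call rate 0.85 after genotype QC
  vt <- genotype_qc(vt)
  out <- variant_qc(vt)
  expect_setequal(out$info$variant_id, c("v001"))
  expect_error(variant_qc(make_vt(geno)), "genotype_qc")
  # boundary: call rate exactly 0.9 is kept
  vt2 <- make_vt(matrix(rep(c(0L, 1L), c(18, 2)), 1, 20))
  vt2$dp[1, 1:2] <- 5L  # call rate exactly 0.9
  out2 <- variant_qc(genotype_qc(vt2))
  expect_equal(nrow(out2$info), 1)
  # variant QC is idempotent
  expect_identical(variant_qc(out)$info, out$info)
})

test_that("singleton PTV definition applies class, carrier and reference rules", {
  n <- 50
  geno <- rbind(single_ptv = rep(c(1L, 0L), c(1, n - 1)),
                two_carriers = rep(c(1L, 0L), c(2, n - 2)),
                missense = rep(c(1L, 0L), c(1, n - 1)),
                in_ext = rep(c(1L, 0L), c(1, n - 1)),
                homalt = c(2L, rep(0L, n - 1)),
                splice = c(0L, 1L, rep(0L, n - 2)))
  vt <- make_vt(geno,
                consequence = c("stop_gained", "splice_donor", "missense",
                                "frameshift", "stop_gained", "splice_acceptor"),
                in_ext = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  vt <- variant_qc(genotype_qc(vt))
  qual <- define_ptv_singletons(vt)
  expect_setequal(qual, c("v001", "v006"))
  expect_error(define_ptv_singletons(genotype_qc(make_vt(geno))),
               "variant_qc")
})

test_that("Firth estimates match the 0.5-corrected log odds ratio on 2x2 tables", {
  set.seed(43)
  for (i in 1:10) {
    cells <- sample(1:20, 4, replace = TRUE)  # a, b, c, d
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    y <- rep(c(1, 1, 0, 0), c(a, b, c, d))
    x <- rep(c(1, 0, 1, 0), c(a, b, c, d))
    fit <- firth_logistic(y, cbind(1, x = x), tol = 1e-10)
    closed <- log((a + 0.5) * (d + 0.5) / ((b + 0.5) * (c + 0.5)))
    expect_equal(unname(fit$coef["x"]), closed, tolerance = 1e-8)
  }
})

test_that("Firth stays finite under separation; zero penalty reproduces the MLE", {
  y <- rep(c(0, 1), each = 12)
  x <- rep(c(0, 1), each = 12)
  fit <- firth_logistic(y, cbind(1, x = x))
  expect_true(all(is.finite(fit$coef)))
  # well-separated (non-degenerate) data: penalty 0 equals glm's MLE
  set.seed(44)
  n <- 300
  x2 <- rnorm(n)
  y2 <- rbinom(n, 1, plogis(0.3 + 0.8 * x2))
  f0 <- firth_logistic(y2, cbind(1, x = x2), penalty = 0)
  g <- glm(y2 ~ x2, family = binomial)
  expect_lt(max(abs(f0$coef - coef(g))), 1e-4)
  expect_error(firth_logistic(rep(1, 10), cbind(1, rnorm(10))),
               "one case and one control")
  expect_error(firth_logistic(y2, cbind(1, x2, x2)), "rank deficient")
})

test_that("Firth null rejections with covariates are calibrated", {
  rej <- vapply(1:500, function(i) {
    withr::with_seed(8000 + i, {
      n <- 120
      x <- rbinom(n, 1, 0.2)
      covar <- rnorm(n)
      y <- rbinom(n, 1, plogis(-0.5 + 0.4 * covar))
      fit <- firth_logistic(y, cbind(1, x = x, covar))
      pnorm(fit$coef["x"] / fit$se["x"], lower.tail = FALSE) < 0.05
    })
  }, NA)
  expect_lt(abs(mean(rej) - 0.05), 2.576 * sqrt(0.05 * 0.95 / 500))
})

test_that("burden pipeline enforces order and recovers the planted odds ratio", {
  fx <- fx_counts()
  cfg <- sim_config(seed = 51, n_cases = 2000, n_controls = 2000,
                    planted_burden_or = 3)
  vt <- gen_rare_variants(cfg, fx$genes, fx$truth)
  expect_error(variant_qc(vt), "genotype_qc")
  expect_error(burden_test(vt, "v", fx$truth$burden_genes), "variant_qc")
  vt <- variant_qc(genotype_qc(vt))
  qual <- define_ptv_singletons(vt)
  res <- burden_test(vt, qual, fx$truth$burden_genes)
  expect_lt(abs(res$or - 3) / 3, 0.5)
  expect_lt(res$p, 0.05)
  expect_error(burden_test(vt, qual, "absent_gene"), "zero total burden")
  # background covariate collinear with the tested set
  coding <- fx$genes$gene_id[fx$genes$biotype == "protein_coding"]
  expect_error(burden_test(vt, qual, coding,
                           background_covariate = "all_expressed",
                           expressed_genes = coding), "rank deficient")
})

test_that("null burden test keeps type-I error near nominal", {
  fx <- fx_counts()
  rej <- vapply(1:500, function(i) {
    cfg <- sim_config(seed = 9000 + i, n_cases = 150, n_controls = 150,
                      planted_burden_or = 1)
    vt <- variant_qc(genotype_qc(gen_rare_variants(cfg, fx$genes, fx$truth)))
    qual <- define_ptv_singletons(vt)
    res <- burden_test(vt, qual, fx$truth$burden_genes)
    res$p < 0.05
  }, NA)
  expect_lte(mean(rej), 0.075)
})
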