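#' Simulation configuration for the synthetic-data generators
#'
#' Bundles every knob the generators use, with defaults that define the
#' standing study conditions for the package's own test-bed: a desk-scale
#' analogue of a developmental cortex snRNA-seq atlas (a few hundred genes,
#' a handful of cell populations plus two deliberately tiny clusters), a
#' 20,000-SNP GWAS with block-diagonal AR(1) LD and a 500-individual
#' reference panel (about the size of the European subset of a public
#' reference panel), and a rare-variant case-control sample.
#'
#' @param seed integer seed; every generator draws from a generator seeded
#'   deterministically from this value, never from global RNG state.
#' @param n_genes number of genes in the gene-model table.
#' @param n_cell_types number of regular cell populations (two extra tiny
#'   clusters of 7 and 3 cells are always added by [gen_counts()]).
#' @param cells_per_type cells per regular population.
#' @param n_donors donors, assigned round-robin to cells.
#' @param marker_fraction fraction of genes planted as markers per type.
#' @param marker_fold fold-change (>= 1) applied to a marker gene's mean in
#'   its own type.
#' @param nb_dispersion negative-binomial size parameter (larger = closer to
#'   Poisson).
#' @param n_snps,n_ld_blocks,ld_rho GWAS panel geometry: SNP count, number of
#'   contiguous LD blocks, and AR(1) within-block correlation in [0, 1).
#' @param panel_n reference-panel individuals (two haplotypes each).
#' @param gwas_n GWAS sample size written into the summary statistics.
#' @param planted_set_effect per-SNP chi-square inflation (>= 0) added to
#'   SNPs inside the planted enriched gene set.
#' @param n_cases,n_controls target case/control counts for the rare-variant
#'   simulation (realized counts are binomial around these).
#' @param planted_burden_or odds ratio (>= 1) linking carried planted PTVs to
#'   case status through a logistic model.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 400L,
                       n_cell_types = 8L,
                       cells_per_type = 80L,
                       n_donors = 6L,
                       marker_fraction = 0.08,
                       marker_fold = 8,
                       nb_dispersion = 2,
                       n_snps = 20000L,
                       n_ld_blocks = 200L,
                       ld_rho = 0.6,
                       panel_n = 500L,
                       gwas_n = 50000L,
                       planted_set_effect = 0,
                       n_cases = 500L,
                       n_controls = 500L,
                       planted_burden_or = 1) {
  for (nm in c("seed", "n_genes", "n_cell_types", "cells_per_type",
               "n_donors", "n_snps", "n_ld_blocks", "panel_n", "gwas_n",
               "n_cases", "n_controls")) {
    assert_count(get(nm), nm)
  }
  assert_fraction(marker_fraction, "marker_fraction")
  if (!is.numeric(marker_fold) || marker_fold < 1)
    stop("configuration error: 'marker_fold' must be >= 1", call. = FALSE)
  if (!is.numeric(nb_dispersion) || nb_dispersion <= 0)
    stop("configuration error: 'nb_dispersion' must be > 0", call. = FALSE)
  if (!is.numeric(ld_rho) || ld_rho < 0 || ld_rho >= 1)
    stop("configuration error: 'ld_rho' must lie in [0, 1)", call. = FALSE)
  if (!is.numeric(planted_set_effect) || planted_set_effect < 0)
    stop("configuration error: 'planted_set_effect' must be >= 0",
         call. = FALSE)
  if (!is.numeric(planted_burden_or) || planted_burden_or < 1)
    stop("configuration error: 'planted_burden_or' must be >= 1",
         call. = FALSE)
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_cell_types = as.integer(n_cell_types),
              cells_per_type = as.integer(cells_per_type),
              n_donors = as.integer(n_donors),
              marker_fraction = marker_fraction, marker_fold = marker_fold,
              nb_dispersion = nb_dispersion, n_snps = as.integer(n_snps),
              n_ld_blocks = as.integer(n_ld_blocks), ld_rho = ld_rho,
              panel_n = as.integer(panel_n), gwas_n = as.integer(gwas_n),
              planted_set_effect = planted_set_effect,
              n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls),
              planted_burden_or = planted_burden_or)
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a gene-model table
#'
#' Places non-overlapping gene intervals (1-based, inclusive) on chr1 and
#' chr2, plus a few genes on chrX and a few inside the extended MHC window
#' chr6:25,000,000-35,000,000 so that the autosome and MHC filters are always
#' exercised. Each gene is tagged `protein_coding` or `noncoding` and given a
#' strand.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns gene_id, chr, start, end, strand, biotype.
#' @export
gen_gene_models <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  if (n < 10) stop("configuration error: need n_genes >= 10", call. = FALSE)
  with_seed(config$seed + 11L, {
    n_x <- max(2L, round(0.02 * n))
    n_mhc <- max(2L, round(0.02 * n))
    n_auto <- n - n_x - n_mhc
    n_chr1 <- ceiling(n_auto / 2)
    n_chr2 <- n_auto - n_chr1

    place <- function(chr, k, origin, max_gap = 1.2e5) {
      len <- round(runif(k, 5e3, 5e4))
      gap <- round(runif(k, 3e4, max_gap))
      start <- origin + cumsum(gap) + c(0, cumsum(len[-k]))
      data.frame(chr = chr, start = start, end = start + len - 1,
                 stringsAsFactors = FALSE)
    }
    tab <- rbind(place("chr1", n_chr1, 1e6),
                 place("chr2", n_chr2, 1e6),
                 place("chr6", n_mhc, 25.4e6, max_gap = 6e4),
                 place("chrX", n_x, 1e6))
    if (any(tab$chr == "chr6" & tab$end > 35e6))
      stop("internal error: MHC genes spilled past 35 Mb")
    tab$gene_id <- sprintf("G%05d", seq_len(n))
    tab$strand <- sample(c("+", "-"), n, replace = TRUE)
    tab$biotype <- sample(c("protein_coding", "noncoding"), n,
                          replace = TRUE, prob = c(0.75, 0.25))
    tab[, c("gene_id", "chr", "start", "end", "strand", "biotype")]
  })
}

#' Generate clustered negative-binomial counts with planted markers
#'
#' Gene baseline means are log-normal; each regular cell type gets a disjoint
#' block of `marker_fraction * n_genes` marker genes whose mean is multiplied
#' by `marker_fold` in that type only. Two tiny clusters (7 and 3 cells, no
#' planted markers) are appended so cluster-size filtering is exercised.
#' Donors are assigned round-robin and carry a developmental-stage label.
#'
#' Also fixes the rest of the planted ground truth used downstream: the
#' GWAS-enriched gene set (the first cell type's marker genes, so the planted
#' population is recoverable by the full scan) and a burden gene set (random
#' autosomal protein-coding genes, for the rare-variant generator).
#'
#' @param config a [sim_config()].
#' @param genes gene-model table from [gen_gene_models()].
#' @return list with `counts` (genes x cells integer matrix), `ann`
#'   (cell annotation data.frame: cell_id, cluster, donor, stage) and
#'   `truth` (marker_genes, enriched_gene_set, burden_genes).
#' @export
gen_counts <- function(config, genes) {
  stopifnot(inherits(config, "sim_config"))
  n_genes <- config$n_genes
  k <- config$n_cell_types
  n_mark <- max(1L, round(config$marker_fraction * n_genes))
  if (k * n_mark > n_genes)
    stop("configuration error: marker blocks exceed the gene count",
         call. = FALSE)
  with_seed(config$seed + 13L, {
    types <- sprintf("CT%02d", seq_len(k))
    tiny <- c(TinyA = 7L, TinyB = 3L)
    sizes <- c(setNames(rep(config$cells_per_type, k), types), tiny)
    cluster <- rep(names(sizes), sizes)
    n_cells <- length(cluster)
    cell_id <- sprintf("cell%05d", seq_len(n_cells))

    base_mu <- exp(rnorm(n_genes, log(0.5), 1))
    marker_genes <- lapply(seq_len(k), function(i) {
      genes$gene_id[((i - 1) * n_mark + 1):(i * n_mark)]
    })
    names(marker_genes) <- types

    mu <- matrix(base_mu, n_genes, length(sizes))
    colnames(mu) <- names(sizes)
    for (t in types) {
      idx <- match(marker_genes[[t]], genes$gene_id)
      mu[idx, t] <- mu[idx, t] * config$marker_fold
    }
    counts <- matrix(0L, n_genes, n_cells,
                     dimnames = list(genes$gene_id, cell_id))
    for (cl in names(sizes)) {
      cols <- which(cluster == cl)
      counts[, cols] <- rnbinom(n_genes * length(cols),
                                mu = mu[, cl], size = config$nb_dispersion)
    }

    donor <- sprintf("D%02d", (seq_len(n_cells) - 1L) %% config$n_donors + 1L)
    stages <- c("fetal", "neonatal", "infancy", "childhood", "adolescence",
                "adult")
    donor_stage <- setNames(
      stages[(seq_len(config$n_donors) - 1L) %% length(stages) + 1L],
      sprintf("D%02d", seq_len(config$n_donors)))
    ann <- data.frame(cell_id = cell_id, cluster = cluster, donor = donor,
                      stage = donor_stage[donor], stringsAsFactors = FALSE,
                      row.names = NULL)

    autosomal <- genes$gene_id[genes$chr %in% autosome_labels() &
                                 !(genes$chr == "chr6" &
                                     genes$start <= 35e6 & genes$end >= 25e6)]
    # the planted GWAS-enriched set is the first cell type's marker genes,
    # so the planted population is recoverable by the full scan
    enriched <- sort(intersect(marker_genes[[1]], autosomal))
    coding <- genes$gene_id[genes$biotype == "protein_coding" &
                              genes$gene_id %in% autosomal]
    burden <- sort(sample(coding, min(30L, length(coding))))
    truth <- list(marker_genes = marker_genes,
                  enriched_gene_set = enriched,
                  burden_genes = burden)
    list(counts = counts, ann = ann, truth = truth)
  })
}

# binary Markov-chain haplotypes: stationary MAF p, adjacent-allele
# correlation rho, so genotype dosages have correlation rho^|i-j| exactly
markov_haplotypes <- function(n_hap, m, p, rho) {
  h <- matrix(0L, n_hap, m)
  h[, 1] <- rbinom(n_hap, 1L, p)
  if (m > 1) {
    for (j in 2:m) {
      pr <- ifelse(h[, j - 1] == 1L, p + rho * (1 - p), p * (1 - rho))
      h[, j] <- rbinom(n_hap, 1L, pr)
    }
  }
  h
}

# AR(1) Gaussian noise within a block (exact stationary construction)
ar1_noise <- function(m, rho) {
  e <- numeric(m)
  e[1] <- rnorm(1)
  if (m > 1) {
    innov <- rnorm(m - 1, sd = sqrt(1 - rho^2))
    for (j in 2:m) e[j] <- rho * e[j - 1] + innov[j - 1]
  }
  e
}

#' Generate an LD reference panel and GWAS summary statistics
#'
#' SNPs are laid down uniformly across the gene-bearing autosomes and grouped
#' into contiguous LD blocks; panel haplotypes are binary Markov chains so
#' that dosage correlation decays exactly as `ld_rho^distance` within a block
#' and is zero across blocks. GWAS z-scores are drawn multivariate normal
#' with the same block correlation; SNPs falling inside genes of the planted
#' enriched set receive a mean shift of size `sqrt(planted_set_effect)`
#' (random sign), inflating their expected chi-square by exactly
#' `planted_set_effect`.
#'
#' @param config a [sim_config()].
#' @param genes gene-model table.
#' @param truth truth list from [gen_counts()] (uses `enriched_gene_set`).
#' @return list with `panel` (class `reference_panel`: `genotypes`
#'   individuals x SNPs dosage matrix, `snps` metadata with cM positions) and
#'   `sumstats` (data.frame SNP, CHR, BP, A1, A2, P, N).
#' @export
gen_panel_and_sumstats <- function(config, genes, truth) {
  stopifnot(inherits(config, "sim_config"))
  if (config$ld_rho >= 1)
    stop("configuration error: ld_rho must be < 1", call. = FALSE)
  with_seed(config$seed + 23L, {
    chroms <- c("chr1", "chr2")
    g <- genes[genes$chr %in% chroms, ]
    span <- do.call(rbind, lapply(chroms, function(ch) {
      gg <- g[g$chr == ch, ]
      data.frame(chr = ch, lo = max(1, min(gg$start) - 5e4),
                 hi = max(gg$end) + 5e4)
    }))
    span$len <- span$hi - span$lo
    n_by_chr <- round(config$n_snps * span$len / sum(span$len))
    n_by_chr[1] <- config$n_snps - sum(n_by_chr[-1])

    rho <- config$ld_rho
    block_size <- max(2L, ceiling(config$n_snps / config$n_ld_blocks))
    snp_meta <- list()
    geno <- matrix(0L, config$panel_n, config$n_snps)
    z <- numeric(config$n_snps)
    offset <- 0L
    for (i in seq_along(chroms)) {
      m <- n_by_chr[i]
      bp <- sort(round(runif(m, span$lo[i], span$hi[i])))
      bp <- bp + seq_len(m)  # break ties, keep sorted
      block <- (seq_len(m) - 1L) %/% block_size + 1L
      for (b in unique(block)) {
        idx <- which(block == b)
        p <- runif(1, 0.1, 0.5)
        hap <- markov_haplotypes(2L * config$panel_n, length(idx), p, rho)
        geno[, offset + idx] <-
          hap[seq_len(config$panel_n), , drop = FALSE] +
          hap[config$panel_n + seq_len(config$panel_n), , drop = FALSE]
        z[offset + idx] <- ar1_noise(length(idx), rho)
      }
      snp_meta[[i]] <- data.frame(chr = chroms[i], bp = bp,
                                  block = paste0(chroms[i], "_", block),
                                  stringsAsFactors = FALSE)
      offset <- offset + m
    }
    snps <- do.call(rbind, snp_meta)
    snps$snp <- sprintf("rs%06d", seq_len(nrow(snps)))
    snps$cm <- snps$bp * 1e-6  # genetic map: 1 cM per Mb
    alle <- c("A", "C", "G", "T")
    snps$a1 <- sample(alle, nrow(snps), replace = TRUE)
    snps$a2 <- vapply(snps$a1, function(a) sample(setdiff(alle, a), 1), "")

    # plant the enriched-set signal
    if (config$planted_set_effect > 0) {
      eg <- genes[genes$gene_id %in% truth$enriched_gene_set, ]
      hit <- overlaps_any(snps$chr, snps$bp, snps$bp,
                          eg$chr, eg$start, eg$end)
      mu <- sqrt(config$planted_set_effect) *
        sample(c(-1, 1), sum(hit), replace = TRUE)
      z[hit] <- z[hit] + mu
    }
    p <- pmax(2 * pnorm(-abs(z)), .Machine$double.xmin)

    panel <- structure(
      list(genotypes = geno,
           snps = snps[, c("snp", "chr", "bp", "cm", "a1", "a2", "block")]),
      class = "reference_panel")
    sumstats <- data.frame(SNP = snps$snp, CHR = snps$chr, BP = snps$bp,
                           A1 = snps$a1, A2 = snps$a2, P = p,
                           N = config$gwas_n, stringsAsFactors = FALSE)
    list(panel = panel, sumstats = sumstats)
  })
}

#' Generate a developmental trajectory with trait-linked expression drift
#'
#' Cells receive pseudotime values equally spaced in [0, 1], strictly
#' increasing with cell index. Each gene's log mean increases linearly with
#' pseudotime at rate `slope * w_g`, where `w_g` is the gene's standardized
#' association z-score, so with `slope = 0` expression carries no trait
#' information and with a large slope trait-associated genes drift upward
#' along the trajectory. Counts are Poisson.
#'
#' @param config a [sim_config()].
#' @param gene_z data.frame with columns `gene_id` and `z` (>= 50 genes).
#' @param n_cells cells along the trajectory.
#' @param slope drift rate (0 = null).
#' @return list with `counts` (genes x cells), `pseudotime` (true values, in
#'   [0,1]), and `ann` (cell_id, donor).
#' @export
gen_trajectory <- function(config, gene_z, n_cells = 300L, slope = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(gene_z) < 50)
    stop("need gene-level statistics for >= 50 genes", call. = FALSE)
  with_seed(config$seed + 37L, {
    n_genes <- nrow(gene_z)
    tt <- seq(0, 1, length.out = n_cells)
    w <- as.numeric(scale(gene_z$z))
    base <- rnorm(n_genes, log(2), 0.5)
    logmu <- outer(w, tt) * slope + base
    counts <- matrix(rpois(length(logmu), exp(logmu)), n_genes, n_cells,
                     dimnames = list(gene_z$gene_id,
                                     sprintf("tcell%04d", seq_len(n_cells))))
    ann <- data.frame(
      cell_id = colnames(counts),
      donor = sprintf("D%02d", (seq_len(n_cells) - 1L) %% config$n_donors + 1L),
      stringsAsFactors = FALSE)
    list(counts = counts, pseudotime = tt, ann = ann)
  })
}

#' Generate case-control rare-variant genotypes with a planted PTV burden
#'
#' Plants singleton protein-truncating variants (PTVs) in the truth's burden
#' genes and an equal number in other protein-coding genes, plus common
#' synonymous/missense variants and one deliberate violation of each QC rule
#' (VQSR fail, low call rate, Hardy-Weinberg failure, low-complexity flag,
#' genotypes with low DP/GQ/bad allele balance, an external-reference-present
#' singleton, and a two-carrier PTV). Case status is then drawn from a
#' logistic model whose log-odds increase by `log(planted_burden_or)` per
#' carried planted PTV, so the Firth burden estimate has a well-defined
#' target.
#'
#' @param config a [sim_config()].
#' @param genes gene-model table.
#' @param truth truth list from [gen_counts()] (uses `burden_genes`).
#' @return a `variant_table`: list with matrices `geno` (0/1/2/NA), `dp`,
#'   `gq`, `ab` (variants x samples), `info` (per-variant metadata), and
#'   `samples` (covariates and case status).
#' @export
gen_rare_variants <- function(config, genes, truth) {
  stopifnot(inherits(config, "sim_config"))
  if (config$planted_burden_or < 1)
    stop("configuration error: planted_burden_or must be >= 1", call. = FALSE)
  with_seed(config$seed + 41L, {
    n <- config$n_cases + config$n_controls
    sample_id <- sprintf("S%05d", seq_len(n))
    ptv_classes <- c("stop_gained", "frameshift", "splice_donor",
                     "splice_acceptor")
    coding <- genes[genes$biotype == "protein_coding", ]
    other_genes <- setdiff(coding$gene_id, truth$burden_genes)

    n_planted <- max(20L, round(0.06 * n))
    n_null <- n_planted

    new_variant <- function(gene_id, consequence, carriers, geno_codes,
                            in_ext = FALSE, vqsr = TRUE, lc = FALSE) {
      g <- integer(n)
      g[carriers] <- geno_codes
      list(gene_id = gene_id, consequence = consequence, geno = g,
           in_external_ref = in_ext, vqsr_pass = vqsr, low_complexity = lc)
    }
    vars <- list()
    # planted singleton PTVs in burden genes
    planted_carriers <- sample(n, n_planted, replace = TRUE)
    for (i in seq_len(n_planted)) {
      vars[[length(vars) + 1L]] <- new_variant(
        sample(truth$burden_genes, 1), sample(ptv_classes, 1),
        planted_carriers[i], 1L)
    }
    n_true_ptv <- length(vars)
    # null singleton PTVs elsewhere
    for (i in seq_len(n_null)) {
      vars[[length(vars) + 1L]] <- new_variant(
        sample(other_genes, 1), sample(ptv_classes, 1), sample(n, 1), 1L)
    }
    # common synonymous / missense background
    for (i in seq_len(100L)) {
      af <- runif(1, 0.002, 0.02)
      g <- rbinom(n, 2L, af)
      v <- new_variant(sample(coding$gene_id, 1),
                       sample(c("synonymous", "missense"), 1),
                       which(g > 0), g[g > 0])
      vars[[length(vars) + 1L]] <- v
    }
    # deliberate QC violations
    vars[[length(vars) + 1L]] <- new_variant(
      sample(other_genes, 1), "stop_gained", sample(n, 1), 1L, vqsr = FALSE)
    vars[[length(vars) + 1L]] <- new_variant(
      sample(other_genes, 1), "frameshift", sample(n, 1), 1L, lc = TRUE)
    i_callrate <- length(vars) + 1L
    vars[[i_callrate]] <- new_variant(
      sample(other_genes, 1), "missense", sample(n, 1), 1L)
    i_hwe <- length(vars) + 1L  # gross heterozygote excess
    vars[[i_hwe]] <- new_variant(
      sample(other_genes, 1), "synonymous",
      sample(n, floor(n / 2)), 1L)
    vars[[length(vars) + 1L]] <- new_variant(  # present in external reference
      sample(truth$burden_genes, 1), "stop_gained", sample(n, 1), 1L,
      in_ext = TRUE)
    vars[[length(vars) + 1L]] <- new_variant(  # two carriers: not a singleton
      sample(other_genes, 1), "splice_donor", sample(n, 2), c(1L, 1L))

    m <- length(vars)
    geno <- do.call(rbind, lapply(vars, `[[`, "geno"))
    dp <- matrix(50L + rbinom(m * n, 30L, 0.5) - 15L, m, n)
    gq <- matrix(99L, m, n)
    ab <- matrix(runif(m * n, 0, 0.05), m, n)
    ab[geno == 1L] <- runif(sum(geno == 1L), 0.35, 0.65)
    ab[geno == 2L] <- runif(sum(geno == 2L), 0.95, 1)
    # low-call-rate variant: 15% of genotypes fall below the depth cutoff
    dp[i_callrate, sample(n, ceiling(0.15 * n))] <- 5L
    # one genotype violating each genotype-QC rule on an otherwise clean variant
    het_pos <- which(geno[1, ] == 1L)[1]
    gq[2, 1] <- 10L            # low GQ
    ab[3, 1] <- 0.15           # hom-ref with bad allele balance
    if (!is.na(het_pos)) ab[1, het_pos] <- ab[1, het_pos]  # keep planted clean

    info <- data.frame(
      variant_id = sprintf("var%05d", seq_len(m)),
      gene_id = vapply(vars, `[[`, "", "gene_id"),
      consequence = vapply(vars, `[[`, "", "consequence"),
      in_external_ref = vapply(vars, `[[`, NA, "in_external_ref"),
      vqsr_pass = vapply(vars, `[[`, NA, "vqsr_pass"),
      low_complexity = vapply(vars, `[[`, NA, "low_complexity"),
      stringsAsFactors = FALSE)
    gpos <- match(info$gene_id, genes$gene_id)
    info$chr <- genes$chr[gpos]
    info$pos <- genes$start[gpos] +
      sample.int(1000L, m, replace = TRUE)
    info$ref <- "A"
    info$alt <- "T"
    dimnames(geno) <- list(info$variant_id, sample_id)

    # case status from a logistic model on true planted-PTV carrier counts
    carrier_count <- colSums(geno[seq_len(n_true_ptv), , drop = FALSE] == 1L)
    eta <- qlogis(config$n_cases / n) +
      log(config$planted_burden_or) * carrier_count
    status <- rbinom(n, 1L, plogis(eta))

    samples <- data.frame(sample_id = sample_id, status = status,
                          sex = sample(1:2, n, replace = TRUE),
                          platform = sample(c("A", "B"), n, replace = TRUE),
                          mean_depth = rnorm(n, 40, 4),
                          ancestry_flag = FALSE,
                          syn_burden = rpois(n, 30),
                          stringsAsFactors = FALSE)
    for (k in 1:10) samples[[paste0("PC", k)]] <- rnorm(n)

    structure(list(geno = geno, dp = dp, gq = gq, ab = ab, info = info,
                   samples = samples,
                   qc = list(genotype = FALSE, variant = FALSE)),
              class = "variant_table")
  })
}
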