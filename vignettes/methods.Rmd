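---
title: "Methods: linking cell populations to genetic liability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking cell populations to genetic liability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`celltrait` asks which cell populations of a tissue are likely to mediate
genetic liability to a trait. It combines single-nuclei RNA-seq expression
specificity with GWAS summary statistics and rare-variant case-control data,
and ships a synthetic-data module that generates every input with planted
ground truth so the whole pipeline can be exercised and tested offline. This
vignette describes the models, the tunable parameters, the numerical choices,
and what the synthetic test-bed does and does not establish about real data.

## Expression specificity

For gene $g$ and cell type $c$, the specificity score is

$$ s_{g,c} = \frac{\bar{x}_{g,c}}{\sum_{c'} \bar{x}_{g,c'}}, $$

where $\bar{x}_{g,c}$ is the gene's mean normalized expression in type $c$.
Each retained gene's row is a probability vector over cell types; a gene
expressed in only one type scores 1 there, a uniformly expressed gene scores
$1/K$ everywhere. Before scoring we remove:

* clusters with fewer than `min_cells` cells (default 10 — small clusters
  cannot give representative mean expression; in the motivating dataset the
  two removed oligodendrocyte clusters had 7 and 3 cells, and 10 is the
  smallest round threshold excluding both);
* non-autosomal genes (sex-linked expression tracks donor sex, not cell
  identity);
* genes overlapping the extended MHC region, chr6:25,000,000–35,000,000
  (hg19), treated as a closed interval with *any* base overlap excluding the
  gene — its extreme LD makes downstream SNP-based enrichment uninterpretable;
* genes expressed in fewer than `min_cells_expressing` cells (default 10);
* uninformative genes, operationalized as a one-way variance test of
  normalized expression across cell types with Benjamini–Hochberg adjusted
  $p > 0.05$. Between-type sums of squares below $10^{-10}$ of the gene's
  total scale are treated as exactly flat, so a constant gene is always
  removed regardless of floating-point dust.

Normalization is log-CP10K by default, $\ln(1 + 10^4 x / \text{total})$,
which is invariant to scaling any cell's counts (so sequencing depth cancels
out of the specificity ratio). A Pearson-residual option
$(x-\mu)/\sqrt{\mu + \mu^2/\theta}$ with fixed $\theta = 100$ and clipping at
$\pm\sqrt{n_\text{cells}}$ is provided as a deterministic, dependency-light
approximation to regularized negative-binomial normalization; we chose not to
re-fit a regularized NB per gene because the specificity ratio depends only
on relative means, which both normalizations preserve.

Top-specificity gene sets take the top decile (`fraction = 0.1`, set size
$\lceil 0.1\,n \rceil$) or a fixed top-$N$ (e.g. 2000) per cell type, with
ties broken by ascending gene identifier so sets are deterministic, and an
optional biotype filter (protein-coding / noncoding) applied before ranking.
Requesting a top-$N$ larger than the ranked list is an error by default
rather than a silent truncation.

## Gene-level association: the SNP-wise mean model

SNP $p$-values are converted to 1-df chi-squares
$q_i = \Phi^{-1}(1-p_i/2)^2$ and averaged over all SNPs whose position falls
in the gene's window (closed intervals; a SNP may belong to several genes).
Windows extend gene bodies 35 kb upstream and 10 kb downstream,
strand-aware: whether the original analyses applied the extension by strand
is not documented, so strand-awareness is the default and configurable.

Under the null, $m \bar{q} \sim \sum_j \lambda_j \chi^2_1$ where $\lambda_j$
are the eigenvalues of the SNP correlation matrix $R$ estimated from the
reference panel. We compute the tail of this quadratic form by Imhof's
characteristic-function inversion. Because naive quadrature of the
oscillatory inversion integral is unreliable for small SNP counts, the
implementation integrates between successive zeros of the oscillating factor
(the phase function is unimodal, so the zeros are simple roots found by
bisection) and sums the resulting alternating series with repeated-averaging
acceleration. Against an independent quadrature oracle this is accurate to
about $10^{-14}$ absolute; values below $10^{-12}$ are reported at the
two-moment (Satterthwaite) magnitude, which slightly compresses extreme gene
z-scores but cannot affect calibration. Equal eigenvalues (independent SNPs)
are detected and evaluated by the exact scaled-chi-square tail, so with
$R = I$ the gene $p$ equals the $\chi^2_m$ tail to machine precision.
Eigenvalues below $10^{-10}$ are truncated to zero; monomorphic panel SNPs
get zero correlation with a warning. The gene z-score is the upper-tail
probit of the gene $p$.

## Competitive gene-set enrichment

Gene z-scores are regressed on a set-membership indicator plus technical
covariates (default: log window length and log SNP count), and the
membership coefficient is tested one-tailed for a *greater* set mean. Gene–
gene correlation induced by LD between neighboring gene windows is **not**
modeled in this regression; the output's `model` field says so. On the
synthetic test-bed this approximation is calibrated (type-I error within
binomial bounds of nominal over 500 simulations), but on real data with
dense gene clusters it can be anticonservative — results should be read as
they are in practice: as a ranking device with Bonferroni-corrected
thresholds, corroborated by the independent heritability-partitioning route.
Degenerate designs (constant z, collinear covariates) return $\beta = 0$,
$p = 0.5$ with a flag rather than an error, so scans over many cell types
never abort on one pathological set.

GO-style over-representation uses the one-sided hypergeometric tail with BH
adjustment across terms, against a background of all genes detected in the
cell population. The intersection analysis re-tests, for the top `top_k`
(default 20) over-represented terms, the genes of the top-specificity decile
that also carry the term, with the Bonferroni threshold $0.05/k$ attached;
intersections under 2 genes are flagged untestable rather than tested.

## Stratified LD-score regression

Per-SNP, per-annotation LD scores are
$\ell(j,c) = \sum_k a_{kc}\,\tilde{r}^2_{jk}$ over SNPs within 1 cM, with
the bias-corrected $\tilde{r}^2 = r^2 - (1-r^2)/(n-2)$ so SNPs in linkage
equilibrium contribute zero in expectation. The synthetic genetic map is
1 cM/Mb. The heritability regression fits per-SNP chi-square on
$N\,\ell(j,\cdot)$ across annotations with an intercept, using
heteroskedasticity weights $1/(\ell_\text{base} \cdot 2(1 + N \hat\tau_\text{base}
\ell_\text{base})^2)$ from an unweighted first pass; exact weighting
conventions differ between published versions of the method and none is
pinned by our sources, so the two-pass scheme is documented here and fixed.
Annotation coefficients get delete-one block-jackknife standard errors over
`n_blocks` contiguous SNP blocks (default 200, the conventional count; block
sufficient statistics make the jackknife $O(Bk^2)$), and one-tailed normal
$p$-values for $\tau > 0$. Duplicated (rank-deficient) annotation designs
are an error, never a silent fit. The real 53-annotation baseline model is
consumed as an input file, not bundled; synthetic runs condition on a
generated baseline, preserving the joint-fit structure without downloads.

## Per-cell trait scores and trajectory regression

For each cell, gene-level association statistics are regressed on that
cell's log-normalized expression with the gene's dataset-average expression
as a covariate; the cell's score is the t-statistic of the expression
coefficient. We regress the gene **z-score** rather than the raw $p$ or
$-\log_{10} p$ (selectable), because the z-scale best matches the linear
model's residual assumptions; our sources do not print which scale was used.
All genes passing the trajectory filter enter every cell's regression,
including zeros in that cell — the covariate-adjusted design needs the full
gene set. Genes expressed in fewer than 10 cells are removed first and the
data log-normalized.

The trajectory test regresses z-scored cell scores on z-scored pseudotime,
so the coefficient is the standardized beta (and equals the Pearson
correlation); leave-one-donor-out repeats it per excluded donor, flagging
donors whose exclusion leaves nothing testable. Pseudotime is expected as an
input column from a dedicated trajectory tool; `simple_pseudotime()` (first
principal component, oriented by root cells, min-max scaled) exists only so
synthetic runs are self-contained, and recovers the planted ordering with
Spearman correlation above 0.9 — it is not a substitute for graph-based
trajectory inference on real branching data.

## Fine-mapped gene rank test

Per cell type, genes with specificity exactly 0 are removed, then a
one-sided Wilcoxon rank-sum test asks whether target (fine-mapped) genes
rank higher than all other expressed genes. With the smaller group at most 8
and no ties the exact null distribution is used; otherwise a normal
approximation with tie correction and continuity correction. The switch
point keeps the oracle-checked exact path for tiny tests while realistic
target sets (tens of genes) use the approximation, which agrees with the
exact tail within 0.01 already at group sizes of 8. The family threshold
$0.05/K$ over cell types is reported alongside (e.g. $5.95\times10^{-4}$ for
84 populations).

## Rare protein-truncating variant burden

Sample QC removes one member of each pair with kinship coefficient
strictly above 0.177 (covering duplicates at 0.354), ancestry-flagged
samples, and mean depth below 20×. Which member of a related pair to drop is
not specified by convention, so we remove greedily by pair degree (ties by
ascending sample id): a relatedness chain A–B, B–C loses only B. Genotype QC
sets to missing genotypes with DP < 10, GQ < 30, or allele balance outside
[0.25, 0.75] for heterozygotes, above 0.1 for hom-ref, below 0.9 for
hom-alt — all boundaries inclusive as printed. Variant QC then removes VQSR
failures, call rate < 0.9 (computed on post-genotype-QC missingness — the
ordering is not documented elsewhere, so it is fixed and logged here),
Hardy–Weinberg exact $p < 10^{-8}$, and low-complexity regions; both
exclusion thresholds are strict inequalities. The HWE exact test enumerates
all heterozygote counts of the observed parity and sums probabilities no
larger than the observed configuration's; it matches brute-force enumeration
for every table up to $n = 50$.

Qualifying variants are singleton PTVs: stop-gain, frameshift, or splice
donor/acceptor consequence, exactly one heterozygous carrier (and no
hom-alt) among retained samples, and absent from the external reference
cohort. The burden test is a Firth penalized-likelihood logistic regression
of case status on the per-sample qualifying-PTV count in the tested gene
set, adjusting for 10 principal components, exome-wide synonymous burden,
platform, and sex, optionally plus the sample's total PTV burden across all
expressed genes so set-specific enrichment is tested above the tissue-wide
background. The Firth score equation is solved by modified-score Newton
iterations with step-halving against the penalized likelihood; convergence
requires every score component below $10^{-6}$ (non-convergence is an error
with the score trace, not a silent result). On a saturated 2×2 design the
estimate equals the 0.5-corrected log odds ratio, and estimates stay finite
under complete separation. The one-tailed $p$ (greater burden in cases) is
Wald-based by default; a penalized-likelihood-ratio alternative was
considered and deferred since the Wald form is what the jackknife-free QC
pipeline needs and the choice is not pinned by our sources.

## The synthetic test-bed

The generators draw everything from a single seeded stream per call (no
global RNG state), so a fixed seed fixes every artifact bit for bit.

* **Counts** are negative-binomial with log-normal gene means; each cell
  type has a disjoint block of marker genes whose mean is multiplied by
  `marker_fold`. Two tiny clusters (7 and 3 cells) are always present so the
  cluster filter is exercised. Default sizes (400 genes, 8 types × 80 cells,
  6 donors, dispersion 2) keep a full scan under a minute while leaving
  enough cells per type for stable means.
* **LD** is block-diagonal: haplotypes are binary Markov chains with
  constant within-block MAF, giving genotype dosage correlation exactly
  $\rho^{|i-j|}$ — the closed form lets LD scores and quadratic-form nulls
  be validated analytically. GWAS z-scores are multivariate normal with the
  same block correlation; SNPs inside planted-set genes get a mean shift of
  $\sqrt{\text{effect}}$ with random sign, inflating expected chi-square by
  exactly the configured effect. The planted enriched set *is* the first
  cell type's marker genes, so the end-to-end scan has one recoverable
  population. Defaults: 20,000 SNPs, 200 blocks, $\rho = 0.6$, a panel of
  500 individuals (the size of a typical European reference subset), GWAS
  $N = 50{,}000$.
* **Trajectory** expression drifts log-linearly with pseudotime at a rate
  proportional to each gene's standardized association z, so slope 0 is an
  exact null and a unit slope yields standardized betas near 1.
* **Rare variants** plant singleton PTVs in the burden genes and assign case
  status by a logistic model on true carrier counts, making
  $\log(\text{OR})$ the estimand of the Firth regression. One deliberate
  violation of every QC rule is always included, plus an
  external-reference-present singleton and a two-carrier PTV, so each filter
  provably fires.

What passing tests show — and what they do not: the test-bed verifies
algorithmic correctness (exact identities, enumeration oracles), statistical
calibration under its own generative model, and power against planted
effects. Real data differ in ways the generators deliberately do not mimic:
no ambient RNA or doublets, no donor batch effects, LD without long-range
structure or MAF-dependent architecture, no population stratification in the
GWAS, and exchangeable samples in the exome arm. Green tests therefore
establish that the methods do what they claim under their stated
assumptions, not that those assumptions hold in any particular dataset.

## Problem sizes, reproducibility, and reporting

The packaged analyses and `scripts/acceptance.R` run at deliberately desk
scale — hundreds of genes, a few thousand to 20,000 SNPs, thousands of
exome samples — chosen so a complete verification pass takes minutes on one
CPU while every statistical property remains measurable. All thresholds
live in `run_config()` (unknown keys are rejected), every run can be
fingerprinted by the config hash recorded in `report()`, and multiple
testing is Bonferroni within each family (cell types; GO terms), with no
additional FDR layering. Stage logs count the genes, SNPs, and variants each
filter removes.
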