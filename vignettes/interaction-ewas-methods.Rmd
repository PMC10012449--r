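---
title: "Methods: interaction EWAS with reference-free cell adjustment and proximity enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interaction EWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(interewas)
```

# The statistical model

`interewas` tests, per CpG site, whether the association between DNA
methylation and a quantitative phenotype (here the ex vivo zoledronic
acid IC50 of donor-derived osteoclasts, in µM) depends on an exposure
(lifetime cigarette count). The per-probe model is ordinary least
squares on the M-value scale:

$$\mathrm{DNAm} = b_0 + b_1\,\mathrm{IC50} + b_2\,\mathrm{Smoking}
  + b_3\,\mathrm{IC50}\times\mathrm{Smoking} + b_4\,\mathrm{Age}
  + b_5\,\mathrm{PC1} + b_6\,\mathrm{PC2} + b_7\,\mathrm{PC3} + \varepsilon$$

with two-sided t-tests on $b_1$, $b_2$, $b_3$ at $n - p$ residual
degrees of freedom. Covariates enter **untransformed and uncentered** —
the exposure is defined as the raw lifetime cigarette count and the
phenotype as the raw IC50, and the interaction is formed on those raw
scales. A `center` flag exists for numerical conditioning but is off by
default; with it off, coefficient magnitudes are naturally small
(IC50×Smoking reaches ~10^6 cigarette·µM, so interaction coefficients
land around 10^-6 to 10^-5 per unit). Because every probe shares one
design matrix, the package fits all probes with a single QR
decomposition; tests verify equality with a normal-equations oracle to
1e-10.

Assumptions worth stating: Gaussian, homoscedastic residuals per probe
(M-values approximate this far better than bounded beta values, which
is why modelling happens on the M scale); independent samples; and a
correctly specified linear interaction. No robust/sandwich errors,
mixed models, or surrogate-variable methods are provided.

## Multiple testing and tiers

`bh_fdr(p, m_total)` implements Benjamini–Hochberg step-up with an
explicit total test count, $\tilde p_{(i)} = \min_{j \ge i}
\min(1, m\,p_{(j)}/j)$. The `m_total` argument exists because a
published top-list is often all one has: adjusting the bundled 59
interaction p-values against the full post-filter count m = 683,408
reproduces the printed FDR column (0.002 at the top CpG — the running
minimum is attained at rank 3 — and 683,408 × 4.27e−06 / 59 = 0.049 at
the boundary). FDR is computed separately per effect, since each effect
is its own family of tests. Tiers: genome-wide iff FDR < 0.05,
otherwise suggestive iff p < 1e−05.

## Degenerate inputs

A constant-y probe reports zero effects with p = 1 rather than failing
the run. An exactly noiseless probe with a planted effect (zero
residual variance, nonzero coefficient) reports the smallest
representable p. A globally rank-deficient design (e.g. an all-never-
smoker cohort making the smoking column zero) aborts with the offending
column named — per-probe skipping is meaningless when the design is
shared. All reported p-values are clamped into (0, 1].

# Preprocessing conventions

Beta values follow the Illumina formula β = M/(M + U + 100); the
offset bounds β by M/(M + 100) < 1. Before the base-2 logit, β is
clipped to [1e−6, 1 − 1e−6]: the M-value transform is undefined at 0
and 1, and synthetic zero-signal probes would otherwise produce
infinities. The clip margin keeps the transform exactly invertible over
the clip-free range (round-trip error < 1e−12).

The detection filter drops a probe when its detection p exceeds 0.01 in
**strictly more than** 5% of samples — with 34 samples the cut sits at
1.7, so two failing samples trigger removal and one is tolerated.
Filters run in a fixed order (detection first, then chrY, then
SNP-overlap) and each drop records a single reason with chrY taking
precedence; chrX probes are retained, which is appropriate for
all-female cohorts. Both filters are idempotent and kept + dropped
always sums to the input count. A no-op normalization hook marks where
between-array (functional) normalization would sit; it needs raw
control-probe data that intensity tables do not carry.

# Reference-free cell composition

Whole blood is a mixture; composition differences confound methylation
associations. Instead of reference-based deconvolution, the package
computes components correlated with the latent proportions: (1)
standardize each probe across samples; (2) form a rank-*d*
approximation from the top *d* principal directions; (3) rank probes by
the Euclidean distance between observed and reconstructed profiles; (4)
keep the *t* closest; (5) PCA on the selected sub-matrix and return the
first *k* sample scores.

Defaults are d = 5, t = 500, k = 3. *k* = 3 matches the number of
components the motivating study carried into its regression; *d* and
*t* are not reported there, so the defaults are conventional values
exposed in the configuration. Standardization makes selection invariant
to probe-wise scaling; zero-variance probes are excluded with a
warning.

**Sign convention.** PCA components are defined up to sign. The naive
"largest-magnitude loading positive" rule turns out to be unstable on
near-rank-1 data: all selected probes then carry loadings of equal
magnitude (±1/√t), and floating-point jitter decides the argmax, so the
sign can flip under mere sample reordering. The package instead makes
positive the loading of the *first probe in name order* whose magnitude
is at least half the maximum — deterministic, and stable under sample
permutation (equivariance error ~1e−13 in tests).

# Proximity enrichment and replication

For a CpG and a phenotype group, the success ratio at maximal distance
D is the fraction of the group's SNPs with |SNP − CpG| **< D** (strict,
per the definition "less than the stated maximal distance") on the
same chromosome; cross-chromosome pairs never count (the natural
reading of genomic distance). The distance ladder defaults to
{1,000; 2,500; 5,000; 10,000; 25,000; 50,000} bp. Ratios are monotone
non-decreasing in D by construction.

Group comparisons use a one-tailed Mann–Whitney U test: exact by
enumeration of all $\binom{n_1+n_2}{n_1}$ label assignments when the
combined sample is ≤ 12 (this handles ties naturally), and the normal
approximation with tie correction and continuity correction otherwise;
both branches are cross-checked against `pwilcox` and `wilcox.test`.

Per-locus enrichment (the per-gene table view) is not fully specified
by its source, which prints per-gene p/FDR without naming the test. The
documented interpretation implemented here: a one-sided Fisher exact
test on the 2×2 table (within-D vs beyond-D × relevant vs control
group), computed through the hypergeometric identity, BH-adjusted
across loci at each distance, with a per-locus summary reporting the
largest distance still significant at FDR < 0.05. The Mann–Whitney
group comparison remains the headline statistic.

SNP catalogs are pre-filtered to **retain** SNPs with association
p < 5e−6: enrichment asks whether *associated* SNPs cluster near the
CpGs, so the suggestive tail is what must be kept (the rule is
config-invertible for the opposite reading). Dataset metadata filters
keep high-confidence GWAS with h2 > 0.01 and h2 z-score ≥ 7.

Replication: a discovery CpG is validated iff a same-chromosome
validation site with q < 0.05 (strict, as printed) lies within ±5 kb
**inclusive** ("within 5 kb" read as closed). Matching uses a sorted
per-chromosome index, O(log n) per query; chromosome labels "chr1" and
"1" are normalized with a warning.

## Over-representation analysis

CpGs map to genes by splitting ";"-joined annotation fields and
deduplicating. The ORA p-value is the upper hypergeometric tail
P(X ≥ k) with universe N, set size K, query size n — n counted *after*
intersection with the universe, the standard convention. The universe
is an explicit argument (defaulting to all annotated genes) rather than
a hidden ontology. The `q_value` column equals the BH-adjusted
`p_adjust`: the two columns are near-identical in the motivating
study's output, and a separate Storey estimator is deliberately out of
scope, so the package documents the identity instead of pretending at a
second estimator.

# What the synthetic generator emulates — and what it does not

`generate_cohort()` reproduces the published cohort's *structure*, not
its unpublished per-donor values: ages uniform on [40, 66]; smoker
classes never/past/current at 12/16/6 of 34; lifetime cigarettes 0 for
never-smokers and log-uniform up to 268,800 otherwise (log-uniform
because per-day × years spans orders of magnitude); IC50 from a
log-normal centred on the published median 0.28 µM (sdlog 1.2),
truncated by inverse-CDF to the published range [0.061, 9.49] µM — so
the generated range brackets the published 156-fold spread.

`generate_methylome()` composes M-values from a per-probe baseline
(N(0, 1.5)), cell-type effects δ for a Dirichlet(2) mixture on a
configurable fraction of probes (default 20%, effect SD 1 — sparse so
feature selection has signal to find), planted covariate effects, and
Gaussian noise. Intensities fix the total signal S = M + U + 100 at
10,000 and solve M = βS, making β = M/(M + U + 100) *exactly*
invertible. Probes carrying planted effects receive no cell-type
effects, so planted-coefficient recovery is scored against the nominal
noise SD. `planted_effect_size()` converts a target expected
t-statistic into a per-unit coefficient via the realised design's
$(X^\top X)^{-1}$.

The genome model is desk-scale (two 10-Mb autosomes plus 5-Mb X/Y
models) — enough to exercise every positional rule, nowhere near a real
karyotype. Not emulated: Infinium I/II probe chemistry, dye bias,
batch effects, background correction, spatial correlation of
methylation, LD structure among SNPs, or realistic minor-allele
clustering. Passing tests therefore demonstrate the *statistics* are
correct and calibrated on data satisfying the model's assumptions; they
do not certify behaviour under array artefacts that real studies must
additionally handle.

In `generate_gene_sets()`, the enriched set contains `excess` × the
chance-expected number of marked genes (a deterministic count with
random identity). A weighted-sampling reading of "excess" was measured
to give only ~93% detection at excess 3 across reasonable sizes; the
deterministic reading gives planted signal of known strength.

# Calibration results the test suite computes

Problem sizes were chosen as the smallest at which the binomial error
bars are meaningfully tight. On 20 seeds of 2,000-probe null
methylomes over 50 donors (components included, estimated from the
data), the interaction test rejects at 0.049–0.051 against the nominal
0.05 (within 3 binomial SE). On mixed runs (25 planted of 500 probes,
n = 100), the empirical FDR of BH at 0.05 stays at ~0.05, below the
0.075 bound asserted. Planted interaction effects sized for expected
|t| = 8 are recovered at FDR < 0.05 in 100% of 100-probe runs over 20
seeds. On 3-cell-type mixtures (n = 60, noise SD 0.1), the first
canonical correlation between the top-3 components and the true
proportions has median ≈ 0.9996 over 20 seeds. A phenotype group with
50% of its SNPs planted within 10 kb of 20 target CpGs is detected
against a uniform control at p < 0.05 in 50/50 seeds.

One calibration choice deserves its own paragraph: power runs fit the
EWAS **without** composition components. At desk scale, planting 5
effects among 100 probes makes the planted direction a dominant
principal direction, and the unsupervised selection step absorbs it
into the components (correlation with the interaction covariate up to
0.8), collapsing power — a known hazard of reference-free adjustment
that is negligible when the signal is 59 probes in 683,408 but
dominant at 5 in 100. Component estimation is exercised where it is
meaningful: in the null calibration (2,000 probes, where the rejection
rate stays nominal with components included) and in the dedicated
mixture-recovery runs.

# Pipeline and reproducibility

`run_pipeline()` executes simulate → preprocess → cellcomp → ewas →
ora → gwasprox → replicate under a single validated configuration
(unknown keys rejected), writes every stage table as TSV plus a JSON
manifest (package version, global seed, per-stage child seeds,
parameters, row counts), and is byte-identical under a fixed seed. The
global seed fans out deterministically to per-stage child seeds kept
inside the 32-bit integer range; the manifest alone suffices to
reproduce a run. A thin Rscript wrapper (`inst/scripts/run_pipeline.R`)
exposes the same entry point to the shell with a YAML config.

# Known limitations

- No raw IDAT parsing, functional normalization, or probe-type
  correction: the pipeline starts at intensity tables.
- OLS only; with n ≈ 34 and 8 parameters, residual degrees of freedom
  are thin and single influential donors can drive interaction terms —
  the package reports, it does not robustify.
- `q_value` is an alias of the BH adjustment, not a Storey estimate.
- The per-locus Fisher construction is this package's documented
  interpretation of an underspecified published table.
- The synthetic validation table and GWAS catalogs are structural
  stand-ins, not re-distributions of any external dataset.
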