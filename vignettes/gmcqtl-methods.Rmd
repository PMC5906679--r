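---
title: "Models and methods behind gmcqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gmcqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmcqtl)
```

`gmcqtl` dissects grain mineral concentrations (GMCs) — Fe, Zn, Cd, Mn, Cu
and Se in milled (polished) rice grain, all in ppm — across a structured
germplasm panel with an indica/*Xian* subset (X) and a japonica/*Geng*
subset (G). This vignette is the package's own account of the statistics
it implements: the models, the tunable parameters and their defaults, the
numerical choices, and what the simulation-based tests do and do not
demonstrate.

## The mixed linear model scan

For one trait the scan fits, per SNP,

$$ y = X\beta + g b + u + e, \qquad
   u \sim N(0, \sigma^2_g K), \quad e \sim N(0, \sigma^2_e I), $$

where `y` is the trait vector, `X` the covariates (intercept plus
principal-component scores), `g` the ALT-allele dosage (0/1/2) and `K` the
VanRaden genomic relationship matrix
$K = ZZ' / (2\sum_i p_i(1-p_i))$ built from frequency-centered dosages.
Monomorphic SNPs are excluded from `K` and missing dosages are mean-imputed
per SNP, so `K` is always defined on polymorphic data; for the per-SNP test
itself, accessions missing `y` are dropped globally and accessions missing
the dosage are dropped for that SNP only (case-wise deletion). The two
policies are deliberate: imputation keeps the relationship matrix
well-conditioned, deletion keeps each test honest.

Variance components come from REML in the EMMA parameterization. Writing
$\delta = \sigma^2_e / \sigma^2_g$, a single eigendecomposition of the
projected kinship $SKS$ (with $S$ the projection off the fixed effects)
reduces the restricted likelihood to a one-dimensional function of
$\delta$, maximized by Brent search over $\log_{10}\delta \in [-5, 5]$ at
tolerance 1e-8. When the surface is flat (e.g. `K = I`, where only
$\sigma^2_g + \sigma^2_e$ is identified) the fit is flagged
`delta_unidentifiable` rather than failing; the ridge sum still equals the
OLS residual variance. The fitted likelihood is verified in the tests
against a direct-formula oracle ($\log|H|$, $\log|X'H^{-1}X|$, $y'Py$
computed with dense matrices) on a 50-point grid.

Testing uses P3D ("population parameters previously determined"): the null
$\hat\delta$ is reused for every SNP, the data are rotated once by the
eigenvectors of `K`, and each SNP costs one weighted least-squares update;
the Wald/F test (1 df) with residual degrees of freedom yields the p-value.
`p3d = FALSE` re-estimates the variance components per SNP for small
panels. The package deliberately implements a *plain* mixed model rather
than a compressed one (grouping individuals into kinship clusters):
compression is a speed device that converges to the plain MLM as the group
count approaches `n`, and the plain model is the cleaner statistical
object to test. With `K = I` and no covariates the entire scan reduces
exactly to ordinary least squares, which the test suite asserts at 1e-8.

Effects are reported on the **favorable allele effect (FAE)** convention:
the regression coefficient is re-expressed for the minor (germplasm)
allele with the major allele as the zero reference, so a positive FAE
means the minor allele raises the trait. At an exact 50/50 frequency tie
the REF allele is the reference and the SNP is flagged `maf_tie`. SNPs
below the minor-allele-frequency threshold (default 0.01; the source
analyses state none, so it is exposed as a parameter) are emitted with
flag `low_maf` and no test.

Principal components are scores of the centered, mean-imputed dosage
matrix with a deterministic sign convention (largest-magnitude loading
positive). The number of PCs is selected by BIC over `0..k_max` on the
null *maximum-likelihood* mixed model (REML likelihoods are not comparable
across fixed-effect sets); ties resolve to the smaller k. With kinship in
the model, PCs enter only when structure aligns strongly with the
phenotype, which matches the intended behaviour of automatic model
selection in standard GWAS tools.

## Locus calling and clustering

Calling uses two thresholds on $-\log_{10} P$: a stringent 6.0 that always
seeds loci and a loose 3.0 that seeds loci only inside a same-trait
support interval (linkage or literature QTL) — the type-II-error guard for
low-heritability traits. Qualifying SNPs within `merge_gap` of each other
merge into one locus spanning them; the peak marker supplies the locus
statistics. The reference analyses never state how their printed locus
ranges were delimited, so `merge_gap` defaults to 300 kb (a typical LD
scale for diverse rice panels) and is exposed in the configuration.

Cadmium loci are additionally chained into physical clusters by
single-linkage: consecutive same-chromosome loci join when the gap (next
start − previous end) is at most `max_gap`, default 3 Mb, labelled
`Clst<chrom><a, b, ...>` positionally. No single gap value reproduces the
printed cluster memberships of the packaged table exactly (its largest
within-cluster gap exceeds the smallest between-cluster gap), so the
packaged table's own labels are used for fixture-derived summaries while
`cluster_cd_loci()` serves new data. Published counts adjacent to that
table are also mutually inconsistent (16 multi-locus + 14 singleton
clusters against 29 total; the fixture recount gives 15 + 14), which the
package reports as recomputed, not as copied.

Health accounting uses the trait polarity map (Fe, Zn, Mn, Cu, Se: `+`;
Cd: `-`): a locus allele is *favorable* when its FAE sign matches the
polarity. Zero FAEs are counted in neither direction and surfaced in
`n_fae_zero` (none occur in the packaged table).

## Duncan's multiple range test and the haplotype screen

Candidate-gene haplotypes are the allele strings over all polymorphic SNPs
in the annotated gene span, per subset. Heterozygous or incompletely
genotyped accessions are excluded (reasons `heterozygous`, `missing`)
rather than imputed — rice germplasm panels are inbred and
near-homozygous, so exclusion is conservative and auditable — and
haplotypes with fewer than `min_count = 5` carriers are excluded as
`rare` (published gene screens in this domain retain 5–9 haplotypes per
gene without stating a floor; 5 keeps every retained group testable).
Retained haplotypes are ranked `Hap1..HapN` by carrier count, ties broken
by first occurrence.

Trait means across haplotypes are compared with Duncan's multiple range
test: one-way ANOVA MSE and df, means ranked, and the critical range for a
stretch of `p` ranked means

$$ R_p = q\!\left(1-\alpha_p,\ p,\ \mathrm{df}\right)\sqrt{\mathrm{MSE}/n_h},
   \qquad \alpha_p = 1-(1-\alpha)^{p-1}, $$

with `q` the studentized-range quantile (R's `qtukey`, i.e. the
distribution function inverted by root finding) and `n_h` the harmonic
mean of the group sizes spanned by the comparison (the equal-`n` rule and
the two-group t-equivalence are exact special cases). The step-down rule —
a stretch is never significant inside a non-significant containing
stretch — produces a compact letter display in which two haplotypes share
a letter exactly when not separated.

One design decision deserves emphasis: the range procedure runs
**protected behind the one-way ANOVA F test** at the same `alpha`
(`protect_f = TRUE`). Unprotected, Duncan's widest stretch is tested at
$1-(1-\alpha)^{k-1}$ (0.185 for five groups), so its family-wise null
separation rate grows well beyond the nominal level — the classical
criticism of the procedure. Gating on the ANOVA F keeps the measured null
any-separation rate at ≈0.05 for five groups of twenty (the test suite
checks the 2,000-replicate Monte-Carlo rate against [0.03, 0.08]) while
leaving the liberal stepwise behaviour intact once a signal is present,
and it changes nothing for two groups, where the F gate is exactly the
squared pooled t-test. This mirrors how the test is ordinarily run after a
significant ANOVA in agronomic practice.

Star levels report the most stringent of the four levels 0.05, 0.01,
0.001, 0.0001 at which at least one haplotype pair separates
(`ns`, `*` … `****`; a published footnote prints a five-asterisk glyph for
the fourth level, normalized here to four stars since only four levels are
defined). The favorable/conditional/unfavorable/neutral verdict codifies
the Fe–Zn–Cd trade-off at the `*` level: a *gain* is being significantly
higher than at least one other haplotype in Fe or Zn; a *nutrient loss* or
*Cd increase* analogously; favorable = gain without loss or Cd increase,
conditional = gain with a trade-off, unfavorable = loss or Cd increase
without gain, neutral otherwise.

## The synthetic panel generator

`simulate_panel()` emulates the study conditions so every stage is
testable offline: 265 X plus 433 G accessions by default, subset allele
frequencies drawn from the Balding–Nichols model (ancestral frequency
Uniform(0.05, 0.95), divergence `fst = 0.1`, producing PC separation like
a real two-subspecies panel), and genotypes generated by founder-haplotype
copying within LD blocks (default 10 SNPs per block, 4 founders per subset)
so gene spans carry few distinct haplotypes, as candidate-gene analysis
requires. Phenotypes are subset baseline + planted causal-haplotype
increments + Gaussian noise truncated at a small positive floor (1e-4 ppm;
concentrations are non-negative). Default baselines reproduce the observed
pooled trait means (Fe 2.4, Zn 16.4, Cd 0.009, Mn 9.7, Cu 3.2, Se 0.04
ppm) with the G subset higher in Zn and Cu, markedly lower in Cd — making
the pooled Cd distribution bimodal — and fully overlapping in Se. No
heritability estimates are published for these traits, so planted effect
sizes are explicit per-gene configuration, not a claim about real
architecture.

What passing tests on these panels show: the estimators are correct and
calibrated under a known generative model (type-I control at the 6.0
threshold, genomic-control λ in [0.9, 1.1] with correction and > 1.2
without, planted-QTL localization, planted-haplotype detection). What they
do not show: performance under real LD decay, admixture gradients,
measurement error in mineral assays, or genotype error — none of which the
generator models.

One integer seed determines every simulated object bit-for-bit, and the
pipeline writes a manifest (config hash, seed, package version, stage
log) with no timestamps, so identical configuration and seed give
byte-identical output trees.

## Numerical choices and problem sizes

- Brent search on $\log_{10}\delta \in [-5,5]$, tolerance 1e-8; endpoint
  likelihoods checked so boundary optima are kept.
- Eigenvalues clipped at zero before weighting (kinship is PSD up to
  rounding; inputs failing PSD beyond −1e-8 raise an error).
- Peak ties in locus calling resolve to the first (leftmost) SNP;
  haplotype count ties resolve to first occurrence; BIC ties to fewer PCs.
- Degenerate inputs: empty association tables yield empty locus tables;
  a monomorphic gene span yields a flagged empty assignment; groups with
  no observations are dropped from the Duncan test with a warning, and an
  all-identical input yields one shared letter.
- The shared-marker utility (`shared_markers()`) joins panels on
  chromosome, position and unordered allele pair — the exact rule used to
  build the historical common marker set is not recorded anywhere, so the
  natural position+allele join is implemented and documented as such.
- Test and acceptance problem sizes are chosen to exercise each property
  at meaningful scale while staying desk-sized: structured panels of
  200–500 accessions × 2,000–5,000 SNPs for calibration and power checks,
  2,000 replicates for Monte-Carlo rates, 20 replicates for recovery
  rates, and the full demo pipeline at 300 × 5,000 with three planted
  genes.

## Known limitations

- The scan is single-trait and additive; no dominance, epistasis,
  multi-trait or rare-variant machinery.
- Locus boundaries are merge-gap heuristics, not LD-defined intervals;
  no conditional/joint analysis or fine-mapping.
- Haplotypes are unphased allele strings of homozygous inbred accessions;
  the heterozygote-exclusion policy would discard most of an outbred
  panel.
- The Cd clustering rule is a single-linkage approximation to a published
  clustering whose exact rule is unrecoverable (see above).
- The generator's LD-block model induces within-block correlation only;
  between-block LD is absent by construction.
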