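---
title: "Methods: integrating gut microbiota and serum lipidomics profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating gut microbiota and serum lipidomics profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipitax)
```

# The analysis problem

`lipitax` implements an integrated analysis of paired high-throughput
profiles from an intervention cohort: genus-level gut-microbiota abundances
(log10 hybridization-signal scale, as produced by phylogenetic microarrays)
and serum lipidomics intensities (log10 scale, species named in the
`CLASS(C:D)` shorthand), with subjects sampled at several time points in two
treatment groups (e.g. a probiotic versus a placebo drink). The questions
the pipeline answers, in order:

1. **Stability** — how similar is a subject's profile to itself over time
   (intra-individual) and to other subjects (inter-individual), and does the
   intervention change that?
2. **Intervention effects** — which taxa shift in the treated group, tested
   with a variance-moderated paired contrast, and what effect size could the
   study have detected (empirical power)?
3. **Cross-omics association** — which taxon–lipid pairs co-vary robustly
   across individuals, controlling the false discovery rate over the
   ~50,000 pairs tested?
4. **Structure of the associations** — do the significant pairs form
   coherent blocks (biclusters), and are those blocks enriched for
   structural lipid categories (chain length, saturation, carbon parity,
   ether linkage) or for bacterial clades?

All statistics operate on the log-transformed values, which are
approximately Gaussian for both platforms.

# The synthetic paired cohort

Because the package must be testable end to end without external data, the
first module is a generator for paired cohorts with a **ground-truth
ledger**. Its defaults are the study conditions everything downstream is
validated against: 25 subjects (11 probiotic / 14 placebo), three faecal
time points, 131 genus-level taxa; serum lipidomes for 22 subjects (8 / 14)
at the first two time points, 407 lipid species in 11 classes.

## Variance components

Each feature follows a three-component Gaussian model on the log10 scale,

$$x_{stf} = \mu + m_f + a_{sf} + e_{stf},$$

with $m_f \sim N(0, \sigma^2_{shared})$ a feature effect shared by all
subjects, $a_{sf} \sim N(0, \sigma^2_{subject})$ a subject-specific feature
effect stable over time, and $e_{stf} \sim N(0, \sigma^2_{noise})$ sample
noise. Writing $\sigma^2_{tot}$ for the sum, the expected profile
correlations are

* inter-individual: $\sigma^2_{shared} / \sigma^2_{tot}$,
* intra-individual: $(\sigma^2_{shared} + \sigma^2_{subject}) / \sigma^2_{tot}$.

Solving this two-equation system for the observed stability of gut
microbiota (intra $\approx 0.94$, inter $\approx 0.77$) gives the microbiota
default $(0.77, 0.17, 0.06)$; the same algebra for serum lipids (0.92 /
0.90) gives $(0.90, 0.02, 0.08)$. The contrast is the scientifically
important one: microbiota profiles are strongly subject-specific, serum
lipid profiles are homeostatically similar across people. The absolute
log10 scale (baseline levels 3.0 and 6.0, total variance 1.0) is a free
choice — the data sources report correlations, not dynamic ranges — and is
documented here rather than claimed to match any particular instrument.

## Planted effects and associations

The intervention is emulated by a +0.5 log10 (≈3-fold) spike of
*Lactobacillus rhamnosus et rel.* in the probiotic group at the
during-intervention time point, transient by construction.

Taxon–lipid associations are planted by **variance-preserving latent
embedding**. For a target correlation $r$, the taxon column and each
associated lipid column devote the fraction $f = |r|$ of their
(mean-centred) variance to a shared standard-normal latent $z$ and keep
$\sqrt{1-f}$ of their original signal:

$$x' = \bar{x} + \sqrt{1-f}\,(x - \bar{x}) \pm \sqrt{f}\,\mathrm{sd}(x)\, z .$$

The resulting population correlation between taxon and lipid is exactly
$\operatorname{sign}(r)\sqrt{f \cdot f} = r$, *independent of the column
variances*, and — crucially — each column's total variance is unchanged, so
planting associations does not disturb the calibrated stability structure.
(A design alternative, adding a latent with equal loadings on both sides,
achieves the same correlation but inflates the involved columns' variances
by more than their base variance at $r = 0.6$, which visibly degrades the
stability calibration; the embedding form was chosen for that reason.)
The latent is 70% subject-stable and 30% per-sample, reflecting that
microbe–lipid covariation is a property of subjects more than of individual
blood draws; this keeps planted associations detectable in data pooled
across time points without breaking the within-subject stability of the
involved lipids.

The default design plants ten associations (69 taxon–lipid pairs over 10
taxa, magnitudes 0.5–0.61) forming the three motifs the analysis should
resolve: a dominant positive block of long-chain triglycerides around a
Clostridium-cluster-XIVa taxon, a negative block of highly unsaturated
high-carbon triglycerides, a negative ether-phosphatidylcholine block
spanning several Proteobacteria, plus a positive cholesteryl-ester
association of an Actinobacteria genus. The enzymatic panel (TC, LDL, HDL,
TG in mmol/L; population means and SDs 5.10 (1.02), 3.00 (1.21), 1.50
(0.33), 1.20 (0.71)) is derived from the planted lipid blocks with mixing
fractions chosen so the panel correlations land near the lipidomics ones,
with HDL loaded oppositely to TG.

What the generator does **not** emulate: per-taxon variance heterogeneity
(every taxon shares one variance profile, whereas real genus-level signals
range from near-constant background to highly variable), compositional
constraints, non-Gaussian tails, dietary covariates, and probe-level
artefacts. Passing tests therefore demonstrate correctness of the
statistical machinery under the calibrated model, not robustness to every
property of real data.

All randomness flows from one integer seed through a documented splitting
scheme (`seed -> 48271 * seed + 7919 * stream (mod 2^31 - 1)`), and
generation is byte-deterministic given the seed.

# Statistical components

## Stability

Intra-individual similarity is the Pearson correlation of a subject's two
feature vectors; inter-individual similarity is the mean over unordered
subject pairs at a time point, both per group. Missing values are handled
pairwise-complete with a minimum overlap of 10 features. Group differences
in per-subject stability use the two-sided Wilcoxon rank-sum test. PCA
(centred, unscaled) is provided for visualisation only; no downstream
decision depends on it, which is why plain PCA is used rather than a sparse
variant that would introduce an unspecified penalty parameter.

## Moderated intervention contrast

With one sample per subject per time point, sample-level and subject-level
random effects are confounded; the identifiable reading of a "random
subject effect" design is the paired within-subject contrast, which the
package fits by exact differencing (and a pooled-variance unpaired contrast
for between-group comparisons). Per-taxon variances are moderated by
empirical Bayes: $\tilde{s}^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$, with the
prior $(d_0, s_0^2)$ estimated by the method of moments on
$\log s^2$ (working distribution: scaled F), inverting the trigamma
function by Newton iteration. When the moment system is inconsistent
(no excess dispersion of the log variances) the fit falls back to complete
shrinkage $d_0 = \infty$ with the prior at the geometric mean of the
observed variances, so that identical variances are an exact fixed point of
the moderation. The moderated $t$ uses $d_0 + d$ degrees of freedom;
multiplicity is handled by Benjamini–Hochberg adjustment (and Storey
q-values are also reported).

## Empirical power

Power is estimated by permutation: each replicate permutes the sample rows
(destroying real structure), splits $2n$ samples into two arms, inserts a
fold-change alteration into one randomly chosen taxon in the treatment arm,
adds Gaussian noise with the data's average per-taxon SD, and applies the
detection rule. The default rule is "BH-adjusted moderated $p < 0.05$".
An optional minimum-effect filter (`detection_rule(min_log2_effect = 1)`)
is available but off by default: an unbiased estimate of an effect sitting
exactly at the filter threshold clears it with probability one half, so the
filter caps power at ~50% for boundary effects and makes "power
$\to$ 1" unattainable even in the noise-free limit. The fold change is
interpreted on the linear scale (×2 = +log10 2) with a flag to switch to a
log-scale shift.

Note that the attainable power depends strongly on the per-taxon
variability of the input matrix. Under the generator's homogeneous
calibration (per-taxon SD ≈ 0.48 log10 units, doubled by the added noise),
a 2-fold alteration at $n = 8$ per arm is essentially undetectable —
detecting it reliably would require an average per-taxon SD nearly four
times smaller, i.e. a data set dominated by near-constant features. The
acceptance script reports the rate the procedure actually computes.

## Biweight midcorrelation screen

Taxon–lipid association uses the biweight midcorrelation: observations are
median-centred, weighted by Tukey's biweight
$w_i = (1-u_i^2)^2 \mathbf{1}[|u_i|<1]$ with
$u_i = (x_i - \mathrm{med})/(9 \cdot \mathrm{mad})$ (unscaled median
absolute deviation; tuning constant 9 is the standard choice and is
configurable), and the correlation is the normalised cross-product of the
weighted centred vectors. Columns with zero MAD (more than half the values
tied at the median) fall back to Pearson weighting with a warning; constant
columns yield `NA`. Because the weights depend on each vector separately,
the full taxa × lipids matrix is computed as a cross-product of transformed
matrices.

P-values use the Student-t transform $t = r\sqrt{(n-2)/(1-r^2)}$ by
default — deterministic and fast — with a permutation mode available for
cross-checking. Observations are pooled across the two time points
(44 rows), mirroring the paired-cohort design this pipeline targets;
because the two samples of a subject are not independent, the analytic
p-values are mildly anti-conservative, which is documented here as a known
property of the pooled design rather than corrected.

Multiplicity over all pairs is controlled with Storey q-values: $\pi_0$ is
estimated on a $\lambda$ grid (0.05–0.95) with a cubic smoothing spline,
falling back conservatively to $\pi_0 = 1$ for fewer than 100 tests or an
unstable fit; $q_i = \min_{p_j \ge p_i} \pi_0 m p_j / \mathrm{rank}(p_j)$.
With $\pi_0 = 1$ this reduces exactly to Benjamini–Hochberg. Significant
pairs are selected at $q < 0.05$ **and** $|r| \ge 0.5$ (both thresholds
exposed as parameters).

## Two-way clustering and the constant plaid model

The correlation matrix restricted to features with at least one significant
cell is clustered two-ways by average-linkage (UPGMA) hierarchical
clustering of the distance $1 -$ Pearson correlation between correlation
profiles ("second-order" correlation); ties break by input order, making
leaf orders deterministic.

Coherent blocks are detected with a constant plaid model,
$Y_{ij} \approx \mu_0 + \sum_k \mu_k \rho_{ik} \kappa_{jk}$, with binary
row/column memberships and one scalar effect per layer. Layers are fitted
greedily on residuals: a seed cell is drawn with probability proportional
to the squared residual (a randomised rank-1-style seeding that lands in
strong blocks with high probability), the layer alternates effect and
membership updates — a row is kept when its squared-error reduction is at
least $(1 - \mathrm{release})$ times the best row's (release 0.7 on both
axes) — and the best of 5 random restarts is taken. A candidate layer is
accepted only if its explained sum of squares beats layers fitted *with
identical effort* to entry-permuted copies of the residual matrix. Because
candidate and references are exchangeable under a pure-noise input, the
false-layer probability is about $1/(K+1)$ for $K$ references; the default
$K = 30$ keeps it near 3%, which is why the package does not use the small
reference counts (3 shuffles) common in older implementations — those admit
~25% false layers. Accepted layers are subtracted and fitting continues to
the first rejection or `max_layers`.

## Enrichment

Over-representation uses Fisher's exact test (two-sided by the
probability-mass rule, matching the convention of the standard
implementations; one-sided available). Lipid categories derive from the
parsed nomenclature: carbon parity (odd-chain fatty acids are of dietary,
bacterial or marine origin), saturation (SAFA / MUFA / PUFA at 0 / 1 / ≥2
double bonds), long-chain (default threshold: total carbons ≥ 54, exposed
as a parameter since published analyses rarely state their cut-off), and
ether linkage. The default enrichment universe is "features with at least
one significant correlation" (what the bicluster saw), with "all profiled
lipids" selectable — the two universes answer different questions and both
are supported because the choice is rarely stated in published analyses.
Taxon enrichment uses the phylum / Clostridium-cluster labels carried in
the taxon annotation. Enrichment p-values are reported raw (no correction
across categories), matching common practice for these small hypothesis
families.

## Lipid nomenclature

The default grammar is `CLASS(C:D)` with a trailing lowercase `e` inside
the parentheses marking ether linkage (`PC(38:4e)`). The ether dialect
varies between data providers, so the recogniser is a configurable regular
expression. Names with explicit per-chain composition
(`TG(16:0/18:1/18:2)`) are outside the default grammar; a non-strict mode
sums their chains. Parse–format round-trips are exact on the grammar.

# Numerical and interface choices

* TSV is the interchange format throughout (samples as rows, first column
  the sample ID); every writer's output is re-readable by the package's
  readers, byte-identically for canonical formatting. A flat key–value
  configuration file and a thin command-line wrapper
  (`inst/scripts/lipitax-cli.R`) drive `run_pipeline()`, which executes
  stability → contrast → power → screen → clustering → biclustering →
  enrichment → panel and writes all tables plus a run log (seed and
  parameter echo) to an output directory; any stage failure aborts with the
  stage name.
* Degenerate inputs are handled explicitly: constant matrices report zero
  variance (PCA) or no layers (plaid); all-tied stability comparisons
  return $p = 1$ with a warning; zero Fisher margins return $p = 1$ by
  convention; `NA` p-values propagate with warnings.
* Test problem sizes are chosen for tight feedback: planted-block recovery
  uses 60 × 100 matrices over 200 seeds, null calibrations use 20–40
  replicate cohorts, and the full property suite runs in a few minutes on
  one CPU.

# Known limitations

* The pooled two-time-point screen ignores within-subject dependence; its
  p-values are anti-conservative and downstream selections inherit that.
* The generator's homogeneous per-taxon variance makes absolute power
  statements pessimistic relative to data sets dominated by stable
  low-variance features (see the empirical-power section).
* The plaid acceptance test controls false layers, not layer membership
  error; releases fixed at 0.7 can clip weak block members.
* Correlation screening cannot separate direct microbe–lipid relationships
  from confounding by diet or host covariates; the pipeline reports
  association structure only.
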