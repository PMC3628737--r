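# lipitax

Integrated analysis of paired gut-microbiota and serum-lipidomics profiles
from intervention cohorts.

Probiotic and dietary trials increasingly collect both a gut microbiota
readout (genus-level abundances on a log10 signal scale) and a serum
lipidome (hundreds of lipid species named `CLASS(C:D)`, e.g. `TG(54:5)`)
from the same subjects at several time points. `lipitax` is for
bioinformaticians and biostatisticians who need to answer, from such paired
data: how stable are the profiles within and between people, did the
intervention shift any taxa, which taxon–lipid pairs co-vary, and do those
pairs form interpretable blocks?

The pipeline implements:

* **Profile stability** — intra-individual (a subject against itself across
  time points) and inter-individual (subject pairs at one time point)
  Pearson correlations per group, with Wilcoxon group comparisons and PCA
  ordination.
* **Moderated intervention testing** — paired within-subject contrasts with
  empirical-Bayes variance moderation,
  `s2_post = (d0 s0^2 + d s^2) / (d0 + d)`, the prior estimated by moments
  on log variances; plus an empirical power calculation that permutes the
  data, inserts a fold-change alteration and measures the detection rate.
* **Robust correlation screen** — the biweight midcorrelation
  (median-centred, Tukey-biweight-weighted; tuning constant 9) between
  every taxon and lipid species, Student-t p-values, Storey q-values
  (`pi0` by the smoother method), and selection at `q < 0.05`,
  `|r| >= 0.5`.
* **Constant plaid biclustering** — `Y_ij ~ mu0 + sum_k mu_k rho_ik
  kappa_jk` fitted greedily on residuals, layers accepted only when they
  beat permuted references, after two-way UPGMA clustering of the
  correlation matrix.
* **Enrichment** — Fisher exact tests of lipid structural categories
  (odd/even carbons, SAFA/MUFA/PUFA, long-chain, ether linkage — parsed
  from the nomenclature) and of bacterial clades within biclusters.
* **Enzymatic panel integration** — the same correlation machinery against
  TC / LDL / HDL / TG concentrations.
* **Synthetic paired cohorts** — a calibrated generator with planted
  intervention effects and taxon–lipid associations plus a ground-truth
  ledger, so the entire pipeline runs and is validated with no external
  data.

## Worked example

```r
library(lipitax)

cohort <- generate_cohort(cohort_design(seed = 1))
cohort
#> Synthetic paired cohort
#>   microbiota: 75 samples x 131 taxa
#>   lipidome:   44 samples x 407 species (11 classes)
#>   planted: 10 association(s), 1 effect

stability_report(cohort$abundance, cohort$metadata)$within
#>       group  n    mean_r        sd_r       pair
#> 1   placebo 14 0.9396704 0.008293857 TP1 vs TP2
#> 2 probiotic 11 0.9356052 0.009059215 TP1 vs TP2
#> 3   placebo 14 0.9390290 0.004060036 TP2 vs TP3
#> 4 probiotic 11 0.9359163 0.009985362 TP2 vs TP3

screen <- correlation_screen(cohort$abundance, cohort$lipids)
screen
#> Correlation screen: 131 taxa x 407 lipids (n = 44 samples)
#>   selected pairs (|r| >= 0.50, q < 0.05): 44, spanning 18 taxa and 44 lipids
#>   class share of significant correlations:
#>     TG: 70%
#>     PC: 16%
#>     ChoE: 7%
#>     PE: 5%
#>     lysoPC: 2%

head(significant_pairs(screen), 3)
#>                           taxon    lipid          r            p            q
#> 1 Megamonas hypermegale et rel. TG(62:6) -0.7444008 6.944203e-09 0.0002292498
#> 2 Megamonas hypermegale et rel. TG(61:9) -0.7403652 9.237427e-09 0.0002292498
#> 3   Ruminococcus gnavus et rel. TG(56:8)  0.7301976 1.853511e-08 0.0003066633
```

Intra-individual microbiota correlations sit near 0.94 while
inter-individual ones sit near 0.77 — gut profiles are strongly
subject-specific — and the screen recovers the planted association motifs:
a dominant block of positive taxon–triglyceride pairs, negative ether-PC
correlations, and a cholesteryl-ester association, which `fit_plaid()`
then resolves into block structure and `category_enrichment()` interprets
(long-chain, saturation, parity, ether classes).

`run_pipeline(out_dir = "results", seed = 1)` executes every stage and
writes all tables (TSV), a correlation heatmap and a run log;
`inst/scripts/lipitax-cli.R` wraps it for shell use
(`simulate` / `run-all` subcommands).

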