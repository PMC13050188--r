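---
title: "Genetic variance with indirect parental, imprinting and sibling effects"
author: "famvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic variance with indirect parental, imprinting and sibling effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famvar)
```

## The model

A child's phenotype at a single biallelic locus (alleles A1, A2 with
frequencies $q_1$, $q_2$) is built from five effect classes, all in trait
units per copy of A2:

* $\beta_c$ — the **direct** effect of the child's own dosage $X_c$;
* $\beta_m$, $\beta_f$ — **indirect maternal and paternal** effects of the
  parents' dosages $X_m$, $X_f$, mediated through the parental phenotypes
  (parenting, provisioning, household environment);
* $\beta_i$ — a **parent-of-origin (imprinting)** effect, expressed only in
  heterozygotes: $+\beta_i$ when the A2 allele came from the mother,
  $-\beta_i$ when it came from the father;
* $\beta_s$ — an **indirect sibling** effect of a co-reared full sibling's
  dosage.

Ordering the child's alleles maternal-first ($A_mA_f$), the imprinting code
is $X_i = A_m - A_f$, so the two reciprocal heterozygotes A1A2 and A2A1
differ whenever $\beta_i \neq 0$ — and also whenever
$\beta_m \neq \beta_f$, because each homozygous parent type can produce
only one of the two ordered heterozygotes. That confounding (parental
effects masquerading as imprinting and vice versa) is visible directly in
the enumeration:

```{r}
trio_table(locus_params(q2 = 0.3, beta_c = 1, beta_m = 0.5, beta_f = -0.5,
                        beta_i = 0.2))
```

`trio_table()` is the package's exact oracle: 16 parent–child combinations
with phenotype multipliers and mating frequencies. Summing over it gives
the closed forms, with population mean $2q_2(\beta_c+\beta_m+\beta_f)$
(imprinting averages out) and random-mating variance

$$V_{RM} = 2q_1q_2\left(\beta_c^2+\beta_m^2+\beta_f^2+\beta_i^2
  +\beta_c\beta_m+\beta_c\beta_f+\beta_m\beta_i-\beta_f\beta_i\right),$$

implemented in `var_rm()` and checked against `enumerate_moments()` to
1e-10 in the test suite. The sibling-difference design analyses
$Y_c - Y_s$ between two full siblings; shared parental terms cancel,
leaving `var_sibdiff_rm()`
$= 2q_1q_2(\beta_c^2+\beta_i^2+\beta_s^2-2\beta_c\beta_s)$ — direct and
sibling effects always oppose each other in the difference.

### Assortative mating

Assortative mating (AM) with mate allele correlation $\rho$ (equivalent to
an inbreeding coefficient $F$) changes the mating frequencies but not the
allele frequencies. The offspring frequencies are
$z_{AM} = P_{AM}(X_m)\,P_{AM}(X_f)\,T(\text{child}\mid\text{parents})
\left[1 + \rho\,d_m d_f / S\right]$, with $P_{AM}$ the $F=\rho$ genotype
frequencies, $d = X - 2q_2$ and $S = 2q_1q_2(1+\rho)$. Two readings of the
printed bracket are typographically possible ($\rho d_m d_f/S$ versus
$\rho S d_m d_f$); both conserve probability and allele frequency (the
correction is mean-zero either way), so the package selects the reading by
the remaining constraint — agreement of the enumeration with the
closed-form AM variance `var_am()` — and the selection is itself a test.
The chosen bracket also makes the mates' genotype correlation exactly
$\rho$, which is the model's definition.

`var_am()` is quadratic in $\rho$ and reduces to `var_rm()` at $\rho=0$;
the sibling-difference variance shrinks as
`var_sibdiff_am()` $= (1-\rho)\,$`var_sibdiff_rm()`. Trio variance grows
under AM while sibling-difference variance shrinks — the two family
designs bracket the truth from above and below.

### Multiple loci

`var_total()` combines per-locus variances $V_j$ with inter-locus genotype
correlations $k_{ij}$ as
$\sum_j V_j + \sum_{i\neq j} k_{ij}\sqrt{V_i V_j}$ (the off-diagonal sum
over ordered pairs, i.e. twice the unordered sum — the only reading under
which the two printed forms of the combination rule agree).
`am_multilocus_covariance()` exposes the complementary allele-level view
under the equal-frequency, equal-effect simplification: the same-locus
correlation $f$, the within-gamete cross-locus correlation $k$ and the
cross-gamete cross-locus correlation $s$ contribute
$l f q_1q_2(\beta_c+\beta_m)(\beta_c+\beta_f)$,
$\tfrac{l(l-1)}{2} k q_1q_2(\beta_c+\beta_{m})^2$ (per gamete, with
$\beta_f$ for the paternal one) and
$l(l-1) s q_1q_2(\beta_c+\beta_m)(\beta_c+\beta_f)$. These are totals over
unordered allele pairs; each enters the variance of the summed genetic
value twice, which a correlated-Bernoulli simulation oracle confirms in
the tests.

## The simulator and what it emulates

`run_generations()` is a forward-in-time family simulator: a synthetic
phased founder panel (`founder_panel()`, a first-order Markov copying
model with tunable LD decay — a stand-in for a real reference panel, which
can be substituted via `read_founder_vcf()`), scenario-based effect
sampling (`sample_effects()`), phenotype-ordering mate assortment
(`assort_mates()`), meiosis with a per-interval crossover process
(`meiosis()`), and two offspring per pair in each generation so that
sibling links always exist and sex counts stay equal.

Scenario presets follow the standard ladder V1–V6 (see
`effect_scenario()`). Component variance defaults — direct 0.5,
maternal/paternal 0.125, imprinting 0.1, environmental 0.5, sibling 0.1
when a sibling-difference study is requested, V5 cross-class effect
correlations of $\pm 0.2$–$0.3$ and V6 direct–parental correlations of
0.5 — are fixed once as plausible values for a strongly heritable,
family-influenced human trait (with direct variance 0.5 and environment
0.5 the direct share is the SNP heritability in V1). The published
scenario ladder does not pin the indirect-effect magnitudes, so these
defaults are the package's own calibration and are deliberately not
revisited per analysis.

Design choices worth knowing:

* **Assortment mechanism.** Mates are rank-matched against a bivariate
  Gaussian template with correlation $\rho_Y$, which achieves intermediate
  correlations smoothly; this is a mechanism choice, the contract is only
  the realized mate correlation. For a polygenic trait the induced
  per-locus mate genotype correlation is of order $\rho_g/l$ — tiny — so
  when a *causal-level* correlation is the target (as in the
  relatedness-curve analyses), `calibrate_rho_g` closes the loop on the
  correlation of the mates' causal genetic scores instead, re-pairing
  within each generation until the realized score correlation hits the
  target. A per-locus mate correlation of e.g. 0.2 is not reachable by
  phenotype ordering at hundreds of loci; the score correlation is the
  quantity the simulator can and does control.
* **Effect scaling** uses realized founder allele frequencies, with
  per-locus draws scaled by $1/\sqrt{2q(1-q)}$ before class-wise
  normalization, so class genic variances hit their targets exactly on the
  simulated panel.
* **Founders** have no in-panel parents: their phenotypes carry only
  direct and imprinting terms. Assortment in the founder generation
  therefore acts on that reduced phenotype; from generation 1 onward all
  terms are present.
* **Theory comparison under AM** (`expected_total()`) plugs *realized*
  quantities into the closed forms: per-locus mate genotype correlations
  $\bar\rho_j$ measured from the actual pairings, allele frequencies from
  the parent generation, and $k_{ij}$ estimated as correlations between
  per-locus *genotypic values* of the predicted generation. Using value
  (effect-weighted) rather than raw dosage correlations keeps the sign of
  the cross term correct when effect sizes differ in sign across loci,
  since AM aligns trait-increasing alleles, not A2 alleles.
* **Variance decomposition** (`decompose_variance()`) uses the true
  simulated effects — an internal-validity check, not an estimator of
  unknown effects (marginal family-based estimates are confounded; a
  per-locus joint regression is included as `fit_trio_effects()` purely
  as a diagnostic). Components plus twice the covariances reconstruct the
  total exactly by construction, which the tests assert.
* **Trio versus sibling-difference runs.** Sibling effects belong to the
  sibling-difference design; the trio closed forms exclude them. The
  replicated comparison `variance_experiment()` therefore runs trio cells
  with $\beta_s = 0$ and sibling-difference cells with the sibling class
  active.

## Relatedness curves

`relatedness_curve()` bins pairs by genomic relationship
$\pi$ (standardized-dosage cross-products at the causal loci) and computes
per-bin Pearson correlations of the members' phenotypes, each unordered
pair entered once in randomized order (symmetric double entry is an
option). Default bin width 0.01 with at least 30 pairs per bin keeps
standard errors finite at desk scale. A weighted least-squares line over
$\pi \in [-0.02, 0.02]$ estimates the unrelated-pair slope; under direct
effects and random mating it recovers the injected direct variance because
with effects drawn independently per locus the expected pair covariance is
exactly (direct variance) $\times\ \pi$ at the causal loci. Pairs are
streamed in blocks, so the full relationship matrix is never materialized.
`full_sib_correlation()` pools all within-family sibling pairs.

Under equilibrium assortment calibrated to a mate causal-score correlation
of 0.2 with direct variance 0.5 and environment 0.5, the infinitesimal
recursion gives equilibrium genetic variance
$V = 0.5/(1-0.2) = 0.625$, sibling genetic covariance $V(1+0.2)/2 =
0.375$ and hence a full-sib phenotypic correlation of
$0.375/1.125 \approx 0.333$ — the simulator reproduces this, and it is
the quantity `scripts/acceptance.R` recomputes end to end.

## Problem sizes and numerical choices

The replicated variance comparison runs 10 replicates of 4,000 individuals
over 10 generations at 200 causal loci per scenario/regime/design cell;
relatedness analyses use 8,000 individuals at 1,000 causal loci. These
sizes give replicate-level agreement of simulation and theory well inside
2 SD while keeping a full run at desk scale. Weight normalization in the
enumeration is guarded at 1e-12; monomorphic loci are excluded from
relatedness with a logged count; negative per-locus variances (impossible
for physical parameters, but conceivable through user-supplied overrides)
abort the multilocus combination rather than being clamped. Disassortative
mating ($\rho < 0$) is rejected: the mating-frequency model is only
established for $\rho \geq 0$.

## Limitations

The synthetic founder panel has geometric LD decay and no mutation,
selection, migration, sex chromosomes, dominance or epistasis; mate choice
by phenotype ordering is deliberately stylized; generations do not
overlap. Passing tests therefore demonstrate internal consistency of
theory and simulation under these idealizations, not that any particular
human trait follows the fitted numbers. Observed external quantities
(e.g. biobank sibling correlations) are not reproduction targets of this
package.
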