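---
title: "Methods: GBLUP prediction of barley seed quality traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GBLUP prediction of barley seed quality traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barleyGP)
```

This vignette is the package's account of its statistical machinery: the
mixed model and its assumptions, the choices made where several
reasonable conventions exist, the numerical strategy, and what the
synthetic breeding-program generator does and does not emulate.

## The mixed model

For each trait, plot-level records follow

$$y = Xt + Z_1 g + Z_1 l + Z_2 c + e$$

* $t$ — fixed trial-structure effects. For standardized seed weight
  (SSW), protein and protein yield the fixed factor is year×location;
  for test weight and ergosterol it is year×location×trial, reflecting
  that the NIT instrument readings vary more between trials. Fitted as
  cell means (one level per factor combination).
* $g \sim N(0, G\sigma^2_g)$ — additive genomic values, with $G$ the
  VanRaden relationship matrix built from −1/0/+1 marker codes. The
  frequencies $p_i$ entering $P$ and the denominator
  $2\sum p_i(1-p_i)$ are recomputed from the QC'd, imputed matrix, so
  the columns of $Z = M - P$ have exactly zero mean and $G$ is
  invariant to flipping which allele is counted at any marker.
* $l \sim N(0, I\sigma^2_l)$ — an iid line effect: genetic variance the
  marker panel does not capture. Dropped for protein yield, where the
  data do not support separating $g$ and $l$.
* $c \sim N(0, I\sigma^2_c)$ — line-by-environment interaction, always
  indexed by line × (year×location), including for traits whose fixed
  factor is finer (trial): the interaction of interest is with the
  growing environment, not the trial layout.
* $e \sim N(0, I\sigma^2_e)$ — plot residual.

Line-mean heritability for a line tested in `n_env = 2` environments
with `n_reps = 6` plots is
$h^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_l + \sigma^2_c/2 +
\sigma^2_e/6)$, its standard error comes from the delta method on the
inverse average-information matrix, and $\sqrt{h^2}$ is the expected
correlation between line means and true genomic values — the accuracy
ceiling.

Phenotyped lines without genotypes (the replicated check varieties) are
excluded from the analysis by default; `ungenotyped = "identity"`
instead appends an identity block scaled to `mean(diag(G))` so their
records still inform the fixed effects.

## Numerical strategy

**G is structurally singular.** Because $Z$'s columns are centered with
data-derived frequencies, $G\mathbf{1} = 0$: the VanRaden matrix always
has the ones vector in its null space (and more null directions when
lines are clones). Any scheme that inverts $G$ therefore works with an
artificially ridged, ill-conditioned matrix; in development this made
the REML trace computations noisy enough to destroy convergence. The
package instead factorizes $G = LL'$ by eigendecomposition (dropping
null-space directions at a $10^{-10}$ relative tolerance) and fits the
exact reparameterization $g = La$, $a \sim N(0, I\sigma^2_g)$. The
likelihood and every BLUP are identical to the $G$-covariance model; no
inverse of $G$ appears anywhere; and every random block of the
mixed-model equations has an identity prior, so all REML traces are
diagonal sums.

**AI-REML with EM fallback.** Each iteration forms the MME coefficient
matrix $C = W'W/\sigma^2_e + D$ (one Cholesky + inverse per iteration),
from which the restricted likelihood, analytic scores, EM updates and
the average-information matrix are all assembled. The AI (Newton) step
is taken on the free components; a component proposed negative is set
to its floor ($10^{-8}\times$ phenotypic variance) and, if its score
still points outward, frozen out of subsequent AI updates (an active
set). If an AI step would decrease the likelihood the iteration falls
back to the EM update, which cannot. Convergence requires
$|\Delta \log L| < 10^{-8}$ and a maximum relative component change
$< 10^{-6}$; non-convergence within `max_iter = 200` is an error that
carries the full trajectory. The AI matrix at the optimum is the
curvature used for component and heritability standard errors. The
test suite verifies the likelihood value and all four analytic score
components against a dense $V$-matrix evaluation.

**Cross-validation folds are exact downdates.** Masking a line removes
its records from $W'W$ and $W'y$; the fold system differs from the
full-data system by a low-rank term. With the full-data $C^{-1}$
precomputed, each leave-one-out or leave-family-out fold is solved by
the Woodbury identity in $O(\dim \times k)$ for $k$ removed records —
exact, not approximate (verified against refactorization to $10^{-13}$).
Folds that empty a fixed-effect level (leave-set-out, where the
held-out year's year×location cells lose all records) or remove more
than a quarter of the records refactorize densely instead, dropping the
empty levels with a warning; prediction into the unseen environment
then flows only through $G$, which is precisely the across-set
question. The training-size experiment builds a small per-subset
system instead, since there lines outside the subset must not enter
training at all.

**Corrected phenotypes** ($y - X\hat t$ averaged per line, with $\hat t$
from the full-data fit) are computed once and used by every design, so
pooled accuracies are comparable across designs. Variance components
are likewise estimated once from the full data and held fixed inside
folds; `reestimate-per-fold` behaviour can be had by calling `reml()`
on the training subset, but fixed components are the default because
small folds cannot estimate four components stably.

## Conventions chosen where several were defensible

* **Allele orientation**: the counted ("second") allele is the
  lexicographically larger symbol; $G$ is provably invariant to the
  choice, and the tests assert it.
* **QC order**: monomorphic markers → lines with more than 2% missing
  calls → minor allele frequency ≥ 5% (inclusive, with a $10^{-9}$
  guard against floating-point representation of exact boundaries),
  with frequencies recomputed after line removal. The per-line
  missingness rule can be read per-marker instead
  (`marker_missing_max`); both readings are available because the
  combination is genuinely ambiguous. Residual missing calls are
  imputed by the marker mean $2\hat p_i - 1$, which preserves each
  marker's mean exactly and is the natural completion for a centered-Z
  model.
* **SSW**: the sieve-fraction weights are heavily skewed, so the f2.5
  and f2.2 fractions are rank-inverse-normal transformed
  ($\Phi^{-1}((r-0.5)/n)$, average ranks for ties; Blom's offset
  available) across all plots and averaged; the sign is flipped so
  larger seeds give larger SSW. Orientation only flips GEBV signs,
  never |accuracy|; the fraction set and a within-environment variant
  are arguments.
* **PCA** of $G$ is column-centered (`prcomp`) by default, uncentered
  by flag; proportions of variance are reported on whichever scale was
  used.
* **Heat-map ordering** uses the genomic distance
  $d^2(i,j) = G_{ii} + G_{jj} - 2G_{ij}$ with complete linkage.
* **LFO multiplicity**: a family is all lines sharing one parent;
  families need at least 4 lines; a line held out under both of its
  parents contributes the mean of its two held-out GEBVs to the pooled
  correlation.
* **Reduction schedules**: sizes shrink by 10% of the *original* count
  per step (compounding by flag). Marker thinning samples only mapped
  markers — the spacing rule needs cM positions — so step sizes are
  fractions of the mapped count; subsets allocate per chromosome by
  largest remainder and enforce ≥ 1 cM spacing, halving the spacing
  whenever the quota is otherwise unreachable (co-located markers can
  never co-occur, since their distance is below any positive spacing).

## What the simulator emulates

`sim_config()` defaults describe the study design the package targets:
two breeding sets of 119 and 190 F6 lines, grown in their own year at
2 locations × 3 replicates; 104 inbred founder parents of which 16 are
used by both sets; 50 crosses per set with lines assigned to crosses
uniformly (so family sizes vary, and families of > 3 lines number a few
dozen); ~3,500 biallelic markers spread near-equally over 7 chromosomes
of 150 cM; founder allele frequencies uniform on [0.1, 0.9]; 1% missing
calls; two non-genotyped check lines sown once per trial and block.
Meiosis is a Poisson crossover process at 1 crossover/100 cM without
interference; five selfing generations leave $(1/2)^5 \approx 3\%$ of
segregating loci heterozygous, matching F6 material.

Traits are simulated from `n_qtl = 100` markers drawn at random with
iid normal effects — many small-effect QTL, as seed quality traits
behave — plus iid line, line×environment and plot effects at the
configured variances. Default components per trait are the estimates
for the 309-line panel (SSW 0.014/0.009/0.006/0.009 and so on); grain
yield, which that table does not cover, uses components (4, 2, 3, 9 on
hkg²·ha⁻²) giving a realistic ~5% CV around a 90 hkg·ha⁻¹ mean so
protein yield can be derived. Fixed environment effects are a
deterministic spread of ±0.5 total-SD around the trait mean. Sieve
fractions are strictly monotone logistic transforms of the per-plot
seed-size value, so the rank-based SSW recovers it exactly up to
standardization.

**Scale convention.** True breeding values are rescaled so their
empirical variance equals $\sigma^2_g \times$ mean diagonal of the
QTL-marker GRM (≈ 2 for inbred lines). This makes the simulated data
consistent with the fitted covariance $G\sigma^2_g$ — the model's
$\sigma^2_g$ is per unit of $G$, whose diagonal for fully homozygous
lines is 2 — so REML recovers the configured components on their own
scale. Configuring variance $v$ for $g$ therefore produces line-level
genetic variance $\approx 2v$; the alternative convention (TBV variance
$= \sigma^2_g$ exactly) would make every recovered $\hat\sigma^2_g$
half the configured value.

What the generator does **not** emulate: selection between generations,
dominance and epistasis, genotyping error beyond random missingness,
linkage disequilibrium between founder alleles (founder genotypes are
drawn independently per marker, so baseline LD comes only from the
crossing structure), spatial field trends, and trait-trait genetic
correlations (QTL are drawn independently per trait). Passing tests on
synthetic data therefore demonstrate correctness of the estimation and
cross-validation machinery under the stated model, not robustness to
real-data pathologies such as assay batch effects or structured
missingness.

## Validation problem sizes

The test suite exercises: solver-vs-oracle equivalence on 200 random
instances of up to 15 lines (tolerance $10^{-8}$); variance-component
recovery within 25% relative error, and $h^2$ within ±0.07, on one
600-line simulation at the SSW components with 2 environments × 3
replicates; and the design ordering LOO ≥ LFO ≥ LSO-across-unrelated-
sets over 10 simulated 300-line populations (gap ≥ 0 within 2 Monte
Carlo SEs), with the training-size experiment at 8 steps × 4 replicates
and the marker-thinning experiment at 9 steps × 3 replicates on one of
them. These sizes were chosen as the smallest at which the Monte Carlo
error is comfortably below the effects being asserted.

## Known limitations

* Single-trait models only; no multi-trait covariances, no marker-effect
  (SNP-BLUP) reparameterization, no Bayesian alternatives.
* The residual-line variance $\sigma^2_l$ is weakly identified against
  $\sigma^2_g$ in panels where $G$ is close to an identity-plus-constant
  structure; its estimate carries the largest sampling error, and at
  600 lines its recovery error is the closest to the 25% band.
* Expected-accuracy queries (`expected_accuracy()`) implement the
  deterministic $\sqrt{Nh^2/(Nh^2 + M_e)}$ formula; estimating the
  effective number of segments $M_e$ from data is out of scope.
* The dense per-iteration Cholesky limits comfortable problem sizes to
  a few thousand lines; that covers the breeding-program scale the
  package targets.
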