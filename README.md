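# barleyGP

GBLUP genomic prediction for seed quality traits in spring barley
breeding programs.

Commercial barley breeders phenotype thousands of plots per season to
select on traits such as seed size, protein content, test weight and
fungal load (ergosterol). Genomic selection replaces much of that
phenotyping: lines are genotyped on a SNP chip, a training set with both
genotypes and field records calibrates a mixed model, and selection
candidates are ranked by genomic estimated breeding values (GEBVs)
computed from marker relationships alone. `barleyGP` implements that
workflow for the two-breeding-set, replicated-trial design typical of a
northern-European spring barley program, together with the
cross-validation designs used to decide whether it works: can a new
breeding set be predicted from last year's? a family from unrelated
families? how small can the training set, or the marker panel, get?

## The model

Marker calls are coded −1/0/+1 (homozygote, heterozygote, opposite
homozygote) into a matrix **M**. With `p_i` the frequency of the counted
allele at marker *i*, the VanRaden genomic relationship matrix is

    G = Z Z' / (2 Σ p_i (1 − p_i)),   Z = M − P,   P_i = 2 (p_i − 0.5)

Plot-level phenotypes follow the linear mixed model

    y = X t + Z₁ g + Z₁ l + Z₂ c + e

with fixed trial effects `t` (year×location, or year×location×trial for
test weight and ergosterol), additive genomic values `g ~ N(0, G σ²g)`,
iid line effects `l ~ N(0, I σ²l)` capturing genetic variance the
markers miss (dropped for protein yield), line-by-environment
interactions `c ~ N(0, I σ²c)` and plot residuals `e ~ N(0, I σ²e)`.
Variance components are estimated by average-information REML with EM
fallback; GEBVs solve Henderson's mixed-model equations at those
components. Line-mean heritability for a line tested in 2 environments
with 6 plots is

    h² = σ²g / (σ²g + σ²l + σ²c/2 + σ²e/6)

and `√h²` is the ceiling on prediction accuracy. Accuracy is the
correlation between GEBVs of held-out lines and their phenotypes
corrected for fixed effects; the regression slope of corrected
phenotypes on GEBVs measures dispersion bias (1 = none).

Cross-validation designs: `cv_loo()` (leave one line out), `cv_lso()`
(leave a breeding set out, both directions), `cv_lso_random()` (random
partitions of the same sizes, SD over replicates), `cv_lfo()` (leave out
a family = all lines sharing a parent), `reduce_training()` and
`reduce_markers()` (accuracy as the training set or the cM-spaced marker
panel shrinks).

A breeding-program simulator (`sim_config()`, `simulate_dataset()`)
generates inbred founders, biparental crosses selfed to F6 with Poisson
recombination, and replicated two-location trials with known variance
components, so every stage can be validated against truth.

## Worked example

Simulate a program with the default study conditions — two breeding sets
of 119 and 190 F6 lines from partially overlapping parents, ~3,500
mapped markers on 7 chromosomes, 2 locations × 3 replicates — then run
QC, fit the model for standardized seed weight (SSW) and cross-validate:

```r
library(barleyGP)

sim  <- simulate_dataset(sim_config(set_sizes = c(119, 190), seed = 2016))
enc  <- encode_genotypes(sim$calls)
qc   <- apply_qc(enc, maf_min = 0.05, line_missing_max = 0.02)
geno <- impute_missing(qc$matrix)
G    <- build_grm(geno)

spec <- model_spec("ssw")
fit  <- reml(spec, sim$phenotypes, G)
fit
#> AI-REML fit for 'ssw' (1854 records, 8 iterations)
#>  component    estimate           se
#>          g 0.010485431 0.0025806947
#>          l 0.010790852 0.0031499212
#>          c 0.006608004 0.0007824332
#>          e 0.008916375 0.0003586692
#> logL: 2785.004354

heritability(fit)
#> h2 = 0.402 (SE 0.100), max accuracy = 0.634

cv_loo(spec, sim$phenotypes, G, fit)
#> LOO cross-validation: 309 lines predicted, accuracy 0.473, bias 1.007
cv_lfo(spec, sim$phenotypes, G, fit, sim$pedigree)
#> LFO cross-validation: 305 lines predicted, accuracy 0.419, bias 1.867
cv_lso(spec, sim$phenotypes, G, fit)
#>  training_set n_train n_test  accuracy     bias
#>            S1     119    190 0.3078403 1.695858
#>            S2     190    119 0.3520325 1.472085
```

Reading the output: the four variance components put the line-mean
heritability at 0.40, so no predictor can beat an accuracy of ~0.63 on
this trait in this design. Leave-one-out reaches 0.47 — close to the
ceiling, as expected when every line has close relatives in training.
Holding out whole families (0.42) and whole breeding sets (0.31–0.35)
costs accuracy because the training set is less related to the
candidates, the pattern that matters when deciding whether next year's
lines can be predicted from this year's data. A bias above 1 means the
GEBVs are under-dispersed relative to the corrected phenotypes.

`run_pipeline()` drives the same stages (simulate or load → QC → GRM →
PCA → REML + h² → chosen CV designs) from one YAML/list config with
per-stage child seeds and writes all tables plus a `summary.json`.

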