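---
title: "Models and methods in bayesrqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in bayesrqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bayesrqtl)
```

`bayesrqtl` implements whole-genome regression for multi-breed dairy
reference populations that mix two kinds of records with very different
precision: cow trait deviations (own performance, repeated up to `r` times)
and bull daughter trait deviations (averages over `d` effective daughters).
This vignette is the package's account of the models, the numerical choices,
and what the synthetic-data generator can and cannot show.

## The model

All analyses fit one linear model to the reference records,

$$ \mathbf{y} = \mathbf{X b} + \mathbf{Z a} + \mathbf{W v} + \mathbf{e}, $$

with fixed effects **b** (overall mean, breed, and sex nested within breed,
reference-level coded with rank-deficient columns dropped), pedigree
polygenic values **a** ~ N(0, **A**&sigma;&sup2;<sub>a</sub>) with **A** the
numerator relationship matrix, SNP effects **v** on column-standardized
dosages **W**, and heteroscedastic residuals
**e** ~ N(0, **E**&sigma;&sup2;<sub>e</sub>), **E** = diag(1/w<sub>i</sub>).

### Record weights

The weights scale every record to the error variance of a single own
performance record:

* bulls: w = d(1 − h²)/(4 − h²) — zero effective daughters means an
  uninformative record, which is dropped with a warning rather than kept at
  infinite error variance;
* cows: w = r(1 − h²)/(1 + (r − 1)t − r h²), which is exactly 1 at r = 1.

`h²` is the single-record heritability and `t` the repeatability;
`trait_params()` ships presets (milk traits 0.33/0.56, stature 0.45,
fertility 0.03/0.05, survival 0.025/0.035). The weight functions admit the
degenerate boundary h² = 0 (they reduce to d/4 and r/(1 + (r−1)t)) even
though the presets keep h² > 0.

Milk composition deviations (fat or protein fraction) are derived from the
yield deviations by linearising the ratio at the within-breed population
means: `composition_deviation()` returns
(Y<sub>P</sub>/M<sub>P</sub>)(y/Y<sub>P</sub> − m/M<sub>P</sub>) on the
fraction scale; multiply by 100 to report percent. The formula itself is
scale-free, so the package standardises on fractions and leaves rendering to
the caller.

### GBLUP

`gblup()` builds the genomic relationship matrix from standardized dosages,
`w_std = (x − 2p)/sqrt(2p(1−p))`. Two diagonals are available: the plain
cross-product `G = WW'/m` (default) and the adjusted self-relationship
`1 + f_hat` with the method-of-moments inbreeding estimator
`(x² − (1+2p)x + 2p²)/(2p(1−p))`. Off-diagonals are always the plain
cross-product. Back-solving SNP effects, `v_hat = W'G⁻¹g_hat/m`, reproduces
`W v_hat = g_hat` exactly only with the plain diagonal, which is why plain is
the default whenever effects are back-solved; with the adjusted diagonal the
identity is approximate. Allele frequencies are computed once from every
genotyped animal supplied (reference plus validation), so validation
genotypes are standardized against the same frequencies as training.

Variance components come from EM-REML (`estimate_variance_components()`),
written in the projection-matrix form with the monotone updates
σ²<sub>c</sub> ← σ²<sub>c</sub> + σ⁴<sub>c</sub>(y'P V<sub>c</sub> P y −
tr(P V<sub>c</sub>))/q<sub>c</sub>; iteration stops when every component
changes by less than 1e-6 relative, or at 200 iterations with a warning and
the last iterate (EM is reliable but slow near variance boundaries; point
estimates at this tolerance are what the downstream solvers need). Standard
errors come from the inverse expected information. Known variance components
can be supplied to skip REML entirely. The mixed-model equations are solved
by one dense factorisation; the solver refuses systems beyond 20000
equations — this is a desk-scale tool, not a national evaluation engine.

### The extended BayesR sampler

SNP effects get a four-component normal-mixture prior with variances 0,
0.0001, 0.001 and 0.01 times σ²<sub>a2</sub>, the additive genetic variance
explained by the pedigree, estimated up front by fitting `y = Xb + Za + e`
(or supplied). Mixture proportions have a Dirichlet prior with one marker
per component. Each Gibbs iteration cycles:

1. σ²<sub>e</sub> ~ ẽ'E⁻¹ẽ / χ²<sub>n−2</sub>,
2. **b** jointly from N([X'R⁻¹X]⁻¹X'R⁻¹y*, [X'R⁻¹X]⁻¹),
3. each polygenic effect from its single-site conditional (precision
   z<sub>i</sub>'R⁻¹z<sub>i</sub> + A<sup>ii</sup>/σ²<sub>a</sub>; animals
   without records shrink to the pedigree expectation),
4. σ²<sub>a</sub> ~ ã'A⁻¹ã / χ²<sub>q−2</sub>,
5. for every marker, in a fresh random permutation: sample a mixture
   component by log-sum-exp softmax over the component log-scores
   −½[log(1 + W'R⁻¹W σ²<sub>k</sub>) − (W'R⁻¹y*) v<sub>jk</sub>] +
   log pr<sub>k</sub>, then the effect from
   N(v<sub>jk</sub>, [W'R⁻¹W + σ<sub>k</sub>⁻²]⁻¹) (exactly 0 in the
   point-mass class),
6. pr ~ Dirichlet(α + class counts).

Numerical choices worth stating. The scaled-inverse-χ² draws use the
conventional conjugate form S/χ²<sub>df</sub> (so the literal mean of the
draw distribution is S/(df − 2)); degrees of freedom are n − 2 for the
residual and q − 2 for the polygenic variance with q the number of pedigree
animals. The term y*'R⁻¹y*, constant across components, is dropped from the
log-scores because it cancels in the softmax. Residuals are updated
incrementally after every accepted change and recomputed from scratch every
1000 iterations to bound floating-point drift (the largest observed gap is
reported as `resid_drift_max` and is asserted below 1e-8 in the tests).
Fixed effects are drawn as one block. Chain seeds are `seed + chain - 1`
and recorded in the fit.

The sweep loop lives in C++ (Rcpp/RcppArmadillo), as is usual for MCMC
whole-genome regression; it draws from R's RNG so runs are reproducible from
`set.seed()`. The same full conditionals are also exposed as small R
functions (`draw_error_variance()`, `snp_component_scores()`, ...) that the
unit tests check against closed forms and Monte-Carlo moments; the compiled
chain is validated end-to-end against two oracles: restricted to a single
non-zero component with frozen proportions it must match closed-form ridge
regression (r > 0.99), and its polygenic block must track the mixed-model
solutions.

Defaults mirror standard practice for this model family: 30000 iterations,
20000 burn-in, five replicate chains, posterior means over all post-burn-in
samples without thinning, final estimates averaged across chains. The tests
and the acceptance script run much shorter chains (stated below) because
their problems are small.

### Validation scoring and QTL mapping

Predictions are `y_hat_v = W v_hat` (SNP-only) and
`y_hat = a_hat + W v_hat`; accuracy is the plain Pearson correlation with
the validation phenotype, bias the regression of phenotype on prediction
(1 = no dispersion error), and the reported approximate standard error is
1/sqrt(n), rounded to three decimals. Scoring is done within breed plus
pooled.

`map_qtl()` slides 250 kb windows in 50 kb steps along each chromosome
(0-based half-open internally; a chromosome shorter than one span gets a
single covering window). Local GEBV are the within-window part of the
genomic value; their variance across animals is computed per breed and
pooled, and a window is called a QTL when its variance strictly exceeds 50
times the mean over marker-bearing windows ("average window" = mean over
windows with at least one marker; empty windows are excluded — the rule is
otherwise ill-defined). Trait-pair correlations of local GEBV are computed
only where both traits strictly exceed 3 times their average window.
Flagged windows whose midpoints are less than 0.5 Mbp apart *and* whose
per-trait sign patterns agree (each trait classified −/+/n against the
window's dominant trait, n below the 3x filter) merge into one region.
Regions are labelled with the nine-class scheme: prefix = the yield trait
(FY/MY/PY) with the largest region variance ratio; suffix − if the
region-level local GEBV of the top trait correlates negatively with any
other yield trait passing the filter, + if any passing correlation is
positive, n if none passes. Regions where only a composition trait passes
are grouped with MYn (a composition shift is read as a sensitive
milk-volume signal); regions with nothing above the filter are reported
unclassified. Overlapping windows double-count variance by construction;
regions, not windows, are the unit of interpretation.

## The synthetic-data generator

`simulate_dataset()` emulates the study design the estimators target: two
reference breeds (A, large; B, smaller) contributing bulls and cows, and a
third breed C that never enters the reference and is only predicted.

* **Genotypes.** Founder haplotypes carry first-order Markov LD (a latent
  uniform copied from the previous marker with probability `ld = 0.9`;
  marginal frequencies Uniform(0.1, 0.9) are preserved). Each breed then
  drifts independently: its haplotype pool (200 haplotypes from a base pool
  of 400) is resampled for 30 generations as random gametes with Poisson
  crossovers at `recomb_rate = 1e-7` per bp — one Morgan per simulated
  10 Mb chromosome, a deliberately compressed genetic map so that LD decays
  over the simulated chromosome lengths the way it does over real cattle
  chromosomes. Without recombination, bottleneck resampling alone produces
  whole-chromosome haplotype blocks in which every marker tags the entire
  chromosome and window-level QTL localisation is impossible in principle;
  with it, short-range marker-QTL LD persists while long-range and
  between-breed LD decay, which is exactly the phenomenon the QTL-mapping
  and across-breed prediction modules need.
* **Effects.** Component labels use exact per-class counts by default
  (100/30/20 markers at multipliers 1e-4/1e-3/1e-2 of σ²<sub>a2</sub>, the
  rest exactly zero), or multinomial proportions. Effects are
  N(0, multiplier × σ²<sub>a2</sub>). At desk scale two facts about real
  dense-genotype analyses cannot both be reproduced: their per-class marker
  counts (thousands/hundreds/tens at 632k markers, i.e. tens/ones when
  scaled to m = 5000) and their SNP share of the additive variance (well
  over half). The generator follows the count reading — the large-QTL count
  is the quantity the QTL-mapping experiments are about — so the markers
  carry roughly a quarter of the additive variance and the polygenic layer
  the rest.
* **Polygenic calibration.** By default the pedigree polygenic variance is
  set so that markers plus polygenic equal σ²<sub>a2</sub> exactly
  (`poly_frac = NULL` auto-calibrates). This keeps the generator self-consistent: the mixture-class
  variances are true fractions of the additive variance that the prior-scale
  REML fit estimates, as they are in real populations where most additive
  variance sits outside the largest classes. The pedigree is two
  generations: unrelated founder sires and dams per breed, genotyped animals
  as their offspring in half/full-sib families. The polygenic values are
  generated down the pedigree independently of the marker genotypes, which
  is a simplification: in real data the "polygenic" residual is still
  marker-linked.
* **Phenotypes.** Records are y = Xb + g + a + e with e ~
  N(0, σ²<sub>e</sub>/w<sub>i</sub>); cows draw r from {1, 2, 3}
  (0.5/0.3/0.2), bulls draw d = 20 + round(Gamma(2, 60)) (every bull has at
  least 20 effective daughters). Bull records emulate daughter trait
  deviations directly as g + heteroscedastic noise — only the weight
  structure matters to the estimators, so daughters themselves are never
  simulated. σ²<sub>e</sub> is set from the realised genetic variance so a
  single-record cow sees heritability h². Fixed effects are known breed
  means (0, 0.6, 0.3) and a sex effect of 0.25 for females.

What passing tests on this generator do **not** show about real data: no
genotyping or imputation error, no selection (reference animals are random
members of their breed), no marker-linked polygenic residual, exact HWE
within the founder pool, and an idealised map with evenly spaced markers.
Results on the generator demonstrate the estimators' correctness and the
qualitative method contrasts, not field performance.

## Study sizes used by the tests and the acceptance script

These are the package's chosen desk-scale conditions; the paper-scale
defaults (30000/20000/5 chains) remain the function defaults.

* Default bundle: 1500 reference records (A: 700 bulls + 400 cows, B: 250 +
  150), 450 validation animals (breed C: 120; C drifts three times as many
  generations as the reference breeds, emulating distinct ancestry),
  m = 5000 markers on 5 × 10 Mb chromosomes. BayesR runs 2 chains × 2500
  iterations (1000 burn-in); the prior scale is estimated by pedigree
  EM-REML on a 600-record subsample; a permuted-phenotype refit provides the
  null. Because bundle-level summaries (truth correlation, class counts,
  accuracies) are stochastic across simulated bundles, the acceptance checks
  evaluate their medians over three seeded replicates.
* Ridge-oracle check: n = 300, m = 500, single non-zero component of known
  variance, 6000 iterations (2000 burn-in).
* QTL-localisation experiment: 20 replicates at n = 400 records, m = 3000
  markers on 12 × 5 Mb chromosomes, a 230-marker small-effect background
  plus one planted QTL. The QTL effect is fixed at sqrt(0.01 σ²<sub>a2</sub>)
  on a marker with MAF ≥ 0.15 — i.e. exactly ten percent of a single-record
  phenotype's variance — rather than drawn from the 0.01 class, because a
  drawn effect usually realises far less variance than its class label
  suggests and the experiment is about a QTL of known size. BayesR runs one
  1500-iteration chain per replicate; GBLUP is fitted by REML. The genome is
  long enough (over 1100 windows) that a ten-percent QTL can clear the 50x
  call threshold; the BayesR-vs-GBLUP span comparison is measured at the 3x
  profile threshold on the QTL chromosome, because GBLUP's back-solved
  signal is diluted below the 50x call threshold essentially always and a
  comparison there would be vacuous.

## Known limitations

* EM-REML can hit its 200-iteration cap on small weighted data sets; it
  warns and returns the last iterate, which is adequate for the solvers but
  not a converged likelihood maximum.
* The dense MME solver and the tabular NRM are O(n²)–O(n³); a few thousand
  animals is the intended ceiling.
* The mixture sampler's class counts for the two smallest classes are not
  identifiable at desk scale (effects of variance 1e-4 σ²<sub>a2</sub> are
  far below the detection limit at n = 1500); only the largest class count
  is a meaningful recovery target.
* Marker-wise correlation between posterior-mean and true effects is a
  volatile summary at n = 1500, m = 5000: the unrecoverable small classes
  add true-effect variance no estimator can touch, the realized LD draw
  moves the marker share of the additive variance from bundle to bundle,
  and strong local LD lets the sampler place mass on a QTL's neighbours
  (which prediction and window variance capture but marker-wise correlation
  punishes). Across simulated bundles it ranges roughly 0.15-0.75; the
  window-level and prediction-level summaries are far more stable and are
  the ones to trust at this scale.
* Yang-diagonal GRMs break the exact back-solve identity; the package warns
  by documentation, not at run time.
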