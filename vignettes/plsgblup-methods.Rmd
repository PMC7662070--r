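---
title: "Marker-prioritised multi-trait genomic prediction: models and design"
author: "plsgblup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-prioritised multi-trait genomic prediction: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Productivity traits in forest-tree breeding — diameter at breast height is
the canonical example — tend to have low narrow-sense heritability and
correspondingly poor prediction accuracy, while companion wood-quality traits
are often moderately to highly heritable. Multi-trait GBLUP can transfer
information from the well-measured traits to the poorly heritable one through
the genetic correlation structure, and marker prioritisation can concentrate
the genomic relationship matrix on markers that actually carry the shared
(pleiotropic) signal. `plsgblup` implements that pipeline end to end:
two-stage phenotype correction, two-block canonical partial least squares
(PLS-CA) for marker loadings, percentile truncation into 0/1 marker weights,
pedigree/VanRaden/weighted relationship matrices, Bayesian univariate and
multi-trait GBLUP by Gibbs sampling, and k-fold cross-validation with
in-fold marker selection.

## Models

**Phenotype correction (stage 1).** Per trait, ordinary least squares
`y = X beta + e` with the declared design factors (replicate,
block-in-replicate, seed orchard). `correct_phenotypes()` returns either
intercept-plus-residual values averaged per genotype, or genotype BLUEs
(clonal means adjusted for design) when a clone factor with ramets is
present. The corrected values are the `Y` of every later stage, so kernel
models need only trait-wise intercepts.

**PLS-CA (stage 2).** With column-standardised marker block `X` and trait
block `Y`, component k maximises `Cov(X u_k, Y v_k)` under unit-norm
loadings; the solution is the leading singular pair of the deflated
cross-product `X_k' Y_k`. Both blocks are deflated on their *own* latent
scores (canonical mode), which makes within-block scores orthogonal across
components. Signs are fixed by making the largest-magnitude entry of `v_k`
positive, so selection tails are reproducible across platforms.

**Percentile truncation.** The marker loadings `u_k` are cut at the
empirical percentile with linear interpolation between order statistics at
position `h = 1 + (p/100)(n - 1)` and `>=`-inclusion at the threshold. For
distinct loadings the selected count is then a closed form in `(n, p)`
alone — e.g. 9,697 loadings at the 90th percentile always select 970 —
which is what makes the selection rule desk-checkable. One-tailed mode keeps
the top positive loadings (positive pleiotropy); two-tailed mode keeps both
tails (`>=` the p-th percentile or `<=` the (100-p)-th), capturing markers
whose effects oppose each other across traits. Multi-component scenarios
take the union of the per-component selections, so counts grow with the
number of components and with decreasing percentile.

**Relationship matrices.** The pedigree matrix `A` uses the recursive
tabular method. The genomic matrix is VanRaden's
`G = Z Z' / (2 sum p_i (1 - p_i))` with `Z = M - 2p` and frequencies always
taken from the analysed sample (no external reference population is
assumed). The weighted matrix is `G_w = Z W Z' / sum(w_i)` exactly as
defined — no heterozygosity factor — so with 0/1 weights it is the
cross-product over selected markers divided by the selected count. Its
scale therefore differs from `G` (mean diagonal near the mean `2p(1-p)`
over selected markers); variance components from `G_w` sit on that other
scale, while correlations, rankings and prediction accuracies are
scale-invariant. A `vanraden_scale = TRUE` escape hatch rescales by
`2 sum(w_i p_i (1 - p_i))` for users who need `G`-comparable variance
components.

**Bayesian GBLUP (stage 3).** `gblup()` fits `Y = X B + a + e` with
`var(a) = Sigma_a %x% K` and `var(e) = Sigma_e %x% I` by Gibbs sampling:
flat prior on `B`, inverse-Wishart full conditionals for `Sigma_a` and
`Sigma_e`. The genetic values are sampled in the eigenbasis of `K`, where
their full conditional factorises over eigen-coordinates; a further
per-iteration rotation that simultaneously diagonalises `Sigma_e` and
`Sigma_a` reduces each coordinate to independent scalar updates, so an
iteration costs a handful of `n x t` matrix products. Zero eigenvalues
(rank-deficient `G`, duplicated clones) are handled exactly — those
directions simply carry no genetic variance — so no diagonal jitter is
needed for fitting (an `ensure_pd()` helper exists for exporting matrices
to other software). Missing cells, including individuals with every trait
missing, are data-augmented from their residual full conditionals, which
makes cross-validation masking exact rather than a post-hoc projection.

Heritability and genetic correlations are computed per retained draw,
`h2 = sigma_a^2 / (sigma_a^2 + sigma_e^2)` and
`r_G = sigma_axy / sqrt(sigma_ax^2 sigma_ay^2)`, then averaged — never from
averaged covariance components, because the ratio of means differs from the
mean of ratios on skewed posteriors. When an extra i.i.d. random effect
(block-in-replicate) is present, `h2` still uses only the genetic and
residual variances, matching the conventional report. Model choice uses the
deviance information criterion on the *conditional* likelihood
`p(Y | B, a, Sigma_e)` over observed cells (`DIC = 2 mean(D) - D(theta-bar)`,
`pD = mean(D) - D(theta-bar)`); conditional and marginal DIC differ, and the
conditional version matches the reporting convention of the Gibbs samplers
this implementation follows.

**Priors.** `nu_a = nu_e = t + 2` and scale matrices set so each of the
genetic and residual components has prior mean equal to half the observed
phenotypic variance per trait — weakly informative and centred on an even
variance split. Both are overridable via `prior =`. A consequence worth
knowing: variance components are only identifiable through the kernel
structure, so with `K = I` the posterior of `h2` reflects the prior (near
0.5), not zero; null checks should use a structured kernel.

**MCMC defaults.** 20,000 iterations, 5,000 burn-in, thinning 10 (1,500
retained draws) — sized so that a 600-individual, 2-to-3-trait fit takes
seconds and the full test suite minutes, with effective sample sizes of a
few hundred for variance components. Production analyses can pass e.g.
300,000 / 50,000 / 10 through the same arguments. Summaries require at
least 200 retained draws. Fixed seeds give bit-identical chains; all
multi-stage randomness derives from one master seed through named
substreams (`substream_seed`).

**Cross-validation (stage 4).** `make_folds()` partitions individuals into
folds differing in size by at most one. Per fold, marker weights are
estimated by PLS-CA on the training rows only (a structural guarantee — the
validation rows never reach the selection step, and tests assert that
corrupting them leaves the fold's weights bit-identical), `G_w` is built
over all individuals, and the multi-trait model is fitted with validation
phenotypes masked. Accuracy per trait is the product-moment correlation
between reference values and the fold's GEBVs, computed per fold then
averaged; the SD is across folds. On simulated data the reference is the
true breeding value; on real data the full-data pedigree-based multivariate
EBVs are the sensible reference, and both are accepted. The paired Wilcoxon
signed-rank test compares per-fold accuracies between scenarios, with an
exact null for up to 25 effective pairs (computed by convolution of the
rank generating function, which also handles midranks from ties exactly)
and a continuity-corrected normal approximation above.

## The synthetic-data generator

`sim_config()`/`simulate_population()` emulate the data a breeding-trial
analysis sees: unrelated founders with allele frequencies uniform on a
configurable interval, offspring by Mendelian gene dropping through full-sib
families (controlled crosses, optionally with clonal ramets) or
open-pollinated half-sib families (pollen parent unrecorded), pleiotropic
QTL architectures, replicate and block-in-replicate effects, and missing
genotype calls. Phenotypic variance is normalised to 1 per trait, so the
additive variance equals the target heritability and residual variance is
`sigma_a^2 (1 - h2)/h2`.

Two design choices deserve explanation.

*Markers are unlinked.* There is no linkage map: each marker segregates
independently, and family co-segregation alone supplies the relatedness
signal that GBLUP exploits. This keeps the generator simple and makes every
QTL a genotyped marker. The flip side is that there is no marker-QTL
linkage-disequilibrium decay, so "tagging quality" — a major driver of
marker-selection benefits on real data — cannot be emulated; see
*Limitations*.

*Effect rescaling.* Raw QTL effects are standard normal with a pleiotropy
structure (a fraction `pleiotropy` of QTLs affect all traits with a shared
effect size, sign-flipped on secondary traits with probability `sign_flip`
to create negative pleiotropy). They are then linearly rescaled through the
empirical covariance of the implied breeding values so that the realised
genetic covariance matches `diag(sqrt(h2)) rG diag(sqrt(h2))` exactly. The
exact transform is lower-triangular and mixes traits, which would break the
structural guarantee that `pleiotropy = 0` means one QTL affects one trait;
when `pleiotropy = 0` and the target `rG` is diagonal, a per-trait diagonal
rescaling is used instead, preserving the sparsity structure while the
off-diagonal covariance vanishes stochastically with QTL count.

## What the tests do and do not show

The unit and acceptance tests validate the machinery against independent
oracles: closed-form selection counts for the two published marker-panel
sizes (9,697 and 58,636), the SVD of the scaled cross-product for PLS-CA,
hand-tabulated pedigree coefficients, algebraic identities linking `G_w`
and `G`, a brute-force naive Gibbs sampler on tiny instances, generalized
least squares for fixed effects under fixed variances, and parameter
recovery on simulated data across a 3 x 3 grid of heritabilities and
genetic correlations (posterior means within two posterior SDs of the
simulation truth).

One documented expectation is *not* reproduced, deliberately left as a
failing check rather than adjusted away: that the best two-tailed selection
scenario beats all-marker multi-trait GBLUP for a low-heritability trait
when its genetic correlations to companion traits are weak-to-moderate, and
not when they are strong. Under this generator the direction is reliably
reversed (measured across four configurations and 48 replicates: selection
wins ~5/24 in the weak-correlation regime and ~23/24 in the strong one).
The mechanism is transparent: with unlinked markers and every causal QTL
genotyped, the all-marker matrix already captures all causal signal, and
the only cost is dilution by neutral markers; the PLS-CA loading
signal-to-noise — hence the chance of enriching causal markers and
un-diluting the kernel — grows with the very covariance being estimated.
On real data, where markers tag unobserved QTLs through decaying linkage
disequilibrium and weak correlations are poorly estimated, the balance can
tip the other way. Passing the remaining tests therefore demonstrates
correct machinery, not that marker selection will help any particular real
dataset; the scenario grid plus DIC and Wilcoxon comparisons exist
precisely so users can measure it on their own data.

## Numerical choices and degenerate inputs

- Quantile definition: linear interpolation at `h = 1 + (p/100)(n-1)`
  (type-7), threshold inclusive; ties at the threshold are all selected.
- Eigenvalues of `K` below `max(d) * 1e-12` are treated as exactly zero;
  inverse-Wishart draws that fail a positive-definiteness check are redrawn
  and counted (`nonpd_redraws`).
- Constant marker or trait columns are an error in PLS-CA (they cannot be
  standardised); monomorphic-in-fold markers are excluded from selection
  with weight 0.
- All-missing markers must be filtered before imputation; mean imputation
  preserves per-marker means and frequencies exactly.
- Matrix round-trips are written with 17 significant digits, so
  `read(write(x))` is bit-identical.
- The matrix correlation between relationship matrices uses the vectorised
  lower triangle *including* the diagonal; element choice is a convention,
  stated here because reasonable alternatives (off-diagonal only) exist.
- Two-tailed counts: a symmetric two-tailed rule selects both tails with
  the same quantile definition. Published two-tailed counts for comparable
  panels are not exactly the sum of the two tails, so the two-tailed rule
  here is the symmetric reading and its counts are not treated as exact
  anchors (the one-tailed counts are).

## Limitations

- No linkage map, dominance, epistasis, genotype-by-environment terms, or
  selection across generations in the simulator.
- The univariate kernel models expect one record per kernel id (the
  two-stage flow handles ramets via BLUEs/averaging); observation-level
  repeated measures with a kernel are out of scope.
- Bayesian credible intervals for `h2` are bounded below by 0 by
  construction, unlike REML-style confidence intervals which can cross 0.
- The exact Wilcoxon null is limited to 25 effective pairs; beyond that the
  continuity-corrected normal approximation is used.
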