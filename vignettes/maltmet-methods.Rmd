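---
title: "Variance components, genomic heritability and trait correlations for NMR metabolomic features"
author: "maltmet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance components, genomic heritability and trait correlations for NMR metabolomic features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In a malting-barley breeding programme, every field plot yields a wort sample
whose 1D ^1^H NMR spectrum is integrated into thousands of chemical-shift
buckets ("metabolomic features"), alongside a handful of malting-quality
traits (filtering speed, wort clearness, extract yield, wort colour,
beta-glucan, wort viscosity). `maltmet` asks two questions of such data:

1. How much of the plot-to-plot variation in each feature is additive-genomic,
   i.e. explained jointly by genome-wide SNP markers?
2. For features with significant genomic variance, how strongly are they
   genetically and phenotypically correlated with the quality traits?

Both questions are answered with plot-level mixed models that use the
VanRaden genomic relationship matrix G among lines, fitted by restricted
maximum likelihood (REML).

## The univariate model

For one feature (or trait) measured on `n` plots,

    y = X b + Z_g g + Z_l l + Z_ig ig + Z_il il + Z_t t + e

with fixed location x year x trial cell effects `b` and independent random
terms

* `g ~ N(0, G sigma_g^2)` — additive genomic line effects,
* `l ~ N(0, I sigma_l^2)` — line effects not captured by the markers,
* `ig ~ N(0, diag(G, ..., G) sigma_ig^2)` — genomic deviations per
  location x year environment (covariance G within an environment, zero
  across environments),
* `il ~ N(0, I sigma_il^2)` — line x environment deviations,
* `t ~ N(0, I sigma_t^2)` — malting/mashing batch effects,
* `e ~ N(0, I sigma_e^2)` — residual.

Because every term enters at plot level, all covariance structures reduce to
`n x n` matrices: `K_g = G[line_i, line_j]`, `K_ig = K_g * 1(env_i = env_j)`,
and so on. The phenotypic variance of a single plot and the plot-level
genomic heritability are

    sigma_P^2 = Gbar sigma_g^2 + sigma_l^2 + Gbar sigma_ig^2 + sigma_il^2
                + sigma_t^2 + sigma_e^2
    h2 = Gbar sigma_g^2 / sigma_P^2

where `Gbar` is the mean diagonal of G. This is deliberately a heritability
of one plot measurement, not of a line mean; it is smaller than line-mean
heritability because interaction and error variances are not divided by
replicate counts. Relative variance components (`compute_rvc()`) are the
Gbar-weighted shares of `sigma_P^2` and sum to one.

## REML estimation

`reml_fit()` maximises the restricted log-likelihood

    ll = -1/2 [ (n - p) log 2*pi + log|V| + log|X' V^-1 X| + y' P y ]

over nonnegative components, where `V = sum_k sigma_k^2 K_k + sigma_e^2 I`
and `P` projects out the fixed effects. The iteration strategy is the one
robust near boundaries:

* five expectation-maximisation warm-start iterations (monotone, slow),
* then average-information (AI) updates with step halving and a
  Levenberg-style ridge fallback,
* components whose update would go negative are pinned at zero and freed
  again when their own gradient turns positive, so exact zeros — which the
  null distribution of h2 piles onto — are representable,
* convergence when the relative log-likelihood change is below `1e-8` and
  the relative parameter change below `1e-6` (cap 200 iterations).

Accepted steps never decrease the likelihood; the unit tests check this on
the recorded iteration path, and two oracles pin the solution down: the
balanced one-way layout (closed-form ANOVA estimators) and a brute-force
grid search of `restricted_loglik()` on a 12-plot instance.

Standard errors come from the inverse AI matrix at the solution. The
delta-method standard error of h2 is a diagnostic extension: significance
of h2 is calibrated by the null simulation, not by this SE.

### Bivariate models

`reml_fit_bivariate()` expands every dispersion parameter to a 2 x 2 block
(`v1`, `cov`, `v2` per term) for a feature-trait pair. Responses are scaled
to unit variance internally and the fit is warm-started from the two
univariate fits. Each proposed block update is projected onto the PSD cone
by 2 x 2 eigenvalue clipping, which keeps every implied correlation inside
[-1, 1] and lets boundary solutions (correlation exactly +/-1) occur — they
do occur in practice for strongly coupled pairs. When a block variance is
pinned at zero its covariance is pinned too (the KKT condition on the PSD
cone); if no Newton-type direction is feasible, a projected steepest-ascent
step can still slide along the boundary, and when no feasible direction
improves the likelihood beyond tolerance the point is accepted as a
boundary-constrained maximum. Missing trait records are handled by giving
each response its own row set, so a trait recorded on fewer plots than the
feature loses nothing.

From the fitted blocks,

    r_g = cov_g / sqrt(vg1 * vg2)
    r_p = (Gbar cov_g + cov_l + Gbar cov_ig + cov_il + cov_t + cov_e)
          / sqrt(sigma_P1^2 sigma_P2^2)

The phenotypic covariance mirrors the univariate `sigma_P^2` identity with
the same Gbar weighting — consistency between numerator and denominator
requires it. Correlations whose genomic variance is pinned at zero are
reported as undefined with a reason code rather than silently zero, and are
excluded (with reported denominators) from summary percentages. Each
estimate carries a delta-method standard error and the two-sided z test
`|estimate/se| > 2.326` (1% on each side of the normal distribution).

## Significance of heritability

The null distribution of h2-hat is estimated on the exact experimental
design: under the null all components except the residual are zero, so each
replicate draws i.i.d. standard-normal responses for every plot, refits the
full model and records h2-hat (`null_cutoff()`). The significance cutoff is
the empirical upper 1% quantile (interpreted as the upper-tail point because
it is used as an upper cut-off). A feature is flagged when its h2-hat is
strictly larger than the cutoff. The replicate count is configurable; the
desk default is 1,000 (the count is always recorded in the output), and
`null_calibration_experiment()` verifies on fresh null features that the
flagged fraction is binomially compatible with 1%.

## Preprocessing of bucket tables

The pipeline starts from a frequency-domain plot x ppm bucket table;
instrument-side FID processing (apodisation, Fourier transform, phasing,
baseline, chemical-shift referencing) is out of scope. Four steps:

1. `exclude_regions()` — removes buckets in closed ppm intervals; defaults
   are the residual water peak (4.7-4.9 ppm) and the DSS standard region
   (-0.2 to 0.2 ppm, which lies outside a 0.70-9.00 ppm grid and then
   removes nothing).
2. `pqn_normalize()` — probabilistic quotient normalisation: each spectrum
   is divided by the median of its bucket-wise quotients to a reference
   (default: the median spectrum), removing per-sample dilution exactly.
3. `align_segments()` — a simplified interval alignment: integer bucket
   shifts per segment maximising cross-correlation with the reference, with
   edge-value padding. Integer-shift cross-correlation is the core of
   interval-correlation alignment methods and is verifiable by brute force;
   sub-bucket interpolation is deliberately not attempted.
4. `standardize()` — column-wise centring and scaling to unit variance
   (n-1 divisor, matching the downstream variance conventions), dropping
   constant buckets with a warning.

The ppm grid is stored ascending regardless of input orientation (NMR
convention displays descending); writers can emit descending order.

## The synthetic-data generator

`sim_config()` + `simulate_*()` generate genotypes, field designs, traits
and spectra-like bucket tables with known ground truth. Design constants
default to the structure of a commercial spring-barley programme: 565 lines
genotyped at 3,889 SNPs (MAF at least 5%), 2 locations x 3 years (six
environments), trials nested in environments as randomised blocks with
three replicates, thinned to about 4.65 plots per line (2,628 plots), and
consecutive plots grouped into malting batches of 48 (the batch layout is
not documented for the real programme; equal consecutive batches are a
neutral choice).

Relatedness is produced by crossing a small founder pool with
recombination-free gamete sampling followed by selfing generations —
reproducing the single-cluster relatedness of elite material without a
genetic map. Two regimes matter:

* the programme-scale default (25 founders, 4 selfing generations) emulates
  F6-type inbred lines; inbreeding pushes the VanRaden mean diagonal to
  about 1.9;
* the validation experiments use a tight pool of 6 founders with outbred
  crosses, for two reasons: the mean G diagonal stays near 1 (~0.92 —
  in-sample allele frequencies on a related sample push it slightly below
  1), so the recovery experiments' component vector
  (0.3, 0.1, 0.1, 0.1, 0.1, 0.3) implies a true plot-level h2 of ~0.28-0.30,
  and recovery is asserted against the realised truth; and strong
  off-diagonal relatedness is what makes `sigma_g` (covariance G)
  statistically separable from the i.i.d. line term `sigma_l`. With weak relatedness the
  two are nearly confounded and the nonnegativity boundary visibly biases
  `sigma_g`-hat downward — a property of the estimator in an
  unidentifiable regime, not of the implementation, and the regime the
  real single-cluster population does not occupy.

Phenotypes are realised exactly under the model: genomic effects through a
symmetric PSD factorisation of G (eigenvalues clipped at zero, since a
finite-marker G can be numerically indefinite), per-environment genomic
deviations drawn independently with covariance G, and feature-trait pairs
sharing genomic and residual covariances (any inconsistent covariance
request is rejected with the offending block named). Emitted spectra are
`dilution * (baseline + response)` with log-normal dilution, which PQN
removes exactly — so preprocessing can be exercised without disturbing the
ground truth.

What the generator does not emulate: raw time-domain NMR signal, peak
shapes and overlapping resonances, linkage maps or QTL architecture
(marker effects are implicit in G), spatial field trends, and systematic
batch drift. Passing tests therefore demonstrate correctness of the
estimation machinery under the stated model, not robustness to every
artefact of real spectra.

## Validation experiments and problem sizes

Because per-feature estimates within one data set share the realised design
and G, all recovery experiments average over independent data-set
replicates and compute Monte-Carlo standard errors from data-set means:

* `h2_recovery_experiment()` — 10 data sets x 5 features, 200 lines,
  ~3 plots per line, 6 environments; mean h2-hat is compared with 0.30
  within two Monte-Carlo SEs.
* `rg_recovery_experiment()` — 10 data sets x 3 feature-trait pairs at a
  true genetic correlation of -0.6, same dimensions.
* `null_calibration_experiment()` — one 120-plot design (60 lines, 2
  locations x 3 years, ~2 plots per line), 500 null replicates for the
  cutoff and 500 fresh null features scored against it.

These sizes keep the full validation suite at desk scale while leaving the
estimators enough data to be informative; they are the package's standing
choices, stated here so results are reproducible.

## Numerical choices and degenerate inputs

* Marker QC uses strict inequalities (MAF strictly above, missingness
  strictly below the thresholds), matching the usual reading of
  "more than" / "less than"; missing dosages are mean-imputed (`2p_j`),
  which is the imputation consistent with VanRaden's centring.
* G eigenvalues below `1e-8` are raised to `1e-8` (the centring null vector
  guarantees at least one exact zero); genuinely negative eigenvalues
  trigger a warning. `Gbar` changes by at most the clip level.
* Fixed effects are absorbed through one-hot trial-cell indicators; any
  aliased columns are dropped deterministically in data order.
* Terms with fewer than two levels (e.g. a single malting batch) are
  inestimable, dropped, and flagged in the model metadata.
* Residual variances have a floor of `1e-8 * var(y)` so V stays invertible;
  all other variances may reach exactly zero.
* Alignment ties between shifts prefer the smaller absolute offset; the
  all-constant segment therefore stays unshifted.
* The e2e pipeline derives every stage's random stream from one master seed
  (`derive_seed()`), so reruns are byte-identical and enlarging one stage
  does not perturb another.

## Known limitations

* Only pairs of responses are modelled jointly; no >2-trait models,
  dominance/epistasis, or pedigree relationship matrices.
* Only the percentile cutoff is provided for significance of h2; a
  false-discovery-rate reading of the same null simulations would need a
  precise construction rule and is deliberately out of scope.
* Dense-matrix algebra bounds practical problem sizes to a few thousand
  plots per fit; the full 24,018-feature scan is embarrassingly parallel
  across features but is not parallelised inside the package.
* Boundary-constrained bivariate solutions are accepted when no feasible
  direction improves the likelihood beyond tolerance; the reported AI-based
  standard errors are asymptotic and optimistic exactly at such boundaries
  (hence the undefined/boundary flags on correlations).
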