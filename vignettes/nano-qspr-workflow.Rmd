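---
title: "Modeling nanoparticle zeta potential from core, coating and corona descriptors"
author: "nanoqspr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling nanoparticle zeta potential from core, coating and corona descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoqspr)
```

## The modeling problem

The zeta potential ζ of a nanoparticle in a biological medium depends on
the particle core, its surface functionalization, and the protein corona
that forms on contact with the medium.  `nanoqspr` represents each
particle by three descriptor blocks — continuous core descriptors,
integer coating counts, and binary protein-fingerprint bits — and fits a
linear latent-variable model

$$\hat\zeta = \bar y + \sum_j b_j \, \tilde x_j,$$

where $\tilde x_j$ are autoscaled descriptors and the coefficients $b_j$
come from a PLS1 decomposition with $A$ latent vectors.  The packaged
`pnp20()` dataset (20 polymeric nanoparticles, five GA-selected
descriptors, endpoints −70…+50 mV) is the worked benchmark used
throughout the tests.

## Preprocessing

Descriptors are autoscaled with parameters fitted **on the training rows
only** and applied unchanged to every partition, so validation samples
are expressed in training units.  Two choices deserve mention:

* **SD denominator.**  The default standard deviation uses the
  population ($n$) denominator; this is the convention under which the
  package's standardized coefficients are defined (the benchmark
  equation's printed coefficients are reproduced to three decimals under
  it, and would be off by the factor $\sqrt{13/14}$ under the sample
  denominator).  `sd_denom = "n-1"` is available.  Predictions are
  unaffected by the choice, because a uniform rescaling of all columns
  does not rotate the PLS subspace.
* **Endpoint handling.**  $y$ is mean-centered but not variance-scaled.
  This keeps every RMSE in mV and makes the scaled-space coefficients
  directly readable as "mV per descriptor SD".
* **Zero-variance columns** are flagged and dropped, never an error.
  This matters inside cross-validation folds: a corona bit carried by a
  single training particle becomes constant when that particle is held
  out, and a constant column carries no usable information.

## The PLS1 core

`nipals_pls1()` implements NIPALS for a single response.  With one
response the weight vector of each component is $X_a' y_a$ normalized, so
the algorithm is exactly deterministic — no iteration, no random
initialization.  Both $X$ and $y$ are deflated per component ($y$
deflation is a no-op for PLS1 predictions but keeps the per-component
variance bookkeeping explicit).  Invariants asserted in the test suite:
unit-norm weights, mutually orthogonal scores, residual sum of squares
non-increasing in $A$, column-permutation equivariance, agreement with an
independently coded SIMPLS oracle to 1e-6, and equality with ordinary
least squares at full rank.

### Variance accounting

Per component, the explained descriptor variance is measured against the
Frobenius norm of the scaled training matrix,
$100\,\lVert t_a p_a'\rVert_F^2 / \lVert X\rVert_F^2$, and the endpoint
variance as the drop in residual sum of squares over the total centered
sum of squares.  Chemometrics packages differ in how they display
descriptor-block variance (per-column averages, score norms, correlation
loadings, and block-restricted displays all circulate), so cumulative
"X-variance" figures are comparable across software only when the
convention is stated; the Frobenius convention used here is the one the
cumulative-R²X literature defines, and on the benchmark table it
attributes 38.3 % of the five-descriptor variance to the first two
latent vectors.  The endpoint-variance decomposition (83.1 % and 12.6 %
on the benchmark) does not suffer from this ambiguity: its cumulative
value equals $100\,R^2$ by construction, which the tests assert.

## Validation battery

`validate_model()` reports, in the Q²F1 convention for external data:

* $R^2 = 1 - SS_{res}/SS_{tot}$ and RMSEC on the training rows;
* $Q^2_{cv}$ and RMSECV from leave-one-out cross-validation in which the
  **scaler is refitted inside every fold** (with zero-variance drops and,
  if needed, a reduced component count, both logged);
* $Q^2_{ext} = 1 - \sum_V (y-\hat y)^2 / \sum_V (y-\bar y_{train})^2$ and
  RMSEP on the validation rows.  With the training-mean reference the
  identity $Q^2_{ext} = 1 - n_V\,\mathrm{RMSEP}^2 / \sum_V (y-\bar
  y_{train})^2$ holds exactly and is asserted in the tests.  The
  fold-mean reference for $Q^2_{cv}$ is available via `reference =
  "fold"`.

The honest per-fold refit is what makes RMSECV on the benchmark table
(≈ 24.8 mV) several times larger than RMSEP (≈ 7.4 mV): the fold holding
out structure 7 loses the only carrier of the `CC1rs` bit and mispredicts
it by ~80 mV.  The report prints this mechanism rather than hiding it.

## Applicability domain

`williams_data()` returns leverage, standardized residual, the critical
leverage $h^* = 3p/n$, and in/out-of-domain flags.  Three conventions are
explicit arguments:

* **Leverage space.**  The default computes leverage in the
  latent-score space, $h_i = t_i'(T'T)^{-1}t_i$ — the hat diagonal of the
  regression the PLS model actually performs, with training leverages
  summing to $A$.  The alternative `space = "descriptor"` uses the full
  descriptor-space hat diagonal $x_i'(X'X)^{-1}x_i$ (training sum $= p$,
  invariant to invertible column reparameterization).  The two disagree
  materially for samples far outside the training range of a single
  descriptor: benchmark structure 18 (the only particle with three sp²
  carbons) has descriptor-space leverage 2.50 but score-space leverage
  0.85.  The score-space default reflects how far a sample lies from the
  training data *as the model sees it*; the descriptor-space option is
  the classical regression diagnostic.
* **$h^*$ convention.**  `convention = "p"` (default) takes $p$ as the
  descriptor count ($3\cdot5/14 = 1.07$ on the benchmark); `"p+1"` adds
  an intercept term ($1.29$).
* **Residual scale.**  Standardized residuals divide by the RMSE of the
  sample's own partition (RMSEC for training, RMSEP for validation) by
  default, or by the pooled RMSE.  A sample is an outlier at
  $|r_{std}| > 3$.

## Genetic-algorithm descriptor selection

`ga_select()` runs a conventional generational GA over descriptor
bit-vectors: tournament selection (size 3), uniform crossover (0.8),
per-bit mutation (2 / pool size), elitism (2), population 50, 100
generations — all exposed in `ga_control()`.  For each chromosome the
component count is chosen jointly as the best of `lv_candidates`
(default 1–3).  The default fitness is the leave-one-out RMSECV computed
by the validation module itself; training-R² fitness is selectable.
Runs are fully reproducible from the seed, and the reported best fitness
is a fresh re-evaluation of the winning subset.

A practical caveat the tests quantify on synthetic pools: minimum-RMSECV
selection with an unconstrained subset size tends to admit one or two
spurious descriptors alongside the true support (leave-one-out error is
a noisy criterion and mildly rewards overfitting), so searches should
declare a maximum subset size on the scale of the expected model.  Within
a declared size bound the GA matches exhaustive enumeration of all
$\binom{30}{\le 3} = 4525$ subsets on a 30-descriptor pool with three
planted effects, and recovers the planted support exactly across seeds.

## Synthetic data

`synthetic_spec()` / `generate_pnp_table()` emulate the structure of a
real descriptor pool: 33 correlated Gaussian core descriptors on
molecular-weight-like scales (mean 6.2, SD 0.7, shared-factor correlation
0.3), 34 Poisson coating counts (mean 1), and 80 Bernoulli corona bits
(prevalence 0.3, independent by default; an optional shared latent
adsorption factor induces realistic co-occurrence, off by default to keep
tests deterministic in distribution).  The endpoint is a planted sparse
linear combination plus Gaussian noise (default SD 5 mV, a realistic
zeta-measurement repeatability), and splits come from the same
endpoint-sorted every-third rule used for real tables.
`fixture_like_spec()` plants five effects whose signs and raw-unit
magnitudes mirror the benchmark equation (positive core weight, negative
sp²-carbon count, two positive and one negative corona bits), giving
endpoints that typically span well over 80 mV across 20 particles.

What passing tests on this generator do **not** show: real corona
fingerprints are strongly co-occurring and compositionally constrained,
real coating chemistry correlates with the core, and real descriptor
pools contain highly collinear families.  The generator validates the
machinery (identifiability, selection, honest cross-validation), not the
biology.

## Numerical choices and degenerate inputs

* Rank exhaustion in NIPALS (weight or score norm below 1e-12 of scale)
  is an error for a user-requested component count, and an automatic
  per-fold reduction inside cross-validation.
* A fold that loses every descriptor predicts the fold mean.
* Singular $X'X$ in descriptor-space leverage falls back to the
  pseudo-inverse with a warning.
* The every-third splitter breaks endpoint ties by a caller-supplied
  deterministic key (default: current row order), making the split
  invariant to row permutation for a fixed key.  The packaged dataset
  ships with its published split labels because endpoint ties make the
  every-third rule non-unique on it.
* Model JSON serialization uses full-precision numbers; round-trips are
  exact to 17 significant digits.

## Known limitations

* The reference predicted column distributed with the packaged dataset
  is metadata, not a target: it is not reproducible by any single linear
  model of the five descriptors (samples 6 and 9 have identical
  descriptor vectors but different reference predictions), and the
  package's own predictions differ from it by up to ~2 mV on the quoted
  spot-check rows.  `reproduce_pnp20()` reports these rows with the
  discrepancy flagged rather than adjusting the model toward them.
* Cumulative descriptor-variance shares depend on the display convention
  (see above); only the Frobenius convention is computed.
* The test suite exercises the GA at reduced budgets (populations 30–40,
  20–30 generations, 60-sample pools) chosen so the whole suite runs in
  a couple of minutes; these are the package's declared problem sizes
  for property checking, and all conclusions asserted there are
  seed-reproducible.
* No multi-response PLS, no nonlinear/kernel variants, no
  probability-density applicability domains, and no descriptor
  computation from chemical structures — tables are the package's input
  contract.
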