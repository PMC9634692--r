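---
title: "Methods: competing-pathway kinetics of aminoacyl-primer RNA copying"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: competing-pathway kinetics of aminoacyl-primer RNA copying}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glykin)
```

## The kinetic model and its assumptions

A primer-template duplex saturated with activated substrate is assumed, so
all steps are pseudo-first-order. The primer pool starts as a mixture —
a fraction `p_gly0` carries a 2′(3′)-aminoacyl ester (ribozyme acylation is
incomplete; observed yields span 26–60%) and the rest is native RNA — and
evolves through three irreversible pathways: extension of the aminoacylated
primer via phosphoramidate formation (`k1`), hydrolysis of the aminoacyl
ester back to native primer (`k2`), and canonical phosphodiester extension
of the native primer (`k3`), all in h⁻¹. Time is in hours throughout and
is not configurable; mixing units is a classic source of silent errors in
rate tables.

The model deliberately ignores: reversibility (products are stable on the
observation time scale), sequence dependence, Mg²⁺ as a continuous
covariate (conditions are discrete labels), and the 2′/3′ regiochemistry of
the aminoacyl group — rapid transacylation makes the regioisomers
experimentally inseparable, so the model treats them as one species and
every fitted `k1` is the combined rate.

`eval_closed_form()` implements the analytic solution; `integrate_numeric()`
solves the same system with `deSolve::lsoda` and exists purely as an
independent oracle — the test suite holds the two within 1e-6 over
randomized rate sets spanning 0.01–50 h⁻¹.

## Numerical choices

* **Degenerate resolvent.** The native-primer solution has the factor
  `(e^(−k3 t) − e^(−K t)) / (K − k3)` with `K = k1 + k2`; when `k3 → K`
  this cancels catastrophically. Within a relative window of 1e-9 the
  analytic limit `k2 p_gly0 t e^(−k3 t)` is used instead. The tests check
  continuity across the boundary to 1e-6.
* **Conservation.** Fractions are never clipped inside the math; the
  fourth species is computed by mass balance and the suite asserts
  conservation to 1e-9, so any defect surfaces instead of being hidden by
  renormalization.
* **k1 optimizer.** The fit has a single free parameter, so bounded scalar
  least squares suffices: L-BFGS-B on `k1 ∈ [0, 1e4]` h⁻¹, multi-started
  from 0.1×, 1× and 10× a slope-based guess (`np1 ≈ k1 p_gly0 t` at early
  times). Multi-start is cheap insurance against the flat-objective corner
  at `k1 = 0`; a fit landing on that boundary is flagged rather than
  silently reported.
* **Non-positive observables.** Noisy lane normalization can produce
  `P ≤ 0`; such points are excluded from log-linear fits with a warning
  and an exclusion count, rather than aborting the analysis or silently
  flooring values.

## Estimator design where the procedure was open

Three choices were genuinely open and are fixed here as package policy:

* The log-linear `k_obs` regression keeps a **free intercept**. Forcing the
  line through the origin is only correct if the t = 0 lane is noiseless;
  with a free intercept the slope is robust to small normalization offsets,
  and the intercept is reported as a diagnostic.
* `fit_k1` **pools replicates** into one unweighted sum of squared
  residuals over the total-primer and NP+1 observables, rather than
  averaging replicates first. Pooling uses every lane's information and
  keeps the objective a plain least-squares statement; with balanced
  designs the two differ only in weighting of missing lanes.
* Monte Carlo propagation draws the fixed inputs `(p_gly0, k2, k3)` from
  **normal distributions truncated at zero** (`p_gly0` also at one), with
  **1000 draws** by default and a mandatory seed. The summary is the median
  with the across-draw standard deviation and 16th/84th percentiles, which
  stay meaningful when the k1 posterior is skewed by the `p_gly0`
  denominator effect.

For ligation the same three-species model is reused with `k1` read as the
aminoacyl ligation rate and `k3` as the native-RNA ligation rate. The two
ligation products co-migrate as one band, so the model response for that
band is the pooled product `p_gly1 + p_rna1`, and fits use only time points
passing the censoring rule: every control replicate must show < 2% ligated
product (the worst replicate decides). Censoring plus the pooled response
makes the censored fit exact on noiseless data rather than biased by the
small native contribution.

## What the synthetic generator emulates — and what it does not

The generator reproduces the statistical structure the estimators assume:

* trajectories from the closed-form model, with `p_gly0` either explicit or
  drawn from the observed 26–60% acylation-yield range;
* gel co-migration: on standard gels one `primer` band (= P_gly + P_rna)
  plus resolved `np1`/`op1` bands; on acidic gels resolved
  `primer_gly`/`primer_rna` bands; in ligation one pooled `ligated` band;
* a lognormally distributed per-lane loading total (sd 0.2, mimicking
  pipetting variability) so that lane normalization is nontrivially
  exercised, and multiplicative lognormal band noise (default sd 0.05 —
  densitometry error scales with band size; the magnitude is a free knob
  because no empirical noise characterization exists to calibrate it);
* a `no_template` experiment type emitting slow non-templated accumulation,
  for qualitative contrasts only.

It does **not** simulate gel physics (smearing, band shape, background),
image quantification, sequence/temperature/pH dependence, or realistic
replicate-to-replicate variance — the triplicate noise defaults are
placeholders to be varied in robustness tests, not estimates of real
inter-replicate error. Passing round-trip tests therefore demonstrates that
the estimators are correct and unbiased under the model's own assumptions
with realistic noise magnitudes; they cannot certify behavior under
model misspecification (e.g., non-first-order hydrolysis or
background-correlated noise).

## Problem sizes and reproducibility

Simulated experiments use 5–7 time points per decade of dynamics,
triplicate lanes, and 5% band noise; Monte Carlo uses 1000 draws; the
robustness suite uses 20 independent noisy datasets and the oracle suite
100 randomized rate sets. These sizes make every property check exact or
tight while keeping the full test suite in the tens of seconds. All
stochastic steps take explicit integer seeds; the pipeline refuses a
stochastic configuration without one, and identical configs produce
byte-identical output tables.

## Known limitations

* `k2` and `k3` are fixed inputs, never co-estimated with `k1`; if their
  independent measurements are biased, the bias propagates into `k1`
  (the Monte Carlo machinery quantifies variance, not bias).
* The censoring rule discards late time points entirely rather than
  modeling the native ligation contribution; with fast native ligation this
  can leave too few points to fit, which the package reports as an
  insufficient-data error rather than extrapolating.
* Fold-change uncertainties use the first-order delta method under
  independence; strongly correlated condition estimates would need a joint
  Monte Carlo instead.
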