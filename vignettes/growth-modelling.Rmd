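---
title: "Modelling pubertal height growth from sparse survey rounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pubertal height growth from sparse survey rounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spurtr)
```

# The problem

Height in children and adolescents follows a characteristic pattern: steady
childhood growth, a pubertal spurt, and a plateau at adult height. Cohort
surveys in low-resource settings typically measure each child only a handful
of times — here, four survey rounds at roughly ages 8, 12, 15 and 19 years,
with ages recorded to 0.1 years and heights to 0.1 cm. The scientific
quantities of interest are the age at peak height velocity (APHV), the peak
velocity itself (PHV), adult height, and how individuals and groups (sexes,
regions) differ in the size, timing and intensity of their growth.

`spurtr` implements the two standard models for this problem and everything
needed to run, test and compare them end-to-end on such sparse designs.

# The models

## PB1

Preece–Baines model 1 describes one child's (or one group's average) height
as

$$h(t) = h_1 - \frac{2\,(h_1 - h_c)}{e^{s_0 (t - c)} + e^{s_1 (t - c)}}$$

* $h_1$ — adult height (cm), the large-age limit of the curve;
* $h_c$ — height at midpuberty (cm): $h(c) = h_c$ exactly, because the
  denominator equals 2 at $t = c$;
* $s_0 < s_1$ — prepubertal and pubertal rate constants. They sit inside
  exponentials of years, so their units are 1/year (growth-study tables
  often print them as "cm/year"; the magnitudes, ~0.1 and ~0.5–1, only make
  sense as rates);
* $c$ — midpuberty age (years). The velocity maximum lies near, but not
  exactly at, $c$; `pb1_peak()` reports the numerical argmax, and `c` is
  available from the parameters.

Two analytic facts the tests lean on: $v(c) = (h_1 - h_c)(s_0 + s_1)/2$,
and with $s_0 = s_1 = s$ the model degenerates to the pure exponential
approach $h_1 - (h_1 - h_c)e^{-s(t-c)}$, whose velocity is monotone — there
is then no interior peak at all.

`fit_pb1()` maximizes the Gaussian likelihood of the pooled observations of
one group (a population-average fit: this is what a table of one fixed-effect
vector per sex reports). The optimizer works on $(h_1, h_c, \log s_0,
\log s_1, c)$, with a small battery of systematic starts plus jittered
restarts — the profile surface has degenerate corners where a rate collapses
to zero — and standard errors come from the inverse observed information of
the full likelihood. Since the curve is symmetric under swapping $s_0$ and
$s_1$, estimates are stored in canonical order. On data without a PB1-shaped
asymptote the information matrix can be singular at the boundary optimum
($s_0 \to 0$); standard errors are then `NA` with a warning. Genuinely flat
(no-growth) data raise an error.

## SITAR

The shape-invariant model expresses every child as a shifted, stretched copy
of one median curve $s(\cdot)$, a natural cubic spline:

$$y_{ij} = \alpha_i + s\big((t_{ij} - x_0 - \beta_i)\, e^{\gamma_i}\big) + e_{ij}$$

* size $\alpha_i$ (cm): vertical offset;
* timing $\beta_i$ (years): horizontal shift — positive means a later spurt;
* intensity $\gamma_i$ (log-units): age-axis scaling — positive means faster
  maturation (a compressed age axis). A $\gamma$ SD of 0.12 corresponds to
  roughly ±12% variation in growth rate;
* $x_0$: the mean observation age. Centring ages before the transform is
  essential — scaling about age 0 would make timing and intensity almost
  collinear over the pubertal window.

$(\alpha_i, \beta_i, \gamma_i)$ follow an unstructured trivariate normal
distribution, estimated together with the spline coefficients and residual
SD by maximum likelihood (ML, not REML, so BIC comparisons across different
fixed-effect structures are valid). The fixed size is absorbed into the
spline intercept; fixed timing and intensity are zero for a single-group
fit, and group offsets (e.g. region offsets on size) can be requested.

# The estimation engine

`fit_nlme()` implements Lindstrom–Bates alternation: a penalized nonlinear
least-squares step updates fixed effects and per-subject modes given the
relative random-effect covariance; a linear mixed-model step updates the
variance parameters (log-Cholesky, so the covariance stays positive
semi-definite and variances may hit the boundary) on the first-order
expansion about the modes. All per-subject algebra is batched through
Woodbury identities, so 891-subject fits take seconds. The alternation is
not monotone in the likelihood; the engine tracks the best visited state and
stops when the relative change in $-2\ell$ falls below $10^{-5}$ or no
improvement occurs for several alternations.

First-order objectives have a known failure mode that this design triggers
hard: with observations clustered in four narrow age bands, a sharply curved
spline can linearize into an apparently excellent fit. Cross-checking
against adaptive Gauss–Hermite quadrature (`marginal_loglik_quadrature()`)
showed first-order "optima" whose claimed log-likelihood was ~100 units
better than the truth basin while their true marginal log-likelihood was
~250 units worse. `laplace_refine()` therefore re-maximizes the exact
Laplace objective — per-subject Newton modes with the model's analytic
second derivatives (for SITAR, $s''$ is available in closed form) and the
full log-determinant term. Reported log-likelihoods and BICs are Laplace
values; on five-subject instances they agree with adaptive quadrature to
well under half a unit.

`fit_sitar()` wraps this in a warm-start strategy chosen after studying the
likelihood surface:

* **df ≤ 3 anchor.** A stiff spline cannot trade wiggle against the variance
  components; its fit is reliable from a cold least-squares start.
* **Warm chain.** Higher-df fits start from the previous stage — curve
  projected onto the new basis, variance parameters and modes carried over —
  and are refined under the Laplace objective, which protects the basin.
* **Spurt-shaped alternative start.** At the final df a second candidate is
  started from a fitted PB1 curve projected onto the spline basis (a PB1
  curve always carries a spurt) with neutral variance starts (timing ~1.25 y,
  intensity ~0.15), and the better Laplace optimum is kept. This guards
  against the smooth-but-spurtless local optimum that cold fits find when
  the spurt falls inside a gap between measurement rounds.

## Numerical choices

* **Knots.** Interior knots are equally spaced over the observed (centred)
  age range. Quantile placement — the usual default for dense designs —
  concentrates knots inside the narrow round bands here and admits the
  pathological curvy family described above.
* **Boundary knots** are placed 0.8 years beyond the observed age range.
  The natural-spline constraint (zero curvature at the boundary) otherwise
  acts exactly where the data stop and visibly flattens a spurt that sits
  near the first round — the girls' spurt at ~10.5 y, between rounds 1 and
  2, was systematically displaced by ~0.3 y until the constraint was moved
  clear. 0.8 y covers the age-measurement jitter plus about half a typical
  timing SD.
* **df.** Default 5 (four interior knots); `select_df()` compares candidates
  by BIC, sharing the warm chain. With only four rounds per subject, small
  df is expected to win.
* **Peaks.** `sitar_peak()` and `pb1_peak()` use a 0.01-y grid with
  quadratic (three-point parabola) refinement; maxima on the search boundary
  are flagged rather than trusted.
* **Degenerate inputs.** Zero-variance cohorts shrink the random-effect SDs
  to the boundary (the log-Cholesky floor, ~e⁻⁸ relative); a single subject
  pins them near zero with a warning; exactly zero residual noise makes
  Gaussian ML ill-posed, so generator-oracle tests use a residual SD far
  below every other scale instead.

# The synthetic cohort

`default_config()` encodes the emulated study: 891 subjects (472 boys, 419
girls) in five regions at the published composition, four rounds at target
ages 8/12/15/19 ± 0.4 y uniform jitter (the cohort's baseline ages spanned
7.5–8.4 y), ages rounded to 0.1 y and heights to 0.1 cm, per-sex residual
SDs 3.63/2.82 cm, and size/timing/intensity SDs of 5.15 cm / 1.28 y / 0.12
(boys) and 5.50 cm / 1.29 y / 0.17 (girls). Per-region size and timing
offsets (default zero) support regional experiments; missingness is
independent Bernoulli per later round, round 1 never lost.

The sex-specific truth median curves are natural cubic splines constructed
by `build_truth_curve()` to pass through configured targets: velocity peaks
of (13.15 y, 5.57 cm/y) for boys and (10.49 y, 6.34 cm/y) for girls, and
near-adult heights of 174.6 / 162.2 cm at age 20. The construction uses a
calibrated PB1 curve as a smooth skeleton — its prepubertal velocity is
penalized above 85% of the target peak so the spurt is the global velocity
maximum — and iterates the skeleton targets so that the *spline's* peak
(after least-squares projection, which smooths slightly) lands on the
configured values to 0.02. Both curve construction and the generator are
unit-tested.

What the generator does *not* emulate: attrition patterns, secular trends,
socioeconomic covariates, non-Gaussian measurement error, or correlation
between the three random effects (the default correlation is identity,
configurable). Passing recovery tests therefore show that the estimator
recovers this idealized data-generating process at the study's size and
design — not that real survey data meet those assumptions.

# What the checks compute

The acceptance tests (in `tests/testthat/test-acceptance.R`) run, at
study-design scale chosen to keep the whole suite within a desk-time budget:

* composition arithmetic of the published region-by-sex table (exact);
* the PB1 closed-form identities at the reference coefficients (0.01 cm);
* analytic-velocity versus finite-difference agreement (10⁻⁵ cm/y);
* engine-versus-quadrature likelihood agreement on 5-subject instances
  (0.5 units) and the balanced one-way closed form (10⁻⁶);
* SITAR parameter recovery at the full 891-subject design over ten seeds
  (warm-started across seeds), and PB1 3-SE coverage over 50 replicates of a
  400-subject design;
* the BIC model-selection direction on a 400-subject cohort;
* null calibration of the regional Wald contrasts over 50 replicates of a
  180-subject design.

A note on the per-seed variance-component tolerance: at this design the ML
sampling spread of the intensity and timing SDs is itself of order 10%
relative, so individual seeds can land outside a 15% band without any
estimator defect; the peak quantities (APHV, PHV) are far more stable.

# Limitations

* The Laplace objective is still an approximation; on designs even sparser
  than four rounds its ranking of extreme-curvature solutions should be
  re-verified against the quadrature oracle.
* Timing-SD estimates for a spurt inside a between-round gap (the girls'
  case) are mildly attenuated (~10%) even at n ≈ 450 per sex.
* The height-for-age screen defaults to a cohort-internal reference
  (per-sex, nearest-year bins, linear interpolation); no claim is made that
  it reproduces any specific external growth reference, which is pluggable
  via `read_reference_chart()`.
* Regional contrasts default to raw p-values (a Holm option exists); the
  per-stratum peak table and the joint offset model answer slightly
  different questions, and both are provided.
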