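---
title: "Continuous age-matched reference values for pediatric B cell subpopulations: methods"
author: "refcurveB"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous reference methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refcurveB)
```

## The problem

Peripheral-blood B cells divide into naive (IgD+CD27-), non-switched memory
(IgD+CD27+) and switched memory (IgD-CD27+) subpopulations, quantified by
flow cytometry as a fraction of CD19+ (or CD20+) B cells and as an absolute
count in cells/ul via a dual-platform approach. Their composition changes
strongly and continuously through childhood: a newborn's B cells are almost
entirely naive, the naive fraction falls over roughly the first decade,
memory fractions rise over the first five years and then plateau, and
absolute memory counts peak around age two before declining slowly.
Interpreting a child's values therefore requires age-matched reference
ranges. Conventional references bin children into a handful of age groups
and publish per-group percentiles; at every group boundary the reference
jumps, which misrepresents a process that is biologically smooth. This
package builds the alternative: a continuous reference in which the center
and limits are smooth functions of age.

## The model

For each subset and measure independently, the expected response at age
$x$ (years) is modeled by the three-parameter exponential

$$\mu(x) = a + b\,e^{c x},$$

with $a$ the asymptote approached in adolescence, $a + b$ the value at
birth, and $c$ (per year) the rate of approach; $c < 0$ gives decay toward
the asymptote, and the sign of $b$ decides whether the curve falls (naive
fraction, total count) or rises (memory fractions). The model is monotone
in age, which matches fractional trajectories well; peaked absolute-count
trajectories are approximated by their dominant trend (see Limitations).

Parameters are estimated by ordinary least squares. `fit_exponential()`
exploits the model's separable structure: for any fixed $c$ the model is
linear in $(a, b)$ and the conditional optimum has a closed form, so only
$c$ has to be searched. The profiled SSR is evaluated on a 321-point grid
over $c \in [-8, 8]$ per year (rates beyond that are indistinguishable from
step functions on a 0–18-year domain), every local minimum of the grid is
polished with 1-D minimization (`stats::optimize`), and the winner is
re-refined until the SSR improves by less than a relative $10^{-10}$.
Grid ties are broken toward smaller $|c|$, i.e. the smoother curve. This
is deterministic, needs no starting values, and is directly checkable
against a brute-force grid oracle — the test suite verifies on random
datasets that the fitted SSR never exceeds the best of 200 exact linear
solves over the same bracket. Constant responses return the degenerate fit
$(a = \bar y,\; b = 0,\; c = 0)$; fewer than 4 points or fewer than 3
distinct ages are rejected. No weighting is applied even though the data
are heteroscedastic: the procedure is plain least squares by design, and
the band construction below absorbs the residual spread empirically.

## Reference bands

The reference limits are distribution-free. With residuals
$r_i = y_i - \hat\mu(x_i)$ from the fit, the band at confidence probability
$p$ is

$$[\hat\mu(x) + q_{(1-p)/2}(r),\; \hat\mu(x) + q_{1-(1-p)/2}(r)],$$

where $q$ is the empirical quantile with linear interpolation between order
statistics (R's `quantile` type 7). The offsets are age-constant: the band
is the fitted curve shifted up and down by a single residual quantile pair,
so its width does not vary with age. Default confidence probabilities are
0.90 and 0.95, with equal tail mass $\,(1-p)/2\,$ on each side. After
construction, limits (and the predictive value) are clamped to the
biologically possible range — fractions to $[0, 100]$ %, counts to
$[0, \infty)$. Intervals are closed: a value exactly on a limit is within
range. `empirical_coverage()` validates the construction: fitting on
$n = 500$ skewed-noise subjects and testing on an independent
10,000-subject draw from the same process recovers the nominal 0.90/0.95
coverage to within about $\pm 0.02$, which is what "distribution-free"
promises and Gaussian-only fixtures could not demonstrate.

Numerical notes: with fewer than 20 residuals the quantile offsets are
poorly determined and a warning is raised; a non-converged fit is refused
outright; zero-spread residuals yield bands that coincide with the curve.

## The synthetic cohort generator

No subject-level data ships with the package, so every analysis runs on
synthetic cohorts from `generate_cohort()`. The defaults emulate the kind
of cross-sectional pediatric study that motivates the method:

* **n = 184** children, ages **2 days to 18 years** (6570 days).
* **Log-uniform age sampling**, over-representing infancy where the curves
  move fastest. This is deliberately more infant-heavy than a typical
  enrollment table; it makes the age-0 behaviour of the fits
  well-determined, which is where the curves are steepest and reference
  errors matter most clinically.
* **Trajectories** (see `default_trajectories()`): naive fraction
  $77 + 21 e^{-0.45x}$ (98 % at birth), total CD19+ count
  $250 + 1550 e^{-0.5x}$ (1800 cells/ul at birth), non-switched and
  switched memory fractions rising from ~0.2 % to 7 % and 8 %. Subset
  absolute counts are derived as *total count x fraction / 100*, so every
  record is internally consistent, and the absolute memory count peaks
  near age 2 as the product of a falling total and a rising fraction — no
  separate peaked trajectory is needed, though a biexponential
  `trajectory_spec` is available for explicitly peaked fixtures. The
  biexponential is generator-only and never fitted.
* **Noise** is skewed by default — a shifted gamma standardized to mean 0
  and unit sd (skewness 1, i.e. gamma shape 4), scaled by
  `noise_scale + noise_prop * |mu|` so counts and memory fractions are
  heteroscedastic. The naive fraction uses a left-skewed tail (values
  bounded above by 100). A Gaussian option exists for closed-form oracle
  tests (e.g. the 95 % half-width $\approx 1.96\sigma$ check). Noise is
  added before clamping, so the generator produces what a laboratory could
  observe.
* **Screening flags** are drawn per subject at rates 16/227, 21/227 and
  6/227 for abnormal counts/CRP, missing labs and insufficient material;
  subjects without material carry no panel. The female fraction is 64/174.
* **CD19/CD20**: each subject's CD20+ fraction of CD19+ B cells is a beta
  draw with mean 0.99; CD20-denominated naive/switched fractions are the
  CD19-denominated ones shifted by +2 and −2 percentage points (clamped),
  reproducing the opposite-signed denominator effects reported for the two
  subsets, which pure denominator arithmetic cannot produce
  simultaneously.

What the generator does **not** emulate: flow-cytometry events, gating or
compensation; longitudinal correlation (every subject is independent);
seasonal or batch effects; and any real-data deviation from the exponential
family of trajectories. Passing tests therefore demonstrate that the
pipeline recovers what this generative model encodes — not that real B cell
development follows a three-parameter exponential.

## Screening

`screen_cohort()` applies the inclusion criteria to a manifest: each record
is assigned to exactly one category in fixed priority order — abnormal
screening (positive CRP/abnormal counts, or age $\geq$ 18 years) first,
then missing labs, then insufficient material, else included. The priority
order is a design choice (no ordering is canonical); it guarantees the
mutually exclusive accounting in which category counts sum to the number
assessed. The age cut is implemented as `age_days < 6570` (365 x 18,
half-open), ignoring leap days. Age-based exclusions are counted inside
the abnormal-screening category rather than reported separately.

## Grouped-versus-continuous comparison

`grouped_reference()` builds the conventional step reference (half-open
age bins, default edges 0–1–2–5–11–18 years; per-group mean and 5th/10th/
50th/90th/95th percentiles with the same type-7 quantile rule), and
`as_grouped_reference()` ingests externally published tables without
refitting — the boundaries must be supplied explicitly because published
tables rarely state them unambiguously. `step_discontinuity()` quantifies
the jumps at group boundaries; the continuous curve's movement is bounded
by `max_daily_increment()` $= |bc|\,e^{\max(0, 18c)}/365$ per day, and on
any trending measure the grouped jumps exceed that bound by orders of
magnitude — the core argument for continuous references. One geometric
subtlety: when residual spread is small the continuous band is narrow, and
a grouped band built from the same data will lie partly *outside* it at
most ages (each group's percentiles span a range of curve values); the
overlay report therefore describes disagreement rather than asserting
containment.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| band confidences | 0.90, 0.95 | — | the two probabilities reference charts conventionally print |
| quantile rule | type 7 | — | linear interpolation between order statistics; continuous in the data |
| `c_range` | [−8, 8] | /year | faster rates are step-like on 0–18 y |
| grid points | 321 | — | 0.05/year spacing; every local basin refined afterwards |
| convergence | rel. SSR < 1e−10 | — | profiled SSR is cheap; tight tolerance is free |
| age coordinate | `age_days/365` | years | day 2 → 0.00548 y; leap days ignored |
| clamping | after noise / after bands | — | matches what a laboratory can observe or report |
| patient age domain | [0, 18] | years | older patients are rejected, not extrapolated |

## Problem sizes

The shipped analyses and tests use cohorts of 184 (the emulated study
size) to 1500 subjects, coverage test sets of 10,000, 200 replicate fits
for rate-recovery checks and 50 random datasets against the brute-force
oracle — sizes at which every stochastic check has comfortable
Monte-Carlo margin while the full suite runs in a few minutes on one CPU.

## Known limitations

* The monotone model cannot represent the early-childhood peak in absolute
  memory counts; the fit smooths through it. A peaked model family was
  deliberately left out of the fitting scope.
* Age-constant band offsets ignore heteroscedasticity: where spread grows
  with the predicted value (counts in infancy), pooled quantiles
  over-cover quiet ages and under-cover noisy ones even though overall
  coverage is nominal. Age-varying widths (e.g. GAM/spline references)
  are other methods' territory and out of scope.
* Empirical 5th/95th residual quantiles need substantial n; below ~20
  residuals the bands are anecdotal (the package warns).
* Fractions and absolute counts are fitted independently; their references
  are not constrained to be mutually consistent.
* The calculator flags values against references; it performs no
  diagnostic classification.
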