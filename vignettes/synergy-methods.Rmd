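---
title: "Scoring two-drug checkerboards: reference models, MuSyC surfaces, and the companion PK/efficacy computations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring two-drug checkerboards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synercomb)
```

## The problem

A checkerboard (combination-matrix) screen crosses increasing concentrations
of two drugs so every dose pair is measured, typically with a vehicle control
and the two monotherapy titrations on the zero-dose edges. The scientific
question is whether the combination does more than the two drugs would do
without interacting — and if so, whether the gain is in potency, in maximal
effect, or in steepness of response. `synercomb` implements the two
complementary ways this question is asked in current practice:

* **Nonparametric delta scores.** For each combination cell, the observed
  inhibition is compared to the inhibition expected under a non-interaction
  reference model; the cell-wise excess, in percentage points, is the delta
  score, and the matrix summary is its mean over combination cells. Four
  reference models are provided: Bliss independence, Loewe additivity,
  highest single agent (HSA) and zero interaction potency (ZIP).
* **Parametric MuSyC surface.** A single dose-response surface is fitted to
  the whole matrix, and synergy is decoupled into dose-independent fold
  metrics: potency (`alpha`), efficacy (`beta`) and cooperativity (`gamma`).

All synergy computation happens on the percent-inhibition scale (0 =
untreated, 100 = complete kill); viability inputs are converted on ingestion.
Inhibition is clipped to [0, 100] before reference-model scoring, because the
Bliss product form needs proper fractions, while the unclipped values are
retained for curve fitting, which should see the raw data.

## Monotherapy model

Every reference expectation is built from **fitted** monotherapy curves, not
from the raw edge wells. The monotherapy model is the four-parameter
log-logistic (Hill) curve

$$E(d) = E_0 + (E_{max} - E_0)\,\frac{d^h}{C^h + d^h},$$

with `C` the relative EC50 (nM) and `h` the Hill slope. On the inhibition
scale, `100 - Emax` is the resistant plateau: the fraction of cells that
survive arbitrarily high dose, a real feature of these cell populations that
the fit must be free to express. `C` and `h` are estimated in log space
(positivity without constrained arithmetic); initialization is deterministic
and multi-start (`h` in {0.5, 1, 2}; `C` at the dose bracketing the
half-range response), so identical inputs always give identical fits. Fits
are unweighted least squares.

Two IC50 notions are reported and labelled, because summary tables in the
literature rarely say which one they print: the **relative EC50** (parameter
`C`) and the **absolute IC50** (the dose at 50% inhibition, `NA` when the
curve never crosses 50%). `curve_shift()` tabulates the absolute IC50 of one
drug at each fixed concentration of the partner, the classic visual check
for potency synergy.

## Reference models

For fitted monotherapy inhibition fractions $y_1(d_1)$, $y_2(d_2)$:

* **Bliss:** expected fraction $y_1 + y_2 - y_1 y_2$ (independent action).
* **HSA:** expected fraction $\max(y_1, y_2)$. Because the Bliss expectation
  dominates the HSA expectation for fractions in [0, 1], HSA deltas are
  cell-wise at least the Bliss deltas — a structural invariant the test
  suite checks on random matrices.
* **Loewe:** the expectation $y$ solves $d_1/D_1(y) + d_2/D_2(y) = 1$, with
  $D_i$ the inverse Hill function. The left side is strictly decreasing in
  $y$, so the root is found by bisection to a tolerance of 1e-9. When $y$
  exceeds one drug's `Emax`, that drug's $D_i(y)$ is infinite and its term
  vanishes, letting a strong partner carry the expectation past a weaker
  drug's plateau. A drug whose fitted curve shows no inhibition gain
  (`Emax <= E0`, which near-flat noisy edges can produce) is treated as
  inactive: its dose contributes nothing and the expectation reduces to the
  other drug's curve. A sham combination (a drug with itself) reproduces the
  monotherapy prediction at the summed dose exactly.
* **ZIP:** monotherapy curves are refitted under the bounded-response
  convention (`E0 = 0`, `Emax = 100`), and the observed side is smoothed by
  conditioned two-parameter Hill fits along each row and column, with the
  lower asymptote pinned at the fitted partner response. The cell delta is
  the average of the two conditioned predictions minus the Bliss expectation
  of the fitted monotherapies. A conditioned fit that fails (e.g. a
  saturated line with no variance) falls back to the raw Bliss delta for
  that line and is flagged in the result.

Delta means are taken over combination cells only (both doses > 0):
monotherapy edges have zero expected interaction by construction and would
only dilute the score. All four deltas are invariant to swapping the two
drugs, and adding a constant to every combination cell adds that constant to
every cell delta.

ZIP is not exactly null under dose additivity: scoring a noise-free sham
combination (the canonical Loewe-null case, built from a full-kill Hill
curve on the 5 x 5 layout) gives a mean ZIP delta of **+0.62** points (Bliss
+0.65, HSA +0.91) — small relative to the ±5-point classification band, but
not zero, which is why sham calibration is asserted at the Loewe score and
only bounded (±2 points) at ZIP.

## The MuSyC surface

The parametric surface is the steady state of a four-state population model:
unaffected (U), affected by drug 1 (A1), by drug 2 (A2), and by both (A12),
with Hill-type mass-action transition rates. The observed response is the
state-weighted mixture $U E_0 + A_1 E_1 + A_2 E_2 + A_{12} E_3$ on the
viability-fraction scale (`E0` near 1). Only rate ratios matter at steady
state, so the base rates are fixed at 1, removing two unidentifiable
parameters. The synergy metrics:

* `alpha21` scales the effective dose of drug 1 acting on cells already
  affected by drug 2 (transition A2 -> A12); `alpha12` symmetric. Values
  above 1 mean each drug potentiates the other.
* `gamma21` scales drug 1's Hill slope in that same transition
  (cooperativity); `gamma12` symmetric.
* `beta = (\min(E_1, E_2) - E_3) / (E_0 - \min(E_1, E_2))` is derived from
  the fitted asymptotes: the fractional increase in maximal effect of the
  combination over the most efficacious single agent. It is negative when
  the combination plateaus shallower than the best single drug.

The subscript convention (which index modulates which drug) is stated here
deliberately: published tables built on this model rarely define it, and the
two orderings are easy to confuse. `synercomb` fixes *alpha21 = how drug 2
changes drug 1's potency*, matching the fitting framework most analyses use.

**Steady-state computation.** The balance system with the normalization
$U + A_1 + A_2 + A_{12} = 1$ is solved in closed form: Cramer's rule reduces
each state occupancy to a sum of four rate monomials of a single sign, which
are evaluated in log space. This is algebraically identical to the naive
4 x 4 linear solve (the tests verify agreement to ~1e-11 over random draws)
but vectorizes over the whole dose grid and cannot overflow at extreme
slopes or EC50s. An independent oracle — long-time integration of the four
rate equations via a repeatedly squared matrix-exponential propagator —
confirms the steady state to 1e-6 over seeded random draws.

**Fitting.** Nonlinear least squares over the twelve parameters, with EC50s,
slopes and the four folds in log space (positivity, and synergy/antagonism
symmetric around log 0). Initialization is deterministic: monotherapy Hill
fits seed the single-drug parameters, `E3` starts at the minimum observed
response, folds start at 1, plus a fixed multi-start over fold
initializations. Bounds: folds in [1e-5, 1e5], slopes in [0.05, 20], and
asymptotes in **[0, 2]** — viability fractions are physically nonnegative,
and the lower bound matters: without it the likelihood admits a degenerate
mode (a vanishing fold parameter compensated by a deeply negative `E3`)
that corrupted roughly one noisy fit in ten during development.

**Instability flagging.** Real kinetic data produce boundary-unstable fold
estimates (enormous values with even larger SDs) at early timepoints where
one drug has barely acted. Rather than clipping, `musyc_fit()` flags a fold
parameter whose profile is flat over a 100-fold range or whose estimate is
pinned against a bound; flagged values are excluded from aggregation means
by default and classification calls on them are marked `not_applicable`.

## Gating, aggregation and classification

Fits with `r_squared` below 0.8 are excluded (with a log naming the
timepoint and assay) before aggregation — in kinetic assays this reproduces
the practice of restricting analysis to the window where single agents show
measurable efficacy (the 28-80 h window is the default). Cross-model and
cross-timepoint summaries are unweighted means with sample SDs (n - 1).

Classification thresholds: a mean delta of at least +5 points is synergism,
at most -5 antagonism, in between additivity (boundaries inclusive; 5 points
is the typical noise level of large combination screens). MuSyC folds are
additive at 1 and `beta` at 0; since a fitted value never equals its
threshold exactly, an additivity band is applied (±0.05 on `beta`, ±5% on
folds). Consensus across reference models grades the call: all models
synergistic is a strong synergy, some but not all is weak, a mix of
synergism and antagonism is discordant.

One aggregation subtlety is worth stating: when assay-level rows are
themselves means over timepoints, the cross-assay mean of the printed rows
need not equal any particular pooled statistic of the underlying matrices.
The package's cross-assay aggregator is defined as the unweighted mean of
per-matrix deltas pooled across assays (`analyze_checkerboards()`), and
`aggregate_models()` separately reproduces the mean-of-model-means
arithmetic used in summary tables.

## What the synthetic generator emulates — and what it does not

`generate_matrix()` evaluates a ground-truth surface (a `musyc_surface()` or
a named null: `bliss`, `loewe_sham`, `hsa`) on one of the two assay layouts
(5 x 5 over 12.5-200 nM x 0.25-4 nM; 7 x 7 over 62.5-4000 nM x 0.625-40 nM,
both with vehicle edges) and adds i.i.d. Gaussian plate noise on the percent
scale (default SD 5, the screen-noise level behind the ±5-point
classification band). Kinetic readouts ramp the kill amplitude linearly from
an onset delay (default 24 h — these drug classes act through slow
signal-transduction cascades, so 12 h and 24 h readouts are near-flat) to
full effect at 80 h. Default truth parameters follow the observed
monotherapy potencies of the emulated assays (EC50s of ~65.7/260 nM for the
row drug and ~0.58/0.8 nM for the column drug), single-agent resistant
plateaus (`E1 = 0.4`, `E2 = 0.3` surviving), potency folds of 2.2 and a
combination plateau giving `beta` near 0.23.

The generator is a *stated world*, not a tuned one: Gaussian plate noise is
the simplest defensible model, biological variability in the PK and tumour
generators is log-normal, and none of these choices were revisited after
seeing test outcomes. Consequences to keep in mind when reading green tests:
real plates have spatial (edge/drift) noise structure, replicate-correlated
errors and occasional gross outliers, none of which are emulated; a
passing recovery test certifies the estimator against the stated noise
model only.

`generate_pk()` produces one-compartment oral profiles
$C(t) = A(e^{-k_e t} - e^{-k_a t})$ scaled to a target Cmax, sampled
destructively (n animals per timepoint, one sample per animal) at 1.5, 4, 8
and 24 h, with per-animal log-normal scale variability and a combination
multiplier to emulate exposure interaction in either direction. The presets
use `ka = 2`/h (fast absorption, observed Tmax at the first 1.5 h sample)
and `ka = 0.5`/h (Tmax at 4 h), `ke = 0.1`/h.

`generate_tumour_study()` grows control tumours exponentially (default
0.14/day from 165 mm^3, log-normal initial-volume CV 10%) and multiplies
each dosing day's growth by `(1 - kill)` under qdx3/qdx6 schedules;
calliper (width, length) pairs are back-computed from volume with a fixed
aspect ratio. `kill_for_ratio()` inverts the schedule algebra so arms can be
specified by their end-of-dosing treated/control volume ratio.

## Statistical precision of MuSyC recovery

How well can `beta` be recovered from one noisy matrix? At the default
7 x 7 design with 5%-SD noise and a truth with `beta = 0.36`, the
Cramer-Rao bound on any unbiased estimator is sd(`beta`) of about 0.11 —
a *single* matrix cannot support median errors much below ~0.075 no matter
the fitting algorithm. The assays this package emulates are run with n = 3-4
replicates, and fitting the replicate-mean matrix (noise SD reduced by
sqrt(3)) brings the observed median absolute error of `beta` to ~0.04 and
of `log alpha` to ~0.21 over 20 seeded experiments. The recovery tests
therefore simulate the full replicate design, which is the package's
recommended workflow for parametric surface fitting; per-replicate fits
remain the right choice for the nonparametric deltas, whose replicate SDs
are themselves reported.

## Non-compartmental PK and tumour growth inhibition

`auc_linear_trapezoid()` implements the linear trapezoidal AUC with a
leading (0, 0) point prepended when the first sample time is after dosing
(extravascular dosing: concentration at dose time is zero; without this
convention AUC from time zero is undefined). No extrapolation to infinity
and no terminal-slope estimation are performed — exposure is AUC(0-last).
Concentrations below a configurable LLOQ are zeroed before integration.
Destructive sampling yields no true animal profiles, so
`nca_from_pseudoprofiles()` forms index-paired pseudo-profiles (the k-th
animal at every timepoint); the resulting SDs are one plausible
reconstruction of how summary tables report variability under this design,
and are documented as a convention, not asserted as the original
computation. Tmax ties resolve to the earlier time.

`tumour_volume()` is the prolate ellipsoid `d^2 D / 2` (width squared times
length over two), with silently swapped calliper axes corrected under a
warning. `tgi_series()` computes per-animal TGI against the control-group
*mean* volume (control uncertainty is not propagated into the SEM — the
source computation is unstated, and this is the simplest defensible
construction), matches measurement days within ±1 day for the 2-3x/week
calliper schedule, and reports the maximum of the per-day means as the
headline "max TGI". Animals leaving the study contribute until their last
measurement; nothing is imputed.

## Numerical choices, in one place

* Loewe bisection tolerance 1e-9 on the response; boundary roots returned
  with a `boundary` attribute rather than an error.
* Hill and MuSyC fits: `nlminb` with `rel.tol = 1e-15`, deterministic
  multi-start, log-space positive parameters; MuSyC asymptotes bounded to
  [0, 2] (see above).
* MuSyC steady state: closed-form log-space monomials; no linear solve at
  run time, no overflow for slopes up to the bound of 20.
* ZIP conditioned-fit failures fall back to raw-vs-Bliss deltas and are
  flagged, never silently dropped.
* Baseline correction of raw plates beyond control normalization is *not*
  applied (the original analyses' setting is unknown); `normalize_response()`
  implements plain control normalization with clipping.
* All generators take a single integer seed that fully determines output.

## Known limitations

* No bootstrap confidence intervals for MuSyC parameters (the raw wells the
  bootstrap would resample are exactly what real studies rarely release).
* Three-or-more-drug combinations are out of scope.
* The ZIP sham bias (+0.6 points at the tested design) means ZIP deltas of
  well under a point should not be over-interpreted.
* Compartmental/PBPK modelling, tissue-distribution corrections and
  tumour-growth model fitting are deliberately not provided; this package
  computes the assay-level quantities those downstream models consume.
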