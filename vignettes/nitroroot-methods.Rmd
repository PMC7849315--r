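---
title: "Methods: the nitroroot model, its calibration and its limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the nitroroot model, its calibration and its limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nitroroot)
```

## Scope and assumptions

`nitroroot` models the first few dozen cells of the epidermis and cortex
files of the Arabidopsis root tip as two parallel one-dimensional chains
of compartments. Cells carry amounts (not concentrations) of auxin,
cytoplasmic PIN2, face-resolved membrane PIN2, a division factor, and a
length. Nitrogen nutrition enters as a single binary signal `N`
(0 = ammonium, 1 = nitrate) with an arbitrary switch schedule
(`nitrogen_regime()`). There is no 2-D geometry, no wall mechanics, no
other auxin carrier, and no description of PIN2 phosphorylation
biochemistry: nitrate acts purely through two phenomenological knobs,
the basal trafficking rate (`tr_n` vs `tr_wn`) and the lateral
redirection fraction (`l_n · N`).

## Tissue topology

Within a file, consecutive cells share one wall; PIN2 carries auxin
across a wall in proportion to the pumping cell's auxin and its PIN2 on
the face adjoining that wall. Basal faces carry no PIN2 by default, so
within-file transport is strictly shootward. The basal wall of cell 1
is closed (the QC input is already represented by the source term).

The two files share one lateral wall per index pair: the lateral
("outer") face of each file sits on this shared wall, so lateral PIN2
pumps auxin *into the adjacent file*, in both directions. Auxin pumped
apically out of the last windowed cell leaves the system (the outer
limit of the simulated tissue strip), and is booked to the mass ledger.

This wiring is a deliberate design decision. The alternative — an
epidermal lateral face that pumps straight out of the root — leaves the
cortex with no auxin input at all (the model excludes an auxin influx
from the inner tissues, and the cortex has no source of its own). A
cortex without auxin can neither elongate nor sustain divisions, which
contradicts the very behaviour the model exists to explain: that
nitrate-induced PIN2 lateralization couples the growth of the two
files. With the shared-wall wiring, ammonium (`l_n·N = 0`) leaves the
cortex auxin-free and asynchronous, while nitrate opens the lateral
route and pulls the cortex into near-synchrony with the epidermis —
the observed contrast.

## Dynamical rules

All rules live as pure R functions in `R/core-model.R` (`auxin_rhs()`,
`pin2_cytoplasm_rhs()`, `pin2_trafficking_rate()`,
`pin2_membrane_rhs()`, `division_factor_rhs()`, `growth_rhs()`); the
compiled integrator reimplements them for speed and is cross-checked
against them in the test suite, one Euler step at `dt = 1e-6` against
the assembled R right-hand sides.

Two reconstructions deserve comment, because the trafficking and
division-factor formulas are typographically ambiguous in their printed
source:

* **Trafficking prefactor.** The basal trafficking rate is read as a
  binary regime selection `N·tr_n + (1−N)·tr_wn`, gated by the standard
  logistic `1/(1+e^{−x})` of `tr_a·A + tr_i·i` (the printed rule names
  logistic coefficients but no functional form). The delivered flux is
  split `l_n·N` to the lateral face, remainder to the apical face.
* **Mass conservation.** As printed, trafficking would create membrane
  PIN2 from nothing and membrane PIN2 would never decay. By default the
  trafficking flux debits the cytoplasmic pool and every membrane face
  decays at the same auxin-enhanced rate `d_p (1 + A/q_p)` as the
  cytoplasmic pool (consistent with the vacuolar-degradation biology
  the model cites). `model_parameters(literal_equations = TRUE)`
  restores the literal non-conservative reading for comparison runs;
  the steady-state solver refuses it (no bounded membrane steady state
  exists).

The division factor follows the grouping
`synthesis = k_v0 k_v1 (A/maxA + len/maxL) / (1 + e^{i·t_v})`,
`degradation = DIV · k_v2 (1 + (A/k_v3)^{h1}) / (1 + (A/k_v4)^{h2})`:
synthesis falls monotonically with distance from the QC, degradation is
linear in the factor and shut down at high auxin.

## Parameters

Defaults in `model_parameters()` are the estimated means of the model
calibration: `s1 = 8.36`, `s2 = 22.53`, `z = 10.6`, `m_p = 30.49`,
`d_p = 0.065`, `q_p = 100`, `l_n = 0.60`, `tr_n = 0.246`,
`tr_wn = 0.13`, `tr_a = −0.05`, `tr_i = 0.30`, `k_v0..k_v4 =
(1.5, 20, 0.3, 3.5, 0.5)`, `t_v = 0.1`, `h1 = 2`, `h2 = 3`,
`k_l = 0.3`, `m_l = 200` (both zones; the printed table gives one value
each although both are zone-dependent in principle, so the per-zone
fields default to the shared value). Only the ratio `d_a/k_a = 0.018`
is identified; it is realized as `k_a = 1`, which *defines* the model
time unit, and `d_a = 0.018`. Lengths are in micrometres, auxin and
PIN2 in arbitrary units.

One documented contradiction is preserved rather than resolved: the
parameter table estimates the source-switch index as `z = 10.6`
(credible interval 8.4–12.0) while the surrounding prose calls it
"cell number 20". The table value is used.

Package-level constants the source leaves open:

* `A_thr_ammonium = 0.4833`, `A_thr_nitrate = 0.5149` — relative-auxin
  elongation thresholds, frozen from
  `calibrate_elongation_thresholds()`, which bisects each threshold
  until the default steady state places the epidermal elongation onset
  at cell 11 (ammonium) and cell 13 (nitrate), the experimentally
  observed onsets. The nitrate threshold is higher, encoding that more
  auxin is required to trigger elongation on nitrate.
* `DIV_thr = 8`, `min_div_length = 7` µm — chosen once from a timescale
  argument: near the QC the division factor recharges at roughly 3–4
  units per time, so a threshold of 8 gives an inter-division time of
  the same order as the growth doubling time (`ln 2 / k_l ≈ 2.3` time
  units, slowed by the auxin gate), which keeps meristematic lengths
  bounded around ~10–30 µm instead of drifting toward `m_l`.
* `window = 40` cells per file; cells pushed past it are dropped and
  their auxin booked as advection loss.
* `maxA` (the relative-auxin normalization) defaults to the running
  maximum over *all* windowed cells of both files. Restricting the
  maximum to meristematic cells — superficially the more literal
  choice — is unstable: auxin rises toward the transition zone, so the
  distal-most meristematic cell always has relative auxin exactly 1,
  any threshold ≤ 1 fires, and the transition cascades cell by cell to
  the QC until the meristem is empty. A fixed numeric `maxA_mode` is
  available as an override.

## Numerics

The simulator advances both files with a fixed-step classical RK4
(explicit Euler retained as a cross-check), default `dt = 0.001` time
units. Before every step the largest per-pool loss-rate coefficient is
computed; the step errors out if `dt × rate ≥ 0.5`. This bound is not
decorative: at default parameters, membrane PIN2 reaches several
hundred units, making the auxin export coefficient `k_a·ΣPINm ≈ 300`
per time — auxin is a fast variable slaved to the PIN2 pattern, and
steps much above `10^-3` are genuinely unstable.

After each step, events are applied in a fixed order: elongation
transitions (closed threshold, `≥`, ties transition; one-way), then
divisions scanned from the QC outward (daughters get half of every
amount, the division factor resets to zero, the event is logged at the
mother's index), then window trimming. The auxin ledger accumulates
source input, turnover, shootward boundary efflux and advection loss
with the same RK4 stage weights as the state update, so it closes to
machine precision (~1e-12 relative; the tests require 1e-8).

The long-run state is a division/growth limit cycle, not a fixed point:
instantaneous onset indices breathe by one to two cells as division
waves pass. `summarize_run()` therefore reports the median onset and
mean meristem size over the trailing third of recorded snapshots, and
threshold calibration uses the same statistic. Two different naive
initializations agree on onset exactly and on meristem size to within
about 2% — residual limit-cycle phase, not a secular drift.

For fitting, a separate positional steady-state solver
(`steady_state_profile()`) computes the exact transport steady state at
fixed positions: because basal faces carry no PIN2, positions decouple
shootward and each epidermis/cortex pair solves a linear 2×2 system
given the membrane pools, with the weak auxin dependence of the pools
(via `q_p` and `tr_a`) handled by an outer fixed-point iteration to
1e-12. It matches brute-force time integration to 1e-5 in the tests
and makes a likelihood evaluation cost milliseconds instead of seconds.

## Inference

The likelihood (`log_likelihood()`) treats each observation as Gamma
distributed with mean equal to the steady-state prediction for its
(condition, tissue, position, measurement) and one free shape
(dispersion) per measurement type — the Gamma family mirrors the
distributional choice made for the original cell-length regressions.
The fitted measurements are the steady-state observables: relative
auxin and PIN2 face intensities. Cell lengths are *not* fitted: their
steady profile is an emergent limit-cycle property, and which
measurements entered the original likelihood is unstated; the
observation generator records which measurements it emitted.

`sample_posterior()` runs an adaptive random-walk Metropolis sampler
(4 chains by default): a Gaussian proposal whose covariance is refreshed
during warmup from the recent sample covariance (scaled `2.4/√d`) with
a global step-size factor tuned toward ~30% acceptance. Split R-hat
and an autocorrelation-based effective sample size are reported per
parameter; violations of R-hat < 1.05 or ESS > 100 warn rather than
error. Priors default to weakly-informative half-normals with scale
three times the parameter's default value, uniform on [0, 1] for
`l_n`, and a half-normal on each Gamma dispersion; with an empty
observation table the sampler reproduces the prior, which is tested.
Note one structural feature: relative-auxin data are normalized, so the
overall source scale is not identified (only ratios such as `s2/s1`
and the switch position `z` are); the scale direction is then set by
the prior, and credible intervals along it are correspondingly wide.

Single-parameter recovery (`recover_parameter()`) maximizes the same
likelihood by coarse-grid bracketing plus golden-section refinement and
errors out when the likelihood is flat in the parameter (e.g. the
division-factor constants, which steady-state observables cannot see).

`psis_loo()` implements Pareto-smoothed importance-sampling
leave-one-out cross-validation directly: per left-out observation the
raw importance ratios `1/p(y_i|θ_s)`, a generalized-Pareto fit
(Zhang–Stephens profile-posterior estimator) to the upper 20% tail,
replacement of the tail by expected order statistics of the fitted
distribution truncated at the raw maximum, and the weighted predictive
density. Points with tail shape `k > 0.7` are flagged; with fewer than
five tail draws (or a failed fit) the estimator falls back to truncated
importance sampling, also flagged. On conjugate-Gaussian problems it
agrees with exact leave-one-out (analytic refits) to better than 0.1
elpd. `compare_models()` fits the four auxin-source scenarios — uniform
(A), two-source QC+LRC (B), natural cubic spline with five knots
clamped non-negative (C), independent per-cell rates (D) — on the same
observations and ranks them by elpd; ties keep input order.

## The synthetic-data generator

The generator produces the statistical *structure* of the study's
measurements, not images:

* `generate_length_profiles()` draws per-root Gamma-noised lengths
  around a flat-then-linear mean curve. Only printed scalars are
  treated as calibration truth: the four position-10..20 OLS slopes
  (3.32639 and 1.22033 µm/cell for ammonium epidermis/cortex, 1.70502
  and 0.82342 for nitrate) and the epidermal onsets 11 (ammonium) and
  13 (nitrate). Cortex onsets are not printed; both are set to 13
  (delayed relative to the ammonium epidermis, matched on nitrate).
  The per-segment slope is solved in closed form so the *expected* OLS
  slope over positions 10–20 equals the target, which makes
  `slope_between()` an unbiased estimator of the calibration value —
  a tested property. The baseline is 10 µm and the Gamma shape 25
  (~20% CV), a realistic spread for cell-length data.
* `generate_model_observations()` is the simulate-then-corrupt path for
  recovery and model-comparison studies: steady-state predictions
  wrapped in multiplicative Gamma noise with a chosen CV.
* `generate_r2d2_profiles()` emulates the ratiometric auxin reporter:
  paired degradable/stable signals whose normalized inverse ratio
  (`normalize_r2d2()`; auxin degrades the Venus moiety, so *low* ratio
  means *high* auxin) rises beyond the onset in the ammonium epidermis
  while the ammonium cortex stays flat, and both files share a trend on
  nitrate. Normalization is per root (the printed description does not
  fix the constant; per-root maximum was chosen).

What passing these tests shows — and does not show: the pipeline
recovers parameters and ranks models correctly *when the data come from
the model's own measurement structure*. Real fluorescence data carry
spatial correlations, segmentation error and attenuation with depth
that the generator deliberately omits.

## Known limitations

* **The ammonium cortex is inert.** With the lateral route closed
  (`l_n·N = 0`) the cortex receives no auxin at all, so it neither
  grows nor divides on ammonium — an exaggeration of the observed
  (slower, delayed) cortex growth. Two artifacts follow: the simulated
  ammonium cortex slowly accumulates membrane PIN2 at fixed positions
  (no division dilution), so the nitrate-over-ammonium membrane-PIN2
  contrast holds per measured position (cells 1–20, the fluorescence
  readout) but not for the whole-window simulated total; and the
  ammonium cortex "onset" is reported as `window + 1`.
* **Epidermal shootward flux ordering.** Redirecting 60% of trafficked
  PIN2 laterally necessarily lowers epidermal apical PIN2 on nitrate,
  and total steady-state throughput is pinned to the source input in
  both regimes, so the model does not reproduce a higher *epidermal*
  basipetal flux on nitrate. The experimentally motivated direction of
  that effect is not recoverable from these equations at these
  parameters.
* **Relative-auxin values are clipped at 1** in the generator (the
  schema bounds them to [0, 1]); at the maximum position this truncates
  the noise distribution slightly downward.
* The sampler is a random-walk method: adequate for the ≤ 23-parameter
  variants used here, but variant D's 20-dimensional source vector
  mixes slowly and its diagnostics routinely warn.

## Problem sizes

The test suite and acceptance script run at deliberately desk-scale
sizes: simulations of 2 × 40 cells to 300 time units (≈ 3·10^5 RK4
steps, a few seconds each), slope round-trips with 10 generations of 18
roots, recovery at 20 seeds × 4 parameters, and model comparison with
500 draws × 2 chains per variant. The whole suite runs in a few
minutes on one CPU.
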