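---
title: "Simulating and analysing oddball pupillometry with oddpupil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing oddball pupillometry with oddpupil}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

In an auditory oddball task a participant listens to a stream of short
(100 ms) tones, most of which (84%) are a frequent *standard*, while two rare
types (8% each) are interleaved: a task-relevant *oddball* that requires a
response, and a task-irrelevant *deviant* that does not. The pupil dilates
transiently after salient events (a *phasic* response riding on a slowly
varying *tonic* level), so the pupil trace around each tone carries
information about how salience, task relevance and motivational state (e.g. a
monetary reward attached to the oddball) are processed.

`oddpupil` implements the complete measurement chain for such experiments:

1. a **session simulator** with fully known ground truth,
2. **readers/writers** for plain TSV sample, event and calibration files,
3. sample-level **preprocessing** (blink and gaze masking, interpolation,
   detrending, calibration to mm²),
4. **epoching** into per-trial baseline/response means and change scores,
5. **mixed-effects analysis** (sum coding, estimated marginal means,
   Holm-corrected contrast families, a tonic baseline model, a
   repeated-measures RT ANOVA).

Because the simulator and the analysis share nothing but the file formats,
the pipeline can be validated end-to-end: inject known effects, run the full
chain, and check that the estimates recover them.

## The generative model

For one block with tone onsets $t_k$ of types $\tau_k$, the simulated pupil
area in mm² is

$$
p(t) \;=\; T \;+\; d\,t \;+\; \sum_k a_{\tau_k}\, k(t - t_k) \;+\; \eta(t),
$$

with $T$ the block's tonic level (participant- and reward-dependent), $d$ a
slow linear drift (alertness declines over a block; centred within the
block so the tonic parameter stays the block's mean level), $k(\cdot)$ a
unit-peak
response kernel, and $\eta$ stationary AR(1) Gaussian noise. The trace is
stored in tracker "arbitrary units" through the inverse of an affine
calibration, which the analysis must estimate back from a table of
artificial-pupil readings.

**Response kernel.** We use the Erlang-family form
$k(t) = (t/t_{\max})^{n} e^{\,n(1 - t/t_{\max})}$ with shape $n = 10.1$ and
$t_{\max} = 930$ ms, the classic parameterisation of the event-related pupil
response: zero at onset, unit peak just before one second, decayed essentially
to zero by three seconds. Both parameters are configurable in
`ground_truth()`.

**Ground-truth parameters live on the measured scale.** Because tones arrive
every 1.2–1.7 s while the kernel lasts ~3 s, each trial's epoch windows
contain the tails of neighbouring responses — and the *baseline* window in
particular sits near the previous tone's response peak. The generator
therefore treats both the amplitudes and the tonic levels as targets for
what the pipeline *measures*, and inverts the measurement model to find the
raw signal parameters that produce them.

**Amplitudes are specified on the change-score scale.** The analysis's
dependent measure is the *change in pupil response*: the mean over the
stimulus response epoch (500–2000 ms after onset) minus the mean over the
pre-stimulus baseline (−500–0 ms). An isolated kernel of peak $a$ contributes
$g\,a$ to that score, where $g \approx 0.48$ is the kernel's window-averaged
mass. In a running sequence, neighbouring tones add expected leakage
$\kappa_{\text{resp}}$ into the response window and $\kappa_{\text{base}}$
into the baseline window per unit of mixture-average peak;
`calibrate_amplitudes()` computes $g$ exactly on the sample grid and the
leakage coefficients by deterministic numeric convolution over the
inter-tone-interval distribution, then inverts the resulting linear system.
(With this kernel and these ITIs the baseline term dominates:
$\kappa = \kappa_{\text{resp}} - \kappa_{\text{base}} \approx -0.63$, a
value the test suite verifies against a brute-force unit-peak simulation.)
Consequently `amp = c(standard = -0.3, oddball = 1.4, deviant = 0.5)` means:
*the measured change scores of this cell are centred on −0.3, +1.4, +0.5
mm²* — which is what makes recovery tests meaningful. A negative standard
amplitude encodes the small constriction (habituation) typically seen for
the frequent tone. Tonic levels are treated the same way: the generator
subtracts the expected baseline leakage $\kappa_{\text{base}}\,\bar p$ from
the tonic parameter, so the pipeline's measured baseline means — and the
tonic reward contrast — are centred on the injected values.

Each block is additionally flanked by a few *context tones* (drawn from the
same 84/8/8 mix) that are simulated in the trace but never logged as trials.
The task runs continuously after a practice block, so the first analysed tone
of a block is not context-free; without these, block-edge trials would
systematically miss neighbour leakage and bias small-block simulations.

**Participant heterogeneity.** Participants differ in tonic level
(`tonic_sd`, default 5 mm²) and in per-type response amplitude (`amp_sd`).
The defaults were chosen from the published scale of between-participant
variation in this paradigm (confidence-interval widths of group-level
marginal means imply amplitude sds of roughly 0.2/1.0/0.6 mm² for
standard/oddball/deviant and a tonic sd of ~5 mm²). These draws are exactly
what the analysis's random intercepts and slopes estimate.

**Artifacts.** Blinks arrive as a Poisson process (default 10/min, 100–400 ms
long); during a blink the pupil is missing, and for 120 ms on each side the
recorded area collapses multiplicatively toward the closure — the
"instability" that motivates masking a 200 ms margin around each missing run.
Gaze follows a bounded mean-reverting walk near fixation with occasional
4–6° excursions (default 2/min), providing targets for the 2° gaze-deviation
rule. Behaviour: oddballs are answered with log-normal response times whose
parameters depend on reward (means ≈ 690/670 ms for low/high), misses and
false alarms occur at configurable rates.

**What the simulator does not emulate.** Pupillary light reflexes (luminance
is constant in the task), saccade dynamics and foreshortening beyond the 2°
exclusion, non-linear drift, and any correlation between blink timing and
task events. Passing recovery tests therefore shows the pipeline is correct
*under this signal model*, not that the model captures every property of real
recordings.

## Preprocessing choices

The cleaning chain runs per block, in this order: detect missing-pupil runs
(missing or zero recorded area — the offline stand-in for the tracker's
online blink flags, whose velocity heuristics cannot be reproduced from
exported samples), widen each run by **200 ms** on both sides, mask samples
with gaze **≥ 2°** (Euclidean, `>=` at the boundary) from fixation, merge all
masks into disjoint half-open spans, **linearly interpolate** across them
(block edges hold the nearest valid value, since a two-point rule is
undefined there), **detrend**, and **calibrate** (least-squares affine fit to
the artificial-pupil table; the fit must have positive slope).

Two deliberate choices deserve emphasis:

* **Detrending is mean-preserving**: only the slope component
  $b\,(t - \bar t)$ is removed. Full line subtraction would also remove each
  block's mean and thereby destroy exactly the quantity the tonic
  (pre-stimulus baseline) analysis compares between reward conditions.
  Whether the original analyses preserved block means is not documented in
  the sources this package follows; the driver exposes the choice.
* **Calibration is applied last.** It is affine, so it commutes with the
  (linear) masking, interpolation and detrending steps; fitting it once and
  applying it at the end keeps every earlier step in native tracker units.

Interpolated samples are flagged and their per-trial fraction is recorded in
the measures table, but trials are *not* rejected by that fraction (rejecting
them would bias against blink-prone trials); stricter policies can be studied
from the recorded fractions.

## Epoching and exclusion rules

Epochs span −500 to +4000 ms around each tone (half-open windows on the
sample grid; 2250 samples at 500 Hz), aligned to the nearest sample at or
after the onset. Epochs that would cross a block edge are dropped with a
warning. The per-trial measures are the baseline mean (−500–0 ms), the
response mean (500–2000 ms), and their difference, the change score — by
construction invariant to any additive shift of the trace.

Errors are: a manual response to a standard or deviant, or no response to an
oddball. Error trials leave the pupil analysis; participants with an overall
error rate *strictly above* 20% leave entirely. In counting blocks no
manual-response criterion applies. Under the reward design, responses slower
than the 0.7 s feedback deadline still count as responses — the deadline
gates reward, not trial validity.

## Statistical model

Change scores are modelled by linear mixed-effects regression (`lme4`, REML)
under **sum-to-zero contrast coding**, so the intercept is the grand mean of
cell means and interactions are interpretable. The participant random
structure is chosen on an AIC ladder — intercept + slopes on all fixed
factors, intercept + slopes on trial type, intercept only — at matched fixed
structure; ties go to the simpler model, and a singular fit falls back one
rung automatically. (Comparing REML fits by AIC across random structures is a
known approximation; an ML toggle is provided.)

Reported quantities are **estimated marginal means**: cell predictions from
the fixed effects averaged with *equal weights* over non-focal factors. With
an 84/8/8 trial-type imbalance, equal-weight averaging differs materially
from observation-weighted averaging; the equal-weight convention is the
standard EMM definition and is what the package computes (and what its tests
check against an independent prediction-grid oracle). Confidence intervals
and contrast tests use the normal reference (`estimate ± 1.96 SE`,
`z = estimate/SE`), matching the z-statistic reporting convention for these
models; contrast families are Holm–Bonferroni corrected. The declared
families are: {oddball − standard, deviant − standard} for the plain design;
{manual − counting} for the response-mode design; the two
difference-of-differences contrasts for the reward design, with the tonic
contrast as its own family.

The tonic analysis fits the per-trial baseline mean with reward as fixed
effect and participant intercepts. Response times enter a one-way
repeated-measures ANOVA on participant means of correct oddball responses,
with partial $\eta^2 = SS_{\text{effect}}/(SS_{\text{effect}} +
SS_{\text{error}})$.

## Numerical conventions and degenerate inputs

* All intervals are half-open `[start, end)` in integer-friendly ms; sampling
  rates must divide 1000 so the grid stays on whole milliseconds.
* Mask spans are merged by a sort-and-sweep union; the result is a fixed
  point of further merging (idempotent masking).
* An entirely missing block, a calibration with fewer than two distinct au
  readings or a non-positive fitted slope, unknown trial-type or reward
  labels, and non-monotone sample times are all hard errors with the
  offending file line named.
* A contrast whose weights cancel exactly reports `z = 0, p = 1` rather than
  0/0; a repeated-measures effect whose sum of squares is rounding dust
  reports `F = 0`, partial $\eta^2 = 0$.
* AR(1) noise is parameterised at the 500 Hz interval and rescaled as
  $\phi^{dt/2}$ at other rates, keeping the autocorrelation time in ms
  rate-invariant.

## A worked example

```{r, eval = FALSE}
library(oddpupil)

# two-block plain oddball study, scaled down for a quick run
sessions <- simulate_study("exp1", n_participants = 24, seed = 1,
                           sampling_rate = 250, trials_per_block = 125)
report <- analyze_sessions(sessions, "exp1")
report
```

The report prints three trial-type EMMs with 95% CIs (centred near the
injected −0.283/+1.403/+0.535 mm²), and the two Holm-corrected contrasts.
`run_pipeline()` wraps the same chain behind a YAML config and writes a
`report.json`, `measures.tsv` and a run manifest;
`inst/cli/pupil-oddball` exposes `simulate`, `run` and `analyze` subcommands
for shell use.

## Validation strategy and problem sizes

The test suite checks every numerical primitive against an independent
oracle (two-point-line interpolation, boolean-timeline interval union,
closed-form OLS, a prediction-grid EMM oracle, closed-form Holm), and then
validates the chain end-to-end at sizes chosen for a single-CPU desk run:

* **Recovery**: 100 simulated studies of 24 participants × 2 blocks × 50
  trials at 100 Hz, full pipeline; the injected amplitude ordering must be
  recovered in ≥95% of seeds and each injected amplitude must fall inside
  its own 95% CI in ≥90%.
* **Error control**: 1000 null studies at the trial-measure level (the
  lightweight `simulate_change_scores()` generator); the Holm family must
  reject in ≤5% of seeds up to Monte-Carlo error.
* **File-based driver**: a deposit-shaped synthetic study written to disk
  and re-analysed purely from its files must recover the injected phasic
  reward modulation, tonic offset and RT speeding.

`scripts/acceptance.R` re-runs the three study designs at near-published
scale (24/20/20 participants, full trial counts, 250 Hz) and writes every
headline quantity to JSON.

## Known limitations

Overlap between consecutive trials is handled in expectation (the
steady-state leakage correction), not deconvolved per trial; trial-level
change scores therefore contain neighbour-composition noise that the models
absorb into residual variance. The blink proxy (missing/zero runs) cannot
reproduce a tracker's online velocity-based flags. Counting-block accuracy
(silent counts) has no trial-level behavioural readout, so counting blocks
contribute no RT or error information. The AIC ladder compares REML fits;
for strict model selection refit with `reml = FALSE`.
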