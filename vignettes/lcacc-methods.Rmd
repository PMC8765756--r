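---
title: "Methods: conditioned spike-count statistics, pupil phase, and evoked responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conditioned spike-count statistics, pupil phase, and evoked responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcacc)
```

## What the package computes

`lcacc` analyses simultaneous recordings from the locus coeruleus (LC) and
the anterior cingulate cortex (ACC) of fixating monkeys, together with the
continuously sampled pupil diameter. The scientific questions it is built
around are (i) whether the moment-by-moment firing of a neuromodulatory
nucleus (LC) covaries with the firing statistics of single cortical neurons
and, more importantly, with the *coordination* between pairs of cortical
neurons; (ii) how both quantities relate to the quasi-periodic resting
fluctuation of the pupil (hippus); and (iii) how transient, startle-evoked
LC responses differ from ongoing LC firing in their cortical correlates.

The package therefore has two halves:

* an **analysis pipeline** — stable-fixation windowing, binned spike
  counts, mean/variance/Fano statistics conditioned on the partner region's
  firing, pairwise spike-count correlations (`r_sc`) with the full
  preprocessing chain, hippus phase maps, and beep-locked (evoked)
  analyses; and
* a **session generator** whose statistical structure is chosen so that
  every stage of the pipeline has an analytic ground truth. The test suite
  and `scripts/acceptance.R` are parameter-recovery exercises against that
  ground truth, not against recorded data.

## The conditioning design

Every conditioned analysis uses the same skeleton. Spiking is evaluated in
a **stable-fixation reference window**: 1.1 s starting 1 s after stable
fixation was attained (`extract_stable_fixation_epochs()`; trials failing
the gaze summary, or too short for the window, are excluded). The
conditioning unit's spike count in that window partitions trials into
count groups 0, 1, 2, 3, 4+ and the binary zero/nonzero split
(`partition_trials_by_partner()`). Groups are defined on *counts*, not
rates: the zero group is literally "no spikes in the window", which forces
the count reading of the group labels.

Target-region spikes are counted in one window per trial per bin size,
anchored at the epoch start, half-open `[start, start + bin)`. Two bin-size
ladders are provided: ten log-spaced windows from 100 ms to 1 s for the
correlation analyses and five linearly spaced windows from 200 ms to 1 s
for the single-unit statistics. Anchoring one window per trial (rather
than averaging tiled windows) keeps counts independent across trials and
makes the thinning algebra below exact; it is also the simplest reading of
a per-trial count.

The conditioning direction is a label table, not a hard-coded region: the
same functions compute LC-conditioned ACC statistics and the
region-swapped (ACC-conditioned LC) analyses.

## Pairwise correlations

`r_sc` is the Pearson correlation of two units' per-trial counts. The
preprocessing chain, applied per pair, per bin size, per condition
(`conditioned_rsc()`):

1. z-score each unit's counts over the trial set being correlated;
2. remove, in a single pass, trials where either |z| exceeds 3 (strictly
   greater removes; a constant count vector has no defined z and removes
   nothing);
3. Pearson-correlate the kept raw counts; conditions left with fewer than
   `min_trials` (default 5) usable trials are flagged missing rather than
   reported as a noisy `r`.

Whether z-scoring happens within the conditioned trial set or once across
all trials is genuinely open; the default z-scores within the set actually
being correlated (each condition's own statistics define its outliers),
and `zscore_scope = "all"` provides the alternative.

Condition-independent `r_sc` (the `all` condition) is computed per bin
size before any conditioning and is the basis for the tercile partition of
pairs (rank split, sizes within one, extras to the lower terciles). The
negative control is `shuffle_count_table()` /`shuffled_null()`:
independently permuting each unit's trials destroys all trial pairing
while preserving marginals, so every conditioned difference must vanish.

## The common-input generator and its ground truth

A simulated ACC pair draws, per trial, independent private counts
$B_1, B_2 \sim \mathrm{Pois}(\lambda_b)$ and a shared count
$C \sim \mathrm{Pois}(\lambda_c)$, with $N_i = B_i + C$. Then

$$ r_{sc} = \frac{\lambda_c}{\lambda_b + \lambda_c} $$

exactly, which is the ground truth for every correlation test. Counts are
realized as spike times placed i.i.d. uniformly in the reference window,
*independently for the two units*. A sub-window holding a fraction $q$ of
the reference window then receives independent binomial thinnings of each
count, so

$$ r_{sc}(q) = q \cdot \frac{\lambda_c}{\lambda_b + \lambda_c}, $$

i.e. the measured correlation grows with bin size toward the
reference-window value — the qualitative bin-size dependence seen in
cortical data. The choice of *independent* placement is deliberate: placing
the shared spikes at identical times in both units would fix `r_sc` at its
reference value at every bin size and produce artificial millisecond
synchrony.

Gated pairs switch $(\lambda_b, \lambda_c)$ by condition while holding
$\lambda_b + \lambda_c$ fixed, so the conditioned `r_sc` difference has an
analytic target while the marginal firing rates are *identical* across
conditions — the generative analogue of the finding that correlation
changes are not rate changes. The default gated configuration moves
$\lambda_c$ from 1.2 (zero condition) to 0.4 (nonzero), i.e.
`r` from 0.3 to 0.1, a difference of −0.2. Outside the reference windows
units fire independent Poisson background at the matched marginal rate, so
sessions look continuous without adding correlation structure.

This construction ties correlations to specific reference windows (the
1.1 s fixation window; the 1 s pre/post windows around a beep). Analyses
at those windows recover targets exactly; analyses elsewhere see the
thinned (attenuated) value. That is a limitation to keep in mind when
interpreting passing tests: real cortical correlations are not anchored to
an experimenter's window.

## The simulated LC unit

The paper-level facts the LC generator reproduces: no spikes on roughly a
third of fixation trials, and a median [IQR] nonzero rate of
1.8 [0.9–3.6] sp/s in the reference window. A stationary Poisson process
cannot produce both (a rate matching the nonzero median leaves far fewer
zero trials), so the per-trial base rate is lognormal — a doubly stochastic
Poisson process. The defaults (median 1.2 sp/s, `sdlog` 1.0) were
calibrated once against those two statistics and then frozen; with them,
P(zero) ≈ 0.31 and the nonzero median [IQR] is 1.8 [0.9–3.6] sp/s. The
calibration is asserted in the test suite with `beep_fraction = 0`,
because these are passive-fixation statistics and an evoked burst landing
inside the reference window would contaminate them.

## Hippus, phase, and the LC–pupil delay

The pupil model per trial is $A \sin(2\pi t/T + \varphi_0)$ with smoothed
Gaussian noise, period $T$ defaulting to 600 ms and a fresh random phase
per trial. Phase is defined behaviourally, not analytically: cycles are
delimited by successive local minima of the smoothed trace, and within a
cycle the four landmarks — maximum dilation rate (0°), maximum size (90°),
maximum constriction rate (180°), minimum size (270°) — anchor a
piecewise-linear phase that is interpolated in time between landmarks.
Detection details: centered moving-average smoothing (default 50 ms);
the derivative is re-smoothed with the same window (a raw central
difference amplifies residual noise enough to displace the rate
landmarks); shallow oscillations are pruned by a minimum peak-to-trough
amplitude (default 0.1 trace units, i.e. 10% of the default hippus
amplitude), so a flat-plus-noise trace yields no cycles at all. Phase
assignment is invariant to constant offsets of the trace by construction.

The LC rate is modulated by the same oscillator:
$r(t) = r_0\,[1 + m \cos(2\pi (t - d)/T + \varphi_0)]$, so the LC
modulation peak falls $d$ ms after the 0° (maximum-dilation-rate)
landmark. With a periodic signal a lag of $d$ is indistinguishable from a
lead of $T - d$; the package fixes the convention on the analysis side:
`fit_phase_slope()` reports the delay as the time at which the fitted
extremum-phase line crosses 0°, reduced into $[0, T)$. Under this
convention the generator parameter `lc_pupil_lead_ms = 270` is recovered
as a 270 ms crossing, matching how such delays are read off
phase-triggered maps. (The near-anti-phase geometry — 270 ms against a
600 ms period — is inherited from the phenomenon being emulated; the
package takes both numbers as free parameters and does not attempt to
reconcile them.)

The phase-triggered map itself (`phase_triggered_map()`): each complete
cycle contributes one occurrence time per phase bin (36 × 10° bins by
default); a cell (offset, phase) averages the signal in a 500 ms window
centered `offset` ms from each occurrence (offsets −1000…1000 ms in
100 ms steps; windows leaving the trial are dropped; cells under 10
occurrences are flagged). For a rate map the cell value is the unit's mean
rate, z-scored across cells; for an `r_sc` map it is the pair's count
correlation across occurrences. A genuine fixed temporal relationship to
the hippus appears as a diagonal of slope $-360/T$ deg/ms; the extremum
phases are circularly unwrapped along offsets (adding ±360° to minimize
successive jumps) before the least-squares fit, and fits whose slope is
not reliably nonzero (p ≥ 0.05) are flagged unreliable. Note the 500 ms
window attenuates a 600 ms-period modulation by the usual sinc factor
(~0.19 here), so recovering the diagonal needs pooled occurrences — the
default map resolution wants a few hundred cycles per phase bin.

## Evoked (startle) analyses

Beeps occur on ~25% of trials, 1–1.5 s after stable fixation. The evoked
LC kernel in the generator is an additive burst (default 50 Hz for
200 ms) followed by a hard pause (rate 0 for 600 ms); the evoked pupil
dilation is an alpha-function kernel whose amplitude is proportional to
the *realized* burst spike count, so the burst-size/dilation-size
correlation is generative ground truth rather than an assumption.

The response classifier (`detect_lc_evoked_response()`) is a declared,
parameterized contract: a trial is "responsive" when the burst window
`[0, 300)` ms after the beep holds ≥ 2 spikes *and* the pause window
`[300, 800)` holds 0. On burst-free Poisson trials at 2 sp/s its
false-alarm rate has the closed form
$P(\mathrm{Pois}(0.6) \ge 2)\,P(\mathrm{Pois}(1.0) = 0) \approx 0.045$,
which the calibration tests check; on kernel trials the windows sit
inside the burst/pause by construction, so the hit rate is near 1. The
fake-beep control draws virtual event times uniformly from the real beep
schedule (1–1.5 s after stable fixation, seeded) on no-beep trials and
applies the identical detector.

Pre/post correlation changes use the 1 s windows immediately before and
after the (real or virtual) event, per trial group, with the same `r_sc`
preprocessing chain; the generator's beep-gated pairs shift
$\lambda_c$ from 0.5 to 1.5 (at fixed margin 4) *only* on trials that
also carry the LC kernel, so the responsive group's post−pre difference
has target +0.25 while the non-responsive group and the fake-beep
contrast are null.

Variability quenching is measured as the Fano factor in 200 ms sliding
windows around the event. The quenching generator scales the pre-event
rate by a per-trial Gaussian gain $g \sim N(1, \sigma)$ (truncated at 0)
and freezes it afterwards; for a window holding $\lambda$ expected spikes
the pre-event Fano is $1 + \lambda\sigma^2$ (1.8 at the default
$\lambda = 5$, $\sigma = 0.4$) and 1 after the freeze. The truncation at 0
biases this by well under a percent at the default $\sigma$.

Event-aligned `r_sc` time courses (500 ms windows stepped by 100 ms by
default) compare each post-event window's per-pair values against the
pooled pre-event baseline (rank-sum) and compare between groups the
per-pair linear slope of `r_sc` over a configurable post-event epoch
(default 100–600 ms).

## Resampling and test layer

All summary intervals are percentile bootstrap CIs of the median (default
1000 resamples, seeded); percentile rather than BCa because the
bootstrapped quantity is always a median over exchangeable units or pairs,
where the percentile interval is adequate and simpler to reason about.
Hypothesis tests delegate to the standard implementations
(`stats::wilcox.test`, `stats::ks.test`, `stats::aov`) behind thin
wrappers returning uniform one-row tibbles; the signed-rank wrapper uses
the exact distribution up to n = 25 without ties and the normal
approximation otherwise. The multi-factor evoked-pupil analysis is a
two-factor fixed-effects ANOVA with interaction (`anova_twoway()`), since
the group-by-pupil-measure interaction is the quantity of interest there.

Calibration is asserted in two forms. For the signed-rank, rank-sum and
ANOVA tests the null p-value distribution is checked for uniformity
directly (KS against uniform). The two-sample KS test's own p-value is
*discrete* at any finite sample size (its statistic takes O(n) values), so
a literal uniformity check fails there no matter the implementation; its
calibration is therefore asserted as test size — the null rejection rate
at α = 0.05 must sit within 3 binomial SDs of 0.05 — which is the property
the analyses actually rely on.

## Problem sizes and determinism

The test battery and the acceptance script run the recovery exercises at
the scales the statistics need, chosen as the smallest sizes at which the
analytic targets are resolvable against sampling noise: 100 pairs × 5000
trials for the correlation identity; 400 trials × 100 gated pairs for the
conditioned difference; 20 seeded sessions of 150 trials for the
phase-delay recovery; 10,000 trials for the detector calibration; 2000
trials × 50 pairs for the evoked contrast. Pupil traces in
simulation-heavy runs are sampled at 50–250 Hz rather than the 1 kHz
session default; the phase machinery is sample-rate-agnostic above ~10
samples per smoothing window.

Every stochastic function takes an explicit seed; `simulate_session()` is
bit-reproducible from its config seed, and the on-disk format writes
doubles at 17 significant digits (and re-parses them with `strtod`) so a
written session is restored bit-exactly.

## Known limitations

* The generator's correlations are anchored to reference windows
  (thinning attenuates them elsewhere); real data have no such anchor.
* LC–pupil coupling is implemented in rate (a cosine modulation), not
  spike-by-spike, and the hippus is a single sinusoid — real hippus is
  broad-band and non-stationary.
* The evoked pause is hard (rate 0); softer kernels are configurable but
  not default.
* Gaze quality enters only as a per-trial pass/fail summary; raw
  eye-trace quality control is assumed upstream.
* Passing recovery tests demonstrates that the pipeline measures what the
  generator encodes; it does not certify behaviour on recorded data with
  non-Poisson history structure (bursting, refractoriness) or slow
  nonstationarities beyond the per-trial rate heterogeneity modeled here.
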