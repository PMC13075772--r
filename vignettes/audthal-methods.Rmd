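---
title: "Methods: pure-tone and narrowband-noise auditory analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pure-tone and narrowband-noise auditory analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, estimators and design choices behind
`audthal`. The package analyzes two kinds of data: go/no-go lever-release
sessions in which an animal detects a brief pure-tone (PT) or
narrowband-noise (NBN) target, and spike-sorted auditory thalamic
recordings obtained while a frequency x level grid of matched PT and NBN
stimuli is played. A synthetic-data generator with the same statistical
structure backs every estimator with recovery tests.

## Stimulus geometry

The recording protocol uses 11 half-octave-spaced center frequencies.
The canonical list (560, 800, 1,120, 1,600, 2,240, 3,150, 4,500, 6,300,
9,000, 12,500, 18,000 Hz) consists of conventional rounded values, not
exact powers of sqrt(2); `build_stimulus_grid(exact = TRUE)` generates the
mathematically exact ladder instead (560 * 2^(k/2), 11th center 17,920 Hz).
The bounds 500–22,000 Hz are applied to the centers. Eight levels run
40–75 dB SPL in 5 dB steps; each condition is repeated 15 times, stimuli
last 100 ms with 10 ms raised-cosine ramps and 200–300 ms inter-trial
intervals.

NBN bands tile the axis without overlap: band edges sit at the geometric
midpoints between adjacent centers, closed by quarter-octave extensions at
the ends. The behavioral band is the stated exception — centered at
8.5 kHz with fixed 7–10 kHz edges (3.0 kHz wide), not geometric around its
center — and is implemented as an explicit override. NBN waveforms are
white noise passed through a causal (forward-only) second-order Butterworth
bandpass at the band edges, matching real-time presentation rather than
zero-phase offline filtering. Levels are RMS-referenced to a configurable
pressure constant; absolute calibration is out of scope since only
relative levels matter downstream. The Fletcher relation
`CB = 10^(CR/10)` converts a critical ratio (dB) to a critical bandwidth
(Hz); at the behavioral band's center the published critical ratio of
35 dB gives 3.16 kHz, essentially the half-octave bandwidth used.

## Behavioral model and signal-detection scoring

Each trial runs from a lever press; the target plays at a uniform random
onset 1,000–3,500 ms later and the animal has 700 ms to release. Scoring
splits trials at 2,250 ms into two equal 1,250 ms segments. Short-onset
trials score hits and misses against the true target window. Long-onset
trials are scored against a *virtual* onset drawn per trial, uniformly
over the hit-window onset range but truncated so the virtual window closes
before the true onset. Releases inside the virtual window are false
alarms, withheld responses correct rejections, and any release before the
scoring window an abort (excluded from rates). The truncation is the one
point where we depart from a literal uniform draw over the full
[1,000, 2,250] ms range: without it, detection-driven releases to late
targets leak into the false-alarm window, which both contradicts the
defining property of the method (no target has occurred by the end of the
FA window, hence FAR cannot depend on target amplitude) and measurably
inflates FAR. The virtual onset is drawn once per trial (seeded); whether
the original analysis fixed one window per session or per trial is not
documented, and the per-trial draw makes the windows statistically
indistinguishable from the animal's perspective. Long-onset trials receive
only FA/CR labels; the animal's eventual response to the real late target
is not additionally scored, keeping the four counts mutually exclusive.

`d' = Z(HR) - Z(FAR)` uses a log-linear correction only when a rate is
exactly 0 or 1 (0.5 added to each of the four counts of the affected
cell); this is the least disruptive standard choice and is switchable.
Rates and d' are computed per session, averaged across the 10 sessions of
each animal, then across animals — in that order. Detection threshold per
stimulus kind is the lowest amplitude at which the group d' differs from
zero (two-sided one-sample t test across animals, alpha = 0.05).

The generator draws, per trial, an abort hazard before 1,000 ms, a
constant spontaneous-release hazard thereafter (discrete 10 ms Bernoulli
steps — adequate at these time scales), and a detection event with
probability `asymptote * pnorm((a - midpoint)/width)` followed by a
log-normal reaction time capped at the response window. When the target
goes undetected the spontaneous hazard simply continues through the
response window, which is what makes d' converge to zero, rather than to a
positive floor, for undetectable targets. Reference calibration: midpoints
32.0 dB (PT) and 28.5 dB (NBN) — one behavioral amplitude step (3.5 dB)
apart — width 1.5 dB, asymptote 0.99, false-alarm hazard 0.08/s (~6%
false-alarm probability per 700 ms window), abort hazard 0.25/s, 8 animals
x 10 sessions x 500 trials. Under this configuration the measured group d'
plateaus near 3.0–3.1 at the highest amplitudes: the plateau measured
through per-session estimates with ~15 target trials per cell is
necessarily compressed relative to the asymptotic value (~3.9) because the
edge correction caps per-session z-transforms. A per-animal "strategy
axis" scales the hazards (exp(+-1.2)) and shifts the psychometric
midpoints (+-0.8 dB) so that animals trade misses against false alarms;
this reproduces the negative per-animal regression of FAR on miss rate at
the lowest amplitude.

## Frequency response areas and log-normal rate-level fits

Responses are spike counts in a 5–95 ms post-onset window (rates =
counts / 0.09 s), averaged over the 15 trials of each condition and
normalized per unit by the FRA matrix maximum. Responsiveness requires a
Bonferroni-corrected per-frequency amplitude effect (one-way ANOVA,
corrected across the 11 bands, p < 0.01), computed alongside the two-way
frequency x amplitude ANOVA. "p_ANOVA for the frequency" is read as the
per-frequency corrected p value, not the omnibus amplitude effect, since
the criterion is applied per band.

The rate-level function at each frequency is the scaled log-normal
`f(x) = E/(x sigma sqrt(2 pi)) exp(-(log x - mu)^2/(2 sigma^2)) + B` with
`x` the SPL in dB and natural log — a literal reading of the fitted form;
all tested SPLs are >= 40 dB so log x is well-defined. Parameters are
strictly positive with upper bounds [150, 20, 10, 0.4] (the baseline bound
presupposes unit-normalized rates). Fitting uses bounded
Levenberg–Marquardt with structured multi-starts: a ladder of dispersions
(sigma in 0.15–0.6) with mu solved so each starting curve's C50 matches
the data's half-range crossing, plus seeded random starts over the box;
the best R^2 wins, ties broken by the smaller E. The structured starts
matter: with 8 points and 4 parameters, naive random initialization
frequently lands in a narrow-dispersion local optimum with the baseline
stuck at its bound, which biases C50 upward and mislabels monotonic units
as O-shaped.

C50 is the SPL at 50% of the baseline-to-maximum range of the fitted
curve, located by grid scan plus root refinement over an evaluation domain
of 0–100 dB — deliberately wider than the tested 40–75 dB so that
monotonic and O-shaped profiles can be told apart. The half-width is the
SPL extent above half the fitted maximum; units whose curve is still above
half-maximum at 100 dB are monotonic (half-width infinite), the rest are
O-shaped. CF is the criterion-passing frequency with the lowest C50; the
four criteria are R^2 > 0.7, fitted maximum >= 50% of the unit-wide
maximum, a width criterion, and corrected p < 0.01. The width criterion
("half-width < 2 octave bands") mixes SPL and frequency units in its
original statement; the default implementation reads it as frequency
selectivity — fewer than 2 contiguous neighboring bands per side whose
response at the candidate's best SPL exceeds half the candidate's response
— because its stated purpose is to ensure selectivity over broadly
distributed responses. An SPL-domain alternative (half-width below a
configurable dB span) is available via `width_mode = "spl"`. An automated
atypical-fit filter (fitted maximum exceeding the data maximum by >50%, or
C50 more than 10 dB outside the tested range) replaces the original
manual curation step.

## Temporal dynamics

Latency is the PSTH time-to-peak at 5 ms resolution, reported at the peak
bin's center with ties resolved to the earliest bin, at the best stimulus
(the SPL with the highest mean response at the CF). ISI decay constants
come from within-trial intervals below 30 ms pooled across the best
condition's 15 trials, binned at 1 ms, normalized to a probability mass
per bin, and fit with `A exp(-t/tau) + C` (t and tau in seconds; init
[1, 1, 1], bounds [0, 0, 0] to [Inf, 1, Inf]; fits kept at R^2 > 0.7, and
at least 30 ISIs are required before fitting). A data-scaled fallback
start guards the canonical [1, 1, 1] initialization against a flat local
optimum. The probability-per-bin normalization keeps the histogram scale
near the canonical initial values; a per-second density (values ~100)
makes the [1, 1, 1] start converge to the degenerate flat solution.

Two honest limitations, visible in the recovery tests: (i) with a
decaying-exponential evoked profile the binned time-to-peak sits a few ms
above the true evoked onset, so the generator's onset parameter (15 ms PT)
is calibrated such that the *measured* median latency lands at ~23 ms
(PT) / ~27 ms (NBN), on the 5 ms lattice the estimator can produce; and
(ii) reliable ISI fits require strongly firing units — at the reference
population's median rates the sub-30 ms ISI counts are usually below what
an R^2 > 0.7 fit needs, exactly as only a subset of real units yields
reliable fits. Recovery properties for tau (rank correlation with the
generating decay constant; PT faster than NBN pairwise) are therefore
demonstrated on a high-rate generator variant (evoked ~150 sp/s, fixed
across units so the ISI scale is driven by the decay constant).

## Single-unit frequency discriminability

Per trial, evoked counts (5–55 ms) minus baseline counts (the last 50 ms
before onset — the stated window length with a placement the original
leaves open) are compared between the CF and an adjacent band:
`D = dCF - dAdj`, with trials paired by acquisition index (a
permutation-averaged pairing mode exists to show insensitivity).
`Pc = (n_{D>0} + 0.5 (1 + n_{D=0}))/(n_total + 1)` gives half credit to
zero-information trials and is strictly inside (0, 1); `d' = sqrt(2)
qnorm(Pc)`. Both adjacent sides are averaged when available; border CFs
use the single available side. Curves are indexed by SPL minus the
unit's C50 snapped to the 5 dB grid (ties toward the lower SPL). In the
generator, frequency tuning broadens with level (bandwidth growing ~30%
per 20 dB above C50), which is what produces the characteristic rise of
d' to a peak 5–10 dB above C50 and its decline at higher levels.

## Population decoding

Pseudopopulations of 50 units are sampled with replacement from the
responsive pool of a stimulus kind, without constraints on CF or C50;
trial k of each condition across units forms one pseudotrial. Spike counts
are taken from stimulus onset (0–50 ms, or 0–25 ms for the early window),
labels are the 11 frequencies irrespective of SPL (120 trials per class).
The decoder is a bank of one-vs-one linear SVMs; prediction minimizes the
class-averaged binary hinge loss (loss-weighted error-correcting output
codes). The SVM box constraint is tuned by a seeded 20-evaluation search
over a log-spaced grid on an inner stratified split — a deterministic,
dependency-light stand-in for Bayesian optimization that is functionally
equivalent at this scale. Train/test splits (2/3 vs 1/3) are stratified by
frequency and amplitude where counts permit. Label-shuffled baselines use
a fixed box constraint of 1: chance-level accuracy does not depend on the
regularizer, while a hyperparameter search against random labels is
extremely slow. Per-frequency x amplitude accuracies are computed from the
same trained model with test trials filtered by amplitude (not retrained
per amplitude). Cross-condition decoding trains on all trials of one kind
(hyperparameters tuned first), reports within-condition accuracy from
stratified five-fold cross-validation on the training data, and tests on
all trials of the other kind.

## Tonotopy

Units are positioned along each penetration by their distance from the
probe tip; the insertion angle (60 degrees to the brain surface by
default) converts distance to vertical depth. Within each penetration with
at least 3 CF-bearing units, log2(CF) is regressed on distance (slope in
log2-CF per mm; the half-octave stimulus spacing makes log2 the natural
scale, and the choice only affects the intercept under frequency
rescaling). Penetrations are classified by slope sign at the regression F
test's alpha = 0.05, and classified counts plus a one-sample t test of
slopes against zero summarize the population. Atlas-image overlay is out
of scope; coordinates are abstract.

## The synthetic generator and what recovery tests show

Units are inhomogeneous Poisson processes over a -100 to 250 ms epoch:
constant spontaneous rate (log-normal, median 2 sp/s — the spontaneous
distribution is a modeling choice, no reference value exists) plus an
onset-locked evoked component (`onset latency + per-trial Gaussian jitter
+ exponential decay`) whose expected count follows the unit's log-normal
amplitude profile and a Gaussian-in-octaves frequency profile with
level-dependent broadening. Reference calibration: PT C50 at CF ~ N(57.7,
5) dB clipped to [45, 66], NBN C50 2.2 dB lower with 0.8 dB per-unit
jitter; dispersion sigma ~ U(0.28, 0.38) for monotonic units (chosen so
the true curve is monotonic over 0–100 dB *and* the fitted E stays inside
its 150 bound on unit-normalized data; beyond sigma ~0.45 the required E
exceeds the bound and fits distort) and U(0.15, 0.22) for the ~3.5% of
O-shaped units; evoked rate at CF/best level log-normal with median
30 sp/s (the criterion-passing units that C50 analyses rest on are the
strongly driven ones); C50 growing 3 dB per band away from CF; PT onset
15 ms with NBN +3 ms; PT decay 30 ms with NBN 1.3x slower — which also
yields the higher PT peak rate at matched evoked counts. Penetration
gradients (negative/positive/unordered in the published 9:1:12
proportions) are imposed by reordering CFs along the shank.

The generator reproduces the *structure* of the real data — Poisson
count noise at 15 trials, log-normal rate-level shapes, condition offsets,
amplitude-independent false alarms — but not everything: no correlated
noise across units or trials, no bursting or refractoriness, no
anesthesia-state fluctuations, no session-level drift. Passing recovery
tests therefore shows that the estimators are unbiased and correctly
implemented under the assumed model, not that the model captures every
property of real recordings. One deliberate asymmetry: peak PSTH rates of
the synthetic units run higher than typically reported medians, because
the delta-onset/exponential-decay profile concentrates the evoked mass;
flattening it further would degrade the latency and C50 recoveries that
the acceptance checks rest on.

## Problem sizes and numerical choices

Recovery analyses use: 8 animals x 10 sessions x 500 trials for behavior;
200 units for the paired C50 recovery (pooled over 10 seeded replicates of
the fitting pipeline at each unit's designed CF — the median of ~1,850
paired differences has a standard error near 0.2 dB; the estimator itself
retains a small attenuation, of order 0.25 dB, because fit errors are not
symmetric near the top of the tested SPL range and PT C50s sit closer to
that edge — re-estimating CF by argmin-C50 would add further selection
noise on top, so the CF-selection route is validated separately);
120-unit pools for the 10 x 50 shuffled-label pseudopopulations. The test
suite uses smaller populations (12–30 units) for module-level checks.
Curve landmarks are located on 600-point grids refined by `uniroot` to
1e-6; fits run at most 200 Levenberg–Marquardt iterations; all random
draws flow through per-stage seeds derived from one master seed, and fixed
seeds give byte-identical outputs end to end.
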