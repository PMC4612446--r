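---
title: "Modelling anticipatory sympathetic arousal from skin conductance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling anticipatory sympathetic arousal from skin conductance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scrdcm)
```

## The generative model

Skin conductance responses (SCR) are the observable consequence of bursts
of sudomotor nerve activity. `scrdcm` models each burst as a Gaussian in
time — peak amplitude $a$, centre $o$, standard deviation $d$ — and the
summed burst train $u(t)$ as the input to a stable third-order linear
differential equation,

$$\dddot x + a_1 \ddot x + a_2 \dot x + a_3 x = b\,u(t),$$

whose output $x(t)$, plus a slow tonic (skin conductance level, SCL)
component, is the conductance trace. In a delay fear-conditioning trial the
model places:

* one **anticipatory** burst with free amplitude, onset and duration, the
  onset confined to the window between CS onset and the potential US
  (3.5 s by default). This constraint is the neural model: anticipatory
  arousal can only occur while the US is being anticipated, but *when* it
  occurs within that window is unknown and varies by trial — which is why
  fixed-latency methods underperform here;
* one **evoked** burst at the US latency with free amplitude and fixed
  0.3 s dispersion (a punctate stimulus elicits a sub-second burst). The
  model is deliberately not told whether the US was actually delivered;
* **spontaneous fluctuations** (SF) confined to the inter-trial interval,
  represented during inversion as a 2 s grid of fixed-width bursts with
  free amplitudes — a tractable approximation to free SF onsets;
* a per-trial **SCL change**: a step at each CS onset smoothed by a
  first-order lag with a 30 s time constant, keeping the tonic component
  spectrally disjoint from phasic responses. With SCL modelling disabled,
  a single constant baseline is estimated on the first chunk and held.

Amplitudes are parameterised as Gaussian peak height (not area), so they
stay comparable across dispersions and map directly onto the conductance
scale: the canonical response kernel is normalised to unit peak.

## Response functions

The canonical response function is an all-real-pole third-order system
with poles $(1.0, 0.8, 0.25)\,\mathrm{s}^{-1}$ — rise constants of about
1 s and a 4 s decay — chosen so the impulse response is unimodal, peaks
3.4 s after the burst and decays to $10^{-6}$ of its peak within 60 s,
matching the stereotyped SCR shape. The exact coefficients are frozen in
`inst/extdata/canonical_rf.json`; all downstream numbers are reproducible
from that file.

An individual response function can be estimated per participant: the
post-US segments of all trials (from the last evoked response to the next
trial onset, truncated to the shortest) are variance-normalised, their
first principal component is extracted with its sign set to make the peak
positive, and a third-order system is fitted to the unit-peak component by
least squares over log-parameterised poles (which enforces stability by
construction) with a free time shift. If the component has no interior
local maximum exceeding three median absolute deviations, a typed
condition is raised and callers fall back to the canonical function —
estimating a response function from a flat or noise-dominated component
would be meaningless. Because the fit only sees the first seconds of the
true kernel (the inter-trial interval is 7–11 s), the tail is an
extrapolation through the fitted poles; this is a known limitation of
individually estimated response functions in paradigms with short
inter-trial intervals.

## Preprocessing

The chain is: optional 11-point median despiking (for MRI gradient
artefacts: 2 ms spikes at 1000 Hz sampling), first-order 5 Hz Butterworth
low-pass, downsampling to 10 Hz, a configurable first-order high-pass, and
normalisation (subtract the minimum, divide by the sample SD). Six
high-pass cutoffs are exposed as presets
($\{0.005, 0.01, 0.0159, 0.035, 0.05, 0.06\}$ Hz) with 0.0159 Hz — a 10 s
time constant — as default. The high-pass is always applied twice:
forward-then-backward ("bi-directional", zero net phase) or twice forward
("uni-directional"); both therefore share the squared magnitude response,
which at the cutoff is exactly $1/2$, and differ only in phase. In
practice the bi-directional filter leaves the peak of an SCR-scale bump on
its original sample, while the doubled causal filter displaces it — in our
measurements *earlier*, by roughly 0.6–0.8 s at the default cutoff, the
phase lead of a high-pass acting on energy near its cutoff. Either way a
latency-sensitive analysis should use the zero-phase variant, which is the
default.

Numerical choices: each filter pass pads the signal by odd reflection over
three filter time constants and starts from the steady state of the first
padded sample, so a constant trace high-passes to exactly zero and edge
transients are strongly suppressed. The median window is centred (the
sample plus 10 neighbours) for zero lag. Normalisation uses the $n-1$
sample SD and is idempotent. Resampling decimates when the rate ratio is
an integer (keeping the first sample) and otherwise interpolates linearly
onto the target grid; upsampling is refused.

## Inversion

Estimation is maximum-a-posteriori over transformed parameters: log for
amplitudes and dispersions (non-negativity), a scaled logit for the
anticipatory onset (hard window constraint), identity for SCL changes and
baseline. Priors are Gaussian in the transformed space: amplitude median
0.1 normalised units with log-SD 1, onset centred mid-window, dispersion
median 0.3 s with log-SD 0.5, SCL changes $N(0, 0.5)$, and an effectively
flat baseline prior centred on the window median — which is what makes the
estimates invariant to adding a constant to the recording.

Whole-session inversion is computationally unattractive, so the session is
split into overlapping chunks of `trial_depth` successive trials (2 by
default, 3 supported), sliding by one trial; each chunk's window runs from
its first CS onset (minus a 2 s lead-in) to the onset following the chunk.
Only the first trial of each window is retained (the final window retains
all), and the retained trials' predicted contribution — response tails and
SCL steps — is subtracted from the signal seen by later chunks, so
response overlap across trials is accounted for. With the default design
pacing a depth of 2 already spans ~18 s past each US, enough to cover most
of the response tail.

Within a chunk the posterior is maximised by a deterministic damped
Gauss–Newton scheme (Levenberg–Marquardt on the stacked residual vector
$[(\hat y - y)/\sigma;\ (\theta-\mu)/s]$ with an analytic Jacobian),
always started from the prior means — determinism is preferred over
global-optimality claims, and two runs on the same input are bit
identical. Because the system is linear and time invariant, the predicted
trace inside the optimiser is computed by exact discrete convolution of
the burst input with the impulse-response kernel (a lower-triangular
Toeplitz matrix per window) rather than re-integrating the differential
equation at every objective evaluation; a test asserts the two routes
agree to better than $10^{-4}$ relative error. The noise variance is
estimated per chunk: a robust initial value from first differences
($[\mathrm{mad}(\Delta y)/\sqrt2]^2$), then iterated to the fixed point of
the fit's residual variance with a floor of $10^{-8}$ (a numerical guard;
on noiseless data this lets the likelihood dominate the priors, which is
what makes exact recovery possible). Residual variance at the *initial*
parameters would be dominated by unmodelled signal and would mis-weight
the priors, which is why the robust estimate seeds the iteration.

## Evaluation

The quantity carried downstream as "the SA estimate" is the anticipatory
burst amplitude. Reinforced CS+ trials are excluded (their unconditioned
response would confound the anticipatory comparison), estimates are
optionally z-standardised within participant (subtract the participant's
mean across all trials, divide by their SD), and per-participant cell
means are formed per CS type. Predictive validity is the ability of these
cell means to predict CS type: a least-squares regression of the label
(CS+ = 1, CS− = 0) on the cell means plus one constant per participant.
Its coefficient t statistic is algebraically the paired t test (verified
against the textbook computation), and its residual sum of squares yields
the negative log likelihood $\mathrm{NLL} = n\log(\mathrm{RSS}/n)$ — the
negative model evidence. Because the dependent variable is identical for
every estimate set, NLL values are comparable across sets; differences are
reported as log Bayes factors, with $|\mathrm{LBF}| > 3$ decisive (the
posterior null probability at that bound is $1/e^{3} \approx 0.0498$).
Both NLL and t are invariant to affine transforms of the estimates — the
shift is absorbed by the participant constants, the scale by the
coefficient — so any numeric CS coding convention gives the same
inferences. No multiplicity correction is applied: raw LBFs against a
single reference are reported, with the decisive flag as the only
annotation.

## The synthetic cohort generator

The generator emulates a discriminant delay fear-conditioning study:
4 s CS, US or omission at 3.5 s, inter-trial intervals drawn uniformly
from $\{7,\dots,11\}$ s, half the trials CS+ with exactly half of those
reinforced, 90 trials per CS type per participant by default, pseudo-
randomised order. Per trial it draws a truncated-normal anticipatory
amplitude around the CS-type effect (defaults 1.0 for CS+, 0.3 for CS−,
SD 0.3), an onset latency of mean 1.5 s jittered with SD 0.8 s truncated
to the CS–US window — the onset jitter is the lever that reproduces the
central premise that unknown anticipation latency defeats fixed-latency
scorers — an evoked burst on reinforced trials, Poisson spontaneous
fluctuations at 3 per minute with mean amplitude 0.4 (spontaneous
responses are commonly of the same order as event-related ones), and a
tonic random walk. The trace is rendered through the forward model and
white measurement noise is added, by default at 10% of the mean
anticipatory response peak.

Two independent participant-level traits scale the signal: a log-normal
**response gain** (SD 0.5) multiplying the CS-locked burst amplitudes, and
a log-normal **electrodermal lability** (SD 0.5) multiplying spontaneous
fluctuations and noise. Keeping these independent matters: whole-trace
normalisation divides by a trace SD that mixes both, so response-scale
differences between participants survive preprocessing — as they do in
real data, where within-participant z-standardisation of the estimates is
known to help. If a single gain scaled everything, normalisation would
cancel it exactly and z-standardisation would be vacuous on synthetic
data.

All draws come from one seeded generator with a documented per-participant
sub-seed ($131\,s + 7919\,p \bmod 2^{31}-1$); identical seeds give bit-
identical cohorts, and a manifest records sub-seeds and trace checksums.

### What the generator does not emulate

Real electrodermal data contain motion artefacts, electrode drift and
detachment, non-Gaussian noise, habituation of response amplitudes over
the session, and between-trial dependencies, none of which are simulated
(the only artefact model is the optional 2 ms MRI spike train used to
exercise the despiker). Passing tests on synthetic cohorts therefore
demonstrates internal consistency — the estimator recovers the parameters
of its own generative model, and its advantage over peak scoring under
onset jitter — not performance on any particular laboratory's recordings.

## Problem sizes and determinism

The test suite and the acceptance script use desk-scale problems chosen to
exercise every code path: single sessions of 10–40 trials for recovery
checks, 20-participant × 40-trial cohorts (ten replicates) for the
predictive-validity and z-standardisation comparisons, and 50 design-only
replicate cohorts for the null calibration of the group statistic. A
40-trial session inverts in roughly two seconds on one core. Every
stochastic step is seeded; the inversion itself contains no randomness.

## Known limitations

* MAP point estimates only: no posterior covariance is propagated, so
  per-trial uncertainty is not quantified.
* The chunk scheme reconciles overlapping estimates by keeping each
  window's first trial; alternatives (averaging duplicates) were not
  explored.
* The spontaneous-fluctuation grid (2 s spacing, fixed 0.3 s dispersion)
  approximates free SF timing; very dense spontaneous activity will be
  partially absorbed by neighbouring grid points.
* The individual response function is fitted on short post-US windows and
  extrapolates the tail; with 7 s minimum inter-trial intervals the
  canonical function is usually the safer choice.
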