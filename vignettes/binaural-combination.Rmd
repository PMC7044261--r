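---
title: "Modelling binaural combination of amplitude modulation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling binaural combination of amplitude modulation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binsum)
```

This vignette is the package's account of its science: the combination
model and its assumptions, the two measurement models that connect it to
discrimination thresholds and steady-state EEG SNRs, what the synthetic
experiment generators do and do not emulate, and the numerical and design
choices made where the design was genuinely open.

## The two-channel gain-control model

Each ear's amplitude-modulation depth (in percent, $100m$) drives an
excitatory nonlinearity that is divisively suppressed by the opposite ear
before the two channels sum:

$$resp \;=\; \frac{C_L^{\,p}}{Z^q + C_L^{\,q} + \omega C_R^{\,q}}
        \;+\; \frac{C_R^{\,p}}{Z^q + C_R^{\,q} + \omega C_L^{\,q}}.$$

The parameters, their units, and the roles they play:

* $p$ (dimensionless, $>q$) — excitatory exponent. Controls the
  accelerating limb of the response function and hence the depth of the
  facilitation "dip" in discrimination thresholds.
* $q$ (dimensionless, $\ge 2$) — suppressive exponent. With $p > q$ the
  transducer accelerates then compresses; the fitting constraint
  $q \ge 2$ keeps the nonlinearity strong enough to produce a dip at all.
  The constraints are those conventionally imposed when fitting this
  model family, and are enforced *exactly* here (see Fitting).
* $Z$ (modulation-percent units) — saturation constant. Sets the depth at
  which the transducer turns over; it anchors the horizontal position of
  the dipper.
* $\omega$ (dimensionless, $\ge 0$) — interaural suppression weight, the
  scientifically interesting parameter. At $\omega = 1$ (the binocular
  regime) the extra excitation from stimulating a second channel is
  cancelled by extra suppression: monaural and binaural response
  functions converge, and a contralateral pedestal produces strong
  dichotic masking. At $\omega \ll 1$ the monaural and binaural curves
  stay apart and dichotic masking is weak. The shipped discrimination
  and EEG parameter sets have $\omega = 0.02$ and $0.14$.
* $\sigma_{40}$, $\sigma_{35}$ (response units) — noise/criterion
  parameters, one per tag frequency (below).

The model is deliberately agnostic about everything upstream of the
modulation signal: the carrier is not represented (an unmodulated carrier
contributes depth 0), there are no interaural time or level cues, and the
response is a scalar per frequency, not a waveform. Carrier-driven
adjustments of $Z$ and phase-tuned extensions are out of scope.

A linear-summation alternative,
$resp = (C_L+C_R)^p / (Z^q + (C_L+C_R)^q)$, keeps the same transducer but
sums depths before it and has no suppression weight. Because it depends on
the inputs only through their sum, it cannot distinguish monaural from
dichotic presentation — one of the qualitative failures the model
comparison exposes.

### Cross-frequency conditions

The frequency-tagged EEG conditions present different modulation
frequencies (40 and 35 Hz) to the two ears, and the combination rule for
that case is not fully determined by the single-frequency equation. The
package's choice (`tagged_response()`): **excitation is tag-specific,
suppression is untuned**. The response read at frequency $f$ takes each
ear's excitatory term only if that ear carries tag $f$, while the
denominator always pools the opposite ear's full depth with weight
$\omega$, whatever its tag. This reduces exactly to the single-frequency
equation when both ears carry the same tag, and it reproduces the
qualitative ordering of the cross conditions (cross-binaural responses
below binaural; a gentle decline of the masker-frequency response as the
other ear's signal deepens). Whether interaural suppression is actually
frequency-tuned cannot be decided from these designs; untuned is the
simplest assumption. For the same reason no within-ear cross-frequency
suppression term exists: each ear carries at most one tag in every
condition, so such a term would be unidentifiable.

## From response surface to discrimination thresholds

A two-interval trial presents a pedestal-only standard and a
pedestal-plus-target signal. The predicted threshold is the smallest
target increment $\Delta m$ for which the *signed* response increase
equals the criterion $\sigma_{40}$:
$resp(\text{signal}) - resp(\text{standard}) = \sigma_{40}$. The signed
reading is deliberate: under strong suppression a small contralateral
target can transiently *decrease* the response, and the solver passes over
any such decrement until the signed increase reaches the criterion,
rather than treating $|\Delta resp|$ as a cue. Whether real observers
could exploit a decrement cue is unknown; the criterion definition used
here mentions only an increase, and the package follows it literally.

Numerics (`increment_threshold()`): all model arithmetic is double
precision; the solver evaluates the response change on a logarithmic grid
(25 points per decade) over $\Delta m \in [10^{-4}, 10^4]$ percent,
brackets the first upward crossing of the criterion, and bisects on
$\log \Delta m$ to a relative tolerance of $10^{-6}$. A criterion with no
crossing in range is reported (error or `NA`), never clipped. The
bracketing grid, not a derivative method, is what guarantees the
*smallest* crossing is found when the response change is non-monotone.
The solver is verified against an exhaustive log-grid search at 2000
points per decade.

Thresholds are expressed in dB re 1% modulation, $20\log_{10}(100m)$, and
a dipper curve (`dipper_curve()`) is this threshold across a pedestal
grid. Two fine points mirror the experimental design: at pedestal 0 the
monaural, dichotic and half-binaural arrangements are literally the same
stimulus, so they share one detection threshold; and in the
strong-suppression regime only the model, not the data, makes the
monaural and binaural handles converge.

## From response surface to steady-state SNRs

The EEG linking function is $SNR = (resp + \sigma)/\sigma$: the measured
spectral amplitude is read as stimulus-driven signal riding on a residual
noise floor, so an absent signal gives the nominal baseline $SNR = 1$ and
the transform is affine in the response. The two tag frequencies get
separate noise parameters ($\sigma_{40}$, $\sigma_{35}$) because maximum
SNRs differ somewhat between them; both frequencies are weighted equally
in the fit objective.

## The synthetic psychophysics experiment

`simulate_experiment()` reproduces the adaptive design: 4 interaural
arrangements crossed with 8 pedestal depths ($100m$ = 0, 1, 2, 4, 8, 16,
32, 64), a pair of 3-down-1-up staircases per cell with 3 dB steps, each
terminating at the lesser of 70 trials or 12 reversals, 3 repetitions per
participant, thresholds from probit fits pooled across repetitions,
detection data pooled across the three identical pedestal-0 arrangements.

The decision model (`prob_correct_2afc()`) is the one free choice here: a
single late Gaussian noise source of standard deviation $\sigma_{40}$ per
interval, giving
$P(\text{correct}) = \Phi\!\big(\Delta resp / (\sigma_{40}\sqrt2)\big)$.
This is the simplest mapping under which the two threshold definitions in
use — "response increase of $\sigma_{40}$" and "75% correct" — agree:
at $\Delta resp = \sigma_{40}$ it gives $\Phi(1/\sqrt2) \approx 0.760$.

Conventions the design leaves unstated, fixed here once:

* **Staircase start level**: 20 dB above the generating observer's
  analytic threshold. High-pedestal cells therefore start above the 100%
  modulation ceiling; levels are clipped to 100% and the clipped trials
  are kept (and flagged) in the log, as a real session would keep them.
* **Interleaving**: the two staircases of a pair are statistically
  independent seeded substreams. Trial-by-trial interleaving would change
  only the ordering of rows in the log, because the simulated observer is
  memoryless — there are no learning, fatigue or sequential effects.
* **Psychometric fit** (`pool_fit_probit()`): maximum binomial likelihood
  of $P(x) = 0.5 + 0.5\,\Phi((x-\mu)/s)$ with $x$ the target level in dB
  (a cumulative log-Gaussian in linear depth), no lapse parameter. The
  75% point of this guessing-floored curve is $\mu$ itself.

One calibration fact worth knowing when interpreting simulated
thresholds: at a couple of hundred trials per cell, the spread of the
fitted 75% point is limited by the psychometric function's shallow
effective slope, not by the estimator — the expected-Fisher-information
bound on $SE(\mu)$ is on the order of 1.3 dB for the shipped observer at
a mid-pedestal cell, and the package's estimator sits essentially at that
bound. Averaging across repetitions and participants, not a better
fitter, is what buys precision.

## The synthetic EEG experiment

`simulate_eeg_experiment()` reproduces the frequency-tagged design: 6
conditions crossed with 5 signal depths ($m$ = 6.25, 12.5, 25, 50, 100%),
maskers fixed at 50%, 10 repetitions of 11-s trials sampled at 1 kHz per
cell, 12 synthetic participants. Analysis follows the standard chain
(`coherent_average()`, `snr_at_frequency()`): the first second of each
trial is discarded to drop onset transients, the remaining 10 s are
Fourier transformed (0.1 Hz bin spacing, so both tags fall exactly on
bins and the rectangular window leaks nothing at the tag frequencies),
complex coefficients are averaged across repetitions — phase-locked
signal survives, random-phase noise cancels as $1/\sqrt{R}$ — and the SNR
at a tag is the bin amplitude divided by the mean amplitude of the 10
surrounding bins ($\pm$0.1 to $\pm$0.5 Hz, centre excluded).

The forward model collapses scalp physiology to a single virtual sensor:
one sinusoid per tag frequency with amplitude proportional to the model
response, phase fixed across repetitions, plus white Gaussian noise,
independent per repetition. Harmonics, the multi-electrode region of
interest, head geometry and the true (coloured) EEG noise spectrum are
all outside the model; the SNR statistic is self-normalizing, so noise
colour would mainly affect variance, not calibration.

Two deliberate calibration choices:

* **Gain** (`eeg_gain_for()`): the per-frequency scalp gain defaults to
  the expected post-averaging noise floor,
  $\sigma_N\sqrt{\pi/(NR)}$, divided by that frequency's noise parameter.
  With this choice the expected analysed SNR curve equals the model's
  $(resp+\sigma)/\sigma$ curve — the synthetic data are generated *on*
  the linking function, which is exactly what a forward-model fidelity
  check needs.
* **Amplitude calibration**: the neighbour-bin SNR estimator is biased
  for a strictly linear readout — the expected magnitude of a noisy
  spectral bin is a Rice mean, and dividing by a noisy floor estimate
  adds a Jensen term — so `synth_trial()` inverts the estimator's
  sampling expectation (closed-form Rice mean, second-order expansion of
  the reciprocal floor) when choosing each tag's amplitude. The analysed
  SNR is then an unbiased realisation of the target curve. A zero
  response maps to amplitude zero (depth-0 trials are pure noise), and
  with `noise_sd = 0` no calibration applies: a noiseless trial set
  carries exactly `gain * resp` at the tag and nothing elsewhere.

What passing round-trip tests do and do not show: they demonstrate that
the analysis chain recovers the generating response functions to within
a fraction of an SNR unit under the stated noise model, sample sizes and
stationarity. They do not validate the virtual-sensor abstraction against
real scalp data — the free gain and noise knobs are calibration devices,
not estimates of cortical quantities.

## Fitting and model comparison

`fit_dipper()` and `fit_eeg()` minimise the root-mean-square error
between model and data across all points of a panel — in dB for
thresholds, in linear SNR units for response functions, all points
weighted equally. The free parameter sets are $\{p,q,Z,\omega,
\sigma_{40}\}$ (thresholds) and $\{p,q,Z,\omega,\sigma_{40},
\sigma_{35}\}$ (EEG); the linear-summation model drops $\omega$ (4 and 5
free parameters respectively). The pooled detection threshold enters the
dipper objective once (plus the binaural detection point once),
mirroring the experimental pooling; counting it per condition is
available by option. The EEG objective covers the seven fitted curves —
40-Hz readouts of the five conditions that drive a 40-Hz response and
35-Hz readouts of the two cross conditions; the cross-monaural condition
is omitted.

Constraints are enforced by reparameterisation rather than penalties:
$q = 2 + e^a$, $p = q + e^b$, $Z = e^c$, $\omega = e^d$,
$\sigma = e^g$. Every returned parameter set satisfies positivity,
$q \ge 2$ and $p > q$ *exactly*, and the boundary fits ($q \to 2$,
$p \to q$) remain reachable in the limit. Optimisation is derivative-free
(Nelder-Mead) from 20 Latin-hypercube starting points in the
unconstrained space, with the best restart polished; fits are
deterministic given data, specification and seed. Multi-start matters
here: the objective has plateaus (e.g. $\omega$ is nearly unidentified
once it is small), and single-start local search is not reliable.
`evaluate_fixed()` recomputes predictions and RMSE under parameter
overrides (canonically $\omega \to 1$) with no optimisation, and
`table1_report()` assembles fits and evaluations into a comparison table
whose every RMSE is recomputed from its own row's parameters.

Out of scope by design: inferential statistics on empirical data
(ANOVAs, post-hoc tests), bootstrap or Bayesian uncertainty on
parameters, and hierarchical per-participant fitting.

## Problem sizes and runtimes

The shipped tests and the reproduction script use the full experimental
designs — 4 x 8 cells with paired 70-trial staircases and 3 repetitions
(6 participants in the reproduction run; single synthetic participants
in the repeated recovery studies, 20 seeded replicates), and 6 x 5 EEG
cells x 10 repetitions x 12 participants — sizes chosen to match the
designs the generators emulate while keeping a full test run in minutes
on one CPU. Parameter-recovery studies use 10 optimisation restarts per
replicate; the headline fits use 20.

## Known limitations

* The model is scalar per tag frequency: no phase, no interaural
  time/level differences, no masking-level-difference phenomena, no
  two-stage or phase-tuned extensions.
* Real EEG ingestion (BrainVision/EDF), artifact handling and scalp
  topography are not implemented; the EEG side starts from synthesized
  virtual-sensor trials or from an SNR table in the package's
  delimited-text schema. Raw-trial export is delimited text only.
* Deposited empirical datasets can be fitted once converted to the
  package's dataset schema (`read_dipper_dataset()`,
  `read_eeg_dataset()`); no assumptions are made about any external
  repository's file layout.
* The cross-frequency suppression rule (untuned) is an assumption the
  generating experiments cannot test; its alternatives would change
  cross-condition predictions quantitatively but not the weak-suppression
  conclusion.
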