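---
title: "Models and methods: value frames, beta-band power regression, and cluster permutation inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its models, its synthetic-data
generator, and the design choices behind both. The package exists to make a
particular style of electrophysiological decision-making analysis fully
testable at the desk: every stage — behavioural choice modelling, single-trial
time-frequency regression, and group-level cluster permutation inference — is
driven by a generator with known ground truth, so the statistical guarantees
of the pipeline can be measured rather than assumed.

## The scientific setting

The analyses target a two-option risky-choice experiment: on every trial a
subject chooses between two prospects, each defined by a reward magnitude and
a reward probability. Trials come in two types. On *comparison* trials both
options appear simultaneously (left/right) and the subject responds freely;
on *sequential* trials the options appear one after the other and the
response is withheld until a go cue. A trial is a *nobrainer* when one option
dominates on both attributes, and *harder* when probability and magnitude
favour opposite options. The central scientific question is one of frames of
reference: whether neural value signals attach to options (*goods space*,
chosen vs unchosen) or to actions (*action space*, contralateral vs
ipsilateral response), and whether the frame depends on trial type. The
neural carrier of interest is beta-band (13–30 Hz) oscillatory power in
motor cortex and ventromedial prefrontal cortex: movement preparation
expresses itself as a beta-power *decrease* (desynchronization), so effects
on power are routinely negative.

## Behavioural model

Choice behaviour is modelled with a three-parameter descriptive model.
Subjective utility is a power function of magnitude, $u(r) = r^\alpha$, and
probability is distorted by a one-parameter weighting function; the default
is the Tversky–Kahneman (1992) inverse-S form

$$w(p) = \frac{p^\gamma}{\left(p^\gamma + (1-p)^\gamma\right)^{1/\gamma}},$$

with the simple power form $w(p)=p^\gamma$ available through
`weight_form = "power"`. Both are canonical one-parameter choices; we expose
the switch because published work uses either, and the package's default is
stated rather than silently assumed. The subjective expected value of a
prospect is $w(p)\,u(r)$, and choices follow a softmax,
$P_i = e^{\beta v_i} / \sum_j e^{\beta v_j}$, with inverse temperature
$\beta \ge 0$. At $\alpha=\gamma=1$ the model collapses to objective expected
value, which is exactly the one-parameter baseline used for BIC comparison
(`compare_bic`): $\mathrm{BIC} = k\ln n + 2\,\mathrm{NLL}$.

Fitting is bounded maximum likelihood (`fit_prospect`): L-BFGS-B within
$\alpha,\gamma \in [0.05, 3]$, $\beta \in [0, 50]$, with 10 restarts (the
first from the identity parameters, the rest random with temperatures spread
over orders of magnitude) because the likelihood is multimodal in
$(\gamma,\beta)$. Choice probabilities are floored at $10^{-10}$ inside the
log so the objective stays finite. Fits are deterministic given a seed.

The logistic-regression analysis (`logistic_choice_analysis`) regresses the
choice of option 1 on standardized $p_1-p_2$, $r_1-r_2$ and objective
$EV_1-EV_2$ with a constant, per subject and per trial type, then applies
group one-sample and between-type paired t-tests. Near-perfect separation
(essentially deterministic choosers) is flagged and either capped or
excluded; the default cap of 10 on standardized-regressor coefficients
corresponds to effectively deterministic choice and keeps group statistics
finite.

## The synthetic-data generator

The generator is first-class, tested code: its defaults *are* the study
conditions everything downstream is validated under.

**Stimuli.** 324 trials per trial type, pseudorandomly interleaved.
Magnitudes are uniform on 10–100 (arbitrary units); probabilities are drawn
from a grid (default 0.2–0.8 in steps of 0.1), mirroring tasks that display
round percentages. Probability and magnitude are never equal across the two
options of a trial. Dominance is imposed by construction — pairing the larger
magnitude with the larger (nobrainer) or smaller (harder) probability — with
a configurable nobrainer proportion, default 1/3: enough dominated trials to
keep an agent motivated, while most trials require integrating both
attributes. The sampling law and the proportion are configuration, not fixed
truth, because display format does not pin down either.

**Choices.** A prospect-theory softmax agent inverts the behavioural model,
with an optional additive utility bias toward the second-presented option on
sequential trials. Comparison-trial response times are shifted-lognormal
with location decreasing in the absolute subjective value difference — the
empirically ubiquitous negative RT–value-difference relation — which is also
why the comparison-trial neural analyses lock to the response rather than
the stimulus.

**Cohorts.** Subject-level parameters are drawn once per cohort
(`draw_subject_params`): $\alpha \sim \mathcal N(0.8, 0.4)$ truncated to
$[0.1,2]$, $\gamma \sim \mathcal N(0.7, 0.12)$ truncated to $[0.2,1.5]$,
$\beta$ lognormal (median 2, sdlog 0.65) truncated to $[0.2,20]$. The wide
curvature/temperature spreads and the narrow weighting spread follow the
pattern of between-subject coefficients of variation reported for this model
class (roughly 0.5, 0.7 and 0.2); the group t-statistics downstream need
genuine between-subject variance, so heterogeneity is not optional.

**Epochs.** Source-level ("virtual channel") single-trial series at 200 Hz,
with the stimulus-locked window $[-1000, 2000)$ ms (600 samples exactly,
half-open convention) and response-locked $[-2000, 1000)$ ms. Each trial is

$$x(t) = A(t)\sin(2\pi f_c t + \phi) + \text{pink} + \text{white},$$

$$A(t) = a_0\left(1 + g_v\, z_v\, \mathrm{env}(t-\tau_v) +
        g_c\, c\, \mathrm{env}(t-\tau_c)\right),$$

with $z_v$ the standardized trial value regressor, $c = \pm 1$ the choice
coding, and $\mathrm{env}$ a raised-cosine envelope of width 400 ms —
sustained effects lasting a few hundred milliseconds with no sharp onset,
which is what slow amplitude modulations of band power look like; the width
is configurable because no canonical shape exists. Negative $g$ produces
desynchronization. The carrier phase is random per trial, so the injected
effects are induced (non-phase-locked) power changes, exactly what wavelet
power picks up. Noise is $1/f$ (spectrally shaped in the frequency domain,
unit variance, default SD 1) plus white noise (SD 0.5) around a carrier of
amplitude 1 at 20 Hz. Default gains of $-0.3$ give per-subject
variance-normalized effects around $-5$ to $-10$ at 324 trials — strong
single-subject effects, as in motor beta.

**Blinks.** `inject_blinks` adds raised-cosine pulses (default width 150 ms,
amplitude 8 background SDs, Poisson arrivals with a 500 ms minimum gap) to
an EOG channel and, scaled by a fixed spatial topography, to the data
channels, returning the ground-truth times and course.

What the generator does *not* emulate: sensor geometry and forward models,
phase-locked evoked components, heartbeat or movement artifacts, non-Poisson
blink dynamics, or non-stationary noise. Passing tests therefore demonstrate
the *statistical machinery* — calibration, recovery, ordering — under a
plausible signal model, not robustness to every pathology of real
recordings.

## Preprocessing

Blink detection band-passes the EOG 1–15 Hz with a zero-phase
forward–backward Butterworth filter (order 3 each way, latency-preserving),
z-scores, and keeps local maxima above 3 SD, retaining only the largest
maximum within a 200 ms refractory window. Removal epochs the data around
detected blinks (default $-200..400$ ms), averages, takes the top spatial
principal component(s) of the averaged blink, and projects them out of the
continuous data by least squares; the projection is idempotent and leaves
events and sampling rate untouched. One component is removed by default.
Epoching uses half-open windows and 0-based sample arithmetic throughout
(at 200 Hz, $[-1000,2000)$ ms is exactly 600 samples), flags — rather than
drops — trials whose window leaves the recording, and subtracts per-channel
baseline means (default window $-200..0$ ms). Visual artifact screening is
replaced by explicit peak-to-peak and flatness thresholds
(`reject_artifacts`) so that the whole pipeline is reproducible.

## Time-frequency regression

Single-trial power comes from complex Morlet wavelets: 40 frequencies
linearly spaced 1–40 Hz by default, Morlet factor 5 (cycles per Gaussian
SD), unit-energy normalization, truncation at $\pm 3$ SD. Output bins whose
wavelet support crosses the epoch boundary are flagged as edges and excluded
from cluster statistics — convolution edge artifacts otherwise masquerade as
early/late effects. Power is computed on a 25 ms output grid (the resolution
at which peak times are reported) as one matrix product per epoch set; the
precomputed basis (`morlet_basis`) is what makes the permutation and
replication studies below affordable. Raw power is regressed by default,
with a log transform available.

The trial-wise model at every (frequency, time) bin is ordinary least
squares on a design with a constant, standardized value regressor(s), and a
$\pm 1$ choice covariate — including choice alongside value is what lets the
analysis attribute variance to value *over and above* the upcoming action.
Named designs cover the option-1 model (sequential, option-1-locked), the
contralateral/ipsilateral action-space model, the chosen/unchosen
goods-space model, and a both-options variant; rank deficiency fails loudly,
naming the collinear columns. The per-subject summary statistic is the
variance-normalized effect $\hat\beta/\mathrm{SE}(\hat\beta)$ — a
per-subject t-value, the standard quantity submitted to group tests; a
strict $\hat\beta/\mathrm{Var}$ reading would only rescale maps per subject
and is not separately implemented. Contrasts of parameter estimates (e.g.
contralateral minus ipsilateral value) propagate the design covariance:
$w^\top\hat\beta / \sqrt{\hat\sigma^2\, w^\top (X^\top X)^{-1} w}$. Bins fit
exactly (zero residual variance) report an effect of 0 rather than a
roundoff ratio.

## Group inference

Per-subject maps are stacked and tested against zero with a one-sample
t-test per bin (df $= n-1$). Cluster-based permutation correction across the
whole time-frequency plane: threshold the t-map at $|T| > 2.0$, form
connected components (4-connectivity by default; 8 available), and measure
extent (bin count; cluster mass is a possible alternative, but extent is the
statistic this pipeline validates). The null distribution multiplies each
subject's entire map by an independent fair $\pm 1$ and records the maximum
supra-threshold cluster extent, 5000 times by default; for $n \le 12$ an
exhaustive $2^n$ enumeration is available and serves as the oracle for the
Monte-Carlo path. Corrected p-values use the add-one convention
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{\text{perm}})$, so
$p \in [1/(n_{\text{perm}}+1), 1]$.

**Tail handling.** Both signed effect directions are scientifically real
here (prefrontal synchronization positive, motor desynchronization
negative), so the default forms positive and negative clusters and compares
*each against the common null of the maximum extent over both signs per
permutation*. This controls the family-wise error across the entire plane
and both signs at the nominal level. Comparing each signed family against
its own signed null is also offered (`tail = "both_separate"`), but it is
anti-conservative — close to doubling the nominal level when both tails are
searched — which is why it is not the default; a strict one-tailed mode
(`tail = "pos"` / `"neg"`) matches analyses that genuinely search one
direction.

## Latency and interaction contrasts

Per-subject peak extraction (`peak_latency`) takes the extremum of the
signed statistic in a band × window (edges excluded), with deterministic
tie-breaking (earliest time, then lowest frequency). The expected direction
is part of the analysis specification — negative in motor beta, positive in
prefrontal beta — because peaks are signed quantities. Search windows follow
the analysis geometry: 0–1000 ms after the second option on sequential
trials, $-1000$–0 ms before the response on comparison trials. Ordering
questions (does the value signal precede the choice signal?) use a paired
t-test on per-subject latencies (df $= n-1$), reporting the median
difference alongside; identical inputs give $t = 0$ and constant nonzero
differences are flagged as degenerate rather than silently producing an
infinite statistic.

The 2×2 region-by-trial-type interaction on peak value effects is computed
from the per-subject double difference $d = (A_1 - A_2) - (B_1 - B_2)$; the
paired t on $d$ squared is exactly the repeated-measures interaction
$F(1, n-1)$ (verified against `aov` with error strata in the tests), and is
invariant to per-subject offsets. Each cell's entry is the peak effect in
that region's expected direction, so "more effect" is positive in both
regions and a crossover does not cancel in the double difference. Post-hoc
per-region paired tests can be one-tailed where a direction is
pre-specified.

## Validation studies and problem sizes

The package validates itself with five simulation studies, all exposed as
functions and rerun by `scripts/acceptance.R` and the test suite:

- **Family-wise error** (`fwe_null_experiment`): 200 independent null
  datasets (12 subjects, 324 sequential trials, 20 frequencies × 60 time
  bins, 500 sign flips each), no injected effects; the fraction of datasets
  with any corrected $p < 0.05$ should sit at or below the nominal level
  (the test allows the binomial 95% upper bound, 0.08). Twelve subjects
  keeps each dataset cheap while remaining in the regime where sign-flip
  inference is exact.
- **Oracle agreement**: OLS effects against explicit normal equations
  ($10^{-8}$); Monte-Carlo sign-flip p-values against exhaustive $2^{10}$
  enumeration (within Monte-Carlo error).
- **Parameter recovery** (`parameter_recovery_experiment`): 50 subjects ×
  648 trials; correlation between generating and recovered $\alpha$ above
  0.9, median absolute error below 0.15.
- **Latency recovery** (`latency_recovery_experiment`): value effect at
  500 ms, choice effect at 700 ms, subject latency jitter SD 50 ms, 18
  subjects × 50 replicate groups; group-median latencies within ±50 ms and
  the value-before-choice ordering detected in over 80% of replicates. The
  analysis restricts itself to the beta band (frequencies 14–30 Hz in 2 Hz
  steps) — the band the injected carrier lives in.
- **Model comparison and interaction**: BIC picks the generating model
  (curved prospect agent vs objective-EV agent, 648 trials) in ≥ 90% of
  datasets; the crossover interaction is detected in > 80% of replicate
  groups.

These sizes were chosen to make each study a stable statistical statement
(binomial error on a rate estimated from 50–200 replicates) while keeping a
full run in the minutes range on one core; they are stated here so that any
rerun is an exact replication, not an approximation.

## Known limitations

- The epochs container is an in-memory R structure with TSV serialization
  for trial tables; there is no on-disk binary epochs format.
- The generator's single virtual channel sidesteps source reconstruction
  entirely; nothing here validates beamforming or forward models.
- Cluster inference assumes exchangeability of subject signs under the
  null — valid for one-sample tests on symmetric per-subject summaries, not
  for arbitrary group designs.
- Peak latencies are grid-quantized at the analysis time step (25 ms);
  sub-step latency differences are invisible.
- The likelihood floor ($10^{-10}$) makes fits robust but means a truly
  deterministic chooser's $\beta$ is bounded by the box constraint, not
  estimated.
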