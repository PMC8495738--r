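---
title: "Methods: period estimation and hit calling in luciferase circadian screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: period estimation and hit calling in luciferase circadian screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CircaScreen)
```

## The problem

A reverse-genetic circadian screen crosses each knockout of a strain
collection to a luciferase reporter, distributes progeny replicates over
96-well plates, and images the plates by CCD camera for 4–5 days under
constant darkness after a light-to-dark transfer. Each well yields a
bioluminescence time course; the scientific question per strain is
whether removing the gene changes the free-running circadian period
relative to wild type. The statistical difficulties are that (i) absolute
signal levels, damping and baseline drift vary strongly between wells,
(ii) period varies technically between camera runs, and (iii) hundreds of
strains are screened, so hit calling needs an explicit wild-type
reference band rather than per-strain hypothesis tests.

CircaScreen implements the complete analysis chain and a synthetic data
generator that emulates the screen's structure with known ground truth,
so every stage can be validated by simulation.

## Signal model and FFT-NLLS

Each trace is modelled as a linear baseline plus a sum of exponentially
damped cosines:

$$y(t) = c + b\,t + \sum_{k} A_k e^{-\lambda_k t}
  \cos\!\left\{ \frac{2\pi (t - \phi_k)}{\tau_k} \right\} + \varepsilon(t).$$

The estimator is the classic FFT-NLLS scheme:

1. **Trim** (`trimWindow()`): the first and last 12 h of each recording
   are discarded. The leading window carries the light-to-dark
   transition transient; the trailing window improves the subsequent
   trend fit.
2. **Detrend** (`detrendTrace()`): values are replaced by residuals of a
   least-squares linear (optionally polynomial, order ≤ 3) trend in
   time. Slow trends — substrate depletion, signal decay — otherwise
   distort the periodogram. Time is kept explicit everywhere, so
   irregular sampling needs no resampling or interpolation.
3. **Seed** (`periodogramSeeds()`): candidate frequencies are the top
   local maxima of a 4×-zero-padded FFT periodogram (regular sampling)
   or a least-squares periodogram on the same frequency grid (irregular
   sampling). Amplitude and phase per candidate come from ordinary least
   squares on the cosine/sine pair at the peak frequency, which is exact
   for any sampling pattern.
4. **Fit** (`fitCosineModel()`): Levenberg–Marquardt nonlinear least
   squares (via `minpack.lm`). Internally each component is
   parameterised as an in-phase/quadrature pair
   $a_k \cos \omega t + b_k \sin \omega t$ — linear in $a_k, b_k$ and
   free of phase-wrapping — and converted back to $(A_k, \phi_k)$ for
   reporting, with standard errors from the local linearization
   (covariance of the NLLS solution; delta method for $A_k$).
5. **Select components** (`estimatePeriod()`): components are added in
   order of spectral power while *every* fitted component's amplitude
   confidence interval excludes zero, up to 4 components. Two further
   numerical guards matter in practice:
   - a candidate model is rejected when two components approach each
     other in frequency by less than half a Fourier resolution element
     ($0.5/\mathrm{span}$). Closer pairs are unresolvable on the record
     length and produce degenerate "beating" fits with enormous,
     mutually cancelling amplitudes;
   - if the optimizer fails to improve on the seed parameters, the seed
     evaluation is returned (the fit's SSE never exceeds the seed SSE).
6. **Report**: the period $\tau$ of the largest-amplitude component
   inside the circadian window, with ties broken by smaller RAE, then
   smaller period.

### Rhythmicity

The rhythmicity statistic is the **relative amplitude error**,
RAE = (half-width of the ~95 % amplitude confidence interval) / amplitude.
A trace is *rhythmic* when its reported component lies in the circadian
window and RAE ≤ 0.5; otherwise *arrhythmic*. The screen this package
models did not publish its numeric rhythmicity rule, so the RAE rule —
the convention of the FFT-NLLS literature — is a documented stand-in,
and both the threshold and the window are configuration parameters.

### Damping

The generator damps its rhythms (visible amplitude decay over 4–5 days);
the fit is undamped by default. On 4–5-day records a per-component free
damping rate trades off against amplitude and degrades identifiability,
while leaving damping out biases period estimates negligibly (the
envelope is even around the carrier). Damped fitting is available via
`damping = TRUE`.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `trim_head_h`, `trim_tail_h` | 12, 12 | h | published analysis window rule |
| `detrend_method` | linear | — | slow monotone trends dominate |
| `circadian_window` | (16, 32) | h | brackets WT 21.76 h and ±2 h effects with margin |
| `rae_threshold` | 0.5 | — | FFT-NLLS convention |
| `max_components` | 4 | — | FFT-NLLS convention |
| `low_signal_fraction` | 0.1 | fraction of WT median raw mean | wells below it are re-analysed normalized |
| `interval_k` | 3 | SDs | ~99.7 % coverage of normal WT variation |
| `alpha` | 0.05 | — | concordance t-test level |
| `min_replicates` | 3 | wells | below it a strain is `insufficient_n` |
| `rhythm_floor` | 0.5 | fraction | below it a strain is classified arrhythmic |

## Screen statistics

**Per-run WT reference.** Every camera run carries wild-type control
wells; the reference is the arithmetic mean of the rhythmic WT replicate
periods in that run, and $\Delta\tau$ = replicate period − reference.
This makes $\Delta\tau$ exactly invariant to any run-level additive
period offset (a tested property). Runs without a rhythmic WT control
are excluded with a warning. WT wells themselves get $\Delta\tau$
relative to their own run's mean (leave-self-in; with the typical 8
controls per run the distinction from leave-one-out is a 1/n effect).

**Tolerance interval.** Mean ± 3 SD of the WT $\Delta\tau$ population,
covering 99.73 % of a normal population. Shapiro–Wilk is computed and a
failed normality check warns but does not block: the interval is a
descriptive band, and refusing to build it would silently drop a screen.
Note the interval is built from *individual well* $\Delta\tau$ values
while hits are called on *strain medians*; medians of $n$ replicates are
less dispersed than single wells, so the realised null hit rate sits
below the nominal 0.27 % — the binomial compatibility test in the
acceptance suite accounts for this direction.

**Hit calling.** A strain whose median is strictly below the lower bound
is `short`, strictly above the upper bound `long`; a median exactly on a
bound is *not* a hit ("outside the interval" read as exceedance).
Arrhythmic strains (rhythm fraction below `rhythm_floor`) are reported
separately and are never hits. Medians (with IQR) are used instead of
means to damp replicate outliers. No multiple-testing correction is
applied — the interval *is* the family-wise control device of this
design — but `interval_k` and `alpha` are exposed.

**Dual-reporter confirmation.** A final candidate must have its median
outside the tolerance interval under both the core-clock and the output
reporter, with the same sign. The Welch two-sample t-test between the
two reporters' replicate sets (Welch, because progeny groups differ in
size and variance) is attached as an annotation: a strain can be
statistically discordant yet confirmed when both medians are shifted the
same way, mirroring screens where a candidate's two reporters disagree
in magnitude but not direction. Primary hits without usable secondary
data are `pending`, never candidates.

## The synthetic generator

`simulateScreen()` generates a dual-reporter screen: 96-well runs, each
with 8 WT control wells, 2 samples/hour for 120 h, WT period 21.76 h,
amplitude 100, baseline 200 with slope −0.3/h, damping 0.01/h, Gaussian
noise SD 10, and an additive transition bump (height 150, decay 0.5/h,
gone within the trimmed window). Strain classes: planted period shifts
(`planted_delta_tau`), arrhythmic strains (zero amplitude), low-signal
strains (signal scaled to 2 % of WT) and discordant strains (shift under
the primary reporter only).

Design notes, in the order they were decided:

- **Noise** is i.i.d. Gaussian on the signal — the simplest model
  consistent with CCD photon counting at these exposure times — scaled
  with each strain's signal level, plus an absolute camera read-noise
  floor (`noise_floor_sd`, 1 unit). The floor is what makes low-signal
  wells genuinely harder: their rhythm sits close to the absolute noise.
- **Run-level period jitter** (SD 0.1 h) creates the inter-run technical
  variation that per-run WT referencing exists to absorb.
- **Per-well period jitter** (SD 0.16 h) models biological
  replicate-to-replicate period variation. Its default is calibrated so
  the simulated WT $\Delta\tau$ dispersion reproduces a 3-SD tolerance
  half-width of roughly ±0.49 h, the band the modelled screen reports;
  without it the only WT variance would be fit error (~0.04 h), far
  tighter than any real screen.
- **Determinism**: one RNG stream per screen seeded once; jitter draws
  always advance the stream, so configurations differing only in a
  jitter SD are comparable draw-by-draw under the same seed.

**What the generator does not emulate** — and what passing tests
therefore do not show about real data: spatial plate effects and
well-to-well crosstalk, non-Gaussian and autocorrelated noise,
non-stationary period (ageing cultures), phase desynchrony within a
well, reporter-specific waveform differences, and missing frames. The
generator's damping and noise levels are plausible placeholders, not
measured values; they are configuration parameters precisely because the
screen they emulate does not report them.

### Low-signal rescue

Cosine fitting is scale-invariant: multiplying a trace by a positive
constant changes no period, phase or RAE (a tested property). Dividing
by the mean therefore cannot change *detectability*; what normalization
does in this pipeline is operational. Wells whose raw mean falls below
`low_signal_fraction` of their run's WT median are treated as
"apparently arrhythmic at raw scale": their call is made on the
mean-normalized trace, and a rhythmic normalized trace is labelled
`low_signal`, keeps its period, and contributes $\Delta\tau$ — so a
faint strain with a wild-type period ends up inside the interval rather
than excluded, and a faint strain with a real shift can still be a hit
(`short`/`long` take precedence over the `low_signal` strain class).

## Numerical choices and degenerate inputs

- Near-zero mean traces refuse normalization (guard: |mean| >
  1e−6 × value scale) — expected for already-detrended series.
- An all-zero or signal-free trace yields an empty seed list and an
  arrhythmic estimate, not an error; optimizer non-convergence is a
  flag on the model, not an error.
- A zero-variance WT population yields a zero-width interval with a
  warning.
- Identical constant samples in the concordance test (degenerate for a
  t-test) are short-circuited to concordant (p = 1) or discordant
  (p = 0) by mean equality.
- Component amplitudes are non-negative by convention (sign absorbed
  into phase); phases are reported in [0, τ).

## Problem sizes used in validation

The test and acceptance suites run at deliberately desk-scale sizes:
100 traces for parameter recovery (120 h at 2 samples/hour each), a
200-strain × 8-replicate single-reporter null screen for the
false-positive property, and 6–10-strain dual-reporter screens for
end-to-end planted-effect recovery. These sizes give Monte Carlo
resolution well below the effect sizes being checked while keeping the
full suite in the low minutes on a single core.

## Known limitations

- Period standard errors come from the local linearization; joint
  nonlinear confidence regions (as the original FFT-NLLS literature
  produces) are wider for heavily damped, short records. Screening uses
  unweighted $\Delta\tau$, so this affects reporting only.
- The RAE threshold and circadian window are conventions, not estimates;
  strains near either boundary deserve manual inspection.
- With `damping = TRUE` on short records the damping rate is weakly
  identified and can absorb amplitude; the default keeps it off.
- The secondary screen re-uses the same tolerance-interval machinery on
  its own WT controls; if an output reporter has systematically higher
  period noise, its interval widens and confirmation becomes more
  conservative — intended, but worth knowing when comparing counts
  between reporters.
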