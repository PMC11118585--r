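---
title: "Methods: quantifying the ontogeny of torsional gaze stabilization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the ontogeny of torsional gaze stabilization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vorquant)
```

## Scope

`vorquant` quantifies the maturation of the torsional vestibulo-ocular
reflex (VOR) in larval zebrafish and of the circuit elements underlying it.
It covers four measurement arms — tilt-step stimulus construction,
eye-trace → gain analysis, tilt-in-place microscopy (TIPM) calcium-trace
scoring, and neuromuscular-junction (NMJ) image quantification — plus the
group-comparison statistics that tie them together, and a synthetic-data
generator for every arm so the full pipeline is testable with known ground
truth. It deliberately does **not** extract torsional angle from raw eye
videos, motion-correct imaging volumes, or segment ROIs: those upstream
steps have their own dedicated tools, and `vorquant` ingests their outputs
(angle traces, ROI fluorescence traces, ROI polygons).

## Stimulus model

A tilt step is parameterized by signed amplitude $A$ (degrees, positive =
nose-up), peak velocity $v$ and peak acceleration $a$. The velocity profile
is trapezoidal: a ramp at $\pm a$ to $v$, a plateau, and a symmetric ramp
down, with

$$t_\mathrm{ramp} = v/a, \qquad
  t_\mathrm{plateau} = \frac{|A| - v^2/a}{v}.$$

The behavioral default is $A = \pm 15°$, $v = 35$ °/s, $a = 150$ °/s²
(ramp 0.233 s, plateau 0.195 s); the fast control uses $v = 90$ °/s,
$a = 600$ °/s². When $v^2/a > |A|$ the commanded plateau is unreachable;
rather than failing we emit a triangular profile peaking at
$\sqrt{|A|\,a}$ with a warning, which keeps small-amplitude gradient steps
usable. Profiles are evaluated analytically (angle is the exact integral of
velocity) on a uniform grid with the phase breakpoints inserted, so the
sampled profile terminates at exactly $A$ and attains its extrema exactly.

Microstep schedules convert a monotone angle profile into firing times of a
stepper emitting fixed 0.0072° increments. The count is
$\lfloor |A| / 0.0072 \rfloor$ with the sub-step residual dropped —
hardware cannot emit fractional steps and the residual (< one microstep) is
far below measurement noise.

Protocols: `behavior` is 50 cycles of four ±15° steps toward and away from
the horizon with 7.5 s holds; `tipm_gradient` presents 7.5/15/22.5/30°
steps 4–5 times each in randomized order; `tipm_longitudinal` a single 25°
step 4–5 times. Randomization is a seeded permutation recorded in the trial
table, so a protocol is fully reproducible from its seed.

## Eye-trace analysis and gain

The pipeline mirrors standard torsional-VOR practice:

1. **Centering** removes the constant offset a pattern-matching torsion
   tracker introduces. Default is the whole-trace mean; a pre-stimulus
   baseline window is available (`method = "baseline"`) since the choice is
   not canonical. For gain the choice is immaterial — differentiation kills
   constants.
2. **Cubic-spline resampling** corrects transient camera slowdowns, which
   appear as duplicated frames. Duplicate timestamps are collapsed and a
   cubic spline (`splinefun`, method `"fmm"`, which reproduces cubic
   polynomials exactly) is evaluated on a uniform 200 Hz grid.
3. **Velocity** is the first difference scaled by the sampling rate,
   low-passed with a 4-pole Butterworth at 3 Hz. We apply it
   forward–backward (`filtfilt`), i.e. zero-phase: peak *timing* within
   the 1 s gain window is then unbiased, at the cost of squaring the
   magnitude response (3 Hz power is halved per pass, −6 dB in amplitude
   total). A single causal pass is available by flag. "4-pole" is
   interpreted as order 4 per pass.
4. **Exclusion**: trials with any unfiltered sample-to-sample displacement
   above 1.5°/sample (≈ 300 °/s at 200 Hz — far above compensatory eye
   velocity) or more than 20 % missing samples are dropped, with reasons
   recorded. This automates what is usually a manual screen for horizontal
   saccades and tracking failures; the threshold is exposed in the API and
   stored in the result.
5. **Gain**: per within-cycle step position, included velocity responses
   are averaged across cycles, the peak |velocity| in the first second
   after command onset is read off the average, and gain is that peak over
   the peak platform velocity. The denominator defaults to the *commanded*
   peak (35 or 90 °/s), with a measured-platform override, and step onset
   means command onset.

Two numerical facts worth knowing. First, a zero-phase Butterworth is not
an envelope-preserving smoother: its step response rings, and on the
trapezoidal velocity pulse the filtered peak overshoots by ≈ 5 %. The
popular invariant "a low-pass filter never amplifies the peak" is false in
the time domain; what holds (and what we test) is that per-frequency
amplitude gain never exceeds one. The overshoot appears as a small,
deterministic positive bias in estimated gain (≈ +0.05 at gain 1, smaller
below), which is shared by any analysis using this filter on this
stimulus, and which keeps the mean absolute recovery error across gains
0.25–1.0 below 0.05. Second, differentiating 0.2° tracker noise at 200 Hz
produces ≈ 56 °/s of velocity noise; the 3 Hz filter reduces it to
≈ 0.33 °/s per trace and cycle averaging (50 cycles) to ≈ 0.05 °/s, which
is why peak-picking within a 1 s window remains unbiased in practice.

## TIPM scoring

TIPM returns the animal to the imaging plane within ~5 ms — much faster
than the GCaMP6s decay — so post-return fluorescence is the decaying
response to the tilt. Scoring is accordingly anchored at the return:

- **Baseline** $F_0$ = mean of the first 10 frames of the trial.
- **dF/F** = (peak $F$ among frames acquired in $[t_\mathrm{return},
  t_\mathrm{return} + 1\,\mathrm{s})$ − $F_0$) / $F_0$. The window is
  half-open and measured from the first frame at/after the return; at ~3
  volumes/s it contains 3 frames. With indicator decay constant $\tau$ the
  worst-case discretization loss of the true peak is
  $1 - e^{-\Delta t/\tau}$ (≈ 10 % at $\Delta t = 1/3$ s, $\tau = 3$ s).
- **ROI-size normalization** rescales fluorescence by a reference/actual
  area ratio when zoom varied; dF/F is a ratio and is provably invariant
  to it, so normalization only matters for raw-fluorescence comparisons.
- **Directionality index** DI = (up − down)/(up + down) on dF/F, tuned when
  |DI| > 0.1. Negative dF/F (noise below baseline) is clipped to zero *for
  the DI only*, keeping it in [−1, 1] for noisy non-responders; a clipped
  sum of zero is reported as DI 0, untuned, flagged degenerate — the
  original definition leaves this case open. Per-neuron responses are the
  mean over the 4–5 repeats before any DI or cross-day computation.
- **Sensitivity** is the OLS slope of dF/F against amplitude over the
  7.5–30° gradient; "sensitive" = slope > 0 with two-sided p < 0.05, which
  under the null fires at 2.5 % (the one-sided half of 5 %).
- **Longitudinal pairing** joins per-day response tables through an
  explicit id map (the map encodes rater-agreed tracking; it is never
  inferred from the data). Differences are later − earlier.
- **Bootstrap SDs** resample with replacement (default 60 replicates, the
  study's convention) and return the SD of the replicated statistic; a
  per-bin histogram-proportion variant serves distribution plots. Whether
  error bars belong on summary statistics or per-bin proportions is
  ambiguous in common usage, so both are exposed.
- Statistics on dF/F use the natural-log transform log(dFF + 1); the base
  is a display convention and rank-based tests are invariant to it.

## NMJ quantification

Per muscle: maximum-intensity z-projection → light Gaussian denoise
(σ = 1 px; see below) → threshold computed from ROI-interior pixels only →
binarize → % area labeled and particle statistics. The ROI is a polygon in
pixel coordinates; a pixel is interior when its center is (the
center-in-polygon rule). Particles are 8-connected components of minimum
size one pixel and no maximum, with areas converted to μm² by the squared
pixel size — area, not length, because the particles are 2-D regions of a
projection.

The original quantification thresholded manually with two raters checking
consistency. An automatic criterion replaces that judgment here: Otsu's
threshold restricted to ROI pixels (default), with percentile and fixed
alternatives for sensitivity analysis; a ±5-point percentile sweep changes
synthetic-image estimates smoothly, which is the automated analogue of the
two-rater check. The pre-threshold Gaussian blur suppresses single-pixel
noise excursions that an automatic threshold would otherwise count as
labeled area or spurious one-pixel particles — the despeckling a rater does
implicitly by eye; `smooth_sigma = 0` disables it. Because the manual
criterion is unrecoverable, absolute % values from real images are not
comparable across labs — within-experiment orderings are.

## Synthetic data: what it does and does not emulate

Generators are pure functions of (spec, seed) and always emit ground truth.

- **Eye traces**: eye = −gain × platform angle (nose-up positive platform,
  compensatory counter-rotation, per the convention that the right eye
  rotates "down" for nose-up), plus Gaussian tracker noise (0.2° default),
  Poisson saccadic artifacts (instantaneous offsets with 0.5 s exponential
  return — exclusion only needs them to be abrupt), and duplicated frames
  at 2 % emulating camera slowdowns. Not emulated: slow drift, torsional
  tracker nonlinearity, eye-position-dependent gain.
- **TIPM traces**: baseline fluorescence, unidirectional tuning
  (non-preferred tilts give zero response), response
  dFF = max(0, intercept + slope·|angle|), exponential decay from the
  return frame with τ = 3 s (GCaMP6s order; scoring uses the early peak so
  the exact value is not critical), Gaussian noise. Not emulated:
  trial-to-trial adaptation, bleaching, neuropil contamination.
- **NMJ images**: an elliptical "muscle" at fiber intensity with bright
  puncta disks placed until a target fraction is reached, then Gaussian
  noise; the default contrast-to-noise is 5. Not emulated: out-of-focus
  light, fiber texture, anisotropic PSF.
- **Ontogeny datasets** draw per-fish gains, longitudinally correlated
  per-neuron dF/F, and per-fish NMJ % area from per-age means/SDs. The
  default plateau configuration — ages 3/5/7/9/15 dpf, gain means
  0.30/0.55/0.70/0.80/0.80, SD 0.10, N = 8 fish/age — matches the shape
  and group sizes typical of this developmental series: a rise to 9 dpf
  and a flat 9→15 tail.

Passing tests on these generators establishes that the *analysis* is
correct and calibrated under the stated noise model; it does not certify
performance on artifacts the generators omit (drift, adaptation, optical
structure), which is why every threshold is exposed and recorded.

## Statistics

`compare_groups` dispatches to base R: Student and paired t-tests, one-way
ANOVA (`aov` + `TukeyHSD`), two-way repeated-measures ANOVA (`aov` with
`Error(subject/within-factor)` — the mixed design with subject as the
repeated unit; the post-hoc uses Tukey-adjusted estimated marginal means
via emmeans, since `TukeyHSD` does not apply to `aovlist`), Kruskal–Wallis,
and Kolmogorov–Smirnov. Bonferroni correction divides α by an *explicitly
declared* family size — the tool never guesses which comparisons form a
family. `dual_analysis` repeats the parametric test (on log(dFF+1)) with a
nonparametric counterpart on raw data — Wilcoxon signed-rank for paired
t-tests, Kruskal–Wallis otherwise (including for the mixed two-way design,
on the first factor, there being no standard nonparametric equivalent) —
and flags significance disagreements rather than hiding them.

## Problem sizes and determinism

The bundled checks run at the scale of the study itself: 50-cycle
experiments at four true gains × 20 seeds for gain recovery; 500 neurons
for DI classification; 4000 null neurons for the sensitivity type-I rate
(the ±1 % assertion band is then ≈ 4 binomial standard errors); 21 images
across 1–10 % labeled fractions for NMJ recovery; 100 plateau runs and 400
flat runs for the ontogeny simulation. Every stochastic step takes an
explicit seed, RNG state is restored after each generator call, and rerun
outputs are byte-identical — including those of the `vor.R` command-line
dispatcher.

## Known limitations

- Gain estimates inherit the ≈ 5 % zero-phase-filter overshoot; comparisons
  *across* ages are unaffected (the bias is common), absolute gains are
  conservative by that margin when compared to unfiltered peaks.
- The saccade screen is a single-sample displacement threshold; slow
  drifts or low-amplitude saccades below threshold pass through, as they
  would a manual screen.
- dF/F peak sampling at 3 volumes/s under-reads fast-decaying responses by
  up to $1 - e^{-\Delta t/\tau}$.
- NMJ absolute percentages depend on the threshold criterion; only
  within-criterion comparisons are meaningful.
- The two-way repeated-measures ANOVA assumes sphericity (no correction is
  applied); with two levels per within-factor, as in the age-pair designs
  here, sphericity is trivially satisfied.
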