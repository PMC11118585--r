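# vorquant

Quantification of vestibulo-ocular reflex (VOR) ontogeny from tilt-step
experiments in larval zebrafish.

Developing fish stabilize gaze by counter-rotating their eyes against body
tilts. Asking *which* element of the circuit limits the maturation of that
behavior requires measuring, in the same units across ages: the behavior
itself (torsional eye velocity against a known platform motion), the
tilt-evoked responses of central and motor neurons (calcium imaging), and
the output synapse (neuromuscular-junction labeling in extraocular
muscle). `vorquant` implements that full measurement chain for
researchers running tilt-step and tilt-in-place microscopy (TIPM)
experiments, plus synthetic-data generators with ground truth so every
stage is testable without recordings.

## What it computes

**VOR gain.** Platform steps follow a trapezoidal velocity profile
(ramp at peak acceleration *a*, plateau at peak velocity *v*, ramp down;
defaults ±15°, 35 °/s, 150 °/s²). The torsional eye trace (200 Hz) is
centered, spline-resampled to a uniform grid, differentiated, low-passed
with a zero-phase 4-pole Butterworth (3 Hz), screened for saccadic
artifacts, and averaged across cycles per step. Gain is

```
gain = peak |eye velocity| in the 1 s after step onset / peak platform velocity
```

**TIPM dF/F and tuning.** For each trial, baseline F0 is the mean of the
first 10 frames and

```
dFF = (peak F in the first second after return to horizontal − F0) / F0
```

The directionality index DI = (up − down)/(up + down) on dF/F lies in
[−1, 1]; |DI| > 0.1 classifies a neuron as direction-tuned. Sensitivity to
tilt amplitude is the OLS slope of dF/F over 7.5–30° steps ("sensitive" =
slope > 0, p < 0.05). Neurons tracked across days are paired through an
explicit id map; bootstrap SDs (60 replicates) accompany difference
distributions.

**NMJ labeling.** Confocal stacks of extraocular muscle are max-projected,
thresholded within a polygonal muscle ROI (Otsu on ROI pixels by default),
and binarized; `% Area Labeled` is the suprathreshold fraction of ROI
pixels, and particle statistics (8-connected, sizes 1 px–∞, converted to
μm²) summarize puncta.

**Statistics.** t/paired-t, one- and two-way repeated-measures ANOVA with
Tukey post-hocs, Kruskal–Wallis, Kolmogorov–Smirnov, Bonferroni correction
over a declared family, log(dFF+1) transforms, and a dual
parametric/nonparametric mode that flags disagreements.

## Worked example

```r
library(vorquant)

# A 50-cycle behavioral experiment from a fish with true gain 0.75
proto <- build_protocol("behavior")
spec  <- synthetic_behavior_spec(true_gain = 0.75, seed = 42)
gen   <- generate_eye_trace(spec, proto)
estimate_gain(gen$trace, proto)
#> <gain_result> gain = 0.791 (peak eye 27.8 / platform 35.0 deg/s); 192 steps included, 8 excluded

# A nose-up-tuned neuron probed with +/-25 deg TIPM trials
nspec <- synthetic_neuron_spec(response_slope = 0.02, noise_sd = 1, seed = 42)
up    <- generate_tipm_trace(nspec, trial_timeline(), +25)
down  <- generate_tipm_trace(nspec, trial_timeline(), -25)
directionality(compute_dff(up$trace), compute_dff(down$trace))
#> dFF up 0.494, down 0.008, DI 0.966, tuned TRUE

# NMJ quantification of a synthetic muscle image (true fraction 5.1%)
img <- generate_nmj_image(synthetic_nmj_spec(target_fraction = 0.05, seed = 42))
quantify_muscle(img$image, img$roi, pixel_size_um = 0.31)
#> <nmj_quant> SO aBTX: 5.39% area labeled, 20 particles (mean 3.58 um^2), threshold 0.2563 (otsu)
```

The gain estimate (0.791 vs 0.75) carries a small deterministic positive
bias from the zero-phase filter's overshoot on the trapezoidal velocity
pulse — see the methods vignette (`vignettes/vor-ontogeny-methods.Rmd`),
which documents every processing choice, default and limitation. 8 of 200
steps were excluded by the automated saccade screen; the dF/F values show
unidirectional tuning (strong nose-up, near-zero nose-down response); the
NMJ estimate recovers the generated labeled fraction to within a few
tenths of a percentage point.

A command-line front end over the same functions lives at
`inst/cli/vor.R` (subcommands `stimulus`, `behavior`, `tipm`, `nmj`,
`stats`, `demo-ontogeny`); all its outputs are byte-reproducible given the
same inputs and seed.

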