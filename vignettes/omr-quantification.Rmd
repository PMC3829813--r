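---
title: "Measuring mouse visual acuity from optomotor head tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring mouse visual acuity from optomotor head tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omrkit)
```

## The measurement problem

When a mouse standing on a small elevated platform is surrounded by a
large moving grating, it reflexively turns its head to follow the motion
(the optomotor response, OMR). Whether the reflex occurs depends on
whether the animal can resolve the grating, so sweeping the grating's
spatial frequency and measuring how much the animal tracks yields a
behavioral estimate of visual acuity — without head fixation, surgery or
markers. `omrkit` implements the computational side of such a setup:

1. a **markerless head-gaze tracker** for overhead video of the platform,
2. the **virtual-cylinder stimulus geometry** (grating photometry,
   rotation protocols, head-position feedback, display linearization),
3. the **automated quantification**: detecting stimulus-related behavior
   from angular velocities, chance correction, response curves, and a
   robust logistic fit whose inflection point is the acuity threshold,
4. a **synthetic-data module** that renders mouse silhouettes with known
   pose and simulates gaze traces with known tracking epochs, so every
   stage can be validated against ground truth.

## Head-gaze tracking

Each overhead frame is reduced to a gaze angle in five steps.

**Calibration.** Platform-region pixels of the first ten frames whose
every channel lies strictly below a cutoff (default 100 of 255) are
pooled; in a lit arena these are fur pixels. Their per-channel mean is
the segmentation threshold. For albino animals on a dark platform the
polarity is inverted (`polarity = "light_on_dark"`).

**Segmentation.** Everything outside the disc the animal can reach with
its nose is discarded, the frame is binarized strictly against the
threshold, 8-connected components are labeled and only the largest is
kept. Droppings and specks survive binarization but lose to the body by
size.

**Weighted center of gravity.** Body coordinates are weighted by a
linear radial ramp — 1 at the platform center, 0 at the reachable
border — and averaged. The ramp only has its endpoints fixed by the
physical setup; we use the linear interpolant as the simplest monotone
choice. Because the abdomen is broader than the front and the weighting
discounts peripheral pixels, this center of gravity lands in the
hindquarters.

**Nose.** The nose is the coordinate of the weighted set farthest from
that center of gravity. Two readings of "farthest weighted coordinate"
are possible: maximizing the raw distance, or maximizing
`w(p) * distance`. We implement the raw distance. The weighted score
fails systematically: whenever the animal's nose points away from the
platform center, the nose pixels carry the *lowest* weights and the tail
wins (a 10° heading grid over off-center poses reproduces this with
errors of the full body length). The raw-distance reading also matches
the intended property that a pixel is the more plausible nose candidate
the farther it sits from the platform center, since the weighting has
already pulled the reference point centerward. Ties are broken
lexicographically so tracking is deterministic.

**Head center and gaze.** The unweighted centroid of the mask inside a
disc around the nose (default radius 10 mm; the physical build does not
fix this number, so it is configurable) lies on the skull's sagittal
axis between the ears. The gaze is the angle of the vector from that
head center to the nose, in degrees counterclockwise seen from above.

On rendered silhouettes the tracker recovers a 10°-spaced heading grid
with sub-degree median error; the acceptance suite requires median ≤ 5°
and maximum ≤ 15°.

## Stimulus geometry and photometry

The grating lives on a virtual cylinder whose axis follows the animal's
head: for every monitor pixel at world position $q$ the azimuth about
the head position $h$ is $\mathrm{atan2}(q_y - h_y,\, q_x - h_x)$, and
the pixel shows the grating value at that azimuth. This keeps the
angular frequency about the head equal to the nominal spatial frequency
wherever the animal stands; `panorama_cycles()` verifies the cycle count
from rendered pixels. A spatial frequency of $f$ cyc/deg corresponds to
$360 f$ pattern repetitions per full cylinder (0.2 cyc/deg = 72
repetitions, 0.6 cyc/deg = 216).

The sinusoidal profile is
$L(\theta) = m + m\,c\,\sin(2\pi n \theta/360)$ in relative luminance,
clipped to $[0,1]$; with mean level $m = 0.5$ the Michelson contrast of
the displayed grating equals the contrast parameter $c$. Displays are
nonlinear, so commanded levels pass through the inverse of a measured
calibration curve (`linearize()`); a synthetic gamma-law curve with the
default luminance limits 0.22 and 152.13 cd/m² stands in for a
spectrometer measurement. A corrected staircase of ten equal luminance
steps deviates from a straight line by less than one quantization step.

The rotation protocol is a triangle wave: constant speed (default
12 °/s) with a direction reversal every 6 s over a 60 s presentation,
i.e. at most ten unidirectional tracking movements of 72° each; zero
velocity gives the static null condition. The head-position feedback to
the cylinder center is a trailing moving average over 20 frames — the
feedback loop is causal, so a centered window is not an option — which
suppresses the abrupt cylinder jumps that startle the animal.

All rendering here is offline (arrays rather than a live graphics loop):
the quantity under test is the geometry and photometry, not display
timing.

## Quantifying tracking behavior

Head and stimulus angle traces are differentiated with shortest-arc wrap
handling (a 359°→1° step is +2°, not −358°). A frame is
**stimulus-related behavior** (SRB) when the signed velocity difference
is strictly below the discrimination parameter:
$|\dot\alpha_{head} - \dot\alpha_{stim}| < \lambda$, with $\lambda =
9$ °/s by default. Signed velocities make the criterion directional: at
a 12 °/s stimulus the accepted band is head velocities in (3, 21) °/s
*in the stimulus direction*. Values of $\lambda$ above 12 would accept a
motionless head; the package allows them (they are useful for
demonstrating exactly that failure) but the default stays at 9. The
fraction of SRB frames over the trial is $T_{track}$; invalid tracker
frames are removed from numerator and denominator alike (the source
material is silent on dropped frames; discarding them from both is the
only choice that leaves $T_{track}$ a proper fraction).

**Chance correction.** Even an ignoring animal occasionally moves its
head inside the band. Null-condition recordings (static grating) are
scored against the standard moving-velocity profile; per animal the
median over its null trials is taken, and the median of the per-animal
medians is the chance level, subtracted from every response. Negative
corrected values are kept by default (clipping is available but distorts
the estimator's distribution).

**Response curve and acuity.** Per animal and frequency the median
corrected $T_{track}$ is taken, then the population median across
animals, normalized to 1 at the optimal frequency (default 0.2 cyc/deg,
with an auto-detect option). The descending branch above 0.2 cyc/deg is
fitted with

$$R(f) = \frac{a}{1 + e^{(f - b)/c}}$$

by minimizing the sum of absolute residuals — robust to an outlying
median, which a least-squares fit visibly is not (the test suite
compares both objectives under an injected outlier). $a$ is the response
maximum, $b$ the inflection point, $c > 0$ the steepness of the decline.
The visual acuity is the frequency eliciting a criterion fraction of the
maximum: for the default 50 % criterion exactly $b$; for a criterion $q$,
$b + c \ln((1-q)/q)$.

### Numerical choices

- The LAD objective is minimized with Nelder–Mead from multiple starts
  of $b$ spread over the fitted range (5 by default), with a polish pass
  from the incumbent. Convergence code 10 (simplex degeneracy) is
  accepted: the objective is non-smooth and the optimizer routinely
  reports it at the exact optimum.
- 95 % prediction bounds come from a 1000-sample residual bootstrap
  (refit on resampled residuals, plus one resampled residual per
  prediction for new-measurement noise); the original analysis states
  bounds without a method, and the bootstrap is assumption-light at
  these sample sizes.
- All strict/non-strict comparisons follow one rule: calibration cutoff
  and binarization are strict (`<`), the SRB criterion is strict, so
  boundary frames are non-SRB and the acceptance band is an open
  interval.
- Component labeling is 8-connected; equal-size ties keep the first
  label; all tie-breaks in the tracker are lexicographic.

## The synthetic-data module

`render_mouse_frame()` draws the platform disc and a connected
silhouette — body ellipse, smaller head ellipse, snout taper — oriented
along a known heading, with proportions fixed so the nose-to-centroid
distance exceeds half the body length (the regime the farthest-point
heuristic assumes). Fur is two-tone: a dark base with sparse lighter
diagonal speckle. This is deliberate: the calibration threshold is the
*mean* of sub-cutoff pixels, and against a flat tone the strict
binarization would be degenerate; the speckle puts the mean strictly
above the base tone, the way real fur variance does.

`simulate_trace()` splits a rotation protocol into its unidirectional
epochs; each epoch is a tracking epoch with probability `p_track`, in
which the head velocity equals the stimulus velocity plus Gaussian noise
(sd 4 °/s by default). Outside tracking epochs the head velocity follows
a single zero-mean Gaussian random walk spanning the whole trial
(sd 6 °/s·√s by default) — one continuous process, so idle statistics do
not depend on how tracking epochs slice the trial, and the chance level
estimated from null trials cancels the idle contribution of moving
trials exactly in expectation. The walk scale was fixed in the mixing
regime: a slow walk either camps inside the SRB band for a whole trial
or never enters it, giving a bimodal per-trial chance that real null
behavior does not show.

`simulate_experiment()` assembles the full study: 6 animals × 10 trials
× 12 spatial frequencies (0.0125–0.6 cyc/deg) plus 10 null trials per
animal, at 25 samples/s (a typical webcam rate; the recording rate is
not fixed by the physical build) for 60 s per trial, with per-frequency
tracking probability following a known logistic with $b = 0.40$ cyc/deg.
The analysis pipeline recovers that $b$ within ±0.05 cyc/deg in at least
18 of 20 seeded replicates.

**What the generator does and does not emulate.** It reproduces the
epoch structure, the velocity statistics the SRB detector sees, and a
realistic ratio of stimulus-driven to chance SRB. It does not reproduce
the absolute tracked fractions of real mice (the simulated raw
$T_{track}$ at the optimum is higher than the ~0.25 a real animal
shows), saccadic return movements, posture changes, fur texture,
shadows, or lens distortion. Passing the end-to-end tests therefore
demonstrates that the *analysis* is correct and unbiased under a known
behavioral model — not that any particular real mouse will produce such
traces.

## A worked run

```{r, eval = FALSE}
ex <- simulate_experiment(seed = 1)
report <- analyze_trials(ex$trials, ex$traces, list(n_boot = 200))
report$chance_level     # ~0.23 under the default idle model
report$acuity_cyc_deg   # 0.409 for this seed; simulation truth is 0.40
```

The same run is available from the shell as `omr demo --seed 1`, and the
full pipeline from serialized inputs as
`omr analyze --manifest trials.csv --lambda 9 --out report.json`.

## Problem sizes and runtime

Tests render 400 × 400 px frames (0.5 mm/px, 53 px platform radius,
160 px reachable radius) and simulate trials at 25 samples/s for 60 s;
the end-to-end recovery check runs 20 replicates of the full 6 × 10 × 12
design. These sizes keep the whole validation suite under a minute on a
single core while leaving every statistic at the study's native
dimensions.

## Known limitations

- One animal per frame; no multi-animal or eye tracking.
- The tracker assumes the animal is the largest dark (or light) object
  within reach; a large foreign object would defeat it.
- Spectral stimulation is out of scope: gratings are achromatic relative
  luminance, and the UV sensitivity of the ventral mouse retina is not
  addressed.
- The response-gain of individual tracking movements (tracking velocity
  over stimulus velocity) is not computed.
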