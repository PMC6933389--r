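---
title: "Mapping mirror-symmetric glomerular odor responses: methods and design"
author: "glomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping mirror-symmetric glomerular odor responses: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package addresses

Most odorant-receptor types in the mouse send their sensory axons to two
glomeruli per olfactory bulb — one in the lateral map and one in the
medial map — so the bulb carries two mirror-symmetric layouts of the same
receptor identities. Whether the two maps carry identical or diversified
odor representations is an open question, and answering it requires
imaging both at glomerular resolution. The medial wall is optically
inaccessible from above; it can be exposed by removing the contralateral
bulb and inserting a right-angle prism with a mirror-coated hypotenuse,
which reflects the medial wall up into a standard widefield microscope.
Two geometric consequences drive the analysis: the through-prism image is
dorso-ventrally inverted, and the prism's anterior-posterior placement
varies between preparations, so comparing the two views requires a
vertical flip plus a 1-D anterior-posterior registration. A third optical
fact — the in-prism light path (1.5 mm) exceeds the focal-plane offset
(1 mm) — means the prism top protrudes 0.5 mm above the dorsal surface;
`prismGeometry()` encodes this arithmetic.

`glomap` implements the complete analysis chain for such recordings:
block-wise photobleaching correction, respiration-triggered trial
alignment, trial-averaged dF/F0 activity mapping, and mirror-map
comparison (flip, registration, glomerulus detection, homologous-pair
matching, chemotopy and concentration-response quantification). Because
no public dataset of this kind exists, the package ships a synthetic
movie generator with complete ground truth; every stage is validated
against it.

## Acquisition model

All defaults mirror the targeted recordings: 13 s trials at 125 Hz
(1,625 frames), 128 x 128 pixels over a 1.75 x 1.75 mm^2 field of view
(13.7 um/px). Odorant pulses last 2 s, are command-synchronized to the
end of an inhalation, and follow at least 4 s of prestimulus baseline.
Nominal concentrations follow the 1:5 flow-dilution rule (a 1% liquid
dilution is reported as 0.2%; `nominalConcentration()`).

## The synthetic generator

The generator (`generateMapPair()`, `generateBreathTrace()`,
`scheduleStimulus()`, `renderTrial()`, `simulateTrialSet()`) emulates:

* **Glomerular layouts.** Gaussian blobs (sigma = radius/2, default
  radius 4 px) placed with a minimum separation; the medial layout is
  the dorsal one reflected about the horizontal image axis and shifted
  by a configurable anterior-posterior prism offset, with identical
  tuning — homologous pairs are known by construction. For ordered
  odorant series the tuning is chemotopic: each odorant's preferred
  position advances along a configurable axis, and each odorant has a
  fully tuned glomerulus, so the most-sensitive glomerulus drifts
  monotonically with series order.
* **Respiration.** The piezo waveform is not specified by any
  measurement we emulate, so we chose the simplest shape with
  unambiguous phase landmarks: a positive sine inhalation lobe (duty
  0.35 of the cycle) followed by a negative sine exhalation lobe scaled
  to zero cycle mean. Ground-truth onsets/ends are the zero crossings.
  The 2 Hz default rate is a literature-plausible value for
  urethane-anesthetized mice (the true rate varies; it is exposed in
  `BreathSpec()`). Cycle periods jitter independently (SD 20 ms);
  sensor noise is additive Gaussian at 5% of the waveform amplitude.
* **Calcium dynamics.** A double-exponential GCaMP6f-like kernel
  (rise 0.05 s, decay 0.6 s) triggered at the first inhalation onset
  after the stimulus command. The sampled kernel is normalized so its
  mean over the 1.6 s response window is exactly 1; a glomerulus'
  "amplitude" is therefore *defined* as the windowed dF/F0 it produces,
  which makes downstream recovery tests independent of the kernel
  shape. Amplitudes scale with concentration through a saturating Hill
  factor calibrated to 1 at the 0.2% reference concentration.
* **Photobleaching.** Multiplicative mono-exponential loss,
  `B(t) = 1 - f (1 - exp(-t/tau))`, defaults f = 0.2, tau = 5 s, with
  optional per-quadrant tau scaling to produce the spatial heterogeneity
  that motivates block-wise correction (homogeneous by default).
* **Noise.** Additive Gaussian, default SD 5 counts on a ~1,000-count
  resting field (0.5% per pixel-frame).

What it does **not** model: optical PSF blur, vascular and hemodynamic
artifacts, motion, shot-noise statistics, slow drift other than the
mono-exponential. Passing recovery tests on this generator therefore
demonstrates correctness of the algorithms under their stated
assumptions, not robustness to every artifact of real recordings.

## Photobleaching correction

Frames are tiled into 4 x 4 pixel blocks (1,024 on a 128 x 128 frame).
Per block, the mean trace's first 480 frames (3.8 s, before any
stimulus) and last 5 frames are fitted with
`y(t) = A exp(-t/tau) + C`; exactly 485 samples enter every fit. The few
tail frames pin the plateau and prevent the overcorrection that fitting
the early frames alone produces. Fitting uses variable projection —
A and C solved linearly at fixed tau, tau optimized by a bounded 1-D
search over [0.1 s, 10 x trial length] — which is deterministic and has
no starting-value failures. A fit is accepted only when |A| exceeds
3 standard errors (from the linear subproblem); otherwise the block is
reported non-converged and passed through, which is what happens on
bleach-free data.

Each pixel is corrected by scaling the block curve to the pixel's first
frame, `k = trace[1] / (A + C)`, and subtracting only the decaying
component `k A exp(-t/tau)`. Subtracting the full scaled curve would
null the baseline and make the later dF/F0 division ill-posed, so the
plateau `k C` is deliberately preserved: a pixel that follows the fitted
shape exactly becomes constant at `k C`. Pixels with a non-positive
first frame are skipped and counted in the report. Using the single
first frame as the scaling reference follows the procedure this
implements literally; it is noise-sensitive, and the noise it injects is
one reason corrected amplitudes can deviate slightly from the
uncorrected bleach-free pipeline.

Two systematic effects are worth stating. First, real (and synthetic)
bleaching is multiplicative while the correction is subtractive: after
correction the response term retains a factor `B(t_resp)/(1 - f)`
(about 1.075 at f = 0.2, tau = 5 s, responses near t = 6 s), a ~7%
amplitude inflation that sits within the 10-15% recovery tolerances we
test. Second, correcting an already-corrected movie changes nothing:
the flattened block traces no longer show a significant amplitude, so
all blocks pass through.

Failed corrections manifest as "block noise" — visible discontinuities
at block boundaries. `blockNoiseScore()` quantifies this as the mean
(over frames) ratio of boundary-pair to within-block neighbor-pair mean
absolute differences: about 1 for seamless images, far above 1 for
blocky ones, defined as 1 for degenerate uniform frames. Trials scoring
above 2 (a conservative default; the procedure we emulate excluded <1%
of trials without stating a criterion) are flagged excluded. Excluded
trials are kept on disk and in the manifest, never silently deleted.

## Respiration alignment

Inhalation onsets are upward zero crossings of the smoothed (40 ms
boxcar), rolling-baseline-subtracted (1 s) piezo signal; ends are the
subsequent downward crossings; a 150 ms refractory period suppresses
double triggers. The landmark definition is ours (the source procedure
does not define one), and polarity is configurable because piezo sign
depends on mounting. Detection is invariant to positive rescaling of
the trace. The trial anchor is the first detected onset at or after the
stimulus command onset (command, not odor arrival, which is unknowable
here), and the anchor frame is `round(t * rate)` half away from zero.

## Activity maps

Order of operations: bleach-correct each trial, anchor it, shift frame
axes so anchors coincide, average the raw aligned intensities across the
3-4 kept trials, and only then compute dF/F0. The response image
averages 200 frames (1.6 s) from the anchor inclusive; the baseline
image averages the 125 frames (1.0 s) in the half-open window 1.4-0.4 s
before the anchor (endpoint conventions are ours; the counts match the
stated 200/125 at 125 Hz exactly, and `computeActivityMap()` asserts
its bounds). The map is `(R - B)/B`; pixels whose baseline falls below
1% of the movie's global median are zeroed and flagged rather than
divided. The map is invariant to positive rescaling of the movie.

## Comparing the mirror maps

* **Flip.** `flipMedial()` reverses rows (dorso-ventral axis); it is an
  involution and warns when applied twice.
* **Registration.** The source procedure aligned views manually using
  labeled-glomerulus landmarks and the prism edge; we substitute an
  exhaustive 1-D integer-shift search along the anterior-posterior axis
  maximizing normalized cross-correlation over the overlap (ties break
  toward the smallest |shift|), with the landmark option replaced by a
  configurable search range. Only the A-P translation is modeled;
  rotation is out of scope.
* **Glomerulus detection.** The emulated workflow identified glomeruli
  by eye; our substitute must be deterministic: Gaussian-smooth
  (sigma 1 px) the pixelwise-max composite across odorant maps, take
  8-neighborhood local maxima above `median + 3 x MAD` (the MAD is
  measured on the unsmoothed composite, so smoothing-shrunk noise peaks
  stay below threshold; a small relative floor guards noise-free
  images), process peaks in descending height, suppress peaks within
  one ROI radius of an accepted one (so blobs closer than the radius
  merge, by design), and grow fixed-radius disk ROIs (radius 3 px)
  whose contested pixels go to the higher peak. Fixed disks were chosen
  over watershed for determinism.
* **Matching.** Greedy nearest-neighbor, ascending distance, one-to-one,
  gated at 5 px after applying the registration; each pair carries the
  Pearson correlation of per-odorant amplitude vectors.
* **Chemotopy.** For an ordered series, the centroid of the
  most-responsive glomerulus per odorant; the monotonicity flag is true
  when the anterior-posterior projections are weakly monotone (either
  direction) over odorants with any response; unresponsive odorants are
  marked absent and skipped.
* **Concentration-response.** Counts ROIs at or above a response floor
  per concentration (the floor default, 2 x robust noise SD, is ours;
  no criterion exists in the emulated workflow); amplitude monotonicity
  across concentrations is reported, not enforced.

## Pipeline, formats, reproducibility

`runPipeline()` executes simulate - correct - align - map - compare from
a single YAML-serializable config (`defaultRunConfig()`,
`saveRunConfig()`/`loadRunConfig()` round-trip exactly) and writes a
manifest with per-trial exclusion decisions and MD5 checksums of every
emitted file; a rerun from the same config and seed is bit-identical.
Movies are 16-bit multi-page TIFF (explicitly quantized, since the TIFF
writer truncates), breath traces two-column CSV, ground truth and
registration JSON, maps 32-bit TIFF min-max scaled with a JSON sidecar
recording the scale, plus a PNG render. A thin command-line wrapper
(`inst/scripts/glomap.R`) exposes the same functions for shell use.

## Numerical choices and degenerate inputs

* Frame/time mapping rounds half away from zero (base `round()` rounds
  half to even, which would map 5.1 s at 125 Hz to frame 637 or 638
  platform-invisibly; we fix 638).
* Exponential fitting: tau bounded in [0.1 s, 10 x trial length];
  constant traces yield amplitude 0, offset = trace mean,
  `converged = FALSE`.
* Registration ties break toward the smallest |shift|; an all-zero
  overlap at every shift is an explicit error.
* Uniform movies score 1 in `blockNoiseScore()` (0/0 convention).
* Baseline positivity floor: 1% of the global median intensity.
* Empty ROI sets, empty match tables and absent chemotopy entries are
  returned as empty/flagged values, not errors.

## Problem sizes used in validation

The packaged tests exercise the full spatial and temporal geometry
(128 x 128, 1,625 frames) where the claim depends on it — bleach/tau
recovery uses 20 such trials (5 sets of 4), symmetry recovery a
5-odorant panel with 4 trials per odorant and view — and compact frames
(32 x 32) for index-arithmetic and orchestration checks, sizes we
consider sufficient to pin every contract while keeping the suite
convenient to run.

## Known limitations

* The subtractive correction of multiplicative bleaching leaves the
  ~7% amplitude inflation described above; a divisive variant would
  remove it but would depart from the procedure this package
  re-implements.
* Detection of dim glomeruli (< 2 x map noise SD) is not attempted;
  the response floor and peak threshold are configurable but not
  auto-calibrated.
* Only translation along the anterior-posterior axis is registered;
  rotational misalignment and non-rigid deformation are out of scope.
* The breathing waveform is a stylized model; detector performance on
  real piezo signals (baseline wander, double peaks) is untested.
* Subregion boundaries for regional response counts (e.g. "posterior
  half of the window") must be supplied by the user.
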