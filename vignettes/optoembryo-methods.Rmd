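---
title: "Methods: models, parameters, and validation by parameter recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and validation by parameter recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optoembryo)
```

## The experimental system this package quantifies

In the pre-gastrulation fly embryo, the maternal transcription factor
Bicoid (Bcd) forms an anterior-to-posterior gradient that patterns the gap
genes (*hb*, *gt*, *Kr*, *kni*). Fusing Bcd to LEXY, a blue-light-inducible
nuclear export tag, turns nuclear Bcd concentration into a switchable
input: light drives the fusion protein out of nuclei within tens of
seconds, darkness lets it return within one to two minutes, with about a
4-fold dark:light difference in nuclear concentration. Transcription of a
gap-gene reporter is read out live with the MS2/MCP system, in which
nascent transcripts appear as diffraction-limited nuclear foci in a second
imaging channel.

`optoembryo` implements the downstream quantification: nuclei segmentation
and tracking from the nuclear-reporter channel, single-exponential fitting
of export/import kinetics, MS2 focus detection and ROI counting, the
max-derivative response-time statistic with its control-relative exclusion
rule, and half-maximal expression-boundary estimation from fixed embryos.
Because raw embryo movies for this experimental design are not publicly
deposited, the package ships a synthetic movie generator with exact ground
truth; every stage is validated by parameter recovery against it.

## Forward models in the generator

The experiments only *measure* translocation and transcription dynamics,
so the generator needs forward models. We use the simplest forms
consistent with the fitted equations and the observed dynamics.

**Nuclear translocation.** Within each illumination segment the nuclear
level relaxes exponentially toward the segment's steady state — `n_dark`
in darkness, `n_dark / fold_change` under light — with time constant
`tau_export` (entering light) or `tau_import` (entering darkness). The
trace starts at the steady state of the opening segment and is evaluated
piecewise in closed form, so it is continuous, monotone within segments,
and exact to machine precision. Defaults: `fold_change = 4`,
`tau_export = 30` s, `tau_import = 90` s (the middle of the reported
1–2 min import range), `n_dark = 200` a.u.

**Foci-activation probability.** The probability that a nucleus displays
an active transcription focus follows a *delayed relaxation*: after a
light transition it holds its value for the direction-appropriate onset
delay, then relaxes exponentially toward the plateau of the new
condition. Plateaus are `p_high = 0.9` (permissive) and `p_low = 0.05`
(repressed). The four presets encode the observed stimulus-response
classes:

| preset | sign | delay TF-gain | delay TF-loss | relaxation | notes |
|---|---|---|---|---|---|
| `hb_like` | activated | 1.7 min | 3.3 min | 1 min | fast, symmetric |
| `gt_like` | activated | 5.9 min | 9 min | 30 min (slow phase) | bi-phasic, history-dependent |
| `Kr_like` | repressed | 22 min | none (infinite) | 3 min | delayed inverted |
| `kni_like` | repressed | 2.9 min | 2.9 min | 1.5 min | fast inverted, asymmetry 0.5 |

Two modelling choices deserve explanation:

* **`gt_like` is bi-exponential.** The *gt* observations are bi-phasic: a
  detectable response within ~6–9 min of the shift, yet transcription
  takes tens of minutes to approach the constant-stimulus states. A single
  30-min relaxation cannot reproduce both — its smoothed derivative is a
  nearly flat plateau, so the time of maximum derivative is dominated by
  sampling noise rather than by the onset. `gt_like` therefore completes
  `fast_fraction = 0.25` of each onset's change with a 1-min time constant
  and the remaining 75% with the 30-min constant. The fast component makes
  the onset detectable (as it evidently was in the real data); the slow
  remainder carries the history dependence.
* **Asymmetry.** For `kni_like` the plateau change in the foci-decreasing
  direction is scaled by `1 - amplitude_asymmetry = 0.5`, encoding the
  reported smaller-amplitude decrease upon TF gain; the magnitude is not
  quantified in the source data, so 0.5 is a default exposed in the
  preset.

**Per-nucleus activity sampling.** Nuclei carry static activation
thresholds `u_i ~ U(0,1)`; nucleus *i* is active at frame *t* iff
`p(t) > u_i`. This encodes stable nucleus-to-nucleus heterogeneity —
expression domains recruit nuclei in a consistent order as the rate
changes — and reflects the minute-scale persistence of MS2 foci, which
makes frame-to-frame count noise in good live data small. On top of this,
each active focus is captured per frame with probability
`focus_visible_prob = 0.98`, emulating occasional misses from z-drift and
finite z-sectioning. The alternative (independent per-frame Bernoulli
draws per nucleus) would inject white noise with a standard deviation of
several counts per frame, which is both unrealistic for persistent foci
and incompatible with reliable max-derivative timing for slowly relaxing
genes.

**Rendering.** Channel 1 draws each nucleus as a uniform disk
(radius 2.5 µm) carrying the translocation trace times a per-nucleus
brightness factor (log-normal, CV 5%); an optional transient multiplicative
dip emulates the loss of nuclear signal at envelope breakdown. Channel 2
renders one focus per active nucleus as a 3-D Gaussian (lateral sigma
`psf_sigma = 0.3` µm, axial 1.2 µm) at a fixed offset inside the nucleus;
focus brightness scales with the activation rate (`0.6 + 0.4 p(t)`), so
intensity- and count-based readouts co-vary as they do in real data. Noise
is Poisson shot noise on expected counts plus additive Gaussian read noise
(SD 10 a.u. on a background of 100 a.u.); the literature for this assay
reports no noise model, so this standard camera model is our choice.
Geometry defaults: 150 × 60 µm field at 0.3 µm/pixel, 8 z-slices 1.1 µm
apart, one frame per 0.5 min. Identical `(config, seed)` re-renders
bit-identical movies.

**What the generator does not emulate.** No mitosis or nuclear flow beyond
slow uniform drift, no optical aberrations or depth attenuation, no
bleaching, one transcribing locus per nucleus, and a continuous bright rim
rather than resolved surface nuclei in the fixed-embryo images. Passing
recovery tests therefore demonstrate correctness of the *analysis* under
these idealized conditions, not robustness to every artifact of real data.

## Analysis-stage choices

**Segmentation** (unspecified in the source methods): Gaussian blur
(sigma 1 µm), global Otsu threshold, distance-transform watershed to split
touching nuclei, minimum area 25% of the expected nuclear area. Mean
nuclear intensity is computed over an eroded interior (2–3 px) because
mask-edge pixels are partial-volume mixtures that bias the mean.
**Tracking**: greedy nearest-centroid linking with a one-nuclear-radius
gate; sufficient for a non-dividing NC14 monolayer; track ids are never
reused. **Cycle timing**: the breakdown dip is detected where intensity
falls below 0.5 × the running median (window 5 frames); the first recovery
frame anchors the NC14 clock at 5.6 min; with no dip the result is flagged
unavailable and movie time is used.

**Kinetics fitting.** The printed fitting forms `n0 exp(-t/tau)` and
`n0 (1 - exp(-t/tau))` decay to / rise from zero, but real traces plateau
at the lit steady state. We therefore subtract the post-transition
asymptote — the mean of the final 10% of the segment for export, the first
sample for import — before fitting (configurable via
`subtract_asymptote`). The optimizer is Levenberg-Marquardt least squares
(`minpack.lm`), initialized at `tau0` = time to reach `1 - 1/e` of the
total change. Non-monotone segments raise a degenerate-fit error;
segments shorter than `tau/2` are flagged `low_coverage`. Averaging
precedes fitting in `average_then_fit()`, matching the published
estimator.

**Foci detection.** Difference of Gaussians (small sigma = the PSF width,
large sigma = 3×) followed by a per-frame robust threshold at
median + 5 × MAD·1.4826 of the band-passed frame, components restricted to
2–100 px. The threshold is per frame (a global-per-movie threshold would
couple frames through bleaching or illumination drift); foci are not
linked over time, matching per-frame counting. ROI inclusion is half-open
(lower edge in, upper edge out), ROI default 150 × 40 µm centered in the
field.

**Response time.** Difference from the interpolated control mean, centered
moving average (window 5 frames; shrinking symmetric windows at the
edges), centered finite differences (one-sided at the endpoints), then the
time of maximum signed derivative at or after the shift, earliest on ties.
The caller declares the expected direction (`expected_response_sign()`
derives it from preset and shift direction), since both rising and falling
responses are measured. The composite smoother-plus-difference filter has
support ±3 frames, so the estimator carries a structural lag of about 2–3
frames (1–1.5 min at default sampling) — the reason recovery is asserted
only to within half the smoothing window plus one frame interval.
Exclusion: an embryo is dropped when its maximum absolute difference is
below 25% of the control-mean peak, inclusive at exactly 25%.

**Boundary quantification.** The embryo contour is found by thresholding
against the slide background (border median plus 15% of the dynamic
range — Otsu is wrong here because the bright anterior rim, not the slide,
dominates its bimodality), taking the largest component and filling holes;
an ellipse is fitted by second moments; intensity is averaged over a
surface band (outer 20% of the elliptical radius) into 2% egg-length bins.
Normalization divides by the mean maximum of co-mounted uniform reference
embryos, then min-max; the boundary is the last downward 0.5-crossing,
linearly interpolated, scanning anterior → posterior ("last" targets the
posterior edge of the anterior domain when profiles are non-monotone).
Boundaries are estimated per embryo and then summarized per genotype,
ordered by decreasing mean boundary position (more posterior = higher
construct activity); equal means keep input order and are flagged as ties.

## Problem sizes used in validation

Response-time cohorts use 8 perturbed plus 8 control embryos with 140
nuclei in the counting ROI (one per ~42 µm² of NC14 surface), simulated at
the trace level — these are exactly the ground-truth ROI counts a rendered
movie would produce, at a fraction of the cost. Pixel-level fidelity
(rendered movie → detection equals ground truth, noise-free; ≥ 90% of
frames within 10% at default noise) is validated separately on rendered
movies of 40 nuclei in a 60 × 40 µm field, 4 z-slices, 13–17 frames.
Kinetics recovery averages 100 traces sampled every 2 s for 3 min at 5%
multiplicative noise. Boundary recovery uses 20 noisy replicates per
condition and 5-embryo genotype cohorts at true boundaries 47/45/43% EL.

## Known limitations

* The watershed split of heavily overlapping nuclei is not guaranteed to
  resolve both (counts of 1 or 2 are both accepted and documented).
* The response-time statistic inherits the smoothing filter's lag; all
  recovered times are biased late by up to ~1.5 min at default sampling,
  uniformly across presets.
* The exclusion rule compares against the control-mean *peak*; when the
  control condition itself has very low counts (e.g. constant-light
  controls of an activated gene) the 25% criterion approaches the sampling
  noise floor and non-responders may pass it.
* Cycle-timing detection assumes dips shorter than half the running-median
  window; longer breakdowns require a wider `window`.
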