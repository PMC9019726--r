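# optoembryo

Quantitative analysis of optogenetic transcription-factor perturbations in
live fly embryos — and a synthetic embryo-movie generator that makes every
analysis stage testable by parameter recovery.

## The problem

In the early *Drosophila* embryo the maternal morphogen Bicoid patterns
the gap genes (*hb*, *gt*, *Kr*, *kni*). Tagging Bicoid with LEXY, a
blue-light-switchable nuclear export domain, makes its nuclear
concentration an acutely controllable input (light: export within tens of
seconds; dark: re-import within minutes; ~4-fold dynamic range), while an
MS2/MCP reporter shows nascent transcription of a target gene as bright
nuclear foci. The quantitative questions are: how fast does nuclear
translocation happen, how quickly and in what direction does each gap
gene's transcription respond to a step change in nuclear Bicoid, and where
do expression boundaries sit along the egg under constructs of different
activity?

`optoembryo` provides the full measurement chain for two-channel
time-lapse movies (nuclear reporter + MS2 foci):

* **Synthetic data** — `render_movie()`, `simulate_foci_count_trace()`,
  `render_profile_image()`: two-channel z-stacked movies and fixed-embryo
  images with exact ground truth, driven by an illumination protocol, a
  translocation model, and per-gene response presets (`hb_like`,
  `gt_like`, `Kr_like`, `kni_like`) whose onset delays encode the reported
  response times (1.7/3.3, 5.9/9, 22, 2.9 min).
* **Segmentation & tracking** — `segment_nuclei()` (blur, Otsu,
  distance-transform watershed), `track_nuclei()`, `extract_cycle_timing()`
  (NC14 clock anchored to 5.6 min at nuclear-envelope re-formation).
* **Translocation kinetics** — `fit_export()` / `fit_import()` /
  `average_then_fit()`: single-exponential fits `n0·exp(−t/τ)` and
  `n0·(1−exp(−t/τ))`; the export rate is `1/τ`.
* **Foci counting** — `zmax_project()`, `detect_foci()`
  (difference-of-Gaussians + robust threshold), `count_in_roi()`
  (half-open 150 × 40 µm ROI), `foci_trace()`.
* **Response time** — `difference_curve()`, `smooth_and_differentiate()`,
  `response_time()`: the time after a light shift at which the smoothed
  embryo-minus-control difference changes fastest in the expected
  direction, with `apply_exclusion()` dropping embryos whose maximum
  change is below 25% of the control peak, and `cohort_summary()`
  (mean ± SEM).
* **Expression boundaries** — `extract_profile()`,
  `normalize_to_reference()`, `minmax_normalize()`, `half_max_boundary()`
  (last downward 0.5-crossing, % egg length), `activity_series()`.
* **Orchestration** — `run_pipeline()` / `validate_config()`: simulate →
  analyze → CSV/JSON outputs with a provenance record, deterministic under
  a fixed seed.

## Worked example

```r
library(optoembryo)

# 8 embryos shifted light->dark at t = 5 min (acute nuclear Bcd gain) vs
# 8 constant-light controls, hb-like fast activation preset:
co <- simulate_response_cohort("hb_like", "ltd", seed = 1)
an <- analyze_response_cohort(co$embryos, co$controls,
                              co$shift_time, co$expected_sign)
an$summary$mean_response_time   # 2.5   (min after the shift)
an$summary$n_included           # 8     (none hit the 25% exclusion rule)
```

The cohort mean of 2.5 min recovers the preset's 1.7-min onset delay up to
the documented lag of the smoothing/differencing filter (≤ half the 2.5-min
smoothing window plus one 0.5-min frame).

```r
# export kinetics from a simulated nuclear trace (true tau = 30 s):
m <- translocation_model()                       # 4-fold range, 30 s / 90 s
tm <- seq(2, 5, by = 2/60)                       # 3 min after light-on
tr <- simulate_nuclear_trace(m, shift_protocol(2, 10, "dtl"), tm)
fit_export(tr, (tm - 2) * 60)
#> export kinetics: tau = 29.62 s (rate 0.0338 /s), n0 = 147.68, ...

# expression boundary of a synthetic fixed embryo (true midpoint 45% EL):
img <- render_profile_image(45, sharpness = 3)
half_max_boundary(minmax_normalize(extract_profile(img$embryo)))$boundary_position
#> 44.86
```

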