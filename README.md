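# sparkletr

Quantal analysis of optical single-channel Ca²⁺ signals ("sparklets") and
pressure-myography vessel reactivity, in R.

## The problem

TRPV4 channels in the native endothelium of small arteries produce
*sparklets*: localized, step-like Ca²⁺-influx events recorded as fractional
fluorescence (F/F₀) at fixed sites in Fluo-4–loaded *en face* preparations,
imaged at 30 frames/s. Because up to four channels gate at one site, a
sparklet trace visits discrete, equally spaced *quantal levels*; the
per-open-channel increment for Fluo-4 in pulmonary arteries is
ΔF/F₀ ≈ 0.29. Sparklet activity per site is summarised by

```
NP_O = (T_level1 + 2·T_level2 + 3·T_level3 + 4·T_level4) / T_total
```

where `T_level i` is the dwell time at quantal level *i* and `T_total` the
recording duration — i.e. the time-averaged number of open channels
(N channels per site × open probability P_O). This package implements the
full analysis chain that produces NP_O and its companions (sparklet sites
per cell, event areas, vessel reactivity percentages, wall shear stress),
plus a ground-truth synthetic-data generator so every stage is verifiable
without experimental recordings:

- **gating simulator** — continuous-time two-state Markov gating of N
  independent channels per site, rendered to F/F₀ traces or multi-page
  TIFF image stacks with known truth (`simulate_open_counts`,
  `render_trace`, `render_movie`);
- **trace/movie preprocessing** — ImageJ-style Kalman stack filter
  (gain 0.8, noise variance 0.05), zero-phase Gaussian 4 Hz display filter,
  5×5-pixel ROI F/F₀ extraction at the sparklet peak, event detection under
  the 5-steady-baseline-/5-steady-peak-point inclusion rule, trapezoidal
  area under the curve (`kalman_stack_filter`, `gaussian_lowpass`,
  `extract_ff0`, `place_roi_at_peak`, `detect_events`, `event_auc`);
- **quantal analysis** — all-points amplitude histograms, equally spaced
  multi-Gaussian mixture fits (component count by BIC), nearest-level
  idealization with half-amplitude hysteresis, dwell times, NP_O and sites
  per cell (`build_histogram`, `fit_multi_gaussian`, `idealize`,
  `compute_npo`, `sites_per_cell`, `analyze_site`);
- **vessel reactivity** — percent constriction
  `100·(d_before − d_after)/d_before`, percent dilation
  `100·(d_dilated − d_basal)/(d_ca_free − d_basal)`, myogenic tone, and
  Poiseuille wall shear stress `τ = 4μQ̇/(πr³)` in dyn/cm²
  (`percent_constriction`, `percent_dilation`, `myogenic_tone`,
  `shear_stress`, `vessel_table`);
- **pipeline & CLI** — JSON run configs, deterministic seeded result
  bundles, CSV/TIFF I/O, and a `sparklet` command-line tool
  (`run_pipeline`, `sparklet_cli`, `inst/cli/sparklet`).

## Worked example

Simulate one sparklet site (N = 4 channels, k_open = 4.4/s,
k_close = 25/s ⇒ P_O ≈ 0.15, true NP_O ≈ 0.60) for 120 s at 30 frames/s,
render it with the Fluo-4 quantal amplitude 0.29 and noise SD 0.05, and
recover NP_O and the quantal spacing:

```r
library(sparkletr)

gp    <- gating_params(n_channels = 4, k_open = 4.4, k_close = 25,
                       duration = 120, frame_rate = 30, seed = 17)
truth <- simulate_open_counts(gp)
trace <- render_trace(truth, render_params(quantal_amplitude = 0.29,
                                           noise_sd = 0.05), seed = 17)
site  <- analyze_site(trace)
site
#> <sparklet_site> NP_O=0.5789  q_hat=0.2906  levels=2  T=120.0 s
truth$true_npo
#> [1] 0.5986395
mean(truth$open_counts)       # what this recording actually contained
#> [1] 0.5777778
```

The recovered NP_O (0.579) tracks the realised occupancy of this particular
recording (0.578); both scatter around the analytic N·P_O (0.599). The
fitted inter-level spacing `q_hat` (0.291) recovers the generator's 0.29,
and `levels = 2` says the histogram fit resolved two occupied open levels
above baseline in this trace. Vessel arithmetic works on plain numbers:

```r
percent_constriction(51, 38)                 # 25.49 % constriction
percent_dilation(38, 48, 53)                 # 66.67 % of passive dilation
shear_stress(flow_record(0.007, 1.47, 25,
  units = c(viscosity = "poise", flow = "uL_min", radius = "um")))
#> [1] 13.98    # dyn/cm^2, top of the physiological 4-14 range
```

## Command line

```sh
inst/cli/sparklet simulate --config config.json --seed 1 --out sim/
inst/cli/sparklet quantal  --in sim/site1.csv --out site1.json
inst/cli/sparklet run      --config config.json --out bundle.json
```

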