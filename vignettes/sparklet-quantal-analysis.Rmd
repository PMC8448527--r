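---
title: "Quantal analysis of Ca2+ sparklets: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantal analysis of Ca2+ sparklets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparkletr)
```

# The measurement model

A sparklet site holds $N$ identical channels (at most 4 resolvable), each an
independent two-state Markov chain with opening rate $k_\mathrm{open}$ and
closing rate $k_\mathrm{close}$ (both s$^{-1}$). The stationary open
probability of one channel is
$P_O = k_\mathrm{open} / (k_\mathrm{open} + k_\mathrm{close})$, dwell times
in each state are exponential, and the site occupancy — the number of
simultaneously open channels — is binomial$(N, P_O)$ at stationarity.

Fluorescence reports occupancy linearly: with $c(t)$ open channels,

$$ F/F_0(t) = \bigl(1 + q\,c(t)\bigr)\,e^{-\beta t} + \varepsilon(t),
   \qquad \varepsilon(t) \sim \mathcal{N}(0, \sigma_n^2), $$

where $q$ is the quantal amplitude (the per-open-channel $\Delta F/F_0$
increment, 0.29 for Fluo-4 in pulmonary arteries), $\beta$ a bleach rate
(default 0), and $\sigma_n$ additive Gaussian acquisition noise in $F/F_0$
units. Sparklet activity per site is

$$ NP_O = \frac{T_1 + 2T_2 + 3T_3 + 4T_4}{T_\mathrm{total}}, $$

with $T_i$ the dwell time at quantal level $i$; algebraically this equals
the time-average of the level sequence, an identity the test suite asserts
to $10^{-12}$.

# The estimation chain

1. **All-points histogram** (`build_histogram`). Every frame's $F/F_0$
   value is binned (left-closed/right-open, last bin closed). The default
   bin width is Freedman–Diaconis; it is overridable because no binning
   rule was prescribed for the original analysis.
2. **Multi-Gaussian mixture fit** (`fit_multi_gaussian`). The histogram is
   fit by weighted least squares (Poisson weights $1/\max(c_k, 1)$) with

   $$ f(x) = \sum_{i=0}^{K} \frac{a_i}{\sqrt{2\pi}\,\sigma_i}
      \exp\!\left(-\frac{(x - \mu_i)^2}{2\sigma_i^2}\right), $$

   component 0 being the shared baseline. Under the default *quantal*
   (equal-spacing) constraint $\mu_i = \mu_0 + i\,\hat q$; $K \le 4$ is
   selected by BIC.
3. **Idealization** (`idealize`). Each frame is assigned the level whose
   ideal amplitude $\mu_0 + i\hat q$ is nearest. With hysteresis (default)
   a transition out of the current level requires *strictly* crossing the
   midpoint between adjacent level means, so a frame exactly at a midpoint
   stays put; on noise-free data this reduces exactly to the brute-force
   nearest-level classifier, which the tests exploit as an oracle. No
   minimum dwell is imposed by default (`min_dwell_frames` exposes one).
4. **NP_O and sites per cell** (`compute_npo`, `sites_per_cell`), plus
   event detection and trapezoidal area under $(F/F_0 - 1)$ over seconds
   for per-event measures.

## Numerical choices in the mixture fit

The histogram fit is the one genuinely ill-posed stage, and four choices
stabilise it. They are all package decisions, made once and documented
here:

- **Baseline anchor.** The baseline is the *lowest-amplitude* accepted
  histogram mode, not the tallest: at high activity (e.g. $N = 4$,
  $P_O = 0.3$) level 1 out-counts level 0, and anchoring at the tallest
  peak would shift every level by one quantum.
- **Robust peak detection.** Modes are local maxima of the
  kernel-smoothed histogram, kept greedily by height only if at least
  $3\sigma^\ast$ from every stronger mode and at least 2.5% of the main
  peak high, where $\sigma^\ast$ is the main peak's SD estimated from its
  interpolated half width (deconvolved for the smoothing kernel). Noise
  lumps in the flanks of the dominant baseline peak sit within
  $\sim\!3\sigma$ and are suppressed; genuine neighbouring levels sit at
  $q \approx 6\sigma$ and survive.
- **Resolvability floor.** The fitted spacing is constrained to
  $\hat q \ge \max(2\,\mathrm{bins},\ 1.5\sigma^\ast)$: adjacent levels
  closer than that are inside one noise peak and not identifiable, and an
  unconstrained fit will happily "explain" the baseline peak by splitting
  it into sub-noise-spaced components.
- **Shared component SD** (`share_sd = TRUE`). With additive acquisition
  noise the level SDs are nearly equal; a per-component SD (available via
  `share_sd = FALSE`) adds freedom that mostly buys degenerate solutions.
  The fit is attempted from two initialisations — the lowest accepted mode
  with mode-spacing seeding, and the global peak with $q = 0.29$ seeding —
  and the better optimum is kept. After model selection, leading/trailing
  components carrying $<1\%$ of the mass are dropped (a near-empty leading
  component means the baseline anchored one level low).

# Preprocessing contracts

- **Kalman stack filter** (`kalman_stack_filter`). The original plug-in is
  specified only by its parameters (gain 0.8, noise variance 0.05), so the
  package fixes a testable contract: per pixel,
  $E_t = G_t E_{t-1} + (1 - G_t) O_t$ with $E_0 = O_0$; in adaptive mode
  $G_t$ follows the scalar Kalman recursion for a static state
  ($K_t = P_{t-1}/(P_{t-1} + R)$, $P_t = (1 - K_t) P_{t-1}$, $P_0$ chosen
  so the first applied gain equals 0.8), and a fixed-gain mode gives the
  closed-form step response $1 - G^k$ used by the tests.
- **Gaussian display filter** (`gaussian_lowpass`). Zero-phase, kernel SD
  $\sqrt{\ln 2} / (2\pi f_c)$ so the amplitude response at the corner
  frequency (default 4 Hz) is $1/\sqrt{2}$ (−3 dB). It exists for display
  only: quantal analysis runs on raw (default) or Kalman-filtered data,
  because temporal smoothing biases dwell times. Which input NP_O uses is
  a logged configuration choice (`use_kalman`), defaulting to raw.
- **ROI extraction** (`extract_ff0`, `place_roi_at_peak`). A 5 × 5 pixel
  box (≈1.7 µm² at 0.26 µm/px) centred on the peak-amplitude pixel; ties
  break by earliest frame, then smallest row, then column. $F_0$ is the
  mean box intensity over an explicit baseline window or, automatically,
  the mean of the lowest decile of frame means (the original baseline
  window is not documented; the lowest decile is robust to activity).
- **Event inclusion** (`detect_events`). An event needs ≥5 consecutive
  steady pre-event baseline points and ≥5 steady peak points. "Steady" is
  undefined in the source analysis; here it means within a tolerance
  defaulting to twice a robust noise SD,
  $2\,\mathrm{MAD}(\Delta F)/\sqrt{2}$ — scale-free and overridable.

# The synthetic world

The generator emulates what the recordings are described to be: 30
frames/s acquisition; up to 4 channels per site; quantal amplitude 0.29;
~15 cells per ~110 × 110 µm field; sites as 2-D Gaussian footprints
(SD 0.8 µm — sparklet microdomains spread over a micron or two, wider than
the optical PSF); 0.26 µm pixels so a 5 × 5 box covers ≈1.7 µm². Values
the source does not state, chosen once:

- **noise_sd = 0.05** $F/F_0$: a free parameter (recording SNR is not
  reported), exposed everywhere, giving $q/\sigma_n \approx 6$ — clearly
  separable levels that still misclassify occasional frames.
- **k_close = 25 s⁻¹** (mean open time 40 ms) for recovery experiments:
  optical sparklet events last tens of milliseconds; at 30 frames/s this
  gives events of ~1–2 frames, the regime the frame-start sampling
  convention is designed for.
- **baseline_f0 = 1000** camera units for movies (16-bit headroom).

Per-frame levels are the occupancy at the frame's *start* time (not
time-averaged within the frame), matching threshold idealization
downstream; the flag is recorded in the generator parameters. Channels are
independent and identical (no cooperativity); bleaching defaults to off
and, when on, scales total fluorescence before noise; noise is additive
Gaussian in $F/F_0$ units, not Poisson photon noise — the synthetic world
matches the *acquisition-noise-variance* framing of the Kalman filter, not
a camera-physics model.

A green test on this world therefore establishes that the estimators
recover known gating from data generated under the stated measurement
model. It does not establish robustness to photon (multiplicative) noise,
motion, bleaching-induced baseline drift, overlapping sites, or
store-release contamination — none of which the generator produces.

# Vessel computations

Diameter ratios are unit-free: percent constriction
$100\,(d_\mathrm{before} - d_\mathrm{after})/d_\mathrm{before}$ (negative
values are flagged as net dilation, not errors) and percent dilation
$100\,(d_\mathrm{dilated} - d_\mathrm{basal}) / (d_{\mathrm{Ca\,free}} -
d_\mathrm{basal})$, anchored at 0 (no response) and 100 (full passive
dilation). The *myogenic tone* formula is not printed in the source
methods; this package defines it against the passive (Ca²⁺-free) diameter
at the same pressure, $100\,(d_{\mathrm{Ca\,free}} -
d_\mathrm{active})/d_{\mathrm{Ca\,free}}$, since the passive diameter is
what the protocol measures last; `reference = "active"` switches the
denominator for comparison with analyses normalising the other way.
Wall shear stress uses CGS throughout, $\tau = 4\mu\dot Q/(\pi r^3)$
dyn/cm², with explicit unit hints (cP → poise, µL/min → cm³/s, µm → cm)
required — the constructor refuses to guess.

# Determinism and I/O

All randomness flows from one integer seed through a documented
multiply-add splitting rule (`derive_seed`), so identical configurations
produce byte-identical result bundles (asserted in the tests). Traces
travel as CSV (`time_s`, `f_over_f0`) with JSON truth sidecars; movies as
uncompressed 16-bit multi-page TIFF with ImageJ-style frame-interval and
pixel-size calibration. The TIFF layer implements only that baseline
subset (the deployment environment has no R TIFF package); it was
validated against an independent TIFF implementation during development,
and reading fails loudly when calibration is absent from both file and
arguments rather than guessing.

# Known limitations

- Site discovery across a field is input-driven (a list of ROIs or
  simulated site positions); automatic spatial segmentation of sparklet
  sites is out of scope.
- The mixture fit needs the baseline level to be *occupied*; a recording
  that never visits the closed state will anchor one level high (the
  per-site audit bundle retains the histogram and fit diagnostics for
  exactly this kind of inspection).
- Idealization assumes the quantal hypothesis (equal spacing, shared
  baseline). Sub-conductance states or drifting baselines violate it.
- NP_O at very low activity ($NP_O \lesssim 0.05$ over 120 s) carries
  ~10% relative sampling error from finite recording length alone; longer
  recordings, not algorithm changes, are the remedy.
- Group statistics (t-tests, ANOVA) on NP_O tables are deliberately not
  reimplemented; standard tools apply downstream.
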