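make_movie <- function(data, frame_rate = 30, pixel_size = 0.26) {
  movie_stack(data, frame_rate = frame_rate, pixel_size = pixel_size)
}

test_that("Kalman filter leaves constant input unchanged and is variance-contracting", {
  d <- array(7, dim = c(20, 4, 4))
  mv <- make_movie(d)
  expect_equal(kalman_stack_filter(mv, kalman_params())$data, d)
  expect_equal(kalman_stack_filter(mv, kalman_params(adaptive = FALSE))$data, d)

  set.seed(1)
  noisy <- array(rnorm(50 * 3 * 3), dim = c(50, 3, 3))
  out <- kalman_stack_filter(make_movie(noisy), kalman_params())$data
  for (i in 1:3) for (j in 1:3)
    expect_lt(var(out[, i, j]), var(noisy[, i, j]))
})

test_that("fixed gain 0 passes observations through; gain 0.8 follows 1 - 0.8^k", {
  step <- c(rep(0, 10), rep(1, 15))
  tr <- fluorescence_trace(step + 1, frame_rate = 30)  # constructor wants finite; offset irrelevant

  out0 <- kalman_filter_trace(tr, kalman_params(gain = 0, adaptive = FALSE))
  expect_equal(out0$values[-1], (step + 1)[-1])

  out <- kalman_filter_trace(tr, kalman_params(gain = 0.8, adaptive = FALSE))
  k <- 1:15
  expect_equal(out$values[10 + k] - 1, 1 - 0.8^k, tolerance = 1e-12)

  mv1 <- make_movie(array(1, dim = c(1, 2, 2)))
  expect_warning(kalman_stack_filter(mv1), "single-frame")
})

test_that("Gaussian low-pass: constant invariance, -3 dB at cutoff, variance contraction", {
  const <- fluorescence_trace(rep(2, 100), frame_rate = 30)
  expect_equal(gaussian_lowpass(const, 4)$values, rep(2, 100))

  fr <- 200; f_c <- 4
  t <- (0:(20 * fr - 1)) / fr
  sine <- fluorescence_trace(1 + sin(2 * pi * f_c * t), frame_rate = fr)
  out <- gaussian_lowpass(sine, f_c)
  ratio <- sine_amplitude(out$values - 1, f_c, fr) /
    sine_amplitude(sine$values - 1, f_c, fr)
  expect_equal(ratio, 1 / sqrt(2), tolerance = 0.02)

  set.seed(2)
  wn <- fluorescence_trace(1 + rnorm(2000, 0, 0.1), frame_rate = 30)
  expect_lt(var(gaussian_lowpass(wn, 4)$values), var(wn$values))

  expect_error(gaussian_lowpass(const, 15), "Nyquist|frame_rate")
})

test_that("extract_ff0 normalises by F0 and rejects non-positive baselines", {
  d <- array(100, dim = c(12, 9, 9))
  mv <- make_movie(d)
  roi <- roi_spec(4, 4)
  tr <- extract_ff0(mv, roi)
  expect_equal(tr$values, rep(1, 12))

  # explicit baseline window and out-of-range rejection
  expect_equal(extract_ff0(mv, roi, baseline = 1:5)$values, rep(1, 12))
  expect_error(extract_ff0(mv, roi, baseline = 0:3), "range")

  dz <- d; dz[3, , ] <- 0
  expect_error(extract_ff0(make_movie(dz), roi, baseline = 3), "F0")
  expect_error(extract_ff0(mv, roi_spec(0, 0)), "outside")
})

test_that("extract_ff0 recovers q times the PSF box-integration factor exactly", {
  gp <- gating_params(2, 4, 8, duration = 4, frame_rate = 30, seed = 9)
  truth <- simulate_open_counts(gp)
  stopifnot(any(truth$open_counts > 0))
  rp <- render_params(noise_sd = 0, psf_sigma = 0.8, pixel_size = 0.26)
  pos <- c(4.03, 3.97)
  mv <- render_movie(list(list(position = pos, truth = truth)),
                     rp, field_size = c(8, 8), seed = 1)
  roi <- place_roi_at_peak(mv)
  tr <- extract_ff0(mv, roi, baseline = which(truth$open_counts == 0))

  fac <- psf_box_factor(pos, 0.26, 0.8)
  expected <- 1 + 0.29 * fac * truth$open_counts
  expect_equal(tr$values, expected, tolerance = 1e-6)
})

test_that("place_roi_at_peak finds the brightest pixel with deterministic tie-breaks", {
  d <- array(10, dim = c(9, 24, 30))
  d[5, 11, 13] <- 50                       # 0-based (10, 12)
  roi <- place_roi_at_peak(make_movie(d))
  expect_equal(c(roi$center_row, roi$center_col), c(10L, 12L))

  # two equal maxima at frames 3 and 7: earliest frame wins
  d2 <- array(10, dim = c(9, 24, 30))
  d2[3, 5, 21] <- 50
  d2[7, 15, 4] <- 50
  roi2 <- place_roi_at_peak(make_movie(d2))
  expect_equal(c(roi2$center_row, roi2$center_col), c(4L, 20L))

  # centre clamped so the 5x5 box stays inside the frame
  d3 <- array(10, dim = c(2, 8, 8)); d3[1, 1, 1] <- 99
  roi3 <- place_roi_at_peak(make_movie(d3))
  expect_equal(c(roi3$center_row, roi3$center_col), c(2L, 2L))
})

test_that("detect_events applies the 5-point baseline / 5-point peak rule", {
  fr <- 30
  flat <- fluorescence_trace(rep(1, 60), frame_rate = fr)
  expect_equal(nrow(detect_events(flat)), 0L)

  # rectangular pulse of 10 frames after 20 flat frames: exactly one event
  pulse <- c(rep(1, 20), rep(1.3, 10), rep(1, 30))
  tr <- fluorescence_trace(pulse, frame_rate = fr)
  ev <- detect_events(tr)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start_frame, 21L)
  expect_equal(ev$end_frame, 30L)
  expect_equal(ev$peak_amplitude, 0.3)

  # 3-frame pulse < min_peak_pts: excluded by the inclusion rule
  short <- fluorescence_trace(c(rep(1, 20), rep(1.3, 3), rep(1, 30)),
                              frame_rate = fr)
  expect_equal(nrow(detect_events(short)), 0L)

  # unstable pre-event baseline: excluded
  wob <- pulse
  wob[16:20] <- c(1, 1.2, 0.8, 1.2, 1)
  expect_equal(nrow(detect_events(fluorescence_trace(wob, frame_rate = fr),
                                  baseline_tolerance = 0.05)), 0L)

  expect_error(detect_events(fluorescence_trace(rep(1, 8), frame_rate = fr)),
               "too short")
})

test_that("detect_events is translation-invariant", {
  fr <- 30
  base <- c(rep(1, 20), 1.1, 1.25, rep(1.3, 8), 1.15, rep(1, 40))
  ev1 <- detect_events(fluorescence_trace(base, frame_rate = fr),
                       baseline_tolerance = 0.05)
  shift <- 17L
  ev2 <- detect_events(fluorescence_trace(c(rep(1, shift), base), frame_rate = fr),
                       baseline_tolerance = 0.05)
  expect_equal(nrow(ev1), 1L)
  expect_equal(ev2$start_frame, ev1$start_frame + shift)
  expect_equal(ev2$end_frame, ev1$end_frame + shift)
  expect_equal(ev2$peak_frame, ev1$peak_frame + shift)
  expect_equal(ev2$auc, ev1$auc)
})

test_that("event_auc matches brute-force trapezoid oracles and is additive", {
  fr <- 30
  # zero-amplitude event
  flat <- fluorescence_trace(rep(1, 40), frame_rate = fr)
  expect_equal(event_auc(flat, 5, 20), 0)
  expect_equal(event_auc(flat, 7, 7), 0)   # degenerate start == end

  # rectangular pulse, amplitude 0.29, 31 frames at 30 fps
  rect <- c(rep(1, 10), rep(1.29, 31), rep(1, 10))
  tr <- fluorescence_trace(rect, frame_rate = fr)
  expect_equal(event_auc(tr, 10, 42),
               trapz_oracle(rect, fr, 10, 42))
  # interior plateau alone: 0.29 * (30 frames) / 30 fps = 0.29 * 1 s
  expect_equal(event_auc(tr, 11, 41), 0.29 * 1.0)

  # triangular pulse 0 -> 0.3 -> 0 over 10 frames each way
  tri <- 1 + c(rep(0, 5), seq(0, 0.3, length.out = 11),
               rev(seq(0, 0.3, length.out = 11))[-1], rep(0, 5))
  trt <- fluorescence_trace(tri, frame_rate = fr)
  expect_equal(event_auc(trt, 1, length(tri)),
               trapz_oracle(tri, fr, 1, length(tri)))

  # additivity at any interior split point
  for (mid in c(12, 20, 27))
    expect_equal(event_auc(trt, 5, mid) + event_auc(trt, mid, 28),
                 event_auc(trt, 5, 28), tolerance = 1e-12)

  expect_error(event_auc(tr, 0, 10), "bounds")
  expect_error(event_auc(tr, 40, 99), "bounds")
})
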