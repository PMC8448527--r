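test_that("build_histogram bins deterministically and conserves counts", {
  tr <- fluorescence_trace(c(1, 1, 1), frame_rate = 30)
  expect_warning(h <- build_histogram(tr, bin_width = 0.1), "fewer than 10")
  expect_equal(sum(h$counts), 3L)
  expect_equal(sum(h$counts > 0), 1L)

  set.seed(4)
  tr2 <- fluorescence_trace(1 + abs(rnorm(500, 0, 0.1)), frame_rate = 30)
  h2 <- build_histogram(tr2)
  expect_equal(sum(h2$counts), 500L)
  expect_true(all(diff(h2$bin_edges) > 0))

  # left-closed / right-open with closed last bin: max lands in last bin
  tr3 <- fluorescence_trace(c(0, 0.49, 1, 1, 1), frame_rate = 30)
  h3 <- suppressWarnings(build_histogram(tr3, bin_width = 0.5))
  expect_equal(h3$counts, c(2L, 3L))
})

test_that("two-level synthetic trace shows modes separated by q", {
  tr <- make_synth_trace(5, n_channels = 1, p_o = 0.4, noise_sd = 0.02,
                         duration = 60)
  h <- build_histogram(tr)
  centers <- (h$bin_edges[-1] + h$bin_edges[-length(h$bin_edges)]) / 2
  # mode-finding oracle: top bin below and above the midpoint 1 + q/2
  lo <- centers < 1 + 0.29 / 2
  m0 <- centers[lo][which.max(h$counts[lo])]
  m1 <- centers[!lo][which.max(h$counts[!lo])]
  expect_lt(abs((m1 - m0) - 0.29), diff(h$bin_edges[1:2]))
})

test_that("fit_multi_gaussian recovers a single Gaussian as baseline-only", {
  set.seed(7)
  n <- 5000; mu <- 1.02; s <- 0.04
  tr <- fluorescence_trace(rnorm(n, mu, s), frame_rate = 30)
  m <- fit_multi_gaussian(build_histogram(tr))
  expect_equal(m$n_components, 0L)
  expect_true(is.na(m$quantal_amplitude))
  expect_lt(abs(m$baseline_mean - mu), 2 * s / sqrt(n))
})

test_that("fit_multi_gaussian recovers q = 0.29 from two equal Gaussians", {
  set.seed(8)
  x <- c(rnorm(10000, 1.00, 0.03), rnorm(10000, 1.29, 0.03))
  tr <- fluorescence_trace(x, frame_rate = 30)
  m <- fit_multi_gaussian(build_histogram(tr))
  expect_equal(m$n_components, 1L)
  expect_equal(m$quantal_amplitude, 0.29, tolerance = 0.01 / 0.29)
  # mixture areas approximately total probability mass
  expect_equal(sum(m$areas), 1, tolerance = 0.05)
})

test_that("unconstrained fit agrees with equal-spacing fit on quantal data", {
  tr <- make_synth_trace(12, p_o = 0.2, noise_sd = 0.03)
  h <- build_histogram(tr)
  m_eq <- fit_multi_gaussian(h, equal_spacing = TRUE)
  m_un <- fit_multi_gaussian(h, equal_spacing = FALSE)
  expect_equal(m_un$quantal_amplitude, m_eq$quantal_amplitude,
               tolerance = 0.05)
  expect_true(all(diff(m_un$means) > 0))
})

test_that("idealize matches truth exactly on noise-free renders", {
  gp <- gating_params(4, 3, 7, duration = 20, seed = 31)
  truth <- simulate_open_counts(gp)
  tr <- render_trace(truth, render_params(noise_sd = 0), seed = 1)
  model <- quantal_model_global(1, 0.29)
  id <- idealize(tr, model)
  expect_identical(id$levels, truth$open_counts)
  expect_equal(sum(id$dwell_times), id$t_total)

  # oracle equivalence: brute-force nearest-level classifier, both modes
  oracle <- nearest_level_oracle(tr$values, 1, 0.29)
  expect_identical(id$levels, oracle)
  expect_identical(idealize(tr, model, hysteresis = FALSE)$levels, oracle)
})

test_that("hysteresis holds the current level at exact midpoints", {
  # q = 0.25 keeps the 0/1 midpoint (1.125) exactly representable in binary
  model <- quantal_model_global(1, 0.25)
  # previous level 0, frame exactly at the 0/1 midpoint: stays 0
  tr <- fluorescence_trace(c(1, 1.125, 1), frame_rate = 30)
  expect_equal(idealize(tr, model)$levels, c(0L, 0L, 0L))
  # previous level 1: the same midpoint stays 1
  tr2 <- fluorescence_trace(c(1.25, 1.125, 1.25), frame_rate = 30)
  expect_equal(idealize(tr2, model)$levels, c(1L, 1L, 1L))
  # without hysteresis the tie resolves to the lower level
  expect_equal(idealize(tr2, model, hysteresis = FALSE)$levels[2], 0L)
  # q must be defined and positive
  flat_fit <- suppressWarnings(
    fit_multi_gaussian(suppressWarnings(
      build_histogram(fluorescence_trace(rep(1, 20), frame_rate = 30)))))
  expect_error(idealize(tr, flat_fit), "quantal amplitude")
})

test_that("noisy idealization agrees with truth on >= 95% of frames", {
  agree <- vapply(1:20, function(s) {
    tr <- make_synth_trace(s, noise_sd = 0.29 / 6, duration = 30)
    id <- idealize(tr, quantal_model_global(1, 0.29))
    mean(id$levels == tr$truth$open_counts)
  }, numeric(1))
  expect_gte(mean(agree), 0.95)
})

test_that("compute_npo is the dwell-time formula and the level mean", {
  # all level 0
  tr0 <- fluorescence_trace(rep(1, 90), frame_rate = 30)
  id0 <- idealize(tr0, quantal_model_global(1, 0.29))
  expect_equal(compute_npo(id0), 0)

  # direct substitution: T1=2, T2=1, T3=0.5, T4=0, T_total=10 -> 0.55
  id <- structure(list(levels = NULL,
                       dwell_times = c(level0 = 6.5, level1 = 2, level2 = 1,
                                       level3 = 0.5, level4 = 0),
                       t_total = 10, frame_rate = 30),
                  class = "idealized_trace")
  expect_equal(compute_npo(id), 0.55)

  # random level sequences: NP_O == mean(levels) to 1e-12
  set.seed(9)
  for (i in 1:10) {
    lv <- sample(0:4, 300, replace = TRUE)
    tr <- fluorescence_trace(1 + 0.29 * lv, frame_rate = 30)
    idr <- idealize(tr, quantal_model_global(1, 0.29))
    expect_identical(idr$levels, as.integer(lv))
    expect_equal(compute_npo(idr), mean(lv), tolerance = 1e-12)
  }
})

test_that("sites_per_cell is a guarded ratio", {
  expect_equal(sites_per_cell(3, 15), 0.2)
  expect_equal(sites_per_cell(0, 15), 0)
  expect_error(sites_per_cell(3, 0), "n_cells")
  expect_error(sites_per_cell(-1, 5), "n_sites")
})

test_that("analyze_site composes the pipeline and handles flat traces", {
  flat <- fluorescence_trace(rep(1, 400), frame_rate = 30)
  site <- suppressWarnings(analyze_site(flat))
  expect_equal(site$npo, 0)
  expect_equal(site$n_levels, 0L)
  expect_true(is.na(site$q_hat))

  # noise-free single channel with P_O 0.25 by construction of dwell times
  lv <- rep(c(0L, 1L, 0L, 0L), 225)   # exactly 25% open
  tr <- fluorescence_trace(1 + 0.29 * lv, frame_rate = 30)
  site2 <- analyze_site(tr, site_config(quantal_mode = "global"))
  expect_equal(site2$npo, 0.25)

  # audit intermediates retained; deterministic given config
  tr3 <- make_synth_trace(77, duration = 60)
  s1 <- analyze_site(tr3)
  s2 <- analyze_site(tr3)
  expect_identical(s1$npo, s2$npo)
  expect_s3_class(s1$histogram, "all_points_histogram")
  expect_s3_class(s1$model, "quantal_model")
  expect_s3_class(s1$ideal, "idealized_trace")
})

test_that("analyze_site errors carry the failing stage name", {
  tr <- fluorescence_trace(c(1, 1.2, 1.4), frame_rate = 30)
  cfgbad <- site_config(bin_width = -1)
  expect_error(suppressWarnings(analyze_site(tr, cfgbad)), "\\[histogram\\]")
})

test_that("NP_O recovery across the (N, P_O) grid and q within tolerance", {
  # reduced grid corners here (full grid is in test-acceptance.R)
  for (cell in list(c(1, 0.3), c(4, 0.1))) {
    errs <- vapply(1:5, function(s) {
      tr <- make_synth_trace(s * 13, n_channels = cell[1], p_o = cell[2],
                             noise_sd = 0.29 / 6, duration = 120)
      site <- analyze_site(tr)
      abs(site$npo - cell[1] * cell[2]) / (cell[1] * cell[2])
    }, numeric(1))
    expect_lte(median(errs), 0.10)
  }
})

test_that("recovered NP_O is monotone in k_open (seed-averaged)", {
  npo_at <- function(k_open) {
    mean(vapply(1:6, function(s) {
      gp <- gating_params(4, k_open, 25, 60, seed = s * 7)
      tr <- render_trace(simulate_open_counts(gp),
                         render_params(noise_sd = 0.29 / 6), seed = s)
      analyze_site(tr, site_config(quantal_mode = "global"))$npo
    }, numeric(1)))
  }
  vals <- vapply(c(1, 4, 12), npo_at, numeric(1))
  expect_true(all(diff(vals) > 0))
})
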