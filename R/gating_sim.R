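#' Parameters of the two-state channel-gating model
#'
#' A sparklet site is modelled as `n_channels` independent, identical
#' channels, each switching between a closed and an open state with
#' exponential dwell times (opening rate `k_open`, closing rate `k_close`,
#' both in 1/s). The stationary open probability of one channel is
#' `P_O = k_open / (k_open + k_close)` and the expected time-averaged number
#' of open channels at the site is `N * P_O`.
#'
#' @param n_channels integer number of channels at the site (N). Quantal
#'   analysis downstream assumes at most 4 simultaneously open channels.
#' @param k_open opening rate, 1/s.
#' @param k_close closing rate, 1/s.
#' @param duration recording duration, s.
#' @param frame_rate acquisition rate, frames/s (default 30).
#' @param seed integer seed; identical parameters and seed give
#'   bit-identical simulations.
#' @return an object of class `gating_params`.
#' @export
#' @examples
#' gating_params(n_channels = 4, k_open = 1, k_close = 9, duration = 120)
gating_params <- function(n_channels = 4L, k_open, k_close,
                          duration, frame_rate = 30, seed = 1L) {
  if (!is.finite(k_open) || !is.finite(k_close) || k_open < 0 || k_close < 0)
    stop("gating rates must be finite and non-negative", call. = FALSE)
  if (!is.finite(n_channels) || n_channels < 0 || n_channels != round(n_channels))
    stop("n_channels must be a non-negative integer", call. = FALSE)
  if (!is.finite(duration) || duration <= 0)
    stop("duration must be positive", call. = FALSE)
  if (!is.finite(frame_rate) || frame_rate <= 0)
    stop("frame_rate must be positive", call. = FALSE)
  structure(
    list(n_channels = as.integer(n_channels), k_open = k_open,
         k_close = k_close, duration = duration,
         frame_rate = frame_rate, seed = as.integer(seed)),
    class = "gating_params"
  )
}

#' Rendering parameters for synthetic fluorescence data
#'
#' Maps simulated open-channel counts to Fluo-4-like F/F0 fluorescence.
#' Each open channel adds a fixed quantal increment `quantal_amplitude`
#' (default 0.29 dF/F0, the per-channel spacing seen in all-points
#' histograms of Fluo-4-loaded arteries). Acquisition noise is additive
#' Gaussian in F/F0 units; photobleaching is off by default and, when on,
#' scales total fluorescence multiplicatively before noise is added.
#'
#' @param quantal_amplitude dF/F0 per open channel (q, > 0; default 0.29).
#' @param baseline_f0 baseline fluorescence in camera units (movies; the
#'   F/F0 trace itself is unitless). Default 1000.
#' @param noise_sd additive Gaussian noise SD in F/F0 units (default 0.05).
#' @param bleach_rate mono-exponential bleach rate, fraction/s (default 0).
#' @param psf_sigma spatial Gaussian footprint SD of a sparklet site, um
#'   (movies only; default 0.8).
#' @param pixel_size um per pixel (movies only; default 0.26, i.e. a
#'   5 x 5 pixel box covers ~1.7 um^2).
#' @param cells_per_field number of endothelial cells per field (default 15,
#'   matching a ~110 x 110 um field).
#' @return an object of class `render_params`.
#' @export
render_params <- function(quantal_amplitude = 0.29, baseline_f0 = 1000,
                          noise_sd = 0.05, bleach_rate = 0,
                          psf_sigma = 0.8, pixel_size = 0.26,
                          cells_per_field = 15L) {
  if (!is.finite(quantal_amplitude) || quantal_amplitude <= 0)
    stop("quantal_amplitude must be positive", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("noise_sd must be non-negative", call. = FALSE)
  if (!is.finite(bleach_rate) || bleach_rate < 0)
    stop("bleach_rate must be non-negative", call. = FALSE)
  structure(
    list(quantal_amplitude = quantal_amplitude, baseline_f0 = baseline_f0,
         noise_sd = noise_sd, bleach_rate = bleach_rate,
         psf_sigma = psf_sigma, pixel_size = pixel_size,
         cells_per_field = as.integer(cells_per_field)),
    class = "render_params"
  )
}

# Continuous-time trajectory of one two-state channel over [0, duration].
# Returns transition times (strictly inside (0, duration)) and the state
# sequence; state[i] holds on [times[i], times[i+1]).
.simulate_channel <- function(k_open, k_close, duration) {
  # stationary initial state; degenerate rate pairs resolve naturally
  p_o <- if (k_open + k_close > 0) k_open / (k_open + k_close) else 0
  state <- as.integer(stats::runif(1) < p_o)
  times <- 0
  states <- state
  t <- 0
  repeat {
    rate <- if (state == 1L) k_close else k_open
    if (rate <= 0) break                       # absorbing state
    t <- t + stats::rexp(1, rate)
    if (t >= duration) break
    state <- 1L - state
    times <- c(times, t)
    states <- c(states, state)
  }
  list(times = times, states = states)
}

#' Simulate per-frame open-channel counts at a sparklet site
#'
#' Event-driven continuous-time Markov simulation of `n_channels`
#' independent two-state channels. The per-frame level is the site
#' occupancy at the frame's start time (frame k starts at `k / frame_rate`,
#' frame 0 at t = 0); occupancy is not time-averaged within the frame.
#' Channels are initialised from the stationary distribution.
#'
#' @param params a [gating_params()] object.
#' @return an object of class `gating_truth` with fields
#'   `open_counts` (integer per frame), `stationary_po`, `true_npo`
#'   (`n_channels * stationary_po`), `true_dwell_times` (named vector,
#'   seconds of continuous time spent at each occupancy level
#'   `0..n_channels`; sums to `duration`), `transitions` (data.frame of the
#'   continuous-time aggregate occupancy: `time`, `count`), and the input
#'   parameters.
#' @export
#' @examples
#' tr <- simulate_open_counts(gating_params(4, 1, 9, duration = 10, seed = 2))
#' mean(tr$open_counts)   # near tr$true_npo = 0.4
simulate_open_counts <- function(params) {
  stopifnot(inherits(params, "gating_params"))
  n <- params$n_channels
  p_o <- if (params$k_open + params$k_close > 0)
    params$k_open / (params$k_open + params$k_close) else 0

  chans <- with_seed(params$seed, {
    lapply(seq_len(n), function(i)
      .simulate_channel(params$k_open, params$k_close, params$duration))
  })

  # merge per-channel step functions into aggregate occupancy
  if (n == 0L) {
    ev_times <- 0
    ev_counts <- 0L
  } else {
    deltas <- numeric(0); dtimes <- numeric(0)
    count0 <- 0L
    for (ch in chans) {
      count0 <- count0 + ch$states[1]
      if (length(ch$times) > 1L) {
        dt <- ch$times[-1]
        dd <- diff(ch$states)        # +1 on opening, -1 on closing
        dtimes <- c(dtimes, dt)
        deltas <- c(deltas, dd)
      }
    }
    o <- order(dtimes)
    ev_times <- c(0, dtimes[o])
    ev_counts <- as.integer(count0 + cumsum(c(0, deltas[o])))
  }

  # continuous-time dwell per occupancy level
  seg_len <- diff(c(ev_times, params$duration))
  dwell <- vapply(0:n, function(l) sum(seg_len[ev_counts == l]), numeric(1))
  names(dwell) <- paste0("level", 0:n)

  # sample at frame starts
  n_frames <- max(1L, as.integer(round(params$duration * params$frame_rate)))
  t_frames <- (seq_len(n_frames) - 1L) / params$frame_rate
  idx <- findInterval(t_frames, ev_times)
  open_counts <- ev_counts[idx]

  structure(
    list(open_counts = open_counts,
         stationary_po = p_o,
         true_npo = n * p_o,
         true_dwell_times = dwell,
         transitions = data.frame(time = ev_times, count = ev_counts),
         params = params),
    class = "gating_truth"
  )
}

#' @export
print.gating_truth <- function(x, ...) {
  cat(sprintf(
    "<gating_truth> N=%d  P_O=%.4f  true NP_O=%.4f  %d frames @ %g fps\n",
    x$params$n_channels, x$stationary_po, x$true_npo,
    length(x$open_counts), x$params$frame_rate))
  invisible(x)
}

#' Render a fluorescence F/F0 trace from simulated gating
#'
#' Applies the forward measurement model
#' `F/F0(t) = (1 + q * open_counts(t)) * exp(-bleach_rate * t) + e(t)`,
#' with `e(t) ~ N(0, noise_sd^2)` i.i.d. Gaussian acquisition noise and `t`
#' the frame start time in seconds.
#'
#' @param truth a [simulate_open_counts()] result.
#' @param render a [render_params()] object.
#' @param seed integer seed for the noise stream.
#' @return a [fluorescence_trace()] with the rendering parameters and
#'   ground truth attached as `truth`.
#' @export
render_trace <- function(truth, render = render_params(), seed = 1L) {
  stopifnot(inherits(truth, "gating_truth"), inherits(render, "render_params"))
  n_frames <- length(truth$open_counts)
  t <- (seq_len(n_frames) - 1L) / truth$params$frame_rate
  clean <- (1 + render$quantal_amplitude * truth$open_counts) *
    exp(-render$bleach_rate * t)
  noise <- if (render$noise_sd > 0) {
    with_seed(derive_seed(seed, "render_trace"),
              stats::rnorm(n_frames, 0, render$noise_sd))
  } else rep(0, n_frames)
  tr <- fluorescence_trace(clean + noise, frame_rate = truth$params$frame_rate,
                           filters_applied = character(0))
  tr$render <- render
  tr$truth <- truth
  tr
}

# 2-D Gaussian footprint (peak 1) of a site evaluated on the pixel grid.
.site_footprint <- function(pos_um, h, w, pixel_size, psf_sigma) {
  rows_um <- (seq_len(h) - 0.5) * pixel_size
  cols_um <- (seq_len(w) - 0.5) * pixel_size
  dr2 <- (rows_um - pos_um[1])^2
  dc2 <- (cols_um - pos_um[2])^2
  outer(dr2, dc2, "+") |> (\(d2) exp(-d2 / (2 * psf_sigma^2)))()
}

#' Render a synthetic sparklet movie
#'
#' Builds a frames x height x width intensity stack standing in for an
#' en face field of Fluo-4-loaded endothelium. Each site contributes a 2-D
#' Gaussian footprint (SD `psf_sigma` um, peak 1 at the site centre) scaled
#' by its instantaneous dF/F0; the background is `baseline_f0` everywhere.
#' Gaussian noise of SD `noise_sd * baseline_f0` is added per pixel and
#' frame. Nuclei positions for `cells_per_field` cells are drawn on a
#' jittered grid and exported for sites-per-cell bookkeeping.
#'
#' @param sites list of `list(position = c(row_um, col_um), truth = <gating_truth>)`.
#'   All truths must share frame rate and frame count.
#' @param render a [render_params()] object.
#' @param field_size c(height_um, width_um) of the field (default c(110, 110)).
#' @param seed integer seed for noise and nuclei placement.
#' @return a [movie_stack()] with attributes `sites` (positions, um),
#'   `nuclei` (positions, um) and `truths`.
#' @export
render_movie <- function(sites, render = render_params(),
                         field_size = c(110, 110), seed = 1L) {
  stopifnot(inherits(render, "render_params"))
  h <- max(1L, as.integer(round(field_size[1] / render$pixel_size)))
  w <- max(1L, as.integer(round(field_size[2] / render$pixel_size)))
  if (length(sites)) {
    n_frames <- length(sites[[1]]$truth$open_counts)
    frame_rate <- sites[[1]]$truth$params$frame_rate
    for (s in sites) {
      if (length(s$truth$open_counts) != n_frames)
        stop("all sites must have the same number of frames", call. = FALSE)
      if (any(s$position < 0) || s$position[1] > field_size[1] ||
          s$position[2] > field_size[2])
        stop("site position outside field", call. = FALSE)
    }
    pos <- t(vapply(sites, function(s) s$position, numeric(2)))
    if (nrow(pos) > 1L &&
        min(stats::dist(pos)) < 2 * render$psf_sigma)
      warning("overlapping sparklet sites (closer than 2 * psf_sigma)")
  } else {
    n_frames <- 30L
    frame_rate <- 30
  }

  data <- array(render$baseline_f0, dim = c(n_frames, h, w))
  for (s in sites) {
    fp <- .site_footprint(s$position, h, w, render$pixel_size, render$psf_sigma)
    dff <- render$quantal_amplitude * s$truth$open_counts   # per-frame dF/F0
    for (t in which(dff != 0)) {
      data[t, , ] <- data[t, , ] + render$baseline_f0 * dff[t] * fp
    }
  }
  nuclei <- with_seed(derive_seed(seed, "nuclei"), {
    k <- render$cells_per_field
    g <- ceiling(sqrt(k))
    centers <- expand.grid(
      row = (seq_len(g) - 0.5) / g * field_size[1],
      col = (seq_len(g) - 0.5) / g * field_size[2])[seq_len(k), ]
    centers$row <- pmin(pmax(centers$row +
      stats::rnorm(k, 0, field_size[1] / (6 * g)), 0), field_size[1])
    centers$col <- pmin(pmax(centers$col +
      stats::rnorm(k, 0, field_size[2] / (6 * g)), 0), field_size[2])
    as.matrix(centers)
  })
  if (render$noise_sd > 0) {
    data <- data + with_seed(derive_seed(seed, "movie_noise"),
      array(stats::rnorm(length(data), 0,
                         render$noise_sd * render$baseline_f0), dim = dim(data)))
  }
  mv <- movie_stack(data, frame_rate = frame_rate,
                    pixel_size = render$pixel_size)
  attr(mv, "sites") <- if (length(sites))
    t(vapply(sites, function(s) s$position, numeric(2))) else
    matrix(numeric(0), 0, 2)
  attr(mv, "nuclei") <- nuclei
  attr(mv, "truths") <- lapply(sites, function(s) s$truth)
  mv
}
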