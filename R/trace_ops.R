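#' Fluorescence movie stack
#'
#' Container for a frames x height x width intensity array with its
#' acquisition calibration.
#'
#' @param data numeric array, dim = c(frames, height, width), finite.
#' @param frame_rate frames/s (> 0).
#' @param pixel_size um per pixel (> 0).
#' @return an object of class `movie_stack`.
#' @export
movie_stack <- function(data, frame_rate, pixel_size) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3-D array (frames x height x width)", call. = FALSE)
  if (dim(data)[1] < 1L) stop("movie needs at least one frame", call. = FALSE)
  if (!all(is.finite(data))) stop("movie contains non-finite values", call. = FALSE)
  if (!is.finite(frame_rate) || frame_rate <= 0)
    stop("frame_rate must be positive", call. = FALSE)
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be positive", call. = FALSE)
  structure(list(data = data, frame_rate = frame_rate,
                 pixel_size = pixel_size),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<movie_stack> %d frames, %d x %d px @ %g fps, %g um/px\n",
              d[1], d[2], d[3], x$frame_rate, x$pixel_size))
  invisible(x)
}

#' Fluorescence F/F0 trace
#'
#' @param values numeric F/F0 sequence, finite, length >= 1.
#' @param frame_rate frames/s.
#' @param roi optional [roi_spec()] provenance.
#' @param filters_applied character vector of filters applied so far.
#' @return an object of class `fluorescence_trace`.
#' @export
fluorescence_trace <- function(values, frame_rate, roi = NULL,
                               filters_applied = character(0)) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("trace must be non-empty", call. = FALSE)
  if (!all(is.finite(values))) stop("trace contains non-finite values", call. = FALSE)
  if (!is.finite(frame_rate) || frame_rate <= 0)
    stop("frame_rate must be positive", call. = FALSE)
  structure(list(values = values, frame_rate = frame_rate, roi = roi,
                 filters_applied = filters_applied),
            class = "fluorescence_trace")
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf("<fluorescence_trace> %d frames @ %g fps (%.1f s)%s\n",
              length(x$values), x$frame_rate,
              length(x$values) / x$frame_rate,
              if (length(x$filters_applied))
                paste0(", filters: ", paste(x$filters_applied, collapse = ", "))
              else ""))
  invisible(x)
}

# frame start times, seconds (frame 0 at t = 0)
trace_times <- function(trace) {
  (seq_along(trace$values) - 1L) / trace$frame_rate
}

#' 5 x 5 pixel region of interest
#'
#' The measurement box used for F/F0 extraction: 5 x 5 pixels (~1.7 um^2 at
#' 0.26 um/px) centred on the sparklet peak. Coordinates are 0-based,
#' row-major.
#'
#' @param center_row,center_col 0-based pixel indices of the box centre.
#' @param size box edge in pixels (odd; default 5).
#' @return an object of class `roi_spec`.
#' @export
roi_spec <- function(center_row, center_col, size = 5L) {
  size <- as.integer(size)
  if (size < 1L || size %% 2L == 0L)
    stop("roi size must be a positive odd integer", call. = FALSE)
  structure(list(center_row = as.integer(center_row),
                 center_col = as.integer(center_col),
                 size = size),
            class = "roi_spec")
}

# 1-based row/col index ranges of the ROI; errors if outside the frame
.roi_index <- function(roi, h, w) {
  half <- (roi$size - 1L) %/% 2L
  rows <- (roi$center_row - half):(roi$center_row + half) + 1L
  cols <- (roi$center_col - half):(roi$center_col + half) + 1L
  if (min(rows) < 1L || max(rows) > h || min(cols) < 1L || max(cols) > w)
    stop("ROI extends outside the frame", call. = FALSE)
  list(rows = rows, cols = cols)
}

#' Kalman stack-filter parameters
#'
#' @param gain initial filter gain in `[0, 1]` (default 0.8).
#' @param noise_variance acquisition noise variance estimate (> 0,
#'   default 0.05).
#' @param adaptive if `TRUE` (default) the per-pixel gain evolves with the
#'   running prediction variance; if `FALSE` the gain is held fixed, giving
#'   the closed-form geometric step response used for testing.
#' @return an object of class `kalman_params`.
#' @export
kalman_params <- function(gain = 0.8, noise_variance = 0.05, adaptive = TRUE) {
  if (!is.finite(gain) || gain < 0 || gain > 1)
    stop("gain must be in [0, 1]", call. = FALSE)
  if (!is.finite(noise_variance) || noise_variance <= 0)
    stop("noise_variance must be positive", call. = FALSE)
  structure(list(gain = gain, noise_variance = noise_variance,
                 adaptive = isTRUE(adaptive)),
            class = "kalman_params")
}

#' Kalman stack filter for fluorescence movies
#'
#' Per-pixel recursive predictive filter in the style of the ImageJ Kalman
#' stack filter: the estimate for frame t is
#' `E_t = G_t * E_{t-1} + (1 - G_t) * O_t`, with `E_0 = O_0` (the first
#' frame is passed through unchanged). In adaptive mode the gain follows the
#' scalar Kalman recursion for a static state: with prediction variance
#' `P_{t-1}` and observation noise variance `R`, the innovation weight is
#' `K_t = P_{t-1} / (P_{t-1} + R)` (so `G_t = 1 - K_t`), and
#' `P_t = (1 - K_t) * P_{t-1}`. `P_0` is chosen so that `G_1` equals the
#' configured initial gain. In fixed-gain mode `G_t` is constant.
#'
#' The same recursion applies to 1-D traces via [kalman_filter_trace()].
#'
#' @param movie a [movie_stack()].
#' @param params a [kalman_params()].
#' @return a filtered [movie_stack()] of the same shape.
#' @export
kalman_stack_filter <- function(movie, params = kalman_params()) {
  stopifnot(inherits(movie, "movie_stack"), inherits(params, "kalman_params"))
  n <- dim(movie$data)[1]
  if (n < 2L) {
    warning("single-frame movie returned unchanged")
    return(movie)
  }
  out <- movie$data
  gains <- .kalman_gains(n, params)
  for (t in 2:n) {
    g <- gains[t - 1L]
    out[t, , ] <- g * out[t - 1L, , ] + (1 - g) * movie$data[t, , ]
  }
  movie$data <- out
  movie
}

# gain sequence G_1..G_{n-1} applied at frames 2..n
.kalman_gains <- function(n, params) {
  if (!params$adaptive) return(rep(params$gain, n - 1L))
  R <- params$noise_variance
  # choose P0 so the first applied gain equals params$gain
  k1 <- 1 - params$gain
  P <- if (k1 <= 0) 0 else R * k1 / (1 - k1)
  gains <- numeric(n - 1L)
  for (i in seq_len(n - 1L)) {
    K <- P / (P + R)
    gains[i] <- 1 - K
    P <- (1 - K) * P
  }
  gains
}

#' @rdname kalman_stack_filter
#' @param trace a [fluorescence_trace()].
#' @export
kalman_filter_trace <- function(trace, params = kalman_params()) {
  stopifnot(inherits(trace, "fluorescence_trace"),
            inherits(params, "kalman_params"))
  n <- length(trace$values)
  if (n < 2L) {
    warning("single-frame trace returned unchanged")
    return(trace)
  }
  v <- trace$values
  gains <- .kalman_gains(n, params)
  for (t in 2:n) {
    g <- gains[t - 1L]
    v[t] <- g * v[t - 1L] + (1 - g) * trace$values[t]
  }
  trace$values <- v
  trace$filters_applied <- c(trace$filters_applied,
                             sprintf("kalman(gain=%g,R=%g,adaptive=%s)",
                                     params$gain, params$noise_variance,
                                     params$adaptive))
  trace
}

#' Zero-phase Gaussian low-pass filter (display)
#'
#' Smooths a trace with a Gaussian kernel whose -3 dB corner frequency is
#' `cutoff_hz`: the kernel SD in seconds is `sqrt(log(2)) / (2 * pi * f_c)`,
#' so the amplitude response at `f_c` is `1 / sqrt(2)`. Edges use symmetric
#' (reflect) padding. This filter is for display only; quantal analysis
#' consumes raw or Kalman-filtered data, because temporal smoothing biases
#' dwell times.
#'
#' @param trace a [fluorescence_trace()].
#' @param cutoff_hz corner frequency, Hz (default 4; must be below Nyquist).
#' @return the filtered trace.
#' @export
gaussian_lowpass <- function(trace, cutoff_hz = 4) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  nyquist <- trace$frame_rate / 2
  if (!is.finite(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= nyquist)
    stop("cutoff_hz must lie in (0, frame_rate / 2)", call. = FALSE)
  sigma_s <- sqrt(log(2)) / (2 * pi * cutoff_hz)
  sigma_n <- sigma_s * trace$frame_rate
  half <- max(1L, ceiling(6 * sigma_n))
  k <- stats::dnorm(-half:half, sd = sigma_n)
  k <- k / sum(k)
  v <- trace$values
  n <- length(v)
  # symmetric padding
  pad <- c(v[pmin(half:1, n)], v, v[pmax(n - (1:half) + 1L, 1L)])
  sm <- stats::filter(pad, k, sides = 2)
  trace$values <- as.numeric(sm[(half + 1L):(half + n)])
  trace$filters_applied <- c(trace$filters_applied,
                             sprintf("gaussian_lowpass(%g Hz)", cutoff_hz))
  trace
}

#' Extract an F/F0 trace from a movie ROI
#'
#' The raw trace is the mean intensity inside the 5 x 5 ROI box per frame;
#' F0 is the mean box intensity over `baseline` (a vector of 1-based frame
#' indices), or, in automatic mode (`baseline = NULL`), the mean of the
#' lowest decile of per-frame box means.
#'
#' @param movie a [movie_stack()].
#' @param roi a [roi_spec()], fully inside the frame.
#' @param baseline optional integer frame indices of the baseline window.
#' @return a [fluorescence_trace()] with `roi` provenance.
#' @export
extract_ff0 <- function(movie, roi, baseline = NULL) {
  stopifnot(inherits(movie, "movie_stack"), inherits(roi, "roi_spec"))
  d <- dim(movie$data)
  ix <- .roi_index(roi, d[2], d[3])
  box <- movie$data[, ix$rows, ix$cols, drop = FALSE]
  means <- apply(box, 1, mean)
  if (is.null(baseline)) {
    k <- max(1L, floor(length(means) / 10))
    f0 <- mean(sort(means)[seq_len(k)])
  } else {
    baseline <- as.integer(baseline)
    if (length(baseline) < 1L || any(baseline < 1L | baseline > d[1]))
      stop("baseline window empty or out of range", call. = FALSE)
    f0 <- mean(means[baseline])
  }
  if (!is.finite(f0) || f0 <= 0)
    stop("baseline fluorescence F0 is not positive", call. = FALSE)
  fluorescence_trace(means / f0, frame_rate = movie$frame_rate, roi = roi,
                     filters_applied = character(0))
}

#' Place the measurement ROI at the sparklet peak
#'
#' Centres a 5 x 5 ROI on the pixel with the maximum intensity across all
#' frames (the point of peak sparklet amplitude); pass a Kalman-filtered
#' movie to suppress noise-driven maxima. Ties are broken by earliest
#' frame, then smallest row, then smallest column. The centre is clamped so
#' the box stays inside the frame.
#'
#' @param movie a [movie_stack()].
#' @param size ROI edge, pixels (default 5).
#' @return a [roi_spec()].
#' @export
place_roi_at_peak <- function(movie, size = 5L) {
  stopifnot(inherits(movie, "movie_stack"))
  d <- dim(movie$data)
  m <- max(movie$data)
  hits <- which(movie$data == m, arr.ind = TRUE)  # frame, row, col; frame fastest
  hits <- hits[order(hits[, 1], hits[, 2], hits[, 3]), , drop = FALSE]
  half <- (as.integer(size) - 1L) %/% 2L
  r <- min(max(hits[1, 2] - 1L, half), d[2] - 1L - half)
  c <- min(max(hits[1, 3] - 1L, half), d[3] - 1L - half)
  roi_spec(r, c, size = size)
}

#' Detect sparklet events under the stable-baseline / steady-peak rule
#'
#' An event is a contiguous run of frames more than `baseline_tolerance`
#' above the baseline level. An event is kept only if (i) the
#' `min_baseline_pts` frames immediately preceding it are all within
#' `baseline_tolerance` of their own mean (stable baseline) and (ii) the run
#' contains at least `min_peak_pts` consecutive frames within
#' `baseline_tolerance` of the event's peak mean (steady peak). Events
#' failing either criterion are excluded.
#'
#' The baseline level is the median of the trace (sparklet openings are
#' sparse, so the median tracks the closed level). `baseline_tolerance`
#' defaults to twice a robust noise SD, estimated as
#' `mad(diff(values)) / sqrt(2)`.
#'
#' @param trace a [fluorescence_trace()].
#' @param min_baseline_pts minimum steady pre-event baseline frames (default 5).
#' @param min_peak_pts minimum steady peak frames (default 5).
#' @param baseline_tolerance amplitude tolerance in F/F0 units; `NULL` for
#'   the robust default.
#' @return a data.frame with one row per event: `start_frame`, `peak_frame`,
#'   `end_frame` (1-based), `peak_amplitude` (dF/F0 above baseline), `auc`
#'   (dF/F0 * s, trapezoidal, see [event_auc()]).
#' @export
detect_events <- function(trace, min_baseline_pts = 5L, min_peak_pts = 5L,
                          baseline_tolerance = NULL) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  v <- trace$values
  n <- length(v)
  if (n <= min_baseline_pts + min_peak_pts)
    stop("trace too short for event detection", call. = FALSE)
  if (is.null(baseline_tolerance)) {
    baseline_tolerance <- 2 * stats::mad(diff(v)) / sqrt(2)
  }
  tol <- max(baseline_tolerance, sqrt(.Machine$double.eps))
  base <- stats::median(v)

  above <- v > base + tol
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  out <- list()
  for (j in runs) {
    s <- starts[j]; e <- ends[j]
    if (s <= min_baseline_pts) next                 # no room for a baseline
    pre <- v[(s - min_baseline_pts):(s - 1L)]
    if (max(abs(pre - mean(pre))) > tol) next       # unstable baseline
    seg <- v[s:e]
    pk_val <- max(seg)
    near_peak <- abs(seg - pk_val) <= tol
    rp <- rle(near_peak)
    if (!any(rp$values & rp$lengths >= min_peak_pts)) next  # no steady peak
    peak_frame <- s + which.max(seg) - 1L
    ev <- data.frame(start_frame = s, peak_frame = peak_frame, end_frame = e,
                     peak_amplitude = pk_val - base)
    out[[length(out) + 1L]] <- ev
  }
  ev <- if (length(out)) do.call(rbind, out) else
    data.frame(start_frame = integer(0), peak_frame = integer(0),
               end_frame = integer(0), peak_amplitude = numeric(0))
  ev$auc <- vapply(seq_len(nrow(ev)), function(i)
    event_auc(trace, ev$start_frame[i], ev$end_frame[i]), numeric(1))
  ev
}

#' Trapezoidal area under an event
#'
#' Integrates `(F/F0 - 1)` over time (seconds) between the event's start
#' and end frames with the trapezoid rule. A degenerate event
#' (`start == end`) has zero area.
#'
#' @param trace a [fluorescence_trace()].
#' @param start_frame,end_frame 1-based frame indices, start <= end.
#' @return area in dF/F0 * s.
#' @export
event_auc <- function(trace, start_frame, end_frame) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  n <- length(trace$values)
  if (start_frame < 1L || end_frame > n || start_frame > end_frame)
    stop("event out of trace bounds", call. = FALSE)
  if (start_frame == end_frame) return(0)
  y <- trace$values[start_frame:end_frame] - 1
  dt <- 1 / trace$frame_rate
  sum((y[-1] + y[-length(y)]) / 2) * dt
}
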