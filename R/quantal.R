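#' All-points amplitude histogram
#'
#' Histogram of every frame's F/F0 value in a trace. Peaks correspond to
#' quantal occupancy levels and are fit with a Gaussian mixture by
#' [fit_multi_gaussian()]. Binning is deterministic: bins are left-closed /
#' right-open over `[min, max]`, with the last bin closed. The default bin
#' width is the Freedman-Diaconis rule, `2 * IQR / n^(1/3)`.
#'
#' @param trace a [fluorescence_trace()].
#' @param bin_width bin width in F/F0 units; `NULL` for Freedman-Diaconis.
#' @param n_bins alternatively, a bin count (ignored if `bin_width` given).
#' @return an object of class `all_points_histogram` with fields
#'   `bin_edges`, `counts`, `n_points`.
#' @export
build_histogram <- function(trace, bin_width = NULL, n_bins = NULL) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  v <- trace$values
  n <- length(v)
  if (n < 10L) warning("all-points histogram from fewer than 10 frames")
  rng <- range(v)
  if (diff(rng) == 0) {
    h <- structure(list(bin_edges = c(rng[1] - .Machine$double.eps,
                                      rng[1] + .Machine$double.eps),
                        counts = n, n_points = n),
                   class = "all_points_histogram")
    return(h)
  }
  if (is.null(bin_width)) {
    if (!is.null(n_bins)) {
      bin_width <- diff(rng) / n_bins
    } else {
      iqr <- stats::IQR(v)
      bin_width <- if (iqr > 0) 2 * iqr / n^(1 / 3) else diff(rng) / ceiling(sqrt(n))
    }
  }
  if (!is.finite(bin_width) || bin_width <= 0)
    stop("bin width must be positive", call. = FALSE)
  k <- max(1L, ceiling(diff(rng) / bin_width))
  edges <- rng[1] + bin_width * (0:k)
  idx <- pmin(floor((v - rng[1]) / bin_width) + 1L, k)  # last bin closed
  counts <- tabulate(idx, nbins = k)
  structure(list(bin_edges = edges, counts = counts, n_points = n),
            class = "all_points_histogram")
}

#' @export
print.all_points_histogram <- function(x, ...) {
  cat(sprintf("<all_points_histogram> %d bins over [%.3f, %.3f], %d points\n",
              length(x$counts), min(x$bin_edges), max(x$bin_edges), x$n_points))
  invisible(x)
}

hist_centers <- function(h) (h$bin_edges[-1] + h$bin_edges[-length(h$bin_edges)]) / 2
hist_width <- function(h) diff(h$bin_edges[1:2])

# mixture count model: expected counts per bin for component means mu,
# sds sigma and areas a (probability mass units)
.mixture_counts <- function(centers, n_points, width, mu, sigma, a) {
  dens <- rep(0, length(centers))
  for (i in seq_along(mu))
    dens <- dens + a[i] * stats::dnorm(centers, mu[i], sigma[i])
  dens * n_points * width
}

# Robust histogram peak detection. Returns the global peak (m_star), its
# half-width-based SD estimate (s_star) and the accepted mode positions:
# local maxima of the kernel-smoothed counts, kept greedily by height only
# if at least 2.5 * s_star from every stronger accepted mode and at least
# 2.5% of the main peak high. The separation rule suppresses noise lumps in
# the flanks of a dominant peak, which otherwise masquerade as levels.
.hist_peaks <- function(h) {
  c0 <- h$counts
  width <- hist_width(h)
  centers <- hist_centers(h)
  n <- length(c0)
  if (n < 5) {
    i <- which.max(c0)
    return(list(m_star = centers[i], s_star = max(width, stats::sd(rep(centers, c0))),
                modes = centers[i]))
  }
  kern_sd <- 1
  kern <- stats::dnorm(-3:3, sd = kern_sd)
  kern <- kern / sum(kern)
  pad <- c(rep(0, 3), c0, rep(0, 3))
  sm <- as.numeric(stats::filter(pad, kern, sides = 2))[4:(n + 3)]

  i_star <- which.max(sm)
  m_star <- centers[i_star]
  # SD of the main peak from its half width at half maximum, measured with
  # sub-bin interpolation and deconvolved for the smoothing kernel
  half <- sm[i_star] / 2
  cross <- function(dir) {
    i <- i_star
    while (i + dir >= 1 && i + dir <= n && sm[i + dir] > half) i <- i + dir
    j <- i + dir
    if (j < 1 || j > n) return(abs(i - i_star) + 0.5)
    abs(i - i_star) + (sm[i] - half) / max(sm[i] - sm[j], 1e-12)
  }
  hwhm_bins <- (cross(-1L) + cross(1L)) / 2
  s_meas <- hwhm_bins / sqrt(2 * log(2))       # HWHM -> Gaussian SD, in bins
  s_star <- max(sqrt(max(s_meas^2 - kern_sd^2, 0.25)) * width, width / 2)

  win <- 2L
  is_max <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - win); hi <- min(n, i + win)
    sm[i] == max(sm[lo:hi]) && sm[i] >= 0.025 * sm[i_star] && c0[i] >= 3
  }, logical(1))
  cand <- which(is_max)
  cand <- cand[order(sm[cand], decreasing = TRUE)]
  # spurious flank lumps sit within ~3 SD of a stronger peak; genuine
  # neighbouring quantal levels are several SD away
  min_sep <- max(3 * s_star, 2 * width)
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) || all(abs(centers[i] - centers[kept]) >= min_sep))
      kept <- c(kept, i)
  }
  if (!length(kept)) kept <- i_star
  list(m_star = m_star, s_star = s_star, modes = sort(centers[kept]))
}

# baseline (closed-level) estimate: the lowest accepted histogram mode,
# refined by a count-weighted mean over neighbouring bins. The baseline is
# shared by all sparklets at a site but is not necessarily the tallest peak
# when the site is very active.
.baseline_from_hist <- function(h) {
  m <- .hist_peaks(h)$modes[1]
  centers <- hist_centers(h)
  near <- abs(centers - m) <= 1.5 * hist_width(h)
  sum(centers[near] * h$counts[near]) / sum(h$counts[near])
}

#' Fit an equally spaced multi-Gaussian mixture to an all-points histogram
#'
#' Weighted least-squares fit of
#' `f(x) = sum_i a_i / (sqrt(2 pi) sigma_i) * exp(-(x - mu_i)^2 / (2 sigma_i^2))`
#' for components `i = 0..K` to the histogram counts, with Poisson weights
#' `1 / max(count, 1)`. Component 0 is the shared baseline (closed level);
#' under the default equal-spacing (quantal) constraint the means are
#' `mu_i = mu_0 + i * q` with a single spacing `q`, the per-open-channel
#' quantal amplitude. The number of non-baseline components `K <= max_levels`
#' is selected by BIC. Initialisation comes from histogram local maxima,
#' falling back to `mu_0 + i * q_init` seeding.
#'
#' @param hist an [build_histogram()] result.
#' @param max_levels maximum number of open-channel levels (default 4).
#' @param equal_spacing constrain means to a common spacing (default TRUE).
#' @param share_sd constrain all components to one SD (default TRUE). With
#'   additive acquisition noise the level SDs are nearly equal; sharing the
#'   SD also blocks a degenerate solution in which the dominant baseline
#'   peak is split into closely spaced sub-components.
#' @param q_init fallback initial spacing, dF/F0 (default 0.29).
#' @return an object of class `quantal_model`: `n_components` (K),
#'   `areas`, `means`, `sds` (length K + 1, baseline first),
#'   `quantal_amplitude` (common or mean spacing; `NA` with a warning flag
#'   when K = 0), `baseline_mean`, `equal_spacing`, and `diagnostics`
#'   (weighted residual norm, convergence flag, BIC table).
#' @export
fit_multi_gaussian <- function(hist, max_levels = 4L, equal_spacing = TRUE,
                               share_sd = TRUE, q_init = 0.29) {
  stopifnot(inherits(hist, "all_points_histogram"))
  if (max_levels < 1L) stop("max_levels must be >= 1", call. = FALSE)
  centers <- hist_centers(hist)
  counts <- hist$counts
  width <- hist_width(hist)
  occupied <- sum(counts > 0)

  # degenerate histogram: baseline-only model, no fit
  if (occupied < 4L) {
    mu0 <- sum(centers * counts) / sum(counts)
    s0 <- sqrt(max(sum(counts * (centers - mu0)^2) / sum(counts), (width / 4)^2))
    return(.quantal_model(K = 0L, a = 1, mu = mu0, sigma = s0, q = NA_real_,
                          equal_spacing = equal_spacing,
                          diagnostics = list(rss = 0, converged = TRUE,
                                             bic = NULL, note = "degenerate histogram")))
  }

  w <- 1 / pmax(counts, 1)
  obj_counts <- function(mu, sigma, a) {
    fit <- .mixture_counts(centers, hist$n_points, width, mu, sigma, a)
    sum(w * (counts - fit)^2)
  }

  pk <- .hist_peaks(hist)
  s0 <- max(pk$s_star, width / 2)
  # resolvability floor: spacings below ~1.5 baseline SD (or 2 bins) would
  # place adjacent levels inside one noise peak and are not identifiable
  q_min <- max(2 * width, 1.5 * s0)
  q_fb <- max(q_init, 1.5 * q_min)           # fallback spacing seed
  q_modes <- if (length(pk$modes) > 1) min(diff(pk$modes)) else NA_real_
  if (!is.finite(q_modes) || q_modes <= q_min) q_modes <- q_fb

  # two anchors: the lowest accepted mode (baseline of an active site) and
  # the global peak with q_init seeding (robust when flank lumps survive)
  inits <- list(list(mu0 = pk$modes[1], q0 = q_modes),
                list(mu0 = pk$m_star, q0 = q_fb))
  if (abs(inits[[2]]$mu0 - inits[[1]]$mu0) < width &&
      abs(inits[[2]]$q0 - inits[[1]]$q0) < width) inits <- inits[1]

  # effective-points precondition limits the richest model attempted
  k_max <- min(as.integer(max_levels),
               max(0L, floor((occupied / 2 - 3) / 3)))

  s_min <- width / 2              # a component narrower than a bin is noise
  s0_free <- log(max(s0 - s_min, width / 4))

  fits <- list()
  for (K in 0:k_max) {
    n_sd <- if (share_sd) 1L else K + 1L
    # theta layout: mu0 | spacing terms (1 if equal_spacing, K if free, 0 if
    # K = 0) | n_sd log-sigmas | K + 1 log-areas; spacings are floored at
    # q_min and sigmas at s_min through log offsets
    n_sp <- if (K == 0L) 0L else if (equal_spacing) 1L else K
    unpack <- function(th) {
      sp <- if (n_sp > 0) q_min + exp(th[2:(1 + n_sp)]) else numeric(0)
      incr <- if (K == 0L) numeric(0)
        else if (equal_spacing) rep(sp, K) else sp
      mu <- th[1] + c(0, cumsum(incr))
      sig <- s_min + exp(th[(2 + n_sp):(1 + n_sp + n_sd)])
      if (share_sd) sig <- rep(sig, K + 1L)
      a <- exp(th[(2 + n_sp + n_sd):(1 + n_sp + n_sd + K + 1L)])
      list(mu = mu, q = if (K == 0L) NA_real_ else mean(incr),
           sigma = sig, a = a)
    }
    f <- function(th) {
      p <- unpack(th)
      val <- obj_counts(p$mu, p$sigma, p$a)
      if (!is.finite(val)) 1e300 else val
    }

    opt <- NULL
    for (ini in inits) {
      mu_seed <- ini$mu0 + (0:K) * ini$q0
      # initial areas: histogram mass nearest each seeded level
      assign <- vapply(centers, function(x) which.min(abs(x - mu_seed)),
                       integer(1))
      a_seed <- pmax(vapply(1:(K + 1), function(i)
        sum(counts[assign == i]) / sum(counts), numeric(1)), 1e-4)
      theta0 <- c(ini$mu0, rep(log(max(ini$q0 - q_min, width / 4)), n_sp),
                  rep(s0_free, n_sd), log(a_seed))
      o <- stats::optim(theta0, f, method = "Nelder-Mead",
                        control = list(maxit = 400 * length(theta0),
                                       reltol = 1e-10))
      o2 <- tryCatch(
        stats::optim(o$par, f, method = "BFGS",
                     control = list(maxit = 200, reltol = 1e-12)),
        error = function(e) o)
      if (o2$value <= o$value) o <- o2
      if (is.null(opt) || o$value < opt$value) opt <- o
    }
    p <- unpack(opt$par)
    nb <- length(counts)
    npar <- length(opt$par)
    bic <- nb * log(max(opt$value, 1e-300) / nb) + npar * log(nb)
    fits[[K + 1]] <- list(K = K, p = p, rss = opt$value, bic = bic,
                          converged = opt$convergence == 0)
  }

  bics <- vapply(fits, `[[`, numeric(1), "bic")
  best <- fits[[which.min(bics)]]
  if (!best$converged)
    warning("mixture fit did not fully converge; diagnostics attached")

  # drop components that carry no mass: a near-zero leading area means the
  # baseline was anchored one level too low; near-zero trailing areas are
  # unoccupied high levels
  p <- best$p; K <- best$K
  note <- NULL
  tot <- sum(p$a)
  while (K > 0L && p$a[1] < 0.01 * tot) {
    p$a <- p$a[-1]; p$mu <- p$mu[-1]; p$sigma <- p$sigma[-1]
    K <- K - 1L
    note <- "dropped empty leading component(s)"
  }
  while (K > 0L && p$a[K + 1L] < 0.005 * tot) {
    p$a <- p$a[-(K + 1L)]; p$mu <- p$mu[-(K + 1L)]
    p$sigma <- p$sigma[-(K + 1L)]
    K <- K - 1L
  }
  q_hat <- if (K == 0L) NA_real_ else mean(diff(p$mu))
  .quantal_model(K = K, a = p$a, mu = p$mu, sigma = p$sigma, q = q_hat,
                 equal_spacing = equal_spacing,
                 diagnostics = list(
                   rss = best$rss, converged = best$converged,
                   bic = data.frame(K = 0:k_max, bic = bics), note = note))
}

.quantal_model <- function(K, a, mu, sigma, q, equal_spacing, diagnostics) {
  structure(list(n_components = as.integer(K), areas = a, means = mu,
                 sds = sigma, quantal_amplitude = q, baseline_mean = mu[1],
                 equal_spacing = equal_spacing, diagnostics = diagnostics),
            class = "quantal_model")
}

#' @export
print.quantal_model <- function(x, ...) {
  cat(sprintf("<quantal_model> K=%d levels, mu0=%.4f, q=%s\n",
              x$n_components, x$baseline_mean,
              if (is.na(x$quantal_amplitude)) "NA (baseline only)"
              else sprintf("%.4f", x$quantal_amplitude)))
  invisible(x)
}

#' Manually specify a quantal model (global-q mode)
#'
#' Used when the quantal amplitude is fixed globally (e.g. 0.29 dF/F0 for
#' Fluo-4) rather than fit per trace; only the baseline mean is estimated
#' from the data.
#'
#' @param baseline_mean baseline F/F0 level mu_0.
#' @param quantal_amplitude per-channel spacing q (> 0).
#' @param sd nominal level SD (optional, default `q / 6`).
#' @param n_components number of open levels assumed reachable (default 4).
#' @return a `quantal_model`.
#' @export
quantal_model_global <- function(baseline_mean, quantal_amplitude = 0.29,
                                 sd = quantal_amplitude / 6,
                                 n_components = 4L) {
  if (!is.finite(quantal_amplitude) || quantal_amplitude <= 0)
    stop("quantal_amplitude must be positive", call. = FALSE)
  K <- as.integer(n_components)
  .quantal_model(K = K, a = rep(NA_real_, K + 1),
                 mu = baseline_mean + (0:K) * quantal_amplitude,
                 sigma = rep(sd, K + 1), q = quantal_amplitude,
                 equal_spacing = TRUE,
                 diagnostics = list(rss = NA_real_, converged = TRUE,
                                    bic = NULL, note = "global q"))
}

#' Idealize a trace to quantal levels
#'
#' Assigns each frame the quantal level (0..`max_level`) whose ideal
#' amplitude `mu_0 + i * q` is nearest. With `hysteresis = TRUE` (default) a
#' transition out of the current level requires strictly crossing the
#' midpoint between adjacent level means: a frame exactly equidistant
#' between the current and a neighbouring level stays at the current level.
#' Without hysteresis, ties resolve to the lower level. No minimum dwell is
#' imposed unless `min_dwell_frames > 0`, in which case runs shorter than
#' the minimum are absorbed into the preceding level.
#'
#' @param trace a [fluorescence_trace()].
#' @param model a [fit_multi_gaussian()] or [quantal_model_global()] result
#'   with defined `baseline_mean` and `quantal_amplitude`.
#' @param max_level highest quantal level (default 4).
#' @param hysteresis logical (default TRUE).
#' @param min_dwell_frames optional minimum dwell, frames (default 0 = off).
#' @return an object of class `idealized_trace`: `levels` (integer per
#'   frame), `dwell_times` (named seconds at levels 0..max_level),
#'   `t_total` (s), `frame_rate`.
#' @export
idealize <- function(trace, model, max_level = 4L, hysteresis = TRUE,
                     min_dwell_frames = 0L) {
  stopifnot(inherits(trace, "fluorescence_trace"),
            inherits(model, "quantal_model"))
  q <- model$quantal_amplitude
  if (is.na(q) || q <= 0)
    stop("model has no defined positive quantal amplitude", call. = FALSE)
  mu0 <- model$baseline_mean
  v <- trace$values
  n <- length(v)
  mus <- mu0 + (0:max_level) * q

  m <- (v - mu0) / q
  nearest_lo <- pmin(pmax(ceiling(m - 0.5), 0L), max_level)  # ties to lower
  if (!hysteresis) {
    levels <- as.integer(nearest_lo)
  } else {
    levels <- integer(n)
    cur <- nearest_lo[1]
    levels[1] <- cur
    for (t in 2:max(n, 2)) {
      if (t > n) break
      d <- abs(v[t] - mus)
      best <- min(d)
      if (d[cur + 1L] > best) cur <- which.min(d) - 1L  # strict: ties stay
      levels[t] <- cur
    }
    if (n == 1L) levels <- levels[1]
  }
  if (min_dwell_frames > 0L && n > 1L) {
    r <- rle(levels)
    for (j in seq_along(r$lengths)[-1]) {
      if (r$lengths[j] < min_dwell_frames) r$values[j] <- r$values[j - 1L]
    }
    levels <- inverse.rle(r)
  }
  dwell <- tabulate(levels + 1L, nbins = max_level + 1L) / trace$frame_rate
  names(dwell) <- paste0("level", 0:max_level)
  structure(list(levels = as.integer(levels), dwell_times = dwell,
                 t_total = n / trace$frame_rate,
                 frame_rate = trace$frame_rate),
            class = "idealized_trace")
}

#' Sparklet activity NP_O from an idealized trace
#'
#' `NP_O = (T_level1 + 2 T_level2 + 3 T_level3 + 4 T_level4) / T_total`,
#' the dwell-time weighted channel count — algebraically the time-average
#' of the level sequence. Bounded by the number of quantal levels (4).
#'
#' @param ideal an [idealize()] result.
#' @return dimensionless NP_O in `[0, 4]`.
#' @export
compute_npo <- function(ideal) {
  stopifnot(inherits(ideal, "idealized_trace"))
  if (!is.finite(ideal$t_total) || ideal$t_total <= 0)
    stop("t_total must be positive", call. = FALSE)
  lev <- seq_along(ideal$dwell_times) - 1L
  sum(lev * ideal$dwell_times) / ideal$t_total
}

#' Sparklet sites per cell
#'
#' Total number of sparklet sites in a field divided by the number of cells
#' in that field.
#'
#' @param n_sites site count (>= 0).
#' @param n_cells cell count (> 0).
#' @return sites per cell.
#' @export
sites_per_cell <- function(n_sites, n_cells) {
  if (!is.finite(n_cells) || n_cells <= 0)
    stop("n_cells must be positive", call. = FALSE)
  if (!is.finite(n_sites) || n_sites < 0)
    stop("n_sites must be non-negative", call. = FALSE)
  n_sites / n_cells
}

#' Per-site analysis configuration
#'
#' @param max_levels maximum quantal level (default 4).
#' @param equal_spacing quantal (equal-spacing) constraint for the mixture
#'   fit (default TRUE).
#' @param quantal_mode `"fit"` to estimate q per trace from the all-points
#'   histogram, `"global"` to fix it at `global_q`.
#' @param global_q global quantal amplitude, dF/F0 (default 0.29).
#' @param hysteresis half-amplitude hysteresis in idealization (default TRUE).
#' @param bin_width histogram bin width; NULL = Freedman-Diaconis.
#' @param use_kalman run the trace Kalman filter before analysis
#'   (default FALSE: NP_O is computed on raw data).
#' @param kalman a [kalman_params()] (used when `use_kalman`).
#' @param min_dwell_frames optional minimum dwell for idealization.
#' @return a list of class `site_config`.
#' @export
site_config <- function(max_levels = 4L, equal_spacing = TRUE,
                        quantal_mode = c("fit", "global"), global_q = 0.29,
                        hysteresis = TRUE, bin_width = NULL,
                        use_kalman = FALSE, kalman = kalman_params(),
                        min_dwell_frames = 0L) {
  structure(list(max_levels = as.integer(max_levels),
                 equal_spacing = isTRUE(equal_spacing),
                 quantal_mode = match.arg(quantal_mode),
                 global_q = global_q, hysteresis = isTRUE(hysteresis),
                 bin_width = bin_width, use_kalman = isTRUE(use_kalman),
                 kalman = kalman,
                 min_dwell_frames = as.integer(min_dwell_frames)),
            class = "site_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Full per-site quantal analysis pipeline
#'
#' Runs histogram construction, mixture fitting (or global-q model),
#' idealization and NP_O on one trace, retaining all intermediates for
#' audit. Deterministic given the trace and configuration. Errors are
#' annotated with the failing stage.
#'
#' @param trace a [fluorescence_trace()].
#' @param config a [site_config()].
#' @return a list of class `sparklet_site`: `npo`, `q_hat`, `n_levels`,
#'   `t_total_s`, plus intermediates `histogram`, `model`, `ideal`,
#'   `config`, `filters_applied`.
#' @export
analyze_site <- function(trace, config = site_config()) {
  stopifnot(inherits(trace, "fluorescence_trace"),
            inherits(config, "site_config"))
  work <- if (config$use_kalman)
    .stage("kalman", kalman_filter_trace(trace, config$kalman)) else trace
  hist <- .stage("histogram", build_histogram(work, bin_width = config$bin_width))
  model <- if (config$quantal_mode == "global") {
    mu0 <- .stage("baseline", .baseline_from_hist(hist))
    quantal_model_global(mu0, config$global_q,
                         n_components = config$max_levels)
  } else {
    .stage("fit", fit_multi_gaussian(hist, max_levels = config$max_levels,
                                     equal_spacing = config$equal_spacing,
                                     q_init = config$global_q))
  }
  if (model$n_components == 0L || is.na(model$quantal_amplitude)) {
    n <- length(work$values)
    dwell <- c(n / work$frame_rate, rep(0, config$max_levels))
    names(dwell) <- paste0("level", 0:config$max_levels)
    ideal <- structure(list(levels = integer(n), dwell_times = dwell,
                            t_total = n / work$frame_rate,
                            frame_rate = work$frame_rate),
                       class = "idealized_trace")
  } else {
    ideal <- .stage("idealize",
                    idealize(work, model, max_level = config$max_levels,
                             hysteresis = config$hysteresis,
                             min_dwell_frames = config$min_dwell_frames))
  }
  npo <- .stage("npo", compute_npo(ideal))
  structure(list(npo = npo, q_hat = model$quantal_amplitude,
                 n_levels = model$n_components,
                 t_total_s = ideal$t_total,
                 histogram = hist, model = model, ideal = ideal,
                 config = config, filters_applied = work$filters_applied),
            class = "sparklet_site")
}

#' @export
print.sparklet_site <- function(x, ...) {
  cat(sprintf("<sparklet_site> NP_O=%.4f  q_hat=%s  levels=%d  T=%.1f s\n",
              x$npo,
              if (is.na(x$q_hat)) "NA" else sprintf("%.4f", x$q_hat),
              x$n_levels, x$t_total_s))
  invisible(x)
}
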