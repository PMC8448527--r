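# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (brute-force sums, closed forms, FFT) so that a
# green test means implementation and oracle agree from different routes.

# block-bootstrap standard error of the mean of an autocorrelated series
block_bootstrap_se <- function(x, block_len, n_boot = 200, seed = 99) {
  n <- length(x)
  n_blocks <- ceiling(n / block_len)
  starts_max <- n - block_len + 1L
  set.seed(seed)
  means <- replicate(n_boot, {
    s <- sample.int(starts_max, n_blocks, replace = TRUE)
    idx <- as.vector(outer(0:(block_len - 1L), s, "+"))[1:n]
    mean(x[idx])
  })
  stats::sd(means)
}

# brute-force trapezoid over (F/F0 - 1), abscissa in seconds
trapz_oracle <- function(values, frame_rate, start, end) {
  y <- values[start:end] - 1
  if (length(y) < 2) return(0)
  dt <- 1 / frame_rate
  s <- 0
  for (i in seq_len(length(y) - 1)) s <- s + (y[i] + y[i + 1]) / 2 * dt
  s
}

# brute-force nearest-level classifier (ties to the lower level)
nearest_level_oracle <- function(values, mu0, q, max_level = 4) {
  vapply(values, function(x) {
    d <- abs(x - (mu0 + (0:max_level) * q))
    which(d == min(d))[1] - 1L
  }, integer(1))
}

# single-frequency amplitude via discrete Fourier projection
sine_amplitude <- function(x, freq_hz, frame_rate) {
  t <- (seq_along(x) - 1) / frame_rate
  2 * sqrt(mean(x * sin(2 * pi * freq_hz * t))^2 +
           mean(x * cos(2 * pi * freq_hz * t))^2)
}

# mean of a 2-D Gaussian footprint (peak 1, SD sigma_um) over an n x n pixel
# box centred on the pixel whose centre is nearest the site position
psf_box_factor <- function(pos_um, pixel_size, sigma_um, n = 5) {
  ctr_px <- round(pos_um / pixel_size - 0.5)      # 0-based pixel indices
  half <- (n - 1) / 2
  vals <- outer(
    (ctr_px[1] - half):(ctr_px[1] + half),
    (ctr_px[2] - half):(ctr_px[2] + half),
    function(r, c) {
      d2 <- ((r + 0.5) * pixel_size - pos_um[1])^2 +
            ((c + 0.5) * pixel_size - pos_um[2])^2
      exp(-d2 / (2 * sigma_um^2))
    })
  mean(vals)
}

# convenience: seeded synthetic trace with known gating truth
make_synth_trace <- function(seed, n_channels = 4, p_o = 0.15, k_close = 25,
                             duration = 120, frame_rate = 30, q = 0.29,
                             noise_sd = 0.05) {
  k_open <- k_close * p_o / (1 - p_o)
  gp <- gating_params(n_channels, k_open, k_close, duration,
                      frame_rate = frame_rate, seed = seed)
  render_trace(simulate_open_counts(gp),
               render_params(quantal_amplitude = q, noise_sd = noise_sd),
               seed = seed + 1000L)
}
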