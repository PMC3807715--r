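# Shared fixtures, built in code at test time.

grid_freqs <- seq(2, 45, by = 0.5)

# A spectrum from an arbitrary density function of frequency.
spectrum_from <- function(fn, freqs = grid_freqs) {
  power_spectrum(freqs, fn(freqs))
}

# 1/f background with optional Gaussian bumps: list(c(center, sd, amp), ...)
bumpy_spectrum <- function(bumps = list(), bg = 10, floor = 0.2,
                           freqs = grid_freqs) {
  p <- bg / freqs + floor
  for (b in bumps) p <- p + b[3L] * exp(-(freqs - b[1L])^2 / (2 * b[2L]^2))
  power_spectrum(freqs, p)
}

# Multichannel sinusoid recording.
sine_recording <- function(freq_hz, seconds = 8, fs = 250, channels = 1,
                           amplitude = 10) {
  t <- seq(0, seconds - 1 / fs, by = 1 / fs)
  x <- amplitude * sin(2 * pi * freq_hz * t)
  eeg_recording(matrix(rep(x, channels), nrow = channels, byrow = TRUE), fs)
}

# White-noise epochs of the given count.
noise_epochs <- function(n_epochs, channels = 1, fs = 250, epoch_s = 2,
                         sd = 1) {
  lapply(seq_len(n_epochs), function(i) {
    matrix(stats::rnorm(channels * fs * epoch_s, sd = sd), nrow = channels)
  })
}

# Independent single-FFT periodogram oracle (one-sided density, Hanning),
# written separately from the package internals.
oracle_psd <- function(epochs, fs, fmin = 2, fmax = 45) {
  n <- ncol(epochs[[1L]])
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  acc <- NULL
  for (e in epochs) {
    per_ch <- t(apply(e, 1L, function(x) {
      X <- fft(x * w)
      2 * Mod(X)^2 / (fs * sum(w^2))
    }))
    acc <- if (is.null(acc)) per_ch else acc + per_ch
  }
  acc <- acc / length(epochs)
  freqs_all <- (seq_len(n) - 1) * fs / n
  keep <- freqs_all >= fmin - 1e-9 & freqs_all <= fmax + 1e-9
  list(freqs = freqs_all[keep], power = colMeans(acc[, keep, drop = FALSE]))
}

# Small cohort data frame with known group structure.
toy_cohort <- function(n = c(6, 8, 6), seed = 1) {
  set.seed(seed)
  g <- factor(rep(c("low", "middle", "high"), n),
              levels = c("low", "middle", "high"))
  data.frame(
    id = seq_len(sum(n)),
    age = rnorm(sum(n), 70, 7),
    sex = rbinom(sum(n), 1, 0.6),
    education = rnorm(sum(n), 8, 3),
    group = g
  )
}

# Thickness dataset on a small grid with no planted effect.
null_thickness <- function(n_per_group = 18, nv_side = 10, noise_sd = 0.17,
                           seed = 1) {
  surf <- make_grid_surface(nv_side, nv_side)
  generate_thickness_dataset(
    surf, factor(rep(c("high", "low"), each = n_per_group)),
    noise_sd = noise_sd, seed = seed)
}
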