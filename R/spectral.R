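#' Resting EEG recording container
#'
#' Bundles a multichannel EEG sample matrix with its sampling rate, channel
#' labels and an optional epoch mask (indices of epochs retained after
#' artifact review).
#'
#' @param samples numeric matrix, channels x time, in microvolts.  A plain
#'   vector is treated as a single channel.
#' @param sampling_rate sampling frequency in Hz (> 0).
#' @param channel_labels optional character vector of 10-20 electrode names;
#'   defaults to `ch1`, `ch2`, ...
#' @param epoch_mask optional integer vector of 0-based epoch indices to
#'   retain when the recording is epoched; `NULL` keeps all epochs.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, sampling_rate, channel_labels = NULL,
                          epoch_mask = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("`samples` must be a numeric channels x time matrix")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive number")
  }
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(nrow(samples)))
  }
  if (length(channel_labels) != nrow(samples)) {
    stop("`channel_labels` length must match the number of channels")
  }
  if (!is.null(epoch_mask)) {
    epoch_mask <- as.integer(epoch_mask)
    if (any(epoch_mask < 0L)) stop("`epoch_mask` indices are 0-based, >= 0")
  }
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         channel_labels = channel_labels, epoch_mask = epoch_mask),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels, %.1f s at %g Hz\n",
              nrow(x$samples), ncol(x$samples) / x$sampling_rate,
              x$sampling_rate))
  invisible(x)
}

#' Split a recording into consecutive non-overlapping epochs
#'
#' Trailing samples that do not fill a whole epoch are discarded.  If the
#' recording carries an `epoch_mask`, only the listed epochs are returned.
#'
#' @param recording an [eeg_recording()].
#' @param epoch_seconds epoch duration in seconds (default 2).
#' @return A list of channels x samples matrices, one per retained epoch.
#' @export
epoch_eeg <- function(recording, epoch_seconds = 2) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$sampling_rate
  nper <- epoch_seconds * fs
  if (abs(nper - round(nper)) > 1e-8) {
    stop("epoch_seconds x sampling_rate must be an integer sample count")
  }
  nper <- as.integer(round(nper))
  ntot <- ncol(recording$samples)
  n_epochs <- ntot %/% nper
  if (n_epochs < 1L) {
    stop("insufficient data: recording shorter than one epoch")
  }
  keep <- seq_len(n_epochs) - 1L
  if (!is.null(recording$epoch_mask)) {
    if (any(recording$epoch_mask >= n_epochs)) {
      stop("epoch_mask contains indices beyond the last full epoch")
    }
    keep <- intersect(keep, recording$epoch_mask)
  }
  lapply(keep, function(e) {
    recording$samples[, (e * nper + 1L):((e + 1L) * nper), drop = FALSE]
  })
}

#' Power spectrum container
#'
#' @param freqs frequency grid in Hz; must be strictly increasing with
#'   uniform 0.5 Hz spacing.
#' @param power non-negative power density per bin (uV^2/Hz).
#' @param n_epochs number of epochs averaged into the estimate.
#' @return An object of class `power_spectrum`.
#' @export
power_spectrum <- function(freqs, power, n_epochs = NA_integer_) {
  if (length(freqs) != length(power)) {
    stop("`freqs` and `power` must have equal length")
  }
  if (length(freqs) > 1L) {
    d <- diff(freqs)
    if (any(d <= 0) || any(abs(d - 0.5) > 1e-8)) {
      stop("`freqs` must be strictly increasing with uniform 0.5 Hz spacing")
    }
  }
  if (any(!is.finite(power)) || any(power < 0)) {
    stop("`power` must be finite and non-negative")
  }
  structure(list(freqs = as.numeric(freqs), power = as.numeric(power),
                 n_epochs = n_epochs),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins, %.1f-%.1f Hz, %s epochs\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              ifelse(is.na(x$n_epochs), "?", x$n_epochs)))
  invisible(x)
}

hanning_window <- function(n) {
  0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))
}

# One-sided Welch periodogram of a channels x samples epoch matrix.
# Returns a channels x nfreq matrix of densities on the bins `bins`
# (1-based FFT bin indices, DC = 1).
epoch_periodogram <- function(epoch, fs, window, bins) {
  n <- ncol(epoch)
  xw <- sweep(epoch, 2L, window, `*`)
  ft <- t(stats::mvfft(t(xw)))           # channels x n complex
  scale <- 2 / (fs * sum(window^2))      # one-sided density normalisation
  (Mod(ft[, bins, drop = FALSE])^2) * scale
}

#' Channel-collapsed Welch power spectrum
#'
#' Computes one Hanning-windowed periodogram per 2-s epoch and channel,
#' averages over epochs, then averages over channels to a single
#' channel-collapsed spectrum on the 0.5 Hz grid.  One Welch segment per
#' epoch, no overlap.
#'
#' @param epochs list of channels x samples matrices, as from [epoch_eeg()].
#' @param sampling_rate sampling frequency in Hz.
#' @param fmin,fmax analysis range in Hz (defaults 2 and 45).
#' @return A [power_spectrum()] restricted to `[fmin, fmax]`.
#' @export
compute_psd <- function(epochs, sampling_rate, fmin = 2, fmax = 45) {
  if (length(epochs) < 1L) stop("at least one epoch is required")
  n <- ncol(epochs[[1L]])
  if (any(vapply(epochs, ncol, 1L) != n)) {
    stop("all epochs must have the same length")
  }
  if (any(vapply(epochs, function(e) any(!is.finite(e)), logical(1L)))) {
    stop("epochs contain NaN or non-finite samples")
  }
  df <- sampling_rate / n
  if (abs(df - 0.5) > 1e-8) {
    stop(sprintf(
      "epoch length yields %.3g Hz resolution; 0.5 Hz required (use 2-s epochs)",
      df))
  }
  freqs <- seq(fmin, fmax, by = 0.5)
  bins <- as.integer(round(freqs / df)) + 1L
  w <- hanning_window(n)
  acc <- 0
  for (e in epochs) acc <- acc + epoch_periodogram(e, sampling_rate, w, bins)
  per_channel <- acc / length(epochs)          # channels x bins
  power_spectrum(freqs, colMeans(per_channel), n_epochs = length(epochs))
}

#' Spectral stationarity control
#'
#' Averages the spectra of the first ten and last ten epochs and tests, by
#' one-way ANOVA on the per-epoch total power over the analysis range,
#' whether power differs between the beginning and the end of the trace.
#' With literally identical head and tail epochs the ANOVA is degenerate;
#' p is reported as 1 and flagged.
#'
#' @param epochs list of epochs (>= 20 required).
#' @param sampling_rate sampling frequency in Hz.
#' @param n_edge number of epochs per end (default 10).
#' @param fmin,fmax analysis range passed to [compute_psd()].
#' @return A list of class `stationarity_report` with elements `p_value`,
#'   `spectrum_head`, `spectrum_tail`, `head_power`, `tail_power`,
#'   `degenerate`.
#' @export
stationarity_check <- function(epochs, sampling_rate, n_edge = 10,
                               fmin = 2, fmax = 45) {
  if (length(epochs) < 2 * n_edge) {
    stop(sprintf("need at least %d epochs for the stationarity control",
                 2 * n_edge))
  }
  head_idx <- seq_len(n_edge)
  tail_idx <- seq(length(epochs) - n_edge + 1L, length(epochs))
  sp_head <- compute_psd(epochs[head_idx], sampling_rate, fmin, fmax)
  sp_tail <- compute_psd(epochs[tail_idx], sampling_rate, fmin, fmax)
  tot <- function(idx) {
    vapply(epochs[idx], function(e) {
      sum(compute_psd(list(e), sampling_rate, fmin, fmax)$power)
    }, numeric(1L))
  }
  head_power <- tot(head_idx)
  tail_power <- tot(tail_idx)
  x <- c(head_power, tail_power)
  g <- factor(rep(c("head", "tail"), each = n_edge))
  degenerate <- stats::var(x) < .Machine$double.eps * max(1, mean(x)^2)
  if (degenerate || identical(head_power, tail_power)) {
    p <- 1
    degenerate <- TRUE
  } else {
    fit <- stats::anova(stats::lm(x ~ g))
    p <- fit$`Pr(>F)`[1L]
    if (!is.finite(p)) {
      p <- 1
      degenerate <- TRUE
    }
  }
  structure(list(p_value = p, spectrum_head = sp_head, spectrum_tail = sp_tail,
                 head_power = head_power, tail_power = tail_power,
                 degenerate = degenerate),
            class = "stationarity_report")
}

#' Pooled stationarity control over a cohort
#'
#' Pools the per-epoch head/tail total powers of several recordings and runs
#' a single head-vs-tail one-way ANOVA.  The per-subject and pooled designs
#' are both defensible readings of a beginning-vs-end control; this is the
#' pooled one.
#'
#' @param epoch_lists list of per-subject epoch lists.
#' @param sampling_rate sampling frequency in Hz.
#' @param n_edge epochs per end and subject (default 10).
#' @return list with `p_value` and the pooled head/tail power vectors.
#' @export
stationarity_check_pooled <- function(epoch_lists, sampling_rate, n_edge = 10) {
  reports <- lapply(epoch_lists, stationarity_check, sampling_rate = sampling_rate,
                    n_edge = n_edge)
  head_power <- unlist(lapply(reports, `[[`, "head_power"))
  tail_power <- unlist(lapply(reports, `[[`, "tail_power"))
  x <- c(head_power, tail_power)
  g <- factor(rep(c("head", "tail"), c(length(head_power), length(tail_power))))
  if (stats::var(x) == 0) return(list(p_value = 1, head_power = head_power,
                                      tail_power = tail_power))
  fit <- stats::anova(stats::lm(x ~ g))
  list(p_value = fit$`Pr(>F)`[1L], head_power = head_power,
       tail_power = tail_power)
}

#' Common-average re-referencing
#'
#' Subtracts the instantaneous mean across channels from every channel,
#' mirroring off-line re-referencing of mastoid-referenced recordings to the
#' common average.
#'
#' @param recording an [eeg_recording()].
#' @return A re-referenced [eeg_recording()].
#' @export
rereference_common_average <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"))
  recording$samples <- sweep(recording$samples, 2L,
                             colMeans(recording$samples), `-`)
  recording
}
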