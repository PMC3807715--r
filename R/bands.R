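#' @name bands
#' @title Individually anchored frequency bands
#' @description
#' Resting-state spectra are anchored per subject on two frequencies: the
#' theta/alpha transition frequency (TF, the power minimum between the theta
#' and alpha peaks) and the individual alpha frequency (IAF, the strongest
#' peak in the extended 5-14 Hz alpha range).  The eight bands
#' delta..gamma are then laid out relative to TF and IAF, and band powers
#' are expressed relative to the mean power over the whole 2-45 Hz range.
NULL

grid_tol <- 1e-9

# Indices of interior local maxima of y (strict rise, non-strict fall so a
# plateau's left edge wins; ties therefore break toward lower frequency).
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0L))
  i <- 2:(n - 1L)
  i[y[i] > y[i - 1L] & y[i] >= y[i + 1L]]
}

# scipy-style topographic prominence of peak index p in y.
peak_prominence <- function(y, p) {
  n <- length(y)
  left_base <- y[p]
  i <- p
  lo <- y[p]
  while (i > 1L) {
    i <- i - 1L
    if (y[i] > y[p]) break
    lo <- min(lo, y[i])
  }
  left_base <- lo
  i <- p
  lo <- y[p]
  while (i < n) {
    i <- i + 1L
    if (y[i] > y[p]) break
    lo <- min(lo, y[i])
  }
  right_base <- lo
  y[p] - max(left_base, right_base)
}

#' Detect the individual alpha frequency (IAF)
#'
#' Returns the frequency of the highest interior local maximum of power in
#' the extended alpha range (5-14 Hz).  If the spectrum has no interior
#' local maximum there (e.g. a monotone 1/f spectrum), the global maximum
#' bin of the range is returned and flagged.  Ties break toward the lower
#' frequency and are flagged.
#'
#' @param spectrum a [power_spectrum()] covering 5-14 Hz.
#' @param range lower/upper bound of the search range (default `c(5, 14)`).
#' @return list with `iaf` (Hz) and `flags` (character).
#' @export
detect_iaf <- function(spectrum, range = c(5, 14)) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  if (all(spectrum$power == 0)) stop("all-zero spectrum: no alpha peak")
  in_rng <- which(spectrum$freqs >= range[1L] - grid_tol &
                  spectrum$freqs <= range[2L] + grid_tol)
  if (length(in_rng) < 1L) stop("spectrum does not cover the alpha range")
  flags <- character(0L)
  peaks <- local_maxima(spectrum$power)
  peaks <- peaks[peaks %in% in_rng]
  if (length(peaks) == 0L) {
    idx <- in_rng[which.max(spectrum$power[in_rng])]
    flags <- c(flags, "iaf_no_local_max")
  } else {
    best <- max(spectrum$power[peaks])
    cand <- peaks[spectrum$power[peaks] >= best - grid_tol * best]
    if (length(cand) > 1L) flags <- c(flags, "iaf_tie")
    idx <- cand[1L]
  }
  list(iaf = spectrum$freqs[idx], flags = flags)
}

#' Detect the theta/alpha transition frequency (TF)
#'
#' TF is the frequency of minimum power in the window
#' `[max(4, iaf - 6), iaf - 1]` below the detected alpha peak, i.e. the
#' trough where the theta and alpha spectra intersect.  Ties break toward
#' the lower frequency.
#'
#' @param spectrum a [power_spectrum()].
#' @param iaf individual alpha frequency in Hz (must exceed 5).
#' @return list with `tf` (Hz) and `flags`.
#' @export
detect_tf <- function(spectrum, iaf) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  if (iaf <= 5) {
    stop("TF search window is empty for iaf <= 5 (degenerate alpha peak)")
  }
  lo <- max(4, iaf - 6)
  hi <- iaf - 1
  win <- which(spectrum$freqs >= lo - grid_tol & spectrum$freqs <= hi + grid_tol)
  if (length(win) < 1L) stop("TF search window contains no bins")
  flags <- character(0L)
  pmin <- min(spectrum$power[win])
  cand <- win[spectrum$power[win] <= pmin + grid_tol * max(pmin, 1)]
  if (length(cand) > 1L) flags <- c(flags, "tf_tie")
  idx <- cand[1L]
  if (idx == win[1L] || idx == win[length(win)]) {
    flags <- c(flags, "tf_window_edge")
  }
  list(tf = spectrum$freqs[idx], flags = flags)
}

#' Detect individual beta and gamma peaks and their band boundaries
#'
#' Finds the three highest-prominence local maxima above the alpha3 band and
#' up to 45 Hz (IBF1, IBF2, IGF, in frequency order).  The beta1/beta2 and
#' beta2/gamma boundaries are the frequencies of minimum power between
#' consecutive peaks.  If fewer than three acceptable peaks exist, fixed
#' fallback boundaries (19.0 and 32.5 Hz, the grid values nearest the
#' whole-sample means) are used and flagged.
#'
#' @param spectrum a [power_spectrum()].
#' @param alpha3_hi upper edge of the alpha3 band in Hz.
#' @param prominence_frac minimum peak prominence as a fraction of the
#'   spectrum maximum (default 0.05).
#' @param fallback_boundaries boundaries used when detection fails
#'   (default `c(19, 32.5)`).
#' @return list with `ibf1`, `ibf2`, `igf`, `boundaries` (length 2) and
#'   `flags`.
#' @export
detect_high_peaks <- function(spectrum, alpha3_hi, prominence_frac = 0.05,
                              fallback_boundaries = c(19, 32.5)) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  if (alpha3_hi >= 45) stop("alpha3 upper edge must lie below 45 Hz")
  win <- which(spectrum$freqs > alpha3_hi + grid_tol &
               spectrum$freqs <= 45 + grid_tol)
  p <- spectrum$power
  peaks <- local_maxima(p)
  peaks <- peaks[peaks %in% win]
  if (length(peaks) > 0L) {
    prom <- vapply(peaks, function(i) peak_prominence(p, i), numeric(1L))
    peaks <- peaks[prom >= prominence_frac * max(p)]
    prom <- prom[prom >= prominence_frac * max(p)]
  }
  flags <- character(0L)
  if (length(peaks) < 3L) {
    flags <- c(flags, "high_peaks_fallback")
    b <- fallback_boundaries
    seg <- function(lo, hi) {
      s <- win[spectrum$freqs[win] >= lo - grid_tol &
               spectrum$freqs[win] < hi - grid_tol]
      s[which.max(p[s])]
    }
    i1 <- seg(alpha3_hi, b[1L]); i2 <- seg(b[1L], b[2L]); i3 <- seg(b[2L], 45.5)
    return(list(ibf1 = spectrum$freqs[i1], ibf2 = spectrum$freqs[i2],
                igf = spectrum$freqs[i3], boundaries = b, flags = flags))
  }
  ord <- order(prom, decreasing = TRUE)
  sel <- sort(peaks[ord[1:3]])
  trough <- function(i, j) {
    span <- i:j
    span[which.min(p[span])]
  }
  b1 <- spectrum$freqs[trough(sel[1L], sel[2L])]
  b2 <- spectrum$freqs[trough(sel[2L], sel[3L])]
  list(ibf1 = spectrum$freqs[sel[1L]], ibf2 = spectrum$freqs[sel[2L]],
       igf = spectrum$freqs[sel[3L]], boundaries = c(b1, b2), flags = flags)
}

#' Detect all anchor frequencies for one spectrum
#'
#' Convenience wrapper running [detect_iaf()], [detect_tf()],
#' [detect_high_peaks()] and the individual theta frequency (ITF, the power
#' maximum within the individual theta band `[tf - 2, tf)`).
#'
#' @param spectrum a [power_spectrum()].
#' @return An `anchor_frequencies` list: `tf`, `iaf`, `itf`, `ibf1`, `ibf2`,
#'   `igf`, `boundaries`, `flags`.
#' @export
detect_anchors <- function(spectrum) {
  a <- detect_iaf(spectrum)
  t <- detect_tf(spectrum, a$iaf)
  h <- detect_high_peaks(spectrum, a$iaf + 2)
  th <- which(spectrum$freqs >= t$tf - 2 - grid_tol &
              spectrum$freqs < t$tf - grid_tol)
  itf <- if (length(th)) spectrum$freqs[th[which.max(spectrum$power[th])]]
         else NA_real_
  structure(list(tf = t$tf, iaf = a$iaf, itf = itf,
                 ibf1 = h$ibf1, ibf2 = h$ibf2, igf = h$igf,
                 boundaries = h$boundaries,
                 flags = c(a$flags, t$flags, h$flags)),
            class = "anchor_frequencies")
}

#' Build the eight individual frequency bands from anchor frequencies
#'
#' Band layout relative to TF and IAF: delta `[TF-4, TF-2)`, theta
#' `[TF-2, TF)`, alpha1 `[TF, mid)`, alpha2 `[mid, IAF)` with
#' `mid = (TF+IAF)/2`, alpha3 `[IAF, IAF+2)`, beta1 `[IAF+2, b1)`, beta2
#' `[b1, b2)`, gamma `[b2, 45]` where `b1`, `b2` are the beta/gamma power
#' troughs (or their fallbacks).  Intervals are half-open on bin centers;
#' gamma is closed at 45 Hz.
#'
#' @param tf theta/alpha transition frequency in Hz, or an
#'   `anchor_frequencies` object.
#' @param iaf individual alpha frequency in Hz (ignored when `tf` is an
#'   `anchor_frequencies`).
#' @param boundaries beta1/beta2 and beta2/gamma boundaries (default
#'   `c(19, 32.5)` when not supplied by anchors).
#' @return An `individual_bands` object: named list of `c(lo, hi)` intervals.
#' @examples
#' build_bands(6.9, 10.9)  # whole-sample mean anchors
#' @export
build_bands <- function(tf, iaf = NULL, boundaries = c(19, 32.5)) {
  if (inherits(tf, "anchor_frequencies")) {
    anchors <- tf
    iaf <- anchors$iaf
    boundaries <- anchors$boundaries
    tf <- anchors$tf
  }
  if (!is.numeric(tf) || !is.numeric(iaf)) stop("tf and iaf must be numeric")
  if (tf >= iaf) stop("invalid anchors: tf must be below iaf")
  if (iaf + 2 > boundaries[1L] || boundaries[1L] >= boundaries[2L] ||
      boundaries[2L] > 45) {
    stop("invalid anchors: need iaf + 2 <= b1 < b2 <= 45")
  }
  mid <- (tf + iaf) / 2
  bands <- list(
    delta  = c(tf - 4, tf - 2),
    theta  = c(tf - 2, tf),
    alpha1 = c(tf, mid),
    alpha2 = c(mid, iaf),
    alpha3 = c(iaf, iaf + 2),
    beta1  = c(iaf + 2, boundaries[1L]),
    beta2  = c(boundaries[1L], boundaries[2L]),
    gamma  = c(boundaries[2L], 45)
  )
  structure(bands, class = "individual_bands")
}

#' @export
print.individual_bands <- function(x, ...) {
  for (b in names(x)) {
    cat(sprintf("%-7s %5.2f - %5.2f Hz\n", b, x[[b]][1L], x[[b]][2L]))
  }
  invisible(x)
}

band_bins <- function(spectrum, interval, closed_hi = FALSE) {
  f <- spectrum$freqs
  if (closed_hi) {
    which(f >= interval[1L] - grid_tol & f <= interval[2L] + grid_tol)
  } else {
    which(f >= interval[1L] - grid_tol & f < interval[2L] - grid_tol)
  }
}

#' Relative band powers and the alpha3/alpha2 ratio
#'
#' Per bin, relative power is the power density divided by the mean density
#' over the full 2-45 Hz grid; a band's relative power is the mean of its
#' bins' relative powers.  The alpha3/alpha2 ratio is the ratio of the two
#' band values.  Bins falling below `delta`'s lower edge belong to no band
#' but still enter the normalisation denominator.
#'
#' @param spectrum a [power_spectrum()] on the 2-45 Hz grid.
#' @param bands an [build_bands()] result.
#' @return A `band_power_profile`: list with `relative_power` (named
#'   numeric), `alpha3_alpha2`, `n_bins` (bins per band).
#' @export
relative_band_power <- function(spectrum, bands) {
  stopifnot(inherits(spectrum, "power_spectrum"),
            inherits(bands, "individual_bands"))
  denom <- mean(spectrum$power)
  if (denom <= 0) stop("spectrum has zero mean power")
  rel <- spectrum$power / denom
  vals <- numeric(0L)
  nb <- integer(0L)
  for (b in names(bands)) {
    idx <- band_bins(spectrum, bands[[b]], closed_hi = (b == "gamma"))
    if (length(idx) == 0L) {
      stop(sprintf("band '%s' contains no frequency bins on the grid", b))
    }
    vals[b] <- mean(rel[idx])
    nb[b] <- length(idx)
  }
  structure(list(relative_power = vals,
                 alpha3_alpha2 = vals[["alpha3"]] / vals[["alpha2"]],
                 n_bins = nb),
            class = "band_power_profile")
}

#' @export
print.band_power_profile <- function(x, ...) {
  print(round(x$relative_power, 4))
  cat(sprintf("alpha3/alpha2 = %.4f\n", x$alpha3_alpha2))
  invisible(x)
}

#' Full spectrum-to-ratio pipeline for one subject
#'
#' Detects anchors, builds bands and computes the band-power profile.
#'
#' @param spectrum a [power_spectrum()].
#' @return list with `anchors`, `bands`, `profile`.
#' @export
analyze_spectrum <- function(spectrum) {
  anchors <- detect_anchors(spectrum)
  bands <- build_bands(anchors)
  profile <- relative_band_power(spectrum, bands)
  list(anchors = anchors, bands = bands, profile = profile)
}
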