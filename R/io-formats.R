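#' @name io-formats
#' @title Minimal NIfTI-1 and EDF support
#' @description
#' Self-contained readers/writers for the two binary interchange formats the
#' pipeline touches: single-file NIfTI-1 volumes (`.nii`, `.nii.gz`) and
#' continuous EDF recordings.  Only the subset needed here is implemented:
#' uncompressed data arrays of common numeric types, no extensions, one
#' contiguous EDF signal block with a shared sampling rate.
NULL

nifti_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a 3-D volume as single-file NIfTI-1
#'
#' @param volume a [volume_image()] or 3-D numeric/logical array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_dims length-3 voxel edge lengths in mm; defaults to the
#'   cube root of `voxel_volume` in each direction.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(volume, path, voxel_dims = NULL) {
  if (inherits(volume, "volume_image")) {
    arr <- volume$voxels
    if (is.null(voxel_dims)) voxel_dims <- rep(volume$voxel_volume^(1 / 3), 3L)
  } else {
    arr <- volume
    if (is.null(voxel_dims)) voxel_dims <- c(1, 1, 1)
  }
  is_mask <- is.logical(arr)
  d <- dim(arr)
  stopifnot(length(d) == 3L)
  con <- nifti_con(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wc <- function(s, len) {
    raw <- charToRaw(s)
    writeBin(c(raw, raw(len - length(raw))), con)
  }
  wi(348L, 4L)                       # sizeof_hdr
  wc("", 10L); wc("", 18L)           # data_type, db_name
  wi(0L, 4L); wi(0L, 2L); wc("r", 1L); wc("", 1L)
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2L)   # dim
  wf(c(0, 0, 0)); wi(0L, 2L)         # intent
  wi(if (is_mask) 2L else 64L, 2L)   # datatype: uint8 / float64
  wi(if (is_mask) 8L else 64L, 2L)   # bitpix
  wi(0L, 2L)
  wf(c(1, voxel_dims, 1, 1, 1, 1))   # pixdim
  wf(352); wf(1); wf(0)              # vox_offset, scl_slope, scl_inter
  wi(0L, 2L); wc("", 1L); wc("\002", 1L)  # slice_end, slice_code, units mm
  wf(c(0, 0, 0, 0)); wi(c(0L, 0L), 4L)
  wc("neuroband", 80L); wc("", 24L)
  wi(c(0L, 1L), 2L)                  # qform_code 0, sform_code 1
  wf(c(0, 0, 0, 0, 0, 0))            # quatern/qoffset
  wf(c(voxel_dims[1L], 0, 0, 0))     # srow_x
  wf(c(0, voxel_dims[2L], 0, 0))     # srow_y
  wf(c(0, 0, voxel_dims[3L], 0))     # srow_z
  wc("", 16L)
  wc("n+1", 4L)
  writeBin(raw(4L), con)             # no extensions
  if (is_mask) {
    writeBin(as.integer(arr), con, size = 1L, endian = "little")
  } else {
    writeBin(as.numeric(arr), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' Read a single-file NIfTI-1 volume
#'
#' Supports datatypes uint8, int16, int32, float32 and float64, with
#' slope/intercept scaling.
#'
#' @param path `.nii` or `.nii.gz` path.
#' @return list with `data` (3-D array), `voxel_dims` (mm),
#'   `voxel_volume` (mm^3).
#' @export
read_nifti <- function(path) {
  con <- nifti_con(path, "rb")
  on.exit(close(con))
  ri <- function(n, size, signed = TRUE)
    readBin(con, "integer", n = n, size = size, signed = signed,
            endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4L,
                            endian = "little")
  hdr_size <- ri(1L, 4L)
  if (hdr_size != 348L) stop("not a NIfTI-1 file (unexpected header size)")
  readBin(con, "raw", n = 36L)                 # data_type..dim_info
  dim_field <- ri(8L, 2L)
  ndim <- dim_field[1L]
  d <- dim_field[2:(1L + max(ndim, 3L))]
  d <- d[seq_len(3L)]
  rf(3L); ri(1L, 2L)
  datatype <- ri(1L, 2L)
  ri(1L, 2L); ri(1L, 2L)
  pixdim <- rf(8L)
  vox_offset <- rf(1L)
  scl_slope <- rf(1L); scl_inter <- rf(1L)
  readBin(con, "raw", n = 348L - 120L)         # rest of the fixed header
  to_skip <- vox_offset - 348                  # extension flag + padding
  if (to_skip > 0) readBin(con, "raw", n = as.integer(to_skip))
  n <- prod(d)
  data <- switch(as.character(datatype),
    "2" = ri(n, 1L, signed = FALSE),
    "4" = ri(n, 2L),
    "8" = ri(n, 4L),
    "16" = rf(n),
    "64" = readBin(con, "numeric", n = n, size = 8L, endian = "little"),
    stop(sprintf("unsupported NIfTI datatype %d", datatype)))
  if (is.na(scl_slope) || scl_slope == 0) scl_slope <- 1
  data <- data * scl_slope + scl_inter
  voxel_dims <- abs(pixdim[2:4])
  list(data = array(data, d), voxel_dims = voxel_dims,
       voxel_volume = prod(voxel_dims))
}

edf_pad <- function(s, len) {
  s <- substr(s, 1L, len)
  paste0(s, strrep(" ", len - nchar(s)))
}

#' Write an EEG recording as EDF
#'
#' Continuous EDF with one data-record per second and a shared sampling
#' rate; samples are scaled to the int16 digital range from each channel's
#' physical min/max.
#'
#' @param recording an [eeg_recording()].
#' @param path output path.
#' @param record_seconds data-record duration (default 1 s).
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, record_seconds = 1) {
  stopifnot(inherits(recording, "eeg_recording"))
  x <- recording$samples
  fs <- recording$sampling_rate
  ns <- nrow(x)
  spr <- as.integer(round(fs * record_seconds))
  n_rec <- ncol(x) %/% spr
  if (n_rec < 1L) stop("recording shorter than one data record")
  x <- x[, seq_len(n_rec * spr), drop = FALSE]
  # physical min/max are stored as 8-char ASCII; round them outward to two
  # decimals and use the rounded values for the digitisation gain, so the
  # reader reconstructs with the exact same scale
  pmin_ <- floor(apply(x, 1L, min) * 100) / 100
  pmax_ <- ceiling(apply(x, 1L, max) * 100) / 100
  same <- pmax_ - pmin_ < 1e-12
  pmax_[same] <- pmin_[same] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s) writeBin(charToRaw(s), con)
  put(edf_pad("0", 8L))
  put(edf_pad("X X X X", 80L))
  put(edf_pad("Startdate X X X X", 80L))
  put(edf_pad("01.01.00", 8L)); put(edf_pad("00.00.00", 8L))
  put(edf_pad(as.character(256L * (ns + 1L)), 8L))
  put(edf_pad("", 44L))
  put(edf_pad(as.character(n_rec), 8L))
  put(edf_pad(format(record_seconds), 8L))
  put(edf_pad(as.character(ns), 4L))
  fld <- function(vals, len) for (v in vals) put(edf_pad(v, len))
  fld(recording$channel_labels, 16L)
  fld(rep("", ns), 80L)
  fld(rep("uV", ns), 8L)
  fld(formatC(pmin_, format = "f", digits = 2), 8L)
  fld(formatC(pmax_, format = "f", digits = 2), 8L)
  fld(rep(as.character(dmin), ns), 8L)
  fld(rep(as.character(dmax), ns), 8L)
  fld(rep("", ns), 80L)
  fld(rep(as.character(spr), ns), 8L)
  fld(rep("", ns), 32L)
  gain <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- round((x[ch, cols] - pmin_[ch]) * gain[ch] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read a continuous EDF recording
#'
#' Requires all signals to share one sampling rate (annotation channels are
#' dropped).  By default the recording is re-referenced to the common
#' average, mirroring the off-line re-referencing applied to
#' mastoid-referenced clinical recordings; disable with
#' `rereference = FALSE`.
#'
#' @param path EDF file path.
#' @param rereference apply common-average re-referencing (default TRUE).
#' @return an [eeg_recording()].
#' @export
read_edf <- function(path, rereference = TRUE) {
  con <- file(path, "rb")
  on.exit(close(con))
  gets <- function(len) {
    trimws(rawToChar(readBin(con, "raw", n = len)))
  }
  gets(8L); gets(80L); gets(80L); gets(8L); gets(8L)
  header_bytes <- as.integer(gets(8L))
  gets(44L)
  n_rec <- as.integer(gets(8L))
  rec_dur <- as.numeric(gets(8L))
  ns <- as.integer(gets(4L))
  fld <- function(len) vapply(seq_len(ns), function(i) gets(len), "")
  labels <- fld(16L)
  fld(80L); fld(8L)
  pmin_ <- as.numeric(fld(8L)); pmax_ <- as.numeric(fld(8L))
  dmin <- as.numeric(fld(8L)); dmax <- as.numeric(fld(8L))
  fld(80L)
  spr <- as.integer(fld(8L))
  fld(32L)
  keep <- !grepl("EDF Annotations", labels, fixed = TRUE)
  if (length(unique(spr[keep])) != 1L) {
    stop("mixed sampling rates are not supported")
  }
  fs <- spr[keep][1L] / rec_dur
  out <- matrix(0, nrow = sum(keep), ncol = n_rec * spr[keep][1L])
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  row_of <- cumsum(keep)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2L,
                     endian = "little")
      if (!keep[ch]) next
      cols <- ((r - 1L) * spr[ch] + 1L):(r * spr[ch])
      out[row_of[ch], cols] <- (dig - dmin[ch]) * gain[ch] + pmin_[ch]
    }
  }
  rec <- eeg_recording(out, fs, channel_labels = labels[keep])
  if (rereference) rec <- rereference_common_average(rec)
  rec
}
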