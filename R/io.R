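#' @name io-tables
#' @title Delimited-text readers and writers
#' @description
#' CSV/JSON interchange for spectra, cohort tables, band/anchor reports,
#' surfaces and thickness matrices.  All files are UTF-8, comma-separated,
#' `.` decimal; every writer round-trips through its reader without loss of
#' the represented precision.
NULL

#' @rdname io-tables
#' @param spectrum a [power_spectrum()].
#' @param path file path.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  df <- data.frame(freq_hz = sprintf("%.1f", spectrum$freqs),
                   power = formatC(spectrum$power, digits = 6, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname io-tables
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path)
  power_spectrum(df$freq_hz, df$power)
}

#' Read a delimited-text EEG recording
#'
#' One row per sample, one column per channel, header row of channel
#' labels.  Text input is assumed already referenced; no re-referencing is
#' applied (unlike [read_edf()]).
#'
#' @param path file path (comma- or whitespace-separated).
#' @param sampling_rate sampling frequency in Hz.
#' @param sep field separator (default `","`).
#' @return an [eeg_recording()].
#' @export
read_eeg_text <- function(path, sampling_rate, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep)
  eeg_recording(t(as.matrix(df)), sampling_rate,
                channel_labels = colnames(df))
}

#' Read an epoch mask file
#'
#' Plain text, one retained 0-based epoch index per line; `#` comments
#' allowed.
#'
#' @param path file path.
#' @return integer vector of retained epoch indices.
#' @export
read_epoch_mask <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  as.integer(lines[nzchar(lines)])
}

#' Write a subject's band/anchor report as JSON
#'
#' @param id subject identifier.
#' @param anchors an `anchor_frequencies` object.
#' @param bands an `individual_bands` object.
#' @param profile a `band_power_profile` object.
#' @param path output path.
#' @export
write_bands_json <- function(id, anchors, bands, profile, path) {
  obj <- list(
    id = id,
    anchors = list(tf = anchors$tf, iaf = anchors$iaf, itf = anchors$itf,
                   ibf1 = anchors$ibf1, ibf2 = anchors$ibf2,
                   igf = anchors$igf),
    bands = lapply(unclass(bands), function(b) list(lo = b[1L], hi = b[2L])),
    relative_power = as.list(profile$relative_power),
    alpha3_alpha2 = profile$alpha3_alpha2,
    flags = as.list(anchors$flags)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname io-tables
#' @param cohort cohort data.frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname io-tables
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("group" %in% names(df)) {
    df$group <- factor(df$group, levels = c("low", "middle", "high"))
  }
  df
}

#' Write a surface as a vertex table
#'
#' Columns: `id`, `area_mm2`, `neighbors` (semicolon-separated ids).
#'
#' @param surface a [make_grid_surface()]-style surface.
#' @param path output path.
#' @export
write_surface_csv <- function(surface, path) {
  df <- data.frame(
    id = seq_along(surface$vertex_area),
    area_mm2 = surface$vertex_area,
    neighbors = vapply(surface$adjacency, paste, "", collapse = ";")
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_surface_csv
#' @export
read_surface_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  adjacency <- lapply(strsplit(as.character(df$neighbors), ";", fixed = TRUE),
                      function(x) as.integer(x))
  list(vertex_area = df$area_mm2, adjacency = adjacency)
}

#' @rdname io-tables
#' @param clusters cluster table (data.frame from [group_contrast()]).
#' @export
write_cluster_csv <- function(clusters, path) {
  utils::write.csv(clusters, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
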