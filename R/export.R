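# Tidy CSV exporters for downstream tooling.

#' Export a PSD matrix as tidy CSV
#'
#' One row per channel and frequency bin: `subject`, `visit`, `channel`,
#' `freq_hz`, `dialect`, `log10_psd`.
#'
#' @param psd a `psd_matrix`.
#' @param path output CSV path.
#' @param subject,visit identifier columns.
#' @return `path`, invisibly.
#' @export
write_psd_csv <- function(psd, path, subject = "S001", visit = 1) {
  df <- data.frame(
    subject = subject, visit = visit,
    channel = rep(psd$channels, times = length(psd$freqs)),
    freq_hz = rep(psd$freqs, each = length(psd$channels)),
    dialect = psd$dialect,
    log10_psd = as.vector(psd$values),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export an ERP average as channels x time CSV
#'
#' First column `channel`, remaining columns the time axis in seconds.
#'
#' @param erp an `erp_average`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_erp_csv <- function(erp, path) {
  df <- data.frame(channel = erp$channels, erp$waveform, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[-1] <- format(erp$times, digits = 6)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a permutation null distribution as single-column CSV
#'
#' @param null a `null_distribution`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_null_csv <- function(null, path) {
  utils::write.csv(data.frame(max_tsize = null$max_tsizes), path,
                   row.names = FALSE)
  invisible(path)
}
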