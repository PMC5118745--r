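#' Build a synchronized ECG + SCG record
#'
#' A record is a tibble with one row per sample and columns `time` (seconds),
#' `ecg` (arbitrary voltage units) and `scg` (dorso-ventral sternal
#' acceleration, arbitrary units), carrying the sampling frequency and a
#' free-text label as attributes. It is the raw material of every stage of
#' the pipeline.
#'
#' @param ecg,scg numeric sample vectors of equal length, all finite.
#' @param fs sampling frequency in Hz (positive).
#' @param label free-text record id.
#' @return a tibble of class `scg_record` with columns `time`, `ecg`, `scg`.
#' @export
#' @examples
#' rec <- scg_record(ecg = sin(1:1000 / 10), scg = rnorm(1000), fs = 500)
#' record_fs(rec)
scg_record <- function(ecg, scg, fs, label = "record") {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive finite number", call. = FALSE)
  }
  ecg <- as.numeric(ecg)
  scg <- as.numeric(scg)
  if (length(ecg) != length(scg)) {
    stop("channel-length mismatch: ecg has ", length(ecg),
         " samples, scg has ", length(scg), call. = FALSE)
  }
  if (length(ecg) == 0L) stop("no samples", call. = FALSE)
  bad <- which(!is.finite(ecg) | !is.finite(scg))
  if (length(bad) > 0L) {
    stop("non-finite sample at row ", bad[1L], call. = FALSE)
  }
  out <- tibble::tibble(
    time = (seq_along(ecg) - 1) / fs,
    ecg = ecg,
    scg = scg
  )
  attr(out, "fs") <- as.numeric(fs)
  attr(out, "label") <- as.character(label)
  class(out) <- c("scg_record", class(out))
  out
}

#' @rdname scg_record
#' @param rec an `scg_record`.
#' @export
record_fs <- function(rec) {
  fs <- attr(rec, "fs")
  if (is.null(fs)) stop("not an scg_record: missing fs attribute", call. = FALSE)
  fs
}

#' @rdname scg_record
#' @export
record_label <- function(rec) attr(rec, "label") %||% "record"

# Rebuild the record class/attributes after a dplyr verb strips them.
as_scg_record <- function(df, fs, label = "record") {
  scg_record(df$ecg, df$scg, fs = fs, label = label)
}

#' Read a two-channel record from delimited text
#'
#' Expects one sample per row with numeric columns `ecg` and `scg`
#' (any extra columns are ignored). Plain CSV carries no metadata, so the
#' sampling frequency is supplied out-of-band.
#'
#' @param path file path to a CSV/TSV file.
#' @param fs sampling frequency in Hz.
#' @param delim field delimiter, default `","`.
#' @param label record id; defaults to the file name.
#' @return an [scg_record()].
#' @export
read_record <- function(path, fs, delim = ",", label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (nrow(df) == 0L) stop("no samples in ", path, call. = FALSE)
  if (!all(c("ecg", "scg") %in% names(df))) {
    stop("file must have columns 'ecg' and 'scg'; found: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  }
  ecg <- suppressWarnings(as.numeric(df$ecg))
  scg <- suppressWarnings(as.numeric(df$scg))
  bad <- which(!is.finite(ecg) | !is.finite(scg))
  if (length(bad) > 0L) {
    stop("non-finite or non-numeric sample at row ", bad[1L], " of ", path,
         call. = FALSE)
  }
  scg_record(ecg, scg, fs = fs, label = label)
}

#' Write a record to delimited text
#'
#' Writes columns `ecg,scg`, one sample per row; the inverse of
#' [read_record()] (up to numeric printing precision).
#'
#' @param rec an [scg_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_record <- function(rec, path) {
  readr::write_csv(tibble::tibble(ecg = rec$ecg, scg = rec$scg), path,
                   progress = FALSE)
  invisible(path)
}
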