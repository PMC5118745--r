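#' Per-beat fiducial annotations
#'
#' One row per beat with 1-based sample indices of the ECG R and Q peaks and
#' the SCG AO (aortic-valve opening), AC (aortic-valve closure) and MO
#' (mitral-valve opening) fiducials, plus the derived systolic time
#' intervals in milliseconds. Within every beat the physiological ordering
#' q <= ao < ac < mo must hold (NA fiducials are allowed for beats the
#' pipeline could not annotate, e.g. the initialization beats).
#'
#' @param beats a data frame with integer columns `r`, `q`, `ao`, `ac`, `mo`
#'   (NA allowed for `q`/`ao`/`ac`/`mo`) and optional logical `flagged`.
#' @param fs sampling frequency in Hz.
#' @param validate check the ordering and range invariants (default TRUE).
#' @return a tibble of class `scg_annotations` with columns
#'   `beat`, `r`, `q`, `ao`, `ac`, `mo`, `pep_ms`, `lvet_ms`, `qs2_ms`,
#'   `flagged`.
#' @export
scg_annotations <- function(beats, fs, validate = TRUE) {
  stopifnot(is.numeric(fs), fs > 0)
  beats <- tibble::as_tibble(beats)
  for (col in c("r", "q", "ao", "ac", "mo")) {
    if (!col %in% names(beats)) beats[[col]] <- NA_integer_
    beats[[col]] <- as.integer(beats[[col]])
  }
  if (!"flagged" %in% names(beats)) beats$flagged <- FALSE
  out <- compute_sti(beats, fs = fs)
  out <- dplyr::mutate(out, beat = dplyr::row_number(), .before = 1)
  out <- out[, c("beat", "r", "q", "ao", "ac", "mo",
                 "pep_ms", "lvet_ms", "qs2_ms", "flagged")]
  attr(out, "fs") <- as.numeric(fs)
  class(out) <- c("scg_annotations", class(out))
  if (validate) validate_annotations(out)
  out
}

validate_annotations <- function(ann) {
  ok_order <- function(a, b) is.na(a) | is.na(b) | a < b
  with(ann, {
    if (any(!is.na(q) & !is.na(r) & q > r)) {
      stop("invariant violated: q must not follow r", call. = FALSE)
    }
    if (any(!is.na(q) & !is.na(ao) & q > ao)) {
      stop("invariant violated: q must not follow ao", call. = FALSE)
    }
    if (!all(ok_order(ao, ac))) {
      stop("invariant violated: ao < ac", call. = FALSE)
    }
    if (!all(ok_order(ac, mo))) {
      stop("invariant violated: ac < mo", call. = FALSE)
    }
    idx <- c(r, q, ao, ac, mo)
    if (any(idx[!is.na(idx)] < 1L)) {
      stop("invariant violated: indices must be >= 1", call. = FALSE)
    }
  })
  invisible(ann)
}

#' Derive systolic time intervals from fiducials
#'
#' PEP (pre-ejection period) is the Q-to-AO interval, LVET (left ventricular
#' ejection time) the AO-to-AC interval and QS2 (electro-mechanical systole)
#' the Q-to-AC interval, so QS2 = PEP + LVET exactly. Intervals are NA where
#' a needed fiducial is missing, and a beat with PEP = 0 (ao == q) is
#' flagged implausible.
#'
#' @param beats a data frame with columns `q`, `ao`, `ac` (sample indices).
#' @param fs sampling frequency in Hz.
#' @return `beats` with columns `pep_ms`, `lvet_ms`, `qs2_ms` (and `flagged`
#'   updated) appended/overwritten.
#' @export
#' @examples
#' compute_sti(data.frame(q = 1, ao = 51, ac = 201), fs = 500)
compute_sti <- function(beats, fs) {
  beats <- tibble::as_tibble(beats)
  if (!"flagged" %in% names(beats)) beats$flagged <- FALSE
  dplyr::mutate(
    beats,
    pep_ms  = (.data$ao - .data$q)  / fs * 1000,
    lvet_ms = (.data$ac - .data$ao) / fs * 1000,
    qs2_ms  = (.data$ac - .data$q)  / fs * 1000,
    flagged = .data$flagged | (!is.na(.data$pep_ms) & .data$pep_ms <= 0)
  )
}

#' Read / write annotation tables
#'
#' CSV dialect: header `beat,r,q,ao,ac,mo,pep_ms,lvet_ms,qs2_ms,flagged`,
#' one row per beat, 1-based integer sample indices, intervals printed with
#' 3 decimals. `read_annotations(write_annotations(a, p), fs)` is the
#' identity; files violating the per-beat ordering invariants are rejected.
#'
#' @param ann an [scg_annotations()] object.
#' @param path file path.
#' @param fs sampling frequency in Hz (not stored in the CSV).
#' @return `write_annotations` returns `path` invisibly; `read_annotations`
#'   returns an [scg_annotations()] object.
#' @export
write_annotations <- function(ann, path) {
  df <- tibble::as_tibble(ann)
  for (col in c("pep_ms", "lvet_ms", "qs2_ms")) {
    df[[col]] <- sprintf("%.3f", df[[col]])
    df[[col]][df[[col]] == "NA"] <- ""
  }
  readr::write_csv(df, path, progress = FALSE, na = "")
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path, fs) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          beat = readr::col_integer(),
                          r = readr::col_integer(), q = readr::col_integer(),
                          ao = readr::col_integer(), ac = readr::col_integer(),
                          mo = readr::col_integer(),
                          pep_ms = readr::col_double(),
                          lvet_ms = readr::col_double(),
                          qs2_ms = readr::col_double(),
                          flagged = readr::col_logical()
                        ))
  scg_annotations(df, fs = fs)
}
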