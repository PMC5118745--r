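#' Band-pass filter specification
#'
#' The preprocessing stage uses a 5th-order Butterworth band-pass per
#' channel: [1, 35] Hz for the SCG and [1, 100] Hz for the ECG. The same
#' design order is used on both channels so filtering introduces no
#' relative latency between them. Default application is zero-phase
#' (forward-backward), which removes group delay entirely for offline
#' annotation; a causal single-pass mode is kept for streaming experiments.
#'
#' @param order filter order per pass (default 5).
#' @param band_hz length-2 passband edges in Hz, low < high.
#' @param mode `"zero_phase"` (forward-backward) or `"causal"`.
#' @return a list of class `filter_spec`.
#' @export
filter_spec <- function(order = 5L, band_hz = c(1, 35),
                        mode = c("zero_phase", "causal")) {
  mode <- match.arg(mode)
  stopifnot(length(band_hz) == 2L, band_hz[1] > 0, band_hz[1] < band_hz[2],
            order >= 1)
  structure(list(order = as.integer(order), band_hz = as.numeric(band_hz),
                 mode = mode),
            class = "filter_spec")
}

#' Annotator configuration
#'
#' Collects every tunable parameter of the annotation pipeline. Defaults
#' are the generalized-15 operating point: 60 initialization beats, a
#' sliding-template depth of 15 beats, anchor fraction 0.2, and 20 ms
#' search tolerances (the tolerance region the grid search finds
#' insensitive). Physiological search ranges: AO is the highest SCG peak
#' 45-120 ms after Q (a relaxed PEP range); AC/MO are the highest peak and
#' lowest valley 240-350 ms after AO (a relaxed LVET range).
#'
#' @param n_it beats averaged into the initial template (default 60).
#' @param n_sl sliding-template depth in beats (default 15; must be
#'   between 1 and `n_it`).
#' @param s anchor fraction: the anchor (R or AO peak) sits at sample
#'   `floor(s*w) + 1` of every length-`w` segment (default 0.2).
#' @param ao_tol_ms half-width of the AO search window around the previous
#'   AO position, ms.
#' @param tol_ac_sl_ms,tol_mo_sl_ms template-domain tracking tolerances, ms.
#' @param tol_ac_ms,tol_mo_ms refinement tolerances on the raw segment, ms.
#' @param pep_range_ms AO search range after Q in the initial template, ms.
#' @param lvet_range_ms AC/MO search range after AO in the initial
#'   template, ms.
#' @param q_window_ms Q is the ECG-template minimum in this window before
#'   R, ms.
#' @param r_refine_ms half-width for refining integrated-signal R
#'   detections to the local ECG maximum, ms.
#' @param scg_filter,ecg_filter [filter_spec()]s for the two channels;
#'   `NULL` for `scg_filter` skips SCG filtering (used when noise is to be
#'   injected after the band-pass).
#' @param rpeak_detector optional replacement R-peak detector: any
#'   `function(ecg, fs)` returning strictly increasing sample indices.
#' @return a list of class `annotator_config`.
#' @export
annotator_config <- function(n_it = 60L, n_sl = 15L, s = 0.2,
                             ao_tol_ms = 20, tol_ac_sl_ms = 20,
                             tol_mo_sl_ms = 20, tol_ac_ms = 20,
                             tol_mo_ms = 20,
                             pep_range_ms = c(45, 120),
                             lvet_range_ms = c(240, 350),
                             q_window_ms = 80, r_refine_ms = 40,
                             scg_filter = filter_spec(5L, c(1, 35)),
                             ecg_filter = filter_spec(5L, c(1, 100)),
                             rpeak_detector = NULL) {
  stopifnot(n_it >= 2, n_sl >= 1, n_sl <= n_it, s > 0, s < 1,
            ao_tol_ms > 0, tol_ac_sl_ms > 0, tol_mo_sl_ms > 0,
            tol_ac_ms > 0, tol_mo_ms > 0,
            length(pep_range_ms) == 2L, length(lvet_range_ms) == 2L)
  structure(list(
    n_it = as.integer(n_it), n_sl = as.integer(n_sl), s = s,
    ao_tol_ms = ao_tol_ms, tol_ac_sl_ms = tol_ac_sl_ms,
    tol_mo_sl_ms = tol_mo_sl_ms, tol_ac_ms = tol_ac_ms,
    tol_mo_ms = tol_mo_ms,
    pep_range_ms = pep_range_ms, lvet_range_ms = lvet_range_ms,
    q_window_ms = q_window_ms, r_refine_ms = r_refine_ms,
    scg_filter = scg_filter, ecg_filter = ecg_filter,
    rpeak_detector = rpeak_detector
  ), class = "annotator_config")
}

#' Read an annotator configuration from YAML or JSON
#'
#' Keys mirror the arguments of [annotator_config()]; nested keys
#' `filter.scg.band`, `filter.ecg.band`, `filter.order`, `filter.mode`
#' populate the two [filter_spec()]s. Unknown keys are an error.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return an [annotator_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- raw
  args$filter <- NULL
  bad <- setdiff(names(args), names(formals(annotator_config)))
  if (length(bad) > 0L) {
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  filt <- raw$filter
  if (!is.null(filt)) {
    order <- filt$order %||% 5L
    mode <- filt$mode %||% "zero_phase"
    if (identical(mode, "zero_phase")) mode <- "zero_phase"
    if (!is.null(filt$scg$band)) {
      args$scg_filter <- filter_spec(order, unlist(filt$scg$band), mode)
    }
    if (!is.null(filt$ecg$band)) {
      args$ecg_filter <- filter_spec(order, unlist(filt$ecg$band), mode)
    }
  }
  do.call(annotator_config, args)
}
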