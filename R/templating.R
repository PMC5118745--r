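#' Segment a signal around anchor points
#'
#' Cuts one fixed-length window per anchor (R-peak or AO-peak), aligned so
#' that the anchor falls at sample `floor(s*w) + 1` of every row: each
#' segment starts `floor(s*w)` samples before its anchor and ends
#' `w - floor(s*w) - 1` samples after it. Anchors whose full window does
#' not fit inside the record are dropped and reported in the `dropped`
#' attribute.
#'
#' @param x numeric sample vector (typically the filtered SCG).
#' @param anchors strictly increasing 1-based anchor indices.
#' @param w segment length in samples (>= 2).
#' @param s anchor fraction in (0, 1); default 0.2.
#' @param anchor_kind `"R"` or `"AO"`, recorded for provenance.
#' @return a list of class `segment_matrix` with elements `data`
#'   (`n_beats x w` matrix), `anchor_pos` (`floor(s*w) + 1`), `w`, `s`,
#'   `anchor_kind`, `beat_start` (1-based start index of each row in `x`),
#'   `anchor` (the retained anchors) and attribute `dropped`.
#' @export
#' @examples
#' m <- segment_by_anchor(rnorm(200), anchors = 101, w = 50, s = 0.2)
#' m$anchor_pos  # 11: the anchor sits at the (floor(0.2*50)+1)th sample
segment_by_anchor <- function(x, anchors, w, s = 0.2,
                              anchor_kind = c("R", "AO")) {
  anchor_kind <- match.arg(anchor_kind)
  stopifnot(w >= 2, s > 0, s < 1)
  anchors <- as.integer(anchors)
  if (is.unsorted(anchors, strictly = TRUE)) {
    stop("anchors must be strictly increasing", call. = FALSE)
  }
  w <- as.integer(w)
  pre <- as.integer(floor(s * w))
  starts <- anchors - pre
  ends <- starts + w - 1L
  ok <- starts >= 1L & ends <= length(x)
  dropped <- anchors[!ok]
  if (!any(ok)) {
    stop("no anchor yields a complete window of length ", w, call. = FALSE)
  }
  starts <- starts[ok]
  data <- t(vapply(starts, function(s0) x[s0:(s0 + w - 1L)], numeric(w)))
  structure(list(data = data, anchor_pos = pre + 1L, w = w, s = s,
                 anchor_kind = anchor_kind, beat_start = starts,
                 anchor = anchors[ok]),
            dropped = dropped, class = "segment_matrix")
}

#' Ensemble-average segments into a template
#'
#' Arithmetic per-sample mean over the selected rows of a
#' [segment_by_anchor()] matrix. Averaging suppresses uncorrelated noise
#' (residual variance falls as sigma^2 / n) while the consistent
#' cardiac-cycle peaks are preserved.
#'
#' @param segments a `segment_matrix`.
#' @param rows row indices to average (default: all rows).
#' @return a list of class `scg_template` with elements `wave`,
#'   `anchor_pos`, `n_averaged` and an empty `landmarks` list.
#' @export
ensemble_average <- function(segments, rows = seq_len(nrow(segments$data))) {
  stopifnot(inherits(segments, "segment_matrix"))
  if (length(rows) == 0L) stop("empty row set", call. = FALSE)
  if (any(rows < 1L | rows > nrow(segments$data))) {
    stop("row index out of range", call. = FALSE)
  }
  wave <- colMeans(segments$data[rows, , drop = FALSE])
  new_template(wave, segments$anchor_pos, n_averaged = length(rows))
}

new_template <- function(wave, anchor_pos, n_averaged = 1L,
                         landmarks = list()) {
  if (length(landmarks) >= 3L &&
      !is.null(landmarks$ao) && !is.null(landmarks$ac) && !is.null(landmarks$mo)) {
    if (!(landmarks$ao < landmarks$ac && landmarks$ac < landmarks$mo)) {
      stop("template landmarks must satisfy AO < AC < MO", call. = FALSE)
    }
  }
  structure(list(wave = as.numeric(wave), anchor_pos = as.integer(anchor_pos),
                 n_averaged = as.integer(n_averaged), landmarks = landmarks),
            class = "scg_template")
}

#' Build the initial template and its landmarks
#'
#' Offline initialization stage. The first `n_it` detected beats are
#' segmented around their R-peaks (segment length `w` = rounded median RR
#' of those beats, anchor fraction `s`) and ensemble-averaged, for both
#' channels. Q is located in the ECG template; then in the SCG template
#' AO is the highest peak 45-120 ms after Q (relaxed PEP range), and
#' AC / MO are the highest peak and lowest valley 240-350 ms after AO
#' (relaxed LVET range). A template that is flat in a search window still
#' yields a landmark (leftmost tie) with a warning.
#'
#' @param scg,ecg filtered sample vectors.
#' @param r an [rpeak_series()] (or vector of R indices) with at least
#'   `cfg$n_it` beats.
#' @param fs sampling frequency in Hz.
#' @param cfg an [annotator_config()].
#' @return a list of class `initial_template`: `scg_template` (with
#'   landmarks `ao`, `ac`, `mo` in template coordinates), `ecg_template`,
#'   `q_pos`, `q_offset` (samples from Q to the R anchor), `lvet_it`
#'   (AC - AO in samples), `w`, `s`, `anchor_pos` and the `segments` used.
#' @export
build_initial_template <- function(scg, ecg, r, fs, cfg = annotator_config()) {
  r_idx <- if (inherits(r, "rpeak_series") || is.data.frame(r)) r$r else as.integer(r)
  if (length(r_idx) < cfg$n_it) {
    stop("insufficient beats for initialization: need ", cfg$n_it,
         ", found ", length(r_idx), call. = FALSE)
  }
  r_init <- r_idx[seq_len(cfg$n_it)]
  w <- round_half_up(stats::median(diff(r_init)))
  seg_scg <- segment_by_anchor(scg, r_init, w = w, s = cfg$s, anchor_kind = "R")
  seg_ecg <- segment_by_anchor(ecg, r_init, w = w, s = cfg$s, anchor_kind = "R")
  tpl_scg <- ensemble_average(seg_scg)
  tpl_ecg <- ensemble_average(seg_ecg)

  q_pos <- locate_q_in_template(tpl_ecg$wave, tpl_scg$anchor_pos, fs,
                                window_ms = cfg$q_window_ms)
  pep_w <- ms_to_samples(cfg$pep_range_ms, fs)
  ao <- window_argmax(tpl_scg$wave, q_pos + pep_w[1], q_pos + pep_w[2])
  lvet_w <- ms_to_samples(cfg$lvet_range_ms, fs)
  ac <- window_argmax(tpl_scg$wave, ao + lvet_w[1], ao + lvet_w[2])
  mo <- window_argmin(tpl_scg$wave, ao + lvet_w[1], ao + lvet_w[2])
  win <- tpl_scg$wave[(ao + lvet_w[1]):min(length(tpl_scg$wave), ao + lvet_w[2])]
  if (max(win) == min(win)) {
    warning("flat SCG template in the diastolic search window; ",
            "landmarks fall at window edges", call. = FALSE)
    mo <- ac + 1L
  }
  if (mo <= ac) {
    # lowest valley precedes highest peak: keep ordering by searching the
    # valley after AC only
    mo <- window_argmin(tpl_scg$wave, ac + 1L, ao + lvet_w[2])
  }
  tpl_scg$landmarks <- list(ao = ao, ac = ac, mo = mo)
  structure(list(
    scg_template = tpl_scg, ecg_template = tpl_ecg,
    q_pos = q_pos, q_offset = tpl_scg$anchor_pos - q_pos,
    lvet_it = ac - ao, w = w, s = cfg$s, anchor_pos = tpl_scg$anchor_pos,
    segments = seg_scg
  ), class = "initial_template")
}
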