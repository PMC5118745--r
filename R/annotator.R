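#' Track AO peaks across a record
#'
#' AO detection needs no template subtraction: the pre-ejection period
#' varies little beat to beat, so the first AO is the segment maximum in a
#' window of half-width `ao_tol_ms` around the initial-template AO
#' position, and every subsequent AO is the maximum around the previous
#' beat's AO (expressed in that beat's segment coordinates). Windows that
#' leave the segment are clipped with a warning. AO is tracked over the
#' initialization beats too, so the sliding window is fully seeded when
#' diastolic annotation starts.
#'
#' @param scg filtered SCG samples.
#' @param r R-peak indices (vector or [rpeak_series()]).
#' @param init an [build_initial_template()] result.
#' @param cfg an [annotator_config()].
#' @param fs sampling frequency in Hz.
#' @return tibble with columns `beat`, `r`, `ao` (absolute 1-based record
#'   indices) and `clipped`; beats whose R-segment falls off-record are
#'   absent (they are reported by [annotate_record()]).
#' @export
detect_ao_sequence <- function(scg, r, init, cfg, fs) {
  r_idx <- if (inherits(r, "rpeak_series") || is.data.frame(r)) r$r else as.integer(r)
  if (length(r_idx) == 0L) stop("empty beat list", call. = FALSE)
  seg <- segment_by_anchor(scg, r_idx, w = init$w, s = init$s, anchor_kind = "R")
  tol <- ms_to_samples(cfg$ao_tol_ms, fs)
  n <- nrow(seg$data)
  ao_seg <- integer(n)       # AO in segment coordinates
  clipped <- logical(n)
  prev <- init$scg_template$landmarks$ao
  for (i in seq_len(n)) {
    lo <- prev - tol
    hi <- prev + tol
    clipped[i] <- window_clipped(lo, hi, seg$w)
    ao_seg[i] <- window_argmax(seg$data[i, ], lo, hi)
    prev <- ao_seg[i]
  }
  if (any(clipped)) {
    warning(sum(clipped), " AO search window(s) clipped to segment bounds",
            call. = FALSE)
  }
  tibble::tibble(
    beat = match(seg$anchor, r_idx),
    r = seg$anchor,
    ao = seg$beat_start + ao_seg - 1L,
    clipped = clipped
  )
}

#' Seed the diastolic template track
#'
#' In AO-aligned segments the AO position `AO_T = floor(s*w) + 1` is the
#' same in every segment, so the diastolic track starts from the
#' initial-template intervals: `AC_T(0) = AO_T + LVET_IT` and
#' `MO_T(0) = AC_T(0) + (MO_IT - AC_IT)`.
#'
#' @param init a [build_initial_template()] result.
#' @return list with `ao_t`, `ac_t`, `mo_t` (template coordinates).
#' @export
init_template_track <- function(init) {
  lm <- init$scg_template$landmarks
  if (is.null(lm$ao) || is.null(lm$ac) || is.null(lm$mo)) {
    stop("initial template is missing AO/AC/MO landmarks", call. = FALSE)
  }
  ao_t <- init$anchor_pos
  ac_t <- ao_t + (lm$ac - lm$ao)
  mo_t <- ac_t + (lm$mo - lm$ac)
  if (!(ao_t < ac_t && ac_t <= mo_t)) {
    stop("degenerate initial landmarks: need AO_T < AC_T <= MO_T", call. = FALSE)
  }
  list(ao_t = ao_t, ac_t = ac_t, mo_t = mo_t)
}

#' Track AC and MO in the sliding template
#'
#' One step of the template-domain tracking recursion. The sliding
#' template is much cleaner than any single beat, so its AC/MO positions
#' move slowly: AC_T(i) is the maximum over
#' `[AC_T(i-1) - tol_ac_sl, MO_T(i-1) - tol_mo_sl]` and MO_T(i) the
#' minimum over `[AC_T(i), MO_T(i-1) + tol_mo_sl]` (the upper AC bound and
#' lower MO bound encode that the mitral valve opens after the aortic
#' valve closes). A window that degenerates after clipping keeps the
#' previous state and flags the beat.
#'
#' @param sliding_tpl an `scg_template` (ensemble of the previous `n_sl`
#'   AO-aligned segments).
#' @param prev list with `ao_t`, `ac_t`, `mo_t` from the previous beat.
#' @param cfg an [annotator_config()].
#' @param fs sampling frequency in Hz.
#' @return list with updated `ac_t`, `mo_t`, constant `ao_t`, and logical
#'   `flagged`.
#' @export
track_template_diastolic <- function(sliding_tpl, prev, cfg, fs) {
  wave <- sliding_tpl$wave
  tol_ac_sl <- ms_to_samples(cfg$tol_ac_sl_ms, fs)
  tol_mo_sl <- ms_to_samples(cfg$tol_mo_sl_ms, fs)
  res <- tryCatch({
    ac_t <- window_argmax(wave, prev$ac_t - tol_ac_sl, prev$mo_t - tol_mo_sl)
    mo_t <- window_argmin(wave, ac_t, prev$mo_t + tol_mo_sl)
    list(ao_t = prev$ao_t, ac_t = ac_t, mo_t = mo_t, flagged = FALSE)
  }, error = function(e) {
    list(ao_t = prev$ao_t, ac_t = prev$ac_t, mo_t = prev$mo_t, flagged = TRUE)
  })
  if (res$ac_t <= res$ao_t) res$flagged <- TRUE
  res
}

#' Refine AC and MO on the actual beat
#'
#' Final per-beat stage: with the template positions in hand, the true AC
#' is the maximum of the beat's own AO-aligned segment over
#' `[AC_T(i) - tol_ac, MO_T(i)]`, and MO is the minimum over
#' `[AC(i), MO_T(i) + tol_mo]` (the lower bound keeps MO after AC).
#' Windows are clipped to the segment with a flag.
#'
#' @param beat_segment numeric AO-aligned segment of the beat.
#' @param ac_t,mo_t template-coordinate landmarks for this beat.
#' @param cfg an [annotator_config()].
#' @param fs sampling frequency in Hz.
#' @return list with `ac`, `mo` (segment coordinates) and `flagged`.
#' @export
refine_diastolic <- function(beat_segment, ac_t, mo_t, cfg, fs) {
  tol_ac <- ms_to_samples(cfg$tol_ac_ms, fs)
  tol_mo <- ms_to_samples(cfg$tol_mo_ms, fs)
  n <- length(beat_segment)
  flag <- window_clipped(ac_t - tol_ac, mo_t, n)
  ac <- window_argmax(beat_segment, ac_t - tol_ac, mo_t)
  flag <- flag || window_clipped(ac, mo_t + tol_mo, n)
  mo <- window_argmin(beat_segment, ac, mo_t + tol_mo)
  if (mo == ac) {
    flag <- TRUE
    mo <- min(n, ac + 1L)
  }
  list(ac = ac, mo = mo, flagged = flag)
}

#' Annotate a full record
#'
#' The complete pipeline: band-pass both channels, detect R-peaks, build
#' the initial template and its AO/AC/MO landmarks, track AO through every
#' beat, then for each beat after the initialization block form the
#' sliding template from the previous `min(i-1, n_sl)` AO-aligned
#' segments, track AC/MO in the template and refine them on the beat
#' itself. Q per beat is the template Q-offset applied to each R. Beats
#' whose windows fall off-record are flagged, never silently dropped.
#'
#' @param rec an [scg_record()].
#' @param cfg an [annotator_config()].
#' @return an object of class `sti_annotation`: list with `beats` (an
#'   [scg_annotations()] tibble; AC/MO are NA for initialization beats),
#'   `init` (the initial template), `track` (per-beat template-landmark
#'   tibble), `config`, `fs`, `label`. Use [generics::tidy()] /
#'   [generics::glance()] / [ggplot2::autoplot()] on it.
#' @export
annotate_record <- function(rec, cfg = annotator_config()) {
  fs <- record_fs(rec)
  filt <- filter_record(rec, scg_spec = cfg$scg_filter, ecg_spec = cfg$ecg_filter)
  r <- if (is.null(cfg$rpeak_detector)) {
    detect_r_peaks(filt$ecg, fs)
  } else {
    rpeak_series(cfg$rpeak_detector(filt$ecg, fs), fs)
  }
  if (nrow(r) == 0L) stop("no R-peaks detected", call. = FALSE)
  if (nrow(r) < cfg$n_it + 1L) {
    stop("insufficient beats for initialization: need ", cfg$n_it + 1L,
         ", found ", nrow(r), call. = FALSE)
  }
  init <- build_initial_template(filt$scg, filt$ecg, r, fs, cfg)
  ao_tbl <- detect_ao_sequence(filt$scg, r, init, cfg, fs)

  # AO-aligned segmentation (same w and s; AO_T constant across segments)
  seg_ao <- segment_by_anchor(filt$scg, ao_tbl$ao, w = init$w, s = init$s,
                              anchor_kind = "AO")
  row_of_beat <- match(ao_tbl$ao, seg_ao$anchor)

  state <- init_template_track(init)
  n_beats <- nrow(ao_tbl)
  ac_abs <- mo_abs <- rep(NA_integer_, n_beats)
  flags <- ao_tbl$clipped
  track <- vector("list", n_beats)
  for (i in seq_len(n_beats)) {
    if (i <= cfg$n_it) next               # initialization block: AO/Q only
    ri <- row_of_beat[i]
    hist_rows <- row_of_beat[max(1L, i - cfg$n_sl):(i - 1L)]
    hist_rows <- hist_rows[!is.na(hist_rows)]
    if (is.na(ri) || length(hist_rows) == 0L) {
      flags[i] <- TRUE
      next
    }
    sl_tpl <- ensemble_average(seg_ao, hist_rows)
    state <- track_template_diastolic(sl_tpl, state, cfg, fs)
    ref <- refine_diastolic(seg_ao$data[ri, ], state$ac_t, state$mo_t, cfg, fs)
    ac_abs[i] <- seg_ao$beat_start[ri] + ref$ac - 1L
    mo_abs[i] <- seg_ao$beat_start[ri] + ref$mo - 1L
    flags[i] <- flags[i] || state$flagged || ref$flagged
    track[[i]] <- tibble::tibble(beat = i, ao_t = state$ao_t,
                                 ac_t = state$ac_t, mo_t = state$mo_t)
  }

  beats <- tibble::tibble(
    r = ao_tbl$r,
    q = ao_tbl$r - init$q_offset,
    ao = ao_tbl$ao,
    ac = ac_abs,
    mo = mo_abs,
    flagged = flags
  )
  # drop ordering-violating beats from annotation rather than erroring out
  bad <- with(beats, (!is.na(ac) & ao >= ac) | (!is.na(mo) & !is.na(ac) & ac >= mo))
  if (any(bad)) {
    beats$ac[bad] <- NA_integer_
    beats$mo[bad] <- NA_integer_
    beats$flagged[bad] <- TRUE
  }
  bad_ao <- with(beats, !is.na(ao) & ao <= q)
  if (any(bad_ao)) {
    beats$ao[bad_ao] <- NA_integer_
    beats$ac[bad_ao] <- NA_integer_
    beats$mo[bad_ao] <- NA_integer_
    beats$flagged[bad_ao] <- TRUE
  }
  structure(list(
    beats = scg_annotations(beats, fs = fs),
    init = init,
    track = dplyr::bind_rows(track),
    config = cfg,
    fs = fs,
    label = record_label(rec)
  ), class = "sti_annotation")
}

#' @export
print.sti_annotation <- function(x, ...) {
  ann <- x$beats
  n_ann <- sum(!is.na(ann$ac))
  cat("<sti_annotation> ", x$label, "\n", sep = "")
  cat("  beats: ", nrow(ann), " (", n_ann, " with diastolic annotation, ",
      sum(ann$flagged), " flagged)\n", sep = "")
  if (n_ann > 0) {
    cat(sprintf("  mean PEP %.1f ms, LVET %.1f ms, QS2 %.1f ms\n",
                mean(ann$pep_ms[!is.na(ann$ac)], na.rm = TRUE),
                mean(ann$lvet_ms, na.rm = TRUE),
                mean(ann$qs2_ms, na.rm = TRUE)))
  }
  invisible(x)
}
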