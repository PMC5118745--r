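#' Number of misclassified peaks
#'
#' A measured peak is misclassified when it lies more than `zeta_ms`
#' (default 2 ms, i.e. 1 sample at 500 Hz) from the paired true peak.
#' Pairing is by beat index; NA pairs are dropped.
#'
#' @param p_true,p_meas equal-length paired sample-index vectors.
#' @param zeta_ms tolerance in ms (converted to samples with the package
#'   rounding rule).
#' @param fs sampling frequency in Hz.
#' @return integer count.
#' @export
#' @examples
#' nmp(c(100, 200, 300), c(100, 202, 300), zeta_ms = 2, fs = 500)  # 1
nmp <- function(p_true, p_meas, zeta_ms = 2, fs = 500) {
  if (length(p_true) != length(p_meas)) {
    stop("length mismatch: ", length(p_true), " vs ", length(p_meas),
         call. = FALSE)
  }
  zeta <- ms_to_samples(zeta_ms, fs)
  d <- abs(p_true - p_meas)
  sum(d > zeta, na.rm = TRUE)
}

#' Fraction of peaks detected within a tolerance
#'
#' The complement of [nmp()]: `detection_accuracy(tol) == 1 - nmp(zeta)/n`
#' when `tol == zeta`. NA pairs count as misses.
#'
#' @inheritParams nmp
#' @param tol_ms tolerance in ms.
#' @return fraction in [0, 1].
#' @export
detection_accuracy <- function(p_true, p_meas, tol_ms = 2, fs = 500) {
  if (length(p_true) != length(p_meas)) {
    stop("length mismatch: ", length(p_true), " vs ", length(p_meas),
         call. = FALSE)
  }
  if (length(p_true) == 0L) return(NA_real_)
  tol <- ms_to_samples(tol_ms, fs)
  d <- abs(p_true - p_meas)
  sum(!is.na(d) & d <= tol) / length(d)
}

#' Bland-Altman agreement analysis
#'
#' Error is defined as `x_e = x_true - x_meas`; the bias is `mean(x_e)`
#' and the limits of agreement are `bias +/- 1.96 * SD(x_e)` with the
#' sample (n-1) standard deviation. The LoA width quantifies detection
#' robustness.
#'
#' @param x_true,x_meas paired value vectors (n >= 2 after NA removal).
#' @return an object of class `bland_altman`: list with `bias`,
#'   `loa_low`, `loa_high`, `loa_width`, `sd`, `n` and a tibble `pairs`
#'   (`mean`, `diff`) for plotting. Has [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()] methods.
#' @export
#' @examples
#' ba <- bland_altman(c(0, 0), c(1, -1))
#' ba$loa_high  # 1.96 * sqrt(2)
bland_altman <- function(x_true, x_meas) {
  if (length(x_true) != length(x_meas)) {
    stop("length mismatch", call. = FALSE)
  }
  ok <- !is.na(x_true) & !is.na(x_meas)
  x_true <- x_true[ok]
  x_meas <- x_meas[ok]
  if (length(x_true) < 2L) stop("need at least 2 pairs", call. = FALSE)
  xe <- x_true - x_meas
  bias <- mean(xe)
  s <- stats::sd(xe)
  structure(list(
    bias = bias, sd = s,
    loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
    loa_width = 2 * 1.96 * s, n = length(xe),
    pairs = tibble::tibble(mean = (x_true + x_meas) / 2, diff = xe)
  ), class = "bland_altman")
}

#' Inject Gaussian noise at a target SNR
#'
#' Adds white Gaussian noise to the SCG channel with variance
#' `signal_power / 10^(snr_db/10)`. The reference signal power is the
#' mean square of the band-pass-filtered SCG in both stages, so 0 dB
#' means equal powers in the band-limited sense. `stage = "pre_filtering"`
#' means the caller will band-pass afterwards (noise added to the raw
#' channel); `"post_filtering"` means the record is filtered here first
#' and noise is added after, in which case the annotator must be run with
#' `scg_filter = NULL` so it is not filtered again.
#'
#' @param rec an [scg_record()].
#' @param snr_db target signal-to-noise ratio in dB.
#' @param stage `"pre_filtering"` or `"post_filtering"`.
#' @param seed RNG seed: same seed, same noise.
#' @param scg_spec the band-pass used for the power reference (and for
#'   filtering in the post stage).
#' @return an [scg_record()] with a noisy SCG channel.
#' @export
add_noise <- function(rec, snr_db, stage = c("pre_filtering", "post_filtering"),
                      seed = 1L, scg_spec = filter_spec(5, c(1, 35))) {
  stage <- match.arg(stage)
  if (!is.finite(snr_db)) stop("snr_db must be finite", call. = FALSE)
  fs <- record_fs(rec)
  if (nrow(rec) == 0L) stop("empty channel", call. = FALSE)
  scg_f <- bandpass_filter(rec$scg, fs, scg_spec)
  p_sig <- mean(scg_f^2)
  sd_n <- sqrt(p_sig / 10^(snr_db / 10))
  noise <- withr::with_seed(as.integer(seed), stats::rnorm(nrow(rec), 0, sd_n))
  scg <- if (stage == "pre_filtering") rec$scg + noise else scg_f + noise
  scg_record(rec$ecg, scg, fs = fs, label = record_label(rec))
}

#' Annotate a record and score it against ground truth
#'
#' Convenience wrapper used by the noise study and grid search: runs
#' [annotate_record()], pairs detections with truth by beat (matching on
#' R-peaks within half an RR interval), and returns per-fiducial NMP,
#' accuracy and Bland-Altman summaries over the diastolic-annotated beats.
#'
#' @param rec an [scg_record()].
#' @param truth ground-truth tibble from [generate_record()] (or an
#'   [scg_annotations()]).
#' @param cfg an [annotator_config()].
#' @param zeta_ms misclassification threshold, ms.
#' @return an object of class `eval_report`: tibble with one row per
#'   fiducial (`ao`, `ac`, `mo`) and columns `n_beats`, `nmp`,
#'   `accuracy`, `ba_bias_ms`, `ba_loa_low_ms`, `ba_loa_high_ms`,
#'   `ba_loa_width_ms`, plus attributes `zeta_ms` and `annotation`.
#' @export
evaluate_annotation <- function(rec, truth, cfg = annotator_config(),
                                zeta_ms = 2) {
  ann <- annotate_record(rec, cfg)
  score_annotation(ann, truth, zeta_ms = zeta_ms)
}

#' @rdname evaluate_annotation
#' @param ann an `sti_annotation` from [annotate_record()].
#' @export
score_annotation <- function(ann, truth, zeta_ms = 2) {
  fs <- ann$fs
  beats <- ann$beats
  # pair by nearest true R-peak
  pair <- vapply(beats$r, function(ri) {
    j <- which.min(abs(truth$r - ri))
    if (abs(truth$r[j] - ri) <= 0.5 * stats::median(diff(truth$r))) j else NA_integer_
  }, integer(1))
  ok <- !is.na(pair)
  one <- function(name) {
    m <- beats[[name]][ok]
    t <- truth[[name]][pair[ok]]
    keep <- !is.na(m)
    n <- sum(keep)
    if (n < 2L) {
      return(tibble::tibble(fiducial = name, n_beats = n, nmp = NA_integer_,
                            accuracy = NA_real_, ba_bias_ms = NA_real_,
                            ba_loa_low_ms = NA_real_, ba_loa_high_ms = NA_real_,
                            ba_loa_width_ms = NA_real_))
    }
    ba <- bland_altman(t[keep] / fs * 1000, m[keep] / fs * 1000)
    tibble::tibble(
      fiducial = name, n_beats = n,
      nmp = nmp(t[keep], m[keep], zeta_ms, fs),
      accuracy = detection_accuracy(t[keep], m[keep], zeta_ms, fs),
      ba_bias_ms = ba$bias, ba_loa_low_ms = ba$loa_low,
      ba_loa_high_ms = ba$loa_high, ba_loa_width_ms = ba$loa_width
    )
  }
  out <- dplyr::bind_rows(one("ao"), one("ac"), one("mo"))
  attr(out, "zeta_ms") <- zeta_ms
  attr(out, "annotation") <- ann
  class(out) <- c("eval_report", class(out))
  out
}

#' Grid search over sliding-template parameters
#'
#' Runs the annotator over every combination of `n_sl`, `tol_ac_sl_ms`
#' and `tol_ac_ms` on each record and averages the AC-peak NMP per trial
#' (per record); the objective is the least NMP. Ties resolve to the
#' smallest `n_sl`, then smallest `tol_ac_sl_ms`, then smallest
#' `tol_ac_ms`. A grid point failing on every record is recorded as NA,
#' not fatal.
#'
#' @param records list of `list(record =, truth =)` pairs (as returned by
#'   [generate_record()]).
#' @param grid named list with numeric vectors `n_sl`, `tol_ac_sl_ms`,
#'   `tol_ac_ms` (all units explicit: beats and ms).
#' @param cfg_base base [annotator_config()] whose other parameters are
#'   held fixed.
#' @param zeta_ms misclassification threshold, ms.
#' @return list with `best` (the winning [annotator_config()]),
#'   `best_point` (one-row tibble) and `surface` (tibble with columns
#'   `n_sl`, `tol_ac_sl_ms`, `tol_ac_ms`, `nmp_per_trial`).
#' @export
grid_search <- function(records, grid, cfg_base = annotator_config(),
                        zeta_ms = 2) {
  stopifnot(length(records) > 0, all(c("n_sl", "tol_ac_sl_ms", "tol_ac_ms")
                                     %in% names(grid)))
  pts <- tidyr::expand_grid(n_sl = grid$n_sl,
                            tol_ac_sl_ms = grid$tol_ac_sl_ms,
                            tol_ac_ms = grid$tol_ac_ms)
  nmp_pt <- purrr::pmap_dbl(pts, function(n_sl, tol_ac_sl_ms, tol_ac_ms) {
    cfg <- cfg_base
    cfg$n_sl <- as.integer(n_sl)
    cfg$tol_ac_sl_ms <- tol_ac_sl_ms
    cfg$tol_ac_ms <- tol_ac_ms
    vals <- purrr::map_dbl(records, function(rt) {
      tryCatch({
        rep <- evaluate_annotation(rt$record, rt$truth, cfg, zeta_ms)
        as.numeric(rep$nmp[rep$fiducial == "ac"])
      }, error = function(e) NA_real_)
    })
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  })
  surface <- dplyr::mutate(pts, nmp_per_trial = nmp_pt)
  ranked <- dplyr::arrange(surface, .data$nmp_per_trial, .data$n_sl,
                           .data$tol_ac_sl_ms, .data$tol_ac_ms)
  ranked <- dplyr::filter(ranked, !is.na(.data$nmp_per_trial))
  if (nrow(ranked) == 0L) stop("every grid point failed", call. = FALSE)
  best_point <- ranked[1L, ]
  best <- cfg_base
  best$n_sl <- as.integer(best_point$n_sl)
  best$tol_ac_sl_ms <- best_point$tol_ac_sl_ms
  best$tol_ac_ms <- best_point$tol_ac_ms
  list(best = best, best_point = best_point, surface = surface)
}

#' Paired comparison of two configurations
#'
#' Two-sided Wilcoxon signed-rank test on paired per-record accuracies
#' (zero differences excluded, as in the standard signed-rank procedure).
#' If every difference is zero the test is undefined; p = 1 is reported
#' with `degenerate = TRUE`.
#'
#' @param acc_a,acc_b paired per-record accuracy vectors (n >= 5).
#' @return list with `statistic`, `p_value`, `degenerate`.
#' @export
compare_configs <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b)) stop("length mismatch", call. = FALSE)
  if (length(acc_a) < 5L) stop("need at least 5 paired records", call. = FALSE)
  d <- acc_a - acc_b
  if (all(d == 0)) {
    return(list(statistic = NA_real_, p_value = 1, degenerate = TRUE))
  }
  wt <- suppressWarnings(stats::wilcox.test(acc_a, acc_b, paired = TRUE,
                                            exact = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       degenerate = FALSE)
}
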