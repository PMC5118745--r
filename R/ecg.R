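#' Detect ECG R-peaks (Pan-Tompkins)
#'
#' Classic Pan-Tompkins chain: band-pass around the QRS energy band
#' (5-15 Hz), five-point derivative, squaring, 150 ms moving-window
#' integration, then adaptive dual thresholds on integrated-signal peaks
#' with a 200 ms refractory period and RR-driven search-back. Each
#' detection is finally refined to the local maximum of the input ECG
#' within +/- `refine_ms`, so the returned fiducials are morphological
#' R-peaks, not envelope peaks. Thresholds are adaptive, so detection
#' positions are invariant to amplitude scaling.
#'
#' @param ecg filtered ECG samples (at least ~3 s of signal).
#' @param fs sampling frequency in Hz.
#' @param refractory_ms minimum spacing between detections (default 200).
#' @param refine_ms half-width of the local-maximum refinement window
#'   (default 40).
#' @return tibble of class `rpeak_series` with column `r` (strictly
#'   increasing 1-based sample indices); empty, with a warning, if no QRS
#'   energy is found.
#' @export
detect_r_peaks <- function(ecg, fs, refractory_ms = 200, refine_ms = 40) {
  if (length(ecg) < 3 * fs) stop("signal too short: need at least 3 s", call. = FALSE)
  empty <- function(msg) {
    warning(msg, call. = FALSE)
    rpeak_series(integer(0), fs)
  }
  if (max(ecg) - min(ecg) <= 0 || stats::sd(ecg) == 0) {
    return(empty("no QRS energy found: flat ECG"))
  }

  # 1) QRS band-pass 5-15 Hz
  bp <- bandpass_filter(ecg, fs, filter_spec(3L, c(5, 15)))
  # 2) five-point derivative, gain fs/8
  h <- c(1, 2, 0, -2, -1) * fs / 8
  der <- as.numeric(stats::filter(c(rep(bp[1], 4), bp), h, sides = 1))[-(1:4)]
  # 3) squaring
  sq <- der^2
  # 4) moving-window integration, 150 ms
  nw <- max(1L, ms_to_samples(150, fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / nw, nw), sides = 1))
  mwi[is.na(mwi)] <- 0

  # candidate peaks of the integrated signal
  pk <- which(diff(sign(diff(mwi))) < 0) + 1L
  pk <- pk[mwi[pk] > 0]
  if (length(pk) == 0L) return(empty("no QRS energy found"))

  refr <- ms_to_samples(refractory_ms, fs)
  # initialize running signal/noise estimates from the first 2 s
  init <- mwi[seq_len(min(length(mwi), 2L * round(fs)))]
  spki <- max(init) * 0.5
  npki <- mean(init) * 0.5
  thr1 <- function() npki + 0.25 * (spki - npki)

  qrs <- integer(0)
  rr_avg <- NA_real_
  last_checked <- 0L
  for (p in pk) {
    if (length(qrs) > 0L && p - qrs[length(qrs)] < refr) next
    if (mwi[p] >= thr1()) {
      qrs <- c(qrs, p)
      spki <- 0.125 * mwi[p] + 0.875 * spki
      if (length(qrs) >= 2L) {
        rr <- diff(utils::tail(qrs, 9L))
        rr_avg <- mean(rr)
      }
    } else {
      npki <- 0.125 * mwi[p] + 0.875 * npki
      # search-back: if no QRS for 1.66 * average RR, accept the largest
      # skipped candidate above the lower threshold
      if (!is.na(rr_avg) && length(qrs) > 0L &&
          p - qrs[length(qrs)] > 1.66 * rr_avg) {
        gap <- pk[pk > qrs[length(qrs)] + refr & pk <= p]
        gap <- gap[mwi[gap] >= 0.5 * thr1()]
        if (length(gap) > 0L) {
          best <- gap[which.max(mwi[gap])]
          qrs <- c(qrs, best)
          qrs <- sort(unique(qrs))
          spki <- 0.25 * mwi[best] + 0.75 * spki
        }
      }
    }
  }
  if (length(qrs) == 0L) return(empty("no peaks found above threshold"))

  # refine to the local ECG maximum: the MWI peak trails the QRS by up to
  # the integration window, so search back over it on the (clean) QRS-band
  # signal first, then take the ECG maximum within +/- refine_ms of that
  half <- ms_to_samples(refine_ms, fs)
  r <- vapply(qrs, function(p) {
    coarse <- window_argmax(bp, p - nw, p + nw)
    window_argmax(ecg, coarse - half, coarse + half)
  }, integer(1))
  r <- sort(unique(r))
  # enforce refractory after refinement: keep the larger of any close pair
  if (length(r) > 1L) {
    keep <- rep(TRUE, length(r))
    for (i in 2:length(r)) {
      j <- max(which(keep[seq_len(i - 1L)]))
      if (r[i] - r[j] < refr) {
        if (ecg[r[i]] > ecg[r[j]]) keep[j] <- FALSE else keep[i] <- FALSE
      }
    }
    r <- r[keep]
  }
  rpeak_series(r, fs)
}

#' @rdname detect_r_peaks
#' @param r strictly increasing 1-based sample indices.
#' @export
rpeak_series <- function(r, fs) {
  r <- as.integer(r)
  if (is.unsorted(r, strictly = TRUE)) {
    stop("R-peak indices must be strictly increasing", call. = FALSE)
  }
  out <- tibble::tibble(r = r)
  attr(out, "fs") <- fs
  class(out) <- c("rpeak_series", class(out))
  out
}

#' Locate the Q-peak in an ECG template
#'
#' Q is taken as the minimum of the ensemble-averaged ECG template in the
#' `window_ms` (default 80 ms) window ending just before the R anchor;
#' ties resolve to the leftmost sample. 80 ms covers normal Q-R intervals.
#'
#' @param ecg_template numeric template waveform.
#' @param r_pos 1-based R anchor position within the template.
#' @param fs sampling frequency in Hz.
#' @param window_ms window length before R to search, ms.
#' @return 1-based index of Q within the template (`< r_pos`).
#' @export
locate_q_in_template <- function(ecg_template, r_pos, fs, window_ms = 80) {
  wl <- ms_to_samples(window_ms, fs)
  lo <- r_pos - wl
  if (lo < 1L) {
    stop("Q window extends before template start (need ", wl,
         " samples before the R anchor)", call. = FALSE)
  }
  window_argmin(ecg_template, lo, r_pos - 1L)
}
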