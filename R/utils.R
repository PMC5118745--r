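#' Round half away from zero
#'
#' Base `round()` rounds half to even; every millisecond-to-sample
#' conversion in this package instead rounds halves up, so that a 2 ms
#' tolerance at 500 Hz is exactly 1 sample.
#'
#' @param x numeric vector.
#' @return integer vector.
#' @keywords internal
round_half_up <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Convert milliseconds to samples
#'
#' Single conversion rule used throughout the package:
#' `round_half_up(ms * fs / 1000)`.
#'
#' @param ms durations in milliseconds.
#' @param fs sampling frequency in Hz.
#' @return integer sample counts.
#' @export
#' @examples
#' ms_to_samples(2, 500)   # 1 sample
#' ms_to_samples(45, 500)  # 22.5 ms*Hz -> 23
ms_to_samples <- function(ms, fs) {
  stopifnot(is.numeric(ms), is.numeric(fs), fs > 0)
  round_half_up(ms * fs / 1000)
}

#' Index of the maximum / minimum within a window, leftmost tie-break
#'
#' All fiducial searches in the annotator reduce to an argmax or argmin
#' over a clipped index window; ties are always resolved to the earliest
#' sample so the pipeline is deterministic.
#'
#' @param x numeric vector.
#' @param lo,hi inclusive 1-based window bounds; clipped to `[1, length(x)]`.
#' @return 1-based index into `x` of the leftmost extremum in the window.
#' @export
window_argmax <- function(x, lo, hi) {
  w <- clip_window(lo, hi, length(x))
  seg <- x[w[1]:w[2]]
  w[1] + which.max(seg) - 1L
}

#' @rdname window_argmax
#' @export
window_argmin <- function(x, lo, hi) {
  w <- clip_window(lo, hi, length(x))
  seg <- x[w[1]:w[2]]
  w[1] + which.min(seg) - 1L
}

# Clip an inclusive window to [1, n]; error if empty after clipping.
clip_window <- function(lo, hi, n) {
  lo2 <- max(1L, as.integer(lo))
  hi2 <- min(as.integer(n), as.integer(hi))
  if (hi2 < lo2) {
    stop("empty search window [", lo, ", ", hi, "] after clipping to [1, ", n, "]",
         call. = FALSE)
  }
  c(lo2, hi2)
}

# TRUE if the window had to be clipped (used to flag beats, not to abort).
window_clipped <- function(lo, hi, n) {
  lo < 1L || hi > n
}
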