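#' Inject a motion-artifact lobe into the SCG channel
#'
#' Adds a large Gaussian lobe to the SCG at a given offset after a beat's
#' AO, emulating a transient motion artifact that can masquerade as a
#' diastolic peak. Used to exercise the sliding template's
#' error-containment behaviour: a single corrupted beat may perturb the
#' template track, but the perturbation is averaged away within the
#' sliding-window depth.
#'
#' @param rec an [scg_record()].
#' @param at_sample 1-based sample index of the artifact centre.
#' @param amp lobe amplitude (same units as the SCG channel).
#' @param width_ms lobe SD in ms.
#' @return an [scg_record()] with the artifact added.
#' @export
inject_artifact <- function(rec, at_sample, amp = 1.5, width_ms = 10) {
  fs <- record_fs(rec)
  sd_s <- width_ms * fs / 1000
  n <- nrow(rec)
  j <- max(1L, floor(at_sample - 6 * sd_s)):min(n, ceiling(at_sample + 6 * sd_s))
  scg <- rec$scg
  scg[j] <- scg[j] + amp * exp(-((j - at_sample)^2) / (2 * sd_s^2))
  scg_record(rec$ecg, scg, fs = fs, label = record_label(rec))
}

#' Corrupt a random subset of beats with artifact lobes
#'
#' Drops one artifact lobe into the diastolic region (uniform offset after
#' AO) of each selected beat. With `rate` as the per-beat corruption
#' probability this emulates intermittent motion contamination.
#'
#' @param rec an [scg_record()].
#' @param truth ground-truth tibble from [generate_record()].
#' @param rate per-beat corruption probability.
#' @param offset_range_ms artifact offset after AO, ms (uniform).
#' @param amp,width_ms lobe parameters, see [inject_artifact()].
#' @param seed RNG seed.
#' @return list with `record` (corrupted) and `beats` (indices corrupted).
#' @export
corrupt_beats <- function(rec, truth, rate = 0.15,
                          offset_range_ms = c(200, 380),
                          amp = 1.5, width_ms = 10, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    hit <- which(stats::runif(nrow(truth)) < rate)
    offs <- stats::runif(length(hit), offset_range_ms[1], offset_range_ms[2])
  })
  fs <- record_fs(rec)
  for (k in seq_along(hit)) {
    at <- truth$ao[hit[k]] + ms_to_samples(offs[k], fs)
    if (at <= nrow(rec)) rec <- inject_artifact(rec, at, amp, width_ms)
  }
  list(record = rec, beats = hit)
}
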