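#' Specification of a synthetic ECG + SCG record
#'
#' The generator emulates the features of sternal-accelerometer recordings
#' the annotator must cope with: quasi-periodic beats with RR jitter and
#' respiratory sinus arrhythmia, one QRS complex per beat, an SCG systolic
#' complex whose largest positive extremum is the true AO, a smaller
#' diastolic complex giving the true AC (peak) and MO (adjacent valley),
#' slow sinusoidal drift of PEP and LVET, respiration-like amplitude
#' modulation of the SCG, and additive Gaussian noise at a controlled SNR.
#' Every fiducial is placed at an exact integer sample and returned as
#' ground truth. Mean PEP must lie in 45-120 ms and mean LVET in
#' 240-350 ms so the truth stays inside the annotator's physiological
#' search ranges.
#'
#' @param fs sampling frequency in Hz (default 500).
#' @param duration_s record length in seconds.
#' @param hr_bpm mean heart rate.
#' @param rr_jitter_pct per-beat RR coefficient of variation, percent.
#' @param rsa_depth_pct,rsa_freq_hz sinusoidal respiratory RR modulation:
#'   relative depth (percent) and frequency (Hz).
#' @param pep_ms,pep_drift_ms mean pre-ejection period and the amplitude
#'   of its slow sinusoidal drift, ms.
#' @param lvet_ms,lvet_drift_ms mean left-ventricular ejection time and
#'   its drift amplitude, ms.
#' @param drift_freq_hz frequency of the PEP/LVET drift sinusoids.
#' @param mo_after_ac_ms MO valley delay after AC.
#' @param qr_ms Q-to-R interval.
#' @param wavelet_freq_hz carrier of the systolic SCG complex (inside the
#'   1-35 Hz SCG band so filtering barely perturbs it).
#' @param wavelet_cycles carrier cycles within one envelope SD.
#' @param amp_mod_pct respiration amplitude modulation of the SCG, percent.
#' @param snr_db additive-noise SNR in dB; `Inf` for a clean record.
#' @param seed RNG seed; substreams for jitter, amplitude modulation and
#'   noise are derived from it so each randomness source is independently
#'   reproducible.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(fs = 500, duration_s = 180, hr_bpm = 60,
                           rr_jitter_pct = 2, rsa_depth_pct = 3,
                           rsa_freq_hz = 0.25,
                           pep_ms = 90, pep_drift_ms = 5,
                           lvet_ms = 300, lvet_drift_ms = 10,
                           drift_freq_hz = 0.05,
                           mo_after_ac_ms = 40, qr_ms = 25,
                           wavelet_freq_hz = 20, wavelet_cycles = 0.6,
                           amp_mod_pct = 10, snr_db = Inf, seed = 1L) {
  stopifnot(fs > 0, duration_s > 0, hr_bpm > 0)
  if (pep_ms < 45 || pep_ms > 120) {
    stop("mean pep_ms must lie in [45, 120] ms", call. = FALSE)
  }
  if (lvet_ms < 240 || lvet_ms > 350) {
    stop("mean lvet_ms must lie in [240, 350] ms", call. = FALSE)
  }
  structure(as.list(environment()), class = "synthetic_spec")
}

# independent substream seeds derived from the master seed (kept < 2^31)
substream_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + 7919L * as.integer(k)
}

#' Generate a per-beat RR series
#'
#' `RR(k) = 60/hr * (1 + rsa_depth * sin(2*pi*rsa_freq*t_k) + jitter_k)`,
#' with iid zero-mean Gaussian jitter (SD = `rr_jitter_pct`/100) and the
#' respiratory modulation evaluated at each beat's onset time. RR values
#' at or below 0.3 s (outside physiologic range) are an error.
#'
#' @param spec a [synthetic_spec()].
#' @param n_beats number of beats; default fills `duration_s`.
#' @return numeric vector of RR intervals in seconds.
#' @export
generate_rr_series <- function(spec,
                               n_beats = ceiling(spec$duration_s *
                                                 spec$hr_bpm / 60) + 2L) {
  rr0 <- 60 / spec$hr_bpm
  jitter <- withr::with_seed(substream_seed(spec$seed, 1L),
                             stats::rnorm(n_beats, 0, spec$rr_jitter_pct / 100))
  rr <- numeric(n_beats)
  t_k <- 0
  for (k in seq_len(n_beats)) {
    rr[k] <- rr0 * (1 + spec$rsa_depth_pct / 100 *
                      sin(2 * pi * spec$rsa_freq_hz * t_k) + jitter[k])
    t_k <- t_k + rr[k]
  }
  if (any(rr <= 0.3)) {
    stop("spec produces RR intervals <= 0.3 s; reduce jitter/RSA or raise RR",
         call. = FALSE)
  }
  rr
}

# Gaussian lobe centred at sample c0 (may be fractional), SD in samples.
gauss_lobe <- function(n, c0, sd) {
  i <- seq_len(n)
  out <- numeric(n)
  lo <- max(1L, floor(c0 - 6 * sd))
  hi <- min(n, ceiling(c0 + 6 * sd))
  if (hi >= lo) {
    j <- lo:hi
    out[j] <- exp(-((j - c0)^2) / (2 * sd^2))
  }
  out
}

# Gaussian-enveloped cosine centred at integer sample c0: its global
# maximum is exactly at c0 (envelope and carrier are both stationary there).
gabor_lobe <- function(n, c0, sd, f_norm) {
  i <- seq_len(n)
  out <- numeric(n)
  lo <- max(1L, floor(c0 - 6 * sd))
  hi <- min(n, ceiling(c0 + 6 * sd))
  if (hi >= lo) {
    j <- lo:hi
    out[j] <- exp(-((j - c0)^2) / (2 * sd^2)) * cos(2 * pi * f_norm * (j - c0))
  }
  out
}

#' Generate a synthetic record with ground truth
#'
#' Builds the two channels beat by beat. ECG: Gaussian P/Q/R/S/T lobes
#' with R at the beat time and Q at `R - qr_ms`. SCG: a Gaussian-windowed
#' cosine (carrier `wavelet_freq_hz`) centred exactly at the true AO
#' sample `q + PEP(k)`, a smaller positive lobe at the true AC
#' (`ao + LVET(k)`) and a negative lobe at the true MO
#' (`ac + mo_after_ac_ms`); PEP and LVET drift as slow sinusoids.
#' Respiration modulates SCG amplitude; independent Gaussian noise streams
#' bring each channel to `snr_db` (noise variance = clean channel power /
#' `10^(snr/10)`). The ground-truth tibble records every fiducial exactly
#' as placed.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `record` (an [scg_record()]) and `truth` (tibble with
#'   per-beat `r`, `q`, `ao`, `ac`, `mo` sample indices and true `pep_ms`,
#'   `lvet_ms`).
#' @export
generate_record <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  fs <- spec$fs
  n <- round(spec$duration_s * fs)
  rr <- generate_rr_series(spec)
  r_times <- 0.5 + cumsum(c(0, rr[-length(rr)]))   # first R at 0.5 s
  r_idx <- round_half_up(r_times * fs) + 1L
  keep <- r_idx + ms_to_samples(spec$lvet_ms + spec$pep_ms +
                                spec$mo_after_ac_ms + 120, fs) <= n &
          r_idx > ms_to_samples(150, fs)
  r_idx <- r_idx[keep]
  nb <- length(r_idx)
  if (nb < 2L) stop("record too short for the requested heart rate", call. = FALSE)

  t_beat <- (r_idx - 1) / fs
  pep_k <- spec$pep_ms + spec$pep_drift_ms *
    sin(2 * pi * spec$drift_freq_hz * t_beat)
  lvet_k <- spec$lvet_ms + spec$lvet_drift_ms *
    sin(2 * pi * spec$drift_freq_hz * t_beat + pi / 3)

  q_idx <- r_idx - ms_to_samples(spec$qr_ms, fs)
  ao_idx <- q_idx + ms_to_samples(pep_k, fs)
  ac_idx <- ao_idx + ms_to_samples(lvet_k, fs)
  mo_idx <- ac_idx + ms_to_samples(spec$mo_after_ac_ms, fs)

  ms <- function(x) x * fs / 1000  # fractional samples for lobe widths
  ecg <- numeric(n)
  scg <- numeric(n)
  amp <- 1 + spec$amp_mod_pct / 100 *
    sin(2 * pi * spec$rsa_freq_hz * t_beat +
          withr::with_seed(substream_seed(spec$seed, 2L),
                           stats::runif(1, 0, 2 * pi)))
  sd_sys <- spec$wavelet_cycles / spec$wavelet_freq_hz * fs
  f_norm <- spec$wavelet_freq_hz / fs
  for (k in seq_len(nb)) {
    # ECG: P, Q, R, S, T
    ecg <- ecg +
      0.15 * gauss_lobe(n, r_idx[k] - ms(160), ms(20)) -
      0.15 * gauss_lobe(n, q_idx[k], ms(5)) +
      1.00 * gauss_lobe(n, r_idx[k], ms(6)) -
      0.25 * gauss_lobe(n, r_idx[k] + ms(30), ms(6)) +
      0.30 * gauss_lobe(n, r_idx[k] + ms(250), ms(35))
    # SCG: systolic Gabor at AO, diastolic lobes at AC / MO
    scg <- scg + amp[k] * (
      1.00 * gabor_lobe(n, ao_idx[k], sd_sys, f_norm) +
      0.45 * gabor_lobe(n, ac_idx[k], ms(9), f_norm) -
      0.40 * gauss_lobe(n, mo_idx[k], ms(9)))
  }
  if (is.finite(spec$snr_db)) {
    noise <- withr::with_seed(substream_seed(spec$seed, 3L), {
      sd_e <- sqrt(mean(ecg^2) / 10^(spec$snr_db / 10))
      sd_s <- sqrt(mean(scg^2) / 10^(spec$snr_db / 10))
      list(ecg = stats::rnorm(n, 0, sd_e), scg = stats::rnorm(n, 0, sd_s))
    })
    ecg <- ecg + noise$ecg
    scg <- scg + noise$scg
  }
  truth <- tibble::tibble(
    beat = seq_len(nb), r = r_idx, q = q_idx, ao = ao_idx,
    ac = ac_idx, mo = mo_idx,
    pep_ms = (ao_idx - q_idx) / fs * 1000,
    lvet_ms = (ac_idx - ao_idx) / fs * 1000
  )
  list(record = scg_record(ecg, scg, fs = fs,
                           label = sprintf("synthetic_seed%d", spec$seed)),
       truth = truth)
}
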