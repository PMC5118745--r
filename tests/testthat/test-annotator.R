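test_that("AO tracking recovers constant and drifting PEP exactly", {
  gt <- cached_record(seed = 41, duration_s = 100)   # clean, drifting PEP
  fs <- 500
  filt <- filter_record(gt$record)
  r <- detect_r_peaks(filt$ecg, fs)
  cfg <- annotator_config()
  init <- build_initial_template(filt$scg, filt$ecg, r, fs, cfg)
  ao <- detect_ao_sequence(filt$scg, r, init, cfg, fs)
  m <- match(ao$r, gt$truth$r)
  expect_true(all(abs(ao$ao - gt$truth$ao[m]) <= 1))
  expect_true(!is.unsorted(ao$ao, strictly = TRUE))

  # steeper drift than the generator default: +1 sample per beat
  pep_fast <- generate_record(synthetic_spec(
    duration_s = 80, pep_drift_ms = 20, drift_freq_hz = 0.02, snr_db = Inf,
    seed = 42))
  filt2 <- filter_record(pep_fast$record)
  r2 <- detect_r_peaks(filt2$ecg, fs)
  init2 <- build_initial_template(filt2$scg, filt2$ecg, r2, fs,
                                  annotator_config(n_it = 30))
  ao2 <- detect_ao_sequence(filt2$scg, r2, init2,
                            annotator_config(n_it = 30), fs)
  m2 <- match(ao2$r, pep_fast$truth$r)
  expect_true(all(abs(ao2$ao - pep_fast$truth$ao[m2]) <= 1))
})

test_that("windowed extrema take the leftmost of tied values", {
  x <- c(0, 1, 0, 1, 0)
  expect_equal(window_argmax(x, 1, 5), 2L)
  expect_equal(window_argmin(x, 2, 4), 3L)
  expect_equal(window_argmax(rep(0, 10), 3, 7), 3L)
})

test_that("the template track is seeded from the initial-template intervals", {
  fake_init <- list(anchor_pos = 80L,
                    scg_template = list(landmarks = list(ao = 60L, ac = 210L,
                                                         mo = 222L)))
  st <- init_template_track(fake_init)
  expect_equal(st$ac_t, 230L)   # AO_T + LVET_IT = 80 + 150
  expect_equal(st$mo_t, 242L)   # AC_T(0) + (MO_IT - AC_IT)

  degen <- list(anchor_pos = 80L,
                scg_template = list(landmarks = list(ao = 60L, ac = 60L,
                                                     mo = 70L)))
  expect_error(init_template_track(degen), "degenerate")

  # generator default LVET 300 ms at 500 Hz -> 150 samples
  gt <- cached_record(seed = 41, duration_s = 100)
  ann <- annotate_record(gt$record)
  st2 <- init_template_track(ann$init)
  expect_lte(abs((st2$ac_t - st2$ao_t) - 150L), ms_to_samples(10, 500))
})

test_that("template tracking is a fixed point on a stationary template", {
  fs <- 500
  wave <- rep(0, 400)
  wave[230] <- 1; wave[245] <- -1
  tpl <- list(wave = wave, anchor_pos = 80L)
  cfg <- annotator_config()
  st <- list(ao_t = 80L, ac_t = 230L, mo_t = 245L)
  for (i in 1:5) {
    st <- track_template_diastolic(tpl, st, cfg, fs)
    expect_equal(st$ac_t, 230L)
    expect_equal(st$mo_t, 245L)
    expect_false(st$flagged)
  }
})

test_that("template tracking follows a moving AC lobe", {
  fs <- 500
  cfg <- annotator_config()
  st <- list(ao_t = 80L, ac_t = 230L, mo_t = 245L)
  pos <- 230L
  for (i in 1:8) {
    pos <- pos + 2L
    wave <- rep(0, 400); wave[pos] <- 1; wave[pos + 15L] <- -1
    st <- track_template_diastolic(list(wave = wave, anchor_pos = 80L),
                                   st, cfg, fs)
    expect_lte(abs(st$ac_t - pos), 2L)
  }
  expect_equal(st$ac_t, pos)
})

test_that("a degenerate tracking window keeps the previous state, flagged", {
  fs <- 500
  cfg <- annotator_config()
  st <- list(ao_t = 80L, ac_t = 395L, mo_t = 398L)
  wave <- rep(0, 120)  # template far shorter than the previous landmarks
  out <- track_template_diastolic(list(wave = wave, anchor_pos = 80L),
                                  st, cfg, fs)
  expect_true(out$flagged)
  expect_equal(out$ac_t, st$ac_t)
  expect_equal(out$mo_t, st$mo_t)
})

test_that("refinement is self-consistent and finds displaced lobes", {
  fs <- 500
  cfg <- annotator_config()
  seg <- rep(0, 400); seg[230] <- 1; seg[245] <- -1
  out <- refine_diastolic(seg, ac_t = 230L, mo_t = 245L, cfg, fs)
  expect_equal(out$ac, 230L)
  expect_equal(out$mo, 245L)

  seg2 <- rep(0, 400); seg2[227] <- 1; seg2[245] <- -1  # AC lobe 3 early
  out2 <- refine_diastolic(seg2, ac_t = 230L, mo_t = 245L, cfg, fs)
  expect_equal(out2$ac, 227L)

  # adversarial spike outside the AC search window is ignored
  seg3 <- seg
  seg3[310] <- 5   # far beyond mo_t
  seg3[200] <- 5   # before ac_t - tol_ac
  out3 <- refine_diastolic(seg3, ac_t = 230L, mo_t = 245L, cfg, fs)
  expect_equal(out3$ac, 230L)
})

test_that("compute_sti does the arithmetic and flags implausible beats", {
  out <- compute_sti(data.frame(q = 1, ao = 51, ac = 201), fs = 500)
  expect_equal(out$pep_ms, 100)
  expect_equal(out$lvet_ms, 300)
  expect_equal(out$qs2_ms, 400)

  zero <- compute_sti(data.frame(q = 51, ao = 51, ac = 201), fs = 500)
  expect_equal(zero$pep_ms, 0)
  expect_true(zero$flagged)

  na <- compute_sti(data.frame(q = 1, ao = NA, ac = 201), fs = 500)
  expect_true(is.na(na$pep_ms) && is.na(na$lvet_ms))
})

test_that("annotation is deterministic and fiducials are ordered", {
  gt <- cached_record(seed = 43, duration_s = 100, snr_db = 20)
  a <- annotate_record(gt$record)
  b <- annotate_record(gt$record)
  expect_identical(tibble::as_tibble(a$beats), tibble::as_tibble(b$beats))

  bt <- a$beats[!a$beats$flagged & !is.na(a$beats$ac), ]
  expect_true(all(bt$q <= bt$ao))
  expect_true(all(bt$ao < bt$ac))
  expect_true(all(bt$ac < bt$mo))
  expect_true(all(bt$qs2_ms == bt$pep_ms + bt$lvet_ms))
})

test_that("records shorter than the initialization block are rejected", {
  gt <- cached_record(seed = 44, duration_s = 30)
  expect_error(annotate_record(gt$record), "insufficient beats")
  expect_error(annotate_record(gt$record, annotator_config(n_it = 25)), NA)
})

test_that("per-beat STI recover the generator profiles", {
  gt <- cached_record(seed = 43, duration_s = 100, snr_db = 20)
  ann <- annotate_record(gt$record)
  b <- ann$beats
  m <- match(b$r, gt$truth$r)
  ok <- !is.na(b$ac) & !is.na(m)
  rms <- function(x) sqrt(mean(x^2))
  expect_lte(rms(b$lvet_ms[ok] - gt$truth$lvet_ms[m[ok]]), 2)
  expect_lte(rms(b$pep_ms[ok] - gt$truth$pep_ms[m[ok]]), 2.5)
})

test_that("the pipeline degenerates gracefully to n_sl = 1", {
  gt <- cached_record(seed = 43, duration_s = 100, snr_db = 20)
  ann <- annotate_record(gt$record, annotator_config(n_sl = 1))
  expect_gt(sum(!is.na(ann$beats$ac)), 20)
})

test_that("tidy/glance/autoplot work on annotation objects", {
  gt <- cached_record(seed = 43, duration_s = 100, snr_db = 20)
  ann <- annotate_record(gt$record)
  td <- generics::tidy(ann)
  expect_true(all(c("beat", "ao", "pep_ms") %in% names(td)))
  gl <- generics::glance(ann)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$hr_bpm, 60, tolerance = 0.05)
  expect_s3_class(ggplot2::autoplot(ann), "ggplot")
  expect_s3_class(ggplot2::autoplot(ann, what = "template"), "ggplot")
})
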