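test_that("segmentation places the anchor at floor(s*w)+1 in every row", {
  x <- as.numeric(1:200)
  m <- segment_by_anchor(x, anchors = 101, w = 50, s = 0.2)
  # window covers samples 91..140; the anchor is the 11th row sample
  expect_equal(m$anchor_pos, 11L)
  expect_equal(m$beat_start, 91L)
  expect_equal(m$data[1, ], x[91:140])
  expect_equal(m$data[1, m$anchor_pos], x[101])

  m2 <- segment_by_anchor(as.numeric(1:300), anchors = c(101, 181),
                          w = 100, s = 0.2)
  expect_equal(m2$beat_start, c(81L, 161L))
  expect_equal(m2$anchor_pos, 21L)
})

test_that("anchors without a complete window are dropped and reported", {
  x <- as.numeric(1:200)
  m <- segment_by_anchor(x, anchors = c(6, 101), w = 50, s = 0.2)
  expect_equal(nrow(m$data), 1L)
  expect_equal(attr(m, "dropped"), 6L)
  expect_error(segment_by_anchor(x, anchors = 6, w = 50, s = 0.2),
               "no anchor")
})

test_that("ensemble_average is the arithmetic mean with inherited anchor", {
  v <- sin(1:50)
  x <- rep(v, 4)
  m <- segment_by_anchor(x, anchors = c(11, 61, 111), w = 50, s = 0.2)
  tpl <- ensemble_average(m)
  expect_equal(tpl$wave, m$data[1, ])     # identical rows: mean == any row
  expect_equal(tpl$n_averaged, 3L)
  expect_equal(tpl$anchor_pos, m$anchor_pos)

  # symmetric noise cancels exactly
  n <- rnorm(50)
  m$data <- rbind(v + n, v - n)
  expect_equal(ensemble_average(m, 1:2)$wave, v)

  expect_error(ensemble_average(m, integer(0)), "empty row set")
})

test_that("averaging N rows suppresses iid noise variance as sigma^2/N", {
  withr::with_seed(42, {
    clean <- sin(2 * pi * (1:100) / 100)
    sigma <- 0.5
    for (N in c(20, 100)) {
      resid_var <- replicate(200, {
        rows <- matrix(rep(clean, N), nrow = N, byrow = TRUE) +
          matrix(rnorm(N * 100, 0, sigma), nrow = N)
        m <- structure(list(data = rows, anchor_pos = 21L, w = 100L, s = 0.2,
                            anchor_kind = "R", beat_start = rep(1L, N)),
                       class = "segment_matrix")
        mean((ensemble_average(m)$wave - clean)^2)
      })
      expect_equal(mean(resid_var), sigma^2 / N, tolerance = 0.25)
    }
  })
})

test_that("one-row average reproduces that beat's window exactly", {
  withr::with_seed(9, {
    x <- rnorm(1000)
    m <- segment_by_anchor(x, anchors = c(200, 500, 800), w = 120, s = 0.2)
    for (i in 1:3) {
      tpl <- ensemble_average(m, i)
      expect_equal(tpl$wave,
                   x[m$beat_start[i]:(m$beat_start[i] + m$w - 1L)])
    }
  })
})

test_that("a w-periodic signal yields identical rows and template", {
  w <- 80L
  x <- rep(cos(2 * pi * (1:w) / w), 10)
  anchors <- seq(2 * w + 17, 7 * w, by = w)
  m <- segment_by_anchor(x, anchors, w = w, s = 0.2)
  for (i in seq_len(nrow(m$data))) expect_equal(m$data[i, ], m$data[1, ])
  expect_equal(ensemble_average(m)$wave, m$data[1, ])
})

test_that("initial template landmarks recover generator ground truth", {
  gt <- cached_record(seed = 31, duration_s = 100)
  fs <- 500
  filt <- filter_record(gt$record)
  r <- detect_r_peaks(filt$ecg, fs)
  cfg <- annotator_config()
  init <- build_initial_template(filt$scg, filt$ecg, r, fs, cfg)
  lm <- init$scg_template$landmarks
  # defaults: PEP 90 ms (with +/-5 drift), LVET 300 ms (+/-10 drift)
  pep_it <- (lm$ao - init$q_pos) / fs * 1000
  lvet_it <- (lm$ac - lm$ao) / fs * 1000
  expect_lt(abs(pep_it - 90), 7)
  expect_lt(abs(lvet_it - 300), 12)
  expect_true(lm$ao < lm$ac && lm$ac < lm$mo)
  expect_equal(init$lvet_it, lm$ac - lm$ao)
  # w is the rounded median RR of the first n_it beats
  expect_equal(init$w, round(stats::median(diff(r$r[1:cfg$n_it]))))
})

test_that("crafted template lobes are landmarked exactly", {
  fs <- 500
  w <- 400L
  ecg_tpl <- rep(0, w); scg_tpl <- rep(0, w)
  anchor <- 81L                      # floor(0.2*400)+1
  q <- anchor - 13L
  ecg_tpl[q] <- -1
  ao <- q + 40L                      # 80 ms after Q, inside [45, 120] ms
  ac <- ao + 150L                    # 300 ms later
  mo <- ac + 10L
  scg_tpl[ao] <- 1; scg_tpl[ac] <- 0.5; scg_tpl[mo] <- -0.5
  q_hat <- locate_q_in_template(ecg_tpl, anchor, fs)
  expect_equal(q_hat, q)
  pep_w <- ms_to_samples(c(45, 120), fs)
  expect_equal(window_argmax(scg_tpl, q_hat + pep_w[1], q_hat + pep_w[2]), ao)
  lvet_w <- ms_to_samples(c(240, 350), fs)
  expect_equal(window_argmax(scg_tpl, ao + lvet_w[1], ao + lvet_w[2]), ac)
  expect_equal(window_argmin(scg_tpl, ao + lvet_w[1], ao + lvet_w[2]), mo)
})

test_that("too few beats abort initialization", {
  gt <- cached_record(seed = 31, duration_s = 100)
  filt <- filter_record(gt$record)
  r <- detect_r_peaks(filt$ecg, 500)
  expect_error(
    build_initial_template(filt$scg, filt$ecg, r$r[1:10], 500,
                           annotator_config()),
    "insufficient beats")
})

test_that("the sliding template equals a naive re-summation oracle", {
  gt <- cached_record(seed = 32, duration_s = 100, snr_db = 20)
  ann <- annotate_record(gt$record)
  cfg <- ann$config
  filt <- filter_record(gt$record)
  seg <- segment_by_anchor(filt$scg, ann$beats$ao[!is.na(ann$beats$ao)],
                           w = ann$init$w, s = cfg$s, anchor_kind = "AO")
  for (i in c(62, 75, 90)) {
    rows <- (i - cfg$n_sl):(i - 1L)
    tpl <- ensemble_average(seg, rows)
    naive <- colSums(seg$data[rows, , drop = FALSE]) / length(rows)
    expect_equal(tpl$wave, naive)
  }
})
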