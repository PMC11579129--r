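test_that("bad-channel detection flags each failure mode with its reason", {
  set.seed(7)
  n <- 4000
  dat <- matrix(rnorm(9 * n), 9, n)
  dat[2, ] <- 0.5                            # flat
  dat[5, ] <- dat[5, ] * 100                 # abnormal amplitude
  dat[7, ] <- sine_wave(50, duration_s = n / 2000)  # pure line noise
  dat[9, seq(1, n, by = 50)] <- 40           # >1% samples beyond 5 sd
  rec <- recording(dat, 2000)
  out <- detect_bad_channels(rec)
  expect_equal(out$report$reasons[2], "flat")
  expect_match(out$report$reasons[5], "amplitude")
  expect_match(out$report$reasons[7], "line_noise")
  expect_match(out$report$reasons[9], "outliers")
  expect_true(all(!out$report$flagged[c(1, 3, 4, 6, 8)]))
  expect_equal(out$good_mask, !out$report$flagged)
})

test_that("notch filtering removes stop bands and passes the rest", {
  fs <- 2000
  rec50 <- recording(rbind(sine_wave(50, fs, 10), sine_wave(10, fs, 10)), fs)
  out <- notch_filter(rec50)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(out$data[1, ]) / rms(rec50$data[1, ]), 0.05)
  expect_gt(rms(out$data[2, ]) / rms(rec50$data[2, ]), 0.95)

  # a 24 Hz harmonic (48 Hz) is also removed (interior, past edge transients)
  rec48 <- recording(matrix(sine_wave(48, fs, 10), 1), fs)
  mid <- 4000:16000
  expect_lt(rms(notch_filter(rec48)$data[1, mid]) / rms(rec48$data[1, mid]),
            0.05)

  bad <- recording(matrix(rnorm(2000), 1), 800)  # 50*8 = 400 = Nyquist
  expect_error(notch_filter(bad), "Nyquist")
})

test_that("common median reference zeroes the per-sample median", {
  rec <- recording(matrix(c(1, 2, 10, 1, 3, 10), 3), 1000)
  out <- common_median_reference(rec)
  expect_equal(out$data, matrix(c(-1, 0, 8, -2, 0, 7), 3))

  same <- recording(matrix(1:10, 5, 10, byrow = TRUE) * 0 + 3.3, 1000)
  expect_true(all(common_median_reference(same)$data == 0))

  # post-condition and exact idempotence (odd good-channel count)
  rec2 <- noise_recording(n_ch = 7, n_samp = 500, seed = 2)
  once <- common_median_reference(rec2)
  expect_equal(max(abs(apply(once$data, 2, median))), 0)
  expect_identical(common_median_reference(once)$data, once$data)

  # bad channels are untouched
  rec3 <- noise_recording(n_ch = 5, n_samp = 100, seed = 3)
  rec3$good_mask[4] <- FALSE
  out3 <- common_median_reference(rec3)
  expect_identical(out3$data[4, ], rec3$data[4, ])
  expect_error(common_median_reference(recording(matrix(1:4, 1), 100)),
               "at least 2")
})

test_that("band-pass filters pass in-band and reject out-of-band energy", {
  fs <- 2000
  x <- sine_wave(100, fs, 4)
  rec <- recording(matrix(x, 1), fs)
  rms <- function(x) sqrt(mean(x^2))
  expect_identical(bandpass_filter(rec, "unfiltered")$data, rec$data)
  expect_gt(rms(bandpass_filter(rec, c(64, 128))$data) / rms(x), 0.90)
  # steady-state rejection, clear of the edge response of the slow band
  mid <- 2001:6000
  expect_lt(rms(bandpass_filter(rec, c(1, 4))$data[1, mid]) / rms(x), 0.01)
  # in-band low-frequency tone passes whole
  s25 <- sine_wave(2.5, fs, 10)
  expect_gt(rms(bandpass_filter(recording(matrix(s25, 1), fs),
                                c(1, 4))$data) / rms(s25), 0.95)
  expect_error(bandpass_filter(rec, c(500, 1200)), "fs/2")
})

test_that("filtering is linear", {
  rec <- noise_recording(n_ch = 1, n_samp = 4000, seed = 9)
  scaled <- rec; scaled$data <- 3.7 * scaled$data
  f1 <- bandpass_filter(rec, c(8, 16))$data
  f2 <- bandpass_filter(scaled, c(8, 16))$data
  expect_equal(f2, 3.7 * f1, tolerance = 1e-9)
  n1 <- notch_filter(rec)$data
  n2 <- notch_filter(scaled)$data
  expect_equal(n2, 3.7 * n1, tolerance = 1e-9)
})

test_that("Morlet band power is flat for a centre-frequency sinusoid", {
  fs <- 2000
  freqs <- exp(seq(log(64), log(128), length.out = 5))
  x <- sine_wave(freqs[3], fs, 2)
  rec <- recording(rbind(x, 0 * x, 2 * x), fs)
  pw <- morlet_band_power(rec, c(64, 128))
  interior <- 1000:3000
  p1 <- pw$data[1, interior]
  expect_lt(sd(p1) / mean(p1), 0.10)
  expect_equal(max(pw$data[2, ]), 0)
  expect_equal(pw$data[3, interior], 4 * p1, tolerance = 1e-9)
  expect_error(morlet_band_power(rec, "unfiltered"), "finite band")
})

test_that("trial segmentation follows both schemes with half-open windows", {
  fs <- 2000
  rec <- recording(matrix(rnorm(2 * 30 * fs), 2), fs)
  ev <- data.frame(onset = c(10, 13, 16), duration = 1.5,
                   trial_type = "stimulus")
  ts <- segment_trials(rec, ev, "half_isi")
  expect_equal(dim(ts$epochs)[3], round(1.5 * fs))
  first_rest <- which(ts$label == "rest")[1]
  expect_equal(ts$onset_s[first_rest], 8.5)
  first_act <- which(ts$label == "active")[1]
  expect_equal(ts$onset_s[first_act], 10)
  # rest epoch is exactly the samples in [8.5, 10) s
  expect_identical(ts$epochs[first_rest, , ],
                   rec$data[, (round(8.5 * fs) + 1):(10 * fs)])

  tf <- segment_trials(rec, ev, "fixed_1p5s")
  expect_equal(tf$onset_s[tf$label == "rest"][1], 8.5)
  expect_equal(dim(tf$epochs)[3], 3000)

  # early onset: rest window before t = 0 is dropped, active kept
  ev2 <- data.frame(onset = c(0.2, 25), duration = 1.5, trial_type = "s")
  t2 <- segment_trials(rec, ev2, "fixed_1p5s")
  expect_false(any(t2$label == "rest" & t2$onset_s < 8))
  expect_true(any(t2$label == "active" & t2$onset_s == 0.2))

  short <- recording(matrix(rnorm(2 * 100), 2), fs)
  expect_error(segment_trials(short, data.frame(onset = c(10, 13),
                                                duration = 1,
                                                trial_type = "s")),
               "no valid trials")
})

test_that("the pipeline stage order is fixed and logged", {
  lay <- make_square_layout(2, 3, 3, 1)
  cfg <- quick_sim_config(seed = 3, duration_s = 8)
  ds <- generate_dataset(cfg, lay, n_trials = 2, isi_s = 3)
  dir <- withr::local_tempdir()
  write_recording(ds$recording, file.path(dir, "rec"))
  write_electrodes(lay, file.path(dir, "electrodes.tsv"))
  write_events(ds$events, file.path(dir, "events.tsv"))
  ac <- analysis_config(recording = file.path(dir, "rec"),
                        electrodes = file.path(dir, "electrodes.tsv"),
                        events = file.path(dir, "events.tsv"),
                        out_dir = file.path(dir, "out"),
                        bands = dyadic_bands()[c(3, 9), ],
                        min_pairs = 2)
  logs <- capture_messages(run_pipeline(ac))
  hits <- vapply(c("bad channels", "notch", "common median", "pairs",
                   "band 8-16", "pipeline complete"),
                 function(p) grep(p, logs)[1], numeric(1))
  expect_false(any(is.na(hits)))
  expect_true(all(diff(hits) > 0))
})
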