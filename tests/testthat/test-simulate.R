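test_that("conduction weight is the exponential kernel", {
  expect_identical(conduction_weight(0, 1), 1)
  expect_equal(conduction_weight(2.5, 2.5), exp(-1))
  expect_equal(conduction_weight(10 * 0.3, 0.3), exp(-10))
  expect_lt(conduction_weight(10 * 0.3, 0.3), 4.6e-5)
  d <- seq(0, 5, by = 0.25)
  expect_true(all(diff(conduction_weight(d, 1.7)) < 0))
  expect_error(conduction_weight(-1, 1), ">= 0")
  expect_error(conduction_weight(1, 0), "positive")
})

test_that("traveling waves carry the stated phase across sources", {
  lay <- make_square_layout(1, 2, 3, 1)
  cfg <- sim_config(duration_s = 0.5,
                    oscillations = list(oscillation(10, 1, 2)),
                    broadband = list(power_law_exponent = 2, amplitude = 0,
                                     spatial_correlation_length_mm = 0.5),
                    sensor_noise_sd = 0, seed = 1)
  f <- simulate_source_field(cfg, lay,
                             source_positions = rbind(c(0, 0), c(3, 0)))
  expect_equal(diff(f$oscillations[[1]]$phase), 2 * pi * 10 * 0.003 / 2)
})

test_that("a zero-amplitude configuration yields an all-zero field", {
  lay <- make_square_layout(2, 2, 1, 0.4)
  cfg <- sim_config(duration_s = 0.1, oscillations = list(),
                    broadband = list(power_law_exponent = 2, amplitude = 0,
                                     spatial_correlation_length_mm = 0.5),
                    source_spacing_mm = 2, sensor_noise_sd = 0, seed = 1)
  f <- simulate_source_field(cfg, lay)
  expect_true(all(source_series(f) == 0))
  rec <- sample_electrodes(f, lay, cfg)
  expect_true(all(rec$data == 0))
})

test_that("the simulation is deterministic given the seed", {
  lay <- make_square_layout(2, 2, 1, 0.4)
  cfg <- quick_sim_config(seed = 9, duration_s = 0.25)
  f1 <- simulate_source_field(cfg, lay)
  f2 <- simulate_source_field(cfg, lay)
  expect_identical(f1$broadband, f2$broadband)
  r1 <- sample_electrodes(f1, lay, cfg)
  r2 <- sample_electrodes(f2, lay, cfg)
  expect_identical(r1$data, r2$data)
  cfg2 <- quick_sim_config(seed = 10, duration_s = 0.25)
  f3 <- simulate_source_field(cfg2, lay)
  expect_false(identical(f1$broadband, f3$broadband))
})

test_that("broadband power falls with frequency as the stated power law", {
  lay <- make_square_layout(1, 2, 3, 1)
  cfg <- sim_config(duration_s = 4, oscillations = list(),
                    broadband = list(power_law_exponent = 2, amplitude = 1,
                                     spatial_correlation_length_mm = 0.1),
                    source_spacing_mm = 4, sensor_noise_sd = 0, seed = 12)
  f <- simulate_source_field(cfg, lay)
  x <- source_series(f)[1, ]
  sp <- Mod(fft(x))^2
  fbin <- seq(0, length(x) - 1) * cfg$fs_hz / length(x)
  band_pow <- function(lo, hi) mean(sp[fbin >= lo & fbin <= hi])
  # one octave up => ~4x less power for a 1/f^2 spectrum
  ratio <- band_pow(8, 16) / band_pow(32, 64)
  expect_gt(ratio, 8)
  expect_lt(ratio, 32)
})

test_that("a single centred source passes through electrodes unchanged", {
  lay <- electrode_layout("E1", 0, 0, pitch_mm = 1, exposed_diameter_mm = 0.5)
  cfg <- sim_config(duration_s = 0.25,
                    oscillations = list(oscillation(12, 1, 2)),
                    broadband = list(power_law_exponent = 2, amplitude = 0,
                                     spatial_correlation_length_mm = 0.5),
                    sensor_noise_sd = 0, seed = 2)
  f <- simulate_source_field(cfg, lay, source_positions = rbind(c(0, 0)))
  rec <- sample_electrodes(f, lay, cfg, n_subpoints = 1)
  expect_equal(rec$data[1, ], source_series(f)[1, ], tolerance = 1e-12)
})

test_that("simulated electrodes obey the sinusoid phase law", {
  # sources exactly at electrode centres with a tiny conduction length
  # isolate each electrode's plane-wave phase
  lay <- make_square_layout(1, 6, 3, 1)
  cfg <- sim_config(duration_s = 1,
                    oscillations = list(oscillation(10, 1, 2)),
                    broadband = list(power_law_exponent = 2, amplitude = 0,
                                     spatial_correlation_length_mm = 0.5),
                    conduction_lambda_mm = 0.05, sensor_noise_sd = 0, seed = 3)
  f <- simulate_source_field(cfg, lay,
                             source_positions = cbind(lay$x, lay$y))
  rec <- sample_electrodes(f, lay, cfg, n_subpoints = 1)
  for (j in 2:6) {
    dphi <- 2 * pi * 10 * (lay$x[j] - lay$x[1]) / 2000
    expect_equal(ndrms_pair(rec$data[1, ], rec$data[j, ]),
                 2 * abs(sin(dphi / 2)), tolerance = 1e-6)
  }
})

test_that("sensor-noise-only channels are independent white noise", {
  lay <- make_square_layout(2, 4, 3, 1)
  cfg <- sim_config(duration_s = 1, oscillations = list(),
                    broadband = list(power_law_exponent = 2, amplitude = 0,
                                     spatial_correlation_length_mm = 0.5),
                    source_spacing_mm = 3, sensor_noise_sd = 1, seed = 8)
  rec <- sample_electrodes(simulate_source_field(cfg, lay), lay, cfg)
  cm <- cor(t(rec$data))
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.1)
  pv <- ndrms_per_pair(rec, pair_distance_table(lay))
  expect_lt(abs(mean(pv$ndrms) - sqrt(2)), 0.05)
})

test_that("larger discs record more similar signals at matched IED", {
  mk <- function(dia, seed) {
    lay <- make_square_layout(2, 4, 3, dia)
    cfg <- sim_config(duration_s = 1.5,
                      oscillations = list(oscillation(10, 1, 2.5)),
                      broadband = list(power_law_exponent = 2, amplitude = 10,
                                       spatial_correlation_length_mm = 0.2),
                      conduction_lambda_mm = 0.4, source_spacing_mm = 0.2,
                      sensor_noise_sd = 0.1, seed = seed)
    rec <- sample_electrodes(simulate_source_field(cfg, lay), lay, cfg)
    pt <- pair_distance_table(lay)
    adj <- abs(pt$distance_mm - 3) < 1e-9
    ia <- match(pt$a[adj], rec$channel_id); ib <- match(pt$b[adj], rec$channel_id)
    cm <- cor(t(rec$data))
    mean(cm[cbind(ia, ib)])
  }
  r_small <- mk(0.2, 41)
  r_big <- mk(1.0, 41)
  expect_gte(r_big, r_small)
})

test_that("generate_dataset lays out events and reproduces byte-identically", {
  lay <- make_square_layout(2, 2, 3, 1)
  cfg <- quick_sim_config(seed = 6, duration_s = 32)
  ds <- generate_dataset(cfg, lay, n_trials = 10, isi_s = 3)
  expect_equal(nrow(ds$events), 10)
  expect_equal(unique(diff(ds$events$onset)), 3)
  ds2 <- generate_dataset(cfg, lay, n_trials = 10, isi_s = 3)
  expect_identical(ds$recording$data, ds2$recording$data)
  expect_identical(ds$events, ds2$events)

  short <- quick_sim_config(seed = 6, duration_s = 5)
  expect_error(generate_dataset(short, lay, n_trials = 10, isi_s = 3),
               "too short")
})

test_that("sim configs survive JSON and YAML round trips", {
  cfg <- sim_config(seed = 77, duration_s = 2.5,
                    task = list(channels = c(1, 2), freq_hz = 80,
                                amplitude = 3))
  for (ext in c(".json", ".yaml")) {
    path <- withr::local_tempfile(fileext = ext)
    write_sim_config(cfg, path)
    back <- read_sim_config(path)
    expect_equal(back$duration_s, cfg$duration_s)
    expect_equal(back$seed, cfg$seed)
    expect_equal(back$oscillations[[1]]$freq_hz, 10)
    expect_equal(back$task$amplitude, 3)
  }
})
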