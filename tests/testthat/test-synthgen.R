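test_that("cohort sampling is seeded, bounded and balanced", {
  cfg <- sim_config(n_fish = 16, seed = 1)
  co <- sample_cohort(cfg)
  expect_equal(nrow(co), 16)
  expect_identical(co, sample_cohort(cfg))  # deterministic on repeat call
  expect_true(all(co$base_eod_freq_hz >= 807 & co$base_eod_freq_hz <= 1151))
  expect_true(all(co$sbl_cm >= 7.6 & co$sbl_cm <= 10.4))
  expect_equal(sum(!co$responder), 1)  # exactly one non-responder by default
  expect_lte(abs(sum(co$preferred_side == "left") -
                   sum(co$preferred_side == "right")), 1)
  co2 <- sample_cohort(sim_config(n_fish = 16, seed = 2))
  expect_true(any(co2$theta != co$theta))
  expect_error(sim_config(n_fish = 0), "n_fish")
})

test_that("cohorts are extensible: fish parameters depend only on seed and index", {
  a <- sample_cohort(sim_config(n_fish = 4, seed = 9, n_nonresponders = 0))
  b <- sample_cohort(sim_config(n_fish = 8, seed = 9, n_nonresponders = 0))
  expect_equal(a$theta, b$theta[1:4])
  expect_equal(a$base_eod_freq_hz, b$base_eod_freq_hz[1:4])
})

test_that("degenerate rates pin the fish in its shelter", {
  cfg <- short_config(seed = 3, roam_rate_base = 0, roam_rate_hypoxic = 0,
                      excursion_rate = 0, baseline_leave_rate = 0,
                      n_nonresponders = 0)
  fish <- sample_cohort(cfg)[1, ]
  log <- simulate_trajectory(fish, cfg)
  s <- bin_intervals(log, cfg$protocol, cfg$geometry, bin_min = 2)
  expect_true(all(s$shelter_time == 100))
  expect_true(all(s$residence_hypoxic == 100))  # never leaves preferred side
  zones <- assign_zone(log$x_cm, log$y_cm, cfg$geometry)
  pref <- side_preference(zones[log$t_s < 240, ])
  expect_equal(pref$preferred_side, fish$preferred_side)
  expect_equal(pref$occupancy_pct, 100)
})

test_that("responders keep a strong baseline side preference", {
  cfg <- sim_config(n_fish = 16, seed = 1)
  co <- sample_cohort(cfg)
  occ <- vapply(1:16, function(i) {
    log <- simulate_trajectory(co[i, ], cfg)
    base <- log[log$t_s < cfg$protocol$baseline_min * 60, ]
    zones <- assign_zone(base$x_cm, base$y_cm, cfg$geometry)
    100 * mean(zones$zone == co$preferred_side[i])
  }, numeric(1))
  expect_true(all(occ >= 79))
  expect_gte(median(occ), 95)
})

test_that("a non-responder stays in hypoxia at the lowest DO step", {
  cfg <- short_config(seed = 7, n_fish = 1, n_nonresponders = 1)
  fish <- sample_cohort(cfg)[1, ]
  expect_false(fish$responder)
  s <- bin_intervals(simulate_trajectory(fish, cfg), cfg$protocol,
                     cfg$geometry, bin_min = 2)
  lowest <- s[s$interval_kind == "hold" & s$nominal_do == 10, ]
  base <- s[s$interval_id == "baseline", ]
  expect_gte(lowest$residence_hypoxic, base$residence_hypoxic - 15)
})

test_that("trajectories are continuous, in-bounds and protocol-consistent", {
  cfg <- short_config(seed = 2, n_fish = 1, n_nonresponders = 0)
  log <- simulate_trajectory(sample_cohort(cfg)[1, ], cfg)
  expect_true(all(in_arena(log$x_cm, log$y_cm, cfg$geometry)))
  step <- sqrt(diff(log$x_cm)^2 + diff(log$y_cm)^2)
  expect_lt(max(step), 10)  # bounded per-second step length
  sched <- protocol_schedule(cfg$protocol)
  do_h <- if (log_meta(log)$hypoxic_side == "left") log$do_left else log$do_right
  expect_lt(max(abs(do_h - sched$do_hypoxic)), 5 * cfg$do_noise_sd + 0.1)
  expect_identical(tibble::as_tibble(log),
                   tibble::as_tibble(simulate_trajectory(sample_cohort(cfg)[1, ], cfg)))
})

test_that("synthesised EOD tracks its Q10 temperature law", {
  # constant temperature, no noise: tracked frequency equals f0 within one bin
  cfg <- short_config(seed = 4, n_fish = 1, temperature_drift = 0,
                      eod_noise_sd = 0, eod_stride_s = 120,
                      n_nonresponders = 0)
  fish <- sample_cohort(cfg)[1, ]
  log <- simulate_trajectory(fish, cfg)
  rec <- simulate_eod(fish, log, cfg)
  track <- track_frequency(rec)
  bin <- attr(track, "bin_width_hz")
  expect_true(all(abs(track$freq_hz - fish$base_eod_freq_hz) <= bin))

  # linear cooling of 0.15 degC at Q10 = 1.55: ~0.7 % end-of-trial drop
  cfg2 <- short_config(seed = 4, n_fish = 1, temperature_drift = -0.15,
                       q10 = 1.55, eod_noise_sd = 0, eod_stride_s = 120,
                       n_nonresponders = 0)
  log2 <- simulate_trajectory(fish, cfg2)
  last_s <- cfg2$protocol$total_s - 1  # full drift reached at trial end
  rec2 <- simulate_eod(fish, log2, cfg2, seconds = c(0, last_s))
  tr2 <- track_frequency(rec2)
  drop_pct <- 100 * (tr2$freq_hz[2] - tr2$freq_hz[1]) / tr2$freq_hz[1]
  expect_equal(drop_pct, q10_predicted_change(1.55, -0.15), tolerance = 0.03)
  expect_equal(round(abs(drop_pct), 1), 0.7)
})

test_that("harmonic amplitude does not move the tracked fundamental", {
  cfg <- short_config(seed = 6, n_fish = 1, temperature_drift = 0,
                      eod_noise_sd = 0, eod_stride_s = 200,
                      eod_harmonics = c(0.35, 0.12), n_nonresponders = 0)
  cfg2 <- short_config(seed = 6, n_fish = 1, temperature_drift = 0,
                       eod_noise_sd = 0, eod_stride_s = 200,
                       eod_harmonics = c(0.7, 0.24), n_nonresponders = 0)
  fish <- sample_cohort(cfg)[1, ]
  log <- simulate_trajectory(fish, cfg)
  f1 <- track_frequency(simulate_eod(fish, log, cfg))$freq_hz
  f2 <- track_frequency(simulate_eod(fish, log, cfg2))$freq_hz
  expect_equal(f1, f2)
})

test_that("EOD phase is continuous across windows", {
  cfg <- short_config(seed = 8, n_fish = 1, temperature_drift = 0,
                      eod_noise_sd = 0, eod_harmonics = numeric(0),
                      eod_stride_s = 1, n_nonresponders = 0)
  fish <- sample_cohort(cfg)[1, ]
  log <- simulate_trajectory(fish, cfg)
  rec <- simulate_eod(fish, log, cfg, seconds = 0:2)
  fs <- rec$sample_rate
  f0 <- fish$base_eod_freq_hz
  expect_equal(rec$samples, sin(2 * pi * f0 / fs * seq_len(3 * fs)),
               tolerance = 1e-8)
  # bounded sample-to-sample increment even with drifting frequency
  cfg2 <- short_config(seed = 8, n_fish = 1, temperature_drift = -0.15,
                       eod_noise_sd = 0, eod_harmonics = numeric(0),
                       eod_stride_s = 60, n_nonresponders = 0)
  rec2 <- simulate_eod(fish, simulate_trajectory(fish, cfg2), cfg2)
  expect_lte(max(abs(diff(rec2$samples))), 2 * pi * 1151 / fs + 1e-6)
})

test_that("EOD recordings round-trip through the raw+sidecar format", {
  rec <- tone_recording(1000, n_sec = 1)
  path <- withr::local_tempfile(fileext = ".f32")
  write_eod_recording(rec, path)
  rec2 <- read_eod_recording(path)
  expect_equal(rec2$samples, rec$samples, tolerance = 1e-6)  # float32
  expect_equal(rec2$sample_rate, rec$sample_rate)
  expect_equal(rec2$second_index, rec$second_index)
})
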