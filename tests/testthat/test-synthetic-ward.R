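# The synthetic ward generator: sensor streams, location traces, the survey
# schedule and the outcome model.

test_that("layout validation enforces the structural invariants", {
  expect_error(ward_layout(data.frame(room_id = c("a", "a"),
                                      room_group = "hallway",
                                      n_sensors = 1L)), "unique")
  expect_error(ward_layout(data.frame(room_id = "off_map",
                                      room_group = "hallway",
                                      n_sensors = 0L)), "reserved")
  expect_silent(wardtrig:::validate_layout(default_ward_layout()))
  # dropping the dual-sensor room breaks the layout contract
  l <- default_ward_layout()
  l$rooms$n_sensors[l$rooms$n_sensors == 2L] <- 1L
  expect_error(wardtrig:::validate_layout(l), "dual-sensor")
})

test_that("sensor streams are reproducible and complete", {
  cfg <- quick_config(11)
  s1 <- simulate_sensor_streams(default_ward_layout(), cfg, seed = 7)
  s2 <- simulate_sensor_streams(default_ward_layout(), cfg, seed = 7)
  expect_identical(s1, s2)
  # one reading per sensor per period per modality over the span
  n_ticks <- cfg$days * 86400 / cfg$sample_period
  cnt <- s1[, .N, by = .(sensor_id, modality)]
  expect_true(all(cnt$N == n_ticks))
  # dual-enclosure room: two distinct ids differing by independent noise
  lr <- s1[room_id == "living_room" & modality == "sound"]
  v1 <- lr[sensor_id == "living_room_s1"]$value
  v2 <- lr[sensor_id == "living_room_s2"]$value
  expect_gt(sd(v1 - v2), 0)
  expect_gt(cor(v1, v2), 0.9)
})

test_that("zero noise scales give the deterministic baseline profile", {
  cfg <- quick_config(
    12,
    light = list(night_lux = 4.5,
                 day_lux = c(living_room = 75, dining_room = 92,
                             hallway = 48, patient_room = 48, other = 62),
                 room_lsd = 0, slow_sd = 0, slow_tau = 1500, noise_sd = 0,
                 meas_lsd = 0),
    sound = list(base_dba = c(living_room = 48, dining_room = 50,
                              hallway = 44, patient_room = 40, other = 44),
                 room_sd = 0, diurnal_gain = 5, slow_sd = 0, slow_tau = 1500,
                 fast_sd = 0, fast_lsd = 0, fast_tau = 1200,
                 burst_rate_day = 0, burst_rate_night = 0, burst_dur = 20,
                 burst_amp = 8, burst_amp_sd = 0, meas_sd = 0),
    days = 1L)
  s1 <- simulate_sensor_streams(default_ward_layout(), cfg, seed = 1,
                                modalities = c("light", "sound"))
  s2 <- simulate_sensor_streams(default_ward_layout(), cfg, seed = 99,
                                modalities = c("light", "sound"))
  expect_equal(s1$value, s2$value)  # no randomness left
  # baseline: light equals the diurnal lognormal profile exactly
  hr <- (s1[sensor_id == "hallway_a_s1" & modality == "light"]$time %% 86400) / 3600
  day <- plogis((hr - 7.25) / 0.9) * plogis((20.75 - hr) / 0.9)
  expect_equal(s1[sensor_id == "hallway_a_s1" & modality == "light"]$value,
               exp(log(4.5) + (log(48) - log(4.5)) * day), tolerance = 1e-12)
})

test_that("pooled light distribution matches the ward's calibration", {
  cfg <- sim_config(seed = 21, n_patients = 2, days = 7, sample_period = 10,
                    smoothing_span = 10)
  s <- simulate_sensor_streams(default_ward_layout(), cfg, seed = 21,
                               modalities = "light")
  med <- median(s$value)
  # per-room medians sit inside the printed IQR band and the pooled median
  # is in the tens of lux
  expect_gt(med, 7); expect_lt(med, 64)
  rm_med <- s[, .(med = median(value)), by = room_id]
  expect_true(all(rm_med$med < 100))
  # diurnal profile present: daytime light well above nighttime
  hr <- (s$time %% 86400) / 3600
  expect_gt(median(s$value[hr >= 10 & hr < 16]),
            5 * median(s$value[hr >= 0 & hr < 5]))
})

test_that("location traces cover the span contiguously", {
  cfg <- quick_config(31)
  tr <- simulate_location_trace(1L, default_ward_layout(), cfg, seed = 5)
  expect_equal(tr$start[1], 0)
  expect_equal(tr$end[nrow(tr)], cfg$days * 86400)
  expect_true(all(abs(tr$end[-nrow(tr)] - tr$start[-1]) < 1e-9))
  expect_true(all(tr$end > tr$start))
})

test_that("off-map fraction: zero config gives none, targets are attained", {
  cfg0 <- quick_config(32, off_map_frac = 0)
  tr0 <- simulate_location_trace(1L, default_ward_layout(), cfg0, seed = 5)
  expect_false("off_map" %in% tr0$room_id)

  cfg3 <- sim_config(seed = 1, n_patients = 1, days = 60, sample_period = 10,
                     smoothing_span = 10, off_map_frac = 0.3)
  tr3 <- simulate_location_trace(1L, default_ward_layout(), cfg3, seed = 6)
  frac <- with(tr3, sum((end - start)[room_id == "off_map"]) /
                 sum(end - start))
  expect_lt(abs(frac - 0.3), 0.05)  # law of large numbers over 60 days
})

test_that("EMA schedule is stratified over the prompt window", {
  cfg <- quick_config(41)
  tt <- schedule_emas(0L, cfg, seed = 8)
  expect_length(tt, 9L)
  expect_true(all(tt >= 8 * 3600 & tt < 20 * 3600))
  expect_true(all(tt %% 60 == 0))

  one <- sim_config(prompts_per_day = 1L)
  expect_length(schedule_emas(0L, one, seed = 8), 1L)

  # stratification: every sub-bin holds exactly one prompt, on every day
  set.seed(9)
  width <- 12 * 3600 / 9
  for (d in 1:300) {
    s <- schedule_emas(0L, cfg) - 8 * 3600
    expect_identical(findInterval(sort(s), width * (0:8)), 1:9)
  }

  expect_error(schedule_emas(0L, sim_config(prompts_per_day = 721L)),
               "1-minute")
})

test_that("null outcome model gives 50% prevalence; coupling is directional", {
  # all betas zero, alpha = 0 => logistic(0) = 0.5, no patient heterogeneity
  cfg <- sim_config(seed = 51, n_patients = 30, days = 3, sample_period = 15,
                    smoothing_span = 15, sigma_b = 1e-6, kappa = 0,
                    alpha = c(agitation = 0, motor = 0, verbal = 0),
                    beta = list(agitation = numeric(0), motor = numeric(0),
                                verbal = numeric(0)),
                    tg_effects = c(tg2 = 0, tg3 = 0, tg4 = 0),
                    room_effects = c(living_room = 0, dining_room = 0,
                                     hallway = 0, patient_room = 0,
                                     other = 0))
  ds <- simulate_ward(cfg)
  pas <- binarize_pas(ds$surveys)
  expect_lt(abs(mean(pas$motor) - 0.5), 0.05)
  expect_lt(abs(mean(pas$verbal) - 0.5), 0.05)

  # large kappa: verbal much more likely given motor
  cfg2 <- sim_config(seed = 52, n_patients = 40, days = 3, sample_period = 15,
                     smoothing_span = 15, kappa = 2.5)
  ds2 <- simulate_ward(cfg2)
  p2 <- binarize_pas(ds2$surveys)
  expect_gt(mean(p2$verbal[p2$motor == 1]), mean(p2$verbal[p2$motor == 0]))
})

test_that("defaults reproduce the study's agitation composition", {
  ds <- simulate_ward(sim_config(seed = 53, n_patients = 40, days = 5,
                                 sample_period = 10, smoothing_span = 10))
  pas <- binarize_pas(ds$surveys)
  # agitated fraction near 191/694 ~ 0.275; more motor-only than verbal-only
  expect_lt(abs(mean(pas$agitation) - 0.275), 0.07)
  expect_gt(sum(pas$motor == 1 & pas$verbal == 0),
            sum(pas$motor == 0 & pas$verbal == 1))
  # a few agitated surveys that are neither motor nor verbal exist
  expect_gt(sum(pas$agitation == 1 & pas$motor == 0 & pas$verbal == 0), 0)
})

test_that("outcome prevalence is monotone in the generative intercept", {
  prev <- vapply(c(-3.5, -2.5, -1.5), function(a) {
    ds <- simulate_ward(sim_config(seed = 54, n_patients = 25, days = 3,
                                   sample_period = 15, smoothing_span = 15,
                                   alpha = c(agitation = -1.7, motor = a,
                                             verbal = -3.35)))
    mean(binarize_pas(ds$surveys)$motor)
  }, numeric(1))
  expect_true(all(diff(prev) > 0))
})

test_that("between-patient spread of agitation rates grows with sigma_b", {
  spread <- vapply(c(0.2, 1, 2.5), function(s) {
    ds <- simulate_ward(sim_config(seed = 55, n_patients = 40, days = 4,
                                   sample_period = 15, smoothing_span = 15,
                                   sigma_b = s))
    sv <- ds$surveys
    rates <- tapply(binarize_pas(sv)$motor, sv$patient_id, mean)
    sd(rates)
  }, numeric(1))
  expect_true(all(diff(spread) > 0))
})

test_that("a fixed seed reproduces the full dataset bitwise", {
  d1 <- simulate_ward(quick_config(61))
  d2 <- simulate_ward(quick_config(61))
  expect_identical(d1$sensors, d2$sensors)
  expect_identical(d1$traces, d2$traces)
  expect_identical(d1$surveys, d2$surveys)
})

test_that("datasets round-trip through the CSV interchange format", {
  ds <- simulate_ward(sim_config(seed = 62, n_patients = 3, days = 1,
                                 sample_period = 30, smoothing_span = 30))
  dir <- withr::local_tempdir()
  write_study_dataset(ds, dir)
  expect_setequal(list.files(dir), c("sensors.csv", "locations.csv",
                                     "surveys.csv", "truth.json"))
  back <- read_study_dataset(dir)
  expect_equal(back$surveys$pas_motor, ds$surveys$pas_motor)
  expect_equal(nrow(back$sensors), nrow(ds$sensors))
  f1 <- extract_features(ds, lengths = 9)$features
  f2 <- extract_features(back, lengths = 9)$features
  expect_equal(f2$sound_mean, f1$sound_mean, tolerance = 1e-4)
  expect_equal(f2$maj_room, f1$maj_room)
})
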