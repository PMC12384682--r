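# Room-level environmental processes.
#
# Each modality is a sum of a room baseline, a smooth diurnal profile, a slow
# stationary AR(1) drift and fast noise; sound additionally carries Poisson
# bursts (care activity, vocalisation on the ward) and a slowly varying noise
# scale so that the window-level SD genuinely differs between windows.
# The same law is used for the full study streams and for the fresh windows
# drawn when calibrating law-level feature moments.

# stationary AR(1) with marginal sd `sd_marg` and correlation time `tau`
# sampled every `dt` seconds
.ar1 <- function(n, tau, sd_marg, dt) {
  if (n == 0L) return(numeric(0))
  if (sd_marg <= 0) return(numeric(n))
  rho <- exp(-dt / tau)
  x0 <- rnorm(1, 0, sd_marg)
  if (n == 1L) return(x0)
  inn <- rnorm(n, 0, sd_marg * sqrt(1 - rho^2))
  inn[1] <- 0
  as.numeric(stats::filter(inn, rho, method = "recursive", init = x0))
}

# smooth daylight indicator in [0, 1] from the local clock hour
.daylight <- function(hour) {
  plogis((hour - 7.25) / 0.9) * plogis((20.75 - hour) / 0.9)
}

# ward activity indicator for care-related sound bursts: near-flat across the
# waking/care hours so burst occurrence is not a proxy for clock time inside
# the survey window
.activity <- function(hour) {
  plogis((hour - 7.0) / 0.35) * plogis((20.9 - hour) / 0.35)
}

# additive burst track: starts are per-tick Bernoulli with rate (per second)
# modulated by ward activity; rectangular bursts of exponential duration
.burst_track <- function(t_abs, hour, snd, dt) {
  rate <- snd$burst_rate_night +
    (snd$burst_rate_day - snd$burst_rate_night) * .activity(hour)
  n <- length(t_abs)
  out <- numeric(n)
  if (snd$burst_rate_day <= 0 && snd$burst_rate_night <= 0) return(out)
  starts <- which(runif(n) < rate * dt)
  for (s in starts) {
    dur <- max(1L, as.integer(round(rexp(1, 1 / snd$burst_dur) / dt)))
    amp <- rnorm(1, snd$burst_amp, snd$burst_amp_sd)
    idx <- s:min(n, s + dur - 1L)
    out[idx] <- out[idx] + amp
  }
  out
}

# realized per-room baselines; drawn once per simulated ward so that the
# sensor streams and the law-moment calibration describe the same ward
draw_ward_params <- function(layout, cfg) {
  r <- layout$rooms
  n <- nrow(r)
  list(
    room_id = r$room_id,
    room_group = r$room_group,
    light_day_lux = cfg$light$day_lux[r$room_group] *
      exp(rnorm(n, 0, cfg$light$room_lsd)),
    sound_base = cfg$sound$base_dba[r$room_group] +
      rnorm(n, 0, cfg$sound$room_sd),
    temp_base = cfg$temperature$base_c +
      rnorm(n, 0, cfg$temperature$room_sd)
  )
}

# underlying room process (before per-enclosure measurement noise) at the
# absolute study times t_abs (seconds since study start at local midnight)
.room_process <- function(room_idx, modality, t_abs, cfg, wp) {
  n <- length(t_abs)
  dt <- cfg$sample_period
  hour <- (t_abs %% 86400) / 3600
  day <- .daylight(hour)
  if (modality == "light") {
    lg <- cfg$light
    ll <- log(lg$night_lux) +
      (log(wp$light_day_lux[room_idx]) - log(lg$night_lux)) * day +
      .ar1(n, lg$slow_tau, lg$slow_sd, dt) +
      rnorm(n, 0, lg$noise_sd)
    exp(ll)
  } else if (modality == "sound") {
    snd <- cfg$sound
    sd_t <- snd$fast_sd * exp(.ar1(n, snd$fast_tau, snd$fast_lsd, dt))
    wp$sound_base[room_idx] + snd$diurnal_gain * day +
      .ar1(n, snd$slow_tau, snd$slow_sd, dt) +
      sd_t * rnorm(n) +
      .burst_track(t_abs, hour, snd, dt)
  } else if (modality == "temperature") {
    tp <- cfg$temperature
    wp$temp_base[room_idx] + tp$diurnal_amp * (day - 0.5) +
      .ar1(n, tp$slow_tau, tp$slow_sd, dt) +
      rnorm(n, 0, tp$noise_sd)
  } else stop("unknown modality: ", modality)
}

# per-enclosure measurement noise on top of the room process
.measure <- function(room_values, modality, cfg) {
  n <- length(room_values)
  switch(modality,
    light = room_values * exp(rnorm(n, 0, cfg$light$meas_lsd)),
    sound = room_values + rnorm(n, 0, cfg$sound$meas_sd),
    temperature = room_values + rnorm(n, 0, cfg$temperature$meas_sd)
  )
}

#' Simulate the ward's environmental sensor streams
#'
#' Generates one reading per sensor enclosure per sampling period per modality
#' over the whole study span. Rooms with two enclosures yield two sensor ids
#' whose values share the room process but differ by independent measurement
#' noise. Light follows a diurnal lognormal profile calibrated so the pooled
#' weekly distribution has a median around 22 lux (IQR roughly 7-64 lux).
#'
#' @param layout a [ward_layout()].
#' @param config a [sim_config()].
#' @param seed optional integer; when `NULL` the current RNG stream is used.
#' @param ward_params realized per-room baselines from an enclosing
#'   [simulate_ward()] call; drawn fresh when `NULL`.
#' @param modalities subset of `c("light", "sound", "temperature")`.
#' @return A `data.table` with columns `time` (seconds since study start),
#'   `sensor_id`, `room_id`, `modality`, `value`.
#' @export
simulate_sensor_streams <- function(layout, config, seed = NULL,
                                    ward_params = NULL,
                                    modalities = c("light", "sound",
                                                   "temperature")) {
  validate_layout(layout)
  cfg <- validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  span <- cfg$days * 86400
  if (span <= 0) stop("zero-duration study span")
  if (is.null(ward_params)) ward_params <- draw_ward_params(layout, cfg)
  t_abs <- seq(0, span - cfg$sample_period, by = cfg$sample_period)
  sensors <- sensor_index(layout)
  out <- vector("list", length(modalities) * nrow(sensors))
  k <- 0L
  for (m in modalities) {
    for (ri in seq_len(nrow(layout$rooms))) {
      room <- layout$rooms$room_id[ri]
      ids <- sensors$sensor_id[sensors$room_id == room]
      if (!length(ids)) next
      rv <- .room_process(ri, m, t_abs, cfg, ward_params)
      for (sid in ids) {
        k <- k + 1L
        out[[k]] <- data.table(
          time = t_abs, sensor_id = sid, room_id = room,
          modality = m, value = .measure(rv, m, cfg)
        )
      }
    }
  }
  rbindlist(out[seq_len(k)])
}

# Law-level moments of the descriptive window features per sensored room:
# mean and SD of each (modality, feature) over fresh causal-length windows
# drawn from the generative law (dual-enclosure rooms averaged, trailing
# smoothing applied), with window start clock times spread evenly over the
# times at which causal windows can occur.
calibrate_room_moments <- function(layout, cfg, ward_params,
                                   n_cal = cfg$n_cal, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  per <- cfg$sample_period
  L <- as.integer(round(cfg$causal_length_min * 60 / per))
  co <- causal_offsets(cfg)
  lo <- cfg$prompt_window[1] * 3600 - co[["start"]] * 60
  hi <- cfg$prompt_window[2] * 3600 - co[["start"]] * 60
  starts <- lo + (seq_len(n_cal) - 0.5) / n_cal * (hi - lo)
  rooms <- layout$rooms[layout$rooms$n_sensors > 0, , drop = FALSE]
  res <- vector("list", nrow(rooms) * 3L)
  k <- 0L
  feats <- c("min", "max", "mean", "median", "sd")
  for (m in c("light", "sound", "temperature")) {
    for (i in seq_len(nrow(rooms))) {
      ri <- match(rooms$room_id[i], layout$rooms$room_id)
      fmat <- matrix(NA_real_, n_cal, 5L)
      for (w in seq_len(n_cal)) {
        t_abs <- starts[w] + (seq_len(L) - 1) * per
        rv <- .room_process(ri, m, t_abs, cfg, ward_params)
        v <- .measure(rv, m, cfg)
        if (rooms$n_sensors[i] == 2L)
          v <- (v + .measure(rv, m, cfg)) / 2
        sm <- smooth_series(t_abs, v, span = cfg$smoothing_span)
        fmat[w, ] <- c(min(sm), max(sm), mean(sm), median(sm), sd(sm))
      }
      k <- k + 1L
      res[[k]] <- data.table(
        room_id = rooms$room_id[i], modality = m, feature = feats,
        law_mean = colMeans(fmat), law_sd = apply(fmat, 2, sd)
      )
    }
  }
  rbindlist(res[seq_len(k)])
}
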