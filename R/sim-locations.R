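#' Simulate a patient's room-level location trace
#'
#' A semi-Markov walk over the ward: dwell times are exponential with a
#' room-group-dependent mean, the next room is drawn by group weight, and
#' after each room visit the patient goes untracked (`"off_map"`) with a
#' probability chosen so the long-run off-map time fraction matches
#' `config$off_map_frac`. Intervals are contiguous and half-open
#' `[start, end)`, covering the whole study span.
#'
#' @param patient_id identifier copied into the trace.
#' @param layout a [ward_layout()].
#' @param config a [sim_config()].
#' @param seed optional integer seed (`NULL`: current RNG stream).
#' @return `data.table` with columns `patient_id`, `start`, `end` (seconds
#'   since study start), `room_id` (a ward room or `"off_map"`).
#' @export
simulate_location_trace <- function(patient_id, layout, config, seed = NULL) {
  validate_layout(layout)
  cfg <- validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  span <- cfg$days * 86400
  rooms <- layout$rooms
  w_room <- cfg$room_weights[rooms$room_group] /
    as.vector(table(rooms$room_group)[rooms$room_group])
  w_room <- w_room / sum(w_room)
  mbar <- sum(w_room * cfg$dwell_mean[rooms$room_group])
  f <- cfg$off_map_frac
  q <- if (f <= 0) 0 else f * mbar / (cfg$off_map_dwell * (1 - f))
  if (q > 1)
    stop("off_map_frac unattainable; increase off_map_dwell or lower the fraction")
  st <- numeric(0); en <- numeric(0); rm <- character(0)
  t <- 0
  cur <- sample(nrow(rooms), 1L, prob = w_room)
  while (t < span) {
    dwell <- rexp(1, 1 / cfg$dwell_mean[[rooms$room_group[cur]]])
    e <- min(t + dwell, span)
    st <- c(st, t); en <- c(en, e); rm <- c(rm, rooms$room_id[cur])
    t <- e
    if (t >= span) break
    if (q > 0 && runif(1) < q) {
      e <- min(t + rexp(1, 1 / cfg$off_map_dwell), span)
      st <- c(st, t); en <- c(en, e); rm <- c(rm, "off_map")
      t <- e
      if (t >= span) break
    }
    w <- w_room
    w[cur] <- 0
    cur <- sample(nrow(rooms), 1L, prob = w / sum(w))
  }
  data.table(patient_id = patient_id, start = st, end = en, room_id = rm)
}
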