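#' Simulate a complete synthetic ward study
#'
#' Generates, from one seed, everything the analysis pipeline consumes: the
#' realized ward (per-room baselines), continuous environmental sensor
#' streams, per-patient location traces, the experience-sampling survey
#' schedule and agitation outcomes driven by the causal pre-survey window.
#' The generative parameters are kept in the returned `truth` so downstream
#' stages can be validated by parameter recovery.
#'
#' @param config a [sim_config()].
#' @param layout a [ward_layout()] (default [default_ward_layout()]).
#' @return Object of class `ward_dataset`: `layout`, `config`, `ward_params`,
#'   `sensors`, `traces`, `surveys` (with PAS scores) and `truth` (random
#'   intercepts, true standardized features, law moments).
#' @examples
#' ds <- simulate_ward(sim_config(n_patients = 2, days = 1, sample_period = 30,
#'                                smoothing_span = 30, n_cal = 8, seed = 42))
#' ds
#' @export
simulate_ward <- function(config = sim_config(),
                          layout = default_ward_layout()) {
  cfg <- validate_sim_config(config)
  validate_layout(layout)
  set.seed(cfg$seed)

  ward_params <- draw_ward_params(layout, cfg)
  sensors <- simulate_sensor_streams(layout, cfg, ward_params = ward_params)
  traces <- rbindlist(lapply(seq_len(cfg$n_patients), function(p)
    simulate_location_trace(p, layout, cfg)))

  b_pat <- rnorm(cfg$n_patients, 0, cfg$sigma_b)
  names(b_pat) <- as.character(seq_len(cfg$n_patients))

  sv <- list(); k <- 0L
  for (p in seq_len(cfg$n_patients)) {
    for (d in seq_len(cfg$days) - 1L) {
      k <- k + 1L
      sv[[k]] <- data.table(patient_id = p,
                            time = schedule_emas(d, cfg),
                            self_initiated = FALSE)
      if (cfg$self_initiated_rate > 0) {
        # nurse-initiated extras: more likely for patients whose latent
        # propensity (random intercept) is high
        n_extra <- rpois(1L, cfg$self_initiated_rate * 2 * plogis(b_pat[p]))
        if (n_extra > 0) {
          k <- k + 1L
          tt <- d * 86400 +
            runif(n_extra, cfg$prompt_window[1] * 3600,
                  cfg$prompt_window[2] * 3600)
          sv[[k]] <- data.table(patient_id = p, time = floor(tt / 60) * 60,
                                self_initiated = TRUE)
        }
      }
    }
  }
  surveys <- rbindlist(sv[seq_len(k)])
  setorder(surveys, patient_id, time)
  surveys[, survey_id := seq_len(.N)]

  ds <- list(layout = layout, config = cfg, ward_params = ward_params,
             sensors = sensors, traces = traces, surveys = surveys)
  oc <- generate_outcomes(ds, cfg, b = b_pat)
  ds$surveys <- oc$surveys
  ds$truth <- oc$truth
  structure(ds, class = "ward_dataset")
}

#' @export
print.ward_dataset <- function(x, ...) {
  pas <- binarize_pas(x$surveys)
  cat("Synthetic ward study dataset\n")
  cat(sprintf("  %d patients x %d days, %d surveys (%.1f%% agitated)\n",
              x$config$n_patients, x$config$days, nrow(x$surveys),
              100 * mean(pas$agitation)))
  cat(sprintf("  %s sensor readings from %d enclosures in %d rooms\n",
              format(nrow(x$sensors), big.mark = ","),
              nrow(sensor_index(x$layout)), nrow(x$layout$rooms)))
  cat(sprintf("  location intervals: %d (off-map fraction %.2f)\n",
              nrow(x$traces),
              with(x$traces, sum((end - start)[room_id == "off_map"]) /
                     sum(end - start))))
  invisible(x)
}

#' Write / read a study dataset as plain CSV + JSON
#'
#' `write_study_dataset()` writes `sensors.csv` (ISO-8601 UTC timestamps,
#' sensor id, room, modality, value), `locations.csv`, `surveys.csv` and
#' `truth.json` (the full simulation configuration including the seed, plus
#' the layout). `read_study_dataset()` reads them back into the same
#' structure `extract_features()` accepts.
#'
#' @param dataset a `ward_dataset`.
#' @param dir output directory (created if needed).
#' @return `write_study_dataset()`: `dir`, invisibly;
#'   `read_study_dataset()`: a `ward_dataset`-shaped list (without `truth`
#'   draws).
#' @export
write_study_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  origin <- as.POSIXct(paste(dataset$config$start_date, "00:00:00"),
                       tz = dataset$config$tz)
  iso <- function(sec) format(origin + sec, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  sen <- as.data.table(dataset$sensors)
  fwrite(sen[, .(timestamp = iso(time), sensor_id, room_id, modality,
                 value = signif(value, 7))],
         file.path(dir, "sensors.csv"))
  tr <- as.data.table(dataset$traces)
  fwrite(tr[, .(patient_id, start = iso(start), end = iso(end), room_id)],
         file.path(dir, "locations.csv"))
  sv <- as.data.table(dataset$surveys)
  fwrite(sv[, .(patient_id, timestamp = iso(time), pas_motor, pas_verbal,
                pas_resist, pas_aggr)],
         file.path(dir, "surveys.csv"))
  cfg <- dataset$config
  jsonlite::write_json(
    list(config = unclass(cfg), layout = dataset$layout$rooms),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' @rdname write_study_dataset
#' @export
read_study_dataset <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  cfg_l <- truth$config
  for (nm in c("dwell_mean", "room_weights", "alpha", "tg_effects",
               "room_effects"))
    cfg_l[[nm]] <- unlist(cfg_l[[nm]])
  cfg_l$beta <- lapply(truth$config$beta, unlist)
  cfg_l$prompt_window <- unlist(cfg_l$prompt_window)
  cfg <- do.call(sim_config, cfg_l)
  layout <- ward_layout(truth$layout)
  origin <- as.POSIXct(paste(cfg$start_date, "00:00:00"), tz = cfg$tz)
  secs <- function(ts) as.numeric(difftime(
    as.POSIXct(ts, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"), origin,
    units = "secs"))
  sen <- fread(file.path(dir, "sensors.csv"))
  sen <- sen[, .(time = secs(timestamp), sensor_id, room_id, modality, value)]
  tr <- fread(file.path(dir, "locations.csv"))
  tr <- tr[, .(patient_id, start = secs(start), end = secs(end), room_id)]
  sv <- fread(file.path(dir, "surveys.csv"))
  sv <- sv[, .(patient_id, time = secs(timestamp), pas_motor, pas_verbal,
               pas_resist, pas_aggr)]
  setorder(sv, patient_id, time)
  sv[, survey_id := seq_len(.N)]
  structure(list(layout = layout, config = cfg, sensors = sen, traces = tr,
                 surveys = sv), class = "ward_dataset")
}
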