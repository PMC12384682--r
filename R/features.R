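# Descriptive window features, PAS binarization, the four quality filters and
# within-majority-room standardization.

.MODALITIES <- c("light", "sound", "temperature")
.FEATURES <- c("min", "max", "mean", "median", "sd")  # fixed tie-break order

#' Binarize Pittsburgh Agitation Scale scores
#'
#' Each subtype (motor, verbal, resistance to care, aggression) is scored
#' 0-4; a score of 1 or more means the subtype was present. Overall agitation
#' is present when any of the four subtypes is, so a survey can be agitated
#' while being neither motor nor verbal.
#'
#' @param scores data.frame (or list) with columns `pas_motor`, `pas_verbal`,
#'   `pas_resist`, `pas_aggr`, each in 0-4.
#' @return data.frame with binary columns `agitation`, `motor`, `verbal`.
#' @examples
#' binarize_pas(data.frame(pas_motor = 2, pas_verbal = 0,
#'                         pas_resist = 0, pas_aggr = 0))
#' @export
binarize_pas <- function(scores) {
  need <- c("pas_motor", "pas_verbal", "pas_resist", "pas_aggr")
  if (!all(need %in% names(scores)))
    stop("scores must contain ", paste(need, collapse = ", "))
  s <- lapply(need, function(k) scores[[k]])
  if (any(unlist(s) < 0 | unlist(s) > 4, na.rm = TRUE))
    stop("PAS scores must lie in 0-4")
  data.frame(
    agitation = as.integer(s[[1]] >= 1 | s[[2]] >= 1 | s[[3]] >= 1 |
                             s[[4]] >= 1),
    motor = as.integer(s[[1]] >= 1),
    verbal = as.integer(s[[2]] >= 1)
  )
}

#' Descriptive features of a window series
#'
#' @param values numeric series (already smoothed); may be empty.
#' @return Named list: `min`, `max`, `mean`, `median`, `sd` (sample SD,
#'   denominator n-1) and `n_points`. An empty series yields `NA` features
#'   (which later fail the quality stage).
#' @examples
#' compute_features(c(1, 2, 3, 4))
#' @export
compute_features <- function(values) {
  n <- length(values)
  if (n == 0L)
    return(list(min = NA_real_, max = NA_real_, mean = NA_real_,
                median = NA_real_, sd = NA_real_, n_points = 0L))
  list(min = min(values), max = max(values), mean = mean(values),
       median = median(values), sd = if (n > 1L) sd(values) else NA_real_,
       n_points = n)
}

#' Time-of-day group of a survey
#'
#' Four clock groups by the hour the survey was completed: 1 = \[8, 12),
#' 2 = \[12, 16), 3 = \[16, 20), 4 = everything else (\[20, 8)). Group 3 is
#' the usual "sundowning" window.
#'
#' @param x survey timestamps: seconds since a midnight-anchored study start,
#'   or `POSIXct` (interpreted in its own timezone).
#' @return Integer vector in 1..4.
#' @examples
#' assign_time_group(c(11, 12, 19.99, 3) * 3600)
#' @export
assign_time_group <- function(x) {
  hour <- if (inherits(x, "POSIXt")) {
    lt <- as.POSIXlt(x)
    lt$hour + lt$min / 60 + lt$sec / 3600
  } else {
    (as.numeric(x) %% 86400) / 3600
  }
  ifelse(hour >= 8 & hour < 12, 1L,
  ifelse(hour >= 12 & hour < 16, 2L,
  ifelse(hour >= 16 & hour < 20, 3L, 4L)))
}

.QUALITY_CRITERIA <- c("off_map_ge_50pct", "lt_50pct_expected_points",
                       "majority_room_sensorless", "outside_8_to_20")

#' Apply the four window quality filters
#'
#' A window is kept only if (1) less than 50% of it is off-map, (2) at least
#' 50% of the expected number of data points are present for every modality,
#' (3) the majority room has environmental sensors (in particular, is not
#' off-map), and (4) the survey was recorded within 8 AM to 8 PM. The
#' inequalities are exactly as stated: an off-map fraction of exactly 0.5
#' fails, a point count of exactly half the expectation passes, and a survey
#' at exactly 20:00 fails.
#'
#' @param window_data a `window_data` from [extract_window()], or a list with
#'   `off_map_fraction`, `n_points` (per modality) and `majority_room`.
#' @param survey_time survey timestamp (seconds since study start or POSIXct).
#' @param expected_points expected points per modality: window seconds divided
#'   by the nominal sampling period.
#' @param layout [ward_layout()] used to decide whether the majority room has
#'   sensors.
#' @return List of class `quality_report`: `survey_id`, `length_min`,
#'   `passed`, `failed_criteria` (subset of
#'   `r paste(wardtrig:::.QUALITY_CRITERIA, collapse = ", ")`).
#' @export
apply_quality_filters <- function(window_data, survey_time, expected_points,
                                  layout) {
  failed <- character(0)
  if (!(window_data$off_map_fraction < 0.5))
    failed <- c(failed, "off_map_ge_50pct")
  if (!all(window_data$n_points >= 0.5 * expected_points))
    failed <- c(failed, "lt_50pct_expected_points")
  maj <- window_data$majority_room
  ns <- if (maj == "off_map") 0L else
    layout$rooms$n_sensors[match(maj, layout$rooms$room_id)]
  if (is.na(ns) || ns < 1L)
    failed <- c(failed, "majority_room_sensorless")
  if (!assign_time_group(survey_time) %in% 1:3)
    failed <- c(failed, "outside_8_to_20")
  structure(list(survey_id = window_data$survey_id %||% NA_integer_,
                 length_min = window_data$spec$length_min %||% NA_real_,
                 passed = length(failed) == 0L,
                 failed_criteria = failed),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("Window quality:", if (x$passed) "PASS" else
    paste("FAIL (", paste(x$failed_criteria, collapse = "; "), ")"), "\n")
  invisible(x)
}

#' Standardize features within the majority room
#'
#' Feature values are z-scored within (majority room, modality, feature)
#' strata so that a value of 1 means one SD above that room's typical value,
#' making features comparable across rooms and wards. The standardizer is
#' fitted on quality-passing rows only, separately per window length. Strata
#' with fewer than 2 rows or zero SD yield undefined z-scores (such rows are
#' excluded from modeling, with the reason recorded in the returned
#' standardizer).
#'
#' @param features feature table (one row per survey) with raw columns
#'   `<modality>_<feature>`, plus `maj_room` and `pass`.
#' @param length_min window length the rows belong to (bookkeeping only).
#' @return List with `features` (input plus `z_<modality>_<feature>` columns)
#'   and `standardizer` (per-stratum mean, SD, n, usable flag).
#' @export
standardize_features <- function(features, length_min = NA_real_) {
  ft <- as.data.table(copy(as.data.table(features)))
  std <- vector("list", length(.MODALITIES) * length(.FEATURES))
  k <- 0L
  for (m in .MODALITIES) for (f in .FEATURES) {
    col <- paste0(m, "_", f)
    zcol <- paste0("z_", col)
    if (!col %in% names(ft)) next
    fit_rows <- ft$pass & !is.na(ft[[col]])
    s <- ft[fit_rows, .(mean = mean(.SD[[1]]), sd = sd(.SD[[1]]), n = .N),
            by = maj_room, .SDcols = col]
    s[, usable := n >= 2L & !is.na(sd) & sd > 0]
    idx <- match(ft$maj_room, s$maj_room)
    mu <- s$mean[idx]; sg <- s$sd[idx]; ok <- s$usable[idx]
    z <- (ft[[col]] - mu) / sg
    z[!ok | is.na(ok)] <- NA_real_
    set(ft, j = zcol, value = z)
    k <- k + 1L
    std[[k]] <- data.table(length_min = length_min, modality = m,
                           feature = f, s)
  }
  list(features = ft, standardizer = rbindlist(std[seq_len(k)]))
}

# ---- batch path ------------------------------------------------------------

# fused per-room series matrices on the regular sampling grid (one matrix per
# modality; dual-enclosure rooms averaged tick-wise)
.room_series_matrices <- function(sensors, layout, period, n_ticks) {
  rooms <- layout$rooms$room_id[layout$rooms$n_sensors > 0]
  out <- list()
  for (m in .MODALITIES) {
    sm <- sensors[modality == m]
    M <- matrix(NA_real_, n_ticks, length(rooms),
                dimnames = list(NULL, rooms))
    if (nrow(sm)) {
      sm <- sm[, .(value = mean(value)),
               by = .(room_id, tick = as.integer(round(time / period)))]
      sm <- sm[tick >= 0L & tick < n_ticks & room_id %in% rooms]
      M[cbind(sm$tick + 1L, match(sm$room_id, rooms))] <- sm$value
    }
    out[[m]] <- M
  }
  out
}

# occupancy segments of all survey windows via interval overlap join
.window_segments <- function(traces, surveys, w0, w1) {
  tr <- as.data.table(traces)[, .(patient_id, start, end, room_id)]
  win <- data.table(survey_id = seq_along(w0),
                    patient_id = surveys$patient_id, start = w0, end = w1)
  setkey(tr, patient_id, start, end)
  ov <- foverlaps(win, tr, type = "any", nomatch = NULL)
  ov[, `:=`(seg_start = pmax(start, i.start), seg_end = pmin(end, i.end))]
  ov <- ov[seg_end > seg_start,
           .(survey_id, room_id, seg_start, seg_end)]
  setorder(ov, survey_id, seg_start)
  ov
}

#' Extract features for every survey at one or more window lengths
#'
#' Vectorized pipeline stage over a whole study dataset: occupancy and
#' majority room per survey window, location-conditioned sensor fusion,
#' trailing smoothing, descriptive features per modality, the four quality
#' filters and within-room standardization (fitted per window length on
#' passing rows). Sensor readings must lie on a regular sampling grid (as the
#' simulator emits); for irregular real-world data use [extract_window()] per
#' survey.
#'
#' @param dataset a `ward_dataset` from [simulate_ward()] (or the same shape
#'   read back from disk).
#' @param lengths window lengths in minutes (default the full sweep 3..30).
#' @param buffer buffer in minutes between window end and survey.
#' @return List of class `ward_features`: `features` (one row per survey x
#'   length with raw and `z_` features, context columns, `pass` and
#'   `failed_criteria`), `quality` (per-criterion flags) and `standardizer`.
#' @export
extract_features <- function(dataset, lengths = seq(3, 30, by = 3),
                             buffer = 12) {
  cfg <- dataset$config
  period <- cfg$sample_period
  span <- cfg$days * 86400
  n_ticks <- as.integer(round(span / period))
  mats <- .room_series_matrices(as.data.table(dataset$sensors),
                                dataset$layout, period, n_ticks)
  surveys <- as.data.table(dataset$surveys)
  res <- lapply(lengths, function(L)
    .extract_features_one(dataset, surveys, mats, L, buffer, period))
  list(
    features = rbindlist(lapply(res, `[[`, "features")),
    quality = rbindlist(lapply(res, `[[`, "quality")),
    standardizer = rbindlist(lapply(res, `[[`, "standardizer"))
  )
}

.extract_features_one <- function(dataset, surveys, mats, L, buffer, period) {
  layout <- dataset$layout
  cfg <- dataset$config
  n <- nrow(surveys)
  w1 <- surveys$time - buffer * 60
  w0 <- w1 - L * 60
  seg <- .window_segments(dataset$traces, surveys, w0, w1)

  sensored <- colnames(mats[[1]])
  seg[, room_col := match(room_id, sensored)]
  seg[is.na(room_col), room_col := 0L]

  ft <- data.table(survey_id = surveys$survey_id,
                   patient_id = surveys$patient_id,
                   time = surveys$time, length_min = L)
  for (m in .MODALITIES) {
    fm <- .window_features_batch(mats[[m]], seg$survey_id, seg$room_col,
                                 seg$seg_start, seg$seg_end, n, period,
                                 cfg$smoothing_span)
    cols <- c(paste0(m, "_", .FEATURES), paste0("n_points_", m))
    for (j in seq_along(cols)) set(ft, j = cols[j], value = fm[, j])
  }

  # occupancy bookkeeping: covered seconds, off-map, majority room
  occ <- seg[, .(seconds = sum(seg_end - seg_start),
                 first_entry = min(seg_start)),
             by = .(survey_id, room_id)]
  cov <- occ[, .(covered = sum(seconds)), by = survey_id]
  off <- occ[room_id == "off_map", .(off_sec = sum(seconds)), by = survey_id]
  setorder(occ, survey_id, -seconds, first_entry)
  maj <- occ[, .(maj_room = room_id[1L], maj_seconds = seconds[1L]),
             by = survey_id]
  win_sec <- L * 60
  ft[, off_map_fraction := win_sec - cov$covered[match(survey_id, cov$survey_id)]]
  ft[is.na(off_map_fraction), off_map_fraction := win_sec]  # fully uncovered
  ft[, off_map_fraction := off_map_fraction +
       ifelse(is.na(off$off_sec[match(survey_id, off$survey_id)]), 0,
              off$off_sec[match(survey_id, off$survey_id)])]
  ft[, off_map_fraction := off_map_fraction / win_sec]
  ft[, maj_room := maj$maj_room[match(survey_id, maj$survey_id)]]
  ft[is.na(maj_room), maj_room := "off_map"]
  grp <- layout$rooms$room_group[match(ft$maj_room, layout$rooms$room_id)]
  ft[, maj_room_group := factor(grp, levels = room_groups())]
  ft[, maj_room_seconds := maj$maj_seconds[match(survey_id, maj$survey_id)]]
  ft[is.na(maj_room_seconds), maj_room_seconds := 0]
  ft[, time_group := assign_time_group(time)]

  # outcomes
  pas <- binarize_pas(surveys)
  ft[, `:=`(agitation = pas$agitation, motor = pas$motor,
            verbal = pas$verbal)]

  # quality criteria
  expected <- win_sec / period
  nsens <- layout$rooms$n_sensors[match(ft$maj_room, layout$rooms$room_id)]
  q <- data.table(
    survey_id = ft$survey_id, length_min = L,
    off_map_ge_50pct = !(ft$off_map_fraction < 0.5),
    lt_50pct_expected_points =
      !(ft$n_points_light >= 0.5 * expected &
        ft$n_points_sound >= 0.5 * expected &
        ft$n_points_temperature >= 0.5 * expected),
    majority_room_sensorless = is.na(nsens) | nsens < 1L,
    outside_8_to_20 = !(ft$time_group %in% 1:3)
  )
  q[, passed := !(off_map_ge_50pct | lt_50pct_expected_points |
                    majority_room_sensorless | outside_8_to_20)]
  ft[, pass := q$passed]
  ft[, failed_criteria := apply(
    as.matrix(q[, .QUALITY_CRITERIA, with = FALSE]), 1L,
    function(r) paste(.QUALITY_CRITERIA[r], collapse = ";"))]
  ft[, time_group := factor(time_group, levels = 1:4)]

  sf <- standardize_features(ft, length_min = L)
  list(features = sf$features, quality = q, standardizer = sf$standardizer)
}
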