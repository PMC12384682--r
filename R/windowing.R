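# Pre-survey window extraction: the analysed interval is
# [t - buffer - length, t - buffer), i.e. it ends `buffer` minutes before the
# survey so that the features predict upcoming agitation rather than detect
# ongoing (audible) agitation. All intervals are half-open: a reading at
# exactly the window start belongs to the window, one at the window end does
# not.

#' Pre-survey window specification
#'
#' @param length_min window length in minutes (the sweep uses 3 to 30 by 3;
#'   the selected analysis window is 21).
#' @param buffer_min gap between window end and the survey timestamp
#'   (default 12 minutes).
#' @return Object of class `window_spec`.
#' @examples
#' window_interval(window_spec(21), 14 * 3600) / 3600  # [13.45h, 13.8h)
#' @export
window_spec <- function(length_min, buffer_min = 12) {
  if (buffer_min < 0) stop("buffer must be non-negative")
  if (length_min <= 0) stop("window length must be positive")
  structure(list(length_min = length_min, buffer_min = buffer_min),
            class = "window_spec")
}

#' @rdname window_spec
#' @param spec a `window_spec`.
#' @param t survey timestamp (seconds since study start).
#' @return `window_interval()`: numeric `c(start, end)` in seconds, half-open.
#' @export
window_interval <- function(spec, t) {
  e <- t - spec$buffer_min * 60
  c(start = e - spec$length_min * 60, end = e)
}

#' Room occupancy within a window
#'
#' Partitions the window over the rooms visited. Time not covered by the
#' trace, and explicit `"off_map"` intervals, count as off-map. The majority
#' room is the room with the most seconds; ties are broken in favour of the
#' room entered earliest within the window.
#'
#' @param trace location intervals for one patient (`start`, `end`,
#'   `room_id`), chronologically sorted, half-open.
#' @param window numeric `c(start, end)` from [window_interval()].
#' @return List with `segments` (chronological, incl. off-map), `occupancy`
#'   (per-room seconds and first entry), `majority_room`,
#'   `majority_room_seconds` and `off_map_fraction`.
#' @export
locate_rooms <- function(trace, window) {
  w0 <- window[[1]]; w1 <- window[[2]]
  stopifnot(w1 > w0)
  tr <- as.data.frame(trace)[, c("start", "end", "room_id")]
  tr <- tr[tr$end > w0 & tr$start < w1, , drop = FALSE]
  tr <- tr[order(tr$start), , drop = FALSE]
  seg <- data.frame(room_id = character(0), start = numeric(0),
                    end = numeric(0), stringsAsFactors = FALSE)
  cur <- w0
  for (i in seq_len(nrow(tr))) {
    s <- max(tr$start[i], w0); e <- min(tr$end[i], w1)
    if (s > cur)  # gap in the trace counts as off-map
      seg <- rbind(seg, data.frame(room_id = "off_map", start = cur, end = s))
    seg <- rbind(seg, data.frame(room_id = tr$room_id[i], start = s, end = e))
    cur <- e
  }
  if (cur < w1)
    seg <- rbind(seg, data.frame(room_id = "off_map", start = cur, end = w1))
  occ <- do.call(rbind, lapply(split(seg, seg$room_id), function(d) {
    data.frame(room_id = d$room_id[1], seconds = sum(d$end - d$start),
               first_entry = min(d$start))
  }))
  occ <- occ[order(-occ$seconds, occ$first_entry), , drop = FALSE]
  rownames(occ) <- NULL
  off <- sum(seg$end[seg$room_id == "off_map"] -
             seg$start[seg$room_id == "off_map"])
  list(segments = seg, occupancy = occ,
       majority_room = occ$room_id[1],
       majority_room_seconds = occ$seconds[1],
       off_map_fraction = off / (w1 - w0))
}

#' Location-conditioned sensor fusion for one modality
#'
#' For each occupied segment, readings of the segment's room are clipped to
#' the segment (half-open). Rooms with two enclosures contribute the
#' timestamp-aligned mean of both sensors (inner join on timestamp);
#' sensorless rooms and off-map time contribute no points. Segments are
#' concatenated chronologically and each point is annotated with its source
#' room.
#'
#' @param sensors long sensor table (`time`, `sensor_id`, `room_id`,
#'   `modality`, `value`).
#' @param segments chronological segments from [locate_rooms()].
#' @param modality one of `"light"`, `"sound"`, `"temperature"`.
#' @param layout optional [ward_layout()]; when given, segment rooms that are
#'   neither ward rooms nor `"off_map"` raise a data-integrity error.
#' @return `data.frame` with `time`, `value`, `room_id`.
#' @export
fuse_sensor_series <- function(sensors, segments, modality, layout = NULL) {
  sen <- as.data.frame(sensors)
  sen <- sen[sen$modality == modality, , drop = FALSE]
  if (!is.null(layout)) {
    bad <- setdiff(unique(segments$room_id),
                   c(layout$rooms$room_id, "off_map"))
    if (length(bad))
      stop("unknown room_id in trace: ", paste(bad, collapse = ", "))
  }
  parts <- lapply(seq_len(nrow(segments)), function(i) {
    room <- segments$room_id[i]
    if (room == "off_map") return(NULL)
    d <- sen[sen$room_id == room &
             sen$time >= segments$start[i] & sen$time < segments$end[i], ,
             drop = FALSE]
    if (!nrow(d)) return(NULL)
    ids <- unique(d$sensor_id)
    if (length(ids) > 1L) {
      # exact-timestamp inner join across the room's enclosures
      tt <- Reduce(intersect, lapply(ids, function(s) d$time[d$sensor_id == s]))
      if (!length(tt)) return(NULL)
      vals <- rowMeans(vapply(ids, function(s) {
        di <- d[d$sensor_id == s, ]
        di$value[match(tt, di$time)]
      }, numeric(length(tt))))
      d <- data.frame(time = tt, value = vals)
    } else {
      d <- d[order(d$time), c("time", "value")]
    }
    d$room_id <- room
    d
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts))
    return(data.frame(time = numeric(0), value = numeric(0),
                      room_id = character(0)))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Trailing moving-average smoother
#'
#' Each point is replaced by the mean of all points in the previous `span`
#' seconds including the point itself, i.e. over `(t - span, t]`. The
#' smoother is causal (no future samples), runs across room-transition
#' boundaries -- smoothing those transitions is its purpose -- and never
#' changes the series length.
#'
#' @param times timestamps (seconds), chronologically sorted.
#' @param values values, same length as `times`.
#' @param span smoothing span in seconds (default 5).
#' @return Numeric vector of smoothed values.
#' @examples
#' smooth_series(0:9, c(rep(0, 5), rep(10, 5)))  # step smoothed to 2,4,...
#' @export
smooth_series <- function(times, values, span = 5) {
  n <- length(values)
  if (n == 0L) return(numeric(0))
  if (is.unsorted(times)) stop("series must be chronologically sorted")
  cs <- c(0, cumsum(values))
  lo <- findInterval(times - span, times)  # points at exactly t - span excluded
  (cs[seq_len(n) + 1L] - cs[lo + 1L]) / (seq_len(n) - lo)
}

#' Extract the full pre-survey window for one survey
#'
#' Composes [locate_rooms()], [fuse_sensor_series()] per modality and
#' [smooth_series()] (applied after concatenation across rooms) into a
#' `window_data` object carrying the smoothed per-modality series, the room
#' occupancy, the majority room and the off-map fraction.
#'
#' @param dataset a `ward_dataset` (or any list with `sensors`, `traces`,
#'   `layout`, `config`).
#' @param survey one row of the survey table (list with `patient_id`, `time`,
#'   optionally `survey_id`).
#' @param spec a [window_spec()].
#' @return Object of class `window_data`.
#' @export
extract_window <- function(dataset, survey, spec) {
  stopifnot(inherits(spec, "window_spec"))
  win <- window_interval(spec, survey$time)
  trace <- dataset$traces[dataset$traces$patient_id == survey$patient_id, ]
  loc <- locate_rooms(trace, win)
  series <- lapply(c(light = "light", sound = "sound",
                     temperature = "temperature"), function(m) {
    s <- fuse_sensor_series(dataset$sensors, loc$segments, m, dataset$layout)
    if (nrow(s))
      s$value <- smooth_series(s$time, s$value,
                               span = dataset$config$smoothing_span)
    s
  })
  structure(list(
    survey_id = survey$survey_id %||% NA_integer_,
    patient_id = survey$patient_id,
    survey_time = survey$time,
    spec = spec,
    window = win,
    series = series,
    occupancy = loc$occupancy,
    majority_room = loc$majority_room,
    majority_room_seconds = loc$majority_room_seconds,
    off_map_fraction = loc$off_map_fraction,
    n_points = vapply(series, nrow, integer(1)),
    precedes_study_start = win[[1]] < 0
  ), class = "window_data")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.window_data <- function(x, ...) {
  cat(sprintf(
    "Pre-survey window [%.0fs, %.0fs) (%g min + %g min buffer)\n",
    x$window[1], x$window[2], x$spec$length_min, x$spec$buffer_min))
  cat(sprintf("  majority room %s (%.0fs), off-map fraction %.2f\n",
              x$majority_room, x$majority_room_seconds, x$off_map_fraction))
  cat("  points:", paste(names(x$n_points), x$n_points, sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}
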