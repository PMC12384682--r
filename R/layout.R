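#' Ward layout
#'
#' A ward layout lists the rooms of the unit, the functional group of each
#' room and how many environmental sensor enclosures it carries (0, 1 or 2;
#' above-average rooms carry two whose readings are averaged). `"off_map"` is
#' a reserved pseudo-room denoting unknown location; it has no group and no
#' sensors and must not appear in the room table.
#'
#' @param rooms data.frame with columns `room_id` (unique character),
#'   `room_group` (one of `"living_room"`, `"dining_room"`, `"hallway"`,
#'   `"patient_room"`, `"other"`) and `n_sensors` (0, 1 or 2).
#' @return An object of class `ward_layout`.
#' @examples
#' ward_layout(data.frame(
#'   room_id = c("lounge", "bedroom"),
#'   room_group = c("living_room", "patient_room"),
#'   n_sensors = c(2, 0)
#' ))
#' @export
ward_layout <- function(rooms) {
  rooms <- as.data.frame(rooms, stringsAsFactors = FALSE)
  stopifnot(all(c("room_id", "room_group", "n_sensors") %in% names(rooms)))
  if (anyDuplicated(rooms$room_id))
    stop("room_ids must be unique")
  if ("off_map" %in% rooms$room_id)
    stop("'off_map' is a reserved pseudo-room and cannot be a ward room")
  if (!all(rooms$room_group %in% room_groups()))
    stop("room_group must be one of: ", paste(room_groups(), collapse = ", "))
  if (!all(rooms$n_sensors %in% 0:2))
    stop("n_sensors must be 0, 1 or 2")
  structure(list(rooms = rooms), class = "ward_layout")
}

#' @export
print.ward_layout <- function(x, ...) {
  cat("Ward layout:", nrow(x$rooms), "rooms,",
      sum(x$rooms$n_sensors), "sensor enclosures\n")
  print(x$rooms, row.names = FALSE)
  invisible(x)
}

#' Room groups used for the majority-room covariate
#' @return Character vector of the five room groups (reference level first).
#' @export
room_groups <- function() {
  c("living_room", "dining_room", "hallway", "patient_room", "other")
}

#' Default synthetic ward layout
#'
#' Communal living and dining spaces (large enough for two sensor enclosures
#' each), a hallway, three patient rooms (one without a sensor, so the
#' off-sensor path is exercised) and a therapy room.
#'
#' @return A [ward_layout()].
#' @export
default_ward_layout <- function() {
  ward_layout(data.frame(
    room_id = c("living_room", "dining_room", "hallway_a",
                "patient_room_1", "patient_room_2", "patient_room_3",
                "therapy_room"),
    room_group = c("living_room", "dining_room", "hallway",
                   "patient_room", "patient_room", "patient_room",
                   "other"),
    n_sensors = c(2L, 2L, 1L, 1L, 1L, 0L, 1L),
    stringsAsFactors = FALSE
  ))
}

# sensor table skeleton: one row per enclosure
sensor_index <- function(layout) {
  rooms <- layout$rooms[layout$rooms$n_sensors > 0, , drop = FALSE]
  data.frame(
    sensor_id = unlist(lapply(seq_len(nrow(rooms)), function(i) {
      paste0(rooms$room_id[i], "_s", seq_len(rooms$n_sensors[i]))
    })),
    room_id = rep(rooms$room_id, rooms$n_sensors),
    stringsAsFactors = FALSE
  )
}

validate_layout <- function(layout) {
  if (!inherits(layout, "ward_layout")) stop("not a ward_layout")
  r <- layout$rooms
  if (!all(room_groups() %in% r$room_group))
    stop("layout must contain at least one room of every group")
  if (!any(r$n_sensors == 0L) || !any(r$n_sensors == 2L))
    stop("layout must contain at least one sensorless and one dual-sensor room")
  invisible(layout)
}
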