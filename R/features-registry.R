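# The 70-feature registry.
#
# The registry reconstructs the sensing feature set from its published
# family enumerations (time, location, motion, communication, device use,
# environment) padded with the standard descriptive-statistic variants;
# the exact published name list is not available, so the mapping is a
# documented reconstruction.  `agg` records how an epoch-level quantity is
# combined over an analysis window: "mean" averages epoch values, "pooled"
# recomputes the statistic on all records pooled over the window (required
# for mobility metrics such as the radius of gyration), "sum" accumulates
# counts/durations, "time" marks the two time encodings.

feature_registry_build <- function() {
  f <- function(name, family, stream, agg, units) {
    data.table::data.table(name = name, family = family, stream = stream,
                           agg = agg, units = units)
  }
  reg <- data.table::rbindlist(list(
    f(c("hour_of_day", "day_of_week"), "time", "clock", "time", "encoded"),
    f(c("acc_mag_mean", "acc_mag_median", "acc_mag_std", "acc_mag_max",
        "acc_mag_min", "acc_mag_range"),
      "motion", "accel", "mean", "m/s^2"),
    f(c("lat_mean", "lat_median", "lat_std", "lat_min", "lat_max", "lat_range",
        "lon_mean", "lon_median", "lon_std", "lon_min", "lon_max", "lon_range",
        "lat_std_stationary", "lon_std_stationary"),
      "location", "gps", "pooled", "degrees"),
    f("radius_of_gyration", "location", "gps", "pooled", "m"),
    f("location_variance", "location", "gps", "pooled", "degrees^2"),
    f(c("location_entropy", "location_entropy_norm"), "location", "gps",
      "pooled", "nats"),
    f("circadian_movement", "location", "gps", "pooled", "log-energy"),
    f("travel_distance", "location", "gps", "pooled", "m"),
    f(c("travel_speed_mean", "travel_speed_max"), "location", "gps", "pooled", "m/s"),
    f("travel_speed_var", "location", "gps", "pooled", "(m/s)^2"),
    f(c("n_locations_passed", "n_places_visited", "n_place_transitions"),
      "location", "gps", "pooled", "count"),
    f("moving_fraction", "location", "gps", "pooled", "fraction"),
    f("time_at_home", "location", "gps", "pooled", "fraction"),
    f(c("dist_home_mean", "dist_home_max"), "location", "gps", "pooled", "m"),
    f(c("stay_duration_mean", "stay_duration_max", "stay_duration_total"),
      "location", "gps", "pooled", "min"),
    f(paste0("dwell_place_", 1:5), "location", "gps", "pooled", "min"),
    f(c("dwell_frac_top1", "dwell_frac_top2"), "location", "gps", "pooled",
      "fraction"),
    f(c("n_calls_in", "n_calls_out"), "communication", "comm", "sum", "count"),
    f(c("call_dur_in", "call_dur_out"), "communication", "comm", "sum", "s"),
    f("call_dur_mean", "communication", "comm", "pooled", "s"),
    f("n_sms", "communication", "comm", "sum", "count"),
    f("n_contacts", "communication", "comm", "pooled", "count"),
    f(c("n_screen_on", "n_screen_off"), "device", "device", "sum", "count"),
    f(c("screen_use_duration", "screen_session_mean"), "device", "device",
      "pooled", "s"),
    f(c("n_unique_apps", "n_app_switches", "n_foreground_apps"), "device",
      "device", "pooled", "count"),
    f("app_use_duration", "device", "device", "pooled", "s"),
    f(c("charging_duration", "time_fully_charged"), "device", "device",
      "pooled", "s"),
    f(c("battery_pct_mean", "battery_pct_min", "battery_pct_max",
        "battery_pct_std"), "device", "device", "pooled", "percent"),
    f("n_unique_wifi", "environment", "wifi", "pooled", "count")
  ))
  stopifnot(nrow(reg) == 70L, !anyDuplicated(reg$name))
  reg
}

.registry_cache <- new.env(parent = emptyenv())

#' The 70-feature registry
#'
#' One row per model feature: name, family (time, location, motion,
#' communication, device, environment), source stream, window-aggregation
#' semantics, and units.
#'
#' @return data.table with 70 rows
#' @export
feature_registry <- function() {
  if (is.null(.registry_cache$reg)) .registry_cache$reg <- feature_registry_build()
  data.table::copy(.registry_cache$reg)
}

#' Export the feature registry as JSON
#' @param path output file
#' @return `path`, invisibly
#' @export
write_feature_spec <- function(path) {
  jsonlite::write_json(feature_registry(), path, dataframe = "rows",
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
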