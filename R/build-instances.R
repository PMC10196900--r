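# From raw streams + labeled events to model-ready instance matrices.
#
# Records are tagged once with the event whose 24-hour pre-onset day they
# fall in (rel_s in [0, 86400) relative to onset - 24 h); an analysis-window
# slice for a (w, d) configuration is then a cheap filter on rel_s.
# Mobility features are recomputed on the pooled window; accelerometer
# statistics follow the two-stage per-minute/per-epoch scheme and are
# averaged over the window's epochs; communication/device counts are true
# zeros when no events occur.

#' Tag stream records with events and precompute places
#'
#' @param streams `sensor_streams`
#' @param events labeled events (from [build_events()]); must carry `onset`
#' @param interpolate fill short (<= 15 min) gaps in GPS/accel/wifi with
#'   flanking averages before tagging
#' @return a `prepared_cohort` list: tagged per-stream records, events,
#'   per-participant significant places and homes
#' @export
prepare_cohort <- function(streams, events, interpolate = TRUE) {
  ev <- data.table::as.data.table(events)
  stopifnot(all(is.finite(ev$onset)))
  if (interpolate) {
    if (nrow(streams$gps %||% data.table::data.table())) {
      streams$gps <- interpolate_gaps(streams$gps, c("lat", "lon"),
                                      cadence_s = gps_cadence(streams$gps))
    }
    if (nrow(streams$accel %||% data.table::data.table())) {
      streams$accel <- interpolate_gaps(streams$accel, c("x", "y", "z"),
                                        cadence_s = gps_cadence(streams$accel))
    }
  }
  win <- ev[, .(participant_id, event_id,
                ws = snap_epoch(onset) - SECONDS_PER_DAY,
                we = snap_epoch(onset))]
  data.table::setkey(win, participant_id, ws, we)
  tag <- function(dt) {
    if (is.null(dt) || !nrow(dt)) return(data.table::data.table())
    pts <- data.table::copy(dt)[, `:=`(start = t, end = t)]
    hit <- data.table::foverlaps(pts, win,
                                 by.x = c("participant_id", "start", "end"),
                                 type = "within", nomatch = NULL)
    hit <- hit[start < we] # windows are half-open [ws, we)
    hit[, rel_s := t - ws]
    hit[, c("start", "end", "ws", "we") := NULL]
    data.table::setorder(hit, event_id, t)
    hit[]
  }
  tagged <- lapply(streams, tag)

  # study-period significant places + home per participant
  places <- list(); homes <- list()
  gps_all <- streams$gps
  pids <- unique(ev$participant_id)
  for (pid in pids) {
    g <- gps_all[participant_id == pid]
    sp <- if (nrow(g)) stay_points(g$t, g$lat, g$lon) else
      stay_points(numeric(0), numeric(0), numeric(0))
    pl <- significant_places(sp)
    places[[pid]] <- pl
    h <- pl[is_home == TRUE]
    homes[[pid]] <- data.table::data.table(
      participant_id = pid,
      home_lat = if (nrow(h)) h$lat else NA_real_,
      home_lon = if (nrow(h)) h$lon else NA_real_)
  }
  homes <- data.table::rbindlist(homes)
  if (nrow(tagged$gps)) {
    tagged$gps[, place := {
      pl <- places[[participant_id[1]]]
      assign_places(lat, lon, pl)
    }, by = participant_id]
  }
  structure(list(tagged = tagged, events = ev, places = places, homes = homes),
            class = "prepared_cohort")
}

gps_cadence <- function(dt) {
  d <- dt[, .(m = median(as.numeric(diff(t)))), by = participant_id]$m
  max(1, median(d, na.rm = TRUE))
}

slice_window <- function(tagged, w, d) {
  lo <- SECONDS_PER_DAY - (w + d) * 3600
  hi <- SECONDS_PER_DAY - d * 3600
  lapply(tagged, function(dt) {
    if (!nrow(dt)) dt else dt[rel_s >= lo & rel_s < hi]
  })
}

#' Build the model instance matrix for one window configuration
#'
#' One row per event: the 70 registry features computed on the
#' `[onset-(w+d), onset-d)` analysis window, the two time encodings
#' (hour of day at prediction time `onset - d`, day of week of the event),
#' the class label and keys.  No record at or after `onset - d`
#' contributes (temporal separation).
#'
#' @param prep a [prepare_cohort()] result
#' @param w analysis window, hours (1, 3, 6, 9 or 12 in the default grid)
#' @param d prediction distance, hours (1, 3 or 6)
#' @return data.table: keys, 70 feature columns, `label`, `day_class`
#' @export
build_instances <- function(prep, w, d) {
  if (w + d > 24) stop("w + d must not exceed 24 hours", call. = FALSE)
  ev <- prep$events
  sl <- slice_window(prep$tagged, w, d)
  reg <- feature_registry()
  homes <- prep$homes

  gps_f <- if (nrow(sl$gps)) {
    sl$gps[homes, on = "participant_id"][
      , c(list(event_id = event_id[1]),
          gps_window_features(t, lat, lon, place, home_lat[1], home_lon[1])),
      by = .(eid = event_id)][, eid := NULL][]
  } else NULL

  acc_f <- if (nrow(sl$accel)) {
    pm <- sl$accel[, .(mag = mean(sqrt(x^2 + y^2 + z^2))),
                   by = .(event_id, epoch = floor(rel_s / EPOCH_SECONDS),
                          minute = floor(rel_s / 60))]
    es <- pm[, .(m = mean(mag), md = median(mag),
                 s = if (.N > 1) sd(mag) else 0, mx = max(mag),
                 mn = min(mag)),
             by = .(event_id, epoch)]
    es[, .(acc_mag_mean = mean(m), acc_mag_median = mean(md),
           acc_mag_std = mean(s), acc_mag_max = mean(mx),
           acc_mag_min = mean(mn), acc_mag_range = mean(mx - mn)),
       by = event_id]
  } else NULL

  comm_f <- if (nrow(sl$comm)) {
    sl$comm[, comm_features(kind, duration, contact_id), by = event_id]
  } else NULL

  dev_f <- if (nrow(sl$device)) {
    hi <- SECONDS_PER_DAY - d * 3600
    sl$device[, device_features(rel_s, kind, app_id, battery_pct, charging,
                                w_end = hi), by = event_id]
  } else NULL

  wifi_f <- if (nrow(sl$wifi)) {
    sl$wifi[, .(n_unique_wifi = wifi_feature(n_unique_hotspots)), by = event_id]
  } else NULL

  out <- ev[, .(event_id, participant_id, date, label, day_class, pseudo,
                hour_of_day = hour_of_day(snap_epoch(onset) - d * 3600),
                day_of_week = day_of_week(date * SECONDS_PER_DAY))]
  for (part in list(gps_f, acc_f, comm_f, dev_f, wifi_f)) {
    if (!is.null(part)) out <- merge(out, part, by = "event_id", all.x = TRUE)
  }
  # true zeros for count-like features of event streams; NA only means the
  # stream itself was absent for location/motion/battery-level features
  zero_fill <- reg[family %in% c("communication", "environment") |
                     (family == "device" & !grepl("battery_pct", name)), name]
  for (cn in setdiff(reg$name, names(out))) out[, (cn) := NA_real_]
  for (cn in zero_fill) data.table::set(out, which(is.na(out[[cn]])), cn, 0)
  data.table::setcolorder(out, c("event_id", "participant_id", "date",
                                 "label", "day_class", "pseudo", reg$name))
  out[, w := w][, d := d][]
}

#' Per-event 24-hour feature rows
#'
#' The full pre-onset day (`w = 18, d = 6` covers the maximal usable span
#' for a grid; here the whole `[onset-24h, onset)` day is used) evaluated
#' for the inclusion/exclusion rules.
#'
#' @param prep a [prepare_cohort()] result
#' @return data.table keyed by `event_id`
#' @export
day_feature_rows <- function(prep) {
  # the full 96-slot day: w = 24 h ending at onset (d = 0 is allowed here
  # because these rows feed the exclusion rule, not a model)
  ev <- prep$events
  reg <- feature_registry()
  homes <- prep$homes
  g <- prep$tagged$gps
  gps_f <- if (nrow(g)) {
    g[homes, on = "participant_id"][
      , c(list(event_id = event_id[1]),
          gps_window_features(t, lat, lon, place, home_lat[1], home_lon[1])),
      by = .(eid = event_id)][, eid := NULL][]
  } else NULL
  a <- prep$tagged$accel
  acc_f <- if (nrow(a)) {
    a[, .(acc_mag_mean = mean(sqrt(x^2 + y^2 + z^2))), by = event_id]
  } else NULL
  out <- ev[, .(event_id)]
  for (part in list(gps_f, acc_f)) {
    if (!is.null(part)) out <- merge(out, part, by = "event_id", all.x = TRUE)
  }
  for (cn in setdiff(c(reg[family == "location", name], "acc_mag_mean"),
                     names(out))) {
    out[, (cn) := NA_real_]
  }
  out[]
}

#' Epoch-level feature rows for a window (alternative instance granularity)
#'
#' One row per 15-minute epoch of the analysis window, with epoch-scoped
#' features; provided as the alternative to the default event-level
#' instances.
#'
#' @inheritParams build_instances
#' @return data.table with one row per (event, epoch slot)
#' @export
build_epoch_instances <- function(prep, w, d) {
  sl <- slice_window(prep$tagged, w, d)
  ev <- prep$events
  slots <- window_slots(w, d)
  grid <- data.table::CJ(event_id = ev$event_id, epoch = slots)
  homes <- prep$homes
  gps_f <- if (nrow(sl$gps)) {
    sl$gps[, epoch := floor(rel_s / EPOCH_SECONDS)][
      homes, on = "participant_id"][
      , c(list(event_id = event_id[1], epoch = epoch[1]),
          gps_window_features(t, lat, lon, place, home_lat[1], home_lon[1])),
      by = .(eid = event_id, ep = epoch)][, c("eid", "ep") := NULL][]
  } else NULL
  acc_f <- if (nrow(sl$accel)) {
    sl$accel[, epoch := floor(rel_s / EPOCH_SECONDS)][
      , accel_features(rel_s, x, y, z), by = .(event_id, epoch)]
  } else NULL
  comm_f <- if (nrow(sl$comm)) {
    sl$comm[, epoch := floor(rel_s / EPOCH_SECONDS)][
      , comm_features(kind, duration, contact_id), by = .(event_id, epoch)]
  } else NULL
  out <- merge(grid,
               ev[, .(event_id, participant_id, label, day_class,
                      onset_day = snap_epoch(onset) - SECONDS_PER_DAY,
                      day_of_week = day_of_week(date * SECONDS_PER_DAY))],
               by = "event_id")
  out[, hour_of_day := hour_of_day(onset_day + epoch * EPOCH_SECONDS)]
  out[, onset_day := NULL]
  for (part in list(gps_f, acc_f, comm_f)) {
    if (!is.null(part)) out <- merge(out, part, by = c("event_id", "epoch"),
                                     all.x = TRUE)
  }
  out[]
}
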