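# Per-window feature computation for each stream family.

#' Accelerometer epoch features (two-stage)
#'
#' Magnitude `sqrt(x^2+y^2+z^2)` is averaged per minute first; the epoch
#' statistics (mean, median, std, max) are then taken over the per-minute
#' means.  An empty epoch gives all-`NA`.
#'
#' @param t sample times (s); @param x,y,z components
#' @return named list: `acc_mag_mean`, `acc_mag_median`, `acc_mag_std`,
#'   `acc_mag_max`
#' @export
accel_features <- function(t, x, y, z) {
  if (!length(t)) {
    return(list(acc_mag_mean = NA_real_, acc_mag_median = NA_real_,
                acc_mag_std = NA_real_, acc_mag_max = NA_real_,
                acc_mag_min = NA_real_, acc_mag_range = NA_real_))
  }
  mag <- sqrt(x^2 + y^2 + z^2)
  per_min <- tapply(mag, floor(t / 60), mean)
  list(acc_mag_mean = mean(per_min), acc_mag_median = median(per_min),
       acc_mag_std = if (length(per_min) > 1) sd(per_min) else 0,
       acc_mag_max = max(per_min), acc_mag_min = min(per_min),
       acc_mag_range = max(per_min) - min(per_min))
}

#' Communication features over a window
#'
#' Simple counts and sums; an empty window is a true zero (absence of
#' communication is informative, not missing).
#'
#' @param kind,duration,contact_id window-scoped communication records
#' @return named list of the 6 communication features
#' @export
comm_features <- function(kind = character(0), duration = numeric(0),
                          contact_id = character(0)) {
  calls <- duration[kind != "sms"]
  out <- list(n_calls_in = sum(kind == "call_in"),
              n_calls_out = sum(kind == "call_out"),
              call_dur_in = sum(duration[kind == "call_in"]),
              call_dur_out = sum(duration[kind == "call_out"]),
              call_dur_mean = if (length(calls)) mean(calls) else 0,
              n_sms = sum(kind == "sms"),
              n_contacts = length(unique(contact_id)))
  lapply(out, as.numeric)
}

#' Device-use features over a window
#'
#' Screen sessions pair each `screen_on` with the next `screen_off`; an
#' unpaired trailing on-event is truncated at the window end.  An app switch
#' is a change of foreground app between consecutive foreground events.
#' Charging/fully-charged durations accumulate the time between consecutive
#' battery reads in the respective state.
#'
#' @param t,kind,app_id,battery_pct,charging window-scoped device records
#' @param w_end window end (same clock as `t`)
#' @return named list of the 14 device features
#' @export
device_features <- function(t = numeric(0), kind = character(0),
                            app_id = character(0), battery_pct = numeric(0),
                            charging = logical(0), w_end = Inf) {
  o <- order(t)
  t <- t[o]; kind <- kind[o]; app_id <- app_id[o]
  battery_pct <- battery_pct[o]; charging <- charging[o]

  ons <- t[kind == "screen_on"]; offs <- t[kind == "screen_off"]
  sess <- numeric(0)
  if (length(ons)) {
    for (on in ons) {
      nxt <- offs[offs > on]
      sess <- c(sess, (if (length(nxt)) min(nxt[1], w_end) else min(w_end, Inf)) - on)
    }
    sess <- pmax(sess[is.finite(sess)], 0)
  }
  apps <- app_id[kind == "app_foreground"]
  app_t <- t[kind == "app_foreground"]
  app_dur <- if (length(app_t)) {
    sum(pmin(diff(c(app_t, min(w_end, max(app_t) + 300))), 1800))
  } else 0
  bp <- battery_pct[kind == "battery"]
  bt <- t[kind == "battery"]
  bc <- charging[kind == "battery"]
  chg_dur <- full_dur <- 0
  if (length(bt) > 1) {
    gap <- diff(bt)
    chg_dur <- sum(gap[bc[-length(bc)] %in% TRUE])
    full_dur <- sum(gap[(bp[-length(bp)] >= 100) %in% TRUE])
  }
  out <- list(n_screen_on = length(ons), n_screen_off = length(offs),
       screen_use_duration = sum(sess),
       screen_session_mean = if (length(sess)) mean(sess) else 0,
       n_unique_apps = length(unique(apps)),
       app_use_duration = app_dur,
       n_app_switches = if (length(apps) > 1) sum(apps[-1] != apps[-length(apps)]) else 0,
       n_foreground_apps = length(apps),
       charging_duration = chg_dur,
       time_fully_charged = full_dur,
       battery_pct_mean = if (length(bp)) mean(bp) else NA_real_,
       battery_pct_min = if (length(bp)) min(bp) else NA_real_,
       battery_pct_max = if (length(bp)) max(bp) else NA_real_,
       battery_pct_std = if (length(bp) > 1) sd(bp) else NA_real_)
  lapply(out, as.numeric)
}

#' Unique Wi-Fi hotspots seen in a window
#'
#' With hotspot identifier sets, the union count; the long-format scan
#' schema carries only per-scan unique counts, in which case the largest
#' per-scan count is used (a lower bound on the union).
#'
#' @param counts per-scan unique-hotspot counts
#' @param ids optional list of per-scan identifier vectors
#' @return count (0 with no scans)
#' @export
wifi_feature <- function(counts = numeric(0), ids = NULL) {
  if (!is.null(ids)) return(length(unique(unlist(ids))))
  if (!length(counts)) return(0L)
  as.integer(max(counts))
}

#' GPS features pooled over a window
#'
#' Computes the 43 location features on all fixes pooled over the window
#' (mobility metrics such as the radius of gyration are not averages of
#' per-epoch values).  With zero fixes every feature is `NA`; absence of
#' location data is missing, never zero.
#'
#' @param t,lat,lon window-scoped fixes (sorted by `t`)
#' @param place integer place id per fix (`NA` = no significant place)
#' @param home_lat,home_lon designated home (NA if undesignated)
#' @param grid_decimals rounding used to count "locations passed" while moving
#' @return named list of location features
#' @export
gps_window_features <- function(t, lat, lon, place = rep(NA_integer_, length(t)),
                                home_lat = NA_real_, home_lon = NA_real_,
                                grid_decimals = 3) {
  reg <- feature_registry()
  out <- setNames(as.list(rep(NA_real_, sum(reg$family == "location"))),
                  reg[family == "location", name])
  n <- length(t)
  if (!n) return(out)
  out$lat_mean <- mean(lat); out$lat_median <- median(lat)
  out$lat_min <- min(lat); out$lat_max <- max(lat)
  out$lat_range <- out$lat_max - out$lat_min
  out$lon_mean <- mean(lon); out$lon_median <- median(lon)
  out$lon_min <- min(lon); out$lon_max <- max(lon)
  out$lon_range <- out$lon_max - out$lon_min
  if (n > 1) { out$lat_std <- sd(lat); out$lon_std <- sd(lon) }
  out$radius_of_gyration <- radius_of_gyration(lat, lon)
  if (n > 1) out$location_variance <- location_variance(lat, lon)
  out$circadian_movement <- circadian_movement(t, lat, lon)

  if (n > 1) {
    step <- haversine_m(lat[-n], lon[-n], lat[-1], lon[-1])
    dt_ <- pmax(diff(t), 1)
    speed <- step / dt_
    out$travel_distance <- sum(step)
    out$travel_speed_mean <- mean(speed)
    out$travel_speed_max <- max(speed)
    out$travel_speed_var <- if (length(speed) > 1) var(speed) else 0
    moving <- speed >= STATIONARY_SPEED_MS
    out$moving_fraction <- mean(moving)
    stat_idx <- c(TRUE, !moving) # fix i stationary if step into it was slow
    if (sum(stat_idx) > 1) {
      out$lat_std_stationary <- sd(lat[stat_idx])
      out$lon_std_stationary <- sd(lon[stat_idx])
    }
    if (any(moving)) {
      cells <- unique(paste(round(lat[-1][moving], grid_decimals),
                            round(lon[-1][moving], grid_decimals)))
      out$n_locations_passed <- length(cells)
    } else out$n_locations_passed <- 0
  }

  if (is.finite(home_lat)) {
    dh <- haversine_m(lat, lon, home_lat, home_lon)
    out$time_at_home <- mean(dh <= 200)
    out$dist_home_mean <- mean(dh); out$dist_home_max <- max(dh)
  }

  # dwell weighting: each fix carries the gap to the next fix (last fix the
  # median gap), so sparse sampling does not distort dwell shares
  wgt <- if (n > 1) c(pmin(diff(t), 3600), median(pmin(diff(t), 3600))) else 1
  pl <- place
  if (any(!is.na(pl))) {
    dwell <- tapply(wgt[!is.na(pl)], pl[!is.na(pl)], sum) / 60
    out$location_entropy <- location_entropy(as.numeric(dwell))
    out$location_entropy_norm <- if (length(dwell) > 1) {
      out$location_entropy / log(length(dwell))
    } else NA_real_
    out$n_places_visited <- length(dwell)
    seqp <- pl[!is.na(pl)]
    out$n_place_transitions <- if (length(seqp) > 1) {
      sum(seqp[-1] != seqp[-length(seqp)])
    } else 0
    runs <- rle(as.integer(seqp))
    run_min <- tapply(wgt[!is.na(pl)],
                      rep(seq_along(runs$lengths), runs$lengths), sum) / 60
    out$stay_duration_mean <- mean(run_min)
    out$stay_duration_max <- max(run_min)
    out$stay_duration_total <- sum(run_min)
    for (k in 1:5) {
      out[[paste0("dwell_place_", k)]] <-
        if (as.character(k) %in% names(dwell)) as.numeric(dwell[as.character(k)]) else 0
    }
    srt <- sort(as.numeric(dwell), decreasing = TRUE)
    out$dwell_frac_top1 <- srt[1] / sum(srt)
    out$dwell_frac_top2 <- if (length(srt) > 1) sum(srt[1:2]) / sum(srt) else NA_real_
  } else {
    out$n_places_visited <- 0
    out$n_place_transitions <- 0
  }
  lapply(out, function(v) as.numeric(v)[1])
}
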