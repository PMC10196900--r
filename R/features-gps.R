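# GPS mobility features: distances, radius of gyration, entropy, variance,
# Lomb-Scargle circadian movement, stay points and significant places.

EARTH_RADIUS_M <- 6371000

#' Great-circle (haversine) distance in meters
#'
#' @param lat1,lon1,lat2,lon2 coordinates in degrees (vectorized)
#' @return distance(s) in meters
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_M)
}

#' Radius of gyration of a set of GPS fixes
#'
#' Root-mean-square haversine distance of the fixes from their coordinate
#' centroid: the radius of the circle of typical travel during the window.
#'
#' @param lat,lon coordinates in degrees
#' @return meters, or `NA` with no fixes
#' @export
radius_of_gyration <- function(lat, lon) {
  ok <- is.finite(lat) & is.finite(lon)
  lat <- lat[ok]; lon <- lon[ok]
  if (!length(lat)) return(NA_real_)
  d <- haversine_m(lat, lon, mean(lat), mean(lon))
  sqrt(mean(d^2))
}

#' Shannon entropy of time spent across significant places
#'
#' @param dwell non-negative dwell times (any unit), one per place
#' @return entropy in nats; `NA` if all dwell is zero
#' @export
location_entropy <- function(dwell) {
  dwell <- dwell[is.finite(dwell) & dwell > 0]
  if (!length(dwell)) return(NA_real_)
  p <- dwell / sum(dwell)
  -sum(p * log(p))
}

#' Sum of latitude and longitude variances (population variance)
#'
#' @param lat,lon coordinates in degrees
#' @return degrees^2; `NA` with fewer than 2 fixes
#' @export
location_variance <- function(lat, lon) {
  ok <- is.finite(lat) & is.finite(lon)
  lat <- lat[ok]; lon <- lon[ok]
  n <- length(lat)
  if (n < 2) return(NA_real_)
  pv <- function(x) mean((x - mean(x))^2)
  pv(lat) + pv(lon)
}

#' Classic Lomb-Scargle periodogram
#'
#' Normalized periodogram of an irregularly sampled series: equivalent to
#' the least-squares power of a sinusoid fit at each frequency, using the
#' time-offset (tau) form.
#'
#' @param t sample times (seconds)
#' @param y values
#' @param freq frequencies in Hz at which to evaluate
#' @return numeric vector of normalized power values
#' @export
lomb_scargle <- function(t, y, freq) {
  y <- y - mean(y)
  s2 <- stats::var(y) * (length(y) - 1) / length(y)
  if (s2 <= 0) return(rep(0, length(freq)))
  vapply(freq, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
    (sum(y * ct)^2 / sum(ct^2) + sum(y * st)^2 / sum(st^2)) / (2 * s2)
  }, numeric(1))
}

#' Band energy of the Lomb-Scargle periodogram around a period
#'
#' Trapezoid-integrated periodogram power over the period band
#' `[period_lo, period_hi]` hours.
#'
#' @param t times (s); @param y values
#' @param period_lo,period_hi band limits in hours
#' @param n_freq number of evaluation frequencies across the band
#' @return integrated power (dimensionless x Hz)
#' @export
ls_band_energy <- function(t, y, period_lo = 23.5, period_hi = 24.5,
                           n_freq = 25) {
  freqs <- seq(1 / (period_hi * 3600), 1 / (period_lo * 3600),
               length.out = n_freq)
  p <- lomb_scargle(t, y, freqs)
  sum((p[-1] + p[-n_freq]) / 2 * diff(freqs))
}

#' Circadian movement of a location trajectory
#'
#' `ln(E_lat + E_lon)` where E is the integrated Lomb-Scargle power of the
#' latitude (resp. longitude) series over the 23.5-24.5 h period band; a
#' measure of how strongly movement follows a 24-hour rhythm.  Requires at
#' least `min_fixes` fixes spanning at least `min_span_h` hours; shorter
#' series give `NA`.  Zero band energy is floored at `ln(1e-12)`.
#'
#' @param t fix times (s); @param lat,lon degrees
#' @param min_fixes,min_span_h preconditions
#' @return log band energy or `NA`
#' @export
circadian_movement <- function(t, lat, lon, min_fixes = 24, min_span_h = 24) {
  ok <- is.finite(lat) & is.finite(lon)
  t <- t[ok]; lat <- lat[ok]; lon <- lon[ok]
  if (length(t) < min_fixes || diff(range(t)) < min_span_h * 3600 * 0.999) {
    return(NA_real_)
  }
  e <- ls_band_energy(t, lat) + ls_band_energy(t, lon)
  log(max(e, 1e-12))
}

# --- stay points and significant places -----------------------------------

STATIONARY_SPEED_MS <- 1.4 # walking pace

#' Stay-point extraction from a GPS trajectory
#'
#' Runs of consecutive fixes moving slower than the stationary speed
#' threshold, lasting at least `min_dwell_s` and staying within
#' `max_radius_m` of the run centroid, become stay points.
#'
#' @param t,lat,lon sorted trajectory for one participant
#' @param min_dwell_s minimum dwell (default 10 min)
#' @param max_radius_m maximum excursion from the run centroid
#' @return data.table of stay points: `lat`, `lon`, `t_start`, `t_end`,
#'   `dwell_min`
#' @export
stay_points <- function(t, lat, lon, min_dwell_s = 600, max_radius_m = 150) {
  n <- length(t)
  empty <- data.table::data.table(lat = numeric(0), lon = numeric(0),
                                  t_start = numeric(0), t_end = numeric(0),
                                  dwell_min = numeric(0))
  if (n < 2) return(empty)
  step <- haversine_m(lat[-n], lon[-n], lat[-1], lon[-1])
  dt_ <- pmax(diff(t), 1)
  stationary <- c(TRUE, step / dt_ < STATIONARY_SPEED_MS)
  r <- rle(stationary)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  rows <- lapply(keep, function(k) {
    i <- starts[k]:ends[k]
    if (t[max(i)] - t[min(i)] < min_dwell_s) return(NULL)
    clat <- mean(lat[i]); clon <- mean(lon[i])
    if (max(haversine_m(lat[i], lon[i], clat, clon)) > max_radius_m) return(NULL)
    data.table::data.table(lat = clat, lon = clon,
                           t_start = t[min(i)], t_end = t[max(i)],
                           dwell_min = (t[max(i)] - t[min(i)]) / 60)
  })
  out <- data.table::rbindlist(rows)
  if (!nrow(out)) empty else out
}

#' Cluster stay points into significant places
#'
#' Greedy dwell-weighted centroid clustering: stay points are visited in
#' decreasing dwell order and merged into the nearest existing place within
#' `cluster_radius_m`, otherwise open a new place.  The place with maximal
#' night-time (00:00-06:00) dwell is flagged as home.
#'
#' @param sp stay points (from [stay_points()])
#' @param cluster_radius_m merge radius
#' @return data.table of places: `place_id`, `lat`, `lon`, `dwell_min`,
#'   `is_home`, ordered by total dwell (place 1 = most dwell)
#' @export
significant_places <- function(sp, cluster_radius_m = 200) {
  empty <- data.table::data.table(place_id = integer(0), lat = numeric(0),
                                  lon = numeric(0), dwell_min = numeric(0),
                                  is_home = logical(0))
  if (!nrow(sp)) return(empty)
  ord <- order(-sp$dwell_min)
  c_lat <- numeric(0); c_lon <- numeric(0); c_w <- numeric(0)
  assign <- integer(nrow(sp))
  for (i in ord) {
    if (length(c_lat)) {
      d <- haversine_m(rep(sp$lat[i], length(c_lat)),
                       rep(sp$lon[i], length(c_lat)), c_lat, c_lon)
      j <- which.min(d)
    }
    if (length(c_lat) && d[j] <= cluster_radius_m) {
      w <- sp$dwell_min[i]
      c_lat[j] <- (c_lat[j] * c_w[j] + sp$lat[i] * w) / (c_w[j] + w)
      c_lon[j] <- (c_lon[j] * c_w[j] + sp$lon[i] * w) / (c_w[j] + w)
      c_w[j] <- c_w[j] + w
      assign[i] <- j
    } else {
      c_lat <- c(c_lat, sp$lat[i]); c_lon <- c(c_lon, sp$lon[i])
      c_w <- c(c_w, sp$dwell_min[i])
      assign[i] <- length(c_lat)
    }
  }
  # night dwell per cluster for home designation
  night_frac <- vapply(seq_len(nrow(sp)), function(i) {
    sod_s <- sp$t_start[i] %% SECONDS_PER_DAY
    sod_e <- sod_s + (sp$t_end[i] - sp$t_start[i])
    # overlap of [sod_s, sod_e) with nightly [0, 6h) windows (approximate:
    # clip to the first crossed night window)
    ov <- function(a, b) max(0, min(b, 6 * 3600) - max(a, 0))
    (ov(sod_s, sod_e) + ov(sod_s - SECONDS_PER_DAY, sod_e - SECONDS_PER_DAY)) / 60
  }, numeric(1))
  night <- tapply(night_frac, assign, sum)
  dwell <- tapply(sp$dwell_min, assign, sum)
  out <- data.table::data.table(
    cluster = as.integer(names(dwell)),
    lat = c_lat[as.integer(names(dwell))],
    lon = c_lon[as.integer(names(dwell))],
    dwell_min = as.numeric(dwell),
    night_min = as.numeric(night))
  data.table::setorder(out, -dwell_min)
  out[, place_id := seq_len(.N)]
  home_id <- if (any(out$night_min > 0)) out$place_id[which.max(out$night_min)] else NA_integer_
  out[, is_home := place_id == home_id & !is.na(home_id)]
  out[, .(place_id, lat, lon, dwell_min, is_home)]
}

#' Assign each GPS fix to its nearest significant place
#'
#' @param lat,lon fix coordinates
#' @param places places table (from [significant_places()])
#' @param max_dist_m assignment radius
#' @return integer place ids (`NA` when no place within radius)
#' @export
assign_places <- function(lat, lon, places, max_dist_m = 200) {
  if (!nrow(places)) return(rep(NA_integer_, length(lat)))
  n <- length(lat)
  best <- rep(NA_integer_, n)
  best_d <- rep(Inf, n)
  for (k in seq_len(nrow(places))) {
    d <- haversine_m(lat, lon, places$lat[k], places$lon[k])
    upd <- which(d < best_d & d <= max_dist_m)
    best[upd] <- places$place_id[k]
    best_d[upd] <- d[upd]
  }
  best
}
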