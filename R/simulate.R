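# Seeded synthetic cohort generator.
#
# Mechanism: each participant lives around a home anchor with a work anchor
# and 2-5 venue anchors.  A per-day latent "going-out" state (implied by the
# day's drinking class) injects, in the hours before drinking onset, a venue
# excursion (elevated mobility: larger travel radius, more visited places)
# together with reduced movement and communication, with magnitudes set by
# the configured effect sizes.  Day-of-week and onset-hour signal is planted
# by drawing the day class from calibrated class-given-day tables and the
# onset hour from class-conditional distributions.  With all effect sizes at
# zero, every class is behaviorally and temporally indistinguishable.

DEG_PER_M_LAT <- 1 / 111320
# one longitude degree spans cos(latitude) of a latitude degree; offsets are
# drawn isotropically in meters (the physical space people move in)
LON_STRETCH <- 1 / cos(40.44 * pi / 180)

polar_offset <- function(n, r_min, r_max) {
  r <- runif(n, r_min, r_max)
  a <- runif(n, 0, 2 * pi)
  cbind(dlat = r * sin(a), dlon = r * cos(a) * LON_STRETCH)
}

#' Simulate a synthetic sensing cohort
#'
#' Deterministic given `config$seed`.  Returns raw sensor streams, drinking
#' self-reports, a participants table, and a ground-truth bundle (planted
#' classes and onsets, participant anchors, injected gaps) used by
#' parameter-recovery tests.
#'
#' @param config a [cohort_config()]
#' @param apply_missingness logical; inject the configured gap pattern
#' @param with_streams logical; `FALSE` skips sensor-stream synthesis and
#'   returns only events/reports (fast path for calibration checks)
#' @return list with elements `streams` (class `sensor_streams`), `ema`,
#'   `participants`, `truth`
#' @export
simulate_cohort <- function(config = cohort_config(), apply_missingness = TRUE,
                            with_streams = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  cal <- calibration_tables(config)
  n_p <- config$n_participants
  n_days <- config$n_weeks * 7L
  d0 <- config$start_day

  ids <- sprintf("p%03d", seq_len(n_p))
  n_f <- round(config$frac_female * n_p)
  sex <- sample(c(rep("female", n_f), rep("male", n_p - n_f)))
  participants <- data.table::data.table(
    participant_id = ids, sex = sex,
    enrolled_days = n_days, tz_offset = 0L)

  # anchors
  home_off <- polar_offset(n_p, 0, 0.12)
  anchors_list <- vector("list", n_p)
  for (i in seq_len(n_p)) {
    n_v <- sample(2:5, 1)
    voff <- polar_offset(n_v, 0.01, 0.06)
    woff <- polar_offset(1, 0.015, 0.05)
    anchors_list[[i]] <- data.table::data.table(
      participant_id = ids[i],
      anchor = c("home", "work", paste0("venue", seq_len(n_v))),
      lat = config$center_lat + home_off[i, 1] + c(0, woff[, 1], voff[, 1]),
      lon = config$center_lon + home_off[i, 2] + c(0, woff[, 2], voff[, 2]))
  }
  anchors <- data.table::rbindlist(anchors_list)

  # events: two fixed report days per participant (weighted sample without
  # replacement), class drawn per day from the calibrated table
  ev_list <- vector("list", n_p)
  thr <- c(female = 4L, male = 5L)
  for (i in seq_len(n_p)) {
    # two report days per week, drawn from the drinking-day propensity
    # weights (weighted sampling without replacement, redrawn weekly so the
    # pair varies with the participant's week-to-week plans)
    weeks <- rep(seq_len(config$n_weeks) - 1L, each = 2L)
    dows <- as.vector(vapply(seq_len(config$n_weeks),
                             function(w) sort(sample(0:6, 2, prob = cal$q)),
                             integer(2)))
    dates <- d0 + weeks * 7L + dows
    lab <- vapply(dows + 1L, function(k) {
      sample(LABELS, 1, prob = cal$p_class_given_day[k, ])
    }, character(1))
    n_ev <- length(dates)
    onset <- rep(NA_real_, n_ev)
    endt <- rep(NA_real_, n_ev)
    drinks <- integer(n_ev)
    for (j in which(lab != "N")) {
      hb <- sample(0:23, 1, prob = cal$onset_probs[, lab[j]])
      onset[j] <- dates[j] * SECONDS_PER_DAY + hb * 3600 + runif(1, 0, 3600)
      endt[j] <- onset[j] + min(6 * 3600, rlnorm(1, log(2.5 * 3600), 0.4))
      th <- thr[[sex[i]]]
      drinks[j] <- if (lab[j] == "D") sample.int(th - 1L, 1) else th + rpois(1, 2)
    }
    ev_list[[i]] <- data.table::data.table(
      participant_id = ids[i], date = dates, dow = dows, class = lab,
      onset_t = onset, end_t = endt, n_drinks = drinks)
  }
  events <- data.table::rbindlist(ev_list)

  ema <- events[, .(participant_id, date, drank = class != "N",
                    n_drinks, onset_t, end_t)]

  if (!with_streams) {
    return(list(streams = NULL, ema = ema, participants = participants,
                truth = list(events = events, anchors = anchors,
                             gaps = data.table::data.table(),
                             config = config, calibration = cal)))
  }
  streams_list <- vector("list", n_p)
  for (i in seq_len(n_p)) {
    streams_list[[i]] <- sim_participant_streams(
      ids[i], anchors_list[[i]], ev_list[[i]], config, d0, n_days)
  }
  streams <- structure(
    lapply(setNames(STREAM_TYPES, STREAM_TYPES), function(type) {
      data.table::rbindlist(lapply(streams_list, `[[`, type))
    }),
    class = "sensor_streams")

  gaps <- data.table::data.table()
  if (apply_missingness) {
    mi <- inject_missingness(streams, config)
    streams <- mi$streams
    gaps <- mi$gaps
  }
  list(streams = streams, ema = ema, participants = participants,
       truth = list(events = events, anchors = anchors, gaps = gaps,
                    config = config, calibration = cal))
}

# intensity of the pre-onset behavioral shift for a drinking day
outing_intensity <- function(class, e) ifelse(class == "BDE", 1, 0.6) * e

# replace post-jump fixes with points along the straight route, traversed
# at `speed` m/s with multiplicative noise
smooth_transitions <- function(t, lat, lon, speed = 8) {
  n <- length(t)
  if (n < 2) return(list(lat = lat, lon = lon))
  orig_lat <- lat; orig_lon <- lon
  step <- haversine_m(orig_lat[-n], orig_lon[-n], orig_lat[-1], orig_lon[-1])
  for (i in which(step > 400)) {
    travel_t <- step[i] / (speed * runif(1, 0.7, 1.3))
    k <- i + 1
    while (k <= n && (t[k] - t[i]) < travel_t) {
      f <- (t[k] - t[i]) / travel_t
      lat[k] <- orig_lat[i] + f * (orig_lat[i + 1] - orig_lat[i])
      lon[k] <- orig_lon[i] + f * (orig_lon[i + 1] - orig_lon[i])
      k <- k + 1
    }
  }
  list(lat = lat, lon = lon)
}

sim_participant_streams <- function(pid, anchors, events, config, d0, n_days) {
  t0 <- d0 * SECONDS_PER_DAY
  t1 <- t0 + n_days * SECONDS_PER_DAY
  home <- as.numeric(anchors[anchor == "home", .(lat, lon)])
  work <- as.numeric(anchors[anchor == "work", .(lat, lon)])
  venues <- as.matrix(anchors[grepl("^venue", anchor), .(lat, lon)])
  n_v <- nrow(venues)

  days <- d0 + 0:(n_days - 1L)
  dows <- (days + 3L) %% 7L

  # --- overlay intervals (venue visits) -----------------------------------
  ov <- list()
  # weekend errands
  wk <- days[dows >= 5L]
  go <- wk[runif(length(wk)) < 0.5]
  if (length(go)) {
    v <- sample.int(n_v, length(go), replace = TRUE)
    s <- go * SECONDS_PER_DAY + 13 * 3600 + runif(length(go), 0, 3600)
    ov[[1]] <- data.table::data.table(s = s, e = s + runif(length(go), 3600, 7200),
                                      lat = venues[v, 1], lon = venues[v, 2])
  }
  # class-independent evening outings (background social noise)
  go <- days[runif(length(days)) < 0.35]
  if (length(go)) {
    v <- sample.int(n_v, length(go), replace = TRUE)
    s <- go * SECONDS_PER_DAY + 18 * 3600 + runif(length(go), 0, 7200)
    ov[[2]] <- data.table::data.table(s = s, e = s + runif(length(go), 7200, 18000),
                                      lat = venues[v, 1], lon = venues[v, 2])
  }
  # pre-onset "going-out" period on drinking days.  Low-risk days park at a
  # single venue; binge days hop between several venues scattered in
  # different directions at comparable distances, so the distinguishing
  # geometry is the spread of visited positions (radius of gyration), not
  # the maximum distance from home.
  drink <- events[class != "N"]
  mod <- data.table::data.table(s = numeric(0), e = numeric(0), f = numeric(0))
  if (nrow(drink)) {
    exc <- vector("list", nrow(drink))
    pre_max <- config$pre_onset_hours * 3600
    pre_len <- numeric(nrow(drink))
    for (j in seq_len(nrow(drink))) {
      e_rg <- config$effect_sizes$rg
      if (e_rg <= 0) next
      # outing length matches the background evening-outing occupancy, so
      # mere time-out-of-home separates drinking days only weakly
      pre <- min(pre_max, runif(1, 4.5, 7) * 3600)
      pre_len[j] <- pre
      # identical temporal structure for D and BDE (same hop counts and
      # dwell pattern); the classes differ in a continuous latent spatial
      # spread, of which the RMS radius of the visited positions is the
      # natural summary
      is_bde <- drink$class[j] == "BDE"
      n_hop <- sample(3:6, 1)
      # both classes visit the same number of distinct stops at the same
      # typical distance from home; binge-day stops scatter in different
      # directions (large positional spread) while low-risk stops stay in
      # one tight neighborhood cluster.  Place counts, dwell patterns,
      # distance-from-home and net displacement are therefore matched
      # between D and BDE, and the spread of visited positions carries the
      # class.  A minority of days cross over, keeping the dose noisy.
      r0 <- runif(1, 0.015, 0.055) * e_rg
      a0 <- runif(1, 0, 2 * pi)
      scattered <- if (is_bde) runif(1) < 0.8 else runif(1) < 0.15
      if (scattered) {
        # city-wide crawl: stops on a ring around home, so the positional
        # spread (not the distance of any one stop) carries the dose
        r <- r0 * runif(n_hop, 0.9, 1.1)
        a <- runif(n_hop, 0, 2 * pi)
        elat <- home[1] + r * sin(a)
        elon <- home[2] + r * cos(a) * LON_STRETCH
      } else {
        # clustered night out: distinct stops in one neighborhood at the
        # same typical distance from home
        noff <- polar_offset(n_hop, 0.004, 0.012)
        elat <- home[1] + r0 * sin(a0) + noff[, 1]
        elon <- home[2] + r0 * cos(a0) + noff[, 2]
      }
      cuts <- sort(runif(n_hop - 1, 0.2, 0.8))
      bounds <- drink$onset_t[j] - pre * (1 - c(0, cuts, 1))
      exc[[j]] <- data.table::data.table(
        s = bounds[-(n_hop + 1)], e = bounds[-1],
        lat = elat, lon = elon)
    }
    ov[[3]] <- data.table::rbindlist(exc)
    mod <- drink[, .(s = onset_t - pmax(pre_len, 3600), e = onset_t,
                     f_acc = 1 - 0.5 * outing_intensity(class, config$effect_sizes$accel),
                     f_comm = 1 - 0.6 * outing_intensity(class, config$effect_sizes$comm))]
  }
  overlays <- data.table::rbindlist(ov)

  position_at <- function(times) {
    sd_ <- times %% SECONDS_PER_DAY
    dw <- (floor(times / SECONDS_PER_DAY) + 3) %% 7
    lat <- rep(home[1], length(times))
    lon <- rep(home[2], length(times))
    kind <- rep("home", length(times))
    at_work <- dw < 5 & sd_ >= 8.75 * 3600 & sd_ < 17.25 * 3600
    lat[at_work] <- work[1]; lon[at_work] <- work[2]; kind[at_work] <- "work"
    if (nrow(overlays)) {
      for (r in seq_len(nrow(overlays))) {
        idx <- which(times >= overlays$s[r] & times < overlays$e[r])
        if (length(idx)) {
          lat[idx] <- overlays$lat[r]; lon[idx] <- overlays$lon[r]
          kind[idx] <- "venue"
        }
      }
    }
    list(lat = lat, lon = lon, kind = kind)
  }

  # --- GPS -----------------------------------------------------------------
  gt <- seq(t0, t1 - 1, by = config$gps_cadence_s) + runif(1, 0, 60)
  pos <- position_at(gt)
  # traverse transitions at a finite (driving-scale) speed instead of
  # teleporting, so instantaneous speeds are realistic for everyone
  sm <- smooth_transitions(gt, pos$lat, pos$lon)
  pos$lat <- sm$lat; pos$lon <- sm$lon
  jit <- 30 * DEG_PER_M_LAT
  glat <- pos$lat + rnorm(length(gt), 0, jit)
  glon <- pos$lon + rnorm(length(gt), 0, jit / cos(pos$lat[1] * pi / 180))
  # urban positioning errors: a small share of fixes lands 1-3 km off
  # (multipath / cell-tower fallback), so extreme-value summaries of a
  # window are noisy while mean-square summaries are barely moved
  nglitch <- rbinom(1, length(gt), 0.02)
  if (nglitch) {
    gi <- sample.int(length(gt), nglitch)
    goff <- polar_offset(nglitch, 0.008, 0.03)
    glat[gi] <- glat[gi] + goff[, 1]
    glon[gi] <- glon[gi] + goff[, 2]
  }
  gps <- data.table::data.table(
    participant_id = pid, t = gt, lat = glat, lon = glon,
    accuracy = round(runif(length(gt), 5, 30), 1))

  mod_factor <- function(times, col) {
    f <- rep(1, length(times))
    if (nrow(mod)) {
      for (r in seq_len(nrow(mod))) {
        idx <- which(times >= mod$s[r] & times < mod$e[r])
        f[idx] <- mod[[col]][r]
      }
    }
    f
  }

  # --- accelerometer -------------------------------------------------------
  at <- seq(t0, t1 - 1, by = config$accel_cadence_s)
  hr <- hour_of_day(at)
  act_mu <- ifelse(hr >= 8 & hr < 22, 0.8, ifelse(hr < 7, 0.15, 0.4))
  act <- abs(rnorm(length(at), act_mu, 0.3)) * mod_factor(at, "f_acc")
  mag <- 9.81 + act
  az <- runif(length(at), 0, 2 * pi)
  el <- runif(length(at), -pi / 2, pi / 2)
  accel <- data.table::data.table(
    participant_id = pid, t = at,
    x = mag * cos(el) * cos(az), y = mag * cos(el) * sin(az),
    z = mag * sin(el))

  # --- communication -------------------------------------------------------
  ht <- seq(t0, t1 - 1, by = 3600)
  hh <- hour_of_day(ht)
  rate <- ifelse(hh >= 9 & hh < 23, 0.5, 0.08) * mod_factor(ht + 1800, "f_comm")
  n_ev <- rpois(length(ht), rate)
  if (sum(n_ev)) {
    et <- rep(ht, n_ev) + runif(sum(n_ev), 0, 3600)
    kind <- sample(COMM_KINDS, sum(n_ev), replace = TRUE, prob = c(.25, .25, .5))
    dur <- ifelse(kind == "sms", 0, round(rlnorm(sum(n_ev), log(90), 1)))
    contact <- paste0(pid, "_c", sample.int(20, sum(n_ev), replace = TRUE,
                                            prob = 1 / seq_len(20)))
    comm <- data.table::data.table(participant_id = pid, t = et, kind = kind,
                                   duration = dur, contact_id = contact)
  } else {
    comm <- data.table::data.table(participant_id = character(0), t = numeric(0),
                                   kind = character(0), duration = numeric(0),
                                   contact_id = character(0))
  }

  # --- device use ----------------------------------------------------------
  scr_rate <- ifelse(hh >= 8 & hh < 23, 1.2, 0.15)
  n_s <- rpois(length(ht), scr_rate)
  dev <- list()
  if (sum(n_s)) {
    on_t <- rep(ht, n_s) + runif(sum(n_s), 0, 3300)
    dur <- pmin(2400, rlnorm(sum(n_s), log(120), 0.9))
    n_apps <- 1L + rpois(sum(n_s), 0.7)
    app_pool <- paste0("app", 1:15)
    dev[[1]] <- data.table::data.table(participant_id = pid, t = on_t,
                                       kind = "screen_on", app_id = NA_character_,
                                       battery_pct = NA_real_, charging = NA)
    dev[[2]] <- data.table::data.table(participant_id = pid, t = on_t + dur,
                                       kind = "screen_off", app_id = NA_character_,
                                       battery_pct = NA_real_, charging = NA)
    app_t <- unlist(lapply(seq_along(on_t), function(k) {
      on_t[k] + sort(runif(n_apps[k], 0, dur[k]))
    }))
    dev[[3]] <- data.table::data.table(
      participant_id = pid, t = app_t, kind = "app_foreground",
      app_id = sample(app_pool, length(app_t), replace = TRUE,
                      prob = 1 / seq_len(15)),
      battery_pct = NA_real_, charging = NA)
  }
  # battery: one overnight charge per day with jittered start/length and a
  # per-day drain slope, so battery level is only a noisy clock
  bt <- seq(t0, t1 - 1, by = 1800)
  cs <- days * SECONDS_PER_DAY + runif(n_days, 21, 27) * 3600
  ce <- cs + runif(n_days, 5, 8) * 3600
  drain <- runif(n_days, 3.5, 8)
  k <- findInterval(bt, cs)
  kk <- pmax(k, 1L)
  charging <- k > 0 & bt < ce[kk]
  ramp <- pmin(1, (bt - cs[kk]) / (0.7 * (ce[kk] - cs[kk])))
  pct <- ifelse(charging, 35 + 65 * ramp,
                pmax(5, 100 - drain[kk] * (bt - ce[kk]) / 3600))
  pct[k == 0] <- pmax(5, 100 - drain[1] * (bt[k == 0] - t0) / 3600)
  pct <- pmin(100, pmax(0, pct + rnorm(length(bt), 0, 2)))
  dev[[4]] <- data.table::data.table(participant_id = pid, t = bt,
                                     kind = "battery", app_id = NA_character_,
                                     battery_pct = round(pct, 1),
                                     charging = charging)
  device <- data.table::rbindlist(dev)

  # --- wifi ----------------------------------------------------------------
  wt <- seq(t0, t1 - 1, by = config$wifi_cadence_s)
  wpos <- position_at(wt)
  lam <- c(home = 2.5, work = 8, venue = 5)[wpos$kind]
  wifi <- data.table::data.table(participant_id = pid, t = wt,
                                 n_unique_hotspots = rpois(length(wt), lam))

  for (s in list(gps, accel, comm, device, wifi)) data.table::setorder(s, t)
  list(gps = gps, accel = accel, comm = comm, device = device, wifi = wifi)
}

#' Inject missingness gaps into sensor streams
#'
#' Removes records inside randomly placed per-participant-day gaps (short,
#' interpolatable minutes-scale gaps and long hours-scale outages), logging
#' every removed span.  Uses the current RNG state, so it is deterministic
#' within a seeded [simulate_cohort()] run; pass `seed` to use standalone.
#'
#' @param streams a `sensor_streams` object
#' @param config a `cohort_config` (uses `config$missingness`)
#' @param seed optional integer seed for standalone use
#' @return list(streams, gaps): modified streams plus a gap log
#' @export
inject_missingness <- function(streams, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  miss <- config$missingness
  gap_log <- list()
  for (type in names(streams)) {
    dt <- streams[[type]]
    if (is.null(dt) || !nrow(dt) || is.null(miss[[type]])) next
    m <- miss[[type]]
    span <- dt[, .(t_min = min(t), t_max = max(t)), by = participant_id]
    gaps <- span[, {
      nd <- max(1, ceiling((t_max - t_min) / SECONDS_PER_DAY))
      n_short <- rpois(1, m$short_rate * nd)
      n_long <- rpois(1, m$long_rate * nd)
      len <- c(runif(n_short, m$short_range[1], m$short_range[2]),
               runif(n_long, m$long_range[1], m$long_range[2]))
      s <- runif(length(len), t_min, t_max)
      .(gap_start = s, gap_end = s + len)
    }, by = participant_id]
    if (nrow(gaps)) {
      gaps[, stream := type]
      pts <- dt[, .(participant_id, start = t, end = t, idx = .I)]
      g <- data.table::copy(gaps)
      data.table::setkey(g, participant_id, gap_start, gap_end)
      hit <- data.table::foverlaps(pts, g,
                                   by.x = c("participant_id", "start", "end"),
                                   type = "within", nomatch = NULL)
      if (nrow(hit)) streams[[type]] <- dt[-unique(hit$idx)]
      gap_log[[type]] <- gaps
    }
  }
  list(streams = streams,
       gaps = data.table::rbindlist(gap_log))
}
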