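# Event building: labels, pseudo-onsets, epoching, window slicing,
# gap interpolation, and inclusion/exclusion filtering.

#' Labeling rules for drinking classes
#'
#' Sex-specific binge thresholds: a single-occasion count at or above the
#' threshold is a binge-drinking event (BDE), counts between 1 and the
#' threshold are low-risk drinking (D), zero is non-drinking (N).
#'
#' @param female_bde_threshold,male_bde_threshold drinks per occasion
#' @return list of class `labeling_rules`
#' @export
labeling_rules <- function(female_bde_threshold = 4, male_bde_threshold = 5) {
  stopifnot(female_bde_threshold >= 1, male_bde_threshold >= 1)
  structure(list(female = female_bde_threshold, male = male_bde_threshold),
            class = "labeling_rules")
}

#' Label a drinking occasion
#'
#' @param n_drinks non-negative drink count(s)
#' @param sex "female" or "male" (recycled)
#' @param rules a [labeling_rules()]
#' @return factor with levels N, D, BDE
#' @export
label_event <- function(n_drinks, sex, rules = labeling_rules()) {
  if (any(n_drinks < 0)) stop("n_drinks must be non-negative", call. = FALSE)
  if (!all(sex %in% c("female", "male"))) stop("unknown sex value", call. = FALSE)
  thr <- ifelse(sex == "female", rules$female, rules$male)
  lab <- ifelse(n_drinks == 0, "N", ifelse(n_drinks >= thr, "BDE", "D"))
  factor(lab, levels = LABELS)
}

#' Sample a pseudo-onset for a non-drinking day
#'
#' Uniform over the 15-minute grid between 18:00 and midnight; these anchor
#' the analysis window on reported non-drinking days.
#'
#' @param date integer day index/indices (days since 1970-01-01, local)
#' @return numeric local-clock timestamps (epoch seconds)
#' @export
pseudo_onset <- function(date) {
  slot <- sample.int(24L, length(date), replace = TRUE) - 1L
  date * SECONDS_PER_DAY + 18 * 3600 + slot * EPOCH_SECONDS
}

#' Classify an event day as weekday or weekend
#'
#' The default weekend is Friday-Sunday, where binge events concentrate;
#' the partition is configurable.
#'
#' @param dow integer day-of-week, Monday = 0 .. Sunday = 6
#' @param weekend_days integer days counted as weekend
#' @return factor with levels weekday, weekend
#' @export
classify_day <- function(dow, weekend_days = c(4L, 5L, 6L)) {
  factor(ifelse(dow %in% weekend_days, "weekend", "weekday"),
         levels = c("weekday", "weekend"))
}

#' Build labeled events from self-reports
#'
#' Assigns labels from drink counts and sex-specific thresholds, snaps
#' reported onsets down to the 15-minute grid, and samples seeded
#' pseudo-onsets (18:00-24:00) for non-drinking days.
#'
#' @param ema EMA table (see [read_ema()])
#' @param participants participants table
#' @param rules a [labeling_rules()]
#' @param seed integer seed for pseudo-onset sampling
#' @param weekend_days passed to [classify_day()]
#' @return data.table of events with `event_id`, `onset` (snapped), `label`,
#'   `pseudo`, `day_class`
#' @export
build_events <- function(ema, participants, rules = labeling_rules(),
                         seed = 1L, weekend_days = c(4L, 5L, 6L)) {
  set.seed(seed)
  ev <- data.table::as.data.table(ema)
  sex <- setNames(participants$sex, participants$participant_id)
  ev[, label := label_event(n_drinks, sex[participant_id], rules)]
  ev[, pseudo := !drank]
  ev[, onset := ifelse(drank, snap_epoch(onset_t), NA_real_)]
  if (any(ev$pseudo)) ev[pseudo == TRUE, onset := pseudo_onset(date)]
  ev[, dow := day_of_week(date * SECONDS_PER_DAY)]
  ev[, day_class := classify_day(dow, weekend_days)]
  ev[, event_id := seq_len(.N)]
  ev[]
}

#' 15-minute epoch grid covering the 24 hours before an onset
#'
#' @param onset local-clock timestamp (snapped down to the grid)
#' @return data.table with `epoch_idx` (0..95), `start`, `end`
#' @export
epochize <- function(onset) {
  o <- snap_epoch(onset)
  start <- o - SECONDS_PER_DAY + EPOCH_SECONDS * (0:95)
  data.table::data.table(epoch_idx = 0:95, start = start,
                         end = start + EPOCH_SECONDS)
}

#' Epoch-slot indices for an analysis window
#'
#' The analysis window of `w` hours ends `d` hours before onset: it covers
#' `[onset - (w+d), onset - d)` and maps to `4*w` epoch slots of the 96-slot
#' day grid.  No slot reaches past `onset - d` (temporal separation).
#'
#' @param w analysis window length, hours
#' @param d prediction distance, hours
#' @return integer epoch indices into the 0..95 grid
#' @export
window_slots <- function(w, d) {
  if (w <= 0 || d <= 0) stop("w and d must be positive", call. = FALSE)
  if (w + d > 24) stop("w + d must not exceed 24 hours", call. = FALSE)
  seq.int(96L - 4L * (w + d), 96L - 4L * d - 1L)
}

#' Extract the epoch slice for an analysis window
#'
#' @param onset event onset timestamp
#' @param w,d window length and prediction distance, hours
#' @return data.table of `4*w` epochs (subset of [epochize()])
#' @export
extract_window <- function(onset, w, d) {
  grid <- epochize(onset)
  grid[window_slots(w, d) + 1L]
}

#' Fill short gaps in a numeric stream by flanking-average interpolation
#'
#' Gaps longer than the nominal cadence but at most `max_gap` seconds are
#' filled at the nominal cadence with the mean of the two flanking values;
#' longer gaps are left untouched.
#'
#' @param dt stream data.table with column `t`, sorted, single participant
#'   per group handled via `by`
#' @param value_cols numeric columns to fill
#' @param cadence_s nominal sampling interval, seconds
#' @param max_gap_s largest gap to fill, seconds (default 15 minutes)
#' @return data.table with inserted rows, sorted by participant and t
#' @export
interpolate_gaps <- function(dt, value_cols, cadence_s, max_gap_s = 900) {
  dt <- data.table::as.data.table(dt)
  fill <- dt[, {
    dgap <- diff(t)
    idx <- which(dgap > cadence_s * 1.5 & dgap <= max_gap_s)
    if (length(idx)) {
      cols <- mget(value_cols)
      new_rows <- lapply(idx, function(k) {
        n_ins <- ceiling((t[k + 1] - t[k]) / cadence_s) - 1
        tt <- t[k] + cadence_s * seq_len(n_ins)
        tt <- tt[tt < t[k + 1]]
        row <- data.table::data.table(t = tt)
        for (vc in value_cols) {
          data.table::set(row, j = vc,
                          value = (cols[[vc]][k] + cols[[vc]][k + 1]) / 2)
        }
        row
      })
      data.table::rbindlist(new_rows)
    } else {
      data.table::data.table(t = numeric(0))
    }
  }, by = participant_id]
  if (nrow(fill)) {
    out <- data.table::rbindlist(list(dt, fill), fill = TRUE)
  } else {
    out <- dt
  }
  data.table::setorder(out, participant_id, t)
  out[]
}

#' Apply inclusion/exclusion rules to events
#'
#' Drops (1) events with no GPS fix anywhere in their 24-hour pre-onset
#' window, (2) events whose 24-hour feature row has more than half of the
#' key features missing, and (3) all events of participants left with fewer
#' than `min_days` qualifying days.  Every drop is logged with a reason code.
#'
#' @param events events table (from [build_events()])
#' @param day_features per-event 24-hour feature rows (wide, keyed by
#'   `event_id`), used for the key-feature missingness rule
#' @param key_features character vector of feature names counted as key
#'   (default: GPS mobility family plus accelerometer magnitude)
#' @param min_days minimum qualifying days per participant
#' @return list(events, exclusions) where exclusions has `event_id`, `reason`
#' @export
apply_inclusion_exclusion <- function(events, day_features,
                                      key_features = default_key_features(),
                                      min_days = 3L) {
  ev <- data.table::as.data.table(events)
  df <- data.table::as.data.table(day_features)
  key_features <- intersect(key_features, names(df))
  excl <- list()

  no_gps_ids <- df[is.na(radius_of_gyration) & is.na(lat_mean), event_id]
  # radius/lat both missing <=> no GPS fix in the 24-h window
  if (length(no_gps_ids)) {
    excl[[1]] <- data.table::data.table(event_id = no_gps_ids, reason = "no_gps")
  }
  rest <- df[!event_id %in% no_gps_ids]
  if (nrow(rest) && length(key_features)) {
    miss_frac <- rowMeans(is.na(as.matrix(rest[, ..key_features])))
    bad <- rest$event_id[miss_frac > 0.5]
    if (length(bad)) {
      excl[[2]] <- data.table::data.table(event_id = bad,
                                          reason = "key_features_missing")
    }
  }
  exclusions <- data.table::rbindlist(excl)
  keep <- ev[!event_id %in% exclusions$event_id]
  cnt <- keep[, .N, by = participant_id]
  few <- cnt[N < min_days, participant_id]
  if (length(few)) {
    exclusions <- data.table::rbindlist(list(
      exclusions,
      data.table::data.table(event_id = keep[participant_id %in% few, event_id],
                             reason = "too_few_days")))
    keep <- keep[!participant_id %in% few]
  }
  list(events = keep, exclusions = exclusions)
}

#' Default key-feature list for the missingness exclusion rule
#' @return character vector of feature names
#' @export
default_key_features <- function() {
  c("radius_of_gyration", "location_variance", "location_entropy",
    "travel_distance", "lat_mean", "lon_mean", "time_at_home",
    "n_places_visited", "acc_mag_mean")
}
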