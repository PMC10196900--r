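# Cohort configuration and day/hour calibration.
#
# Defaults emulate the motivating 14-week young-adult risky-drinking cohort:
# 75 participants reporting twice weekly, an event mix of roughly
# 65% non-drinking (N) / 19% low-risk drinking (D) / 16% binge (BDE) days,
# BDEs concentrated Friday-Sunday, and onset times peaking at 5 PM.

# Empirical calibration frequencies (n = 122 binge events):
# day-of-week counts, Monday..Sunday
BDE_DOW_COUNTS <- c(2, 0, 5, 7, 36, 52, 20)
# onset-hour counts, bins [00:00,01:00) .. [23:00,24:00)
BDE_ONSET_COUNTS <- c(3, 0, 0, 0, 1, 0, 1, 4, 1, 3, 6, 3,
                      5, 2, 6, 9, 7, 15, 11, 12, 11, 8, 10, 4)
# analyzed event counts by class
EVENT_CLASS_COUNTS <- c(N = 489, D = 143, BDE = 122)

LABELS <- c("N", "D", "BDE")

#' Construct a synthetic-cohort configuration
#'
#' All defaults are the study conditions the pipeline is designed around;
#' see the methods vignette for the rationale behind each value.
#' `effect_sizes` couple the latent "going-out" state on drinking days to
#' observable behavior: `dow` and `hour` interpolate the class-conditional
#' day-of-week and onset-hour distributions between the uninformative
#' report-day marginal and the calibrated empirical distributions
#' (0 = no signal, 1 = fully calibrated); `rg` scales the pre-onset
#' mobility excursion (venue hopping, larger travel radius); `accel` and
#' `comm` scale the pre-onset reduction in movement and communication.
#'
#' @param n_participants number of participants
#' @param n_weeks study length in weeks (2 report days per week)
#' @param seed integer RNG seed; fixed seed gives bit-identical output
#' @param frac_female proportion of female participants
#' @param base_rates named probabilities of day classes N, D, BDE (sum 1)
#' @param bde_dow_probs length-7 day-of-week distribution (Mon..Sun) targeted
#'   for BDE days at `effect_sizes$dow = 1`
#' @param onset_time_distribution length-24 hourly distribution targeted for
#'   BDE onsets at `effect_sizes$hour = 1`
#' @param effect_sizes list with elements `hour`, `dow`, `rg`, `accel`,
#'   `comm`, each in `[0, 1]`
#' @param missingness per-stream gap injection settings; see
#'   [inject_missingness()]
#' @param gps_cadence_s,accel_cadence_s,wifi_cadence_s sampling intervals
#'   (the collection framework's rates are configurable, not fixed)
#' @param pre_onset_hours length of the pre-onset behavioral window on
#'   drinking days
#' @param center_lat,center_lon center of the simulated metro area
#' @return an object of class `cohort_config`
#' @export
cohort_config <- function(n_participants = 75,
                          n_weeks = 14,
                          seed = 7,
                          frac_female = 53 / 75,
                          base_rates = EVENT_CLASS_COUNTS / sum(EVENT_CLASS_COUNTS),
                          bde_dow_probs = BDE_DOW_COUNTS / sum(BDE_DOW_COUNTS),
                          onset_time_distribution = BDE_ONSET_COUNTS / sum(BDE_ONSET_COUNTS),
                          effect_sizes = list(hour = 1, dow = 1, rg = 1,
                                              accel = 0.5, comm = 0.5),
                          missingness = default_missingness(),
                          gps_cadence_s = 300,
                          accel_cadence_s = 300,
                          wifi_cadence_s = 900,
                          pre_onset_hours = 12,
                          center_lat = 40.44,
                          center_lon = -79.99) {
  if (n_participants <= 0 || n_weeks <= 0) {
    stop("n_participants and n_weeks must be positive", call. = FALSE)
  }
  base_rates <- base_rates / sum(base_rates)
  stopifnot(length(base_rates) == 3, all(base_rates >= 0),
            length(bde_dow_probs) == 7,
            length(onset_time_distribution) == 24)
  es <- utils::modifyList(list(hour = 1, dow = 1, rg = 1, accel = 0.5, comm = 0.5),
                          effect_sizes)
  stopifnot(all(unlist(es) >= 0), all(unlist(es) <= 1))
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_weeks = as.integer(n_weeks),
    seed = as.integer(seed),
    frac_female = frac_female,
    base_rates = setNames(as.numeric(base_rates), LABELS),
    bde_dow_probs = bde_dow_probs / sum(bde_dow_probs),
    onset_time_distribution = onset_time_distribution / sum(onset_time_distribution),
    effect_sizes = es,
    missingness = missingness,
    gps_cadence_s = gps_cadence_s,
    accel_cadence_s = accel_cadence_s,
    wifi_cadence_s = wifi_cadence_s,
    pre_onset_hours = pre_onset_hours,
    center_lat = center_lat,
    center_lon = center_lon,
    # first simulated day: a Monday (day index mod 7 == 4)
    start_day = 18995L
  )
  class(cfg) <- "cohort_config"
  cfg
}

#' Configuration calibrated to the empirical day and onset-hour tables
#'
#' Returns a [cohort_config()] whose BDE day-of-week probability vector is
#' the normalized empirical frequency column (e.g. P(Saturday) = 52/122) and
#' whose onset-hour vector is the normalized hourly frequency column
#' (e.g. P(onset in 17:00-18:00) = 15/122).
#'
#' @param ... passed to [cohort_config()]
#' @return a `cohort_config`
#' @export
table_calibrated_config <- function(...) {
  cohort_config(bde_dow_probs = BDE_DOW_COUNTS / sum(BDE_DOW_COUNTS),
                onset_time_distribution = BDE_ONSET_COUNTS / sum(BDE_ONSET_COUNTS),
                ...)
}

#' Configuration for the signal-recovery experiment
#'
#' The calibrated cohort with planted effects on hour of day, day of week
#' and radius of gyration only (no accelerometer or communication shift),
#' used to test that the pipeline recovers exactly the planted channels.
#'
#' @param seed cohort seed (default 7)
#' @param ... passed to [cohort_config()]
#' @return a `cohort_config`
#' @export
signal_recovery_config <- function(seed = 7, ...) {
  cohort_config(seed = seed,
                effect_sizes = list(hour = 1, dow = 1, rg = 1,
                                    accel = 0, comm = 0), ...)
}

#' Effect-free (null) configuration
#'
#' All effect sizes zero: day class, onset hour and behavior are mutually
#' independent, so no model should beat the day-of-week baseline beyond
#' chance.  Used by the null-calibration suite.
#'
#' @param seed cohort seed
#' @param n_participants,n_weeks cohort size (smaller default than the main
#'   study so that repeated null runs are cheap)
#' @param ... passed to [cohort_config()]
#' @return a `cohort_config`
#' @export
null_config <- function(seed, n_participants = 24, n_weeks = 6, ...) {
  cohort_config(seed = seed, n_participants = n_participants,
                n_weeks = n_weeks,
                effect_sizes = list(hour = 0, dow = 0, rg = 0,
                                    accel = 0, comm = 0), ...)
}

#' Default per-stream missingness settings
#'
#' Each stream gets short gaps (minutes, interpolatable) and long gaps
#' (hours, e.g. battery death) at the given expected number per
#' participant-day; lengths are drawn uniformly from the ranges (seconds).
#'
#' @param short_rate,long_rate expected gaps per participant-day
#' @param short_range,long_range gap-length ranges in seconds
#' @return nested list keyed by stream type
#' @export
default_missingness <- function(short_rate = 0.5, long_rate = 0.05,
                                short_range = c(300, 900),
                                long_range = c(3600, 21600)) {
  one <- list(short_rate = short_rate, long_rate = long_rate,
              short_range = short_range, long_range = long_range)
  setNames(rep(list(one), length(STREAM_TYPES)), STREAM_TYPES)
}

# --- calibration arithmetic ------------------------------------------------

# Report-day sampling weights: a blend of the BDE day-of-week shape and a
# uniform week, so that heavy drinking days are over-represented among the
# two report days each participant keeps all study long.
report_day_weights <- function(config) {
  q <- 0.5 * config$bde_dow_probs + 0.5 / 7
  q / sum(q)
}

# Closed-form event-day marginal when each participant's two report days are
# a weighted sample without replacement (successive draws) with weights q.
# P(day d in pair) = q_d * (1 + sum_{j != d} q_j / (1 - q_j)); each report
# day hosts one event, so the per-event marginal is half of that.
pair_event_marginal <- function(q) {
  s <- q / (1 - q)
  p_in_pair <- q * (1 + (sum(s) - s))
  p_in_pair / 2
}

#' Class-given-day and onset calibration tables for a configuration
#'
#' Derives, in closed form, the per-day class probabilities such that the
#' marginal class mix equals `base_rates` and the day-of-week distribution
#' of simulated BDEs equals the configured target (Bayes inversion against
#' the report-day marginal).  Also returns the class-conditional onset-hour
#' distributions after effect-size interpolation.
#'
#' @param config a `cohort_config`
#' @return list with `q` (report-day weights), `day_marginal`,
#'   `drink_day_probs` (target day shape for D/BDE), `p_class_given_day`
#'   (7 x 3 matrix), `onset_probs` (24 x 3 matrix, per class)
#' @export
calibration_tables <- function(config) {
  q <- report_day_weights(config)
  M <- pair_event_marginal(q)
  e_dow <- config$effect_sizes$dow
  t_drink <- (1 - e_dow) * M + e_dow * config$bde_dow_probs
  t_drink <- t_drink / sum(t_drink)
  b <- config$base_rates
  resid <- M - (b[["D"]] + b[["BDE"]]) * t_drink
  if (any(resid < 0)) {
    stop("day calibration infeasible: residual N-class day mass negative; ",
         "reduce effect_sizes$dow or base drinking rates", call. = FALSE)
  }
  t_n <- resid / b[["N"]]
  p_class_given_day <- cbind(
    N = b[["N"]] * t_n / M,
    D = b[["D"]] * t_drink / M,
    BDE = b[["BDE"]] * t_drink / M
  )
  rownames(p_class_given_day) <- DAY_NAMES
  stopifnot(max(abs(rowSums(p_class_given_day) - 1)) < 1e-9)

  # onset hours: the null distribution is uniform over the evening (18-24),
  # matching the pseudo-onset convention for non-drinking days.  Low-risk
  # onsets stay evening-uniform at every effect size, so the onset-hour
  # channel is specific to the binge class (whose empirical distribution
  # has substantial mass outside the evening).
  u_even <- c(rep(0, 18), rep(1 / 6, 6))
  e_h <- config$effect_sizes$hour
  onset_bde <- (1 - e_h) * u_even + e_h * config$onset_time_distribution
  onset_probs <- cbind(N = u_even, D = u_even, BDE = onset_bde)

  list(q = q, day_marginal = M, drink_day_probs = t_drink,
       p_class_given_day = p_class_given_day, onset_probs = onset_probs)
}
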