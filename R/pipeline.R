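# End-to-end orchestration: simulate -> label -> prepare -> filter -> grid
# -> explain, plus the privacy-accuracy experiment and small cohort
# arithmetic helpers.

#' Class mix and exclusion arithmetic for a reported cohort
#'
#' Percentages of each event class among analyzed events and the mean
#' number of excluded events per participant.
#'
#' @param class_counts named counts for N, D, BDE among analyzed events
#' @param n_reported total reported events before exclusion
#' @param n_participants cohort size
#' @return list: `pct` (named percentages), `mean_excluded_per_participant`
#' @export
cohort_arithmetic <- function(class_counts = EVENT_CLASS_COUNTS,
                              n_reported = 1168, n_participants = 75) {
  tot <- sum(class_counts)
  list(pct = 100 * class_counts / tot,
       n_analyzed = tot,
       mean_excluded_per_participant = (n_reported - tot) / n_participants)
}

#' Run the full prediction pipeline on a cohort
#'
#' Simulates (or accepts) a cohort, builds labeled events with seeded
#' pseudo-onsets, tags streams, applies inclusion/exclusion, runs the model
#' grid, and (optionally) explains the best models.
#'
#' @param config a [cohort_config()] (ignored when `cohort` is supplied)
#' @param cohort optional pre-simulated cohort (list as returned by
#'   [simulate_cohort()])
#' @param seed pipeline seed (splits, pseudo-onsets, search)
#' @param day_classes,w_list,d_list,algorithms,search_trials,split_mode
#'   passed to [run_grid()]
#' @param explain also compute Shapley attributions for best cells
#' @return list: `cohort`, `events`, `exclusions`, `prep`, `grid`,
#'   `explanations`
#' @export
run_pipeline <- function(config = cohort_config(), cohort = NULL, seed = 1L,
                         day_classes = c("weekday", "weekend"),
                         w_list = c(1, 3, 6, 9, 12), d_list = c(1, 3, 6),
                         algorithms = "xgboost", search_trials = 0,
                         split_mode = "row", explain = FALSE) {
  if (is.null(cohort)) cohort <- simulate_cohort(config)
  events <- build_events(cohort$ema, cohort$participants, seed = seed)
  prep <- prepare_cohort(cohort$streams, events)
  day_rows <- day_feature_rows(prep)
  flt <- apply_inclusion_exclusion(events, day_rows)
  prep$events <- flt$events
  grid <- run_grid(prep, w_list = w_list, d_list = d_list,
                   day_classes = day_classes, algorithms = algorithms,
                   seed = seed, search_trials = search_trials,
                   split_mode = split_mode)
  explanations <- NULL
  if (explain) {
    explanations <- lapply(grid$artifacts, function(a) {
      x <- feature_matrix(a$instances)
      xs <- minmax_apply(a$scaler, median_impute_apply(a$med, x))
      shap <- compute_shap(a$model, xs)
      list(shap = shap,
           importance = global_importance(shap, class = "BDE", k = 20))
    })
  }
  list(cohort = cohort, events = flt$events, exclusions = flt$exclusions,
       prep = prep, grid = grid, explanations = explanations)
}

#' Privacy-accuracy experiment: retrain on coarsened coordinates
#'
#' Rounds every raw GPS fix to `precision` decimal places (1 decimal is
#' roughly 11.1 km), rebuilds the best cell's features and model with the
#' identical split and seed, and compares held-out accuracy against the
#' full-precision model.
#'
#' @param pipeline a [run_pipeline()] result
#' @param day_class which best cell to rerun (default "weekend")
#' @param precision decimal places kept in the rounded run
#' @param seed seed (use the pipeline's for a paired comparison)
#' @return list: `full_accuracy`, `rounded_accuracy`, `delta`, rows of both
#'   cell evaluations
#' @export
privacy_experiment <- function(pipeline, day_class = "weekend", precision = 1,
                               seed = 1L) {
  dc <- day_class
  best <- pipeline$grid$best[day_class == dc][1]
  b <- pipeline$grid$artifacts[[dc]]
  w <- best$w; d <- best$d
  streams <- pipeline$cohort$streams
  streams$gps <- data.table::copy(streams$gps)[
    , `:=`(lat = round(lat, precision), lon = round(lon, precision))]
  prep_r <- prepare_cohort(streams, pipeline$prep$events)
  inst_r <- build_instances(prep_r, w, d)[day_class == dc]
  inst_f <- b$instances
  row_f <- evaluate_cell(inst_f, best$algorithm, seed = seed,
                         params = b$params)
  row_r <- evaluate_cell(inst_r[event_id %in% inst_f$event_id],
                         best$algorithm, seed = seed, params = b$params)
  list(full_accuracy = row_f$accuracy, rounded_accuracy = row_r$accuracy,
       delta = row_f$accuracy - row_r$accuracy,
       full = row_f, rounded = row_r)
}
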