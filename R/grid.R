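# The analysis-window x prediction-distance model grid.

ALG_ABBREV <- c(xgboost = "XGB", random_forest = "RF", decision_tree = "DT",
                svm = "SVM", logistic = "LR")

model_id <- function(day_class, algorithm, w, d) {
  sprintf("%s%s-W%dD%d", ifelse(day_class == "weekend", "WE", "WD"),
          ALG_ABBREV[[algorithm]], w, d)
}

feature_matrix <- function(instances) {
  reg_names <- feature_registry()$name
  x <- as.matrix(instances[, reg_names, with = FALSE])
  storage.mode(x) <- "double"
  x
}

#' Evaluate one grid cell
#'
#' Splits the instances, fits imputation + min-max scaling + SMOTE on the
#' training side only, trains the algorithm, and scores the held-out test
#' side together with the day-of-week baseline on the same split.
#'
#' @param instances instance table for one day class and one (w, d)
#' @param algorithm one of the five supported algorithms
#' @param seed integer seed
#' @param test_frac,split_mode passed to [split_instances()]
#' @param smote_k SMOTE neighbors
#' @param params optional algorithm hyperparameters
#' @param keep_model return the fitted artifact and transforms
#' @return one-row data.table of metrics (plus `artifact` attribute when
#'   `keep_model`)
#' @export
evaluate_cell <- function(instances, algorithm = "xgboost", seed = 1L,
                          test_frac = 0.2, split_mode = "row", smote_k = 5,
                          params = NULL, keep_model = FALSE) {
  w <- instances$w[1]; d <- instances$d[1]
  dc <- as.character(instances$day_class[1])
  sp <- split_instances(instances, test_frac, split_mode, seed = seed)
  x <- feature_matrix(instances)
  y <- droplevels(factor(instances$label, levels = LABELS))
  prep <- prepare_xy(x[sp$train, , drop = FALSE], y[sp$train], smote_k = smote_k)
  art <- fit_algorithm(algorithm, prep$x, prep$y, seed = seed, params = params)
  xt <- minmax_apply(prep$scaler,
                     median_impute_apply(prep$med, x[sp$test, , drop = FALSE]))
  pred <- predict(art, xt, type = "class")
  met <- evaluate_predictions(pred, y[sp$test])
  base_pred <- baseline_day_of_week(instances$day_of_week[sp$train], y[sp$train],
                                    instances$day_of_week[sp$test])
  base <- evaluate_predictions(base_pred, y[sp$test])
  bde <- met$per_class[class == "BDE"]
  row <- data.table::data.table(
    model_id = model_id(dc, algorithm, w, d),
    day_class = dc, algorithm = algorithm, w = w, d = d,
    accuracy = met$accuracy, macro_f1 = met$macro_f1, kappa = met$kappa,
    bde_precision = if (nrow(bde)) bde$precision else NA_real_,
    bde_recall = if (nrow(bde)) bde$recall else NA_real_,
    bde_f1 = if (nrow(bde)) bde$f1 else NA_real_,
    baseline_accuracy = base$accuracy, baseline_macro_f1 = base$macro_f1,
    baseline_kappa = base$kappa,
    n_train = length(sp$train), n_test = length(sp$test))
  if (keep_model) {
    attr(row, "artifact") <- list(model = art, scaler = prep$scaler,
                                  med = prep$med, split = sp,
                                  metrics = met, baseline = base)
  }
  row
}

# best cell: highest BDE F1, kappa as tie-breaker
select_best <- function(rows) {
  rows[order(-bde_f1, -kappa)][1]
}

#' Run the analysis-window / prediction-distance model grid
#'
#' For each day class: sweep analysis windows `w_list` at the shortest
#' prediction distance, pick the best window (by BDE F1, kappa as
#' tie-breaker), then sweep the remaining prediction distances at that
#' window.  `sweep = "full"` instead evaluates every feasible (w, d) cell.
#' The overall best cell per day class is refit (optionally after a
#' cross-validated hyperparameter search) and kept as an artifact.
#'
#' @param prep a [prepare_cohort()] result (post-exclusion events)
#' @param w_list,d_list grid values in hours
#' @param day_classes day classes to model
#' @param algorithms algorithms to evaluate per cell
#' @param seed integer seed
#' @param search_trials hyperparameter-search budget for the best cell
#'   (0 = keep default parameters)
#' @param test_frac,split_mode,smote_k as in [evaluate_cell()]
#' @param sweep "paper" (two sweep families) or "full"
#' @return list: `grid` (one row per evaluated cell), `best` (per day
#'   class), `artifacts` (per day class: fitted best model + transforms +
#'   instances), `search` (per day class, when searched)
#' @export
run_grid <- function(prep, w_list = c(1, 3, 6, 9, 12), d_list = c(1, 3, 6),
                     day_classes = c("weekday", "weekend"),
                     algorithms = "xgboost", seed = 1L, search_trials = 0,
                     test_frac = 0.2, split_mode = "row", smote_k = 5,
                     sweep = c("paper", "full")) {
  sweep <- match.arg(sweep)
  d0 <- min(d_list)
  cells <- if (sweep == "full") {
    expand.grid(w = w_list, d = d_list)
  } else {
    expand.grid(w = w_list, d = d0)
  }
  cells <- cells[cells$w + cells$d <= 24, ]
  inst_cache <- new.env()
  get_inst <- function(w, d) {
    key <- paste(w, d)
    if (is.null(inst_cache[[key]])) inst_cache[[key]] <- build_instances(prep, w, d)
    inst_cache[[key]]
  }
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    inst <- get_inst(cells$w[i], cells$d[i])
    for (dc in day_classes) {
      idc <- inst[day_class == dc]
      if (!nrow(idc)) next
      for (alg in algorithms) {
        rows[[length(rows) + 1]] <-
          evaluate_cell(idc, alg, seed = seed + 13L * i, test_frac = test_frac,
                        split_mode = split_mode, smote_k = smote_k)
      }
    }
  }
  grid <- data.table::rbindlist(rows)
  if (sweep == "paper") {
    extra <- list()
    for (dc in day_classes) {
      gdc <- grid[day_class == dc]
      if (!nrow(gdc)) next
      w_best <- select_best(gdc)$w
      for (d in setdiff(d_list, d0)) {
        if (w_best + d > 24) next
        inst <- get_inst(w_best, d)
        idc <- inst[day_class == dc]
        for (alg in algorithms) {
          extra[[length(extra) + 1]] <-
            evaluate_cell(idc, alg, seed = seed + 997L + round(7 * d),
                          test_frac = test_frac, split_mode = split_mode,
                          smote_k = smote_k)
        }
      }
    }
    if (length(extra)) grid <- data.table::rbindlist(c(list(grid), extra))
  }

  best <- list(); artifacts <- list(); search <- list()
  for (dc in day_classes) {
    gdc <- grid[day_class == dc]
    if (!nrow(gdc)) next
    b <- select_best(gdc)
    inst <- get_inst(b$w, b$d)[day_class == dc]
    params <- NULL
    if (search_trials > 0 && b$algorithm == "xgboost") {
      sp <- split_instances(inst, test_frac, split_mode, seed = seed)
      x <- feature_matrix(inst)
      y <- droplevels(factor(inst$label, levels = LABELS))
      sr <- cross_validated_search(x[sp$train, , drop = FALSE], y[sp$train],
                                   n_trials = search_trials, seed = seed,
                                   smote_k = smote_k)
      search[[dc]] <- sr
      refit <- evaluate_cell(inst, b$algorithm, seed = seed,
                             test_frac = test_frac, split_mode = split_mode,
                             smote_k = smote_k, params = sr$best_params,
                             keep_model = TRUE)
      # keep the searched model only if it does not degrade the held-out cell
      if (refit$bde_f1 >= b$bde_f1) {
        params <- sr$best_params
        b <- refit
      }
    }
    final <- evaluate_cell(inst, b$algorithm, seed = seed,
                           test_frac = test_frac, split_mode = split_mode,
                           smote_k = smote_k, params = params,
                           keep_model = TRUE)
    best[[dc]] <- final
    artifacts[[dc]] <- c(attr(final, "artifact"),
                         list(instances = inst, params = params))
  }
  list(grid = grid, best = data.table::rbindlist(best), artifacts = artifacts,
       search = search)
}
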