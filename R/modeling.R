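# Model training and evaluation: 80/20 split, min-max scaling, SMOTE,
# 3-class metrics with chance correction, five classifier families, seeded
# hyperparameter search, and the analysis-window x prediction-distance grid.

#' Split instances into training and testing sets
#'
#' Row mode draws test rows at random within each class (so every class is
#' represented on both sides); grouped mode keeps each participant wholly in
#' one side, guarding against identity leakage.
#'
#' @param instances instance table (needs `label`; grouped mode needs
#'   `participant_id`)
#' @param test_frac test fraction (default 0.2)
#' @param mode "row" or "grouped"
#' @param seed integer seed
#' @param max_redraw grouped mode: re-draws allowed when a class is missing
#'   from one side
#' @return list(train, test) of row indices
#' @export
split_instances <- function(instances, test_frac = 0.2,
                            mode = c("row", "grouped"), seed = 1L,
                            max_redraw = 20L) {
  mode <- match.arg(mode)
  stopifnot(test_frac > 0, test_frac < 1)
  set.seed(seed)
  y <- instances$label
  n <- length(y)
  if (mode == "row") {
    test <- unlist(lapply(split(seq_len(n), y), function(idx) {
      sample(idx, round(length(idx) * test_frac))
    }), use.names = FALSE)
  } else {
    pids <- unique(instances$participant_id)
    for (try in seq_len(max_redraw)) {
      tp <- sample(pids, max(1, round(length(pids) * test_frac)))
      test <- which(instances$participant_id %in% tp)
      ok <- length(unique(y[test])) == nlevels(droplevels(y)) &&
        length(unique(y[-test])) == nlevels(droplevels(y))
      if (ok) break
      if (try == max_redraw) warning("class absent from one side after redraws")
    }
  }
  list(train = sort(setdiff(seq_len(n), test)), test = sort(test))
}

#' Fit / apply min-max feature scaling
#'
#' Fitted on training data only; training columns map to `[0, 1]`, constant
#' columns map to 0, test values outside the training range are not clipped.
#'
#' @param x numeric matrix (training features)
#' @return for `minmax_fit`, a scaler; for `minmax_apply`, the scaled matrix
#' @export
minmax_fit <- function(x) {
  lo <- apply(x, 2, function(v) suppressWarnings(min(v, na.rm = TRUE)))
  hi <- apply(x, 2, function(v) suppressWarnings(max(v, na.rm = TRUE)))
  lo[!is.finite(lo)] <- 0; hi[!is.finite(hi)] <- 0
  list(lo = lo, rng = ifelse(hi > lo, hi - lo, 1), const = hi <= lo)
}

#' @rdname minmax_fit
#' @param scaler a fitted scaler; @param newx matrix to transform
#' @export
minmax_apply <- function(scaler, newx) {
  out <- sweep(sweep(newx, 2, scaler$lo), 2, scaler$rng, "/")
  out[, scaler$const] <- 0
  out
}

median_impute_fit <- function(x) {
  med <- apply(x, 2, function(v) suppressWarnings(median(v, na.rm = TRUE)))
  med[!is.finite(med)] <- 0
  med
}

median_impute_apply <- function(med, x) {
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- med[j]
  }
  x
}

#' SMOTE oversampling to balance classes
#'
#' Every minority class is grown to the majority count; each synthetic
#' point lies on the segment between a minority point and one of its `k`
#' nearest same-class neighbors (Euclidean).  Applied to training data only.
#'
#' @param x numeric feature matrix (no NAs)
#' @param y class factor
#' @param k neighbors (reduced with a warning when a class is too small)
#' @return list(x, y) balanced
#' @export
smote_oversample <- function(x, y, k = 5) {
  y <- droplevels(as.factor(y))
  counts <- table(y)
  n_max <- max(counts)
  add_x <- list(); add_y <- list()
  for (cl in names(counts)) {
    need <- n_max - counts[[cl]]
    if (need == 0) next
    xi <- x[y == cl, , drop = FALSE]
    n_c <- nrow(xi)
    kk <- k
    if (n_c <= kk) {
      kk <- max(1, n_c - 1)
      warning(sprintf("class %s has %d members; reducing k to %d", cl, n_c, kk))
    }
    if (n_c == 1) {
      syn <- xi[rep(1, need), , drop = FALSE]
    } else {
      dmat <- as.matrix(dist(xi))
      diag(dmat) <- Inf
      nn <- matrix(t(apply(dmat, 1, function(r) order(r)[seq_len(kk)])),
                   nrow = n_c, ncol = kk)
      base <- sample.int(n_c, need, replace = TRUE)
      nb <- nn[cbind(base, sample.int(kk, need, replace = TRUE))]
      u <- runif(need)
      syn <- xi[base, , drop = FALSE] + u * (xi[nb, , drop = FALSE] - xi[base, , drop = FALSE])
    }
    add_x[[cl]] <- syn
    add_y[[cl]] <- rep(cl, need)
  }
  if (length(add_x)) {
    x <- rbind(x, do.call(rbind, add_x))
    y <- factor(c(as.character(y), unlist(add_y)), levels = levels(y))
  }
  list(x = x, y = y)
}

#' Classification metrics with chance correction
#'
#' Accuracy, per-class precision/recall/F1, macro-averaged F1, Cohen's
#' kappa `(p_o - p_e)/(1 - p_e)` with expected agreement from marginal
#' products, and the confusion matrix.  Undefined ratios (empty class) are
#' reported as 0; `p_e = 1` gives kappa 0 with a warning.
#'
#' @param pred,truth aligned label vectors (coerced to a common factor)
#' @return list: `accuracy`, `macro_f1`, `kappa`, `per_class` (data.table),
#'   `confusion`
#' @export
evaluate_predictions <- function(pred, truth) {
  lev <- union(levels(as.factor(truth)), levels(as.factor(pred)))
  pred <- factor(pred, levels = lev); truth <- factor(truth, levels = lev)
  ok <- !is.na(pred) & !is.na(truth)
  if (!any(ok)) {
    warning("no valid prediction/truth pairs; metrics are zero")
    per <- data.table::data.table(class = lev, precision = 0, recall = 0, f1 = 0)
    return(list(accuracy = 0, macro_f1 = 0, kappa = 0, per_class = per,
                confusion = table(truth = truth[0], pred = pred[0])))
  }
  pred <- pred[ok]; truth <- truth[ok]
  cm <- table(truth = truth, pred = pred)
  n <- sum(cm)
  p_o <- sum(diag(cm)) / n
  p_e <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (abs(1 - p_e) < 1e-12) {
    warning("expected agreement is 1; kappa defined as 0")
    0
  } else (p_o - p_e) / (1 - p_e)
  per <- data.table::rbindlist(lapply(lev, function(cl) {
    tp <- cm[cl, cl]
    prec <- if (sum(cm[, cl]) > 0) tp / sum(cm[, cl]) else 0
    rec <- if (sum(cm[cl, ]) > 0) tp / sum(cm[cl, ]) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.table::data.table(class = cl, precision = prec, recall = rec, f1 = f1)
  }))
  list(accuracy = p_o, macro_f1 = mean(per$f1), kappa = kappa,
       per_class = per, confusion = cm)
}

#' Day-of-week majority baseline
#'
#' Predicts, for each test instance, the training-majority class of its day
#' of week; unseen days fall back to the global training majority.
#'
#' @param train_dow,train_y training day-of-week and labels
#' @param test_dow test day-of-week
#' @return factor of predictions with the levels of `train_y`
#' @export
baseline_day_of_week <- function(train_dow, train_y, test_dow) {
  train_y <- as.factor(train_y)
  glob <- names(which.max(table(train_y)))
  maj <- tapply(train_y, train_dow, function(v) names(which.max(table(v))))
  pred <- maj[as.character(test_dow)]
  pred[is.na(pred)] <- glob
  factor(unname(pred), levels = levels(train_y))
}

# --- classifier wrappers ---------------------------------------------------

ALGORITHMS <- c("xgboost", "random_forest", "decision_tree", "svm", "logistic")

default_xgb_params <- function() {
  list(booster = "gbtree", max_depth = 6, min_child_weight = 2,
       eta = 0.3, gamma = 1e-8, grow_policy = "depthwise", nrounds = 100,
       subsample = 0.9, colsample_bytree = 0.7, colsample_bynode = 0.3)
}

fit_xgboost <- function(x, y, params = default_xgb_params(), seed = 1L) {
  set.seed(seed)
  lev <- levels(y)
  dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
  xp <- list(objective = "multi:softprob", num_class = length(lev),
             nthread = 1, seed = seed,
             booster = params$booster %||% "gbtree",
             eta = params$eta %||% 0.3)
  if (!identical(xp$booster, "gblinear")) {
    xp$gamma <- params$gamma %||% 0
    xp$max_depth <- params$max_depth %||% 6
    xp$min_child_weight <- params$min_child_weight %||% 1
    xp$subsample <- params$subsample %||% 0.9
    xp$colsample_bytree <- params$colsample_bytree %||% 0.7
    xp$colsample_bynode <- params$colsample_bynode %||% 0.3
  }
  if (identical(xp$booster, "gbtree")) xp$grow_policy <- params$grow_policy %||% "depthwise"
  if (identical(xp$booster, "dart")) {
    xp$sample_type <- params$sample_type %||% "uniform"
    xp$normalize_type <- params$normalize_type %||% "tree"
    xp$rate_drop <- params$rate_drop %||% 0
    xp$skip_drop <- params$skip_drop %||% 0
  }
  booster <- xgboost::xgb.train(params = xp, data = dtrain,
                                nrounds = params$nrounds %||% 100, verbose = 0)
  list(fit = booster, levels = lev,
       predict_prob = function(m, newx) {
         p <- predict(m$fit, xgboost::xgb.DMatrix(newx))
         colnames(p) <- m$levels
         p
       })
}

fit_algorithm <- function(algorithm, x, y, seed = 1L, params = NULL) {
  y <- droplevels(as.factor(y))
  set.seed(seed)
  art <- switch(algorithm,
    xgboost = fit_xgboost(x, y, params %||% default_xgb_params(), seed),
    random_forest = list(
      fit = randomForest::randomForest(x, y, ntree = 300),
      levels = levels(y),
      predict_prob = function(m, newx) predict(m$fit, newx, type = "prob")),
    decision_tree = {
      df <- data.frame(x); df$.y <- y
      list(fit = rpart::rpart(.y ~ ., df, method = "class"),
           levels = levels(y),
           predict_prob = function(m, newx) {
             predict(m$fit, data.frame(newx), type = "prob")
           })
    },
    svm = list(
      fit = e1071::svm(x, y, probability = TRUE, kernel = "radial"),
      levels = levels(y),
      predict_prob = function(m, newx) {
        p <- attr(predict(m$fit, newx, probability = TRUE), "probabilities")
        p[, m$levels, drop = FALSE]
      }),
    logistic = {
      df <- data.frame(x); df$.y <- y
      list(fit = nnet::multinom(.y ~ ., df, trace = FALSE, MaxNWts = 5000),
           levels = levels(y),
           predict_prob = function(m, newx) {
             p <- predict(m$fit, data.frame(newx), type = "probs")
             if (is.null(dim(p))) {
               p <- rbind(p) # single row
             }
             if (ncol(p) == 1) { # binomial fallback
               p <- cbind(1 - p, p); colnames(p) <- m$levels
             }
             p
           })
    },
    stop("unknown algorithm: ", algorithm, call. = FALSE))
  art$algorithm <- algorithm
  art$seed <- seed
  class(art) <- "bingesense_model"
  art
}

#' Predict class probabilities / labels from a fitted model artifact
#' @param object a `bingesense_model`; @param newx feature matrix
#' @param type "prob" or "class"
#' @param ... unused
#' @export
predict.bingesense_model <- function(object, newx, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- object$predict_prob(object, newx)
  if (type == "prob") return(p)
  factor(object$levels[max.col(p, ties.method = "first")], levels = object$levels)
}

#' Train the five classifier families on a prepared training matrix
#'
#' @param x numeric feature matrix (imputed + scaled)
#' @param y label factor
#' @param algorithms subset of
#'   `c("xgboost", "random_forest", "decision_tree", "svm", "logistic")`
#' @param seed integer seed
#' @return named list of model artifacts
#' @export
train_algorithms <- function(x, y, algorithms = ALGORITHMS, seed = 1L) {
  if (any(!is.finite(as.matrix(x)))) {
    stop("non-finite features; impute before fitting", call. = FALSE)
  }
  setNames(lapply(algorithms, fit_algorithm, x = x, y = y, seed = seed),
           algorithms)
}

# --- hyperparameter search -------------------------------------------------

#' Draw one hyperparameter configuration from the gradient-boosting space
#'
#' Space: booster in {gbtree, gblinear, dart}; max_depth 3-9;
#' min_child_weight 2-10; eta, gamma log-uniform 1e-8 to 1;
#' grow_policy {depthwise, lossguide}; dart-only sample_type, normalize_type,
#' rate_drop, skip_drop.
#'
#' @return named list of parameters
#' @export
sample_xgb_params <- function() {
  p <- list(booster = sample(c("gbtree", "gblinear", "dart"), 1),
            max_depth = sample(3:9, 1),
            min_child_weight = sample(2:10, 1),
            eta = 10^runif(1, -8, 0),
            gamma = 10^runif(1, -8, 0),
            grow_policy = sample(c("depthwise", "lossguide"), 1),
            nrounds = 100)
  if (p$booster == "dart") {
    p$sample_type <- sample(c("uniform", "weighted"), 1)
    p$normalize_type <- sample(c("tree", "forest"), 1)
    p$rate_drop <- 10^runif(1, -8, 0)
    p$skip_drop <- 10^runif(1, -8, 0)
  }
  p
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Seeded random search with stratified cross-validation
#'
#' Evaluates `n_trials` random draws from the hyperparameter space by
#' k-fold cross-validated macro-F1; imputation, scaling and SMOTE are
#' fitted inside each fold on that fold's training part only (no leakage).
#'
#' @param x raw (unscaled, possibly NA) training features
#' @param y training labels
#' @param n_trials search budget (default 100)
#' @param folds number of CV folds (default 10)
#' @param seed integer seed
#' @param smote_k SMOTE neighbors
#' @param param_sampler function returning one parameter draw
#' @return list: `best_params`, `best_score`, `history` (data.table)
#' @export
cross_validated_search <- function(x, y, n_trials = 100, folds = 10, seed = 1L,
                                   smote_k = 5,
                                   param_sampler = sample_xgb_params) {
  set.seed(seed)
  y <- droplevels(as.factor(y))
  fold <- stratified_folds(y, folds)
  trials <- replicate(n_trials, param_sampler(), simplify = FALSE)
  scores <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    fs <- vapply(seq_len(folds), function(f) {
      tr <- fold != f
      if (length(unique(y[!tr])) < 1 || sum(tr) < 2) return(NA_real_)
      tryCatch({
        prep <- prepare_xy(x[tr, , drop = FALSE], y[tr], smote_k = smote_k)
        m <- fit_xgboost(prep$x, prep$y, trials[[i]], seed = seed + i)
        xt <- minmax_apply(prep$scaler,
                           median_impute_apply(prep$med, x[!tr, , drop = FALSE]))
        p <- m$predict_prob(m, xt)
        if (any(!is.finite(p))) return(NA_real_)
        pred <- factor(m$levels[max.col(p)], levels = levels(y))
        suppressWarnings(evaluate_predictions(pred, y[!tr])$macro_f1)
      }, error = function(e) NA_real_)
    }, numeric(1))
    scores[i] <- if (all(is.na(fs))) -Inf else mean(fs, na.rm = TRUE)
  }
  best <- which.max(scores)
  hist <- data.table::data.table(trial = seq_len(n_trials), score = scores)
  list(best_params = trials[[best]], best_score = scores[best], history = hist)
}

# impute -> scale -> SMOTE, returning the fitted transforms
prepare_xy <- function(x, y, smote_k = 5, smote = TRUE) {
  med <- median_impute_fit(x)
  xi <- median_impute_apply(med, x)
  scaler <- minmax_fit(xi)
  xs <- minmax_apply(scaler, xi)
  if (smote && length(unique(y)) > 1) {
    sm <- suppressWarnings(smote_oversample(xs, y, k = smote_k))
  } else {
    sm <- list(x = xs, y = y)
  }
  list(x = sm$x, y = sm$y, med = med, scaler = scaler)
}
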