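test_that("row and grouped splits have the promised structure", {
  inst <- toy_instances(100)
  sp <- split_instances(inst, 0.2, "row", seed = 1)
  expect_equal(length(sp$test), 20, tolerance = 1)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(split_instances(inst, 0.2, "row", seed = 1), sp)
  spg <- split_instances(inst, 0.25, "grouped", seed = 2)
  expect_length(intersect(unique(inst$participant_id[spg$train]),
                          unique(inst$participant_id[spg$test])), 0)
})

test_that("min-max scaling maps training columns to [0,1] without clipping", {
  x <- cbind(a = c(2, 4, 6), b = c(5, 5, 5))
  sc <- minmax_fit(x)
  xs <- minmax_apply(sc, x)
  expect_equal(xs[, "a"], c(0, 0.5, 1))
  expect_equal(xs[, "b"], c(0, 0, 0)) # constant column
  xt <- minmax_apply(sc, cbind(a = 8, b = 9))
  expect_gt(xt[1, "a"], 1) # out-of-range test values are not clipped
})

test_that("SMOTE balances counts and synthesizes on neighbor segments", {
  set.seed(5)
  x <- matrix(rnorm(80 * 3), 80, 3)
  y <- factor(rep(c("N", "D", "BDE"), c(50, 20, 10)))
  out <- smote_oversample(x, y, k = 5)
  expect_equal(as.vector(table(out$y)), c(50, 50, 50))
  # already balanced input is unchanged
  yb <- factor(rep(c("N", "D"), each = 30))
  outb <- smote_oversample(x[1:60, ], yb)
  expect_equal(nrow(outb$x), 60)
  # tiny class triggers the k-reduction warning
  ys <- factor(rep(c("N", "D"), c(56, 4)))
  expect_warning(smote_oversample(x[1:60, ], ys, k = 5), "reducing k")
})

test_that("metrics match hand computation including the kappa example", {
  m <- evaluate_predictions(factor(c("a", "a", "b")), factor(c("a", "a", "b")))
  expect_equal(m$accuracy, 1); expect_equal(m$kappa, 1)
  expect_equal(m$macro_f1, 1)
  # the 2x2 matrix [[2,1],[1,2]]
  lab <- labels_from_cm(matrix(c(2, 1, 1, 2), 2, 2, byrow = TRUE,
                               dimnames = list(c("x", "y"), c("x", "y"))))
  m2 <- evaluate_predictions(lab$pred, lab$truth)
  expect_equal(m2$accuracy, 2 / 3, tolerance = 1e-12)
  expect_equal(m2$kappa, 1 / 3, tolerance = 1e-12)
  # constant prediction on balanced classes is chance-level
  truth <- factor(rep(c("a", "b", "c"), each = 10))
  pred <- factor(rep("a", 30), levels = c("a", "b", "c"))
  expect_equal(evaluate_predictions(pred, truth)$kappa, 0, tolerance = 1e-12)
})

test_that("the day-of-week baseline is the per-day training majority", {
  train_dow <- c(5, 5, 5, 2, 2)
  train_y <- factor(c("BDE", "BDE", "N", "N", "N"), levels = c("N", "D", "BDE"))
  pred <- baseline_day_of_week(train_dow, train_y, c(5, 2, 3))
  expect_equal(as.character(pred), c("BDE", "N", "N")) # unseen day -> majority
  # single-class training data is a constant predictor
  pred2 <- baseline_day_of_week(c(1, 2), factor(c("D", "D")), c(0, 5))
  expect_true(all(pred2 == "D"))
  # agreement with a brute-force majority oracle on random data
  set.seed(9)
  for (k in 1:5) {
    dows <- sample(0:6, 60, TRUE)
    ys <- factor(sample(c("N", "D", "BDE"), 60, TRUE), levels = c("N", "D", "BDE"))
    td <- sample(0:6, 20, TRUE)
    got <- baseline_day_of_week(dows, ys, td)
    glob <- names(which.max(table(ys)))
    want <- vapply(td, function(d) {
      sub <- ys[dows == d]
      if (!length(sub)) glob else names(which.max(table(sub)))
    }, character(1))
    expect_equal(as.character(got), want)
  }
})

test_that("all five algorithm families separate an easy 3-class problem", {
  set.seed(11)
  n <- 90
  y <- factor(rep(c("N", "D", "BDE"), each = n / 3), levels = c("N", "D", "BDE"))
  x <- cbind(f1 = rnorm(n, rep(c(0, 6, 12), each = n / 3), 0.3),
             f2 = rnorm(n))
  models <- train_algorithms(x, y, seed = 1)
  for (alg in names(models)) {
    pred <- predict(models[[alg]], x, type = "class")
    expect_gt(mean(pred == y), 0.99, label = alg)
  }
  # non-finite features are rejected before fitting
  xb <- x; xb[1, 1] <- NA
  expect_error(train_algorithms(xb, y), "non-finite")
  # seeded boosting is deterministic
  p1 <- predict(fit_algorithm("xgboost", x, y, seed = 3), x)
  p2 <- predict(fit_algorithm("xgboost", x, y, seed = 3), x)
  expect_identical(p1, p2)
})

test_that("label-shuffled data scores near chance", {
  set.seed(21)
  f1s <- replicate(5, {
    n <- 150
    x <- matrix(rnorm(n * 5), n, 5)
    y <- factor(sample(rep(c("N", "D", "BDE"), each = n / 3)),
                levels = c("N", "D", "BDE"))
    tr <- sample(n, 0.8 * n)
    m <- fit_algorithm("xgboost", x[tr, ], y[tr], seed = 1)
    evaluate_predictions(predict(m, x[-tr, ], type = "class"), y[-tr])$macro_f1
  })
  expect_lt(mean(f1s), 0.45)
  expect_gt(mean(f1s), 0.15)
})

test_that("the seeded search is reproducible and picks dominant settings", {
  set.seed(2)
  n <- 120
  y <- factor(rep(c("N", "D", "BDE"), each = n / 3), levels = c("N", "D", "BDE"))
  x <- cbind(f1 = rnorm(n, rep(c(0, 3, 6), each = n / 3)), f2 = rnorm(n))
  # collapsed space returns its single point
  one <- function() list(booster = "gbtree", max_depth = 4, eta = 0.2,
                         nrounds = 20)
  sr <- cross_validated_search(x, y, n_trials = 2, folds = 3, seed = 5,
                               param_sampler = one)
  expect_equal(sr$best_params$max_depth, 4)
  # identical trajectory under the same seed
  sr2 <- cross_validated_search(x, y, n_trials = 4, folds = 3, seed = 9)
  sr3 <- cross_validated_search(x, y, n_trials = 4, folds = 3, seed = 9)
  expect_equal(sr2$history, sr3$history)
  # a strictly better configuration wins
  flip <- local({
    i <- 0
    function() {
      i <<- i + 1
      if (i %% 2 == 1) list(booster = "gbtree", max_depth = 5, eta = 0.3, nrounds = 30)
      else list(booster = "gbtree", max_depth = 1, eta = 1e-8, nrounds = 2)
    }
  })
  sr4 <- cross_validated_search(x, y, n_trials = 2, folds = 3, seed = 5,
                                param_sampler = flip)
  expect_equal(sr4$best_params$eta, 0.3)
})

test_that("equal BDE F1 is broken by the higher kappa", {
  rows <- data.table::data.table(
    model_id = c("a", "b"), day_class = "weekend", algorithm = "xgboost",
    w = c(3, 6), d = 1, accuracy = c(0.8, 0.8), macro_f1 = c(0.7, 0.7),
    kappa = c(0.5, 0.7), bde_precision = 0.8, bde_recall = 0.8,
    bde_f1 = c(0.8, 0.8), baseline_accuracy = 0.5, baseline_macro_f1 = 0.3,
    baseline_kappa = 0, n_train = 100, n_test = 25)
  expect_equal(bingesense:::select_best(rows)$model_id, "b")
})

test_that("a test-only leakage canary cannot improve held-out scores", {
  co <- tiny_cohort(n_participants = 5, n_weeks = 4, seed = 10)
  ev <- build_events(co$ema, co$participants, seed = 1)
  prep <- prepare_cohort(co$streams, ev)
  inst <- build_instances(prep, 3, 1)
  x <- bingesense:::feature_matrix(inst)
  y <- droplevels(factor(inst$label, levels = c("N", "D", "BDE")))
  sp <- split_instances(inst, 0.25, seed = 3)
  fit_eval <- function(xm) {
    pr <- bingesense:::prepare_xy(xm[sp$train, , drop = FALSE], y[sp$train])
    m <- fit_algorithm("xgboost", pr$x, pr$y, seed = 1)
    xt <- minmax_apply(pr$scaler,
                       bingesense:::median_impute_apply(pr$med,
                                                        xm[sp$test, , drop = FALSE]))
    evaluate_predictions(predict(m, xt, type = "class"), y[sp$test])$macro_f1
  }
  base_f1 <- fit_eval(x)
  canary <- rnorm(nrow(x))
  canary[sp$test] <- as.integer(y[sp$test]) # label leaked on test rows only
  f1_canary <- fit_eval(cbind(x, canary = canary))
  expect_lte(f1_canary, base_f1 + 0.05)
})
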