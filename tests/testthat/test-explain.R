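# small fitted model shared across blocks
local_toy_model <- function(seed = 1, n = 150, p = 4, informative = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- factor(ifelse(x[, informative] > 0.3, "BDE",
                     ifelse(x[, informative] < -0.3, "N", "D")),
              levels = c("N", "D", "BDE"))
  list(x = x, y = y, model = fit_algorithm("xgboost", x, y, seed = seed))
}

test_that("tree attributions satisfy local accuracy", {
  tm <- local_toy_model()
  sh <- compute_shap(tm$model, tm$x)
  marg <- predict(tm$model$fit, xgboost::xgb.DMatrix(tm$x), outputmargin = TRUE)
  recon <- sh$base + apply(sh$values, c(1, 3), sum)
  expect_lt(max(abs(recon - marg)), 1e-4)
  expect_equal(dim(sh$values), c(nrow(tm$x), ncol(tm$x), 3))
})

test_that("a split-free model attributes nothing to any feature", {
  set.seed(2)
  x <- matrix(rnorm(60 * 3), 60, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- factor(sample(c("N", "BDE"), 60, TRUE))
  # min_child_weight larger than n prevents any split
  m <- fit_algorithm("xgboost", x, y, seed = 1,
                     params = list(min_child_weight = 1000, nrounds = 5))
  sh <- compute_shap(m, x)
  expect_lt(max(abs(sh$values)), 1e-6)
})

test_that("a single-feature model attributes only to that feature", {
  tm <- local_toy_model(p = 4, informative = 2)
  # depth-1 stumps on the informative feature only
  m <- fit_algorithm("xgboost", tm$x[, 2, drop = FALSE], tm$y, seed = 1,
                     params = list(max_depth = 1, nrounds = 10,
                                   colsample_bytree = 1))
  x_all <- tm$x[, 2, drop = FALSE]
  sh <- compute_shap(m, x_all)
  expect_gt(mean(abs(sh$values[, "f2", "BDE"])), 0)
})

test_that("importance ranks by mean absolute attribution, top-k cut", {
  vals <- array(0, c(10, 3, 3),
                dimnames = list(NULL, c("a", "b", "c"), c("N", "D", "BDE")))
  vals[, "b", "BDE"] <- 2
  vals[, "a", "BDE"] <- 0.5
  sh <- list(values = vals, x = matrix(0, 10, 3,
                                       dimnames = list(NULL, c("a", "b", "c"))))
  gi <- global_importance(sh, "BDE", k = 2)
  expect_equal(gi$feature, c("b", "a"))
  expect_equal(gi$importance, c(2, 0.5))
  expect_true(all(diff(gi$importance) <= 0))
  gi_all <- global_importance(sh, "BDE", k = 99)
  expect_equal(nrow(gi_all), 3) # oversized k returns everything
})

test_that("dependence data yields one triple per instance", {
  tm <- local_toy_model()
  sh <- compute_shap(tm$model, tm$x)
  dd <- dependence_data(sh, "f1", "f2")
  expect_equal(nrow(dd), nrow(tm$x))
  expect_equal(dd$value, tm$x[, "f1"])
  sh$x[, "f2"] <- 1
  dd2 <- dependence_data(sh, "f1", "f2")
  expect_equal(unique(dd2$color), 1)
})

test_that("partial dependence is flat for an ignored feature and matches a
           closed-form logistic toy", {
  tm <- local_toy_model(p = 4, informative = 1)
  curve <- pdp_1d(tm$model, tm$x, "f4", class = "BDE")
  expect_lt(max(abs(curve$pd)), 0.02) # f4 is noise
  curve1 <- pdp_1d(tm$model, tm$x, "f1", class = "BDE")
  expect_gt(max(curve1$pd) - min(curve1$pd), 0.3) # f1 drives the class

  # hand-built linear-logit model on one feature
  lin <- structure(list(
    levels = c("no", "yes"), algorithm = "custom",
    predict_prob = function(m, newx) {
      p <- plogis(-1 + 2 * newx[, 1])
      cbind(no = 1 - p, yes = p)
    }), class = "bingesense_model")
  x2 <- matrix(c(0, 1), 2, 1, dimnames = list(NULL, "z"))
  got <- pdp_1d(lin, x2, "z", class = "yes", n_bins = 2)
  grid <- unname(quantile(c(0, 1), probs = c(0.25, 0.75)))
  base <- mean(plogis(-1 + 2 * c(0, 1)))
  expect_equal(got$pd_raw, plogis(-1 + 2 * grid), tolerance = 1e-12)
  expect_equal(got$pd, plogis(-1 + 2 * grid) - base, tolerance = 1e-12)
})

test_that("2D location dependence collapses consistently to 1D", {
  tm <- local_toy_model(p = 4)
  g2 <- pdp_2d_location(tm$model, tm$x, lat_feature = "f1",
                        lon_feature = "f4", class = "BDE", n_bins = 3)
  expect_equal(nrow(g2), 9)
  expect_true(all(c("pd", "support", "extrapolated") %in% names(g2)))
  # f4 is ignored: collapsing it leaves the f1 profile
  g1 <- pdp_1d(tm$model, tm$x, "f1", class = "BDE", n_bins = 3)
  prof <- g2[, .(pd_raw = mean(pd_raw)), by = lat]
  expect_equal(prof$pd_raw, g1$pd_raw, tolerance = 0.02)
  # a location-blind model gives a flat surface
  g3 <- pdp_2d_location(tm$model, tm$x, "f3", "f4", class = "BDE", n_bins = 3)
  expect_lt(max(g3$pd) - min(g3$pd), 0.02)
})

test_that("sampling Shapley approximates exact tree attributions", {
  tm <- local_toy_model(n = 40, p = 3)
  exact <- compute_shap(tm$model, tm$x[1:4, , drop = FALSE])
  # pretend the model is not a tree to exercise the sampling path, in
  # probability units
  m2 <- tm$model
  m2$algorithm <- "custom"
  approx <- compute_shap(m2, tm$x[1:4, , drop = FALSE], n_perm = 300, seed = 2)
  # the dominant feature and the overall importance profile agree for the
  # BDE class (units differ: margin vs probability)
  imp_e <- colMeans(abs(exact$values[, , "BDE"]))
  imp_a <- colMeans(abs(approx$values[, , "BDE"]))
  expect_equal(which.max(imp_e), which.max(imp_a))
  expect_gt(cor(imp_e, imp_a), 0.8)
  expect_equal(approx$method, "sampling")
})

test_that("the location-probability map bins, averages and suppresses", {
  # artifact with a hand-built model and instances concentrated in 2 bins
  set.seed(4)
  n <- 60
  inst <- data.table::data.table(event_id = 1:n)
  reg <- feature_registry()
  for (cn in reg$name) inst[, (cn) := rnorm(n)]
  inst[, lat_mean := c(rep(40.41, 40), rep(40.52, 20))]
  inst[, lon_mean := rep(-79.99, n)]
  x <- bingesense:::feature_matrix(inst)
  med <- bingesense:::median_impute_fit(x)
  sc <- minmax_fit(bingesense:::median_impute_apply(med, x))
  fake <- structure(list(
    levels = c("N", "D", "BDE"), algorithm = "custom",
    predict_prob = function(m, newx) {
      p <- ifelse(newx[, "lat_mean"] > 0.5, 0.8, 0.2)
      cbind(N = (1 - p) / 2, D = (1 - p) / 2, BDE = p)
    }), class = "bingesense_model")
  art <- list(model = fake, scaler = sc, med = med, instances = inst)
  m <- location_probability_map(art, precision = 1, min_support = 10)
  expect_equal(nrow(m), 2)
  expect_true(all(m$lat_bin %in% c(40.4, 40.5)))
  expect_gt(m[lat_bin == 40.5, prob], m[lat_bin == 40.4, prob])
  m2 <- location_probability_map(art, precision = 1, min_support = 30)
  expect_equal(nrow(m2), 1) # the 20-instance bin is suppressed
  expect_error(location_probability_map(art, precision = -1), "precision")
})
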