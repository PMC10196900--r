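# Explanation layer: per-class Shapley attributions, global importance,
# dependence data, partial dependence (1D and 2D), and the privacy-binned
# location-probability map.

#' Per-class Shapley attributions for a fitted model
#'
#' Tree models (gradient boosting) get exact tree-path attributions in
#' margin (log-odds) units, satisfying local accuracy: per instance and
#' class, base value + feature attributions = model margin.  Other models
#' fall back to a seeded permutation-sampling approximation in probability
#' units.
#'
#' @param model a `bingesense_model`
#' @param x model-ready feature matrix (imputed + scaled)
#' @param n_perm permutations for the sampling fallback
#' @param seed seed for the sampling fallback
#' @return list: `values` (array instance x feature x class), `base`
#'   (matrix instance x class), `x`, `levels`, `method`
#' @export
compute_shap <- function(model, x, n_perm = 2048, seed = 1L) {
  stopifnot(inherits(model, "bingesense_model"))
  lev <- model$levels
  if (model$algorithm == "xgboost") {
    contrib <- predict(model$fit, xgboost::xgb.DMatrix(x), predcontrib = TRUE)
    if (length(dim(contrib)) == 2) { # binary/regression edge case
      contrib <- array(contrib, c(nrow(contrib), 1, ncol(contrib)))
    }
    nf <- dim(contrib)[3] - 1L
    values <- aperm(contrib[, , seq_len(nf), drop = FALSE], c(1, 3, 2))
    base <- contrib[, , nf + 1L]
    if (is.null(dim(base))) base <- matrix(base, ncol = length(lev))
    dimnames(values) <- list(NULL, colnames(x), lev)
    colnames(base) <- lev
    method <- "tree_exact"
  } else {
    ss <- sampling_shap(function(nx) predict(model, nx, type = "prob"),
                        x, n_perm = n_perm, seed = seed)
    values <- ss$values; base <- ss$base
    dimnames(values) <- list(NULL, colnames(x), lev)
    colnames(base) <- lev
    method <- "sampling"
  }
  list(values = values, base = base, x = x, levels = lev, method = method)
}

#' Permutation-sampling Shapley values
#'
#' Monte Carlo estimate over random feature orderings: walking each
#' permutation, features are switched from a background value to the
#' instance value and the change in model output is credited to the
#' switched feature.
#'
#' @param predict_fun function(matrix) -> matrix of class outputs
#' @param x instances to explain
#' @param n_perm number of sampled permutations
#' @param background background matrix (default: `x` itself)
#' @param seed integer seed
#' @return list(values, base)
#' @export
sampling_shap <- function(predict_fun, x, n_perm = 2048, background = x,
                          seed = 1L) {
  set.seed(seed)
  n <- nrow(x); p <- ncol(x)
  out0 <- predict_fun(background)
  k <- ncol(out0)
  base_vec <- colMeans(out0)
  values <- array(0, c(n, p, k))
  for (i in seq_len(n)) {
    acc <- matrix(0, p, k)
    for (r in seq_len(n_perm)) {
      ord <- sample.int(p)
      bg <- background[sample.int(nrow(background), 1), ]
      cur <- bg
      prev_out <- predict_fun(rbind(cur))
      for (j in ord) {
        cur[j] <- x[i, j]
        new_out <- predict_fun(rbind(cur))
        acc[j, ] <- acc[j, ] + (new_out - prev_out)
        prev_out <- new_out
      }
    }
    values[i, , ] <- acc / n_perm
  }
  list(values = values, base = matrix(rep(base_vec, each = n), n, k))
}

#' Global feature importance from Shapley attributions
#'
#' Mean absolute attribution across instances for one class, descending;
#' top `k` returned.
#'
#' @param shap a [compute_shap()] result
#' @param class class name (default "BDE")
#' @param k cut (default 20)
#' @return data.table: `feature`, `importance`
#' @export
global_importance <- function(shap, class = "BDE", k = 20) {
  v <- shap$values[, , class, drop = FALSE]
  imp <- colMeans(abs(v[, , 1, drop = FALSE]))[, 1]
  ord <- order(-imp)
  data.table::data.table(feature = colnames(shap$x)[ord],
                         importance = unname(imp[ord]))[seq_len(min(k, length(imp)))]
}

#' Dependence-plot triples for one feature
#'
#' One (feature value, attribution, color value) triple per instance for
#' the requested class; no binning.
#'
#' @param shap a [compute_shap()] result
#' @param feature,color_feature feature names
#' @param class class name
#' @return data.table: `value`, `attribution`, `color`
#' @export
dependence_data <- function(shap, feature, color_feature, class = "BDE") {
  stopifnot(feature %in% colnames(shap$x), color_feature %in% colnames(shap$x))
  data.table::data.table(value = shap$x[, feature],
                         attribution = shap$values[, feature, class],
                         color = shap$x[, color_feature])
}

pdp_grid <- function(v, n_bins) {
  if (length(unique(v)) == 1) {
    warning("constant feature; single-point curve")
    return(unique(v))
  }
  unname(quantile(v, probs = (seq_len(n_bins) - 0.5) / n_bins, type = 7))
}

#' One-dimensional partial dependence curve
#'
#' At each of `n_bins` equal-count grid values the feature is overwritten
#' for every reference instance and the mean predicted class probability is
#' taken; curves are centered so 0 is the expected (mean) class
#' probability.
#'
#' @param model a `bingesense_model`
#' @param x reference feature matrix (model-ready)
#' @param feature feature name
#' @param class class name
#' @param n_bins equal-count grid size (default 9)
#' @return data.table: `grid`, `pd` (centered), `pd_raw`
#' @export
pdp_1d <- function(model, x, feature, class = "BDE", n_bins = 9) {
  stopifnot(feature %in% colnames(x))
  grid <- pdp_grid(x[, feature], n_bins)
  base <- mean(predict(model, x, type = "prob")[, class])
  pd <- vapply(grid, function(g) {
    xx <- x; xx[, feature] <- g
    mean(predict(model, xx, type = "prob")[, class])
  }, numeric(1))
  data.table::data.table(grid = grid, pd = pd - base, pd_raw = pd)
}

#' Two-way partial dependence over latitude x longitude
#'
#' BDE-class partial dependence on a quantile grid of the two coordinate
#' features, with per-cell reference support counts; cells with no observed
#' instance nearby are flagged as extrapolated.
#'
#' @param model a `bingesense_model`
#' @param x reference feature matrix
#' @param lat_feature,lon_feature coordinate feature names
#' @param class class name
#' @param n_bins per-axis grid size
#' @return data.table: `lat`, `lon`, `pd` (centered), `pd_raw`, `support`,
#'   `extrapolated`
#' @export
pdp_2d_location <- function(model, x, lat_feature = "lat_mean",
                            lon_feature = "lon_mean", class = "BDE",
                            n_bins = 9) {
  g_lat <- pdp_grid(x[, lat_feature], n_bins)
  g_lon <- pdp_grid(x[, lon_feature], n_bins)
  base <- mean(predict(model, x, type = "prob")[, class])
  lat_step <- if (length(g_lat) > 1) median(diff(g_lat)) else 1
  lon_step <- if (length(g_lon) > 1) median(diff(g_lon)) else 1
  rows <- list()
  for (a in g_lat) for (b in g_lon) {
    xx <- x; xx[, lat_feature] <- a; xx[, lon_feature] <- b
    pd <- mean(predict(model, xx, type = "prob")[, class])
    support <- sum(abs(x[, lat_feature] - a) <= lat_step &
                     abs(x[, lon_feature] - b) <= lon_step)
    rows[[length(rows) + 1]] <- data.table::data.table(
      lat = a, lon = b, pd = pd - base, pd_raw = pd,
      support = support, extrapolated = support == 0)
  }
  data.table::rbindlist(rows)
}

#' Binned location-probability map
#'
#' Rounds per-instance average coordinates to `precision` decimal places
#' (1 decimal is roughly an 11.1 km latitude bin), then reports the mean
#' predicted BDE probability and support per bin; bins under `min_support`
#' are suppressed to avoid singleton disclosure.
#'
#' @param artifact best-cell artifact from [run_grid()] (model + transforms
#'   + instances)
#' @param precision decimal places for rounding (>= 0)
#' @param class class name
#' @param min_support minimum instances per reported bin
#' @return data.table: `lat_bin`, `lon_bin`, `prob`, `support`
#' @export
location_probability_map <- function(artifact, precision = 1, class = "BDE",
                                     min_support = 10) {
  if (precision < 0) stop("precision must be >= 0", call. = FALSE)
  inst <- artifact$instances
  x <- feature_matrix(inst)
  xs <- minmax_apply(artifact$scaler, median_impute_apply(artifact$med, x))
  prob <- predict(artifact$model, xs, type = "prob")[, class]
  dt <- data.table::data.table(
    lat_bin = round(inst$lat_mean, precision),
    lon_bin = round(inst$lon_mean, precision),
    prob = prob)
  out <- dt[!is.na(lat_bin), .(prob = mean(prob), support = .N),
            by = .(lat_bin, lon_bin)]
  out[support >= min_support][order(-prob)]
}
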