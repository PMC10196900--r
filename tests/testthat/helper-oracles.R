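# Independent brute-force oracles, written from the definitions and kept
# free of the package's implementation paths.

oracle_haversine <- function(lat1, lon1, lat2, lon2, r = 6371000) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

oracle_rg <- function(lat, lon) {
  clat <- sum(lat) / length(lat); clon <- sum(lon) / length(lon)
  s <- 0
  for (i in seq_along(lat)) s <- s + oracle_haversine(lat[i], lon[i], clat, clon)^2
  sqrt(s / length(lat))
}

oracle_entropy <- function(dwell) {
  p <- dwell / sum(dwell)
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log(pi)
  h
}

oracle_locvar <- function(lat, lon) {
  pv <- function(x) {
    m <- sum(x) / length(x)
    sum((x - m)^2) / length(x)
  }
  pv(lat) + pv(lon)
}

oracle_travel <- function(lat, lon) {
  s <- 0
  for (i in seq_len(length(lat) - 1)) {
    s <- s + oracle_haversine(lat[i], lon[i], lat[i + 1], lon[i + 1])
  }
  s
}

# least-squares spectrum: explained sum of squares of a two-parameter
# sinusoid fit to the centered series, over twice the series variance
oracle_ls_power <- function(t, y, freq) {
  yc <- y - mean(y)
  s2 <- sum(yc^2) / length(y)
  vapply(freq, function(f) {
    w <- 2 * pi * f
    X <- cbind(cos(w * t), sin(w * t))
    beta <- solve(crossprod(X), crossprod(X, yc))
    sum((X %*% beta)^2) / (2 * s2)
  }, numeric(1))
}

oracle_ls_band <- function(t, y, period_lo = 23.5, period_hi = 24.5, n_freq = 25) {
  freqs <- seq(1 / (period_hi * 3600), 1 / (period_lo * 3600), length.out = n_freq)
  p <- oracle_ls_power(t, y, freqs)
  sum((p[-1] + p[-n_freq]) / 2 * diff(freqs))
}

oracle_accel <- function(t, x, y, z) {
  mins <- unique(floor(t / 60))
  per_min <- vapply(mins, function(m) {
    idx <- which(floor(t / 60) == m)
    mean(sqrt(x[idx]^2 + y[idx]^2 + z[idx]^2))
  }, numeric(1))
  list(mean = mean(per_min), median = median(per_min),
       std = if (length(per_min) > 1) sd(per_min) else 0,
       max = max(per_min))
}

# metrics recomputed from the confusion matrix with explicit loops
oracle_metrics <- function(cm) {
  lev <- rownames(cm)
  n <- sum(cm)
  acc <- sum(diag(cm)) / n
  pe <- 0
  for (cl in lev) pe <- pe + sum(cm[cl, ]) * sum(cm[, cl])
  pe <- pe / n^2
  kap <- if (abs(1 - pe) < 1e-12) 0 else (acc - pe) / (1 - pe)
  f1s <- prs <- rcs <- numeric(length(lev))
  for (i in seq_along(lev)) {
    tp <- cm[i, i]
    pr <- if (sum(cm[, i]) > 0) tp / sum(cm[, i]) else 0
    rc <- if (sum(cm[i, ]) > 0) tp / sum(cm[i, ]) else 0
    f1s[i] <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
    prs[i] <- pr; rcs[i] <- rc
  }
  list(accuracy = acc, kappa = kap, macro_f1 = mean(f1s),
       precision = prs, recall = rcs, f1 = f1s)
}

# labels drawn from a confusion matrix (row = truth, col = pred)
labels_from_cm <- function(cm) {
  lev <- rownames(cm)
  truth <- pred <- character(0)
  for (i in seq_along(lev)) for (j in seq_along(lev)) {
    k <- cm[i, j]
    truth <- c(truth, rep(lev[i], k))
    pred <- c(pred, rep(lev[j], k))
  }
  list(truth = factor(truth, levels = lev), pred = factor(pred, levels = lev))
}

# --- exhaustive Shapley oracle for gradient-boosted trees ------------------

# cover-weighted conditional expectation of one dumped tree given the
# coalition S of known features
tree_expect <- function(tr, x, S) {
  walk <- function(id) {
    row <- tr[tr$ID == id, ]
    if (row$Feature == "Leaf") return(row$Gain)
    if (row$Feature %in% S) {
      v <- x[[row$Feature]]
      nxt <- if (is.na(v)) row$Missing else if (v < row$Split) row$Yes else row$No
      return(walk(nxt))
    }
    yes <- tr[tr$ID == row$Yes, ]; no <- tr[tr$ID == row$No, ]
    (yes$Cover * walk(row$Yes) + no$Cover * walk(row$No)) / (yes$Cover + no$Cover)
  }
  walk(tr$ID[1])
}

booster_value <- function(trees, x, S) {
  s <- 0
  for (k in unique(trees$Tree)) {
    s <- s + tree_expect(trees[trees$Tree == k, ], x, S)
  }
  s
}

# exact Shapley values by enumeration over all 2^p coalitions
oracle_shapley <- function(trees, x) {
  feats <- setdiff(unique(trees$Feature), "Leaf")
  p_all <- colnames(x)
  phi <- setNames(numeric(length(p_all)), p_all)
  n_f <- length(p_all)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), n_f))
  xl <- as.list(setNames(as.numeric(x), p_all))
  vals <- apply(subsets, 1, function(m) booster_value(trees, xl, p_all[m]))
  for (j in seq_len(n_f)) {
    for (r in seq_len(nrow(subsets))) {
      m <- unlist(subsets[r, ])
      if (m[j]) next
      s_size <- sum(m)
      w <- factorial(s_size) * factorial(n_f - s_size - 1) / factorial(n_f)
      m2 <- m; m2[j] <- TRUE
      r2 <- sum(2^(which(m2) - 1)) + 1
      phi[j] <- phi[j] + w * (vals[r2] - vals[r])
    }
  }
  phi
}

# --- small fixtures --------------------------------------------------------

tiny_cohort <- function(n_participants = 4, n_weeks = 3, seed = 7, ...) {
  simulate_cohort(cohort_config(n_participants = n_participants,
                                n_weeks = n_weeks, seed = seed, ...))
}

toy_instances <- function(n = 120, seed = 1) {
  set.seed(seed)
  y <- factor(sample(c("N", "D", "BDE"), n, TRUE, prob = c(.6, .25, .15)),
              levels = c("N", "D", "BDE"))
  data.table::data.table(
    event_id = seq_len(n),
    participant_id = sample(sprintf("p%02d", 1:8), n, TRUE),
    label = y,
    day_of_week = sample(0:6, n, TRUE),
    f1 = rnorm(n) + 2 * (y == "BDE"),
    f2 = rnorm(n))
}
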