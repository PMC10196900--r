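test_that("drink counts map to labels at sex-specific thresholds", {
  r <- labeling_rules()
  expect_equal(as.character(label_event(4, "female", r)), "BDE")
  expect_equal(as.character(label_event(3, "female", r)), "D")
  expect_equal(as.character(label_event(4, "male", r)), "D")
  expect_equal(as.character(label_event(5, "male", r)), "BDE")
  expect_equal(as.character(label_event(0, "female", r)), "N")
  expect_equal(as.character(label_event(0, "male", r)), "N")
  expect_error(label_event(-1, "male", r), "non-negative")
  # vectorized with recycling
  expect_equal(as.character(label_event(c(0, 2, 9), "female", r)),
               c("N", "D", "BDE"))
})

test_that("pseudo-onsets are uniform over the evening 15-minute grid", {
  set.seed(42)
  on <- pseudo_onset(rep(19000L, 10000))
  sod <- on %% 86400
  expect_true(all(sod >= 18 * 3600 & sod < 24 * 3600))
  expect_true(all(sod %% 900 == 0))
  slots <- (sod - 18 * 3600) / 900
  gof <- chisq.test(tabulate(slots + 1, nbins = 24))
  expect_gt(gof$p.value, 0.01)
  set.seed(7); a <- pseudo_onset(19000L)
  set.seed(7); b <- pseudo_onset(19000L)
  expect_identical(a, b)
})

test_that("the epoch grid covers exactly the 24 hours before onset", {
  onset <- 19000 * 86400 + 21 * 3600 # 21:00
  g <- epochize(onset)
  expect_equal(nrow(g), 96)
  expect_equal(g$start[1], onset - 86400)
  expect_equal(g$end[96], onset)
  expect_true(all(g$start %% 900 == 0))
  # off-grid onsets snap down to the containing boundary
  g2 <- epochize(onset + 7 * 60) # 21:07
  expect_equal(g2$end[96], onset)
})

test_that("analysis-window slices respect length and temporal separation", {
  onset <- 19000 * 86400 + 18 * 3600 # 18:00
  w <- extract_window(onset, 3, 6)
  expect_equal(nrow(w), 12)
  expect_equal(w$start[1], 19000 * 86400 + 9 * 3600) # 09:00
  expect_equal(w$end[12], 19000 * 86400 + 12 * 3600) # 12:00
  # prediction times for d = 1 and d = 3
  expect_equal(max(extract_window(onset, 1, 1)$end), onset - 3600) # 17:00
  expect_equal(max(extract_window(onset, 1, 3)$end), onset - 3 * 3600) # 15:00
  # midnight crossing
  w3 <- extract_window(19000 * 86400, 1, 1)
  expect_equal(w3$start[1], 18999 * 86400 + 22 * 3600)
  expect_equal(w3$end[4], 18999 * 86400 + 23 * 3600)
  expect_error(extract_window(onset, 20, 6), "24")
})

test_that("short gaps are filled with the flanking average, long gaps kept", {
  dt <- data.table::data.table(
    participant_id = "p1",
    t = c(0, 300, 900, 1200), # 600 s gap between 300 and 900
    v = c(10, 10, 20, 20))
  out <- interpolate_gaps(dt, "v", cadence_s = 300, max_gap_s = 900)
  ins <- out[!t %in% dt$t]
  expect_equal(nrow(ins), 1)
  expect_equal(ins$v, 15)
  # a four-hour gap is untouched
  dt2 <- data.table::data.table(participant_id = "p1",
                                t = c(0, 300, 300 + 4 * 3600), v = 1)
  expect_equal(nrow(interpolate_gaps(dt2, "v", 300)), 3)
  # gapless input is the identity
  dt3 <- data.table::data.table(participant_id = "p1", t = (0:5) * 300, v = 1)
  expect_equal(nrow(interpolate_gaps(dt3, "v", 300)), 6)
})

test_that("day classification follows the configurable weekend set", {
  expect_equal(as.character(classify_day(5L)), "weekend") # Saturday
  expect_equal(as.character(classify_day(1L)), "weekday") # Tuesday
  expect_equal(as.character(classify_day(4L, weekend_days = c(5L, 6L))),
               "weekday") # Friday under an alternate split
})

test_that("event building conserves label counts from the reports", {
  co <- tiny_cohort(n_participants = 5, n_weeks = 4, seed = 3)
  ev <- build_events(co$ema, co$participants, seed = 1)
  expect_equal(as.vector(table(ev$label)),
               as.vector(table(factor(co$truth$events$class,
                                      levels = c("N", "D", "BDE")))))
  expect_true(all(is.finite(ev$onset)))
  expect_true(all(ev[pseudo == TRUE, (onset %% 86400) >= 18 * 3600]))
})

test_that("inclusion/exclusion drops GPS-free events and sparse participants", {
  co <- tiny_cohort(n_participants = 4, n_weeks = 3, seed = 8)
  ev <- build_events(co$ema, co$participants, seed = 1)
  # remove all GPS for one participant
  drop_pid <- ev$participant_id[1]
  co$streams$gps <- co$streams$gps[participant_id != drop_pid]
  prep <- prepare_cohort(co$streams, ev)
  flt <- apply_inclusion_exclusion(ev, day_feature_rows(prep))
  expect_false(drop_pid %in% flt$events$participant_id)
  expect_true(all(flt$exclusions[grepl("no_gps|too_few", reason),
                                 event_id] %in% ev[participant_id == drop_pid |
                                                     TRUE, event_id]))
  expect_setequal(unique(flt$exclusions[event_id %in%
                                          ev[participant_id == drop_pid, event_id],
                                        reason]),
                  c("no_gps"))
  # a fully observed cohort has no exclusions
  co2 <- tiny_cohort(n_participants = 3, n_weeks = 3, seed = 8,
                     missingness = default_missingness(short_rate = 0,
                                                       long_rate = 0))
  ev2 <- build_events(co2$ema, co2$participants, seed = 1)
  prep2 <- prepare_cohort(co2$streams, ev2)
  flt2 <- apply_inclusion_exclusion(ev2, day_feature_rows(prep2))
  expect_equal(nrow(flt2$exclusions), 0)
})
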