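test_that("midpoint imputation maps the five periods to their midpoints", {
  expect_equal(midpoint_impute("0-6w"), 0.75)
  expect_equal(midpoint_impute("6w-3m"), 2.25)
  expect_equal(midpoint_impute("3-6m"), 4.5)
  expect_equal(midpoint_impute("6-9m"), 7.5)
  expect_equal(midpoint_impute("9-12m"), 10.5)
  expect_error(midpoint_impute("12-15m"), "unknown")
  # order-preserving across the periods
  mids <- midpoint_impute(c("0-6w", "6w-3m", "3-6m", "6-9m", "9-12m"))
  expect_true(all(diff(mids) > 0))
})

test_that("state paths follow discontinuation, direct-transition and clock rules", {
  sp <- fogt2_space()
  # discontinuation by request in 3-6m, DM at 8, death at 14
  r <- ten_patient_cohort()[3, ]
  p <- derive_state_path(r, sp)
  expect_equal(p$path$state, c(1, 4, 7, 8))
  expect_equal(p$path$entry, c(0, 4.5, 8, 14))
  expect_false(p$censored)
  # event-triggered discontinuation: direct 1 -> 7, state 4 never visited
  r <- data.frame(subject_id = 1, disc_status = "event_triggered",
                  disc_time = NA, disc_period = NA, lr_time = NA, dm_time = 5,
                  both_lr_dm = FALSE, death_time = NA, censor_time = 30)
  p <- derive_state_path(r, sp)
  expect_equal(p$path$state, c(1, 7))
  expect_equal(p$path$entry, c(0, 5))
  # no events, full CTx, censored at 40: forced jumps at exactly 6 and 12
  r <- ten_patient_cohort()[1, ]
  p <- derive_state_path(r, sp)
  expect_equal(p$path$state, c(1, 2, 3))
  expect_equal(p$path$entry, c(0, 6, 12))
  expect_true(p$censored)
  expect_equal(p$end_time, 40)
})

test_that("masked both-LR-and-DM records enter the DM state at the recorded time", {
  r <- data.frame(subject_id = 1, disc_status = "none", disc_time = NA,
                  disc_period = NA, lr_time = NA, dm_time = 22,
                  both_lr_dm = TRUE, death_time = 40, censor_time = NA)
  p <- derive_state_path(r, fogt2_space())
  expect_equal(p$path$state, c(1, 2, 3, 7, 8))
  expect_equal(p$path$entry, c(0, 6, 12, 22, 40))
  expect_false(6 %in% p$path$state)
})

test_that("invalid records are rejected", {
  sp <- fogt2_space()
  base <- data.frame(subject_id = 1, disc_status = "none", disc_time = NA,
                     disc_period = NA, lr_time = NA, dm_time = NA,
                     both_lr_dm = FALSE, death_time = NA, censor_time = NA)
  expect_error(derive_state_path(base, sp), "exactly one")
  both <- base; both$death_time <- 10; both$censor_time <- 20
  expect_error(derive_state_path(both, sp), "exactly one")
  late <- base; late$dm_time <- 30; late$censor_time <- 20
  expect_error(derive_state_path(late, sp), "after death/censoring")
  # event sequence with no corresponding arrow: DM under a pruned arrow set
  no17 <- fogt2_space(transitions = data.frame(
    from = c(1, 1, 1, 2, 2, 2, 2, 3, 3, 3, 4, 4, 4, 5, 5, 5, 6, 6, 7),
    to = c(4, 6, 8, 5, 6, 7, 8, 6, 7, 8, 6, 7, 8, 6, 7, 8, 7, 8, 8)))
  dm5 <- base; dm5$dm_time <- 5; dm5$censor_time <- 30
  expect_error(derive_state_path(dm5, no17), "no arrow")
})

test_that("long format stacks one row per stochastic outgoing transition", {
  sp <- fogt2_space()
  cohort <- data.frame(subject_id = 1, age_years = 60, bmi = 25, sex = "male",
                       uicc = "II", grade = "1+2", arm = "5FU",
                       surgery = "anterior_resection",
                       disc_status = "event_triggered", disc_time = NA,
                       disc_period = NA, lr_time = NA, dm_time = 5,
                       both_lr_dm = FALSE, death_time = 9, censor_time = NA)
  long <- to_long_format(cohort, sp)
  # path (1,0) -> (7,5) -> (8,9): state 1 emits its 4 stochastic arrows
  # (1 -> 2 is deterministic and produces no estimable rows), state 7 one row
  s1 <- long[long$from == 1, ]
  expect_equal(nrow(s1), 4)
  expect_setequal(s1$to, c(4, 6, 7, 8))
  expect_true(all(s1$tstart == 0 & s1$tstop == 5))
  expect_equal(s1$status[s1$to == 7], 1)
  expect_equal(sum(s1$status), 1)
  s7 <- long[long$from == 7, ]
  expect_equal(nrow(s7), 1)
  expect_equal(s7$tstart, 5)
  expect_equal(s7$tstop, 9)
  expect_equal(s7$status, 1)
})

test_that("a subject censored early leaves only censored state-1 rows", {
  cohort <- ten_patient_cohort()[10, ]
  cohort$censor_time <- 3
  long <- to_long_format(cohort)
  expect_true(all(long$from == 1))
  expect_true(all(long$status == 0))
  expect_true(all(long$tstop == 3))
})

test_that("episodes tile follow-up and deterministic times bound them", {
  cohort <- ten_patient_cohort()
  long <- to_long_format(cohort)
  for (id in cohort$subject_id) {
    rows <- long[long$subject_id == id, ]
    eps <- unique(rows[, c("tstart", "tstop")])
    eps <- eps[order(eps$tstart), ]
    expect_true(all(eps$tstart < eps$tstop))
    if (nrow(eps) > 1)  # no gaps, no overlaps
      expect_equal(eps$tstart[-1], eps$tstop[-nrow(eps)])
    expect_equal(eps$tstart[1], 0)
  }
  # subject 1 (uneventful, censored at 40) has episode breaks at 6 and 12
  e1 <- sort(unique(long$tstop[long$subject_id == 1]))
  expect_equal(e1, c(6, 12, 40))
})

test_that("event totals are conserved between paths and long rows", {
  set.seed(42)
  cohort <- simulate_cohort(fogt2_sim_config(n = 300), seed = 42)
  sp <- fogt2_space()
  long <- to_long_format(cohort, sp)
  paths <- lapply(seq_len(nrow(cohort)),
                  function(i) derive_state_path(cohort[i, ], sp))
  for (q in sp$transitions$trans) {
    fr <- sp$transitions$from[q]; to <- sp$transitions$to[q]
    n_path <- sum(vapply(paths, function(p) {
      s <- p$path$state
      any(s[-length(s)] == fr & s[-1] == to)
    }, FALSE))
    expect_equal(sum(long$status[long$trans == q]), n_path, label = q)
  }
})

test_that("long-format construction is deterministic and idempotent", {
  cohort <- ten_patient_cohort()
  a <- to_long_format(cohort)
  b <- to_long_format(cohort)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("percentage arithmetic matches the published worked examples", {
  expect_equal(fmt_pct(215, 471), 45.6)     # recurrences in the cohort
  expect_equal(fmt_pct(157, 215, 0), 73)    # DM among recurrences
  expect_equal(fmt_pct(25, 215), 11.6)      # both LR and DM among recurrences
  expect_equal(fmt_pct(471, 796), 59.2)     # analysed fraction of the trial
  expect_equal(fmt_pct(266, 471), 56.5)     # censored
  expect_equal(fmt_pct(205, 471), 43.5)     # died
  expect_equal(fmt_pct(276, 471), 58.6)     # completed 12 months CTx
  expect_equal(fmt_pct(195, 471), 41.4)     # discontinued
  expect_equal(fmt_pct(25, 182), 13.7)      # both, among DM-state entrants
  expect_equal(fmt_pct(0, 10), 0)
  expect_error(fmt_pct(1, 0), "positive")
})

test_that("cohort_summary tabulates marginals, events and occupancy", {
  cohort <- ten_patient_cohort()
  cs <- cohort_summary(cohort)
  expect_equal(cs$n, 10)
  expect_equal(sum(cs$occupancy$n), 10)
  ev <- cs$events
  expect_equal(ev$n[ev$what == "any recurrence"], 5)
  expect_equal(ev$pct[ev$what == "any recurrence"], 50)
  expect_equal(ev$n[ev$what == "DM only"], 2)
  expect_equal(ev$n[ev$what == "LR only"], 1)
  expect_equal(ev$n[ev$what == "both LR and DM"], 2)
  expect_equal(ev$n[ev$what == "censored"], 4)
  expect_equal(ev$n[ev$what == "died"], 6)
  males <- cs$covariates[cs$covariates$variable == "sex" &
                         cs$covariates$level == "male", ]
  expect_equal(males$n, 10)
  expect_equal(males$pct, 100)
  expect_error(cohort_summary(ten_patient_cohort()[0, ]), "empty")
})
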