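# fits on a small simulated cohort, shared across the blocks below
fit_demo <- local({
  cohort <- simulate_cohort(fogt2_sim_config(n = 1500), seed = 4)
  long <- to_long_format(cohort)
  fit_transitions(long)
})

test_that("subject cumulative hazards scale baselines by exp(beta'z)", {
  fits <- fit_demo
  # all-reference profile with age 0 and BMI 0 encodes to z = 0
  ref0 <- reference_patient(list(
    age_years = 0, bmi = 0, sex = "male", uicc = "II", grade = "1+2",
    arm = "5FU", surgery = "abdominoperineal"))
  ch <- subject_cumhaz(fits, ref0)
  for (q in names(fits))
    expect_equal(ch[[q]]$increment, fits[[q]]$basehaz$increment)
  # arbitrary profile: per-increment scaling against independent arithmetic
  hp <- reference_patient("high_risk")
  chh <- subject_cumhaz(fits, hp)
  zh <- as.numeric(encode_covariates(hp, fogt2_covariates())[1, ])
  names(zh) <- msmclock:::covariate_terms(fogt2_covariates())
  for (q in names(fits)) {
    f <- fits[[q]]
    hr <- if (isTRUE(f$modelled)) exp(sum(f$coef * zh[names(f$coef)])) else 1
    expect_equal(chh[[q]]$increment, f$basehaz$increment * hr)
  }
  expect_error(subject_cumhaz(fits, reference_patient(list(age_years = 50))),
               "missing covariate")
})

test_that("with no hazard and no rules the probability matrix stays identity", {
  sp <- two_state_space()
  ch <- structure(list("1" = data.frame(time = numeric(0),
                                        increment = numeric(0))),
                  space = sp, class = "subject_cumhaz")
  tp <- aalen_johansen(ch, sp, s = 0, tmax = 24, grid = c(6, 12, 24))
  for (i in seq_along(tp$times))
    expect_equal(tp$P[, , i], diag(2))
})

test_that("two-state constant hazard recovers the exponential closed form", {
  set.seed(77)
  n <- 5000
  cfg <- two_state_config(rate = 0.1, n = n, admin = 60)
  rec <- simulate_paths(cfg, no_covariate_table(n))
  long <- to_long_format(rec, cfg$space, specs = list())
  fits <- fit_transitions(long, specs = list())
  ch <- subject_cumhaz(fits, data.frame(dummy = 1))
  tp <- aalen_johansen(ch, cfg$space, s = 0, tmax = 12, grid = 12)
  p12 <- tp$P[1, 2, length(tp$times)]
  truth <- 1 - exp(-1.2)
  mc_se <- sqrt(truth * (1 - truth) / n)
  expect_lt(abs(p12 - truth), 3 * mc_se)
  # row sums stay 1 on the whole grid
  expect_lt(max(abs(apply(tp$P, c(1, 3), sum) - 1)), 1e-10)
})

test_that("forced jumps move all remaining occupancy at the rule times", {
  # no stochastic events at all: occupancy follows the deterministic clock
  sp <- fogt2_space()
  ch <- structure(setNames(lapply(1:20, function(q)
    data.frame(time = numeric(0), increment = numeric(0))),
    as.character(1:20)), space = sp, class = "subject_cumhaz")
  tp <- aalen_johansen(ch, sp, s = 0, tmax = 24, grid = c(5.999, 6, 12))
  at <- function(t) tp$P[1, , which(tp$times == t)]
  expect_equal(at(5.999), c(1, rep(0, 7)))
  expect_equal(at(6), c(0, 1, rep(0, 6)))      # all mass 1 -> 2 at 6.0
  expect_equal(at(12), c(0, 0, 1, rep(0, 5)))  # and 2 -> 3 at 12.0
})

test_that("transition probabilities satisfy Chapman-Kolmogorov exactly", {
  fits <- fit_demo
  ch <- subject_cumhaz(fits, reference_patient("high_risk"))
  sp <- attr(fit_demo, "space")
  p0_24 <- aalen_johansen(ch, sp, s = 0, tmax = 24, grid = c(12, 24))
  p0_12 <- aalen_johansen(ch, sp, s = 0, tmax = 12, grid = 12)
  p12_24 <- aalen_johansen(ch, sp, s = 12, tmax = 24, grid = 24)
  A <- p0_24$P[, , length(p0_24$times)]
  B <- p0_12$P[, , length(p0_12$times)] %*% p12_24$P[, , length(p12_24$times)]
  expect_lt(max(abs(A - B)), 1e-12)
})

test_that("probability arrays are row-stochastic with absorbing unit rows", {
  fits <- fit_demo
  for (prof in list(reference_patient("high_risk"),
                    reference_patient("low_risk"))) {
    ch <- subject_cumhaz(fits, prof)
    tp <- aalen_johansen(ch, attr(fit_demo, "space"), s = 0, tmax = 60)
    expect_lt(max(abs(apply(tp$P, c(1, 3), sum) - 1)), 1e-10)
    expect_true(all(tp$P >= -1e-12 & tp$P <= 1 + 1e-12))
    expect_equal(tp$P[, , 1], diag(8))  # P(s, s) = I
    for (i in seq_along(tp$times))     # death row is a unit vector always
      expect_equal(tp$P[8, , i], c(rep(0, 7), 1))
    # cumulative death probability is nondecreasing in t
    for (k in 1:7) expect_true(all(diff(tp$P[k, 8, ]) >= -1e-12))
  }
})

test_that("stacked curves cumulate to one and merge bands by summation", {
  fits <- fit_demo
  ch <- subject_cumhaz(fits, reference_patient("low_risk"))
  tp <- aalen_johansen(ch, attr(fit_demo, "space"), s = 0, tmax = 60)
  stk <- stacked_probabilities(tp)
  expect_equal(names(stk), c("time", "1+2", "3", "4", "5", "6", "7", "8"))
  top <- stk[[ncol(stk)]]
  expect_lt(max(abs(top - 1)), 1e-10)
  # merged band equals P11 + P12 at every grid time
  expect_equal(stk[["1+2"]],
               tp$P[1, 1, ] + tp$P[1, 2, ])
  # bands are nonnegative and nondecreasing across the stack
  mat <- as.matrix(stk[, -1])
  expect_true(all(mat >= -1e-12))
  expect_true(all(diff(t(mat)) >= -1e-12))
  expect_error(stacked_probabilities(tp, display = list(1:2, 3:4)),
               "partition")
})

test_that("dynamic prediction equals independent pointwise evaluations", {
  fits <- fit_demo
  sp <- attr(fit_demo, "space")
  hp <- reference_patient("high_risk")
  history <- data.frame(state = c(1, 2, 5, 7), time = c(0, 6, 8, 12))
  dp <- fixed_horizon_survival(fits, hp, history, horizon = 60)
  ch <- subject_cumhaz(fits, hp)
  probe <- seq(0, 60, length.out = 20)
  for (s in probe) {
    k <- history$state[max(which(history$time <= s))]
    direct <- if (k == 8) 0 else {
      tp <- aalen_johansen(ch, sp, s = s, tmax = 60)
      1 - tp$P[k, 8, length(tp$times)]
    }
    dp_at <- fixed_horizon_survival(fits, hp, history, horizon = 60,
                                    times = s)
    expect_lt(abs(dp_at$survival - direct), 1e-12)
  }
})

test_that("dynamic prediction is 0 after death and 1 at the horizon alive", {
  fits <- fit_demo
  hp <- reference_patient("high_risk")
  dead <- data.frame(state = c(1, 7, 8), time = c(0, 10, 20))
  dp <- fixed_horizon_survival(fits, hp, dead, horizon = 60)
  expect_true(all(dp$survival[dp$s >= 20] == 0))
  expect_true(all(dp$survival[dp$s < 20] > 0))
  alive <- data.frame(state = c(1, 2, 3), time = c(0, 6, 12))
  dp2 <- fixed_horizon_survival(fits, hp, alive, horizon = 60)
  expect_equal(dp2$survival[dp2$s == 60], 1)
  # histories that contradict the arrow set are rejected
  expect_error(fixed_horizon_survival(fits, hp,
                                      data.frame(state = c(1, 3), time = c(0, 4))),
               "no arrow")
})

test_that("survival drops when the history enters the metastasis state", {
  fits <- fit_demo
  hp <- reference_patient("high_risk")
  with_dm <- data.frame(state = c(1, 2, 5, 7), time = c(0, 6, 8, 12))
  without <- data.frame(state = c(1, 2, 5), time = c(0, 6, 8))
  s_dm <- fixed_horizon_survival(fits, hp, with_dm, times = 12)$survival
  s_no <- fixed_horizon_survival(fits, hp, without, times = 12)$survival
  expect_lt(s_dm, s_no)
})

test_that("bootstrap SEs are seed-reproducible and near the binomial scale", {
  set.seed(55)
  n <- 500
  cfg <- two_state_config(rate = 0.05, n = n, admin = 24)
  cohort <- simulate_paths(cfg, no_covariate_table(n))
  stat <- function(fits) {
    ch <- subject_cumhaz(fits, data.frame(dummy = 1))
    tp <- aalen_johansen(ch, cfg$space, s = 0, tmax = 12, grid = 12)
    c(p12 = tp$P[1, 2, length(tp$times)])
  }
  b1 <- bootstrap_se(cohort, stat, B = 200, seed = 9, space = cfg$space,
                     specs = list())
  b2 <- bootstrap_se(cohort, stat, B = 200, seed = 9, space = cfg$space,
                     specs = list())
  expect_identical(b1$se, b2$se)
  # no censoring before 12 months, so the estimator is a binomial fraction
  long <- to_long_format(cohort, cfg$space, specs = list())
  fits <- fit_transitions(long, specs = list())
  p_hat <- stat(fits)[["p12"]]
  binom <- sqrt(p_hat * (1 - p_hat) / n)
  expect_lt(abs(b1$se[["p12"]] - binom) / binom, 0.3)
  # B = 2 smoke contract: SE is the two-replicate standard deviation
  b3 <- bootstrap_se(cohort, stat, B = 2, seed = 3, space = cfg$space,
                     specs = list())
  expect_equal(b3$se[["p12"]], stats::sd(b3$estimates[, "p12"]))
  expect_error(bootstrap_se(cohort, stat, B = 1, seed = 1,
                            space = cfg$space, specs = list()))
})
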