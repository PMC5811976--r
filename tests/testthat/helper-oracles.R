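# Independent oracles and small fixtures shared across test files.

# Explicitly coded Breslow-ties Cox partial log-likelihood for
# counting-process rows (tstart, tstop, status, x), one covariate.
# Kept deliberately independent of the package's fitting path.
breslow_loglik_1cov <- function(beta, rows) {
  et <- sort(unique(rows$tstop[rows$status == 1]))
  ll <- 0
  for (tj in et) {
    ev <- rows$status == 1 & rows$tstop == tj
    risk <- rows$tstart < tj & rows$tstop >= tj
    ll <- ll + sum(beta * rows$x[ev]) -
      sum(ev) * log(sum(exp(beta * rows$x[risk])))
  }
  ll
}

# brute-force maximizer of the coded partial likelihood over beta in [-5, 5]
oracle_beta_1cov <- function(rows) {
  stats::optimize(function(b) breslow_loglik_1cov(b, rows),
                  interval = c(-5, 5), maximum = TRUE, tol = 1e-9)$maximum
}

# right-censored single-transition rows in msm_long shape (one covariate x)
simple_cox_rows <- function(time, status, x) {
  data.frame(subject_id = seq_along(time), trans = 1L, from = 1L, to = 2L,
             tstart = 0, tstop = time, status = as.integer(status), x = x)
}

one_cov_specs <- function() list(x = covariate_spec("x", "continuous"))

# minimal alive -> dead state space, no deterministic rules
two_state_space <- function() {
  state_space(
    states = data.frame(id = 1:2, label = c("alive", "dead"),
                        absorbing = c(FALSE, TRUE)),
    transitions = data.frame(from = 1, to = 2)
  )
}

illness_death_space <- function() {
  state_space(
    states = data.frame(id = 1:3, label = c("healthy", "ill", "dead"),
                        absorbing = c(FALSE, FALSE, TRUE)),
    transitions = data.frame(from = c(1, 1, 2), to = c(2, 3, 3))
  )
}

# two-state simulation config with a single constant hazard and no covariates
two_state_config <- function(rate, n, admin = Inf, dropout = 0) {
  simulation_config(two_state_space(), rates = c("1->2" = rate),
                    specs = list(), marginals = NULL,
                    admin_censor = admin, dropout_rate = dropout, n = n,
                    coarsen_discontinuation = FALSE, mask_second_event = FALSE)
}

no_covariate_table <- function(n) data.frame(subject_id = seq_len(n))

# recovery-experiment data-generating process on the 8-state preset: eight
# transitions with several hundred events each (covariate-modelled), all
# others kept far below the 20-event gate; known categorical log-HRs,
# all |beta| <= 1.1
recovery_sim_config <- function(n = 1500) {
  rates <- c("1->4" = 0.031, "1->6" = 0.0005, "1->7" = 0.02, "1->8" = 0.0005,
             "2->5" = 0.045, "2->6" = 0.0005, "2->7" = 0.028, "2->8" = 0.0005,
             "3->6" = 0.0003, "3->7" = 0.012, "3->8" = 0.0003,
             "4->6" = 0.0005, "4->7" = 0.035, "4->8" = 0.001,
             "5->6" = 0.0005, "5->7" = 0.035, "5->8" = 0.001,
             "6->7" = 0.01, "6->8" = 0.01, "7->8" = 0.05)
  betas <- list(
    "1->4" = c(sex_female = -0.4, grade_X3.4 = 0.4),
    "1->7" = c(grade_X3.4 = 0.7),
    "2->5" = c(uicc_IIIb = 0.3),
    "2->7" = c(arm_X5FU_FA = -0.5),
    "3->7" = c(uicc_IIIb = 0.85, uicc_IIIc = 1.1),
    "4->7" = c(uicc_IIIc = 1.1),
    "5->7" = c(uicc_IIIc = 1.1, surgery_anterior_resection = -1.0),
    "7->8" = c(uicc_IIIc = 0.55, sex_female = 0.2))
  base <- fogt2_sim_config(n = n)
  simulation_config(base$space, rates, betas = betas,
                    marginals = base$marginals, admin_censor = 72,
                    dropout_rate = 0.008, n = n)
}

# true log-HR matrix (transition key x encoded term) implied by a config
true_beta_matrix <- function(cfg) {
  keys <- sprintf("%d->%d", cfg$space$transitions$from,
                  cfg$space$transitions$to)
  terms <- msmclock:::covariate_terms(cfg$specs)
  B <- matrix(0, length(keys), length(terms),
              dimnames = list(keys, terms))
  for (k in names(cfg$betas)) B[k, names(cfg$betas[[k]])] <- cfg$betas[[k]]
  B
}

# hand-written 10-patient cohort on the 8-state preset; the expected flow
# tallies in test-reporting.R were enumerated by hand from these records
ten_patient_cohort <- function() {
  rec <- function(id, disc_status = "none", disc_time = NA, disc_period = NA,
                  lr = NA, dm = NA, both = FALSE, death = NA, cens = NA)
    data.frame(subject_id = id, age_years = 60, bmi = 25, sex = "male",
               uicc = "II", grade = "1+2", arm = "5FU",
               surgery = "anterior_resection",
               disc_status = disc_status, disc_time = disc_time,
               disc_period = disc_period, lr_time = lr, dm_time = dm,
               both_lr_dm = both, death_time = death, censor_time = cens,
               stringsAsFactors = FALSE)
  rbind(
    rec(1, cens = 40),                                   # 1-2-3, censored in 3
    rec(2, death = 30),                                  # 1-2-3, died from 3
    rec(3, disc_status = "discontinued", disc_period = "3-6m",
        dm = 8, death = 14),                             # 1-4-7-8
    rec(4, disc_status = "discontinued", disc_period = "6-9m",
        cens = 50),                                      # 1-2-5, censored in 5
    rec(5, dm = 5, death = 20),                          # 1-7-8 (direct)
    rec(6, lr = 20, cens = 45),                          # 1-2-3-6, censored
    rec(7, lr = 14, dm = 18, death = 30),                # 1-2-3? lr at 14 from 3, dm 18: 6->7
    rec(8, both = TRUE, dm = 22, death = 40),            # 1-2-3-7-8 (masked both)
    rec(9, death = 4),                                   # 1-8 early death
    rec(10, cens = 9)                                    # 1-2, censored in 2
  )
}
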