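#' Hazard-ratio report table across transitions
#'
#' One block per covariate-modelled transition, covariates in declared order,
#' reference levels shown as "1" with empty CI and p. Hazard ratios are
#' rendered as "HR (lower; upper)"; p-values below 0.001 as "< 0.001",
#' otherwise with three decimals; results significant at a strict two-sided
#' p < 0.05 are starred. Gated-off transitions appear as a single
#' "not modelled" row.
#'
#' @param fits an `msm_fits`.
#' @return data frame: `trans`, `from`, `to`, `variable`, `level`,
#'   `hr_ci`, `p_value`, `significant`.
#' @export
hr_table <- function(fits) {
  specs <- attr(fits, "specs")
  blocks <- lapply(fits, function(fit) {
    head_cols <- data.frame(trans = fit$trans, from = fit$from, to = fit$to)
    if (!isTRUE(fit$modelled)) {
      return(cbind(head_cols, variable = "(all)", level = "",
                   hr_ci = "not modelled", p_value = "", significant = FALSE))
    }
    ws <- wald_summary(fit)
    rows <- lapply(specs, function(sp) {
      if (sp$kind == "continuous") {
        trm <- sp$name
        i <- match(trm, ws$term)
        lab <- if (sp$scale != 1)
          sprintf("(per %g units)", sp$scale) else "(per unit)"
        data.frame(variable = sp$name, level = lab,
                   hr_ci = fmt_hr_ci(ws$hr[i], ws$ci_lower[i], ws$ci_upper[i]),
                   p_value = fmt_p(ws$p[i]),
                   significant = ws$p[i] < 0.05)
      } else {
        ref <- data.frame(variable = sp$name, level = sp$reference,
                          hr_ci = "1", p_value = "", significant = FALSE)
        oth <- do.call(rbind, lapply(setdiff(sp$levels, sp$reference),
          function(l) {
            trm <- paste0(sp$name, "_", make.names(l))
            i <- match(trm, ws$term)
            data.frame(variable = sp$name, level = l,
                       hr_ci = fmt_hr_ci(ws$hr[i], ws$ci_lower[i],
                                         ws$ci_upper[i]),
                       p_value = fmt_p(ws$p[i]),
                       significant = ws$p[i] < 0.05)
          }))
        rbind(ref, oth)
      }
    })
    body <- do.call(rbind, rows)
    cbind(head_cols[rep(1, nrow(body)), ], body)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

fmt_hr_ci <- function(hr, lo, hi)
  sprintf("%.2f (%.2f; %.2f)", hr, lo, hi)

fmt_p <- function(p) ifelse(p < 0.001, "< 0.001", sprintf("%.3f", p))

#' Transition and occupancy counts of a cohort
#'
#' Per-arrow realized transition counts (deterministic rules included) and
#' per-state occupancy at end of follow-up; the occupancy column sums to the
#' cohort size.
#'
#' @param cohort patient-record data frame (non-empty).
#' @param space a `state_space`.
#' @return list with `transition_counts` (`from`, `to`, `n`) and `occupancy`
#'   (`state`, `label`, `n`).
#' @export
flow_counts <- function(cohort, space = fogt2_space()) {
  if (!NROW(cohort)) stop("empty cohort")
  cs <- cohort_summary(cohort, space)
  list(transition_counts = cs$transition_counts, occupancy = cs$occupancy)
}

#' Run the complete analysis pipeline on a simulated cohort
#'
#' Simulate, stack, fit, predict, and write every artifact as plain CSV/JSON:
#' the cohort, the long-format data, the hazard-ratio table, stacked
#' transition-probability curves for the reference patients, fixed-horizon
#' dynamic predictions along the supplied histories, and a run-summary JSON
#' (parameters, per-transition event counts, convergence flags). Outputs are
#' deterministic given `config` and `seed`.
#'
#' @param config a `simulation_config`; see [fogt2_sim_config()].
#' @param out_dir output directory (created if needed).
#' @param seed RNG seed.
#' @param profiles named list of [reference_patient()]s.
#' @param histories named list of history data frames (`state`, `time`).
#' @param horizon fixed prediction horizon in months.
#' @param bootstrap_B bootstrap replicates for the SE of the predicted
#'   survival at `s = 0` (0 = skip).
#' @return (invisibly) list of the in-memory results.
#' @export
run_msm_pipeline <- function(config, out_dir, seed = 1,
                             profiles = list(high_risk = reference_patient("high_risk"),
                                             low_risk = reference_patient("low_risk")),
                             histories = list(
                               uneventful = data.frame(state = 1, time = 0)),
                             horizon = 60, bootstrap_B = 0) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(config, seed = seed)
  long <- to_long_format(cohort, config$space, config$specs)
  fits <- fit_transitions(long, config$specs)
  gate <- attr(fits, "gate")
  tab <- hr_table(fits)

  utils::write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(long), file.path(out_dir, "long_format.csv"),
                   row.names = FALSE)
  utils::write.csv(tab, file.path(out_dir, "hr_table.csv"), row.names = FALSE)

  curves <- list(); dyn <- list()
  for (nm in names(profiles)) {
    ch <- subject_cumhaz(fits, profiles[[nm]])
    tp <- aalen_johansen(ch, config$space, s = 0, tmax = horizon)
    stk <- stacked_probabilities(tp)
    stk$profile <- nm
    curves[[nm]] <- stk
    for (hn in names(histories)) {
      dp <- fixed_horizon_survival(fits, profiles[[nm]], histories[[hn]],
                                   horizon = horizon, space = config$space)
      dp$profile <- nm; dp$history <- hn
      dyn[[paste(nm, hn, sep = ".")]] <- as.data.frame(dp)
    }
  }
  utils::write.csv(do.call(rbind, curves),
                   file.path(out_dir, "stacked_probabilities.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, dyn),
                   file.path(out_dir, "dynamic_prediction.csv"),
                   row.names = FALSE)

  boot <- NULL
  if (bootstrap_B > 0) {
    prof <- profiles[[1]]
    stat <- function(f) {
      dp <- fixed_horizon_survival(f, prof,
                                   data.frame(state = 1, time = 0),
                                   horizon = horizon, times = 0,
                                   space = config$space)
      c(surv_at_start = dp$survival[1])
    }
    boot <- bootstrap_se(cohort, stat, B = bootstrap_B, seed = seed + 1,
                         space = config$space, specs = config$specs)
  }

  summary_json <- list(
    seed = seed, n = config$n, horizon_months = horizon,
    admin_censor_months = config$admin_censor,
    dropout_rate_per_month = config$dropout_rate,
    coarsen_discontinuation = config$coarsen_discontinuation,
    mask_second_event = config$mask_second_event,
    gate = gate,
    converged = vapply(fits, `[[`, TRUE, "converged"),
    bootstrap = if (!is.null(boot))
      list(B = bootstrap_B, se = as.list(boot$se),
           dropped = boot$n_dropped) else NULL
  )
  jsonlite::write_json(summary_json, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  invisible(list(cohort = cohort, long = long, fits = fits, hr_table = tab,
                 stacked = curves, dynamic = dyn, bootstrap = boot))
}
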