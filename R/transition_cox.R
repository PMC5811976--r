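#' @importFrom survival coxph Surv coxph.control
#' @importFrom stats pnorm qnorm as.formula
NULL

#' Event-count gate for covariate modelling
#'
#' Transitions with too few observed events are not covariate-modelled: their
#' cumulative hazard is estimated nonparametrically instead. The default gate
#' admits a transition if and only if it has strictly more than 20 events.
#'
#' @param long an `msm_long` data frame.
#' @param min_events_exclusive transitions with `events <= min_events_exclusive`
#'   are not modelled (default 20).
#' @return data frame with one row per stochastic transition: `trans`,
#'   `n_events`, `modelled`.
#' @export
gate_covariates <- function(long, min_events_exclusive = 20) {
  space <- attr(long, "space")
  trans <- if (!is.null(space)) space$transitions$trans else sort(unique(long$trans))
  n_events <- vapply(trans, function(q) sum(long$status[long$trans == q]), 0L)
  data.frame(trans = trans, n_events = as.integer(n_events),
             modelled = n_events > min_events_exclusive)
}

#' Fit a transition-specific Cox proportional-hazards model
#'
#' Fits a multivariable Cox model to the rows of one stochastic transition of
#' stacked long-format data, using the Breslow approximation for tied event
#' times (Newton-Raphson with step-halving, relative log-likelihood tolerance
#' 1e-9, at most 50 iterations). The Breslow baseline cumulative hazard is
#' computed at the zero covariate vector (uncentered). If the transition is
#' gated off (or `covariates = FALSE`) a null model is returned whose baseline
#' is the Nelson-Aalen-type estimator with increments d_j / n_j.
#'
#' @param long an `msm_long` data frame.
#' @param transition_id stochastic transition number.
#' @param specs covariate specifications (defaults to the specs attached to
#'   `long`).
#' @param covariates logical: model covariates? Typically the gate decision.
#' @return a `cox_transition_fit`: list with `trans`, `from`, `to`,
#'   `modelled`, `coef`, `vcov`, `loglik`, `n_rows`, `n_events`, `converged`,
#'   `monotone` (unbounded-likelihood flag) and `basehaz` (data frame `time`,
#'   `increment`, `cumhaz`).
#' @export
fit_transition_cox <- function(long, transition_id, specs = attr(long, "specs"),
                               covariates = TRUE) {
  rows <- long[long$trans == transition_id, , drop = FALSE]
  space <- attr(long, "space")
  arrow <- if (!is.null(space))
    space$transitions[space$transitions$trans == transition_id, ] else
    data.frame(from = unique(rows$from)[1], to = unique(rows$to)[1])
  terms <- covariate_terms(specs)
  n_events <- sum(rows$status)
  fit <- list(trans = transition_id, from = arrow$from[1], to = arrow$to[1],
              modelled = FALSE, coef = NULL, vcov = NULL, loglik = NA_real_,
              n_rows = nrow(rows), n_events = as.integer(n_events),
              converged = TRUE, monotone = FALSE, terms = terms)
  if (!covariates || n_events == 0 || !length(terms)) {
    fit$basehaz <- nelson_aalen_increments(rows)
    class(fit) <- "cox_transition_fit"
    return(fit)
  }
  X <- as.matrix(rows[, terms, drop = FALSE])
  Xc <- sweep(X, 2, colMeans(X))
  if (qr(Xc)$rank < ncol(Xc))
    stop("rank-deficient design matrix for transition ", transition_id,
         " (constant or collinear covariates on the risk set)")
  f <- as.formula(paste("survival::Surv(tstart, tstop, status) ~",
                        paste(sprintf("`%s`", terms), collapse = " + ")))
  cf <- survival::coxph(f, data = rows, ties = "breslow",
                        control = survival::coxph.control(eps = 1e-9,
                                                          iter.max = 50))
  beta <- unname(cf$coefficients)
  names(beta) <- terms
  fit$modelled <- TRUE
  fit$coef <- beta
  fit$vcov <- unname(cf$var)
  dimnames(fit$vcov) <- list(terms, terms)
  fit$loglik <- cf$loglik[2]
  fit$converged <- cf$iter < 50 && all(is.finite(beta))
  # a binary covariate with all its events in one group sends beta to
  # +/- infinity (monotone partial likelihood); flag rather than error
  ev <- rows$status == 1
  sep <- vapply(seq_len(ncol(X)), function(j) {
    v <- X[, j]
    if (!all(v %in% c(0, 1))) return(FALSE)
    sum(ev & v == 1) == 0 || sum(ev & v == 0) == 0
  }, FALSE)
  fit$monotone <- any(sep) || any(abs(beta) > 10) ||
    any(!is.finite(diag(fit$vcov)))
  fit$basehaz <- breslow_increments(rows, X, beta)
  class(fit) <- "cox_transition_fit"
  fit
}

# Nelson-Aalen-type increments d_j / n_j for a null model
nelson_aalen_increments <- function(rows) {
  et <- sort(unique(rows$tstop[rows$status == 1]))
  if (!length(et))
    return(data.frame(time = numeric(0), increment = numeric(0),
                      cumhaz = numeric(0)))
  inc <- vapply(et, function(tj) {
    d <- sum(rows$status == 1 & rows$tstop == tj)
    n <- sum(rows$tstart < tj & rows$tstop >= tj)
    d / n
  }, 0)
  data.frame(time = et, increment = inc, cumhaz = cumsum(inc))
}

# Breslow baseline increments d_j / sum_{at risk} exp(x'beta), uncentered
breslow_increments <- function(rows, X, beta) {
  et <- sort(unique(rows$tstop[rows$status == 1]))
  if (!length(et))
    return(data.frame(time = numeric(0), increment = numeric(0),
                      cumhaz = numeric(0)))
  elp <- exp(drop(X %*% beta))
  inc <- vapply(et, function(tj) {
    at_risk <- rows$tstart < tj & rows$tstop >= tj
    sum(rows$status == 1 & rows$tstop == tj) / sum(elp[at_risk])
  }, 0)
  data.frame(time = et, increment = inc, cumhaz = cumsum(inc))
}

#' Fit all transitions of a multi-state model
#'
#' Applies the event-count gate and fits each stochastic transition on its own
#' rows (separate baselines, no shared strata).
#'
#' @param long an `msm_long` data frame.
#' @param specs covariate specifications.
#' @param min_events_exclusive gate threshold; see [gate_covariates()].
#' @return an `msm_fits` object: list of `cox_transition_fit`s indexed by
#'   transition number, with attributes `space`, `specs`, `gate`.
#' @export
fit_transitions <- function(long, specs = attr(long, "specs"),
                            min_events_exclusive = 20) {
  space <- attr(long, "space")
  gate <- gate_covariates(long, min_events_exclusive)
  fits <- lapply(gate$trans, function(q)
    fit_transition_cox(long, q, specs,
                       covariates = gate$modelled[gate$trans == q]))
  names(fits) <- as.character(gate$trans)
  structure(fits, space = space, specs = specs, gate = gate,
            class = "msm_fits")
}

#' @export
print.msm_fits <- function(x, ...) {
  gate <- attr(x, "gate")
  cat(sprintf("msm_fits: %d transitions, %d covariate-modelled\n",
              nrow(gate), sum(gate$modelled)))
  print(gate, row.names = FALSE)
  invisible(x)
}

#' Wald summary of a transition fit
#'
#' Hazard ratios `exp(beta)`, 95% Wald confidence intervals
#' `exp(beta +- 1.96 se)` and two-sided normal p-values per covariate. When
#' HR < 1 the percent risk reduction `(1 - HR) * 100` is also reported.
#'
#' @param fit a covariate-modelled `cox_transition_fit`.
#' @return data frame: `term`, `coef`, `se`, `hr`, `ci_lower`, `ci_upper`,
#'   `p`, `risk_reduction_pct` (NA when HR >= 1).
#' @export
wald_summary <- function(fit) {
  if (!isTRUE(fit$modelled)) stop("fit has no covariates (gated off)")
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  beta <- fit$coef
  se <- sqrt(diag(fit$vcov))
  z <- beta / se
  hr <- exp(beta)
  data.frame(
    term = names(beta), coef = unname(beta), se = unname(se),
    hr = unname(hr),
    ci_lower = unname(exp(beta - 1.96 * se)),
    ci_upper = unname(exp(beta + 1.96 * se)),
    p = unname(2 * stats::pnorm(-abs(z))),
    risk_reduction_pct = unname(ifelse(hr < 1, (1 - hr) * 100, NA_real_)),
    row.names = NULL
  )
}

#' Baseline cumulative hazard of a transition fit
#'
#' Right-continuous nondecreasing step function, zero before the first event
#' time: the Breslow estimator at covariate vector 0 for modelled transitions,
#' the Nelson-Aalen-type estimator for gated-off ones.
#'
#' @param fit a `cox_transition_fit`.
#' @param times optional evaluation times; if omitted the step-function data
#'   frame (`time`, `increment`, `cumhaz`) is returned.
#' @return data frame, or numeric vector of the cumulative hazard at `times`.
#' @export
baseline_cumhaz <- function(fit, times = NULL) {
  bh <- fit$basehaz
  if (is.null(times)) return(bh)
  if (!nrow(bh)) return(rep(0, length(times)))
  idx <- findInterval(times, bh$time)
  c(0, bh$cumhaz)[idx + 1]
}
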