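#' Covariate-specific cumulative transition hazards
#'
#' Scales each transition's baseline cumulative-hazard increments by
#' `exp(beta' z)` for a given covariate profile (standard Cox prediction).
#' Gated-off transitions, which carry no coefficients, keep their unscaled
#' nonparametric baseline.
#'
#' @param fits an `msm_fits` object.
#' @param profile a [reference_patient()] (raw covariate values).
#' @return a `subject_cumhaz`: list of per-transition data frames (`time`,
#'   `increment`), with attributes `space` and `hr` (the per-transition
#'   `exp(beta' z)`).
#' @export
subject_cumhaz <- function(fits, profile) {
  specs <- attr(fits, "specs")
  z <- as.numeric(encode_covariates(profile, specs)[1, ])
  names(z) <- covariate_terms(specs)
  hrs <- numeric(length(fits))
  out <- vector("list", length(fits))
  for (i in seq_along(fits)) {
    fit <- fits[[i]]
    hr <- if (isTRUE(fit$modelled)) {
      miss <- setdiff(names(fit$coef), names(z))
      if (length(miss)) stop("profile missing covariate term(s): ",
                             paste(miss, collapse = ", "))
      exp(sum(fit$coef * z[names(fit$coef)]))
    } else 1
    hrs[i] <- hr
    bh <- fit$basehaz
    out[[i]] <- data.frame(time = bh$time, increment = bh$increment * hr)
  }
  names(out) <- names(fits)
  structure(out, space = attr(fits, "space"), hr = hrs,
            class = "subject_cumhaz")
}

# step matrices (I + dA), with forced deterministic jumps appended at rule
# times, over the grid of all hazard jump times in (s, tmax]
aj_step_matrices <- function(cumhaz, space, s, tmax, extra_times = NULL) {
  K <- nrow(space$states)
  jump_times <- sort(unique(c(
    unlist(lapply(cumhaz, function(h) h$time), use.names = FALSE),
    space$deterministic$time, extra_times)))
  jump_times <- jump_times[jump_times > s & jump_times <= tmax]
  tr <- space$transitions
  steps <- vector("list", length(jump_times))
  for (m in seq_along(jump_times)) {
    u <- jump_times[m]
    dA <- matrix(0, K, K)
    for (q in seq_len(nrow(tr))) {
      h <- cumhaz[[as.character(tr$trans[q])]]
      hit <- h$increment[h$time == u]
      if (length(hit)) dA[tr$from[q], tr$to[q]] <- dA[tr$from[q], tr$to[q]] + sum(hit)
    }
    diag(dA) <- diag(dA) - rowSums(dA)
    if (any(1 + diag(dA) < 0))
      stop(sprintf("hazard increment exceeds 1 at time %g (negative diagonal in I + dA)", u))
    step <- diag(K) + dA
    rules <- space$deterministic[space$deterministic$time == u, , drop = FALSE]
    for (r in seq_len(nrow(rules))) {
      J <- diag(K)
      J[rules$from[r], rules$from[r]] <- 0
      J[rules$from[r], rules$to[r]] <- 1
      step <- step %*% J
    }
    steps[[m]] <- step
  }
  list(times = jump_times, steps = steps)
}

#' Aalen-Johansen transition probabilities by product integration
#'
#' Computes the matrix of transition probabilities `P(s, t)` for a set of
#' covariate-specific cumulative hazards as the product integral over the
#' evaluation grid: at each hazard jump time the factor `I + dA(u)` is
#' applied, where `dA` has off-diagonal (j, k) entries equal to the hazard
#' increment of arrow j -> k and diagonal entries minus the row sums; at each
#' deterministic rule time the factor is additionally post-multiplied by the
#' forced jump matrix that moves all remaining occupancy of the rule's source
#' state to its target (hazard increments at exactly the rule time act
#' first). Rows sum to one by construction; no renormalization is applied.
#'
#' @param cumhaz a `subject_cumhaz` (or any named list of `time`/`increment`
#'   data frames aligned to the space's transition numbers).
#' @param space a `state_space`; defaults to the space attached to `cumhaz`.
#' @param s origin time (months).
#' @param tmax last evaluation time.
#' @param grid optional extra evaluation times to include in the output grid.
#' @return a `transprob`: list with `s`, `times` (grid, starting at `s`) and
#'   `P`, an array `K x K x length(times)` with `P[, , 1]` the identity.
#' @export
aalen_johansen <- function(cumhaz, space = attr(cumhaz, "space"), s = 0,
                           tmax, grid = NULL) {
  stopifnot(tmax >= s)
  K <- nrow(space$states)
  sm <- aj_step_matrices(cumhaz, space, s, tmax, extra_times = grid)
  out_times <- sort(unique(c(s, sm$times, grid[grid > s & grid <= tmax], tmax)))
  P <- array(0, dim = c(K, K, length(out_times)))
  cur <- diag(K)
  j <- 1L
  P[, , 1] <- cur
  for (i in seq_along(out_times)[-1]) {
    while (j <= length(sm$times) && sm$times[j] <= out_times[i]) {
      cur <- cur %*% sm$steps[[j]]
      j <- j + 1L
    }
    P[, , i] <- cur
  }
  structure(list(s = s, times = out_times, P = P,
                 states = space$states),
            class = "transprob")
}

#' @export
print.transprob <- function(x, ...) {
  cat(sprintf("transprob: P(%g, t) on %d grid times up to %g months\n",
              x$s, length(x$times), max(x$times)))
  cat("P(s, tmax):\n")
  M <- x$P[, , length(x$times)]
  dimnames(M) <- list(x$states$label, x$states$label)
  print(round(M, 4))
  invisible(x)
}

#' Probability of being in each state over time, from a given start state
#'
#' @param tp a `transprob`.
#' @param from start state id.
#' @return data frame: `time`, one column per state.
#' @export
occupancy_curves <- function(tp, from = 1) {
  K <- dim(tp$P)[1]
  out <- as.data.frame(t(vapply(seq_along(tp$times),
                                function(i) tp$P[from, , i], numeric(K))))
  names(out) <- paste0("state", seq_len(K))
  cbind(time = tp$times, out)
}

#' Stacked transition-probability curves
#'
#' Cumulative sums of the state-occupancy probabilities from state 1 in a
#' declared display order, optionally merging display states (e.g. the two
#' on-treatment states into one "on CTx" band). The topmost curve is
#' identically 1.
#'
#' @param tp a `transprob` with origin state 1 at `s = 0`.
#' @param display list of integer vectors: each element is a display band
#'   (states merged by summation), bottom band first. Must partition the
#'   state set.
#' @return data frame: `time`, then one cumulative column per band (named
#'   after the merged state ids).
#' @export
stacked_probabilities <- function(tp,
                                  display = list(c(1, 2), 3, 4, 5, 6, 7, 8)) {
  K <- dim(tp$P)[1]
  flat <- sort(unlist(display))
  if (!identical(as.integer(flat), seq_len(K)))
    stop("display order must partition the state set")
  probs <- vapply(display, function(band)
    vapply(seq_along(tp$times),
           function(i) sum(tp$P[1, band, i]), 0), numeric(length(tp$times)))
  cum <- t(apply(probs, 1, cumsum))
  if (length(display) == 1) cum <- t(cum)
  out <- as.data.frame(cum)
  names(out) <- vapply(display, function(b) paste(b, collapse = "+"), "")
  cbind(time = tp$times, out)
}

# state occupied at prediction time s along an ordered history
history_state_at <- function(history, s) {
  idx <- max(which(history$time <= s))
  history$state[idx]
}

#' Fixed-horizon dynamic prediction of survival along a clinical history
#'
#' For a fixed horizon `T` on the study clock (default 60 months after start
#' of chemotherapy), computes at each prediction time `s` the probability of
#' being alive at `T` given the history's state at `s` and the covariate
#' profile: `1 - P[k(s), death](s, T | z)`. The value is 0 once the history
#' enters the death state and 1 at `s = T` for a subject alive at `T`.
#' Counterfactual curves are obtained by supplying an alternative history.
#'
#' @param fits an `msm_fits`.
#' @param profile a [reference_patient()].
#' @param history data frame (`state`, `time`): ordered states entered along
#'   the study clock, starting with state 1 at time 0. Consecutive states
#'   must be joined by a stochastic or deterministic arrow.
#' @param horizon fixed horizon T in months (study clock, not sliding).
#' @param times prediction times `s`; default is a grid over `[0, horizon]`
#'   combining history times, deterministic times and monthly steps.
#' @param space a `state_space`; defaults to the one attached to `fits`.
#' @return a `dynamic_prediction` data frame: `s`, `state`, `survival`.
#' @export
fixed_horizon_survival <- function(fits, profile, history,
                                   horizon = 60, times = NULL,
                                   space = attr(fits, "space")) {
  history <- as.data.frame(history)
  stopifnot(all(c("state", "time") %in% names(history)))
  if (history$time[1] != 0 || history$state[1] != 1)
    stop("history must start in state 1 at time 0")
  if (is.unsorted(history$time)) stop("history times must be nondecreasing")
  if (max(history$time) > horizon) stop("horizon precedes the last history time")
  for (i in seq_len(nrow(history) - 1)) {
    a <- history$state[i]; b <- history$state[i + 1]
    ok <- !is.na(transition_id(space, a, b)) ||
      any(space$deterministic$from == a & space$deterministic$to == b)
    if (!ok) stop(sprintf("history step %d -> %d has no arrow", a, b))
  }
  death_states <- space$states$id[space$states$absorbing]
  ch <- subject_cumhaz(fits, profile)
  sm <- aj_step_matrices(ch, space, 0, horizon)
  K <- nrow(space$states)
  if (is.null(times))
    times <- sort(unique(c(0, history$time, space$deterministic$time,
                           seq(0, horizon, by = 1), horizon)))
  times <- times[times >= 0 & times <= horizon]
  # suffix products: S_i = A_i A_{i+1} ... A_m, so P(s, horizon) = S_{i(s)}
  m <- length(sm$times)
  suffix <- vector("list", m + 1)
  suffix[[m + 1]] <- diag(K)
  for (i in rev(seq_len(m)))
    suffix[[i]] <- sm$steps[[i]] %*% suffix[[i + 1]]
  surv <- vapply(times, function(s) {
    k <- history_state_at(history, s)
    if (k %in% death_states) return(0)
    i <- findInterval(s, sm$times, left.open = FALSE) + 1L
    # first step with time > s
    while (i <= m && sm$times[i] <= s) i <- i + 1L
    P <- suffix[[i]]
    1 - sum(P[k, death_states])
  }, 0)
  state_at <- vapply(times,
                     function(s) as.integer(history_state_at(history, s)), 0L)
  structure(data.frame(s = times, state = state_at, survival = surv),
            horizon = horizon, history = history,
            class = c("dynamic_prediction", "data.frame"))
}

#' Bootstrap standard errors of pipeline-derived quantities
#'
#' Patient-level resampling with replacement: each replicate re-stacks the
#' resampled cohort, refits every transition, and evaluates a user statistic
#' on the refitted model. Replicates on which the statistic cannot be
#' evaluated (e.g. zero events on a required transition) are dropped and
#' counted; a warning is issued when more than 20% are dropped.
#'
#' @param cohort patient-record data frame.
#' @param statistic function `(fits) -> named numeric vector`.
#' @param B number of bootstrap replicates (>= 2).
#' @param seed RNG seed; same seed, same SEs.
#' @param space,specs model structure and covariates.
#' @param min_events_exclusive gate threshold passed to [fit_transitions()].
#' @return list: `se` (named), `estimates` (B_kept x p matrix), `n_dropped`.
#' @export
bootstrap_se <- function(cohort, statistic, B, seed = 1,
                         space = fogt2_space(), specs = fogt2_covariates(),
                         min_events_exclusive = 20) {
  stopifnot(B >= 2)
  set.seed(seed)
  n <- nrow(cohort)
  reps <- vector("list", B)
  dropped <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot <- cohort[idx, , drop = FALSE]
    boot$subject_id <- seq_len(n)
    val <- tryCatch({
      long <- to_long_format(boot, space, specs)
      fits <- fit_transitions(long, specs, min_events_exclusive)
      statistic(fits)
    }, error = function(e) NULL)
    if (is.null(val)) dropped <- dropped + 1L else reps[[b]] <- val
  }
  kept <- do.call(rbind, reps[!vapply(reps, is.null, TRUE)])
  if (dropped > 0.2 * B)
    warning(sprintf("%d of %d bootstrap replicates dropped", dropped, B))
  if (is.null(kept) || nrow(kept) < 2)
    stop("fewer than 2 usable bootstrap replicates")
  list(se = apply(kept, 2, stats::sd), estimates = kept, n_dropped = dropped)
}
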