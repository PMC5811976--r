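#' @importFrom stats setNames
NULL

# the five discontinuation reporting periods, in months (6 weeks = 1.5 months)
disc_periods <- function() {
  data.frame(label = c("0-6w", "6w-3m", "3-6m", "6-9m", "9-12m"),
             lower = c(0, 1.5, 3, 6, 9),
             upper = c(1.5, 3, 6, 9, 12),
             stringsAsFactors = FALSE)
}

#' Midpoint imputation of an interval-coarsened discontinuation time
#'
#' Treatment discontinuation is reported only as one of five calendar periods
#' on the chemotherapy clock: 0-6 weeks, 6 weeks-3 months, 3-6, 6-9 and 9-12
#' months. The event time is imputed as the midpoint of the period, with 6
#' weeks = 1.5 months.
#'
#' @param period character vector of period labels (`"0-6w"`, `"6w-3m"`,
#'   `"3-6m"`, `"6-9m"`, `"9-12m"`).
#' @return numeric vector of imputed times in months.
#' @examples
#' midpoint_impute("3-6m")  # 4.5
#' @export
midpoint_impute <- function(period) {
  p <- disc_periods()
  idx <- match(period, p$label)
  if (anyNA(idx)) stop("unknown discontinuation period label: ",
                       paste(unique(period[is.na(idx)]), collapse = ", "))
  (p$lower[idx] + p$upper[idx]) / 2
}

# bin an exact discontinuation time into its reporting period label
disc_period_of <- function(time) {
  p <- disc_periods()
  idx <- findInterval(time, c(p$lower, Inf), left.open = TRUE,
                      rightmost.closed = FALSE)
  idx[time == 0] <- 1L
  if (any(idx < 1 | idx > nrow(p)))
    stop("discontinuation time outside 0-12 months: ",
         paste(time[idx < 1 | idx > nrow(p)], collapse = ", "))
  p$label[idx]
}

#' Derive a subject's state path from a patient record
#'
#' Applies the model's conventions to one raw record: the path starts in
#' state 1 at time 0; deterministic rules fire at their clock times for
#' subjects still in the source state (an event at exactly the rule time is
#' attributed to the pre-jump state); non-event discontinuation moves the
#' subject to the early (< 6 months) or late (6-12 months) discontinuation
#' state at the (possibly midpoint-imputed) time; discontinuation caused by
#' recurrence or metastasis is a *direct* transition to the event state —
#' the discontinuation states are never visited; subjects with both LR and DM
#' but only the second date recorded enter the DM state at that recorded time.
#'
#' @param record one-row data frame (or list) with the patient-record fields;
#'   see [simulate_cohort()] for the schema.
#' @param space a `state_space`; defaults to [fogt2_space()].
#' @return a `state_path`: list with `path` (data frame `state`, `entry`),
#'   `end_time` (death or censoring time) and `censored` flag.
#' @export
derive_state_path <- function(record, space = fogt2_space()) {
  r <- as.list(record)
  num <- function(x) if (is.null(x) || length(x) == 0 || is.na(x)) NA_real_ else as.numeric(x)
  chr <- function(x) if (is.null(x) || length(x) == 0 || is.na(x)) NA_character_ else as.character(x)
  death <- num(r$death_time); cens <- num(r$censor_time)
  if (is.na(death) == is.na(cens))
    stop("exactly one of death_time and censor_time must be present")
  end_time <- if (is.na(death)) cens else death
  disc_status <- chr(r$disc_status); if (is.na(disc_status)) disc_status <- "none"
  t_disc <- NA_real_; disc_exact <- FALSE
  if (disc_status == "discontinued") {
    t_disc <- num(r$disc_time)
    disc_exact <- !is.na(t_disc)
    if (!disc_exact) {
      per <- chr(r$disc_period)
      if (is.na(per)) stop("discontinued record without time or period")
      t_disc <- midpoint_impute(per)
    }
  }
  both <- isTRUE(as.logical(r$both_lr_dm))
  t_lr <- if (both) NA_real_ else num(r$lr_time)
  t_dm <- num(r$dm_time)
  # recorded times must respect the terminal time; a midpoint-imputed
  # discontinuation may overshoot it and is then simply never reached
  tmax <- suppressWarnings(max(c(if (disc_exact) t_disc, t_lr, t_dm),
                               na.rm = TRUE))
  if (is.finite(tmax) && tmax > end_time)
    stop("event time after death/censoring time")

  det <- space$deterministic
  death_state <- space$states$id[space$states$absorbing][1]
  if (!is.na(death) && is.na(death_state))
    stop("space has no absorbing state to receive the death event")
  path_state <- 1L; path_entry <- 0
  cur <- 1L; t <- 0
  lr_done <- FALSE; dm_done <- FALSE; disc_done <- FALSE
  move <- function(to, at) {
    if (is.na(transition_id(space, cur, to)) &&
        !any(det$from == cur & det$to == to))
      stop(sprintf("no arrow %d -> %d in the state space", cur, to))
    path_state <<- c(path_state, as.integer(to))
    path_entry <<- c(path_entry, at)
    cur <<- as.integer(to); t <<- at
  }
  repeat {
    if (space$states$absorbing[cur]) break
    # candidate stochastic events from the current state
    cand_time <- numeric(0); cand_to <- integer(0)
    add <- function(time, to) {
      if (!is.na(time) && time >= t) {
        cand_time <<- c(cand_time, time)
        cand_to <<- c(cand_to, as.integer(to))
      }
      invisible(NULL)
    }
    if (disc_status == "discontinued" && !disc_done) {
      # <6m discontinuation leaves state 1 for 4; 6-12m leaves state 2 for 5;
      # an event exactly at 6.0 is attributed to state 1
      if (cur == 1L && t_disc <= 6) add(t_disc, 4L)
      if (cur == 2L && t_disc > 6) add(t_disc, 5L)
    }
    if (!lr_done && !is.na(t_lr) && (dm_done || is.na(t_dm) || t_lr <= t_dm))
      add(t_lr, 6L)
    if (!dm_done && !is.na(t_dm) && (lr_done || is.na(t_lr) || t_dm < t_lr))
      add(t_dm, 7L)
    if (!is.na(death)) add(death, death_state)
    t_event <- if (length(cand_time)) min(cand_time) else Inf
    rule <- det[det$from == cur & det$time > t, , drop = FALSE]
    t_rule <- if (nrow(rule)) rule$time[1] else Inf
    if (is.infinite(t_event) && is.infinite(t_rule)) break
    if (t_event <= t_rule && t_event <= end_time) {
      # ties at the rule time are attributed to the pre-jump state
      to <- cand_to[which.min(cand_time)]
      if (to == 4L || to == 5L) disc_done <- TRUE
      if (to == 6L) lr_done <- TRUE
      if (to == 7L) dm_done <- TRUE
      move(to, t_event)
    } else if (t_rule < t_event && t_rule <= end_time) {
      move(rule$to[1], t_rule)
    } else break
  }
  if (!is.na(death) && !space$states$absorbing[cur])
    stop(sprintf("death has no corresponding arrow out of state %d", cur))
  structure(list(path = data.frame(state = path_state, entry = path_entry),
                 end_time = end_time, censored = is.na(death)),
            class = "state_path")
}

#' Stack a cohort into long-format transition data
#'
#' For every at-risk episode of every subject, emits one row per allowed
#' stochastic transition out of the occupied state, with entry/exit times on
#' the study clock and an event indicator that is 1 only on the realized
#' transition. Deterministic rules end episodes (all rows censored at the rule
#' time) but contribute no estimable rows of their own. Zero-length episodes
#' (two events at the same instant) are dropped.
#'
#' @param cohort data frame, one row per patient (patient-record schema).
#' @param space a `state_space`.
#' @param specs covariate specifications; see [fogt2_covariates()].
#' @return data frame of class `msm_long` with columns `subject_id`, `trans`,
#'   `from`, `to`, `tstart`, `tstop`, `status` and one column per encoded
#'   covariate term; attributes `space` and `specs`.
#' @export
to_long_format <- function(cohort, space = fogt2_space(),
                           specs = fogt2_covariates()) {
  stopifnot(nrow(cohort) >= 1)
  Z <- encode_covariates(cohort, specs)
  tr <- space$transitions
  out_by_state <- lapply(seq_len(nrow(space$states)),
                         function(s) which(tr$from == s))
  acc_i <- list(); acc_q <- list(); acc_t0 <- list(); acc_t1 <- list()
  acc_st <- list(); k <- 0
  for (i in seq_len(nrow(cohort))) {
    sp <- derive_state_path(cohort[i, ], space)
    p <- sp$path
    ends <- c(p$entry[-1], sp$end_time)
    for (j in seq_len(nrow(p))) {
      st <- p$state[j]
      if (space$states$absorbing[st]) break
      out <- out_by_state[[st]]
      if (!length(out)) next
      t0 <- p$entry[j]; t1 <- ends[j]
      if (t1 <= t0) next  # zero-length episode: no risk time
      realized <- if (j < nrow(p)) p$state[j + 1] else NA_integer_
      k <- k + 1
      acc_i[[k]] <- rep.int(i, length(out))
      acc_q[[k]] <- out
      acc_t0[[k]] <- rep.int(t0, length(out))
      acc_t1[[k]] <- rep.int(t1, length(out))
      acc_st[[k]] <- as.integer(!is.na(realized) & tr$to[out] == realized)
    }
  }
  idx <- unlist(acc_i); q <- unlist(acc_q)
  long <- data.frame(
    subject_id = cohort$subject_id[idx],
    trans = tr$trans[q], from = tr$from[q], to = tr$to[q],
    tstart = unlist(acc_t0), tstop = unlist(acc_t1),
    status = unlist(acc_st)
  )
  long <- cbind(long, Z[idx, , drop = FALSE])
  rownames(long) <- NULL
  structure(long, space = space, specs = specs,
            class = c("msm_long", "data.frame"))
}

#' Percentage formatting used in cohort summaries
#'
#' @param count,denom counts.
#' @param digits decimal places (1 by default, 0 where integer percentages are
#'   reported).
#' @return `100 * count / denom` rounded to `digits`.
#' @examples
#' fmt_pct(215, 471)      # 45.6
#' fmt_pct(157, 215, 0)   # 73
#' @export
fmt_pct <- function(count, denom, digits = 1) {
  if (any(denom <= 0)) stop("denominator must be positive")
  round(100 * count / denom, digits)
}

#' Summarize a cohort: covariate marginals, event flow, final occupancy
#'
#' @param cohort patient-record data frame.
#' @param space a `state_space`.
#' @param specs covariate specifications (categorical marginals are tabulated).
#' @return list with `n`, `covariates` (variable, level, n, pct), `events`
#'   (recurrence composition with percentages), `occupancy` (final state at
#'   end of follow-up) and `transition_counts` (realized count per arrow,
#'   deterministic rules included).
#' @export
cohort_summary <- function(cohort, space = fogt2_space(),
                           specs = fogt2_covariates()) {
  n <- nrow(cohort)
  if (!n) stop("empty cohort")
  cov_tab <- do.call(rbind, lapply(specs, function(sp) {
    if (sp$kind != "categorical") return(NULL)
    cnt <- vapply(sp$levels, function(l) sum(cohort[[sp$name]] == l), 0L)
    data.frame(variable = sp$name, level = sp$levels, n = as.integer(cnt),
               pct = fmt_pct(cnt, n), row.names = NULL)
  }))
  paths <- lapply(seq_len(n), function(i) derive_state_path(cohort[i, ], space))
  finals <- vapply(paths, function(p) p$path$state[nrow(p$path)], 0L)
  occupancy <- data.frame(state = space$states$id,
                          label = space$states$label,
                          n = vapply(space$states$id,
                                     function(s) sum(finals == s), 0L))
  arrows <- rbind(space$transitions[, c("from", "to")],
                  space$deterministic[, c("from", "to")])
  counts <- vapply(seq_len(nrow(arrows)), function(k) {
    sum(vapply(paths, function(p) {
      s <- p$path$state
      any(s[-length(s)] == arrows$from[k] & s[-1] == arrows$to[k])
    }, FALSE))
  }, 0L)
  transition_counts <- cbind(arrows, n = counts)
  visited <- function(st) vapply(paths, function(p) st %in% p$path$state, FALSE)
  lr_any <- visited(6L); dm_any <- visited(7L)
  both_flag <- if ("both_lr_dm" %in% names(cohort))
    cohort$both_lr_dm %in% TRUE else rep(FALSE, n)
  rec_n <- sum(lr_any | dm_any)
  events <- data.frame(
    what = c("any recurrence", "DM only", "LR only", "both LR and DM",
             "censored", "died"),
    n = c(rec_n,
          sum(dm_any & !lr_any & !both_flag),
          sum(lr_any & !dm_any),
          sum((lr_any & dm_any) | both_flag),
          sum(vapply(paths, `[[`, TRUE, "censored")),
          sum(finals == 8L)),
    denom = c(n, rec_n, rec_n, rec_n, n, n)
  )
  events$pct <- fmt_pct(events$n, pmax(events$denom, 1L))
  list(n = n, covariates = cov_tab, events = events, occupancy = occupancy,
       transition_counts = transition_counts)
}
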