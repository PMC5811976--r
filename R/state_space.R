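#' Define a multi-state model structure
#'
#' A `state_space` couples a set of numbered states with two kinds of
#' transitions: *stochastic* transitions, driven by hazards and numbered
#' consecutively, and *deterministic rules*, which fire at a fixed time on the
#' study clock (e.g. a treatment-schedule state entered by every subject still
#' on treatment at 6 months). Deterministic rules are not hazard-driven and are
#' never assigned a transition number.
#'
#' @param states data frame with columns `id` (integer, 1..K), `label`
#'   (character) and `absorbing` (logical).
#' @param transitions data frame with columns `from` and `to` (state ids);
#'   stochastic arrows. Transition numbers 1..Q are assigned in row order.
#' @param deterministic data frame with columns `time` (months, > 0), `from`
#'   and `to`, or `NULL` for none.
#'
#' @return An object of class `state_space` with elements `states`,
#'   `transitions` (with a `trans` id column) and `deterministic` (sorted by
#'   time).
#'
#' @details Validation enforces: absorbing states have no outgoing arrows of
#'   either kind; no self-transitions; `(from, to)` pairs are unique across
#'   stochastic and deterministic arrows together; each state is the source of
#'   at most one deterministic rule; rule times are positive.
#'
#' @examples
#' # a 3-state illness-death model
#' sp <- state_space(
#'   states = data.frame(id = 1:3, label = c("healthy", "ill", "dead"),
#'                       absorbing = c(FALSE, FALSE, TRUE)),
#'   transitions = data.frame(from = c(1, 1, 2), to = c(2, 3, 3))
#' )
#' n_transitions(sp)
#' @export
state_space <- function(states, transitions, deterministic = NULL) {
  states <- as.data.frame(states)
  transitions <- as.data.frame(transitions)
  stopifnot(all(c("id", "label", "absorbing") %in% names(states)),
            all(c("from", "to") %in% names(transitions)))
  states$id <- as.integer(states$id)
  states <- states[order(states$id), c("id", "label", "absorbing")]
  transitions <- data.frame(trans = seq_len(nrow(transitions)),
                            from = as.integer(transitions$from),
                            to = as.integer(transitions$to))
  if (is.null(deterministic)) {
    deterministic <- data.frame(time = numeric(0), from = integer(0),
                                to = integer(0))
  } else {
    deterministic <- as.data.frame(deterministic)
    stopifnot(all(c("time", "from", "to") %in% names(deterministic)))
    deterministic <- data.frame(time = as.numeric(deterministic$time),
                                from = as.integer(deterministic$from),
                                to = as.integer(deterministic$to))
    deterministic <- deterministic[order(deterministic$time), ]
    rownames(deterministic) <- NULL
  }
  obj <- structure(list(states = states, transitions = transitions,
                        deterministic = deterministic),
                   class = "state_space")
  validate_state_space(obj)
  obj
}

#' Validate a state_space object
#'
#' Checks all structural invariants; called by [state_space()] and after any
#' programmatic modification.
#'
#' @param space a `state_space`.
#' @return `space`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_state_space <- function(space) {
  st <- space$states; tr <- space$transitions; dt <- space$deterministic
  ids <- st$id
  if (anyDuplicated(ids) || !identical(ids, seq_len(nrow(st))))
    stop("state ids must be the integers 1..K without gaps")
  all_arrows <- rbind(tr[, c("from", "to")], dt[, c("from", "to")])
  if (nrow(all_arrows)) {
    if (!all(all_arrows$from %in% ids) || !all(all_arrows$to %in% ids))
      stop("transition endpoints must be declared states")
    if (any(all_arrows$from == all_arrows$to))
      stop("self-transitions are not allowed")
    if (anyDuplicated(all_arrows))
      stop("duplicate (from, to) pair across transitions and deterministic rules")
  }
  absorbing <- st$id[st$absorbing]
  if (any(all_arrows$from %in% absorbing))
    stop("absorbing state has an outgoing transition")
  if (!identical(tr$trans, seq_len(nrow(tr))))
    stop("transition ids must be contiguous starting at 1")
  if (nrow(dt)) {
    if (any(dt$time <= 0)) stop("deterministic rule time must be > 0")
    if (is.unsorted(dt$time)) stop("deterministic rules must be sorted by time")
    if (anyDuplicated(dt$from))
      stop("each state may be the source of at most one deterministic rule")
  }
  invisible(space)
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("state_space: %d states, %d stochastic transitions, %d deterministic rules\n",
              nrow(x$states), nrow(x$transitions), nrow(x$deterministic)))
  cat("states:\n"); print(x$states, row.names = FALSE)
  cat("transitions:\n"); print(x$transitions, row.names = FALSE)
  if (nrow(x$deterministic)) {
    cat("deterministic rules:\n"); print(x$deterministic, row.names = FALSE)
  }
  invisible(x)
}

#' Number of stochastic transitions
#' @param space a `state_space`.
#' @return integer Q.
#' @export
n_transitions <- function(space) nrow(space$transitions)

#' Look up a stochastic transition id by its endpoints
#' @param space a `state_space`.
#' @param from,to state ids.
#' @return transition id, or `NA` if no such stochastic arrow exists.
#' @export
transition_id <- function(space, from, to) {
  hit <- space$transitions$trans[space$transitions$from == from &
                                 space$transitions$to == to]
  if (length(hit)) hit else NA_integer_
}

#' The 8-state adjuvant-chemotherapy model for locally advanced rectal cancer
#'
#' Preset state space for the course of disease after start of adjuvant
#' chemotherapy (CTx): state 1 = on CTx < 6 months (start), 2 = on CTx 6-12
#' months, 3 = CTx completed (12 months), 4 = early discontinuation (< 6
#' months), 5 = late discontinuation (6-12 months), 6 = local recurrence (LR)
#' only, 7 = distant metastasis (DM) only or both DM and LR, 8 = death
#' (absorbing). Transitions 1 -> 2 (at 6.0 months) and 2 -> 3 (at 12.0 months)
#' are deterministic: every subject still in the source state makes the jump
#' at that moment. All times are in months; 6 weeks = 1.5 months.
#'
#' The default stochastic arrow set is 1 -> \{4,6,7,8\}, 2 -> \{5,6,7,8\},
#' 3 -> \{6,7,8\}, 4 -> \{6,7,8\}, 5 -> \{6,7,8\}, 6 -> \{7,8\}, 7 -> \{8\}
#' (Q = 20). Early deaths on treatment are routed 1 -> 8 before 6 months and
#' 2 -> 8 between 6 and 12 months. The arrow set is overridable for
#' sensitivity analyses.
#'
#' @param transitions optional data frame (`from`, `to`) replacing the default
#'   stochastic arrow set.
#' @return a `state_space`.
#' @examples
#' sp <- fogt2_space()
#' n_transitions(sp)  # 20
#' @export
fogt2_space <- function(transitions = NULL) {
  states <- data.frame(
    id = 1:8,
    label = c("CTx < 6m", "CTx 6-12m", "CTx completed",
              "early discontinuation", "late discontinuation",
              "LR only", "DM or DM+LR", "death"),
    absorbing = c(rep(FALSE, 7), TRUE)
  )
  if (is.null(transitions)) {
    transitions <- data.frame(
      from = c(1, 1, 1, 1,  2, 2, 2, 2,  3, 3, 3,  4, 4, 4,  5, 5, 5,  6, 6,  7),
      to   = c(4, 6, 7, 8,  5, 6, 7, 8,  6, 7, 8,  6, 7, 8,  6, 7, 8,  7, 8,  8)
    )
  }
  deterministic <- data.frame(time = c(6, 12), from = c(1, 2), to = c(2, 3))
  state_space(states, transitions, deterministic)
}

#' Write a state space to a JSON document
#'
#' The document has three arrays: `states` (id, label, absorbing),
#' `transitions` (from, to) and `deterministic` (time_months, from, to).
#' [read_state_space()] restores an identical object.
#'
#' @param space a `state_space`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_state_space <- function(space, path) {
  doc <- list(
    states = space$states,
    transitions = space$transitions[, c("from", "to")],
    deterministic = data.frame(time_months = space$deterministic$time,
                               from = space$deterministic$from,
                               to = space$deterministic$to)
  )
  jsonlite::write_json(doc, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a state space from a JSON document
#' @param path file path written by [write_state_space()] or hand-authored in
#'   the same schema.
#' @return a validated `state_space`.
#' @export
read_state_space <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  det <- NULL
  if (!is.null(doc$deterministic) && NROW(doc$deterministic))
    det <- data.frame(time = doc$deterministic$time_months,
                      from = doc$deterministic$from,
                      to = doc$deterministic$to)
  state_space(doc$states, doc$transitions, det)
}

#' States reachable from a given state
#'
#' Follows both stochastic and deterministic arrows.
#' @param space a `state_space`.
#' @param from state id.
#' @return sorted integer vector of reachable state ids (excluding `from`
#'   unless it lies on a cycle).
#' @export
reachable_states <- function(space, from) {
  arrows <- rbind(space$transitions[, c("from", "to")],
                  space$deterministic[, c("from", "to")])
  seen <- integer(0)
  frontier <- from
  while (length(frontier)) {
    nxt <- unique(arrows$to[arrows$from %in% frontier])
    frontier <- setdiff(nxt, seen)
    seen <- union(seen, nxt)
  }
  sort(seen)
}
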