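#' Arm specification
#'
#' Describes one arm of a platform cohort: its role, true response rate (for
#' simulation), planned sample size and calendar opening time. Each cohort has
#' exactly one control arm; experimental arms default to 30 planned patients
#' and may open at staggered times (the protocol spaces new arms 6 months
#' apart).
#'
#' @param arm_id Character identifier, unique within a scenario.
#' @param role `"control"` or `"experimental"`.
#' @param true_rate True binary-endpoint rate in `[0, 1]` used when
#'   simulating.
#' @param planned_n Planned number of patients (experimental arms analyze
#'   after treating this many). The control arm accrues indefinitely while any
#'   experimental arm is open, so `planned_n` is ignored for it.
#' @param open_time Calendar time in months at which the arm opens to accrual.
#' @return An object of class `arm_spec`.
#' @export
arm_spec <- function(arm_id, role = c("experimental", "control"), true_rate,
                     planned_n = 30, open_time = 0) {
  role <- match.arg(role)
  stopifnot(is.character(arm_id), length(arm_id) == 1L, nzchar(arm_id),
            is.numeric(true_rate), length(true_rate) == 1L,
            true_rate >= 0, true_rate <= 1,
            is.numeric(planned_n), length(planned_n) == 1L,
            planned_n >= 0, planned_n == round(planned_n),
            is.numeric(open_time), length(open_time) == 1L, open_time >= 0)
  structure(list(arm_id = arm_id, role = role,
                 true_rate = as.numeric(true_rate),
                 planned_n = as.integer(planned_n),
                 open_time = as.numeric(open_time)),
            class = "arm_spec")
}

#' Allocation state of the randomization scheme
#'
#' Snapshot of the quantities that determine the current allocation
#' probabilities: how many patients the control arm has treated, the control
#' cap, and which experimental arms are actively accruing.
#'
#' @param active_arm_ids Character vector of experimental arms currently open
#'   to accrual and below their planned sample size.
#' @param control_treated Number of patients treated on the control arm so
#'   far.
#' @param control_cap Control-arm size at which allocation switches from equal
#'   randomization to the rescaled `1/(1 + 3m)` scheme; default 30.
#' @return An object of class `allocation_state`.
#' @export
allocation_state <- function(active_arm_ids, control_treated,
                             control_cap = 30) {
  stopifnot(is.character(active_arm_ids), !anyDuplicated(active_arm_ids),
            is.numeric(control_treated), length(control_treated) == 1L,
            control_treated >= 0,
            is.numeric(control_cap), length(control_cap) == 1L,
            control_cap > 0)
  structure(list(active_arm_ids = active_arm_ids,
                 m = length(active_arm_ids),
                 control_treated = as.integer(control_treated),
                 control_cap = control_cap),
            class = "allocation_state")
}

#' Allocation probabilities over control and open experimental arms
#'
#' Before the control arm reaches its cap, all open arms (control included)
#' are randomized equally, each with probability `1/(m + 1)` where `m` is the
#' number of active experimental arms. Once the control arm has treated its
#' cap, the control probability is rescaled to `1/(1 + 3m)` and each
#' experimental arm receives `3/(1 + 3m)`: with 2 open experimental arms the
#' control probability drops to 1/7, with 3 arms to 1/10.
#'
#' @param state An [allocation_state()].
#' @return A named probability vector: first element `"control"`, then one
#'   element per active experimental arm; sums to 1.
#' @examples
#' st <- allocation_state(c("A", "B"), control_treated = 30)
#' allocation_probabilities(st) # control 1/7, each experimental 3/7
#' @export
allocation_probabilities <- function(state) {
  stopifnot(inherits(state, "allocation_state"))
  m <- state$m
  if (m == 0L)
    stop("no open experimental arm: the platform cannot randomize",
         call. = FALSE)
  p <- if (state$control_treated < state$control_cap)
    rep(1 / (m + 1), m + 1)
  else
    c(1, rep(3, m)) / (1 + 3 * m)
  names(p) <- c("control", state$active_arm_ids)
  p
}

#' Randomize one patient
#'
#' Samples an arm from the current allocation probabilities using R's global
#' random number stream, so assignment sequences are reproducible under
#' `set.seed()`.
#'
#' @param state An [allocation_state()].
#' @return The assigned arm id (`"control"` or an experimental arm id).
#' @export
assign_patient <- function(state) {
  p <- allocation_probabilities(state)
  names(p)[sample.int(length(p), 1L, prob = p)]
}

#' Arm opening timeline
#'
#' Orders the arm-opening events of a scenario by calendar time. Closing to
#' accrual happens when an arm reaches its planned sample size, which depends
#' on the realized randomization sequence and is therefore reported by
#' [simulate_trial()]; the only closings known in advance are degenerate arms
#' with `planned_n = 0`, which close the moment they open.
#'
#' @param arms A list of [arm_spec()] objects.
#' @return A data frame with columns `time`, `arm_id`, `event`
#'   (`"open"`/`"close"`), ordered by time.
#' @export
open_close_schedule <- function(arms) {
  stopifnot(is.list(arms), length(arms) >= 1L,
            all(vapply(arms, inherits, logical(1), "arm_spec")))
  ids <- vapply(arms, `[[`, character(1), "arm_id")
  if (anyDuplicated(ids))
    stop("duplicate arm_id: ", ids[duplicated(ids)][1L], call. = FALSE)
  ev <- data.frame(
    time = vapply(arms, `[[`, numeric(1), "open_time"),
    arm_id = ids,
    event = "open",
    stringsAsFactors = FALSE
  )
  degenerate <- vapply(arms, function(a)
    a$role == "experimental" && a$planned_n == 0L, logical(1))
  if (any(degenerate))
    ev <- rbind(ev, data.frame(time = ev$time[degenerate],
                               arm_id = ids[degenerate], event = "close",
                               stringsAsFactors = FALSE))
  ev <- ev[order(ev$time, match(ev$event, c("open", "close"))), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}
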