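#' Accrual model
#'
#' Patient arrival process for the platform simulation. `"poisson"` draws
#' exponential interarrival times at the given rate; `"fixed"` spaces arrivals
#' deterministically at `1/rate` months.
#'
#' @param kind `"poisson"` or `"fixed"`.
#' @param rate Accrual rate in patients per month; default 5.
#' @return An object of class `accrual_model`.
#' @export
accrual_model <- function(kind = c("poisson", "fixed"), rate = 5) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(rate), length(rate) == 1L, rate > 0)
  structure(list(kind = kind, rate = as.numeric(rate)),
            class = "accrual_model")
}

#' Platform trial scenario
#'
#' Complete specification of one simulated cohort: the arms (one control plus
#' staggered experimental arms), the binary endpoint, the superiority decision
#' rule, the beta priors, the accrual model, the control cap and the
#' control-comparison convention.
#'
#' @param arms List of [arm_spec()] objects containing exactly one control
#'   arm; experimental `open_time`s must be strictly increasing.
#' @param endpoint `"MPR"` (major pathological response at 12 weeks) or
#'   `"DCR"` (6-month disease control rate); informational label.
#' @param rule A [decision_rule()] with the margin and threshold.
#' @param prior_e,prior_c Efficacy priors; default non-informative
#'   `beta_prior(1, 1)` for both.
#' @param accrual An [accrual_model()]; default Poisson at 5 patients/month.
#' @param control_cap Control size at which allocation rescales; default 30.
#' @param comparison Which control patients enter each arm's posterior
#'   analysis: `"final"` (all control patients treated over the whole trial,
#'   the default), `"at-completion"` (controls accrued by the time the arm
#'   finished enrollment) or `"concurrent"` (controls enrolled while the arm
#'   was open).
#' @return An object of class `trial_scenario`.
#' @seealso [mpr_scenario()], [dcr_scenario()] for the protocol's two
#'   reference scenarios.
#' @export
trial_scenario <- function(arms, endpoint = c("MPR", "DCR"), rule,
                           prior_e = beta_prior(1, 1),
                           prior_c = beta_prior(1, 1),
                           accrual = accrual_model("poisson", 5),
                           control_cap = 30,
                           comparison = c("final", "at-completion",
                                          "concurrent")) {
  endpoint <- match.arg(endpoint)
  comparison <- match.arg(comparison)
  stopifnot(is.list(arms),
            all(vapply(arms, inherits, logical(1), "arm_spec")),
            inherits(rule, "decision_rule"),
            inherits(prior_e, "beta_prior"), inherits(prior_c, "beta_prior"),
            inherits(accrual, "accrual_model"),
            is.numeric(control_cap), length(control_cap) == 1L,
            control_cap > 0)
  roles <- vapply(arms, `[[`, character(1), "role")
  if (sum(roles == "control") != 1L)
    stop("scenario must contain exactly one control arm", call. = FALSE)
  ids <- vapply(arms, `[[`, character(1), "arm_id")
  if (anyDuplicated(ids))
    stop("duplicate arm_id: ", ids[duplicated(ids)][1L], call. = FALSE)
  exp_times <- vapply(arms[roles == "experimental"], `[[`, numeric(1),
                      "open_time")
  if (length(exp_times) > 1L && any(diff(exp_times) <= 0))
    stop("experimental open_times must be strictly increasing", call. = FALSE)
  structure(list(arms = arms, endpoint = endpoint, rule = rule,
                 prior_e = prior_e, prior_c = prior_c, accrual = accrual,
                 control_cap = control_cap, comparison = comparison),
            class = "trial_scenario")
}

#' @export
print.trial_scenario <- function(x, ...) {
  cat(sprintf("Platform scenario, endpoint %s (delta %.2f, theta_t %.2f, %s controls)\n",
              x$endpoint, x$rule$delta, x$rule$theta_t, x$comparison))
  for (a in x$arms)
    cat(sprintf("  %-12s %-12s rate %.3f, n %s, opens month %g\n",
                a$arm_id, a$role, a$true_rate,
                if (a$role == "control") "open-ended" else a$planned_n,
                a$open_time))
  invisible(x)
}

#' Reference MPR scenario
#'
#' The resectable/borderline-resectable cohort design: control major
#' pathological response rate 0.13 with four experimental arms at true rates
#' 0.195, 0.26, 0.13 and 0.30 opening at months 0, 6, 12 and 18, threshold
#' 0.67.
#'
#' @param true_rates Experimental true rates; override for null scenarios.
#' @param theta_t Posterior threshold; default 0.67.
#' @param ... Passed on to [trial_scenario()] (e.g. `accrual`, `comparison`).
#' @return A [trial_scenario()].
#' @export
mpr_scenario <- function(true_rates = c(0.195, 0.26, 0.13, 0.30),
                         theta_t = 0.67, ...) {
  .reference_scenario("MPR", 0.13, true_rates, theta_t, ...)
}

#' Reference DCR scenario
#'
#' The locally advanced cohort design: control 6-month disease control rate
#' 0.70 with four experimental arms at true rates 0.70, 0.80, 0.90 and 0.95
#' opening at months 0, 6, 12 and 18, threshold 0.72.
#'
#' @inheritParams mpr_scenario
#' @return A [trial_scenario()].
#' @export
dcr_scenario <- function(true_rates = c(0.70, 0.80, 0.90, 0.95),
                         theta_t = 0.72, ...) {
  .reference_scenario("DCR", 0.70, true_rates, theta_t, ...)
}

.reference_scenario <- function(endpoint, control_rate, true_rates, theta_t,
                                ...) {
  stopifnot(length(true_rates) >= 1L)
  open_times <- seq(0, by = 6, length.out = length(true_rates))
  arms <- c(list(arm_spec("control", "control", control_rate)),
            lapply(seq_along(true_rates), function(i)
              arm_spec(paste0("arm", i), "experimental", true_rates[i],
                       planned_n = 30, open_time = open_times[i])))
  trial_scenario(arms, endpoint = endpoint,
                 rule = decision_rule(0.05, theta_t), ...)
}

#' Null version of a scenario
#'
#' Sets every experimental arm's true rate to the control rate, the
#' configuration under which the probability of claiming success is the
#' type-I error.
#'
#' @param scenario A [trial_scenario()].
#' @return The modified scenario.
#' @export
null_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "trial_scenario"))
  roles <- vapply(scenario$arms, `[[`, character(1), "role")
  pc <- scenario$arms[[which(roles == "control")]]$true_rate
  scenario$arms <- lapply(scenario$arms, function(a) {
    if (a$role == "experimental") a$true_rate <- pc
    a
  })
  scenario
}

# memoised posterior superiority probability over integer data
.pp_memo <- function(xe, ne, xc, nc, scenario, cache = NULL) {
  if (is.null(cache))
    return(prob_exceeds_margin(
      update_posterior(scenario$prior_e, xe, ne),
      update_posterior(scenario$prior_c, xc, nc),
      scenario$rule$delta))
  key <- paste(xe, ne, xc, nc, sep = ":")
  val <- cache[[key]]
  if (is.null(val)) {
    val <- prob_exceeds_margin(
      update_posterior(scenario$prior_e, xe, ne),
      update_posterior(scenario$prior_c, xc, nc),
      scenario$rule$delta)
    cache[[key]] <- val
  }
  val
}

#' Simulate one platform trial
#'
#' Discrete-event simulation of one cohort: patients arrive under the accrual
#' model, are randomized among the control arm and the open experimental arms
#' (equal allocation until the control cap, then `1/(1 + 3m)` to control),
#' and contribute an independent Bernoulli outcome at their arm's true rate.
#' Experimental arms open at their scheduled calendar times and close when
#' they reach their planned size; accrual pauses when no experimental arm is
#' open. When an arm completes enrollment it is compared to the control data
#' selected by the scenario's `comparison` convention via [decide()]. The
#' trial ends when the last experimental arm completes.
#'
#' @param scenario A [trial_scenario()].
#' @param seed Optional integer seed (`set.seed`) for reproducibility.
#' @return An object of class `trial_result`: a list with `arms` (a data
#'   frame of per-arm counts, posterior probabilities, success flags,
#'   analysis times and the control sample used), `n_control`,
#'   `x_control` and `duration` (months to last arm completion).
#' @export
simulate_trial <- function(scenario, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  .simulate_trial_impl(scenario, cache = NULL)
}

.simulate_trial_impl <- function(scenario, cache = NULL) {
  stopifnot(inherits(scenario, "trial_scenario"))
  roles <- vapply(scenario$arms, `[[`, character(1), "role")
  exp_arms <- scenario$arms[roles == "experimental"]
  if (!length(exp_arms))
    stop("scenario has no experimental arm to evaluate", call. = FALSE)
  control <- scenario$arms[[which(roles == "control")]]

  k <- length(exp_arms)
  ids <- vapply(exp_arms, `[[`, character(1), "arm_id")
  open <- vapply(exp_arms, `[[`, numeric(1), "open_time")
  nmax <- vapply(exp_arms, `[[`, integer(1), "planned_n")
  rate_e <- vapply(exp_arms, `[[`, numeric(1), "true_rate")

  ne <- integer(k); xe <- integer(k)
  completion <- rep(NA_real_, k)
  snap_xc <- integer(k); snap_nc <- integer(k)      # control data at completion
  ctrl_t <- numeric(0); ctrl_y <- integer(0)        # control arrival log
  arr_rate <- scenario$accrual$rate
  poisson <- scenario$accrual$kind == "poisson"
  t <- 0

  while (any(ne < nmax)) {
    open_idx <- which(open <= t & ne < nmax)
    if (!length(open_idx)) {               # accrual pauses until the next arm
      t <- min(open[ne < nmax & open > t])
      next
    }
    t <- t + if (poisson) stats::rexp(1L, arr_rate) else 1 / arr_rate
    open_idx <- which(open <= t & ne < nmax)
    if (!length(open_idx)) next
    m <- length(open_idx)
    nc <- length(ctrl_t)
    probs <- if (nc < scenario$control_cap) rep(1 / (m + 1), m + 1)
             else c(1, rep(3, m)) / (1 + 3 * m)
    pick <- sample.int(m + 1L, 1L, prob = probs)
    if (pick == 1L) {
      ctrl_t <- c(ctrl_t, t)
      ctrl_y <- c(ctrl_y, stats::rbinom(1L, 1L, control$true_rate))
    } else {
      a <- open_idx[pick - 1L]
      ne[a] <- ne[a] + 1L
      xe[a] <- xe[a] + stats::rbinom(1L, 1L, rate_e[a])
      if (ne[a] == nmax[a]) {
        completion[a] <- t
        snap_nc[a] <- length(ctrl_t)
        snap_xc[a] <- sum(ctrl_y)
      }
    }
  }

  pp <- rep(NA_real_, k); succ <- rep(NA, k)
  used_nc <- rep(NA_integer_, k); used_xc <- rep(NA_integer_, k)
  for (a in seq_len(k)) {
    if (nmax[a] == 0L) next                       # degenerate arm, no analysis
    sel <- switch(scenario$comparison,
      "final" = rep(TRUE, length(ctrl_t)),
      "at-completion" = NULL,                      # use the completion snapshot
      "concurrent" = ctrl_t >= open[a] & ctrl_t <= completion[a])
    if (is.null(sel)) {
      used_nc[a] <- snap_nc[a]; used_xc[a] <- snap_xc[a]
    } else {
      used_nc[a] <- sum(sel); used_xc[a] <- sum(ctrl_y[sel])
    }
    pp[a] <- .pp_memo(xe[a], nmax[a], used_xc[a], used_nc[a], scenario, cache)
    succ[a] <- pp[a] > scenario$rule$theta_t
  }

  structure(list(
    arms = data.frame(arm_id = ids, true_rate = rate_e, n_treated = ne,
                      n_success = xe, posterior_prob = pp, success = succ,
                      analysis_time = completion, n_control_used = used_nc,
                      x_control_used = used_xc, stringsAsFactors = FALSE),
    n_control = length(ctrl_t), x_control = sum(ctrl_y),
    duration = max(completion, na.rm = TRUE),
    comparison = scenario$comparison),
    class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("Simulated platform trial (%d control patients, %.1f months)\n",
              x$n_control, x$duration))
  print(x$arms, digits = 3)
  invisible(x)
}

#' Operating characteristics of a platform scenario
#'
#' Runs [simulate_trial()] over independent replicates (each replicate gets
#' its own substream seed drawn from the master seed) and aggregates per-arm
#' success proportions and mean sample sizes, the quantities tabulated as the
#' design's operating characteristics.
#'
#' @param scenario A [trial_scenario()].
#' @param reps Number of replicates; default 1000.
#' @param seed Master integer seed.
#' @return An object of class `oc_table`: a data frame with one row per arm
#'   (`arm_id`, `role`, `true_rate`, `start_time_months`, `mean_n`,
#'   `prob_success`) plus attributes `reps`, `seed` and
#'   `posterior_prob_matrix` (replicates x experimental arms, reused by
#'   [calibrate_threshold()]).
#' @export
operating_characteristics <- function(scenario, reps = 1000, seed = 1) {
  stopifnot(inherits(scenario, "trial_scenario"),
            is.numeric(reps), length(reps) == 1L, reps >= 1,
            reps == round(reps),
            is.numeric(seed), length(seed) == 1L)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, reps)
  cache <- new.env(parent = emptyenv())
  roles <- vapply(scenario$arms, `[[`, character(1), "role")
  k <- sum(roles == "experimental")
  PP <- matrix(NA_real_, nrow = reps, ncol = k)
  NE <- matrix(NA_real_, nrow = reps, ncol = k)
  NC <- numeric(reps)
  for (r in seq_len(reps)) {
    set.seed(rep_seeds[r])
    res <- .simulate_trial_impl(scenario, cache = cache)
    PP[r, ] <- res$arms$posterior_prob
    NE[r, ] <- res$arms$n_treated
    NC[r] <- res$n_control
  }
  exp_arms <- scenario$arms[roles == "experimental"]
  control <- scenario$arms[[which(roles == "control")]]
  tab <- data.frame(
    arm_id = c(control$arm_id, vapply(exp_arms, `[[`, character(1),
                                      "arm_id")),
    role = c("control", rep("experimental", k)),
    true_rate = c(control$true_rate,
                  vapply(exp_arms, `[[`, numeric(1), "true_rate")),
    start_time_months = c(control$open_time,
                          vapply(exp_arms, `[[`, numeric(1), "open_time")),
    mean_n = c(mean(NC), colMeans(NE)),
    prob_success = c(NA_real_,
                     colMeans(PP > scenario$rule$theta_t, na.rm = TRUE)),
    stringsAsFactors = FALSE
  )
  structure(tab, class = c("oc_table", "data.frame"),
            reps = reps, seed = seed, endpoint = scenario$endpoint,
            theta_t = scenario$rule$theta_t,
            posterior_prob_matrix = PP)
}

#' @export
print.oc_table <- function(x, ...) {
  cat(sprintf(
    "Operating characteristics (%s, theta_t %.2f, %d replicates, seed %d)\n",
    attr(x, "endpoint"), attr(x, "theta_t"), attr(x, "reps"),
    attr(x, "seed")))
  df <- as.data.frame(x)
  df$mean_n <- round(df$mean_n, 1)
  df$prob_success <- round(df$prob_success, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
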