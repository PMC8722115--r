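#' Bayesian toxicity monitoring rule
#'
#' Defines the continuous toxicity monitoring applied to an experimental arm:
#' with a `Beta(0.6, 1.4)` prior on the toxicity probability `pi_tox`, the arm
#' is terminated early if `Pr(pi_tox > unacceptable_rate | data) >
#' posterior_cutoff` at a monitoring look. Looks happen in cohorts (default
#' after 10, 20 and 30 patients).
#'
#' @param prior Toxicity prior, a [beta_prior()]; default `beta_prior(0.6,
#'   1.4)` (prior mean 0.3).
#' @param unacceptable_rate Toxicity rate considered unacceptable; default
#'   0.3.
#' @param posterior_cutoff Posterior probability cutoff; default 0.8.
#' @param cohort_size Patients between monitoring looks; default 10.
#' @param max_n Maximum arm size; default 30. Must be a multiple of
#'   `cohort_size`.
#' @return An object of class `tox_rule`.
#' @export
tox_rule <- function(prior = beta_prior(0.6, 1.4), unacceptable_rate = 0.3,
                     posterior_cutoff = 0.8, cohort_size = 10, max_n = 30) {
  stopifnot(inherits(prior, "beta_prior"),
            unacceptable_rate > 0, unacceptable_rate < 1,
            posterior_cutoff > 0, posterior_cutoff < 1,
            cohort_size >= 1, cohort_size == round(cohort_size),
            max_n >= cohort_size, max_n == round(max_n))
  if (max_n %% cohort_size != 0)
    stop("'max_n' must be a multiple of 'cohort_size'", call. = FALSE)
  structure(list(prior = prior, unacceptable_rate = unacceptable_rate,
                 posterior_cutoff = posterior_cutoff,
                 cohort_size = as.integer(cohort_size),
                 max_n = as.integer(max_n)),
            class = "tox_rule")
}

#' Toxicity stopping boundary at one look
#'
#' The smallest cumulative toxicity count `x` among `n` treated patients for
#' which the posterior `Beta(alpha + x, beta + n - x)` puts more than
#' `posterior_cutoff` probability above the unacceptable rate. Under the
#' default rule the boundaries are 5/10, 8/20 and 12/30.
#'
#' @param rule A [tox_rule()].
#' @param n Number of patients evaluated, `1 <= n <= max_n`.
#' @return Integer boundary, or `NA_integer_` when no count up to `n`
#'   triggers the rule.
#' @examples
#' tox_boundary(tox_rule(), 10) # 5
#' @export
tox_boundary <- function(rule, n) {
  stopifnot(inherits(rule, "tox_rule"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("'n' must be a single integer >= 1", call. = FALSE)
  for (x in 0:n) {
    post_tail <- stats::pbeta(rule$unacceptable_rate,
                              rule$prior$alpha + x,
                              rule$prior$beta + n - x,
                              lower.tail = FALSE)
    if (post_tail > rule$posterior_cutoff)
      return(as.integer(x))
  }
  NA_integer_
}

#' Full stopping-boundary schedule
#'
#' @param rule A [tox_rule()].
#' @return A data frame with one row per monitoring look: `n_evaluated` and
#'   `min_toxicities_to_stop` (`NA` if the look cannot stop).
#' @export
tox_boundary_schedule <- function(rule) {
  stopifnot(inherits(rule, "tox_rule"))
  looks <- seq(rule$cohort_size, rule$max_n, by = rule$cohort_size)
  data.frame(n_evaluated = looks,
             min_toxicities_to_stop = vapply(looks, tox_boundary,
                                             integer(1), rule = rule))
}

#' Exact operating characteristics of the toxicity rule
#'
#' Enumerates all binomial toxicity paths across the look schedule: the arm
#' continues past a look only while the cumulative toxicity count is below
#' that look's boundary. `early_stop_prob` is the probability of terminating
#' the arm before full enrollment, i.e. of crossing a boundary at a look
#' strictly before `max_n` (a boundary crossing at the final look flags the
#' arm but the full sample is already enrolled). `expected_n` sums the
#' patients added at each look weighted by the probability of reaching it.
#'
#' @param rule A [tox_rule()].
#' @param true_rate True toxicity probability in `[0, 1]`.
#' @return An object of class `tox_oc`: list with `true_rate`,
#'   `early_stop_prob` and `expected_n`.
#' @examples
#' tox_oc(tox_rule(), 0.4) # early stop ~0.623, expected n ~20.1
#' @export
tox_oc <- function(rule, true_rate) {
  stopifnot(inherits(rule, "tox_rule"),
            is.numeric(true_rate), length(true_rate) == 1L,
            true_rate >= 0, true_rate <= 1)
  sched <- tox_boundary_schedule(rule)
  looks <- sched$n_evaluated
  bounds <- sched$min_toxicities_to_stop
  # distribution of cumulative toxicities among trajectories still enrolling
  cum <- 0L; w <- 1; prev_n <- 0L
  expected_n <- 0; early_stop <- 0
  for (i in seq_along(looks)) {
    add <- looks[i] - prev_n
    expected_n <- expected_n + add * sum(w)
    grid <- outer(cum, 0:add, `+`)
    wts <- outer(w, stats::dbinom(0:add, add, true_rate), `*`)
    tab <- tapply(as.vector(wts), as.vector(grid), sum)
    keys <- as.integer(names(tab)); vals <- as.numeric(tab)
    crossed <- if (is.na(bounds[i])) rep(FALSE, length(keys))
               else keys >= bounds[i]
    if (looks[i] < rule$max_n)
      early_stop <- early_stop + sum(vals[crossed])
    cum <- keys[!crossed]; w <- vals[!crossed]
    prev_n <- looks[i]
    if (!length(cum)) break
  }
  structure(list(true_rate = true_rate,
                 early_stop_prob = early_stop,
                 expected_n = expected_n),
            class = "tox_oc")
}

#' @export
print.tox_oc <- function(x, ...) {
  cat(sprintf("true rate %.2f: early stop prob %.3f, expected n %.1f\n",
              x$true_rate, x$early_stop_prob, x$expected_n))
  invisible(x)
}

#' Toxicity operating-characteristics table
#'
#' @param rule A [tox_rule()].
#' @param true_rates Vector of true toxicity probabilities; defaults to the
#'   protocol's five tabulated rates 0.2-0.6.
#' @return A data frame with columns `true_rate`, `early_stop_prob`,
#'   `expected_n`.
#' @export
tox_oc_table <- function(rule = tox_rule(),
                         true_rates = seq(0.2, 0.6, by = 0.1)) {
  rows <- lapply(true_rates, tox_oc, rule = rule)
  data.frame(true_rate = vapply(rows, `[[`, numeric(1), "true_rate"),
             early_stop_prob = vapply(rows, `[[`, numeric(1),
                                      "early_stop_prob"),
             expected_n = vapply(rows, `[[`, numeric(1), "expected_n"))
}
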