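#' Beta prior / posterior distribution
#'
#' Constructs a beta distribution used as prior or posterior for a binomial
#' response probability. The non-informative `beta_prior(1, 1)` is the default
#' prior for both efficacy arms; `beta_prior(0.6, 1.4)` (prior mean 0.3) is the
#' default toxicity prior.
#'
#' @param alpha Positive shape parameter (pseudo-successes).
#' @param beta Positive shape parameter (pseudo-failures).
#' @return An object of class `beta_prior` with elements `alpha` and `beta`.
#' @examples
#' beta_prior(1, 1)
#' update_posterior(beta_prior(1, 1), successes = 6, n = 30)
#' @export
beta_prior <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), is.numeric(beta), length(alpha) == 1L,
            length(beta) == 1L, is.finite(alpha), is.finite(beta))
  if (alpha <= 0 || beta <= 0)
    stop("'alpha' and 'beta' must both be positive", call. = FALSE)
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta)),
            class = "beta_prior")
}

#' @export
print.beta_prior <- function(x, ...) {
  cat(sprintf("Beta(%g, %g)  [mean %.3f]\n", x$alpha, x$beta,
              x$alpha / (x$alpha + x$beta)))
  invisible(x)
}

#' Conjugate beta-binomial update
#'
#' Updates a beta prior with binomial data: `successes` responders out of `n`
#' evaluable patients yield `Beta(alpha + successes, beta + n - successes)`.
#'
#' @param prior A [beta_prior()].
#' @param successes Non-negative integer count of successes.
#' @param n Non-negative integer number of trials; `successes <= n`.
#' @return The posterior as a [beta_prior()] object.
#' @examples
#' update_posterior(beta_prior(0.6, 1.4), 5, 10) # Beta(5.6, 6.4)
#' @export
update_posterior <- function(prior, successes, n) {
  stopifnot(inherits(prior, "beta_prior"))
  .check_count(successes, "successes")
  .check_count(n, "n")
  if (successes > n)
    stop("'successes' must not exceed 'n'", call. = FALSE)
  beta_prior(prior$alpha + successes, prior$beta + n - successes)
}

.check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 ||
      x != round(x))
    stop(sprintf("'%s' must be a single non-negative integer", name),
         call. = FALSE)
  invisible(x)
}

#' Posterior probability that one rate exceeds another by a margin
#'
#' Computes `Pr(pi_e > pi_c + delta)` for independent beta posteriors `post_e`
#' and `post_c` by one-dimensional adaptive quadrature of the control density
#' against the experimental survival function,
#' `integral over [0, 1 - delta] of f_c(x) * S_e(x + delta) dx`.
#' This is the success statistic of the platform design: an experimental arm
#' is claimed successful when this probability exceeds the calibrated
#' threshold.
#'
#' @param post_e Experimental-arm posterior, a [beta_prior()].
#' @param post_c Control-arm posterior, a [beta_prior()].
#' @param delta Superiority margin in `[0, 1)`; default 0.05.
#' @return A single probability, accurate to about 1e-8.
#' @examples
#' # two uniform posteriors: closed form (1 - delta)^2 / 2
#' prob_exceeds_margin(beta_prior(1, 1), beta_prior(1, 1), 0.05) # 0.45125
#' @export
prob_exceeds_margin <- function(post_e, post_c, delta = 0.05) {
  stopifnot(inherits(post_e, "beta_prior"), inherits(post_c, "beta_prior"))
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) ||
      delta < 0)
    stop("'delta' must be a single number in [0, 1)", call. = FALSE)
  if (delta >= 1)
    stop("'delta' >= 1: the superiority probability is identically 0; ",
         "this is almost certainly a caller error", call. = FALSE)
  integrand <- function(x)
    stats::dbeta(x, post_c$alpha, post_c$beta) *
      stats::pbeta(x + delta, post_e$alpha, post_e$beta, lower.tail = FALSE)
  val <- stats::integrate(integrand, lower = 0, upper = 1 - delta,
                          abs.tol = 1e-9, rel.tol = 1e-9,
                          subdivisions = 500L, stop.on.error = FALSE)$value
  min(max(val, 0), 1)
}

#' Superiority decision rule
#'
#' Bundles the superiority margin `delta` and the posterior threshold
#' `theta_t` against which the posterior probability of superiority is
#' compared. The protocol's calibrated thresholds are 0.67 for the major
#' pathological response (MPR) endpoint and 0.72 for the 6-month disease
#' control rate (DCR) endpoint.
#'
#' @param delta Superiority margin in `[0, 1)`; default 0.05.
#' @param theta_t Posterior threshold in `(0, 1)`.
#' @return An object of class `decision_rule`.
#' @export
decision_rule <- function(delta = 0.05, theta_t) {
  stopifnot(is.numeric(delta), length(delta) == 1L, delta >= 0, delta < 1,
            is.numeric(theta_t), length(theta_t) == 1L,
            theta_t > 0, theta_t < 1)
  structure(list(delta = as.numeric(delta), theta_t = as.numeric(theta_t)),
            class = "decision_rule")
}

#' Apply the posterior superiority decision rule
#'
#' Computes the posterior probability `Pr(pi_e > pi_c + delta | data)` and
#' declares success when it strictly exceeds the threshold `theta_t`.
#'
#' @param post_e,post_c Experimental and control posteriors
#'   ([beta_prior()] objects).
#' @param rule A [decision_rule()].
#' @return An object of class `posterior_decision`: a list with
#'   `posterior_prob` and logical `success`.
#' @examples
#' post_e <- update_posterior(beta_prior(1, 1), 12, 30)
#' post_c <- update_posterior(beta_prior(1, 1), 4, 30)
#' decide(post_e, post_c, decision_rule(0.05, 0.67))
#' @export
decide <- function(post_e, post_c, rule) {
  stopifnot(inherits(rule, "decision_rule"))
  pp <- prob_exceeds_margin(post_e, post_c, rule$delta)
  structure(list(posterior_prob = pp, success = pp > rule$theta_t,
                 theta_t = rule$theta_t),
            class = "posterior_decision")
}

#' @export
print.posterior_decision <- function(x, ...) {
  cat(sprintf("Pr(pi_e > pi_c + delta | data) = %.4f  (threshold %.2f): %s\n",
              x$posterior_prob, x$theta_t,
              if (x$success) "SUCCESS" else "no success"))
  invisible(x)
}
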