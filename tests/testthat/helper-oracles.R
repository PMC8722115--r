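# Independent oracles used across the suite.

# Monte-Carlo estimate of Pr(pi_e > pi_c + delta) from paired beta draws;
# independent of the quadrature path in prob_exceeds_margin().
mc_prob_exceeds <- function(post_e, post_c, delta, draws = 1e6) {
  e <- rbeta(draws, post_e$alpha, post_e$beta)
  c_ <- rbeta(draws, post_c$alpha, post_c$beta)
  mean(e > c_ + delta)
}

# Probability of claiming success for fixed arm sizes, by full binomial
# enumeration of both arms' outcome grids.
enum_claim_prob <- function(pe, pc, ne, nc, delta, theta_t,
                            prior_e = beta_prior(1, 1),
                            prior_c = beta_prior(1, 1)) {
  pp <- outer(0:ne, 0:nc, Vectorize(function(xe, xc)
    prob_exceeds_margin(update_posterior(prior_e, xe, ne),
                        update_posterior(prior_c, xc, nc), delta)))
  w <- outer(dbinom(0:ne, ne, pe), dbinom(0:nc, nc, pc))
  sum(w * (pp > theta_t))
}

# Monte-Carlo operating characteristics of a toxicity rule with cohort looks;
# independent of the exact path-enumeration in tox_oc().
mc_tox_oc <- function(rule, true_rate, reps = 1e5) {
  looks <- seq(rule$cohort_size, rule$max_n, by = rule$cohort_size)
  bounds <- vapply(looks, tox_boundary, integer(1), rule = rule)
  tox <- matrix(rbinom(reps * rule$max_n, 1L, true_rate), nrow = reps)
  cum <- t(apply(tox, 1L, cumsum))[, looks, drop = FALSE]
  going <- rep(TRUE, reps)
  early <- rep(FALSE, reps)
  n_used <- rep(0L, reps)
  prev <- 0L
  for (i in seq_along(looks)) {
    n_used[going] <- n_used[going] + (looks[i] - prev)
    crossed <- going & !is.na(bounds[i]) & cum[, i] >= bounds[i]
    if (looks[i] < rule$max_n) early <- early | crossed
    going <- going & !crossed
    prev <- looks[i]
  }
  list(early_stop_prob = mean(early), expected_n = mean(n_used))
}
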