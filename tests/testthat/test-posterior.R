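test_that("conjugate updating follows beta-binomial arithmetic", {
  cases <- list(
    list(prior = beta_prior(1, 1), x = 6, n = 30, post = c(7, 25)),
    list(prior = beta_prior(0.6, 1.4), x = 5, n = 10, post = c(5.6, 6.4)),
    list(prior = beta_prior(1, 1), x = 0, n = 0, post = c(1, 1))
  )
  for (cs in cases) {
    post <- update_posterior(cs$prior, cs$x, cs$n)
    expect_equal(c(post$alpha, post$beta), cs$post)
  }
  expect_error(update_posterior(beta_prior(1, 1), 5, 3), "exceed")
  expect_error(beta_prior(0, 1), "positive")
})

test_that("superiority probability matches closed forms and frozen MC oracle", {
  # independent uniforms: Pr(U1 > U2 + delta) = (1 - delta)^2 / 2
  expect_equal(prob_exceeds_margin(beta_prior(1, 1), beta_prior(1, 1), 0.05),
               0.95^2 / 2, tolerance = 1e-7)
  expect_equal(prob_exceeds_margin(beta_prior(1, 1), beta_prior(1, 1), 0.2),
               0.8^2 / 2, tolerance = 1e-7)
  # identical posteriors at zero margin: symmetry gives exactly 1/2
  expect_equal(prob_exceeds_margin(beta_prior(4, 9), beta_prior(4, 9), 0),
               0.5, tolerance = 1e-7)
  # frozen value from 1e7 paired beta draws (seed 20240901):
  # Beta(7,25) vs Beta(5,27), delta = 0.05 -> 0.551418
  expect_equal(prob_exceeds_margin(beta_prior(7, 25), beta_prior(5, 27),
                                   0.05),
               0.551418, tolerance = 3e-4)
  expect_error(prob_exceeds_margin(beta_prior(1, 1), beta_prior(1, 1), 1),
               "delta")
})

test_that("superiority probability is monotone in evidence and margin", {
  base_e <- beta_prior(7, 25); base_c <- beta_prior(5, 27)
  p0 <- prob_exceeds_margin(base_e, base_c, 0.05)
  # more experimental successes raise it
  expect_true(prob_exceeds_margin(beta_prior(9, 23), base_c, 0.05) > p0)
  # more control successes lower it
  expect_true(prob_exceeds_margin(base_e, beta_prior(8, 24), 0.05) < p0)
  # non-increasing in delta
  deltas <- seq(0, 0.5, by = 0.05)
  vals <- vapply(deltas, function(d)
    prob_exceeds_margin(base_e, base_c, d), numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("complementarity holds at zero margin for random posterior pairs", {
  set.seed(41)
  for (i in 1:25) {
    a <- beta_prior(runif(1, 0.5, 40), runif(1, 0.5, 40))
    b <- beta_prior(runif(1, 0.5, 40), runif(1, 0.5, 40))
    expect_equal(prob_exceeds_margin(a, b, 0) + prob_exceeds_margin(b, a, 0),
                 1, tolerance = 1e-6)
  }
})

test_that("quadrature agrees with Monte-Carlo within 3 SE over random pairs", {
  set.seed(99)
  draws <- 1e6
  for (i in 1:50) {
    a <- beta_prior(runif(1, 0.5, 60), runif(1, 0.5, 60))
    b <- beta_prior(runif(1, 0.5, 60), runif(1, 0.5, 60))
    d <- runif(1, 0, 0.2)
    q <- prob_exceeds_margin(a, b, d)
    m <- mc_prob_exceeds(a, b, d, draws)
    se <- sqrt(max(m * (1 - m), 1e-12) / draws)
    expect_lt(abs(q - m), 3 * se + 1e-6)
  }
})

test_that("decision rule compares strictly against the threshold", {
  # PP is exactly 0.5 here, not > 0.5, so no success
  same <- beta_prior(3, 3)
  d <- decide(same, same, decision_rule(0, 0.5))
  expect_equal(d$posterior_prob, 0.5, tolerance = 1e-7)
  expect_false(d$success)
  # overwhelming separation forces success
  expect_true(decide(beta_prior(31, 1), beta_prior(1, 31),
                     decision_rule(0.05, 0.67))$success)
  # uniform vs uniform: PP = 0.45125 < 0.67
  expect_false(decide(beta_prior(1, 1), beta_prior(1, 1),
                      decision_rule(0.05, 0.67))$success)
})
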