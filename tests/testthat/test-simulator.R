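test_that("degenerate outcome rates force the obvious decisions", {
  # nobody responds anywhere: no arm can claim success
  sc0 <- mpr_scenario(true_rates = c(0, 0))
  sc0$arms[[1]]$true_rate <- 0
  r0 <- simulate_trial(sc0, seed = 5)
  expect_false(any(r0$arms$success))
  expect_true(all(r0$arms$posterior_prob < 0.67))

  # perfect experimental arm against a dead control: success every time
  sc1 <- trial_scenario(
    arms = list(arm_spec("control", "control", 0),
                arm_spec("won", "experimental", 1)),
    rule = decision_rule(0.05, 0.67))
  for (s in 1:10)
    expect_true(simulate_trial(sc1, seed = s)$arms$success)
})

test_that("simulation is reproducible and respects planned sample sizes", {
  sc <- mpr_scenario()
  r1 <- simulate_trial(sc, seed = 42)
  r2 <- simulate_trial(sc, seed = 42)
  expect_identical(r1, r2)
  expect_true(all(r1$arms$n_treated == 30L))
  expect_true(all(r1$arms$n_success <= r1$arms$n_treated))
  # arms complete in their opening order under staggered entry
  expect_true(all(diff(r1$arms$analysis_time) > 0))

  oc1 <- operating_characteristics(sc, reps = 25, seed = 9)
  oc2 <- operating_characteristics(sc, reps = 25, seed = 9)
  expect_identical(as.data.frame(oc1), as.data.frame(oc2))
  expect_true(all(oc1$mean_n[oc1$role == "experimental"] == 30))
  # once at least two arms stay open past the cap, control keeps accruing
  expect_gt(oc1$mean_n[oc1$role == "control"], 30)
})

test_that("single replicate gives 0/1 success proportions", {
  oc <- operating_characteristics(mpr_scenario(), reps = 1, seed = 4)
  p <- oc$prob_success[oc$role == "experimental"]
  expect_true(all(p %in% c(0, 1)))
})

test_that("errors on scenarios the platform cannot run", {
  expect_error(trial_scenario(
    arms = list(arm_spec("c1", "control", 0.1),
                arm_spec("c2", "control", 0.1)),
    rule = decision_rule(0.05, 0.67)), "exactly one control")
  sc <- trial_scenario(arms = list(arm_spec("control", "control", 0.1)),
                       rule = decision_rule(0.05, 0.67))
  expect_error(simulate_trial(sc, seed = 1), "no experimental arm")
})

test_that("simulator matches exact enumeration with an uncapped single arm", {
  # With one experimental arm of planned_n = 10 and an uncapped control,
  # allocation stays 1/2 throughout, so the control size at the end is
  # negative binomial: P(nc = k) = C(k + 9, k) / 2^(10 + k). Mixing the
  # fixed-size enumeration over that law gives the exact claim probability.
  ne <- 10; pe <- 0.5; pc <- 0.3; delta <- 0.05; theta <- 0.6
  sc <- trial_scenario(
    arms = list(arm_spec("control", "control", pc),
                arm_spec("e", "experimental", pe, planned_n = ne)),
    rule = decision_rule(delta, theta),
    control_cap = 1e9)
  kmax <- qnbinom(1 - 1e-8, ne, 0.5)
  exact <- sum(vapply(0:kmax, function(k)
    dnbinom(k, ne, 0.5) *
      (if (k == 0) {
        # no control data: posterior is the prior
        pp <- vapply(0:ne, function(xe)
          prob_exceeds_margin(update_posterior(beta_prior(1, 1), xe, ne),
                              beta_prior(1, 1), delta), numeric(1))
        sum(dbinom(0:ne, ne, pe) * (pp > theta))
      } else enum_claim_prob(pe, pc, ne, k, delta, theta)),
    numeric(1)))

  reps <- 3000
  oc <- operating_characteristics(sc, reps = reps, seed = 314)
  sim <- oc$prob_success[oc$role == "experimental"]
  se <- sqrt(exact * (1 - exact) / reps)
  expect_lt(abs(sim - exact), 3 * se)
})

test_that("success probability rises with the true rate", {
  # deterministic check by conditional enumeration at a fixed control size
  pows <- vapply(c(0.13, 0.195, 0.26, 0.30), function(pe)
    enum_claim_prob(pe, 0.13, 30, 40, 0.05, 0.67), numeric(1))
  expect_true(all(diff(pows) > 0))
})

test_that("comparison conventions select the intended control subsets", {
  sc_fin <- mpr_scenario()
  sc_at <- mpr_scenario(comparison = "at-completion")
  sc_con <- mpr_scenario(comparison = "concurrent")
  r_fin <- simulate_trial(sc_fin, seed = 88)
  r_at <- simulate_trial(sc_at, seed = 88)
  r_con <- simulate_trial(sc_con, seed = 88)
  # identical seed: same accrual history, different analysis sets
  expect_identical(r_fin$n_control, r_at$n_control)
  expect_true(all(r_fin$arms$n_control_used == r_fin$n_control))
  # controls accrued by completion can only be fewer
  expect_true(all(r_at$arms$n_control_used <= r_fin$arms$n_control_used))
  # concurrent windows are subsets of the at-completion sets
  expect_true(all(r_con$arms$n_control_used <= r_at$arms$n_control_used))
  # the last arm analyzed with all controls: final and at-completion agree
  k <- nrow(r_fin$arms)
  expect_equal(r_at$arms$posterior_prob[k], r_fin$arms$posterior_prob[k])
})
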