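cfg <- default_design()
table1 <- tox_obs(dose = c(1, 2, 2, 2, 3, 3, 3), y = c(0, 1, 1, 0, 0, 0, 1))
no_data <- tox_obs(integer(0), integer(0))

test_that("probit link reproduces the skeleton at beta = 0 and its tails", {
  expect_equal(probit_prob(0, 0.25), 0.25)
  expect_equal(probit_prob(0, c(0.13, 0.59)), c(0.13, 0.59))
  expect_lt(probit_prob(-50, 0.25), 1e-12)
  expect_equal(probit_prob(1, 0.13), pnorm(1 + qnorm(0.13)), tolerance = 1e-12)
  # strictly increasing in both arguments
  expect_true(all(diff(probit_prob(seq(-2, 2, 0.5), 0.3)) > 0))
  expect_true(all(diff(probit_prob(0.4, c(0.1, 0.3, 0.5, 0.7))) > 0))
  expect_error(probit_prob(0, 1.2), "skeleton")
})

test_that("linear TITE weight follows the partial-follow-up rule", {
  expect_equal(linear_weight(5, 10, 0), 0.5)
  expect_equal(linear_weight(12, 10, 0), 1)
  expect_equal(linear_weight(2, 10, 1), 1)
  expect_equal(linear_weight(0, 10, 0), 0)
  expect_error(linear_weight(-1, 10, 0), "negative")
  # more follow-up never means less weight for a pending patient
  w <- linear_weight(seq(0, 15, 0.5), 10, 0)
  expect_true(all(diff(w) >= 0))
})

test_that("weighted log likelihood matches direct computation", {
  expect_equal(log_weighted_likelihood(0.7, no_data, 1, cfg), 0)
  one <- tox_obs(2, 1)  # q = 0.25 under order 1
  expect_equal(log_weighted_likelihood(0, one, 1, cfg), log(0.25))
  # seven-term sum accumulated independently
  q1 <- cfg$ordering_set$q[table1$dose, 1]
  p <- pnorm(0.3 + qnorm(q1))
  byhand <- sum(ifelse(table1$y == 1, log(p), log(1 - p)))
  expect_equal(log_weighted_likelihood(0.3, table1, 1, cfg), byhand,
               tolerance = 1e-12)
  # partial weights enter the non-DLT factors
  part <- tox_obs(c(1, 2), c(0, 0), c(0.4, 0.7))
  p2 <- pnorm(-0.2 + qnorm(cfg$ordering_set$q[1:2, 1]))
  expect_equal(log_weighted_likelihood(-0.2, part, 1, cfg),
               log1p(-0.4 * p2[1]) + log1p(-0.7 * p2[2]), tolerance = 1e-12)
})

test_that("order posterior equals the prior without data and favors the
           order matching the observed toxicity pattern", {
  set.seed(1)
  op0 <- order_posterior(no_data, cfg)
  expect_equal(op0$weights, c(0.5, 0.5), tolerance = 1e-12)
  expect_true(op0$tie_broken)

  op <- order_posterior(table1, cfg)
  # 2/3 DLT at d2 vs 1/3 at d3 supports d1-d3-d2-d4
  expect_equal(op$selected, 2L)
  expect_false(op$tie_broken)
  expect_equal(sum(op$weights), 1, tolerance = 1e-10)
  # against the brute-force Riemann oracle
  m1 <- oracle_marginal(table1, 1, cfg)
  m2 <- oracle_marginal(table1, 2, cfg)
  expect_equal(op$weights, c(m1, m2) / (m1 + m2), tolerance = 1e-6)

  # swapping the outcomes at d2 and d3 mirrors the posterior
  swapped <- table1
  swapped$dose <- c(1, 3, 3, 3, 2, 2, 2)
  ops <- order_posterior(swapped, cfg)
  expect_equal(ops$weights, rev(op$weights), tolerance = 1e-9)
  expect_equal(ops$selected, 1L)
})

test_that("posterior DLT probabilities match the fine-grid oracle and
           preserve the skeleton ranking", {
  for (m in 1:2) {
    expect_equal(posterior_dlt_probs(no_data, m, cfg),
                 oracle_phat(no_data, m, cfg), tolerance = 1e-6)
    expect_equal(posterior_dlt_probs(table1, m, cfg),
                 oracle_phat(table1, m, cfg), tolerance = 1e-6)
  }
  # no data: estimates ordered as the skeleton under order 1
  expect_true(all(diff(posterior_dlt_probs(no_data, 1, cfg)) > 0))
  # a DLT at d1 pulls its estimate up from the prior value
  p0 <- posterior_dlt_probs(no_data, 1, cfg)[1]
  p1 <- posterior_dlt_probs(tox_obs(1, 1), 1, cfg)[1]
  expect_gt(p1, p0)
  # ranking preservation on random weighted datasets
  set.seed(7)
  for (i in 1:10) {
    obs <- random_obs(sample(2:10, 1))
    for (m in 1:2) {
      ph <- posterior_dlt_probs(obs, m, cfg)
      expect_equal(order(ph), cfg$ordering_set$orders[[m]])
    }
  }
})

test_that("posterior concentrates near a single dose's empirical DLT rate", {
  # 200 fully observed patients at dose 2, 25% DLT rate
  obs <- tox_obs(rep(2, 200), rep(c(1, 0, 0, 0), 50))
  expect_equal(posterior_dlt_probs(obs, 1, cfg)[2], 0.25, tolerance = 0.03)
  obs2 <- tox_obs(rep(1, 200), rep(c(1, 1, 0, 0, 0), 40))
  expect_equal(posterior_dlt_probs(obs2, 1, cfg)[1], 0.40, tolerance = 0.03)
})

test_that("MTDC selection takes the closest dose, ties to the lower level", {
  expect_equal(select_mtdc(c(0.10, 0.24, 0.41, 0.59), 0.25), 2L)
  expect_equal(select_mtdc(c(0.20, 0.30), 0.25), 1L)
  expect_equal(select_mtdc(c(0.50, 0.64, 0.58, 0.78), 0.25), 1L)
})

test_that("safe set keeps doses not exceeding the MTDC's estimate", {
  expect_equal(safe_set(c(0.10, 0.24, 0.41, 0.59), 2L), c(1L, 2L))
  expect_equal(safe_set(rep(0.25, 4), 1L), 1:4)
  expect_equal(safe_set(c(0.50, 0.58, 0.64, 0.78), 1L), 1L)
})

test_that("toxicity stop has the closed-form prior probability and fires
           only under strong evidence at dose 1", {
  ts0 <- toxicity_stop(no_data, cfg, m = 1)
  closed <- 1 - pnorm((qnorm(0.25) - qnorm(0.13)) / 0.74)
  expect_equal(ts0$prob, closed, tolerance = 1e-9)
  expect_false(ts0$stop)

  cfg1 <- cfg
  cfg1$p_ut <- 1.0
  sixdlt <- tox_obs(rep(1, 6), rep(1, 6))
  expect_false(toxicity_stop(sixdlt, cfg1, m = 1)$stop)

  ts6 <- toxicity_stop(sixdlt, cfg, m = 1)
  expect_equal(ts6$prob, oracle_tail_prob(sixdlt, 1, cfg), tolerance = 1e-6)
  expect_true(ts6$stop)
})
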