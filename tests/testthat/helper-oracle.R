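# Independent brute-force oracles: midpoint Riemann sums on a fine beta
# grid, written without reference to the package's quadrature machinery.

riemann_grid <- function(config, n = 100000L) {
  lim <- 8 * config$prior_sd
  h <- 2 * lim / n
  list(beta = seq(-lim + h / 2, lim - h / 2, by = h), h = h)
}

# likelihood of obs at one beta under order m, direct product
oracle_lik <- function(beta, obs, m, config) {
  q <- config$ordering_set$q
  vapply(beta, function(b) {
    if (nrow(obs) == 0) return(1)
    p <- pnorm(b + qnorm(q[obs$dose, m]))
    prod((obs$w * p)^obs$y * (1 - obs$w * p)^(1 - obs$y))
  }, numeric(1))
}

oracle_marginal <- function(obs, m, config, n = 100000L) {
  g <- riemann_grid(config, n)
  sum(oracle_lik(g$beta, obs, m, config) *
        dnorm(g$beta, 0, config$prior_sd)) * g$h
}

oracle_phat <- function(obs, m, config, n = 100000L) {
  g <- riemann_grid(config, n)
  wts <- oracle_lik(g$beta, obs, m, config) * dnorm(g$beta, 0, config$prior_sd)
  q <- config$ordering_set$q
  vapply(seq_len(nrow(q)), function(j)
    sum(pnorm(g$beta + qnorm(q[j, m])) * wts) / sum(wts), numeric(1))
}

oracle_tail_prob <- function(obs, m, config, n = 100000L) {
  g <- riemann_grid(config, n)
  cc <- qnorm(config$theta_star) - qnorm(config$ordering_set$q[1, m])
  wts <- oracle_lik(g$beta, obs, m, config) * dnorm(g$beta, 0, config$prior_sd)
  sum(wts[g$beta > cc]) / sum(wts)
}

# random small TITE datasets on the default 4-dose grid
random_obs <- function(n) {
  dose <- sample(1:4, n, replace = TRUE)
  y <- rbinom(n, 1, 0.3)
  w <- ifelse(y == 1, 1, round(runif(n, 0.1, 1), 3))
  tox_obs(dose, y, w)
}
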