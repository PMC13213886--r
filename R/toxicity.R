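# Probit TITE model for partially ordered dose combinations.
#
# All posterior quantities are 1-D integrals over the probit parameter beta;
# they are evaluated with fixed Gauss-Legendre quadrature over +/- 8 prior
# SDs, entirely in log space. The node positions and the per-node dose
# probabilities depend only on the design, so they are precomputed once into
# a "workspace" and reused at every decision point.

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Precompute quadrature nodes and per-node DLT probabilities for a design.
# tail_*: second node set on [c, 8*sd] for the toxicity-stop tail integral,
# where c = qnorm(theta*) - qnorm(q at dose 1) (dose 1 is first in every
# candidate order, so its skeleton value is order-invariant).
design_workspace <- function(config) {
  stopifnot(inherits(config, "fmtdc_design"))
  v <- validate_config(config)
  if (length(v)) stop("invalid design: ", paste(v, collapse = "; "))
  sd <- config$prior_sd
  lim <- 8 * sd
  gl <- pracma::gaussLegendre(config$quad_points, -lim, lim)
  q <- config$ordering_set$q
  M <- ncol(q)
  pmat <- lapply(seq_len(M), function(m)
    outer(gl$x, stats::qnorm(q[, m]), function(b, z) stats::pnorm(b + z)))
  cstop <- stats::qnorm(config$theta_star) - stats::qnorm(q[1, 1])
  glt <- pracma::gaussLegendre(max(101L, config$quad_points %/% 2L),
                               min(cstop, lim), lim)
  pmat_t <- lapply(seq_len(M), function(m)
    outer(glt$x, stats::qnorm(q[, m]), function(b, z) stats::pnorm(b + z)))
  list(nodes = gl$x,
       logf = log(gl$w) + stats::dnorm(gl$x, 0, sd, log = TRUE),
       pmat = pmat, logpmat = lapply(pmat, log),
       tail_nodes = glt$x,
       tail_logf = log(glt$w) + stats::dnorm(glt$x, 0, sd, log = TRUE),
       tail_pmat = pmat_t,
       cstop = cstop, M = M, J = nrow(q))
}

get_workspace <- function(config) {
  ws <- attr(config, "workspace")
  if (is.null(ws)) ws <- design_workspace(config)
  ws
}

#' Attach a precomputed quadrature workspace to a design
#'
#' Optional speed-up: inference functions rebuild quadrature tables from the
#' design on every call unless a workspace is attached. The trial engine and
#' simulator do this automatically.
#'
#' @param config an `fmtdc_design`.
#' @return the design with cached tables attached as an attribute.
#' @export
prepare_design <- function(config) {
  attr(config, "workspace") <- design_workspace(config)
  config
}

#' Probit DLT probability
#'
#' The one-parameter model `p = pnorm(beta + qnorm(q))`: at `beta = 0` the
#' DLT probability equals the skeleton value `q`, and `beta` shifts the
#' whole curve on the probit scale.
#'
#' @param beta probit parameter (any real).
#' @param q skeleton probability in (0, 1).
#' @return DLT probability; vectorized over both arguments.
#' @examples
#' probit_prob(0, 0.25)
#' @export
probit_prob <- function(beta, q) {
  if (any(q <= 0 | q >= 1)) stop("skeleton value outside (0,1)")
  stats::pnorm(beta + stats::qnorm(q))
}

#' Linear time-to-event weight
#'
#' The fraction of the DLT window a pending patient has been observed for:
#' `t/T` while the patient is DLT-free inside the window, 1 once the window
#' is complete or a DLT has occurred (a DLT meets the endpoint and is fully
#' observed).
#'
#' @param t follow-up time since treatment start (weeks), `t >= 0`.
#' @param T_window DLT observation window (weeks).
#' @param y DLT indicator at time `t` (0/1).
#' @return weight in `[0, 1]`; vectorized.
#' @examples
#' linear_weight(5, 10, 0)   # 0.5
#' linear_weight(2, 10, 1)   # 1: a DLT is fully observed
#' @export
linear_weight <- function(t, T_window, y = 0) {
  if (any(t < 0)) stop("negative follow-up time")
  if (any(T_window <= 0)) stop("DLT window must be positive")
  ifelse(y == 1 | t >= T_window, 1, t / T_window)
}

#' Toxicity observations at a decision time
#'
#' Convenience constructor for the per-patient rows entering the weighted
#' likelihood: dose received, current DLT status, and TITE weight.
#'
#' @param dose integer dose indices received.
#' @param y 0/1 DLT status.
#' @param w weights in `[0,1]`; default 1 (complete follow-up).
#' @return data.frame with columns `dose`, `y`, `w`.
#' @export
tox_obs <- function(dose, y, w = rep(1, length(dose))) {
  stopifnot(length(y) == length(dose), length(w) == length(dose))
  if (any(w < 0 | w > 1)) stop("weights outside [0,1]")
  if (any(y == 1 & w != 1)) stop("a DLT must carry weight 1")
  data.frame(dose = as.integer(dose), y = as.integer(y), w = as.numeric(w))
}

# log weighted likelihood evaluated at every quadrature node (vector over
# nodes) for order m, from precomputed node-by-dose probability tables.
loglik_nodes <- function(ws, m, obs, tail = FALSE) {
  P <- if (tail) ws$tail_pmat[[m]] else ws$pmat[[m]]
  ll <- numeric(nrow(P))
  i1 <- which(obs$y == 1L)
  if (length(i1))
    ll <- ll + rowSums(log(P[, obs$dose[i1], drop = FALSE]))
  i0 <- which(obs$y == 0L & obs$w > 0)
  if (length(i0)) {
    WP <- P[, obs$dose[i0], drop = FALSE] *
      rep(obs$w[i0], each = nrow(P))
    ll <- ll + rowSums(log1p(-WP))
  }
  ll
}

#' Log weighted likelihood
#'
#' Log of `prod_i (w_i p_{j_i,m})^{y_i} (1 - w_i p_{j_i,m})^{1 - y_i}`, the
#' TITE-weighted binomial likelihood of the current data under candidate
#' order `m`.
#'
#' @param beta probit parameter value(s).
#' @param obs a [tox_obs()] data.frame (may be empty).
#' @param m candidate-order index.
#' @param config an `fmtdc_design`.
#' @return log-likelihood, vectorized over `beta`; 0 for empty data.
#' @export
log_weighted_likelihood <- function(beta, obs, m, config) {
  q <- config$ordering_set$q
  sapply(beta, function(b) {
    if (nrow(obs) == 0) return(0)
    p <- probit_prob(b, q[obs$dose, m])
    sum(obs$y * log(obs$w * p) + (1 - obs$y) * log1p(-obs$w * p))
  })
}

# log marginal likelihood log integral L_{t,m}(beta) f(beta) dbeta per order.
log_marginals <- function(obs, config, ws = get_workspace(config)) {
  vapply(seq_len(ws$M),
         function(m) log_sum_exp(loglik_nodes(ws, m, obs) + ws$logf),
         numeric(1))
}

#' Posterior over candidate toxicity orders
#'
#' Bayesian model averaging weight of each candidate simple order: prior
#' order weight times the marginal likelihood of the current weighted data,
#' normalized. The working order is the one with the largest posterior
#' weight; exact ties are broken uniformly at random (consuming the current
#' RNG stream).
#'
#' @param obs a [tox_obs()] data.frame.
#' @param config an `fmtdc_design`.
#' @return list with `weights` (posterior probabilities summing to 1),
#'   `selected` (working order index), `tie_broken` (logical), and
#'   `log_marginals`.
#' @examples
#' cfg <- default_design()
#' obs <- tox_obs(dose = c(1, 2, 2, 2, 3, 3, 3), y = c(0, 1, 1, 0, 0, 0, 1))
#' order_posterior(obs, cfg)$weights
#' @export
order_posterior <- function(obs, config) {
  ws <- get_workspace(config)
  lm <- log_marginals(obs, config, ws)
  lw <- log(config$ordering_set$prior_weights) + lm
  if (all(!is.finite(lw))) stop("all order marginal likelihoods underflowed")
  w <- exp(lw - log_sum_exp(lw))
  top <- which(w >= max(w) - 1e-12)
  tie <- length(top) > 1L
  sel <- if (tie) top[sample.int(length(top), 1L)] else top[1L]
  list(weights = w, selected = sel, tie_broken = tie, log_marginals = lm)
}

#' Posterior-mean DLT probabilities under an order
#'
#' The posterior mean of `pnorm(beta + qnorm(q_{j,m}))` for every dose under
#' candidate order `m`, with the TITE-weighted likelihood and the normal
#' prior on `beta`, by deterministic quadrature.
#'
#' @inheritParams order_posterior
#' @param m candidate-order index.
#' @return numeric vector of length `J` of estimated DLT probabilities.
#' @export
posterior_dlt_probs <- function(obs, m, config) {
  ws <- get_workspace(config)
  ll <- loglik_nodes(ws, m, obs) + ws$logf
  post <- exp(ll - log_sum_exp(ll))
  as.vector(crossprod(post, ws$pmat[[m]]))
}

#' Estimated maximum tolerated dose combination
#'
#' The dose whose estimated DLT probability is closest to the target rate;
#' ties go to the lower dose index (conservative).
#'
#' @param p_hat estimated DLT probabilities per dose.
#' @param theta_star target DLT rate.
#' @return dose index.
#' @examples
#' select_mtdc(c(0.10, 0.24, 0.41, 0.59), 0.25)
#' @export
select_mtdc <- function(p_hat, theta_star) {
  d <- abs(p_hat - theta_star)
  which(d <= min(d) + 1e-12)[1L]
}

#' Safe dose set under an order
#'
#' All doses whose estimated DLT probability does not exceed that of the
#' estimated MTDC.
#'
#' @param p_hat estimated DLT probabilities per dose.
#' @param j_star MTDC dose index.
#' @return integer vector of dose indices.
#' @export
safe_set <- function(p_hat, j_star) {
  which(p_hat <= p_hat[j_star] + 1e-12)
}

#' Toxicity stopping rule
#'
#' Posterior probability that even the lowest dose is too toxic, i.e. that
#' `beta` exceeds `qnorm(theta*) - qnorm(q_1)` (the value at which dose 1's
#' DLT probability reaches the target), under the weighted-likelihood
#' posterior of the working order. The trial stops when this probability
#' exceeds the cutoff `p_ut`.
#'
#' @inheritParams order_posterior
#' @param m candidate-order index whose posterior is used; by default the
#'   order with the largest posterior weight (ties to the lower index, so
#'   the standalone call is deterministic).
#' @return list with `stop` (logical) and `prob`.
#' @export
toxicity_stop <- function(obs, config, m = NULL) {
  ws <- get_workspace(config)
  if (is.null(m)) {
    lm <- log(config$ordering_set$prior_weights) +
      log_marginals(obs, config, ws)
    m <- which.max(lm)
  }
  denom <- log_sum_exp(loglik_nodes(ws, m, obs) + ws$logf)
  num <- log_sum_exp(loglik_nodes(ws, m, obs, tail = TRUE) + ws$tail_logf)
  prob <- min(exp(num - denom), 1)
  list(stop = prob > config$p_ut, prob = prob)
}
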