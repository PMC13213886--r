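# Dirichlet-multinomial model of cell-therapy dose feasibility.
#
# Each expanded patient contributes one count to X = (X_0, ..., X_K), the
# category of their individual highest feasible cell dose (IHFCD); X_0 holds
# patients whose product fell below even the lowest cell dose. With a
# Dirichlet(a) prior on the category probabilities, the tail probability
# phi_k = pi_k + ... + pi_K that a patient is feasible at cell dose k has a
# conjugate Beta posterior with tail-sum parameters, so every feasibility
# decision reduces to an incomplete-beta evaluation.

#' Feasibility counting state
#'
#' @param K number of cell-therapy dose levels.
#' @param a Dirichlet prior parameters `(a_0, ..., a_K)`; default flat.
#' @param counts optional initial counts `(X_0, ..., X_K)`.
#' @return list of class `fmtdc_feas` with `counts`, `a`, `K`.
#' @examples
#' st <- feasibility_state(K = 2)
#' st <- record_ihfcd(st, 2)
#' st$counts
#' @export
feasibility_state <- function(K, a = rep(1, K + 1), counts = rep(0L, K + 1)) {
  stopifnot(length(a) == K + 1, length(counts) == K + 1,
            all(a >= 0), all(counts >= 0))
  structure(list(counts = as.integer(counts), a = as.numeric(a),
                 K = as.integer(K)),
            class = "fmtdc_feas")
}

#' Record a patient's individual highest feasible cell dose
#'
#' @param state a [feasibility_state()].
#' @param k IHFCD category, `0..K` (0 = below the lowest cell dose).
#' @return updated state with `counts[k]` incremented.
#' @export
record_ihfcd <- function(state, k) {
  if (length(k) != 1L || is.na(k) || k < 0 || k > state$K || k != round(k))
    stop("IHFCD must be a single integer in 0..K")
  state$counts[k + 1L] <- state$counts[k + 1L] + 1L
  state
}

#' Beta posterior of a cell dose's feasibility probability
#'
#' The tail probability `phi_k = pi_k + ... + pi_K` has posterior
#' `Beta(sum_{r>=k}(a_r + X_r), sum_{l<k}(a_l + X_l))`.
#'
#' @param state a [feasibility_state()].
#' @param k cell dose index, `1..K`.
#' @return named numeric vector `c(alpha, beta)`.
#' @export
phi_posterior_params <- function(state, k) {
  stopifnot(k >= 1, k <= state$K)
  post <- state$a + state$counts
  idx <- seq_len(state$K + 1L) - 1L        # categories 0..K
  c(alpha = sum(post[idx >= k]), beta = sum(post[idx < k]))
}

#' Is a cell dose feasible?
#'
#' Cell dose `k` is considered feasible while the posterior probability that
#' its population feasibility falls below the threshold `phi_star` is less
#' than the cutoff `p_uf`.
#'
#' @inheritParams phi_posterior_params
#' @param phi_star minimum required feasibility probability.
#' @param p_uf upper posterior-probability cutoff.
#' @return list with `feasible` (logical) and `prob` = P(phi_k < phi* | X).
#' @export
is_cell_dose_feasible <- function(state, k, phi_star, p_uf) {
  par <- phi_posterior_params(state, k)
  prob <- stats::pbeta(phi_star, par[["alpha"]], par[["beta"]])
  list(feasible = prob < p_uf, prob = prob)
}

#' Global highest feasible cell dose (GHFCD)
#'
#' The largest cell dose still considered feasible across the patient
#' population, or 0 when none (including the lowest) is.
#'
#' @inheritParams is_cell_dose_feasible
#' @return integer in `0..K`.
#' @export
ghfcd <- function(state, phi_star, p_uf) {
  feas <- vapply(seq_len(state$K),
                 function(k) is_cell_dose_feasible(state, k, phi_star, p_uf)$feasible,
                 logical(1))
  if (!any(feas)) 0L else max(which(feas))
}

#' Globally feasible dose-combination set
#'
#' All combinations whose cell count does not exceed that of the GHFCD's
#' cell dose; empty when the GHFCD is 0, in which case the trial stops for
#' insufficient feasibility.
#'
#' @param state a [feasibility_state()].
#' @param config an `fmtdc_design` (supplies the grid and thresholds).
#' @return integer vector of dose indices, possibly empty.
#' @export
globally_feasible_set <- function(state, config) {
  k <- ghfcd(state, config$phi_star, config$p_uf)
  if (k == 0L) return(integer(0))
  g <- config$dose_grid
  cap <- g$cell_count[match(TRUE, g$cell_dose_index == k)]
  sort(g$index[g$cell_count <= cap])
}
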