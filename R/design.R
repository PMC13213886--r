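#' Dose-combination grid
#'
#' Build the grid of drug-combination dose levels. Each combination pairs a
#' cell-therapy dose (indexed by `cell_dose_index`, the component subject to
#' manufacturing feasibility) with a level of the partner agent. `cell_count`
#' is the number of cells defining each cell dose; its only role is the
#' "at most as many cells" comparison used to expand the globally feasible
#' cell dose into a set of combinations, so any strictly increasing labelling
#' works.
#'
#' @param index integer vector of combination indices `1..J`.
#' @param cell_dose_index integer vector, cell-therapy dose index `1..K` of
#'   each combination.
#' @param partner_dose_index integer vector, level of the non-cell agent.
#' @param cell_count numeric vector, cells per cell dose (arbitrary units);
#'   must be constant within a `cell_dose_index` and increasing across them.
#' @return a `data.frame` of class `fmtdc_grid` with one row per combination.
#' @examples
#' dose_grid(1:4, c(1, 1, 2, 2), c(1, 2, 1, 2), c(1e9, 1e9, 2e9, 2e9))
#' @export
dose_grid <- function(index, cell_dose_index, partner_dose_index,
                      cell_count = cell_dose_index) {
  g <- data.frame(index = as.integer(index),
                  cell_dose_index = as.integer(cell_dose_index),
                  partner_dose_index = as.integer(partner_dose_index),
                  cell_count = as.numeric(cell_count))
  class(g) <- c("fmtdc_grid", "data.frame")
  g
}

#' Candidate toxicity orderings and their skeletons
#'
#' A simple order is a complete putative ranking of the combinations by DLT
#' probability; when only a partial order is known, several candidate simple
#' orders are carried and averaged over. Under order `m` the dose occupying
#' position `r` receives the `r`-th skeleton value, so each column of the
#' resulting `q` matrix is a rearrangement of the skeleton.
#'
#' @param orders list of integer vectors, each a permutation of `1..J` giving
#'   the dose indices from least to most toxic.
#' @param skeleton strictly increasing prior DLT probability guesses, one per
#'   position.
#' @param prior_weights prior probability of each order (default uniform).
#' @return list of class `fmtdc_orders` with elements `orders`, `skeleton`,
#'   `prior_weights`, and the `J x M` matrix `q` with `q[j, m]` the skeleton
#'   value of dose `j` under order `m`.
#' @examples
#' os <- ordering_set(list(c(1, 2, 3, 4), c(1, 3, 2, 4)),
#'                    skeleton = c(0.13, 0.25, 0.41, 0.59))
#' os$q
#' @export
ordering_set <- function(orders, skeleton, prior_weights = NULL) {
  if (is.null(prior_weights))
    prior_weights <- rep(1 / length(orders), length(orders))
  J <- length(skeleton)
  q <- matrix(NA_real_, J, length(orders))
  for (m in seq_along(orders)) {
    o <- orders[[m]]
    if (length(o) == J && setequal(o, seq_len(J)))
      q[o, m] <- skeleton
  }
  structure(list(orders = lapply(orders, as.integer),
                 skeleton = as.numeric(skeleton),
                 prior_weights = as.numeric(prior_weights),
                 q = q),
            class = "fmtdc_orders")
}

#' Trial design configuration
#'
#' Collect every fixed constant of the design. The constructor performs no
#' validation so that candidate configurations can be inspected with
#' [validate_config()]; inference functions refuse invalid configurations.
#'
#' @param dose_grid a [dose_grid()].
#' @param ordering_set an [ordering_set()].
#' @param theta_star target DLT rate defining the MTDC.
#' @param phi_star minimum required population feasibility probability for a
#'   cell dose.
#' @param p_ut upper posterior-probability cutoff for the toxicity stop: the
#'   trial stops when P(lowest dose too toxic | data) exceeds it.
#' @param p_uf upper posterior-probability cutoff for the feasibility stop.
#' @param n_max maximum number of toxicity-evaluable (treated) patients.
#' @param c_max maximum number of patients whose cells are expanded
#'   (feasibility-evaluable), `n_max <= c_max`.
#' @param dlt_window DLT observation window `T` in weeks.
#' @param prior_sd standard deviation of the Normal(0, sd^2) prior on the
#'   probit parameter.
#' @param dirichlet_a Dirichlet prior parameters `(a_0, ..., a_K)` over the
#'   highest-feasible-cell-dose categories; default flat (all 1).
#' @param accrual_mean_gap mean weeks between arrivals (simulation only).
#' @param rng_seed optional integer seed recorded for reproducibility.
#' @param quad_points number of Gauss-Legendre nodes for the 1-D integrals
#'   over the probit parameter.
#' @param feas_check when the feasibility stopping rule is evaluated:
#'   `"each_failure"` (default) tests it during conduct at every
#'   manufacture-failure (IHFCD = 0) event and again at the final analysis,
#'   following the conduct algorithm; `"final"` defers the decision to the
#'   final analysis only. With a flat Dirichlet prior the mid-trial test is
#'   sensitive to early failures (two or three failures among the first few
#'   patients can already trigger it); see the methods vignette.
#' @return list of class `fmtdc_design`.
#' @seealso [default_design()] for a ready-made four-dose configuration.
#' @export
design_config <- function(dose_grid, ordering_set,
                          theta_star = 0.25, phi_star = 0.80,
                          p_ut = 0.90, p_uf = 0.90,
                          n_max = 24L, c_max = 30L,
                          dlt_window = 10, prior_sd = 0.74,
                          dirichlet_a = NULL, accrual_mean_gap = 4,
                          rng_seed = NULL, quad_points = 251L,
                          feas_check = c("each_failure", "final")) {
  feas_check <- match.arg(feas_check)
  K <- if (nrow(dose_grid)) max(dose_grid$cell_dose_index) else 0L
  if (is.null(dirichlet_a)) dirichlet_a <- rep(1, K + 1L)
  structure(list(dose_grid = dose_grid, ordering_set = ordering_set,
                 theta_star = theta_star, phi_star = phi_star,
                 p_ut = p_ut, p_uf = p_uf,
                 n_max = as.integer(n_max), c_max = as.integer(c_max),
                 dlt_window = dlt_window, prior_sd = prior_sd,
                 dirichlet_a = as.numeric(dirichlet_a),
                 accrual_mean_gap = accrual_mean_gap,
                 rng_seed = rng_seed, K = as.integer(K),
                 J = nrow(dose_grid), quad_points = as.integer(quad_points),
                 feas_check = feas_check),
            class = "fmtdc_design")
}

#' Validate a design configuration
#'
#' Checks every structural invariant of the design and returns a description
#' of each violation instead of raising, so a configuration file can be fully
#' audited in one pass.
#'
#' @param config an [design_config()] object.
#' @return character vector of violation messages; `character(0)` when valid.
#' @export
validate_config <- function(config) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  g <- config$dose_grid
  os <- config$ordering_set
  J <- nrow(g)

  if (anyDuplicated(g$index)) add("dose indices not unique")
  if (!identical(sort(g$index), seq_len(J))) add("dose indices are not 1..J")
  K <- config$K
  if (any(g$cell_dose_index < 1L | g$cell_dose_index > K))
    add("cell dose index outside 1..K")
  cc <- tapply(g$cell_count, g$cell_dose_index, unique)
  if (any(lengths(cc) != 1L))
    add("combinations sharing a cell dose have unequal cell counts")
  else if (K > 1 && any(diff(unlist(cc)[order(as.integer(names(cc)))]) <= 0))
    add("cell count not strictly increasing in cell dose index")

  sk <- os$skeleton
  if (any(sk <= 0 | sk >= 1)) add("skeleton values outside (0,1)")
  if (any(diff(sk) <= 0)) add("skeleton not increasing")
  if (length(sk) != J) add("skeleton length differs from number of doses")
  for (m in seq_along(os$orders)) {
    o <- os$orders[[m]]
    if (!(length(o) == J && setequal(o, seq_len(J))))
      add(sprintf("order %d is not a permutation of 1..%d", m, J))
  }
  if (abs(sum(os$prior_weights) - 1) > 1e-8)
    add("prior weights do not sum to 1")
  if (any(os$prior_weights < 0)) add("prior weights negative")

  if (!(config$theta_star > 0 && config$theta_star < 1))
    add("theta_star outside (0,1)")
  if (!(config$phi_star > 0 && config$phi_star < 1))
    add("phi_star outside (0,1)")
  if (!(config$p_ut > 0 && config$p_ut <= 1)) add("p_ut outside (0,1]")
  if (!(config$p_uf > 0 && config$p_uf <= 1)) add("p_uf outside (0,1]")
  if (config$n_max > config$c_max) add("n_max exceeds c_max")
  if (config$n_max < 1) add("n_max below 1")
  if (!(config$dlt_window > 0)) add("dlt_window not positive")
  if (!(config$prior_sd > 0)) add("prior_sd not positive")
  if (length(config$dirichlet_a) != K + 1L)
    add("dirichlet_a does not have length K+1")
  if (any(config$dirichlet_a < 0)) add("dirichlet_a has negative entries")
  if (!(config$accrual_mean_gap > 0)) add("accrual_mean_gap not positive")
  if (!isTRUE(config$feas_check %in% c("final", "each_failure")))
    add("feas_check not one of 'final', 'each_failure'")
  v
}

#' Default four-dose, two-cell-dose design
#'
#' The configuration of a motivating bispecific-antibody-activated T-cell
#' plus checkpoint-inhibitor combination trial: four combinations, the lower
#' two sharing cell dose 1 and the upper two cell dose 2, so that only the
#' relative toxicity of combinations 2 and 3 is unknown. The two candidate
#' simple orders are d1-d2-d3-d4 and d1-d3-d2-d4 with a uniform prior.
#' Target DLT rate 0.25, minimum feasibility 0.80, stop cutoffs 0.90, at
#' most 24 treated / 30 expanded patients, a 10-week DLT window, skeleton
#' (0.13, 0.25, 0.41, 0.59) and a Normal(0, 0.74^2) prior on the probit
#' parameter; the feasibility prior is a flat Dirichlet.
#'
#' @return a valid `fmtdc_design`.
#' @examples
#' cfg <- default_design()
#' validate_config(cfg)
#' @export
default_design <- function() {
  g <- dose_grid(index = 1:4,
                 cell_dose_index = c(1L, 1L, 2L, 2L),
                 partner_dose_index = c(1L, 2L, 1L, 2L),
                 cell_count = c(1, 1, 2, 2))
  os <- ordering_set(list(c(1L, 2L, 3L, 4L), c(1L, 3L, 2L, 4L)),
                     skeleton = c(0.13, 0.25, 0.41, 0.59))
  design_config(g, os)
}

#' @export
print.fmtdc_design <- function(x, ...) {
  cat("Dose-finding design:", x$J, "combinations,", x$K, "cell doses,",
      length(x$ordering_set$orders), "candidate orders\n")
  cat(sprintf("  target DLT rate %.2f | min feasibility %.2f | cutoffs tox %.2f / feas %.2f\n",
              x$theta_star, x$phi_star, x$p_ut, x$p_uf))
  cat(sprintf("  caps: %d treated / %d expanded | DLT window %g wk | prior SD %.2f\n",
              x$n_max, x$c_max, x$dlt_window, x$prior_sd))
  cat("  skeleton:", paste(format(x$ordering_set$skeleton), collapse = ", "), "\n")
  v <- validate_config(x)
  if (length(v)) cat("  INVALID:", paste(v, collapse = "; "), "\n")
  invisible(x)
}
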