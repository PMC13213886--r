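# Synthetic-trial generator and operating-characteristics study.
#
# A scenario is a pair of true curves: per-combination DLT probabilities and
# per-cell-dose marginal feasibility probabilities (the chance a random
# patient's product reaches at least that cell dose). Feasibility tails are
# converted to the implied IHFCD multinomial by successive differences.
# Patients arrive by a Poisson process; a patient destined to have a DLT at
# their received dose gets a Uniform(0, T) toxicity time, so outcomes can be
# pending at later decision points.

#' Define a simulation scenario
#'
#' @param true_dlt true DLT probability of each dose combination.
#' @param true_phi true feasibility probability of each cell dose (the
#'   probability a patient's IHFCD is at least `k`); must be non-increasing.
#' @param accrual_mean_gap mean weeks between arrivals (exponential gaps).
#' @param dlt_window DLT observation window in weeks.
#' @param label optional scenario label.
#' @return list of class `fmtdc_scenario`, including the implied IHFCD
#'   category probabilities `pi` over `0..K`.
#' @examples
#' sc <- scenario(c(0.22, 0.32, 0.38, 0.46), c(0.89, 0.37))
#' sc$pi
#' @export
scenario <- function(true_dlt, true_phi, accrual_mean_gap = 4,
                     dlt_window = 10, label = NULL) {
  if (any(true_dlt < 0 | true_dlt > 1) || any(true_phi < 0 | true_phi > 1))
    stop("probabilities outside [0,1]")
  if (any(diff(true_phi) > 0))
    stop("true_phi must be non-increasing in cell dose")
  pi <- c(1 - true_phi[1], -diff(c(true_phi, 0)))
  names(pi) <- 0:length(true_phi)
  structure(list(true_dlt = as.numeric(true_dlt),
                 true_phi = as.numeric(true_phi), pi = pi,
                 accrual_mean_gap = accrual_mean_gap,
                 dlt_window = dlt_window, label = label),
            class = "fmtdc_scenario")
}

#' IHFCD category probabilities implied by feasibility tails
#'
#' @param true_phi non-increasing feasibility probabilities per cell dose.
#' @return probability vector over IHFCD categories `0..K`.
#' @export
ihfcd_probs <- function(true_phi) scenario(numeric(0), true_phi)$pi

#' Draw one arriving patient
#'
#' @param sc an [scenario()].
#' @return list with `gap` (exponential interarrival time, weeks) and
#'   `ihfcd` (category drawn from the implied multinomial).
#' @export
draw_patient <- function(sc) {
  list(gap = stats::rexp(1, 1 / sc$accrual_mean_gap),
       ihfcd = sample(0:(length(sc$pi) - 1L), 1L, prob = sc$pi))
}

#' Draw a patient's toxicity outcome at a dose
#'
#' @param sc an [scenario()].
#' @param j dose-combination index.
#' @return list with `dlt` (0/1) and `dlt_time` (Uniform(0, T) weeks when
#'   `dlt == 1`, otherwise `NA`).
#' @export
draw_outcome <- function(sc, j) {
  dlt <- as.integer(stats::runif(1) < sc$true_dlt[j])
  list(dlt = dlt,
       dlt_time = if (dlt == 1L) stats::runif(1, 0, sc$dlt_window) else NA_real_)
}

#' Simulate one complete trial
#'
#' Draws arrivals, IHFCDs, and latent toxicity outcomes under the scenario's
#' true curves and runs the conduct algorithm to completion (a stopping rule
#' or either accrual cap), then finalizes. Uses the current RNG state.
#'
#' @param sc an [scenario()].
#' @param config an `fmtdc_design`.
#' @return an `fmtdc_result` (see [finalize()]).
#' @export
run_trial <- function(sc, config) {
  if (is.null(attr(config, "workspace"))) config <- prepare_design(config)
  state <- new_trial(config)
  repeat {
    gap <- stats::rexp(1, 1 / sc$accrual_mean_gap)
    ihfcd <- sample(0:config$K, 1L, prob = sc$pi)
    u <- stats::runif(1)
    event <- list(time = state$time + gap, ihfcd = ihfcd,
                  dlt_by_dose = as.integer(u < sc$true_dlt),
                  dlt_time = stats::runif(1, 0, sc$dlt_window))
    state <- step_trial(state, event, config)
    if (!is.na(state$stopped) || state$n_treated >= config$n_max ||
        state$n_expanded >= config$c_max) break
  }
  finalize(state, config)
}

#' Operating characteristics over repeated simulated trials
#'
#' @param sc an [scenario()].
#' @param config an `fmtdc_design`.
#' @param n_sims number of simulated trials.
#' @param seed master seed; each trial runs on its own sub-seed drawn once
#'   from the master stream, so results are reproducible and independent of
#'   how trials are batched.
#' @return list of class `fmtdc_oc`: `selection_pct` per dose, `none_pct`,
#'   `mean_treated_per_dose`, `mean_dlt`, `mean_duration`, `mean_treated`,
#'   `mean_expanded`, `stop_pct` by reason, `n_sims`.
#' @examples
#' \donttest{
#' oc <- run_scenario(scenario(c(0.22, 0.32, 0.38, 0.46), c(0.89, 0.37)),
#'                    default_design(), n_sims = 50, seed = 1)
#' oc$selection_pct
#' }
#' @export
run_scenario <- function(sc, config, n_sims = 2000L, seed = 1L) {
  config <- prepare_design(config)
  set.seed(seed)
  sub <- sample.int(2147483646L, n_sims)
  J <- config$J
  fmtdc <- integer(n_sims)
  treated <- matrix(0, n_sims, J)
  dlt <- dur <- ntr <- nex <- numeric(n_sims)
  reason <- character(n_sims)
  for (i in seq_len(n_sims)) {
    set.seed(sub[i])
    res <- run_trial(sc, config)
    fmtdc[i] <- res$fmtdc
    rd <- res$records$received_dose
    treated[i, ] <- tabulate(rd[!is.na(rd)], J)
    dlt[i] <- res$n_dlt; dur[i] <- res$duration
    ntr[i] <- res$n_treated; nex[i] <- res$n_expanded
    reason[i] <- res$stop_reason
  }
  structure(list(
    scenario = sc, n_sims = n_sims,
    selection_pct = 100 * vapply(seq_len(J), function(j) mean(fmtdc == j),
                                 numeric(1)),
    none_pct = 100 * mean(fmtdc == 0L),
    stop_pct = c(toxicity = 100 * mean(reason == "toxicity"),
                 feasibility = 100 * mean(reason == "feasibility")),
    mean_treated_per_dose = colMeans(treated),
    mean_dlt = mean(dlt), mean_duration = mean(dur),
    mean_treated = mean(ntr), mean_expanded = mean(nex)),
    class = "fmtdc_oc")
}

#' @export
print.fmtdc_oc <- function(x, ...) {
  J <- length(x$selection_pct)
  tab <- data.frame(dose = seq_len(J),
                    true_dlt = x$scenario$true_dlt,
                    selection_pct = round(x$selection_pct, 1),
                    mean_treated = round(x$mean_treated_per_dose, 1))
  if (!is.null(x$scenario$label)) cat(x$scenario$label, "\n")
  print(tab, row.names = FALSE)
  cat(sprintf("none: %.1f%% (tox %.1f%%, feas %.1f%%) | mean DLTs %.1f | mean duration %.0f wk | %d sims\n",
              x$none_pct, x$stop_pct[["toxicity"]], x$stop_pct[["feasibility"]],
              x$mean_dlt, x$mean_duration, x$n_sims))
  invisible(x)
}

#' Benchmark scenario set
#'
#' Twelve paired toxicity/feasibility scenarios for the four-dose,
#' two-cell-dose design: six monotone DLT curves (order 1 correct) and the
#' same six with the probabilities of doses 2 and 3 exchanged (order 2
#' correct), sharing the same feasibility curves.
#'
#' @return list of 12 [scenario()] objects.
#' @export
oc_scenarios <- function() {
  pt <- list(c(0.22, 0.32, 0.38, 0.46),
             c(0.18, 0.24, 0.36, 0.40),
             c(0.10, 0.15, 0.25, 0.37),
             c(0.11, 0.15, 0.19, 0.29),
             c(0.50, 0.58, 0.64, 0.78),
             c(0.31, 0.37, 0.63, 0.88))
  pf <- list(c(0.89, 0.37), c(0.87, 0.36), c(0.96, 0.91),
             c(0.97, 0.84), c(0.96, 0.88), c(0.60, 0.23))
  sc <- vector("list", 12L)
  for (s in 1:6)
    sc[[s]] <- scenario(pt[[s]], pf[[s]], label = sprintf("scenario %d", s))
  for (s in 1:6)
    sc[[s + 6L]] <- scenario(pt[[s]][c(1, 3, 2, 4)], pf[[s]],
                             label = sprintf("scenario %d", s + 6L))
  sc
}
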