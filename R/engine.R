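# Trial conduct: accrual, feasibility screening, toxicity evaluation, order
# selection, dose assignment with no-skipping, stopping, and final FMTDC
# determination. Decisions are made at each arrival using every patient's
# follow-up at that calendar time (continual enrollment; the trial is never
# suspended to wait out the DLT window).

#' Start a new trial state
#'
#' @param config a valid `fmtdc_design`.
#' @return list of class `fmtdc_trial_state`.
#' @export
new_trial <- function(config) {
  v <- validate_config(config)
  if (length(v)) stop("invalid design: ", paste(v, collapse = "; "))
  structure(list(
    time = 0,
    records = data.frame(patient_id = integer(0), arrival_time = numeric(0),
                         assigned_dose = integer(0), received_dose = integer(0),
                         ihfcd = integer(0), dlt = integer(0),
                         dlt_time = numeric(0), order_used = integer(0)),
    feas = feasibility_state(config$K, config$dirichlet_a),
    stopped = NA_character_,
    n_treated = 0L, n_expanded = 0L,
    tried = integer(0),
    decision = NULL),
    class = "fmtdc_trial_state")
}

# Weighted toxicity observations for all treated patients at calendar time.
current_obs <- function(records, time, config) {
  tr <- records[!is.na(records$received_dose), , drop = FALSE]
  if (nrow(tr) == 0) return(tox_obs(integer(0), integer(0)))
  elapsed <- pmax(time - tr$arrival_time, 0)
  y <- as.integer(tr$dlt == 1L & !is.na(tr$dlt_time) & tr$dlt_time <= elapsed)
  w <- ifelse(y == 1L, 1,
              linear_weight(pmin(elapsed, config$dlt_window),
                            config$dlt_window, 0))
  tox_obs(tr$received_dose, y, w)
}

# Order posterior, working order, DLT estimates, MTDC and stop probability
# at one decision point. Consumes RNG only on exact order-posterior ties.
trial_decision <- function(obs, config) {
  op <- order_posterior(obs, config)
  m <- op$selected
  p_hat <- posterior_dlt_probs(obs, m, config)
  ts <- toxicity_stop(obs, config, m = m)
  list(order_posterior = op, order = m, p_hat = p_hat,
       mtdc = select_mtdc(p_hat, config$theta_star),
       safe = safe_set(p_hat, select_mtdc(p_hat, config$theta_star)),
       tox_stop = ts$stop, tox_stop_prob = ts$prob)
}

#' Dose assignment for an arriving patient
#'
#' Implements the assignment rule: treat at the estimated MTDC when the
#' patient's product supports its cell dose; otherwise, among the doses the
#' patient can receive whose position under the working order does not
#' exceed the MTDC's, treat at the one with estimated DLT probability
#' closest to the target. Escalation may not skip: the assigned dose can be
#' at most one position beyond the highest position already tried under the
#' working order. The first treated patient always receives dose 1.
#'
#' @param p_hat estimated DLT probabilities per dose under the working order.
#' @param m working-order index.
#' @param ihfcd the patient's highest feasible cell dose (must be >= 1;
#'   infeasible patients are excluded before assignment).
#' @param config an `fmtdc_design`.
#' @param tried integer vector of dose indices already tried.
#' @param first logical; force dose 1 (defaults to TRUE when nothing has
#'   been tried).
#' @return assigned dose index.
#' @export
assign_dose <- function(p_hat, m, ihfcd, config, tried = integer(0),
                        first = length(tried) == 0L) {
  if (ihfcd < 1) stop("assign_dose requires IHFCD >= 1")
  if (first) return(1L)
  ord <- config$ordering_set$orders[[m]]
  pos <- match(seq_len(config$J), ord)
  cellk <- config$dose_grid$cell_dose_index
  maxpos <- if (length(tried)) max(pos[tried]) else 0L
  elig <- which(cellk <= ihfcd & pos <= maxpos + 1L)
  if (!length(elig)) {                      # defensive; never hit when dose 1
    elig <- which(cellk <= ihfcd)           # leads every order
    if (!length(elig)) stop("no dose the patient can receive")
  }
  mtdc <- select_mtdc(p_hat, config$theta_star)
  if (mtdc %in% elig) return(mtdc)
  cand <- elig[pos[elig] <= pos[mtdc]]
  if (!length(cand)) cand <- elig
  d <- abs(p_hat[cand] - config$theta_star)
  cand[which(d <= min(d) + 1e-12)[1L]]
}

#' Process one arrival event
#'
#' Runs the conduct algorithm for a single accrued patient: record the
#' IHFCD in the feasibility counts; exclude the patient (and check the
#' feasibility stop) if their product misses the lowest cell dose; otherwise
#' re-evaluate toxicity at the current calendar time, check the toxicity
#' stop, select the working order, and assign and treat at a dose.
#'
#' @param state an `fmtdc_trial_state`.
#' @param event list with `time` (calendar weeks, non-decreasing), `ihfcd`
#'   (0..K), and for treated patients the latent outcome: `dlt_by_dose`
#'   (0/1 per dose index: would this patient have a DLT at that dose) and
#'   `dlt_time` (weeks after treatment start, used when the received dose
#'   yields a DLT).
#' @param config an `fmtdc_design`.
#' @return updated state.
#' @export
step_trial <- function(state, event, config) {
  if (!is.na(state$stopped)) stop("trial already stopped")
  if (event$time < state$time) stop("event time precedes trial clock")
  state$time <- event$time
  state$n_expanded <- state$n_expanded + 1L
  state$feas <- record_ihfcd(state$feas, event$ihfcd)
  pid <- nrow(state$records) + 1L

  if (event$ihfcd == 0L) {
    state$records[pid, ] <- list(pid, event$time, NA_integer_, NA_integer_,
                                 0L, NA_integer_, NA_real_, NA_integer_)
    if (identical(config$feas_check, "each_failure") &&
        ghfcd(state$feas, config$phi_star, config$p_uf) == 0L)
      state$stopped <- "feasibility"
    return(state)
  }

  obs <- current_obs(state$records, state$time, config)
  dec <- trial_decision(obs, config)
  state$decision <- dec
  if (dec$tox_stop) {
    state$stopped <- "toxicity"
    state$records[pid, ] <- list(pid, event$time, NA_integer_, NA_integer_,
                                 as.integer(event$ihfcd), NA_integer_,
                                 NA_real_, NA_integer_)
    return(state)
  }

  first <- state$n_treated == 0L
  assigned <- assign_dose(dec$p_hat, dec$order, config$K, config,
                          state$tried, first)
  received <- assign_dose(dec$p_hat, dec$order, event$ihfcd, config,
                          state$tried, first)
  dlt <- as.integer(event$dlt_by_dose[received])
  state$records[pid, ] <- list(pid, event$time, assigned, received,
                               as.integer(event$ihfcd), dlt,
                               if (dlt == 1L) event$dlt_time else NA_real_,
                               dec$order)
  state$n_treated <- state$n_treated + 1L
  state$tried <- sort(unique(c(state$tried, received)))
  state
}

#' Final estimates and FMTDC selection
#'
#' Completes all follow-ups (every weight 1), recomputes the order posterior
#' and DLT estimates, re-checks feasibility, and selects the feasible MTDC
#' from the intersection of the safe set and the globally feasible set; the
#' FMTDC is 0 when a stopping rule fired, the lowest cell dose is no longer
#' feasible, or the intersection is empty.
#'
#' @param state an `fmtdc_trial_state` with accrual complete.
#' @param config an `fmtdc_design`.
#' @return list of class `fmtdc_result`: `fmtdc`, `stop_reason`, `order`
#'   (selected), `order_weights`, `p_hat`, `mtdc`, `safe_set`,
#'   `feasible_set`, `ghfcd`, `omega_sf`, per-patient `records`, counts and
#'   `duration` (weeks).
#' @export
finalize <- function(state, config) {
  tr <- state$records[!is.na(state$records$received_dose), , drop = FALSE]
  obs <- tox_obs(tr$received_dose, as.integer(tr$dlt))
  dec <- trial_decision(obs, config)
  g <- ghfcd(state$feas, config$phi_star, config$p_uf)
  fset <- globally_feasible_set(state$feas, config)

  stop_reason <- state$stopped
  if (is.na(stop_reason) && g == 0L) stop_reason <- "feasibility"
  omega_sf <- intersect(dec$safe, fset)
  fmtdc <- 0L
  if (is.na(stop_reason) && length(omega_sf)) {
    d <- abs(dec$p_hat[omega_sf] - config$theta_star)
    fmtdc <- omega_sf[which(d <= min(d) + 1e-12)[1L]]
  }
  structure(list(
    fmtdc = fmtdc,
    stop_reason = if (is.na(stop_reason)) "none" else stop_reason,
    order = dec$order,
    order_weights = dec$order_posterior$weights,
    p_hat = dec$p_hat, mtdc = dec$mtdc,
    safe_set = dec$safe, feasible_set = fset, ghfcd = g,
    omega_sf = sort(omega_sf),
    records = state$records,
    n_treated = state$n_treated, n_expanded = state$n_expanded,
    n_dlt = sum(tr$dlt == 1L),
    duration = state$time +
      if (is.na(state$stopped) && state$n_treated > 0L) config$dlt_window else 0),
    class = "fmtdc_result")
}

#' @export
print.fmtdc_result <- function(x, ...) {
  cat("FMTDC:", if (x$fmtdc == 0) "none (0)" else x$fmtdc,
      "| stop:", x$stop_reason, "\n")
  cat("working order:", x$order, " posterior:",
      paste(sprintf("%.3f", x$order_weights), collapse = ", "), "\n")
  cat("estimated DLT probabilities:",
      paste(sprintf("%.3f", x$p_hat), collapse = ", "), "\n")
  cat("safe set: {", paste(x$safe_set, collapse = ","),
      "}  feasible set: {", paste(x$feasible_set, collapse = ","), "}\n")
  cat(x$n_treated, "treated /", x$n_expanded, "expanded;",
      x$n_dlt, "DLTs;", sprintf("%.1f", x$duration), "weeks\n")
  invisible(x)
}
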