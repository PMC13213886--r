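# Plain-text interfaces: patient-record tables (tab- or comma-delimited)
# and design configuration files (YAML or JSON).

REC_COLS <- c("patient_id", "arrival_time", "assigned_dose", "received_dose",
              "ihfcd", "followup_time", "dlt", "dlt_time")

#' Read a patient-record table
#'
#' One row per accrued patient with columns `patient_id`, `arrival_time`,
#' `assigned_dose`, `received_dose`, `ihfcd`, `followup_time`, `dlt`,
#' `dlt_time`. An empty/missing `received_dose` marks a patient whose
#' product missed the lowest cell dose (excluded from the toxicity model
#' but counted for feasibility).
#'
#' @param path file path; delimiter inferred from the extension
#'   (`.csv` = comma, otherwise tab).
#' @return data.frame with the columns above.
#' @export
read_patient_records <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  rec <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  missing <- setdiff(REC_COLS, names(rec))
  if (length(missing))
    stop("patient-record table lacks columns: ", paste(missing, collapse = ", "))
  rec[REC_COLS]
}

#' Write a patient-record table
#'
#' @param records data.frame of patient records.
#' @param path output path (`.csv` = comma-delimited, otherwise tab).
#' @export
write_patient_records <- function(records, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(records, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
}

#' Read a design configuration file
#'
#' A flat YAML or JSON document with keys matching [design_config()]
#' arguments; the dose grid is a list of `{index, cell_dose_index,
#' partner_dose_index, cell_count}` records and orders are lists of dose
#' indices.
#'
#' @param path file path (`.json` parsed as JSON, otherwise YAML).
#' @return an `fmtdc_design`.
#' @export
read_design <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  g <- x$dose_grid
  if (is.data.frame(g))
    grid <- dose_grid(g$index, g$cell_dose_index, g$partner_dose_index,
                      if (is.null(g$cell_count)) g$cell_dose_index else g$cell_count)
  else
    grid <- dose_grid(vapply(g, `[[`, 0, "index"),
                      vapply(g, `[[`, 0, "cell_dose_index"),
                      vapply(g, `[[`, 0, "partner_dose_index"),
                      vapply(g, function(r)
                        if (is.null(r$cell_count)) r$cell_dose_index
                        else r$cell_count, 0))
  orders <- x$orders
  if (is.matrix(orders)) orders <- asplit(orders, 1)
  orders <- lapply(orders, as.integer)
  os <- ordering_set(orders, as.numeric(x$skeleton),
                     if (is.null(x$order_prior)) NULL
                     else as.numeric(x$order_prior))
  args <- x[intersect(names(x),
                      c("theta_star", "phi_star", "p_ut", "p_uf", "n_max",
                        "c_max", "dlt_window", "prior_sd", "dirichlet_a",
                        "accrual_mean_gap", "rng_seed", "quad_points"))]
  do.call(design_config, c(list(dose_grid = grid, ordering_set = os), args))
}

#' Write a design configuration file
#'
#' @param config an `fmtdc_design`.
#' @param path output path (`.json` writes JSON, otherwise YAML).
#' @export
write_design <- function(config, path) {
  g <- as.data.frame(config$dose_grid)
  x <- list(dose_grid = lapply(seq_len(nrow(g)), function(i)
              as.list(g[i, , drop = FALSE])),
            orders = config$ordering_set$orders,
            skeleton = config$ordering_set$skeleton,
            order_prior = config$ordering_set$prior_weights,
            theta_star = config$theta_star, phi_star = config$phi_star,
            p_ut = config$p_ut, p_uf = config$p_uf,
            n_max = config$n_max, c_max = config$c_max,
            dlt_window = config$dlt_window, prior_sd = config$prior_sd,
            dirichlet_a = config$dirichlet_a,
            accrual_mean_gap = config$accrual_mean_gap)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  else yaml::write_yaml(x, path)
  invisible(path)
}

#' Decision support for an ongoing trial
#'
#' Computes everything the conduct algorithm needs at the current moment
#' from an observed patient-record table: the order posterior and working
#' order, estimated DLT probabilities, MTDC and safe set, both stopping
#' rules, the feasibility state and globally feasible set, and the dose the
#' next patient would receive given their IHFCD.
#'
#' @param records patient-record data.frame (see [read_patient_records()]).
#' @param config an `fmtdc_design`.
#' @param next_ihfcd IHFCD of the patient awaiting assignment (default: the
#'   top cell dose, i.e. no manufacturing restriction).
#' @return list of class `fmtdc_recommendation`.
#' @export
recommend <- function(records, config, next_ihfcd = config$K) {
  v <- validate_config(config)
  if (length(v)) stop("invalid design: ", paste(v, collapse = "; "))
  config <- prepare_design(config)
  tr <- records[!is.na(records$received_dose), , drop = FALSE]
  obs <- tox_obs(tr$received_dose, tr$dlt,
                 linear_weight(tr$followup_time, config$dlt_window, tr$dlt))
  dec <- trial_decision(obs, config)
  feas <- feasibility_state(config$K, config$dirichlet_a)
  for (k in records$ihfcd) feas <- record_ihfcd(feas, k)
  g <- ghfcd(feas, config$phi_star, config$p_uf)
  rec_dose <- if (next_ihfcd >= 1L)
    assign_dose(dec$p_hat, dec$order, next_ihfcd, config,
                tried = sort(unique(tr$received_dose)),
                first = nrow(tr) == 0L)
  else NA_integer_
  structure(list(
    order_posterior = dec$order_posterior$weights, order = dec$order,
    p_hat = dec$p_hat, mtdc = dec$mtdc, safe_set = dec$safe,
    tox_stop = dec$tox_stop, tox_stop_prob = dec$tox_stop_prob,
    feas_counts = feas$counts, ghfcd = g,
    feasible_set = globally_feasible_set(feas, config),
    feas_stop = g == 0L,
    recommended_dose = rec_dose,
    n_treated = nrow(tr), n_expanded = nrow(records)),
    class = "fmtdc_recommendation")
}

#' @export
print.fmtdc_recommendation <- function(x, ...) {
  cat("order posterior:",
      paste(sprintf("%.3f", x$order_posterior), collapse = ", "),
      "-> working order", x$order, "\n")
  cat("estimated DLT probabilities:",
      paste(sprintf("%.3f", x$p_hat), collapse = ", "), "\n")
  cat("MTDC:", x$mtdc, " safe set: {", paste(x$safe_set, collapse = ","),
      "}  feasible set: {", paste(x$feasible_set, collapse = ","), "}\n")
  cat(sprintf("toxicity stop: %s (P = %.3f) | feasibility stop: %s (GHFCD = %d)\n",
              x$tox_stop, x$tox_stop_prob, x$feas_stop, x$ghfcd))
  cat("recommended dose for next patient:", x$recommended_dose, "\n")
  invisible(x)
}

#' Final FMTDC from an observed trial
#'
#' Applies the end-of-trial rule to a completed patient-record table:
#' complete follow-ups, recompute estimates, intersect the safe and
#' globally feasible sets, and pick the dose closest to the target.
#'
#' @inheritParams recommend
#' @param stopped stop reason already triggered during conduct, if any
#'   (`"none"`, `"toxicity"`, `"feasibility"`).
#' @return an `fmtdc_result`.
#' @export
finalize_records <- function(records, config, stopped = "none") {
  v <- validate_config(config)
  if (length(v)) stop("invalid design: ", paste(v, collapse = "; "))
  config <- prepare_design(config)
  state <- new_trial(config)
  tr <- !is.na(records$received_dose)
  state$records <- data.frame(
    patient_id = records$patient_id, arrival_time = records$arrival_time,
    assigned_dose = records$assigned_dose,
    received_dose = records$received_dose, ihfcd = records$ihfcd,
    dlt = records$dlt, dlt_time = records$dlt_time,
    order_used = if (is.null(records$order_used)) NA_integer_
                 else records$order_used)
  for (k in records$ihfcd) state$feas <- record_ihfcd(state$feas, k)
  state$n_treated <- sum(tr)
  state$n_expanded <- nrow(records)
  state$time <- if (nrow(records)) max(records$arrival_time) else 0
  if (stopped != "none") state$stopped <- stopped
  finalize(state, config)
}
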