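cfg <- prepare_design(default_design())

test_that("dose assignment follows the feasibility-capped, no-skipping rule", {
  # the first treated patient always starts at dose 1
  expect_equal(assign_dose(c(0.18, 0.29, 0.43, 0.57), 1, 2, cfg,
                           tried = integer(0)), 1L)
  # MTDC's cell dose within the patient's reach: treat at the MTDC
  expect_equal(assign_dose(c(0.10, 0.18, 0.26, 0.40), 1, 2, cfg,
                           tried = c(1L, 2L, 3L)), 3L)
  # restricted product (IHFCD 1): best dose at cell dose 1 not beyond the
  # MTDC's position
  expect_equal(assign_dose(c(0.10, 0.18, 0.26, 0.40), 1, 1, cfg,
                           tried = c(1L, 2L, 3L)), 2L)
  expect_equal(assign_dose(c(0.13, 0.25, 0.22, 0.40), 1, 1, cfg,
                           tried = c(1L, 2L, 3L)), 2L)
  # no skipping under the working order: dose 4 allowed only once position
  # 3 has been tried
  expect_equal(assign_dose(c(0.10, 0.15, 0.20, 0.26), 1, 2, cfg,
                           tried = c(1L, 2L, 3L)), 4L)
  expect_equal(assign_dose(c(0.10, 0.15, 0.20, 0.26), 1, 2, cfg,
                           tried = c(1L, 2L)), 3L)
  # under order 2 the position-3 dose is d2
  expect_equal(assign_dose(c(0.10, 0.20, 0.15, 0.26), 2, 2, cfg,
                           tried = c(1L, 3L)), 2L)
  expect_error(assign_dose(c(0.1, 0.2, 0.3, 0.4), 1, 0, cfg), "IHFCD")
})

test_that("a manufacture failure excludes the patient but keeps accrual", {
  st <- new_trial(cfg)
  set.seed(2)
  st <- step_trial(st, list(time = 3, ihfcd = 0), cfg)
  expect_true(is.na(st$stopped))
  expect_equal(st$n_treated, 0L)
  expect_equal(st$n_expanded, 1L)
  expect_equal(st$feas$counts, c(1L, 0L, 0L))
  expect_true(is.na(st$records$received_dose[1]))
})

test_that("repeated manufacture failures trigger the feasibility stop", {
  st <- new_trial(cfg)
  set.seed(2)
  st <- step_trial(st, list(time = 3, ihfcd = 0), cfg)
  expect_true(is.na(st$stopped))            # Beta(2,2): P = 0.896 < 0.9
  st <- step_trial(st, list(time = 5, ihfcd = 0), cfg)
  expect_equal(st$stopped, "feasibility")   # Beta(2,3): P = 0.973
  res <- finalize(st, cfg)
  expect_equal(res$fmtdc, 0L)
  expect_equal(res$stop_reason, "feasibility")
  # under final-only checking the same events do not stop mid-trial
  cfg_f <- prepare_design(design_config(
    cfg$dose_grid, cfg$ordering_set, feas_check = "final"))
  st2 <- new_trial(cfg_f)
  set.seed(2)
  st2 <- step_trial(st2, list(time = 3, ihfcd = 0), cfg_f)
  st2 <- step_trial(st2, list(time = 5, ihfcd = 0), cfg_f)
  expect_true(is.na(st2$stopped))
})

test_that("events must respect the trial clock", {
  st <- new_trial(cfg)
  set.seed(3)
  st <- step_trial(st, list(time = 4, ihfcd = 2,
                            dlt_by_dose = c(0L, 0L, 0L, 0L),
                            dlt_time = 5), cfg)
  expect_error(step_trial(st, list(time = 2, ihfcd = 1,
                                   dlt_by_dose = c(0L, 0L, 0L, 0L),
                                   dlt_time = 5), cfg),
               "precedes")
})

test_that("final selection intersects the safe and feasible sets", {
  # toxicity data pointing above dose 2, feasibility limited to cell dose 1
  rec <- data.frame(
    patient_id = 1:12, arrival_time = seq(4, 48, by = 4),
    assigned_dose = c(1, 2, 2, 3, 3, 3, 2, 2, 2, 2, 2, 2),
    received_dose = c(1, 2, 2, 3, 3, 3, 2, 2, 2, 2, 2, 2),
    ihfcd = c(2, 2, 2, 2, 2, 2, 1, 1, 1, 1, 1, 1),
    followup_time = rep(10, 12),
    dlt = c(0, 0, 0, 1, 1, 1, 0, 1, 0, 0, 0, 0),
    dlt_time = c(NA, NA, NA, 3, 5, 7, NA, 4, NA, NA, NA, NA))
  res <- finalize_records(rec, cfg)
  expect_equal(res$omega_sf, intersect(res$safe_set, res$feasible_set))
  expect_true(res$fmtdc %in% res$omega_sf)
  # d3 carried 3/3 DLTs: it cannot be the selected FMTDC
  expect_false(res$fmtdc == 3)
  # an early stop forces FMTDC = 0 regardless of the data
  res0 <- finalize_records(rec, cfg, stopped = "toxicity")
  expect_equal(res0$fmtdc, 0L)
  expect_equal(res0$stop_reason, "toxicity")
})

test_that("simulated trajectories respect feasibility, no-skipping and
           the safe-and-feasible selection constraint", {
  scs <- oc_scenarios()
  grid_k <- cfg$dose_grid$cell_dose_index
  set.seed(11)
  for (i in 1:18) {
    sc <- scs[[sample.int(12, 1)]]
    res <- run_trial(sc, cfg)
    tr <- res$records[!is.na(res$records$received_dose), ]
    if (nrow(tr)) {
      expect_true(all(grid_k[tr$received_dose] <= tr$ihfcd))
      # no-skipping within the working order used at each assignment
      for (r in seq_len(nrow(tr))) {
        m <- tr$order_used[r]
        pos <- match(seq_len(cfg$J), cfg$ordering_set$orders[[m]])
        prevmax <- if (r == 1) 0 else max(pos[tr$received_dose[1:(r - 1)]])
        expect_lte(pos[tr$received_dose[r]], prevmax + 1)
      }
    }
    expect_lte(res$n_treated, cfg$n_max)
    expect_lte(res$n_expanded, cfg$c_max)
    if (res$fmtdc != 0) {
      expect_equal(res$stop_reason, "none")
      expect_true(res$fmtdc %in% res$omega_sf)
    } else {
      expect_true(res$stop_reason != "none" || length(res$omega_sf) == 0)
    }
  }
})

test_that("a replayed seed reproduces the trial ledger exactly", {
  sc <- oc_scenarios()[[2]]
  set.seed(314)
  r1 <- run_trial(sc, cfg)
  set.seed(314)
  r2 <- run_trial(sc, cfg)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$fmtdc, r2$fmtdc)
  expect_identical(r1$order_weights, r2$order_weights)
})
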