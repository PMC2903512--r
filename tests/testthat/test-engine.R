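test_that("annual_to_cycle_prob matches the closed form and rejects bad input", {
  expect_equal(annual_to_cycle_prob(0), 0)
  expect_equal(annual_to_cycle_prob(1), 1)
  # closed form evaluated independently: 1 - (1 - 0.0098)^(12/52)
  expect_equal(annual_to_cycle_prob(0.0098), 0.0022701, tolerance = 1e-4)
  expect_equal(annual_to_cycle_prob(0.5, cycle_weeks = 52), 0.5)
  expect_error(annual_to_cycle_prob(-0.1), "\\[0, 1\\]")
  expect_error(annual_to_cycle_prob(1.1), "\\[0, 1\\]")
})

test_that("relapse probability honours the extrapolation switch", {
  cfg_const <- model_config(relapse_extrapolation = "constant")
  cfg_stop <- model_config(relapse_extrapolation = "stop_after_25_weeks")
  expect_equal(relapse_prob_for_cycle(1, base_params, cfg_const), 0.065)
  expect_equal(relapse_prob_for_cycle(1, base_params, cfg_stop), 0.065)
  expect_equal(relapse_prob_for_cycle(2, base_params, cfg_stop), 0.065)
  expect_equal(relapse_prob_for_cycle(5, base_params, cfg_const), 0.065)
  expect_equal(relapse_prob_for_cycle(5, base_params, cfg_stop), 0)
})

test_that("transition rows are stochastic, DEAD is absorbing, and the
           initial IVIG split matches the pooled response rate", {
  # stochastic-matrix property across cycles and perturbed parameter sets
  for (seed in 1:5) {
    p <- perturb_parameters(base_params, 0.2, seed)
    for (t in c(1, 7, 22)) {
      M <- transition_matrix(t, p, base_config)
      expect_equal(unname(rowSums(M)), rep(1, nrow(M)), tolerance = 1e-12)
      expect_true(all(M >= 0))
    }
  }

  row <- transition_row("DEAD", 3, base_params, base_config)
  expect_equal(unname(row["DEAD"]), 1)
  expect_equal(sum(row), 1)

  # zero mortality isolates the response split
  row1 <- transition_row("IVIG_INITIAL", 1, params_no_mortality, base_config)
  expect_equal(unname(row1["IVIG_RESPONDER"]), 0.473)
  expect_equal(unname(row1["STEROID_ON_1"]), 0.527)

  expect_error(transition_row("NOT_A_STATE", 1, base_params, base_config),
               "unknown state")
})

test_that("degenerate limits: no events means no movement", {
  # steroid arm with no AEs and no mortality stays put
  cfg <- model_config(arm = "steroid")
  p <- zero_ae(params_no_mortality)
  tr <- run_cohort(cfg, p)
  expect_equal(unname(tr$occupancy[, "STEROID_ON_1"]),
               c(1, rep(0, 21)))
  expect_equal(unname(tr$occupancy[22, "STEROID_ON_3"]), 1)
  expect_equal(unname(aggregate_states(tr$occupancy)[, "STEROID_ON"]),
               rep(1, 22))

  # IVIG arm with no relapse and no mortality holds responders at 0.473
  p2 <- params_no_mortality
  p2$relapse_per_cycle <- 0
  tr2 <- run_cohort(model_config(arm = "IVIG"), p2)
  expect_equal(unname(tr2$occupancy[2:22, "IVIG_RESPONDER"]),
               rep(0.473, 21))
})

test_that("two-cycle IVIG occupancy equals the hand-multiplied chain", {
  cfg <- model_config(arm = "IVIG")
  tr <- run_cohort(cfg, base_params)

  # independent arithmetic from the raw inputs
  q54 <- 1 - (1 - life_table_prob(base_params$life_table, 54))^(12 / 52)
  resp2 <- (1 - q54) * 0.473
  ster2 <- (1 - q54) * 0.527
  expect_equal(unname(tr$occupancy[2, "IVIG_RESPONDER"]), resp2,
               tolerance = 1e-12)
  expect_equal(unname(tr$occupancy[2, "STEROID_ON_1"]), ster2,
               tolerance = 1e-12)
  expect_equal(unname(tr$occupancy[2, "DEAD"]), q54, tolerance = 1e-12)

  # cycle 3: responders decay by relapse, steroids shed AE mass sequentially
  p_ae <- 1 - (1 - base_params$ae_annual)^(12 / 52)
  resp3 <- resp2 * (1 - q54) * (1 - 0.065)
  frac3 <- ster2 * (1 - q54) * p_ae[["fracture"]]
  diab3 <- ster2 * (1 - q54) * (1 - p_ae[["fracture"]]) * p_ae[["diabetes"]]
  expect_equal(unname(tr$occupancy[3, "IVIG_RESPONDER"]), resp3,
               tolerance = 1e-12)
  expect_equal(unname(tr$occupancy[3, "FRACTURE_Y1_1"]), frac3,
               tolerance = 1e-12)
  expect_equal(unname(tr$occupancy[3, "DIABETES_Y1_1"]), diab3,
               tolerance = 1e-12)
})

test_that("occupancy is conserved and death is monotone for any inputs", {
  for (seed in 1:5) {
    p <- perturb_parameters(base_params, 0.25, seed)
    for (arm in c("IVIG", "steroid")) {
      tr <- run_cohort(model_config(arm = arm), p)
      expect_equal(unname(rowSums(tr$occupancy)), rep(1, 22),
                   tolerance = 1e-9)
      expect_true(all(diff(tr$occupancy[, "DEAD"]) >= -1e-12))
    }
  }
})

test_that("without extrapolated relapse, responder occupancy is constant
           after cycle 2 (absent mortality)", {
  cfg <- model_config(arm = "IVIG",
                      relapse_extrapolation = "stop_after_25_weeks")
  tr <- run_cohort(cfg, params_no_mortality)
  resp <- tr$occupancy[, "IVIG_RESPONDER"]
  expect_equal(unname(resp[2]), 0.473)
  expect_equal(unname(resp[3:22]), rep(0.473 * (1 - 0.065), 20),
               tolerance = 1e-12)
})

test_that("the switch-to-IVIG scenario reroutes tunnel exits in the steroid
           arm only", {
  cfg_sw <- model_config(arm = "steroid",
                         steroid_switch_to_ivig_after_ae = TRUE)
  M <- transition_matrix(10, base_params, cfg_sw)
  for (from in c("FRACTURE_Y1_4", "DIABETES_Y1_4", "GLAUCOMA_Y1_4",
                 "INFECTION_ACUTE"))
    expect_gt(M[from, "IVIG_INITIAL"], 0.8)
  # cataract keeps its permanent post-surgical state
  expect_gt(M["CATARACT_WAIT", "CATARACT_POST"], 0.9)
  expect_equal(M["CATARACT_WAIT", "IVIG_INITIAL"], 0)

  # the IVIG arm is unaffected by the flag
  cfg_ivig <- model_config(arm = "IVIG",
                           steroid_switch_to_ivig_after_ae = TRUE)
  M2 <- transition_matrix(10, base_params, cfg_ivig)
  expect_equal(M2["INFECTION_ACUTE", "IVIG_INITIAL"], 0)
  expect_gt(M2["INFECTION_ACUTE", "OFF_TREATMENT"], 0.8)
})

test_that("cohort trace agrees with a seeded microsimulation of 1e5 patients", {
  cfg <- model_config(arm = "IVIG")
  tr <- run_cohort(cfg, base_params)
  n_ind <- 1e5
  ms <- microsim_occupancy(cfg, base_params, n_ind, seed = 11,
                           record_cycles = c(1, 5, 10))
  for (t in c(1, 5, 10)) {
    pc <- tr$occupancy[t, ]
    se <- sqrt(pmax(pc * (1 - pc), 1e-12) / n_ind)
    expect_true(all(abs(ms[[as.character(t)]] - pc) <= 3 * se + 1e-9),
                label = sprintf("microsim within 3 SE at cycle %d", t))
  }
})

test_that("horizon scenarios use whole 12-week cycles", {
  expect_equal(n_cycles(model_config(horizon_years = 5)), 22L)
  expect_equal(n_cycles(model_config(horizon_years = 1)), 4L)
  expect_equal(n_cycles(model_config(horizon_years = 20)), 87L)
  expect_equal(nrow(run_cohort(model_config(horizon_years = 1),
                               base_params)$occupancy), 4L)
})
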