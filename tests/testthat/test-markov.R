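test_that("annual-to-monthly conversion compounds back exactly", {
  expect_equal(annual_to_monthly_prob(0), 0)
  for (p in c(0.004, 0.108, 0.121, 0.162, 0.9)) {
    expect_equal(1 - (1 - annual_to_monthly_prob(p))^12, p, tolerance = 1e-12)
  }
  expect_gt(annual_to_monthly_prob(0.162), annual_to_monthly_prob(0.121))
  expect_error(annual_to_monthly_prob(1), "\\[0, 1\\)")
})

test_that("initial distributions follow screening and enrollment", {
  occ <- initial_distribution("MDPP", base_params)
  expect_equal(unname(occ[c("RF_NEG", "RF_POS_ENROLLED", "RF_POS_NOT_ENROLLED")]),
               c(0.690, 0.31 * 0.47, 0.31 * 0.53))
  expect_equal(sum(occ), 1)
  expect_equal(unname(occ[c("STABLE_DM", "COMPLICATED_DM", "DEAD")]), c(0, 0, 0))

  uc <- initial_distribution("USUAL_CARE", base_params)
  expect_equal(unname(uc[["RF_POS_NOT_ENROLLED"]]), 0.31)
  expect_equal(unname(uc[["RF_POS_ENROLLED"]]), 0)

  # no screening positives -> everyone risk-factor-negative
  p0 <- set_base_values(base_params, c(p_screen_positive = 0))
  expect_equal(unname(initial_distribution("MDPP", p0)[["RF_NEG"]]), 1)
  # enrollment does not touch the usual-care arm
  p1 <- set_base_values(base_params, c(p_enroll = 1))
  expect_equal(initial_distribution("USUAL_CARE", p1),
               initial_distribution("USUAL_CARE", base_params))
})

test_that("transition matrices are row-stochastic with absorbing death", {
  for (year in 1:3) {
    M <- build_transition_matrix("MDPP", year, 55 + year - 1, base_params,
                                 base_mort)
    expect_equal(unname(rowSums(M)), rep(1, 6), tolerance = 1e-12)
    expect_true(all(M >= 0 & M <= 1))
    expect_equal(unname(M["DEAD", ]), c(0, 0, 0, 0, 0, 1))
  }
})

test_that("resolution entries follow the scenario mode and model year", {
  b <- base_values(base_params)
  surv <- function(M, s) 1 - M[s, "DEAD"]
  # base: enrolled resolve at the in-program rate in year 1 only
  M1 <- build_transition_matrix("MDPP", 1, 55, base_params, base_mort)
  expect_equal(M1["RF_POS_ENROLLED", "RF_NEG"],
               surv(M1, "RF_POS_ENROLLED") * annual_to_monthly_prob(0.162))
  M2 <- build_transition_matrix("MDPP", 2, 56, base_params, base_mort)
  expect_equal(M2["RF_POS_ENROLLED", "RF_NEG"],
               surv(M2, "RF_POS_ENROLLED") * annual_to_monthly_prob(0.121))
  expect_equal(M2["RF_POS_ENROLLED", "RF_NEG"] / surv(M2, "RF_POS_ENROLLED"),
               M2["RF_POS_NOT_ENROLLED", "RF_NEG"] / surv(M2, "RF_POS_NOT_ENROLLED"))
  # no resolution after year 1 for anyone
  fl <- scenario_flags("none_after_year1_both")
  M2b <- build_transition_matrix("MDPP", 2, 56, base_params, base_mort, fl)
  expect_equal(unname(M2b["RF_POS_ENROLLED", "RF_NEG"]), 0)
  expect_equal(unname(M2b["RF_POS_NOT_ENROLLED", "RF_NEG"]), 0)
  # enrolled-only variant keeps the non-enrolled rate
  fl2 <- scenario_flags("none_after_year1_enrolled_only")
  M2c <- build_transition_matrix("MDPP", 2, 56, base_params, base_mort, fl2)
  expect_equal(unname(M2c["RF_POS_ENROLLED", "RF_NEG"]), 0)
  expect_gt(M2c["RF_POS_NOT_ENROLLED", "RF_NEG"], 0)
  # diabetes risk differs by enrollment
  expect_equal(M1["RF_POS_ENROLLED", "STABLE_DM"],
               surv(M1, "RF_POS_ENROLLED") * annual_to_monthly_prob(b[["p_dm_in_program_yr"]]))
  expect_equal(M1["RF_POS_NOT_ENROLLED", "STABLE_DM"],
               surv(M1, "RF_POS_NOT_ENROLLED") * annual_to_monthly_prob(b[["p_dm_rfpos_no_program_yr"]]))
})

test_that("expected multiplier has product form and unit fixed point", {
  expect_equal(expected_multiplier(c(0.3, 0.9), c(1, 1)), 1)
  expect_equal(expected_multiplier(0.75, 1.14), 1.105)
  expect_equal(expected_multiplier(c(0.75, 0.271), c(1.14, 0.82)),
               (1 + 0.75 * 0.14) * (1 - 0.271 * 0.18))
})

test_that("cycle rewards: screening/program costs only at cycle 0 of mDPP", {
  rw_m <- cycle_rewards("MDPP", base_params)
  rw_u <- cycle_rewards("USUAL_CARE", base_params)
  expect_equal(sum(rw_u$onetime), 0)
  occ <- initial_distribution("MDPP", base_params)
  expect_equal(sum(occ * rw_m$onetime),
               0.31 * 35 + 0.69 * 32 + 0.31 * 0.47 * 219)
  # dead accrues nothing
  expect_equal(unname(rw_m$cost[["DEAD"]]), 0)
  expect_equal(unname(rw_m$utility[["DEAD"]]), 0)
  # equalized utilities raise the usual-care RF+ weight to the program value
  rw_eq <- cycle_rewards("USUAL_CARE", base_params,
                         scenario_flags(equalize_rfpos_utilities = TRUE))
  expect_equal(rw_eq$utility[["RF_POS_NOT_ENROLLED"]],
               rw_eq$utility[["RF_POS_ENROLLED"]])
})

test_that("cohort trace conserves mass with monotone death occupancy", {
  for (arm in strategy_arms()) {
    tr <- run_cohort(arm, base_config, base_params, base_mort)
    expect_equal(unname(rowSums(tr$occupancy)), rep(1, 37), tolerance = 1e-12)
    expect_false(is.unsorted(tr$occupancy[, "DEAD"]))
    expect_true(all(tr$occupancy >= 0))
  }
})

test_that("frozen cohort with zero mortality gives the closed-form QALYs", {
  m0 <- mortality_model(zero_life_table(), fraction_female = 0.75)
  p <- set_base_values(frozen_params(), c(p_screen_positive = 0))
  cfg <- model_config(annual_discount_rate = 0)
  tr <- run_cohort("USUAL_CARE", cfg, p, m0)
  expect_equal(sum(tr$discounted_qaly_per_cycle), 3 * 0.88)
  expect_equal(sum(tr$discounted_cost_per_cycle), 3 * 616)
  expect_equal(unname(tr$occupancy[37, "DEAD"]), 0)
})

test_that("zero mortality keeps the dead state empty at every cycle", {
  m0 <- mortality_model(zero_life_table(), fraction_female = 0.75)
  tr <- run_cohort("MDPP", base_config, base_params, m0)
  expect_equal(unname(tr$occupancy[, "DEAD"]), rep(0, 37))
})

test_that("discounting strictly reduces totals", {
  tr0 <- run_cohort("MDPP", model_config(annual_discount_rate = 0),
                    base_params, base_mort)
  tr3 <- run_cohort("MDPP", base_config, base_params, base_mort)
  expect_lt(sum(tr3$discounted_cost_per_cycle), sum(tr0$discounted_cost_per_cycle))
  expect_lt(sum(tr3$discounted_qaly_per_cycle), sum(tr0$discounted_qaly_per_cycle))
})

test_that("summaries track incidence by inflow with complication <= diabetes", {
  for (arm in strategy_arms()) {
    out <- summarize_trace(run_cohort(arm, base_config, base_params, base_mort))
    expect_gte(out$cum_diabetes_incidence, out$cum_complication_incidence)
    expect_true(out$cum_diabetes_incidence >= 0 && out$cum_diabetes_incidence <= 1)
  }
  # no diabetes inflow when every diabetes rate is zero
  out0 <- summarize_trace(run_cohort("MDPP", base_config, frozen_params(), base_mort))
  expect_equal(out0$cum_diabetes_incidence, 0)
  expect_equal(out0$cum_complication_incidence, 0)
})

test_that("tidy trace export has one row per cycle and state", {
  tr <- run_cohort("MDPP", base_config, base_params, base_mort)
  df <- as.data.frame(tr)
  expect_equal(nrow(df), 37 * 6)
  expect_setequal(unique(df$state), health_states())
  expect_equal(sum(df$occupancy), 37, tolerance = 1e-9)
})

test_that("the intervention arm costs more and yields more QALYs at base", {
  out_m <- summarize_trace(run_cohort("MDPP", base_config, base_params, base_mort))
  out_u <- summarize_trace(run_cohort("USUAL_CARE", base_config, base_params, base_mort))
  expect_gt(out_m$total_discounted_cost, out_u$total_discounted_cost)
  expect_gt(out_m$total_discounted_qaly, out_u$total_discounted_qaly)
  expect_lt(out_m$cum_diabetes_incidence, out_u$cum_diabetes_incidence)
})
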