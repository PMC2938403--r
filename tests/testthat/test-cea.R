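mk_outcome <- function(cost, qaly, arm = "MDPP") {
  structure(list(arm = arm, total_discounted_cost = cost,
                 total_discounted_qaly = qaly,
                 cum_diabetes_incidence = 0, cum_complication_incidence = 0),
            class = "arm_outcome")
}

test_that("ICER arithmetic and dominance tagging", {
  r <- compute_icer(mk_outcome(2600, 2.45), mk_outcome(2500, 2.40))
  expect_equal(r$icer, 100 / 0.05)
  expect_equal(r$dominance, "none")

  dom <- compute_icer(mk_outcome(2490, 2.41), mk_outcome(2500, 2.40))
  expect_equal(dom$dominance, "mdpp_dominant")
  expect_true(is.na(dom$icer))

  dtd <- compute_icer(mk_outcome(2600, 2.39), mk_outcome(2500, 2.40))
  expect_equal(dtd$dominance, "mdpp_dominated")

  # no QALY difference but extra cost: tagged, never divided
  inf <- compute_icer(mk_outcome(2600, 2.40), mk_outcome(2500, 2.40))
  expect_equal(inf$dominance, "mdpp_dominated")
  expect_true(is.na(inf$icer))
})

test_that("null-effect program yields exactly zero deltas", {
  r <- evaluate_null <- run_base_case(
    model_config(scenario = scenario_flags(equalize_rfpos_utilities = TRUE)),
    null_effect_params(), base_mort)
  expect_lt(abs(r$delta_cost), 1e-9)
  expect_lt(abs(r$delta_qaly), 1e-12)
  expect_equal(r$dominance, "none")
})

test_that("ICER is invariant to a constant cost added to every state", {
  base <- run_base_case(base_config, base_params, base_mort)
  shift <- function(arm) {
    summarize_trace(run_cohort(arm, base_config, base_params, base_mort,
                               cost_offset = 50))
  }
  shifted <- compute_icer(shift("MDPP"), shift("USUAL_CARE"))
  expect_equal(shifted$icer, base$icer, tolerance = 1e-9)
  expect_gt(shifted$cost_mdpp, base$cost_mdpp)
})

test_that("one-way sensitivity honours ranges and rejects fixed parameters", {
  tor <- one_way_sensitivity(base_config, base_params, base_mort,
                             parameters = c("p_resolve_no_program_yr",
                                            "u_rfpos_usual"))
  expect_equal(tor$low_input[tor$parameter == "p_resolve_no_program_yr"], 0.032)
  expect_equal(tor$high_input[tor$parameter == "p_resolve_no_program_yr"], 0.259)
  expect_false(is.unsorted(rev(tor$swing)))
  expect_error(one_way_sensitivity(base_config, base_params, base_mort,
                                   parameters = "rr_death_rfneg"),
               "fixed")
})

test_that("raising the no-program resolution rate raises the ICER", {
  icer_at <- function(v) {
    evaluate <- run_base_case(base_config,
                              set_base_values(base_params,
                                              c(p_resolve_no_program_yr = v)),
                              base_mort)
    evaluate$icer
  }
  vals <- vapply(c(0.05, 0.121, 0.20, 0.259), icer_at, numeric(1))
  expect_false(is.unsorted(vals))
})

test_that("PSA is reproducible under a fixed seed and stays in support", {
  p1 <- run_psa(base_config, base_params, base_mort, n = 25, seed = 99)
  p2 <- run_psa(base_config, base_params, base_mort, n = 25, seed = 99)
  expect_identical(p1$delta_cost, p2$delta_cost)
  expect_identical(attr(p1, "samples"), attr(p2, "samples"))
  s <- attr(p1, "samples")
  expect_true(all(s[, "u_rfneg"] >= 0.84 & s[, "u_rfneg"] <= 0.92))
  expect_true(all(s[, "p_enroll"] > 0 & s[, "p_enroll"] < 1))
  expect_true(all(s[, "rr_death_rfpos"] > 0))
})

test_that("PSA with all distributions collapsed reproduces the base case", {
  base <- run_base_case(base_config, base_params, base_mort)
  psa <- run_psa(base_config, fix_all_params(), base_mort, n = 2, seed = 1)
  expect_equal(psa$delta_cost, rep(base$delta_cost, 2))
  expect_equal(psa$delta_qaly, rep(base$delta_qaly, 2))
})

test_that("CEAC is a valid, threshold-monotone probability curve", {
  psa <- run_psa(base_config, base_params, base_mort, n = 200, seed = 3)
  cc <- ceac(psa, c(0, 10000, 20000, 50000, 1e7))
  expect_true(all(cc$probability_mdpp_preferred >= 0 &
                    cc$probability_mdpp_preferred <= 1))
  expect_equal(cc$probability_mdpp_preferred[cc$threshold == 0],
               mean(psa$delta_cost < 0))
  if (all(psa$delta_qaly > 0)) {
    expect_false(is.unsorted(cc$probability_mdpp_preferred))
    expect_equal(cc$probability_mdpp_preferred[cc$threshold == 1e7], 1)
  }
})

test_that("scenario catalogue dispatches and rejects unknown names", {
  expect_error(run_scenario("nonesuch", base_config, base_params, base_mort),
               "available")
  r_eq <- run_scenario("equal_rfpos_utilities", base_config, base_params, base_mort)
  r_base <- run_scenario("base", base_config, base_params, base_mort)
  # removing the RF+ utility advantage shrinks the QALY gain
  expect_lt(r_eq$delta_qaly, r_base$delta_qaly)
  expect_gt(r_eq$icer, r_base$icer)
  # stopping enrolled resolution after year 1 hurts the intervention
  r_en <- run_scenario("no_resolution_after_y1_enrolled_only",
                       base_config, base_params, base_mort)
  expect_gt(r_en$icer, r_base$icer)
})
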