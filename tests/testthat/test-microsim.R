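test_that("microsimulation is deterministic under a fixed seed", {
  a <- simulate_individuals("MDPP", base_config, base_params, base_mort,
                            n = 500, seed = 21)
  b <- simulate_individuals("MDPP", base_config, base_params, base_mort,
                            n = 500, seed = 21)
  expect_identical(a$mean_cost, b$mean_cost)
  expect_identical(a$mean_qaly, b$mean_qaly)
})

test_that("with all rates and mortality zero the path never moves", {
  m0 <- mortality_model(zero_life_table(), fraction_female = 0.75)
  sim <- simulate_individuals("USUAL_CARE", base_config, frozen_params(), m0,
                              n = 1, seed = 5, keep_paths = TRUE)
  expect_equal(length(unique(as.vector(sim$paths))), 1L)
  expect_equal(sim$cum_diabetes_incidence, 0)
})

test_that("cohort engine matches the microsimulation within Monte-Carlo error", {
  n <- 20000
  for (arm in strategy_arms()) {
    coh <- summarize_trace(run_cohort(arm, base_config, base_params, base_mort))
    sim <- simulate_individuals(arm, base_config, base_params, base_mort,
                                n = n, seed = 31)
    expect_lt(abs(sim$mean_qaly - coh$total_discounted_qaly), 3 * sim$se_qaly)
    expect_lt(abs(sim$mean_cost - coh$total_discounted_cost), 3 * sim$se_cost)
    expect_lt(abs(sim$cum_diabetes_incidence - coh$cum_diabetes_incidence),
              3 * sim$se_dm)
  }
})

test_that("oracle agreement holds across random parameter draws", {
  set.seed(77)
  varied <- names(base_params)[vapply(base_params,
                                      function(s) s$family != "fixed",
                                      logical(1))]
  for (k in 1:5) {
    draw <- vapply(base_params[varied],
                   function(s) fit_distribution(s)(1), numeric(1))
    p_k <- set_base_values(base_params, draw)
    if (length(validate_parameters(p_k))) next
    cfg <- base_config
    cfg$starting_age <- as.integer(round(base_values(p_k)[["starting_age"]]))
    m_k <- mortality_model(base_mort$life_table,
                           base_values(p_k)[["fraction_female"]])
    coh <- summarize_trace(run_cohort("MDPP", cfg, p_k, m_k))
    sim <- simulate_individuals("MDPP", cfg, p_k, m_k, n = 8000, seed = 100 + k)
    expect_lt(abs(sim$mean_qaly - coh$total_discounted_qaly), 3.5 * sim$se_qaly)
    expect_lt(abs(sim$mean_cost - coh$total_discounted_cost), 3.5 * sim$se_cost)
  }
})

test_that("synthetic cohort export is tidy and round-trips", {
  sim <- simulate_individuals("MDPP", base_config, base_params, base_mort,
                              n = 10, seed = 8, keep_paths = TRUE)
  f <- withr::local_tempfile(fileext = ".csv")
  export_synthetic_cohort(sim, f)
  df <- read.csv(f, stringsAsFactors = FALSE)
  expect_equal(nrow(df), 10 * 37)
  expect_equal(names(df), c("id", "cycle", "state", "cost_cum", "qaly_cum"))
  expect_setequal(unique(df$id), 1:10)
  expect_equal(df$state, health_states()[as.vector(t(sim$paths))])
  expect_equal(df$cost_cum, as.vector(t(sim$cost_path)))
  # once dead, stays dead
  for (i in 1:10) {
    s <- df$state[df$id == i]
    dead_at <- which(s == "DEAD")
    if (length(dead_at)) expect_true(all(s[min(dead_at):length(s)] == "DEAD"))
  }
})

test_that("export without retained paths fails with guidance", {
  sim <- simulate_individuals("MDPP", base_config, base_params, base_mort,
                              n = 5, seed = 9)
  expect_error(export_synthetic_cohort(sim, tempfile()), "keep_paths")
})
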