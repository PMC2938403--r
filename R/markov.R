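# Cohort engine: per-cycle transition matrices for each strategy arm,
# 36-cycle propagation, and discounted cost/QALY accrual.

#' Health states of the natural-history model
#'
#' Six states: risk-factor-negative, risk-factor-positive enrolled in the
#' prevention program, risk-factor-positive not enrolled, stable diabetes,
#' complicated diabetes, and dead. The dead state is absorbing; the
#' enrolled state can only be populated at cycle 0 of the intervention arm
#' (screening and enrollment happen once, at model start).
#'
#' @return Character vector of state names, in matrix order.
#' @export
health_states <- function() {
  c("RF_NEG", "RF_POS_ENROLLED", "RF_POS_NOT_ENROLLED",
    "STABLE_DM", "COMPLICATED_DM", "DEAD")
}

#' Strategy arms
#'
#' @return Character vector `c("MDPP", "USUAL_CARE")`: the community
#'   lifestyle-intervention arm and the comparator with no screening
#'   program and no intervention.
#' @export
strategy_arms <- function() c("MDPP", "USUAL_CARE")

#' Convert an annual probability to a monthly one
#'
#' Constant-hazard conversion `1 - (1 - p)^(1/12)`: compounding the monthly
#' probability over twelve cycles recovers the annual probability exactly.
#'
#' @param p_annual Annual probability in `[0, 1)`.
#' @return Monthly probability.
#' @export
#' @examples
#' p <- annual_to_monthly_prob(0.108)
#' 1 - (1 - p)^12 # 0.108
annual_to_monthly_prob <- function(p_annual) {
  if (any(p_annual < 0 | p_annual >= 1)) {
    stop("annual probability must be in [0, 1)")
  }
  1 - (1 - p_annual)^(1 / 12)
}

#' Initial state distribution of an arm
#'
#' The cohort is screened once at model start. In the intervention arm,
#' those screening risk-factor-positive enroll with probability `p_enroll`;
#' under usual care there is no program, so all risk-factor-positive
#' subjects are non-enrolled. No one starts with diabetes or dead.
#'
#' @param arm `"MDPP"` or `"USUAL_CARE"`.
#' @param p A `parameter_set`.
#' @return Named occupancy vector over [health_states()] summing to 1.
#' @export
initial_distribution <- function(arm, p) {
  arm <- match.arg(arm, strategy_arms())
  b <- base_values(p)
  occ <- stats::setNames(numeric(6), health_states())
  occ["RF_NEG"] <- 1 - b[["p_screen_positive"]]
  if (arm == "MDPP") {
    occ["RF_POS_ENROLLED"] <- b[["p_screen_positive"]] * b[["p_enroll"]]
    occ["RF_POS_NOT_ENROLLED"] <- b[["p_screen_positive"]] * (1 - b[["p_enroll"]])
  } else {
    occ["RF_POS_NOT_ENROLLED"] <- b[["p_screen_positive"]]
  }
  occ
}

# Annual metabolic-syndrome resolution rate for an RF+ state, by enrollment,
# model year and scenario mode. Enrolled subjects resolve at the in-program
# rate in year 1 and at the no-program rate thereafter (base case).
resolution_rate_yr <- function(enrolled, model_year, b, flags) {
  mode <- flags$mets_resolution_mode
  if (model_year <= 1) {
    return(if (enrolled) b[["p_resolve_in_program_yr"]] else b[["p_resolve_no_program_yr"]])
  }
  switch(mode,
    base = b[["p_resolve_no_program_yr"]],
    none_after_year1_both = 0,
    none_after_year1_enrolled_only =
      if (enrolled) 0 else b[["p_resolve_no_program_yr"]]
  )
}

#' Build the monthly transition matrix for one arm, year and age
#'
#' Competing risks within a cycle are ordered death-first: each alive state
#' dies with the age- and state-specific monthly probability (baseline
#' mortality times the state's relative risk on the hazard scale); the
#' remaining transitions are applied conditional on survival, with staying
#' put as the residual. Annual input probabilities are converted to monthly
#' via [annual_to_monthly_prob()].
#'
#' @param arm `"MDPP"` or `"USUAL_CARE"` (affects nothing in the matrix
#'   itself beyond which states carry mass, but is kept for provenance).
#' @param model_year 1, 2 or 3 (years beyond 3 use the year-2+ rates).
#' @param age Cohort age in whole years this cycle.
#' @param p A `parameter_set`.
#' @param m A [mortality_model()].
#' @param flags A [scenario_flags()].
#' @return 6 x 6 row-stochastic matrix over [health_states()].
#' @export
build_transition_matrix <- function(arm, model_year, age, p, m,
                                    flags = scenario_flags()) {
  arm <- match.arg(arm, strategy_arms())
  b <- base_values(p)
  st <- health_states()
  M <- matrix(0, 6, 6, dimnames = list(st, st))

  q_die <- c(
    RF_NEG = monthly_death_prob(m, age, b[["rr_death_rfneg"]]),
    RF_POS_ENROLLED = monthly_death_prob(m, age, b[["rr_death_rfpos"]]),
    RF_POS_NOT_ENROLLED = monthly_death_prob(m, age, b[["rr_death_rfpos"]]),
    STABLE_DM = monthly_death_prob(m, age, b[["rr_death_stable_dm"]]),
    COMPLICATED_DM = monthly_death_prob(m, age, b[["rr_death_complicated_dm"]])
  )

  # survival-conditional monthly exit probabilities per state
  exits <- list(
    RF_NEG = c(
      STABLE_DM = annual_to_monthly_prob(b[["p_dm_rfneg_yr"]]),
      RF_POS_NOT_ENROLLED = annual_to_monthly_prob(b[["p_become_rfpos_yr"]])
    ),
    RF_POS_ENROLLED = c(
      STABLE_DM = annual_to_monthly_prob(b[["p_dm_in_program_yr"]]),
      RF_NEG = annual_to_monthly_prob(
        resolution_rate_yr(TRUE, model_year, b, flags))
    ),
    RF_POS_NOT_ENROLLED = c(
      STABLE_DM = annual_to_monthly_prob(b[["p_dm_rfpos_no_program_yr"]]),
      RF_NEG = annual_to_monthly_prob(
        resolution_rate_yr(FALSE, model_year, b, flags))
    ),
    STABLE_DM = c(
      COMPLICATED_DM = annual_to_monthly_prob(b[["p_progress_complicated_yr"]])
    ),
    COMPLICATED_DM = numeric(0)
  )

  for (s in names(exits)) {
    ex <- exits[[s]]
    if (sum(ex) > 1) {
      stop(sprintf("combined monthly exit probability from %s exceeds 1", s))
    }
    M[s, "DEAD"] <- q_die[[s]]
    surv <- 1 - q_die[[s]]
    for (to in names(ex)) M[s, to] <- surv * ex[[to]]
    M[s, s] <- surv * (1 - sum(ex))
  }
  M["DEAD", "DEAD"] <- 1
  M
}

#' Expected cost multiplier over a cohort profile
#'
#' Each cost multiplier applies to the fraction of the cohort with the
#' corresponding characteristic, so the cohort-expected factor for a state
#' cost is the product over conditions of `1 + prevalence * (multiplier -
#' 1)` (exact under independent characteristics, since the expectation of a
#' product of independent factors is the product of expectations).
#'
#' @param prevalences Numeric vector of condition prevalences in `[0, 1]`.
#' @param multipliers Numeric vector (same length) of cost multipliers.
#' @return Scalar expected multiplier.
#' @export
#' @examples
#' expected_multiplier(0.75, 1.14) # 1.105
expected_multiplier <- function(prevalences, multipliers) {
  stopifnot(length(prevalences) == length(multipliers),
            all(prevalences >= 0 & prevalences <= 1), all(multipliers > 0))
  prod(1 + prevalences * (multipliers - 1))
}

# Expected demographic/comorbidity multipliers for the three multiplied
# state costs. Female/African American apply to RF+, stable and complicated
# diabetes; comorbidity multipliers apply to complicated diabetes only.
state_cost_multipliers <- function(p) {
  b <- base_values(p)
  pr <- cohort_profile(p)
  list(
    rfpos = expected_multiplier(
      c(pr$fraction_female, pr$fraction_african_american),
      c(b[["m_rfpos_female"]], b[["m_rfpos_aa"]])),
    dm = expected_multiplier(
      c(pr$fraction_female, pr$fraction_african_american),
      c(b[["m_dm_female"]], b[["m_dm_aa"]])),
    comp = expected_multiplier(
      c(pr$fraction_female, pr$fraction_african_american, pr$prev_angina,
        pr$prev_htn_treated, pr$prev_cardiac_arrest_mi, pr$prev_stroke,
        pr$prev_pvd),
      c(b[["m_comp_female"]], b[["m_comp_aa"]], b[["m_comp_angina"]],
        b[["m_comp_htn"]], b[["m_comp_mi"]], b[["m_comp_stroke"]],
        b[["m_comp_pvd"]]))
  )
}

#' Per-cycle rewards and one-time costs
#'
#' Returns per-state per-cycle costs (annual state cost divided by 12, with
#' the expected demographic/comorbidity multipliers applied) and utilities
#' (annual utility divided by 12), plus the one-time cycle-0 cost vector:
#' in the intervention arm, screening costs for everyone (positive or
#' negative result) and the program fee for the enrolled mass; usual care
#' has no screening program, so no one-time costs.
#'
#' @param arm `"MDPP"` or `"USUAL_CARE"`.
#' @param p A `parameter_set`.
#' @param flags A [scenario_flags()]; `equalize_rfpos_utilities` replaces
#'   the usual-care risk-factor-positive utility with the in-program value.
#' @return List with named vectors `cost` (dollars/cycle), `utility`
#'   (QALY/cycle) and `onetime` (dollars, applied to cycle-0 occupancy).
#' @export
cycle_rewards <- function(arm, p, flags = scenario_flags()) {
  arm <- match.arg(arm, strategy_arms())
  b <- base_values(p)
  mult <- state_cost_multipliers(p)
  st <- health_states()

  u_rfpos_usual <- if (flags$equalize_rfpos_utilities) {
    b[["u_rfpos_program"]]
  } else {
    b[["u_rfpos_usual"]]
  }
  utility <- stats::setNames(c(
    b[["u_rfneg"]], b[["u_rfpos_program"]], u_rfpos_usual,
    b[["u_stable_dm"]], b[["u_complicated_dm"]], 0
  ) / 12, st)

  cost <- stats::setNames(c(
    b[["c_rfneg_yr"]],
    b[["c_rfpos_yr"]] * mult$rfpos,
    b[["c_rfpos_yr"]] * mult$rfpos,
    b[["c_dm_base_yr"]] * mult$dm,
    b[["c_complicated_dm_base_yr"]] * mult$comp,
    0
  ) / 12, st)

  onetime <- stats::setNames(numeric(6), st)
  if (arm == "MDPP") {
    onetime["RF_NEG"] <- b[["c_screen_negative"]]
    onetime["RF_POS_ENROLLED"] <- b[["c_screen_positive"]] + b[["c_program"]]
    onetime["RF_POS_NOT_ENROLLED"] <- b[["c_screen_positive"]]
  }
  list(cost = cost, utility = utility, onetime = onetime)
}

#' Run the cohort through the model horizon
#'
#' Propagates the initial occupancy through the monthly transition matrices
#' (one matrix per model year, since the input rates and the cohort's age
#' change yearly), accruing discounted costs and QALYs at cycle start with
#' discount factor `(1 + r)^(-t/12)` at cycle `t`. No half-cycle correction
#' is applied. Cumulative diabetes and complication incidence are tracked by
#' inflow accounting (probability mass crossing into the stable-diabetes and
#' complicated-diabetes states), not point occupancy.
#'
#' @param arm `"MDPP"` or `"USUAL_CARE"`.
#' @param config A [model_config()].
#' @param p A `parameter_set`; the scenario's `parameter_overrides` are
#'   applied on entry.
#' @param m A [mortality_model()]; if `NULL`, built from the bundled life
#'   table with the parameter set's female fraction.
#' @param flags Scenario flags; defaults to `config$scenario`.
#' @param cost_offset Constant added to every state's per-cycle cost
#'   (including dead); useful for invariance checks.
#' @return A `cohort_trace` with the occupancy matrix (`horizon + 1` rows),
#'   discounted per-cycle cost and QALY vectors, and incidence inflows.
#' @export
run_cohort <- function(arm, config, p, m = NULL, flags = config$scenario,
                       cost_offset = 0) {
  arm <- match.arg(arm, strategy_arms())
  p <- set_base_values(p, flags$parameter_overrides)
  viol <- validate_parameters(p)
  if (length(viol)) stop("invalid parameters:\n  ", paste(viol, collapse = "\n  "))
  if (is.null(m)) {
    m <- mortality_model(fraction_female = base_values(p)[["fraction_female"]])
  }
  H <- config$horizon_cycles
  st <- health_states()
  rw <- cycle_rewards(arm, p, flags)
  cost_state <- rw$cost + cost_offset

  occ <- matrix(0, H + 1, 6, dimnames = list(0:H, st))
  occ[1, ] <- initial_distribution(arm, p)
  disc_cost <- disc_qaly <- numeric(H)
  inflow_dm <- inflow_comp <- numeric(H)
  r <- config$annual_discount_rate

  n_years <- H / 12L
  mats <- lapply(seq_len(n_years), function(y) {
    build_transition_matrix(arm, y, config$starting_age + (y - 1L), p, m, flags)
  })

  for (t in 0:(H - 1)) {
    y <- t %/% 12L + 1L
    M <- mats[[y]]
    d <- (1 + r)^(-t / 12)
    o <- occ[t + 1, ]
    disc_cost[t + 1] <- d * sum(o * cost_state)
    if (t == 0) disc_cost[1] <- disc_cost[1] + sum(o * rw$onetime)
    disc_qaly[t + 1] <- d * sum(o * rw$utility)
    inflow_dm[t + 1] <- sum(o[c("RF_NEG", "RF_POS_ENROLLED", "RF_POS_NOT_ENROLLED")] *
                              M[c("RF_NEG", "RF_POS_ENROLLED", "RF_POS_NOT_ENROLLED"),
                                "STABLE_DM"])
    inflow_comp[t + 1] <- o[["STABLE_DM"]] * M["STABLE_DM", "COMPLICATED_DM"]
    occ[t + 2, ] <- as.numeric(o %*% M)
  }

  structure(
    list(arm = arm, occupancy = occ,
         discounted_cost_per_cycle = disc_cost,
         discounted_qaly_per_cycle = disc_qaly,
         inflow_dm = inflow_dm, inflow_comp = inflow_comp,
         config = config),
    class = "cohort_trace"
  )
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("<cohort_trace> arm %s, %d cycles\n", x$arm, nrow(x$occupancy) - 1L))
  cat(sprintf("  discounted cost %.2f, discounted QALYs %.4f\n",
              sum(x$discounted_cost_per_cycle), sum(x$discounted_qaly_per_cycle)))
  invisible(x)
}

#' Tidy export of a cohort trace
#'
#' @param x A `cohort_trace`.
#' @param row.names,optional,... Ignored (data.frame method signature).
#' @return Data frame with one row per (cycle, state): `cycle`, `state`,
#'   `occupancy`, and the cycle-level `discounted_cost`, `discounted_qaly`
#'   and `arm` (repeated across the cycle's states; cycle `horizon` has no
#'   accrual row).
#' @export
as.data.frame.cohort_trace <- function(x, row.names = NULL, optional = FALSE, ...) {
  H <- nrow(x$occupancy) - 1L
  cyc <- rep(0:H, each = 6L)
  data.frame(
    cycle = cyc,
    state = rep(health_states(), H + 1L),
    occupancy = as.vector(t(x$occupancy)),
    discounted_cost = c(rep(x$discounted_cost_per_cycle, each = 6L), rep(NA_real_, 6L)),
    discounted_qaly = c(rep(x$discounted_qaly_per_cycle, each = 6L), rep(NA_real_, 6L)),
    arm = x$arm,
    stringsAsFactors = FALSE
  )
}

#' Summarize a cohort trace into arm-level outcomes
#'
#' @param trace A `cohort_trace`.
#' @return An `arm_outcome` list: `total_discounted_cost`,
#'   `total_discounted_qaly`, `cum_diabetes_incidence` (probability mass
#'   ever entering stable diabetes) and `cum_complication_incidence`
#'   (mass ever entering complicated diabetes).
#' @export
summarize_trace <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  structure(
    list(arm = trace$arm,
         total_discounted_cost = sum(trace$discounted_cost_per_cycle),
         total_discounted_qaly = sum(trace$discounted_qaly_per_cycle),
         cum_diabetes_incidence = sum(trace$inflow_dm),
         cum_complication_incidence = sum(trace$inflow_comp)),
    class = "arm_outcome"
  )
}

#' @export
print.arm_outcome <- function(x, ...) {
  cat(sprintf("<arm_outcome> %s: cost $%.2f, %.4f QALYs, DM %.2f%%, complicated %.2f%%\n",
              x$arm, x$total_discounted_cost, x$total_discounted_qaly,
              100 * x$cum_diabetes_incidence, 100 * x$cum_complication_incidence))
  invisible(x)
}
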