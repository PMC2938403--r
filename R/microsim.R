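# Individual-level Monte-Carlo simulator of the same natural history:
# an independent brute-force oracle for the cohort engine, and a generator
# of synthetic individual-level cohorts.

#' Simulate individual patients through the model
#'
#' Each simulated individual draws sex, race and comorbidity flags from the
#' cohort-profile prevalences (independently, held fixed over the run),
#' draws a starting state from [initial_distribution()], and then walks the
#' exact per-cycle transition matrices used by the cohort engine. Costs use
#' the individual's sampled characteristic flags (a female African American
#' individual pays the female times African American multiplier), not the
#' cohort-expected multiplier, so agreement with the cohort engine also
#' validates the product-form expected-multiplier approximation.
#'
#' Random draws are consumed in a fixed documented order (initial states,
#' then the seven characteristic flags, then one uniform per individual per
#' cycle), so results are reproducible across refactors for a given seed.
#'
#' @param arm `"MDPP"` or `"USUAL_CARE"`.
#' @param config A [model_config()].
#' @param p A `parameter_set`.
#' @param m A [mortality_model()]; `NULL` rebuilds from the bundled table.
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @param flags Scenario flags (default `config$scenario`).
#' @param keep_paths If `TRUE`, retain per-individual state paths and
#'   cumulative accumulators (memory grows as `n * (horizon + 1)`; intended
#'   for small `n`).
#' @return A `microsim_result`: means and Monte-Carlo standard errors of
#'   discounted cost and QALYs, cumulative diabetes and complication
#'   incidence, and (with `keep_paths`) the path matrices.
#' @export
simulate_individuals <- function(arm, config, p, m = NULL, n = 1000L,
                                 seed = 1L, flags = config$scenario,
                                 keep_paths = FALSE) {
  arm <- match.arg(arm, strategy_arms())
  stopifnot(n >= 1)
  p <- set_base_values(p, flags$parameter_overrides)
  if (is.null(m)) {
    m <- mortality_model(fraction_female = base_values(p)[["fraction_female"]])
  }
  set.seed(seed)
  H <- config$horizon_cycles
  st <- health_states()
  b <- base_values(p)
  pr <- cohort_profile(p)

  init <- initial_distribution(arm, p)
  state <- sample.int(6L, n, replace = TRUE, prob = init)

  flag <- function(prob) stats::runif(n) < prob
  female <- flag(pr$fraction_female)
  aa     <- flag(pr$fraction_african_american)
  angina <- flag(pr$prev_angina)
  htn    <- flag(pr$prev_htn_treated)
  mi     <- flag(pr$prev_cardiac_arrest_mi)
  strk   <- flag(pr$prev_stroke)
  pvd    <- flag(pr$prev_pvd)

  mult_if <- function(f, mlt) ifelse(f, mlt, 1)
  mult_rfpos <- mult_if(female, b[["m_rfpos_female"]]) * mult_if(aa, b[["m_rfpos_aa"]])
  mult_dm    <- mult_if(female, b[["m_dm_female"]]) * mult_if(aa, b[["m_dm_aa"]])
  mult_comp  <- mult_if(female, b[["m_comp_female"]]) * mult_if(aa, b[["m_comp_aa"]]) *
    mult_if(angina, b[["m_comp_angina"]]) * mult_if(htn, b[["m_comp_htn"]]) *
    mult_if(mi, b[["m_comp_mi"]]) * mult_if(strk, b[["m_comp_stroke"]]) *
    mult_if(pvd, b[["m_comp_pvd"]])

  rw <- cycle_rewards(arm, p, flags)
  # per-individual monthly cost by state: multiplied states scale with the
  # individual's own flags instead of the cohort-expected factor
  cost_by_state <- function(s) {
    out <- numeric(length(s))
    out[s == 1L] <- b[["c_rfneg_yr"]] / 12
    i <- s == 2L | s == 3L
    out[i] <- b[["c_rfpos_yr"]] / 12 * mult_rfpos[i]
    i <- s == 4L
    out[i] <- b[["c_dm_base_yr"]] / 12 * mult_dm[i]
    i <- s == 5L
    out[i] <- b[["c_complicated_dm_base_yr"]] / 12 * mult_comp[i]
    out
  }

  cost_acc <- rw$onetime[state]
  qaly_acc <- numeric(n)
  ever_dm <- state == 4L | state == 5L
  ever_comp <- state == 5L
  r <- config$annual_discount_rate

  if (keep_paths) {
    paths <- matrix(NA_integer_, n, H + 1L)
    paths[, 1L] <- state
    cost_path <- qaly_path <- matrix(NA_real_, n, H + 1L)
    cost_path[, 1L] <- cost_acc
    qaly_path[, 1L] <- 0
  }

  n_years <- H / 12L
  mats <- lapply(seq_len(n_years), function(y) {
    build_transition_matrix(arm, y, config$starting_age + (y - 1L), p, m, flags)
  })
  cum_rows <- lapply(mats, function(M) {
    cm <- t(apply(M, 1L, cumsum))
    cm[, 6L] <- 1 # guard against 1e-16 shortfall in the last column
    cm
  })

  for (t in 0:(H - 1)) {
    d <- (1 + r)^(-t / 12)
    cost_acc <- cost_acc + d * cost_by_state(state)
    qaly_acc <- qaly_acc + d * rw$utility[state]
    cum <- cum_rows[[t %/% 12L + 1L]]
    u <- stats::runif(n)
    # row lookup: next state is the first column whose cumulative prob >= u
    new_state <- integer(n)
    for (s in 1:6) {
      i <- state == s
      if (any(i)) {
        new_state[i] <- findInterval(u[i], cum[s, ], left.open = TRUE) + 1L
      }
    }
    state <- new_state
    ever_dm <- ever_dm | state == 4L
    ever_comp <- ever_comp | state == 5L
    if (keep_paths) {
      paths[, t + 2L] <- state
      cost_path[, t + 2L] <- cost_acc
      qaly_path[, t + 2L] <- qaly_acc
    }
  }

  se <- function(x) stats::sd(x) / sqrt(n)
  out <- list(
    arm = arm, n = n, seed = seed,
    mean_cost = mean(cost_acc), se_cost = se(cost_acc),
    mean_qaly = mean(qaly_acc), se_qaly = se(qaly_acc),
    cum_diabetes_incidence = mean(ever_dm), se_dm = se(ever_dm),
    cum_complication_incidence = mean(ever_comp), se_comp = se(ever_comp)
  )
  if (keep_paths) {
    out$paths <- paths
    out$cost_path <- cost_path
    out$qaly_path <- qaly_path
  }
  structure(out, class = "microsim_result")
}

#' @export
print.microsim_result <- function(x, ...) {
  cat(sprintf("<microsim_result> %s, n = %d\n", x$arm, x$n))
  cat(sprintf("  cost  $%.2f (SE %.3f)\n", x$mean_cost, x$se_cost))
  cat(sprintf("  QALYs %.5f (SE %.6f)\n", x$mean_qaly, x$se_qaly))
  invisible(x)
}

#' Export a simulated cohort as tidy CSV
#'
#' Writes one row per individual per cycle: `id`, `cycle`, `state`,
#' `cost_cum`, `qaly_cum` (discounted cumulative accumulators at that
#' cycle). Requires a simulation run with `keep_paths = TRUE`.
#'
#' @param sim A `microsim_result` with paths.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_synthetic_cohort <- function(sim, path) {
  stopifnot(inherits(sim, "microsim_result"))
  if (is.null(sim$paths)) {
    stop("simulation was run without keep_paths = TRUE; nothing to export")
  }
  n <- nrow(sim$paths)
  H1 <- ncol(sim$paths)
  df <- data.frame(
    id = rep(seq_len(n), each = H1),
    cycle = rep(0:(H1 - 1L), times = n),
    state = health_states()[as.vector(t(sim$paths))],
    cost_cum = as.vector(t(sim$cost_path)),
    qaly_cum = as.vector(t(sim$qaly_path)),
    stringsAsFactors = FALSE
  )
  ok <- tryCatch(utils::write.csv(df, path, row.names = FALSE),
                 error = function(e) stop("failed writing cohort CSV to ",
                                          path, ": ", conditionMessage(e)))
  invisible(path)
}
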