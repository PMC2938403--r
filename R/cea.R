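# Cost-effectiveness layer: incremental analysis, one-way (tornado)
# sensitivity, probabilistic sensitivity analysis, acceptability curve,
# and the named scenario analyses.

#' Incremental cost-effectiveness of the intervention versus usual care
#'
#' @param outcome_mdpp,outcome_usual `arm_outcome` objects from
#'   [summarize_trace()], computed under the same configuration.
#' @return A `cea_result` with per-arm totals, incremental cost and QALYs,
#'   the ICER (`delta_cost / delta_qaly`, dollars per QALY) and a dominance
#'   tag: `"mdpp_dominant"` (cheaper and more effective),
#'   `"mdpp_dominated"` (costlier and less effective, or costlier with no
#'   QALY gain), or `"none"` (ICER defined). When both deltas are zero the
#'   ICER is `NA` and dominance is `"none"`.
#' @export
compute_icer <- function(outcome_mdpp, outcome_usual) {
  stopifnot(inherits(outcome_mdpp, "arm_outcome"),
            inherits(outcome_usual, "arm_outcome"))
  dc <- outcome_mdpp$total_discounted_cost - outcome_usual$total_discounted_cost
  de <- outcome_mdpp$total_discounted_qaly - outcome_usual$total_discounted_qaly
  dominance <- "none"
  icer <- NA_real_
  if (de > 0 && dc < 0) {
    dominance <- "mdpp_dominant"
  } else if (de < 0 && dc > 0) {
    dominance <- "mdpp_dominated"
  } else if (de == 0) {
    if (dc > 0) dominance <- "mdpp_dominated"
    if (dc < 0) dominance <- "mdpp_dominant"
  } else {
    icer <- dc / de
  }
  structure(
    list(cost_mdpp = outcome_mdpp$total_discounted_cost,
         cost_usual = outcome_usual$total_discounted_cost,
         qaly_mdpp = outcome_mdpp$total_discounted_qaly,
         qaly_usual = outcome_usual$total_discounted_qaly,
         delta_cost = dc, delta_qaly = de,
         icer = icer, dominance = dominance,
         dm_incidence_mdpp = outcome_mdpp$cum_diabetes_incidence,
         dm_incidence_usual = outcome_usual$cum_diabetes_incidence,
         comp_incidence_mdpp = outcome_mdpp$cum_complication_incidence,
         comp_incidence_usual = outcome_usual$cum_complication_incidence),
    class = "cea_result"
  )
}

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result> mDPP vs usual care\n")
  cat(sprintf("  cost:  $%.2f vs $%.2f (delta $%.2f)\n",
              x$cost_mdpp, x$cost_usual, x$delta_cost))
  cat(sprintf("  QALYs: %.4f vs %.4f (delta %.5f, %.2f days)\n",
              x$qaly_mdpp, x$qaly_usual, x$delta_qaly, x$delta_qaly * 365.25))
  if (x$dominance == "none" && is.finite(x$icer)) {
    cat(sprintf("  ICER:  $%.0f per QALY\n", x$icer))
  } else {
    cat(sprintf("  dominance: %s\n", x$dominance))
  }
  invisible(x)
}

# Rebuild the mortality model against a (possibly resampled) parameter set:
# the female fraction feeds the sex mixture.
rebuild_mortality <- function(m, p) {
  mortality_model(m$life_table, base_values(p)[["fraction_female"]])
}

# One full two-arm evaluation at a given parameter set (plus optional point
# overrides). The starting age always tracks the parameter set.
evaluate_arms <- function(config, p, m, flags = config$scenario,
                          overrides = NULL) {
  if (length(overrides)) p <- set_base_values(p, overrides)
  # fold scenario overrides in here too, so starting age and the mortality
  # mixture track them (run_cohort re-applies them, which is idempotent)
  if (length(flags$parameter_overrides)) {
    p <- set_base_values(p, flags$parameter_overrides)
  }
  cfg <- config
  cfg$starting_age <- as.integer(round(base_values(p)[["starting_age"]]))
  m <- rebuild_mortality(m, p)
  out_m <- summarize_trace(run_cohort("MDPP", cfg, p, m, flags))
  out_u <- summarize_trace(run_cohort("USUAL_CARE", cfg, p, m, flags))
  compute_icer(out_m, out_u)
}

#' Base-case cost-effectiveness analysis
#'
#' Runs both strategy arms at the parameter set's base values and returns
#' the incremental comparison.
#'
#' @param config A [model_config()].
#' @param p A `parameter_set` (defaults to [default_parameter_set()]).
#' @param m A [mortality_model()] (defaults to the bundled life table).
#' @return A `cea_result`.
#' @export
#' @examples
#' run_base_case(model_config())
run_base_case <- function(config = model_config(),
                          p = default_parameter_set(),
                          m = mortality_model()) {
  evaluate_arms(config, p, m)
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-evaluates the model with each varied parameter set to the low and
#' high end of its examined range, all other parameters at base, and
#' records the ICER at both extremes. Entries are ranked by the width of
#' the ICER interval (the tornado bar); entries whose swing stays under
#' $7,000 per QALY are flagged as minor.
#'
#' @param config,p,m As in [run_base_case()].
#' @param parameters Character vector of parameter names to vary; default
#'   all non-fixed parameters. Requesting a fixed parameter is an error.
#' @return Data frame of class `tornado_result`: `parameter`, `low_input`,
#'   `high_input`, `icer_at_low`, `icer_at_high`, `dominance_at_low`,
#'   `dominance_at_high`, `swing`, `minor`, sorted by decreasing swing.
#' @export
one_way_sensitivity <- function(config = model_config(),
                                p = default_parameter_set(),
                                m = mortality_model(),
                                parameters = NULL) {
  varied <- names(p)[vapply(p, function(s) s$family != "fixed", logical(1))]
  if (is.null(parameters)) {
    parameters <- varied
  } else {
    bad <- setdiff(parameters, varied)
    if (length(bad)) {
      stop("not varied (fixed) parameter(s): ", paste(bad, collapse = ", "),
           "; variable parameters are: ", paste(varied, collapse = ", "))
    }
  }
  one_end <- function(nm, value) {
    r <- evaluate_arms(config, p, m, overrides = stats::setNames(list(value), nm))
    icer <- if (is.finite(r$icer)) r$icer else r$delta_cost / r$delta_qaly
    c(icer = icer, dom = r$dominance)
  }
  rows <- lapply(parameters, function(nm) {
    lo <- one_end(nm, p[[nm]]$low)
    hi <- one_end(nm, p[[nm]]$high)
    data.frame(parameter = nm,
               low_input = p[[nm]]$low, high_input = p[[nm]]$high,
               icer_at_low = as.numeric(lo[["icer"]]),
               icer_at_high = as.numeric(hi[["icer"]]),
               dominance_at_low = lo[["dom"]],
               dominance_at_high = hi[["dom"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$swing <- abs(out$icer_at_high - out$icer_at_low)
  out$minor <- pmax(out$icer_at_low, out$icer_at_high, na.rm = TRUE) < 7000 |
    is.na(out$swing)
  out <- out[order(-out$swing), ]
  rownames(out) <- NULL
  class(out) <- c("tornado_result", "data.frame")
  out
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` independent joint samples of every non-fixed parameter from
#' its calibrated distribution ([fit_distribution()]; parameters are
#' sampled independently, with no covariance structure), evaluates both
#' arms for each draw, and returns the incremental results. Draws failing
#' parameter validation (possible only in the distribution tails) are
#' redrawn; the redraw count is attached as an attribute.
#'
#' @param config,p,m As in [run_base_case()].
#' @param n Number of draws (default `config$psa_iterations`).
#' @param seed Integer seed (default `config$rng_seed`); fixing it makes
#'   the analysis exactly reproducible.
#' @return Data frame of class `psa_result` with one row per draw: `draw`,
#'   per-arm costs/QALYs, `delta_cost`, `delta_qaly`, `icer`. The matrix of
#'   sampled parameter values is attached as `attr(, "samples")`.
#' @export
run_psa <- function(config = model_config(),
                    p = default_parameter_set(),
                    m = mortality_model(),
                    n = config$psa_iterations,
                    seed = config$rng_seed) {
  stopifnot(n >= 1)
  set.seed(seed)
  varied <- names(p)[vapply(p, function(s) s$family != "fixed", logical(1))]
  samplers <- lapply(p[varied], fit_distribution)

  draw_one <- function() {
    vapply(samplers, function(f) f(1L), numeric(1))
  }
  redraws <- 0L
  samples <- matrix(NA_real_, n, length(varied),
                    dimnames = list(NULL, varied))
  results <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      x <- draw_one()
      p_i <- set_base_values(p, x)
      if (!length(validate_parameters(p_i))) break
      redraws <- redraws + 1L
      if (redraws > 100L * n) stop("too many invalid PSA draws; check distributions")
    }
    samples[i, ] <- x
    r <- evaluate_arms(config, p, m, overrides = x)
    results[[i]] <- data.frame(
      draw = i,
      cost_mdpp = r$cost_mdpp, cost_usual = r$cost_usual,
      qaly_mdpp = r$qaly_mdpp, qaly_usual = r$qaly_usual,
      delta_cost = r$delta_cost, delta_qaly = r$delta_qaly,
      icer = if (is.finite(r$icer)) r$icer else NA_real_
    )
  }
  out <- do.call(rbind, results)
  attr(out, "samples") <- samples
  attr(out, "redraws") <- redraws
  attr(out, "seed") <- seed
  class(out) <- c("psa_result", "data.frame")
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the probability that the
#' intervention is preferred is the fraction of probabilistic draws with
#' positive net monetary benefit, `lambda * delta_qaly - delta_cost > 0`.
#' The net-benefit formulation handles dominant and dominated draws without
#' ICER sign ambiguity.
#'
#' @param psa A `psa_result` from [run_psa()].
#' @param thresholds Numeric vector of willingness-to-pay values
#'   (dollars/QALY); the default grid spans $0-100,000 and includes the
#'   conventional $20,000 and $50,000 benchmarks.
#' @return Data frame with `threshold` and `probability_mdpp_preferred`.
#' @export
ceac <- function(psa, thresholds = c(seq(0, 100000, by = 5000), 20000)) {
  stopifnot(inherits(psa, "psa_result"), nrow(psa) >= 1)
  thresholds <- sort(unique(thresholds))
  prob <- vapply(thresholds, function(l) {
    mean(l * psa$delta_qaly - psa$delta_cost > 0)
  }, numeric(1))
  data.frame(threshold = thresholds, probability_mdpp_preferred = prob)
}

# scenario definitions: flag bundle + point overrides
scenario_catalog <- function() {
  list(
    base = list(),
    no_resolution_after_y1_both = list(mets_resolution_mode = "none_after_year1_both"),
    no_resolution_after_y1_enrolled_only =
      list(mets_resolution_mode = "none_after_year1_enrolled_only"),
    equal_rfpos_utilities = list(equalize_rfpos_utilities = TRUE),
    worst_case_3 = list(
      equalize_rfpos_utilities = TRUE,
      parameter_overrides = list(p_dm_in_program_yr = 0.098, u_rfneg = 0.77)
    ),
    worst_case_4 = list(
      equalize_rfpos_utilities = TRUE,
      parameter_overrides = list(p_dm_in_program_yr = 0.098, u_rfneg = 0.77,
                                 p_resolve_in_program_yr = 0.141)
    )
  )
}

#' Named scenario analyses
#'
#' Applies one of the predefined assumption bundles and recomputes the
#' incremental comparison:
#' \describe{
#'   \item{`base`}{Base-case assumptions.}
#'   \item{`no_resolution_after_y1_both`}{No metabolic-syndrome resolution
#'     after model year 1 for enrolled or non-enrolled subjects.}
#'   \item{`no_resolution_after_y1_enrolled_only`}{Enrolled subjects stop
#'     resolving after year 1; non-enrolled continue at the no-program
#'     rate.}
#'   \item{`equal_rfpos_utilities`}{The usual-care risk-factor-positive
#'     utility is set equal to the in-program value.}
#'   \item{`worst_case_3`}{Equalized utilities, in-program diabetes risk
#'     raised to 9.8\%/year, risk-factor-negative utility lowered to 0.77.}
#'   \item{`worst_case_4`}{`worst_case_3` plus in-program resolution cut to
#'     14.1\%/year.}
#' }
#'
#' @param name Scenario name (see above).
#' @param config,p,m As in [run_base_case()].
#' @return A `cea_result`.
#' @export
run_scenario <- function(name, config = model_config(),
                         p = default_parameter_set(),
                         m = mortality_model()) {
  cat_ <- scenario_catalog()
  if (!name %in% names(cat_)) {
    stop("unknown scenario '", name, "'; available: ",
         paste(names(cat_), collapse = ", "))
  }
  sc <- cat_[[name]]
  flags <- scenario_flags(
    mets_resolution_mode = sc$mets_resolution_mode %||%
      config$scenario$mets_resolution_mode,
    equalize_rfpos_utilities = sc$equalize_rfpos_utilities %||%
      config$scenario$equalize_rfpos_utilities,
    parameter_overrides = utils::modifyList(
      config$scenario$parameter_overrides, sc$parameter_overrides %||% list())
  )
  evaluate_arms(config, p, m, flags = flags)
}
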