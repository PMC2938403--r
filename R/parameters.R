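# Parameter set: every model input with its base value, sensitivity range
# and distribution family. Stored as a flat named list of dist_spec objects;
# the `kind` table below drives validation and reward/transition wiring.

# role of each parameter; used by validate_parameters() and the PSA
param_kinds <- c(
  starting_age               = "age",
  fraction_female            = "prevalence",
  fraction_african_american  = "prevalence",
  prev_angina                = "prevalence",
  prev_htn_treated           = "prevalence",
  prev_cardiac_arrest_mi     = "prevalence",
  prev_stroke                = "prevalence",
  prev_pvd                   = "prevalence",
  p_screen_positive          = "probability",
  p_enroll                   = "probability",
  p_dm_rfpos_no_program_yr   = "probability",
  p_dm_rfneg_yr              = "probability",
  p_dm_in_program_yr         = "probability",
  p_become_rfpos_yr          = "probability",
  p_progress_complicated_yr  = "probability",
  p_resolve_no_program_yr    = "probability",
  p_resolve_in_program_yr    = "probability",
  rr_death_rfpos             = "relative_risk",
  rr_death_rfneg             = "relative_risk",
  rr_death_stable_dm         = "relative_risk",
  rr_death_complicated_dm    = "relative_risk",
  u_rfpos_usual              = "utility",
  u_rfpos_program            = "utility",
  u_rfneg                    = "utility",
  u_stable_dm                = "utility",
  u_complicated_dm           = "utility",
  c_screen_positive          = "cost",
  c_screen_negative          = "cost",
  c_program                  = "cost",
  c_rfpos_yr                 = "cost",
  c_rfneg_yr                 = "cost",
  c_dm_base_yr               = "cost",
  c_complicated_dm_base_yr   = "cost",
  m_rfpos_female             = "multiplier",
  m_rfpos_aa                 = "multiplier",
  m_dm_female                = "multiplier",
  m_dm_aa                    = "multiplier",
  m_comp_female              = "multiplier",
  m_comp_aa                  = "multiplier",
  m_comp_angina              = "multiplier",
  m_comp_htn                 = "multiplier",
  m_comp_mi                  = "multiplier",
  m_comp_stroke              = "multiplier",
  m_comp_pvd                 = "multiplier"
)

#' Base-case model parameterization
#'
#' Returns the full parameter set for the mDPP versus usual-care comparison:
#' cohort characteristics, screening and enrollment probabilities, yearly
#' probabilities of acquiring diabetes / becoming risk-factor-positive /
#' resolving the metabolic syndrome, relative risks of death by state,
#' state utilities, and costs with demographic/comorbidity cost multipliers.
#' Each entry is a [dist_spec()] carrying the base value, the range examined
#' in sensitivity analysis, and the sampling family (beta for probabilities
#' and prevalences, uniform for utilities and unit costs, log-normal for
#' relative risks, normal for cost multipliers; parameters that are not
#' varied are `fixed`). All probabilities and prevalences are stored as
#' proportions, costs in year-2000 US dollars.
#'
#' @return A named list of class `parameter_set`.
#' @export
#' @examples
#' p <- default_parameter_set()
#' p$p_enroll
#' validate_parameters(p)
default_parameter_set <- function() {
  p <- list(
    starting_age              = dist_spec("uniform", 55, 45, 65),
    fraction_female           = dist_spec("beta", 0.75, 0.482, 0.940),
    fraction_african_american = dist_spec("beta", 0.271, 0.065, 0.558),
    prev_angina               = dist_spec("beta", 0.038, 0.010, 0.083),
    prev_htn_treated          = dist_spec("beta", 0.849, 0.045, 1.000),
    prev_cardiac_arrest_mi    = dist_spec("beta", 0.019, 0.005, 0.042),
    prev_stroke               = dist_spec("beta", 0.019, 0.005, 0.042),
    prev_pvd                  = dist_spec("beta", 0.047, 0.013, 0.102),

    p_screen_positive         = dist_spec("beta", 0.310, 0.072, 0.635),
    p_enroll                  = dist_spec("beta", 0.470, 0.092, 0.867),
    p_dm_rfpos_no_program_yr  = dist_spec("beta", 0.108, 0.029, 0.233),
    p_dm_rfneg_yr             = dist_spec("beta", 0.004, 0.0005, 0.0075),
    p_dm_in_program_yr        = dist_spec("beta", 0.048, 0.013, 0.105),
    p_become_rfpos_yr         = dist_spec("beta", 0.040, 0.010, 0.087),
    p_progress_complicated_yr = dist_spec("beta", 0.075, 0.020, 0.163),
    p_resolve_no_program_yr   = dist_spec("beta", 0.121, 0.032, 0.259),
    p_resolve_in_program_yr   = dist_spec("beta", 0.162, 0.042, 0.344),

    rr_death_rfpos            = dist_spec("lognormal", 1.7, 1.5, 1.8),
    rr_death_rfneg            = dist_spec("fixed", 1.0),
    rr_death_stable_dm        = dist_spec("lognormal", 2.0, 1.8, 2.2),
    rr_death_complicated_dm   = dist_spec("lognormal", 2.4, 2.2, 2.6),

    u_rfpos_usual             = dist_spec("uniform", 0.73, 0.71, 0.75),
    u_rfpos_program           = dist_spec("uniform", 0.75, 0.73, 0.77),
    u_rfneg                   = dist_spec("uniform", 0.88, 0.84, 0.92),
    u_stable_dm               = dist_spec("uniform", 0.69, 0.66, 0.72),
    u_complicated_dm          = dist_spec("uniform", 0.59, 0.51, 0.68),

    c_screen_positive         = dist_spec("uniform", 35, 18, 53),
    c_screen_negative         = dist_spec("uniform", 32, 16, 48),
    c_program                 = dist_spec("uniform", 219, 110, 329),
    c_rfpos_yr                = dist_spec("fixed", 1296),
    c_rfneg_yr                = dist_spec("fixed", 616),
    c_dm_base_yr              = dist_spec("fixed", 1684),
    c_complicated_dm_base_yr  = dist_spec("fixed", 1684),

    m_rfpos_female            = dist_spec("normal", 1.14, 1.05, 1.25),
    m_rfpos_aa                = dist_spec("normal", 0.82, 0.70, 0.95),
    m_dm_female               = dist_spec("normal", 1.25, 1.14, 1.35),
    m_dm_aa                   = dist_spec("normal", 0.82, 0.70, 0.95),
    m_comp_female             = dist_spec("normal", 1.25, 1.14, 1.35),
    m_comp_aa                 = dist_spec("normal", 0.82, 0.70, 0.95),
    m_comp_angina             = dist_spec("normal", 1.73, 1.31, 2.14),
    m_comp_htn                = dist_spec("normal", 1.24, 1.10, 1.37),
    m_comp_mi                 = dist_spec("normal", 1.90, 1.64, 2.17),
    m_comp_stroke             = dist_spec("normal", 1.30, 1.20, 1.40),
    m_comp_pvd                = dist_spec("normal", 1.31, 1.10, 1.53)
  )
  stopifnot(identical(names(p), names(param_kinds)))
  structure(p, class = "parameter_set")
}

#' Validate a parameter set
#'
#' Checks the structural invariants of a parameter set: every probability,
#' prevalence and utility in `[0, 1]`, costs non-negative, relative risks
#' strictly positive, range endpoints ordered around the base value, and
#' family-specific constraints (beta support, log-normal positivity).
#' Violations are returned, not raised, so callers can report them all.
#'
#' @param p A `parameter_set`.
#' @return Character vector of violation messages; empty when valid.
#' @export
validate_parameters <- function(p) {
  viol <- character()
  missing <- setdiff(names(param_kinds), names(p))
  if (length(missing)) {
    return(sprintf("missing parameter: %s", missing))
  }
  unknown <- setdiff(names(p), names(param_kinds))
  if (length(unknown)) {
    viol <- c(viol, sprintf("unknown parameter: %s", unknown))
  }
  for (nm in names(param_kinds)) {
    s <- p[[nm]]
    if (!is_dist_spec(s)) {
      viol <- c(viol, sprintf("%s: not a dist_spec", nm))
      next
    }
    viol <- c(viol, validate_dist_spec(s, nm))
    vals <- c(base = s$base, low = s$low, high = s$high)
    bad <- switch(param_kinds[[nm]],
      probability = ,
      prevalence = any(vals < 0 | vals > 1),
      utility = any(vals < 0 | vals > 1),
      cost = any(vals < 0),
      relative_risk = any(vals <= 0),
      multiplier = any(vals <= 0),
      age = any(vals < 18 | vals > 100)
    )
    if (isTRUE(bad)) {
      viol <- c(viol, sprintf("%s: value out of range for a %s",
                              nm, param_kinds[[nm]]))
    }
  }
  viol
}

#' Extract base-case values from a parameter set
#'
#' @param p A `parameter_set`.
#' @return Named numeric vector of base values.
#' @export
base_values <- function(p) {
  vapply(p, function(s) s$base, numeric(1))
}

#' Replace parameter base values
#'
#' Applies point overrides (named numeric values) to a parameter set,
#' replacing each named parameter's base value and leaving its family and
#' range untouched. Used by scenario analyses and the probabilistic
#' sensitivity analysis.
#'
#' @param p A `parameter_set`.
#' @param overrides Named numeric vector or list of replacement base values.
#' @return The modified `parameter_set`.
#' @export
set_base_values <- function(p, overrides) {
  overrides <- unlist(overrides)
  if (!length(overrides)) return(p)
  unknown <- setdiff(names(overrides), names(p))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         "; valid names are: ", paste(names(param_kinds), collapse = ", "))
  }
  for (nm in names(overrides)) {
    v <- unname(overrides[[nm]])
    p[[nm]]$base <- v
    # scenario point values may sit outside the sensitivity range; widen it
    p[[nm]]$low <- min(p[[nm]]$low, v)
    p[[nm]]$high <- max(p[[nm]]$high, v)
  }
  p
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("<parameter_set> %d parameters (%d varied, %d fixed)\n",
              length(x),
              sum(vapply(x, function(s) s$family != "fixed", logical(1))),
              sum(vapply(x, function(s) s$family == "fixed", logical(1)))))
  invisible(x)
}

# Cohort profile: prevalence of each cost-multiplier condition, read off the
# parameter set's base values.
cohort_profile <- function(p) {
  b <- base_values(p)
  list(
    fraction_female           = b[["fraction_female"]],
    fraction_african_american = b[["fraction_african_american"]],
    prev_angina               = b[["prev_angina"]],
    prev_htn_treated          = b[["prev_htn_treated"]],
    prev_cardiac_arrest_mi    = b[["prev_cardiac_arrest_mi"]],
    prev_stroke               = b[["prev_stroke"]],
    prev_pvd                  = b[["prev_pvd"]]
  )
}
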