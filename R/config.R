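#' Model run configuration
#'
#' Bundles the run-level settings of the cohort model: starting age of the
#' cohort, number of monthly cycles, annual discount rate applied to both
#' costs and QALYs, probabilistic-sensitivity-analysis size, random seed,
#' and the active scenario flags.
#'
#' @param starting_age Cohort age in years at cycle 0 (integer).
#' @param horizon_cycles Number of monthly cycles; must be a positive
#'   multiple of 12 (36 = three years in the base case).
#' @param annual_discount_rate Annual discount rate in `[0, 1]` (0.03 base).
#' @param psa_iterations Number of probabilistic draws (1000 base).
#' @param rng_seed Integer seed for all stochastic analyses.
#' @param scenario A [scenario_flags()] object.
#' @return An object of class `model_config`. The cycle length is fixed at
#'   one month (1/12 year).
#' @export
model_config <- function(starting_age = 55L,
                         horizon_cycles = 36L,
                         annual_discount_rate = 0.03,
                         psa_iterations = 1000L,
                         rng_seed = 1L,
                         scenario = scenario_flags()) {
  starting_age <- as.integer(round(starting_age))
  horizon_cycles <- as.integer(horizon_cycles)
  if (horizon_cycles <= 0L || horizon_cycles %% 12L != 0L) {
    stop("horizon_cycles must be a positive multiple of 12")
  }
  if (annual_discount_rate < 0 || annual_discount_rate > 1) {
    stop("annual_discount_rate must be in [0, 1]")
  }
  structure(
    list(starting_age = starting_age,
         horizon_cycles = horizon_cycles,
         cycle_length = 1 / 12,
         annual_discount_rate = annual_discount_rate,
         psa_iterations = as.integer(psa_iterations),
         rng_seed = as.integer(rng_seed),
         scenario = scenario),
    class = "model_config"
  )
}

#' Scenario switches
#'
#' Controls the structural assumptions examined in the scenario analyses:
#' how metabolic-syndrome resolution behaves after model year 1, whether the
#' utility of risk-factor-positive patients under usual care is set equal to
#' the in-program utility, and arbitrary point overrides of parameter base
#' values.
#'
#' @param mets_resolution_mode `"base"` (enrolled resolve at the in-program
#'   rate in year 1 then at the no-program rate in years 2-3; non-enrolled
#'   at the no-program rate throughout), `"none_after_year1_both"` (no
#'   resolution after year 1 for anyone), or
#'   `"none_after_year1_enrolled_only"` (enrolled stop resolving after year
#'   1; non-enrolled continue at the no-program rate).
#' @param equalize_rfpos_utilities If `TRUE`, the usual-care
#'   risk-factor-positive utility is set equal to the in-program value.
#' @param parameter_overrides Named numeric values replacing parameter base
#'   values (see [set_base_values()]).
#' @return An object of class `scenario_flags`.
#' @export
scenario_flags <- function(mets_resolution_mode = c("base",
                                                    "none_after_year1_both",
                                                    "none_after_year1_enrolled_only"),
                           equalize_rfpos_utilities = FALSE,
                           parameter_overrides = list()) {
  structure(
    list(mets_resolution_mode = match.arg(mets_resolution_mode),
         equalize_rfpos_utilities = isTRUE(equalize_rfpos_utilities),
         parameter_overrides = as.list(parameter_overrides)),
    class = "scenario_flags"
  )
}

# kinds whose config-file values may be given in percent
percent_kinds <- c("probability", "prevalence")

#' Read a model configuration file
#'
#' Parses a YAML configuration holding a `model` block (run settings), an
#' optional `scenario` block, an optional `probability_units` key (`
#' "proportion"`, the default, or `"percent"` — in which case probability
#' and prevalence entries are divided by 100 on read), and a `parameters`
#' block with one entry per model parameter giving `family`, `base`, `low`,
#' `high`. Every parameter in [default_parameter_set()] must be present.
#'
#' @param path Path to the YAML file.
#' @return A list with elements `config` ([model_config()]) and `params`
#'   (`parameter_set`).
#' @seealso [write_config()]; the bundled base-case file
#'   `system.file("extdata", "table1_base.yaml", package = "dppcea")`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$parameters)) stop("config file has no 'parameters' block: ", path)
  units <- doc$probability_units %||% "proportion"
  if (!units %in% c("proportion", "percent")) {
    stop("probability_units must be 'proportion' or 'percent', got: ", units)
  }
  missing <- setdiff(names(param_kinds), names(doc$parameters))
  if (length(missing)) {
    stop("config file missing parameter(s): ", paste(missing, collapse = ", "))
  }
  unknown <- setdiff(names(doc$parameters), names(param_kinds))
  if (length(unknown)) {
    stop("unknown parameter(s) in config: ", paste(unknown, collapse = ", "),
         "; valid names are: ", paste(names(param_kinds), collapse = ", "))
  }
  scale_of <- function(nm) {
    if (units == "percent" && param_kinds[[nm]] %in% percent_kinds) 100 else 1
  }
  p <- lapply(names(param_kinds), function(nm) {
    e <- doc$parameters[[nm]]
    for (f in c("family", "base")) {
      if (is.null(e[[f]])) stop(sprintf("parameter %s: missing field '%s'", nm, f))
    }
    sc <- scale_of(nm)
    dist_spec(e$family,
              base = e$base / sc,
              low = (e$low %||% e$base) / sc,
              high = (e$high %||% e$base) / sc)
  })
  names(p) <- names(param_kinds)
  p <- structure(p, class = "parameter_set")
  viol <- validate_parameters(p)
  if (length(viol)) {
    stop("invalid parameters in ", path, ":\n  ", paste(viol, collapse = "\n  "))
  }
  m <- doc$model %||% list()
  s <- doc$scenario %||% list()
  cfg <- model_config(
    starting_age = m$starting_age %||% 55L,
    horizon_cycles = m$horizon_cycles %||% 36L,
    annual_discount_rate = m$annual_discount_rate %||% 0.03,
    psa_iterations = m$psa_iterations %||% 1000L,
    rng_seed = m$rng_seed %||% 1L,
    scenario = scenario_flags(
      mets_resolution_mode = s$mets_resolution_mode %||% "base",
      equalize_rfpos_utilities = s$equalize_rfpos_utilities %||% FALSE,
      parameter_overrides = s$parameter_overrides %||% list()
    )
  )
  list(config = cfg, params = p)
}

#' Write a model configuration file
#'
#' Serializes a configuration and parameter set to YAML such that
#' [read_config()] recovers them exactly (probabilities are always written
#' as proportions).
#'
#' @param config A [model_config()].
#' @param params A `parameter_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, params, path) {
  stopifnot(inherits(config, "model_config"), inherits(params, "parameter_set"))
  doc <- list(
    probability_units = "proportion",
    model = list(
      starting_age = config$starting_age,
      horizon_cycles = config$horizon_cycles,
      annual_discount_rate = config$annual_discount_rate,
      psa_iterations = config$psa_iterations,
      rng_seed = config$rng_seed
    ),
    scenario = list(
      mets_resolution_mode = config$scenario$mets_resolution_mode,
      equalize_rfpos_utilities = config$scenario$equalize_rfpos_utilities,
      parameter_overrides = config$scenario$parameter_overrides
    ),
    parameters = lapply(unclass(params), function(s) {
      list(family = s$family, base = s$base, low = s$low, high = s$high)
    })
  )
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
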