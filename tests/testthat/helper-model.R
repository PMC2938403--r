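# Shared fixtures, built in code.

base_params <- default_parameter_set()
base_config <- model_config()
base_mort <- mortality_model(fraction_female = 0.75)

# a life table with zero mortality, bypassing the loader's open-interval
# check, for closed-form cohort tests
zero_life_table <- function(ages = 45:70) {
  lt <- rbind(
    data.frame(age = ages, sex = "F", q_annual = 0),
    data.frame(age = ages, sex = "M", q_annual = 0)
  )
  class(lt) <- c("life_table", "data.frame")
  lt
}

# parameter set with every transition switched off (cohort frozen in its
# initial states)
frozen_params <- function(p = default_parameter_set()) {
  set_base_values(p, c(
    p_dm_rfpos_no_program_yr = 0, p_dm_rfneg_yr = 0, p_dm_in_program_yr = 0,
    p_become_rfpos_yr = 0, p_progress_complicated_yr = 0,
    p_resolve_no_program_yr = 0, p_resolve_in_program_yr = 0
  ))
}

# parameter set where the program has no effect and costs nothing
null_effect_params <- function(p = default_parameter_set()) {
  b <- base_values(p)
  set_base_values(p, c(
    p_dm_in_program_yr = b[["p_dm_rfpos_no_program_yr"]],
    p_resolve_in_program_yr = b[["p_resolve_no_program_yr"]],
    c_screen_positive = 0, c_screen_negative = 0, c_program = 0
  ))
}

# collapse every distribution to a point at its base value
fix_all_params <- function(p = default_parameter_set()) {
  for (nm in names(p)) {
    p[[nm]] <- dist_spec("fixed", p[[nm]]$base)
  }
  structure(p, class = "parameter_set")
}
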