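# Baseline all-cause mortality: an age- and sex-specific life table plus
# the conversion to per-cycle, state-adjusted death probabilities.

#' Load an age- and sex-specific life table
#'
#' Reads a CSV with columns `age` (integer years), `sex` (`F`/`M`) and
#' `q_annual` (annual probability of death) and validates it: both sexes
#' must cover ages 45-70 contiguously and every `q_annual` must lie strictly
#' inside (0, 1). Mortality that decreases with age is tolerated with a
#' warning (real tables can have local dips); the synthetic generator is
#' strictly monotone.
#'
#' The bundled default is a synthetic Gompertz-form table calibrated to
#' plausible adult US mortality levels around 2000 (see
#' [generate_synthetic_life_table()]); it stands in for the unpublished
#' national life table and is labelled synthetic accordingly.
#'
#' @param path CSV path; defaults to the bundled synthetic table.
#' @return A `life_table`: data frame with columns `age`, `sex`, `q_annual`.
#' @export
load_life_table <- function(path = system.file("extdata",
                                               "synthetic_us_lifetable.csv",
                                               package = "dppcea")) {
  lt <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age", "sex", "q_annual")
  if (!all(need %in% names(lt))) {
    stop("life table must have columns age, sex, q_annual: ", path)
  }
  lt$sex <- toupper(lt$sex)
  if (!all(lt$sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  lt <- lt[!duplicated(lt[c("age", "sex")]), need]
  for (sx in c("F", "M")) {
    ages <- sort(lt$age[lt$sex == sx])
    gaps <- setdiff(45:70, ages)
    if (length(gaps)) {
      stop(sprintf("life table missing sex %s at age(s) %s",
                   sx, paste(gaps, collapse = ", ")))
    }
  }
  if (any(lt$q_annual <= 0 | lt$q_annual >= 1)) {
    bad <- lt[lt$q_annual <= 0 | lt$q_annual >= 1, ]
    stop(sprintf("q_annual must lie in (0, 1); offending row: age %d sex %s q %g",
                 bad$age[1], bad$sex[1], bad$q_annual[1]))
  }
  for (sx in c("F", "M")) {
    sub <- lt[lt$sex == sx, ]
    sub <- sub[order(sub$age), ]
    if (is.unsorted(sub$q_annual)) {
      warning("q_annual not non-decreasing in age for sex ", sx)
    }
  }
  lt <- lt[order(lt$sex, lt$age), ]
  rownames(lt) <- NULL
  class(lt) <- c("life_table", "data.frame")
  lt
}

#' Generate a synthetic Gompertz life table
#'
#' Builds an adult life table from a Gompertz hazard: the male annual death
#' probability at age `x` is `1 - exp(-a * exp(b * x))`; the female hazard
#' is the male hazard multiplied by `female_factor`. This yields mortality
#' that increases with age and is lower for women, the two qualitative
#' features of real adult life tables the model relies on.
#'
#' @param a Hazard scale (> 0).
#' @param b Hazard growth per year of age (>= 0).
#' @param female_factor Female/male hazard ratio in (0, 1].
#' @param ages Integer ages to cover (default 45:70).
#' @return A `life_table` data frame (columns `age`, `sex`, `q_annual`).
#' @export
#' @examples
#' lt <- generate_synthetic_life_table()
#' subset(lt, age == 55)
generate_synthetic_life_table <- function(a = 8.4e-5, b = 0.085,
                                          female_factor = 0.55,
                                          ages = 45:70) {
  stopifnot(a > 0, b >= 0, female_factor > 0, female_factor <= 1)
  haz_m <- a * exp(b * ages)
  q <- function(h) 1 - exp(-h)
  if (any(q(haz_m) >= 1)) {
    stop("parameters yield q_annual >= 1 within the requested age range")
  }
  lt <- rbind(
    data.frame(age = ages, sex = "F", q_annual = q(haz_m * female_factor)),
    data.frame(age = ages, sex = "M", q_annual = q(haz_m))
  )
  lt <- lt[order(lt$sex, lt$age), ]
  rownames(lt) <- NULL
  class(lt) <- c("life_table", "data.frame")
  lt
}

#' Mortality model: life table plus cohort sex mix
#'
#' Combines a life table with the cohort's female fraction into the object
#' the transition engine queries. The cohort is modelled as a single pooled
#' group; the sexes' annual death probabilities are mixed with weight
#' `fraction_female` before hazard conversion.
#'
#' @param life_table A `life_table` (see [load_life_table()]).
#' @param fraction_female Mixture weight in `[0, 1]` (0.75 base case).
#' @return An object of class `mortality_model`.
#' @export
mortality_model <- function(life_table = load_life_table(),
                            fraction_female = 0.75) {
  stopifnot(inherits(life_table, "life_table"),
            fraction_female >= 0, fraction_female <= 1)
  # fast lookup vectors keyed by age
  qf <- life_table$q_annual[life_table$sex == "F"]
  names(qf) <- life_table$age[life_table$sex == "F"]
  qm <- life_table$q_annual[life_table$sex == "M"]
  names(qm) <- life_table$age[life_table$sex == "M"]
  structure(
    list(life_table = life_table, fraction_female = fraction_female,
         q_female = qf, q_male = qm),
    class = "mortality_model"
  )
}

# pooled annual death probability at an integer age
annual_death_prob <- function(m, age) {
  key <- as.character(as.integer(age))
  qf <- m$q_female[key]
  qm <- m$q_male[key]
  if (anyNA(qf) || anyNA(qm)) {
    stop(sprintf("age %d outside life-table coverage; extend the table", as.integer(age)))
  }
  unname(m$fraction_female * qf + (1 - m$fraction_female) * qm)
}

#' Monthly probability of death at a given age and relative risk
#'
#' Converts the pooled annual death probability to a monthly probability
#' under a state-specific relative risk acting on the hazard scale:
#' `q_month = 1 - (1 - q_annual_mix)^(rr / 12)`. Compounding twelve monthly
#' steps at `rr = 1` recovers the annual probability exactly, and the
#' result stays inside (0, 1) for any `rr > 0`.
#'
#' @param m A [mortality_model()].
#' @param age Age in whole years (must be covered by the table).
#' @param rr Relative risk of death (> 0); 1 for risk-factor-negative,
#'   higher for metabolic syndrome and diabetes states.
#' @return Monthly death probability.
#' @export
monthly_death_prob <- function(m, age, rr = 1) {
  stopifnot(rr > 0)
  q <- annual_death_prob(m, age)
  1 - (1 - q)^(rr / 12)
}
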