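#' Sample ages at death from other causes
#'
#' Draws, for each individual, a continuous age at death from causes other
#' than colorectal cancer, conditional on being alive at `current_age`. The
#' discrete year of death follows the life table's annual probabilities `q`;
#' the death instant is placed uniformly within that year. Draws use the
#' global RNG stream.
#'
#' @param current_age integer ages (vector), within the life-table range
#' @param sex character vector, `"male"`/`"female"`, recycled to the length
#'   of `current_age`
#' @param life_table stacked life table with columns sex, age, q
#' @return numeric vector of death ages, each `>=` its `current_age`
#' @export
#' @examples
#' lt <- default_life_tables()
#' set.seed(1)
#' sample_other_cause_death_age(rep(60L, 5), "male", lt)
sample_other_cause_death_age <- function(current_age, sex, life_table) {
  n <- length(current_age)
  sex <- rep_len(sex, n)
  out <- numeric(n)
  lt <- data.table::as.data.table(life_table)
  for (s in unique(sex)) {
    q <- lt[lt$sex == s, ][order(age), q]
    if (!length(q)) stop("life table has no rows for sex ", s)
    ages <- lt[lt$sex == s, ][order(age), age]
    if (ages[1L] != 0L || any(diff(ages) != 1L))
      stop("life-table ages must be contiguous from 0")
    # lsurv[k+1] = P(alive at exact age k)
    lsurv <- c(1, cumprod(1 - q))
    sel_s <- which(sex == s)
    for (a in unique(current_age[sel_s])) {
      idx <- sel_s[current_age[sel_s] == a]
      if (lsurv[a + 1L] <= 0) stop("no survival mass at age ", a)
      # death-year distribution conditional on being alive at age a
      k <- a:(length(q) - 1L)
      pk <- (lsurv[k + 1L] - lsurv[k + 2L]) / lsurv[a + 1L]
      yr <- k[sample.int(length(k), length(idx), replace = TRUE, prob = pk)]
      out[idx] <- yr + stats::runif(length(idx))
    }
  }
  out
}

#' Build the simulated population
#'
#' Samples `round(total * scale)` individuals whose (sex, age) distribution
#' follows the demography pyramid, assigns each an other-cause death age
#' conditional on being alive at the reference year, a gamma frailty
#' `risk_index` (mean 1, variance `frailty_var`) multiplying adenoma onset,
#' and a first-invitation calendar year under the phased roll-out: each
#' age-eligible person is attached to one of the roll-out years between
#' `start_year` and `full_implementation_year` with equal probability, and is
#' first invited at the later of that year and the year they turn `age_min`.
#' People older than `age_max` at their roll-out year, or turning `age_min`
#' after `last_new_cohort_year`, are never invited (`first_invitation_year`
#' is `NA`).
#'
#' @param pyramid demography pyramid from [generate_demography()] (attribute
#'   `reference_year` used as the baseline year)
#' @param life_table stacked life table, both sexes
#' @param program programme configuration, see [default_program_config()]
#' @param scale sampling fraction in (0, 1]; outputs are later rescaled to
#'   the full population by `1/scale`
#' @param seed integer seed
#' @param frailty_var variance of the gamma risk index (0 disables frailty)
#' @return a data.table of individuals: `id`, `sex`, `age0` (age at the
#'   reference year), `birth_year`, `death_age_other`, `risk_index`,
#'   `first_invitation_year`; attributes `reference_year` and `scale_factor`
#' @export
build_population <- function(pyramid, life_table,
                             program = default_program_config(),
                             scale = 1, seed = 1L, frailty_var = 1) {
  total <- sum(pyramid$count)
  if (total <= 0) stop("no population")
  n <- round(total * scale)
  if (n < 1) stop("scale too small: no individuals to simulate")
  set.seed(seed)
  rows <- sample.int(nrow(pyramid), n, replace = TRUE, prob = pyramid$count)
  ref_year <- attr(pyramid, "reference_year") %||% 2008L
  pop <- data.table::data.table(
    id = seq_len(n),
    sex = pyramid$sex[rows],
    age0 = as.integer(pyramid$age[rows])
  )
  pop[, "birth_year" := ref_year - pop$age0]
  pop[, "death_age_other" := sample_other_cause_death_age(pop$age0, pop$sex,
                                                          life_table)]
  pop[, "risk_index" := if (frailty_var > 0) {
    stats::rgamma(n, shape = 1 / frailty_var, rate = 1 / frailty_var)
  } else rep(1, n)]

  ramp_years <- program$start_year:program$full_implementation_year
  ramp <- ramp_years[1L + floor(stats::runif(n) * length(ramp_years))]
  turn_min <- pop$birth_year + program$age_min
  first <- pmax(ramp, turn_min)
  age_at_first <- first - pop$birth_year
  first[age_at_first > program$age_max |
          turn_min > program$last_new_cohort_year] <- NA_integer_
  pop[, "first_invitation_year" := as.integer(first)]
  data.table::setattr(pop, "reference_year", ref_year)
  data.table::setattr(pop, "scale_factor", total / n)
  pop[]
}

#' Build a birth cohort for calibration runs
#'
#' A simpler population used when fitting natural-history parameters: `n`
#' individuals (split evenly between the sexes unless `sex` is given),
#' followed from birth, with other-cause death ages from the life table and
#' gamma frailty. No screening roll-out is attached.
#'
#' @param n cohort size
#' @param life_table stacked life table
#' @param frailty_var gamma frailty variance
#' @param seed integer seed
#' @param sex optionally restrict to one sex
#' @return individuals data.table as in [build_population()], with `age0 = 0`
#' @export
make_cohort <- function(n, life_table, frailty_var = 1, seed = 1L,
                        sex = NULL) {
  set.seed(seed)
  sx <- if (is.null(sex)) {
    rep(c("male", "female"), length.out = n)
  } else rep(sex, n)
  pop <- data.table::data.table(id = seq_len(n), sex = sx, age0 = 0L,
                                birth_year = 0L)
  pop[, "death_age_other" := sample_other_cause_death_age(pop$age0, pop$sex,
                                                          life_table)]
  pop[, "risk_index" := if (frailty_var > 0) {
    stats::rgamma(n, shape = 1 / frailty_var, rate = 1 / frailty_var)
  } else rep(1, n)]
  pop[, "first_invitation_year" := NA_integer_]
  data.table::setattr(pop, "reference_year", 0L)
  data.table::setattr(pop, "scale_factor", 1)
  pop[]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
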