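#' Generate a Gompertz-Makeham life table
#'
#' Builds an other-cause mortality life table with annual death probabilities
#' `q(a) = 1 - exp(-H(a))`, where the integrated hazard over the year of age
#' `a` is `H(a) = A + (B/theta) * (exp(theta*(a+1)) - exp(theta*a))`: a
#' Makeham constant `A` plus a Gompertz term with level `B` and log-slope
#' `theta`. The terminal age (110) always has `q = 1`.
#'
#' @param sex `"male"` or `"female"`; selects the default parameters when
#'   `makeham` is `NULL`
#' @param makeham optional list with components `A`, `B`, `theta`
#' @param max_age terminal age, default 110
#' @return a [data.table::data.table] with columns `sex`, `age` (0..max_age)
#'   and `q`, the annual probability of death from other causes
#' @export
#' @examples
#' lt <- generate_life_table("male")
#' lt[age == 80, q]
generate_life_table <- function(sex = c("male", "female"), makeham = NULL,
                                max_age = 110L) {
  sex <- match.arg(sex)
  if (is.null(makeham)) {
    makeham <- if (sex == "male") {
      list(A = 2e-4, B = 3.0e-5, theta = 0.095)
    } else {
      list(A = 1.5e-4, B = 1.6e-5, theta = 0.098)
    }
  }
  stopifnot(makeham$A >= 0, makeham$B >= 0, makeham$theta > 0)
  age <- 0:max_age
  H <- makeham$A + (makeham$B / makeham$theta) *
    (exp(makeham$theta * (age + 1)) - exp(makeham$theta * age))
  q <- 1 - exp(-H)
  bad <- (q >= 1 | !is.finite(q)) & age < max_age
  if (any(bad)) {
    warning("hazard saturates (q = 1) before the terminal age; clamping")
    q[q > 1 | !is.finite(q)] <- 1
  }
  q[length(q)] <- 1
  data.table::data.table(sex = sex, age = age, q = q)
}

#' Default pair of life tables (both sexes)
#'
#' @return stacked life table for males and females
#' @export
default_life_tables <- function() {
  data.table::rbindlist(list(generate_life_table("male"),
                             generate_life_table("female")))
}

#' Generate a demography pyramid
#'
#' Distributes `total_count` people over single ages 0-100 and two sexes. The
#' default age profile is a piecewise-linear bulge peaking in mid-adulthood,
#' emulating a 2008-style European population with a large baby-boom cohort
#' approaching screening age. Counts are integers and sum to `total_count`
#' exactly (largest-remainder rounding within each sex); the female total is
#' `round(total_count * female_share)`.
#'
#' @param total_count total population size
#' @param female_share share of women, in (0,1)
#' @param age_profile optional data.frame with columns `age` and `weight`
#'   giving piecewise-linear profile nodes
#' @param reference_year calendar year the pyramid refers to
#' @return a data.table with columns `sex`, `age`, `count` and attribute
#'   `reference_year`
#' @export
#' @examples
#' pyr <- generate_demography(2230000, 0.51)
#' sum(pyr$count)
generate_demography <- function(total_count, female_share = 0.51,
                                age_profile = NULL, reference_year = 2008L) {
  stopifnot(total_count > 0, female_share > 0, female_share < 1)
  if (is.null(age_profile)) {
    age_profile <- data.frame(
      age = c(0, 30, 45, 65, 85, 100),
      weight = c(0.80, 1.20, 1.30, 0.90, 0.35, 0.02)
    )
  }
  ages <- 0:100
  w <- stats::approx(age_profile$age, age_profile$weight, xout = ages,
                     rule = 2)$y
  w <- pmax(w, 0)
  if (sum(w) <= 0) stop("age profile has no mass")
  p <- w / sum(w)

  apportion <- function(total) {
    raw <- total * p
    base <- floor(raw)
    left <- total - sum(base)
    if (left > 0) {
      extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
      base[extra] <- base[extra] + 1
    }
    as.integer(base)
  }
  n_f <- round(total_count * female_share)
  n_m <- total_count - n_f
  out <- data.table::data.table(
    sex = rep(c("male", "female"), each = length(ages)),
    age = rep(ages, 2L),
    count = c(apportion(n_m), apportion(n_f))
  )
  data.table::setattr(out, "reference_year", as.integer(reference_year))
  out
}

#' Generate calibration target tables from known parameters
#'
#' Simulates the natural history of `n_individuals` (half per sex, followed
#' from birth with other-cause mortality from `life_table`) under
#' `true_nh_params`, and tabulates the resulting adenoma prevalence and
#' clinically diagnosed cancer incidence into registry-style target tables.
#' Because the generating parameters are known, the output supports
#' parameter-recovery experiments for the calibration engine.
#'
#' @param true_nh_params natural-history parameter list
#' @param life_table stacked life table covering both sexes
#' @param n_individuals cohort size (total across sexes)
#' @param seed integer seed; identical seeds give identical tables
#' @param age_bands optional data.table with `age_lo`, `age_hi`
#' @return list with elements `prevalence` (sex, age_lo, age_hi, prevalence,
#'   n_alive) and `incidence` (sex, age_lo, age_hi, location, stage,
#'   rate_per_100k, person_years, events); empty bands carry zero counts and
#'   `flag_empty = TRUE`
#' @export
generate_calibration_targets <- function(true_nh_params, life_table,
                                         n_individuals, seed,
                                         age_bands = default_age_bands()) {
  stopifnot(n_individuals >= 1)
  cohort <- make_cohort(n_individuals, life_table,
                        frailty_var = true_nh_params$frailty_var,
                        seed = seed)
  hist <- run_natural_history(cohort, true_nh_params, seed = seed + 1L)
  summarize_epidemiology(hist, age_bands)
}

#' Default 5-year age bands (40-44 ... 85+)
#'
#' @return data.table with columns `age_lo`, `age_hi` (the 85+ band runs to
#'   the terminal age)
#' @export
default_age_bands <- function() {
  lo <- seq(40L, 85L, by = 5L)
  data.table::data.table(age_lo = lo, age_hi = c(lo[-1L] - 1L, 110L))
}

#' Unit costs and utility losses of the screening programme
#'
#' Returns the cost table (2012 euros) and utility table used by the
#' economics layer: invitation including letter, FIT kit and management
#' (6.06), FIT laboratory analysis (0.99), primary-care consultation after a
#' positive result (78.00), colonoscopy with/without polypectomy
#' (461.30/281.30), colonoscopy complication (5157.00), initial treatment cost
#' by stage (I 6968, II 12765, III 13075; none booked for stage IV), annual
#' follow-up for stages I-III (404, capped at `followup_cap_years`), and a
#' flat annual cost of 24255 for each year lived with stage IV disease.
#' Utility losses: 0.0055 QALY per colonoscopy (two days of life), 0.0384
#' QALY per complication (two weeks), plus configurable annual losses per
#' life-year with cancer care by stage (surrogate values).
#'
#' @return list with elements `costs` and `utilities`
#' @export
#' @examples
#' default_cost_utility_tables()$costs$invitation
default_cost_utility_tables <- function() {
  list(
    costs = list(
      invitation = 6.06,
      fit_analysis = 0.99,
      consult_positive = 78.00,
      colonoscopy_with_polypectomy = 461.30,
      colonoscopy_without_polypectomy = 281.30,
      complication = 5157.00,
      treatment_initial = c(I = 6968, II = 12765, III = 13075, IV = 0),
      followup_annual_stage_I_III = 404,
      stage_IV_annual = 24255,
      followup_cap_years = 5,
      currency_year = 2012
    ),
    utilities = list(
      disutility_colonoscopy = 0.0055,
      disutility_complication = 0.0384,
      annual_loss_with_crc_care = c(I = 0.05, II = 0.08, III = 0.12, IV = 0.30)
    )
  )
}

#' Convert days of life lost to a QALY decrement
#'
#' Uses a 365-day year and rounds to four decimals, the convention under
#' which two days equal 0.0055 QALY and fourteen days equal 0.0384 QALY.
#'
#' @param days days of life lost
#' @param days_per_year days per year, default 365
#' @return QALY decrement, rounded to 4 decimals
#' @export
days_to_qaly <- function(days, days_per_year = 365) {
  round(days / days_per_year, 4)
}

# ---- CSV / JSON interfaces ------------------------------------------------

#' Read and write the model's plain-text input tables
#'
#' CSV files are comma-separated UTF-8 with a header row and period decimal
#' separator; numeric values round-trip exactly. Cost and utility tables are
#' stored as JSON.
#'
#' @param x table to write
#' @param path file path
#' @name crcscreen-io
NULL

#' @rdname crcscreen-io
#' @export
write_life_table <- function(x, path) data.table::fwrite(x, path)

#' @rdname crcscreen-io
#' @export
read_life_table <- function(path) {
  lt <- data.table::fread(path, colClasses = list(character = "sex"))
  stopifnot(all(c("sex", "age", "q") %in% names(lt)),
            all(lt$q >= 0 & lt$q <= 1))
  lt
}

#' @rdname crcscreen-io
#' @export
write_demography <- function(x, path) data.table::fwrite(x, path)

#' @rdname crcscreen-io
#' @param reference_year calendar year of the pyramid
#' @export
read_demography <- function(path, reference_year = 2008L) {
  d <- data.table::fread(path, colClasses = list(character = "sex"))
  stopifnot(all(c("sex", "age", "count") %in% names(d)), all(d$count >= 0),
            sum(d$count) > 0)
  data.table::setattr(d, "reference_year", as.integer(reference_year))
  d
}

#' @rdname crcscreen-io
#' @param targets calibration target list as from
#'   [generate_calibration_targets()]
#' @param prevalence_path,incidence_path file paths for the two tables
#' @export
write_targets <- function(targets, prevalence_path, incidence_path) {
  data.table::fwrite(targets$prevalence, prevalence_path)
  data.table::fwrite(targets$incidence, incidence_path)
  invisible(targets)
}

#' @rdname crcscreen-io
#' @export
read_targets <- function(prevalence_path, incidence_path) {
  prev <- data.table::fread(prevalence_path,
                            colClasses = list(character = "sex"))
  inc <- data.table::fread(incidence_path,
                           colClasses = list(character = c("sex", "location",
                                                           "stage")))
  stopifnot(all(prev$prevalence >= 0 & prev$prevalence <= 1),
            all(inc$rate_per_100k >= 0))
  list(prevalence = prev, incidence = inc)
}

#' @rdname crcscreen-io
#' @param tables list with `costs` and `utilities`
#' @param costs_path,utilities_path file paths for the two JSON files
#' @export
write_cost_utility_tables <- function(tables, costs_path, utilities_path) {
  listify <- function(x) {
    # named vectors become JSON objects, preserving the stage names
    lapply(x, function(el) if (length(el) > 1L) as.list(el) else el)
  }
  jsonlite::write_json(listify(tables$costs), costs_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(listify(tables$utilities), utilities_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(tables)
}

#' @rdname crcscreen-io
#' @export
read_cost_utility_tables <- function(costs_path, utilities_path) {
  fix <- function(x) {
    for (nm in names(x)) if (is.list(x[[nm]])) x[[nm]] <- unlist(x[[nm]])
    x
  }
  list(costs = fix(jsonlite::read_json(costs_path, simplifyVector = TRUE)),
       utilities = fix(jsonlite::read_json(utilities_path,
                                           simplifyVector = TRUE)))
}
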