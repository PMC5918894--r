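#' Default natural-history parameters
#'
#' Returns the parameter set governing the adenoma-carcinoma sequence:
#' a piecewise-constant adenoma onset intensity by age and sex (multiplied per
#' person by a gamma frailty `risk_index`), exponential dwell times for adenoma
#' growth (small <=5 mm, medium 6-9 mm, large >=10 mm), per-size malignant
#' transformation hazards, exponential preclinical stage sojourns (I-III),
#' stage-specific symptomatic-diagnosis hazards, and a stage- and sex-specific
#' survival model (cure fraction plus exponential time to cancer death).
#'
#' All values are structural surrogates chosen to emulate a high
#' adenoma-prevalence European population; they are intended to be refined
#' against target tables with [calibrate_parameters()].
#'
#' @return A named list with components `onset`, `frailty_var`, `dwell_mean`,
#'   `transform_rate`, `large_gt20_prob`, `sojourn_mean`, `sympt_rate`,
#'   `cure_frac`, `surv_mean`, `p_colon`.
#' @export
#' @examples
#' p <- default_nh_params()
#' p$transform_rate
default_nh_params <- function() {
  rate_m <- c(0.004, 0.010, 0.016, 0.024, 0.028, 0.028, 0.022)
  stages <- c("I", "II", "III", "IV")
  cure <- rbind(male = c(0.90, 0.75, 0.45, 0.05),
                female = c(0.90, 0.75, 0.45, 0.05))
  smean <- rbind(male = c(8, 6, 4, 1.5),
                 female = c(8, 6, 4, 1.5))
  colnames(cure) <- colnames(smean) <- stages
  list(
    onset = list(
      # annual onset intensity per person of average risk, from each break age
      # to the next (last band extends to age 110); zero before the first break
      breaks = c(20, 30, 40, 50, 60, 70, 80),
      rate_male = rate_m,
      rate_female = 0.7 * rate_m,
      multiplier = 1
    ),
    frailty_var = 1,
    dwell_mean = c(small_to_medium = 12, medium_to_large = 12),
    transform_rate = c(small = 0, medium = 0.0007, large = 0.014),
    large_gt20_prob = 0.15,
    sojourn_mean = c(I = 2.5, II = 2.0, III = 1.5),
    sympt_rate = c(I = 0.05, II = 0.20, III = 0.50, IV = 1.0),
    cure_frac = cure,
    surv_mean = smean,
    p_colon = 0.65
  )
}

# registry of scalar parameters addressable by flat name (calibration surface)
.nh_flat_registry <- list(
  onset_multiplier = function(p, v) {
    if (missing(v)) p$onset$multiplier else { p$onset$multiplier <- v; p }
  },
  frailty_var = function(p, v) {
    if (missing(v)) p$frailty_var else { p$frailty_var <- v; p }
  },
  dwell_small_medium = function(p, v) {
    if (missing(v)) p$dwell_mean[["small_to_medium"]] else { p$dwell_mean[["small_to_medium"]] <- v; p }
  },
  dwell_medium_large = function(p, v) {
    if (missing(v)) p$dwell_mean[["medium_to_large"]] else { p$dwell_mean[["medium_to_large"]] <- v; p }
  },
  transform_small = function(p, v) {
    if (missing(v)) p$transform_rate[["small"]] else { p$transform_rate[["small"]] <- v; p }
  },
  transform_medium = function(p, v) {
    if (missing(v)) p$transform_rate[["medium"]] else { p$transform_rate[["medium"]] <- v; p }
  },
  transform_large = function(p, v) {
    if (missing(v)) p$transform_rate[["large"]] else { p$transform_rate[["large"]] <- v; p }
  },
  sojourn_I = function(p, v) {
    if (missing(v)) p$sojourn_mean[["I"]] else { p$sojourn_mean[["I"]] <- v; p }
  },
  sojourn_II = function(p, v) {
    if (missing(v)) p$sojourn_mean[["II"]] else { p$sojourn_mean[["II"]] <- v; p }
  },
  sojourn_III = function(p, v) {
    if (missing(v)) p$sojourn_mean[["III"]] else { p$sojourn_mean[["III"]] <- v; p }
  },
  sympt_I = function(p, v) {
    if (missing(v)) p$sympt_rate[["I"]] else { p$sympt_rate[["I"]] <- v; p }
  },
  sympt_II = function(p, v) {
    if (missing(v)) p$sympt_rate[["II"]] else { p$sympt_rate[["II"]] <- v; p }
  },
  sympt_III = function(p, v) {
    if (missing(v)) p$sympt_rate[["III"]] else { p$sympt_rate[["III"]] <- v; p }
  },
  sympt_IV = function(p, v) {
    if (missing(v)) p$sympt_rate[["IV"]] else { p$sympt_rate[["IV"]] <- v; p }
  },
  p_colon = function(p, v) {
    if (missing(v)) p$p_colon else { p$p_colon <- v; p }
  },
  large_gt20_prob = function(p, v) {
    if (missing(v)) p$large_gt20_prob else { p$large_gt20_prob <- v; p }
  }
)

#' Get or set a natural-history parameter by flat name
#'
#' Scalar parameters that the calibration engine can free are addressed by a
#' flat name such as `"onset_multiplier"` or `"transform_large"`.
#'
#' @param params parameter list as returned by [default_nh_params()]
#' @param name flat parameter name; see `nh_param_names()`
#' @param value replacement value (for `nh_param_set`)
#' @return `nh_param_get` returns the scalar value; `nh_param_set` the
#'   modified parameter list.
#' @export
nh_param_get <- function(params, name) {
  f <- .nh_flat_registry[[name]]
  if (is.null(f)) stop("unknown natural-history parameter: ", name)
  f(params)
}

#' @rdname nh_param_get
#' @export
nh_param_set <- function(params, name, value) {
  f <- .nh_flat_registry[[name]]
  if (is.null(f)) stop("unknown natural-history parameter: ", name)
  f(params, value)
}

#' @rdname nh_param_get
#' @export
nh_param_names <- function() names(.nh_flat_registry)

#' Validate a natural-history parameter list
#'
#' Checks non-negativity of hazards, positivity of dwell means, cure fractions
#' in \[0,1\], and the stochastic ordering of the stage survival model (cure
#' fractions non-increasing and mean survival times non-increasing with stage)
#' required for screen-detection stage anticipation never to shorten an
#' individual's simulated survival.
#'
#' @param params parameter list
#' @return `params`, invisibly; errors on violation.
#' @export
validate_nh_params <- function(params) {
  stopifnot(
    length(params$onset$breaks) == length(params$onset$rate_male),
    length(params$onset$breaks) == length(params$onset$rate_female),
    all(params$onset$rate_male >= 0), all(params$onset$rate_female >= 0),
    params$onset$multiplier >= 0,
    params$frailty_var >= 0,
    all(params$dwell_mean > 0),
    all(params$transform_rate >= 0),
    params$large_gt20_prob >= 0, params$large_gt20_prob <= 1,
    all(params$sojourn_mean > 0),
    all(params$sympt_rate >= 0), params$sympt_rate[["IV"]] > 0,
    all(params$cure_frac >= 0), all(params$cure_frac <= 1),
    all(params$surv_mean > 0),
    params$p_colon >= 0, params$p_colon <= 1
  )
  ord <- function(x) all(diff(x) <= 0)
  for (s in rownames(params$cure_frac)) {
    if (!ord(params$cure_frac[s, ]) || !ord(params$surv_mean[s, ]))
      stop("stage survival must be stochastically ordered (cure fraction and ",
           "mean survival non-increasing with stage)")
  }
  invisible(params)
}

#' Default programme configuration
#'
#' Organised biennial FIT screening offered to ages 50-69, started in 2009,
#' fully implemented by 2013, taking in new cohorts until 2038; individuals
#' already included keep receiving rounds until age 69. Costs and QALYs are
#' discounted at 3% to base year 2009.
#'
#' @return named list of programme settings
#' @export
default_program_config <- function() {
  list(
    start_year = 2009,
    full_implementation_year = 2013,
    last_new_cohort_year = 2038,
    age_min = 50,
    age_max = 69,
    screening_interval = 2,
    discount_rate = 0.03,
    base_year = 2009,
    surveillance_after_69 = TRUE
  )
}

#' Default FIT and colonoscopy test characteristics
#'
#' Per-lesion FIT sensitivity by lesion class at the 20 ug haemoglobin/g
#' faeces cut-off, per-person FIT specificity, per-lesion colonoscopy
#' sensitivity (reach and completeness folded in), the probability of a
#' complication on a colonoscopy with polypectomy, and the fraction of lesions
#' that are persistently FIT-undetectable in the correlated false-negative
#' scenario (0 = independent test results).
#'
#' These defaults are surrogates taken from the FIT screening literature, not
#' fitted values from any specific programme; calibrate them to observed
#' positivity and detection rates before drawing quantitative conclusions.
#'
#' @return named list of test characteristics
#' @export
default_test_characteristics <- function() {
  list(
    fit_sensitivity = c(small = 0.04, medium = 0.12, large = 0.32, crc = 0.75),
    fit_specificity = 0.955,
    colo_sensitivity = c(small = 0.77, medium = 0.88, large = 0.96, crc = 0.97),
    complication_prob = 0.008,
    systematic_fn_fraction = 0
  )
}

#' Default participation model
#'
#' FIT participation probability by age band, separately for the first and for
#' successive invitations, and colonoscopy compliance after a positive FIT.
#' Surrogate values emulating organised-programme uptake around 65%.
#'
#' @return named list: `age_breaks`, `fit_initial`, `fit_successive`,
#'   `colonoscopy_compliance`
#' @export
default_participation_model <- function() {
  list(
    age_breaks = c(50, 55, 60, 65),
    fit_initial = c(0.55, 0.62, 0.67, 0.70),
    fit_successive = c(0.68, 0.72, 0.76, 0.78),
    colonoscopy_compliance = 0.92
  )
}

#' Default post-polypectomy surveillance rules
#'
#' Priority-ordered dispositions after a colonoscopy that found adenomas:
#' 1-year surveillance colonoscopy for at least one adenoma > 20 mm or five or
#' more adenomas; 3-year surveillance for at least one adenoma > 10 mm or 3-4
#' adenomas; return to FIT in 5 years for 1-2 adenomas all < 10 mm; a negative
#' colonoscopy returns the person to routine biennial FIT.
#'
#' @return named list of rule thresholds and toggles
#' @export
default_surveillance_rules <- function() {
  list(
    mm_1y = 20,       # any adenoma strictly larger than this -> 1-year recall
    n_1y = 5,         # this many adenomas or more -> 1-year recall
    mm_3y = 10,       # any adenoma strictly larger than this -> 3-year recall
    n_3y_min = 3, n_3y_max = 4,
    fit5_max_n = 2,   # 1..this many small adenomas -> FIT in 5 years
    surveillance_after_69 = TRUE,
    negative_colonoscopy = "routine_biennial_fit"
  )
}

# representative diameters (mm) used to evaluate size-based surveillance rules
# for lesions modelled as size classes; large lesions may exceed 20 mm with
# probability large_gt20_prob, drawn persistently per lesion
.class_mm <- c(4, 7, 12)
.class_mm_gt20 <- 22
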