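#' Sample adenoma onset ages
#'
#' Adenoma onsets follow, for each individual, a non-homogeneous Poisson
#' process whose intensity is the individual's `risk_index` times the
#' piecewise-constant sex-specific baseline, truncated at the individual's
#' other-cause death age. Several adenomas may coexist. Locations (colon or
#' rectum) are assigned independently with probability `p_colon`.
#'
#' Vectorised over individuals; draws come from the global RNG stream.
#'
#' @param persons individuals table from [build_population()] or
#'   [make_cohort()]
#' @param params natural-history parameters
#' @return data.table of lesions: `pid`, `aid` (lesion index), `onset_age`,
#'   `location`
#' @export
sample_adenoma_onsets <- function(persons, params) {
  n <- nrow(persons)
  breaks <- params$onset$breaks
  mult <- params$onset$multiplier
  horizon <- pmin(persons$death_age_other, 110)
  rate_tab <- rbind(params$onset$rate_male, params$onset$rate_female)
  sexi <- ifelse(persons$sex == "male", 1L, 2L)
  pid_acc <- list(); age_acc <- list()
  for (j in seq_along(breaks)) {
    b0 <- breaks[j]
    b1 <- if (j < length(breaks)) breaks[j + 1L] else 110
    len <- pmax(0, pmin(b1, horizon) - b0)
    lam <- persons$risk_index * mult * rate_tab[cbind(sexi, j)] * len
    nj <- stats::rpois(n, lam)
    tot <- sum(nj)
    if (tot > 0L) {
      parent <- rep.int(seq_len(n), nj)
      pid_acc[[j]] <- persons$id[parent]
      age_acc[[j]] <- b0 + stats::runif(tot) * len[parent]
    }
  }
  pid <- unlist(pid_acc, use.names = FALSE)
  if (is.null(pid)) pid <- integer(0)
  ad <- data.table::data.table(pid = pid,
                               onset_age = unlist(age_acc,
                                                  use.names = FALSE) %||%
                                 numeric(0))
  data.table::setorderv(ad, c("pid", "onset_age"))
  ad[, "aid" := seq_len(.N)]
  ad[, "location" := ifelse(stats::runif(nrow(ad)) < params$p_colon,
                            "colon", "rectum")]
  ad[]
}

#' Simulate adenoma growth and malignant transformation
#'
#' Each adenoma progresses through the size states small (<=5 mm), medium
#' (6-9 mm), large (>=10 mm). In each state a competing-risks draw between
#' exponential growth to the next size (mean dwell `dwell_mean`) and
#' exponential malignant transformation (`transform_rate`) decides the next
#' event; transformation seeds a preclinical stage I cancer at
#' `malignant_age`. Size never regresses. Two persistent lesion traits are
#' also drawn: whether a large lesion exceeds 20 mm (for surveillance rules)
#' and a uniform `u_missed` deciding systematic FIT undetectability in the
#' correlated false-negative scenario.
#'
#' @param adenomas table from [sample_adenoma_onsets()]
#' @param params natural-history parameters
#' @return the input with added columns `age_medium`, `age_large`,
#'   `malignant_age` (each `Inf` when the event never happens), `gt20`,
#'   `u_missed`
#' @export
simulate_adenoma_progression <- function(adenomas, params) {
  n <- nrow(adenomas)
  ad <- data.table::copy(adenomas)
  if (n == 0L) {
    ad[, c("age_medium", "age_large", "malignant_age") := numeric(0)]
    ad[, "gt20" := logical(0)]
    ad[, "u_missed" := numeric(0)]
    return(ad[])
  }
  g1 <- 1 / params$dwell_mean[["small_to_medium"]]
  g2 <- 1 / params$dwell_mean[["medium_to_large"]]
  m <- params$transform_rate
  onset <- ad$onset_age

  t1 <- stats::rexp(n, g1 + m[["small"]])
  tr1 <- stats::runif(n) < m[["small"]] / (g1 + m[["small"]])
  t2 <- stats::rexp(n, g2 + m[["medium"]])
  tr2 <- stats::runif(n) < m[["medium"]] / (g2 + m[["medium"]])
  t3 <- if (m[["large"]] > 0) stats::rexp(n, m[["large"]]) else rep(Inf, n)

  age_medium <- rep(Inf, n); age_large <- rep(Inf, n)
  malignant <- rep(Inf, n)
  malignant[tr1] <- onset[tr1] + t1[tr1]
  grew1 <- !tr1
  age_medium[grew1] <- onset[grew1] + t1[grew1]
  malignant[grew1 & tr2] <- age_medium[grew1 & tr2] + t2[grew1 & tr2]
  grew2 <- grew1 & !tr2
  age_large[grew2] <- age_medium[grew2] + t2[grew2]
  malignant[grew2] <- age_large[grew2] + t3[grew2]

  ad[, "age_medium" := age_medium]
  ad[, "age_large" := age_large]
  ad[, "malignant_age" := malignant]
  ad[, "gt20" := stats::runif(n) < params$large_gt20_prob]
  ad[, "u_missed" := stats::runif(n)]
  ad[]
}

# survival delay from diagnosis given the persistent uniform u:
# P(T > t) = cf + (1 - cf) * exp(-t / mean); sampled by inverse CDF, so for
# stochastically ordered stage distributions an earlier detected stage maps
# the same u to an equal-or-later death (Inf = cured)
surv_delay_from_u <- function(stage, sexi, u, params) {
  cf <- params$cure_frac[cbind(sexi, stage)]
  m <- params$surv_mean[cbind(sexi, stage)]
  delay <- rep(Inf, length(u))
  unc <- u < 1 - cf
  delay[unc] <- -m[unc] * log(1 - u[unc] / (1 - cf[unc]))
  delay
}

#' Simulate the preclinical course and survival of a cancer
#'
#' From its preclinical stage I onset, each cancer faces in every stage a
#' competing-risks draw between exponential progression to the next stage
#' (mean sojourn `sojourn_mean`) and exponential symptomatic diagnosis
#' (`sympt_rate`); stage IV can only be diagnosed (its diagnosis hazard is
#' required to be positive). At diagnosis, survival is drawn from the stage-
#' and sex-specific cure-fraction/exponential model through a persistent
#' uniform `surv_u`, reused by the screening overlay when a screen detection
#' anticipates the stage.
#'
#' @param cancers data.table with `pid`, `aid`, `onset_age`, `location` and
#'   a column `sexi` (1 male, 2 female)
#' @param params natural-history parameters
#' @return input with columns `e2`, `e3`, `e4` (stage entry ages, `Inf` when
#'   never reached), `sympt_dx_age`, `dx_stage`, `surv_u`, `crc_death_age`
#'   (`Inf` when cured)
#' @export
simulate_cancer_course <- function(cancers, params) {
  n <- nrow(cancers)
  ca <- data.table::copy(cancers)
  if (n == 0L) {
    ca[, c("e2", "e3", "e4", "sympt_dx_age") := numeric(0)]
    ca[, "dx_stage" := integer(0)]
    ca[, c("surv_u", "crc_death_age") := numeric(0)]
    return(ca[])
  }
  cur <- ca$onset_age
  active <- rep(TRUE, n)
  dx_age <- rep(Inf, n)
  dx_stage <- rep(NA_integer_, n)
  entry <- matrix(Inf, n, 3L)  # entry ages into stages II, III, IV
  for (s in 1:3) {
    rate_p <- 1 / params$sojourn_mean[[s]]
    rate_d <- params$sympt_rate[[s]]
    t <- stats::rexp(n, rate_p + rate_d)
    isdx <- stats::runif(n) < rate_d / (rate_p + rate_d)
    dxnow <- active & isdx
    dx_age[dxnow] <- cur[dxnow] + t[dxnow]
    dx_stage[dxnow] <- s
    adv <- active & !isdx
    cur[adv] <- cur[adv] + t[adv]
    entry[adv, s] <- cur[adv]
    active[adv] <- TRUE
    active[dxnow] <- FALSE
  }
  t4 <- stats::rexp(n, params$sympt_rate[["IV"]])
  dx_age[active] <- cur[active] + t4[active]
  dx_stage[active] <- 4L

  u <- stats::runif(n)
  delay <- surv_delay_from_u(dx_stage, ca$sexi, u, params)
  ca[, "e2" := entry[, 1L]]
  ca[, "e3" := entry[, 2L]]
  ca[, "e4" := entry[, 3L]]
  ca[, "sympt_dx_age" := dx_age]
  ca[, "dx_stage" := dx_stage]
  ca[, "surv_u" := u]
  ca[, "crc_death_age" := dx_age + delay]
  ca[]
}

# resolve per-person death ages against a set of diagnosed-cancer candidates:
# a cancer is clinically diagnosed only if its dx age precedes the person's
# (updated) death; earlier diagnoses can pre-empt later ones through an
# earlier cancer death. Returns realised dx flags and death ages.
resolve_deaths <- function(death_other, pid_of_cancer, dx_age, crc_death_age,
                           person_index) {
  death <- death_other
  if (length(pid_of_cancer)) {
    ord <- order(person_index, dx_age)
    rk <- sequence(rle(person_index[ord])$lengths)
    valid <- logical(length(pid_of_cancer))
    for (r in seq_len(max(rk))) {
      rows <- ord[rk == r]
      ok <- dx_age[rows] < death[person_index[rows]]
      rows_ok <- rows[ok]
      valid[rows_ok] <- TRUE
      death[person_index[rows_ok]] <-
        pmin(death[person_index[rows_ok]], crc_death_age[rows_ok])
    }
  } else {
    valid <- logical(0)
  }
  list(death = death, dx_valid = valid)
}

#' Run the natural history of colorectal cancer for a population
#'
#' Composes onset sampling, adenoma progression and cancer-course simulation
#' for every individual, truncates all events at death, and resolves each
#' person's death age and cause (the minimum of the other-cause death age and
#' the earliest cancer death among cancers actually diagnosed while alive).
#' This is the counterfactual (no screening) arm.
#'
#' For populations referenced to a baseline year (`age0 > 0`), cancers whose
#' symptomatic diagnosis would have occurred before the baseline age are
#' removed together with their parent lesion: such individuals are known to
#' be alive at baseline and prevalent diagnosed cases are out of scope.
#'
#' @param persons individuals table
#' @param params natural-history parameters
#' @param seed integer seed; the same seed reproduces the identical history
#' @return an object of class `crc_histories`: a list with `persons` (with
#'   added `death_age`, `cause`), `adenomas`, `cancers`, `params`
#' @export
run_natural_history <- function(persons, params = default_nh_params(),
                                seed = 1L) {
  validate_nh_params(params)
  set.seed(seed)
  persons <- data.table::copy(data.table::as.data.table(persons))
  ad <- sample_adenoma_onsets(persons, params)
  ad <- simulate_adenoma_progression(ad, params)

  pidx <- match(ad$pid, persons$id)
  is_ca <- ad$malignant_age < persons$death_age_other[pidx]
  ca <- ad[is_ca, c("pid", "aid", "malignant_age", "location")]
  data.table::setnames(ca, "malignant_age", "onset_age")
  cidx <- match(ca$pid, persons$id)
  ca[, "sexi" := ifelse(persons$sex[cidx] == "male", 1L, 2L)]
  ca <- simulate_cancer_course(ca, params)

  # baseline conditioning: drop cancers (and their lesions) diagnosed before
  # the age at the reference year
  if (any(persons$age0 > 0L) && nrow(ca)) {
    pre <- ca$sympt_dx_age < persons$age0[match(ca$pid, persons$id)]
    if (any(pre)) {
      drop_aid <- ca$aid[pre]
      ca <- ca[!pre]
      ad <- ad[!(ad$aid %in% drop_aid)]
    }
  }

  ridx <- match(ca$pid, persons$id)
  res <- resolve_deaths(persons$death_age_other, ca$pid, ca$sympt_dx_age,
                        ca$crc_death_age, ridx)
  ca[, "cf_dx_valid" := res$dx_valid]
  persons[, "death_age" := res$death]
  persons[, "cause" := ifelse(persons$death_age < persons$death_age_other,
                              "crc", "other")]
  structure(list(persons = persons, adenomas = ad, cancers = ca,
                 params = params),
            class = "crc_histories")
}

#' @export
print.crc_histories <- function(x, ...) {
  cat("<crc_histories> ", nrow(x$persons), " individuals, ",
      nrow(x$adenomas), " adenomas, ", nrow(x$cancers),
      " preclinical cancers\n", sep = "")
  invisible(x)
}

#' Tabulate adenoma prevalence and cancer incidence
#'
#' Adenoma prevalence in an age band is the share of individuals alive at the
#' band midpoint who carry at least one non-excised, not-yet-malignant
#' adenoma at that age. Incidence is the number of clinically diagnosed
#' cancers per 100,000 person-years lived within the band, by sex, location
#' and stage at diagnosis.
#'
#' @param hist a `crc_histories` object
#' @param age_bands data.table with `age_lo`, `age_hi`
#' @return list of two data.tables shaped like calibration targets:
#'   `prevalence` and `incidence`
#' @export
summarize_epidemiology <- function(hist, age_bands = default_age_bands()) {
  persons <- hist$persons
  ad <- hist$adenomas
  ca <- hist$cancers
  if (nrow(persons) == 0L) stop("no histories to summarise")
  stages <- c("I", "II", "III", "IV")

  prev_list <- vector("list", nrow(age_bands))
  for (b in seq_len(nrow(age_bands))) {
    mid <- (age_bands$age_lo[b] + age_bands$age_hi[b] + 1) / 2
    alive <- persons$death_age > mid
    carrier_pid <- unique(ad$pid[ad$onset_age <= mid & ad$malignant_age > mid])
    has_ad <- persons$id %in% carrier_pid
    dt <- data.table::data.table(sex = c("male", "female"),
                                 age_lo = age_bands$age_lo[b],
                                 age_hi = age_bands$age_hi[b])
    n_alive <- c(sum(alive & persons$sex == "male"),
                 sum(alive & persons$sex == "female"))
    n_car <- c(sum(alive & has_ad & persons$sex == "male"),
               sum(alive & has_ad & persons$sex == "female"))
    dt[, "prevalence" := ifelse(n_alive > 0, n_car / n_alive, 0)]
    dt[, "n_alive" := n_alive]
    prev_list[[b]] <- dt
  }
  prev <- data.table::rbindlist(prev_list)
  prev[, "flag_empty" := prev$n_alive == 0L]

  # person-years per sex x band
  grid <- data.table::CJ(sex = c("male", "female"),
                         band = seq_len(nrow(age_bands)),
                         location = c("colon", "rectum"),
                         stage = stages, sorted = FALSE)
  py <- matrix(0, 2L, nrow(age_bands))
  sexi_p <- ifelse(persons$sex == "male", 1L, 2L)
  for (b in seq_len(nrow(age_bands))) {
    lo <- age_bands$age_lo[b]; hi <- age_bands$age_hi[b] + 1
    contrib <- pmax(0, pmin(persons$death_age, hi) - lo)
    py[1L, b] <- sum(contrib[sexi_p == 1L])
    py[2L, b] <- sum(contrib[sexi_p == 2L])
  }
  ev <- ca[ca$cf_dx_valid == TRUE, ]
  band_of <- findInterval(ev$sympt_dx_age, c(age_bands$age_lo, 110 + 1))
  keep <- band_of >= 1L & band_of <= nrow(age_bands)
  ev <- ev[keep]; band_of <- band_of[keep]
  sexchr <- ifelse(ev$sexi == 1L, "male", "female")
  key <- paste(sexchr, band_of, ev$location, stages[ev$dx_stage])
  counts <- table(key)
  gkey <- paste(grid$sex, grid$band, grid$location, grid$stage)
  grid[, "events" := as.integer(ifelse(gkey %in% names(counts),
                                       counts[gkey], 0L))]
  grid[, "person_years" := py[cbind(ifelse(grid$sex == "male", 1L, 2L),
                                    grid$band)]]
  grid[, "rate_per_100k" := ifelse(grid$person_years > 0,
                                   grid$events / grid$person_years * 1e5, 0)]
  grid[, "age_lo" := age_bands$age_lo[grid$band]]
  grid[, "age_hi" := age_bands$age_hi[grid$band]]
  inc <- grid[, c("sex", "age_lo", "age_hi", "location", "stage",
                  "rate_per_100k", "person_years", "events")]
  list(prevalence = prev[], incidence = inc)
}
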