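test_that("onset counts match the Poisson process oracle", {
  # constant intensity 0.02/yr over a 50-year horizon: mean count 1.0
  p <- constant_onset_params(0.02)
  persons <- mk_persons(10000, death = 50)
  set.seed(12)
  ad <- sample_adenoma_onsets(persons, p)
  m <- nrow(ad) / 10000
  expect_lt(abs(m - 1), 3 * sqrt(1 / 10000))
  expect_true(all(ad$onset_age <= 50))
  expect_true(all(ad$location %in% c("colon", "rectum")))
})

test_that("zero baseline intensity yields no adenomas", {
  p <- constant_onset_params(0)
  set.seed(1)
  ad <- sample_adenoma_onsets(mk_persons(200), p)
  expect_identical(nrow(ad), 0L)
})

test_that("gamma frailty overdisperses per-person adenoma counts", {
  # mixed Poisson: Var = m + v m^2 = 1 + 1 = 2 for m = 1, v = 1
  p <- constant_onset_params(0.02)
  set.seed(9)
  risk <- stats::rgamma(10000, shape = 1, rate = 1)
  persons <- mk_persons(10000, death = 50, risk = risk)
  ad <- sample_adenoma_onsets(persons, p)
  counts <- tabulate(ad$pid, 10000)
  expect_gt(stats::var(counts), 1.5)
  expect_lt(stats::var(counts), 2.6)
})

test_that("state-wise transformation follows the competing-exponential law", {
  # transformation from the small state only, against growth:
  # P(transform before growing) = m / (m + g)
  g <- 0.1; m <- 0.05
  p <- toy_params(dwell_small_medium = 1 / g, transform_small = m,
                  transform_medium = 0, transform_large = 0)
  ad0 <- data.table::data.table(pid = 1:10000, aid = 1:10000,
                                onset_age = 40, location = "colon")
  set.seed(14)
  ad <- simulate_adenoma_progression(ad0, p)
  transformed <- is.finite(ad$malignant_age) & !is.finite(ad$age_medium)
  ptr <- mean(transformed)
  expect_lt(abs(ptr - 1 / 3), 3 * sqrt((1 / 3) * (2 / 3) / 10000))
})

test_that("adenoma size paths are monotone and never regress", {
  set.seed(15)
  ad0 <- data.table::data.table(pid = 1:5000, aid = 1:5000,
                                onset_age = runif(5000, 20, 60),
                                location = "colon")
  ad <- simulate_adenoma_progression(ad0, default_nh_params())
  has_med <- is.finite(ad$age_medium)
  expect_true(all(ad$onset_age[has_med] < ad$age_medium[has_med]))
  has_lar <- is.finite(ad$age_large)
  expect_true(all(has_med[has_lar]))
  expect_true(all(ad$age_medium[has_lar] < ad$age_large[has_lar]))
  # transformation can only happen from the state reached
  tr <- is.finite(ad$malignant_age)
  expect_true(all(ad$malignant_age[tr] > ad$onset_age[tr]))
})

test_that("zero transformation hazards produce no cancers at all", {
  p <- constant_onset_params(0.05, transform_small = 0,
                             transform_medium = 0, transform_large = 0)
  h <- run_natural_history(mk_persons(2000), p, seed = 5)
  expect_identical(nrow(h$cancers), 0L)
  expect_true(all(h$persons$cause == "other"))
  s <- summarize_epidemiology(h)
  expect_true(all(s$incidence$rate_per_100k == 0))
})

test_that("cancer course honours forced-stage and cure-fraction corners", {
  p <- default_nh_params()
  # no symptomatic diagnosis before stage IV: every dx is stage IV
  p$sympt_rate <- c(I = 0, II = 0, III = 0, IV = 0.8)
  ca0 <- data.table::data.table(pid = 1:2000, aid = 1:2000, onset_age = 50,
                                location = "colon", sexi = 1L)
  set.seed(16)
  ca <- simulate_cancer_course(ca0, p)
  expect_true(all(ca$dx_stage == 4L))
  expect_true(all(ca$sympt_dx_age > 50))
  expect_true(all(diff(t(as.matrix(ca[1:50, c("e2", "e3", "e4")]))) > 0))

  # certain cure in stage I: no cancer death for stage-I diagnoses
  p2 <- default_nh_params()
  p2$cure_frac["male", ] <- c(1, 1, 1, 1)
  p2$surv_mean["male", ] <- c(1, 1, 1, 1)
  set.seed(17)
  ca2 <- simulate_cancer_course(ca0, p2)
  expect_true(all(!is.finite(ca2$crc_death_age)))
})

test_that("preclinical sojourn mean matches the exponential oracle", {
  # one-stage toy: diagnosis hazard d, progression made negligible
  d <- 0.5
  p <- default_nh_params()
  p$sojourn_mean[] <- 1e9
  p$sympt_rate <- c(I = d, II = d, III = d, IV = d)
  ca0 <- data.table::data.table(pid = 1:10000, aid = 1:10000, onset_age = 0,
                                location = "colon", sexi = 1L)
  set.seed(18)
  ca <- simulate_cancer_course(ca0, p)
  expect_true(all(ca$dx_stage == 1L))
  m <- mean(ca$sympt_dx_age)
  expect_lt(abs(m - 1 / d), 3 * (1 / d) / sqrt(10000))
})

test_that("events are truncated at death and histories are deterministic", {
  # onset intensity only after age 40, death at 40: no adenomas survive
  p <- default_nh_params()
  p$onset$breaks <- 40
  p$onset$rate_male <- 0.5
  p$onset$rate_female <- 0.5
  h <- run_natural_history(mk_persons(500, death = 40), p, seed = 6)
  expect_identical(nrow(h$adenomas), 0L)

  h1 <- run_natural_history(mk_persons(300, death = 90),
                            default_nh_params(), seed = 77)
  h2 <- run_natural_history(mk_persons(300, death = 90),
                            default_nh_params(), seed = 77)
  expect_identical(h1$adenomas, h2$adenomas)
  expect_identical(h1$cancers, h2$cancers)
  expect_identical(h1$persons, h2$persons)
  # death age is the minimum of other-cause and realised cancer deaths
  expect_true(all(h1$persons$death_age <= h1$persons$death_age_other))
})

test_that("hand-built histories give the expected band prevalence", {
  h <- run_natural_history(mk_persons(4, death = 100),
                           constant_onset_params(0), seed = 1)
  # two of four carry an adenoma spanning age 62.5
  h$adenomas <- data.table::data.table(
    pid = c(1L, 2L), onset_age = c(50, 55), aid = c(1L, 2L),
    location = "colon", age_medium = Inf, age_large = Inf,
    malignant_age = Inf, gt20 = FALSE, u_missed = 0.9)
  s <- summarize_epidemiology(h)
  row <- s$prevalence[s$prevalence$age_lo == 60 & s$prevalence$sex == "male", ]
  expect_equal(row$prevalence, 0.5)
})

test_that("summary agrees with an independent brute-force tally", {
  h <- run_natural_history(mk_persons(800, death = 95,
                                      risk = rep(c(0.5, 1, 2), length.out = 800)),
                           default_nh_params(), seed = 41)
  bands <- default_age_bands()
  s <- summarize_epidemiology(h, bands)

  persons <- as.data.frame(h$persons)
  ads <- as.data.frame(h$adenomas)
  cas <- as.data.frame(h$cancers)
  for (b in c(2L, 5L, 9L)) {
    mid <- (bands$age_lo[b] + bands$age_hi[b] + 1) / 2
    alive <- 0L; carry <- 0L
    for (i in seq_len(nrow(persons))) {
      if (persons$death_age[i] > mid) {
        alive <- alive + 1L
        rows <- ads[ads$pid == persons$id[i], ]
        if (nrow(rows) &&
            any(rows$onset_age <= mid & rows$malignant_age > mid)) {
          carry <- carry + 1L
        }
      }
    }
    got <- s$prevalence[s$prevalence$age_lo == bands$age_lo[b], ]
    expect_equal(sum(got$n_alive), alive)
    naive_prev <- if (alive > 0) carry / alive else 0
    pooled <- sum(got$prevalence * got$n_alive) / max(1, sum(got$n_alive))
    expect_equal(pooled, naive_prev, tolerance = 1e-12)

    # incidence events: naive count of clinical diagnoses in the band
    ev_naive <- 0L
    for (j in seq_len(nrow(cas))) {
      if (cas$cf_dx_valid[j] && cas$sympt_dx_age[j] >= bands$age_lo[b] &&
          cas$sympt_dx_age[j] < bands$age_hi[b] + 1) {
        ev_naive <- ev_naive + 1L
      }
    }
    inc_b <- s$incidence[s$incidence$age_lo == bands$age_lo[b], ]
    expect_equal(sum(inc_b$events), ev_naive)
  }
})

test_that("cumulative adenoma prevalence is non-decreasing in age", {
  p <- constant_onset_params(0.03, transform_small = 0,
                             transform_medium = 0, transform_large = 0)
  h <- run_natural_history(mk_persons(4000, death = 110), p, seed = 8)
  s <- summarize_epidemiology(h)
  prev_m <- s$prevalence[s$prevalence$sex == "male", ]
  expect_true(all(diff(prev_m$prevalence) >= -0.02))
})
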