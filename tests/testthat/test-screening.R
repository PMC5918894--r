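test_that("invitation schedules follow the biennial 50-69 rule", {
  prog <- default_program_config()
  sch <- build_invitation_schedule(list(birth_year = 1950,
                                        first_invitation_year = 2009), prog)
  expect_identical(sch$age, as.integer(c(59, 61, 63, 65, 67, 69)))
  expect_identical(nrow(sch), 6L)

  # 70 or older in 2009: never invited
  none <- build_invitation_schedule(list(birth_year = 1939,
                                         first_invitation_year = NA), prog)
  expect_identical(nrow(none), 0L)

  # death truncates the schedule
  short <- build_invitation_schedule(list(birth_year = 1950,
                                          first_invitation_year = 2009),
                                     prog, death_age = 60)
  expect_identical(short$age, 59L)
})

test_that("FIT behaves at the degenerate operating points", {
  zero <- default_test_characteristics()
  zero$fit_sensitivity[] <- 0
  zero$fit_specificity <- 1
  set.seed(2)
  res <- replicate(200, perform_fit(list(adenoma_class = c(1L, 3L),
                                         n_crc = 1L), zero))
  expect_true(all(!res))
  res2 <- replicate(50, perform_fit(list(adenoma_class = integer(0),
                                         n_crc = 0L), zero))
  expect_true(all(!res2))
})

test_that("lesion-free false-positive rate matches specificity", {
  chars <- default_test_characteristics()
  chars$fit_specificity <- 0.95
  set.seed(3)
  res <- replicate(10000, perform_fit(list(adenoma_class = integer(0),
                                           n_crc = 0L), chars))
  se <- sqrt(0.05 * 0.95 / 10000)
  expect_lt(abs(mean(res) - 0.05), 3 * se)
})

test_that("a systematically missed lesion never triggers the FIT", {
  chars <- default_test_characteristics()
  chars$fit_sensitivity[] <- 1
  set.seed(4)
  res <- replicate(500, perform_fit(list(adenoma_class = 3L,
                                         adenoma_missed = TRUE,
                                         n_crc = 0L), chars))
  expect_true(all(!res))
})

test_that("perfect colonoscopy excises everything; complications obey their rate", {
  chars <- default_test_characteristics()
  chars$colo_sensitivity[] <- 1
  set.seed(5)
  f <- perform_colonoscopy(list(adenoma_class = c(1L, 2L, 3L), n_crc = 0L),
                           "diagnostic", chars)
  expect_true(all(f$det_a))
  expect_true(f$polypectomy)
  g <- perform_colonoscopy(list(adenoma_class = integer(0), n_crc = 0L),
                           "diagnostic", chars)
  expect_false(g$polypectomy)
  expect_length(g$det_a, 0)

  chars$complication_prob <- 0.2
  set.seed(6)
  comp <- replicate(10000, perform_colonoscopy(list(adenoma_class = 1L,
                                                    n_crc = 0L),
                                               "diagnostic",
                                               chars)$complication)
  # condition on polypectomy having occurred
  set.seed(6)
  poly <- replicate(10000, perform_colonoscopy(list(adenoma_class = 1L,
                                                    n_crc = 0L),
                                               "diagnostic",
                                               chars)$polypectomy)
  rate <- sum(comp) / sum(poly)
  expect_lt(abs(rate - 0.2), 3 * sqrt(0.2 * 0.8 / sum(poly)))
})

test_that("surveillance dispositions follow the priority-ordered rules", {
  expect_equal(next_disposition(c(22)), "colonoscopy_in_1y")
  expect_equal(next_disposition(rep(4, 5)), "colonoscopy_in_1y")
  expect_equal(next_disposition(c(12)), "colonoscopy_in_3y")
  expect_equal(next_disposition(c(4, 4, 4)), "colonoscopy_in_3y")
  expect_equal(next_disposition(c(4, 4)), "fit_in_5y")
  expect_equal(next_disposition(c(7)), "fit_in_5y")
  expect_equal(next_disposition(numeric(0)), "routine_biennial_fit")
  # priority: a 22 mm adenoma outranks the 3-adenoma rule
  expect_equal(next_disposition(c(22, 4, 4)), "colonoscopy_in_1y")
})

# shared small screened population for the engine tests
mk_screen_setup <- function(n_total = 60000, scale = 0.1, seed = 9) {
  pyr <- generate_demography(n_total, 0.51)
  lt <- default_life_tables()
  pop <- build_population(pyr, lt, scale = scale, seed = seed)
  run_natural_history(pop, default_nh_params(), seed = seed + 1)
}

test_that("a null programme changes nothing but the invitation log", {
  hist <- mk_screen_setup()
  part0 <- default_participation_model()
  part0$fit_initial[] <- 0
  part0$fit_successive[] <- 0
  scr <- run_screening(hist, participation = part0, seed = 55)
  uns <- unscreened_arm(hist)
  non_inv <- scr$events[scr$events$event != EV$invite &
                          scr$events$event != EV$colo &
                          scr$events$event != EV$dx, ]
  expect_identical(nrow(non_inv), 0L)
  # identical outcomes person by person
  expect_equal(scr$persons$death_age, uns$persons$death_age)
  expect_identical(nrow(scr$dx), nrow(uns$dx))
  expect_equal(sort(scr$dx$dx_age), sort(uns$dx$dx_age))
})

test_that("perfect screening of pre-50 precursors removes all later cancers", {
  # onsets confined to ages 20-45, perfect tests and full participation:
  # every lesion is excised at the first attended round, so no cancer that
  # begins after that round is ever diagnosed in the screened arm
  p <- default_nh_params()
  p$onset$breaks <- c(20, 45)
  p$onset$rate_male <- c(0.06, 0)
  p$onset$rate_female <- c(0.06, 0)
  pyr <- generate_demography(30000, 0.5)
  pop <- build_population(pyr, default_life_tables(), scale = 0.2, seed = 31)
  hist <- run_natural_history(pop, p, seed = 32)

  chars <- default_test_characteristics()
  chars$fit_sensitivity[] <- 1
  chars$fit_specificity <- 1
  chars$colo_sensitivity[] <- 1
  part <- default_participation_model()
  part$fit_initial[] <- 1
  part$fit_successive[] <- 1
  part$colonoscopy_compliance <- 1
  scr <- run_screening(hist, chars = chars, participation = part, seed = 33)

  first_age <- hist$persons$first_invitation_year - hist$persons$birth_year
  onset_of <- hist$cancers$onset_age[match(scr$dx$aid, hist$cancers$aid)]
  fa <- first_age[scr$dx$pid]
  # a cancer diagnosed before the first invitation suspends screening, so
  # restrict to people who actually reached (and by construction attended)
  # their first round alive and undiagnosed
  early_dx <- tapply(scr$dx$dx_age < fa, scr$dx$pid, any)
  had_early <- unname(early_dx[as.character(scr$dx$pid)])
  attended <- !is.na(fa) & !had_early &
    hist$persons$death_age_other[scr$dx$pid] > fa
  expect_gt(sum(attended), 0)
  expect_true(all(onset_of[attended] <= fa[attended]))
})

test_that("the screening overlay is deterministic and decoupled from costs", {
  hist <- mk_screen_setup()
  s1 <- run_screening(hist, seed = 21)
  s2 <- run_screening(hist, seed = 21)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$dx, s2$dx)
  expect_equal(s1$persons$death_age, s2$persons$death_age)

  uns <- unscreened_arm(hist)
  cu <- default_cost_utility_tables()
  costs2 <- cu$costs
  costs2$invitation <- 50
  costs2$stage_IV_annual <- 1
  cea1 <- compute_cea(s1, uns, cu$costs, cu$utilities)
  cea2 <- compute_cea(s1, uns, costs2, cu$utilities)
  expect_equal(cea1$delta_qaly, cea2$delta_qaly)
})

test_that("screening count identities and age limits hold", {
  hist <- mk_screen_setup()
  part <- default_participation_model()
  part$colonoscopy_compliance <- 1
  scr <- run_screening(hist, participation = part, seed = 77)
  ev <- scr$events
  n_pos <- sum(ev$event == EV$fit_pos)
  n_diag <- sum(ev$event == EV$colo & ev$purpose == PURPOSE$diag)
  expect_identical(n_diag, n_pos)  # full compliance
  expect_lte(sum(ev$polypectomy), sum(ev$event == EV$colo))
  expect_lte(sum(ev$event == EV$fit), sum(ev$event == EV$invite))

  # routine events stay inside the 50-69 window
  routine <- ev[ev$event %in% c(EV$invite, EV$fit, EV$fit_pos), ]
  expect_true(all(routine$age >= 50 & routine$age <= 69))
  # surveillance may continue past 69, clinical events may happen at any age
  surv <- ev[ev$event == EV$colo & ev$purpose == PURPOSE$surv, ]
  if (nrow(surv)) expect_true(all(surv$age >= 50))
})

test_that("screening can only reduce or anticipate cancer burden (CRN)", {
  hist <- mk_screen_setup()
  scr <- run_screening(hist, seed = 13)
  uns <- unscreened_arm(hist)
  # no one dies earlier with screening than without
  expect_true(all(scr$persons$death_age >= uns$persons$death_age - 1e-9))
  # total diagnosed cancers do not increase, cancer deaths do not increase
  expect_lte(nrow(scr$dx), nrow(uns$dx))
  expect_lte(sum(scr$persons$cause == "crc"), sum(uns$persons$cause == "crc"))
  # each clinically diagnosed cancer in the screened arm exists, with the
  # same diagnosis age, in the counterfactual
  clin <- scr$dx[scr$dx$mode == crcscreen:::.MODE_CLINICAL, ]
  cf <- hist$cancers[match(clin$aid, hist$cancers$aid), ]
  expect_equal(clin$dx_age, cf$sympt_dx_age)
  # screen detections are never later than the counterfactual diagnosis
  sdx <- scr$dx[scr$dx$mode == crcscreen:::.MODE_SCREEN, ]
  cf2 <- hist$cancers[match(sdx$aid, hist$cancers$aid), ]
  expect_true(all(sdx$dx_age <= cf2$sympt_dx_age))
  expect_true(all(sdx$stage <= cf2$dx_stage))
})

test_that("correlated FIT false negatives can only lose positives", {
  hist <- mk_screen_setup(n_total = 40000, scale = 0.1)
  chars_on <- default_test_characteristics()
  chars_on$systematic_fn_fraction <- 1
  part <- default_participation_model()
  scr_on <- run_screening(hist, chars = chars_on, participation = part,
                          seed = 91)
  scr_off <- run_screening(hist, participation = part, seed = 91)
  pos_on <- sum(scr_on$events$event == EV$fit_pos)
  pos_off <- sum(scr_off$events$event == EV$fit_pos)
  expect_lte(pos_on, pos_off)
  # with every lesion missed, only false positives on lesion-free people and
  # their colonoscopies remain; no screen detection can occur
  expect_identical(sum(scr_on$dx$mode == crcscreen:::.MODE_SCREEN), 0L)
})
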