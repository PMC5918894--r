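# event type codes used in the compact internal log
.EV_INVITE <- 1L; .EV_FIT <- 2L; .EV_FIT_POS <- 3L; .EV_COLO <- 4L
.EV_COMPLICATION <- 5L; .EV_CRC_DX <- 6L
.PURPOSE_DIAG <- 1L; .PURPOSE_SURV <- 2L; .PURPOSE_CLIN <- 3L
.MODE_SCREEN <- 1L; .MODE_CLINICAL <- 2L

#' Routine invitation schedule for one individual
#'
#' Biennial invitations starting at the individual's first invitation year
#' (phased roll-out), continuing while the person is at most `age_max` years
#' old; invitations after death are dropped. Surveillance pathways and
#' cancer diagnoses, which suspend routine invitations, are handled by the
#' full programme overlay in [run_screening()], not here.
#'
#' @param individual list or one-row data.frame with `birth_year` and
#'   `first_invitation_year`
#' @param program programme configuration
#' @param death_age optional truncation age
#' @return data.table with columns `year` and `age` (possibly empty)
#' @export
#' @examples
#' build_invitation_schedule(list(birth_year = 1950,
#'                                first_invitation_year = 2009),
#'                           default_program_config())
build_invitation_schedule <- function(individual,
                                      program = default_program_config(),
                                      death_age = Inf) {
  f <- individual$first_invitation_year
  if (is.null(f) || is.na(f)) {
    return(data.table::data.table(year = integer(0), age = integer(0)))
  }
  b <- individual$birth_year
  yrs <- seq(f, b + program$age_max, by = program$screening_interval)
  ages <- yrs - b
  keep <- ages >= program$age_min & ages <= program$age_max & ages < death_age
  data.table::data.table(year = as.integer(yrs[keep]),
                         age = as.integer(ages[keep]))
}

# kernel: one FIT draw given the lesion inventory. One uniform per lesion;
# a lesion-free person gets a single false-positive draw against specificity.
.fit_positive <- function(a_class, a_missed, n_crc, crc_missed, chars) {
  n_a <- length(a_class)
  if (n_a + n_crc == 0L) {
    return(stats::runif(1) < 1 - chars$fit_specificity)
  }
  pos <- FALSE
  if (n_a > 0L) {
    hit <- stats::runif(n_a) < chars$fit_sensitivity[a_class] & !a_missed
    pos <- any(hit)
  }
  if (n_crc > 0L) {
    hitc <- stats::runif(n_crc) < chars$fit_sensitivity[["crc"]] & !crc_missed
    pos <- pos || any(hitc)
  }
  pos
}

# kernel: one colonoscopy draw; detection is independent per lesion
.colo_findings <- function(a_class, n_crc, chars) {
  det_a <- if (length(a_class)) {
    stats::runif(length(a_class)) < chars$colo_sensitivity[a_class]
  } else logical(0)
  det_c <- if (n_crc > 0L) {
    stats::runif(n_crc) < chars$colo_sensitivity[["crc"]]
  } else logical(0)
  poly <- any(det_a)
  compl <- FALSE
  if (poly) compl <- stats::runif(1) < chars$complication_prob
  list(det_a = det_a, det_c = det_c, polypectomy = poly,
       complication = compl)
}

#' Perform one FIT on a person state
#'
#' A person with no lesions tests positive with probability
#' `1 - fit_specificity`. Otherwise every lesion is tested independently
#' against its class sensitivity, and the test is positive if any lesion
#' triggers; lesions flagged as systematically missed never trigger
#' (correlated false-negative scenario).
#'
#' @param person_state list with `adenoma_class` (integer vector, 1 small /
#'   2 medium / 3 large), `adenoma_missed` (logical), `n_crc` (count of
#'   preclinical cancers) and `crc_missed` (logical)
#' @param chars test characteristics
#' @return logical: positive test?
#' @export
perform_fit <- function(person_state, chars = default_test_characteristics()) {
  .fit_positive(person_state$adenoma_class %||% integer(0),
                person_state$adenoma_missed %||%
                  rep(FALSE, length(person_state$adenoma_class)),
                person_state$n_crc %||% 0L,
                person_state$crc_missed %||% rep(FALSE,
                                                 person_state$n_crc %||% 0L),
                chars)
}

#' Perform one colonoscopy on a person state
#'
#' Every lesion is detected independently with its class-specific
#' colonoscopy sensitivity (incompleteness of reach is folded into the
#' sensitivity). All detected adenomas are excised (polypectomy); a
#' complication can occur only on a colonoscopy with polypectomy.
#'
#' @inheritParams perform_fit
#' @param purpose one of `"diagnostic"`, `"surveillance"`, `"clinical"`
#' @return list with `det_a` (logical per adenoma), `det_c` (logical per
#'   preclinical cancer), `polypectomy`, `complication`
#' @export
perform_colonoscopy <- function(person_state,
                                purpose = c("diagnostic", "surveillance",
                                            "clinical"),
                                chars = default_test_characteristics()) {
  purpose <- match.arg(purpose)
  .colo_findings(person_state$adenoma_class %||% integer(0),
                 person_state$n_crc %||% 0L, chars)
}

#' Surveillance disposition after a colonoscopy
#'
#' Applies the priority-ordered surveillance rules to the sizes (mm) of the
#' adenomas detected at a colonoscopy without cancer: 1-year recall for any
#' adenoma above 20 mm or five or more adenomas; 3-year recall for any
#' adenoma above 10 mm or 3-4 adenomas; return to FIT in five years for 1-2
#' small adenomas; routine biennial FIT after a negative colonoscopy.
#'
#' @param sizes_mm numeric vector of detected adenoma diameters (mm); empty
#'   for a negative colonoscopy
#' @param rules rule set, see [default_surveillance_rules()]
#' @return one of `"colonoscopy_in_1y"`, `"colonoscopy_in_3y"`,
#'   `"fit_in_5y"`, `"routine_biennial_fit"`
#' @export
#' @examples
#' next_disposition(c(22))        # 1-year recall
#' next_disposition(c(4, 4))      # back to FIT in 5 years
next_disposition <- function(sizes_mm,
                             rules = default_surveillance_rules()) {
  n <- length(sizes_mm)
  if (n >= rules$n_1y || any(sizes_mm > rules$mm_1y)) {
    "colonoscopy_in_1y"
  } else if (any(sizes_mm > rules$mm_3y) ||
             (n >= rules$n_3y_min && n <= rules$n_3y_max)) {
    "colonoscopy_in_3y"
  } else if (n >= 1L) {
    "fit_in_5y"
  } else {
    rules$negative_colonoscopy
  }
}

# derive a deterministic per-person RNG seed below 2^31 from the master seed
.person_seeds <- function(master, ids) {
  as.integer((as.numeric(master) + 1000003 * as.numeric(ids)) %% 2147483629)
}

#' Overlay the organised FIT screening programme on simulated histories
#'
#' Walks, for every individual, the invitation and surveillance calendar of
#' the programme: biennial FIT invitations between ages 50 and 69,
#' participation and colonoscopy compliance draws, per-lesion FIT and
#' colonoscopy detection, polypectomy (which cancels the excised lesion's
#' future cancer), surveillance scheduling by findings, complications, and
#' screen detection of preclinical cancer with stage anticipation. A
#' screen-detected cancer's survival is re-drawn from the detected (earlier)
#' stage reusing the cancer's persistent survival uniform, so anticipation
#' never shortens an individual's life. Other-cause death ages are untouched.
#'
#' Each person has their own RNG substream derived from `seed`, so paired
#' scenario runs (for example correlated versus independent FIT results)
#' share random draws person by person.
#'
#' @param hist `crc_histories` from [run_natural_history()]
#' @param program programme configuration
#' @param participation participation model
#' @param chars test characteristics (set `systematic_fn_fraction > 0` for
#'   the correlated false-negative scenario)
#' @param rules surveillance rules
#' @param seed integer master seed for the screening overlay
#' @return a `crc_arm` object: list with `persons` (screened death ages and
#'   causes), `events` (person, year, age, event, purpose, stage,
#'   polypectomy), `dx` (realised diagnoses with mode screen/clinical) and
#'   `label = "screened"`
#' @export
run_screening <- function(hist, program = default_program_config(),
                          participation = default_participation_model(),
                          chars = default_test_characteristics(),
                          rules = default_surveillance_rules(),
                          seed = 1L) {
  persons <- hist$persons
  n <- nrow(persons)
  stopifnot(identical(persons$id, seq_len(n)))
  ad <- hist$adenomas
  ca <- hist$cancers
  params <- hist$params

  # person-major slices of the lesion tables
  data.table::setorderv(ad, c("pid", "aid"))
  data.table::setorderv(ca, c("pid", "aid"))
  a_cnt <- tabulate(ad$pid, n); a_end <- cumsum(a_cnt)
  a_beg <- a_end - a_cnt + 1L
  c_cnt <- tabulate(ca$pid, n); c_end <- cumsum(c_cnt)
  c_beg <- c_end - c_cnt + 1L

  aon <- ad$onset_age; amed <- ad$age_medium; alar <- ad$age_large
  amal <- ad$malignant_age; agt20 <- ad$gt20
  a_missed <- ad$u_missed < chars$systematic_fn_fraction
  aid_v <- ad$aid

  con <- ca$onset_age; ce2 <- ca$e2; ce3 <- ca$e3; ce4 <- ca$e4
  cdx <- ca$sympt_dx_age; cstage <- ca$dx_stage; cu <- ca$surv_u
  cdeath <- ca$crc_death_age; c_aid <- ca$aid
  c_missed <- if (nrow(ca)) {
    ad$u_missed[match(ca$aid, ad$aid)] < chars$systematic_fn_fraction
  } else logical(0)

  birth <- persons$birth_year; d_other <- persons$death_age_other
  first_inv <- persons$first_invitation_year
  sexi <- ifelse(persons$sex == "male", 1L, 2L)
  pseed <- .person_seeds(seed, persons$id)

  fs <- chars$fit_sensitivity; cs <- chars$colo_sensitivity
  age_breaks <- participation$age_breaks
  p_init <- participation$fit_initial
  p_succ <- participation$fit_successive
  p_colo <- participation$colonoscopy_compliance
  interval <- program$screening_interval
  age_max <- program$age_max
  surv69 <- rules$surveillance_after_69

  # growing event / diagnosis accumulators
  cap <- max(64L, 16L * n)
  ev_pid <- integer(cap); ev_year <- integer(cap); ev_age <- numeric(cap)
  ev_type <- integer(cap); ev_purp <- integer(cap); ev_stage <- integer(cap)
  ev_poly <- logical(cap); ev_len <- 0L
  dcap <- max(64L, n %/% 8L)
  dx_pid <- integer(dcap); dx_age <- numeric(dcap); dx_stage <- integer(dcap)
  dx_mode <- integer(dcap); dx_aid <- integer(dcap); dx_len <- 0L

  push_ev <- function(pid, year, age, type, purp, stage, poly) {
    if (ev_len == length(ev_pid)) {
      grow <- function(x) c(x, x)
      ev_pid <<- grow(ev_pid); ev_year <<- grow(ev_year)
      ev_age <<- grow(ev_age); ev_type <<- grow(ev_type)
      ev_purp <<- grow(ev_purp); ev_stage <<- grow(ev_stage)
      ev_poly <<- grow(ev_poly)
    }
    ev_len <<- ev_len + 1L
    ev_pid[ev_len] <<- pid; ev_year[ev_len] <<- year
    ev_age[ev_len] <<- age; ev_type[ev_len] <<- type
    ev_purp[ev_len] <<- purp; ev_stage[ev_len] <<- stage
    ev_poly[ev_len] <<- poly
  }
  push_dx <- function(pid, age, stage, mode, aid) {
    if (dx_len == length(dx_pid)) {
      dx_pid <<- c(dx_pid, dx_pid); dx_age <<- c(dx_age, dx_age)
      dx_stage <<- c(dx_stage, dx_stage); dx_mode <<- c(dx_mode, dx_mode)
      dx_aid <<- c(dx_aid, dx_aid)
    }
    dx_len <<- dx_len + 1L
    dx_pid[dx_len] <<- pid; dx_age[dx_len] <<- age
    dx_stage[dx_len] <<- stage; dx_mode[dx_len] <<- mode
    dx_aid[dx_len] <<- aid
  }

  death <- d_other  # screened-arm death ages, updated per diagnosis
  handled <- rep(FALSE, n)

  invited <- which(!is.na(first_inv))
  for (p in invited) {
    handled[p] <- TRUE
    set.seed(pseed[p])
    b <- birth[p]
    dth <- d_other[p]
    ai <- if (a_cnt[p] > 0L) a_beg[p]:a_end[p] else integer(0)
    ci <- if (c_cnt[p] > 0L) c_beg[p]:c_end[p] else integer(0)
    exc <- rep(FALSE, length(ai))
    cancelled <- rep(FALSE, length(ci))
    dxed <- rep(FALSE, length(ci))
    next_fit <- as.numeric(first_inv[p]); next_surv <- Inf
    inv_count <- 0L
    exited <- FALSE

    finish_clinical <- function(dth_in) {
      # resolve remaining clinical diagnoses in time order
      dth_l <- dth_in
      repeat {
        open <- ci[!cancelled & !dxed]
        if (!length(open)) break
        rel <- open[which.min(cdx[open])]
        if (cdx[rel] >= dth_l) break
        k <- match(rel, ci); dxed[k] <<- TRUE
        a_dx <- cdx[rel]; y_dx <- as.integer(b + floor(a_dx))
        push_ev(p, y_dx, a_dx, .EV_COLO, .PURPOSE_CLIN, 0L, FALSE)
        push_ev(p, y_dx, a_dx, .EV_CRC_DX, .MODE_CLINICAL, cstage[rel], FALSE)
        push_dx(p, a_dx, cstage[rel], .MODE_CLINICAL, c_aid[rel])
        dth_l <- min(dth_l, cdeath[rel])
      }
      dth_l
    }

    repeat {
      ev_y <- min(next_fit, next_surv)
      ev_a <- ev_y - b
      # clinical pre-emption before the next scheduled screening contact
      open <- ci[!cancelled & !dxed]
      if (length(open)) {
        first_dx <- min(cdx[open])
        if (first_dx < min(ev_a, dth)) {
          dth <- finish_clinical(dth)
          exited <- TRUE
        }
      }
      if (exited || !is.finite(ev_y) || ev_a >= dth) break

      is_surv <- next_surv <= next_fit
      if (is_surv) next_surv <- Inf else next_fit <- Inf

      do_colo <- FALSE
      purpose <- .PURPOSE_SURV
      if (!is_surv) {
        inv_count <- inv_count + 1L
        push_ev(p, as.integer(ev_y), ev_a, .EV_INVITE, 0L, 0L, FALSE)
        band <- findInterval(ev_a, age_breaks)
        band <- max(1L, min(band, length(p_init)))
        p_part <- if (inv_count == 1L) p_init[band] else p_succ[band]
        if (stats::runif(1) < p_part) {
          push_ev(p, as.integer(ev_y), ev_a, .EV_FIT, 0L, 0L, FALSE)
          act_a <- ai[!exc & aon[ai] <= ev_a & amal[ai] > ev_a]
          act_c <- ci[!cancelled & !dxed & con[ci] <= ev_a]
          cls <- 1L + (ev_a >= amed[act_a]) + (ev_a >= alar[act_a])
          pos <- .fit_positive(cls, a_missed[act_a], length(act_c),
                               c_missed[act_c], chars)
          if (pos) {
            push_ev(p, as.integer(ev_y), ev_a, .EV_FIT_POS, 0L, 0L, FALSE)
            if (stats::runif(1) < p_colo) {
              do_colo <- TRUE
              purpose <- .PURPOSE_DIAG
            }
          }
        }
        if (!do_colo) {
          nf <- ev_y + interval
          if (nf - b <= age_max) next_fit <- nf
          next
        }
      } else {
        # surveillance colonoscopy appointment
        if (stats::runif(1) < p_colo) {
          do_colo <- TRUE
          purpose <- .PURPOSE_SURV
        } else {
          nf <- ev_y + interval
          if (nf - b <= age_max) next_fit <- nf
          next
        }
      }

      # colonoscopy at (ev_y, ev_a)
      act_a <- ai[!exc & aon[ai] <= ev_a & amal[ai] > ev_a]
      act_c <- ci[!cancelled & !dxed & con[ci] <= ev_a]
      cls <- 1L + (ev_a >= amed[act_a]) + (ev_a >= alar[act_a])
      f <- .colo_findings(cls, length(act_c), chars)
      push_ev(p, as.integer(ev_y), ev_a, .EV_COLO, purpose, 0L,
              f$polypectomy)
      if (f$complication) {
        push_ev(p, as.integer(ev_y), ev_a, .EV_COMPLICATION, 0L, 0L, FALSE)
      }
      if (any(f$det_a)) {
        rem <- act_a[f$det_a]
        exc[match(rem, ai)] <- TRUE
        # an excised adenoma generates no later cancer
        if (length(ci)) {
          dead_ca <- ci[c_aid[ci] %in% aid_v[rem] & con[ci] > ev_a]
          cancelled[match(dead_ca, ci)] <- TRUE
        }
      }
      if (any(f$det_c)) {
        found <- act_c[f$det_c]
        st_now <- 1L + (ev_a >= ce2[found]) + (ev_a >= ce3[found]) +
          (ev_a >= ce4[found])
        for (k in seq_along(found)) {
          rel <- found[k]
          dxed[match(rel, ci)] <- TRUE
          delay <- surv_delay_from_u(st_now[k], sexi[p], cu[rel], params)
          push_ev(p, as.integer(ev_y), ev_a, .EV_CRC_DX, .MODE_SCREEN,
                  st_now[k], FALSE)
          push_dx(p, ev_a, st_now[k], .MODE_SCREEN, c_aid[rel])
          # survival re-drawn from the detected stage with the same uniform;
          # floored at the counterfactual course so earlier detection (lead
          # time) can only preserve or extend the individual's life
          dth <- min(dth, max(ev_a + delay, cdeath[rel]))
        }
        dth <- finish_clinical(dth)
        break
      }
      disp <- next_disposition(
        ifelse(cls[f$det_a] == 3L,
               ifelse(agt20[act_a[f$det_a]], .class_mm_gt20, .class_mm[3L]),
               .class_mm[cls[f$det_a]]),
        rules)
      if (disp == "colonoscopy_in_1y") {
        if (surv69 || ev_a + 1 <= age_max) next_surv <- ev_y + 1
      } else if (disp == "colonoscopy_in_3y") {
        if (surv69 || ev_a + 3 <= age_max) next_surv <- ev_y + 3
      } else if (disp == "fit_in_5y") {
        if (ev_a + 5 <= age_max) next_fit <- ev_y + 5
      } else {
        if (ev_a + interval <= age_max) next_fit <- ev_y + interval
      }
    }
    if (!exited) dth <- finish_clinical(dth)
    death[p] <- dth
  }

  # individuals never invited: counterfactual outcomes carry over
  rest <- which(!handled)
  if (length(rest)) {
    death[rest] <- hist$persons$death_age[rest]
    if (nrow(ca)) {
      sel <- which(ca$cf_dx_valid & ca$pid %in% rest)
      for (r in sel) {
        p <- ca$pid[r]; a_dx <- cdx[r]
        y_dx <- as.integer(birth[p] + floor(a_dx))
        push_ev(p, y_dx, a_dx, .EV_COLO, .PURPOSE_CLIN, 0L, FALSE)
        push_ev(p, y_dx, a_dx, .EV_CRC_DX, .MODE_CLINICAL, cstage[r], FALSE)
        push_dx(p, a_dx, cstage[r], .MODE_CLINICAL, c_aid[r])
      }
    }
  }

  ev <- data.table::data.table(
    pid = ev_pid[seq_len(ev_len)], year = ev_year[seq_len(ev_len)],
    age = ev_age[seq_len(ev_len)], event = ev_type[seq_len(ev_len)],
    purpose = ev_purp[seq_len(ev_len)], stage = ev_stage[seq_len(ev_len)],
    polypectomy = ev_poly[seq_len(ev_len)])
  dx <- data.table::data.table(
    pid = dx_pid[seq_len(dx_len)], dx_age = dx_age[seq_len(dx_len)],
    stage = dx_stage[seq_len(dx_len)], mode = dx_mode[seq_len(dx_len)],
    aid = dx_aid[seq_len(dx_len)])
  dx[, "dx_year" := as.integer(floor(persons$birth_year[dx$pid] + dx$dx_age))]
  out_persons <- persons[, c("id", "sex", "age0", "birth_year",
                             "death_age_other")]
  out_persons[, "death_age" := death]
  out_persons[, "cause" := ifelse(death < d_other, "crc", "other")]
  structure(list(persons = out_persons, events = ev, dx = dx,
                 label = "screened"),
            class = "crc_arm")
}

#' Counterfactual (no screening) arm of a simulated population
#'
#' Packs the natural-history outcome into the same arm structure produced by
#' [run_screening()]: one clinical colonoscopy and diagnosis event per cancer
#' diagnosed while alive, and the counterfactual death ages.
#'
#' @param hist `crc_histories`
#' @return `crc_arm` with label `"unscreened"`
#' @export
unscreened_arm <- function(hist) {
  persons <- hist$persons
  ca <- hist$cancers[hist$cancers$cf_dx_valid == TRUE, ]
  b <- persons$birth_year[match(ca$pid, persons$id)]
  y <- as.integer(floor(b + ca$sympt_dx_age))
  ev <- data.table::rbindlist(list(
    data.table::data.table(pid = ca$pid, year = y, age = ca$sympt_dx_age,
                           event = .EV_COLO, purpose = .PURPOSE_CLIN,
                           stage = 0L, polypectomy = FALSE),
    data.table::data.table(pid = ca$pid, year = y, age = ca$sympt_dx_age,
                           event = .EV_CRC_DX, purpose = .MODE_CLINICAL,
                           stage = ca$dx_stage, polypectomy = FALSE)))
  data.table::setorderv(ev, c("pid", "year"))
  dx <- data.table::data.table(pid = ca$pid, dx_age = ca$sympt_dx_age,
                               stage = ca$dx_stage, mode = .MODE_CLINICAL,
                               aid = ca$aid, dx_year = y)
  out_persons <- persons[, c("id", "sex", "age0", "birth_year",
                             "death_age_other", "death_age", "cause")]
  structure(list(persons = out_persons, events = ev, dx = dx,
                 label = "unscreened"),
            class = "crc_arm")
}

#' @export
print.crc_arm <- function(x, ...) {
  cat("<crc_arm:", x$label, "> ", nrow(x$persons), " individuals, ",
      nrow(x$events), " events, ", nrow(x$dx), " cancer diagnoses\n",
      sep = "")
  invisible(x)
}
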