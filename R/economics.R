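#' Discount a value to the programme base year
#'
#' Annual compounding: `amount / (1 + rate)^(event_year - base_year)`.
#'
#' @param amount numeric amount(s)
#' @param event_year calendar year(s) of the event, `>= base_year`
#' @param base_year discounting base year (programme start)
#' @param rate annual discount rate
#' @return discounted amount
#' @export
#' @examples
#' discount_value(100, 2010)  # 97.0874
discount_value <- function(amount, event_year, base_year = 2009,
                           rate = 0.03) {
  stopifnot(all(event_year >= base_year))
  amount / (1 + rate)^(event_year - base_year)
}

# map internal event codes to cost ledger categories
.colo_cat <- c("colonoscopy_diag", "colonoscopy_surv", "colonoscopy_clin")

# annual streams (follow-up costs, care disutilities) for diagnosed cancers:
# stage I-III streams run from diagnosis until death or the cap, stage IV
# until death; partial years accrue pro rata and are booked in the calendar
# year they fall in
.care_stream <- function(dx, death_age, rate_by_stage, cap_I_III) {
  if (nrow(dx) == 0L) {
    return(data.table::data.table(year = integer(0), amount = numeric(0)))
  }
  dur <- pmax(0, death_age - dx$dx_age)
  capped <- dx$stage <= 3L
  dur[capped] <- pmin(dur[capped], cap_I_III)
  kmax <- ceiling(dur)
  kmax[!is.finite(kmax)] <- 0L
  idx <- rep.int(seq_len(nrow(dx)), kmax)
  k <- sequence(kmax)
  frac <- pmin(1, dur[idx] - (k - 1))
  data.table::data.table(
    year = dx$dx_year[idx] + k,
    amount = rate_by_stage[dx$stage[idx]] * frac
  )
}

#' Cost ledger of one simulation arm
#'
#' Prices every event of an arm with the unit-cost table: invitation cost for
#' every invitation, FIT analysis for every returned kit, a primary-care
#' consultation for every positive result, colonoscopy cost keyed on the
#' polypectomy flag, complication cost per complication; treatment costs per
#' diagnosis (initial cost at diagnosis for stages I-III, annual follow-up
#' for stages I-III up to `followup_cap_years`, and the flat annual stage-IV
#' amount for each year lived with stage-IV disease). Undiscounted.
#'
#' @param arm `crc_arm` object
#' @param costs cost table, see [default_cost_utility_tables()]
#' @return data.table with columns `year`, `category`, `amount`, `count`
#' @export
tally_costs <- function(arm, costs = default_cost_utility_tables()$costs) {
  ev <- arm$events
  unit <- numeric(nrow(ev))
  cat <- character(nrow(ev))
  unit[ev$event == .EV_INVITE] <- costs$invitation
  cat[ev$event == .EV_INVITE] <- "invitation"
  unit[ev$event == .EV_FIT] <- costs$fit_analysis
  cat[ev$event == .EV_FIT] <- "fit"
  unit[ev$event == .EV_FIT_POS] <- costs$consult_positive
  cat[ev$event == .EV_FIT_POS] <- "consult"
  is_colo <- ev$event == .EV_COLO
  unit[is_colo] <- ifelse(ev$polypectomy[is_colo],
                          costs$colonoscopy_with_polypectomy,
                          costs$colonoscopy_without_polypectomy)
  cat[is_colo] <- .colo_cat[ev$purpose[is_colo]]
  unit[ev$event == .EV_COMPLICATION] <- costs$complication
  cat[ev$event == .EV_COMPLICATION] <- "complication"
  keep <- cat != ""   # diagnosis events carry no direct cost
  led <- data.table::data.table(year = ev$year[keep], category = cat[keep],
                                amount = unit[keep])
  led <- led[, list(amount = sum(amount), count = .N),
             by = c("year", "category")]

  dx <- arm$dx
  if (nrow(dx)) {
    death <- arm$persons$death_age[dx$pid]
    init <- dx[dx$stage <= 3L, ]
    init_led <- data.table::data.table(
      year = init$dx_year,
      category = "treatment_initial",
      amount = costs$treatment_initial[init$stage],
      count = 1L)
    fu <- .care_stream(dx[dx$stage <= 3L, ], death[dx$stage <= 3L],
                       rep(costs$followup_annual_stage_I_III, 3L),
                       costs$followup_cap_years)
    fu[, "category" := "treatment_followup"]
    s4 <- .care_stream(dx[dx$stage == 4L, ], death[dx$stage == 4L],
                       c(0, 0, 0, costs$stage_IV_annual), Inf)
    s4[, "category" := "treatment_stage4"]
    extra <- data.table::rbindlist(list(
      init_led,
      fu[, list(amount = sum(amount), count = .N),
         by = c("year", "category")],
      s4[, list(amount = sum(amount), count = .N),
         by = c("year", "category")]), use.names = TRUE)
    led <- data.table::rbindlist(list(led, extra), use.names = TRUE)
  }
  data.table::setorderv(led, c("year", "category"))
  led[]
}

# discounted life-years lived from base_year until death, mid-year placement
# off: the life-year fraction lived in calendar year y is discounted by the
# factor of year y
.disc_life_years <- function(birth_year, death_age, base_year, rate) {
  d_cal <- birth_year + death_age
  v <- 1 / (1 + rate)
  K <- pmax(0, floor(d_cal) - base_year)
  frac <- pmax(0, pmin(d_cal - base_year, d_cal - floor(d_cal)))
  frac[d_cal <= base_year] <- 0
  full <- if (rate > 0) (1 - v^K) / (1 - v) else K
  full + frac * v^K
}

#' Quality-adjusted life-years of one simulation arm
#'
#' QALYs are discounted life-years lived from the base year, minus the
#' discounted event disutilities (per colonoscopy and per complication),
#' minus discounted annual utility losses for each life-year lived with
#' diagnosed cancer care (stages I-III up to the follow-up cap, stage IV
#' until death).
#'
#' @param arm `crc_arm`
#' @param utilities utility table
#' @param rate discount rate
#' @param base_year base year
#' @param followup_cap_years cap on the stage I-III care-loss years
#' @return list with `qaly`, `disc_life_years`, `life_years` (undiscounted),
#'   `event_disutility`, `care_loss`
#' @export
tally_qalys <- function(arm,
                        utilities = default_cost_utility_tables()$utilities,
                        rate = 0.03, base_year = 2009,
                        followup_cap_years = 5) {
  pers <- arm$persons
  dly <- sum(.disc_life_years(pers$birth_year, pers$death_age, base_year,
                              rate))
  ly <- sum(pmax(0, pers$birth_year + pers$death_age - base_year))
  ev <- arm$events
  colo_years <- ev$year[ev$event == .EV_COLO]
  comp_years <- ev$year[ev$event == .EV_COMPLICATION]
  dis <- sum(discount_value(rep(utilities$disutility_colonoscopy,
                                length(colo_years)),
                            pmax(colo_years, base_year), base_year, rate)) +
    sum(discount_value(rep(utilities$disutility_complication,
                           length(comp_years)),
                       pmax(comp_years, base_year), base_year, rate))
  dx <- arm$dx
  care <- 0
  if (nrow(dx)) {
    death <- pers$death_age[dx$pid]
    cl <- .care_stream(dx, death, utilities$annual_loss_with_crc_care,
                       followup_cap_years)
    if (nrow(cl)) {
      care <- sum(discount_value(cl$amount, pmax(cl$year, base_year),
                                 base_year, rate))
    }
  }
  list(qaly = dly - dis - care, disc_life_years = dly, life_years = ly,
       event_disutility = dis, care_loss = care)
}

#' Cost-effectiveness verdict
#'
#' A strategy is dominant when it costs less and yields more QALYs than its
#' comparator, dominated in the opposite quadrant; otherwise the incremental
#' cost-effectiveness ratio (ICER) is the incremental cost divided by the
#' incremental QALYs.
#'
#' @param delta_cost incremental cost (intervention minus comparator)
#' @param delta_qaly incremental QALYs
#' @return list with `verdict` (`"dominant"`, `"dominated"` or `"icer"`) and
#'   `icer` (numeric; `NA` when dominance applies)
#' @export
#' @examples
#' cea_verdict(-93.1e6, 56664.8)$verdict
cea_verdict <- function(delta_cost, delta_qaly) {
  if (delta_cost < 0 && delta_qaly > 0) {
    list(verdict = "dominant", icer = NA_real_)
  } else if (delta_cost > 0 && delta_qaly < 0) {
    list(verdict = "dominated", icer = NA_real_)
  } else {
    list(verdict = "icer", icer = delta_cost / delta_qaly)
  }
}

#' Cost-effectiveness analysis of paired arms
#'
#' Discounts the cost ledgers and QALYs of a screened and an unscreened arm
#' built from the same individuals (common random numbers), rescales from
#' the simulated sample to the full population, and returns incremental
#' costs, incremental QALYs and the ICER or dominance verdict.
#'
#' @param screened,unscreened `crc_arm` objects sharing the same individuals
#' @param costs,utilities unit cost and utility tables
#' @param scale_factor population persons represented per simulated person
#' @param rate,base_year discounting configuration
#' @return object of class `crc_cea`
#' @export
compute_cea <- function(screened, unscreened,
                        costs = default_cost_utility_tables()$costs,
                        utilities = default_cost_utility_tables()$utilities,
                        scale_factor = 1, rate = 0.03, base_year = 2009) {
  stopifnot(nrow(screened$persons) == nrow(unscreened$persons))
  disc_total <- function(led) {
    sum(discount_value(led$amount, pmax(led$year, base_year), base_year,
                       rate))
  }
  led_s <- tally_costs(screened, costs)
  led_u <- tally_costs(unscreened, costs)
  treat_cats <- c("treatment_initial", "treatment_followup",
                  "treatment_stage4")
  cost_s <- disc_total(led_s) * scale_factor
  cost_u <- disc_total(led_u) * scale_factor
  treat_s <- disc_total(led_s[led_s$category %in% treat_cats, ]) *
    scale_factor
  treat_u <- disc_total(led_u[led_u$category %in% treat_cats, ]) *
    scale_factor
  q_s <- tally_qalys(screened, utilities, rate, base_year,
                     costs$followup_cap_years)
  q_u <- tally_qalys(unscreened, utilities, rate, base_year,
                     costs$followup_cap_years)
  dC <- cost_s - cost_u
  dE <- (q_s$qaly - q_u$qaly) * scale_factor
  v <- cea_verdict(dC, dE)
  n <- nrow(screened$persons)
  structure(list(
    cost_screened = cost_s, cost_unscreened = cost_u,
    treatment_cost_screened = treat_s, treatment_cost_unscreened = treat_u,
    qaly_screened = q_s$qaly * scale_factor,
    qaly_unscreened = q_u$qaly * scale_factor,
    delta_cost = dC, delta_treatment_cost = treat_s - treat_u,
    delta_qaly = dE,
    verdict = v$verdict, icer = v$icer,
    life_years_unscreened_per_person = q_u$life_years / n,
    life_days_gained_per_person =
      365 * mean(screened$persons$death_age - unscreened$persons$death_age),
    scale_factor = scale_factor, n_simulated = n,
    rate = rate, base_year = base_year
  ), class = "crc_cea")
}

#' @export
print.crc_cea <- function(x, ...) {
  cat("<crc_cea> screening vs no screening (discounted at ",
      x$rate * 100, "%)\n", sep = "")
  cat(sprintf("  incremental cost : %10.1f million\n", x$delta_cost / 1e6))
  cat(sprintf("  incremental QALY : %10.1f\n", x$delta_qaly))
  if (x$verdict == "icer") {
    cat(sprintf("  ICER             : %10.1f per QALY\n", x$icer))
  } else {
    cat("  verdict          : ", x$verdict, "\n", sep = "")
  }
  invisible(x)
}

# component classification used by the budget impact analysis
.bia_component <- function(category) {
  data.table::fcase(
    category %in% c("invitation", "fit", "consult"), "screening",
    category %in% c("colonoscopy_diag", "colonoscopy_surv",
                    "colonoscopy_clin", "complication"), "diagnosis",
    default = "treatment")
}

#' Budget impact analysis of paired arms
#'
#' Undiscounted annual cost streams per arm over the analysis window, by
#' component (screening, diagnosis, treatment), their yearly incremental
#' difference, and the annual colonoscopy counts by purpose in the screened
#' arm (capacity planning companion output).
#'
#' @inheritParams compute_cea
#' @param years analysis window (calendar years)
#' @return object of class `crc_bia` with elements `stream` (year, arm,
#'   component, cost), `incremental` (year, cost), `colonoscopies` (year,
#'   purpose, count) and window totals
#' @export
compute_bia <- function(screened, unscreened,
                        costs = default_cost_utility_tables()$costs,
                        scale_factor = 1, years = 2009:2038) {
  comp_stream <- function(arm, label) {
    led <- tally_costs(arm, costs)
    led <- led[led$year %in% years, ]
    led[, "component" := .bia_component(led$category)]
    s <- led[, list(cost = sum(amount) * scale_factor),
             by = c("year", "component")]
    s[, "arm" := label]
    s
  }
  s_s <- comp_stream(screened, "screened")
  s_u <- comp_stream(unscreened, "unscreened")
  stream <- data.table::rbindlist(list(s_s, s_u), use.names = TRUE)
  grid <- data.table::CJ(year = years, arm = c("screened", "unscreened"))
  tot <- stream[, list(cost = sum(cost)), by = c("year", "arm")]
  tot <- tot[grid, on = c("year", "arm")]
  tot[is.na(tot$cost), "cost" := 0]
  wide <- data.table::dcast(tot, year ~ arm, value.var = "cost")
  inc <- data.table::data.table(year = wide$year,
                                cost = wide$screened - wide$unscreened)
  ev <- screened$events
  colo <- ev[ev$event == .EV_COLO & ev$year %in% years, ]
  purpose_lab <- c("diagnostic", "surveillance", "clinical")
  colo_tab <- colo[, list(count = .N * scale_factor),
                   by = c("year", "purpose")]
  colo_tab[, "purpose" := purpose_lab[colo_tab$purpose]]
  data.table::setorderv(colo_tab, c("year", "purpose"))
  structure(list(stream = stream[order(stream$year), ],
                 incremental = inc[order(inc$year), ],
                 colonoscopies = colo_tab[],
                 total_screened = sum(tot$cost[tot$arm == "screened"]),
                 total_unscreened = sum(tot$cost[tot$arm == "unscreened"]),
                 years = years, scale_factor = scale_factor),
            class = "crc_bia")
}

#' @export
print.crc_bia <- function(x, ...) {
  cat("<crc_bia> ", min(x$years), "-", max(x$years),
      sprintf(": screened %.1f M, unscreened %.1f M, incremental %.1f M\n",
              x$total_screened / 1e6, x$total_unscreened / 1e6,
              (x$total_screened - x$total_unscreened) / 1e6), sep = "")
  invisible(x)
}

#' Re-price the programme over a range of invitation unit costs
#'
#' The dynamics (and therefore QALYs, event counts and colonoscopy demand)
#' do not depend on unit costs, so the same event logs are re-priced at each
#' candidate invitation cost; only the incremental cost moves, linearly in
#' the discounted number of invitations.
#'
#' @inheritParams compute_cea
#' @param invitation_costs numeric vector of unit costs to evaluate
#' @return data.table with columns `invitation_cost`, `delta_cost`,
#'   `delta_qaly`, `verdict`, `icer`
#' @export
invitation_cost_sweep <- function(screened, unscreened,
                                  costs =
                                    default_cost_utility_tables()$costs,
                                  utilities =
                                    default_cost_utility_tables()$utilities,
                                  scale_factor = 1,
                                  invitation_costs = c(6.06, 15, 20, 25, 30,
                                                       40, 50),
                                  rate = 0.03, base_year = 2009) {
  base <- compute_cea(screened, unscreened, costs, utilities, scale_factor,
                      rate, base_year)
  ev <- screened$events
  inv_years <- ev$year[ev$event == .EV_INVITE]
  disc_inv <- sum(discount_value(rep(1, length(inv_years)),
                                 pmax(inv_years, base_year), base_year,
                                 rate)) * scale_factor
  out <- data.table::data.table(invitation_cost = invitation_costs)
  out[, "delta_cost" := base$delta_cost +
        (out$invitation_cost - costs$invitation) * disc_inv]
  out[, "delta_qaly" := base$delta_qaly]
  vs <- lapply(out$delta_cost, cea_verdict, delta_qaly = base$delta_qaly)
  out[, "verdict" := vapply(vs, `[[`, "", "verdict")]
  out[, "icer" := vapply(vs, `[[`, 0, "icer")]
  out[]
}
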