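# fixtures are built in code; no data files

# life table with constant annual death probability (terminal age forced)
flat_life_table <- function(q = 0, sexes = c("male", "female"),
                            max_age = 110L) {
  data.table::rbindlist(lapply(sexes, function(s) {
    data.table::data.table(sex = s, age = 0:max_age,
                           q = c(rep(q, max_age), 1))
  }))
}

# q = 0 everywhere except a single year (and the terminal age)
step_life_table <- function(death_year, sexes = c("male", "female"),
                            max_age = 110L) {
  data.table::rbindlist(lapply(sexes, function(s) {
    qv <- rep(0, max_age + 1L)
    qv[death_year + 1L] <- 1
    qv[max_age + 1L] <- 1
    data.table::data.table(sex = s, age = 0:max_age, q = qv)
  }))
}

# hand-built individuals table accepted by the natural-history samplers
mk_persons <- function(n, sex = "male", death = 110, risk = 1) {
  data.table::data.table(
    id = seq_len(n), sex = rep_len(sex, n), age0 = 0L, birth_year = 0L,
    death_age_other = rep_len(death, n), risk_index = rep_len(risk, n),
    first_invitation_year = NA_integer_)
}

# natural-history parameters with selective overrides via flat names
toy_params <- function(...) {
  p <- default_nh_params()
  mods <- list(...)
  for (nm in names(mods)) p <- nh_param_set(p, nm, mods[[nm]])
  p
}

# constant onset intensity from birth (single band starting at age 0)
constant_onset_params <- function(lambda, ...) {
  p <- toy_params(...)
  p$onset$breaks <- 0
  p$onset$rate_male <- lambda
  p$onset$rate_female <- lambda
  p
}

# minimal hand-built arm for the economics layer
mk_arm <- function(persons, events = NULL, dx = NULL, label = "test") {
  if (is.null(events)) {
    events <- data.table::data.table(
      pid = integer(0), year = integer(0), age = numeric(0),
      event = integer(0), purpose = integer(0), stage = integer(0),
      polypectomy = logical(0))
  }
  if (is.null(dx)) {
    dx <- data.table::data.table(
      pid = integer(0), dx_age = numeric(0), stage = integer(0),
      mode = integer(0), aid = integer(0), dx_year = integer(0))
  }
  structure(list(persons = persons, events = events, dx = dx,
                 label = label), class = "crc_arm")
}

mk_arm_persons <- function(birth_year, death_age, sex = "male") {
  n <- length(birth_year)
  data.table::data.table(
    id = seq_len(n), sex = rep_len(sex, n), age0 = 0L,
    birth_year = birth_year, death_age_other = death_age,
    death_age = death_age, cause = "other")
}

ev_row <- function(pid, year, event, purpose = 0L, stage = 0L,
                   poly = FALSE, age = 60) {
  data.table::data.table(pid = pid, year = as.integer(year), age = age,
                         event = event, purpose = purpose, stage = stage,
                         polypectomy = poly)
}

EV <- list(invite = crcscreen:::.EV_INVITE, fit = crcscreen:::.EV_FIT,
           fit_pos = crcscreen:::.EV_FIT_POS, colo = crcscreen:::.EV_COLO,
           compl = crcscreen:::.EV_COMPLICATION,
           dx = crcscreen:::.EV_CRC_DX)
PURPOSE <- list(diag = crcscreen:::.PURPOSE_DIAG,
                surv = crcscreen:::.PURPOSE_SURV,
                clin = crcscreen:::.PURPOSE_CLIN)
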