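# small FNV-1a hash over a serialized object; used for run manifests
.fnv1a <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

.derive_seed <- function(master, k) {
  as.integer((as.numeric(master) + 1000003 * k) %% 2147483629)
}

#' Default end-to-end scenario configuration
#'
#' Nested configuration consumed by [run_scenario()]. The population block
#' sets the full population the simulation represents (2.23 million, 51%
#' women, referenced to 2008) and the number of individuals actually
#' simulated; outputs are rescaled by the implied factor. Scenario switches
#' activate the sensitivity analyses: lower adenoma prevalence (onset
#' intensity scaled down), correlated FIT false negatives (a persistent
#' fraction of lesions never detectable by FIT), and an invitation unit-cost
#' sweep.
#'
#' @param ... named overrides merged (recursively) into the defaults, e.g.
#'   `scenario_config(seed = 7, scenario = list(correlated_fit = TRUE))`
#' @return nested configuration list
#' @export
scenario_config <- function(...) {
  cu <- default_cost_utility_tables()
  cfg <- list(
    seed = 1L,
    population = list(total = 2230000, female_share = 0.51,
                      reference_year = 2008L, n_simulated = 50000L),
    program = default_program_config(),
    nh_params = default_nh_params(),
    screening = list(participation = default_participation_model(),
                     chars = default_test_characteristics(),
                     rules = default_surveillance_rules()),
    economics = list(costs = cu$costs, utilities = cu$utilities),
    scenario = list(low_prevalence = FALSE,
                    low_prevalence_multiplier = 0.6,
                    correlated_fit = FALSE,
                    systematic_fn_fraction = 0.25,
                    invitation_cost_sweep = NULL)
  )
  overrides <- list(...)
  if (length(overrides)) cfg <- utils::modifyList(cfg, overrides)
  cfg
}

#' Read a scenario configuration from YAML
#'
#' Reads a YAML file whose keys mirror [scenario_config()] and merges it
#' into the defaults. Unknown keys are kept (and ignored by the runner).
#'
#' @param path YAML file path
#' @return nested configuration list
#' @export
read_scenario_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(scenario_config, y)
}

#' Run an end-to-end screening scenario
#'
#' Builds the population once, simulates every individual's natural history,
#' then evaluates the unscreened (counterfactual) and screened arms on the
#' identical individuals with aligned random streams, and produces the
#' cost-effectiveness result, the budget impact streams, the colonoscopy
#' projection, and a manifest sufficient to reproduce the run bit-for-bit.
#'
#' Sub-seeds for the population, the natural history and the screening
#' overlay are derived deterministically from the master seed, so scenarios
#' that share a master seed and natural-history parameters have
#' byte-identical unscreened arms, and toggling only screening parameters
#' preserves person-level pairing of the screening draws.
#'
#' @param config configuration from [scenario_config()] /
#'   [read_scenario_config()]
#' @return object of class `crc_scenario`: `cea`, `bia`, `sweep` (or NULL),
#'   `screened`, `unscreened`, `histories`, `population`, `manifest`
#' @export
run_scenario <- function(config = scenario_config()) {
  stopifnot(!is.null(config$seed))
  seed_pop <- .derive_seed(config$seed, 1)
  seed_nh <- .derive_seed(config$seed, 2)
  seed_scr <- .derive_seed(config$seed, 3)

  lt <- default_life_tables()
  pyr <- generate_demography(config$population$total,
                             config$population$female_share,
                             reference_year =
                               config$population$reference_year)
  scale <- config$population$n_simulated / config$population$total
  nhp <- config$nh_params
  if (isTRUE(config$scenario$low_prevalence)) {
    nhp$onset$multiplier <- nhp$onset$multiplier *
      config$scenario$low_prevalence_multiplier
  }
  pop <- build_population(pyr, lt, config$program, scale = scale,
                          seed = seed_pop, frailty_var = nhp$frailty_var)
  hist <- run_natural_history(pop, nhp, seed = seed_nh)
  uns <- unscreened_arm(hist)
  chars <- config$screening$chars
  if (isTRUE(config$scenario$correlated_fit)) {
    chars$systematic_fn_fraction <- config$scenario$systematic_fn_fraction
  }
  scr <- run_screening(hist, config$program,
                       config$screening$participation, chars,
                       config$screening$rules, seed = seed_scr)
  sf <- attr(pop, "scale_factor")
  costs <- config$economics$costs
  utilities <- config$economics$utilities
  cea <- compute_cea(scr, uns, costs, utilities, scale_factor = sf,
                     rate = config$program$discount_rate,
                     base_year = config$program$base_year)
  bia <- compute_bia(scr, uns, costs, scale_factor = sf,
                     years = config$program$start_year:
                       config$program$last_new_cohort_year)
  sweep <- NULL
  if (!is.null(config$scenario$invitation_cost_sweep)) {
    sweep <- invitation_cost_sweep(
      scr, uns, costs, utilities, scale_factor = sf,
      invitation_costs = config$scenario$invitation_cost_sweep,
      rate = config$program$discount_rate,
      base_year = config$program$base_year)
  }
  manifest <- list(
    seed = config$seed,
    sub_seeds = c(population = seed_pop, natural_history = seed_nh,
                  screening = seed_scr),
    n_simulated = nrow(pop),
    scale_factor = sf,
    config_hash = .fnv1a(config),
    package_version = as.character(utils::packageVersion("crcscreen"))
  )
  structure(list(cea = cea, bia = bia, sweep = sweep, screened = scr,
                 unscreened = uns, histories = hist, population = pop,
                 manifest = manifest, config = config),
            class = "crc_scenario")
}

#' @export
print.crc_scenario <- function(x, ...) {
  cat("<crc_scenario> seed ", x$manifest$seed, ", ",
      x$manifest$n_simulated, " simulated individuals (x",
      format(x$manifest$scale_factor, digits = 4), ")\n", sep = "")
  print(x$cea)
  print(x$bia)
  invisible(x)
}

#' Export an arm's event log as CSV
#'
#' Writes the canonical event-log table (person, calendar year, age, event
#' type, detail, polypectomy flag) with human-readable labels.
#'
#' @param arm `crc_arm`
#' @param path CSV path
#' @return the labelled table, invisibly
#' @export
write_event_log <- function(arm, path) {
  ev <- data.table::copy(arm$events)
  type_lab <- c("invitation", "fit", "fit_positive", "colonoscopy",
                "complication", "crc_diagnosis")
  purpose_lab <- c("diagnostic", "surveillance", "clinical")
  ev[, "event_type" := type_lab[ev$event]]
  ev[, "detail" := data.table::fcase(
    ev$event == .EV_COLO, purpose_lab[pmax(ev$purpose, 1L)],
    ev$event == .EV_CRC_DX,
    paste0(c("screen", "clinical")[pmax(ev$purpose, 1L)], "_stage_",
           c("I", "II", "III", "IV")[pmax(ev$stage, 1L)]),
    default = "")]
  out <- ev[, c("pid", "year", "age", "event_type", "detail", "polypectomy")]
  data.table::setnames(out, "pid", "person_id")
  data.table::fwrite(out, path)
  invisible(out)
}
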