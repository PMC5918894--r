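# target-anchored standard errors: binomial for prevalence cells, Poisson for
# incidence rates (per 100,000 person-years); degenerate cells get a
# continuity floor so residuals stay finite
.prev_se <- function(p, n) {
  v <- p * (1 - p)
  adj <- v <= 0 & n > 0
  p2 <- (p * n + 0.5) / (n + 1)
  v[adj] <- (p2 * (1 - p2))[adj]
  sqrt(v / pmax(n, 1))
}

.inc_se <- function(rate, py) {
  ev <- pmax(rate * py / 1e5, 0.5)
  sqrt(ev) / pmax(py, 1) * 1e5
}

#' Weighted Pearson deviance between simulated and target tables
#'
#' Sums squared Pearson-type residuals over all target cells: prevalence
#' cells are scaled by a binomial standard error (target proportion, target
#' sample size), incidence cells by a Poisson standard error of the rate.
#' Cells with no observable population (`n_alive == 0` or zero person-years)
#' are skipped. The objective is zero iff every cell matches exactly, and is
#' invariant to row order.
#'
#' @param simulated list of `prevalence`/`incidence` tables from
#'   [summarize_epidemiology()]
#' @param targets calibration target list with the same band structure
#' @param weights list with scalar `prevalence` and `incidence` weights
#' @return non-negative scalar deviance
#' @export
objective_deviance <- function(simulated, targets,
                               weights = list(prevalence = 1,
                                              incidence = 1)) {
  pt <- data.table::as.data.table(targets$prevalence)
  ps <- data.table::as.data.table(simulated$prevalence)
  keyp <- c("sex", "age_lo", "age_hi")
  m <- ps[pt, on = keyp]
  if (anyNA(m$prevalence)) stop("prevalence band structures do not match")
  ok <- m$i.n_alive > 0L
  se <- .prev_se(m$i.prevalence[ok], m$i.n_alive[ok])
  dev_p <- sum(((m$prevalence[ok] - m$i.prevalence[ok]) / se)^2)

  it <- data.table::as.data.table(targets$incidence)
  is <- data.table::as.data.table(simulated$incidence)
  keyi <- c("sex", "age_lo", "age_hi", "location", "stage")
  mi <- is[it, on = keyi]
  if (anyNA(mi$rate_per_100k)) stop("incidence band structures do not match")
  oki <- mi$i.person_years > 0
  sei <- .inc_se(mi$i.rate_per_100k[oki], mi$i.person_years[oki])
  dev_i <- sum(((mi$rate_per_100k[oki] - mi$i.rate_per_100k[oki]) / sei)^2)

  weights$prevalence * dev_p + weights$incidence * dev_i
}

# deterministic simulation-based objective: the same seed is used on every
# call (common random numbers), so the surface seen by the optimizer is a
# fixed function of the parameters
.make_objective <- function(initial_params, free, targets, life_table,
                            n_per_eval, seed, weights, sex, age_bands,
                            trace_env) {
  function(logx) {
    p <- initial_params
    for (i in seq_along(free)) {
      p <- nh_param_set(p, free[i], exp(logx[i]))
    }
    val <- tryCatch({
      cohort <- make_cohort(n_per_eval, life_table,
                            frailty_var = p$frailty_var, seed = seed,
                            sex = sex)
      sim <- summarize_epidemiology(
        run_natural_history(cohort, p, seed = seed + 1L), age_bands)
      objective_deviance(sim, targets, weights)
    }, error = function(e) Inf)
    if (!is.finite(val)) val <- 1e12  # rejected evaluation
    k <- trace_env$k + 1L
    trace_env$k <- k
    trace_env$value[k] <- val
    trace_env$par[[k]] <- exp(logx)
    val
  }
}

#' Fit natural-history parameters to target tables
#'
#' Derivative-free minimisation of [objective_deviance()] over the selected
#' free parameters (on the log scale, keeping them positive). Every
#' objective evaluation simulates a fresh cohort of `n_per_eval` individuals
#' under the candidate parameters with the *same* seed, so the objective is
#' deterministic and a simplex optimizer can act on it. With two or more
#' free parameters, Nelder-Mead with random restarts is used; a single free
#' parameter is minimised by bounded one-dimensional search.
#'
#' @param initial_params starting natural-history parameters
#' @param free character vector of flat parameter names to fit (see
#'   [nh_param_names()]); empty means nothing to fit
#' @param targets calibration targets (filtered internally to `sex` when
#'   given)
#' @param life_table stacked life table
#' @param n_per_eval simulated individuals per objective evaluation
#'   (at least 1000)
#' @param seed integer seed shared by all evaluations
#' @param sex calibrate one sex (`"male"`/`"female"`) or `NULL` for both
#' @param weights objective weights
#' @param control list: `restarts` (default 3), `maxit` (default 200),
#'   `span` (log-scale search half-width, default `log(6)`)
#' @param age_bands age-band table matching the targets
#' @return object of class `crc_calibration`: `params` (full parameter list
#'   with fitted values), `fitted` (named vector), `objective`,
#'   `initial_objective`, `trace` (one row per evaluation), `convergence`,
#'   `n_eval`, `sex`
#' @export
calibrate_parameters <- function(initial_params, free, targets, life_table,
                                 n_per_eval = 20000L, seed = 1L,
                                 sex = NULL, weights = list(prevalence = 1,
                                                            incidence = 1),
                                 control = list(),
                                 age_bands = default_age_bands()) {
  stopifnot(n_per_eval >= 1000L)
  if (!is.null(sex)) {
    targets <- list(
      prevalence = targets$prevalence[targets$prevalence$sex == sex, ],
      incidence = targets$incidence[targets$incidence$sex == sex, ])
  }
  restarts <- control$restarts %||% 3L
  maxit <- control$maxit %||% 200L
  span <- control$span %||% log(6)
  trace_env <- new.env()
  trace_env$k <- 0L; trace_env$value <- numeric(0); trace_env$par <- list()
  obj <- .make_objective(initial_params, free, targets, life_table,
                         n_per_eval, seed, weights, sex, age_bands,
                         trace_env)
  x0 <- log(vapply(free, function(nm) nh_param_get(initial_params, nm), 0))

  if (length(free) == 0L) {
    cohort <- make_cohort(n_per_eval, life_table,
                          frailty_var = initial_params$frailty_var,
                          seed = seed, sex = sex)
    sim <- summarize_epidemiology(
      run_natural_history(cohort, initial_params, seed = seed + 1L),
      age_bands)
    val <- objective_deviance(sim, targets, weights)
    return(structure(list(params = initial_params,
                          fitted = stats::setNames(numeric(0),
                                                   character(0)),
                          objective = val, initial_objective = val,
                          trace = data.table::data.table(eval = 1L,
                                                         value = val),
                          convergence = TRUE, n_eval = 1L, sex = sex),
                     class = "crc_calibration"))
  }

  f0 <- obj(x0)
  best_par <- x0; best_val <- f0; conv <- TRUE
  if (length(free) == 1L) {
    op <- stats::optimize(function(z) obj(z), lower = x0 - span,
                          upper = x0 + span, tol = 1e-3)
    if (op$objective < best_val) {
      best_val <- op$objective; best_par <- op$minimum
    }
  } else {
    set.seed(seed + 7L)
    starts <- c(list(x0), lapply(seq_len(restarts), function(i) {
      x0 + stats::runif(length(x0), -span / 2, span / 2)
    }))
    for (st in starts) {
      op <- stats::optim(st, obj, method = "Nelder-Mead",
                         control = list(maxit = maxit))
      if (op$value < best_val) {
        best_val <- op$value; best_par <- op$par
        conv <- op$convergence == 0L
      }
    }
  }
  fitted <- stats::setNames(exp(best_par), free)
  p <- initial_params
  for (i in seq_along(free)) p <- nh_param_set(p, free[i], fitted[i])
  tr <- data.table::data.table(eval = seq_len(trace_env$k),
                               value = trace_env$value[seq_len(trace_env$k)])
  parmat <- do.call(rbind, trace_env$par)
  colnames(parmat) <- free
  tr <- cbind(tr, data.table::as.data.table(parmat))
  structure(list(params = p, fitted = fitted, objective = best_val,
                 initial_objective = f0, trace = tr,
                 convergence = conv, n_eval = trace_env$k, sex = sex),
            class = "crc_calibration")
}

#' @export
print.crc_calibration <- function(x, ...) {
  cat("<crc_calibration> objective ", format(x$objective, digits = 5),
      " after ", x$n_eval, " evaluations\n", sep = "")
  if (length(x$fitted)) {
    cat("  fitted: ",
        paste(names(x$fitted), signif(x$fitted, 4), sep = " = ",
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Goodness-of-fit report for a parameter set
#'
#' Simulates a fresh cohort (independent seed) under `params` and compares
#' every target cell with the simulation: observed (target) value, simulated
#' value, target-anchored standard error, Pearson residual, and a flag for
#' residuals beyond three standard errors.
#'
#' @param params natural-history parameters to validate
#' @param targets calibration targets
#' @param life_table stacked life table
#' @param n cohort size for the validation run
#' @param seed integer seed (use one not involved in fitting)
#' @param sex restrict to one sex, or `NULL`
#' @param age_bands band table matching the targets
#' @return data.table with one row per target cell: `type`, identifiers,
#'   `target`, `simulated`, `se`, `residual`, `flag`
#' @export
validate_fit <- function(params, targets, life_table, n = 50000L,
                         seed = 99L, sex = NULL,
                         age_bands = default_age_bands()) {
  if (!is.null(sex)) {
    targets <- list(
      prevalence = targets$prevalence[targets$prevalence$sex == sex, ],
      incidence = targets$incidence[targets$incidence$sex == sex, ])
  }
  cohort <- make_cohort(n, life_table, frailty_var = params$frailty_var,
                        seed = seed, sex = sex)
  sim <- summarize_epidemiology(
    run_natural_history(cohort, params, seed = seed + 1L), age_bands)

  pt <- data.table::as.data.table(targets$prevalence)
  m <- data.table::as.data.table(sim$prevalence)[pt,
                                                 on = c("sex", "age_lo",
                                                        "age_hi")]
  prev <- data.table::data.table(
    type = "prevalence", sex = m$sex, age_lo = m$age_lo, age_hi = m$age_hi,
    location = NA_character_, stage = NA_character_,
    target = m$i.prevalence, simulated = m$prevalence,
    se = .prev_se(m$i.prevalence, m$i.n_alive))
  it <- data.table::as.data.table(targets$incidence)
  mi <- data.table::as.data.table(sim$incidence)[it,
                                                 on = c("sex", "age_lo",
                                                        "age_hi", "location",
                                                        "stage")]
  inc <- data.table::data.table(
    type = "incidence", sex = mi$sex, age_lo = mi$age_lo,
    age_hi = mi$age_hi, location = mi$location, stage = mi$stage,
    target = mi$i.rate_per_100k, simulated = mi$rate_per_100k,
    se = .inc_se(mi$i.rate_per_100k, mi$i.person_years))
  rep <- data.table::rbindlist(list(prev, inc), use.names = TRUE)
  rep[, "residual" := (rep$simulated - rep$target) / rep$se]
  rep[, "flag" := abs(rep$residual) > 3]
  rep[]
}
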