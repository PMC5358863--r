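# Synthetic calibration: national-scale daily donation and demand streams
# by ABO/Rh phenotype, standing in for proprietary donation/claims series.

#' Baseline US phenotype prevalence
#'
#' Standard US population ABO/Rh frequencies, in canonical phenotype order,
#' summing to 1. Shipped as an editable CSV (`extdata/us_prevalence.csv`);
#' this accessor reads it.
#'
#' @param path Optional path to an alternative prevalence CSV with columns
#'   `phenotype`, `probability`.
#' @return Named numeric vector of 8 probabilities.
#' @export
us_phenotype_prevalence <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "us_prevalence.csv", package = "rbcflow",
                        mustWork = TRUE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  p <- stats::setNames(df$probability, df$phenotype)[rbc_phenotypes()]
  validate_prevalence(p)
  p
}

validate_prevalence <- function(p) {
  if (length(p) != 8L || anyNA(p) || any(p < 0)) {
    stop("prevalence must be 8 non-negative probabilities in canonical order")
  }
  if (abs(sum(p) - 1) > 1e-9) stop("prevalence must sum to 1")
  invisible(p)
}

#' Dirichlet model of phenotype-prevalence uncertainty
#'
#' Prevalence is not known exactly; between-run variability is modelled by a
#' Dirichlet distribution centred on a baseline vector, with shape
#' parameters `baseline * concentration`. Larger concentrations give draws
#' closer to the baseline (component variance
#' `p_i (1 - p_i) / (concentration + 1)`); concentrations of 1,000 and
#' 10,000 bracket plausible levels of uncertainty.
#'
#' @param baseline Named prevalence vector (default
#'   [us_phenotype_prevalence()]).
#' @param concentration Positive scalar.
#' @return An object of class `rbc_prevalence_model`.
#' @export
prevalence_model <- function(baseline = us_phenotype_prevalence(),
                             concentration = 1000) {
  validate_prevalence(baseline)
  if (concentration <= 0) stop("concentration must be positive")
  if (any(baseline * concentration <= 0)) {
    stop("all Dirichlet shape parameters must be positive")
  }
  structure(list(baseline = baseline, concentration = concentration),
            class = "rbc_prevalence_model")
}

#' Draw a phenotype prevalence vector
#'
#' One draw from the Dirichlet distribution of a [prevalence_model()],
#' via normalized independent gamma variates.
#'
#' @param model An `rbc_prevalence_model`.
#' @return Named numeric vector on the 8-simplex.
#' @export
sample_prevalence <- function(model) {
  stopifnot(inherits(model, "rbc_prevalence_model"))
  g <- stats::rgamma(8L, shape = model$baseline * model$concentration, rate = 1)
  stats::setNames(g / sum(g), rbc_phenotypes())
}

#' Daily donation/demand flow model
#'
#' Day totals for donations and demand are negative binomial with the given
#' means (times an optional day-of-week multiplier) and dispersion `size`
#' parameter; each total is then thinned to phenotypes by a multinomial draw
#' with the current prevalence. Dispersion is the negative binomial `size`:
#' the coefficient of variation of a day total is roughly
#' `sqrt(1/mean + 1/dispersion)`, so the default (400) gives about 5% CV at
#' national scale; `dispersion = Inf` is the Poisson limit.
#'
#' @param mean_daily_donations,mean_daily_demand Positive mean day totals
#'   (units/day). Defaults: demand 40,000, the order of magnitude of the
#'   ~14 million RBC units transfused annually in the US, and donations 8%
#'   higher (43,200). National collections exceed transfusions; the surplus
#'   is what ages in storage and eventually outdates, and without it a
#'   lost-sales inventory system cannot maintain standing stock at all —
#'   every unit would be transfused young and nothing would ever expire.
#' @param dispersion Positive negative-binomial size parameter
#'   (`Inf` = Poisson).
#' @param weekday_multipliers 7 positive scalars averaging 1 (Mon..Sun),
#'   default flat.
#' @return An object of class `rbc_flow_model`.
#' @export
flow_model <- function(mean_daily_donations = 43200,
                       mean_daily_demand = 40000,
                       dispersion = 400,
                       weekday_multipliers = rep(1, 7)) {
  if (mean_daily_donations <= 0 || mean_daily_demand <= 0) {
    stop("mean daily flows must be positive")
  }
  if (dispersion <= 0) stop("dispersion must be positive")
  if (length(weekday_multipliers) != 7L || any(weekday_multipliers <= 0)) {
    stop("weekday_multipliers must be 7 positive values")
  }
  if (abs(mean(weekday_multipliers) - 1) > 1e-6) {
    stop("weekday_multipliers must average to 1")
  }
  structure(list(mean_daily_donations = mean_daily_donations,
                 mean_daily_demand = mean_daily_demand,
                 dispersion = dispersion,
                 weekday_multipliers = weekday_multipliers),
            class = "rbc_flow_model")
}

rnbinom_mu <- function(n, mu, size) {
  if (is.infinite(size)) stats::rpois(n, mu) else
    stats::rnbinom(n, size = size, mu = mu)
}

thin_to_phenotypes <- function(total, prevalence) {
  stats::setNames(as.integer(stats::rmultinom(1L, total, prevalence)),
                  rbc_phenotypes())
}

#' Draw one day's donations and demand by phenotype
#'
#' @param model An [flow_model()].
#' @param prevalence Prevalence vector (e.g. from [sample_prevalence()]).
#' @param day_of_week Integer 0..6 selecting the weekday multiplier.
#' @return List with named integer vectors `donations` and `demand`; each
#'   vector sums to its drawn day total.
#' @export
sample_daily_flows <- function(model, prevalence = us_phenotype_prevalence(),
                               day_of_week = 0L) {
  stopifnot(inherits(model, "rbc_flow_model"))
  validate_prevalence(prevalence)
  m <- model$weekday_multipliers[(as.integer(day_of_week) %% 7L) + 1L]
  don <- rnbinom_mu(1L, model$mean_daily_donations * m, model$dispersion)
  dem <- rnbinom_mu(1L, model$mean_daily_demand * m, model$dispersion)
  list(donations = thin_to_phenotypes(don, prevalence),
       demand = thin_to_phenotypes(dem, prevalence))
}

#' Draw a replicate's full flow series
#'
#' Samples the replicate's prevalence once from the Dirichlet model (the
#' Dirichlet captures between-run prevalence uncertainty; set
#' `redraw_daily = TRUE` to redraw each day instead), then the daily
#' donation and demand streams over the horizon. Used to share identical
#' draws across scenarios (common random numbers).
#'
#' @param flow An [flow_model()].
#' @param prev_model A [prevalence_model()].
#' @param horizon Number of days.
#' @param redraw_daily Redraw prevalence each day (default FALSE).
#' @return List with `prevalence` (the replicate draw) and integer matrices
#'   `donations`, `demand` of dimension horizon x 8.
#' @export
sample_replicate_flows <- function(flow, prev_model, horizon,
                                   redraw_daily = FALSE) {
  prev <- sample_prevalence(prev_model)
  don <- matrix(0L, horizon, 8L, dimnames = list(NULL, rbc_phenotypes()))
  dem <- don
  p <- prev
  for (d in seq_len(horizon)) {
    if (redraw_daily) p <- sample_prevalence(prev_model)
    f <- sample_daily_flows(flow, p, day_of_week = (d - 1L) %% 7L)
    don[d, ] <- f$donations
    dem[d, ] <- f$demand
  }
  list(prevalence = prev, donations = don, demand = dem)
}

#' Read a flow model from a calibration CSV
#'
#' Two-column `key,value` CSV with keys `mean_daily_donations`,
#' `mean_daily_demand`, `dispersion` and optionally `weekday_1` ...
#' `weekday_7`.
#'
#' @param path CSV file.
#' @return An [flow_model()].
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  kv <- stats::setNames(as.numeric(df$value), df$key)
  wd <- kv[sprintf("weekday_%d", 1:7)]
  flow_model(
    mean_daily_donations = kv[["mean_daily_donations"]],
    mean_daily_demand = kv[["mean_daily_demand"]],
    dispersion = if ("dispersion" %in% names(kv)) kv[["dispersion"]] else 400,
    weekday_multipliers = if (anyNA(wd)) rep(1, 7) else unname(wd)
  )
}
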