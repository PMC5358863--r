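# Daily simulation loop over the Collector and Hospital banks.
#
# Within-day event order (the single point of truth for the model):
#   (a) donations enter the Collector at age 1 (same-day availability by
#       default; a config switch delays them to the next day);
#   (b) the Hospital fills each high-risk class's demand with the
#       Threshold Method under the practical compatibility rules;
#   (c) the Hospital fills baseline (BBR) demand, oldest-first by default;
#   (d) the Collector ships to the Hospital: first young units (age at most
#       the youngest scenario threshold) to cover the next day's expected
#       high-risk demand, then units of any age, oldest first, to restore
#       the Hospital to `hospital_inventory_days` times the expected total
#       daily demand (standard compatibility rules);
#   (e) both banks age one day; units past shelf life expire.

#' Simulation configuration
#'
#' @param horizon Days per replicate (default 365, one year).
#' @param n_replicates Independent replicate simulations (default 500).
#' @param n_steady_state_runs Burn-in simulations averaged into the initial
#'   banks (default 100).
#' @param burn_in_days Length of each burn-in run (default 200 days; long
#'   enough for the two-bank system to forget an empty start under the
#'   default calibration).
#' @param hospital_inventory_days Hospital stock target in days of expected
#'   demand (default 6).
#' @param shelf_life Default shelf life in days for scenarios that do not
#'   override it (default 42).
#' @param seed Master seed; every random stream of an experiment is derived
#'   from it.
#' @param partition_mode How daily demand is split across recipient classes
#'   (see [partition_daily_demand()]).
#' @param collections_available_same_day If `TRUE` (default) a unit
#'   collected on day d is in the Collector at age 1 and can ship the same
#'   day; if `FALSE` it enters after end-of-day aging and is first usable
#'   the next day.
#' @return An object of class `rbc_sim_config`.
#' @export
simulation_config <- function(horizon = 365L, n_replicates = 500L,
                              n_steady_state_runs = 100L,
                              burn_in_days = 200L,
                              hospital_inventory_days = 6,
                              shelf_life = 42L, seed = 1L,
                              partition_mode = c("multinomial", "proportional"),
                              collections_available_same_day = TRUE) {
  partition_mode <- match.arg(partition_mode)
  stopifnot(horizon >= 1, n_replicates >= 1, n_steady_state_runs >= 1,
            burn_in_days >= 1, hospital_inventory_days > 0, shelf_life >= 1)
  structure(list(horizon = as.integer(horizon),
                 n_replicates = as.integer(n_replicates),
                 n_steady_state_runs = as.integer(n_steady_state_runs),
                 burn_in_days = as.integer(burn_in_days),
                 hospital_inventory_days = hospital_inventory_days,
                 shelf_life = as.integer(shelf_life),
                 seed = as.integer(seed),
                 partition_mode = partition_mode,
                 collections_available_same_day = collections_available_same_day),
            class = "rbc_sim_config")
}

# fast allocation path used inside the daily loop; donors are precomputed
# integer row indices in preference order
alloc_fast <- function(counts, donors, quantity, method, threshold, sl) {
  units <- 0L; agesum <- 0; stage3 <- 0L
  remaining <- quantity
  if (method == "TM") {
    g <- greedy_take(counts, cell_order(donors[1L], threshold:1), remaining)
    counts <- g$counts
    units <- units + g$n; remaining <- remaining - g$n
    agesum <- agesum + sum(g$take * ((g$idx - 1L) %/% 8L + 1L))
    if (remaining > 0L && length(donors) > 1L) {
      g <- greedy_take(counts, cell_order(donors[-1L], threshold:1), remaining)
      counts <- g$counts
      units <- units + g$n; remaining <- remaining - g$n
      agesum <- agesum + sum(g$take * ((g$idx - 1L) %/% 8L + 1L))
    }
    if (remaining > 0L) {
      g <- greedy_take(counts, cell_order(donors, 1:sl), remaining)
      counts <- g$counts
      units <- units + g$n; remaining <- remaining - g$n
      stage3 <- g$n
      agesum <- agesum + sum(g$take * ((g$idx - 1L) %/% 8L + 1L))
    }
    uba <- stage3 + remaining
  } else {
    ages <- if (method %in% c("LO", "FIFO")) sl:1 else 1:sl
    g <- greedy_take(counts, cell_order(donors, ages), remaining)
    counts <- g$counts
    units <- g$n; remaining <- remaining - g$n
    agesum <- sum(g$take * ((g$idx - 1L) %/% 8L + 1L))
    uba <- 0L
  }
  list(counts = counts, units = units, agesum = agesum,
       unmet = remaining, unmet_by_age = uba)
}

# move units from collector to hospital along an ordered cell scan
ship_cells <- function(collector, hospital, idx, quantity) {
  g <- greedy_take(collector, idx, quantity)
  hospital[g$idx] <- hospital[g$idx] + g$take
  list(collector = g$counts, hospital = hospital, n = g$n)
}

# age a counts matrix one day; returns shifted matrix and expired-by-phenotype
age_counts <- function(counts) {
  sl <- ncol(counts)
  expired <- counts[, sl]
  if (sl > 1L) counts[, 2:sl] <- counts[, 1:(sl - 1L)]
  counts[, 1L] <- 0L
  list(counts = counts, expired = expired)
}

#' Build a simulation state
#'
#' Assembles the mutable state driven by [run_day()]: the two banks (empty
#' unless initial counts are given, truncated or zero-padded to the
#' scenario's shelf life), precomputed donor preference orders under both
#' rule sets, the per-phenotype expected daily demand used for shipment
#' targets, and the scenario's youngest threshold age.
#'
#' @param scenario An `rbc_scenario`.
#' @param config An [simulation_config()].
#' @param expected_demand Named numeric vector: expected daily demand by
#'   phenotype (mean daily demand times prevalence).
#' @param initial_collector,initial_hospital Optional initial counts
#'   matrices.
#' @param practical,standard Compatibility matrices for transfusion and
#'   inter-bank transfer respectively.
#' @return A list consumed by [run_day()].
#' @export
new_sim_state <- function(scenario, config, expected_demand,
                          initial_collector = NULL, initial_hospital = NULL,
                          practical = compatibility_matrix("practical"),
                          standard = compatibility_matrix("standard")) {
  sl <- scenario$shelf_life
  blank <- matrix(0L, 8L, sl, dimnames = list(rbc_phenotypes(), seq_len(sl)))
  fit <- function(m) {
    if (is.null(m)) return(blank)
    out <- blank
    k <- min(ncol(m), sl)
    out[, 1:k] <- m[, 1:k]
    out
  }
  cls <- scenario$classes
  hrg <- !is.na(cls$threshold_age) & cls$name != "BBR"
  tau <- if (any(hrg)) min(cls$threshold_age[hrg]) else NA_integer_
  hrg_share <- sum(cls$share[hrg]) / 100
  donors_p <- lapply(rbc_phenotypes(),
                     function(p) phenotype_index(ordered_donors(p, practical)))
  donors_s <- lapply(rbc_phenotypes(),
                     function(p) phenotype_index(ordered_donors(p, standard)))
  list(collector = fit(initial_collector), hospital = fit(initial_hospital),
       scenario = scenario, sl = sl, tau = tau,
       expected_demand = expected_demand,
       expected_hrg_demand = expected_demand * hrg_share,
       hospital_target = config$hospital_inventory_days * expected_demand,
       donors_practical = donors_p, donors_standard = donors_s,
       methods = vapply(seq_len(nrow(cls)),
                        function(i) parse_policy(cls$method[i])$method, ""),
       thresholds = cls$threshold_age,
       config = config)
}

#' Simulate one day
#'
#' Executes the within-day event order (donations, high-risk transfusion,
#' baseline transfusion, collector-to-hospital shipments, aging/expiry) on a
#' simulation state and returns the state plus one ledger row. Shortfalls
#' are ledger data, never errors. Mainly useful for inspecting the
#' mechanics; [run_replicate()] drives it over a horizon.
#'
#' @param state Internal state from `new_sim_state()` (see
#'   [run_replicate()]).
#' @param donations,demand Named integer vectors of the day's flows by
#'   phenotype.
#' @return List with `state` and `row`, a named numeric vector holding the
#'   day's donations, shipments, per-class demand/transfused/age-unit-sum/
#'   unmet/unmet-by-age, expiries per bank, and end-of-day bank totals.
#' @export
run_day <- function(state, donations, demand) {
  sc <- state$scenario
  cls <- sc$classes
  k <- nrow(cls)
  same_day <- state$config$collections_available_same_day
  if (same_day) {
    state$collector[, 1L] <- state$collector[, 1L] + as.integer(donations)
  }

  part <- partition_daily_demand(demand, sc, state$config$partition_mode)

  units <- agesum <- unmet <- uba <- numeric(k)
  H <- state$hospital
  for (i in seq_len(k)) {
    for (p in which(part[i, ] > 0L)) {
      a <- alloc_fast(H, state$donors_practical[[p]], part[i, p],
                      state$methods[i], state$thresholds[i], state$sl)
      H <- a$counts
      units[i] <- units[i] + a$units
      agesum[i] <- agesum[i] + a$agesum
      unmet[i] <- unmet[i] + a$unmet
      uba[i] <- uba[i] + a$unmet_by_age
    }
  }

  # shipments: young units for tomorrow's expected high-risk demand, then
  # restock to the hospital inventory target, oldest first
  C <- state$collector
  shipped_young <- 0L; shipped_restock <- 0L
  if (!is.na(state$tau) && state$tau > 1L) {
    # units shipped today serve tomorrow's demand, after end-of-day aging:
    # only ages <= tau - 1 today still satisfy the threshold tomorrow
    tau1 <- min(state$tau - 1L, state$sl)
    for (p in 1:8) {
      have <- sum(H[p, seq_len(tau1)])
      need <- ceiling(state$expected_hrg_demand[p]) - have
      if (need > 0) {
        s <- ship_cells(C, H, cell_order(state$donors_standard[[p]], tau1:1),
                        as.integer(need))
        C <- s$collector; H <- s$hospital
        shipped_young <- shipped_young + s$n
      }
    }
  }
  for (p in 1:8) {
    need <- round(state$hospital_target[p]) - sum(H[p, ])
    if (need > 0) {
      s <- ship_cells(C, H, cell_order(state$donors_standard[[p]], state$sl:1),
                      as.integer(need))
      C <- s$collector; H <- s$hospital
      shipped_restock <- shipped_restock + s$n
    }
  }

  ac <- age_counts(C)
  ah <- age_counts(H)
  state$collector <- ac$counts
  state$hospital <- ah$counts
  if (!same_day) {
    state$collector[, 1L] <- state$collector[, 1L] + as.integer(donations)
  }

  row <- c(donations = sum(donations), demand = sum(demand),
           shipped_young = shipped_young, shipped_restock = shipped_restock,
           expired_collector = sum(ac$expired),
           expired_hospital = sum(ah$expired),
           collector_end = sum(state$collector),
           hospital_end = sum(state$hospital))
  per_class <- rbind(demand = rowSums(part), transfused = units,
                     agesum = agesum, unmet = unmet, unmet_by_age = uba)
  row <- c(row, stats::setNames(as.numeric(per_class),
                                paste(rownames(per_class),
                                      rep(cls$name, each = 5L), sep = ".")))
  list(state = state, row = row)
}

#' Run one replicate simulation
#'
#' Simulates a scenario for `horizon` days from given initial banks against
#' a pre-drawn flow series (so the same draws can be replayed under several
#' scenarios — common random numbers). Initial banks with a different shelf
#' life are truncated to the scenario's: units older than the scenario's
#' shelf life are discarded at initialization.
#'
#' @param scenario An `rbc_scenario`.
#' @param config An [simulation_config()].
#' @param flows A flow series from [sample_replicate_flows()] with at least
#'   `config$horizon` days.
#' @param flow Flow model (supplies the expected daily demand used for
#'   shipment targets).
#' @param initial_collector,initial_hospital Initial counts matrices
#'   (default empty banks).
#' @return A `data.frame` ledger, one row per day, with the columns of
#'   [run_day()] plus `day`. Attribute `initial_total` records the starting
#'   stock after any shelf-life truncation.
#' @export
run_replicate <- function(scenario, config, flows, flow,
                          initial_collector = NULL, initial_hospital = NULL) {
  expected <- flow$mean_daily_demand * flows$prevalence
  state <- new_sim_state(scenario, config, expected,
                         initial_collector, initial_hospital)
  initial_total <- sum(state$collector) + sum(state$hospital)
  horizon <- config$horizon
  stopifnot(nrow(flows$demand) >= horizon)
  rows <- NULL
  for (d in seq_len(horizon)) {
    r <- run_day(state, flows$donations[d, ], flows$demand[d, ])
    state <- r$state
    if (is.null(rows)) {
      rows <- matrix(0, horizon, length(r$row),
                     dimnames = list(NULL, names(r$row)))
    }
    rows[d, ] <- r$row
  }
  ledger <- data.frame(day = seq_len(horizon), rows, check.names = FALSE)
  attr(ledger, "initial_total") <- initial_total
  attr(ledger, "final_collector") <- state$collector
  attr(ledger, "final_hospital") <- state$hospital
  attr(ledger, "scenario") <- scenario$name
  ledger
}

#' Grand conservation check
#'
#' Verifies the accounting identity of a replicate ledger: initial stock +
#' total donations = total transfused + total expired + final stock.
#'
#' @param ledger A ledger from [run_replicate()].
#' @return `TRUE` invisibly, or an error describing the imbalance.
#' @export
check_conservation <- function(ledger) {
  transfused <- sum(ledger[, grep("^transfused\\.", names(ledger)), drop = FALSE])
  lhs <- attr(ledger, "initial_total") + sum(ledger$donations)
  rhs <- transfused + sum(ledger$expired_collector) +
    sum(ledger$expired_hospital) +
    utils::tail(ledger$collector_end, 1L) + utils::tail(ledger$hospital_end, 1L)
  if (lhs != rhs) {
    stop(sprintf("conservation violated: in %s vs out %s", lhs, rhs))
  }
  invisible(TRUE)
}

#' Steady-state initial banks
#'
#' Runs independent burn-in simulations of a scenario from empty banks and
#' returns the cell-wise average of the final Collector and Hospital
#' inventories, rounded to integers — the shared starting point for
#' scenario experiments.
#'
#' @param config An [simulation_config()] (`n_steady_state_runs` and
#'   `burn_in_days` control the burn-in).
#' @param scenario Scenario used during burn-in (normally the baseline).
#' @param flow,prev_model Calibration models.
#' @param seed Seed for the burn-in random streams.
#' @return List with integer matrices `collector` and `hospital`.
#' @export
initialize_steady_state <- function(config, scenario, flow, prev_model,
                                    seed = config$seed) {
  n <- config$n_steady_state_runs
  burn_cfg <- config
  burn_cfg$horizon <- config$burn_in_days
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n)
  acc_c <- acc_h <- 0
  for (r in seq_len(n)) {
    set.seed(run_seeds[r])
    flows <- sample_replicate_flows(flow, prev_model, burn_cfg$horizon)
    ledger <- run_replicate(scenario, burn_cfg, flows, flow)
    acc_c <- acc_c + attr(ledger, "final_collector")
    acc_h <- acc_h + attr(ledger, "final_hospital")
  }
  list(collector = round(acc_c / n), hospital = round(acc_h / n))
}

#' Run a multi-scenario replicate experiment
#'
#' Runs every scenario over the same replicate set with common random
#' numbers: all scenarios share the same initial banks (steady state under
#' `init_scenario`, unless `initial_banks` is supplied) and, within each
#' replicate, the same prevalence draw and daily donation/demand series;
#' the demand-partition stream is also re-seeded identically per replicate,
#' so scenarios with the same class structure see identical partitions.
#' Cross-scenario differences are therefore paired, not sampling noise.
#'
#' @param scenarios A list of `rbc_scenario` objects (named, or names are
#'   taken from the scenarios).
#' @param config An [simulation_config()]; `config$seed` drives every
#'   stream.
#' @param flow,prev_model Calibration models (defaults: [flow_model()],
#'   [prevalence_model()]).
#' @param initial_banks Optional list with `collector`/`hospital` matrices;
#'   default computed by [initialize_steady_state()].
#' @param init_scenario Scenario for steady-state initialization (default
#'   the baseline).
#' @return An object of class `rbc_experiment`: list with `ledgers` (named
#'   list: scenario -> list of replicate ledgers), `initial_banks`,
#'   `config`.
#' @export
run_experiment <- function(scenarios, config,
                           flow = flow_model(),
                           prev_model = prevalence_model(),
                           initial_banks = NULL,
                           init_scenario = builtin_scenario("baseline")) {
  if (is.null(names(scenarios)) || any(!nzchar(names(scenarios)))) {
    names(scenarios) <- vapply(scenarios, function(s) s$name, "")
  }
  set.seed(config$seed)
  init_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  flow_seeds <- sample.int(.Machine$integer.max - 1L, config$n_replicates)
  part_seeds <- sample.int(.Machine$integer.max - 1L, config$n_replicates)
  if (is.null(initial_banks)) {
    initial_banks <- initialize_steady_state(config, init_scenario, flow,
                                             prev_model, seed = init_seed)
  }
  ledgers <- lapply(scenarios, function(s) vector("list", config$n_replicates))
  for (r in seq_len(config$n_replicates)) {
    set.seed(flow_seeds[r])
    flows <- sample_replicate_flows(flow, prev_model, config$horizon)
    for (s in names(ledgers)) {
      set.seed(part_seeds[r])
      ledgers[[s]][[r]] <- run_replicate(scenarios[[s]], config, flows, flow,
                                         initial_banks$collector,
                                         initial_banks$hospital)
    }
  }
  structure(list(ledgers = ledgers, initial_banks = initial_banks,
                 config = config),
            class = "rbc_experiment")
}

#' @export
print.rbc_experiment <- function(x, ...) {
  cat(sprintf("<rbc_experiment: %d scenario(s) x %d replicate(s), %d days>\n",
              length(x$ledgers), x$config$n_replicates, x$config$horizon))
  invisible(x)
}
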