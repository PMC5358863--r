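# Performance measures: annual-average-daily (AAD) statistics, weighted age
# of transfused units, percent unmet-by-age, efficiency, and cross-scenario
# comparisons with 95% confidence intervals across replicates.

#' Annual average daily value
#'
#' The arithmetic mean of a daily series over the horizon.
#'
#' @param series Numeric vector of daily values.
#' @return Scalar mean.
#' @export
aad <- function(series) {
  if (length(series) < 1L) stop("series must have at least one day")
  mean(series)
}

ledger_class_names <- function(ledger) {
  sub("^demand\\.", "", grep("^demand\\.", names(ledger), value = TRUE))
}

#' Weighted age of transfused units
#'
#' Unit-weighted mean storage age of the units transfused to a class (or to
#' everyone), pooled over the whole horizon:
#' `sum(age * units at that age) / sum(units)`.
#'
#' @param ledger A ledger from [run_replicate()].
#' @param class Class name (e.g. `"BBR"`, `"HRG-TM7"`) or `NULL` for all
#'   recipients.
#' @return Mean age in days; `NA` if no units were transfused.
#' @export
weighted_age_of_transfused <- function(ledger, class = NULL) {
  cls <- if (is.null(class)) ledger_class_names(ledger) else class
  units <- sum(ledger[, paste0("transfused.", cls), drop = FALSE])
  ages <- sum(ledger[, paste0("agesum.", cls), drop = FALSE])
  if (units == 0) return(NA_real_)
  ages / units
}

#' Percent of demanded units unmet by age
#'
#' 100 x (units that failed the age requirement) / (units demanded), pooled
#' over the horizon for one class. Units count as unmet-by-age when they
#' were issued above the class's threshold age (freshest-available
#' fallback) or not issued at all.
#'
#' @inheritParams weighted_age_of_transfused
#' @return Percent in `[0, 100]`; `NA` if the class had no demand.
#' @export
pct_unmet_by_age <- function(ledger, class = NULL) {
  cls <- if (is.null(class)) ledger_class_names(ledger) else class
  demanded <- sum(ledger[, paste0("demand.", cls), drop = FALSE])
  if (demanded == 0) return(NA_real_)
  100 * sum(ledger[, paste0("unmet_by_age.", cls), drop = FALSE]) / demanded
}

#' Normal-approximation 95% confidence interval
#'
#' Mean plus/minus 1.96 standard errors across replicate values.
#'
#' @param x Numeric vector of per-replicate values.
#' @return Named vector `(low, point, high)`; interval is `NA` with fewer
#'   than 2 replicates.
#' @export
ci95 <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  if (length(x) < 2L) {
    return(c(low = NA_real_, point = m, high = NA_real_))
  }
  se <- stats::sd(x) / sqrt(length(x))
  c(low = m - 1.96 * se, point = m, high = m + 1.96 * se)
}

#' Per-replicate performance measures
#'
#' Reduces one replicate ledger to the study's measures: AAD total supply
#' (collector + hospital), AAD expired units (total and collector-only),
#' AAD unmet-by-age, percent unmet-by-age and efficiency
#' (100 - percent unmet) per class and overall, and the weighted age of
#' transfused units per class and overall.
#'
#' @param ledger A ledger from [run_replicate()].
#' @return A one-row data frame.
#' @export
replicate_metrics <- function(ledger) {
  cls <- ledger_class_names(ledger)
  out <- data.frame(
    aad_total_supply = aad(ledger$collector_end + ledger$hospital_end),
    aad_expired = aad(ledger$expired_collector + ledger$expired_hospital),
    aad_expired_collector = aad(ledger$expired_collector),
    aad_unmet_by_age = sum(ledger[, paste0("unmet_by_age.", cls)]) /
      nrow(ledger),
    pct_unmet_by_age = pct_unmet_by_age(ledger),
    age_transfused = weighted_age_of_transfused(ledger)
  )
  for (cl in cls) {
    out[[paste0("pct_unmet_by_age.", cl)]] <- pct_unmet_by_age(ledger, cl)
    out[[paste0("efficiency.", cl)]] <- 100 - pct_unmet_by_age(ledger, cl)
    out[[paste0("age_transfused.", cl)]] <- weighted_age_of_transfused(ledger, cl)
    out[[paste0("aad_unmet_by_age.", cl)]] <-
      sum(ledger[[paste0("unmet_by_age.", cl)]]) / nrow(ledger)
  }
  out$efficiency <- 100 - out$pct_unmet_by_age
  out
}

#' Summarize a scenario across replicates
#'
#' @param ledgers List of replicate ledgers for one scenario.
#' @return List with `replicates` (data frame of [replicate_metrics()] rows)
#'   and `summary` (data frame with columns `metric`, `low`, `point`,
#'   `high`, the 95% CI across replicates for every metric).
#' @export
summarize_scenario <- function(ledgers) {
  reps <- do.call(rbind, lapply(ledgers, replicate_metrics))
  cis <- t(vapply(reps, ci95, numeric(3)))
  summary <- data.frame(metric = rownames(cis), cis, row.names = NULL,
                        stringsAsFactors = FALSE)
  list(replicates = reps, summary = summary)
}

#' Summarize an experiment
#'
#' @param experiment An `rbc_experiment` from [run_experiment()].
#' @return Named list of [summarize_scenario()] results, one per scenario.
#' @export
summarize_experiment <- function(experiment) {
  stopifnot(inherits(experiment, "rbc_experiment"))
  lapply(experiment$ledgers, summarize_scenario)
}

summary_point <- function(s, metric) {
  s$summary$point[match(metric, s$summary$metric)]
}

#' Compare scenarios to a baseline
#'
#' Tabulates, per scenario, the AAD total supply and its percent reduction
#' relative to the baseline scenario, the AAD expired units, and the
#' overall percent unmet-by-age, sorted in descending total-supply order.
#'
#' @param summaries Named list of [summarize_scenario()] results (as from
#'   [summarize_experiment()]).
#' @param baseline Name of the baseline scenario in `summaries`.
#' @return A data frame sorted by descending `aad_total_supply`.
#' @export
compare_to_baseline <- function(summaries, baseline = "baseline") {
  if (!baseline %in% names(summaries)) {
    stop("baseline scenario '", baseline, "' not found")
  }
  base_supply <- summary_point(summaries[[baseline]], "aad_total_supply")
  rows <- lapply(names(summaries), function(nm) {
    s <- summaries[[nm]]
    supply <- summary_point(s, "aad_total_supply")
    data.frame(
      scenario = nm,
      aad_total_supply = supply,
      pct_reduction_supply = 100 * (base_supply - supply) / base_supply,
      aad_expired = summary_point(s, "aad_expired"),
      aad_unmet_by_age = summary_point(s, "aad_unmet_by_age"),
      pct_unmet_by_age = summary_point(s, "pct_unmet_by_age"),
      age_transfused = summary_point(s, "age_transfused"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out[order(-out$aad_total_supply), , drop = FALSE]
}

#' Write scenario metrics to CSV
#'
#' @param summaries As for [compare_to_baseline()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(summaries, path) {
  rows <- lapply(names(summaries), function(nm) {
    cbind(scenario = nm, summaries[[nm]]$summary)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Bar chart of a metric across scenarios
#'
#' A small convenience plot (requires ggplot2): scenario bars with 95% CI
#' error bars, descending-supply order.
#'
#' @param summaries As for [compare_to_baseline()].
#' @param metric Metric name from the summary tables.
#' @return A ggplot object.
#' @export
plot_scenario_metric <- function(summaries, metric = "aad_total_supply") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_scenario_metric requires ggplot2")
  }
  df <- do.call(rbind, lapply(names(summaries), function(nm) {
    s <- summaries[[nm]]$summary
    cbind(scenario = nm, s[s$metric == metric, , drop = FALSE])
  }))
  df$scenario <- stats::reorder(df$scenario, -df$point)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scenario, y = .data$point)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$low, ymax = .data$high),
                           width = 0.25) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}
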