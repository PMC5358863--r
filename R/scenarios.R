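# Share algebra over mutually exclusive high-risk groups and scenario
# construction, including the youngest-threshold rule for overlapping groups.

HRG_LABELS <- c("ICU", "CS", "CCU", "TR")

#' Mutually exclusive high-risk-group transfusion shares
#'
#' The packaged table of average percentages of total RBC units transfused
#' to each mutually exclusive combination of the four high-risk groups
#' (ICU, CS, CCU, TR) among US elderly inpatients, 2007-2012, with 95%
#' confidence intervals. Each row is one mutually exclusive patient set
#' (`labels`, semicolon-joined group names); shares across rows do not
#' overlap, so unions of groups are obtained by adding rows
#' ([union_share()]).
#'
#' @param path Optional path to an alternative CSV with columns `labels`,
#'   `share`, `ci_low`, `ci_high`; default reads the packaged table.
#' @return A data frame with columns `labels` (list of character vectors),
#'   `share`, `ci_low`, `ci_high` (percent).
#' @export
#' @examples
#' tab <- hrg_share_table()
#' union_share(tab, "ICU")
hrg_share_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hrg_shares.csv", package = "rbcflow",
                        mustWork = TRUE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("labels", "share") %in% names(df))) {
    stop("share table must have columns labels, share")
  }
  df$labels <- lapply(strsplit(df$labels, ";", fixed = TRUE), trimws)
  bad <- !vapply(df$labels, function(l) length(l) > 0 && all(l %in% HRG_LABELS),
                 logical(1))
  if (any(bad)) stop("unknown group label(s) in share table")
  keys <- vapply(df$labels, function(l) paste(sort(l), collapse = ";"), "")
  if (anyDuplicated(keys)) stop("share table rows must be pairwise distinct")
  if (any(df$share < 0) || sum(df$share) > 100) {
    stop("shares must be non-negative and sum to at most 100")
  }
  df
}

check_group <- function(group) {
  if (!group %in% HRG_LABELS) {
    stop("unknown high-risk group: ", group,
         " (expected one of ", paste(HRG_LABELS, collapse = ", "), ")")
  }
  group
}

#' Share of all patients in a high-risk group
#'
#' Sums the mutually exclusive rows whose label set contains `group`,
#' giving the share of "any `group` patients" (e.g. any ICU patient,
#' whether or not also CS/CCU/TR).
#'
#' @param table A table from [hrg_share_table()].
#' @param group One of `"ICU"`, `"CS"`, `"CCU"`, `"TR"`.
#' @return Percent of total RBC units transfused (unrounded sum).
#' @export
union_share <- function(table, group) {
  check_group(group)
  has <- vapply(table$labels, function(l) group %in% l, logical(1))
  sum(table$share[has])
}

#' Share in one group but not another
#'
#' Sums rows whose label set contains `include` but not `exclude` (e.g. the
#' cardiac-surgery patients who are never in the ICU). With `exclude`
#' absent this reduces to [union_share()].
#'
#' @inheritParams union_share
#' @param include,exclude Group labels.
#' @return Percent of total RBC units transfused.
#' @export
difference_share <- function(table, include, exclude = NULL) {
  check_group(include)
  if (is.null(exclude)) return(union_share(table, include))
  check_group(exclude)
  keep <- vapply(table$labels,
                 function(l) include %in% l && !(exclude %in% l), logical(1))
  sum(table$share[keep])
}

#' Build a scenario from high-risk groups and age thresholds
#'
#' Constructs the ordered recipient classes of a simulation scenario from a
#' mutually exclusive share table and a named vector of age thresholds
#' (days) for the selected groups. Each table row intersecting at least one
#' selected group is assigned the youngest (minimum) threshold among the
#' selected groups it contains — overlapping patients get the stricter
#' requirement — and rows are then pooled by threshold into `TM<k>` classes.
#' The residual share goes to the baseline blood recipients (BBRs), served
#' by the `LO` policy unless `baseline_method` says otherwise (the BBR-TM
#' variants give the baseline class a threshold policy too).
#'
#' @param table A table from [hrg_share_table()].
#' @param groups Named numeric vector, e.g. `c(ICU = 7, CS = 14)`; names
#'   are group labels, values threshold ages in days. Empty for the
#'   baseline scenario. Thresholds outside {7, 14, 28} are allowed with a
#'   warning.
#' @param name Scenario label.
#' @param baseline_method Policy name for the baseline class (default
#'   `"LO"`).
#' @param shelf_life Shelf life in days attached to the scenario (default
#'   42; the shortened-shelf-life scenarios change only this).
#' @return An object of class `rbc_scenario`: list with `name`,
#'   `shelf_life`, and `classes`, a data frame with columns `name`, `share`
#'   (percent), `method`, `threshold_age`, high-risk classes first and the
#'   baseline class last. Class shares sum to 100.
#' @export
#' @examples
#' tab <- hrg_share_table()
#' build_scenario(tab, c(ICU = 7), name = "icu")
build_scenario <- function(table, groups = numeric(0), name = "scenario",
                           baseline_method = "LO", shelf_life = 42L) {
  if (length(groups)) {
    if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
      stop("groups must be a named vector: label -> threshold days")
    }
    vapply(names(groups), check_group, "")
    if (anyDuplicated(names(groups))) stop("duplicate group labels")
    if (any(groups < 1)) stop("threshold ages must be positive")
    if (any(!groups %in% c(7, 14, 28))) {
      warning("threshold age(s) outside the usual {7, 14, 28} days")
    }
  }
  # youngest threshold among selected groups present in each row
  assigned <- vapply(table$labels, function(l) {
    hit <- intersect(l, names(groups))
    if (length(hit)) min(groups[hit]) else NA_real_
  }, numeric(1))
  hrg_rows <- !is.na(assigned)
  classes <- data.frame(name = character(0), share = numeric(0),
                        method = character(0), threshold_age = integer(0),
                        stringsAsFactors = FALSE)
  for (k in sort(unique(assigned[hrg_rows]))) {
    classes <- rbind(classes, data.frame(
      name = sprintf("HRG-TM%d", as.integer(k)),
      share = sum(table$share[hrg_rows & assigned == k]),
      method = sprintf("TM%d", as.integer(k)),
      threshold_age = as.integer(k), stringsAsFactors = FALSE))
  }
  bbr_share <- 100 - sum(classes$share)
  if (bbr_share < -0.1) stop("class shares exceed 100%")
  pol <- parse_policy(baseline_method)
  classes <- rbind(classes, data.frame(
    name = "BBR", share = bbr_share, method = baseline_method,
    threshold_age = if (is.null(pol$threshold_age)) NA_integer_ else
      pol$threshold_age,
    stringsAsFactors = FALSE))
  if (abs(sum(classes$share) - 100) > 0.1) stop("class shares must sum to 100")
  structure(list(name = name, shelf_life = as.integer(shelf_life),
                 classes = classes),
            class = "rbc_scenario")
}

#' @export
print.rbc_scenario <- function(x, ...) {
  cat(sprintf("<rbc_scenario '%s', shelf life %d days>\n", x$name, x$shelf_life))
  print(x$classes, row.names = FALSE)
  invisible(x)
}

#' Built-in scenarios
#'
#' The named scenarios of the study: `baseline` (all recipients oldest-first),
#' single-group threshold scenarios `icu` (TM7), `cs`/`ccu` (TM14), `tr`
#' (TM28), the combined `icu-cs` (TM7 for any ICU patient, TM14 for
#' non-overlapping CS), `all-hrgs-tm7`/`all-hrgs-tm14`/`all-hrgs-tm28`
#' (all four groups pooled at one threshold), `bbr-tm7`/`bbr-tm14`
#' (baseline recipients also under a threshold policy), and shortened
#' shelf-life scenarios `sl-35` ... `sl-7` (baseline allocation, shorter
#' shelf life).
#'
#' @param name Scenario name (see Details).
#' @param table Share table, default the packaged one.
#' @return An `rbc_scenario`.
#' @export
builtin_scenario <- function(name, table = hrg_share_table()) {
  all4 <- function(k) stats::setNames(rep(k, 4), HRG_LABELS)
  switch(name,
    "baseline"      = build_scenario(table, name = name),
    "icu"           = build_scenario(table, c(ICU = 7), name = name),
    "cs"            = build_scenario(table, c(CS = 14), name = name),
    "ccu"           = build_scenario(table, c(CCU = 14), name = name),
    "tr"            = build_scenario(table, c(TR = 28), name = name),
    "icu-cs"        = build_scenario(table, c(ICU = 7, CS = 14), name = name),
    "all-hrgs-tm7"  = build_scenario(table, all4(7), name = name),
    "all-hrgs-tm14" = build_scenario(table, all4(14), name = name),
    "all-hrgs-tm28" = build_scenario(table, all4(28), name = name),
    "bbr-tm7"       = build_scenario(table, name = name, baseline_method = "TM7"),
    "bbr-tm14"      = build_scenario(table, name = name, baseline_method = "TM14"),
    "sl-35"         = build_scenario(table, name = name, shelf_life = 35L),
    "sl-28"         = build_scenario(table, name = name, shelf_life = 28L),
    "sl-21"         = build_scenario(table, name = name, shelf_life = 21L),
    "sl-14"         = build_scenario(table, name = name, shelf_life = 14L),
    "sl-7"          = build_scenario(table, name = name, shelf_life = 7L),
    stop("unknown built-in scenario: ", name)
  )
}

#' Read a scenario from a YAML file
#'
#' Keys: `name`, `groups` (map of group label to threshold days, may be
#' empty), `baseline_method` (default `"LO"`), `shelf_life` (default 42).
#'
#' @param path YAML file.
#' @param table Share table used to resolve group shares.
#' @return An `rbc_scenario`.
#' @export
read_scenario_yaml <- function(path, table = hrg_share_table()) {
  cfg <- yaml::read_yaml(path)
  groups <- unlist(cfg$groups %||% list())
  build_scenario(table,
                 groups = if (length(groups)) groups else numeric(0),
                 name = cfg$name %||% basename(path),
                 baseline_method = cfg$baseline_method %||% "LO",
                 shelf_life = cfg$shelf_life %||% 42L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split a day's demand across recipient classes
#'
#' Partitions each phenotype's integer demand across the scenario's classes.
#' By default the split is a multinomial draw with probabilities equal to the
#' class shares (the shares are annual averages, so day-to-day composition
#' fluctuates); `mode = "proportional"` gives a deterministic
#' largest-remainder split instead. Class totals always sum exactly to the
#' input demand for every phenotype.
#'
#' @param total_demand Named integer vector of demanded units by phenotype.
#' @param scenario An `rbc_scenario`.
#' @param mode `"multinomial"` (default) or `"proportional"`.
#' @return Integer matrix: classes in rows, phenotypes in columns.
#' @export
partition_daily_demand <- function(total_demand, scenario,
                                   mode = c("multinomial", "proportional")) {
  mode <- match.arg(mode)
  stopifnot(inherits(scenario, "rbc_scenario"))
  shares <- scenario$classes$share / 100
  k <- length(shares)
  out <- matrix(0L, k, length(total_demand),
                dimnames = list(scenario$classes$name, names(total_demand)))
  for (j in seq_along(total_demand)) {
    n <- as.integer(total_demand[j])
    if (n <= 0L) next
    if (k == 1L) { out[1L, j] <- n; next }
    if (mode == "multinomial") {
      out[, j] <- as.integer(stats::rmultinom(1L, n, shares))
    } else {
      raw <- n * shares
      base <- floor(raw)
      rem <- n - sum(base)
      if (rem > 0) {
        extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
      }
      out[, j] <- as.integer(base)
    }
  }
  out
}
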