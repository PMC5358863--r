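# Issuing policies over an aged, phenotype-stratified inventory.
#
# All policies operate on the raw counts matrix (8 phenotypes x shelf_life
# ages) of a bank and return the units issued, the residual unmet demand,
# and (for the Threshold Method) the units that failed the age requirement.

# Greedily take up to `quantity` units from `counts` scanning cells in the
# priority order given by flat column-major indices `idx`. Returns updated
# counts and the take per cell.
greedy_take <- function(counts, idx, quantity) {
  avail <- counts[idx]
  prior <- cumsum(avail) - avail
  take <- pmin(avail, pmax(0L, quantity - prior))
  counts[idx] <- avail - take
  list(counts = counts, idx = idx, take = take, n = sum(take))
}

# Flat column-major indices for cells ordered age-major (outer loop over
# `ages` in the given sequence, inner loop over donor rows in preference
# order), for an 8-row counts matrix.
cell_order <- function(donor_rows, ages) {
  rep((ages - 1L) * 8L, each = length(donor_rows)) + donor_rows
}

empty_issue <- function(shelf_life) {
  matrix(0L, 8L, shelf_life, dimnames = list(rbc_phenotypes(), seq_len(shelf_life)))
}

#' Age-ordered issuing (FIFO/LO oldest-first, LIFO/LN newest-first)
#'
#' Greedily issues compatible units scanning storage ages from the stated
#' direction; within each age step, donors are taken in the recipient's
#' preference order ([ordered_donors()]). Shortfall is recorded as unmet
#' demand, not an error.
#'
#' @param counts 8 x shelf_life integer counts matrix (a bank's `counts`).
#' @param recipient Recipient phenotype label.
#' @param quantity Non-negative number of units requested.
#' @param matrix Compatibility matrix governing which donor phenotypes may
#'   be issued.
#' @param direction `"oldest_first"` (FIFO/LO) or `"newest_first"`
#'   (LIFO/LN).
#' @return A list: `issued` (8 x shelf_life matrix of issued units),
#'   `unmet` (requested minus issued), `unmet_by_age` (0 for age-ordered
#'   policies), and `counts` (the decremented inventory).
#' @export
allocate_age_ordered <- function(counts, recipient, quantity,
                                 matrix = compatibility_matrix(),
                                 direction = c("oldest_first", "newest_first")) {
  direction <- match.arg(direction)
  quantity <- as.integer(quantity)
  if (quantity < 0L) stop("quantity must be non-negative")
  sl <- ncol(counts)
  donors <- phenotype_index(ordered_donors(recipient, matrix))
  ages <- if (direction == "oldest_first") sl:1 else 1:sl
  g <- greedy_take(counts, cell_order(donors, ages), quantity)
  issued <- empty_issue(sl)
  issued[g$idx] <- g$take
  list(issued = issued, unmet = quantity - g$n, unmet_by_age = 0L,
       counts = g$counts)
}

#' Threshold Method issuing
#'
#' The three-stage age-threshold policy used to transfuse high-risk patient
#' groups with fresher stored units. Demand is filled by: (1) exact-phenotype
#' units with age at most `threshold_age`, oldest qualifying age first;
#' (2) compatible-phenotype units within the threshold, oldest first, donors
#' in preference order within each age; (3) if within-threshold stock is
#' exhausted, the freshest available compatible unit regardless of age
#' (last-in-first-out fallback). Units issued by the stage-3 fallback, plus
#' any demand left unfilled, count as "unmet by age": demanded units that
#' could not be supplied at or below the required age.
#'
#' @inheritParams allocate_age_ordered
#' @param threshold_age Oldest acceptable storage age, in `1..shelf_life`.
#' @return As [allocate_age_ordered()], with `unmet_by_age` = stage-3 issued
#'   units + residual unmet demand. Always `sum(issued) + unmet == quantity`.
#' @export
allocate_threshold <- function(counts, recipient, quantity, threshold_age,
                               matrix = compatibility_matrix()) {
  quantity <- as.integer(quantity)
  if (quantity < 0L) stop("quantity must be non-negative")
  sl <- ncol(counts)
  threshold_age <- as.integer(threshold_age)
  if (threshold_age < 1L || threshold_age > sl) {
    stop(sprintf("threshold_age must lie in 1..%d", sl))
  }
  donors <- phenotype_index(ordered_donors(recipient, matrix))
  issued <- empty_issue(sl)
  remaining <- quantity

  # stage 1: exact match within threshold, oldest qualifying first
  g <- greedy_take(counts, cell_order(donors[1L], threshold_age:1), remaining)
  issued[g$idx] <- issued[g$idx] + g$take
  counts <- g$counts
  remaining <- remaining - g$n

  # stage 2: compatible within threshold
  if (remaining > 0L && length(donors) > 1L) {
    g <- greedy_take(counts, cell_order(donors[-1L], threshold_age:1), remaining)
    issued[g$idx] <- issued[g$idx] + g$take
    counts <- g$counts
    remaining <- remaining - g$n
  }

  # stage 3: freshest available compatible unit, any age (LIFO fallback)
  stage3 <- 0L
  if (remaining > 0L) {
    g <- greedy_take(counts, cell_order(donors, 1:sl), remaining)
    issued[g$idx] <- issued[g$idx] + g$take
    counts <- g$counts
    remaining <- remaining - g$n
    stage3 <- g$n
  }

  list(issued = issued, unmet = remaining,
       unmet_by_age = stage3 + remaining, counts = counts)
}

#' Issue units under a named policy
#'
#' Dispatches on the policy names used in scenario configuration: `"FIFO"`
#' and `"LO"` issue oldest-first, `"LIFO"` and `"LN"` newest-first, and
#' `"TM"` applies [allocate_threshold()] (named `TM7`, `TM14`, `TM28` ... in
#' configs, the suffix being the threshold age in days).
#'
#' @inheritParams allocate_age_ordered
#' @param method One of `"FIFO"`, `"LIFO"`, `"LO"`, `"LN"`, `"TM"`.
#' @param threshold_age Required when `method = "TM"`.
#' @return As [allocate_age_ordered()].
#' @export
allocate <- function(counts, recipient, quantity,
                     method = c("LO", "FIFO", "LN", "LIFO", "TM"),
                     threshold_age = NULL,
                     matrix = compatibility_matrix()) {
  method <- match.arg(method)
  if (method == "TM") {
    if (is.null(threshold_age)) stop("method TM requires threshold_age")
    allocate_threshold(counts, recipient, quantity, threshold_age, matrix)
  } else {
    dir <- if (method %in% c("FIFO", "LO")) "oldest_first" else "newest_first"
    allocate_age_ordered(counts, recipient, quantity, matrix, dir)
  }
}

#' Parse a policy name from configuration
#'
#' Splits strings such as `"TM7"` into method `"TM"` with threshold 7;
#' passes `"FIFO"`, `"LIFO"`, `"LO"`, `"LN"` through unchanged.
#'
#' @param name Policy string.
#' @return List with elements `method` and `threshold_age` (NULL unless TM).
#' @export
parse_policy <- function(name) {
  if (name %in% c("FIFO", "LIFO", "LO", "LN")) {
    return(list(method = name, threshold_age = NULL))
  }
  if (grepl("^TM[0-9]+$", name)) {
    return(list(method = "TM",
                threshold_age = as.integer(sub("^TM", "", name))))
  }
  stop("unknown allocation policy: ", name)
}
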