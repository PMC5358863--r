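#' Create an empty aged blood bank
#'
#' A bank holds integer counts of RBC units stratified by phenotype and
#' storage age (days since collection). Ages run from 1 to `shelf_life`;
#' units that would exceed the shelf life at the end-of-day aging step are
#' removed as expired.
#'
#' @param role Either `"collector"` (the aggregate collection bank that
#'   receives donations) or `"hospital"` (the aggregate distributor that
#'   transfuses patients). The role is fixed at construction.
#' @param shelf_life Maximum permitted storage age in days (default 42,
#'   current US policy).
#' @return An object of class `rbc_bank`: a list with elements `role`,
#'   `shelf_life` and `counts`, an 8 x `shelf_life` integer matrix with
#'   phenotypes in rows (canonical order) and ages in columns.
#' @export
#' @examples
#' b <- new_bank("hospital")
#' b <- add_units(b, "O+", age = 5, n = 10)
#' bank_total(b)
new_bank <- function(role = c("collector", "hospital"), shelf_life = 42L) {
  role <- match.arg(role)
  shelf_life <- as.integer(shelf_life)
  if (length(shelf_life) != 1L || is.na(shelf_life) || shelf_life < 1L) {
    stop("shelf_life must be a positive integer")
  }
  counts <- matrix(0L, nrow = 8L, ncol = shelf_life,
                   dimnames = list(rbc_phenotypes(), seq_len(shelf_life)))
  structure(list(role = role, shelf_life = shelf_life, counts = counts),
            class = "rbc_bank")
}

#' @export
print.rbc_bank <- function(x, ...) {
  cat(sprintf("<rbc_bank: %s, shelf life %d days, %d units>\n",
              x$role, x$shelf_life, bank_total(x)))
  invisible(x)
}

stopifnot_valid_age <- function(bank, age) {
  if (any(age < 1L) || any(age > bank$shelf_life)) {
    stop(sprintf("age must lie in 1..%d", bank$shelf_life))
  }
}

#' Add units to a bank
#'
#' @param bank An [new_bank()] object.
#' @param phenotype Phenotype label.
#' @param age Storage age in days, in `1..shelf_life`.
#' @param n Non-negative number of units.
#' @return The updated bank.
#' @export
add_units <- function(bank, phenotype, age, n) {
  stopifnot(inherits(bank, "rbc_bank"))
  age <- as.integer(age)
  n <- as.integer(n)
  stopifnot_valid_age(bank, age)
  if (any(n < 0L)) stop("n must be non-negative")
  i <- phenotype_index(phenotype)
  idx <- cbind(i, age)
  bank$counts[idx] <- bank$counts[idx] + n
  bank
}

#' Age a bank by one day
#'
#' Every stored unit's age increases by one day; units whose new age would
#' exceed the shelf life are removed and reported as expired. Total units
#' are conserved: `before == after + sum(expired)`.
#'
#' @param bank An [new_bank()] object.
#' @return A list with elements `bank` (aged bank) and `expired` (named
#'   integer vector of expired units by phenotype).
#' @export
age_one_day <- function(bank) {
  stopifnot(inherits(bank, "rbc_bank"))
  sl <- bank$shelf_life
  expired <- bank$counts[, sl]
  if (sl > 1L) {
    bank$counts[, 2:sl] <- bank$counts[, 1:(sl - 1L)]
    bank$counts[, 1L] <- 0L
  } else {
    bank$counts[, 1L] <- 0L
  }
  list(bank = bank, expired = expired)
}

#' Count units of a phenotype at or below an age
#'
#' The stock a threshold-age issuing policy can draw on: units of the given
#' phenotype stored for at most `max_age` days.
#'
#' @param bank An [new_bank()] object.
#' @param phenotype Phenotype label.
#' @param max_age Oldest acceptable age, in `1..shelf_life`.
#' @return Non-negative integer count.
#' @export
count_within_age <- function(bank, phenotype, max_age) {
  stopifnot(inherits(bank, "rbc_bank"))
  max_age <- as.integer(max_age)
  stopifnot_valid_age(bank, max_age)
  i <- phenotype_index(phenotype)
  sum(bank$counts[i, seq_len(max_age)])
}

#' Total units in a bank
#'
#' @param bank An [new_bank()] object.
#' @return Integer count of all units across phenotypes and ages.
#' @export
bank_total <- function(bank) {
  stopifnot(inherits(bank, "rbc_bank"))
  sum(bank$counts)
}

#' Total supply across banks
#'
#' The system-wide stock: sum of all units over a list of banks
#' (collector + hospital in the two-bank model).
#'
#' @param banks A list of [new_bank()] objects.
#' @return Integer count.
#' @export
total_supply <- function(banks) {
  if (inherits(banks, "rbc_bank")) banks <- list(banks)
  sum(vapply(banks, bank_total, numeric(1)))
}

#' Snapshot a bank as a data frame
#'
#' One row per non-zero (phenotype, age) cell, with columns `bank`,
#' `phenotype`, `age`, `count` — the plain-text serialization format for
#' inventory snapshots.
#'
#' @param bank An [new_bank()] object.
#' @return A data frame.
#' @seealso [write_inventory_csv()], [read_inventory_csv()]
#' @export
inventory_snapshot <- function(bank) {
  stopifnot(inherits(bank, "rbc_bank"))
  nz <- which(bank$counts > 0L, arr.ind = TRUE)
  data.frame(
    bank = rep(bank$role, nrow(nz)),
    phenotype = rbc_phenotypes()[nz[, 1L]],
    age = as.integer(nz[, 2L]),
    count = bank$counts[nz],
    stringsAsFactors = FALSE
  )[order(nz[, 2L], nz[, 1L]), , drop = FALSE]
}

#' Write inventory snapshots to CSV
#'
#' @param banks A bank or list of banks.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_inventory_csv <- function(banks, path) {
  if (inherits(banks, "rbc_bank")) banks <- list(banks)
  df <- do.call(rbind, lapply(banks, inventory_snapshot))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read inventory snapshots from CSV
#'
#' @param path CSV written by [write_inventory_csv()].
#' @param shelf_life Shelf life of the reconstructed banks.
#' @return A named list of banks, one per distinct `bank` value in the file.
#' @export
read_inventory_csv <- function(path, shelf_life = 42L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("bank", "phenotype", "age", "count")
  if (!all(needed %in% names(df))) {
    stop("inventory CSV must have columns: ", paste(needed, collapse = ", "))
  }
  out <- lapply(split(df, df$bank), function(d) {
    b <- new_bank(d$bank[1L], shelf_life = shelf_life)
    add_units(b, d$phenotype, d$age, d$count)
  })
  out
}
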