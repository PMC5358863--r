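#' Red-cell ABO/Rh compatibility matrices
#'
#' Builds an 8 x 8 logical matrix `allowed[recipient, donor]` under textbook
#' red-cell rules: donor group O is ABO-compatible with every recipient, A
#' with A/AB, B with B/AB, AB only with AB; an Rh-negative donor is
#' compatible with both Rh signs, an Rh-positive donor only with Rh-positive
#' recipients. Two named rule sets exist in the model: `"standard"` governs
#' collector-to-hospital transfers and `"practical"` governs
#' hospital-to-patient transfusion. Both default to the textbook rules; the
#' standard (inter-bank) set can be restricted to identical-phenotype
#' transfers only via `identical_only`, and either set can be replaced from
#' a CSV file with [read_compatibility_csv()].
#'
#' @param name Rule-set label, `"practical"` or `"standard"`.
#' @param identical_only If `TRUE`, only exact-phenotype transfers are
#'   allowed (an optional restriction of the inter-bank rule set).
#' @return A logical 8 x 8 matrix with `name` attribute; rows are recipients,
#'   columns donors, both in canonical phenotype order.
#' @export
#' @examples
#' m <- compatibility_matrix("practical")
#' m["A+", "O-"]   # universal donor
compatibility_matrix <- function(name = c("practical", "standard"),
                                 identical_only = FALSE) {
  name <- match.arg(name)
  ph <- rbc_phenotypes()
  abo <- phenotype_abo()
  rh <- phenotype_rh()
  allowed <- matrix(FALSE, 8L, 8L, dimnames = list(ph, ph))
  for (r in 1:8) {
    for (d in 1:8) {
      abo_ok <- abo[d] == "O" || abo[d] == abo[r] ||
        (abo[r] == "AB" && abo[d] %in% c("A", "B"))
      rh_ok <- rh[d] == "-" || rh[r] == "+"
      allowed[r, d] <- abo_ok && rh_ok
    }
  }
  if (identical_only) allowed <- allowed & diag(8L) > 0
  attr(allowed, "name") <- name
  allowed
}

#' Test red-cell compatibility
#'
#' @param recipient,donor Phenotype labels (vectorized).
#' @param matrix A matrix from [compatibility_matrix()] or
#'   [read_compatibility_csv()].
#' @return Logical vector.
#' @export
is_compatible <- function(recipient, donor, matrix = compatibility_matrix()) {
  matrix[cbind(phenotype_index(recipient), phenotype_index(donor))]
}

#' Donor preference order for a recipient
#'
#' Orders the donors allowed by a compatibility matrix for one recipient:
#' the exact match comes first, then ABO-compatible donors of identical Rh
#' sign, then Rh-crossing donors; within each tier, canonical phenotype
#' order. Rh-preserving before Rh-crossing conserves Rh-negative stock, a
#' standard blood-banking heuristic.
#'
#' @param recipient Phenotype label.
#' @param matrix Compatibility matrix.
#' @return Character vector of donor phenotypes, a permutation of the
#'   allowed set with the recipient's own phenotype first.
#' @export
#' @examples
#' ordered_donors("A+")   # A+, then O+, then the Rh-crossing donors
ordered_donors <- function(recipient, matrix = compatibility_matrix()) {
  r <- phenotype_index(recipient)
  allowed <- which(matrix[r, ])
  rh <- phenotype_rh()
  exact <- allowed[allowed == r]
  same_rh <- allowed[allowed != r & rh[allowed] == rh[r]]
  cross_rh <- allowed[allowed != r & rh[allowed] != rh[r]]
  rbc_phenotypes()[c(exact, sort(same_rh), sort(cross_rh))]
}

#' Read a compatibility matrix from CSV
#'
#' Format: an 8 x 8 table of 0/1 cells with a header row and a first column
#' of phenotype labels; rows are recipients, columns donors.
#'
#' @param path CSV file path.
#' @param name Label to attach (`"practical"` or `"standard"`).
#' @return A logical 8 x 8 matrix in canonical phenotype order.
#' @export
read_compatibility_csv <- function(path, name = "practical") {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  if (!setequal(rownames(df), rbc_phenotypes()) ||
      !setequal(colnames(df), rbc_phenotypes())) {
    stop("compatibility CSV must have the 8 phenotype labels as row and column names")
  }
  m <- as.matrix(df)[rbc_phenotypes(), rbc_phenotypes()] > 0
  attr(m, "name") <- name
  m
}

#' Write a compatibility matrix to CSV
#'
#' @param matrix Compatibility matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_compatibility_csv <- function(matrix, path) {
  utils::write.csv(matrix * 1L, path, quote = FALSE)
  invisible(path)
}
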