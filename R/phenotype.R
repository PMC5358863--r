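#' Canonical ABO/Rh phenotype labels
#'
#' The eight red-cell phenotypes in the fixed canonical order used everywhere
#' deterministic iteration is needed: `O-`, `O+`, `A-`, `A+`, `B-`, `B+`,
#' `AB-`, `AB+`.
#'
#' @return Character vector of length 8.
#' @export
#' @examples
#' rbc_phenotypes()
rbc_phenotypes <- function() {
  c("O-", "O+", "A-", "A+", "B-", "B+", "AB-", "AB+")
}

# ABO group and Rh sign of each canonical phenotype, by position
phenotype_abo <- function() c("O", "O", "A", "A", "B", "B", "AB", "AB")
phenotype_rh  <- function() c("-", "+", "-", "+", "-", "+", "-", "+")

#' Validate and index phenotype labels
#'
#' Maps phenotype labels to their positions in the canonical order, rejecting
#' unknown labels.
#'
#' @param x Character vector of phenotype labels.
#' @return Integer vector of positions in [rbc_phenotypes()].
#' @export
phenotype_index <- function(x) {
  i <- match(x, rbc_phenotypes())
  if (anyNA(i)) {
    stop("unknown phenotype label(s): ", paste(x[is.na(i)], collapse = ", "))
  }
  i
}
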