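# Test helpers: small inventory builders and a brute-force allocation
# oracle, independent of the greedy implementation.

# counts matrix from a list like list("O+" = c(`10` = 2, `20` = 3))
mk_counts <- function(cells, shelf_life = 42L) {
  m <- matrix(0L, 8L, shelf_life,
              dimnames = list(rbc_phenotypes(), seq_len(shelf_life)))
  for (p in names(cells)) {
    v <- cells[[p]]
    m[p, as.integer(names(v))] <- as.integer(v)
  }
  m
}

mk_bank <- function(role, cells, shelf_life = 42L) {
  b <- new_bank(role, shelf_life)
  b$counts <- mk_counts(cells, shelf_life)
  b
}

# Exhaustive search over all feasible per-cell takes from the compatible
# non-zero cells (per-cell take capped at the request). Returns, over all
# assignments issuing the maximum feasible number of units:
#   max_issued, and conditional on that, max/min total age, and the
#   maximum number of units with age <= threshold together with the
#   maximum total issued achieving it (the Threshold Method's objective:
#   within-threshold units first, total issued second).
oracle_allocation <- function(counts, recipient, quantity, matrix, threshold = NULL) {
  donors <- which(matrix[phenotype_index(recipient), ])
  cells <- which(counts > 0L, arr.ind = TRUE)
  cells <- cells[cells[, 1L] %in% donors, , drop = FALSE]
  if (nrow(cells) == 0L || quantity == 0L) {
    return(list(max_issued = 0L, max_agesum = 0L, min_agesum = 0L,
                max_within = 0L))
  }
  caps <- pmin(counts[cells], quantity)
  grid <- as.matrix(expand.grid(lapply(caps, function(k) 0:k)))
  tot <- rowSums(grid)
  grid <- grid[tot <= quantity, , drop = FALSE]
  tot <- rowSums(grid)
  ages <- cells[, 2L]
  agesum <- as.vector(grid %*% ages)
  best <- max(tot)
  at_best <- tot == best
  out <- list(max_issued = best,
              max_agesum = max(agesum[at_best]),
              min_agesum = min(agesum[at_best]))
  if (!is.null(threshold)) {
    within <- as.vector(grid %*% (ages <= threshold))
    w <- max(within)
    out$max_within <- w
    out$max_issued_at_w <- max(tot[within == w])
  }
  out
}

# random small instance for oracle-equivalence checks
random_instance <- function(shelf_life = 10L) {
  n_cells <- sample(1:6, 1L)
  phen <- sample(rbc_phenotypes(), n_cells, replace = TRUE)
  age <- sample(seq_len(shelf_life), n_cells, replace = TRUE)
  counts <- matrix(0L, 8L, shelf_life,
                   dimnames = list(rbc_phenotypes(), seq_len(shelf_life)))
  for (i in seq_len(n_cells)) {
    counts[phen[i], age[i]] <- counts[phen[i], age[i]] + sample(1:4, 1L)
  }
  list(counts = counts,
       recipient = sample(rbc_phenotypes(), 1L),
       quantity = sample(0:5, 1L),
       threshold = sample(seq_len(shelf_life), 1L))
}

# check one instance against the oracle for every policy; returns TRUE or
# a description of the first mismatch
check_instance_against_oracle <- function(inst, matrix = compatibility_matrix()) {
  with(inst, {
    issued_age <- function(res) sum(res$issued %*% seq_len(ncol(counts)))
    orc <- oracle_allocation(counts, recipient, quantity, matrix, threshold)
    lo <- allocate_age_ordered(counts, recipient, quantity, matrix, "oldest_first")
    if (sum(lo$issued) != min(quantity, orc$max_issued) ||
        issued_age(lo) != (if (sum(lo$issued)) orc$max_agesum else 0))
      return("oldest_first mismatch")
    ln <- allocate_age_ordered(counts, recipient, quantity, matrix, "newest_first")
    if (sum(ln$issued) != min(quantity, orc$max_issued) ||
        issued_age(ln) != (if (sum(ln$issued)) orc$min_agesum else 0))
      return("newest_first mismatch")
    tm <- allocate_threshold(counts, recipient, quantity, threshold, matrix)
    within <- sum(tm$issued[, seq_len(threshold), drop = FALSE])
    if (within != min(quantity, orc$max_within))
      return("TM within-threshold mismatch")
    if (sum(tm$issued) != min(quantity, orc$max_issued))
      return("TM total issued mismatch")
    if (sum(tm$issued) + tm$unmet != quantity) return("TM accounting mismatch")
    TRUE
  })
}
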