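test_that("age-ordered issuing follows the stated direction", {
  inv <- mk_counts(list("O+" = c(`10` = 2, `20` = 3)))

  lo <- allocate_age_ordered(inv, "O+", 4, direction = "oldest_first")
  expect_equal(unname(lo$issued["O+", c(10, 20)]), c(1, 3))
  expect_equal(lo$unmet, 0)

  ln <- allocate_age_ordered(inv, "O+", 4, direction = "newest_first")
  expect_equal(unname(ln$issued["O+", c(10, 20)]), c(2, 2))

  # inventory decremented exactly by what was issued
  expect_equal(lo$counts + lo$issued, inv)
})

test_that("age-ordered issuing crosses phenotypes oldest-first when compatible", {
  inv <- mk_counts(list("A+" = c(`5` = 1), "O-" = c(`30` = 1)))
  res <- allocate_age_ordered(inv, "A+", 3, direction = "oldest_first")
  expect_equal(sum(res$issued), 2)
  expect_equal(res$unmet, 1)
  expect_equal(unname(res$issued["O-", 30]), 1)
  expect_equal(unname(res$issued["A+", 5]), 1)
  # oldest first: the O- age-30 unit outranks the fresher exact match
  orc <- oracle_allocation(inv, "A+", 3, compatibility_matrix())
  expect_equal(sum(res$issued %*% 1:42), orc$max_agesum)
})

test_that("threshold issuing fills within the age limit before falling back", {
  # threshold satisfied exactly
  r1 <- allocate_threshold(mk_counts(list("O+" = c(`5` = 2))), "O+", 2, 7)
  expect_equal(unname(r1$issued["O+", 5]), 2)
  expect_equal(r1$unmet_by_age, 0)

  # only over-age stock: LIFO fallback issues but counts as unmet-by-age
  r2 <- allocate_threshold(mk_counts(list("O+" = c(`10` = 3))), "O+", 2, 7)
  expect_equal(unname(r2$issued["O+", 10]), 2)
  expect_equal(r2$unmet, 0)
  expect_equal(r2$unmet_by_age, 2)

  # compatible within threshold beats exact over threshold
  inv <- mk_counts(list("O+" = c(`10` = 1), "O-" = c(`6` = 1)))
  r3 <- allocate_threshold(inv, "O+", 2, 7)
  expect_equal(unname(r3$issued["O-", 6]), 1)   # stage 2
  expect_equal(unname(r3$issued["O+", 10]), 1)  # stage 3 fallback
  expect_equal(r3$unmet_by_age, 1)
  orc <- oracle_allocation(inv, "O+", 2, compatibility_matrix(), threshold = 7)
  expect_equal(sum(r3$issued[, 1:7]), orc$max_within)
})

test_that("issuing satisfies the accounting identity on random instances", {
  set.seed(31)
  m <- compatibility_matrix()
  for (i in 1:100) {
    inst <- random_instance()
    for (fn in list(
      function() allocate_age_ordered(inst$counts, inst$recipient,
                                      inst$quantity, m, "oldest_first"),
      function() allocate_age_ordered(inst$counts, inst$recipient,
                                      inst$quantity, m, "newest_first"),
      function() allocate_threshold(inst$counts, inst$recipient,
                                    inst$quantity, inst$threshold, m))) {
      res <- fn()
      expect_equal(sum(res$issued) + res$unmet, inst$quantity)
      expect_true(all(res$counts >= 0))
      expect_equal(res$counts + res$issued, inst$counts)
      expect_true(res$unmet_by_age <= inst$quantity)
    }
  }
})

test_that("unmet-by-age is non-increasing in the threshold age", {
  set.seed(55)
  for (i in 1:50) {
    inst <- random_instance(shelf_life = 42L)
    uba <- sapply(c(7, 14, 28, 42), function(th) {
      allocate_threshold(inst$counts, inst$recipient, inst$quantity,
                         th)$unmet_by_age
    })
    expect_true(all(diff(uba) <= 0))
    # at threshold = shelf life the fallback never triggers
    at_sl <- allocate_threshold(inst$counts, inst$recipient, inst$quantity, 42L)
    expect_equal(at_sl$unmet_by_age, at_sl$unmet)
  }
})

test_that("oldest-first issues older blood than newest-first on average", {
  set.seed(77)
  m <- compatibility_matrix()
  for (i in 1:50) {
    inst <- random_instance()
    lo <- allocate_age_ordered(inst$counts, inst$recipient, inst$quantity, m,
                               "oldest_first")
    ln <- allocate_age_ordered(inst$counts, inst$recipient, inst$quantity, m,
                               "newest_first")
    if (sum(lo$issued) > 0) {
      ages <- seq_len(ncol(inst$counts))
      expect_gte(sum(lo$issued %*% ages), sum(ln$issued %*% ages))
    }
  }
})

test_that("greedy policies match the brute-force oracle on small instances", {
  set.seed(99)
  for (i in 1:150) {
    expect_true(isTRUE(check_instance_against_oracle(random_instance())))
  }
})

test_that("policy names parse to methods and thresholds", {
  expect_equal(parse_policy("TM14"), list(method = "TM", threshold_age = 14L))
  expect_equal(parse_policy("LO")$method, "LO")
  expect_null(parse_policy("FIFO")$threshold_age)
  expect_error(parse_policy("TMx"), "unknown")
  expect_error(allocate(mk_counts(list()), "O+", 1, method = "TM"),
               "threshold_age")
})
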