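# Small-world engine tests: a single-phenotype toy system where every step
# of the daily loop can be traced by hand, plus determinism and
# conservation on short runs.

toy_scenario <- function(threshold = 7L) {
  structure(list(
    name = "toy", shelf_life = 42L,
    classes = data.frame(
      name = c(sprintf("HRG-TM%d", threshold), "BBR"),
      share = c(100, 0),
      method = c(sprintf("TM%d", threshold), "LO"),
      threshold_age = c(as.integer(threshold), NA_integer_),
      stringsAsFactors = FALSE)),
    class = "rbc_scenario")
}

o_plus <- function(x) stats::setNames(c(0L, as.integer(x), rep(0L, 6)),
                                      rbc_phenotypes())

test_that("a day with no flows only ages the banks", {
  cfg <- simulation_config(horizon = 1, n_replicates = 1,
                           n_steady_state_runs = 1, burn_in_days = 1)
  st <- new_sim_state(builtin_scenario("baseline"), cfg,
                      expected_demand = rep(0, 8),
                      initial_hospital = mk_counts(list("O+" = c(`42` = 3, `10` = 2))))
  r <- run_day(st, o_plus(0), o_plus(0))
  expect_equal(unname(r$row["expired_hospital"]), 3)
  expect_equal(unname(r$row["hospital_end"]), 2)
  expect_equal(unname(r$row["transfused.BBR"]), 0)
})

test_that("the daily loop traces correctly in a one-phenotype world", {
  # Hospital holds 3 old units (age 10); the high-risk class demands 2 at
  # threshold 7; the Collector holds 10 fresh units (age 5).
  cfg <- simulation_config(horizon = 1, n_replicates = 1,
                           n_steady_state_runs = 1, burn_in_days = 1)
  st <- new_sim_state(toy_scenario(7L), cfg,
                      expected_demand = o_plus(2),
                      initial_collector = mk_counts(list("O+" = c(`5` = 10))),
                      initial_hospital = mk_counts(list("O+" = c(`10` = 3))))
  r <- run_day(st, o_plus(0), o_plus(2))
  row <- r$row
  # transfusion: only age-10 stock, so both units issue via the fallback
  expect_equal(unname(row["transfused.HRG-TM7"]), 2)
  expect_equal(unname(row["unmet_by_age.HRG-TM7"]), 2)
  expect_equal(unname(row["agesum.HRG-TM7"]), 20)
  expect_equal(unname(row["unmet.HRG-TM7"]), 0)
  # shipment moves at least 2 young units that still satisfy the
  # threshold after overnight aging (shipped at age 5, used at age 6)
  expect_gte(unname(row["shipped_young"]), 2)
  expect_gte(sum(r$state$hospital["O+", 1:7]), 2)
  # restock tops the hospital up toward 6 days x expected demand
  expect_equal(unname(row["hospital_end"]),
               min(12, 1 + 10))  # 1 leftover old unit + all collector stock
  expect_equal(unname(row["collector_end"]), 0)
})

test_that("replicates are deterministic and ledgers satisfy conservation", {
  cfg <- simulation_config(horizon = 60, n_replicates = 2,
                           n_steady_state_runs = 2, burn_in_days = 40,
                           seed = 404)
  fl <- flow_model(216, 200)
  pm <- prevalence_model()
  scens <- list(builtin_scenario("baseline"), builtin_scenario("icu"))
  ex1 <- run_experiment(scens, cfg, fl, pm)
  ex2 <- run_experiment(scens, cfg, fl, pm)
  expect_identical(ex1$ledgers, ex2$ledgers)
  expect_identical(ex1$initial_banks, ex2$initial_banks)
  for (nm in names(ex1$ledgers)) {
    for (l in ex1$ledgers[[nm]]) {
      expect_true(check_conservation(l))
      # daily hospital/collector totals are never negative
      expect_true(all(l$collector_end >= 0 & l$hospital_end >= 0))
    }
  }
  expect_equal(nrow(ex1$ledgers[["baseline"]][[1]]), 60)
})

test_that("a one-day horizon yields a single-row ledger", {
  cfg <- simulation_config(horizon = 1, n_replicates = 1,
                           n_steady_state_runs = 1, burn_in_days = 1, seed = 7)
  fl <- flow_model(108, 100)
  set.seed(1)
  flows <- sample_replicate_flows(fl, prevalence_model(), 1)
  led <- run_replicate(builtin_scenario("baseline"), cfg, flows, fl)
  expect_equal(nrow(led), 1)
  expect_true(check_conservation(led))
})

test_that("steady-state initialization is reproducible and integer-valued", {
  cfg <- simulation_config(horizon = 30, n_replicates = 1,
                           n_steady_state_runs = 3, burn_in_days = 50,
                           seed = 11)
  fl <- flow_model(216, 200)
  pm <- prevalence_model()
  b1 <- initialize_steady_state(cfg, builtin_scenario("baseline"), fl, pm)
  b2 <- initialize_steady_state(cfg, builtin_scenario("baseline"), fl, pm)
  expect_identical(b1, b2)
  expect_true(all(b1$collector == round(b1$collector)))
  expect_true(all(b1$collector >= 0) && all(b1$hospital >= 0))
  expect_gt(sum(b1$hospital), 0)
})

test_that("shorter shelf lives never increase total supply under common draws", {
  cfg <- simulation_config(horizon = 90, n_replicates = 3,
                           n_steady_state_runs = 2, burn_in_days = 150,
                           seed = 2024)
  fl <- flow_model(216, 200)
  pm <- prevalence_model()
  ex <- run_experiment(list(builtin_scenario("baseline"),
                            builtin_scenario("sl-21"),
                            builtin_scenario("sl-7")),
                       cfg, fl, pm)
  supply <- sapply(ex$ledgers, function(reps) {
    sapply(reps, function(l) mean(l$collector_end + l$hospital_end))
  })
  # per replicate: shelf life 42 >= 21 >= 7
  expect_true(all(supply[, "baseline"] >= supply[, "sl-21"]))
  expect_true(all(supply[, "sl-21"] >= supply[, "sl-7"]))
})
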