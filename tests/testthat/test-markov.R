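test_that("transition matrix encodes the monthly probabilities", {
  p <- base_params()
  tm <- build_transition_model(p)
  expect_equal(tm["well", "mild"], 0.0244 * 0.243)            # 0.0059292
  expect_equal(tm["well", "dead"], 2.5e-5)
  expect_equal(tm["mild", "dead"], 2.5e-5 * 1.81)             # 4.525e-5
  expect_equal(tm["mild", "well"], 0.0054)
  expect_equal(tm["moderate", "well"], 0.0054)
  expect_equal(unname(tm["dead", ]), c(0, 0, 0, 0, 1))
  expect_equal(unname(rowSums(tm)), rep(1, 5), tolerance = 1e-14)
  # symptomatic staying mass is redistributed by the severity mix
  stay <- 1 - 0.0054 - 2.5e-5 * 1.81
  expect_equal(tm["severe", "mild"], stay * 0.243)
})

test_that("well state is absorbing without relapse and mortality", {
  p <- base_params(relapse_monthly = 0, mortality_monthly = 0)
  tm <- build_transition_model(p)
  expect_equal(unname(tm["well", ]), c(1, 0, 0, 0, 0))
})

test_that("row-stochasticity holds across random parameter sets", {
  for (s in 1:20) {
    tm <- build_transition_model(perturbed_params(s))
    expect_equal(unname(rowSums(tm)), rep(1, 5), tolerance = 1e-12)
    expect_true(all(tm >= 0))
  }
})

test_that("discount factors follow the closed form", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(12, 0.03), 1 / 1.03)
  expect_equal(discount_factor(60, 0), 1)
  expect_equal(discount_factor(30, 0.03), 1.03^(-2.5))
  expect_error(discount_factor(1, -1.5))
})

test_that("stationary symptomatic share matches the two-macro-state closed form", {
  p <- base_params(mortality_monthly = 0)
  tm <- build_transition_model(p)
  # independent oracle: stationary distribution from the eigen decomposition
  ev <- eigen(t(unclass(tm)[1:4, 1:4]))
  i <- which.min(abs(ev$values - 1))
  pi_vec <- abs(Re(ev$vectors[, i]))
  pi_vec <- pi_vec / sum(pi_vec)
  expect_equal(sum(pi_vec[2:4]), 0.0244 / (0.0244 + 0.0054), tolerance = 1e-10)
  expect_equal(sum(pi_vec[2:4]), 0.818792, tolerance = 1e-6)
})

test_that("a fully-well cohort without relapse or death never moves", {
  p <- base_params(relapse_monthly = 0, mortality_monthly = 0)
  init <- structure(list(p_well = 1, p_mild = 0, p_moderate = 0, p_severe = 0,
                         program_cost = 0),
                    strategy = "internet", class = "cea_initial")
  trace <- run_cohort(init, build_transition_model(p), p)
  expect_true(all(trace$occupancy[, "well"] == 1))
  expect_true(all(trace$occupancy[, c("mild", "moderate", "severe", "dead")] == 0))
})

test_that("cumulative dropout matches the survival-product closed form", {
  # all-symptomatic cohort, no remission/relapse/death: the dropout counter
  # must equal 1 - (1 - h)^60 exactly
  p <- base_params(remission_monthly = 0, mortality_monthly = 0)
  init <- structure(list(p_well = 0, p_mild = 1, p_moderate = 0, p_severe = 0,
                         program_cost = 0),
                    strategy = "internet", class = "cea_initial")
  trace <- run_cohort(init, build_transition_model(p), p)
  h <- 0.00193
  expect_equal(trace$cum_dropout[61], 1 - (1 - h)^60, tolerance = 1e-12)
  expect_equal(trace$cum_dropout[61], 0.1094, tolerance = 1e-3)
  expect_true(all(diff(trace$cum_dropout) >= 0))
  expect_lte(max(trace$cum_dropout), 1)
})

test_that("cycle accruals price occupancy as specified", {
  p <- base_params()
  sev <- c(well = 0, mild = 0, moderate = 0, severe = 1, dead = 0)
  # hospitalization component on a fully severe cohort: 0.0178 * 1500
  a <- accrue_cycle(sev, 0, base_params(outpatient_monthly = 0))
  expect_equal(a[["cost"]], 0.0178 * 1500)   # 26.70
  expect_equal(accrue_cycle(sev, 0, p)[["cost"]], 231 + 26.70)
  expect_equal(accrue_cycle(sev, 0, p,
                            cea_settings(outpatient_scope = "moderate_severe"))[["cost"]],
               231 + 26.70)
  mild <- c(well = 0, mild = 1, moderate = 0, severe = 0, dead = 0)
  expect_equal(accrue_cycle(mild, 0, p,
                            cea_settings(outpatient_scope = "moderate_severe"))[["cost"]],
               0)

  well <- c(well = 1, mild = 0, moderate = 0, severe = 0, dead = 0)
  expect_equal(accrue_cycle(well, 0, p)[["qaly"]], 0.80 / 12)
  expect_equal(accrue_cycle(well, 0, p,
                            cea_settings(well_utility = "age"))[["qaly"]], 0.92 / 12)
  dead <- c(well = 0, mild = 0, moderate = 0, severe = 0, dead = 1)
  expect_equal(unname(accrue_cycle(dead, 0, p)), c(0, 0))
  # discounting applies through the cycle index
  expect_equal(accrue_cycle(well, 12, p)[["qaly"]], 0.80 / 12 / 1.03)
})

test_that("strategy evaluation is deterministic and respects bounds", {
  p <- base_params()
  o1 <- run_strategy("internet", p)
  o2 <- run_strategy("internet", p)
  expect_identical(o1$total_cost, o2$total_cost)
  expect_identical(o1$total_qaly, o2$total_qaly)
  expect_identical(o1$dropout_prob, o2$dropout_prob)
  # QALY ceiling: horizon-years times the maximum utility
  expect_lte(o1$total_qaly, 5 * 0.92)
  expect_gte(o1$total_qaly, 0)
  expect_gte(o1$total_cost, 0)
  expect_true(o1$dropout_prob >= 0 && o1$dropout_prob <= 1)
})

test_that("discounting only shrinks totals, with equality at rate zero", {
  p <- base_params()
  p0 <- base_params(discount_annual = 0)
  for (strat in c("internet", "in_person")) {
    disc <- run_strategy(strat, p, keep_trace = FALSE)
    undisc <- run_strategy(strat, p0, keep_trace = FALSE)
    expect_lt(disc$total_cost, undisc$total_cost)
    expect_lt(disc$total_qaly, undisc$total_qaly)
  }
})

test_that("an empty horizon leaves only the program cost", {
  p <- base_params(horizon_months = 0)
  o <- run_strategy("internet", p)
  expect_equal(o$total_cost, 0.753 * (189 * 0.0923 + 24))
  expect_equal(o$total_qaly, 0)
  expect_equal(o$dropout_prob, 0)
})

test_that("occupancy is conserved and school occupancy never exceeds it", {
  for (s in c(3, 17)) {
    p <- perturbed_params(s)
    tr <- run_strategy("internet", p)$trace
    expect_equal(unname(rowSums(tr$occupancy)), rep(1, 61), tolerance = 1e-10)
    expect_true(all(tr$school <= tr$occupancy + 1e-12))
    expect_true(all(diff(tr$cum_dropout) >= 0))
  }
})

test_that("equalising the arms makes the strategy outcomes identical", {
  eq <- equalised_params()
  oi <- run_strategy("internet", eq)
  op <- run_strategy("in_person", eq)
  expect_equal(oi$total_cost, op$total_cost, tolerance = 1e-12)
  expect_equal(oi$total_qaly, op$total_qaly, tolerance = 1e-12)
  expect_equal(oi$dropout_prob, op$dropout_prob, tolerance = 1e-12)
})

test_that("structural switches move the totals in the expected direction", {
  p <- base_params()
  base <- run_strategy("internet", p, keep_trace = FALSE)
  wider <- run_strategy("internet", p,
                        cea_settings(highint_cbt = "initial"), keep_trace = FALSE)
  expect_gt(wider$total_cost, base$total_cost)
  entries <- run_strategy("internet", p,
                          cea_settings(highint_cbt = "entries"), keep_trace = FALSE)
  expect_gt(entries$total_cost, wider$total_cost)
  narrower <- run_strategy("internet", p,
                           cea_settings(outpatient_scope = "moderate_severe"),
                           keep_trace = FALSE)
  expect_lt(narrower$total_cost, base$total_cost)
  no_trunc <- run_strategy("internet", p,
                           cea_settings(dropout_truncates = FALSE),
                           keep_trace = FALSE)
  expect_gt(no_trunc$total_cost, base$total_cost)
  expect_gt(no_trunc$total_qaly, base$total_qaly)
})
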