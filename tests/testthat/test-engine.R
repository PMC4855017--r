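test_that("discounting follows the annual compound form at cycle-start times", {
  expect_equal(discount_factor(0, 0.03), 1.0)
  expect_equal(discount_factor(1, 0.03), 1 / 1.03)
  expect_equal(discount_factor(10, 0.03), 1.03^-10)
  expect_equal(discount_factor(5, 0), 1.0)
})

test_that("annual treatment costs reproduce the printed cost arithmetic", {
  p <- base_params
  rani1 <- annual_treatment_cost(p, "ranibizumab", 1)
  expect_equal(rani1$drug_cost, 8 * 1523.8)
  expect_equal(rani1$total, 8 * (1523.8 + 41.3))
  expect_equal(annual_treatment_cost(p, "bevacizumab", 2)$drug_cost, 6 * 10.5)
  expect_equal(annual_treatment_cost(p, "pdt", 1)$drug_cost, 2.05 * (2539.7 + 238.1))
  # treatment stops after year 2; usual care never treats
  expect_equal(annual_treatment_cost(p, "ranibizumab", 3)$total, 0)
  expect_equal(annual_treatment_cost(p, "usual_care", 1)$total, 0)
})

test_that("cycle costs apply only to the living and track eligible-state occupancy", {
  p <- base_params
  expect_equal(cycle_costs(p, "bevacizumab", c(0, 0, 0, 0, 0, 1), 1), 0)

  # full cohort in the best state: no comorbidity cost component
  best <- cycle_costs(p, "usual_care", c(1, 0, 0, 0, 0, 0), 3)
  worst <- cycle_costs(p, "usual_care", c(0, 0, 0, 0, 1, 0), 3)
  expect_equal(worst - best, 0.25 * (3 + 23 + 77.9))
  expect_error(cycle_costs(p, "laser", c(1, 0, 0, 0, 0, 0), 1), "unknown strategy")
})

test_that("cycle QALYs weight occupancy by state utility", {
  u <- base_params$utilities
  expect_equal(cycle_qalys(u, c(1, 0, 0, 0, 0, 0), 0.25), 0.25 * 0.89)
  expect_equal(cycle_qalys(u, c(0, 0, 0, 0, 0, 1), 0.25), 0)
  expect_equal(cycle_qalys(u, c(rep(0.2, 5), 0), 0.25), 0.1595)
})

test_that("an immortal perfect-health year matches the closed-form annuity", {
  p0 <- analytic_params(discount = 0)
  tr0 <- run_cohort(p0, build_schedule(p0, "usual_care", "occult"))
  expect_equal(sum(tr0$disc_qaly), 1.0)

  p3 <- analytic_params(discount = 0.03)
  tr3 <- run_cohort(p3, build_schedule(p3, "usual_care", "occult"))
  annuity <- 0.25 * sum(1.03^(-c(0, 0.25, 0.5, 0.75)))
  expect_equal(sum(tr3$disc_qaly), annuity)
  expect_equal(sum(tr3$disc_qaly), 0.98901, tolerance = 1e-5)
  # discounted never exceeds undiscounted
  expect_lt(sum(tr3$disc_qaly), sum(tr3$qaly))
})

test_that("with frozen vision the trace reproduces the life-table survival curve", {
  p <- freeze_vision(base_params)
  tr <- run_cohort(p, build_schedule(p, "usual_care", "occult"))
  alive <- tr$occ_va1 + tr$occ_va2 + tr$occ_va3 + tr$occ_va4 + tr$occ_va5

  lt <- p$life_table
  ages <- floor(p$cohort$start_age + (tr$cycle - 1) * 0.25)
  surv_factors <- (1 - lt$qx[match(ages, lt$age)])^0.25
  expected <- c(1, cumprod(surv_factors))[seq_len(nrow(tr))]
  expect_equal(alive, expected, tolerance = 1e-12)
  # occupancy is conserved and death is monotone
  expect_equal(alive + tr$occ_dead, rep(1, nrow(tr)), tolerance = 1e-10)
  expect_true(all(diff(tr$occ_dead) >= -1e-15))
})

test_that("vision-years integrate occupancy above the acuity cutoff", {
  p <- analytic_params(init = c(0.5, 0, 0, 0, 0.5))
  p <- freeze_vision(p)
  tr <- run_cohort(p, build_schedule(p, "usual_care", "occult"))
  expect_equal(vision_years(tr), 0.5)
  expect_equal(vision_years(tr, cutoff = 5), 1.0)

  # full cohort below the cutoff
  p2 <- analytic_params(init = c(0, 0, 0, 0, 1))
  p2 <- freeze_vision(p2)
  expect_equal(vision_years(run_cohort(p2, build_schedule(p2, "usual_care", "occult"))), 0)
})

test_that("zero discounting, zero costs and utility shifts behave as expected", {
  p <- base_params
  p$cohort$discount_rate <- 0
  tr <- run_cohort(p, build_schedule(p, "pdt", "occult"))
  expect_equal(sum(tr$disc_cost), sum(tr$cost))
  expect_equal(sum(tr$disc_qaly), sum(tr$qaly))

  pz <- zero_costs(base_params)
  for (s in strategies()) {
    expect_equal(run_strategy(pz, s, "occult")$cost, 0)
  }

  base_q <- run_strategy(base_params, "usual_care", "occult")$qaly
  for (st in 1:5) {
    up <- set_parameter(base_params, paste0("utility:", st),
      min(get_parameter(base_params, paste0("utility:", st)) + 0.05, 1))
    up$utilities$high <- pmax(up$utilities$high, up$utilities$utility)
    expect_gte(run_strategy(up, "usual_care", "occult")$qaly, base_q)
  }
})

test_that("glance and trace bookkeeping agree", {
  p <- base_params
  tr <- run_cohort(p, build_schedule(p, "bevacizumab", "predominantly_classic"))
  g <- glance(tr)
  expect_equal(g$cost, sum(tr$disc_cost))
  expect_equal(g$qaly, sum(tr$disc_qaly))
  expect_equal(g$cost, tr$cum_disc_cost[nrow(tr)])
  expect_equal(g$strategy, "bevacizumab")
  # total person-time cannot exceed the horizon
  expect_lte(g$life_years, nrow(tr) * 0.25)
})
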