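# Independent rate-form oracle for the period->cycle conversion:
# cumulative P over the period corresponds to rate -ln(1-P); a quarter of
# the rate gives the per-cycle probability 1 - exp(-rate/4).
rate_form <- function(P, k = 4) 1 - exp(-(-log(1 - P)) / k)

test_that("period-to-cycle conversion matches the constant-rate oracle and inverts", {
  expect_equal(annual_to_cycle_prob(0, 4), 0)
  expect_equal(annual_to_cycle_prob(0.2310, 4), rate_form(0.2310))
  expect_equal(annual_to_cycle_prob(0.2310, 4), 0.06355649, tolerance = 1e-7)

  grid <- seq(0, 0.99, by = 0.015)
  expect_equal(annual_to_cycle_prob(grid, 4), rate_form(grid), tolerance = 1e-14)
  # compounding the cycle probability over the period recovers P
  expect_equal(1 - (1 - annual_to_cycle_prob(grid, 4))^4, grid, tolerance = 1e-12)

  expect_error(annual_to_cycle_prob(1, 4), "infinite rate")
  expect_error(annual_to_cycle_prob(-0.1, 4), "non-negative")
})

test_that("risk-ratio scaling multiplies, clamps at 1, and rejects negatives", {
  expect_equal(apply_risk_ratio(0.0192, 6.69), 0.128448)
  P <- c(0, 0.2, 0.99)
  expect_equal(apply_risk_ratio(P, 1.0), P)
  expect_warning(out <- apply_risk_ratio(0.6, 2.0), "clamping")
  expect_equal(out, 1.0)
  expect_error(apply_risk_ratio(0.5, -1), "non-negative")
})

test_that("arm outcomes follow the indirect-comparison chain", {
  p <- base_params
  expect_equal(
    unlist(derive_arm_outcomes(p, "usual_care", "occult", 1), use.names = FALSE),
    c(0.0217, 0.2283, 0.3261)
  )
  # ranibizumab vs PDT (predominantly classic): baseline x RR
  rani <- derive_arm_outcomes(p, "ranibizumab", "predominantly_classic", 1)
  expect_equal(rani$gain, 0.0566 * 7.2)
  expect_equal(rani$loss36, 0.2651 * 0.1)
  expect_equal(rani$loss6, 0)
  # bevacizumab chains the head-to-head RR onto ranibizumab
  bev <- derive_arm_outcomes(p, "bevacizumab", "predominantly_classic", 1)
  expect_equal(bev$gain, 0.0566 * 7.2 * 0.92)
  # minimally classic / occult use the usual-care comparator
  rani_mc <- derive_arm_outcomes(p, "ranibizumab", "minimally_classic", 1)
  expect_equal(rani_mc$gain, 0.0192 * 6.69)
  # beyond the trials every arm reverts to usual-care year-2 outcomes
  for (s in strategies()) {
    expect_equal(
      derive_arm_outcomes(p, s, "occult", 3),
      derive_arm_outcomes(p, "usual_care", "occult", 2)
    )
  }
  expect_error(derive_arm_outcomes(p, "aflibercept", "occult", 1), "unknown strategy")
})

test_that("cycle matrices move mass by band with death first and boundary folding", {
  id <- build_cycle_matrix(list(gain = 0, loss36 = 0, loss6 = 0), 0)
  expect_equal(id, diag(6))

  # gains from the best state fold back into staying put
  top <- build_cycle_matrix(list(gain = 0.3, loss36 = 0, loss6 = 0), 0)
  expect_equal(top[1, 1], 1)

  # hand-computed row from the middle state: survivors 0.98 split
  # (gain .1 -> state 2, stay .65, loss36 .2 -> state 4, loss6 .05 -> state 5)
  M <- build_cycle_matrix(list(gain = 0.1, loss36 = 0.2, loss6 = 0.05), 0.02)
  expect_equal(M[3, ], c(0, 0.098, 0.637, 0.196, 0.049, 0.02))
  # from the worst VA state both losses fold into staying
  expect_equal(M[5, 5], 0.98 * 0.9)
  expect_equal(rowSums(M), rep(1, 6))
  expect_equal(M[6, ], c(0, 0, 0, 0, 0, 1))

  expect_error(
    build_cycle_matrix(list(gain = 0.5, loss36 = 0.4, loss6 = 0.2), 0),
    "sum to more than 1"
  )
})

test_that("schedules are row-stochastic with the published period structure", {
  p <- base_params
  sched <- build_schedule(p, "ranibizumab", "occult")
  uc <- build_schedule(p, "usual_care", "occult")

  for (M in schedule_matrices(sched, c(1, 5, 9, 50, sched$n_cycles))) {
    expect_equal(rowSums(M), rep(1, 6), tolerance = 1e-12)
    expect_true(all(M >= 0))
  }
  # year 1 cycles share vision outcomes, as do year 2 and the extrapolation
  expect_equal(sched$period[1:4], rep(1L, 4))
  expect_equal(sched$period[5:8], rep(2L, 4))
  expect_true(all(sched$period[9:sched$n_cycles] == 3L))
  # extrapolation period: usual-care year-2 outcomes for every arm
  expect_equal(sched$vision[[3]]$cycle, uc$vision[[3]]$cycle)
  expect_equal(uc$vision[[2]]$cycle, uc$vision[[3]]$cycle)
  # usual care: cycles 5 and 41 share vision outcomes (year-2 values feed
  # the extrapolation) while mortality tracks age
  expect_equal(uc$vision[[uc$period[5]]]$cycle, uc$vision[[uc$period[41]]]$cycle)
  expect_false(uc$mortality[5] == uc$mortality[41])
  # terminal age is absorbing
  final <- schedule_matrices(sched, sched$n_cycles)[[1]]
  expect_equal(final[1:5, 6], rep(1, 5))

  p2 <- p
  p2$cohort$horizon_years <- 60
  expect_error(build_schedule(p2, "usual_care", "occult"), "exceeds the life table")
})

test_that("audit export lists every cycle transition", {
  p <- base_params
  p$cohort$horizon_years <- 2
  td <- tidy(build_schedule(p, "pdt", "occult"))
  expect_equal(nrow(td), 8 * 36)
  sums <- tapply(td$probability, list(td$cycle, td$from_state), sum)
  expect_equal(as.vector(sums), rep(1, 48), tolerance = 1e-12)
})

test_that("a higher severe-loss risk ratio never increases downstream QALYs", {
  p <- base_params
  base <- run_strategy(p, "bevacizumab", "occult")$qaly
  for (mult in c(1.2, 1.5, 2)) {
    p2 <- set_parameter(p, "rr:bev_vs_rani:loss6:1",
      get_parameter(p, "rr:bev_vs_rani:loss6:1")[1] * mult)
    expect_lte(run_strategy(p2, "bevacizumab", "occult")$qaly, base)
  }
})
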