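test_that("parameter addressing resolves, round-trips, and rejects unknowns", {
  p <- base_params
  ids <- c(
    "cohort:start_age", "utility:3", "cost:bevacizumab",
    "freq:bevacizumab:1", "rr:bev_vs_rani:gain:1",
    "vision:usual_care:occult:1:gain",
    "sae_cost:endophthalmitis:bevacizumab", "comorbidity_cost:fall"
  )
  for (id in ids) {
    cur <- get_parameter(p, id)[1]
    p2 <- set_parameter(p, id, cur * 0.9)
    expect_equal(get_parameter(p2, id)[1], cur * 0.9, label = id)
  }
  expect_error(set_parameter(p, "cost:aspirin", 1), "cannot resolve")
  expect_error(get_parameter(p, "nonsense"), "cannot resolve")
})

test_that("zero-width one-way ranges reproduce the base case exactly", {
  p <- base_params
  base <- get_parameter(p, "cost:bevacizumab")
  ow <- one_way(p, "cost:bevacizumab", base, base, "occult")
  expect_equal(ow$icer_low, ow$icer_base)
  expect_equal(ow$icer_high, ow$icer_base)
})

test_that("the ICER is monotone in the drug price", {
  ow <- one_way(base_params, "cost:bevacizumab", 7.9, 13.1, "occult")
  expect_lt(ow$icer_low, ow$icer_base)
  expect_gt(ow$icer_high, ow$icer_base)
})

test_that("one-way bounds violating invariants fail before running", {
  expect_error(
    one_way(base_params, "utility:1", 0.5, 1.4, "occult"),
    "out of \\[0,1\\]"
  )
  expect_error(one_way(base_params, "utility:1", 0.9, 0.5, "occult"), "low <= high")
})

test_that("an empty tornado is an empty report", {
  empty <- tornado_parameters(base_params)[0, ]
  tor <- run_tornado(base_params, "occult", parameters = empty)
  expect_equal(nrow(tor), 0)
  expect_true(all(c("parameter_id", "icer_low", "icer_high") %in% names(tor)))
})

test_that("degenerate initial state scenarios rerun the pipeline coherently", {
  p <- base_params
  sc <- scenario_initial_state(p, 2, p$cohort$start_age, "occult")
  q <- p
  q$cohort$init_dist <- c(0, 1, 0, 0, 0)
  expect_equal(
    sc$qaly[sc$strategy == "bevacizumab"],
    run_strategy(q, "bevacizumab", "occult")$qaly
  )
  expect_true(is.na(sc$icer_vs_reference[sc$strategy == "usual_care"]))

  # starting everyone blind removes most of the attainable benefit
  sc_blind <- scenario_initial_state(p, 5, p$cohort$start_age, "occult")
  base_icer <- icer_occ <- sc$icer_vs_reference[sc$strategy == "bevacizumab"]
  expect_gt(
    sc_blind$icer_vs_reference[sc_blind$strategy == "bevacizumab"],
    base_icer
  )
})

test_that("moment-matched samplers hit their first two moments", {
  set.seed(9)
  b <- amdcea:::rbeta_mom(10000, 0.89, 0.2)
  expect_true(all(b >= 0 & b <= 1))
  expect_equal(mean(b), 0.89, tolerance = 0.02)
  expect_equal(stats::sd(b), 0.2 * 0.89, tolerance = 0.05)

  ln <- amdcea:::rlnorm_mom(10000, 1523.8, 0.2)
  expect_true(all(ln > 0))
  expect_equal(mean(ln), 1523.8, tolerance = 0.02 * 1523.8)

  # degenerate cases collapse to the base value
  expect_equal(amdcea:::rbeta_mom(5, 0, 0.2), rep(0, 5))
  expect_equal(amdcea:::rlnorm_mom(5, 100, 0), rep(100, 5))
})

test_that("PSA draws are reproducible and degenerate SDs recover the base case", {
  p <- base_params
  d1 <- sample_psa_parameters(p, 3, seed = 5)
  d2 <- sample_psa_parameters(p, 3, seed = 5)
  expect_equal(d1[[2]]$vision$p, d2[[2]]$vision$p)
  expect_equal(d1[[3]]$unit_costs$unit_cost, d2[[3]]$unit_costs$unit_cost)

  psa0 <- run_psa(p, n = 1, seed = 3, lesion = "occult", sd_frac = 0)
  base <- purrr::map_dfr(strategies(), function(s) run_strategy(p, s, "occult"))
  expect_equal(psa0$cost, base$cost)
  expect_equal(psa0$qaly, base$qaly)
  expect_equal(psa0$delta_cost[psa0$strategy == "usual_care"], 0)
})

test_that("acceptability curves are proper probabilities with the right limits", {
  psa <- run_psa(base_params, n = 40, seed = 11, lesion = "occult")
  ceac <- compute_ceac(psa, wtp_grid = c(0, 5000, 7480, 1e9))
  sums <- tapply(ceac$probability, ceac$wtp, sum)
  expect_equal(as.vector(sums), rep(1, 4))

  # WTP 0: probability of being cheapest; WTP -> Inf: of having max QALYs
  wide_c <- tidyr::pivot_wider(psa[, c("draw", "strategy", "cost")],
    names_from = "strategy", values_from = "cost")
  cheapest <- table(factor(
    c("usual_care", "pdt", "ranibizumab", "bevacizumab")[
      max.col(-as.matrix(wide_c[strategies()]), ties.method = "first")],
    levels = strategies()
  )) / nrow(wide_c)
  at0 <- ceac[ceac$wtp == 0, ]
  expect_equal(at0$probability, as.vector(cheapest[at0$strategy]))

  wide_q <- tidyr::pivot_wider(psa[, c("draw", "strategy", "qaly")],
    names_from = "strategy", values_from = "qaly")
  maxq <- table(factor(
    strategies()[max.col(as.matrix(wide_q[strategies()]), ties.method = "first")],
    levels = strategies()
  )) / nrow(wide_q)
  atInf <- ceac[ceac$wtp == 1e9, ]
  expect_equal(atInf$probability, as.vector(maxq[atInf$strategy]))

  expect_error(compute_ceac(psa, wtp_grid = numeric(0)), "non-empty")

  # pairwise variant: reference probability is 0 against itself
  pw <- compute_ceac(psa, wtp_grid = 7480, pairwise = TRUE)
  expect_equal(pw$probability[pw$strategy == "usual_care"], 0)
})
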