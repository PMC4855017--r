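test_that("ICER arithmetic and flags follow the sign conventions", {
  uc <- tibble::tibble(cost = 8618.5, qaly = 3.97)
  bev <- tibble::tibble(cost = 9232.8, qaly = 4.46)
  out <- icer(uc, bev)
  expect_equal(out$icer, (9232.8 - 8618.5) / (4.46 - 3.97))
  expect_equal(out$icer, 1253.67, tolerance = 1e-4)
  expect_equal(out$flag, "ok")

  expect_equal(icer(uc, uc)$flag, "no_incremental_effect")
  expect_true(is.na(icer(uc, uc)$icer))

  dom <- icer(tibble::tibble(cost = 100, qaly = 1), tibble::tibble(cost = 50, qaly = 2))
  expect_equal(dom$flag, "dominant")
  expect_lt(dom$icer, 0)
})

test_that("net monetary benefit is the linear decision rule", {
  expect_equal(net_monetary_benefit(tibble::tibble(cost = 0, qaly = 1), 7480), 7480)
  bev_occ <- tibble::tibble(cost = 9227.8, qaly = 4.21)
  expect_equal(net_monetary_benefit(bev_occ, 7480), 7480 * 4.21 - 9227.8)
  expect_equal(net_monetary_benefit(bev_occ, 0), -9227.8)
})

test_that("published reference-case totals classify PDT as dominated", {
  tab <- tibble::tibble(
    strategy = c("usual_care", "pdt", "ranibizumab", "bevacizumab"),
    cost = c(8618.5, 18292.5, 29468.3, 9232.8),
    qaly = c(3.97, 4.19, 4.55, 4.46)
  )
  fr <- build_frontier(tab)
  expect_equal(fr$dominance[fr$strategy == "pdt"], "strictly dominated")
  expect_equal(fr$comment[fr$strategy == "pdt"], "Dominated")
  expect_equal(fr$comment[fr$strategy == "bevacizumab"], "Cost-effective")
  expect_equal(fr$comment[fr$strategy == "ranibizumab"], "Not cost-effective")
  # dominated strategies still carry their ICER versus the reference
  expect_equal(fr$icer_vs_reference[fr$strategy == "pdt"],
    (18292.5 - 8618.5) / (4.19 - 3.97))
})

test_that("degenerate frontiers resolve ties and collinearity", {
  two <- tibble::tibble(strategy = c("a", "b"), cost = c(10, 20), qaly = c(1, 1))
  fr <- build_frontier(two, reference = "a")
  expect_equal(fr$dominance, c("on-frontier", "strictly dominated"))

  # middle of three collinear-ish points with a steeper first segment
  tri <- tibble::tibble(
    strategy = c("a", "b", "c"),
    cost = c(0, 100, 120),
    qaly = c(0, 1, 2)
  )
  fr2 <- build_frontier(tri, reference = "a")
  expect_equal(fr2$dominance[2], "extendedly dominated")
  expect_equal(fr2$icer_frontier[3], 60)
})

test_that("frontier matches the gift-wrapping oracle on random instances", {
  set.seed(402)
  for (i in 1:200) {
    inst <- tibble::tibble(
      strategy = letters[1:4],
      cost = runif(4, 0, 1000),
      qaly = runif(4, 0, 5)
    )
    fr <- build_frontier(inst, reference = NULL)
    got <- which(fr$dominance == "on-frontier")
    expect_equal(got, oracle_frontier_idx(inst$cost, inst$qaly),
      label = paste("instance", i))

    # the max-NMB strategy at any threshold lies on the frontier
    for (w in c(0, 150, 1e6)) {
      best <- which.max(w * inst$qaly - inst$cost)
      expect_true(fr$dominance[best] == "on-frontier",
        label = paste("instance", i, "wtp", w))
    }
  }
})

test_that("adding a strictly dominated strategy leaves frontier ICERs unchanged", {
  set.seed(77)
  for (i in 1:50) {
    inst <- tibble::tibble(
      strategy = letters[1:4],
      cost = runif(4, 0, 1000),
      qaly = runif(4, 0, 5)
    )
    fr1 <- build_frontier(inst, reference = NULL)
    worst <- tibble::tibble(
      strategy = "z",
      cost = max(inst$cost) + 10,
      qaly = min(inst$qaly)
    )
    fr2 <- build_frontier(dplyr::bind_rows(inst, worst), reference = NULL)
    expect_equal(fr2$dominance[5], "strictly dominated")
    expect_equal(fr2$icer_frontier[1:4], fr1$icer_frontier)
  }
})
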