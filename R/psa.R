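#' Method-of-moments beta and lognormal samplers
#'
#' Probabilistic sensitivity analysis samples probabilities, proportions
#' and utilities from beta distributions and costs (and risk ratios, which
#' are positive and right-skewed) from lognormal distributions, each
#' parameterized by method of moments with mean equal to the base value and
#' standard deviation a fixed fraction of the mean (20% by default).
#'
#' When the implied beta variance is infeasible (mean too close to 0 or 1)
#' the SD is shrunk to 95% of its feasible maximum; a base value of exactly
#' 0 or 1 (or SD 0) degenerates to the base value.
#'
#' @param n Number of draws.
#' @param mean Base value (vectorized; recycled against `n` draws each).
#' @param sd_frac SD as a fraction of the mean.
#' @return Numeric vector of draws.
#' @keywords internal
rbeta_mom <- function(n, mean, sd_frac = 0.2) {
  if (mean <= 0 || mean >= 1 || sd_frac == 0) return(rep(mean, n))
  sd <- sd_frac * mean
  max_sd <- sqrt(mean * (1 - mean))
  if (sd >= max_sd) sd <- 0.95 * max_sd
  nu <- mean * (1 - mean) / sd^2 - 1
  rbeta(n, mean * nu, (1 - mean) * nu)
}

#' @rdname rbeta_mom
#' @keywords internal
rlnorm_mom <- function(n, mean, sd_frac = 0.2) {
  if (mean <= 0 || sd_frac == 0) return(rep(mean, n))
  sdlog2 <- log(1 + sd_frac^2)
  rlnorm(n, meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

sample_one_draw <- function(params, sd_frac) {
  p <- params
  p$vision$p <- vapply(params$vision$p, function(m) rbeta_mom(1, m, sd_frac), numeric(1))
  p$rr$rr <- vapply(params$rr$rr, function(m) rlnorm_mom(1, m, sd_frac), numeric(1))
  p$utilities$utility <- vapply(params$utilities$utility,
    function(m) rbeta_mom(1, m, sd_frac), numeric(1))
  # published ranges no longer bracket the draw; widen so validation
  # checks the structural invariants only
  p$utilities$low <- 0
  p$utilities$high <- 1
  p$unit_costs$unit_cost <- vapply(params$unit_costs$unit_cost,
    function(m) rlnorm_mom(1, m, sd_frac), numeric(1))
  p$unit_costs$low <- 0
  p$unit_costs$high <- Inf
  p$sae$annual_cost <- vapply(params$sae$annual_cost,
    function(m) rlnorm_mom(1, m, sd_frac), numeric(1))
  p$sae$prob <- vapply(params$sae$prob, function(m) rbeta_mom(1, m, sd_frac), numeric(1))
  p$comorbidity$annual_cost <- vapply(params$comorbidity$annual_cost,
    function(m) rlnorm_mom(1, m, sd_frac), numeric(1))
  p$comorbidity$prob <- vapply(params$comorbidity$prob,
    function(m) rbeta_mom(1, m, sd_frac), numeric(1))
  p
}

draw_is_valid <- function(p) {
  # cheap structural screen: outcome probabilities must remain a sub-simplex
  # and derived (RR-chained) cumulative probabilities must stay below 1 so
  # every arm's schedule is well defined
  key <- paste(p$vision$arm, p$vision$lesion, p$vision$year)
  if (any(tapply(p$vision$p, key, sum) > 1)) return(FALSE)
  ok <- TRUE
  suppressWarnings(
    for (lesion in lesion_types()) {
      for (strategy in c("ranibizumab", "bevacizumab")) {
        for (year in 1:2) {
          res <- tryCatch(
            derive_arm_outcomes(p, strategy, lesion, year),
            error = function(e) NULL
          )
          if (is.null(res)) ok <- FALSE
        }
      }
    }
  )
  ok
}

#' Sample parameter sets for probabilistic sensitivity analysis
#'
#' Draws `n` parameter sets: probabilities and utilities from
#' method-of-moments beta distributions, costs and risk ratios from
#' lognormal distributions, all with SD equal to `sd_frac` of the base
#' value (20% default; `sd_frac = 0` degenerates every distribution to the
#' base case). Utilities are drawn independently per state; draws that
#' invert the VA ordering are counted (attribute `ordering_violations`) but
#' not corrected. Draws whose outcome probabilities leave the model
#' undefined are regenerated (attribute `regenerated`).
#'
#' @param params Base `amd_params`.
#' @param n Number of draws.
#' @param seed Integer seed; fixed seed gives identical draws.
#' @param sd_frac SD as a fraction of the mean for every sampled quantity.
#' @return List of `n` `amd_params` objects with attributes
#'   `regenerated` and `ordering_violations`.
#' @export
sample_psa_parameters <- function(params, n, seed = 1L, sd_frac = 0.2) {
  stopifnot(n >= 1)
  set.seed(seed)
  regenerated <- 0L
  violations <- 0L
  draws <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      p <- sample_one_draw(params, sd_frac)
      if (draw_is_valid(p)) break
      regenerated <- regenerated + 1L
      if (regenerated > 100L * n) abort("PSA draw regeneration limit exceeded")
    }
    if (any(diff(p$utilities$utility) > 0)) violations <- violations + 1L
    draws[[i]] <- p
  }
  if (regenerated > 0) {
    message(regenerated, " PSA draw(s) regenerated (invalid outcome probabilities)")
  }
  if (violations > 0) {
    message(violations, " PSA draw(s) with non-monotone utilities (kept)")
  }
  structure(draws, regenerated = regenerated, ordering_violations = violations)
}

#' Run the probabilistic sensitivity analysis
#'
#' Second-order Monte-Carlo: for each sampled parameter set the schedules
#' are rebuilt and all four strategies rerun with the same draw (common
#' parameters across arms, so incremental quantities are coherent).
#'
#' @inheritParams sample_psa_parameters
#' @param lesion Lesion subtype.
#' @param reference Strategy used for incremental coordinates.
#' @return An `amd_psa` tibble: `draw`, `strategy`, `cost`, `qaly`,
#'   `delta_cost`, `delta_qaly` (versus the reference within the draw),
#'   with attributes `lesion`, `seed`, `wtp`.
#' @export
run_psa <- function(params, n = 1000, seed = 1L, lesion = "occult",
                    sd_frac = 0.2, reference = "usual_care") {
  match_lesion(lesion)
  draws <- sample_psa_parameters(params, n, seed = seed, sd_frac = sd_frac)
  res <- purrr::imap(draws, function(p, i) {
    one <- purrr::map_dfr(strategies(), function(s) run_strategy(p, s, lesion))
    one$draw <- i
    one
  }) |>
    dplyr::bind_rows()
  ref <- res |>
    dplyr::filter(.data$strategy == reference) |>
    dplyr::select("draw", ref_cost = "cost", ref_qaly = "qaly")
  out <- res |>
    dplyr::left_join(ref, by = "draw") |>
    dplyr::mutate(
      delta_cost = .data$cost - .data$ref_cost,
      delta_qaly = .data$qaly - .data$ref_qaly
    ) |>
    dplyr::select("draw", "strategy", "cost", "qaly", "delta_cost", "delta_qaly")
  structure(out, class = c("amd_psa", class(out)),
    lesion = lesion, seed = seed, reference = reference,
    wtp = params$cohort$wtp,
    regenerated = attr(draws, "regenerated"),
    ordering_violations = attr(draws, "ordering_violations"))
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value, the probability (share of PSA draws)
#' that each strategy has the greatest net monetary benefit of the four
#' (`pairwise = FALSE`, probabilities sum to 1 at every WTP), or — with
#' `pairwise = TRUE` — the probability that each strategy's NMB exceeds the
#' reference strategy's.
#'
#' @param psa An `amd_psa` from [run_psa()].
#' @param wtp_grid Willingness-to-pay grid in US$/QALY (default 0-30,000 in
#'   steps of 250, spanning 1x and 3x per-capita GDP).
#' @param pairwise Compare each strategy against the reference instead of
#'   best-of-all.
#' @return An `amd_ceac` tibble: `wtp`, `strategy`, `probability`.
#' @export
compute_ceac <- function(psa, wtp_grid = seq(0, 30000, by = 250),
                         pairwise = FALSE) {
  if (length(wtp_grid) == 0) abort("WTP grid must be non-empty")
  strat <- unique(psa$strategy)
  wide_q <- psa |>
    dplyr::select("draw", "strategy", "qaly") |>
    tidyr::pivot_wider(names_from = "strategy", values_from = "qaly")
  wide_c <- psa |>
    dplyr::select("draw", "strategy", "cost") |>
    tidyr::pivot_wider(names_from = "strategy", values_from = "cost")
  Q <- as.matrix(wide_q[strat])
  C <- as.matrix(wide_c[strat])
  ref <- attr(psa, "reference") %||% "usual_care"

  out <- purrr::map_dfr(wtp_grid, function(w) {
    nmb <- w * Q - C
    if (pairwise) {
      pr <- colMeans(nmb > nmb[, ref])
    } else {
      best <- max.col(nmb, ties.method = "first")
      pr <- vapply(seq_along(strat), function(j) mean(best == j), numeric(1))
      names(pr) <- strat
    }
    tibble::tibble(wtp = w, strategy = strat, probability = as.numeric(pr[strat]))
  })
  structure(out, class = c("amd_ceac", class(out)),
    pairwise = pairwise, reference = ref)
}

#' Probability a strategy is cost-effective versus a reference
#'
#' Share of PSA draws in which the strategy's net monetary benefit at the
#' given willingness-to-pay exceeds the reference strategy's — i.e. the
#' draw-level decision "adopt over the reference at this threshold"
#' (equivalently, ICER below the threshold or dominance).
#'
#' @inheritParams compute_ceac
#' @param strategy Strategy of interest.
#' @param wtp Willingness to pay (default: the threshold the PSA was run
#'   with).
#' @param reference Comparator strategy.
#' @return Proportion in `[0, 1]`.
#' @export
prob_cost_effective <- function(psa, strategy = "bevacizumab",
                                wtp = attr(psa, "wtp"),
                                reference = attr(psa, "reference") %||% "usual_care") {
  s <- psa[psa$strategy == strategy, ]
  r <- psa[psa$strategy == reference, ]
  s <- s[order(s$draw), ]
  r <- r[order(r$draw), ]
  mean(wtp * s$qaly - s$cost > wtp * r$qaly - r$cost)
}
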