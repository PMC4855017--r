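#' Gompertz-Makeham life-table specification
#'
#' The model needs an age-indexed annual mortality table. Real national
#' life tables can be supplied as CSV ([read_life_table()]); for
#' self-contained runs and testing a synthetic table is generated from a
#' Gompertz-Makeham hazard \eqn{\mu(x) = \lambda + a e^{bx}}: a constant
#' background risk plus an exponentially age-increasing senescent component,
#' the standard two-parameter description of adult human mortality.
#'
#' The default (`lambda = 5e-4`, `a = 4.83e-5`, `b = 0.09`, ages 40-105) is
#' calibrated so that residual life expectancy at age 73.6 is about 12
#' years, plausible for the elderly Chinese population around 2011.
#'
#' @param lambda Makeham (age-independent) hazard, `>= 0` per year.
#' @param a Gompertz scale, `> 0`.
#' @param b Gompertz shape (log-hazard slope per year of age), `> 0`.
#' @param start_age,terminal_age Integer age range of the table; the
#'   terminal age is made absorbing (`qx = 1`).
#' @return A `gompertz_makeham_spec` list.
#' @export
gompertz_makeham_spec <- function(lambda = 5e-4, a = 4.83e-5, b = 0.09,
                                  start_age = 40L, terminal_age = 105L) {
  if (lambda < 0 || a <= 0 || b <= 0) {
    abort("Gompertz-Makeham parameters must satisfy lambda >= 0, a > 0, b > 0")
  }
  if (terminal_age <= start_age) abort("terminal_age must exceed start_age")
  structure(
    list(lambda = lambda, a = a, b = b,
      start_age = as.integer(start_age),
      terminal_age = as.integer(terminal_age)),
    class = "gompertz_makeham_spec"
  )
}

#' Generate a synthetic life table
#'
#' Annual death probabilities from a [gompertz_makeham_spec()]:
#' `qx = 1 - exp(-(lambda + a * exp(b * age)))`, clipped to `[0, 1]`, with
#' the terminal age forced absorbing.
#'
#' @param spec A `gompertz_makeham_spec`.
#' @return Life-table tibble with columns `age`, `qx`.
#' @export
#' @examples
#' lt <- generate_life_table(gompertz_makeham_spec())
#' head(lt)
generate_life_table <- function(spec = gompertz_makeham_spec()) {
  ages <- spec$start_age:spec$terminal_age
  hazard <- spec$lambda + spec$a * exp(spec$b * ages)
  qx <- pmin(pmax(1 - exp(-hazard), 0), 1)
  qx[length(qx)] <- 1
  tibble::tibble(age = as.integer(ages), qx = qx)
}

#' Generate a random but valid parameter set
#'
#' Draws every model input from wide but invariant-respecting ranges:
#' outcome probabilities from a Dirichlet-like construction keeping their
#' sum below 1, risk ratios log-uniform, costs log-uniform around plausible
#' magnitudes, utilities sorted decreasing across VA states, and a random
#' Gompertz-Makeham life table. Intended for property-based testing of the
#' calibration, engine and economics layers; any returned set passes
#' [validate_parameters()] with zero errors.
#'
#' @param seed Integer seed; the same seed reproduces the same set.
#' @return An `amd_params` object.
#' @export
generate_parameter_set <- function(seed) {
  set.seed(seed)
  params <- amd_parameters(
    life_table = generate_life_table(gompertz_makeham_spec(
      lambda = runif(1, 1e-4, 2e-3),
      a = runif(1, 2e-5, 1e-4),
      b = runif(1, 0.07, 0.11)
    ))
  )

  # Outcome probabilities capped so that even the worst-case chained risk
  # ratios (two factors of at most 1.3) keep every derived arm's outcome
  # probabilities summing below 1: 0.55 * 1.3^2 < 0.93.
  rand_probs <- function(n_groups) {
    t(vapply(seq_len(n_groups), function(i) {
      raw <- runif(3, 0.005, 0.3)
      s <- sum(raw)
      if (s > 0.55) raw <- raw * 0.55 / s
      raw
    }, numeric(3)))
  }
  groups <- params$vision |>
    dplyr::distinct(.data$arm, .data$lesion, .data$year)
  pr <- rand_probs(nrow(groups))
  vis <- tidyr::expand_grid(groups,
    tibble::tibble(outcome = c("gain", "loss36", "loss6")))
  vis$p <- as.vector(t(pr))
  vis$low <- 0.8 * vis$p
  vis$high <- pmin(1.2 * vis$p, 1)
  params$vision <- vis

  # keep derived (RR-chained) probabilities inside [0,1]: modest RRs
  params$rr$rr <- exp(runif(nrow(params$rr), log(0.3), log(1.3)))
  params$rr$low <- 0.8 * params$rr$rr
  params$rr$high <- 1.2 * params$rr$rr

  u <- sort(runif(5, 0.2, 0.99), decreasing = TRUE)
  params$utilities$utility <- u
  params$utilities$low <- pmax(u - 0.05, 0)
  params$utilities$high <- pmin(u + 0.05, 1)

  params$unit_costs$unit_cost <- params$unit_costs$unit_cost *
    exp(runif(nrow(params$unit_costs), log(0.5), log(2)))
  params$unit_costs$low <- 0.8 * params$unit_costs$unit_cost
  params$unit_costs$high <- 1.2 * params$unit_costs$unit_cost

  params$sae$annual_cost <- params$sae$annual_cost *
    exp(runif(nrow(params$sae), log(0.5), log(2)))
  params$comorbidity$annual_cost <- params$comorbidity$annual_cost *
    exp(runif(nrow(params$comorbidity), log(0.5), log(2)))

  params$cohort$start_age <- runif(1, 55, 85)
  params$cohort$discount_rate <- runif(1, 0, 0.05)
  d <- runif(5)
  params$cohort$init_dist <- d / sum(d)
  params
}

#' Individual-level microsimulation of a schedule
#'
#' First-order Monte-Carlo cross-check of the cohort engine: `n`
#' individuals start in states sampled from the initial distribution and
#' walk the same per-cycle transition matrices, with costs and QALYs
#' accrued per individual by the same cycle-start accrual and discounting
#' rules as [run_cohort()]. Because each individual's accrual is the
#' cohort formula evaluated at a degenerate occupancy vector, the
#' microsimulation mean converges to the cohort result.
#'
#' @param schedule An `amd_schedule`.
#' @param params The `amd_params` the schedule was built from.
#' @param n_individuals Number of simulated patients.
#' @param seed Integer seed.
#' @return One-row tibble: `strategy`, `lesion`, `n`, mean `cost` and
#'   `qaly` (discounted), their standard errors `cost_se`, `qaly_se`, and
#'   mean `vision_years`.
#' @export
microsim_oracle <- function(schedule, params, n_individuals, seed = 1L) {
  stopifnot(n_individuals >= 1)
  set.seed(seed)
  ch <- params$cohort
  cl <- ch$cycle_length
  cpy <- as.integer(round(1 / cl))
  u <- c(params$utilities$utility[order(params$utilities$state)], 0)

  fu_annual <- annual_followup_cost(params)
  cm_annual <- annual_comorbidity_cost(params)
  years_needed <- ((schedule$n_cycles - 1L) %/% cpy) + 1L
  active_years <- seq_len(min(years_needed, ch$treatment_years))
  treat_by_year <- sae_by_year <- numeric(years_needed)
  treat_by_year[active_years] <- vapply(active_years, function(y) {
    annual_treatment_cost(params, schedule$strategy, y)$total
  }, numeric(1))
  sae_by_year[active_years] <- annual_sae_cost(params, schedule$strategy)
  in_cm_state <- seq_len(6) %in% ch$comorbidity_states

  n <- as.integer(n_individuals)
  state <- sample.int(5L, n, replace = TRUE, prob = ch$init_dist)
  tot_cost <- tot_qaly <- tot_vy <- numeric(n)

  # cumulative transition rows per period for survivor vision moves
  vis_cum <- lapply(schedule$vision, function(v) {
    cm <- t(apply(v$V, 1, cumsum))
    cm[, 5] <- 1 # guard against floating-point shortfall in the last band
    cm
  })

  for (k in seq_len(schedule$n_cycles)) {
    alive <- state != 6L
    if (!any(alive)) break
    year_idx <- ((k - 1L) %/% cpy) + 1L
    disc <- discount_factor((k - 1L) * cl, ch$discount_rate)

    per_head <- cl * (treat_by_year[year_idx] + sae_by_year[year_idx] + fu_annual)
    cyc_cost <- ifelse(alive, per_head + cl * cm_annual * in_cm_state[state], 0)
    tot_cost <- tot_cost + disc * cyc_cost
    tot_qaly <- tot_qaly + disc * cl * u[state]
    tot_vy <- tot_vy + cl * (alive & state <= ch$vision_cutoff)

    m <- schedule$mortality[k]
    idx <- which(alive)
    dies <- runif(length(idx)) < m
    state[idx[dies]] <- 6L
    surv <- idx[!dies]
    if (length(surv) > 0) {
      cm <- vis_cum[[schedule$period[k]]]
      r <- runif(length(surv))
      rows <- cm[state[surv], , drop = FALSE]
      state[surv] <- max.col(rows >= r, ties.method = "first")
    }
  }

  tibble::tibble(
    strategy = schedule$strategy, lesion = schedule$lesion, n = n,
    cost = mean(tot_cost), cost_se = stats::sd(tot_cost) / sqrt(n),
    qaly = mean(tot_qaly), qaly_se = stats::sd(tot_qaly) / sqrt(n),
    vision_years = mean(tot_vy)
  )
}
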