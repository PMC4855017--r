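#' Discount factor at a point in model time
#'
#' @param t Time since model start, in years.
#' @param annual_rate Annual discount rate (proportion, e.g. 0.03).
#' @return `(1 + annual_rate)^(-t)`.
#' @export
#' @examples
#' discount_factor(10, 0.03) # 0.744094
discount_factor <- function(t, annual_rate) {
  stopifnot(all(t >= 0), annual_rate >= 0)
  (1 + annual_rate)^(-t)
}

#' Annual treatment-cost components for an active arm
#'
#' The annual drug-acquisition and administration cost of a strategy in a
#' trial year: per-administration price times the average number of
#' administrations that year. For PDT an administration is one verteporfin
#' infusion plus laser activation; for the anti-VEGF arms one drug dose plus
#' one intravitreal injection procedure. Usual care has no treatment cost.
#'
#' @inheritParams derive_arm_outcomes
#' @param year Trial year (1 or 2); active treatment stops after year 2.
#' @return One-row tibble with `n_admin`, `drug_cost` (drug/verteporfin plus
#'   laser where applicable), `procedure_cost` (injection fee) and `total`,
#'   all annual US$.
#' @export
#' @examples
#' annual_treatment_cost(amd_parameters(), "ranibizumab", 1)
annual_treatment_cost <- function(params, strategy, year) {
  match_strategy(strategy)
  if (strategy == "usual_care" || year > params$cohort$treatment_years) {
    return(tibble::new_tibble(
      list(n_admin = 0, drug_cost = 0, procedure_cost = 0, total = 0),
      nrow = 1L
    ))
  }
  unit <- function(item) {
    params$unit_costs$unit_cost[params$unit_costs$item == item]
  }
  freq <- params$treatment_freq |>
    dplyr::filter(.data$strategy == !!strategy, .data$year == !!year)
  if (nrow(freq) != 1) abort(paste0("no treatment frequency for ", strategy, " year ", year))
  n <- freq$n
  if (strategy == "pdt") {
    drug <- n * (unit("verteporfin") + unit("laser"))
    proc <- 0
  } else {
    drug <- n * unit(strategy)
    proc <- n * unit("injection")
  }
  tibble::tibble(n_admin = n, drug_cost = drug, procedure_cost = proc,
    total = drug + proc)
}

annual_followup_cost <- function(params) {
  fu <- dplyr::left_join(params$followup, params$unit_costs, by = "item")
  sum(fu$per_year * fu$unit_cost)
}

annual_sae_cost <- function(params, strategy) {
  if (!strategy %in% c("ranibizumab", "bevacizumab")) return(0)
  sum(params$sae$annual_cost[params$sae$arm == strategy])
}

annual_comorbidity_cost <- function(params) {
  sum(params$comorbidity$annual_cost)
}

#' Cost accrued by the cohort in one cycle
#'
#' Sums, per cycle and weighted by living occupancy: a quarter of the
#' annual treatment cost for the arm and trial year (zero after year 2), the
#' routine follow-up costs (consultation, OCT, fluorescein angiography), a
#' quarter of the annual serious-adverse-event cost (anti-VEGF arms during
#' the treatment years), and a quarter of the annual comorbidity cost
#' (depression, falls, assisted living) weighted by occupancy of the
#' low-vision states configured in `cohort$comorbidity_states`.
#'
#' @inheritParams derive_arm_outcomes
#' @param state_occupancy Length-6 occupancy vector at cycle start.
#' @param year_index Model year the cycle belongs to (1-based).
#' @return Cost in US$ for the cycle (undiscounted).
#' @export
cycle_costs <- function(params, strategy, state_occupancy, year_index) {
  match_strategy(strategy)
  stopifnot(length(state_occupancy) == n_states(), year_index >= 1)
  cl <- params$cohort$cycle_length
  alive <- sum(state_occupancy[1:5])
  if (alive <= 0) return(0)

  treat <- annual_treatment_cost(params, strategy, year_index)$total
  sae <- if (year_index <= params$cohort$treatment_years) {
    annual_sae_cost(params, strategy)
  } else {
    0
  }
  fu <- annual_followup_cost(params)
  comorb_occ <- sum(state_occupancy[params$cohort$comorbidity_states])
  cl * ((treat + sae + fu) * alive + annual_comorbidity_cost(params) * comorb_occ)
}

#' Quality-adjusted life-years accrued in one cycle
#'
#' @param utilities Tibble with columns `state` (1-5) and `utility`.
#' @param state_occupancy Length-6 occupancy vector; the dead state
#'   contributes zero.
#' @param cycle_length Cycle length in years.
#' @return Undiscounted QALYs for the cycle.
#' @export
#' @examples
#' cycle_qalys(amd_parameters()$utilities, c(1, 0, 0, 0, 0, 0), 0.25) # 0.2225
cycle_qalys <- function(utilities, state_occupancy, cycle_length) {
  stopifnot(length(state_occupancy) == n_states())
  u <- utilities$utility[order(utilities$state)]
  cycle_length * sum(state_occupancy[1:5] * u)
}

#' Run the Markov cohort simulation
#'
#' Evolves the cohort occupancy through the transition schedule,
#' accruing costs and QALYs at the start of each cycle (no half-cycle
#' correction by default) and discounting both at the annual rate from the
#' cohort settings, evaluated at cycle-start time. The run stops when the
#' schedule ends or the cohort is (numerically) extinct.
#'
#' With `cohort$half_cycle_correction = TRUE`, accrual uses the average of
#' the start- and end-of-cycle occupancy instead.
#'
#' @inheritParams derive_arm_outcomes
#' @param schedule An `amd_schedule` built from the same parameter set.
#' @return An `amd_trace`: a tibble with one row per cycle (`cycle`, `age`,
#'   occupancy `occ_va1`..`occ_dead`, `cost`, `qaly`, `disc_cost`,
#'   `disc_qaly`, cumulative discounted totals) carrying the strategy/lesion
#'   as attributes.
#' @export
run_cohort <- function(params, schedule) {
  if (!inherits(schedule, "amd_schedule")) abort("schedule must come from build_schedule()")
  if (abs(schedule$start_age - params$cohort$start_age) > 1e-9 ||
    abs(schedule$cycle_length - params$cohort$cycle_length) > 1e-12) {
    abort("schedule and parameter set disagree on cohort settings")
  }
  ch <- params$cohort
  cl <- ch$cycle_length
  cpy <- as.integer(round(1 / cl))
  u <- params$utilities$utility[order(params$utilities$state)]

  # Per-year cost components are constant within a model year; precompute.
  years_needed <- ((schedule$n_cycles - 1L) %/% cpy) + 1L
  fu_annual <- annual_followup_cost(params)
  cm_annual <- annual_comorbidity_cost(params)
  active_years <- seq_len(min(years_needed, ch$treatment_years))
  treat_by_year <- sae_by_year <- numeric(years_needed)
  treat_by_year[active_years] <- vapply(active_years, function(y) {
    annual_treatment_cost(params, schedule$strategy, y)$total
  }, numeric(1))
  sae_by_year[active_years] <- annual_sae_cost(params, schedule$strategy)
  cm_states <- ch$comorbidity_states

  occ <- c(ch$init_dist, 0)
  n <- schedule$n_cycles
  occ_mat <- matrix(NA_real_, n, 6)
  cost <- qaly <- disc <- numeric(n)
  used <- 0L
  for (k in seq_len(n)) {
    p <- schedule$period[k]
    m <- schedule$mortality[k]
    year_idx <- ((k - 1L) %/% cpy) + 1L

    alive_occ <- occ[1:5]
    survivors <- (1 - m) * alive_occ
    occ_end <- c(as.vector(survivors %*% schedule$vision[[p]]$V),
      occ[6] + m * sum(alive_occ))

    acc <- if (isTRUE(ch$half_cycle_correction)) (occ + occ_end) / 2 else occ
    alive <- sum(acc[1:5])
    cost[k] <- cl * ((treat_by_year[year_idx] + sae_by_year[year_idx] + fu_annual) *
      alive + cm_annual * sum(acc[cm_states]))
    qaly[k] <- cl * sum(acc[1:5] * u)
    disc[k] <- discount_factor((k - 1L) * cl, ch$discount_rate)
    occ_mat[k, ] <- occ
    used <- k
    occ <- occ_end
    if (occ[6] >= 1 - 1e-9) break
  }
  idx <- seq_len(used)
  trace <- tibble::tibble(
    cycle = idx,
    age = schedule$start_age + (idx - 1L) * cl,
    occ_va1 = occ_mat[idx, 1], occ_va2 = occ_mat[idx, 2],
    occ_va3 = occ_mat[idx, 3], occ_va4 = occ_mat[idx, 4],
    occ_va5 = occ_mat[idx, 5], occ_dead = occ_mat[idx, 6],
    cost = cost[idx], qaly = qaly[idx],
    disc_cost = cost[idx] * disc[idx],
    disc_qaly = qaly[idx] * disc[idx]
  )
  trace$cum_disc_cost <- cumsum(trace$disc_cost)
  trace$cum_disc_qaly <- cumsum(trace$disc_qaly)
  structure(trace,
    class = c("amd_trace", class(trace)),
    strategy = schedule$strategy, lesion = schedule$lesion,
    final_occupancy = occ,
    cycle_length = cl,
    vision_cutoff = ch$vision_cutoff
  )
}

#' Undiscounted expected years with preserved vision
#'
#' "Vision-years": expected time spent with visual acuity better than the
#' cutoff band (default better than 20/200, i.e. states 1-3), computed from
#' the undiscounted state occupancy of a trace.
#'
#' @param trace An `amd_trace` from [run_cohort()].
#' @param cutoff Highest (worst) state index still counted as preserved
#'   vision; defaults to the value the trace was run with.
#' @return Years (numeric scalar).
#' @export
vision_years <- function(trace, cutoff = attr(trace, "vision_cutoff") %||% 3L) {
  occ_cols <- paste0("occ_va", seq_len(cutoff))
  cl <- attr(trace, "cycle_length") %||% 0.25
  sum(vapply(occ_cols, function(cn) sum(trace[[cn]]), numeric(1))) * cl
}

#' Totals of a cohort run
#'
#' @param x An `amd_trace`.
#' @param ... Unused.
#' @return `glance()`: one-row tibble with `strategy`, `lesion`, `cost`
#'   (total discounted US$), `qaly` (total discounted QALYs),
#'   `vision_years`, `life_years` (undiscounted) and `n_cycles`.
#' @method glance amd_trace
#' @export
glance.amd_trace <- function(x, ...) {
  alive <- x$occ_va1 + x$occ_va2 + x$occ_va3 + x$occ_va4 + x$occ_va5
  cl <- attr(x, "cycle_length") %||% 0.25
  tibble::tibble(
    strategy = attr(x, "strategy"),
    lesion = attr(x, "lesion"),
    cost = sum(x$disc_cost),
    qaly = sum(x$disc_qaly),
    vision_years = vision_years(x),
    life_years = sum(alive) * cl,
    n_cycles = nrow(x)
  )
}

#' Run one strategy end to end
#'
#' Convenience wrapper: builds the transition schedule and runs the cohort,
#' returning the discounted totals.
#'
#' @inheritParams derive_arm_outcomes
#' @return One-row tibble as [glance.amd_trace()].
#' @export
#' @examples
#' run_strategy(amd_parameters(), "bevacizumab", "occult")
run_strategy <- function(params, strategy, lesion) {
  glance(run_cohort(params, build_schedule(params, strategy, lesion)))
}

#' Export a trace as CSV
#'
#' @param trace An `amd_trace`.
#' @param path Output CSV path.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
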