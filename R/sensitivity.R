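#' Address a single model input by identifier
#'
#' One-way sensitivity analysis perturbs one input at a time; inputs are
#' addressed with colon-separated identifiers:
#'
#' * `cohort:<field>` — e.g. `cohort:start_age`, `cohort:horizon_years`,
#'   `cohort:discount_rate`
#' * `utility:<state>` — utility of VA state 1-5
#' * `cost:<item>` — a unit cost from the cost table (e.g.
#'   `cost:bevacizumab`, `cost:injection`)
#' * `freq:<strategy>:<year>` — annual number of administrations
#' * `rr:<comparison>:<outcome>:<year>` — a risk-ratio component
#'   (`rani_vs_pdt`, `rani_vs_uc`, `bev_vs_rani`; outcomes `gain`,
#'   `loss36`, `loss6`), applied across all lesion subtypes
#' * `vision:<arm>:<lesion>:<year>:<outcome>` — a cumulative trial
#'   probability
#' * `sae_cost:<event>:<arm>`, `comorbidity_cost:<condition>` — annual mean
#'   costs
#'
#' @param params An `amd_params` object.
#' @param id Parameter identifier (see above).
#' @param value New value.
#' @return `set_parameter()`: the modified `amd_params`;
#'   `get_parameter()`: the current value.
#' @export
#' @examples
#' p <- set_parameter(amd_parameters(), "cost:bevacizumab", 13.1)
#' get_parameter(p, "cost:bevacizumab")
set_parameter <- function(params, id, value) {
  parts <- strsplit(id, ":", fixed = TRUE)[[1]]
  bad <- function() abort(paste0("cannot resolve parameter id '", id, "'"))
  kind <- parts[1]

  if (kind == "cohort") {
    if (length(parts) != 2 || !parts[2] %in% names(params$cohort)) bad()
    params$cohort[[parts[2]]] <- value
  } else if (kind == "utility") {
    s <- suppressWarnings(as.integer(parts[2]))
    if (length(parts) != 2 || is.na(s) || !s %in% 1:5) bad()
    params$utilities$utility[params$utilities$state == s] <- value
  } else if (kind == "cost") {
    i <- which(params$unit_costs$item == parts[2])
    if (length(parts) != 2 || length(i) != 1) bad()
    params$unit_costs$unit_cost[i] <- value
  } else if (kind == "freq") {
    i <- which(params$treatment_freq$strategy == parts[2] &
      params$treatment_freq$year == as.numeric(parts[3]))
    if (length(parts) != 3 || length(i) != 1) bad()
    params$treatment_freq$n[i] <- value
  } else if (kind == "rr") {
    i <- which(params$rr$comparison == parts[2] &
      params$rr$outcome == parts[3] &
      params$rr$year == as.numeric(parts[4]))
    if (length(parts) != 4 || length(i) == 0) bad()
    params$rr$rr[i] <- value
  } else if (kind == "vision") {
    i <- which(params$vision$arm == parts[2] &
      params$vision$lesion == parts[3] &
      params$vision$year == as.numeric(parts[4]) &
      params$vision$outcome == parts[5])
    if (length(parts) != 5 || length(i) != 1) bad()
    params$vision$p[i] <- value
  } else if (kind == "sae_cost") {
    i <- which(params$sae$event == parts[2] & params$sae$arm == parts[3])
    if (length(parts) != 3 || length(i) != 1) bad()
    params$sae$annual_cost[i] <- value
  } else if (kind == "comorbidity_cost") {
    i <- which(params$comorbidity$condition == parts[2])
    if (length(parts) != 2 || length(i) != 1) bad()
    params$comorbidity$annual_cost[i] <- value
  } else {
    bad()
  }
  params
}

#' @rdname set_parameter
#' @export
get_parameter <- function(params, id) {
  parts <- strsplit(id, ":", fixed = TRUE)[[1]]
  kind <- parts[1]
  switch(kind,
    cohort = params$cohort[[parts[2]]],
    utility = params$utilities$utility[params$utilities$state == as.integer(parts[2])],
    cost = params$unit_costs$unit_cost[params$unit_costs$item == parts[2]],
    freq = params$treatment_freq$n[params$treatment_freq$strategy == parts[2] &
      params$treatment_freq$year == as.numeric(parts[3])],
    rr = unique(params$rr$rr[params$rr$comparison == parts[2] &
      params$rr$outcome == parts[3] &
      params$rr$year == as.numeric(parts[4])]),
    vision = params$vision$p[params$vision$arm == parts[2] &
      params$vision$lesion == parts[3] &
      params$vision$year == as.numeric(parts[4]) &
      params$vision$outcome == parts[5]],
    sae_cost = params$sae$annual_cost[params$sae$event == parts[2] &
      params$sae$arm == parts[3]],
    comorbidity_cost = params$comorbidity$annual_cost[
      params$comorbidity$condition == parts[2]],
    abort(paste0("cannot resolve parameter id '", id, "'"))
  )
}

icer_vs_reference <- function(params, lesion, strategy, reference) {
  a <- run_strategy(params, reference, lesion)
  b <- run_strategy(params, strategy, lesion)
  icer(a, b)$icer
}

#' One-way sensitivity analysis of a single input
#'
#' Re-runs the full pipeline (calibration, cohort simulation, incremental
#' analysis) twice with the addressed input set to its low and high bound,
#' everything else held at base, and reports the ICER of the target
#' strategy versus the reference at each bound alongside the base-case
#' ICER.
#'
#' @inheritParams set_parameter
#' @param low,high Bound values (`low <= high`).
#' @param lesion Lesion subtype to analyse.
#' @param strategy,reference ICER numerator/denominator strategies
#'   (defaults: bevacizumab vs usual care).
#' @return One-row tibble: `parameter_id`, `low`, `high`, `icer_low`,
#'   `icer_high`, `icer_base`.
#' @export
one_way <- function(params, id, low, high, lesion,
                    strategy = "bevacizumab", reference = "usual_care") {
  if (low > high) abort("one_way bounds must satisfy low <= high")
  at <- function(value) {
    p <- set_parameter(params, id, value)
    stop_if_invalid(p, where = paste0("one-way bound for '", id, "'"))
    icer_vs_reference(p, lesion, strategy, reference)
  }
  tibble::tibble(
    parameter_id = id, low = low, high = high,
    icer_low = at(low), icer_high = at(high),
    icer_base = icer_vs_reference(params, lesion, strategy, reference)
  )
}

#' Default tornado parameter list
#'
#' The inputs conventionally varied in the one-way analysis: starting age,
#' the bevacizumab-vs-ranibizumab risk-ratio components (at +/-20% of
#' base), the five state utilities over their published ranges, the
#' bevacizumab and intravitreal-injection unit costs, the injection
#' frequencies in years 1 and 2, and the time horizon (2 and 10 years
#' versus lifetime).
#'
#' @param params An `amd_params` object.
#' @return Tibble with columns `parameter_id`, `low`, `high`.
#' @export
tornado_parameters <- function(params) {
  u <- params$utilities
  rr_ids <- tidyr::expand_grid(outcome = c("gain", "loss36", "loss6"), year = 1:2)
  dplyr::bind_rows(
    tibble::tibble(parameter_id = "cohort:start_age", low = 55, high = 88),
    tibble::tibble(
      parameter_id = paste0("rr:bev_vs_rani:", rr_ids$outcome, ":", rr_ids$year),
      low = 0.8 * vapply(parameter_id, function(i) get_parameter(params, i)[1], numeric(1)),
      high = 1.2 * vapply(parameter_id, function(i) get_parameter(params, i)[1], numeric(1))
    ),
    tibble::tibble(
      parameter_id = paste0("utility:", u$state),
      low = u$low, high = u$high
    ),
    tibble::tibble(
      parameter_id = c("cost:bevacizumab", "cost:injection"),
      low = params$unit_costs$low[match(c("bevacizumab", "injection"), params$unit_costs$item)],
      high = params$unit_costs$high[match(c("bevacizumab", "injection"), params$unit_costs$item)]
    ),
    tibble::tibble(
      parameter_id = c("freq:bevacizumab:1", "freq:bevacizumab:2"),
      low = c(6, 4.5), high = c(12, 12)
    ),
    tibble::tibble(parameter_id = "cohort:horizon_years", low = 2, high = 10)
  )
}

#' Tornado (multi-parameter one-way) analysis
#'
#' Runs [one_way()] for each row of a parameter table (default
#' [tornado_parameters()]).
#'
#' @inheritParams one_way
#' @param parameters Tibble with `parameter_id`, `low`, `high`; an empty
#'   tibble yields an empty result.
#' @return An `amd_tornado` tibble: one row per parameter as [one_way()].
#' @export
run_tornado <- function(params, lesion, parameters = tornado_parameters(params),
                        strategy = "bevacizumab", reference = "usual_care") {
  out <- purrr::pmap(parameters, function(parameter_id, low, high) {
    one_way(params, parameter_id, low, high, lesion,
      strategy = strategy, reference = reference)
  }) |>
    dplyr::bind_rows()
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      parameter_id = character(), low = numeric(), high = numeric(),
      icer_low = numeric(), icer_high = numeric(), icer_base = numeric()
    )
  }
  structure(out, class = c("amd_tornado", class(out)),
    lesion = lesion, strategy = strategy, reference = reference)
}

#' Scenario analysis over initial VA state and starting age
#'
#' Sets the whole cohort to start in one VA state (degenerate initial
#' distribution) at a given age, reruns all four strategies, and reports
#' each active strategy's ICER versus the reference.
#'
#' @inheritParams one_way
#' @param state Initial VA state (1-5).
#' @param age Starting age in years (within the life-table range).
#' @return Tibble: `strategy`, `cost`, `qaly`, `vision_years`,
#'   `icer_vs_reference`.
#' @export
scenario_initial_state <- function(params, state, age, lesion,
                                   reference = "usual_care") {
  stopifnot(state %in% 1:5)
  init <- rep(0, 5)
  init[state] <- 1
  p <- params
  p$cohort$init_dist <- init
  p$cohort$start_age <- age
  stop_if_invalid(p, where = "scenario")
  res <- purrr::map_dfr(strategies(), function(s) run_strategy(p, s, lesion))
  ref <- res[res$strategy == reference, ]
  res$icer_vs_reference <- vapply(seq_len(nrow(res)), function(i) {
    if (res$strategy[i] == reference) NA_real_ else icer(ref, res[i, ])$icer
  }, numeric(1))
  res
}
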