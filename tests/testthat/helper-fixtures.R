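# Shared fixtures. The base parameter set is deterministic, so build it once.
base_params <- amd_parameters()

# Parameters for analytic engine checks: perfect utility, no background
# mortality until the (absorbing) terminal age, fixed 1-year horizon.
analytic_params <- function(discount = 0, horizon_years = 1,
                            init = c(1, 0, 0, 0, 0)) {
  p <- amd_parameters(
    life_table = tibble::tibble(age = 40:105, qx = c(rep(0, 65), 1))
  )
  p$utilities$utility <- rep(1, 5)
  p$utilities$low <- rep(0, 5)
  p$utilities$high <- rep(1, 5)
  p$cohort$discount_rate <- discount
  p$cohort$horizon_years <- horizon_years
  p$cohort$init_dist <- init
  p
}

# Freeze all vision change: every arm keeps its state (identity transitions).
freeze_vision <- function(p) {
  p$vision$p <- rep(0, nrow(p$vision))
  p$vision$low <- rep(0, nrow(p$vision))
  p$vision$high <- rep(0, nrow(p$vision))
  p$rr$rr <- rep(0, nrow(p$rr))
  p$rr$low <- rep(0, nrow(p$rr))
  p$rr$high <- rep(0, nrow(p$rr))
  p
}

zero_costs <- function(p) {
  p$unit_costs$unit_cost <- rep(0, nrow(p$unit_costs))
  p$unit_costs$low <- rep(0, nrow(p$unit_costs))
  p$unit_costs$high <- rep(0, nrow(p$unit_costs))
  p$sae$annual_cost <- rep(0, nrow(p$sae))
  p$comorbidity$annual_cost <- rep(0, nrow(p$comorbidity))
  p$comorbidity$unit_cost <- rep(0, nrow(p$comorbidity))
  p
}

# Independent efficiency-frontier oracle: gift-wrapping from the cheapest
# strategy, at each step following the smallest cost-per-QALY slope among
# strictly more effective strategies. Distinct from the iterative-deletion
# algorithm in build_frontier().
oracle_frontier_idx <- function(cost, qaly) {
  cur <- which.min(cost)
  front <- cur
  repeat {
    cand <- which(qaly > qaly[cur])
    if (length(cand) == 0) break
    slope <- (cost[cand] - cost[cur]) / (qaly[cand] - qaly[cur])
    cur <- cand[which.min(slope)]
    front <- c(front, cur)
  }
  sort(front)
}
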