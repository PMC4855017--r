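#' Convert a cumulative period probability to a per-cycle probability
#'
#' Assumes the event follows an exponential (constant-rate) process within
#' the period, so a cumulative probability `P` over a period split into
#' `cycles_in_period` equal cycles corresponds to a per-cycle probability
#' `1 - (1 - P)^(1/cycles_in_period)`. Compounding the result over the
#' period recovers `P` exactly.
#'
#' @param P Cumulative probability over the period, in `[0, 1)`.
#' @param cycles_in_period Number of equal cycles in the period (default 4,
#'   i.e. 3-month cycles in a year).
#' @return Per-cycle probability.
#' @export
#' @examples
#' annual_to_cycle_prob(0.2310, 4) # 0.06355
annual_to_cycle_prob <- function(P, cycles_in_period = 4) {
  if (any(P < 0)) abort("cumulative probability must be non-negative")
  if (any(P >= 1)) abort("cumulative probability of 1 implies an infinite rate")
  if (cycles_in_period < 1) abort("cycles_in_period must be >= 1")
  1 - (1 - P)^(1 / cycles_in_period)
}

#' Scale a cumulative probability by a risk ratio
#'
#' Indirect treatment comparison on the cumulative-probability scale: the
#' comparator's cumulative event probability is multiplied by the risk ratio
#' between the target and comparator arms. Products exceeding 1 are clamped
#' to 1 with a warning.
#'
#' @param P Cumulative probability in `[0, 1]`.
#' @param rr Risk ratio, `>= 0`.
#' @return Adjusted cumulative probability in `[0, 1]`.
#' @export
#' @examples
#' apply_risk_ratio(0.0192, 6.69) # 0.128448
apply_risk_ratio <- function(P, rr) {
  if (any(rr < 0)) abort("risk ratio must be non-negative")
  if (any(P < 0 | P > 1)) abort("probability must lie in [0,1]")
  out <- P * rr
  if (any(out > 1)) {
    warn("risk-ratio product exceeds 1; clamping to 1")
    out <- pmin(out, 1)
  }
  out
}

#' Cumulative vision outcomes for a strategy, lesion and trial year
#'
#' Usual care and PDT use their trial-reported cumulative probabilities
#' directly. Ranibizumab outcomes are derived indirectly: the comparator
#' baseline (PDT for predominantly classic lesions, usual care otherwise)
#' scaled by the ranibizumab-vs-comparator risk ratio. Bevacizumab chains
#' the bevacizumab-vs-ranibizumab risk ratio onto the derived ranibizumab
#' probabilities. For model years beyond 2 the usual-care year-2 outcomes
#' apply to every strategy (post-trial extrapolation).
#'
#' @param params An `amd_params` object.
#' @param strategy One of [strategies()].
#' @param lesion One of [lesion_types()].
#' @param year Model year (1, 2, or 3+ for the extrapolation period).
#' @return One-row tibble with columns `gain`, `loss36`, `loss6`
#'   (cumulative probabilities for the year).
#' @export
#' @examples
#' derive_arm_outcomes(amd_parameters(), "bevacizumab", "occult", 1)
derive_arm_outcomes <- function(params, strategy, lesion, year) {
  match_strategy(strategy)
  match_lesion(lesion)
  if (year >= 3) {
    strategy <- "usual_care"
    year <- 2
  }

  outcomes <- c("gain", "loss36", "loss6")
  base_probs <- function(arm) {
    v <- params$vision
    sel <- v$arm == arm & v$lesion == lesion & v$year == year
    setNames(v$p[sel][match(outcomes, v$outcome[sel])], outcomes)
  }
  rr_vals <- function(comparison) {
    r <- params$rr
    sel <- r$comparison == comparison & r$lesion == lesion & r$year == year
    setNames(r$rr[sel][match(outcomes, r$outcome[sel])], outcomes)
  }

  probs <- switch(strategy,
    usual_care = base_probs("usual_care"),
    pdt = base_probs("pdt"),
    ranibizumab = {
      if (lesion == "predominantly_classic") {
        apply_risk_ratio(base_probs("pdt"), rr_vals("rani_vs_pdt"))
      } else {
        apply_risk_ratio(base_probs("usual_care"), rr_vals("rani_vs_uc"))
      }
    },
    bevacizumab = {
      rani <- derive_arm_outcomes(params, "ranibizumab", lesion, year)
      apply_risk_ratio(
        c(gain = rani$gain, loss36 = rani$loss36, loss6 = rani$loss6),
        rr_vals("bev_vs_rani")
      )
    }
  )
  if (sum(probs) > 1) {
    abort(paste0(
      "derived cumulative outcome probabilities exceed 1 for ",
      strategy, "/", lesion, "/year ", year
    ))
  }
  tibble::new_tibble(
    list(gain = probs[["gain"]], loss36 = probs[["loss36"]], loss6 = probs[["loss6"]]),
    nrow = 1L
  )
}

#' Assemble one 6x6 cycle transition matrix
#'
#' Death is applied first: every living state loses mass `cycle_mortality`
#' to the absorbing dead state. Among survivors, a gain of more than 3
#' Snellen lines moves up one VA state, a loss of 3-6 lines moves down one,
#' a loss of more than 6 lines moves down two (each VA band spans roughly
#' one Snellen doubling, i.e. 3 lines). Moves past the best or worst state
#' are folded into the boundary state; the remaining mass stays put.
#'
#' @param cycle_probs One-row tibble or named list with per-cycle
#'   probabilities `gain`, `loss36`, `loss6`.
#' @param cycle_mortality Per-cycle probability of death.
#' @return A 6x6 row-stochastic matrix (rows/cols ordered as [va_states()]).
#' @export
build_cycle_matrix <- function(cycle_probs, cycle_mortality) {
  q_gain <- cycle_probs[["gain"]]
  q_l36 <- cycle_probs[["loss36"]]
  q_l6 <- cycle_probs[["loss6"]]
  stopifnot(
    q_gain >= 0, q_l36 >= 0, q_l6 >= 0,
    cycle_mortality >= 0, cycle_mortality <= 1
  )
  if (q_gain + q_l36 + q_l6 > 1) {
    abort("survivor outcome probabilities sum to more than 1")
  }
  V <- matrix(0, 5, 5)
  for (s in 1:5) {
    up <- max(s - 1L, 1L)
    down1 <- min(s + 1L, 5L)
    down2 <- min(s + 2L, 5L)
    V[s, up] <- V[s, up] + q_gain
    V[s, down1] <- V[s, down1] + q_l36
    V[s, down2] <- V[s, down2] + q_l6
    V[s, s] <- V[s, s] + 1 - q_gain - q_l36 - q_l6
  }
  M <- matrix(0, 6, 6)
  M[1:5, 1:5] <- (1 - cycle_mortality) * V
  M[1:5, 6] <- cycle_mortality
  M[6, 6] <- 1
  M
}

#' Build the full per-cycle transition schedule for one strategy
#'
#' Cycles 1-4 use the strategy's year-1 cumulative outcomes, cycles 5-8 its
#' year-2 outcomes, and every later cycle the usual-care year-2 outcomes
#' (post-trial extrapolation, identical for all strategies). Yearly
#' cumulative probabilities are converted to per-cycle probabilities with
#' [annual_to_cycle_prob()]. Age-specific mortality advances with cohort
#' age: the annual `qx` at `floor(current age)` is converted to a per-cycle
#' probability. The schedule runs to the terminal life-table age (where
#' `qx = 1` kills the cohort within its year) or to `horizon_years` when the
#' cohort specifies a truncated horizon.
#'
#' @inheritParams derive_arm_outcomes
#' @return An `amd_schedule` object: cycle-indexed mortality, period-indexed
#'   vision matrices, and accessors [schedule_matrices()] / [tidy()].
#' @export
build_schedule <- function(params, strategy, lesion) {
  match_strategy(strategy)
  match_lesion(lesion)
  ch <- params$cohort
  lt <- params$life_table
  cl <- ch$cycle_length
  cpy <- as.integer(round(1 / cl)) # cycles per year

  terminal_age <- max(lt$age)
  if (is.null(ch$horizon_years)) {
    # one cycle past the last fractional year so the cohort reaches the
    # absorbing terminal age (qx = 1)
    n_cycles <- as.integer(ceiling((terminal_age - ch$start_age) * cpy)) + 1L
  } else {
    n_cycles <- as.integer(round(ch$horizon_years * cpy))
    if (ch$start_age + n_cycles * cl > terminal_age + 1) {
      abort("horizon exceeds the life table's terminal age")
    }
  }
  if (n_cycles < 1L) abort("empty schedule: horizon shorter than one cycle")

  ages <- floor(ch$start_age + (seq_len(n_cycles) - 1L) * cl)
  qx <- lt$qx[match(ages, lt$age)]
  if (any(is.na(qx))) abort("cohort ages run outside the life table")
  mortality <- ifelse(qx >= 1, 1, 1 - (1 - qx)^cl)

  # Vision outcomes are piecewise-constant over three periods.
  periods <- pmin(((seq_len(n_cycles) - 1L) %/% cpy) + 1L, 3L)
  vision <- lapply(1:3, function(yr) {
    cum <- derive_arm_outcomes(params, strategy, lesion, yr)
    cyc <- lapply(cum, annual_to_cycle_prob, cycles_in_period = cpy)
    structure(
      list(cum = cum, cycle = tibble::as_tibble(cyc),
        V = build_cycle_matrix(cyc, 0)[1:5, 1:5]),
      names = c("cum", "cycle", "V")
    )
  })

  structure(
    list(
      strategy = strategy, lesion = lesion,
      start_age = ch$start_age, cycle_length = cl,
      n_cycles = n_cycles, period = periods,
      mortality = mortality, vision = vision
    ),
    class = "amd_schedule"
  )
}

#' @export
print.amd_schedule <- function(x, ...) {
  cat("<amd_schedule> ", x$strategy, " / ", x$lesion, ": ",
    x$n_cycles, " cycles of ", x$cycle_length, " y from age ",
    x$start_age, "\n",
    sep = ""
  )
  invisible(x)
}

#' Materialize the transition matrices of a schedule
#'
#' @param schedule An `amd_schedule` from [build_schedule()].
#' @param cycles Which cycles to materialize (default all).
#' @return A list of 6x6 row-stochastic matrices, one per requested cycle.
#' @export
schedule_matrices <- function(schedule, cycles = seq_len(schedule$n_cycles)) {
  lapply(cycles, function(k) {
    p <- schedule$period[k]
    build_cycle_matrix(schedule$vision[[p]]$cycle, schedule$mortality[k])
  })
}

#' Long-format audit export of a schedule
#' @param x An `amd_schedule`.
#' @param ... Unused.
#' @return Tibble with `cycle`, `from_state`, `to_state`, `probability`.
#' @method tidy amd_schedule
#' @export
tidy.amd_schedule <- function(x, ...) {
  mats <- schedule_matrices(x)
  purrr::imap_dfr(mats, function(M, k) {
    tibble::tibble(
      cycle = k,
      from_state = rep(1:6, times = 6),
      to_state = rep(1:6, each = 6),
      probability = as.vector(M)
    )
  })
}
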