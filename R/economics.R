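#' Incremental cost-effectiveness ratio between two strategy results
#'
#' `(cost_b - cost_a) / (qaly_b - qaly_a)`, i.e. the extra cost per extra
#' QALY of `b` over `a`. When the QALY difference is below `1e-9` the ratio
#' is undefined and flagged; when `b` is cheaper and more effective the
#' (negative) ratio is flagged `"dominant"`, and when costlier and less
#' effective `"dominated"`.
#'
#' @param a,b One-row tibbles with columns `cost` and `qaly` (e.g. from
#'   [run_strategy()]); `b` is compared against `a`.
#' @return One-row tibble with `icer` (NA when undefined), `delta_cost`,
#'   `delta_qaly` and `flag` (`"ok"`, `"dominant"`, `"dominated"`,
#'   `"no_incremental_effect"`).
#' @export
#' @examples
#' icer(
#'   tibble::tibble(cost = 8618.5, qaly = 3.97),
#'   tibble::tibble(cost = 9232.8, qaly = 4.46)
#' )
icer <- function(a, b) {
  dc <- b$cost - a$cost
  dq <- b$qaly - a$qaly
  if (abs(dq) < 1e-9) {
    return(tibble::tibble(icer = NA_real_, delta_cost = dc, delta_qaly = dq,
      flag = "no_incremental_effect"))
  }
  val <- dc / dq
  flag <- if (dc <= 0 && dq > 0) {
    "dominant"
  } else if (dc >= 0 && dq < 0) {
    "dominated"
  } else {
    "ok"
  }
  tibble::tibble(icer = val, delta_cost = dc, delta_qaly = dq, flag = flag)
}

#' Net monetary benefit
#'
#' `wtp * qaly - cost`: positive when the strategy's health gain, valued at
#' the willingness-to-pay threshold, exceeds its cost. Linear in `wtp`, so
#' the strategy with the greatest NMB at a threshold is the optimal choice
#' there.
#'
#' @param result One-row tibble (or data frame) with `cost` and `qaly`.
#' @param wtp Willingness to pay, US$ per QALY (`>= 0`); may be a vector.
#' @return Numeric NMB in US$ (vectorized over `wtp`).
#' @export
net_monetary_benefit <- function(result, wtp) {
  stopifnot(all(wtp >= 0))
  wtp * result$qaly - result$cost
}

#' Cost-effectiveness frontier with dominance classification
#'
#' Strategies that are costlier and no more effective than another are
#' strictly dominated. Among the rest, sorted by cost, strategies whose
#' incremental ICER is not strictly increasing along the frontier are
#' removed iteratively (extended dominance). On-frontier strategies carry
#' the pairwise frontier ICER; every strategy (dominated or not) carries an
#' ICER versus the reference strategy, since decision tables conventionally
#' print both.
#'
#' Verdict labels follow WHO GDP-multiple bands on the ICER versus the
#' reference: at most 1x per-capita GDP is `"Cost-effective"`, at most 3x is
#' `"Marginally cost-effective"`, above that `"Not cost-effective"`;
#' dominated strategies are labelled `"Dominated"`.
#'
#' @param results Tibble with columns `strategy`, `cost`, `qaly` (one row
#'   per strategy; extra columns are preserved).
#' @param reference Strategy name used for the ICER-vs-reference column
#'   (default `"usual_care"`; ignored with a warning when absent).
#' @param gdp Per-capita GDP used for the verdict bands (default 7480).
#' @return An `amd_frontier` tibble: input columns plus `dominance`
#'   (`"on-frontier"`, `"strictly dominated"`, `"extendedly dominated"`),
#'   `icer_frontier`, `icer_vs_reference` and `comment`.
#' @export
build_frontier <- function(results, reference = "usual_care", gdp = 7480) {
  if (nrow(results) < 2) abort("frontier needs at least two strategies")
  res <- tibble::as_tibble(results)
  n <- nrow(res)

  strict <- vapply(seq_len(n), function(i) {
    any(res$cost < res$cost[i] & res$qaly >= res$qaly[i])
  }, logical(1))

  cand <- which(!strict)
  cand <- cand[order(res$cost[cand], res$qaly[cand])]
  repeat {
    if (length(cand) <= 2) break
    ic <- diff(res$cost[cand]) / diff(res$qaly[cand])
    drop <- which(diff(ic) <= 0)
    if (length(drop) == 0) break
    cand <- cand[-(drop[1] + 1L)] # interior point with non-increasing ICER
  }

  dominance <- rep("on-frontier", n)
  dominance[strict] <- "strictly dominated"
  dominance[!strict & !(seq_len(n) %in% cand)] <- "extendedly dominated"

  icer_frontier <- rep(NA_real_, n)
  if (length(cand) >= 2) {
    icer_frontier[cand[-1]] <- diff(res$cost[cand]) / diff(res$qaly[cand])
  }

  icer_vs_ref <- rep(NA_real_, n)
  ref_i <- which(res$strategy == reference)
  if (length(ref_i) == 1) {
    for (i in setdiff(seq_len(n), ref_i)) {
      icer_vs_ref[i] <- icer(res[ref_i, ], res[i, ])$icer
    }
  } else if (!is.null(reference)) {
    warn(paste0("reference strategy '", reference, "' not present; skipping ICER vs reference"))
  }

  comment <- vapply(seq_len(n), function(i) {
    if (length(ref_i) == 1 && i == ref_i) return("Reference")
    if (dominance[i] != "on-frontier") return("Dominated")
    ic <- icer_vs_ref[i]
    if (is.na(ic)) return("On frontier")
    if (ic <= gdp) {
      "Cost-effective"
    } else if (ic <= 3 * gdp) {
      "Marginally cost-effective"
    } else {
      "Not cost-effective"
    }
  }, character(1))

  out <- res |>
    dplyr::mutate(
      dominance = dominance,
      icer_frontier = icer_frontier,
      icer_vs_reference = icer_vs_ref,
      comment = comment
    )
  structure(out, class = c("amd_frontier", class(out)),
    reference = reference, gdp = gdp)
}

#' Tidy a frontier back to a plain tibble
#' @param x An `amd_frontier`.
#' @param ... Unused.
#' @method tidy amd_frontier
#' @export
tidy.amd_frontier <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}
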