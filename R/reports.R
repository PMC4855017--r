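#' Base-case cost-utility report
#'
#' Runs all four strategies through the lifetime model for one or all
#' lesion subtypes and lays the results out as a reference-case decision
#' table: discounted lifetime cost, vision-years, QALYs, ICER versus usual
#' care and a dominance/threshold comment per strategy.
#'
#' @param params An `amd_params` object (default: packaged base case).
#' @param lesion A lesion subtype or `"all"`.
#' @return An `amd_base_case` tibble with one row per strategy and lesion:
#'   `lesion`, `strategy`, `cost`, `vision_years`, `qaly`, `dominance`,
#'   `icer_vs_reference`, `comment`.
#' @export
#' @examples
#' run_base_case(amd_parameters(), lesion = "occult")
run_base_case <- function(params = amd_parameters(), lesion = "all") {
  lesions <- if (identical(lesion, "all")) lesion_types() else match_lesion(lesion)
  out <- purrr::map_dfr(lesions, function(les) {
    res <- purrr::map_dfr(strategies(), function(s) run_strategy(params, s, les))
    fr <- build_frontier(
      res |> dplyr::select("strategy", "cost", "qaly", "vision_years"),
      reference = "usual_care", gdp = params$cohort$gdp_per_capita
    )
    tidy(fr) |>
      dplyr::mutate(lesion = les) |>
      dplyr::select("lesion", "strategy", "cost", "vision_years", "qaly",
        "dominance", "icer_vs_reference", "comment")
  })
  structure(out, class = c("amd_base_case", class(out)))
}

#' @export
print.amd_base_case <- function(x, ...) {
  cat("Lifetime reference-case results (discounted, 2012 US$)\n")
  df <- as.data.frame(x)
  df$cost <- round(df$cost, 1)
  df$vision_years <- round(df$vision_years, 2)
  df$qaly <- round(df$qaly, 2)
  df$icer_vs_reference <- round(df$icer_vs_reference)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write an analysis report to CSV and JSON
#'
#' @param x A result tibble (base case, tornado, PSA, CEAC...).
#' @param path Output path without extension; `<path>.csv` is always
#'   written, `<path>.json` additionally when `jsonlite` is installed.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(x, path) {
  written <- character(0)
  csv <- paste0(path, ".csv")
  utils::write.csv(as.data.frame(x), csv, row.names = FALSE)
  written <- csv
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    js <- paste0(path, ".json")
    jsonlite::write_json(as.data.frame(x), js, auto_unbox = TRUE, digits = NA)
    written <- c(written, js)
  }
  invisible(written)
}

#' Run manifest for reproducible reporting
#'
#' Records what produced a set of output files: config path, seed,
#' subcommand, package version, timestamp and the outputs themselves.
#'
#' @param subcommand Name of the analysis run.
#' @param config Path of the configuration used (or `"<packaged default>"`).
#' @param seed Seed used, if any.
#' @param outputs Character vector of files written.
#' @return A tibble (also suitable for `write.csv`).
#' @export
run_manifest <- function(subcommand, config, seed = NA_integer_, outputs = character()) {
  tibble::tibble(
    subcommand = subcommand,
    config = config,
    seed = seed,
    version = as.character(utils::packageVersion("amdcea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    output = if (length(outputs) == 0) NA_character_ else outputs
  )
}
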