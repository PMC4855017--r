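#' Health states of the visual-acuity Markov model
#'
#' The model tracks Snellen-chart visual acuity (VA) in the better-seeing eye
#' across five ordered bands — each band roughly one Snellen doubling, i.e.
#' about three chart lines — plus an absorbing death state. State 1 is the
#' best vision (better than 20/40), state 5 the worst (20/400 or less, light
#' perception only), state 6 is death.
#'
#' @return A tibble with columns `state` (integer 1-6), `code` (short
#'   identifier) and `label` (human-readable Snellen band).
#' @export
#' @examples
#' va_states()
va_states <- function() {
  tibble::tibble(
    state = 1:6,
    code  = c("va1", "va2", "va3", "va4", "va5", "dead"),
    label = c(
      ">20/40",
      "<=20/40 to >20/80",
      "<=20/80 to >20/200",
      "<=20/200 to >20/400",
      "<=20/400",
      "Dead"
    )
  )
}

#' @rdname va_states
#' @export
n_states <- function() 6L

#' @rdname va_states
#' @export
n_va_states <- function() 5L

#' Treatment strategies and lesion subtypes
#'
#' The four strategies compared by the model and the three angiographic
#' lesion subtypes of wet AMD the trials stratify on.
#'
#' @return Character vector of identifiers.
#' @export
strategies <- function() {
  c("usual_care", "pdt", "ranibizumab", "bevacizumab")
}

#' @rdname strategies
#' @export
lesion_types <- function() {
  c("predominantly_classic", "minimally_classic", "occult")
}

match_strategy <- function(strategy) {
  if (length(strategy) != 1L || !strategy %in% strategies()) {
    abort(paste0(
      "unknown strategy '", paste(strategy, collapse = ","),
      "'; must be one of: ", paste(strategies(), collapse = ", ")
    ))
  }
  strategy
}

match_lesion <- function(lesion) {
  if (length(lesion) != 1L || !lesion %in% lesion_types()) {
    abort(paste0(
      "unknown lesion type '", paste(lesion, collapse = ","),
      "'; must be one of: ", paste(lesion_types(), collapse = ", ")
    ))
  }
  lesion
}
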