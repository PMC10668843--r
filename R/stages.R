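#' The 27-stage porcine skeletal-muscle developmental registry
#'
#' The longissimus-dorsi time course covers 15 embryonic stages (days 33-105,
#' labels LE33-LE105) and 12 postnatal stages (days 0-180, labels LD0-LD180).
#' Each stage maps to one of four physiological states of muscle development:
#' primary myofiber formation (LE33-LE65), secondary myofiber formation
#' (LE70-LE105), myofiber-type transition (LD0-LD60) and fattening
#' (LD80-LD180).
#'
#' @return A data.frame with columns \code{stage} (ordered labels),
#'   \code{phase} (\code{"embryonic"}/\code{"postnatal"}) and \code{state}.
#' @examples
#' reg <- stageRegistry()
#' table(reg$state)
#' @export
stageRegistry <- function() {
  le <- c(33, 40, 45, 50, 55, 60, 65, 70, 75, 80, 85, 90, 95, 100, 105)
  ld <- c(0, 9, 20, 30, 40, 60, 80, 100, 120, 140, 160, 180)
  stage <- c(paste0("LE", le), paste0("LD", ld))
  phase <- c(rep("embryonic", length(le)), rep("postnatal", length(ld)))
  state <- c(
    ifelse(le <= 65, "primary_myofiber", "secondary_myofiber"),
    ifelse(ld <= 60, "fiber_type_transition", "fattening")
  )
  data.frame(stage = stage, phase = phase, state = state,
             stringsAsFactors = FALSE)
}

#' Developmental states in registry order
#' @return character(4) state names.
#' @export
developmentalStates <- function() {
  c("primary_myofiber", "secondary_myofiber", "fiber_type_transition",
    "fattening")
}
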