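#' Health states of the cohort model
#'
#' The model tracks a cohort of CIDP patients through treatment and
#' corticosteroid adverse-event (AE) states over 12-week cycles.  Conditions
#' that last a fixed time before resolution or discovery (first year after
#' fracture, diabetes or glaucoma onset; the cataract surgical wait; the
#' acute phase of a serious infection) are encoded as tunnel states.  Because
#' a cohort model is memoryless, each multi-cycle tunnel is expanded
#' internally into one sub-state per cycle of dwell time, and the time-on-
#' steroid cost schedule (first, second, subsequent cycles) is likewise
#' carried by three `STEROID_ON` sub-states.
#'
#' @return `model_states()` returns the character vector of expanded engine
#'   states, in transition-matrix order.  `state_groups()` returns a named
#'   character vector mapping each expanded state to its canonical state id
#'   (the 13 states a user sees in a trace).
#' @export
model_states <- function() {
  c("IVIG_INITIAL", "IVIG_RESPONDER",
    paste0("STEROID_ON_", 1:3),
    paste0("FRACTURE_Y1_", 1:4), "FRACTURE_POST",
    paste0("DIABETES_Y1_", 1:4), "DIABETES_POST",
    "CATARACT_WAIT", "CATARACT_POST",
    paste0("GLAUCOMA_Y1_", 1:4),
    "INFECTION_ACUTE", "OFF_TREATMENT", "DEAD")
}

#' @rdname model_states
#' @export
state_groups <- function() {
  s <- model_states()
  g <- s
  g[grepl("^STEROID_ON_", s)] <- "STEROID_ON"
  g[grepl("^FRACTURE_Y1_", s)] <- "FRACTURE_Y1"
  g[grepl("^DIABETES_Y1_", s)] <- "DIABETES_Y1"
  g[grepl("^GLAUCOMA_Y1_", s)] <- "GLAUCOMA_Y1"
  names(g) <- s
  g
}

#' @rdname model_states
#' @export
canonical_states <- function() unique(unname(state_groups()))

# number of 12-week cycles a first-year tunnel lasts (1 year ~ 4.33 cycles,
# truncated to whole cycles by the whole-cycle engine)
Y1_CYCLES <- 4L

# weeks per model cycle (fixed by the model design)
CYCLE_WEEKS <- 12
WEEKS_PER_YEAR <- 52
CYCLE_YEARS <- CYCLE_WEEKS / WEEKS_PER_YEAR

#' Aggregate an expanded-state occupancy vector or matrix to canonical states
#'
#' @param occ a numeric vector named by `model_states()`, or a matrix with
#'   those column names (one row per cycle).
#' @return the same object aggregated to `canonical_states()`.
#' @export
aggregate_states <- function(occ) {
  grp <- state_groups()
  if (is.matrix(occ)) {
    out <- sapply(canonical_states(), function(g)
      rowSums(occ[, grp[colnames(occ)] == g, drop = FALSE]))
    if (nrow(occ) == 1L) out <- matrix(out, nrow = 1L,
                                       dimnames = list(NULL, canonical_states()))
    out
  } else {
    tapply(occ, grp[names(occ)], sum)[canonical_states()]
  }
}
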