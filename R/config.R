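#' Run-level model configuration
#'
#' Captures everything about a model run that is not an evidence parameter:
#' the cohort's starting age and weight, the time horizon, the (fixed)
#' 12-week cycle length, the annual discount rate, the treatment arm, the
#' IVIG maintenance dosing scenario, and two structural switches used in
#' scenario analysis.
#'
#' @param start_age cohort age at entry, years (basecase 54).
#' @param weight patient weight in kg (basecase 75); IVIG dosing, and hence
#'   cost, scales with weight.
#' @param horizon_years model time horizon (basecase 5).
#' @param discount_rate_annual annual discount rate applied to both costs and
#'   QALYs (basecase 0.05).
#' @param arm `"IVIG"` or `"steroid"`.
#' @param maintenance_dose IVIG maintenance dose, grams per kg (basecase 1).
#' @param maintenance_interval weeks between maintenance administrations; 3,
#'   6 or 8 (an 8-week interval gives 1.5 administrations per 12-week cycle,
#'   the average of the alternating 1/2 schedule).
#' @param steroid_switch_to_ivig_after_ae scenario switch: corticosteroid
#'   patients start IVIG once an adverse event resolves or is discovered
#'   (applies to the steroid arm only).
#' @param relapse_extrapolation `"constant"` keeps the 6.5% 12-week relapse
#'   probability for the whole horizon; `"stop_after_25_weeks"` applies it
#'   only to the first two cycles (the span of the source trial).
#' @param half_cycle_correction accrue costs/QALYs on the mean of start- and
#'   end-of-cycle occupancy instead of full start-of-cycle membership.
#'   Off by default (the published model does not mention one).
#' @return a list of class `cidp_config`.
#' @export
model_config <- function(start_age = 54, weight = 75, horizon_years = 5,
                         discount_rate_annual = 0.05,
                         arm = c("IVIG", "steroid"),
                         maintenance_dose = 1.0, maintenance_interval = 3,
                         steroid_switch_to_ivig_after_ae = FALSE,
                         relapse_extrapolation = c("constant",
                                                   "stop_after_25_weeks"),
                         half_cycle_correction = FALSE) {
  arm <- match.arg(arm)
  relapse_extrapolation <- match.arg(relapse_extrapolation)
  stopifnot(horizon_years > 0, weight > 0, start_age > 0,
            discount_rate_annual >= 0, discount_rate_annual <= 1,
            maintenance_dose > 0)
  if (!maintenance_interval %in% c(3, 6, 8))
    stop("maintenance_interval must be 3, 6 or 8 weeks")
  cfg <- list(start_age = start_age, weight = weight,
              horizon_years = horizon_years,
              cycle_length_weeks = CYCLE_WEEKS,
              discount_rate_annual = discount_rate_annual, arm = arm,
              maintenance_dose = maintenance_dose,
              maintenance_interval = maintenance_interval,
              steroid_switch_to_ivig_after_ae =
                isTRUE(steroid_switch_to_ivig_after_ae),
              relapse_extrapolation = relapse_extrapolation,
              half_cycle_correction = isTRUE(half_cycle_correction))
  class(cfg) <- "cidp_config"
  cfg
}

#' Number of whole 12-week cycles in a horizon
#'
#' Horizons are run as whole cycles: `round(h * 52 / 12)` (22 cycles, 264
#' weeks, for the 5-year basecase).
#'
#' @param config a `cidp_config`.
#' @return integer cycle count.
#' @export
n_cycles <- function(config) {
  as.integer(round(config$horizon_years * WEEKS_PER_YEAR / CYCLE_WEEKS))
}

#' @export
print.cidp_config <- function(x, ...) {
  cat(sprintf(
    "<cidp_config> %s arm: age %g, %g kg, %g y (%d cycles), %g%%/y discount\n",
    x$arm, x$start_age, x$weight, x$horizon_years, n_cycles(x),
    100 * x$discount_rate_annual))
  cat(sprintf("  maintenance %g g/kg q%gw; relapse %s%s%s\n",
              x$maintenance_dose, x$maintenance_interval,
              x$relapse_extrapolation,
              if (x$steroid_switch_to_ivig_after_ae)
                "; steroid arm switches to IVIG after AE" else "",
              if (x$half_cycle_correction) "; half-cycle correction" else ""))
  invisible(x)
}
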