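#' Model parameter set
#'
#' `default_parameters()` builds the evidence bundle the basecase analysis
#' runs on: the pooled IVIG response probability, the 12-week IVIG relapse
#' probability, annual corticosteroid adverse-event (AE) probabilities,
#' age-banded general-population utilities, the IVIG utility increment,
#' per-AE disutilities / mortality increments / costs (age-banded for
#' fracture and diabetes, first year vs subsequent years), unit drug and
#' nursing costs, and the background life table.  All monetary values are
#' 2008 Canadian dollars.
#'
#' Age-banded tables are data frames whose `age_lo` column gives the lower
#' bound of each band; a value applies from its `age_lo` up to the next
#' band's `age_lo` (the last band is open-ended, and ages below the first
#' band use the first band).
#'
#' @param life_table optional `cidp_life_table`; defaults to the bundled
#'   synthetic fixture.
#' @return a list of class `cidp_parameters`.
#' @export
default_parameters <- function(life_table = make_default_life_table()) {
  p <- list(
    # treatment effectiveness
    response_rate    = 0.473,   # pooled initial IVIG response probability
    relapse_25wk     = 0.13,    # cumulative 25-week relapse probability (trial)
    relapse_per_cycle = 0.065,  # 12-week relapse probability (25-week halved)

    # annual probabilities of corticosteroid adverse events
    ae_annual = c(fracture = 0.0098, diabetes = 0.0043, cataract = 0.0114,
                  glaucoma = 0.0008, infection = 0.0035),

    # unisex general-population utility by age band (mean of female/male)
    utilities_by_age = data.frame(
      age_lo  = c(35, 45, 55, 65, 75),
      utility = c(0.91, 0.845, 0.795, 0.78, 0.73)),

    ivig_utility_gain = 0.12,   # additive utility while on effective IVIG

    # fracture / diabetes: first-year and subsequent-year values by age band
    fracture = data.frame(
      age_lo          = c(40, 45, 50, 55, 60, 65, 70),
      disutility_y1   = c(0.0833, 0.0971, 0.1047, 0.1068, 0.1094, 0.1113, 0.1212),
      disutility_post = c(0.0293, 0.0324, 0.0349, 0.0371, 0.0391, 0.0412, 0.0425),
      mortality_y1    = c(0.0092, 0.0115, 0.0127, 0.0142, 0.0187, 0.0260, 0.0541),
      mortality_post  = c(0.0001, 0.0001, 0.0001, 0.0002, 0.0003, 0.0006, 0.0018),
      cost_y1         = c(3926, 4643, 5041, 5159, 5302, 7901, 10880),
      cost_post       = c(63, 68, 73, 78, 83, 87, 744)),
    diabetes = data.frame(
      age_lo          = c(40, 45, 50, 55, 60, 65, 70),
      disutility_y1   = c(0.000179, 0.000173, 0.000160, 0.000074, 0.000040,
                          0.000003, 0.000128),
      disutility_post = c(0.000333, 0.000247, 0.000263, 0.000681, 0.000727,
                          0.000618, 0.000754),
      mortality_y1    = c(0.000390, 0.000715, 0.000875, 0.001160, 0.001525,
                          0.002025, 0.002645),
      mortality_post  = c(0.000320, 0.000285, 0.000685, 0.000320, 0.000755,
                          0.001035, 0.000850),
      cost_y1         = c(12, 13, 16, 21, 24, 25, 27),
      cost_post       = c(24, 32, 55, 93, 151, 260, 341)),

    # cataract, glaucoma, serious infection
    cataract_disutility_wait = 0.38,   # while waiting for surgery
    cataract_disutility_post = 0.10,   # after surgery
    cataract_wait_days       = 109,    # mapped to one 12-week cycle
    cataract_cost            = 6218,   # surgery, charged once
    glaucoma_disutility      = 0.061,
    glaucoma_cost            = 152,    # charged once at onset
    infection_cost           = 24334,  # acute episode, charged once
    infection_mortality_lt65 = 0.018,  # in-episode death probability, age < 65
    infection_mortality_ge65 = 0.111,  # age >= 65

    # unit costs
    ivig_cost_per_gram  = 59.19,
    nurse_rate_per_hour = 32,
    nurse_hours_per_administration = 3.5,
    # per-cycle corticosteroid cost schedule (first, second, subsequent)
    steroid_cycle_costs = c(51.19, 43.57, 39.87),
    # inputs to the bottom-up corticosteroid cost reconstruction
    prednisone_50mg_pill = 0.0913,
    prednisone_5mg_pill  = 0.022,
    etidronate_kit       = 19.99,  # 90-tablet cyclical kit
    pharmacy_markup      = 0.08,
    dispensing_fee       = 7.00,

    life_table = life_table
  )
  class(p) <- "cidp_parameters"
  validate_parameters(p)
  p
}

#' Validate a parameter set
#'
#' Checks every structural invariant and reports all violations at once.
#'
#' @param params a `cidp_parameters` list.
#' @return `params`, invisibly, if valid; otherwise an error listing every
#'   offending field.
#' @export
validate_parameters <- function(params) {
  problems <- character()
  bad <- function(msg) problems <<- c(problems, msg)
  chk_prob <- function(x, field) {
    if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1))
      bad(sprintf("%s: must be a probability in [0, 1]", field))
  }
  chk_nonneg <- function(x, field) {
    if (!is.numeric(x) || anyNA(x) || any(x < 0))
      bad(sprintf("%s: must be non-negative", field))
  }
  required <- c("response_rate", "relapse_per_cycle", "ae_annual",
                "utilities_by_age", "ivig_utility_gain", "fracture",
                "diabetes", "cataract_disutility_wait",
                "cataract_disutility_post", "glaucoma_disutility",
                "infection_mortality_lt65", "infection_mortality_ge65",
                "cataract_cost", "glaucoma_cost", "infection_cost",
                "ivig_cost_per_gram", "nurse_rate_per_hour",
                "nurse_hours_per_administration", "steroid_cycle_costs",
                "life_table")
  missing <- setdiff(required, names(params))
  if (length(missing))
    stop("invalid parameter set:\n  missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  chk_prob(params$response_rate, "response_rate")
  chk_prob(params$relapse_per_cycle, "relapse_per_cycle")
  chk_prob(params$ae_annual, "ae_annual")
  chk_prob(params$utilities_by_age$utility, "utilities_by_age$utility")
  for (ae in c("fracture", "diabetes")) {
    tab <- params[[ae]]
    for (col in c("disutility_y1", "disutility_post"))
      chk_nonneg(tab[[col]], paste0(ae, "$", col))
    for (col in c("mortality_y1", "mortality_post"))
      chk_prob(tab[[col]], paste0(ae, "$", col))
    for (col in c("cost_y1", "cost_post"))
      chk_nonneg(tab[[col]], paste0(ae, "$", col))
  }
  chk_nonneg(params$cataract_disutility_wait, "cataract_disutility_wait")
  chk_nonneg(params$cataract_disutility_post, "cataract_disutility_post")
  chk_nonneg(params$glaucoma_disutility, "glaucoma_disutility")
  chk_prob(params$infection_mortality_lt65, "infection_mortality_lt65")
  chk_prob(params$infection_mortality_ge65, "infection_mortality_ge65")
  for (f in c("cataract_cost", "glaucoma_cost", "infection_cost",
              "ivig_cost_per_gram", "nurse_rate_per_hour",
              "nurse_hours_per_administration", "steroid_cycle_costs"))
    chk_nonneg(params[[f]], f)
  if (length(params$steroid_cycle_costs) != 3L)
    bad("steroid_cycle_costs: must have 3 entries (first, second, subsequent)")
  lt <- try(as_life_table(as.data.frame(params$life_table)), silent = TRUE)
  if (inherits(lt, "try-error")) bad(paste0("life_table: ", attr(lt, "condition")$message))

  if (length(problems))
    stop("invalid parameter set:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  invisible(params)
}

#' Look up an age-banded value
#'
#' @param tab data frame with an `age_lo` column.
#' @param age age in years (scalar).
#' @param column which column to return.
#' @return the value of the band containing `age` (ages below the first band
#'   are clamped to it).
#' @export
age_band_value <- function(tab, age, column) {
  i <- findInterval(age, tab$age_lo)
  tab[[column]][max(i, 1L)]
}

#' Serialize / load a parameter set as JSON
#'
#' The bundled basecase fixture `inst/extdata/parameters_basecase.json`
#' round-trips through these functions.
#'
#' @param params a `cidp_parameters` list.
#' @param path file path.
#' @return `load_parameters()` returns a validated `cidp_parameters`.
#' @export
save_parameters <- function(params, path) {
  validate_parameters(params)
  x <- unclass(params)
  x$ae_annual <- as.list(x$ae_annual)
  x$steroid_cycle_costs <- as.list(x$steroid_cycle_costs)
  x$life_table <- as.data.frame(x$life_table)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname save_parameters
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$ae_annual <- unlist(x$ae_annual)
  x$steroid_cycle_costs <- unname(unlist(x$steroid_cycle_costs))
  for (f in c("utilities_by_age", "fracture", "diabetes"))
    x[[f]] <- as.data.frame(x[[f]])
  x$life_table <- as_life_table(as.data.frame(x$life_table))
  class(x) <- "cidp_parameters"
  validate_parameters(x)
  x
}

#' @export
print.cidp_parameters <- function(x, ...) {
  cat("<cidp_parameters>\n")
  cat(sprintf("  response rate %.3f, relapse/cycle %.3f, IVIG utility gain %+.2f\n",
              x$response_rate, x$relapse_per_cycle, x$ivig_utility_gain))
  cat(sprintf("  AE annual probs: %s\n",
              paste(sprintf("%s=%.4f", names(x$ae_annual), x$ae_annual),
                    collapse = ", ")))
  cat(sprintf("  IVIG $%.2f/g; steroid cycle costs $%.2f/$%.2f/$%.2f\n",
              x$ivig_cost_per_gram, x$steroid_cycle_costs[1],
              x$steroid_cycle_costs[2], x$steroid_cycle_costs[3]))
  cat(sprintf("  life table ages %d-%d\n", min(x$life_table$age),
              max(x$life_table$age)))
  invisible(x)
}
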