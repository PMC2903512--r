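#' Distribution specification for one probabilistic parameter
#'
#' @param name parameter identifier (unique within a spec list).
#' @param family `"beta"`, `"gamma"`, `"normal"` or `"fixed"`.
#' @param parameters named numeric vector: `c(alpha=, beta=)` for beta,
#'   `c(shape=, scale=)` for gamma, `c(mean=, sd=)` for normal, `c(value=)`
#'   for fixed.
#' @param apply how a draw maps onto the parameter set: `"value"` (replace),
#'   `"half"` (draw / 2, used for the 25-week relapse probability),
#'   `"one_minus"` (1 - draw, for utility weights applied as disutilities) or
#'   `"multiplier"` (scale the basecase value(s), truncated at 0 and, for
#'   probabilities, at 1).
#' @param target character path of the target field in the parameter set,
#'   e.g. `"response_rate"`, `"ae_annual.fracture"`,
#'   `"fracture.disutility_y1"`, `"utilities_by_age.2"`.
#' @return a list of class `cidp_dist_spec`.
#' @export
dist_spec <- function(name, family = c("beta", "gamma", "normal", "fixed"),
                      parameters, apply = c("value", "half", "one_minus",
                                            "multiplier"),
                      target = name) {
  family <- match.arg(family)
  apply <- match.arg(apply)
  parameters <- unlist(parameters)
  ok <- switch(family,
    beta = all(c("alpha", "beta") %in% names(parameters)) &&
      all(parameters[c("alpha", "beta")] > 0),
    gamma = all(c("shape", "scale") %in% names(parameters)) &&
      all(parameters[c("shape", "scale")] > 0),
    normal = all(c("mean", "sd") %in% names(parameters)) &&
      parameters["sd"] >= 0,
    fixed = "value" %in% names(parameters))
  if (!ok) stop("invalid parameters for ", family, " spec '", name, "'")
  structure(list(name = name, family = family, parameters = parameters,
                 apply = apply, target = target),
            class = "cidp_dist_spec")
}

# method-of-moments conversions
beta_mom <- function(mean, sd) {
  stopifnot(mean > 0, mean < 1, sd^2 < mean * (1 - mean))
  nu <- mean * (1 - mean) / sd^2 - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}
gamma_mom <- function(mean, sd) {
  stopifnot(mean > 0, sd > 0)
  c(shape = (mean / sd)^2, scale = sd^2 / mean)
}

#' Default probabilistic sensitivity analysis specification
#'
#' Beta distributions for probabilities and utility weights (published alpha
#' and beta where printed), a normal for the IVIG utility increment
#' (mean 0.12, sd 0.08), gamma distributions for adverse-event costs, and
#' normals for AE disutility and mortality increments.  Where the source
#' prints a family but no spread (AE costs, fracture/diabetes disutility and
#' mortality, baseline utilities), the spread defaults to `rel_sd` x mean
#' (20%), applied as a multiplier on the age-banded basecase values so the
#' age structure is preserved.  Unit IVIG and corticosteroid drug costs stay
#' fixed.
#'
#' @param params the basecase `cidp_parameters` (for method-of-moments
#'   means).
#' @param rel_sd relative standard deviation for parameters without a
#'   printed spread (default 0.20).
#' @return a list of `cidp_dist_spec`.
#' @export
default_psa_specs <- function(params = default_parameters(), rel_sd = 0.20) {
  specs <- list(
    dist_spec("response_rate", "beta", c(alpha = 35.52, beta = 39.61)),
    dist_spec("relapse_25wk", "beta", c(alpha = 4.03, beta = 26.97),
              apply = "half", target = "relapse_per_cycle"),
    dist_spec("ivig_utility_gain", "normal", c(mean = 0.12, sd = 0.08)),
    dist_spec("ae_fracture", "beta", c(alpha = 1.20, beta = 120.8),
              target = "ae_annual.fracture"),
    dist_spec("ae_diabetes", "beta", c(alpha = 0.48, beta = 111.52),
              target = "ae_annual.diabetes"),
    dist_spec("ae_cataract", "beta", c(alpha = 1.39, beta = 120.61),
              target = "ae_annual.cataract"),
    dist_spec("ae_glaucoma", "beta", c(alpha = 0.09, beta = 111.91),
              target = "ae_annual.glaucoma"),
    dist_spec("ae_infection", "beta", c(alpha = 0.39, beta = 120.8),
              target = "ae_annual.infection"),
    # utility weights published as beta; applied as disutility = 1 - weight
    dist_spec("glaucoma_weight", "beta", c(alpha = 214.32, beta = 13.68),
              apply = "one_minus", target = "glaucoma_disutility"),
    dist_spec("cataract_wait_weight", "beta", c(alpha = 62, beta = 38),
              apply = "one_minus", target = "cataract_disutility_wait"),
    dist_spec("cataract_post_weight", "beta", c(alpha = 90, beta = 10),
              apply = "one_minus", target = "cataract_disutility_post"))

  # baseline utilities: beta, method of moments at rel_sd x mean
  for (i in seq_len(nrow(params$utilities_by_age))) {
    u <- params$utilities_by_age$utility[i]
    specs <- c(specs, list(dist_spec(
      paste0("utility_band_", params$utilities_by_age$age_lo[i]), "beta",
      beta_mom(u, rel_sd * u), target = paste0("utilities_by_age.", i))))
  }
  # AE disutility and mortality increments: normal multipliers N(1, rel_sd)
  for (ae in c("fracture", "diabetes"))
    for (col in c("disutility_y1", "disutility_post", "mortality_y1",
                  "mortality_post"))
      specs <- c(specs, list(dist_spec(
        paste(ae, col, sep = "_"), "normal", c(mean = 1, sd = rel_sd),
        apply = "multiplier", target = paste(ae, col, sep = "."))))
  specs <- c(specs, list(
    dist_spec("infection_mortality_lt65", "normal", c(mean = 1, sd = rel_sd),
              apply = "multiplier"),
    dist_spec("infection_mortality_ge65", "normal", c(mean = 1, sd = rel_sd),
              apply = "multiplier")))
  # AE costs: gamma; banded costs as multipliers, scalar costs direct
  for (ae in c("fracture", "diabetes"))
    for (col in c("cost_y1", "cost_post"))
      specs <- c(specs, list(dist_spec(
        paste(ae, col, sep = "_"), "gamma", gamma_mom(1, rel_sd),
        apply = "multiplier", target = paste(ae, col, sep = "."))))
  for (f in c("cataract_cost", "glaucoma_cost", "infection_cost"))
    specs <- c(specs, list(dist_spec(
      f, "gamma", gamma_mom(params[[f]], rel_sd * params[[f]]))))
  specs
}

# one draw column per spec, n rows; independent per-parameter substreams so
# adding a parameter does not perturb the others' draws
sample_draw_matrix <- function(specs, n, seed) {
  draws <- vapply(seq_along(specs), function(j) {
    sp <- specs[[j]]
    withr::with_seed((abs(seed) * 127 + j * 9973) %% 2147483647L, {
      switch(sp$family,
        beta = stats::rbeta(n, sp$parameters["alpha"], sp$parameters["beta"]),
        gamma = stats::rgamma(n, shape = sp$parameters["shape"],
                              scale = sp$parameters["scale"]),
        normal = stats::rnorm(n, sp$parameters["mean"], sp$parameters["sd"]),
        fixed = rep(unname(sp$parameters["value"]), n))
    })
  }, numeric(n))
  draws <- matrix(draws, nrow = n)
  colnames(draws) <- vapply(specs, `[[`, "", "name")
  draws
}

# apply one row of draws to the basecase parameter set
apply_parameter_draws <- function(base, draws, specs) {
  p <- base
  set_field <- function(path, value) {
    parts <- strsplit(path, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1L) {
      p[[parts]] <<- value
    } else if (parts[1] == "utilities_by_age") {
      p$utilities_by_age$utility[as.integer(parts[2])] <<- value
    } else if (parts[1] == "ae_annual") {
      p$ae_annual[[parts[2]]] <<- value
    } else {
      p[[parts[1]]][[parts[2]]] <<- value
    }
  }
  get_field <- function(path) {
    parts <- strsplit(path, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1L) p[[parts]]
    else if (parts[1] == "utilities_by_age")
      p$utilities_by_age$utility[as.integer(parts[2])]
    else if (parts[1] == "ae_annual") p$ae_annual[[parts[2]]]
    else p[[parts[1]]][[parts[2]]]
  }
  is_prob_target <- function(path)
    grepl("^(response_rate|relapse_per_cycle|ae_annual|utilities_by_age|infection_mortality)|mortality_(y1|post)$",
          path)
  for (j in seq_along(specs)) {
    sp <- specs[[j]]
    d <- draws[[sp$name]]
    value <- switch(sp$apply,
      value = d,
      half = d / 2,
      one_minus = 1 - d,
      multiplier = pmax(get_field(sp$target) * max(d, 0), 0))
    is_cost <- grepl("cost", sp$target)
    if (sp$apply %in% c("value", "half", "one_minus") &&
        sp$name != "ivig_utility_gain")
      value <- if (is_cost) pmax(value, 0) else pmin(pmax(value, 0), 1)
    if (sp$apply == "multiplier" && is_prob_target(sp$target))
      value <- pmin(value, 1)
    set_field(sp$target, value)
  }
  p
}

#' Draw one parameter set from the PSA distributions
#'
#' @param specs list of [dist_spec()] objects.
#' @param base basecase `cidp_parameters`.
#' @param seed integer seed (per-parameter substreams are derived from it).
#' @return a valid `cidp_parameters`.
#' @export
sample_parameter_set <- function(specs, base, seed) {
  draws <- as.data.frame(sample_draw_matrix(specs, 1L, seed))
  out <- apply_parameter_draws(base, draws, specs)
  validate_parameters(out)
  out
}

#' Net monetary benefit
#'
#' `lambda x dQALY - dCost`: positive when the incremental effect is worth
#' more than the incremental cost at willingness-to-pay `lambda`.
#'
#' @param delta_cost incremental cost (CAD).
#' @param delta_qaly incremental QALYs.
#' @param lambda willingness to pay per QALY (CAD, >= 0).
#' @return CAD (vectorized).
#' @export
net_monetary_benefit <- function(delta_cost, delta_qaly, lambda) {
  if (any(lambda < 0)) stop("lambda must be >= 0")
  lambda * delta_qaly - delta_cost
}

#' Probabilistic sensitivity analysis with CEAC
#'
#' Runs `n_sims` second-order Monte Carlo simulations: each simulation draws
#' one parameter set from `specs` (common to both arms), runs both arms of
#' the Markov model, and records the incremental cost and QALYs of IVIG
#' versus corticosteroids.  The cost-effectiveness acceptability curve gives,
#' at each willingness-to-pay threshold, the fraction of simulations with
#' strictly positive net monetary benefit (ties count as not
#' cost-effective).
#'
#' @param config a `cidp_config` (arm is ignored; both arms are run).
#' @param specs list of [dist_spec()]; default [default_psa_specs()].
#' @param n_sims number of simulations (the published analysis used 1000).
#' @param seed master integer seed.
#' @param wtp_grid willingness-to-pay thresholds (CAD/QALY).
#' @param base_params basecase `cidp_parameters`.
#' @return list of class `cidp_psa`: `draws` (per-sim incremental cost/QALY),
#'   `ceac` (data frame `wtp`, `prob_ce`), `n_sims`, `seed`.
#' @export
run_psa <- function(config = model_config(), specs = NULL, n_sims = 1000,
                    seed = 1, wtp_grid = seq(0, 1e6, by = 1e4),
                    base_params = default_parameters()) {
  stopifnot(n_sims >= 1)
  if (is.null(specs)) specs <- default_psa_specs(base_params)
  draws <- as.data.frame(sample_draw_matrix(specs, n_sims, seed))
  cfg_i <- config; cfg_i$arm <- "IVIG"
  cfg_s <- config; cfg_s$arm <- "steroid"
  inc_cost <- inc_qaly <- numeric(n_sims)
  for (i in seq_len(n_sims)) {
    p_i <- apply_parameter_draws(base_params, draws[i, , drop = FALSE], specs)
    ti <- run_cohort(cfg_i, p_i)
    ts <- run_cohort(cfg_s, p_i)
    inc_cost[i] <- unname(ti$totals["cost"] - ts$totals["cost"])
    inc_qaly[i] <- unname(ti$totals["qaly"] - ts$totals["qaly"])
  }
  prob_ce <- vapply(wtp_grid, function(l)
    mean(net_monetary_benefit(inc_cost, inc_qaly, l) > 0), numeric(1))
  out <- list(draws = data.frame(sim = seq_len(n_sims), inc_cost = inc_cost,
                                 inc_qaly = inc_qaly),
              ceac = data.frame(wtp = wtp_grid, prob_ce = prob_ce),
              n_sims = n_sims, seed = seed)
  class(out) <- "cidp_psa"
  out
}

#' @export
print.cidp_psa <- function(x, ...) {
  cat(sprintf("<cidp_psa> %d simulations (seed %d)\n", x$n_sims, x$seed))
  cat(sprintf("  median incremental cost $%s, QALYs %.3f\n",
              format(round(stats::median(x$draws$inc_cost)), big.mark = ","),
              stats::median(x$draws$inc_qaly)))
  show <- x$ceac[x$ceac$wtp %in% c(0, 5e4, 5e5, 67e4, 1e6), ]
  if (nrow(show))
    cat(paste(sprintf("  P(cost-effective | WTP $%s) = %.3f",
                      format(show$wtp, big.mark = ","), show$prob_ce),
              collapse = "\n"), "\n")
  invisible(x)
}

#' CEAC interpolation helper
#'
#' @param psa a `cidp_psa`.
#' @param lambda willingness-to-pay value(s); the probability is recomputed
#'   exactly from the stored per-simulation draws (no grid interpolation).
#' @return probability IVIG is cost-effective at each `lambda`.
#' @export
prob_cost_effective <- function(psa, lambda) {
  vapply(lambda, function(l)
    mean(net_monetary_benefit(psa$draws$inc_cost, psa$draws$inc_qaly, l) > 0),
    numeric(1))
}

#' Built-in one-way / scenario sensitivity table
#'
#' One entry per published scenario: patient weights 35-95 kg, starting ages
#' 35-75, discount rates 0% and 3%, horizons 1-20 years, an IVIG utility
#' gain of 0.25, the post-AE switch to IVIG, no relapse extrapolation beyond
#' 25 weeks, and the six maintenance dose x interval combinations.
#'
#' @return a list of scenarios, each `list(label, config = named overrides,
#'   params = named overrides)`.
#' @export
owsa_scenarios <- function() {
  sc <- list()
  add <- function(label, config = list(), params = list())
    sc[[length(sc) + 1L]] <<- list(label = label, config = config,
                                   params = params)
  for (w in seq(35, 95, by = 10))
    add(sprintf("Patient weight %d kg", w), list(weight = w))
  for (a in seq(35, 75, by = 10))
    add(sprintf("Starting age %d years", a), list(start_age = a))
  for (d in c(0, 0.03))
    add(sprintf("Discount rate %g%%", 100 * d),
        list(discount_rate_annual = d))
  for (h in c(1, 3, 5, 10, 20))
    add(sprintf("Time horizon %d years", h), list(horizon_years = h))
  add("IVIG utility gain 0.25", params = list(ivig_utility_gain = 0.25))
  add("Steroid patients switch to IVIG after AE",
      list(steroid_switch_to_ivig_after_ae = TRUE))
  add("Relapse not extrapolated beyond 25 weeks",
      list(relapse_extrapolation = "stop_after_25_weeks"))
  for (dose in c(1.0, 0.4))
    for (iv in c(3, 6, 8))
      add(sprintf("Maintenance %.1f g/kg every %d weeks", dose, iv),
          list(maintenance_dose = dose, maintenance_interval = iv))
  sc
}

#' Run the one-way / scenario sensitivity analysis
#'
#' Each scenario alters exactly the named configuration or parameter fields
#' and re-runs both arms.
#'
#' @param base_config basecase `cidp_config`.
#' @param base_params basecase `cidp_parameters`.
#' @param scenarios list from [owsa_scenarios()] (the default) or the same
#'   shape.
#' @return data frame: `scenario`, `inc_cost`, `inc_qaly`, `icur`.
#' @export
run_owsa <- function(base_config = model_config(),
                     base_params = default_parameters(),
                     scenarios = owsa_scenarios()) {
  rows <- lapply(scenarios, function(sc) {
    cfg <- base_config
    bad <- setdiff(names(sc$config), names(cfg))
    if (length(bad)) stop("unknown config field(s) in scenario '", sc$label,
                          "': ", paste(bad, collapse = ", "))
    for (f in names(sc$config)) cfg[[f]] <- sc$config[[f]]
    par <- base_params
    bad <- setdiff(names(sc$params), names(par))
    if (length(bad)) stop("unknown parameter field(s) in scenario '",
                          sc$label, "': ", paste(bad, collapse = ", "))
    for (f in names(sc$params)) par[[f]] <- sc$params[[f]]
    ce <- run_basecase(cfg, par)
    data.frame(scenario = sc$label, inc_cost = ce$inc_cost,
               inc_qaly = ce$inc_qaly, icur = ce$icur)
  })
  do.call(rbind, rows)
}
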