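# shared fixtures, built once per test run

base_params <- default_parameters()
base_config <- model_config()

# life table with no background mortality, for closed-form checks
no_mortality_lt <- as_life_table(
  data.frame(age = 35:100, annual_death_prob = 0))

params_no_mortality <- local({
  p <- base_params
  p$life_table <- no_mortality_lt
  p
})

# parameters with no adverse events at all
zero_ae <- function(p) {
  p$ae_annual[] <- 0
  p
}

# parameters with no AE mortality increments
zero_ae_mortality <- function(p) {
  p$fracture$mortality_y1[] <- 0
  p$fracture$mortality_post[] <- 0
  p$diabetes$mortality_y1[] <- 0
  p$diabetes$mortality_post[] <- 0
  p$infection_mortality_lt65 <- 0
  p$infection_mortality_ge65 <- 0
  p
}

# degenerate PSA specification: every distribution replaced by the fixed
# value that reproduces the basecase parameter set
degenerate_specs <- function(params = base_params) {
  lapply(default_psa_specs(params), function(sp) {
    v0 <- switch(sp$apply,
      value = {
        parts <- strsplit(sp$target, ".", fixed = TRUE)[[1]]
        if (length(parts) == 1L) params[[parts]]
        else if (parts[1] == "utilities_by_age")
          params$utilities_by_age$utility[as.integer(parts[2])]
        else if (parts[1] == "ae_annual") params$ae_annual[[parts[2]]]
        else params[[parts[1]]][[parts[2]]]
      },
      half = 2 * params$relapse_per_cycle,
      one_minus = 1 - params[[sp$target]],
      multiplier = 1)
    dist_spec(sp$name, "fixed", c(value = v0), apply = sp$apply,
              target = sp$target)
  })
}

# independent per-individual microsimulation oracle for the cohort engine
microsim_occupancy <- function(config, params, n_ind, seed, record_cycles) {
  s <- model_states()
  ns <- length(s)
  start <- if (config$arm == "IVIG") "IVIG_INITIAL" else "STEROID_ON_1"
  state <- rep(match(start, s), n_ind)
  out <- list()
  withr::with_seed(seed, {
    for (t in seq_len(max(record_cycles))) {
      if (t %in% record_cycles) {
        occ <- tabulate(state, nbins = ns) / n_ind
        out[[as.character(t)]] <- setNames(occ, s)
      }
      M <- transition_matrix(t, params, config)
      nxt <- state
      for (si in unique(state)) {
        idx <- which(state == si)
        nxt[idx] <- sample.int(ns, length(idx), replace = TRUE, prob = M[si, ])
      }
      state <- nxt
    }
  })
  out
}
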