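#' Simulate response trials for meta-analysis testing
#'
#' Generates `k` studies around a common true response proportion on the
#' logit scale: each study's latent proportion is
#' `plogis(rnorm(1, qlogis(true_p), tau))` and its responder count is
#' binomial.  With `tau = 0` every latent proportion equals `true_p`, so
#' pooled estimates should recover it as sample sizes grow.
#'
#' @param k number of studies (>= 1).
#' @param true_p common response probability, in (0, 1).
#' @param tau between-study standard deviation on the logit scale (>= 0).
#' @param n_range integer pair: per-study sample sizes are drawn uniformly
#'   from this range.
#' @param seed integer seed; identical seeds give identical records.
#' @return a `cidp_trials` data frame with an attribute `latent_p` of the
#'   per-study latent proportions.
#' @export
simulate_trials <- function(k, true_p, tau = 0, n_range = c(7, 59), seed = 1) {
  if (k < 1) stop("k must be >= 1")
  if (!(true_p > 0 && true_p < 1)) stop("true_p must be in (0, 1)")
  if (tau < 0) stop("tau must be >= 0")
  stopifnot(length(n_range) == 2, n_range[1] >= 1, n_range[2] >= n_range[1])
  out <- withr::with_seed(seed, {
    sizes <- seq.int(n_range[1], n_range[2])
    n <- sizes[sample.int(length(sizes), k, replace = TRUE)]
    p <- stats::plogis(stats::rnorm(k, stats::qlogis(true_p), tau))
    r <- stats::rbinom(k, n, p)
    list(n = n, p = p, r = r)
  })
  trials <- trial_records(sprintf("sim_%02d", seq_len(k)), out$n, out$r)
  attr(trials, "latent_p") <- out$p
  trials
}

#' Randomly perturb a parameter set
#'
#' Jitters every scalar probability, utility, disutility and cost in a
#' parameter set by independent multiplicative log-normal-ish noise
#' (`x * exp(rnorm(1, 0, scale))`), clipping probabilities and utilities
#' back into \[0, 1\].  Used to stress-test the engine's structural
#' invariants on inputs other than the basecase; `scale = 0` returns the
#' input unchanged.
#'
#' @param base a `cidp_parameters`.
#' @param scale perturbation scale (>= 0).
#' @param seed integer seed.
#' @return a valid `cidp_parameters`.
#' @export
perturb_parameters <- function(base, scale, seed = 1) {
  if (scale < 0) stop("scale must be >= 0")
  if (scale == 0) return(base)
  p <- base
  withr::with_seed(seed, {
    jit <- function(x) x * exp(stats::rnorm(length(x), 0, scale))
    jit01 <- function(x) pmin(jit(x), 1)
    p$response_rate <- jit01(p$response_rate)
    p$relapse_per_cycle <- jit01(p$relapse_per_cycle)
    p$ae_annual <- jit01(p$ae_annual)
    p$utilities_by_age$utility <- jit01(p$utilities_by_age$utility)
    p$ivig_utility_gain <- p$ivig_utility_gain +
      stats::rnorm(1, 0, scale * 0.1)
    for (ae in c("fracture", "diabetes")) {
      for (col in c("disutility_y1", "disutility_post"))
        p[[ae]][[col]] <- jit(p[[ae]][[col]])
      for (col in c("mortality_y1", "mortality_post"))
        p[[ae]][[col]] <- jit01(p[[ae]][[col]])
      for (col in c("cost_y1", "cost_post"))
        p[[ae]][[col]] <- jit(p[[ae]][[col]])
    }
    p$cataract_disutility_wait <- jit(p$cataract_disutility_wait)
    p$cataract_disutility_post <- jit(p$cataract_disutility_post)
    p$glaucoma_disutility <- jit(p$glaucoma_disutility)
    p$infection_mortality_lt65 <- jit01(p$infection_mortality_lt65)
    p$infection_mortality_ge65 <- jit01(p$infection_mortality_ge65)
    for (f in c("cataract_cost", "glaucoma_cost", "infection_cost",
                "ivig_cost_per_gram", "nurse_rate_per_hour",
                "steroid_cycle_costs"))
      p[[f]] <- jit(p[[f]])
  })
  validate_parameters(p)
  p
}
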