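#' Trial records for the response-rate meta-analysis
#'
#' @param study_label character study labels.
#' @param n numbers of IVIG-treated patients.
#' @param responders numbers of responders.
#' @return a data frame of class `cidp_trials`.
#' @export
trial_records <- function(study_label, n, responders) {
  n <- as.integer(n); responders <- as.integer(responders)
  if (any(n < 1)) stop("n must be positive")
  if (any(responders < 0 | responders > n)) stop("responders must be in [0, n]")
  out <- data.frame(study_label = as.character(study_label), n = n,
                    responders = responders)
  class(out) <- c("cidp_trials", "data.frame")
  out
}

#' The six randomized trials reporting IVIG response in CIDP
#'
#' Per-arm sample sizes and responder counts used to derive the model's
#' initial response probability.
#'
#' @return a `cidp_trials` data frame.
#' @export
default_trials <- function() {
  trial_records(
    study_label = c("Zinman (2005)", "Thompson (1996)", "Mendell (2001)",
                    "Hughes (2008)", "Vermuelen (1993)", "Hahn (1996)"),
    n = c(8, 7, 29, 59, 15, 30),
    responders = c(4, 3, 11, 32, 4, 19))
}

#' DerSimonian-Laird random-effects pooling of response proportions
#'
#' Pools raw study proportions `p_i = responders_i / n_i` with inverse-
#' variance weights `1 / (v_i + tau^2)`, `v_i = p_i (1 - p_i) / n_i`, where
#' `tau^2` is the DerSimonian-Laird moment estimate of between-study
#' variance.  The 95% confidence interval uses the normal approximation
#' (z = 1.959964).  Pooling is on the raw proportion scale by default, which
#' reproduces the published study weights and interval; a logit-scale
#' alternative is available for comparison.
#'
#' Degenerate proportions (0 or 1) receive a 0.5 continuity correction to
#' both cell counts and are flagged.  A single study is returned as-is with
#' `tau2 = 0` and a flag.
#'
#' @param trials a `cidp_trials` data frame (or any data frame with columns
#'   `study_label`, `n`, `responders`).
#' @param method pooling model; only `"random_effects"` is implemented.
#' @param scale `"raw"` (default) or `"logit"`.
#' @return a list of class `cidp_pooled`: `estimate`, `ci_low`, `ci_high`,
#'   `tau2`, `study_weights` (normalized, summing to 1), `Q`, `I2`, `flags`.
#' @export
pool_response_rate <- function(trials, method = "random_effects",
                               scale = c("raw", "logit")) {
  method <- match.arg(method, "random_effects")
  scale <- match.arg(scale)
  stopifnot(nrow(trials) >= 1, all(trials$responders <= trials$n),
            all(trials$n >= 1))
  z <- 1.959964
  flags <- character()

  r <- trials$responders; n <- trials$n
  degenerate <- r == 0 | r == n
  if (any(degenerate)) {
    r <- r + 0.5 * degenerate
    n <- n + 1.0 * degenerate
    flags <- c(flags, "continuity correction 0.5 applied to degenerate counts")
  }
  p <- r / n

  if (nrow(trials) == 1L) {
    est <- p[1]
    v <- p[1] * (1 - p[1]) / n[1]
    out <- list(estimate = est, ci_low = max(0, est - z * sqrt(v)),
                ci_high = min(1, est + z * sqrt(v)), tau2 = 0,
                study_weights = data.frame(study_label = trials$study_label,
                                           weight = 1),
                Q = 0, I2 = 0,
                flags = c(flags, "single study: no pooling performed"))
    class(out) <- "cidp_pooled"
    return(out)
  }

  if (scale == "raw") {
    y <- p
    v <- p * (1 - p) / n
  } else {
    y <- log(p / (1 - p))
    v <- 1 / r + 1 / (n - r)
  }
  het <- dl_heterogeneity(y, v)
  w <- 1 / (v + het$tau2)
  est <- sum(w * y) / sum(w)
  se <- sqrt(1 / sum(w))
  lo <- est - z * se; hi <- est + z * se
  if (scale == "logit") {
    inv <- function(x) 1 / (1 + exp(-x))
    est <- inv(est); lo <- inv(lo); hi <- inv(hi)
  } else {
    lo <- max(0, lo); hi <- min(1, hi)
  }
  out <- list(estimate = est, ci_low = lo, ci_high = hi, tau2 = het$tau2,
              study_weights = data.frame(study_label = trials$study_label,
                                         weight = w / sum(w)),
              Q = het$Q, I2 = het$I2, flags = flags)
  class(out) <- "cidp_pooled"
  out
}

# DerSimonian-Laird moment estimator on effect estimates y with within-study
# variances v
dl_heterogeneity <- function(y, v) {
  w <- 1 / v
  ybar <- sum(w * y) / sum(w)
  Q <- sum(w * (y - ybar)^2)
  df <- length(y) - 1
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - df) / C)
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  list(Q = Q, tau2 = tau2, I2 = I2)
}

#' Heterogeneity statistics for a set of trials
#'
#' Cochran's Q, the DerSimonian-Laird `tau^2` and `I^2 = max(0, (Q - df)/Q)
#' x 100`, computed on raw proportions.
#'
#' @param trials a `cidp_trials` data frame with at least 2 studies.
#' @return list with `Q`, `tau2`, `I2`.
#' @export
heterogeneity <- function(trials) {
  if (nrow(trials) < 2) stop("heterogeneity requires at least 2 trials")
  r <- trials$responders; n <- trials$n
  degenerate <- r == 0 | r == n
  r <- r + 0.5 * degenerate
  n <- n + 1.0 * degenerate
  p <- r / n
  dl_heterogeneity(p, p * (1 - p) / n)
}

#' @export
print.cidp_pooled <- function(x, ...) {
  cat(sprintf("<cidp_pooled> %.1f%% (95%% CI %.1f%%, %.1f%%), tau2 = %.4f, I2 = %.1f%%\n",
              100 * x$estimate, 100 * x$ci_low, 100 * x$ci_high, x$tau2, x$I2))
  w <- x$study_weights
  cat(paste(sprintf("  %-18s w = %.2f", w$study_label, w$weight),
            collapse = "\n"), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
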