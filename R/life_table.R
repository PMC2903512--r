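#' Background-mortality life tables
#'
#' The model applies all-cause background mortality from a unisex period life
#' table (annual probability of death by single year of age).  The published
#' analysis cites national life tables without printing them, so the package
#' bundles a frozen synthetic stand-in calibrated to values typical of
#' Canadian unisex tables of the late 2000s.  See
#' [synthesize_life_table()] for the generating form.
#'
#' A life table is a data frame with columns `age` (integer years, strictly
#' increasing) and `annual_death_prob` (in \[0, 1\]).
#'
#' @param path file to read; defaults to the bundled fixture
#'   (`life_table_synthetic.tsv`, tab-separated, `#`-comment header).
#' @return a `data.frame` of class `cidp_life_table`.
#' @export
make_default_life_table <- function(path = system.file("extdata",
                                                       "life_table_synthetic.tsv",
                                                       package = "cidpce")) {
  stopifnot(nzchar(path), file.exists(path))
  lt <- utils::read.delim(path, comment.char = "#", header = TRUE)
  as_life_table(lt)
}

#' @rdname make_default_life_table
#' @param x a data frame with columns `age` and `annual_death_prob`.
#' @export
as_life_table <- function(x) {
  stopifnot(is.data.frame(x), all(c("age", "annual_death_prob") %in% names(x)))
  x$age <- as.integer(x$age)
  if (any(diff(x$age) <= 0)) stop("life table ages must be strictly increasing")
  if (any(x$annual_death_prob < 0 | x$annual_death_prob > 1))
    stop("life table probabilities must be in [0, 1]")
  class(x) <- c("cidp_life_table", "data.frame")
  x
}

#' Synthetic Gompertz-Makeham life table
#'
#' Annual hazard `h(x) = A + B * exp(G * x)`; annual death probability
#' `1 - exp(-h(x))`.  Defaults are calibrated so that the probability of
#' death within a year is about 0.004 at age 54 and 0.045 at age 80, typical
#' of Canadian unisex tables around 2006.  This generator exists so the
#' frozen bundled fixture can be verified in tests; analyses read the frozen
#' file via [make_default_life_table()].
#'
#' @param ages integer vector of ages covered.
#' @param A Makeham age-independent hazard component (per year).
#' @param B,G Gompertz level and log-slope of the senescent hazard.
#' @return a `cidp_life_table`.
#' @export
synthesize_life_table <- function(ages = 35:100, A = 2e-4, B = 2.78e-5,
                                  G = 0.092) {
  hazard <- A + B * exp(G * ages)
  as_life_table(data.frame(age = as.integer(ages),
                           annual_death_prob = round(1 - exp(-hazard), 7)))
}

#' Look up the annual death probability at an age
#'
#' Ages are floored to whole years and clamped to the table's range.
#'
#' @param lt a `cidp_life_table`.
#' @param age age in years (vectorized).
#' @return annual death probabilities.
#' @export
life_table_prob <- function(lt, age) {
  a <- pmin(pmax(floor(age), min(lt$age)), max(lt$age))
  lt$annual_death_prob[match(a, lt$age)]
}
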