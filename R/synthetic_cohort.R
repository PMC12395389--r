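# Derive a per-operation substream seed from a master seed, keeping the
# result a valid 32-bit integer. Offsets separate pipeline stages so that
# e.g. exposure draws and outcome draws never share a stream.
substream_seed <- function(seed, offset) {
  s <- (as.numeric(seed) * 7919 + offset * 104729) %% 2147483647
  as.integer(s)
}

#' Simulate binary exposure profiles
#'
#' Draws an `n x length(rates)` matrix of independent Bernoulli exposures,
#' column j with success probability `rates[j]` — the binomial mechanism used
#' to build the 100,000-record simulation population from literature
#' exposure prevalences.
#'
#' @param n Number of participants.
#' @param rates Named numeric vector of exposure prevalences in `[0, 1]`
#'   (names become column names).
#' @param seed Integer RNG seed; the draw is reproducible given the seed.
#' @return Integer 0/1 matrix with one column per factor.
#' @examples
#' x <- simulate_exposures(1000, c(hypertension = 0.58, diabetes = 0.297), seed = 1)
#' colMeans(x)
#' @export
simulate_exposures <- function(n, rates, seed) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("`n` must be a positive count", call. = FALSE)
  }
  if (!is.numeric(rates) || any(is.na(rates)) || any(rates < 0 | rates > 1)) {
    stop("exposure `rates` must lie in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  m <- matrix(0L, nrow = n, ncol = length(rates),
              dimnames = list(NULL, names(rates)))
  # column-wise: uniform draw below the prevalence marks exposure
  for (j in seq_along(rates)) {
    m[, j] <- as.integer(stats::runif(n) < rates[j])
  }
  m
}

#' Calibrate the logistic intercept to a target incidence
#'
#' Finds the intercept alpha such that the mean predicted risk
#' `mean(plogis(alpha + X %*% beta))` over the supplied exposure profiles
#' equals `target_incidence`. The mean risk is strictly increasing in alpha,
#' so a monotone root search converges to machine precision.
#'
#' @param betas Named coefficient vector (order must match `exposures`
#'   columns when names are absent).
#' @param exposures Binary exposure matrix.
#' @param target_incidence Desired mean outcome probability, in (0, 1).
#' @return The calibrated intercept (numeric scalar); the achieved mean risk
#'   matches the target within 1e-6.
#' @export
calibrate_alpha <- function(betas, exposures, target_incidence) {
  if (target_incidence <= 0 || target_incidence >= 1) {
    stop("`target_incidence` must lie strictly between 0 and 1", call. = FALSE)
  }
  lp <- linear_predictor(exposures, betas)
  f <- function(a) mean(stats::plogis(a + lp)) - target_incidence
  lo <- -40; hi <- 40
  if (f(lo) > 0 || f(hi) < 0) {
    stop("target incidence unreachable for these coefficients", call. = FALSE)
  }
  root <- stats::uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.75)$root
  if (abs(f(root)) > 1e-6) {
    stop("intercept calibration failed to reach the target incidence", call. = FALSE)
  }
  root
}

# Align a named coefficient vector with the columns of an exposure matrix.
linear_predictor <- function(exposures, betas) {
  if (!is.null(names(betas)) && !is.null(colnames(exposures))) {
    missing <- setdiff(colnames(exposures), names(betas))
    if (length(missing) > 0) {
      stop("no coefficient for factor(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    betas <- betas[colnames(exposures)]
  } else if (length(betas) != ncol(exposures)) {
    stop("coefficient length does not match the number of exposure columns",
         call. = FALSE)
  }
  drop(exposures %*% betas)
}

#' Generate binary outcomes from a logistic model
#'
#' Assigns each participant a stroke outcome drawn from
#' Bernoulli(plogis(alpha + X beta)) — the generator inverts the logistic
#' model the analysis fits, so fitted coefficients have a known truth.
#'
#' @param exposures Binary exposure matrix.
#' @param alpha Logistic intercept.
#' @param betas Named coefficient vector.
#' @param seed Integer RNG seed.
#' @return Integer 0/1 outcome vector of length `nrow(exposures)`.
#' @export
generate_outcomes <- function(exposures, alpha, betas, seed) {
  p <- stats::plogis(alpha + linear_predictor(exposures, betas))
  set.seed(seed)
  as.integer(stats::runif(nrow(exposures)) < p)
}

#' Generate a synthetic screening cohort
#'
#' Produces a cohort data frame with one row per participant: a unique
#' `participant_id`, the eight binary exposures, chronic-history flags
#' (defaulting to the corresponding hypertension/diabetes/heart-disease
#' exposures), and a binary stroke `outcome` drawn from a logistic model
#' whose intercept is calibrated so the expected incidence matches
#' `target_incidence`. Optional missingness is injected completely at
#' random per factor.
#'
#' @param n Cohort size (the study cohort has 11,692 participants).
#' @param panel A `risk_panel` supplying exposure prevalences and logistic
#'   coefficients; defaults to [stroke_panel()].
#' @param target_incidence Expected outcome incidence used to calibrate the
#'   intercept when `alpha = "auto"`; defaults to the cohort's 6.6%.
#' @param alpha `"auto"` (calibrate) or a numeric intercept.
#' @param missing_rates Optional named vector of per-factor MCAR missingness
#'   rates in `[0, 1]`; outcomes are never masked.
#' @param seed Master integer seed; exposure, outcome and missingness draws
#'   use substreams derived from it.
#' @return Object of class `rk_cohort` (a data frame) with attributes
#'   `alpha`, `seed` and `panel_factors`.
#' @examples
#' coh <- generate_cohort(n = 2000, seed = 42)
#' mean(coh$outcome)
#' @export
generate_cohort <- function(n, panel = stroke_panel(),
                            target_incidence = 0.066, alpha = "auto",
                            missing_rates = NULL, seed = 1L) {
  rates <- stats::setNames(panel$prevalence, panel$name)
  betas <- stats::setNames(panel$beta, panel$name)
  x <- simulate_exposures(n, rates, seed = substream_seed(seed, 1))
  if (identical(alpha, "auto")) {
    alpha <- calibrate_alpha(betas, x, target_incidence)
  }
  y <- generate_outcomes(x, alpha, betas, seed = substream_seed(seed, 2))
  cohort <- data.frame(participant_id = seq_len(n), x, outcome = y)
  chronic <- intersect(chronic_disease_factors(), panel$name)
  for (f in chronic) cohort[[paste0("history_", f)]] <- cohort[[f]]
  if (!is.null(missing_rates)) {
    cohort <- inject_missingness(cohort, missing_rates,
                                 seed = substream_seed(seed, 3))
  }
  structure(cohort, class = c("rk_cohort", "data.frame"),
            alpha = alpha, seed = seed, panel_factors = panel$name)
}

#' Inject missing-completely-at-random exposure values
#'
#' Masks each targeted exposure field independently with its own rate,
#' emulating item non-response in the screening questionnaire (in the study
#' cohort, 2556 of 11,692 participants lacked blood-lipid information).
#' The outcome column is never masked.
#'
#' @param cohort Cohort data frame.
#' @param missing_rates Named vector of rates in `[0, 1]`; names must be
#'   cohort exposure columns.
#' @param seed Integer RNG seed.
#' @return The cohort with `NA`s injected.
#' @export
inject_missingness <- function(cohort, missing_rates, seed) {
  if (any(missing_rates < 0 | missing_rates > 1)) {
    stop("missingness rates must lie in [0, 1]", call. = FALSE)
  }
  targets <- names(missing_rates)
  if (is.null(targets) || any(!nzchar(targets))) {
    stop("`missing_rates` must be named by factor", call. = FALSE)
  }
  if ("outcome" %in% targets) {
    stop("the outcome may not be masked", call. = FALSE)
  }
  unknown <- setdiff(targets, names(cohort))
  if (length(unknown) > 0) {
    stop("unknown factor(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  for (f in targets) {
    mask <- stats::runif(nrow(cohort)) < missing_rates[[f]]
    cohort[[f]][mask] <- NA
  }
  cohort
}

#' Read and write cohort files
#'
#' Cohort files are comma-separated with a header naming the factor columns,
#' one row per participant; an empty cell encodes a missing value. Written
#' and re-read cohorts round-trip exactly.
#'
#' @param path File path.
#' @return `read_cohort()` returns the cohort data frame; `write_cohort()`
#'   invisibly returns `path`.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = "", check.names = FALSE)
  if (nrow(df) == 0) stop("cohort file contains no records", call. = FALSE)
  df
}

#' @rdname read_cohort
#' @param cohort Cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}
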