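#' Population attributable risk percent by Levin's formula
#'
#' Computes the fraction of population disease incidence attributable to a
#' binary exposure from its prevalence and odds ratio, using Levin's formula
#' \deqn{PAR\% = \frac{P(OR - 1)}{P(OR - 1) + 1}.}
#' In the packaged stroke panel PAR\% is a literature-sourced input; this
#' function is the standard fallback when a parameter table lacks the column.
#'
#' @param prevalence Exposure prevalence, strictly between 0 and 1.
#' @param odds_ratio Odds ratio of the exposure, strictly positive.
#' @return The attributable fraction, in (-1, 1); 0 when `odds_ratio` is 1,
#'   negative for protective exposures (OR < 1).
#' @examples
#' compute_par_levin(0.58, 3.0)
#' compute_par_levin(0.5, 1.0) # exactly 0
#' @export
compute_par_levin <- function(prevalence, odds_ratio) {
  if (!is.numeric(prevalence) || any(prevalence <= 0 | prevalence >= 1)) {
    stop("`prevalence` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.numeric(odds_ratio) || any(odds_ratio <= 0)) {
    stop("`odds_ratio` must be strictly positive", call. = FALSE)
  }
  excess <- prevalence * (odds_ratio - 1)
  excess / (excess + 1)
}

#' Baseline morbidity ratio
#'
#' The Rothman-Keller baseline morbidity ratio of a factor is the share of
#' incidence *not* attributable to it: \eqn{\rho = 1 - PAR\%}. It is the risk
#' score assigned to the unexposed stratum.
#'
#' @param par_pct Population attributable risk fraction, in `[0, 1)`. Stored
#'   as a fraction (0.505 for 50.5%).
#' @return `1 - par_pct`, in (0, 1].
#' @examples
#' baseline_ratio(0.505) # hypertension: 0.495
#' @export
baseline_ratio <- function(par_pct) {
  if (!is.numeric(par_pct) || any(par_pct < 0 | par_pct >= 1)) {
    stop("`par_pct` must lie in [0, 1)", call. = FALSE)
  }
  1 - par_pct
}

#' Per-factor Rothman-Keller risk scores
#'
#' Each factor contributes a score of \eqn{\rho} when unexposed and
#' \eqn{S = \rho \times OR} when exposed, where \eqn{\rho = 1 - PAR\%}.
#' A factor with OR < 1 therefore scores *lower* when exposed.
#'
#' @inheritParams baseline_ratio
#' @inheritParams compute_par_levin
#' @return Named numeric vector `c(exposed = rho * OR, unexposed = rho)`.
#' @examples
#' factor_scores(0.505, 3.00) # hypertension: exposed 1.485, unexposed 0.495
#' factor_scores(0.196, 0.94) # dyslipidemia: exposed below unexposed
#' @export
factor_scores <- function(par_pct, odds_ratio) {
  rho <- baseline_ratio(par_pct)
  if (!is.numeric(odds_ratio) || any(odds_ratio <= 0)) {
    stop("`odds_ratio` must be strictly positive", call. = FALSE)
  }
  c(exposed = rho * odds_ratio, unexposed = rho)
}

#' Combine per-factor scores into the total risk score Q
#'
#' Synthesises one score per participant from their per-factor scores using
#' the standard Rothman-Keller convention: elevated scores (\eqn{S \ge 1})
#' enter additively, protective scores (\eqn{S < 1}) multiplicatively,
#' \deqn{Q = \Big(\sum_{S_i \ge 1} S_i - (k - 1)\Big) \times \prod_{S_j < 1} S_j,}
#' where \eqn{k} is the number of elevated scores. The sum term defaults to 1
#' when no score is elevated and the product term to 1 when none is
#' protective, so a panel of all-neutral scores yields Q = 1.
#'
#' @param scores Numeric vector of strictly positive per-factor scores.
#' @return An object of class `combined_score`: a list with `q_value`,
#'   `n_elevated` and `n_protective`.
#' @examples
#' combine_scores(c(1.485, 1.825, 0.756))
#' @export
combine_scores <- function(scores) {
  if (length(scores) == 0) stop("`scores` must be non-empty", call. = FALSE)
  if (!is.numeric(scores) || any(!is.finite(scores)) || any(scores <= 0)) {
    stop("all scores must be finite and strictly positive", call. = FALSE)
  }
  elevated <- scores >= 1
  k <- sum(elevated)
  sum_term <- if (k >= 1) sum(scores[elevated]) - (k - 1) else 1
  prod_term <- if (k < length(scores)) prod(scores[!elevated]) else 1
  structure(
    list(
      q_value = sum_term * prod_term,
      n_elevated = k,
      n_protective = length(scores) - k
    ),
    class = "combined_score"
  )
}

#' @export
print.combined_score <- function(x, ...) {
  cat(
    sprintf(
      "Combined Rothman-Keller score Q = %.6g (%d elevated, %d protective factors)\n",
      x$q_value, x$n_elevated, x$n_protective
    )
  )
  invisible(x)
}

#' Individual relative risk of stroke
#'
#' Scales a combined score by the population incidence:
#' individual risk = incidence \eqn{\times Q}. The result is a *relative*
#' risk level measured against the population average, not a calibrated
#' probability; Q > 1 marks above-average risk and the product may exceed
#' the incidence accordingly.
#'
#' @param combined A `combined_score` object or a bare non-negative Q value.
#' @param incidence Population stroke incidence, strictly between 0 and 1.
#' @return Non-negative numeric risk value.
#' @examples
#' individual_risk(combine_scores(c(1.485, 0.826)), incidence = 0.066)
#' @export
individual_risk <- function(combined, incidence) {
  if (!is.numeric(incidence) || length(incidence) != 1 ||
      incidence <= 0 || incidence >= 1) {
    stop("`incidence` must lie strictly between 0 and 1", call. = FALSE)
  }
  q <- if (inherits(combined, "combined_score")) combined$q_value else combined
  if (!is.numeric(q) || any(q < 0)) {
    stop("combined score must be non-negative", call. = FALSE)
  }
  incidence * q
}

#' Build a validated risk-factor panel
#'
#' Materialises a raw parameter table (one row per factor, columns `name`,
#' `prevalence`, `odds_ratio`, `beta`, `par_pct`) into a validated panel with
#' the derived Rothman-Keller columns `rho`, `score_exposed` and
#' `score_unexposed`.
#'
#' @param raw_params Data frame with the five parameter columns. `par_pct`
#'   may be `NA` when `par_fallback = TRUE`.
#' @param incidence Population incidence used as the individual-risk
#'   multiplier. Defaults to the 10-year cohort incidence 0.066.
#' @param par_fallback If `TRUE`, rows with missing `par_pct` are filled via
#'   [compute_par_levin()] from their prevalence and odds ratio; if `FALSE`
#'   (default) a missing `par_pct` is a validation error.
#' @return Object of class `risk_panel`: the validated data frame with
#'   derived columns and an `incidence` attribute.
#' @seealso [stroke_panel()] for the packaged 8-factor stroke panel.
#' @export
build_panel <- function(raw_params, incidence = 0.066, par_fallback = FALSE) {
  required <- c("name", "prevalence", "odds_ratio", "beta", "par_pct")
  missing_cols <- setdiff(required, names(raw_params))
  if (length(missing_cols) > 0) {
    stop("parameter table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  p <- as.data.frame(raw_params)[required]
  if (nrow(p) == 0) stop("parameter table has no rows", call. = FALSE)
  if (anyDuplicated(p$name)) {
    stop("factor names must be unique; duplicated: ",
         paste(unique(p$name[duplicated(p$name)]), collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(p))) {
    row_id <- sprintf("row %d (%s)", i, p$name[i])
    if (is.na(p$prevalence[i]) || p$prevalence[i] <= 0 || p$prevalence[i] >= 1) {
      stop(row_id, ": `prevalence` must lie strictly between 0 and 1", call. = FALSE)
    }
    if (is.na(p$odds_ratio[i]) || p$odds_ratio[i] <= 0) {
      stop(row_id, ": `odds_ratio` must be strictly positive", call. = FALSE)
    }
    if (is.na(p$beta[i])) {
      stop(row_id, ": `beta` is missing", call. = FALSE)
    }
    if (is.na(p$par_pct[i])) {
      if (!par_fallback) {
        stop(row_id, ": `par_pct` is missing (set `par_fallback = TRUE` to ",
             "fill it with Levin's formula)", call. = FALSE)
      }
      p$par_pct[i] <- compute_par_levin(p$prevalence[i], p$odds_ratio[i])
    }
    if (p$par_pct[i] < 0 || p$par_pct[i] >= 1) {
      stop(row_id, ": `par_pct` must lie in [0, 1)", call. = FALSE)
    }
  }
  p$rho <- baseline_ratio(p$par_pct)
  p$score_unexposed <- p$rho
  p$score_exposed <- p$rho * p$odds_ratio
  structure(p, class = c("risk_panel", "data.frame"), incidence = incidence)
}

#' @export
print.risk_panel <- function(x, ...) {
  cat(sprintf(
    "Rothman-Keller risk-factor panel: %d factors, incidence multiplier %.4g\n\n",
    nrow(x), attr(x, "incidence")
  ))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' The packaged 8-factor stroke risk panel
#'
#' Loads the parameter table for the eight screening risk factors
#' (hypertension, diabetes, dyslipidemia, heart disease, smoking, overweight,
#' physical inactivity, family history of stroke): literature exposure
#' prevalences, cohort-derived odds ratios and logistic coefficients, and
#' literature PAR\% values, with the derived Rothman-Keller columns.
#'
#' @param incidence Individual-risk multiplier; defaults to the cohort's
#'   observed 10-year stroke incidence, 0.066.
#' @return A `risk_panel` with 8 rows.
#' @examples
#' stroke_panel()
#' @export
stroke_panel <- function(incidence = 0.066) {
  path <- system.file("extdata", "risk_factor_params.csv", package = "strokeRK",
                      mustWork = TRUE)
  read_panel(path, incidence = incidence)
}

#' Read and write risk-factor parameter files
#'
#' The parameter file is comma-separated with header
#' `name,prevalence,odds_ratio,beta,par_pct`. Proportions are fractions;
#' a percentage is accepted only with an explicit `%` suffix (`"50.5%"`)
#' in the `prevalence` and `par_pct` columns.
#'
#' @param path File path.
#' @inheritParams build_panel
#' @return `read_panel()` returns a `risk_panel`; `write_panel()` invisibly
#'   returns `path` after writing the five raw parameter columns.
#' @export
read_panel <- function(path, incidence = 0.066, par_fallback = FALSE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("name", "prevalence", "odds_ratio", "beta", "par_pct")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("parameter file lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  parse_prop <- function(x, col) {
    pct <- grepl("%\\s*$", x)
    val <- suppressWarnings(as.numeric(sub("%\\s*$", "", x)))
    bad <- !is.na(x) & x != "" & is.na(val)
    if (any(bad)) {
      stop(sprintf("column `%s`: unparseable value '%s'", col, x[bad][1]),
           call. = FALSE)
    }
    val[pct] <- val[pct] / 100
    val
  }
  out <- data.frame(
    name = raw$name,
    prevalence = parse_prop(raw$prevalence, "prevalence"),
    odds_ratio = suppressWarnings(as.numeric(raw$odds_ratio)),
    beta = suppressWarnings(as.numeric(raw$beta)),
    par_pct = parse_prop(raw$par_pct, "par_pct"),
    stringsAsFactors = FALSE
  )
  build_panel(out, incidence = incidence, par_fallback = par_fallback)
}

#' @rdname read_panel
#' @param panel A `risk_panel`.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "risk_panel"))
  utils::write.csv(
    as.data.frame(panel)[c("name", "prevalence", "odds_ratio", "beta", "par_pct")],
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

# Names of the factors whose presence counts as chronic-disease history in
# the rule-based classifier.
chronic_disease_factors <- function() c("hypertension", "diabetes", "heart_disease")
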