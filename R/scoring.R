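#' Rule-based "8+2" risk classification
#'
#' Applies the national screening rule to the eight binary risk factors:
#' participants with 3 or more factors are **high** risk; participants with
#' fewer than 3 factors but a history of chronic disease (hypertension,
#' diabetes or heart disease) are **medium** risk; everyone else is **low**
#' risk. A count of exactly 3 satisfies both printed rules; high risk takes
#' precedence, matching the programme's intent of sensitive high-risk
#' capture.
#'
#' @param exposures Binary matrix or data frame with one column per factor
#'   (any columns named `history_*` or `participant_id`/`outcome` are
#'   ignored so a full cohort can be passed).
#' @param chronic_history Optional binary vector/matrix of chronic-disease
#'   history flags; by default the hypertension, diabetes and heart-disease
#'   exposure columns are used.
#' @return Ordered factor with levels `low < medium < high`, one per row.
#' @examples
#' coh <- generate_cohort(200, seed = 7)
#' table(classify_8plus2(coh))
#' @export
classify_8plus2 <- function(exposures, chronic_history = NULL) {
  x <- exposure_matrix(exposures)
  if (anyNA(x)) {
    stop("exposures contain missing values; classification needs complete ",
         "(post-imputation) data", call. = FALSE)
  }
  if (is.null(chronic_history)) {
    chronic_cols <- intersect(chronic_disease_factors(), colnames(x))
    if (length(chronic_cols) == 0) {
      stop("no chronic-disease columns found and `chronic_history` not given",
           call. = FALSE)
    }
    chronic <- rowSums(x[, chronic_cols, drop = FALSE]) > 0
  } else {
    ch <- as.matrix(chronic_history)
    chronic <- rowSums(ch, na.rm = FALSE) > 0
  }
  n_factors <- rowSums(x)
  cat_idx <- ifelse(n_factors >= 3, 3L, ifelse(chronic, 2L, 1L))
  risk_category(c("low", "medium", "high")[cat_idx])
}

# Ordered category factor used throughout.
risk_category <- function(x) {
  factor(x, levels = c("low", "medium", "high"), ordered = TRUE)
}

# Extract the factor columns of a cohort-like object as a numeric matrix.
exposure_matrix <- function(exposures, factors = NULL) {
  x <- as.data.frame(exposures)
  drop_cols <- c("participant_id", "outcome",
                 grep("^history_", names(x), value = TRUE))
  x <- x[setdiff(names(x), drop_cols)]
  if (!is.null(factors)) {
    missing <- setdiff(factors, names(x))
    if (length(missing) > 0) {
      stop("factor(s) absent from the data: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    x <- x[factors]
  }
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  bad <- !is.na(m) & m != 0 & m != 1
  if (any(bad)) {
    stop("exposure values must be 0, 1 or missing", call. = FALSE)
  }
  m
}

#' Fit a logistic risk model by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic regression of a binary outcome on the binary
#' risk factors, via Newton/IRLS iterated to a gradient norm below `tol`.
#' Returns coefficients, Wald standard errors, odds ratios with 95%
#' confidence intervals. Quasi-separation (fitted probabilities collapsing
#' to 0/1 with diverging coefficients) and non-convergence are reported as
#' errors, never as silent results.
#'
#' @param cohort Cohort data frame containing the factor columns and an
#'   `outcome` column, or an exposure matrix (then supply `outcome`).
#' @param outcome Optional binary outcome vector when `cohort` is a bare
#'   matrix.
#' @param max_iter Maximum Newton iterations.
#' @param tol Convergence threshold on the max absolute score (gradient).
#' @return Object of class `rk_logit`: list with `alpha`, `betas`, `se`,
#'   `odds_ratios` (with `ci_low`/`ci_high`), `n_iter`, `deviance`.
#' @examples
#' coh <- generate_cohort(5000, seed = 3)
#' fit <- fit_logistic(coh)
#' fit$odds_ratios
#' @export
fit_logistic <- function(cohort, outcome = NULL, max_iter = 50L, tol = 1e-8) {
  if (is.null(outcome)) {
    if (!"outcome" %in% names(as.data.frame(cohort))) {
      stop("`cohort` has no `outcome` column and `outcome` was not supplied",
           call. = FALSE)
    }
    outcome <- as.data.frame(cohort)$outcome
  }
  x <- exposure_matrix(cohort)
  if (anyNA(x) || anyNA(outcome)) {
    stop("logistic fitting requires complete exposures and outcomes", call. = FALSE)
  }
  y <- as.numeric(outcome)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, x)
  beta <- numeric(ncol(X))
  # start the intercept at the empirical log-odds
  beta[1] <- stats::qlogis(mean(y))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    p <- stats::plogis(drop(X %*% beta))
    grad <- drop(crossprod(X, y - p))
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    w <- p * (1 - p)
    if (min(w) < 1e-10 && max(abs(beta)) > 15) {
      stop("quasi-separation detected: fitted probabilities degenerate and ",
           "coefficients diverge", call. = FALSE)
    }
    info <- crossprod(X * w, X)
    step <- tryCatch(solve(info, grad), error = function(e) {
      stop("singular information matrix (collinear or constant factors)",
           call. = FALSE)
    })
    beta <- beta + step
  }
  if (!converged) {
    p <- stats::plogis(drop(X %*% beta))
    if (max(abs(drop(crossprod(X, y - p)))) >= tol) {
      stop("IRLS failed to converge in ", max_iter, " iterations", call. = FALSE)
    }
  }
  # under separation the score equation is satisfied only in the limit of
  # diverging coefficients, so a "converged" huge estimate is still degenerate
  if (max(abs(beta)) > 15) {
    stop("quasi-separation detected: coefficient estimates diverge",
         call. = FALSE)
  }
  p <- stats::plogis(drop(X %*% beta))
  info <- crossprod(X * (p * (1 - p)), X)
  se <- sqrt(diag(solve(info)))
  names(beta) <- names(se) <- colnames(X)
  z <- stats::qnorm(0.975)
  betas <- beta[-1]
  or_tab <- data.frame(
    factor = names(betas),
    beta = unname(betas),
    se = unname(se[-1]),
    or = exp(unname(betas)),
    ci_low = exp(unname(betas) - z * unname(se[-1])),
    ci_high = exp(unname(betas) + z * unname(se[-1])),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      alpha = unname(beta[1]), betas = betas, se = se,
      odds_ratios = or_tab, n_iter = it,
      deviance = -2 * sum(y * log(p) + (1 - y) * log1p(-p)),
      n = nrow(X)
    ),
    class = "rk_logit"
  )
}

#' @export
print.rk_logit <- function(x, ...) {
  cat(sprintf("Logistic risk model (IRLS, %d iterations, n = %d)\n", x$n_iter, x$n))
  cat(sprintf("Intercept alpha = %.4f\n\n", x$alpha))
  print(x$odds_ratios, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Predict logistic stroke risk
#'
#' Returns `plogis(alpha + sum(beta_j x_j))` for each participant.
#'
#' @param model An `rk_logit` fit, or a list with elements `alpha` and
#'   `betas` (e.g. a literature-parameterised model).
#' @param newdata Cohort data frame or exposure matrix with complete
#'   exposures for every model factor.
#' @return Numeric probability vector in (0, 1).
#' @export
predict_logistic <- function(model, newdata) {
  x <- exposure_matrix(newdata, factors = names(model$betas))
  if (anyNA(x)) stop("missing exposure values in `newdata`", call. = FALSE)
  unname(stats::plogis(model$alpha + drop(x %*% model$betas)))
}

#' Predict Rothman-Keller individual risk
#'
#' Scores each participant by selecting, per factor, the exposed or
#' unexposed stratum score from the panel, combining them with
#' [combine_scores()] and scaling by the panel's incidence via
#' [individual_risk()].
#'
#' @param panel A `risk_panel`.
#' @param newdata Cohort data frame or exposure matrix with complete
#'   exposures for every panel factor.
#' @return Non-negative numeric risk vector.
#' @examples
#' predict_rk(stroke_panel(), generate_cohort(100, seed = 1))[1:5]
#' @export
predict_rk <- function(panel, newdata) {
  stopifnot(inherits(panel, "risk_panel"))
  x <- exposure_matrix(newdata, factors = panel$name)
  if (anyNA(x)) stop("missing exposure values in `newdata`", call. = FALSE)
  # per-participant per-factor scores: exposed or unexposed stratum
  s <- x * rep(panel$score_exposed, each = nrow(x)) +
    (1 - x) * rep(panel$score_unexposed, each = nrow(x))
  elevated <- s >= 1
  k <- rowSums(elevated)
  sum_term <- ifelse(k >= 1, rowSums(s * elevated) - (k - 1), 1)
  prod_term <- exp(rowSums(log(s) * (1 - elevated)))
  unname(attr(panel, "incidence") * sum_term * prod_term)
}

#' Assign three-level risk categories from continuous risk values
#'
#' Applies two ordered cut points with half-open intervals, boundaries
#' belonging to the upper category: low when `value < t_low_med`, medium
#' when `t_low_med <= value < t_med_high`, high when `value >= t_med_high`.
#'
#' @param risk_values Numeric vector of continuous risk values.
#' @param thresholds A `threshold_set` (see [select_nodes()]) or a numeric
#'   vector `c(t_low_med, t_med_high)` with `t_low_med < t_med_high`.
#' @return Ordered factor with levels `low < medium < high`.
#' @examples
#' categorize(c(0.01, 0.0617, 0.2), c(0.0617, 0.1645))
#' @export
categorize <- function(risk_values, thresholds) {
  t <- if (inherits(thresholds, "threshold_set")) {
    c(thresholds$t_low_med, thresholds$t_med_high)
  } else {
    as.numeric(thresholds)
  }
  if (length(t) != 2 || anyNA(t) || t[1] >= t[2]) {
    stop("thresholds must be two ordered values with t_low_med < t_med_high",
         call. = FALSE)
  }
  idx <- 1L + (risk_values >= t[1]) + (risk_values >= t[2])
  risk_category(c("low", "medium", "high")[idx])
}

#' Write per-participant scores to a delimited file
#'
#' Scored-cohort files carry `participant_id`, `model_name`, `risk_value`
#' and `category`, one row per participant.
#'
#' @param ids Participant identifiers.
#' @param model_name Model label (`"score8plus2"`, `"logistic"` or
#'   `"rothman_keller"`).
#' @param risk_values Continuous risk values (the 0/1/2 ordinal for the
#'   rule-based score).
#' @param categories Ordered risk categories.
#' @param path Output file path.
#' @return Invisibly, the data frame written.
#' @export
write_scores <- function(ids, model_name, risk_values, categories, path) {
  df <- data.frame(
    participant_id = ids, model_name = model_name,
    risk_value = risk_values, category = as.character(categories),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
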