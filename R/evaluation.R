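# Build a pROC roc object with fixed orientation (higher score = more
# case-like), never letting pROC auto-flip the direction.
proc_roc <- function(risk_values, outcomes) {
  outcomes <- as.integer(outcomes)
  if (length(risk_values) != length(outcomes)) {
    stop("scores and outcomes differ in length", call. = FALSE)
  }
  if (!all(outcomes %in% c(0L, 1L))) {
    stop("outcomes must be binary 0/1", call. = FALSE)
  }
  if (length(unique(outcomes)) < 2) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  pROC::roc(response = outcomes, predictor = as.numeric(risk_values),
            levels = c(0, 1), direction = "<", quiet = TRUE)
}

#' ROC area under the curve with DeLong confidence interval
#'
#' Computes the AUC as the Mann-Whitney statistic with midrank tie handling
#' (the probability a random case outscores a random control, plus half the
#' tie probability), its variance by DeLong's structural-components method,
#' and a Wald 95% confidence interval truncated to `[0, 1]`. The rule-based
#' three-level score enters as an ordinal 0/1/2 predictor.
#'
#' @param risk_values Numeric risk scores (higher = riskier).
#' @param outcomes Binary 0/1 outcome vector.
#' @return Object of class `auc_result`: list with `auc`, `ci_low`,
#'   `ci_high`, `variance`, `n_cases`, `n_controls`.
#' @examples
#' roc_auc(c(1, 4, 3, 5), c(0, 0, 1, 1))
#' @export
roc_auc <- function(risk_values, outcomes) {
  r <- proc_roc(risk_values, outcomes)
  auc <- as.numeric(r$auc)
  # for a degenerate AUC of 0 or 1 the structural-component variance is
  # exactly 0; pROC flags this with an advisory warning we do not propagate
  v <- as.numeric(suppressWarnings(pROC::var(r, method = "delong")))
  hw <- stats::qnorm(0.975) * sqrt(v)
  structure(
    list(
      auc = auc,
      ci_low = max(0, auc - hw), ci_high = min(1, auc + hw),
      variance = v,
      n_cases = sum(outcomes == 1), n_controls = sum(outcomes == 0)
    ),
    class = "auc_result"
  )
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (95%% CI %.3f-%.3f), DeLong variance %.3g\n",
              x$auc, x$ci_low, x$ci_high, x$variance))
  invisible(x)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Two-sided Z test for the difference between the AUCs of two risk models
#' scored on the same participants, using the paired covariance of DeLong
#' structural components. Identical score vectors — or any pair whose AUC
#' difference and its variance both vanish, e.g. strictly monotone
#' transforms of one another — give Z = 0, p = 1.
#'
#' @param risk_values_a,risk_values_b Paired score vectors for the two
#'   models.
#' @param outcomes Binary 0/1 outcome vector.
#' @return List with `z`, `p_value`, `auc_a`, `auc_b`, `delta_auc`.
#' @examples
#' y <- rep(c(0, 1), each = 10)
#' delong_test(seq_len(20), rev(seq_len(20)), y)
#' @export
delong_test <- function(risk_values_a, risk_values_b, outcomes) {
  if (length(risk_values_a) != length(risk_values_b)) {
    stop("the two score vectors differ in length", call. = FALSE)
  }
  ra <- proc_roc(risk_values_a, outcomes)
  rb <- proc_roc(risk_values_b, outcomes)
  auc_a <- as.numeric(ra$auc)
  auc_b <- as.numeric(rb$auc)
  delta <- auc_a - auc_b
  if (isTRUE(all.equal(as.numeric(risk_values_a),
                       as.numeric(risk_values_b), tolerance = 0))) {
    z <- 0; p <- 1
  } else {
    tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
    z <- as.numeric(tst$statistic)
    p <- as.numeric(tst$p.value)
    if (!is.finite(z)) { # zero-variance difference (e.g. monotone transform)
      z <- 0; p <- 1
    }
  }
  list(z = z, p_value = p, auc_a = auc_a, auc_b = auc_b, delta_auc = delta)
}

#' Sensitivity and specificity of a three-level classification
#'
#' Collapses the three risk categories to a binary screen-positive call and
#' counts true/false positives against the outcome. The default rule treats
#' medium or high risk as positive (any elevated category triggers
#' follow-up); `"high_only"` restricts positivity to the high-risk group.
#'
#' @param categories Ordered risk categories (`low`/`medium`/`high`).
#' @param outcomes Binary 0/1 outcome vector.
#' @param positive_rule `"medium_or_high"` (default) or `"high_only"`.
#' @return List with `sensitivity`, `specificity`, `positive_rule` and the
#'   2x2 counts `tp`, `fp`, `tn`, `fn`.
#' @export
sens_spec <- function(categories, outcomes,
                      positive_rule = c("medium_or_high", "high_only")) {
  positive_rule <- match.arg(positive_rule)
  categories <- risk_category(as.character(categories))
  if (anyNA(categories)) stop("categories must be low/medium/high", call. = FALSE)
  outcomes <- as.integer(outcomes)
  if (sum(outcomes == 1) == 0 || sum(outcomes == 0) == 0) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  positive <- if (positive_rule == "high_only") {
    categories == "high"
  } else {
    categories >= "medium"
  }
  tp <- sum(positive & outcomes == 1)
  fn <- sum(!positive & outcomes == 1)
  tn <- sum(!positive & outcomes == 0)
  fp <- sum(positive & outcomes == 0)
  list(
    sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    positive_rule = positive_rule, tp = tp, fp = fp, tn = tn, fn = fn
  )
}

#' Cross-tabulate risk reclassification by event status
#'
#' Builds the two 3x3 tables (events and non-events separately) of old
#' against new risk categories that underlie the categorical net
#' reclassification improvement: the diagonal holds unchanged
#' classifications, cells above the diagonal are moves to a higher risk
#' category.
#'
#' @param categories_old,categories_new Ordered risk categories under the
#'   reference and the candidate model.
#' @param outcomes Binary 0/1 outcome vector.
#' @return Object of class `reclass_table`: list with `counts_events` and
#'   `counts_nonevents` (3x3 matrices, rows = old, cols = new) and
#'   `category_order`.
#' @export
reclassification_table <- function(categories_old, categories_new, outcomes) {
  if (length(categories_old) != length(categories_new) ||
      length(categories_old) != length(outcomes)) {
    stop("inputs differ in length", call. = FALSE)
  }
  old <- risk_category(as.character(categories_old))
  new <- risk_category(as.character(categories_new))
  if (anyNA(old) || anyNA(new)) {
    stop("categories must be low/medium/high", call. = FALSE)
  }
  outcomes <- as.integer(outcomes)
  tab <- function(keep) {
    m <- table(old = old[keep], new = new[keep])
    matrix(as.integer(m), nrow = 3, dimnames = dimnames(m))
  }
  structure(
    list(
      counts_events = tab(outcomes == 1),
      counts_nonevents = tab(outcomes == 0),
      category_order = c("low", "medium", "high")
    ),
    class = "reclass_table"
  )
}

#' @export
print.reclass_table <- function(x, ...) {
  cat("Reclassification (rows = old category, cols = new)\nEvents:\n")
  print(x$counts_events)
  cat("Non-events:\n")
  print(x$counts_nonevents)
  invisible(x)
}

#' Categorical net reclassification improvement
#'
#' For events, moving to a higher risk category is an improvement; for
#' non-events, moving lower is. The stratum components are
#' `nri_events = (up_e - down_e) / n_events` and
#' `nri_nonevents = (down_ne - up_ne) / n_nonevents`; the absolute NRI is
#' their sum, in `[-2, 2]`. Significance uses the standard asymptotic Z with
#' per-stratum variance `(up + down) / n^2` and a two-sided p value.
#'
#' @param table A `reclass_table` from [reclassification_table()].
#' @return Object of class `nri_result`: list with `nri_events`,
#'   `nri_nonevents`, `absolute_nri`, `z_stat`, `p_value`.
#' @examples
#' old <- rep(c("low", "medium"), 50); new <- rep(c("medium", "low"), 50)
#' y <- rep(c(1, 0), 50)
#' nri(reclassification_table(old, new, y))
#' @export
nri <- function(table) {
  stopifnot(inherits(table, "reclass_table"))
  up_down <- function(m) {
    c(up = sum(m[upper.tri(m)]), down = sum(m[lower.tri(m)]), n = sum(m))
  }
  e <- up_down(table$counts_events)
  ne <- up_down(table$counts_nonevents)
  if (e[["n"]] == 0 || ne[["n"]] == 0) {
    stop("both an event and a non-event stratum are required", call. = FALSE)
  }
  nri_e <- (e[["up"]] - e[["down"]]) / e[["n"]]
  nri_ne <- (ne[["down"]] - ne[["up"]]) / ne[["n"]]
  absolute <- nri_e + nri_ne
  v <- (e[["up"]] + e[["down"]]) / e[["n"]]^2 +
    (ne[["up"]] + ne[["down"]]) / ne[["n"]]^2
  z <- if (v > 0) absolute / sqrt(v) else 0
  structure(
    list(
      nri_events = nri_e, nri_nonevents = nri_ne, absolute_nri = absolute,
      z_stat = z, p_value = if (v > 0) 2 * stats::pnorm(-abs(z)) else 1
    ),
    class = "nri_result"
  )
}

#' @export
print.nri_result <- function(x, ...) {
  cat(sprintf(
    "NRI: events %+.3f, non-events %+.3f, absolute %+.3f (Z = %.3f, p = %.3g)\n",
    x$nri_events, x$nri_nonevents, x$absolute_nri, x$z_stat, x$p_value
  ))
  invisible(x)
}
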