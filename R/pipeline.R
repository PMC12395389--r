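#' Assemble a pipeline configuration
#'
#' Collects every knob of the end-to-end run in one validated list:
#' generator settings, threshold-simulation settings (size, per-model node
#' ranks), evaluation settings and the master seed. All stage seeds are
#' substreams of the master seed, so a rerun with the same configuration is
#' bit-identical.
#'
#' @param n Cohort size; defaults to the study cohort's 11,692.
#' @param target_incidence Expected outcome incidence for intercept
#'   calibration.
#' @param sim_n Monte-Carlo population size for threshold derivation.
#' @param ranks_logistic,ranks_rk Node ranks for the two continuous models.
#' @param positive_rule Binarization rule for sensitivity/specificity.
#' @param missing_rates Optional named MCAR missingness rates (a pipeline
#'   run requires complete data, so nonzero rates are only useful for
#'   exercising [validate_cohort_file()]).
#' @param seed Master integer seed.
#' @return Object of class `pipeline_config` (a list).
#' @export
pipeline_config <- function(n = 11692L, target_incidence = 0.066,
                            sim_n = 100000L,
                            ranks_logistic = c(25844L, 77778L),
                            ranks_rk = c(25426L, 64553L),
                            positive_rule = "medium_or_high",
                            missing_rates = NULL, seed = 1L) {
  cfg <- list(
    n = as.integer(n), target_incidence = target_incidence,
    sim_n = as.integer(sim_n),
    ranks_logistic = as.integer(ranks_logistic), ranks_rk = as.integer(ranks_rk),
    positive_rule = match.arg(positive_rule, c("medium_or_high", "high_only")),
    missing_rates = missing_rates, seed = as.integer(seed)
  )
  if (cfg$n < 100) stop("`n` must be at least 100", call. = FALSE)
  if (any(cfg$ranks_logistic < 1) || any(cfg$ranks_rk < 1) ||
      cfg$ranks_logistic[1] >= cfg$ranks_logistic[2] ||
      cfg$ranks_rk[1] >= cfg$ranks_rk[2] ||
      max(cfg$ranks_logistic, cfg$ranks_rk) > cfg$sim_n) {
    stop("node ranks must be ordered and within 1..sim_n", call. = FALSE)
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()], optionally nested under
#' `generator` (`n`, `target_incidence`, `missing_rates`), `thresholds`
#' (`sim_n`, `ranks_logistic`, `ranks_rk`), `evaluation` (`positive_rule`)
#' and a top-level `seed`.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  flat <- c(y$generator, y$thresholds, y$evaluation,
            y[setdiff(names(y), c("generator", "thresholds", "evaluation"))])
  # YAML 1.1 reads a bare `n` key as boolean; restore the cohort-size name
  names(flat)[names(flat) %in% c("FALSE", "false")] <- "n"
  args <- flat[intersect(names(flat), names(formals(pipeline_config)))]
  if (!is.null(args$missing_rates)) args$missing_rates <- unlist(args$missing_rates)
  do.call(pipeline_config, args)
}

#' Run the full validation pipeline
#'
#' Executes generate -> fit logistic -> derive thresholds (both continuous
#' models) -> score (three models) -> evaluate, and writes every artifact
#' (cohort, thresholds, per-model scores, evaluation summary and a
#' machine-readable provenance record) to `out_dir`. The "8+2" baseline is
#' always computed from the raw exposures by its counting rule, never from
#' thresholds. Evaluation reports per-model AUCs with confidence intervals,
#' the three pairwise DeLong comparisons, sensitivity/specificity under both
#' binarization rules, and the NRI of each continuous model against the
#' rule-based baseline.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created if absent); `NULL` skips all
#'   file output.
#' @return Invisibly, a list with `cohort`, `fit`, `thresholds`, `scores`,
#'   `categories`, `evaluation` and `config`.
#' @examples
#' \donttest{
#' res <- run_pipeline(pipeline_config(n = 2000, sim_n = 5000,
#'                                     ranks_logistic = c(1250, 3900),
#'                                     ranks_rk = c(1270, 3230), seed = 11))
#' res$evaluation$auc$rothman_keller
#' }
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  panel <- stroke_panel(incidence = config$target_incidence)

  cohort <- stage("generate", generate_cohort(
    n = config$n, panel = panel, target_incidence = config$target_incidence,
    missing_rates = config$missing_rates, seed = substream_seed(config$seed, 10)
  ))
  fit <- stage("fit", fit_logistic(cohort))
  thr <- stage("thresholds", list(
    logistic = derive_thresholds("logistic", panel, config$sim_n,
                                 seed = substream_seed(config$seed, 20),
                                 ranks = config$ranks_logistic),
    rothman_keller = derive_thresholds("rk", panel, config$sim_n,
                                       seed = substream_seed(config$seed, 30),
                                       ranks = config$ranks_rk)
  ))
  scores <- stage("score", {
    cat8 <- classify_8plus2(cohort)
    list(
      score8plus2 = as.integer(cat8) - 1L, # ordinal 0/1/2
      logistic = predict_logistic(fit, cohort),
      rothman_keller = predict_rk(panel, cohort)
    )
  })
  categories <- list(
    score8plus2 = risk_category(c("low", "medium", "high")[scores$score8plus2 + 1L]),
    logistic = categorize(scores$logistic, thr$logistic),
    rothman_keller = categorize(scores$rothman_keller, thr$rothman_keller)
  )
  evaluation <- stage("evaluate", {
    y <- cohort$outcome
    auc <- lapply(scores, roc_auc, outcomes = y)
    delong <- list(
      logistic_vs_8plus2 = delong_test(scores$logistic, scores$score8plus2, y),
      rk_vs_8plus2 = delong_test(scores$rothman_keller, scores$score8plus2, y),
      rk_vs_logistic = delong_test(scores$rothman_keller, scores$logistic, y)
    )
    ss <- lapply(categories, function(cats) {
      list(medium_or_high = sens_spec(cats, y, "medium_or_high"),
           high_only = sens_spec(cats, y, "high_only"))
    })
    nri_res <- list(
      logistic_vs_8plus2 = nri(reclassification_table(
        categories$score8plus2, categories$logistic, y)),
      rk_vs_8plus2 = nri(reclassification_table(
        categories$score8plus2, categories$rothman_keller, y))
    )
    incidence_by_group <- lapply(categories, function(cats) {
      tapply(y, cats, mean)
    })
    list(auc = auc, delong = delong, sens_spec = ss, nri = nri_res,
         incidence_by_group = incidence_by_group)
  })
  result <- list(cohort = cohort, fit = fit, thresholds = thr,
                 scores = scores, categories = categories,
                 evaluation = evaluation, config = config)
  if (!is.null(out_dir)) stage("write", write_run_artifacts(result, out_dir))
  invisible(result)
}

# Serialise run artifacts: cohort, thresholds, scores, a human-readable
# summary and a JSON provenance record (config + seeds + fixture columns).
write_run_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(result$cohort, file.path(out_dir, "cohort.csv"))
  write_thresholds(result$thresholds, file.path(out_dir, "thresholds.csv"))
  for (m in names(result$scores)) {
    write_scores(result$cohort$participant_id, m, result$scores[[m]],
                 result$categories[[m]], file.path(out_dir, paste0("scores_", m, ".csv")))
  }
  ev <- result$evaluation
  lines <- c(
    "Model evaluation summary",
    "========================",
    vapply(names(ev$auc), function(m) {
      a <- ev$auc[[m]]
      sprintf("AUC %-15s %.3f (95%% CI %.3f-%.3f)", m, a$auc, a$ci_low, a$ci_high)
    }, character(1)),
    vapply(names(ev$delong), function(k) {
      d <- ev$delong[[k]]
      sprintf("DeLong %-20s Z = %.3f, p = %.4g", k, d$z, d$p_value)
    }, character(1)),
    vapply(names(ev$nri), function(k) {
      x <- ev$nri[[k]]
      sprintf("NRI %-20s events %+.3f, non-events %+.3f, absolute %+.3f (p = %.3g)",
              k, x$nri_events, x$nri_nonevents, x$absolute_nri, x$p_value)
    }, character(1))
  )
  writeLines(lines, file.path(out_dir, "summary.txt"))
  prov <- list(
    config = unclass(result$config),
    alpha = attr(result$cohort, "alpha"),
    panel_factors = attr(result$cohort, "panel_factors"),
    r_version = as.character(getRversion())
  )
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Validate a cohort file
#'
#' Schema-checks a delimited cohort file: required columns, binary exposure
#' domains (0/1/empty), binary outcome, and non-emptiness. Errors are
#' collected, each addressed by row and column, rather than stopping at the
#' first.
#'
#' @param path Cohort file path.
#' @param factors Factor columns expected; defaults to the packaged panel's
#'   eight factors.
#' @return The validated cohort data frame; if validation fails, an error
#'   whose message lists every violation.
#' @export
validate_cohort_file <- function(path, factors = stroke_panel()$name) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                    check.names = FALSE),
    error = function(e) stop("unreadable cohort file: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (nrow(df) == 0) stop("cohort file contains no records", call. = FALSE)
  errors <- character(0)
  for (col in setdiff(c(factors, "outcome"), names(df))) {
    errors <- c(errors, sprintf("missing column `%s`", col))
  }
  for (col in intersect(factors, names(df))) {
    bad <- which(!is.na(df[[col]]) & !(df[[col]] %in% c(0, 1)))
    for (i in utils::head(bad, 5)) {
      errors <- c(errors, sprintf("row %d, column `%s`: value '%s' not in {0, 1}",
                                  i, col, df[[col]][i]))
    }
  }
  if ("outcome" %in% names(df)) {
    bad <- which(is.na(df$outcome) | !(df$outcome %in% c(0, 1)))
    for (i in utils::head(bad, 5)) {
      errors <- c(errors, sprintf("row %d, column `outcome`: value '%s' invalid",
                                  i, df$outcome[i]))
    }
  }
  if (length(errors) > 0) {
    stop("cohort validation failed:\n", paste("-", errors, collapse = "\n"),
         call. = FALSE)
  }
  df
}
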