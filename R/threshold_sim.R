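#' Simulate the risk-score distribution of a model
#'
#' Draws `sim_n` exposure profiles from independent Bernoulli draws at the
#' panel's literature prevalences and scores each profile with the requested
#' model, without generating outcomes (cut points depend only on the score
#' distribution). This reproduces the Monte-Carlo population used to place
#' the risk-category nodes (100,000 records in the reference procedure).
#'
#' @param model `"rk"` or `"logistic"`.
#' @param panel A `risk_panel` supplying prevalences and, for the logistic
#'   model, coefficients.
#' @param sim_n Number of simulated participants (at least 1000).
#' @param seed Integer RNG seed.
#' @param alpha Intercept for the logistic model: `"auto"` calibrates it to
#'   the panel's incidence attribute over the simulated profiles.
#' @return Ascending-sorted numeric vector of length `sim_n` with attributes
#'   `model_name`, `seed`, `alpha` (logistic only).
#' @examples
#' r <- simulate_score_distribution("rk", stroke_panel(), sim_n = 2000, seed = 9)
#' range(r)
#' @export
simulate_score_distribution <- function(model = c("rk", "logistic"),
                                        panel = stroke_panel(),
                                        sim_n = 100000L, seed = 1L,
                                        alpha = "auto") {
  model <- match.arg(model)
  if (sim_n < 1000) stop("`sim_n` must be at least 1000", call. = FALSE)
  rates <- stats::setNames(panel$prevalence, panel$name)
  x <- simulate_exposures(sim_n, rates, seed = seed)
  if (model == "rk") {
    scores <- predict_rk(panel, x)
    a <- NA_real_
  } else {
    betas <- stats::setNames(panel$beta, panel$name)
    a <- if (identical(alpha, "auto")) {
      calibrate_alpha(betas, x, attr(panel, "incidence"))
    } else {
      alpha
    }
    scores <- stats::plogis(a + linear_predictor(x, betas))
  }
  structure(sort(scores, method = "radix"),
            model_name = if (model == "rk") "rothman_keller" else "logistic",
            seed = seed, alpha = a)
}

#' Select risk-category nodes at fixed ranks
#'
#' Picks the two cut points as the risk values at given positions of the
#' ascending-sorted simulated score vector (stable rank semantics: the value
#' at the exact rank, ties left in index order). The shipped default ranks
#' are the node positions observed in the reference 100,000-record run:
#' 25844/77778 for the logistic model and 25426/64553 for the
#' Rothman-Keller model.
#'
#' @param sorted_risks Ascending-sorted numeric vector (as returned by
#'   [simulate_score_distribution()]).
#' @param rank_low_med,rank_med_high Integer ranks with
#'   `1 <= rank_low_med < rank_med_high <= length(sorted_risks)`.
#' @param model_name Optional model label (defaults to the vector's
#'   attribute).
#' @return Object of class `threshold_set`: list with `model_name`,
#'   `t_low_med`, `t_med_high`, `rank_low_med`, `rank_med_high`, `sim_n`,
#'   `seed`. Equal values at the two ranks (a degenerate, e.g. constant,
#'   distribution) are an error.
#' @export
select_nodes <- function(sorted_risks, rank_low_med, rank_med_high,
                         model_name = NULL) {
  n <- length(sorted_risks)
  if (is.unsorted(sorted_risks)) {
    stop("`sorted_risks` must be ascending-sorted", call. = FALSE)
  }
  if (rank_low_med < 1 || rank_med_high > n || rank_low_med >= rank_med_high) {
    stop("ranks must satisfy 1 <= rank_low_med < rank_med_high <= sim_n",
         call. = FALSE)
  }
  t1 <- sorted_risks[[rank_low_med]]
  t2 <- sorted_risks[[rank_med_high]]
  if (t1 >= t2) {
    stop("degenerate thresholds: the risk values at the two ranks coincide",
         call. = FALSE)
  }
  structure(
    list(
      model_name = model_name %||% attr(sorted_risks, "model_name") %||% "unknown",
      t_low_med = t1, t_med_high = t2,
      rank_low_med = as.integer(rank_low_med),
      rank_med_high = as.integer(rank_med_high),
      sim_n = n, seed = attr(sorted_risks, "seed")
    ),
    class = "threshold_set"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf(
    "Risk thresholds [%s]: low/medium %.8g (rank %d), medium/high %.8g (rank %d); sim_n = %d\n",
    x$model_name, x$t_low_med, x$rank_low_med, x$t_med_high, x$rank_med_high, x$sim_n
  ))
  invisible(x)
}

#' Derive model thresholds by Monte-Carlo simulation
#'
#' Convenience wrapper: simulates the score distribution and selects the
#' nodes at the model's replication ranks.
#'
#' @inheritParams simulate_score_distribution
#' @param ranks Integer vector of two node ranks; defaults to the observed
#'   replication ranks of each model.
#' @return A `threshold_set`.
#' @examples
#' derive_thresholds("rk", sim_n = 5000, seed = 2, ranks = c(1271, 3228))
#' @export
derive_thresholds <- function(model = c("rk", "logistic"),
                              panel = stroke_panel(), sim_n = 100000L,
                              seed = 1L, ranks = NULL, alpha = "auto") {
  model <- match.arg(model)
  if (is.null(ranks)) {
    ranks <- if (model == "rk") c(25426L, 64553L) else c(25844L, 77778L)
    if (sim_n != 100000L) {
      stop("default replication ranks assume sim_n = 100000; supply `ranks`",
           call. = FALSE)
    }
  }
  sorted <- simulate_score_distribution(model, panel, sim_n, seed, alpha)
  select_nodes(sorted, ranks[1], ranks[2])
}

#' Exhaustively enumerate the 2^k exposure profiles of a panel
#'
#' Builds the full table of exposure profiles with each profile's Bernoulli
#' probability under the panel prevalences, its combined score Q and its
#' individual risk. Serves as the exact oracle for the Monte-Carlo
#' simulation: the simulated support is a subset of these values and the
#' exact expectation `sum(prob * risk)` bounds the simulation mean.
#'
#' @param panel A `risk_panel` (8 factors gives 256 rows).
#' @return Data frame with one 0/1 column per factor plus `prob`, `q_value`
#'   and `risk`; `prob` sums to 1 within 1e-12.
#' @examples
#' prof <- enumerate_profiles(stroke_panel())
#' sum(prof$prob)
#' @export
enumerate_profiles <- function(panel) {
  stopifnot(inherits(panel, "risk_panel"))
  k <- nrow(panel)
  grid <- as.matrix(expand.grid(rep(list(0:1), k)))
  colnames(grid) <- panel$name
  prob <- apply(grid, 1, function(x) {
    prod(ifelse(x == 1, panel$prevalence, 1 - panel$prevalence))
  })
  risk <- predict_rk(panel, grid)
  out <- data.frame(grid, prob = prob, risk = risk)
  out$q_value <- risk / attr(panel, "incidence")
  out
}

#' Read and write threshold files
#'
#' Threshold files are comma-separated with columns `model_name`,
#' `t_low_med`, `t_med_high`, `rank_low_med`, `rank_med_high`, `sim_n`,
#' `seed`, one row per model.
#'
#' @param path File path.
#' @return `read_thresholds()` returns a list of `threshold_set` objects
#'   named by model; `write_thresholds()` invisibly returns `path`.
#' @export
read_thresholds <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    structure(
      list(
        model_name = df$model_name[i],
        t_low_med = df$t_low_med[i], t_med_high = df$t_med_high[i],
        rank_low_med = as.integer(df$rank_low_med[i]),
        rank_med_high = as.integer(df$rank_med_high[i]),
        sim_n = as.integer(df$sim_n[i]), seed = df$seed[i]
      ),
      class = "threshold_set"
    )
  })
  stats::setNames(out, df$model_name)
}

#' @rdname read_thresholds
#' @param thresholds A `threshold_set` or list of them.
#' @export
write_thresholds <- function(thresholds, path) {
  if (inherits(thresholds, "threshold_set")) thresholds <- list(thresholds)
  df <- do.call(rbind, lapply(thresholds, function(t) {
    data.frame(
      model_name = t$model_name, t_low_med = t$t_low_med,
      t_med_high = t$t_med_high, rank_low_med = t$rank_low_med,
      rank_med_high = t$rank_med_high, sim_n = t$sim_n,
      seed = t$seed %||% NA, stringsAsFactors = FALSE
    )
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
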