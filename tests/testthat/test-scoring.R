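make_record <- function(exposed = character(0)) {
  x <- as.data.frame(as.list(setNames(rep(0L, 8), stroke_panel()$name)))
  x[exposed] <- 1L
  x
}

test_that("the 8+2 rule classifies by factor count then chronic history", {
  expect_equal(
    as.character(classify_8plus2(make_record(c("hypertension", "dyslipidemia", "overweight")))),
    "high"
  )
  expect_equal(as.character(classify_8plus2(make_record("hypertension"))), "medium")
  expect_equal(
    as.character(classify_8plus2(make_record(c("smoking", "overweight")))),
    "low"
  )
  # exactly 3 factors: the high-risk rule takes precedence
  expect_equal(
    as.character(classify_8plus2(make_record(c("smoking", "overweight", "family_history")))),
    "high"
  )
  # explicit chronic-history flags override the exposure-derived default
  expect_equal(
    as.character(classify_8plus2(make_record("smoking"), chronic_history = 1L)),
    "medium"
  )
})

test_that("the 8+2 rule partitions every record into exactly one category", {
  coh <- generate_cohort(5000, seed = 55)
  cats <- classify_8plus2(coh)
  expect_equal(length(cats), 5000)
  expect_false(anyNA(cats))
  expect_equal(sum(table(cats)), 5000)

  missing <- inject_missingness(coh, c(hypertension = 0.1), seed = 1)
  expect_error(classify_8plus2(missing), "missing")
})

test_that("single-factor logistic fit reproduces the 2x2 cross-product odds ratio", {
  # a = 50 exposed cases, b = 50 exposed non-cases, c = 25, d = 100
  x <- matrix(c(rep(1L, 100), rep(0L, 125)), dimnames = list(NULL, "exposed"))
  y <- c(rep(1, 50), rep(0, 50), rep(1, 25), rep(0, 100))
  fit <- fit_logistic(x, outcome = y)
  expect_equal(exp(unname(fit$betas)), (50 * 100) / (50 * 25), tolerance = 1e-8)

  # independent route: stats::glm on the same data
  g <- stats::glm(y ~ x, family = stats::binomial())
  expect_equal(unname(fit$alpha), unname(stats::coef(g)[1]), tolerance = 1e-6)
  expect_equal(unname(fit$betas), unname(stats::coef(g)[2]), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(summary(g)$coefficients[, 2]),
               tolerance = 1e-5)
})

test_that("multi-factor IRLS agrees with glm and recovers generating coefficients", {
  coh <- generate_cohort(20000, seed = 42)
  fit <- fit_logistic(coh)
  g <- stats::glm(
    outcome ~ hypertension + diabetes + dyslipidemia + heart_disease +
      smoking + overweight + physical_inactivity + family_history,
    family = stats::binomial(), data = coh
  )
  expect_equal(unname(c(fit$alpha, fit$betas)), unname(stats::coef(g)),
               tolerance = 1e-6)

  # generating truth inside Wald 95% CI for the two strongest factors
  panel <- stroke_panel()
  for (f in c("hypertension", "diabetes")) {
    b <- fit$betas[[f]]; s <- fit$se[[f]]
    expect_lt(abs(b - panel$beta[panel$name == f]), 1.96 * s)
  }
})

test_that("logistic fitting reports degenerate inputs instead of silent results", {
  x <- matrix(c(0L, 0L, 1L, 1L), dimnames = list(NULL, "f"))
  expect_error(fit_logistic(x, outcome = c(1, 1, 1, 1)), "both outcome classes")
  # perfectly separated factor
  xs <- matrix(rep(c(0L, 1L), each = 50), dimnames = list(NULL, "f"))
  expect_error(fit_logistic(xs, outcome = rep(c(0, 1), each = 50)), "separation")
  # constant column
  xc <- cbind(f = rep(1L, 100))
  expect_error(fit_logistic(xc, outcome = rep(c(0, 1), 50)), "singular")
})

test_that("under a null model fitted coefficients stay within 3 standard errors", {
  hits <- 0L; total <- 0L
  for (seed in 1:25) {
    x <- simulate_exposures(800, c(a = 0.4, b = 0.2, c = 0.6), seed = seed)
    set.seed(seed + 1000)
    y <- rbinom(800, 1, 0.15)
    fit <- fit_logistic(x, outcome = y)
    hits <- hits + sum(abs(fit$betas) < 3 * fit$se[-1])
    total <- total + 3L
  }
  expect_gte(hits / total, 0.95)
})

test_that("logistic prediction is the inverse-logit of the linear predictor", {
  model <- list(alpha = 0, betas = setNames(rep(0.5, 8), stroke_panel()$name))
  expect_equal(predict_logistic(model, make_record()), 0.5)
  model$alpha <- qlogis(0.066)
  expect_equal(predict_logistic(model, make_record()), 0.066)
  # monotone in any positive-coefficient factor
  p0 <- predict_logistic(model, make_record())
  p1 <- predict_logistic(model, make_record("smoking"))
  expect_gt(p1, p0)
  expect_error(
    predict_logistic(model, transform(make_record(), hypertension = NA)),
    "missing"
  )
})

test_that("Rothman-Keller prediction composes stratum scores, Q and incidence", {
  panel <- stroke_panel()
  expect_equal(predict_rk(panel, make_record()), 0.005975022, tolerance = 1e-7)

  # all-exposed record against the explicit per-record route
  rec <- make_record(panel$name)
  q <- combine_scores(panel$score_exposed)$q_value
  expect_equal(predict_rk(panel, rec), individual_risk(q, 0.066))
  expect_equal(predict_rk(panel, rec), 0.0507977505, tolerance = 1e-9)

  expect_gt(predict_rk(panel, make_record("hypertension")),
            predict_rk(panel, make_record()))
  expect_error(predict_rk(panel, transform(make_record(), smoking = NA)), "missing")
  expect_error(predict_rk(panel, make_record()[, -1]), "absent")
})

test_that("an all-neutral panel returns the population incidence for everyone", {
  neutral <- build_panel(data.frame(
    name = stroke_panel()$name, prevalence = 0.5, odds_ratio = 1,
    beta = 0, par_pct = 0
  ), incidence = 0.066)
  coh <- generate_cohort(500, seed = 3)
  expect_equal(predict_rk(neutral, coh), rep(0.066, 500))
})

test_that("vectorised RK scores equal the per-record combine/risk route", {
  panel <- stroke_panel()
  coh <- generate_cohort(200, seed = 17)
  x <- coh[, panel$name]
  expected <- vapply(seq_len(nrow(x)), function(i) {
    s <- ifelse(x[i, ] == 1, panel$score_exposed, panel$score_unexposed)
    individual_risk(combine_scores(as.numeric(s)), 0.066)
  }, numeric(1))
  expect_equal(predict_rk(panel, coh), expected)
})

test_that("categorization uses half-open intervals with boundaries going up", {
  expect_equal(as.character(categorize(0.0617, c(0.0617, 0.1645))), "medium")
  expect_equal(as.character(categorize(0.01, c(0.0617, 0.1645))), "low")
  expect_equal(as.character(categorize(0.1645, c(0.0617, 0.1645))), "high")
  expect_equal(as.character(categorize(0.005, c(0.0022, 0.0048))), "high")
  expect_error(categorize(0.1, c(0.2, 0.1)), "ordered")

  # monotone: sorting by risk never yields a higher category before a lower
  v <- sort(runif(200))
  cats <- categorize(v, c(0.3, 0.7))
  expect_true(all(diff(as.integer(cats)) >= 0))
})
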