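test_that("AUC equals the all-pairs Mann-Whitney statistic with midrank ties", {
  # perfectly separated scores
  expect_equal(roc_auc(c(1, 2, 9, 10), c(0, 0, 1, 1))$auc, 1)
  # hand-enumerated fixture: cases {3, 5}, controls {1, 4} -> 3/4
  expect_equal(roc_auc(c(1, 4, 3, 5), c(0, 0, 1, 1))$auc, 0.75)

  set.seed(202)
  for (i in 1:30) {
    n <- sample(20:200, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.3)) # both classes guaranteed
    s <- sample(1:8, n, replace = TRUE) # heavy ties
    res <- roc_auc(s, y)
    expect_equal(res$auc, oracle_auc(s, y))
    expect_lte(res$ci_low, res$auc)
    expect_gte(res$ci_high, res$auc)
    expect_gte(res$variance, 0)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(7)
  y <- rbinom(100, 1, 0.4)
  y[1:2] <- c(0, 1)
  s <- rnorm(100)
  a <- roc_auc(s, y)$auc
  expect_equal(roc_auc(exp(s), y)$auc, a)
  expect_equal(roc_auc(5 * s - 3, y)$auc, a)
})

test_that("a score independent of the outcome gives AUC near one half", {
  set.seed(11)
  y <- rbinom(4000, 1, 0.3)
  s <- runif(4000)
  expect_lt(abs(roc_auc(s, y)$auc - 0.5), 0.03)
})

test_that("the paired DeLong test matches a first-principles reference", {
  set.seed(31)
  for (i in 1:10) {
    y <- c(0, 1, rbinom(18, 1, 0.5))
    a <- round(rnorm(20), 1) # rounding induces ties
    b <- round(0.5 * a + rnorm(20), 1)
    got <- delong_test(a, b, y)
    ref <- oracle_delong(a, b, y)
    expect_equal(got$z, ref$z, tolerance = 1e-8)
    expect_equal(got$p_value, ref$p, tolerance = 1e-8)
    expect_equal(got$delta_auc, ref$delta)
  }
})

test_that("DeLong degenerate pairs give Z = 0, p = 1", {
  y <- rep(c(0, 1), each = 10)
  s <- rnorm(20)
  same <- delong_test(s, s, y)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
  # strictly monotone transform: identical ranks, zero AUC difference
  mono <- delong_test(s, exp(s) + 2, y)
  expect_equal(mono$z, 0)
  expect_equal(mono$delta_auc, 0)
  expect_error(delong_test(s[1:10], s, y), "length")
  expect_error(delong_test(s, s, rep(1, 20)), "classes")
})

test_that("sensitivity and specificity follow the binarization rule", {
  perfect <- sens_spec(c("high", "high", "low", "low"), c(1, 1, 0, 0))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  # hand fixture: events {H,H,M,L}, non-events {L,L,M,H}
  cats <- c("high", "high", "medium", "low", "low", "low", "medium", "high")
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  mh <- sens_spec(cats, y, "medium_or_high")
  expect_equal(mh$sensitivity, 3 / 4)
  expect_equal(mh$specificity, 2 / 4)
  ho <- sens_spec(cats, y, "high_only")
  expect_equal(ho$sensitivity, 2 / 4)
  expect_equal(ho$specificity, 3 / 4)

  # categories independent of outcome: sens ~ q, spec ~ 1 - q
  set.seed(19)
  yy <- rbinom(5000, 1, 0.2)
  cc <- sample(c("low", "medium", "high"), 5000, replace = TRUE,
               prob = c(0.5, 0.3, 0.2))
  ind <- sens_spec(cc, yy)
  expect_lt(abs(ind$sensitivity - 0.5), 0.05)
  expect_lt(abs((1 - ind$specificity) - 0.5), 0.05)

  expect_error(sens_spec(cats, rep(0, 8)), "classes")
})

test_that("reclassification tables count moves by event stratum", {
  old <- c("low", "medium", "high", "low")
  y <- c(1, 0, 0, 0)
  same <- reclassification_table(old, old, y)
  expect_true(all(same$counts_events[upper.tri(same$counts_events)] == 0))
  expect_true(all(same$counts_events[lower.tri(same$counts_events)] == 0))
  expect_equal(sum(same$counts_events), 1)
  expect_equal(sum(same$counts_nonevents), 3)

  new <- c("high", "medium", "high", "low")
  moved <- reclassification_table(old, new, y)
  expect_equal(moved$counts_events["low", "high"], 1L)
  expect_equal(sum(moved$counts_events), 1)

  # invariance under participant reordering
  set.seed(5)
  o <- sample(c("low", "medium", "high"), 300, replace = TRUE)
  n <- sample(c("low", "medium", "high"), 300, replace = TRUE)
  yy <- rbinom(300, 1, 0.3)
  perm <- sample(300)
  t1 <- reclassification_table(o, n, yy)
  t2 <- reclassification_table(o[perm], n[perm], yy[perm])
  expect_identical(t1$counts_events, t2$counts_events)
  expect_identical(t1$counts_nonevents, t2$counts_nonevents)

  expect_error(reclassification_table(o[1:10], n, yy), "length")
})

test_that("NRI components follow the up/down arithmetic exactly", {
  # events: 10 up, 2 down of 100; non-events: 32 up, 5 down of 1000
  res <- nri(constructed_table(10, 2, 100, 32, 5, 1000))
  expect_equal(res$nri_events, 0.08)
  expect_equal(res$nri_nonevents, -0.027)
  expect_equal(res$absolute_nri, 0.053)
  expect_equal(res$absolute_nri, res$nri_events + res$nri_nonevents,
               tolerance = 1e-12)
  # asymptotic z against direct arithmetic
  v <- (10 + 2) / 100^2 + (32 + 5) / 1000^2
  expect_equal(res$z_stat, 0.053 / sqrt(v))
  expect_equal(res$p_value, 2 * pnorm(-abs(res$z_stat)))

  none <- nri(constructed_table(0, 0, 50, 0, 0, 50))
  expect_equal(none$absolute_nri, 0)
  expect_equal(none$p_value, 1)

  # bound attained: every event up, every non-event down
  maxed <- nri(constructed_table(50, 0, 50, 0, 80, 80))
  expect_equal(maxed$absolute_nri, 2)
})

test_that("NRI is antisymmetric under swapping old and new classifications", {
  set.seed(23)
  o <- sample(c("low", "medium", "high"), 400, replace = TRUE)
  n <- sample(c("low", "medium", "high"), 400, replace = TRUE)
  y <- c(1, 0, rbinom(398, 1, 0.3))
  fwd <- nri(reclassification_table(o, n, y))
  rev <- nri(reclassification_table(n, o, y))
  expect_equal(fwd$nri_events, -rev$nri_events, tolerance = 1e-12)
  expect_equal(fwd$nri_nonevents, -rev$nri_nonevents, tolerance = 1e-12)
  expect_equal(fwd$absolute_nri, -rev$absolute_nri, tolerance = 1e-12)
})

test_that("NRI detects a model that adds real signal", {
  set.seed(61)
  truth <- runif(6000)
  y <- rbinom(6000, 1, plogis(-4 + 4 * truth))
  noisy <- truth + rnorm(6000, sd = 1.5) # weak model
  sharp <- truth + rnorm(6000, sd = 0.2) # strong model
  cats_old <- categorize(noisy, quantile(noisy, c(0.5, 0.85)))
  cats_new <- categorize(sharp, quantile(sharp, c(0.5, 0.85)))
  res <- nri(reclassification_table(cats_old, cats_new, y))
  expect_gt(res$absolute_nri, 0)
  expect_lt(res$p_value, 0.05)
})
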