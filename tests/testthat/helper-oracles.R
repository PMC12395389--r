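# Independent reference implementations used as oracles. These deliberately
# use naive loops / explicit enumeration, never the package's code paths.

# Explicit partition / sum / product reference for the combined score.
oracle_combine <- function(scores) {
  elevated <- scores[scores >= 1]
  protective <- scores[scores < 1]
  sum_term <- 1
  if (length(elevated) >= 1) {
    sum_term <- sum(elevated) - (length(elevated) - 1)
  }
  prod_term <- 1
  for (s in protective) prod_term <- prod_term * s
  sum_term * prod_term
}

# All-pairs Mann-Whitney AUC with midrank tie handling.
oracle_auc <- function(scores, outcomes) {
  cases <- scores[outcomes == 1]
  controls <- scores[outcomes == 0]
  total <- 0
  for (a in cases) {
    for (b in controls) {
      total <- total + (a > b) + 0.5 * (a == b)
    }
  }
  total / (length(cases) * length(controls))
}

# Paired DeLong test from first principles via structural components.
oracle_delong <- function(a, b, outcomes) {
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  comp <- function(s) {
    cases <- s[outcomes == 1]; controls <- s[outcomes == 0]
    v10 <- vapply(cases, function(x) mean(psi(x, controls)), numeric(1))
    v01 <- vapply(controls, function(y) mean(psi(cases, y)), numeric(1))
    list(auc = mean(v10), v10 = v10, v01 = v01)
  }
  ca <- comp(a); cb <- comp(b)
  m <- sum(outcomes == 1); n <- sum(outcomes == 0)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  z <- (ca$auc - cb$auc) / sqrt(v)
  list(z = z, p = 2 * stats::pnorm(-abs(z)), delta = ca$auc - cb$auc)
}

# A tiny hand-made two-factor panel for construction tests.
toy_params <- function() {
  data.frame(
    name = c("a", "b"),
    prevalence = c(0.4, 0.1),
    odds_ratio = c(2.0, 0.8),
    beta = c(log(2.0), log(0.8)),
    par_pct = c(0.3, 0.05),
    stringsAsFactors = FALSE
  )
}

# Printed parameter-table reference values (3-decimal rho and S columns).
table2_reference <- function() {
  data.frame(
    name = c("hypertension", "diabetes", "dyslipidemia", "heart_disease",
             "smoking", "overweight", "physical_inactivity", "family_history"),
    rho = c(0.495, 0.826, 0.804, 0.496, 0.918, 0.979, 0.651, 0.949),
    s_exposed = c(1.485, 1.825, 0.756, 0.615, 0.808, 1.478, 0.658, 1.329),
    stringsAsFactors = FALSE
  )
}

# Build a reclassification table with prescribed up/down/same counts.
constructed_table <- function(up_e, down_e, n_e, up_ne, down_ne, n_ne) {
  mk <- function(up, down, n) {
    m <- matrix(0L, 3, 3, dimnames = list(c("low", "medium", "high"),
                                          c("low", "medium", "high")))
    m["low", "medium"] <- up
    m["medium", "low"] <- down
    m["low", "low"] <- n - up - down
    m
  }
  structure(
    list(counts_events = mk(up_e, down_e, n_e),
         counts_nonevents = mk(up_ne, down_ne, n_ne),
         category_order = c("low", "medium", "high")),
    class = "reclass_table"
  )
}
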