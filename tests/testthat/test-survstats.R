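# Kaplan-Meier, log-rank, Cox, Mann-Whitney, AE tabulation, PK summaries
# and 3+3 escalation decisions.

srec <- function(times, events = TRUE, endpoint = "PFS") {
  data.frame(patient_id = seq_along(times), endpoint = endpoint,
             time_days = times, event = rep_len(events, length(times)))
}

test_that("KM without censoring equals the empirical survival curve", {
  km <- km_estimate(srec(1:9), query_day = 5)
  expect_equal(km$median, 5)
  expect_equal(summary(km$fit, times = 1:9)$surv, (8:0) / 9)
  expect_equal(km$surv_at_query, 4 / 9)
})

test_that("KM six-month landmark reproduces the product-limit value", {
  # 10 patients, 6 events before day 183, no earlier censoring
  times <- c(58, 90, 120, 150, 160, 174, 200, 230, 250, 260)
  ev <- c(rep(TRUE, 6), rep(TRUE, 4))
  km <- km_estimate(srec(times, ev), query_day = 183)
  expect_equal(km$surv_at_query, 0.40)
})

test_that("all-censored input flags the median as undefined", {
  km <- km_estimate(srec(c(100, 200), events = FALSE))
  expect_false(km$median_defined)
  expect_equal(summary(km$fit, times = 150, extend = TRUE)$surv, 1)
})

test_that("log-rank matches hand risk tables and is null on identical groups", {
  a <- srec(c(2, 4, 6)); b <- srec(c(10, 12, 14))
  lr <- logrank_test(a, b)
  expect_equal(lr$chisq, oracle_logrank_chisq(c(2, 4, 6), c(10, 12, 14)),
               tolerance = 1e-8)
  same <- srec(c(3, 7, 11, 15))
  lr0 <- logrank_test(same, same)
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1, tolerance = 1e-9)
  expect_warning(logrank_test(srec(1:3), srec(4:6, events = FALSE)),
                 "zero events")
})

test_that("log-rank chi-square is invariant under monotone time transforms", {
  set.seed(8)
  a <- srec(rexp(20, 0.01)); b <- srec(rexp(20, 0.02))
  lr1 <- logrank_test(a, b)
  a2 <- a; b2 <- b
  a2$time_days <- sqrt(a$time_days); b2$time_days <- sqrt(b$time_days)
  lr2 <- logrank_test(a2, b2)
  expect_equal(lr1$chisq, lr2$chisq, tolerance = 1e-10)
})

test_that("log-rank type-I error is nominal under label permutation", {
  set.seed(99)
  times <- rexp(40, 0.005)
  rej <- 0
  for (i in 1:1000) {
    lab <- sample(rep(c(TRUE, FALSE), 20))
    p <- logrank_test(srec(times[lab]), srec(times[!lab]))$p
    if (p < 0.05) rej <- rej + 1
  }
  expect_gte(rej / 1000, 0.03)
  expect_lte(rej / 1000, 0.07)
})

test_that("Cox HR behaves under identity and label swap, and recovers truth", {
  d <- srec(c(2, 5, 8, 11, 14, 17))
  dup <- rbind(transform(d, group = "A"), transform(d, group = "B"))
  expect_equal(cox_hr(dup)$hr, 1, tolerance = 1e-8)

  set.seed(12)
  n <- 200
  g <- rep(c(0, 1), each = n / 2)
  t <- rexp(n, 0.01 * exp(log(0.5) * g))
  dd <- data.frame(patient_id = 1:n, endpoint = "PFS", time_days = t,
                   event = TRUE, group = ifelse(g == 1, "B", "A"))
  fit <- cox_hr(dd, level_of_interest = "B")
  swapped <- cox_hr(dd, level_of_interest = "A")
  expect_equal(fit$hr, 1 / swapped$hr, tolerance = 1e-8)
  expect_true(fit$ci_low <= fit$hr && fit$hr <= fit$ci_high)

  hits <- 0
  for (s in 1:200) {
    set.seed(3000 + s)
    t <- rexp(n, 0.01 * exp(log(0.5) * g))
    dd$time_days <- t
    hr <- cox_hr(dd, level_of_interest = "B")$hr
    if (hr >= 0.35 && hr <= 0.72) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.9)
})

test_that("Mann-Whitney exact enumeration reproduces textbook values", {
  r <- mann_whitney(1:3, 4:6)
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)
  expect_identical(r$method, "exact")

  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)

  shifted <- mann_whitney(1:3 + 100, 4:6 + 100)
  expect_equal(shifted$U, r$U)

  # large-sample route agrees with the standard implementation
  set.seed(2)
  x <- rnorm(15); y <- rnorm(18, 0.5)
  got <- mann_whitney(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_identical(got$method, "normal_tie_corrected")
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-6)
})

test_that("AE table reconstructed from printed counts reproduces the shares", {
  # grade margin 87/59/24/1/0 and relationship margin, with the four
  # drug-related grade>=2 events placed in the combined categories
  listing <- data.frame(
    grade = c(rep(1, 87), rep(2, 59), rep(3, 24), 4),
    relationship = c(
      rep("nox_a12", 13), rep("nox_a12_gbm", 4), rep("none", 40),
      rep("gbm", 20), rep("rt", 8), rep("rt_gbm", 2),             # 87 grade 1
      rep("nox_a12_rt", 2), rep("nox_a12_rt_gbm", 2), rep("none", 30),
      rep("gbm", 15), rep("rt", 6), rep("rt_gbm", 4),             # 59 grade 2
      rep("none", 11), rep("gbm", 8), rep("rt", 5),               # 24 grade 3
      "rt"))                                                      # 1 grade 4
  s <- ae_summary(listing)
  expect_equal(s$total, 171)
  expect_equal(s$by_grade$n, c(87, 59, 24, 1, 0))
  expect_equal(s$by_grade$pct, c(50.9, 34.5, 14.0, 0.6, 0))
  rel_n <- setNames(s$by_relationship$n, s$by_relationship$relationship)
  expect_equal(unname(rel_n[c("none", "gbm", "rt", "rt_gbm", "nox_a12",
                              "nox_a12_gbm", "nox_a12_rt",
                              "nox_a12_rt_gbm")]),
               c(81, 43, 20, 6, 13, 4, 2, 2))
  rel <- setNames(s$by_relationship$pct, s$by_relationship$relationship)
  expect_equal(rel[["nox_a12"]], 7.6)
  expect_equal(s$grade2plus$total, 84)
  expect_equal(s$grade2plus$drug_related, 4)
  expect_equal(s$grade2plus$drug_related_pct, 4.8)  # 4/84 recomputed
})

test_that("AE summary validates inputs and handles the empty listing", {
  expect_error(ae_summary(data.frame(grade = 6, relationship = "none")),
               "grade")
  expect_error(ae_summary(data.frame(grade = 1, relationship = "martian")),
               "relationship")
  z <- ae_summary(data.frame(grade = integer(), relationship = character()))
  expect_equal(z$total, 0)
  expect_true(all(is.na(z$by_grade$pct)))
})

test_that("percentages always re-derive from counts", {
  set.seed(31)
  listing <- data.frame(grade = sample(1:5, 200, TRUE),
                        relationship = sample(c("none", "gbm", "nox_a12"),
                                              200, TRUE))
  s <- ae_summary(listing)
  expect_equal(sum(s$by_grade$n), s$total)
  expect_equal(s$by_grade$pct,
               sign(s$by_grade$n) * floor(abs(100 * s$by_grade$n / s$total) *
                                            10 + 0.5) / 10)
})

test_that("PK summaries find the steady state and the threshold flags", {
  cfg <- synth_config(seed = 1, pk_dose_mg_per_week = 200)
  series <- generate_pk_series(cfg, days = seq(0, 28, by = 0.5))
  s <- pk_summary(series)
  expect_true(s$exceeds_threshold)
  expect_true(s$drug_over_target)
  expect_lte(s$steady_state_day, 7)

  const <- data.frame(day = seq(0, 20, by = 2), conc_uM = 2)
  expect_equal(pk_summary(const)$steady_state_day, 0)
  expect_error(pk_summary(data.frame(day = c(0, 5, 3, 8, 20),
                                     conc_uM = 1)), "increasing")
  expect_error(pk_summary(data.frame(day = c(0, 2, 4, 6, 8), conc_uM = 1)),
               "spanning")
})

test_that("3+3 decisions reproduce the hand-enumerated protocol table", {
  for (level in 1:3) {
    for (n in 0:6) {
      for (dlt in 0:n) {
        got <- escalation_decision(n, dlt, dose_level = level)
        expect_identical(got$decision, oracle_escalation(n, dlt, level),
                         info = sprintf("n=%d dlt=%d level=%d", n, dlt, level))
      }
    }
  }
  top <- escalation_decision(3, 0, dose_level = 3)
  expect_identical(top$decision, "declare_RP2D")
  expect_equal(top$rp2d_mg_per_week, 600)
  expect_identical(escalation_decision(3, 1)$decision, "expand_same_level")
  stopd <- escalation_decision(6, 2, dose_level = 2)
  expect_identical(stopd$decision, "stop_declare_MTD")
  expect_equal(stopd$mtd_level, 1)
  expect_error(escalation_decision(7, 0), "protocol violation")
})
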