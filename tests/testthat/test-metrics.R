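test_that("confusion statistics match hand-computed ratios", {
  cs <- confusion_stats(tp = 8, fp = 2, fn = 2, tn = 88)
  expect_equal(cs$sensitivity, 80)
  expect_equal(cs$ppv, 80)
  expect_equal(cs$f1, 80)
  expect_equal(cs$accuracy, 96)
  perfect <- confusion_stats(10, 0, 0, 90)
  expect_equal(perfect$f1, 100)
  # undefined ratios are NA, never 0 or 100
  none <- confusion_stats(0, 0, 0, 50)
  expect_true(is.na(none$sensitivity))
  expect_true(is.na(none$ppv))
  expect_equal(none$specificity, 100)
})

test_that("bootstrap CIs are seeded, degenerate-safe, and match closed form", {
  x <- rep(0.5, 30)
  ci <- bootstrap_ci(x, mean, n_reps = 200, seed = 1)
  expect_equal(unname(ci), c(0.5, 0.5, 0.5), ignore_attr = TRUE)
  y <- stats::rbinom(200, 1, 0.8)
  ci1 <- bootstrap_ci(y, mean, n_reps = 2000, seed = 9)
  ci2 <- bootstrap_ci(y, mean, n_reps = 2000, seed = 9)
  expect_identical(ci1, ci2)
  # point estimate inside its own interval
  expect_lte(ci1[["lower"]], ci1[["point"]])
  expect_gte(ci1[["upper"]], ci1[["point"]])
  # percentile width close to the asymptotic binomial interval width
  phat <- mean(y)
  closed <- 2 * stats::qnorm(0.975) * sqrt(phat * (1 - phat) / 200)
  expect_lt(abs((ci1[["upper"]] - ci1[["lower"]]) - closed), 0.02)
})

test_that("relative risk, its CI and Fisher p behave on canonical tables", {
  eq <- relative_risk(5, 50, 5, 50)
  expect_equal(eq$rr, 1)
  expect_equal(eq$p_value, 1)
  rr <- relative_risk(1, 10, 5, 10)
  expect_equal(rr$rr, 5)
  expect_equal(rr$p_value, fisher_oracle(1, 10, 5, 10))
  # zero events in the reference arm: infinite RR, CI unavailable
  z <- relative_risk(0, 100, 10, 100)
  expect_true(is.infinite(z$rr))
  expect_true(is.na(z$lower))
  # zero events in both arms: undefined
  zz <- relative_risk(0, 50, 0, 50)
  expect_true(is.na(zz$rr))
  expect_equal(zz$p_value, 1)
})

test_that("prevalence weighting scales by the inverse searched fraction", {
  expect_equal(weight_to_population(12, 7303, 14606), 24)
  expect_equal(weight_to_population(7, 500, 500), 7)
  expect_error(weight_to_population(1, 600, 500), "exceed")
  expect_error(weight_to_population(1, 0, 500), "positive")
})

outcome_row <- function(pid, class, reader, verdict, days = 14) {
  data.frame(strip_id = paste0("S", pid), patient_id = pid,
             recording_id = pid, class = class, reader = reader,
             verdict = verdict, misclassified_as = NA_character_,
             panel_confirmed_present = verdict %in% c("true_positive",
                                                      "false_negative"),
             detected = verdict == "true_positive",
             recording_days = days)
}

test_that("patient-level FN requires a miss by one reader and a catch by the other", {
  rows <- list()
  for (i in 1:10) {
    miss_a <- i <= 2  # reader A misses all episodes in patients 1-2
    rows[[i]] <- rbind(
      outcome_row(sprintf("P%02d", i), "af", "ai",
                  if (miss_a) "false_negative" else "true_positive"),
      outcome_row(sprintf("P%02d", i), "af", "technician", "true_positive"))
  }
  out <- do.call(rbind, rows)
  pf <- patient_false_negatives(out)
  expect_equal(pf$fn[pf$reader == "ai"], 2)
  expect_equal(pf$fn_per_1000[pf$reader == "ai"], 200)
  expect_equal(pf$fn[pf$reader == "technician"], 0)
  # sensitivity and the FN fraction partition the confirmed patients
  a <- pf[pf$reader == "ai", ]
  expect_equal(100 * a$tp / (a$tp + a$fn) + 100 * a$fn / (a$tp + a$fn), 100)
})

test_that("patients missed by every reader count for no reader", {
  out <- rbind(outcome_row("P01", "af", "ai", "false_negative"),
               outcome_row("P01", "af", "technician", "false_negative"),
               outcome_row("P02", "af", "ai", "true_positive"),
               outcome_row("P02", "af", "technician", "false_negative"))
  pf <- patient_false_negatives(out)
  expect_equal(pf$fn[pf$reader == "ai"], 0)
  expect_equal(pf$fn[pf$reader == "technician"], 1)
})

test_that("false-positive rates per 1,000 patient-days match hand arithmetic", {
  mk_v <- function(class, n) {
    data.frame(strip_id = sprintf("%s%03d", class, seq_len(n)),
               reader = "ai", class = class, verdict = "false_positive",
               misclassified_as = NA, variant = "primary")
  }
  recs <- data.frame(recording_id = sprintf("R%03d", 1:100),
                     patient_id = sprintf("P%03d", 1:100),
                     duration_days = 21)
  v <- mk_v("vt", 42)
  r <- fp_rate_per_1000_patient_days(v, recs)
  expect_equal(r$rate_per_1000_patient_days, 20)  # 42 / 2,100 days
  # two classes with per-class rates 6 and 74 over 1,000 patient-days
  v2 <- rbind(mk_v("vt", 6), mk_v("asystole", 74))
  recs2 <- recs[1:10, ]
  recs2$duration_days <- 100
  r2 <- fp_rate_per_1000_patient_days(v2, recs2)
  expect_equal(sort(r2$per_class$rate_per_1000_patient_days), c(6, 74))
  expect_equal(r2$median, 40)
  expect_equal(unname(r2$iqr), c(6, 74))
  expect_error(fp_rate_per_1000_patient_days(v, recs[0, ]), "positive")
})
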