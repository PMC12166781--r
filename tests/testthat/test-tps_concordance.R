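test_that("TPS is 100 * TC+ / (TC+ + TC-), undefined without tumor cells", {
  expect_equal(compute_tps(cell_counts(0, 4366, 2413)), 0)
  expect_equal(compute_tps(cell_counts(708, 4366, 2413)), 13.95,
               tolerance = 0.01 / 13.95)
  expect_equal(compute_tps(cell_counts(5, 0, 0)), 100)
  expect_true(is.na(compute_tps(cell_counts(0, 0, 50))))  # explicit null, not 0
  expect_error(cell_counts(-1, 5), "nonnegative")

  # monotone in TC+ up, in TC- down; always within [0, 100]
  set.seed(53)
  for (i in 1:30) {
    pos <- sample(0:500, 1); neg <- sample(1:500, 1)
    t0 <- compute_tps(cell_counts(pos, neg))
    expect_true(t0 >= 0 && t0 <= 100)
    expect_gte(compute_tps(cell_counts(pos + 5, neg)), t0)
    expect_lte(compute_tps(cell_counts(pos, neg + 5)), t0)
  }
})

test_that("TPS is invariant to how cells are partitioned into patches", {
  set.seed(59)
  for (i in 1:10) {
    pos <- sample(1:300, 1); neg <- sample(1:300, 1)
    parts <- sample(1:6, 1)
    split_pos <- tabulate(sample(parts, pos, replace = TRUE), parts)
    split_neg <- tabulate(sample(parts, neg, replace = TRUE), parts)
    total <- cell_counts(sum(split_pos), sum(split_neg))
    expect_equal(compute_tps(total), compute_tps(cell_counts(pos, neg)))
  }
})

test_that("patient aggregation averages defined slide scores", {
  expect_equal(round(aggregate_patient(c(12.33, 11.39)), 2), 11.86)
  expect_equal(aggregate_patient(7.5), 7.5)
  expect_equal(aggregate_patient(c(0.08, 0.20)), 0.14)
  expect_equal(aggregate_patient(c(30, NA)), 30)
  expect_true(is.na(aggregate_patient(c(NA_real_, NA_real_))))
  expect_equal(aggregate_patient(c(10, 40), method = "max"), 40)
})

test_that("discrepancy flags are strict at the 10-point threshold and symmetric", {
  expect_identical(flag_discrepancies(12.33, c(2, 30, 20)),
                   c(TRUE, TRUE, FALSE))
  expect_false(flag_discrepancies(50, 60))   # exactly 10 points: not flagged
  expect_false(flag_discrepancies(25, 25))
  expect_true(flag_discrepancies(50, 60.01))
  set.seed(61)
  a <- runif(50, 0, 100); b <- runif(50, 0, 100)
  expect_identical(flag_discrepancies(a, b), flag_discrepancies(b, a))
})

test_that("cutoff concordance counts discordant binarized cases", {
  # 2 and 4 discordant cases of 63
  ai <- rep(c(5, 40), c(40, 23))
  r2 <- ai; r2[c(1, 45)] <- c(95, 2)    # flips sides at the 20 % cutoff
  cc2 <- cutoff_concordance(ai, r2)
  expect_equal(cc2$discordant, 2)
  expect_equal(round(cc2$accuracy, 2), 96.83)
  r4 <- ai; r4[c(1, 2, 45, 46)] <- c(95, 80, 2, 3)
  cc4 <- cutoff_concordance(ai, r4)
  expect_equal(cc4$discordant, 4)
  expect_equal(round(cc4$accuracy, 2), 93.65)

  ident <- cutoff_concordance(ai, ai)
  expect_equal(ident$accuracy, 100)
  expect_equal(ident$discordant, 0)

  # boundary: a score exactly at the cutoff is positive on both sides
  expect_equal(cutoff_concordance(20, 20)$discordant, 0)
  expect_equal(cutoff_concordance(19.99, 20)$discordant, 1)

  expect_error(cutoff_concordance(1:3, 1:4), "length")

  set.seed(67)
  for (i in 1:10) {
    x <- runif(sample(3:40, 1), 0, 100)
    expect_equal(cutoff_concordance(x, x)$accuracy, 100)
  }
})

test_that("correlation agrees with the covariance formula oracle", {
  x <- c(1, 20, 35, 60, 90)
  expect_equal(concordance_correlation(x, x), 1.0)
  expect_equal(concordance_correlation(x, 100 - x), -1.0)
  set.seed(71)
  for (i in 1:10) {
    a <- runif(20, 0, 100); b <- 0.5 * a + rnorm(20, sd = 15)
    r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(concordance_correlation(a, b), r_oracle, tolerance = 1e-12)
  }
  expect_warning(r0 <- concordance_correlation(rep(5, 10), runif(10)), "variance")
  expect_true(is.na(r0))
  expect_error(concordance_correlation(1:2, 1:2), "at least 3")
})

test_that("reassessment summary counts flagged patients and assessments", {
  # 63 patients x 3 raters with exactly 33 flagged assessments
  rec <- expand.grid(patient_id = 1:63, rater_id = 1:3)
  rec$flagged <- FALSE
  rec$flagged[seq_len(33)] <- TRUE   # 33 of 189
  s <- reassessment_summary(rec)
  expect_equal(s$n_assessments_flagged, 33)
  expect_equal(round(s$pct_assessments, 2), 17.46)

  none <- reassessment_summary(transform(rec, flagged = FALSE))
  expect_equal(none$n_assessments_flagged, 0)
  expect_equal(none$pct_assessments, 0)
  expect_equal(none$n_patients_flagged, 0)

  # random records against exhaustive enumeration
  set.seed(73)
  for (i in 1:10) {
    rr <- expand.grid(patient_id = 1:12, rater_id = 1:3)
    rr$flagged <- runif(36) < 0.3
    rr$changed <- ifelse(rr$flagged, runif(36) < 0.5, NA)
    ss <- reassessment_summary(rr)
    expect_equal(ss$n_assessments_flagged, sum(rr$flagged))
    expect_equal(ss$n_patients_flagged,
                 length(unique(rr$patient_id[rr$flagged])))
    expect_equal(ss$n_changed, sum(rr$flagged & rr$changed %in% TRUE))
    expect_equal(ss$n_unchanged, sum(rr$flagged & rr$changed %in% FALSE))
    expect_equal(ss$n_changed + ss$n_unchanged, sum(rr$flagged))
  }
})

test_that("simulated pathologists reproduce the analytic flag rate", {
  truth <- rep(50, 30)
  exact <- simulate_pathologists(truth, n_raters = 3, noise_sd = 0, seed = 1)
  expect_equal(exact$tps, truth[exact$patient_id])

  # a +15-point bias on one case forces a flag when the AI equals truth
  biased <- simulate_pathologists(truth, n_raters = 1, noise_sd = 0,
                                  bias_rules = data.frame(patient = 4, rater = NA,
                                                          bias = 15),
                                  seed = 2)
  flags <- flag_discrepancies(truth[biased$patient_id], biased$tps)
  expect_identical(which(flags), 4L)

  # empirical flag probability vs the normal-tail oracle, 200 cohorts
  sd0 <- 8
  p_true <- 2 * stats::pnorm(-10 / sd0)
  hits <- 0; n_tot <- 0
  for (k in 1:200) {
    sim <- simulate_pathologists(truth, n_raters = 1, noise_sd = sd0, seed = 1000 + k)
    hits <- hits + sum(flag_discrepancies(truth[sim$patient_id], sim$tps))
    n_tot <- n_tot + nrow(sim)
  }
  p_emp <- hits / n_tot
  se <- sqrt(p_true * (1 - p_true) / n_tot)
  expect_lt(abs(p_emp - p_true), 3 * se)

  # flag rate grows monotonically with the noise scale
  rate_at <- function(sd) {
    mean(vapply(1:200, function(k) {
      sim <- simulate_pathologists(truth, 1, sd, seed = 2000 + k)
      mean(flag_discrepancies(truth[sim$patient_id], sim$tps))
    }, numeric(1)))
  }
  rates <- vapply(c(2, 6, 12), rate_at, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("concordance report joins, flags and summarizes per rater", {
  ai <- data.frame(patient_id = rep(1:10, each = 1),
                   slide_id = paste0("s", 1:10),
                   tps = c(5, 15, 25, 35, 45, 55, 65, 75, 85, 95))
  path <- rbind(
    data.frame(patient_id = 1:10, rater_id = "A",
               tps = c(5, 15, 25, 35, 45, 55, 65, 75, 85, 95)),
    data.frame(patient_id = 1:10, rater_id = "B",
               tps = c(30, 15, 25, 10, 45, 55, 65, 75, 85, 40))
  )
  rep_ <- concordance_report(ai, path)
  expect_equal(nrow(rep_$table), 20)
  a_rows <- rep_$table[rep_$table$rater_id == "A", ]
  expect_false(any(a_rows$flagged))
  expect_true(all(a_rows$concordant))
  b <- rep_$summary$per_rater[[which(vapply(rep_$summary$per_rater, `[[`, "",
                                            "rater_id") == "B")]]
  expect_equal(b$discordant, 2)   # patients 1 and 4 cross the 20 % cutoff
  expect_equal(b$accuracy, 80)
  expect_equal(rep_$summary$reassessment$n_assessments_flagged, 3)
  expect_equal(rep_$summary$reassessment$n_patients_flagged, 3)

  # multi-slide patient: AI aggregated by mean before comparison
  ai2 <- data.frame(patient_id = c(1, 1), slide_id = c("a", "b"),
                    tps = c(12.33, 11.39))
  path2 <- data.frame(patient_id = 1, rater_id = c("A", "B", "C"),
                      tps = c(2, 30, 20))
  t2 <- concordance_report(ai2, path2)$table
  expect_equal(unique(round(t2$ai_tps, 2)), 11.86)
  expect_identical(t2$flagged[order(t2$rater_id)], c(FALSE, TRUE, FALSE))
})
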