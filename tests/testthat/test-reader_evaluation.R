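test_that("confusion quadruples match hand-verified printed percentages", {
  # 160 reads per class; 10 FP + 1 FN
  cm <- confusion_from_counts(tp = 159, fp = 10, tn = 150, fn = 1)
  expect_equal(cm$sensitivity, 159 / 160)
  expect_equal(cm$specificity, 150 / 160)
  expect_equal(round_half_up(100 * cm$sensitivity), 99.4)
  expect_equal(round_half_up(100 * cm$specificity), 93.8)
  expect_equal(round_half_up(100 * cm$ppv), 94.1)
  expect_equal(round_half_up(100 * cm$npv), 99.3)

  # 3 FP + 0 FN on the same class sizes
  cm <- confusion_from_counts(tp = 160, fp = 3, tn = 157, fn = 0)
  expect_equal(cm$sensitivity, 1)
  expect_equal(cm$specificity, 0.98125)
  expect_equal(round_half_up(100 * cm$ppv), 98.2)
  expect_equal(cm$npv, 1)
})

test_that("confusion metrics satisfy their identities on random records", {
  set.seed(3)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    truth <- stats::setNames(sample(c("normal", "pathological"), n, TRUE),
                             sprintf("s%d", 1:n))
    rec <- data.frame(
      reader_id = "R1", experience = "experienced",
      scan_id = names(truth), run = "no_ai",
      predicted = sample(c("normal", "pathological"), n, TRUE),
      stringsAsFactors = FALSE)
    cm <- confusion_metrics(rec, truth)
    expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, n)
    if (cm$tp + cm$fn > 0)
      expect_equal(cm$sensitivity, cm$tp / (cm$tp + cm$fn))
    if (cm$tp + cm$fp > 0)
      expect_equal(cm$ppv, cm$tp / (cm$tp + cm$fp))
  }
})

test_that("undefined metric denominators surface as NA, never as 0", {
  cm <- confusion_from_counts(tp = 0, fp = 0, tn = 5, fn = 0)
  expect_true(is.na(cm$sensitivity))
  expect_true(is.na(cm$ppv))
  expect_equal(cm$specificity, 1)
  expect_output(print(cm), "undefined")
})

test_that("confusion metrics honor run and experience filters", {
  truth <- c(s1 = "normal", s2 = "pathological")
  rec <- expand.grid(reader_id = c("R1", "R3"), scan_id = c("s1", "s2"),
                     run = c("no_ai", "ai"), stringsAsFactors = FALSE)
  rec$experience <- ifelse(rec$reader_id == "R1", "experienced",
                           "inexperienced")
  rec$predicted <- ifelse(rec$run == "ai", truth[rec$scan_id], "normal")
  cm <- confusion_metrics(rec, truth, run = "ai")
  expect_equal(cm$fn, 0)
  cm <- confusion_metrics(rec, truth, run = "no_ai",
                          experience = "experienced")
  expect_equal(cm$n, 2)
  expect_equal(cm$fn, 1)
  expect_error(confusion_metrics(
    data.frame(scan_id = "zz", predicted = "normal", run = "ai",
               experience = "experienced", stringsAsFactors = FALSE),
    truth), "missing ground truth")
})

test_that("test yield counts conclusive labels", {
  labels <- rep(c("normal", "pathological", "inconclusive"),
                c(30, 30, 20))
  y <- test_yield(labels)
  expect_equal(y$yield, 0.75)
  expect_equal(y$n_conclusive, 60)
  expect_equal(test_yield(rep("inconclusive", 5))$yield, 0)

  # per-ground-truth breakdown equals brute-force counting
  set.seed(9)
  labels <- sample(c("normal", "pathological", "inconclusive"), 200, TRUE)
  truth <- sample(c("normal", "pathological"), 200, TRUE)
  y <- test_yield(labels, truth)
  for (g in c("normal", "pathological")) {
    expect_equal(y$by_truth$n_conclusive[y$by_truth$ground_truth == g],
                 sum(labels != "inconclusive" & truth == g))
  }
})

test_that("completeness counts finding opportunities per group", {
  scans <- simulate_scan_table(seed = 1) # 89 findings over 40 scans
  rec <- simulate_reader_study(scans, seed = 2)
  comp <- completeness(rec, scans)
  all_rows <- comp[comp$experience == "all", ]
  expect_equal(unique(all_rows$n_opportunities), 4 * 89)

  # a reader who reports every finding misses none
  rec_perfect <- rec
  rec_perfect$predicted_findings <- lapply(rec$scan_id, function(id)
    scans$findings[[match(id, scans$scan_id)]])
  comp <- completeness(rec_perfect, scans)
  expect_true(all(comp$n_missed == 0))
  expect_true(all(comp$completeness == 1))
})

test_that("missed-finding counts follow the binomial model", {
  scans <- simulate_scan_table(seed = 1)
  mr <- default_miss_rates()
  missed <- numeric(500)
  for (i in 1:500) {
    rec <- simulate_reader_study(scans, seed = 3000 + i)
    comp <- completeness(rec, scans)
    missed[i] <- comp$n_missed[comp$run == "no_ai" &
                                 comp$experience == "all"]
  }
  expected <- mr[["no_ai"]] * 356
  se <- sqrt(356 * mr[["no_ai"]] * (1 - mr[["no_ai"]])) / sqrt(500)
  expect_lt(abs(mean(missed) - expected), 4 * se)
})

test_that("reporting-time reductions reproduce known group means", {
  expect_equal(round_half_up(delta_rt(65.1, 54.9)), 15.7)
  expect_equal(round_half_up(delta_rt(59.6, 46.3)), 22.3)
  expect_equal(delta_rt(60, 60), 0)

  scans <- simulate_scan_table(seed = 4)
  rec <- simulate_reader_study(scans, seed = 5)
  summ <- reporting_time_summary(rec, scans)
  row <- summ[summ$experience == "all" & summ$ground_truth == "all", ]
  expect_equal(row$delta_rt_pct,
               delta_rt(row$mean_no_ai, row$mean_ai))
  # manual check of one subgroup
  gt <- stats::setNames(scans$ground_truth, scans$scan_id)
  sel <- rec$run == "ai" & rec$experience == "experienced" &
    gt[rec$scan_id] == "normal"
  row <- summ[summ$experience == "experienced" &
                summ$ground_truth == "normal", ]
  expect_equal(row$mean_ai, mean(rec$reporting_time[sel]))
  expect_equal(row$sd_ai, stats::sd(rec$reporting_time[sel]))
})

test_that("paired t test matches the textbook formula and handles ties", {
  x <- c(61.2, 70.4, 55.9, 68.0, 64.8, 59.7, 73.1, 66.5, 62.3, 69.9)
  y <- c(54.0, 62.1, 50.2, 66.8, 55.9, 52.5, 70.3, 60.0, 57.7, 61.4)
  got <- paired_t_test(x, y)
  d <- x - y
  tstat <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  expect_equal(got$statistic, tstat)
  expect_equal(got$p.value,
               2 * stats::pt(-abs(tstat), length(d) - 1))
  expect_false(got$degenerate)

  same <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_true(same$degenerate)
})

test_that("paired t test has power against a real shift", {
  set.seed(10)
  reject <- vapply(1:200, function(i) {
    x <- stats::rnorm(80, 65, 9)
    y <- x - stats::rnorm(80, 10, 9)
    paired_t_test(x, y)$p.value < 0.05
  }, TRUE)
  expect_gt(mean(reject), 0.8)
})

test_that("signed-rank statistic matches hand computation with ties", {
  got <- wilcoxon_signed_rank(c(1, 2, 3, -1))
  # |d| = {1, 2, 3, 1} -> midranks {1.5, 3, 4, 1.5}; positives sum 8.5
  expect_equal(got$statistic, 8.5)
  expect_equal(got$method, "exact")

  degen <- wilcoxon_signed_rank(c(0, 0, 0))
  expect_true(degen$degenerate)
})

test_that("exact signed-rank p equals full enumeration for n <= 10", {
  set.seed(6)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    d <- sample(c(-5:-1, 1:5), n, replace = TRUE)
    if (all(d == 0)) next
    got <- wilcoxon_signed_rank(d)
    oracle <- wilcoxon_enumeration_oracle(d)
    expect_equal(got$statistic, oracle$statistic)
    expect_equal(got$p.value, oracle$p.value, tolerance = 1e-12)
  }
})

test_that("tie-free exact p agrees with the reference implementation", {
  set.seed(8)
  for (i in 1:10) {
    n <- sample(6:15, 1)
    d <- sample(seq_len(50), n) * sample(c(-1, 1), n, TRUE)
    got <- wilcoxon_signed_rank(d)
    ref <- suppressWarnings(stats::wilcox.test(d, exact = TRUE))
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("large-sample signed-rank uses the tie-corrected approximation", {
  set.seed(13)
  d <- round(stats::rnorm(60, 0.3, 1), 1)
  d <- d[d != 0]
  got <- wilcoxon_signed_rank(d)
  expect_equal(got$method, "normal approximation")
  ref <- suppressWarnings(stats::wilcox.test(d, correct = TRUE))
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-8)
})

test_that("Likert summaries report both moment and quantile views", {
  rec <- data.frame(run = "ai", experience = "experienced",
                    confidence = c(5, 5, 5, 5))
  s <- likert_summary(rec)
  expect_equal(s$mean, 5)
  expect_equal(s$sd, 0)

  rec$confidence <- c(4, 4, 5, 3)
  s <- likert_summary(rec)
  expect_equal(s$mean, 4)
  expect_equal(s$sd, stats::sd(c(4, 4, 5, 3)))
  expect_equal(s$median, 4)

  # latent moment matching reproduces target discrete moments
  lp <- likert_latent_params(4.30, 0.84)
  set.seed(2)
  draws <- pmin(5, pmax(1, round(stats::rnorm(4e4, lp["mu"], lp["sigma"]))))
  expect_lt(abs(mean(draws) - 4.30), 0.02)
  expect_lt(abs(stats::sd(draws) - 0.84), 0.02)
})
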