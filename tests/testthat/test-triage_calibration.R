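test_that("threshold placement follows the extreme-score rule", {
  # overlapping classes leave a proper inconclusive band
  thr <- calibrate_thresholds(c(0.01, 0.02, 0.05, 0.03, 0.20),
                              c("normal", "normal", "normal",
                                "pathological", "pathological"))
  expect_equal(thr$t_lower, 0.03)
  expect_equal(thr$t_upper, 0.05)

  # separable classes collapse the band instead of inverting it
  thr <- calibrate_thresholds(c(0.01, 0.02, 0.03, 0.10, 0.12),
                              c("normal", "normal", "normal",
                                "pathological", "pathological"))
  expect_equal(thr$t_lower, 0.03)
  expect_equal(thr$t_upper, 0.03)

  expect_error(calibrate_thresholds(c(0.1, 0.2), c("normal", "normal")),
               "each class")
  expect_error(calibrate_thresholds(c(0.1, 1.2),
                                    c("normal", "pathological")),
               "\\[0, 1\\]")
})

test_that("triage applies strict inequalities with inconclusive bounds", {
  thr <- calibrate_thresholds(c(0.05, 0.03), c("normal", "pathological"))
  expect_equal(thr$t_lower, 0.03)
  expect_equal(thr$t_upper, 0.05)
  expect_equal(triage(c(0.02, 0.04, 0.20), thr),
               c("normal", "inconclusive", "pathological"))
  # boundary scores are inconclusive
  expect_equal(triage(c(0.03, 0.05), thr),
               c("inconclusive", "inconclusive"))
  expect_error(triage(1.5, thr), "\\[0, 1\\]")
})

test_that("triage is monotone in the anomaly score", {
  set.seed(12)
  for (i in 1:25) {
    sc <- stats::runif(8)
    lab <- sample(c("normal", "pathological"), 8, replace = TRUE)
    if (length(unique(lab)) < 2) next
    thr <- calibrate_thresholds(sc, lab)
    rank_of <- c(normal = 1L, inconclusive = 2L, pathological = 3L)
    s <- sort(stats::runif(50))
    expect_true(all(diff(rank_of[triage(s, thr)]) >= 0))
  }
})

test_that("calibration guarantees hold by construction on random sets", {
  set.seed(7)
  for (i in 1:100) {
    n0 <- sample(2:30, 1)
    n1 <- sample(2:30, 1)
    sc <- c(stats::rbeta(n0, 1, 30), stats::rbeta(n1, 2, 10))
    lab <- rep(c("normal", "pathological"), c(n0, n1))
    thr <- calibrate_thresholds(sc, lab)
    expect_lte(thr$t_lower, thr$t_upper)
    expect_gte(thr$t_lower, 0)
    expect_lte(thr$t_upper, 1)
    got <- triage(sc, thr)
    # false omission rate 0: no pathological scan labelled normal
    expect_equal(sum(got == "normal" & lab == "pathological"), 0L)
    # false positive rate 0: no normal scan labelled pathological
    expect_equal(sum(got == "pathological" & lab == "normal"), 0L)
  }
})

test_that("optional margins widen the inconclusive band outward", {
  # separable pair collapses at t_upper = 0.02, then the lower margin
  # pulls t_lower down
  thr <- calibrate_thresholds(c(0.02, 0.05), c("normal", "pathological"),
                              margin = 0.01)
  expect_equal(thr$t_upper, 0.02)
  expect_equal(thr$t_lower, 0.01)
  thr <- calibrate_thresholds(c(0.02, 0.005), c("normal", "pathological"),
                              margin = 0.1)
  expect_equal(thr$t_lower, 0) # clamped at zero

  # upper generalization margin raises t_upper, never above 1
  thr <- calibrate_thresholds(c(0.02, 0.30), c("normal", "pathological"),
                              margin_upper = 0.05)
  expect_equal(thr$t_upper, 0.07)
  expect_equal(thr$t_lower, 0.07)
  thr <- calibrate_thresholds(c(0.99, 0.995), c("normal", "pathological"),
                              margin_upper = 0.1)
  expect_equal(thr$t_upper, 1)
  # calibration-set guarantees survive any margins
  sc <- c(0.01, 0.02, 0.05, 0.20)
  lab <- c("normal", "normal", "pathological", "pathological")
  thr <- calibrate_thresholds(sc, lab, margin = 0.01, margin_upper = 0.03)
  got <- triage(sc, thr)
  expect_equal(sum(got == "normal" & lab == "pathological"), 0L)
  expect_equal(sum(got == "pathological" & lab == "normal"), 0L)
})

test_that("worklists put pathological scans first, by descending score", {
  thr <- calibrate_thresholds(c(0.02, 0.05, 0.03),
                              c("normal", "normal", "pathological"))
  df <- data.frame(scan_id = sprintf("s%d", 1:6),
                   score = c(0.01, 0.2, 0.04, 0.5, 0.0, 0.06))
  wl <- triage_worklist(df, thr)
  expect_equal(wl$label[1:2], c("pathological", "pathological"))
  expect_equal(wl$scan_id[1:2], c("s4", "s2"))
  prio <- c(pathological = 1L, inconclusive = 2L, normal = 3L)
  expect_true(all(diff(prio[wl$label]) >= 0))
  expect_equal(unname(wl$color[wl$label == "pathological"][1]), "red")
  expect_equal(unname(wl$color[wl$label == "normal"][1]), "green")
  expect_equal(unname(wl$color[wl$label == "inconclusive"][1]), "white")

  # degenerate: all zero scores with a positive lower threshold
  thr2 <- calibrate_thresholds(c(0.01, 0.5), c("normal", "pathological"))
  all0 <- triage_worklist(data.frame(scan_id = "a", score = 0), thr2)
  expect_equal(all0$label, "normal")
})

test_that("thresholds round-trip through JSON", {
  thr <- calibrate_thresholds(c(0.02, 0.07), c("normal", "pathological"),
                              tag = "scannerA")
  f <- withr::local_tempfile(fileext = ".json")
  write_thresholds(thr, f)
  back <- read_thresholds(f)
  expect_equal(back$t_lower, thr$t_lower)
  expect_equal(back$t_upper, thr$t_upper)
  expect_equal(back$tag, "scannerA")
})

test_that("held-out triage separates well-separated synthetic cohorts", {
  # miniature version of the separability study: scores drawn from the
  # anomaly-score model (baseline tail vs lesion fraction + tail)
  tail0 <- 2 * stats::pnorm(-2.576)
  ok <- 0L
  inconclusive_on_normal <- TRUE
  set.seed(41)
  for (rep in 1:20) {
    draw <- function(n, f) pmin(1, pmax(0,
      f + tail0 + stats::rnorm(n, 0, 0.002)))
    cal_sc <- c(draw(10, 0), draw(10, stats::runif(10, 0.03, 0.10)))
    cal_lab <- rep(c("normal", "pathological"), each = 10)
    thr <- calibrate_thresholds(cal_sc, cal_lab,
                                margin_upper = 3 * stats::sd(cal_sc[1:10]))
    held_sc <- c(draw(10, 0), draw(10, stats::runif(10, 0.03, 0.10)))
    held_lab <- rep(c("normal", "pathological"), each = 10)
    got <- triage(held_sc, thr)
    for_zero <- sum(got == "normal" & held_lab == "pathological") == 0
    fpr_zero <- sum(got == "pathological" & held_lab == "normal") == 0
    if (for_zero && fpr_zero) ok <- ok + 1L
    if (any(got == "inconclusive" & held_lab == "pathological"))
      inconclusive_on_normal <- FALSE
  }
  expect_gte(ok, 19L)
  expect_true(inconclusive_on_normal)
})
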