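# Reader-study evaluation statistics: confusion-matrix metrics with
# pathological as the positive class, conclusive test yield, diagnostic
# completeness over finding classes, reporting-time summaries with
# percent reductions, the paired t test and a Wilcoxon signed-rank test
# with exact tie-aware null for small samples.

truth_vector <- function(truth) {
  if (is.data.frame(truth)) {
    stats::setNames(truth$ground_truth, truth$scan_id)
  } else truth
}

filter_records <- function(records, run = NULL, experience = NULL) {
  if (!is.null(run)) records <- records[records$run %in% run, , drop = FALSE]
  if (!is.null(experience))
    records <- records[records$experience %in% experience, , drop = FALSE]
  records
}

new_confusion <- function(tp, fp, tn, fn) {
  sdiv <- function(a, b) if (b == 0) NA_real_ else a / b
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 n = tp + fp + tn + fn,
                 sensitivity = sdiv(tp, tp + fn),
                 specificity = sdiv(tn, tn + fp),
                 ppv = sdiv(tp, tp + fp),
                 npv = sdiv(tn, tn + fn)),
            class = "confusion_metrics")
}

#' Confusion metrics from explicit counts
#'
#' Pathological is the positive class. Metrics with a zero denominator are
#' reported as `NA` (an explicit "undefined" marker), never silently 0.
#'
#' @param tp,fp,tn,fn Counts.
#' @return A `confusion_metrics` object.
#' @export
confusion_from_counts <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  new_confusion(tp, fp, tn, fn)
}

#' Confusion metrics of reader records against ground truth
#'
#' @param records Reader records (see [simulate_reader_study()]).
#' @param truth Named vector `scan_id -> ground_truth`, or a data frame
#'   with `scan_id` and `ground_truth` columns.
#' @param run,experience Optional filters (`"no_ai"`/`"ai"`,
#'   `"experienced"`/`"inexperienced"`).
#' @return A `confusion_metrics` object: counts plus sensitivity,
#'   specificity, PPV and NPV (`NA` where undefined).
#' @export
confusion_metrics <- function(records, truth, run = NULL,
                              experience = NULL) {
  tv <- truth_vector(truth)
  records <- filter_records(records, run, experience)
  if (!nrow(records)) return(new_confusion(0L, 0L, 0L, 0L))
  gt <- tv[records$scan_id]
  if (any(is.na(gt)))
    stop("missing ground truth for scan(s): ",
         paste(unique(records$scan_id[is.na(gt)]), collapse = ", "))
  pred <- records$predicted
  new_confusion(tp = sum(pred == "pathological" & gt == "pathological"),
                fp = sum(pred == "pathological" & gt == "normal"),
                tn = sum(pred == "normal" & gt == "normal"),
                fn = sum(pred == "normal" & gt == "pathological"))
}

#' @export
print.confusion_metrics <- function(x, ...) {
  f <- function(p) if (is.na(p)) "undefined" else
    sprintf("%.1f%%", fmt_pct(p))
  cat(sprintf("<confusion_metrics> tp %d fp %d tn %d fn %d (n = %d)\n",
              x$tp, x$fp, x$tn, x$fn, x$n))
  cat(sprintf("  sensitivity %s  specificity %s  PPV %s  NPV %s\n",
              f(x$sensitivity), f(x$specificity), f(x$ppv), f(x$npv)))
  invisible(x)
}

#' Conclusive test yield of triage labels
#'
#' The fraction of scans receiving a conclusive (normal or pathological)
#' label, with an optional per-ground-truth breakdown.
#'
#' @param labels Character triage labels
#'   (`normal`/`inconclusive`/`pathological`).
#' @param truth Optional ground-truth vector aligned with `labels`.
#' @return List with `yield`, `n_conclusive`, `n`, and (when `truth` is
#'   given) a `by_truth` data frame.
#' @export
test_yield <- function(labels, truth = NULL) {
  if (!length(labels)) stop("no labels")
  conclusive <- labels != "inconclusive"
  out <- list(yield = mean(conclusive), n_conclusive = sum(conclusive),
              n = length(labels))
  if (!is.null(truth)) {
    stopifnot(length(truth) == length(labels))
    by <- lapply(unique(truth), function(g) {
      sel <- truth == g
      data.frame(ground_truth = g, n = sum(sel),
                 n_conclusive = sum(conclusive[sel]),
                 yield = mean(conclusive[sel]),
                 stringsAsFactors = FALSE)
    })
    out$by_truth <- do.call(rbind, by)
  }
  out
}

#' Diagnostic completeness over finding classes
#'
#' An opportunity is one (reader, scan, finding-class) triple on a
#' pathological scan; the finding is missed iff it is absent from the
#' reader's `predicted_findings` for that scan in that run. Counts are
#' reported per run, for all readers and per experience group.
#'
#' @param records Reader records with a `predicted_findings` list-column.
#' @param scan_findings Data frame with `scan_id` and a `findings`
#'   list-column (e.g. from [simulate_scan_table()] or [read_worklist()]).
#' @return Data frame with `run`, `experience` (includes `"all"`),
#'   `n_missed`, `n_opportunities`, `completeness`.
#' @export
completeness <- function(records, scan_findings) {
  fmap <- stats::setNames(scan_findings$findings, scan_findings$scan_id)
  path_ids <- scan_findings$scan_id[
    vapply(scan_findings$findings, length, 0L) > 0L]
  recs <- records[records$scan_id %in% path_ids, , drop = FALSE]
  miss_count <- function(r) {
    missed <- 0L; opp <- 0L
    for (i in seq_len(nrow(r))) {
      f <- fmap[[r$scan_id[i]]]
      opp <- opp + length(f)
      missed <- missed + sum(!f %in% r$predicted_findings[[i]])
    }
    c(missed, opp)
  }
  rows <- list()
  for (run in unique(recs$run)) {
    for (exp_lvl in c("all", unique(recs$experience))) {
      r <- recs[recs$run == run, , drop = FALSE]
      if (exp_lvl != "all")
        r <- r[r$experience == exp_lvl, , drop = FALSE]
      mc <- miss_count(r)
      rows[[length(rows) + 1L]] <-
        data.frame(run = run, experience = exp_lvl, n_missed = mc[1],
                   n_opportunities = mc[2],
                   completeness = if (mc[2] > 0) 1 - mc[1] / mc[2]
                                  else NA_real_,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Percent reduction in mean reporting time
#'
#' `100 * (mean_without - mean_with) / mean_without`; positive values mean
#' faster reporting with triage support.
#'
#' @param mean_no_ai,mean_ai Group mean reporting times (seconds).
#' @return Percent reduction.
#' @export
delta_rt <- function(mean_no_ai, mean_ai) {
  100 * (mean_no_ai - mean_ai) / mean_no_ai
}

#' Reporting-time summaries per subgroup
#'
#' Mean, SD and n of reporting times per run for each subgroup of
#' experience level x ground truth (including the marginal "all" rows),
#' plus the percent reduction between runs.
#'
#' @param records Reader records.
#' @param truth Ground truth (named vector or data frame).
#' @return Data frame with one row per subgroup.
#' @export
reporting_time_summary <- function(records, truth) {
  tv <- truth_vector(truth)
  gt <- tv[records$scan_id]
  if (any(is.na(gt))) stop("missing ground truth")
  rows <- list()
  for (exp_lvl in c("all", unique(records$experience))) {
    for (g in c("all", "normal", "pathological")) {
      sel <- rep(TRUE, nrow(records))
      if (exp_lvl != "all") sel <- sel & records$experience == exp_lvl
      if (g != "all") sel <- sel & gt == g
      r <- records[sel, , drop = FALSE]
      if (!nrow(r)) next
      if (!all(c("no_ai", "ai") %in% r$run))
        stop("both runs must be present in subgroup ",
             exp_lvl, "/", g)
      t0 <- r$reporting_time[r$run == "no_ai"]
      t1 <- r$reporting_time[r$run == "ai"]
      rows[[length(rows) + 1L]] <- data.frame(
        experience = exp_lvl, ground_truth = g,
        mean_no_ai = mean(t0), sd_no_ai = stats::sd(t0), n_no_ai = length(t0),
        mean_ai = mean(t1), sd_ai = stats::sd(t1), n_ai = length(t1),
        delta_rt_pct = delta_rt(mean(t0), mean(t1)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Paired t test on reporting times
#'
#' Standard two-sided paired Student's t test. Degenerate inputs (all
#' differences zero, or zero variance of differences) return an explicit
#' degenerate result instead of failing.
#'
#' @param x,y Paired measurements (e.g. per-scan times in the two runs).
#' @return List with `statistic`, `df`, `p.value`, `mean_difference`,
#'   `degenerate`.
#' @export
paired_t_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(statistic = 0, df = length(d) - 1L, p.value = 1,
                  mean_difference = 0, degenerate = TRUE))
    return(list(statistic = sign(d[1]) * Inf, df = length(d) - 1L,
                p.value = 0, mean_difference = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, mean_difference = unname(tt$estimate),
       degenerate = FALSE)
}

# Exact null distribution of the signed-rank statistic over doubled
# midranks (so ties stay integral): probability mass g[s + 1] = P(2V = s).
signed_rank_null <- function(r2) {
  g <- c(1, rep(0, sum(r2)))
  len <- length(g)
  for (ri in r2) {
    g <- 0.5 * g
    g[(ri + 1L):len] <- g[(ri + 1L):len] + g[seq_len(len - ri)]
  }
  g
}

#' Wilcoxon signed-rank test with exact tie-aware null
#'
#' Zero differences are excluded; tied absolute differences receive
#' midranks. For n <= `exact_max_n` non-zero differences the two-sided
#' p-value comes from the exact null distribution of the positive-rank
#' sum (computed by convolution, valid under ties); above that, a normal
#' approximation with tie correction and continuity correction is used.
#' All-zero differences yield an explicit degenerate result.
#'
#' @param x,y Paired measurements; or differences in `x` with `y = NULL`.
#' @param exact_max_n Largest n for the exact null.
#' @return List with `statistic` (positive-rank sum V), `p.value`, `n`
#'   (non-zero differences), `method`, `degenerate`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max_n = 25L) {
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = NA_real_, p.value = NA_real_, n = 0L,
                method = "degenerate", degenerate = TRUE))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max_n) {
    r2 <- as.integer(round(2 * r))
    g <- signed_rank_null(r2)
    v2 <- as.integer(round(2 * v))
    p <- min(1, 2 * min(sum(g[seq_len(v2 + 1L)]),
                        sum(g[(v2 + 1L):length(g)])))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    s2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - 0.5 * sign(v - mu)) / sqrt(s2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = v, p.value = p, n = n, method = method,
       degenerate = FALSE)
}

#' Summaries of Likert confidence scores per group
#'
#' Reports both the mean +/- SD and the median with 25%/75% percentiles.
#'
#' @param records Reader records with a `confidence` column.
#' @param by Grouping columns of `records`.
#' @return Data frame with one row per group.
#' @export
likert_summary <- function(records, by = c("run", "experience")) {
  key <- interaction(records[by], drop = TRUE, sep = "/")
  rows <- lapply(split(records$confidence, key), function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(mean = mean(v), sd = stats::sd(v), median = q[2],
               q25 = q[1], q75 = q[3], n = length(v))
  })
  grp <- do.call(rbind, strsplit(names(rows), "/", fixed = TRUE))
  out <- cbind(as.data.frame(grp, stringsAsFactors = FALSE),
               do.call(rbind, rows))
  names(out)[seq_along(by)] <- by
  rownames(out) <- NULL
  out
}
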