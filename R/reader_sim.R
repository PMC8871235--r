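# Simulated reader studies: a scan cohort with documented pathology
# classes, and per reader x scan x run records (predicted label, predicted
# findings, reporting time, Likert confidence) drawn from configurable
# error-rate, reporting-time and confidence models. Defaults emulate a
# four-reader, 80-scan, two-run (with/without triage support) crossover.

#' Default reader panel: two experienced, two inexperienced readers
#' @export
default_readers <- function() {
  data.frame(reader_id = c("R1", "R2", "R3", "R4"),
             experience = c("experienced", "experienced",
                            "inexperienced", "inexperienced"),
             stringsAsFactors = FALSE)
}

#' Default per-(run, experience) misclassification probabilities
#'
#' `fp` is the probability of calling a normal scan pathological, `fn` the
#' probability of calling a pathological scan normal, per read.
#' @export
default_error_rates <- function() {
  data.frame(
    run = c("no_ai", "no_ai", "ai", "ai"),
    experience = c("experienced", "inexperienced",
                   "experienced", "inexperienced"),
    fp = c(4 / 80, 6 / 80, 0, 3 / 80),
    fn = c(0, 1 / 80, 0, 0),
    stringsAsFactors = FALSE)
}

#' Default reporting-time model (seconds)
#'
#' Truncated-normal mean/SD per (run, experience, ground truth).
#' @export
default_time_model <- function() {
  data.frame(
    run = rep(c("no_ai", "ai"), each = 4),
    experience = rep(rep(c("experienced", "inexperienced"), each = 2), 2),
    ground_truth = rep(c("normal", "pathological"), 4),
    mean = c(56.9, 76.2, 62.3, 64.4,
             46.2, 64.3, 46.3, 62.3),
    sd = c(7.2, 13.9, 8.4, 6.7,
           7.3, 10.2, 2.7, 7.1),
    stringsAsFactors = FALSE)
}

#' Default diagnostic-confidence model (5-point Likert)
#'
#' Target mean/SD of the discrete 1-5 confidence scores per
#' (run, experience); the simulator moment-matches a latent Gaussian so
#' the rounded, clamped scores reproduce these values.
#' @export
default_confidence_model <- function() {
  data.frame(
    run = c("no_ai", "ai", "no_ai", "ai"),
    experience = c("experienced", "experienced",
                   "inexperienced", "inexperienced"),
    mean = c(4.58, 4.61, 4.30, 4.35),
    sd = c(0.74, 0.72, 0.84, 0.79),
    stringsAsFactors = FALSE)
}

#' Default per-run probability of missing an individual finding class
#' @export
default_miss_rates <- function() {
  c(no_ai = 30 / 356, ai = 17 / 356)
}

# Expected discrete moments of round+clamp(N(mu, sigma)) on 1..5.
likert_moments <- function(mu, sigma) {
  cuts <- c(-Inf, 1.5, 2.5, 3.5, 4.5, Inf)
  p <- diff(stats::pnorm((cuts - mu) / sigma))
  m <- sum((1:5) * p)
  c(mean = m, sd = sqrt(sum((1:5)^2 * p) - m^2))
}

#' Latent Gaussian parameters matching target Likert moments
#'
#' Rounding and clamping a Gaussian to the 1-5 scale shifts its moments,
#' so the latent parameters are found by least-squares moment matching of
#' the closed-form discretized mean/SD.
#'
#' @param target_mean,target_sd Desired moments of the discrete scores.
#' @return Named vector `c(mu, sigma)` of the latent Gaussian.
#' @export
likert_latent_params <- function(target_mean, target_sd) {
  obj <- function(p) {
    mo <- likert_moments(p[1], exp(p[2]))
    sum((mo - c(target_mean, target_sd))^2)
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      control = list(reltol = 1e-12, maxit = 2000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

#' Simulate a labelled scan cohort with documented finding classes
#'
#' Pathological scans receive one main finding drawn from a fixed
#' frequency mix (tumors and subacute strokes most common) plus randomly
#' assigned additional findings so the cohort averages ~2.2 finding
#' classes per pathological scan. Normal scans carry no findings.
#'
#' @param n_normal,n_pathological Cohort sizes.
#' @param seed RNG seed.
#' @return Data frame with `scan_id`, `ground_truth` and a `findings`
#'   list-column.
#' @export
simulate_scan_table <- function(n_normal = 40, n_pathological = 40,
                                seed = 1) {
  main_counts <- c("tumor" = 10, "subacute stroke" = 7,
                   "intraparenchymal hemorrhage" = 6,
                   "subarachnoid hemorrhage" = 5, "late stroke" = 4,
                   "acute subdural hematoma" = 3, "cavernoma" = 2,
                   "acute stroke" = 2, "atrophy" = 1)
  with_seed(seed, {
    if (n_pathological == sum(main_counts)) {
      main <- sample(rep(names(main_counts), main_counts))
    } else {
      main <- sample(names(main_counts), n_pathological, replace = TRUE,
                     prob = main_counts / sum(main_counts))
    }
    findings <- lapply(main, function(f) f)
    n_extra <- round(2.225 * n_pathological) - n_pathological
    for (i in seq_len(n_extra)) {
      s <- sample.int(n_pathological, 1L)
      avail <- setdiff(finding_vocabulary, findings[[s]])
      if (length(avail))
        findings[[s]] <- c(findings[[s]], sample(avail, 1L))
    }
    ids <- sprintf("s%03d", seq_len(n_normal + n_pathological))
    gt <- sample(rep(c("normal", "pathological"),
                     c(n_normal, n_pathological)))
    fl <- vector("list", length(ids))
    fl[gt == "pathological"] <- findings
    fl[gt == "normal"] <- list(character(0))
    out <- data.frame(scan_id = ids, ground_truth = gt,
                      stringsAsFactors = FALSE)
    out$findings <- fl
    out
  })
}

# Truncated-normal draws with a positive floor (rejection sampling).
rtnorm_floor <- function(n, mean, sd, floor = 5) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < floor))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

lookup_row <- function(df, ...) {
  keys <- list(...)
  sel <- rep(TRUE, nrow(df))
  for (k in names(keys)) sel <- sel & df[[k]] == keys[[k]]
  if (sum(sel) != 1L)
    stop("model table must match exactly one row for ",
         paste(unlist(keys), collapse = "/"))
  df[sel, , drop = FALSE]
}

#' Simulate a two-run reader study
#'
#' One record per reader x scan x run. Patient-level labels flip from
#' ground truth with the per-(run, experience) probabilities; individual
#' finding classes on pathological scans are missed independently with
#' the per-run probability; reporting times follow a truncated normal
#' (floor 5 s) per (run, experience, ground truth); confidence scores are
#' discretized latent Gaussians per (run, experience).
#'
#' @param scans Cohort from [simulate_scan_table()] (or [read_worklist()]).
#' @param readers Data frame `reader_id`, `experience`.
#' @param error_rates,time_model,confidence_model,miss_rates Model tables;
#'   see the `default_*()` functions.
#' @param seed RNG seed.
#' @return Data frame of reader records with a `predicted_findings`
#'   list-column.
#' @export
simulate_reader_study <- function(scans = simulate_scan_table(),
                                  readers = default_readers(),
                                  error_rates = default_error_rates(),
                                  time_model = default_time_model(),
                                  confidence_model = default_confidence_model(),
                                  miss_rates = default_miss_rates(),
                                  seed = 1) {
  stopifnot(all(error_rates$fp >= 0 & error_rates$fp <= 1),
            all(error_rates$fn >= 0 & error_rates$fn <= 1),
            all(time_model$sd >= 0))
  latent <- lapply(seq_len(nrow(confidence_model)), function(i)
    likert_latent_params(confidence_model$mean[i], confidence_model$sd[i]))
  out <- list()
  with_seed(seed, {
    for (run in c("no_ai", "ai")) {
      for (ri in seq_len(nrow(readers))) {
        exp_lvl <- readers$experience[ri]
        er <- lookup_row(error_rates, run = run, experience = exp_lvl)
        ci <- which(confidence_model$run == run &
                      confidence_model$experience == exp_lvl)
        lp <- latent[[ci]]
        n <- nrow(scans)
        gt <- scans$ground_truth
        flip <- stats::runif(n) < ifelse(gt == "normal", er$fp, er$fn)
        predicted <- ifelse(xor(gt == "pathological", flip),
                            "pathological", "normal")
        pf <- vector("list", n)
        for (si in seq_len(n)) {
          f <- scans$findings[[si]]
          if (!length(f)) {
            # a false-positive read still attributes some finding label
            pf[[si]] <- if (predicted[si] == "pathological")
              sample(finding_vocabulary, 1L) else character(0)
          } else {
            keep <- stats::runif(length(f)) >= miss_rates[[run]]
            pf[[si]] <- f[keep]
          }
        }
        times <- numeric(n)
        for (g in c("normal", "pathological")) {
          tm <- lookup_row(time_model, run = run, experience = exp_lvl,
                           ground_truth = g)
          sel <- gt == g
          times[sel] <- rtnorm_floor(sum(sel), tm$mean, tm$sd)
        }
        conf <- pmin(5L, pmax(1L, as.integer(round(
          stats::rnorm(n, lp[["mu"]], lp[["sigma"]])))))
        rec <- data.frame(reader_id = readers$reader_id[ri],
                          experience = exp_lvl,
                          scan_id = scans$scan_id, run = run,
                          predicted = predicted,
                          reporting_time = times, confidence = conf,
                          stringsAsFactors = FALSE)
        rec$predicted_findings <- pf
        out[[length(out) + 1L]] <- rec
      }
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
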