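# Two-threshold triage of anomaly scores into normal / inconclusive /
# pathological, with thresholds calibrated to minimize the false positive
# rate under a false-omission-rate-of-0 constraint.

#' Calibrate triage thresholds on a labelled validation set
#'
#' Places the thresholds at the observed extremes: `t_upper` is the
#' maximum score among normal calibration scans, `t_lower` the minimum
#' score among pathological scans (clamped to `t_upper` when the classes
#' separate, so the band collapses instead of inverting). Under the
#' strict-inequality labelling rule of [triage()], this guarantees on the
#' calibration set that no pathological scan is labelled normal (false
#' omission rate 0) and no normal scan is labelled pathological (false
#' positive rate 0), and it is the tightest such pair, i.e. it maximizes
#' the conclusive yield subject to both constraints.
#'
#' @param scores Numeric anomaly scores in [0, 1].
#' @param labels Character vector, `"normal"` or `"pathological"`.
#' @param margin Optional safety margin subtracted from `t_lower`
#'   (clamped at 0).
#' @param margin_upper Optional generalization margin added to `t_upper`
#'   (clamped at 1). The default 0 places `t_upper` exactly at the
#'   maximum normal calibration score; because a fresh normal scan
#'   exceeds the maximum of n calibration normals with probability
#'   1/(n+1), a positive margin (e.g. a few SDs of the normal
#'   calibration scores) is needed for the zero-false-positive
#'   behaviour to generalize to unseen scans. Both constraints on the
#'   calibration set are preserved for any margin.
#' @param tag Free-form calibration tag (e.g. scanner identifier);
#'   thresholds are scanner-specific.
#' @return An object of class `triage_thresholds` with `t_lower`,
#'   `t_upper`, `n_normal`, `n_pathological`, `tag`.
#' @export
calibrate_thresholds <- function(scores, labels, margin = 0,
                                 margin_upper = 0, tag = NA_character_) {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  if (any(!is.finite(scores)) || any(scores < 0) || any(scores > 1))
    stop("scores must lie in [0, 1]")
  if (!all(labels %in% c("normal", "pathological")))
    stop("labels must be 'normal' or 'pathological'")
  norm <- scores[labels == "normal"]
  path <- scores[labels == "pathological"]
  if (!length(norm) || !length(path))
    stop("need at least one score of each class")
  t_upper <- min(1, max(norm) + margin_upper)
  t_lower <- min(min(path), t_upper)
  t_lower <- max(0, t_lower - margin)
  structure(list(t_lower = t_lower, t_upper = t_upper,
                 n_normal = length(norm), n_pathological = length(path),
                 tag = tag),
            class = "triage_thresholds")
}

#' @export
print.triage_thresholds <- function(x, ...) {
  cat(sprintf(
    "<triage_thresholds> t_lower = %.4f, t_upper = %.4f (%d normal, %d pathological%s)\n",
    x$t_lower, x$t_upper, x$n_normal, x$n_pathological,
    if (is.na(x$tag)) "" else paste0(", tag ", x$tag)))
  invisible(x)
}

#' Save/load thresholds as JSON
#'
#' @param thresholds A `triage_thresholds` object.
#' @param path JSON file path.
#' @export
write_thresholds <- function(thresholds, path) {
  jsonlite::write_json(unclass(thresholds), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x[c("t_lower", "t_upper", "n_normal", "n_pathological", "tag")],
            class = "triage_thresholds")
}

#' Map anomaly scores to triage labels
#'
#' Strict inequalities: `s < t_lower` is `"normal"`, `s > t_upper` is
#' `"pathological"`, everything in between — including scores exactly on a
#' threshold — is `"inconclusive"`.
#'
#' @param score Numeric vector of scores in [0, 1].
#' @param thresholds A `triage_thresholds` object.
#' @return Character vector of labels.
#' @export
triage <- function(score, thresholds) {
  stopifnot(inherits(thresholds, "triage_thresholds"))
  if (any(!is.finite(score)) || any(score < 0) || any(score > 1))
    stop("scores must lie in [0, 1]")
  ifelse(score < thresholds$t_lower, "normal",
         ifelse(score > thresholds$t_upper, "pathological",
                "inconclusive"))
}

#' Colors used to present triage labels
#' @export
triage_colors <- c(normal = "green", inconclusive = "white",
                   pathological = "red")

#' Build a triaged worklist
#'
#' One row per scan with score, label and display color, sorted
#' pathological-first, then by descending score — every red row precedes
#' every white and green row.
#'
#' @param results List of `anomaly_result` objects (or a data frame with
#'   `scan_id` and `score`).
#' @param thresholds A `triage_thresholds` object.
#' @return Data frame with `scan_id`, `score`, `label`, `color`.
#' @export
triage_worklist <- function(results, thresholds) {
  if (is.data.frame(results)) {
    df <- results[c("scan_id", "score")]
  } else {
    df <- data.frame(
      scan_id = vapply(results, function(r) as.character(r$scan_id), ""),
      score = vapply(results, function(r) r$score, 0),
      stringsAsFactors = FALSE)
  }
  df$label <- triage(df$score, thresholds)
  df$color <- unname(triage_colors[df$label])
  prio <- c(pathological = 1L, inconclusive = 2L, normal = 3L)
  df <- df[order(prio[df$label], -df$score), ]
  rownames(df) <- NULL
  df
}
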