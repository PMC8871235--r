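# Inference against the normative atlas: outlier voxels, the patient-level
# anomaly score (outlier voxels / brain volume, in [0, 1]) and exceedance
# heatmaps.

#' Detect outlier voxels against the atlas bounds
#'
#' A voxel is an outlier iff it lies inside the brain mask AND its
#' (clipped) intensity falls strictly outside `[lower, upper]`. Voxels
#' exactly on a bound are not outliers; the strict inequality is a fixed,
#' measure-zero convention. The atlas clip window is applied to the scan
#' first so scan and atlas see the same preprocessing.
#'
#' @param v A [volume_grid()] on the atlas grid.
#' @param atlas A `normal_atlas` from [fit_atlas()].
#' @return A [binary_mask()] of outlier voxels (subset of the brain mask).
#' @export
detect_outliers <- function(v, atlas) {
  stopifnot(inherits(v, "volume_grid"), inherits(atlas, "normal_atlas"))
  stop_grid_mismatch(v, atlas$brain_mask)
  a <- v$data
  if (!is.null(atlas$clip_range))
    a <- pmin(pmax(a, atlas$clip_range[1]), atlas$clip_range[2])
  out <- atlas$brain_mask$data & !is.na(atlas$lower) &
    (a < atlas$lower | a > atlas$upper)
  out[is.na(out)] <- FALSE
  binary_mask(out, v$spacing, v$origin)
}

#' Patient-level anomaly score
#'
#' The exact ratio of outlier voxels to brain-mask voxels, in [0, 1].
#'
#' @param outliers [binary_mask()] of outlier voxels.
#' @param brain [binary_mask()]; must be non-empty and contain `outliers`.
#' @return Scalar score in [0, 1].
#' @export
anomaly_score <- function(outliers, brain) {
  stop_grid_mismatch(outliers, brain)
  nb <- sum(brain$data)
  if (nb == 0L) stop("empty brain mask")
  if (any(outliers$data & !brain$data))
    stop("outlier mask extends outside the brain mask")
  sum(outliers$data) / nb
}

#' Build an exceedance heatmap
#'
#' Zero outside the outlier mask; inside it, the magnitude of bound
#' exceedance in SD units:
#' `max(0, (v - upper)/sigma, (lower - v)/sigma)`.
#' Set `binary = TRUE` for a plain 0/1 anomaly map.
#'
#' @param v Scored [volume_grid()] (atlas grid).
#' @param atlas A `normal_atlas`.
#' @param outliers [binary_mask()] from [detect_outliers()].
#' @param binary Emit 0/1 instead of SD-units exceedance.
#' @return A [volume_grid()].
#' @export
build_heatmap <- function(v, atlas, outliers, binary = FALSE) {
  stop_grid_mismatch(v, atlas$brain_mask)
  stop_grid_mismatch(outliers, atlas$brain_mask)
  h <- array(0, dim(v$data))
  sel <- outliers$data
  if (any(sel)) {
    if (binary) {
      h[sel] <- 1
    } else {
      a <- v$data
      if (!is.null(atlas$clip_range))
        a <- pmin(pmax(a, atlas$clip_range[1]), atlas$clip_range[2])
      e <- pmax(0, (a[sel] - atlas$upper[sel]) / atlas$sigma[sel],
                (atlas$lower[sel] - a[sel]) / atlas$sigma[sel])
      h[sel] <- e
    }
  }
  volume_grid(h, v$spacing, v$origin)
}

#' Score one scan against the atlas
#'
#' The full inference chain: optional registration to the atlas template,
#' outlier detection, anomaly score and heatmap.
#'
#' @param v A [volume_grid()].
#' @param atlas A `normal_atlas`.
#' @param registration_mode `"identity"` (scan already in atlas space),
#'   `"translation"` or `"affine"`.
#' @param scan_id Identifier carried into the result.
#' @param ... Further arguments passed to [register()].
#' @return An object of class `anomaly_result`: `scan_id`, `score`,
#'   `outlier_mask`, `heatmap`, `n_outlier`, `n_brain`,
#'   `registration` (or `NULL`).
#' @export
score_scan <- function(v, atlas, registration_mode = "identity",
                       scan_id = NA_character_, ...) {
  reg <- NULL
  if (registration_mode != "identity") {
    reg <- log_stage("register",
                     register(v, atlas$template, mode = registration_mode,
                              ...))
    v <- reg$resampled
  }
  outliers <- log_stage("detect_outliers", detect_outliers(v, atlas))
  s <- anomaly_score(outliers, atlas$brain_mask)
  heat <- build_heatmap(v, atlas, outliers)
  structure(list(scan_id = scan_id, score = s, outlier_mask = outliers,
                 heatmap = heat, n_outlier = sum(outliers$data),
                 n_brain = sum(atlas$brain_mask$data),
                 registration = reg),
            class = "anomaly_result")
}

#' @export
print.anomaly_result <- function(x, ...) {
  cat(sprintf("<anomaly_result> scan %s: score %.4f (%d / %d voxels)\n",
              x$scan_id, x$score, x$n_outlier, x$n_brain))
  invisible(x)
}
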