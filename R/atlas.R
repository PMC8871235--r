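# The voxel-wise Gaussian normative atlas: per-voxel mean/SD across
# registered normal scans and the derived acceptance bounds
# [mu - k*sigma, mu + k*sigma] inside a brain mask. Voxels outside the
# mask carry undefined (NA) statistics and are never scored.

#' Extract a brain mask by HU windowing and morphology
#'
#' Thresholds the volume to a soft-tissue window, applies morphological
#' opening then closing (Euclidean-ball structuring elements) and keeps
#' the largest 6-connected component. Air background and the dense skull
#' shell fall outside the window by construction.
#'
#' @param v A [volume_grid()].
#' @param tissue_window Inclusive HU interval considered brain tissue.
#' @param opening_radius,closing_radius Structuring-element radii
#'   (voxels); 0 skips the operation.
#' @return A [binary_mask()].
#' @export
extract_brain_mask <- function(v, tissue_window = c(0, 100),
                               opening_radius = 1, closing_radius = 1) {
  stopifnot(inherits(v, "volume_grid"))
  m <- v$data >= tissue_window[1] & v$data <= tissue_window[2]
  if (opening_radius > 0) m <- open3d(m, opening_radius)
  if (closing_radius > 0) m <- close3d(m, closing_radius)
  if (!any(m)) stop("empty brain mask")
  m <- largest_component3d(m)
  if (!any(m)) stop("empty brain mask")
  binary_mask(m, v$spacing, v$origin)
}

#' Fit the voxel-wise Gaussian normative atlas
#'
#' Computes the per-voxel sample mean and sample SD (denominator n-1)
#' across registered normal scans, floors the SD at `sigma_min`, and
#' derives the normative bounds `lower = mu - k*sigma`,
#' `upper = mu + k*sigma`. Intensities are clipped to `clip_range` before
#' fitting (a brain display window); scoring applies the same clip. The
#' fit is invariant to the order of the scan list.
#'
#' @param scans List of [volume_grid()]s, all on the template grid.
#' @param brain_mask [binary_mask()] delimiting scored voxels.
#' @param k Bound half-width in SD units. The default 2.576 gives 99%
#'   two-sided Gaussian coverage.
#' @param sigma_min SD floor (HU), keeping bounds non-degenerate at
#'   zero-variance voxels.
#' @param clip_range HU clip window applied before fitting, or `NULL`.
#' @param template Optional [volume_grid()] template to store; defaults
#'   to the voxelwise mean volume.
#' @return An object of class `normal_atlas` with fields `template`,
#'   `brain_mask`, `mu`, `sigma`, `lower`, `upper` (arrays, `NA` outside
#'   the mask), `k`, `sigma_min`, `clip_range`, `n_train`.
#' @export
fit_atlas <- function(scans, brain_mask, k = 2.576, sigma_min = 1,
                      clip_range = c(-100, 200), template = NULL) {
  if (length(scans) < 2L) stop("need at least 2 training scans")
  stopifnot(inherits(brain_mask, "binary_mask"), k >= 0, sigma_min > 0)
  ref <- scans[[1L]]
  for (s in scans) stop_grid_mismatch(s, ref)
  stop_grid_mismatch(brain_mask, ref)
  if (!any(brain_mask$data)) stop("brain mask is empty")
  n <- length(scans)
  nv <- length(ref$data)
  X <- matrix(0, n, nv)
  for (i in seq_len(n)) {
    a <- scans[[i]]$data
    if (!is.null(clip_range)) a <- pmin(pmax(a, clip_range[1]), clip_range[2])
    X[i, ] <- a
  }
  mu <- colMeans(X)
  sigma <- sqrt(colSums(sweep(X, 2L, mu)^2) / (n - 1))
  sigma <- pmax(sigma, sigma_min)
  dm <- dim(ref$data)
  mu <- array(mu, dm); sigma <- array(sigma, dm)
  if (is.null(template)) template <- volume_grid(mu, ref$spacing, ref$origin)
  outside <- !brain_mask$data
  mu[outside] <- NA_real_
  sigma[outside] <- NA_real_
  structure(list(template = template, brain_mask = brain_mask,
                 mu = mu, sigma = sigma,
                 lower = mu - k * sigma, upper = mu + k * sigma,
                 k = k, sigma_min = sigma_min, clip_range = clip_range,
                 n_train = n),
            class = "normal_atlas")
}

#' @export
print.normal_atlas <- function(x, ...) {
  cat(sprintf(
    "<normal_atlas> %s voxels, %d brain voxels, n_train = %d, k = %g\n",
    paste(dim(x$mu), collapse = "x"), sum(x$brain_mask$data),
    x$n_train, x$k))
  cat(sprintf("  sigma in [%.3g, %.3g] HU (floor %g)\n",
              min(x$sigma, na.rm = TRUE), max(x$sigma, na.rm = TRUE),
              x$sigma_min))
  invisible(x)
}

#' Persist an atlas as a directory of NIfTI volumes plus JSON metadata
#'
#' Statistic maps are stored with 0 outside the brain mask (NIfTI has no
#' native missingness); [read_atlas()] restores the `NA`s from the mask.
#'
#' @param atlas A `normal_atlas`.
#' @param dir Output directory (created if needed).
#' @export
write_atlas <- function(atlas, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gm <- atlas$brain_mask
  zero_fill <- function(a) {
    a[is.na(a)] <- 0
    volume_grid(a, gm$spacing, gm$origin)
  }
  write_volume(atlas$template, file.path(dir, "template.nii.gz"))
  write_volume(gm, file.path(dir, "brain_mask.nii.gz"))
  write_volume(zero_fill(atlas$mu), file.path(dir, "mu.nii.gz"))
  write_volume(zero_fill(atlas$sigma), file.path(dir, "sigma.nii.gz"))
  jsonlite::write_json(
    list(k = atlas$k, sigma_min = atlas$sigma_min,
         clip_range = atlas$clip_range, n_train = atlas$n_train),
    file.path(dir, "atlas.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "atlas.json"),
                              simplifyVector = TRUE)
  template <- read_volume(file.path(dir, "template.nii.gz"))
  mask <- mask_from_volume(read_volume(file.path(dir, "brain_mask.nii.gz")))
  restore <- function(name) {
    a <- read_volume(file.path(dir, paste0(name, ".nii.gz")))$data
    a[!mask$data] <- NA_real_
    a
  }
  mu <- restore("mu")
  sigma <- restore("sigma")
  structure(list(template = template, brain_mask = mask, mu = mu,
                 sigma = sigma, lower = mu - meta$k * sigma,
                 upper = mu + meta$k * sigma, k = meta$k,
                 sigma_min = meta$sigma_min, clip_range = meta$clip_range,
                 n_train = meta$n_train),
            class = "normal_atlas")
}
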