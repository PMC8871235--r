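# Core volumetric containers and NIfTI / worklist I/O.
#
# Axis convention: arrays are indexed [i, j, k]; voxel (i, j, k) sits at
# physical position origin + (index - 1) * spacing on each axis, with an
# axis-aligned, positively oriented grid. All modelling and scoring happens
# in the voxel space of the atlas template after registration, so only
# internal consistency of this convention matters.

#' Finding vocabulary
#'
#' The fixed set of pathology class labels a scan record may carry.
#' @export
finding_vocabulary <- c(
  "tumor", "subacute stroke", "intraparenchymal hemorrhage",
  "subarachnoid hemorrhage", "late stroke", "acute subdural hematoma",
  "cavernoma", "acute stroke", "atrophy", "intraventricular hemorrhage",
  "midline shift", "skull fracture"
)

#' Construct a volume grid
#'
#' A `volume_grid` is a 3D scalar intensity field (Hounsfield-unit-like
#' scale) together with voxel spacing (mm) and the physical position of
#' voxel (1,1,1) (mm).
#'
#' @param data 3D numeric array of intensities.
#' @param spacing Length-3 positive voxel edge lengths in mm.
#' @param origin Length-3 physical coordinate of the first voxel, mm.
#' @param check_finite Reject non-finite voxels (default `TRUE`).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        check_finite = TRUE) {
  data <- unclass(data)
  attributes(data) <- list(dim = dim(data))
  if (length(dim(data)) != 3L) stop("volume must be 3D")
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive finite numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite numbers")
  if (check_finite && !all(is.finite(data)))
    stop("volume contains non-finite voxels")
  structure(list(data = data, spacing = spacing, origin = origin,
                 axis_order = "ijk"),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s voxels, spacing %s mm, origin (%s)\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

#' Construct a binary mask on a volume grid
#'
#' @param data 3D logical array.
#' @param spacing,origin Grid metadata, as in [volume_grid()].
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- unclass(data)
  attributes(data) <- list(dim = dim(data))
  if (length(dim(data)) != 3L) stop("mask must be 3D")
  if (!is.logical(data)) {
    if (!all(data %in% c(0, 1))) stop("mask values must be logical or 0/1")
    data <- array(as.logical(data), dim(data))
  }
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), axis_order = "ijk"),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels, %d foreground (%.2f%%)\n",
              paste(dim(x$data), collapse = "x"), sum(x$data),
              100 * mean(x$data)))
  invisible(x)
}

#' @export
dim.binary_mask <- function(x) dim(x$data)

# Grids compatible for voxelwise operations?
same_grid <- function(a, b, tol = 1e-4) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

stop_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b)) stop("grid mismatch between volumes/masks")
  invisible(TRUE)
}

#' Read a NIfTI volume
#'
#' Reads a 3D NIfTI-1 file (`.nii`/`.nii.gz`); spacing and origin come from
#' the header transform. By default, non-finite voxels are a hard error —
#' silently repaired values would hide acquisition problems; opt into
#' replacement with `nonfinite = "repair"`.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param nonfinite `"error"` (default) or `"repair"` (replace non-finite
#'   voxels with `background`).
#' @param background Replacement value for `nonfinite = "repair"`, HU.
#' @return A [volume_grid()].
#' @export
read_volume <- function(path, nonfinite = c("error", "repair"),
                        background = -1000) {
  nonfinite <- match.arg(nonfinite)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("volume must be 3D")
  m <- RNifti::xform(img)
  spacing <- sqrt(colSums(m[1:3, 1:3]^2))
  if (any(spacing <= 0)) spacing <- RNifti::pixdim(img)
  origin <- m[1:3, 4]
  a <- array(as.numeric(img), dim(img))
  if (!all(is.finite(a))) {
    if (nonfinite == "error")
      stop("volume contains non-finite voxels (use nonfinite = \"repair\")")
    a[!is.finite(a)] <- background
  }
  volume_grid(a, spacing = spacing, origin = origin)
}

#' Write a volume to NIfTI
#'
#' Stored as float64, so the round trip through [read_volume()] is exact.
#'
#' @param v A [volume_grid()] or [binary_mask()] (masks are written 0/1).
#' @param path Output `.nii` or `.nii.gz` path.
#' @export
write_volume <- function(v, path) {
  if (inherits(v, "binary_mask"))
    v <- volume_grid(array(as.numeric(v$data), dim(v$data)),
                     v$spacing, v$origin)
  if (!inherits(v, "volume_grid")) stop("v must be a volume_grid")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path: ", path)
  img <- RNifti::asNifti(v$data, datatype = "double")
  m <- rbind(cbind(diag(v$spacing), v$origin), c(0, 0, 0, 1))
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Threshold a stored 0/1 volume back into a mask
#'
#' @param v A [volume_grid()].
#' @param threshold Values `> threshold` become `TRUE`.
#' @return A [binary_mask()].
#' @export
mask_from_volume <- function(v, threshold = 0.5) {
  binary_mask(v$data > threshold, v$spacing, v$origin)
}

#' Read a scan worklist
#'
#' CSV with columns `scan_id`, `volume_path`, `ground_truth`
#' (`normal`/`pathological`) and `finding_labels` (semicolon-separated,
#' drawn from [finding_vocabulary]). Label/finding consistency is enforced:
#' normal scans must have no findings, pathological scans at least one.
#'
#' @param path CSV path.
#' @return A data frame with a `findings` list-column.
#' @export
read_worklist <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("scan_id", "volume_path", "ground_truth", "finding_labels")
  if (!all(need %in% names(df)))
    stop("worklist must have columns: ", paste(need, collapse = ", "))
  findings <- lapply(df$finding_labels, function(s) {
    f <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    f[nzchar(f)]
  })
  for (i in seq_len(nrow(df))) {
    gt <- df$ground_truth[i]
    f <- findings[[i]]
    if (!gt %in% c("normal", "pathological"))
      stop("row ", i, ": ground_truth must be 'normal' or 'pathological'")
    bad <- setdiff(f, finding_vocabulary)
    if (length(bad))
      stop("row ", i, ": unknown finding label(s): ",
           paste(bad, collapse = ", "))
    if (gt == "normal" && length(f))
      stop("row ", i, ": normal scan must not carry findings")
    if (gt == "pathological" && !length(f))
      stop("row ", i, ": pathological scan must carry at least one finding")
  }
  out <- data.frame(scan_id = df$scan_id, volume_path = df$volume_path,
                    ground_truth = df$ground_truth,
                    stringsAsFactors = FALSE)
  out$findings <- findings
  out
}

#' Write a scan worklist
#'
#' @param worklist Data frame as returned by [read_worklist()].
#' @param path Output CSV path.
#' @export
write_worklist <- function(worklist, path) {
  df <- data.frame(
    scan_id = worklist$scan_id,
    volume_path = worklist$volume_path,
    ground_truth = worklist$ground_truth,
    finding_labels = vapply(worklist$findings, paste, "", collapse = ";"),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
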