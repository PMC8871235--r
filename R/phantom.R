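# Synthetic head-CT phantoms: an ellipsoidal brain with a thin skull shell
# on an air background, per-voxel Gaussian intensity variation (a smooth
# texture field plus independent noise), optional small affine
# misalignment, and focal hyper-/hypodense lesions of controlled volume
# fraction. Every output is fully determined by its seed.

#' Specify a phantom
#'
#' Defaults describe a desk-scale head phantom: a 32^3 grid (1 mm voxels)
#' holding an ellipsoidal brain of ~35 HU soft tissue with smooth texture
#' (SD 3 HU, correlation length ~2 voxels), independent voxel noise
#' (SD 5 HU), a 700 HU skull shell and -1000 HU air. Misalignment is
#' opt-in via `jitter_translation`/`jitter_rotation`.
#'
#' @param shape Grid dimensions (voxels).
#' @param brain_semiaxes Ellipsoid semi-axes of the brain (voxels).
#' @param brain_center Ellipsoid center (voxel index); defaults to the
#'   grid center.
#' @param tissue_mean Mean brain intensity (HU).
#' @param tissue_texture_sd SD of the smooth spatial texture field (HU).
#' @param texture_smoothness Gaussian smoothing sigma of the texture
#'   field (voxels).
#' @param noise_sd SD of independent per-voxel noise (HU).
#' @param background_value Intensity outside the head (HU).
#' @param skull_value Intensity of the skull shell (HU).
#' @param skull_thickness Shell thickness (voxels).
#' @param jitter_translation Maximum per-axis translation applied to
#'   simulate misalignment (voxels; 0 disables).
#' @param jitter_rotation Maximum per-axis rotation (degrees; 0 disables).
#' @param anatomy_blobs Number of smooth Gaussian intensity blobs that
#'   form the fixed internal anatomy of the template (0 for a flat
#'   brain). The blobs are drawn once from `seed` and shared by every
#'   scan of the phantom, mimicking stable anatomical structure.
#' @param anatomy_amplitude SD of the blob amplitudes (HU).
#' @param edge_width Width (voxels) of the smooth logistic transition at
#'   the tissue/skull/air interfaces; 0 gives crisp binary edges. A
#'   positive width makes the scene analytically smooth, which is the
#'   appropriate ground truth for registration accuracy studies.
#' @param spacing Voxel size (mm).
#' @param seed RNG seed; fully determines every generated scan.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32, 32, 32),
                         brain_semiaxes = c(11, 13, 9),
                         brain_center = (shape + 1) / 2,
                         tissue_mean = 35,
                         tissue_texture_sd = 3,
                         texture_smoothness = 2,
                         noise_sd = 5,
                         background_value = -1000,
                         skull_value = 700,
                         skull_thickness = 2,
                         jitter_translation = 0,
                         jitter_rotation = 0,
                         anatomy_blobs = 25,
                         anatomy_amplitude = 6,
                         edge_width = 0,
                         spacing = c(1, 1, 1),
                         seed = 1) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L),
            length(brain_semiaxes) == 3L, all(brain_semiaxes > 0),
            noise_sd >= 0, tissue_texture_sd >= 0,
            jitter_translation >= 0, jitter_rotation >= 0)
  outer_extent <- brain_semiaxes + skull_thickness
  if (any(brain_center - outer_extent < 1) ||
      any(brain_center + outer_extent > shape))
    stop("brain ellipsoid (plus skull shell) exceeds the grid")
  structure(list(shape = shape, brain_semiaxes = brain_semiaxes,
                 brain_center = brain_center, tissue_mean = tissue_mean,
                 tissue_texture_sd = tissue_texture_sd,
                 texture_smoothness = texture_smoothness,
                 noise_sd = noise_sd, background_value = background_value,
                 skull_value = skull_value,
                 skull_thickness = skull_thickness,
                 jitter_translation = jitter_translation,
                 jitter_rotation = jitter_rotation,
                 anatomy_blobs = as.integer(anatomy_blobs),
                 anatomy_amplitude = anatomy_amplitude,
                 edge_width = edge_width,
                 spacing = as.numeric(spacing), seed = seed),
            class = "phantom_spec")
}

#' Specify focal lesions
#'
#' Lesions are ellipsoids with random axis ratios, placed fully inside the
#' (eroded) brain mask, jointly covering a controlled fraction of brain
#' voxels. `contrast` is the signed HU offset added inside lesions:
#' positive emulates hyperdense findings (bleeds), negative hypodense ones
#' (strokes).
#'
#' @param count Number of lesions.
#' @param target_volume_fraction Lesion voxels / brain voxels, in (0, 1).
#' @param contrast Signed HU offset inside lesions.
#' @param axis_ratio_range Bounds for the random relative semi-axes.
#' @param seed RNG seed (defaults to the phantom seed at simulation time).
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(count = 2, target_volume_fraction = 0.05,
                        contrast = 50, axis_ratio_range = c(0.7, 1.4),
                        seed = NULL) {
  stopifnot(count >= 1, target_volume_fraction > 0,
            target_volume_fraction < 1, length(axis_ratio_range) == 2L,
            axis_ratio_range[1] > 0,
            axis_ratio_range[2] >= axis_ratio_range[1])
  structure(list(count = as.integer(count),
                 target_volume_fraction = target_volume_fraction,
                 contrast = contrast, axis_ratio_range = axis_ratio_range,
                 seed = seed),
            class = "lesion_spec")
}

# Fixed anatomy of a phantom: Gaussian blob centers (physical mm),
# widths and amplitudes, drawn once from the phantom seed so every scan
# of the phantom shares the same internal structure.
anatomy_params <- function(spec) {
  if (spec$anatomy_blobs < 1L || spec$anatomy_amplitude <= 0) return(NULL)
  with_seed(spec$seed + 777L, {
    b <- spec$anatomy_blobs
    u <- matrix(stats::rnorm(3 * b), 3)
    u <- u / rep(sqrt(colSums(u^2)), each = 3)
    rad <- stats::runif(b)^(1 / 3) * 0.75
    centers <- (spec$brain_center - 1) * spec$spacing +
      u * rep(rad, each = 3) * (spec$brain_semiaxes * spec$spacing)
    list(centers = centers,
         sd = stats::runif(b, 2, 4) * mean(spec$spacing),
         amp = stats::rnorm(b, 0, spec$anatomy_amplitude))
  })
}

# Evaluate the analytic scene (brain/skull geometry + anatomy blobs) at
# arbitrary physical coordinates (3 x N matrix). With edge_width > 0 the
# tissue/skull/air interfaces are logistic ramps instead of steps.
eval_scene <- function(spec, anat, pts) {
  cphys <- (spec$brain_center - 1) * spec$spacing
  enorm <- function(semi) {
    colSums(((pts - cphys) / (semi * spec$spacing))^2)
  }
  d_in <- enorm(spec$brain_semiaxes)
  d_out <- enorm(spec$brain_semiaxes + spec$skull_thickness)
  brain <- d_in <= 1
  field <- 0
  if (!is.null(anat)) {
    for (b in seq_along(anat$amp))
      field <- field + anat$amp[b] *
        exp(-colSums((pts - anat$centers[, b])^2) / (2 * anat$sd[b]^2))
  }
  tissue <- spec$tissue_mean + field
  if (spec$edge_width > 0) {
    # ellipsoid-norm offset ~ 2 * (radial distance) / rbar at the surface
    slope <- mean(spec$brain_semiaxes) / spec$edge_width
    s_in <- stats::plogis(-(d_in - 1) * slope)
    s_out <- stats::plogis(-(d_out - 1) * slope)
    val <- spec$background_value +
      (spec$skull_value - spec$background_value) * s_out +
      (tissue - spec$skull_value) * s_in
  } else {
    val <- rep(spec$background_value, ncol(pts))
    val[d_out <= 1] <- spec$skull_value
    val[brain] <- rep(tissue, length.out = ncol(pts))[brain]
  }
  list(values = val, brain = brain)
}

grid_coords <- function(shape, spacing, origin = c(0, 0, 0)) {
  xs <- origin[1] + (seq_len(shape[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(shape[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(shape[3]) - 1) * spacing[3]
  rbind(rep(xs, times = shape[2] * shape[3]),
        rep(rep(ys, each = shape[1]), times = shape[3]),
        rep(zs, each = shape[1] * shape[2]))
}

#' Build the noiseless template and its brain mask
#'
#' The template carries the texture field at its mean (i.e. no texture, no
#' noise): tissue plus the fixed smooth anatomy field inside the brain
#' ellipsoid, the skull shell, and background elsewhere. The scene is
#' analytic, so it can be sampled at an arbitrary `pose`: a transform
#' mapping grid coordinates to scene coordinates (pull convention),
#' yielding an exactly misaligned template with no interpolation error —
#' useful as ground truth for registration.
#'
#' @param spec A [phantom_spec()].
#' @param pose Optional [affine_transform()]; `NULL` samples the scene in
#'   its native pose.
#' @return List with `template` (a [volume_grid()]) and `brain_mask`
#'   (a [binary_mask()]).
#' @export
make_template <- function(spec, pose = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  anat <- anatomy_params(spec)
  pts <- grid_coords(spec$shape, spec$spacing)
  if (!is.null(pose)) pts <- apply_transform(pose, pts)
  sc <- eval_scene(spec, anat, pts)
  list(template = volume_grid(array(sc$values, spec$shape),
                              spacing = spec$spacing),
       brain_mask = binary_mask(array(sc$brain, spec$shape),
                                spacing = spec$spacing))
}

# Unjittered normal scan: template + smooth texture + iid noise.
simulate_normal_core <- function(tmpl, spec) {
  a <- tmpl$data
  if (spec$tissue_texture_sd > 0) {
    z <- gaussian_smooth3d(array(stats::rnorm(length(a)), dim(a)),
                           spec$texture_smoothness)
    a <- a + z / stats::sd(z) * spec$tissue_texture_sd
  }
  if (spec$noise_sd > 0)
    a <- a + array(stats::rnorm(length(a), 0, spec$noise_sd), dim(a))
  a
}

# Draw a small random rigid misalignment from the spec (or NULL if off).
draw_jitter <- function(spec, tmpl) {
  if (spec$jitter_translation <= 0 && spec$jitter_rotation <= 0)
    return(NULL)
  tr <- stats::runif(3, -spec$jitter_translation, spec$jitter_translation) *
    spec$spacing
  ang <- stats::runif(3, -spec$jitter_rotation, spec$jitter_rotation)
  rigid_transform(angles = ang, translation = tr,
                  center = grid_center(tmpl))
}

#' Simulate a normal scan
#'
#' Adds a smooth zero-mean texture field and independent per-voxel noise to
#' the template, then (when the spec asks for it) applies a small random
#' rigid misalignment. Per-voxel intensities inside the brain are Gaussian
#' draws centred on the template value with SD
#' `sqrt(tissue_texture_sd^2 + noise_sd^2)`.
#'
#' @param phantom Result of [make_template()] (or a [volume_grid()]).
#' @param spec The [phantom_spec()] used to build the template.
#' @param seed RNG seed; defaults to `spec$seed`.
#' @return A [volume_grid()]; any applied misalignment is attached as
#'   attribute `"jitter"` (an affine transform, or `NULL`).
#' @export
simulate_normal_scan <- function(phantom, spec, seed = spec$seed) {
  tmpl <- if (inherits(phantom, "volume_grid")) phantom else phantom$template
  with_seed(seed, {
    a <- simulate_normal_core(tmpl, spec)
    v <- volume_grid(a, tmpl$spacing, tmpl$origin)
    jit <- draw_jitter(spec, tmpl)
    if (!is.null(jit))
      v <- resample(v, jit, v, interpolation = "linear",
                    fill = spec$background_value)
    attr(v, "jitter") <- jit
    v
  })
}

# Place `lesions$count` disjoint ellipsoidal lesions inside the eroded
# brain mask, hitting the target voxel count exactly: each lesion is the
# n_i voxels of smallest ellipsoid norm within an oversized candidate
# ellipsoid that must itself be contained in the eroded mask.
place_lesions <- function(brain, lesions) {
  dm <- dim(brain)
  n_brain <- sum(brain)
  target_total <- max(1L, round(lesions$target_volume_fraction * n_brain))
  eroded <- erode3d(brain, 1)
  if (!any(eroded)) stop("brain mask too thin to host lesions")
  inside <- which(eroded)
  lesmask <- array(FALSE, dm)
  for (i in seq_len(lesions$count)) {
    n_i <- round((target_total - sum(lesmask)) / (lesions$count - i + 1))
    if (n_i < 1) next
    placed <- FALSE
    # progressively shrink the candidate oversize factor: large factors
    # give rounder trimmed lesions, small ones still fit large volume
    # fractions into the brain
    for (oversize in c(1.6, 1.35, 1.15)) {
      for (try in 1:300) {
        ratios <- stats::runif(3, lesions$axis_ratio_range[1],
                               lesions$axis_ratio_range[2])
        ratios <- ratios / prod(ratios)^(1 / 3)
        s0 <- max(1.3, (oversize * n_i * 3 / (4 * pi))^(1 / 3))
        center <- arrayInd(sample(inside, 1L), dm)
        d <- ellipsoid_norm(dm, as.numeric(center), s0 * ratios)
        cand <- which(d <= 1)
        if (length(cand) < n_i) next
        if (!all(brain[cand]) || any(lesmask[cand])) next
        take <- cand[order(d[cand])][seq_len(n_i)]
        lesmask[take] <- TRUE
        placed <- TRUE
        break
      }
      if (placed) break
    }
    if (!placed)
      stop("cannot place requested lesion volume fraction inside brain")
  }
  lesmask
}

#' Simulate a pathological scan with ground-truth lesion mask
#'
#' A normal scan (same texture/noise model) with `lesions$contrast` HU
#' added inside randomly placed ellipsoidal lesions. The realized lesion
#' fraction equals the target up to integer voxel rounding by
#' construction; lesions always lie strictly inside the brain mask.
#'
#' @param phantom Result of [make_template()].
#' @param spec The [phantom_spec()].
#' @param lesions A [lesion_spec()].
#' @param seed RNG seed; defaults to `lesions$seed`, then `spec$seed`.
#' @return List with `scan` ([volume_grid()]), `lesion_mask`
#'   ([binary_mask()], in the same space as the scan) and
#'   `realized_fraction`.
#' @export
simulate_pathological_scan <- function(phantom, spec, lesions,
                                       seed = NULL) {
  stopifnot(inherits(lesions, "lesion_spec"))
  tmpl <- phantom$template
  brain <- phantom$brain_mask$data
  if (is.null(seed)) seed <- if (!is.null(lesions$seed)) lesions$seed else spec$seed
  with_seed(seed, {
    a <- simulate_normal_core(tmpl, spec)
    lesmask <- place_lesions(brain, lesions)
    a[lesmask] <- a[lesmask] + lesions$contrast
    realized <- sum(lesmask) / sum(brain)
    v <- volume_grid(a, tmpl$spacing, tmpl$origin)
    m <- binary_mask(lesmask, tmpl$spacing, tmpl$origin)
    jit <- draw_jitter(spec, tmpl)
    if (!is.null(jit)) {
      v <- resample(v, jit, v, interpolation = "linear",
                    fill = spec$background_value)
      mj <- resample(volume_grid(array(as.numeric(lesmask), dim(lesmask)),
                                 tmpl$spacing, tmpl$origin),
                     jit, v, interpolation = "nearest", fill = 0)
      m <- mask_from_volume(mj)
    }
    attr(v, "jitter") <- jit
    list(scan = v, lesion_mask = m, realized_fraction = realized)
  })
}
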