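# Simplified, pluggable spatial normalization into atlas space.
#
# Direction convention (important): transforms use the pull/resampling
# convention — they map TEMPLATE (fixed/reference) physical coordinates to
# MOVING physical coordinates. resample(v, t, reference) therefore fills
# each reference voxel x with v evaluated at t(x), and register() returns
# the transform you pass straight to resample() to bring the moving image
# onto the template grid.

#' Construct an affine transform
#'
#' Physical-coordinate map `y = linear %*% x + offset` (mm), pull
#' convention (template coordinates in, moving coordinates out).
#'
#' @param linear 3x3 matrix; must be invertible (|det| > 1e-8).
#' @param offset Length-3 translation (mm).
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(linear = diag(3), offset = c(0, 0, 0)) {
  linear <- matrix(as.numeric(linear), 3, 3)
  offset <- as.numeric(offset)
  stopifnot(length(offset) == 3L, all(is.finite(linear)),
            all(is.finite(offset)))
  if (abs(det(linear)) <= 1e-8) stop("singular transform")
  structure(list(linear = linear, offset = offset),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform> (pull convention)\n")
  print(round(as_matrix4(x), 6))
  invisible(x)
}

#' Rigid (+ optional anisotropic scale) transform about a center
#'
#' Euler rotations are applied in Z-Y-X order; `center` is the fixed point
#' of rotation/scaling (mm).
#'
#' @param angles Length-3 rotations about x, y, z (degrees).
#' @param translation Length-3 translation (mm).
#' @param center Rotation/scaling center (mm).
#' @param scales Length-3 axis scale factors.
#' @return An [affine_transform()].
#' @export
rigid_transform <- function(angles = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0), scales = c(1, 1, 1)) {
  r <- angles * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  A <- Rz %*% Ry %*% Rx %*% diag(as.numeric(scales))
  center <- as.numeric(center)
  affine_transform(A, center + translation - A %*% center)
}

#' @rdname affine_transform
#' @param t,a,b Affine transforms.
#' @export
invert_transform <- function(t) {
  Ai <- solve(t$linear)
  affine_transform(Ai, -Ai %*% t$offset)
}

#' @rdname affine_transform
#' @details `compose_transforms(a, b)` is the transform `x -> a(b(x))`.
#' @export
compose_transforms <- function(a, b) {
  affine_transform(a$linear %*% b$linear,
                   a$linear %*% b$offset + a$offset)
}

#' @rdname affine_transform
#' @param x An `affine_transform` (for `as_matrix4`) or 4x4 matrix (for
#'   `from_matrix4`).
#' @export
as_matrix4 <- function(x) {
  rbind(cbind(x$linear, x$offset), c(0, 0, 0, 1))
}

#' @rdname affine_transform
#' @export
from_matrix4 <- function(x) {
  stopifnot(is.matrix(x), all(dim(x) == c(4, 4)))
  affine_transform(x[1:3, 1:3], x[1:3, 4])
}

#' Read/write a transform as a plain-text 4x4 matrix sidecar
#'
#' @param t An [affine_transform()].
#' @param path Text file path.
#' @export
write_transform <- function(t, path) {
  utils::write.table(as_matrix4(t), path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  from_matrix4(as.matrix(utils::read.table(path)))
}

# Apply transform to a 3xN matrix of physical coordinates.
apply_transform <- function(t, pts) {
  t$linear %*% pts + t$offset
}

# Physical coordinate of the grid center of a volume.
grid_center <- function(v) {
  v$origin + (dim(v$data) - 1) / 2 * v$spacing
}

#' Resample a volume through an affine transform
#'
#' Evaluates `v` at `t`(reference voxel centers) with trilinear or
#' nearest-neighbour interpolation; out-of-field voxels get `fill`. Use
#' nearest interpolation for masks so the output stays strictly binary.
#'
#' @param v Source [volume_grid()].
#' @param t An [affine_transform()] (pull convention).
#' @param reference [volume_grid()] (or mask) defining the output grid.
#' @param interpolation `"linear"`, `"nearest"`, or `"bspline2"` — a
#'   quadratic B-spline smoothing kernel whose blur is independent of the
#'   sub-voxel offset (variance 1/4 voxel^2 per axis). It does not
#'   interpolate exactly, so it is used for similarity metrics rather
#'   than image output.
#' @param fill Value for voxels mapping outside `v` (HU).
#' @return A [volume_grid()] on the reference grid.
#' @export
resample <- function(v, t, reference,
                     interpolation = c("linear", "nearest", "bspline2"),
                     fill = -1000) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(v, "volume_grid"), inherits(t, "affine_transform"))
  dm <- dim(reference$data)
  n <- prod(dm)
  xs <- reference$origin[1] + (seq_len(dm[1]) - 1) * reference$spacing[1]
  ys <- reference$origin[2] + (seq_len(dm[2]) - 1) * reference$spacing[2]
  zs <- reference$origin[3] + (seq_len(dm[3]) - 1) * reference$spacing[3]
  pts <- rbind(rep(xs, times = dm[2] * dm[3]),
               rep(rep(ys, each = dm[1]), times = dm[3]),
               rep(zs, each = dm[1] * dm[2]))
  q <- apply_transform(t, pts)
  # continuous 1-based voxel index in v; clamped far outside the grid so
  # extreme transforms degrade to fill values instead of overflowing
  clamp <- function(u) pmin(pmax(u, -1e6), 1e6)
  u1 <- clamp((q[1, ] - v$origin[1]) / v$spacing[1] + 1)
  u2 <- clamp((q[2, ] - v$origin[2]) / v$spacing[2] + 1)
  u3 <- clamp((q[3, ] - v$origin[3]) / v$spacing[3] + 1)
  dv <- dim(v$data)
  gather <- function(i1, i2, i3) {
    ok <- i1 >= 1L & i1 <= dv[1] & i2 >= 1L & i2 <= dv[2] &
      i3 >= 1L & i3 <= dv[3]
    out <- rep(fill, n)
    lin <- (i3[ok] - 1L) * (dv[1] * dv[2]) + (i2[ok] - 1L) * dv[1] + i1[ok]
    out[ok] <- v$data[lin]
    out
  }
  if (interpolation == "nearest") {
    res <- gather(as.integer(round(u1)), as.integer(round(u2)),
                  as.integer(round(u3)))
  } else if (interpolation == "bspline2") {
    c1 <- round(u1); c2 <- round(u2); c3 <- round(u3)
    t1 <- u1 - c1; t2 <- u2 - c2; t3 <- u3 - c3
    c1 <- as.integer(c1); c2 <- as.integer(c2); c3 <- as.integer(c3)
    w <- function(tt) list((0.5 - tt)^2 / 2, 0.75 - tt^2,
                           (0.5 + tt)^2 / 2)
    w1 <- w(t1); w2 <- w(t2); w3 <- w(t3)
    res <- 0
    for (a in -1:1) for (b in -1:1) for (cc in -1:1)
      res <- res + w1[[a + 2L]] * w2[[b + 2L]] * w3[[cc + 2L]] *
        gather(c1 + a, c2 + b, c3 + cc)
  } else {
    f1 <- floor(u1); f2 <- floor(u2); f3 <- floor(u3)
    w1 <- u1 - f1; w2 <- u2 - f2; w3 <- u3 - f3
    f1 <- as.integer(f1); f2 <- as.integer(f2); f3 <- as.integer(f3)
    res <-
      (1 - w1) * (1 - w2) * (1 - w3) * gather(f1,      f2,      f3) +
      w1       * (1 - w2) * (1 - w3) * gather(f1 + 1L, f2,      f3) +
      (1 - w1) * w2       * (1 - w3) * gather(f1,      f2 + 1L, f3) +
      w1       * w2       * (1 - w3) * gather(f1 + 1L, f2 + 1L, f3) +
      (1 - w1) * (1 - w2) * w3       * gather(f1,      f2,      f3 + 1L) +
      w1       * (1 - w2) * w3       * gather(f1 + 1L, f2,      f3 + 1L) +
      (1 - w1) * w2       * w3       * gather(f1,      f2 + 1L, f3 + 1L) +
      w1       * w2       * w3       * gather(f1 + 1L, f2 + 1L, f3 + 1L)
  }
  volume_grid(array(res, dm), reference$spacing, reference$origin)
}

# Block-mean downsample by an integer factor (multiresolution pyramid).
downsample_volume <- function(v, factor = 2L) {
  dm <- dim(v$data)
  dk <- dm %/% factor
  a <- v$data[seq_len(dk[1] * factor), seq_len(dk[2] * factor),
              seq_len(dk[3] * factor), drop = FALSE]
  dim(a) <- c(factor, dk[1], factor, dk[2], factor, dk[3])
  out <- apply(a, c(2, 4, 6), mean)
  volume_grid(out, v$spacing * factor,
              v$origin + (factor - 1) / 2 * v$spacing)
}

similarity_objective <- function(a, b, metric) {
  if (metric == "mse") mean((a - b)^2)
  else {
    s <- stats::sd(a) * stats::sd(b)
    if (s == 0) 0 else -stats::cor(a, b)
  }
}

# params -> transform for the built-in parameterizations; log-scales are
# clamped to keep line searches from proposing degenerate transforms
params_to_transform <- function(p, mode, center) {
  if (mode == "translation")
    affine_transform(diag(3), p)
  else
    rigid_transform(angles = p[4:6], translation = p[1:3],
                    center = center,
                    scales = exp(pmin(pmax(p[7:9], -0.7), 0.7)))
}

#' Register a moving volume to a template
#'
#' A simplified, pluggable spatial normalization: intensity-based affine
#' alignment by 2-level multiresolution Nelder-Mead on a similarity
#' objective (mean squared error, or negative normalized cross-
#' correlation). Modes: `identity` (no-op), `translation` (3 parameters)
#' and `affine` (translation + rotation + anisotropic scale, 9
#' parameters). The returned transform maps template coordinates to moving
#' coordinates (pull convention) and is already applied to produce
#' `$resampled`. The final objective never exceeds the objective of the
#' initialization: if the optimizer fails to improve, the initial
#' transform is kept.
#'
#' An external engine can replace the built-in optimizer: pass
#' `engine = function(moving, template) -> affine_transform`.
#'
#' @param moving,template [volume_grid()]s.
#' @param mode `"identity"`, `"translation"` or `"affine"`.
#' @param metric `"mse"` or `"ncc"`.
#' @param levels Number of resolution levels (coarse-to-fine).
#' @param max_iter Per-level Nelder-Mead iteration caps (coarse first).
#' @param smooth_sigma Gaussian pre-smoothing (voxels) of both images
#'   before the metric is evaluated. Smoothing removes the interpolation
#'   bias that sharp skull/air edges induce in the similarity surface;
#'   the reported objectives are still computed on the unsmoothed images.
#' @param fill Background fill used during resampling (HU).
#' @param engine Optional plug-in registration function.
#' @return List with `transform`, `resampled`, `objective`,
#'   `initial_objective` and `mode`.
#' @export
register <- function(moving, template,
                     mode = c("affine", "translation", "identity"),
                     metric = c("mse", "ncc"), levels = 2L,
                     max_iter = c(400L, 150L), smooth_sigma = 1,
                     fill = -1000, engine = NULL) {
  mode <- match.arg(mode)
  metric <- match.arg(metric)
  obj_for <- function(t) {
    r <- resample(moving, t, template, fill = fill)
    similarity_objective(r$data, template$data, metric)
  }
  if (!is.null(engine)) {
    t <- engine(moving, template)
    return(list(transform = t, resampled = resample(moving, t, template,
                                                    fill = fill),
                objective = obj_for(t),
                initial_objective = obj_for(affine_transform()),
                mode = "engine"))
  }
  id <- affine_transform()
  init_obj <- obj_for(id)
  if (mode == "identity") {
    return(list(transform = id,
                resampled = resample(moving, id, template, fill = fill),
                objective = init_obj, initial_objective = init_obj,
                mode = mode))
  }
  center <- grid_center(template)
  np <- if (mode == "translation") 3L else 9L
  p <- rep(0, np)
  parscale <- if (mode == "translation") rep(1, 3)
              else c(rep(1, 3), rep(1, 3), rep(0.02, 3))
  blur <- function(v, s) {
    if (s <= 0) return(v)
    volume_grid(gaussian_smooth3d(v$data, s), v$spacing, v$origin)
  }
  # During optimization the moving image is sampled with a quadratic
  # B-spline kernel, whose blur (1/4 voxel^2 per axis) does not depend on
  # the sub-voxel offset — unlike trilinear interpolation, whose
  # offset-dependent blur biases the similarity optimum towards
  # blur-matching poses. The template gets the exactly matching discrete
  # [1/8, 3/4, 1/8] convolution, so both sides carry identical blur at
  # every candidate pose.
  bspline_conv <- function(v) {
    a <- v$data
    for (ax in 1:3) {
      e <- c(0L, 0L, 0L); e[ax] <- 1L
      a <- 0.75 * a +
        0.125 * (shift3d(a, e, fill = fill) + shift3d(a, -e, fill = fill))
    }
    volume_grid(a, v$spacing, v$origin)
  }
  m1 <- blur(moving, smooth_sigma)
  t1 <- blur(template, smooth_sigma)
  pyramid <- list(list(m = m1, t = bspline_conv(t1)))
  if (levels >= 2L &&
      all(dim(template$data) >= 2L * 8L) && all(dim(moving$data) >= 2L * 8L))
    pyramid <- c(list(list(m = downsample_volume(m1),
                           t = bspline_conv(downsample_volume(t1)))),
                 pyramid)
  for (li in seq_along(pyramid)) {
    lev <- pyramid[[li]]
    fn <- function(pp) {
      t <- params_to_transform(pp, mode, center)
      r <- resample(lev$m, t, lev$t, interpolation = "bspline2",
                    fill = fill)
      similarity_objective(r$data, lev$t$data, metric)
    }
    it <- max_iter[min(li, length(max_iter))]
    if (li == 1L && mode == "affine") {
      # translation-first initialization stabilizes the 9-D search
      ft <- function(tt) fn(c(tt, p[4:9]))
      p[1:3] <- stats::optim(p[1:3], ft, method = "Nelder-Mead",
                             control = list(maxit = it,
                                            parscale = rep(1, 3)))$par
    }
    # quasi-Newton with numeric gradients; one restart recovers from a
    # stale Hessian approximation
    val <- fn(p)
    for (restart in 1:2) {
      fit <- stats::optim(p, fn, method = "BFGS",
                          control = list(maxit = it, parscale = parscale,
                                         reltol = 1e-12))
      if (fit$value < val) { p <- fit$par; val <- fit$value }
    }
  }
  t <- params_to_transform(p, mode, center)
  final_obj <- obj_for(t)
  if (!is.finite(final_obj) || final_obj > init_obj) {
    t <- id
    final_obj <- init_obj
  }
  list(transform = t,
       resampled = resample(moving, t, template, fill = fill),
       objective = final_obj, initial_objective = init_obj, mode = mode)
}
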