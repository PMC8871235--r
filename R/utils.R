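# Internal numerics shared across modules: display rounding, seeded RNG
# scoping, 3D array shifts, binary morphology, connected components and
# FFT-based Gaussian smoothing. All operate on plain base-R arrays.

#' Round half away from zero
#'
#' Display rounding used for printed percentages (1 decimal, half-up),
#' as opposed to the round-half-even rule of [base::round()].
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# proportion -> printed percentage (1 decimal, half-up)
fmt_pct <- function(p, digits = 1) round_half_up(100 * p, digits)

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Shift a 3D array by integer offset d (length 3), filling vacated voxels.
shift3d <- function(a, d, fill = FALSE) {
  dm <- dim(a)
  out <- array(fill, dm)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    n <- dm[ax]; k <- d[ax]
    if (abs(k) >= n) return(out)
    if (k >= 0) { dst[[ax]] <- (k + 1):n; src[[ax]] <- 1:(n - k) }
    else        { dst[[ax]] <- 1:(n + k); src[[ax]] <- (1 - k):n }
  }
  out[dst[[1L]], dst[[2L]], dst[[3L]]] <-
    a[src[[1L]], src[[2L]], src[[3L]]]
  out
}

# Integer offsets of a Euclidean ball of radius r (structuring element).
ball_offsets <- function(r) {
  s <- seq(-floor(r), floor(r))
  g <- as.matrix(expand.grid(s, s, s))
  g[rowSums(g^2) <= r^2 + 1e-9, , drop = FALSE]
}

erode3d <- function(mask, r = 1) {
  off <- ball_offsets(r)
  out <- mask
  for (i in seq_len(nrow(off))) {
    d <- off[i, ]
    if (all(d == 0)) next
    out <- out & shift3d(mask, d, fill = FALSE)
  }
  out
}

dilate3d <- function(mask, r = 1) {
  off <- ball_offsets(r)
  out <- mask
  for (i in seq_len(nrow(off))) {
    d <- off[i, ]
    if (all(d == 0)) next
    out <- out | shift3d(mask, d, fill = FALSE)
  }
  out
}

open3d  <- function(mask, r = 1) dilate3d(erode3d(mask, r), r)
close3d <- function(mask, r = 1) erode3d(dilate3d(mask, r), r)

# Label 6-connected components by vectorized frontier growth.
connected_components3d <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  lab <- array(0L, dim(mask))
  remaining <- mask
  offs <- rbind(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
                c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))
  cur <- 0L
  while (any(remaining)) {
    cur <- cur + 1L
    frontier <- array(FALSE, dim(mask))
    frontier[which(remaining)[1L]] <- TRUE
    comp <- frontier
    repeat {
      grown <- array(FALSE, dim(mask))
      for (i in 1:6) grown <- grown | shift3d(frontier, offs[i, ])
      frontier <- grown & remaining & !comp
      if (!any(frontier)) break
      comp <- comp | frontier
    }
    lab[comp] <- cur
    remaining <- remaining & !comp
  }
  lab
}

largest_component3d <- function(mask) {
  lab <- connected_components3d(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

# Circular (periodic) Gaussian smoothing of a 3D field via FFT. Used for
# the phantom texture field, where wrap-around keeps the marginal
# distribution spatially homogeneous.
gaussian_smooth3d <- function(a, sigma) {
  if (sigma <= 0) return(a)
  dm <- dim(a)
  k1 <- lapply(1:3, function(ax) {
    n <- dm[ax]
    p <- 0:(n - 1L)
    d <- pmin(p, n - p)
    k <- exp(-d^2 / (2 * sigma^2))
    k / sum(k)
  })
  K <- outer(outer(k1[[1L]], k1[[2L]]), k1[[3L]])
  dim(K) <- dm
  Re(stats::fft(stats::fft(a) * stats::fft(K), inverse = TRUE)) / prod(dm)
}

# Squared ellipsoid norm of every voxel: sum(((index - center)/semiaxes)^2).
# Voxels with value <= 1 lie inside the ellipsoid.
ellipsoid_norm <- function(shape, center, semiaxes) {
  u <- ((seq_len(shape[1L]) - center[1L]) / semiaxes[1L])^2
  v <- ((seq_len(shape[2L]) - center[2L]) / semiaxes[2L])^2
  w <- ((seq_len(shape[3L]) - center[3L]) / semiaxes[3L])^2
  d <- outer(outer(u, v, `+`), w, `+`)
  dim(d) <- shape
  d
}
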