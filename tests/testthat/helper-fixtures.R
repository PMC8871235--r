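# Shared fixtures, built in code and cached for the duration of the run.

.fixtures <- new.env(parent = emptyenv())

# Desk-scale phantom used by most imaging tests.
tiny_spec <- function(...) {
  phantom_spec(shape = c(24, 24, 24), brain_semiaxes = c(8, 9, 7),
               skull_thickness = 1.5, ...)
}

get_test_phantom <- function() {
  if (is.null(.fixtures$ph)) {
    .fixtures$spec <- tiny_spec()
    .fixtures$ph <- make_template(.fixtures$spec)
  }
  list(spec = .fixtures$spec, ph = .fixtures$ph)
}

# Normative atlas fitted on `n_train` tiny normal phantoms (cached).
get_test_atlas <- function(n_train = 60, k = 2.576) {
  key <- sprintf("atlas_%d_%g", n_train, k)
  if (is.null(.fixtures[[key]])) {
    fx <- get_test_phantom()
    scans <- lapply(seq_len(n_train), function(i)
      simulate_normal_scan(fx$ph, fx$spec, seed = 10000 + i))
    .fixtures[[key]] <- fit_atlas(scans, fx$ph$brain_mask, k = k)
  }
  .fixtures[[key]]
}

# Independent enumeration oracle for the signed-rank test: all 2^n sign
# assignments of the midranks, two-sided p as twice the smaller tail.
wilcoxon_enumeration_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  vs <- signs %*% r
  list(statistic = v,
       p.value = min(1, 2 * min(mean(vs <= v), mean(vs >= v))))
}

# Angular and translational deviation of `est` from the inverse of a
# reference transform, measured at the grid center (voxel units for
# translation, degrees): est composed with ref should be the identity.
transform_error <- function(est, ref, center) {
  resid <- compose_transforms(est, ref)
  terr <- sqrt(sum((apply_transform(resid, matrix(center, 3, 1)) -
                      center)^2))
  sv <- svd(resid$linear)
  R <- sv$u %*% t(sv$v)
  aerr <- acos(pmin(1, (sum(diag(R)) - 1) / 2)) * 180 / pi
  c(translation = terr, rotation = aerr)
}
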