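# YAML configuration and stderr logging.

#' Default configuration
#'
#' All tunables in one list: atlas bound width `k` (SD units), the SD floor
#' `sigma_min` (HU), the intensity clip window applied before fitting and
#' scoring (HU), the brain-extraction tissue window (HU), registration
#' settings, and the optional safety margin subtracted from the lower
#' triage threshold.
#'
#' @return Named list of settings.
#' @export
ctriage_config <- function() {
  list(
    atlas = list(
      k = 2.576,                 # 99% two-sided Gaussian coverage
      sigma_min = 1,             # HU floor on per-voxel SD
      clip_range = c(-100, 200), # HU window applied before fitting/scoring
      n_train_reference = 191    # documented reference training-set size
    ),
    brain_mask = list(
      tissue_window = c(0, 100), # HU
      opening_radius = 1,
      closing_radius = 1
    ),
    registration = list(
      mode = "affine",           # identity | translation | affine
      metric = "mse",            # mse | ncc
      levels = 2,
      max_iter = c(400, 150)
    ),
    triage = list(
      margin = 0                 # safety margin subtracted from t_lower
    ),
    io = list(
      nonfinite = "error",       # error | repair
      background = -1000
    ),
    seed = 1
  )
}

#' Read a YAML configuration file
#'
#' Settings present in the file override the defaults of
#' [ctriage_config()]; everything else keeps its default.
#'
#' @param path YAML file path.
#' @return Named list of settings.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  user <- yaml::read_yaml(path)
  modifyList(ctriage_config(), user)
}

#' Write a configuration list to YAML
#'
#' @param config Named list, e.g. from [ctriage_config()].
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# Structured logging to stderr with per-stage timings. Quiet unless
# options(ctriage.verbose = TRUE).
log_stage <- function(stage, expr) {
  verbose <- isTRUE(getOption("ctriage.verbose", FALSE))
  t0 <- proc.time()[["elapsed"]]
  res <- force(expr)
  if (verbose)
    message(sprintf("[ctriage] %-20s %.2fs", stage,
                    proc.time()[["elapsed"]] - t0))
  res
}
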