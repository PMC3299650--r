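config_defaults <- function() {
  list(
    geometry = list(grid_nx = 64L, grid_ny = 64L, pixel_size = 1.0,
                    n_angles = 60L, n_bins = 95L, bin_width = 1.0),
    protocol = list(total_counts = 1e5, random_fraction = 0.6,
                    scatter_fraction = 0.2, n_realizations = 50L, seed = 0L),
    method = list(beta = NULL, alpha = 0.5, epsilon = 1e-4, qv = 1e-3,
                  assumed_error = 0.06, structure = "scaled_projector",
                  lambda_mode = "alpha_shortcut", max_iter = 30L,
                  x0_mode = "fbp"),
    paths = list(out_dir = "."),
    seed = 0L,
    log_level = "info")
}

validate_config <- function(cfg) {
  with(cfg, {
    if (geometry$grid_nx < 1 || geometry$grid_ny < 1)
      stop("config error in key 'geometry$grid_nx/grid_ny': must be positive")
    if (protocol$random_fraction < 0 || protocol$random_fraction > 1)
      stop("config error in key 'protocol$random_fraction': must be in [0, 1]")
    if (protocol$scatter_fraction < 0 || protocol$scatter_fraction > 1)
      stop("config error in key 'protocol$scatter_fraction': must be in [0, 1]")
    if (protocol$total_counts <= 0)
      stop("config error in key 'protocol$total_counts': must be positive")
    if (method$alpha < 0)
      stop("config error in key 'method$alpha': must be nonnegative")
    if (method$epsilon < 0)
      stop("config error in key 'method$epsilon': must be nonnegative")
    if (method$assumed_error < 0)
      stop("config error in key 'method$assumed_error': must be nonnegative")
    if (!method$lambda_mode %in% c("alpha_shortcut", "line_search"))
      stop("config error in key 'method$lambda_mode'")
    if (!method$x0_mode %in% c("fbp", "zero"))
      stop("config error in key 'method$x0_mode'")
  })
  invisible(cfg)
}

#' Load a run configuration
#'
#' Reads a hierarchical YAML configuration with blocks `geometry`,
#' `protocol`, `method`, `paths` plus top-level `seed` and `log_level`,
#' fills defaults for missing keys, rejects unknown keys by name, and
#' validates values (errors name the offending key).  An empty file yields
#' the full default configuration.
#'
#' @param path YAML file path.
#' @return A validated `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defs <- config_defaults()
  for (key in names(user)) {
    if (!key %in% names(defs))
      stop("unknown config key: '", key, "'")
    if (is.list(defs[[key]])) {
      for (sub in names(user[[key]]))
        if (!sub %in% names(defs[[key]]))
          stop("unknown config key: '", key, "$", sub, "'")
    }
  }
  cfg <- utils::modifyList(defs, user, keep.null = TRUE)
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

#' Write a run configuration
#' @param cfg A `run_config` (or plain list with the same shape).
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Build a seeded end-to-end on-disk fixture
#'
#' Generates a complete small dataset for tests and demos: phantom, exact
#' system matrix, a 6\% perturbation, and 3 prompt/delayed realizations,
#' written as a [write_scan_container()] directory.  `"tiny"` is an 8x8
#' grid with 10 angles x 11 bins at 1,000 counts; `"small"` is 32x32 with
#' 30 angles x 47 bins at 20,000 counts.  Deterministic per seed.
#'
#' @param size `"tiny"` or `"small"`.
#' @param seed Integer seed.
#' @param dir Output directory (default: under `tempdir()`).
#' @return The container directory path, invisibly.
#' @export
make_fixture <- function(size = c("tiny", "small"), seed = 0L,
                         dir = NULL) {
  size <- match.arg(size)
  if (is.null(dir))
    dir <- file.path(tempdir(), sprintf("robustpet_fixture_%s_%d", size, seed))
  geom <- if (size == "tiny")
    scan_geometry(8, 8, n_angles = 10, n_bins = 11)
  else scan_geometry(32, 32, n_angles = 30, n_bins = 47)
  counts <- if (size == "tiny") 1e3 else 2e4
  proto <- scan_protocol(total_counts = counts, n_realizations = 3L,
                         seed = seed)
  phantom <- shepp_logan_phantom(geom)
  D <- build_system_matrix(geom)
  pert <- perturb_system_matrix(D, 0.06, seed = seed)
  scans <- lapply(0:2, function(r) simulate_scan(phantom, D, proto, r))
  write_scan_container(dir, phantom, D, pert, proto, scans)
  invisible(dir)
}
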