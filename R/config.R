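#' Run configuration and artifact provenance
#'
#' A nested configuration covering every pipeline stage, with the reference
#' hyperparameters as defaults, YAML (de)serialization with schema validation
#' (unknown keys rejected), and a stable hash embedded in output artifacts so
#' every result can be traced to the configuration that produced it.
#'
#' @name io_cli
NULL

default_run_config <- function() {
  list(
    data = list(rate = 100, n_sensors = 8, n_channels = 9),
    preprocess = list(lowpass_cutoff = 20, lowpass_order = 4,
                      filter_alpha = 0.98, z_thresh = 3.5, max_gap = 4),
    segment = list(rise_thresh = 20, fall_thresh = 30, debounce = 0.05,
                   grid_points = 101, min_duration = 0.4, max_duration = 1.2,
                   min_peak_force_bw = 0.8),
    features = list(n_features = 127),
    model = list(profile = "tiny", dropout = 0.1, mc_passes = 30),
    constraints = list(kappa = 0.1, kappa1 = 0.5, kappa2 = 0.3,
                       beta_sym = 0.15, c0 = 0.05),
    curriculum = list(lambda0 = c(0.1, 0.15, 0.08, 0.12),
                      warmup_epochs = 20, ramp_epochs = 80, gamma = 0.15),
    train = list(profile = "desk", lr = 2e-3, weight_decay = 1e-5,
                 epochs = 30, batch = 16, grad_clip = 1.0,
                 scheduler = "cosine", seed = 1),
    eval = list(val_fraction = 0.25, snr_levels = c(20, 10)))
}

#' Load, validate and hash a run configuration
#'
#' Reads a YAML configuration, validates it against the package schema
#' (unknown sections or keys are rejected by name), fills unspecified keys
#' with the defaults and attaches a provenance hash.
#'
#' @param path YAML file path, or NULL for pure defaults
#' @return object of class \code{run_config}
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (sec in names(user)) {
      if (!sec %in% names(cfg))
        stop("unknown configuration section: '", sec, "'")
      for (key in names(user[[sec]])) {
        if (!key %in% names(cfg[[sec]]))
          stop("unknown configuration key: '", sec, ".", key, "'")
        cfg[[sec]][[key]] <- user[[sec]][[key]]
      }
    }
  }
  attr(cfg, "hash") <- config_hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' Stable hash of a configuration
#'
#' @param cfg a configuration list
#' @return hexadecimal string
#' @export
config_hash <- function(cfg) {
  attributes(cfg) <- NULL
  txt <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  # polynomial rolling hash over the serialized bytes: dependency-free,
  # stable across runs and platforms
  bytes <- utf8ToInt(as.character(txt))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a configuration (with its hash) to YAML
#'
#' @param cfg a \code{run_config}
#' @param path output path
#' @return invisibly, \code{path}
#' @export
save_run_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$provenance <- list(hash = attr(cfg, "hash") %||% config_hash(cfg),
                       package = as.character(utils::packageVersion("pigait")))
  yaml::write_yaml(x, path)
  invisible(path)
}
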