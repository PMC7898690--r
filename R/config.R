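#' Default run configuration
#'
#' The fully resolved defaults used when a config file omits a key:
#' relaxivity 4.2 /mM/s, hematocrit 0.45, tissue-concentration noise
#' 2.0e-3 mM, 250,000 Monte-Carlo runs, the default VIF and two-map
#' scheme, and the default phantom.
#'
#' @return A nested named list (the resolved configuration schema).
#' @export
default_config <- function() {
  list(
    constants = list(r1 = 4.2, hct = 0.45),
    simulation = list(
      tissue = list(ktrans = 5.0e-4, vp = 0.036, ve = 0.05),
      vif = list(t0 = 0, t_peak = 0.93, a_peak = 1.5, m = 0.03,
                 shape = "linear"),
      scheme = list(first = 4.333, last = 30, n_additional = 0),
      noise_sd = 2.0e-3,
      n_runs = 250000,
      seed = 20201208,
      impaired_factor = 20,
      n_additional = 0:5,
      last_times = seq(9, 39, by = 2),
      fast = FALSE
    ),
    phantom = list(
      grid = c(32, 32, 32),
      voxel_size = c(1.2, 1.2, 1.2),
      baseline_t1 = list(WM = 1.2, GM = 2.0, SSS = 2.4),
      scheme = list(first = 4.333, last = 25, n_additional = 0),
      map_noise_sd = 0.012,
      dynamic_noise_sd = 0.02,
      n_dynamic = 90,
      dynamic_spacing = 1.86,
      seed = 42
    ),
    quantify = list(trim = 0.95, wilcoxon_mode = "asymptotic"),
    output = list(dir = ".", verbosity = 1)
  )
}

# recursive merge of user values over defaults, rejecting unknown keys
merge_config <- function(defaults, user, path = character()) {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) {
    stop(sprintf("config key '%s' must be a mapping.",
                 paste(path, collapse = ".")), call. = FALSE)
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop(sprintf("unknown config key '%s'.",
                 paste(c(path, unknown[1]), collapse = ".")), call. = FALSE)
  }
  for (key in names(user)) {
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

validate_config <- function(config) {
  cc <- config$constants
  if (cc$r1 <= 0) stop("config constants.r1 must be positive.", call. = FALSE)
  if (cc$hct < 0 || cc$hct >= 1) {
    stop("config constants.hct must be in [0, 1).", call. = FALSE)
  }
  sim <- config$simulation
  if (sim$noise_sd < 0) {
    stop("config simulation.noise_sd must be non-negative.", call. = FALSE)
  }
  if (sim$n_runs < 1) {
    stop("config simulation.n_runs must be at least 1.", call. = FALSE)
  }
  if (sim$scheme$last <= sim$scheme$first) {
    stop("config simulation.scheme.last must exceed .first.", call. = FALSE)
  }
  ph <- config$phantom
  if (any(unlist(ph$baseline_t1) <= 0)) {
    stop("config phantom.baseline_t1 values must be positive.", call. = FALSE)
  }
  if (ph$map_noise_sd < 0 || ph$dynamic_noise_sd < 0) {
    stop("config phantom noise SDs must be non-negative.", call. = FALSE)
  }
  if (config$quantify$trim <= 0 || config$quantify$trim > 1) {
    stop("config quantify.trim must be in (0, 1].", call. = FALSE)
  }
  config
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration, overlays it on [default_config()],
#' rejects unknown keys (naming the offending key), and validates value
#' ranges. An empty file yields the full defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return The resolved configuration list, class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(user) || (is.list(user) && length(user) == 0)) user <- list()
  resolved <- validate_config(merge_config(default_config(), user))
  structure(resolved, class = c("run_config", "list"))
}

#' Save a resolved configuration
#'
#' @param config A `run_config` (or plain list).
#' @param path Output path; format chosen by extension (`.json` or YAML).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(unclass(config), path)
  }
  invisible(path)
}

# builders bridging config lists to package objects
config_constants <- function(config) {
  relaxation_constants(r1 = config$constants$r1, hct = config$constants$hct)
}

config_vif <- function(config) {
  v <- config$simulation$vif
  vif_model(t0 = v$t0, t_peak = v$t_peak, a_peak = v$a_peak, m = v$m,
            shape = v$shape)
}

config_sim <- function(config) {
  sim <- config$simulation
  n_runs <- if (isTRUE(sim$fast)) min(sim$n_runs, 25000) else sim$n_runs
  sim_config(
    tissue = tissue_params(sim$tissue$ktrans, sim$tissue$vp, sim$tissue$ve),
    vif = config_vif(config),
    scheme = make_scheme(sim$scheme$first, sim$scheme$last,
                         sim$scheme$n_additional),
    noise_sd = sim$noise_sd, n_runs = n_runs, seed = sim$seed
  )
}

config_phantom <- function(config) {
  ph <- config$phantom
  phantom_spec(
    grid = ph$grid, voxel_size = ph$voxel_size,
    baseline_t1 = unlist(ph$baseline_t1),
    vif = config_vif(config),
    scheme = make_scheme(ph$scheme$first, ph$scheme$last,
                         ph$scheme$n_additional),
    consts = config_constants(config),
    map_noise_sd = ph$map_noise_sd, dynamic_noise_sd = ph$dynamic_noise_sd,
    n_dynamic = ph$n_dynamic, dynamic_spacing = ph$dynamic_spacing,
    seed = ph$seed
  )
}
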