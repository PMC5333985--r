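#' @title Simulation configuration
#' @description Strict, versioned configuration in JSON. Every key has an
#'   explicit default; unknown keys are errors, not warnings; out-of-order
#'   bounds are rejected before any step runs.
#' @name config
NULL

CONFIG_SCHEMA_VERSION <- "1"

#' Default simulation configuration
#'
#' @param seed master seed
#' @param n_steps number of decision epochs
#' @return a nested list, the full configuration with all defaults resolved
#' @export
default_config <- function(seed = 1L, n_steps = 50L) {
  list(
    schema_version = CONFIG_SCHEMA_VERSION,
    seed = as.integer(seed),
    n_steps = as.integer(n_steps),
    band = list(delta_comfort = 0.5, theta_neglect = 0.01,
                theta_saturated = 0.99, delta_b1 = 1.5),
    shm = list(p_lethal = 0.3, p_del = 0.5, p_heavy = 0.6, sigma_step = 0.4,
               cap_h = 30L, cap_l = 20L),
    working_range = list(kd_min = 1e-14, kd_max = 1e-3),
    germline = list(kd_min = 1e-10, kd_max = 1e-6),
    agents = list(bcr_per_cell = 1e5, edit_attempts = 3L, switch_gain = 10,
                  population_cap = 2^20, division_mode = "double",
                  b1_division_period = 8L),
    blood = list(volume = 5.0, n_species = 8L, conc_low = 1e-12,
                 conc_high = 1e-3),
    bone_marrow = list(volume = 1e-9, display_efficiency = 0.1),
    follicle = list(volume = 1e-9, display_efficiency = 0.1),
    gc = list(f_present = 0.5, alpha = 4, div_cap = 6L, pool_decay = 0.1,
              residual_frac = 0.01, max_cycles = 15L, max_clones = 120L,
              volume = 1e-7, dose_conc = 1e-6, founder_n = 20L,
              matured_floor = 2.0e-12, matured_ceiling = 1.0e-7,
              n_doses = 3L, capture_mode = "proportional",
              second_signal = TRUE),
    clones = list(n_founders = 5L, start_niche = "BONE_MARROW",
                  second_signal = FALSE),
    out_dir = "."
  )
}

.assert_known_keys <- function(cfg, ref, path = "") {
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra) > 0) {
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", extra)), collapse = ", "),
         call. = FALSE)
  }
  for (k in names(cfg)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]]))) {
      if (!is.list(cfg[[k]])) {
        stop("config key ", path, ".", k, " must be a table", call. = FALSE)
      }
      .assert_known_keys(cfg[[k]], ref[[k]], paste0(path, ".", k))
    }
  }
  invisible(TRUE)
}

.merge_config <- function(cfg, ref) {
  for (k in names(ref)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]]))) {
      cfg[[k]] <- .merge_config(if (is.null(cfg[[k]])) list() else cfg[[k]],
                                ref[[k]])
    } else if (is.null(cfg[[k]])) {
      cfg[[k]] <- ref[[k]]
    }
  }
  cfg
}

#' Validate a configuration
#'
#' Checks schema version, key completeness (no implicit values at run time),
#' ordering of bounds and parameter ranges. Errors (never silently fixes) on
#' violation.
#'
#' @param cfg a configuration list
#' @return `cfg`, invisibly, on success
#' @export
validate_config <- function(cfg) {
  ref <- default_config()
  .assert_known_keys(cfg, ref)
  missing <- setdiff(names(ref), names(cfg))
  if (length(missing)) {
    stop("config missing key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!identical(as.character(cfg$schema_version), CONFIG_SCHEMA_VERSION)) {
    stop("unsupported config schema_version: ", cfg$schema_version,
         call. = FALSE)
  }
  with(cfg, {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    if (n_steps < 0) stop("n_steps must be >= 0", call. = FALSE)
  })
  if (cfg$working_range$kd_min >= cfg$working_range$kd_max) {
    stop("working_range bounds out of order", call. = FALSE)
  }
  if (cfg$germline$kd_min >= cfg$germline$kd_max) {
    stop("germline bounds out of order", call. = FALSE)
  }
  if (cfg$blood$conc_low >= cfg$blood$conc_high) {
    stop("blood concentration bounds out of order", call. = FALSE)
  }
  # these constructors carry the detailed range checks
  do.call(engagement_band, cfg$band)
  do.call(shm_params, cfg$shm)
  stopifnot(cfg$blood$volume > 0, cfg$bone_marrow$volume > 0,
            cfg$follicle$volume > 0,
            cfg$bone_marrow$display_efficiency > 0,
            cfg$agents$population_cap >= 1, cfg$agents$bcr_per_cell > 0)
  gc_fields <- cfg$gc[setdiff(names(cfg$gc), "n_doses")]
  do.call(gc_params, gc_fields)
  if (cfg$gc$n_doses < 1) stop("gc.n_doses must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' Read / write a configuration file (strict JSON)
#'
#' Unspecified keys take their documented defaults; unknown keys are errors.
#'
#' @param path file path
#' @return validated configuration list
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  .assert_known_keys(cfg, default_config())
  cfg <- .merge_config(cfg, default_config())
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @param cfg configuration list
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.band_from_config <- function(cfg) do.call(engagement_band, cfg$band)
.shm_from_config <- function(cfg) do.call(shm_params, cfg$shm)
.gc_params_from_config <- function(cfg) {
  fields <- cfg$gc[setdiff(names(cfg$gc), "n_doses")]
  fields$germline_bounds <- c(cfg$germline$kd_min, cfg$germline$kd_max)
  do.call(gc_params, fields)
}
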