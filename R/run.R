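# End-to-end runs: a versioned YAML run configuration plus the three
# entry points (simulate, process, mc) that the command-line script in
# inst/exec/wmnirs wraps. Every output carries the config hash and seeds
# so a run is reproducible from its files alone.

#' Default run configuration
#'
#' The full configuration consumed by [run_simulate()], [run_process()]
#' and [run_mc()]. Unknown keys in a user configuration are errors
#' (silent typos corrupt studies), enforced by [read_run_config()].
#'
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    version = 1L,
    simulate = list(
      seed = 1L,
      hair = TRUE,
      hair_params = list(
        c_hair_mean = 0.03, c_hair_sd = 0.012,
        coupling_mean = 0.5, coupling_sd = 0.25,
        correlation_length = 20),
      scene = list(beta0 = 5.5, beta1 = 7.0, G0 = 2.0),
      protocol = list(
        n_rows = 10L, n_cols = 15L, spacing = 10, separation = 20,
        dark_level = 5, dark_sd = 0.2, noise_sd = 0.003)),
    process = list(
      wavelengths = c(760, 800),
      order = 12L,
      window = c(700, 840),
      unmix = list(scatter = FALSE, beta = NULL,
                   p_grid = list(from = 0.2, to = 3.0, by = 0.05))),
    mc = list(
      seed = 1L,
      n_photons = 1e6,
      n_boot = 50L,
      lambdas = list(from = 650, to = 830, by = 10),
      F_list = default_F_list(),
      scatter = list(mus = 10, g = 0.95, power = 0, lambda_ref = 800),
      geometry = list(slab_dim = c(100, 100, 25), sphere_diameter = 10,
                      sphere_depth = 10, separation = 20,
                      detector_radius = 2.5))),
    class = "run_config")
}

#' Read and validate a run configuration
#'
#' Reads a YAML run configuration, checks the schema version, rejects
#' unknown keys at any nesting level, and fills unspecified keys from
#' [default_run_config()].
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  defaults <- default_run_config()
  if (!is.null(user$version) && user$version != defaults$version) {
    abort(sprintf("unsupported config version %s (expected %d)",
                  user$version, defaults$version))
  }
  merged <- merge_config(unclass(defaults), user, path = "")
  structure(merged, class = "run_config")
}

merge_config <- function(defaults, user, path) {
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    abort(sprintf("unknown config key%s: %s",
                  if (length(unknown) > 1) "s" else "",
                  paste0(sub("^\\.", "", paste0(path, ".", unknown)),
                         collapse = ", ")))
  }
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      merge_config(defaults[[k]], user[[k]], paste0(path, ".", k))
    } else {
      user[[k]]
    }
  }
  defaults
}

config_hash <- function(config) rlang::hash(unclass(config))

expand_range <- function(x) {
  if (is.list(x) && all(c("from", "to", "by") %in% names(x))) {
    seq(x$from, x$to, by = x$by)
  } else {
    unlist(x)
  }
}

#' Simulate a scan to disk
#'
#' Builds the phantom scene, hair field and protocol from a run
#' configuration, generates the synthetic scan, and writes it with
#' [write_scan()]. Identical configurations produce byte-identical data
#' files.
#'
#' @param config A `run_config` (default [default_run_config()]).
#' @param out_dir Output directory.
#' @return The scan directory path, invisibly.
#' @export
run_simulate <- function(config = default_run_config(), out_dir) {
  cfg <- config$simulate
  scene <- build_phantom_scene(beta0 = cfg$scene$beta0, beta1 = cfg$scene$beta1,
                             G0 = cfg$scene$G0)
  protocol <- do.call(scan_protocol, cfg$protocol)
  hair <- if (isTRUE(cfg$hair)) {
    do.call(sample_hair_field,
            c(list(protocol = protocol), cfg$hair_params,
              list(seed = cfg$seed + 100L)))
  } else {
    NULL
  }
  scan <- generate_scan(scene, protocol, hair = hair, seed = cfg$seed)
  dir <- file.path(out_dir, "scan")
  write_scan(scan, dir)
  stamp_config(dir, config)
  message(sprintf("wrote %d-position scan to %s",
                  protocol$n_rows * protocol$n_cols, dir))
  invisible(dir)
}

#' Process a scan directory into images and unmixed maps
#'
#' Reads a scan, runs the gradient pipeline, and writes: the broadband
#' attenuation image, attenuation and attenuation-gradient images at the
#' configured wavelengths, the unmixed `r_dye` and `c_m` maps, a
#' per-target contrast table for each gradient image, and a per-position
#' unmixing diagnostics table.
#'
#' @param scan_dir Directory written by [run_simulate()] (or
#'   [write_scan()]).
#' @param out_dir Output directory for images and tables.
#' @param config A `run_config`.
#' @return Character vector of written files, invisibly.
#' @export
run_process <- function(scan_dir, out_dir, config = default_run_config()) {
  scan <- read_scan(scan_dir)
  cfg <- config$process
  if (length(cfg$wavelengths) < 2L) {
    abort("config process.wavelengths needs at least 2 wavelengths for unmixing")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  processed <- process_scan(scan, wavelengths = cfg$wavelengths,
                            order = cfg$order, window = cfg$window)
  files <- character()
  put <- function(img, name) {
    path <- file.path(out_dir, name)
    write_image(img, path)
    files <<- c(files, path)
  }
  put(assemble_image(processed, "broadband"), "attenuation_broadband.tsv")
  for (wl in cfg$wavelengths) {
    put(assemble_image(processed, "attenuation", wl),
        sprintf("attenuation_%g.tsv", wl))
    put(assemble_image(processed, "gradient", wl),
        sprintf("gradient_%g.tsv", wl))
  }
  maps <- if (isTRUE(cfg$unmix$scatter)) {
    unmix_scan(processed, wavelengths = cfg$wavelengths,
               beta = cfg$unmix$beta, scatter = TRUE,
               p_grid = expand_range(cfg$unmix$p_grid))
  } else {
    unmix_scan(processed, wavelengths = cfg$wavelengths,
               beta = cfg$unmix$beta, scatter = FALSE)
  }
  put(unmix_image(maps, "r_dye"), "r_dye.tsv")
  put(unmix_image(maps, "c_m"), "c_m.tsv")

  diag_path <- file.path(out_dir, "unmix_diagnostics.tsv")
  readr::write_tsv(as_tibble(maps), diag_path)
  files <- c(files, diag_path)

  contrasts <- purrr::map(cfg$wavelengths, function(wl) {
    contrast_at_targets(assemble_image(processed, "gradient", wl),
                        scan$scene) %>%
      mutate(metric = sprintf("gradient_%g", wl), .before = 1)
  }) %>% bind_rows()
  ct_path <- file.path(out_dir, "target_contrast.tsv")
  readr::write_tsv(contrasts, ct_path)
  files <- c(files, ct_path)
  stamp_config(out_dir, config)
  message(sprintf("wrote %d files to %s", length(files), out_dir))
  invisible(files)
}

#' Run the Monte Carlo sweep and extremum report
#'
#' Runs [mc_sweep()] at the configured photon count, writes the sweep
#' tables, and reports the extremum location of the attenuation gradient
#' versus target absorption at 760 and 800 nm with bootstrap intervals
#' (flagged `wide` when the interval is uninformative, e.g. at smoke-test
#' photon counts).
#'
#' @param config A `run_config`.
#' @param out_dir Output directory.
#' @return The report list, invisibly.
#' @export
run_mc <- function(config = default_run_config(), out_dir) {
  cfg <- config$mc
  geometry <- do.call(slab_geometry, cfg$geometry)
  scatter <- do.call(scatter_model, cfg$scatter)
  sweep <- mc_sweep(geometry, scatter,
                    lambdas = expand_range(cfg$lambdas),
                    F_list = unlist(cfg$F_list),
                    n_photons = cfg$n_photons, seed = cfg$seed,
                    n_boot = cfg$n_boot)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_sweep(sweep, out_dir)

  deriv_tab <- purrr::map(c(760, 800), function(wl) {
    spectral_derivative(sweep, "A", wl) %>%
      mutate(lambda = wl, .before = 1)
  }) %>% bind_rows()
  readr::write_tsv(deriv_tab, file.path(out_dir, "dA_dlambda.tsv"))

  report <- list(
    config_hash = config_hash(config),
    n_photons = cfg$n_photons, seed = cfg$seed,
    extremum_760 = extremum_interval(sweep, 760),
    extremum_800 = extremum_interval(sweep, 800))
  yaml::write_yaml(report, file.path(out_dir, "extremum_report.yaml"))
  stamp_config(out_dir, config)
  if (isTRUE(report$extremum_760$wide) || isTRUE(report$extremum_800$wide)) {
    message("extremum intervals are wide; increase mc.n_photons")
  }
  invisible(report)
}

stamp_config <- function(dir, config) {
  cfg <- unclass(config)
  cfg$hash <- config_hash(config)
  yaml::write_yaml(cfg, file.path(dir, "run_config.yaml"))
}
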