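# Text serialization: every artifact is a delimited table plus a YAML
# header carrying provenance (models, protocol, seeds, config hash), so a
# run can be reproduced from its files alone.

#' Write and read a synthetic scan
#'
#' A scan directory contains `scan.tsv` (`position_row`, `position_col`,
#' `wavelength_nm`, `intensity`), `source.tsv` and `dark.tsv` (2-column
#' spectra), optionally `hair.tsv`, and `header.yaml` with the scene,
#' protocol and seeds. `read_scan()` restores a fully functional
#' `nirs_scan`.
#'
#' @param scan A [generate_scan()] result.
#' @param dir Directory to write into (created if needed).
#' @return `write_scan()` the directory, invisibly; `read_scan()` a
#'   `nirs_scan`.
#' @export
write_scan <- function(scan, dir) {
  stopifnot(inherits(scan, "nirs_scan"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(
    tibble(position_row = scan$data$row, position_col = scan$data$col,
           wavelength_nm = scan$data$wavelength,
           intensity = scan$data$intensity),
    file.path(dir, "scan.tsv"))
  write_spectrum(scan$source, file.path(dir, "source.tsv"))
  write_spectrum(scan$dark, file.path(dir, "dark.tsv"))
  if (!is.null(scan$hair)) {
    readr::write_tsv(as_tibble(scan$hair)[, c("row", "col", "c_hair", "k")],
                     file.path(dir, "hair.tsv"))
  }
  header <- list(
    format = "wmnirs-scan", version = 1L,
    seed = scan$seed,
    scene = scene_to_list(scan$scene),
    melanin = unclass(scan$melanin),
    protocol = unclass(scan$protocol),
    hair_params = if (is.null(scan$hair)) NULL else attr(scan$hair, "params"))
  header$hash <- rlang::hash(header)
  yaml::write_yaml(header, file.path(dir, "header.yaml"), precision = 15)
  invisible(dir)
}

#' @rdname write_scan
#' @export
read_scan <- function(dir) {
  hpath <- file.path(dir, "header.yaml")
  if (!file.exists(hpath)) abort(sprintf("missing header file: %s", hpath))
  header <- yaml::read_yaml(hpath)
  if (!identical(header$format, "wmnirs-scan")) {
    abort(sprintf("%s is not a scan header", hpath))
  }
  raw <- readr::read_tsv(file.path(dir, "scan.tsv"),
                         show_col_types = FALSE, progress = FALSE)
  need <- c("position_row", "position_col", "wavelength_nm", "intensity")
  if (!all(need %in% names(raw))) {
    abort(sprintf("malformed scan file %s: expected columns %s",
                  file.path(dir, "scan.tsv"), paste(need, collapse = ", ")))
  }
  protocol <- do.call(scan_protocol, header$protocol[
    c("n_rows", "n_cols", "spacing", "separation", "wavelengths",
      "dark_level", "dark_sd", "noise_sd")])
  scene <- scene_from_list(header$scene)
  melanin <- melanin_model(header$melanin$scale, header$melanin$decay,
                           header$melanin$reference)
  hair <- NULL
  if (file.exists(file.path(dir, "hair.tsv"))) {
    hf <- readr::read_tsv(file.path(dir, "hair.tsv"),
                          show_col_types = FALSE, progress = FALSE)
    hair <- left_join(grid_positions(protocol), hf, by = c("row", "col"))
    class(hair) <- c("hair_field", class(hair))
    attr(hair, "params") <- header$hair_params
  }
  data <- tibble(row = raw$position_row, col = raw$position_col,
                 wavelength = raw$wavelength_nm, intensity = raw$intensity) %>%
    mutate(x = (.data$col - 1) * protocol$spacing,
           y = (.data$row - 1) * protocol$spacing) %>%
    select("row", "col", "x", "y", "wavelength", "intensity")
  structure(
    list(data = data,
         source = read_spectrum(file.path(dir, "source.tsv")),
         dark = read_spectrum(file.path(dir, "dark.tsv")),
         scene = scene, protocol = protocol, hair = hair,
         melanin = melanin, seed = header$seed),
    class = "nirs_scan")
}

write_spectrum <- function(spectrum, path) {
  readr::write_tsv(tibble(wavelength_nm = spectrum$wavelength,
                          value = spectrum$intensity), path)
}

read_spectrum <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("wavelength_nm", "value") %in% names(df))) {
    abort(sprintf("malformed spectrum file %s", path))
  }
  tibble(wavelength = df$wavelength_nm, intensity = df$value)
}

scene_to_list <- function(scene) {
  list(block_dim = unname(scene$block_dim),
       scan_origin = unname(scene$scan_origin),
       dye = unclass(scene$dye)[c("baseline", "amplitude", "center", "width")],
       mus_p = scene$mus_p, G0 = scene$G0,
       beta0 = scene$beta0, beta1 = scene$beta1,
       mean_dpf = scene$mean_dpf,
       f_ref = scene$f_ref, f_sigma = scene$f_sigma,
       f_depth_scale = scene$f_depth_scale,
       Lt_ref = scene$Lt_ref, Lt_depth_scale = scene$Lt_depth_scale,
       targets = lapply(seq_len(nrow(scene$targets)),
                        function(i) as.list(scene$targets[i, ])))
}

scene_from_list <- function(x) {
  dye <- dye_model(x$dye$baseline, x$dye$amplitude, x$dye$center, x$dye$width)
  scene <- build_phantom_scene(dye = dye, beta0 = x$beta0, beta1 = x$beta1,
                             G0 = x$G0, mean_dpf = x$mean_dpf)
  scene$mus_p <- x$mus_p
  scene$f_ref <- x$f_ref; scene$f_sigma <- x$f_sigma
  scene$f_depth_scale <- x$f_depth_scale
  scene$Lt_ref <- x$Lt_ref; scene$Lt_depth_scale <- x$Lt_depth_scale
  scene$targets <- bind_rows(lapply(x$targets, as_tibble))
  scene
}

#' Write and read a topographic image
#'
#' Images are stored as a value matrix in tab-delimited text plus a YAML
#' sidecar (`<path>.yaml`) holding the metric, wavelength, grid spacing
#' and provenance; the round trip is lossless.
#'
#' @param image An `optical_image`.
#' @param path Path of the matrix file (e.g. `gradient_760.tsv`).
#' @return `write_image()` the path, invisibly; `read_image()` the image.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "optical_image"))
  wide <- image %>%
    arrange(.data$row, .data$col) %>%
    tidyr::pivot_wider(id_cols = "row", names_from = "col",
                       values_from = "value") %>%
    select(-"row")
  readr::write_tsv(wide, path, col_names = FALSE)
  meta <- list(format = "wmnirs-image", version = 1L,
               metric = attr(image, "metric"),
               wavelength = attr(image, "wavelength"),
               spacing = attr(image, "spacing"),
               n_rows = max(image$row), n_cols = max(image$col))
  meta$hash <- rlang::hash(meta)
  yaml::write_yaml(meta, paste0(path, ".yaml"), precision = 15)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  meta_path <- paste0(path, ".yaml")
  if (!file.exists(meta_path)) abort(sprintf("missing image sidecar %s", meta_path))
  meta <- yaml::read_yaml(meta_path)
  if (!identical(meta$format, "wmnirs-image")) {
    abort(sprintf("%s is not an image sidecar", meta_path))
  }
  m <- as.matrix(readr::read_tsv(path, col_names = FALSE,
                                 show_col_types = FALSE, progress = FALSE))
  df <- tidyr::expand_grid(row = seq_len(meta$n_rows),
                           col = seq_len(meta$n_cols)) %>%
    mutate(x = (.data$col - 1) * meta$spacing,
           y = (.data$row - 1) * meta$spacing,
           value = as.vector(t(m)))
  new_optical_image(df, metric = meta$metric,
                    wavelength = if (is.null(meta$wavelength) ||
                                     is.na(meta$wavelength)) NULL
                                 else meta$wavelength,
                    spacing = meta$spacing)
}

#' Serialize absorber models to a structured text config
#'
#' Writes (reads) the dye and melanin model parameters as YAML with keys
#' `baseline`, `amplitude`, `center`, `width` (dye) and `scale`, `decay`,
#' `reference` (melanin).
#'
#' @param dye A [dye_model()].
#' @param melanin A [melanin_model()].
#' @param path File path.
#' @return `write_absorbers()` the path invisibly; `read_absorbers()` a
#'   list with elements `dye` and `melanin`.
#' @export
write_absorbers <- function(dye, melanin, path) {
  yaml::write_yaml(list(
    format = "wmnirs-absorbers", version = 1L,
    dye = unclass(dye)[c("baseline", "amplitude", "center", "width")],
    melanin = unclass(melanin)[c("scale", "decay", "reference")]), path,
    precision = 15)
  invisible(path)
}

#' @rdname write_absorbers
#' @export
read_absorbers <- function(path) {
  x <- yaml::read_yaml(path)
  if (!identical(x$format, "wmnirs-absorbers")) {
    abort(sprintf("%s is not an absorber config", path))
  }
  list(dye = dye_model(x$dye$baseline, x$dye$amplitude,
                       x$dye$center, x$dye$width),
       melanin = melanin_model(x$melanin$scale, x$melanin$decay,
                               x$melanin$reference))
}

#' Export an evaluated spectrum as 2-column delimited text
#'
#' @param data Data frame with a wavelength column and one value column.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_spectrum_tsv <- function(data, path) {
  data <- as_tibble(data)
  stopifnot(ncol(data) == 2L, "wavelength" %in% names(data))
  out <- tibble(wavelength_nm = data$wavelength,
                value = data[[setdiff(names(data), "wavelength")]])
  readr::write_tsv(out, path)
  invisible(path)
}

#' Export a Monte Carlo sweep as delimited tables
#'
#' Writes `sweep.tsv` (`lambda_nm`, `F`, `A`, `beta`, `G`, `se_A`,
#' `se_beta`) and a YAML header with the run configuration (photon
#' count, seed, geometry, scattering).
#'
#' @param sweep An [mc_sweep()] result.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_sweep <- function(sweep, dir) {
  stopifnot(inherits(sweep, "mc_sweep"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- as_tibble(sweep)
  names(tab)[names(tab) == "lambda"] <- "lambda_nm"
  readr::write_tsv(tab, file.path(dir, "sweep.tsv"))
  g <- attr(sweep, "geometry"); s <- attr(sweep, "scatter")
  header <- list(format = "wmnirs-sweep", version = 1L,
                 n_photons = attr(sweep, "n_photons"),
                 seed = attr(sweep, "seed"),
                 n_boot = attr(sweep, "n_boot"),
                 shared_paths = attr(sweep, "shared_paths"),
                 geometry = list(slab_dim = g$slab_dim,
                                 sphere_depth = g$sphere_center[3],
                                 sphere_radius = g$sphere_radius,
                                 separation = g$separation,
                                 detector_radius = g$detector_radius),
                 scatter = unclass(s))
  header$hash <- rlang::hash(header)
  yaml::write_yaml(header, file.path(dir, "header.yaml"), precision = 15)
  invisible(dir)
}
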