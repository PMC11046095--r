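#' Build the reference tissue-equivalent phantom scene
#'
#' Constructs the standard solid-phantom scene used throughout the
#' package: a 130 x 190 x 40 mm block of tissue-like resin (transport
#' scatter 1.0 mm^-1 at 800 nm, background absorption from the calibrated
#' dye model) with two rows of four embedded cylindrical targets
#' (length 10 mm, diameter 10 mm, axis parallel to the surface) whose
#' absorption is 5, 10, 20 and 50 times the background, centred at depths
#' of 15 mm (shallow row) and 25 mm (deep row).
#'
#' Coordinates are those of the 150 x 100 mm imaged area: `x` runs along
#' the 15-column scan direction (0-140 mm), `y` along the 10-row
#' direction (0-90 mm). Target lateral positions are spaced uniformly
#' within that area (a convention; only the grid-relative layout matters).
#'
#' The scene also carries the parameters of the two-path forward model
#' used by [generate_scan()]: a background differential pathlength factor
#' `beta0`, a longer target-interacting pathlength factor `beta1`, a
#' Gaussian lateral sensitivity kernel, and a mean in-target pathlength
#' that decays with target depth.
#'
#' @param dye Background absorber, a [dye_model()]; defaults to the
#'   calibrated package model.
#' @param beta0,beta1 Differential pathlength factors of the
#'   non-interacting and target-interacting photon populations
#'   (`beta0 < beta1`).
#' @param G0 Baseline geometric (scatter) attenuation offset, unitless.
#' @param mean_dpf Band-mean DPF assumed when unmixing; `NULL` (default)
#'   computes it from [mean_dpf()] at first use.
#' @return An object of class `phantom_scene`.
#' @export
build_phantom_scene <- function(dye = default_dye_model(),
                                beta0 = 5.5, beta1 = 7.0, G0 = 2.0,
                              mean_dpf = NULL) {
  if (beta0 <= 0 || beta1 <= beta0) abort("need 0 < beta0 < beta1")
  targets <- tibble(
    target = 1:8,
    x = rep(c(20, 60, 100, 140), 2),
    y = rep(c(30, 60), each = 4),
    depth = rep(c(15, 25), each = 4),
    factor = rep(c(5, 10, 20, 50), 2),
    length = 10, diameter = 10)
  scene <- structure(
    list(
      block_dim = c(x = 190, y = 130, z = 40),
      scan_origin = c(x = 25, y = 20), # margin of the imaged area on the block
      dye = dye,
      mus_p = 1.0,
      G0 = G0,
      beta0 = beta0,
      beta1 = beta1,
      mean_dpf = mean_dpf,
      # two-path closure parameters
      f_ref = 0.30, f_sigma = 8, f_depth_scale = 12,
      Lt_ref = 10, Lt_depth_scale = 25,
      targets = targets),
    class = "phantom_scene")
  stopifnot(all(target_inside_block(scene)))
  scene
}

target_inside_block <- function(scene) {
  t <- scene$targets
  r <- t$diameter / 2
  ok_depth <- (t$depth - r) > 0 & (t$depth + r) < scene$block_dim["z"]
  xb <- t$x + scene$scan_origin["x"] # cylinder axis along x
  yb <- t$y + scene$scan_origin["y"]
  ok_xy <- (xb - t$length / 2) > 0 & (xb + t$length / 2) < scene$block_dim["x"] &
    (yb - r) > 0 & (yb + r) < scene$block_dim["y"]
  ok_depth & ok_xy
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("<phantom_scene> %g x %g x %g mm block, %d targets (F = %s) at depths %s mm\n",
              x$block_dim[1], x$block_dim[2], x$block_dim[3],
              nrow(x$targets),
              paste(unique(x$targets$factor), collapse = "/"),
              paste(unique(x$targets$depth), collapse = "/")))
  invisible(x)
}

#' Scan protocol for the topographic grid acquisition
#'
#' Describes the probe scan: a 10-row by 15-column grid at 10 mm spacing
#' (150 positions; positions are the source-detector midpoints), a
#' source-detector separation of 20 mm, a spectrometer grid of ~1 nm
#' spacing over 650-850 nm, and the measurement noise model (additive
#' dark level/noise in counts plus multiplicative intensity noise).
#'
#' Noise defaults are calibrated so repeated acquisitions spread by less
#' than 0.01 in attenuation and 0.0001 nm^-1 in the attenuation gradient.
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param spacing Grid spacing, mm.
#' @param separation Source-detector separation d, mm.
#' @param wavelengths Spectrometer wavelength grid, nm.
#' @param dark_level Mean dark (background) signal, counts.
#' @param dark_sd Standard deviation of additive dark noise, counts.
#' @param noise_sd Standard deviation of multiplicative intensity noise.
#' @return An object of class `scan_protocol`.
#' @export
scan_protocol <- function(n_rows = 10, n_cols = 15, spacing = 10,
                          separation = 20,
                          wavelengths = seq(650, 850, by = 1),
                          dark_level = 5, dark_sd = 0.2,
                          noise_sd = 0.003) {
  if (separation <= 0) abort("separation must be positive")
  spectral_grid(wavelengths, max_spacing = 2)
  structure(
    list(n_rows = n_rows, n_cols = n_cols, spacing = spacing,
         separation = separation, wavelengths = wavelengths,
         dark_level = dark_level, dark_sd = dark_sd, noise_sd = noise_sd),
    class = "scan_protocol")
}

#' Grid positions of a scan protocol
#'
#' @param protocol A [scan_protocol()].
#' @return Tibble with `row`, `col`, `x`, `y` (mm).
#' @export
grid_positions <- function(protocol) {
  tidyr::expand_grid(row = seq_len(protocol$n_rows),
                     col = seq_len(protocol$n_cols)) %>%
    mutate(x = (.data$col - 1) * protocol$spacing,
           y = (.data$row - 1) * protocol$spacing)
}

#' Sample a spatially correlated hair field
#'
#' Emulates a heterogeneous layer of dark hair on the phantom surface.
#' Each scan position receives an effective melanin areal concentration
#' `c_hair` (mg/ml mm) and a wavelength-independent coupling factor
#' `k` in (0, 1]. Both derive from independent Gaussian random fields
#' with a squared-exponential spatial correlation; `c_hair` is floored at
#' zero and `k = exp(-max(0, u))` for a correlated loss field `u`, so the
#' hair contributes both wavelength-dependent melanin absorption and a
#' flat coupling loss. Setting all intensity parameters to zero yields a
#' bare phantom (`c_hair = 0`, `k = 1`).
#'
#' @param protocol A [scan_protocol()].
#' @param c_hair_mean,c_hair_sd Mean and sd of the melanin areal
#'   concentration field, mg/ml mm.
#' @param coupling_mean,coupling_sd Mean and sd of the coupling-loss field
#'   `u` (`k = exp(-u)`), unitless.
#' @param correlation_length Correlation length of both fields, mm.
#' @param seed Integer seed; identical seeds give identical fields.
#' @return Tibble of class `hair_field` with columns `row`, `col`, `x`,
#'   `y`, `c_hair`, `k`.
#' @export
sample_hair_field <- function(protocol,
                              c_hair_mean = 0.03, c_hair_sd = 0.012,
                              coupling_mean = 0.5, coupling_sd = 0.25,
                              correlation_length = 20, seed = 1) {
  if (correlation_length <= 0) abort("correlation_length must be positive")
  pos <- grid_positions(protocol)
  n <- nrow(pos)
  draw <- withr::with_seed(seed, {
    if (c_hair_sd > 0 || coupling_sd > 0) {
      L <- hair_field_chol(pos, correlation_length)
      list(z1 = drop(L %*% rnorm(n)), z2 = drop(L %*% rnorm(n)))
    } else {
      list(z1 = numeric(n), z2 = numeric(n))
    }
  })
  pos$c_hair <- pmax(0, c_hair_mean + c_hair_sd * draw$z1)
  pos$k <- exp(-pmax(0, coupling_mean + coupling_sd * draw$z2))
  if (c_hair_mean == 0 && c_hair_sd == 0) pos$c_hair <- rep(0, n)
  if (coupling_mean == 0 && coupling_sd == 0) pos$k <- rep(1, n)
  class(pos) <- c("hair_field", class(pos))
  attr(pos, "params") <- list(
    c_hair_mean = c_hair_mean, c_hair_sd = c_hair_sd,
    coupling_mean = coupling_mean, coupling_sd = coupling_sd,
    correlation_length = correlation_length, seed = seed)
  pos
}

hair_field_chol <- function(pos, ell) {
  D2 <- outer(pos$x, pos$x, "-")^2 + outer(pos$y, pos$y, "-")^2
  S <- exp(-D2 / (2 * ell^2))
  t(chol(S + diag(1e-8, nrow(S))))
}

#' Variance of the mean of a sampled hair field
#'
#' Closed-form variance of the spatial mean of the correlated `c_hair`
#' field (ignoring the zero floor), used to judge whether a sampled field
#' is consistent with its configured mean.
#'
#' @param protocol A [scan_protocol()].
#' @param c_hair_sd,correlation_length As in [sample_hair_field()].
#' @return Variance of the field mean.
#' @export
hair_field_mean_variance <- function(protocol, c_hair_sd,
                                     correlation_length = 20) {
  pos <- grid_positions(protocol)
  D2 <- outer(pos$x, pos$x, "-")^2 + outer(pos$y, pos$y, "-")^2
  S <- exp(-D2 / (2 * correlation_length^2))
  c_hair_sd^2 * sum(S) / nrow(pos)^2
}

#' Generate a smooth broadband source spectrum
#'
#' A tungsten-halogen-like broadband curve: the log intensity is a fixed
#' low-order polynomial plus small seeded Chebyshev perturbations (orders
#' 3-8), emulating subtle structure in a real lamp spectrum. Because the
#' log spectrum is a polynomial of order at most 8 by construction, a
#' 12th-order processing fit represents it to machine precision.
#'
#' @param wavelengths Spectrometer wavelength grid, nm.
#' @param seed Integer seed.
#' @param log_level Overall log-intensity level (counts scale).
#' @param perturb_sd Standard deviation of the perturbation coefficients.
#' @return Tibble with `wavelength`, `intensity` (all positive).
#' @export
generate_source_spectrum <- function(wavelengths, seed = 1,
                                     log_level = 10, perturb_sd = 0.02) {
  u <- to_unit(wavelengths, range(wavelengths))
  base <- log_level + 0.8 * u - 0.15 * u^2
  pert_coef <- withr::with_seed(seed, rnorm(6, sd = perturb_sd))
  pert <- drop(cheb_design(u, 8)[, 4:9] %*% pert_coef)
  tibble(wavelength = wavelengths, intensity = exp(base + pert))
}

#' Two-path modified Beer-Lambert forward model
#'
#' Predicts the detected spectrum at one probe position. The model is a
#' two-population closure of photon transport: a fraction `1 - f` of
#' detected light never interacts with the (nearest/strongest) embedded
#' target and attenuates along the background path with DPF `beta0`; a
#' fraction `f` interacts with the target, travels a longer path (DPF
#' `beta1`) and picks up the target's excess absorption over a mean
#' in-target pathlength `L_t`:
#' \deqn{I = k I_0 e^{-2 c_{hair} \epsilon_m(\lambda)} e^{-G_0}
#'   [(1-f) e^{-\mu_a \beta_0 d} +
#'    f e^{-\mu_a \beta_1 d - (F-1)\mu_a L_t}].}
#' The interaction fraction `f` follows a Gaussian kernel of the lateral
#' distance between the probe midpoint and the target, scaled down with
#' target depth. Hair enters twice (in and out, hence the factor 2) and
#' also through the wavelength-independent coupling factor `k`.
#'
#' With `f = 0`, no hair and `k = 1` the attenuation is exactly
#' `mu_a * beta0 * d + G0`, the homogeneous modified Beer-Lambert law.
#'
#' @param scene A [build_phantom_scene()] scene.
#' @param position Length-2 numeric `c(x, y)`, mm (probe midpoint).
#' @param source Source spectrum tibble (`wavelength`, `intensity`).
#' @param c_hair,k Hair melanin areal concentration and coupling factor
#'   at this position.
#' @param melanin Melanin extinction model for the hair layer.
#' @param separation Source-detector separation d, mm.
#' @return Tibble with `wavelength`, `intensity`.
#' @export
forward_intensity <- function(scene, position, source,
                              c_hair = 0, k = 1,
                              melanin = melanin_model(),
                              separation = 20) {
  stopifnot(inherits(scene, "phantom_scene"))
  if (k <= 0 || k > 1) abort("coupling factor k must be in (0, 1]")
  if (c_hair < 0) abort("c_hair must be non-negative")
  wl <- source$wavelength
  mu <- dye_absorption(scene$dye, wl)
  d <- separation

  tf <- target_fraction(scene, position)
  f <- tf$f
  if (f < 0 || f > 1) abort("target-interaction fraction outside [0, 1]")

  bg_branch <- exp(-mu * scene$beta0 * d)
  mix <- if (f > 0) {
    Lt <- scene$Lt_ref * exp(-(tf$depth - 15) / scene$Lt_depth_scale)
    (1 - f) * bg_branch +
      f * exp(-mu * scene$beta1 * d - (tf$factor - 1) * mu * Lt)
  } else {
    bg_branch
  }
  intensity <- k * source$intensity *
    exp(-2 * c_hair * melanin_extinction(melanin, wl)) *
    exp(-scene$G0) * mix
  if (any(intensity < 0)) abort("negative intensity in forward model")
  tibble(wavelength = wl, intensity = intensity)
}

# interaction fraction of the dominant (max-f) target at a probe position
target_fraction <- function(scene, position) {
  t <- scene$targets
  dist2 <- (t$x - position[1])^2 + (t$y - position[2])^2
  amp <- scene$f_ref * exp(-(t$depth - 15) / scene$f_depth_scale)
  f_all <- amp * exp(-dist2 / (2 * scene$f_sigma^2))
  i <- which.max(f_all)
  list(f = f_all[i], factor = t$factor[i], depth = t$depth[i], target = i)
}

#' Generate a full synthetic grid scan
#'
#' Runs the two-path forward model at every protocol grid position,
#' applies multiplicative intensity noise and additive dark noise, and
#' assembles the result with its source and dark reference spectra.
#'
#' @param scene A [build_phantom_scene()] scene.
#' @param protocol A [scan_protocol()].
#' @param hair Optional [sample_hair_field()] result; `NULL` for a bare
#'   phantom (`c_hair = 0`, `k = 1` everywhere).
#' @param melanin Melanin model for the hair layer.
#' @param seed Integer seed controlling the source perturbations and all
#'   measurement noise.
#' @return An object of class `nirs_scan`: a list with `data` (tibble
#'   `row`, `col`, `x`, `y`, `wavelength`, `intensity`), `source`, `dark`,
#'   and the provenance (`scene`, `protocol`, `hair`, `melanin`, `seed`).
#' @export
generate_scan <- function(scene, protocol = scan_protocol(), hair = NULL,
                          melanin = melanin_model(), seed = 1) {
  pos <- grid_positions(protocol)
  if (is.null(hair)) {
    pos$c_hair <- 0
    pos$k <- 1
  } else {
    pos <- left_join(pos, as_tibble(hair)[, c("row", "col", "c_hair", "k")],
                     by = c("row", "col"))
    if (anyNA(pos$c_hair)) abort("hair field does not cover the scan grid")
  }
  source <- generate_source_spectrum(protocol$wavelengths, seed = seed)
  nl <- length(protocol$wavelengths)

  data <- withr::with_seed(seed + 1L, {
    purrr::pmap(pos, function(row, col, x, y, c_hair, k) {
      clean <- forward_intensity(scene, c(x, y), source,
                                 c_hair = c_hair, k = k, melanin = melanin,
                                 separation = protocol$separation)
      meas <- clean$intensity * (1 + rnorm(nl, sd = protocol$noise_sd)) +
        protocol$dark_level + rnorm(nl, sd = protocol$dark_sd)
      tibble(row = row, col = col, x = x, y = y,
             wavelength = clean$wavelength,
             intensity = pmax(meas, 0))
    }) %>% bind_rows()
  })

  dark <- tibble(wavelength = protocol$wavelengths,
                 intensity = rep(protocol$dark_level, nl))
  structure(
    list(data = data, source = source, dark = dark,
         scene = scene, protocol = protocol, hair = hair,
         melanin = melanin, seed = seed),
    class = "nirs_scan")
}

#' Apply per-position coupling factors to a scan
#'
#' Multiplies the optical (dark-subtracted) component of every position's
#' measured spectrum by a coupling factor `k`, leaving the dark offset in
#' place — the physical effect of a change in probe-surface coupling.
#' Attenuation images shift by exactly `-ln k` per position; gradient
#' images are unchanged, which is the central coupling-immunity property
#' of spectral-derivative imaging.
#'
#' @param scan A [generate_scan()] result.
#' @param k Either a single factor in (0, 1] or a data frame with
#'   columns `row`, `col`, `k` covering every scan position.
#' @return The scan with rescaled intensities.
#' @export
apply_coupling <- function(scan, k) {
  stopifnot(inherits(scan, "nirs_scan"))
  if (is.data.frame(k)) {
    kk <- left_join(scan$data[, c("row", "col")], as_tibble(k),
                    by = c("row", "col"))$k
    if (anyNA(kk)) abort("k does not cover all scan positions")
  } else {
    kk <- k
  }
  if (any(kk <= 0 | kk > 1)) abort("coupling factors must be in (0, 1]")
  dark <- scan$dark$intensity[match(scan$data$wavelength, scan$dark$wavelength)]
  scan$data$intensity <- kk * (scan$data$intensity - dark) + dark
  scan
}

#' @export
print.nirs_scan <- function(x, ...) {
  cat(sprintf("<nirs_scan> %d positions x %d wavelengths (%g-%g nm), seed %d, hair %s\n",
              x$protocol$n_rows * x$protocol$n_cols,
              length(x$protocol$wavelengths),
              min(x$protocol$wavelengths), max(x$protocol$wavelengths),
              x$seed, if (is.null(x$hair)) "off" else "on"))
  invisible(x)
}
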