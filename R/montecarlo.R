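#' Slab-with-spherical-target Monte Carlo geometry
#'
#' The reduced transport geometry used to explain the nonlinear
#' relationship between attenuation-gradient contrast and target
#' absorption: a 100 x 100 x 25 mm slab with a 10 mm diameter spherical
#' target centred at 10 mm depth immediately below the source-detector
#' midpoint, separation 20 mm. The detector is a disc on the top surface
#' (default radius 2.5 mm, matching a 5 mm probe aperture).
#'
#' @param slab_dim Slab dimensions `c(x, y, z)`, mm.
#' @param sphere_diameter,sphere_depth Target diameter and centre depth, mm.
#' @param separation Source-detector separation d, mm.
#' @param detector_radius Detector disc radius, mm.
#' @return Object of class `slab_geometry`.
#' @export
slab_geometry <- function(slab_dim = c(100, 100, 25),
                          sphere_diameter = 10, sphere_depth = 10,
                          separation = 20, detector_radius = 2.5) {
  r <- sphere_diameter / 2
  if (sphere_depth - r < 0 || sphere_depth + r > slab_dim[3]) {
    abort("sphere must lie fully inside the slab")
  }
  if (separation / 2 > slab_dim[1] / 2) abort("probe outside the slab surface")
  structure(
    list(slab_dim = slab_dim,
         sphere_center = c(0, 0, sphere_depth), sphere_radius = r,
         source = c(-separation / 2, 0), detector = c(separation / 2, 0),
         separation = separation, detector_radius = detector_radius),
    class = "slab_geometry")
}

#' Scattering model for the Monte Carlo slab
#'
#' Constant scattering (`power = 0`) or the power-law variant
#' \eqn{\mu_s(\lambda) = \mu_s^{ref} (\lambda/\lambda_{ref})^{-power}}.
#' Defaults: \eqn{\mu_s = 10} mm^-1, anisotropy g = 0.95, so
#' \eqn{\mu_s' = 0.5} mm^-1; the wavelength-dependent variant uses
#' power = 1.2 at reference 800 nm.
#'
#' @param mus Scattering coefficient at the reference wavelength, mm^-1.
#' @param g Scattering anisotropy (mean deflection cosine), in (-1, 1).
#' @param power Power-law exponent (0 for wavelength-independent scatter).
#' @param lambda_ref Reference wavelength, nm.
#' @return Object of class `scatter_model` with derived `mus_p`.
#' @export
scatter_model <- function(mus = 10, g = 0.95, power = 0, lambda_ref = 800) {
  if (mus <= 0) abort("mus must be positive")
  if (g <= -1 || g >= 1) abort("g must be in (-1, 1)")
  structure(list(mus = mus, g = g, power = power, lambda_ref = lambda_ref,
                 mus_p = mus * (1 - g)),
            class = "scatter_model")
}

#' @rdname scatter_model
#' @param model A `scatter_model`.
#' @param wavelength Wavelengths, nm.
#' @export
mus_at <- function(model, wavelength) {
  model$mus * (wavelength / model$lambda_ref)^(-model$power)
}

#' Simulate absorption-free photon paths through the slab
#'
#' Runs the pencil-beam Henyey-Greenstein random walk and records, for
#' every detected photon, the path length outside (`L_out`) and inside
#' (`L_in`) the spherical target. Absorption is deliberately absent from
#' the walk: it is applied analytically at [replay()] time, which lets a
#' single path ensemble serve every wavelength and target-absorption
#' factor when scattering is wavelength-independent.
#'
#' @param geometry A [slab_geometry()].
#' @param scatter A [scatter_model()].
#' @param n_photons Number of injected photons.
#' @param seed Integer seed (R RNG; identical seeds give identical paths).
#' @param wavelength Wavelength (nm) at which to evaluate `mus` for
#'   power-law scatter; ignored when `power = 0`.
#' @param max_path Total path-length cap per photon, mm (guard only).
#' @return Object of class `photon_paths`: `L_out`, `L_in` (mm, detected
#'   photons), `n_injected`, plus the geometry and scattering used.
#' @export
simulate_paths <- function(geometry, scatter = scatter_model(),
                           n_photons = 1e6, seed = 1,
                           wavelength = scatter$lambda_ref,
                           max_path = 2000) {
  stopifnot(inherits(geometry, "slab_geometry"), n_photons >= 1)
  mus <- mus_at(scatter, wavelength)
  res <- withr::with_seed(seed, simulate_paths_cpp(
    as.integer(n_photons),
    geometry$slab_dim[1], geometry$slab_dim[2], geometry$slab_dim[3],
    geometry$source[1], geometry$detector[1], geometry$detector_radius,
    geometry$sphere_center[1], geometry$sphere_center[2],
    geometry$sphere_center[3], geometry$sphere_radius,
    mus, scatter$g, max_path))
  structure(
    list(L_out = res$L_out, L_in = res$L_in,
         n_injected = res$n_injected, n_detected = length(res$L_out),
         separation = geometry$separation, mus = mus, g = scatter$g,
         geometry = geometry, seed = seed),
    class = "photon_paths")
}

#' @export
print.photon_paths <- function(x, ...) {
  cat(sprintf("<photon_paths> %d detected of %d injected (%.3g%%), mus = %g mm^-1, g = %g\n",
              x$n_detected, x$n_injected, 100 * x$n_detected / x$n_injected,
              x$mus, x$g))
  invisible(x)
}

#' Elementary transport samplers
#'
#' Direct access to the simulator's step-length and Henyey-Greenstein
#' deflection samplers, for distributional checks: step lengths are
#' exponential with mean `1/mus`; deflection cosines have mean `g`.
#'
#' @param n Number of draws.
#' @param mus Scattering coefficient, mm^-1.
#' @param g Anisotropy parameter in (-1, 1).
#' @return Numeric vector of draws.
#' @export
sample_steps <- function(n, mus) {
  if (mus <= 0) abort("mus must be positive")
  sample_step_cpp(as.integer(n), mus)
}

#' @rdname sample_steps
#' @export
sample_hg <- function(n, g) {
  if (g <= -1 || g >= 1) abort("g must be in (-1, 1)")
  sample_hg_cpp(as.integer(n), g)
}

#' Replay recorded paths at given absorption
#'
#' Applies absorption analytically to a recorded path ensemble: each
#' detected photon receives the weight
#' \eqn{w = \exp(-\mu_a L_{out} - F \mu_a L_{in})}, giving the
#' attenuation \eqn{A = -\ln(\sum w / n_{injected})} and the DPF
#' \eqn{\beta = \sum w (L_{out}+L_{in}) / (d \sum w)} (mean detected
#' pathlength over separation). `F = Inf` zeroes the weight of any
#' photon that touched the target (total in-target absorption).
#' On a fixed ensemble A is exactly non-decreasing in F.
#'
#' @param paths A [simulate_paths()] ensemble.
#' @param mu_a Background absorption coefficient, mm^-1 (> 0 unless the
#'   `mu_a = 0` limit is wanted, which gives `A = -ln(detected fraction)`).
#' @param F Target absorption factor (>= 1, or `Inf`).
#' @return List with `A` (unitless) and `beta` (unitless DPF).
#' @export
replay <- function(paths, mu_a, F = 1) {
  stopifnot(inherits(paths, "photon_paths"))
  if (mu_a < 0) abort("mu_a must be non-negative")
  if (F < 1) abort("F must be >= 1 (or Inf)")
  w <- if (is.infinite(F)) {
    exp(-mu_a * paths$L_out) * (paths$L_in == 0)
  } else {
    exp(-mu_a * paths$L_out - F * mu_a * paths$L_in)
  }
  sw <- sum(w)
  if (sw == 0) abort("no surviving photons at this absorption")
  Ltot <- paths$L_out + paths$L_in
  list(A = -log(sw / paths$n_injected),
       beta = sum(w * Ltot) / sw / paths$separation)
}

#' Geometric factor from the modified Beer-Lambert identity
#'
#' With perfect coupling (k = 1) and known background absorption, the
#' modified Beer-Lambert law defines the scatter-dependent geometric
#' factor as \eqn{G = A - \mu_a \beta d}. The background `mu_a` is used
#' with the total pathlength throughout, so for a heterogeneous slab `G`
#' also absorbs the target's excess absorption (which is why G tracks A
#' closely as the target absorption grows).
#'
#' @param A Attenuation (unitless).
#' @param beta DPF (unitless).
#' @param mu_a Background absorption, mm^-1.
#' @param d Source-detector separation, mm.
#' @return G (unitless).
#' @export
compute_G <- function(A, beta, mu_a, d) {
  A - mu_a * beta * d
}

#' Default target-absorption-factor list
#'
#' Fourteen approximately log-spaced finite factors in \[1, 50\] plus the
#' infinite-absorption sentinel.
#'
#' @param infinite Append `Inf`.
#' @return Numeric vector.
#' @export
default_F_list <- function(infinite = TRUE) {
  f <- c(1, 1.5, 2, 3, 4, 5, 7, 10, 14, 20, 28, 35, 42, 50)
  if (infinite) c(f, Inf) else f
}

#' Monte Carlo spectral sweep over wavelength and target absorption
#'
#' Computes A, beta and G on the full (wavelength, F) grid. For
#' wavelength-independent scatter one path ensemble is shared across the
#' entire grid (the pathlength-replay estimator), which makes A exactly
#' monotone in F and A(lambda) smooth; for power-law scatter one
#' ensemble is simulated per wavelength. Bootstrap standard errors
#' (resampling detected photons) are attached per grid point.
#'
#' @param geometry A [slab_geometry()].
#' @param scatter A [scatter_model()].
#' @param dye Background absorber, a [dye_model()].
#' @param lambdas Wavelength grid, nm (default 650-830 nm step 10, 19
#'   values).
#' @param F_list Target absorption factors (default [default_F_list()]).
#' @param n_photons Injected photons per ensemble.
#' @param seed Integer seed.
#' @param n_boot Bootstrap resamples for standard errors.
#' @param share_paths `NULL` (auto: share exactly when scatter is
#'   wavelength-independent) or `FALSE` to force one ensemble per
#'   wavelength, e.g. for seed-matched comparisons against a power-law
#'   run.
#' @return Tibble of class `mc_sweep` with columns `lambda`, `F`, `A`,
#'   `beta`, `G`, `se_A`, `se_beta`; attributes carry the run
#'   configuration and path ensemble sizes.
#' @export
mc_sweep <- function(geometry = slab_geometry(),
                     scatter = scatter_model(),
                     dye = default_dye_model(),
                     lambdas = seq(650, 830, by = 10),
                     F_list = default_F_list(),
                     n_photons = 1e6, seed = 1, n_boot = 50,
                     share_paths = NULL) {
  mu_bg <- dye_absorption(dye, lambdas)
  shared <- if (is.null(share_paths)) scatter$power == 0 else {
    if (isTRUE(share_paths) && scatter$power != 0) {
      abort("paths cannot be shared across wavelengths with power-law scatter")
    }
    isTRUE(share_paths)
  }
  nl <- length(lambdas); nf <- length(F_list)

  A <- beta <- se_A <- se_beta <- matrix(NA_real_, nl, nf)
  A_boot <- array(NA_real_, c(nl, nf, n_boot))

  run_lambda <- function(i, paths, counts) {
    for (j in seq_len(nf)) {
      r <- replay(paths, mu_bg[i], F_list[j])
      A[i, j] <<- r$A
      beta[i, j] <<- r$beta
      b <- replay_bootstrap(paths, counts, mu_bg[i], F_list[j])
      se_A[i, j] <<- b$se_A
      se_beta[i, j] <<- b$se_beta
      A_boot[i, j, ] <<- b$A_b
    }
  }

  if (shared) {
    paths <- simulate_paths(geometry, scatter, n_photons, seed)
    counts <- boot_counts(paths, n_boot, seed)
    for (i in seq_len(nl)) run_lambda(i, paths, counts)
    n_det <- paths$n_detected
  } else {
    n_det <- integer(nl)
    for (i in seq_len(nl)) {
      paths <- simulate_paths(geometry, scatter, n_photons, seed + i,
                              wavelength = lambdas[i])
      counts <- boot_counts(paths, n_boot, seed + i)
      run_lambda(i, paths, counts)
      n_det[i] <- paths$n_detected
    }
  }
  out <- tidyr::expand_grid(lambda = lambdas, F = F_list) %>%
    mutate(A = as.vector(t(A)), beta = as.vector(t(beta)),
           G = compute_G(.data$A, .data$beta,
                         rep(mu_bg, each = nf), geometry$separation),
           se_A = as.vector(t(se_A)), se_beta = as.vector(t(se_beta)))
  structure(out,
            geometry = geometry, scatter = scatter, dye = dye,
            lambdas = lambdas, F_list = F_list,
            n_photons = n_photons, seed = seed, n_boot = n_boot,
            n_detected = n_det, shared_paths = shared, A_boot = A_boot,
            class = c("mc_sweep", class(out)))
}

# multinomial bootstrap resample counts, drawn once per path ensemble and
# reused across the (lambda, F) grid so bootstrap surfaces are smooth in
# lambda and F
boot_counts <- function(paths, n_boot, seed) {
  n <- paths$n_detected
  if (n < 2L) abort("too few detected photons to bootstrap")
  withr::with_seed(seed + 10000L, stats::rmultinom(n_boot, n, rep(1 / n, n)))
}

replay_bootstrap <- function(paths, counts, mu_a, F) {
  w <- if (is.infinite(F)) {
    exp(-mu_a * paths$L_out) * (paths$L_in == 0)
  } else {
    exp(-mu_a * paths$L_out - F * mu_a * paths$L_in)
  }
  Ltot <- paths$L_out + paths$L_in
  sw <- drop(crossprod(w, counts))
  swl <- drop(crossprod(w * Ltot, counts))
  A_b <- ifelse(sw > 0, -log(sw / paths$n_injected), NA_real_)
  beta_b <- ifelse(sw > 0, swl / sw / paths$separation, NA_real_)
  list(se_A = sd(A_b, na.rm = TRUE), se_beta = sd(beta_b, na.rm = TRUE),
       A_b = A_b)
}

#' Bootstrap interval for the extremum location
#'
#' Re-derives the derivative-vs-F curve on each bootstrap replicate of
#' the sweep's attenuation surface and locates the extremum, giving a
#' percentile interval for `F*`. Replicates whose extremum falls on the
#' boundary of the F range are counted and excluded from the interval.
#'
#' @param sweep An [mc_sweep()] result.
#' @param lambda Query wavelength, nm.
#' @param type Extremum type passed to [find_extremum_F()].
#' @param probs Interval probabilities.
#' @param order Polynomial order for the spectral fits.
#' @return List: `F_star` (point estimate), `lower`, `upper`,
#'   `boundary_fraction`, `wide` (TRUE when the interval spans more than
#'   a factor of 4 in F or any replicate hit the boundary).
#' @export
extremum_interval <- function(sweep, lambda, type = "auto",
                              probs = c(0.025, 0.975), order = 8) {
  stopifnot(inherits(sweep, "mc_sweep"))
  A_boot <- attr(sweep, "A_boot")
  lambdas <- attr(sweep, "lambdas")
  F_list <- attr(sweep, "F_list")
  point <- find_extremum_F(spectral_derivative(sweep, "A", lambda, order),
                           type = type)
  boot_F <- rep(NA_real_, dim(A_boot)[3])
  boundary <- logical(dim(A_boot)[3])
  for (b in seq_len(dim(A_boot)[3])) {
    Ab <- A_boot[, , b]
    if (anyNA(Ab)) next
    dv <- purrr::map_dbl(seq_along(F_list), function(j) {
      fit_spectral_derivative(tibble(wavelength = lambdas, value = Ab[, j]),
                              lambda = lambda, order = order)
    })
    ex <- find_extremum_F(tibble(F = F_list, derivative = dv),
                          type = point$type)
    boundary[b] <- ex$boundary
    if (!ex$boundary) boot_F[b] <- ex$F_star
  }
  qs <- quantile(boot_F[!is.na(boot_F)], probs, na.rm = TRUE)
  wide <- any(boundary) || (qs[2] / max(qs[1], .Machine$double.eps) > 4)
  list(F_star = point$F_star, type = point$type,
       lower = unname(qs[1]), upper = unname(qs[2]),
       boundary_fraction = mean(boundary), wide = wide)
}

#' Spectral derivative of a sampled quantity by polynomial fit
#'
#' Fits an 8th-order polynomial (Chebyshev basis on the rescaled
#' wavelength domain) to values sampled on a wavelength grid and returns
#' the analytic derivative at the query wavelength.
#'
#' @param data Data frame with columns `wavelength` and `value` (one
#'   value per grid wavelength).
#' @param lambda Query wavelength, nm (inside the grid range).
#' @param order Polynomial order (default 8).
#' @return Derivative value (per nm).
#' @export
fit_spectral_derivative <- function(data, lambda, order = 8) {
  data <- as_tibble(data)
  stopifnot(all(c("wavelength", "value") %in% names(data)))
  fit <- fit_cheb(data$wavelength, data$value, order = order,
                  window = range(data$wavelength))
  eval_cheb_deriv(fit, lambda)
}

#' Spectral derivatives across a Monte Carlo sweep
#'
#' Applies [fit_spectral_derivative()] to one quantity of an
#' [mc_sweep()] result, per target absorption factor.
#'
#' @param sweep An [mc_sweep()] result.
#' @param quantity `"A"`, `"beta"` or `"G"`.
#' @param lambda Query wavelength, nm.
#' @param order Polynomial order.
#' @return Tibble with `F` and `derivative` (per nm).
#' @export
spectral_derivative <- function(sweep, quantity = c("A", "beta", "G"),
                                lambda, order = 8) {
  quantity <- match.arg(quantity)
  stopifnot(inherits(sweep, "mc_sweep"))
  tab <- as_tibble(sweep)
  Fs <- sort(unique(tab$F))
  deriv <- purrr::map_dbl(Fs, function(Fv) {
    sub <- tab[tab$F == Fv, ]
    fit_spectral_derivative(
      tibble(wavelength = sub$lambda, value = sub[[quantity]]),
      lambda = lambda, order = order)
  })
  tibble(F = Fs, derivative = deriv)
}

#' Locate the extremum of a derivative-vs-F curve
#'
#' Finds the target absorption factor at which a spectral-derivative
#' curve is extremal (maximum at 760 nm, minimum at 800 nm for the
#' standard dye), refining the gridded extremum by quadratic
#' interpolation of the three bracketing points on a log-F axis. An
#' extremum on the boundary of the finite F range is flagged and
#' returned without interpolation.
#'
#' @param deriv Data frame with columns `F` and `derivative` (infinite F
#'   rows are ignored); at least 5 finite F values.
#' @param type `"max"`, `"min"`, or `"auto"` (pick whichever extremum is
#'   interior; if both are, the one deviating more from the F = 1 value).
#' @return List with `F_star`, `type`, `boundary` (logical) and `value`.
#' @export
find_extremum_F <- function(deriv, type = c("auto", "max", "min")) {
  type <- match.arg(type)
  deriv <- as_tibble(deriv) %>%
    filter(is.finite(.data$F)) %>%
    arrange(.data$F)
  if (nrow(deriv) < 5L) abort("need at least 5 finite F values")
  v <- deriv$derivative
  i_max <- which.max(v); i_min <- which.min(v)
  interior <- function(i) i > 1L && i < length(v)
  if (type == "auto") {
    if (interior(i_max) && !interior(i_min)) type <- "max"
    else if (interior(i_min) && !interior(i_max)) type <- "min"
    else type <- if (abs(v[i_max] - v[1]) >= abs(v[i_min] - v[1])) "max" else "min"
  }
  i <- if (type == "max") i_max else i_min
  if (!interior(i)) {
    return(list(F_star = deriv$F[i], type = type, boundary = TRUE,
                value = v[i]))
  }
  u <- log(deriv$F[(i - 1):(i + 1)])
  y <- v[(i - 1):(i + 1)]
  # parabola vertex through three points
  denom <- (u[1] - u[2]) * (u[1] - u[3]) * (u[2] - u[3])
  a <- (u[3] * (y[2] - y[1]) + u[2] * (y[1] - y[3]) + u[1] * (y[3] - y[2])) / denom
  b <- (u[3]^2 * (y[1] - y[2]) + u[2]^2 * (y[3] - y[1]) + u[1]^2 * (y[2] - y[3])) / denom
  u_star <- -b / (2 * a)
  u_star <- min(max(u_star, u[1]), u[3])
  list(F_star = exp(u_star), type = type, boundary = FALSE,
       value = y[2])
}

#' Plot a Monte Carlo sweep
#'
#' @param object An [mc_sweep()] result.
#' @param lambda Wavelengths to display (default 760 and 800 nm).
#' @param ... Unused.
#' @return A ggplot of A, beta and G against F at the chosen wavelengths.
#' @export
autoplot.mc_sweep <- function(object, lambda = c(760, 800), ...) {
  nearest <- purrr::map_dbl(lambda, function(l) {
    object$lambda[which.min(abs(unique(object$lambda) - l))]
  })
  df <- object %>%
    as_tibble() %>%
    filter(.data$lambda %in% nearest, is.finite(.data$F)) %>%
    tidyr::pivot_longer(c("A", "beta", "G"), names_to = "quantity")
  ggplot2::ggplot(df, ggplot2::aes(.data$F, .data$value,
                                   colour = factor(.data$lambda))) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "target absorption factor F", y = NULL,
                  colour = "wavelength (nm)")
}

#' @export
glance.mc_sweep <- function(x, ...) {
  tibble(n_photons = attr(x, "n_photons"),
         n_lambda = length(unique(x$lambda)),
         n_F = length(unique(x$F)),
         shared_paths = attr(x, "shared_paths"),
         seed = attr(x, "seed"))
}
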