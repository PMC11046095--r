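#' Validate a spectral wavelength grid
#'
#' Wavelength grids used throughout the package are strictly ascending
#' vectors in nanometres, restricted to the near-infrared window
#' \[650, 850\] nm where the phantom dye and eumelanin spectra are defined.
#'
#' @param wavelengths Numeric vector of wavelengths in nm.
#' @param max_spacing Maximum permitted spacing in nm (10 nm for processing
#'   grids; synthetic spectrometer grids use ~1 nm).
#' @return The validated wavelength vector, invisibly usable downstream.
#' @export
spectral_grid <- function(wavelengths, max_spacing = 10) {
  if (length(wavelengths) < 2L || any(diff(wavelengths) <= 0)) {
    abort("wavelengths must be strictly ascending with at least 2 values")
  }
  if (any(wavelengths < 650 - 1e-9 | wavelengths > 850 + 1e-9)) {
    abort("wavelengths must lie within [650, 850] nm")
  }
  if (max(diff(wavelengths)) > max_spacing + 1e-9) {
    abort(sprintf("wavelength spacing exceeds %g nm", max_spacing))
  }
  wavelengths
}

#' Gaussian-plus-constant absorption model for the phantom dye
#'
#' The near-infrared dye used in solid tissue-equivalent phantoms has a
#' smooth unimodal absorption spectrum over 700-840 nm. It is modelled here
#' as a constant baseline plus a single Gaussian bump,
#' \deqn{\mu_{a}(\lambda) = b + a \exp\{-(\lambda - c)^2 / (2 w^2)\},}
#' the minimal smooth four-parameter family consistent with the published
#' spectral anchors (see [dye_reference_anchors()]). The analytic first
#' derivative has exactly one maximum (at \eqn{c - w}) and one minimum
#' (at \eqn{c + w}).
#'
#' @param baseline Constant absorption offset b, mm^-1 (> 0).
#' @param amplitude Gaussian amplitude a, mm^-1 (>= 0).
#' @param center Gaussian centre c, nm.
#' @param width Gaussian width w, nm (> 0).
#' @return An object of class `dye_model`.
#' @seealso [calibrate_dye_model()], [default_dye_model()]
#' @export
dye_model <- function(baseline, amplitude, center, width) {
  if (baseline <= 0) abort("baseline must be positive")
  if (amplitude < 0) abort("amplitude must be non-negative")
  if (width <= 0) abort("width must be positive")
  structure(
    list(baseline = unname(baseline), amplitude = unname(amplitude),
         center = unname(center), width = unname(width)),
    class = "dye_model")
}

#' Evaluate dye absorption and its spectral derivative
#'
#' @param model A [dye_model()].
#' @param wavelength Wavelengths in nm.
#' @return Numeric vector: absorption in mm^-1 (`dye_absorption`) or its
#'   analytic derivative in mm^-1 nm^-1 (`dye_gradient`).
#' @export
dye_absorption <- function(model, wavelength) {
  stopifnot(inherits(model, "dye_model"))
  z <- (wavelength - model$center) / model$width
  model$baseline + model$amplitude * exp(-z^2 / 2)
}

#' @rdname dye_absorption
#' @export
dye_gradient <- function(model, wavelength) {
  stopifnot(inherits(model, "dye_model"))
  z <- (wavelength - model$center) / model$width
  -model$amplitude * z / model$width * exp(-z^2 / 2)
}

#' Reference spectral anchors for the phantom dye
#'
#' The four published anchor values that pin down the dye spectrum of the
#' solid phantom: the spectral-derivative maximum of +0.00017 mm^-1 nm^-1
#' at 756 nm, the minimum of -0.00018 mm^-1 nm^-1 at 808 nm, and the
#' absorption coefficients 0.0102 and 0.01 mm^-1 at 760 and 800 nm.
#'
#' @return A tibble with columns `wavelength`, `kind`
#'   ("absorption" or "gradient") and `value`.
#' @export
dye_reference_anchors <- function() {
  tibble(
    wavelength = c(756, 808, 760, 800),
    kind = c("gradient", "gradient", "absorption", "absorption"),
    value = c(0.00017, -0.00018, 0.0102, 0.01))
}

#' Calibrate the dye model against spectral constraints
#'
#' Fits the four parameters of the Gaussian-plus-constant dye model by
#' least squares on *relative* constraint residuals (gradient and
#' absorption constraints differ by two orders of magnitude, so absolute
#' residuals would let the absorption anchors dominate). Optionally the
#' wavelengths of the derivative extrema are constrained as well: the
#' reference anchors state the wavelengths *at which* the derivative is
#' maximal/minimal, and for this model family those are exactly
#' `center - width` and `center + width`.
#'
#' @param constraints Data frame with columns `wavelength` (nm), `kind`
#'   ("absorption" or "gradient") and `value`; at least 4 rows.
#' @param extrema Optional length-2 vector: wavelengths (nm) of the
#'   derivative maximum and minimum, added as soft location constraints.
#'   `NULL` to fit the value constraints alone.
#' @param extremum_scale_nm Scale (nm) on which an extremum-location
#'   mismatch counts as one unit of relative residual; default 6 nm.
#' @param max_rel_residual Calibration fails if any value constraint has a
#'   relative residual above this (default 0.10).
#' @return A calibrated [dye_model()] carrying the fit diagnostics in
#'   attribute `"calibration"`.
#' @export
calibrate_dye_model <- function(constraints,
                                extrema = NULL,
                                extremum_scale_nm = 6,
                                max_rel_residual = 0.10) {
  constraints <- as_tibble(constraints)
  stopifnot(all(c("wavelength", "kind", "value") %in% names(constraints)))
  if (nrow(constraints) < 4L) abort("at least 4 constraints are required")
  if (!all(constraints$kind %in% c("absorption", "gradient"))) {
    abort("constraint kind must be 'absorption' or 'gradient'")
  }
  if (!is.null(extrema) && length(extrema) != 2L) {
    abort("extrema must be c(max_wavelength, min_wavelength)")
  }

  scale_of <- function(v) ifelse(abs(v) > 0, abs(v), 1)
  eval_model <- function(par) {
    m <- list(baseline = par[1], amplitude = par[2],
              center = par[3], width = par[4])
    class(m) <- "dye_model"
    m
  }
  residuals_fn <- function(par) {
    m <- eval_model(c(abs(par[1]), abs(par[2]), par[3], abs(par[4])))
    pred <- ifelse(constraints$kind == "gradient",
                   dye_gradient(m, constraints$wavelength),
                   dye_absorption(m, constraints$wavelength))
    res <- (pred - constraints$value) / scale_of(constraints$value)
    if (!is.null(extrema)) {
      res <- c(res,
               ((par[3] - abs(par[4])) - extrema[1]) / extremum_scale_nm,
               ((par[3] + abs(par[4])) - extrema[2]) / extremum_scale_nm)
    }
    res
  }

  start <- calibration_start(constraints, extrema)
  fit <- minpack.lm::nls.lm(
    par = start, fn = residuals_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (fit$info %in% c(0L, 9L)) abort("dye calibration failed to converge")
  par <- fit$par
  model <- dye_model(baseline = abs(par[1]), amplitude = abs(par[2]),
                     center = par[3], width = abs(par[4]))

  pred <- ifelse(constraints$kind == "gradient",
                 dye_gradient(model, constraints$wavelength),
                 dye_absorption(model, constraints$wavelength))
  rel <- (pred - constraints$value) / scale_of(constraints$value)
  if (any(abs(rel) > max_rel_residual)) {
    abort(sprintf(
      "dye calibration residual %.1f%% exceeds %.0f%% on constraint %d",
      100 * max(abs(rel)), 100 * max_rel_residual, which.max(abs(rel))))
  }
  attr(model, "calibration") <- tibble(
    wavelength = constraints$wavelength, kind = constraints$kind,
    target = constraints$value, fitted = pred, rel_residual = rel)
  model
}

# starting values: centre/width from gradient-constraint geometry when
# available, amplitude/baseline from the absorption levels
calibration_start <- function(constraints, extrema) {
  abs_rows <- constraints[constraints$kind == "absorption", ]
  grad_rows <- constraints[constraints$kind == "gradient", ]
  if (!is.null(extrema)) {
    center <- mean(extrema); width <- diff(extrema) / 2
  } else if (nrow(grad_rows) >= 2L) {
    center <- mean(range(grad_rows$wavelength))
    width <- max(diff(range(grad_rows$wavelength)) / 2, 5)
  } else {
    center <- 780; width <- 26
  }
  gmax <- if (nrow(grad_rows)) max(abs(grad_rows$value)) else 0
  amplitude <- max(gmax * width * exp(0.5), 1e-6)
  baseline <- max(mean(abs_rows$value) - amplitude / 2, 1e-4)
  c(baseline = baseline, amplitude = amplitude, center = center, width = width)
}

the_dye_cache <- new.env(parent = emptyenv())

#' Default calibrated dye model
#'
#' The package-default phantom dye spectrum: the Gaussian-plus-constant
#' model calibrated to [dye_reference_anchors()] with the derivative
#' extrema constrained to 756 and 808 nm. The result is cached.
#'
#' @return A calibrated [dye_model()].
#' @export
default_dye_model <- function() {
  if (is.null(the_dye_cache$model)) {
    the_dye_cache$model <- calibrate_dye_model(
      dye_reference_anchors(), extrema = c(756, 808))
  }
  the_dye_cache$model
}

#' Exponential eumelanin extinction model
#'
#' Eumelanin, the dominant absorber of dark hair, has a smoothly and
#' approximately exponentially decreasing extinction coefficient across
#' the visible and near-infrared range. It is modelled as
#' \deqn{\epsilon_m(\lambda) = s \exp\{-k (\lambda - \lambda_{ref})\}}
#' with scale s in mm^-1 (mg/ml)^-1 at the reference wavelength and decay
#' k in nm^-1. The default (s = 50 at 650 nm, k = 0.005 nm^-1) gives a
#' smooth NIR exponential; the absolute scale is arbitrary because the
#' melanin concentrations recovered downstream are effective ones.
#'
#' @param scale Extinction at the reference wavelength, mm^-1 (mg/ml)^-1.
#' @param decay Exponential decay constant, nm^-1 (> 0).
#' @param reference Reference wavelength, nm.
#' @return An object of class `melanin_model`.
#' @export
melanin_model <- function(scale = 50, decay = 0.005, reference = 650) {
  if (scale <= 0 || decay <= 0) abort("scale and decay must be positive")
  structure(list(scale = unname(scale), decay = unname(decay),
                 reference = unname(reference)),
            class = "melanin_model")
}

#' Evaluate melanin extinction and its spectral derivative
#'
#' @param model A [melanin_model()].
#' @param wavelength Wavelengths in nm.
#' @return Extinction in mm^-1 (mg/ml)^-1, or its derivative in
#'   mm^-1 (mg/ml)^-1 nm^-1 (always negative).
#' @export
melanin_extinction <- function(model, wavelength) {
  stopifnot(inherits(model, "melanin_model"))
  model$scale * exp(-model$decay * (wavelength - model$reference))
}

#' @rdname melanin_extinction
#' @export
melanin_gradient <- function(model, wavelength) {
  -model$decay * melanin_extinction(model, wavelength)
}

#' Fit a melanin model to tabulated extinction values
#'
#' Log-linear regression of tabulated extinction measurements, for users
#' who want a melanin spectrum anchored to their own data rather than the
#' package default.
#'
#' @param data Data frame with columns `wavelength` (nm) and `extinction`
#'   (mm^-1 (mg/ml)^-1, all positive).
#' @param reference Reference wavelength for the fitted scale, nm.
#' @return A fitted [melanin_model()].
#' @export
fit_melanin <- function(data, reference = 650) {
  data <- as_tibble(data)
  stopifnot(all(c("wavelength", "extinction") %in% names(data)))
  if (any(data$extinction <= 0)) abort("extinction values must be positive")
  fit <- lm(log(extinction) ~ I(wavelength - reference), data = data)
  cf <- coef(fit)
  if (cf[2] >= 0) abort("fitted extinction does not decrease with wavelength")
  melanin_model(scale = exp(cf[1]), decay = -cf[2], reference = reference)
}

#' Wavelength-dependent scatter basis term
#'
#' The empirical homogeneous-medium gradient model includes a
#' \eqn{-\alpha \lambda^{-p}} term accommodating the wavelength dependence
#' of the transport scattering coefficient. This returns the basis values
#' \eqn{\lambda^{-p}} (strictly decreasing, positive).
#'
#' @param wavelength Wavelengths in nm.
#' @param p Positive unitless exponent.
#' @return Numeric vector of \eqn{\lambda^{-p}}.
#' @export
scatter_basis <- function(wavelength, p) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0) {
    abort("scatter exponent p must be a positive scalar")
  }
  wavelength^(-p)
}

#' Chromophore derivative basis on a wavelength grid
#'
#' Assembles the spectral-derivative basis used by the unmixing equations:
#' the dye absorption derivative, the melanin extinction derivative, and
#' optionally the (negated) scatter term \eqn{-\lambda^{-p}}. A condition
#' number of the column-scaled basis is attached; a warning is raised when
#' it exceeds 1e3 (near-collinear bases, e.g. melanin vs. scatter, make
#' the unmixing ambiguous).
#'
#' @param wavelength Wavelengths in nm (the fit wavelengths).
#' @param dye A [dye_model()]; default [default_dye_model()].
#' @param melanin A [melanin_model()]; default [melanin_model()].
#' @param scatter_p Optional positive exponent; when supplied a
#'   `d_scatter` column holding \eqn{-\lambda^{-p}} is included.
#' @return Tibble with columns `wavelength`, `d_dye`, `d_melanin` and
#'   optionally `d_scatter`; attribute `"condition"` holds the scaled
#'   condition number.
#' @export
chromophore_basis <- function(wavelength, dye = default_dye_model(),
                              melanin = melanin_model(), scatter_p = NULL) {
  out <- tibble(
    wavelength = wavelength,
    d_dye = dye_gradient(dye, wavelength),
    d_melanin = melanin_gradient(melanin, wavelength))
  if (!is.null(scatter_p)) {
    out$d_scatter <- -scatter_basis(wavelength, scatter_p)
  }
  M <- as.matrix(out[, -1L, drop = FALSE])
  cond <- scaled_condition(M)
  if (is.finite(cond) && cond > 1e3) {
    warn(sprintf("chromophore basis is near-collinear (condition %.3g)", cond))
  }
  attr(out, "condition") <- cond
  out
}

# condition number after normalizing columns to unit norm
scaled_condition <- function(M) {
  nrm <- sqrt(colSums(M^2))
  if (any(nrm == 0)) return(Inf)
  sv <- svd(sweep(M, 2, nrm, "/"), nu = 0, nv = 0)$d
  if (min(sv) == 0) Inf else max(sv) / min(sv)
}

#' @export
print.dye_model <- function(x, ...) {
  cat(sprintf(
    "<dye_model> mu_a(lambda) = %.5g + %.5g * exp(-(lambda - %.4g)^2 / (2 * %.4g^2)) mm^-1\n",
    x$baseline, x$amplitude, x$center, x$width))
  cal <- attr(x, "calibration")
  if (!is.null(cal)) {
    cat(sprintf("  calibrated: max |relative residual| %.2f%%\n",
                100 * max(abs(cal$rel_residual))))
  }
  invisible(x)
}

#' @export
print.melanin_model <- function(x, ...) {
  cat(sprintf(
    "<melanin_model> eps_m(lambda) = %.4g * exp(-%.4g * (lambda - %g)) mm^-1 (mg/ml)^-1\n",
    x$scale, x$decay, x$reference))
  invisible(x)
}

#' @export
tidy.dye_model <- function(x, ...) {
  tibble(term = c("baseline", "amplitude", "center", "width"),
         estimate = c(x$baseline, x$amplitude, x$center, x$width),
         unit = c("mm^-1", "mm^-1", "nm", "nm"))
}

#' @export
tidy.melanin_model <- function(x, ...) {
  tibble(term = c("scale", "decay", "reference"),
         estimate = c(x$scale, x$decay, x$reference),
         unit = c("mm^-1 (mg/ml)^-1", "nm^-1", "nm"))
}

#' @export
glance.dye_model <- function(x, ...) {
  cal <- attr(x, "calibration")
  tibble(
    n_constraints = if (is.null(cal)) NA_integer_ else nrow(cal),
    max_rel_residual = if (is.null(cal)) NA_real_ else max(abs(cal$rel_residual)),
    gradient_max_nm = x$center - x$width,
    gradient_min_nm = x$center + x$width)
}

#' Plot an absorber spectrum and its derivative
#'
#' @param object A [dye_model()] or [melanin_model()].
#' @param wavelength Wavelength grid for display.
#' @param ... Unused.
#' @return A ggplot object with absorption/extinction and derivative panels.
#' @export
autoplot.dye_model <- function(object, wavelength = seq(650, 850, 1), ...) {
  df <- tibble(
    wavelength = wavelength,
    value = dye_absorption(object, wavelength),
    derivative = dye_gradient(object, wavelength)) %>%
    tidyr::pivot_longer(-wavelength, names_to = "quantity")
  ggplot2::ggplot(df, ggplot2::aes(wavelength, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "wavelength (nm)", y = NULL,
                  title = "Phantom dye absorption model")
}

#' @rdname autoplot.dye_model
#' @export
autoplot.melanin_model <- function(object, wavelength = seq(650, 850, 1), ...) {
  df <- tibble(
    wavelength = wavelength,
    value = melanin_extinction(object, wavelength),
    derivative = melanin_gradient(object, wavelength)) %>%
    tidyr::pivot_longer(-wavelength, names_to = "quantity")
  ggplot2::ggplot(df, ggplot2::aes(wavelength, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "wavelength (nm)", y = NULL,
                  title = "Eumelanin extinction model")
}
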