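#' Dark-subtract a measured spectrum
#'
#' Subtracts the dark reference from a measured spectrum and floors the
#' result at a small positive value (the larger of the dark noise level
#' and 1e-12 of the spectrum peak) so the logarithm is defined. Floored
#' bins are counted in the `"n_flagged"` attribute.
#'
#' @param spectrum Measured spectrum tibble (`wavelength`, `intensity`).
#' @param dark Dark reference on the same grid.
#' @param dark_sd Dark noise level used as the floor, counts.
#' @return Tibble with `wavelength`, `intensity`; attribute `"n_flagged"`.
#' @export
preprocess <- function(spectrum, dark, dark_sd = 0) {
  if (!isTRUE(all.equal(spectrum$wavelength, dark$wavelength))) {
    abort("spectrum and dark must share one wavelength grid")
  }
  net <- spectrum$intensity - dark$intensity
  floor_val <- max(dark_sd, 1e-12 * max(spectrum$intensity))
  if (all(net <= 0)) abort("spectrum is entirely at or below the dark level")
  flagged <- net < floor_val
  out <- tibble(wavelength = spectrum$wavelength,
                intensity = pmax(net, floor_val))
  attr(out, "n_flagged") <- sum(flagged)
  out
}

#' Fit a 12th-order polynomial to a log spectrum
#'
#' Least-squares polynomial fit of `ln(intensity)` over the processing
#' window (default 700-840 nm), the standard smooth representation from
#' which attenuation and attenuation-gradient values are read off. The
#' fit is performed in a Chebyshev basis on the window mapped to
#' \[-1, 1\]; a raw monomial fit of order 12 at wavelengths near 800 nm
#' would be numerically singular.
#'
#' @param spectrum Preprocessed spectrum tibble (`wavelength`,
#'   `intensity`, all positive).
#' @param order Polynomial order (default 12).
#' @param window Fit window in nm (default `c(700, 840)`); at least 20
#'   samples must fall inside.
#' @return An object of class `log_poly_fit` with the scaled-basis
#'   coefficients, window and residual RMS.
#' @export
fit_log_poly <- function(spectrum, order = 12, window = c(700, 840)) {
  inside <- spectrum$wavelength >= window[1] & spectrum$wavelength <= window[2]
  if (sum(inside) < 20L) abort("need at least 20 samples inside the fit window")
  if (any(spectrum$intensity[inside] <= 0)) {
    abort("log fit requires positive intensities; preprocess() first")
  }
  fit <- fit_cheb(spectrum$wavelength[inside], log(spectrum$intensity[inside]),
                  order = order, window = window)
  structure(fit, class = "log_poly_fit")
}

#' @export
print.log_poly_fit <- function(x, ...) {
  cat(sprintf("<log_poly_fit> order %d over [%g, %g] nm, residual RMS %.3g\n",
              x$order, x$window[1], x$window[2], x$rms))
  invisible(x)
}

#' @export
glance.log_poly_fit <- function(x, ...) {
  tibble(order = x$order, window_min = x$window[1], window_max = x$window[2],
         rms = x$rms, n = x$n)
}

#' Attenuation and attenuation gradient from log-spectrum fits
#'
#' `attenuation_at()` is the difference between the source and
#' measurement log-spectrum fits at a wavelength,
#' \eqn{A(\lambda) = \ln I_0(\lambda) - \ln I(\lambda)};
#' `gradient_at()` is the corresponding difference of analytic
#' polynomial derivatives, \eqn{\partial A / \partial \lambda}, in nm^-1.
#' Scaling a measured spectrum by a constant coupling factor shifts
#' `attenuation_at` by `-ln k` but leaves `gradient_at` unchanged — the
#' principle that makes gradient images immune to coupling losses.
#'
#' @param fit [fit_log_poly()] of the measured spectrum.
#' @param source_fit [fit_log_poly()] of the source spectrum.
#' @param lambda Query wavelengths, nm (inside both fit windows).
#' @return Numeric vector of attenuation (unitless) or gradient (nm^-1).
#' @export
attenuation_at <- function(fit, source_fit, lambda) {
  eval_cheb(source_fit, lambda) - eval_cheb(fit, lambda)
}

#' @rdname attenuation_at
#' @export
gradient_at <- function(fit, source_fit, lambda) {
  eval_cheb_deriv(source_fit, lambda) - eval_cheb_deriv(fit, lambda)
}

#' Broadband attenuation over the processing window
#'
#' The natural log of the ratio of the source and measured spectra, each
#' integrated (trapezoidally on the native grid) over the window.
#'
#' @param spectrum Preprocessed spectrum tibble.
#' @param source Source spectrum tibble on the same grid.
#' @param window Integration window, nm.
#' @return Unitless attenuation (positive when the spectrum is dimmer
#'   than the source).
#' @export
broadband_attenuation <- function(spectrum, source, window = c(700, 840)) {
  if (!isTRUE(all.equal(spectrum$wavelength, source$wavelength))) {
    abort("spectrum and source must share one wavelength grid")
  }
  inside <- spectrum$wavelength >= window[1] & spectrum$wavelength <= window[2]
  wl <- spectrum$wavelength[inside]
  num <- pracma::trapz(wl, source$intensity[inside])
  den <- pracma::trapz(wl, spectrum$intensity[inside])
  if (num <= 0 || den <= 0) abort("non-positive integrated signal")
  log(num / den)
}

#' Process a grid scan into per-position spectral metrics
#'
#' Runs the full spectrometer pipeline on every position of a scan:
#' dark subtraction, log-spectrum polynomial fits of measurement and
#' source, then broadband attenuation plus attenuation and attenuation
#' gradient at the requested wavelengths.
#'
#' @param scan A [generate_scan()] result (or a scan read back with
#'   [read_scan()]).
#' @param wavelengths Wavelengths (nm) at which attenuation and gradient
#'   are evaluated; default `c(760, 800)`.
#' @param order Polynomial order of the log fits.
#' @param window Fit window, nm.
#' @return Object of class `processed_scan`: list with `values` (long
#'   tibble `row`, `col`, `x`, `y`, `metric`, `wavelength`, `value`),
#'   `fit_rms` per position, and the processing settings.
#' @export
process_scan <- function(scan, wavelengths = c(760, 800),
                         order = 12, window = c(700, 840)) {
  stopifnot(inherits(scan, "nirs_scan"))
  source_pre <- preprocess(scan$source, zero_dark(scan$source))
  source_fit <- fit_log_poly(source_pre, order = order, window = window)

  per_pos <- scan$data %>%
    tidyr::nest(spectra = c("wavelength", "intensity"))

  res <- purrr::map2(per_pos$spectra, seq_len(nrow(per_pos)), function(sp, i) {
    pre <- preprocess(sp, scan$dark, dark_sd = scan$protocol$dark_sd)
    fit <- fit_log_poly(pre, order = order, window = window)
    vals <- bind_rows(
      tibble(metric = "broadband", wavelength = NA_real_,
             value = broadband_attenuation(pre, scan$source, window)),
      tibble(metric = "attenuation", wavelength = wavelengths,
             value = attenuation_at(fit, source_fit, wavelengths)),
      tibble(metric = "gradient", wavelength = wavelengths,
             value = gradient_at(fit, source_fit, wavelengths)))
    list(vals = vals, rms = fit$rms)
  })

  values <- per_pos %>%
    select("row", "col", "x", "y") %>%
    mutate(vals = purrr::map(res, "vals")) %>%
    tidyr::unnest("vals")
  structure(
    list(values = values,
         fit_rms = purrr::map_dbl(res, "rms"),
         wavelengths = wavelengths, order = order, window = window,
         protocol = scan$protocol,
         scene = scan$scene),
    class = "processed_scan")
}

zero_dark <- function(spectrum) {
  tibble(wavelength = spectrum$wavelength,
         intensity = rep(0, length(spectrum$wavelength)))
}

#' Assemble a topographic image from a scan
#'
#' Builds the 2D map of one metric over the scan grid (10 x 15 for the
#' default protocol). Accepts either a raw scan (processed on the fly) or
#' a [process_scan()] result.
#'
#' @param scan A `nirs_scan` or `processed_scan`.
#' @param metric `"broadband"`, `"attenuation"` or `"gradient"`.
#' @param lambda Wavelength (nm); required for attenuation/gradient.
#' @param ... Passed on to [process_scan()] when `scan` is raw.
#' @return Tibble of class `optical_image` (`row`, `col`, `x`, `y`,
#'   `value`) with attributes `metric`, `wavelength` and `spacing`.
#'   Units: attenuation unitless, gradient nm^-1.
#' @export
assemble_image <- function(scan, metric = c("broadband", "attenuation", "gradient"),
                           lambda = NULL, ...) {
  metric <- match.arg(metric)
  if (metric != "broadband" && is.null(lambda)) {
    abort("lambda is required for attenuation/gradient images")
  }
  if (inherits(scan, "nirs_scan")) {
    scan <- process_scan(scan, wavelengths = if (is.null(lambda)) c(760, 800) else lambda, ...)
  }
  stopifnot(inherits(scan, "processed_scan"))
  vals <- scan$values %>% filter(.data$metric == !!metric)
  if (metric != "broadband") {
    vals <- vals %>% filter(abs(.data$wavelength - lambda) < 1e-9)
    if (nrow(vals) == 0) abort(sprintf("no %s values at %g nm", metric, lambda))
  }
  expected <- scan$protocol$n_rows * scan$protocol$n_cols
  if (nrow(vals) != expected) {
    abort(sprintf("incomplete grid: %d of %d positions", nrow(vals), expected))
  }
  img <- vals %>%
    select("row", "col", "x", "y", "value") %>%
    arrange(.data$row, .data$col)
  new_optical_image(img, metric = metric, wavelength = lambda,
                    spacing = scan$protocol$spacing)
}

new_optical_image <- function(df, metric, wavelength, spacing) {
  structure(as_tibble(df),
            metric = metric,
            wavelength = if (is.null(wavelength)) NA_real_ else wavelength,
            spacing = spacing,
            class = c("optical_image", class(as_tibble(df))))
}

#' Per-target contrast of a topographic image
#'
#' Reads the image value at the grid position nearest to each embedded
#' target (ties broken toward the lower row/column index) and summarises
#' the background over all positions more than `background_margin` mm
#' (lateral) from every target.
#'
#' @param image An [assemble_image()] result.
#' @param scene The [build_phantom_scene()] scene that generated the data.
#' @param background_margin Minimum lateral distance from any target for
#'   a position to count as background, mm.
#' @return Tibble with one row per target (`target`, `x`, `y`, `depth`,
#'   `factor`, `value`, `contrast`) plus attributes `background_mean`
#'   and `background_sd`; `contrast = value - background_mean`.
#' @export
contrast_at_targets <- function(image, scene, background_margin = 15) {
  stopifnot(inherits(image, "optical_image"))
  t <- scene$targets
  nearest <- purrr::map_int(seq_len(nrow(t)), function(i) {
    d2 <- (image$x - t$x[i])^2 + (image$y - t$y[i])^2
    which(d2 == min(d2))[1] # image sorted by row, col: lower index wins ties
  })
  min_dist <- purrr::map_dbl(seq_len(nrow(image)), function(j) {
    sqrt(min((t$x - image$x[j])^2 + (t$y - image$y[j])^2))
  })
  bg <- image$value[min_dist > background_margin]
  out <- tibble(
    target = t$target, x = t$x, y = t$y, depth = t$depth, factor = t$factor,
    value = image$value[nearest],
    contrast = image$value[nearest] - mean(bg))
  attr(out, "background_mean") <- mean(bg)
  attr(out, "background_sd") <- sd(bg)
  attr(out, "n_background") <- length(bg)
  out
}

#' Plot a topographic image
#'
#' @param object An [assemble_image()] result.
#' @param ... Unused.
#' @return A ggplot raster map in physical coordinates.
#' @export
autoplot.optical_image <- function(object, ...) {
  metric <- attr(object, "metric")
  wl <- attr(object, "wavelength")
  lab <- if (is.na(wl)) metric else sprintf("%s at %g nm", metric, wl)
  unit <- if (identical(metric, "gradient")) "nm^-1" else "unitless"
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(name = unit) +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", title = lab)
}
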