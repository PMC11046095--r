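#' Diffusion-model differential pathlength factor
#'
#' Steady-state diffusion estimate of the DPF for a reflectance
#' measurement at separation `d` on a slab,
#' \deqn{\beta = \tfrac{1}{2}\sqrt{3\mu_s'/\mu_a}
#'   \left[1 - \frac{1}{1 + d\sqrt{3\mu_a\mu_s'}}\right],}
#' with a leading-order image-source correction
#' \eqn{\times (1 - e^{-2\mu_{eff} T})} applied when the slab thickness
#' `T` is less than five separations (negligible, <5%, for the default
#' 40 mm phantom).
#'
#' @param mu_a Absorption coefficient, mm^-1 (> 0); vectorised.
#' @param mu_s_p Transport scattering coefficient, mm^-1 (> 0).
#' @param d Source-detector separation, mm (> 0).
#' @param thickness Slab thickness, mm; `Inf` for a semi-infinite medium.
#' @return DPF (unitless), strictly decreasing in `mu_a`.
#' @export
dpf_diffusion <- function(mu_a, mu_s_p, d, thickness = Inf) {
  if (any(mu_a <= 0) || mu_s_p <= 0 || d <= 0 || thickness <= 0) {
    abort("mu_a, mu_s_p, d and thickness must be positive")
  }
  mu_eff <- sqrt(3 * mu_a * mu_s_p)
  dpf <- 0.5 * sqrt(3 * mu_s_p / mu_a) * (1 - 1 / (1 + d * mu_eff))
  if (is.finite(thickness) && thickness < 5 * d) {
    dpf <- dpf * (1 - exp(-2 * mu_eff * thickness))
  }
  dpf
}

#' Band-mean DPF for an absorber model
#'
#' Averages [dpf_diffusion()] over the processing band using the dye
#' model's absorption spectrum; the standard choice for the assumed mean
#' DPF in the unmixing equations.
#'
#' @param dye A [dye_model()].
#' @param mu_s_p Transport scattering coefficient, mm^-1.
#' @param d Source-detector separation, mm.
#' @param window Averaging band, nm.
#' @param thickness Slab thickness, mm.
#' @param step Wavelength step for the average, nm.
#' @return Mean DPF (unitless); approximately 6 for the default phantom
#'   optics (mu_s' = 1 mm^-1, d = 20 mm).
#' @export
mean_dpf <- function(dye = default_dye_model(), mu_s_p = 1.0, d = 20,
                     window = c(700, 840), thickness = Inf, step = 1) {
  wl <- seq(window[1], window[2], by = step)
  mean(dpf_diffusion(dye_absorption(dye, wl), mu_s_p, d, thickness))
}

# minimum-norm least squares via SVD pseudo-inverse
ls_minnorm <- function(X, y, tol = NULL) {
  s <- svd(X)
  if (is.null(tol)) tol <- max(dim(X)) * .Machine$double.eps * max(s$d)
  keep <- s$d > tol
  coef <- s$v[, keep, drop = FALSE] %*%
    ((t(s$u[, keep, drop = FALSE]) %*% y) / s$d[keep])
  resid <- y - drop(X %*% coef)
  list(coef = drop(coef),
       residual = sqrt(sum(resid^2)),
       rank = sum(keep),
       condition = scaled_condition(X))
}

new_unmix_fit <- function(coefs, residual, condition, rank, method,
                          profile = NULL, flags = character()) {
  structure(
    list(r_dye = unname(coefs["r_dye"]), c_m = unname(coefs["c_m"]),
         alpha = if ("alpha" %in% names(coefs)) unname(coefs["alpha"]) else NULL,
         p = if ("p" %in% names(coefs)) unname(coefs["p"]) else NULL,
         residual = residual, condition = condition, rank = rank,
         method = method, profile = profile, flags = flags),
    class = "unmix_fit")
}

#' Two-absorber spectral-gradient unmixing (linear)
#'
#' Solves the wavelength-independent-scatter unmixing equation
#' \deqn{\partial A/\partial\lambda \approx d\langle\beta\rangle
#'   (r_{dye}\,\partial\mu_{a,dye}/\partial\lambda +
#'    c_m\,\partial\epsilon_m/\partial\lambda)}
#' for the relative dye absorption `r_dye` (unitless) and effective
#' melanin concentration `c_m` (mg/ml) by minimum-norm least squares.
#' With exactly two wavelengths and a full-rank basis this is the unique
#' exact solution. Rank deficiency is not an error: the pseudo-inverse
#' solution is returned with a `"rank_deficient"` flag.
#'
#' @param gradients Data frame with columns `wavelength` (nm) and
#'   `gradient` (nm^-1); at least 2 rows.
#' @param d Source-detector separation, mm.
#' @param beta Assumed mean DPF; `NULL` uses [mean_dpf()] for `dye`.
#' @param dye,melanin Absorber models supplying the derivative basis.
#' @return An object of class `unmix_fit` with elements `r_dye`, `c_m`,
#'   `residual`, `condition`, `flags`.
#' @export
solve_unmix_linear <- function(gradients, d = 20, beta = NULL,
                               dye = default_dye_model(),
                               melanin = melanin_model()) {
  gradients <- as_tibble(gradients)
  stopifnot(all(c("wavelength", "gradient") %in% names(gradients)))
  if (nrow(gradients) < 2L) abort("at least 2 wavelengths are required")
  if (is.null(beta)) beta <- mean_dpf(dye, d = d)
  wl <- gradients$wavelength
  X <- d * beta * cbind(r_dye = dye_gradient(dye, wl),
                        c_m = melanin_gradient(melanin, wl))
  sol <- ls_minnorm(X, gradients$gradient)
  flags <- character()
  if (sol$rank < ncol(X)) flags <- c(flags, "rank_deficient")
  if (is.finite(sol$condition) && sol$condition > 1e3) {
    flags <- c(flags, "ill_conditioned")
    warn(sprintf("unmixing design condition number %.3g", sol$condition))
  }
  new_unmix_fit(setNames(sol$coef, c("r_dye", "c_m")), sol$residual,
                sol$condition, sol$rank, method = "linear", flags = flags)
}

#' Two-absorber unmixing with a wavelength-dependent scatter term
#'
#' Adds the empirical scatter term \eqn{-\alpha\lambda^{-p}} to the
#' linear unmixing equation and solves by profiling: for each `p` on a
#' fixed grid the subproblem in `(r_dye, c_m, alpha)` is linear and is
#' solved by minimum-norm least squares; the `p` minimising the residual
#' is returned together with the full residual-vs-p profile. Because the
#' melanin exponential and the scatter power law are nearly collinear
#' over the NIR band, solutions with negative `c_m` or `alpha` are
#' common; they are returned as-is and flagged (`"negative_c_m"`,
#' `"negative_alpha"`), unless `nonneg = TRUE`, which re-solves with the
#' offending coefficients constrained to zero.
#'
#' @inheritParams solve_unmix_linear
#' @param p_grid Grid of scatter exponents to profile over.
#' @param nonneg Constrain `c_m` and `alpha` to be non-negative.
#' @return An `unmix_fit` with `alpha`, `p`, and a `profile` tibble
#'   (`p`, `residual`).
#' @export
solve_unmix_scatter <- function(gradients, d = 20, beta = NULL,
                                dye = default_dye_model(),
                                melanin = melanin_model(),
                                p_grid = seq(0.2, 3.0, by = 0.05),
                                nonneg = FALSE) {
  gradients <- as_tibble(gradients)
  stopifnot(all(c("wavelength", "gradient") %in% names(gradients)))
  if (nrow(gradients) < 4L) abort("at least 4 wavelengths are required")
  if (length(p_grid) == 0L) abort("empty p grid")
  if (is.null(beta)) beta <- mean_dpf(dye, d = d)
  wl <- gradients$wavelength
  y <- gradients$gradient
  base <- d * beta * cbind(r_dye = dye_gradient(dye, wl),
                           c_m = melanin_gradient(melanin, wl))

  solve_at_p <- function(p) {
    X <- cbind(base, alpha = -scatter_basis(wl, p))
    sol <- if (nonneg) ls_nonneg(X, y, nonneg_idx = c(2L, 3L)) else ls_minnorm(X, y)
    sol$p <- p
    sol
  }
  sols <- purrr::map(p_grid, solve_at_p)
  resids <- purrr::map_dbl(sols, "residual")
  best <- sols[[which.min(resids)]]

  flags <- character()
  coefs <- setNames(best$coef, c("r_dye", "c_m", "alpha"))
  if (coefs["c_m"] < 0) flags <- c(flags, "negative_c_m")
  if (coefs["alpha"] < 0) flags <- c(flags, "negative_alpha")
  if (is.finite(best$condition) && best$condition > 1e3) {
    flags <- c(flags, "ill_conditioned")
  }
  new_unmix_fit(c(coefs, p = best$p), best$residual, best$condition,
                best$rank, method = "scatter",
                profile = tibble(p = p_grid, residual = resids),
                flags = flags)
}

# tiny active-set non-negative LS: enumerate zero-sets over the constrained
# columns (at most 2 here) and keep the feasible solution with least residual
ls_nonneg <- function(X, y, nonneg_idx) {
  best <- NULL
  subsets <- purrr::map(0:length(nonneg_idx), ~ utils::combn(nonneg_idx, .x, simplify = FALSE)) %>%
    purrr::flatten()
  for (zero in subsets) {
    keep <- setdiff(seq_len(ncol(X)), zero)
    sol <- ls_minnorm(X[, keep, drop = FALSE], y)
    coef <- numeric(ncol(X)); coef[keep] <- sol$coef
    if (all(coef[nonneg_idx] >= -1e-12) &&
        (is.null(best) || sol$residual < best$residual)) {
      best <- list(coef = coef, residual = sol$residual,
                   rank = sol$rank, condition = scaled_condition(X))
    }
  }
  best
}

#' Homogeneous-medium concentration fit from attenuation gradients
#'
#' Fits the general homogeneous gradient model
#' \deqn{\partial A/\partial\lambda \approx d\langle\beta\rangle
#'   \sum_n c_n \partial\epsilon_n/\partial\lambda - \alpha\lambda^{-p}}
#' for arbitrary chromophore bases: concentrations enter linearly and the
#' scatter exponent `p` is profiled over a grid, as in
#' [solve_unmix_scatter()]. Wavelengths should be placed where the basis
#' derivatives are large and mutually distinct; the scaled condition
#' number of the design is checked.
#'
#' @param gradients Data frame with `wavelength` (nm) and `gradient`
#'   (nm^-1); at least as many rows as unknowns.
#' @param basis Data frame with `wavelength` plus one derivative column
#'   per chromophore (e.g. from [chromophore_basis()] without scatter).
#' @param d Source-detector separation, mm.
#' @param beta Assumed mean DPF.
#' @param scatter Include the \eqn{-\alpha\lambda^{-p}} term.
#' @param p_grid Scatter-exponent grid when `scatter = TRUE`.
#' @return Object of class `homog_fit`: `concentrations` tibble
#'   (`term`, `estimate`), `alpha`, `p`, `residual`, `condition`.
#' @export
solve_homogeneous <- function(gradients, basis, d = 20, beta = 6,
                              scatter = TRUE,
                              p_grid = seq(0.2, 3.0, by = 0.05)) {
  gradients <- as_tibble(gradients)
  basis <- as_tibble(basis)
  stopifnot("wavelength" %in% names(basis))
  m <- left_join(gradients, basis, by = "wavelength")
  if (anyNA(m)) abort("basis does not cover all gradient wavelengths")
  terms <- setdiff(names(basis), "wavelength")
  n_unknown <- length(terms) + if (scatter) 2L else 0L
  if (nrow(m) < n_unknown) abort("fewer wavelengths than unknowns")
  B <- d * beta * as.matrix(m[, terms, drop = FALSE])
  y <- m$gradient
  if (!scatter) {
    sol <- ls_minnorm(B, y)
    best <- list(coef = sol$coef, residual = sol$residual,
                 condition = sol$condition, rank = sol$rank, p = NA_real_)
    alpha <- NA_real_
    profile <- NULL
  } else {
    if (length(p_grid) == 0L) abort("empty p grid")
    sols <- purrr::map(p_grid, function(p) {
      sol <- ls_minnorm(cbind(B, -scatter_basis(m$wavelength, p)), y)
      sol$p <- p
      sol
    })
    resids <- purrr::map_dbl(sols, "residual")
    best <- sols[[which.min(resids)]]
    alpha <- best$coef[length(best$coef)]
    best$coef <- best$coef[-length(best$coef)]
    profile <- tibble(p = p_grid, residual = resids)
  }
  structure(
    list(concentrations = tibble(term = terms, estimate = unname(best$coef)),
         alpha = alpha, p = best$p,
         residual = best$residual, condition = best$condition,
         profile = profile, d = d, beta = beta),
    class = "homog_fit")
}

#' @export
print.unmix_fit <- function(x, ...) {
  cat(sprintf("<unmix_fit:%s> r_dye = %.4g, c_m = %.4g", x$method, x$r_dye, x$c_m))
  if (!is.null(x$alpha)) cat(sprintf(", alpha = %.4g, p = %.3g", x$alpha, x$p))
  cat(sprintf(" (residual %.3g)\n", x$residual))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.unmix_fit <- function(x, ...) {
  out <- tibble(term = c("r_dye", "c_m"), estimate = c(x$r_dye, x$c_m))
  if (!is.null(x$alpha)) {
    out <- bind_rows(out, tibble(term = c("alpha", "p"),
                                 estimate = c(x$alpha, x$p)))
  }
  out
}

#' @export
glance.unmix_fit <- function(x, ...) {
  tibble(method = x$method, residual = x$residual, condition = x$condition,
         rank = x$rank, n_flags = length(x$flags))
}

#' @export
print.homog_fit <- function(x, ...) {
  cat("<homog_fit>\n")
  print(x$concentrations)
  if (!is.na(x$p)) cat(sprintf("alpha = %.4g, p = %.3g\n", x$alpha, x$p))
  cat(sprintf("residual %.3g, condition %.3g\n", x$residual, x$condition))
  invisible(x)
}

#' @export
tidy.homog_fit <- function(x, ...) {
  out <- x$concentrations
  if (!is.na(x$p)) {
    out <- bind_rows(out, tibble(term = c("alpha", "p"),
                                 estimate = c(x$alpha, x$p)))
  }
  out
}

#' @export
glance.homog_fit <- function(x, ...) {
  tibble(residual = x$residual, condition = x$condition,
         p = x$p, d = x$d, beta = x$beta)
}

#' Unmix a processed scan into absorber maps
#'
#' Applies [solve_unmix_linear()] (or [solve_unmix_scatter()]) to the
#' attenuation-gradient values of every scan position, producing
#' topographic maps of relative dye absorption `r_dye` and effective
#' melanin concentration `c_m` together with per-position diagnostics.
#'
#' @param processed A [process_scan()] result containing gradient values
#'   at the unmixing wavelengths.
#' @param wavelengths Wavelengths (nm) to unmix at; default `c(760, 800)`.
#' @param d Source-detector separation, mm; defaults to the protocol's.
#' @param beta Assumed mean DPF; `NULL` uses [mean_dpf()].
#' @param dye,melanin Absorber models.
#' @param scatter Use the scatter-term solver (requires >= 4 wavelengths).
#' @param ... Further arguments to the per-position solver.
#' @return Tibble of class `unmix_maps`: `row`, `col`, `x`, `y`,
#'   `r_dye`, `c_m` (plus `alpha`, `p` when `scatter = TRUE`),
#'   `residual`, `condition`, `flags`.
#' @export
unmix_scan <- function(processed, wavelengths = c(760, 800),
                       d = NULL, beta = NULL,
                       dye = default_dye_model(), melanin = melanin_model(),
                       scatter = FALSE, ...) {
  stopifnot(inherits(processed, "processed_scan"))
  if (length(wavelengths) < 2L) abort("unmixing needs at least 2 wavelengths")
  if (scatter && length(wavelengths) < 4L) {
    abort("scatter-term unmixing needs at least 4 wavelengths")
  }
  missing <- setdiff(wavelengths, processed$wavelengths)
  if (length(missing)) {
    abort(sprintf("no gradient values at %s nm; re-run process_scan()",
                  paste(missing, collapse = ", ")))
  }
  if (is.null(d)) d <- processed$protocol$separation
  if (is.null(beta)) beta <- mean_dpf(dye, d = d)

  g <- processed$values %>%
    filter(.data$metric == "gradient", .data$wavelength %in% wavelengths) %>%
    select("row", "col", "x", "y", "wavelength", "value")
  solver <- if (scatter) solve_unmix_scatter else solve_unmix_linear
  maps <- g %>%
    tidyr::nest(grad = c("wavelength", "value")) %>%
    mutate(fit = purrr::map(.data$grad, function(gg) {
      solver(tibble(wavelength = gg$wavelength, gradient = gg$value),
             d = d, beta = beta, dye = dye, melanin = melanin, ...)
    })) %>%
    select(-"grad") %>%
    mutate(
      r_dye = purrr::map_dbl(.data$fit, "r_dye"),
      c_m = purrr::map_dbl(.data$fit, "c_m"),
      alpha = if (scatter) purrr::map_dbl(.data$fit, "alpha") else NULL,
      p = if (scatter) purrr::map_dbl(.data$fit, "p") else NULL,
      residual = purrr::map_dbl(.data$fit, "residual"),
      condition = purrr::map_dbl(.data$fit, "condition"),
      flags = purrr::map_chr(.data$fit, ~ paste(.x$flags, collapse = ";"))) %>%
    select(-"fit")
  structure(maps,
            wavelengths = wavelengths, d = d, beta = beta, scatter = scatter,
            spacing = processed$protocol$spacing,
            class = c("unmix_maps", class(maps)))
}

#' Extract one unmixed map as a topographic image
#'
#' @param maps An [unmix_scan()] result.
#' @param quantity Column to extract, e.g. `"r_dye"` or `"c_m"`.
#' @return An `optical_image` tibble usable with [contrast_at_targets()]
#'   and [autoplot()].
#' @export
unmix_image <- function(maps, quantity = "r_dye") {
  stopifnot(inherits(maps, "unmix_maps"), quantity %in% names(maps))
  img <- tibble(row = maps$row, col = maps$col, x = maps$x, y = maps$y,
                value = maps[[quantity]]) %>%
    arrange(.data$row, .data$col)
  new_optical_image(img, metric = quantity, wavelength = NULL,
                    spacing = attr(maps, "spacing"))
}
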