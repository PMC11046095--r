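# Chebyshev least-squares fitting on an affinely rescaled domain.
#
# High-order polynomial fits (order 12 over a 140 nm window at wavelengths
# near 800 nm) are numerically singular in the raw monomial basis; all
# polynomial fitting in the package therefore maps the window to [-1, 1]
# and works in the Chebyshev basis, where the design matrix is
# well-conditioned at the orders used here (8 and 12).

cheb_design <- function(u, order) {
  n <- length(u)
  T <- matrix(0, n, order + 1L)
  T[, 1L] <- 1
  if (order >= 1L) T[, 2L] <- u
  if (order >= 2L) {
    for (k in 3:(order + 1L)) T[, k] <- 2 * u * T[, k - 1L] - T[, k - 2L]
  }
  T
}

# dT_k/du = k * U_{k-1}(u), with U the second-kind Chebyshev polynomials
cheb_design_deriv <- function(u, order) {
  n <- length(u)
  D <- matrix(0, n, order + 1L)
  if (order < 1L) return(D)
  U <- matrix(0, n, order) # U_0 .. U_{order-1}
  U[, 1L] <- 1
  if (order >= 2L) U[, 2L] <- 2 * u
  if (order >= 3L) {
    for (k in 3:order) U[, k] <- 2 * u * U[, k - 1L] - U[, k - 2L]
  }
  for (k in 1:order) D[, k + 1L] <- k * U[, k]
  D
}

to_unit <- function(x, window) 2 * (x - window[1]) / (window[2] - window[1]) - 1

fit_cheb <- function(x, y, order, window = range(x)) {
  inside <- x >= window[1] & x <= window[2]
  x <- x[inside]; y <- y[inside]
  if (length(x) <= order) {
    abort(sprintf("need more than %d points inside [%g, %g] for an order-%d fit",
                  order, window[1], window[2], order))
  }
  u <- to_unit(x, window)
  X <- cheb_design(u, order)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) abort("rank-deficient polynomial design")
  cf <- qr.coef(qrX, y)
  res <- y - drop(X %*% cf)
  list(coef = unname(cf), order = order, window = window,
       rms = sqrt(mean(res^2)), n = length(x))
}

eval_cheb <- function(fit, x) {
  check_window(x, fit$window)
  drop(cheb_design(to_unit(x, fit$window), fit$order) %*% fit$coef)
}

eval_cheb_deriv <- function(fit, x) {
  check_window(x, fit$window)
  scale <- 2 / (fit$window[2] - fit$window[1])
  drop(cheb_design_deriv(to_unit(x, fit$window), fit$order) %*% fit$coef) * scale
}

check_window <- function(x, window) {
  if (any(x < window[1] - 1e-9 | x > window[2] + 1e-9)) {
    abort(sprintf("wavelength outside the fit window [%g, %g] nm",
                  window[1], window[2]))
  }
  invisible(x)
}
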