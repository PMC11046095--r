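test_that("two-wavelength unmixing equals the closed-form 2x2 solution", {
  dye <- default_dye_model(); mel <- melanin_model()
  wl <- c(760, 800); d <- 20; beta <- 6
  truth <- c(r_dye = 1.0, c_m = 0.02)
  M <- d * beta * cbind(dye_gradient(dye, wl), melanin_gradient(mel, wl))
  g <- drop(M %*% truth)
  fit <- solve_unmix_linear(tibble::tibble(wavelength = wl, gradient = g),
                            d = d, beta = beta, dye = dye, melanin = mel)
  expect_equal(fit$r_dye, 1.0, tolerance = 1e-10)
  expect_equal(fit$c_m, 0.02, tolerance = 1e-10)
  # independent oracle: solve() on the same 2x2 system
  oracle <- solve(M, g)
  expect_equal(c(fit$r_dye, fit$c_m), unname(oracle), tolerance = 1e-12)

  zero <- solve_unmix_linear(tibble::tibble(wavelength = wl, gradient = c(0, 0)),
                             d = d, beta = beta, dye = dye, melanin = mel)
  expect_equal(c(zero$r_dye, zero$c_m), c(0, 0))
  expect_error(solve_unmix_linear(tibble::tibble(wavelength = 760, gradient = 1)),
               "2 wavelengths")
})

test_that("overdetermined noisy unmixing is unbiased", {
  dye <- default_dye_model(); mel <- melanin_model()
  wl <- c(710, 740, 760, 790, 820); d <- 20; beta <- 6
  g0 <- d * beta * (1.0 * dye_gradient(dye, wl) +
                      0.02 * melanin_gradient(mel, wl))
  est <- withr::with_seed(31, {
    purrr::map_dbl(1:200, function(i) {
      g <- g0 * (1 + rnorm(length(wl), sd = 0.01))
      solve_unmix_linear(tibble::tibble(wavelength = wl, gradient = g),
                         d = d, beta = beta, dye = dye, melanin = mel)$r_dye
    })
  })
  expect_lt(abs(mean(est) - 1.0), 2 * sd(est) / sqrt(length(est)))
})

test_that("rank-deficient designs are flagged, not fatal", {
  dye <- default_dye_model(); mel <- melanin_model()
  # duplicated wavelength makes a 2x2 design of rank 1
  wl <- c(760, 760)
  g <- tibble::tibble(wavelength = wl, gradient = c(0.01, 0.01))
  fit <- suppressWarnings(
    solve_unmix_linear(g, d = 20, beta = 6, dye = dye, melanin = mel))
  expect_true("rank_deficient" %in% fit$flags ||
                "ill_conditioned" %in% fit$flags)
  expect_true(is.finite(fit$r_dye))
})

test_that("scatter profile recovers self-consistent parameters", {
  dye <- default_dye_model(); mel <- melanin_model()
  wl <- c(710, 730, 756, 780, 808, 830); d <- 20; beta <- 6
  truth <- list(r_dye = 0.8, c_m = 0.004, alpha = 20, p = 1.4) # p on the grid
  g <- d * beta * (truth$r_dye * dye_gradient(dye, wl) +
                     truth$c_m * melanin_gradient(mel, wl)) -
    truth$alpha * wl^(-truth$p)
  fit <- solve_unmix_scatter(tibble::tibble(wavelength = wl, gradient = g),
                             d = d, beta = beta, dye = dye, melanin = mel)
  # residual at the true p is minimal over the whole profile
  res_true <- fit$profile$residual[abs(fit$profile$p - truth$p) < 1e-9]
  expect_lte(res_true, min(fit$profile$residual) + 1e-12)
  expect_equal(fit$p, truth$p)
  expect_equal(fit$r_dye, truth$r_dye, tolerance = 1e-6)
  expect_error(
    solve_unmix_scatter(tibble::tibble(wavelength = wl[1:3], gradient = g[1:3])),
    "4 wavelengths")
  expect_error(
    solve_unmix_scatter(tibble::tibble(wavelength = wl, gradient = g),
                        p_grid = numeric(0)), "empty")
})

test_that("the scatter solve nests the linear solve", {
  dye <- default_dye_model(); mel <- melanin_model()
  wl <- c(720, 750, 770, 790, 810, 835); d <- 20; beta <- 6
  g <- d * beta * (1.1 * dye_gradient(dye, wl) +
                     0.003 * melanin_gradient(mel, wl)) # alpha = 0 data
  lin <- solve_unmix_linear(tibble::tibble(wavelength = wl, gradient = g),
                            d = d, beta = beta, dye = dye, melanin = mel)
  sca <- solve_unmix_scatter(tibble::tibble(wavelength = wl, gradient = g),
                             d = d, beta = beta, dye = dye, melanin = mel)
  expect_equal(sca$r_dye, lin$r_dye, tolerance = 1e-8)
  expect_equal(sca$c_m, lin$c_m, tolerance = 1e-8)
})

test_that("unmixing is scale-equivariant", {
  dye <- default_dye_model(); mel <- melanin_model()
  wl <- c(710, 740, 770, 800, 830); d <- 20; beta <- 6
  g <- d * beta * (0.9 * dye_gradient(dye, wl) +
                     0.005 * melanin_gradient(mel, wl)) - 8 * wl^(-1.2)
  tb <- tibble::tibble(wavelength = wl, gradient = g)
  f1 <- solve_unmix_scatter(tb, d = d, beta = beta, dye = dye, melanin = mel)
  f2 <- solve_unmix_scatter(dplyr::mutate(tb, gradient = gradient * 3),
                            d = d, beta = beta, dye = dye, melanin = mel)
  expect_equal(f2$r_dye / f1$r_dye, 3, tolerance = 1e-8)
  expect_equal(f2$c_m / f1$c_m, 3, tolerance = 1e-8)
  expect_equal(f2$alpha / f1$alpha, 3, tolerance = 1e-8)
  expect_equal(f2$p, f1$p)
})

test_that("melanin and power-law scatter are nearly degenerate", {
  dye <- default_dye_model(); mel <- melanin_model()
  wl <- c(710, 730, 756, 780, 808, 830); d <- 20; beta <- 6
  g0 <- d * beta * 0.004 * melanin_gradient(mel, wl)

  # noise-free melanin-only data: every p on the grid explains the data
  # equally well (the profile carries no information about p)
  fit0 <- solve_unmix_scatter(tibble::tibble(wavelength = wl, gradient = g0),
                              d = d, beta = beta, dye = dye, melanin = mel)
  rel_spread <- (max(fit0$profile$residual) - min(fit0$profile$residual)) /
    sqrt(sum(g0^2))
  expect_lt(rel_spread, 1e-12)

  # under 1% noise the melanin/scatter split wanders: c_m variance far
  # above the scatter-free solve, and a substantial fraction of
  # replicates is flagged with unphysical negative c_m or alpha
  res <- withr::with_seed(42, {
    purrr::map(1:50, function(i) {
      g <- g0 * (1 + rnorm(6, sd = 0.01))
      tb <- tibble::tibble(wavelength = wl, gradient = g)
      s <- solve_unmix_scatter(tb, d = d, beta = beta, dye = dye, melanin = mel)
      l <- solve_unmix_linear(tb, d = d, beta = beta, dye = dye, melanin = mel)
      list(cm_s = s$c_m, cm_l = l$c_m,
           flagged = any(c("negative_c_m", "negative_alpha") %in% s$flags))
    })
  })
  cv_s <- sd(purrr::map_dbl(res, "cm_s")) / mean(purrr::map_dbl(res, "cm_s"))
  cv_l <- sd(purrr::map_dbl(res, "cm_l")) / mean(purrr::map_dbl(res, "cm_l"))
  expect_gt(cv_s, 5 * cv_l)
  expect_gt(mean(purrr::map_lgl(res, "flagged")), 0.1)
})

test_that("non-negativity switch clamps unphysical coefficients", {
  dye <- default_dye_model(); mel <- melanin_model()
  wl <- c(710, 730, 756, 780, 808, 830); d <- 20; beta <- 6
  # pure dye + *positive* lambda^-p contribution => unconstrained alpha < 0
  g <- d * beta * 1.0 * dye_gradient(dye, wl) + 10 * wl^(-1.0)
  fit <- solve_unmix_scatter(tibble::tibble(wavelength = wl, gradient = g),
                             d = d, beta = beta, dye = dye, melanin = mel)
  expect_true(any(c("negative_alpha", "negative_c_m") %in% fit$flags))
  nn <- solve_unmix_scatter(tibble::tibble(wavelength = wl, gradient = g),
                            d = d, beta = beta, dye = dye, melanin = mel,
                            nonneg = TRUE)
  expect_gte(nn$c_m, -1e-12)
  expect_gte(nn$alpha, -1e-12)
})

test_that("homogeneous fits recover concentrations", {
  dye <- default_dye_model(); mel <- melanin_model()
  wl <- c(710, 730, 756, 780, 808, 830)
  basis <- chromophore_basis(wl, dye, mel)

  # single absorber, no scatter, exact data -> exact recovery
  g1 <- tibble::tibble(wavelength = wl,
                       gradient = 20 * 6 * 0.7 * basis$d_dye)
  f1 <- solve_homogeneous(g1, basis[, c("wavelength", "d_dye")],
                          d = 20, beta = 6, scatter = FALSE)
  expect_equal(f1$concentrations$estimate, 0.7, tolerance = 1e-10)

  # permuting wavelength order changes nothing
  g2 <- tibble::tibble(wavelength = wl,
                       gradient = 20 * 6 * (basis$d_dye + 0.003 * basis$d_melanin) -
                         15 * wl^(-1.2))
  fa <- solve_homogeneous(g2, basis, d = 20, beta = 6)
  fb <- solve_homogeneous(g2[sample.int(6), ], basis, d = 20, beta = 6)
  expect_equal(fa$concentrations$estimate, fb$concentrations$estimate,
               tolerance = 1e-10)
  expect_equal(fa$p, fb$p)

  expect_error(solve_homogeneous(g2[1:3, ], basis, d = 20, beta = 6),
               "fewer wavelengths")
})

test_that("diffusion DPF has the expected closed form and limits", {
  # independent re-derivation of the closed form at one point
  mu_a <- 0.01; mu_s <- 1.0; d <- 20
  mueff <- sqrt(3 * mu_a * mu_s)
  oracle <- sqrt(3 * mu_s / mu_a) / 2 * (1 - 1 / (1 + d * mueff))
  expect_equal(dpf_diffusion(mu_a, mu_s, d), oracle)
  expect_gt(oracle, 6); expect_lt(oracle, 7)

  # strictly decreasing in mu_a
  mus <- 10^seq(-3, 0, length.out = 20)
  expect_true(all(diff(dpf_diffusion(mus, 1, 20)) < 0))

  # asymptotic sqrt(mus'/mua) scaling when d * mueff >> 1
  r <- dpf_diffusion(0.09, 4, 500) / dpf_diffusion(0.36, 4, 500)
  expect_equal(r, sqrt((4 / 0.09) / (4 / 0.36)), tolerance = 0.02)

  expect_error(dpf_diffusion(-1, 1, 20), "positive")
  # finite-thickness correction is small but present
  thick <- dpf_diffusion(0.01, 1, 20, thickness = 40)
  expect_lt(thick, dpf_diffusion(0.01, 1, 20))
  expect_gt(thick / dpf_diffusion(0.01, 1, 20), 0.95)
})

test_that("unmixing a quiet scan gives flat maps at the expected level", {
  proc <- quiet_processed()
  maps <- unmix_scan(proc)
  # background r_dye is constant up to the beta0/<beta> scale factor
  expect_lt(sd(maps$r_dye[maps$row >= 9]) / mean(maps$r_dye[maps$row >= 9]),
            0.01)
  scale <- quiet_scan()$scene$beta0 / attr(maps, "beta")
  expect_equal(median(maps$r_dye), scale, tolerance = 0.05)
  # c_m map is ~0 without hair
  expect_lt(max(abs(maps$c_m)), 1e-3)
  expect_error(unmix_scan(proc, wavelengths = 760), "2 wavelengths")
  expect_error(unmix_scan(proc, wavelengths = c(760, 810)), "810")
})

test_that("coupling-only hair cannot enter the melanin map", {
  scan <- quiet_scan()
  k <- grid_positions(scan$protocol)
  k$k <- withr::with_seed(8, runif(nrow(k), 0.2, 1))
  maps <- unmix_scan(process_scan(apply_coupling(scan, k)))
  expect_lt(max(abs(maps$c_m)), 1e-3)
})

test_that("hair-layer scans unmix into melanin and dye maps", {
  scan <- hairy_scan()
  maps <- unmix_scan(hairy_processed())
  hair <- dplyr::arrange(tibble::as_tibble(scan$hair), row, col)
  expect_gt(cor(maps$c_m, hair$c_hair), 0.8)
  # the dye map shows far less background variation than the raw
  # gradient image (relative to their means)
  g <- assemble_image(hairy_processed(), "gradient", 760)
  ct_g <- contrast_at_targets(g, scan$scene)
  ct_r <- contrast_at_targets(unmix_image(maps, "r_dye"), scan$scene)
  rel_g <- attr(ct_g, "background_sd") / abs(attr(ct_g, "background_mean"))
  rel_r <- attr(ct_r, "background_sd") / abs(attr(ct_r, "background_mean"))
  expect_lt(rel_r, rel_g / 10)
})

test_that("tidy methods summarise unmixing fits", {
  dye <- default_dye_model(); mel <- melanin_model()
  wl <- c(760, 800)
  g <- tibble::tibble(wavelength = wl,
                      gradient = 20 * 6 * dye_gradient(dye, wl))
  fit <- solve_unmix_linear(g, d = 20, beta = 6, dye = dye, melanin = mel)
  td <- tidy(fit)
  expect_equal(td$term, c("r_dye", "c_m"))
  expect_equal(glance(fit)$method, "linear")
})
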