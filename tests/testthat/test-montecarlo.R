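test_that("geometry and scattering models validate their inputs", {
  expect_error(slab_geometry(sphere_depth = 2), "inside the slab")
  expect_error(scatter_model(mus = -1), "positive")
  expect_error(scatter_model(g = 1), "in \\(-1, 1\\)")
  sc <- scatter_model()
  expect_equal(sc$mus_p, 0.5)
  scw <- scatter_model(power = 1.2)
  expect_equal(mus_at(scw, 800), 10)
  expect_equal(mus_at(scw, 700), 10 * (700 / 800)^(-1.2))
})

test_that("elementary samplers match their distributions", {
  steps <- withr::with_seed(1, sample_steps(1e6, mus = 10))
  expect_lt(abs(mean(steps) - 0.1), 3 * sd(steps) / sqrt(length(steps)))
  cosines <- withr::with_seed(2, sample_hg(1e6, g = 0.95))
  expect_true(all(cosines >= -1 & cosines <= 1))
  expect_lt(abs(mean(cosines) - 0.95), 3 * sd(cosines) / sqrt(length(cosines)))
  # isotropic limit
  iso <- withr::with_seed(3, sample_hg(1e5, g = 0))
  expect_lt(abs(mean(iso)), 3 * sd(iso) / sqrt(length(iso)))
})

test_that("path ensembles are reproducible and geometrically sane", {
  p1 <- mc_paths()
  p2 <- simulate_paths(slab_geometry(), scatter_model(), n_photons = 2e5,
                       seed = 42)
  expect_identical(p1$L_out, p2$L_out)
  expect_identical(p1$L_in, p2$L_in)
  expect_gt(p1$n_detected, 50)
  expect_true(all(p1$L_out >= 0) && all(p1$L_in >= 0))
  # detected paths at least span source to detector disc edge
  expect_true(all(p1$L_out + p1$L_in >=
                    p1$separation - 2 * p1$geometry$detector_radius))
  # a sphere far outside the sensitive region is never touched
  geom_far <- slab_geometry(slab_dim = c(300, 300, 25), sphere_depth = 12)
  geom_far$sphere_center <- c(140, 140, 12)
  refar <- simulate_paths(geom_far, scatter_model(), n_photons = 2e4, seed = 9)
  expect_true(all(refar$L_in == 0))
})

test_that("replay reproduces the homogeneous limits", {
  paths <- mc_paths()
  r1 <- replay(paths, 0.0102, F = 1)
  # F = 1 collapses to a homogeneous slab: same as weighting total path
  w <- exp(-0.0102 * (paths$L_out + paths$L_in))
  expect_equal(r1$A, -log(sum(w) / paths$n_injected), tolerance = 1e-12)
  # mu_a -> 0: A -> -ln(detected fraction), independent of F
  a0 <- replay(paths, 1e-12, F = 1)$A
  a0_inf <- replay(paths, 1e-12, F = 50)$A
  expect_equal(a0, -log(paths$n_detected / paths$n_injected), tolerance = 1e-6)
  expect_equal(a0, a0_inf, tolerance = 1e-6)
  expect_error(replay(paths, 0.01, F = 0.5), ">= 1")
})

test_that("attenuation is exactly monotone in F on a fixed ensemble", {
  paths <- mc_paths()
  Fs <- c(default_F_list(infinite = FALSE), Inf)
  A <- purrr::map_dbl(Fs, ~ replay(paths, 0.0102, .x)$A)
  expect_true(all(diff(A) > 0))
})

test_that("an opaque target shortens detected pathlengths", {
  paths <- mc_paths()
  sw <- mc_small_sweep()
  r1 <- replay(paths, 0.0102, 1)
  rInf <- replay(paths, 0.0102, Inf)
  expect_lt(rInf$beta, r1$beta)
  # significant at >= 3 bootstrap standard errors
  tab <- tibble::as_tibble(sw)
  row1 <- tab[tab$lambda == 760 & tab$F == 1, ]
  rowI <- tab[tab$lambda == 760 & is.infinite(tab$F), ]
  se <- sqrt(row1$se_beta^2 + rowI$se_beta^2)
  expect_gt(row1$beta - rowI$beta, 3 * se)
})

test_that("G is defined by the Beer-Lambert identity and tracks A", {
  sw <- mc_small_sweep()
  tab <- tibble::as_tibble(sw)
  mu <- dye_absorption(default_dye_model(), tab$lambda)
  expect_equal(tab$G, tab$A - mu * tab$beta * 20, tolerance = 1e-12)
  at760 <- tab[tab$lambda == 760 & is.finite(tab$F), ]
  expect_gt(cor(at760$G, at760$A), 0.9)
  # non-absorbing homogeneous medium: G = -ln(detected fraction)
  paths <- mc_paths()
  r <- replay(paths, 1e-12, 1)
  expect_equal(compute_G(r$A, r$beta, 1e-12, 20),
               -log(paths$n_detected / paths$n_injected), tolerance = 1e-6)
})

test_that("the sweep covers the prescribed grid and is smooth in lambda", {
  sw <- mc_small_sweep()
  expect_equal(length(unique(sw$lambda)), 19L)
  expect_equal(unique(sw$lambda), seq(650, 830, 10))
  Fs <- unique(sw$F)
  expect_equal(sum(is.finite(Fs)), 14L)
  expect_true(any(is.infinite(Fs)))
  # shared-path replay makes A continuous in mu_a(lambda)
  tab <- tibble::as_tibble(sw)
  for (Fv in c(1, 10)) {
    sub <- tab[tab$F == Fv, ]
    sub <- sub[order(sub$lambda), ]
    gap <- abs(diff(sub$A))
    se_pair <- sqrt(sub$se_A[-1]^2 + sub$se_A[-nrow(sub)]^2)
    expect_true(all(gap < 5 * pmax(se_pair, 1e-6) + 0.08))
  }
})

test_that("spectral derivative fits are exact on representable curves", {
  wl <- seq(650, 830, 10)
  u <- 2 * (wl - 650) / 180 - 1
  vals <- 2 - 0.3 * u + 0.8 * u^3 - 0.1 * u^6
  # analytic derivative with the chain rule du/dlambda = 2/180
  dv <- (-0.3 + 2.4 * u^2 - 0.6 * u^5) * (2 / 180)
  for (q in c(680, 760, 800)) {
    uu <- 2 * (q - 650) / 180 - 1
    expect_equal(
      fit_spectral_derivative(tibble::tibble(wavelength = wl, value = vals), q),
      (-0.3 + 2.4 * uu^2 - 0.6 * uu^5) * (2 / 180), tolerance = 1e-9)
  }
  expect_equal(
    fit_spectral_derivative(tibble::tibble(wavelength = wl, value = rep(4, 19)),
                            760), 0, tolerance = 1e-12)
  expect_error(
    fit_spectral_derivative(tibble::tibble(wavelength = wl, value = vals), 640),
    "window")
})

test_that("the homogeneous attenuation gradient decomposes term-wise", {
  sw <- mc_small_sweep()
  dA <- spectral_derivative(sw, "A", 760)
  dB <- spectral_derivative(sw, "beta", 760)
  dG <- spectral_derivative(sw, "G", 760)
  tab <- tibble::as_tibble(sw)
  f1 <- tab[tab$F == 1, ]
  fitb <- f1$beta[f1$lambda == 760]
  mu760 <- dye_absorption(default_dye_model(), 760)
  dmu760 <- dye_gradient(default_dye_model(), 760)
  lhs <- dA$derivative[dA$F == 1]
  rhs <- 20 * (fitb * dmu760 + mu760 * dB$derivative[dB$F == 1]) +
    dG$derivative[dG$F == 1]
  # identity A = mu*beta*d + G transfers to the fitted derivatives up to
  # the product-rule cross terms of separate polynomial fits
  expect_equal(lhs, rhs, tolerance = 0.05)
})

test_that("the gradient extremum sits at intermediate target absorption", {
  sw <- mc_small_sweep()
  ex760 <- find_extremum_F(spectral_derivative(sw, "A", 760))
  expect_equal(ex760$type, "max")
  expect_false(ex760$boundary)
  expect_gt(ex760$F_star, 5); expect_lt(ex760$F_star, 20)
  ex800 <- find_extremum_F(spectral_derivative(sw, "A", 800))
  expect_equal(ex800$type, "min")
  expect_gt(ex800$F_star, 5); expect_lt(ex800$F_star, 20)
  # the F = infinity gradient keeps the F = 1 sign with smaller magnitude
  d760 <- spectral_derivative(sw, "A", 760)
  v1 <- d760$derivative[d760$F == 1]
  vI <- d760$derivative[is.infinite(d760$F)]
  expect_equal(sign(vI), sign(v1))
  expect_lt(abs(vI), abs(v1))
})

test_that("find_extremum_F interpolates exactly and flags boundaries", {
  Fs <- c(2, 4, 8, 10, 12.5, 25, 50)
  vals <- -(log(Fs) - log(10))^2 # exact parabola in log F, vertex at 10
  ex <- find_extremum_F(tibble::tibble(F = Fs, derivative = vals))
  expect_equal(ex$F_star, 10, tolerance = 1e-9)
  mono <- find_extremum_F(tibble::tibble(F = Fs, derivative = log(Fs)),
                          type = "max")
  expect_true(mono$boundary)
  expect_equal(mono$F_star, 50)
  expect_error(find_extremum_F(tibble::tibble(F = 1:3, derivative = 1:3)),
               "5 finite")
})

test_that("bootstrap intervals cover the extremum estimate", {
  sw <- mc_small_sweep()
  ci <- extremum_interval(sw, 760)
  expect_true(ci$lower <= ci$F_star && ci$F_star <= ci$upper)
  expect_equal(ci$type, "max")
})

test_that("power-law scattering runs per-wavelength ensembles that match
           the constant run at the reference wavelength", {
  n <- 2e4
  const <- mc_sweep(scatter = scatter_model(power = 0), n_photons = n,
                    seed = 17, n_boot = 5, share_paths = FALSE,
                    lambdas = seq(750, 830, 10))
  wdep <- mc_sweep(scatter = scatter_model(power = 1.2), n_photons = n,
                   seed = 17, n_boot = 5, lambdas = seq(750, 830, 10))
  expect_false(attr(wdep, "shared_paths"))
  # mus(800) is the reference: with matched seeds the two runs use
  # identical path ensembles there, and only there
  tc <- tibble::as_tibble(const); tw <- tibble::as_tibble(wdep)
  expect_identical(tw$A[tw$lambda == 800], tc$A[tc$lambda == 800])
  expect_identical(tw$beta[tw$lambda == 800], tc$beta[tc$lambda == 800])
  expect_false(isTRUE(all.equal(tw$A[tw$lambda == 750],
                                tc$A[tc$lambda == 750])))
  # shorter wavelengths scatter more under the power law
  expect_true(all(diff(mus_at(scatter_model(power = 1.2),
                              seq(650, 830, 10))) < 0))
  expect_error(mc_sweep(scatter = scatter_model(power = 1.2),
                        share_paths = TRUE), "cannot be shared")
})
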