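test_that("the reference scene matches the phantom layout", {
  scene <- build_phantom_scene()
  expect_equal(nrow(scene$targets), 8L)
  expect_setequal(unique(scene$targets$depth), c(15, 25))
  expect_setequal(unique(scene$targets$factor), c(5, 10, 20, 50))
  expect_equal(unname(scene$block_dim), c(190, 130, 40))
  expect_true(all(target_inside_block(scene)))
  expect_error(build_phantom_scene(beta0 = 6, beta1 = 5), "beta0 < beta1")
})

test_that("hair fields are reproducible and respect their parameters", {
  protocol <- scan_protocol()
  bare <- sample_hair_field(protocol, c_hair_mean = 0, c_hair_sd = 0,
                            coupling_mean = 0, coupling_sd = 0, seed = 1)
  expect_true(all(bare$c_hair == 0))
  expect_true(all(bare$k == 1))

  h1 <- sample_hair_field(protocol, seed = 33)
  h2 <- sample_hair_field(protocol, seed = 33)
  expect_identical(h1$c_hair, h2$c_hair)
  expect_identical(h1$k, h2$k)
  expect_true(all(h1$c_hair >= 0))
  expect_true(all(h1$k > 0 & h1$k <= 1))

  # field mean consistent with the configured mean (3 standard errors,
  # accounting for spatial correlation)
  se <- sqrt(hair_field_mean_variance(protocol, c_hair_sd = 0.012,
                                      correlation_length = 20))
  expect_lt(abs(mean(h1$c_hair) - 0.03), 3 * se)
})

test_that("source spectra are smooth, positive and polynomial-representable", {
  wl <- seq(650, 850, 1)
  s1 <- generate_source_spectrum(wl, seed = 4)
  s2 <- generate_source_spectrum(wl, seed = 4)
  expect_identical(s1, s2)
  expect_true(all(s1$intensity > 0))
  fit <- fit_log_poly(s1)
  expect_lt(fit$rms, 1e-9)
})

test_that("forward model recovers the homogeneous law far from targets", {
  scene <- build_phantom_scene()
  src <- generate_source_spectrum(seq(650, 850, 1), seed = 2)
  sp <- forward_intensity(scene, c(-500, -500), src) # f underflows to 0
  A <- log(src$intensity / sp$intensity)
  expected <- dye_absorption(scene$dye, src$wavelength) * scene$beta0 * 20 +
    scene$G0
  expect_equal(A, expected, tolerance = 1e-12)
})

test_that("infinite target absorption leaves only the background branch", {
  scene <- build_phantom_scene()
  scene$targets$factor <- rep(1e12, 8)
  src <- generate_source_spectrum(seq(650, 850, 1), seed = 2)
  over <- scene$targets[1, ] # directly over a shallow target: f = f_ref
  sp <- forward_intensity(scene, c(over$x, over$y), src)
  f <- scene$f_ref
  expected <- src$intensity * exp(-scene$G0) * (1 - f) *
    exp(-dye_absorption(scene$dye, src$wavelength) * scene$beta0 * 20)
  expect_equal(sp$intensity, expected, tolerance = 1e-12)
})

test_that("gradient over a target has an interior maximum in F", {
  # sweep the target absorption factor at fixed interaction fraction
  src <- generate_source_spectrum(seq(650, 850, 1), seed = 2)
  src_fit <- fit_log_poly(src)
  g760 <- purrr::map_dbl(c(1, 2, 5, 10, 20, 35, 50), function(Fv) {
    scene <- build_phantom_scene()
    scene$targets$factor <- rep(Fv, 8)
    sp <- forward_intensity(scene, c(20, 30), src) # over target 1, f = 0.3
    gradient_at(fit_log_poly(sp), src_fit, 760)
  })
  i <- which.max(g760)
  expect_gt(i, 1L)
  expect_lt(i, length(g760))
})

test_that("scans are complete, deterministic and noise-calibrated", {
  scan <- hairy_scan()
  expect_equal(nrow(scan$data), 150 * length(scan$protocol$wavelengths))
  expect_equal(nrow(dplyr::distinct(scan$data, row, col)), 150L)
  expect_true(all(scan$data$intensity >= 0))

  again <- generate_scan(scan$scene, scan$protocol, hair = scan$hair,
                         seed = scan$seed)
  expect_identical(scan$data, again$data)
  expect_identical(scan$source, again$source)
})

test_that("noise-free scans round-trip through the pipeline exactly", {
  scan <- quiet_scan()
  pos <- scan$data[scan$data$row == 1 & scan$data$col == 1, ]
  pre <- preprocess(tibble::tibble(wavelength = pos$wavelength,
                                   intensity = pos$intensity),
                    scan$dark)
  clean <- forward_intensity(scan$scene, c(pos$x[1], pos$y[1]), scan$source)
  expect_equal(pre$intensity, clean$intensity, tolerance = 1e-10)
  # pointwise attenuation equals the forward model's attenuation
  A_pt <- log(scan$source$intensity / pre$intensity)
  A_fwd <- log(scan$source$intensity / clean$intensity)
  expect_equal(A_pt, A_fwd, tolerance = 1e-10)
})

test_that("repeated noisy acquisitions spread below the calibrated limits", {
  scene <- build_phantom_scene()
  protocol <- scan_protocol()
  src <- generate_source_spectrum(protocol$wavelengths, seed = 1)
  src_fit <- fit_log_poly(src)
  nl <- length(protocol$wavelengths)
  clean <- forward_intensity(scene, c(70, 10), src)
  res <- withr::with_seed(99, {
    purrr::map(1:40, function(i) {
      meas <- tibble::tibble(
        wavelength = clean$wavelength,
        intensity = clean$intensity * (1 + rnorm(nl, sd = protocol$noise_sd)) +
          protocol$dark_level + rnorm(nl, sd = protocol$dark_sd))
      pre <- preprocess(meas, tibble::tibble(wavelength = clean$wavelength,
                                             intensity = rep(protocol$dark_level, nl)),
                        dark_sd = protocol$dark_sd)
      fit <- fit_log_poly(pre)
      c(A = attenuation_at(fit, src_fit, 760),
        g = gradient_at(fit, src_fit, 760))
    })
  })
  A <- purrr::map_dbl(res, "A"); g <- purrr::map_dbl(res, "g")
  expect_lt(sd(A), 0.01)
  expect_lt(sd(g), 1e-4)
})

test_that("coupling factors are validated", {
  scan <- quiet_scan()
  expect_error(apply_coupling(scan, 0), "in \\(0, 1\\]")
  expect_error(apply_coupling(scan, 1.2), "in \\(0, 1\\]")
  same <- apply_coupling(scan, 1)
  expect_equal(same$data$intensity, scan$data$intensity)
})
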