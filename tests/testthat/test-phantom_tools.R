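test_that("FWHM matches closed forms for rectangle, triangle and Gaussian profiles", {
  # rectangle of width w samples
  rect <- c(0, 0, 1, 1, 1, 1, 0, 0)
  expect_equal(fwhm(rect)$fwhm, 4)
  expect_equal(fwhm(rect, spacing = 0.1)$fwhm, 0.4)
  # triangle of base b: half-max width is b / 2
  tri <- c(0, 1, 2, 3, 4, 3, 2, 1, 0)
  expect_equal(fwhm(tri)$fwhm, 4)
  # Gaussian: 2*sqrt(2*log(2)) * sigma within one grid spacing
  x <- 0:400
  for (s in c(2, 5, 10, 20)) {
    prof <- exp(-(x - 200)^2 / (2 * s^2))
    expect_lt(abs(fwhm(prof)$fwhm - 2 * sqrt(2 * log(2)) * s), 1)
  }
  expect_equal(fwhm(exp(-(x - 200)^2 / 50))$peak_position, 200)
})

test_that("degenerate FWHM inputs are rejected with the offending side named", {
  expect_error(fwhm(c(0.6, 0.8, 1, 0.7, 0.2)), "left")
  expect_error(fwhm(c(0.2, 0.7, 1, 0.8, 0.6)), "right")
  expect_error(fwhm(c(0, 1, 0, 0, 1, 0)), "not connected")
})

test_that("Gaussian convolution never decreases FWHM", {
  x <- 0:300
  base <- exp(-(x - 150)^2 / (2 * 4^2)) + 0.4 * exp(-(x - 165)^2 / (2 * 3^2))
  conv_with <- function(p, s) {
    k <- dnorm(-40:40, sd = s); k <- k / sum(k)
    as.numeric(stats::filter(c(rep(0, 40), p, rep(0, 40)), k, sides = 2))[41:341]
  }
  f0 <- fwhm(base)$fwhm
  prev <- f0
  for (s in c(1, 3, 6, 12)) {
    f <- fwhm(conv_with(base, s))$fwhm
    expect_gte(f, prev - 1e-9)
    prev <- f
  }
  expect_gt(prev, f0)
})

test_that("perpendicular averaging reduces residual noise like 1/sqrt(N)", {
  resid_sd <- function(nrows, seed) {
    tp <- tube_phantom_spec(depth_blur_sigma = 1.5, noise_sd = 0.05,
                            image_shape = c(nrows + 4L, 81L), seed = seed)
    img <- generate_tube_image(tp)
    line <- line_spec(c(3, 41), c(nrows + 2, 41), width = 41L, pixel_pitch = 0.1)
    tp0 <- tube_phantom_spec(depth_blur_sigma = 1.5, noise_sd = 0,
                             image_shape = c(nrows + 4L, 81L))
    clean <- mean_perpendicular_profile(generate_tube_image(tp0),
                                        line)$profile
    noisy <- mean_perpendicular_profile(img, line)$profile
    sd(noisy - clean)
  }
  s_few <- mean(vapply(1:6, function(k) resid_sd(4L, k), numeric(1)))
  s_many <- mean(vapply(1:6, function(k) resid_sd(64L, k), numeric(1)))
  expect_equal(s_few / s_many, sqrt(64 / 4), tolerance = 0.35)
})

test_that("filter trade-off reports percentage FWHM change between configurations", {
  expect_equal(filter_tradeoff(c(10, 20), c(10, 20))$mean_change, 0)
  expect_equal(filter_tradeoff(c(10, 20), c(11, 22))$mean_change, 10)
  # blur sigmas sigma vs 1.07 sigma give ~ +7% for Gaussian-dominated profiles
  x <- 0:400
  f_at <- function(s) fwhm(exp(-(x - 200)^2 / (2 * s^2)))$fwhm
  sig <- c(6, 10, 14)
  tr <- filter_tradeoff(vapply(sig, f_at, numeric(1)),
                        vapply(1.07 * sig, f_at, numeric(1)),
                        depths = c(0, 1, 3))
  expect_equal(tr$mean_change, 7, tolerance = 0.5)
  expect_named(tr$per_depth, c("0", "1", "3"))
  expect_error(filter_tradeoff(c(1, 2), c(1, 2, 3)), "matched")
})

test_that("the sensitivity series applies the strict monotone 3-sigma cut", {
  ctrl <- roi_stats_summary(0, 1)
  stats_at <- function(k) roi_stats_summary(k)  # excess = k * sigma
  # all wells identical to control: none detectable
  res0 <- sensitivity_series(c(1, 2), list(roi_stats_summary(0), roi_stats_summary(0)), ctrl)
  expect_true(is.na(res0$limit))
  # excess {1,2,4,8} sigma: 4 sigma (12.04 dB) is the first detectable
  res <- sensitivity_series(c(1, 2, 4, 8), lapply(c(1, 2, 4, 8), stats_at), ctrl)
  expect_equal(res$limit, 4)
  expect_equal(unname(res$snr_db), 20 * log10(c(1, 2, 4, 8)))
  # a single well just above 3 sigma is detectable
  res1 <- sensitivity_series(1, list(stats_at(3.001)), ctrl)
  expect_equal(res1$limit, 1)
  # raising every well's signal never raises the limit
  res_up <- sensitivity_series(c(1, 2, 4, 8), lapply(2 * c(1, 2, 4, 8), stats_at), ctrl)
  expect_lte(res_up$limit, res$limit)
  # a spurious low pass below non-detectable wells is not a limit
  res_sp <- sensitivity_series(c(1, 2, 4), lapply(c(4, 1, 4), stats_at), ctrl)
  expect_equal(res_sp$limit, 4)
})

test_that("black-body spectra satisfy Planck limits, linearity and Wien's law", {
  wl <- seq(300, 3000, 2)
  for (T in c(2800, 3200, 5800)) {
    bb <- blackbody(wl, T)
    expect_lt(abs(wl[which.max(bb$values)] - 2.8977719e6 / T), 2)
  }
  bb1 <- blackbody(wl, 3200); bb2 <- blackbody(wl, 3200, scale = 2)
  expect_equal(bb2$values, 2 * bb1$values)
  expect_lt(blackbody(c(1, 2, 3), 3200)$values[1], 1e-100)  # -> 0 as lambda -> 0
  expect_error(blackbody(wl, -10), "> 0 K")
})

test_that("fit_blackbody recovers temperature and scale in closed loop", {
  wl <- seq(350, 2500, 5)
  truth <- blackbody(wl, 3200, scale = 5)
  fit <- fit_blackbody(truth)
  expect_lt(abs(fit$temperature - 3200), 1)
  expect_lt(abs(fit$scale - 5) / 5, 0.001)
  # 1% multiplicative noise: temperature within 2%
  noisy <- generate_lamp_spectrum(3200, 1, wl, relative_noise_sd = 0.01,
                                  scale = 5, seed = 30L)
  fit_n <- fit_blackbody(noisy)
  expect_lt(abs(fit_n$temperature - 3200) / 3200, 0.02)
  # flat spectrum has no Planck shape
  expect_error(fit_blackbody(spectrum(wl, rep(1, length(wl)))), "converge")
})

test_that("spectral correction recovers the detector response in closed loop", {
  wl <- seq(900, 1700, 4)
  response <- 1 + 0.3 * exp(-((wl - 1300) / 120)^2)
  recorded <- generate_lamp_spectrum(3200, response, wl)
  cal_file <- blackbody(wl, 3200)          # the lamp's calibration spectrum
  fit <- fit_blackbody(cal_file)
  corr <- spectral_correction(recorded, fit)
  # applying the correction to the recorded lamp returns the fitted curve
  expect_equal(apply_correction(recorded, corr)$values, fit$fitted$values,
               tolerance = 1e-9)
  # the correction is 1/response up to the fitted scale
  resp_hat <- 1 / corr$values
  ratio <- resp_hat / response
  expect_lt(sd(ratio) / mean(ratio), 1e-6)
  # lamp already equal to its fit: correction is exactly 1
  corr1 <- spectral_correction(fit$fitted, fit)
  expect_equal(corr1$values, rep(1, length(wl)), tolerance = 1e-9)
  expect_error(spectral_correction(spectrum(wl, rep(0, length(wl))), fit),
               "positive")
})
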