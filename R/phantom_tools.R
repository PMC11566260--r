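#' Mean cross-section profile perpendicular to a tube phantom
#'
#' Averages the perpendicular cross-sections along a straight fluorescent
#' ridge (the dye-filled tube) and normalizes the averaged profile to its own
#' maximum, so profiles from different filters/depths are comparable and
#' feed directly into [fwhm()].
#'
#' @param image [modality_image()] or matrix.
#' @param axis_line a [line_spec()] running along the ridge; its `width`
#'   sets the perpendicular extent of the profile.
#' @return list with `offsets_mm` (signed perpendicular position),
#'   `profile` (peak-normalized mean cross-section) and `spacing` (mm).
#' @export
mean_perpendicular_profile <- function(image, axis_line) {
  sub <- extract_subimage(image, axis_line)
  prof <- rowMeans(sub)
  mx <- max(prof)
  if (mx <= 0) stop("profile maximum is not positive (all-zero image?)")
  h <- (axis_line$width - 1L) / 2L
  list(offsets_mm = (-h:h) * axis_line$pixel_pitch,
       profile = prof / mx,
       spacing = axis_line$pixel_pitch)
}

#' Full width at half maximum of a 1-D profile
#'
#' Half-maximum crossings on either side of the (unique, connected) peak
#' region are located by linear interpolation between the bracketing
#' samples. The baseline is assumed near zero (profiles are peak-normalized
#' background-subtracted intensities), so half maximum is `max / 2`.
#' Profiles whose above-half-max samples are not contiguous (multimodal) are
#' rejected rather than guessed at.
#'
#' @param profile numeric vector of intensities.
#' @param spacing physical distance between samples (mm; 1 = pixel units).
#' @return an `fwhm_result`: list with `fwhm`, `peak_position`, `peak_value`
#'   (positions measured from the first sample).
#' @export
fwhm <- function(profile, spacing = 1) {
  n <- length(profile)
  if (n < 3L) stop("profile too short")
  peak <- max(profile)
  half <- peak / 2
  above <- which(profile > half)
  if (length(above) == 0L) stop("profile never exceeds half maximum")
  if (any(diff(above) != 1L))
    stop("above-half-maximum region is not connected (multimodal profile)")
  i_l <- above[1]; i_r <- above[length(above)]
  if (i_l == 1L)
    stop("profile does not fall below half maximum on the left side")
  if (i_r == n)
    stop("profile does not fall below half maximum on the right side")
  x_left <- (i_l - 1) + (half - profile[i_l - 1]) / (profile[i_l] - profile[i_l - 1])
  x_right <- i_r + (half - profile[i_r]) / (profile[i_r + 1] - profile[i_r])
  structure(list(fwhm = (x_right - x_left) * spacing,
                 peak_position = (which.max(profile) - 1) * spacing,
                 peak_value = peak),
            class = "fwhm_result")
}

#' FWHM trade-off between two filter configurations
#'
#' Percentage change in FWHM of configuration B relative to configuration A
#' at matched depths, used to pick the filter that best balances resolution
#' against noise (e.g. a long-pass filter accepted at the cost of a small
#' average FWHM increase).
#'
#' @param fwhm_a,fwhm_b equal-length numeric vectors of FWHM values (or
#'   lists of [fwhm()] results) at matched depth conditions.
#' @param depths optional labels for the matched conditions.
#' @return list with `per_depth` (percent change per condition) and
#'   `mean_change` (average percent change).
#' @export
filter_tradeoff <- function(fwhm_a, fwhm_b, depths = seq_along(fwhm_a)) {
  to_num <- function(x) {
    if (is.list(x)) vapply(x, function(e) e$fwhm, numeric(1)) else as.numeric(x)
  }
  a <- to_num(fwhm_a); b <- to_num(fwhm_b)
  if (length(a) != length(b) || length(a) != length(depths))
    stop("configurations must cover the same matched depth conditions")
  pc <- 100 * (b - a) / a
  list(per_depth = stats::setNames(pc, depths), mean_change = mean(pc))
}

#' Lowest detectable concentration of a liquid-phantom dilution series
#'
#' Computes the SNR in dB of every well against the zero-concentration
#' control ([snr_db()]) and applies the strict 3-sigma (> 9.5 dB)
#' detectability rule. The reported limit is the smallest concentration that
#' is detectable together with every larger concentration (a monotone cut:
#' an isolated spurious pass below non-detectable wells is not a limit).
#'
#' @param concentrations increasing numeric vector of dye concentrations.
#' @param well_stats list of [roi_stats()] for each well, same order.
#' @param control [roi_stats()] of the zero-concentration control well.
#' @return list with `limit` (concentration, or `NA` if none detectable),
#'   `snr_db` and `detectable` per well.
#' @export
sensitivity_series <- function(concentrations, well_stats, control) {
  if (length(concentrations) != length(well_stats))
    stop("one RoiStats per concentration is required")
  if (length(concentrations) == 0L) stop("empty concentration series")
  if (is.unsorted(concentrations)) {
    o <- order(concentrations)
    concentrations <- concentrations[o]
    well_stats <- well_stats[o]
  }
  snr <- vapply(well_stats, snr_db, numeric(1), control = control)
  det <- is_detectable(snr)
  suffix_ok <- rev(cumprod(rev(det))) == 1
  limit <- if (any(suffix_ok)) concentrations[which(suffix_ok)[1]] else NA_real_
  list(limit = limit,
       snr_db = stats::setNames(snr, concentrations),
       detectable = stats::setNames(det, concentrations))
}

# Second radiation constant h*c/k_B in nm.K.
C2_NM_K <- 1.438776877e7

#' Black-body emission spectrum (wavelength form)
#'
#' Planck spectral radiance up to an arbitrary common scale:
#' `B(lambda, T) = scale / lambda^5 / (exp(c2 / (lambda T)) - 1)` with
#' `c2 = h c / k_B = 1.4388e7 nm K`.
#'
#' @param wavelengths strictly increasing grid in nm.
#' @param temperature black-body temperature in K (> 0).
#' @param scale arbitrary multiplicative factor.
#' @return a `spectrum` object: list with `wavelengths` (nm) and `values`.
#' @export
blackbody <- function(wavelengths, temperature, scale = 1) {
  if (temperature <= 0) stop("temperature must be > 0 K")
  spectrum(wavelengths, scale / wavelengths^5 / expm1(C2_NM_K / (wavelengths * temperature)))
}

#' @param values spectral values (a.u., >= 0) on the wavelength grid.
#' @rdname blackbody
#' @export
spectrum <- function(wavelengths, values) {
  wavelengths <- as.numeric(wavelengths); values <- as.numeric(values)
  if (length(wavelengths) != length(values)) stop("length mismatch")
  if (length(wavelengths) < 3L) stop("a spectrum needs at least 3 samples")
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  structure(list(wavelengths = wavelengths, values = values), class = "spectrum")
}

#' Fit a black-body curve to a measured lamp spectrum
#'
#' Least-squares fit of temperature and scale. The scale is solved in closed
#' form for any candidate temperature, leaving a one-dimensional profile
#' objective in T which is minimized by a coarse log-spaced grid followed by
#' golden-section refinement - deterministic, with no starting value to
#' supply. A fit is rejected (non-convergence error) when the optimum pins
#' to the search boundary or when the black-body shape explains less than
#' half of the spectral variance (e.g. a flat spectrum has no Planck shape).
#'
#' @param measured a [spectrum()] (>= 10 samples spanning the peak or its
#'   flank).
#' @param t_range search interval for the temperature in K.
#' @return list with `temperature` (K), `scale`, `fitted` (the fitted
#'   [blackbody()] spectrum on the same grid) and `r_squared`.
#' @export
fit_blackbody <- function(measured, t_range = c(300, 30000)) {
  lam <- measured$wavelengths
  m <- measured$values
  if (length(lam) < 10L) stop("at least 10 spectral samples are required")
  shape <- function(T) 1 / lam^5 / expm1(C2_NM_K / (lam * T))
  rss <- function(T) {
    b <- shape(T)
    s <- sum(m * b) / sum(b * b)
    sum((m - s * b)^2)
  }
  grid_t <- exp(seq(log(t_range[1]), log(t_range[2]), length.out = 200))
  i <- which.min(vapply(grid_t, rss, numeric(1)))
  lo <- grid_t[max(1L, i - 1L)]
  hi <- grid_t[min(length(grid_t), i + 1L)]
  opt <- stats::optimize(rss, interval = c(lo, hi), tol = 1e-6)
  T_hat <- opt$minimum
  if (T_hat < t_range[1] * 1.02 || T_hat > t_range[2] * 0.98)
    stop("black-body fit did not converge: optimum at the temperature search boundary")
  b <- shape(T_hat)
  s_hat <- sum(m * b) / sum(b * b)
  r2 <- 1 - opt$objective / sum((m - mean(m))^2)
  if (!is.finite(r2) || r2 < 0.5)
    stop("black-body fit did not converge: spectrum lacks a Planck-like shape (r^2 = ",
         signif(r2, 3), ")")
  list(temperature = T_hat, scale = s_hat,
       fitted = blackbody(lam, T_hat, s_hat), r_squared = r2)
}

#' Spectral-response correction from a calibrated lamp
#'
#' The recorded spectrum of a calibrated halogen lamp is the true (black
#' body-like) emission multiplied by the unknown spectral response of the
#' detection chain. Dividing the black-body fit of the lamp's calibration
#' file by the recorded spectrum yields a per-wavelength correction curve;
#' multiplying any raw spectrum by the correction removes the instrument
#' response.
#'
#' @param measured_lamp recorded lamp [spectrum()] (values > 0).
#' @param fitted a [fit_blackbody()] result or a [spectrum()] on the same
#'   wavelength grid.
#' @return the correction [spectrum()].
#' @export
spectral_correction <- function(measured_lamp, fitted) {
  fit_spec <- if (!is.null(fitted$fitted)) fitted$fitted else fitted
  if (!isTRUE(all.equal(measured_lamp$wavelengths, fit_spec$wavelengths)))
    stop("wavelength grids differ")
  if (any(measured_lamp$values <= 0))
    stop("recorded lamp spectrum must be strictly positive")
  spectrum(measured_lamp$wavelengths, fit_spec$values / measured_lamp$values)
}

#' @param raw a raw [spectrum()] to correct.
#' @param correction the correction [spectrum()] from [spectral_correction()].
#' @rdname spectral_correction
#' @export
apply_correction <- function(raw, correction) {
  if (!isTRUE(all.equal(raw$wavelengths, correction$wavelengths)))
    stop("wavelength grids differ")
  spectrum(raw$wavelengths, raw$values * correction$values)
}
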