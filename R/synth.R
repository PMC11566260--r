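#' Specify a synthetic paired-modality tissue-slice scene
#'
#' Ground-truth parameters for a pair of fluorescence images of the same
#' simulated tissue slice seen by two modalities (A plays the NIR role, B
#' the SWIR role). The scene is an elliptical "tumor" of elevated mean
#' intensity on a background, per-modality Gaussian PSF blur (stronger for
#' the shorter-wavelength modality A, emulating scattering), additive
#' Gaussian noise, an optional smooth additive autofluorescent background
#' for modality B (the failure mode seen in strongly autofluorescent
#' tissue), and a known similarity-transform misalignment applied to
#' modality B as the *last* synthesis step - so the true registration
#' transform is exactly `st_inverse(misalignment)` and registration has an
#' exact oracle.
#'
#' Default intensities mirror the magnitude of published clinical medians:
#' tumor/background mean ratios of 1.43 (A) and 1.25 (B), with noise SDs
#' chosen so the whole-slice aCNR is 0.60 (A) and 0.86 (B). Intensities are
#' kept inside `[0, 1]` so images round-trip through float TIFF unchanged.
#'
#' @param image_shape `(rows, cols)` in pixels.
#' @param pixel_pitch mm per pixel.
#' @param tumor_center,tumor_axes,tumor_angle ellipse center `(row, col)`,
#'   semi-axes in pixels, and orientation in radians.
#' @param tumor_mean_a,bg_mean_a,tumor_mean_b,bg_mean_b class mean
#'   intensities (a.u.).
#' @param noise_sd_a,noise_sd_b additive Gaussian noise SDs.
#' @param blur_sigma_a,blur_sigma_b Gaussian PSF SDs in pixels.
#' @param autofluor_amplitude_b SD of the smooth additive background field
#'   on modality B (0 = none).
#' @param autofluor_scale_px correlation length (blur sigma) of that field.
#' @param misalignment [similarity_transform()] mapping A-frame to B-frame
#'   coordinates.
#' @param seed integer seed; identical spec + seed gives bit-identical images.
#' @return a `slice_phantom_spec` object.
#' @export
slice_phantom_spec <- function(image_shape = c(200L, 200L),
                               pixel_pitch = 0.1,
                               tumor_center = c(100, 100),
                               tumor_axes = c(60, 52),
                               tumor_angle = 0.4,
                               tumor_mean_a = 0.143, bg_mean_a = 0.100,
                               tumor_mean_b = 0.125, bg_mean_b = 0.100,
                               noise_sd_a = 0.0358, noise_sd_b = 0.0145,
                               blur_sigma_a = 2, blur_sigma_b = 1,
                               autofluor_amplitude_b = 0,
                               autofluor_scale_px = 15,
                               misalignment = similarity_transform(
                                 scale = 1.02, rotation = 0.03,
                                 translation = c(3.5, -2.5)),
                               seed = 1L) {
  vals <- c(tumor_mean_a, bg_mean_a, tumor_mean_b, bg_mean_b,
            noise_sd_a, noise_sd_b, blur_sigma_a, blur_sigma_b,
            autofluor_amplitude_b)
  if (any(vals < 0)) stop("intensities, noise SDs and blur sigmas must be >= 0")
  if (any(tumor_axes <= 0)) stop("tumor ellipse axes must be > 0 (degenerate region)")
  r_max <- max(tumor_axes)
  if (tumor_center[1] - r_max < 1 || tumor_center[1] + r_max > image_shape[1] ||
      tumor_center[2] - r_max < 1 || tumor_center[2] + r_max > image_shape[2])
    stop("tumor region must lie fully inside the image")
  stopifnot(inherits(misalignment, "similarity_transform"))
  structure(list(image_shape = as.integer(image_shape), pixel_pitch = pixel_pitch,
                 tumor_center = tumor_center, tumor_axes = tumor_axes,
                 tumor_angle = tumor_angle,
                 tumor_mean_a = tumor_mean_a, bg_mean_a = bg_mean_a,
                 tumor_mean_b = tumor_mean_b, bg_mean_b = bg_mean_b,
                 noise_sd_a = noise_sd_a, noise_sd_b = noise_sd_b,
                 blur_sigma_a = blur_sigma_a, blur_sigma_b = blur_sigma_b,
                 autofluor_amplitude_b = autofluor_amplitude_b,
                 autofluor_scale_px = autofluor_scale_px,
                 misalignment = misalignment, seed = as.integer(seed)),
            class = "slice_phantom_spec")
}

# Margin (px) such that the B frame's pre-image under the misalignment lies
# inside the padded canvas.
scene_pad <- function(misalignment, shape) {
  Minv <- st_inverse(misalignment)
  corners <- rbind(c(1, 1), c(1, shape[2]), c(shape[1], 1), shape)
  src <- transform_points(Minv, corners)
  excess <- max(1 - src[, 1], src[, 1] - shape[1],
                1 - src[, 2], src[, 2] - shape[2], 0)
  as.integer(ceiling(excess) + 2L)
}

ellipse_mask <- function(shape, center, axes, angle) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2]) - center[1]
  c <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE) - center[2]
  x <- r * cos(angle) + c * sin(angle)
  y <- -r * sin(angle) + c * cos(angle)
  (x / axes[1])^2 + (y / axes[2])^2 <= 1
}

#' Generate a synthetic paired-modality slice
#'
#' Builds both modality images in A's frame (piecewise-constant scene,
#' PSF blur, additive noise, plus the smooth autofluorescent field for B),
#' then warps modality B by `spec$misalignment` into its own camera frame.
#'
#' @param spec a [slice_phantom_spec()].
#' @return list with `image_a`, `image_b` ([modality_image()]s),
#'   `tumor_mask` (logical, A's frame), `true_registration` (the
#'   [similarity_transform()] mapping B's frame back onto A's, i.e. the
#'   exact answer registration should recover) and `spec`.
#' @export
generate_slice_pair <- function(spec) {
  stopifnot(inherits(spec, "slice_phantom_spec"))
  withr::with_seed(spec$seed, {
    shp <- spec$image_shape
    # The tissue extends beyond the A camera's frame: synthesize on a padded
    # canvas wide enough that the misaligned B view is covered everywhere,
    # so image_b has no out-of-frame pixels (a real camera sees a full frame).
    pad <- scene_pad(spec$misalignment, shp)
    pshp <- shp + 2L * pad
    pctr <- spec$tumor_center + pad
    maskp <- ellipse_mask(pshp, pctr, spec$tumor_axes, spec$tumor_angle)
    mask <- maskp[(pad + 1):(pad + shp[1]), (pad + 1):(pad + shp[2])]
    scene_a <- matrix(spec$bg_mean_a, pshp[1], pshp[2])
    scene_a[maskp] <- spec$tumor_mean_a
    scene_b <- matrix(spec$bg_mean_b, pshp[1], pshp[2])
    scene_b[maskp] <- spec$tumor_mean_b
    a <- blur_gaussian(scene_a, spec$blur_sigma_a)
    if (spec$noise_sd_a > 0)
      a <- a + matrix(stats::rnorm(prod(pshp), 0, spec$noise_sd_a), pshp[1], pshp[2])
    a <- a[(pad + 1):(pad + shp[1]), (pad + 1):(pad + shp[2])]
    b <- blur_gaussian(scene_b, spec$blur_sigma_b)
    if (spec$autofluor_amplitude_b > 0) {
      f <- blur_gaussian(matrix(stats::rnorm(prod(pshp)), pshp[1], pshp[2]),
                         spec$autofluor_scale_px)
      f <- (f - mean(f)) / stats::sd(f)
      b <- b + spec$autofluor_amplitude_b * f
    }
    if (spec$noise_sd_b > 0)
      b <- b + matrix(stats::rnorm(prod(pshp), 0, spec$noise_sd_b), pshp[1], pshp[2])
    # padded-canvas coords -> B-frame coords: undo the pad shift, then misalign
    pad_shift <- similarity_transform(translation = c(pad, pad))
    b_img <- apply_transform(b, st_compose(spec$misalignment, st_inverse(pad_shift)),
                             output_shape = shp, interpolation = "bilinear")
    list(image_a = modality_image(a, spec$pixel_pitch, "A"),
         image_b = modality_image(b_img, spec$pixel_pitch, "B"),
         tumor_mask = mask,
         true_registration = st_inverse(spec$misalignment),
         spec = spec)
  })
}

#' Specify a synthetic tube phantom
#'
#' A straight dye-filled transparent tube (default inner/outer diameter
#' 0.6 / 1.2 mm) imaged through increasing simulated tissue depth: the
#' cross-section is the tube indicator profile convolved with a Gaussian of
#' `depth_blur_sigma` (monotone in depth), plus additive noise.
#'
#' @param tube_inner_diameter,tube_outer_diameter mm, inner < outer.
#' @param depth_blur_sigma Gaussian blur SD in pixels.
#' @param peak_intensity ridge peak intensity (a.u.).
#' @param noise_sd additive Gaussian noise SD.
#' @param pixel_pitch mm per pixel.
#' @param image_shape `(rows, cols)`; the tube runs vertically through the
#'   center column.
#' @param seed integer seed.
#' @return a `tube_phantom_spec` object.
#' @export
tube_phantom_spec <- function(tube_inner_diameter = 0.6,
                              tube_outer_diameter = 1.2,
                              depth_blur_sigma = 0,
                              peak_intensity = 0.8,
                              noise_sd = 0,
                              pixel_pitch = 0.1,
                              image_shape = c(64L, 81L),
                              seed = 1L) {
  if (tube_inner_diameter <= 0 || tube_outer_diameter <= 0)
    stop("tube diameters must be > 0")
  if (tube_inner_diameter >= tube_outer_diameter)
    stop("inner diameter must be smaller than outer diameter")
  if (depth_blur_sigma < 0 || peak_intensity < 0 || noise_sd < 0 || pixel_pitch <= 0)
    stop("all parameters must be >= 0 (pixel_pitch > 0)")
  structure(list(tube_inner_diameter = tube_inner_diameter,
                 tube_outer_diameter = tube_outer_diameter,
                 depth_blur_sigma = depth_blur_sigma,
                 peak_intensity = peak_intensity, noise_sd = noise_sd,
                 pixel_pitch = pixel_pitch,
                 image_shape = as.integer(image_shape), seed = as.integer(seed)),
            class = "tube_phantom_spec")
}

#' Generate a tube-phantom image
#'
#' The noiseless cross-section is analytic: with no blur it is the
#' pixel-area-integrated tube indicator (so the FWHM of the noiseless
#' profile equals `inner_diameter / pixel_pitch` pixels exactly for
#' even-integer widths); with blur it is the rect-Gaussian convolution
#' `Phi((h - d)/sigma) + Phi((h + d)/sigma) - 1`.
#'
#' @param spec a [tube_phantom_spec()].
#' @return a [modality_image()]; attribute `center_col` holds the ridge
#'   center column.
#' @export
generate_tube_image <- function(spec) {
  stopifnot(inherits(spec, "tube_phantom_spec"))
  withr::with_seed(spec$seed, {
    shp <- spec$image_shape
    cc <- (shp[2] + 1) / 2
    d <- seq_len(shp[2]) - cc
    h <- (spec$tube_inner_diameter / 2) / spec$pixel_pitch
    s <- spec$depth_blur_sigma
    cross <- if (s == 0) {
      # pixel-area coverage of [-h, h] by [d - 0.5, d + 0.5]
      pmax(0, pmin(d + 0.5, h) - pmax(d - 0.5, -h))
    } else {
      stats::pnorm((h - d) / s) + stats::pnorm((h + d) / s) - 1
    }
    cross <- spec$peak_intensity * cross / max(cross)
    img <- matrix(cross, shp[1], shp[2], byrow = TRUE)
    if (spec$noise_sd > 0)
      img <- img + matrix(stats::rnorm(prod(shp), 0, spec$noise_sd), shp[1], shp[2])
    out <- modality_image(img, spec$pixel_pitch, "tube")
    attr(out, "center_col") <- cc
    out
  })
}

#' Generate a liquid-phantom dilution well series
#'
#' One small image per concentration plus a leading zero-concentration
#' control well. Each well is a centered disk whose mean signal is
#' `background_mean + gain * concentration`; additive Gaussian noise of SD
#' `floor_sd` everywhere (the sensor noise floor).
#'
#' @param concentrations non-negative dye concentrations (a.u.), one well each.
#' @param gain signal per unit concentration.
#' @param floor_sd noise SD.
#' @param background_mean intensity of dye-free regions.
#' @param well_radius disk radius in pixels.
#' @param image_shape per-well image shape.
#' @param seed integer seed.
#' @return list of wells, each a list with `concentration`, `image`
#'   ([modality_image()]) and `mask` (the disk); element 1 is the control.
#' @export
generate_well_series <- function(concentrations, gain, floor_sd,
                                 background_mean = 0.05,
                                 well_radius = 10, image_shape = c(33L, 33L),
                                 seed = 1L) {
  if (length(concentrations) == 0L) stop("empty concentration list")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  if (gain < 0 || floor_sd < 0) stop("gain and floor_sd must be >= 0")
  withr::with_seed(as.integer(seed), {
    shp <- as.integer(image_shape)
    ctr <- (shp + 1) / 2
    r <- matrix(seq_len(shp[1]), shp[1], shp[2]) - ctr[1]
    c <- matrix(seq_len(shp[2]), shp[1], shp[2], byrow = TRUE) - ctr[2]
    disk <- r^2 + c^2 <= well_radius^2
    make_well <- function(conc) {
      img <- matrix(background_mean, shp[1], shp[2])
      img[disk] <- background_mean + gain * conc
      if (floor_sd > 0)
        img <- img + matrix(stats::rnorm(prod(shp), 0, floor_sd), shp[1], shp[2])
      list(concentration = conc,
           image = modality_image(img, 1, "well"),
           mask = disk)
    }
    lapply(c(0, concentrations), make_well)
  })
}

#' Generate a recorded lamp spectrum with a known detector response
#'
#' Black-body emission at `true_temperature` multiplied by a per-wavelength
#' detector response, with optional multiplicative Gaussian noise - the
#' closed-loop test bed for [fit_blackbody()] and [spectral_correction()].
#'
#' @param true_temperature lamp temperature in K (> 0).
#' @param response_curve per-wavelength multiplier (> 0), recycled scalar ok.
#' @param wavelengths nm grid.
#' @param relative_noise_sd SD of multiplicative noise (0 = noiseless).
#' @param scale overall intensity scale.
#' @param seed integer seed.
#' @return a [spectrum()].
#' @export
generate_lamp_spectrum <- function(true_temperature, response_curve, wavelengths,
                                   relative_noise_sd = 0, scale = 1, seed = 1L) {
  if (true_temperature <= 0) stop("temperature must be > 0 K")
  response_curve <- rep_len(as.numeric(response_curve), length(wavelengths))
  if (any(response_curve <= 0)) stop("response curve must be > 0 on the grid")
  bb <- blackbody(wavelengths, true_temperature, scale)
  v <- bb$values * response_curve
  if (relative_noise_sd > 0) {
    v <- withr::with_seed(as.integer(seed),
                          v * (1 + stats::rnorm(length(v), 0, relative_noise_sd)))
  }
  spectrum(wavelengths, v)
}

#' Write a synthetic two-modality study to disk
#'
#' Materializes `n_slices` seeded [generate_slice_pair()] scenes as the file
#' layout [run_study()] consumes: float TIFF image pairs, 8-bit PNG tumor
#' masks, control-point and line-annotation CSVs, and a `manifest.csv`
#' listing the files plus the ground-truth generator parameters. Control
#' points are noiseless correspondences through the true misalignment; the
#' four lines per slice (the study-design convention) run from the tumor
#' center outward across the border at evenly spaced angles.
#'
#' @param dir output directory (created if needed).
#' @param n_slices number of slices.
#' @param base_spec template [slice_phantom_spec()]; per-slice seeds are
#'   derived from `seed`.
#' @param n_lines lines per slice.
#' @param n_control_points control-point pairs per slice.
#' @param seed study-level seed.
#' @return the manifest as a data.frame (also written to
#'   `file.path(dir, "manifest.csv")`).
#' @export
write_study_bundle <- function(dir, n_slices = 2L,
                               base_spec = slice_phantom_spec(),
                               n_lines = 4L, n_control_points = 6L,
                               seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", n_slices)
  for (k in seq_len(n_slices)) {
    spec <- base_spec
    spec$seed <- as.integer(seed * 1000L + k)
    sl <- generate_slice_pair(spec)
    id <- sprintf("slice%03d", k)
    pa <- file.path(dir, paste0(id, "_A.tif"))
    pb <- file.path(dir, paste0(id, "_B.tif"))
    pm <- file.path(dir, paste0(id, "_mask.png"))
    write_image_tiff(sl$image_a, pa)
    write_image_tiff(sl$image_b, pb)
    write_mask_png(sl$tumor_mask, pm)

    shp <- spec$image_shape
    fixed <- cbind(row = c(30, 30, shp[1] - 30, shp[1] - 30, shp[1] / 2, 45),
                   col = c(30, shp[2] - 30, 30, shp[2] - 30, shp[2] / 2, shp[2] / 2))
    fixed <- fixed[seq_len(min(n_control_points, nrow(fixed))), , drop = FALSE]
    moving <- transform_points(spec$misalignment, fixed)
    pc <- file.path(dir, paste0(id, "_cps.csv"))
    utils::write.csv(data.frame(moving_row = moving[, 1], moving_col = moving[, 2],
                                fixed_row = fixed[, 1], fixed_col = fixed[, 2]),
                     pc, row.names = FALSE)

    ang <- spec$tumor_angle + seq(0, by = 2 * pi / n_lines, length.out = n_lines)
    ctr <- spec$tumor_center
    ldf <- do.call(rbind, lapply(seq_len(n_lines), function(j) {
      u <- c(cos(ang[j]), sin(ang[j]))
      # ellipse radius along u (centered, rotated frame)
      x <- cos(spec$tumor_angle) * u[1] + sin(spec$tumor_angle) * u[2]
      y <- -sin(spec$tumor_angle) * u[1] + cos(spec$tumor_angle) * u[2]
      r_edge <- 1 / sqrt((x / spec$tumor_axes[1])^2 + (y / spec$tumor_axes[2])^2)
      inner <- pmax(r_edge - 25, 2)
      outer <- r_edge + 25
      data.frame(line_id = j,
                 start_row = ctr[1] + inner * u[1], start_col = ctr[2] + inner * u[2],
                 end_row = ctr[1] + outer * u[1], end_col = ctr[2] + outer * u[2])
    }))
    pl <- file.path(dir, paste0(id, "_lines.csv"))
    utils::write.csv(ldf, pl, row.names = FALSE)

    rows[[k]] <- data.frame(
      slice_id = id, image_a = basename(pa), image_b = basename(pb),
      mask = basename(pm), control_points = basename(pc), lines = basename(pl),
      pixel_pitch = spec$pixel_pitch,
      true_tbr_a = spec$tumor_mean_a / spec$bg_mean_a,
      true_tbr_b = spec$tumor_mean_b / spec$bg_mean_b,
      seed = spec$seed, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
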