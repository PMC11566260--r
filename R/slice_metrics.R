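#' Region-of-interest statistics
#'
#' Mean fluorescence intensity (MFI), population standard deviation
#' (divisor n: regions hold thousands of pixels, so the n vs n-1 difference
#' is negligible and the population form keeps the contrast formulas exact),
#' pixel count and extremes over the in-mask pixels of an image. `NA`
#' (out-of-frame sentinel) pixels are excluded, so registration never biases
#' an MFI.
#'
#' @param image [modality_image()] or numeric matrix.
#' @param mask logical (or 0/1) matrix of the same shape.
#' @return a `roi_stats` object: list with `mfi`, `sd`, `n`, `min`, `max`.
#' @seealso [roi_stats_summary()] to build the object from known summary
#'   values (e.g. analytic inputs or tabulated well statistics).
#' @export
roi_stats <- function(image, mask) {
  m <- img_data(image)
  msk <- as.matrix(mask) != 0
  if (!all(dim(m) == dim(msk))) stop("image and mask shapes differ")
  v <- m[msk]
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("mask selects no in-frame pixels")
  roi_stats_summary(
    mfi = mean(v),
    sd = sqrt(mean((v - mean(v))^2)),
    n = length(v),
    min = min(v),
    max = max(v))
}

#' @param mfi,sd,n,min,max summary values (`sd` is the population SD).
#' @rdname roi_stats
#' @export
roi_stats_summary <- function(mfi, sd = NA_real_, n = NA_integer_,
                              min = NA_real_, max = NA_real_) {
  if (!is.na(sd) && sd < 0) stop("sd must be >= 0")
  structure(list(mfi = as.numeric(mfi), sd = as.numeric(sd),
                 n = as.integer(n), min = as.numeric(min), max = as.numeric(max)),
            class = "roi_stats")
}

#' @export
print.roi_stats <- function(x, ...) {
  cat(sprintf("<roi_stats> MFI %.6g, SD %.6g, n %s, range [%.6g, %.6g]\n",
              x$mfi, x$sd, format(x$n), x$min, x$max))
  invisible(x)
}

#' Tumor-to-background ratio (TBR)
#'
#' The current standard of fluorescence image assessment: the ratio of the
#' tumor MFI to the background MFI.
#'
#' @param tumor,background [roi_stats()] objects (or lists with an `mfi`
#'   element; `background` additionally needs `sd` for [acnr()]).
#' @return the ratio `tumor$mfi / background$mfi`.
#' @export
tbr <- function(tumor, background) {
  if (background$mfi == 0) stop("background MFI is zero: TBR undefined")
  tumor$mfi / background$mfi
}

#' Adapted contrast-to-noise ratio (aCNR)
#'
#' Contrast-to-noise ratio with the background standard deviation scaled by
#' a factor of two, which makes the measure more robust to noise:
#' `(MFI_tumor - MFI_background) / (2 * sigma_background)`. A pixel exactly
#' two background SDs above the background mean has aCNR = 1, the value used
#' as the tumor-border criterion in the line analysis.
#'
#' @inheritParams tbr
#' @return the adapted contrast-to-noise ratio.
#' @export
acnr <- function(tumor, background) {
  if (is.na(background$sd) || background$sd <= 0)
    stop("background SD must be > 0: contrast-to-noise is undefined")
  (tumor$mfi - background$mfi) / (2 * background$sd)
}

#' Signal-to-noise ratio in decibels
#'
#' `SNR(dB) = 20 * log10((MFI_signal - MFI_control) / sigma_control)`.
#' When the signal mean does not exceed the control mean the concentration is
#' not detectable and `NA` is returned (flag, not a number);
#' [is_detectable()] maps it to `FALSE`.
#'
#' @param signal [roi_stats()] for the signal region (e.g. a dye-filled well).
#' @param control [roi_stats()] for the zero-concentration control region.
#' @return SNR in dB, or `NA` when `signal$mfi <= control$mfi`.
#' @export
snr_db <- function(signal, control) {
  if (is.na(control$sd) || control$sd <= 0) stop("control SD must be > 0")
  excess <- signal$mfi - control$mfi
  if (excess <= 0) return(NA_real_)
  20 * log10(excess / control$sd)
}

#' Detectability rule for SNR
#'
#' A detectable signal must exceed at least three control standard
#' deviations, i.e. SNR strictly greater than 9.5 dB
#' (`20 * log10(3) = 9.54 dB`).
#'
#' @param snr SNR in dB as returned by [snr_db()] (`NA` = not detectable).
#' @return logical.
#' @export
is_detectable <- function(snr) {
  !is.na(snr) & snr > 9.5
}

#' Min-max intensity normalization
#'
#' Rescales in-frame pixels to `[0, 1]` via `(x - min) / (max - min)`.
#'
#' @param image [modality_image()] or numeric matrix; must not be constant.
#' @return normalized image of the same class.
#' @export
min_max_normalize <- function(image) {
  m <- img_data(image)
  rng <- range(m, na.rm = TRUE)
  if (!is.finite(rng[1])) stop("image has no in-frame pixels")
  if (rng[2] <= rng[1]) stop("constant image: min-max normalization undefined")
  res <- (m - rng[1]) / (rng[2] - rng[1])
  if (inherits(image, "modality_image"))
    res <- modality_image(res, pixel_pitch = img_pitch(image),
                          modality = attr(image, "modality"))
  res
}

#' Background-image subtraction
#'
#' Pixelwise subtraction of an acquisition-matched background image, clipped
#' at zero (negative fluorescence is unphysical and would shift the
#' downstream min-max scaling).
#'
#' @param image,bg_image same-shape images.
#' @return `pmax(image - bg_image, 0)`, same class as `image`.
#' @export
background_subtract <- function(image, bg_image) {
  m <- img_data(image); b <- img_data(bg_image)
  if (!all(dim(m) == dim(b))) stop("image and background image shapes differ")
  res <- pmax(m - b, 0)
  dim(res) <- dim(m)
  if (inherits(image, "modality_image"))
    res <- modality_image(res, pixel_pitch = img_pitch(image),
                          modality = attr(image, "modality"))
  res
}
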