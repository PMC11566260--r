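#' Collect paired per-pixel intensities from two co-registered modalities
#'
#' Min-max-normalizes each modality over its in-mask, in-frame pixels and
#' pairs them pixel by pixel. Pixels that are `NA` (out-of-frame sentinel) in
#' either modality are dropped, so frame clipping after registration never
#' produces spurious pairs.
#'
#' @param image_a reference-frame image of modality A.
#' @param image_b_registered modality B resampled into A's frame.
#' @param tumor_mask,bg_mask disjoint logical masks in A's frame.
#' @return a data.frame with columns `a`, `b` (normalized intensities in
#'   `[0, 1]`) and `label` (`"tumor"`/`"background"`), of class
#'   `paired_pixels`.
#' @export
collect_paired_pixels <- function(image_a, image_b_registered, tumor_mask, bg_mask) {
  a <- img_data(image_a); b <- img_data(image_b_registered)
  tm <- as.matrix(tumor_mask) != 0
  bm <- as.matrix(bg_mask) != 0
  if (!all(dim(a) == dim(b)) || !all(dim(a) == dim(tm)) || !all(dim(a) == dim(bm)))
    stop("images and masks must share one shape (A's frame)")
  if (any(tm & bm)) stop("tumor and background masks overlap")
  sel <- (tm | bm) & !is.na(a) & !is.na(b)
  if (!any(sel)) stop("no in-frame pixels under the masks")
  av <- a[sel]; bv <- b[sel]
  norm01 <- function(v) {
    rng <- range(v)
    if (rng[2] <= rng[1]) stop("constant intensities: normalization undefined")
    (v - rng[1]) / (rng[2] - rng[1])
  }
  out <- data.frame(a = norm01(av), b = norm01(bv),
                    label = ifelse(tm[sel], "tumor", "background"),
                    stringsAsFactors = FALSE)
  class(out) <- c("paired_pixels", "data.frame")
  out
}

#' Coefficient of determination of the pixelwise modality relation
#'
#' Ordinary least-squares simple linear regression of `b` on `a`; returns
#' r-squared.
#'
#' @param a_values,b_values equal-length numeric vectors (>= 3 pairs).
#' @return r-squared in `[0, 1]`.
#' @export
linear_r2 <- function(a_values, b_values) {
  if (length(a_values) != length(b_values)) stop("length mismatch")
  if (length(a_values) < 3L) stop("at least 3 pairs are required")
  if (stats::var(a_values) == 0) stop("zero variance in predictor")
  # perfect fits (identical modalities) are legitimate: silence lm's warning
  suppressWarnings(summary(stats::lm(b_values ~ a_values))$r.squared)
}

#' Bland-Altman agreement between modalities
#'
#' Bias is the mean of the paired differences, oriented `b - a`
#' (SWIR minus NIR by default; flip the arguments for the other
#' orientation). The limits of agreement are `bias +/- 2 * SD`.
#'
#' @param a_values,b_values equal-length numeric vectors (>= 2 pairs).
#' @return list with `bias`, `sd` (sample SD of differences), `loa_lower`,
#'   `loa_upper`, `orientation`.
#' @export
bland_altman <- function(a_values, b_values) {
  if (length(a_values) != length(b_values)) stop("length mismatch")
  if (length(a_values) < 2L) stop("at least 2 pairs are required")
  d <- b_values - a_values
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, sd = s,
       loa_lower = bias - 2 * s, loa_upper = bias + 2 * s,
       orientation = "b - a")
}

#' Tumor/background intensity overlap percentage
#'
#' The percentage of tumor pixels whose intensity does not exceed the
#' maximum background intensity (inclusive at the background maximum) - a
#' rank statistic of how poorly a single intensity threshold separates tumor
#' from background in a modality.
#'
#' @param pairs a [collect_paired_pixels()] data.frame (or any data.frame
#'   with columns `a`, `b`, `label`).
#' @param modality which modality's intensities to assess, `"a"` or `"b"`.
#' @return percentage in `[0, 100]`.
#' @export
tumor_bg_overlap <- function(pairs, modality = c("a", "b")) {
  modality <- match.arg(modality)
  v <- pairs[[modality]]
  tum <- v[pairs$label == "tumor"]
  bg <- v[pairs$label == "background"]
  if (length(tum) < 1L || length(bg) < 1L)
    stop("both a tumor and a background pixel class are required")
  100 * mean(tum <= max(bg))
}
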