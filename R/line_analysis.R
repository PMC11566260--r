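#' Specify a widened line across the tumor border
#'
#' Lines are drawn through tumor tissue perpendicular to the pathology tumor
#' edge. Each line is widened to a sub-image of `width` pixels (default 11)
#' which is then collapsed back to one pixel with a Gaussian mean to reduce
#' noise.
#'
#' @param start,end `(row, col)` coordinates of the line endpoints in the
#'   reference frame (1-based, pixel centers at integers).
#' @param width odd number of perpendicular pixels (default 11).
#' @param pixel_pitch mm per pixel, used to express positions in mm.
#' @return a `line_spec` object.
#' @export
line_spec <- function(start, end, width = 11L, pixel_pitch = 1) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != 2L || length(end) != 2L || !all(is.finite(c(start, end))))
    stop("start and end must be finite (row, col) pairs")
  if (all(start == end)) stop("start and end coincide")
  width <- as.integer(width)
  if (width < 1L || width %% 2L == 0L) stop("width must be odd and >= 1")
  if (pixel_pitch <= 0) stop("pixel_pitch must be > 0")
  structure(list(start = start, end = end, width = width,
                 pixel_pitch = pixel_pitch),
            class = "line_spec")
}

# Sample positions along the centerline at 1-pixel steps, plus unit
# direction u and perpendicular v.
line_geometry <- function(line) {
  d <- line$end - line$start
  len <- sqrt(sum(d^2))
  u <- d / len
  steps <- 0:floor(len + 1e-9)
  centers <- cbind(line$start[1] + steps * u[1], line$start[2] + steps * u[2])
  list(u = u, v = c(-u[2], u[1]), steps = steps, centers = centers, length_px = len)
}

#' Extract the widened sub-image under a line
#'
#' Samples the image at 1-pixel steps along the line and at integer
#' perpendicular offsets `-(width-1)/2 ... +(width-1)/2`, with bilinear
#' interpolation (exact on locally affine intensity fields, alias-free on
#' oblique lines).
#'
#' @param image [modality_image()] or numeric matrix.
#' @param line a [line_spec()] fully inside the image domain.
#' @return a `width x n_positions` numeric matrix; row `i` is perpendicular
#'   offset `i - (width+1)/2`.
#' @export
extract_subimage <- function(image, line) {
  m <- img_data(image)
  g <- line_geometry(line)
  h <- (line$width - 1L) / 2L
  offsets <- -h:h
  nr <- nrow(m); nc <- ncol(m)
  sub <- matrix(NA_real_, line$width, length(g$steps))
  bad <- logical(length(offsets))
  for (i in seq_along(offsets)) {
    r <- g$centers[, 1] + offsets[i] * g$v[1]
    c <- g$centers[, 2] + offsets[i] * g$v[2]
    if (any(r < 1 | r > nr | c < 1 | c > nc)) { bad[i] <- TRUE; next }
    sub[i, ] <- bilinear_sample(m, r, c)
  }
  if (any(bad))
    stop("line exits the image at perpendicular offsets: ",
         paste(offsets[bad], collapse = ", "))
  sub
}

#' Collapse a widened line with a Gaussian mean
#'
#' Weighted mean across the perpendicular width with Gaussian weights
#' centered on the middle offset and normalized to sum 1. The default
#' `sigma_perp = width / 6` puts the +-3 sigma support of the kernel on the
#' full width (about 1.83 px for the default 11-pixel line). `sigma_perp =
#' Inf` gives the unweighted row mean.
#'
#' @param subimage `width x n` matrix from [extract_subimage()]; width odd.
#' @param sigma_perp Gaussian SD of the perpendicular weights, in pixels.
#' @return numeric vector of length `n` (the filtered one-pixel line).
#' @export
gaussian_collapse <- function(subimage, sigma_perp = nrow(subimage) / 6) {
  w <- nrow(subimage)
  if (w %% 2L == 0L) stop("sub-image width must be odd")
  h <- (w - 1L) / 2L
  if (!is.finite(sigma_perp) || sigma_perp > 1e6) {
    wt <- rep(1, w)
  } else {
    if (sigma_perp <= 0) stop("sigma_perp must be > 0")
    wt <- stats::dnorm(-h:h, sd = sigma_perp)
  }
  wt <- wt / sum(wt)
  as.numeric(crossprod(wt, subimage))
}

#' Label line positions from the pathology mask
#'
#' Each sample of the filtered line is assigned tumor or background by
#' nearest-neighbour lookup in the (H&E-derived) tumor mask along the line
#' centerline. The line must cross the mask boundary exactly once (lines are
#' drawn perpendicular to the tumor edge); the ground-truth border position
#' is the midpoint between the last sample on one side and the first on the
#' other.
#'
#' @param line a [line_spec()].
#' @param tumor_mask logical matrix in the same frame.
#' @return list with `labels` (character, `"tumor"`/`"background"`) and
#'   `border_position` (mm from the line start).
#' @export
label_positions <- function(line, tumor_mask) {
  msk <- as.matrix(tumor_mask) != 0
  g <- line_geometry(line)
  ri <- round(g$centers[, 1]); ci <- round(g$centers[, 2])
  if (any(ri < 1 | ri > nrow(msk) | ci < 1 | ci > ncol(msk)))
    stop("line centerline exits the mask domain")
  lab <- ifelse(msk[cbind(ri, ci)], "tumor", "background")
  n_cross <- sum(lab[-1] != lab[-length(lab)])
  if (n_cross != 1L)
    stop("line must cross the tumor boundary exactly once (found ",
         n_cross, " crossings)")
  i <- which(lab[-1] != lab[-length(lab)])
  border <- (g$steps[i] + g$steps[i + 1]) / 2 * line$pixel_pitch
  list(labels = lab, border_position = border)
}

#' Assemble a collapsed line profile
#'
#' @param positions mm along the line from its start (strictly increasing,
#'   spacing = pixel pitch).
#' @param intensity collapsed intensities at those positions.
#' @param labels `"tumor"`/`"background"` per position.
#' @param border_position ground-truth pathology border in mm, or `NA`.
#' @param pixel_pitch mm per pixel.
#' @return a `line_profile` object.
#' @export
line_profile <- function(positions, intensity, labels,
                         border_position = NA_real_, pixel_pitch = 1) {
  n <- length(positions)
  if (length(intensity) != n || length(labels) != n)
    stop("positions, intensity and labels must have equal length")
  if (n >= 2 && any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  if (!all(labels %in% c("tumor", "background")))
    stop("labels must be 'tumor' or 'background'")
  structure(list(positions = as.numeric(positions),
                 intensity = as.numeric(intensity),
                 labels = as.character(labels),
                 border_position = border_position,
                 pixel_pitch = pixel_pitch),
            class = "line_profile")
}

#' Reverse the orientation of a line profile
#'
#' Mirrors positions about the line extent so the profile reads tumor-first,
#' as the crossing detector expects.
#'
#' @param profile a [line_profile()].
#' @return the reversed [line_profile()].
#' @export
rev_line_profile <- function(profile) {
  total <- profile$positions[length(profile$positions)]
  line_profile(rev(total - profile$positions), rev(profile$intensity),
               rev(profile$labels),
               border_position = if (is.na(profile$border_position)) NA_real_
                                 else total - profile$border_position,
               pixel_pitch = profile$pixel_pitch)
}

bg_values <- function(profile) profile$intensity[profile$labels == "background"]

#' Per-position TBR over a line
#'
#' Each collapsed intensity divided by the mean of all background intensities
#' of the same line. The summary mean is taken over all positions of the
#' line, tumor and background (`scope = "tumor"` restricts it).
#'
#' @param profile a [line_profile()] with at least one background position.
#' @param scope positions included in the summary mean.
#' @return list with `values` (per-position ratios) and `mean`.
#' @export
profile_tbr <- function(profile, scope = c("all", "tumor")) {
  scope <- match.arg(scope)
  bg <- bg_values(profile)
  if (length(bg) < 1L) stop("line has no background positions")
  mu <- mean(bg)
  if (mu == 0) stop("background mean is zero: TBR undefined")
  v <- profile$intensity / mu
  list(values = v,
       mean = mean(if (scope == "all") v else v[profile$labels == "tumor"]))
}

#' Per-position aCNR over a line
#'
#' `(x_i - MFI_background) / (2 * sigma_background)` with the background MFI
#' and (population) SD taken from the background positions of the same line.
#'
#' @inheritParams profile_tbr
#' @return list with `values`, `mean`, `bg_mfi`, `bg_sd`.
#' @export
profile_acnr <- function(profile, scope = c("all", "tumor")) {
  scope <- match.arg(scope)
  bg <- bg_values(profile)
  if (length(bg) < 2L) stop("at least 2 background positions are required")
  mu <- mean(bg)
  sdv <- sqrt(mean((bg - mu)^2))
  if (sdv <= 0) stop("background SD is zero: aCNR undefined")
  v <- (profile$intensity - mu) / (2 * sdv)
  list(values = v,
       mean = mean(if (scope == "all") v else v[profile$labels == "tumor"]),
       bg_mfi = mu, bg_sd = sdv)
}

#' Area under the aCNR curve over the tumor pixels
#'
#' Trapezoidal integral of the aCNR profile over the tumor-labeled run, with
#' the abscissa in pixels (a constant aCNR of c over k tumor pixels gives
#' c * (k - 1)).
#'
#' @param acnr_values per-position aCNR values ([profile_acnr()]`$values`).
#' @param labels per-position labels.
#' @return the dimensionless area.
#' @export
acnr_auc <- function(acnr_values, labels) {
  idx <- which(labels == "tumor")
  if (length(idx) < 2L) stop("at least 2 tumor positions are required for an AUC")
  if (any(diff(idx) != 1L)) stop("tumor positions must form a single contiguous run")
  pracma::trapz(seq_along(idx), acnr_values[idx])
}

#' Locate the aCNR = 1 crossing along a line
#'
#' Scanning from the tumor end toward the background end, returns the
#' position of the last transition from aCNR > 1 to aCNR <= 1 occurring at
#' or before the first background sample (noise spikes in the far background
#' must not define the border); if the profile is still above 1 when it
#' enters the background, the first subsequent down-crossing is used. The
#' crossing is linearly interpolated between the bracketing samples. When
#' the profile never exceeds 1 there is no crossing (`NA`): a valid outcome,
#' counted as "absent" by [crossing_agreement()].
#'
#' @param acnr_values per-position aCNR values.
#' @param labels per-position labels, ordered tumor first.
#' @param positions mm positions of the samples.
#' @return crossing position in mm, or `NA_real_` when absent.
#' @export
find_acnr_crossing <- function(acnr_values, labels, positions) {
  n <- length(acnr_values)
  if (length(labels) != n || length(positions) != n) stop("length mismatch")
  if (labels[1] != "tumor") stop("profile must be ordered tumor -> background")
  first_bg <- match("background", labels)
  if (is.na(first_bg)) stop("profile has no background positions")
  down <- which(acnr_values[-n] > 1 & acnr_values[-1] <= 1)
  if (length(down) == 0L) return(NA_real_)
  before <- down[down <= first_bg]
  i <- if (length(before)) max(before) else min(down)
  frac <- (acnr_values[i] - 1) / (acnr_values[i] - acnr_values[i + 1])
  positions[i] + frac * (positions[i + 1] - positions[i])
}

#' Distance from the aCNR = 1 crossing to the pathology border
#'
#' @param crossing_position mm, or `NA` when no crossing was found.
#' @param border_position mm (ground-truth pathology border).
#' @return absolute distance in mm (`NA` propagates).
#' @export
crossing_distance <- function(crossing_position, border_position) {
  abs(crossing_position - border_position)
}

#' Agreement between two modalities on finding an aCNR = 1 crossing
#'
#' Positive agreement: of the lines where the reference modality found a
#' crossing, the percentage where the test modality also did. Negative
#' agreement: of the reference-absent lines, the percentage where the test
#' modality also found none. A percentage whose denominator is empty is
#' `NA` (e.g. it cannot be determined when the reference finds a crossing on
#' every line).
#'
#' @param test_found,reference_found logical vectors (crossing present per
#'   line), equal length. `NA` crossing positions count as "not found".
#' @return list with `positive` and `negative` percentages (0-100 or `NA`).
#' @export
crossing_agreement <- function(test_found, reference_found) {
  test_found <- !is.na(test_found) & as.logical(test_found)
  reference_found <- !is.na(reference_found) & as.logical(reference_found)
  if (length(test_found) != length(reference_found))
    stop("paired lists must have equal length")
  pos <- if (any(reference_found)) 100 * mean(test_found[reference_found]) else NA_real_
  neg <- if (any(!reference_found)) 100 * mean(!test_found[!reference_found]) else NA_real_
  list(positive = pos, negative = neg)
}

#' Full line analysis for one modality
#'
#' Convenience wrapper: widen, Gaussian-collapse, label from the mask
#' (reorienting tumor-first if needed), and compute the per-line report.
#'
#' @param image [modality_image()] or matrix in the reference frame.
#' @param line a [line_spec()].
#' @param tumor_mask logical matrix in the reference frame.
#' @param sigma_perp collapse kernel SD ([gaussian_collapse()]).
#' @param scope summary-mean scope ([profile_tbr()]).
#' @return list with `profile` ([line_profile()]), `tbr`, `acnr`,
#'   `mean_tbr`, `mean_acnr`, `auc_acnr`, `crossing_position`,
#'   `crossing_distance`.
#' @export
analyze_line <- function(image, line, tumor_mask,
                         sigma_perp = line$width / 6,
                         scope = c("all", "tumor")) {
  scope <- match.arg(scope)
  sub <- extract_subimage(image, line)
  if (anyNA(sub)) stop("line crosses out-of-frame (sentinel) pixels")
  prof <- gaussian_collapse(sub, sigma_perp)
  lab <- label_positions(line, tumor_mask)
  g <- line_geometry(line)
  lp <- line_profile(g$steps * line$pixel_pitch, prof, lab$labels,
                     border_position = lab$border_position,
                     pixel_pitch = line$pixel_pitch)
  if (lp$labels[1] != "tumor") lp <- rev_line_profile(lp)
  t_res <- profile_tbr(lp, scope)
  a_res <- profile_acnr(lp, scope)
  cross <- find_acnr_crossing(a_res$values, lp$labels, lp$positions)
  list(profile = lp,
       tbr = t_res$values, acnr = a_res$values,
       mean_tbr = t_res$mean, mean_acnr = a_res$mean,
       auc_acnr = acnr_auc(a_res$values, lp$labels),
       crossing_position = cross,
       crossing_distance = crossing_distance(cross, lp$border_position))
}
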