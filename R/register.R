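#' Similarity transforms between the two camera frames
#'
#' A similarity transform is an isotropic scale, a rotation and a translation
#' (no reflection: the two cameras view the same physical slice, which cannot
#' be mirrored). It maps *moving*-frame coordinates to *fixed*-frame
#' coordinates: `y = s R x + t`, with `x`, `y` as `(row, col)` column vectors
#' and `R` the rotation matrix `[[cos, -sin], [sin, cos]]`.
#'
#' @param scale isotropic scale factor, > 0.
#' @param rotation rotation angle in radians.
#' @param translation length-2 numeric, `(row, col)` offset in pixels.
#' @return a `similarity_transform` object.
#' @export
similarity_transform <- function(scale = 1, rotation = 0, translation = c(0, 0)) {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop("scale must be a single positive finite number (no reflection component)")
  if (!is.numeric(rotation) || length(rotation) != 1L || !is.finite(rotation))
    stop("rotation must be a single finite number (radians)")
  translation <- as.numeric(translation)
  if (length(translation) != 2L || !all(is.finite(translation)))
    stop("translation must be two finite numbers (row, col)")
  structure(list(scale = scale, rotation = rotation, translation = translation),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("<similarity_transform> scale %.6g, rotation %.6g rad, translation (%.6g, %.6g)\n",
              x$scale, x$rotation, x$translation[1], x$translation[2]))
  invisible(x)
}

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

# 2x2 linear part s*R.
st_linear <- function(T) T$scale * rot2(T$rotation)

#' Compose and invert similarity transforms
#'
#' `st_compose(T2, T1)` is the transform "apply `T1`, then `T2`";
#' `st_inverse(T)` satisfies `st_compose(T, st_inverse(T)) = identity`.
#'
#' @param T,T1,T2 [similarity_transform()] objects.
#' @return a [similarity_transform()].
#' @export
st_compose <- function(T2, T1) {
  similarity_transform(
    scale = T2$scale * T1$scale,
    rotation = T2$rotation + T1$rotation,
    translation = as.numeric(st_linear(T2) %*% T1$translation) + T2$translation)
}

#' @rdname st_compose
#' @export
st_inverse <- function(T) {
  Ainv <- rot2(-T$rotation) / T$scale
  similarity_transform(
    scale = 1 / T$scale,
    rotation = -T$rotation,
    translation = as.numeric(-Ainv %*% T$translation))
}

#' Map points through a similarity transform
#'
#' @param T a [similarity_transform()] mapping moving to fixed coordinates.
#' @param points n x 2 matrix (or length-2 vector) of `(row, col)` coordinates.
#' @return n x 2 matrix of transformed coordinates.
#' @export
transform_points <- function(T, points) {
  points <- rbind2cols(points)
  out <- points %*% t(st_linear(T))
  out[, 1] <- out[, 1] + T$translation[1]
  out[, 2] <- out[, 2] + T$translation[2]
  colnames(out) <- c("row", "col")
  out
}

rbind2cols <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2, byrow = TRUE)
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("points must have two columns (row, col)")
  storage.mode(points) <- "double"
  points
}

#' Least-squares similarity transform from control points
#'
#' Closed-form Procrustes/Umeyama estimate of the similarity transform
#' (rotation + isotropic scale + translation, reflection disallowed) that
#' minimizes the mean squared error between the mapped moving points and the
#' fixed points. This is the control-point registration step: corresponding
#' landmarks are clicked in both modality images and the fitted transform
#' resamples one modality into the other's frame.
#'
#' @param moving n x 2 matrix of `(row, col)` landmark coordinates in the
#'   moving image's frame (n >= 2, not all coincident).
#' @param fixed n x 2 matrix of corresponding coordinates in the fixed frame.
#' @return a [similarity_transform()] with attributes `rms_residual` (root
#'   mean square residual per coordinate) and `residuals` (n x 2 matrix
#'   `fixed - T(moving)`).
#' @export
fit_similarity <- function(moving, fixed) {
  X <- rbind2cols(moving)
  Y <- rbind2cols(fixed)
  if (nrow(X) != nrow(Y)) stop("moving and fixed must have the same number of points")
  n <- nrow(X)
  if (n < 2L) stop("at least 2 control-point pairs are required")
  if (!all(is.finite(X)) || !all(is.finite(Y))) stop("control points must be finite")
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  var_x <- sum(Xc^2) / n
  if (var_x < .Machine$double.eps)
    stop("all moving points coincide: scale is indeterminate")
  S <- crossprod(Yc, Xc) / n
  sv <- svd(S)
  d <- sign(det(sv$u) * det(sv$v))
  if (d == 0) d <- 1
  D <- c(1, d)
  R <- sv$u %*% diag(D) %*% t(sv$v)
  s <- sum(sv$d * D) / var_x
  if (s <= 0) stop("degenerate configuration: non-positive scale")
  theta <- atan2(R[2, 1], R[1, 1])
  t_vec <- my - s * as.numeric(R %*% mx)
  T <- similarity_transform(scale = s, rotation = theta, translation = t_vec)
  res <- Y - transform_points(T, X)
  attr(T, "rms_residual") <- sqrt(sum(res^2) / (2 * n))
  attr(T, "residuals") <- res
  T
}

#' Resample an image through a similarity transform
#'
#' Maps `image` (moving frame) into the fixed frame: output pixel `p` takes
#' the value of the input at `T^-1(p)`. Pixels whose pre-image falls outside
#' the input domain are filled with the `NA` sentinel and excluded from all
#' downstream statistics.
#'
#' @param image [modality_image()] or numeric matrix (the moving image).
#' @param T [similarity_transform()] mapping moving to fixed coordinates.
#' @param output_shape `(rows, cols)` of the fixed frame; default `dim(image)`.
#' @param interpolation `"bilinear"` (default) or `"nearest"`.
#' @return resampled image of size `output_shape` (a [modality_image()] when
#'   the input was one).
#' @export
apply_transform <- function(image, T, output_shape = dim(image),
                            interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  m <- img_data(image)
  nr <- nrow(m); nc <- ncol(m)
  or <- output_shape[1]; oc <- output_shape[2]
  Tinv <- st_inverse(T)
  g <- cbind(rep(seq_len(or), times = oc), rep(seq_len(oc), each = or))
  src <- transform_points(Tinv, g)
  r <- src[, 1]; c <- src[, 2]
  out <- rep(NA_real_, or * oc)
  # domain membership up to floating-point noise, so a numerically-identity
  # transform does not shed boundary pixels
  eps <- 1e-9
  if (interpolation == "nearest") {
    ri <- round(r); ci <- round(c)
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    out[ok] <- m[cbind(ri[ok], ci[ok])]
  } else {
    ok <- r >= 1 - eps & r <= nr + eps & c >= 1 - eps & c <= nc + eps
    out[ok] <- bilinear_sample(m, pmin(pmax(r[ok], 1), nr), pmin(pmax(c[ok], 1), nc))
  }
  res <- matrix(out, or, oc)
  if (inherits(image, "modality_image"))
    res <- modality_image(res, pixel_pitch = img_pitch(image),
                          modality = attr(image, "modality"))
  res
}

# Bilinear interpolation at fractional (row, col); callers guarantee
# 1 <= r <= nrow, 1 <= c <= ncol. NA neighbours propagate to NA.
bilinear_sample <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- pmin(floor(r), nr - 1L); r0 <- pmax(r0, 1L)
  c0 <- pmin(floor(c), nc - 1L); c0 <- pmax(c0, 1L)
  fr <- r - r0; fc <- c - c0
  v00 <- m[cbind(r0, c0)]
  v10 <- m[cbind(r0 + 1L, c0)]
  v01 <- m[cbind(r0, c0 + 1L)]
  v11 <- m[cbind(r0 + 1L, c0 + 1L)]
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}

#' Warp a binary mask through a similarity transform
#'
#' Nearest-neighbour warp so pathology regions of interest drawn in one
#' frame apply to the other. Out-of-frame pixels become `FALSE`.
#'
#' @param mask logical (or 0/1) matrix.
#' @param T [similarity_transform()] mapping the mask's frame to the target frame.
#' @param output_shape `(rows, cols)` of the target frame; default `dim(mask)`.
#' @return logical matrix.
#' @export
warp_mask <- function(mask, T, output_shape = dim(mask)) {
  m <- (as.matrix(mask) != 0) * 1.0
  w <- apply_transform(m, T, output_shape = output_shape, interpolation = "nearest")
  w <- img_data(w)
  w[is.na(w)] <- 0
  w != 0
}
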