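# Independent brute-force oracles and small fixture builders. These
# deliberately use plain loops / elementary arithmetic so they share no code
# path with the implementation they check.

brute_mean <- function(v) sum(v) / length(v)

brute_pop_sd <- function(v) {
  m <- brute_mean(v)
  sqrt(sum((v - m)^2) / length(v))
}

# per-position TBR of a profile: x_i / mean(background values)
brute_profile_tbr <- function(intensity, labels) {
  bg <- intensity[labels == "background"]
  out <- numeric(length(intensity))
  for (i in seq_along(intensity)) out[i] <- intensity[i] / brute_mean(bg)
  out
}

# per-position aCNR: (x_i - bg mean) / (2 * bg population SD)
brute_profile_acnr <- function(intensity, labels) {
  bg <- intensity[labels == "background"]
  out <- numeric(length(intensity))
  for (i in seq_along(intensity))
    out[i] <- (intensity[i] - brute_mean(bg)) / (2 * brute_pop_sd(bg))
  out
}

# trapezoid integral with unit abscissa spacing
brute_trapz <- function(v) {
  s <- 0
  for (i in seq_len(length(v) - 1)) s <- s + (v[i] + v[i + 1]) / 2
  s
}

# OLS r-squared from the closed form cov^2 / (var * var)
brute_r2 <- function(a, b) {
  n <- length(a)
  ca <- a - brute_mean(a); cb <- b - brute_mean(b)
  (sum(ca * cb) / n)^2 / ((sum(ca^2) / n) * (sum(cb^2) / n))
}

# smooth test image: isotropic Gaussian blob
gauss_blob <- function(nr, nc, center, sigma, amplitude = 1) {
  r <- matrix(seq_len(nr), nr, nc)
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  amplitude * exp(-((r - center[1])^2 + (c - center[2])^2) / (2 * sigma^2))
}

ellipse_mask_fixture <- function(n, center, radius) {
  r <- matrix(seq_len(n), n, n)
  c <- matrix(seq_len(n), n, n, byrow = TRUE)
  (r - center[1])^2 + (c - center[2])^2 <= radius^2
}

centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  colMeans(idx)
}

# a noise- and blur-free, perfectly aligned slice spec (analytic oracles exact)
clean_spec <- function(tumor_mean_a = 2, bg_mean_a = 1, ...) {
  slice_phantom_spec(
    tumor_mean_a = tumor_mean_a, bg_mean_a = bg_mean_a,
    noise_sd_a = 0, noise_sd_b = 0,
    blur_sigma_a = 0, blur_sigma_b = 0,
    misalignment = similarity_transform(),
    ...)
}
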