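test_that("axis-aligned sub-images equal the corresponding image crop", {
  set.seed(10)
  img <- matrix(runif(40 * 50), 40, 50)
  line <- line_spec(c(20, 10), c(20, 30), width = 5L)
  sub <- extract_subimage(img, line)
  # vertical offsets for a col-direction line: rows 18..22 (perp = (-u2, u1))
  expect_equal(dim(sub), c(5L, 21L))
  expect_equal(sub, img[22:18, 10:30], tolerance = 1e-12)
  # constant image -> constant sub-image, oblique line
  sub_const <- extract_subimage(matrix(3, 40, 50), line_spec(c(10, 8), c(30, 42)))
  expect_equal(as.vector(sub_const), rep(3, length(sub_const)), tolerance = 1e-12)
  expect_error(extract_subimage(img, line_spec(c(1, 10), c(1, 30), width = 5L)),
               "offsets")
})

test_that("bilinear sampling is exact on a linear intensity plane", {
  r <- matrix(seq_len(40), 40, 50)
  c <- matrix(seq_len(50), 40, 50, byrow = TRUE)
  plane <- 0.3 * r - 0.2 * c + 5
  line <- line_spec(c(8.3, 6.1), c(31.7, 41.9), width = 7L)
  sub <- extract_subimage(plane, line)
  g <- fgscontrast:::line_geometry(line)
  for (i in 1:7) {
    off <- i - 4
    rr <- g$centers[, 1] + off * g$v[1]
    cc <- g$centers[, 2] + off * g$v[2]
    expect_equal(sub[i, ], 0.3 * rr - 0.2 * cc + 5, tolerance = 1e-10)
  }
})

test_that("Gaussian collapse is a normalized, symmetric weighted mean", {
  const <- matrix(4.2, 11, 30)
  expect_equal(gaussian_collapse(const), rep(4.2, 30))
  set.seed(11)
  sub <- matrix(runif(11 * 20), 11, 20)
  # infinite sigma -> unweighted row mean
  expect_equal(gaussian_collapse(sub, Inf), colMeans(sub), tolerance = 1e-6)
  # symmetric kernel: flipping the offsets leaves the profile unchanged
  expect_equal(gaussian_collapse(sub[11:1, ]), gaussian_collapse(sub),
               tolerance = 1e-12)
  expect_error(gaussian_collapse(sub[1:10, ]), "odd")
})

test_that("position labels come from the mask with a single-crossing contract", {
  mask <- matrix(FALSE, 50, 60); mask[, 1:30] <- TRUE   # half-plane tumor
  line <- line_spec(c(25, 10), c(25, 50), pixel_pitch = 0.2)
  lab <- label_positions(line, mask)
  expect_equal(lab$labels, c(rep("tumor", 21), rep("background", 20)))
  # analytic boundary at col 30.5 -> 20.5 steps from col 10 -> 4.1 mm
  expect_equal(lab$border_position, 20.5 * 0.2, tolerance = 0.5 * 0.2)
  # reversing the line flips the labels and mirrors the border position
  rev_lab <- label_positions(line_spec(c(25, 50), c(25, 10), pixel_pitch = 0.2), mask)
  expect_equal(rev_lab$labels, rev(lab$labels))
  expect_equal(rev_lab$border_position, 40 * 0.2 - lab$border_position,
               tolerance = 1e-9)
  # a line that never leaves the tumor has no crossing
  expect_error(label_positions(line_spec(c(25, 2), c(25, 20)), mask), "0 crossings")
  # a line crossing in and out has two
  mask2 <- matrix(FALSE, 50, 60); mask2[, 20:40] <- TRUE
  expect_error(label_positions(line_spec(c(25, 10), c(25, 50)), mask2), "2 crossings")
})

test_that("per-position TBR and aCNR match brute-force arithmetic", {
  labels <- c("tumor", "tumor", "tumor", "background", "background", "background")
  intensity <- c(5, 4, 3, 2, 1, 2)
  lp <- line_profile(0:5, intensity, labels)
  t_res <- profile_tbr(lp)
  expect_equal(t_res$values, brute_profile_tbr(intensity, labels))
  expect_equal(t_res$mean, brute_mean(brute_profile_tbr(intensity, labels)))
  a_res <- profile_acnr(lp)
  expect_equal(a_res$values, brute_profile_acnr(intensity, labels))
  expect_equal(a_res$mean, brute_mean(brute_profile_acnr(intensity, labels)))
  # trivial anchors
  const <- line_profile(0:5, rep(2, 6), labels)
  expect_equal(profile_tbr(const)$values, rep(1, 6))
  step <- line_profile(0:5, c(2, 2, 2, 1, 1, 1), labels)
  expect_error(profile_acnr(step), "SD is zero")
  expect_equal(profile_tbr(step)$values, c(2, 2, 2, 1, 1, 1))
  # a value at bg mean + 2 bg SD has per-position aCNR exactly 1
  lab2 <- c("tumor", rep("background", 4))
  bgv <- c(4, 6, 5, 5)
  x <- brute_mean(bgv) + 2 * brute_pop_sd(bgv)
  lp2 <- line_profile(0:4, c(x, bgv), lab2)
  expect_equal(profile_acnr(lp2)$values[1], 1, tolerance = 1e-12)
  expect_equal(profile_acnr(lp2)$values[2:5][bgv == 5][1], 0, tolerance = 1e-12)
})

test_that("the tumor-pixel AUC is the trapezoid rule in pixel units", {
  labels <- c(rep("tumor", 11), rep("background", 4))
  expect_equal(acnr_auc(c(rep(0, 11), 1:4), labels), 0)
  expect_equal(acnr_auc(c(rep(1, 11), 1:4), labels), 10)
  # triangular ramp: half base x height
  tri <- c(0, 1, 2, 3, 4, 5, 4, 3, 2, 1, 0)
  expect_equal(acnr_auc(c(tri, 1:4), labels), 25)
  expect_equal(acnr_auc(c(tri, 1:4), labels), brute_trapz(tri))
  set.seed(12)
  v <- runif(15)
  expect_equal(acnr_auc(v, labels), brute_trapz(v[1:11]))
  expect_error(acnr_auc(1:5, c("tumor", rep("background", 4))), "at least 2 tumor")
})

test_that("the aCNR=1 crossing is the interpolated last tumor-side down-crossing", {
  lab <- c(rep("tumor", 3), rep("background", 3))
  pos <- 0:5
  # entirely below 1: absent
  expect_true(is.na(find_acnr_crossing(rep(0.5, 6), lab, pos)))
  # 1.5 then 0.5: midpoint
  expect_equal(find_acnr_crossing(c(3, 2, 1.5, 0.5, 0.2, 0.1), lab, pos), 2.5)
  # general interpolation between the bracketing samples
  expect_equal(find_acnr_crossing(c(3, 2.5, 2, 0.5, 0.2, 0.1), lab, pos),
               2 + (2 - 1) / (2 - 0.5))
  # a noise spike in the far background does not redefine the border
  lab2 <- c(rep("tumor", 3), rep("background", 5))
  v <- c(3, 1.4, 0.8, 0.5, 1.2, 0.4, 0.3, 0.2)
  expect_equal(find_acnr_crossing(v, lab2, 0:7), 1 + (1.4 - 1) / (1.4 - 0.8))
  # still above 1 at the border: first down-crossing beyond it is used
  v2 <- c(3, 2, 1.8, 1.5, 0.5, 0.2, 0.1, 0.1)
  expect_equal(find_acnr_crossing(v2, lab2, 0:7), 3 + 0.5 / 1)
  expect_error(find_acnr_crossing(c(2, 1), c("background", "tumor"), 0:1),
               "tumor -> background")
})

test_that("crossing distances and agreement percentages follow their definitions", {
  expect_equal(crossing_distance(2.0, 2.0), 0)
  expect_equal(crossing_distance(2.0, 1.8), 0.2)
  expect_equal(crossing_distance(NA_real_, 1.8), NA_real_)
  # pixel pitch 0.1 mm, crossing 3 samples past the border
  expect_equal(crossing_distance(5 + 3 * 0.1, 5), 0.3, tolerance = 1e-12)

  expect_equal(crossing_agreement(c(TRUE, FALSE), c(TRUE, FALSE)),
               list(positive = 100, negative = 100))
  # reference found a crossing in all cases: negative agreement undetermined
  expect_true(is.na(crossing_agreement(c(TRUE, FALSE), c(TRUE, TRUE))$negative))
  # 4 paired outcomes enumerated by hand: ref {T,T,F,F}, test {T,F,T,F}
  ag <- crossing_agreement(c(TRUE, FALSE, TRUE, FALSE), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(ag$positive, 50)
  expect_equal(ag$negative, 50)
  expect_error(crossing_agreement(TRUE, c(TRUE, FALSE)), "equal length")
})

test_that("aCNR profile and crossing are invariant to positive affine intensity maps", {
  set.seed(13)
  lab <- c(rep("tumor", 12), rep("background", 12))
  for (rep in 1:5) {
    base <- c(rnorm(12, 3, 0.3), rnorm(12, 1, 0.3))
    lp1 <- line_profile(0:23, base, lab)
    a <- runif(1, 0.2, 4); b <- runif(1, -1, 1)
    lp2 <- line_profile(0:23, a * base + b, lab)
    r1 <- profile_acnr(lp1); r2 <- profile_acnr(lp2)
    expect_equal(r1$values, r2$values, tolerance = 1e-9)
    c1 <- find_acnr_crossing(r1$values, lab, 0:23)
    c2 <- find_acnr_crossing(r2$values, lab, 0:23)
    expect_equal(c1, c2, tolerance = 1e-9)
  }
})
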