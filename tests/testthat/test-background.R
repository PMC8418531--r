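test_that("box_background returns the mean and sample sd of the box", {
  img <- matrix(7, 40, 40)
  b <- box_background(img, bg_box(2, 2, 10, 10))
  expect_identical(b$mean, 7)
  expect_identical(b$sd, 0)

  img2 <- matrix(rep(c(1, 3), 200), 20, 20)
  b2 <- box_background(img2, bg_box(1, 1, 20, 20))
  expect_equal(b2$mean, 2)
  expect_equal(b2$sd, sd(img2))

  set.seed(5)
  img3 <- matrix(rnorm(10000, 100, 5), 100, 100)
  b3 <- box_background(img3, bg_box(1, 1, 100, 100))
  expect_lt(abs(b3$mean - 100), 0.2)
  expect_lt(abs(b3$sd - 5), 0.2)

  expect_error(box_background(img, bg_box(2, 2, 5, 5)), "minimum")
  m <- matrix(FALSE, 40, 40); m[5, 5] <- TRUE
  expect_error(box_background(img, bg_box(2, 2, 10, 10), mask = m), "overlaps")
})

test_that("mbs_ratio subtracts scalars and flags non-positive denominators", {
  r <- mbs_ratio(matrix(10, 3, 3), matrix(6, 3, 3), 2, 2)
  expect_true(all(r$ratio == 2))
  expect_identical(r$params$n_invalid, 0L)

  expect_warning(r2 <- mbs_ratio(matrix(1, 3, 3), matrix(5, 3, 3), 0, 5),
                 "invalid")
  expect_true(all(r2$invalid))
  expect_true(all(is.na(r2$ratio)))

  expect_error(mbs_ratio(matrix(1, 2, 2), matrix(1, 3, 3), 0, 0), "shape")

  # noise-free wedge with exact backgrounds: ratio is a0 wherever S2 > 0
  sc <- make_wedge_scene(tiny_spec(noise_sigma1 = 0, noise_sigma2 = 0))
  rr <- mbs_ratio(sc$img1, sc$img2, 120, 100)
  inside <- sc$truth$S2_field > 0
  expect_lt(max(abs(rr$ratio[inside] - 0.7)), 1e-12)
})

test_that("halfway background is the midpoint and rejects inconsistent input", {
  expect_identical(halfway_background(100, 100), 100)
  expect_identical(halfway_background(100, 140), 120)
  for (x in c(0, 1, 57.5)) expect_identical(halfway_background(0, 2 * x), x)
  expect_error(halfway_background(100, 90), "inconsistent")
})

test_that("edge intensities are sampled outside the cell in traversal order", {
  img <- matrix(3, 12, 12)
  m <- matrix(FALSE, 12, 12); m[5:8, 5:8] <- TRUE
  ct <- extract_edge_contour(m, "outer")[[1]]
  ct <- sample_edge_intensity(img, ct)
  expect_true(all(ct$raw_intensity == 3))

  # hot pixel on the contour shows up at exactly one traversal index
  img[ct$pixels[4, 1], ct$pixels[4, 2]] <- 99
  ct2 <- sample_edge_intensity(img, extract_edge_contour(m, "outer")[[1]])
  expect_identical(which(ct2$raw_intensity == 99), 4L)

  # background gradient sampled by direct lookup
  grad <- 50 + 2 * row(matrix(0, 12, 12))
  ct3 <- sample_edge_intensity(grad, extract_edge_contour(m, "outer")[[1]])
  expect_identical(ct3$raw_intensity, grad[ct3$pixels])

  ct_in <- extract_edge_contour(m, "inner")[[1]]
  expect_error(sample_edge_intensity(img, ct_in), "outer")
})

test_that("contour Gaussian smoothing preserves constants and matches the kernel", {
  for (sg in c(0.5, 2, 10))
    expect_lt(max(abs(smooth_contour_gaussian(rep(4.2, 50), sg) - 4.2)), 1e-14)

  # unit impulse: output equals the renormalized truncated kernel
  L <- 101; sigma <- 2
  I <- c(1, rep(0, L - 1))
  sm <- smooth_contour_gaussian(I, sigma)
  K <- ceiling(3 * sigma)
  w <- exp(-(-K:K)^2 / (2 * sigma^2)); w <- w / sum(w)
  expected <- numeric(L)
  for (k in -K:K) expected[(k %% L) + 1] <- w[k + K + 1]
  expect_lt(max(abs(sm - expected)), 1e-15)

  # strong smoothing of a periodic signal collapses to its mean
  L2 <- 64
  s <- sin(2 * pi * (0:(L2 - 1)) / L2)
  expect_lt(max(abs(smooth_contour_gaussian(s, 10 * L2))), 1e-3)

  # shift equivariance on closed contours
  set.seed(3)
  I2 <- rnorm(40)
  rot <- function(x, k) c(tail(x, k), head(x, length(x) - k))
  expect_equal(smooth_contour_gaussian(rot(I2, 7), 3),
               rot(smooth_contour_gaussian(I2, 3), 7), tolerance = 1e-12)

  expect_error(smooth_contour_gaussian(1:10, 0), "sigma")
  expect_error(smooth_contour_gaussian(c(1, 2), 1), "3 pixels")
})

test_that("inverse-distance interpolation matches the direct formula", {
  mk_ct <- function(px, vals) structure(
    list(pixels = px, side = "outer", component_id = 1L, closed = TRUE,
         raw_intensity = vals, smoothed_intensity = vals),
    class = "edge_contour")

  dom <- matrix(TRUE, 9, 9)
  one <- mk_ct(matrix(c(5L, 5L), 1, 2), 11)
  f1 <- interpolate_background(one, dom, m = 2)
  expect_true(all(f1 == 11))

  # equidistant point between two contour pixels averages them, any m
  two <- mk_ct(matrix(c(5L, 5L, 3L, 7L), 2, 2), c(10, 20))
  for (m in c(1, 2, 4)) {
    f2 <- interpolate_background(two, dom, m = m)
    expect_equal(f2[4, 5], 15)
  }

  # double-loop oracle on a 64x64 scene
  msk <- disc_mask(64, 15)
  set.seed(2)
  img <- 100 + matrix(rnorm(64 * 64, 0, 5), 64, 64)
  ct <- sample_edge_intensity(img, extract_edge_contour(msk, "outer")[[1]])
  ct <- smooth_edge_intensity(ct, 5)
  f <- interpolate_background(ct, matrix(TRUE, 64, 64), m = 2)
  bf <- matrix(NA_real_, 64, 64)
  for (r in 1:64) for (cc in 1:64) {
    d2 <- (ct$pixels[, 1] - r)^2 + (ct$pixels[, 2] - cc)^2
    bf[r, cc] <- if (any(d2 == 0)) ct$smoothed_intensity[which(d2 == 0)[1]]
                 else sum(ct$smoothed_intensity / d2) / sum(1 / d2)
  }
  expect_lt(max(abs(f - bf)), 1e-9)

  # boundedness: field lies within [min, max] of the contour values
  expect_gte(min(f), min(ct$smoothed_intensity))
  expect_lte(max(f), max(ct$smoothed_intensity))

  expect_error(interpolate_background(ct, matrix(FALSE, 64, 64)), "domain")
})

test_that("nonuniform_ratio reduces to MBS for constant fields and flags strips", {
  sc <- make_wedge_scene(tiny_spec(seed = 4))
  c1 <- matrix(120, 96, 96); c2 <- matrix(100, 96, 96)
  ru <- nonuniform_ratio(sc$img1, sc$img2, c1, c2)
  rm_ <- mbs_ratio(sc$img1, sc$img2, 120, 100)
  expect_identical(ru$ratio, rm_$ratio)
  expect_identical(ru$invalid, rm_$invalid)

  # noise-free wedge with exact per-pixel backgrounds: ratio is a0 on S2 > 0
  sc0 <- make_wedge_scene(tiny_spec(noise_sigma1 = 0, noise_sigma2 = 0))
  r0 <- nonuniform_ratio(sc0$img1, sc0$img2, c1, c2)
  inside <- sc0$truth$S2_field > 0
  expect_lt(max(abs(r0$ratio[inside] - 0.7)), 1e-12)

  # bg2 >= img2 in a strip: those pixels invalid, counted
  big2 <- c2; big2[, 1:5] <- 1e6
  rs <- nonuniform_ratio(sc$img1, sc$img2, c1, big2)
  expect_true(all(rs$invalid[, 1:5]))
  expect_identical(rs$params$n_invalid, sum(rs$invalid))
})

test_that("the full edge-interpolated background is unbiased on a flat background", {
  sc <- make_wedge_scene(tiny_spec(seed = 6))
  f2 <- edge_background_field(sc$img2, sc$truth$mask_true,
                              domain = sc$truth$mask_true)
  vals <- f2[sc$truth$mask_true]
  expect_lt(abs(mean(vals) - 100), 3)   # true B2 = 100
})
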