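test_that("ncf_ratio reduces to the raw ratio at ncf = 0 and is exact with the true NCF", {
  set.seed(1)
  a <- matrix(runif(64, 10, 20), 8, 8)
  b <- matrix(runif(64, 5, 15), 8, 8)
  expect_identical(ncf_ratio(a, b, 0)$ratio, a / b)

  # noise-free generative scene: exact a0 at EVERY pixel, background included
  sc <- make_wedge_scene(tiny_spec(noise_sigma1 = 0, noise_sigma2 = 0))
  r <- ncf_ratio(sc$img1, sc$img2, 50)    # true NCF = 120 - 0.7 * 100
  expect_lt(max(abs(r$ratio - 0.7)), 1e-12)
  expect_identical(sum(r$invalid), 0L)

  # with an activity field, the closed form a0 + a1 S2 / (S2 + B2) holds
  sc2 <- add_edge_band_activity(sc, width_px = 3, amplitude = 0.4)
  r2 <- ncf_ratio(sc2$img1, sc2$img2, 50)
  S2 <- sc2$truth$S2_field
  closed <- 0.7 + sc2$truth$a1_field * S2 / (S2 + 100)
  expect_lt(max(abs(r2$ratio - closed)), 1e-12)
})

test_that("ratio maps match a naive per-pixel loop", {
  set.seed(7)
  a <- matrix(rnorm(256, 100, 10), 16, 16)
  b <- matrix(rnorm(256, 80, 30), 16, 16)
  rm_ <- mbs_ratio(a, b, 12, 60)
  rn <- ncf_ratio(a, b, 12)
  loop_m <- matrix(NA_real_, 16, 16); loop_n <- loop_m
  for (i in 1:16) for (j in 1:16) {
    if (b[i, j] - 60 > 0) loop_m[i, j] <- (a[i, j] - 12) / (b[i, j] - 60)
    if (b[i, j] > 0) loop_n[i, j] <- (a[i, j] - 12) / b[i, j]
  }
  expect_equal(rm_$ratio, loop_m, tolerance = 1e-12)
  expect_equal(rn$ratio, loop_n, tolerance = 1e-12)
})

test_that("fit_proportionality recovers exact and noisy generative parameters", {
  set.seed(11)
  x <- matrix(runif(400, 50, 500), 20, 20)
  all_px <- matrix(TRUE, 20, 20)

  f1 <- fit_proportionality(0.5 * x, x, all_px)
  expect_equal(f1$a0, 0.5, tolerance = 1e-12)
  expect_lt(abs(f1$intercept), 1e-9)
  expect_lt(f1$residual_rms, 1e-9)

  # the exact-line structure behind the single-chain calibration
  f2 <- fit_proportionality(0.63 * x + 53.4, x, all_px)
  expect_equal(f2$a0, 0.63, tolerance = 1e-12)
  expect_equal(f2$intercept, 53.4, tolerance = 1e-9)

  # seeded noisy wedge: a0 within 0.01, intercept within 5% of B1 - a0 B2 = 50
  sc <- make_wedge_scene(tiny_spec(seed = 2, noise_sigma1 = 5, noise_sigma2 = 5))
  f3 <- fit_proportionality(sc$img1, sc$img2, sc$truth$mask_true)
  expect_lt(abs(f3$a0 - 0.7), 0.01)
  expect_lt(abs(f3$intercept - 50), 0.05 * 50)

  expect_error(fit_proportionality(x, matrix(1, 20, 20), all_px), "degenerate")
})

test_that("theoretical_ncf is B1 - a0 * B2", {
  expect_identical(theoretical_ncf(120, 0, 300), 120)
  expect_identical(theoretical_ncf(70, 0.7, 100), 0)
  expect_identical(theoretical_ncf(120, 0.7, 100), 50)
})

test_that("dev_in is zero at the exact NCF and grows away from it", {
  sc <- make_wedge_scene(tiny_spec(noise_sigma1 = 0, noise_sigma2 = 0))
  interior <- distance_from_edge(sc$truth$mask_true) > 10
  d0 <- dev_in(50, sc$img1, sc$img2, 120, 100, interior)
  expect_lt(d0, 1e-24)
  for (delta in c(-10, -1, 1, 10))
    expect_gt(dev_in(50 + delta, sc$img1, sc$img2, 120, 100, interior), d0)
})

test_that("dev_in argmin on a noisy wedge matches a brute-force grid and the truth", {
  sc <- make_wedge_scene(tiny_spec(seed = 3))
  interior <- distance_from_edge(sc$truth$mask_true) > 10
  grid <- c(0, 240, 1000)
  fit <- suppressWarnings(
    optimize_ncf("dev_in", sc$img1, sc$img2, grid = grid,
                 bg1 = 120, bg2 = 100, interior = interior))
  # independent re-evaluation of the objective at every grid point
  cand <- seq(0, 240, length.out = 1000)
  brute <- vapply(cand, dev_in, numeric(1), img1 = sc$img1, img2 = sc$img2,
                  bg1 = 120, bg2 = 100, interior = interior)
  expect_identical(fit$ncf, cand[which.min(brute)])
  expect_lt(abs(fit$ncf - 50) / 50, 0.05)
})

test_that("dev_out vanishes on a noise-free scene at the true NCF", {
  sc <- make_wedge_scene(tiny_spec(noise_sigma1 = 0, noise_sigma2 = 0))
  rs <- build_region_set(sc$truth$mask_true, depth_out = 12,
                         bg_box = tiny_box())
  expect_lt(dev_out(50, sc$img1, sc$img2, 0.7, rs$bg_ring), 1e-20)
  ring_const <- ncf_ratio(sc$img1, sc$img2, 50)$ratio[rs$bg_ring]
  expect_lt(max(abs(ring_const - 0.7)), 1e-12)
})

test_that("per-cell dev_in and dev_out estimates agree on a noisy two-cell scene", {
  sc <- make_two_cell_scene()
  res <- suppressWarnings(
    calibrate_ncf_per_cell(sc$img1, sc$img2, sc$truth$mask_true,
                           bg_box = bg_box(8, 160, 40, 40)))
  for (i in 1:2) {
    true_ncf <- sc$truth$true_ncf[i]
    ncf <- res$per_cell[[i]]$ncf
    expect_lt(abs(ncf[["dev_in"]] - true_ncf) / true_ncf, 0.05)
    expect_lt(abs(ncf[["dev_out"]] - true_ncf) / true_ncf, 0.05)
    expect_lt(abs(ncf[["dev_in"]] - ncf[["dev_out"]]) / ncf[["dev_out"]], 0.10)
  }
})

test_that("optimize_ncf performs exhaustive grid search with documented tie-breaks", {
  fit <- optimize_ncf(function(x) (x - 42)^2, grid = c(0, 100, 1001))
  expect_equal(fit$ncf, 42, tolerance = 1e-9)
  expect_identical(length(fit$dev_curve), 1001L)

  w <- capture_warnings(flat <- optimize_ncf(function(x) 1, grid = c(10, 20, 11)))
  expect_true(any(grepl("tied", w)))
  expect_identical(flat$ncf, 10)

  expect_warning(optimize_ncf(function(x) x, grid = c(0, 1, 5)), "boundary")
  expect_error(optimize_ncf(function(x) NA_real_, grid = c(0, 1, 5)),
               "undefined")
  expect_error(optimize_ncf(function(x) x, grid = c(1, 0, 5)), "lo < hi")
})

test_that("flatness objective is exact on constructed profiles and noise-free scenes", {
  prof <- data.frame(d = 1:3, mean = c(1.0, 1.1, 1.05), std = 0, n = 100)
  expect_equal(relative_range(prof), 0.1, tolerance = 1e-12)
  prof2 <- data.frame(d = 1:3, mean = rep(2, 3), std = 0, n = 100)
  expect_identical(relative_range(prof2), 0)

  sc <- make_wedge_scene(tiny_spec(noise_sigma1 = 0, noise_sigma2 = 0))
  dm <- distance_from_edge(sc$truth$mask_true)
  expect_lt(flatness_objective(50, sc$img1, sc$img2, dm), 1e-12)
})

test_that("flatness grid search matches pointwise objective evaluation", {
  sc <- make_wedge_scene(tiny_spec(seed = 5))
  dm <- distance_from_edge(sc$truth$mask_true)
  grid <- c(20, 80, 61)
  fit <- suppressWarnings(
    optimize_ncf("flatness", sc$img1, sc$img2, grid = grid, distmap = dm))
  cand <- seq(20, 80, length.out = 61)
  brute <- vapply(cand, function(cc)
    tryCatch(flatness_objective(cc, sc$img1, sc$img2, dm),
             error = function(e) NA_real_), numeric(1))
  expect_identical(fit$ncf, cand[which.min(brute)])
  expect_equal(fit$dev_curve, brute, tolerance = 1e-10)
})

test_that("MBS and NCF agree in the high-signal interior within sampling error", {
  # interior restricted to S2 >= 20 * B2 (the deep-cell regime)
  for (s in 1:5) {
    sc <- make_wedge_scene(tiny_spec(seed = s))
    deep <- sc$truth$S2_field >= 20 * 100
    rm_ <- mbs_ratio(sc$img1, sc$img2, 120, 100)
    rn <- ncf_ratio(sc$img1, sc$img2, 50)
    dif <- (rn$ratio - rm_$ratio)[deep & !rm_$invalid]
    se <- sd(dif) / sqrt(length(dif))
    expect_lt(abs(mean(dif)), 3 * se + 1e-12)
  }
})

test_that("the dev_out-optimal NCF levels the ring with the in-cell reference", {
  sc <- make_wedge_scene(tiny_spec(seed = 10))
  rs <- build_region_set(sc$truth$mask_true, depth_in = 8, depth_out = 20,
                         bg_box = tiny_box())
  cal <- suppressWarnings(calibrate_ncf(sc$img1, sc$img2, rs))
  ring_vals <- ncf_ratio(sc$img1, sc$img2,
                         cal$ncf[["dev_out"]])$ratio[rs$bg_ring]
  se <- sd(ring_vals) / sqrt(length(ring_vals))
  # the ring mean carries a second-order Jensen bias ~ a0 (sigma2/B2)^2
  # (E[1/(B2+N2)] > 1/B2); allow it on top of the sampling band
  jensen <- cal$a0_ref * (cal$bg2$sd / cal$bg2$mean)^2
  expect_lt(abs(mean(ring_vals) - cal$a0_ref), 2 * se + jensen)
})

test_that("calibration reports all five estimators and advises on weak proportionality", {
  sc <- make_wedge_scene(tiny_spec(seed = 8))
  rs <- build_region_set(sc$truth$mask_true, depth_in = 8, depth_out = 20,
                         bg_box = tiny_box())
  cal <- suppressWarnings(calibrate_ncf(sc$img1, sc$img2, rs))
  expect_named(cal$ncf, c("theoretical", "fit_intercept", "dev_in",
                          "dev_out", "flatness"))
  expect_true(all(abs(cal$ncf - 50) / 50 < 0.1))

  # dual-chain-like channels: numerator unrelated to denominator
  set.seed(9)
  img1 <- matrix(rnorm(96 * 96, 500, 150), 96, 96)
  expect_message(
    suppressWarnings(calibrate_ncf(img1, sc$img2, rs)),
    "dev_out")
})
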