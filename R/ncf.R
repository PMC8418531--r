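#' Ratio map with noise-correction-factor subtraction
#'
#' `(img1 - ncf) / img2` per pixel, over the whole image including the
#' region outside the cell. No background is subtracted from the
#' denominator, so the ratio never divides by a noise-dominated value: with
#' raw counts `img2 = S2 + B2 + N2` the denominator stays near or above the
#' background level `B2` everywhere. Only pixels with `img2 <= 0` or
#' non-finite inputs are invalid.
#'
#' @param img1,img2 numerator / denominator channels (raw counts, no
#'   background subtracted).
#' @param ncf scalar noise correction factor, `B1 - a0 * B2` in the
#'   generative model.
#' @return a `ratio_result` with method `"NCF"`.
#' @export
ncf_ratio <- function(img1, img2, ncf) {
  .check_image(img1, "img1"); .check_image(img2, "img2")
  if (!all(dim(img1) == dim(img2))) stop("img1 and img2 differ in shape")
  if (!is.finite(ncf)) stop("ncf must be finite")
  .make_ratio_result(img1 - ncf, img2, "NCF", list(ncf = ncf))
}

#' Theoretical noise correction factor
#'
#' `NCF = B1 - a0 * B2`: the constant whose subtraction from the numerator
#' turns the raw-count ratio into `a0` plus attenuated noise, exactly.
#'
#' @param B1,B2 per-channel background levels.
#' @param a0 proportionality coefficient between the pure channel signals.
#' @return scalar NCF.
#' @export
theoretical_ncf <- function(B1, a0, B2) {
  stopifnot(is.finite(B1), is.finite(a0), is.finite(B2))
  B1 - a0 * B2
}

#' Pixelwise proportionality fit between the two channels
#'
#' Ordinary least squares of `img1` on `img2` (with intercept) over the
#' pixels of `region`. Under the generative model
#' `img1 = a0 * img2 + (B1 - a0 * B2) + noise`, the slope estimates `a0`
#' and the intercept is an independent estimate of the NCF.
#'
#' @param img1,img2 channels.
#' @param region logical matrix selecting the pixels to fit (>= 2 pixels
#'   with distinct `img2` values).
#' @return list of class `proportionality_fit`: `a0`, `intercept`,
#'   `n_pixels`, `residual_rms`.
#' @export
fit_proportionality <- function(img1, img2, region) {
  region <- .as_mask(region)
  x <- img2[region]; y <- img1[region]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2 || length(unique(x)) < 2)
    stop("degenerate region: need >= 2 pixels with distinct denominator values")
  fit <- stats::lm.fit(cbind(intercept = 1, slope = x), y)
  structure(list(a0 = unname(fit$coefficients["slope"]),
                 intercept = unname(fit$coefficients["intercept"]),
                 n_pixels = length(x),
                 residual_rms = sqrt(mean(fit$residuals^2))),
            class = "proportionality_fit")
}

#' @export
print.proportionality_fit <- function(x, ...) {
  cat(sprintf("proportionality_fit: a0=%.4f intercept=%.3f (n=%d, rms=%.3f)\n",
              x$a0, x$intercept, x$n_pixels, x$residual_rms))
  invisible(x)
}

#' In-cell deviation objective for NCF selection
#'
#' Mean squared difference between the NCF ratio and the MBS ratio over an
#' off-edge interior region, where both methods should agree. The minimizer
#' over candidate NCF values is the in-cell NCF estimate.
#'
#' @param ncf candidate NCF.
#' @param img1,img2 channels (raw counts).
#' @param bg1,bg2 scalar backgrounds for the MBS reference.
#' @param interior logical matrix, the eroded cell interior.
#' @param min_valid minimum number of pixels valid under both methods.
#' @return scalar mean squared deviation.
#' @export
dev_in <- function(ncf, img1, img2, bg1, bg2, interior, min_valid = 100) {
  interior <- .as_mask(interior)
  if (!any(interior)) stop("interior region is empty")
  r_mbs <- (img1[interior] - bg1) / (img2[interior] - bg2)
  r_ncf <- (img1[interior] - ncf) / img2[interior]
  ok <- is.finite(r_mbs) & is.finite(r_ncf) &
    (img2[interior] - bg2) > 0 & img2[interior] > 0
  if (sum(ok) < min_valid)
    stop("only ", sum(ok), " interior pixels valid under both methods (need ",
         min_valid, ")")
  mean((r_ncf[ok] - r_mbs[ok])^2)
}

#' Background-flattening objective for NCF selection
#'
#' Mean squared deviation of the NCF ratio from the zero-activity reference
#' ratio `a0_ref` over the near-edge background ring: the correct NCF makes
#' the background ratio flat at `a0`. `a0_ref` is typically the mean MBS
#' ratio over the eroded interior.
#'
#' @param ncf candidate NCF.
#' @param img1,img2 channels (raw counts).
#' @param a0_ref zero-activity reference ratio.
#' @param bg_ring logical matrix of near-edge background pixels.
#' @return scalar mean squared deviation.
#' @export
dev_out <- function(ncf, img1, img2, a0_ref, bg_ring) {
  bg_ring <- .as_mask(bg_ring)
  if (!any(bg_ring)) stop("background ring is empty")
  d <- img2[bg_ring]
  ok <- is.finite(d) & d > 0 & is.finite(img1[bg_ring])
  if (!any(ok)) stop("no valid ring pixels (img2 must be > 0 on the ring)")
  r <- (img1[bg_ring][ok] - ncf) / d[ok]
  mean((r - a0_ref)^2)
}

#' Flatness objective for NCF selection
#'
#' Relative range `(max_d<I> - min_d<I>) / min_d<I>` of the NCF ratio's
#' distance profile over `d_range`: zero when the mean ratio is constant at
#' every distance from the edge.
#'
#' @param ncf candidate NCF.
#' @param img1,img2 channels.
#' @param distmap distance-from-edge map of the cell mask (see
#'   [distance_from_edge()]).
#' @param d_range length-2 integer range of distance bins to use (default:
#'   all populated bins).
#' @param min_bin_count minimum pixels per distance bin.
#' @return scalar relative range.
#' @export
flatness_objective <- function(ncf, img1, img2, distmap, d_range = NULL,
                               min_bin_count = 50) {
  r <- ncf_ratio(img1, img2, ncf)
  p <- distance_profile(r, distmap, min_bin_count = min_bin_count)
  if (!is.null(d_range)) p <- p[p$d >= d_range[1] & p$d <= d_range[2], ]
  if (nrow(p) < 2) stop("fewer than 2 populated distance bins in d_range")
  relative_range(p)
}

# per-bin means of the NCF ratio are linear in the candidate:
# mean_b(c) = mean_b(img1/img2) - c * mean_b(1/img2); precompute both.
.flatness_curve <- function(candidates, img1, img2, distmap, d_range,
                            min_bin_count) {
  sel <- distmap > 0 & is.finite(img1) & is.finite(img2) & img2 > 0
  if (!any(sel)) return(rep(NA_real_, length(candidates)))
  bins <- ceiling(distmap[sel])
  u <- img1[sel] / img2[sel]
  v <- 1 / img2[sel]
  n_b <- tapply(u, bins, length)
  keep <- n_b >= min_bin_count
  d_vals <- as.integer(names(n_b))
  if (!is.null(d_range)) keep <- keep & d_vals >= d_range[1] & d_vals <= d_range[2]
  if (sum(keep) < 2) return(rep(NA_real_, length(candidates)))
  A <- tapply(u, bins, mean)[keep]
  B <- tapply(v, bins, mean)[keep]
  vapply(candidates, function(cc) {
    m <- A - cc * B
    mn <- min(m)
    if (mn <= 0) NA_real_ else (max(m) - mn) / mn
  }, numeric(1))
}

#' Grid-search NCF optimization
#'
#' Exhaustively evaluates one of the selection objectives over a uniform
#' grid of candidate NCF values and returns the argmin with the full
#' objective curve for auditing. Ties break toward the smallest candidate;
#' an argmin on the grid boundary triggers a warning that the interval is
#' probably too narrow.
#'
#' @param objective `"dev_in"`, `"dev_out"`, `"flatness"`, or a function
#'   of one scalar NCF candidate returning the objective value (`NA` where
#'   undefined).
#' @param img1,img2 channels (raw counts).
#' @param grid numeric `c(lo, hi, n_steps)` with `lo < hi`, `n_steps >= 2`.
#'   Default: 1001 candidates spanning `[0, 2 * mean(img1)]`.
#' @param bg1,bg2 scalar backgrounds (dev_in only).
#' @param interior interior mask (dev_in only).
#' @param a0_ref zero-activity reference ratio (dev_out only).
#' @param bg_ring near-edge background mask (dev_out only).
#' @param distmap distance map (flatness only).
#' @param d_range,min_bin_count distance-profile controls (flatness only).
#' @param min_valid dev_in valid-pixel floor.
#' @return list of class `ncf_fit`: `ncf`, `objective`, `grid` (candidate
#'   values), `dev_curve`, `a0_used`.
#' @export
optimize_ncf <- function(objective = c("dev_in", "dev_out", "flatness"),
                         img1 = NULL, img2 = NULL, grid = NULL,
                         bg1 = NULL, bg2 = NULL, interior = NULL,
                         a0_ref = NULL, bg_ring = NULL,
                         distmap = NULL, d_range = NULL, min_bin_count = 50,
                         min_valid = 100) {
  obj_fun <- NULL
  if (is.function(objective)) {
    obj_fun <- objective
    objective <- "custom"
  } else {
    objective <- match.arg(objective)
  }
  if (is.null(grid)) {
    if (is.null(img1)) stop("a custom objective needs an explicit grid")
    grid <- c(0, 2 * mean(img1[is.finite(img1)]), 1001)
  }
  lo <- grid[1]; hi <- grid[2]; n <- as.integer(grid[3])
  if (n < 2) stop("grid needs at least 2 steps")
  if (!(lo < hi)) stop("grid must have lo < hi")
  cand <- seq(lo, hi, length.out = n)
  a0_used <- NULL
  if (objective == "dev_in") {
    interior <- .as_mask(interior)
    x1 <- img1[interior]; x2 <- img2[interior]
    r_mbs <- (x1 - bg1) / (x2 - bg2)
    ok <- is.finite(x1) & is.finite(x2) & (x2 - bg2) > 0 & x2 > 0
    if (sum(ok) < min_valid)
      stop("only ", sum(ok), " interior pixels valid under both methods")
    u <- x1[ok] / x2[ok]; v <- 1 / x2[ok]; w <- u - r_mbs[ok]
    mww <- mean(w^2); mwv <- mean(w * v); mvv <- mean(v^2)
    curve <- mww - 2 * cand * mwv + cand^2 * mvv
  } else if (objective == "dev_out") {
    bg_ring <- .as_mask(bg_ring)
    x1 <- img1[bg_ring]; x2 <- img2[bg_ring]
    ok <- is.finite(x1) & is.finite(x2) & x2 > 0
    if (!any(ok)) stop("no valid ring pixels")
    u <- x1[ok] / x2[ok]; v <- 1 / x2[ok]; w <- u - a0_ref
    mww <- mean(w^2); mwv <- mean(w * v); mvv <- mean(v^2)
    curve <- mww - 2 * cand * mwv + cand^2 * mvv
    a0_used <- a0_ref
  } else if (objective == "flatness") {
    if (is.null(distmap)) stop("flatness objective needs a distmap")
    curve <- .flatness_curve(cand, img1, img2, distmap, d_range, min_bin_count)
  } else {
    curve <- vapply(cand, function(cc)
      tryCatch(obj_fun(cc), error = function(e) NA_real_), numeric(1))
  }
  if (all(is.na(curve))) stop("objective undefined at every grid point")
  best <- which.min(curve)  # first minimum = smallest candidate on ties
  if (sum(curve == curve[best], na.rm = TRUE) > 1)
    warning("tied objective minima; returning the smallest candidate")
  if (best == 1L || best == n)
    warning("argmin lies on the grid boundary; widen the search interval")
  structure(list(ncf = cand[best], objective = objective, grid = cand,
                 dev_curve = curve, a0_used = a0_used),
            class = "ncf_fit")
}

#' @export
print.ncf_fit <- function(x, ...) {
  cat(sprintf("ncf_fit: NCF=%.4g by %s (grid of %d over [%.4g, %.4g])\n",
              x$ncf, x$objective, length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

#' Estimate the NCF by every available route
#'
#' Runs the full calibration on one scene: distant backgrounds from the
#' box, the pixelwise proportionality fit (slope `a0`, intercept = NCF
#' estimate), the theoretical NCF from the fitted `a0` and the box
#' backgrounds, and grid minimization of the in-cell deviation, the
#' background-flattening deviation, and the flatness metric. All five
#' estimates are reported side by side; none is declared canonical.
#'
#' When the proportionality fit is weak (`residual_rms` large relative to
#' the fitted signal span, as for dual-chain biosensors), an advisory
#' message recommends the background-flattening (dev_out) estimate; the
#' objective is never switched silently.
#'
#' @param img1,img2 channels (raw counts).
#' @param regions a `region_set` (with `bg_box` set).
#' @param grid optional `c(lo, hi, n)` candidate grid.
#' @param d_range,min_bin_count flatness-profile controls.
#' @return list of class `ncf_calibration`: `bg1`, `bg2`, `fit`,
#'   `a0_ref`, `ncf` (named vector: theoretical, fit_intercept, dev_in,
#'   dev_out, flatness), and the three `ncf_fit` objects.
#' @export
calibrate_ncf <- function(img1, img2, regions, grid = NULL,
                          d_range = NULL, min_bin_count = 50) {
  if (!inherits(regions, "region_set")) stop("regions must be a region_set")
  if (is.null(regions$bg_box)) stop("calibration needs a bg_box in the region set")
  b1 <- box_background(img1, regions$bg_box, mask = regions$mask)
  b2 <- box_background(img2, regions$bg_box, mask = regions$mask)
  if (is.null(grid)) grid <- c(0, 2 * b1$mean, 1001)
  fit <- fit_proportionality(img1, img2, regions$mask)
  ncf_theo <- theoretical_ncf(b1$mean, fit$a0, b2$mean)
  r_mbs <- mbs_ratio(img1, img2, b1$mean, b2$mean)
  a0_ref <- mean(r_mbs$ratio[regions$interior & !r_mbs$invalid])
  dmap <- distance_from_edge(regions$mask)
  f_in <- optimize_ncf("dev_in", img1, img2, grid = grid,
                       bg1 = b1$mean, bg2 = b2$mean,
                       interior = regions$interior)
  f_out <- optimize_ncf("dev_out", img1, img2, grid = grid,
                        a0_ref = a0_ref, bg_ring = regions$bg_ring)
  f_flat <- optimize_ncf("flatness", img1, img2, grid = grid,
                         distmap = dmap, d_range = d_range,
                         min_bin_count = min_bin_count)
  rel_rms <- fit$residual_rms / (abs(fit$a0) * stats::sd(img2[regions$mask]))
  if (is.finite(rel_rms) && rel_rms > 0.5)
    message("weak channel proportionality (relative residual ",
            sprintf("%.2f", rel_rms),
            "): prefer the dev_out (background-flattening) estimate")
  structure(list(
    bg1 = b1, bg2 = b2, fit = fit, a0_ref = a0_ref,
    ncf = c(theoretical = ncf_theo, fit_intercept = fit$intercept,
            dev_in = f_in$ncf, dev_out = f_out$ncf, flatness = f_flat$ncf),
    fit_dev_in = f_in, fit_dev_out = f_out, fit_flatness = f_flat),
    class = "ncf_calibration")
}

#' @export
print.ncf_calibration <- function(x, ...) {
  cat("ncf_calibration (a0 =", sprintf("%.4f", x$fit$a0), ")\n")
  print(round(x$ncf, 4))
  invisible(x)
}

#' Per-cell NCF calibration
#'
#' Splits the mask into 8-connected components and calibrates each cell
#' separately with its own interior and background ring (the ring excludes
#' every cell in the scene); a pooled scene-global calibration is returned
#' alongside.
#'
#' @param img1,img2 channels.
#' @param mask full scene mask (all cells).
#' @param depth_in,depth_out region depths, px.
#' @param bg_box distant-background [bg_box()].
#' @param grid optional candidate grid.
#' @return list with `per_cell` (list of `ncf_calibration`) and `global`.
#' @export
calibrate_ncf_per_cell <- function(img1, img2, mask, depth_in = 10,
                                   depth_out = 50, bg_box, grid = NULL) {
  mask <- .as_mask(mask)
  lab <- label_components(mask)
  per_cell <- lapply(seq_len(max(lab)), function(id) {
    comp <- lab == id
    rs <- build_region_set(comp, depth_in = depth_in, depth_out = depth_out,
                           bg_box = bg_box)
    rs$bg_ring <- rs$bg_ring & !mask   # exclude every cell in the scene
    calibrate_ncf(img1, img2, rs, grid = grid)
  })
  rs_all <- build_region_set(mask, depth_in = depth_in, depth_out = depth_out,
                             bg_box = bg_box)
  list(per_cell = per_cell,
       global = calibrate_ncf(img1, img2, rs_all, grid = grid))
}
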