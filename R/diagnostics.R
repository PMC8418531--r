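#' Mean ratio as a function of distance from the cell edge
#'
#' Valid in-mask pixels are binned by the ceiling of their Euclidean
#' distance to the edge into integer bins 1..`max_d` (bin 1 is the
#' innermost contour layer); bins with fewer than `min_bin_count` pixels
#' are dropped.
#'
#' @param ratio a `ratio_result` (or plain numeric matrix).
#' @param distmap distance-from-edge map of the same mask.
#' @param max_d largest bin to report (default: all).
#' @param min_bin_count minimum pixels per bin (default 50).
#' @return data.frame of class `distance_profile`: columns `d`, `mean`,
#'   `std`, `n`.
#' @export
distance_profile <- function(ratio, distmap, max_d = NULL, min_bin_count = 50) {
  r <- if (inherits(ratio, "ratio_result")) ratio$ratio else ratio
  if (!all(dim(r) == dim(distmap))) stop("ratio and distmap differ in shape")
  sel <- distmap > 0 & is.finite(r)
  if (!any(sel)) stop("no valid in-mask pixels to profile")
  bins <- ceiling(distmap[sel])
  vals <- r[sel]
  if (!is.null(max_d)) {
    keep <- bins <= max_d
    bins <- bins[keep]; vals <- vals[keep]
  }
  n <- tapply(vals, bins, length)
  m <- tapply(vals, bins, mean)
  s <- tapply(vals, bins, stats::sd)
  d <- as.integer(names(n))
  ok <- n >= min_bin_count
  if (!any(ok)) stop("no distance bin reaches min_bin_count = ", min_bin_count)
  out <- data.frame(d = d[ok], mean = as.numeric(m[ok]),
                    std = as.numeric(s[ok]), n = as.integer(n[ok]))
  out$std[is.na(out$std)] <- 0
  class(out) <- c("distance_profile", "data.frame")
  out
}

#' Relative range of a distance profile (flatness metric)
#'
#' `(max_d<I> - min_d<I>) / min_d<I>` over the reported bins; zero for a
#' perfectly flat profile.
#'
#' @param profile a `distance_profile` (or data.frame with a `mean` column).
#' @return scalar relative range.
#' @export
relative_range <- function(profile) {
  m <- profile$mean
  if (length(m) < 2) stop("relative range needs at least 2 bins")
  if (min(m) <= 0) stop("relative range undefined: minimum bin mean <= 0")
  (max(m) - min(m)) / min(m)
}

#' Band statistics along the cell edge
#'
#' Pixels are grouped into 1-px-wide bands by signed distance from the cell
#' edge: offset 0 is the innermost in-mask layer (distance to background in
#' (0, 1]), positive offsets move inward (offset k = distance in
#' (k, k+1]), negative offsets move outward into the background (offset -k
#' = complement distance in (k-1, k]). Each band is compared with the next
#' band inward by a two-sided Welch two-sample t-test; raw and
#' Bonferroni-adjusted p-values are both reported. Negative offsets
#' require a ratio defined outside the cell, i.e. the NCF method.
#'
#' @param ratio a `ratio_result` (or numeric matrix).
#' @param mask logical cell mask.
#' @param offsets contiguous integer offsets, e.g. `-2:4`.
#' @return data.frame of class `band_stats`: `offset`, `mean`, `se`, `n`,
#'   `t`, `p`, `p_bonferroni` (p-values vs the next band inward; `NA` for
#'   the innermost band or empty bands).
#' @export
edge_band_stats <- function(ratio, mask, offsets) {
  r <- if (inherits(ratio, "ratio_result")) ratio$ratio else ratio
  mask <- .as_mask(mask)
  offsets <- sort(unique(as.integer(offsets)))
  if (!all(diff(offsets) == 1)) stop("offsets must be contiguous integers")
  if (any(offsets < 0) && inherits(ratio, "ratio_result") &&
      ratio$method == "MBS")
    warning("negative offsets with an MBS ratio: values outside the cell are noise/noise")
  d_in <- distance_from_edge(mask)
  d_out <- distance_from_edge(!mask)
  band_values <- lapply(offsets, function(k) {
    sel <- if (k >= 0) mask & ceiling(d_in) == k + 1
           else (!mask) & ceiling(d_out) == -k
    v <- r[sel]
    v[is.finite(v)]
  })
  n <- vapply(band_values, length, integer(1))
  mu <- vapply(band_values, function(v) if (length(v)) mean(v) else NA_real_,
               numeric(1))
  se <- vapply(band_values, function(v)
    if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_, numeric(1))
  tt <- rep(NA_real_, length(offsets)); pp <- rep(NA_real_, length(offsets))
  for (i in seq_along(offsets)) {
    j <- i + 1L  # next band inward
    if (j > length(offsets)) next
    a <- band_values[[i]]; b <- band_values[[j]]
    if (length(a) > 1 && length(b) > 1) {
      if (stats::sd(a) > 0 || stats::sd(b) > 0) {
        ht <- stats::t.test(a, b, var.equal = FALSE)
        tt[i] <- unname(ht$statistic); pp[i] <- ht$p.value
      } else if (mean(a) == mean(b)) {
        tt[i] <- 0; pp[i] <- 1   # identical constants: no evidence of difference
      } else {
        tt[i] <- sign(mean(a) - mean(b)) * Inf; pp[i] <- 0
      }
    }
  }
  ntests <- sum(is.finite(pp))
  out <- data.frame(offset = offsets, mean = mu, se = se, n = n,
                    t = tt, p = pp,
                    p_bonferroni = pmin(1, pp * max(1, ntests)))
  class(out) <- c("band_stats", "data.frame")
  attr(out, "test") <- "Welch two-sample t-test, two-sided, vs next band inward"
  out
}

#' Classify pixels by intensity against background statistics
#'
#' `in_cell`: intensity at or above the mask threshold; `background`:
#' intensity below the background mean plus three standard deviations;
#' `near_edge_bg`: in between (the boundary value `bg_mean + 3 bg_sd`
#' belongs to the middle class). The labels partition all pixels.
#'
#' @param image numeric matrix.
#' @param mask_threshold intensity defining the cell mask.
#' @param bg_mean,bg_sd background-box statistics.
#' @return integer matrix (0 = background, 1 = near_edge_bg, 2 = in_cell)
#'   with attribute `levels`.
#' @export
classify_pixels <- function(image, mask_threshold, bg_mean, bg_sd) {
  .check_image(image)
  if (bg_sd < 0) stop("bg_sd must be >= 0")
  cut_bg <- bg_mean + 3 * bg_sd
  if (mask_threshold < cut_bg)
    warning("mask threshold below bg_mean + 3 sd: near_edge_bg class is empty by construction")
  lab <- matrix(0L, nrow(image), ncol(image))
  lab[image >= cut_bg] <- 1L
  lab[image >= mask_threshold] <- 2L
  attr(lab, "levels") <- c("background", "near_edge_bg", "in_cell")
  lab
}

#' Compose a ratio map for display
#'
#' `bg_to_mean` replaces every out-of-mask pixel by the mean valid in-mask
#' ratio before color scaling, so in-cell variation is visible against a
#' neutral background (display only — never fed back into statistics);
#' `raw` leaves values untouched. Scale bounds are the in-mask 1st/99th
#' percentiles.
#'
#' @param ratio a `ratio_result` (or numeric matrix).
#' @param mask logical cell mask.
#' @param mode `"raw"` or `"bg_to_mean"`.
#' @return list: `display` (matrix), `bounds` (length-2 numeric).
#' @export
render_ratio_map <- function(ratio, mask, mode = c("raw", "bg_to_mean")) {
  mode <- match.arg(mode)
  r <- if (inherits(ratio, "ratio_result")) ratio$ratio else ratio
  mask <- .as_mask(mask)
  inside <- r[mask]
  inside <- inside[is.finite(inside)]
  if (length(inside) == 0) stop("no valid in-mask ratio pixel to render")
  disp <- r
  if (mode == "bg_to_mean") disp[!mask] <- mean(inside)
  bounds <- unname(stats::quantile(inside, c(0.01, 0.99)))
  list(display = disp, bounds = bounds)
}

#' Monotone-trend diagnostic over the background ring
#'
#' Detects a spatially graded (shade-like) artifact: ring pixels are
#' projected onto `direction`, grouped into `n_bins` equal-count bins, and
#' the Spearman correlation between the bin-mean ratio and the bin-mean
#' projection is returned. Near +/-1 for a monotone shade bias, near 0 for
#' a clean background.
#'
#' @param ratio a `ratio_result` (or numeric matrix; NCF method, since the
#'   ratio must be meaningful outside the cell).
#' @param bg_ring logical matrix of near-edge background pixels.
#' @param direction length-2 numeric, the gradient axis (row, col).
#' @param n_bins number of projection bins (default 16).
#' @return list: `rho` (Spearman), `bins` (data.frame projection/mean/n).
#' @export
ring_gradient_trend <- function(ratio, bg_ring, direction, n_bins = 16) {
  r <- if (inherits(ratio, "ratio_result")) ratio$ratio else ratio
  bg_ring <- .as_mask(bg_ring)
  if (sum(direction^2) == 0) stop("direction must be a nonzero vector")
  u <- direction / sqrt(sum(direction^2))
  idx <- which(bg_ring & is.finite(r))
  if (length(idx) < n_bins * 2) stop("too few valid ring pixels")
  rr <- (idx - 1) %% nrow(r) + 1
  cc <- (idx - 1) %/% nrow(r) + 1
  proj <- rr * u[1] + cc * u[2]
  q <- stats::quantile(proj, probs = seq(0, 1, length.out = n_bins + 1))
  grp <- cut(proj, breaks = unique(q), include.lowest = TRUE)
  bins <- data.frame(
    projection = as.numeric(tapply(proj, grp, mean)),
    mean = as.numeric(tapply(r[idx], grp, mean)),
    n = as.integer(tapply(proj, grp, length)))
  rho <- stats::cor(bins$projection, bins$mean, method = "spearman")
  list(rho = rho, bins = bins)
}
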