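#' Mean and standard deviation of a distant background box
#'
#' @param image numeric matrix.
#' @param box a [bg_box()].
#' @param mask optional logical matrix; the box must not overlap it.
#' @param min_area minimum box area in pixels.
#' @return list(mean, sd, n).
#' @export
box_background <- function(image, box, mask = NULL, min_area = 100) {
  .check_image(image)
  bi <- .box_indices(box, dim(image))
  vals <- image[bi$rows, bi$cols]
  if (length(vals) < min_area)
    stop("background box has only ", length(vals), " px (minimum ", min_area, ")")
  if (!is.null(mask) && any(.as_mask(mask)[bi$rows, bi$cols]))
    stop("background box overlaps the cell mask")
  list(mean = mean(vals), sd = stats::sd(as.numeric(vals)), n = length(vals))
}

.make_ratio_result <- function(num, den, method, params) {
  invalid <- !is.finite(num) | !is.finite(den) | den <= 0
  ratio <- num / den
  ratio[invalid] <- NA_real_
  params$n_invalid <- sum(invalid)
  if (all(invalid)) warning("all pixels invalid (denominator <= 0 everywhere)")
  structure(list(ratio = ratio, method = method, invalid = invalid,
                 params = params),
            class = "ratio_result")
}

#' @export
print.ratio_result <- function(x, ...) {
  cat(sprintf("ratio_result (%s): %d x %d, %d invalid px\n",
              x$method, nrow(x$ratio), ncol(x$ratio), sum(x$invalid)))
  invisible(x)
}

#' Ratio map with mean background subtraction (MBS)
#'
#' `(img1 - bg1) / (img2 - bg2)` per pixel. Pixels where the subtracted
#' denominator is non-positive (or either input non-finite) are flagged
#' invalid and set to `NA`.
#'
#' @param img1,img2 numerator / denominator channels (numeric matrices,
#'   equal shape).
#' @param bg1,bg2 scalar background estimates per channel.
#' @return a `ratio_result`.
#' @export
mbs_ratio <- function(img1, img2, bg1, bg2) {
  .check_image(img1, "img1"); .check_image(img2, "img2")
  if (!all(dim(img1) == dim(img2))) stop("img1 and img2 differ in shape")
  .make_ratio_result(img1 - bg1, img2 - bg2, "MBS",
                     list(bg1 = bg1, bg2 = bg2))
}

#' Halfway background level
#'
#' The midpoint between the distant background value and the intensity used
#' to define the cell mask (the value right at the cell edge) — the
#' elevated-background baseline.
#'
#' @param distant_mean distant-background mean.
#' @param mask_threshold_value mask threshold intensity (must be >=
#'   `distant_mean`).
#' @return scalar.
#' @export
halfway_background <- function(distant_mean, mask_threshold_value) {
  if (mask_threshold_value < distant_mean)
    stop("mask threshold (", format(mask_threshold_value),
         ") below distant background (", format(distant_mean), "): inconsistent")
  (distant_mean + mask_threshold_value) / 2
}

#' Sample intensities along an outer edge contour
#'
#' Fills `raw_intensity` with the image value at each contour pixel, in
#' traversal order. Backgrounds must be sampled just outside the cell, so
#' only outer-side contours are accepted.
#'
#' @param image numeric matrix.
#' @param contour an `edge_contour` with `side = "outer"`.
#' @return the contour with `raw_intensity` filled.
#' @export
sample_edge_intensity <- function(image, contour) {
  .check_image(image)
  if (!inherits(contour, "edge_contour")) stop("contour must be an edge_contour")
  if (contour$side != "outer")
    stop("background must be sampled outside the cell: pass an outer-side contour")
  contour$raw_intensity <- image[contour$pixels]
  contour
}

#' Gaussian smoothing of a signal along a contour
#'
#' Convolution with a Gaussian kernel `exp(-(i-j)^2 / (2 sigma^2))`
#' truncated at +/- 3 sigma and renormalized to sum to 1, so constants are
#' preserved exactly. Closed contours use circular (periodic) indexing;
#' open contours use reflective padding.
#'
#' @param I numeric vector of per-contour-pixel values (length >= 3).
#' @param sigma smoothing scale in contour-pixel units (> 0).
#' @param closed treat the contour as a closed loop.
#' @return numeric vector, same length as `I`.
#' @export
smooth_contour_gaussian <- function(I, sigma, closed = TRUE) {
  if (sigma <= 0) stop("sigma must be > 0")
  L <- length(I)
  if (L < 3) stop("contour must have at least 3 pixels")
  K <- ceiling(3 * sigma)
  j <- -K:K
  w <- exp(-j^2 / (2 * sigma^2))
  w <- w / sum(w)
  out <- numeric(L)
  idx0 <- seq_len(L)
  for (k in seq_along(j)) {
    idx <- idx0 + j[k]
    if (closed) {
      idx <- (idx - 1L) %% L + 1L
    } else {
      # whole-sample reflection at both ends, repeated until in range
      while (any(idx < 1L | idx > L)) {
        idx <- ifelse(idx < 1L, 2L - idx, idx)
        idx <- ifelse(idx > L, 2L * L - idx, idx)
      }
    }
    out <- out + w[k] * I[idx]
  }
  out
}

#' Smooth a contour's sampled intensities
#'
#' Convenience wrapper filling `smoothed_intensity` from `raw_intensity`.
#'
#' @param contour an `edge_contour` with `raw_intensity` filled.
#' @param sigma smoothing scale, contour-pixel units.
#' @return the contour with `smoothed_intensity` filled.
#' @export
smooth_edge_intensity <- function(contour, sigma = 10) {
  if (is.null(contour$raw_intensity)) stop("raw_intensity not filled")
  contour$smoothed_intensity <-
    smooth_contour_gaussian(contour$raw_intensity, sigma,
                            closed = isTRUE(contour$closed))
  contour
}

#' Inverse-distance interpolation of edge background into the image
#'
#' `BG(x, y) = sum_i Ibar(i) / d_i(x,y)^m / sum_i 1 / d_i(x,y)^m`, where
#' `d_i` is the Euclidean distance from contour pixel `i` to `(x, y)` and
#' `m` controls how deep the edge values extend before averaging out. At a
#' pixel coinciding with a contour pixel the value is that pixel's
#' `Ibar` exactly.
#'
#' @param contours an `edge_contour` with `smoothed_intensity` filled, or a
#'   list of them (components are pooled).
#' @param domain logical matrix: where to evaluate (default everywhere).
#' @param m inverse-distance exponent (> 0), default 2.
#' @param subsample use every k-th contour pixel (default 1 = all).
#' @return numeric matrix, `NA` outside the domain, with attribute `params`.
#' @export
interpolate_background <- function(contours, domain, m = 2, subsample = 1) {
  if (inherits(contours, "edge_contour")) contours <- list(contours)
  if (m <= 0) stop("m must be > 0")
  px <- do.call(rbind, lapply(contours, function(ct) {
    if (is.null(ct$smoothed_intensity)) stop("smoothed_intensity not filled")
    cbind(ct$pixels, ct$smoothed_intensity)
  }))
  if (is.null(px) || nrow(px) == 0L) stop("empty contour")
  if (subsample > 1) px <- px[seq(1, nrow(px), by = subsample), , drop = FALSE]
  domain <- .as_mask(domain)
  if (!any(domain)) stop("empty domain")
  out <- matrix(NA_real_, nrow(domain), ncol(domain))
  didx <- which(domain)
  dr <- (didx - 1L) %% nrow(domain) + 1L
  dc <- (didx - 1L) %/% nrow(domain) + 1L
  cr <- px[, 1]; cc <- px[, 2]; Ibar <- px[, 3]
  # |p - q|^2 expanded through tcrossprod: all terms are integers held in
  # doubles, so this is exact, and the BLAS product is much faster than outer()
  tt <- cr^2 + cc^2
  dd <- dr^2 + dc^2
  chunk <- max(1L, floor(4e6 / nrow(px)))
  for (s in seq(1, length(didx), by = chunk)) {
    e <- min(s + chunk - 1L, length(didx))
    G <- tcrossprod(cbind(dr[s:e], dc[s:e]), cbind(cr, cc))
    D2 <- (dd[s:e] - 2 * G) + rep(tt, each = e - s + 1L)
    # rows with a zero distance would give Inf weights (and stall the BLAS
    # multiply); give them a dummy weight, they are overwritten exactly below
    D2[D2 == 0] <- 1
    W <- if (m == 2) 1 / D2 else D2^(-m / 2)
    out[didx[s:e]] <- as.numeric((W %*% Ibar) / rowSums(W))
  }
  # pixels coinciding with a contour pixel take that pixel's value exactly
  # (first traversal occurrence on duplicates)
  hit <- domain[cbind(cr, cc)] & !duplicated(cbind(cr, cc))
  out[cbind(cr[hit], cc[hit])] <- Ibar[hit]
  attr(out, "params") <- list(m = m, subsample = subsample,
                              n_contour_px = nrow(px))
  out
}

#' Ratio map with nonuniform (per-pixel) background subtraction
#'
#' `(img1 - bg1_field) / (img2 - bg2_field)` per pixel, with the same
#' invalid-pixel contract as [mbs_ratio()].
#'
#' @param img1,img2 channels.
#' @param bg1_field,bg2_field per-pixel background maps (matrices).
#' @return a `ratio_result`.
#' @export
nonuniform_ratio <- function(img1, img2, bg1_field, bg2_field) {
  .check_image(img1, "img1"); .check_image(img2, "img2")
  if (!all(dim(img1) == dim(img2)) || !all(dim(img1) == dim(bg1_field)) ||
      !all(dim(img1) == dim(bg2_field)))
    stop("images and background fields differ in shape")
  .make_ratio_result(img1 - bg1_field, img2 - bg2_field, "nonuniform",
                     list(bg1_field = "per-pixel", bg2_field = "per-pixel"))
}

#' One-call nonuniform background field for a masked image
#'
#' Samples the intensity just outside the mask, smooths it along the
#' contour, and interpolates inward — the full edge-interpolated background
#' pipeline for one channel.
#'
#' @param image numeric matrix.
#' @param mask logical cell mask.
#' @param sigma contour smoothing scale (contour px), default 10.
#' @param m interpolation exponent, default 2.
#' @param domain evaluation domain (default: full image).
#' @param subsample contour subsampling stride.
#' @return background field matrix.
#' @export
edge_background_field <- function(image, mask, sigma = 10, m = 2,
                                  domain = NULL, subsample = 1) {
  if (is.null(domain)) domain <- matrix(TRUE, nrow(image), ncol(image))
  cts <- extract_edge_contour(mask, side = "outer")
  cts <- lapply(cts, function(ct) {
    ct <- sample_edge_intensity(image, ct)
    smooth_edge_intensity(ct, sigma = sigma)
  })
  interpolate_background(cts, domain, m = m, subsample = subsample)
}
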