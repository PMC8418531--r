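#' Specification of a synthetic two-channel scene
#'
#' The generative model is the wedge cell: a cell whose thickness — hence
#' pure denominator signal `S2` — rises linearly from zero at the edge to a
#' plateau over `ramp_width` pixels. Channels are assembled as
#' `img1 = (a0 + a1) * S2 + B1 + shade1 + noise1` and
#' `img2 = S2 + B2 + shade2 + noise2`, with zero-mean Gaussian noise left
#' unclipped so the algebraic identities of the NCF method hold exactly.
#' The true NCF of each cell is `B1 - a0 * B2`.
#'
#' @param shape image dimensions c(rows, cols).
#' @param cells list of cell geometries; each is either
#'   `list(center = c(row, col), radius = r)` (disc) or
#'   `list(vertices = <n x 2 matrix>)` (polygon).
#' @param ramp_width px over which `S2` rises from 0 to the plateau.
#' @param s2_plateau denominator pure-signal plateau.
#' @param a0 proportionality coefficient(s), recycled per cell.
#' @param B1,B2 per-channel additive background constants.
#' @param noise_sigma1,noise_sigma2 Gaussian noise scales.
#' @param seed integer RNG seed.
#' @return list of class `scene_spec`.
#' @export
scene_spec <- function(shape = c(256, 256),
                       cells = list(list(center = c(128, 128), radius = 80)),
                       ramp_width = 20, s2_plateau = 2000, a0 = 0.7,
                       B1 = 120, B2 = 100,
                       noise_sigma1 = 8, noise_sigma2 = 8, seed = 1) {
  stopifnot(s2_plateau > 0, B1 >= 0, B2 >= 0,
            noise_sigma1 >= 0, noise_sigma2 >= 0, ramp_width >= 1)
  a0 <- rep_len(a0, length(cells))
  structure(list(shape = as.integer(shape), cells = cells,
                 ramp_width = ramp_width, s2_plateau = s2_plateau, a0 = a0,
                 B1 = B1, B2 = B2, noise_sigma1 = noise_sigma1,
                 noise_sigma2 = noise_sigma2, seed = as.integer(seed)),
            class = "scene_spec")
}

.cell_mask <- function(cell, shape) {
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  if (!is.null(cell$center)) {
    ctr <- cell$center; rad <- cell$radius
    if (ctr[1] - rad < 1 || ctr[1] + rad > shape[1] ||
        ctr[2] - rad < 1 || ctr[2] + rad > shape[2])
      stop("cell geometry exceeds image bounds")
    (rr - ctr[1])^2 + (cc - ctr[2])^2 <= rad^2
  } else if (!is.null(cell$vertices)) {
    v <- cell$vertices
    if (min(v) < 1 || max(v[, 1]) > shape[1] || max(v[, 2]) > shape[2])
      stop("cell geometry exceeds image bounds")
    # even-odd rule point-in-polygon
    inside <- matrix(FALSE, shape[1], shape[2])
    nv <- nrow(v); j <- nv
    for (i in seq_len(nv)) {
      yi <- v[i, 1]; xi <- v[i, 2]; yj <- v[j, 1]; xj <- v[j, 2]
      crosses <- ((yi > rr) != (yj > rr)) &
        (cc < (xj - xi) * (rr - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses & is.finite(crosses))
      j <- i
    }
    inside
  } else stop("cell must have either center/radius or vertices")
}

.assemble_scene <- function(truth) {
  list(img1 = (truth$a0_field + truth$a1_field) * truth$S2_field +
         truth$B1 + truth$shade1 + truth$noise1,
       img2 = truth$S2_field + truth$B2 + truth$shade2 + truth$noise2)
}

#' Generate a wedge-cell scene with ground truth
#'
#' @param spec a [scene_spec()].
#' @return list of class `ncf_scene`: `img1`, `img2`, `truth` (fields
#'   `S2_field`, `a0_field`, `a1_field`, `true_a0`, `true_ncf` (per cell),
#'   `mask_true`, `cell_id`, `noise1`, `noise2`, `shade1`, `shade2`,
#'   `B1`, `B2`), `spec`, and attribute `snr_edge` (per-pixel edge
#'   signal-to-noise slope `s2_plateau / (ramp_width * noise_sigma2)`).
#' @export
make_wedge_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  sh <- spec$shape
  masks <- lapply(spec$cells, .cell_mask, shape = sh)
  if (length(masks) > 1) {
    for (i in seq_along(masks)) for (j in seq_len(i - 1))
      if (any(masks[[i]] & masks[[j]])) stop("cells overlap")
  }
  cell_id <- matrix(0L, sh[1], sh[2])
  for (i in seq_along(masks)) cell_id[masks[[i]]] <- i
  mask_true <- cell_id > 0L
  d <- distance_from_edge(mask_true)
  S2 <- spec$s2_plateau * pmin(1, d / spec$ramp_width)
  a0_field <- matrix(0, sh[1], sh[2])
  for (i in seq_along(masks)) a0_field[masks[[i]]] <- spec$a0[i]
  zero <- matrix(0, sh[1], sh[2])
  set.seed(spec$seed)
  noise1 <- matrix(stats::rnorm(prod(sh), 0, spec$noise_sigma1), sh[1], sh[2])
  noise2 <- matrix(stats::rnorm(prod(sh), 0, spec$noise_sigma2), sh[1], sh[2])
  truth <- list(S2_field = S2, a0_field = a0_field, a1_field = zero,
                true_a0 = spec$a0, true_ncf = spec$B1 - spec$a0 * spec$B2,
                mask_true = mask_true, cell_id = cell_id,
                noise1 = noise1, noise2 = noise2,
                shade1 = zero, shade2 = zero,
                B1 = spec$B1, B2 = spec$B2)
  imgs <- .assemble_scene(truth)
  structure(list(img1 = imgs$img1, img2 = imgs$img2, truth = truth,
                 spec = spec),
            class = "ncf_scene",
            snr_edge = spec$s2_plateau /
              (spec$ramp_width * max(spec$noise_sigma2, .Machine$double.eps)))
}

#' @export
print.ncf_scene <- function(x, ...) {
  cat(sprintf("ncf_scene: %d x %d, %d cell(s), a0 = %s, true NCF = %s, seed %d\n",
              nrow(x$img1), ncol(x$img1), length(x$spec$cells),
              paste(x$truth$true_a0, collapse = "/"),
              paste(x$truth$true_ncf, collapse = "/"), x$spec$seed))
  invisible(x)
}

#' Two-cell scene with distinct proportionality coefficients
#'
#' Two disjoint wedge cells sharing backgrounds and noise model, each with
#' its own `a0` (defaults 0.63 and 0.72) and hence its own true NCF.
#'
#' @param spec optional [scene_spec()]; the default places two radius-60
#'   discs on a 256 x 384 canvas.
#' @return an `ncf_scene` (see [make_wedge_scene()]).
#' @export
make_two_cell_scene <- function(spec = NULL) {
  if (is.null(spec))
    spec <- scene_spec(shape = c(256, 384),
                       cells = list(list(center = c(128, 96), radius = 60),
                                    list(center = c(128, 288), radius = 60)),
                       a0 = c(0.63, 0.72))
  if (length(spec$cells) != 2) stop("two-cell scene needs exactly two cells")
  make_wedge_scene(spec)
}

#' Add a linear shade gradient to a scene
#'
#' Adds `amplitude * t(x, y)` to the chosen channel(s), where `t` is the
#' pixel's projection onto `direction` normalized to [0, 1] across the
#' image — emulating uneven illumination or an uncorrected camera bias.
#' Ground truth is updated so the reconstruction identity still holds.
#'
#' @param scene an `ncf_scene`.
#' @param direction length-2 numeric gradient axis (row, col), nonzero.
#' @param amplitude intensity added across the full projection span.
#' @param channels which channels receive the gradient (subset of 1:2).
#' @return the modified scene.
#' @export
add_shade_gradient <- function(scene, direction, amplitude, channels = 1L) {
  stopifnot(inherits(scene, "ncf_scene"), is.finite(amplitude))
  if (sum(direction^2) == 0) stop("direction must be a nonzero vector")
  u <- direction / sqrt(sum(direction^2))
  sh <- dim(scene$img1)
  rr <- matrix(seq_len(sh[1]), sh[1], sh[2])
  cc <- matrix(seq_len(sh[2]), sh[1], sh[2], byrow = TRUE)
  proj <- rr * u[1] + cc * u[2]
  t01 <- (proj - min(proj)) / max(max(proj) - min(proj), .Machine$double.eps)
  field <- amplitude * t01
  if (1L %in% channels) scene$truth$shade1 <- scene$truth$shade1 + field
  if (2L %in% channels) scene$truth$shade2 <- scene$truth$shade2 + field
  imgs <- .assemble_scene(scene$truth)
  scene$img1 <- imgs$img1; scene$img2 <- imgs$img2
  scene
}

#' Add a narrow activity band at the cell edge
#'
#' Raises the activity field `a1` by `amplitude` for in-mask pixels within
#' `width_px` of the edge; the numerator is rebuilt through the generative
#' identity, so the added activity scales with the local signal `S2` (the
#' single-chain model `a0 + a1(x, y)`).
#'
#' @param scene an `ncf_scene`.
#' @param width_px band width in pixels (>= 1).
#' @param amplitude activity increment (ratio units at full signal).
#' @return the modified scene.
#' @export
add_edge_band_activity <- function(scene, width_px, amplitude) {
  stopifnot(inherits(scene, "ncf_scene"), width_px >= 1)
  d <- distance_from_edge(scene$truth$mask_true)
  band <- scene$truth$mask_true & d <= width_px
  scene$truth$a1_field[band] <- scene$truth$a1_field[band] + amplitude
  imgs <- .assemble_scene(scene$truth)
  scene$img1 <- imgs$img1; scene$img2 <- imgs$img2
  scene
}

#' Verify a scene's generative reconstruction identity
#'
#' Reassembles both channels from the stored ground-truth fields and
#' checks they match the emitted images bit-exactly.
#'
#' @param scene an `ncf_scene`.
#' @return `TRUE` (invisibly) or an error.
#' @export
check_scene_identity <- function(scene) {
  imgs <- .assemble_scene(scene$truth)
  if (!identical(imgs$img1, scene$img1) || !identical(imgs$img2, scene$img2))
    stop("scene reconstruction identity violated")
  invisible(TRUE)
}
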