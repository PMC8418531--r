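#' @importFrom stats sd quantile t.test cor rnorm lm.fit
#' @importFrom utils write.csv
NULL

# 8-neighbour offsets in clockwise order starting from "up"
# (row grows downward, so this is clockwise on screen).
.moore_offsets <- matrix(c(-1L, 0L, -1L, 1L, 0L, 1L, 1L, 1L,
                           1L, 0L, 1L, -1L, 0L, -1L, -1L, -1L),
                         ncol = 2L, byrow = TRUE)

.as_mask <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  if (!is.logical(mask)) mask <- mask != 0
  mask[is.na(mask)] <- FALSE
  mask
}

.check_image <- function(image, name = "image") {
  if (!is.matrix(image) || !is.numeric(image))
    stop(name, " must be a numeric matrix")
  invisible(image)
}

#' Label 8-connected foreground components
#'
#' Foreground pixels are considered connected through edges and corners
#' (8-connectivity); background is implicitly 4-connected, the standard
#' digital-topology pairing.
#'
#' @param mask logical matrix, `TRUE` = foreground.
#' @return integer matrix of component labels, 0 for background.
#' @export
label_components <- function(mask) {
  mask <- .as_mask(mask)
  lab <- EBImage::imageData(EBImage::bwlabel(mask * 1))
  storage.mode(lab) <- "integer"
  nl <- max(lab)
  if (nl <= 1L) return(lab)
  # bwlabel is 4-connected; merge labels that touch diagonally (union-find)
  parent <- seq_len(nl)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  nr <- nrow(lab); nc <- ncol(lab)
  merge_pairs <- function(a, b) {
    sel <- a > 0L & b > 0L & a != b
    if (!any(sel)) return(invisible(NULL))
    for (p in unique(a[sel] * (nl + 1L) + b[sel])) {
      i <- find(p %/% (nl + 1L)); j <- find(p %% (nl + 1L))
      if (i != j) parent[max(i, j)] <<- min(i, j)
    }
  }
  merge_pairs(lab[-nr, -nc], lab[-1, -1])   # down-right diagonal
  merge_pairs(lab[-nr, -1], lab[-1, -nc])   # down-left diagonal
  root <- vapply(seq_len(nl), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

#' Threshold an intensity image into a cell mask
#'
#' Pixels with intensity at or above `threshold` become foreground, split
#' into 8-connected components; components smaller than `min_area` are
#' discarded and holes inside the retained components are filled.
#'
#' @param image numeric matrix of intensities.
#' @param threshold finite scalar intensity cutoff.
#' @param min_area minimum component area (pixels) to retain.
#' @param fill_holes fill enclosed background regions of retained components.
#' @return logical matrix (the mask), with attribute `n_components`.
#' @export
threshold_mask <- function(image, threshold, min_area = 1, fill_holes = TRUE) {
  .check_image(image)
  if (!is.finite(threshold)) stop("threshold must be finite")
  fg <- is.finite(image) & image >= threshold
  if (!any(fg)) stop("empty mask: no pixel reaches threshold ", format(threshold))
  lab <- label_components(fg)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= min_area)
  if (length(keep) == 0L)
    stop("empty mask: no component of area >= ", min_area,
         " at threshold ", format(threshold))
  mask <- matrix(lab %in% keep, nrow(image), ncol(image))
  if (fill_holes) mask <- fill_mask_holes(mask)
  attr(mask, "n_components") <- length(keep)
  mask
}

#' Fill enclosed holes in a binary mask
#'
#' A hole is a 4-connected background region that does not touch the image
#' border.
#'
#' @param mask logical matrix.
#' @return logical matrix with holes set to `TRUE`.
#' @export
fill_mask_holes <- function(mask) {
  mask <- .as_mask(mask)
  bg_lab <- EBImage::imageData(EBImage::bwlabel((!mask) * 1))  # 4-connected
  border <- unique(c(bg_lab[1, ], bg_lab[nrow(bg_lab), ],
                     bg_lab[, 1], bg_lab[, ncol(bg_lab)]))
  border <- border[border > 0]
  mask | (bg_lab > 0 & !(bg_lab %in% border))
}

#' Euclidean distance from every in-mask pixel to the cell edge
#'
#' Exact Euclidean distance transform: each foreground pixel maps to the
#' distance (in pixel units, between pixel centers) to the nearest
#' background pixel; background pixels map to 0.
#'
#' @param mask logical matrix with at least one foreground and one
#'   background pixel.
#' @return numeric matrix of distances.
#' @export
distance_from_edge <- function(mask) {
  mask <- .as_mask(mask)
  if (!any(mask)) stop("mask is empty")
  if (all(mask)) stop("mask has no background pixels: distance undefined")
  d <- EBImage::imageData(EBImage::distmap(mask * 1, metric = "euclidean"))
  matrix(as.numeric(d), nrow(mask), ncol(mask))
}

# Trace one component's inner boundary by Moore-neighbour tracing,
# clockwise, starting at the topmost-then-leftmost pixel. Out-of-image is
# treated as background, so the traversal is always a closed loop.
.trace_component <- function(comp) {
  nr <- nrow(comp); nc <- ncol(comp)
  inside <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && comp[r, c]
  idx <- which(comp)
  rows <- (idx - 1L) %% nr + 1L; cols <- (idx - 1L) %/% nr + 1L
  r0 <- min(rows); c0 <- min(cols[rows == r0])
  if (length(idx) == 1L) return(matrix(c(r0, c0), 1L, 2L))
  off <- .moore_offsets
  # backtrack direction: came from "up" (offset index 1)
  path <- matrix(0L, 8L * length(idx) + 8L, 2L)
  npts <- 0L
  p <- c(r0, c0); bdir <- 1L   # index in `off` of the backtrack neighbour
  start_state <- NULL
  seen <- new.env(hash = TRUE, parent = emptyenv())
  repeat {
    # scan clockwise starting just after the backtrack direction
    found <- FALSE
    for (k in 1:8) {
      j <- (bdir - 1L + k - 1L) %% 8L + 1L
      nb <- p + off[j, ]
      if (inside(nb[1], nb[2])) {
        state <- c(p, j)
        if (is.null(start_state)) {
          start_state <- state
        } else if (all(state == start_state)) {
          return(path[seq_len(npts), , drop = FALSE])
        }
        key <- paste(state, collapse = ",")
        if (!is.null(seen[[key]])) return(path[seq_len(npts), , drop = FALSE])
        seen[[key]] <- TRUE
        npts <- npts + 1L
        if (npts > nrow(path)) path <- rbind(path, path * 0L)
        path[npts, ] <- p
        # new backtrack = direction from new pixel back toward previous scan pos
        prev_j <- (j - 2L) %% 8L + 1L          # last background neighbour checked
        back <- p + off[prev_j, ] - nb         # vector from nb to that bg pixel
        bdir <- which(off[, 1] == back[1] & off[, 2] == back[2])
        p <- nb
        found <- TRUE
        break
      }
    }
    if (!found) return(matrix(c(r0, c0), 1L, 2L))  # isolated pixel
  }
}

#' Extract ordered edge contours of a mask
#'
#' One contour per 8-connected component, ordered by Moore boundary tracing
#' (clockwise, starting from the topmost-then-leftmost boundary pixel).
#' `side = "inner"` returns mask pixels on the boundary; `side = "outer"`
#' returns background pixels 8-adjacent to the component, ordered by
#' projecting each onto the inner traversal order (nearest inner contour
#' pixel, ties to the earliest traversal index).
#'
#' @param mask logical matrix, non-empty.
#' @param side `"inner"` or `"outer"`.
#' @return list of `edge_contour` objects (fields `pixels` (n x 2 matrix of
#'   1-based row, col), `side`, `component_id`, `closed`, `raw_intensity`,
#'   `smoothed_intensity`).
#' @export
extract_edge_contour <- function(mask, side = c("inner", "outer")) {
  side <- match.arg(side)
  mask <- .as_mask(mask)
  if (!any(mask)) stop("mask is empty")
  lab <- label_components(mask)
  out <- list()
  for (id in seq_len(max(lab))) {
    comp <- lab == id
    inner <- .trace_component(comp)
    # deduplicate consecutive revisits are fine (Moore tracing may revisit
    # pixels of 1-px-wide arms); keep traversal as traced.
    if (side == "inner") {
      px <- inner
    } else {
      nr <- nrow(mask); nc <- ncol(mask)
      cand <- which(!mask)
      cr <- (cand - 1L) %% nr + 1L; cc <- (cand - 1L) %/% nr + 1L
      # 8-adjacent to this component?
      adj <- logical(length(cand))
      for (k in 1:8) {
        rr <- cr + .moore_offsets[k, 1]; cc2 <- cc + .moore_offsets[k, 2]
        okk <- rr >= 1L & rr <= nr & cc2 >= 1L & cc2 <= nc
        adj[okk] <- adj[okk] | comp[cbind(rr[okk], cc2[okk])]
      }
      cr <- cr[adj]; cc <- cc[adj]
      if (length(cr) == 0L) {
        px <- matrix(numeric(0), 0L, 2L)
      } else {
        # unique inner pixels with their first traversal index
        key <- inner[, 1] * (nc + 1L) + inner[, 2]
        first <- !duplicated(key)
        ir <- inner[first, 1]; ic <- inner[first, 2]
        iidx <- seq_len(nrow(inner))[first]
        ord_idx <- numeric(length(cr)); ord_d <- numeric(length(cr))
        for (i in seq_along(cr)) {
          d2 <- (ir - cr[i])^2 + (ic - cc[i])^2
          j <- which.min(d2)  # ties -> smallest traversal index (sorted order)
          ord_idx[i] <- iidx[j]; ord_d[i] <- d2[j]
        }
        o <- order(ord_idx, cr, cc)
        px <- cbind(cr[o], cc[o])
      }
    }
    out[[id]] <- structure(list(
      pixels = px, side = side, component_id = id, closed = TRUE,
      raw_intensity = NULL, smoothed_intensity = NULL),
      class = "edge_contour")
  }
  out
}

#' @export
print.edge_contour <- function(x, ...) {
  cat(sprintf("edge_contour: %d pixels, side=%s, component=%d, %s\n",
              nrow(x$pixels), x$side, x$component_id,
              if (isTRUE(x$closed)) "closed" else "open"))
  invisible(x)
}

#' Define a rectangular background box
#'
#' @param row0,col0 1-based top-left corner.
#' @param height,width extent in pixels.
#' @return named integer vector of class `bg_box`.
#' @export
bg_box <- function(row0, col0, height, width) {
  v <- as.integer(c(row0 = row0, col0 = col0, height = height, width = width))
  names(v) <- c("row0", "col0", "height", "width")
  if (any(v[c("height", "width")] < 1)) stop("bg_box must have positive extent")
  class(v) <- "bg_box"
  v
}

.box_indices <- function(box, dim) {
  rows <- box[["row0"]]:(box[["row0"]] + box[["height"]] - 1L)
  cols <- box[["col0"]]:(box[["col0"]] + box[["width"]] - 1L)
  if (min(rows) < 1 || max(rows) > dim[1] || min(cols) < 1 || max(cols) > dim[2])
    stop("bg_box extends outside the image")
  list(rows = rows, cols = cols)
}

#' Build the region set derived from a cell mask
#'
#' `interior` is the mask eroded by `depth_in` (pixels with Euclidean
#' distance to the edge strictly greater than `depth_in`); `bg_ring` is the
#' near-edge background: pixels outside every mask within Euclidean distance
#' `depth_out` of the mask, excluding an optional border margin.
#'
#' @param mask logical matrix.
#' @param depth_in erosion depth, px (default 10).
#' @param depth_out dilation depth for the background ring, px (default 50).
#' @param bg_box optional [bg_box()] of the distant background, disjoint
#'   from the mask.
#' @param border_margin exclude ring pixels within this many pixels of the
#'   image border.
#' @return object of class `region_set`: list(mask, interior, bg_ring,
#'   bg_box, depth_in, depth_out).
#' @export
build_region_set <- function(mask, depth_in = 10, depth_out = 50,
                             bg_box = NULL, border_margin = 0) {
  mask <- .as_mask(mask)
  if (!any(mask)) stop("mask is empty")
  d_in <- distance_from_edge(mask)
  interior <- d_in > depth_in
  if (!any(interior))
    stop("interior is empty after erosion by ", depth_in,
         " px; use a smaller depth_in")
  if (depth_out > 0) {
    d_out <- distance_from_edge(!mask)
    ring <- !mask & d_out <= depth_out
  } else {
    ring <- mask & FALSE
    warning("depth_out = 0: background ring is empty")
  }
  if (border_margin > 0) {
    nr <- nrow(mask); nc <- ncol(mask)
    rr <- row(mask); cc <- col(mask)
    ring <- ring & rr > border_margin & rr <= nr - border_margin &
      cc > border_margin & cc <= nc - border_margin
  }
  if (!is.null(bg_box)) {
    bi <- .box_indices(bg_box, dim(mask))
    if (any(mask[bi$rows, bi$cols])) stop("bg_box overlaps the cell mask")
  }
  structure(list(mask = mask, interior = interior, bg_ring = ring,
                 bg_box = bg_box, depth_in = depth_in, depth_out = depth_out),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set: mask %d px, interior %d px (depth_in=%g), ring %d px (depth_out=%g)\n",
              sum(x$mask), sum(x$interior), x$depth_in, sum(x$bg_ring), x$depth_out))
  invisible(x)
}

#' Sample image values along a line segment
#'
#' Values are sampled at unit-spaced positions from `p0` toward `p1`
#' (endpoint included) by nearest-pixel lookup.
#'
#' @param image numeric matrix.
#' @param p0,p1 numeric length-2 vectors, 1-based (row, col) endpoints.
#' @return data.frame with columns `position_px`, `row`, `col`, `value`.
#' @export
line_scan <- function(image, p0, p1) {
  .check_image(image)
  for (p in list(p0, p1))
    if (p[1] < 1 || p[1] > nrow(image) || p[2] < 1 || p[2] > ncol(image))
      stop("line_scan endpoint outside image bounds")
  L <- sqrt(sum((p1 - p0)^2))
  t <- seq(0, floor(L), by = 1)
  if (L > 0 && max(t) < L) t <- c(t, L)
  if (L == 0) {
    rows <- round(p0[1]); cols <- round(p0[2])
  } else {
    rows <- round(p0[1] + t / L * (p1[1] - p0[1]))
    cols <- round(p0[2] + t / L * (p1[2] - p0[2]))
  }
  data.frame(position_px = t, row = rows, col = cols,
             value = image[cbind(rows, cols)])
}

#' Default mask threshold from background statistics
#'
#' The background-box mean plus three standard deviations, the
#' pixel-classification cut separating true background from near-edge
#' background.
#'
#' @param bg_mean,bg_sd background mean and standard deviation.
#' @return scalar threshold.
#' @export
default_mask_threshold <- function(bg_mean, bg_sd) bg_mean + 3 * bg_sd
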