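#' Assemble a pipeline configuration
#'
#' Every parameter consumed anywhere in the pipeline lives here and is
#' echoed into the output sidecars, so any result can be reproduced from
#' its own provenance record. Image inputs may be file paths or in-memory
#' matrices.
#'
#' @param img1,img2 numerator / denominator: TIFF paths or matrices.
#' @param dark1,dark2 optional dark-current frames (paths or matrices).
#' @param shading1,shading2 optional shading references (paths or matrices).
#' @param mask optional precomputed mask (path or logical matrix); when
#'   absent the mask is thresholded at `mask_threshold`, and when that is
#'   also absent the default policy `bg mean + 3 sd` (which requires
#'   `bg_box`) applies.
#' @param bg_box a [bg_box()] for the distant background.
#' @param mask_threshold optional explicit mask threshold.
#' @param min_area minimum mask component area, px.
#' @param depth_in,depth_out region depths, px.
#' @param sigma contour smoothing scale (contour px) for the nonuniform
#'   background.
#' @param m inverse-distance interpolation exponent.
#' @param grid optional NCF candidate grid `c(lo, hi, n)`.
#' @param methods ratio methods to compute, subset of
#'   `c("MBS", "halfway", "nonuniform", "NCF")`.
#' @param max_d,min_bin_count distance-profile controls.
#' @param band_offsets contiguous offsets for edge band statistics.
#' @param seed RNG seed recorded for provenance.
#' @param out_dir output directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(img1, img2, dark1 = NULL, dark2 = NULL,
                            shading1 = NULL, shading2 = NULL, mask = NULL,
                            bg_box = NULL, mask_threshold = NULL,
                            min_area = 50, depth_in = 10, depth_out = 50,
                            sigma = 10, m = 2, grid = NULL,
                            methods = c("MBS", "halfway", "nonuniform", "NCF"),
                            max_d = NULL, min_bin_count = 50,
                            band_offsets = -2:4, seed = 1, out_dir) {
  cfg <- list(img1 = img1, img2 = img2, dark1 = dark1, dark2 = dark2,
              shading1 = shading1, shading2 = shading2, mask = mask,
              bg_box = bg_box, mask_threshold = mask_threshold,
              min_area = min_area, depth_in = depth_in, depth_out = depth_out,
              sigma = sigma, m = m, grid = grid, methods = methods,
              max_d = max_d, min_bin_count = min_bin_count,
              band_offsets = band_offsets, seed = seed, out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  # validate before any computation
  if (is.null(cfg$mask) && is.null(cfg$mask_threshold) && is.null(cfg$bg_box))
    stop("config invalid: no mask and no mask_threshold, so the default ",
         "threshold policy applies, which requires bg_box")
  if (is.null(cfg$bg_box))
    stop("config invalid: bg_box is required for background statistics")
  cfg
}

.load_input <- function(x, what) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) read_channel(x) else { .check_image(x, what); x }
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the full two-channel ratio pipeline
#'
#' Preprocess (dark current, shading) -> mask -> regions -> background
#' statistics -> NCF calibration (all estimators) -> ratio maps for every
#' requested method -> diagnostics. Writes float32 ratio TIFFs with
#' invalid-pixel masks, a JSON calibration report, objective-curve and
#' profile and band-statistics CSVs, rendered PNGs, the merged config, and
#' a run log. With a fixed config the outputs are byte-identical across
#' runs.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with the in-memory results: `regions`,
#'   `calibration`, `ratios`, `profiles`, `bands`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  set.seed(config$seed)

  img1 <- .stage("read", .load_input(config$img1, "img1"))
  img2 <- .stage("read", .load_input(config$img2, "img2"))
  for (ch in c("1", "2")) {
    dk <- .load_input(config[[paste0("dark", ch)]], "dark")
    sh <- .load_input(config[[paste0("shading", ch)]], "shading")
    nm <- paste0("img", ch)
    if (!is.null(dk)) assign(nm, .stage("dark_current", dark_current_correct(get(nm), dk)))
    if (!is.null(sh)) assign(nm, .stage("shading", shading_correct(get(nm), sh)))
  }

  b1 <- .stage("background", box_background(img1, config$bg_box))
  b2 <- .stage("background", box_background(img2, config$bg_box))
  say(sprintf("distant background: img1 %.3f +/- %.3f, img2 %.3f +/- %.3f",
              b1$mean, b1$sd, b2$mean, b2$sd))

  mask <- .stage("mask", {
    if (!is.null(config$mask)) {
      if (is.character(config$mask)) read_mask(config$mask) else .as_mask(config$mask)
    } else {
      thr <- if (!is.null(config$mask_threshold)) config$mask_threshold
             else default_mask_threshold(b2$mean, b2$sd)
      say(sprintf("mask threshold: %.3f", thr))
      threshold_mask(img2, thr, min_area = config$min_area)
    }
  })
  regions <- .stage("regions",
    build_region_set(mask, depth_in = config$depth_in,
                     depth_out = config$depth_out, bg_box = config$bg_box))
  dmap <- distance_from_edge(mask)

  cal <- .stage("calibrate",
    calibrate_ncf(img1, img2, regions, grid = config$grid,
                  min_bin_count = config$min_bin_count))
  say("NCF estimates: ",
      paste(sprintf("%s=%.4g", names(cal$ncf), cal$ncf), collapse = ", "))

  ratios <- list()
  if ("MBS" %in% config$methods)
    ratios$MBS <- .stage("ratio_MBS", mbs_ratio(img1, img2, b1$mean, b2$mean))
  if ("halfway" %in% config$methods) {
    thr <- if (!is.null(config$mask_threshold)) config$mask_threshold
           else default_mask_threshold(b2$mean, b2$sd)
    thr1 <- if (!is.null(config$mask_threshold)) config$mask_threshold
            else default_mask_threshold(b1$mean, b1$sd)
    ratios$halfway <- .stage("ratio_halfway",
      mbs_ratio(img1, img2, halfway_background(b1$mean, max(b1$mean, thr1)),
                halfway_background(b2$mean, max(b2$mean, thr))))
  }
  if ("nonuniform" %in% config$methods) {
    f1 <- .stage("nonuniform_bg",
                 edge_background_field(img1, mask, sigma = config$sigma,
                                       m = config$m))
    f2 <- .stage("nonuniform_bg",
                 edge_background_field(img2, mask, sigma = config$sigma,
                                       m = config$m))
    ratios$nonuniform <- .stage("ratio_nonuniform",
                                nonuniform_ratio(img1, img2, f1, f2))
  }
  if ("NCF" %in% config$methods)
    ratios$NCF <- .stage("ratio_NCF",
                         ncf_ratio(img1, img2, cal$ncf[["dev_in"]]))

  out <- config$out_dir
  profiles <- list()
  for (nm in names(ratios)) {
    rr <- ratios[[nm]]
    say(sprintf("%s: %d invalid px", nm, sum(rr$invalid)))
    write_channel(rr$ratio * ifelse(rr$invalid, NA, 1),
                  file.path(out, paste0("ratio_", nm, ".tif")))
    write_mask(rr$invalid, file.path(out, paste0("invalid_", nm, ".tif")))
    p <- .stage("profile",
                distance_profile(rr, dmap, max_d = config$max_d,
                                 min_bin_count = config$min_bin_count))
    profiles[[nm]] <- p
    utils::write.csv(p, file.path(out, paste0("profile_", nm, ".csv")),
                     row.names = FALSE)
    rend <- render_ratio_map(rr, mask, mode = "bg_to_mean")
    sc <- (rend$display - rend$bounds[1]) /
      max(rend$bounds[2] - rend$bounds[1], .Machine$double.eps)
    sc[!is.finite(sc)] <- 0
    png::writePNG(pmin(pmax(sc, 0), 1),
                  file.path(out, paste0("render_", nm, ".png")))
    writeLines(sprintf("scale_bounds\t%.10g\t%.10g",
                       rend$bounds[1], rend$bounds[2]),
               file.path(out, paste0("render_", nm, ".png.txt")))
  }

  bands <- NULL
  if ("NCF" %in% names(ratios)) {
    bands <- .stage("bandstats",
                    edge_band_stats(ratios$NCF, mask, config$band_offsets))
    utils::write.csv(bands, file.path(out, "bandstats.csv"), row.names = FALSE)
  }

  for (obj in c("dev_in", "dev_out", "flatness")) {
    f <- cal[[paste0("fit_", obj)]]
    utils::write.csv(data.frame(ncf_candidate = f$grid,
                                objective_value = f$dev_curve),
                     file.path(out, paste0("dev_curve_", obj, ".csv")),
                     row.names = FALSE)
  }

  report <- list(ncf = as.list(cal$ncf), a0 = cal$fit$a0,
                 a0_ref = cal$a0_ref,
                 fit = cal$fit[c("a0", "intercept", "n_pixels", "residual_rms")],
                 bg1 = cal$bg1, bg2 = cal$bg2,
                 flatness = lapply(profiles, relative_range),
                 invalid_px = lapply(ratios, function(r) sum(r$invalid)))
  jsonlite::write_json(report, file.path(out, "calibration.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg_out <- config
  for (f in c("img1", "img2", "dark1", "dark2", "shading1", "shading2", "mask"))
    if (!is.null(cfg_out[[f]]) && !is.character(cfg_out[[f]]))
      cfg_out[[f]] <- "<in-memory matrix>"
  cfg_out$bg_box <- as.list(unclass(cfg_out$bg_box))
  jsonlite::write_json(unclass(cfg_out), file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  writeLines(log_lines, file.path(out, "log.txt"))
  invisible(list(regions = regions, calibration = cal, ratios = ratios,
                 profiles = profiles, bands = bands))
}
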