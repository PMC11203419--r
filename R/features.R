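# Instrument-style masks and per-event morphometric/intensity features.
#
# Conventions fixed by this package (the commercial feature definitions are
# unpublished): gradients are central differences with replicated edges;
# circularity is mean/sd of boundary-pixel distances from the centroid;
# axis lengths come from second-order mask moments with a 1/12 unit-square
# correction; boundary pixels are mask pixels with at least one non-mask
# 4-neighbour; the background estimate is the per-channel median outside
# the dilated cell mask.

.brush <- function(r) EBImage::makeBrush(2L * r + 1L, shape = "disc")

#' Whole-cell mask from a brightfield raster
#'
#' Thresholds the absolute deviation from the background mode with Otsu's
#' method, applies a morphological closing and keeps the largest connected
#' component. A frame without a detectable object yields an empty, flagged
#' mask.
#'
#' @param bf_raster Numeric matrix (brightfield image).
#' @return An `ifc_mask`: list with `mask` (logical matrix), `origin`
#'   (`"whole_cell"`) and `empty` flag.
#' @export
cell_mask <- function(bf_raster) {
  bg <- stats::median(bf_raster)
  dev <- abs(bf_raster - bg)
  spread <- stats::mad(bf_raster)
  if (max(dev) <= max(4 * spread, 1e-8)) {
    return(structure(list(mask = matrix(FALSE, nrow(bf_raster),
                                        ncol(bf_raster)),
                          origin = "whole_cell", empty = TRUE),
                     class = "ifc_mask"))
  }
  sc <- dev / max(dev)
  thr <- EBImage::otsu(EBImage::Image(sc), range = c(0, 1))
  bin <- sc > thr
  bin <- EBImage::closing(bin, .brush(1L)) > 0
  lab <- EBImage::bwlabel(bin)
  tab <- tabulate(lab[lab > 0])
  if (length(tab) == 0) {
    return(structure(list(mask = matrix(FALSE, nrow(bf_raster),
                                        ncol(bf_raster)),
                          origin = "whole_cell", empty = TRUE),
                     class = "ifc_mask"))
  }
  mask <- lab == which.max(tab)
  structure(list(mask = mask, origin = "whole_cell",
                 empty = sum(mask) < 5),
            class = "ifc_mask")
}

#' Membrane ring mask
#'
#' `dilation(cell, 1)` minus `erosion(cell, ring_width - 1)`: a ring of
#' roughly `ring_width` pixels straddling the cell boundary, used for the
#' membrane-localised CD45 intensity.
#'
#' @param cell An `ifc_mask` (whole-cell) or logical matrix.
#' @param ring_width Ring width in pixels (>= 1).
#' @return An `ifc_mask` with origin `"membrane_ring"`.
#' @export
membrane_mask <- function(cell, ring_width = 3L) {
  if (ring_width < 1) stop("ring_width must be at least 1", call. = FALSE)
  m <- if (inherits(cell, "ifc_mask")) cell$mask else cell
  dil <- EBImage::dilate(m, .brush(1L)) > 0
  ero <- if (ring_width >= 2)
    EBImage::erode(m, .brush(as.integer(ring_width) - 1L)) > 0
  else m
  ring <- dil & !ero
  structure(list(mask = ring, origin = "membrane_ring",
                 empty = !any(ring)), class = "ifc_mask")
}

#' Gradient RMS focus score
#'
#' Root mean square of the central-difference gradient magnitude over the
#' mask pixels (whole frame if no mask). Invariant to additive constants;
#' 0 for a constant raster or an empty mask.
#'
#' @param raster Numeric matrix.
#' @param mask Optional `ifc_mask` or logical matrix restricting the pixels.
#' @return Non-negative scalar.
#' @export
gradient_rms <- function(raster, mask = NULL) {
  m <- if (is.null(mask)) NULL
  else if (inherits(mask, "ifc_mask")) mask$mask else mask
  if (!is.null(m) && !any(m)) return(0)
  n <- nrow(raster); p <- ncol(raster)
  up    <- raster[c(1, seq_len(n - 1)), , drop = FALSE]
  down  <- raster[c(seq_len(n - 1) + 1, n), , drop = FALSE]
  left  <- raster[, c(1, seq_len(p - 1)), drop = FALSE]
  right <- raster[, c(seq_len(p - 1) + 1, p), drop = FALSE]
  gx <- (down - up) / 2
  gy <- (right - left) / 2
  g2 <- gx^2 + gy^2
  if (!is.null(m)) g2 <- g2[m]
  sqrt(mean(g2))
}

.boundary_pixels <- function(m) {
  n <- nrow(m); p <- ncol(m)
  pad <- matrix(FALSE, n + 2, p + 2)
  pad[2:(n + 1), 2:(p + 1)] <- m
  inner <- pad[1:n, 2:(p + 1)] & pad[3:(n + 2), 2:(p + 1)] &
    pad[2:(n + 1), 1:p] & pad[2:(n + 1), 3:(p + 2)]
  m & !inner
}

#' Mask shape features: area, aspect ratio, circularity
#'
#' Area is the pixel count scaled by the pixel area. The aspect ratio is
#' minor/major axis length from the second-order mask moments (each pixel
#' treated as a unit square, so an axis-aligned 2:1 rectangle gives exactly
#' 0.5). Circularity is mean/sd of the boundary-pixel distances from the
#' mask centroid — large values mean round; clipped or debris-contaminated
#' masks score low. A single-pixel mask has circularity `Inf`.
#'
#' @param mask An `ifc_mask` or logical matrix (non-empty).
#' @param pixel_size Micrometres per pixel.
#' @return Named list `area_um2`, `aspect_ratio`, `circularity`.
#' @export
shape_features <- function(mask, pixel_size = 0.3) {
  m <- if (inherits(mask, "ifc_mask")) mask$mask else mask
  if (!any(m)) stop("shape_features requires a non-empty mask",
                    call. = FALSE)
  idx <- which(m, arr.ind = TRUE)
  n <- nrow(idx)
  area <- n * pixel_size^2
  cx <- mean(idx[, 1]); cy <- mean(idx[, 2])
  if (n == 1) {
    return(list(area_um2 = area, aspect_ratio = 1, circularity = Inf))
  }
  dx <- idx[, 1] - cx; dy <- idx[, 2] - cy
  cov <- matrix(c(mean(dx^2) + 1 / 12, mean(dx * dy),
                  mean(dx * dy), mean(dy^2) + 1 / 12), 2, 2)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  aspect <- sqrt(max(ev[2], 0) / ev[1])
  bd <- .boundary_pixels(m)
  bidx <- which(bd, arr.ind = TRUE)
  r <- sqrt((bidx[, 1] - cx)^2 + (bidx[, 2] - cy)^2)
  circ <- if (length(r) < 2 || stats::sd(r) == 0) Inf
  else mean(r) / stats::sd(r)
  list(area_um2 = area, aspect_ratio = aspect, circularity = circ)
}

#' Per-event intensity features
#'
#' Background-subtracted integrated intensity per fluorescence channel over
#' the whole-cell mask (clipped at zero), the membrane-ring CD45 intensity,
#' and per-channel `raw_max_pixel` / `saturation_count` computed on the
#' uncompensated rasters over the whole frame. The background estimate is
#' the per-channel median of pixels outside the dilated cell mask.
#'
#' @param event An `ifc_event`.
#' @param cell An `ifc_mask` (whole-cell).
#' @param membrane An `ifc_mask` (membrane ring).
#' @return Named list of scalars.
#' @export
intensity_features <- function(event, cell, membrane) {
  fluor <- ifc_fluor_channels()
  missing_ch <- setdiff(fluor, names(event$channels))
  if (length(missing_ch))
    stop("event is missing channel(s): ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  m <- cell$mask
  outside <- !(EBImage::dilate(m, .brush(2L)) > 0)
  if (!any(outside)) outside <- !m
  out <- list()
  for (ch in fluor) {
    x <- event$channels[[ch]]
    bg <- stats::median(x[outside])
    out[[paste0("intensity_", ch)]] <-
      if (any(m)) max(0, sum(x[m] - bg)) else 0
    out[[paste0("raw_max_", ch)]] <- max(x)
    out[[paste0("sat_count_", ch)]] <- sum(x >= event$adc_max)
    # membrane-ring intensities for every channel so that the ring vector
    # can be spillover-compensated like the whole-cell vector
    out[[paste0("membrane_", ch)]] <-
      if (!membrane$empty) max(0, sum(x[membrane$mask] - bg)) else 0
  }
  out$cd45_membrane_intensity <- out$membrane_Ch08
  x6 <- event$channels[["Ch06"]]
  bg6 <- stats::median(x6[outside])
  out$intensity_Ch06 <- if (any(m)) max(0, sum(x6[m] - bg6)) else 0
  out
}

#' Compute the full feature table of an event store
#'
#' Runs mask construction and all feature extractors over every event:
#' brightfield gradient RMS (focus), mask shape features, per-channel
#' intensities, raw max pixel and saturation counts, and the
#' membrane-localised CD45 intensity. Events with an empty cell mask get
#' zero shape/intensity features and are flagged.
#'
#' @param store An `ifc_store`.
#' @param ring_width Membrane ring width in pixels.
#' @return A data.frame (one row per event) carrying the event metadata
#'   and all features; class `ifc_features`.
#' @export
ifc_features <- function(store, ring_width = 3L) {
  n <- length(store$events)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ev <- store$events[[i]]
    cm <- cell_mask(ev$channels[["Ch01"]])
    base <- list(
      event_id = ev$event_id, sample_id = ev$sample_id,
      patient_id = if (is.null(ev$patient_id)) NA_character_ else
        ev$patient_id,
      time = ev$time,
      mask_empty = cm$empty,
      gradient_rms_bf = gradient_rms(ev$channels[["Ch01"]], cm)
    )
    if (!cm$empty) {
      mm <- membrane_mask(cm, ring_width)
      sf <- shape_features(cm, store$pixel_size)
      intf <- intensity_features(ev, cm, mm)
      base <- c(base, sf, intf)
    } else {
      base <- c(base, list(area_um2 = 0, aspect_ratio = 0,
                           circularity = 0))
      for (ch in ifc_fluor_channels()) {
        base[[paste0("intensity_", ch)]] <- 0
        base[[paste0("raw_max_", ch)]] <- max(ev$channels[[ch]])
        base[[paste0("sat_count_", ch)]] <-
          sum(ev$channels[[ch]] >= ev$adc_max)
        base[[paste0("membrane_", ch)]] <- 0
      }
      base$cd45_membrane_intensity <- 0
      base$intensity_Ch06 <- 0
    }
    rows[[i]] <- base
  }
  fields <- names(rows[[1]])
  cols <- lapply(fields, function(f)
    unlist(lapply(rows, `[[`, f), use.names = FALSE))
  names(cols) <- fields
  out <- as.data.frame(cols, stringsAsFactors = FALSE)
  class(out) <- c("ifc_features", "data.frame")
  out
}
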