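# Event rendering: one synthetic cell -> multi-channel image stack.
#
# Cells are soft-edged elliptical discs. Stochastic structure (texture
# fields, granule positions) is drawn on a cell-local patch so that placing
# the same latent draw at a different integer centre translates the image
# exactly; frame-level read noise and quantisation are applied last and can
# be disabled via the config.

# Soft-edge elliptical radial field on a (2h+1)^2 patch. Returns the
# effective radial distance (px) of every patch pixel from the cell centre,
# normalised so the ellipse boundary maps onto radius r_px.
.radial_field <- function(half, r_px, aspect, theta) {
  idx <- seq(-half, half)
  u <- matrix(idx, 2 * half + 1, 2 * half + 1)
  v <- t(u)
  ur <- u * cos(theta) + v * sin(theta)
  vr <- -u * sin(theta) + v * cos(theta)
  a <- r_px / sqrt(aspect)   # semi-major
  b <- r_px * sqrt(aspect)   # semi-minor
  r_px * sqrt((ur / a)^2 + (vr / b)^2)
}

.sigmoid_disc <- function(d, r_px, edge = 0.7) {
  1 / (1 + exp((d - r_px) / edge))
}

# Sample latent morphology and marker totals for one event.
sample_latent <- function(population, config, patient_id = NA) {
  mp <- as.list(config$morphology_params[population, ])
  if (population == "LSC") {
    hs <- as.list(config$morphology_params["HSC", ])
    eff <- config$effect_sizes
    grp <- list(
      BF  = c("radius_um", "edge_depth", "bf_texture_sd"),
      SSC = c("granule_lambda", "granule_brightness"),
      DNA = c("nuclear_fraction", "dna_texture_rel")
    )
    for (g in names(grp)) for (p in grp[[g]])
      mp[[p]] <- hs[[p]] + eff[[g]] * (mp[[p]] - hs[[p]])
    if (!is.na(patient_id)) {
      pp <- config$patient_profiles
      row <- pp[pp$patient_id == patient_id, ]
      if (nrow(row) == 1) {
        mp$radius_um       <- mp$radius_um + row$radius_shift_um
        mp$granule_lambda  <- max(0, mp$granule_lambda + row$granule_shift)
        mp$dna_texture_rel <- max(0, mp$dna_texture_rel +
                                    row$nuclear_texture_shift)
        mp$bf_texture_sd   <- max(1, mp$bf_texture_sd + row$bf_texture_shift)
        if (!is.null(row$edge_depth_shift))
          mp$edge_depth    <- max(50, mp$edge_depth + row$edge_depth_shift)
      }
    }
  }
  mk <- config$marker_params
  totals <- stats::rlnorm(length(ifc_fluor_channels()),
                          meanlog = log(mk$median[population, ]),
                          sdlog = mk$sdlog)
  names(totals) <- ifc_fluor_channels()
  list(
    population = population,
    radius_um = max(0.4, stats::rnorm(1, mp$radius_um, mp$radius_sd)),
    aspect = stats::runif(1, mp$aspect_min, 1),
    theta = stats::runif(1, 0, pi),
    edge_depth = mp$edge_depth,
    bf_texture_sd = mp$bf_texture_sd,
    granule_count = stats::rpois(1, max(0, mp$granule_lambda)),
    granule_brightness = mp$granule_brightness,
    nuclear_fraction = mp$nuclear_fraction,
    dna_texture_rel = mp$dna_texture_rel,
    totals = totals
  )
}

# Render the per-channel local patches for one cell. Returns a list of
# signal patches (values relative to channel background): bf (signed),
# ssc, dna weight map, cell weight map, membrane weight map.
.render_patches <- function(latent, half) {
  r_px <- latent$radius_px
  d <- .radial_field(half, r_px, latent$aspect, latent$theta)
  f <- .sigmoid_disc(d, r_px, 0.7)
  np <- length(d)

  bf <- -latent$edge_depth * f +
    f * stats::rnorm(np, 0, latent$bf_texture_sd)

  ssc <- matrix(0, nrow(d), ncol(d))
  if (latent$granule_count > 0) {
    k <- outer(c(0.2, 0.6, 0.2), c(0.2, 0.6, 0.2))
    a <- r_px / sqrt(latent$aspect)
    b <- r_px * sqrt(latent$aspect)
    for (g in seq_len(latent$granule_count)) {
      rho <- sqrt(stats::runif(1)) * 0.8
      phi <- stats::runif(1, 0, 2 * pi)
      ug <- rho * a * cos(phi)
      vg <- rho * b * sin(phi)
      gx <- round(ug * cos(latent$theta) - vg * sin(latent$theta)) + half + 1
      gy <- round(ug * sin(latent$theta) + vg * cos(latent$theta)) + half + 1
      amp <- latent$granule_brightness * stats::rlnorm(1, 0, 0.25)
      if (gx >= 2 && gx <= nrow(ssc) - 1 && gy >= 2 && gy <= ncol(ssc) - 1)
        ssc[(gx - 1):(gx + 1), (gy - 1):(gy + 1)] <-
          ssc[(gx - 1):(gx + 1), (gy - 1):(gy + 1)] + amp * k
    }
  }

  # whole-cell stains are bounded by the membrane: slightly interior and
  # sharper-edged than the optical brightfield profile
  f_fl <- .sigmoid_disc(d, r_px - 0.5, 0.5)
  w_cell <- f_fl * pmax(0, 1 + 0.08 * stats::rnorm(np))
  w_cell <- w_cell / sum(w_cell)

  # membrane stain sits just inside the optical cell boundary
  wm <- exp(-(d - (r_px - 1))^2 / (2 * 0.7^2))
  wm <- wm / sum(wm)

  if (latent$nuclear_fraction > 0) {
    rn <- latent$nuclear_fraction * r_px
    g <- .sigmoid_disc(d, rn, 0.6)
    tex <- pmax(0.05, 1 + latent$dna_texture_rel * stats::rnorm(np))
    w_dna <- g * tex
  } else {
    w_dna <- f * pmax(0.05, 1 + 0.1 * stats::rnorm(np))
  }
  w_dna <- w_dna / sum(w_dna)

  list(bf = bf, ssc = ssc, w_cell = w_cell, w_membrane = wm, w_dna = w_dna)
}

.add_patch <- function(frame, patch, cx, cy, half) {
  rows <- (cx - half):(cx + half)
  cols <- (cy - half):(cy + half)
  frame[rows, cols] <- frame[rows, cols] + patch
  frame
}

# Channel background offsets (ADC counts) and read-noise SDs.
.bg_offset <- function() {
  c(Ch01 = 3000, Ch02 = 4, Ch03 = 4, Ch04 = 4, Ch06 = 3, Ch07 = 4,
    Ch08 = 4, Ch10 = 4, Ch11 = 4)
}

#' Render one event's multi-channel image stack
#'
#' Turns a latent parameter draw (see the truth table of
#' [generate_cohort()]) into the nine-channel image stack of one event:
#' a bright background with a darker textured cell disc (brightfield Ch01),
#' sparse bright granules (SSC Ch06), a textured nuclear disc scaled to the
#' event's DNA signal (Ch07), whole-cell-distributed fluorescence for
#' ZG/CLEC12A/CD14/CD38/CD34, and membrane-localised CD45 (Ch08).
#' Fluorescence channels are mixed by the spillover matrix before
#' background, read noise and quantisation are applied.
#'
#' @param latent Latent parameter list as produced internally (fields
#'   `population`, `radius_um`, `aspect`, `theta`, `edge_depth`,
#'   `bf_texture_sd`, `granule_count`, `granule_brightness`,
#'   `nuclear_fraction`, `dna_texture_rel`, `totals`).
#' @param config An [ifc_config()].
#' @param center Integer (row, col) cell centre; default frame centre.
#' @param out_of_focus Apply a Gaussian blur to the image channels.
#' @param saturated Clip at least one pixel of the brightest fluorescence
#'   channel to `adc_max`.
#' @param doublet_latent Optional second latent draw rendered as a touching
#'   cell.
#' @param spill Spillover matrix used for mixing (defaults to the config's
#'   truth matrix).
#' @return An `ifc_event`: list with `channels` (named list of matrices),
#'   `adc_max` and the centre used.
#' @export
render_event <- function(latent, config, center = NULL,
                         out_of_focus = FALSE, saturated = FALSE,
                         doublet_latent = NULL,
                         spill = config$spillover_truth) {
  fs <- config$frame_size
  latent$radius_px <- latent$radius_um / config$pixel_size
  if (2 * ceiling(latent$radius_px) + 2 > fs)
    stop("frame too small for sampled cell (radius ",
         signif(latent$radius_um, 3), " um)", call. = FALSE)
  if (is.null(center)) center <- c(fs %/% 2, fs %/% 2)

  fluor <- ifc_fluor_channels()
  frames <- lapply(ifc_channels(), function(ch) matrix(0, fs, fs))
  names(frames) <- ifc_channels()

  cells <- list(list(latent = latent, center = as.integer(center)))
  if (!is.null(doublet_latent)) {
    doublet_latent$radius_px <- doublet_latent$radius_um / config$pixel_size
    off <- 0.9 * (latent$radius_px + doublet_latent$radius_px)
    ang <- stats::runif(1, 0, 2 * pi)
    c2 <- as.integer(round(center + off * c(cos(ang), sin(ang))))
    # keep the partner inside the frame
    h2 <- ceiling(doublet_latent$radius_px) + 6
    c2 <- pmin(pmax(c2, h2 + 1L), fs - h2)
    cells[[2]] <- list(latent = doublet_latent, center = c2)
  }

  for (cell in cells) {
    lat <- cell$latent
    half <- ceiling(lat$radius_px) + 6
    ctr <- cell$center
    if (any(ctr - half < 1) || any(ctr + half > fs)) {
      half <- min(ctr - 1, fs - ctr)   # clip margin for edge-touching cells
      if (half < ceiling(lat$radius_px))
        stop("frame too small for sampled cell (radius ",
             signif(lat$radius_um, 3), " um)", call. = FALSE)
    }
    p <- .render_patches(lat, half)
    frames$Ch01 <- .add_patch(frames$Ch01, p$bf, ctr[1], ctr[2], half)
    frames$Ch06 <- .add_patch(frames$Ch06, p$ssc, ctr[1], ctr[2], half)
    for (ch in fluor) {
      w <- switch(ch, Ch07 = p$w_dna, Ch08 = p$w_membrane, p$w_cell)
      frames[[ch]] <- .add_patch(frames[[ch]], lat$totals[[ch]] * w,
                                 ctr[1], ctr[2], half)
    }
  }

  if (out_of_focus) {
    for (ch in c("Ch01", "Ch06", "Ch07"))
      frames[[ch]] <- EBImage::gblur(frames[[ch]], sigma = 3,
                                     radius = 9)
  }

  # spillover mixing of the fluorescence channels (per pixel)
  Ftrue <- vapply(fluor, function(ch) as.vector(frames[[ch]]),
                  numeric(fs * fs))
  Fobs <- Ftrue %*% t(spill[fluor, fluor])
  for (i in seq_along(fluor))
    frames[[fluor[i]]] <- matrix(Fobs[, i], fs, fs)

  bg <- .bg_offset()
  for (ch in ifc_channels()) {
    x <- frames[[ch]] + bg[[ch]]
    if (config$noise && ch == "Ch01")
      x <- x + stats::rnorm(fs * fs, 0, 12)
    x <- pmin(pmax(x, 0), config$adc_max)
    if (config$quantize) {
      x <- round(x)
      storage.mode(x) <- "integer"   # halves the memory of event stores
    }
    frames[[ch]] <- x
  }

  if (saturated) {
    peak <- vapply(frames[fluor], max, numeric(1))
    ch <- fluor[which.max(peak)]
    x <- frames[[ch]]
    top <- order(x, decreasing = TRUE)[1:2]
    x[top] <- config$adc_max
    frames[[ch]] <- x
  }

  structure(list(channels = frames, adc_max = config$adc_max,
                 center = as.integer(center)),
            class = "ifc_event")
}
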