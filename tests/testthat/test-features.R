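# Masks and morphometric/intensity features: closed-form oracles on
# rasterised shapes plus invariance properties.

test_that("gradient RMS matches hand arithmetic and its invariances", {
  # constant raster
  expect_equal(gradient_rms(matrix(5, 8, 8)), 0)
  # 3x3 spike: central differences with replicated edges give magnitude 2
  # at the four edge centres and 0 elsewhere -> RMS = sqrt(16/9)
  r <- matrix(0, 3, 3); r[2, 2] <- 4
  expect_equal(gradient_rms(r), sqrt(16 / 9))
  # additive invariance
  set.seed(1)
  x <- matrix(rnorm(400), 20)
  expect_equal(gradient_rms(x), gradient_rms(x + 17.3))
  # averaging blur strictly reduces the score for non-constant rasters
  blur3 <- function(m) {
    k <- matrix(1 / 9, 3, 3)
    as.matrix(EBImage::filter2(m, k))
  }
  for (i in 1:5) {
    x <- matrix(rnorm(400, sd = i), 20)
    expect_lt(gradient_rms(blur3(x)), gradient_rms(x))
  }
  # empty mask scores 0
  expect_equal(gradient_rms(x, matrix(FALSE, 20, 20)), 0)
})

test_that("shape features match moment and boundary oracles", {
  px <- 0.3
  # 2:1 axis-aligned rectangle: aspect ratio exactly 0.5
  rc <- shape_features(rect_mask(20, 10), px)
  expect_equal(rc$aspect_ratio, 0.5)
  expect_equal(rc$area_um2, 200 * px^2)
  # rasterised disc: near-unit aspect, area within 10% of pi r^2
  d <- disc_mask(12)
  dc <- shape_features(d, px)
  expect_gte(dc$aspect_ratio, 0.95)
  expect_lte(dc$aspect_ratio, 1.0)
  expect_lt(abs(sum(d) - pi * 144) / (pi * 144), 0.10)
  # disc is rounder than an elongated blob of the same area
  blob <- rect_mask(48, 9, size = 60)   # 432 px, close to disc area 441
  expect_gt(dc$circularity, shape_features(blob, px)$circularity)
  # single-pixel mask: circularity is the +Inf sentinel
  m1 <- matrix(FALSE, 5, 5); m1[3, 3] <- TRUE
  expect_equal(shape_features(m1, px)$circularity, Inf)
  expect_error(shape_features(matrix(FALSE, 4, 4), px), "non-empty")
})

test_that("cell mask finds the object and flags blank frames", {
  # uniform raster -> empty, flagged
  cm <- cell_mask(matrix(3000, 48, 48))
  expect_true(cm$empty)
  expect_equal(sum(cm$mask), 0)
  # synthetic dark disc on bright background, radius 10
  set.seed(2)
  bg <- matrix(3000 + rnorm(64^2, 0, 10), 64)
  d <- disc_mask(10, 64)
  img <- bg - 600 * d
  cm2 <- cell_mask(img)
  expect_false(cm2$empty)
  expect_lt(abs(sum(cm2$mask) - pi * 100) / (pi * 100), 0.10)
  # two touching discs give a single connected mask spanning both
  img2 <- bg
  sh <- function(m, k) m[, c((k + 1):64, rep(64, k))]
  both <- d | sh(d, 18)
  img2 <- bg - 600 * both
  cm3 <- cell_mask(img2)
  expect_false(cm3$empty)
  expect_gt(sum(cm3$mask), 1.8 * pi * 100)
  expect_equal(max(EBImage::bwlabel(cm3$mask)), 1)
})

test_that("membrane ring is a boundary set of the expected size", {
  d <- disc_mask(10, 40)
  cm <- structure(list(mask = d, origin = "whole_cell", empty = FALSE),
                  class = "ifc_mask")
  ring <- membrane_mask(cm, ring_width = 2L)
  # disjoint from the 2-px erosion, inside the 1-px dilation
  ero <- EBImage::erode(d, EBImage::makeBrush(5, "disc")) > 0
  dil <- EBImage::dilate(d, EBImage::makeBrush(3, "disc")) > 0
  expect_equal(sum(ring$mask & ero), 0L)
  expect_true(all(dil[ring$mask]))
  expect_lt(sum(ring$mask), sum(d))
  expect_error(membrane_mask(cm, 0), "ring_width")
})

test_that("membrane ring captures the bulk of a membrane-localised stain", {
  # identity spillover so Ch08 carries only the membrane-rendered CD45
  S <- diag(7)
  dimnames(S) <- list(ifc_fluor_channels(), ifc_fluor_channels())
  r1 <- render_one("HSC", seed = 4,
                   config = one_sample_config(1, 4, noise = FALSE,
                                              spillover_truth = S))
  ev <- r1$event
  cm <- cell_mask(ev$channels$Ch01)
  mm <- membrane_mask(cm, 3L)
  bg <- stats::median(ev$channels$Ch08)
  ring_sum <- sum(ev$channels$Ch08[mm$mask] - bg)
  cell_sum <- sum(ev$channels$Ch08[cm$mask | mm$mask] - bg)
  expect_gte(ring_sum / cell_sum, 0.80)
})

test_that("intensity features: saturation counting and planted budgets", {
  cfg <- one_sample_config(1, 9, noise = FALSE, quantize = FALSE,
                           spillover_truth = diag(7) + 0)
  dimnames(cfg$spillover_truth) <- list(ifc_fluor_channels(),
                                        ifc_fluor_channels())
  r1 <- render_one("LSC", seed = 9, config = cfg)
  ev <- r1$event
  cm <- cell_mask(ev$channels$Ch01)
  mm <- membrane_mask(cm, 3L)
  intf <- intensity_features(ev, cm, mm)
  # noiseless render with identity spillover: recovered intensity equals
  # the planted photon budget up to the soft-edge tail that falls outside
  # the thresholded mask (a few percent of whole-cell signal)
  for (ch in c("Ch07", "Ch11", "Ch03")) {
    planted <- r1$latent$totals[[ch]]
    expect_lt(abs(intf[[paste0("intensity_", ch)]] - planted) / planted,
              0.06)
  }
  # saturation bookkeeping: plant a single clipped pixel
  ev$channels$Ch10[5, 5] <- ev$adc_max
  intf2 <- intensity_features(ev, cm, mm)
  expect_equal(intf2$sat_count_Ch10, 1)
  expect_equal(intf2$raw_max_Ch10, ev$adc_max)
  # missing channel errors by name
  ev$channels$Ch04 <- NULL
  expect_error(intensity_features(ev, cm, mm), "Ch04")
})

test_that("features are translation invariant for a noiseless render", {
  cfg <- one_sample_config(1, 12, noise = FALSE, quantize = FALSE)
  set.seed(12)
  lat <- ifcstem:::sample_latent("HSC", cfg, "P5")
  set.seed(99)
  ev1 <- render_event(lat, cfg, center = c(28, 28))
  set.seed(99)
  ev2 <- render_event(lat, cfg, center = c(33, 33))
  ev1$event_id <- ev2$event_id <- "e"; ev1$sample_id <- ev2$sample_id <- "s"
  ev1$time <- ev2$time <- 0; ev1$patient_id <- ev2$patient_id <- "P"
  st <- function(ev) structure(list(events = list(ev),
                                    meta = data.frame(event_id = "e"),
                                    frame_size = cfg$frame_size,
                                    pixel_size = cfg$pixel_size,
                                    adc_max = cfg$adc_max, kind = "AML"),
                               class = "ifc_store")
  f1 <- ifc_features(st(ev1))
  f2 <- ifc_features(st(ev2))
  num <- vapply(f1, is.numeric, TRUE)
  expect_equal(unlist(f1[, num]), unlist(f2[, num]), tolerance = 1e-6)
})

test_that("shape features depend only on the mask, never on intensities", {
  d <- disc_mask(9)
  s1 <- shape_features(d, 0.3)
  s2 <- shape_features(d, 0.3)   # same mask, any raster content irrelevant
  expect_identical(s1, s2)
  expect_named(s1, c("area_um2", "aspect_ratio", "circularity"))
})
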