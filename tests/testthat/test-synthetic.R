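# Synthetic cohort generator: ground-truth bookkeeping, determinism,
# control-store structure and planted-effect behaviour.

test_that("configuration invariants are enforced", {
  expect_error(one_sample_config(10, 1, mix = pure_mix("HSC") + 0.01),
               "sum to 1")
  expect_error(one_sample_config(10, 1, frame_size = 160), "at most 150")
  expect_error(one_sample_config(10, 1,
                                 artifact_rates = c(doublet = -0.1,
                                                    out_of_focus = 0,
                                                    saturated = 0)),
               "rates")
  bad_mix <- pure_mix("HSC"); names(bad_mix)[2] <- "blast"
  expect_error(one_sample_config(10, 1, mix = bad_mix), "populations")
})

test_that("degenerate mixture yields a single population", {
  cfg <- one_sample_config(40, 5, mix = pure_mix("HSC"))
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh$truth), 40)
  expect_true(all(coh$truth$true_population == "HSC"))
  expect_equal(length(coh$store$events), 40)
})

test_that("identical configurations generate identical stores", {
  cfg <- one_sample_config(30, 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$store$events, b$store$events)
  # different seed changes the draw
  c2 <- generate_cohort(one_sample_config(30, 8))
  expect_false(identical(a$truth$radius_um, c2$truth$radius_um))
})

test_that("event geometry and pixel-range invariants hold", {
  coh <- fixture("aml2000", function()
    generate_cohort(one_sample_config(2000, 13)))
  ev <- coh$store$events[[1]]
  dims <- vapply(ev$channels, dim, integer(2))
  expect_true(all(dims == 64))
  for (ev in coh$store$events[seq(1, 2000, by = 97)]) {
    px <- unlist(ev$channels)
    expect_gte(min(px), 0)
    expect_lte(max(px), 4095)
    expect_true(all(px == round(px)))
  }
})

test_that("truth LSC count lies in the exact binomial interval", {
  # one AML sample, default LSC fraction 0.30, n = 2000
  coh <- fixture("aml2000", function()
    generate_cohort(one_sample_config(2000, 13)))
  k <- sum(coh$truth$true_population == "LSC")
  expect_gte(k, qbinom(0.005, 2000, 0.30))
  expect_lte(k, qbinom(0.995, 2000, 0.30))
})

test_that("emitted population fractions match the mixture", {
  coh <- fixture("aml2000", function()
    generate_cohort(one_sample_config(2000, 13)))
  tab <- table(factor(coh$truth$true_population, levels = all_pops))
  p <- ifc_default_mix("AML")[all_pops]
  expect_gt(chisq.test(as.vector(tab), p = p)$p.value, 0.01)
})

test_that("artifact flags mark real image properties", {
  coh <- fixture("aml2000", function()
    generate_cohort(one_sample_config(2000, 13)))
  tr <- coh$truth
  # saturation flag implies a clipped pixel in some fluorescence channel
  idx <- which(tr$is_saturated)[1:5]
  for (i in idx) {
    mx <- max(vapply(coh$store$events[[i]]$channels[ifc_fluor_channels()],
                     max, numeric(1)))
    expect_equal(mx, 4095)
  }
  # unstable-window flag matches the configured burst interval
  expect_true(all(tr$time[tr$in_unstable_window] >= 20 &
                    tr$time[tr$in_unstable_window] <= 25))
  # the burst raises the in-window event count well above the uniform share
  expect_gt(sum(tr$in_unstable_window), 2 * 2000 * 5 / 120)
})

test_that("out-of-focus rendering strictly lowers the focus score", {
  cfg <- one_sample_config(1, 31)
  for (s in 1:4) {
    set.seed(s)
    lat <- ifcstem:::sample_latent("LSC", cfg, "P5")
    set.seed(100 + s)
    sharp <- render_event(lat, cfg)
    set.seed(100 + s)
    blurred <- render_event(lat, cfg, out_of_focus = TRUE)
    g1 <- gradient_rms(sharp$channels$Ch01, cell_mask(sharp$channels$Ch01))
    g2 <- gradient_rms(blurred$channels$Ch01,
                       cell_mask(blurred$channels$Ch01))
    expect_lt(g2, g1)
  }
})

test_that("dead cells and debris have their defining signatures", {
  dead <- class_store("dead", 25, 41)
  live <- class_store("HSC", 25, 42)
  deb <- class_store("debris", 25, 43)
  f_dead <- ifc_features(dead); f_live <- ifc_features(live)
  f_deb <- ifc_features(deb)
  # viability dye uptake: dead cells far above the live distribution
  expect_gt(min(f_dead$intensity_Ch02),
            quantile(f_live$intensity_Ch02, 0.99))
  # debris mask area below the smallest cell class's 1st percentile
  lym <- ifc_features(class_store("lymphocyte", 25, 44))
  expect_lt(median(f_deb$area_um2), quantile(lym$area_um2, 0.01))
})

test_that("doublets render as touching pairs with larger masks", {
  cfg <- one_sample_config(40, 17, mix = pure_mix("HSC"),
                           artifact_rates = c(doublet = 1, out_of_focus = 0,
                                              saturated = 0))
  coh <- generate_cohort(cfg)
  expect_true(all(coh$truth$is_doublet))
  ft <- ifc_features(coh$store)
  single <- ifc_features(class_store("HSC", 40, 17))
  expect_gt(median(ft$area_um2), 1.5 * median(single$area_um2))
  expect_lt(median(ft$aspect_ratio), 0.75)
})

test_that("frame too small for the sampled cell raises a generation error", {
  cfg <- one_sample_config(5, 3, mix = pure_mix("granulocyte"),
                           frame_size = 32)
  expect_error(generate_cohort(cfg), "frame too small")
})

test_that("brightfield class separation scales with the BF effect size", {
  stat_gap <- function(eff) {
    cfgH <- one_sample_config(30, 51, mix = pure_mix("HSC"),
                              effect_sizes = c(BF = eff, SSC = 1, DNA = 1))
    cfgL <- one_sample_config(30, 52, mix = pure_mix("LSC"),
                              effect_sizes = c(BF = eff, SSC = 1, DNA = 1))
    fH <- ifc_features(generate_cohort(cfgH)$store)
    fL <- ifc_features(generate_cohort(cfgL)$store)
    abs(mean(fL$gradient_rms_bf) - mean(fH$gradient_rms_bf))
  }
  gaps <- vapply(c(0.25, 1, 2.5), stat_gap, numeric(1))
  expect_true(all(diff(gaps) > 0))
})

test_that("control stores have the stated staining structure", {
  cfg <- one_sample_config(150, 19, n_events_per_control = 150)
  ctl <- make_controls(cfg)
  expect_setequal(names(ctl$single_stain), ifc_fluor_channels())
  # FM2 carries spillover from its stained channels, so the background-only
  # property of its blanked channels shows on compensated intensities
  S <- structure(ifcstem:::.sample_spillover("AML1", cfg),
                 condition_number = 1, class = "spillover_matrix")
  fm2 <- compensate(ifc_features(ctl$per_sample$AML1$fm2), S)
  unst <- compensate(ifc_features(ctl$per_sample$AML1$unstained), S)
  # FM2: CD38/CLEC12A at background level only
  expect_lte(median(fm2$intensity_Ch03),
             median(unst$intensity_Ch03) * 1.05 + 50)
  expect_lte(median(fm2$intensity_Ch10),
             median(unst$intensity_Ch10) * 1.05 + 50)
  # FM2 retains the other stains (DNA signal far above unstained)
  expect_gt(median(fm2$intensity_Ch07), 10 * (median(unst$intensity_Ch07) + 1))
  # DNA-only control: Ch07 stained, CD34 at background
  dna <- ifc_features(ctl$per_sample$AML1$dna_only)
  expect_gt(median(dna$intensity_Ch07), 10 * (median(dna$intensity_Ch11) + 1))
})
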