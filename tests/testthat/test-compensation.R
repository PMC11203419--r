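# Spillover estimation (no-intercept regression on single-stain controls)
# and matrix-inverse compensation.

# Synthetic feature table with planted spillover: primary channel bright,
# off-channels = S[i, j] * primary + independent background.
fake_single_stain <- function(ch, S, n = 400, seed = 1) {
  set.seed(seed)
  x <- rlnorm(n, log(20000), 0.6)
  ft <- data.frame(event_id = sprintf("%s_%04d", ch, 1:n))
  for (i in ifc_fluor_channels())
    ft[[paste0("intensity_", i)]] <-
      if (i == ch) x else S[i, ch] * x + rnorm(n, 0, 30)
  ft
}

fake_controls <- function(S, n = 400, seed = 1) {
  out <- lapply(seq_along(ifc_fluor_channels()), function(k)
    fake_single_stain(ifc_fluor_channels()[k], S, n, seed + k))
  names(out) <- ifc_fluor_channels()
  out
}

test_that("estimation recovers planted matrices and the identity", {
  S0 <- diag(7); dimnames(S0) <- list(ifc_fluor_channels(),
                                      ifc_fluor_channels())
  est0 <- estimate_spillover(fake_controls(S0))
  expect_lt(max(abs(est0 - S0)), 0.01)
  S1 <- ifc_default_spillover()
  est1 <- estimate_spillover(fake_controls(S1))
  expect_lt(max(abs(est1 - S1)), 0.01)
  expect_equal(unname(diag(est1)), rep(1, 7))
})

test_that("slopes agree with the least-squares oracle and scale invariance", {
  S <- ifc_default_spillover()
  ctl <- fake_controls(S, n = 500, seed = 9)
  est <- estimate_spillover(ctl)
  # independent oracle: no-intercept lm on the same table
  o <- unname(coef(lm(intensity_Ch04 ~ intensity_Ch03 - 1,
                      data = ctl$Ch03)))
  expect_equal(unname(est["Ch04", "Ch03"]), o, tolerance = 1e-8)
  expect_equal(o, 0.12, tolerance = 0.02)
  # doubling all intensities leaves slopes unchanged
  ctl2 <- lapply(ctl, function(ft) {
    ft[grep("^intensity_", names(ft))] <-
      ft[grep("^intensity_", names(ft))] * 2
    ft
  })
  expect_equal(unclass(estimate_spillover(ctl2)), unclass(est),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("estimation errors on degenerate controls", {
  S <- diag(7); dimnames(S) <- list(ifc_fluor_channels(),
                                    ifc_fluor_channels())
  ctl <- fake_controls(S)
  ctl$Ch10$intensity_Ch10 <- 0
  expect_error(estimate_spillover(ctl), "Ch10")
  expect_error(estimate_spillover(ctl[1:3]), "missing")
})

test_that("single-stain stores from the generator yield the truth slopes", {
  S <- ifc_default_spillover()
  S["Ch10", "Ch11"] <- 0.15   # planted spill for the worked example
  cfg <- one_sample_config(1, 27, n_events_per_control = 350,
                           spillover_truth = S)
  ctl <- make_controls(cfg)
  ft11 <- ifc_features(ctl$single_stain$Ch11)
  slope <- unname(coef(lm(intensity_Ch10 ~ intensity_Ch11 - 1,
                          data = ft11)))
  expect_lt(abs(slope - 0.15), 0.02)
})

test_that("compensation inverts mixing and leaves raw pixel stats alone", {
  set.seed(5)
  fluor <- ifc_fluor_channels()
  for (rep in 1:10) {
    S <- diag(7) + matrix(runif(49, 0, 0.3), 7) * (1 - diag(7))
    dimnames(S) <- list(fluor, fluor)
    truth <- matrix(rlnorm(7 * 20, log(5000), 1), 20, 7,
                    dimnames = list(NULL, fluor))
    mixed <- truth %*% t(S)
    ft <- data.frame(event_id = sprintf("e%02d", 1:20))
    for (i in seq_along(fluor)) {
      ft[[paste0("intensity_", fluor[i])]] <- mixed[, i]
      ft[[paste0("raw_max_", fluor[i])]] <- 4095
      ft[[paste0("sat_count_", fluor[i])]] <- 0
    }
    comp <- compensate(ft, S)
    got <- as.matrix(comp[, paste0("intensity_", fluor)])
    expect_equal(unname(got), unname(truth), tolerance = 1e-9)
    expect_true(all(comp$raw_max_Ch10 == 4095))
  }
  # identity leaves the table unchanged
  S1 <- diag(7); dimnames(S1) <- list(fluor, fluor)
  expect_equal(compensate(ft, S1)[, paste0("intensity_", fluor)],
               ft[, paste0("intensity_", fluor)], tolerance = 1e-12)
  # a singular matrix is rejected with a condition-number report
  Sbad <- matrix(1, 7, 7); dimnames(Sbad) <- list(fluor, fluor)
  expect_error(compensate(ft, Sbad), "condition number")
})

test_that("compensation removes spill-induced channel correlation", {
  sim <- fixture("sim_small", function()
    ifc_simulate(one_sample_config(1000, 23, n_events_per_control = 300)))
  g <- fixture("gate_small", function() ifc_gate(sim))
  raw <- ifc_features(sim$cohort$store)
  comp <- g$results$AML1$features
  # DNA (Ch07) spills into CD45 (Ch08): correlation within the CD45-low
  # stem/progenitor compartment (homogeneous CD45) drops after
  # compensation
  nuc <- sim$cohort$truth$true_population %in%
    c("HSC", "LSC", "progenitor")
  r_raw <- cor(raw$intensity_Ch07[nuc], raw$intensity_Ch08[nuc])
  r_comp <- cor(comp$intensity_Ch07[nuc], comp$intensity_Ch08[nuc])
  expect_gt(r_raw, 0.3)
  expect_lt(abs(r_comp), r_raw)
})

test_that("per-sample DNA column re-estimation tracks the scaled truth", {
  sim <- fixture("sim_small", function()
    ifc_simulate(one_sample_config(1000, 23, n_events_per_control = 300)))
  cfg <- one_sample_config(1000, 23, n_events_per_control = 300)
  S_est <- estimate_spillover(sim$controls$single_stain)
  S_s <- update_dna_spillover(S_est,
                              ifc_features(sim$controls$per_sample$AML1$dna_only))
  S_true <- ifcstem:::.sample_spillover("AML1", cfg)
  expect_lt(max(abs(S_s[, "Ch07"] - S_true[, "Ch07"])), 0.02)
  # non-DNA columns are untouched
  expect_equal(S_s[, "Ch02"], S_est[, "Ch02"])
})
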