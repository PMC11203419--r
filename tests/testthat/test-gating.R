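# The eleven-step gate sequence: control-anchored thresholds, boundary
# semantics, short-circuiting, report telescoping and truth recovery.

# Minimal feature table where every event passes every gate unless a field
# is perturbed.
passing_features <- function(n = 6) {
  n1 <- max(n, 1L)
  ft <- data.frame(
    event_id = sprintf("e%02d", seq_len(n1)),
    sample_id = "S", patient_id = "P", time = seq_len(n1) + 30,
    mask_empty = FALSE,
    gradient_rms_bf = 120, area_um2 = 40, aspect_ratio = 0.95,
    circularity = 20, cd45_membrane_intensity = 6000,
    stringsAsFactors = FALSE
  )
  vals <- c(Ch02 = 200, Ch03 = 9000, Ch04 = 300, Ch07 = 40000,
            Ch08 = 7000, Ch10 = 300, Ch11 = 15000)
  for (ch in ifc_fluor_channels()) {
    ft[[paste0("intensity_", ch)]] <- vals[[ch]]
    ft[[paste0("raw_max_", ch)]] <- 3000
    ft[[paste0("sat_count_", ch)]] <- 0
    ft[[paste0("membrane_", ch)]] <- vals[[ch]]
  }
  ft$intensity_Ch06 <- 5000
  ft[seq_len(n), , drop = FALSE]
}

manual_thresholds <- function() {
  thr <- ifc_gate_defaults()
  thr$clec12a_pos_min <- 500
  thr$cd38_pos_min <- 900
  thr$vdcv_pos_min <- 320
  thr$zg_live_max <- 3000
  thr$time_windows_excluded <- matrix(c(20, 25), 1,
                                      dimnames = list(NULL,
                                                      c("start", "end")))
  structure(thr, class = "gate_thresholds")
}

test_that("all-pass input gives 100% at every gate and full telescoping", {
  res <- apply_gates(passing_features(8), manual_thresholds(), "AML")
  expect_true(all(res$final_label == "LSC"))
  rep_ <- gate_report(res)
  expect_true(all(rep_$pct_of_parent == 100))
  expect_equal(rep_$parent[-1], rep_$child[-nrow(rep_)])
  # NBM labelling
  res2 <- apply_gates(passing_features(3), manual_thresholds(), "NBM")
  expect_true(all(res2$final_label == "HSC"))
})

test_that("single gate failures exclude at the right step and short-circuit", {
  thr <- manual_thresholds()
  perturb <- list(
    focus = function(ft) { ft$gradient_rms_bf <- 10; ft },
    unsaturated = function(ft) { ft$sat_count_Ch10 <- 1; ft },
    stable_time = function(ft) { ft$time <- 22; ft },
    singlet = function(ft) { ft$aspect_ratio <- 0.5; ft },
    live = function(ft) { ft$intensity_Ch02 <- 50000; ft },
    nucleated = function(ft) { ft$intensity_Ch07 <- 100; ft },
    cd45low = function(ft) { ft$intensity_Ch06 <- 30000; ft },
    cd14neg = function(ft) { ft$intensity_Ch04 <- 20000; ft },
    cd34pos_cd38neg = function(ft) { ft$intensity_Ch10 <- 5000; ft },
    clec12a_pos = function(ft) { ft$intensity_Ch03 <- 100; ft },
    circular = function(ft) { ft$circularity <- 3; ft }
  )
  for (gate in names(perturb)) {
    ft <- perturb[[gate]](passing_features(1))
    res <- apply_gates(ft, thr, "AML")
    expect_equal(res$final_label, paste0("excluded@", gate), info = gate)
    k <- match(gate, colnames(res$gates))
    if (k < ncol(res$gates))
      expect_true(all(is.na(res$gates[1, (k + 1):ncol(res$gates)])),
                  info = gate)
  }
  # saturation excludes regardless of later features (raw max variant too)
  ft <- passing_features(1); ft$raw_max_Ch03 <- 4096
  expect_equal(apply_gates(ft, thr, "AML")$final_label,
               "excluded@unsaturated")
})

test_that("boundary semantics: circularity exactly at the cut is excluded", {
  ft <- passing_features(1)
  ft$circularity <- 5
  res <- apply_gates(ft, manual_thresholds(), "AML")
  expect_equal(res$final_label, "excluded@circular")
  ft$circularity <- 5 + 1e-9
  expect_equal(apply_gates(ft, manual_thresholds(), "AML")$final_label,
               "LSC")
})

test_that("CLEC12A gate applies to AML only and is monotone in its cut", {
  ft <- passing_features(6)
  ft$intensity_Ch03 <- c(100, 400, 600, 2000, 9000, 50)
  thr <- manual_thresholds()
  res_nbm <- apply_gates(ft, thr, "NBM")
  expect_true(all(res_nbm$final_label == "HSC"))
  counts <- vapply(c(50, 500, 5000, 1e5), function(cut) {
    thr$clec12a_pos_min <- cut
    sum(apply_gates(ft, thr, "AML")$final_label == "LSC")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("final population equals the unconditional conjunction of gates", {
  # gates short-circuit for reporting, but the surviving set must be the
  # plain AND of all predicates, so reordering pure filters cannot change it
  set.seed(8)
  ft <- passing_features(60)
  ft$gradient_rms_bf <- sample(c(10, 120), 60, TRUE)
  ft$time <- sample(c(22, 40), 60, TRUE)
  ft$sat_count_Ch07 <- sample(c(0, 1), 60, TRUE)
  ft$intensity_Ch03 <- sample(c(100, 9000), 60, TRUE)
  thr <- manual_thresholds()
  res <- apply_gates(ft, thr, "AML")
  manual <- ft$gradient_rms_bf >= thr$focus_min &
    ft$sat_count_Ch07 < 1 &
    !(ft$time >= 20 & ft$time < 25) &
    ft$intensity_Ch03 >= thr$clec12a_pos_min
  expect_equal(res$final_label == "LSC", manual)
})

test_that("gate_report handles empty input without division errors", {
  res <- apply_gates(passing_features(0), manual_thresholds(), "AML")
  rep_ <- gate_report(res)
  expect_equal(rep_$parent, rep(0L, 11))
  expect_equal(rep_$pct_of_parent, rep(0, 11))
})

test_that("schema errors name the missing column", {
  ft <- passing_features(2)
  ft$intensity_Ch04 <- NULL
  expect_error(apply_gates(ft, manual_thresholds(), "AML"),
               "intensity_Ch04")
})

test_that("threshold fitting anchors on the control quantiles", {
  fm2 <- data.frame(intensity_Ch03 = runif(400, 0, 800),
                    intensity_Ch10 = runif(400, 0, 900))
  unst <- data.frame(intensity_Ch07 = runif(400, 0, 300),
                     intensity_Ch02 = runif(400, 0, 200))
  smp <- data.frame(intensity_Ch02 = c(rlnorm(300, log(250), 0.4),
                                       rlnorm(60, log(30000), 0.4)),
                    time = runif(360, 0, 60))
  thr <- fit_thresholds(smp, fm2, unst)
  expect_gte(thr$clec12a_pos_min,
             quantile(fm2$intensity_Ch03, 0.995) - 1e-9)
  expect_equal(thr$cd38_pos_min, quantile(fm2$intensity_Ch10, 0.995,
                                          names = FALSE))
  expect_equal(thr$vdcv_pos_min, quantile(unst$intensity_Ch07, 0.99,
                                          names = FALSE))
  # viability valley lies between the two planted modes
  expect_gt(thr$zg_live_max, quantile(smp$intensity_Ch02[1:300], 0.99))
  expect_lt(thr$zg_live_max, 19000)
  # determinism on identical stores
  thr2 <- fit_thresholds(smp, fm2, unst)
  expect_identical(thr[names(thr) != "time_windows_excluded"],
                   thr2[names(thr2) != "time_windows_excluded"])
  # unimodal viability distribution falls back with a warning
  smp2 <- smp; smp2$intensity_Ch02 <- rlnorm(360, log(250), 0.4)
  expect_warning(thr3 <- fit_thresholds(smp2, fm2, unst), "unimodal")
  expect_equal(thr3$zg_live_max, quantile(unst$intensity_Ch02, 0.99,
                                          names = FALSE))
})

test_that("unstable-flow windows are detected from event-rate bursts", {
  set.seed(3)
  base <- runif(3000, 0, 120)
  burst <- runif(700, 20, 25)
  win <- detect_unstable_windows(c(base, burst))
  expect_gte(nrow(win), 1)
  expect_true(any(win[, "start"] <= 20.5 & win[, "end"] >= 24.5))
  expect_equal(nrow(detect_unstable_windows(base)), 0)
})

test_that("gating a synthetic cohort recovers truth LSCs with high purity", {
  sim <- fixture("sim_small", function()
    ifc_simulate(one_sample_config(1000, 23, n_events_per_control = 300)))
  g <- fixture("gate_small", function() ifc_gate(sim))
  tr <- sim$cohort$truth
  res <- g$results$AML1
  lab <- res$gates$final_label
  sel <- lab == "LSC"
  expect_gt(sum(sel), 100)
  # purity: selected events are overwhelmingly truth LSCs
  expect_gte(mean(tr$true_population[sel] == "LSC"), 0.95)
  # recovery of artifact-passing truth LSCs
  clean <- !tr$is_doublet & !tr$is_out_of_focus & !tr$is_saturated &
    !tr$in_unstable_window
  den <- tr$true_population == "LSC" & clean
  expect_gte(sum(sel & den) / sum(den), 0.90)
  # report telescopes
  rep_ <- gate_report(res$gates)
  expect_equal(rep_$parent[-1], rep_$child[-nrow(rep_)])
  # CLEC12A false-positive rate among truth-negative stem cells stays at
  # the quantile level the FM2 anchors (binomial upper bound around 0.5%)
  stem_neg <- tr$true_population == "HSC" & clean
  if (sum(stem_neg) >= 10) {
    fp <- sum(res$features$intensity_Ch03[stem_neg] >=
                res$thresholds$clec12a_pos_min)
    expect_lte(fp, qbinom(0.995, sum(stem_neg), 0.02))
  }
})
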