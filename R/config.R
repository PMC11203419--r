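#' Default per-population morphology parameters
#'
#' One row per population. Units: radii in micrometres; `edge_depth` and
#' `bf_texture_sd` in ADC counts on the brightfield channel;
#' `granule_lambda` is the Poisson mean granule count and
#' `granule_brightness` the mean integrated signal per granule (ADC counts);
#' `nuclear_fraction` is the nuclear radius as a fraction of the cell radius;
#' `dna_texture_rel` is the relative (multiplicative) chromatin texture
#' amplitude. `aspect_min` is the lower bound of the sampled minor/major
#' axis ratio.
#'
#' Class differences are ordered brightfield > DNA > side scatter: LSCs
#' differ from HSCs most in cell size and brightfield texture, moderately in
#' nuclear size/chromatin texture, and only subtly in granularity.
#'
#' @return A data.frame with one row per population.
#' @export
ifc_default_morphology <- function() {
  m <- data.frame(
    population        = ifc_populations(),
    radius_um         = c(3.4, 4.0, 3.0, 4.8, 5.0, 3.5, 3.1, 0.9),
    radius_sd         = c(0.22, 0.28, 0.20, 0.30, 0.30, 0.22, 0.25, 0.25),
    aspect_min        = c(0.85, 0.85, 0.88, 0.80, 0.80, 0.85, 0.75, 0.50),
    edge_depth        = c(620, 720, 600, 650, 680, 640, 700, 160),
    bf_texture_sd     = c(45, 70, 40, 70, 75, 55, 90, 25),
    granule_lambda    = c(5.0, 5.8, 2.0, 9.0, 25.0, 5.0, 5.0, 0),
    granule_brightness = c(900, 900, 800, 950, 1300, 900, 700, 0),
    nuclear_fraction  = c(0.74, 0.63, 0.85, 0.60, 0.55, 0.72, 0.60, 0),
    dna_texture_rel   = c(0.60, 0.85, 0.55, 0.70, 0.65, 0.70, 1.20, 0),
    stringsAsFactors  = FALSE
  )
  rownames(m) <- m$population
  m
}

#' Default per-population marker intensity parameters
#'
#' Median integrated fluorescence per event (ADC counts, before spillover
#' mixing) for each of the seven fluorescence channels, plus the per-channel
#' log-normal `sdlog`. Positives and negatives are separated by roughly two
#' orders of magnitude, reproducing the bimodal structure the gating
#' sequence relies on (CLEC12A positivity appears only on LSCs and,
#' dimly, on monocytes/granulocytes; CD34 marks the stem/progenitor
#' compartment; CD38 separates progenitors from HSC/LSC).
#'
#' @return A list with `median` (population x channel matrix) and `sdlog`
#'   (named per-channel vector).
#' @export
ifc_default_markers <- function() {
  ch <- ifc_fluor_channels()
  pops <- ifc_populations()
  med <- matrix(0, length(pops), length(ch), dimnames = list(pops, ch))
  #                     ZG      CLEC12A CD14   VDCV   CD45   CD38   CD34
  med["HSC", ]        <- c(250,  120,   200, 40000,  6000,   250, 15000)
  med["LSC", ]        <- c(250, 20000,  200, 48000,  6000,   250, 15000)
  med["lymphocyte", ] <- c(250,  120,   200, 40000, 60000,  2500,   150)
  med["monocyte", ]   <- c(250, 8000, 30000, 45000, 40000, 12000,   150)
  med["granulocyte", ] <- c(250, 3000, 1500, 42000, 25000,  2500,   150)
  med["progenitor", ] <- c(250,  600,   200, 50000,  7000, 15000, 15000)
  med["dead", ]       <- c(30000, 400,  400, 30000,  8000,   800,   400)
  med["debris", ]     <- c(60,    60,    60,    50,    60,    60,    60)
  sdlog <- c(Ch02 = 0.40, Ch03 = 0.50, Ch04 = 0.50, Ch07 = 0.35,
             Ch08 = 0.35, Ch10 = 0.50, Ch11 = 0.50)
  # per-channel autofluorescence medians: the background level measured in
  # unstained cells, matching each channel's negative-population level so
  # that FM2-blanked channels anchor positivity at the sample's negatives
  autofluor <- c(Ch02 = 250, Ch03 = 120, Ch04 = 200, Ch07 = 100,
                 Ch08 = 150, Ch10 = 250, Ch11 = 120)
  list(median = med, sdlog = sdlog, autofluor = autofluor)
}

#' Default population mixtures
#'
#' Event fractions per population for AML-like and NBM-like samples. The
#' stem-cell compartment is enriched far beyond unsorted marrow so that
#' desk-scale runs yield usable HSC/LSC counts; the AML mixture carries a
#' 0.30 LSC fraction.
#'
#' @param kind `"AML"` or `"NBM"`.
#' @return Named numeric vector summing to 1.
#' @export
ifc_default_mix <- function(kind = c("AML", "NBM")) {
  kind <- match.arg(kind)
  if (kind == "AML") {
    c(HSC = 0.02, LSC = 0.30, lymphocyte = 0.20, monocyte = 0.12,
      granulocyte = 0.12, progenitor = 0.14, dead = 0.06, debris = 0.04)
  } else {
    c(HSC = 0.06, LSC = 0.00, lymphocyte = 0.38, monocyte = 0.16,
      granulocyte = 0.18, progenitor = 0.12, dead = 0.06, debris = 0.04)
  }
}

#' Default spillover truth matrix
#'
#' Square mixing matrix over the seven fluorescence channels; entry
#' `S[i, j]` is the fraction of channel-`j` signal appearing in channel `i`.
#' Diagonal is exactly 1; off-diagonals are modest (< 0.3) single-direction
#' spills between spectrally adjacent detector pairs.
#'
#' @return 7 x 7 numeric matrix with channel dimnames.
#' @export
ifc_default_spillover <- function() {
  ch <- ifc_fluor_channels()
  S <- diag(length(ch))
  dimnames(S) <- list(ch, ch)
  S["Ch03", "Ch02"] <- 0.10   # viability dye into PE
  S["Ch04", "Ch03"] <- 0.12   # PE into PE-Texas Red
  S["Ch03", "Ch04"] <- 0.05
  S["Ch08", "Ch07"] <- 0.15   # DNA dye into KrO (405 nm pair)
  S["Ch07", "Ch08"] <- 0.04
  S["Ch10", "Ch08"] <- 0.06
  S["Ch10", "Ch11"] <- 0.08
  S["Ch11", "Ch10"] <- 0.03
  S
}

#' Default per-patient LSC morphology offsets
#'
#' Additive offsets applied to the LSC morphology means for events belonging
#' to each synthetic AML patient, emulating inter-patient morphological
#' heterogeneity. Patient `P1` is deliberately shifted towards the HSC
#' phenotype (smaller, smoother, fewer granules), so brightfield-based
#' classifiers recall its LSCs worst.
#'
#' @return A data.frame with one row per patient.
#' @export
ifc_default_patients <- function() {
  data.frame(
    patient_id            = paste0("P", 1:5),
    radius_shift_um       = c(-0.55, 0.05, -0.05, 0.10, 0.00),
    granule_shift         = c(-0.70, 0.30, -0.30, 0.50, 0.00),
    nuclear_texture_shift = c(-0.20, -0.04, 0.03, 0.05, 0.00),
    bf_texture_shift      = c(-22, -4, 2, 4, 0),
    edge_depth_shift      = c(-85, -8, 4, 6, 0),
    stringsAsFactors      = FALSE
  )
}

#' Generator configuration
#'
#' Builds the configuration object consumed by [generate_cohort()] and
#' [make_controls()]. Defaults define the package's reference study
#' conditions; every field can be overridden.
#'
#' @param n_events_per_sample Events generated per declared sample.
#' @param samples data.frame with columns `sample_id`, `kind`
#'   (`"AML"`/`"NBM"`) and `patient_id` (`NA` for NBM donors).
#' @param population_mix Either a single named fraction vector used for all
#'   samples, or a list with `AML` and `NBM` elements picked by sample kind.
#' @param artifact_rates Named fractions `doublet`, `out_of_focus`,
#'   `saturated`.
#' @param unstable_window List `start`, `end` (seconds) and
#'   `rate_multiplier`: event rate inside the window relative to outside.
#' @param acquisition_duration Total acquisition time per sample (seconds).
#' @param patient_profiles Per-patient LSC morphology offsets; see
#'   [ifc_default_patients()].
#' @param morphology_params See [ifc_default_morphology()].
#' @param marker_params See [ifc_default_markers()].
#' @param effect_sizes Named multipliers `BF`, `SSC`, `DNA` scaling the
#'   LSC-minus-HSC differences of the corresponding morphology parameters.
#' @param spillover_truth Mixing matrix; see [ifc_default_spillover()].
#' @param dna_spill_range Per-sample uniform range scaling the DNA (Ch07)
#'   spillover column, emulating sample-to-sample DNA signal variation.
#' @param frame_size Square frame side in pixels (at most 150).
#' @param pixel_size Micrometres per pixel (default 0.3, emulating 60x
#'   magnification).
#' @param adc_max Maximum ADC value (default 4095, 12-bit).
#' @param n_events_per_control Events per control store.
#' @param noise Logical; disable to render noise-free images.
#' @param quantize Logical; disable to keep continuous pixel values.
#' @param seed Integer seed governing the whole generation.
#' @return An object of class `ifc_config`.
#' @export
ifc_config <- function(n_events_per_sample = 2000,
                       samples = NULL,
                       population_mix = list(AML = ifc_default_mix("AML"),
                                             NBM = ifc_default_mix("NBM")),
                       artifact_rates = c(doublet = 0.03, out_of_focus = 0.04,
                                          saturated = 0.01),
                       unstable_window = list(start = 20, end = 25,
                                              rate_multiplier = 4),
                       acquisition_duration = 120,
                       patient_profiles = ifc_default_patients(),
                       morphology_params = ifc_default_morphology(),
                       marker_params = ifc_default_markers(),
                       effect_sizes = c(BF = 1, SSC = 1, DNA = 1),
                       spillover_truth = ifc_default_spillover(),
                       dna_spill_range = c(0.8, 1.3),
                       frame_size = 64,
                       pixel_size = 0.3,
                       adc_max = 4095,
                       n_events_per_control = 500,
                       noise = TRUE,
                       quantize = TRUE,
                       seed = 1L) {
  if (is.null(samples)) {
    samples <- data.frame(
      sample_id = paste0("AML", 1:5),
      kind = "AML",
      patient_id = paste0("P", 1:5),
      stringsAsFactors = FALSE
    )
  }
  cfg <- structure(list(
    n_events_per_sample = as.integer(n_events_per_sample),
    samples = samples,
    population_mix = population_mix,
    artifact_rates = artifact_rates,
    unstable_window = unstable_window,
    acquisition_duration = acquisition_duration,
    patient_profiles = patient_profiles,
    morphology_params = morphology_params,
    marker_params = marker_params,
    effect_sizes = effect_sizes,
    spillover_truth = spillover_truth,
    dna_spill_range = dna_spill_range,
    frame_size = as.integer(frame_size),
    pixel_size = pixel_size,
    adc_max = as.integer(adc_max),
    n_events_per_control = as.integer(n_events_per_control),
    noise = isTRUE(noise),
    quantize = isTRUE(quantize),
    seed = as.integer(seed)
  ), class = "ifc_config")
  validate_ifc_config(cfg)
  cfg
}

validate_ifc_config <- function(cfg) {
  mixes <- if (is.list(cfg$population_mix)) cfg$population_mix else
    list(cfg$population_mix)
  for (mx in mixes) {
    if (!setequal(names(mx), ifc_populations()))
      stop("population_mix must name exactly the supported populations",
           call. = FALSE)
    if (abs(sum(mx) - 1) > 1e-9)
      stop("population_mix fractions must sum to 1 (got ", sum(mx), ")",
           call. = FALSE)
    if (any(mx < 0)) stop("population_mix fractions must be >= 0",
                          call. = FALSE)
  }
  if (any(cfg$artifact_rates < 0) || any(cfg$artifact_rates > 1))
    stop("artifact rates must lie in [0, 1]", call. = FALSE)
  if (cfg$frame_size > 150)
    stop("frame_size must be at most 150 pixels", call. = FALSE)
  if (cfg$frame_size < 16)
    stop("frame_size too small (< 16 px)", call. = FALSE)
  mp <- cfg$morphology_params
  if (any(mp$radius_um <= 0) || any(mp$radius_sd <= 0))
    stop("all radii and radius spreads must be positive", call. = FALSE)
  if (any(cfg$marker_params$sdlog <= 0))
    stop("all marker sdlog values must be positive", call. = FALSE)
  S <- cfg$spillover_truth
  if (!isTRUE(all.equal(diag(S), rep(1, nrow(S)), check.names = FALSE)))
    stop("spillover_truth diagonal must be exactly 1", call. = FALSE)
  off <- S[row(S) != col(S)]
  if (any(off < 0 | off >= 1))
    stop("spillover_truth off-diagonals must lie in [0, 1)", call. = FALSE)
  invisible(cfg)
}

#' @export
print.ifc_config <- function(x, ...) {
  cat("IFC generator configuration\n")
  cat("  samples:", nrow(x$samples), "(",
      paste(x$samples$sample_id, collapse = ", "), ")\n")
  cat("  events/sample:", x$n_events_per_sample,
      " frame:", x$frame_size, "x", x$frame_size,
      " pixel:", x$pixel_size, "um  adc_max:", x$adc_max, "\n")
  cat("  seed:", x$seed, " noise:", x$noise, " quantize:", x$quantize, "\n")
  invisible(x)
}

#' Read a generator configuration from YAML
#'
#' Scalar fields of the YAML document override the corresponding
#' [ifc_config()] defaults; unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @param seed Optional seed overriding the file's value.
#' @return An `ifc_config` object.
#' @export
read_ifc_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(ifc_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$samples)) raw$samples <- as.data.frame(raw$samples)
  if (!is.null(raw$spillover_truth))
    raw$spillover_truth <- {
      S <- do.call(rbind, raw$spillover_truth)
      dimnames(S) <- list(ifc_fluor_channels(), ifc_fluor_channels())
      S
    }
  if (!is.null(seed)) raw$seed <- as.integer(seed)
  do.call(ifc_config, raw)
}
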