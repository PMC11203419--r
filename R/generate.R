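# Cohort and control-store generation with ground truth.

# Deterministic per-sample scale factor for the DNA (Ch07) spillover
# column, emulating sample-to-sample variation in DNA signal strength.
.dna_spill_scale <- function(sample_id, config) {
  h <- sum(utf8ToInt(sample_id) * seq_along(utf8ToInt(sample_id)))
  frac <- ((config$seed * 7919 + h * 104729) %% 10007) / 10006
  rg <- config$dna_spill_range
  rg[1] + frac * (rg[2] - rg[1])
}

.sample_spillover <- function(sample_id, config) {
  S <- config$spillover_truth
  sc <- .dna_spill_scale(sample_id, config)
  off <- rownames(S) != "Ch07"
  S[off, "Ch07"] <- pmin(0.95, S[off, "Ch07"] * sc)
  S
}

# Acquisition times: uniform over the run, with an event-rate burst inside
# the configured unstable-flow window.
.sample_times <- function(n, config) {
  uw <- config$unstable_window
  D <- config$acquisition_duration
  L <- uw$end - uw$start
  m <- uw$rate_multiplier
  p_in <- m * L / ((D - L) + m * L)
  inside <- stats::runif(n) < p_in
  t <- numeric(n)
  t[inside] <- stats::runif(sum(inside), uw$start, uw$end)
  u <- stats::runif(sum(!inside), 0, D - L)
  t[!inside] <- ifelse(u < uw$start, u, u + L)
  t
}

.empty_truth <- function() {
  data.frame(event_id = character(), sample_id = character(),
             patient_id = character(), true_population = character(),
             is_doublet = logical(), is_out_of_focus = logical(),
             is_saturated = logical(), in_unstable_window = logical(),
             time = numeric(), stringsAsFactors = FALSE)
}

# Generate one store of n events for one sample. `marker_override` maps
# (totals, population) -> totals, used to emulate control staining.
.generate_store <- function(config, sample_id, kind, patient_id, n, mix,
                            marker_override = NULL, spill = NULL,
                            artifacts = TRUE) {
  if (is.null(spill)) spill <- .sample_spillover(sample_id, config)
  pops <- sample(names(mix), n, replace = TRUE, prob = mix)
  times <- .sample_times(n, config)
  ar <- if (artifacts) config$artifact_rates else
    c(doublet = 0, out_of_focus = 0, saturated = 0)
  fl_doub <- stats::runif(n) < ar[["doublet"]]
  fl_oof <- stats::runif(n) < ar[["out_of_focus"]]
  fl_sat <- stats::runif(n) < ar[["saturated"]]
  uw <- config$unstable_window
  fs <- config$frame_size

  events <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    lat <- sample_latent(pops[i], config, patient_id)
    if (!is.null(marker_override))
      lat$totals <- marker_override(lat$totals, pops[i])
    lat2 <- NULL
    if (fl_doub[i]) {
      lat2 <- sample_latent(pops[i], config, patient_id)
      if (!is.null(marker_override))
        lat2$totals <- marker_override(lat2$totals, pops[i])
      # keep the pair inside the frame
      fit <- function(l1, l2)
        (l1$radius_um + l2$radius_um) * 1.9 / config$pixel_size + 4 <= fs
      if (!fit(lat, lat2)) {
        shrink <- (fs - 4) * config$pixel_size / ((lat$radius_um +
                                                     lat2$radius_um) * 1.9)
        lat$radius_um <- lat$radius_um * shrink
        lat2$radius_um <- lat2$radius_um * shrink
      }
    }
    ctr <- fs %/% 2 + sample(-3:3, 2, replace = TRUE)
    ev <- render_event(lat, config, center = ctr,
                       out_of_focus = fl_oof[i], saturated = fl_sat[i],
                       doublet_latent = lat2, spill = spill)
    id <- sprintf("%s_ev%05d", sample_id, i)
    ev$event_id <- id
    ev$sample_id <- sample_id
    ev$patient_id <- patient_id
    ev$time <- times[i]
    events[[i]] <- ev
    truth[[i]] <- data.frame(
      event_id = id, sample_id = sample_id,
      patient_id = if (is.na(patient_id)) NA_character_ else patient_id,
      true_population = pops[i],
      is_doublet = fl_doub[i], is_out_of_focus = fl_oof[i],
      is_saturated = fl_sat[i],
      in_unstable_window = times[i] >= uw$start & times[i] <= uw$end,
      time = times[i],
      radius_um = lat$radius_um, aspect = lat$aspect,
      granule_count = lat$granule_count,
      nuclear_fraction = lat$nuclear_fraction,
      stringsAsFactors = FALSE
    )
    for (ch in ifc_fluor_channels())
      truth[[i]][[paste0("total_", ch)]] <- lat$totals[[ch]]
  }
  truth <- do.call(rbind, truth)
  meta <- truth[, c("event_id", "sample_id", "patient_id", "time")]
  meta$adc_max <- config$adc_max
  structure(list(events = events, meta = meta, truth = truth,
                 frame_size = fs, pixel_size = config$pixel_size,
                 adc_max = config$adc_max, kind = kind),
            class = "ifc_store")
}

#' @export
print.ifc_store <- function(x, ...) {
  cat("IFC event store:", length(x$events), "events,",
      x$frame_size, "x", x$frame_size, "px,",
      length(ifc_channels()), "channels\n")
  cat("  samples:", paste(unique(x$meta$sample_id), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.ifc_store <- function(x) length(x$events)

# Concatenate stores (shared geometry assumed).
.bind_stores <- function(stores) {
  st <- stores[[1]]
  st$events <- do.call(c, lapply(stores, `[[`, "events"))
  st$meta <- do.call(rbind, lapply(stores, `[[`, "meta"))
  st$truth <- do.call(rbind, lapply(stores, `[[`, "truth"))
  rownames(st$meta) <- rownames(st$truth) <- NULL
  st
}

#' Generate a seeded synthetic IFC cohort with ground truth
#'
#' Draws `n_events_per_sample` events for every sample declared in the
#' configuration. Each event carries nine channel images (see
#' [render_event()]); the truth table records the population label,
#' artifact flags and the sampled latent morphology/marker values.
#' Identical configurations (including the seed) give identical output.
#'
#' @param config An [ifc_config()].
#' @return A list with `store` (an `ifc_store`) and `truth` (data.frame,
#'   one row per event).
#' @export
generate_cohort <- function(config) {
  validate_ifc_config(config)
  set.seed(config$seed)
  stores <- list()
  for (k in seq_len(nrow(config$samples))) {
    srow <- config$samples[k, ]
    mix <- if (is.list(config$population_mix))
      config$population_mix[[srow$kind]] else config$population_mix
    stores[[k]] <- .generate_store(config, srow$sample_id, srow$kind,
                                   srow$patient_id,
                                   config$n_events_per_sample, mix)
  }
  store <- .bind_stores(stores)
  list(store = store, truth = store$truth)
}

#' Generate one single-stain compensation control store
#'
#' Bead-style events stained in a single fluorescence channel (bright
#' log-normal signal before spillover mixing) with near-zero off-channel
#' autofluorescence: cell-level autofluorescence would bias the
#' through-origin spillover slopes upward. Generating stores one channel
#' at a time lets callers reduce each to a feature table before building
#' the next.
#'
#' @param config An [ifc_config()].
#' @param channel One fluorescence channel id.
#' @return An `ifc_store`.
#' @export
make_single_stain_store <- function(config, channel) {
  channel <- match.arg(channel, ifc_fluor_channels())
  set.seed(config$seed + 101L +
             7L * match(channel, ifc_fluor_channels()))
  bead_mix <- c(HSC = 0.5, LSC = 0, lymphocyte = 0.5, monocyte = 0,
                granulocyte = 0, progenitor = 0, dead = 0, debris = 0)
  ovr <- function(tot, pop) {
    tot[] <- stats::rlnorm(length(tot), log(30), 0.5)
    tot[[channel]] <- stats::rlnorm(1, log(20000), 0.6)
    tot
  }
  .generate_store(config, paste0("SS_", channel), "control",
                  NA_character_, config$n_events_per_control, bead_mix,
                  marker_override = ovr, spill = config$spillover_truth,
                  artifacts = FALSE)
}

#' Generate the control stores for compensation and gating thresholds
#'
#' Emits, per declared sample, a fluorescence-minus-two (FM2) store in which
#' CD38 (Ch10) and CLEC12A (Ch03) signal is generated at background level
#' only, an unstained store (all channels at autofluorescence level) and a
#' DNA-dye-only store; plus one single-stain store per fluorescence channel
#' (signal only in that channel before spillover mixing), shared across
#' samples as bead-style compensation controls.
#'
#' @param config An [ifc_config()].
#' @param what Which control families to generate (both by default).
#' @return A list with `single_stain` (list by channel id) and `per_sample`
#'   (list by sample id of lists `fm2`, `unstained`, `dna_only`).
#' @export
make_controls <- function(config, what = c("single_stain", "per_sample")) {
  what <- match.arg(what, several.ok = TRUE)
  validate_ifc_config(config)
  nc <- config$n_events_per_control
  fluor <- ifc_fluor_channels()
  af <- config$marker_params$autofluor
  if (is.null(af))
    af <- setNames(rep(100, length(fluor)), fluor)
  auto <- function(chs) stats::rlnorm(length(chs), log(af[chs]), 0.5)

  single <- list()
  if ("single_stain" %in% what) for (ch in fluor)
    single[[ch]] <- make_single_stain_store(config, ch)

  per_sample <- list()
  if ("per_sample" %in% what) for (k in seq_len(nrow(config$samples))) {
    srow <- config$samples[k, ]
    set.seed(config$seed + 211L + 13L * k)
    mix <- if (is.list(config$population_mix))
      config$population_mix[[srow$kind]] else config$population_mix
    fm2 <- .generate_store(config, paste0(srow$sample_id, "_FM2"), srow$kind,
                           srow$patient_id, nc, mix,
                           marker_override = function(tot, pop) {
                             tot[c("Ch03", "Ch10")] <-
                               auto(c("Ch03", "Ch10"))
                             tot
                           },
                           spill = .sample_spillover(srow$sample_id, config))
    unst <- .generate_store(config, paste0(srow$sample_id, "_UNST"),
                            srow$kind, srow$patient_id, nc, mix,
                            marker_override = function(tot, pop) {
                              tot[] <- auto(names(tot))
                              tot
                            },
                            spill = .sample_spillover(srow$sample_id, config))
    dna <- .generate_store(config, paste0(srow$sample_id, "_DNA"),
                           srow$kind, srow$patient_id, nc, mix,
                           marker_override = function(tot, pop) {
                             keep <- tot[["Ch07"]]
                             tot[] <- auto(names(tot))
                             tot[["Ch07"]] <- keep
                             tot
                           },
                           spill = .sample_spillover(srow$sample_id, config))
    per_sample[[srow$sample_id]] <- list(fm2 = fm2, unstained = unst,
                                         dna_only = dna)
  }
  list(single_stain = single, per_sample = per_sample)
}
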