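# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

all_pops <- c("HSC", "LSC", "lymphocyte", "monocyte", "granulocyte",
              "progenitor", "dead", "debris")

pure_mix <- function(pop) {
  mix <- setNames(rep(0, length(all_pops)), all_pops)
  mix[pop] <- 1
  mix
}

one_sample_config <- function(n, seed, kind = "AML", patient = "P5",
                              mix = NULL, ...) {
  args <- list(
    n_events_per_sample = n,
    samples = data.frame(sample_id = paste0(kind, "1"), kind = kind,
                         patient_id = if (kind == "AML") patient else
                           NA_character_,
                         stringsAsFactors = FALSE),
    seed = seed, ...
  )
  if (!is.null(mix)) args$population_mix <- mix
  do.call(ifc_config, args)
}

# Pure-population store without acquisition artifacts (for classifier and
# feature fixtures).
class_store <- function(pop, n, seed, patient = "P5", ...) {
  cfg <- one_sample_config(
    n, seed, patient = patient, mix = pure_mix(pop),
    artifact_rates = c(doublet = 0, out_of_focus = 0, saturated = 0), ...)
  cfg$samples$sample_id <- paste0(pop, "_", patient)
  generate_cohort(cfg)$store
}

bind_stores <- function(stores) bind_event_stores(stores)

# One rendered event from explicit latent parameters, drawn reproducibly.
render_one <- function(pop = "HSC", seed = 1, config = NULL, ...) {
  if (is.null(config)) config <- one_sample_config(1, seed)
  set.seed(seed)
  lat <- ifcstem:::sample_latent(pop, config, "P5")
  list(latent = lat, config = config,
       event = render_event(lat, config, ...))
}

# Rasterised solid shapes for mask/shape oracles.
disc_mask <- function(r, size = 2 * r + 9) {
  ctr <- (size + 1) / 2
  d <- sqrt(outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2, "+"))
  d <= r
}

rect_mask <- function(w, h, size = max(w, h) + 8) {
  m <- matrix(FALSE, size, size)
  m[4:(3 + w), 4:(3 + h)] <- TRUE
  m
}
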