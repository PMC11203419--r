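# Orchestration of the full analysis: simulate -> gate -> balance/split ->
# train the seven models -> evaluate the per-patient holdout. These
# functions (plus the thin wrapper script in inst/cli/) are the pipeline's
# command surface; every stage is reproducible from (config, seed).

#' Simulate a cohort plus all control stores
#'
#' @param config An [ifc_config()].
#' @param out_dir Optional directory; when given, the cohort store, truth
#'   table and a run manifest (config hash, seed) are persisted.
#' @param force Overwrite an existing non-empty `out_dir`.
#' @return List with `cohort` (store + truth), `controls` and `manifest`.
#' @export
ifc_simulate <- function(config, out_dir = NULL, force = FALSE) {
  cohort <- generate_cohort(config)
  controls <- make_controls(config)
  manifest <- list(config_hash = .config_hash(config), seed = config$seed,
                   n_events = length(cohort$store$events),
                   samples = config$samples$sample_id,
                   created = "run")
  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force)
      stop("output directory ", out_dir, " is not empty; use force = TRUE",
           call. = FALSE)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_event_store(cohort$store, file.path(out_dir, "cohort"),
                      force = force)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(cohort = cohort, controls = controls, manifest = manifest)
}

#' Compensate and gate a simulated cohort
#'
#' Estimates the spillover matrix from the single-stain controls,
#' re-estimates the DNA column per sample from its DNA-only control,
#' compensates each sample's feature table, fits control-anchored
#' thresholds and applies the eleven-step gate sequence.
#'
#' @param sim Output of [ifc_simulate()] (or a list with `cohort` and
#'   `controls`).
#' @param gate_config Defaults from [ifc_gate_defaults()].
#' @param spillover Optional precomputed `spillover_matrix` (skips
#'   estimation).
#' @return List with `spillover`, per-sample `results` (each: `features`,
#'   `thresholds`, `gates`, `report`) and `populations` (data.frame of
#'   final HSC/LSC labels with sample/patient ids).
#' @export
ifc_gate <- function(sim, gate_config = ifc_gate_defaults(),
                     spillover = NULL) {
  store <- sim$cohort$store
  controls <- sim$controls
  if (is.null(spillover))
    spillover <- estimate_spillover(controls$single_stain)
  feats <- ifc_features(store)
  results <- list()
  pops <- list()
  for (s in unique(store$meta$sample_id)) {
    kind <- store$meta$patient_id[store$meta$sample_id == s][1]
    kind <- if (is.na(kind)) "NBM" else "AML"
    ctl <- controls$per_sample[[s]]
    if (is.null(ctl))
      stop("no per-sample controls for sample ", s, call. = FALSE)
    S_s <- update_dna_spillover(spillover, ifc_features(ctl$dna_only))
    fts <- feats[feats$sample_id == s, , drop = FALSE]
    comp <- compensate(fts, S_s)
    fm2 <- compensate(ifc_features(ctl$fm2), S_s)
    unst <- compensate(ifc_features(ctl$unstained), S_s)
    thr <- fit_thresholds(comp, fm2, unst, gate_config)
    res <- apply_gates(comp, thr, kind)
    results[[s]] <- list(features = comp, thresholds = thr, gates = res,
                         report = gate_report(res))
    keep <- res$final_label %in% c("HSC", "LSC")
    if (any(keep))
      pops[[s]] <- data.frame(
        event_id = comp$event_id[keep],
        sample_id = s,
        patient_id = comp$patient_id[keep],
        label = res$final_label[keep],
        stringsAsFactors = FALSE)
  }
  populations <- if (length(pops)) do.call(rbind, pops) else
    data.frame(event_id = character(), sample_id = character(),
               patient_id = character(), label = character())
  rownames(populations) <- NULL
  list(spillover = spillover, results = results, populations = populations)
}

#' Balance classes and build the train/val/test split and holdout
#'
#' Under-samples the majority class to the minority class size using the
#' per-sample water-filling allocation, splits both classes 80/10/10
#' (stratified) and groups the undrawn LSCs into per-patient holdout sets.
#'
#' @param populations The `populations` frame from [ifc_gate()], or any
#'   data.frame with `event_id`, `sample_id`, `patient_id`, `label`.
#' @param target_total Balanced size per class; defaults to the minority
#'   class count.
#' @param seed Seed for the draws.
#' @return List with `allocation`, `split` (an `ifc_split`), `holdout`
#'   (patient -> event ids) and `drawn` (balanced LSC ids).
#' @export
ifc_balance_split <- function(populations, target_total = NULL, seed = 1L) {
  hsc <- populations[populations$label == "HSC", , drop = FALSE]
  lsc <- populations[populations$label == "LSC", , drop = FALSE]
  if (nrow(hsc) < 10 || nrow(lsc) < 10)
    stop("need at least 10 events per class to split", call. = FALSE)
  if (is.null(target_total)) target_total <- min(nrow(hsc), nrow(lsc))
  avail <- vapply(split(lsc$event_id, lsc$sample_id), length, 1L)
  alloc <- balance_classes(avail, target_total)
  set.seed(as.integer(seed))
  drawn <- unlist(take_allocation(split(lsc$event_id, lsc$sample_id),
                                  alloc), use.names = FALSE)
  hsc_ids <- hsc$event_id
  if (nrow(hsc) > target_total)
    hsc_ids <- sample(hsc_ids, target_total)
  split_df <- split_train_val_test(list(HSC = hsc_ids, LSC = drawn),
                                   seed = seed)
  hold <- holdout_sets(split(lsc$event_id, lsc$patient_id), drawn)
  list(allocation = alloc, split = split_df, holdout = hold, drawn = drawn)
}

#' Train CNN models over channel combinations
#'
#' Prepares the three image channels once for all split events, then trains
#' one model per requested combination on the train/validation partitions
#' and evaluates it on the test partition.
#'
#' @param store The `ifc_store` holding all split events.
#' @param split An `ifc_split`.
#' @param combos Combination names (default all seven).
#' @param spec_base A [cnn_spec()] supplying everything but the channels.
#' @param quiet Suppress progress messages.
#' @return List per combo: `model` (`ifc_cnn`), `metrics` (`ifc_metrics`),
#'   `confusion` and test `predictions`.
#' @export
ifc_train_all <- function(store, split, combos = names(ifc_channel_combos()),
                          spec_base = cnn_spec(), quiet = FALSE) {
  bad <- setdiff(combos, names(ifc_channel_combos()))
  if (length(bad))
    stop("unknown combo(s): ", paste(bad, collapse = ", "), call. = FALSE)
  all_ch <- c("Ch01", "Ch06", "Ch07")
  x_all <- prepare_inputs(store, split$event_id, all_ch,
                          spec_base$input_size)
  part <- split$partition
  y <- split$class
  out <- list()
  for (cb in combos) {
    ch <- ifc_channel_combos()[[cb]]
    ci <- match(ch, all_ch)
    spec <- spec_base
    spec$combo_name <- cb
    spec$channels <- ch
    pick <- function(p) x_all[, , ci, part == p, drop = FALSE]
    if (!quiet) message("training ", cb, " model ...")
    model <- ifc_cnn(pick("train"), y[part == "train"],
                     pick("val"), y[part == "val"], spec)
    pred <- predict(model, pick("test"))
    cm <- confusion(y[part == "test"], as.character(pred))
    out[[cb]] <- list(model = model, confusion = cm,
                      metrics = metric_report(cm),
                      predictions = data.frame(
                        event_id = split$event_id[part == "test"],
                        truth = y[part == "test"],
                        predicted = as.character(pred),
                        prob_lsc = attr(pred, "prob")[, "LSC"],
                        stringsAsFactors = FALSE))
  }
  out
}

#' Evaluate trained models on the per-patient LSC holdout
#'
#' Classifies the held-out (all-LSC) events with every model and reports
#' per-patient and pooled LSC recall.
#'
#' @param store The `ifc_store` holding the holdout events.
#' @param holdout Patient -> event ids, from [ifc_balance_split()].
#' @param models List of `ifc_cnn` models (as from [ifc_train_all()],
#'   elements may be the fit lists or bare models).
#' @return List with `table` (data.frame patient x model recall %, plus a
#'   pooled row) and `per_model` (raw [patient_recall()] outputs).
#' @export
ifc_evaluate_holdout <- function(store, holdout, models) {
  ids <- unlist(holdout, use.names = FALSE)
  if (length(ids) == 0)
    stop("holdout is empty", call. = FALSE)
  pat <- rep(names(holdout), vapply(holdout, length, 1L))
  all_ch <- c("Ch01", "Ch06", "Ch07")
  x_all <- NULL
  rows <- list()
  per_model <- list()
  for (nm in names(models)) {
    m <- models[[nm]]
    if (!inherits(m, "ifc_cnn")) m <- m$model
    if (is.null(x_all))
      x_all <- prepare_inputs(store, ids, all_ch, m$spec$input_size)
    ci <- match(m$spec$channels, all_ch)
    pred <- predict(m, x_all[, , ci, , drop = FALSE])
    pr <- patient_recall(as.character(pred), pat)
    per_model[[nm]] <- pr
    rows[[nm]] <- data.frame(model = nm,
                             patient = c(pr$per_patient$patient, "pooled"),
                             n = c(pr$per_patient$n, length(ids)),
                             recall_pct = c(pr$per_patient$recall_pct,
                                            pr$pooled_pct),
                             stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, per_model = per_model)
}
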