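# Event-store persistence: one multi-page TIFF per event (pages ordered by
# channel id) under <sample>/<event_id>.tiff, with CSV sidecar metadata and
# truth tables.

#' Write an event store to disk
#'
#' Layout: `<dir>/<sample_id>/<event_id>.tiff` (16-bit multi-page TIFF,
#' pages in [ifc_channels()] order), `<dir>/events.csv` (event metadata)
#' and, when the store carries ground truth, `<dir>/truth.csv`.
#'
#' @param store An `ifc_store`.
#' @param dir Output directory.
#' @param force Overwrite an existing non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_event_store <- function(store, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force)
    stop("output directory ", dir, " is not empty; use force = TRUE",
         call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ev in store$events) {
    sdir <- file.path(dir, ev$sample_id)
    dir.create(sdir, showWarnings = FALSE)
    pages <- lapply(ifc_channels(), function(ch)
      ev$channels[[ch]] / 65535)
    tiff::writeTIFF(pages, file.path(sdir, paste0(ev$event_id, ".tiff")),
                    bits.per.sample = 16L, compression = "none")
  }
  utils::write.csv(store$meta, file.path(dir, "events.csv"),
                   row.names = FALSE)
  if (!is.null(store$truth))
    utils::write.csv(store$truth, file.path(dir, "truth.csv"),
                     row.names = FALSE)
  geom <- data.frame(frame_size = store$frame_size,
                     pixel_size = store$pixel_size,
                     adc_max = store$adc_max, kind = store$kind)
  utils::write.csv(geom, file.path(dir, "geometry.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read an event store written by [write_event_store()]
#'
#' @param dir Store directory.
#' @return An `ifc_store`.
#' @export
read_event_store <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "events.csv"),
                          stringsAsFactors = FALSE)
  geom <- utils::read.csv(file.path(dir, "geometry.csv"),
                          stringsAsFactors = FALSE)
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path))
    utils::read.csv(truth_path, stringsAsFactors = FALSE) else NULL
  events <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    path <- file.path(dir, meta$sample_id[i],
                      paste0(meta$event_id[i], ".tiff"))
    pages <- tiff::readTIFF(path, all = TRUE)
    channels <- lapply(pages, function(p) round(p * 65535))
    names(channels) <- ifc_channels()
    events[[i]] <- structure(list(
      channels = channels, adc_max = meta$adc_max[i],
      event_id = meta$event_id[i], sample_id = meta$sample_id[i],
      patient_id = meta$patient_id[i], time = meta$time[i]
    ), class = "ifc_event")
  }
  structure(list(events = events, meta = meta, truth = truth,
                 frame_size = geom$frame_size, pixel_size = geom$pixel_size,
                 adc_max = geom$adc_max, kind = geom$kind),
            class = "ifc_store")
}

# Stable hash of a configuration (used to version run outputs).
.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[order(names(unclass(config)))]), tmp)
  unname(tools::md5sum(tmp))
}

#' Concatenate event stores
#'
#' Binds several stores (shared frame geometry) into one; metadata and
#' truth tables are stacked in order.
#'
#' @param stores List of `ifc_store` objects.
#' @return An `ifc_store`.
#' @export
bind_event_stores <- function(stores) .bind_stores(stores)

#' Subset a store by event ids
#' @param store An `ifc_store`.
#' @param event_ids Ids to keep (order preserved).
#' @return An `ifc_store`.
#' @export
subset_store <- function(store, event_ids) {
  ids <- vapply(store$events, `[[`, "", "event_id")
  pos <- match(event_ids, ids)
  if (anyNA(pos)) stop("unknown event id(s)", call. = FALSE)
  store$events <- store$events[pos]
  store$meta <- store$meta[pos, , drop = FALSE]
  if (!is.null(store$truth))
    store$truth <- store$truth[pos, , drop = FALSE]
  store
}
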