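# Class balancing by under-sampling (per-sample water-filling), the
# stratified 80/10/10 split and the per-patient holdout sets.

#' Balance a class across samples by iterative water-filling
#'
#' Distributes `target_total` take counts over samples: any sample whose
#' availability is below the current equal share contributes everything it
#' has; the remainder is split equally among the rest. The integer
#' remainder is handed out one per sample to the uncapped samples with the
#' largest availability (ties broken by ascending sample id) — the rule
#' that reproduces the reference allocation in which the sample with the
#' smallest uncapped pool receives the smaller share.
#'
#' @param available Named integer vector of per-sample availabilities.
#' @param target_total Total events to draw.
#' @return An `ifc_allocation`: list with `take` (named integer vector),
#'   `target_total` and `capped_samples`.
#' @export
balance_classes <- function(available, target_total) {
  if (is.null(names(available)) || any(!nzchar(names(available))))
    stop("available must be a named vector", call. = FALSE)
  available <- available[order(names(available))]
  if (sum(available) < target_total)
    stop("infeasible: only ", sum(available), " events available for a ",
         "target of ", target_total, call. = FALSE)
  take <- setNames(integer(length(available)), names(available))
  capped <- character(0)
  remaining <- as.integer(target_total)
  pool <- names(available)
  repeat {
    share <- remaining / length(pool)
    below <- pool[available[pool] < share]
    if (length(below) == 0) break
    take[below] <- available[below]
    capped <- c(capped, below)
    remaining <- remaining - sum(available[below])
    pool <- setdiff(pool, below)
    if (length(pool) == 0) break
  }
  if (length(pool) > 0) {
    base <- remaining %/% length(pool)
    extra <- remaining %% length(pool)
    take[pool] <- base
    if (extra > 0) {
      ord <- pool[order(-available[pool], pool)]
      take[ord[seq_len(extra)]] <- base + 1L
    }
  }
  stopifnot(sum(take) == target_total, all(take <= available))
  structure(list(take = take, target_total = as.integer(target_total),
                 capped_samples = sort(capped)),
            class = "ifc_allocation")
}

#' @export
print.ifc_allocation <- function(x, ...) {
  cat("Class-balancing allocation: target", x$target_total, "\n")
  print(x$take)
  if (length(x$capped_samples))
    cat("  capped (all events taken):",
        paste(x$capped_samples, collapse = ", "), "\n")
  invisible(x)
}

#' Draw the balanced event set according to an allocation
#'
#' Uniform sampling without replacement within each sample, using the
#' current RNG state (seed the run before calling).
#'
#' @param ids_by_sample Named list: sample id -> event ids available.
#' @param allocation An `ifc_allocation` over the same samples.
#' @return Named list: sample id -> drawn event ids.
#' @export
take_allocation <- function(ids_by_sample, allocation) {
  out <- list()
  for (s in names(allocation$take)) {
    ids <- ids_by_sample[[s]]
    k <- allocation$take[[s]]
    if (k > length(ids))
      stop("allocation for ", s, " exceeds availability", call. = FALSE)
    out[[s]] <- if (k == length(ids)) ids else sample(ids, k)
  }
  out
}

#' Stratified 80/10/10 train/validation/test split
#'
#' Per class of size n: validation and test sets each get round(n/10)
#' events (round-half-up) and training takes the remainder, so n = 8818
#' yields 7054/882/882. Assignment is uniformly random without replacement
#' per class.
#'
#' @param events_per_class Named list: class -> event ids.
#' @param seed Integer seed.
#' @return data.frame with columns `event_id`, `class`, `partition`;
#'   class `ifc_split`.
#' @export
split_train_val_test <- function(events_per_class, seed) {
  half_up <- function(x) floor(x + 0.5)
  out <- list()
  set.seed(as.integer(seed))
  for (cl in names(events_per_class)) {
    ids <- events_per_class[[cl]]
    n <- length(ids)
    if (n < 10) stop("class ", cl, " has fewer than 10 events",
                     call. = FALSE)
    n_val <- half_up(n / 10)
    n_test <- half_up(n / 10)
    perm <- sample(ids, n)
    part <- rep("train", n)
    part[seq_len(n_val)] <- "val"
    part[n_val + seq_len(n_test)] <- "test"
    out[[cl]] <- data.frame(event_id = perm, class = cl, partition = part,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("ifc_split", "data.frame")
  res
}

#' Per-patient holdout LSC sets
#'
#' The holdout is every gated LSC that was NOT drawn into the balanced
#' training pool, grouped by patient. A patient whose entire pool was drawn
#' has an empty holdout. Errors if the two sets overlap.
#'
#' @param lsc_ids_by_patient Named list: patient id -> all gated LSC event
#'   ids.
#' @param drawn_ids Character vector of event ids in the balanced set.
#' @return Named list: patient id -> held-out event ids.
#' @export
holdout_sets <- function(lsc_ids_by_patient, drawn_ids) {
  out <- list()
  for (p in names(lsc_ids_by_patient)) {
    ids <- lsc_ids_by_patient[[p]]
    held <- setdiff(ids, drawn_ids)
    if (length(intersect(held, drawn_ids)) > 0)
      stop("integrity error: holdout overlaps the balanced set",
           call. = FALSE)
    out[[p]] <- held
  }
  out
}
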