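# Ordered eleven-step immunophenotypic gating with control-anchored
# thresholds.

.gate_names <- c("focus", "unsaturated", "stable_time", "singlet", "live",
                 "nucleated", "cd45low", "cd14neg", "cd34pos_cd38neg",
                 "clec12a_pos", "circular")

#' Default gate threshold configuration
#'
#' Thresholds that are not anchored on control stores. Intensity floors and
#' ceilings are in the same integrated-ADC units as the feature table and
#' are matched to the default generator scales; all are overridable.
#'
#' @param focus_min Brightfield gradient-RMS floor (focus gate).
#' @param area_bounds_um2 Singlet area window (um^2).
#' @param aspect_min Singlet aspect-ratio floor.
#' @param cd45_floor,cd45_ceiling Membrane CD45 window of the CD45-low gate.
#' @param ssc_max SSC intensity ceiling of the CD45-low gate (excludes
#'   residual granulocytes).
#' @param cd14_pos_min CD14 positivity floor (monocyte exclusion).
#' @param cd34_pos_min CD34 positivity floor.
#' @param positivity_quantile FM2 quantile anchoring CD38/CLEC12A
#'   positivity boundaries.
#' @param circularity_min Circularity cut; events with circularity at or
#'   below this value are excluded.
#' @param raw_max_limit Raw max pixel limit of the saturation gate.
#' @param time_bin_s,time_rate_z Unstable-flow detection: sliding window
#'   width (s) and robust-SD multiplier on the event rate.
#' @return Named list of defaults.
#' @export
ifc_gate_defaults <- function(focus_min = 85,
                              area_bounds_um2 = c(12, 110),
                              aspect_min = 0.70,
                              cd45_floor = 1000,
                              cd45_ceiling = 22000,
                              ssc_max = 18000,
                              cd14_pos_min = 6000,
                              cd34_pos_min = 2500,
                              positivity_quantile = 0.995,
                              circularity_min = 5,
                              raw_max_limit = 4096,
                              time_bin_s = 1,
                              time_rate_z = 5) {
  as.list(environment())
}

# Valley between the two dominant modes of log1p(x); NULL if unimodal.
# min_sep (log units) keeps shoulder bumps of one mode from being read as
# the second mode: the negative and positive stain populations sit orders
# of magnitude apart.
.bimodal_valley <- function(x, min_sep = 2) {
  x <- x[is.finite(x)]
  t <- log1p(pmax(x, 0))
  if (length(unique(t)) < 10) return(NULL)
  d <- stats::density(t, n = 512)
  y <- d$y
  pk <- which(diff(sign(diff(y))) == -2) + 1
  pk <- pk[y[pk] >= 0.05 * max(y)]   # substantial modes only
  if (length(pk) < 2) return(NULL)
  pos <- pk[length(pk)]              # positive (bright) mode: rightmost
  left <- pk[d$x[pk] <= d$x[pos] - min_sep]
  if (length(left) == 0) return(NULL)
  neg <- left[which.max(y[left])]    # dominant negative mode
  valley <- neg - 1 + which.min(y[neg:pos])
  expm1(d$x[valley])
}

#' Detect unstable-flow time windows
#'
#' Bins acquisition times into `bin_s`-second windows and flags windows
#' whose event rate deviates from the median rate by more than `z` robust
#' standard deviations (1.4826 x MAD). Adjacent flagged windows are merged.
#'
#' @param times Event acquisition times (seconds).
#' @param bin_s Window width in seconds.
#' @param z Robust-SD multiplier.
#' @return A two-column matrix of excluded `[start, end)` intervals
#'   (possibly zero rows).
#' @export
detect_unstable_windows <- function(times, bin_s = 1, z = 5) {
  if (length(times) < 10)
    return(matrix(numeric(0), 0, 2,
                  dimnames = list(NULL, c("start", "end"))))
  edges <- seq(0, ceiling(max(times) / bin_s) * bin_s, by = bin_s)
  counts <- graphics::hist(times, breaks = edges, plot = FALSE)$counts
  med <- stats::median(counts)
  rsd <- stats::mad(counts)
  flagged <- if (rsd == 0) counts > med + z * sqrt(max(med, 1))
  else abs(counts - med) > z * rsd
  if (!any(flagged))
    return(matrix(numeric(0), 0, 2,
                  dimnames = list(NULL, c("start", "end"))))
  r <- rle(flagged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  out <- cbind(start = edges[starts[keep]], end = edges[ends[keep] + 1])
  out
}

#' Fit control-anchored gate thresholds
#'
#' CD38 and CLEC12A positivity boundaries are the configured quantile
#' (default 99.5%) of the FM2 store's compensated Ch10/Ch03 intensities.
#' The viability ceiling is the valley between the live and dead modes of
#' the stained sample's Ch02 distribution (floor-bounded by the unstained
#' 99th percentile; falls back to the unstained threshold with a warning if
#' the distribution is unimodal). The nucleation floor is the unstained
#' 99th percentile of Ch07. Unstable-flow windows are detected from the
#' sample's event times; the remaining cuts come from the defaults.
#'
#' @param sample_features Compensated feature table of the stained sample.
#' @param fm2_features,unstained_features Compensated feature tables of the
#'   sample's FM2 and unstained controls.
#' @param config Defaults from [ifc_gate_defaults()].
#' @return A `gate_thresholds` object.
#' @export
fit_thresholds <- function(sample_features, fm2_features,
                           unstained_features,
                           config = ifc_gate_defaults()) {
  q <- config$positivity_quantile
  thr <- config
  thr$clec12a_pos_min <- stats::quantile(fm2_features$intensity_Ch03, q,
                                         names = FALSE)
  thr$cd38_pos_min <- stats::quantile(fm2_features$intensity_Ch10, q,
                                      names = FALSE)
  thr$vdcv_pos_min <- stats::quantile(unstained_features$intensity_Ch07,
                                      0.99, names = FALSE)
  unst_zg <- stats::quantile(unstained_features$intensity_Ch02, 0.99,
                             names = FALSE)
  valley <- .bimodal_valley(sample_features$intensity_Ch02)
  if (is.null(valley)) {
    warning("Ch02 distribution looks unimodal; using unstained-based ",
            "viability threshold", call. = FALSE)
    thr$zg_live_max <- unst_zg
  } else {
    thr$zg_live_max <- max(valley, unst_zg)
  }
  thr$time_windows_excluded <-
    detect_unstable_windows(sample_features$time, config$time_bin_s,
                            config$time_rate_z)
  structure(thr, class = "gate_thresholds")
}

#' @export
print.gate_thresholds <- function(x, ...) {
  cat("Gate thresholds\n")
  cat(sprintf("  focus >= %.3g | singlet area [%g, %g] um2, aspect >= %g\n",
              x$focus_min, x$area_bounds_um2[1], x$area_bounds_um2[2],
              x$aspect_min))
  cat(sprintf("  ZG live <= %.4g | VDCV+ >= %.4g\n",
              x$zg_live_max, x$vdcv_pos_min))
  cat(sprintf("  CD45 membrane [%g, %g], SSC <= %g | CD14 < %g\n",
              x$cd45_floor, x$cd45_ceiling, x$ssc_max, x$cd14_pos_min))
  cat(sprintf("  CD34+ >= %g | CD38- < %.4g | CLEC12A+ >= %.4g\n",
              x$cd34_pos_min, x$cd38_pos_min, x$clec12a_pos_min))
  cat(sprintf("  circularity > %g | %d excluded time window(s)\n",
              x$circularity_min, nrow(x$time_windows_excluded)))
  invisible(x)
}

#' Apply the ordered eleven-step gating sequence
#'
#' Gates, in order: (1) in focus, (2) unsaturated in every fluorescence
#' channel, (3) stable flow, (4) singlet by area/aspect ratio, (5) live
#' (ZG negative-to-dim, inclusive of the valley), (6) nucleated (VDCV+),
#' (7) CD45-low/SSC window, (8) CD14-, (9) CD34+CD38-, (10, AML only)
#' CLEC12A+, (11) circularity above the cut. Gates short-circuit: an event
#' failing gate k has `NA` for all later gates. NBM survivors are labelled
#' `HSC`, AML survivors `LSC`; everything else `excluded@<gate>`.
#'
#' @param features Compensated `ifc_features` table.
#' @param thr A `gate_thresholds` object.
#' @param sample_kind `"AML"` or `"NBM"`.
#' @return An `ifc_gate_result`: list with `gates` (logical matrix,
#'   event x gate), `final_label` and `sample_kind`.
#' @export
apply_gates <- function(features, thr, sample_kind = c("AML", "NBM")) {
  sample_kind <- match.arg(sample_kind)
  needed <- c("gradient_rms_bf", "area_um2", "aspect_ratio", "circularity",
              "time", "cd45_membrane_intensity",
              paste0("intensity_", ifc_fluor_channels()),
              paste0("raw_max_", ifc_fluor_channels()),
              paste0("sat_count_", ifc_fluor_channels()),
              "intensity_Ch06")
  missing_col <- setdiff(needed, names(features))
  if (length(missing_col))
    stop("feature table lacks column(s): ",
         paste(missing_col, collapse = ", "), call. = FALSE)

  n <- nrow(features)
  fluor <- ifc_fluor_channels()
  unsat <- rep(TRUE, n)
  for (ch in fluor)
    unsat <- unsat & features[[paste0("raw_max_", ch)]] < thr$raw_max_limit &
      features[[paste0("sat_count_", ch)]] < 1
  tw <- thr$time_windows_excluded
  stable <- rep(TRUE, n)
  if (!is.null(tw) && nrow(tw) > 0)
    for (k in seq_len(nrow(tw)))
      stable <- stable & !(features$time >= tw[k, 1] &
                             features$time < tw[k, 2])

  preds <- list(
    focus = features$gradient_rms_bf >= thr$focus_min,
    unsaturated = unsat,
    stable_time = stable,
    singlet = features$area_um2 >= thr$area_bounds_um2[1] &
      features$area_um2 <= thr$area_bounds_um2[2] &
      features$aspect_ratio >= thr$aspect_min,
    live = features$intensity_Ch02 <= thr$zg_live_max,
    nucleated = features$intensity_Ch07 >= thr$vdcv_pos_min,
    cd45low = features$cd45_membrane_intensity >= thr$cd45_floor &
      features$cd45_membrane_intensity <= thr$cd45_ceiling &
      features$intensity_Ch06 <= thr$ssc_max,
    cd14neg = features$intensity_Ch04 < thr$cd14_pos_min,
    cd34pos_cd38neg = features$intensity_Ch11 >= thr$cd34_pos_min &
      features$intensity_Ch10 < thr$cd38_pos_min,
    clec12a_pos = if (sample_kind == "AML")
      features$intensity_Ch03 >= thr$clec12a_pos_min else rep(TRUE, n),
    circular = features$circularity > thr$circularity_min
  )
  gates <- matrix(NA, n, length(.gate_names),
                  dimnames = list(NULL, .gate_names))
  alive <- rep(TRUE, n)
  for (g in .gate_names) {
    gates[alive, g] <- preds[[g]][alive]
    alive <- alive & !is.na(gates[, g]) & gates[, g]
  }
  label <- character(n)
  label[alive] <- if (sample_kind == "AML") "LSC" else "HSC"
  first_fail <- apply(gates, 1, function(r) {
    i <- which(!r)[1]
    if (is.na(i)) NA_character_ else .gate_names[i]
  })
  excl <- !alive
  label[excl] <- paste0("excluded@", first_fail[excl])
  structure(list(gates = gates, final_label = label,
                 event_id = features$event_id,
                 sample_kind = sample_kind),
            class = "ifc_gate_result")
}

#' @export
print.ifc_gate_result <- function(x, ...) {
  cat("Gate result (", x$sample_kind, "):", length(x$final_label),
      "events,", sum(x$final_label %in% c("HSC", "LSC")),
      "in final population\n")
  print(gate_report(x))
  invisible(x)
}

#' Hierarchical gate count report
#'
#' Per gate: the parent population size (events reaching the gate), the
#' child size (events passing it) and the percent of parent, in gate order.
#' Counts telescope: each gate's child count is the next gate's parent
#' count.
#'
#' @param result An `ifc_gate_result`.
#' @return data.frame with columns `gate`, `parent`, `child`,
#'   `pct_of_parent`.
#' @export
gate_report <- function(result) {
  g <- result$gates
  parent <- integer(ncol(g))
  child <- integer(ncol(g))
  for (k in seq_len(ncol(g))) {
    evaluated <- !is.na(g[, k])
    parent[k] <- sum(evaluated)
    child[k] <- sum(g[evaluated, k])
  }
  data.frame(
    gate = colnames(g),
    parent = parent,
    child = child,
    pct_of_parent = ifelse(parent > 0, 100 * child / parent, 0),
    stringsAsFactors = FALSE
  )
}
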