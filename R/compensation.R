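# Spillover estimation from single-stain controls and intensity
# compensation by the matrix inverse.

#' Estimate the spillover matrix from single-stain controls
#'
#' Column `j` of the spillover matrix holds, for every off channel `i`, the
#' slope of the no-intercept least-squares regression of the channel-`i`
#' background-subtracted intensity on the channel-`j` intensity across the
#' events of channel `j`'s single-stain store ("best fit linear
#' regression"). The diagonal is set to 1 and negative slopes are clipped
#' to 0. Slopes through the origin are scale invariant, so the controls'
#' staining brightness does not matter.
#'
#' @param single_stain_stores Named list (by fluorescence channel id) of
#'   `ifc_store` objects, or of precomputed `ifc_features` tables.
#' @param feature_fn Function turning a store into a feature table
#'   (default [ifc_features()]).
#' @return A `spillover_matrix`: 7 x 7 matrix with a `condition_number`
#'   attribute.
#' @export
estimate_spillover <- function(single_stain_stores,
                               feature_fn = ifc_features) {
  fluor <- ifc_fluor_channels()
  missing_ch <- setdiff(fluor, names(single_stain_stores))
  if (length(missing_ch))
    stop("missing single-stain store(s) for: ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  S <- diag(length(fluor))
  dimnames(S) <- list(fluor, fluor)
  for (j in fluor) {
    obj <- single_stain_stores[[j]]
    ft <- if (inherits(obj, "ifc_features") || is.data.frame(obj)) obj
    else feature_fn(obj)
    xj <- ft[[paste0("intensity_", j)]]
    if (stats::var(xj) <= 0 || sum(xj^2) == 0)
      stop("degenerate single-stain control for channel ", j,
           ": no variance in primary-channel intensity", call. = FALSE)
    for (i in setdiff(fluor, j)) {
      xi <- ft[[paste0("intensity_", i)]]
      S[i, j] <- max(0, sum(xi * xj) / sum(xj^2))
    }
  }
  structure(S, condition_number = kappa(S), class = "spillover_matrix")
}

#' Re-estimate the DNA spillover column from a sample's DNA-only control
#'
#' DNA signal strength varies between samples, so the Ch07 column of the
#' spillover matrix is re-fit per sample from its DNA-dye-only control
#' store, leaving all other columns untouched.
#'
#' @param S A `spillover_matrix`.
#' @param dna_only_store `ifc_store` (or feature table) of the sample's
#'   DNA-only control.
#' @param feature_fn See [estimate_spillover()].
#' @return The updated `spillover_matrix`.
#' @export
update_dna_spillover <- function(S, dna_only_store,
                                 feature_fn = ifc_features) {
  ft <- if (is.data.frame(dna_only_store)) dna_only_store
  else feature_fn(dna_only_store)
  xj <- ft[["intensity_Ch07"]]
  if (sum(xj^2) == 0)
    stop("degenerate DNA-only control: no Ch07 signal", call. = FALSE)
  for (i in setdiff(ifc_fluor_channels(), "Ch07")) {
    xi <- ft[[paste0("intensity_", i)]]
    S[i, "Ch07"] <- max(0, sum(xi * xj) / sum(xj^2))
  }
  structure(S, condition_number = kappa(unclass(S)),
            class = "spillover_matrix")
}

#' @export
print.spillover_matrix <- function(x, ...) {
  cat("Spillover matrix (", nrow(x), "fluorescence channels ), condition",
      "number", signif(attr(x, "condition_number"), 4), "\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Apply compensation to a feature table
#'
#' Replaces each event's whole-cell fluorescence intensity vector `x` by
#' `solve(S, x)`, and likewise the membrane-ring intensity vector (from
#' which the CD45 membrane feature is taken). Negative compensated
#' intensities are retained. `raw_max_*` and `sat_count_*` columns are
#' untouched: saturation is a property of the uncompensated rasters.
#'
#' @param features An `ifc_features` table.
#' @param S A `spillover_matrix` (invertible).
#' @return The compensated feature table.
#' @export
compensate <- function(features, S) {
  fluor <- ifc_fluor_channels()
  Su <- unclass(S)[fluor, fluor]
  cn <- kappa(Su)
  if (!is.finite(cn) || cn > 1e8)
    stop("spillover matrix is not invertible (condition number ",
         format(cn), ")", call. = FALSE)
  cols <- paste0("intensity_", fluor)
  missing_col <- setdiff(cols, names(features))
  if (length(missing_col))
    stop("feature table lacks column(s): ",
         paste(missing_col, collapse = ", "), call. = FALSE)
  out <- features
  out[, cols] <- t(solve(Su, t(as.matrix(features[, cols]))))
  mcols <- paste0("membrane_", fluor)
  if (all(mcols %in% names(features))) {
    out[, mcols] <- t(solve(Su, t(as.matrix(features[, mcols]))))
    out$cd45_membrane_intensity <- out$membrane_Ch08
  }
  attr(out, "compensated") <- TRUE
  out
}
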