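#' Channel layout of the emulated imaging flow cytometer
#'
#' The emulated instrument captures, per event, a brightfield (BF) morphology
#' image, a side-scatter (SSC, darkfield) image and seven fluorescence images.
#' Channel identifiers follow the detection layout of the seven-colour
#' HSC/LSC panel: viability dye (Zombie Green) in Ch02, CLEC12A PE in Ch03,
#' CD14 PE-Texas Red in Ch04, DNA dye (Vybrant DyeCycle Violet, VDCV) in
#' Ch07, CD45 KrO in Ch08, CD38 SBV610 in Ch10 and CD34 AF647 in Ch11.
#' Brightfield is Ch01 and SSC is Ch06.
#'
#' `ifc_channels()` returns all nine channel ids;
#' `ifc_fluor_channels()` the seven fluorescence channels (the domain of the
#' spillover matrix); `ifc_image_channels()` the three channels used for
#' CNN image classification (BF, SSC, DNA).
#'
#' @return Character vector of channel identifiers.
#' @export
ifc_channels <- function() {
  c("Ch01", "Ch02", "Ch03", "Ch04", "Ch06", "Ch07", "Ch08", "Ch10", "Ch11")
}

#' @rdname ifc_channels
#' @export
ifc_fluor_channels <- function() {
  c("Ch02", "Ch03", "Ch04", "Ch07", "Ch08", "Ch10", "Ch11")
}

#' @rdname ifc_channels
#' @export
ifc_image_channels <- function() {
  c(BF = "Ch01", SSC = "Ch06", DNA = "Ch07")
}

#' Marker names of the fluorescence channels
#' @return Named character vector mapping channel id to marker/dye.
#' @export
ifc_channel_markers <- function() {
  c(Ch01 = "BF", Ch02 = "ZG", Ch03 = "CLEC12A", Ch04 = "CD14",
    Ch06 = "SSC", Ch07 = "VDCV", Ch08 = "CD45", Ch10 = "CD38",
    Ch11 = "CD34")
}

# Populations emitted by the generator.
ifc_populations <- function() {
  c("HSC", "LSC", "lymphocyte", "monocyte", "granulocyte", "progenitor",
    "dead", "debris")
}

#' The seven channel combinations used for CNN model development
#'
#' Combinations of brightfield (Ch01), side scatter (Ch06) and DNA (Ch07)
#' imagery on which the classifiers are trained.
#'
#' @return Named list; each element is a character vector of channel ids in
#'   fixed stacking order (Ch01, Ch06, Ch07 subset order).
#' @export
ifc_channel_combos <- function() {
  list(
    "BF"           = c("Ch01"),
    "SSC"          = c("Ch06"),
    "DNA"          = c("Ch07"),
    "SSC+DNA"      = c("Ch06", "Ch07"),
    "BF+SSC"       = c("Ch01", "Ch06"),
    "BF+DNA"       = c("Ch01", "Ch07"),
    "BF+SSC+DNA"   = c("Ch01", "Ch06", "Ch07")
  )
}
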