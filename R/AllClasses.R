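#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib kvclust, .registration = TRUE
NULL

#' ImageFrame: a calibrated single-channel intensity image
#'
#' The unit of analysis: one cell's basal-membrane plane recorded as a 2D
#' grid of non-negative intensities with an isotropic physical pixel size.
#'
#' @slot pixels numeric matrix of non-negative intensities (rows = image
#'   rows, i.e. y; columns = x).
#' @slot pixelSize physical pixel size in micrometres per pixel (isotropic).
#' @slot bitDepth integer, 8 or 16; intensities must fit the depth.
#' @slot id character identifier, used as `cell_id` in all tables.
#'
#' @section Coordinates:
#' Pixel coordinates are 1-based `(row, col)` indices; physical positions in
#' micrometres are measured from the top-left pixel centre, `x = (col - 1) *
#' pixelSize`, `y = (row - 1) * pixelSize`. The physical area of any set of
#' `n` pixels is `n * pixelSize^2` square micrometres.
#'
#' @export
setClass("ImageFrame",
  representation(pixels = "matrix", pixelSize = "numeric",
                 bitDepth = "integer", id = "character"),
  prototype(pixelSize = NA_real_, bitDepth = 16L, id = "frame"))

setValidity("ImageFrame", function(object) {
  p <- object@pixels
  if (!is.numeric(p) || length(dim(p)) != 2L)
    return("pixels must be a numeric matrix")
  if (length(object@pixelSize) != 1L || is.na(object@pixelSize) ||
      object@pixelSize <= 0)
    return("pixelSize must be a single positive number (um/pixel)")
  if (!object@bitDepth %in% c(8L, 16L))
    return("bitDepth must be 8 or 16")
  if (any(p < 0)) return("pixel intensities must be non-negative")
  if (max(p) > 2^object@bitDepth - 1)
    return(sprintf("pixel intensities exceed %d-bit range", object@bitDepth))
  TRUE
})

#' Construct an ImageFrame
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param pixelSize pixel size in micrometres per pixel.
#' @param bitDepth 8 or 16 (default 16).
#' @param id frame identifier.
#' @return An [ImageFrame-class] object.
#' @examples
#' f <- ImageFrame(matrix(0, 8, 8), pixelSize = 0.05, id = "demo")
#' pixelSize(f)
#' @export
ImageFrame <- function(pixels, pixelSize, bitDepth = 16L, id = "frame") {
  new("ImageFrame", pixels = pixels, pixelSize = as.numeric(pixelSize),
      bitDepth = as.integer(bitDepth), id = as.character(id))
}

#' CellRegion: the segmented footprint of one cell
#'
#' @slot mask logical matrix, TRUE inside the cell footprint.
#' @slot pixelSize micrometres per pixel, copied from the source frame.
#' @slot area cell area in square micrometres.
#' @slot ifs total integrated fluorescence signal inside the mask
#'   (background-uncorrected).
#' @slot background estimated per-pixel diffuse signal level inside the mask.
#' @export
setClass("CellRegion",
  representation(mask = "matrix", pixelSize = "numeric", area = "numeric",
                 ifs = "numeric", background = "numeric"))

setValidity("CellRegion", function(object) {
  if (!is.logical(object@mask)) return("mask must be a logical matrix")
  if (object@area <= 0) return("area must be positive")
  if (object@ifs < 0) return("ifs must be non-negative")
  if (object@background < 0) return("background must be non-negative")
  TRUE
})

#' ClusterSet: segmented clusters of one cell
#'
#' Holds one row per cluster plus the per-cluster pixel memberships.
#' Cluster pixel sets within one cell are mutually disjoint, each cluster is
#' 8-connected and contains its seed spot, and `ifsc` never exceeds the raw
#' integrated signal of the cluster's pixels.
#'
#' @slot clusters data.frame with columns `cell_id`, `cluster_id`,
#'   `seed_row`, `seed_col`, `x_um`, `y_um`, `n_pixels`, `area_um2`, `raw`
#'   (uncorrected integrated signal), `ifsc` (background-corrected, clipped
#'   at 0), `intensity` (`ifsc / area_um2`), `edge` (touches image border).
#' @slot pixels list of integer vectors; linear indices (column-major, into
#'   the source frame) of each cluster's pixels.
#' @slot pixelSize micrometres per pixel.
#' @export
setClass("ClusterSet",
  representation(clusters = "data.frame", pixels = "list",
                 pixelSize = "numeric"))

setValidity("ClusterSet", function(object) {
  if (nrow(object@clusters) != length(object@pixels))
    return("one pixel set per cluster row required")
  if (nrow(object@clusters) > 0L) {
    idx <- unlist(object@pixels)
    if (anyDuplicated(idx)) return("cluster pixel sets must be disjoint")
    if (any(object@clusters$ifsc > object@clusters$raw + 1e-9))
      return("ifsc cannot exceed the raw integrated cluster signal")
  }
  TRUE
})

#' GroundTruth: the known scene behind a synthetic image
#'
#' @slot cell list of scene-level truth: `area_um2` (rasterised mask area),
#'   `background` (mean diffuse photon level per pixel), `ifs` (total
#'   expected in-mask photons, pre-blur/pre-noise), `gain` (counts per
#'   photon applied before noise), `count_factor`/`intensity_factor`
#'   (cell-level log-normal dispersion factors).
#' @slot clusters data.frame, one row per planted cluster: `cluster_id`,
#'   `row`, `col`, `x_um`, `y_um`, `sigma_um` (intrinsic Gaussian width),
#'   `area_um2` (operational half-maximum footprint area), `signal`
#'   (operational background-corrected in-footprint signal, photons),
#'   `intensity` (`signal / area_um2`), `flux` (total rendered above-
#'   background photons of the cluster).
#' @slot mask logical matrix, the true cell footprint.
#' @slot seed integer seed the scene was drawn from.
#' @export
setClass("GroundTruth",
  representation(cell = "list", clusters = "data.frame", mask = "matrix",
                 seed = "integer"))

#' StatsResult: a named statistical test or fit outcome
#'
#' @slot test character label of the procedure.
#' @slot statistic test statistic value (NA for pure fits).
#' @slot df degrees of freedom (length 1 or 2).
#' @slot p.value p-value in `[0, 1]` (NA for pure fits).
#' @slot estimate named numeric vector of estimates (group coefficients, or
#'   `slope` / `intercept` / `r.squared` for regressions).
#' @slot groups character vector of group labels compared.
#' @export
setClass("StatsResult",
  representation(test = "character", statistic = "numeric", df = "numeric",
                 p.value = "numeric", estimate = "numeric",
                 groups = "character"),
  prototype(statistic = NA_real_, df = NA_real_, p.value = NA_real_,
            estimate = numeric(0), groups = character(0)))

setValidity("StatsResult", function(object) {
  p <- object@p.value
  if (length(p) == 1L && !is.na(p) && (p < 0 || p > 1))
    return("p.value must lie in [0, 1]")
  r2 <- object@estimate["r.squared"]
  if (!is.na(r2) && (r2 < -1e-12 || r2 > 1 + 1e-12))
    return("r.squared must lie in [0, 1]")
  TRUE
})
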