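# Accessors and show methods for the core classes.

#' @rdname ImageFrame-class
#' @export
setMethod("pixels", "ImageFrame", function(x) x@pixels)

#' @rdname ImageFrame-class
#' @export
setMethod("pixelSize", "ImageFrame", function(x) x@pixelSize)

#' @rdname ImageFrame-class
#' @export
setMethod("frameId", "ImageFrame", function(x) x@id)

#' @rdname ImageFrame-class
#' @export
setMethod("dim", "ImageFrame", function(x) dim(x@pixels))

setMethod("show", "ImageFrame", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ImageFrame '%s': %d x %d px, %.4g um/px (%.1f x %.1f um), %d-bit\n",
              object@id, d[1], d[2], object@pixelSize,
              d[1] * object@pixelSize, d[2] * object@pixelSize,
              object@bitDepth))
  cat(sprintf("  intensity range [%.6g, %.6g]\n",
              min(object@pixels), max(object@pixels)))
})

#' @rdname CellRegion-class
#' @export
setMethod("cellMask", "CellRegion", function(x) x@mask)

#' @rdname CellRegion-class
#' @export
setMethod("cellArea", "CellRegion", function(x) x@area)

#' @rdname CellRegion-class
#' @export
setMethod("cellIfs", "CellRegion", function(x) x@ifs)

#' @rdname CellRegion-class
#' @export
setMethod("background", "CellRegion", function(x) x@background)

setMethod("show", "CellRegion", function(object) {
  cat(sprintf("CellRegion: %.1f um2 (%d px), IFS = %.4g, background = %.4g per px\n",
              object@area, sum(object@mask), object@ifs, object@background))
})

#' @rdname ClusterSet-class
#' @export
setMethod("clusterTable", "ClusterSet", function(x) x@clusters)

#' @rdname ClusterSet-class
#' @export
setMethod("length", "ClusterSet", function(x) nrow(x@clusters))

#' @rdname ClusterSet-class
#' @param row.names,optional,... passed on for S3 compatibility (unused).
#' @export
as.data.frame.ClusterSet <- function(x, row.names = NULL, optional = FALSE, ...) {
  x@clusters
}

setMethod("show", "ClusterSet", function(object) {
  n <- nrow(object@clusters)
  cat(sprintf("ClusterSet: %d clusters\n", n))
  if (n > 0L)
    cat(sprintf("  total ifsc = %.4g, mean intensity = %.4g per um2\n",
                sum(object@clusters$ifsc), mean(object@clusters$intensity)))
})

#' @rdname GroundTruth-class
#' @export
setMethod("truthTable", "GroundTruth", function(x) x@clusters)

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth (seed %d): cell %.1f um2, %d clusters, gain %.3f\n",
              object@seed, object@cell$area_um2, nrow(object@clusters),
              object@cell$gain))
})

setMethod("show", "StatsResult", function(object) {
  cat(sprintf("StatsResult: %s\n", object@test))
  if (!is.na(object@statistic))
    cat(sprintf("  statistic = %.6g, df = %s, p = %.4g\n", object@statistic,
                paste(format(object@df), collapse = ", "), object@p.value))
  if (length(object@estimate))
    cat("  estimates:", paste(sprintf("%s = %.6g", names(object@estimate),
                                      object@estimate), collapse = ", "), "\n")
})
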