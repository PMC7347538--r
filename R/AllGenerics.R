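#' @rdname ImageFrame-class
#' @param object,x an object.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname ImageFrame-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname ImageFrame-class
#' @export
setGeneric("frameId", function(x) standardGeneric("frameId"))

#' @rdname CellRegion-class
#' @param x an object.
#' @export
setGeneric("cellMask", function(x) standardGeneric("cellMask"))

#' @rdname CellRegion-class
#' @export
setGeneric("cellArea", function(x) standardGeneric("cellArea"))

#' @rdname CellRegion-class
#' @export
setGeneric("cellIfs", function(x) standardGeneric("cellIfs"))

#' @rdname CellRegion-class
#' @export
setGeneric("background", function(x) standardGeneric("background"))

#' @rdname ClusterSet-class
#' @param x an object.
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))

#' @rdname GroundTruth-class
#' @param x an object.
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))
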