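#' Read a calibrated single-channel TIFF
#'
#' Reads a grayscale 2D TIFF into an [ImageFrame-class]. The physical pixel
#' size is resolved in this order: TIFF resolution tags (X/YResolution with
#' a unit of inch or centimetre), a JSON sidecar written by [writeFrame()]
#' (`<path>.json` with a `pixel_size` field), then `pixel_size_override`.
#' A frame is never silently assumed to be calibrated: if none of the three
#' sources is available the read fails.
#'
#' @param path TIFF file path.
#' @param pixel_size_override pixel size in um/px used when the file
#'   carries no calibration.
#' @param id frame identifier; defaults to the file name.
#' @return An [ImageFrame-class].
#' @export
readFrame <- function(path, pixel_size_override = NULL, id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  if (length(dim(img)) == 3L && dim(img)[3] > 1L)
    stop("single-channel grayscale required: '", basename(path),
         "' has ", dim(img)[3], " channels")
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  info <- attributes(img)
  bits <- info$bits.per.sample
  if (is.null(bits)) bits <- if (max(img) > 255) 16L else 8L

  pxsz <- pixelSizeFromTags(info)
  if (is.na(pxsz)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar)
      if (!is.null(meta$pixel_size)) pxsz <- as.numeric(meta$pixel_size)
    }
  }
  if (is.na(pxsz)) {
    if (is.null(pixel_size_override))
      stop("'", basename(path), "' carries no pixel-size calibration ",
           "(no TIFF resolution tags, no sidecar); pass pixel_size_override")
    pxsz <- as.numeric(pixel_size_override)
  }
  storage.mode(img) <- "double"
  attributes(img) <- list(dim = dim(img))
  ImageFrame(img, pixelSize = pxsz, bitDepth = as.integer(bits),
             id = if (is.null(id)) sub("\\.tiff?$", "", basename(path)) else id)
}

# um/px from TIFF resolution tags; NA when absent or unitless.
pixelSizeFromTags <- function(info) {
  xr <- info$x.resolution
  unit <- info$res.unit
  if (is.null(unit)) unit <- info$resolution.unit
  if (is.null(xr) || is.null(unit) || !is.finite(xr) || xr <= 0)
    return(NA_real_)
  umPerUnit <- switch(as.character(unit), inch = 25400, cm = 10000,
                      centimeter = 10000, NA_real_)
  if (is.na(umPerUnit)) return(NA_real_)
  umPerUnit / xr
}

#' Write an ImageFrame as a 16- or 8-bit grayscale TIFF
#'
#' Pixel values are written verbatim (rounded to integers). Because
#' baseline TIFF writing here cannot embed resolution tags, the physical
#' pixel size is persisted in a JSON sidecar `<path>.json`, which
#' [readFrame()] consults; round trips are bit-identical in both pixels
#' and calibration.
#'
#' @param frame an [ImageFrame-class].
#' @param path output TIFF path.
#' @return invisibly, `path`.
#' @export
writeFrame <- function(frame, path) {
  stopifnot(is(frame, "ImageFrame"))
  dynmax <- 2^frame@bitDepth - 1
  tiff::writeTIFF(round(frame@pixels) / dynmax, path,
                  bits.per.sample = frame@bitDepth,
                  compression = "none", reduce = FALSE)
  jsonlite::write_json(list(pixel_size = frame@pixelSize,
                            bit_depth = frame@bitDepth, id = frame@id),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write and read cluster tables
#'
#' CSV with the fixed header `cell_id, cluster_id, area_um2, ifsc,
#' intensity, x, y` and deterministic row order (`cell_id`, then
#' `cluster_id`). Coordinates are micrometres from the top-left pixel
#' centre. Comma-separated, '.' decimal, UTF-8.
#'
#' @param records data.frame carrying at least the header columns above
#'   (a [ClusterSet-class] table from [segmentClusters()] works as is), or
#'   an empty data.frame for a header-only file.
#' @param path CSV path.
#' @return `writeClusterTable` invisibly returns `path`; `readClusterTable`
#'   returns the table with the same columns and ordering.
#' @export
writeClusterTable <- function(records, path) {
  cols <- c("cell_id", "cluster_id", "area_um2", "ifsc", "intensity", "x", "y")
  if (is(records, "ClusterSet")) records <- clusterTable(records)
  if (nrow(records) == 0L) {
    out <- data.frame(cell_id = character(0), cluster_id = integer(0),
                      area_um2 = numeric(0), ifsc = numeric(0),
                      intensity = numeric(0), x = numeric(0), y = numeric(0))
  } else {
    if (!"x" %in% names(records) && "x_um" %in% names(records)) {
      records$x <- records$x_um
      records$y <- records$y_um
    }
    miss <- setdiff(cols, names(records))
    if (length(miss))
      stop("cluster table is missing columns: ", paste(miss, collapse = ", "))
    out <- records[order(records$cell_id, records$cluster_id), cols]
  }
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeClusterTable
#' @export
readClusterTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
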