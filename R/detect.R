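#' Robust noise-based detection tolerance
#'
#' Estimates the image noise level as a median-absolute-deviation-style
#' scale of horizontal first differences (`1.4826 * median(|dx|) / sqrt(2)`)
#' over pixel pairs inside the mask, and returns `k` times it. First
#' differences cancel smooth structure (the diffuse signal and cluster
#' bodies), so the estimate reflects pixel noise rather than biology.
#'
#' @param frame an [ImageFrame-class].
#' @param cell_mask optional logical matrix; restrict to pairs whose both
#'   pixels are inside.
#' @param k multiplier (default 5).
#' @return single numeric tolerance in intensity units.
#' @export
autoNoiseTolerance <- function(frame, cell_mask = NULL, k = 5) {
  p <- pixels(frame)
  d <- p[, -1, drop = FALSE] - p[, -ncol(p), drop = FALSE]
  if (!is.null(cell_mask)) {
    keep <- cell_mask[, -1, drop = FALSE] & cell_mask[, -ncol(p), drop = FALSE]
    d <- d[keep]
  }
  if (!length(d)) stop("no pixel pairs available for noise estimation")
  k * 1.4826 * stats::median(abs(d)) / sqrt(2)
}

#' Detect cluster candidate spots by box scanning
#'
#' Scans the image with a square box of odd side `box_size` at stride 1
#' (fully inside the frame). The box's maximum pixel is accepted as a spot
#' when it is the (first, in row-then-column order, for equal-valued
#' plateaus) maximum of the box centred on it and exceeds the mean of the
#' four box-corner pixels by more than `noise_tolerance`. Accepted maxima
#' within `box_size/2` (Chebyshev distance) of a stronger accepted maximum
#' are suppressed, since overlapping box placements re-report one peak.
#'
#' @param frame an [ImageFrame-class].
#' @param box_size odd integer box side in pixels, >= 3.
#' @param noise_tolerance minimum peak-over-corner-mean margin; use
#'   [autoNoiseTolerance()] for a data-driven value.
#' @param cell_mask optional logical matrix; spots outside are discarded.
#' @return data.frame sorted by decreasing peak (ties: row, then column)
#'   with columns `row`, `col` (1-based pixel coordinates), `x_um`, `y_um`,
#'   `peak`, `corner_mean`, `margin`.
#' @examples
#' img <- matrix(0, 21, 21); img[11, 11] <- 100
#' f <- ImageFrame(img, pixelSize = 0.05)
#' detectSpots(f, box_size = 5, noise_tolerance = 10)
#' @export
detectSpots <- function(frame, box_size = 5L, noise_tolerance = 0,
                        cell_mask = NULL) {
  stopifnot(is(frame, "ImageFrame"))
  box_size <- as.integer(box_size)
  if (box_size %% 2L == 0L) stop("box_size must be odd")
  if (box_size < 3L) stop("box_size must be >= 3")
  d <- dim(frame)
  if (box_size > min(d)) stop("box_size exceeds the image dimensions")
  if (noise_tolerance < 0) stop("noise_tolerance must be >= 0")
  half <- (box_size - 1L) %/% 2L
  cand <- cpp_box_scan(pixels(frame), half, noise_tolerance)
  cand <- as.data.frame(cand)
  if (!is.null(cell_mask) && nrow(cand)) {
    ## the peak and all four corner samples must lie inside the cell:
    ## corners outside it sample darkness, not background, and would pass
    ## the margin gate spuriously along the cell boundary
    ok <- cell_mask[cbind(cand$row, cand$col)] &
      cell_mask[cbind(cand$row - half, cand$col - half)] &
      cell_mask[cbind(cand$row - half, cand$col + half)] &
      cell_mask[cbind(cand$row + half, cand$col - half)] &
      cell_mask[cbind(cand$row + half, cand$col + half)]
    cand <- cand[ok, , drop = FALSE]
  }

  ## suppression: greedy from the strongest peak
  if (nrow(cand) > 1L) {
    cand <- cand[order(-cand$peak, cand$row, cand$col), , drop = FALSE]
    keep <- logical(nrow(cand))
    supr <- floor(box_size / 2)
    for (i in seq_len(nrow(cand))) {
      j <- which(keep)
      keep[i] <- !length(j) ||
        all(pmax(abs(cand$row[i] - cand$row[j]),
                 abs(cand$col[i] - cand$col[j])) > supr)
    }
    cand <- cand[keep, , drop = FALSE]
  } else if (nrow(cand) == 1L) {
    cand <- cand[order(-cand$peak, cand$row, cand$col), , drop = FALSE]
  }
  cand$margin <- cand$peak - cand$corner_mean
  cand$x_um <- (cand$col - 1) * pixelSize(frame)
  cand$y_um <- (cand$row - 1) * pixelSize(frame)
  rownames(cand) <- NULL
  cand[, c("row", "col", "x_um", "y_um", "peak", "corner_mean", "margin")]
}
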