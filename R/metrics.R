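# The four per-cell clustering attributes and their per-variant aggregates.

#' Per-cell clustering attributes
#'
#' Computes the four clustering attributes of one cell: normalized
#' expression level (IFS per unit cell area), clusters per unit area,
#' fraction of the cell's signal found in clusters (sum of
#' background-corrected cluster signals over the cell's total IFS), and
#' the per-cluster signal intensities (IFSc per cluster area) that proxy
#' ion channel density within clusters.
#'
#' @param cell a [CellRegion-class].
#' @param clusters a [ClusterSet-class] belonging to the cell.
#' @return one-row data.frame with `cell_id`, `cell_area_um2`, `ifs`,
#'   `background`, `normalized_expression`, `n_clusters`,
#'   `clusters_per_area`, `fraction_in_clusters`, and a list column
#'   `intensities` holding the per-cluster intensity vector.
#' @examples
#' cellr <- new("CellRegion", mask = matrix(TRUE, 10, 10), pixelSize = 0.1,
#'              area = 1, ifs = 1e6, background = 0)
#' cellMetrics(cellr, new("ClusterSet", clusters = kvclust:::emptyClusterFrame(),
#'                        pixels = list(), pixelSize = 0.1))
#' @export
cellMetrics <- function(cell, clusters) {
  stopifnot(is(cell, "CellRegion"), is(clusters, "ClusterSet"))
  cl <- clusterTable(clusters)
  n <- nrow(cl)
  if (cell@ifs == 0 && n > 0L)
    stop("inconsistent cell: zero IFS but ", n, " clusters present")
  sumIfsc <- if (n) sum(cl$ifsc) else 0
  if (sumIfsc > cell@ifs * (1 + 1e-9))
    stop("conservation violated: summed cluster IFSc exceeds the cell IFS")
  frac <- if (cell@ifs > 0) sumIfsc / cell@ifs else 0
  out <- data.frame(
    cell_id = if (n) cl$cell_id[1] else NA_character_,
    cell_area_um2 = cell@area, ifs = cell@ifs, background = cell@background,
    normalized_expression = cell@ifs / cell@area,
    n_clusters = n, clusters_per_area = n / cell@area,
    fraction_in_clusters = frac, stringsAsFactors = FALSE)
  out$intensities <- list(if (n) cl$intensity else numeric(0))
  out
}

#' Summarize a variant cohort
#'
#' Aggregates per-cell metrics into the per-variant summary: mean and
#' standard error of each cell-level attribute, and the mean and SE of the
#' cluster signal intensity over the pooled cluster population (not the
#' mean of cell means: the sampling unit for density statistics is the
#' cluster).
#'
#' @param cells data.frame of rows from [cellMetrics()].
#' @param preset one-row preset supplying `name`, `chain_length`,
#'   `reversed` and `binding_energy` (optional; NAs otherwise).
#' @return one-row data.frame with n's, `mean`/`se` pairs for the four
#'   attributes, and the preset annotation columns.
#' @export
summarizeVariant <- function(cells, preset = NULL) {
  if (is.null(cells) || nrow(cells) == 0L) stop("no cells to summarize")
  se <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
  pooled <- unlist(cells$intensities)
  out <- data.frame(
    name = if (!is.null(preset)) preset$name else NA_character_,
    chain_length = if (!is.null(preset)) preset$chain_length else NA_integer_,
    reversed = if (!is.null(preset) && !is.null(preset$reversed))
      preset$reversed else NA,
    n_cells = nrow(cells),
    n_clusters = sum(cells$n_clusters),
    expression_mean = mean(cells$normalized_expression),
    expression_se = se(cells$normalized_expression),
    clusters_per_area_mean = mean(cells$clusters_per_area),
    clusters_per_area_se = se(cells$clusters_per_area),
    fraction_mean = mean(cells$fraction_in_clusters),
    fraction_se = se(cells$fraction_in_clusters),
    intensity_mean = if (length(pooled)) mean(pooled) else NA_real_,
    intensity_se = if (length(pooled) > 1L)
      stats::sd(pooled) / sqrt(length(pooled)) else NA_real_,
    binding_energy = if (!is.null(preset) && !is.null(preset$binding_energy))
      preset$binding_energy else NA_real_,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Cluster-density histogram
#'
#' Histogram of cluster signal intensities in half-open bins
#' `[k*w, (k+1)*w)` starting at zero, the binning in which cluster
#' ion-channel-density distributions are conventionally displayed
#' (default step 2e5 IFSc per square micrometre).
#'
#' @param intensities numeric vector of non-negative cluster intensities.
#' @param bin_width positive bin width (default `2e5`).
#' @return list of class `densityHistogram` with `breaks` (bin edges,
#'   length `nbins + 1`), `counts`, and `bin_width`. Counts always sum to
#'   `length(intensities)`.
#' @examples
#' densityHistogram(c(1e5, 3e5, 3.5e5))
#' @export
densityHistogram <- function(intensities, bin_width = 2e5) {
  if (bin_width <= 0) stop("bin_width must be positive")
  if (any(intensities < 0)) stop("negative intensities are not allowed")
  if (!length(intensities)) {
    out <- list(breaks = c(0, bin_width), counts = 0L, bin_width = bin_width)
    class(out) <- "densityHistogram"
    return(out)
  }
  nb <- max(1L, floor(max(intensities) / bin_width) + 1L)
  idx <- pmin(floor(intensities / bin_width) + 1L, nb)  # guard fp edge at max
  counts <- tabulate(idx, nb)
  out <- list(breaks = bin_width * (0:nb), counts = counts,
              bin_width = bin_width)
  class(out) <- "densityHistogram"
  out
}

#' @export
print.densityHistogram <- function(x, ...) {
  cat(sprintf("densityHistogram: %d bins of width %.4g, %d values\n",
              length(x$counts), x$bin_width, sum(x$counts)))
  invisible(x)
}
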