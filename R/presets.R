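#' Packaged channel-variant presets
#'
#' Loads the packaged table of ten Shaker Kv channel C-terminal chain-length
#' variants with their measured clustering attributes and PSD-95 binding
#' energies. Values are stored in the CSV on the scales on which they are
#' conventionally printed (expression and cluster intensity in units of
#' 1e5 per square micrometre, clusters per area in units of 1e-2 per square
#' micrometre, fraction in clusters in units of 1e-3); the loader converts
#' them to raw per-micrometre units, which every other function in the
#' package uses.
#'
#' @param file path to a preset CSV. Defaults to the packaged table.
#' @return data.frame with one row per variant and columns `name`,
#'   `chain_length` (amino acids), `reversed` (logical; reversed-sequence
#'   control), `expression_level` (IFS/um2), `clusters_per_area` (1/um2),
#'   `fraction_in_clusters` (dimensionless), `cluster_intensity`
#'   (IFSc/um2), `binding_energy` (kcal/mol, negative; NA where not
#'   determined), the matching `*_se` columns, and `cluster_area_um2`, the
#'   mean operational cluster area implied jointly by the four attributes
#'   (see [generateCell()]).
#' @examples
#' p <- kvPresets()
#' p[p$chain_length == 61, c("name", "cluster_intensity")]
#' @export
kvPresets <- function(file = system.file("extdata", "shaker_presets.csv",
                                         package = "kvclust")) {
  raw <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("name", "chain_length", "reversed", "expr_1e5", "expr_se_1e5",
            "cpa_1e2", "cpa_se_1e2", "frac_1e3", "frac_se_1e3",
            "intens_1e5", "intens_se_1e5", "dg_kcal", "dg_se_kcal")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("preset file is missing columns: ", paste(miss, collapse = ", "))
  p <- data.frame(
    name = raw$name,
    chain_length = as.integer(raw$chain_length),
    reversed = as.logical(raw$reversed),
    expression_level = raw$expr_1e5 * 1e5,
    expression_se = raw$expr_se_1e5 * 1e5,
    clusters_per_area = raw$cpa_1e2 * 1e-2,
    clusters_per_area_se = raw$cpa_se_1e2 * 1e-2,
    fraction_in_clusters = raw$frac_1e3 * 1e-3,
    fraction_in_clusters_se = raw$frac_se_1e3 * 1e-3,
    cluster_intensity = raw$intens_1e5 * 1e5,
    cluster_intensity_se = raw$intens_se_1e5 * 1e5,
    binding_energy = raw$dg_kcal,
    binding_energy_se = raw$dg_se_kcal,
    stringsAsFactors = FALSE)
  p$cluster_area_um2 <- impliedClusterArea(p)
  validatePresets(p)
  p
}

# Mean operational cluster area implied by the four attributes: the summed
# in-cluster signal of a cell is both fraction * IFS and
# n_clusters * intensity * mean_area, so
#   mean_area = fraction * expression / (clusters_per_area * intensity).
impliedClusterArea <- function(p) {
  a <- p$fraction_in_clusters * p$expression_level /
    (p$clusters_per_area * p$cluster_intensity)
  a[!is.finite(a)] <- NA_real_
  a
}

validatePresets <- function(p) {
  stopifnot(is.data.frame(p), nrow(p) >= 1L)
  if (any(p$fraction_in_clusters < 0 | p$fraction_in_clusters > 1))
    stop("fraction_in_clusters must lie in [0, 1] after scale conversion")
  if (any(p$expression_level < 0) || any(p$clusters_per_area < 0) ||
      any(p$cluster_intensity < 0))
    stop("expression, cluster density and intensity must be non-negative")
  bad <- !is.na(p$binding_energy) & p$binding_energy >= 0
  if (any(bad))
    stop("binding_energy must be negative (kcal/mol) where present")
  invisible(p)
}

# Coerce a one-row preset data.frame (or named list) to the internal form.
asPreset <- function(preset) {
  if (is.data.frame(preset)) {
    stopifnot(nrow(preset) == 1L)
    preset <- as.list(preset)
  }
  need <- c("name", "expression_level", "clusters_per_area",
            "fraction_in_clusters", "cluster_intensity")
  miss <- setdiff(need, names(preset))
  if (length(miss))
    stop("preset is missing fields: ", paste(miss, collapse = ", "))
  if (preset$fraction_in_clusters < 0 || preset$fraction_in_clusters > 1)
    stop("preset fraction_in_clusters outside [0, 1]")
  if (is.null(preset$cluster_area_um2) || !is.finite(preset$cluster_area_um2)) {
    a <- preset$fraction_in_clusters * preset$expression_level /
      (preset$clusters_per_area * preset$cluster_intensity)
    preset$cluster_area_um2 <- if (is.finite(a)) a else NA_real_
  }
  preset
}
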