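#' Default parameters of the synthetic scene generator
#'
#' Returns the generator's tunable parameters with their defaults. All are
#' overridable through the `geometry`, `noise` and `shape` arguments of
#' [generateCell()] or through the matching config keys of [runPipeline()].
#'
#' @return named list with entries `geometry` (`pixel_size` um/px Nyquist
#'   for ~150 nm lateral resolution; `cell_area` um2 range of the cell
#'   footprint; `pad_um` empty border around the cell), `noise`
#'   (`read_noise_frac` Gaussian read noise SD as a fraction of the 16-bit
#'   dynamic range; `gain_target` fraction of the dynamic range the
#'   brightest expected pixel is scaled to), and `shape` (`psf_fwhm_um`
#'   lateral resolution as PSF full width at half maximum; `area_cv`
#'   log-normal CV of per-cluster footprint area; `intensity_shape` gamma
#'   shape of per-cluster intensity; `cell_cv` log-normal CV of the
#'   cell-level count and intensity factors; `gradient` relative amplitude
#'   of the linear diffuse-illumination tilt; `boundary_rough` amplitude of
#'   the low-order Fourier perturbation of the cell outline; `min_sigma_um`
#'   smallest intrinsic cluster width; `sep_factor` multiple of summed
#'   half-maximum radii enforced between cluster centres; `place_attempts`
#'   placement attempts per cluster before giving up).
#' @export
synthDefaults <- function() {
  list(
    geometry = list(pixel_size = 0.05, cell_area = c(500, 1500), pad_um = 0.8),
    noise = list(read_noise_frac = 0.002, gain_target = 0.8),
    shape = list(psf_fwhm_um = 0.15, area_cv = 0.2, intensity_shape = 8,
                 cell_cv = 0.2, gradient = 0.02, boundary_rough = 0.10,
                 min_sigma_um = 0.03, sep_factor = 1.1, place_attempts = 200))
}

mergeParams <- function(defaults, user) {
  if (is.null(user)) return(defaults)
  utils::modifyList(defaults, user)
}

#' Generate one synthetic cell image with ground truth
#'
#' Draws a single cell scene that emulates the basal-membrane plane of a
#' fixed cell expressing a clustered membrane channel: an irregular smooth
#' cell footprint carrying a diffuse signal with a mild illumination tilt,
#' plus bright, approximately Gaussian clusters. The scene is blurred with
#' a Gaussian point-spread function of the stated resolution and corrupted
#' by Poisson shot noise and Gaussian read noise.
#'
#' @section Calibration:
#' Cluster brightness is calibrated in the *operational* convention in
#' which clustering attributes are measured: a cluster's "signal" is its
#' background-corrected flux within the half-maximum footprint of the
#' blurred profile and its "intensity" is that signal divided by the
#' footprint area. For a Gaussian cluster of intrinsic width `sigma`
#' blurred to `sigma' = sqrt(sigma^2 + sigma_psf^2)`, the footprint area is
#' `2*pi*log(2)*sigma'^2` and holds half the total flux, so the peak
#' amplitude that realises intensity I is `2*log(2)*I*sigma'^2/sigma^2`.
#' The mean footprint area per variant is taken from the preset's
#' `cluster_area_um2`, the value jointly implied by the four measured
#' attributes (see [kvPresets()]); the diffuse level is then set so the
#' in-cluster signal fraction and, in expectation, the normalized
#' expression level both match the preset.
#'
#' @param preset one-row data.frame or named list; see [kvPresets()].
#' @param geometry,noise,shape named lists overriding [synthDefaults()].
#' @param seed integer seed; the same seed reproduces the scene bit for bit.
#' @return list with elements `frame` ([ImageFrame-class]) and `truth`
#'   ([GroundTruth-class]).
#' @examples
#' p <- kvPresets()
#' cell <- generateCell(p[p$chain_length == 9, ],
#'                      geometry = list(cell_area = c(150, 200)), seed = 1)
#' cell$truth
#' @export
generateCell <- function(preset, geometry = NULL, noise = NULL, shape = NULL,
                         seed = 1L) {
  preset <- asPreset(preset)
  geometry <- mergeParams(synthDefaults()$geometry, geometry)
  noise <- mergeParams(synthDefaults()$noise, noise)
  shape <- mergeParams(synthDefaults()$shape, shape)
  px <- geometry$pixel_size
  stopifnot(px > 0)
  dynmax <- 2^16 - 1

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  ## cell outline: low-order Fourier perturbation of a circle
  areaTarget <- stats::runif(1, geometry$cell_area[1], geometry$cell_area[2])
  kk <- 2:4
  amp <- stats::runif(3, 0, shape$boundary_rough / (kk - 1))
  phi <- stats::runif(3, 0, 2 * pi)
  r0 <- sqrt(areaTarget / (pi * (1 + sum(amp^2) / 2)))
  radius <- function(theta) {
    r <- rep(r0, length(theta))
    for (h in seq_along(kk))
      r <- r + r0 * amp[h] * cos(kk[h] * theta + phi[h])
    r
  }
  maxr <- r0 * (1 + sum(amp))
  half <- ceiling((maxr + geometry$pad_um) / px)
  n <- 2L * half + 1L
  ctr <- half + 1L
  dx <- (col(matrix(0, n, n)) - ctr) * px
  dy <- (row(matrix(0, n, n)) - ctr) * px
  rr <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)
  mask <- rr <= radius(th)
  npxMask <- sum(mask)
  areaMask <- npxMask * px^2

  ## cell-level dispersion (independent factors for count and intensity)
  s <- sqrt(log(1 + shape$cell_cv^2))
  fCount <- stats::rlnorm(1, -s^2 / 2, s)
  fInt <- stats::rlnorm(1, -s^2 / 2, s)

  sigP <- shape$psf_fwhm_um / (2 * sqrt(2 * log(2)))
  nClusters <- if (preset$clusters_per_area > 0)
    stats::rpois(1, preset$clusters_per_area * areaMask * fCount) else 0L
  if (nClusters > 0 && preset$fraction_in_clusters <= 0)
    stop("preset requests clusters but a zero fraction of signal in clusters")

  clusters <- data.frame()
  blobs <- matrix(0, n, n)
  fluxes <- numeric(0)
  if (nClusters > 0) {
    abar <- preset$cluster_area_um2
    if (!is.finite(abar) || abar <= 0)
      stop("preset does not determine a positive mean cluster area")
    sa <- sqrt(log(1 + shape$area_cv^2))
    aOp <- stats::rlnorm(nClusters, log(abar) - sa^2 / 2, sa)
    sigB2 <- aOp / (2 * pi * log(2))          # blurred width^2
    sigI <- sqrt(pmax(sigB2 - sigP^2, shape$min_sigma_um^2))
    sigB2 <- sigI^2 + sigP^2                  # after flooring, re-derive
    aOp <- 2 * pi * log(2) * sigB2
    kapa <- shape$intensity_shape
    intens <- stats::rgamma(nClusters, shape = kapa,
                            rate = kapa / (preset$cluster_intensity * fInt))
    sig <- intens * aOp                        # operational signal (photons)

    ## placement: inside the mask with a full-margin, minimum separation
    rHalf <- sqrt(sigB2) * sqrt(2 * log(2))
    marg <- 2 * sigI + 2 * sigP
    cx <- numeric(nClusters); cy <- numeric(nClusters)
    attempts <- 0L
    budget <- shape$place_attempts * nClusters
    for (i in seq_len(nClusters)) {
      placed <- FALSE
      while (!placed) {
        attempts <- attempts + 1L
        if (attempts > budget)
          stop(sprintf(paste0("could not place %d clusters of radius ~%.2f um ",
                              "in %.0f um2 after %d attempts: requested cluster ",
                              "density is too high"),
                       nClusters, mean(rHalf), areaMask, budget))
        x <- stats::runif(1, -maxr, maxr)
        y <- stats::runif(1, -maxr, maxr)
        if (sqrt(x^2 + y^2) > radius(atan2(y, x)) - marg[i]) next
        if (i > 1L) {
          j <- seq_len(i - 1L)
          if (any((x - cx[j])^2 + (y - cy[j])^2 <
                  (shape$sep_factor * (rHalf[i] + rHalf[j]))^2)) next
        }
        cx[i] <- x; cy[i] <- y; placed <- TRUE
      }
    }

    ## render truncated Gaussian blobs (pre-blur, photon units)
    fluxes <- numeric(nClusters)
    a0px <- 2 * log(2) * intens * sigB2 / sigI^2 * px^2  # peak photons/px
    for (i in seq_len(nClusters)) {
      rad <- 2 * sigI[i]
      i0 <- max(1L, floor(ctr + cy[i] / px - rad / px))
      i1 <- min(n, ceiling(ctr + cy[i] / px + rad / px))
      j0 <- max(1L, floor(ctr + cx[i] / px - rad / px))
      j1 <- min(n, ceiling(ctr + cx[i] / px + rad / px))
      pdy <- ((i0:i1) - ctr) * px - cy[i]
      pdx <- ((j0:j1) - ctr) * px - cx[i]
      d2 <- outer(pdy^2, pdx^2, "+")
      patch <- a0px[i] * exp(-d2 / (2 * sigI[i]^2))
      patch[d2 > rad^2] <- 0
      fluxes[i] <- sum(patch)
      blobs[i0:i1, j0:j1] <- blobs[i0:i1, j0:j1] + patch
    }
    clusters <- data.frame(
      cluster_id = seq_len(nClusters),
      row = ctr + cy / px, col = ctr + cx / px,
      x_um = (ctr - 1) * px + cx, y_um = (ctr - 1) * px + cy,
      sigma_um = sigI, area_um2 = aOp, signal = sig, intensity = intens,
      flux = fluxes)
  }

  ## diffuse level set by the in-cluster signal fraction (and thereby, in
  ## expectation, by the normalized expression level)
  if (nClusters > 0) {
    diffuseTotal <- sum(clusters$signal) / preset$fraction_in_clusters -
      sum(fluxes)
    if (diffuseTotal <= 0)
      stop(paste0("preset demands more cluster signal than its expression ",
                  "level allows (fraction of signal in clusters too high)"))
  } else {
    diffuseTotal <- preset$expression_level * areaMask
  }
  gdir <- stats::runif(1, 0, 2 * pi)
  u <- dx * cos(gdir) + dy * sin(gdir)
  u <- u - mean(u[mask])
  w <- 1 + shape$gradient * u / max(abs(u[mask]), 1e-12)
  diffuse <- matrix(0, n, n)
  diffuse[mask] <- diffuseTotal * w[mask] / sum(w[mask])

  expected <- diffuse + blobs
  ifsTrue <- sum(expected[mask])

  blurred <- blurMatrix(expected, sigP / px)
  blurred[blurred < 0] <- 0

  peakExp <- max(blurred)
  gain <- if (peakExp > 0) noise$gain_target * dynmax / peakExp else 1
  counts <- stats::rpois(length(blurred), blurred * gain) +
    stats::rnorm(length(blurred), 0, noise$read_noise_frac * dynmax)
  counts <- matrix(pmin(pmax(round(counts), 0), dynmax), n, n)

  frame <- ImageFrame(counts, pixelSize = px, bitDepth = 16L,
                      id = sprintf("%s_seed%d", preset$name, as.integer(seed)))
  truth <- new("GroundTruth",
    cell = list(area_um2 = areaMask, background = diffuseTotal / npxMask,
                diffuse_total = diffuseTotal, ifs = ifsTrue, gain = gain,
                count_factor = fCount, intensity_factor = fInt,
                pixel_size = px, target_area_um2 = areaTarget),
    clusters = clusters, mask = mask, seed = as.integer(seed))
  list(frame = frame, truth = truth)
}

# Gaussian blur of a plain matrix (sigma in pixels); separable kernel
# truncated at 4 sigma, zero beyond the image border.
blurMatrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  cpp_gauss_blur(m, sigma)
}

#' Generate a cohort of synthetic cells
#'
#' Draws `n_cells` independent cells from one preset. Per-cell seeds are
#' derived deterministically from the master seed, so a cohort is fully
#' reproducible while cells remain mutually independent; cell-to-cell
#' variability comes from the generator's log-normal dispersion factors.
#'
#' @param preset one-row preset (see [kvPresets()]).
#' @param n_cells number of cells (>= 1).
#' @param seed master seed.
#' @inheritParams generateCell
#' @return list of `n_cells` elements, each as returned by [generateCell()].
#' @export
generateCohort <- function(preset, n_cells, seed = 1L, geometry = NULL,
                           noise = NULL, shape = NULL) {
  stopifnot(n_cells >= 1L)
  lapply(seq_len(n_cells), function(i)
    generateCell(preset, geometry = geometry, noise = noise, shape = shape,
                 seed = deriveSeed(seed, i)))
}

# Deterministic per-unit seed derivation; stays inside 32-bit integer range.
deriveSeed <- function(master, index, stream = 0L) {
  v <- (abs(as.double(master)) * 100003 + as.double(index) * 10007 +
        as.double(stream) * 99991) %% 2147483629
  as.integer(v) + 1L
}

#' Write a synthetic cohort to disk
#'
#' Writes one 16-bit grayscale TIFF per cell (with a JSON sidecar carrying
#' the pixel size, see [writeFrame()]), a ground-truth cluster table, a
#' per-cell truth table, and a run manifest echoing the generator
#' configuration and seed.
#'
#' @param cohort list as returned by [generateCohort()].
#' @param dir output directory (created if missing).
#' @param manifest named list merged into the manifest (e.g. preset, seed).
#' @return invisibly, the manifest list.
#' @export
writeCohort <- function(cohort, dir, manifest = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cellRows <- list(); clusterRows <- list(); files <- character(0)
  for (i in seq_along(cohort)) {
    fr <- cohort[[i]]$frame; tr <- cohort[[i]]$truth
    fn <- file.path(dir, sprintf("cell_%03d.tif", i))
    writeFrame(fr, fn)
    files <- c(files, fn)
    cellRows[[i]] <- data.frame(
      cell_id = frameId(fr), file = basename(fn), seed = tr@seed,
      area_um2 = tr@cell$area_um2, background = tr@cell$background,
      ifs = tr@cell$ifs, gain = tr@cell$gain)
    tc <- tr@clusters
    if (nrow(tc)) {
      tc <- cbind(cell_id = frameId(fr),
                  tc[, c("cluster_id", "x_um", "y_um", "area_um2",
                         "signal", "intensity")])
      clusterRows[[i]] <- tc
    }
  }
  cells <- do.call(rbind, cellRows)
  utils::write.csv(cells, file.path(dir, "cells_truth.csv"), row.names = FALSE)
  clus <- if (length(clusterRows)) do.call(rbind, clusterRows) else
    data.frame(cell_id = character(0), cluster_id = integer(0),
               x_um = numeric(0), y_um = numeric(0), area_um2 = numeric(0),
               signal = numeric(0), intensity = numeric(0))
  utils::write.csv(clus, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  man <- c(manifest, list(n_cells = length(cohort), files = basename(files),
                          pixel_size = pixelSize(cohort[[1]]$frame)))
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(man)
}
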