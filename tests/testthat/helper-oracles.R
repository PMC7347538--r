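# Independent brute-force references and small scene builders used across
# the test files. The oracles re-state the published rules literally and
# share no code with the package implementation.

# Literal box-scan reference: enumerate every box placement, take the box
# maximum (first in row-major order for plateaus), apply the corner gate,
# then the stronger-peak suppression within box/2 Chebyshev distance.
bruteForceSpots <- function(img, box, tol) {
  half <- (box - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  rows <- integer(0); cols <- integer(0); peaks <- numeric(0)
  for (i in (1 + half):(nr - half)) {
    for (j in (1 + half):(nc - half)) {
      win <- img[(i - half):(i + half), (j - half):(j + half)]
      v <- img[i, j]
      if (v < max(win)) next
      pos <- which(t(win) == max(win))[1]    # row-major first maximum
      wr <- (pos - 1) %/% box + 1
      wc <- (pos - 1) %% box + 1
      if (wr != half + 1 || wc != half + 1) next
      cm <- mean(c(win[1, 1], win[1, box], win[box, 1], win[box, box]))
      if (v - cm > tol) {
        rows <- c(rows, i); cols <- c(cols, j); peaks <- c(peaks, v)
      }
    }
  }
  out <- data.frame(row = rows, col = cols, peak = peaks)
  if (nrow(out) > 1L) {
    out <- out[order(-out$peak, out$row, out$col), ]
    supr <- floor(box / 2)
    keep <- logical(nrow(out))
    for (i in seq_len(nrow(out))) {
      j <- which(keep)
      keep[i] <- !length(j) ||
        all(pmax(abs(out$row[i] - out$row[j]),
                 abs(out$col[i] - out$col[j])) > supr)
    }
    out <- out[keep, ]
  }
  rownames(out) <- NULL
  out
}

# Exhaustive seeded-growth reference: for seed s, pixels above thr[s] in
# s's exact nearest-seed cell (ties: stronger peak, then lower index),
# 8-connected component containing the seed. Returns column-major linear
# index sets.
bruteForceGrow <- function(img, mask, seeds, thr, peaks) {
  nr <- nrow(img); nc <- ncol(img)
  n <- nrow(seeds)
  near <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      d2 <- (r - seeds$row)^2 + (c - seeds$col)^2
      near[r, c] <- order(d2, -peaks, seq_len(n))[1]
    }
  }
  lapply(seq_len(n), function(s) {
    cand <- mask & img >= thr[s] & near == s
    comp <- matrix(FALSE, nr, nc)
    comp[seeds$row[s], seeds$col[s]] <- cand[seeds$row[s], seeds$col[s]]
    repeat {
      idx <- which(comp, arr.ind = TRUE)
      grown <- comp
      for (k in seq_len(nrow(idx))) {
        rs <- max(1, idx[k, 1] - 1):min(nr, idx[k, 1] + 1)
        cs <- max(1, idx[k, 2] - 1):min(nc, idx[k, 2] + 1)
        grown[rs, cs] <- grown[rs, cs] | cand[rs, cs]
      }
      if (identical(grown, comp)) break
      comp <- grown
    }
    which(comp)
  })
}

# Add an isotropic Gaussian blob (peak `amp`, width sigma in px) to an
# image matrix.
addBlob <- function(img, row, col, sigma, amp) {
  d2 <- outer((seq_len(nrow(img)) - row)^2, (seq_len(ncol(img)) - col)^2, "+")
  img + amp * exp(-d2 / (2 * sigma^2))
}

# Minimal uncompressed little-endian grayscale TIFF with X/YResolution and
# ResolutionUnit tags (unit = cm). Fixture builder for the calibrated-read
# path; values must stay below 32768 (written as signed 16-bit).
writeTiffWithResolution <- function(path, mat, pixels_per_cm) {
  nr <- nrow(mat); nc <- ncol(mat)
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) { w2(tag); w2(type); w4(count); w4(value) }
  writeBin(charToRaw("II"), con); w2(42L); w4(8L)     # header, IFD at 8
  nEntries <- 12L
  ratOff <- 8L + 2L + nEntries * 12L + 4L             # after IFD
  datOff <- ratOff + 16L
  w2(nEntries)
  entry(256L, 3L, 1L, nc)                 # ImageWidth
  entry(257L, 3L, 1L, nr)                 # ImageLength
  entry(258L, 3L, 1L, 16L)                # BitsPerSample
  entry(259L, 3L, 1L, 1L)                 # Compression: none
  entry(262L, 3L, 1L, 1L)                 # Photometric: BlackIsZero
  entry(273L, 4L, 1L, datOff)             # StripOffsets
  entry(277L, 3L, 1L, 1L)                 # SamplesPerPixel
  entry(278L, 3L, 1L, nr)                 # RowsPerStrip
  entry(279L, 4L, 1L, nr * nc * 2L)       # StripByteCounts
  entry(282L, 5L, 1L, ratOff)             # XResolution
  entry(283L, 5L, 1L, ratOff + 8L)        # YResolution
  entry(296L, 3L, 1L, 3L)                 # ResolutionUnit: cm
  w4(0L)                                  # next IFD: none
  w4(round(pixels_per_cm)); w4(1L)        # XResolution rational
  w4(round(pixels_per_cm)); w4(1L)        # YResolution rational
  w2(as.vector(t(mat)))                   # row-major pixel data
  invisible(path)
}

# Shared smoke preset: small, sparse and fast.
smallPreset <- function() {
  p <- kvPresets()
  p[p$chain_length == 50, ]
}

smallGeometry <- function() list(cell_area = c(150, 220))
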