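frameOf <- function(m, px = 0.1) ImageFrame(m, pixelSize = px)

regionOf <- function(m, px = 0.1, background = 0) {
  mask <- matrix(TRUE, nrow(m), ncol(m))
  new("CellRegion", mask = mask, pixelSize = px,
      area = length(m) * px^2, ifs = sum(m), background = background)
}

test_that("cell segmentation recovers a uniform block exactly", {
  m <- matrix(0, 60, 60)
  m[25:34, 25:34] <- 10                       # 100 px of 0.01 um2
  cell <- segmentCell(frameOf(m), min_area_um2 = 0.5)
  expect_equal(cellArea(cell), 1.0)
  expect_equal(cellIfs(cell), 1000)
  expect_error(segmentCell(frameOf(matrix(0, 40, 40))), "no cell found")
})

test_that("segmented masks overlap the true cell footprint (Jaccard >= 0.9)", {
  pr <- smallPreset()
  for (s in 1:20) {
    cell <- generateCell(pr, geometry = smallGeometry(), seed = s)
    got <- segmentCell(cell$frame)
    tru <- cell$truth@mask
    jac <- sum(got@mask & tru) / sum(got@mask | tru)
    expect_gte(jac, 0.9)
  }
})

test_that("cluster photometry follows the stated arithmetic", {
  # uniform 20-px cluster of intensity 50 on zero background
  m <- matrix(0, 30, 30)
  m[10:14, 10:13] <- 50                       # 20 px of 0.01 um2
  cell <- regionOf(m)
  spots <- data.frame(row = 12L, col = 11L, peak = 50)
  for (f in c(0.2, 0.5, 0.8)) {
    cl <- clusterTable(segmentClusters(frameOf(m), cell, spots,
                                       threshold_fraction = f,
                                       background = 0))
    expect_equal(cl$area_um2, 0.20)
    expect_equal(cl$ifsc, 1000)
    expect_equal(cl$intensity, 5000)
  }
  # same cluster (absolute intensity 50) on uniform background 10:
  # ifsc = (50 - 10) * 20
  m2 <- matrix(10, 30, 30)
  m2[10:14, 10:13] <- 50
  cl2 <- clusterTable(segmentClusters(frameOf(m2), regionOf(m2, background = 10),
                                      data.frame(row = 12L, col = 11L, peak = 50),
                                      background = 10))
  expect_equal(cl2$ifsc, (50 - 10) * 20)
  expect_equal(cl2$area_um2, 0.20)
})

test_that("two seeds in one bright region split into disjoint halves", {
  m <- matrix(0, 32, 32)
  m[10:22, 8:26] <- 40                        # one merged bright slab
  cell <- regionOf(m)
  spots <- data.frame(row = c(16L, 16L), col = c(12L, 22L), peak = c(40, 40))
  cs <- segmentClusters(frameOf(m), cell, spots, threshold_fraction = 0.5,
                        background = 0)
  expect_equal(length(cs), 2L)
  idx <- cs@pixels
  expect_equal(length(intersect(idx[[1]], idx[[2]])), 0L)
  expect_setequal(c(idx[[1]], idx[[2]]), which(m >= 20))
})

test_that("region growth matches the exhaustive nearest-seed reference", {
  for (s in 1:6) {
    set.seed(300 + s)
    m <- matrix(rpois(32 * 32, 8), 32, 32)
    m <- addBlob(m, 10, 11, 2.5, 60)
    m <- addBlob(m, 18, 20, 2.5, 45)
    m <- addBlob(m, 24, 8, 2, 50)
    mask <- matrix(TRUE, 32, 32); mask[1:2, ] <- FALSE
    spots <- data.frame(row = c(10L, 18L, 24L), col = c(11L, 20L, 8L),
                        peak = c(m[10, 11], m[18, 20], m[24, 8]))
    bg <- 8
    cs <- segmentClusters(ImageFrame(m, pixelSize = 0.1),
                          new("CellRegion", mask = mask, pixelSize = 0.1,
                              area = sum(mask) * 0.01, ifs = sum(m[mask]),
                              background = bg),
                          spots, threshold_fraction = 0.5, background = bg,
                          local_background = FALSE)
    thr <- bg + 0.5 * (spots$peak - bg)
    ref <- bruteForceGrow(m, mask, spots, thr, spots$peak)
    for (k in seq_len(3)) {
      expect_setequal(cs@pixels[[match(k, cs@clusters$cluster_id)]], ref[[k]])
    }
  }
})

test_that("photometry is scale-equivariant and rotation-invariant", {
  set.seed(77)
  m <- matrix(rpois(40 * 40, 30), 40, 40)
  m <- addBlob(m, 15, 15, 2, 200)
  m <- addBlob(m, 28, 30, 2.5, 150)
  spots <- data.frame(row = c(15L, 28L), col = c(15L, 30L),
                      peak = c(m[15, 15], m[28, 30]))
  base <- clusterTable(segmentClusters(frameOf(m), regionOf(m, background = 30),
                                       spots, background = 30))
  # scale: x3 on every pixel and the background
  m3 <- 3 * m
  sc <- clusterTable(segmentClusters(frameOf(m3), regionOf(m3, background = 90),
                                     transform(spots, peak = 3 * peak),
                                     background = 90))
  expect_equal(sc$area_um2, base$area_um2)
  expect_equal(sc$ifsc, 3 * base$ifsc)
  expect_equal(sc$intensity, 3 * base$intensity)
  # rotation by 90 degrees
  rot <- t(m)[, nrow(m):1]
  rspots <- data.frame(row = spots$col,
                       col = nrow(m) + 1L - spots$row, peak = spots$peak)
  rt <- clusterTable(segmentClusters(frameOf(rot), regionOf(rot, background = 30),
                                     rspots, background = 30))
  expect_equal(sort(rt$area_um2), sort(base$area_um2))
  expect_equal(sort(rt$ifsc), sort(base$ifsc))
})

test_that("spots outside the mask are skipped with a warning", {
  m <- matrix(0, 20, 20); m[5, 5] <- 50; m[15, 15] <- 50
  mask <- matrix(FALSE, 20, 20); mask[1:10, 1:10] <- TRUE
  cell <- new("CellRegion", mask = mask, pixelSize = 0.1, area = 1,
              ifs = sum(m[mask]), background = 0)
  spots <- data.frame(row = c(5L, 15L), col = c(5L, 15L), peak = c(50, 50))
  expect_warning(cs <- segmentClusters(frameOf(m), cell, spots,
                                       background = 0),
                 "outside the cell mask")
  expect_equal(length(cs), 1L)
})

test_that("background re-estimation excludes dilated cluster pixels", {
  m <- matrix(10, 30, 30)
  m[14:16, 14:16] <- 100
  fr <- frameOf(m)
  cell <- regionOf(m, background = 10)
  cs <- segmentClusters(fr, cell, data.frame(row = 15L, col = 15L, peak = 100),
                        background = 10)
  expect_equal(estimateBackground(fr, cell, cs), 10)
  # size filters drop implausible clusters
  tiny <- segmentClusters(fr, cell, data.frame(row = 15L, col = 15L, peak = 100),
                          background = 10, min_area_um2 = 1)
  expect_equal(length(tiny), 0L)
})
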