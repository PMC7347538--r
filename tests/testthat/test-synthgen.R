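test_that("the same preset and seed reproduce a scene bit for bit", {
  pr <- smallPreset()
  a <- generateCell(pr, geometry = smallGeometry(), seed = 11)
  b <- generateCell(pr, geometry = smallGeometry(), seed = 11)
  expect_identical(pixels(a$frame), pixels(b$frame))
  expect_identical(truthTable(a$truth), truthTable(b$truth))
  c <- generateCell(pr, geometry = smallGeometry(), seed = 12)
  expect_false(identical(pixels(a$frame), pixels(c$frame)))
})

test_that("a zero-cluster-density preset yields a diffuse-only cell", {
  pr <- smallPreset()
  pr$clusters_per_area <- 0
  cell <- generateCell(pr, geometry = smallGeometry(), seed = 3)
  expect_equal(nrow(truthTable(cell$truth)), 0L)
  # total expected in-mask signal equals expression * area exactly
  expect_equal(cell$truth@cell$ifs,
               pr$expression_level * cell$truth@cell$area_um2,
               tolerance = 1e-12)
})

test_that("pre-noise signal is conserved: diffuse + cluster flux = total", {
  for (s in 1:5) {
    cell <- generateCell(smallPreset(), geometry = smallGeometry(), seed = s)
    tt <- truthTable(cell$truth)
    expect_equal(cell$truth@cell$ifs,
                 cell$truth@cell$diffuse_total + sum(tt$flux),
                 tolerance = 1e-9)
  }
})

test_that("the in-cluster signal fraction holds exactly by construction", {
  for (s in 1:5) {
    cell <- generateCell(smallPreset(), geometry = smallGeometry(), seed = s)
    tt <- truthTable(cell$truth)
    expect_gt(nrow(tt), 0)
    expect_equal(sum(tt$signal) / cell$truth@cell$ifs,
                 smallPreset()$fraction_in_clusters, tolerance = 1e-9)
  }
})

test_that("every planted cluster lies inside the cell mask", {
  cell <- generateCell(smallPreset(), geometry = smallGeometry(), seed = 7)
  tt <- truthTable(cell$truth)
  msk <- cell$truth@mask
  expect_true(all(msk[cbind(round(tt$row), round(tt$col))]))
  # and with its full truncated footprint: flux conservation above already
  # implies no cluster photons fall outside the mask
})

test_that("impossible preset demands are rejected with parameter errors", {
  pr <- smallPreset()
  pr$fraction_in_clusters <- 0.9    # more cluster signal than expression
  expect_error(generateCell(pr, geometry = smallGeometry(), seed = 1),
               "more cluster signal")
  pr2 <- smallPreset()
  pr2$clusters_per_area <- 30       # unplaceable density
  expect_error(generateCell(pr2, geometry = smallGeometry(),
                            shape = list(place_attempts = 10), seed = 1),
               "density is too high")
})

test_that("cohorts derive distinct per-cell seeds deterministically", {
  pr <- smallPreset()
  co <- generateCohort(pr, 3, seed = 5, geometry = smallGeometry())
  expect_length(co, 3L)
  seeds <- vapply(co, function(x) x$truth@seed, integer(1))
  expect_equal(anyDuplicated(seeds), 0L)
  co2 <- generateCohort(pr, 3, seed = 5, geometry = smallGeometry())
  expect_identical(pixels(co[[2]]$frame), pixels(co2[[2]]$frame))
  one <- generateCohort(pr, 1, seed = 5, geometry = smallGeometry())
  expect_length(one, 1L)
  # different master seeds give different scenes
  co3 <- generateCohort(pr, 3, seed = 6, geometry = smallGeometry())
  expect_false(identical(pixels(co[[1]]$frame), pixels(co3[[1]]$frame)))
})

test_that("a chain-61 cohort carries a realistic total cluster count", {
  # 30 cells of a well-spread neuroblastoma cell footprint; the densest
  # variant should land in the low-thousands of clusters in total
  pr <- kvPresets()
  pr <- pr[pr$chain_length == 61, ]
  co <- generateCohort(pr, 30, seed = 2, geometry = list(cell_area = c(250, 400)))
  total <- sum(vapply(co, function(x) nrow(truthTable(x$truth)), integer(1)))
  expect_gt(total, 350)
  expect_lt(total, 7500)
  # ground-truth mean cluster intensity matches the preset within
  # simulation error at n = 30 cells
  pooled <- unlist(lapply(co, function(x) truthTable(x$truth)$intensity))
  expect_equal(mean(pooled), 44.8e5, tolerance = 0.1)
})

test_that("doubling the requested intensity doubles the recovered density", {
  pr <- smallPreset()
  pr2 <- pr
  pr2$cluster_intensity <- 2 * pr$cluster_intensity
  pr2$cluster_area_um2 <- NA  # re-derive from the doubled intensity
  co1 <- generateCohort(pr, 6, seed = 31, geometry = smallGeometry())
  co2 <- generateCohort(pr2, 6, seed = 31, geometry = smallGeometry())
  m1 <- mean(analyzeCohort(co1)$intensities)
  m2 <- mean(analyzeCohort(co2)$intensities)
  expect_equal(m2 / m1, 2, tolerance = 0.1)
})

test_that("scenes stay inside the 16-bit range with headroom", {
  cell <- generateCell(kvPresets()[5, ], geometry = smallGeometry(), seed = 1)
  expect_lte(max(pixels(cell$frame)), 2^16 - 1)
  expect_gte(min(pixels(cell$frame)), 0)
  expect_true(cell$truth@cell$gain > 0)
})
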