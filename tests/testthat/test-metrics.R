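makeClusterSet <- function(ifsc, area, raw = NULL, px = 0.1) {
  n <- length(ifsc)
  if (is.null(raw)) raw <- ifsc
  cl <- data.frame(
    cell_id = "c1", cluster_id = seq_len(n), seed_row = seq_len(n),
    seed_col = seq_len(n), x_um = 0, y_um = 0,
    n_pixels = as.integer(area / px^2), area_um2 = area, raw = raw,
    ifsc = ifsc, intensity = ifsc / area, edge = FALSE)
  new("ClusterSet", clusters = cl,
      pixels = lapply(seq_len(n), function(i) i * 1000L + seq_len(3L)),
      pixelSize = px)
}

makeCell <- function(area, ifs, background = 0, px = 0.1) {
  n <- round(sqrt(area) / px)
  new("CellRegion", mask = matrix(TRUE, n, n), pixelSize = px,
      area = area, ifs = ifs, background = background)
}

test_that("per-cell attributes follow the four defining ratios", {
  # 3 clusters with ifsc {100, 200, 700} in a 50 um2 cell with IFS 2000
  cm <- cellMetrics(makeCell(50, 2000), makeClusterSet(c(100, 200, 700),
                                                       c(0.5, 0.5, 1)))
  expect_equal(cm$fraction_in_clusters, 0.5)
  expect_equal(cm$clusters_per_area, 0.06)
  expect_equal(cm$normalized_expression, 40)
  expect_equal(cm$intensities[[1]], c(200, 400, 700))
  # no clusters
  cm0 <- cellMetrics(makeCell(100, 1e6),
                     new("ClusterSet", clusters = kvclust:::emptyClusterFrame(),
                         pixels = list(), pixelSize = 0.1))
  expect_equal(cm0$normalized_expression, 1e4)
  expect_equal(cm0$fraction_in_clusters, 0)
  # all signal in clusters on zero background: the conservation limit
  cm1 <- cellMetrics(makeCell(50, 1000), makeClusterSet(c(400, 600), c(1, 1)))
  expect_equal(cm1$fraction_in_clusters, 1)
})

test_that("inconsistent cells are reported, not silently clamped", {
  expect_error(cellMetrics(makeCell(50, 0), makeClusterSet(100, 1)),
               "zero IFS")
  expect_error(cellMetrics(makeCell(50, 500), makeClusterSet(c(400, 200),
                                                             c(1, 1))),
               "conservation")
})

test_that("variant summaries pool clusters and report standard errors", {
  c1 <- cellMetrics(makeCell(50, 2000), makeClusterSet(c(100, 300), c(1, 1)))
  c2 <- cellMetrics(makeCell(50, 2000), makeClusterSet(500, 1))
  s <- summarizeVariant(rbind(c1, c2))
  expect_equal(s$n_cells, 2L)
  expect_equal(s$n_clusters, 3L)
  # pooled over clusters, not mean of cell means (which would be 350)
  expect_equal(s$intensity_mean, 300)
  expect_equal(s$expression_se, 0)
  # identical cells have zero SE on cell-level attributes
  s2 <- summarizeVariant(rbind(c1, c1))
  expect_equal(s2$fraction_se, 0)
  expect_equal(s2$clusters_per_area_se, 0)
  # a single cell: means equal that cell's values
  s3 <- summarizeVariant(c2)
  expect_equal(s3$fraction_mean, 0.25)
  expect_true(is.na(s3$expression_se))
  expect_error(summarizeVariant(c1[0, ]), "no cells")
})

test_that("density histograms use half-open bins from zero", {
  h <- densityHistogram(c(1e5, 3e5, 3.5e5))
  expect_equal(h$counts, c(1L, 2L))
  expect_equal(h$breaks, c(0, 2e5, 4e5))
  # the boundary value 2e5 belongs to the second bin
  expect_equal(densityHistogram(c(2e5))$counts, c(0L, 1L))
  # empty input: an all-zero histogram
  h0 <- densityHistogram(numeric(0))
  expect_equal(sum(h0$counts), 0L)
  expect_error(densityHistogram(c(-1, 2)), "negative")
  expect_error(densityHistogram(1, bin_width = 0), "positive")
})

test_that("histogram counts are conserved and refine consistently", {
  set.seed(9)
  for (rep in 1:5) {
    x <- rgamma(400, 4, rate = 4 / 20e5)
    w <- 2e5
    h1 <- densityHistogram(x, w)
    expect_equal(sum(h1$counts), length(x))
    h2 <- densityHistogram(x, 2 * w)
    fine <- h1$counts
    if (length(fine) %% 2L) fine <- c(fine, 0L)
    merged <- fine[seq(1, length(fine), 2)] + fine[seq(2, length(fine), 2)]
    expect_equal(merged[seq_along(h2$counts)], h2$counts)
  }
})
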