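test_that("one-way ANOVA reproduces the textbook closed form", {
  # groups {1,2,3} and {2,3,4}: SSB = 1.5, SSW = 4, df = (1, 4), F = 1.5
  r <- anovaOneway(list(a = c(1, 2, 3), b = c(2, 3, 4)))
  expect_equal(r@statistic, 1.5)
  expect_equal(r@df, c(1, 4))
  expect_equal(r@p.value, 0.2878, tolerance = 1e-3)
  # identical groups: F = 0, p = 1
  r0 <- anovaOneway(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(r0@statistic, 0)
  expect_equal(r0@p.value, 1)
  expect_error(anovaOneway(list(1, c(1, 2))), "at least two values")
  expect_error(anovaOneway(list(c(1, 2))), "at least two groups")
})

test_that("ANOVA type-I error is calibrated at the nominal level", {
  set.seed(1234)
  reject <- logical(1000)
  for (i in seq_along(reject)) {
    g <- list(rnorm(20), rnorm(20), rnorm(20))
    reject[i] <- anovaOneway(g)@p.value < 0.05
  }
  expect_gte(mean(reject), 0.03)
  expect_lte(mean(reject), 0.07)
})

test_that("the gamma GLM reproduces group means exactly through the log link", {
  set.seed(5)
  y1 <- rgamma(40, 5, rate = 5 / 10)
  y2 <- rgamma(40, 5, rate = 5 / 30)
  r <- gammaGlmLogLink(c(y1, y2), rep(c("a", "b"), each = 40))
  expect_equal(exp(r@estimate[["(Intercept)"]]), mean(y1), tolerance = 1e-8)
  expect_equal(exp(r@estimate[["(Intercept)"]] + r@estimate[["gb"]]),
               mean(y2), tolerance = 1e-8)
  expect_true(r@p.value >= 0 && r@p.value <= 1)
  expect_equal(r@df, 1)
  expect_error(gammaGlmLogLink(c(-1, 2, 3), c("a", "a", "b")), "positive")
  expect_error(gammaGlmLogLink(y1, rep("a", 40)), "two groups")
})

test_that("the gamma GLM recovers a two-fold density ratio", {
  set.seed(99)
  y <- c(rgamma(500, 5, rate = 5), rgamma(500, 5, rate = 5 / 2))
  r <- gammaGlmLogLink(y, rep(c("a", "b"), each = 500))
  expect_lt(abs(r@estimate[["gb"]] - log(2)), 0.1)
  expect_lt(r@p.value, 1e-6)
})

test_that("ANOVA and gamma-GLM Wald agree on a large effect", {
  set.seed(17)
  y <- c(rgamma(200, 8, rate = 8), rgamma(200, 8, rate = 8 / 3))
  g <- rep(c("a", "b"), each = 200)
  expect_lt(anovaOneway(split(y, g))@p.value, 1e-10)
  expect_lt(gammaGlmLogLink(y, g)@p.value, 1e-10)
})

test_that("the affinity-density regression reproduces the long-chain fit", {
  s <- kvPresets()
  s$intensity_mean <- s$cluster_intensity
  r <- affinityDensityRegression(s, min_chain_length = 61)
  expect_equal(r@estimate[["n"]], 6)          # 61, 88, 104, 106, 144, 144
  expect_equal(r@estimate[["r.squared"]], 0.96, tolerance = 0.021)
  expect_lt(r@estimate[["slope"]], 0)         # higher affinity, denser
  # the correlation breaks down when the short chains are included
  rAll <- affinityDensityRegression(s, min_chain_length = 9)
  expect_lt(rAll@estimate[["r.squared"]], 0.5)
  # display scaling leaves the fit quality unchanged
  s2 <- s; s2$intensity_mean <- s2$intensity_mean / 1e5
  r2 <- affinityDensityRegression(s2, min_chain_length = 61)
  expect_equal(r2@estimate[["r.squared"]], r@estimate[["r.squared"]])
  # reversed-chain control can be excluded explicitly
  r5 <- affinityDensityRegression(s, include_reversed = FALSE)
  expect_equal(r5@estimate[["n"]], 5)
  expect_error(affinityDensityRegression(s[s$chain_length > 140, ]),
               "at least three")
})

test_that("perfect linear data give R squared of one", {
  d <- data.frame(name = c("a", "b", "c"), chain_length = c(70, 80, 90),
                  intensity_mean = c(10, 20, 30),
                  binding_energy = c(-11, -10.5, -10))
  r <- affinityDensityRegression(d, min_chain_length = 61)
  expect_equal(r@estimate[["r.squared"]], 1)
  expect_equal(r@estimate[["slope"]], 20)
})

test_that("the density curve peaks at the chain-61 variant", {
  s <- kvPresets()
  s$intensity_mean <- s$cluster_intensity
  expect_equal(bellCurveArgmax(s), 61L)
  # monotone series: the endpoint wins
  mono <- data.frame(chain_length = c(10, 20, 30), intensity_mean = 1:3)
  expect_equal(bellCurveArgmax(mono), 30L)
  # ties go to the shorter chain
  tie <- data.frame(chain_length = c(10, 20, 30), intensity_mean = c(1, 5, 5))
  expect_equal(bellCurveArgmax(tie), 20L)
  expect_error(bellCurveArgmax(mono[1:2, ]), "three")
})
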