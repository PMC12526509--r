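writeTestRaster <- function(path, px) {
  tiff::writeTIFF(lapply(seq_len(dim(px)[3]), function(b) px[, , b]),
                  path, bits.per.sample = 32L)
}

test_that("loadPlot clips rectangles half-open and checks band count", {
  dir <- withr::local_tempdir()
  px <- array(runif(64 * 64 * 6), c(64, 64, 6))
  f <- file.path(dir, "r.tif"); writeTestRaster(f, px)

  full <- loadPlot(f, list(plot_id = "A", row0 = 0, row1 = 64,
                           col0 = 0, col1 = 64))
  expect_equal(dim(reflectance(full)), c(64, 64, 6))
  expect_equal(reflectance(full), px, tolerance = 1e-6)
  expect_true(all(vegMask(full)))

  half <- loadPlot(f, list(plot_id = "B", row0 = 0, row1 = 32,
                           col0 = 0, col1 = 64))
  expect_equal(dim(reflectance(half))[1:2], c(32, 64))

  # 5-band raster: error names the missing band
  f5 <- file.path(dir, "r5.tif")
  tiff::writeTIFF(lapply(1:5, function(b) px[, , b]), f5,
                  bits.per.sample = 32L)
  expect_error(loadPlot(f5, list(plot_id = "C", row0 = 0, row1 = 8,
                                 col0 = 0, col1 = 8)), "NIR")
  # empty intersection
  expect_error(loadPlot(f, list(plot_id = "D", row0 = 70, row1 = 80,
                                col0 = 0, col1 = 8)), "intersect")
})

test_that("loadPlot rasterizes GeoJSON polygons in pixel coordinates", {
  dir <- withr::local_tempdir()
  px <- array(runif(32 * 32 * 6), c(32, 32, 6))
  f <- file.path(dir, "r.tif"); writeTestRaster(f, px)
  gj <- list(type = "Feature", properties = list(plot_id = "poly"),
             geometry = list(type = "Polygon",
                             coordinates = list(rbind(c(4, 4), c(20, 4),
                                                      c(20, 12), c(4, 12),
                                                      c(4, 4)))))
  gf <- file.path(dir, "plot.geojson")
  jsonlite::write_json(gj, gf, auto_unbox = TRUE)
  p <- loadPlot(f, gf)
  expect_equal(plotId(p), "poly")
  # bbox crop: rows 4..12, cols 4..20 -> 8 x 16, all centres inside
  expect_equal(dim(reflectance(p))[1:2], c(8, 16))
  expect_true(all(vegMask(p)))
})

test_that("vegetation masking thresholds, refines, and never edits pixels", {
  # build a plot whose NDVI is 0.2 on soil and 0.5 on vegetation
  mkplot <- function(ndviGrid) {
    px <- array(0.2, c(nrow(ndviGrid), ncol(ndviGrid), 6))
    px[, , 6] <- 0.2 * (1 + ndviGrid) / (1 - ndviGrid)  # invert NDVI
    reflectancePlot("m", px)
  }
  g <- matrix(0.2, 8, 8); g[3:6, 3:6] <- 0.5
  p <- mkplot(g)
  before <- reflectance(p)
  masked <- suppressMessages(vegetationMask(p, tau = 0.35))
  expect_identical(reflectance(masked), before)   # reflectance untouched
  expect_identical(unname(vegMask(masked)), unname(g > 0.35))

  # a single isolated vegetation pixel is removed by 3x3 opening
  g1 <- matrix(0.2, 8, 8); g1[4, 4] <- 0.5
  expect_error(suppressMessages(vegetationMask(mkplot(g1), tau = 0.35)),
               "empty")
  # without morphology it survives
  m2 <- suppressMessages(vegetationMask(mkplot(g1), tau = 0.35,
                                        morphology = FALSE))
  expect_equal(sum(vegMask(m2)), 1)

  # tau = 0 on a strictly positive index keeps everything
  m3 <- suppressMessages(vegetationMask(mkplot(matrix(0.5, 8, 8)), tau = 0))
  expect_true(all(vegMask(m3)))

  # checkerboard: opening removes all singletons -> empty-mask error
  cb <- matrix(0.2, 8, 8); cb[(row(cb) + col(cb)) %% 2 == 0] <- 0.5
  expect_error(suppressMessages(vegetationMask(mkplot(cb), tau = 0.35)),
               "empty")
})

test_that("opening-then-closing refinement is idempotent", {
  set.seed(13)
  refine <- function(mask) {
    brush <- EBImage::makeBrush(3, "box")
    m <- EBImage::closing(EBImage::opening(EBImage::Image(mask * 1), brush),
                          brush)
    EBImage::imageData(m) > 0
  }
  for (i in 1:5) {
    mask <- matrix(runif(400) < 0.6, 20, 20)
    once <- refine(mask)
    expect_identical(refine(once), once)
  }
})

test_that("Otsu tau selection clamps to [0.30, 0.40] and matches brute force", {
  mkplot <- function(ndvi) {
    px <- array(0.2, c(1, length(ndvi), 6))
    px[, , 6] <- 0.2 * (1 + ndvi) / (1 - ndvi)
    suppressWarnings(reflectancePlot("t", px))
  }
  # well-separated modes at 0.1 / 0.8: any Otsu threshold separates the
  # clusters (the within-class variance is flat across the gap), so the
  # unclamped threshold sits in the inter-mode gap, above 0.40, and the
  # clamped tau is exactly 0.40
  set.seed(31)
  v <- c(rnorm(400, 0.1, 0.02), rnorm(400, 0.8, 0.02))
  gap <- c(max(v[v < 0.45]), min(v[v > 0.45]))
  expect_gt(bruteOtsu(v), gap[1]); expect_lt(bruteOtsu(v), gap[2])
  unclamped <- selectTau(mkplot(v), clampTo = c(0, 1))
  expect_gt(unclamped, 0.40)
  expect_equal(selectTau(mkplot(v)), 0.40)

  # modes inside the clamp window: tau separates the two clusters, exactly
  # as the brute-force Otsu does
  v <- c(rnorm(400, 0.31, 0.005), rnorm(400, 0.39, 0.005))
  tau <- selectTau(mkplot(v))
  expect_gt(tau, 0.31); expect_lt(tau, 0.39)
  expect_equal(mean(v <= tau), mean(v <= bruteOtsu(v)), tolerance = 0.01)

  # constant index errors
  expect_error(selectTau(mkplot(rep(0.35, 50))), "constant")
})
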