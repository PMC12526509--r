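# builds a small TextureExperiment with planted structure, bypassing imagery
makeToyTE <- function(n = 36, seed = 101) {
  set.seed(seed)
  X <- matrix(runif(n * 48, 0.2, 2), n, 48,
              dimnames = list(sprintf("P%03d", 1:n), positionLabels()))
  shallow <- 20 + 4 * scale(X[, "DIS1"])[, 1] + rnorm(n, 0, 0.8)
  mid <- 20 + 0.6 * (shallow - 20) + rnorm(n, 0, 1.6)
  deep <- 20 + 0.6 * (mid - 20) + rnorm(n, 0, 1.6)
  feats <- cbind(data.frame(plot_id = rownames(X)), as.data.frame(X))
  smc <- data.frame(
    plot_id = rep(rownames(X), 3),
    depth_layer = rep(c("0-20", "20-40", "40-60"), each = n),
    smc = c(shallow, mid, deep))
  textureExperiment(feats, smc)
}

test_that("combination ids enumerate the non-empty subsets of 3 groups", {
  members <- combinationMembers(1:7)
  expect_length(members, 7)
  expect_identical(members[[1]], "raw")
  expect_identical(members[[2]], "idx2d")
  expect_identical(members[[3]], "idx3d")
  expect_setequal(members[[7]], c("raw", "idx2d", "idx3d"))
  # all 7 subsets are distinct and non-empty
  keys <- vapply(members, function(m) paste(sort(m), collapse = "+"), "")
  expect_length(unique(keys), 7)
  expect_error(combinationMembers(8), "1..7")
})

test_that("assembled combinations are deduplicated unions of survivors", {
  ds <- new("DepthScreen", depthLayer = "0-20", results = list(),
            survivorList = list(raw = c("DIS1", "VAR4"),
                                idx2d = c("ATI(HOM2,MEA2)"),
                                idx3d = c("DTTI(HOM5,HOM2,SEC6)")),
            features = matrix(0, 1, 1), screenIds = "P001")
  expect_identical(assembleCombination(ds, 1), c("DIS1", "VAR4"))
  expect_setequal(assembleCombination(ds, 7),
                  c("DIS1", "VAR4", "ATI(HOM2,MEA2)",
                    "DTTI(HOM5,HOM2,SEC6)"))
  ds@survivorList$idx2d <- character(0)
  expect_error(assembleCombination(ds, 2), "empty")
})

test_that("the evaluation grid completes with flagged, never fatal, cells", {
  te <- makeToyTE()
  res <- runGrid(te, seed = 5, combinations = 1:7, models = "RF",
                 screenParams = list(chunkSize = 30000))
  # 3 depths x 7 combinations x 1 model
  expect_equal(nrow(res$records), 21)
  expect_true(all(res$records$flag == "" | is.na(res$records$R2)))
  expect_true(all(res$records$RMSE >= 0, na.rm = TRUE))
  expect_true(all(res$records$R2 <= 1, na.rm = TRUE))
  # reproducible bit-for-bit under the same pipeline seed
  res2 <- runGrid(te, seed = 5, combinations = 1:7, models = "RF",
                  screenParams = list(chunkSize = 30000))
  expect_identical(res$records, res2$records)
  # improvement report is definitional
  imp <- relativeImprovement(res$records)
  r <- res$records
  r1 <- r$R2[r$depth_layer == "0-20" & r$combination == 1]
  r7 <- r$R2[r$depth_layer == "0-20" & r$combination == 7]
  expect_equal(imp$improvementPct[imp$depth_layer == "0-20"],
               100 * (r7 - r1) / r1)
})

test_that("training fit of the fused input dominates its subsets for RF", {
  te <- makeToyTE(seed = 103)
  X <- positionMatrix(te)
  y <- smcValues(te, "0-20")
  sp <- makeSplit(y, seed = 2)
  screen <- screenDepth(X, y, screenIds = sp$trainIds, depthLayer = "0-20",
                        chunkSize = 30000)
  feat <- screenedFeatures(screen)
  trainFit <- function(cid) {
    labs <- assembleCombination(screen, cid)
    Fc <- feat[sp$trainIds, labs, drop = FALSE]
    std <- foldStandardize(Fc)
    m <- fitRf(std$train, y[sp$trainIds], seed = 11)
    evaluatePredictions(predictSMC(m, std$train), y[sp$trainIds])$R2
  }
  full <- trainFit(7)
  for (cid in c(1, 2, 3)) expect_gte(full, trainFit(cid) - 0.02)
})

test_that("scatter report recovers slope and intercept exactly", {
  preds <- data.frame(depth_layer = "0-20", combination = 1, model = "RF",
                      plot_id = sprintf("P%02d", 1:20),
                      observed = seq(10, 30, length.out = 20))
  # perfect predictions: slope 1, intercept 0
  preds$predicted <- preds$observed
  f <- scatterReport(preds, combinations = 1)$fits
  expect_equal(f$slope, 1); expect_equal(f$intercept, 0)
  # attenuated predictions: slope 0.5 recovered
  preds$predicted <- 0.5 * preds$observed + mean(preds$observed) / 2
  f <- scatterReport(preds, combinations = 1)$fits
  expect_equal(f$slope, 0.5)
  expect_equal(f$intercept, mean(preds$observed) / 2)
  # closed-form least squares on noisy data
  set.seed(9); preds$predicted <- preds$observed + rnorm(20)
  f <- scatterReport(preds, combinations = 1)$fits
  ls <- unname(coef(lm(predicted ~ observed, preds)))
  expect_equal(c(f$intercept, f$slope), ls, tolerance = 1e-10)
})
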