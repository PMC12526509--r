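test_that("stratified split is 2:1, balanced, and deterministic", {
  set.seed(55)
  smc <- setNames(runif(96, 10, 30), sprintf("P%03d", 1:96))
  sp <- makeSplit(smc, seed = 3)
  expect_length(sp$trainIds, 64)
  expect_length(sp$validationIds, 32)
  expect_length(intersect(sp$trainIds, sp$validationIds), 0)
  # folds partition the training set
  expect_setequal(names(sp$folds), sp$trainIds)
  expect_equal(sort(unique(sp$folds)), 1:10)
  # identical seed, identical split
  expect_identical(makeSplit(smc, seed = 3), sp)
  expect_false(identical(makeSplit(smc, seed = 4)$validationIds,
                         sp$validationIds))

  # on a uniform ramp the validation mean sits within one within-stratum
  # step of the training mean
  ramp <- setNames(seq(10, 30, length.out = 96), sprintf("P%03d", 1:96))
  sp <- makeSplit(ramp, seed = 9)
  step <- diff(ramp)[1] * 3
  expect_lt(abs(mean(ramp[sp$validationIds]) - mean(ramp[sp$trainIds])),
            step)
  expect_error(makeSplit(smc[1:5]), "at least 9")
})

test_that("standardization is train-only, population-sd, leak-free", {
  train <- cbind(a = c(1, 2, 3), b = c(2, 2, 4))
  hold <- cbind(a = c(2, 5), b = c(3, 0))
  std <- foldStandardize(train, hold)
  expect_equal(unname(std$train[, "a"]),
               c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  # held-out value equal to the training mean maps to zero
  expect_equal(unname(std$applied[1, "a"]), 0)
  # zero-variance feature dropped with a warning
  expect_warning(s2 <- foldStandardize(cbind(a = c(1, 2, 3),
                                             z = c(5, 5, 5))),
                 "zero-variance")
  expect_identical(s2$kept, "a")
})

test_that("model metrics match hand arithmetic", {
  m <- evaluatePredictions(c(10, 20, 30), c(10, 20, 30))
  expect_equal(m$R2, 1); expect_equal(m$RMSE, 0); expect_equal(m$MRE, 0)

  obs <- c(10, 20, 30)
  m <- evaluatePredictions(obs * 1.02, obs)
  expect_equal(m$MRE, 2)

  m <- evaluatePredictions(c(11, 19, 33), obs)
  expect_equal(m$RMSE, sqrt(11 / 3), tolerance = 1e-10)
  expect_equal(m$MRE, (0.1 + 0.05 + 0.1) / 3 * 100, tolerance = 1e-10)
  # zero observed variance: R2 undefined
  expect_true(is.na(evaluatePredictions(c(1, 2), c(5, 5))$R2))
})

test_that("PLSR recovers an exact rank-1 linear response with 1 LV", {
  set.seed(61)
  n <- 120
  # centered orthogonal predictors so the rank-1 response lies exactly on
  # the first latent variable
  X <- qr.Q(qr(scale(matrix(rnorm(n * 4), n, 4), scale = FALSE))) * sqrt(n)
  dimnames(X) <- list(sprintf("P%03d", 1:n), paste0("f", 1:4))
  y <- setNames(3 * X[, 1], rownames(X))
  folds <- setNames(rep_len(1:10, n), rownames(X))
  fit <- fitPlsr(X, y, folds)
  expect_equal(fit@hyper$ncomp, 1)
  pr <- predictSMC(fit, X)
  expect_equal(unname(pr), unname(y), tolerance = 1e-6)
})

test_that("RF handles constant response and nonlinearity beats PLSR", {
  set.seed(67)
  n <- 60
  X <- matrix(rnorm(n * 2), n, 2,
              dimnames = list(sprintf("P%02d", 1:n), c("x1", "x2")))
  folds <- setNames(rep_len(1:10, n), rownames(X))

  # constant y: RF predicts the constant (randomForest itself warns about
  # regression on a degenerate response; that is expected here)
  fit <- suppressWarnings(fitRf(X, setNames(rep(5, n), rownames(X)),
                                seed = 2))
  expect_equal(unname(predictSMC(fit, X[1:5, ])), rep(5, 5),
               tolerance = 1e-9)

  # planted multiplicative interaction: trees beat the linear model
  y <- setNames(X[, 1] * X[, 2] + rnorm(n, 0, 0.05), rownames(X))
  Xv <- matrix(rnorm(40 * 2), 40, 2, dimnames = list(NULL, c("x1", "x2")))
  yv <- Xv[, 1] * Xv[, 2] + rnorm(40, 0, 0.05)
  r2 <- function(m) evaluatePredictions(predictSMC(m, Xv), yv)$R2
  expect_gt(r2(fitRf(X, y, seed = 5)),
            r2(fitPlsr(X, y, folds)))
})

test_that("BPNN fits a smooth nonlinear response and is reproducible", {
  set.seed(71)
  n <- 50
  X <- matrix(runif(n, -2, 2), n, 1, dimnames = list(NULL, "x"))
  rownames(X) <- sprintf("P%02d", 1:n)
  y <- setNames(tanh(2 * X[, 1]) + rnorm(n, 0, 0.02), rownames(X))
  folds <- setNames(rep_len(1:5, n), rownames(X))
  fit <- fitBpnn(X, y, folds, hiddenGrid = c(5L, 10L), maxit = 200L,
                 restarts = 3L, seed = 4)
  pr <- predictSMC(fit, X)
  expect_gt(evaluatePredictions(pr, y)$R2, 0.95)
  # determinism under a fixed seed
  fit2 <- fitBpnn(X, y, folds, hiddenGrid = c(5L, 10L), maxit = 200L,
                  restarts = 3L, seed = 4)
  expect_identical(predictSMC(fit2, X), pr)
  expect_true(fit@hyper$hidden %in% c(5L, 10L))
})

test_that("BPNN gradient matches a numerical finite-difference check", {
  set.seed(73)
  X <- matrix(rnorm(20), 10, 2)
  y <- rnorm(10)
  p <- 2L; h <- 3L
  par <- rnorm((p + 1) * h + h + 1, 0, 0.5)
  g <- texSMC:::bpnnGradient(par, X, y, p, h, decay = 0.01)
  num <- vapply(seq_along(par), function(k) {
    e <- rep(0, length(par)); e[k] <- 1e-6
    (texSMC:::bpnnObjective(par + e, X, y, p, h, 0.01) -
     texSMC:::bpnnObjective(par - e, X, y, p, h, 0.01)) / 2e-6
  }, 0)
  expect_equal(g, num, tolerance = 1e-6)
})
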