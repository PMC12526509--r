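#' Depth-stratified train/validation split with CV folds
#'
#' Plots are sorted by SMC and partitioned into consecutive strata of
#' three; one plot per stratum is drawn into the validation set, giving an
#' approximately 2:1 train:validation split balanced across the SMC range.
#' The training plots additionally receive a 10-fold cross-validation
#' assignment used for hyperparameter selection.
#'
#' @param smc named SMC vector (plot ids as names) for one depth layer.
#' @param seed RNG seed; the split is deterministic given the seed.
#' @param nFolds folds over the training set (default 10).
#' @return list with `trainIds`, `validationIds` (disjoint), and `folds`
#'   (named integer vector partitioning `trainIds`).
#' @export
makeSplit <- function(smc, seed = 1L, nFolds = 10L) {
  ids <- names(smc)
  if (length(ids) < 9L) stop("need at least 9 plots to split")
  ord <- ids[order(smc, ids)]
  withSeed(seed, {
    val <- character(0)
    for (s in seq(1, length(ord), by = 3L)) {
      stratum <- ord[s:min(s + 2L, length(ord))]
      if (length(stratum) == 3L)
        val <- c(val, sample(stratum, 1L))
    }
    train <- setdiff(ids, val)
    k <- min(nFolds, length(train))
    folds <- setNames(sample(rep_len(seq_len(k), length(train))), train)
    list(trainIds = train, validationIds = val, folds = folds)
  })
}

#' Standardize predictors on training statistics only
#'
#' z-standardization (mean 0, variance 1, population sd) fitted on the
#' training rows and applied unchanged to held-out rows; zero-variance
#' features are dropped with a warning.
#'
#' @param train training rows x features matrix.
#' @param apply rows to transform with the training parameters (default:
#'   the training matrix itself).
#' @return list with `train`, `applied`, `center`, `scale`, `kept`.
#' @export
foldStandardize <- function(train, apply = train) {
  ctr <- colMeans(train)
  n <- nrow(train)
  scl <- sqrt(colMeans(sweep(train, 2, ctr)^2))   # population sd
  kept <- scl > 0
  if (any(!kept))
    warning("dropping zero-variance feature(s): ",
            paste(colnames(train)[!kept], collapse = ", "))
  z <- function(M) sweep(sweep(M[, kept, drop = FALSE], 2, ctr[kept]),
                         2, scl[kept], "/")
  list(train = z(train), applied = z(apply),
       center = ctr[kept], scale = scl[kept],
       kept = colnames(train)[kept])
}

# ---------------------------------------------------------------------------
# model fitting
# ---------------------------------------------------------------------------

#' Fit the random-forest SMC model
#'
#' 200-tree bagged regression ensemble with variance-reduction splits and
#' all features eligible at each split; the out-of-bag MSE is recorded.
#'
#' @param X standardized training predictors.
#' @param y training SMC.
#' @param ntree number of trees (default 200).
#' @param seed RNG seed.
#' @return an [SMCModel-class].
#' @export
fitRf <- function(X, y, ntree = 200L, seed = 1L) {
  fit <- withSeed(seed, randomForest::randomForest(
    x = X, y = y, ntree = ntree, mtry = ncol(X)))
  new("SMCModel", family = "RF", fit = fit,
      hyper = list(ntree = ntree, mtry = ncol(X),
                   oobMSE = unname(fit$mse[ntree])),
      scaling = list(), featureNames = colnames(X))
}

#' Fit the PLSR SMC model with CV-selected latent variables
#'
#' The latent-variable count is the largest for which every increment of
#' the cumulative explained variance of Y — estimated by k-fold
#' cross-validated prediction — is at least `minGain` (default 5%),
#' i.e. LVs are added only while each adds a >= 5% gain.
#'
#' @param X standardized training predictors.
#' @param y training SMC.
#' @param folds named fold assignment over the training rows.
#' @param maxComp largest LV count considered.
#' @param minGain minimum incremental explained-variance gain.
#' @return an [SMCModel-class].
#' @export
fitPlsr <- function(X, y, folds, maxComp = 10L, minGain = 0.05) {
  maxComp <- min(maxComp, ncol(X), nrow(X) - 2L)
  sst <- sum((y - mean(y))^2)
  ev <- numeric(maxComp)
  if (maxComp > 1L) {
    press <- matrix(0, maxComp, 1)
    for (f in unique(folds)) {
      hold <- names(folds)[folds == f]
      keep <- setdiff(names(folds), hold)
      nc <- min(maxComp, length(keep) - 1L)
      fit <- mixOmics::pls(X[keep, , drop = FALSE],
                           matrix(y[keep], ncol = 1),
                           ncomp = nc, mode = "regression")
      pr <- predict(fit, X[hold, , drop = FALSE])$predict
      for (c in seq_len(maxComp))
        press[c] <- press[c] +
          sum((pr[, 1, min(c, nc)] - y[hold])^2)
    }
    ev <- 1 - press[, 1] / sst
  }
  gains <- diff(c(0, ev))
  ncomp <- 1L
  while (ncomp < maxComp && gains[ncomp + 1L] >= minGain)
    ncomp <- ncomp + 1L
  fit <- mixOmics::pls(X, matrix(y, ncol = 1), ncomp = ncomp,
                       mode = "regression")
  new("SMCModel", family = "PLSR", fit = fit,
      hyper = list(ncomp = ncomp, cvExplainedVar = ev),
      scaling = list(), featureNames = colnames(X))
}

# --- single-hidden-layer tanh network, batch quasi-Newton (BFGS) ----------

bpnnPack <- function(W1, w2) c(as.vector(W1), w2)
bpnnUnpack <- function(par, p, h) {
  list(W1 = matrix(par[seq_len((p + 1) * h)], p + 1, h),
       w2 = par[(p + 1) * h + seq_len(h + 1)])
}

bpnnForward <- function(par, X, p, h) {
  w <- bpnnUnpack(par, p, h)
  H <- tanh(cbind(1, X) %*% w$W1)
  as.vector(cbind(1, H) %*% w$w2)
}

bpnnObjective <- function(par, X, y, p, h, decay) {
  w <- bpnnUnpack(par, p, h)
  H <- tanh(cbind(1, X) %*% w$W1)
  e <- as.vector(cbind(1, H) %*% w$w2) - y
  0.5 * mean(e^2) + 0.5 * decay * (sum(w$W1^2) + sum(w$w2^2))
}

bpnnGradient <- function(par, X, y, p, h, decay) {
  w <- bpnnUnpack(par, p, h)
  X1 <- cbind(1, X)
  A <- X1 %*% w$W1
  H <- tanh(A)
  H1 <- cbind(1, H)
  e <- (as.vector(H1 %*% w$w2) - y) / length(y)
  gw2 <- as.vector(crossprod(H1, e)) + decay * w$w2
  dH <- (e %o% w$w2[-1]) * (1 - H^2)
  gW1 <- crossprod(X1, dH) + decay * w$W1
  bpnnPack(gW1, gw2)
}

bpnnTrain <- function(X, y, h, decay, maxit, restarts, seed) {
  p <- ncol(X)
  best <- NULL
  for (rs in seq_len(restarts)) {
    par0 <- withSeed(fanSeed(seed, rs), {
      c(runif((p + 1) * h, -0.7, 0.7) / sqrt(p + 1),
        runif(h + 1, -0.7, 0.7) / sqrt(h + 1))
    })
    opt <- try(optim(par0,
                     function(w) bpnnObjective(w, X, y, p, h, decay),
                     function(w) bpnnGradient(w, X, y, p, h, decay),
                     method = "BFGS",
                     control = list(maxit = maxit, reltol = 1e-8)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("BPNN failed to converge after ", restarts,
                          " restarts")
  best
}

#' Fit the BPNN SMC model
#'
#' Single hidden layer with tanh activation, trained by batch BFGS
#' (quasi-Newton) with weight decay; multiple random restarts, the best
#' kept. The hidden-layer size is selected over `hiddenGrid` (default 10
#' to 100 in steps of five) by fold-averaged cross-validated RMSE. The
#' response is standardized internally and back-transformed at prediction.
#'
#' @param X standardized training predictors.
#' @param y training SMC.
#' @param folds named fold assignment over the training rows.
#' @param hiddenGrid candidate hidden-layer sizes.
#' @param decay L2 weight-decay strength.
#' @param maxit BFGS iteration cap for the final fit (the CV fits use
#'   `maxit / 3`).
#' @param restarts random restarts for the final fit (CV uses 1).
#' @param seed RNG seed.
#' @return an [SMCModel-class].
#' @export
fitBpnn <- function(X, y, folds, hiddenGrid = seq(10L, 100L, by = 5L),
                    decay = 1e-3, maxit = 300L, restarts = 5L, seed = 1L) {
  yc <- mean(y); ys <- sd(y)
  if (ys == 0) ys <- 1
  yz <- (y - yc) / ys
  cvRmse <- sapply(hiddenGrid, function(h) {
    errs <- 0; nTot <- 0
    for (f in unique(folds)) {
      hold <- names(folds)[folds == f]
      keep <- setdiff(names(folds), hold)
      fit <- bpnnTrain(X[keep, , drop = FALSE], yz[keep], h, decay,
                       maxit = max(40L, maxit %/% 5L), restarts = 1L,
                       seed = fanSeed(seed, h * 100 + f))
      pr <- bpnnForward(fit$par, X[hold, , drop = FALSE], ncol(X), h)
      errs <- errs + sum((pr - yz[hold])^2)
      nTot <- nTot + length(hold)
    }
    sqrt(errs / nTot)
  })
  hidden <- hiddenGrid[order(cvRmse, hiddenGrid)][1]
  fit <- bpnnTrain(X, yz, hidden, decay, maxit, restarts,
                   seed = fanSeed(seed, 7))
  new("SMCModel", family = "BPNN", fit = fit,
      hyper = list(hidden = hidden, decay = decay,
                   optimizer = "BFGS (quasi-Newton, batch)",
                   cvRmse = setNames(cvRmse, hiddenGrid)),
      scaling = list(yCenter = yc, yScale = ys),
      featureNames = colnames(X))
}

#' Fit one model family
#'
#' @param family `"RF"`, `"PLSR"` or `"BPNN"`.
#' @param X standardized training predictors.
#' @param y training SMC.
#' @param folds fold assignment (hyperparameter CV).
#' @param seed RNG seed.
#' @param modelParams optional list of family-specific overrides passed to
#'   [fitRf()], [fitPlsr()] or [fitBpnn()].
#' @return an [SMCModel-class].
#' @export
fitModel <- function(family, X, y, folds, seed = 1L, modelParams = list()) {
  args <- switch(family,
    RF = c(list(X = X, y = y, seed = seed), modelParams),
    PLSR = c(list(X = X, y = y, folds = folds), modelParams),
    BPNN = c(list(X = X, y = y, folds = folds, seed = seed), modelParams),
    stop("unknown model family '", family, "'"))
  do.call(switch(family, RF = fitRf, PLSR = fitPlsr, BPNN = fitBpnn), args)
}

#' Predict SMC from a fitted model
#'
#' @param object an [SMCModel-class].
#' @param newX standardized predictor matrix (same columns/scaling as
#'   training).
#' @return numeric predictions in SMC units.
#' @export
predictSMC <- function(object, newX) {
  newX <- newX[, object@featureNames, drop = FALSE]
  switch(object@family,
    RF = as.vector(predict(object@fit, newX)),
    PLSR = {
      pr <- predict(object@fit, newX)$predict
      as.vector(pr[, 1, dim(pr)[3]])
    },
    BPNN = {
      h <- object@hyper$hidden
      z <- bpnnForward(object@fit$par, newX, ncol(newX), h)
      z * object@scaling$yScale + object@scaling$yCenter
    })
}

#' Validation metrics of an SMC model
#'
#' `R2 = 1 - SSE/SST` on the validation set, `RMSE` in SMC units, and
#' `MRE = mean(|pred - obs| / obs) * 100` percent.
#'
#' @param pred predicted SMC.
#' @param obs observed SMC (all > 0 for MRE).
#' @return list with `R2`, `RMSE`, `MRE`; `R2` is `NA` (undefined) when
#'   the observed variance is zero.
#' @export
evaluatePredictions <- function(pred, obs) {
  stopifnot(length(pred) == length(obs), length(obs) > 0)
  sse <- sum((pred - obs)^2)
  sst <- sum((obs - mean(obs))^2)
  list(R2 = if (sst > 0) 1 - sse / sst else NA_real_,
       RMSE = sqrt(mean((pred - obs)^2)),
       MRE = mean(abs(pred - obs) / obs) * 100)
}
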