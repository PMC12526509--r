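#' The seven model-input combinations
#'
#' The non-empty subsets of the three feature groups: 1 = raw texture
#' features, 2 = 2-D texture indices, 3 = 3-D texture indices, 4 = raw +
#' 2-D, 5 = raw + 3-D, 6 = 2-D + 3-D, 7 = raw + 2-D + 3-D.
#'
#' @param id combination id 1..7 (vectorized).
#' @return list of character vectors of group names
#'   (`raw`, `idx2d`, `idx3d`).
#' @export
combinationMembers <- function(id = 1:7) {
  defs <- list(`1` = "raw", `2` = "idx2d", `3` = "idx3d",
               `4` = c("raw", "idx2d"), `5` = c("raw", "idx3d"),
               `6` = c("idx2d", "idx3d"), `7` = c("raw", "idx2d", "idx3d"))
  if (any(!id %in% 1:7)) stop("combination id must be in 1..7")
  defs[as.character(id)]
}

#' Assemble a combination's feature labels from screened survivors
#'
#' Union of the surviving feature labels of the member groups,
#' deduplicated, in deterministic (group, keep) order.
#'
#' @param screen a [DepthScreen-class].
#' @param id combination id 1..7.
#' @return character vector of feature labels.
#' @export
assembleCombination <- function(screen, id) {
  members <- combinationMembers(id)[[1]]
  labels <- unique(unlist(screen@survivorList[members], use.names = FALSE))
  if (length(labels) == 0L)
    stop("combination ", id, " is empty for depth ", screen@depthLayer,
         " (no surviving features)")
  labels
}

#' Run the depth x combination x model evaluation grid
#'
#' For each requested depth layer: builds the stratified 2:1
#' train/validation split, screens features (on training rows only in
#' `"strict"` leakage mode; on all plots in `"paper"` mode, which screens
#' before splitting), assembles the requested input combinations, fits
#' each model family on standardized training data (hyperparameters by
#' 10-fold CV within the training set) and evaluates on the validation
#' set. A failing cell is flagged, never fatal — the grid always
#' completes.
#'
#' @param te a [TextureExperiment-class].
#' @param seed pipeline seed, fanned out deterministically to split, RF
#'   and BPNN.
#' @param depths depth layers (default: all in `te`).
#' @param combinations combination ids (default 1:7).
#' @param models model families (default RF, PLSR, BPNN).
#' @param mode `"strict"` (default) or `"paper"` leakage handling.
#' @param cells optional data.frame with columns `combination` and `model`
#'   selecting specific grid cells; overrides `combinations`/`models`.
#' @param modelParams named list of per-family override lists.
#' @param screenParams list of overrides for [screenDepth()].
#' @return list with `records` (data.frame: depth_layer, combination,
#'   model, nFeatures, R2, RMSE, MRE, flag), `predictions` (long
#'   data.frame of validation predictions) and `screens` (per-depth
#'   [DepthScreen-class]).
#' @export
runGrid <- function(te, seed = 1L, depths = depthLayers(te),
                    combinations = 1:7,
                    models = c("RF", "PLSR", "BPNN"),
                    mode = c("strict", "paper"), cells = NULL,
                    modelParams = list(), screenParams = list()) {
  mode <- match.arg(mode)
  if (is.null(cells))
    cells <- expand.grid(combination = combinations, model = models,
                         stringsAsFactors = FALSE)
  X <- positionMatrix(te)
  records <- list(); preds <- list(); screens <- list()
  for (di in seq_along(depths)) {
    depth <- depths[di]
    y <- smcValues(te, depth)
    split <- makeSplit(y, seed = fanSeed(seed, di))
    screenIds <- if (mode == "strict") split$trainIds else rownames(X)
    screen <- do.call(screenDepth, c(
      list(X = X, y = y, screenIds = screenIds, depthLayer = depth),
      screenParams))
    screens[[depth]] <- screen
    feat <- screenedFeatures(screen)
    for (cid in unique(cells$combination)) {
      labels <- try(assembleCombination(screen, cid), silent = TRUE)
      for (fam in cells$model[cells$combination == cid]) {
        rec <- data.frame(depth_layer = depth, combination = cid,
                          model = fam, nFeatures = NA_integer_,
                          R2 = NA_real_, RMSE = NA_real_, MRE = NA_real_,
                          flag = "", stringsAsFactors = FALSE)
        out <- try({
          if (inherits(labels, "try-error")) stop(attr(labels, "condition"))
          Fc <- feat[, labels, drop = FALSE]
          ok <- complete.cases(Fc)
          trainIds <- intersect(split$trainIds, rownames(Fc)[ok])
          valIds <- intersect(split$validationIds, rownames(Fc)[ok])
          std <- foldStandardize(Fc[trainIds, , drop = FALSE],
                                 Fc[valIds, , drop = FALSE])
          model <- fitModel(fam, std$train, y[trainIds],
                            folds = split$folds[trainIds],
                            seed = fanSeed(seed, di * 100 + cid),
                            modelParams = modelParams[[fam]] %||% list())
          pr <- predictSMC(model, std$applied)
          m <- evaluatePredictions(pr, y[valIds])
          rec$nFeatures <- ncol(std$train)
          rec$R2 <- m$R2; rec$RMSE <- m$RMSE; rec$MRE <- m$MRE
          preds[[length(preds) + 1L]] <- data.frame(
            depth_layer = depth, combination = cid, model = fam,
            plot_id = valIds, observed = unname(y[valIds]),
            predicted = pr, stringsAsFactors = FALSE)
          NULL
        }, silent = TRUE)
        if (inherits(out, "try-error"))
          rec$flag <- conditionMessage(attr(out, "condition"))
        records[[length(records) + 1L]] <- rec
      }
    }
  }
  list(records = do.call(rbind, records),
       predictions = if (length(preds)) do.call(rbind, preds) else NULL,
       screens = screens)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Relative R-squared improvement of the fused input over raw textures
#'
#' `100 * (R2_c7 - R2_c1) / R2_c1` per depth for one model family.
#'
#' @param records the `records` table of [runGrid()].
#' @param model model family (default `"RF"`).
#' @return data.frame with `depth_layer` and `improvementPct`.
#' @export
relativeImprovement <- function(records, model = "RF") {
  sub <- records[records$model == model & records$combination %in% c(1, 7), ]
  out <- lapply(split(sub, sub$depth_layer), function(d) {
    r1 <- d$R2[d$combination == 1]; r7 <- d$R2[d$combination == 7]
    data.frame(depth_layer = d$depth_layer[1],
               improvementPct = 100 * (r7 - r1) / r1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Observed-vs-predicted scatter data with least-squares fit
#'
#' For each depth x model x combination cell, returns the plot-ready
#' validation scatter plus the least-squares slope/intercept (the 1:1 line
#' is the reference).
#'
#' @param predictions the `predictions` table of [runGrid()].
#' @param combinations combinations to report (default 1 and 7).
#' @return list with `points` (the filtered prediction rows) and `fits`
#'   (data.frame of slope/intercept per cell).
#' @export
scatterReport <- function(predictions, combinations = c(1, 7)) {
  pts <- predictions[predictions$combination %in% combinations, ]
  cells <- split(pts, interaction(pts$depth_layer, pts$model,
                                  pts$combination, drop = TRUE))
  fits <- do.call(rbind, lapply(cells, function(d) {
    b <- cov(d$observed, d$predicted) / var(d$observed)
    a <- mean(d$predicted) - b * mean(d$observed)
    data.frame(depth_layer = d$depth_layer[1], model = d$model[1],
               combination = d$combination[1], slope = b, intercept = a,
               stringsAsFactors = FALSE)
  }))
  rownames(fits) <- NULL
  list(points = pts, fits = fits)
}

#' Run the full pipeline on a synthetic or loaded dataset
#'
#' Convenience orchestration: generate (or accept) a dataset, apply the
#' vegetation mask, compute the 48 plot textures, build the
#' [TextureExperiment-class] and run the evaluation grid. Stage outputs
#' are written as CSV when `outDir` is given.
#'
#' @param config a [SyntheticConfig-class] (ignored when `dataset` given).
#' @param dataset optional result of [generateDataset()]/[loadDataset()].
#' @param seed pipeline seed.
#' @param remask re-derive the vegetation mask with [vegetationMask()]
#'   (Otsu tau) instead of trusting the dataset's mask (default TRUE).
#' @param outDir optional output directory for CSV results.
#' @param ... passed to [runGrid()].
#' @return the [runGrid()] result, plus `te`.
#' @export
runPipeline <- function(config = syntheticConfig(), dataset = NULL,
                        seed = config@seed, remask = TRUE,
                        outDir = NULL, ...) {
  if (is.null(dataset)) dataset <- generateDataset(config)
  plots <- dataset$plots
  if (remask)
    plots <- suppressMessages(lapply(plots, vegetationMask))
  features <- computeTextures(plots)
  te <- textureExperiment(features, dataset$smc)
  res <- runGrid(te, seed = seed, ...)
  res$te <- te
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    write.csv(res$records, file.path(outDir, "records.csv"),
              row.names = FALSE)
    if (!is.null(res$predictions))
      write.csv(res$predictions, file.path(outDir, "predictions.csv"),
                row.names = FALSE)
    write.csv(screenSummary(res$screens),
              file.path(outDir, "screening.csv"), row.names = FALSE)
  }
  res
}
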