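#' @include AllGenerics.R
NULL

#' Canonical band order of the six-band multispectral camera
#'
#' Band1-Band6 are blue (450 nm), green (555 nm), red (660 nm),
#' red-edge (720 nm), red-edge (750 nm) and NIR (840 nm).
#'
#' @export
BAND_NAMES <- c("blue", "green", "red", "RE720", "RE750", "NIR")

#' The eight GLCM texture metrics
#'
#' Mean, variance, homogeneity, contrast, dissimilarity, entropy,
#' second moment (angular second moment / energy) and correlation.
#'
#' @export
GLCM_METRICS <- c("MEA", "VAR", "HOM", "CON", "DIS", "ENT", "SEC", "COR")

#' Depth-layer labels of the soil profile (cm)
#' @export
DEPTH_LAYERS <- c("0-20", "20-40", "40-60")

# ---------------------------------------------------------------------------
# SyntheticConfig
# ---------------------------------------------------------------------------

#' Configuration of the synthetic canopy / SMC generator
#'
#' Defines the study conditions the generator emulates: number of plots,
#' image size, volumetric SMC range (percent), texture-moisture coupling
#' per depth layer, inter-layer SMC autocorrelation and sensor noise.
#'
#' @slot nPlots number of plots (default 96).
#' @slot plotPx pixels per plot side (default 64).
#' @slot nBands number of spectral bands (fixed 6).
#' @slot depthLayerLabels ordered depth-layer labels.
#' @slot smcRange lower/upper volumetric SMC bounds in percent.
#' @slot depthCoupling per-layer texture-SMC coupling strength in \[0,1\],
#'   non-increasing with depth; element 1 is the gain used by the image
#'   generator, deeper elements are realized through the AR(1) depth chain.
#' @slot depthAutocorr AR(1) coefficient linking SMC across layers, in \[0,1).
#' @slot noiseSd per-band additive sensor noise (reflectance units).
#' @slot gapProb Bernoulli rate of soil-gap seeds (dilated 3x3) in the mask.
#' @slot baseReflectance per-band canopy reflectance baseline.
#' @slot bandGain per-band gain of the heterogeneity field (NIR/red-edge
#'   strongest).
#' @slot soilReflectance per-band reflectance of soil-gap pixels.
#' @slot betaRange spectral-slope range of the Gaussian random field mapped
#'   over the SMC range (wetter = steeper slope = smoother canopy).
#' @slot fieldScale reflectance amplitude of the heterogeneity field.
#' @slot seed RNG seed.
#' @export
setClass("SyntheticConfig",
  representation(
    nPlots = "integer", plotPx = "integer", nBands = "integer",
    depthLayerLabels = "character", smcRange = "numeric",
    depthCoupling = "numeric", depthAutocorr = "numeric",
    noiseSd = "numeric", gapProb = "numeric",
    baseReflectance = "numeric", bandGain = "numeric",
    soilReflectance = "numeric", betaRange = "numeric",
    fieldScale = "numeric", seed = "integer"
  )
)

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@nPlots < 10L) msg <- c(msg, "nPlots must be >= 10")
  if (object@plotPx < 16L)
    msg <- c(msg, "plotPx must be >= 16 (windowed textures need interior pixels)")
  if (object@nBands != 6L) msg <- c(msg, "nBands is fixed at 6")
  if (length(object@smcRange) != 2L || diff(object@smcRange) <= 0)
    msg <- c(msg, "smcRange must be increasing bounds")
  if (length(object@depthCoupling) != length(object@depthLayerLabels))
    msg <- c(msg, "depthCoupling needs one value per depth layer")
  if (any(object@depthCoupling < 0 | object@depthCoupling > 1))
    msg <- c(msg, "depthCoupling values must lie in [0, 1]")
  if (any(diff(object@depthCoupling) > 1e-12))
    msg <- c(msg, "depthCoupling must be non-increasing with depth")
  if (object@depthAutocorr < 0 || object@depthAutocorr >= 1)
    msg <- c(msg, "depthAutocorr must lie in [0, 1)")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  for (s in c("baseReflectance", "bandGain", "soilReflectance"))
    if (length(slot(object, s)) != 6L) msg <- c(msg, paste(s, "needs 6 values"))
  if (length(msg)) msg else TRUE
})

#' @describeIn SyntheticConfig constructor with the default study conditions
#'   (96 plots x 3 depth layers, 64 px plots, SMC 10-30 % volumetric).
#' @param nPlots,plotPx,smcRange,depthCoupling,depthAutocorr,noiseSd,gapProb
#'   see slots.
#' @param baseReflectance,bandGain,soilReflectance,betaRange,fieldScale,seed
#'   see slots.
#' @export
syntheticConfig <- function(nPlots = 96L, plotPx = 64L,
                            smcRange = c(10, 30),
                            depthAutocorr = 0.6,
                            depthCoupling = c(1, depthAutocorr,
                                              depthAutocorr^2),
                            noiseSd = 0.01, gapProb = 0.015,
                            baseReflectance = c(0.05, 0.09, 0.05,
                                                0.25, 0.35, 0.45),
                            bandGain = c(0.3, 0.4, 0.3, 0.8, 0.9, 1.0),
                            soilReflectance = c(0.12, 0.18, 0.30,
                                                0.33, 0.36, 0.38),
                            betaRange = c(1.2, 3.2),
                            fieldScale = 0.05, seed = 1L) {
  new("SyntheticConfig",
      nPlots = as.integer(nPlots), plotPx = as.integer(plotPx),
      nBands = 6L, depthLayerLabels = DEPTH_LAYERS,
      smcRange = as.numeric(smcRange),
      depthCoupling = as.numeric(depthCoupling),
      depthAutocorr = as.numeric(depthAutocorr),
      noiseSd = as.numeric(noiseSd), gapProb = as.numeric(gapProb),
      baseReflectance = as.numeric(baseReflectance),
      bandGain = as.numeric(bandGain),
      soilReflectance = as.numeric(soilReflectance),
      betaRange = as.numeric(betaRange),
      fieldScale = as.numeric(fieldScale), seed = as.integer(seed))
}

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig:", object@nPlots, "plots,",
      object@plotPx, "x", object@plotPx, "px, 6 bands\n")
  cat("  SMC range [% vol]:", paste(object@smcRange, collapse = "-"),
      " depth coupling:", paste(round(object@depthCoupling, 3), collapse = "/"),
      " rho:", object@depthAutocorr, "\n")
  cat("  noise sd:", object@noiseSd, " seed:", object@seed, "\n")
})

# ---------------------------------------------------------------------------
# ReflectancePlot
# ---------------------------------------------------------------------------

#' Six-band reflectance grid of one plot with vegetation mask
#'
#' @slot plotId plot label.
#' @slot pixels rows x cols x 6 array of reflectance (unitless, 0-1), band
#'   order blue, green, red, RE720, RE750, NIR.
#' @slot mask logical rows x cols grid, `TRUE` = vegetation.
#' @slot pixelSize metres per pixel (metadata only).
#' @export
setClass("ReflectancePlot",
  representation(plotId = "character", pixels = "array",
                 mask = "matrix", pixelSize = "numeric"))

setValidity("ReflectancePlot", function(object) {
  msg <- character()
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 6L)
    msg <- c(msg, "pixels must be a rows x cols x 6 array")
  if (!identical(dim(object@mask), d[1:2]))
    msg <- c(msg, "mask dimensions must match the pixel grid")
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (any(!is.finite(object@pixels)))
    msg <- c(msg, "reflectance values must be finite")
  if (length(msg)) msg else TRUE
})

#' @describeIn ReflectancePlot constructor; negative reflectance is clipped
#'   to zero with a warning (sensor-noise tolerance).
#' @param plotId,pixels,mask,pixelSize see slots.
#' @export
reflectancePlot <- function(plotId, pixels,
                            mask = matrix(TRUE, dim(pixels)[1], dim(pixels)[2]),
                            pixelSize = NA_real_) {
  if (any(pixels < 0, na.rm = TRUE)) {
    warning("negative reflectance clipped to 0 in plot ", plotId)
    pixels[pixels < 0] <- 0
  }
  new("ReflectancePlot", plotId = as.character(plotId), pixels = pixels,
      mask = mask, pixelSize = pixelSize)
}

#' @rdname reflectance
#' @export
setMethod("reflectance", "ReflectancePlot", function(x) x@pixels)

#' @rdname reflectance
#' @export
setMethod("vegMask", "ReflectancePlot", function(x) x@mask)

#' @rdname reflectance
#' @export
setMethod("plotId", "ReflectancePlot", function(x) x@plotId)

setMethod("show", "ReflectancePlot", function(object) {
  d <- dim(object@pixels)
  cat("ReflectancePlot", object@plotId, ":", d[1], "x", d[2],
      "px, 6 bands;", sprintf("%.1f%% vegetation\n",
                              100 * mean(object@mask)))
})

# ---------------------------------------------------------------------------
# GLCMParams
# ---------------------------------------------------------------------------

#' GLCM computation parameters
#'
#' Defaults follow the fixed texture protocol: 64 gray levels, 5 x 5 moving
#' window, one-pixel offset, four directions (0/45/90/135 degrees) averaged.
#'
#' @slot grayLevels gray-level quantization depth G.
#' @slot window moving-window side length (odd).
#' @slot offset pixel offset of the co-occurrence pair.
#' @slot directions direction angles in degrees.
#' @slot symmetric logical; pairs accumulated in both orders.
#' @slot minWindowValidFrac minimum fraction of valid (masked-in) pixels for
#'   a window to enter the plot aggregate.
#' @slot percentileClip lower/upper percentiles used to scale a band before
#'   quantization (guards against hot pixels).
#' @slot scalingMode `"perimage"` (percentile clip per band per plot) or
#'   `"global"` (fixed per-band ranges for cross-flight comparability).
#' @slot globalRange 6 x 2 matrix of per-band min/max for `"global"` mode.
#' @export
setClass("GLCMParams",
  representation(grayLevels = "integer", window = "integer",
                 offset = "integer", directions = "numeric",
                 symmetric = "logical", minWindowValidFrac = "numeric",
                 percentileClip = "numeric", scalingMode = "character",
                 globalRange = "matrix"))

setValidity("GLCMParams", function(object) {
  msg <- character()
  if (object@grayLevels < 2L) msg <- c(msg, "grayLevels must be >= 2")
  if (object@window %% 2L == 0L || object@window < 3L)
    msg <- c(msg, "window must be odd and >= 3")
  if (object@offset < 1L) msg <- c(msg, "offset must be >= 1")
  if (!all(object@directions %in% c(0, 45, 90, 135)))
    msg <- c(msg, "directions must be a subset of 0/45/90/135")
  if (!object@scalingMode %in% c("perimage", "global"))
    msg <- c(msg, "scalingMode must be 'perimage' or 'global'")
  if (length(msg)) msg else TRUE
})

#' @describeIn GLCMParams constructor.
#' @param grayLevels,window,offset,directions,symmetric,minWindowValidFrac
#'   see slots.
#' @param percentileClip,scalingMode,globalRange see slots.
#' @export
glcmParams <- function(grayLevels = 64L, window = 5L, offset = 1L,
                       directions = c(0, 45, 90, 135), symmetric = TRUE,
                       minWindowValidFrac = 0.6,
                       percentileClip = c(0.01, 0.99),
                       scalingMode = "perimage",
                       globalRange = matrix(c(rep(0, 6), rep(1, 6)), 6, 2)) {
  new("GLCMParams", grayLevels = as.integer(grayLevels),
      window = as.integer(window), offset = as.integer(offset),
      directions = directions, symmetric = symmetric,
      minWindowValidFrac = minWindowValidFrac,
      percentileClip = percentileClip, scalingMode = scalingMode,
      globalRange = globalRange)
}

setMethod("show", "GLCMParams", function(object) {
  cat("GLCMParams: G =", object@grayLevels, ", window",
      object@window, "x", object@window, ", offset", object@offset,
      ", directions", paste(object@directions, collapse = "/"), "\n")
})

# ---------------------------------------------------------------------------
# TextureExperiment
# ---------------------------------------------------------------------------

#' Plots-by-features container aligned to per-depth SMC
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass: the
#' `"textures"` assay holds features (rows) by plots (columns); `colData`
#' carries one volumetric-SMC column (percent) per depth layer, named
#' `smc_<layer>`.
#'
#' @export
#' @import SummarizedExperiment
setClass("TextureExperiment", contains = "SummarizedExperiment")

setValidity("TextureExperiment", function(object) {
  msg <- character()
  if (!"textures" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'textures' is required")
  if (!any(grepl("^smc_", colnames(SummarizedExperiment::colData(object)))))
    msg <- c(msg, "colData must carry smc_<layer> columns")
  if (length(msg)) msg else TRUE
})

#' Build a TextureExperiment from a feature table and an SMC table
#'
#' @param features data.frame with a `plot_id` column plus one numeric column
#'   per feature (e.g. the 48 position labels), one row per plot.
#' @param smc long-format data.frame with columns `plot_id`, `depth_layer`
#'   (one of `"0-20"`, `"20-40"`, `"40-60"`) and `smc` (volumetric %).
#' @return a [TextureExperiment-class].
#' @export
textureExperiment <- function(features, smc) {
  stopifnot("plot_id" %in% names(features),
            all(c("plot_id", "depth_layer", "smc") %in% names(smc)))
  ids <- as.character(features$plot_id)
  mat <- t(as.matrix(features[setdiff(names(features), "plot_id")]))
  colnames(mat) <- ids
  layers <- unique(as.character(smc$depth_layer))
  cd <- S4Vectors::DataFrame(row.names = ids)
  for (lay in layers) {
    sub <- smc[smc$depth_layer == lay, ]
    v <- setNames(sub$smc, as.character(sub$plot_id))[ids]
    cd[[paste0("smc_", lay)]] <- as.numeric(v)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(textures = mat), colData = cd)
  new("TextureExperiment", se)
}

#' @rdname positionMatrix
#' @export
setMethod("positionMatrix", "TextureExperiment", function(x)
  t(SummarizedExperiment::assay(x, "textures")))

#' @rdname positionMatrix
#' @export
setMethod("depthLayers", "TextureExperiment", function(x) {
  nm <- colnames(SummarizedExperiment::colData(x))
  sub("^smc_", "", nm[grepl("^smc_", nm)])
})

#' @rdname positionMatrix
#' @export
setMethod("smcValues", "TextureExperiment", function(x, layer) {
  col <- paste0("smc_", layer)
  cd <- SummarizedExperiment::colData(x)
  if (!col %in% colnames(cd))
    stop("no SMC recorded for depth layer '", layer, "'")
  setNames(cd[[col]], rownames(cd))
})

# ---------------------------------------------------------------------------
# ScreenResult / DepthScreen
# ---------------------------------------------------------------------------

#' Result of an exhaustive correlation search for one index family
#'
#' @slot depthLayer depth-layer label.
#' @slot family index family name, or `"raw"` for single positions.
#' @slot bestLabel label of the maximum-|r| combination.
#' @slot r Pearson correlation of the best combination with SMC.
#' @slot p two-sided p-value of `r`.
#' @slot candidates data.frame of retained combinations (label, r, p, n).
#' @slot nSearched size of the searched tuple space.
#' @export
setClass("ScreenResult",
  representation(depthLayer = "character", family = "character",
                 bestLabel = "character", r = "numeric", p = "numeric",
                 candidates = "data.frame", nSearched = "numeric"))

setMethod("show", "ScreenResult", function(object) {
  cat(sprintf("ScreenResult [%s, %s]: best %s  r = %.3f (p = %.3g)  over %s tuples\n",
              object@depthLayer, object@family, object@bestLabel,
              object@r, object@p, format(object@nSearched, big.mark = ",")))
})

#' Full screening state of one depth layer
#'
#' Holds the per-family search results, the survivor labels per feature
#' group after significance, redundancy and VIF filtering, and the survivor
#' feature values for all plots (screening statistics themselves are
#' computed only on the screening rows).
#'
#' @slot depthLayer depth-layer label.
#' @slot results named list of [ScreenResult-class] (raw + index families).
#' @slot survivorList named list (`raw`, `idx2d`, `idx3d`) of label vectors.
#' @slot features plots x survivors numeric matrix (all plots).
#' @slot screenIds plot ids the screening statistics were computed on.
#' @export
setClass("DepthScreen",
  representation(depthLayer = "character", results = "list",
                 survivorList = "list", features = "matrix",
                 screenIds = "character"))

#' @rdname survivors
#' @export
setMethod("survivors", "DepthScreen", function(x, group = NULL) {
  if (is.null(group)) unique(unlist(x@survivorList, use.names = FALSE))
  else x@survivorList[[group]]
})

#' @rdname survivors
#' @export
setMethod("screenedFeatures", "DepthScreen", function(x) x@features)

setMethod("show", "DepthScreen", function(object) {
  cat("DepthScreen", object@depthLayer, "- survivors:",
      paste(sprintf("%s=%d", names(object@survivorList),
                    lengths(object@survivorList)), collapse = ", "), "\n")
  for (r in object@results) show(r)
})

# ---------------------------------------------------------------------------
# SMCModel
# ---------------------------------------------------------------------------

#' A fitted SMC regression model
#'
#' @slot family `"RF"`, `"PLSR"` or `"BPNN"`.
#' @slot fit the underlying fitted object.
#' @slot hyper list of chosen hyperparameters (e.g. `ntree`, `ncomp`,
#'   `hidden`).
#' @slot scaling list with `center`/`scale` used to standardize predictors
#'   (and, for BPNN, the response).
#' @slot featureNames predictor labels in training order.
#' @export
setClass("SMCModel",
  representation(family = "character", fit = "ANY", hyper = "list",
                 scaling = "list", featureNames = "character"))

setMethod("show", "SMCModel", function(object) {
  h <- paste(names(object@hyper), unlist(lapply(object@hyper, paste,
             collapse = ",")), sep = "=", collapse = ", ")
  cat("SMCModel", object@family, "(", length(object@featureNames),
      "features );", h, "\n")
})
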