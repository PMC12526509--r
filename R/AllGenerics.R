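#' @import methods
#' @importFrom stats cor cov fft optim predict pt quantile
#'   rnorm runif sd setNames var complete.cases
#' @importFrom utils head read.csv write.csv
NULL

#' Reflectance pixel data of a plot
#'
#' @param x a [ReflectancePlot-class] object.
#' @return `reflectance()` returns the rows x cols x 6 reflectance array,
#'   `vegMask()` the logical vegetation mask, `plotId()` the plot label.
#' @export
setGeneric("reflectance", function(x) standardGeneric("reflectance"))

#' @rdname reflectance
#' @export
setGeneric("vegMask", function(x) standardGeneric("vegMask"))

#' @rdname reflectance
#' @export
setGeneric("plotId", function(x) standardGeneric("plotId"))

#' Plots-by-features matrix of a TextureExperiment
#'
#' @param x a [TextureExperiment-class] object.
#' @param layer a depth-layer label (`"0-20"`, `"20-40"` or `"40-60"`).
#' @return `positionMatrix()` returns the plots x 48 position matrix;
#'   `smcValues()` the per-plot SMC vector (volumetric %) of one depth layer;
#'   `depthLayers()` the available layer labels.
#' @export
setGeneric("positionMatrix", function(x) standardGeneric("positionMatrix"))

#' @rdname positionMatrix
#' @export
setGeneric("smcValues", function(x, layer) standardGeneric("smcValues"))

#' @rdname positionMatrix
#' @export
setGeneric("depthLayers", function(x) standardGeneric("depthLayers"))

#' Survivor features of a depth screen
#'
#' @param x a [DepthScreen-class] object.
#' @param group one of `"raw"`, `"idx2d"`, `"idx3d"`, or `NULL` for all.
#' @return `survivors()` returns surviving feature labels;
#'   `screenedFeatures()` the plots x survivors value matrix.
#' @export
setGeneric("survivors", function(x, group = NULL) standardGeneric("survivors"))

#' @rdname survivors
#' @export
setGeneric("screenedFeatures", function(x) standardGeneric("screenedFeatures"))
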