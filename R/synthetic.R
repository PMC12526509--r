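#' Gaussian random field via spectral (FFT) synthesis
#'
#' White noise filtered in the Fourier domain by a power-law spectrum
#' `|f|^(-beta/2)`; larger `beta` shifts power to low frequencies, giving a
#' smoother field. Output is normalized to zero mean, unit variance.
#'
#' @param n side length in pixels.
#' @param beta spectral slope (>= 0).
#' @return n x n numeric matrix.
#' @keywords internal
grfField <- function(n, beta) {
  w <- matrix(rnorm(n * n), n, n)
  half <- n %/% 2L
  fx <- c(0:half, if (n - half - 1L > 0) -((n - half - 1L):1)) / n
  f <- sqrt(outer(fx^2, fx^2, "+"))
  filt <- ifelse(f == 0, 0, f^(-beta / 2))
  fld <- Re(fft(fft(w) * filt, inverse = TRUE)) / (n * n)
  fld <- fld - mean(fld)
  s <- sd(as.vector(fld))
  if (s > 0) fld <- fld / s
  fld
}

#' Simulate per-plot, per-depth volumetric SMC
#'
#' The shallow layer is uniform over `smcRange`; deeper layers follow a
#' first-order autoregressive chain over depth with coefficient
#' `depthAutocorr`, so they are correlated with, but not identical to, the
#' shallow layer. Values are clipped to `smcRange`.
#'
#' @param config a [SyntheticConfig-class].
#' @return data.frame with columns `plot_id`, `depth_layer`, `smc`
#'   (volumetric %), one row per plot per layer; deterministic given the
#'   config seed.
#' @export
generateSmc <- function(config) {
  validObject(config)
  lo <- config@smcRange[1]; hi <- config@smcRange[2]
  mid <- (lo + hi) / 2
  sdU <- (hi - lo) / sqrt(12)           # sd of the uniform shallow layer
  rho <- config@depthAutocorr
  nL <- length(config@depthLayerLabels)
  withSeed(config@seed, {
    s <- matrix(NA_real_, config@nPlots, nL)
    s[, 1] <- runif(config@nPlots, lo, hi)
    for (d in seq_len(nL - 1L) + 1L) {
      eps <- rnorm(config@nPlots, 0, sdU * sqrt(1 - rho^2))
      s[, d] <- mid + rho * (s[, d - 1L] - mid) + eps
    }
    s <- pmin(pmax(s, lo), hi)
    data.frame(
      plot_id = rep(sprintf("P%03d", seq_len(config@nPlots)), times = nL),
      depth_layer = rep(config@depthLayerLabels, each = config@nPlots),
      smc = as.vector(s), stringsAsFactors = FALSE)
  })
}

#' Simulate the six-band canopy image of one plot
#'
#' The canopy is a smooth Gaussian random field whose spatial correlation
#' structure is a monotone function of shallow-layer SMC: wetter plots get a
#' steeper spectral slope (smoother, less contrasted canopy), emulating the
#' denser, more uniform canopies of well-watered wheat. Band-specific gains
#' make the NIR and red-edge bands respond most strongly. Soil gaps
#' (Bernoulli seeds dilated 3 x 3) carry soil reflectance and are excluded
#' from the vegetation mask. Independent per-band Gaussian noise of sd
#' `noiseSd` is added last.
#'
#' @param smcShallow shallow-layer SMC (volumetric %), within `smcRange`.
#' @param config a [SyntheticConfig-class].
#' @param plotSeed RNG seed of this plot.
#' @return a [ReflectancePlot-class]; bit-identical for identical
#'   `(smcShallow, config, plotSeed)`.
#' @export
generatePlotImage <- function(smcShallow, config, plotSeed) {
  validObject(config)
  lo <- config@smcRange[1]; hi <- config@smcRange[2]
  if (smcShallow < lo || smcShallow > hi)
    stop("smcShallow = ", smcShallow, " outside smcRange [", lo, ", ", hi, "]")
  n <- config@plotPx
  kappa <- config@depthCoupling[1]
  beta <- config@betaRange[1] +
    kappa * diff(config@betaRange) * (smcShallow - lo) / (hi - lo)
  withSeed(plotSeed, {
    fld <- grfField(n, beta)
    soil <- matrix(runif(n * n) < config@gapProb, n, n)
    soil <- EBImage::imageData(EBImage::dilate(
      EBImage::Image(soil * 1), EBImage::makeBrush(3, "box"))) > 0
    px <- array(0, c(n, n, 6))
    for (b in 1:6) {
      band <- config@baseReflectance[b] +
        config@bandGain[b] * config@fieldScale * fld
      band[soil] <- config@soilReflectance[b]
      if (config@noiseSd > 0)
        band <- band + rnorm(n * n, 0, config@noiseSd)
      px[, , b] <- pmin(pmax(band, 0), 1)
    }
    new("ReflectancePlot", plotId = "synthetic", pixels = px,
        mask = !soil, pixelSize = 0.022)
  })
}

#' Generate the full synthetic dataset
#'
#' One six-band image per plot (driven by its shallow-layer SMC) plus the
#' aligned SMC table. When `dir` is given, imagery is written as multipage
#' TIFF (bands 1-6 as float32 pages, the vegetation mask as page 7), SMC as
#' CSV (`plot_id,depth_layer,smc`), and a YAML manifest records every
#' config field so the dataset can be regenerated exactly.
#'
#' @param config a [SyntheticConfig-class].
#' @param dir optional output directory.
#' @return list with `plots` (list of [ReflectancePlot-class]), `smc`
#'   (data.frame) and `config`.
#' @export
generateDataset <- function(config = syntheticConfig(), dir = NULL) {
  validObject(config)
  smc <- generateSmc(config)
  shallow <- smc[smc$depth_layer == config@depthLayerLabels[1], ]
  plots <- vector("list", config@nPlots)
  for (i in seq_len(config@nPlots)) {
    p <- generatePlotImage(shallow$smc[i], config, fanSeed(config@seed, i))
    p@plotId <- shallow$plot_id[i]
    plots[[i]] <- p
  }
  names(plots) <- shallow$plot_id
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (p in plots) {
      path <- file.path(dir, paste0(plotId(p), ".tif"))
      pages <- lapply(1:6, function(b) reflectance(p)[, , b])
      pages <- c(pages, list(vegMask(p) * 1))
      ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 32L),
                silent = TRUE)
      if (inherits(ok, "try-error"))
        stop("failed to write imagery to '", path, "'")
    }
    write.csv(smc, file.path(dir, "smc.csv"), row.names = FALSE)
    yaml::write_yaml(configToList(config), file.path(dir, "manifest.yaml"))
  }
  list(plots = plots, smc = smc, config = config)
}

configToList <- function(config) {
  nm <- slotNames(config)
  out <- lapply(nm, function(s) {
    v <- slot(config, s)
    if (is.matrix(v)) as.vector(v) else v
  })
  names(out) <- nm
  out
}

#' Reload (or regenerate) a dataset from its manifest
#'
#' Reads the manifest, the SMC CSV and the per-plot TIFFs written by
#' [generateDataset()].
#'
#' @param dir dataset directory.
#' @return same structure as [generateDataset()].
#' @export
loadDataset <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  config <- do.call(syntheticConfig, man[c(
    "nPlots", "plotPx", "smcRange", "depthCoupling", "depthAutocorr",
    "noiseSd", "gapProb", "baseReflectance", "bandGain", "soilReflectance",
    "betaRange", "fieldScale", "seed")])
  smc <- read.csv(file.path(dir, "smc.csv"), stringsAsFactors = FALSE)
  ids <- unique(smc$plot_id)
  plots <- lapply(ids, function(id) {
    pages <- tiff::readTIFF(file.path(dir, paste0(id, ".tif")), all = TRUE)
    px <- simplify2array(pages[1:6])
    new("ReflectancePlot", plotId = id, pixels = px,
        mask = pages[[7]] > 0.5, pixelSize = 0.022)
  })
  names(plots) <- ids
  list(plots = plots, smc = smc, config = config)
}
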