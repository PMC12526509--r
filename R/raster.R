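#' Load a plot from a multiband reflectance raster
#'
#' Reads a multipage/multiband TIFF (>= 6 bands, band order configurable)
#' and clips it to a plot geometry. Geometries are either axis-aligned
#' rectangles — `list(plot_id =, row0 =, row1 =, col0 =, col1 =)`, 0-based,
#' half-open on pixel boundaries — or GeoJSON-style polygons in pixel
#' coordinates (`x` = column, `y` = row): the grid is cropped to the
#' polygon's bounding box and pixels whose centre falls outside the polygon
#' are masked out.
#'
#' @param rasterPath path to the TIFF.
#' @param geometry rectangle list (above), or a list with `plot_id` and
#'   `coordinates` (n x 2 matrix of polygon vertices), or a path to a
#'   GeoJSON file holding one Polygon feature.
#' @param bandOrder integer mapping from file band index to the canonical
#'   order blue, green, red, RE720, RE750, NIR.
#' @return a [ReflectancePlot-class] with an all-true provisional mask
#'   (polygon geometries mask exterior pixels).
#' @export
loadPlot <- function(rasterPath, geometry, bandOrder = 1:6) {
  pages <- tiff::readTIFF(rasterPath, all = TRUE)
  if (is.array(pages) || is.matrix(pages)) pages <- list(pages)
  # a page may itself carry multiple channels
  bands <- list()
  for (pg in pages) {
    if (length(dim(pg)) == 3L)
      for (k in seq_len(dim(pg)[3])) bands[[length(bands) + 1L]] <- pg[, , k]
    else bands[[length(bands) + 1L]] <- pg
  }
  if (length(bands) < max(bandOrder)) {
    missing <- BAND_NAMES[bandOrder > length(bands)]
    stop("raster '", rasterPath, "' has ", length(bands),
         " band(s); missing canonical band(s): ",
         paste(missing, collapse = ", "))
  }
  px <- simplify2array(bands[bandOrder])
  if (is.character(geometry) && length(geometry) == 1L)
    geometry <- readGeojsonPlot(geometry)
  if (!is.null(geometry$coordinates)) {
    clipPolygon(px, geometry)
  } else {
    r0 <- geometry$row0; r1 <- geometry$row1
    c0 <- geometry$col0; c1 <- geometry$col1
    nr <- dim(px)[1]; nc <- dim(px)[2]
    r0 <- max(r0, 0L); c0 <- max(c0, 0L)
    r1 <- min(r1, nr); c1 <- min(c1, nc)
    if (r1 <= r0 || c1 <= c0)
      stop("plot geometry '", geometry$plot_id,
           "' does not intersect the raster extent")
    reflectancePlot(geometry$plot_id,
                    px[(r0 + 1L):r1, (c0 + 1L):c1, , drop = FALSE])
  }
}

readGeojsonPlot <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = TRUE)
  feat <- if (!is.null(gj$features)) gj$features else gj
  geom <- if (!is.null(feat$geometry)) feat$geometry else feat
  coords <- geom$coordinates
  if (is.list(coords)) coords <- coords[[1]]
  if (length(dim(coords)) == 3L) coords <- coords[1, , ]
  pid <- feat$properties$plot_id
  if (is.null(pid)) pid <- "polygon"
  list(plot_id = as.character(pid)[1],
       coordinates = matrix(as.numeric(coords), ncol = 2))
}

clipPolygon <- function(px, geometry) {
  xy <- geometry$coordinates                  # x = col, y = row (pixel units)
  nr <- dim(px)[1]; nc <- dim(px)[2]
  c0 <- max(floor(min(xy[, 1])), 0); c1 <- min(ceiling(max(xy[, 1])), nc)
  r0 <- max(floor(min(xy[, 2])), 0); r1 <- min(ceiling(max(xy[, 2])), nr)
  if (r1 <= r0 || c1 <= c0)
    stop("plot geometry '", geometry$plot_id,
         "' does not intersect the raster extent")
  sub <- px[(r0 + 1L):r1, (c0 + 1L):c1, , drop = FALSE]
  rows <- (r0 + 1L):r1 - 0.5                  # pixel centres
  cols <- (c0 + 1L):c1 - 0.5
  ctr <- cbind(col = rep(cols, each = length(rows)),
               row = rep(rows, times = length(cols)))
  inside <- pracma::inpolygon(ctr[, "col"], ctr[, "row"], xy[, 1], xy[, 2])
  mask <- matrix(inside, length(rows), length(cols))
  if (!any(mask))
    stop("plot geometry '", geometry$plot_id, "' covers no pixel centre")
  reflectancePlot(geometry$plot_id, sub, mask = mask)
}

#' Read a rectangle-geometry table
#'
#' CSV with columns `plot_id, row0, row1, col0, col1` (0-based, half-open).
#'
#' @param path CSV path.
#' @return list of rectangle geometries usable with [loadPlot()].
#' @export
readPlotRectangles <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "row0", "row1", "col0", "col1")
  if (!all(need %in% names(tab)))
    stop("rectangle table must have columns ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i) as.list(tab[i, need]))
}

# spectral index registry used for vegetation masking; NDVI is the default
# NIR-based index (tau range 0.30-0.40 is conventional for NDVI masks)
spectralIndex <- function(px, name = "ndvi") {
  nir <- px[, , 6]; red <- px[, , 3]; green <- px[, , 2]
  switch(tolower(name),
         ndvi = (nir - red) / (nir + red),
         gndvi = (nir - green) / (nir + green),
         stop("unknown spectral index '", name, "'"))
}

#' Otsu threshold of a vegetation index, clamped to \[0.30, 0.40\]
#'
#' Minimum intra-class-variance threshold of the index histogram (256
#' candidate levels over the observed index range), clamped to the
#' conventional NDVI masking interval 0.30-0.40.
#'
#' @param plot a [ReflectancePlot-class].
#' @param indexName spectral index (default `"ndvi"`).
#' @param clampTo clamp interval for the selected threshold.
#' @return threshold tau.
#' @export
selectTau <- function(plot, indexName = "ndvi", clampTo = c(0.30, 0.40)) {
  idx <- spectralIndex(reflectance(plot), indexName)
  v <- idx[vegMask(plot)]
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) <= 0)
    stop("index '", indexName, "' is constant; cannot select tau")
  z <- (v - rng[1]) / diff(rng)
  t01 <- EBImage::otsu(EBImage::as.Image(matrix(z, nrow = 1)),
                       range = c(0, 1), levels = 256L)
  tau <- rng[1] + t01 * diff(rng)
  min(max(tau, clampTo[1]), clampTo[2])
}

#' Vegetation masking of a plot
#'
#' Recomputes the vegetation mask as `index > tau`, intersected with the
#' current mask, then refined by 3 x 3 binary morphological opening
#' followed by 3 x 3 closing. Reflectance values are never altered.
#'
#' @param plot a [ReflectancePlot-class].
#' @param tau threshold in \[0, 1\], or `"auto"` for Otsu selection via
#'   [selectTau()].
#' @param indexName spectral index (default `"ndvi"`).
#' @param morphology apply the opening/closing refinement (default TRUE).
#' @return the plot with an updated mask; the retained-pixel fraction is
#'   reported via `message()`.
#' @export
vegetationMask <- function(plot, tau = "auto", indexName = "ndvi",
                           morphology = TRUE) {
  if (identical(tau, "auto")) tau <- selectTau(plot, indexName)
  stopifnot(is.numeric(tau), tau >= 0, tau <= 1)
  idx <- spectralIndex(reflectance(plot), indexName)
  mask <- (idx > tau) & vegMask(plot)
  if (morphology) {
    brush <- EBImage::makeBrush(3, "box")
    m <- EBImage::Image(mask * 1)
    m <- EBImage::closing(EBImage::opening(m, brush), brush)
    mask <- EBImage::imageData(m) > 0
  }
  if (!any(mask))
    stop("vegetation mask of plot '", plotId(plot), "' is empty at tau = ",
         signif(tau, 3), "; review the threshold/index choice")
  message(sprintf("plot %s: %.1f%% of pixels retained at tau = %.3f",
                  plotId(plot), 100 * mean(mask), tau))
  plot@mask <- mask
  plot
}
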