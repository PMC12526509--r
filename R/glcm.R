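#' @useDynLib texSMC, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Quantize a reflectance band to G gray levels
#'
#' Linearly scales masked pixels from a reference range to levels
#' `0..G-1`. The reference range is either the percentile-clipped range of
#' the masked pixels of this band (`"perimage"`, default) or a fixed
#' per-band range (`"global"`) for cross-flight comparability.
#'
#' @param grid numeric matrix of reflectance.
#' @param mask logical matrix; `FALSE` pixels are marked invalid (`NA`).
#' @param G number of gray levels (default 64).
#' @param clip lower/upper percentiles for `"perimage"` scaling.
#' @param range fixed `c(lo, hi)`; when supplied it overrides the
#'   percentile clip (global scaling mode).
#' @return integer matrix with levels in `0..G-1`, `NA` outside the mask.
#'   A constant band maps entirely to level 0 with a warning.
#' @examples
#' q <- quantizeBand(matrix(c(0, 1), 2, 2), G = 64)
#' range(q)  # 0 63
#' @export
quantizeBand <- function(grid, mask = NULL, G = 64L,
                         clip = c(0.01, 0.99), range = NULL) {
  stopifnot(is.matrix(grid), all(is.finite(grid[if (is.null(mask)) TRUE
                                                else mask])))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(grid), ncol(grid))
  vals <- grid[mask]
  if (length(vals) == 0L) stop("mask leaves no pixel to quantize")
  if (is.null(range)) {
    lo <- as.numeric(quantile(vals, clip[1], names = FALSE))
    hi <- as.numeric(quantile(vals, clip[2], names = FALSE))
  } else {
    lo <- range[1]; hi <- range[2]
  }
  q <- matrix(NA_integer_, nrow(grid), ncol(grid))
  if (hi <= lo) {
    warning("constant band: all pixels quantized to level 0")
    q[mask] <- 0L
    return(q)
  }
  lev <- floor((grid[mask] - lo) / (hi - lo) * G)
  q[mask] <- as.integer(pmin(pmax(lev, 0), G - 1L))
  q
}

#' Build the normalized GLCM of a quantized grid for one direction
#'
#' Counts pixel pairs `(p, p + offset)` where both pixels are valid,
#' accumulated symmetrically (both orderings), and normalizes to sum 1.
#' Gray levels in the output matrix are indexed 1..G as in the texture
#' formulas.
#'
#' @param q integer matrix of levels `0..G-1` with `NA` for invalid pixels.
#' @param G number of gray levels.
#' @param offset pair offset in pixels.
#' @param direction one of 0, 45, 90, 135 (degrees).
#' @return list with the normalized matrix `P` (G x G), the GLCM mean `u`,
#'   marginal means `meaI`/`meaJ` and variances `varI`/`varJ`, and the pair
#'   count `nPairs`; or `NULL` when the grid holds no valid pair for the
#'   direction (window skipped, signaled, not fatal).
#' @export
glcmMatrix <- function(q, G, offset = 1L, direction = 0) {
  step <- switch(as.character(direction),
                 "0" = c(0L, 1L), "45" = c(-1L, 1L),
                 "90" = c(-1L, 0L), "135" = c(-1L, -1L),
                 stop("direction must be 0, 45, 90 or 135"))
  dr <- step[1] * offset; dc <- step[2] * offset
  nr <- nrow(q); nc <- ncol(q)
  P <- matrix(0, G, G)
  n <- 0L
  for (r in seq_len(nr)) {
    rp <- r + dr
    if (rp < 1L || rp > nr) next
    for (cc in seq_len(nc)) {
      cp <- cc + dc
      if (cp < 1L || cp > nc) next
      a <- q[r, cc]; b <- q[rp, cp]
      if (is.na(a) || is.na(b)) next
      P[a + 1L, b + 1L] <- P[a + 1L, b + 1L] + 1
      P[b + 1L, a + 1L] <- P[b + 1L, a + 1L] + 1
      n <- n + 1L
    }
  }
  if (n == 0L) return(NULL)
  P <- P / sum(P)
  pi_ <- rowSums(P); pj <- colSums(P)
  meaI <- sum(seq_len(G) * pi_); meaJ <- sum(seq_len(G) * pj)
  list(P = P, u = meaI,
       meaI = meaI, meaJ = meaJ,
       varI = sum((seq_len(G) - meaI)^2 * pi_),
       varJ = sum((seq_len(G) - meaJ)^2 * pj),
       nPairs = n)
}

#' The eight GLCM texture metrics of a co-occurrence matrix
#'
#' Computes MEA, VAR, HOM, CON, DIS, ENT, SEC and COR from a normalized
#' GLCM. Entropy uses the Shannon form `-sum(P log P)` in natural log so
#' that ENT >= 0. COR uses the marginal means/variances of the symmetric
#' matrix and is `NA` (undefined) when the marginal variance product is
#' zero.
#'
#' @param stats result of [glcmMatrix()].
#' @return named numeric vector of length 8.
#' @export
glcmFeatures <- function(stats) {
  P <- stats$P
  G <- nrow(P)
  i <- matrix(seq_len(G), G, G)       # row index
  j <- t(i)                           # column index
  u <- stats$u
  pos <- P > 0
  cor <- if (stats$varI * stats$varJ > 0)
    sum((i - stats$meaJ) * (j - stats$meaI) * P) /
      sqrt(stats$varI * stats$varJ) else NA_real_
  c(MEA = sum(i * P),
    VAR = sum((i - u)^2 * P),
    HOM = sum(P / (1 + (i - j)^2)),
    CON = sum((i - j)^2 * P),
    DIS = sum(P * abs(i - j)),
    ENT = -sum(P[pos] * log(P[pos])),
    SEC = sum(P^2),
    COR = cor)
}

#' Plot-level texture features: the 48 positions
#'
#' For each of the six bands, quantizes the band, slides the GLCM window
#' over all interior positions whose window contains at least
#' `minWindowValidFrac` valid pixels, averages each metric over the four
#' directions per window, and takes the arithmetic mean over admissible
#' windows. Windows with undefined COR (zero GLCM variance in any
#' direction) are excluded from COR's mean only.
#'
#' @param plot a [ReflectancePlot-class].
#' @param params a [GLCMParams-class]; defaults to the fixed protocol
#'   (G = 64, 5 x 5 window, offset 1, four directions averaged).
#' @return named numeric vector of the 48 position values
#'   (`MEA1` ... `COR6`).
#' @export
plotTextures <- function(plot, params = glcmParams()) {
  px <- reflectance(plot)
  msk <- vegMask(plot)
  out <- setNames(numeric(0), character(0))
  for (b in 1:6) {
    rng <- if (params@scalingMode == "global") params@globalRange[b, ] else NULL
    q <- quantizeBand(px[, , b], msk, G = params@grayLevels,
                      clip = params@percentileClip, range = rng)
    res <- .cppBandTextures(q, params@grayLevels, params@window,
                            params@offset, params@minWindowValidFrac)
    if (res$nWindows == 0)
      stop("no admissible GLCM window in plot '", plotId(plot),
           "' band ", b, " (mask too sparse?)")
    f <- res$features
    names(f) <- paste0(names(f), b)
    out <- c(out, f)
  }
  out[positionLabels()]
}

#' Texture feature table for a set of plots
#'
#' @param plots list of [ReflectancePlot-class] objects.
#' @param params a [GLCMParams-class].
#' @return data.frame with `plot_id` plus the 48 position columns.
#' @export
computeTextures <- function(plots, params = glcmParams()) {
  rows <- lapply(plots, function(p) {
    v <- plotTextures(p, params)
    cbind(data.frame(plot_id = plotId(p), stringsAsFactors = FALSE),
          as.data.frame(as.list(v)))
  })
  do.call(rbind, rows)
}
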