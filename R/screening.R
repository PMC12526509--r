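#' Pearson correlation with a t-based two-sided p-value
#'
#' Non-finite pairs are dropped first. The p-value uses the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors (paired).
#' @return list with `r`, `p`, `n` (pairs used). Zero variance in either
#'   column yields the undefined marker (`r = p = NA`).
#' @export
pearsonWithP <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired finite observations")
  if (sd(x) == 0 || sd(y) == 0) return(list(r = NA_real_, p = NA_real_, n = n))
  r <- cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(t), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

# Vectorized Pearson r of every column of M against y, with per-column
# pairwise deletion of undefined (NA) entries. Columns whose undefined
# fraction exceeds maxUndefFrac, with fewer than 3 pairs, or with zero
# variance are NA.
colwiseR <- function(M, y, maxUndefFrac = 0.1) {
  n <- nrow(M)
  if (anyNA(M)) {
    F <- is.finite(M)
    M0 <- M; M0[!F] <- 0
    nOK <- colSums(F)
    Sy <- as.vector(crossprod(F, y))
    Syy <- as.vector(crossprod(F, y^2))
  } else {
    M0 <- M
    nOK <- rep(n, ncol(M))
    Sy <- rep(sum(y), ncol(M))
    Syy <- rep(sum(y^2), ncol(M))
  }
  Sx <- colSums(M0)
  Sxx <- colSums(M0^2)
  Sxy <- as.vector(crossprod(M0, y))
  vx <- Sxx - Sx^2 / nOK
  vy <- Syy - Sy^2 / nOK
  r <- (Sxy - Sx * Sy / nOK) / sqrt(pmax(vx, 0) * pmax(vy, 0))
  bad <- nOK < 3 | (n - nOK) / n > maxUndefFrac |
    vx <= 1e-12 * pmax(Sxx, 1) | vy <= 0
  r[bad] <- NA_real_
  r
}

# decode tuple index t (1-based, first position fastest) into position
# indices; nP = number of positions, arity 2 or 3
tupleIndices <- function(t, nP, arity) {
  t0 <- t - 1
  i <- t0 %% nP + 1
  j <- (t0 %/% nP) %% nP + 1
  if (arity == 2L) cbind(i = i, j = j)
  else cbind(i = i, j = j, k = (t0 %/% (nP * nP)) %% nP + 1)
}

# family values for a block of tuples; returns n x length(tuples) matrix
tupleValues <- function(X, idx, family, arity) {
  Ti <- X[, idx[, "i"], drop = FALSE]
  Tj <- X[, idx[, "j"], drop = FALSE]
  if (arity == 2L) eval2d(family, Ti, Tj)
  else eval3d(family, Ti, Tj, X[, idx[, "k"], drop = FALSE])
}

# full |r| surface of one family over the ordered-with-repetition tuple
# grid, computed blockwise to bound memory
tupleCorrelations <- function(X, y, family, chunkSize = 20000,
                              maxUndefFrac = 0.1) {
  arity <- indexArity(family)
  nP <- ncol(X)
  total <- nP^arity
  r <- numeric(total)
  for (start in seq(1, total, by = chunkSize)) {
    t <- start:min(start + chunkSize - 1, total)
    idx <- tupleIndices(t, nP, arity)
    M <- tupleValues(X, idx, family, arity)
    r[t] <- colwiseR(M, y, maxUndefFrac)
  }
  r
}

tupleLabels <- function(t, positions, family, arity) {
  idx <- tupleIndices(t, length(positions), arity)
  inner <- positions[idx[, "i"]]
  inner <- paste(inner, positions[idx[, "j"]], sep = ",")
  if (arity == 3L) inner <- paste(inner, positions[idx[, "k"]], sep = ",")
  paste0(family, "(", inner, ")")
}

#' Exhaustive correlation search of one feature family
#'
#' Evaluates the Pearson correlation with SMC of every tuple in the
#' family's space — the single positions for `"raw"`, all ordered pairs
#' with repetition for a 2-D family (`nP^2`), all ordered triples for a
#' 3-D family (`nP^3`) — and reports the maximum-|r| combination plus the
#' retained candidate set (p < `alpha`; for index families additionally
#' within `capFrac` of the best |r|, capped at `capN`). Ties in |r| break
#' lexicographically by column label.
#'
#' @param X screening rows x positions matrix (position-label colnames).
#' @param y SMC vector aligned to the rows of `X`.
#' @param family `"raw"` or an index family name.
#' @param alpha significance level (default 0.05, unadjusted as in the
#'   two-stage screening protocol).
#' @param capFrac candidate band as a fraction of the best |r| (index
#'   families; `"raw"` keeps all significant positions).
#' @param capN candidate cap per family.
#' @param chunkSize tuples per evaluation block.
#' @param maxUndefFrac columns with a larger undefined fraction are
#'   excluded.
#' @param depthLayer label recorded in the result.
#' @return a [ScreenResult-class].
#' @export
exhaustiveSearch <- function(X, y, family, alpha = 0.05, capFrac = 0.95,
                             capN = 20L, chunkSize = 20000,
                             maxUndefFrac = 0.1, depthLayer = "") {
  stopifnot(is.matrix(X), !is.null(colnames(X)), nrow(X) == length(y))
  positions <- colnames(X)
  if (family == "raw") {
    r <- colwiseR(X, y, maxUndefFrac)
    labels <- positions
    capFrac <- 0; capN <- Inf
  } else {
    arity <- indexArity(family)
    r <- tupleCorrelations(X, y, family, chunkSize, maxUndefFrac)
    labels <- NULL
  }
  if (all(is.na(r))) stop("all ", family, " combinations are undefined")
  absr <- abs(r)
  best <- max(absr, na.rm = TRUE)
  lab <- function(t) if (is.null(labels))
    tupleLabels(t, positions, family, indexArity(family)) else labels[t]
  # near-ties (e.g. symmetric tuples evaluated in different operand order)
  # are resolved lexicographically by label
  bestT <- which(absr >= best - 1e-12 * max(1, best))
  bestLab <- sort(lab(bestT))[1]
  bestT <- bestT[lab(bestT) == bestLab][1]

  candT <- which(!is.na(absr) & absr >= capFrac * best)
  if (length(candT) > 3000L)            # plenty to fill the cap after ties
    candT <- candT[order(-absr[candT])][1:3000]
  candLab <- lab(candT)
  ord <- order(-absr[candT], candLab)
  candT <- candT[ord]; candLab <- candLab[ord]
  # exact r/p/n per candidate from the actual column
  stats <- lapply(candT, function(t) {
    col <- if (family == "raw") X[, t] else
      tupleValues(X, tupleIndices(t, length(positions), indexArity(family)),
                  family, indexArity(family))[, 1]
    pearsonWithP(col, y)
  })
  cand <- data.frame(label = candLab,
                     r = vapply(stats, `[[`, 0, "r"),
                     p = vapply(stats, `[[`, 0, "p"),
                     n = vapply(stats, `[[`, 0L, "n"),
                     stringsAsFactors = FALSE)
  cand <- cand[!is.na(cand$p) & cand$p < alpha, , drop = FALSE]
  if (is.finite(capN)) cand <- head(cand, capN)
  rownames(cand) <- NULL
  bp <- pearsonWithP(if (family == "raw") X[, bestT] else
    tupleValues(X, tupleIndices(bestT, length(positions),
                                indexArity(family)),
                family, indexArity(family))[, 1], y)
  new("ScreenResult", depthLayer = depthLayer, family = family,
      bestLabel = bestLab, r = bp$r, p = bp$p, candidates = cand,
      nSearched = as.numeric(length(r)))
}

#' Long-format correlation grid of one family (heatmap export)
#'
#' @inheritParams exhaustiveSearch
#' @return data.frame with columns `label`, `r` over the full tuple space.
#' @export
correlationGrid <- function(X, y, family, chunkSize = 20000,
                            maxUndefFrac = 0.1) {
  if (family == "raw") {
    data.frame(label = colnames(X), r = colwiseR(X, y, maxUndefFrac),
               stringsAsFactors = FALSE)
  } else {
    arity <- indexArity(family)
    r <- tupleCorrelations(X, y, family, chunkSize, maxUndefFrac)
    data.frame(label = tupleLabels(seq_along(r), colnames(X), family, arity),
               r = r, stringsAsFactors = FALSE)
  }
}

#' Redundancy filter: drop inter-feature correlations |r| >= 0.90
#'
#' Greedy elimination: features are walked in order of descending |r| with
#' SMC (ties lexicographic by label); a feature is kept only if its |r|
#' with every already-kept feature is below `rCut`.
#'
#' @param F screening rows x features matrix (labelled columns).
#' @param rSmc named vector of each feature's correlation with SMC.
#' @param rCut redundancy threshold (default 0.90).
#' @return surviving labels, in keep order.
#' @export
redundancyFilter <- function(F, rSmc, rCut = 0.90) {
  labels <- colnames(F)
  stopifnot(all(labels %in% names(rSmc)))
  ord <- labels[order(-abs(rSmc[labels]), labels)]
  kept <- character(0)
  for (lab in ord) {
    if (length(kept) == 0L) { kept <- lab; next }
    cc <- suppressWarnings(
      abs(cor(F[, lab], F[, kept, drop = FALSE],
              use = "pairwise.complete.obs")))
    cc[is.na(cc)] <- 0
    if (all(cc < rCut)) kept <- c(kept, lab)
  }
  kept
}

#' VIF filter: iteratively drop features until all VIF <= vifMax
#'
#' `VIF_j = 1 / (1 - R_j^2)`, computed as the diagonal of the inverse
#' sample correlation matrix. The feature with the largest VIF is dropped
#' first; perfectly collinear features are dropped first with a warning.
#'
#' @param F screening rows x features matrix (labelled columns).
#' @param rSmc named |r|-with-SMC vector, used to break ties and to shed
#'   features when there are too few rows to regress.
#' @param vifMax VIF ceiling (default 10).
#' @return surviving labels.
#' @export
vifFilter <- function(F, rSmc, vifMax = 10) {
  labels <- colnames(F)
  if (length(labels) < 2L) return(labels)
  F <- F[complete.cases(F), , drop = FALSE]
  n <- nrow(F)
  while (length(labels) >= 2L && n <= length(labels) + 1L) {
    weakest <- labels[order(abs(rSmc[labels]), labels)][1]
    warning("too few rows for VIF with ", length(labels),
            " features; dropping '", weakest, "'")
    labels <- setdiff(labels, weakest)
  }
  repeat {
    if (length(labels) < 2L) break
    Fs <- scale(F[, labels, drop = FALSE])
    qrd <- qr(Fs)
    if (qrd$rank < length(labels)) {
      drop <- labels[qrd$pivot[(qrd$rank + 1L):length(labels)]][1]
      warning("perfect collinearity: dropping '", drop, "'")
      labels <- setdiff(labels, drop)
      next
    }
    vif <- diag(solve(cor(F[, labels, drop = FALSE])))
    if (max(vif) <= vifMax) break
    worst <- labels[order(-vif, abs(rSmc[labels]), labels)][1]
    labels <- setdiff(labels, worst)
  }
  labels
}

#' Full screening of one depth layer
#'
#' Runs the two-stage screening protocol for one depth: (i) exhaustive
#' Pearson screening of the 48 raw positions, the six 2-D and the four 3-D
#' index families against SMC, keeping significant features (p < `alpha`;
#' index families: the best combination plus combinations within
#' `capFrac` of the best |r|, cap `capN` per family); (ii) redundancy
#' removal at |r| >= `rCut` followed by the VIF <= `vifMax` filter, applied
#' per feature group (raw / 2-D / 3-D). Screening statistics use only the
#' rows in `screenIds` (training rows in strict leakage mode; all plots in
#' paper-faithful mode); survivor feature values are materialized for all
#' plots.
#'
#' @param X all-plots x 48 position matrix (plot ids as rownames).
#' @param y named SMC vector for this depth (all plots).
#' @param screenIds plot ids used for the screening statistics.
#' @param depthLayer label recorded in the results.
#' @param alpha,rCut,vifMax,capFrac,capN,chunkSize see above.
#' @return a [DepthScreen-class].
#' @export
screenDepth <- function(X, y, screenIds = rownames(X), depthLayer = "",
                        alpha = 0.05, rCut = 0.90, vifMax = 10,
                        capFrac = 0.95, capN = 20L, chunkSize = 20000) {
  stopifnot(!is.null(rownames(X)), all(screenIds %in% rownames(X)))
  Xs <- X[screenIds, , drop = FALSE]
  ys <- y[screenIds]
  results <- list()

  filterGroup <- function(cands, valuesOf) {
    if (nrow(cands) == 0L) return(character(0))
    Ftrain <- valuesOf(Xs, cands$label)
    rSmc <- setNames(cands$r, cands$label)
    kept <- redundancyFilter(Ftrain, rSmc, rCut)
    vifFilter(Ftrain[, kept, drop = FALSE], rSmc, vifMax)
  }
  rawRes <- exhaustiveSearch(Xs, ys, "raw", alpha, depthLayer = depthLayer)
  results[["raw"]] <- rawRes
  rawSurv <- filterGroup(rawRes@candidates,
                         function(M, lab) M[, lab, drop = FALSE])

  groupSurv <- function(fams) {
    cands <- list()
    for (fam in fams) {
      res <- exhaustiveSearch(Xs, ys, fam, alpha, capFrac, capN,
                              chunkSize, depthLayer = depthLayer)
      results[[fam]] <<- res
      cands[[fam]] <- res@candidates
    }
    pooled <- do.call(rbind, cands)
    pooled <- pooled[!duplicated(pooled$label), , drop = FALSE]
    filterGroup(pooled, function(M, lab) batchIndices(M, lab))
  }
  surv2d <- groupSurv(.FAM2D)
  surv3d <- groupSurv(.FAM3D)

  feat <- cbind(X[, rawSurv, drop = FALSE],
                batchIndices(X, c(surv2d, surv3d)))
  new("DepthScreen", depthLayer = depthLayer, results = results,
      survivorList = list(raw = rawSurv, idx2d = surv2d, idx3d = surv3d),
      features = feat, screenIds = as.character(screenIds))
}

#' Tabular summary of screening results (per-depth best combinations)
#'
#' @param screens list of [DepthScreen-class] objects.
#' @return data.frame with columns `depth_layer`, `family`, `best`, `r`,
#'   `p` — one row per family per depth, mirroring the best-combination
#'   reporting of the screening stage.
#' @export
screenSummary <- function(screens) {
  rows <- lapply(screens, function(ds)
    do.call(rbind, lapply(ds@results, function(sr)
      data.frame(depth_layer = sr@depthLayer, family = sr@family,
                 best = sr@bestLabel, r = sr@r, p = sr@p,
                 stringsAsFactors = FALSE))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
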