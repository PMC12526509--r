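# Independent brute-force oracles. These deliberately re-derive every
# quantity with naive loops, sharing no code with the package internals.

# Naive windowed GLCM texture features: enumerates all windows, directions
# and pixel pairs explicitly and builds the full G x G matrix per window.
naiveBandTextures <- function(q, G, win = 5L, offset = 1L,
                              minValidFrac = 0.6) {
  dirs <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
               `90` = c(-1L, 0L), `135` = c(-1L, -1L))
  nr <- nrow(q); nc <- ncol(q)
  sums <- setNames(numeric(8), c("MEA", "VAR", "HOM", "CON", "DIS",
                                 "ENT", "SEC", "COR"))
  corSum <- 0; nWin <- 0; nCorWin <- 0
  for (r0 in seq_len(nr - win + 1L)) {
    for (c0 in seq_len(nc - win + 1L)) {
      w <- q[r0:(r0 + win - 1L), c0:(c0 + win - 1L)]
      if (sum(!is.na(w)) < ceiling(minValidFrac * win * win)) next
      perDir <- list(); ok <- TRUE
      for (d in dirs) {
        P <- matrix(0, G, G)
        for (r in seq_len(win)) for (cc in seq_len(win)) {
          rp <- r + d[1] * offset; cp <- cc + d[2] * offset
          if (rp < 1 || rp > win || cp < 1 || cp > win) next
          a <- w[r, cc]; b <- w[rp, cp]
          if (is.na(a) || is.na(b)) next
          P[a + 1, b + 1] <- P[a + 1, b + 1] + 1
          P[b + 1, a + 1] <- P[b + 1, a + 1] + 1
        }
        if (sum(P) == 0) { ok <- FALSE; break }
        P <- P / sum(P)
        f <- setNames(numeric(8), names(sums))
        u <- 0
        for (i in 1:G) for (j in 1:G) u <- u + i * P[i, j]
        varv <- 0
        for (i in 1:G) for (j in 1:G) varv <- varv + (i - u)^2 * P[i, j]
        corNum <- 0
        for (i in 1:G) for (j in 1:G) {
          p <- P[i, j]
          f["HOM"] <- f["HOM"] + p / (1 + (i - j)^2)
          f["CON"] <- f["CON"] + (i - j)^2 * p
          f["DIS"] <- f["DIS"] + p * abs(i - j)
          if (p > 0) f["ENT"] <- f["ENT"] - p * log(p)
          f["SEC"] <- f["SEC"] + p^2
          corNum <- corNum + (i - u) * (j - u) * p
        }
        f["MEA"] <- u; f["VAR"] <- varv
        f["COR"] <- if (varv > 0) corNum / varv else NA_real_
        perDir[[length(perDir) + 1L]] <- f
      }
      if (!ok) next
      m <- Reduce(`+`, lapply(perDir, function(f) {
        f["COR"] <- 0; f
      })) / 4
      sums <- sums + m
      if (!any(vapply(perDir, function(f) is.na(f["COR"]), TRUE))) {
        corSum <- corSum + mean(vapply(perDir, `[[`, 0, "COR"))
        nCorWin <- nCorWin + 1
      }
      nWin <- nWin + 1
    }
  }
  if (nWin == 0) return(NULL)
  out <- sums / nWin
  out["COR"] <- if (nCorWin > 0) corSum / nCorWin else NA_real_
  out
}

# Literal nested-loop search over ordered tuples with repetition;
# returns the max-|r| combination. Shares nothing with exhaustiveSearch.
bruteTupleSearch <- function(X, y, family, arity) {
  pos <- colnames(X)
  bestR <- NA_real_; bestLab <- NA_character_
  idxSets <- if (arity == 2L) expand.grid(i = pos, j = pos,
                                          stringsAsFactors = FALSE)
             else expand.grid(i = pos, j = pos, k = pos,
                              stringsAsFactors = FALSE)
  for (row in seq_len(nrow(idxSets))) {
    g <- idxSets[row, ]
    v <- if (arity == 2L) eval2d(family, X[, g$i], X[, g$j])
         else eval3d(family, X[, g$i], X[, g$j], X[, g$k])
    okRows <- is.finite(v)
    if (sum(!okRows) / length(v) > 0.1 || sum(okRows) < 3) next
    # degenerate tuples (e.g. NDTTI(a,a,a) = -1/3 up to rounding) carry no
    # signal; exclude on negligible relative spread, as the pipeline does
    if (sd(v[okRows]) < 1e-7 * (abs(mean(v[okRows])) + 1)) next
    if (sd(y[okRows]) == 0) next
    r <- cor(v[okRows], y[okRows])
    lab <- paste0(family, "(", paste(unlist(g), collapse = ","), ")")
    if (is.na(bestR) || abs(r) > abs(bestR) + 1e-12 ||
        (abs(abs(r) - abs(bestR)) <= 1e-12 && lab < bestLab)) {
      bestR <- r; bestLab <- lab
    }
  }
  list(r = bestR, label = bestLab)
}

# Otsu threshold by brute force over candidate cut points
bruteOtsu <- function(v, nCand = 256L) {
  cand <- seq(min(v), max(v), length.out = nCand + 2L)[-c(1, nCand + 2L)]
  wcv <- vapply(cand, function(t) {
    a <- v[v <= t]; b <- v[v > t]
    if (!length(a) || !length(b)) return(Inf)
    (length(a) * ifelse(length(a) > 1, var(a) * (length(a) - 1) / length(a), 0) +
     length(b) * ifelse(length(b) > 1, var(b) * (length(b) - 1) / length(b), 0)) /
      length(v)
  }, 0)
  cand[which.min(wcv)]
}

# VIF via explicit per-feature regression on the remaining features
bruteVif <- function(F) {
  vapply(seq_len(ncol(F)), function(j) {
    fit <- lm(F[, j] ~ F[, -j, drop = FALSE])
    1 / (1 - summary(fit)$r.squared)
  }, 0)
}

defaultTestConfig <- function(seed, nPlots = 96L)
  syntheticConfig(nPlots = nPlots, seed = seed)
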