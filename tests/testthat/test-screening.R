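test_that("pearsonWithP matches the textbook formula and cor.test", {
  # identity: r = 1, p ~ 0
  x <- 1:10
  res <- pearsonWithP(x, x)
  expect_equal(res$r, 1)
  expect_equal(res$p, 0)

  # orthogonal contrast against constant-mean response: r = 0, p = 1
  res <- pearsonWithP(c(-1, 1, -1, 1), c(2, 2, 4, 4) - 3)
  expect_equal(res$r, 0)
  expect_equal(res$p, 1)

  # random columns agree with an independent implementation to 1e-12
  set.seed(12)
  for (i in 1:5) {
    x <- rnorm(30); y <- rnorm(30)
    res <- pearsonWithP(x, y)
    ct <- cor.test(x, y)
    expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$p, ct$p.value, tolerance = 1e-12)
  }
  # zero variance: undefined marker
  expect_true(is.na(pearsonWithP(rep(1, 5), rnorm(5))$r))
  expect_error(pearsonWithP(c(1, NA, NA, NA), c(1, 2, 3, 4)), "3 paired")
})

test_that("vectorized column correlations equal per-column cor()", {
  set.seed(7)
  M <- matrix(rnorm(40 * 20), 40, 20)
  M[sample(length(M), 30)] <- NA   # sparse undefined entries
  y <- rnorm(40)
  r <- texSMC:::colwiseR(M, y, maxUndefFrac = 0.2)
  ref <- sapply(seq_len(ncol(M)), function(j)
    cor(M[, j], y, use = "complete.obs"))
  expect_equal(r, ref, tolerance = 1e-12)
  # a column above the undefined-fraction cap is excluded
  M[1:20, 3] <- NA
  expect_true(is.na(texSMC:::colwiseR(M, y, maxUndefFrac = 0.2)[3]))
})

test_that("exhaustive search equals a literal nested-loop oracle", {
  set.seed(15)
  pos <- c("MEA1", "HOM2", "CON3", "DIS4", "SEC5")   # reduced 5-position space
  X <- matrix(runif(30 * 5, 0.2, 3), 30, 5, dimnames = list(NULL, pos))
  y <- rnorm(30)
  for (fam in indexFamilies(2)$family) {
    fast <- exhaustiveSearch(X, y, fam)
    slow <- bruteTupleSearch(X, y, fam, 2L)
    expect_equal(fast@bestLabel, slow$label, info = fam)
    expect_equal(fast@r, slow$r, tolerance = 1e-10, info = fam)
    expect_equal(fast@nSearched, 25, info = fam)
  }
  for (fam in indexFamilies(3)$family) {
    fast <- exhaustiveSearch(X, y, fam)
    slow <- bruteTupleSearch(X, y, fam, 3L)
    expect_equal(fast@bestLabel, slow$label, info = fam)
    expect_equal(fast@r, slow$r, tolerance = 1e-10, info = fam)
    expect_equal(fast@nSearched, 125, info = fam)
  }
})

test_that("a planted perfect correlate always wins the raw search", {
  set.seed(19)
  X <- matrix(rnorm(40 * 48), 40, 48,
              dimnames = list(sprintf("P%03d", 1:40), positionLabels()))
  y <- rnorm(40)
  X[, "DIS1"] <- y   # plant
  res <- exhaustiveSearch(X, y, "raw")
  expect_identical(res@bestLabel, "DIS1")
  expect_equal(res@r, 1)
  # restricted sub-space never beats the full space
  sub <- exhaustiveSearch(X[, c("MEA1", "HOM2", "CON3")], y, "raw")
  expect_lte(abs(sub@r), abs(res@r))
})

test_that("redundancy filter keeps a pairwise-|r|<0.90 subset", {
  set.seed(23)
  n <- 60
  base <- rnorm(n)
  F <- cbind(a = base,
             b = base + rnorm(n, 0, 0.01),       # ~identical to a
             c = rnorm(n),
             d = rnorm(n))
  y <- base + rnorm(n, 0, 0.5)
  rSmc <- setNames(sapply(colnames(F), function(j) cor(F[, j], y)),
                   colnames(F))
  kept <- redundancyFilter(F, rSmc)
  # exactly one of the duplicated pair survives - the higher-|r| member
  expect_equal(sum(c("a", "b") %in% kept), 1)
  expect_true(names(which.max(abs(rSmc[c("a", "b")]))) %in% kept)
  C <- abs(cor(F[, kept])); diag(C) <- 0
  expect_true(all(C < 0.90))

  # mutually orthogonal columns all survive
  Fo <- qr.Q(qr(matrix(rnorm(n * 4), n, 4)))
  colnames(Fo) <- letters[1:4]
  rS <- setNames(runif(4, 0.1, 0.9), letters[1:4])
  expect_setequal(redundancyFilter(Fo, rS), letters[1:4])

  # identical columns tie on |r|: lexicographic keep
  Fi <- cbind(z = base, m = base)
  rT <- setNames(c(0.5, 0.5), c("z", "m"))
  expect_identical(redundancyFilter(Fi, rT), "m")
})

test_that("greedy elimination matches an exhaustive check of keep order", {
  # 6 columns with a planted correlation structure; verify the greedy
  # walk against an independent re-implementation over the sorted order
  set.seed(29)
  n <- 80
  z1 <- rnorm(n); z2 <- rnorm(n)
  F <- cbind(f1 = z1, f2 = z1 * 0.97 + rnorm(n, 0, 0.05),
             f3 = z2, f4 = z2 * 0.99 + rnorm(n, 0, 0.02),
             f5 = rnorm(n), f6 = 0.7 * z1 + 0.7 * z2 + rnorm(n, 0, 0.4))
  rSmc <- setNames(c(0.9, 0.85, 0.8, 0.82, 0.3, 0.6), colnames(F))
  kept <- redundancyFilter(F, rSmc)
  # independent walk
  ord <- names(sort(-abs(rSmc)))
  ref <- character(0)
  for (lab in ord) {
    if (all(abs(cor(F[, lab], F[, ref, drop = FALSE])) < 0.9) ||
        length(ref) == 0) ref <- c(ref, lab)
  }
  expect_setequal(kept, ref)
})

test_that("VIF filter matches the matrix-inverse closed form and lm oracle", {
  # 4 columns with a specified covariance structure
  set.seed(37)
  n <- 200
  S <- matrix(c(1, .7, .2, 0,
                .7, 1, .3, 0,
                .2, .3, 1, .5,
                0, 0, .5, 1), 4, 4)
  L <- chol(S)
  F <- matrix(rnorm(n * 4), n, 4) %*% L
  colnames(F) <- paste0("v", 1:4)
  vifClosed <- diag(solve(cor(F)))
  expect_equal(unname(vifClosed), bruteVif(F), tolerance = 1e-8)

  # two independent columns: VIF ~ 1, nothing dropped
  F2 <- matrix(rnorm(400), 200, 2, dimnames = list(NULL, c("a", "b")))
  expect_setequal(vifFilter(F2, setNames(c(.5, .4), c("a", "b"))),
                  c("a", "b"))

  # near-duplicate pair: one member dropped
  F3 <- cbind(a = F2[, 1], b = F2[, 1] + rnorm(200, 0, 1e-4),
              c = F2[, 2])
  kept <- vifFilter(F3, setNames(c(.5, .45, .3), c("a", "b", "c")))
  expect_equal(sum(c("a", "b") %in% kept), 1)
  expect_true("c" %in% kept)
})

test_that("depth screening output is internally consistent", {
  set.seed(41)
  n <- 48
  X <- matrix(runif(n * 48, 0.2, 2), n, 48,
              dimnames = list(sprintf("P%03d", 1:n), positionLabels()))
  y <- setNames(X[, "DIS1"] * 2 + rnorm(n, 0, 0.3), rownames(X))
  ds <- screenDepth(X, y, depthLayer = "0-20", chunkSize = 5000)
  expect_s4_class(ds, "DepthScreen")
  # survivors are significant and pairwise below the redundancy cut
  feat <- screenedFeatures(ds)
  expect_identical(rownames(feat), rownames(X))
  for (grp in c("raw", "idx2d", "idx3d")) {
    labs <- survivors(ds, grp)
    if (length(labs) < 2) next
    C <- abs(cor(feat[, labs], use = "pairwise.complete.obs"))
    diag(C) <- 0
    expect_true(all(C < 0.90))
  }
  # the planted raw signal is found
  expect_identical(ds@results$raw@bestLabel, "DIS1")
  expect_true(all(ds@results$raw@candidates$p < 0.05))
})
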