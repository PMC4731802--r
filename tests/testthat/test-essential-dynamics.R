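test_that("PCA recovers generator variances and spectral invariants", {
  set.seed(61)
  n <- 20000
  X <- cbind(rnorm(n, sd = 2), matrix(rnorm(n * 5), n, 5))
  arr <- array(NA_real_, c(n, 2, 3))
  for (s in 1:2) for (ax in 1:3) arr[, s, ax] <- X[, (s - 1) * 3 + ax]
  st <- makeSiteTrajectory(arr)
  pca <- fitPCA(st)
  expect_equal(pcaValues(pca)[1], 4, tolerance = 0.05 * 4)
  expect_equal(crossprod(pcaVectors(pca)), diag(6), tolerance = 1e-8,
               ignore_attr = TRUE)

  # frozen trajectory: all eigenvalues zero (and the rank warning fires)
  frozen <- makeSiteTrajectory(array(1, c(5, 2, 3)))
  expect_warning(pcaF <- fitPCA(frozen), "rank-deficient")
  expect_equal(pcaValues(pcaF), rep(0, 6))

  # rotated coordinate frame: identical spectrum
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  arrR <- arr
  for (s in 1:2) arrR[, s, ] <- arr[, s, ] %*% R
  expect_equal(pcaValues(fitPCA(makeSiteTrajectory(arrR))),
               pcaValues(pca), tolerance = 1e-6)

  # trace conservation against the mobility profile, exact
  expect_equal(sum(pcaValues(pca)),
               sum(mobilityValues(rmsf(st))^2), tolerance = 1e-8)

  expect_error(fitPCA(makeSiteTrajectory(array(0, c(1, 2, 3)))),
               "insufficient frames")
})

test_that("PCA on the elastic-network ensemble recovers the soft mode", {
  spec <- gaussianEnsembleSpec(5, cbind(1:4, 2:5), anchors = 0.05,
                               seed = 62)
  tr <- buildGaussianEnsemble(spec, 20000)
  pca <- fitPCA(tr)
  # generator's top mode: leading Kirchhoff-inverse eigenvector on each axis
  eg <- eigen(spec@covariance, symmetric = TRUE)
  top <- eg$vectors[, 1]
  v <- pcaVectors(pca)[, 1]
  # the estimated mode lives in one Cartesian axis; compare site loadings
  load <- sapply(1:3, function(ax) v[seq(ax, by = 3, length.out = 5)])
  norms <- sqrt(colSums(load^2))
  best <- load[, which.max(norms)] / max(norms)
  expect_gt(abs(sum(best * top)), 0.99)
})

test_that("projections have the stated geometry", {
  set.seed(63)
  arr <- array(rnorm(2000 * 2 * 3), c(2000, 2, 3))
  st <- makeSiteTrajectory(arr)
  pca <- fitPCA(st)
  q1 <- projectMode(st, pca, 1)
  expect_equal(mean(q1), 0, tolerance = 1e-10)
  expect_equal(var(q1) * (1999 / 2000), pcaValues(pca)[1],
               tolerance = 1e-10)
  # the mean structure projects to zero by construction
  mid <- makeSiteTrajectory(array(rep(apply(arr, c(2, 3), mean), each = 2),
                                  c(2, 2, 3)))
  expect_lt(max(abs(projectMode(mid, pca, 1))), 1e-10)
  expect_error(projectMode(st, pca, 99), "out of range")
})

test_that("1-D free energy reproduces harmonic and uniform closed forms", {
  set.seed(64)
  s <- rnorm(200000)
  fes <- freeEnergy1D(s, bins = 50)
  Fv <- surfaceF(fes)
  expect_identical(min(Fv, na.rm = TRUE), 0)
  expect_true(all(Fv >= 0, na.rm = TRUE))
  i <- which.min(abs(surfaceMids(fes)[[1]] - 1))
  expect_equal(Fv[i], 0.5, tolerance = 0.1)  # F(sigma) = 0.5 kT

  u <- runif(200000)
  fu <- surfaceF(freeEnergy1D(u, bins = 20))
  expect_lt(max(fu, na.rm = TRUE), 0.1)

  # kcal/mol unit scales by k_B T
  fk <- freeEnergy1D(s, bins = 50, temperature = 300, unit = "kcal/mol")
  expect_equal(surfaceF(fk)[i], 0.5 * 0.0019872041 * 300, tolerance = 0.12)

  expect_warning(fes0 <- freeEnergy1D(rep(1, 500)), "constant")
  expect_equal(as.vector(surfaceP(fes0)), 1)
})

test_that("bimodal barrier height matches the generating density", {
  set.seed(65)
  n <- 400000
  w <- 0.5
  comp <- rbinom(n, 1, w)
  s <- ifelse(comp == 1, rnorm(n, -2, 0.7), rnorm(n, 2, 0.7))
  fes <- freeEnergy1D(s, bins = 60)
  dens <- function(q) w * dnorm(q, -2, 0.7) + (1 - w) * dnorm(q, 2, 0.7)
  mids <- surfaceMids(fes)[[1]]
  saddle <- mids[which.min(abs(mids))]
  peak <- mids[which.min(abs(mids + 2))]
  expected <- -log(dens(saddle) / dens(peak))
  inner <- which.min(abs(mids))
  barrier <- surfaceF(fes)[inner] - min(surfaceF(fes)[abs(mids + 2) < 0.3],
                                        na.rm = TRUE)
  expect_equal(barrier, expected, tolerance = 0.25)
})

test_that("2-D landscapes show canyons for coupled pairs and not otherwise", {
  set.seed(66)
  n <- 50000
  a <- rnorm(n)
  b <- 0.9 * a + sqrt(1 - 0.81) * rnorm(n)
  fes <- freeEnergy2D(a, b, bins = 40)
  expect_identical(min(surfaceF(fes), na.rm = TRUE), 0)
  # off-diagonal quadrant occupancy from the fitted P
  qa <- surfaceMids(fes)[[1]]; qb <- surfaceMids(fes)[[2]]
  off <- outer(qa > 0, qb < 0) | outer(qa < 0, qb > 0)
  occ <- sum(surfaceP(fes)[off])
  orthant <- 2 * (0.25 - asin(0.9) / (2 * pi))
  expect_lt(occ, orthant + 0.01)
  expect_lt(occ, 0.2)

  # shuffled copy decouples: roughly a quarter of mass per quadrant
  bs <- sample(b)
  fesS <- freeEnergy2D(a, bs, bins = 40)
  occS <- sum(surfaceP(fesS)[off])
  expect_equal(occS, 0.5, tolerance = 0.03)

  # marginals of the 2-D P recover the 1-D surfaces within binning error
  f1 <- freeEnergy1D(a, bins = 40)
  pm <- rowSums(surfaceP(fes))
  expect_equal(pm, as.vector(surfaceP(f1)), tolerance = 0.01)

  expect_error(freeEnergy2D(a, b[-1]), "alignment error")
})

test_that("free-energy surfaces are invariant to affine rescaling", {
  set.seed(67)
  s <- rnorm(30000)
  f1 <- surfaceF(freeEnergy1D(s, bins = 30))
  f2 <- surfaceF(freeEnergy1D(5 * s + 3, bins = 30))
  expect_equal(f1, f2, tolerance = 1e-12)
})
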