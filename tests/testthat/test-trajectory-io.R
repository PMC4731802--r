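test_that("PDB topology parsing preserves residues, chains and flags", {
  tf <- writeTempPDB(dipeptideLines())
  m <- readTopology(tf)
  res <- siteInfo(m)
  expect_equal(nrow(res), 2L)
  expect_equal(res$resid, c("ALA", "GLY"))
  expect_equal(nrow(m@atoms), 9L)
  expect_false(any(m@atoms$hydrogen))

  twoChains <- c(dipeptideLines()[1:5],
                 sub(" A   2", " B   2", dipeptideLines()[6:9]),
                 "END")
  m2 <- readTopology(writeTempPDB(twoChains))
  expect_setequal(siteInfo(m2)$chain, c("A", "B"))
})

test_that("malformed and empty topologies raise format errors", {
  bad <- dipeptideLines()
  substr(bad[3], 33, 36) <- "abcd"
  expect_error(readTopology(writeTempPDB(bad)), "line 3")
  expect_error(readTopology(writeTempPDB(c("REMARK nothing", "END"))),
               "empty input")
})

test_that("multi-model PDB and fixture dialect agree on frames and atoms", {
  tf <- writeTempPDB(dipeptideLines())
  m <- readTopology(tf)
  body <- dipeptideLines()[1:9]
  mm <- unlist(lapply(1:4, function(k)
    c(sprintf("MODEL %8d", k), body, "ENDMDL")))
  tr <- readTrajectory(writeTempPDB(c(mm, "END")), m)
  expect_equal(nFrames(tr), 4L)

  ft <- tempfile(fileext = ".traj")
  writeFixtureTrajectory(tr, ft)
  tr2 <- readTrajectory(ft, m, format = "fixture")
  expect_identical(coords(tr2), coords(tr))  # %.6f round trip is exact here

  # atom-count mismatch against the model
  short <- c("FRAME 1", apply(coords(tr)[1, 1:5, ], 1,
                              function(v) paste(v, collapse = " ")))
  sf <- tempfile(fileext = ".traj")
  writeLines(short, sf)
  expect_error(readTrajectory(sf, m, format = "fixture"), "format error")
})

test_that("site selection places representative atoms and falls back to COG", {
  tf <- writeTempPDB(dipeptideLines())
  m <- readTopology(tf)
  arr <- array(NA_real_, c(2, 9, 3))
  for (f in 1:2) arr[f, , ] <- as.matrix(m@atoms[, c("x", "y", "z")]) + f
  tr <- new("Trajectory", coords = arr, dt = NA_real_)

  st <- selectSites(tr, m)
  expect_equal(nSites(st), 2L)
  # CA of residue 1 is atom 2
  expect_equal(st@coords[1, 1, ], arr[1, 2, ])

  # nucleotide rule: C1' is the representative atom
  dna <- c(pdbLine(1, "P",   "DG", "A", 1, 0, 0, 0, "P"),
           pdbLine(2, "C1'", "DG", "A", 1, 1, 2, 3, "C"),
           pdbLine(3, "N9",  "DG", "A", 1, 2, 2, 2, "N"),
           "END")
  mdna <- readTopology(writeTempPDB(dna))
  dco <- array(NA_real_, c(2, 3, 3))
  for (f in 1:2) dco[f, , ] <- as.matrix(mdna@atoms[, c("x", "y", "z")])
  trd <- new("Trajectory", coords = dco, dt = NA_real_)
  std <- selectSites(trd, mdna)
  expect_equal(std@coords[1, 1, ], c(1, 2, 3))

  # hand-computed heavy-atom centroid under the cog rule
  stc <- selectSites(tr, m, rule = "cog")
  expect_equal(stc@coords[1, 1, ],
               unname(colMeans(as.matrix(m@atoms[1:5, c("x", "y", "z")]))) + 1)
})

test_that("superposition recovers rigidly transformed copies exactly", {
  set.seed(41)
  base <- matrix(rnorm(30), 10, 3)
  arr <- array(NA_real_, c(8, 10, 3))
  arr[1, , ] <- base
  for (f in 2:8) {
    th <- runif(3, 0, 2 * pi)
    Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]),
                   0, -sin(th[1]), cos(th[1])), 3, 3)
    Rz <- matrix(c(cos(th[3]), sin(th[3]), 0,
                   -sin(th[3]), cos(th[3]), 0, 0, 0, 1), 3, 3)
    arr[f, , ] <- base %*% (Rx %*% Rz) +
      matrix(runif(3, -10, 10), 10, 3, byrow = TRUE)
  }
  st <- makeSiteTrajectory(arr)
  fit <- superpose(st, reference = 1)
  expect_lt(max(mobilityValues(rmsd(fit, 1))), 1e-6)

  # idempotence
  fit2 <- superpose(fit, reference = 1)
  expect_lt(max(abs(coords(fit2) - coords(fit))), 1e-10)

  # pose invariance: RMSD profile unchanged if the whole input is
  # rigidly moved before fitting
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  arrRot <- arr
  for (f in 1:8) arrRot[f, , ] <- arr[f, , ] %*% R + 5
  fitRot <- superpose(makeSiteTrajectory(arrRot))
  expect_equal(mobilityValues(rmsd(fitRot, "mean")),
               mobilityValues(rmsd(superpose(st), "mean")),
               tolerance = 1e-6)

  expect_error(superpose(st, fitSites = 1:2), "degenerate")
  line <- array(rep(cbind(1:5, 0, 0), each = 3), c(3, 5, 3))
  expect_error(superpose(makeSiteTrajectory(line)), "collinear")
})

test_that("rmsf matches closed forms and rmsd conventions hold", {
  # two-point ensemble: site alternates between (+a, 0, 0) and (-a, 0, 0)
  a <- 1.7
  arr <- array(0, c(4, 2, 3))
  arr[, 1, 1] <- c(a, -a, a, -a)
  st <- makeSiteTrajectory(arr)
  prof <- rmsf(st)
  expect_equal(mobilityValues(prof)[1], a)
  expect_equal(mobilityValues(prof)[2], 0)  # frozen site

  # isotropic Gaussian site: RMSF -> sigma * sqrt(3)
  set.seed(7)
  sig <- 0.6
  g <- array(rnorm(10000 * 1 * 3, sd = sig), c(10000, 1, 3))
  stg <- makeSiteTrajectory(g, makeSites(1))
  expect_equal(mobilityValues(rmsf(stg)), sig * sqrt(3), tolerance = 0.03)

  expect_error(rmsf(makeSiteTrajectory(array(0, c(1, 2, 3)))),
               "insufficient frames")
  expect_equal(mobilityValues(rmsd(st, 1))[1], 0)  # RMSD(frame, itself) = 0
})

test_that("differential RMSF subtracts bound from apo with sign convention", {
  sites <- makeSites(3)
  apo <- new("MobilityProfile", values = c(2, 1, 0.5), kind = "rmsf",
             reference = "mean", sites = sites)
  bound <- new("MobilityProfile", values = c(1.5, 1, 0.8), kind = "rmsf",
               reference = "mean", sites = sites)
  d <- differentialRmsf(apo, bound)
  expect_equal(d$dRMSF, c(0.5, 0, -0.3))
  expect_equal(differentialRmsf(apo, apo)$dRMSF, rep(0, 3))

  other <- new("MobilityProfile", values = 1:2 / 2, kind = "rmsf",
               reference = "mean", sites = makeSites(2))
  expect_error(differentialRmsf(apo, other), "alignment error")
})

test_that("B-factor export writes scores with clipping and defaults", {
  m <- readTopology(writeTempPDB(dipeptideLines()))
  tf <- tempfile(fileext = ".pdb")
  writeScoresAsBfactor(m, c("A:1" = 1, "A:2" = 1), tf)
  lines <- grep("^ATOM", readLines(tf), value = TRUE)
  expect_true(all(trimws(substr(lines, 61, 66)) == "1.00"))

  w <- capture_warnings(writeScoresAsBfactor(m, c("A:1" = 12345.6), tf))
  expect_true(any(grepl("clipped", w)))
  expect_true(any(grepl("absent", w)))
  lines <- grep("^ATOM", readLines(tf), value = TRUE)
  expect_equal(trimws(substr(lines[1], 61, 66)), "999.99")
  expect_equal(trimws(substr(lines[9], 61, 66)), "0.00")  # missing -> 0
})
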