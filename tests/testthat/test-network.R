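test_that("contact persistence thresholds follow the 5.5 A / 75% rule", {
  # two sites at fixed separations across 4 frames
  mkPair <- function(dists) {
    arr <- array(0, c(length(dists), 2, 3))
    arr[, 2, 1] <- dists
    makeSiteTrajectory(arr)
  }
  cm55 <- contactMap(mkPair(rep(5.0, 4)))
  expect_true(cm55@adjacency[1, 2])
  expect_equal(cm55@fraction[1, 2], 1.0)
  expect_false(contactMap(mkPair(rep(6.0, 4)))@adjacency[1, 2])
  # in contact half the frames: 0.5 < 0.75 -> no contact
  half <- contactMap(mkPair(c(5, 5, 7, 7)))
  expect_equal(half@fraction[1, 2], 0.5)
  expect_false(half@adjacency[1, 2])
})

test_that("atomic contact maps use any heavy-atom pair between residues", {
  m <- readTopology(writeTempPDB(dipeptideLines()))
  arr <- array(NA_real_, c(2, 9, 3))
  for (f in 1:2) arr[f, , ] <- as.matrix(m@atoms[, c("x", "y", "z")])
  tr <- new("Trajectory", coords = arr, dt = NA_real_)
  cmap <- contactMap(tr, m, distanceCutoff = 2.0)
  # the peptide bond C(1)-N(2) is ~1.33 A: residues are in contact
  expect_true(cmap@adjacency[1, 2])
  expect_false(any(diag(cmap@adjacency)))
})

test_that("network edges carry w = -log(GC) and drop zero-GC contacts", {
  arr <- array(0, c(2, 3, 3))
  arr[, 2, 1] <- 3; arr[, 3, 1] <- 3.4
  st <- makeSiteTrajectory(arr)
  cmap <- contactMap(st, distanceCutoff = 3.5)  # all three pairs touch
  g <- matrix(c(1, 0.5, 0, 0.5, 1, 0.8, 0, 0.8, 1), 3)
  cm <- makeCM(g)
  expect_warning(net <- buildNetwork(cmap, cm), "GC = 0")
  e <- networkEdges(net)
  expect_equal(nrow(e), 2L)  # the GC = 0 contact was dropped
  expect_equal(sort(e$w), sort(-log(c(0.5, 0.8))), tolerance = 1e-12)

  g2 <- g; g2[2, 3] <- g2[3, 2] <- 1; g2[1, 3] <- g2[3, 1] <- 0.4
  expect_message(net2 <- buildNetwork(cmap, makeCM(g2)), "zero-length")
  expect_equal(min(networkEdges(net2)$w), 0)

  other <- makeCM(g, makeSites(3, chain = "B"))
  expect_error(buildNetwork(cmap, other), "alignment error")
})

test_that("shortest paths match hand solutions and exhaustive enumeration", {
  tri <- makeNet(data.frame(from = c("A", "B", "A"), to = c("B", "C", "C"),
                            gc = exp(-c(1, 1, 3)),
                            stringsAsFactors = FALSE))
  sp <- shortestPath(tri, "A", "C")
  expect_equal(sp$nodes, c("A", "B", "C"))
  expect_equal(sp$length, 2)

  single <- makeNet(data.frame(from = "A", to = "B", gc = 0.5,
                               stringsAsFactors = FALSE))
  expect_equal(shortestPath(single, "A", "B")$nodes, c("A", "B"))

  # unreachable pair: explicit status, not an exception
  disc <- makeNet(data.frame(from = "A", to = "B", gc = 0.5,
                             stringsAsFactors = FALSE),
                  nodes = c("A", "B", "C"))
  expect_equal(shortestPath(disc, "A", "C")$status, "unreachable")

  set.seed(51)
  for (rep in 1:25) {
    n <- sample(5:8, 1)
    net <- randomConnectedNet(n)
    W <- netWeightMatrix(net)
    apsp <- allPairsShortestPaths(net)
    # against exhaustive enumeration (exact)
    for (t in 2:n) {
      expect_equal(unname(apsp$dist[1, t]), bruteShortestLength(W, 1, t))
    }
    # path reconstruction is consistent with the reported length
    p <- shortestPath(net, "A:1", sprintf("A:%d", n), apsp)
    steps <- cbind(head(p$nodes, -1), p$nodes[-1])
    expect_equal(sum(W[steps]), p$length, tolerance = 1e-9)
    # and against igraph as an independent implementation
    g <- asIgraph(net)
    dIg <- igraph::distances(g, weights = igraph::E(g)$w)
    expect_equal(unname(apsp$dist[rownames(dIg), colnames(dIg)]),
                 unname(dIg), tolerance = 1e-12)
  }
})

test_that("suboptimal path sets equal brute-force enumeration", {
  # threshold arithmetic on a hand graph with path lengths 10, 10.1, 10.3
  hand <- makeNet(data.frame(
    from = c("S", "S", "S", "P", "Q", "R"),
    to = c("P", "Q", "R", "T", "T", "T"),
    gc = exp(-c(5, 5.05, 5.15, 5, 5.05, 5.15)),
    stringsAsFactors = FALSE))
  got <- suboptimalPaths(hand, "S", "T", tolerance = 0.02)
  expect_equal(vapply(got, `[[`, numeric(1), "length"), c(10, 10.1),
               tolerance = 1e-9)
  expect_equal(got[[1]]$status, "shortest")
  expect_equal(got[[2]]$status, "suboptimal")

  # unique path topology: exactly the shortest
  chain <- makeNet(data.frame(from = c("A", "B"), to = c("B", "C"),
                              gc = c(0.5, 0.5), stringsAsFactors = FALSE))
  expect_length(suboptimalPaths(chain, "A", "C"), 1L)

  set.seed(52)
  for (rep in 1:15) {
    n <- 7
    net <- randomConnectedNet(n, pEdge = 0.45)
    W <- netWeightMatrix(net)
    tol <- 0.25
    brute <- allSimplePaths(W, 1, n)
    lim <- min(brute$lengths) * (1 + tol) + 1e-9
    keep <- which(brute$lengths <= lim)
    bruteSet <- sort(vapply(keep, function(i)
      paste(brute$paths[[i]], collapse = "-"), character(1)))
    got <- suboptimalPaths(net, "A:1", sprintf("A:%d", n), tolerance = tol)
    gotSet <- sort(vapply(got, function(p)
      paste(match(p$nodes, networkNodes(net)$name), collapse = "-"),
      character(1)))
    expect_equal(gotSet, bruteSet)
  }

  # truncation is loud, never silent
  dense <- randomConnectedNet(8, pEdge = 1)
  expect_warning(suboptimalPaths(dense, "A:1", "A:8", tolerance = 5,
                                 maxPaths = 3L), "truncated")
})

test_that("edge betweenness matches hand counts and igraph", {
  pg <- makeNet(data.frame(from = c("A", "B"), to = c("B", "C"),
                           gc = c(0.5, 0.5), stringsAsFactors = FALSE))
  eb <- edgeBetweenness(pg)
  expect_equal(eb$betweenness, c(2, 2))  # pairs (A,B),(A,C) and (B,C),(A,C)
  expect_equal(edgeBetweenness(pg, "census")$betweenness, c(2, 2))

  # barbell: the bridge edge has maximal betweenness
  bb <- twoCliqueBridgeNet()
  ebb <- edgeBetweenness(bb)
  bridge <- which(ebb$from == "A:1" & ebb$to == "A:6")
  expect_equal(which.max(ebb$betweenness), bridge)

  set.seed(53)
  for (rep in 1:10) {
    net <- randomConnectedNet(sample(5:8, 1))
    mine <- edgeBetweenness(net)
    g <- asIgraph(net)
    ig <- igraph::edge_betweenness(g, weights = igraph::E(g)$w)
    expect_equal(mine$betweenness, ig, tolerance = 1e-9)
  }
})

test_that("modularity matches hand values and the adjacency definition", {
  bb <- twoCliqueBridgeNet()
  nodes <- networkNodes(bb)$name
  cliquePart <- setNames(rep(0:1, each = 5L), nodes)
  expect_equal(modularityScore(bb, cliquePart), 10 / 21 * 2 - 0.5,
               tolerance = 1e-12)
  # single community: exactly zero
  expect_identical(modularityScore(bb, setNames(rep(0L, 10), nodes)), 0)

  set.seed(54)
  for (rep in 1:10) {
    net <- randomConnectedNet(6)
    memb <- setNames(sample(0:2, 6, TRUE), networkNodes(net)$name)
    expect_equal(modularityScore(net, memb), bruteModularity(net, memb),
                 tolerance = 1e-12)
    g <- asIgraph(net)
    expect_equal(modularityScore(net, memb),
                 igraph::modularity(g, memb[igraph::V(g)$name] + 1,
                                    weights = igraph::E(g)$gc),
                 tolerance = 1e-12)
  }
})

test_that("Girvan-Newman recovers planted structure and bounds modularity", {
  bb <- twoCliqueBridgeNet()
  part <- girvanNewman(bb)
  expect_equal(part@nCommunities, 2L)
  expect_equal(modularityValue(part), 19 / 42, tolerance = 1e-9)
  memb <- communityIds(part)
  expect_length(unique(memb[sprintf("A:%d", 1:5)]), 1L)
  expect_length(unique(memb[sprintf("A:%d", 6:10)]), 1L)

  # complete graph: no community structure, single community returned
  ed6 <- t(combn(6, 2))
  k6 <- makeNet(data.frame(from = sprintf("A:%d", ed6[, 1]),
                           to = sprintf("A:%d", ed6[, 2]), gc = 0.7,
                           stringsAsFactors = FALSE))
  p6 <- girvanNewman(k6)
  expect_equal(p6@nCommunities, 1L)
  expect_identical(modularityValue(p6), 0)

  # never exceeds the exhaustive maximum over all partitions (n <= 7),
  # determined with the independent modularity oracle
  set.seed(55)
  for (rep in 1:3) {
    net <- randomConnectedNet(6, pEdge = 0.5)
    nodes <- networkNodes(net)$name
    parts <- allPartitions(6)
    qBest <- max(vapply(parts, function(p)
      bruteModularity(net, setNames(p, nodes)), numeric(1)))
    expect_lte(modularityValue(girvanNewman(net)), qBest + 1e-9)
  }

  # deterministic output on repeated runs
  expect_identical(communityIds(girvanNewman(bb)), memb)
})

test_that("CRD is an exhaustively verified pseudometric", {
  p1 <- setNames(c(0L, 0L, 1L, 1L), letters[1:4])
  p2 <- setNames(c(0L, 1L, 0L, 1L), letters[1:4])
  expect_identical(crd(p1, p1), 0)
  expect_equal(crd(p1, p2), 4 / 6)
  expect_equal(crd(p1, p2), bruteCRD(p1, p2))

  set.seed(56)
  for (rep in 1:20) {
    n <- sample(5:9, 1)
    a <- setNames(sample(0:2, n, TRUE), paste0("n", seq_len(n)))
    b <- setNames(sample(0:2, n, TRUE), paste0("n", seq_len(n)))
    cc <- setNames(sample(0:2, n, TRUE), paste0("n", seq_len(n)))
    expect_equal(crd(a, b), crd(b, a))
    expect_equal(crd(a, b), bruteCRD(a, b), tolerance = 1e-12)
    expect_gte(crd(a, b), 0)
    # empirical triangle inequality
    expect_lte(crd(a, cc), crd(a, b) + crd(b, cc) + 1e-12)
  }

  expect_error(crd(p1, setNames(0:2, letters[1:3])), "alignment error")
})

test_that("path structure is invariant to the logarithm base of the weights", {
  set.seed(57)
  net <- randomConnectedNet(7)
  # log10 lengths are a uniform rescaling of the natural-log lengths
  net10 <- net
  net10@edges$w <- -log10(net10@edges$gc)
  spA <- suboptimalPaths(net, "A:1", "A:7", tolerance = 0.02)
  spB <- suboptimalPaths(net10, "A:1", "A:7", tolerance = 0.02)
  expect_equal(lapply(spA, `[[`, "nodes"), lapply(spB, `[[`, "nodes"))
  expect_equal(vapply(spB, `[[`, numeric(1), "length") /
               vapply(spA, `[[`, numeric(1), "length"),
               rep(1 / log(10), length(spA)), tolerance = 1e-9)
})

test_that("cutoff scans report CRD across the grid and record misses", {
  toy <- toyTwoDomainTrajectory(seed = 2, nFrames = 400)
  cm <- makeCM(analyticGC(toy$spec), toy$spec@sites)
  scan <- cutoffScan(toy$traj, cm = cm, distanceGrid = c(1, 5.5, 5.5),
                     frameGrid = 0.75)
  # identical neighbouring grid points agree exactly
  last <- scan[scan$distance1 == 5.5 & scan$distance2 == 5.5, ]
  expect_true(nrow(last) >= 1 && all(last$crd == 0))
  # a 1 A cutoff yields an empty network, recorded as missing
  expect_true(is.na(scan$crd[scan$distance1 == 1][1]))
  expect_true(is.null(attr(scan, "partitions")[[1]]))
})

test_that("networks export to edge-list TSV and GraphML", {
  net <- twoCliqueBridgeNet()
  tf <- tempfile(fileext = ".tsv")
  writeNetwork(net, tf)
  e <- read.table(tf, header = TRUE, sep = "\t")
  expect_equal(nrow(e), 21L)
  expect_equal(e$w, -log(e$gc), tolerance = 1e-9)
  gf <- tempfile(fileext = ".graphml")
  writeNetwork(net, gf, format = "graphml")
  g2 <- igraph::read_graph(gf, format = "graphml")
  expect_equal(igraph::gorder(g2), 10)
  expect_equal(igraph::gsize(g2), 21)
})
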