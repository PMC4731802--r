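# In-code fixtures shared across the suite.

# fixed-width PDB ATOM record
pdbLine <- function(eleno, name, resid, chain, resno, x, y, z, element) {
  paste0("ATOM  ", sprintf("%5d", eleno), " ", sprintf("%-4s", name), " ",
         sprintf("%-3s", resid), " ", chain, sprintf("%4d", resno), "    ",
         sprintf("%8.3f%8.3f%8.3f", x, y, z), sprintf("%6.2f%6.2f", 1, 0),
         "          ", sprintf("%2s", element))
}

# 2-residue, 9-atom dipeptide (matches inst/extdata/toy_dipeptide.pdb)
dipeptideLines <- function() {
  c(pdbLine(1, "N",  "ALA", "A", 1, 0.0,   0.0,   0.0,    "N"),
    pdbLine(2, "CA", "ALA", "A", 1, 1.458, 0.0,   0.0,    "C"),
    pdbLine(3, "C",  "ALA", "A", 1, 2.009, 1.420, 0.0,    "C"),
    pdbLine(4, "O",  "ALA", "A", 1, 1.251, 2.390, 0.0,    "O"),
    pdbLine(5, "CB", "ALA", "A", 1, 1.988, -0.773, -1.199, "C"),
    pdbLine(6, "N",  "GLY", "A", 2, 3.332, 1.536, 0.0,    "N"),
    pdbLine(7, "CA", "GLY", "A", 2, 4.001, 2.832, 0.0,    "C"),
    pdbLine(8, "C",  "GLY", "A", 2, 5.513, 2.662, 0.0,    "C"),
    pdbLine(9, "O",  "GLY", "A", 2, 6.012, 1.533, 0.0,    "O"),
    "END")
}

writeTempPDB <- function(lines) {
  tf <- tempfile(fileext = ".pdb")
  writeLines(lines, tf)
  tf
}

# minimal site metadata table
makeSites <- function(n, chain = "A", domain = NA_character_) {
  data.frame(resno = seq_len(n), resid = "ALA", chain = chain,
             domain = domain, stringsAsFactors = FALSE)
}

makeSiteTrajectory <- function(arr, sites = NULL) {
  if (is.null(sites)) sites <- makeSites(dim(arr)[2])
  new("SiteTrajectory", coords = arr, sites = sites, d = 3L)
}

# WeightedNetwork from an edge table (gc given; w derived)
makeNet <- function(edges, nodes = NULL, trueLabel = NA_integer_) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$from, edges$to)))
  nd <- data.frame(name = nodes, resno = seq_along(nodes), chain = "A",
                   domain = NA_character_, trueLabel = trueLabel,
                   stringsAsFactors = FALSE)
  edges$w <- -log(edges$gc)
  new("WeightedNetwork", nodes = nd, edges = edges)
}

# CorrelationMatrix around a given GC matrix (for score bookkeeping)
makeCM <- function(g, sites = NULL) {
  n <- nrow(g)
  g <- (g + t(g)) / 2
  diag(g) <- 1
  if (is.null(sites)) sites <- makeSites(n)
  mi <- -3 / 2 * log(1 - pmin(g, 1 - 1e-12)^2)
  diag(mi) <- NA_real_
  new("CorrelationMatrix", gc = g, mi = mi, k = 6L, nFrames = 1000L,
      d = 3L, nReplicas = 1L, sites = sites)
}

# random connected weighted graph on n nodes (gc weights)
randomConnectedNet <- function(n, pEdge = 0.5) {
  repeat {
    ed <- t(combn(n, 2))
    keep <- runif(nrow(ed)) < pEdge
    # always keep a spanning path so connectivity is likely
    path <- (ed[, 2] - ed[, 1]) == 1
    ed2 <- ed[keep | path, , drop = FALSE]
    edges <- data.frame(from = sprintf("A:%d", ed2[, 1]),
                        to = sprintf("A:%d", ed2[, 2]),
                        gc = runif(nrow(ed2), 0.3, 0.95),
                        stringsAsFactors = FALSE)
    net <- makeNet(edges, nodes = sprintf("A:%d", seq_len(n)))
    if (igraph::is_connected(asIgraph(net))) return(net)
  }
}

# two K5 cliques joined by a single bridge edge, uniform weights
twoCliqueBridgeNet <- function(gc = 0.5) {
  ed <- NULL
  for (i in 1:4) for (j in (i + 1):5) ed <- rbind(ed, c(i, j), c(i + 5, j + 5))
  ed <- rbind(ed, c(1, 6))
  edges <- data.frame(from = sprintf("A:%d", ed[, 1]),
                      to = sprintf("A:%d", ed[, 2]), gc = gc,
                      stringsAsFactors = FALSE)
  makeNet(edges, nodes = sprintf("A:%d", 1:10),
          trueLabel = rep(0:1, each = 5L))
}
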