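## Synthetic fluctuation ensembles with analytically known correlation
## structure, and random graphs with planted communities.  These give
## every downstream estimator an exact oracle.

#' Construct an elastic-network Gaussian ensemble specification
#'
#' Sites are beads connected by Hookean springs (a Gaussian network
#' model).  The per-axis site covariance is \code{kT} times the
#' (pseudo-)inverse of the Kirchhoff matrix; 3-D fluctuations are
#' isotropic, independent across axes.  Optional per-site anchor
#' springs tether sites to the laboratory frame, removing the rigid
#' translation mode so the covariance becomes full rank; without
#' anchors the uniform-translation null mode is projected out
#' (fluctuations are taken about a fixed mean structure, so no
#' superposition is needed for generated data).
#'
#' @param nSites number of sites.
#' @param edges two-column matrix/data.frame of connected site pairs.
#' @param springs per-edge spring constants, recycled (default 1).
#' @param anchors per-site tether constants, recycled (default 0).
#' @param kT temperature scale of the covariance (default 1).
#' @param refGeometry n x 3 mean structure; default is a straight chain
#'   with 3.8 Angstrom spacing.
#' @param sites optional site metadata data.frame (resno, resid, chain,
#'   domain); default chain A, residue types cycled over 20 amino acids.
#' @param seed RNG seed used when sampling from the spec.
#' @return a \code{\link{GaussianEnsembleSpec}}.
#' @examples
#' spec <- gaussianEnsembleSpec(5, cbind(1:4, 2:5), anchors = 0.2, seed = 1)
#' analyticGC(spec, 1, 2)
#' @export
gaussianEnsembleSpec <- function(nSites, edges, springs = 1, anchors = 0,
                                 kT = 1, refGeometry = NULL, sites = NULL,
                                 seed = 1L) {
  nSites <- as.integer(nSites)
  edges <- as.matrix(edges)
  storage.mode(edges) <- "integer"
  if (nrow(edges) && (any(edges < 1) || any(edges > nSites) ||
                      any(edges[, 1] == edges[, 2])))
    stop("edges must connect distinct sites in 1..nSites")
  springs <- rep_len(springs, nrow(edges))
  anchors <- rep_len(anchors, nSites)
  if (any(springs <= 0) || any(anchors < 0))
    stop("spring constants must be positive, anchors non-negative")

  K <- matrix(0, nSites, nSites)
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    K[i, j] <- K[i, j] - springs[e]
    K[j, i] <- K[j, i] - springs[e]
    K[i, i] <- K[i, i] + springs[e]
    K[j, j] <- K[j, j] + springs[e]
  }
  diag(K) <- diag(K) + anchors

  eg <- eigen(K, symmetric = TRUE)
  tol <- 1e-9 * max(abs(eg$values), 1)
  null <- eg$values < tol
  expectedNull <- if (all(anchors == 0)) 1L else 0L
  if (sum(null) > expectedNull)
    warning("elastic network is disconnected: ", sum(null) - expectedNull,
            " extra zero mode(s); the corresponding motions carry no ",
            "fluctuation")
  inv <- ifelse(null, 0, 1 / pmax(eg$values, tol))
  C <- kT * (eg$vectors %*% (inv * t(eg$vectors)))
  C <- (C + t(C)) / 2

  if (is.null(refGeometry))
    refGeometry <- cbind(3.8 * (seq_len(nSites) - 1), 0, 0)
  refGeometry <- as.matrix(refGeometry)
  if (is.null(sites)) {
    aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
            "TYR", "VAL")
    sites <- data.frame(resno = seq_len(nSites),
                        resid = rep_len(aa, nSites),
                        chain = "A", domain = NA_character_,
                        stringsAsFactors = FALSE)
  }
  new("GaussianEnsembleSpec", nSites = nSites, edges = edges,
      springs = springs, anchors = anchors, kT = kT, covariance = C,
      refGeometry = refGeometry, sites = sites, seed = as.integer(seed))
}

#' Sample a fluctuation ensemble from an elastic-network spec
#'
#' Frames are drawn i.i.d. from the multivariate normal defined by the
#' spec: each Cartesian axis is an independent draw with the spec's
#' per-axis site covariance, added to the fixed reference geometry.
#' Sampling is fully reproducible from \code{spec@seed}.
#'
#' @param spec a \code{\link{GaussianEnsembleSpec}}.
#' @param nFrames number of frames (>= 2).
#' @return a \code{\link{SiteTrajectory}}.
#' @export
buildGaussianEnsemble <- function(spec, nFrames) {
  stopifnot(is(spec, "GaussianEnsembleSpec"))
  nFrames <- as.integer(nFrames)
  if (nFrames < 2) stop("nFrames must be at least 2")
  n <- spec@nSites
  set.seed(spec@seed)
  arr <- array(NA_real_, dim = c(nFrames, n, 3))
  for (ax in 1:3) {
    flux <- MASS::mvrnorm(nFrames, mu = rep(0, n), Sigma = spec@covariance)
    arr[, , ax] <- sweep(flux, 2, spec@refGeometry[, ax], `+`)
  }
  new("SiteTrajectory", coords = arr, sites = spec@sites, d = 3L)
}

#' Closed-form generalized correlation of a Gaussian ensemble
#'
#' For jointly Gaussian site fluctuations the mutual information is
#' available in closed form,
#' \eqn{I_{ij} = \frac{1}{2}\ln(\det\Sigma_i \det\Sigma_j /
#' \det\Sigma_{ij})}, which maps to the generalized correlation
#' coefficient \eqn{GC_{ij} = \{1 - \exp(-2 I_{ij}/3)\}^{1/2}}.  This is
#' the exact value the k-NN estimator converges to on ensembles drawn
#' from the spec.
#'
#' @param spec a \code{\link{GaussianEnsembleSpec}}.
#' @param i,j site indices; omit both to get the full matrix.
#' @return a GC value in [0, 1], or the full symmetric matrix with unit
#'   diagonal.
#' @export
analyticGC <- function(spec, i = NULL, j = NULL) {
  stopifnot(is(spec, "GaussianEnsembleSpec"))
  C <- spec@covariance
  one <- function(i, j) {
    a <- C[i, i]; b <- C[j, j]; cc <- C[i, j]
    if (a <= 0 || b <= 0)
      stop("numeric error: singular marginal block for site ", i, " or ", j,
           " (site carries no fluctuation; disconnected without anchor?)")
    S <- rbind(cbind(diag(a, 3), diag(cc, 3)),
               cbind(diag(cc, 3), diag(b, 3)))
    dj <- max(det(S), 0)
    if (dj == 0) return(1)
    mi <- 0.5 * log(a^3 * b^3 / dj)
    sqrt(max(0, 1 - exp(-2 * mi / 3)))
  }
  if (!is.null(i) && !is.null(j)) return(one(i, j))
  n <- spec@nSites
  G <- diag(1, n)
  for (p in seq_len(n - 1)) {
    for (q in (p + 1):n) G[p, q] <- G[q, p] <- one(p, q)
  }
  G
}

#' Topology model for the sites of a synthetic ensemble
#'
#' Builds a minimal \code{\link{StructureModel}} with one CA
#' pseudo-atom per site at the spec's reference geometry, so that
#' synthetic ensembles can flow through the same file-based pipeline as
#' real systems (topology writing, contact maps, B-factor export).
#'
#' @param spec a \code{\link{GaussianEnsembleSpec}}.
#' @return a \code{\link{StructureModel}}.
#' @export
siteTopology <- function(spec) {
  stopifnot(is(spec, "GaussianEnsembleSpec"))
  s <- spec@sites
  atoms <- data.frame(
    eleno = seq_len(nrow(s)), name = "CA", element = "C",
    resno = s$resno, resid = s$resid, chain = s$chain,
    x = spec@refGeometry[, 1], y = spec@refGeometry[, 2],
    z = spec@refGeometry[, 3],
    hydrogen = FALSE, stringsAsFactors = FALSE)
  new("StructureModel", atoms = atoms, residues = s, pdb = list())
}

#' Construct a planted-partition graph specification
#'
#' @param sizes community sizes (>= 2 communities of >= 3 nodes).
#' @param pIn within-community edge probability.
#' @param pOut between-community edge probability (< pIn).
#' @param wMin,wMax edge correlation strengths drawn uniformly from
#'   \code{[wMin, wMax]} (must lie in (0, 1] so edge lengths
#'   \eqn{-\log w} are non-negative).
#' @param seed RNG seed.
#' @return a \code{\link{PlantedGraphSpec}}.
#' @export
plantedGraphSpec <- function(sizes, pIn, pOut, wMin = 0.5, wMax = 0.9,
                             seed = 1L) {
  new("PlantedGraphSpec", sizes = as.integer(sizes), pIn = pIn, pOut = pOut,
      wMin = wMin, wMax = wMax, seed = as.integer(seed))
}

#' Sample a weighted graph with planted community structure
#'
#' Draws a stochastic-block-model graph, attaches ground-truth labels
#' to the nodes and uniform random correlation weights to the edges.
#' Disconnected draws are rejected and resampled (up to 10 attempts).
#'
#' @param spec a \code{\link{PlantedGraphSpec}}.
#' @return a \code{\link{WeightedNetwork}} whose nodes carry
#'   \code{trueLabel} (0-based community ids).
#' @export
plantedPartitionGraph <- function(spec) {
  stopifnot(is(spec, "PlantedGraphSpec"))
  n <- sum(spec@sizes)
  k <- length(spec@sizes)
  pref <- matrix(spec@pOut, k, k)
  diag(pref) <- spec@pIn
  set.seed(spec@seed)
  g <- NULL
  for (attempt in 1:10) {
    cand <- igraph::sample_sbm(n, pref.matrix = pref,
                               block.sizes = spec@sizes)
    if (igraph::is_connected(cand)) { g <- cand; break }
  }
  if (is.null(g))
    stop("could not draw a connected planted graph in 10 attempts; ",
         "increase pIn/pOut or community sizes")
  el <- igraph::as_edgelist(g, names = FALSE)
  gcw <- runif(nrow(el), spec@wMin, spec@wMax)
  labels <- rep(seq_along(spec@sizes) - 1L, spec@sizes)
  nodeName <- sprintf("A:%d", seq_len(n))
  nodes <- data.frame(name = nodeName, resno = seq_len(n), chain = "A",
                      domain = NA_character_, trueLabel = labels,
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = nodeName[el[, 1]], to = nodeName[el[, 2]],
                      gc = gcw, w = -log(gcw), stringsAsFactors = FALSE)
  new("WeightedNetwork", nodes = nodes, edges = edges)
}

# Elastic-network design of the desk-scale two-domain fixture: two
# 10-site chains (chains A and B, domains "alpha" and "beta") lying
# side by side 4.6 A apart, stiff backbone springs within each chain,
# weak anchors to suppress global drift, and two designed cross-domain
# springs -- a strong one (A:5 -- B:5) and a weaker one (A:8 -- B:8).
.toyTwoDomainSpec <- function(seed = 1L) {
  nPer <- 10L
  n <- 2L * nPer
  backbone <- rbind(cbind(1:(nPer - 1), 2:nPer),
                    cbind(nPer + 1:(nPer - 1), nPer + 2:nPer))
  nextNear <- rbind(cbind(1:(nPer - 2), 3:nPer),
                    cbind(nPer + 1:(nPer - 2), nPer + 3:nPer))
  cross <- rbind(c(5L, nPer + 5L), c(8L, nPer + 8L))
  edges <- rbind(backbone, nextNear, cross)
  springs <- c(rep(6, nrow(backbone)), rep(1.5, nrow(nextNear)), 10, 2.5)
  # gently helical chains: a non-planar reference keeps the rigid-body
  # fit well conditioned when the pipeline superposes the frames
  t <- 0:(nPer - 1)
  ref <- rbind(cbind(3.8 * t, 1.2 * sin(1.1 * t), 1.2 * cos(1.1 * t)),
               cbind(3.8 * t, 4.6 + 1.2 * sin(1.1 * t),
                     1.2 * cos(1.1 * t)))
  aa <- c("ALA", "ARG", "ASN", "ASP", "GLN", "GLU", "GLY", "HIS", "ILE",
          "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR",
          "VAL", "SER")
  sites <- data.frame(
    resno = rep(seq_len(nPer), 2),
    resid = aa,
    chain = rep(c("A", "B"), each = nPer),
    domain = rep(c("alpha", "beta"), each = nPer),
    stringsAsFactors = FALSE)
  gaussianEnsembleSpec(n, edges, springs = springs, anchors = 0.5,
                       kT = 0.8, refGeometry = ref, sites = sites,
                       seed = seed)
}

#' Desk-scale two-domain fixture ensemble
#'
#' A 20-site elastic-network ensemble in two labelled domains (chains A
#' and B) with strong within-domain couplings and two designed
#' cross-domain couplings, A:5--B:5 (strong) and A:8--B:8 (weaker).
#' The designed pairs are recorded so tests can verify that the
#' estimated inter-domain correlation ranking recovers them.
#'
#' @param seed RNG seed.
#' @param nFrames frames to sample (default 10000).
#' @return list with elements \code{traj} (a
#'   \code{\link{SiteTrajectory}}), \code{spec} (the generating
#'   \code{\link{GaussianEnsembleSpec}}), \code{model} (matching
#'   \code{\link{StructureModel}}), \code{coupledPairs} (data.frame of
#'   the designed cross-domain pairs) and \code{domainMap}.
#' @export
toyTwoDomainTrajectory <- function(seed = 1L, nFrames = 10000L) {
  spec <- .toyTwoDomainSpec(as.integer(seed))
  traj <- buildGaussianEnsemble(spec, nFrames)
  coupled <- data.frame(from = c("A:5", "A:8"), to = c("B:5", "B:8"),
                        stringsAsFactors = FALSE)
  domainMap <- data.frame(chain = c("A", "B"), start = 1L, end = 10L,
                          domain = c("alpha", "beta"),
                          stringsAsFactors = FALSE)
  list(traj = traj, spec = spec, model = siteTopology(spec),
       coupledPairs = coupled, domainMap = domainMap)
}

#' Serialize an ensemble spec to a structured text config
#'
#' Writes the defining fields (topology, spring constants, anchors,
#' temperature scale, reference geometry, site metadata, seed) as YAML;
#' the derived covariance is reconstructed on read, so the round trip
#' is exact up to floating-point reproducibility of the eigensolve.
#'
#' @param spec a \code{\link{GaussianEnsembleSpec}}.
#' @param path output YAML file.
#' @return \code{path}, invisibly.
#' @export
writeEnsembleSpec <- function(spec, path) {
  stopifnot(is(spec, "GaussianEnsembleSpec"))
  yaml::write_yaml(list(
    nSites = spec@nSites,
    edges = apply(spec@edges, 1, as.list),
    springs = as.list(spec@springs),
    anchors = as.list(spec@anchors),
    kT = spec@kT,
    refGeometry = apply(spec@refGeometry, 1, as.list),
    sites = lapply(seq_len(nrow(spec@sites)), function(i)
      as.list(spec@sites[i, ])),
    seed = spec@seed), path, precision = 17L)
  invisible(path)
}

#' Read an ensemble spec from a structured text config
#'
#' @param path YAML file written by \code{\link{writeEnsembleSpec}}.
#' @return a \code{\link{GaussianEnsembleSpec}}.
#' @export
readEnsembleSpec <- function(path) {
  y <- yaml::read_yaml(path)
  edges <- if (length(y$edges))
    do.call(rbind, lapply(y$edges, unlist)) else matrix(integer(0), 0, 2)
  sites <- do.call(rbind, lapply(y$sites, function(s)
    data.frame(resno = s$resno, resid = s$resid, chain = s$chain,
               domain = if (is.null(s$domain)) NA_character_ else s$domain,
               stringsAsFactors = FALSE)))
  gaussianEnsembleSpec(
    nSites = y$nSites, edges = edges, springs = unlist(y$springs),
    anchors = unlist(y$anchors), kT = y$kT,
    refGeometry = do.call(rbind, lapply(y$refGeometry, unlist)),
    sites = sites, seed = y$seed)
}
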