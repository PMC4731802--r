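## Contact-filtered weighted residue network: construction, shortest
## and sub-optimal communication pathways, edge betweenness,
## Girvan-Newman communities, modularity and the community repartition
## difference (CRD) convergence diagnostic.

#' Persistence-filtered residue contact map
#'
#' Two residues are in contact in a frame if any heavy-atom pair
#' between them lies within \code{distanceCutoff}; the pair counts as a
#' network contact if that holds in at least \code{frameCutoff} of the
#' frames.  The defaults (5.5 Angstrom, 75\% of frames) select
#' persistent physical contacts and discard transient encounters.
#'
#' @param x a \code{\link{Trajectory}} (atomic; needs \code{model}) or
#'   a \code{\link{SiteTrajectory}} (sites treated as single
#'   pseudo-atoms).
#' @param model the \code{\link{StructureModel}} matching an atomic
#'   trajectory.
#' @param distanceCutoff Angstrom, default 5.5.
#' @param frameCutoff fraction of frames, default 0.75.
#' @return a \code{\link{ContactMap}}.
#' @export
contactMap <- function(x, model = NULL, distanceCutoff = 5.5,
                       frameCutoff = 0.75) {
  stopifnot(distanceCutoff > 0, frameCutoff > 0, frameCutoff <= 1)
  if (is(x, "SiteTrajectory")) {
    arr <- x@coords
    sites <- x@sites
    nRes <- dim(arr)[2]
    frac <- matrix(0, nRes, nRes)
    cut2 <- distanceCutoff^2
    for (i in seq_len(nRes - 1)) {
      for (j in (i + 1):nRes) {
        d2 <- rowSums((arr[, i, , drop = TRUE] -
                       arr[, j, , drop = TRUE])^2)
        frac[i, j] <- frac[j, i] <- mean(d2 < cut2)
      }
    }
  } else if (is(x, "Trajectory")) {
    if (is.null(model))
      stop("an atomic Trajectory needs its StructureModel")
    atoms <- model@atoms
    res <- model@residues
    heavy <- which(!atoms$hydrogen)
    if (!length(heavy)) stop("annotation error: no heavy atoms in model")
    rk <- residueKey(res$chain, res$resno)
    ak <- residueKey(atoms$chain, atoms$resno)[heavy]
    R <- outer(ak, rk, `==`) * 1          # heavy-atom x residue indicator
    nRes <- nrow(res)
    sites <- res
    counts <- matrix(0, nRes, nRes)
    nf <- dim(x@coords)[1]
    for (f in seq_len(nf)) {
      D <- as.matrix(stats::dist(x@coords[f, heavy, ])) < distanceCutoff
      counts <- counts + (crossprod(R, D %*% R) > 0)
    }
    frac <- counts / nf
    diag(frac) <- 0
  } else {
    stop("x must be a Trajectory or SiteTrajectory")
  }
  diag(frac) <- 0
  adj <- frac >= frameCutoff
  diag(adj) <- FALSE
  new("ContactMap", fraction = frac, adjacency = adj,
      distanceCutoff = distanceCutoff, frameCutoff = frameCutoff,
      sites = sites)
}

#' Build the weighted residue network
#'
#' Takes an edge for every persistent contact and assigns it the length
#' \eqn{w_{ij} = -\log GC_{ij}}: strongly correlated contacts are short,
#' so minimum-length paths maximise the correlation carried along the
#' path.  Contacts with GC = 0 carry no information and are dropped
#' (warning); GC = 1 gives zero-length edges, which are kept but
#' reported since they make shortest paths degenerate.
#'
#' @param contacts a \code{\link{ContactMap}}.
#' @param cm a \code{\link{CorrelationMatrix}} over the same residues.
#' @return a \code{\link{WeightedNetwork}}.
#' @export
buildNetwork <- function(contacts, cm) {
  stopifnot(is(contacts, "ContactMap"), is(cm, "CorrelationMatrix"))
  kc <- residueKey(contacts@sites$chain, contacts@sites$resno)
  km <- residueKey(cm@sites$chain, cm@sites$resno)
  if (!identical(kc, km))
    stop("alignment error: contact map and correlation matrix cover ",
         "different residue lists")
  idx <- which(contacts@adjacency & upper.tri(contacts@adjacency),
               arr.ind = TRUE)
  gcv <- cm@gc[idx]
  zero <- gcv <= 0
  if (any(zero)) {
    warning(sum(zero), " contact(s) with GC = 0 dropped from the network")
    idx <- idx[!zero, , drop = FALSE]
    gcv <- gcv[!zero]
  }
  if (any(gcv >= 1))
    message(sum(gcv >= 1), " zero-length edge(s) (GC = 1) present")
  nodes <- data.frame(name = km,
                      resno = cm@sites$resno, chain = cm@sites$chain,
                      domain = cm@sites$domain, trueLabel = NA_integer_,
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = km[idx[, 1]], to = km[idx[, 2]],
                      gc = gcv, w = -log(gcv), stringsAsFactors = FALSE)
  new("WeightedNetwork", nodes = nodes, edges = edges)
}

#' Convert a WeightedNetwork to an igraph graph
#'
#' @param net a \code{\link{WeightedNetwork}}.
#' @return an undirected igraph object with edge attributes
#'   \code{weight} (the length w) and \code{gc}.
#' @export
asIgraph <- function(net) {
  stopifnot(is(net, "WeightedNetwork"))
  e <- net@edges
  e$weight <- e$w
  igraph::graph_from_data_frame(e, directed = FALSE,
                                vertices = net@nodes)
}

# length matrix (w, Inf off-edge) in node order; also GC adjacency
.lengthMatrix <- function(net) {
  n <- nrow(net@nodes)
  nm <- net@nodes$name
  W <- matrix(Inf, n, n, dimnames = list(nm, nm))
  G <- matrix(0, n, n, dimnames = list(nm, nm))
  diag(W) <- 0
  if (nrow(net@edges)) {
    i <- match(net@edges$from, nm)
    j <- match(net@edges$to, nm)
    W[cbind(i, j)] <- W[cbind(j, i)] <- net@edges$w
    G[cbind(i, j)] <- G[cbind(j, i)] <- net@edges$gc
  }
  list(W = W, G = G, names = nm)
}

# Floyd-Warshall with path reconstruction ("next hop" matrix).
# Deterministic: a path is replaced only on a strict improvement, so
# with the fixed node order the first-found lexicographic route wins.
.floydWarshall <- function(W) {
  n <- nrow(W)
  D <- W
  nxt <- matrix(NA_integer_, n, n)
  has <- is.finite(W) & row(W) != col(W)
  nxt[has] <- col(W)[has]
  diag(nxt) <- seq_len(n)
  for (k in seq_len(n)) {
    alt <- outer(D[, k], D[k, ], `+`)
    better <- alt < D
    if (any(better)) {
      D[better] <- alt[better]
      kcol <- matrix(nxt[, k], n, n)[better]
      nxt[better] <- kcol
    }
  }
  list(dist = D, nxt = nxt)
}

.reconstructPath <- function(nxt, i, j) {
  if (is.na(nxt[i, j])) return(NULL)
  path <- i
  while (i != j) {
    i <- nxt[i, j]
    path <- c(path, i)
  }
  path
}

#' All-pairs shortest path lengths
#'
#' Floyd-Warshall over the weighted network; lengths are sums of edge
#' lengths \eqn{w = -\log GC}.
#'
#' @param net a \code{\link{WeightedNetwork}}.
#' @return list with \code{dist} (named matrix, Inf = unreachable) and
#'   the internal predecessor structure used by
#'   \code{\link{shortestPath}}.
#' @export
allPairsShortestPaths <- function(net) {
  lm <- .lengthMatrix(net)
  fw <- .floydWarshall(lm$W)
  dimnames(fw$dist) <- list(lm$names, lm$names)
  list(dist = fw$dist, nxt = fw$nxt, names = lm$names)
}

.nodeIndex <- function(net, node) {
  i <- match(node, net@nodes$name)
  if (is.na(i)) stop("unknown node: ", node)
  i
}

#' Shortest communication pathway between two residues
#'
#' @param net a \code{\link{WeightedNetwork}}.
#' @param source,target node names (\code{"CHAIN:RESNO"}).
#' @param apsp optional precomputed \code{\link{allPairsShortestPaths}}
#'   result (to avoid recomputation in loops).
#' @return list with \code{nodes} (ordered node names, NULL if
#'   unreachable), \code{length}, \code{status} ("shortest" or
#'   "unreachable").
#' @export
shortestPath <- function(net, source, target, apsp = NULL) {
  if (is.null(apsp)) apsp <- allPairsShortestPaths(net)
  i <- .nodeIndex(net, source); j <- .nodeIndex(net, target)
  if (!is.finite(apsp$dist[i, j]))
    return(list(nodes = NULL, length = Inf, status = "unreachable"))
  p <- .reconstructPath(apsp$nxt, i, j)
  list(nodes = apsp$names[p], length = unname(apsp$dist[i, j]),
       status = "shortest")
}

#' Sub-optimal communication pathways
#'
#' Enumerates every simple path from source to target whose total
#' length is within \code{tolerance} (default 2\%) of the shortest
#' pathway length, by depth-first search pruned with exact
#' shortest-distance bounds to the target.  Near-degenerate path
#' families like these are the rule when communication runs through
#' consecutive residues of the same secondary structure.
#'
#' @param net a \code{\link{WeightedNetwork}}.
#' @param source,target node names.
#' @param tolerance admissible fractional excess over the shortest
#'   length (default 0.02).
#' @param maxPaths stop after this many admissible paths (default
#'   10000) with a warning; never silent.
#' @return list of path records (\code{nodes}, \code{length},
#'   \code{status} "shortest"/"suboptimal"), sorted by length.
#' @export
suboptimalPaths <- function(net, source, target, tolerance = 0.02,
                            maxPaths = 10000L) {
  stopifnot(tolerance >= 0)
  apsp <- allPairsShortestPaths(net)
  i0 <- .nodeIndex(net, source); j0 <- .nodeIndex(net, target)
  L <- apsp$dist[i0, j0]
  if (!is.finite(L)) stop("no path between ", source, " and ", target)
  eps <- 1e-9 * max(1, L)
  limit <- L * (1 + tolerance) + eps
  lm <- .lengthMatrix(net)
  n <- nrow(lm$W)
  adj <- lapply(seq_len(n), function(i) {
    js <- which(is.finite(lm$W[i, ]) & seq_len(n) != i)
    js[order(lm$W[i, js], js)]
  })
  toTarget <- apsp$dist[, j0]

  paths <- list()
  lens <- numeric(0)
  truncated <- FALSE
  onPath <- logical(n)
  visit <- function(v, len, trail) {
    if (truncated) return()
    if (v == j0) {
      paths[[length(paths) + 1L]] <<- trail
      lens[length(lens) + 1L] <<- len
      if (length(paths) >= maxPaths) truncated <<- TRUE
      return()
    }
    onPath[v] <<- TRUE
    for (u in adj[[v]]) {
      if (!onPath[u] && len + lm$W[v, u] + toTarget[u] <= limit)
        visit(u, len + lm$W[v, u], c(trail, u))
    }
    onPath[v] <<- FALSE
  }
  visit(i0, 0, i0)
  if (truncated)
    warning("path enumeration truncated at maxPaths = ", maxPaths,
            "; the sub-optimal set is incomplete")
  ord <- order(lens, vapply(paths, function(p)
    paste(sprintf("%04d", p), collapse = ""), character(1)))
  lapply(ord, function(o) {
    list(nodes = lm$names[paths[[o]]], length = lens[o],
         status = if (lens[o] <= L + eps) "shortest" else "suboptimal")
  })
}

# Brandes betweenness with Dijkstra (dense, fine for residue graphs).
# Returns per-edge fractional counts over unordered node pairs.
.brandesEdgeBetweenness <- function(W) {
  n <- nrow(W)
  eb <- matrix(0, n, n)
  tol <- 1e-10
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    sigma <- rep(0, n); sigma[s] <- 1
    preds <- vector("list", n)
    done <- logical(n)
    order_settled <- integer(0)
    repeat {
      cand <- which(!done & is.finite(dist))
      if (!length(cand)) break
      v <- cand[which.min(dist[cand])]
      done[v] <- TRUE
      order_settled <- c(order_settled, v)
      for (u in which(is.finite(W[v, ]))) {
        if (u == v) next
        alt <- dist[v] + W[v, u]
        reltol <- tol * max(1, abs(alt))
        if (alt < dist[u] - reltol) {
          dist[u] <- alt
          sigma[u] <- sigma[v]
          preds[[u]] <- v
        } else if (abs(alt - dist[u]) <= reltol && !done[u]) {
          sigma[u] <- sigma[u] + sigma[v]
          preds[[u]] <- c(preds[[u]], v)
        }
      }
    }
    delta <- rep(0, n)
    for (v in rev(order_settled)) {
      for (p in preds[[v]]) {
        c_pv <- sigma[p] / sigma[v] * (1 + delta[v])
        eb[p, v] <- eb[p, v] + c_pv
        eb[v, p] <- eb[v, p] + c_pv
        delta[p] <- delta[p] + c_pv
      }
    }
  }
  eb / 2  # each unordered pair contributes from both endpoints
}

#' Edge betweenness of the weighted network
#'
#' The number of all-pairs shortest pathways (weighted, by edge length)
#' crossing each edge.  Mode \code{"fractional"} splits ties among
#' equal-length shortest paths (the standard convention);
#' \code{"census"} counts one canonical (first-found lexicographic)
#' shortest path per unordered pair, giving integer counts.
#'
#' @param net a \code{\link{WeightedNetwork}}.
#' @param mode \code{"fractional"} or \code{"census"}.
#' @return the edge table of \code{net} with a \code{betweenness}
#'   column.
#' @export
edgeBetweenness <- function(net, mode = c("fractional", "census")) {
  mode <- match.arg(mode)
  lm <- .lengthMatrix(net)
  n <- nrow(lm$W)
  if (mode == "fractional") {
    eb <- .brandesEdgeBetweenness(lm$W)
  } else {
    fw <- .floydWarshall(lm$W)
    eb <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        p <- if (is.finite(fw$dist[i, j])) .reconstructPath(fw$nxt, i, j)
             else NULL
        if (length(p) >= 2) {
          for (s in seq_len(length(p) - 1)) {
            a <- p[s]; b <- p[s + 1]
            eb[a, b] <- eb[a, b] + 1
            eb[b, a] <- eb[b, a] + 1
          }
        }
      }
    }
  }
  out <- net@edges
  i <- match(out$from, lm$names); j <- match(out$to, lm$names)
  out$betweenness <- eb[cbind(i, j)]
  out
}

#' Newman-Girvan modularity of a partition
#'
#' \deqn{Q = \sum_c (e_{cc} - a_c^2)} with \eqn{e_{cc}} the fraction of
#' edge weight inside community c and \eqn{a_c} the fraction of edge
#' ends attached to c, using the correlation strengths (GC) as weights.
#' A single community always gives exactly 0.
#'
#' @param net a \code{\link{WeightedNetwork}}.
#' @param partition a \code{\link{CommunityPartition}} (or an integer
#'   vector named by node).
#' @return modularity Q.
#' @export
modularityScore <- function(net, partition) {
  membership <- if (is(partition, "CommunityPartition"))
    partition@membership else partition
  nm <- net@nodes$name
  if (!all(nm %in% names(membership)))
    stop("partition error: partition does not cover every node")
  m <- membership[nm]
  e <- net@edges
  if (!nrow(e)) return(0)
  wTot <- sum(e$gc)
  ci <- m[e$from]; cj <- m[e$to]
  eIn <- tapply(e$gc * (ci == cj), factor(ci, levels = unique(m)), sum)
  eIn[is.na(eIn)] <- 0
  strength <- setNames(rep(0, length(unique(m))), unique(m))
  for (lev in unique(m)) {
    strength[as.character(lev)] <-
      sum(e$gc[ci == lev]) + sum(e$gc[cj == lev])
  }
  sum(eIn / wTot) - sum((strength / (2 * wTot))^2)
}

.makePartition <- function(membership, q) {
  # relabel to contiguous ids from 0, in order of first appearance
  ids <- match(membership, unique(membership)) - 1L
  names(ids) <- names(membership)
  new("CommunityPartition", membership = ids, q = q,
      nCommunities = length(unique(ids)))
}

# connected components of an edge set over n nodes (BFS)
.componentsOf <- function(n, ei, ej) {
  comp <- rep(NA_integer_, n)
  cur <- 0L
  adj <- vector("list", n)
  for (e in seq_along(ei)) {
    adj[[ei[e]]] <- c(adj[[ei[e]]], ej[e])
    adj[[ej[e]]] <- c(adj[[ej[e]]], ei[e])
  }
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adj[[v]]) {
        if (is.na(comp[u])) { comp[u] <- cur; queue <- c(queue, u) }
      }
    }
  }
  comp
}

#' Girvan-Newman community detection
#'
#' Iteratively removes the edge with the highest (fractional,
#' shortest-path) betweenness, recomputing betweenness after every
#' removal, and records the partition into connected components each
#' time the network splits.  The returned partition is the one with
#' maximal modularity (computed on the full network with GC weights).
#' Betweenness ties are broken towards the lexicographically smallest
#' edge, so the procedure is seedless and fully reproducible.
#'
#' @param net a non-empty \code{\link{WeightedNetwork}}.
#' @return a \code{\link{CommunityPartition}}.
#' @export
girvanNewman <- function(net) {
  stopifnot(is(net, "WeightedNetwork"))
  if (!nrow(net@nodes)) stop("empty network")
  nm <- net@nodes$name
  n <- length(nm)
  e <- net@edges
  ei <- match(e$from, nm); ej <- match(e$to, nm)
  swap <- ei > ej
  tmp <- ei[swap]; ei[swap] <- ej[swap]; ej[swap] <- tmp

  best <- NULL
  consider <- function(compIds) {
    memb <- setNames(compIds, nm)
    q <- modularityScore(net, memb)
    if (is.null(best) || q > best$q + 1e-12)
      best <<- list(membership = memb, q = q)
  }
  consider(.componentsOf(n, ei, ej))
  nComp <- max(.componentsOf(n, ei, ej))

  alive <- rep(TRUE, length(ei))
  while (any(alive)) {
    W <- matrix(Inf, n, n)
    diag(W) <- 0
    idx <- which(alive)
    W[cbind(ei[idx], ej[idx])] <- e$w[idx]
    W[cbind(ej[idx], ei[idx])] <- e$w[idx]
    eb <- .brandesEdgeBetweenness(W)
    vals <- eb[cbind(ei[idx], ej[idx])]
    mx <- max(vals)
    cand <- idx[vals >= mx - 1e-9 * max(1, mx)]
    pick <- cand[order(ei[cand], ej[cand])][1]
    alive[pick] <- FALSE
    comp <- .componentsOf(n, ei[alive], ej[alive])
    if (max(comp) > nComp) {
      nComp <- max(comp)
      consider(comp)
    }
  }
  .makePartition(best$membership, best$q)
}

#' Community repartition difference between two partitions
#'
#' The fraction of node pairs whose co-membership status (together or
#' apart) differs between two partitions.  0 means identical grouping,
#' 1 maximal disagreement; used to verify that the community structure
#' has converged across contact-cutoff choices.
#'
#' @param p1,p2 \code{\link{CommunityPartition}}s (or named integer
#'   vectors) over the same node set.
#' @param normalize \code{"all-pairs"} divides by N(N-1)/2 (default);
#'   \code{"union-pairs"} divides by the number of pairs grouped
#'   together in at least one partition.
#' @return CRD value in [0, 1].
#' @export
crd <- function(p1, p2, normalize = c("all-pairs", "union-pairs")) {
  normalize <- match.arg(normalize)
  m1 <- if (is(p1, "CommunityPartition")) p1@membership else p1
  m2 <- if (is(p2, "CommunityPartition")) p2@membership else p2
  if (is.null(names(m1)) || is.null(names(m2)) ||
      !setequal(names(m1), names(m2)))
    stop("alignment error: partitions cover different node sets")
  m2 <- m2[names(m1)]
  z1 <- outer(m1, m1, `==`)
  z2 <- outer(m2, m2, `==`)
  ut <- upper.tri(z1)
  disagree <- sum(z1[ut] != z2[ut])
  denom <- if (normalize == "all-pairs") sum(ut)
           else sum(z1[ut] | z2[ut])
  if (denom == 0) return(0)
  disagree / denom
}

#' Community convergence scan over contact cutoffs
#'
#' Rebuilds the network and its optimal Girvan-Newman partition on a
#' grid of distance and frame cutoffs and reports the CRD between
#' neighbouring grid points.  A plateau of near-zero CRD identifies the
#' cutoff region where the community structure is converged, the
#' criterion used to justify the 5.5 Angstrom / 75\% defaults.
#'
#' @param x trajectory input accepted by \code{\link{contactMap}}.
#' @param model matching \code{\link{StructureModel}} (atomic input).
#' @param cm a \code{\link{CorrelationMatrix}}.
#' @param distanceGrid increasing distance cutoffs (Angstrom).
#' @param frameGrid frame cutoffs (default 0.75).
#' @param tolerance CRD below which neighbouring points count as
#'   converged (default 0.05).
#' @return data.frame with one row per neighbouring grid pair:
#'   cutoffs, \code{crd} (NA when a partition is missing) and
#'   \code{converged}.  Attribute \code{partitions} holds the per-point
#'   partitions (NULL for empty networks, recorded as missing).
#' @export
cutoffScan <- function(x, model = NULL, cm, distanceGrid,
                       frameGrid = 0.75, tolerance = 0.05) {
  stopifnot(length(distanceGrid) >= 1, length(frameGrid) >= 1)
  grid <- expand.grid(distance = distanceGrid, frame = frameGrid,
                      KEEP.OUT.ATTRS = FALSE)
  parts <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cmap <- contactMap(x, model, distanceCutoff = grid$distance[g],
                       frameCutoff = grid$frame[g])
    net <- suppressWarnings(buildNetwork(cmap, cm))
    parts[[g]] <- if (nrow(net@edges) == 0) NULL else girvanNewman(net)
  }
  pairRows <- list()
  addPair <- function(a, b) {
    val <- if (is.null(parts[[a]]) || is.null(parts[[b]])) NA_real_
           else crd(parts[[a]], parts[[b]])
    pairRows[[length(pairRows) + 1L]] <<- data.frame(
      distance1 = grid$distance[a], frame1 = grid$frame[a],
      distance2 = grid$distance[b], frame2 = grid$frame[b],
      crd = val, converged = !is.na(val) & val <= tolerance)
  }
  # expand.grid order: distance varies fastest; pair neighbours along
  # each axis by position so repeated grid values stay distinct points
  nd <- length(distanceGrid)
  at <- function(di, fi) di + (fi - 1L) * nd
  for (fi in seq_along(frameGrid))
    for (di in seq_len(nd - 1))
      addPair(at(di, fi), at(di + 1L, fi))
  for (di in seq_len(nd))
    for (fi in seq_len(length(frameGrid) - 1))
      addPair(at(di, fi), at(di, fi + 1L))
  out <- do.call(rbind, pairRows)
  attr(out, "partitions") <- parts
  attr(out, "grid") <- grid
  out
}

#' Write a network as a TSV edge list or GraphML
#'
#' @param net a \code{\link{WeightedNetwork}}.
#' @param path output file.
#' @param format \code{"tsv"} (node_i, node_j, GC, w; default) or
#'   \code{"graphml"} for graph tools.
#' @param header comment lines (TSV only).
#' @return \code{path}, invisibly.
#' @export
writeNetwork <- function(net, path, format = c("tsv", "graphml"),
                         header = character(0)) {
  stopifnot(is(net, "WeightedNetwork"))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(asIgraph(net), path, format = "graphml")
  } else {
    .writeTSV(net@edges[, c("from", "to", "gc", "w")], path, header)
  }
  invisible(path)
}
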