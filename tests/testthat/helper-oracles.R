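# Independent brute-force oracles.  Deliberately naive: they share no
# code with the implementations they check.

# KSG algorithm-1 mutual information via full distance matrices
bruteKnnMI <- function(x, y, k) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  DJ <- as.matrix(dist(cbind(x, y), method = "maximum")); diag(DJ) <- Inf
  DX <- as.matrix(dist(x, method = "maximum")); diag(DX) <- Inf
  DY <- as.matrix(dist(y, method = "maximum")); diag(DY) <- Inf
  eps <- apply(DJ, 1, function(v) sort(v)[k])
  nx <- rowSums(DX < eps)
  ny <- rowSums(DY < eps)
  digamma(k) + digamma(n) - mean(digamma(nx + 1) + digamma(ny + 1))
}

# weight matrix (Inf off-edge) of a WeightedNetwork, in node order
netWeightMatrix <- function(net) {
  nodes <- networkNodes(net)$name
  n <- length(nodes)
  W <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(W) <- 0
  e <- networkEdges(net)
  i <- match(e$from, nodes); j <- match(e$to, nodes)
  W[cbind(i, j)] <- W[cbind(j, i)] <- e$w
  W
}

# every simple path between two nodes, with lengths (recursive DFS,
# no pruning: the oracle must stay exhaustive)
allSimplePaths <- function(W, s, t) {
  n <- nrow(W)
  paths <- list(); lens <- numeric(0)
  visit <- function(v, len, trail) {
    if (v == t) {
      paths[[length(paths) + 1L]] <<- trail
      lens[length(lens) + 1L] <<- len
      return()
    }
    for (u in seq_len(n)) {
      if (u != v && is.finite(W[v, u]) && !(u %in% trail))
        visit(u, len + W[v, u], c(trail, u))
    }
  }
  visit(s, 0, s)
  list(paths = paths, lengths = lens)
}

# shortest-path length by exhaustive enumeration
bruteShortestLength <- function(W, s, t) {
  res <- allSimplePaths(W, s, t)
  if (!length(res$lengths)) Inf else min(res$lengths)
}

# all set partitions of 1..n as membership vectors (restricted growth)
allPartitions <- function(n) {
  out <- list()
  rec <- function(assign, maxId) {
    i <- length(assign) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- assign
      return()
    }
    for (c in seq_len(maxId + 1L))
      rec(c(assign, c), max(maxId, c))
  }
  rec(integer(0), 0L)
  out
}

# modularity straight from the adjacency definition
bruteModularity <- function(net, membership) {
  nodes <- networkNodes(net)$name
  m <- membership[nodes]
  e <- networkEdges(net)
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(e))) {
    A[e$from[r], e$to[r]] <- A[e$from[r], e$to[r]] + e$gc[r]
    A[e$to[r], e$from[r]] <- A[e$to[r], e$from[r]] + e$gc[r]
  }
  twoM <- sum(A)
  if (twoM == 0) return(0)
  deg <- rowSums(A)
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (m[i] == m[j]) q <- q + A[i, j] - deg[i] * deg[j] / twoM
  unname(q / twoM)
}

# CRD by explicit pair loop
bruteCRD <- function(m1, m2) {
  nodes <- names(m1)
  n <- length(nodes)
  dis <- 0; tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    z1 <- m1[nodes[i]] == m1[nodes[j]]
    z2 <- m2[nodes[i]] == m2[nodes[j]]
    tot <- tot + 1
    if (z1 != z2) dis <- dis + 1
  }
  dis / tot
}

# contribution table by explicit pair loop
bruteContribution <- function(g, type) {
  n <- nrow(g)
  TS <- 0
  AS <- setNames(rep(0, length(unique(type))), sort(unique(type)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    TS <- TS + g[i, j]
    touched <- unique(c(type[i], type[j]))
    for (tp in touched) AS[tp] <- AS[tp] + g[i, j]
  }
  Nk <- table(type)[names(AS)]
  ES <- TS * as.numeric(Nk) / n
  data.frame(type = names(AS), N = as.integer(Nk), AS = unname(AS),
             ES = ES, contribution = unname(AS) - ES,
             TS = TS, stringsAsFactors = FALSE)
}
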