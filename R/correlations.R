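## Mutual information, generalized correlation coefficients, and the
## correlation / contribution score summaries.

#' MIEstimate: a k-NN mutual-information estimate
#'
#' @slot mi estimate in nats, clamped at 0.
#' @slot miRaw the raw estimator output (may be slightly negative).
#' @slot k neighbour count.
#' @slot n sample count.
#' @slot jittered whether tie-breaking jitter was applied.
#' @exportClass MIEstimate
setClass("MIEstimate",
  representation(mi = "numeric", miRaw = "numeric", k = "integer",
                 n = "integer", jittered = "logical"))

setMethod("show", "MIEstimate", function(object) {
  cat(sprintf("MIEstimate: %.4f nats (raw %.4f, k = %d, n = %d%s)\n",
              object@mi, object@miRaw, object@k, object@n,
              if (object@jittered) ", jittered" else ""))
})

#' MI value of an estimate
#' @param x an \code{MIEstimate}
#' @return the clamped MI in nats
#' @export
miValue <- function(x) {
  stopifnot(is(x, "MIEstimate"))
  x@mi
}

# raw KSG call with duplicate handling; x, y are n x d matrices
.ksgMI <- function(x, y, k) {
  res <- cpp_knn_mi(x, y, as.integer(k))
  jittered <- FALSE
  if (is.na(res$mi)) {
    # duplicate samples give zero neighbour distances; break ties with
    # a tiny seeded jitter (documented contract of the estimator)
    warning("duplicate samples detected (", res$duplicates,
            "); applying tie-breaking jitter")
    scale <- 1e-8 * max(apply(x, 2, sd), apply(y, 2, sd), 1e-12)
    x <- x + matrix(rnorm(length(x), sd = scale), nrow(x))
    y <- y + matrix(rnorm(length(y), sd = scale), nrow(y))
    res <- cpp_knn_mi(x, y, as.integer(k))
    jittered <- TRUE
    if (is.na(res$mi))
      stop("numeric error: degenerate input, MI undefined even after jitter")
  }
  list(mi = res$mi, jittered = jittered)
}

#' Kraskov k-nearest-neighbour mutual information
#'
#' Estimates I(X; Y) in nats with the Kraskov-Stoegbauer-Grassberger
#' estimator (algorithm 1): max-norm k-th neighbour distances in the
#' joint space, neighbour counts within those distances in each
#' marginal.  Raw estimates may be slightly negative for (nearly)
#' independent variables; the reported \code{mi} is clamped at 0 and
#' the raw value retained.
#'
#' @param x,y numeric vectors or n x d matrices (equal sample counts).
#' @param k neighbour count (default 6).
#' @return an \code{\link{MIEstimate}}.
#' @examples
#' set.seed(1)
#' x <- rnorm(2000); y <- 0.8 * x + 0.6 * rnorm(2000)
#' miValue(knnMI(x, y))          # close to -0.5 * log(1 - 0.64)
#' @export
knnMI <- function(x, y, k = 6L) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("x and y must have equal sample counts")
  if (nrow(x) < k + 1) stop("need at least k + 1 samples")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("data error: non-finite samples")
  est <- .ksgMI(x, y, k)
  new("MIEstimate", mi = max(0, est$mi), miRaw = est$mi,
      k = as.integer(k), n = nrow(x), jittered = est$jittered)
}

.gcFromMI <- function(mi, d) sqrt(pmax(1 - exp(-2 * pmax(mi, 0) / d), 0))

#' Generalized correlation matrix of a site trajectory
#'
#' For every site pair the mutual information between the two 3-D
#' fluctuation variables is estimated with \code{\link{knnMI}} and
#' mapped to a generalized correlation coefficient
#' \deqn{GC_{ij} = \{1 - \exp(-2 I_{ij} / d)\}^{1/2}, \quad d = 3,}
#' which ranges from 0 (independent) to 1 (fully correlated) and, being
#' mutual-information based, captures nonlinear and orthogonally
#' oriented couplings that a Pearson coefficient misses.  The diagonal
#' is 1 by convention.
#'
#' @param straj a superposed (or synthetic) \code{\link{SiteTrajectory}}.
#' @param k neighbour count for the estimator (default 6).
#' @return a \code{\link{CorrelationMatrix}}.
#' @export
gcMatrix <- function(straj, k = 6L) {
  stopifnot(is(straj, "SiteTrajectory"))
  arr <- straj@coords
  if (any(!is.finite(arr))) {
    bad <- which(!is.finite(arr), arr.ind = TRUE)[1, ]
    stop("data error: non-finite coordinate at frame ", bad[1],
         ", site ", bad[2])
  }
  nf <- dim(arr)[1]; ns <- dim(arr)[2]
  if (nf < 100)
    warning("only ", nf, " frames: k-NN MI estimates will be very noisy")
  mi <- matrix(NA_real_, ns, ns)
  clamped <- 0L
  for (i in seq_len(ns - 1)) {
    xi <- arr[, i, ]
    for (j in (i + 1):ns) {
      est <- .ksgMI(xi, arr[, j, ], k)
      if (est$mi < 0) clamped <- clamped + 1L
      mi[i, j] <- mi[j, i] <- max(0, est$mi)
    }
  }
  if (clamped > 0)
    message(clamped, " of ", ns * (ns - 1) / 2,
            " pair MI estimates were negative and clamped to 0")
  gc <- .gcFromMI(mi, 3)
  diag(gc) <- 1
  new("CorrelationMatrix", gc = gc, mi = mi, k = as.integer(k),
      nFrames = as.integer(nf), d = 3L, nReplicas = 1L,
      sites = straj@sites)
}

#' Average correlation matrices over replicas
#'
#' Entrywise arithmetic mean of the GC (and MI) matrices of independent
#' replica simulations, the standard way to stabilise the estimate
#' across independent trajectories of the same system.
#'
#' @param matrices list of \code{\link{CorrelationMatrix}} objects with
#'   identical site lists and estimator settings.
#' @return a \code{\link{CorrelationMatrix}} with
#'   \code{nReplicas} = total replica count.
#' @export
averageMatrices <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 1,
            all(vapply(matrices, is, logical(1), "CorrelationMatrix")))
  ref <- matrices[[1]]
  refKey <- residueKey(ref@sites$chain, ref@sites$resno)
  for (m in matrices[-1]) {
    if (!identical(residueKey(m@sites$chain, m@sites$resno), refKey))
      stop("alignment error: replicas cover different site lists")
    if (m@k != ref@k || m@d != ref@d)
      stop("settings error: replicas estimated with different k or d")
  }
  gc <- Reduce(`+`, lapply(matrices, function(m) m@gc)) / length(matrices)
  mi <- Reduce(`+`, lapply(matrices, function(m) m@mi)) / length(matrices)
  diag(gc) <- 1
  new("CorrelationMatrix", gc = (gc + t(gc)) / 2, mi = (mi + t(mi)) / 2,
      k = ref@k, nFrames = ref@nFrames, d = ref@d,
      nReplicas = sum(vapply(matrices, function(m) m@nReplicas,
                             integer(1))),
      sites = ref@sites)
}

#' Per-residue correlation scores
#'
#' The correlation score of residue i is the sum of its generalized
#' correlation coefficients over the included pairs,
#' \eqn{S_i = \sum_{j \ne i} GC_{ij}}, restricted to pairs above the
#' intensity cutoff and, optionally, to intra- or inter-domain pairs.
#' It measures both the number and the intensity of correlations a
#' residue takes part in; the default cutoff of 0.6 keeps only intense
#' couplings, filtering out the backdrop of weak rigid-body
#' correlations.
#'
#' @param cm a \code{\link{CorrelationMatrix}}.
#' @param mode \code{"all"}, \code{"intra"} (same domain only) or
#'   \code{"inter"} (different domains only).
#' @param cutoff include only pairs with \eqn{GC_{ij} >} cutoff
#'   (default 0.6).
#' @return data.frame with the site metadata and column \code{score};
#'   attributes \code{mode} and \code{cutoff} record the filter.
#' @export
correlationScores <- function(cm, mode = c("all", "intra", "inter"),
                              cutoff = 0.6) {
  stopifnot(is(cm, "CorrelationMatrix"), cutoff >= 0, cutoff <= 1)
  mode <- match.arg(mode)
  g <- cm@gc
  include <- g > cutoff
  diag(include) <- FALSE
  if (mode != "all") {
    dom <- cm@sites$domain
    if (anyNA(dom))
      stop("annotation error: ", mode,
           "-domain scores need a domain label on every site")
    same <- outer(dom, dom, `==`)
    include <- include & (if (mode == "intra") same else !same)
  }
  out <- cm@sites
  out$score <- rowSums(g * include)
  attr(out, "mode") <- mode
  attr(out, "cutoff") <- cutoff
  out
}

#' Residue-type contribution scores
#'
#' Measures whether a residue type participates in the correlation
#' network more or less than expected from its abundance alone.  With
#' TS the total score (sum of all pairwise GC, each unordered pair
#' once), the expected score of type i is
#' \deqn{ES_i = TS \cdot N_i / N,}
#' the accumulated score \eqn{AS_i} is the sum of GC over pairs
#' involving at least one residue of type i (a pair within the type
#' counted once), and the contribution is \eqn{AS_i - ES_i}: positive
#' for types that convey more correlation than their abundance
#' predicts.
#'
#' @param cm a \code{\link{CorrelationMatrix}}.
#' @param typeMap optional character vector of residue types, either
#'   named by \code{"CHAIN:RESNO"} or in site order; defaults to the
#'   residue names in the site metadata.
#' @return data.frame with columns \code{type}, \code{N}, \code{AS},
#'   \code{ES}, \code{contribution}; attributes \code{TS} (total
#'   score) and \code{Ntotal}.
#' @export
contributionScores <- function(cm, typeMap = NULL) {
  stopifnot(is(cm, "CorrelationMatrix"))
  key <- residueKey(cm@sites$chain, cm@sites$resno)
  type <- if (is.null(typeMap)) {
    cm@sites$resid
  } else if (!is.null(names(typeMap))) {
    unname(typeMap[key])
  } else {
    if (length(typeMap) != length(key))
      stop("annotation error: typeMap does not cover every residue")
    as.character(typeMap)
  }
  if (anyNA(type) || any(!nzchar(type)))
    stop("annotation error: untyped residue(s) present")
  g <- cm@gc
  ut <- which(upper.tri(g), arr.ind = TRUE)
  val <- g[ut]
  TS <- sum(val)
  ti <- type[ut[, 1]]; tj <- type[ut[, 2]]
  levelsT <- sort(unique(type))
  AS <- vapply(levelsT, function(tp) sum(val[ti == tp | tj == tp]),
               numeric(1))
  N <- as.vector(table(factor(type, levels = levelsT)))
  Ntot <- length(type)
  ES <- TS * N / Ntot
  out <- data.frame(type = levelsT, N = N, AS = AS, ES = ES,
                    contribution = AS - ES, stringsAsFactors = FALSE)
  attr(out, "TS") <- TS
  attr(out, "Ntotal") <- Ntot
  out
}

#' Write a correlation matrix as dense text
#'
#' Whitespace-delimited GC matrix with a header line of site ids and
#' provenance comments; a second block with the MI values follows if
#' requested.
#'
#' @param cm a \code{\link{CorrelationMatrix}}.
#' @param path output file.
#' @param what \code{"gc"} or \code{"mi"}.
#' @param header extra comment lines.
#' @return \code{path}, invisibly.
#' @export
writeCorrelationMatrix <- function(cm, path, what = c("gc", "mi"),
                                   header = character(0)) {
  stopifnot(is(cm, "CorrelationMatrix"))
  what <- match.arg(what)
  m <- if (what == "gc") cm@gc else cm@mi
  ids <- residueKey(cm@sites$chain, cm@sites$resno)
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(header,
           sprintf("%s matrix: k = %d, frames = %d, replicas = %d",
                   toupper(what), cm@k, cm@nFrames, cm@nReplicas))
  writeLines(paste0("# ", hdr), con)
  writeLines(paste(ids, collapse = " "), con)
  apply(m, 1, function(row)
    writeLines(paste(sprintf("%.10g", row), collapse = " "), con))
  invisible(path)
}
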