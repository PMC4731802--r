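## Essential dynamics: PCA of site fluctuations and free-energy
## landscapes along principal modes.

BOLTZMANN_KCAL <- 0.0019872041  # kcal / (mol K)

# frames x 3N matrix in site-major order (x1, y1, z1, x2, ...)
.flattenCoords <- function(arr) {
  nf <- dim(arr)[1]; ns <- dim(arr)[2]
  matrix(aperm(arr, c(1, 3, 2)), nf, 3 * ns)
}

#' Principal component analysis of site fluctuations
#'
#' Diagonalises the 3N x 3N covariance matrix of the (superposed) site
#' positions about their mean.  Modes are sorted by eigenvalue, so the
#' first principal component is the system's highest-amplitude
#' collective motion; eigenvalues are the mean-square fluctuation along
#' each mode (Angstrom^2).  The covariance is mass-unweighted.
#'
#' @param straj a superposed \code{\link{SiteTrajectory}} (synthetic
#'   ensembles sampled about a fixed mean need no superposition).
#' @return a \code{\link{PCAModel}}.
#' @export
fitPCA <- function(straj) {
  stopifnot(is(straj, "SiteTrajectory"))
  X <- .flattenCoords(straj@coords)
  if (nrow(X) < 2)
    stop("insufficient frames: PCA needs at least 2 frames")
  if (nrow(X) <= ncol(X))
    warning("fewer frames (", nrow(X), ") than coordinates (", ncol(X),
            "): covariance is rank-deficient")
  mu <- colMeans(X)
  # population (1/n) covariance: the trace then equals the summed
  # per-site mean-square fluctuation exactly
  C <- stats::cov(X) * (nrow(X) - 1) / nrow(X)
  eg <- eigen(C, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  new("PCAModel", center = mu, vectors = eg$vectors, values = vals,
      varFraction = if (sum(vals) > 0) vals / sum(vals)
                    else rep(0, length(vals)),
      sites = straj@sites)
}

#' Project a trajectory onto a principal mode
#'
#' \eqn{q_t = (x_t - \bar{x}) \cdot v_{mode}}; the variance of the
#' series equals the mode eigenvalue (within sampling error).
#'
#' @param straj a \code{\link{SiteTrajectory}} over the same sites as
#'   the model.
#' @param model a \code{\link{PCAModel}}.
#' @param mode mode index (1 = highest amplitude).
#' @return numeric per-frame projection series (Angstrom).
#' @export
projectMode <- function(straj, model, mode = 1L) {
  stopifnot(is(straj, "SiteTrajectory"), is(model, "PCAModel"))
  if (mode < 1 || mode > ncol(model@vectors))
    stop("mode index out of range")
  ka <- residueKey(straj@sites$chain, straj@sites$resno)
  kb <- residueKey(model@sites$chain, model@sites$resno)
  if (!identical(ka, kb))
    stop("alignment error: trajectory and PCA model cover different sites")
  X <- .flattenCoords(straj@coords)
  as.vector(sweep(X, 2, model@center) %*% model@vectors[, mode])
}

.fesFromCounts <- function(counts, temperature, unit) {
  P <- counts / sum(counts)
  kT <- if (unit == "kT") 1 else BOLTZMANN_KCAL * temperature
  Fv <- -kT * log(P / max(P))
  Fv[counts == 0] <- NA_real_  # unsampled: undefined, never 0
  list(P = P, F = Fv)
}

#' One-dimensional free-energy profile along a projection
#'
#' Histograms the series and converts occupation probabilities to free
#' energies, \eqn{F(q) = -k_B T \ln(P(q)/P_{max}(q))}, so the most
#' probable bin sits at F = 0 exactly.  Empty bins are reported as NA
#' (undefined), never as finite values.
#'
#' @param series projection values (typically from
#'   \code{\link{projectMode}}).
#' @param bins number of equal-width bins (>= 10; default 50).
#' @param temperature Kelvin (default 310; only scales the kcal/mol
#'   unit).
#' @param unit \code{"kT"} (default) or \code{"kcal/mol"}.
#' @return a \code{\link{FreeEnergySurface}}.
#' @export
freeEnergy1D <- function(series, bins = 50L, temperature = 310,
                         unit = c("kT", "kcal/mol")) {
  unit <- match.arg(unit)
  series <- as.numeric(series)
  if (length(series) < 100)
    warning("fewer than 100 samples: the free-energy profile will be rough")
  rng <- range(series)
  if (diff(rng) == 0) {
    warning("constant series: degenerate single-bin surface")
    return(new("FreeEnergySurface", dim = 1L, mids = list(rng[1]),
               P = array(1), F = array(0), temperature = temperature,
               unit = unit))
  }
  if (bins < 10) stop("need at least 10 bins")
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  idx <- pmin(pmax(findInterval(series, breaks, rightmost.closed = TRUE),
                   1L), bins)
  counts <- tabulate(idx, nbins = bins)
  fes <- .fesFromCounts(counts, temperature, unit)
  mids <- (breaks[-1] + breaks[-(bins + 1)]) / 2
  new("FreeEnergySurface", dim = 1L, mids = list(mids),
      P = array(fes$P), F = array(fes$F), temperature = temperature,
      unit = unit)
}

#' Two-dimensional free-energy landscape over two projections
#'
#' Joint histogram of the two series with the same probability-to-free
#' energy transform as \code{\link{freeEnergy1D}}.  Correlated mode
#' pairs show up as a narrow diagonal "canyon": the accessible region
#' collapses onto combinations where the two coordinates move together.
#'
#' @param seriesA,seriesB equal-length projection series.
#' @param bins bins per axis (default 50).
#' @param temperature Kelvin.
#' @param unit \code{"kT"} or \code{"kcal/mol"}.
#' @return a \code{\link{FreeEnergySurface}} with \code{dim = 2}.
#' @export
freeEnergy2D <- function(seriesA, seriesB, bins = 50L, temperature = 310,
                         unit = c("kT", "kcal/mol")) {
  unit <- match.arg(unit)
  if (length(seriesA) != length(seriesB))
    stop("alignment error: series lengths differ")
  if (bins < 10) stop("need at least 10 bins")
  binAxis <- function(v) {
    rng <- range(v)
    if (diff(rng) == 0) stop("constant series: no 2-D surface")
    breaks <- seq(rng[1], rng[2], length.out = bins + 1)
    list(idx = pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE),
                         1L), bins),
         mids = (breaks[-1] + breaks[-(bins + 1)]) / 2)
  }
  a <- binAxis(seriesA); b <- binAxis(seriesB)
  counts <- matrix(0L, bins, bins)
  tab <- table(factor(a$idx, levels = 1:bins),
               factor(b$idx, levels = 1:bins))
  counts[] <- as.integer(tab)
  fes <- .fesFromCounts(counts, temperature, unit)
  new("FreeEnergySurface", dim = 2L, mids = list(a$mids, b$mids),
      P = array(fes$P, dim = c(bins, bins)),
      F = array(fes$F, dim = c(bins, bins)),
      temperature = temperature, unit = unit)
}

#' Write a free-energy surface as gridded TSV
#'
#' @param fes a \code{\link{FreeEnergySurface}}.
#' @param path output file.
#' @param header comment lines.
#' @return \code{path}, invisibly.
#' @export
writeSurface <- function(fes, path, header = character(0)) {
  stopifnot(is(fes, "FreeEnergySurface"))
  df <- if (fes@dim == 1L) {
    data.frame(q = fes@mids[[1]], P = as.vector(fes@P),
               F = as.vector(fes@F))
  } else {
    grid <- expand.grid(q1 = fes@mids[[1]], q2 = fes@mids[[2]],
                        KEEP.OUT.ATTRS = FALSE)
    data.frame(grid, P = as.vector(fes@P), F = as.vector(fes@F))
  }
  .writeTSV(df, path,
            c(header, paste0("free energy in ", fes@unit,
                             ", T = ", fes@temperature, " K; NA = unsampled")))
  invisible(path)
}
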