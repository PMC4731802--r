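## S4 containers for the pipeline stages.  Site order is fixed at
## construction (file order of residues) and carried unchanged through
## every downstream object; residues are addressed as "CHAIN:RESNO".

#' StructureModel: a parsed molecular topology
#'
#' Holds the atom records of a PDB-format topology together with a
#' per-residue table.  Hydrogens are retained but flagged; solvent and
#' counter-ions are stripped on read (see \code{\link{readTopology}}).
#'
#' @slot atoms data.frame with columns \code{eleno}, \code{name},
#'   \code{element}, \code{resno}, \code{resid}, \code{chain},
#'   \code{x}, \code{y}, \code{z}, \code{hydrogen}.
#' @slot residues data.frame with one row per residue: \code{resno},
#'   \code{resid}, \code{chain}, \code{domain} (NA until assigned).
#' @slot pdb the underlying bio3d \code{pdb} object (or empty list),
#'   kept for round-trip writing.
#' @exportClass StructureModel
setClass("StructureModel",
  representation(atoms = "data.frame", residues = "data.frame",
                 pdb = "list"))

setValidity("StructureModel", function(object) {
  a <- object@atoms; r <- object@residues
  need <- c("eleno", "name", "element", "resno", "resid", "chain",
            "x", "y", "z", "hydrogen")
  if (!all(need %in% names(a)))
    return(paste("atoms table lacks columns:",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  if (!all(c("resno", "resid", "chain", "domain") %in% names(r)))
    return("residue table lacks required columns")
  if (any(!is.finite(c(a$x, a$y, a$z))))
    return("non-finite atom coordinates")
  ak <- paste(a$chain, a$resno)
  rk <- paste(r$chain, r$resno)
  if (!all(ak %in% rk))
    return("atom residue indices reference missing residues")
  heavy <- tapply(!a$hydrogen, factor(ak, levels = rk), any)
  if (any(!heavy, na.rm = TRUE) || anyNA(heavy))
    return("every residue must have at least one heavy atom")
  TRUE
})

#' Trajectory: multi-frame coordinates for a StructureModel
#'
#' @slot coords numeric array \code{[frames, atoms, 3]}, Angstrom.
#' @slot dt frame interval in ps (NA if unknown).
#' @exportClass Trajectory
setClass("Trajectory",
  representation(coords = "array", dt = "numeric"))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[3] != 3L)
    return("coords must be a frames x atoms x 3 array")
  TRUE
})

#' SiteTrajectory: per-residue fluctuation ensemble
#'
#' One three-dimensional site per residue.  This is the variable the
#' mutual-information machinery operates on.  Sites keep the residue
#' order of the source model; row \code{i} of \code{sites} describes
#' coordinate slab \code{coords[, i, ]}.
#'
#' @slot coords numeric array \code{[frames, sites, 3]}, Angstrom.
#' @slot sites data.frame: \code{resno}, \code{resid}, \code{chain},
#'   \code{domain}.
#' @slot d integer dimensionality per site (always 3).
#' @exportClass SiteTrajectory
setClass("SiteTrajectory",
  representation(coords = "array", sites = "data.frame", d = "integer"))

setValidity("SiteTrajectory", function(object) {
  dm <- dim(object@coords)
  if (length(dm) != 3L || dm[3] != 3L)
    return("coords must be a frames x sites x 3 array")
  if (dm[2] != nrow(object@sites))
    return("site metadata does not match coordinate array")
  if (object@d != 3L) return("site dimensionality must be 3")
  TRUE
})

#' MobilityProfile: RMSF or RMSD values
#'
#' @slot values numeric, Angstrom, all \eqn{\ge 0}.
#' @slot kind \code{"rmsf"} (per site) or \code{"rmsd"} (per frame).
#' @slot reference description of the reference structure/frame.
#' @slot sites site metadata (for RMSF profiles; empty for RMSD).
#' @exportClass MobilityProfile
setClass("MobilityProfile",
  representation(values = "numeric", kind = "character",
                 reference = "character", sites = "data.frame"))

setValidity("MobilityProfile", function(object) {
  if (any(object@values < -1e-12, na.rm = TRUE))
    return("mobility values must be non-negative")
  if (!object@kind %in% c("rmsf", "rmsd")) return("kind must be rmsf or rmsd")
  TRUE
})

#' GaussianEnsembleSpec: elastic-network Gaussian generator spec
#'
#' Defines a stationary multivariate-Gaussian fluctuation ensemble whose
#' per-axis site covariance is the (scaled) pseudo-inverse of the
#' Kirchhoff matrix of an elastic-network topology, with isotropic 3-D
#' blocks.  Because the covariance is known in closed form, generalized
#' correlation coefficients for the ensemble are available analytically
#' (\code{\link{analyticGC}}), giving downstream estimators an oracle.
#'
#' @slot nSites number of sites.
#' @slot edges integer matrix (m x 2) of connected site pairs.
#' @slot springs per-edge spring constants (dimensionless).
#' @slot anchors per-site tether constants to the laboratory frame.
#' @slot kT temperature scale; per-axis covariance is
#'   \code{kT * pinv(Kirchhoff)}.
#' @slot covariance derived per-axis site covariance (n x n, PSD).
#' @slot refGeometry mean structure (n x 3, Angstrom).
#' @slot sites site metadata passed to generated trajectories.
#' @slot seed RNG seed used by \code{\link{buildGaussianEnsemble}}.
#' @exportClass GaussianEnsembleSpec
setClass("GaussianEnsembleSpec",
  representation(nSites = "integer", edges = "matrix", springs = "numeric",
                 anchors = "numeric", kT = "numeric", covariance = "matrix",
                 refGeometry = "matrix", sites = "data.frame",
                 seed = "integer"))

setValidity("GaussianEnsembleSpec", function(object) {
  n <- object@nSites
  C <- object@covariance
  if (!isTRUE(all.equal(C, t(C), tolerance = 1e-8)))
    return("covariance must be symmetric")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    return("covariance must be positive semi-definite")
  if (nrow(C) != n || nrow(object@refGeometry) != n)
    return("covariance/reference geometry dimension mismatch")
  TRUE
})

#' PlantedGraphSpec: stochastic block model with known communities
#'
#' @slot sizes community sizes (each >= 3, at least 2 communities).
#' @slot pIn within-community edge probability.
#' @slot pOut between-community edge probability (\code{pOut < pIn}).
#' @slot wMin,wMax edge weights (correlation strengths) drawn uniformly
#'   from \code{[wMin, wMax]}.
#' @slot seed RNG seed.
#' @exportClass PlantedGraphSpec
setClass("PlantedGraphSpec",
  representation(sizes = "integer", pIn = "numeric", pOut = "numeric",
                 wMin = "numeric", wMax = "numeric", seed = "integer"))

setValidity("PlantedGraphSpec", function(object) {
  if (object@pOut >= object@pIn || object@pOut < 0 || object@pIn > 1)
    return("need 0 <= pOut < pIn <= 1")
  if (length(object@sizes) < 2L || any(object@sizes < 3L))
    return("need at least 2 communities of size >= 3")
  if (object@wMin <= 0 || object@wMax > 1 || object@wMin > object@wMax)
    return("edge weights must satisfy 0 < wMin <= wMax <= 1")
  TRUE
})

#' CorrelationMatrix: generalized correlation coefficients
#'
#' Symmetric matrix of generalized correlation coefficients
#' \eqn{GC_{ij} = \{1 - \exp(-2 I_{ij}/d)\}^{1/2}} together with the
#' underlying mutual-information estimates (nats).  The diagonal is 1
#' by convention (self-information diverges).
#'
#' @slot gc symmetric numeric matrix in \eqn{[0, 1]}, unit diagonal.
#' @slot mi mutual-information matrix (nats, clamped at 0; NA diagonal).
#' @slot k neighbour count used by the estimator.
#' @slot nFrames frames per replica used for estimation.
#' @slot d dimensionality of each site variable.
#' @slot nReplicas number of replicas averaged into this matrix.
#' @slot sites site metadata (residue, chain, domain).
#' @exportClass CorrelationMatrix
setClass("CorrelationMatrix",
  representation(gc = "matrix", mi = "matrix", k = "integer",
                 nFrames = "integer", d = "integer", nReplicas = "integer",
                 sites = "data.frame"))

setValidity("CorrelationMatrix", function(object) {
  g <- object@gc
  if (nrow(g) != ncol(g)) return("gc must be square")
  if (nrow(g) != nrow(object@sites))
    return("site metadata does not match matrix dimension")
  if (!isTRUE(all.equal(g, t(g), tolerance = 1e-10)))
    return("gc must be symmetric")
  if (any(g < -1e-12 | g > 1 + 1e-12)) return("gc entries must lie in [0, 1]")
  if (any(abs(diag(g) - 1) > 1e-12)) return("gc diagonal must be 1")
  TRUE
})

#' ContactMap: persistence-filtered residue contacts
#'
#' A residue pair is in contact in a frame if any heavy-atom pair is
#' within \code{distanceCutoff}; the pair is a network contact if that
#' holds in at least a fraction \code{frameCutoff} of frames.
#'
#' @slot fraction symmetric matrix of per-pair contact fractions.
#' @slot adjacency logical matrix, \code{fraction >= frameCutoff},
#'   diagonal FALSE.
#' @slot distanceCutoff Angstrom (default 5.5).
#' @slot frameCutoff fraction of frames (default 0.75).
#' @slot sites residue metadata.
#' @exportClass ContactMap
setClass("ContactMap",
  representation(fraction = "matrix", adjacency = "matrix",
                 distanceCutoff = "numeric", frameCutoff = "numeric",
                 sites = "data.frame"))

setValidity("ContactMap", function(object) {
  f <- object@fraction
  if (any(f < -1e-12 | f > 1 + 1e-12)) return("fractions must lie in [0, 1]")
  if (!isTRUE(all.equal(f, t(f)))) return("fraction matrix must be symmetric")
  if (any(diag(object@adjacency))) return("diagonal must be excluded")
  ok <- object@adjacency == (f >= object@frameCutoff)
  diag(ok) <- TRUE
  if (!all(ok)) return("adjacency inconsistent with fraction/frameCutoff")
  TRUE
})

#' WeightedNetwork: contact-filtered correlation network
#'
#' Residue graph with one node per residue and an edge for every
#' persistent contact, of length \eqn{w_{ij} = -\log GC_{ij}}.  Short
#' edges join strongly correlated residues, so minimum-length paths are
#' maximum-correlation communication routes.
#'
#' @slot nodes data.frame: \code{name} ("CHAIN:RESNO"), \code{resno},
#'   \code{chain}, \code{domain}, \code{trueLabel} (ground truth for
#'   synthetic graphs, NA otherwise).
#' @slot edges data.frame: \code{from}, \code{to} (node names),
#'   \code{gc}, \code{w}.
#' @exportClass WeightedNetwork
setClass("WeightedNetwork",
  representation(nodes = "data.frame", edges = "data.frame"))

setValidity("WeightedNetwork", function(object) {
  e <- object@edges
  if (nrow(e) &&
      (!all(e$from %in% object@nodes$name) ||
       !all(e$to %in% object@nodes$name)))
    return("edge endpoints must be declared nodes")
  if (nrow(e) && any(e$w < -1e-12))
    return("edge lengths must be non-negative (GC <= 1)")
  if (anyDuplicated(object@nodes$name)) return("node names must be unique")
  TRUE
})

#' CommunityPartition: node-to-community assignment
#'
#' @slot membership integer vector named by node, community ids
#'   contiguous from 0.
#' @slot q Newman-Girvan modularity of the partition.
#' @slot nCommunities number of communities.
#' @exportClass CommunityPartition
setClass("CommunityPartition",
  representation(membership = "integer", q = "numeric",
                 nCommunities = "integer"))

setValidity("CommunityPartition", function(object) {
  m <- object@membership
  if (is.null(names(m))) return("membership must be named by node")
  ids <- sort(unique(m))
  if (!identical(ids, seq.int(0L, length.out = length(ids))))
    return("community ids must be contiguous from 0")
  if (object@nCommunities != length(ids))
    return("nCommunities inconsistent with membership")
  if (length(object@q) == 1 && is.finite(object@q) &&
      (object@q < -0.5 - 1e-9 || object@q > 1 + 1e-9))
    return("modularity out of range [-0.5, 1]")
  TRUE
})

#' PCAModel: essential dynamics of a site trajectory
#'
#' @slot center mean structure, flattened (length 3N; x1,y1,z1,x2,...).
#' @slot vectors orthonormal eigenvectors, columns sorted by eigenvalue.
#' @slot values eigenvalues (Angstrom^2), descending, clamped at 0.
#' @slot varFraction fraction of total variance per mode.
#' @slot sites site metadata.
#' @exportClass PCAModel
setClass("PCAModel",
  representation(center = "numeric", vectors = "matrix", values = "numeric",
                 varFraction = "numeric", sites = "data.frame"))

setValidity("PCAModel", function(object) {
  V <- object@vectors
  g <- crossprod(V)
  if (max(abs(g - diag(ncol(V)))) > 1e-8)
    return("eigenvectors must be orthonormal")
  if (is.unsorted(rev(object@values))) return("eigenvalues must be descending")
  if (any(object@values < 0)) return("eigenvalues must be clamped at >= 0")
  TRUE
})

#' FreeEnergySurface: binned free-energy profile along principal modes
#'
#' \eqn{F(q) = -k_B T \ln(P(q)/P_{max}(q))}, so the most probable bin
#' has F = 0 exactly and empty bins are NA (undefined), never 0.
#'
#' @slot dim 1 or 2.
#' @slot mids list of bin-centre vectors (one per axis).
#' @slot P probability array (sums to 1 over occupied bins).
#' @slot F free energy array; NA marks unsampled bins.
#' @slot temperature Kelvin.
#' @slot unit \code{"kT"} or \code{"kcal/mol"}.
#' @exportClass FreeEnergySurface
setClass("FreeEnergySurface",
  representation(dim = "integer", mids = "list", P = "array", F = "array",
                 temperature = "numeric", unit = "character"))

setValidity("FreeEnergySurface", function(object) {
  f <- object@F
  if (abs(min(f, na.rm = TRUE)) > 1e-12)
    return("minimum free energy must be exactly 0")
  if (any(f < 0, na.rm = TRUE)) return("free energy must be non-negative")
  if (abs(sum(object@P) - 1) > 1e-8) return("P must sum to 1")
  TRUE
})
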