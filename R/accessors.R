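## Generics, accessors and show() methods.  Slots are never reached for
## directly by user code; these accessors are the supported surface.

#' Number of frames in an ensemble object
#' @param x a \code{Trajectory} or \code{SiteTrajectory}
#' @return integer frame count
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Number of sites (residues) in an object
#' @param x a site-level object
#' @return integer site count
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' Coordinate array of an ensemble object
#' @param x a \code{Trajectory} or \code{SiteTrajectory}
#' @return numeric array \code{[frames, sites/atoms, 3]} (Angstrom)
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' Site/residue metadata table
#' @param x any site-level object
#' @return data.frame with residue number, name, chain and domain label
#' @export
setGeneric("siteInfo", function(x) standardGeneric("siteInfo"))

#' Generalized correlation coefficient matrix
#' @param x a \code{CorrelationMatrix}
#' @return symmetric numeric matrix in [0, 1] with unit diagonal
#' @export
setGeneric("gcValues", function(x) standardGeneric("gcValues"))

#' Mutual information matrix (nats)
#' @param x a \code{CorrelationMatrix}
#' @return symmetric numeric matrix, NA on the diagonal
#' @export
setGeneric("miValues", function(x) standardGeneric("miValues"))

#' Community ids of a partition
#' @param x a \code{CommunityPartition}
#' @return integer vector named by node, ids contiguous from 0
#' @export
setGeneric("communityIds", function(x) standardGeneric("communityIds"))

#' Modularity of a partition
#' @param x a \code{CommunityPartition}
#' @return numeric Newman-Girvan modularity Q
#' @export
setGeneric("modularityValue", function(x) standardGeneric("modularityValue"))

#' Node table of a network
#' @param x a \code{WeightedNetwork}
#' @return data.frame of nodes with metadata
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' Edge table of a network
#' @param x a \code{WeightedNetwork}
#' @return data.frame with columns from, to, gc, w
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @describeIn nFrames frames of an atomic trajectory
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[1])

#' @describeIn nFrames frames of a site trajectory
#' @export
setMethod("nFrames", "SiteTrajectory", function(x) dim(x@coords)[1])

#' @describeIn nSites sites of a site trajectory
#' @export
setMethod("nSites", "SiteTrajectory", function(x) dim(x@coords)[2])

#' @describeIn nSites sites of a correlation matrix
#' @export
setMethod("nSites", "CorrelationMatrix", function(x) nrow(x@gc))

#' @describeIn nSites sites of a generator spec
#' @export
setMethod("nSites", "GaussianEnsembleSpec", function(x) x@nSites)

#' @describeIn coords atomic coordinates
#' @export
setMethod("coords", "Trajectory", function(x) x@coords)

#' @describeIn coords site coordinates
#' @export
setMethod("coords", "SiteTrajectory", function(x) x@coords)

#' @describeIn siteInfo sites of a site trajectory
#' @export
setMethod("siteInfo", "SiteTrajectory", function(x) x@sites)

#' @describeIn siteInfo residues of a structure model
#' @export
setMethod("siteInfo", "StructureModel", function(x) x@residues)

#' @describeIn siteInfo sites of a correlation matrix
#' @export
setMethod("siteInfo", "CorrelationMatrix", function(x) x@sites)

#' @describeIn siteInfo residues of a contact map
#' @export
setMethod("siteInfo", "ContactMap", function(x) x@sites)

#' @describeIn gcValues extract the GC matrix
#' @export
setMethod("gcValues", "CorrelationMatrix", function(x) x@gc)

#' @describeIn miValues extract the MI matrix
#' @export
setMethod("miValues", "CorrelationMatrix", function(x) x@mi)

#' @describeIn communityIds extract the membership vector
#' @export
setMethod("communityIds", "CommunityPartition", function(x) x@membership)

#' @describeIn modularityValue extract Q
#' @export
setMethod("modularityValue", "CommunityPartition", function(x) x@q)

#' @describeIn networkNodes extract the node table
#' @export
setMethod("networkNodes", "WeightedNetwork", function(x) x@nodes)

#' @describeIn networkEdges extract the edge table
#' @export
setMethod("networkEdges", "WeightedNetwork", function(x) x@edges)

#' Mobility values
#' @param x a \code{MobilityProfile}
#' @return numeric vector of RMSF (per site) or RMSD (per frame), Angstrom
#' @export
mobilityValues <- function(x) {
  stopifnot(is(x, "MobilityProfile"))
  x@values
}

#' PCA eigenvalues
#' @param x a \code{PCAModel}
#' @return numeric vector of eigenvalues (Angstrom^2), descending
#' @export
pcaValues <- function(x) {
  stopifnot(is(x, "PCAModel"))
  x@values
}

#' PCA eigenvectors
#' @param x a \code{PCAModel}
#' @return matrix whose columns are orthonormal modes (length 3N)
#' @export
pcaVectors <- function(x) {
  stopifnot(is(x, "PCAModel"))
  x@vectors
}

#' Free-energy values of a surface
#' @param x a \code{FreeEnergySurface}
#' @return numeric array of F values (NA where unsampled)
#' @export
surfaceF <- function(x) {
  stopifnot(is(x, "FreeEnergySurface"))
  x@F
}

#' Occupation probabilities of a surface
#' @param x a \code{FreeEnergySurface}
#' @return numeric array of bin probabilities
#' @export
surfaceP <- function(x) {
  stopifnot(is(x, "FreeEnergySurface"))
  x@P
}

#' Bin centres of a surface
#' @param x a \code{FreeEnergySurface}
#' @return list of bin-centre vectors, one per axis
#' @export
surfaceMids <- function(x) {
  stopifnot(is(x, "FreeEnergySurface"))
  x@mids
}

setMethod("show", "StructureModel", function(object) {
  cat("StructureModel:", nrow(object@atoms), "atoms,",
      nrow(object@residues), "residues,",
      length(unique(object@residues$chain)), "chain(s)\n")
})

setMethod("show", "Trajectory", function(object) {
  d <- dim(object@coords)
  cat("Trajectory:", d[1], "frames x", d[2], "atoms\n")
})

setMethod("show", "SiteTrajectory", function(object) {
  d <- dim(object@coords)
  cat("SiteTrajectory:", d[1], "frames x", d[2], "sites (3-D each)\n")
  dom <- unique(object@sites$domain)
  if (!all(is.na(dom)))
    cat("  domains:", paste(stats::na.omit(dom), collapse = ", "), "\n")
})

setMethod("show", "MobilityProfile", function(object) {
  cat(sprintf("MobilityProfile (%s, ref: %s): n = %d, range %.3f - %.3f A\n",
              object@kind, object@reference, length(object@values),
              min(object@values), max(object@values)))
})

setMethod("show", "GaussianEnsembleSpec", function(object) {
  cat("GaussianEnsembleSpec:", object@nSites, "sites,",
      nrow(object@edges), "springs, kT =", object@kT,
      ", seed =", object@seed, "\n")
})

setMethod("show", "PlantedGraphSpec", function(object) {
  cat("PlantedGraphSpec: sizes", paste(object@sizes, collapse = "+"),
      sprintf(", p_in = %.2f, p_out = %.2f, seed = %d\n",
              object@pIn, object@pOut, object@seed))
})

setMethod("show", "CorrelationMatrix", function(object) {
  off <- object@gc[upper.tri(object@gc)]
  cat(sprintf(
    "CorrelationMatrix: %d sites (k = %d, %d frames, %d replica(s))\n",
    nrow(object@gc), object@k, object@nFrames, object@nReplicas))
  cat(sprintf("  off-diagonal GC: median %.3f, max %.3f\n",
              stats::median(off), max(off)))
})

setMethod("show", "ContactMap", function(object) {
  cat(sprintf(
    "ContactMap: %d residues, %d contacts (cutoffs: %.2f A, %.0f%% frames)\n",
    nrow(object@fraction), sum(object@adjacency[upper.tri(object@adjacency)]),
    object@distanceCutoff, 100 * object@frameCutoff))
})

setMethod("show", "WeightedNetwork", function(object) {
  cat("WeightedNetwork:", nrow(object@nodes), "nodes,",
      nrow(object@edges), "edges (w = -log GC)\n")
})

setMethod("show", "CommunityPartition", function(object) {
  cat(sprintf("CommunityPartition: %d communities over %d nodes, Q = %.4f\n",
              object@nCommunities, length(object@membership), object@q))
})

setMethod("show", "PCAModel", function(object) {
  cat(sprintf("PCAModel: %d modes, leading eigenvalue %.4f A^2 (%.1f%% var)\n",
              length(object@values), object@values[1],
              100 * object@varFraction[1]))
})

setMethod("show", "FreeEnergySurface", function(object) {
  cat(sprintf(
    "FreeEnergySurface (%d-D, %s, T = %g K): %d bins, %d unsampled\n",
    object@dim, object@unit, object@temperature, length(object@F),
    sum(is.na(object@F))))
})
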