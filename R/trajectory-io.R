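## Topology / trajectory reading, site reduction, superposition and
## mobility measures.  All coordinates are Angstrom internally.

SOLVENT_RESIDUES <- c("HOH", "WAT", "TIP3", "TIP4", "TIP5", "SPC", "SOL",
                      "SOD", "CLA", "POT", "NA+", "CL-", "MG", "ZN2", "CES")

NUCLEOTIDE_RESIDUES <- c("DA", "DT", "DG", "DC", "DU",
                         "A", "T", "G", "C", "U",
                         "ADE", "THY", "GUA", "CYT", "URA")

residueKey <- function(chain, resno) paste(chain, resno, sep = ":")

.deriveElement <- function(name, elesy = NULL) {
  el <- character(length(name))
  if (!is.null(elesy)) {
    ok <- !is.na(elesy) & nzchar(trimws(elesy))
    el[ok] <- toupper(trimws(elesy[ok]))
  }
  miss <- !nzchar(el)
  if (any(miss)) {
    # PDB convention: leading digits mark hydrogens (e.g. 1HB2)
    nm <- toupper(sub("^[0-9]+", "H", trimws(name[miss])))
    first <- substr(nm, 1, 1)
    two <- substr(nm, 1, 2)
    el[miss] <- ifelse(two %in% c("CL", "BR", "MG", "FE", "ZN", "NA"),
                       two, first)
  }
  el
}

#' Read a PDB-format topology
#'
#' Parses ATOM/HETATM records into a \code{\link{StructureModel}}.
#' Hydrogens are retained but flagged; water, common counter-ions and
#' alternate locations other than the first are dropped.  Chain ids and
#' residue numbering are preserved exactly as in the file.
#'
#' @param path path to a PDB file.
#' @param keepSolvent keep water/ion records (default FALSE).
#' @return a \code{\link{StructureModel}}.
#' @examples
#' pdb <- system.file("extdata", "toy_dipeptide.pdb", package = "allonet")
#' readTopology(pdb)
#' @export
readTopology <- function(path, keepSolvent = FALSE) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("empty input: no ATOM/HETATM records in ", path)
  bad <- which(rec)[vapply(which(rec), function(i) {
    fields <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
                substr(lines[i], 47, 54))
    any(is.na(suppressWarnings(as.numeric(fields))))
  }, logical(1))]
  if (length(bad))
    stop("format error: malformed coordinate field at line ", bad[1],
         " of ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  .modelFromAtomTable(pdb$atom, keepSolvent = keepSolvent, pdb = pdb)
}

.modelFromAtomTable <- function(at, keepSolvent = FALSE, pdb = NULL) {
  at$chain[is.na(at$chain)] <- " "
  if (!keepSolvent) at <- at[!(toupper(at$resid) %in% SOLVENT_RESIDUES), ,
                             drop = FALSE]
  if (!nrow(at)) stop("empty input: no atoms left after solvent stripping")
  # first altLoc only
  keepAlt <- is.na(at$alt) | at$alt %in% c("", " ", "A")
  at <- at[keepAlt, , drop = FALSE]
  dupKey <- paste(at$chain, at$resno, at$insert, at$elety)
  at <- at[!duplicated(dupKey), , drop = FALSE]
  element <- .deriveElement(at$elety, at$elesy)
  atoms <- data.frame(
    eleno = at$eleno, name = trimws(at$elety), element = element,
    resno = at$resno, resid = trimws(at$resid), chain = at$chain,
    x = at$x, y = at$y, z = at$z,
    hydrogen = element == "H", stringsAsFactors = FALSE)
  key <- residueKey(atoms$chain, atoms$resno)
  first <- !duplicated(key)
  residues <- data.frame(
    resno = atoms$resno[first], resid = atoms$resid[first],
    chain = atoms$chain[first], domain = NA_character_,
    stringsAsFactors = FALSE)
  gaps <- tapply(residues$resno, residues$chain,
                 function(v) any(diff(sort(v)) > 1))
  if (any(unlist(gaps), na.rm = TRUE))
    message("note: residue numbering gaps present in chain(s) ",
            paste(names(which(unlist(gaps))), collapse = ", "))
  new("StructureModel", atoms = atoms, residues = residues,
      pdb = if (is.null(pdb)) list() else list(pdb = pdb))
}

#' Assign domain labels to residues
#'
#' @param model a \code{\link{StructureModel}}.
#' @param map data.frame with columns \code{chain}, \code{start},
#'   \code{end}, \code{domain}; residues with \code{start <= resno <=
#'   end} on \code{chain} get the label.
#' @return the model with its residue table annotated.
#' @export
assignDomains <- function(model, map) {
  stopifnot(is(model, "StructureModel"),
            all(c("chain", "start", "end", "domain") %in% names(map)))
  res <- model@residues
  for (i in seq_len(nrow(map))) {
    hit <- res$chain == map$chain[i] &
      res$resno >= map$start[i] & res$resno <= map$end[i]
    res$domain[hit] <- map$domain[i]
  }
  model@residues <- res
  model
}

#' Read a multi-frame coordinate set
#'
#' Supported formats: multi-model PDB (MODEL/ENDMDL), DCD, and a plain
#' text fixture dialect (a line \code{FRAME k} followed by one
#' \code{x y z} line per atom, Angstrom).  Frames must match the atom
#' count of \code{model} (after the same solvent stripping).
#'
#' @param path trajectory file.
#' @param model the \code{\link{StructureModel}} the frames belong to.
#' @param format \code{"auto"} (by extension), \code{"pdb"},
#'   \code{"dcd"} or \code{"fixture"}.
#' @param dt frame interval in ps (metadata only).
#' @return a \code{\link{Trajectory}}.
#' @export
readTrajectory <- function(path, model,
                           format = c("auto", "pdb", "dcd", "fixture"),
                           dt = NA_real_) {
  stopifnot(is(model, "StructureModel"))
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      pdb = "pdb", ent = "pdb", dcd = "dcd",
      xtc = stop("XTC input is not supported; convert to DCD or ",
                 "multi-model PDB first"),
      "fixture")
  }
  nAtoms <- nrow(model@atoms)
  xyz <- switch(format,
    pdb = {
      pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
      m <- .modelFromAtomTable(pdb$atom)
      if (nrow(m@atoms) != nAtoms)
        stop("dimension error: trajectory has ", nrow(m@atoms),
             " atoms, model has ", nAtoms)
      keep <- !(toupper(trimws(pdb$atom$resid)) %in% SOLVENT_RESIDUES)
      idx <- which(keep)
      cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
      pdb$xyz[, cols, drop = FALSE]
    },
    dcd = {
      m <- bio3d::read.dcd(path, verbose = FALSE)
      if (ncol(m) != 3 * nAtoms)
        stop("dimension error: trajectory has ", ncol(m) / 3,
             " atoms, model has ", nAtoms)
      m
    },
    fixture = .readFixtureXYZ(path, nAtoms))
  nf <- nrow(xyz)
  arr <- array(NA_real_, dim = c(nf, nAtoms, 3))
  arr[, , 1] <- xyz[, seq(1, 3 * nAtoms, 3), drop = FALSE]
  arr[, , 2] <- xyz[, seq(2, 3 * nAtoms, 3), drop = FALSE]
  arr[, , 3] <- xyz[, seq(3, 3 * nAtoms, 3), drop = FALSE]
  new("Trajectory", coords = arr, dt = dt)
}

.readFixtureXYZ <- function(path, nAtoms) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  hdr <- grep("^FRAME\\b", lines)
  if (!length(hdr)) stop("format error: no FRAME headers in ", path)
  nf <- length(hdr)
  ends <- c(hdr[-1] - 1L, length(lines))
  xyz <- matrix(NA_real_, nf, 3 * nAtoms)
  for (f in seq_len(nf)) {
    block <- lines[(hdr[f] + 1L):ends[f]]
    if (length(block) != nAtoms || hdr[f] + 1L > ends[f])
      stop("format error: frame ", f, " has ", max(0L, length(block)),
           " coordinate lines, expected ", nAtoms,
           if (length(block) < nAtoms) " (truncated frame?)" else "")
    vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(block),
                                                        "[[:space:]]+"))))
    if (length(vals) != 3 * nAtoms || anyNA(vals))
      stop("format error: malformed coordinates in frame ", f)
    xyz[f, ] <- as.vector(t(matrix(vals, ncol = 3, byrow = TRUE)))
  }
  xyz
}

#' Write coordinates in the plain-text fixture dialect
#'
#' One \code{FRAME k} header per frame, then one \code{x y z} line per
#' atom/site, printed with \code{\%.6f}.  Reading the file back
#' reproduces the coordinates exactly at that precision.
#'
#' @param x a \code{Trajectory}, \code{SiteTrajectory} or
#'   \code{[frames, atoms, 3]} array.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeFixtureTrajectory <- function(x, path) {
  arr <- if (is.array(x) && length(dim(x)) == 3) x else coords(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(dim(arr)[1])) {
    writeLines(paste("FRAME", f), con)
    writeLines(sprintf("%.6f %.6f %.6f",
                       arr[f, , 1], arr[f, , 2], arr[f, , 3]), con)
  }
  invisible(path)
}

#' Reduce an atomic trajectory to one site per residue
#'
#' The default rule places each site at the residue's representative
#' atom: the alpha-carbon (CA) for amino acids and C1' for nucleotides.
#' Residues lacking the representative atom fall back to their
#' heavy-atom centre of geometry (with a warning).  Rule \code{"cog"}
#' uses the heavy-atom centre of geometry for every residue.
#'
#' @param traj a \code{\link{Trajectory}}.
#' @param model the matching \code{\link{StructureModel}}.
#' @param rule \code{"representative"} or \code{"cog"}.
#' @return a \code{\link{SiteTrajectory}} with one 3-D site per residue,
#'   in the residue order of the model.
#' @export
selectSites <- function(traj, model, rule = c("representative", "cog")) {
  stopifnot(is(traj, "Trajectory"), is(model, "StructureModel"))
  rule <- match.arg(rule)
  atoms <- model@atoms
  res <- model@residues
  if (!nrow(res)) stop("empty input: model has no residues")
  if (dim(traj@coords)[2] != nrow(atoms))
    stop("dimension error: trajectory/model atom count mismatch")
  nf <- dim(traj@coords)[1]
  out <- array(NA_real_, dim = c(nf, nrow(res), 3))
  akey <- residueKey(atoms$chain, atoms$resno)
  fellBack <- character(0)
  for (i in seq_len(nrow(res))) {
    key <- residueKey(res$chain[i], res$resno[i])
    idx <- which(akey == key)
    pick <- integer(0)
    if (rule == "representative") {
      repName <- if (toupper(res$resid[i]) %in% NUCLEOTIDE_RESIDUES)
        c("C1'", "C1*") else "CA"
      pick <- idx[atoms$name[idx] %in% repName & !atoms$hydrogen[idx]]
    }
    if (length(pick) >= 1L) {
      out[, i, ] <- traj@coords[, pick[1], ]
    } else {
      heavy <- idx[!atoms$hydrogen[idx]]
      if (rule == "representative") fellBack <- c(fellBack, key)
      slab <- traj@coords[, heavy, , drop = FALSE]
      out[, i, ] <- apply(slab, c(1, 3), mean)
    }
  }
  if (length(fellBack))
    warning("no representative atom for ", length(fellBack),
            " residue(s) (", paste(head(fellBack, 5), collapse = ", "),
            if (length(fellBack) > 5) ", ..." else "",
            "); used heavy-atom centre of geometry")
  sites <- res
  rownames(sites) <- NULL
  new("SiteTrajectory", coords = out, sites = sites, d = 3L)
}

# optimal rigid-body superposition (Kabsch): returns P (n x 3) moved so
# that P[idx, ] least-squares fits Q[idx, ]
.kabschFit <- function(P, Q, idx) {
  cp <- colMeans(P[idx, , drop = FALSE])
  cq <- colMeans(Q[idx, , drop = FALSE])
  H <- crossprod(sweep(P[idx, , drop = FALSE], 2, cp),
                 sweep(Q[idx, , drop = FALSE], 2, cq))
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  U <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(sweep(P, 2, cp) %*% t(U), 2, cq, `+`)
}

#' Rigid-body superposition of a site trajectory
#'
#' Least-squares fits every frame (optimal rotation + translation,
#' Kabsch algorithm) onto a reference over a fit selection.  With the
#' default \code{reference = "mean"} the fit follows the essential
#' dynamics convention: fit to the current mean structure, recompute the
#' mean, refit (two passes).
#'
#' @param straj a \code{\link{SiteTrajectory}}.
#' @param reference \code{"mean"} or an integer frame index.
#' @param fitSites integer site indices used for fitting (default: all).
#' @return a new, superposed \code{\link{SiteTrajectory}}.
#' @export
superpose <- function(straj, reference = "mean", fitSites = NULL) {
  stopifnot(is(straj, "SiteTrajectory"))
  arr <- straj@coords
  nf <- dim(arr)[1]; ns <- dim(arr)[2]
  if (is.null(fitSites)) fitSites <- seq_len(ns)
  if (length(fitSites) < 3)
    stop("degenerate fit: need at least 3 fit sites")
  refFrame <- if (identical(reference, "mean")) {
    apply(arr, c(2, 3), mean)
  } else {
    stopifnot(is.numeric(reference), reference >= 1, reference <= nf)
    arr[reference, , ]
  }
  sel <- refFrame[fitSites, , drop = FALSE]
  sv <- svd(sweep(sel, 2, colMeans(sel)))$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    stop("degenerate fit: fit selection is (near-)collinear")
  passes <- if (identical(reference, "mean")) 2L else 1L
  for (p in seq_len(passes)) {
    for (f in seq_len(nf)) {
      arr[f, , ] <- .kabschFit(arr[f, , ], refFrame, fitSites)
    }
    if (identical(reference, "mean") && p < passes)
      refFrame <- apply(arr, c(2, 3), mean)
  }
  new("SiteTrajectory", coords = arr, sites = straj@sites, d = 3L)
}

#' Per-frame RMSD against a reference
#'
#' @param straj a (superposed) \code{\link{SiteTrajectory}}.
#' @param reference integer frame index or \code{"mean"}.
#' @return a \code{\link{MobilityProfile}} of kind \code{"rmsd"} with
#'   one value per frame, Angstrom.
#' @export
rmsd <- function(straj, reference = 1L) {
  stopifnot(is(straj, "SiteTrajectory"))
  arr <- straj@coords
  ref <- if (identical(reference, "mean")) apply(arr, c(2, 3), mean)
         else arr[reference, , ]
  vals <- vapply(seq_len(dim(arr)[1]), function(f) {
    sqrt(mean(rowSums((arr[f, , ] - ref)^2)))
  }, numeric(1))
  new("MobilityProfile", values = vals, kind = "rmsd",
      reference = if (identical(reference, "mean")) "mean structure"
                  else paste("frame", reference),
      sites = data.frame())
}

#' Per-site root-mean-square fluctuation
#'
#' RMSF about the time-mean position; the trajectory should be
#' superposed first so rigid-body motion does not inflate the values.
#'
#' @param straj a superposed \code{\link{SiteTrajectory}} with at least
#'   2 frames.
#' @return a \code{\link{MobilityProfile}} of kind \code{"rmsf"},
#'   Angstrom, one value per site.
#' @export
rmsf <- function(straj) {
  stopifnot(is(straj, "SiteTrajectory"))
  arr <- straj@coords
  if (dim(arr)[1] < 2)
    stop("insufficient frames: RMSF needs at least 2 frames")
  mu <- apply(arr, c(2, 3), mean)
  dev2 <- sweep(arr, c(2, 3), mu)^2
  vals <- sqrt(apply(dev2, 2, mean) * 3)  # mean over frames & axes, x3
  new("MobilityProfile", values = vals, kind = "rmsf",
      reference = "time-mean structure", sites = straj@sites)
}

#' Differential RMSF between two states
#'
#' \code{apo - bound} per site: positive values mark residues stabilised
#' upon binding, negative values residues mobilised.
#'
#' @param apo,bound \code{\link{MobilityProfile}}s of kind
#'   \code{"rmsf"} over identical site lists.
#' @return data.frame with the site metadata and column \code{dRMSF}.
#' @export
differentialRmsf <- function(apo, bound) {
  stopifnot(is(apo, "MobilityProfile"), is(bound, "MobilityProfile"),
            apo@kind == "rmsf", bound@kind == "rmsf")
  ka <- residueKey(apo@sites$chain, apo@sites$resno)
  kb <- residueKey(bound@sites$chain, bound@sites$resno)
  if (!identical(ka, kb))
    stop("alignment error: the two profiles cover different site lists")
  out <- apo@sites
  out$dRMSF <- apo@values - bound@values
  out
}

#' Write per-residue scores into the B-factor column of a PDB file
#'
#' Every atom of a residue gets the residue's score; residues missing
#' from \code{scores} get 0 (with a warning).  Values outside the fixed
#' PDB column width are clipped to [-99.99, 999.99] with a warning.
#'
#' @param model a \code{\link{StructureModel}}.
#' @param scores numeric vector, either named by \code{"CHAIN:RESNO"} or
#'   of length \code{nrow(siteInfo(model))} in residue order.
#' @param path output PDB path.
#' @return \code{path}, invisibly.
#' @export
writeScoresAsBfactor <- function(model, scores, path) {
  stopifnot(is(model, "StructureModel"))
  res <- model@residues
  key <- residueKey(res$chain, res$resno)
  if (is.null(names(scores))) {
    if (length(scores) != nrow(res))
      stop("scores must be named by CHAIN:RESNO or cover every residue")
    names(scores) <- key
  }
  full <- setNames(rep(0, nrow(res)), key)
  known <- intersect(names(scores), key)
  full[known] <- scores[known]
  if (length(known) < nrow(res))
    warning(nrow(res) - length(known),
            " residue(s) absent from scores; B-factor set to 0")
  if (any(full > 999.99 | full < -99.99)) {
    warning("scores clipped to the PDB B-factor column width")
    full <- pmin(pmax(full, -99.99), 999.99)
  }
  atoms <- model@atoms
  b <- full[residueKey(atoms$chain, atoms$resno)]
  xyz <- as.vector(t(as.matrix(atoms[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = atoms$resno,
                   resid = atoms$resid, eleno = atoms$eleno,
                   elety = atoms$name, chain = atoms$chain,
                   b = round(b, 2))
  invisible(path)
}

#' Write a mobility profile as TSV
#'
#' @param profile a \code{\link{MobilityProfile}}.
#' @param path output file.
#' @param header optional comment lines (each prefixed with '#').
#' @return \code{path}, invisibly.
#' @export
writeMobilityProfile <- function(profile, path, header = character(0)) {
  stopifnot(is(profile, "MobilityProfile"))
  df <- if (nrow(profile@sites)) {
    data.frame(site_index = seq_along(profile@values),
               chain = profile@sites$chain, resid = profile@sites$resno,
               value = profile@values)
  } else {
    data.frame(frame = seq_along(profile@values), value = profile@values)
  }
  .writeTSV(df, path, header)
  invisible(path)
}

.writeTSV <- function(df, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.10g", v))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}
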