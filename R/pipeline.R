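## Configuration-driven orchestration of the full analysis chain.

#' Read a pipeline run configuration
#'
#' Configurations are YAML.  Recognised fields (defaults in
#' parentheses):
#' \preformatted{
#' topology: path.pdb           # required
#' trajectories: [r1.traj, ...] # required, one per replica
#' domains:                     # optional chain/start/end/domain rows
#'   - {chain: A, start: 1, end: 10, domain: alpha}
#' k: 6                         # MI neighbour count
#' siteRule: representative     # or cog
#' distanceCutoff: 5.5          # contact distance, Angstrom
#' frameCutoff: 0.75            # contact persistence fraction
#' suboptTolerance: 0.02        # sub-optimal path tolerance
#' intensityCutoff: 0.6         # correlation-score GC cutoff
#' bins: 50                     # FES bins per axis
#' temperature: 310             # K
#' seed: 1
#' paths:                       # optional source/target pairs
#'   - {source: "A:5", target: "B:5"}
#' crdScan: {distanceGrid: [5.0, 5.5, 6.0]}   # optional
#' outputDir: out
#' }
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  cfg$configFile <- path
  validateRunConfig(cfg)
}

#' Validate and complete a pipeline configuration
#'
#' Fills defaults and checks every cutoff range before any computation.
#'
#' @param cfg configuration list (see \code{\link{readRunConfig}}).
#' @return the completed configuration.
#' @export
validateRunConfig <- function(cfg) {
  defaults <- list(k = 6L, siteRule = "representative",
                   distanceCutoff = 5.5, frameCutoff = 0.75,
                   suboptTolerance = 0.02, intensityCutoff = 0.6,
                   bins = 50L, temperature = 310, seed = 1L,
                   superpose = TRUE, outputDir = "allonet-out")
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  fail <- function(...) stop("validation error: ", ...)
  if (is.null(cfg$topology)) fail("topology path missing")
  if (is.null(cfg$trajectories) || !length(cfg$trajectories))
    fail("trajectories missing")
  if (cfg$frameCutoff <= 0 || cfg$frameCutoff > 1)
    fail("frameCutoff must lie in (0, 1]")
  if (cfg$distanceCutoff <= 0) fail("distanceCutoff must be positive")
  if (cfg$suboptTolerance < 0) fail("suboptTolerance must be >= 0")
  if (cfg$intensityCutoff < 0 || cfg$intensityCutoff >= 1)
    fail("intensityCutoff must lie in [0, 1)")
  if (cfg$k < 1) fail("k must be >= 1")
  if (cfg$bins < 10) fail("bins must be >= 10")
  if (!cfg$siteRule %in% c("representative", "cog"))
    fail("unknown siteRule: ", cfg$siteRule)
  if (!is.logical(cfg$superpose)) fail("superpose must be true/false")
  cfg$k <- as.integer(cfg$k)
  cfg$bins <- as.integer(cfg$bins)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

.configHash <- function(cfg) {
  # hash only the analysis-relevant fields: where the outputs land (or
  # which file the config came from) must not change the numbers
  cfg$configFile <- NULL
  cfg$outputDir <- NULL
  cfg <- cfg[order(names(cfg))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: topology/trajectory reading, site selection,
#' superposition, per-replica generalized correlation estimation and
#' replica averaging, correlation and contribution scores, contact map,
#' weighted network construction, requested shortest/sub-optimal
#' pathways, Girvan-Newman communities, optional cutoff-convergence
#' scan, PCA, and 1-D/2-D free-energy surfaces along PC1/PC2.  All
#' stage outputs are plain text files in \code{outputDir}, each headed
#' by the package version, config hash and seed; a run is therefore
#' byte-reproducible given the same config and seed.  A
#' \code{manifest.json} lists parameters and per-file checksums.  On a
#' stage failure the manifest records the partial completion before the
#' error propagates.
#'
#' @param config a config list or path to a YAML config
#'   (\code{\link{readRunConfig}}).
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config) {
  cfg <- if (is.character(config)) readRunConfig(config)
         else validateRunConfig(config)
  dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
  hash <- .configHash(cfg)
  hdr <- c(paste0("allonet ", as.character(packageVersion("allonet"))),
           paste0("config: ", hash), paste0("seed: ", cfg$seed))
  manifest <- list(package = as.character(packageVersion("allonet")),
                   configHash = hash, seed = cfg$seed,
                   parameters = cfg[setdiff(names(cfg),
                                            c("configFile", "outputDir"))],
                   stages = character(0), outputs = list())
  outPath <- function(name) file.path(cfg$outputDir, name)
  record <- function(stage, files = character(0)) {
    manifest$stages <<- c(manifest$stages, stage)
    for (f in files)
      manifest$outputs[[basename(f)]] <<- unname(tools::md5sum(f))
    writeManifest()
  }
  writeManifest <- function() {
    jsonlite::write_json(manifest, outPath("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  run <- function() {
    set.seed(cfg$seed)
    model <- readTopology(cfg$topology)
    if (!is.null(cfg$domains)) {
      dm <- do.call(rbind, lapply(cfg$domains, as.data.frame))
      model <- assignDomains(model, dm)
    }
    record("topology")

    strajs <- lapply(cfg$trajectories, function(tp) {
      traj <- readTrajectory(tp, model)
      straj <- selectSites(traj, model,
                           rule = if (cfg$siteRule == "cog") "cog"
                                  else "representative")
      if (isTRUE(cfg$superpose)) superpose(straj) else straj
    })
    record("sites")

    cms <- lapply(strajs, gcMatrix, k = cfg$k)
    cm <- if (length(cms) > 1) averageMatrices(cms) else cms[[1]]
    writeCorrelationMatrix(cm, outPath("gc_matrix.txt"), header = hdr)
    record("gc", outPath("gc_matrix.txt"))

    prof <- rmsf(strajs[[1]])
    writeMobilityProfile(prof, outPath("rmsf.tsv"), header = hdr)
    record("rmsf", outPath("rmsf.tsv"))

    haveDomains <- !anyNA(cm@sites$domain)
    sAll <- correlationScores(cm, "all", cfg$intensityCutoff)
    .writeTSV(sAll, outPath("scores_all.tsv"), hdr)
    scoreFiles <- outPath("scores_all.tsv")
    if (haveDomains) {
      sInter <- correlationScores(cm, "inter", cfg$intensityCutoff)
      .writeTSV(sInter, outPath("scores_inter.tsv"), hdr)
      scoreFiles <- c(scoreFiles, outPath("scores_inter.tsv"))
    }
    contrib <- contributionScores(cm)
    .writeTSV(contrib, outPath("contribution_scores.tsv"),
              c(hdr, sprintf("TS = %.10g, N = %d", attr(contrib, "TS"),
                             attr(contrib, "Ntotal"))))
    record("scores", c(scoreFiles, outPath("contribution_scores.tsv")))

    pooled <- .concatSiteTrajectories(strajs)
    cmap <- contactMap(pooled, distanceCutoff = cfg$distanceCutoff,
                       frameCutoff = cfg$frameCutoff)
    net <- buildNetwork(cmap, cm)
    writeNetwork(net, outPath("network_edges.tsv"), header = hdr)
    record("network", outPath("network_edges.tsv"))

    if (!is.null(cfg$paths)) {
      pathRecords <- lapply(cfg$paths, function(p) {
        sp <- shortestPath(net, p$source, p$target)
        sub <- if (sp$status == "shortest")
          suboptimalPaths(net, p$source, p$target,
                          tolerance = cfg$suboptTolerance)
        else list()
        list(source = p$source, target = p$target, shortest = sp,
             suboptimal = sub)
      })
      jsonlite::write_json(pathRecords, outPath("paths.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      record("paths", outPath("paths.json"))
    }

    part <- girvanNewman(net)
    .writeTSV(data.frame(node = names(part@membership),
                         community = unname(part@membership)),
              outPath("communities.tsv"),
              c(hdr, sprintf("modularity Q = %.10g", part@q)))
    manifest$modularity <<- part@q
    record("communities", outPath("communities.tsv"))

    if (!is.null(cfg$crdScan)) {
      scan <- cutoffScan(pooled, cm = cm,
                         distanceGrid = unlist(cfg$crdScan$distanceGrid),
                         frameGrid = if (is.null(cfg$crdScan$frameGrid))
                           cfg$frameCutoff
                         else unlist(cfg$crdScan$frameGrid))
      .writeTSV(scan, outPath("crd_scan.tsv"), hdr)
      record("crd-scan", outPath("crd_scan.tsv"))
    }

    pca <- fitPCA(pooled)
    .writeTSV(data.frame(mode = seq_along(pca@values),
                         eigenvalue = pca@values,
                         varFraction = pca@varFraction),
              outPath("pca_eigenvalues.tsv"), hdr)
    q1 <- projectMode(pooled, pca, 1L)
    q2 <- if (length(pca@values) >= 2) projectMode(pooled, pca, 2L)
          else NULL
    .writeTSV(data.frame(frame = seq_along(q1), pc1 = q1,
                         pc2 = if (is.null(q2)) NA_real_ else q2),
              outPath("projections.tsv"), hdr)
    record("pca", c(outPath("pca_eigenvalues.tsv"),
                    outPath("projections.tsv")))

    writeSurface(freeEnergy1D(q1, cfg$bins, cfg$temperature),
                 outPath("fes_pc1.tsv"), hdr)
    fesFiles <- outPath("fes_pc1.tsv")
    if (!is.null(q2)) {
      writeSurface(freeEnergy2D(q1, q2, cfg$bins, cfg$temperature),
                   outPath("fes_pc1_pc2.tsv"), hdr)
      fesFiles <- c(fesFiles, outPath("fes_pc1_pc2.tsv"))
    }
    record("fes", fesFiles)
  }

  ok <- tryCatch({ run(); TRUE },
                 error = function(e) {
                   manifest$error <<- conditionMessage(e)
                   writeManifest()
                   stop(e)
                 })
  manifest$complete <- ok
  writeManifest()
  invisible(manifest)
}

.concatSiteTrajectories <- function(strajs) {
  if (length(strajs) == 1) return(strajs[[1]])
  ref <- strajs[[1]]
  arrs <- lapply(strajs, function(s) s@coords)
  total <- sum(vapply(arrs, function(a) dim(a)[1], numeric(1)))
  out <- array(NA_real_, dim = c(total, dim(arrs[[1]])[2], 3))
  at <- 1L
  for (a in arrs) {
    nf <- dim(a)[1]
    out[at:(at + nf - 1), , ] <- a
    at <- at + nf
  }
  new("SiteTrajectory", coords = out, sites = ref@sites, d = 3L)
}
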