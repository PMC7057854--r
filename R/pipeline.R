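## Pipeline orchestration: config handling and the simulate ->
## populations -> fep -> dissect -> lipo stages, each writing TSV + JSON
## reports. All defaults are materialized into the config and echoed
## into every report for provenance; reports carry no timestamps so a
## rerun with the same config and seed is byte-identical.

#' Assemble a pipeline configuration
#'
#' Materializes every default so that reports can echo the exact
#' settings used. Values: `threshold` 2.6 Angstrom (population split),
#' `binWidth` 0.1 Angstrom (RMSD histograms), `nBlocks` 5 (block
#' uncertainties), `temperature` 298.15 K, `probeRadius` 1.4 Angstrom,
#' `nPoints` 960 (SASA lattice), `surfaceStride` 20 (SASA frame
#' subsampling), `nFrames` 5000 and `pValues` (the synthetic study),
#' `referenceLigand` "5_MeMe", `seed` 1.
#'
#' @param ... overrides of any default, plus path entries
#'   (`ensembleDir`, `referencePath`, `fepEdgeTable`, `affinityTable`,
#'   `outDir`).
#' @return named list with class "PipelineConfig".
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    threshold = 2.6, binWidth = 0.1, nBlocks = 5L,
    temperature = 298.15, probeRadius = 1.4, nPoints = 960L,
    surfaceStride = 20L, nFrames = 5000L,
    pValues = c("7_HH" = 0.06, "9_MeH" = 0.16,
                "5_MeMe" = 0.30, "11_EtMe" = 0.40),
    referenceLigand = "5_MeMe", seed = 1L,
    ensembleDir = NULL, referencePath = NULL, fepEdgeTable = NULL,
    affinityTable = NULL, outDir = ".")
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config entr", if (length(unknown) > 1) "ies: " else "y: ",
         paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML (or JSON) file
#'
#' Keys present in the file override the defaults of
#' [pipelineConfig()]; everything else keeps its default.
#'
#' @param path path to a YAML key-value file.
#' @return a "PipelineConfig" list.
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$pValues)) vals$pValues <- unlist(vals$pValues)
  do.call(pipelineConfig, vals)
}

.configEcho <- function(config) {
  e <- unclass(config)
  e$pValues <- as.list(e$pValues)
  e[!vapply(e, is.null, logical(1))]
}

.writeReport <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, na = "null")
  invisible(path)
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.loadEnsembles <- function(config) {
  if (is.null(config$ensembleDir))
    stop("config$ensembleDir is not set")
  if (!dir.exists(config$ensembleDir))
    stop("ensemble directory not found: ", config$ensembleDir)
  files <- list.files(config$ensembleDir, pattern = "\\.(pdb|xyz)$",
                      full.names = TRUE)
  files <- files[basename(files) != "reference.pdb"]
  if (!length(files)) stop("no ensemble files in ", config$ensembleDir)
  ens <- lapply(sort(files), readEnsemble)
  names(ens) <- vapply(ens, ligandId, character(1))
  ens
}

.loadReference <- function(config) {
  if (is.null(config$referencePath))
    stop("config$referencePath is not set")
  e <- readEnsemble(config$referencePath, ligandId = "reference")
  # reference files carry one model; masks: backbone = N/CA/C/O atoms,
  # crosslink = CX-named atoms
  atoms <- atomData(e)
  bb <- which(atoms$name %in% c("N", "CA", "C", "O"))
  cx <- grep("^CX", atoms$name)
  msk <- list(backbone = bb, all = seq_len(nrow(atoms)))
  if (length(cx)) msk$crosslink <- cx
  ReferenceStructure(atoms, frames(e)[[1]], masks = msk)
}

#' Simulate a complete synthetic study to disk
#'
#' Writes, under `config$outDir`: one multi-model PDB ensemble per
#' ligand of the synthetic population study, the toy reference
#' structure (`reference.pdb`), a two-leg FEP edge table
#' (`fep_edges.tsv`) whose true node values correspond to a direct-term
#' series, and an affinity/logD table (`affinity.tsv`).
#'
#' @param config a [pipelineConfig()]; `nFrames`, `pValues` and `seed`
#'   control the study.
#' @return list of written paths, invisibly.
#' @export
runSimulate <- function(config = pipelineConfig()) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  study <- makeStudy(nFrames = config$nFrames, seed = config$seed,
                     pValues = config$pValues)
  paths <- list()
  refPath <- file.path(config$outDir, "reference.pdb")
  refEns <- ConformerEnsemble("reference", study$reference@atoms,
                              list(study$reference@coords))
  writeEnsemble(refEns, refPath)
  paths$reference <- refPath
  for (id in names(study$ensembles)) {
    p <- file.path(config$outDir, paste0(id, ".pdb"))
    writeEnsemble(study$ensembles[[id]], p)
    paths[[id]] <- p
  }
  # FEP network over the study ligands: direct-interaction differences
  # (kcal/mol, vs the reference ligand), a chain of edges plus
  # skip-one redundancy so the network has cycles
  ids <- names(config$pValues)
  if (length(ids) < 2L) stop("the study needs at least 2 ligands")
  nodeDdg <- setNames(seq(2.7, -0.3, length.out = length(ids)), ids)
  if (config$referenceLigand %in% ids)
    nodeDdg <- nodeDdg - nodeDdg[[config$referenceLigand]]
  chain <- data.frame(from = ids[-length(ids)], to = ids[-1],
                      stringsAsFactors = FALSE)
  skip <- if (length(ids) >= 3L)
    data.frame(from = ids[seq_len(length(ids) - 2L)],
               to = ids[-(1:2)], stringsAsFactors = FALSE)
  edges <- rbind(chain, skip)
  tabs <- lapply(c(0.1, 1, 10), function(fc)
    makeFepNetwork(NetworkSpec(nodeDdg, edges, noiseSigma = 0.15,
                               seed = (config$seed %% 2000000L) * 100L +
                                 round(fc * 10)),
                   forceConstant = fc))
  fepPath <- file.path(config$outDir, "fep_edges.tsv")
  .writeTsv(do.call(rbind, tabs), fepPath)
  paths$fepEdges <- fepPath
  # affinity table spanning the measured ranges of the substitution
  # panel (pKd 3.5-6.1, MW ~1358-1400 g/mol, logD 0.63-1.31)
  k <- length(ids)
  aff <- data.frame(
    ligand_id = ids,
    pKd = seq(3.5, 6.06, length.out = k),
    MW = round(seq(1358, 1400, length.out = k)),
    logD = seq(0.63, 1.31, length.out = k))
  affPath <- file.path(config$outDir, "affinity.tsv")
  .writeTsv(aff, affPath)
  paths$affinity <- affPath
  invisible(paths)
}

#' Population analysis stage
#'
#' Computes an RMSD series per ligand ensemble against the reference,
#' classifies frames into populations 1/2 at the configured threshold,
#' and writes `populations.tsv`, `histograms.tsv` and
#' `populations.json` (with the full config echoed) under
#' `config$outDir`.
#'
#' @param config a [pipelineConfig()] with `ensembleDir` and
#'   `referencePath` set (or pass objects directly).
#' @param ensembles optional named list of [ConformerEnsemble-class],
#'   bypassing `ensembleDir`.
#' @param reference optional [ReferenceStructure-class], bypassing
#'   `referencePath`.
#' @return list with `estimates` (per-ligand
#'   [PopulationEstimate-class]), `table` (data.frame) and
#'   `histograms`; invisibly.
#' @export
runPopulations <- function(config = pipelineConfig(), ensembles = NULL,
                           reference = NULL) {
  if (is.null(ensembles)) ensembles <- .loadEnsembles(config)
  if (is.null(reference)) reference <- .loadReference(config)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  estimates <- list(); histRows <- list()
  for (id in names(ensembles)) {
    rs <- rmsdSeries(ensembles[[id]], reference)
    estimates[[id]] <- classifyPopulations(rs, threshold = config$threshold,
                                           nBlocks = config$nBlocks)
    h <- rmsdHistogram(rs, binWidth = config$binWidth)
    h$ligand <- id
    histRows[[id]] <- h
  }
  tab <- do.call(rbind, lapply(estimates, function(e) data.frame(
    ligand = e@ligandId, p1 = e@p1, p2 = e@p2, sigma_p1 = e@sigmaP1,
    threshold_A = e@threshold, n_blocks = e@nBlocks,
    stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  hist <- do.call(rbind, histRows); rownames(hist) <- NULL
  .writeTsv(tab, file.path(config$outDir, "populations.tsv"))
  .writeTsv(hist, file.path(config$outDir, "histograms.tsv"))
  .writeReport(list(
    config = .configEcho(config),
    populations = lapply(estimates, function(e) list(
      ligand = e@ligandId, p1 = e@p1, p2 = e@p2,
      sigma_p1 = e@sigmaP1, per_block_p1 = e@perBlockP1,
      threshold_A = e@threshold, n_blocks = e@nBlocks))),
    file.path(config$outDir, "populations.json"))
  invisible(list(estimates = estimates, table = tab, histograms = hist))
}

#' FEP network stage
#'
#' Reads the edge table, assembles one binding network per restraint
#' level, and reports per-level relative pKd estimates, per-edge
#' hysteresis, cycle-closure errors and the restraint-sensitivity
#' spread. Writes `fep.tsv` (per-ligand, per-level dpkd) and
#' `fep.json`.
#'
#' @param config a [pipelineConfig()] with `fepEdgeTable` and
#'   `referenceLigand` set.
#' @return list with `networks`, `dpkd` (data.frame ligand x level),
#'   `hysteresis`, `closure`, `sensitivity`; invisibly.
#' @export
runFep <- function(config = pipelineConfig()) {
  if (is.null(config$fepEdgeTable)) stop("config$fepEdgeTable is not set")
  tab <- read.delim(config$fepEdgeTable, stringsAsFactors = FALSE)
  nets <- readFepEdges(config$fepEdgeTable, config$referenceLigand)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  dpkdTables <- lapply(nets, relativeDpkd, temperature = config$temperature)
  long <- do.call(rbind, lapply(names(dpkdTables), function(fc) {
    d <- dpkdTables[[fc]]; d$force_constant <- fc; d
  }))
  rownames(long) <- NULL
  hyst <- if ("ddG_reverse_kcal_mol" %in% names(tab))
    data.frame(tab[, c("ligand_from", "ligand_to", "leg")],
               force_constant = tab$force_constant,
               hysteresis = edgeHysteresis(tab$ddG_kcal_mol,
                                           tab$ddG_reverse_kcal_mol))
  else NULL
  closure <- lapply(nets, cycleClosure)
  sens <- if (length(dpkdTables) >= 2L)
    restraintSensitivity(dpkdTables) else NULL
  .writeTsv(long, file.path(config$outDir, "fep.tsv"))
  .writeReport(list(
    config = .configEcho(config),
    dpkd = long,
    cycle_closure = lapply(closure, function(cl)
      list(rms = cl$rms, closures = cl$cycles$closure)),
    rms_hysteresis = if (!is.null(hyst))
      sqrt(mean(hyst$hysteresis^2, na.rm = TRUE)) else NULL,
    restraint_sensitivity = sens),
    file.path(config$outDir, "fep.json"))
  invisible(list(networks = nets, dpkd = long, hysteresis = hyst,
                 closure = closure, sensitivity = sens))
}

#' Dissection stage: direct vs. conformational contributions
#'
#' Combines the FEP stage's direct-interaction Delta-pKd (averaged over
#' restraint levels) with the population stage's conformational term
#' `log10(p1_ligand / p1_reference)` into per-ligand dissections versus
#' the reference ligand. Writes `dissect.tsv` and `dissect.json`.
#'
#' @param config a [pipelineConfig()].
#' @param populations output of [runPopulations()]; recomputed from
#'   config paths when `NULL`.
#' @param fep output of [runFep()]; recomputed when `NULL`.
#' @return data.frame of dissections, invisibly.
#' @export
runDissect <- function(config = pipelineConfig(), populations = NULL,
                       fep = NULL) {
  if (is.null(populations)) populations <- runPopulations(config)
  if (is.null(fep)) fep <- runFep(config)
  ref <- config$referenceLigand
  popTab <- populations$table
  if (!ref %in% popTab$ligand)
    stop("reference ligand '", ref, "' missing from the population report")
  direct <- stats::aggregate(dpkd ~ ligand, data = fep$dpkd, FUN = mean)
  shared <- intersect(direct$ligand, popTab$ligand)
  shared <- setdiff(shared, ref)
  if (!length(shared))
    stop("population and FEP reports share no non-reference ligands")
  pRef <- popTab$p1[popTab$ligand == ref]
  rows <- lapply(shared, function(id) {
    d <- dissectAffinity(
      direct$dpkd[direct$ligand == id],
      conformationalDpkd(popTab$p1[popTab$ligand == id], pRef),
      ligandPair = c(id, ref))
    data.frame(ligand = id, reference = ref,
               dpkd_direct = d$dpkdDirect,
               dpkd_conformational = d$dpkdConformational,
               dpkd_total = d$dpkdTotal,
               fraction_conformational = d$fractionConformational,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  .writeTsv(out, file.path(config$outDir, "dissect.tsv"))
  .writeReport(list(config = .configEcho(config), dissection = out),
               file.path(config$outDir, "dissect.json"))
  invisible(out)
}

#' Lipophilicity stage: dynamic surface areas and the logD model
#'
#' Computes ensemble-averaged PSA/NPSA per ligand (subsampling frames
#' by `surfaceStride`), correlates them with measured logD from the
#' affinity table, and fits the linear logD model when at least four
#' ligands carry logD (otherwise correlations only, with a warning).
#' Writes `lipo.tsv` and `lipo.json`.
#'
#' @param config a [pipelineConfig()] with `affinityTable` set.
#' @param ensembles optional named list of ensembles (bypasses
#'   `ensembleDir`).
#' @return list with `surfaces` (data.frame), `correlations`, `model`
#'   (a [LipoModel-class] or `NULL`) and `predictions`; invisibly.
#' @export
runLipo <- function(config = pipelineConfig(), ensembles = NULL) {
  if (is.null(ensembles)) ensembles <- .loadEnsembles(config)
  if (is.null(config$affinityTable)) stop("config$affinityTable is not set")
  aff <- readAffinityTable(config$affinityTable)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  surf <- do.call(rbind, lapply(names(ensembles), function(id) {
    e <- ensembles[[id]]
    keep <- seq(1L, nFrames(e), by = max(1L, config$surfaceStride))
    s <- ensembleSurface(e, probeRadius = config$probeRadius,
                         nPoints = config$nPoints, framesSubset = keep)
    data.frame(ligand = id, n_frames_used = length(keep),
               mean_psa_A2 = s@meanPsa, mean_npsa_A2 = s@meanNpsa,
               sigma_psa = s@sigmaPsa, sigma_npsa = s@sigmaNpsa,
               stringsAsFactors = FALSE)
  }))
  merged <- merge(surf, aff[, c("ligand_id", "logD")],
                  by.x = "ligand", by.y = "ligand_id")
  merged <- merged[!is.na(merged$logD), ]
  corrs <- NULL; model <- NULL; preds <- NULL
  if (nrow(merged) >= 3L) {
    corrs <- list(
      psa_logd = pearsonR(merged$mean_psa_A2, merged$logD),
      npsa_logd = pearsonR(merged$mean_npsa_A2, merged$logD))
  }
  if (nrow(merged) >= 4L) {
    model <- fitLogdModel(merged$mean_psa_A2, merged$mean_npsa_A2,
                          merged$logD, descriptorScale = "Angstrom^2")
    preds <- data.frame(
      ligand = merged$ligand, logD_measured = merged$logD,
      logD_predicted = predictLogd(model, merged$mean_psa_A2,
                                   merged$mean_npsa_A2))
  } else {
    warning("fewer than 4 ligands with logD: regression skipped")
  }
  .writeTsv(surf, file.path(config$outDir, "lipo.tsv"))
  .writeReport(list(
    config = .configEcho(config), surfaces = surf,
    correlations = corrs,
    model = if (!is.null(model)) list(
      coef_npsa = model@coefNpsa, coef_psa = model@coefPsa,
      intercept = model@intercept, r_fit = model@pearsonRFit,
      n = model@n, descriptor_scale = model@descriptorScale),
    predictions = preds),
    file.path(config$outDir, "lipo.json"))
  invisible(list(surfaces = surf, correlations = corrs, model = model,
                 predictions = preds))
}
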