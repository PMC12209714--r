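#' Pipeline run configuration
#'
#' Defaults reproduce the analysis settings the package targets: age and TIV
#' covariates, a K = 2..10 stability scan with 5 folds, FDR level 0.05 and a
#' 40-voxel extent threshold with 26-connectivity.
#'
#' @param tablePath morphometry table (delimited text).
#' @param outDir output directory.
#' @param altTablePath optional alternate-parcellation table for cross-atlas
#'   validation.
#' @param clinicalPath optional clinical score table.
#' @param phantomPath,labelsPath optional 4D subject volumes and 3D label map
#'   (NIfTI) for the voxel-wise stage.
#' @param covariates,kRange,nFolds,C,nRestarts,finalRestarts,maxIter
#'   subtyping settings (see \code{\link{subtypingConfig}}).
#' @param alpha FDR level.
#' @param minCluster voxel extent threshold (survival requires size > this).
#' @param connectivity 6, 18 or 26.
#' @param seed master seed for every stochastic stage.
#' @param runSplitHalf run split-half validation (default TRUE).
#' @return named list of class \code{"RunConfig"}.
#' @export
runConfig <- function(tablePath, outDir, altTablePath = NULL,
                      clinicalPath = NULL, phantomPath = NULL,
                      labelsPath = NULL,
                      covariates = c("age", "tiv"), kRange = 2:10,
                      nFolds = 5L, C = 1, nRestarts = 2L, finalRestarts = 10L,
                      maxIter = 50L, alpha = 0.05, minCluster = 40,
                      connectivity = 26, seed = 1L, runSplitHalf = TRUE) {
  structure(list(tablePath = tablePath, outDir = outDir,
                 altTablePath = altTablePath, clinicalPath = clinicalPath,
                 phantomPath = phantomPath, labelsPath = labelsPath,
                 covariates = covariates, kRange = kRange, nFolds = nFolds,
                 C = C, nRestarts = nRestarts, finalRestarts = finalRestarts,
                 maxIter = maxIter, alpha = alpha, minCluster = minCluster,
                 connectivity = connectivity, seed = as.integer(seed),
                 runSplitHalf = isTRUE(runSplitHalf)),
            class = "RunConfig")
}

#' Load a RunConfig from JSON
#'
#' @param path JSON file written by \code{\link{saveRunConfig}}.
#' @return a \code{"RunConfig"} list.
#' @export
loadRunConfig <- function(path) {
  stopIf(!file.exists(path), "config file not found: %s", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$kRange <- as.integer(cfg$kRange)
  do.call(runConfig, cfg[!vapply(cfg, is.null, logical(1))])
}

#' Save a RunConfig to JSON
#'
#' @param config a \code{"RunConfig"}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
saveRunConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

# Renumber consensus labels so that subtype 1 is the most morphologically
# altered (most significant regions vs controls), subtype 2 the next, etc.
canonicalizeSubtypes <- function(labels, features, alpha = 0.05) {
  ks <- sort(unique(labels))
  counts <- vapply(ks, function(k) {
    tmp <- ifelse(labels == k, 1L, 2L)
    sum(roiGroupTest(features, tmp, "subtype1", alpha = alpha)$significant)
  }, numeric(1))
  ord <- order(-counts, ks)
  map <- integer(max(ks))
  map[ks[ord]] <- seq_along(ks)
  list(labels = stats::setNames(map[labels], names(labels)),
       sigCounts = stats::setNames(counts[ord], seq_along(ks)))
}

#' Run the full subtyping analysis pipeline
#'
#' Stages, in order: ingest and validate inputs; residualize covariates;
#' stability-scan K and derive consensus subtypes; canonicalize subtype
#' numbering (subtype 1 = most altered vs controls); split-half and
#' cross-parcellation validation; region-wise difference tests per contrast;
#' optional voxel-wise difference maps; optional clinical comparisons; and a
#' single JSON run report recording every seed, parameter and result.
#' Outputs carry no timestamps, so re-running an identical config reproduces
#' them byte for byte.
#'
#' @param config a \code{"RunConfig"} (see \code{\link{runConfig}}) or the
#'   path to its JSON serialization.
#' @return the run report, invisibly (also written to
#'   \code{outDir/run_report.json}).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- loadRunConfig(config)
  stopifnot(inherits(config, "RunConfig"))
  for (f in c("tablePath", "altTablePath", "clinicalPath", "phantomPath",
              "labelsPath")) {
    pth <- config[[f]]
    stopIf(!is.null(pth) && !file.exists(pth),
           "input file for %s not found: %s", f, pth)
  }
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  report <- list(parameters = unclass(config))

  ms <- readMorphometryTable(config$tablePath, parcellation = "primary")
  scfg <- subtypingConfig(covariates = config$covariates,
                          kRange = config$kRange, nFolds = config$nFolds,
                          C = config$C, nRestarts = config$nRestarts,
                          finalRestarts = config$finalRestarts,
                          maxIter = config$maxIter)

  run <- subtypeCohort(ms, scfg, seed = config$seed)
  canon <- canonicalizeSubtypes(run$labels, run$features, config$alpha)
  labels <- canon$labels
  writeSubtypeTable(labels, file.path(config$outDir, "subtypes.tsv"))
  report$stability <- list(K = run$profile@K, mean_ari = run$profile@meanARI,
                           n_folds = run$profile@nFolds,
                           selected_k = selectedK(run$profile),
                           forced_k = length(config$kRange) == 1L)
  report$subtypes <- list(counts = as.list(table(labels)),
                          sig_region_counts = as.list(canon$sigCounts))
  jsonlite::write_json(report$stability,
                       file.path(config$outDir, "stability_profile.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (config$runSplitHalf) {
    sh <- splitHalfConsistency(ms, scfg, seed = config$seed,
                               reference = labels)
    report$split_half <- lapply(sh$reports, agreementAsList)
  }
  if (!is.null(config$altTablePath)) {
    msAlt <- readMorphometryTable(config$altTablePath, parcellation = "alternate")
    cp <- crossParcellationAgreement(ms, msAlt, scfg, seed = config$seed)
    report$cross_parcellation <- agreementAsList(cp$report)
  }

  contrasts <- c("subtype1", "subtype2", "patients")
  report$roi_tests <- list()
  for (ctr in contrasts) {
    res <- roiGroupTest(run$features, labels, ctr, alpha = config$alpha)
    data.table::fwrite(as.data.frame(res),
                       file.path(config$outDir, sprintf("roi_%s.tsv", ctr)),
                       sep = "\t", quote = FALSE)
    report$roi_tests[[ctr]] <- list(n_significant = sum(res$significant))
  }

  if (!is.null(config$phantomPath)) {
    arr <- RNifti::readNifti(config$phantomPath)
    labmap <- readLabelVolume(config$labelsPath)
    stopIf(!all(dim(arr)[1:3] == dim(labmap)),
           "geometry mismatch: subjects %s vs labels %s",
           paste(dim(arr)[1:3], collapse = "x"), paste(dim(labmap), collapse = "x"))
    grp <- subjectGroups(ms)
    isS1 <- grp == "patient" & subjectIds(ms) %in% names(labels)[labels == 1L]
    sel <- grp == "control" | isS1
    vx <- voxelwiseGroupTest(array(arr[, , , sel], c(dim(labmap), sum(sel))),
                             ifelse(isS1[sel], "patient", "control"),
                             alpha = config$alpha,
                             minCluster = config$minCluster,
                             connectivity = config$connectivity,
                             outDir = file.path(config$outDir, "voxelwise"),
                             template = labmap)
    report$voxelwise <- list(contrast = "subtype1_vs_controls",
                             n_sig_voxels = vx$nSigVoxels,
                             clusters = vx$clusters)
  }

  if (!is.null(config$clinicalPath)) {
    clin <- data.table::fread(config$clinicalPath, data.table = FALSE)
    cmp <- compareSubtypes(clin, labels)
    data.table::fwrite(cmp, file.path(config$outDir, "clinical_comparison.tsv"),
                       sep = "\t", quote = FALSE)
    report$clinical <- cmp
  }

  jsonlite::write_json(report, file.path(config$outDir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", null = "null")
  invisible(report)
}

#' Create a demonstration workspace
#'
#' Generates the default synthetic cohort, an alternate-parcellation
#' re-measurement, hidden truth labels, clinical scores, a small voxel
#' phantom, a run configuration, and a one-command reproduction script.
#' Byte-identical for identical seeds.
#'
#' @param dir target directory (created if needed).
#' @param seed master seed.
#' @param effectSize planted shift for subtype 1 (default 1.0 for a clearly
#'   separated demonstration cohort).
#' @param kRange stability-scan range used by the demo config (default 2:5
#'   to keep the demo quick; the full analysis default is 2:10).
#' @return path to the written config JSON, invisibly.
#' @export
makeDemo <- function(dir, seed = 7L, effectSize = 1.0, kRange = 2:5) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stopIf(file.access(dir, 2) != 0, "target directory not writable: %s", dir)
  design <- cohortDesign(effectSize = effectSize, seed = seed)
  sim <- simulateCohort(design)
  writeMorphometryTable(sim$cohort, file.path(dir, "cohort.tsv"))
  alt <- alternateParcellation(sim$cohort,
                               mergedParcellationGrouping(design$nRegions, 166L),
                               noiseSd = 0.05, seed = childSeed(seed, 2L))
  writeMorphometryTable(alt, file.path(dir, "cohort_alt.tsv"))
  writeSubtypeTable(sim$truth, file.path(dir, "truth.tsv"))

  truthLab <- stats::setNames(sim$truth$subtype, sim$truth$subject_id)
  clin <- simulateClinicalScores(truthLab, seed = childSeed(seed, 3L))
  data.table::fwrite(clin, file.path(dir, "clinical.tsv"), sep = "\t",
                     quote = FALSE)

  labmap <- makeBlockLabelMap(c(16L, 16L, 16L), list(
    list(label = 1L, from = c(3, 3, 3), to = c(6, 6, 6)),       # 64 voxels
    list(label = 2L, from = c(10, 10, 10), to = c(13, 13, 12))  # 48 voxels
  ))
  grpVox <- ifelse(subjectIds(sim$cohort) %in%
                     sim$truth$subject_id[sim$truth$subtype == 1L],
                   "patient", "control")
  ph <- simulateVoxelPhantom(labmap, grpVox,
                             baseOffsets = c("1" = 1, "2" = 1),
                             groupOffsets = c("1" = 0.5),
                             noiseSd = 0.2, seed = childSeed(seed, 4L))
  RNifti::writeNifti(RNifti::asNifti(ph), file.path(dir, "phantom.nii.gz"))
  writeStatMap(labmap + 0, file.path(dir, "phantom_labels.nii.gz"))

  cfg <- runConfig(tablePath = file.path(dir, "cohort.tsv"),
                   outDir = file.path(dir, "results"),
                   altTablePath = file.path(dir, "cohort_alt.tsv"),
                   clinicalPath = file.path(dir, "clinical.tsv"),
                   phantomPath = file.path(dir, "phantom.nii.gz"),
                   labelsPath = file.path(dir, "phantom_labels.nii.gz"),
                   kRange = kRange, seed = seed)
  cfgPath <- file.path(dir, "config.json")
  saveRunConfig(cfg, cfgPath)
  writeLines(c("#!/usr/bin/env Rscript",
               "# Reproduce the demo analysis end to end:",
               sprintf("MorphoSubtype::runPipeline(\"%s\")", cfgPath)),
             file.path(dir, "run_demo.R"))
  invisible(cfgPath)
}
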