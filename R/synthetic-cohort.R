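#' Default pain-related region set
#'
#' Indices of the 30 regions designated "pain-related" in the default
#' 246-region annotation: bilateral subdivisions of the caudate, putamen,
#' thalamus, hippocampus, amygdala, precuneus and parahippocampal gyrus.
#' These are the regions the generator shifts in the morphologically
#' altered subtype.
#'
#' @param nRegions parcellation size; the default annotation assumes 246.
#' @return integer vector of 30 region indices.
#' @export
defaultPainRegions <- function(nRegions = 246L) {
  ann <- brainRegionAnnotation(nRegions)
  which(ann$pain_related)
}

#' Per-region annotation for the default 246-region parcellation
#'
#' Builds a region table in the style of a whole-brain structural atlas:
#' generic cortical area labels plus named subcortical/limbic subdivisions,
#' with a logical \code{pain_related} flag marking 30 regions (bilateral
#' caudate, putamen, thalamus, hippocampus, amygdala, precuneus,
#' parahippocampus subdivisions).
#'
#' @param nRegions parcellation size (>= 60 for the named block to fit).
#' @return \code{DataFrame} with \code{region_id}, \code{name},
#'   \code{pain_related}.
#' @export
brainRegionAnnotation <- function(nRegions = 246L) {
  nRegions <- as.integer(nRegions)
  stopIf(nRegions < 60L, "annotation requires at least 60 regions, got %d", nRegions)
  id <- sprintf("region_%04d", seq_len(nRegions))
  name <- sprintf("cortical_area_%03d", seq_len(nRegions))
  structures <- c(caudate = 3L, putamen = 2L, thalamus = 4L,
                  hippocampus = 2L, amygdala = 2L,
                  precuneus = 1L, parahippocampus = 1L)
  pain <- logical(nRegions)
  # Place the named block in the upper range, as subcortical labels sit at the
  # end of typical whole-brain parcellations.
  pos <- nRegions - 36L
  for (s in names(structures)) {
    for (k in seq_len(structures[[s]])) {
      for (side in c("L", "R")) {
        pos <- pos + 1L
        name[pos] <- sprintf("%s_%s_%d", side, s, k)
        pain[pos] <- TRUE
      }
    }
  }
  DataFrame(region_id = id, name = name, pain_related = pain, row.names = id)
}

#' Cohort design for the synthetic morphometry generator
#'
#' Encodes the generating model for a two-subtype patient cohort against
#' healthy controls: per-region volume = baseline + betaAge*age + betaTiv*tiv
#' (+ effectSize*noiseSd in affected regions, subtype 1 only) + Gaussian noise.
#' Subtype 2 is drawn from the control model, so it differs from controls in
#' group label only. Defaults emulate a female chronic-pain cohort: 93
#' controls, 38 + 37 patients, 246 regions, 30 pain-related affected regions,
#' age ~ N(46, 10) years, TIV ~ N(1400, 120) mL.
#'
#' @param nControls,nSubtype1,nSubtype2 subject counts (>= 0).
#' @param nRegions parcellation size.
#' @param affectedRegions indices (within 1..nRegions) shifted in subtype 1.
#' @param effectSize standardized mean shift, in residual-noise SD units.
#' @param ageMean,ageSd,tivMean,tivSd covariate distributions.
#' @param betaAge,betaTiv per-region covariate slopes (scalar or length
#'   nRegions); defaults give age-related decline and head-size scaling.
#' @param noiseSd residual SD of regional volume (> 0).
#' @param baseline intercept volume per region.
#' @param seed integer RNG seed.
#' @return a named list of class \code{"CohortDesign"}.
#' @export
cohortDesign <- function(nControls = 93L, nSubtype1 = 38L, nSubtype2 = 37L,
                         nRegions = 246L,
                         affectedRegions = defaultPainRegions(nRegions),
                         effectSize = 0.8,
                         ageMean = 46, ageSd = 10,
                         tivMean = 1400, tivSd = 120,
                         betaAge = -0.01, betaTiv = 0.002,
                         noiseSd = 0.5, baseline = 5,
                         seed = 1L) {
  d <- list(nControls = as.integer(nControls), nSubtype1 = as.integer(nSubtype1),
            nSubtype2 = as.integer(nSubtype2), nRegions = as.integer(nRegions),
            affectedRegions = as.integer(affectedRegions),
            effectSize = effectSize, ageMean = ageMean, ageSd = ageSd,
            tivMean = tivMean, tivSd = tivSd, betaAge = betaAge,
            betaTiv = betaTiv, noiseSd = noiseSd, baseline = baseline,
            seed = as.integer(seed))
  stopIf(any(c(d$nControls, d$nSubtype1, d$nSubtype2) < 0L),
         "subject counts must be >= 0")
  stopIf(d$nControls + d$nSubtype1 + d$nSubtype2 == 0L,
         "cohort must contain at least one subject")
  stopIf(length(d$affectedRegions) > 0 &&
           (min(d$affectedRegions) < 1L || max(d$affectedRegions) > d$nRegions),
         "affectedRegions must lie within 1..%d", d$nRegions)
  stopIf(d$effectSize < 0, "effectSize must be >= 0")
  stopIf(d$noiseSd <= 0, "noiseSd must be > 0")
  class(d) <- "CohortDesign"
  d
}

#' Simulate a two-subtype morphometry cohort
#'
#' Draws ages and TIVs from the design's covariate model for every subject,
#' then regional volumes from the linear generating model. Subtype 1 patients
#' receive an additive shift of \code{effectSize * noiseSd} in the affected
#' regions; subtype 2 patients are distributionally identical to controls.
#' Hidden truth labels are returned as a sidecar, never inside the table.
#'
#' @param design a \code{\link{cohortDesign}}.
#' @return list with \code{cohort} (a \linkS4class{MorphometrySet} with
#'   parcellation \code{"BN246-like"}) and \code{truth} (data.frame
#'   \code{subject_id}, \code{subtype} for patients only).
#' @export
simulateCohort <- function(design) {
  stopifnot(inherits(design, "CohortDesign"))
  n <- design$nControls + design$nSubtype1 + design$nSubtype2
  p <- design$nRegions
  betaAge <- rep_len(design$betaAge, p)
  betaTiv <- rep_len(design$betaTiv, p)
  baseline <- rep_len(design$baseline, p)
  withSeed(design$seed, {
    age <- stats::rnorm(n, design$ageMean, design$ageSd)
    tiv <- stats::rnorm(n, design$tivMean, design$tivSd)
    noise <- matrix(stats::rnorm(n * p, 0, design$noiseSd), nrow = p)
  })
  group <- c(rep("control", design$nControls),
             rep("patient", design$nSubtype1 + design$nSubtype2))
  subtype <- c(rep(NA_integer_, design$nControls),
               rep(1L, design$nSubtype1), rep(2L, design$nSubtype2))
  vol <- baseline + outer(betaAge, age) + outer(betaTiv, tiv) + noise
  shift <- design$effectSize * design$noiseSd
  if (length(design$affectedRegions) && design$nSubtype1 > 0)
    vol[design$affectedRegions, which(subtype == 1L)] <-
      vol[design$affectedRegions, which(subtype == 1L)] + shift
  ids <- c(sprintf("CTRL%04d", seq_len(design$nControls)),
           sprintf("PAT%04d", seq_len(design$nSubtype1 + design$nSubtype2)))
  ann <- if (p >= 60L) brainRegionAnnotation(p) else
    DataFrame(region_id = sprintf("region_%04d", seq_len(p)),
              row.names = sprintf("region_%04d", seq_len(p)))
  rownames(vol) <- rownames(ann)
  ms <- MorphometrySet(vol, group, age, tiv, subjectId = ids,
                       parcellation = "BN246-like", regionData = ann)
  truth <- data.frame(subject_id = ids[group == "patient"],
                      subtype = subtype[group == "patient"],
                      stringsAsFactors = FALSE)
  list(cohort = ms, truth = truth)
}

#' Build a merged parcellation grouping
#'
#' Maps an original parcellation onto a coarser one by near-even contiguous
#' blocks, emulating re-measurement under a different atlas (e.g. 246 to 166
#' regions).
#'
#' @param nOld original region count.
#' @param nNew new region count (\code{<= nOld}).
#' @return named list: new region id -> integer indices of merged originals.
#' @export
mergedParcellationGrouping <- function(nOld, nNew) {
  stopIf(nNew > nOld || nNew < 1, "need 1 <= nNew <= nOld")
  cut <- round(seq(0, nOld, length.out = nNew + 1))
  grouping <- lapply(seq_len(nNew), function(i) seq(cut[i] + 1L, cut[i + 1L]))
  names(grouping) <- sprintf("merged_%04d", seq_len(nNew))
  grouping
}

#' Re-measure a cohort under an alternate parcellation
#'
#' Produces a new morphometry table whose region volumes are sums of grouped
#' original-region volumes plus small re-measurement noise; subjects, groups
#' and covariates are unchanged. Used for cross-atlas validation.
#'
#' @param ms a \linkS4class{MorphometrySet}.
#' @param grouping named list mapping each new region to the integer indices
#'   of the original regions it merges; must cover regions within range.
#' @param noiseSd SD of additive re-measurement noise (0 for exact sums).
#' @param seed RNG seed.
#' @param parcellation name recorded for the new table.
#' @return a \linkS4class{MorphometrySet} with \code{length(grouping)} regions.
#' @export
alternateParcellation <- function(ms, grouping, noiseSd = 0.05, seed = 1L,
                                  parcellation = "AAL3-like") {
  stopIf(length(grouping) == 0, "grouping is empty")
  idx <- unlist(grouping, use.names = FALSE)
  stopIf(min(idx) < 1L || max(idx) > nrow(ms),
         "grouping refers to region index outside 1..%d", nrow(ms))
  v <- volumes(ms)
  newv <- t(vapply(grouping, function(g) colSums(v[g, , drop = FALSE]),
                   numeric(ncol(ms))))
  if (is.null(names(grouping)))
    rownames(newv) <- sprintf("merged_%04d", seq_along(grouping))
  if (noiseSd > 0)
    newv <- newv + withSeed(seed, matrix(stats::rnorm(length(newv), 0, noiseSd),
                                         nrow = nrow(newv)))
  MorphometrySet(newv, subjectGroups(ms), colData(ms)$age, colData(ms)$tiv,
                 subjectId = subjectIds(ms), parcellation = parcellation)
}

#' Block label map for voxel phantoms
#'
#' @param dim integer length-3 grid shape.
#' @param blocks list of \code{list(label, from, to)} with \code{from}/\code{to}
#'   length-3 voxel index ranges (1-based, inclusive).
#' @return 3D integer array of region labels (0 = background).
#' @export
makeBlockLabelMap <- function(dim, blocks) {
  stopIf(length(dim) != 3, "dim must have length 3")
  lab <- array(0L, dim = dim)
  for (b in blocks) {
    stopIf(any(b$from < 1) || any(b$to > dim),
           "block exceeds grid bounds")
    lab[b$from[1]:b$to[1], b$from[2]:b$to[2], b$from[3]:b$to[3]] <- as.integer(b$label)
  }
  lab
}

#' Simulate per-subject voxel phantoms
#'
#' Each subject's 3D intensity grid is the per-region base offset, plus a
#' group-dependent offset in affected regions for subjects in the second
#' (patient) group, plus i.i.d. Gaussian voxel noise. A test bed for the
#' voxel-wise comparison stage, not an image simulator.
#'
#' @param labels 3D integer label array (0 = background); at least one
#'   labeled voxel is required.
#' @param groups character/factor per subject with exactly two levels; the
#'   second level (or \code{"patient"} if present) receives the group offsets.
#' @param baseOffsets named numeric: base intensity per region label.
#' @param groupOffsets named numeric: additional intensity per region label
#'   for the offset group (may be empty).
#' @param noiseSd voxel noise SD (>= 0).
#' @param seed RNG seed.
#' @return 4D numeric array, \code{c(dim(labels), length(groups))}.
#' @export
simulateVoxelPhantom <- function(labels, groups, baseOffsets = numeric(),
                                 groupOffsets = numeric(), noiseSd = 0.2,
                                 seed = 1L) {
  stopIf(length(dim(labels)) != 3, "labels must be a 3D array")
  stopIf(any(labels < 0), "labels must be nonnegative")
  stopIf(!any(labels > 0), "no labeled regions")
  known <- as.character(sort(unique(labels[labels > 0])))
  badB <- setdiff(names(baseOffsets), known)
  badG <- setdiff(names(groupOffsets), known)
  stopIf(length(badB) || length(badG),
         "offsets name unknown region label(s): %s",
         paste(c(badB, badG), collapse = ", "))
  groups <- as.character(groups)
  lv <- unique(groups)
  stopIf(length(lv) != 2, "groups must have exactly two levels")
  offsetGroup <- if ("patient" %in% lv) "patient" else lv[2]
  base <- array(0, dim = dim(labels))
  for (r in names(baseOffsets)) base[labels == as.integer(r)] <- baseOffsets[[r]]
  extra <- array(0, dim = dim(labels))
  for (r in names(groupOffsets)) extra[labels == as.integer(r)] <- groupOffsets[[r]]
  n <- length(groups)
  out <- array(0, dim = c(dim(labels), n))
  withSeed(seed, {
    for (i in seq_len(n)) {
      img <- base + if (groups[i] == offsetGroup) extra else 0
      if (noiseSd > 0)
        img <- img + array(stats::rnorm(length(img), 0, noiseSd), dim = dim(labels))
      out[, , , i] <- img
    }
  })
  out
}
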