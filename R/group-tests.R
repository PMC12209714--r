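# Vectorized two-sample t over matrix rows (units x subjects per group).
rowTwoSampleT <- function(A, B, variant = "pooled") {
  nA <- ncol(A)
  nB <- ncol(B)
  mA <- rowMeans(A)
  mB <- rowMeans(B)
  vA <- rowSums((A - mA)^2) / (nA - 1)
  vB <- rowSums((B - mB)^2) / (nB - 1)
  if (variant == "pooled") {
    df <- rep(nA + nB - 2, nrow(A))
    se <- sqrt((((nA - 1) * vA + (nB - 1) * vB) / df) * (1 / nA + 1 / nB))
  } else {
    se <- sqrt(vA / nA + vB / nB)
    df <- (vA / nA + vB / nB)^2 /
      ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  }
  diff <- mA - mB
  t <- ifelse(se == 0, ifelse(diff == 0, 0, sign(diff) * Inf), diff / se)
  p <- ifelse(is.infinite(t), 0, 2 * stats::pt(-abs(t), df))
  p[se == 0 & diff == 0] <- 1
  d <- (mA - mB) / sqrt(((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2))
  list(t = t, df = df, p = p, d = d)
}

#' Region-wise group difference testing
#'
#' Per-region two-sample t tests of one patient contrast against controls,
#' with Benjamini-Hochberg FDR across regions and Cohen's d effect sizes.
#' Supported contrasts: one subtype vs controls, or all patients vs
#' controls. Running on covariate-adjusted features (the default input in
#' the pipeline) removes age/TIV nuisance variance first.
#'
#' @param x a \linkS4class{MorphometrySet} (raw volumes) or
#'   \linkS4class{AdjustedFeatures} (adjusted features).
#' @param subtypes named integer vector of subtype labels over patients;
#'   required for subtype contrasts.
#' @param contrast \code{"subtype1"}, \code{"subtype2"} or \code{"patients"}.
#' @param alpha FDR level (default 0.05).
#' @param variant t-test variant.
#' @return \code{DataFrame}: region, t, df, p, q, d, significant.
#' @export
roiGroupTest <- function(x, subtypes = NULL,
                         contrast = c("subtype1", "subtype2", "patients"),
                         alpha = 0.05, variant = c("pooled", "welch")) {
  contrast <- match.arg(contrast)
  variant <- match.arg(variant)
  if (is(x, "MorphometrySet")) {
    dat <- volumes(x)                       # regions x subjects
    grp <- ifelse(subjectGroups(x) == "patient", 1L, -1L)
    ids <- subjectIds(x)
  } else if (is(x, "AdjustedFeatures")) {
    dat <- t(x@features)
    grp <- unname(x@group)
    ids <- rownames(x@features)
  } else stop("x must be a MorphometrySet or AdjustedFeatures", call. = FALSE)
  ctrl <- which(grp == -1L)
  pat <- which(grp == 1L)
  stopIf(length(ctrl) < 2, "need >= 2 controls")
  selA <- if (contrast == "patients") pat else {
    stopIf(is.null(subtypes), "subtypes are required for contrast '%s'", contrast)
    want <- if (contrast == "subtype1") 1L else 2L
    lab <- subtypes[ids[pat]]
    stopIf(all(is.na(lab)), "subtype labels do not match patient ids")
    stopIf(!any(lab == want, na.rm = TRUE), "no patients with subtype label %d", want)
    pat[which(lab == want)]
  }
  stopIf(length(selA) < 2, "contrast group needs n >= 2")
  res <- rowTwoSampleT(dat[, selA, drop = FALSE], dat[, ctrl, drop = FALSE],
                       variant = variant)
  fdr <- bhFdr(res$p, alpha)
  DataFrame(region = rownames(dat), t = res$t, df = res$df, p = res$p,
            q = fdr$q, d = res$d, significant = fdr$reject,
            row.names = rownames(dat))
}

#' Voxel-wise group difference testing with FDR and extent thresholding
#'
#' Per-voxel two-sample t tests between two subject groups, BH-FDR over
#' in-mask voxels, then cluster-extent filtering of the significant mask
#' (threshold-then-cluster). Optionally writes t, d and q maps as NIfTI.
#'
#' @param vols 4D array (x, y, z, subject) or list of 3D arrays sharing one
#'   geometry.
#' @param groups two-level vector per subject; the \code{"patient"} level
#'   (or the second level) is contrasted against the other.
#' @param alpha FDR level (default 0.05).
#' @param minCluster extent threshold; clusters survive if size
#'   \code{> minCluster} (default 40).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param mask optional 3D logical analysis mask; default: voxels with
#'   nonzero variance.
#' @param variant t-test variant.
#' @param outDir optional directory for NIfTI outputs.
#' @param template optional NIfTI image supplying output geometry.
#' @return list: \code{t}, \code{d}, \code{q} (3D arrays; q = 1 outside the
#'   mask), \code{mask} (significant voxels after extent filtering),
#'   \code{clusters} (cluster table), \code{nSigVoxels}.
#' @export
voxelwiseGroupTest <- function(vols, groups, alpha = 0.05, minCluster = 40,
                               connectivity = 26, mask = NULL,
                               variant = c("pooled", "welch"),
                               outDir = NULL, template = NULL) {
  variant <- match.arg(variant)
  arr <- asVolumeStack(vols)
  dims <- dim(arr)[1:3]
  n <- dim(arr)[4]
  groups <- as.character(groups)
  stopIf(length(groups) != n, "one group label per subject required")
  lv <- unique(groups)
  stopIf(length(lv) != 2, "groups must have exactly two levels")
  posLevel <- if ("patient" %in% lv) "patient" else lv[2]
  flat <- matrix(arr, prod(dims), n)
  A <- flat[, groups == posLevel, drop = FALSE]
  B <- flat[, groups != posLevel, drop = FALSE]
  res <- rowTwoSampleT(A, B, variant = variant)
  if (is.null(mask)) {
    v <- apply(flat, 1, stats::var)
    mask <- array(v > 0, dims)
  } else {
    stopIf(!all(dim(mask) == dims), "mask geometry mismatch: %s vs %s",
           paste(dim(mask), collapse = "x"), paste(dims, collapse = "x"))
  }
  inMask <- which(as.vector(mask))
  qv <- rep(1, prod(dims))
  sig <- rep(FALSE, prod(dims))
  if (length(inMask)) {
    fdr <- bhFdr(res$p[inMask], alpha)
    qv[inMask] <- fdr$q
    sig[inMask] <- fdr$reject
  }
  tMap <- array(res$t, dims)
  dMap <- array(res$d, dims)
  qMap <- array(qv, dims)
  filt <- clusterExtentFilter(array(sig, dims), minSize = minCluster,
                              connectivity = connectivity, stat = tMap)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeStatMap(tMap, file.path(outDir, "tmap.nii.gz"), template)
    writeStatMap(dMap, file.path(outDir, "dmap.nii.gz"), template)
    writeStatMap(qMap, file.path(outDir, "qmap.nii.gz"), template)
    writeStatMap(filt$mask + 0, file.path(outDir, "sigmask.nii.gz"), template)
  }
  list(t = tMap, d = dMap, q = qMap, mask = filt$mask,
       clusters = filt$clusters, nSigVoxels = sum(filt$mask))
}
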