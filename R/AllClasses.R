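#' @import methods
#' @importFrom S4Vectors DataFrame metadata SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' MorphometrySet: regional gray-matter volumes with subject metadata
#'
#' A \linkS4class{SummarizedExperiment} holding one assay, \code{"volumes"}
#' (regions x subjects), with subject group (\code{"patient"}/\code{"control"}),
#' age in years and total intracranial volume (TIV) in \code{colData}, and
#' region identifiers in \code{rowData}. The parcellation name is kept in
#' \code{metadata(x)$parcellation}.
#'
#' @slot .Data inherited SummarizedExperiment structure.
#' @export
setClass("MorphometrySet", contains = "SummarizedExperiment")

setValidity("MorphometrySet", function(object) {
  msg <- NULL
  if (!"volumes" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'volumes' is required")
  cd <- colData(object)
  for (f in c("subject_id", "group", "age", "tiv"))
    if (!f %in% colnames(cd)) msg <- c(msg, sprintf("colData field '%s' is required", f))
  if ("subject_id" %in% colnames(cd)) {
    dup <- unique(cd$subject_id[duplicated(cd$subject_id)])
    if (length(dup))
      msg <- c(msg, sprintf("duplicate subject_id: %s", paste(dup, collapse = ", ")))
  }
  if ("group" %in% colnames(cd) && !all(cd$group %in% c("patient", "control")))
    msg <- c(msg, "group must be 'patient' or 'control'")
  if ("volumes" %in% SummarizedExperiment::assayNames(object)) {
    v <- assay(object, "volumes")
    if (anyNA(v) || any(!is.finite(v)))
      msg <- c(msg, "volumes must be finite and non-missing")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a MorphometrySet
#'
#' @param volumes numeric matrix, regions x subjects; rownames are region ids,
#'   colnames are subject ids (taken from \code{subjectId} if unset).
#' @param group character vector, \code{"patient"} or \code{"control"} per subject.
#' @param age numeric vector, years.
#' @param tiv numeric vector, total intracranial volume (mL).
#' @param subjectId character vector of unique subject identifiers.
#' @param parcellation single string naming the parcellation scheme.
#' @param regionData optional \code{DataFrame} of per-region annotation.
#' @return A \linkS4class{MorphometrySet}.
#' @export
MorphometrySet <- function(volumes, group, age, tiv,
                           subjectId = colnames(volumes),
                           parcellation = "unnamed",
                           regionData = NULL) {
  volumes <- as.matrix(volumes)
  if (is.null(subjectId))
    subjectId <- sprintf("S%04d", seq_len(ncol(volumes)))
  colnames(volumes) <- subjectId
  if (is.null(rownames(volumes)))
    rownames(volumes) <- sprintf("region_%04d", seq_len(nrow(volumes)))
  group <- tolower(as.character(group))
  cd <- DataFrame(subject_id = as.character(subjectId), group = group,
                  age = as.numeric(age), tiv = as.numeric(tiv),
                  row.names = subjectId)
  rd <- if (is.null(regionData)) DataFrame(region_id = rownames(volumes),
                                           row.names = rownames(volumes)) else regionData
  se <- SummarizedExperiment(assays = list(volumes = volumes),
                             colData = cd, rowData = rd)
  S4Vectors::metadata(se)$parcellation <- parcellation
  new("MorphometrySet", se)
}

#' AdjustedFeatures: covariate-adjusted, control-standardized features
#'
#' Subjects x regions matrix of volumes with covariate effects (estimated on
#' controls only) removed, then standardized by control mean/SD per region.
#'
#' @slot features numeric matrix, subjects x regions.
#' @slot group named integer vector, +1 patient / -1 control.
#' @slot betas numeric matrix of regression coefficients
#'   ((intercept + covariates) x regions) fitted on controls.
#' @slot center,scale numeric vectors used for control standardization.
#' @slot covariates character vector of covariate names used.
#' @slot parcellation parcellation name carried through.
#' @export
setClass("AdjustedFeatures",
         representation(features = "matrix", group = "integer",
                        betas = "matrix", center = "numeric", scale = "numeric",
                        covariates = "character", parcellation = "character"))

setValidity("AdjustedFeatures", function(object) {
  msg <- NULL
  if (any(!is.finite(object@features))) msg <- c(msg, "features must be finite")
  if (nrow(object@features) != length(object@group))
    msg <- c(msg, "group length must match feature rows")
  if (!all(object@group %in% c(-1L, 1L)))
    msg <- c(msg, "group must be +1 (patient) or -1 (control)")
  if (is.null(msg)) TRUE else msg
})

#' PolytopeModel: K max-margin faces separating patients from controls
#'
#' @slot K number of faces (subtypes).
#' @slot W numeric matrix, features x K, hyperplane normals.
#' @slot b numeric length-K intercepts.
#' @slot cost margin-violation penalty used in fitting.
#' @slot seed,nRestarts fitting reproducibility parameters.
#' @slot objective final value of the regularized hinge objective (minimized).
#' @slot objectiveTrace objective after each alternating iteration (best restart).
#' @slot converged logical, assignments stabilized before \code{maxIter}.
#' @slot iterations alternating iterations used by the best restart.
#' @export
setClass("PolytopeModel",
         representation(K = "integer", W = "matrix", b = "numeric",
                        cost = "numeric", seed = "integer", nRestarts = "integer",
                        objective = "numeric", objectiveTrace = "numeric",
                        converged = "logical", iterations = "integer"))

setValidity("PolytopeModel", function(object) {
  msg <- NULL
  if (object@K < 1L) msg <- c(msg, "K must be >= 1")
  if (ncol(object@W) != object@K) msg <- c(msg, "W must have K columns")
  if (length(object@b) != object@K) msg <- c(msg, "b must have length K")
  if (any(!is.finite(object@W)) || any(!is.finite(object@b)))
    msg <- c(msg, "model parameters must be finite")
  if (all(object@W == 0)) msg <- c(msg, "weight vectors are all zero")
  if (is.null(msg)) TRUE else msg
})

#' FaceAssignment: per-patient face (subtype) labels and signed scores
#'
#' @slot face named integer vector, face index in 1..K per patient.
#' @slot scores numeric matrix, patients x K, signed scores per face.
#' @export
setClass("FaceAssignment",
         representation(face = "integer", scores = "matrix"))

setValidity("FaceAssignment", function(object) {
  msg <- NULL
  if (length(object@face) != nrow(object@scores))
    msg <- c(msg, "face length must match score rows")
  K <- ncol(object@scores)
  if (length(object@face) && (any(object@face < 1L) || any(object@face > K)))
    msg <- c(msg, "face indices must lie in 1..K")
  ok <- vapply(seq_along(object@face), function(i) {
    abs(object@scores[i, object@face[i]] - max(object@scores[i, ])) < 1e-8
  }, logical(1))
  if (length(ok) && !all(ok))
    msg <- c(msg, "each assigned face must attain the maximal score")
  if (is.null(msg)) TRUE else msg
})

#' StabilityProfile: cross-validated ARI per candidate K
#'
#' @slot K integer vector of scanned cluster numbers.
#' @slot meanARI mean pairwise adjusted Rand index across CV folds, per K.
#' @slot nFolds folds used.
#' @slot selectedK K attaining the highest mean ARI (ties: smallest K).
#' @slot foldLabels list (one per K) of patients x folds label matrices.
#' @export
setClass("StabilityProfile",
         representation(K = "integer", meanARI = "numeric", nFolds = "integer",
                        selectedK = "integer", foldLabels = "list"))

setValidity("StabilityProfile", function(object) {
  msg <- NULL
  if (length(object@K) != length(object@meanARI))
    msg <- c(msg, "K and meanARI must have equal length")
  if (any(object@meanARI < -1 - 1e-9 | object@meanARI > 1 + 1e-9))
    msg <- c(msg, "ARI values must lie in [-1, 1]")
  if (length(object@K)) {
    best <- max(object@meanARI)
    if (abs(object@meanARI[match(object@selectedK, object@K)] - best) > 1e-12)
      msg <- c(msg, "selectedK must attain the maximum mean ARI")
  }
  if (is.null(msg)) TRUE else msg
})

#' AgreementReport: label agreement between two subtyping runs
#'
#' @slot nCompared,nConsistent subject counts.
#' @slot fractionConsistent nConsistent / nCompared.
#' @slot permutation integer vector mapping second-run labels onto first-run labels.
#' @slot concordant named logical vector per compared subject.
#' @export
setClass("AgreementReport",
         representation(nCompared = "integer", nConsistent = "integer",
                        fractionConsistent = "numeric", permutation = "integer",
                        concordant = "logical"))

setValidity("AgreementReport", function(object) {
  msg <- NULL
  if (object@nConsistent > object@nCompared)
    msg <- c(msg, "nConsistent cannot exceed nCompared")
  if (object@nCompared > 0 &&
      abs(object@fractionConsistent - object@nConsistent / object@nCompared) > 1e-12)
    msg <- c(msg, "fractionConsistent must equal nConsistent/nCompared")
  if (is.null(msg)) TRUE else msg
})
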