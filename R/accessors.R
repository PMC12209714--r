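#' Accessors for MorphometrySet
#'
#' \code{volumes} returns the regions x subjects volume matrix;
#' \code{subjectGroups} the patient/control labels; \code{subjectIds} the
#' subject identifiers; \code{parcellationName} the parcellation scheme name;
#' \code{regionIds} the ordered region labels.
#'
#' @param x a \linkS4class{MorphometrySet}.
#' @return See the individual descriptions.
#' @name MorphometrySet-accessors
NULL

#' @rdname MorphometrySet-accessors
#' @export
setMethod("volumes", "MorphometrySet", function(x) assay(x, "volumes"))

#' @rdname MorphometrySet-accessors
#' @export
setMethod("subjectGroups", "MorphometrySet", function(x) colData(x)$group)

#' @rdname MorphometrySet-accessors
#' @export
setMethod("subjectIds", "MorphometrySet", function(x) colData(x)$subject_id)

#' @rdname MorphometrySet-accessors
#' @export
setMethod("parcellationName", "MorphometrySet",
          function(x) S4Vectors::metadata(x)$parcellation)

#' @rdname MorphometrySet-accessors
#' @export
setMethod("regionIds", "MorphometrySet", function(x) rownames(x))

#' Patient indicator
#'
#' @param x a MorphometrySet.
#' @return logical vector, TRUE for patients.
#' @export
isPatient <- function(x) subjectGroups(x) == "patient"

#' Accessors for FaceAssignment
#'
#' \code{faceLabels} returns the per-patient face (subtype) index;
#' \code{faceScores} the patients x K signed score matrix.
#'
#' @param x a \linkS4class{FaceAssignment}.
#' @name FaceAssignment-accessors
NULL

#' @rdname FaceAssignment-accessors
#' @export
setMethod("faceLabels", "FaceAssignment", function(x) x@face)

#' @rdname FaceAssignment-accessors
#' @export
setMethod("faceScores", "FaceAssignment", function(x) x@scores)

#' Accessors for StabilityProfile
#'
#' \code{selectedK} returns the cluster number attaining the highest mean
#' cross-validated ARI; \code{meanARI} the named vector of mean ARI per K.
#'
#' @param x a \linkS4class{StabilityProfile}.
#' @name StabilityProfile-accessors
NULL

#' @rdname StabilityProfile-accessors
#' @export
setMethod("selectedK", "StabilityProfile", function(x) x@selectedK)

#' @rdname StabilityProfile-accessors
#' @export
setMethod("meanARI", "StabilityProfile",
          function(x) stats::setNames(x@meanARI, x@K))

setMethod("show", "MorphometrySet", function(object) {
  cat("MorphometrySet:", nrow(object), "regions x", ncol(object), "subjects\n")
  cat("  parcellation:", parcellationName(object), "\n")
  tb <- table(subjectGroups(object))
  cat("  groups:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
})

setMethod("show", "PolytopeModel", function(object) {
  cat("PolytopeModel: K =", object@K, "faces,", nrow(object@W), "features\n")
  cat(sprintf("  C = %g, restarts = %d, objective = %.4f, converged = %s (%d iter)\n",
              object@cost, object@nRestarts, object@objective,
              object@converged, object@iterations))
})

setMethod("show", "StabilityProfile", function(object) {
  cat("StabilityProfile over K = {", paste(object@K, collapse = ", "), "}\n")
  cat("  mean ARI:", paste(sprintf("%d:%.3f", object@K, object@meanARI),
                           collapse = "  "), "\n")
  cat("  selected K =", object@selectedK, "(", object@nFolds, "folds )\n")
})

setMethod("show", "AgreementReport", function(object) {
  cat(sprintf("AgreementReport: %d/%d consistent (%.1f%%)\n",
              object@nConsistent, object@nCompared,
              100 * object@fractionConsistent))
})
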