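#' @rdname MorphometrySet-accessors
#' @export
setGeneric("volumes", function(x) standardGeneric("volumes"))

#' @rdname MorphometrySet-accessors
#' @export
setGeneric("subjectGroups", function(x) standardGeneric("subjectGroups"))

#' @rdname MorphometrySet-accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname MorphometrySet-accessors
#' @export
setGeneric("parcellationName", function(x) standardGeneric("parcellationName"))

#' @rdname MorphometrySet-accessors
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))

#' @rdname FaceAssignment-accessors
#' @export
setGeneric("faceLabels", function(x) standardGeneric("faceLabels"))

#' @rdname FaceAssignment-accessors
#' @export
setGeneric("faceScores", function(x) standardGeneric("faceScores"))

#' @rdname StabilityProfile-accessors
#' @export
setGeneric("selectedK", function(x) standardGeneric("selectedK"))

#' @rdname StabilityProfile-accessors
#' @export
setGeneric("meanARI", function(x) standardGeneric("meanARI"))
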