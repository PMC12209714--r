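#' Write a morphometry table to delimited text
#'
#' Columns: \code{subject_id}, \code{group}, \code{age}, \code{tiv}, then one
#' column per region (named by region id, in table order). Values are written
#' at full precision so that write-then-read round-trips exactly.
#'
#' @param ms a \linkS4class{MorphometrySet}.
#' @param path output file.
#' @param sep field delimiter, tab by default.
#' @return \code{path}, invisibly.
#' @export
writeMorphometryTable <- function(ms, path, sep = "\t") {
  v <- t(volumes(ms))
  df <- data.frame(subject_id = subjectIds(ms), group = subjectGroups(ms),
                   age = colData(ms)$age, tiv = colData(ms)$tiv,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(v, check.names = FALSE))
  # serialize doubles with 17 significant digits so read-back is bit-exact
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  data.table::fwrite(df, path, sep = sep, quote = FALSE)
  invisible(path)
}

#' Read a morphometry table from delimited text
#'
#' Accepts tab- or comma-delimited files with a header row. The mandatory
#' columns are \code{subject_id}, \code{group}, \code{age}, \code{tiv}; all
#' remaining columns are taken as region volumes in header order (never
#' reordered). Group strings are normalized case-insensitively to
#' \code{"patient"}/\code{"control"}.
#'
#' @param path input file.
#' @param parcellation name recorded on the returned table.
#' @param onMissing \code{"error"} (default) rejects any missing value;
#'   \code{"drop"} excludes incomplete rows and messages the count.
#' @return a \linkS4class{MorphometrySet}.
#' @export
readMorphometryTable <- function(path, parcellation = "unnamed",
                                 onMissing = c("error", "drop")) {
  onMissing <- match.arg(onMissing)
  stopIf(!file.exists(path), "file not found: %s", path)
  df <- data.table::fread(path, header = TRUE, data.table = FALSE)
  need <- c("subject_id", "group", "age", "tiv")
  miss <- setdiff(need, colnames(df))
  stopIf(length(miss) > 0, "missing mandatory column(s): %s",
         paste(miss, collapse = ", "))
  regionCols <- setdiff(colnames(df), need)
  stopIf(length(regionCols) == 0, "no region columns found")
  bad <- regionCols[!vapply(df[regionCols], is.numeric, logical(1))]
  stopIf(length(bad) > 0, "non-numeric volume column(s): %s",
         paste(bad, collapse = ", "))
  dup <- unique(df$subject_id[duplicated(df$subject_id)])
  stopIf(length(dup) > 0, "duplicate subject_id: %s", paste(dup, collapse = ", "))
  incomplete <- !stats::complete.cases(df[c(need, regionCols)])
  if (any(incomplete)) {
    if (onMissing == "error")
      stop(sprintf("missing values in row(s): %s",
                   paste(which(incomplete), collapse = ", ")), call. = FALSE)
    message(sprintf("excluding %d row(s) with missing values", sum(incomplete)))
    df <- df[!incomplete, , drop = FALSE]
  }
  grp <- tolower(trimws(df$group))
  stopIf(!all(grp %in% c("patient", "control")),
         "group values must be patient/control; offending rows: %s",
         paste(which(!grp %in% c("patient", "control")), collapse = ", "))
  vol <- t(as.matrix(df[regionCols]))
  rownames(vol) <- regionCols
  MorphometrySet(vol, grp, df$age, df$tiv, subjectId = df$subject_id,
                 parcellation = parcellation)
}

#' Write a truth/subtype sidecar table
#'
#' @param labels named vector (names = subject ids) or a two-column
#'   data.frame \code{subject_id}, \code{subtype}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSubtypeTable <- function(labels, path) {
  df <- if (is.data.frame(labels)) labels else
    data.frame(subject_id = names(labels), subtype = as.integer(labels),
               stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a 3D label volume from NIfTI
#'
#' @param path a NIfTI-1 file (optionally gzip-compressed).
#' @return integer 3D array with the NIfTI image attributes preserved.
#' @export
readLabelVolume <- function(path) {
  stopIf(!file.exists(path), "file not found: %s", path)
  img <- RNifti::readNifti(path)
  stopIf(length(dim(img)) != 3, "label volume must be 3D, got %dD",
         length(dim(img)))
  vals <- as.vector(img)
  stopIf(any(abs(vals - round(vals)) > 1e-8), "non-integer labels in %s", path)
  stopIf(any(vals < 0), "negative labels in %s", path)
  stopIf(all(vals == 0), "no labeled regions in %s", path)
  img
}

#' Write a statistic map as NIfTI
#'
#' @param map 3D numeric array.
#' @param path output \code{.nii}/\code{.nii.gz} file.
#' @param template optional NIfTI image whose geometry (affine, voxel size)
#'   the output inherits.
#' @return \code{path}, invisibly.
#' @export
writeStatMap <- function(map, path, template = NULL) {
  stopIf(length(dim(map)) != 3, "stat map must be 3D")
  if (!is.null(template)) {
    stopIf(!all(dim(map) == dim(template)),
           "geometry mismatch: map %s vs template %s",
           paste(dim(map), collapse = "x"), paste(dim(template), collapse = "x"))
    img <- RNifti::asNifti(map, reference = template)
  } else {
    img <- RNifti::asNifti(map)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Check that subject volumes share one geometry
#'
#' @param vols 4D array or list of 3D arrays.
#' @return the volumes as a 4D array; errors name both shapes on mismatch.
#' @export
asVolumeStack <- function(vols) {
  if (is.list(vols)) {
    d1 <- dim(vols[[1]])
    for (i in seq_along(vols)) {
      di <- dim(vols[[i]])
      stopIf(length(di) != 3 || !all(di == d1),
             "geometry mismatch between subjects: %s vs %s",
             paste(d1, collapse = "x"), paste(di, collapse = "x"))
    }
    arr <- array(0, dim = c(d1, length(vols)))
    for (i in seq_along(vols)) arr[, , , i] <- vols[[i]]
    return(arr)
  }
  stopIf(length(dim(vols)) != 4, "expected a 4D array or list of 3D arrays")
  vols
}
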