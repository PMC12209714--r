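#' Align cluster labels of one partition onto another
#'
#' Cluster labels are arbitrary, so two partitions are compared after finding
#' the label permutation of the second that maximizes exact matches with the
#' first — an optimal assignment on the K x K contingency table, solved as a
#' maximum-weight bipartite matching.
#'
#' @param a,b integer label vectors (labels in 1..K) over the same subjects,
#'   in the same order.
#' @return integer vector \code{perm} such that \code{perm[b]} is \code{b}
#'   relabeled onto \code{a}'s label set; unmatched labels of \code{b} (when
#'   it has more clusters than \code{a}) receive fresh labels above
#'   \code{max(a)}.
#' @export
alignLabels <- function(a, b) {
  stopIf(length(a) != length(b), "differing subject sets: %d vs %d",
         length(a), length(b))
  stopIf(length(a) == 0, "empty partitions")
  Ka <- max(a)
  Kb <- max(b)
  ct <- matrix(0, Ka, Kb)
  tt <- table(factor(a, levels = seq_len(Ka)), factor(b, levels = seq_len(Kb)))
  ct[] <- tt
  # complete bipartite graph, weight = match count + 1 so that every maximum
  # matching is perfect on the smaller side
  edges <- as.vector(rbind(rep(seq_len(Ka), each = Kb),
                           Ka + rep(seq_len(Kb), times = Ka)))
  g <- igraph::make_bipartite_graph(c(rep(TRUE, Ka), rep(FALSE, Kb)), edges)
  w <- as.vector(t(ct)) + 1
  mm <- igraph::max_bipartite_match(g, weights = w)$matching
  perm <- integer(Kb)
  for (j in seq_len(Kb)) {
    m <- mm[Ka + j]
    perm[j] <- if (is.na(m)) NA_integer_ else as.integer(m)
  }
  nxt <- Ka
  for (j in which(is.na(perm))) {
    nxt <- nxt + 1L
    perm[j] <- nxt
  }
  perm
}

# Build an AgreementReport from two label vectors over the same subjects.
agreementReport <- function(ref, other) {
  ids <- names(ref)
  stopIf(is.null(ids) || is.null(names(other)) ||
           !identical(sort(ids), sort(names(other))),
         "subject sets differ between the two runs")
  other <- other[ids]
  perm <- alignLabels(ref, other)
  aligned <- perm[other]
  conc <- aligned == ref
  new("AgreementReport", nCompared = length(ref),
      nConsistent = as.integer(sum(conc)),
      fractionConsistent = sum(conc) / length(ref),
      permutation = perm,
      concordant = stats::setNames(as.logical(conc), ids))
}

#' Cross-parcellation agreement of subtyping results
#'
#' Runs the full subtyping procedure (residualize, ARI-stability K scan,
#' consensus) independently on two morphometry tables of the same subjects —
#' typically the default parcellation and an alternate-atlas re-measurement —
#' and reports how many patients receive the same subtype after optimal
#' label alignment.
#'
#' @param msA,msB \linkS4class{MorphometrySet}s over the same subjects.
#' @param config a \code{\link{subtypingConfig}} shared by both runs.
#' @param seed seed shared by both runs.
#' @return list: \code{report} (\linkS4class{AgreementReport}),
#'   \code{labelsA}, \code{labelsB}, \code{profileA}, \code{profileB}.
#' @export
crossParcellationAgreement <- function(msA, msB, config = subtypingConfig(),
                                       seed = 1L) {
  stopIf(!identical(sort(subjectIds(msA)), sort(subjectIds(msB))),
         "the two tables cover different subjects")
  runA <- subtypeCohort(msA, config, seed = seed, fitFinal = FALSE)
  runB <- subtypeCohort(msB, config, seed = seed, fitFinal = FALSE)
  list(report = agreementReport(runA$labels, runB$labels),
       labelsA = runA$labels, labelsB = runB$labels,
       profileA = runA$profile, profileB = runB$profile)
}

#' Split-half consistency of subtyping results
#'
#' Randomly divides the cohort into two halves, stratified by group with
#' sizes as equal as possible, re-runs the subtyping procedure on each half,
#' and compares each half's patient labels — after optimal alignment — with
#' the full-data labels of those same patients.
#'
#' @param ms a \linkS4class{MorphometrySet}.
#' @param config a \code{\link{subtypingConfig}} shared by all runs.
#' @param seed seed for the split and the half runs.
#' @param reference optional named full-data consensus labels; computed from
#'   \code{ms} when missing.
#' @return list: \code{reports} (two \linkS4class{AgreementReport}s),
#'   \code{halves} (subject id lists), \code{reference}.
#' @export
splitHalfConsistency <- function(ms, config = subtypingConfig(), seed = 1L,
                                 reference = NULL) {
  if (is.null(reference))
    reference <- subtypeCohort(ms, config, seed = seed, fitFinal = FALSE)$labels
  grp <- subjectGroups(ms)
  half <- integer(ncol(ms))
  withSeed(childSeed(seed, 5L), {
    for (s in unique(grp)) {
      idx <- sample(which(grp == s))
      n1 <- floor(length(idx) / 2)
      half[idx[seq_len(n1)]] <- 1L
      half[idx[-seq_len(n1)]] <- 2L
    }
  })
  reports <- vector("list", 2)
  halves <- vector("list", 2)
  for (h in 1:2) {
    sub <- ms[, half == h]
    g <- subjectGroups(sub)
    stopIf(!any(g == "patient") || !any(g == "control"),
           "half %d has no %s", h, if (!any(g == "patient")) "patients" else "controls")
    run <- subtypeCohort(sub, config, seed = childSeed(seed, 10L + h),
                         fitFinal = FALSE)
    refH <- reference[names(run$labels)]
    reports[[h]] <- agreementReport(refH, run$labels)
    halves[[h]] <- subjectIds(sub)
  }
  list(reports = reports, halves = halves, reference = reference)
}

#' Serialize an AgreementReport to a list (for JSON output)
#'
#' @param x an \linkS4class{AgreementReport}.
#' @return plain list with counts, fraction and permutation.
#' @export
agreementAsList <- function(x) {
  list(n_compared = x@nCompared, n_consistent = x@nConsistent,
       fraction_consistent = x@fractionConsistent,
       permutation = x@permutation)
}
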