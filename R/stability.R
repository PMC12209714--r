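# Subset an AdjustedFeatures object to a set of subject rows.
subsetFeatures <- function(features, idx) {
  new("AdjustedFeatures",
      features = features@features[idx, , drop = FALSE],
      group = features@group[idx],
      betas = features@betas, center = features@center, scale = features@scale,
      covariates = features@covariates, parcellation = features@parcellation)
}

#' Cross-validated ARI stability profile over candidate cluster numbers
#'
#' For each K in \code{kRange}, the polytope model is refit on each fold's
#' training portion (folds stratified by patient/control), every fold's model
#' assigns the full patient set, and the mean pairwise adjusted Rand index
#' across all fold pairs measures how stable the K-cluster solution is. The
#' selected K attains the maximum mean ARI; ties break to the smallest K.
#'
#' @param features an \linkS4class{AdjustedFeatures} object.
#' @param kRange candidate cluster numbers (default 2:10).
#' @param nFolds folds (default 5, >= 2).
#' @param C margin penalty passed to \code{\link{fitPolytope}}.
#' @param seed seed controlling fold construction and fits.
#' @param nRestarts restarts per fold fit (default 2: k-means init plus one
#'   random restart; see the package vignette for the rationale).
#' @param maxIter alternating iteration cap per fit.
#' @return a \linkS4class{StabilityProfile}; \code{@foldLabels} keeps the
#'   patients x folds label matrix per K for consensus labeling.
#' @export
stabilityProfile <- function(features, kRange = 2:10, nFolds = 5L, C = 1,
                             seed = 1L, nRestarts = 2L, maxIter = 50L) {
  stopifnot(is(features, "AdjustedFeatures"))
  kRange <- sort(unique(as.integer(kRange)))
  stopIf(length(kRange) == 0, "kRange is empty")
  nFolds <- as.integer(nFolds)
  stopIf(nFolds < 2L, "nFolds must be >= 2")
  grp <- features@group
  stopIf(sum(grp == 1L) < nFolds || sum(grp == -1L) < nFolds,
         "every fold needs at least one patient and one control")
  fold <- stratifiedFolds(grp, nFolds, childSeed(seed, 1000L))
  patIdx <- which(grp == 1L)
  Xp <- features@features[patIdx, , drop = FALSE]
  nPat <- length(patIdx)
  meanARI <- numeric(length(kRange))
  foldLabels <- vector("list", length(kRange))
  for (ki in seq_along(kRange)) {
    K <- kRange[ki]
    labs <- matrix(NA_integer_, nPat, nFolds,
                   dimnames = list(rownames(Xp), NULL))
    for (f in seq_len(nFolds)) {
      train <- subsetFeatures(features, fold != f)
      fit <- fitPolytope(train, K, C = C, seed = childSeed(seed, K * 100L + f),
                         nRestarts = nRestarts, maxIter = maxIter)
      labs[, f] <- faceLabels(assignFaces(fit$model, Xp))
    }
    pairs <- utils::combn(nFolds, 2)
    meanARI[ki] <- mean(apply(pairs, 2, function(pr)
      adjustedRandIndex(labs[, pr[1]], labs[, pr[2]])))
    foldLabels[[ki]] <- labs
  }
  names(foldLabels) <- as.character(kRange)
  new("StabilityProfile", K = kRange, meanARI = meanARI, nFolds = nFolds,
      selectedK = kRange[which.max(meanARI)], foldLabels = foldLabels)
}

#' Subtyping hyperparameter bundle
#'
#' Collects the settings shared by a subtyping run and its validation
#' re-runs.
#'
#' @param covariates covariates residualized before clustering.
#' @param kRange candidate cluster numbers.
#' @param nFolds cross-validation folds.
#' @param C margin penalty.
#' @param nRestarts restarts per cross-validation fit.
#' @param finalRestarts restarts for the final full-data fit.
#' @param maxIter alternating iteration cap.
#' @return a named list of class \code{"SubtypingConfig"}.
#' @export
subtypingConfig <- function(covariates = c("age", "tiv"), kRange = 2:10,
                            nFolds = 5L, C = 1, nRestarts = 2L,
                            finalRestarts = 10L, maxIter = 50L) {
  structure(list(covariates = covariates, kRange = kRange, nFolds = nFolds,
                 C = C, nRestarts = nRestarts, finalRestarts = finalRestarts,
                 maxIter = maxIter),
            class = "SubtypingConfig")
}

#' Full subtyping run on one morphometry table
#'
#' Residualizes covariates, scans \code{kRange} by cross-validated ARI
#' stability, and produces a consensus patient labeling at the selected K
#' from the fold-wise solutions. Optionally refits a final full-data model
#' at the selected K.
#'
#' @param ms a \linkS4class{MorphometrySet}.
#' @param config a \code{\link{subtypingConfig}}.
#' @param seed integer seed for folds and fits.
#' @param fitFinal refit a full-data \linkS4class{PolytopeModel} at the
#'   selected K (default TRUE).
#' @return list: \code{features}, \code{profile}, \code{labels} (named
#'   consensus subtype per patient), and, when \code{fitFinal},
#'   \code{model}/\code{assignment} from the full-data fit.
#' @export
subtypeCohort <- function(ms, config = subtypingConfig(), seed = 1L,
                          fitFinal = TRUE) {
  feats <- residualizeCovariates(ms, config$covariates)
  prof <- stabilityProfile(feats, kRange = config$kRange, nFolds = config$nFolds,
                           C = config$C, seed = seed,
                           nRestarts = config$nRestarts, maxIter = config$maxIter)
  labs <- prof@foldLabels[[as.character(selectedK(prof))]]
  cons <- consensusAssignment(lapply(seq_len(ncol(labs)), function(f)
    stats::setNames(labs[, f], rownames(labs))))
  out <- list(features = feats, profile = prof, labels = cons)
  if (fitFinal) {
    fit <- fitPolytope(feats, selectedK(prof), C = config$C,
                       seed = childSeed(seed, 77L),
                       nRestarts = config$finalRestarts, maxIter = config$maxIter)
    out$model <- fit$model
    out$assignment <- fit$assignment
  }
  out
}
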