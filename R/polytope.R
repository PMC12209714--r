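#' @importFrom e1071 svm
NULL

# Fit one face: weighted soft-margin linear discriminant with the face's
# patients on the positive side (weight 1) and every control on the negative
# side (weight 1/K). Returns the patient-positive oriented (w, b).
fitFace <- function(Xpos, Xctrl, C, K) {
  X <- rbind(Xpos, Xctrl)
  y <- factor(c(rep("1", nrow(Xpos)), rep("-1", nrow(Xctrl))),
              levels = c("1", "-1"))
  m <- e1071::svm(X, y, type = "C-classification", kernel = "linear",
                  cost = C, class.weights = c("1" = 1, "-1" = 1 / K),
                  scale = FALSE, tolerance = 1e-5)
  w <- drop(t(m$coefs) %*% m$SV)
  b <- -m$rho
  if (mean(Xpos %*% w) + b < mean(Xctrl %*% w) + b) {
    w <- -w
    b <- -b
  }
  list(w = w, b = b)
}

# Regularized weighted hinge objective over all K faces (minimized).
polytopeObjective <- function(W, b, Xp, Xc, face, C) {
  K <- ncol(W)
  Sp <- Xp %*% W + matrix(b, nrow(Xp), K, byrow = TRUE)
  Sc <- Xc %*% W + matrix(b, nrow(Xc), K, byrow = TRUE)
  J <- 0.5 * sum(W^2)
  hingeP <- pmax(0, 1 - Sp[cbind(seq_len(nrow(Xp)), face)])
  hingeC <- pmax(0, 1 + Sc)
  J + C * (sum(hingeP) + sum(hingeC) / K)
}

# One alternating-optimization run from a given initial assignment.
runPolytope <- function(Xp, Xc, init, K, C, maxIter) {
  face <- init
  W <- matrix(0, ncol(Xp), K)
  b <- numeric(K)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    for (k in seq_len(K)) {
      fk <- fitFace(Xp[face == k, , drop = FALSE], Xc, C, K)
      W[, k] <- fk$w
      b[k] <- fk$b
    }
    Sp <- Xp %*% W + matrix(b, nrow(Xp), K, byrow = TRUE)
    newFace <- max.col(Sp, ties.method = "first")
    # re-seed any emptied face with the lowest-margin patient of a
    # multiply-occupied face, keeping all K faces live
    for (k in seq_len(K)) {
      if (!any(newFace == k)) {
        counts <- tabulate(newFace, K)
        movable <- which(counts[newFace] > 1L)
        if (!length(movable)) break
        margins <- Sp[cbind(movable, newFace[movable])]
        newFace[movable[which.min(margins)]] <- k
      }
    }
    trace <- c(trace, polytopeObjective(W, b, Xp, Xc, newFace, C))
    if (all(newFace == face)) {
      converged <- TRUE
      break
    }
    face <- newFace
    if (iter >= maxIter) break
  }
  list(W = W, b = b, face = face, trace = trace,
       converged = converged, iterations = iter)
}

# Initial patient partitions: k-means split first, then random partitions.
polytopeInits <- function(Xp, K, nRestarts, seed) {
  n <- nrow(Xp)
  inits <- vector("list", nRestarts)
  inits[[1]] <- withSeed(childSeed(seed, 0L), {
    if (K == 1L) rep(1L, n)
    else as.integer(stats::kmeans(Xp, centers = K, nstart = 5)$cluster)
  })
  if (nRestarts > 1) {
    for (r in 2:nRestarts) {
      inits[[r]] <- withSeed(childSeed(seed, r - 1L),
                             sample(rep_len(seq_len(K), n)))
    }
  }
  inits
}

#' Fit a max-margin polytope separating patients from controls
#'
#' Alternating optimization of K hyperplane faces: given assignments, each
#' face is fit as a weighted soft-margin linear discriminant (its patients
#' vs all controls, control weight 1/K); given faces, each patient is
#' reassigned to the face with maximal signed score. Iterates until the
#' assignment is unchanged or \code{maxIter}; across \code{nRestarts}
#' initializations (a k-means split of patient features plus random
#' partitions) the solution with the lowest regularized hinge objective is
#' returned. Deterministic given \code{(seed, nRestarts)}.
#'
#' @param features an \linkS4class{AdjustedFeatures} object.
#' @param K number of faces (subtypes), \code{1 <= K <=} distinct patients.
#' @param C margin-violation penalty (default 1).
#' @param seed integer seed controlling all initializations.
#' @param nRestarts number of initializations (default 10).
#' @param maxIter maximum alternating iterations per restart (default 50).
#' @return list with \code{model} (\linkS4class{PolytopeModel}) and
#'   \code{assignment} (\linkS4class{FaceAssignment} over patients).
#' @export
fitPolytope <- function(features, K, C = 1, seed = 1L, nRestarts = 10L,
                        maxIter = 50L) {
  stopifnot(is(features, "AdjustedFeatures"))
  K <- as.integer(K)
  stopIf(K < 1L, "K must be >= 1")
  Xp <- features@features[features@group == 1L, , drop = FALSE]
  Xc <- features@features[features@group == -1L, , drop = FALSE]
  stopIf(nrow(Xp) < 1L || nrow(Xc) < 1L, "need at least one patient and one control")
  nDistinct <- nrow(unique(Xp))
  stopIf(K > nDistinct, "K (%d) exceeds distinct patient rows (%d)", K, nDistinct)
  stopIf(any(!is.finite(Xp)) || any(!is.finite(Xc)), "non-finite features")
  inits <- polytopeInits(Xp, K, as.integer(nRestarts), as.integer(seed))
  best <- NULL
  for (ini in inits) {
    sol <- runPolytope(Xp, Xc, ini, K, C, as.integer(maxIter))
    if (is.null(best) || sol$trace[length(sol$trace)] < best$trace[length(best$trace)])
      best <- sol
  }
  rownames(best$W) <- colnames(features@features)
  model <- new("PolytopeModel", K = K, W = best$W, b = best$b, cost = C,
               seed = as.integer(seed), nRestarts = as.integer(nRestarts),
               objective = best$trace[length(best$trace)],
               objectiveTrace = best$trace, converged = best$converged,
               iterations = best$iterations)
  scores <- Xp %*% best$W + matrix(best$b, nrow(Xp), K, byrow = TRUE)
  rownames(scores) <- rownames(Xp)
  assignment <- new("FaceAssignment",
                    face = stats::setNames(best$face, rownames(Xp)),
                    scores = scores)
  list(model = model, assignment = assignment)
}

#' Assign subjects to polytope faces
#'
#' Each subject is assigned to the face with maximal signed score
#' \code{x . w_k + b_k}; exact ties break to the lowest face index.
#'
#' @param model a \linkS4class{PolytopeModel}.
#' @param x numeric matrix (subjects x features) or an
#'   \linkS4class{AdjustedFeatures} object, in which case only patients are
#'   assigned.
#' @return a \linkS4class{FaceAssignment}.
#' @export
assignFaces <- function(model, x) {
  if (is(x, "AdjustedFeatures"))
    x <- x@features[x@group == 1L, , drop = FALSE]
  x <- as.matrix(x)
  stopIf(ncol(x) != nrow(model@W),
         "feature dimension mismatch: %d vs model %d", ncol(x), nrow(model@W))
  scores <- x %*% model@W + matrix(model@b, nrow(x), model@K, byrow = TRUE)
  rownames(scores) <- rownames(x)
  new("FaceAssignment",
      face = stats::setNames(max.col(scores, ties.method = "first"), rownames(x)),
      scores = scores)
}

#' Consensus labeling across repeated assignments
#'
#' Aligns each labeling to the first by the best label permutation
#' (\code{\link{alignLabels}}), then takes a per-patient majority vote; vote
#' ties break to the lowest aligned label.
#'
#' @param assignments list of \linkS4class{FaceAssignment} objects or named
#'   integer label vectors over the same patients.
#' @return named integer vector of consensus labels.
#' @export
consensusAssignment <- function(assignments) {
  stopIf(length(assignments) == 0, "no assignments given")
  labs <- lapply(assignments, function(a)
    if (is(a, "FaceAssignment")) faceLabels(a) else a)
  ref <- labs[[1]]
  ids <- names(ref)
  for (l in labs)
    stopIf(is.null(names(l)) || !identical(sort(names(l)), sort(ids)),
           "assignments cover inconsistent patient sets")
  labs <- lapply(labs, function(l) l[ids])
  K <- max(vapply(labs, max, integer(1)))
  aligned <- vapply(labs, function(l) {
    perm <- alignLabels(ref, l)
    perm[l]
  }, integer(length(ref)))
  aligned <- matrix(aligned, nrow = length(ref))
  out <- apply(aligned, 1, function(v) which.max(tabulate(v, max(K, max(v)))))
  stats::setNames(as.integer(out), ids)
}
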