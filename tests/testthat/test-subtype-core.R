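test_that("residualization removes exactly-linear covariate structure", {
  set.seed(1)
  n <- 40
  age <- rnorm(n, 46, 10)
  tiv <- rnorm(n, 1400, 120)
  vol <- rbind(2 + 0.5 * age + 0.003 * tiv,
               1 - 0.2 * age + 0.001 * tiv,
               4 + 0.0 * age + 0.002 * tiv)
  # add a touch of independent variation so control SDs are nonzero
  vol <- vol + matrix(rnorm(3 * n, 0, 1e-6), 3)
  ms <- MorphometrySet(vol, c(rep("control", 30), rep("patient", 10)),
                       age, tiv, subjectId = sprintf("S%02d", 1:n))
  feats <- residualizeCovariates(ms)
  raw <- t(vol) - cbind(1, age, tiv) %*% feats@betas
  expect_lt(max(abs(raw)), 1e-4)
  expect_equal(unname(feats@betas["age", ]), c(0.5, -0.2, 0.0), tolerance = 1e-3)
})

test_that("planted covariate slopes are recovered from controls", {
  d <- cohortDesign(nControls = 500, nSubtype1 = 20, nSubtype2 = 20,
                    nRegions = 60, affectedRegions = 1:10,
                    betaAge = 0.5, betaTiv = 0.002, seed = 13)
  feats <- residualizeCovariates(simulateCohort(d)$cohort)
  expect_lt(max(abs(feats@betas["age", ] - 0.5)), 0.05)
  # adjusted control features are uncorrelated with the covariates
  ctrl <- feats@group == -1L
  sim <- simulateCohort(d)
  age <- SummarizedExperiment::colData(sim$cohort)$age[ctrl]
  r <- apply(feats@features[ctrl, ], 2, cor, y = age)
  expect_lt(max(abs(r)), 0.05)
  # control standardization contract
  expect_lt(max(abs(colMeans(feats@features[ctrl, ]))), 1e-10)
  expect_equal(unname(apply(feats@features[ctrl, ], 2, sd)), rep(1, 60),
               tolerance = 1e-10)
})

test_that("residualization rejects degenerate inputs", {
  set.seed(6)
  vol <- matrix(rnorm(18), 3)
  ms <- MorphometrySet(vol, c(rep("control", 5), "patient"),
                       age = 40:45, tiv = rep(1400, 6))
  expect_error(residualizeCovariates(ms), "constant covariate")
  vol2 <- matrix(rnorm(12), 3)
  ms2 <- MorphometrySet(vol2, c("control", "patient", "patient", "patient"),
                        age = c(40, 41, 42, 43), tiv = c(1300, 1350, 1400, 1450))
  expect_error(residualizeCovariates(ms2), "fewer controls")
})

test_that("adjusted Rand index matches hand-worked cases and is label-invariant", {
  expect_equal(adjustedRandIndex(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1.0)
  expect_equal(adjustedRandIndex(c(1, 1, 2, 2), c(1, 2, 2, 2)), 0.0)
  expect_equal(adjustedRandIndex(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1.0)
  expect_equal(adjustedRandIndex(rep(1, 5), rep(1, 5)), 1.0)
  expect_equal(adjustedRandIndex(1:5, 1:5), 1.0)
  set.seed(42)
  for (i in 1:20) {
    a <- sample(1:3, 12, replace = TRUE)
    b <- sample(1:4, 12, replace = TRUE)
    perm <- sample(4)
    expect_equal(adjustedRandIndex(a, b), adjustedRandIndex(a, perm[b]))
    expect_equal(adjustedRandIndex(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_error(adjustedRandIndex(1:3, 1:4), "lengths differ")
  expect_error(adjustedRandIndex(integer(0), integer(0)), "empty")
})

test_that("a single face reduces to one max-margin patient/control classifier", {
  X <- rbind(c(-1, 0), c(-2, 1), c(1, 0), c(2, 1))
  feats <- new("AdjustedFeatures",
               features = `rownames<-`(X, paste0("S", 1:4)),
               group = stats::setNames(c(-1L, -1L, 1L, 1L), paste0("S", 1:4)),
               betas = matrix(0, 1, 2), center = c(0, 0), scale = c(1, 1),
               covariates = character(0), parcellation = "toy")
  fit <- fitPolytope(feats, K = 1, seed = 1, nRestarts = 1)
  expect_equal(unname(faceLabels(fit$assignment)), c(1L, 1L))
  s <- X %*% fit$model@W[, 1] + fit$model@b[1]
  expect_true(all(s[1:2] < 0))
  expect_true(all(s[3:4] > 0))
})

makeToyFeatures <- function(seed = 3, nCtrl = 40, nPer = 20, shift = 4) {
  set.seed(seed)
  Xc <- matrix(rnorm(nCtrl * 2), nCtrl)
  X1 <- cbind(rnorm(nPer, shift), rnorm(nPer))
  X2 <- cbind(rnorm(nPer), rnorm(nPer, shift))
  X <- rbind(Xc, X1, X2)
  ids <- sprintf("S%03d", seq_len(nrow(X)))
  rownames(X) <- ids
  list(feats = new("AdjustedFeatures", features = X,
                   group = stats::setNames(rep(c(-1L, 1L), c(nCtrl, 2 * nPer)), ids),
                   betas = matrix(0, 1, 2), center = c(0, 0), scale = c(1, 1),
                   covariates = character(0), parcellation = "toy"),
       truth = rep(1:2, each = nPer))
}

test_that("two faces recover a planted two-direction patient split exactly", {
  toy <- makeToyFeatures()
  fit <- fitPolytope(toy$feats, K = 2, seed = 1, nRestarts = 5)
  est <- unname(faceLabels(fit$assignment))
  expect_equal(adjustedRandIndex(est, toy$truth), 1.0)
  expect_true(fit$model@converged)
})

test_that("the polytope objective is non-increasing across iterations", {
  for (s in 1:5) {
    sim <- simulateCohort(cohortDesign(nControls = 40, nSubtype1 = 15,
                                       nSubtype2 = 15, nRegions = 60,
                                       affectedRegions = 1:10,
                                       effectSize = 1.0, seed = s))
    fit <- fitPolytope(residualizeCovariates(sim$cohort), K = 2,
                       seed = s, nRestarts = 2)
    tr <- fit$model@objectiveTrace
    if (length(tr) > 1)
      expect_true(all(diff(tr) <= 1e-5 * pmax(abs(tr[-length(tr)]), 1)))
  }
})

test_that("on separable data controls score negative on every face", {
  toy <- makeToyFeatures(seed = 7, shift = 6)
  fit <- fitPolytope(toy$feats, K = 2, seed = 2, nRestarts = 3)
  Xc <- toy$feats@features[toy$feats@group == -1L, ]
  Sc <- Xc %*% fit$model@W + matrix(fit$model@b, nrow(Xc), 2, byrow = TRUE)
  expect_true(all(Sc <= 0))
  # and each patient scores positive on its assigned face
  sp <- faceScores(fit$assignment)
  expect_true(all(sp[cbind(seq_len(nrow(sp)),
                           unname(faceLabels(fit$assignment)))] > 0))
})

test_that("duplicated identical patients are always co-assigned", {
  toy <- makeToyFeatures(seed = 9)
  X <- toy$feats@features
  # duplicate two patients exactly
  pat <- which(toy$feats@group == 1L)
  Xd <- rbind(X, X[pat[1:2], , drop = FALSE])
  rownames(Xd) <- c(rownames(X), "DUP1", "DUP2")
  grp <- c(toy$feats@group, DUP1 = 1L, DUP2 = 1L)
  names(grp) <- rownames(Xd)
  featsD <- new("AdjustedFeatures", features = Xd, group = grp,
                betas = matrix(0, 1, 2), center = c(0, 0), scale = c(1, 1),
                covariates = character(0), parcellation = "toy")
  fit <- fitPolytope(featsD, K = 2, seed = 4, nRestarts = 3)
  lab <- faceLabels(fit$assignment)
  expect_equal(unname(lab["DUP1"]), unname(lab[names(lab)[1]][[1]] * 0 +
                                             lab[rownames(X)[pat[1]]][[1]]))
  expect_equal(unname(lab["DUP2"]), unname(lab[rownames(X)[pat[2]]][[1]]))
})

test_that("polytope fitting is deterministic and validates inputs", {
  toy <- makeToyFeatures(seed = 5)
  f1 <- fitPolytope(toy$feats, K = 2, seed = 10, nRestarts = 3)
  f2 <- fitPolytope(toy$feats, K = 2, seed = 10, nRestarts = 3)
  expect_identical(f1$model@W, f2$model@W)
  expect_identical(faceLabels(f1$assignment), faceLabels(f2$assignment))
  expect_error(fitPolytope(toy$feats, K = 100), "exceeds distinct patient rows")
  expect_error(fitPolytope(toy$feats, K = 0), "K must be >= 1")
})

test_that("assignFaces applies the max-score rule with lowest-index ties", {
  W <- cbind(c(1, 0), c(0, 1))
  m <- new("PolytopeModel", K = 2L, W = W, b = c(0, 0), cost = 1,
           seed = 1L, nRestarts = 1L, objective = 0, objectiveTrace = 0,
           converged = TRUE, iterations = 1L)
  a <- assignFaces(m, rbind(c(2, 1), c(1, 2), c(3, 3)))
  expect_equal(unname(faceLabels(a)), c(1L, 2L, 1L))
  expect_error(assignFaces(m, matrix(0, 2, 3)), "dimension mismatch")
  # training-set consistency with fitPolytope's own assignment
  toy <- makeToyFeatures(seed = 12)
  fit <- fitPolytope(toy$feats, K = 2, seed = 3, nRestarts = 3)
  re <- assignFaces(fit$model, toy$feats)
  expect_identical(faceLabels(re), faceLabels(fit$assignment))
})

test_that("stability profiling selects the only K in a singleton range", {
  sim <- tinyCohort(seed = 2)
  feats <- residualizeCovariates(sim$cohort)
  prof <- stabilityProfile(feats, kRange = 3, nFolds = 3, seed = 1,
                           nRestarts = 1)
  expect_equal(selectedK(prof), 3L)
  expect_length(meanARI(prof), 1)
})

test_that("planted structure raises K = 2 stability above the noise floor", {
  # CV folds share 80% of subjects, so even null cohorts show nonzero ARI;
  # the meaningful invariant is the structured-vs-null contrast.
  ariAt2 <- function(effect, seed) {
    sim <- simulateCohort(cohortDesign(effectSize = effect, seed = seed))
    feats <- residualizeCovariates(sim$cohort)
    meanARI(stabilityProfile(feats, kRange = 2, nFolds = 5, seed = seed,
                             nRestarts = 2))
  }
  for (s in 4:5) expect_gt(ariAt2(1.0, s), ariAt2(0, s) + 0.1)
})

test_that("consensus labeling aligns, votes and recovers noisy copies", {
  lab <- stats::setNames(rep(1:2, each = 4), paste0("P", 1:8))
  expect_identical(consensusAssignment(list(lab, lab)), lab)
  swapped <- stats::setNames(3L - lab, names(lab))
  expect_identical(consensusAssignment(list(lab, swapped)), lab)
  # 5 noisy copies of a planted labeling recover >= 98% of patients
  set.seed(31)
  planted <- stats::setNames(sample(1:2, 200, replace = TRUE), paste0("P", 1:200))
  copies <- lapply(1:5, function(i) {
    flip <- runif(200) < 0.05
    stats::setNames(ifelse(flip, 3L - planted, planted), names(planted))
  })
  cons <- consensusAssignment(copies)
  expect_gte(mean(cons == planted), 0.98)
  bad <- stats::setNames(lab[1:7], names(lab)[1:7])
  expect_error(consensusAssignment(list(lab, bad)), "inconsistent")
})
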