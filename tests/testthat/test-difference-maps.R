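test_that("two-sample t matches stats::t.test in both variants", {
  set.seed(3)
  for (i in 1:10) {
    a <- rnorm(8 + i, sd = 1 + i / 5)
    b <- rnorm(14, mean = 0.3)
    tp <- twoSampleT(a, b, variant = "pooled")
    ref <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(tp$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(tp$p, ref$p.value, tolerance = 1e-12)
    expect_equal(tp$df, unname(ref$parameter), tolerance = 1e-12)
    tw <- twoSampleT(a, b, variant = "welch")
    refW <- stats::t.test(a, b, var.equal = FALSE)
    expect_equal(tw$t, unname(refW$statistic), tolerance = 1e-12)
    expect_equal(tw$p, refW$p.value, tolerance = 1e-12)
    expect_equal(tw$df, unname(refW$parameter), tolerance = 1e-12)
    # antisymmetry in the group order
    expect_equal(twoSampleT(b, a)$t, -tp$t, tolerance = 1e-12)
  }
})

test_that("degenerate zero-variance inputs follow the documented conventions", {
  same <- twoSampleT(c(2, 2, 2), c(2, 2, 2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  apart <- twoSampleT(c(3, 3, 3), c(2, 2, 2, 2))
  expect_equal(apart$t, Inf)
  expect_equal(apart$p, 0)
  expect_equal(twoSampleT(c(1, 1), c(2, 2))$t, -Inf)
  expect_error(twoSampleT(1, 1:3), "each group needs n >= 2")
})

test_that("BH adjustment reproduces the worked five-test example", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042)
  res <- bhFdr(p, alpha = 0.05)
  expect_true(all(res$reject))
  # raw BH ratios are 0.005, 0.02, 0.065, 0.05125, 0.042; the running
  # minimum from the largest p enforces monotonicity
  expect_equal(res$q, c(0.005, 0.020, 0.042, 0.042, 0.042), tolerance = 1e-12)
})

test_that("BH agrees with an independent step-up oracle on random inputs", {
  set.seed(8)
  for (i in 1:50) {
    m <- sample(1:200, 1)
    p <- runif(m)^sample(1:3, 1)
    alpha <- runif(1, 0.01, 0.2)
    res <- bhFdr(p, alpha)
    oracle <- stepUpBH(p, alpha)
    expect_equal(res$q, oracle$q, tolerance = 1e-12)
    expect_identical(res$reject, oracle$reject)
  }
  # all-null edge case and q monotonicity in p
  resNull <- bhFdr(rep(1, 10), 0.05)
  expect_false(any(resNull$reject))
  p <- sort(runif(30))
  expect_true(all(diff(bhFdr(p, 0.05)$q) >= -1e-15))
})

test_that("Cohen's d reproduces hand-checked pooled values", {
  expect_equal(cohensD(1, 1, 10, 1, 1, 10), 0)
  # PSS 30.7 (8.9) n=38 vs 25.0 (9.4) n=37
  expect_equal(cohensD(30.7, 8.9, 38, 25.0, 9.4, 37), 0.623, tolerance = 1e-3)
  # age 43.3 (9.8) n=38 vs 48.4 (10.8) n=37
  expect_equal(cohensD(43.3, 9.8, 38, 48.4, 10.8, 37), -0.495, tolerance = 1e-3)
})

test_that("cluster extent filtering keeps > minSize components only", {
  lab <- makeBlockLabelMap(c(12, 12, 12), list(
    list(label = 1, from = c(1, 1, 1), to = c(5, 4, 2)),    # 40 voxels
    list(label = 2, from = c(8, 8, 8), to = c(12, 12, 10)), # 75 voxels
    list(label = 3, from = c(1, 10, 1), to = c(1, 10, 1)))) # single voxel
  mask <- lab > 0
  res <- clusterExtentFilter(mask, minSize = 40)
  expect_equal(sum(res$mask), 75)            # 40 is not strictly > 40
  expect_equal(nrow(res$clusters), 1)
  expect_equal(res$clusters$size, 75)
  # 0-based peak coordinates fall inside the surviving block
  expect_true(all(res$clusters[, c("peak_x", "peak_y", "peak_z")] >= 7))
  res41 <- clusterExtentFilter(mask, minSize = 39)
  expect_equal(sum(res41$mask), 115)
  # idempotence
  again <- clusterExtentFilter(res$mask, minSize = 40)
  expect_identical(again$mask, res$mask)
})

test_that("connectivity controls whether diagonal voxels join a component", {
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- TRUE
  m[2, 2, 2] <- TRUE  # corner neighbor
  comp26 <- labelComponents3D(m, connectivity = 26)
  expect_equal(max(comp26), 1)
  comp6 <- labelComponents3D(m, connectivity = 6)
  expect_equal(max(comp6), 2)
  m[2, 2, 1] <- TRUE  # edge neighbor of both
  expect_equal(max(labelComponents3D(m, connectivity = 18)), 1)
})

test_that("component labeling matches a flood-fill oracle on random volumes", {
  set.seed(12)
  for (conn in c(6L, 18L, 26L)) {
    for (i in 1:3) {
      mask <- array(runif(512) < 0.25, c(8, 8, 8))
      ours <- labelComponents3D(mask, connectivity = conn)
      oracle <- floodFillLabel(mask, conn)
      expect_equal(max(ours), max(oracle))
      # same partition of the on-voxels, up to label numbering
      on <- which(mask)
      if (length(on) > 1)
        expect_equal(adjustedRandIndex(ours[on], oracle[on]), 1.0)
    }
  }
})

test_that("ROI tests flag planted regions and validate contrasts", {
  sim <- tinyCohort(seed = 25, effectSize = 2.0)
  labels <- stats::setNames(sim$truth$subtype, sim$truth$subject_id)
  res <- roiGroupTest(sim$cohort, labels, contrast = "subtype1")
  expect_s4_class(res, "DataFrame")
  expect_equal(nrow(res), 60)
  sig <- which(res$significant)
  expect_gte(length(intersect(sig, 1:10)), 9)
  expect_lte(length(setdiff(sig, 1:10)), 3)
  expect_true(all(res$d[1:10] > 0))  # planted effect increases volume
  expect_error(roiGroupTest(sim$cohort, labels, contrast = "nope"),
               "'arg' should be one of")
  expect_error(roiGroupTest(sim$cohort, labels[-1], contrast = "subtype1"),
               NA)  # subset of patients is allowed by named matching
  badNames <- stats::setNames(labels, paste0("X", seq_along(labels)))
  expect_error(roiGroupTest(sim$cohort, badNames), "do not match patient ids")
})

test_that("voxelwise testing is empty under the null and recovers planted blocks", {
  lab <- makeBlockLabelMap(c(12, 12, 12), list(
    list(label = 1, from = c(2, 2, 2), to = c(6, 6, 3)),   # 50 voxels
    list(label = 2, from = c(9, 9, 9), to = c(12, 12, 9))))# 16 voxels
  grp <- rep(c("control", "patient"), each = 16)
  # identical groups: nothing survives
  ph0 <- simulateVoxelPhantom(lab, grp, noiseSd = 0.2, seed = 2)
  res0 <- voxelwiseGroupTest(ph0, grp, alpha = 0.05, minCluster = 40)
  expect_equal(res0$nSigVoxels, 0)
  # offset in both blocks: the 50-voxel block survives, the 16-voxel one cannot
  ph <- simulateVoxelPhantom(lab, grp, groupOffsets = c("1" = 1, "2" = 1),
                             noiseSd = 0.2, seed = 3)
  res <- voxelwiseGroupTest(ph, grp, alpha = 0.05, minCluster = 40)
  inBlock <- lab == 1
  expect_gte(sum(res$mask & inBlock) / 50, 0.9)
  expect_equal(sum(res$mask & (lab == 2)), 0)
  expect_true(all(res$clusters$size > 40))
  # NIfTI side outputs are written when requested
  out <- withr::local_tempdir()
  res2 <- voxelwiseGroupTest(ph, grp, alpha = 0.05, minCluster = 40,
                             outDir = out)
  expect_true(all(file.exists(file.path(out, c("tmap.nii.gz", "dmap.nii.gz",
                                               "qmap.nii.gz",
                                               "sigmask.nii.gz")))))
  tm <- RNifti::readNifti(file.path(out, "tmap.nii.gz"))
  expect_equal(dim(tm), c(12, 12, 12))
  expect_error(voxelwiseGroupTest(ph, rep("control", 32)), "two levels")
})
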