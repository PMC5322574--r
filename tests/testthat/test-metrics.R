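test_that("confusion counts match the set definitions and the voxel loop", {
  t <- randomLabelMap(c(4, 4, 4), 1, 0.4)
  s <- randomLabelMap(c(4, 4, 4), 2, 0.4)
  cc <- confusionCounts(t, s)
  oracle <- bruteConfusion(as.vector(labelArray(t)), as.vector(labelArray(s)))
  expect_identical(cc, oracle)
  expect_identical(cc$tp + cc$fp + cc$fn + cc$tn, 64L)

  same <- confusionCounts(t, t)
  expect_identical(same$fp, 0L)
  expect_identical(same$fn, 0L)

  empty <- LabelMap(array(0L, c(4, 4, 4)), unitGrid(c(4, 4, 4)))
  cc2 <- confusionCounts(t, empty)
  expect_identical(cc2$tp, 0L)
  expect_identical(cc2$fn, sum(labelArray(t) == 1L))
  expect_error(confusionCounts(t, randomLabelMap(c(5, 5, 5), 1)),
               "incompatible")
})

test_that("dice and pvd follow their closed forms", {
  expect_equal(dice(list(tp = 40L, fp = 10L, fn = 10L, tn = 0L)), 80)
  expect_equal(dice(list(tp = 5L, fp = 0L, fn = 0L, tn = 10L)), 100)
  expect_equal(dice(list(tp = 0L, fp = 3L, fn = 4L, tn = 0L)), 0)
  expect_error(dice(list(tp = 0L, fp = 0L, fn = 0L, tn = 8L)), "empty")

  expect_equal(pvd(list(tp = 90L, fp = 0L, fn = 10L, tn = 0L))$signed, 10)
  p <- pvd(list(tp = 100L, fp = 10L, fn = 0L, tn = 0L))
  expect_equal(p$signed, -10)
  expect_equal(p$abs, 10)
  expect_equal(pvd(list(tp = 50L, fp = 5L, fn = 5L, tn = 0L))$signed, 0)
  expect_error(pvd(list(tp = 0L, fp = 3L, fn = 0L, tn = 8L)), "empty")

  # agreement with the direct set formulas on random maps
  for (seed in 1:3) {
    t <- randomLabelMap(c(5, 5, 5), seed, 0.4)
    s <- randomLabelMap(c(5, 5, 5), seed + 10, 0.4)
    g <- labelArray(t) == 1L
    ss <- labelArray(s) == 1L
    cc <- confusionCounts(t, s)
    expect_equal(dice(cc), 100 * 2 * sum(g & ss) / (sum(g) + sum(ss)))
    expect_equal(pvd(cc)$signed, 100 * (sum(g) - sum(ss)) / sum(g))
  }
})

test_that("surface extraction finds face-boundary kidney voxels", {
  d <- c(5, 5, 5)
  single <- array(0L, d); single[3, 3, 3] <- 1L
  sv <- surfaceVoxels(LabelMap(single, unitGrid(d)))
  expect_identical(unname(sv), matrix(c(2L, 2L, 2L), 1))

  block <- array(0L, d); block[2:4, 2:4, 2:4] <- 1L
  sv2 <- surfaceVoxels(LabelMap(block, unitGrid(d)))
  expect_identical(nrow(sv2), 26L)     # all of the 3^3 block but its centre
  expect_false(any(sv2[, 1] == 2 & sv2[, 2] == 2 & sv2[, 3] == 2))

  full <- LabelMap(array(1L, d), unitGrid(d))
  sv3 <- surfaceVoxels(full)
  expect_identical(nrow(sv3), as.integer(prod(d)) - 27L)  # outer shell only
  expect_error(surfaceVoxels(LabelMap(array(0L, d), unitGrid(d))), "empty")
})

test_that("directed Hausdorff matches Cartesian geometry and the oracle", {
  expect_equal(directedHausdorff(matrix(c(0, 0, 0), 1),
                                 matrix(c(3, 4, 0), 1)), 5)
  a <- matrix(c(0, 0, 0), 1)
  expect_equal(directedHausdorff(a, a, percentile = 0.95), 0)

  set.seed(6)
  G <- matrix(sample(0:9, 30 * 3, TRUE), 30)
  S <- matrix(sample(0:9, 24 * 3, TRUE), 24)
  sp <- c(0.64, 0.64, 0.9)
  for (pc in c(0.5, 0.95, 1))
    expect_equal(directedHausdorff(G, S, sp, pc),
                 bruteDirectedHD(G, S, sp, pc))
  # percentile is monotone and 1.0 recovers the classical max
  d50 <- directedHausdorff(G, S, sp, 0.5)
  d95 <- directedHausdorff(G, S, sp, 0.95)
  d100 <- directedHausdorff(G, S, sp, 1)
  expect_true(d50 <= d95 && d95 <= d100)
  expect_error(directedHausdorff(G[0, , drop = FALSE], S), "empty")
})

test_that("bhd95 is symmetric, zero on identity, and spacing-aware", {
  t <- smallCohort(2, 9)[[1]]@truth
  expect_equal(bhd95(t, t), 0)

  arr <- labelArray(t)
  er <- array(0L, dim(arr))
  er[2:31, 2:31, 2:31] <- arr[2:31, 2:31, 2:31]   # crop-damaged copy
  er[10:14, , ] <- 0L
  s <- LabelMap(er, voxelGrid(t))
  expect_equal(bhd95(t, s), bhd95(s, t))

  # two single-voxel kidneys 5 mm apart
  d <- c(8, 8, 8)
  a <- array(0L, d); a[2, 2, 2] <- 1L
  b <- array(0L, d); b[7, 2, 2] <- 1L
  g <- VoxelGrid(d, c(1, 1, 1))
  expect_equal(bhd95(LabelMap(a, g), LabelMap(b, g)), 5)
  g2 <- VoxelGrid(d, c(0.5, 1, 1))
  expect_equal(bhd95(LabelMap(a, g2), LabelMap(b, g2)), 2.5)
})

test_that("ROC/AUC equals the Mann-Whitney statistic with tie handling", {
  # perfectly ordered probabilities
  y <- c(rep(1L, 8), rep(0L, 12))
  p <- c(seq(0.6, 0.95, length.out = 8), seq(0.05, 0.45, length.out = 12))
  r <- rocAuc(y, p)
  expect_equal(r$auc, 1)
  expect_equal(r$roc$fpr[1], 0)
  expect_equal(r$roc$tpr[nrow(r$roc)], 1)

  # constant probabilities sit on the chance line
  expect_equal(rocAuc(y, rep(0.4, 20))$auc, 0.5)

  # 20-voxel case with ties: AUC = normalized pairwise-comparison count
  set.seed(9)
  p2 <- sample(seq(0, 1, 0.1), 20, TRUE)
  expect_equal(rocAuc(y, p2)$auc, bruteAUC(y, p2))
  # independent library cross-check with an explicit orientation
  expect_equal(rocAuc(y, p2)$auc,
               as.numeric(pROC::auc(pROC::roc(response = y, predictor = p2,
                                              levels = c(0, 1),
                                              direction = "<",
                                              quiet = TRUE))))

  expect_error(rocAuc(rep(1L, 10), runif(10)), "single class")
})

test_that("evaluateSegmentation assembles a coherent report", {
  cohort <- smallCohort(2, 9)
  t <- cohort[[1]]@truth
  noisy <- labelArray(t)
  set.seed(2)
  fl <- sample(which(noisy == 1L), 20)
  noisy[fl] <- 0L
  s <- LabelMap(noisy, voxelGrid(t))
  pm <- ProbabilityMap(array(pmin(pmax(
    labelArray(t) * 0.8 + runif(length(noisy)) * 0.2, 0), 1),
    dim(noisy)), voxelGrid(t))
  rep <- evaluateSegmentation(t, s, pm)
  expect_true(rep@dc > 0 && rep@dc < 100)
  expect_equal(rep@pvdAbs, abs(rep@pvd))
  expect_gte(rep@bhd95, 0)
  expect_true(rep@auc > 0.5 && rep@auc <= 1)
  p <- withr::local_tempfile(fileext = ".json")
  writeEvalReport(rep, p)
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(back$dc, rep@dc)
  expect_equal(back$bhd95, rep@bhd95)
})
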