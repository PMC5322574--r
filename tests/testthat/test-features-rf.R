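test_that("the neighborhood engine matches brute-force neighbor loops", {
  set.seed(3)
  arr <- array(rnorm(125), c(5, 5, 5))
  for (off in list(RenalSeg:::.OFFSETS_CUBE26, RenalSeg:::.OFFSETS_PLANE8))
    expect_equal(RenalSeg:::.neighborhoodMean(arr, off),
                 bruteNeighborhoodMean(arr, off), tolerance = 1e-12)
})

test_that("feature columns follow the local/cube26/plane8 contract", {
  d <- c(5, 5, 5)
  g <- unitGrid(d)
  # constant channel: all three statistics equal the constant
  vol <- IntensityVolume(array(7, d), g)
  pri <- ProbabilityMap(array(0.25, d), g)
  spa <- ProbabilityMap(array(0.75, d), g)
  ft <- extractFeatures(vol, pri, spa)
  expect_identical(colnames(ft),
                   c("app_local", "app_cube26", "app_plane8",
                     "shape_local", "shape_cube26", "shape_plane8",
                     "spatial_local", "spatial_cube26", "spatial_plane8"))
  expect_equal(nrow(ft), prod(d))
  expect_true(all(ft[, 1:3] == 7))
  expect_true(all(ft[, 4:6] == 0.25))
  expect_true(all(ft[, 7:9] == 0.75))

  # single interior spike of 27: a face neighbour's 26-cube mean is 27/26
  spike <- array(0, d); spike[3, 3, 3] <- 27
  ft2 <- extractFeatures(IntensityVolume(spike, g), pri, spa)
  arr <- array(ft2[, "app_cube26"], d)
  expect_equal(arr[2, 3, 3], 27 / 26)
  expect_equal(arr[3, 3, 3], 0)         # centre excluded

  # corner voxel averages its 3 existing in-plane neighbors
  corner <- array(0, d)
  corner[2, 1, 1] <- 3; corner[1, 2, 1] <- 6; corner[2, 2, 1] <- 12
  ft3 <- extractFeatures(IntensityVolume(corner, g), pri, spa)
  expect_equal(array(ft3[, "app_plane8"], d)[1, 1, 1], (3 + 6 + 12) / 3)

  # rows are the lexicographic (z, y, x) scan: x varies fastest
  probe <- array(seq_len(prod(d)), d)
  ft4 <- extractFeatures(IntensityVolume(probe, g), pri, spa)
  expect_identical(ft4[, "app_local"], as.numeric(seq_len(prod(d))))
})

test_that("appearance normalization is the min-max affine map", {
  d <- c(4, 4, 4)
  g <- unitGrid(d)
  vals <- array(seq(-100, 300, length.out = prod(d)), d)
  ft <- extractFeatures(IntensityVolume(vals, g),
                        ProbabilityMap(array(0.5, d), g),
                        ProbabilityMap(array(0.5, d), g))
  nt <- normalizeAppearance(ft)
  expect_equal(min(nt[, "app_local"]), 0)
  expect_equal(max(nt[, "app_local"]), 1)
  expect_equal(nt[which.min(abs(ft[, "app_local"] - 100)), "app_local"],
               (ft[which.min(abs(ft[, "app_local"] - 100)), "app_local"] +
                  100) / 400)
  expect_identical(nt[, "shape_local"], ft[, "shape_local"])
  # a column already spanning [0, 1] is unchanged
  ft01 <- ft
  ft01[, c("app_local", "app_cube26", "app_plane8")] <-
    (ft[, c("app_local", "app_cube26", "app_plane8")] + 100) / 400
  r <- range(ft01[, "app_local"])
  expect_equal(r, c(0, 1))
  expect_equal(normalizeAppearance(ft01)[, "app_local"],
               ft01[, "app_local"])
  # constant columns map to zeros with a warning
  ftc <- ft
  ftc[, "app_plane8"] <- 5
  expect_warning(out <- normalizeAppearance(ftc), "constant")
  expect_true(all(out[, "app_plane8"] == 0))
})

test_that("the forest separates separable data and is seed-reproducible", {
  set.seed(1)
  n <- 600
  y <- rep(c(1L, 0L), each = n / 2)
  x <- matrix(rnorm(9 * n), n, 9)
  x[, 1] <- x[, 1] + 4 * y            # linearly separable margin
  colnames(x) <- paste0("f", 1:9)
  fm <- trainForest(x, y, nTrees = 100, seed = 5)
  pred <- predictForest(fm, x, VoxelGrid(c(n, 1, 1), c(1, 1, 1)))
  acc <- mean((probKT(pred$probability) >= 0.5) == (y == 1L))
  expect_gte(acc, 0.99)

  fm2 <- trainForest(x, y, nTrees = 100, seed = 5)
  pred2 <- predictForest(fm2, x, VoxelGrid(c(n, 1, 1), c(1, 1, 1)))
  expect_identical(probKT(pred$probability), probKT(pred2$probability))

  # single tree is a valid degenerate forest
  fm1 <- trainForest(x, y, nTrees = 1, seed = 5)
  p1 <- predictForest(fm1, x, VoxelGrid(c(n, 1, 1), c(1, 1, 1)))
  expect_true(all(probKT(p1$probability) %in% c(0, 1)))

  expect_error(trainForest(x, rep(1L, n)), "both classes")
})

test_that("prediction enforces the vote-threshold label contract", {
  set.seed(2)
  n <- 200
  y <- rep(c(1L, 0L), each = n / 2)
  x <- matrix(rnorm(9 * n), n, 9)
  x[, 2] <- x[, 2] + 1.2 * y          # overlapping classes -> mixed votes
  colnames(x) <- paste0("f", 1:9)
  fm <- trainForest(x, y, nTrees = 51, seed = 9)
  pred <- predictForest(fm, x, VoxelGrid(c(n, 1, 1), c(1, 1, 1)))
  p <- probKT(pred$probability)
  expect_identical(labelArray(pred$labels), array(as.integer(p >= 0.5),
                                                  c(n, 1, 1)))
  expect_error(predictForest(fm, x[, 1:8], VoxelGrid(c(n, 1, 1))),
               "column-count")
})

test_that("median postprocessing smooths by cube majority", {
  d <- c(7, 7, 7)
  g <- unitGrid(d)
  const <- LabelMap(array(1L, d), g)
  expect_identical(labelArray(postprocessMedian(const)), labelArray(const))

  lone <- array(0L, d); lone[4, 4, 4] <- 1L
  out <- postprocessMedian(LabelMap(lone, g))
  expect_true(all(labelArray(out) == 0L))

  # decreasing churn: the second pass changes no more voxels than the first
  noisy <- smallCohort(2, 9, "hard")[[1]]@truth
  set.seed(8)
  arr <- labelArray(noisy)
  flips <- sample(length(arr), round(0.08 * length(arr)))
  arr[flips] <- 1L - arr[flips]
  nm <- LabelMap(arr, voxelGrid(noisy))
  once <- postprocessMedian(nm)
  twice <- postprocessMedian(once)
  ch1 <- sum(labelArray(once) != labelArray(nm))
  ch2 <- sum(labelArray(twice) != labelArray(once))
  expect_lte(ch2, ch1)
})
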