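test_that("clique families follow the 18-connectivity geometry", {
  fams <- buildCliqueFamilies()
  orders <- vapply(fams, function(f) f@order, integer(1))
  expect_identical(as.integer(table(orders)[c("2", "3", "4")]),
                   c(9L, 9L, 3L))
  is18 <- function(d) {
    s <- sum(abs(d))
    all(abs(d) <= 1) && s >= 1 && s <= 2
  }
  for (f in fams) {
    off <- f@offsets
    expect_identical(ncol(off), f@order)
    # every inter-voxel step within the clique is an 18-connectivity step
    for (i in seq_len(ncol(off) - 1))
      expect_true(is18(off[, i + 1] - off[, i]))
    if (f@order == 4L) expect_identical(ncol(off), 4L)
  }
})

test_that("equality rates match the closed forms and the enumeration oracle", {
  g <- unitGrid(c(8, 8, 8))
  fams <- buildCliqueFamilies()
  const <- LabelMap(array(1L, c(8, 8, 8)), g)
  for (f in fams) expect_equal(equalityRate(const, f), 1)

  idx <- expand.grid(x = 0:7, y = 0:7, z = 0:7)
  chk <- LabelMap(array(as.integer((idx$x + idx$y + idx$z) %% 2), c(8, 8, 8)),
                  g)
  # axis-aligned pairs always straddle the parity flip
  expect_equal(equalityRate(chk, fams[[1]]), 0)
  # oracle equivalence on a random map, all 21 families
  rl <- randomLabelMap(c(6, 6, 6), 3)
  for (f in fams)
    expect_equal(equalityRate(rl, f), bruteEqualityRate(labelArray(rl), f))
  expect_error(equalityRate(LabelMap(array(0L, c(1, 1, 1)),
                                     unitGrid(c(1, 1, 1))),
                            fams[[4]]), "degenerate")
})

test_that("analytic potentials hit their closed-form anchors", {
  g <- unitGrid(c(8, 8, 8))
  fams <- buildCliqueFamilies()
  const <- LabelMap(array(1L, c(8, 8, 8)), g)
  pm <- estimatePotentials(const, fams)
  # order-n family on a constant map: V = 4 (1 - 2^(1-n))
  expect_equal(unname(pm@potentials[1]), 2)          # pairwise
  expect_equal(unname(pm@potentials[10]), 3)         # triple
  expect_equal(unname(pm@potentials[19]), 3.5)       # quad
  idx <- expand.grid(x = 0:7, y = 0:7, z = 0:7)
  chk <- LabelMap(array(as.integer((idx$x + idx$y + idx$z) %% 2), c(8, 8, 8)),
                  g)
  expect_equal(unname(estimatePotentials(chk, fams)@potentials[1]), -2)
})

test_that("iid fair labels calibrate the potentials to zero", {
  iid <- randomLabelMap(c(32, 32, 32), 7)
  v <- estimatePotentials(iid)@potentials
  expect_lt(max(abs(v)), 0.05)
})

test_that("the intensity model pools per-label moments with a sd floor", {
  d <- c(8, 8, 8)
  set.seed(5)
  lab <- randomLabelMap(d, 5, pKT = 0.3)
  vals <- array(rnorm(prod(d), 20, 4), d)
  vals[labelArray(lab) == 1L] <- rnorm(sum(labelArray(lab)), 100, 9)
  e1 <- list(subjectId = "a", phase = "late",
             volume = IntensityVolume(vals, unitGrid(d)), labels = lab)
  m <- estimateIntensityModel(list(e1))
  expect_equal(m@means[["KT"]], 100, tolerance = 0.05)
  expect_equal(m@means[["OT"]], 20, tolerance = 0.05)
  expect_equal(m@sds[["KT"]], 9, tolerance = 0.2)

  # degenerate constant class: sd clamped, not zero
  constKT <- e1
  constKT$volume@values[labelArray(lab) == 1L] <- 100
  m2 <- estimateIntensityModel(list(constKT))
  expect_identical(m2@sds[["KT"]], 1e-3)

  # single-class atlas is an estimation error
  allOT <- list(subjectId = "b", phase = "late",
                volume = IntensityVolume(vals, unitGrid(d)),
                labels = LabelMap(array(0L, d), unitGrid(d)))
  expect_error(estimateIntensityModel(list(allOT)), "absent")
})

test_that("initial labeling combines prior and likelihood as specified", {
  d <- c(4, 4, 4)
  vol <- IntensityVolume(array(c(100, 20), d), unitGrid(d))
  model <- new("IntensityClassModel", means = c(KT = 100, OT = 20),
               sds = c(KT = 10, OT = 10))
  # prior mass 1 on KT forces KT regardless of intensity
  one <- ProbabilityMap(array(1, d), unitGrid(d))
  expect_true(all(labelArray(initialLabeling(vol, one, model)) == 1L))
  # flat prior reduces to the likelihood-ratio classifier
  half <- ProbabilityMap(array(0.5, d), unitGrid(d))
  lab <- initialLabeling(vol, half, model)
  expect_identical(labelArray(lab),
                   array(as.integer(intensities(vol) > 60), d))
  # exact ties go to OT
  tieVol <- IntensityVolume(array(60, d), unitGrid(d))
  expect_true(all(labelArray(initialLabeling(tieVol, half, model)) == 0L))
})

test_that("Gibbs conditionals are symmetric, normalized and energy-ordered", {
  g <- unitGrid(c(5, 5, 5))
  fams <- buildCliqueFamilies()
  m <- randomLabelMap(c(5, 5, 5), 11)
  zero <- new("PottsModel", families = fams,
              potentials = setNames(rep(0, 21),
                                    vapply(fams, function(f) f@name,
                                           character(1))))
  expect_true(all(probKT(gibbsProbability(m, zero)) == 0.5))

  const <- LabelMap(array(1L, c(5, 5, 5)), g)
  pmConst <- estimatePotentials(const, fams)
  pg <- gibbsProbability(const, pmConst)
  expect_gt(probKT(pg)[3, 3, 3], 0.5)
})

test_that("Gibbs conditionals match brute-force clique enumeration", {
  set.seed(13)
  for (seed in c(2, 8)) {
    m <- randomLabelMap(c(5, 5, 5), seed)
    fams <- buildCliqueFamilies()
    pm <- new("PottsModel", families = fams,
              potentials = setNames(runif(21, -1, 1),
                                    vapply(fams, function(f) f@name,
                                           character(1))))
    expect_equal(probKT(gibbsProbability(m, pm)),
                 bruteGibbs(labelArray(m), pm), tolerance = 1e-12)
  }
})

test_that("relabeling KT and OT leaves the spatial model invariant", {
  m <- randomLabelMap(c(8, 8, 8), 17)
  flip <- LabelMap(1L - labelArray(m), voxelGrid(m))
  fams <- buildCliqueFamilies()
  for (f in fams[c(1, 5, 12, 20)])
    expect_equal(equalityRate(m, f), equalityRate(flip, f))
  pm <- estimatePotentials(m)
  pmF <- estimatePotentials(flip)
  expect_equal(pm@potentials, pmF@potentials)
  # P(assigned label) is preserved under the flip
  pKT <- probKT(gibbsProbability(m, pm))
  pKTF <- probKT(gibbsProbability(flip, pmF))
  expect_equal(pKT, 1 - pKTF, tolerance = 1e-12)
})
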