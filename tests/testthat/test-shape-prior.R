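test_that("ncc has the Pearson normalization properties", {
  v <- randomVolume(c(6, 6, 6), 1)
  expect_equal(ncc(v, v), 1)
  neg <- IntensityVolume(-intensities(v), voxelGrid(v))
  expect_equal(ncc(v, neg), -1)
  shifted <- IntensityVolume(intensities(v) + 10, voxelGrid(v))
  expect_equal(ncc(v, shifted), 1)      # mean-invariance
  scaled <- IntensityVolume(3 * intensities(v) - 7, voxelGrid(v))
  expect_equal(ncc(v, scaled), 1)
  const <- IntensityVolume(array(5, c(6, 6, 6)), voxelGrid(v))
  expect_error(ncc(v, const), "variance")
  other <- randomVolume(c(6, 6, 6), 2)
  expect_equal(ncc(v, other),
               cor(as.vector(intensities(v)), as.vector(intensities(other))))
})

test_that("selectTop ranks by NCC with deterministic exclusion and errors", {
  cohort <- smallCohort(3, 9)
  db <- nativeAtlas(cohort)
  test <- cohort[[1]]@records[[2]]@volume

  # the identical entry ranks first
  sel <- selectTop(test, db, 3)
  expect_identical(sel[[1]]$subjectId, "S01")
  expect_identical(sel[[1]]$phase, "postcontrast")
  expect_equal(sel[[1]]$ncc, 1)

  # exhaustive selection returns everything, sorted descending
  all9 <- selectTop(test, db, length(db@entries))
  sc <- vapply(all9, function(e) e$ncc, numeric(1))
  expect_identical(sc, sort(sc, decreasing = TRUE))

  # excluding the test subject removes its three scans
  sel2 <- selectTop(test, db, 6, excludeSubject = "S01")
  expect_false(any(vapply(sel2, function(e) e$subjectId, character(1)) ==
                   "S01"))
  expect_error(selectTop(test, db, 7, excludeSubject = "S01"),
               "cohort-size")
})

test_that("a leave-one-out selection over 20 subjects keeps 19 of 57 scans", {
  # structure-only mirror of the clinical protocol: 60 scans, minus the
  # test subject's 3, leaves 57 candidates of which the top 19 are kept
  ids <- sprintf("S%02d", 1:20)
  entries <- list()
  set.seed(1)
  for (sid in ids) for (ph in c("noncontrast", "postcontrast", "late"))
    entries[[length(entries) + 1L]] <- list(
      subjectId = sid, phase = ph,
      volume = randomVolume(c(4, 4, 4), length(entries) + 1),
      labels = randomLabelMap(c(4, 4, 4), length(entries) + 1))
  db <- AtlasDatabase(entries, referenceId = "S01_postcontrast")
  expect_length(db@entries, 60)
  test <- randomVolume(c(4, 4, 4), 999)
  kept <- Filter(function(e) e$subjectId != "S05", db@entries)
  expect_length(kept, 57)
  sel <- selectTop(test, db, 19, excludeSubject = "S05")
  expect_length(sel, 19)
  expect_false(any(vapply(sel, function(e) e$subjectId, character(1)) ==
                   "S05"))
})

test_that("the prior equals the enumerated match fraction on a crafted case", {
  # single atlas image; at the centre voxel the 3x3x3 cube holds exactly 4
  # intensity matches, 3 of them kidney -> P(KT) = 0.75
  d <- c(5, 5, 5)
  test <- array(1000, d)        # far from every atlas voxel except matches
  g <- array(0, d)
  m <- array(0L, d)
  g[3, 3, 3] <- 1000; m[3, 3, 3] <- 1L
  g[2, 3, 3] <- 1010; m[2, 3, 3] <- 1L
  g[4, 3, 3] <- 990;  m[4, 3, 3] <- 1L
  g[3, 2, 3] <- 1040; m[3, 2, 3] <- 0L
  entry <- list(subjectId = "a", phase = "late",
                volume = IntensityVolume(g, unitGrid(d)),
                labels = LabelMap(m, unitGrid(d)))
  prior <- computeShapePrior(IntensityVolume(test, unitGrid(d)), list(entry),
                             shapePriorParams(tau = 50, hwInit = 1, hwMax = 1))
  expect_equal(probKT(prior)[3, 3, 3], 0.75)
})

test_that("all-background matches give 0 and empty matches fall back to 0.5", {
  d <- c(4, 4, 4)
  test <- IntensityVolume(array(100, d), unitGrid(d))
  gOT <- IntensityVolume(array(100, d), unitGrid(d))
  mOT <- LabelMap(array(0L, d), unitGrid(d))
  entry <- list(subjectId = "a", phase = "late", volume = gOT, labels = mOT)
  prior <- computeShapePrior(test, list(entry), shapePriorParams(10, 1, 2))
  expect_true(all(probKT(prior) == 0))

  # no atlas voxel within tau even at the maximum cube: fallback 0.5
  far <- IntensityVolume(array(10000, d), unitGrid(d))
  prior2 <- computeShapePrior(far, list(entry), shapePriorParams(10, 1, 2))
  expect_true(all(probKT(prior2) == 0.5))
  expect_error(computeShapePrior(test, list()), "non-empty")
})

test_that("P(KT) and P(OT) always sum to one", {
  cohort <- smallCohort(3, 9)
  db <- nativeAtlas(cohort, excludeSubject = "S01")
  sel <- selectTop(cohort[[1]]@records[[2]]@volume, db, 6)
  prior <- computeShapePrior(cohort[[1]]@records[[2]]@volume, sel)
  p <- probKT(prior)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(p + (1 - p), array(1, dim(p)))
})

test_that("consensus atlases give a confident prior inside the kidney", {
  # noise-free phantoms with identical anatomy: the prior is 1 strictly
  # inside the consensus kidney and 0 far outside
  spec <- smallSpec(noiseSd = 0, biasAmplitude = 0, nDistractors = 0,
                    deformMm = 0)
  subj <- generateSubject(spec, 5)
  entries <- lapply(subj@records, function(r)
    list(subjectId = "S", phase = r@phase, volume = r@volume,
         labels = r@truth))
  test <- subj@records[[2]]@volume
  prior <- computeShapePrior(test, entries, shapePriorParams(5, 1, 2))
  p <- probKT(prior)
  lab <- labelArray(subj@truth)
  inner <- RenalSeg:::.neighborhoodMean(lab, RenalSeg:::.OFFSETS_CUBE26) == 1 &
    lab == 1L
  expect_true(all(p[inner] == 1))
  farOut <- RenalSeg:::.neighborhoodMean(lab, RenalSeg:::.OFFSETS_CUBE26) == 0 &
    lab == 0L
  expect_true(all(p[farOut & p != 0.5] == 0))
})
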