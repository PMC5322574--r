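## End-to-end segmentation: co-alignment into atlas space, NCC atlas
## selection, shape prior, MGRF spatial probabilities, 9-feature extraction,
## per-fold random-forest training, prediction, median postprocessing, and
## inverse mapping of the result onto the scan's native grid -- plus the
## leave-one-subject-out (LOSO) evaluation protocol.

#' PipelineConfig: tunable parameters of the segmentation pipeline
#'
#' @slot nAtlas number of NCC-top-ranked atlas scans (protocol value 19;
#'   must not exceed the scans available after excluding the test subject).
#' @slot nTrees random-forest size (protocol value 400).
#' @slot tau shape-prior intensity-similarity threshold.
#' @slot hwInit,hwMax shape-prior search-cube half-widths, voxels.
#' @slot medianRadius 3D median postprocessing radius.
#' @slot trainCapPerClass stratified per-scan training cap (kidney rows up
#'   to the cap plus an equal background sample); keeps desk-scale runs
#'   tractable.
#' @slot useBspline add the B-spline step after the affine alignment.
#' @slot ctrlSpacing B-spline control-point spacing, voxels.
#' @slot seed master seed for training and any subsampling.
#' @export
setClass("PipelineConfig",
  representation(nAtlas = "integer", nTrees = "integer", tau = "numeric",
                 hwInit = "integer", hwMax = "integer",
                 medianRadius = "integer", trainCapPerClass = "integer",
                 useBspline = "logical", ctrlSpacing = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (object@nAtlas < 1L) return("nAtlas must be >= 1")
    if (object@nTrees < 1L) return("nTrees must be >= 1")
    if (object@tau < 0) return("tau must be >= 0")
    if (object@hwInit < 1L || object@hwMax < object@hwInit)
      return("need 1 <= hwInit <= hwMax")
    TRUE
  })

#' @rdname PipelineConfig-class
#' @param nAtlas,nTrees,tau,hwInit,hwMax,medianRadius,trainCapPerClass
#'   see slots.
#' @param useBspline,ctrlSpacing,seed see slots.
#' @export
pipelineConfig <- function(nAtlas = 19L, nTrees = 400L, tau = 50,
                           hwInit = 1L, hwMax = 5L, medianRadius = 1L,
                           trainCapPerClass = 1500L, useBspline = TRUE,
                           ctrlSpacing = 8, seed = 1L) {
  new("PipelineConfig", nAtlas = as.integer(nAtlas),
      nTrees = as.integer(nTrees), tau = as.numeric(tau),
      hwInit = as.integer(hwInit), hwMax = as.integer(hwMax),
      medianRadius = as.integer(medianRadius),
      trainCapPerClass = as.integer(trainCapPerClass),
      useBspline = isTRUE(useBspline), ctrlSpacing = as.numeric(ctrlSpacing),
      seed = as.integer(seed))
}

.scanId <- function(rec) paste(rec@subjectId, rec@phase, sep = "_")

## Cached two-step registration of `moving` onto `reference`; `cache` is an
## environment keyed by (reference id, moving id) shared across LOSO folds.
.registerCached <- function(refId, refVol, rec, config, cache) {
  key <- paste(refId, .scanId(rec), sep = "|")
  if (!is.null(cache[[key]])) return(cache[[key]])
  res <- registerTwoStep(refVol, rec@volume, bspline = config@useBspline,
                         ctrlSpacing = config@ctrlSpacing)
  cache[[key]] <- res
  res
}

#' Build a co-aligned atlas database from subject records
#'
#' Registers every record onto the reference scan (the two-step affine +
#' B-spline method) and propagates each ground-truth label map with
#' nearest-neighbour resampling. The reference anchors the common atlas
#' space.
#'
#' @param records list of \linkS4class{SubjectRecord}s with truth.
#' @param reference the reference \linkS4class{SubjectRecord}.
#' @param config a \linkS4class{PipelineConfig}.
#' @param cache optional environment memoising registrations across calls.
#' @return An \linkS4class{AtlasDatabase}.
#' @export
buildAtlas <- function(records, reference, config = pipelineConfig(),
                       cache = new.env(parent = emptyenv())) {
  refVol <- reference@volume
  refId <- .scanId(reference)
  entries <- lapply(records, function(rec) {
    if (is.null(rec@truth))
      stop("atlas records require ground-truth label maps", call. = FALSE)
    if (.scanId(rec) == refId) {
      alignedV <- rec@volume
      alignedL <- rec@truth
    } else {
      reg <- .registerCached(refId, refVol, rec, config, cache)
      alignedV <- reg$aligned
      alignedL <- applyTransform(rec@truth, reg$chain, refVol@grid,
                                 mode = "nearest")
    }
    list(subjectId = rec@subjectId, phase = rec@phase,
         volume = alignedV, labels = alignedL)
  })
  AtlasDatabase(entries, grid = refVol@grid, reference = refVol,
                referenceId = refId)
}

## Shape prior + spatial probability + normalized features for one atlas-space
## volume against a selected entry set.
.volumeFeatures <- function(vol, selected, config, intensityModel) {
  prior <- computeShapePrior(vol, selected,
                             shapePriorParams(config@tau, config@hwInit,
                                              config@hwMax))
  spat <- spatialProbability(vol, prior, intensityModel)
  list(table = normalizeAppearance(extractFeatures(vol, prior, spat$prob)),
       prior = prior, spatial = spat$prob)
}

#' Segment one CT volume with the full pipeline
#'
#' Executes the four pipeline steps: (1) two-step registration of the test
#' volume into atlas space and NCC top-N atlas selection; (2) shape-prior,
#' spatial (MGRF) and appearance feature extraction; (3) random-forest
#' training on the selected atlas scans (each training scan's shape prior
#' is computed against the selected entries of the other subjects,
#' mirroring the leave-one-subject-out condition of the test scan); (4)
#' prediction, 0.5-vote thresholding and 3D median postprocessing. Label
#' and probability maps are mapped back to the test scan's native grid via
#' the inverse alignment.
#'
#' @param test the native-space test \linkS4class{IntensityVolume}.
#' @param atlas an \linkS4class{AtlasDatabase} that must not contain any
#'   scan of the test subject.
#' @param config a \linkS4class{PipelineConfig}.
#' @param cache optional registration cache environment.
#' @param trainMemo optional environment memoising per-scan training
#'   features within one fold.
#' @param testId id string used only for cache keys and logging.
#' @return List with \code{labels} (\linkS4class{LabelMap}),
#'   \code{probability} (\linkS4class{ProbabilityMap}) -- both on the
#'   native grid -- their atlas-space counterparts, the transform
#'   \code{chain}, and a \code{provenance} record of every scan id used.
#' @export
segmentVolume <- function(test, atlas, config = pipelineConfig(),
                          cache = new.env(parent = emptyenv()),
                          trainMemo = new.env(parent = emptyenv()),
                          testId = "test") {
  t0 <- proc.time()[["elapsed"]]
  if (length(atlas@entries) < config@nAtlas)
    stop(sprintf(paste0("cohort-size error: nAtlas = %d exceeds the %d ",
                        "available atlas scans"),
                 config@nAtlas, length(atlas@entries)), call. = FALSE)
  refVol <- atlas@reference
  ## Step 1: co-alignment + NCC selection (phase tag on the wrapper record
  ## is irrelevant for registration; only the id keys the cache)
  reg <- .registerCached(atlas@referenceId, refVol,
                         SubjectRecord(testId, "postcontrast", test),
                         config, cache)
  aligned <- reg$aligned
  selected <- selectTop(aligned, atlas, config@nAtlas)
  selIds <- vapply(selected, function(e)
    paste(e$subjectId, e$phase, sep = "_"), character(1))
  ## Step 2: features of the test volume
  intensityModel <- estimateIntensityModel(selected)
  testFeat <- .volumeFeatures(aligned, selected, config, intensityModel)
  ## Step 3: RF training on the selected scans
  tables <- vector("list", length(selected))
  truths <- vector("list", length(selected))
  keys <- character(length(selected))
  for (i in seq_along(selected)) {
    e <- selected[[i]]
    eid <- paste(e$subjectId, e$phase, sep = "_")
    others <- Filter(function(x) x$subjectId != e$subjectId, selected)
    if (length(others) == 0L) others <- selected  # single-subject atlas
    key <- paste(eid, paste(sort(vapply(others, function(x)
      paste(x$subjectId, x$phase, sep = "_"), character(1))),
      collapse = ","), sep = "#")
    if (is.null(trainMemo[[key]])) {
      trainMemo[[key]] <- .volumeFeatures(e$volume, others, config,
                                          intensityModel)$table
    }
    tables[[i]] <- trainMemo[[key]]
    truths[[i]] <- e$labels
    keys[i] <- key
  }
  ## identical training sets within a fold (same selection, same seed)
  ## yield the same forest; memoise it alongside the feature tables
  forestKey <- paste("forest", paste(keys, collapse = ";"),
                     config@nTrees, config@seed, sep = "|")
  if (is.null(trainMemo[[forestKey]])) {
    trainMemo[[forestKey]] <- trainForest(
      tables, truths, nTrees = config@nTrees, seed = config@seed,
      capPerClass = config@trainCapPerClass)
  }
  forest <- trainMemo[[forestKey]]
  ## Step 4: prediction + postprocessing + inverse mapping
  pred <- predictForest(forest, testFeat$table, atlas@grid)
  smoothed <- postprocessMedian(pred$labels, config@medianRadius)
  ## one chain inversion serves both outputs
  invVox <- .physToVoxel(
    .invertChainCoords(reg$chain, .gridCoords(test@grid), atlas@grid),
    atlas@grid)
  nativeLabels <- .mapBackToNative(smoothed, reg$chain, test@grid,
                                   atlas@grid, vox = invVox)
  nativeProb <- .mapBackToNative(pred$probability, reg$chain, test@grid,
                                 atlas@grid, vox = invVox)
  logInfo("segmentVolume[%s]: grid %s, %d atlas scans, %.1fs", testId,
          paste(test@grid@dims, collapse = "x"), length(selected),
          proc.time()[["elapsed"]] - t0)
  list(labels = nativeLabels, probability = nativeProb,
       atlasLabels = smoothed, atlasProbability = pred$probability,
       chain = reg$chain,
       provenance = list(selected = selIds,
                         atlasSubjects = unique(vapply(atlas@entries,
                           function(e) e$subjectId, character(1))),
                         testId = testId))
}

#' LosoResult: leave-one-subject-out evaluation summary
#'
#' @slot perScan data.frame with one row per scan (subject, phase, dc, pvd,
#'   pvdAbs, bhd95, auc).
#' @slot perSubject per-subject means of the same metrics.
#' @slot summary named list of cohort mean and sd per metric plus the
#'   pooled AUC.
#' @slot reports list of \linkS4class{EvalReport} keyed "subject_phase".
#' @export
setClass("LosoResult",
  representation(perScan = "data.frame", perSubject = "data.frame",
                 summary = "list", reports = "list"))

setMethod("show", "LosoResult", function(object) {
  s <- object@summary
  cat(sprintf("LOSO over %d scans (%d subjects)\n", nrow(object@perScan),
              nrow(object@perSubject)))
  cat(sprintf("  DC    %.2f +/- %.2f %%\n", s$dc_mean, s$dc_sd))
  cat(sprintf("  |PVD| %.2f +/- %.2f %%\n", s$pvd_mean, s$pvd_sd))
  cat(sprintf("  BHD95 %.3f +/- %.3f mm\n", s$bhd95_mean, s$bhd95_sd))
  cat(sprintf("  pooled AUC %.4f\n", s$auc_pooled))
})

#' Leave-one-subject-out evaluation of a phantom cohort
#'
#' For each subject in turn, every scan of that subject is withheld from
#' the atlas (and hence from selection, the shape prior, the intensity
#' model and forest training), the remaining scans form the fold's
#' co-aligned atlas anchored on the first training subject's postcontrast
#' scan, and each withheld scan is segmented and scored against the
#' subject's ground truth on its native grid. Registrations are cached
#' across folds.
#'
#' @param cohort list of \linkS4class{PhantomSubject}.
#' @param config a \linkS4class{PipelineConfig}; \code{nAtlas} must not
#'   exceed \code{3 * (nSubjects - 1)}.
#' @return A \linkS4class{LosoResult}.
#' @export
losoEvaluate <- function(cohort, config = pipelineConfig()) {
  if (length(cohort) < 2L)
    stop("LOSO needs at least 2 subjects", call. = FALSE)
  if (3L * (length(cohort) - 1L) < config@nAtlas)
    stop(sprintf("cohort too small: nAtlas = %d but only %d scans remain ",
                 config@nAtlas, 3L * (length(cohort) - 1L)), call. = FALSE)
  cache <- new.env(parent = emptyenv())
  reports <- list()
  rows <- list()
  pooledY <- list()
  pooledP <- list()
  for (si in seq_along(cohort)) {
    testSubj <- cohort[[si]]
    others <- cohort[-si]
    trainRecs <- cohortRecords(others)
    reference <- Filter(function(r) r@phase == "postcontrast",
                        others[[1]]@records)[[1]]
    atlas <- buildAtlas(trainRecs, reference, config, cache)
    trainMemo <- new.env(parent = emptyenv())
    for (rec in testSubj@records) {
      id <- .scanId(rec)
      seg <- segmentVolume(rec@volume, atlas, config, cache = cache,
                           trainMemo = trainMemo, testId = id)
      stopifnot(!testSubj@subjectId %in% seg$provenance$atlasSubjects)
      rep <- evaluateSegmentation(rec@truth, seg$labels, seg$probability)
      reports[[id]] <- rep
      rows[[id]] <- data.frame(subject = rec@subjectId, phase = rec@phase,
                               dc = rep@dc, pvd = rep@pvd,
                               pvdAbs = rep@pvdAbs, bhd95 = rep@bhd95,
                               auc = rep@auc)
      pooledY[[id]] <- as.vector(rec@truth@labels)
      pooledP[[id]] <- as.vector(seg$probability@p)
    }
  }
  perScan <- do.call(rbind, rows)
  rownames(perScan) <- NULL
  pooled <- rocAuc(unlist(pooledY), unlist(pooledP))
  perSubject <- aggregate(perScan[, c("dc", "pvdAbs", "bhd95", "auc")],
                          by = list(subject = perScan$subject), FUN = mean)
  summary <- list(dc_mean = mean(perScan$dc), dc_sd = sd(perScan$dc),
                  pvd_mean = mean(perScan$pvdAbs), pvd_sd = sd(perScan$pvdAbs),
                  bhd95_mean = mean(perScan$bhd95),
                  bhd95_sd = sd(perScan$bhd95),
                  auc_mean = mean(perScan$auc), auc_pooled = pooled$auc)
  new("LosoResult", perScan = perScan, perSubject = perSubject,
      summary = summary, reports = reports)
}

#' Serialize a LosoResult (JSON summary + per-scan CSV)
#'
#' @param result a \linkS4class{LosoResult}.
#' @param jsonPath summary JSON path (NULL to skip).
#' @param csvPath flat per-scan CSV path (NULL to skip).
#' @return Invisibly, the list of written paths.
#' @export
writeLosoResult <- function(result, jsonPath = NULL, csvPath = NULL) {
  if (!is.null(jsonPath))
    jsonlite::write_json(c(result@summary,
                           list(perSubject = result@perSubject)),
                         jsonPath, auto_unbox = TRUE, digits = NA)
  if (!is.null(csvPath))
    utils::write.csv(result@perScan, csvPath, row.names = FALSE)
  invisible(list(json = jsonPath, csv = csvPath))
}
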