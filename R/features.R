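## The 9-feature voxel descriptor and the random-forest classifier. Each of
## the three channels -- appearance (Hounsfield-like intensity), shape prior
## and spatial (Gibbs) probability -- contributes its local value, the mean
## over the 26-neighbor cube and the mean over the 8 in-plane neighbors
## (centre excluded; border voxels use the neighbors that exist). Appearance
## columns are min-max normalized to [0, 1] so no channel dominates the
## probabilistic ones.

.OFFSETS_CUBE26 <- {
  o <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  t(o[rowSums(abs(o)) > 0, , drop = FALSE])
}
.OFFSETS_PLANE8 <- {
  o <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = 0))
  t(o[rowSums(abs(o[, 1:2])) > 0, , drop = FALSE])
}

## Shared neighborhood engine: mean of `arr` over the given offsets, border
## voxels averaging over the neighbors that exist.
.neighborhoodMean <- function(arr, offsets) {
  s <- array(0, dim(arr))
  cnt <- array(0L, dim(arr))
  for (j in seq_len(ncol(offsets))) {
    aj <- shiftArray(arr, offsets[, j], fill = NA)
    ok <- !is.na(aj)
    aj[!ok] <- 0
    s <- s + aj
    cnt <- cnt + ok
  }
  s / pmax(cnt, 1L)
}

.channelFeatures <- function(arr, prefix) {
  out <- cbind(as.vector(arr),
               as.vector(.neighborhoodMean(arr, .OFFSETS_CUBE26)),
               as.vector(.neighborhoodMean(arr, .OFFSETS_PLANE8)))
  colnames(out) <- paste0(prefix, c("_local", "_cube26", "_plane8"))
  out
}

#' Extract the 9-feature voxel descriptor table
#'
#' One row per voxel in lexicographic (z, y, x) scan order (x fastest, the
#' native array order), 9 columns: local / 26-neighbor cube mean / 8
#' in-plane neighbor mean for each of the appearance, shape and spatial
#' channels.
#'
#' @param volume \linkS4class{IntensityVolume} (appearance channel).
#' @param prior shape-prior \linkS4class{ProbabilityMap}.
#' @param spatial Gibbs \linkS4class{ProbabilityMap}.
#' @return Numeric matrix (nVoxels x 9).
#' @export
extractFeatures <- function(volume, prior, spatial) {
  stopGridsCompatible(volume@grid, prior@grid, "volume and prior")
  stopGridsCompatible(volume@grid, spatial@grid, "volume and spatial")
  cbind(.channelFeatures(volume@values, "app"),
        .channelFeatures(prior@p, "shape"),
        .channelFeatures(spatial@p, "spatial"))
}

#' Min-max normalize the appearance columns
#'
#' Rescales the three appearance columns to [0, 1] per volume; shape and
#' spatial columns are already probabilities and are left untouched. A
#' constant appearance column maps to all zeros with a warning.
#'
#' @param table feature matrix from \code{\link{extractFeatures}}.
#' @return The table with normalized appearance columns.
#' @export
normalizeAppearance <- function(table) {
  for (cn in c("app_local", "app_cube26", "app_plane8")) {
    x <- table[, cn]
    r <- range(x)
    if (r[1] == r[2]) {
      warning(sprintf("constant appearance column '%s' mapped to zeros", cn))
      table[, cn] <- 0
    } else {
      table[, cn] <- (x - r[1]) / (r[2] - r[1])
    }
  }
  table
}

#' Train the random-forest voxel classifier
#'
#' Bagged forest of decision trees with per-node random feature subsetting
#' (features-per-split = 3 = sqrt(9)); a fixed seed makes training and
#' prediction reproducible. Both classes must be present in the pooled
#' training rows.
#'
#' @param tables list of feature matrices (or a single matrix).
#' @param truths list of \linkS4class{LabelMap}s paired with \code{tables},
#'   or a vector/list of 0/1 labels per row.
#' @param nTrees number of trees (the protocol value is 400).
#' @param seed training seed.
#' @param capPerClass optional per-table stratified cap: at most this many
#'   KT and this many OT rows are sampled from each table (NULL = all rows).
#' @return A \linkS4class{ForestModel}.
#' @export
trainForest <- function(tables, truths, nTrees = 400L, seed = 1L,
                        capPerClass = NULL) {
  if (is.matrix(tables)) tables <- list(tables)
  if (!is.list(truths)) truths <- list(truths)
  xs <- vector("list", length(tables))
  ys <- vector("list", length(tables))
  for (i in seq_along(tables)) {
    y <- truths[[i]]
    y <- if (is(y, "LabelMap")) as.vector(y@labels) else as.vector(y)
    stopifnot(length(y) == nrow(tables[[i]]))
    if (!is.null(capPerClass)) {
      idx <- withLocalSeed(seed + i, .stratifiedIndices(y, capPerClass))
      xs[[i]] <- tables[[i]][idx, , drop = FALSE]
      ys[[i]] <- y[idx]
    } else {
      xs[[i]] <- tables[[i]]
      ys[[i]] <- y
    }
  }
  x <- do.call(rbind, xs)
  y <- factor(ifelse(unlist(ys) == 1L, "KT", "OT"), levels = c("KT", "OT"))
  if (length(unique(y)) < 2L)
    stop("training error: both classes (KT, OT) must be present",
         call. = FALSE)
  fit <- ranger::ranger(x = x, y = y, num.trees = nTrees, mtry = 3L,
                        seed = as.integer(seed), num.threads = 1L,
                        classification = TRUE)
  new("ForestModel", fit = fit, nTrees = as.integer(nTrees),
      seed = as.integer(seed))
}

## Stratified per-class subsampling: all kidney rows up to the cap plus an
## equal-sized background sample (keeps training at desk scale).
.stratifiedIndices <- function(y, capPerClass) {
  iKT <- which(y == 1L)
  iOT <- which(y == 0L)
  if (length(iKT) > capPerClass) iKT <- sample(iKT, capPerClass)
  nOT <- min(length(iOT), max(capPerClass, length(iKT)))
  if (length(iOT) > nOT) iOT <- sample(iOT, nOT)
  sort(c(iKT, iOT))
}

#' Predict kidney probability and labels with a trained forest
#'
#' The probability at each voxel is the fraction of tree votes for KT
#' (majority voting); the label is KT iff that fraction is >= 0.5, so a
#' 50/50 tie labels KT and thresholding the probability map at 0.5
#' reproduces the label map exactly.
#'
#' @param model a \linkS4class{ForestModel}.
#' @param table feature matrix with the 9 descriptor columns.
#' @param grid \linkS4class{VoxelGrid} the rows came from.
#' @param chunkSize rows per prediction block (memory guard).
#' @return List with \code{probability} (\linkS4class{ProbabilityMap}) and
#'   \code{labels} (\linkS4class{LabelMap}).
#' @export
predictForest <- function(model, table, grid, chunkSize = 65536L) {
  if (ncol(table) != 9L)
    stop(sprintf("column-count mismatch: expected 9 features, got %d",
                 ncol(table)), call. = FALSE)
  n <- nrow(table)
  prob <- numeric(n)
  ktCode <- which(model@fit$forest$levels == "KT")
  start <- 1L
  while (start <= n) {
    end <- min(start + chunkSize - 1L, n)
    pr <- stats::predict(model@fit, data = table[start:end, , drop = FALSE],
                         predict.all = TRUE, num.threads = 1L)$predictions
    ## per-tree class indices; vote fraction for class "KT"
    prob[start:end] <- rowMeans(pr == ktCode)
    start <- end + 1L
  }
  probMap <- ProbabilityMap(array(prob, grid@dims), grid)
  labMap <- LabelMap(array(as.integer(prob >= 0.5), grid@dims), grid)
  list(probability = probMap, labels = labMap)
}

#' 3D median (majority) label smoothing
#'
#' Replaces each voxel's label by the majority label within the
#' (2r + 1)^3 cube clipped to the volume (centre included). For the binary
#' label set this is exactly the 3D median filter; ties go to OT.
#'
#' @param labels a \linkS4class{LabelMap}.
#' @param radius cube radius r >= 1 (default 1, i.e. 3x3x3).
#' @return Smoothed \linkS4class{LabelMap}.
#' @export
postprocessMedian <- function(labels, radius = 1L) {
  stopifnot(radius >= 1L)
  off <- as.matrix(expand.grid(x = -radius:radius, y = -radius:radius,
                               z = -radius:radius))
  s <- array(0, dim(labels@labels))
  cnt <- array(0L, dim(labels@labels))
  for (j in seq_len(nrow(off))) {
    aj <- shiftArray(labels@labels, off[j, ], fill = NA)
    ok <- !is.na(aj)
    aj[!ok] <- 0L
    s <- s + aj
    cnt <- cnt + ok
  }
  LabelMap(array(as.integer(s * 2L > cnt), dim(labels@labels)), labels@grid)
}
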