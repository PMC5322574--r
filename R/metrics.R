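## Segmentation evaluation: confusion-subset volumetrics (Dice coefficient,
## percentage volume difference), the bidirectional 95th-percentile
## Hausdorff distance between surface-voxel sets in physical millimetres,
## and ROC/AUC from probability maps.

#' Voxel confusion counts between truth and segmentation
#'
#' Counts the true-positive, false-positive, false-negative and
#' true-negative voxels of the kidney sets G (truth) and S (segmentation):
#' \code{c_tp = |G intersect S|}, \code{c_fp = |S \\ G|},
#' \code{c_fn = |G \\ S|}.
#'
#' @param truth,seg \linkS4class{LabelMap}s on compatible grids.
#' @return Named list (tp, fp, fn, tn).
#' @export
confusionCounts <- function(truth, seg) {
  stopGridsCompatible(truth@grid, seg@grid, "truth and segmentation")
  g <- truth@labels == 1L
  s <- seg@labels == 1L
  list(tp = sum(g & s), fp = sum(!g & s), fn = sum(g & !s),
       tn = sum(!g & !s))
}

#' Dice coefficient (percent)
#'
#' \code{DC = 100 * 2 c_tp / (2 c_tp + c_fp + c_fn)}; 100 for identical
#' non-empty sets, 0 for disjoint ones. Undefined (an error) when both sets
#' are empty.
#'
#' @param c confusion counts from \code{\link{confusionCounts}}.
#' @return Percentage in [0, 100].
#' @export
dice <- function(c) {
  den <- 2 * c$tp + c$fp + c$fn
  if (den == 0)
    stop("Dice undefined: both the truth and the segmentation are empty",
         call. = FALSE)
  100 * 2 * c$tp / den
}

#' Percentage volume difference
#'
#' Signed \code{PVD = 100 (|G| - |S|) / |G|}; positive when the
#' segmentation under-covers the truth. The absolute value is reported
#' alongside. Requires a non-empty ground truth.
#'
#' @param c confusion counts.
#' @return Named list (signed, abs).
#' @export
pvd <- function(c) {
  nG <- c$tp + c$fn
  if (nG == 0)
    stop("PVD undefined: empty ground truth", call. = FALSE)
  v <- 100 * (nG - (c$tp + c$fp)) / nG
  list(signed = v, abs = abs(v))
}

#' Surface voxels of the kidney set
#'
#' KT voxels with at least one of their 6 face-neighbors labelled OT or
#' lying outside the volume.
#'
#' @param m a \linkS4class{LabelMap} with at least one KT voxel.
#' @return Integer matrix (n x 3) of 0-based voxel coordinates.
#' @export
surfaceVoxels <- function(m) {
  lab <- m@labels
  if (sum(lab) == 0L)
    stop("empty KT set: no surface exists", call. = FALSE)
  boundary <- array(FALSE, dim(lab))
  for (k in 1:3) for (sgn in c(1L, -1L)) {
    d <- integer(3); d[k] <- sgn
    nb <- shiftArray(lab, d, fill = 0L)
    boundary <- boundary | (nb == 0L)
  }
  idx <- which(lab == 1L & boundary, arr.ind = TRUE)
  colnames(idx) <- c("x", "y", "z")
  idx - 1L
}

#' Directed percentile Hausdorff distance (mm)
#'
#' For each surface point of \code{from}, the Euclidean distance (voxel
#' coordinates scaled by the spacing, i.e. physical mm) to its nearest
#' point of \code{to}; returns the given percentile of these distances by
#' the nearest-rank rule (percentile 1 = the classical directed Hausdorff
#' maximum).
#'
#' @param fromSet,toSet 0-based voxel coordinate matrices (n x 3).
#' @param spacing mm triple.
#' @param percentile fraction in (0, 1].
#' @return Distance in mm.
#' @export
directedHausdorff <- function(fromSet, toSet, spacing = c(1, 1, 1),
                              percentile = 1) {
  if (nrow(fromSet) == 0L || nrow(toSet) == 0L)
    stop("directed Hausdorff undefined for an empty surface set",
         call. = FALSE)
  fm <- sweep(matrix(as.numeric(fromSet), ncol = 3), 2, spacing, "*")
  tm <- sweep(matrix(as.numeric(toSet), ncol = 3), 2, spacing, "*")
  d <- sort(.min_dists_cpp(fm, tm))
  d[max(1L, ceiling(percentile * length(d)))]
}

#' Bidirectional 95th-percentile Hausdorff distance (mm)
#'
#' The maximum of the two directed 95th-percentile surface distances
#' between the truth and segmentation kidney boundaries; symmetric by
#' construction and 0 iff the two surface sets coincide.
#'
#' @param truth,seg \linkS4class{LabelMap}s, both with KT voxels.
#' @param percentile distance percentile (default 0.95).
#' @return Distance in mm.
#' @export
bhd95 <- function(truth, seg, percentile = 0.95) {
  stopGridsCompatible(truth@grid, seg@grid, "truth and segmentation")
  sp <- truth@grid@spacing
  sg <- surfaceVoxels(truth)
  ss <- surfaceVoxels(seg)
  max(directedHausdorff(sg, ss, sp, percentile),
      directedHausdorff(ss, sg, sp, percentile))
}

#' ROC curve and AUC of a probability map against truth
#'
#' Sweeps the classification threshold over the distinct probability values
#' (plus 0 and 1), computes the true/false positive rate at each operating
#' point and integrates the curve by the trapezoidal rule. Equals the
#' normalized Mann-Whitney U statistic. Both classes must be present.
#'
#' @param truth a \linkS4class{LabelMap}.
#' @param prob a \linkS4class{ProbabilityMap} (or bare numeric vector of
#'   per-voxel P(KT) paired with a 0/1 truth vector).
#' @return List with \code{roc} (data.frame of threshold, fpr, tpr, sorted
#'   along the curve) and \code{auc}.
#' @export
rocAuc <- function(truth, prob) {
  if (is(truth, "LabelMap")) {
    stopGridsCompatible(truth@grid, prob@grid, "truth and probability")
    y <- as.vector(truth@labels)
    p <- as.vector(prob@p)
  } else {
    y <- as.vector(truth)
    p <- as.vector(prob)
  }
  nP <- sum(y == 1L)
  nN <- sum(y == 0L)
  if (nP == 0L || nN == 0L)
    stop("ROC undefined: truth contains a single class", call. = FALSE)
  ## counts of positives/negatives at each distinct probability value
  ord <- order(p, decreasing = TRUE)
  ps <- p[ord]; ys <- y[ord]
  grp <- cumsum(!duplicated(ps))
  tpAt <- tapply(ys, grp, sum)
  nAt <- tapply(ys, grp, length)
  uv <- ps[!duplicated(ps)]
  tpr <- cumsum(tpAt) / nP
  fpr <- cumsum(nAt - tpAt) / nN
  roc <- data.frame(threshold = uv, fpr = as.numeric(fpr),
                    tpr = as.numeric(tpr))
  ## prepend the all-negative operating point; append all-positive
  roc <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0), roc)
  if (roc$fpr[nrow(roc)] < 1 || roc$tpr[nrow(roc)] < 1)
    roc <- rbind(roc, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
  list(roc = roc, auc = auc)
}

#' Full evaluation report for one (truth, segmentation) pair
#'
#' @param truth,seg \linkS4class{LabelMap}s.
#' @param prob optional \linkS4class{ProbabilityMap} enabling ROC/AUC.
#' @return An \linkS4class{EvalReport}.
#' @export
evaluateSegmentation <- function(truth, seg, prob = NULL) {
  cc <- confusionCounts(truth, seg)
  pv <- pvd(cc)
  r <- if (is.null(prob)) list(roc = data.frame(), auc = NA_real_)
       else rocAuc(truth, prob)
  new("EvalReport", dc = dice(cc), pvd = pv$signed, pvdAbs = pv$abs,
      bhd95 = bhd95(truth, seg), auc = r$auc, roc = r$roc)
}

#' Serialize an EvalReport to JSON
#'
#' @param report an \linkS4class{EvalReport}.
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeEvalReport <- function(report, path) {
  jsonlite::write_json(
    list(dc = report@dc, pvd = report@pvd, pvd_abs = report@pvdAbs,
         bhd95 = report@bhd95, auc = report@auc,
         roc = report@roc),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
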