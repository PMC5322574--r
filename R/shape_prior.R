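## Atlas ranking by normalized cross correlation and the adaptive,
## appearance-conditioned voxel-wise kidney shape prior. For a test voxel p,
## atlas voxels rho inside a search cube C_p whose intensity matches the
## test signal within tau contribute their labels; the prior is the KT
## fraction of those contributions, pooled with equal weight over the
## selected atlas images. An empty match set grows the cube; if it stays
## empty at the maximum size the prior falls back to the uninformative 0.5.

#' ShapePriorParams: tuning of the adaptive shape prior
#'
#' @slot tau intensity-difference threshold (same units as the volumes);
#'   atlas voxels count as similar when |g_i(rho) - g_t(p)| <= tau.
#' @slot hwInit initial search-cube half-width, voxels (1 = 3x3x3).
#' @slot hwMax maximum half-width reached by progressive growth.
#' @export
setClass("ShapePriorParams",
  representation(tau = "numeric", hwInit = "integer", hwMax = "integer"),
  validity = function(object) {
    if (object@tau < 0) return("tau must be >= 0")
    if (object@hwInit < 1L || object@hwMax < object@hwInit)
      return("need 1 <= hwInit <= hwMax")
    TRUE
  })

#' @rdname ShapePriorParams-class
#' @param tau,hwInit,hwMax see slots.
#' @export
shapePriorParams <- function(tau = 50, hwInit = 1L, hwMax = 5L)
  new("ShapePriorParams", tau = as.numeric(tau), hwInit = as.integer(hwInit),
      hwMax = as.integer(hwMax))

#' Normalized cross correlation of two volumes
#'
#' Pearson-type NCC over all voxels; the value lies in [-1, 1]. Both volumes
#' must be non-constant (the normalization is undefined otherwise) and share
#' one grid.
#'
#' @param a,b \linkS4class{IntensityVolume}s on compatible grids.
#' @return Scalar NCC.
#' @export
ncc <- function(a, b) {
  stopGridsCompatible(a@grid, b@grid, "NCC inputs")
  av <- as.vector(a@values); bv <- as.vector(b@values)
  sa <- sd(av); sb <- sd(bv)
  if (sa == 0 || sb == 0)
    stop("undefined variance: NCC requires non-constant volumes",
         call. = FALSE)
  sum((av - mean(av)) * (bv - mean(bv))) / ((length(av) - 1) * sa * sb)
}

#' Select the top-N most similar atlas entries
#'
#' Ranks atlas entries by NCC against the (co-aligned) test volume and
#' returns the \code{n} best, in descending similarity. All entries of
#' \code{excludeSubject} are removed first (leave-one-subject-out hygiene);
#' ties break deterministically by (subjectId, phase) lexicographic order.
#'
#' @param test co-aligned test \linkS4class{IntensityVolume}.
#' @param db an \linkS4class{AtlasDatabase}.
#' @param n number of entries to keep (the protocol default is 19).
#' @param excludeSubject subject id to remove, or NULL.
#' @return List of atlas entries (each with an added \code{ncc} element).
#' @export
selectTop <- function(test, db, n, excludeSubject = NULL) {
  entries <- db@entries
  if (!is.null(excludeSubject))
    entries <- Filter(function(e) e$subjectId != excludeSubject, entries)
  if (length(entries) < n)
    stop(sprintf(paste0("cohort-size error: %d atlas entries remain after ",
                        "exclusion but n = %d requested"),
                 length(entries), n), call. = FALSE)
  scores <- vapply(entries, function(e) ncc(test, e$volume), numeric(1))
  sid <- vapply(entries, function(e) e$subjectId, character(1))
  ph <- vapply(entries, function(e) e$phase, character(1))
  ord <- order(-scores, sid, ph)
  out <- entries[ord[seq_len(n)]]
  for (i in seq_along(out)) out[[i]]$ncc <- scores[ord[i]]
  out
}

#' Adaptive appearance-conditioned shape prior
#'
#' Computes the per-voxel kidney probability: over the selected atlas
#' images, voxels inside the search cube around p whose intensity lies
#' within \code{tau} of the test signal vote with their labels, all images
#' weighted equally. Empty match sets trigger progressive cube growth up to
#' \code{hwMax}; a still-empty set yields the fallback value 0.5, so the
#' prior is defined everywhere and P(KT) + P(OT) = 1 holds by construction.
#'
#' @param test co-aligned test \linkS4class{IntensityVolume}.
#' @param selected list of atlas entries (from \code{\link{selectTop}}).
#' @param params a \linkS4class{ShapePriorParams}.
#' @return A \linkS4class{ProbabilityMap} of P(KT).
#' @export
computeShapePrior <- function(test, selected, params = shapePriorParams()) {
  if (length(selected) < 1L)
    stop("the selected atlas set must be non-empty", call. = FALSE)
  for (e in selected)
    stopGridsCompatible(test@grid, e$volume@grid, "test and atlas entry")
  t0 <- proc.time()[["elapsed"]]
  g <- lapply(selected, function(e) as.vector(e$volume@values))
  m <- lapply(selected, function(e) as.vector(e$labels@labels))
  p <- .shape_prior_cpp(as.vector(test@values), test@grid@dims, g, m,
                        params@tau, params@hwInit, params@hwMax)
  logInfo("computeShapePrior: grid %s, %d atlases, tau %.3g, %.2fs",
          paste(test@grid@dims, collapse = "x"), length(selected),
          params@tau, proc.time()[["elapsed"]] - t0)
  ProbabilityMap(array(p, test@grid@dims), test@grid)
}
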