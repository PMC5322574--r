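## Two-step co-alignment: a 12-dof 3D affine transform for global motion,
## then a cubic B-spline free-form deformation for local kidney deformation.
## Both steps maximize normalized cross correlation (NCC) with a
## multi-resolution scheme; the resulting TransformChain is applied to
## grayscale volumes (trilinear) and propagated to label maps
## (nearest-neighbour, so labels are never interpolated).

# 3x3 linear part: rotation %*% shear %*% scale.
.affineMatrix <- function(rot, scl, shr) {
  cx <- cos(rot[1]); sx <- sin(rot[1])
  cy <- cos(rot[2]); sy <- sin(rot[2])
  cz <- cos(rot[3]); sz <- sin(rot[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  H <- rbind(c(1, shr[1], shr[2]), c(0, 1, shr[3]), c(0, 0, 1))
  Rz %*% Ry %*% Rx %*% H %*% diag(scl)
}

.affineFromPar <- function(par, center, converged = TRUE)
  AffineTransform(translation = par[1:3], rotation = par[4:6],
                  scaling = par[7:9], shearing = par[10:12],
                  center = center, converged = converged)

.parFromAffine <- function(at)
  c(at@translation, at@rotation, at@scaling, at@shearing)

# Map fixed-space physical coords (n x 3 mm) to moving-space coords.
.affineApplyCoords <- function(at, xyz) {
  A <- .affineMatrix(at@rotation, at@scaling, at@shearing)
  out <- sweep(xyz, 2, at@center) %*% t(A)
  sweep(out, 2, at@center + at@translation, "+")
}

# Exact inverse of the affine map.
.affineInvertCoords <- function(at, xyz) {
  A <- .affineMatrix(at@rotation, at@scaling, at@shearing)
  sweep(sweep(xyz, 2, at@center + at@translation) %*% t(solve(A)),
        2, at@center, "+")
}

# Block-mean downsampling by integer factor f (pyramid levels).
.downsampleArr <- function(arr, f) {
  if (f == 1L) return(arr)
  d <- dim(arr)
  nd <- pmax(d %/% f, 1L)
  a <- arr[seq_len(nd[1] * f), seq_len(nd[2] * f), seq_len(nd[3] * f)]
  dim(a) <- c(f, nd[1], f, nd[2], f, nd[3])
  a <- aperm(a, c(1, 3, 5, 2, 4, 6))
  array(colMeans(matrix(a, f^3)), nd)
}

.downsampleVolume <- function(vol, f) {
  arr <- .downsampleArr(vol@values, f)
  g <- vol@grid
  IntensityVolume(arr, VoxelGrid(dim(arr), g@spacing * f,
                                 g@origin + (f - 1) / 2 * g@spacing))
}

# Physical mm -> continuous 0-based voxel coords of `grid`.
.physToVoxel <- function(xyz, grid)
  sweep(sweep(xyz, 2, grid@origin), 2, grid@spacing, "/")

# Sample a volume at physical coordinates (n x 3 mm).
.sampleVolume <- function(vol, xyz, nearest = FALSE, fill = NA_real_)
  .interp3_cpp(as.vector(vol@values), vol@grid@dims,
               .physToVoxel(xyz, vol@grid), nearest, fill)

# NCC between two vectors, NA-tolerant; penalty when overlap is too small.
.nccVec <- function(a, b, minFrac = 0.1) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < minFrac * length(a)) return(-1)
  a <- a[ok]; b <- b[ok]
  sa <- sd(a); sb <- sd(b)
  if (sa == 0 || sb == 0) return(-1)
  mean((a - mean(a)) * (b - mean(b))) * length(a) / (length(a) - 1) / (sa * sb)
}

#' Affine registration (12 degrees of freedom)
#'
#' Estimates translation, rotation, anisotropic scaling and shearing that
#' maximize the NCC between \code{fixed} and the resampled \code{moving},
#' using a 3-level multi-resolution pyramid with a translation-first stage
#' and BFGS refinement. Identical inputs yield a near-identity transform.
#'
#' @param fixed,moving \linkS4class{IntensityVolume}s on compatible grids.
#' @param levels integer downsampling factors, coarse to fine. The default
#'   stops at half resolution: the optimum there is well inside the
#'   sub-voxel regime the downstream stages need, at a fraction of the
#'   full-resolution cost; pass \code{c(4L, 2L, 1L)} for a final
#'   full-resolution polish.
#' @param maxIter per-level iteration cap; hitting the cap at the finest
#'   level flags the (still returned, best-found) transform via
#'   \code{converged = FALSE}.
#' @return An \linkS4class{AffineTransform}.
#' @export
registerAffine <- function(fixed, moving, levels = c(4L, 2L),
                           maxIter = 60L) {
  stopGridsCompatible(fixed@grid, moving@grid, "fixed and moving")
  center <- fixed@grid@origin + (fixed@grid@dims - 1) / 2 * fixed@grid@spacing
  par <- c(0, 0, 0, 0, 0, 0, 1, 1, 1, 0, 0, 0)
  parscale <- c(rep(1, 3), rep(0.02, 9))
  converged <- TRUE
  t0 <- proc.time()[["elapsed"]]
  for (li in seq_along(levels)) {
    f <- levels[li]
    fl <- .downsampleVolume(fixed, f)
    ml <- .downsampleVolume(moving, f)
    ## fixed-grid coordinates relative to the rotation centre, precomputed;
    ## the whole map (affine + phys -> voxel) folds into one matmul
    xyzc <- sweep(.gridCoords(fl@grid), 2, center)
    fv <- as.vector(fl@values)
    mvals <- as.vector(ml@values)
    mdims <- ml@grid@dims
    msp <- ml@grid@spacing
    moff <- (center - ml@grid@origin) / msp
    obj <- function(p, mask) {
      full <- par
      full[mask] <- p
      A <- .affineMatrix(full[4:6], full[7:9], full[10:12])
      A2 <- A / msp                      # rows scaled: phys -> voxel units
      vox <- xyzc %*% t(A2)
      vox[, 1] <- vox[, 1] + (moff[1] + full[1] / msp[1])
      vox[, 2] <- vox[, 2] + (moff[2] + full[2] / msp[2])
      vox[, 3] <- vox[, 3] + (moff[3] + full[3] / msp[3])
      w <- .interp3_cpp(mvals, mdims, vox, FALSE, NA_real_)
      -.nccVec(fv, w)
    }
    if (li == 1L) {  # translation-first at the coarsest level
      o <- optim(par[1:3], obj, mask = 1:3, method = "Nelder-Mead",
                 control = list(maxit = 4L * maxIter))
      par[1:3] <- o$par
    }
    it <- if (f == 1L) max(8L, maxIter %/% 6L) else maxIter
    o <- optim(par, obj, mask = 1:12, method = "BFGS",
               control = list(maxit = it, parscale = parscale,
                              reltol = 1e-9))
    par <- o$par
    if (f == 1L) converged <- (o$convergence == 0L)
  }
  logInfo("registerAffine: grid %s, %.2fs, NCC %.4f",
          paste(fixed@grid@dims, collapse = "x"),
          proc.time()[["elapsed"]] - t0, -o$value)
  .affineFromPar(par, center, converged)
}

# Dense mm displacement of a deformation field on a full-resolution grid of
# dims `d` (must match def@fixedDims), returned as list of three arrays.
.denseDisplacement <- function(def, d) {
  stopifnot(all(d == def@fixedDims))
  nc <- dim(def@disp)[1:3]
  Wx <- bsplineWeights1d(seq(0, d[1] - 1), def@ctrlSpacing, nc[1])
  Wy <- bsplineWeights1d(seq(0, d[2] - 1), def@ctrlSpacing, nc[2])
  Wz <- bsplineWeights1d(seq(0, d[3] - 1), def@ctrlSpacing, nc[3])
  lapply(1:3, function(k) applySeparable(def@disp[, , , k], Wx, Wy, Wz))
}

#' B-spline free-form deformation registration
#'
#' Refines an affine initialization with a cubic B-spline deformation whose
#' control displacements are optimized by gradient ascent on the NCC
#' objective (analytic gradient via the chain rule through trilinear
#' sampling). The optimization runs on a downsampled copy of the volumes;
#' the returned field is defined over the full-resolution fixed grid. The
#' step is guarded: if no deformation improves on the affine initialization
#' the zero field is returned, so the objective never worsens.
#'
#' @param fixed,moving \linkS4class{IntensityVolume}s on compatible grids.
#' @param init an \linkS4class{AffineTransform} (from
#'   \code{\link{registerAffine}}).
#' @param ctrlSpacing control-point spacing in full-resolution voxels.
#' @param level downsampling factor of the optimization grid.
#' @param maxIter gradient iterations.
#' @param stepMm initial update magnitude, mm.
#' @return A \linkS4class{DeformationField}.
#' @export
registerBspline <- function(fixed, moving, init, ctrlSpacing = 8,
                            level = 2L, maxIter = 25L, stepMm = 0.8) {
  stopGridsCompatible(fixed@grid, moving@grid, "fixed and moving")
  d <- fixed@grid@dims
  nc <- vapply(1:3, function(k) nCtrlBspline(d[k], ctrlSpacing), 1L)
  fl <- .downsampleVolume(fixed, level)
  dl <- fl@grid@dims
  ## level voxel j corresponds to full-resolution coordinate j*level+(level-1)/2
  posl <- lapply(1:3, function(k) seq(0, dl[k] - 1) * level + (level - 1) / 2)
  Wx <- bsplineWeights1d(posl[[1]], ctrlSpacing, nc[1])
  Wy <- bsplineWeights1d(posl[[2]], ctrlSpacing, nc[2])
  Wz <- bsplineWeights1d(posl[[3]], ctrlSpacing, nc[3])
  xyz <- .gridCoords(fl@grid)
  amap <- .affineApplyCoords(init, xyz)
  fv <- as.vector(fl@values)
  n <- length(fv)

  ## moving-volume spatial gradient (per mm), for the chain rule
  mg <- lapply(1:3, function(k) {
    dplus <- shiftArray(moving@values, as.integer(1:3 == k), fill = NA)
    dminus <- shiftArray(moving@values, -as.integer(1:3 == k), fill = NA)
    g <- (dplus - dminus) / (2 * moving@grid@spacing[k])
    g[is.na(g)] <- 0
    IntensityVolume(g, moving@grid)
  })

  ctrl <- array(0, c(nc, 3L))
  evalNcc <- function(ctrl) {
    disp <- vapply(1:3, function(k)
      as.vector(applySeparable(ctrl[, , , k], Wx, Wy, Wz)), numeric(n))
    w <- .sampleVolume(moving, amap + disp)
    list(ncc = .nccVec(fv, w), w = w, coords = amap + disp)
  }
  cur <- evalNcc(ctrl)
  ncc0 <- cur$ncc
  best <- list(ncc = ncc0, ctrl = ctrl)
  step <- stepMm
  t0 <- proc.time()[["elapsed"]]
  for (it in seq_len(maxIter)) {
    w <- cur$w
    ok <- !is.na(w)
    nOk <- sum(ok)
    if (nOk < 10) break
    mw <- mean(w[ok]); mf <- mean(fv[ok])
    sw <- sd(w[ok]); sf <- sd(fv[ok])
    if (sw == 0 || sf == 0) break
    dndw <- numeric(n)
    dndw[ok] <- ((fv[ok] - mf) - cur$ncc * sf / sw * (w[ok] - mw)) /
      (nOk * sf * sw)
    gradField <- vapply(1:3, function(k) {
      gk <- .sampleVolume(mg[[k]], cur$coords, fill = 0)
      gk[is.na(gk)] <- 0
      v <- dndw * gk
      as.vector(applySeparable(array(v, dl), t(Wx), t(Wy), t(Wz)))
    }, numeric(prod(nc)))
    gmax <- max(abs(gradField))
    if (gmax < 1e-14) break
    cand <- ctrl + array(gradField, c(nc, 3L)) * (step / gmax)
    res <- evalNcc(cand)
    if (res$ncc > cur$ncc) {
      ctrl <- cand
      cur <- res
      if (res$ncc > best$ncc) best <- list(ncc = res$ncc, ctrl = ctrl)
    } else {
      step <- step / 2
      if (step < 1e-3) break
    }
  }
  logInfo("registerBspline: grid %s, %.2fs, NCC %.4f -> %.4f",
          paste(d, collapse = "x"), proc.time()[["elapsed"]] - t0,
          ncc0, best$ncc)
  new("DeformationField", ctrlSpacing = ctrlSpacing,
      disp = if (best$ncc > ncc0) best$ctrl else array(0, c(nc, 3L)),
      fixedDims = d)
}

# Moving-space physical coordinates of all voxels of fixedGrid under a chain.
.chainCoords <- function(chain, fixedGrid) {
  xyz <- .gridCoords(fixedGrid)
  out <- .affineApplyCoords(chain@affine, xyz)
  if (!is.null(chain@deformation)) {
    disp <- .denseDisplacement(chain@deformation, fixedGrid@dims)
    for (k in 1:3) out[, k] <- out[, k] + as.vector(disp[[k]])
  }
  out
}

#' @describeIn applyTransform Trilinear (or nearest) resampling of an
#'   intensity volume onto the fixed grid; out-of-volume sites take the
#'   moving volume's minimum.
setMethod("applyTransform", "IntensityVolume",
  function(input, chain, fixedGrid, mode = c("linear", "nearest")) {
    mode <- match.arg(mode)
    if (is(chain, "AffineTransform")) chain <- TransformChain(chain)
    coords <- .chainCoords(chain, fixedGrid)
    v <- .interp3_cpp(as.vector(input@values), input@grid@dims,
                      .physToVoxel(coords, input@grid),
                      mode == "nearest", min(input@values))
    IntensityVolume(array(v, fixedGrid@dims), fixedGrid)
  })

#' @describeIn applyTransform Nearest-neighbour propagation of a label map;
#'   linear mode is a contract violation (labels are never interpolated).
setMethod("applyTransform", "LabelMap",
  function(input, chain, fixedGrid, mode = c("linear", "nearest")) {
    mode <- match.arg(mode, c("nearest", "linear"))
    if (mode != "nearest")
      stop("label maps must be resampled with mode = 'nearest'",
           call. = FALSE)
    if (is(chain, "AffineTransform")) chain <- TransformChain(chain)
    coords <- .chainCoords(chain, fixedGrid)
    v <- .interp3_cpp(as.vector(as.double(input@labels)), input@grid@dims,
                      .physToVoxel(coords, input@grid), TRUE, 0)
    LabelMap(array(as.integer(v), fixedGrid@dims), fixedGrid)
  })

# Invert a chain pointwise: find atlas-space physical coords x such that
# chain(x) = y for each native-space y. Affine part is inverted exactly;
# the B-spline displacement by fixed-point iteration on the dense
# displacement field (valid for the small smooth fields produced here).
.invertChainCoords <- function(chain, yxyz, atlasGrid, iters = 5L) {
  x <- .affineInvertCoords(chain@affine, yxyz)
  if (!is.null(chain@deformation)) {
    dsp <- .denseDisplacement(chain@deformation, atlasGrid@dims)
    dspv <- lapply(dsp, as.vector)
    for (i in seq_len(iters)) {
      vox <- .physToVoxel(x, atlasGrid)
      d <- vapply(dspv, function(c_)
        .interp3_cpp(c_, atlasGrid@dims, vox, FALSE, 0), numeric(nrow(vox)))
      x <- .affineInvertCoords(chain@affine, yxyz - d)
    }
  }
  x
}

# Pull a result computed on the atlas grid back onto the native grid of the
# original scan (`chain` maps atlas space -> native space). `vox` may carry
# precomputed inverse voxel coordinates (shared across several outputs).
.mapBackToNative <- function(obj, chain, nativeGrid, atlasGrid,
                             vox = NULL) {
  if (is.null(vox)) {
    yxyz <- .gridCoords(nativeGrid)
    x <- .invertChainCoords(chain, yxyz, atlasGrid)
    vox <- .physToVoxel(x, atlasGrid)
  }
  if (is(obj, "LabelMap")) {
    v <- .interp3_cpp(as.vector(as.double(obj@labels)), atlasGrid@dims,
                      vox, TRUE, 0)
    LabelMap(array(as.integer(v), nativeGrid@dims), nativeGrid)
  } else if (is(obj, "ProbabilityMap")) {
    v <- .interp3_cpp(as.vector(obj@p), atlasGrid@dims, vox, FALSE, 0)
    ProbabilityMap(array(pmin(pmax(v, 0), 1), nativeGrid@dims), nativeGrid)
  } else stop("unsupported type")
}

#' Register a scan into atlas space with the two-step method
#'
#' Convenience wrapper: affine, then (optionally) B-spline, returning the
#' \linkS4class{TransformChain} and the co-aligned volume.
#'
#' @param fixed atlas-space reference \linkS4class{IntensityVolume}.
#' @param moving scan to align.
#' @param bspline logical; add the free-form deformation step.
#' @param ctrlSpacing B-spline control spacing, voxels.
#' @return List with elements \code{chain} and \code{aligned}.
#' @export
registerTwoStep <- function(fixed, moving, bspline = TRUE, ctrlSpacing = 8) {
  aff <- registerAffine(fixed, moving)
  def <- if (bspline) registerBspline(fixed, moving, aff, ctrlSpacing)
         else NULL
  chain <- TransformChain(aff, def)
  list(chain = chain,
       aligned = applyTransform(moving, chain, fixed@grid, "linear"))
}

#' Serialize / restore a transform chain (JSON)
#'
#' @param chain a \linkS4class{TransformChain}.
#' @param path output JSON file.
#' @return \code{writeTransformChain}: the path, invisibly;
#'   \code{readTransformChain}: the chain.
#' @export
writeTransformChain <- function(chain, path) {
  aff <- chain@affine
  obj <- list(affine = list(translation = aff@translation,
                            rotation = aff@rotation, scaling = aff@scaling,
                            shearing = aff@shearing, center = aff@center,
                            converged = aff@converged))
  if (!is.null(chain@deformation)) {
    def <- chain@deformation
    obj$deformation <- list(ctrlSpacing = def@ctrlSpacing,
                            ctrlDims = dim(def@disp)[1:3],
                            fixedDims = def@fixedDims,
                            disp = as.vector(def@disp))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTransformChain
#' @export
readTransformChain <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  aff <- AffineTransform(obj$affine$translation, obj$affine$rotation,
                         obj$affine$scaling, obj$affine$shearing,
                         obj$affine$center, isTRUE(obj$affine$converged))
  def <- NULL
  if (!is.null(obj$deformation)) {
    def <- new("DeformationField",
               ctrlSpacing = obj$deformation$ctrlSpacing,
               disp = array(obj$deformation$disp,
                            c(obj$deformation$ctrlDims, 3L)),
               fixedDims = as.integer(obj$deformation$fixedDims))
  }
  TransformChain(aff, def)
}
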