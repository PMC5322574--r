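# Internal helpers: array shifting, local RNG scopes, logging.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shift a 3D array by integer offset d: out[p] = a[p + d]; vacated sites get
# `fill`. Used by the neighborhood engine, the MGRF clique sums and surface
# extraction. Integer inputs come back integer.
shiftArray <- function(a, d, fill = NA) {
  out <- .shift3_cpp(as.double(a), dim(a), as.integer(d), as.double(fill))
  dim(out) <- dim(a)
  if (is.integer(a)) storage.mode(out) <- "integer"
  out
}

# Evaluate expr with the global RNG seeded to `seed`, restoring the caller's
# RNG state afterwards. Keeps every generator a pure function of its seeds.
withLocalSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Derive a stream of child seeds from a master seed; stays below 2^31.
deriveSeeds <- function(masterSeed, n, salt = 0L) {
  (as.numeric(masterSeed) * 48271 + salt * 7919 + seq_len(n) * 104729) %%
    2147483629
}

#' Toggle INFO-level pipeline logging
#'
#' Every pipeline stage logs its inputs' grid, key parameters and elapsed
#' time when logging is enabled (option \code{RenalSeg.verbose}).
#'
#' @param on logical.
#' @return The previous setting, invisibly.
#' @export
renalSegVerbose <- function(on = TRUE) {
  old <- getOption("RenalSeg.verbose", FALSE)
  options(RenalSeg.verbose = isTRUE(on))
  invisible(old)
}

logInfo <- function(fmt, ...) {
  if (isTRUE(getOption("RenalSeg.verbose", FALSE)))
    message(sprintf(paste0("[RenalSeg %s] ", fmt),
                    format(Sys.time(), "%H:%M:%S"), ...))
  invisible(NULL)
}

# Time a stage and log it.
logStage <- function(name, grid, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- force(expr)
  logInfo("%s: grid %s, %.2fs", name,
          paste(grid@dims, collapse = "x"),
          proc.time()[["elapsed"]] - t0)
  res
}

stopGridsCompatible <- function(a, b, what = "inputs") {
  if (!validateCompatible(a, b))
    stop(sprintf("incompatible voxel grids between %s (dims/spacing differ)",
                 what), call. = FALSE)
  invisible(TRUE)
}

# --- separable tensor-field evaluation -------------------------------------
# Dense evaluation of a field attached to a coarse control lattice, one axis
# at a time: field = (Wx x Wy x Wz) ctrl, where each W is a dense
# (positions x control-points) weight matrix. Shared by the B-spline
# deformation model and the phantom's smooth random fields.

applySeparable <- function(ctrl, Wx, Wy, Wz) {
  d <- dim(ctrl)
  m <- Wx %*% matrix(ctrl, d[1], d[2] * d[3])           # (X, ny*nz)
  a <- array(m, c(nrow(Wx), d[2], d[3]))
  a <- aperm(a, c(2, 1, 3))
  m <- Wy %*% matrix(a, d[2], nrow(Wx) * d[3])          # (Y, X*nz)
  a <- array(m, c(nrow(Wy), nrow(Wx), d[3]))
  a <- aperm(a, c(3, 2, 1))                             # (nz, X, Y)
  m <- Wz %*% matrix(a, d[3], nrow(Wx) * nrow(Wy))
  a <- array(m, c(nrow(Wz), nrow(Wx), nrow(Wy)))
  aperm(a, c(2, 3, 1))                                  # (X, Y, Z)
}

# Linear interpolation weights from `n` evenly spaced positions spanning
# [0, n-1] onto `nc` control points spanning the same range.
linearWeights1d <- function(n, nc) {
  W <- matrix(0, n, nc)
  if (nc == 1L) { W[, 1] <- 1; return(W) }
  t <- seq(0, nc - 1, length.out = n)
  i0 <- pmin(floor(t), nc - 2)
  f <- t - i0
  idx <- cbind(seq_len(n), i0 + 1)
  W[idx] <- 1 - f
  W[cbind(seq_len(n), i0 + 2)] <- f
  W
}

# Cubic B-spline kernel (support [-2, 2], C2, partition of unity), in the
# branch-free form ((2-|u|)_+^3 - 4 (1-|u|)_+^3) / 6.
cubicBsplineKernel <- function(u) {
  au <- abs(u)
  (pmax(2 - au, 0)^3 - 4 * pmax(1 - au, 0)^3) / 6
}

# Weights of voxel positions `pos` (0-based, full-resolution coordinates)
# against a cubic B-spline control lattice with knot spacing `h` voxels;
# control point j (1-based) sits at voxel coordinate (j - 2) * h, giving a
# one-knot margin on each side. nCtrlBspline() returns the lattice size that
# covers a grid of extent n.
nCtrlBspline <- function(n, h) as.integer(ceiling((n - 1) / h)) + 3L

bsplineWeights1d <- function(pos, h, nc) {
  W <- matrix(0, length(pos), nc)
  for (j in seq_len(nc)) {
    W[, j] <- cubicBsplineKernel(pos / h - (j - 2))
  }
  W
}
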