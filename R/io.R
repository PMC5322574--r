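#' Test geometric compatibility of two voxel grids
#'
#' Two grids are compatible iff their dims are equal and spacings agree within
#' a relative tolerance of 1e-6. Compatibility is required before any two
#' volumes are combined anywhere in the package.
#'
#' @param a,b \linkS4class{VoxelGrid}s.
#' @return TRUE or FALSE.
#' @export
validateCompatible <- function(a, b) {
  if (!all(a@dims == b@dims)) return(FALSE)
  all(abs(a@spacing - b@spacing) <= .SPACING_RTOL * pmax(abs(a@spacing),
                                                         abs(b@spacing)))
}

.niftiGrid <- function(img, path) {
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("'%s': expected a 3D image, got %dD (field: dim)",
                 path, length(d)), call. = FALSE)
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0))
    stop(sprintf("'%s': unreadable or non-positive voxel spacing (field: pixdim)",
                 path), call. = FALSE)
  xf <- try(RNifti::xform(img), silent = TRUE)
  orig <- if (inherits(xf, "try-error")) c(0, 0, 0) else unname(xf[1:3, 4])
  VoxelGrid(d, sp[1:3], orig)
}

.asNiftiImage <- function(arr, grid) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- grid@spacing
  m <- diag(c(grid@spacing, 1))
  m[1:3, 4] <- grid@origin
  RNifti::`qform<-`(img, structure(m, code = 2L))
}

#' Read / write intensity volumes (NIfTI)
#'
#' Volumes are exchanged as NIfTI (.nii / .nii.gz). Geometry (dims, spacing,
#' origin) is carried in the header; values are written as float64 so that
#' write-then-read is the identity.
#'
#' @param path file path.
#' @return \code{readVolume}: an \linkS4class{IntensityVolume}.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path),
                               call. = FALSE)
  img <- RNifti::readNifti(path)
  grid <- .niftiGrid(img, path)
  vals <- as.array(img)
  attributes(vals) <- list(dim = dim(vals))
  if (!all(is.finite(vals)))
    stop(sprintf("'%s': non-finite intensity values", path), call. = FALSE)
  IntensityVolume(vals, grid)
}

#' @rdname readVolume
#' @param volume an \linkS4class{IntensityVolume}.
#' @return \code{writeVolume}: the path, invisibly.
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "IntensityVolume"))
  if (!all(is.finite(volume@values)))
    stop("refusing to write non-finite intensity values", call. = FALSE)
  RNifti::writeNifti(.asNiftiImage(volume@values, volume@grid), path,
                     datatype = "double")
  invisible(path)
}

#' Read / write binary label maps (NIfTI)
#'
#' On-disk encoding: 0 = OT (background), 1 = KT (kidney). Any other stored
#' value is a label-domain error; labels are never interpolated.
#'
#' @param path file path.
#' @return \code{readLabelMap}: a \linkS4class{LabelMap}.
#' @export
readLabelMap <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path),
                               call. = FALSE)
  img <- RNifti::readNifti(path)
  grid <- .niftiGrid(img, path)
  vals <- as.array(img)
  attributes(vals) <- list(dim = dim(vals))
  if (!all(vals %in% c(0, 1)))
    stop(sprintf("'%s': label-domain error, stored values outside {0, 1}",
                 path), call. = FALSE)
  LabelMap(vals, grid)
}

#' @rdname readLabelMap
#' @param labelmap a \linkS4class{LabelMap}.
#' @return \code{writeLabelMap}: the path, invisibly.
#' @export
writeLabelMap <- function(labelmap, path) {
  stopifnot(is(labelmap, "LabelMap"))
  RNifti::writeNifti(.asNiftiImage(labelmap@labels, labelmap@grid), path,
                     datatype = "uint8")
  invisible(path)
}

#' @rdname readVolume
#' @param prob a \linkS4class{ProbabilityMap}.
#' @export
writeProbabilityMap <- function(prob, path) {
  stopifnot(is(prob, "ProbabilityMap"))
  RNifti::writeNifti(.asNiftiImage(prob@p, prob@grid), path,
                     datatype = "double")
  invisible(path)
}

#' @rdname readVolume
#' @export
readProbabilityMap <- function(path) {
  v <- readVolume(path)
  ProbabilityMap(pmin(pmax(v@values, 0), 1), v@grid)
}
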