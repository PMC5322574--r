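#' @import methods
#' @importFrom stats sd rnorm runif quantile dnorm aggregate optim
#' @importFrom utils head
#' @importFrom Rcpp sourceCpp
#' @useDynLib RenalSeg, .registration = TRUE
NULL

.SPACING_RTOL <- 1e-6
.PHASES <- c("noncontrast", "postcontrast", "late")

## ---------------------------------------------------------------------------
## Lattice geometry
## ---------------------------------------------------------------------------

#' VoxelGrid: geometry of a 3D voxel lattice
#'
#' Describes the arithmetic lattice supporting a volume: integer dimensions
#' \code{(X, Y, Z)}, physical voxel spacing in millimetres and the physical
#' position of voxel \code{(0, 0, 0)}. Voxel indices are 0-based; the physical
#' position of voxel \code{p} is \code{origin + p * spacing}.
#'
#' @slot dims integer vector of length 3, all >= 1.
#' @slot spacing numeric vector of length 3, strictly positive, in mm.
#' @slot origin numeric vector of length 3, in mm.
#' @export
setClass("VoxelGrid",
  representation(dims = "integer", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@dims) != 3L || any(object@dims < 1L))
      msg <- c(msg, "dims must be three integers >= 1")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be three positive finite values (mm)")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      msg <- c(msg, "origin must be three finite values (mm)")
    if (length(msg)) msg else TRUE
  })

#' Construct a VoxelGrid
#'
#' @param dims integer vector (X, Y, Z).
#' @param spacing voxel spacing in mm (default 0.64 x 0.64 x 0.9, a typical
#'   abdominal CT acquisition geometry).
#' @param origin physical position of voxel (0, 0, 0) in mm.
#' @return A \linkS4class{VoxelGrid}.
#' @export
VoxelGrid <- function(dims, spacing = c(0.64, 0.64, 0.9), origin = c(0, 0, 0)) {
  new("VoxelGrid", dims = as.integer(dims), spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

## ---------------------------------------------------------------------------
## Volumes on a grid
## ---------------------------------------------------------------------------

#' @rdname IntensityVolume-class
#' @export
setClass("Volume3D", representation("VIRTUAL", grid = "VoxelGrid"))

#' IntensityVolume: scalar (Hounsfield-like) 3D volume
#'
#' A grayscale volume \code{g = \{g_p\}} on a \linkS4class{VoxelGrid}; values
#' must be finite, one per lattice site.
#'
#' @slot grid a \linkS4class{VoxelGrid}.
#' @slot values 3D numeric array matching \code{dims(grid)}.
#' @aliases Volume3D-class
#' @export
setClass("IntensityVolume", contains = "Volume3D",
  representation(values = "array"),
  validity = function(object) {
    d <- dim(object@values)
    if (length(d) != 3L || !all(d == object@grid@dims))
      return("values must be a 3D array matching the grid dims")
    if (!all(is.finite(object@values)))
      return("intensity values must all be finite")
    TRUE
  })

#' LabelMap: binary kidney/background label volume
#'
#' Per-voxel region labels over the label set \{KT, OT\} (kidney tissue /
#' other tissue), stored as integers 1 = KT, 0 = OT.
#'
#' @slot grid a \linkS4class{VoxelGrid}.
#' @slot labels 3D integer array of 0/1 matching the grid.
#' @export
setClass("LabelMap", contains = "Volume3D",
  representation(labels = "array"),
  validity = function(object) {
    d <- dim(object@labels)
    if (length(d) != 3L || !all(d == object@grid@dims))
      return("labels must be a 3D array matching the grid dims")
    if (!all(object@labels %in% c(0L, 1L)))
      return("labels must lie in {0 (OT), 1 (KT)}")
    TRUE
  })

#' ProbabilityMap: per-voxel kidney probability
#'
#' Holds \code{P(KT)} per voxel; \code{P(OT)} is implicitly \code{1 - P(KT)}.
#' Shared container for shape priors, Gibbs conditionals and classifier vote
#' fractions.
#'
#' @slot grid a \linkS4class{VoxelGrid}.
#' @slot p 3D numeric array in [0, 1] matching the grid.
#' @export
setClass("ProbabilityMap", contains = "Volume3D",
  representation(p = "array"),
  validity = function(object) {
    d <- dim(object@p)
    if (length(d) != 3L || !all(d == object@grid@dims))
      return("p must be a 3D array matching the grid dims")
    if (any(!is.finite(object@p)) || any(object@p < 0) || any(object@p > 1))
      return("probabilities must lie in [0, 1]")
    TRUE
  })

#' Construct an IntensityVolume
#' @param values 3D numeric array.
#' @param grid a \linkS4class{VoxelGrid}; defaults to unit-ish CT spacing.
#' @return An \linkS4class{IntensityVolume}.
#' @export
IntensityVolume <- function(values, grid = VoxelGrid(dim(values))) {
  storage.mode(values) <- "double"
  new("IntensityVolume", grid = grid, values = values)
}

#' Construct a LabelMap
#' @param labels 3D array coercible to integer 0/1.
#' @param grid a \linkS4class{VoxelGrid}.
#' @return A \linkS4class{LabelMap}.
#' @export
LabelMap <- function(labels, grid = VoxelGrid(dim(labels))) {
  storage.mode(labels) <- "integer"
  new("LabelMap", grid = grid, labels = labels)
}

#' Construct a ProbabilityMap
#' @param p 3D numeric array in [0, 1].
#' @param grid a \linkS4class{VoxelGrid}.
#' @return A \linkS4class{ProbabilityMap}.
#' @export
ProbabilityMap <- function(p, grid = VoxelGrid(dim(p))) {
  storage.mode(p) <- "double"
  new("ProbabilityMap", grid = grid, p = p)
}

## ---------------------------------------------------------------------------
## Subjects and the atlas database
## ---------------------------------------------------------------------------

#' SubjectRecord: one contrast-phase scan of one subject
#'
#' @slot subjectId character scalar.
#' @slot phase one of "noncontrast", "postcontrast", "late".
#' @slot volume the scan as an \linkS4class{IntensityVolume}.
#' @slot truth ground-truth \linkS4class{LabelMap} on the same grid, or NULL.
#' @export
setClass("SubjectRecord",
  representation(subjectId = "character", phase = "character",
                 volume = "IntensityVolume", truth = "ANY"),
  validity = function(object) {
    if (!object@phase %in% .PHASES)
      return(sprintf("phase must be one of %s", paste(.PHASES, collapse = ", ")))
    if (!is.null(object@truth)) {
      if (!is(object@truth, "LabelMap")) return("truth must be a LabelMap or NULL")
      if (!validateCompatible(object@volume@grid, object@truth@grid))
        return("volume and truth must share one VoxelGrid")
    }
    TRUE
  })

#' @rdname SubjectRecord-class
#' @param subjectId,phase,volume,truth see slots.
#' @export
SubjectRecord <- function(subjectId, phase, volume, truth = NULL)
  new("SubjectRecord", subjectId = subjectId, phase = phase,
      volume = volume, truth = truth)

#' PhantomSubject: a synthetic subject with three contrast phases
#'
#' Three phase scans sharing one phase-independent ground-truth label map.
#'
#' @slot subjectId character scalar.
#' @slot records list of three \linkS4class{SubjectRecord}s (one per phase).
#' @slot truth the shared \linkS4class{LabelMap}.
#' @export
setClass("PhantomSubject",
  representation(subjectId = "character", records = "list", truth = "LabelMap"),
  validity = function(object) {
    if (length(object@records) != 3L)
      return("a phantom subject carries exactly three phase records")
    ph <- vapply(object@records, function(r) r@phase, character(1))
    if (!setequal(ph, .PHASES)) return("records must cover the three phases")
    for (r in object@records) {
      if (!identical(r@truth@labels, object@truth@labels))
        return("the truth label map must be identical across phases")
    }
    TRUE
  })

#' AtlasDatabase: co-aligned grayscale + label training entries
#'
#' All entries live on one shared grid (the atlas space). Each entry is a list
#' with elements \code{subjectId}, \code{phase}, \code{volume}
#' (\linkS4class{IntensityVolume}) and \code{labels} (\linkS4class{LabelMap}).
#'
#' @slot grid the common atlas-space \linkS4class{VoxelGrid}.
#' @slot entries list of entries as described above.
#' @slot reference the atlas-space reference \linkS4class{IntensityVolume}.
#' @slot referenceId id string of the reference scan (cache key for
#'   registrations into this atlas space).
#' @export
setClass("AtlasDatabase",
  representation(grid = "VoxelGrid", entries = "list", reference = "ANY",
                 referenceId = "character"),
  validity = function(object) {
    for (e in object@entries) {
      if (!all(c("subjectId", "phase", "volume", "labels") %in% names(e)))
        return("each entry needs subjectId, phase, volume, labels")
      if (!validateCompatible(e$volume@grid, object@grid) ||
          !validateCompatible(e$labels@grid, object@grid))
        return("all atlas entries must share the atlas-space grid")
    }
    TRUE
  })

#' @rdname AtlasDatabase-class
#' @param entries,grid,reference,referenceId see slots.
#' @export
AtlasDatabase <- function(entries, grid = entries[[1]]$volume@grid,
                          reference = NULL, referenceId = "reference")
  new("AtlasDatabase", grid = grid, entries = entries, reference = reference,
      referenceId = referenceId)

## ---------------------------------------------------------------------------
## Transforms
## ---------------------------------------------------------------------------

#' AffineTransform: 12-parameter 3D affine map
#'
#' Maps fixed-space physical coordinates to moving-space coordinates as
#' \code{x_m = R S H (x_f - c) + c + t}, with rotation \code{R}, anisotropic
#' scaling \code{S}, shearing \code{H}, rotation centre \code{c} and
#' translation \code{t}. Twelve degrees of freedom: 3 translation (mm),
#' 3 rotation (radians), 3 scaling, 3 shearing.
#'
#' @slot translation,rotation,scaling,shearing numeric length-3 parameter
#'   blocks.
#' @slot center rotation/scaling centre in mm.
#' @slot converged logical; FALSE flags an optimizer that hit its iteration
#'   cap (the best transform found is still returned).
#' @export
setClass("AffineTransform",
  representation(translation = "numeric", rotation = "numeric",
                 scaling = "numeric", shearing = "numeric",
                 center = "numeric", converged = "logical"),
  validity = function(object) {
    for (s in c("translation", "rotation", "scaling", "shearing", "center"))
      if (length(slot(object, s)) != 3L || any(!is.finite(slot(object, s))))
        return(sprintf("%s must be three finite numbers", s))
    if (any(object@scaling == 0))
      return("scale parameters must be nonzero (invertibility)")
    TRUE
  })

#' @rdname AffineTransform-class
#' @param translation,rotation,scaling,shearing,center,converged see slots.
#' @export
AffineTransform <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                            scaling = c(1, 1, 1), shearing = c(0, 0, 0),
                            center = c(0, 0, 0), converged = TRUE)
  new("AffineTransform", translation = as.numeric(translation),
      rotation = as.numeric(rotation), scaling = as.numeric(scaling),
      shearing = as.numeric(shearing), center = as.numeric(center),
      converged = converged)

#' DeformationField: cubic B-spline free-form deformation
#'
#' Displacements (mm, in fixed space) attached to a coarse control-point
#' lattice; the dense field is the separable cubic B-spline interpolation of
#' the control displacements, hence C2-smooth by construction.
#'
#' @slot ctrlSpacing control-point spacing in fixed-grid voxels.
#' @slot disp 4D numeric array (nx, ny, nz, 3) of control displacements (mm).
#' @slot fixedDims dims of the fixed grid the field is defined over.
#' @export
setClass("DeformationField",
  representation(ctrlSpacing = "numeric", disp = "array",
                 fixedDims = "integer"),
  validity = function(object) {
    d <- dim(object@disp)
    if (length(d) != 4L || d[4] != 3L)
      return("disp must be a (nx, ny, nz, 3) array")
    if (object@ctrlSpacing <= 0) return("ctrlSpacing must be positive")
    if (any(!is.finite(object@disp))) return("displacements must be finite")
    TRUE
  })

#' TransformChain: affine followed by optional B-spline deformation
#'
#' Application order is coarse-to-fine: the affine map first, then the
#' deformation, i.e. \code{x_m = A(x_f) + D(x_f)}.
#'
#' @slot affine an \linkS4class{AffineTransform}.
#' @slot deformation a \linkS4class{DeformationField} or NULL.
#' @export
setClass("TransformChain",
  representation(affine = "AffineTransform", deformation = "ANY"),
  validity = function(object) {
    if (!is.null(object@deformation) &&
        !is(object@deformation, "DeformationField"))
      return("deformation must be a DeformationField or NULL")
    TRUE
  })

#' @rdname TransformChain-class
#' @param affine,deformation see slots.
#' @export
TransformChain <- function(affine, deformation = NULL)
  new("TransformChain", affine = affine, deformation = deformation)

## ---------------------------------------------------------------------------
## MGRF spatial model
## ---------------------------------------------------------------------------

#' CliqueFamily: one translation-invariant clique shape
#'
#' The family is the set of all lattice translations of a fixed voxel-offset
#' pattern. Orders 2 (pairs), 3 (collinear triples) and 4 (planar 2x2 quads)
#' are used; every inter-voxel step lies in the 18-connectivity neighborhood.
#'
#' @slot order integer in \{2, 3, 4\}.
#' @slot offsets 3 x order integer matrix of voxel offsets (first column 0).
#' @slot name human-readable family tag.
#' @export
setClass("CliqueFamily",
  representation(order = "integer", offsets = "matrix", name = "character"),
  validity = function(object) {
    if (!object@order %in% 2:4) return("order must be 2, 3 or 4")
    if (!all(dim(object@offsets) == c(3L, object@order)))
      return("offsets must be a 3 x order matrix")
    if (anyDuplicated(t(object@offsets))) return("offsets must be distinct")
    TRUE
  })

#' PottsModel: clique families with analytically estimated potentials
#'
#' One scalar potential per family, applied as \code{+V} when all clique
#' labels agree and \code{-V} otherwise (Potts form).
#'
#' @slot families list of \linkS4class{CliqueFamily}.
#' @slot potentials named numeric vector, one finite value per family.
#' @export
setClass("PottsModel",
  representation(families = "list", potentials = "numeric"),
  validity = function(object) {
    if (length(object@families) != length(object@potentials))
      return("one potential per clique family")
    if (any(!is.finite(object@potentials)))
      return("potentials must be finite")
    TRUE
  })

#' IntensityClassModel: per-label Gaussian appearance model
#'
#' @slot means named numeric (KT, OT) intensity means.
#' @slot sds named numeric (KT, OT) standard deviations, > 0.
#' @export
setClass("IntensityClassModel",
  representation(means = "numeric", sds = "numeric"),
  validity = function(object) {
    if (!all(c("KT", "OT") %in% names(object@means)) ||
        !all(c("KT", "OT") %in% names(object@sds)))
      return("means and sds must be named with KT and OT")
    if (any(object@sds <= 0)) return("standard deviations must be positive")
    TRUE
  })

## ---------------------------------------------------------------------------
## Classifier and evaluation containers
## ---------------------------------------------------------------------------

#' ForestModel: trained random-forest voxel classifier
#'
#' @slot fit the underlying ranger forest.
#' @slot nTrees number of decision trees.
#' @slot seed training seed (prediction is deterministic given the model).
#' @export
setClass("ForestModel",
  representation(fit = "ANY", nTrees = "integer", seed = "integer"))

#' EvalReport: segmentation quality metrics for one (truth, segmentation) pair
#'
#' @slot dc Dice coefficient, percent.
#' @slot pvd signed percentage volume difference; \code{pvdAbs} its magnitude.
#' @slot pvdAbs absolute percentage volume difference.
#' @slot bhd95 bidirectional 95th-percentile Hausdorff distance, mm.
#' @slot auc area under the ROC curve (NA when no probabilities given).
#' @slot roc data.frame of (fpr, tpr) operating points.
#' @export
setClass("EvalReport",
  representation(dc = "numeric", pvd = "numeric", pvdAbs = "numeric",
                 bhd95 = "numeric", auc = "numeric", roc = "data.frame"),
  validity = function(object) {
    if (object@dc < 0 || object@dc > 100) return("dc must lie in [0, 100]")
    if (object@bhd95 < 0) return("bhd95 must be >= 0")
    if (!is.na(object@auc) && (object@auc < 0 || object@auc > 1))
      return("auc must lie in [0, 1]")
    TRUE
  })

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "VoxelGrid", function(object) {
  cat(sprintf("VoxelGrid %d x %d x %d, spacing %.3g x %.3g x %.3g mm\n",
              object@dims[1], object@dims[2], object@dims[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
})

setMethod("show", "IntensityVolume", function(object) {
  cat(sprintf("IntensityVolume %d x %d x %d, range [%.4g, %.4g]\n",
              object@grid@dims[1], object@grid@dims[2], object@grid@dims[3],
              min(object@values), max(object@values)))
})

setMethod("show", "LabelMap", function(object) {
  n <- sum(object@labels)
  cat(sprintf("LabelMap %d x %d x %d, %d KT voxels (%.2f%%)\n",
              object@grid@dims[1], object@grid@dims[2], object@grid@dims[3],
              n, 100 * n / length(object@labels)))
})

setMethod("show", "ProbabilityMap", function(object) {
  cat(sprintf("ProbabilityMap %d x %d x %d, mean P(KT) = %.4f\n",
              object@grid@dims[1], object@grid@dims[2], object@grid@dims[3],
              mean(object@p)))
})

setMethod("show", "AtlasDatabase", function(object) {
  cat(sprintf("AtlasDatabase: %d co-aligned entries on a %d x %d x %d grid\n",
              length(object@entries), object@grid@dims[1],
              object@grid@dims[2], object@grid@dims[3]))
})

setMethod("show", "AffineTransform", function(object) {
  cat("AffineTransform (12 dof)\n")
  cat("  translation (mm):", signif(object@translation, 4), "\n")
  cat("  rotation (rad):  ", signif(object@rotation, 4), "\n")
  cat("  scaling:         ", signif(object@scaling, 4), "\n")
  cat("  shearing:        ", signif(object@shearing, 4), "\n")
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: DC %.2f%%, PVD %+.2f%%, BHD95 %.3f mm%s\n",
              object@dc, object@pvd, object@bhd95,
              if (is.na(object@auc)) "" else sprintf(", AUC %.4f", object@auc)))
})

setMethod("show", "PottsModel", function(object) {
  cat(sprintf("PottsModel: %d clique families\n", length(object@families)))
  print(signif(object@potentials, 4))
})
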