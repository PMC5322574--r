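## Digital kidney phantom: seeded generator of multi-subject, multi-phase
## CT-like volumes with ground-truth labels. Emulates the challenges of
## dynamic abdominal CT -- low contrast at the noncontrast phase, smooth
## intensity inhomogeneity (bias field), cortex/medulla inhomogeneity,
## nearby organs of similar intensity -- so every downstream stage can be
## benchmarked without clinical data.

#' PhantomSpec: parameters of the digital kidney phantom
#'
#' The kidney is a bean shape (ellipsoid minus a spherical notch at one pole)
#' with 2--4 interior medulla lobes. Each subject is a smooth random
#' deformation plus a small affine jitter of the canonical shape; each of the
#' three contrast phases re-renders the same anatomy with its own class means.
#'
#' @slot dims,spacing,origin grid geometry (defaults 64^3 at
#'   0.64 x 0.64 x 0.9 mm).
#' @slot halfAxes kidney ellipsoid half-axes, mm.
#' @slot concavity hilum-notch depth as a fraction in [0, 0.5] of the first
#'   half-axis.
#' @slot means 3 x 3 numeric matrix of class means, rows = phases
#'   (noncontrast, postcontrast, late), columns = (cortex, medulla,
#'   background), HU-like units.
#' @slot noiseSd additive Gaussian noise standard deviation.
#' @slot biasAmplitude amplitude of the multiplicative low-order polynomial
#'   bias field (0 disables it).
#' @slot nDistractors number of distractor ellipsoids with near-kidney
#'   intensity.
#' @slot deformMm magnitude of the inter-subject smooth deformation, mm.
#' @slot seed base seed of the spec.
#' @export
setClass("PhantomSpec",
  representation(dims = "integer", spacing = "numeric", origin = "numeric",
                 halfAxes = "numeric", concavity = "numeric",
                 means = "matrix", noiseSd = "numeric",
                 biasAmplitude = "numeric", nDistractors = "integer",
                 deformMm = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (any(object@dims < 8L)) msg <- c(msg, "dims must be >= 8 per axis")
    if (any(object@spacing <= 0)) msg <- c(msg, "spacing must be positive")
    if (object@concavity < 0 || object@concavity > 0.5)
      msg <- c(msg, "concavity must lie in [0, 0.5]")
    if (!all(dim(object@means) == c(3L, 3L)) || any(!is.finite(object@means)))
      msg <- c(msg, "means must be a finite 3 x 3 matrix (phase x class)")
    if (object@noiseSd < 0) msg <- c(msg, "noise sd must be >= 0")
    ext <- (object@dims - 5L) / 2 * object@spacing
    if (any(object@halfAxes >= ext))
      msg <- c(msg, "kidney must fit inside the grid with >= 2-voxel margin")
    if (length(msg)) msg else TRUE
  })

#' Construct a PhantomSpec
#'
#' @param difficulty preset regime: "easy" (low noise, no bias, no
#'   distractors), "moderate" (the default benchmarking condition) or "hard"
#'   (strong noise, bias and distractors). Individual arguments override the
#'   preset.
#' @param dims,spacing,origin,halfAxes,concavity,means,noiseSd,biasAmplitude
#'   see \linkS4class{PhantomSpec}.
#' @param nDistractors,deformMm,seed see \linkS4class{PhantomSpec}.
#' @return A \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(difficulty = c("moderate", "easy", "hard"),
                        dims = c(64L, 64L, 64L),
                        spacing = c(0.64, 0.64, 0.9),
                        origin = c(0, 0, 0),
                        halfAxes = c(9, 12, 16),
                        concavity = 0.3,
                        means = NULL,
                        noiseSd = NULL,
                        biasAmplitude = NULL,
                        nDistractors = NULL,
                        deformMm = NULL,
                        seed = 1L) {
  difficulty <- match.arg(difficulty)
  preset <- switch(difficulty,
    easy     = list(noiseSd = 4,  biasAmplitude = 0.05, nDistractors = 0L,
                    deformMm = 2),
    moderate = list(noiseSd = 10, biasAmplitude = 0.20, nDistractors = 2L,
                    deformMm = 3),
    hard     = list(noiseSd = 22, biasAmplitude = 0.35, nDistractors = 4L,
                    deformMm = 4))
  if (is.null(means)) {
    means <- rbind(noncontrast = c(60, 55, 40),
                   postcontrast = c(180, 90, 50),
                   late = c(120, 100, 50))
    colnames(means) <- c("cortex", "medulla", "background")
  }
  new("PhantomSpec", dims = as.integer(dims), spacing = as.numeric(spacing),
      origin = as.numeric(origin), halfAxes = as.numeric(halfAxes),
      concavity = concavity, means = means,
      noiseSd = as.numeric(noiseSd %||% preset$noiseSd),
      biasAmplitude = as.numeric(biasAmplitude %||% preset$biasAmplitude),
      nDistractors = as.integer(nDistractors %||% preset$nDistractors),
      deformMm = as.numeric(deformMm %||% preset$deformMm),
      seed = as.integer(seed))
}

#' Contrast-phase class means
#'
#' Returns the (cortex, medulla, background) mean triple of one contrast
#' phase. The defaults encode the qualitative enhancement pattern of dynamic
#' renal CT: weak kidney/background separation before contrast, strong
#' cortical enhancement (cortex much brighter than medulla) post contrast,
#' and intermediate, partially medulla-enhanced values at the late phase.
#'
#' @param phase one of "noncontrast", "postcontrast", "late".
#' @param spec a \linkS4class{PhantomSpec} supplying the mean table.
#' @return Named numeric triple (cortex, medulla, background).
#' @export
phaseContrastProfile <- function(phase, spec = phantomSpec()) {
  if (length(phase) != 1L || !phase %in% .PHASES)
    stop(sprintf("unknown phase '%s'", paste(phase, collapse = ",")),
         call. = FALSE)
  spec@means[phase, ]
}

# Physical coordinates (n x 3, mm) of every voxel of a grid, x fastest.
.gridCoords <- function(grid) {
  d <- grid@dims
  cbind(
    rep.int(seq_len(d[1]) - 1, d[2] * d[3]) * grid@spacing[1] + grid@origin[1],
    rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3]) * grid@spacing[2] +
      grid@origin[2],
    rep(seq_len(d[3]) - 1, each = d[1] * d[2]) * grid@spacing[3] +
      grid@origin[3])
}

.inEllipsoid <- function(xyz, center, halfAxes) {
  ((xyz[, 1] - center[1]) / halfAxes[1])^2 +
    ((xyz[, 2] - center[2]) / halfAxes[2])^2 +
    ((xyz[, 3] - center[3]) / halfAxes[3])^2 <= 1
}

# Smooth random per-axis displacement field (mm) on the full grid: trilinear
# upsampling of a 5^3 lattice of uniform draws, scaled to `mag` mm.
.smoothRandomField <- function(dims, mag, nCtrl = 5L) {
  Wx <- linearWeights1d(dims[1], nCtrl)
  Wy <- linearWeights1d(dims[2], nCtrl)
  Wz <- linearWeights1d(dims[3], nCtrl)
  lapply(1:3, function(k) {
    ctrl <- array(runif(nCtrl^3, -1, 1) * mag, rep(nCtrl, 3))
    applySeparable(ctrl, Wx, Wy, Wz)
  })
}

# Low-order polynomial bias field in [-1, 1], max-normalized.
.biasField <- function(grid) {
  d <- grid@dims
  nx <- seq(-1, 1, length.out = d[1])
  ny <- seq(-1, 1, length.out = d[2])
  nz <- seq(-1, 1, length.out = d[3])
  co <- runif(9, -1, 1)
  X <- array(rep.int(nx, d[2] * d[3]), d)
  Y <- array(rep.int(rep(ny, each = d[1]), d[3]), d)
  Z <- array(rep(nz, each = d[1] * d[2]), d)
  b <- co[1] * X + co[2] * Y + co[3] * Z + co[4] * X * Y + co[5] * X * Z +
    co[6] * Y * Z + co[7] * X^2 + co[8] * Y^2 + co[9] * Z^2
  b / max(abs(b), 1e-12)
}

#' Generate one phantom subject
#'
#' Produces three phase scans (noncontrast, postcontrast, late) of one
#' synthetic subject plus the shared phase-independent ground truth. The
#' generator is a pure function of \code{(spec, subjectSeed)}: identical
#' inputs give bit-identical output.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param subjectSeed integer seed of this subject.
#' @param subjectId id string (default derived from the seed).
#' @return A \linkS4class{PhantomSubject}.
#' @export
generateSubject <- function(spec, subjectSeed,
                            subjectId = sprintf("S%d", subjectSeed)) {
  grid <- VoxelGrid(spec@dims, spec@spacing, spec@origin)
  d <- spec@dims
  withLocalSeed(subjectSeed, {
    ## --- subject-specific geometry ------------------------------------
    rot <- runif(3, -0.06, 0.06)
    scl <- 1 + runif(3, -0.05, 0.05)
    trn <- runif(3, -1, 1) * min(spec@deformMm, 2)
    shr <- runif(3, -0.03, 0.03)
    defo <- .smoothRandomField(d, spec@deformMm)

    xyz <- .gridCoords(grid)
    c0 <- spec@origin + (d - 1) / 2 * spec@spacing
    A <- .affineMatrix(rot, scl, shr)
    can <- sweep(xyz, 2, c0) %*% t(A)
    can <- sweep(can, 2, c0 + trn, "+")
    can[, 1] <- can[, 1] + as.vector(defo[[1]])
    can[, 2] <- can[, 2] + as.vector(defo[[2]])
    can[, 3] <- can[, 3] + as.vector(defo[[3]])

    kid <- .inEllipsoid(can, c0, spec@halfAxes)
    if (spec@concavity > 0) {
      notchC <- c0 + c(spec@halfAxes[1], 0, 0)
      notchR <- 2 * spec@concavity * spec@halfAxes[1]
      kid <- kid & !(rowSums(sweep(can, 2, notchC)^2) <= notchR^2)
    }
    lobes <- list(c(-0.35, -0.30, -0.40), c(-0.30, 0.25, 0.05),
                  c(-0.35, -0.10, 0.45))
    med <- rep(FALSE, nrow(can))
    for (lb in lobes)
      med <- med | .inEllipsoid(can, c0 + lb * spec@halfAxes,
                                0.30 * spec@halfAxes)
    med <- med & kid

    truthArr <- array(as.integer(kid), d)
    ## >= 2-voxel margin between the kidney and the grid boundary
    if (any(truthArr[c(1, 2, d[1] - 1, d[1]), , ] == 1L) ||
        any(truthArr[, c(1, 2, d[2] - 1, d[2]), ] == 1L) ||
        any(truthArr[, , c(1, 2, d[3] - 1, d[3])] == 1L))
      stop("phantom spec error: kidney overflows the grid margin",
           call. = FALSE)

    ## --- distractor organs ---------------------------------------------
    distract <- vector("list", spec@nDistractors)
    if (spec@nDistractors > 0) {
      lim0 <- spec@origin + 4 * spec@spacing
      lim1 <- spec@origin + (d - 5) * spec@spacing
      for (k in seq_len(spec@nDistractors)) {
        for (try in 1:50) {
          ctr <- runif(3, lim0, lim1)
          if (sum(((ctr - c0) / (1.5 * spec@halfAxes))^2) > 1) break
        }
        distract[[k]] <- list(center = ctr, axes = runif(3, 3, 6))
      }
    }
    distMask <- rep(FALSE, nrow(xyz))
    for (dk in distract)
      distMask <- distMask | .inEllipsoid(can, dk$center, dk$axes)
    distMask <- distMask & !kid

    ## --- per-phase rendering -------------------------------------------
    truth <- LabelMap(truthArr, grid)
    records <- lapply(.PHASES, function(ph) {
      mu <- spec@means[ph, ]
      img <- rep(mu[["background"]], nrow(xyz))
      img[kid] <- mu[["cortex"]]
      img[med] <- mu[["medulla"]]
      if (spec@nDistractors > 0) {
        dInt <- mu[["cortex"]] * runif(1, 0.85, 1.05)
        img[distMask] <- dInt
      }
      img <- array(img, d)
      if (spec@biasAmplitude > 0)
        img <- img * (1 + spec@biasAmplitude * .biasField(grid))
      if (spec@noiseSd > 0)
        img <- img + rnorm(length(img), 0, spec@noiseSd)
      SubjectRecord(subjectId, ph, IntensityVolume(img, grid), truth)
    })
    new("PhantomSubject", subjectId = subjectId, records = records,
        truth = truth)
  })
}

#' Generate a phantom cohort
#'
#' Per-subject seeds are derived deterministically from \code{masterSeed};
#' all subjects share one grid. A leave-one-subject-out evaluation needs at
#' least two subjects.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param nSubjects number of subjects (>= 2); each contributes three scans.
#' @param masterSeed integer master seed.
#' @return List of \linkS4class{PhantomSubject}.
#' @export
generateCohort <- function(spec, nSubjects, masterSeed = spec@seed) {
  if (nSubjects < 2L)
    stop("a cohort needs at least 2 subjects (leave-one-subject-out is ",
         "undefined otherwise)", call. = FALSE)
  seeds <- deriveSeeds(masterSeed, nSubjects)
  lapply(seq_len(nSubjects), function(i)
    generateSubject(spec, seeds[i], subjectId = sprintf("S%02d", i)))
}

#' Flatten a cohort into per-scan SubjectRecords
#'
#' @param cohort list of \linkS4class{PhantomSubject}.
#' @return List of \linkS4class{SubjectRecord} (3 per subject).
#' @export
cohortRecords <- function(cohort)
  unlist(lapply(cohort, function(s) s@records), recursive = FALSE)
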