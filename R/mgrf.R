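## Higher-order Markov-Gibbs random field spatial model. The traditional
## pairwise Potts clique family on the 18-connectivity neighborhood is
## extended with collinear triple and planar 2x2 quad families; one scalar
## potential per family (applied +V when all clique labels agree, -V
## otherwise) is estimated analytically from the empirical clique-equality
## rate of an initial shape-and-intensity labeling. A single sweep of Gibbs
## conditionals then yields the per-voxel kidney/background spatial
## probability that feeds the classifier.

## The 9 unique directions of the 18-connectivity neighborhood
## (3 axis-aligned + 6 edge-diagonal; each direction and its negation define
## the same pairwise family).
.DIR18 <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 0), c(1, -1, 0), c(1, 0, 1),
                c(1, 0, -1), c(0, 1, 1), c(0, 1, -1))

#' Build the pairwise, triple and quad clique families
#'
#' Pairwise: one family per unique 18-connectivity direction (9 families).
#' Triple: collinear \{p - d, p, p + d\} along each direction (9 families).
#' Quad: unit 2x2 squares in the three axis-aligned planes (3 families).
#' Every inter-voxel step within a clique is an 18-connectivity step.
#'
#' @return List of 21 \linkS4class{CliqueFamily} objects.
#' @export
buildCliqueFamilies <- function() {
  fams <- list()
  for (i in seq_len(nrow(.DIR18))) {
    d <- .DIR18[i, ]
    nm <- paste0("(", paste(d, collapse = ","), ")")
    fams[[length(fams) + 1L]] <-
      new("CliqueFamily", order = 2L,
          offsets = cbind(c(0L, 0L, 0L), as.integer(d)),
          name = paste0("pair", nm))
  }
  for (i in seq_len(nrow(.DIR18))) {
    d <- .DIR18[i, ]
    nm <- paste0("(", paste(d, collapse = ","), ")")
    fams[[length(fams) + 1L]] <-
      new("CliqueFamily", order = 3L,
          offsets = cbind(-as.integer(d), c(0L, 0L, 0L), as.integer(d)),
          name = paste0("triple", nm))
  }
  quads <- list(
    xy = cbind(c(0L, 0L, 0L), c(1L, 0L, 0L), c(0L, 1L, 0L), c(1L, 1L, 0L)),
    xz = cbind(c(0L, 0L, 0L), c(1L, 0L, 0L), c(0L, 0L, 1L), c(1L, 0L, 1L)),
    yz = cbind(c(0L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L), c(0L, 1L, 1L)))
  for (nm in names(quads))
    fams[[length(fams) + 1L]] <-
      new("CliqueFamily", order = 4L, offsets = quads[[nm]],
          name = paste0("quad_", nm))
  fams
}

#' Pooled per-label Gaussian intensity model
#'
#' Sample mean and standard deviation of the intensity of each label, pooled
#' over all atlas entries. Degenerate (constant) classes have their sd
#' clamped to a small floor so the Gaussian stays proper.
#'
#' @param atlas an \linkS4class{AtlasDatabase} (or plain list of entries).
#' @param sdFloor lower clamp for the standard deviations.
#' @return An \linkS4class{IntensityClassModel}.
#' @export
estimateIntensityModel <- function(atlas, sdFloor = 1e-3) {
  entries <- if (is(atlas, "AtlasDatabase")) atlas@entries else atlas
  gKT <- unlist(lapply(entries, function(e)
    e$volume@values[e$labels@labels == 1L]))
  gOT <- unlist(lapply(entries, function(e)
    e$volume@values[e$labels@labels == 0L]))
  if (length(gKT) == 0L || length(gOT) == 0L)
    stop("estimation error: a label is absent from the atlas", call. = FALSE)
  means <- c(KT = mean(gKT), OT = mean(gOT))
  sds <- c(KT = max(if (length(gKT) > 1) sd(gKT) else 0, sdFloor),
           OT = max(if (length(gOT) > 1) sd(gOT) else 0, sdFloor))
  new("IntensityClassModel", means = means, sds = sds)
}

#' Initial voxel-wise labeling from shape and intensity
#'
#' Labels each voxel by the maximum of P_s(l) * N(g_p; mean_l, sd_l), the
#' product of the shape-prior probability and the class-conditional Gaussian
#' likelihood. Ties go to background (OT).
#'
#' @param volume \linkS4class{IntensityVolume} to label.
#' @param prior shape prior \linkS4class{ProbabilityMap}.
#' @param model an \linkS4class{IntensityClassModel}.
#' @return A \linkS4class{LabelMap}.
#' @export
initialLabeling <- function(volume, prior, model) {
  stopGridsCompatible(volume@grid, prior@grid, "volume and prior")
  g <- volume@values
  postKT <- prior@p * dnorm(g, model@means[["KT"]], model@sds[["KT"]])
  postOT <- (1 - prior@p) * dnorm(g, model@means[["OT"]], model@sds[["OT"]])
  LabelMap(array(as.integer(postKT > postOT), dim(g)), volume@grid)
}

## Sum of labels over the clique members anchored at each lattice site, and
## validity (all members inside the lattice). out[p] relates to the clique
## anchored at p.
.cliqueLabelSum <- function(labels, offsets) {
  s <- array(0, dim(labels))
  valid <- array(TRUE, dim(labels))
  for (j in seq_len(ncol(offsets))) {
    lj <- shiftArray(labels, offsets[, j], fill = NA)
    na <- is.na(lj)
    valid <- valid & !na
    lj[na] <- 0L
    s <- s + lj
  }
  list(sum = s, valid = valid)
}

#' Empirical clique-equality rate
#'
#' Fraction of the family's lattice-translated cliques, counting only
#' cliques fully inside the volume, whose labels are all equal.
#'
#' @param m a \linkS4class{LabelMap}.
#' @param family a \linkS4class{CliqueFamily}.
#' @return Scalar in [0, 1].
#' @export
equalityRate <- function(m, family) {
  cs <- .cliqueLabelSum(m@labels, family@offsets)
  nValid <- sum(cs$valid)
  if (nValid == 0L)
    stop("degenerate volume: no clique of this family fits inside",
         call. = FALSE)
  eq <- cs$valid & (cs$sum == 0L | cs$sum == family@order)
  sum(eq) / nValid
}

#' Analytic estimation of the Potts potentials
#'
#' Per family of order n the potential is the centred, scaled equality
#' statistic \code{V = (K^2 / (K - 1)) (F_eq - K^(1 - n))} with K = 2
#' labels: the closed-form maximum-likelihood estimate of the pairwise
#' Potts potential, extended uniformly to the triple and quad families.
#' \code{K^(1 - n)} is the equality rate of iid equiprobable labels, so iid
#' maps give potentials near zero; a constant map gives +2 for pairs and a
#' checkerboard -2.
#'
#' @param m a \linkS4class{LabelMap} (typically the initial labeling).
#' @param families clique families (default \code{\link{buildCliqueFamilies}}).
#' @return A \linkS4class{PottsModel}.
#' @export
estimatePotentials <- function(m, families = buildCliqueFamilies()) {
  K <- 2
  v <- vapply(families, function(fam) {
    (K^2 / (K - 1)) * (equalityRate(m, fam) - K^(1 - fam@order))
  }, numeric(1))
  names(v) <- vapply(families, function(f) f@name, character(1))
  new("PottsModel", families = families, potentials = v)
}

#' Gibbs conditional kidney probability
#'
#' One sweep of the Gibbs conditionals of the Potts model: for each voxel p
#' and candidate label l, the energy \code{E_p(l)} sums +V (all clique
#' labels equal under m_p := l) or -V over every clique of every family
#' containing p and fully inside the lattice; the returned map holds
#' \code{P(KT) = exp(E_p(KT)) / (exp(E_p(KT)) + exp(E_p(OT)))}.
#'
#' @param m the initial \linkS4class{LabelMap}.
#' @param model a \linkS4class{PottsModel}.
#' @return A \linkS4class{ProbabilityMap}.
#' @export
gibbsProbability <- function(m, model) {
  t0 <- proc.time()[["elapsed"]]
  lab <- m@labels
  dE <- array(0, dim(lab))   # E(KT) - E(OT)
  for (fi in seq_along(model@families)) {
    fam <- model@families[[fi]]
    V <- model@potentials[fi]
    off <- fam@offsets
    ord <- fam@order
    ## role r: the clique anchored at p - off[, r] contains p; its other
    ## members sit at p + (off[, j] - off[, r]).
    for (r in seq_len(ord)) {
      s <- array(0, dim(lab))
      valid <- array(TRUE, dim(lab))
      for (j in seq_len(ord)) {
        if (j == r) next
        lj <- shiftArray(lab, off[, j] - off[, r], fill = NA)
        na <- is.na(lj)
        valid <- valid & !na
        lj[na] <- 0L
        s <- s + lj
      }
      ## E(l) contribution: +V iff all others == l, else -V
      eqKT <- (s == (ord - 1L))
      eqOT <- (s == 0L)
      dE <- dE + valid * V * (2 * eqKT - 1 - (2 * eqOT - 1))
    }
  }
  p <- 1 / (1 + exp(-dE))
  logInfo("gibbsProbability: grid %s, %d families, %.2fs",
          paste(m@grid@dims, collapse = "x"), length(model@families),
          proc.time()[["elapsed"]] - t0)
  ProbabilityMap(p, m@grid)
}

#' Spatial probability channel from shape and intensity
#'
#' Convenience composition of the spatial model: initial labeling from the
#' shape prior and the pooled intensity model, analytic potential
#' estimation on that labeling (self-calibrated per volume), then one Gibbs
#' conditional sweep.
#'
#' @param volume \linkS4class{IntensityVolume} in atlas space.
#' @param prior its shape-prior \linkS4class{ProbabilityMap}.
#' @param intensityModel an \linkS4class{IntensityClassModel}.
#' @return List with \code{prob} (\linkS4class{ProbabilityMap}),
#'   \code{initial} (\linkS4class{LabelMap}) and \code{potts}
#'   (\linkS4class{PottsModel}).
#' @export
spatialProbability <- function(volume, prior, intensityModel) {
  m0 <- initialLabeling(volume, prior, intensityModel)
  potts <- estimatePotentials(m0)
  list(prob = gibbsProbability(m0, potts), initial = m0, potts = potts)
}
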