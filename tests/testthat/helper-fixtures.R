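# Shared fixtures and independent brute-force oracles. Expensive fixtures
# are built once per test run and memoised in `.fx`.

.fx <- new.env(parent = emptyenv())

unitGrid <- function(dims, spacing = c(1, 1, 1)) VoxelGrid(dims, spacing)

# Small random intensity volume (deterministic).
randomVolume <- function(dims, seed = 1, spacing = c(1, 1, 1)) {
  set.seed(seed)
  IntensityVolume(array(rnorm(prod(dims), 100, 25), dims),
                  VoxelGrid(dims, spacing))
}

randomLabelMap <- function(dims, seed = 1, pKT = 0.5, spacing = c(1, 1, 1)) {
  set.seed(seed)
  LabelMap(array(as.integer(runif(prod(dims)) < pKT), dims),
           VoxelGrid(dims, spacing))
}

# A small, quick phantom cohort on a coarse grid with the same physical
# field of view as the default spec (spacing doubled).
smallSpec <- function(difficulty = "easy", ...) {
  phantomSpec(difficulty, dims = c(32L, 32L, 32L),
              spacing = c(1.28, 1.28, 1.8), ...)
}

smallCohort <- function(n = 3L, seed = 9L, difficulty = "easy") {
  key <- sprintf("cohort_%d_%d_%s", n, seed, difficulty)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- generateCohort(smallSpec(difficulty), n, seed)
  .fx[[key]]
}

# Atlas database built directly from native-space records (no registration;
# phantom subjects share one grid, so this is a valid co-aligned database
# for tests that exercise the prior/MGRF/feature stages in isolation).
nativeAtlas <- function(cohort, excludeSubject = NULL) {
  recs <- cohortRecords(cohort)
  if (!is.null(excludeSubject))
    recs <- Filter(function(r) r@subjectId != excludeSubject, recs)
  entries <- lapply(recs, function(r)
    list(subjectId = r@subjectId, phase = r@phase, volume = r@volume,
         labels = r@truth))
  AtlasDatabase(entries, reference = entries[[1]]$volume,
                referenceId = "native")
}

## ---------------------------------------------------------------------------
## Independent oracles (deliberately naive; loop-based)
## ---------------------------------------------------------------------------

# Shape prior by direct triple-loop enumeration of the search cube.
bruteShapePrior <- function(test, atlasVols, atlasLabs, tau, hw0, hwMax) {
  d <- dim(test)
  out <- array(NA_real_, d)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    gt <- test[x, y, z]
    total <- 0L; kt <- 0L
    for (hw in hw0:hwMax) {
      total <- 0L; kt <- 0L
      for (a in seq_along(atlasVols)) {
        g <- atlasVols[[a]]; m <- atlasLabs[[a]]
        for (zz in max(1, z - hw):min(d[3], z + hw))
          for (yy in max(1, y - hw):min(d[2], y + hw))
            for (xx in max(1, x - hw):min(d[1], x + hw))
              if (abs(g[xx, yy, zz] - gt) <= tau) {
                total <- total + 1L
                kt <- kt + m[xx, yy, zz]
              }
      }
      if (total > 0L) break
    }
    out[x, y, z] <- if (total > 0L) kt / total else 0.5
  }
  out
}

# All cliques of a family inside a lattice: list of `order`-row index
# matrices (1-based voxel coordinates).
enumerateCliques <- function(dims, family) {
  off <- family@offsets
  cliques <- list()
  for (z in 1:dims[3]) for (y in 1:dims[2]) for (x in 1:dims[1]) {
    vox <- cbind(x + off[1, ], y + off[2, ], z + off[3, ])
    if (all(vox >= 1) && all(vox[, 1] <= dims[1]) &&
        all(vox[, 2] <= dims[2]) && all(vox[, 3] <= dims[3]))
      cliques[[length(cliques) + 1L]] <- vox
  }
  cliques
}

bruteEqualityRate <- function(lab, family) {
  cl <- enumerateCliques(dim(lab), family)
  eq <- vapply(cl, function(vox) {
    v <- lab[vox]
    all(v == v[1])
  }, logical(1))
  mean(eq)
}

# Gibbs conditional P(KT) by brute-force enumeration of both label
# hypotheses over every clique containing each voxel.
bruteGibbs <- function(lab, model) {
  d <- dim(lab)
  cliquesByFam <- lapply(model@families, function(f) enumerateCliques(d, f))
  eKT <- array(0, d); eOT <- array(0, d)
  for (fi in seq_along(model@families)) {
    V <- model@potentials[fi]
    for (vox in cliquesByFam[[fi]]) {
      for (r in seq_len(nrow(vox))) {
        p <- vox[r, , drop = FALSE]
        others <- vox[-r, , drop = FALSE]
        ov <- lab[others]
        eKT[p] <- eKT[p] + V * (if (all(ov == 1L)) 1 else -1)
        eOT[p] <- eOT[p] + V * (if (all(ov == 0L)) 1 else -1)
      }
    }
  }
  1 / (1 + exp(eOT - eKT))
}

# Neighborhood mean by explicit neighbor loops.
bruteNeighborhoodMean <- function(arr, offsets) {
  d <- dim(arr)
  out <- array(NA_real_, d)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    vals <- c()
    for (j in seq_len(ncol(offsets))) {
      q <- c(x, y, z) + offsets[, j]
      if (all(q >= 1 & q <= d)) vals <- c(vals, arr[q[1], q[2], q[3]])
    }
    out[x, y, z] <- if (length(vals)) mean(vals) else arr[x, y, z]
  }
  out
}

bruteConfusion <- function(g, s) {
  tp <- 0L; fp <- 0L; fn <- 0L; tn <- 0L
  for (i in seq_along(g)) {
    if (g[i] == 1L && s[i] == 1L) tp <- tp + 1L
    else if (g[i] == 0L && s[i] == 1L) fp <- fp + 1L
    else if (g[i] == 1L && s[i] == 0L) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Directed percentile Hausdorff by O(|G||S|) scan.
bruteDirectedHD <- function(from, to, spacing, percentile) {
  dmin <- numeric(nrow(from))
  for (i in seq_len(nrow(from))) {
    best <- Inf
    for (j in seq_len(nrow(to))) {
      dd <- sqrt(sum(((from[i, ] - to[j, ]) * spacing)^2))
      if (dd < best) best <- dd
    }
    dmin[i] <- best
  }
  sort(dmin)[max(1, ceiling(percentile * length(dmin)))]
}

# AUC as the normalized Mann-Whitney pairwise-comparison count.
bruteAUC <- function(y, p) {
  pos <- p[y == 1L]; neg <- p[y == 0L]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}
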