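# RenalSeg

Automated 3D kidney segmentation for dynamic (multi-phase contrast)
abdominal CT, in R. The framework classifies every voxel with a random
forest whose features fuse three channels — first-order appearance, an
adaptive appearance-conditioned probabilistic shape prior, and a
higher-order Markov–Gibbs random field (MGRF) spatial probability — so that
it can separate kidney from background even where intensity alone cannot:
noncontrast phases with low contrast, inhomogeneous cortex/medulla
parenchyma, bias fields, and adjacent organs of similar intensity.

It is aimed at researchers in medical image analysis who need a complete,
reproducible multi-atlas + classifier segmentation pipeline — registration,
atlas selection, priors, classification, postprocessing, evaluation — that
runs end to end on a desk machine against a built-in digital phantom
cohort, with every stage exposed as a documented function.

## The model

Voxels `p` of a CT volume `g` on the lattice `R` receive labels
`m_p ∈ {KT, OT}` (kidney / other tissue). Three probability-bearing
channels feed a 9-feature descriptor (each channel contributes its local
value, its 26-neighbour cube mean and its 8-neighbour in-plane mean):

* **Appearance** — Hounsfield-like intensities, min–max normalized.
* **Adaptive shape prior** (per voxel, over the N = 19 NCC-top-ranked
  co-aligned atlas scans):

      P_s:p(KT) = (1 / v_p) Σ_i Σ_{ρ ∈ v_i:p} δ(KT − m_i:ρ),

  where `v_i:p` collects atlas voxels inside a search cube `C_p` whose
  intensity lies within τ of the test voxel's, and `v_p` is their total
  count — an atlas prior conditioned on appearance, updated for every test
  volume.
* **MGRF spatial probability** — a Potts-type model on the 18-connectivity
  neighbourhood with pairwise, collinear-triple and planar-quad clique
  families; one potential per family, estimated analytically as
  `V = (K²/(K−1)) (F_eq − K^(1−n))` (K = 2) from the clique-equality rate
  of an initial shape-and-intensity labeling, then turned into per-voxel
  Gibbs conditionals `P_G:p(KT)`.

A 400-tree bagged forest votes per voxel; vote fraction = P(KT), labels by
the 0.5 majority rule, followed by a 3D median filter. Accuracy is reported
as Dice coefficient (DC, %), percentage volume difference
(PVD = 100 (|G| − |S|)/|G|), the bidirectional 95th-percentile Hausdorff
distance (BHD95, mm) between surface voxels, and ROC/AUC from the
probability maps.

## Worked example

Generate a small phantom cohort, segment one scan with an atlas built from
the other subjects, and score it:

```r
library(RenalSeg)

spec   <- phantomSpec("easy", dims = c(32L, 32L, 32L),
                      spacing = c(1.28, 1.28, 1.8))
cohort <- generateCohort(spec, 3, masterSeed = 5)

config <- pipelineConfig(nAtlas = 6L, nTrees = 60L,
                         trainCapPerClass = 400L, seed = 7L)
ref    <- Filter(function(r) r@phase == "postcontrast",
                 cohort[[2]]@records)[[1]]
atlas  <- buildAtlas(cohortRecords(cohort[-1]), ref, config)

seg <- segmentVolume(cohort[[1]]@records[[2]]@volume, atlas, config)
evaluateSegmentation(cohort[[1]]@truth, seg$labels, seg$probability)
```

```
EvalReport: DC 94.71%, PVD -8.51%, BHD95 1.280 mm, AUC 1.0000
```

DC is the volumetric overlap with the phantom's ground truth; the negative
PVD says the segmentation slightly over-covers the true kidney volume (by
8.5 % of it); BHD95 says 95 % of boundary voxels sit within 1.3 mm (one
in-plane voxel at this coarse test grid) of the true surface; AUC 1 means
the vote fractions rank every kidney voxel above every background voxel. A full cross-validated benchmark is one call:
`losoEvaluate(cohort, config)` scores every scan of every subject with that
subject's data held out of atlas, prior and training.

The same pipeline is scriptable through the bundled CLI
(`inst/exec/renalseg`): `phantom`, `register`, `shape-prior`, `mgrf-prob`,
`segment`, `evaluate` and `loso` subcommands over NIfTI files.

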