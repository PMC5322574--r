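---
title: "Spatial-appearance kidney segmentation: models, parameters and design choices"
author: "RenalSeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial-appearance kidney segmentation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(RenalSeg)
```

# The problem

Segmenting the kidney in dynamic (multi-phase contrast) abdominal CT is hard
for reasons that compound each other: the organ is internally inhomogeneous
(enhancing cortex versus darker medulla), neighbouring organs can share its
intensity range, the intensity of every tissue drifts across the contrast
phases as the agent transits, and scanner bias fields add smooth
inhomogeneity on top. A classifier that looks at intensity alone therefore
cannot separate kidney from background at every phase; a rigid shape
template cannot absorb the anatomical variability between subjects.

RenalSeg addresses this with a voxel-wise random-forest classifier whose
features combine three complementary channels:

1. **First-order appearance** — the local Hounsfield-like intensity plus two
   regional summaries (the mean over the 26-neighbour cube and the mean over
   the 8 in-plane neighbours).
2. **Adaptive shape prior** — a probabilistic atlas that is conditioned on
   appearance at query time (details below), again as local value, cube mean
   and in-plane mean.
3. **Higher-order spatial (MGRF) probability** — a Gibbs conditional
   probability derived from a Potts-type Markov–Gibbs random field with
   pairwise, triple and quad clique families, again in the three regional
   flavours.

That yields a 9-dimensional descriptor per voxel. A bagged forest of
decision trees with random feature subsetting (3 of 9 per split) votes per
voxel; the vote fraction is the kidney probability, a 0.5 majority
threshold gives the labels, and a 3D median filter smooths the result.

# The adaptive shape prior

All training scans are co-aligned into a common atlas space (see
Registration). For a test volume $g_t$, the $N$ most similar atlas scans are
selected by normalized cross correlation. The prior at voxel $p$ is then
built from *appearance-matched* atlas voxels: inside a search cube $C_p$
around $p$, an atlas voxel $\rho$ of scan $i$ contributes its label whenever
$|g_{i:\rho} - g_{t:p}| \le \tau$, and

$$P_{s:p}(\mathrm{KT}) \;=\; \frac{1}{v_p}\sum_{i=1}^{N}\ \sum_{\rho \in
\mathbf{v}_{i:p}} \delta(\mathrm{KT} - m_{i:\rho}),$$

the fraction of matched voxels carrying the kidney label, with $v_p$ the
total number of matches pooled over all selected scans with equal weight.
The conditioning on intensity is what makes the prior *adaptive*: at a
given location it asks "what label do atlas voxels with an intensity like
mine carry around here?", which lets one prior serve all three contrast
phases.

Two degenerate situations need a rule. If no atlas voxel matches within
$\tau$ at the initial cube size, the cube grows one voxel per side at a
time (3×3×3 up to 11×11×11); if the match set is still empty at the
maximum size, the prior falls back to the uninformative value 0.5. The
growth rule keeps the prior as local as the data allow; the fallback keeps
it defined everywhere, so $P(\mathrm{KT}) + P(\mathrm{OT}) = 1$ holds
unconditionally.

Parameter defaults (all exposed in `shapePriorParams()` /
`pipelineConfig()`):

* $\tau$ = 50 intensity units. The similarity threshold controls how
  strictly "like mine" is interpreted; 50 spans roughly half the
  cortex–background contrast of the postcontrast phantom phase, wide
  enough to match across moderate noise (sd 10) and bias, narrow enough to
  keep cortex and background apart.
* Cube half-widths 1 to 5 voxels. At 0.64–0.9 mm spacing the initial cube
  is under 2 mm across — genuinely local — and the 11-voxel ceiling stays
  well below the kidney diameter.
* $N$ = 19 selected scans, the study-protocol value. With fewer available
  scans (small cohorts) the caller passes a smaller `nAtlas`; selection
  degenerates gracefully to "all available" and the leave-one-subject-out
  driver refuses configurations where `nAtlas` exceeds the remaining
  scans.

# The higher-order spatial model

Label interactions are modelled by a Markov–Gibbs random field of Potts
type over the 18-connectivity neighbourhood, extended beyond the
traditional pairwise cliques:

* **pairwise** families — one per unique 18-neighbourhood direction
  (3 axis-aligned + 6 edge-diagonal = 9 families);
* **triple** families — collinear $\{p-d, p, p+d\}$ along the same 9
  directions;
* **quad** families — unit 2×2 squares in the three axis-aligned planes.

These are the minimal translation-invariant clique shapes consistent with
18-connectivity; richer geometries would add parameters without adding
information at the phantom's smoothness scale. Each family $a$ of order $n$
carries one scalar potential applied as $+V_a$ when all clique labels
agree and $-V_a$ otherwise. The potentials are estimated *analytically*
from the empirical clique-equality rate $F_a$ of an initial labeling:

$$V_a = \frac{K^2}{K-1}\left(F_a - K^{1-n}\right), \qquad K = 2,$$

the closed-form maximum-likelihood estimate for the pairwise Potts model,
applied uniformly to orders 3 and 4. $K^{1-n}$ is the equality rate of iid
equiprobable labels, so the estimator is centred: iid noise gives
$V \approx 0$, a constant map gives $+2$ for pairs, a checkerboard $-2$ —
anchors the test suite verifies exactly. Potentials are re-estimated per
test volume from its own initial labeling (self-calibration) rather than
frozen at training time, so the spatial model adapts to each scan's
geometry.

The initial labeling itself is the voxel-wise maximiser of
$P_{s:p}(l)\,\mathcal{N}(g_p;\mu_l,\sigma_l)$ — shape prior times a
Gaussian class likelihood whose moments are pooled from the selected atlas
scans (ties go to background; degenerate class variances are clamped to
$10^{-3}$). One sweep of Gibbs conditionals then converts labels to
probabilities: for both hypotheses at $p$ the clique energies are summed
over every clique containing $p$ (cliques crossing the volume border are
skipped — free boundary — in both estimation and the conditional sums), and

$$P_{G:p}(\mathrm{KT}) = \frac{e^{E_p(\mathrm{KT})}}
{e^{E_p(\mathrm{KT})} + e^{E_p(\mathrm{OT})}}.$$

No iterated conditional modes follow: the map's role is to supply a
spatial-context feature channel for the forest, not a standalone
segmentation.

# Registration

Co-alignment is two-step and coarse-to-fine: a 12-dof affine transform
(translation, rotation, anisotropic scale, shear, all about the volume
centre) followed by a cubic B-spline free-form deformation. Design choices
where the method family leaves room:

* **Similarity objective**: normalized cross correlation for both steps,
  matching the NCC used for atlas ranking. NCC is insensitive to the
  global intensity shifts the contrast phases induce, which matters because
  noncontrast scans register onto a postcontrast reference.
* **Optimizer**: the affine step uses a multi-resolution pyramid
  (block-mean downsampling by 4 then 2, optionally 1), a translation-only
  Nelder–Mead warm start at the coarsest level, and BFGS with numerical
  gradients thereafter. The default stops at half resolution: the optimum
  there is already sub-voxel (the test suite asserts synthetic translation
  recovery within half a voxel), and the final level triples the cost. The
  full pyramid is one argument away and is used for the recovery-accuracy
  checks.
* **B-spline step**: control points every 8 voxels, optimized by gradient
  ascent on NCC with the analytic chain-rule gradient (image gradient ×
  B-spline basis), on a half-resolution grid. The update is guarded: if no
  step improves on the affine initialization, the zero field is returned,
  so the deformation never worsens the objective.
* **Reference frame**: the first training subject's postcontrast scan
  anchors the atlas space of each fold (postcontrast has the strongest
  structure for NCC). Nothing in the method depends on which scan anchors;
  the leave-one-subject-out driver re-anchors per fold so the test subject
  never defines the space.
* **Label propagation** uses nearest-neighbour resampling only; the final
  label/probability maps are mapped back to the scan's native grid through
  the exact affine inverse composed with a damped fixed-point inversion of
  the (small, smooth) B-spline displacement.

# The digital phantom

No public accession exists for the kind of multi-phase clinical cohort the
method targets, so the package ships a seeded phantom generator that
reproduces the *challenges* of such data rather than its photometric
detail:

* a bean-shaped kidney (ellipsoid of half-axes 9 × 12 × 16 mm minus a
  spherical hilum notch, depth fraction 0.3) with three interior medulla
  lobes;
* three contrast phases re-rendering one fixed anatomy —
  noncontrast (cortex 60 / medulla 55 / background 40: low contrast),
  postcontrast (180 / 90 / 50: strong cortical enhancement, maximal
  cortex–medulla inhomogeneity), late (120 / 100 / 50: intermediate, with
  partial medulla enhancement);
* a smooth multiplicative bias field (low-order polynomial, amplitude 0.2
  by default) emulating intensity inhomogeneity;
* additive Gaussian noise (sd 10 by default, about one fifth of the
  postcontrast kidney–background contrast);
* distractor ellipsoids at 85–105 % of cortex intensity, emulating
  adjacent organs of similar intensity;
* inter-subject variation via a smooth random displacement field (3 mm
  scale) plus small affine jitter (≤ ±6 % scale, ≤ ±0.06 rad, ≤ 2 mm
  shift), which is what gives the registration stage real work.

The `easy` / `moderate` / `hard` presets move noise, bias, distractor
count and deformation together; `moderate` is the benchmarking condition
used throughout. The generator is a pure function of `(spec, seed)` and the
truth map is phase-invariant by construction.

What the phantom does *not* model — and hence what passing benchmarks do
not demonstrate — includes partial-volume effects at the kidney boundary,
beam hardening and streak artifacts, perfusion pharmacokinetics (phases
differ only by class means), textured parenchyma, and anatomy beyond
"ellipsoidal distractors". Results on it certify the machinery
(registration recovery, prior correctness, classifier integration), not
clinical accuracy.

# Problem sizes and numerical choices

The benchmark configuration used by the test suite and the acceptance
script is a 6-subject, 64³ cohort at 0.64 × 0.64 × 0.9 mm spacing —
18 scans, leave-one-subject-out, `nAtlas = 15` (all available scans per
fold; 19 is impossible with 15 candidates), 400 trees, and a stratified
per-scan training cap of 1500 kidney voxels plus an equal background
sample. The cap is what keeps a full LOSO run at desk scale; phantom
kidneys contain ~15–20 k voxels, so the cap subsamples the kidney class
about tenfold while preserving class balance. Registrations are cached
across folds (a scan registers to a given reference once), and within a
fold the per-scan training features and the forest are memoised across the
fold's three test scans.

Other numerical rules worth knowing:

* Training-scan shape priors are computed against the selected entries *of
  other subjects*, mirroring the leave-one-subject-out condition the test
  scan experiences, so the shape feature has the same distribution at
  train and test time.
* Grid compatibility is enforced everywhere with a relative spacing
  tolerance of $10^{-6}$; no operation silently mixes geometries.
* Min–max appearance normalization maps a constant column to zeros with a
  warning (the degenerate case of the affine rescale).
* The forest's vote-fraction ties (exactly 0.5) label kidney, so
  thresholding the probability map at 0.5 reproduces the label map
  exactly.
* PVD is kept signed per scan (positive = under-segmentation) with the
  magnitude reported alongside; cohort summaries use the magnitude.
* Hausdorff distances are measured between surface-voxel centres
  (6-connectivity boundary) in physical millimetres with the nearest-rank
  percentile rule; percentile 1.0 recovers the classical maximum.
* RNG discipline: every stochastic component (phantom, training
  subsampling, forest) draws from locally seeded streams derived from the
  caller's seeds, and the global RNG state is restored afterwards, so any
  seeded run is bit-reproducible.

# Known limitations

* The B-spline registration optimizes on a half-resolution grid with a
  modest iteration budget; it reliably improves on the affine alignment
  but is not a diffeomorphic or inverse-consistent method, and its
  fixed-point inverse is approximate (adequate for the small fields it
  produces).
* The MGRF potential estimator extends the pairwise closed form uniformly
  to triples and quads; it is exact at the iid and constant anchors but is
  an approximation, not the per-order maximum-likelihood solution.
* Pooling all phases in atlas selection and forest training follows the
  study protocol, but on data with stronger phase-specific appearance a
  phase-matched variant may be preferable; the selection function accepts
  any entry subset.
* With very small cohorts (2–3 subjects) the shape prior's consensus is
  weak and accuracy degrades gracefully rather than failing loudly — the
  difficulty-ladder test tracks exactly this monotone degradation.
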