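---
title: "Surrogate-driven internal motion estimation: methods and design notes"
author: "respicor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate-driven internal motion estimation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respicor)
```

# The model and its assumptions

`respicor` estimates the motion of internal thoracic structures
(tumor, lung surface) from the motion of the external torso surface.
The premise is clinical: during radiotherapy the external surface can
be watched continuously and without dose by optical cameras, while the
internal anatomy cannot. If the internal–external relationship learned
from a planning 4DCT still holds at treatment time, internal motion
can be inferred from the surface alone.

The model is linear and phase-based. All motion is expressed as
deformation vector fields (DVFs) relative to the mid-position (MidP)
reference — the per-vertex time average over the breathing cycle. For
phase $j$ the composite vector

$$d_j = [\,I_j;\; S_{1,j}, A_{1,j};\; \dots;\; S_{N,j}, A_{N,j}\,]$$

stacks the internal per-vertex DVF $I_j$ (3M entries, vertex-major
x, y, z) with, per external patch, the phasic patch DVF $S_{n,j}$ and
the directional DVF $A_{n,j} = S_{n,j} - S_{n,j-1}$. The centered
composite matrix $D$ (columns $d_j - \bar d$) is decomposed by PCA,
computed through the small $J \times J$ Gram matrix $D^\top D$ rather
than the large covariance $D D^\top$ — mapping Gram eigenvectors $X$
through $D$ gives the covariance eigenvectors $DX$ with the same
nonzero eigenvalues. Splitting the retained eigenbasis $E$ into its
internal rows $E_I$ and external rows $E_S$ and eliminating the mode
weights yields the correlation operator $B = E_I E_S^{+}$, and the
prediction $\tilde I(t) = B\,(s(t) - \bar d_S)$.

Assumptions worth keeping in mind:

- **Stable breathing.** The model is a fixed linear map learned from
  one cycle; it has no notion of drifting or irregular breathing
  beyond what re-basing (below) absorbs.
- **Corresponded surfaces.** Every phase mesh shares vertex indexing
  with every other phase. In this package correspondence is exact by
  construction (the phantom) or provided by a pluggable
  `correspondVertices()` provider; a registration algorithm would fill
  this role on real data and its errors would propagate into the
  model.
- **Phase-indexed motion.** Training and prediction are indexed by
  breathing phase fraction, not wall-clock time, so a change of period
  between cycles is invisible to the model — by design.

## Why the directional term matters

Real breathing is hysteretic: the surface configuration at a given
amplitude differs between inhale and exhale. A purely phasic external
signal of a (near-)rank-one surface motion pattern cannot distinguish
the two branches, and any internal motion component in temporal
quadrature with the surface signal is unobservable through it. The
directional DVFs restore observability: a cyclic difference of
samples of one sinusoid contains the quadrature sinusoid (
$\cos\theta_j - \cos\theta_{j-1}$ has a $\sin\theta_j$ component), so
the `SurMod` external block spans both temporal phases. The phantom
encodes exactly this situation (ML tumor motion in quadrature with the
AP/SI surface signal), and the test suite checks the consequence: the
phasic-only variants fail in ML, `SurMod` does not.

# Tunable parameters

| parameter | default | units | notes |
|---|---|---|---|
| `K` (modes) | $J-1$ = 9 | — | the maximum permitted; numerically zero eigenvalues (below $10^{-12}\lambda_1$) are dropped afterwards, so the retained count adapts to the data's true rank. `chooseK()` offers variance-fraction selection (e.g. 95%) as a non-default alternative. |
| patch grid | 14 × 11 | — | 14 SI × 11 ML uniform bins on the anterior surface = 154 patches; empty patches are excluded with a warning. |
| `roiCount` | 10 | — | `RoiMod` patch count, chosen by largest mean displacement magnitude (ties by patch id). The historically used patch locations are not recoverable, so amplitude ranking is this package's documented surrogate. |
| voxel spacing | 2.0 × 2.0 × 2.5 | mm | mask resolution for all volume metrics. |
| `noiseSigma` | 0 | mm | optional Gaussian vertex jitter on the emitted phantom meshes, emulating surface-registration error. Masks are always voxelized from the noise-free geometry: they play the role of contoured ground truth. |
| mesh density | ~1500 | vertices/structure | balances surface detail against runtime; the correlation model itself is insensitive to density on the smooth phantom. |

# The synthetic phantom

The phantom replaces an anthropomorphic software phantom with nested
analytic ellipsoids: a torso shell, one lung, and a spherical tumor in
the inferior lung. Only the motion structure is treated as normative;
the anatomy is deliberately simple.

Per cycle (period $T$ s, surface amplitude $H$ mm), the tumor centroid
moves by

$$\begin{aligned}
\mathrm{ML}(t) &= (H/10)\,\sin(2\pi/T\,(t - T/2))\\
\mathrm{AP}(t) &= (H/10)\,(\sin(2\pi/T\,(t - T/4)) + 1)\\
\mathrm{SI}(t) &= (H/2)\,(\sin(2\pi/T\,(t - T/4)) + 1)
\end{aligned}$$

sampled at $t_j = (j-1)T/J$, $J = 10$. The five standard cycles use
$(T, H, \text{diam}) =$ (5, 12, 30), (4.5, 10, 30), (5.5, 14, 30),
(4.5, 8, 20), (6, 16, 20); cycle 1 trains, 2–3 test intra-fraction,
4–5 test inter-fraction with a shrunk tumor.

Design choices that were genuinely open:

- **Spatial gain fields.** How the surface amplitude $H$ distributes
  over the torso is a modeling choice: here the anterior wall carries
  the maximum (AP peak-to-peak equals $H$ at the anterior pole, since
  the AP trajectory component has peak-to-peak $H/5$ the anterior gain
  is 5), tapering linearly to zero at the posterior couch side; the
  lung moves mostly in SI with the largest gain at the diaphragm
  (inferior pole) and small constant AP/ML gains. Every structure's
  displacement is a per-vertex scalar gain times the shared trajectory
  components, so internal and external motion share the temporal
  structure the model assumes — and the phasic DVF matrix of any
  structure has rank exactly 2 (the two sinusoid phases), which the
  property tests assert.
- **Phase sampling.** $J = 10$ uniform samples of one period; 4DCT
  sorting provides no timestamps, so uniformity is assumed.
- **External surface extent.** The full torso ellipsoid is emitted;
  the patch grid restricts itself to anterior-facing vertices (outward
  normal with positive AP component), which excludes the couch-contact
  region naturally.

What the phantom does *not* emulate: irregular or drifting breathing,
cardiac motion, surface-registration error structure (the optional
jitter is i.i.d. Gaussian, real registration errors are spatially
correlated), CT intensities, and anatomically realistic shapes.
Passing the phantom suites therefore demonstrates the correctness and
internal consistency of the machinery — not clinical accuracy. On the
noiseless phantom the intra-fraction predictions are near-exact, so
the measured tracking errors sit far below what is achievable on real
data; they are meaningful as upper-bound checks on the pipeline, not
as clinical claims.

# Evaluation protocols

- `phantom_intra`: fit on cycle 1; predict every phase of cycles 2–3
  from external DVFs measured against the *training* MidP (same
  anatomy, changed period/amplitude). The amplitude change introduces
  a small baseline offset in the observed signal; part of it is
  misattributed by the linear model to the quadrature mode, which is
  the dominant (sub-0.1 mm) error source on the noiseless phantom.
- `phantom_inter` / `inter_4dct`: before prediction the model is
  re-based (`rebaseModel()`): the stored MidP anatomy is replaced by
  the test fraction's own MidP meshes and the composite mean is reset
  (observations are measured from the new MidP, whose phase mean
  vanishes), while the operator $B$ is kept. This mirrors the clinical
  update of registering treatment-day anatomy to the planning CT.
- `loo_intra`: leave one phase out, fit on the remaining $J-1$
  ($K \le J-2$), score the held-out phase. The directional term of the
  held-out phase uses the cyclic previous phase of the full sequence.

All protocols score center-of-mass error, Dice, percent error,
Hausdorff distance and per-direction centroid errors per phase, and
summaries are always recomputed from the stored per-phase values.

# Numerical choices

- **$E_S^{+}$.** The eigenbasis external block is rectangular, so the
  "inverse" in the prediction operator is the Moore–Penrose
  pseudo-inverse with singular values truncated below
  $10^{-10}\sigma_{\max}$ — equivalently, least-squares estimation of
  the mode weights from the observation. Rank deficiency (routine for
  phasic-only variants on low-rank motion) triggers a warning and is
  regularized by the truncation. $B$ is invariant under rescaling of
  the eigenbasis columns, so eigenvector normalization cannot affect
  predictions (tested).
- **Eigenvector convention.** Unit norm; sign fixed so the
  largest-magnitude entry is positive; near-degenerate eigenvalues
  warn and keep the symmetric eigensolver's deterministic order.
- **Zero-mode dropping.** Eigenpairs below $10^{-12}\lambda_1$ are
  discarded before normalization: their eigenvectors are numerical
  noise and would contaminate $E_S^{+}$.
- **Directional wraparound.** $A_1 = S_1 - S_J$: breathing phases are
  cyclic and this choice gives the exact telescoping invariant
  $\sum_j A_j = 0$.
- **Voxelization.** A voxel is foreground iff its center lies inside
  the closed surface, decided by parity of $+z$ ray crossings; ray
  origins carry a fixed $10^{-4}$-of-spacing offset so rays do not hit
  mesh edges of surfaces in general position. Watertightness (every
  undirected edge shared by exactly two opposed faces) is checked
  first and violations are reported by name.
- **Patch binning.** A vertex exactly on a bin boundary goes to the
  lower-index bin.
- **Metrics.** Overlap metrics are computed on the ground-truth grid
  (nearest-neighbor resampling if grids differ); boundary points use
  the 6-connectivity face rule; Hausdorff is the exact max–min form
  (no percentile variant); volume centroids are unweighted.

# Problem sizes

The default study uses ~1500 vertices per structure, $J = 10$ phases,
five cycles, and 2.0 × 2.0 × 2.5 mm masks; a full intra-fraction
evaluation of one variant on both structures runs in well under a
minute on one CPU. The unit-test fixtures use ~300-vertex meshes,
which exercise every code path at a fraction of the cost; the
acceptance script always runs the full default sizes.

# Known limitations

- Linear, phase-indexed, single-fraction model: no online update, no
  forward prediction for camera latency, no nonlinear correlation.
- Correspondence is assumed given; the nearest-neighbor provider is
  only adequate for mild perturbations of aligned surfaces.
- The inter-fraction update is baseline re-centering only; systematic
  anatomical deformation between fractions beyond the new MidP is not
  re-learned.
- The voxelizer requires watertight meshes; a predicted surface that
  self-intersects heavily after an extreme extrapolation could produce
  ray-parity artifacts (unpaired crossings are dropped with a
  warning).
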