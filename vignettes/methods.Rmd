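---
title: "Gram-trajectory fall detection: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gram-trajectory fall detection: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gramfall)
```

## The model

A monitored person's pose in frame $t$ is an $n \times 2$ matrix $V_t$ of
joint image coordinates. `gramfall` classifies a whole sequence
$V_1, \dots, V_m$ as a fall or a daily activity in four steps.

**Gram embedding.** Each frame becomes $G_t = V_t V_t^\top$, an
$n \times n$ positive semidefinite matrix of rank at most 2, i.e. a point
on the fixed-rank manifold $S^+(2, n)$. The map is invariant under
$V_t \mapsto V_t Q$ for any $2 \times 2$ orthogonal $Q$: what survives is
the configuration's shape-and-scale, not its in-plane orientation. Raw
pixel coordinates would additionally make the representation depend on
where the subject stands in the image, so the default preprocessing
centroid-centers every frame first; centering is a switch
(`center_frames()`, mode `"none"`) because the uncentered variant of the
embedding is still well defined. Scale is deliberately *not* normalized by
default: a body collapsing to the floor genuinely changes apparent
configuration scale, and that is signal, not nuisance. A
unit-Frobenius-norm option (`scale_frames()`) exists for cameras with
strong zoom variation.

**Frame distance.** Two embedded frames are compared with the Bures-type
Riemannian distance

$$ d(G_1, G_2) \;=\; \sqrt{\operatorname{tr} G_1 + \operatorname{tr} G_2
   - 2\,\operatorname{tr}\!\big( (G_1^{1/2} G_2 G_1^{1/2})^{1/2} \big)}, $$

which for Gram matrices of 2-column configurations equals the orthogonal
Procrustes distance $\min_{Q \in O(2)} \lVert V_1 Q - V_2 \rVert_F$. The
minimizer is $Q^\ast = A U^\top$ where $V_1^\top V_2 = A \Sigma U^\top$ is
the SVD, and the minimum has the closed form
$\sqrt{\lVert V_1\rVert_F^2 + \lVert V_2\rVert_F^2 - 2(\sigma_1+\sigma_2)}$.
Both routes are implemented (`bures_distance()`, `procrustes_distance()`)
and the test suite holds them to $10^{-8}$ relative agreement over random
configurations, with a $10^4$-point brute-force grid over $O(2)$ as a third,
assumption-free referee. The pipeline itself uses the Procrustes form: for
2D landmarks the nuclear norm of the $2\times 2$ product $V_1^\top V_2$ is
$\sqrt{\lVert M\rVert_F^2 + 2\lvert\det M\rvert}$, so an entire
$\tau_1 \times \tau_2$ frame-distance matrix reduces to a handful of dense
matrix products (`frame_distance_matrix()`). A rotation-only variant
(alignment restricted to $SO(2)$, reflections not quotiented) is available
behind the `rotation_only` flag but is not the default, because the closed
form above optimizes over the full orthogonal group.

**Sequence alignment.** The frame-distance matrix feeds standard DTW:
$M(0,0)=0$, first row and column $+\infty$, and
$M(i,j) = D(i,j) + \min\{M(i,j{-}1), M(i{-}1,j{-}1), M(i{-}1,j)\}$, with
the sequence distance $D_{\mathrm{DTW}} = M(\tau_1, \tau_2)$. DTW absorbs
*local* speed variation by letting one frame align to several, yet the
total still accumulates over at least $\max(\tau_1, \tau_2)$ steps, so a
half-second fall and a four-second lying-down remain far apart — which is
precisely the discriminative signal for falls, whose kinematic signature is
acceleration rather than final pose.

**Kernel and classifier.** Sequence distances become similarities through
a Gaussian kernel $k(i,j) = \exp(-D_{\mathrm{DTW}}(i,j)^2 / 2\sigma^2)$,
and each sequence is represented by its vector of similarities to the
training sequences. A linear soft-margin SVM on these similarity-feature
vectors separates fall (positive class) from non-fall. Because the feature
vectors are ordinary Euclidean vectors, no positive semidefiniteness of
the DTW kernel is required; an eigenvalue-clipping repair
(`repair_kernel()`) is provided for anyone wanting a precomputed-kernel
SVM instead.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `centering` | `"centroid"` | — | removes image-position dependence of the Gram embedding; `"joint:<id>"` and `"none"` available |
| `imputation` | `"linear"` | — | preserves sequence length, which DTW totals depend on; `"hold"` and `"drop_frame"` available |
| `confidence_threshold` | 0.1 | — | JSON keypoints below this detector confidence count as missing |
| `sigma` | median heuristic | DTW-distance units (pixel·frames) | puts the kernel's active range at the typical inter-sequence distance; always echoed to output |
| `half_factor` | `FALSE` | — | optional 1/2 kernel prefactor; a monotone rescaling the SVM absorbs |
| `square_distance` | `TRUE` | — | standard Gaussian kernel; `FALSE` uses the unsquared distance |
| `accumulation_mode` | `"distance"` | — | DTW accumulates raw frame distances and the kernel is applied once at sequence level; `"literal_kernel"` accumulates frame-level kernel values instead (kept for reproduction of that reading — under a min-recursion it *minimizes* similarity, so it is not the default) |
| `path_normalization` | `"none"` | — | dividing by warping-path length removes the length signal; off by default because sequence length carries the fall/non-fall contrast |
| `C` | 1 | — | SVM soft-margin cost; class weights off by default |

## What the simulator emulates — and what it does not

`simulate_event()` builds a 15-joint articulated skeleton (head, neck,
shoulders, elbows, wrists, pelvis, hips, knees, ankles) in image
coordinates (y down), nominal 25 fps, body length 120 px. The event kinds
differ only in the time profiles of the trunk angle, the pelvis trajectory
and limb motion:

* **fall** — trunk rotates $0 \to \pi/2$ along a logistic profile over
  0.4–1.2 s; pelvis drops to the floor with constant (ballistic)
  acceleration; arms flail.
* **walk** — upright translation with gait and arm swing; centroid height
  nearly constant.
* **sit** — pelvis height decreases 40% over 1.5–3 s, knees fold, trunk
  tilt at most $\pi/18$.
* **bend** — trunk tilts to $\pi/4$ and returns, slowly.
* **slow_lie** — the hard negative: the *same* endpoint pose as a fall
  ($\theta \to \pi/2$, pelvis on the floor) reached smoothly over 3–5 s.

Per-joint Gaussian coordinate noise (SD 2 px) and Bernoulli missingness
(p = 0.02) are applied last, so the imputation path is exercised by
default. Event streams are reproducible: each event's seed is derived from
the dataset seed by a documented counter scheme
(`event_seed = (seed * 131071 + index) mod (2^31 - 1)`).

The durations encode the generator's separability premise — falls are the
only sub-second whole-body descent — and the constructor refuses
configurations where `max(fall_duration_s) >= min(sit_duration_s)`. One
consequence of the 10–80 frame budget: a 25 fps slow-lie event would need
up to ~145 frames, so over-long events are sampled on a coarser time grid
that still covers the whole motion, and each sequence records the sampling
rate actually realized. This is the right trade for testing DTW (whose
point is robustness to such re-timing) and keeps the hard negative's full
descent, including its horizontal endpoint, in every sequence.

What the simulator does **not** model: pose-estimator failure modes that
are correlated in time or across joints (real detectors lose whole limbs
for many consecutive frames), perspective foreshortening and camera tilt,
occlusion by furniture, multiple people, or post-fall behavior such as
getting up again. Passing the synthetic recovery test therefore shows the
pipeline's machinery is sound and sensitive to motion dynamics; it does
not certify performance on real video, where detector noise structure and
activity diversity are harsher.

## Numerical choices

* **Near-zero distances.** The Procrustes radicand
  $\lVert V_1\rVert^2 + \lVert V_2\rVert^2 - 2(\sigma_1 + \sigma_2)$
  cancels catastrophically when the configurations are near-congruent, so
  the scalar `procrustes_distance()` evaluates the residual
  $\lVert V_1 Q^\ast - V_2\rVert_F$ at the SVD minimizer instead, which is
  accurate to machine precision at zero. The vectorized frame-distance
  matrix keeps the radicand form (flooring at 0) for speed; its near-zero
  entries carry an $\approx \sqrt{\varepsilon}\,\lVert V \rVert$ noise
  floor ($\sim 10^{-6}$ at pixel scales), which is negligible against
  inter-frame distances of order $10^1$–$10^2$.
* **Eigenvalue clipping.** `bures_distance()` zeroes eigenvalues below
  $10^{-12} \lambda_{\max}$ before square roots: a rank-2 product has
  trailing eigenvalues that are pure round-off of order
  $\varepsilon\,\lambda_{\max}$, and `sqrt` would amplify them into the
  trace ($\sqrt{10^{-10}} = 10^{-5}$).
* **DTW ties.** Backtracking prefers the diagonal step, then vertical;
  this makes reported paths deterministic and cannot affect the total.
* **Degenerate inputs.** Rank-1 (collinear) and rank-0 (all-coincident)
  frames are valid; $d(G(0), G(V)) = \lVert V \rVert_F$ exactly. A frame
  distance matrix must be nonnegative and finite; `NaN` costs are errors,
  not silently skipped.
* **Determinism.** The simulator saves and restores the global RNG state;
  libsvm is deterministic for a fixed input ordering (its solution depends
  on row order only at optimizer tolerance, which is why fold predictions,
  not raw scores, are the order-invariance contract).

## Evaluation protocol choices

Leave-one-out features deliberately *exclude* the held-out sequence's
similarity column from the training feature space: each fold's feature
dimension is the $s-1$ training sequences, and the held-out item enters
only through its own test vector. The all-$s$-dimension variant (in which
every feature vector keeps a coordinate for the held-out sequence, matching
the literal full-similarity-matrix description) is available as
`include_self = TRUE`; it is not the default because it leaks test-item
identity into training geometry and changes feature dimension semantics
across folds. A dedicated test corrupts the held-out column and verifies
no fold's prediction moves.

Cross-dataset evaluation fits the kernel bandwidth on the training split
only; test sequences are featurized against training ids. Reports carry
full-precision metrics; `render_percent()` reproduces the mixed rounding
conventions of published comparison tables (integers for
sensitivity/specificity, two decimals for accuracy).

## Problem sizes

The shipped tests run the geometry equivalence at 1000 random frame pairs
($n \in 3..20$), metric axioms at 1000 random triples, the DTW oracle at
500 random cost matrices up to $6 \times 6$ against exhaustive
warping-path enumeration, and the end-to-end study at 80 sequences
(40 falls, 10 each of walk/sit/bend/slow-lie, dataset seed 42) — the size
at which the similarity matrix (3160 DTW alignments) builds in a couple of
seconds and leave-one-out refits 80 linear SVMs. The shuffled-label null
uses the same 80-sequence similarity matrix.

## Known limitations

* The method is 2D ($d = 2$); 3D skeletons would need $S^+(3, n)$ and a
  different closed form.
* No windowed/banded DTW (Sakoe–Chiba) or soft-DTW; alignment cost is
  $O(\tau_1 \tau_2)$ per pair and the similarity matrix is $O(s^2)$
  alignments — fine at hundreds of sequences, not at tens of thousands.
* Online/streaming detection is out of scope: the unit of classification
  is a complete segmented sequence.
* Because unnormalized DTW totals grow with sequence length, segmentation
  conventions (how much lead-in/tail a clip carries) influence distances;
  consistent segmentation across a dataset matters more here than in
  path-normalized settings.
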