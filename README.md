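# gramfall

Skeleton-based fall detection from 2D pose sequences, for researchers and
engineers building camera-based monitoring systems for older adults. The
package consumes the per-frame keypoint output of any 2D pose estimator
(OpenPose, V2V-PoseNet-style detectors, ...) and classifies each sequence as
a **fall** or a **non-fall** daily activity. It also ships a seeded
kinematic simulator of fall and daily-activity skeleton motion, so the full
pipeline can be exercised, benchmarked and regression-tested without any
video data.

## Method

Each video frame is an `n x 2` matrix `V_t` of joint image coordinates.
The pipeline is:

1. **Gram embedding.** Every frame is mapped to its Gram matrix
   `G_t = V_t V_t'`, an `n x n` positive semidefinite matrix of rank <= 2 —
   a point on the manifold `S+(2, n)`. The embedding quotients out in-plane
   rotations and reflections of the skeleton; frames are centroid-centered
   first so image position is quotiented too (a config switch).
2. **Riemannian frame distance.** Two frames are compared with the
   Bures-type distance
   `d(G1, G2) = sqrt(tr G1 + tr G2 - 2 tr((G1^{1/2} G2 G1^{1/2})^{1/2}))`,
   which equals the orthogonal Procrustes distance
   `min_Q ||V1 Q - V2||_F` over `Q` in O(2). The package implements both
   forms (they cross-validate each other in the tests) and uses the cheap
   SVD/Procrustes form, vectorized over all frame pairs, inside the
   pipeline.
3. **Dynamic Time Warping.** The `tau1 x tau2` frame-distance matrix feeds
   the standard DTW dynamic program, yielding a sequence-level distance
   `D_DTW` that is invariant to differences in execution speed along the
   warping path. Since DTW accumulates costs over at least
   `max(tau1, tau2)` steps, fast (short) falls and slow (long) activities
   remain distinguishable.
4. **Gaussian similarity kernel.** `k(i, j) = exp(-D_DTW(i,j)^2 / (2 sigma^2))`,
   with `sigma` set by the median heuristic over training DTW distances
   unless given.
5. **Similarity-feature SVM.** Each sequence is represented by its vector
   of similarity scores to the training sequences, and a linear SVM
   (fall = positive class) separates fall from non-fall. Using similarity
   rows as ordinary feature vectors sidesteps the fact that DTW kernels
   are not guaranteed positive semidefinite.

Evaluation utilities implement leave-one-out and cross-dataset protocols,
confusion counts, sensitivity / specificity / accuracy, and ROC/AUC.

## Worked example

```r
library(gramfall)

# 15 simulated events: 6 falls, plus walking, sitting and the slow-lying
# hard negative (same final pose as a fall, executed slowly)
d   <- make_dataset(n_fall = 6,
                    activity_counts = c(walk = 3, sit = 3, slow_lie = 3),
                    seed = 11)
pp  <- lapply(d$sequences, preprocess_sequence)   # impute + center
sim <- similarity_matrix(pp)                      # DTW + Gaussian kernel
print(sim)
#> <similarity_matrix: 15 sequences, sigma = 1632.295, mode = distance>

report <- loo_evaluate(labeled_dataset(sim, d$labels), C = 1)
print(report)
#> Fall-detection evaluation report
#>   n = 15   TP 6  FP 0  TN 9  FN 0
#>   sensitivity 100.00%   specificity 100.00%   accuracy 100.00%   AUC 1.000

head(report$per_sequence, 3)
#>   sequence_id truth predicted     score
#> 1    fall_001  fall      fall 0.9055157
#> 2    fall_002  fall      fall 0.8255940
#> 3    fall_003  fall      fall 0.9016022
```

`sigma = 1632.295` is the median of the off-diagonal DTW distances (the
kernel bandwidth actually used — always echoed so runs are auditable);
`score` is the signed distance to the separating hyperplane, positive
meaning fall. All 6 falls are recovered (sensitivity 100%) and all 9
activities rejected (specificity 100%), including the slow-lie negatives
that end in the same horizontal pose as a fall and differ only in dynamics.

The same run is available from a shell:

```sh
Rscript inst/cli/gramfall.R simulate --out data/ --n-fall 6 --walk 3 --sit 3 --slow-lie 3 --seed 11
Rscript inst/cli/gramfall.R evaluate --input data/ --out run/
```

which persists `run/config.echo.json`, `run/run.similarity.tsv`,
`run/run.ddtw.tsv`, `run/report.json`, `run/roc.png` and `run/run.log`.

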