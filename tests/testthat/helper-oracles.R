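# Independent oracles and small fixture builders shared across test files.

# Brute-force orthogonal Procrustes: minimize ||V1 Q - V2||_F over a grid of
# `steps` rotations and the same grid of rotoreflections. Uses only the trig
# identity tr(Q' M); never touches the SVD route it checks.
grid_procrustes <- function(V1, V2, steps = 1e4, rotation_only = FALSE) {
  M <- crossprod(V1, V2)
  th <- seq(0, 2 * pi, length.out = steps + 1)[-(steps + 1)]
  # Q = R(theta): tr(Q' M) = cos(m11 + m22) + sin(m21 - m12)
  tr_rot <- cos(th) * (M[1, 1] + M[2, 2]) + sin(th) * (M[2, 1] - M[1, 2])
  best <- max(tr_rot)
  if (!rotation_only) {
    # Q = R(theta) %*% diag(1, -1)
    tr_ref <- cos(th) * (M[1, 1] - M[2, 2]) + sin(th) * (M[1, 2] + M[2, 1])
    best <- max(best, tr_ref)
  }
  sqrt(max(0, sum(V1^2) + sum(V2^2) - 2 * best))
}

# Exhaustive DTW oracle: the minimum accumulated cost over every monotone
# warping path, by direct recursion over the path set (no tabulation).
dtw_path_oracle <- function(D) {
  rec <- function(i, j) {
    c0 <- D[i, j]
    if (i == 1 && j == 1) return(c0)
    best <- Inf
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    c0 + best
  }
  rec(nrow(D), ncol(D))
}

# Mann-Whitney concordance AUC oracle: P(score_pos > score_neg) + 0.5 ties.
auc_concordance_oracle <- function(scores, labels, positive = "fall") {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Tiny hand-built skeleton sequence (3 joints) from a list of 3x2 frames.
tiny_sequence <- function(frames, id = "tiny", missing = NULL, ...) {
  skeleton_sequence(frames, c("a", "b", "c"), id, missing = missing, ...)
}

random_config <- function(n, scale = 10) {
  matrix(stats::runif(2 * n, -scale, scale), n, 2)
}

# A trajectory straight from configuration matrices (bypasses skeleton io).
traj_from_configs <- function(configs, id = "traj") {
  n <- nrow(configs[[1]])
  arr <- array(0, c(length(configs), n, 2))
  for (t in seq_along(configs)) arr[t, , ] <- configs[[t]]
  ids <- paste0("j", seq_len(n))
  embed_sequence(skeleton_sequence(arr, ids, id))
}

# Small preprocessed simulated dataset for classifier tests.
sim_dataset <- function(n_fall, counts, seed, config = sim_config()) {
  d <- make_dataset(n_fall, counts, config = config, seed = seed)
  d$preprocessed <- lapply(d$sequences, preprocess_sequence)
  d
}
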