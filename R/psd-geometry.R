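#' Gram matrix of a 2D landmark configuration
#'
#' For an n x 2 joint-coordinate matrix V, the Gram matrix G = V V' is an
#' n x n symmetric positive semidefinite matrix of rank at most 2. It is
#' invariant to right-multiplication of V by any 2 x 2 orthogonal matrix, so
#' two configurations that differ only by an in-plane rotation or reflection
#' map to the same point of the manifold S+(2, n) of fixed-rank-2 PSD
#' matrices.
#'
#' @param V numeric n x 2 matrix of joint coordinates.
#' @return an n x n symmetric matrix of class `gram_matrix`. The product is
#'   explicitly symmetrized, `(G + G')/2`, to kill round-off asymmetry.
#' @examples
#' gram(matrix(c(1, 0, 0, 0, 1, 0), ncol = 2))
#' @export
gram <- function(V) {
  V <- as.matrix(V)
  if (ncol(V) != 2L) stop("'V' must have exactly 2 columns")
  if (!all(is.finite(V))) stop("non-finite coordinates in configuration")
  G <- tcrossprod(V)
  G <- (G + t(G)) / 2
  class(G) <- c("gram_matrix", class(G))
  G
}

# PSD square root via eigendecomposition. Eigenvalues below a relative
# floor are zeroed, not just negatives clipped: for a rank-2 matrix the
# trailing eigenvalues are pure round-off noise of order eps * lambda_max,
# and sqrt() would amplify them (sqrt(1e-10) = 1e-5) into the trace.
psd_sqrt <- function(G) {
  e <- eigen(G, symmetric = TRUE)
  lam <- e$values
  lam[lam < 1e-12 * max(lam, 1e-300)] <- 0
  e$vectors %*% (sqrt(lam) * t(e$vectors))
}

#' Bures-type Riemannian distance between Gram matrices
#'
#' The affine-invariant comparison used on S+(2, n):
#' \deqn{d(G_1, G_2) = \sqrt{\mathrm{tr}\,G_1 + \mathrm{tr}\,G_2 -
#'   2\,\mathrm{tr}\big((G_1^{1/2} G_2 G_1^{1/2})^{1/2}\big)}}
#' Matrix square roots are taken by eigendecomposition with negative
#' eigenvalues clipped to zero, and the radicand is floored at zero to guard
#' against round-off. For Gram matrices of configurations V1, V2 this equals
#' the orthogonal Procrustes distance [procrustes_distance()], which is the
#' cheaper route used inside the pipeline; this closed form is retained for
#' cross-validation.
#'
#' @param G1,G2 n x n PSD matrices (e.g. from [gram()]).
#' @return nonnegative scalar distance.
#' @export
bures_distance <- function(G1, G2) {
  G1 <- unclass(G1); G2 <- unclass(G2)
  if (!identical(dim(G1), dim(G2)))
    stop("Gram matrices have mismatched dimensions")
  S <- psd_sqrt(G1)
  M <- S %*% G2 %*% S
  M <- (M + t(M)) / 2
  lam <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  lam[lam < 1e-12 * max(lam, 1e-300)] <- 0
  cross <- sum(sqrt(lam))
  sqrt(max(0, sum(diag(G1)) + sum(diag(G2)) - 2 * cross))
}

#' Orthogonal Procrustes distance between two 2D configurations
#'
#' Computes \eqn{\min_{Q} \|V_1 Q - V_2\|_F} over 2 x 2 orthogonal Q
#' (rotations and reflections). The minimum has the closed form
#' \deqn{d = \sqrt{\|V_1\|_F^2 + \|V_2\|_F^2 - 2(\sigma_1 + \sigma_2)}}
#' with \eqn{\sigma_1, \sigma_2} the singular values of \eqn{V_1' V_2}; the
#' implementation evaluates the residual at the SVD minimizer instead,
#' which is numerically exact near zero where the radicand form cancels
#' catastrophically. With `rotation_only = TRUE` the minimization is
#' restricted to SO(2) and the smaller singular value enters with the sign
#' of \eqn{\det(V_1' V_2)}. The full-O(2) form equals [bures_distance()] of
#' the two Gram matrices.
#'
#' @param V1,V2 n x 2 configuration matrices with the same n.
#' @param rotation_only restrict the alignment to proper rotations
#'   (default `FALSE`).
#' @return nonnegative scalar distance.
#' @seealso [procrustes_alignment()] for the minimizing Q.
#' @export
procrustes_distance <- function(V1, V2, rotation_only = FALSE) {
  # evaluating the residual at the optimal Q (rather than the radicand
  # ||V1||^2 + ||V2||^2 - 2(s1+s2)) avoids catastrophic cancellation when
  # the configurations are near-congruent and the distance is near zero
  procrustes_alignment(V1, V2, rotation_only)$residual
}

#' Optimal orthogonal alignment between two configurations
#'
#' Returns the 2 x 2 orthogonal matrix Q minimizing `||V1 Q - V2||_F`,
#' computed from the SVD `V1' V2 = A diag(s) U'` as `Q = A U'` (restricted to
#' a proper rotation when `rotation_only = TRUE`, via the usual determinant
#' sign correction), together with the attained residual.
#'
#' @inheritParams procrustes_distance
#' @return list with elements `Q` (2 x 2 orthogonal matrix) and `residual`
#'   (the attained Frobenius distance, equal to
#'   `procrustes_distance(V1, V2, rotation_only)`).
#' @export
procrustes_alignment <- function(V1, V2, rotation_only = FALSE) {
  V1 <- as.matrix(V1); V2 <- as.matrix(V2)
  if (!identical(dim(V1), dim(V2)))
    stop("configurations have mismatched dimensions")
  M <- crossprod(V1, V2)
  sv <- svd(M)
  d <- diag(2L)
  if (rotation_only && det(sv$u %*% t(sv$v)) < 0) d[2L, 2L] <- -1
  Q <- sv$u %*% d %*% t(sv$v)
  list(Q = Q, residual = norm(V1 %*% Q - V2, "F"))
}

#' Embed a skeleton sequence as a Gram-matrix trajectory
#'
#' Maps each frame V_t of a (preprocessed) skeleton sequence to its Gram
#' matrix G_t = V_t V_t', yielding a trajectory of points on S+(2, n). The
#' underlying configurations are retained because the Procrustes form of the
#' frame distance works directly on them.
#'
#' @param seq an imputed (and typically centered) [skeleton_sequence()].
#' @return an object of class `gram_trajectory`: list with `grams` (list of
#'   n x n `gram_matrix`), `configs` (m x n x 2 array of frame
#'   configurations), `n`, and the source `sequence_id`.
#' @export
embed_sequence <- function(seq) {
  if (any(seq$missing))
    stop("embed_sequence requires an imputed sequence")
  m <- n_frames(seq)
  grams <- vector("list", m)
  for (t in seq_len(m)) grams[[t]] <- gram(frame_coords(seq, t))
  structure(list(grams = grams, configs = seq$coords, n = n_joints(seq),
                 sequence_id = seq$sequence_id),
            class = "gram_trajectory")
}

#' @export
print.gram_trajectory <- function(x, ...) {
  cat(sprintf("<gram_trajectory '%s': %d frames on S+(2, %d)>\n",
              x$sequence_id, length(x$grams), x$n))
  invisible(x)
}

#' @export
length.gram_trajectory <- function(x) length(x$grams)

#' Dump the eigenvalue spectra of a trajectory's Gram matrices
#'
#' Debugging aid: one row per frame, columns `frame`, `lambda1`, ...,
#' `lambdan` (descending). For exact rank-2 embeddings all but the first two
#' columns are numerically zero.
#'
#' @param traj a [embed_sequence()] result.
#' @param path optional CSV path; if `NULL` the data frame is returned only.
#' @return data frame of spectra, invisibly if written.
#' @export
gram_spectra <- function(traj, path = NULL) {
  sp <- t(vapply(traj$grams, function(G)
    eigen(unclass(G), symmetric = TRUE, only.values = TRUE)$values,
    numeric(traj$n)))
  df <- data.frame(frame = seq_len(nrow(sp)), sp)
  names(df) <- c("frame", paste0("lambda", seq_len(traj$n)))
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
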