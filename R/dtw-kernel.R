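#' Kernel / DTW configuration
#'
#' Collects the tunable parameters of the sequence-comparison stage.
#'
#' @param sigma Gaussian bandwidth. `NULL` (default) means: set it from the
#'   data with the median heuristic ([median_sigma()]) when the similarity
#'   matrix is built. Must be positive when given.
#' @param half_factor multiply kernel values by 1/2 (default `FALSE`). A
#'   monotone rescaling that the downstream SVM absorbs; provided for the
#'   variant of the kernel that carries the 1/2 prefactor.
#' @param square_distance use `exp(-d^2 / (2 sigma^2))` (default, the
#'   standard Gaussian kernel); `FALSE` uses `exp(-d / (2 sigma^2))`.
#' @param accumulation_mode `"distance"` (default): DTW accumulates raw
#'   Riemannian frame distances and the Gaussian kernel is applied once to
#'   the sequence-level DTW distance. `"literal_kernel"`: the frame-level
#'   Gaussian kernel value is the DTW step cost and the accumulated total is
#'   itself the sequence score (no sequence-level kernel); kept for
#'   reproduction of that reading, not recommended.
#' @param path_normalization `"none"` (default) or `"path_length"` (divide
#'   the DTW total by the warping-path length; useful when sequence lengths
#'   vary wildly).
#' @return an object of class `kernel_config`.
#' @export
kernel_config <- function(sigma = NULL, half_factor = FALSE,
                          square_distance = TRUE,
                          accumulation_mode = c("distance", "literal_kernel"),
                          path_normalization = c("none", "path_length")) {
  if (!is.null(sigma) && (!is.numeric(sigma) || length(sigma) != 1L ||
                          !is.finite(sigma) || sigma <= 0))
    stop("'sigma' must be a positive number (or NULL for the median heuristic)")
  structure(list(sigma = sigma,
                 half_factor = isTRUE(half_factor),
                 square_distance = isTRUE(square_distance),
                 accumulation_mode = match.arg(accumulation_mode),
                 path_normalization = match.arg(path_normalization)),
            class = "kernel_config")
}

#' Pairwise Riemannian frame-distance matrix between two trajectories
#'
#' Entry (i, j) is the Procrustes/Bures distance between frame i of the
#' first trajectory and frame j of the second. Computed in closed form: for
#' 2-column configurations, the nuclear norm of the 2 x 2 cross-product
#' `V_i' W_j` is `sqrt(||M||_F^2 + 2 |det M|)`, so the whole matrix reduces
#' to a handful of dense matrix products.
#'
#' @param T1,T2 [embed_sequence()] results with the same joint count.
#' @param rotation_only restrict frame alignment to proper rotations.
#' @return a tau1 x tau2 nonnegative matrix.
#' @export
frame_distance_matrix <- function(T1, T2, rotation_only = FALSE) {
  if (length(T1) == 0L || length(T2) == 0L)
    stop("cannot compare an empty trajectory")
  if (T1$n != T2$n)
    stop("trajectories have different joint counts (", T1$n, " vs ", T2$n, ")")
  X1 <- T1$configs[, , 1L, drop = FALSE]; dim(X1) <- dim(T1$configs)[1:2]
  Y1 <- T1$configs[, , 2L, drop = FALSE]; dim(Y1) <- dim(T1$configs)[1:2]
  X2 <- T2$configs[, , 1L, drop = FALSE]; dim(X2) <- dim(T2$configs)[1:2]
  Y2 <- T2$configs[, , 2L, drop = FALSE]; dim(Y2) <- dim(T2$configs)[1:2]
  # entries of M_ij = V_i' W_j for all frame pairs at once
  m11 <- tcrossprod(X1, X2); m12 <- tcrossprod(X1, Y2)
  m21 <- tcrossprod(Y1, X2); m22 <- tcrossprod(Y1, Y2)
  frob2 <- m11^2 + m12^2 + m21^2 + m22^2
  detm <- m11 * m22 - m12 * m21
  nuclear <- if (rotation_only) {
    # sigma1 + sign(det) * sigma2
    s_sum <- sqrt(pmax(frob2 + 2 * abs(detm), 0))   # sigma1 + sigma2
    s_dif <- sqrt(pmax(frob2 - 2 * abs(detm), 0))   # sigma1 - sigma2
    ifelse(detm < 0, s_dif, s_sum)
  } else {
    sqrt(pmax(frob2 + 2 * abs(detm), 0))
  }
  n1 <- rowSums(X1^2 + Y1^2)
  n2 <- rowSums(X2^2 + Y2^2)
  D2 <- outer(n1, n2, "+") - 2 * nuclear
  sqrt(pmax(D2, 0))
}

#' Dynamic Time Warping over a frame-cost matrix
#'
#' Standard DTW dynamic program: with boundary `M(0,0) = 0` and the first
#' row and column at `+Inf`,
#' `M(i,j) = cost(i,j) + min(M(i,j-1), M(i-1,j-1), M(i-1,j))`, and the
#' sequence-level total is the bottom-right accumulated value. In the
#' default `"distance"` mode the step cost is the raw frame distance
#' `D(i,j)`; in `"literal_kernel"` mode it is the frame-level Gaussian
#' kernel of `D(i,j)` (requires `config$sigma`). The warping path is
#' recovered by backtracking with diagonal-preferred (then vertical)
#' tie-breaking; the choice affects only the reported path, never the total.
#'
#' @param D tau1 x tau2 matrix of nonnegative finite frame costs, e.g. from
#'   [frame_distance_matrix()].
#' @param config a [kernel_config()].
#' @return an object of class `dtw_alignment`: list with `values` (the
#'   (tau1+1) x (tau2+1) accumulator), `path` (k x 2 matrix of 1-based index
#'   pairs from (1,1) to (tau1,tau2) with steps in {(1,0),(0,1),(1,1)}), and
#'   `total` (the accumulated cost, divided by the path length under
#'   `path_normalization = "path_length"`).
#' @export
dtw <- function(D, config = kernel_config()) {
  D <- as.matrix(D)
  if (length(D) == 0L) stop("empty cost matrix")
  if (anyNA(D)) stop("NaN/NA frame cost")
  if (any(!is.finite(D))) stop("non-finite frame cost")
  if (any(D < 0)) stop("negative frame cost")
  costs <- if (config$accumulation_mode == "literal_kernel") {
    if (is.null(config$sigma))
      stop("literal_kernel mode needs an explicit sigma in the config")
    gaussian_kernel(D, config)
  } else D
  M <- dtw_accumulate(costs)
  t1 <- nrow(D); t2 <- ncol(D)
  # backtrack from (t1, t2); prefer diagonal, then vertical
  path <- matrix(0L, t1 + t2, 2L)
  i <- t1; j <- t2; k <- 0L
  while (i >= 1L && j >= 1L) {
    k <- k + 1L
    path[k, ] <- c(i, j)
    if (i == 1L && j == 1L) break
    up <- M[i, j + 1L]; diag_ <- M[i, j]; left <- M[i + 1L, j]
    if (diag_ <= up && diag_ <= left) {
      i <- i - 1L; j <- j - 1L
    } else if (up <= left) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  path <- path[seq_len(k), , drop = FALSE][k:1, , drop = FALSE]
  total <- M[t1 + 1L, t2 + 1L]
  if (config$path_normalization == "path_length") total <- total / k
  structure(list(values = M, path = path, total = total),
            class = "dtw_alignment")
}

#' DTW distance between two Gram trajectories
#'
#' Convenience wrapper: [frame_distance_matrix()] followed by [dtw()].
#'
#' @inheritParams frame_distance_matrix
#' @param config a [kernel_config()].
#' @return scalar DTW total (a distance in the default mode).
#' @export
dtw_distance <- function(T1, T2, config = kernel_config(),
                         rotation_only = FALSE) {
  dtw(frame_distance_matrix(T1, T2, rotation_only), config)$total
}

#' Gaussian similarity kernel of a DTW distance
#'
#' Default reading: `exp(-d^2 / (2 sigma^2))`; `half_factor` multiplies by
#' 1/2; `square_distance = FALSE` uses the unsquared distance in the
#' exponent. Monotone decreasing in the distance in all variants.
#'
#' @param ddtw nonnegative distance value(s); vectorized.
#' @param config a [kernel_config()] with `sigma` set.
#' @return kernel value(s) in (0, 1] (or (0, 0.5] with `half_factor`).
#' @export
gaussian_kernel <- function(ddtw, config = kernel_config(sigma = 1)) {
  if (is.null(config$sigma)) stop("config$sigma is not set")
  if (any(ddtw < 0)) stop("negative distance passed to gaussian_kernel")
  ex <- if (config$square_distance) ddtw^2 else ddtw
  k <- exp(-ex / (2 * config$sigma^2))
  if (config$half_factor) k <- k / 2
  k
}

#' Median-heuristic bandwidth
#'
#' The median of the strictly positive (off-diagonal, if a matrix is given)
#' DTW distances. A standard default when no bandwidth is prescribed: it
#' puts the kernel's active range at the scale of typical inter-sequence
#' distances.
#'
#' @param ddtw numeric vector or square matrix of nonnegative DTW distances.
#' @return positive scalar bandwidth.
#' @export
median_sigma <- function(ddtw) {
  v <- if (is.matrix(ddtw)) ddtw[row(ddtw) != col(ddtw)] else as.numeric(ddtw)
  v <- v[v > 0]
  if (length(v) == 0L)
    stop("all DTW distances are zero; supply an explicit sigma")
  stats::median(v)
}

#' All-pairs similarity matrix over a set of skeleton sequences
#'
#' Embeds each sequence as a Gram trajectory, computes the DTW distance for
#' every unordered pair once (mirrored to both triangles), then applies the
#' Gaussian kernel. If `config$sigma` is `NULL` the bandwidth is first set
#' by [median_sigma()] on the computed DTW distances. The diagonal holds the
#' kernel value at distance zero. In `"literal_kernel"` mode the DTW totals
#' are themselves the similarity scores.
#'
#' @param seqs list of (consistently preprocessed) [skeleton_sequence()]
#'   objects, length >= 2, with unique sequence ids.
#' @param config a [kernel_config()].
#' @param rotation_only restrict frame alignment to proper rotations.
#' @return an object of class `similarity_matrix`: list with `values`
#'   (s x s kernel scores), `ddtw` (s x s DTW distances), `sequence_ids`,
#'   `sigma` (the bandwidth actually used), and `config`.
#' @export
similarity_matrix <- function(seqs, config = kernel_config(),
                              rotation_only = FALSE) {
  s <- length(seqs)
  if (s < 2L) stop("need at least 2 sequences")
  ids <- vapply(seqs, function(x) x$sequence_id, character(1L))
  if (anyDuplicated(ids)) stop("duplicate sequence ids")
  trajs <- lapply(seqs, embed_sequence)
  literal <- config$accumulation_mode == "literal_kernel"
  ddtw <- matrix(0, s, s, dimnames = list(ids, ids))
  raw <- matrix(0, s, s, dimnames = list(ids, ids))
  for (i in seq_len(s - 1L)) {
    for (j in (i + 1L):s) {
      D <- frame_distance_matrix(trajs[[i]], trajs[[j]], rotation_only)
      if (literal) {
        raw[i, j] <- raw[j, i] <- dtw(D, config)$total
        dd <- dtw(D, kernel_config())$total  # plain distance for reporting
      } else {
        dd <- dtw(D, config)$total
      }
      ddtw[i, j] <- ddtw[j, i] <- dd
    }
  }
  if (literal) {
    # the accumulated frame-kernel total is the score; self-score is the
    # accumulated diagonal cost of a sequence against itself
    for (i in seq_len(s)) {
      D <- frame_distance_matrix(trajs[[i]], trajs[[i]], rotation_only)
      raw[i, i] <- dtw(D, config)$total
    }
    return(structure(list(values = raw, ddtw = ddtw, sequence_ids = ids,
                          sigma = config$sigma, config = config),
                     class = "similarity_matrix"))
  }
  sigma <- config$sigma
  if (is.null(sigma)) sigma <- median_sigma(ddtw)
  cfg <- config; cfg$sigma <- sigma
  values <- gaussian_kernel(ddtw, cfg)
  structure(list(values = values, ddtw = ddtw, sequence_ids = ids,
                 sigma = sigma, config = cfg),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix: %d sequences, sigma = %s, mode = %s>\n",
              length(x$sequence_ids),
              if (is.null(x$sigma)) "unset" else format(x$sigma),
              x$config$accumulation_mode))
  invisible(x)
}

#' Clip a similarity matrix to the nearest PSD matrix
#'
#' DTW-based kernels are not guaranteed positive semidefinite. The default
#' classifier consumes similarity rows as ordinary feature vectors, which
#' needs no PSD property; this repair (eigenvalue clipping at zero) is for
#' the optional precomputed-kernel SVM route.
#'
#' @param sim a [similarity_matrix()].
#' @return the same object with `values` replaced by its PSD projection.
#' @export
repair_kernel <- function(sim) {
  e <- eigen((sim$values + t(sim$values)) / 2, symmetric = TRUE)
  v <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
  dimnames(v) <- dimnames(sim$values)
  sim$values <- v
  sim
}

#' Export / import a similarity matrix as TSV
#'
#' `write_similarity()` writes `<stem>.similarity.tsv` (kernel scores) and
#' `<stem>.ddtw.tsv` (DTW distances), both with a header row of sequence
#' ids, plus a JSON sidecar `<stem>.config.json` echoing the configuration
#' and the bandwidth actually used. `read_similarity()` reverses it.
#'
#' @param sim a [similarity_matrix()].
#' @param stem output path stem (directory must exist).
#' @return `write_similarity()`: the stem, invisibly. `read_similarity()`:
#'   a `similarity_matrix`.
#' @export
write_similarity <- function(sim, stem) {
  wr <- function(mat, path) {
    utils::write.table(
      format(mat, digits = 17, trim = TRUE, scientific = TRUE),
      path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  }
  wr(sim$values, paste0(stem, ".similarity.tsv"))
  wr(sim$ddtw, paste0(stem, ".ddtw.tsv"))
  cfg <- sim$config
  side <- list(sigma = sim$sigma,
               half_factor = cfg$half_factor,
               square_distance = cfg$square_distance,
               accumulation_mode = cfg$accumulation_mode,
               path_normalization = cfg$path_normalization,
               sequence_ids = sim$sequence_ids)
  jsonlite::write_json(side, paste0(stem, ".config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(stem)
}

#' @rdname write_similarity
#' @export
read_similarity <- function(stem) {
  rd <- function(path) {
    d <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE)
    as.matrix(d)
  }
  values <- rd(paste0(stem, ".similarity.tsv"))
  ddtw <- rd(paste0(stem, ".ddtw.tsv"))
  side <- jsonlite::fromJSON(paste0(stem, ".config.json"))
  ids <- as.character(side$sequence_ids)
  dimnames(values) <- dimnames(ddtw) <- list(ids, ids)
  cfg <- kernel_config(sigma = side$sigma,
                       half_factor = side$half_factor,
                       square_distance = side$square_distance,
                       accumulation_mode = side$accumulation_mode,
                       path_normalization = side$path_normalization)
  structure(list(values = values, ddtw = ddtw, sequence_ids = ids,
                 sigma = side$sigma, config = cfg),
            class = "similarity_matrix")
}
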