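#' Construct a 2D skeleton sequence
#'
#' A `skeleton_sequence` holds an ordered series of 2D skeleton frames: per
#' frame, an n x 2 matrix of joint image coordinates (pixels, image
#' convention: origin top-left, y increasing downward). Joints that a pose
#' estimator failed to detect in a frame are flagged in a missing mask and
#' carry `NA` coordinates until imputed with [impute_missing()].
#'
#' @param coords numeric array of dimension `c(m, n, 2)` (frames x joints x
#'   xy), or a list of `m` n x 2 matrices. `NA` allowed only where `missing`
#'   is `TRUE`.
#' @param joint_ids character vector of `n` unique joint names, the common
#'   joint ordering of all frames.
#' @param sequence_id character scalar identifying the sequence.
#' @param label optional, `"fall"` or `"nonfall"`.
#' @param fps optional positive frame rate (Hz).
#' @param missing optional m x n logical matrix of missing-joint flags;
#'   defaults to all `FALSE` (or `TRUE` wherever coordinates are `NA`).
#' @param confidence optional m x n matrix of per-joint detector confidences
#'   in `[0, 1]`.
#' @return an object of class `skeleton_sequence`.
#' @examples
#' coords <- array(rnorm(2 * 3 * 2), c(2, 3, 2))
#' skeleton_sequence(coords, c("head", "hip", "ankle"), "example")
#' @export
skeleton_sequence <- function(coords, joint_ids, sequence_id,
                              label = NULL, fps = NULL,
                              missing = NULL, confidence = NULL) {
  if (is.list(coords)) {
    m <- length(coords)
    if (m < 1L) stop("a skeleton sequence needs at least one frame")
    n <- nrow(coords[[1L]])
    arr <- array(NA_real_, c(m, n, 2L))
    for (t in seq_len(m)) {
      fr <- as.matrix(coords[[t]])
      if (!identical(dim(fr), c(n, 2L)))
        stop("frame ", t, " is not an ", n, " x 2 matrix")
      arr[t, , ] <- fr
    }
    coords <- arr
  }
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[3L] != 2L)
    stop("'coords' must be an m x n x 2 array or a list of n x 2 matrices")
  m <- dim(coords)[1L]
  n <- dim(coords)[2L]
  if (m < 1L) stop("a skeleton sequence needs at least one frame")
  if (n < 3L) stop("a skeleton needs at least 3 joints, got ", n)
  joint_ids <- as.character(joint_ids)
  if (length(joint_ids) != n) stop("length(joint_ids) must equal ", n)
  if (anyDuplicated(joint_ids)) stop("duplicate joint ids")
  if (is.null(missing)) {
    missing <- apply(is.na(coords), c(1L, 2L), any)
  }
  missing <- matrix(as.logical(missing), m, n)
  ok <- is.finite(coords[, , 1L, drop = FALSE]) &
    is.finite(coords[, , 2L, drop = FALSE])
  if (any(!ok[, , 1L] & !missing))
    stop("non-finite coordinates at joints not flagged missing")
  if (!is.null(label)) label <- match.arg(label, c("fall", "nonfall"))
  if (!is.null(fps) && (!is.numeric(fps) || fps <= 0))
    stop("'fps' must be a positive number")
  structure(
    list(coords = coords, joint_ids = joint_ids,
         sequence_id = as.character(sequence_id), label = label,
         fps = fps, missing = missing, confidence = confidence),
    class = "skeleton_sequence"
  )
}

#' @export
print.skeleton_sequence <- function(x, ...) {
  cat(sprintf("<skeleton_sequence '%s': %d frames x %d joints%s%s>\n",
              x$sequence_id, n_frames(x), n_joints(x),
              if (!is.null(x$label)) paste0(", label=", x$label) else "",
              if (any(x$missing)) sprintf(", %d missing joint obs",
                                          sum(x$missing)) else ""))
  invisible(x)
}

#' Number of frames / joints in a skeleton sequence
#' @param seq a [skeleton_sequence()].
#' @return integer count.
#' @export
n_frames <- function(seq) dim(seq$coords)[1L]

#' @rdname n_frames
#' @export
n_joints <- function(seq) dim(seq$coords)[2L]

#' Extract one frame's joint configuration
#' @param seq a [skeleton_sequence()].
#' @param t frame index in `1:n_frames(seq)`.
#' @return n x 2 numeric matrix with joint ids as row names.
#' @export
frame_coords <- function(seq, t) {
  V <- seq$coords[t, , , drop = TRUE]
  dim(V) <- c(n_joints(seq), 2L)
  rownames(V) <- seq$joint_ids
  V
}

#' Read a skeleton sequence from long-format CSV
#'
#' Expected columns: `frame_index` (contiguous nonnegative integers after
#' sorting), `joint_id`, `x`, `y` and optionally `confidence`. Joints absent
#' from a frame's rows are flagged missing; the joint ordering is the sorted
#' union of all joint ids seen in the file.
#'
#' @param path file path.
#' @param sequence_id id to assign; default is the file name without
#'   extension.
#' @param fps optional frame rate to record.
#' @return a [skeleton_sequence()].
#' @export
read_skeleton_csv <- function(path, sequence_id = NULL, fps = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  if (nrow(raw) == 0L) stop("empty skeleton CSV: ", path)
  need <- c("frame_index", "joint_id", "x", "y")
  if (!all(need %in% names(raw)))
    stop("skeleton CSV must have columns ", paste(need, collapse = ", "))
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !(raw[[col]] %in% c("NA", "")))
    if (length(bad))
      stop(sprintf("malformed numeric value in column '%s' at line %d of %s",
                   col, bad[1L] + 1L, path))  # +1 for header row
    v
  }
  fi <- num("frame_index")
  if (any(fi != round(fi)) || any(fi < 0))
    stop("frame_index values must be nonnegative integers")
  x <- num("x"); y <- num("y")
  if (anyNA(x) || anyNA(y)) stop("missing x/y values in skeleton CSV")
  conf <- if ("confidence" %in% names(raw)) num("confidence") else NULL
  frames_seen <- sort(unique(fi))
  if (length(frames_seen) != max(frames_seen) - min(frames_seen) + 1)
    stop("frame_index values are not a contiguous range")
  joint_ids <- sort(unique(raw$joint_id))
  m <- length(frames_seen); n <- length(joint_ids)
  coords <- array(NA_real_, c(m, n, 2L))
  missing <- matrix(TRUE, m, n)
  cmat <- if (is.null(conf)) NULL else matrix(NA_real_, m, n)
  ti <- match(fi, frames_seen)
  ji <- match(raw$joint_id, joint_ids)
  for (r in seq_along(ti)) {
    coords[ti[r], ji[r], 1L] <- x[r]
    coords[ti[r], ji[r], 2L] <- y[r]
    missing[ti[r], ji[r]] <- FALSE
    if (!is.null(cmat)) cmat[ti[r], ji[r]] <- conf[r]
  }
  if (is.null(sequence_id))
    sequence_id <- sub("\\.[^.]*$", "", basename(path))
  skeleton_sequence(coords, joint_ids, sequence_id, fps = fps,
                    missing = missing, confidence = cmat)
}

#' Write a skeleton sequence to long-format CSV
#'
#' Missing joints are omitted from their frame's rows, mirroring
#' [read_skeleton_csv()]; coordinates are printed with full double
#' precision so a write/read round trip is bit-exact.
#'
#' @param seq a [skeleton_sequence()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_skeleton_csv <- function(seq, path) {
  m <- n_frames(seq); n <- n_joints(seq)
  con <- file(path, "w")
  on.exit(close(con))
  has_conf <- !is.null(seq$confidence)
  writeLines(paste(c("frame_index", "joint_id", "x", "y",
                     if (has_conf) "confidence"), collapse = ","), con)
  for (t in seq_len(m)) {
    for (j in seq_len(n)) {
      if (seq$missing[t, j]) next
      fields <- c(t - 1L, seq$joint_ids[j],
                  sprintf("%.17g", seq$coords[t, j, 1L]),
                  sprintf("%.17g", seq$coords[t, j, 2L]))
      if (has_conf)
        fields <- c(fields, sprintf("%.17g", seq$confidence[t, j]))
      writeLines(paste(fields, collapse = ","), con)
    }
  }
  invisible(path)
}

#' Read a skeleton sequence from a JSON keypoints dump
#'
#' Dialect compatible with common per-frame pose-estimator keypoint dumps:
#' `{"sequence_id": str, "fps": num, "joints": [names...],
#' "frames": [[x1,y1,c1, x2,y2,c2, ...], ...]}` — one flat list of
#' (x, y, confidence) triples per frame. Joints whose confidence falls below
#' `confidence_threshold` are flagged missing.
#'
#' @param path file path.
#' @param confidence_threshold joints with confidence strictly below this are
#'   treated as undetected (default 0.1).
#' @return a [skeleton_sequence()].
#' @export
read_keypoints_json <- function(path, confidence_threshold = 0.1) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$frames) || length(obj$frames) == 0L)
    stop("keypoints JSON has an empty frame list: ", path)
  joint_ids <- vapply(obj$joints, as.character, character(1L))
  n <- length(joint_ids)
  m <- length(obj$frames)
  coords <- array(NA_real_, c(m, n, 2L))
  missing <- matrix(FALSE, m, n)
  cmat <- matrix(NA_real_, m, n)
  for (t in seq_len(m)) {
    fr <- as.numeric(unlist(obj$frames[[t]]))
    if (length(fr) != 3L * n)
      stop(sprintf(
        "frame %d has %d values; expected %d (x,y,confidence per joint)",
        t, length(fr), 3L * n))
    xs <- fr[seq(1L, by = 3L, length.out = n)]
    ys <- fr[seq(2L, by = 3L, length.out = n)]
    cs <- fr[seq(3L, by = 3L, length.out = n)]
    low <- cs < confidence_threshold
    coords[t, , 1L] <- ifelse(low, NA_real_, xs)
    coords[t, , 2L] <- ifelse(low, NA_real_, ys)
    missing[t, ] <- low
    cmat[t, ] <- cs
  }
  skeleton_sequence(coords, joint_ids,
                    sequence_id = if (!is.null(obj$sequence_id))
                      obj$sequence_id else sub("\\.[^.]*$", "", basename(path)),
                    fps = if (!is.null(obj$fps)) as.numeric(obj$fps) else NULL,
                    missing = missing, confidence = cmat)
}

#' Write a skeleton sequence to the JSON keypoints dialect
#'
#' Missing joints are emitted with confidence 0 (and coordinate 0), so
#' [read_keypoints_json()] flags them missing again under any threshold
#' above zero.
#'
#' @inheritParams write_skeleton_csv
#' @return `path`, invisibly.
#' @export
write_keypoints_json <- function(seq, path) {
  m <- n_frames(seq); n <- n_joints(seq)
  frames <- vector("list", m)
  for (t in seq_len(m)) {
    fr <- numeric(3L * n)
    for (j in seq_len(n)) {
      miss <- seq$missing[t, j]
      fr[3L * j - 2L] <- if (miss) 0 else seq$coords[t, j, 1L]
      fr[3L * j - 1L] <- if (miss) 0 else seq$coords[t, j, 2L]
      fr[3L * j] <- if (miss) 0 else if (!is.null(seq$confidence) &&
                                          is.finite(seq$confidence[t, j]))
        seq$confidence[t, j] else 1
    }
    frames[[t]] <- fr
  }
  obj <- list(sequence_id = seq$sequence_id,
              fps = if (is.null(seq$fps)) 25 else seq$fps,
              joints = seq$joint_ids, frames = frames)
  # I(17) = 17 significant digits: doubles survive the round trip bit-exactly
  writeLines(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE), path)
  invisible(path)
}

#' Impute missing joints in a skeleton sequence
#'
#' @param seq a [skeleton_sequence()].
#' @param method `"linear"` (default): per-joint linear interpolation over
#'   frame index, ends extrapolated by the nearest observed value;
#'   `"hold"`: last observation carried forward, leading gaps backfilled;
#'   `"drop_frame"`: frames containing any missing joint removed.
#' @return a `skeleton_sequence` with all coordinates finite and an all-
#'   `FALSE` missing mask. Non-missing coordinates are never altered.
#' @export
impute_missing <- function(seq, method = c("linear", "hold", "drop_frame")) {
  method <- match.arg(method)
  if (!any(seq$missing)) {
    out <- seq
    return(out)
  }
  m <- n_frames(seq); n <- n_joints(seq)
  if (method == "drop_frame") {
    keep <- !apply(seq$missing, 1L, any)
    if (!any(keep))
      stop("drop_frame imputation would remove every frame")
    return(skeleton_sequence(seq$coords[keep, , , drop = FALSE],
                             seq$joint_ids, seq$sequence_id,
                             label = seq$label, fps = seq$fps,
                             missing = seq$missing[keep, , drop = FALSE],
                             confidence = if (!is.null(seq$confidence))
                               seq$confidence[keep, , drop = FALSE]))
  }
  coords <- seq$coords
  for (j in seq_len(n)) {
    obs <- which(!seq$missing[, j])
    if (length(obs) == 0L)
      stop("joint '", seq$joint_ids[j],
           "' is missing in every frame and cannot be imputed")
    gaps <- which(seq$missing[, j])
    if (length(gaps) == 0L) next
    for (ax in 1:2) {
      v <- coords[, j, ax]
      if (length(obs) == 1L) {
        v[gaps] <- v[obs]
      } else if (method == "linear") {
        v[gaps] <- stats::approx(obs, v[obs], xout = gaps,
                                 method = "linear", rule = 2)$y
      } else {
        v[gaps] <- stats::approx(obs, v[obs], xout = gaps,
                                 method = "constant", f = 0, rule = 2)$y
      }
      coords[, j, ax] <- v
    }
  }
  skeleton_sequence(coords, seq$joint_ids, seq$sequence_id,
                    label = seq$label, fps = seq$fps,
                    missing = matrix(FALSE, m, n),
                    confidence = seq$confidence)
}

#' Translate each frame of a skeleton sequence
#'
#' Gram matrices of raw pixel coordinates are sensitive to where the subject
#' stands in the image; centering each frame removes that translation
#' component, so the downstream Riemannian distance compares configuration
#' shape rather than image position. `"centroid"` subtracts each frame's
#' joint mean (output frames have column means (0,0)); `"joint:<id>"` moves
#' the named joint to the origin; `"none"` is the identity.
#'
#' @param seq an imputed [skeleton_sequence()].
#' @param mode `"centroid"` (default), `"none"`, or `"joint:<id>"`.
#' @return a `skeleton_sequence` with translated frames.
#' @export
center_frames <- function(seq, mode = "centroid") {
  if (any(seq$missing))
    stop("center_frames requires an imputed sequence; run impute_missing()")
  if (mode == "none") return(seq)
  coords <- seq$coords
  if (mode == "centroid") {
    for (ax in 1:2) {
      sl <- coords[, , ax, drop = FALSE]
      dim(sl) <- dim(coords)[1:2]
      coords[, , ax] <- sl - rowMeans(sl)
    }
  } else if (startsWith(mode, "joint:")) {
    id <- sub("^joint:", "", mode)
    j <- match(id, seq$joint_ids)
    if (is.na(j)) stop("unknown joint id in centering mode: '", id, "'")
    for (ax in 1:2) {
      sl <- coords[, , ax, drop = FALSE]
      dim(sl) <- dim(coords)[1:2]
      coords[, , ax] <- sl - sl[, j]
    }
  } else {
    stop("unknown centering mode: '", mode, "'")
  }
  skeleton_sequence(coords, seq$joint_ids, seq$sequence_id,
                    label = seq$label, fps = seq$fps,
                    missing = seq$missing, confidence = seq$confidence)
}

#' Scale each frame to unit Frobenius norm
#'
#' Optional size normalization. Off by default in the pipeline: falls
#' genuinely change the apparent configuration scale, which carries signal.
#'
#' @param seq an imputed [skeleton_sequence()].
#' @return a `skeleton_sequence` whose frames each have Frobenius norm 1.
#' @export
scale_frames <- function(seq) {
  coords <- seq$coords
  nrm <- sqrt(rowSums(matrix(coords^2, nrow = dim(coords)[1L])))
  if (any(nrm == 0)) stop("cannot scale a frame with all-zero coordinates")
  coords <- coords / nrm
  skeleton_sequence(coords, seq$joint_ids, seq$sequence_id,
                    label = seq$label, fps = seq$fps,
                    missing = seq$missing, confidence = seq$confidence)
}

#' Standard preprocessing: impute, center, optionally scale
#'
#' The pipeline default is linear imputation (preserves sequence length for
#' DTW) followed by centroid centering, no scale normalization.
#'
#' @param seq a [skeleton_sequence()].
#' @param imputation passed to [impute_missing()].
#' @param centering passed to [center_frames()].
#' @param scale if `TRUE`, apply [scale_frames()].
#' @return a preprocessed `skeleton_sequence`.
#' @export
preprocess_sequence <- function(seq, imputation = "linear",
                                centering = "centroid", scale = FALSE) {
  out <- impute_missing(seq, imputation)
  out <- center_frames(out, centering)
  if (isTRUE(scale)) out <- scale_frames(out)
  out
}
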