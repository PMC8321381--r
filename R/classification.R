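#' Labeled dataset for similarity-feature classification
#'
#' Binds fall/non-fall labels to a [similarity_matrix()] over the same
#' sequence ids. Fall is the positive class throughout: sensitivity is the
#' fall-detection rate and specificity the daily-activity rejection rate.
#'
#' @param similarity a [similarity_matrix()].
#' @param labels character vector of `"fall"`/`"nonfall"`, either in the
#'   similarity matrix's id order or named by sequence id.
#' @return an object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(similarity, labels) {
  ids <- similarity$sequence_ids
  if (!is.null(names(labels))) {
    if (!setequal(names(labels), ids))
      stop("label names do not match the similarity matrix's sequence ids")
    labels <- labels[ids]
  } else if (length(labels) != length(ids)) {
    stop("need one label per sequence (", length(ids), ")")
  }
  labels <- as.character(labels)
  if (!all(labels %in% c("fall", "nonfall")))
    stop("labels must be 'fall' or 'nonfall'")
  structure(list(sequence_ids = ids, labels = stats::setNames(labels, ids),
                 similarity = similarity),
            class = "labeled_dataset")
}

#' Similarity-score feature vector for one sequence
#'
#' The feature representation: the vector of kernel similarities from the
#' target sequence to each training sequence, in training-id order. When the
#' target is itself a training member its self-similarity entry (1.0 under
#' the default kernel) is included at its own position.
#'
#' @param sim a [similarity_matrix()].
#' @param training_ids ordered ids defining the feature dimensions.
#' @param target_id the sequence to featurize.
#' @return numeric vector of `length(training_ids)` similarities.
#' @export
features_from_similarity <- function(sim, training_ids, target_id) {
  ids <- sim$sequence_ids
  if (!target_id %in% ids) stop("unknown sequence id: '", target_id, "'")
  bad <- setdiff(training_ids, ids)
  if (length(bad)) stop("unknown training id(s): ",
                        paste(sQuote(bad), collapse = ", "))
  sim$values[target_id, training_ids]
}

# e1071/libsvm reports decision values for "first/second" class as named in
# the column header; flip so that larger always means "fall".
orient_scores <- function(dv) {
  cn <- colnames(dv)[1L]
  pos_first <- identical(strsplit(cn, "/", fixed = TRUE)[[1L]][1L], "fall")
  s <- as.numeric(dv[, 1L])
  if (pos_first) s else -s
}

#' Train the linear SVM on similarity features
#'
#' Fits a linear max-margin classifier (soft margin, cost `C`) on the
#' similarity-score feature vectors of the dataset's sequences, all of which
#' serve as training dimensions. Deterministic for fixed inputs.
#'
#' @param dataset a [labeled_dataset()] containing both classes.
#' @param C positive soft-margin cost (default 1).
#' @param class_weights optional named weights, e.g.
#'   `c(fall = 2, nonfall = 1)`; default unweighted.
#' @return an object of class `fall_classifier`: the fitted model plus the
#'   `training_ids` that define its feature space.
#' @export
train_classifier <- function(dataset, C = 1, class_weights = NULL) {
  if (!is.numeric(C) || length(C) != 1L || !is.finite(C) || C <= 0)
    stop("'C' must be a positive number")
  y <- factor(dataset$labels, levels = c("fall", "nonfall"))
  if (nlevels(droplevels(y)) < 2L)
    stop("training data must contain both classes")
  ids <- dataset$sequence_ids
  X <- dataset$similarity$values[ids, ids, drop = FALSE]
  fit <- e1071::svm(x = X, y = y, kernel = "linear", cost = C,
                    scale = FALSE, class.weights = class_weights)
  structure(list(model = fit, training_ids = ids, C = C),
            class = "fall_classifier")
}

#' Predict fall/non-fall for sequences from a similarity matrix
#'
#' @param object a [train_classifier()] result.
#' @param sim a [similarity_matrix()] containing both the model's training
#'   ids and the target ids.
#' @param ids sequences to predict (default: every id in `sim`).
#' @param ... unused.
#' @return data frame with columns `sequence_id`, `predicted`
#'   (`"fall"`/`"nonfall"`) and `score` (signed distance to the separating
#'   hyperplane; positive leans fall).
#' @export
predict.fall_classifier <- function(object, sim, ids = sim$sequence_ids, ...) {
  X <- t(vapply(ids, function(id)
    features_from_similarity(sim, object$training_ids, id),
    numeric(length(object$training_ids))))
  pr <- stats::predict(object$model, X, decision.values = TRUE)
  score <- orient_scores(attr(pr, "decision.values"))
  data.frame(sequence_id = ids,
             predicted = ifelse(score > 0, "fall", "nonfall"),
             score = score, row.names = NULL, stringsAsFactors = FALSE)
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' With fall as the positive class: sensitivity = 100 TP/(TP+FN),
#' specificity = 100 TN/(TN+FP), accuracy = 100 (TP+TN)/total.
#'
#' @param tp,fp,tn,fn nonnegative integer confusion counts; both margins
#'   (`tp + fn` and `tn + fp`) must be positive.
#' @return named list of the three percentages at full precision.
#' @seealso [render_percent()] for nearest-integer / two-decimal rendering.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  cnt <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("confusion counts must be nonnegative integers")
  if (tp + fn == 0) stop("no positive (fall) examples: sensitivity undefined")
  if (tn + fp == 0) stop("no negative (non-fall) examples: specificity undefined")
  list(sensitivity = 100 * tp / (tp + fn),
       specificity = 100 * tn / (tn + fp),
       accuracy = 100 * (tp + tn) / sum(cnt))
}

#' Render a percentage the way evaluation tables print them
#'
#' @param x percentage value(s).
#' @param digits 0 for nearest integer (the common convention for
#'   sensitivity/specificity), 2 for accuracy-style two decimals.
#' @return character vector.
#' @export
render_percent <- function(x, digits = 0) {
  formatC(round(unlist(x), digits), format = "f", digits = digits)
}

#' ROC curve and AUC from decision scores
#'
#' Sweeps a threshold over the scores from high to low, grouping tied
#' scores, and accumulates (false-positive rate, true-positive rate) points
#' from (0,0) to (1,1). AUC is the trapezoid-rule area, which equals the
#' Mann-Whitney concordance probability with ties counted 1/2.
#'
#' @param scores numeric decision scores, larger meaning more fall-like.
#' @param labels `"fall"`/`"nonfall"` per score; both classes required.
#' @param positive the positive-class label (default `"fall"`).
#' @return list with `points` (data frame `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_curve <- function(scores, labels, positive = "fall") {
  stopifnot(length(scores) == length(labels))
  pos <- labels == positive
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0L || nn == 0L)
    stop("ROC needs both classes present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; p <- pos[o]
  grp <- cumsum(!duplicated(s))           # tie groups of equal scores
  tp_g <- tapply(p, grp, sum)
  fp_g <- tapply(!p, grp, sum)
  tpr <- c(0, cumsum(tp_g) / np)
  fpr <- c(0, cumsum(fp_g) / nn)
  thr <- c(Inf, s[!duplicated(s)])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr, threshold = thr),
       auc = auc)
}

# Build an eval_report from per-sequence truth/prediction/score. Metrics
# whose margin is empty (e.g. a test split with a single class) come out NA
# instead of erroring, so degenerate splits still yield a report.
eval_report <- function(ids, truth, predicted, scores) {
  tp <- sum(truth == "fall" & predicted == "fall")
  fn <- sum(truth == "fall" & predicted == "nonfall")
  tn <- sum(truth == "nonfall" & predicted == "nonfall")
  fp <- sum(truth == "nonfall" & predicted == "fall")
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  acc <- 100 * (tp + tn) / length(truth)
  roc <- if (tp + fn > 0 && tn + fp > 0) roc_curve(scores, truth) else
    list(points = NULL, auc = NA_real_)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens,
                 specificity = spec,
                 accuracy = acc,
                 roc_points = roc$points, auc = roc$auc,
                 per_sequence = data.frame(
                   sequence_id = ids, truth = truth, predicted = predicted,
                   score = scores, row.names = NULL,
                   stringsAsFactors = FALSE)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Fall-detection evaluation report\n")
  cat(sprintf("  n = %d   TP %d  FP %d  TN %d  FN %d\n",
              x$tp + x$fp + x$tn + x$fn, x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  sensitivity %s%%   specificity %s%%   accuracy %s%%   AUC %.3f\n",
              render_percent(x$sensitivity, 2),
              render_percent(x$specificity, 2),
              render_percent(x$accuracy, 2), x$auc))
  invisible(x)
}

#' Plot the ROC curve of an evaluation report
#'
#' @param x an `eval_report`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.eval_report <- function(x, ...) {
  graphics::plot(x$roc_points$fpr, x$roc_points$tpr, type = "s",
                 xlab = "False positive rate", ylab = "True positive rate",
                 xlim = c(0, 1), ylim = c(0, 1),
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report an `eval_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  obj <- list(counts = list(tp = report$tp, fp = report$fp,
                            tn = report$tn, fn = report$fn),
              metrics = list(sensitivity = report$sensitivity,
                             specificity = report$specificity,
                             accuracy = report$accuracy,
                             auc = report$auc),
              roc_points = report$roc_points,
              per_sequence = report$per_sequence)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Leave-one-out evaluation
#'
#' For each sequence in turn: the other s-1 sequences are the training set;
#' feature vectors for all items are similarities to those s-1 training ids
#' only; the linear SVM is fitted on the s-1 and the held-out item is
#' predicted from its own similarity row restricted to the training ids.
#' The full similarity matrix is computed once (it lives in the dataset) and
#' sliced per fold. The held-out item's own similarity column is never a
#' training feature dimension, so no information leaks from the test item
#' into the fold's model; set `include_self = TRUE` for the literal
#' full-matrix variant in which every feature vector keeps all s dimensions.
#'
#' @param dataset a [labeled_dataset()] with at least 3 sequences.
#' @param C positive SVM cost (default 1).
#' @param class_weights optional named class weights.
#' @param include_self keep the held-out sequence's column as a feature
#'   dimension (default `FALSE`).
#' @return an `eval_report` aggregating all folds.
#' @export
loo_evaluate <- function(dataset, C = 1, class_weights = NULL,
                         include_self = FALSE) {
  ids <- dataset$sequence_ids
  s <- length(ids)
  if (s < 3L) stop("leave-one-out needs at least 3 sequences")
  S <- dataset$similarity$values[ids, ids, drop = FALSE]
  labels <- dataset$labels[ids]
  predicted <- character(s)
  score <- numeric(s)
  for (i in seq_len(s)) {
    tr <- ids[-i]
    if (length(unique(labels[tr])) < 2L)
      stop("fold holding out '", ids[i], "' has a single-class training set")
    feat_ids <- if (include_self) ids else tr
    X <- S[tr, feat_ids, drop = FALSE]
    y <- factor(labels[tr], levels = c("fall", "nonfall"))
    fit <- e1071::svm(x = X, y = y, kernel = "linear", cost = C,
                      scale = FALSE, class.weights = class_weights)
    xi <- S[ids[i], feat_ids, drop = FALSE]
    pr <- stats::predict(fit, xi, decision.values = TRUE)
    score[i] <- orient_scores(attr(pr, "decision.values"))
    predicted[i] <- if (score[i] > 0) "fall" else "nonfall"
  }
  eval_report(ids, unname(labels), predicted, score)
}

#' Cross-dataset evaluation
#'
#' Trains on one collection of labeled sequences and tests on a disjoint
#' one, as in a transfer protocol: the kernel bandwidth is fitted on the
#' training set only (median heuristic, unless `config$sigma` is given),
#' feature vectors for both splits are similarities to the training ids, the
#' SVM is fitted on the training split and the report covers the test split.
#'
#' @param train_seqs,test_seqs lists of preprocessed [skeleton_sequence()]
#'   objects with disjoint id spaces.
#' @param train_labels,test_labels `"fall"`/`"nonfall"` vectors aligned with
#'   the sequence lists.
#' @param config a [kernel_config()].
#' @param C positive SVM cost.
#' @param class_weights optional named class weights.
#' @param rotation_only restrict frame alignment to proper rotations.
#' @return an `eval_report` over the test split.
#' @export
cross_dataset_evaluate <- function(train_seqs, train_labels,
                                   test_seqs, test_labels,
                                   config = kernel_config(), C = 1,
                                   class_weights = NULL,
                                   rotation_only = FALSE) {
  stopifnot(length(train_seqs) == length(train_labels),
            length(test_seqs) == length(test_labels))
  tr_ids <- vapply(train_seqs, function(x) x$sequence_id, character(1L))
  te_ids <- vapply(test_seqs, function(x) x$sequence_id, character(1L))
  if (length(intersect(tr_ids, te_ids)))
    stop("train and test id spaces overlap")
  tr_sim <- similarity_matrix(train_seqs, config, rotation_only)
  cfg <- tr_sim$config  # sigma now fixed from the training split
  tr_traj <- lapply(train_seqs, embed_sequence)
  te_traj <- lapply(test_seqs, embed_sequence)
  ddtw_te <- matrix(0, length(te_ids), length(tr_ids),
                    dimnames = list(te_ids, tr_ids))
  for (i in seq_along(te_traj)) {
    for (j in seq_along(tr_traj)) {
      D <- frame_distance_matrix(te_traj[[i]], tr_traj[[j]], rotation_only)
      ddtw_te[i, j] <- dtw(D, if (cfg$accumulation_mode == "literal_kernel")
        cfg else kernel_config(
          path_normalization = cfg$path_normalization))$total
    }
  }
  feats_te <- if (cfg$accumulation_mode == "literal_kernel") ddtw_te
              else gaussian_kernel(ddtw_te, cfg)
  ds <- labeled_dataset(tr_sim, stats::setNames(train_labels, tr_ids))
  clf <- train_classifier(ds, C = C, class_weights = class_weights)
  pr <- stats::predict(clf$model, feats_te[, clf$training_ids, drop = FALSE],
                       decision.values = TRUE)
  score <- orient_scores(attr(pr, "decision.values"))
  predicted <- ifelse(score > 0, "fall", "nonfall")
  eval_report(te_ids, as.character(test_labels), predicted, score)
}
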