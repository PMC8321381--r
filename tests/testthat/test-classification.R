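# Shared small labeled dataset: separable by construction (distinct event
# dynamics), built once per file.
clf_data <- local({
  d <- sim_dataset(6, c(walk = 3, sit = 3), seed = 41)
  sim <- similarity_matrix(d$preprocessed)
  list(d = d, sim = sim, ds = labeled_dataset(sim, d$labels))
})

test_that("similarity feature vectors follow the training-id order and include self", {
  sim <- clf_data$sim
  ids <- sim$sequence_ids
  tr <- ids[1:5]
  v <- features_from_similarity(sim, tr, ids[3])
  expect_length(v, 5)
  expect_equal(unname(v[3]), 1.0)             # self-similarity
  expect_equal(unname(v), unname(sim$values[ids[3], tr]))
  expect_error(features_from_similarity(sim, tr, "ghost"), "unknown")
  expect_error(features_from_similarity(sim, c(tr, "ghost"), ids[1]),
               "unknown training")
})

test_that("identical sequences get identical feature vectors", {
  s1 <- clf_data$d$preprocessed[[1]]
  s2 <- s1; s2$sequence_id <- "twin"
  sim <- similarity_matrix(c(clf_data$d$preprocessed[1:4], list(s2)),
                           kernel_config(sigma = 500))
  tr <- sim$sequence_ids[2:4]
  expect_equal(unname(features_from_similarity(sim, tr, s1$sequence_id)),
               unname(features_from_similarity(sim, tr, "twin")),
               tolerance = 1e-9)
})

test_that("the linear SVM separates well-separated clusters and is deterministic", {
  clf <- train_classifier(clf_data$ds, C = 1)
  pr <- predict(clf, clf_data$sim)
  expect_equal(pr$predicted, ifelse(clf_data$d$labels == "fall",
                                    "fall", "nonfall"))
  pr2 <- predict(train_classifier(clf_data$ds, C = 1), clf_data$sim)
  expect_identical(pr$score, pr2$score)
  expect_error(train_classifier(clf_data$ds, C = 0), "positive")
  expect_error(train_classifier(clf_data$ds, C = -3), "positive")
})

test_that("training on a duplicated dataset leaves predictions on originals unchanged", {
  d <- clf_data$d
  twins <- lapply(d$preprocessed, function(s) {
    s$sequence_id <- paste0(s$sequence_id, "_dup"); s
  })
  all_seqs <- c(d$preprocessed, twins)
  sim_all <- similarity_matrix(all_seqs, kernel_config(sigma = clf_data$sim$sigma))
  ds_all <- labeled_dataset(sim_all, rep(d$labels, 2))
  pr_all <- predict(train_classifier(ds_all), sim_all,
                    ids = d$manifest$sequence_id)
  pr_orig <- predict(train_classifier(clf_data$ds), clf_data$sim)
  expect_equal(pr_all$predicted, pr_orig$predicted)
})

test_that("single-class training data is rejected", {
  d <- sim_dataset(0, c(walk = 3), seed = 43)
  sim <- similarity_matrix(d$preprocessed)
  ds <- labeled_dataset(sim, d$labels)
  expect_error(train_classifier(ds), "both classes")
})

test_that("confusion metrics reproduce benchmark-table arithmetic", {
  # 97/0/19/131 confusion: perfect fall recall, 131/150 rejection
  m1 <- confusion_metrics(tp = 97, fp = 19, tn = 131, fn = 0)
  expect_equal(m1$sensitivity, 100)
  expect_equal(m1$specificity, 100 * 131 / 150)
  expect_equal(render_percent(m1$specificity), "87")
  expect_equal(render_percent(m1$specificity, 2), "87.33")
  m2 <- confusion_metrics(tp = 63, fp = 2, tn = 27, fn = 0)
  expect_equal(m2$sensitivity, 100)
  expect_equal(render_percent(m2$specificity), "93")
  expect_equal(render_percent(m2$specificity, 2), "93.10")
  expect_equal(confusion_metrics(1, 0, 1, 0),
               list(sensitivity = 100, specificity = 100, accuracy = 100))
  expect_error(confusion_metrics(0, 1, 2, 0), "sensitivity undefined")
  expect_error(confusion_metrics(1, 0, 0, 0), "specificity undefined")
  expect_error(confusion_metrics(1.5, 0, 1, 0), "integers")
})

test_that("ROC agrees with the concordance oracle, including ties", {
  hand <- list(scores = c(0.9, 0.8, 0.8, 0.4, 0.3, 0.1),
               labels = c("fall", "fall", "nonfall", "fall",
                          "nonfall", "nonfall"))
  r <- roc_curve(hand$scores, hand$labels)
  expect_equal(r$auc, auc_concordance_oracle(hand$scores, hand$labels))
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[nrow(r$points)], 1)
  expect_true(all(diff(r$points$fpr) >= 0) && all(diff(r$points$tpr) >= 0))
  set.seed(44)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # many ties
    labels <- sample(c("fall", "nonfall"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_curve(scores, labels)$auc,
                 auc_concordance_oracle(scores, labels))
  }
  expect_equal(roc_curve(c(1, 2, 3, 4), c("nonfall", "nonfall", "fall",
                                          "fall"))$auc, 1)
  expect_equal(roc_curve(rep(2, 6), rep(c("fall", "nonfall"), 3))$auc, 0.5)
  expect_error(roc_curve(1:3, rep("fall", 3)), "both classes")
})

test_that("ROC matches an established implementation on random scores", {
  skip_if_not_installed("pROC")
  set.seed(45)
  scores <- rnorm(40)
  labels <- sample(c("fall", "nonfall"), 40, replace = TRUE)
  ours <- roc_curve(scores, labels)$auc
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("nonfall", "fall"),
    direction = "<")))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
})

test_that("leave-one-out achieves perfect recovery on a separable set and conserves counts", {
  d <- sim_dataset(10, c(walk = 5, sit = 5), seed = 46)
  sim <- similarity_matrix(d$preprocessed)
  rep <- loo_evaluate(labeled_dataset(sim, d$labels))
  expect_equal(rep$tp + rep$fp + rep$tn + rep$fn, 20)
  expect_equal(rep$accuracy, 100)
  expect_equal(rep$sensitivity, 100)
  # consistency identities recomputed from counts
  expect_equal(rep$sensitivity, 100 * rep$tp / (rep$tp + rep$fn))
  expect_equal(rep$specificity, 100 * rep$tn / (rep$tn + rep$fp))
  expect_equal(rep$accuracy,
               100 * (rep$tp + rep$tn) / (rep$tp + rep$fp + rep$tn + rep$fn))
})

test_that("LOO predictions are invariant to sequence order", {
  d <- sim_dataset(4, c(slow_lie = 2, walk = 2), seed = 47)
  sim <- similarity_matrix(d$preprocessed)
  r1 <- loo_evaluate(labeled_dataset(sim, d$labels))
  set.seed(48)
  perm <- sample(length(d$preprocessed))
  sim_p <- similarity_matrix(d$preprocessed[perm],
                             kernel_config(sigma = sim$sigma))
  r2 <- loo_evaluate(labeled_dataset(sim_p, d$labels[perm]))
  m1 <- r1$per_sequence[order(r1$per_sequence$sequence_id), ]
  m2 <- r2$per_sequence[order(r2$per_sequence$sequence_id), ]
  expect_equal(m1$predicted, m2$predicted)
  # scores agree only to optimizer tolerance: reordering rows changes the
  # solver's path, not the separator it converges to
  expect_equal(m1$score, m2$score, tolerance = 5e-3)
})

test_that("the held-out column never leaks into a fold's training features", {
  sim <- clf_data$sim
  base <- loo_evaluate(clf_data$ds)
  set.seed(49)
  for (i in sample(length(sim$sequence_ids), 4)) {
    sim_bad <- sim
    sim_bad$values[, i] <- runif(nrow(sim$values))  # corrupt column only
    diag(sim_bad$values) <- diag(sim$values)
    r <- loo_evaluate(labeled_dataset(sim_bad, clf_data$d$labels))
    expect_identical(r$per_sequence$predicted[i],
                     base$per_sequence$predicted[i])
    expect_equal(r$per_sequence$score[i], base$per_sequence$score[i],
                 tolerance = 1e-9)
  }
})

test_that("LOO rejects degenerate folds and tiny datasets", {
  d <- sim_dataset(1, c(walk = 3), seed = 50)
  sim <- similarity_matrix(d$preprocessed)
  expect_error(loo_evaluate(labeled_dataset(sim, d$labels)), "single-class")
  d2 <- sim_dataset(1, c(walk = 1), seed = 51)
  sim2 <- similarity_matrix(d2$preprocessed)
  expect_error(loo_evaluate(labeled_dataset(sim2, d2$labels)), "at least 3")
})

test_that("cross-dataset evaluation trains its bandwidth and model on the training split only", {
  tr <- sim_dataset(5, c(walk = 3, sit = 2), seed = 52)
  te_cfg <- sim_config(coordinate_noise_px = 4)   # domain shift: 2x noise
  te_raw <- make_dataset(3, c(walk = 2, slow_lie = 2), config = te_cfg,
                         seed = 53)
  te <- lapply(te_raw$sequences, function(s) {
    s$sequence_id <- paste0("te_", s$sequence_id)
    preprocess_sequence(s)
  })
  rep <- cross_dataset_evaluate(tr$preprocessed, tr$labels,
                                te, te_raw$labels)
  expect_equal(rep$tp + rep$fp + rep$tn + rep$fn, 7)
  expect_equal(nrow(rep$per_sequence), 7)
  # single test sequence still yields a (degenerate-margin) report
  rep1 <- cross_dataset_evaluate(tr$preprocessed, tr$labels,
                                 te[1], te_raw$labels[1])
  expect_equal(rep1$tp + rep1$fp + rep1$tn + rep1$fn, 1)
  expect_error(cross_dataset_evaluate(tr$preprocessed, tr$labels,
                                      tr$preprocessed, tr$labels),
               "overlap")
})

test_that("aliased train/test cross evaluation reproduces training accuracy", {
  d <- clf_data$d
  alias <- lapply(d$preprocessed, function(s) {
    s$sequence_id <- paste0("alias_", s$sequence_id); s
  })
  rep <- cross_dataset_evaluate(d$preprocessed, d$labels, alias, d$labels)
  clf <- train_classifier(clf_data$ds)
  tr_acc <- 100 * mean(predict(clf, clf_data$sim)$predicted ==
                         ifelse(d$labels == "fall", "fall", "nonfall"))
  expect_equal(rep$accuracy, tr_acc)
})
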