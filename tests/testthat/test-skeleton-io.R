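test_that("well-formed CSV parses into an ordered sequence", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame_index,joint_id,x,y",
               "1,head,4,5", "1,hip,6,7", "1,ankle,8,9",
               "0,ankle,2.5,3", "0,head,0.5,1", "0,hip,1.5,2"), f)
  s <- read_skeleton_csv(f)
  expect_s3_class(s, "skeleton_sequence")
  expect_equal(n_frames(s), 2L)
  expect_equal(n_joints(s), 3L)
  expect_equal(s$joint_ids, c("ankle", "head", "hip"))  # sorted union
  expect_equal(frame_coords(s, 1)["head", ], c(0.5, 1), ignore_attr = TRUE)
  expect_false(any(s$missing))
})

test_that("joints absent from a frame are flagged missing, not an error", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame_index,joint_id,x,y",
               "0,head,0,0", "0,hip,1,1", "0,ankle,2,2",
               "1,hip,1,1", "1,ankle,2,2"), f)
  s <- read_skeleton_csv(f)
  expect_true(s$missing[2, match("head", s$joint_ids)])
  expect_false(any(s$missing[1, ]))
})

test_that("malformed CSV rows fail with a line number; empty file fails", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame_index,joint_id,x,y",
               "0,head,0,0", "0,hip,oops,1", "0,ankle,2,2"), f)
  expect_error(read_skeleton_csv(f), "line 3")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("frame_index,joint_id,x,y", f2)
  expect_error(read_skeleton_csv(f2), "empty")
  expect_error(read_skeleton_csv(file.path(tempdir(), "nope.csv")),
               "not found")
})

test_that("JSON keypoints dialect parses and applies the confidence threshold", {
  f <- withr::local_tempfile(fileext = ".json")
  n <- 15
  frame <- as.numeric(rbind(seq_len(n), seq_len(n) + 100, rep(1, n)))
  jsonlite::write_json(
    list(sequence_id = "k", fps = 25,
         joints = paste0("j", seq_len(n)), frames = list(frame)),
    f, auto_unbox = TRUE, digits = NA)
  s <- read_keypoints_json(f)
  expect_equal(n_frames(s), 1L)
  expect_equal(n_joints(s), 15L)
  expect_false(any(s$missing))
  # drop one joint's confidence to 0: flagged missing under default threshold
  frame[3 * 4] <- 0
  jsonlite::write_json(
    list(sequence_id = "k", fps = 25,
         joints = paste0("j", seq_len(n)), frames = list(frame)),
    f, auto_unbox = TRUE, digits = NA)
  s2 <- read_keypoints_json(f)
  expect_true(s2$missing[1, 4])
  expect_equal(sum(s2$missing), 1L)
})

test_that("JSON wrong arity and empty frame lists are format errors", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(sequence_id = "k", fps = 25,
                            joints = c("a", "b", "c"),
                            frames = list(c(1, 2, 3, 4))),
                       f, auto_unbox = TRUE)
  expect_error(read_keypoints_json(f), "expected 9")
  jsonlite::write_json(list(sequence_id = "k", fps = 25,
                            joints = c("a", "b", "c"), frames = list()),
                       f, auto_unbox = TRUE)
  expect_error(read_keypoints_json(f), "empty")
})

test_that("write/read round trips are bit-exact in both dialects", {
  set.seed(11)
  ev <- simulate_event("walk", seed = 5)
  s <- ev$sequence
  csv <- withr::local_tempfile(fileext = ".csv")
  write_skeleton_csv(s, csv)
  s2 <- read_skeleton_csv(csv, sequence_id = s$sequence_id)
  expect_identical(s2$joint_ids, sort(s$joint_ids))
  perm <- match(s2$joint_ids, s$joint_ids)
  expect_identical(s2$coords[, , 1], s$coords[, perm, 1])
  expect_identical(s2$coords[, , 2], s$coords[, perm, 2])
  expect_identical(s2$missing, unname(s$missing[, perm]))

  js <- withr::local_tempfile(fileext = ".json")
  write_keypoints_json(s, js)
  s3 <- read_keypoints_json(js)
  expect_identical(s3$joint_ids, s$joint_ids)   # JSON preserves joint order
  keep <- !s$missing
  expect_identical(s3$coords[, , 1][keep], s$coords[, , 1][keep])
  expect_identical(s3$coords[, , 2][keep], s$coords[, , 2][keep])
  expect_identical(s3$missing, s$missing)
})

test_that("linear imputation interpolates gaps and holds ends", {
  frames <- list(matrix(c(0, 0, 0, 0, 1, 2), 3, 2),
                 matrix(NA_real_, 3, 2),
                 matrix(c(2, 2, 2, 2, 3, 4), 3, 2))
  miss <- rbind(c(FALSE, FALSE, FALSE), c(TRUE, TRUE, TRUE),
                c(FALSE, FALSE, FALSE))
  s <- tiny_sequence(frames, missing = miss)
  li <- impute_missing(s, "linear")
  expect_equal(frame_coords(li, 2)["a", ], c(1, 1), ignore_attr = TRUE)
  expect_false(any(li$missing))
  expect_true(all(is.finite(li$coords)))
  ho <- impute_missing(s, "hold")
  expect_equal(frame_coords(ho, 2)["a", ], c(0, 0), ignore_attr = TRUE)
  dr <- impute_missing(s, "drop_frame")
  expect_equal(n_frames(dr), 2L)
})

test_that("imputation never alters observed coordinates and is a no-op when complete", {
  ev <- simulate_event("sit", seed = 9)
  s <- ev$sequence
  obs <- !s$missing
  for (method in c("linear", "hold")) {
    out <- impute_missing(s, method)
    expect_identical(out$coords[, , 1][obs], s$coords[, , 1][obs])
    expect_identical(out$coords[, , 2][obs], s$coords[, , 2][obs])
  }
  full <- impute_missing(s, "linear")
  expect_identical(impute_missing(full, "linear")$coords, full$coords)
  expect_identical(impute_missing(full, "drop_frame")$coords, full$coords)
})

test_that("unimputable and frame-destroying inputs error", {
  frames <- list(matrix(c(0, 0, 0, 0, 1, 2), 3, 2),
                 matrix(c(1, 1, 1, 1, 2, 3), 3, 2))
  miss <- rbind(c(TRUE, FALSE, FALSE), c(TRUE, FALSE, FALSE))
  fr <- lapply(frames, function(m) { m[1, ] <- NA; m })
  s <- tiny_sequence(fr, missing = miss)
  expect_error(impute_missing(s, "linear"), "every frame")
  expect_error(impute_missing(s, "drop_frame"), "every frame")
})

test_that("centroid centering matches hand arithmetic and is idempotent", {
  s <- tiny_sequence(list(matrix(c(0, 2, 1, 0, 0, 3), 3, 2)))
  cc <- center_frames(s, "centroid")
  expect_equal(frame_coords(cc, 1),
               matrix(c(-1, 1, 0, -1, -1, 2), 3, 2), ignore_attr = TRUE)
  expect_identical(center_frames(s, "none")$coords, s$coords)
  ev <- preprocess_sequence(simulate_event("walk", seed = 2)$sequence)
  means <- apply(ev$coords, c(1, 3), mean)
  expect_lt(max(abs(means)), 1e-12)
  again <- center_frames(ev, "centroid")
  expect_equal(again$coords, ev$coords, tolerance = 1e-14)
})

test_that("joint-anchored centering and error cases behave", {
  s <- tiny_sequence(list(matrix(c(1, 2, 3, 4, 5, 6), 3, 2)))
  cj <- center_frames(s, "joint:b")
  expect_equal(frame_coords(cj, 1)["b", ], c(0, 0), ignore_attr = TRUE)
  expect_error(center_frames(s, "joint:nose"), "unknown joint")
  expect_error(center_frames(s, "weird"), "unknown centering mode")
})

test_that("scale_frames yields unit Frobenius norm per frame", {
  ev <- preprocess_sequence(simulate_event("bend", seed = 3)$sequence,
                            scale = TRUE)
  nrm <- sqrt(apply(ev$coords^2, 1, sum))
  expect_equal(nrm, rep(1, n_frames(ev)), tolerance = 1e-12)
})

test_that("sequence constructor enforces its invariants", {
  expect_error(skeleton_sequence(array(0, c(1, 2, 2)), c("a", "b"), "x"),
               "at least 3 joints")
  expect_error(skeleton_sequence(array(0, c(1, 3, 2)), c("a", "a", "b"), "x"),
               "duplicate")
  bad <- array(0, c(1, 3, 2)); bad[1, 1, 1] <- Inf
  expect_error(skeleton_sequence(bad, c("a", "b", "c"), "x"), "non-finite")
})
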