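# Evaluation: optimal matching, accuracy, RMSE, confusion, ROI scoping.

test_that("perfect and empty detections give the trivial matchings", {
  tr <- data.frame(x_px = c(3, 10, 20), y_px = c(4, 4, 9))
  mt <- match_detections(tr, tr, max_dist_px = 5)
  expect_equal(nrow(mt$pairs), 3L)
  expect_true(all(mt$pairs$dist_px == 0))
  expect_equal(detection_accuracy(mt), 1.0)
  mt0 <- match_detections(tr, tr[0, ], max_dist_px = 5)
  expect_equal(length(mt0$unmatched_truth), 3L)
  expect_equal(nrow(mt0$pairs), 0L)
})

test_that("assignment is optimal, not greedy, on crossing configurations", {
  # greedy would grab the 1.0 distance pair and force a far/failed second match
  tr <- data.frame(x_px = c(0, 2), y_px = c(0, 0))
  dt <- data.frame(x_px = c(1, 4), y_px = c(0, 0))
  mt <- match_detections(tr, dt, max_dist_px = 2.5)
  expect_equal(nrow(mt$pairs), 2L)   # optimal pairs 0->1 (d1) and 2->4 (d2)
  expect_equal(sum(mt$pairs$dist_px), 3)
  # random 3v3 configurations match the permutation oracle
  set.seed(41)
  for (rep in 1:20) {
    tr <- data.frame(x_px = runif(3, 0, 10), y_px = runif(3, 0, 10))
    dt <- data.frame(x_px = runif(3, 0, 10), y_px = runif(3, 0, 10))
    mt <- match_detections(tr, dt, max_dist_px = 4)
    want <- match_oracle(tr, dt, 4)
    expect_equal(nrow(mt$pairs), want$n_matched)
    if (want$n_matched > 0)
      expect_equal(sum(mt$pairs$dist_px), want$total_dist, tolerance = 1e-9)
  }
})

test_that("bookkeeping identities hold and sides are one-to-one", {
  set.seed(43)
  tr <- data.frame(x_px = runif(8, 0, 50), y_px = runif(8, 0, 50))
  dt <- data.frame(x_px = runif(6, 0, 50), y_px = runif(6, 0, 50))
  mt <- match_detections(tr, dt, max_dist_px = 10)
  expect_equal(nrow(mt$pairs) + length(mt$unmatched_truth), 8L)
  expect_equal(nrow(mt$pairs) + length(mt$unmatched_detections), 6L)
  expect_false(any(duplicated(mt$pairs$truth_idx)))
  expect_false(any(duplicated(mt$pairs$det_idx)))
  expect_true(all(mt$pairs$dist_px <= 10))
})

test_that("accuracy reads only TP and truth; FP reported separately", {
  tr <- data.frame(x_px = c(0, 10), y_px = c(0, 0))
  dt <- data.frame(x_px = c(0, 10, 40, 50), y_px = c(0, 0, 0, 0))
  mt <- match_detections(tr, dt, max_dist_px = 2)
  expect_equal(detection_accuracy(mt), 1.0)
  expect_equal(length(mt$unmatched_detections), 2L)
  # 612 truth with half matched -> 0.5 (the small reference image's count)
  tr6 <- data.frame(x_px = seq_len(612) * 10, y_px = rep(0, 612))
  dt6 <- tr6[seq_len(306), ]
  expect_equal(detection_accuracy(match_detections(tr6, dt6, 1)), 0.5)
  expect_error(detection_accuracy(match_detections(tr6[0, ], dt6, 1)),
               "undefined")
})

test_that("removing one matched detection lowers accuracy by 1/total", {
  tr <- data.frame(x_px = c(0, 10, 20, 30), y_px = rep(0, 4))
  full <- detection_accuracy(match_detections(tr, tr, 1))
  drop1 <- detection_accuracy(match_detections(tr, tr[-2, ], 1))
  expect_equal(full - drop1, 1 / 4)
})

test_that("center RMSE matches closed forms and dominates the mean", {
  tr <- data.frame(x_px = c(0, 0), y_px = c(0, 10))
  dt <- data.frame(x_px = c(3, 4), y_px = c(0, 10))
  mt <- match_detections(tr, dt, max_dist_px = 5)
  expect_equal(center_rmse(mt), sqrt((9 + 16) / 2), tolerance = 1e-12)
  # rigid shift by (1, 0) -> RMSE exactly 1
  dt2 <- data.frame(x_px = tr$x_px + 1, y_px = tr$y_px)
  expect_equal(center_rmse(match_detections(tr, dt2, 5)), 1.0)
  expect_error(center_rmse(match_detections(tr, tr[0, ], 5)), "no matched")
  # Jensen: RMSE >= mean distance on random instances
  set.seed(47)
  for (rep in 1:10) {
    tr <- data.frame(x_px = runif(6, 0, 30), y_px = runif(6, 0, 30))
    dt <- data.frame(x_px = tr$x_px + rnorm(6), y_px = tr$y_px + rnorm(6))
    mt <- match_detections(tr, dt, max_dist_px = 10)
    expect_gte(center_rmse(mt) + 1e-12, mean(mt$pairs$dist_px))
  }
  # per-group breakdown covers all matched pairs
  groups <- c(0, 1)
  r <- center_rmse(mt, groups = rep(groups, 3))
  expect_named(r, c("overall", "per_group"))
})

test_that("size confusion is diagonal for perfect recovery and flags
           systematic mislabeling", {
  tr <- data.frame(x_px = c(0, 10, 20, 30), y_px = rep(0, 4),
                   diameter_nm = c(6, 6, 12, 12))
  dt <- data.frame(x_px = tr$x_px, y_px = tr$y_px, group = c(0L, 0L, 1L, 1L))
  mt <- match_detections(tr, dt, 1)
  conf <- size_confusion(mt, tr$diameter_nm, dt$group)
  expect_equal(unclass(conf)[1, ], c(`0` = 2L, `1` = 0L))
  expect_equal(unclass(conf)[2, ], c(`0` = 0L, `1` = 2L))
  expect_equal(attr(conf, "recall"), c(1, 1))
  # all small labeled large -> off-diagonal first row
  dt2 <- dt; dt2$group <- c(1L, 1L, 1L, 1L)
  conf2 <- size_confusion(match_detections(tr, dt2, 1), tr$diameter_nm, dt2$group)
  expect_equal(unclass(conf2)["6", "1"], 2L)
})

test_that("an ROI mask restricts scoring on both sides", {
  tr <- data.frame(x_px = c(5, 25), y_px = c(5, 5), diameter_nm = c(6, 6))
  dt <- data.frame(x_px = c(5, 25), y_px = c(5, 5))
  roi <- matrix(FALSE, 32, 32); roi[, 1:16] <- TRUE   # left half only
  mt <- match_detections(tr, dt, 3, roi = roi)
  expect_equal(mt$n_truth, 1L)
  expect_equal(mt$n_detections, 1L)
  expect_equal(detection_accuracy(mt), 1.0)
})

test_that("evaluation_report bundles the metrics coherently", {
  sp <- scene_spec(96, 96, counts_per_diameter = c(2L, 2L))
  pr <- render_scene(sp, seed = 19)
  recs <- extract_particles(pr$mask, extraction_params())
  rep <- evaluation_report(pr$truth, recs, pixel_size_nm = 1.11)
  expect_equal(rep$accuracy, 1.0)
  expect_lt(rep$rmse$overall, 1)
  expect_equal(rep$false_positives, 0L)
  expect_output(print(rep), "accuracy")
})
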