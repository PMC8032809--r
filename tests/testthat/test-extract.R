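# Mask-to-particle extraction: binarization, components, statistics,
# exact 1-D clustering, end-to-end record recovery.

test_that("binarize thresholds inclusively and handles edge thresholds", {
  m <- matrix(c(0, 0.2, 0.5, 0.9), 2, 2)
  expect_equal(sum(binarize(m, 0.5)), 2L)
  expect_true(all(binarize(m, 0)))            # threshold at minimum
  expect_false(any(binarize(matrix(0, 3, 3), 0.5)))
  # ramp: count below/above follows from arithmetic
  ramp <- matrix(seq(0, 1, length.out = 101), 1)
  expect_equal(sum(binarize(ramp, 0.5)), 51L)
})

test_that("connectivity 4 vs 8 differ exactly on diagonal contacts", {
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- m[2, 2] <- TRUE
  expect_equal(attr(connected_components(m, 8L), "n_components"), 1L)
  expect_equal(attr(connected_components(m, 4L), "n_components"), 2L)
  expect_equal(attr(connected_components(matrix(FALSE, 3, 3), 8L),
                    "n_components"), 0L)
})

test_that("labeling matches an independent flood-fill oracle", {
  set.seed(101)
  for (rep in 1:25) {
    m <- matrix(runif(32 * 32) < 0.35, 32, 32)
    for (conn in c(4L, 8L)) {
      ours <- canon_labels(connected_components(m, conn))
      oracle <- floodfill_oracle(m, conn)
      expect_identical(unclass(ours)[, ], oracle[, ],
                       label = sprintf("rep %d conn %d", rep, conn))
    }
  }
})

test_that("labels are assigned in first-encounter raster order", {
  m <- matrix(FALSE, 5, 5)
  m[1, 4] <- TRUE          # row 0, col 3: encountered first (row-major)
  m[2, 1] <- TRUE          # row 1, col 0: second
  m[5, 5] <- TRUE
  lab <- connected_components(m, 8L)
  expect_equal(lab[1, 4], 1L)
  expect_equal(lab[2, 1], 2L)
  expect_equal(lab[5, 5], 3L)
})

test_that("component statistics are exact means and counts", {
  m <- matrix(FALSE, 8, 8)
  m[4, 6] <- TRUE                             # single pixel r=3, c=5 (0-based)
  st <- component_stats(connected_components(m, 8L))
  expect_equal(st$x_px, 5); expect_equal(st$y_px, 3); expect_equal(st$area_px, 1L)
  # 11x11 square at rows/cols 0..10
  m2 <- matrix(FALSE, 12, 12); m2[1:11, 1:11] <- TRUE
  st2 <- component_stats(connected_components(m2, 8L))
  expect_equal(st2$x_px, 5); expect_equal(st2$y_px, 5)
  expect_equal(st2$area_px, 121L)
  # arbitrary component equals a direct summation oracle
  set.seed(7)
  m3 <- matrix(FALSE, 10, 10)
  px <- sample(100, 10)
  m3[px] <- TRUE
  lab3 <- connected_components(m3, 8L)
  st3 <- component_stats(lab3)
  for (l in st3$label) {
    idx <- which(lab3 == l)
    expect_equal(st3$x_px[st3$label == l], mean((idx - 1) %/% 10))
    expect_equal(st3$y_px[st3$label == l], mean((idx - 1) %% 10))
  }
  # partition property: areas sum to foreground count
  expect_equal(sum(st3$area_px), sum(m3))
})

test_that("cluster_sizes is optimal, deterministic and permutation-stable", {
  r <- cluster_sizes(c(20, 22, 24, 90, 95, 100), 2L)
  expect_equal(r$assignment, c(0L, 0L, 0L, 1L, 1L, 1L))
  expect_equal(r$group_mean_area, c(22, 95))
  # one group / degenerate input
  r1 <- cluster_sizes(rep(42, 5), 1L)
  expect_true(all(r1$assignment == 0))
  expect_equal(r1$group_mean_area, 42)
  expect_error(cluster_sizes(c(3, 4), 3L), "at least")
  # matches the exhaustive optimal partition oracle (on sqrt scale)
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    k <- sample(1:3, 1)
    if (k > n) next
    areas <- sample(1:400, n, replace = TRUE)
    got <- cluster_sizes(areas, k)
    want <- partition_oracle(sqrt(areas), k)
    # compare achieved SSE on sqrt scale (labelings may tie)
    sse <- function(asg) sum(unlist(lapply(split(sqrt(areas), asg),
                                           function(v) sum((v - mean(v))^2))))
    expect_equal(sse(got$assignment), want$sse, tolerance = 1e-9)
  }
  # permutation equivariance
  areas <- c(12, 80, 15, 95, 11, 70)
  base <- cluster_sizes(areas, 2L)$assignment
  perm <- sample(6)
  shuf <- cluster_sizes(areas[perm], 2L)$assignment
  expect_equal(shuf, base[perm])
})

test_that("6 vs 12 nm footprint areas separate perfectly at 1.11 nm/px", {
  # equivalent-disk areas ~23 and ~92 px^2
  a6 <- round(pi * (6 / 1.11 / 2)^2); a12 <- round(pi * (12 / 1.11 / 2)^2)
  areas <- c(a6 + c(-2, 0, 3), a12 + c(-5, 0, 4))
  r <- cluster_sizes(areas, 2L)
  expect_equal(r$assignment, c(0L, 0L, 0L, 1L, 1L, 1L))
})

test_that("extract_particles composes the pipeline and filters small noise", {
  tm <- render_target_mask(data.frame(x_px = 20, y_px = 30, diameter_nm = 12),
                           64, 64)
  recs <- extract_particles(tm, extraction_params(n_groups = 1L))
  expect_equal(nrow(recs), 1L)
  expect_equal(recs$x_px, 20); expect_equal(recs$y_px, 30)
  # equivalent-circle diameter of the 11 px square mask: 2*sqrt(121/pi)*1.11
  expect_equal(recs$diameter_nm_est, 2 * sqrt(121 / pi) * 1.11,
               tolerance = 1e-12)
  expect_gt(recs$diameter_nm_est, 10.5); expect_lt(recs$diameter_nm_est, 14)
  # sub-min-area components vanish
  small <- matrix(0, 16, 16); small[4, 4] <- 1; small[4, 5] <- 1
  expect_equal(nrow(extract_particles(small, extraction_params(min_area_px = 4L))),
               0L)
  # empty mask -> empty frame, not an error
  expect_equal(nrow(extract_particles(matrix(0, 8, 8))), 0L)
})

test_that("target-mask extraction recovers truth exactly on clean scenes", {
  sp <- scene_spec(192, 192, counts_per_diameter = c(4L, 3L))
  for (seed in c(2, 12)) {
    pr <- render_scene(sp, seed = seed)
    recs <- extract_particles(pr$mask, extraction_params())
    expect_equal(nrow(recs), nrow(pr$truth))
    mt <- match_detections(pr$truth, recs, max_dist_px = 1)
    expect_equal(nrow(mt$pairs), nrow(pr$truth))   # centroids within 1 px
    conf <- size_confusion(mt, pr$truth$diameter_nm, recs$group)
    expect_equal(unclass(conf)[1, 2], 0L); expect_equal(unclass(conf)[2, 1], 0L)
  }
})

test_that("records are sorted by (y, x) and groups ascend with area", {
  tr <- data.frame(x_px = c(50, 10, 30), y_px = c(40, 40, 10),
                   diameter_nm = c(6, 12, 6))
  tm <- render_target_mask(tr, 64, 64)
  recs <- extract_particles(tm, extraction_params())
  expect_equal(recs$y_px, sort(recs$y_px))
  expect_true(all(diff(order(recs$y_px, recs$x_px)) > 0))
  m6 <- mean(recs$area_px[recs$group == 0])
  m12 <- mean(recs$area_px[recs$group == 1])
  expect_lt(m6, m12)
})
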