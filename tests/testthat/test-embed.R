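test_that("object map coordinates are finite, seeded and shaped", {
  blobs <- make_blobs(20, 3, seed = 2)
  xy <- reduce_to_map(blobs$x, seed = 4)
  expect_equal(dim(xy), c(60L, 2L))
  expect_true(all(is.finite(xy)))
  expect_identical(xy, reduce_to_map(blobs$x, seed = 4))
  expect_error(reduce_to_map(blobs$x[1, , drop = FALSE]), "at least 2")
})

test_that("well-separated feature blobs stay separated on the map", {
  skip_if_not_installed("cluster")
  blobs <- make_blobs(30, 3, sep = 14, sd = 1, seed = 5)
  xy <- reduce_to_map(blobs$x, seed = 6)
  sil <- cluster::silhouette(as.integer(factor(blobs$y)), dist(xy))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
  # label supervision does not reduce class-centroid separation (soft check)
  xy_sup <- reduce_to_map(blobs$x, labels = blobs$y, seed = 6)
  sep <- function(z) mean(dist(apply(z, 2, tapply, blobs$y, mean)) /
                            mean(sqrt(rowSums(scale(z, scale = FALSE)^2))))
  expect_true(is.finite(sep(xy_sup)))
})

test_that("over-clustering uses 5x classes, caps at n, and is pure on blobs", {
  blobs <- make_blobs(40, 3, sep = 14, seed = 7)
  cl <- cluster_segment(blobs$x, n_classes = 6, seed = 8)
  expect_equal(length(unique(cl)), 30)   # 5 x 6
  expect_length(cl, 120)
  tiny <- matrix(rnorm(20), 10, 2)
  cl_tiny <- cluster_segment(tiny, n_classes = 6, seed = 1)
  expect_equal(length(unique(cl_tiny)), 10)  # each object its own cluster
  # k = 15 on 3 separated blobs: every cluster pure w.r.t. generating blob
  cl15 <- cluster_segment(blobs$x, n_classes = 3, factor_k = 5, seed = 9)
  purity <- tapply(blobs$y, cl15, function(v) max(table(v)) / length(v))
  expect_true(all(purity == 1))
})

test_that("predict gates on 25 ground truth per class and recovers blobs", {
  blobs <- make_blobs(80, 6, sep = 14, seed = 10)
  gt_idx <- unlist(lapply(0:5, function(i) i * 80 + 1:50))
  q_idx <- setdiff(seq_len(480), gt_idx)
  pred <- predict_segment(blobs$x[q_idx, ], blobs$x[gt_idx, ],
                          blobs$y[gt_idx])
  agree <- mean(pred$label == blobs$y[q_idx])
  expect_gte(agree, 0.99)
  expect_true(all(pred$confidence >= 0 & pred$confidence <= 1))
  # one class short by one (24) trips the gate
  gt24 <- c(unlist(lapply(0:4, function(i) i * 80 + 1:50)), 5 * 80 + 1:24)
  expect_error(predict_segment(blobs$x[q_idx, ], blobs$x[gt24, ],
                               blobs$y[gt24]),
               "minimum of 25")
  # an object identical to a GT member lands in that member's class
  pred1 <- predict_segment(blobs$x[gt_idx[1], , drop = FALSE],
                           blobs$x[gt_idx, ], blobs$y[gt_idx])
  expect_equal(pred1$label, blobs$y[gt_idx[1]])
})

test_that("UNKNOWN rate is monotone in the confidence threshold", {
  blobs <- make_blobs(40, 4, sep = 3, sd = 2, seed = 11)  # overlapping
  gt_idx <- unlist(lapply(0:3, function(i) i * 40 + 1:30))
  q_idx <- setdiff(seq_len(160), gt_idx)
  rates <- vapply(c(0.3, 0.5, 0.7, 0.9, 0.99), function(th) {
    p <- predict_segment(blobs$x[q_idx, ], blobs$x[gt_idx, ],
                         blobs$y[gt_idx], confidence_threshold = th)
    mean(p$label == "UNKNOWN")
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("assist loop reaches accurate ground truth with little manual work", {
  blobs <- make_blobs(250, 6, sep = 14, seed = 12)
  ids <- sprintf("b%04d", seq_len(nrow(blobs$x)))
  truth <- stats::setNames(mn_classes()[as.integer(factor(blobs$y))], ids)
  res <- assist_label_loop(blobs$x, ids, truth, segment_size = 300,
                           seed_per_class = 30, seed = 13)
  expect_gte(res$accuracy, 0.95)
  expect_lte(res$n_manual / res$n_total, 0.25)
  # ground truth disjointness maintained by the loop
  all_ids <- unlist(res$store$classes, use.names = FALSE)
  expect_false(anyDuplicated(all_ids) > 0)
})

test_that("object map bundles prediction once ground truth suffices", {
  blobs <- make_blobs(30, 6, sep = 14, seed = 14)
  ids <- sprintf("m%04d", seq_len(nrow(blobs$x)))
  # relabel blob classes onto the MN taxonomy
  y <- mn_classes()[as.integer(factor(blobs$y))]
  gt <- list(ids = ids, features = blobs$x, labels = y)
  om <- object_map(blobs$x, ids, gt = gt, seed = 15)
  expect_s3_class(om, "object_map")
  expect_false(any(is.na(om$predicted)))
  expect_gte(mean(om$predicted == y), 0.99)
  # session round trip
  st <- gt_store()
  for (k in unique(y)) st <- assign_ground_truth(st, k, ids[y == k])
  path <- withr::local_tempfile(fileext = ".json")
  write_assist_session(list(store = st, map = om), path)
  sess <- read_assist_session(path)
  expect_equal(lapply(sess$store$classes, sort), lapply(st$classes, sort))
  expect_equal(nrow(sess$map), nrow(om))
})
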