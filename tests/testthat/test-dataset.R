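test_that("min-max normalization maps any input into [0, 1]", {
  expect_equal(normalize_image(matrix(c(0, 10, 5, 10), 2)),
               matrix(c(0, 1, 0.5, 1), 2))
  expect_equal(normalize_image(matrix(7, 3, 3)), matrix(0, 3, 3))
  x16 <- matrix(sample.int(65535, 64), 8)
  out <- normalize_image(x16)
  expect_true(all(out >= 0 & out <= 1))
  expect_equal(min(out), 0)
  expect_equal(max(out), 1)
  expect_error(normalize_image(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("segments sample without replacement, exhaust small pools, reproduce", {
  ids <- sprintf("o%05d", 1:4000)
  seg <- make_segment(ids, size = 1500, seed = 3)
  expect_length(seg, 1500)
  expect_false(anyDuplicated(seg) > 0)
  expect_identical(seg, make_segment(ids, size = 1500, seed = 3))
  expect_length(make_segment(ids[1:100], size = 1500, seed = 1), 100)
  expect_error(make_segment(character(0)), "empty")
  segs <- make_segments(ids, n_segments = 2, size = 1500, seed = 5)
  expect_equal(length(unique(unlist(segs))), 3000)
})

test_that("ground-truth store keeps classes disjoint under reassignment", {
  st <- gt_store()
  st <- assign_ground_truth(st, "BN", "x")
  st <- assign_ground_truth(st, "BN_MN", "x")
  expect_equal(gt_counts(st)[["BN"]], 0)
  expect_equal(st$classes$BN_MN, "x")
  expect_error(assign_ground_truth(st, "UNKNOWN", "y"), "UNKNOWN")
  # 50 per class across six classes totals 300
  st2 <- gt_store()
  ids <- sprintf("g%03d", 1:300)
  for (i in seq_along(mn_classes()))
    st2 <- assign_ground_truth(st2, mn_classes()[i],
                               ids[(i - 1) * 50 + 1:50])
  expect_equal(sum(gt_counts(st2)), 300)
  # property: disjointness after many random (re)assignments
  set.seed(11)
  st3 <- gt_store()
  pool <- sprintf("p%03d", 1:40)
  for (i in 1:1000)
    st3 <- assign_ground_truth(st3, sample(mn_classes(), 1), sample(pool, 1))
  all_ids <- unlist(st3$classes, use.names = FALSE)
  expect_false(anyDuplicated(all_ids) > 0)
  # JSON round trip
  path <- withr::local_tempfile(fileext = ".json")
  write_gt_store(st3, path)
  st4 <- read_gt_store(path)
  expect_equal(lapply(st4$classes, sort), lapply(st3$classes, sort))
})

test_that("80/10/10 split uses floor + priority-order remainder, stratified", {
  mk <- function(sizes) {
    st <- gt_store()
    at <- 0
    for (i in seq_along(sizes)) {
      st <- assign_ground_truth(st, mn_classes()[i],
                                sprintf("s%05d", at + seq_len(sizes[i])))
      at <- at + sizes[i]
    }
    st
  }
  sp10 <- split_ground_truth(mk(rep(10, 6)), seed = 1)
  t10 <- table(sp10$label, sp10$split)
  expect_true(all(t10[, "train"] == 8 & t10[, "validation"] == 1 &
                    t10[, "test"] == 1))
  # class of 147 -> 118/15/14
  sp147 <- split_ground_truth(mk(c(147, rep(10, 5))), seed = 2)
  t147 <- table(sp147$label, sp147$split)[mn_classes()[1], ]
  expect_equal(unname(t147[c("train", "validation", "test")]), c(118, 15, 14))
  # sizes divisible by 10 -> exact 80/10/10 overall
  sizes <- c(10000, 1500, 10000, 1500, 3500, 5000)  # 31,500 ground truth
  sp <- split_ground_truth(mk(sizes), seed = 3)
  expect_equal(as.vector(table(sp$split)), c(25200, 3150, 3150))
  # partition of the store, disjoint cover
  expect_equal(nrow(sp), 31500)
  expect_false(anyDuplicated(sp$object_id) > 0)
  expect_error(split_ground_truth(mk(c(2, rep(10, 5)))), "fewer than 3")
})

test_that("class balancing oversamples to the majority and keeps originals", {
  cls <- list(A = sprintf("a%03d", 1:100), B = sprintf("b%03d", 1:50))
  bal <- balance_classes(cls, seed = 4)
  expect_equal(vapply(bal, length, 1L), c(A = 100L, B = 100L))
  expect_true(all(cls$B %in% bal$B))
  expect_true(all(bal$B %in% cls$B))
  # fixed point when already balanced
  expect_identical(balance_classes(list(A = cls$A, B = cls$A), seed = 1),
                   list(A = cls$A, B = cls$A))
  # uniform class frequency after balancing
  bal3 <- balance_classes(list(A = letters[1:7], B = letters[1:3],
                               C = letters[1:5]), seed = 9)
  expect_true(all(vapply(bal3, length, 1L) == 7))
})

test_that("dihedral augmentations preserve labels and component counts", {
  cell <- render_cell(cell_spec(2, 1), seed = 21)
  r180 <- augment_image(augment_image(cell, transform = "rot180"),
                        transform = "rot180")
  expect_identical(r180$dna, cell$dna)
  r360 <- cell
  for (i in 1:4) r360 <- augment_image(r360, transform = "rot90")
  expect_identical(r360$dna, cell$dna)
  base_count <- count_components(cell$mask)
  for (tr in c("identity", "rot90", "rot180", "rot270", "flip_h", "flip_v")) {
    aug <- augment_image(cell, transform = tr)
    expect_equal(aug$truth_label, cell$truth_label)
    expect_equal(count_components(aug$mask), base_count, info = tr)
  }
  # random draw is seeded
  a1 <- augment_image(cell, seed = 5)
  a2 <- augment_image(cell, seed = 5)
  expect_identical(a1$bf, a2$bf)
})
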