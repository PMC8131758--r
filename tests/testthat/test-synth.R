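test_that("truth labels follow the six-class taxonomy", {
  expect_equal(render_cell(cell_spec(2, 1), seed = 1)$truth_label, "BN_MN")
  expect_equal(render_cell(cell_spec(1, 0), seed = 1)$truth_label, "MONO")
  expect_equal(render_cell(cell_spec(1, 2), seed = 1)$truth_label, "MONO_MN")
  expect_equal(render_cell(cell_spec(3, 0), seed = 1)$truth_label, "POLY")
  expect_equal(
    render_cell(cell_spec(2, 1, "overlapping_nuclei"), seed = 1)$truth_label,
    "IRREG")
  # taxonomy is a pure function of geometry for regular morphology
  expect_equal(label_from_geometry(4, 0), "POLY")
  expect_error(label_from_geometry(5, 0), "1..4")
  expect_error(cell_spec(1, 0, "size_mismatch"), "requires n_nuclei >= 2")
})

test_that("noiseless DNA mask has exactly n_nuclei + n_mn components", {
  one <- render_cell(cell_spec(1, 0), seed = 3)
  expect_equal(count_components(one$mask), 1L)
  set.seed(7)
  for (i in 1:60) {
    n <- sample(1:4, 1)
    mn <- if (n <= 2) sample(0:2, 1) else 0L
    spec <- cell_spec(n, mn,
                      nucleus_radius = runif(1, 8, 12),
                      mn_diameter_ratio = runif(1, 1 / 16, 1 / 3),
                      blur_sigma = runif(1, 0.4, 1.2),
                      noise_sd = runif(1, 0.01, 0.06))
    cell <- render_cell(spec, seed = 1000 + i)
    expect_equal(count_components(cell$mask), n + mn,
                 info = sprintf("case %d: n=%d mn=%d", i, n, mn))
  }
})

test_that("brightfield cytoplasm encloses all DNA objects", {
  for (s in 1:10) {
    cell <- render_cell(cell_spec(2, 2), seed = s)
    # every mask pixel lies where the (pre-noise) cytoplasm disk is bright
    bf_clean <- cell$bf
    expect_true(all(bf_clean[cell$mask] > 0.15))
  }
})

test_that("labeled dataset generation is seeded, sized and mixed correctly", {
  cfg <- synth_config(600, seed = 5, difficulty = "easy")
  ds <- generate_labeled_dataset(cfg)
  expect_equal(dim(ds$images), c(64, 64, 2, 600))
  expect_equal(nrow(ds$manifest), 600)
  expect_false(anyDuplicated(ds$manifest$object_id) > 0)
  # empirical class fractions within binomial 3-SE of the uniform mixture
  counts <- table(factor(ds$manifest$truth_label, levels = mn_classes()))
  se <- sqrt(600 * (1 / 6) * (5 / 6))
  expect_true(all(abs(counts - 100) <= 3 * se))
  # determinism: identical config + seed => bit-identical dataset
  ds2 <- generate_labeled_dataset(cfg)
  expect_identical(ds$images, ds2$images)
  expect_identical(ds$manifest, ds2$manifest)
  # degenerate mixture
  mix <- stats::setNames(c(1, 0, 0, 0, 0, 0), mn_classes())
  dmono <- generate_labeled_dataset(synth_config(30, class_mixture = mix,
                                                 seed = 2))
  expect_true(all(dmono$manifest$truth_label == "MONO"))
  expect_error(synth_config(10, class_mixture = stats::setNames(rep(0.3, 6),
                                                                mn_classes())),
               "sum to 1")
})

test_that("dose-response cohort has the configured file structure and MN rate", {
  cfg <- dose_response_config(
    doses = c("solvent", "dosed"),
    mn_probability_per_dose = c(0.01, 0.05),
    mode = "cytb", replicates_per_dose = 2L, files_per_replicate = 3L,
    events_per_file = 5000L, seed = 9)
  cohort <- generate_dose_response_cohort(cfg, render = "counts")
  man <- cohort$manifest
  expect_equal(length(unique(man$file_id)), 12)  # 2 doses x 2 reps x 3 files
  expect_true(all(table(man$file_id) == 5000))
  # per-file BN MN fraction within 3-SE binomial of the dose probability
  for (fid in unique(man$file_id)) {
    sub <- man[man$file_id == fid, ]
    p <- cfg$mn_probability_per_dose[match(sub$dose[1], cfg$doses)]
    bn <- sum(sub$truth_label %in% c("BN", "BN_MN"))
    mn <- sum(sub$truth_label == "BN_MN")
    expect_lt(abs(mn - bn * p), 3 * sqrt(bn * p * (1 - p)) + 1e-9)
  }
  # null chemical: equal probabilities differ only by sampling noise
  null_cfg <- dose_response_config(
    doses = c("solvent", "dosed"), mn_probability_per_dose = c(0.03, 0.03),
    replicates_per_dose = 1L, files_per_replicate = 3L,
    events_per_file = 4000L, seed = 10)
  nc <- generate_dose_response_cohort(null_cfg, render = "counts")$manifest
  rate <- sapply(c("solvent", "dosed"), function(d) {
    sub <- nc[nc$dose == d, ]
    sum(sub$truth_label == "BN_MN") / sum(sub$truth_label %in% c("BN", "BN_MN"))
  })
  expect_lt(abs(diff(rate)), 3 * sqrt(2 * 0.03 * 0.97 / (4000 * 0.45)))
})

test_that("TIFF + manifest round trip preserves the dataset", {
  ds <- easy_dataset()
  small <- ds
  small$images <- ds$images[, , , 1:8, drop = FALSE]
  small$manifest <- ds$manifest[1:8, ]
  dir <- withr::local_tempdir()
  paths <- write_dataset(small, dir, basename = "t")
  back <- read_dataset(paths[["tiff"]])
  expect_equal(back$manifest$object_id, small$manifest$object_id)
  expect_equal(back$manifest$truth_label, small$manifest$truth_label)
  # 16-bit storage: equal to within one quantization step
  expect_lt(max(abs(back$images - small$images)), 1 / 65535 + 1e-9)
})
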