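test_that("sample scoring derives MN frequencies and excludes IRREG/UNKNOWN", {
  preds <- c(rep("BN", 1900), rep("BN_MN", 100), rep("MONO", 500),
             rep("IRREG", 50), rep("UNKNOWN", 25))
  s <- score_sample(preds, file_id = "f1", min_bn = 1000)
  expect_equal(s$pct_mn_bn, 5.0)
  expect_equal(s$n_scorable, 2500)  # IRREG and UNKNOWN never counted
  expect_true(s$qc_pass)            # 2000 BN cells, double the 1000 minimum
  s0 <- score_sample(c(rep("BN", 10), rep("MONO", 5)), min_bn = 5)
  expect_equal(s0$pct_mn_bn, 0.0)
  expect_equal(s0$pct_bn, 100 * 10 / 15)
  expect_error(score_sample(character(0)), "empty")
})

test_that("CBPI cytostasis matches hand computation and flags the band edge", {
  eq <- cytostasis_cbpi(c(600, 300, 100), c(600, 300, 100))
  expect_equal(eq$cytotoxicity, 0)
  r <- cytostasis_cbpi(treated = c(800, 150, 50), control = c(600, 300, 100))
  expect_equal(r$cbpi_control, 1.5)
  expect_equal(r$cbpi_treated, 1.25)
  expect_equal(r$cytotoxicity, 50.0)
  expect_false(r$exceeds_limit)
  # 62% cytotoxicity exceeds the 55 +/- 5% band
  hot <- cytostasis_cbpi(c(1000 - 190, 190, 0), c(500, 500, 0))
  expect_equal(hot$cytotoxicity, 62, tolerance = 1e-9)
  expect_true(hot$exceeds_limit)
  expect_error(cytostasis_cbpi(c(10, 5, 5), c(100, 0, 0)), "undefined")
  # CBPI bounded in [1, 3]
  expect_equal(cytostasis_cbpi(c(0, 0, 10), c(5, 5, 0))$cbpi_treated, 3)
})

test_that("relative-count cytotoxicity handles growth and inhibition", {
  expect_equal(relative_count_cytotoxicity(100, 100)$cytotoxicity, 0)
  expect_equal(relative_count_cytotoxicity(80, 100)$cytotoxicity, 20.0)
  expect_lt(relative_count_cytotoxicity(110, 100)$cytotoxicity, 0)
  expect_error(relative_count_cytotoxicity(50, 0), "> 0")
})

test_that("one-sided Fisher p equals exhaustive hypergeometric enumeration", {
  expect_equal(fisher_exact_one_sided(0, 10, 0, 10), 1.0)
  expect_equal(fisher_exact_one_sided(3, 10, 0, 10),
               enum_fisher_greater(3, 10, 0, 10), tolerance = 1e-12)
  # agreement with stats::fisher.test as an independent implementation
  set.seed(17)
  for (i in 1:40) {
    n_d <- sample(1:40, 1); n_c <- sample(1:40, 1)
    mn_d <- sample(0:n_d, 1); mn_c <- sample(0:n_c, 1)
    tab <- matrix(c(mn_d, n_d - mn_d, mn_c, n_c - mn_c), 2)
    expect_equal(fisher_exact_one_sided(mn_d, n_d, mn_c, n_c),
                 stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
  # monotone non-increasing in mn_dosed at fixed margins
  ps <- vapply(0:12, function(k) fisher_exact_one_sided(k, 20, 2, 25),
               numeric(1))
  expect_true(all(diff(ps) <= 1e-15))
  expect_error(fisher_exact_one_sided(1, 0, 0, 10), "degenerate")
})

test_that("dose-response analysis summarizes replicates and tests vs control", {
  mk_score <- function(fid, dose, bn, bn_mn)
    score_sample(c(rep("BN", bn), rep("BN_MN", bn_mn), rep("MONO", 100)),
                 file_id = fid, dose = dose, min_bn = 1)
  scores <- rbind(
    mk_score("c1", "ctl", 1000, 10), mk_score("c2", "ctl", 1000, 10),
    mk_score("d1", "dose", 960, 40), mk_score("d2", "dose", 940, 60))
  res <- dose_response_analysis(scores, control = "ctl", endpoint = "mn_bn")
  expect_equal(res$sd_mn_pct[res$dose == "ctl"], 0)
  expect_equal(res$mean_mn_pct[res$dose == "dose"],
               mean(c(100 * 40 / 1000, 100 * 60 / 1000)))
  # pooled Fisher: 100/2000 vs 20/2020
  expect_equal(res$p_value[res$dose == "dose"],
               fisher_exact_one_sided(100, 2000, 20, 2020))
  expect_true(res$significant[res$dose == "dose"])
  # {4, 5, 6}% across three files -> mean 5, sample SD 1
  s3 <- rbind(mk_score("a", "x", 960, 40), mk_score("b", "x", 950, 50),
              mk_score("c", "x", 940, 60), mk_score("k", "ctl", 1000, 10))
  r3 <- dose_response_analysis(s3, control = "ctl", endpoint = "mn_bn")
  expect_equal(r3$mean_mn_pct[r3$dose == "x"], 5)
  expect_equal(r3$sd_mn_pct[r3$dose == "x"], 1)
  expect_error(dose_response_analysis(scores, control = "nope"), "control")
})

test_that("assay summary joins genotoxicity with cytotoxicity per dose", {
  cfg <- dose_response_config(
    doses = c("ctl", "hi"), mn_probability_per_dose = c(0.01, 0.06),
    prolif_mix_per_dose = rbind(c(0.3, 0.5, 0.2), c(0.7, 0.25, 0.05)),
    replicates_per_dose = 1L, files_per_replicate = 3L,
    events_per_file = 4000L, seed = 23)
  cohort <- generate_dose_response_cohort(cfg, render = "counts")
  man <- cohort$manifest
  scores <- do.call(rbind, lapply(split(man, man$file_id), function(sub)
    score_sample(sub$truth_label, file_id = sub$file_id[1],
                 dose = sub$dose[1], replicate = sub$replicate[1])))
  summ <- assay_summary(scores, control = "ctl", mode = "cytb")
  expect_equal(summ$dose[1], "ctl")
  expect_true(summ$significant[summ$dose == "hi"])
  expect_gt(summ$cytotoxicity_pct[summ$dose == "hi"], 0)  # fewer BN/POLY
  expect_equal(summ$cytotoxicity_pct[summ$dose == "ctl"], 0)
  rep_lines <- format_assay_report(summ)
  expect_length(rep_lines, 3 + nrow(summ))
})
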