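test_that("config validation names the offending field", {
  expect_error(cohort_config(msi_proportions = c(0.5, 0.2, 0.2)),
               "msi_proportions")
  expect_error(cohort_config(sexlinked_X_effect = 1.2), "sexlinked_X_effect")
  expect_error(cohort_config(probe_spacing_bp = 0), "probe_spacing_bp")
  expect_error(cohort_config(noise_sd = -1), "noise_sd")
  expect_error(cohort_config(planted_clades = list(list(members = 50,
                                                        n_shared = 2))),
               "planted_clades")
})

test_that("identical seeds give identical cohorts, and the degenerate mixture works", {
  cfg <- cohort_config(n_samples = 27, seed = 1)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  mss_only <- generate_cohort(cohort_config(
    n_samples = 20, msi_proportions = c(1, 0, 0), seed = 3))
  expect_true(all(mss_only$samples$msi == "MSS"))
  expect_true(all(mss_only$msi_marker_calls[, -1] == "stable"))
})

test_that("planted right-sided location probability is recovered at large n", {
  coh <- generate_cohort(cohort_config(n_samples = 2000, seed = 17))
  h <- coh$samples[coh$samples$msi == "MSI-H", ]
  phat <- mean(h$location == "R")
  se3 <- 3 * sqrt(0.8 * 0.2 / nrow(h))
  expect_lt(abs(phat - 0.8), max(se3, 0.03))
})

test_that("planted clades inject characters on exactly their members", {
  cfg <- cohort_config(n_samples = 15, seed = 5, planted_clades = list(
    list(members = 1:4, n_shared = 5), list(members = 8:10, n_shared = 3)))
  coh <- generate_cohort(cfg)
  calls <- filter_by_fold(coh$interval_reports)
  m <- build_matrix(calls)
  for (cl in coh$truth$clades) {
    keys <- canonicalize(cl$intervals)
    expect_true(all(keys %in% colnames(m)))
    for (k in keys) {
      carriers <- rownames(m)[m[, k] == 1]
      expect_setequal(carriers, cl$members)
    }
  }
})

test_that("per-sample interval reports never overlap within a direction", {
  coh <- generate_cohort(cohort_config(n_samples = 10, seed = 9))
  iv <- coh$interval_reports
  iv$direction <- ifelse(iv$fold_change > 1, "gain", "loss")
  for (key in unique(paste(iv$sample, iv$chrom, iv$direction))) {
    p <- iv[paste(iv$sample, iv$chrom, iv$direction) == key, ]
    p <- p[order(p$start), ]
    if (nrow(p) > 1) expect_true(all(p$start[-1] >= p$end[-nrow(p)]))
  }
})

test_that("probe tracks are exact in the noiseless case", {
  reg <- data.frame(chrom = "chr1", start = 0L, end = 2e6L)
  iv <- data.frame(chrom = "chr1", start = 5e5L, end = 15e5L,
                   fold_change = 1.5)
  tr <- emit_probe_track(iv, probe_spacing_bp = 1e4, noise_sd = 0,
                         seed = 1, regions = reg)
  inside <- tr$position >= 5e5 & tr$position < 15e5
  expect_equal(sum(inside), 100)  # 1 Mb at 10 kb spacing, half-open
  expect_true(all(tr$log_ratio[inside] == log2(1.5)))
  expect_true(all(tr$log_ratio[!inside] == 0))
  none <- emit_probe_track(iv[0, ], probe_spacing_bp = 1e4, noise_sd = 0,
                           seed = 1, regions = reg)
  expect_true(all(none$log_ratio == 0))
  expect_error(emit_probe_track(iv, probe_spacing_bp = -5), "probe_spacing")
  expect_error(emit_probe_track(iv, noise_sd = -0.1), "noise_sd")
})

test_that("write/read round-trips a cohort without its truth sidecar", {
  coh <- generate_cohort(cohort_config(n_samples = 27, seed = 2))
  d <- withr::local_tempdir()
  write_cohort(coh, d)
  back <- read_cohort(d)
  expect_null(back$truth)
  expect_equal(back$samples, coh$samples)
  expect_equal(back$msi_marker_calls, coh$msi_marker_calls)
  expect_equal(back$methylation_calls, coh$methylation_calls)
  expect_equal(back$interval_reports$start, coh$interval_reports$start)
  expect_equal(back$interval_reports$fold_change,
               coh$interval_reports$fold_change, tolerance = 1e-12)
  expect_equal(nrow(read.delim(file.path(d, "clinical.tsv"))), 27)
})

test_that("an empty cohort writes valid files with headers", {
  coh <- generate_cohort(cohort_config(n_samples = 0, seed = 1))
  d <- withr::local_tempdir()
  write_cohort(coh, d)
  clin <- read.delim(file.path(d, "clinical.tsv"))
  expect_equal(nrow(clin), 0)
  expect_true(all(c("sample", "age", "sex", "msi") %in% names(clin)))
})

test_that("planted probabilities are recovered across replicate cohorts", {
  # each replicate: empirical P(right | MSI-H) within 3 binomial SE
  hits <- 0L
  reps <- 10L
  for (r in seq_len(reps)) {
    coh <- generate_cohort(cohort_config(n_samples = 1000, seed = 1000 + r))
    h <- coh$samples[coh$samples$msi == "MSI-H", ]
    se3 <- 3 * sqrt(0.8 * 0.2 / nrow(h))
    if (abs(mean(h$location == "R") - 0.8) <= se3) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.9)
})
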