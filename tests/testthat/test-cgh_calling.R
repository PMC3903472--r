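reg30 <- data.frame(chrom = "chr1", start = 0L, end = 3e7L)

test_that("segmentation recovers a noiseless interval exactly", {
  iv <- data.frame(chrom = "chr1", start = 5e6L, end = 6e6L,
                   fold_change = 1.5)
  tr <- emit_probe_track(iv, 1e4, noise_sd = 0, seed = 1, regions = reg30)
  sg <- segment_probes(tr)
  expect_equal(nrow(sg), 1)
  expect_equal(sg$start, 5e6)
  expect_equal(sg$end, 6e6)
  expect_equal(sg$fold_change, 1.5)
  expect_equal(sg$direction, "gain")
})

test_that("segmentation of a flat track returns no calls, unsorted input errors", {
  flat <- data.frame(chrom = "chr1", position = seq(0, 1e6, 1e4),
                     log_ratio = 0)
  expect_equal(nrow(segment_probes(flat)), 0)
  expect_equal(nrow(segment_probes(flat[0, ])), 0)
  expect_error(segment_probes(flat[c(5, 1, 2), ]), "sorted")
  expect_error(segment_probes(flat, window_bp = 0), "window_bp")
})

test_that("losses are recovered with the right direction", {
  iv <- data.frame(chrom = "chr1", start = 1e6L, end = 2e6L,
                   fold_change = 0.5)
  tr <- emit_probe_track(iv, 1e4, noise_sd = 0, seed = 1, regions = reg30)
  sg <- segment_probes(tr)
  expect_equal(sg$direction, "loss")
  expect_equal(sg$fold_change, 0.5)
})

test_that("fold filtering is strict at the boundaries and idempotent", {
  calls <- data.frame(fold_change = c(0.79, 0.8, 1.0, 1.2, 1.21, 1.25))
  kept <- filter_by_fold(calls)
  expect_equal(kept$fold_change, c(0.79, 1.21, 1.25))
  expect_equal(kept$direction, c("loss", "gain", "gain"))
  expect_equal(filter_by_fold(kept), kept)
  # brute-force check of the strict-inequality reading
  grid <- data.frame(fold_change = seq(0.05, 3, by = 0.05))
  expect_equal(filter_by_fold(grid)$fold_change,
               grid$fold_change[grid$fold_change > 1.2 |
                                  grid$fold_change < 0.8])
  expect_error(filter_by_fold(calls, gain_fold = 0.9), "loss_fold < 1")
})

test_that("gene intersection uses half-open 1 bp overlap arithmetic", {
  ann <- data.frame(gene = "G", chrom = "chr1", start = 100L, end = 200L)
  mk <- function(s, e) data.frame(sample = "S1", chrom = "chr1", start = s,
                                  end = e, direction = "gain")
  expect_equal(nrow(intersect_genes(mk(0L, 1000L), ann)), 1)   # containment
  expect_equal(nrow(intersect_genes(mk(199L, 300L), ann)), 1)  # 1 bp
  expect_equal(nrow(intersect_genes(mk(200L, 300L), ann)), 0)  # adjacent
  expect_warning(
    out <- intersect_genes(
      data.frame(sample = "S1", chrom = "chr99", start = 1L, end = 5L,
                 direction = "loss"), ann),
    "chr99")
  expect_equal(nrow(out), 0)
})

test_that("gene intersection agrees with an all-pairs brute-force scan", {
  set.seed(21)
  genome <- genome_model()[1:5, ]
  calls <- data.frame(
    sample = sample(paste0("S", 1:4), 50, TRUE),
    chrom = sample(genome$chrom, 50, TRUE),
    start = st <- sample.int(5e7, 50),
    end = st + sample.int(2e6, 50),
    direction = sample(c("gain", "loss"), 50, TRUE))
  ann <- data.frame(gene = paste0("G", 1:50),
                    chrom = sample(genome$chrom, 50, TRUE),
                    start = gs <- sample.int(5e7, 50),
                    end = gs + sample.int(3e5, 50))
  got <- intersect_genes(calls, ann)
  want <- list()
  for (i in seq_len(nrow(calls))) for (j in seq_len(nrow(ann))) {
    if (calls$chrom[i] == ann$chrom[j] &&
        calls$start[i] < ann$end[j] && ann$start[j] < calls$end[i])
      want[[length(want) + 1L]] <- paste(calls$sample[i], ann$gene[j],
                                         calls$direction[i])
  }
  expect_setequal(paste(got$sample, got$gene, got$direction),
                  unique(unlist(want)))
})

test_that("chromosome summary counts add up and split by sex", {
  clinical <- data.frame(sample = c("A", "B"), sex = c("M", "F"))
  calls <- data.frame(
    sample = c("A", "A", "A", "A", "A", "B"),
    chrom = c(rep("chr1", 5), "chr2"),
    direction = c("gain", "gain", "gain", "loss", "loss", "gain"))
  cs <- chromosome_summary(calls, clinical)
  r1 <- cs[cs$chrom == "chr1", ]
  expect_equal(unlist(r1[, c("total", "amplifications", "deletions",
                             "amp_males", "del_males")], use.names = FALSE),
               c(5, 3, 2, 3, 2))
  expect_true(all(cs$total == cs$amplifications + cs$deletions))
  expect_error(chromosome_summary(
    calls, data.frame(sample = c("A", "B"), sex = c("M", "X"))), "sex")
  expect_error(chromosome_summary(
    calls, data.frame(sample = "A", sex = "M")), "missing")
  empty <- chromosome_summary(calls[0, ], clinical)
  expect_true(all(empty$total == 0))
})

test_that("summary totals conserve the per-sample tallies on a synthetic cohort", {
  coh <- generate_cohort(cohort_config(n_samples = 8, seed = 13))
  calls <- filter_by_fold(coh$interval_reports)
  cs <- chromosome_summary(calls, coh$samples)
  totals <- per_sample_totals(calls, coh$samples$sample)
  expect_equal(sum(cs$total), sum(totals))
  expect_equal(unname(totals), unname(coh$truth$aberration_count))
})

test_that("per-sample totals report zeroes and handle empties", {
  calls <- data.frame(sample = c("A", "A", "A"),
                      direction = c("gain", "loss", "gain"))
  expect_equal(per_sample_totals(calls), c(A = 3L))
  expect_equal(per_sample_totals(calls, samples = c("A", "B")),
               c(A = 3L, B = 0L))
  expect_equal(length(per_sample_totals(calls[0, ])), 0)
})

test_that("noisy planted intervals are recovered at reciprocal overlap", {
  iv <- data.frame(chrom = "chr1", start = 5e6L, end = 6e6L,
                   fold_change = 1.5)
  ok <- 0L
  reps <- 40L
  for (s in seq_len(reps)) {
    tr <- emit_probe_track(iv, 1e4, noise_sd = 0.2, seed = s,
                           regions = reg30)
    sg <- segment_probes(tr)
    if (nrow(sg)) {
      ov <- pmin(sg$end, 6e6) - pmax(sg$start, 5e6)
      best <- which.max(ov)
      if (ov[best] >= 0.5 * 1e6 &&
          ov[best] >= 0.5 * (sg$end[best] - sg$start[best]))
        ok <- ok + 1L
    }
  }
  expect_gte(ok / reps, 0.95)
})
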