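test_that("genome models tile chromosomes into the requested bin count", {
  g <- make_genome_model("toy")
  expect_s3_class(g, "genome_model")
  expect_equal(nrow(g$bins), 400)
  # equal chromosome lengths force an equal split
  expect_true(all(table(g$bins$chrom) == 100))
  # bins tile each chromosome without gaps or overlaps
  for (cc in unique(g$bins$chrom)) {
    b <- g$bins[g$bins$chrom == cc, ]
    expect_equal(b$start[1], 0)
    expect_equal(b$end[nrow(b)], g$chroms$length[g$chroms$chrom == cc])
    expect_equal(b$start[-1], b$end[-nrow(b)])
  }
  expect_true(all(g$bins$arm %in% c("p", "q")))

  gh <- make_genome_model("hg19", n_bins = 2000)
  expect_equal(nrow(gh$bins), 2000)
  # bin allocation proportional to chromosome length (within rounding)
  got <- as.vector(table(factor(gh$bins$chrom, levels = gh$chroms$chrom)))
  want <- gh$chroms$length / sum(gh$chroms$length) * 2000
  expect_true(all(abs(got - want) <= 1))

  expect_error(make_genome_model("toy", n_bins = 3), "at least")
})

test_that("simulated bin counts follow the tumor-fraction mixture model", {
  g <- make_genome_model("toy")
  ev <- cna_event("chr1", 5e7, 1e8, +1)   # chr1q single-copy gain

  # f = 0: uniform expectation regardless of events
  e0 <- expected_bin_counts(g, ev, tumor_fraction = 0, total_reads = 4e5)
  expect_true(all(abs(e0$count - 1000) < 1e-9))

  # f = 1: affected bins at 1.5x the diploid baseline (closed form (2+1)/2)
  e1 <- expected_bin_counts(g, ev, tumor_fraction = 1, total_reads = 4e5)
  hit <- e1$chrom == "chr1" & e1$start >= 5e7
  expect_equal(mean(e1$count[hit]) / mean(e1$count[!hit]), 1.5,
               tolerance = 1e-12)

  # conservation + determinism
  c1 <- simulate_bin_counts(g, ev, 0.3, 123457, seed = 7)
  c2 <- simulate_bin_counts(g, ev, 0.3, 123457, seed = 7)
  expect_identical(c1, c2)
  expect_equal(sum(c1$count), 123457)
  expect_error(simulate_bin_counts(g, ev, 1.2, 1000, seed = 1), "tumor_fraction")
})

test_that("size histograms are normalized nucleosomal mixtures", {
  h <- simulate_size_histogram(0.8, 0.2, 0, seed = 11)
  expect_s3_class(h, "size_histogram")
  expect_equal(sum(diff(h$size_bp) * (head(h$density, -1) + tail(h$density, -1)) / 2),
               1, tolerance = 1e-6)
  expect_true(all(h$density >= 0))
  # determinism
  expect_identical(h, simulate_size_histogram(0.8, 0.2, 0, seed = 11))
  expect_error(simulate_size_histogram(0, 0, 0), "positive")
  expect_error(simulate_size_histogram(-1, 2, 0), "non-negative")
})

test_that("deep-seq counts are binomial with calibrated mean", {
  expect_equal(simulate_deep_seq_counts(0, 500, seed = 1)$mutant, 0)
  expect_equal(simulate_deep_seq_counts(1, 500, seed = 1)$mutant, 500)
  # Monte-Carlo calibration at the printed tumor-A DDR2 AF
  afs <- vapply(1:1000, function(s)
    simulate_deep_seq_counts(0.364, 10000, seed = s)$mutant / 10000, 0)
  expect_lt(abs(mean(afs) - 0.364), 0.005)
  # empirical AF within 3 standard errors of truth
  se <- sqrt(0.364 * 0.636 / 10000) / sqrt(1000)
  expect_lt(abs(mean(afs) - 0.364), 3 * se + 1e-9)
  expect_error(simulate_deep_seq_counts(1.5, 100, seed = 1), "true_af")
})

test_that("index fixture plants the published mutation structure", {
  fx <- make_index_patient_fixture(seed = 3, n_bins = 500)
  af <- fx$af_truth
  truncal5 <- c("PCDH20", "OR4X1", "ALK", "DNPEP", "SH3TC2")
  # truncal five present in every lesion
  expect_true(all(af[truncal5, ] > 0))
  # MLL3 in A and lymph nodes only; PIK3CA in lymph nodes only
  expect_true(all(af["MLL3", c("A", "LN15", "LN17", "LNA")] > 0))
  expect_true(all(af["MLL3", c("C", "D")] == 0))
  expect_true(all(af["PIK3CA", c("LN15", "LN17", "LNA")] > 0))
  expect_true(all(af["PIK3CA", c("A", "C", "D")] == 0))
  # DDR2 elevated in A vs C/D at the printed values
  expect_equal(unname(af["DDR2", c("A", "C", "D")]), c(0.364, 0.153, 0.166))
  # phylogeny consistency: each child's SNV set contains its parent's
  snvs <- lapply(fx$lesions, function(l) names(l$snvs))
  expect_true(all(snvs$C %in% snvs$A))
  for (ln in c("LN15", "LN17", "LNA"))
    expect_true(all(snvs$A %in% snvs[[ln]]))
  # CTC pools carry all eight SNVs and the 1p loss novel to CTCs
  for (p in fx$ctc) {
    expect_equal(sort(names(p$af)), sort(rownames(af)))
    has_1p <- any(p$events$chrom == "chr1" & p$events$delta < 0)
    expect_true(has_1p)
  }
  for (l in fx$lesions)
    expect_false(any(l$events$chrom == "chr1" & l$events$delta < 0))
  # plasma tumor fractions and true AFs in the published 2-3% window
  for (p in fx$plasma) {
    expect_true(p$tumor_fraction >= 0.02 && p$tumor_fraction <= 0.03)
    expect_true(all(p$true_af >= 0.02 & p$true_af <= 0.03))
  }
  # determinism of the whole bundle
  expect_identical(fx, make_index_patient_fixture(seed = 3, n_bins = 500))
})

test_that("cohort simulation honors its composition and is byte-deterministic", {
  cfg <- cohort_config(composition = c(bi_det = 3, bi_und = 2, mono_det = 1,
                                       mono_und = 4), n_bins = 300,
                       total_reads = 50000)
  b1 <- simulate_cohort(cfg, seed = 5)
  expect_equal(nrow(b1$metadata), 10)
  expect_equal(sum(b1$metadata$size_class_true == "biphasic"), 5)
  expect_equal(sum(b1$metadata$detected_true), 4)
  # serialized outputs byte-identical across reruns
  f1 <- tempfile(); f2 <- tempfile()
  write_bin_counts(b1$samples[[1]]$counts, f1)
  b2 <- simulate_cohort(cfg, seed = 5)
  write_bin_counts(b2$samples[[1]]$counts, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_error(cohort_config(composition = c(bi_det = -1, bi_und = 0,
                                             mono_det = 0, mono_und = 2)),
               "non-negative")
})
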