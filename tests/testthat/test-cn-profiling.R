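toy_profile <- function(l2, chrom = rep("chr1", length(l2))) {
  structure(list(bins = data.frame(chrom = chrom,
                                   start = seq_along(l2) - 1,
                                   end = seq_along(l2), log2 = l2,
                                   status = NA_character_,
                                   stringsAsFactors = FALSE),
                 segments = NULL), class = "cn_profile")
}

test_that("counts_to_log2 reproduces closed-form ratios", {
  g <- make_genome_model("toy")
  base <- expected_bin_counts(g, total_reads = 4e5)

  # identity
  p0 <- counts_to_log2(base, base)
  expect_true(all(abs(p0$bins$log2) < 1e-12))

  # noise-free single-copy gain: log2(1.5) at f = 1, log2(1.1) at f = 0.2
  ev <- cna_event("chr1", 5e7, 1e8, +1)
  for (f in c(1, 0.2)) {
    e <- expected_bin_counts(g, ev, tumor_fraction = f, total_reads = 4e5)
    p <- counts_to_log2(e, base)
    hit <- p$bins$chrom == "chr1" & p$bins$start >= 5e7
    shift <- mean(p$bins$log2[hit]) - mean(p$bins$log2[!hit])
    expect_equal(shift, log2((2 + f) / 2), tolerance = 1e-9)
  }
  bad <- base; bad$count[1] <- 0
  expect_error(counts_to_log2(base, bad), "strictly positive")
  expect_error(counts_to_log2(base[-1, ], base), "grids")
})

test_that("segmentation recovers exact breakpoints and matches exhaustive search", {
  # noise-free two-level step: exact recovery
  y <- c(rep(0, 20), rep(1, 15))
  p <- segment_profile(toy_profile(y), penalty = 0.1)
  expect_equal(nrow(p$segments), 2)
  expect_equal(p$segments$start_bin, c(1, 21))
  expect_equal(p$segments$mean_log2, c(0, 1))

  # constant profile: one segment per chromosome
  p2 <- segment_profile(toy_profile(rep(0.3, 30),
                                    chrom = rep(c("chrA", "chrB"), each = 15)),
                        penalty = 0.1)
  expect_equal(nrow(p2$segments), 2)

  # oracle equivalence on random <= 12-bin chromosomes
  for (s in 1:20) {
    y <- withr::with_seed(s, stats::rnorm(sample(4:12, 1)))
    pen <- withr::with_seed(100 + s, stats::runif(1, 0.05, 2))
    got <- segment_profile(toy_profile(y), penalty = pen)
    cost <- sum(vapply(seq_len(nrow(got$segments)), function(k) {
      seg <- y[got$segments$start_bin[k]:got$segments$end_bin[k]]
      sum((seg - mean(seg))^2)
    }, 0)) + pen * nrow(got$segments)
    oracle <- oracle_segment_exhaustive(y, pen)
    expect_equal(cost, oracle$cost, tolerance = 1e-9)
    expect_equal(got$segments$end_bin[-nrow(got$segments)], oracle$breaks)
  }
  expect_error(segment_profile(toy_profile(c(0, NA, 1))), "finite")
})

test_that("status calling thresholds segment means correctly", {
  y <- c(rep(0.585, 10), rep(0, 10), rep(-0.9, 10))
  p <- call_status(segment_profile(toy_profile(y), penalty = 0.05))
  expect_equal(p$segments$status, c("gain", "neutral", "loss"))
  expect_equal(as.vector(table(p$bins$status)[c("gain", "loss", "neutral")]),
               c(10L, 10L, 10L))
  expect_error(call_status(segment_profile(toy_profile(y), penalty = 0.05),
                           gain_cut = -0.1, loss_cut = 0.1), "loss_cut")
})

test_that("balanced calls follow the aberrant-bin fraction", {
  p_neutral <- call_status(segment_profile(toy_profile(rep(0, 50)),
                                           penalty = 0.05))
  expect_true(is_balanced(p_neutral))
  y <- c(rep(0.6, 10), rep(0, 40))   # 20% of bins aberrant
  p_gain <- call_status(segment_profile(toy_profile(y), penalty = 0.05))
  expect_false(is_balanced(p_gain))
  expect_true(is_balanced(p_gain, min_aberrant_fraction = 0.5))
})

test_that("recurrence summary uses unbalanced profiles only", {
  mk <- function(y) call_status(segment_profile(toy_profile(y), penalty = 0.05))
  unb <- mk(c(rep(0.6, 10), rep(0, 10)))
  bal <- mk(rep(0, 20))
  r <- recurrence_summary(list(unb, bal, unb))
  expect_equal(attr(r, "n_unbalanced"), 2)
  expect_true(all(r$gain_frac %in% c(0, 1)))
  expect_equal(sum(r$gain_frac), 10)
  expect_error(recurrence_summary(list(bal)), "no unbalanced")
})

test_that("Manhattan distances on status codes are a metric", {
  mk <- function(y) call_status(segment_profile(toy_profile(y), penalty = 0.05))
  a <- mk(rep(0, 20))
  b <- mk(c(0.6, rep(0, 19)))          # one gained bin
  c_ <- mk(c(-0.9, rep(0, 19)))        # same bin lost
  d <- manhattan_distance_matrix(list(A = a, B = b, C = c_))
  expect_equal(unname(diag(d)), c(0, 0, 0))
  expect_equal(d["A", "B"], 1)
  expect_equal(d["B", "C"], 2)          # gain vs loss = |1 - (-1)|
  expect_equal(d, t(d))
  # triangle inequality on random profiles
  for (s in 1:10) {
    ys <- withr::with_seed(s, replicate(4, sample(c(-0.9, 0, 0.6), 15,
                                                  replace = TRUE),
                                        simplify = FALSE))
    dm <- manhattan_distance_matrix(stats::setNames(lapply(ys, mk),
                                                    paste0("S", 1:4)))
    for (i in 1:4) for (j in 1:4) for (k in 1:4)
      expect_lte(dm[i, j], dm[i, k] + dm[k, j] + 1e-9)
  }
})

test_that("complete-linkage clustering matches the brute-force oracle", {
  # 3-point worked example: first merge {A,B} at 1, then C at 10
  d <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  dn <- hcluster_complete(d)
  expect_equal(dn$height, c(1, 10))
  expect_setequal(cut_clusters(dn, 5)[[1]], c("A", "B"))

  # oracle equivalence for random metric matrices, n <= 6
  for (s in 1:15) {
    n <- withr::with_seed(s, sample(3:6, 1))
    pts <- withr::with_seed(s + 50, matrix(stats::rnorm(n * 3), n))
    dm <- as.matrix(stats::dist(pts, method = "manhattan"))
    dimnames(dm) <- list(LETTERS[1:n], LETTERS[1:n])
    got <- hcluster_complete(dm)
    want <- oracle_complete_linkage(dm)
    expect_equal(got$height, want$heights, tolerance = 1e-9)
    # merge heights non-decreasing
    expect_true(all(diff(got$height) >= -1e-9))
    # agreement with stats::hclust heights as a second, independent route
    expect_equal(sort(got$height),
                 sort(stats::hclust(stats::as.dist(dm),
                                    method = "complete")$height),
                 tolerance = 1e-9)
  }
  expect_error(hcluster_complete(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  single <- hcluster_complete(matrix(0, 1, 1, dimnames = list("X", "X")))
  expect_equal(single$newick, "X;")
})

test_that("newick output round-trips through ape", {
  d <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  dn <- hcluster_complete(d)
  tr <- ape::read.tree(text = dn$newick)
  expect_setequal(tr$tip.label, c("a", "b", "c"))
})
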