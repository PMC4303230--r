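# Independent oracles used by the unit and acceptance tests.  These are
# deliberately naive re-derivations (enumeration, closed forms, direct
# sampling) that never share code with the implementation they check.

# exhaustive least-squares segmentation: minimize SSE + penalty * k over
# every breakpoint subset of one chromosome (feasible for <= ~15 bins)
oracle_segment_exhaustive <- function(y, penalty) {
  n <- length(y)
  best <- NULL
  for (mask in 0:(2^(n - 1) - 1)) {
    bks <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)  # break after bin i
    bounds <- c(0, bks, n)
    cost <- penalty * (length(bounds) - 1)
    for (s in seq_len(length(bounds) - 1)) {
      seg <- y[(bounds[s] + 1):bounds[s + 1]]
      cost <- cost + sum((seg - mean(seg))^2)
    }
    if (is.null(best) || cost < best$cost - 1e-12)
      best <- list(cost = cost, breaks = bks)
  }
  best
}

# from-scratch complete-linkage clustering: cluster distances recomputed
# every step as the max over all original leaf pairs (no Lance-Williams
# updates), same lexicographic tie-break contract
oracle_complete_linkage <- function(d, labels = rownames(d)) {
  clusters <- as.list(seq_len(nrow(d)))
  names(clusters) <- labels
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- NULL
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      h <- max(d[clusters[[a]], clusters[[b]]])
      key <- sort(c(min(labels[clusters[[a]]]), min(labels[clusters[[b]]])))
      if (is.null(best) || h < best$h - 1e-12 ||
          (abs(h - best$h) <= 1e-12 && (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2]))))
        best <- list(a = a, b = b, h = h, key = key)
    }
    heights <- c(heights, best$h)
    merges[[length(merges) + 1]] <-
      sort(c(names(clusters)[best$a], names(clusters)[best$b]))
    clusters[[best$a]] <- c(clusters[[best$a]], clusters[[best$b]])
    names(clusters)[best$a] <- min(names(clusters)[c(best$a, best$b)])
    clusters[[best$b]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# permutation null for the 2x2 chi-squared: permuting the detection
# labels with margins fixed makes cell `a` hypergeometric
oracle_chi2_permutation_p <- function(a, b, c, d, n_perm = 1e5, seed = 42) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d; n <- r1 + r2
  chi2 <- function(A) {
    B <- r1 - A; C <- c1 - A; D <- r2 - C
    n * (A * D - B * C)^2 / (r1 * r2 * c1 * c2)
  }
  obs <- chi2(a)
  withr::with_seed(seed, {
    draws <- stats::rhyper(n_perm, m = a + b, n = c + d, k = a + c)
    v <- chi2(draws)
    # mid-p convention: half weight on the observed statistic's point
    # mass, the standard continuity match to the asymptotic p
    mean(v > obs + 1e-9) + 0.5 * mean(abs(v - obs) <= 1e-9)
  })
}

# two-pass variance (sum of squared deviations from a pre-computed mean)
oracle_sd_two_pass <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# leaf sets of every cluster in a dendrogram cut, from the merge table
dendro_clusters_at <- function(dendro, h) {
  sort(vapply(cut_clusters(dendro, h),
              function(g) paste(sort(g), collapse = "+"), ""))
}
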