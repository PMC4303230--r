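#' Per-bin log2 copy-number ratios from shallow-WGS read counts
#'
#' Converts binned read counts into depth-normalized log2 ratios against a
#' baseline of expected counts (a diploid panel or the generator's
#' noise-free expectation): `log2((count_i / total) / (baseline_i /
#' baseline_total))`, median-centered to 0.  Zero-count bins are floored
#' at half a read before taking the ratio.
#'
#' @param counts data.frame with columns chrom, start, end, count.
#' @param baseline data.frame on the identical bin grid with strictly
#'   positive expected counts.
#' @return A `cn_profile`: list with `bins` (chrom, start, end, log2,
#'   status) and `segments` (`NULL` until [segment_profile()]).
#' @export
counts_to_log2 <- function(counts, baseline) {
  .check_grid(counts, baseline)
  if (any(baseline$count <= 0)) stop("baseline counts must be strictly positive")
  obs <- pmax(counts$count, 0.5) / sum(counts$count)
  ref <- baseline$count / sum(baseline$count)
  l2 <- log2(obs / ref)
  l2 <- l2 - stats::median(l2)
  structure(list(
    bins = data.frame(chrom = counts$chrom, start = counts$start,
                      end = counts$end, log2 = l2,
                      status = NA_character_, stringsAsFactors = FALSE),
    segments = NULL
  ), class = "cn_profile")
}

.check_grid <- function(a, b) {
  ba <- if (inherits(a, "cn_profile")) a$bins else a
  bb <- if (inherits(b, "cn_profile")) b$bins else b
  if (nrow(ba) != nrow(bb) || !all(ba$chrom == bb$chrom) ||
      !all(ba$start == bb$start) || !all(ba$end == bb$end))
    stop("bin grids do not match")
  invisible(TRUE)
}

#' @export
print.cn_profile <- function(x, ...) {
  st <- x$bins$status
  cat(sprintf("cn_profile: %d bins%s%s\n", nrow(x$bins),
              if (is.null(x$segments)) "" else
                sprintf(", %d segments", nrow(x$segments)),
              if (all(is.na(st))) "" else
                sprintf(" (%d gain / %d loss bins)",
                        sum(st == "gain", na.rm = TRUE),
                        sum(st == "loss", na.rm = TRUE))))
  invisible(x)
}

#' Segment a log2 profile into piecewise-constant copy-number levels
#'
#' Exact least-squares segmentation per chromosome: minimizes
#' `SSE + penalty * (number of segments)` over all segmentations by
#' dynamic programming (optimal partitioning), so the result equals an
#' exhaustive search over breakpoint sets.  Deterministic; no sampling.
#'
#' @param profile a `cn_profile` with finite log2 values.
#' @param penalty positive penalty per segment.  Default is a BIC-like
#'   `2 * sigma^2 * log(n_bins)` with `sigma` estimated from the median
#'   absolute first difference of the log2 values (robust to the
#'   piecewise-constant signal itself).
#' @return the profile with `segments` filled in (chrom, start_bin,
#'   end_bin, start, end, n_bins, mean_log2, status).
#' @export
segment_profile <- function(profile, penalty = NULL) {
  stopifnot(inherits(profile, "cn_profile"))
  l2 <- profile$bins$log2
  if (any(!is.finite(l2))) stop("log2 values must be finite")
  if (is.null(penalty)) {
    d <- diff(l2)
    sigma <- stats::median(abs(d)) / (0.6745 * sqrt(2))
    penalty <- max(2 * sigma^2 * log(length(l2)), 1e-12)
  }
  if (penalty <= 0) stop("penalty must be positive")
  chroms <- unique(profile$bins$chrom)
  seg_list <- lapply(chroms, function(cc) {
    idx <- which(profile$bins$chrom == cc)
    bk <- .segment_dp(l2[idx], penalty)   # per-chromosome segment index ranges
    data.frame(chrom = cc,
               start_bin = idx[bk$from], end_bin = idx[bk$to],
               start = profile$bins$start[idx[bk$from]],
               end = profile$bins$end[idx[bk$to]],
               n_bins = bk$to - bk$from + 1L,
               mean_log2 = bk$mean, status = NA_character_,
               stringsAsFactors = FALSE)
  })
  profile$segments <- do.call(rbind, seg_list)
  rownames(profile$segments) <- NULL
  profile
}

# optimal partitioning: F[j] = min_i F[i-1] + sse(i, j) + penalty
.segment_dp <- function(y, penalty) {
  n <- length(y)
  s1 <- cumsum(y); s2 <- cumsum(y^2)
  sse <- function(i, j) {
    s <- s1[j] - c(0, s1)[i]
    q <- s2[j] - c(0, s2)[i]
    q - s^2 / (j - i + 1)
  }
  f <- c(0, rep(Inf, n))
  prev <- integer(n)
  for (j in seq_len(n)) {
    i <- seq_len(j)
    cand <- f[i] + sse(i, j) + penalty
    best <- which.min(cand)
    f[j + 1] <- cand[best]
    prev[j] <- best
  }
  # backtrack
  to <- integer(0); from <- integer(0)
  j <- n
  while (j > 0) { from <- c(prev[j], from); to <- c(j, to); j <- prev[j] - 1L }
  mu <- (s1[to] - c(0, s1)[from]) / (to - from + 1)
  list(from = from, to = to, mean = mu)
}

#' Call gain/neutral/loss status on a segmented profile
#'
#' Segments with mean log2 at or above `gain_cut` are gains, at or below
#' `loss_cut` losses, otherwise neutral; the segment status is broadcast
#' to its bins.
#'
#' @param profile a segmented `cn_profile`.
#' @param gain_cut,loss_cut log2-ratio thresholds with
#'   `loss_cut < 0 < gain_cut` (defaults -0.2 / +0.2).
#' @return the profile with per-segment and per-bin statuses assigned.
#' @export
call_status <- function(profile, gain_cut = 0.2, loss_cut = -0.2) {
  stopifnot(inherits(profile, "cn_profile"))
  if (is.null(profile$segments)) stop("profile must be segmented first")
  if (!(loss_cut < 0 && 0 < gain_cut)) stop("need loss_cut < 0 < gain_cut")
  st <- ifelse(profile$segments$mean_log2 >= gain_cut, "gain",
               ifelse(profile$segments$mean_log2 <= loss_cut, "loss", "neutral"))
  profile$segments$status <- st
  bin_status <- rep(NA_character_, nrow(profile$bins))
  for (k in seq_len(nrow(profile$segments)))
    bin_status[profile$segments$start_bin[k]:profile$segments$end_bin[k]] <- st[k]
  profile$bins$status <- bin_status
  profile
}

#' Is a copy-number profile balanced?
#'
#' A profile is *balanced* when fewer than `min_aberrant_fraction` of its
#' bins carry a non-neutral call.  Balanced plasma profiles indicate a
#' tumor fraction below the shallow-WGS detection limit (roughly 10%
#' mutant allele fraction); the aberrations of a high-burden tumor are
#' attenuated below the calling cuts.
#'
#' @param profile a `cn_profile` with statuses assigned.
#' @param min_aberrant_fraction fraction of aberrant bins needed to call
#'   the profile unbalanced (default 0.05).
#' @return logical.
#' @export
is_balanced <- function(profile, min_aberrant_fraction = 0.05) {
  stopifnot(inherits(profile, "cn_profile"))
  st <- profile$bins$status
  if (all(is.na(st))) stop("statuses must be assigned (run call_status)")
  mean(st != "neutral") < min_aberrant_fraction
}

#' Run the full shallow-WGS profiling chain on one sample
#'
#' Convenience wrapper: [counts_to_log2()] then [segment_profile()] then
#' [call_status()].
#'
#' @inheritParams counts_to_log2
#' @inheritParams segment_profile
#' @inheritParams call_status
#' @export
cn_pipeline <- function(counts, baseline, penalty = NULL, gain_cut = 0.2,
                        loss_cut = -0.2) {
  call_status(segment_profile(counts_to_log2(counts, baseline), penalty),
              gain_cut, loss_cut)
}

#' Per-bin recurrence of gains and losses across a cohort
#'
#' For the unbalanced profiles of a cohort (balanced profiles carry no
#' detectable tumor signal and are excluded), computes the fraction of
#' samples with a gain, and with a loss, at every bin — a per-bin
#' recurrent-event summary of the cohort's copy-number landscape.
#'
#' @param profiles list of `cn_profile` objects on a shared bin grid,
#'   statuses assigned.
#' @param min_aberrant_fraction passed to [is_balanced()] to select the
#'   unbalanced subset.
#' @return data.frame: chrom, start, end, gain_frac, loss_frac,
#'   n_unbalanced (attribute `n_unbalanced` also set).
#' @export
recurrence_summary <- function(profiles, min_aberrant_fraction = 0.05) {
  if (length(profiles) == 0) stop("no profiles supplied")
  for (p in profiles[-1]) .check_grid(profiles[[1]], p)
  unb <- Filter(function(p) !is_balanced(p, min_aberrant_fraction), profiles)
  if (length(unb) == 0) stop("no unbalanced profiles in input")
  gains <- rowMeans(sapply(unb, function(p) p$bins$status == "gain"))
  losses <- rowMeans(sapply(unb, function(p) p$bins$status == "loss"))
  out <- data.frame(chrom = profiles[[1]]$bins$chrom,
                    start = profiles[[1]]$bins$start,
                    end = profiles[[1]]$bins$end,
                    gain_frac = gains, loss_frac = losses,
                    stringsAsFactors = FALSE)
  attr(out, "n_unbalanced") <- length(unb)
  out
}

#' Manhattan distance matrix over copy-number statuses
#'
#' Encodes each profile's per-bin status as loss = -1, neutral = 0,
#' gain = +1 and returns the pairwise Manhattan (L1) distances — the
#' metric used for clonal clustering of tumor, lymph-node and CTC
#' profiles.  With `use_log2 = TRUE` the raw log2 ratios are used
#' instead of the 3-level calls.
#'
#' @param profiles named list of `cn_profile` objects on a shared grid.
#' @param use_log2 use continuous log2 ratios instead of status codes.
#' @return symmetric matrix of class `dist`-compatible numeric matrix
#'   with zero diagonal, dimnames from the list names.
#' @export
manhattan_distance_matrix <- function(profiles, use_log2 = FALSE) {
  if (length(profiles) == 0) stop("no profiles supplied")
  for (p in profiles[-1]) .check_grid(profiles[[1]], p)
  enc <- sapply(profiles, function(p) {
    if (use_log2) p$bins$log2
    else c(loss = -1, neutral = 0, gain = 1)[p$bins$status]
  })
  if (any(is.na(enc))) stop("statuses must be assigned on all profiles")
  d <- as.matrix(stats::dist(t(enc), method = "manhattan"))
  dimnames(d) <- list(names(profiles), names(profiles))
  d
}

#' Complete-linkage hierarchical clustering with deterministic ties
#'
#' Agglomerative clustering under the complete (maximum) linkage rule.
#' At every step the pair of clusters with the smallest linkage distance
#' is merged; ties are broken by the lexicographically smallest pair of
#' cluster labels, so the dendrogram is fully deterministic.
#'
#' @param d symmetric distance matrix with zero diagonal (dimnames used
#'   as labels unless `labels` given).
#' @param labels optional character vector of leaf labels.
#' @return list of class `ctdx_dendro` with `merge`, `height`, `labels`
#'   (an `hclust`-compatible triple), `hclust` (a proper `hclust`
#'   object) and `newick` (ultrametric Newick string).
#' @export
hcluster_complete <- function(d, labels = NULL) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-9))
    stop("distance matrix must be square and symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have zero diagonal")
  n <- nrow(d)
  if (is.null(labels)) labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("S", seq_len(n))

  # active clusters: list of member leaf indices; id <0 = leaf, >0 = merge row
  members <- as.list(seq_len(n))
  ids <- -seq_len(n)
  keys <- labels                       # lexicographic tie-break key per cluster
  merge <- matrix(0L, nrow = max(n - 1, 0), ncol = 2)
  height <- numeric(max(n - 1, 0))
  for (step in seq_len(n - 1)) {
    k <- length(members)
    best <- NULL
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      h <- max(d[members[[a]], members[[b]]])
      key <- sort(c(keys[a], keys[b]))
      if (is.null(best) || h < best$h - 1e-12 ||
          (abs(h - best$h) <= 1e-12 &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best <- list(a = a, b = b, h = h, key = key)
      }
    }
    merge[step, ] <- sort(c(ids[best$a], ids[best$b]))
    height[step] <- best$h
    members[[best$a]] <- c(members[[best$a]], members[[best$b]])
    keys[best$a] <- min(keys[best$a], keys[best$b])
    ids[best$a] <- step
    members[[best$b]] <- NULL
    keys <- keys[-best$b]; ids <- ids[-best$b]
  }
  if (n == 1) {
    return(structure(list(merge = merge, height = height, labels = labels,
                          hclust = NULL, newick = paste0(labels, ";")),
                     class = "ctdx_dendro"))
  }
  hc <- structure(list(merge = merge, height = height,
                       order = .dendro_order(merge, n), labels = labels,
                       method = "complete", dist.method = "manhattan"),
                  class = "hclust")
  newick <- ape::write.tree(ape::as.phylo(hc))
  structure(list(merge = merge, height = height, labels = labels,
                 hclust = hc, newick = newick), class = "ctdx_dendro")
}

.dendro_order <- function(merge, n) {
  expand <- function(i) {
    if (i < 0) return(-i)
    c(expand(merge[i, 1]), expand(merge[i, 2]))
  }
  expand(nrow(merge))
}

#' @export
print.ctdx_dendro <- function(x, ...) {
  cat("complete-linkage dendrogram:", x$newick, "\n")
  invisible(x)
}

#' Leaf labels of each cluster at a given cut height
#'
#' @param dendro a `ctdx_dendro`.
#' @param h cut height (clusters merged at height <= h stay together).
#' @return list of character vectors (leaf labels per cluster).
#' @export
cut_clusters <- function(dendro, h) {
  if (is.null(dendro$hclust)) return(list(dendro$labels))
  grp <- stats::cutree(dendro$hclust, h = h)
  unname(split(dendro$labels, grp))
}
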