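#' Simulate shallow-WGS per-bin read counts
#'
#' Draws binned read counts for a plasma (or tumor) sample as a multinomial
#' over the genome's bin grid.  The expected count of bin *i* is
#' proportional to `width_i * (2 + f * delta_i) / 2`, i.e. a mixture of a
#' diploid background at weight `1 - f` and a tumor genome carrying the
#' supplied copy-number events at tumor fraction `f`.
#'
#' @param genome a `genome_model`.
#' @param events data.frame of CNA events (see [cna_event()]); `NULL` for a
#'   flat genome.
#' @param tumor_fraction fraction of tumor-derived DNA in [0, 1].
#' @param total_reads total read count to distribute (> 0).
#' @param seed integer seed; identical inputs give identical counts.
#' @return data.frame: chrom, start, end, count (one row per bin; counts
#'   sum to `total_reads` exactly).
#' @export
simulate_bin_counts <- function(genome, events, tumor_fraction, total_reads,
                                seed) {
  stopifnot(inherits(genome, "genome_model"))
  if (tumor_fraction < 0 || tumor_fraction > 1)
    stop("tumor_fraction must be in [0, 1]")
  if (total_reads <= 0) stop("total_reads must be positive")
  delta <- .bin_deltas(genome, events)
  w <- (genome$bins$end - genome$bins$start) * (2 + tumor_fraction * delta) / 2
  if (any(w < 0)) stop("events drive expected copy number below zero")
  counts <- withr::with_seed(seed,
    as.vector(stats::rmultinom(1, size = total_reads, prob = w / sum(w))))
  data.frame(chrom = genome$bins$chrom, start = genome$bins$start,
             end = genome$bins$end, count = counts, stringsAsFactors = FALSE)
}

#' Expected (noise-free) per-bin counts
#'
#' The multinomial expectation of [simulate_bin_counts()]; used as the
#' diploid baseline (with no events) or as a noise-free profile oracle.
#'
#' @inheritParams simulate_bin_counts
#' @export
expected_bin_counts <- function(genome, events = NULL, tumor_fraction = 0,
                                total_reads = 1e6) {
  delta <- .bin_deltas(genome, events)
  w <- (genome$bins$end - genome$bins$start) * (2 + tumor_fraction * delta) / 2
  data.frame(chrom = genome$bins$chrom, start = genome$bins$start,
             end = genome$bins$end, count = w / sum(w) * total_reads,
             stringsAsFactors = FALSE)
}

#' Simulate a plasma DNA fragment-size histogram
#'
#' Cell-free DNA fragment lengths reflect nucleosomal protection: DNA
#' wrapped around a nucleosome (~142 bp) plus a linker (~20 bp) yields a
#' mononucleosomal peak near 162 bp, with di- and tri-nucleosomal
#' fragments near 324 and 486 bp.  The generator draws fragment lengths
#' from a Gaussian mixture at those centers (component spread 15 bp),
#' adds measurement jitter of `noise_sd` bp, and bins them on a 1-bp grid.
#'
#' @param mono_fraction,di_fraction,tri_fraction non-negative mixture
#'   weights (sum > 0; internally normalized).
#' @param noise_sd measurement noise added to each fragment length (bp).
#' @param seed integer seed.
#' @param n_fragments number of fragments sampled to build the histogram.
#' @param grid integration grid in bp (ascending).
#' @param component_sd spread of each nucleosomal component (bp).
#' @return A `size_histogram`: list with `size_bp` (grid) and `density`
#'   (trapezoid-normalized to integrate to 1).
#' @export
simulate_size_histogram <- function(mono_fraction, di_fraction = 0,
                                    tri_fraction = 0, noise_sd = 3, seed = 1,
                                    n_fragments = 20000, grid = 50:600,
                                    component_sd = 15) {
  w <- c(mono_fraction, di_fraction, tri_fraction)
  if (any(w < 0)) stop("mixture weights must be non-negative")
  if (sum(w) <= 0) stop("at least one mixture weight must be positive")
  centers <- c(162, 324, 486)
  sizes <- withr::with_seed(seed, {
    comp <- sample.int(3, n_fragments, replace = TRUE, prob = w / sum(w))
    stats::rnorm(n_fragments, mean = centers[comp],
                 sd = sqrt(component_sd^2 + noise_sd^2))
  })
  counts <- tabulate(findInterval(sizes, grid), nbins = length(grid))
  size_histogram(grid, counts)
}

#' Construct (and normalize) a fragment-size histogram
#'
#' @param size_bp ascending bp grid.
#' @param density non-negative densities (any scale; renormalized so the
#'   trapezoid integral is 1).
#' @return object of class `size_histogram`.
#' @export
size_histogram <- function(size_bp, density) {
  if (length(size_bp) < 2 || is.unsorted(size_bp, strictly = TRUE))
    stop("size grid must be strictly increasing with >= 2 points")
  if (length(density) != length(size_bp)) stop("grid/density length mismatch")
  if (any(density < 0) || any(!is.finite(density)))
    stop("density must be finite and non-negative")
  total <- .trapz(size_bp, density)
  if (total <= 0) stop("histogram must carry positive total mass")
  structure(list(size_bp = as.numeric(size_bp),
                 density = as.numeric(density) / total),
            class = "size_histogram")
}

#' @export
print.size_histogram <- function(x, ...) {
  cat(sprintf("size_histogram: %d points, %g-%g bp\n",
              length(x$size_bp), min(x$size_bp), max(x$size_bp)))
  invisible(x)
}

.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Simulate targeted deep-sequencing read counts at one variant
#'
#' Mutant reads are binomial in the true allele fraction at the given
#' depth (the sampling model behind amplicon deep sequencing, ignoring
#' sequencing error).
#'
#' @param true_af true allele fraction in [0, 1].
#' @param depth total read depth (> 0).
#' @param seed integer seed.
#' @return list with `mutant` and `total` read counts.
#' @export
simulate_deep_seq_counts <- function(true_af, depth, seed) {
  if (true_af < 0 || true_af > 1) stop("true_af must be in [0, 1]")
  if (depth <= 0) stop("depth must be positive")
  mutant <- withr::with_seed(seed, stats::rbinom(1, size = depth, prob = true_af))
  list(mutant = mutant, total = as.integer(depth))
}
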