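#' Genome models for binned copy-number analysis
#'
#' A `genome_model` carries the chromosome set, chromosome lengths, the
#' p/q arm boundary per chromosome, and a genome-wide grid of `n_bins`
#' equal-count-target bins (equal width under a uniform baseline).  The
#' default full-genome model is hg19-proportioned with 50,000 bins, the
#' resolution used for shallow whole-genome (plasma-Seq style) profiling;
#' a small "toy" model keeps tests fast.
#'
#' @param preset `"toy"` (4 chromosomes of 100 Mb, arm boundary at 50 Mb)
#'   or `"hg19"` (22 autosomes + X with hg19 lengths and centromeres).
#' @param n_bins total number of bins genome-wide (default 400 for the toy
#'   preset, 50,000 for hg19).
#' @param chrom_lengths optional named vector of chromosome lengths (bp);
#'   overrides the preset.
#' @param arm_boundaries optional named vector of p/q boundary positions
#'   (bp); required when `chrom_lengths` is supplied.
#'
#' @return An object of class `genome_model`: a list with `chroms`
#'   (data.frame: chrom, length, arm_boundary) and `bins` (data.frame:
#'   chrom, start, end, arm; 0-based half-open coordinates).
#'
#' @details Bins are allocated to chromosomes proportionally to length
#'   (largest-remainder rounding so they sum to `n_bins` exactly, at least
#'   one bin per chromosome) and each chromosome is tiled by equal-width
#'   bins.  A bin belongs to the arm containing its midpoint.
#' @export
make_genome_model <- function(preset = c("toy", "hg19"), n_bins = NULL,
                              chrom_lengths = NULL, arm_boundaries = NULL) {
  preset <- match.arg(preset)
  if (is.null(chrom_lengths)) {
    if (preset == "toy") {
      chrom_lengths <- stats::setNames(rep(1e8, 4), paste0("chr", 1:4))
      arm_boundaries <- stats::setNames(rep(5e7, 4), names(chrom_lengths))
      if (is.null(n_bins)) n_bins <- 400L
    } else {
      info <- hg19_chrom_info()
      chrom_lengths <- stats::setNames(info$length, info$chrom)
      arm_boundaries <- stats::setNames(info$centromere, info$chrom)
      if (is.null(n_bins)) n_bins <- 50000L
    }
  } else {
    if (is.null(arm_boundaries) || !all(names(chrom_lengths) %in% names(arm_boundaries)))
      stop("arm_boundaries must be supplied for every chromosome")
    arm_boundaries <- arm_boundaries[names(chrom_lengths)]
    if (is.null(n_bins)) stop("n_bins must be given with custom chromosome lengths")
  }
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (any(arm_boundaries <= 0 | arm_boundaries >= chrom_lengths))
    stop("arm boundaries must lie strictly inside each chromosome")
  n_bins <- as.integer(n_bins)
  n_chrom <- length(chrom_lengths)
  if (n_bins < n_chrom)
    stop(sprintf("n_bins (%d) must be at least the number of chromosomes (%d)",
                 n_bins, n_chrom))

  per_chrom <- .allocate_bins(chrom_lengths, n_bins)
  bins <- do.call(rbind, lapply(seq_len(n_chrom), function(i) {
    k <- per_chrom[i]
    edges <- round(seq(0, chrom_lengths[i], length.out = k + 1))
    data.frame(chrom = names(chrom_lengths)[i],
               start = edges[-(k + 1)], end = edges[-1],
               stringsAsFactors = FALSE)
  }))
  mid <- (bins$start + bins$end) / 2
  bins$arm <- ifelse(mid < arm_boundaries[bins$chrom], "p", "q")
  rownames(bins) <- NULL
  structure(list(
    chroms = data.frame(chrom = names(chrom_lengths),
                        length = unname(chrom_lengths),
                        arm_boundary = unname(arm_boundaries),
                        n_bins = unname(per_chrom),
                        stringsAsFactors = FALSE),
    bins = bins,
    n_bins = n_bins
  ), class = "genome_model")
}

# largest-remainder apportionment with a floor of 1 bin per chromosome
.allocate_bins <- function(lengths, n_bins) {
  quota <- lengths / sum(lengths) * n_bins
  base <- pmax(1L, floor(quota))
  left <- n_bins - sum(base)
  if (left > 0) {
    ord <- order(quota - floor(quota), decreasing = TRUE)
    add <- rep(0L, length(lengths))
    add[ord[seq_len(left)]] <- 1L
    base <- base + add
  } else if (left < 0) {
    # floors of 1 overshot: trim from the largest allocations
    ord <- order(base, decreasing = TRUE)
    i <- 1
    while (left < 0) {
      if (base[ord[i]] > 1L) { base[ord[i]] <- base[ord[i]] - 1L; left <- left + 1 }
      i <- if (i == length(base)) 1 else i + 1
    }
  }
  stats::setNames(as.integer(base), names(lengths))
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosomes, %d bins (%.1f kb median width)\n",
              nrow(x$chroms), x$n_bins,
              stats::median(x$bins$end - x$bins$start) / 1e3))
  invisible(x)
}

#' hg19 chromosome sizes and centromere positions
#'
#' Chromosome lengths and approximate centromere midpoints (bp) for the
#' hg19/GRCh37 assembly, chr1-chr22 plus chrX, used to build
#' arm-resolved genome models without external annotation files.
#'
#' @return data.frame with columns `chrom`, `length`, `centromere`.
#' @export
hg19_chrom_info <- function() {
  data.frame(
    chrom = paste0("chr", c(1:22, "X")),
    length = c(249250621, 243199373, 198022430, 191154276, 180915260,
               171115067, 159138663, 146364022, 141213431, 135534747,
               135006516, 133851895, 115169878, 107349540, 102531392,
               90354753, 81195210, 78077248, 59128983, 63025520,
               48129895, 51304566, 155270560),
    centromere = c(125000000, 93300000, 91000000, 50400000, 48400000,
                   61000000, 59900000, 45600000, 49000000, 40200000,
                   53700000, 35800000, 17900000, 17600000, 19000000,
                   36600000, 24000000, 17200000, 26500000, 27500000,
                   13200000, 14700000, 60600000),
    stringsAsFactors = FALSE
  )
}

#' Construct a copy-number aberration event
#'
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval (bp).
#' @param delta integer copy-number change relative to diploid (non-zero;
#'   positive = gain, negative = loss).
#' @return A one-row data.frame with class `cna_event` semantics
#'   (chrom, start, end, delta, direction).
#' @export
cna_event <- function(chrom, start, end, delta) {
  if (delta == 0) stop("delta must be non-zero")
  if (start < 0 || end <= start) stop("invalid interval")
  data.frame(chrom = chrom, start = start, end = end, delta = as.integer(delta),
             direction = ifelse(delta > 0, "gain", "loss"),
             stringsAsFactors = FALSE)
}

#' Whole-arm (or distal sub-arm) copy-number event on a genome model
#'
#' @param genome a `genome_model`.
#' @param chrom chromosome name.
#' @param arm `"p"` or `"q"`.
#' @param delta integer copy-number change (non-zero).
#' @param distal_fraction keep only the distal (telomeric) fraction of the
#'   arm; 1 = whole arm.
#' @export
arm_event <- function(genome, chrom, arm, delta, distal_fraction = 1) {
  row <- genome$chroms[genome$chroms$chrom == chrom, ]
  if (nrow(row) != 1) stop("unknown chromosome: ", chrom)
  if (!arm %in% c("p", "q")) stop("arm must be 'p' or 'q'")
  if (distal_fraction <= 0 || distal_fraction > 1) stop("distal_fraction in (0, 1]")
  b <- row$arm_boundary
  if (arm == "p") { lo <- 0; hi <- b } else { lo <- b; hi <- row$length }
  w <- (hi - lo) * distal_fraction
  # the distal (telomeric) end is the chromosome start for p, the end for q
  if (arm == "p") hi <- lo + w else lo <- hi - w
  cna_event(chrom, round(lo), round(hi), delta)
}

#' CNA event sets used throughout the package
#'
#' `index_cna_events()` is the aberration set observed in the index
#' patient's tumor, lymph-node and CTC samples: gains of 1q and 8q, losses
#' of 6q, 8p, distal 11q and 17p. `ctc_extra_events()` adds the 1p loss
#' novel to the circulating tumor cells. `breast_archetype_events()` is
#' the recurrent metastatic breast-cancer pattern (losses 1p, 8p, 13q,
#' 16q; gains 1q, 8q, 16p, 17q) planted in the synthetic cohort.
#'
#' @param genome a `genome_model` built from the `"hg19"` preset (any bin
#'   count).
#' @return data.frame of events (chrom, start, end, delta, direction).
#' @export
index_cna_events <- function(genome) {
  rbind(
    arm_event(genome, "chr1", "q", +1),
    arm_event(genome, "chr8", "q", +1),
    arm_event(genome, "chr6", "q", -1),
    arm_event(genome, "chr8", "p", -1),
    arm_event(genome, "chr11", "q", -1, distal_fraction = 0.5),
    arm_event(genome, "chr17", "p", -1)
  )
}

#' @rdname index_cna_events
#' @export
ctc_extra_events <- function(genome) {
  arm_event(genome, "chr1", "p", -1)
}

#' @rdname index_cna_events
#' @export
breast_archetype_events <- function(genome) {
  rbind(
    arm_event(genome, "chr1", "p", -1),
    arm_event(genome, "chr1", "q", +1),
    arm_event(genome, "chr8", "p", -1),
    arm_event(genome, "chr8", "q", +1),
    arm_event(genome, "chr13", "q", -1),
    arm_event(genome, "chr16", "p", +1),
    arm_event(genome, "chr16", "q", -1),
    arm_event(genome, "chr17", "q", +1)
  )
}

# per-bin integer copy-number delta implied by a set of events
# (a bin takes the delta of the event covering its midpoint; overlapping
# events sum)
.bin_deltas <- function(genome, events) {
  delta <- numeric(nrow(genome$bins))
  if (is.null(events) || nrow(events) == 0) return(delta)
  mid <- (genome$bins$start + genome$bins$end) / 2
  for (i in seq_len(nrow(events))) {
    hit <- genome$bins$chrom == events$chrom[i] &
      mid >= events$start[i] & mid < events$end[i]
    delta[hit] <- delta[hit] + events$delta[i]
  }
  delta
}
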