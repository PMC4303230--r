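#' Variant call tables
#'
#' Throughout the package a variant call table is a data.frame with
#' columns `chrom`, `pos` (1-based), `ref`, `alt` (single nucleotides),
#' `gene` (symbol) and `sample`.  `variant_key()` builds the canonical
#' `chrom:pos:ref:alt` identity string used for all set operations.
#'
#' @param calls a variant call data.frame.
#' @return character vector of keys.
#' @export
variant_key <- function(calls) {
  # positions may arrive as doubles; never let them format scientifically
  paste(calls$chrom, format(calls$pos, scientific = FALSE, trim = TRUE),
        calls$ref, calls$alt, sep = ":")
}

.check_calls <- function(calls) {
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(calls))) stop("call table lacks columns: ",
                                         paste(setdiff(need, names(calls)), collapse = ", "))
  bad <- !grepl("^[ACGT]$", calls$ref) | !grepl("^[ACGT]$", calls$alt)
  if (any(bad)) stop("alleles must be single nucleotides (A/C/G/T); ",
                     sum(bad), " malformed rows")
  invisible(TRUE)
}

#' Subtract germline variants from a tumor call table
#'
#' Keeps tumor calls whose exact (chrom, pos, ref, alt) identity is
#' absent from the germline set.  Exact-identity matching (not
#' position-only) keeps the subtraction deterministic and strict.
#'
#' @param tumor_calls,germline_calls variant call tables sharing the same
#'   coordinate convention (1-based positions).
#' @return the somatic subset of `tumor_calls`.
#' @export
subtract_germline <- function(tumor_calls, germline_calls) {
  .check_calls(tumor_calls); .check_calls(germline_calls)
  tumor_calls[!(variant_key(tumor_calls) %in% variant_key(germline_calls)), ,
              drop = FALSE]
}

#' Restrict calls to exons with a 2-bp pad
#'
#' Keeps calls whose position falls inside any exon interval expanded by
#' `pad` bp on each side.  Exons are 0-based half-open `[start, end)`;
#' a 1-based position `p` is inside the padded exon when
#' `p >= start + 1 - pad` and `p <= end + pad`.
#'
#' @param calls variant call table.
#' @param exons data.frame with columns chrom, start, end (0-based
#'   half-open), optionally gene.
#' @param pad flanking bases kept on each side (default 2).
#' @return the exonic subset of `calls`.
#' @export
restrict_exonic <- function(calls, exons, pad = 2) {
  if (nrow(calls) == 0 || nrow(exons) == 0) return(calls[0, , drop = FALSE])
  if (any(exons$end <= exons$start)) stop("invalid exon intervals")
  keep <- logical(nrow(calls))
  for (cc in unique(calls$chrom)) {
    ci <- which(calls$chrom == cc)
    ex <- exons[exons$chrom == cc, , drop = FALSE]
    if (nrow(ex) == 0) next
    for (j in seq_len(nrow(ex))) {
      keep[ci] <- keep[ci] |
        (calls$pos[ci] >= ex$start[j] + 1 - pad & calls$pos[ci] <= ex$end[j] + pad)
    }
  }
  calls[keep, , drop = FALSE]
}

#' Partition calls into dbSNP-known and novel
#'
#' @param calls variant call table.
#' @param known_set character vector of `chrom:pos:ref:alt` keys (or a
#'   call table, from which keys are taken).
#' @return list with `known`, `novel` (subsets of `calls`) and `counts`
#'   (named vector known/novel/total; known + novel = total always).
#' @export
annotate_dbsnp <- function(calls, known_set) {
  if (is.data.frame(known_set)) known_set <- variant_key(known_set)
  hit <- variant_key(calls) %in% known_set
  list(known = calls[hit, , drop = FALSE],
       novel = calls[!hit, , drop = FALSE],
       counts = c(known = sum(hit), novel = sum(!hit), total = length(hit)))
}

#' Keep calls in known cancer driver genes
#'
#' @param calls variant call table with `gene` populated.
#' @param driver_genes character vector of driver gene symbols (a
#'   COSMIC-style census list).
#' @return the driver-gene subset of `calls`.
#' @export
filter_cosmic <- function(calls, driver_genes) {
  if (!"gene" %in% names(calls)) stop("call table lacks a gene column")
  calls[calls$gene %in% driver_genes, , drop = FALSE]
}

#' Keep variants shared by several samples
#'
#' @param calls variant call table with `sample` populated (all samples
#'   stacked).
#' @param min_samples minimum number of distinct samples a variant
#'   identity must appear in (>= 2).
#' @return subset of `calls` at shared variants.
#' @export
filter_shared <- function(calls, min_samples = 3) {
  if (min_samples < 2) stop("min_samples must be >= 2")
  if (!"sample" %in% names(calls)) stop("call table lacks a sample column")
  key <- variant_key(calls)
  n_samp <- tapply(calls$sample, key, function(s) length(unique(s)))
  calls[n_samp[key] >= min_samples, , drop = FALSE]
}

#' Run the full variant-prioritization cascade
#'
#' Applies, in order: germline subtraction, exonic restriction (+/- 2
#' bp), driver-gene (COSMIC) filter, shared-sample filter — the cascade
#' that reduces thousands of raw somatic calls per lesion to a handful of
#' validated multi-lesion candidates.  A per-sample audit records the
#' in/out counts of every step.
#'
#' @param tumor_calls variant call table for all tumor samples (stacked,
#'   `sample` column populated).
#' @param germline_calls germline call table.
#' @param resources list with `exons` (data.frame chrom/start/end),
#'   `driver_genes` (character) and optionally `dbsnp` (keys; only used
#'   for reporting, not filtering).
#' @param min_samples passed to [filter_shared()] (default 3).
#' @return list with `candidates` (call table of unique candidate
#'   variants, one row per variant x sample) and `audit` (data.frame:
#'   sample, step, n_in, n_out in cascade order).
#' @export
run_cascade <- function(tumor_calls, germline_calls, resources,
                        min_samples = 3) {
  steps <- list(
    subtract_germline = function(x) subtract_germline(x, germline_calls),
    restrict_exonic = function(x) restrict_exonic(x, resources$exons),
    filter_cosmic = function(x) filter_cosmic(x, resources$driver_genes),
    filter_shared = function(x) filter_shared(x, min_samples)
  )
  samples <- unique(tumor_calls$sample)
  audit <- data.frame(sample = character(0), step = character(0),
                      n_in = integer(0), n_out = integer(0))
  cur <- tumor_calls
  for (nm in names(steps)) {
    nxt <- steps[[nm]](cur)
    audit <- rbind(audit, data.frame(
      sample = "(all)", step = nm, n_in = nrow(cur), n_out = nrow(nxt)))
    for (s in samples) {
      audit <- rbind(audit, data.frame(
        sample = s, step = nm,
        n_in = sum(cur$sample == s), n_out = sum(nxt$sample == s)))
    }
    cur <- nxt
  }
  rownames(cur) <- NULL
  list(candidates = cur, audit = audit)
}
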