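#' Plain-text readers and writers
#'
#' All tabular artifacts travel as TSV: bin counts and baselines
#' (chrom, start, end, count; 0-based half-open), size histograms
#' (size_bp, density), copy-number profiles (chrom, start, end, log2,
#' status), variant call tables (chrom, pos, ref, alt, gene, sample; pos
#' 1-based), AF matrices (variant rows x lesion columns) and deep-seq
#' count tables (variant, sample, mutant, total).  A minimal VCF 4.2
#' writer is provided for interoperability.
#'
#' @param x object to write; `path` file path.
#' @name ctdx_io
NULL

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
.read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname ctdx_io
#' @param path file path.
#' @export
write_bin_counts <- function(x, path) .write_tsv(x, path)

#' @rdname ctdx_io
#' @export
read_bin_counts <- function(path) .read_tsv(path)

#' @rdname ctdx_io
#' @export
write_size_histogram <- function(x, path) {
  stopifnot(inherits(x, "size_histogram"))
  .write_tsv(data.frame(size_bp = x$size_bp, density = x$density), path)
}

#' @rdname ctdx_io
#' @export
read_size_histogram <- function(path) {
  df <- .read_tsv(path)
  size_histogram(df$size_bp, df$density)
}

#' @rdname ctdx_io
#' @export
write_cn_profile <- function(x, path) {
  stopifnot(inherits(x, "cn_profile"))
  .write_tsv(x$bins, path)
}

#' @rdname ctdx_io
#' @export
read_cn_profile <- function(path) {
  df <- .read_tsv(path)
  structure(list(bins = df, segments = NULL), class = "cn_profile")
}

#' @rdname ctdx_io
#' @export
write_variant_table <- function(x, path) .write_tsv(x, path)

#' @rdname ctdx_io
#' @export
read_variant_table <- function(path) .read_tsv(path)

#' @rdname ctdx_io
#' @export
write_af_matrix <- function(x, path) {
  df <- data.frame(variant = rownames(x), x, check.names = FALSE)
  .write_tsv(df, path)
}

#' @rdname ctdx_io
#' @export
read_af_matrix <- function(path) {
  df <- .read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$variant
  m
}

#' @rdname ctdx_io
#' @export
write_vcf <- function(x, path) {
  .check_calls(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=ctdx",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  info <- if ("gene" %in% names(x)) paste0("GENE=", x$gene) else "."
  writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                     x$chrom, x$pos, x$ref, x$alt, info), con)
  invisible(path)
}

#' @rdname ctdx_io
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      gene = character(0)))
  f <- strsplit(body, "\t")
  df <- data.frame(chrom = vapply(f, `[[`, "", 1),
                   pos = as.integer(vapply(f, `[[`, "", 2)),
                   ref = vapply(f, `[[`, "", 4),
                   alt = vapply(f, `[[`, "", 5),
                   stringsAsFactors = FALSE)
  info <- vapply(f, `[[`, "", 8)
  df$gene <- ifelse(grepl("GENE=", info), sub(".*GENE=([^;]+).*", "\\1", info),
                    NA_character_)
  df
}
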