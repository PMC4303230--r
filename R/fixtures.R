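#' The eight index-patient variants
#'
#' Synthetic loci (chromosome, position, alleles) for the eight genes
#' whose somatic SNVs survive the prioritization cascade in the index
#' patient: five truncal (PCDH20, OR4X1, ALK, DNPEP, SH3TC2), DDR2
#' (truncal, AF-elevated in tumor A), MLL3 (tumor A and lymph nodes) and
#' PIK3CA (lymph nodes and CTCs only).  Chromosome assignments follow the
#' genes' real locations; positions and alleles are synthetic.
#'
#' @return variant table (chrom, pos, ref, alt, gene), one row per gene.
#' @export
index_variants <- function() {
  data.frame(
    chrom = c("chr13", "chr11", "chr2", "chr2", "chr5", "chr1", "chr7", "chr3"),
    pos = c(61960000L, 48280000L, 29450000L, 220000000L, 148400000L,
            162750000L, 151870000L, 178920000L),
    ref = c("C", "G", "A", "C", "G", "T", "C", "A"),
    alt = c("T", "A", "G", "T", "A", "C", "T", "G"),
    gene = c("PCDH20", "OR4X1", "ALK", "DNPEP", "SH3TC2", "DDR2", "MLL3",
             "PIK3CA"),
    stringsAsFactors = FALSE
  )
}

#' True allele-fraction matrix of the index patient's lesions
#'
#' Ground-truth cellular AFs planted in the index fixture.  The five
#' truncal variants carry approximately the same AF in every lesion;
#' DDR2 is elevated in tumor A (36.4%) relative to tumors C (15.3%) and
#' D (16.6%); MLL3 is carried by tumor A (14.1%) and at higher AF by the
#' lymph nodes (18.9-24.2%); PIK3CA is restricted to the lymph nodes.
#'
#' @return numeric matrix, 8 variants x 6 lesions (A, C, D, LN15, LN17,
#'   LNA).
#' @export
index_af_truth <- function() {
  genes <- index_variants()$gene
  lesions <- c("A", "C", "D", "LN15", "LN17", "LNA")
  m <- matrix(0, length(genes), length(lesions),
              dimnames = list(genes, lesions))
  truncal <- c(PCDH20 = 0.32, OR4X1 = 0.28, ALK = 0.35, DNPEP = 0.30,
               SH3TC2 = 0.33)
  for (g in names(truncal)) m[g, ] <- truncal[g]
  m["DDR2", ] <- c(0.364, 0.153, 0.166, 0.37, 0.36, 0.35)
  m["MLL3", ] <- c(0.141, 0, 0, 0.242, 0.2155, 0.189)
  m["PIK3CA", ] <- c(0, 0, 0, 0.22, 0.20, 0.24)
  m
}

#' Synthetic index-patient bundle
#'
#' Builds every input of the index-patient analysis: lesion
#' specifications with planted SNVs and copy-number events, deep-seq
#' read counts per lesion and variant, CTC pools carrying all eight
#' variants plus the CTC-novel 1p loss, and three plasma samples with a
#' mononucleosomal-only size distribution, a low tumor fraction (2-3%),
#' deep-seq counts at plasma AFs of 2-3%, and the measured mutant
#' fragment concentrations (6,320 / 8,524 / 4,419 fragments per ml).
#'
#' @param seed integer seed for all sampling.
#' @param n_bins genome-wide bin count of the hg19-proportioned model
#'   used for the copy-number inputs (default 1,000; the full-resolution
#'   analysis uses 50,000).
#' @param depth targeted deep-sequencing depth per variant.
#' @param reads shallow-WGS reads per sample.
#' @return list with components `genome`, `variants`, `af_truth`,
#'   `lesions` (list of lesion specs: id, parent, snvs, events),
#'   `deep_seq` (data.frame variant/sample/mutant/total), `ctc` (AF
#'   vectors and events of three CTC pools), `plasma` (per-sample tumor
#'   fraction, size histogram, bin counts, deep-seq counts, per-ml
#'   mutant fragments) and `baseline` (expected diploid counts).
#' @export
make_index_patient_fixture <- function(seed = 1, n_bins = 1000,
                                       depth = 10000, reads = 250000) {
  genome <- make_genome_model("hg19", n_bins = n_bins)
  variants <- index_variants()
  af <- index_af_truth()
  base_events <- index_cna_events(genome)
  # small private/derived events separate the clades in CN space:
  # tumor A gained 20q; the LN deposits (and CTCs) lost 16q; CTCs
  # additionally lost 1p (the change novel to the CTCs).
  a_extra <- arm_event(genome, "chr20", "q", +1)
  ln_extra <- arm_event(genome, "chr16", "q", -1)
  ctc_extra <- ctc_extra_events(genome)
  ev <- list(A = rbind(base_events, a_extra),
             C = base_events, D = base_events,
             LN15 = rbind(base_events, ln_extra),
             LN17 = rbind(base_events, ln_extra),
             LNA = rbind(base_events, ln_extra))
  parents <- c(A = "C+D", C = NA, D = NA, LN15 = "A", LN17 = "A", LNA = "A")
  lesions <- lapply(colnames(af), function(ls) {
    snvs <- af[, ls][af[, ls] > 0]
    list(id = ls, parent = unname(parents[ls]), snvs = snvs,
         events = ev[[ls]])
  })
  names(lesions) <- colnames(af)

  deep_seq <- do.call(rbind, lapply(colnames(af), function(ls) {
    do.call(rbind, lapply(rownames(af), function(v) {
      cnt <- simulate_deep_seq_counts(af[v, ls], depth,
                                      seed = .sub_seed(seed, ls, v))
      data.frame(variant = v, sample = ls, mutant = cnt$mutant,
                 total = cnt$total, stringsAsFactors = FALSE)
    }))
  }))

  ctc_events <- rbind(base_events, ln_extra, ctc_extra)
  ctc <- lapply(1:3, function(i) {
    list(id = paste0("CTC", i),
         af = stats::setNames(rep(0.4, nrow(variants)), variants$gene),
         events = ctc_events)
  })
  names(ctc) <- vapply(ctc, `[[`, "", "id")

  baseline <- expected_bin_counts(genome, total_reads = reads)
  per_ml <- c(P1 = 6320, P2 = 8524, P3 = 4419)
  plasma <- lapply(seq_along(per_ml), function(i) {
    id <- names(per_ml)[i]
    tf <- withr::with_seed(.sub_seed(seed, id, "tf"),
                           stats::runif(1, 0.02, 0.03))
    plasma_af <- withr::with_seed(.sub_seed(seed, id, "af"),
                                  stats::runif(nrow(variants), 0.02, 0.03))
    names(plasma_af) <- variants$gene
    ds <- do.call(rbind, lapply(variants$gene, function(v) {
      cnt <- simulate_deep_seq_counts(plasma_af[v], depth,
                                      seed = .sub_seed(seed, id, v))
      data.frame(variant = v, sample = id, mutant = cnt$mutant,
                 total = cnt$total, stringsAsFactors = FALSE)
    }))
    list(id = id, tumor_fraction = tf, true_af = plasma_af,
         hist = simulate_size_histogram(1, 0, 0,
                                        seed = .sub_seed(seed, id, "hist")),
         counts = simulate_bin_counts(genome, base_events, tf, reads,
                                      seed = .sub_seed(seed, id, "cnt")),
         deep_seq = ds, per_ml = unname(per_ml[i]))
  })
  names(plasma) <- names(per_ml)

  list(genome = genome, variants = variants, af_truth = af,
       lesions = lesions, deep_seq = deep_seq, ctc = ctc, plasma = plasma,
       baseline = baseline, reads = reads, depth = depth)
}

# derive a reproducible 31-bit sub-seed from a master seed and string tags
.sub_seed <- function(seed, ...) {
  tag <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 2147483647L
  as.integer(h)
}

#' Synthetic exome-cascade fixture for the index patient
#'
#' Emulates the exome-sequencing call tables that feed the variant
#' prioritization cascade: a germline table of 21,741 SNVs of which
#' 20,749 are in the known-variant (dbSNP-style) set and 992 are novel;
#' per-lesion tumor tables whose post-subtraction somatic counts span
#' 716 (tumor C) to 1,589 (LN15); exon intervals; and a driver-gene
#' list.  The eight index variants are planted with their lesion
#' presence patterns; all other somatic calls are sample-private, so the
#' cascade (germline subtraction, exonic restriction, driver filter,
#' shared-in->=3-samples filter) returns exactly the eight candidates.
#'
#' @param seed integer seed.
#' @return list with `tumor_calls` (stacked call table), `germline`,
#'   `resources` (list: exons, driver_genes, dbsnp keys) and
#'   `somatic_totals` (named vector of planted per-sample counts).
#' @export
make_exome_fixture <- function(seed = 1) {
  withr::with_seed(.sub_seed(seed, "exome"), {
    idx <- index_variants()
    af <- index_af_truth()
    drivers_extra <- c("TP53", "GATA3", "MAP3K1", "CDH1", "PTEN", "RB1",
                       "ESR1", "ERBB2", "AKT1", "KRAS", "BRCA1", "BRCA2")
    driver_genes <- c(idx$gene, drivers_extra)
    bg_genes <- sprintf("GENE%03d", 1:200)
    chroms <- paste0("chr", 1:22)
    gene_tab <- data.frame(gene = c(driver_genes, bg_genes),
                           stringsAsFactors = FALSE)
    gene_tab$chrom <- sample(chroms, nrow(gene_tab), replace = TRUE)
    gene_tab$chrom[match(idx$gene, gene_tab$gene)] <- idx$chrom
    gene_tab$start <- sample.int(2e8, nrow(gene_tab)) # 0-based exon start
    gene_tab$start[match(idx$gene, gene_tab$gene)] <- idx$pos - 1000
    gene_tab$end <- gene_tab$start + 2000
    exons <- gene_tab[, c("chrom", "start", "end", "gene")]

    nt <- c("A", "C", "G", "T")
    rand_calls <- function(n, genes) {
      g <- if (length(genes) == 1) rep(genes, n) else
        sample(genes, n, replace = TRUE)
      i <- match(g, gene_tab$gene)
      ref <- sample(nt, n, replace = TRUE)
      data.frame(chrom = gene_tab$chrom[i],
                 pos = gene_tab$start[i] + sample.int(2000, n, replace = TRUE),
                 ref = ref,
                 alt = vapply(ref, function(r) sample(setdiff(nt, r), 1), ""),
                 gene = g, stringsAsFactors = FALSE)
    }
    dedupe <- function(x) x[!duplicated(paste(x$chrom, x$pos, x$ref, x$alt)), ]

    # germline: 21,741 unique SNVs scattered over background-gene exons
    germline <- rand_calls(26000, bg_genes)
    germline <- utils::head(dedupe(germline), 21741)
    stopifnot(nrow(germline) == 21741)
    germline$sample <- "germline"
    known_idx <- sample.int(21741, 20749)
    dbsnp <- c(variant_key(germline[known_idx, ]),
               # known variants not seen in this genome
               paste0("chr1:", sample.int(1e6, 5000), ":A:G"))

    samples <- colnames(af)
    totals <- c(A = 1100, C = 716, D = 920, LN15 = 1589, LN17 = 1350,
                LNA = 1210)
    tumor <- do.call(rbind, lapply(samples, function(s) {
      planted <- idx[af[idx$gene, s] > 0, , drop = FALSE]
      n_decoy <- 3
      decoys <- rand_calls(n_decoy, drivers_extra)
      n_bg <- totals[s] - nrow(planted) - n_decoy
      n_ex <- round(0.6 * n_bg)
      bg_ex <- rand_calls(n_ex, bg_genes)
      # intergenic calls: outside every (padded) exon, dropped at the
      # exonic-restriction step
      bg_out <- rand_calls(n_bg - n_ex, bg_genes)
      bg_out$pos <- bg_out$pos + 3000
      bg_out$gene <- "."
      # germline contamination rows, removed at the subtraction step
      contam <- germline[sample.int(21741, 200), names(idx)]
      calls <- rbind(planted, decoys, bg_ex, bg_out, contam)
      calls$sample <- s
      calls$fixed <- c(rep(TRUE, nrow(planted)),
                       rep(FALSE, n_decoy + n_bg),
                       rep(TRUE, nrow(contam)))
      calls
    }))
    # make non-planted somatic calls sample-private and germline-free:
    # perturb any movable key that collides across samples or with germline
    germ_keys <- variant_key(germline)
    key <- variant_key(tumor)
    dup <- (duplicated(key) | key %in% germ_keys) & !tumor$fixed
    while (any(dup)) {
      tumor$pos[dup] <- tumor$pos[dup] + sample.int(500, sum(dup), replace = TRUE)
      key <- variant_key(tumor)
      dup <- (duplicated(key) | key %in% germ_keys) & !tumor$fixed
    }
    tumor$fixed <- NULL
    rownames(tumor) <- NULL
    list(tumor_calls = tumor, germline = germline,
         resources = list(exons = exons, driver_genes = driver_genes,
                          dbsnp = dbsnp),
         somatic_totals = totals)
  })
}
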