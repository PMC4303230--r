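#' Cohort simulation configuration
#'
#' The stated world of the synthetic plasma cohort.  `composition` fixes
#' how many samples fall in each cell of the size-class x detectability
#' 2x2 table; tumor fractions are then drawn from ranges where the
#' default classifiers make the intended call essentially surely
#' (detected: 0.45-0.65; undetected: 0.01-0.03, matching the balanced
#' index-patient plasma at 2-3% AF).  `paper_replica_config()` is the
#' shipped 71-sample composition: 25 biphasic-detected, 7
#' biphasic-undetected, 3 monophasic-detected, 36 monophasic-undetected
#' (32 biphasic / 39 monophasic in total).
#'
#' @param composition named integer vector `c(bi_det, bi_und, mono_det,
#'   mono_und)`.
#' @param n_bins genome bins of the hg19-proportioned model.
#' @param total_reads shallow-WGS reads per sample.
#' @param tf_detected,tf_undetected tumor-fraction ranges (min, max).
#' @param di_biphasic dinucleosomal-weight range for biphasic samples.
#' @param event_prob inclusion probability of each archetype CNA event in
#'   a detected sample (at least `min_events` kept).
#' @param min_events minimum archetype events per detected sample.
#' @param liver_log_odds log-odds increase of liver metastasis for
#'   CNA-detected samples (metadata covariate only).
#' @param liver_intercept baseline log-odds of liver metastasis.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(composition = c(bi_det = 25, bi_und = 7,
                                          mono_det = 3, mono_und = 36),
                          n_bins = 1000, total_reads = 250000,
                          tf_detected = c(0.45, 0.65),
                          tf_undetected = c(0.01, 0.03),
                          di_biphasic = c(0.15, 0.35),
                          event_prob = 0.8, min_events = 4,
                          liver_log_odds = 2, liver_intercept = -1.5) {
  if (any(composition < 0) || any(composition != round(composition)))
    stop("composition counts must be non-negative integers")
  if (sum(composition) == 0) stop("composition is empty (infeasible)")
  structure(list(composition = composition, n_bins = n_bins,
                 total_reads = total_reads, tf_detected = tf_detected,
                 tf_undetected = tf_undetected, di_biphasic = di_biphasic,
                 event_prob = event_prob, min_events = min_events,
                 liver_log_odds = liver_log_odds,
                 liver_intercept = liver_intercept),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @export
paper_replica_config <- function() cohort_config()

#' Simulate a plasma cohort
#'
#' Generates, for every sample of the configured composition, a
#' fragment-size histogram (mononucleosomal only, or with a
#' dinucleosomal admixture), shallow-WGS bin counts carrying a random
#' subset of the recurrent breast-cancer CNA archetype attenuated by the
#' sample's tumor fraction, and a metadata row with a liver-metastasis
#' covariate correlated with detectability by a configurable log-odds.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; identical (config, seed) give identical
#'   bundles.
#' @return list with `genome`, `baseline`, `samples` (list: id, class
#'   truth, tumor fraction, events, hist, counts) and `metadata`
#'   (data.frame).
#' @export
simulate_cohort <- function(config, seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  genome <- make_genome_model("hg19", n_bins = config$n_bins)
  archetype <- breast_archetype_events(genome)
  baseline <- expected_bin_counts(genome, total_reads = config$total_reads)
  comp <- config$composition
  cells <- rep(c("bi_det", "bi_und", "mono_det", "mono_und"), comp)
  n <- length(cells)
  cells <- withr::with_seed(.sub_seed(seed, "order"), sample(cells))
  samples <- lapply(seq_len(n), function(i) {
    id <- sprintf("S%02d", i)
    biphasic <- grepl("^bi", cells[i])
    det <- grepl("det$", cells[i])
    tf_rng <- if (det) config$tf_detected else config$tf_undetected
    tf <- withr::with_seed(.sub_seed(seed, id, "tf"),
                           stats::runif(1, tf_rng[1], tf_rng[2]))
    events <- withr::with_seed(.sub_seed(seed, id, "ev"), {
      repeat {
        keep <- stats::runif(nrow(archetype)) < config$event_prob
        if (sum(keep) >= config$min_events) break
      }
      archetype[keep, , drop = FALSE]
    })
    di <- if (biphasic)
      withr::with_seed(.sub_seed(seed, id, "di"),
                       stats::runif(1, config$di_biphasic[1],
                                    config$di_biphasic[2]))
    else 0
    hist <- simulate_size_histogram(1 - di, di, 0,
                                    seed = .sub_seed(seed, id, "hist"))
    counts <- simulate_bin_counts(genome, events, tf, config$total_reads,
                                  seed = .sub_seed(seed, id, "cnt"))
    list(id = id, biphasic_true = biphasic, detected_true = det,
         tumor_fraction = tf, di_fraction = di, events = events,
         hist = hist, counts = counts)
  })
  names(samples) <- vapply(samples, `[[`, "", "id")
  liver_p <- stats::plogis(config$liver_intercept +
                             config$liver_log_odds *
                             vapply(samples, `[[`, logical(1), "detected_true"))
  liver <- withr::with_seed(.sub_seed(seed, "liver"),
                            stats::runif(n) < liver_p)
  metadata <- data.frame(
    sample = names(samples),
    size_class_true = ifelse(vapply(samples, `[[`, logical(1), "biphasic_true"),
                             "biphasic", "monophasic"),
    detected_true = vapply(samples, `[[`, logical(1), "detected_true"),
    tumor_fraction = vapply(samples, `[[`, numeric(1), "tumor_fraction"),
    liver_metastasis = liver, stringsAsFactors = FALSE)
  rownames(metadata) <- NULL
  list(genome = genome, baseline = baseline, samples = samples,
       metadata = metadata, config = config)
}
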