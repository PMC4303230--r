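#' Run the cohort pipeline end to end
#'
#' simulate -> size-classify -> copy-number profile -> 2x2 tally ->
#' chi-squared -> recurrence summary.  All classification is done by the
#' default classifiers on the simulated data (nothing is read off the
#' generator's truth labels), so the realized tally is a measurement.
#' Results and a reproducibility manifest are written under `out_dir`
#' when given.
#'
#' @param config a [cohort_config()] (default [paper_replica_config()]).
#' @param seed integer seed.
#' @param out_dir optional output directory (created if missing).
#' @return list with `tally` (`contingency_2x2`), `percentages`,
#'   `chi_square`, `recurrence`, `size_calls`, `balanced`, `metadata`
#'   and `manifest`.
#' @export
run_cohort_pipeline <- function(config = paper_replica_config(), seed = 1,
                                out_dir = NULL) {
  bundle <- .stage("simulate", simulate_cohort(config, seed))
  calls <- .stage("size-classify",
                  lapply(bundle$samples, function(s) classify_profile(s$hist)))
  profiles <- .stage("cn-profile",
                     lapply(bundle$samples, function(s)
                       cn_pipeline(s$counts, bundle$baseline)))
  detected <- !vapply(profiles, is_balanced, logical(1))
  tally <- .stage("tally", tally_cohort(calls, detected))
  pct <- row_percentages(tally)
  chi <- chi_square_2x2(tally)
  recur <- .stage("recurrence", recurrence_summary(profiles))
  size_calls <- data.frame(
    sample = names(calls),
    class = vapply(calls, `[[`, "", "class"),
    long_mass = vapply(calls, `[[`, numeric(1), "long_mass"),
    cna_detected = unname(detected), stringsAsFactors = FALSE)
  rownames(size_calls) <- NULL
  result <- list(tally = tally, percentages = pct, chi_square = chi,
                 recurrence = recur, size_calls = size_calls,
                 balanced = !detected, metadata = bundle$metadata)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_tsv(size_calls, file.path(out_dir, "size_calls.tsv"))
    .write_tsv(bundle$metadata, file.path(out_dir, "metadata.tsv"))
    .write_tsv(recur, file.path(out_dir, "recurrence.tsv"))
    jsonlite::write_json(
      list(tally = tally[c("a", "b", "c", "d", "n")],
           percentages = as.list(pct),
           chi_square = chi[c("statistic", "df", "p_value")]),
      file.path(out_dir, "cohort_stats.json"), auto_unbox = TRUE, digits = NA)
    result$manifest <- .write_manifest(out_dir, config, seed)
  }
  result
}

#' Run the index-patient pipeline end to end
#'
#' prioritize -> AF-quantify -> clonal-infer -> cluster -> mutant-fragment
#' totals, all on the synthetic index-patient bundle.
#'
#' @param seed integer seed.
#' @param out_dir optional output directory.
#' @param n_bins,depth passed to [make_index_patient_fixture()].
#' @return list with `fixture`, `cascade` (candidates + audit),
#'   `af_matrix` (measured lesion AFs), `tree` (`clone_tree`),
#'   `ctc_nodes` (node assignment per CTC pool), `dendrogram`
#'   (`ctdx_dendro` over lesions + CTC pools), `plasma_af` (summary of
#'   measured plasma AFs), `fragment_totals` and `manifest`.
#' @export
run_index_pipeline <- function(seed = 1, out_dir = NULL, n_bins = 1000,
                               depth = 10000) {
  fx <- .stage("fixture", make_index_patient_fixture(seed, n_bins = n_bins,
                                                     depth = depth))
  ex <- .stage("exome", make_exome_fixture(seed))
  casc <- .stage("prioritize",
                 run_cascade(ex$tumor_calls, ex$germline, ex$resources,
                             min_samples = 3))

  lesions <- colnames(fx$af_truth)
  af_mat <- matrix(NA_real_, nrow(fx$af_truth), length(lesions),
                   dimnames = dimnames(fx$af_truth))
  for (i in seq_len(nrow(fx$deep_seq))) {
    r <- fx$deep_seq[i, ]
    af_mat[r$variant, r$sample] <- compute_af(r$mutant, r$total)$af
  }
  tree <- .stage("clonal", order_lesions(af_mat))
  ctc_nodes <- vapply(fx$ctc, function(p) assign_sample(p$af, tree), "")

  # copy-number clustering over lesions + CTC pools
  prof_inputs <- c(
    lapply(fx$lesions, function(l)
      simulate_bin_counts(fx$genome, l$events, 0.7, fx$reads,
                          seed = .sub_seed(seed, l$id, "lesion_cnt"))),
    lapply(fx$ctc, function(p)
      simulate_bin_counts(fx$genome, p$events, 0.95, fx$reads,
                          seed = .sub_seed(seed, p$id, "ctc_cnt"))))
  profiles <- .stage("cluster-profiles",
                     lapply(prof_inputs, function(cnt)
                       cn_pipeline(cnt, fx$baseline)))
  dmat <- manhattan_distance_matrix(profiles)
  dendro <- hcluster_complete(dmat)

  plasma_af <- lapply(fx$plasma, function(p)
    summarize_afs(mapply(compute_af, p$deep_seq$mutant, p$deep_seq$total,
                         SIMPLIFY = FALSE)))
  plasma_profiles <- lapply(fx$plasma, function(p)
    cn_pipeline(p$counts, fx$baseline))
  totals <- lapply(fx$plasma, function(p) total_mutant_fragments(p$per_ml))

  result <- list(fixture = fx, cascade = casc, af_matrix = af_mat,
                 tree = tree, ctc_nodes = ctc_nodes, dendrogram = dendro,
                 plasma_af = plasma_af,
                 plasma_balanced = vapply(plasma_profiles, is_balanced,
                                          logical(1)),
                 fragment_totals = totals)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_tsv(casc$candidates, file.path(out_dir, "candidates.tsv"))
    .write_tsv(casc$audit, file.path(out_dir, "cascade_audit.tsv"))
    write_af_matrix(af_mat, file.path(out_dir, "af_matrix.tsv"))
    writeLines(clone_tree_json(tree), file.path(out_dir, "clone_tree.json"))
    writeLines(dendro$newick, file.path(out_dir, "dendrogram.nwk"))
    jsonlite::write_json(
      list(ctc_nodes = as.list(ctc_nodes),
           plasma_balanced = as.list(result$plasma_balanced),
           fragment_totals = lapply(totals, function(t)
             t[c("per_ml", "n_total", "n_total_2sf")])),
      file.path(out_dir, "index_results.json"), auto_unbox = TRUE,
      digits = NA)
    result$manifest <- .write_manifest(out_dir, list(n_bins = n_bins,
                                                     depth = depth), seed)
  }
  result
}

# stage wrapper: tags errors with the failing stage, logs to stderr
.stage <- function(name, expr) {
  message(sprintf("[ctdx:%s] running", name))
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

# manifest: seed, package version, config hash, md5 of every output file
.write_manifest <- function(out_dir, config, seed) {
  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  files <- setdiff(list.files(out_dir), "manifest.json")
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(
    tool = "ctdx",
    version = as.character(utils::packageVersion("ctdx")),
    seed = seed, config_hash = cfg_hash,
    files = stats::setNames(as.list(unname(sums)), files),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  manifest
}
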