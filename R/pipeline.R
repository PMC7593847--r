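#' End-to-end run configuration
#'
#' Bundles the configuration of every pipeline stage: synthetic cohort
#' generation (optional — existing files can be supplied to
#' [run_pipeline()] instead), Monte-Carlo feature selection, the IFS
#' classifier and scan depth, the comparator filter settings, and a single
#' global seed from which every stage derives its own seed by stage-name
#' hashing (so stages are independently reproducible).
#'
#' @param spec a [synthetic_spec()] or `NULL` when input files are given.
#' @param mcfs an [mcfs_config()]. The pipeline default (`s = 200`) is a
#'   desk-scale setting; raise `s` for production runs.
#' @param classifier a [classifier_spec()].
#' @param K IFS scan depth (capped at the feature count at run time).
#' @param delta accuracy sacrifice accepted when choosing the key set.
#' @param k_neighbors ReliefF neighbor count.
#' @param min_bucket OneR minimum bucket size.
#' @param universe hypergeometric universe size; `NULL` means the combined
#'   feature count.
#' @param seed global integer seed.
#' @return an object of class `run_config`.
#' @export
run_config <- function(spec = synthetic_spec(),
                       mcfs = mcfs_config(s = 200),
                       classifier = classifier_spec("svm"),
                       K = 100, delta = 0.02, k_neighbors = 10,
                       min_bucket = 6, universe = NULL, seed = 1L) {
  structure(list(spec = spec, mcfs = mcfs, classifier = classifier,
                 K = as.integer(K), delta = delta,
                 k_neighbors = as.integer(k_neighbors),
                 min_bucket = as.integer(min_bucket), universe = universe,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full pipeline
#'
#' simulate (optional) -> combine -> Monte-Carlo ranking -> IFS -> filter
#' bank -> rank comparison and overlap enrichment, writing every artifact
#' into `outdir`:
#' `tumor.tsv`, `adjacent.tsv`, `annotation.tsv`, `truth.txt` (simulated
#' runs), `ranking.tsv`, `curve.tsv`, `key_features.tsv`,
#' `filters/<method>.tsv`, `comparison.tsv`, `enrichment.tsv` and
#' `manifest.json`. A rerun with the same config and seed is byte-identical.
#'
#' @param config a [run_config()].
#' @param outdir output directory (created).
#' @param tumor,adjacent,annotation optional paths to existing input tables;
#'   when all three are given, `config$spec` is ignored and no simulation is
#'   performed.
#' @return invisibly, a list with the key results (`ranking`, `curve`,
#'   `selection`, `key_features`, `comparison`, `enrichment`, `paths`).
#' @export
run_pipeline <- function(config = run_config(), outdir,
                         tumor = NULL, adjacent = NULL, annotation = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  from_files <- !is.null(tumor) && !is.null(adjacent) && !is.null(annotation)

  truth <- NULL
  if (from_files) {
    message("stage combine: reading supplied matrices")
    tum <- read_expression(tumor, "tumor")
    adj <- read_expression(adjacent, "adjacent")
    ann <- read_annotation(annotation)
  } else {
    message("stage simulate")
    spec <- config$spec
    spec$seed <- stage_seed(config$seed, "simulate")
    cohort <- generate_cohort(spec)
    write_cohort(cohort, outdir)
    tum <- cohort$tumor
    adj <- cohort$adjacent
    ann <- cohort$annotation
    truth <- cohort$truth
  }

  combined <- combine_tissues(tum, adj, ann)

  message("stage rank: Monte-Carlo feature selection")
  mcfs <- config$mcfs
  mcfs$seed <- stage_seed(config$seed, "rank")
  ranking <- run_mcfs(combined, mcfs)
  write_ranking(ranking, file.path(outdir, "ranking.tsv"))

  message("stage ifs")
  K <- min(config$K, ncol(combined$x))
  curve <- ifs_scan(combined, ranking, config$classifier, K = K)
  utils::write.table(
    data.frame(k = curve$k, accuracy = sprintf("%.17g", curve$accuracy)),
    file.path(outdir, "curve.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  sel <- select_key_set(curve, config$delta)
  key <- summarize_key_features(combined, ranking, sel$k_final)
  utils::write.table(
    data.frame(key[c("rank", "feature_id", "tissue")],
               ri = sprintf("%.17g", key$ri)),
    file.path(outdir, "key_features.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  message("stage filters")
  filters <- rank_all(combined, config$k_neighbors, config$min_bucket)
  fdir <- file.path(outdir, "filters")
  dir.create(fdir, showWarnings = FALSE)
  for (mth in names(filters))
    write_ranking(filters[[mth]], file.path(fdir, paste0(mth, ".tsv")))

  message("stage compare")
  key_rank <- ranking[seq_len(sel$k_final), , drop = FALSE]
  comparison <- compare_ranks(key_rank, filters)
  utils::write.table(comparison, file.path(outdir, "comparison.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  N <- if (is.null(config$universe)) ncol(combined$x) else config$universe
  enrich <- enrichment_table(ranking, filters, k = sel$k_final, N = N)
  utils::write.table(
    data.frame(enrich[c("method", "overlap")],
               p = sprintf("%.17g", enrich$p),
               fold = sprintf("%.17g", enrich$fold)),
    file.path(outdir, "enrichment.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  manifest <- list(
    package = "mcifs",
    version = as.character(utils::packageVersion("mcifs")),
    seed = config$seed,
    config = serialize_config(config),
    n_patients = nrow(combined$x),
    n_features = ncol(combined$x),
    k_peak = sel$k_peak, acc_peak = sel$acc_peak,
    k_final = sel$k_final, acc_final = sel$acc_final,
    tissue_counts = as.list(attr(key, "tissue_counts")))
  if (!is.null(truth)) {
    manifest$truth_recall_key_set <-
      mean(truth %in% key$feature_id)
    manifest$truth_fraction_top_2x <-
      mean(truth %in% ranking$feature_id[seq_len(2 * length(truth))])
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(combined = combined, ranking = ranking, curve = curve,
                 selection = sel, key_features = key,
                 comparison = comparison, enrichment = enrich,
                 truth = truth, outdir = outdir))
}

# Internal: plain-list view of a run_config for the manifest.
serialize_config <- function(config) {
  list(spec = if (is.null(config$spec)) NULL else unclass(config$spec),
       mcfs = unclass(config$mcfs),
       classifier = unclass(config$classifier),
       K = config$K, delta = config$delta,
       k_neighbors = config$k_neighbors, min_bucket = config$min_bucket,
       universe = config$universe, seed = config$seed)
}
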