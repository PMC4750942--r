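#' Build a validated pipeline run configuration
#'
#' Collects every tunable the pipeline stages consume into one validated
#' list, so a run is reproducible from its configuration and seed alone.
#' Defaults mirror the study design the package models: two libraries
#' (media vs iron), feature-level testing with thresholds 0.05 and 0.15,
#' an F-test variance filter at 0.05, 10 random gene sets per null
#' universe, and a RefSeq-scale background of 19,107 protein-coding
#' genes.
#'
#' @param seed integer master seed; every stage derives its own stream
#'   from it.
#' @param n_genes synthetic universe size.
#' @param depth total valid reads per library (scaled desk depth;
#'   the assay this emulates sequenced ~26 million valid reads per
#'   library, retained here only as a documented full-scale setting).
#' @param n_marker_pairs endothelial / non-endothelial marker pairs.
#' @param de_fraction,de_fold,dispersion truth-table parameters
#'   (see [simulateUniverse()]).
#' @param thresholds DE significance thresholds.
#' @param variance_filter_alpha F-test filter alpha.
#' @param n_random_sets random gene sets per null universe.
#' @param refseq_universe_size size of the annotated protein-coding
#'   background universe.
#' @param n_terms,term_size_range synthetic ontology shape.
#' @param spike_term plant the DE genes as one annotation term (so the
#'   enrichment stage has a recoverable signal).
#' @param simulate_reads also emit FASTQ and re-count it through the QC
#'   path (slower; keeps depth small).
#' @param cell_type,timepoint_h library metadata.
#' @param out_dir optional directory; when set, all tables and the run
#'   manifest are written there.
#' @return a validated list of class `ferroseq_config`.
#' @export
ferroseqConfig <- function(seed = 1L, n_genes = 400L, depth = 5e5,
                           n_marker_pairs = 5L, de_fraction = 0.05,
                           de_fold = 4, dispersion = 0.05,
                           thresholds = c(0.05, 0.15),
                           variance_filter_alpha = 0.05,
                           n_random_sets = 10L,
                           refseq_universe_size = 19107L,
                           n_terms = 40L,
                           term_size_range = c(10L, 80L),
                           spike_term = TRUE, simulate_reads = FALSE,
                           cell_type = "HDMEC", timepoint_h = 1,
                           out_dir = NULL) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              depth = depth, n_marker_pairs = as.integer(n_marker_pairs),
              de_fraction = de_fraction, de_fold = de_fold,
              dispersion = dispersion, thresholds = thresholds,
              variance_filter_alpha = variance_filter_alpha,
              n_random_sets = as.integer(n_random_sets),
              refseq_universe_size = as.integer(refseq_universe_size),
              n_terms = as.integer(n_terms),
              term_size_range = term_size_range,
              spike_term = isTRUE(spike_term),
              simulate_reads = isTRUE(simulate_reads),
              cell_type = cell_type, timepoint_h = timepoint_h,
              out_dir = out_dir)
  if (any(cfg$thresholds <= 0 | cfg$thresholds >= 1))
    stop("config error: thresholds must lie in (0, 1)")
  if (cfg$variance_filter_alpha <= 0 || cfg$variance_filter_alpha >= 1)
    stop("config error: variance_filter_alpha must lie in (0, 1)")
  if (cfg$n_genes < 2 || cfg$depth < 1 || cfg$n_random_sets < 1)
    stop("config error: sizes must be positive")
  class(cfg) <- "ferroseq_config"
  cfg
}

.stageSeed <- function(cfg, offset) (cfg$seed * 101L + offset) %% .Machine$integer.max

#' Run the full synthetic-study pipeline
#'
#' Orchestrates simulate -> (optional read QC/recount) -> FPKM ->
#' species/marker QC -> differential expression -> enrichment with
#' kappa clustering and random-set null controls -> qPCR/assay
#' validation statistics, and assembles a manifest (package version,
#' seeds, full configuration, stage runtimes) so identical
#' configurations reproduce identical outputs.
#'
#' @param config a `ferroseq_config` from [ferroseqConfig()].
#' @return a report bundle (list): `models`, `truth`, `counts`
#'   (FPKM-normalized [FeatureCounts-class]), `qc` (NULL unless reads
#'   were simulated), `species_profile`, `marker_specificity`,
#'   `de` (results + threshold counts), `enrichment`, `clusters`,
#'   `random_control_experiment`, `random_control_refseq`,
#'   `qpcr`, `concordance`, `assay_stats`, `manifest`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "ferroseq_config"))
  t0 <- proc.time()[["elapsed"]]
  times <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    times[stage] <<- round(t1 - t0, 3)
    t0 <<- t1
  }

  ## -- simulate universe + counts
  u <- simulateUniverse(config$n_genes,
                        n_marker_pairs = config$n_marker_pairs,
                        de_fraction = config$de_fraction,
                        de_fold = config$de_fold,
                        dispersion = config$dispersion,
                        seed = .stageSeed(config, 1L))
  libs <- makeLibraries(depth = config$depth,
                        cell_type = config$cell_type,
                        timepoint_h = config$timepoint_h)
  fc <- simulateCounts(u$models, u$truth, libs,
                       seed = .stageSeed(config, 2L))
  tick("simulate")

  ## -- optional toy read path: emit FASTQ and re-count through QC
  qc <- NULL
  if (config$simulate_reads) {
    rd <- simulateReads(u$models, fc, dir = tempdir(),
                        seed = .stageSeed(config, 3L))
    rc <- qcAndCountReads(rd$fastq, rd$sequences,
                          libraries = libs[, setdiff(names(libs),
                                                     "total_valid_reads")])
    qc <- rc$qc
  }
  tick("reads")

  ## -- normalization and QC summaries
  fc <- fpkmNormalize(fc, u$models)
  sp <- speciesProfile(fc, u$models)
  ms <- if (config$n_marker_pairs > 0)
    markerSpecificity(fc, u$models) else NULL
  tick("quantify")

  ## -- differential expression
  de <- runDifferentialExpression(fc, u$models,
                                  thresholds = config$thresholds,
                                  variance_filter_alpha =
                                    config$variance_filter_alpha)
  tick("diffexpr")

  ## -- enrichment on the p < max(thresholds) list, synthetic ontology
  detected <- de$results$gene_id[de$results$tested]
  spike <- if (config$spike_term)
    u$truth$gene_id[u$truth$is_de] else NULL
  terms <- makeSyntheticTermSets(geneIds(u$models),
                                 n_terms = config$n_terms,
                                 size_range = config$term_size_range,
                                 spike_genes = spike,
                                 seed = .stageSeed(config, 4L))
  sel <- max(config$thresholds)
  query <- de$results$gene_id[de$results$tested & de$results$p_t < sel]
  universe <- detected
  enr <- if (length(query) >= 1)
    enrichGeneList(query, terms, universe) else NULL
  cl <- if (!is.null(enr) && nrow(enr) > 0)
    clusterTerms(enr, terms, query) else NULL
  rc_exp <- if (length(query) >= 1 && length(universe) > length(query))
    randomSetControl(universe, length(query), terms,
                     n_sets = config$n_random_sets,
                     seed = .stageSeed(config, 5L)) else NULL
  ## RefSeq-scale background: synthetic protein-coding universe ids
  refseq_universe <- sprintf("R%05d", seq_len(config$refseq_universe_size))
  refseq_terms <- makeSyntheticTermSets(refseq_universe,
                                        n_terms = config$n_terms,
                                        size_range =
                                          config$term_size_range,
                                        seed = .stageSeed(config, 6L))
  rc_ref <- randomSetControl(refseq_universe,
                             min(850L, config$refseq_universe_size),
                             refseq_terms,
                             n_sets = config$n_random_sets,
                             seed = .stageSeed(config, 7L))
  tick("enrichment")

  ## -- validation arm: qPCR on top DE genes + two flat references
  flat <- u$truth$gene_id[u$truth$fold_change == 1 &
                            geneTable(u$models)$marker_class == "none"]
  refs <- utils::head(flat, 2)
  targets <- utils::head(de$results$gene_id[de$results$tested &
                                              de$results$rank %in% 1:6], 6)
  val <- simulateValidationData(u$truth, targets, refs,
                                seed = .stageSeed(config, 8L))
  rq <- relativeExpression(val$plate, refs, calibrator_sample = "media")
  ## concordance: gene-level mean FPKM (iron) vs iron-sample mean Ct
  fp <- fpkm(fc)
  ft <- featureTable(u$models)
  genes_conc <- unique(val$plate$gene_id)
  al <- vapply(genes_conc, function(g)
    mean(fp[ft$feature_id[ft$gene_id == g], "iron_1"]), 0)
  cts <- vapply(genes_conc, function(g)
    mean(val$plate$ct[val$plate$gene_id == g &
                        val$plate$sample_id == "iron"]), 0)
  conc <- concordanceRegression(al, cts)
  assay_stats <- do.call(rbind, lapply(split(val$assays,
                                             seq_len(nrow(val$assays))),
    function(d) {
      ps <- proportionStat(d$n_positive, d$n_total)
      data.frame(assay = d$assay, group = d$group,
                 n_positive = d$n_positive, n_total = d$n_total,
                 percent = ps$percent, ci_low = ps$ci_low,
                 ci_high = ps$ci_high, stringsAsFactors = FALSE)
    }))
  rownames(assay_stats) <- NULL
  tick("validation")

  manifest <- list(
    package = "ferroseq",
    version = as.character(utils::packageVersion("ferroseq")),
    r_version = R.version.string,
    seed = config$seed,
    stage_seeds = stats::setNames(
      vapply(1:8, function(i) .stageSeed(config, i), 0),
      c("universe", "counts", "reads", "termsets", "null_experiment",
        "refseq_termsets", "null_refseq", "validation")),
    config = unclass(config),
    runtimes_s = as.list(times),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  bundle <- list(models = u$models, truth = u$truth, counts = fc,
                 qc = qc, species_profile = sp, marker_specificity = ms,
                 de = de, enrichment = enr, clusters = cl,
                 random_control_experiment = rc_exp,
                 random_control_refseq = rc_ref, qpcr = rq,
                 concordance = conc, assay_stats = assay_stats,
                 manifest = manifest)
  if (!is.null(config$out_dir)) .writeBundle(bundle, config$out_dir)
  bundle
}

.writeBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeCountMatrix(bundle$counts, file.path(dir, "counts.tsv"))
  writeGeneModels(bundle$models, file.path(dir, "gene_models.bed"))
  utils::write.table(bundle$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$de$results, file.path(dir, "de_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$de$threshold_counts,
                     file.path(dir, "de_threshold_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$enrichment))
    utils::write.table(bundle$enrichment,
                       file.path(dir, "enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$clusters))
    utils::write.table(bundle$clusters,
                       file.path(dir, "term_clusters.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$qpcr, file.path(dir, "qpcr_rq.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$assay_stats,
                     file.path(dir, "assay_stats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$manifest,
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
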