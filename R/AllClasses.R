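#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assay<- assayNames colData rowData
NULL

.BIOTYPES <- c("mRNA", "miRNA", "rRNA", "lincRNA", "other")
.MARKER_CLASSES <- c("endothelial", "non_endothelial", "none")
.FEATURE_KINDS <- c("exon", "junction", "stem_loop")
.CONDITIONS <- c("media", "iron")

#' Gene models: genes and their countable features
#'
#' A `GeneModels` object holds the annotation the pipeline counts against:
#' one row per gene (strand, biotype, marker class) and one row per
#' countable feature (exon body, exon-exon splice junction, or miRNA
#' stem-loop), each with an effective length in base pairs used for
#' FPKM normalization. Counting is strand-aware at the gene level: every
#' feature inherits its gene's strand, so "gene strand only" semantics are
#' structural rather than a filtering step.
#'
#' @slot genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `biotype` (mRNA, miRNA, rRNA, lincRNA, other) and
#'   `marker_class` (endothelial, non_endothelial, none).
#' @slot features data.frame with columns `feature_id`, `gene_id`, `kind`
#'   (exon, junction, stem_loop) and `effective_length` (integer bp >= 1).
#'
#' @seealso [readGeneModels()], [simulateUniverse()]
#' @export
setClass("GeneModels",
  representation(genes = "data.frame", features = "data.frame"))

setValidity("GeneModels", function(object) {
  g <- object@genes
  f <- object@features
  msgs <- character(0)
  need_g <- c("gene_id", "chrom", "strand", "biotype", "marker_class")
  need_f <- c("feature_id", "gene_id", "kind", "effective_length")
  if (!all(need_g %in% names(g)))
    return(paste("genes slot must have columns:", paste(need_g, collapse = ", ")))
  if (!all(need_f %in% names(f)))
    return(paste("features slot must have columns:", paste(need_f, collapse = ", ")))
  if (anyDuplicated(g$gene_id))
    msgs <- c(msgs, "duplicated gene_id")
  if (anyDuplicated(f$feature_id))
    msgs <- c(msgs, "duplicated feature_id")
  if (!all(g$strand %in% c("+", "-")))
    msgs <- c(msgs, "strand must be '+' or '-'")
  if (!all(g$biotype %in% .BIOTYPES))
    msgs <- c(msgs, paste("biotype must be one of:", paste(.BIOTYPES, collapse = ", ")))
  if (!all(g$marker_class %in% .MARKER_CLASSES))
    msgs <- c(msgs, "invalid marker_class")
  if (!all(f$kind %in% .FEATURE_KINDS))
    msgs <- c(msgs, "invalid feature kind")
  if (!all(f$gene_id %in% g$gene_id))
    msgs <- c(msgs, "features reference unknown gene_id")
  if (nrow(g) > 0 && !all(g$gene_id %in% f$gene_id))
    msgs <- c(msgs, "every gene must have at least one feature")
  if (any(!is.finite(f$effective_length)) || any(f$effective_length < 1) ||
      any(f$effective_length != round(f$effective_length)))
    msgs <- c(msgs, "effective_length must be integer >= 1")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Feature-level count container
#'
#' `FeatureCounts` extends [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with a mandatory integer `"counts"` assay (features x libraries) and
#' per-library metadata in `colData`: `condition` (media or iron),
#' `cell_type`, `timepoint_h`, and `total_valid_reads` -- the library's
#' sequencing depth after quality filtering, which must be at least the
#' column sum of the counts (a read can be valid yet align nowhere).
#' After [fpkmNormalize()] the object additionally carries an `"fpkm"`
#' assay whose zero pattern matches the counts exactly.
#'
#' @seealso [FeatureCounts()], [fpkmNormalize()], [readCountMatrix()]
#' @export
setClass("FeatureCounts", contains = "SummarizedExperiment")

setValidity("FeatureCounts", function(object) {
  msgs <- character(0)
  if (!"counts" %in% assayNames(object))
    return("missing 'counts' assay")
  m <- assay(object, "counts")
  if (any(!is.finite(m)) || any(m < 0) || any(m != round(m)))
    msgs <- c(msgs, "counts must be nonnegative integers")
  cd <- colData(object)
  need <- c("condition", "cell_type", "timepoint_h", "total_valid_reads")
  miss <- setdiff(need, names(cd))
  if (length(miss))
    return(paste("colData missing:", paste(miss, collapse = ", ")))
  if (!all(cd$condition %in% .CONDITIONS))
    msgs <- c(msgs, "condition must be 'media' or 'iron'")
  if (any(cd$total_valid_reads < 1))
    msgs <- c(msgs, "total_valid_reads must be >= 1")
  if (ncol(m) > 0 && any(cd$total_valid_reads < colSums(m)))
    msgs <- c(msgs, "total_valid_reads below the library's summed feature counts")
  if ("fpkm" %in% assayNames(object)) {
    fp <- assay(object, "fpkm")
    if (any(fp < 0)) msgs <- c(msgs, "fpkm values must be >= 0")
    if (!identical(unname(fp == 0), unname(m == 0)))
      msgs <- c(msgs, "fpkm zero pattern must match counts")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Gene-set (term) annotation collection
#'
#' Holds term-to-gene annotations as parsed from a GMT file: a named list
#' of gene-id character vectors plus a one-line description per term.
#'
#' @slot sets named list of character vectors (term_id -> gene ids).
#' @slot description named character vector of term descriptions.
#' @seealso [readTermSets()], [enrichGeneList()]
#' @export
setClass("TermSets",
  representation(sets = "list", description = "character"))

setValidity("TermSets", function(object) {
  s <- object@sets
  if (length(s) == 0) return(TRUE)
  if (is.null(names(s)) || anyDuplicated(names(s)))
    return("term ids must be unique and named")
  if (any(lengths(s) == 0))
    return("empty term gene set")
  if (!identical(names(s), names(object@description)))
    return("description names must match set names")
  TRUE
})
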