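#' Construct a GeneModels object
#'
#' @param genes data.frame of genes (`gene_id`, `chrom`, `strand`,
#'   `biotype`, `marker_class`). Missing `chrom` defaults to `"chrUn"`;
#'   missing `marker_class` to `"none"`.
#' @param features data.frame of features (`feature_id`, `gene_id`,
#'   `kind`, `effective_length`).
#' @return A validated [GeneModels-class] object.
#' @export
GeneModels <- function(genes, features) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (is.null(genes$chrom)) genes$chrom <- "chrUn"
  if (is.null(genes$marker_class)) genes$marker_class <- "none"
  genes <- genes[, c("gene_id", "chrom", "strand", "biotype", "marker_class")]
  features <- features[, c("feature_id", "gene_id", "kind", "effective_length")]
  features$effective_length <- as.integer(features$effective_length)
  rownames(genes) <- NULL
  rownames(features) <- NULL
  new("GeneModels", genes = genes, features = features)
}

#' Accessors for GeneModels
#'
#' `geneTable()`/`featureTable()` return the underlying data.frames;
#' `geneIds()`/`featureIds()` the id vectors; `markerGenes()` the gene ids
#' in a marker class (`"endothelial"` or `"non_endothelial"`).
#'
#' @param x A [GeneModels-class] object.
#' @param class Marker class to select.
#' @name GeneModels-accessors
#' @aliases geneTable featureTable geneIds featureIds markerGenes
NULL

#' @rdname GeneModels-accessors
#' @export
setMethod("geneTable", "GeneModels", function(x) x@genes)

#' @rdname GeneModels-accessors
#' @export
setMethod("featureTable", "GeneModels", function(x) x@features)

#' @rdname GeneModels-accessors
#' @export
setMethod("geneIds", "GeneModels", function(x) x@genes$gene_id)

#' @rdname GeneModels-accessors
#' @export
setMethod("featureIds", "GeneModels", function(x) x@features$feature_id)

#' @rdname GeneModels-accessors
#' @export
setMethod("markerGenes", "GeneModels", function(x, class) {
  class <- match.arg(class, c("endothelial", "non_endothelial"))
  x@genes$gene_id[x@genes$marker_class == class]
})

setMethod("length", "GeneModels", function(x) nrow(x@genes))

setMethod("show", "GeneModels", function(object) {
  g <- object@genes
  f <- object@features
  cat("GeneModels with", nrow(g), "genes and", nrow(f), "features\n")
  if (nrow(g)) {
    cat("  biotypes:",
        paste(sprintf("%s=%d", names(table(g$biotype)), table(g$biotype)),
              collapse = " "), "\n")
    cat("  feature kinds:",
        paste(sprintf("%s=%d", names(table(f$kind)), table(f$kind)),
              collapse = " "), "\n")
    nm <- sum(g$marker_class != "none")
    if (nm) cat("  marker genes:", nm, "\n")
  }
})

#' Construct a FeatureCounts object
#'
#' @param counts integer matrix, features x libraries, with feature ids as
#'   rownames. Column order follows `libraries$library_id`.
#' @param libraries data.frame with columns `library_id`, `condition`
#'   (media/iron), `cell_type`, `timepoint_h`, `total_valid_reads`.
#' @return A validated [FeatureCounts-class] object.
#' @export
FeatureCounts <- function(counts, libraries) {
  counts <- as.matrix(counts)
  libraries <- as.data.frame(libraries, stringsAsFactors = FALSE)
  stopifnot("library_id" %in% names(libraries))
  if (is.null(colnames(counts))) colnames(counts) <- libraries$library_id
  counts <- counts[, libraries$library_id, drop = FALSE]
  storage.mode(counts) <- "integer"
  cd <- S4Vectors::DataFrame(
    libraries[, c("condition", "cell_type", "timepoint_h", "total_valid_reads")],
    row.names = libraries$library_id)
  se <- SummarizedExperiment(assays = list(counts = counts), colData = cd)
  new("FeatureCounts", se)
}

#' Accessors for FeatureCounts
#'
#' `counts()` and `fpkm()` return the respective assays (the latter errors
#' until [fpkmNormalize()] has been applied); `libraryInfo()` returns the
#' per-library metadata as a plain data.frame with a `library_id` column;
#' `totalValidReads()` the named depth vector.
#'
#' @param x,object A [FeatureCounts-class] object.
#' @param ... ignored.
#' @name FeatureCounts-accessors
#' @aliases fpkm libraryInfo totalValidReads
NULL

#' @rdname FeatureCounts-accessors
#' @importFrom BiocGenerics counts
#' @export counts
#' @export
setMethod("counts", "FeatureCounts", function(object) assay(object, "counts"))

#' @rdname FeatureCounts-accessors
#' @export
setMethod("fpkm", "FeatureCounts", function(x) {
  if (!"fpkm" %in% assayNames(x))
    stop("no 'fpkm' assay; run fpkmNormalize() first")
  assay(x, "fpkm")
})

#' @rdname FeatureCounts-accessors
#' @export
setMethod("libraryInfo", "FeatureCounts", function(x) {
  cd <- as.data.frame(colData(x))
  data.frame(library_id = rownames(cd), cd, row.names = NULL,
             stringsAsFactors = FALSE)
})

#' @rdname FeatureCounts-accessors
#' @export
setMethod("totalValidReads", "FeatureCounts", function(x) {
  stats::setNames(colData(x)$total_valid_reads, colnames(x))
})

setMethod("show", "FeatureCounts", function(object) {
  cat("FeatureCounts:", nrow(object), "features x", ncol(object),
      "libraries\n")
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
  li <- libraryInfo(object)
  cat("  libraries:",
      paste(sprintf("%s (%s, %gh, depth %d)", li$library_id, li$condition,
                    li$timepoint_h, li$total_valid_reads), collapse = "; "),
      "\n")
})

#' Construct a TermSets object
#'
#' @param sets named list of gene-id character vectors.
#' @param description optional named character vector of descriptions
#'   (defaults to the term ids).
#' @return A validated [TermSets-class] object.
#' @export
TermSets <- function(sets, description = NULL) {
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (length(sets) == 0)
    return(new("TermSets", sets = stats::setNames(list(), character(0)),
               description = stats::setNames(character(0), character(0))))
  if (is.null(description))
    description <- stats::setNames(names(sets), names(sets))
  description <- description[names(sets)]
  names(description) <- names(sets)
  new("TermSets", sets = sets, description = description)
}

#' Accessors for TermSets
#'
#' @param x,object A [TermSets-class] object.
#' @param i term index or id.
#' @name TermSets-accessors
#' @aliases termSets termDescription
NULL

#' @rdname TermSets-accessors
#' @export
setMethod("termSets", "TermSets", function(x) x@sets)

#' @rdname TermSets-accessors
#' @export
setMethod("termDescription", "TermSets", function(x) x@description)

setMethod("length", "TermSets", function(x) length(x@sets))

setMethod("names", "TermSets", function(x) names(x@sets))

#' @rdname TermSets-accessors
#' @export
setMethod("[[", "TermSets", function(x, i) x@sets[[i]])

setMethod("show", "TermSets", function(object) {
  cat("TermSets with", length(object), "terms")
  if (length(object))
    cat("; set sizes", paste(range(lengths(object@sets)), collapse = "-"))
  cat("\n")
})
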