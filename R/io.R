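#' Read gene models from a BED-like feature table
#'
#' The dialect is a headerless, tab-separated file with one countable
#' feature per line and 10 or 11 columns:
#' `chrom, start, end, feature_id, score, strand, gene_id, kind, biotype,
#' marker_class[, effective_length]`. Coordinates are 0-based half-open
#' and are optional metadata -- only effective lengths feed any
#' computation. When the 11th column is absent or `"."`, exon lengths
#' default to `end - start` and junction/stem-loop lengths to
#' `default_junction_length` (a junction's mappable span is bounded by the
#' read length, so the read length is the natural default). Lines starting
#' with `#` are skipped.
#'
#' @param path file to read.
#' @param default_junction_length integer bp used when a junction or
#'   stem-loop line carries no explicit effective length. Default 40,
#'   the read length of the assay this pipeline targets.
#' @return A [GeneModels-class] object (empty file gives an empty one).
#' @details All features of a gene must lie on one strand; a file placing
#'   features of the same gene on both strands is rejected. Malformed
#'   lines are reported with their line number.
#' @export
readGeneModels <- function(path, default_junction_length = 40L) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(GeneModels(
      genes = data.frame(gene_id = character(0), chrom = character(0),
                         strand = character(0), biotype = character(0),
                         marker_class = character(0)),
      features = data.frame(feature_id = character(0), gene_id = character(0),
                            kind = character(0),
                            effective_length = integer(0))))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 10 | nf > 11)
  if (length(bad))
    stop("malformed gene-model line ", lineno[bad[1]], ": expected 10-11 ",
         "tab-separated fields, found ", nf[bad[1]])
  rec <- do.call(rbind, lapply(parts, function(p) p[1:10]))
  efflen <- vapply(parts, function(p) if (length(p) >= 11) p[11] else ".", "")
  strand <- rec[, 6]
  badstr <- which(!strand %in% c("+", "-"))
  if (length(badstr))
    stop("unknown strand '", strand[badstr[1]], "' at line ",
         lineno[badstr[1]])
  kind <- rec[, 8]
  badk <- which(!kind %in% .FEATURE_KINDS)
  if (length(badk))
    stop("unknown feature kind '", kind[badk[1]], "' at line ",
         lineno[badk[1]])
  start <- suppressWarnings(as.numeric(rec[, 2]))
  end <- suppressWarnings(as.numeric(rec[, 3]))
  badc <- which(is.na(start) | is.na(end) | end < start)
  if (length(badc))
    stop("malformed coordinates at line ", lineno[badc[1]])
  len <- suppressWarnings(as.integer(efflen))
  noexplicit <- efflen == "." | is.na(len)
  len[noexplicit & kind == "exon"] <-
    as.integer(end - start)[noexplicit & kind == "exon"]
  len[noexplicit & kind != "exon"] <- as.integer(default_junction_length)
  feat <- data.frame(feature_id = rec[, 4], gene_id = rec[, 7], kind = kind,
                     effective_length = len, stringsAsFactors = FALSE)
  # one strand/biotype/marker/chrom per gene, else the file is inconsistent
  per_gene <- split(seq_len(nrow(feat)), feat$gene_id)
  colmap <- c(strand = 6, biotype = 9, marker_class = 10, chrom = 1)
  genes <- lapply(per_gene, function(i) {
    for (nm in names(colmap)) {
      if (length(unique(rec[i, colmap[[nm]]])) != 1)
        stop("gene '", feat$gene_id[i[1]], "' has inconsistent ", nm,
             " across its features (first at line ", lineno[i[1]], ")")
    }
    data.frame(gene_id = feat$gene_id[i[1]], chrom = rec[i[1], 1],
               strand = rec[i[1], 6], biotype = rec[i[1], 9],
               marker_class = rec[i[1], 10], stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, genes)
  genes <- genes[match(unique(feat$gene_id), genes$gene_id), ]
  GeneModels(genes = genes, features = feat)
}

#' Write gene models in the BED-like feature-table dialect
#'
#' Inverse of [readGeneModels()]; coordinates are emitted as
#' `0..effective_length` placeholders when the object carries none.
#'
#' @param models A [GeneModels-class] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGeneModels <- function(models, path) {
  f <- featureTable(models)
  g <- geneTable(models)
  i <- match(f$gene_id, g$gene_id)
  lines <- paste(g$chrom[i], 0L, f$effective_length, f$feature_id, 0L,
                 g$strand[i], f$gene_id, f$kind, g$biotype[i],
                 g$marker_class[i], f$effective_length, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read term-gene annotations from a GMT file
#'
#' Standard GMT: one term per line, tab-separated `term_id`,
#' `description`, then gene ids. When a `universe` is supplied each term
#' is intersected with it and terms left empty are dropped (a message
#' reports how many).
#'
#' @param path GMT file.
#' @param universe optional character vector of gene ids.
#' @return A [TermSets-class] object.
#' @export
readTermSets <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(TermSets(list()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short))
    stop("malformed GMT line ", short[1], ": fewer than 3 fields")
  ids <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(ids))
    stop("duplicate term_id in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  desc <- stats::setNames(vapply(parts, `[[`, "", 2), ids)
  sets <- stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])), ids)
  if (!is.null(universe)) {
    sets <- lapply(sets, intersect, y = universe)
    empty <- lengths(sets) == 0
    if (any(empty))
      message(sum(empty), " term(s) dropped: no genes in universe")
    sets <- sets[!empty]
    desc <- desc[!empty]
  }
  TermSets(sets, desc)
}

#' Write term sets as GMT
#'
#' @param terms A [TermSets-class] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTermSets <- function(terms, path) {
  s <- termSets(terms)
  d <- termDescription(terms)
  writeLines(vapply(names(s), function(id)
    paste(c(id, d[[id]], s[[id]]), collapse = "\t"), ""), path)
  invisible(path)
}

#' Read / write a feature-by-library count matrix as TSV
#'
#' The format is a header row `feature_id<TAB>lib1<TAB>lib2...` followed
#' by one row per feature. Cells must be nonnegative integers; anything
#' else (e.g. `3.5`) is rejected.
#'
#' @param path TSV file.
#' @return For `readCountMatrix`, an integer matrix with feature ids as
#'   rownames; `writeCountMatrix` returns `path` invisibly.
#' @export
readCountMatrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (names(df)[1] != "feature_id")
    stop("first column of a count matrix must be 'feature_id'")
  m <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(as.numeric(m))
  if (any(is.na(num)) || any(num < 0) || any(num != round(num)))
    stop("count matrix cells must be nonnegative integers")
  out <- matrix(as.integer(num), nrow = nrow(m),
                dimnames = list(df$feature_id, colnames(m)))
  out
}

#' @param counts integer matrix with feature ids as rownames (or a
#'   [FeatureCounts-class] object, whose counts assay is written).
#' @rdname readCountMatrix
#' @export
writeCountMatrix <- function(counts, path) {
  if (is(counts, "FeatureCounts")) counts <- counts(counts)
  df <- data.frame(feature_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-library metadata from CSV
#'
#' Expects columns `library_id`, `condition`, `cell_type`, `timepoint_h`,
#' `total_valid_reads`.
#'
#' @param path CSV file.
#' @return data.frame of library metadata.
#' @export
readLibraryInfo <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("library_id", "condition", "cell_type", "timepoint_h",
            "total_valid_reads")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("library metadata missing columns: ", paste(miss, collapse = ", "))
  df$total_valid_reads <- as.integer(df$total_valid_reads)
  df
}
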