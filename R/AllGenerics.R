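#' @rdname GeneModels-accessors
#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))

#' @rdname GeneModels-accessors
#' @export
setGeneric("featureTable", function(x) standardGeneric("featureTable"))

#' @rdname GeneModels-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname GeneModels-accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname GeneModels-accessors
#' @export
setGeneric("markerGenes", function(x, class) standardGeneric("markerGenes"))

#' @rdname FeatureCounts-accessors
#' @export
setGeneric("fpkm", function(x) standardGeneric("fpkm"))

#' @rdname FeatureCounts-accessors
#' @export
setGeneric("libraryInfo", function(x) standardGeneric("libraryInfo"))

#' @rdname FeatureCounts-accessors
#' @export
setGeneric("totalValidReads", function(x) standardGeneric("totalValidReads"))

#' @rdname TermSets-accessors
#' @export
setGeneric("termSets", function(x) standardGeneric("termSets"))

#' @rdname TermSets-accessors
#' @export
setGeneric("termDescription", function(x) standardGeneric("termDescription"))
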