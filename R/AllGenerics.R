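#' @rdname GenomeCatalog-class
#' @param object,x a pancora object
#' @export
setGeneric("genomeIds", function(x) standardGeneric("genomeIds"))

#' @rdname GenomeCatalog-class
#' @export
setGeneric("nGenomes", function(x) standardGeneric("nGenomes"))

#' @rdname GenomeCatalog-class
#' @param genome a genome id (optional)
#' @export
setGeneric("seqLengths", function(x, genome = NULL) standardGeneric("seqLengths"))

#' @rdname PanBlockSet-class
#' @export
setGeneric("blockIds", function(x) standardGeneric("blockIds"))

#' @rdname PanBlockSet-class
#' @export
setGeneric("nBlocks", function(x) standardGeneric("nBlocks"))

#' @rdname PanBlockSet-class
#' @export
setGeneric("blockClasses", function(x) standardGeneric("blockClasses"))

#' @rdname PanBlockSet-class
#' @export
setGeneric("catalog", function(x) standardGeneric("catalog"))

#' @rdname PanBlockSet-class
#' @export
setGeneric("isClassified", function(x) standardGeneric("isClassified"))

#' @rdname PanBlockSet-class
#' @export
setGeneric("blockTable", function(x) standardGeneric("blockTable"))

#' @rdname ConsensusOrdering-class
#' @export
setGeneric("consensusBlocks", function(x) standardGeneric("consensusBlocks"))

#' @rdname ConsensusOrdering-class
#' @export
setGeneric("consensusPaths", function(x) standardGeneric("consensusPaths"))

#' @rdname ConsensusOrdering-class
#' @export
setGeneric("projections", function(x) standardGeneric("projections"))
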