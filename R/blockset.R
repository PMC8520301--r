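#' Construct a set of alignment blocks
#'
#' @param intervals a \code{data.frame} with columns \code{block_id}
#'   (non-negative integer), \code{genome_id}, \code{seq_name},
#'   \code{start}, \code{end} (bp, 0-based half-open), \code{strand}
#'   (\code{"+"}/\code{"-"}); one row per (block, genome) interval.
#' @param catalog the \code{\linkS4class{GenomeCatalog}} the coordinates
#'   refer to.
#' @return a \code{\linkS4class{PanBlockSet}} (unclassified).
#' @seealso \code{\link{classifyBlocks}}, \code{\link{readXMFA}}
#' @export
PanBlockSet <- function(intervals, catalog) {
  if (nrow(intervals)) {
    if (any(intervals$end <= intervals$start))
      stop("coordinate error: end <= start")
    gr <- GenomicRanges::GRanges(
      seqnames = paste(intervals$genome_id, intervals$seq_name, sep = "|"),
      ranges = IRanges::IRanges(start = intervals$start + 1L,
                                end = intervals$end),
      strand = intervals$strand)
  } else {
    gr <- GenomicRanges::GRanges()
  }
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    block_id = as.integer(intervals$block_id),
    genome_id = as.character(intervals$genome_id),
    seq_name = as.character(intervals$seq_name))
  new("PanBlockSet", ranges = gr, catalog = catalog, classified = FALSE)
}

#' @rdname PanBlockSet-class
#' @export
setMethod("blockIds", "PanBlockSet", function(x)
  sort(unique(S4Vectors::mcols(x@ranges)$block_id)))

#' @rdname PanBlockSet-class
#' @export
setMethod("nBlocks", "PanBlockSet", function(x) length(blockIds(x)))

#' @rdname PanBlockSet-class
#' @export
setMethod("catalog", "PanBlockSet", function(x) x@catalog)

#' @rdname PanBlockSet-class
#' @export
setMethod("isClassified", "PanBlockSet", function(x) isTRUE(x@classified))

#' @rdname PanBlockSet-class
#' @export
setMethod("genomeIds", "PanBlockSet", function(x) genomeIds(x@catalog))

#' @rdname PanBlockSet-class
#' @export
setMethod("nGenomes", "PanBlockSet", function(x) nGenomes(x@catalog))

#' @describeIn PanBlockSet-class per-interval table with 0-based
#'   half-open coordinates (one row per (block, genome) interval).
#' @export
setMethod("blockTable", "PanBlockSet", function(x) {
  gr <- x@ranges
  mc <- S4Vectors::mcols(gr)
  out <- data.frame(block_id = mc$block_id,
                    genome_id = mc$genome_id,
                    seq_name = mc$seq_name,
                    start = BiocGenerics::start(gr) - 1L,
                    end = BiocGenerics::end(gr),
                    strand = as.character(BiocGenerics::strand(gr)),
                    stringsAsFactors = FALSE)
  if (isClassified(x)) {
    out$block_class <- mc$block_class
    out$class_label <- mc$class_label
  }
  out[order(out$block_id, out$genome_id), , drop = FALSE]
})

#' @describeIn PanBlockSet-class per-block class vector (named by block
#'   id); errors if the set is unclassified.
#' @export
setMethod("blockClasses", "PanBlockSet", function(x) {
  if (!isClassified(x)) stop("blocks are not classified yet")
  mc <- S4Vectors::mcols(x@ranges)
  first <- !duplicated(mc$block_id)
  stats::setNames(mc$block_class[first], mc$block_id[first])
})

setMethod("show", "PanBlockSet", function(object) {
  mc <- S4Vectors::mcols(object@ranges)
  cat(sprintf("PanBlockSet: %d blocks over %d genomes (%d intervals)\n",
              length(unique(mc$block_id)), nGenomes(object), length(object@ranges)))
  if (isClassified(object)) {
    cl <- blockClasses(object)
    cat(sprintf("  classes: %d core, %d dispensable, %d unique\n",
                sum(cl == "CORE"), sum(cl == "DISPENSABLE"), sum(cl == "UNIQUE")))
  } else cat("  (unclassified)\n")
  invisible(NULL)
})
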