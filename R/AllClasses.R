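#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- queryHits subjectHits
#' @importFrom BiocGenerics start end width strand
#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom stats median
#' @importFrom utils read.table write.table head
#' @useDynLib pancora, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Catalog of the genomes and sequences in a pan-genome analysis
#'
#' A \code{GenomeCatalog} records, for each of the \eqn{n} input genomes,
#' its sequences (chromosomes or scaffolds) and their lengths in bp. It is
#' the coordinate frame every alignment block is validated against, and it
#' fixes the XMFA sequence-index mapping: the \eqn{k}-th row of the catalog
#' corresponds to XMFA sequence index \eqn{k}.
#'
#' @slot seqs a \code{data.frame} with columns \code{genome_id},
#'   \code{seq_name}, \code{seq_length} (one row per sequence) and an
#'   optional \code{display_name}.
#' @export
setClass("GenomeCatalog", representation(seqs = "data.frame"))

setValidity("GenomeCatalog", function(object) {
  s <- object@seqs
  need <- c("genome_id", "seq_name", "seq_length")
  if (!all(need %in% names(s)))
    return(sprintf("catalog must have columns %s", paste(need, collapse = ", ")))
  if (nrow(s) == 0L) return("catalog has no sequences")
  if (any(duplicated(s[c("genome_id", "seq_name")])))
    return("duplicated (genome_id, seq_name) in catalog")
  if (any(!is.finite(s$seq_length)) || any(s$seq_length <= 0))
    return("seq_length must be strictly positive")
  TRUE
})

#' Set of alignment blocks over a genome catalog
#'
#' A \code{PanBlockSet} holds the blocks of a multiple whole-genome
#' alignment. Each block has at most one interval per genome; intervals
#' are stored as a \code{GRanges} whose seqnames are \code{"genome|seq"}
#' composites, with block id, genome id and (after
#' \code{\link{classifyBlocks}}) block class and label in the metadata
#' columns. Coordinates are 0-based half-open internally; the GRanges
#' carries the equivalent 1-based closed ranges.
#'
#' @slot ranges \code{GRanges} of per-genome block intervals with mcols
#'   \code{block_id}, \code{genome_id}, \code{seq_name} and (optionally)
#'   \code{block_class}, \code{class_label}.
#' @slot catalog the \code{\linkS4class{GenomeCatalog}}.
#' @slot classified logical; \code{TRUE} once classes have been assigned.
#' @export
setClass("PanBlockSet", representation(
  ranges = "GRanges",
  catalog = "GenomeCatalog",
  classified = "logical"
))

setValidity("PanBlockSet", function(object) {
  gr <- object@ranges
  mc <- S4Vectors::mcols(gr)
  need <- c("block_id", "genome_id", "seq_name")
  if (!all(need %in% names(mc)))
    return("ranges must carry mcols block_id, genome_id, seq_name")
  if (length(gr) == 0L) return(TRUE)
  key <- paste(mc$block_id, mc$genome_id)
  if (anyDuplicated(key))
    return("a genome appears more than once in one block")
  # genome/sequence must exist in catalog; interval within bounds
  cat <- object@catalog@seqs
  ck <- paste(cat$genome_id, cat$seq_name)
  ik <- paste(mc$genome_id, mc$seq_name)
  bad <- !(ik %in% ck)
  if (any(bad))
    return(sprintf("interval on unknown sequence %s", ik[which(bad)[1L]]))
  len <- cat$seq_length[match(ik, ck)]
  if (any(BiocGenerics::end(gr) > len) || any(BiocGenerics::start(gr) < 1L))
    return("interval outside sequence bounds")
  # per-genome non-overlap on the same sequence (strand-blind):
  # sort by (genome|seq, start) and compare neighbors
  st <- BiocGenerics::start(gr); en <- BiocGenerics::end(gr)
  ord <- order(ik, st, en)
  same <- ik[ord][-1L] == ik[ord][-length(ord)]
  clash <- same & (st[ord][-1L] <= en[ord][-length(ord)])
  if (any(clash)) {
    i <- which(clash)[1L]
    a <- ord[i]; b <- ord[i + 1L]
    return(sprintf("overlapping intervals in genome %s (blocks %d and %d)",
                   mc$genome_id[a], mc$block_id[a], mc$block_id[b]))
  }
  if (isTRUE(object@classified)) {
    if (!all(c("block_class", "class_label") %in% names(mc)))
      return("classified set must carry block_class and class_label")
  }
  TRUE
})

#' Final consensus ordering of core blocks
#'
#' Holds the ordered, oriented, coordinate-assigned sequence of core
#' blocks (possibly split across several paths when the greedy ordering
#' could not bridge variable regions), plus the per-genome projection
#' table used for dot-plots.
#'
#' @slot blocks \code{data.frame}: one row per core block in consensus
#'   order, with \code{rank}, \code{block_id}, \code{orientation}
#'   (\code{+1}/\code{-1}), \code{length}, \code{consensus_start},
#'   \code{consensus_end} (bp, 0-based half-open on the consensus axis),
#'   \code{path} (path index) and \code{group} (chromosome group).
#' @slot paths list of signed integer vectors, the finalized paths in
#'   consensus order.
#' @slot projections \code{data.frame}: per (genome, core block) the
#'   genome-side coordinates and strand next to the consensus coordinates.
#' @export
setClass("ConsensusOrdering", representation(
  blocks = "data.frame",
  paths = "list",
  projections = "data.frame"
))

setValidity("ConsensusOrdering", function(object) {
  b <- object@blocks
  if (nrow(b) == 0L) return(TRUE)
  if (anyDuplicated(b$block_id)) return("a core block appears twice")
  if (any(diff(b$consensus_start) <= 0))
    return("consensus coordinates must be strictly increasing")
  if (any(b$consensus_end <= b$consensus_start))
    return("blocks must have positive length")
  TRUE
})
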