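#' Best local alignment of a path against one permutation
#'
#' Smith-Waterman local alignment over block-id symbols with score +1
#' for an aligned block and -1 for a gap or a mismatch; the highest
#' scoring local alignment is returned (ties: leftmost start in the
#' permutation, then shortest span). Symbols are compared unsigned
#' unless \code{signed = TRUE}.
#'
#' @param path signed integer vector (a consensus path).
#' @param perm signed integer vector (a genome's core permutation), or a
#'   single \code{CorePermutationList} entry.
#' @param signed compare signed symbols.
#' @return list with \code{score}, \code{path_span} and \code{perm_span}
#'   (1-based inclusive index pairs; \code{c(0, 0)} for an empty
#'   alignment).
#' @examples
#' localAlignBlocks(c(1, 2, 3), c(3, 2, 1))$score  # 1
#' @export
localAlignBlocks <- function(path, perm, signed = FALSE) {
  if (is.list(perm)) perm <- perm$ids
  a <- as.integer(path); b <- as.integer(perm)
  if (!signed) { a <- abs(a); b <- abs(b) }
  if (length(a) == 0L || length(b) == 0L)
    return(list(score = 0L, path_span = c(0L, 0L), perm_span = c(0L, 0L)))
  r <- .local_align_cpp(a, b)
  list(score = r$score, path_span = c(r$a_start, r$a_end),
       perm_span = c(r$b_start, r$b_end))
}

# Best alignment of a path within one genome: max over that genome's
# sequence permutations (ties: first sequence in catalog order).
.bestForGenome <- function(path, entries, signed = FALSE) {
  best <- NULL
  for (k in seq_along(entries)) {
    al <- localAlignBlocks(path, entries[[k]], signed = signed)
    if (is.null(best) || al$score > best$score) {
      best <- al; best$entry <- k
    }
  }
  if (is.null(best))
    best <- list(score = 0L, path_span = c(0L, 0L), perm_span = c(0L, 0L),
                 entry = NA_integer_)
  best
}

.entriesByGenome <- function(perms) {
  split(perms, vapply(perms, `[[`, "", "genome"))
}

# Summed best local-alignment score of a path across all genomes.
.pathScore <- function(path, by_genome, signed = FALSE) {
  tot <- 0L
  for (g in names(by_genome))
    tot <- tot + .bestForGenome(path, by_genome[[g]], signed)$score
  tot
}

#' Orient a path against the input genomes
#'
#' The path and its reversal (order reversed, signs flipped) are each
#' aligned locally against every genome's core permutation; the
#' orientation with the higher summed best score is kept (exact ties
#' keep the forward path). Idempotent.
#'
#' @param path signed integer vector, nonempty.
#' @param perms a \code{CorePermutationList}.
#' @param signed compare signed symbols in the alignment.
#' @return list with \code{ids} (the oriented path), \code{reversed}
#'   (logical), \code{score_forward}, \code{score_reverse}.
#' @export
orientPath <- function(path, perms, signed = FALSE) {
  stopifnot(length(path) >= 1L)
  by_genome <- .entriesByGenome(perms)
  fwd <- .pathScore(path, by_genome, signed)
  revp <- -rev(as.integer(path))
  rev_score <- .pathScore(revp, by_genome, signed)
  if (rev_score > fwd)
    list(ids = revp, reversed = TRUE, score_forward = fwd,
         score_reverse = rev_score)
  else
    list(ids = as.integer(path), reversed = FALSE, score_forward = fwd,
         score_reverse = rev_score)
}

# Highest attainable summed score for a path: one +1 per alignable block
# per genome, capped by both the path length and the genome's longest
# sequence permutation.
.maxPathScore <- function(path_len, by_genome) {
  sum(vapply(by_genome, function(entries) {
    plen <- max(vapply(entries, function(e) length(e$ids), integer(1)), 0L)
    min(path_len, plen)
  }, numeric(1)))
}

#' Detect and split mis-joined paths
#'
#' A path whose summed best local-alignment score against the genomes
#' falls below \code{threshold_frac} of the highest attainable score is
#' treated as a mis-join: it is cut at the boundaries of its best
#' aligned central span into a central piece plus up to two overhangs,
#' and each piece is re-oriented and re-checked until every piece
#' passes. Pieces of one or two blocks are finalized outright (no
#' detectable mis-join under unit scoring), which guarantees
#' termination; the multiset of blocks is conserved across the output.
#'
#' @param path signed integer vector (oriented; the function re-orients
#'   pieces it creates).
#' @param perms a \code{CorePermutationList}.
#' @param threshold_frac minimum acceptable fraction of the attainable
#'   score, in (0, 1]; default 0.8.
#' @param signed compare signed symbols.
#' @return list of signed integer vectors: the finalized path pieces.
#' @export
splitMisjoins <- function(path, perms, threshold_frac = 0.8, signed = FALSE) {
  if (!is.numeric(threshold_frac) || threshold_frac <= 0 || threshold_frac > 1)
    stop("config error: threshold_frac must be in (0, 1]")
  by_genome <- .entriesByGenome(perms)
  finalize <- function(p) list(as.integer(p))
  recurse <- function(p) {
    p <- as.integer(p)
    if (length(p) <= 2L) return(finalize(p))
    maxs <- .maxPathScore(length(p), by_genome)
    if (maxs <= 0) return(finalize(p))
    best_sum <- 0L; best_al <- NULL
    for (g in names(by_genome)) {
      al <- .bestForGenome(p, by_genome[[g]], signed)
      best_sum <- best_sum + al$score
      if (is.null(best_al) || al$score > best_al$score) best_al <- al
    }
    if (best_sum >= threshold_frac * maxs) return(finalize(p))
    span <- best_al$path_span
    if (span[1] == 0L) return(finalize(p))  # aligned nowhere: keep intact
    if (span[1] == 1L && span[2] == length(p)) return(finalize(p))
    pieces <- list()
    if (span[1] > 1L) pieces <- c(pieces, list(p[1:(span[1] - 1L)]))
    pieces <- c(pieces, list(p[span[1]:span[2]]))
    if (span[2] < length(p)) pieces <- c(pieces, list(p[(span[2] + 1L):length(p)]))
    out <- list()
    for (piece in pieces) {
      op <- orientPath(piece, perms, signed)$ids
      out <- c(out, recurse(op))
    }
    out
  }
  recurse(as.integer(path))
}

# Orient + split every path of a PathSet; returns list of finalized
# signed paths.
.refinePathSet <- function(pathset, perms, threshold_frac = 0.8,
                           signed = FALSE) {
  out <- list()
  for (p in pathset$paths) {
    op <- orientPath(p$ids, perms, signed)$ids
    out <- c(out, splitMisjoins(op, perms, threshold_frac, signed))
  }
  out
}

#' Order finalized paths and assign consensus coordinates
#'
#' Each path is anchored by a majority vote on its best local alignment
#' against the input genomes: the anchor is the median, over genomes, of
#' the bp start of the aligned span in the genome; the chromosome group
#' is the most common aligned sequence name. Paths are sorted by (group,
#' anchor) and consensus bp coordinates are laid out cumulatively, each
#' block with its median per-genome interval length.
#'
#' @param paths list of finalized signed paths (from
#'   \code{\link{splitMisjoins}}).
#' @param perms a \code{CorePermutationList}.
#' @param signed compare signed symbols when aligning.
#' @return a \code{\linkS4class{ConsensusOrdering}}.
#' @export
assignCoordinates <- function(paths, perms, signed = FALSE) {
  by_genome <- .entriesByGenome(perms)
  info <- lapply(paths, function(p) {
    anchors <- numeric(0); seqs <- character(0)
    for (g in names(by_genome)) {
      entries <- by_genome[[g]]
      al <- .bestForGenome(p, entries, signed)
      if (al$score > 0L) {
        e <- entries[[al$entry]]
        anchors <- c(anchors, e$start[al$perm_span[1]])
        seqs <- c(seqs, e$seq)
      }
    }
    if (length(anchors) == 0L)
      stop("internal error: path aligns to no genome after refinement")
    grp <- names(sort(table(seqs), decreasing = TRUE))
    grp <- sort(grp[table(seqs)[grp] == max(table(seqs))])[1L]
    list(anchor = stats::median(anchors), group = grp)
  })
  anchor <- vapply(info, `[[`, numeric(1), "anchor")
  group <- vapply(info, `[[`, character(1), "group")
  first_id <- vapply(paths, function(p) min(abs(p)), numeric(1))
  ord <- order(group, anchor, first_id)
  paths <- paths[ord]; group <- group[ord]

  # median bp length of each core block over its genome occurrences
  occ_id <- abs(unlist(lapply(perms, `[[`, "ids")))
  occ_len <- unlist(lapply(perms, function(e) e$end - e$start))
  med_len <- tapply(occ_len, occ_id, function(v) max(1, round(stats::median(v))))

  rows <- list(); off <- 0; rank <- 0L
  for (i in seq_along(paths)) {
    for (s in paths[[i]]) {
      rank <- rank + 1L
      len <- med_len[[as.character(abs(s))]]
      if (is.null(len)) len <- 1
      rows[[rank]] <- data.frame(
        rank = rank, block_id = abs(s),
        orientation = if (s < 0) -1L else 1L, length = as.numeric(len),
        consensus_start = off, consensus_end = off + len,
        path = i, group = group[i], stringsAsFactors = FALSE)
      off <- off + len
    }
  }
  blocks <- if (length(rows)) do.call(rbind, rows) else
    data.frame(rank = integer(), block_id = integer(), orientation = integer(),
               length = numeric(), consensus_start = numeric(),
               consensus_end = numeric(), path = integer(), group = character())

  proj <- list()
  for (e in perms) {
    if (length(e$ids) == 0L) next
    m <- match(abs(e$ids), blocks$block_id)
    keep <- !is.na(m)
    if (!any(keep)) next
    proj[[length(proj) + 1L]] <- data.frame(
      genome_id = e$genome, seq_name = e$seq,
      block_id = abs(e$ids)[keep],
      start = e$start[keep], end = e$end[keep],
      strand = ifelse(e$ids[keep] < 0, "-", "+"),
      consensus_rank = blocks$rank[m[keep]],
      consensus_start = blocks$consensus_start[m[keep]],
      consensus_end = blocks$consensus_end[m[keep]],
      consensus_orientation = blocks$orientation[m[keep]],
      stringsAsFactors = FALSE)
  }
  projections <- if (length(proj)) do.call(rbind, proj) else
    data.frame(genome_id = character(), seq_name = character(),
               block_id = integer(), start = numeric(), end = numeric(),
               strand = character(), consensus_rank = integer(),
               consensus_start = numeric(), consensus_end = numeric(),
               consensus_orientation = integer())
  new("ConsensusOrdering", blocks = blocks, paths = paths,
      projections = projections)
}

#' Compute the consensus ordering of core blocks
#'
#' End-to-end consensus construction: core permutations, neighbor
#' frequencies, greedy path building, orientation, mis-join splitting
#' and coordinate assignment.
#'
#' @param x a classified \code{\linkS4class{PanBlockSet}} or a
#'   \code{CorePermutationList}.
#' @param threshold_frac mis-join threshold, fraction of the attainable
#'   alignment score (default 0.8).
#' @param signed compare signed symbols in alignments and distances.
#' @return a \code{\linkS4class{ConsensusOrdering}}.
#' @examples
#' co <- consensusOrdering(corePermutationList(list(1:4, 1:4, 1:4)))
#' consensusBlocks(co)
#' @export
consensusOrdering <- function(x, threshold_frac = 0.8, signed = FALSE) {
  perms <- if (inherits(x, "CorePermutationList")) x else corePermutations(x)
  if (length(unlist(lapply(perms, `[[`, "ids"))) == 0L)
    return(new("ConsensusOrdering",
               blocks = data.frame(rank = integer(), block_id = integer(),
                                   orientation = integer(), length = numeric(),
                                   consensus_start = numeric(),
                                   consensus_end = numeric(), path = integer(),
                                   group = character()),
               paths = list(), projections = data.frame()))
  ps <- buildPathSet(perms)
  finalized <- .refinePathSet(ps, perms, threshold_frac, signed)
  assignCoordinates(finalized, perms, signed)
}

#' @rdname ConsensusOrdering-class
#' @export
setMethod("consensusBlocks", "ConsensusOrdering", function(x) x@blocks)

#' @rdname ConsensusOrdering-class
#' @export
setMethod("consensusPaths", "ConsensusOrdering", function(x) x@paths)

#' @rdname ConsensusOrdering-class
#' @export
setMethod("projections", "ConsensusOrdering", function(x) x@projections)

setMethod("show", "ConsensusOrdering", function(object) {
  b <- object@blocks
  cat(sprintf("ConsensusOrdering: %d core blocks in %d path(s), %.3f Mbp\n",
              nrow(b), length(object@paths),
              if (nrow(b)) max(b$consensus_end) / 1e6 else 0))
  invisible(NULL)
})

#' Write the consensus ordering as TSV
#' @param x a \code{ConsensusOrdering}
#' @param path output file
#' @export
writeConsensusTSV <- function(x, path) {
  utils::write.table(consensusBlocks(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
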