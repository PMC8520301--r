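#' Classify alignment blocks as core, dispensable or unique
#'
#' With \eqn{n} input genomes, a block present in all \eqn{n} genomes is
#' a core (C) block; a block present in at least two and at most
#' \eqn{n-1} genomes is dispensable (D); a block present in exactly one
#' genome is unique (U). Class labels \code{C<k>}/\code{D<k>}/\code{U<k>}
#' number the blocks consecutively within each class in input (block id)
#' order.
#'
#' @param x a \code{\linkS4class{PanBlockSet}}.
#' @return \code{x} with class annotations (\code{isClassified(x)} is
#'   \code{TRUE}).
#' @examples
#' cat <- GenomeCatalog(c("gA", "gB", "gC"), rep("chr1", 3), rep(1000L, 3))
#' df <- data.frame(block_id = c(1L, 1L, 1L, 2L),
#'                  genome_id = c("gA", "gB", "gC", "gA"),
#'                  seq_name = "chr1", start = c(0L, 0L, 0L, 500L),
#'                  end = c(100L, 100L, 100L, 600L), strand = "+")
#' blockClasses(classifyBlocks(PanBlockSet(df, cat)))
#' @export
classifyBlocks <- function(x) {
  stopifnot(is(x, "PanBlockSet"))
  n <- nGenomes(x)
  if (n < 2L) stop("classification needs at least 2 genomes")
  mc <- S4Vectors::mcols(x@ranges)
  counts <- table(mc$block_id)
  ids <- as.integer(names(counts))
  k <- as.integer(counts)
  if (any(k > n)) stop("invariant error: block present in more than n genomes")
  cls <- ifelse(k == n, "CORE", ifelse(k == 1L, "UNIQUE", "DISPENSABLE"))
  ord <- order(ids)
  serial <- integer(length(ids))
  for (cc in c("CORE", "DISPENSABLE", "UNIQUE")) {
    sel <- ord[cls[ord] == cc]
    serial[sel] <- seq_along(sel)
  }
  lab <- paste0(substr(cls, 1L, 1L), serial)
  mc$block_class <- cls[match(mc$block_id, ids)]
  mc$class_label <- lab[match(mc$block_id, ids)]
  S4Vectors::mcols(x@ranges) <- mc
  x@classified <- TRUE  # coordinates unchanged; constructor already validated
  x
}

#' Per-class summary of a classified block set
#'
#' @param x a classified \code{\linkS4class{PanBlockSet}}.
#' @param mergeUnique if \code{TRUE}, report unique blocks as part of the
#'   dispensable class (the convention in part of the literature; the
#'   package itself keeps the three-way partition).
#' @return \code{data.frame} with columns \code{class}, \code{count},
#'   \code{bp} (cumulative interval bp over all genomes) and
#'   \code{fraction} (of summed genome length).
#' @export
blockSummary <- function(x, mergeUnique = FALSE) {
  if (!isClassified(x)) stop("classify blocks first")
  tab <- blockTable(x)
  tot <- sum(x@catalog@seqs$seq_length)
  cl <- if (mergeUnique)
    ifelse(tab$block_class == "UNIQUE", "DISPENSABLE", tab$block_class)
  else tab$block_class
  classes <- if (mergeUnique) c("CORE", "DISPENSABLE")
             else c("CORE", "DISPENSABLE", "UNIQUE")
  out <- do.call(rbind, lapply(classes, function(cc) {
    sub <- tab[cl == cc, , drop = FALSE]
    data.frame(class = cc, count = length(unique(sub$block_id)),
               bp = sum(sub$end - sub$start),
               stringsAsFactors = FALSE)
  }))
  out$fraction <- out$bp / tot
  out
}

#' Fraction of the pan-genome covered by core blocks
#'
#' The overall fraction is the summed bp of core intervals over all
#' genomes divided by the summed genome lengths; per-genome fractions
#' (core bp in that genome over its length) are also reported so either
#' denominator convention is recoverable.
#'
#' @param x a classified \code{\linkS4class{PanBlockSet}}.
#' @return list with \code{overall} (scalar in [0,1]) and
#'   \code{per_genome} (named numeric).
#' @export
coreFraction <- function(x) {
  if (!isClassified(x)) stop("classify blocks first")
  tab <- blockTable(x)
  core <- tab[tab$block_class == "CORE", , drop = FALSE]
  cs <- x@catalog@seqs
  glen <- tapply(cs$seq_length, cs$genome_id, sum)
  gcore <- vapply(names(glen), function(g)
    sum(core$end[core$genome_id == g] - core$start[core$genome_id == g]),
    numeric(1))
  list(overall = sum(gcore) / sum(glen),
       per_genome = gcore / as.numeric(glen))
}

#' Rewrite each genome as an ordered sequence of classified blocks
#'
#' @param x a classified \code{\linkS4class{PanBlockSet}}.
#' @return a \code{GenomeBlockSequenceList}: named list (one element per
#'   genome) of \code{data.frame}s sorted by (seq_name, start) with
#'   columns \code{block_id}, \code{block_class}, \code{class_label},
#'   \code{seq_name}, \code{start}, \code{end}, \code{strand}.
#' @export
genomeBlockSequences <- function(x) {
  if (!isClassified(x)) stop("classify blocks first")
  tab <- blockTable(x)
  out <- lapply(genomeIds(x), function(g) {
    sub <- tab[tab$genome_id == g, , drop = FALSE]
    if (nrow(sub) == 0L)
      warning(sprintf("genome %s occurs in no alignment block", g))
    sub <- sub[order(sub$seq_name, sub$start), , drop = FALSE]
    rownames(sub) <- NULL
    sub[, c("block_id", "block_class", "class_label", "seq_name",
            "start", "end", "strand")]
  })
  names(out) <- genomeIds(x)
  class(out) <- "GenomeBlockSequenceList"
  out
}

#' Project genomes onto their core-block permutations
#'
#' Drops dispensable and unique occurrences, leaving per (genome,
#' sequence) the signed permutation of core block ids (sign = strand)
#' together with the bp coordinates of each occurrence.
#'
#' @param x a classified \code{\linkS4class{PanBlockSet}} or a
#'   \code{GenomeBlockSequenceList}.
#' @return a \code{CorePermutationList}: list of entries, each a list
#'   with \code{genome}, \code{seq}, \code{ids} (signed integer vector),
#'   \code{start}, \code{end} (bp, aligned with \code{ids}). One entry
#'   per (genome, sequence) pair with any block occurrence; a sequence
#'   whose occurrences are all D/U yields an entry with empty \code{ids}.
#' @export
corePermutations <- function(x) {
  seqs <- if (is(x, "PanBlockSet")) genomeBlockSequences(x) else x
  stopifnot(inherits(seqs, "GenomeBlockSequenceList"))
  out <- list()
  for (g in names(seqs)) {
    sub <- seqs[[g]]
    core <- sub[sub$block_class == "CORE", , drop = FALSE]
    if (anyDuplicated(core$block_id))
      stop(sprintf("invariant error: core block occurs twice in genome %s", g))
    for (sq in unique(sub$seq_name)) {
      cs <- core[core$seq_name == sq, , drop = FALSE]
      out[[length(out) + 1L]] <- list(
        genome = g, seq = sq,
        ids = as.integer(ifelse(cs$strand == "-", -cs$block_id, cs$block_id)),
        start = cs$start, end = cs$end)
    }
  }
  class(out) <- "CorePermutationList"
  out
}

#' Build a CorePermutationList from bare signed permutations
#'
#' Convenience constructor for working directly with permutations (e.g.
#' when comparing the greedy consensus against exact references). Each
#' permutation becomes one genome with a single sequence; occurrence
#' coordinates are laid out uniformly (1 kb blocks, 100 bp apart).
#'
#' @param perms list of signed integer vectors, one per genome.
#' @param genomes optional genome names (default \code{g1, g2, ...}).
#' @return a \code{CorePermutationList}.
#' @examples
#' corePermutationList(list(c(1, 2, 3), c(1, -3, 2)))
#' @export
corePermutationList <- function(perms, genomes = NULL) {
  if (is.null(genomes)) genomes <- paste0("g", seq_along(perms))
  out <- lapply(seq_along(perms), function(i) {
    v <- as.integer(perms[[i]])
    pos <- seq_along(v)
    list(genome = genomes[i], seq = "chr1", ids = v,
         start = (pos - 1L) * 1100L, end = (pos - 1L) * 1100L + 1000L)
  })
  class(out) <- "CorePermutationList"
  out
}
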