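#' Read a multiple-genome alignment in XMFA format
#'
#' XMFA (eXtended Multi-FastA) stores one alignment block per group of
#' FASTA records terminated by a \code{=} line; record headers are
#' \code{>seqIndex:start-end strand} with 1-based inclusive coordinates.
#' \code{seqIndex} is resolved to (genome, sequence) through the catalog:
#' index \eqn{k} is the \eqn{k}-th catalog row. Gapped sequence payload is
#' discarded; only coordinates, strands and block membership are kept.
#' Zero-length entries (\code{start=0, end=0}, the convention for absent
#' genomes) are dropped from the block.
#'
#' @param path XMFA file path.
#' @param catalog a \code{\linkS4class{GenomeCatalog}} resolving sequence
#'   indices.
#' @return a \code{\linkS4class{PanBlockSet}} with blocks numbered in
#'   file order (1, 2, ...).
#' @examples
#' cat <- GenomeCatalog(c("gA", "gB"), c("chr1", "chr1"), c(1000L, 1000L))
#' f <- tempfile(fileext = ".xmfa")
#' df <- data.frame(block_id = 1L, genome_id = c("gA", "gB"),
#'                  seq_name = "chr1", start = c(100L, 200L),
#'                  end = c(150L, 250L), strand = c("+", "-"))
#' writeXMFA(PanBlockSet(df, cat), f)
#' readXMFA(f, cat)
#' @export
readXMFA <- function(path, catalog) {
  lines <- readLines(path)
  nseq <- nrow(catalog@seqs)
  rows <- list(); cur <- list(); bid <- 0L
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) next
    if (startsWith(ln, "=")) {
      if (length(cur)) {
        bid <- bid + 1L
        rows[[bid]] <- cbind(block_id = bid, do.call(rbind, cur))
      }
      cur <- list()
      next
    }
    if (startsWith(ln, ">")) {
      m <- regmatches(ln, regexec("^>\\s*(\\d+):(\\d+)-(\\d+)\\s+([+-])", ln))[[1]]
      if (length(m) == 0L)
        stop(sprintf("XMFA parse error at line %d: malformed header '%s'", i, ln))
      idx <- as.integer(m[2]); a <- as.integer(m[3]); b <- as.integer(m[4])
      if (a == 0L && b == 0L) next  # absent-genome convention
      if (idx < 1L || idx > nseq)
        stop(sprintf("XMFA catalog error at line %d: seqIndex %d outside catalog (%d sequences)",
                     i, idx, nseq))
      if (b < a)
        stop(sprintf("XMFA coordinate error at line %d: end %d < start %d", i, b, a))
      cs <- catalog@seqs[idx, ]
      cur[[length(cur) + 1L]] <- data.frame(
        genome_id = cs$genome_id, seq_name = cs$seq_name,
        start = a - 1L, end = b, strand = m[5], stringsAsFactors = FALSE)
    }
    # sequence payload lines are ignored
  }
  if (length(cur)) {
    bid <- bid + 1L
    rows[[bid]] <- cbind(block_id = bid, do.call(rbind, cur))
  }
  iv <- if (length(rows)) do.call(rbind, rows) else
    data.frame(block_id = integer(), genome_id = character(),
               seq_name = character(), start = integer(), end = integer(),
               strand = character(), stringsAsFactors = FALSE)
  iv$block_id <- as.integer(iv$block_id)
  PanBlockSet(iv, catalog)
}

#' Write alignment blocks as XMFA
#'
#' The inverse of \code{\link{readXMFA}}: coordinates are emitted 1-based
#' inclusive and the sequence payload is filled with placeholder residues
#' of the correct ungapped length (the block model carries no sequence).
#'
#' @param x a \code{\linkS4class{PanBlockSet}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeXMFA <- function(x, path) {
  tab <- blockTable(x)
  idx <- .catalogIndex(x@catalog)
  cat_s <- x@catalog@seqs
  lens <- stats::setNames(cat_s$seq_length,
                          paste(cat_s$genome_id, cat_s$seq_name, sep = "|"))
  key <- paste(tab$genome_id, tab$seq_name, sep = "|")
  if (nrow(tab) && any(tab$end > lens[key]))
    stop("coordinate error: interval outside genome bounds")
  con <- file(path, "w"); on.exit(close(con))
  writeLines("#FormatVersion Mauve1", con)
  for (g in names(idx))
    writeLines(sprintf("#Sequence%d\t%s", idx[[g]], g), con)
  for (b in sort(unique(tab$block_id))) {
    sub <- tab[tab$block_id == b, , drop = FALSE]
    sub <- sub[order(idx[paste(sub$genome_id, sub$seq_name, sep = "|")]), ,
               drop = FALSE]
    for (r in seq_len(nrow(sub))) {
      iv <- sub[r, ]
      writeLines(sprintf(">%d:%d-%d %s", idx[[paste(iv$genome_id, iv$seq_name,
                                                    sep = "|")]],
                         iv$start + 1L, iv$end, iv$strand), con)
      seqlen <- iv$end - iv$start
      full <- strrep("A", 80L)
      n80 <- seqlen %/% 80L; rem <- seqlen %% 80L
      if (n80 > 0L) writeLines(rep(full, n80), con)
      if (rem > 0L) writeLines(strrep("A", rem), con)
    }
    writeLines("=", con)
  }
  invisible(path)
}

#' Read a Mauve-style backbone coordinate table
#'
#' Tab-separated table with header \code{seq0_leftend seq0_rightend
#' seq1_leftend ...}; one row per block, one signed 1-based coordinate
#' pair per genome (column pair \eqn{i} is the \eqn{i+1}-th catalog
#' genome). \code{0 0} means the genome is absent from the block; a
#' negative pair means reverse strand. The dialect has no sequence
#' field, so every genome in the catalog must have exactly one sequence.
#'
#' @inheritParams readXMFA
#' @return a \code{\linkS4class{PanBlockSet}} with blocks numbered in
#'   row order.
#' @export
readBackbone <- function(path, catalog) {
  gids <- genomeIds(catalog)
  cs <- catalog@seqs
  if (any(table(cs$genome_id) != 1L))
    stop("backbone format supports only one sequence per genome; use XMFA")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  n <- length(gids)
  if (ncol(tab) %% 2L != 0L || ncol(tab) != 2L * n)
    stop(sprintf("backbone format error: %d columns, expected %d (2 per genome)",
                 ncol(tab), 2L * n))
  rows <- vector("list", nrow(tab))
  for (r in seq_len(nrow(tab))) {
    ivs <- list()
    for (g in seq_len(n)) {
      l <- tab[r, 2L * g - 1L]; rr <- tab[r, 2L * g]
      if (l == 0L && rr == 0L) next
      if (sign(l) != sign(rr))
        stop(sprintf("backbone coordinate error at row %d: mixed signs", r))
      if (l > rr)
        stop(sprintf("backbone coordinate error at row %d: leftend > rightend", r))
      lo <- min(abs(l), abs(rr)); hi <- max(abs(l), abs(rr))
      seq_row <- cs[cs$genome_id == gids[g], ]
      ivs[[length(ivs) + 1L]] <- data.frame(
        genome_id = gids[g], seq_name = seq_row$seq_name,
        start = lo - 1L, end = hi, strand = if (l < 0L) "-" else "+",
        stringsAsFactors = FALSE)
    }
    if (length(ivs) == 0L)
      stop(sprintf("backbone format error at row %d: all-zero row (empty block)", r))
    rows[[r]] <- cbind(block_id = r, do.call(rbind, ivs))
  }
  iv <- if (length(rows)) do.call(rbind, rows) else
    data.frame(block_id = integer(), genome_id = character(),
               seq_name = character(), start = integer(), end = integer(),
               strand = character(), stringsAsFactors = FALSE)
  iv$block_id <- as.integer(iv$block_id)
  PanBlockSet(iv, catalog)
}

#' Write alignment blocks as a Mauve-style backbone table
#' @inheritParams writeXMFA
#' @export
writeBackbone <- function(x, path) {
  gids <- genomeIds(x@catalog)
  if (any(table(x@catalog@seqs$genome_id) != 1L))
    stop("backbone format supports only one sequence per genome; use XMFA")
  tab <- blockTable(x)
  n <- length(gids)
  bids <- sort(unique(tab$block_id))
  out <- matrix(0L, nrow = length(bids), ncol = 2L * n)
  for (i in seq_along(bids)) {
    sub <- tab[tab$block_id == bids[i], , drop = FALSE]
    for (r in seq_len(nrow(sub))) {
      g <- match(sub$genome_id[r], gids)
      lo1 <- sub$start[r] + 1L; hi <- sub$end[r]
      if (sub$strand[r] == "-") {
        out[i, 2L * g - 1L] <- -hi; out[i, 2L * g] <- -lo1
      } else {
        out[i, 2L * g - 1L] <- lo1; out[i, 2L * g] <- hi
      }
    }
  }
  colnames(out) <- as.vector(rbind(sprintf("seq%d_leftend", seq_len(n) - 1L),
                                   sprintf("seq%d_rightend", seq_len(n) - 1L)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
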