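# Shared fixture builders (everything is generated in code; no stored data).

tinyCatalog <- function(n = 3L, len = 100000L, seqs = 1L) {
  gid <- rep(paste0("g", seq_len(n)), each = seqs)
  sq <- rep(paste0("chr", seq_len(seqs)), n)
  GenomeCatalog(gid, sq, rep(len, n * seqs))
}

# One interval row per (block, genome); 0-based half-open.
ivRow <- function(block, genome, start, end, strand = "+", seq = "chr1") {
  data.frame(block_id = block, genome_id = genome, seq_name = seq,
             start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

# Canonical per-block interval signature, block-id independent: used for
# order-insensitive block-set comparison across serialization round trips.
blockKey <- function(blockset) {
  tab <- blockTable(blockset)
  sig <- vapply(split(tab, tab$block_id), function(x) {
    x <- x[order(x$genome_id, x$seq_name, x$start), , drop = FALSE]
    paste(x$genome_id, x$seq_name, x$start, x$end, x$strand,
          sep = ":", collapse = "|")
  }, character(1))
  sort(unname(sig))
}

# A chimeric-path instance: collinear genomes plus a path made of two
# runs from distant loci; the planted junction index is after run A.
chimericInstance <- function(seed) {
  set.seed(seed)
  M <- sample(30:50, 1L)
  labels <- sample(1000L, M)
  n <- sample(3:5, 1L)
  perms <- corePermutationList(lapply(seq_len(n), function(i) labels))
  a <- sample(6:10, 1L)
  b <- sample((ceiling(0.3 * a) + 1L):(a - 1L), 1L)
  gapstart <- a + b + 3L + sample(0:3, 1L)
  list(perms = perms, labels = labels,
       path = c(labels[1:a], labels[gapstart:(gapstart + b - 1L)]),
       junction = a, run_a = labels[1:a],
       run_b = labels[gapstart:(gapstart + b - 1L)])
}

# Random rearranged unsigned permutation instances for oracle bounds.
randomPermInstance <- function(seed, m_max = 7L, n_max = 5L) {
  set.seed(seed)
  m <- sample(4:m_max, 1L)
  n <- sample(2:n_max, 1L)
  base <- sample(m)
  perms <- lapply(seq_len(n), function(i) {
    p <- base
    for (k in seq_len(sample(0:2, 1L))) {
      ij <- sort(sample(m, 2L))
      p[ij[1]:ij[2]] <- rev(p[ij[1]:ij[2]])
    }
    if (stats::runif(1) < 0.3 && m >= 3L) {
      from <- sample(m, 1L); p2 <- p[-from]
      at <- sample(m - 1L, 1L)
      p <- append(p2, p[from], after = at)
    }
    p
  })
  perms
}
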