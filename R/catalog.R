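#' Construct a genome catalog
#'
#' @param genome_id character vector, one entry per sequence row (ids may
#'   repeat across rows for multi-chromosome genomes).
#' @param seq_name sequence (chromosome/scaffold) names.
#' @param seq_length sequence lengths in bp (strictly positive integers).
#' @param display_name optional per-row display names (defaults to
#'   \code{genome_id}).
#' @return a \code{\linkS4class{GenomeCatalog}}.
#' @examples
#' GenomeCatalog(c("gA", "gB"), c("chr1", "chr1"), c(10000L, 12000L))
#' @export
GenomeCatalog <- function(genome_id, seq_name, seq_length,
                          display_name = genome_id) {
  seqs <- data.frame(genome_id = as.character(genome_id),
                     seq_name = as.character(seq_name),
                     seq_length = as.integer(seq_length),
                     display_name = as.character(display_name),
                     stringsAsFactors = FALSE)
  new("GenomeCatalog", seqs = seqs)
}

#' Read a genome catalog from TSV or YAML
#'
#' TSV catalogs have columns \code{genome_id}, \code{seq_name},
#' \code{seq_length}; YAML catalogs are a list of genomes, each with
#' \code{genome_id} and a \code{sequences} map of name to length.
#'
#' @param path file path (\code{.tsv}/\code{.txt} or \code{.yaml}/\code{.yml}).
#' @return a \code{\linkS4class{GenomeCatalog}}.
#' @export
readGenomeCatalog <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    rows <- do.call(rbind, lapply(y, function(g) {
      data.frame(genome_id = g$genome_id,
                 seq_name = names(g$sequences),
                 seq_length = as.integer(unlist(g$sequences)),
                 display_name = if (is.null(g$display_name)) g$genome_id
                                else g$display_name,
                 stringsAsFactors = FALSE)
    }))
    new("GenomeCatalog", seqs = rows)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    GenomeCatalog(tab$genome_id, tab$seq_name, tab$seq_length,
                  if ("display_name" %in% names(tab)) tab$display_name
                  else tab$genome_id)
  }
}

#' Write a genome catalog as TSV
#' @param x a \code{GenomeCatalog}
#' @param path output file path
#' @export
writeGenomeCatalog <- function(x, path) {
  utils::write.table(x@seqs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname GenomeCatalog-class
#' @export
setMethod("genomeIds", "GenomeCatalog", function(x) unique(x@seqs$genome_id))

#' @rdname GenomeCatalog-class
#' @export
setMethod("nGenomes", "GenomeCatalog", function(x) length(genomeIds(x)))

#' @rdname GenomeCatalog-class
#' @export
setMethod("seqLengths", "GenomeCatalog", function(x, genome = NULL) {
  s <- x@seqs
  if (!is.null(genome)) s <- s[s$genome_id == genome, , drop = FALSE]
  stats::setNames(s$seq_length, s$seq_name)
})

setMethod("show", "GenomeCatalog", function(object) {
  s <- object@seqs
  cat(sprintf("GenomeCatalog: %d genomes, %d sequences, %.3f Mbp total\n",
              length(unique(s$genome_id)), nrow(s), sum(s$seq_length) / 1e6))
  for (g in unique(s$genome_id)) {
    gs <- s[s$genome_id == g, ]
    cat(sprintf("  %s: %d seq (%s)\n", g, nrow(gs),
                paste(utils::head(gs$seq_name, 4), collapse = ", ")))
  }
  invisible(NULL)
})

# Internal: the row index of (genome, seq) in the catalog = XMFA seqIndex.
.catalogIndex <- function(catalog) {
  s <- catalog@seqs
  stats::setNames(seq_len(nrow(s)), paste(s$genome_id, s$seq_name, sep = "|"))
}
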