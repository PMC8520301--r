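#' Default track colors (RGB strings)
#'
#' Light blue: core blocks collinear with the consensus; dark blue:
#' translocated core blocks; pink: inverted core blocks; green:
#' dispensable; red: unique; grey: annotation pass-through.
#' @export
trackColors <- function() {
  c(core_collinear = "173,216,230", core_translocated = "0,0,139",
    core_inverted = "255,105,180", dispensable = "0,128,0",
    unique = "255,0,0", annotation = "128,128,128")
}

# Longest order-preserving chain classification for one (genome, seq):
# ranks r (consensus ranks in genome order) and relative orientation o
# (+1/-1). Returns character vector of per-position classes.
.chainClassify <- function(r, o) {
  L <- length(r)
  if (L == 0L) return(character(0))
  run_one <- function(r, o) {
    L <- length(r)
    # elements: forward singletons; maximal strictly-decreasing runs of
    # inverted blocks collapse to one element covering their rank range.
    elem <- list(); i <- 1L
    while (i <= L) {
      if (o[i] < 0) {
        j <- i
        while (j < L && o[j + 1L] < 0 && r[j + 1L] < r[j]) j <- j + 1L
        elem[[length(elem) + 1L]] <- list(lo = min(r[i:j]), hi = max(r[i:j]),
                                          w = j - i + 1L, members = i:j,
                                          inv = TRUE)
        i <- j + 1L
      } else {
        elem[[length(elem) + 1L]] <- list(lo = r[i], hi = r[i], w = 1L,
                                          members = i, inv = FALSE)
        i <- i + 1L
      }
    }
    k <- length(elem)
    lo <- vapply(elem, `[[`, numeric(1), "lo")
    hi <- vapply(elem, `[[`, numeric(1), "hi")
    w <- vapply(elem, `[[`, numeric(1), "w")
    dp <- numeric(k); pred <- integer(k)
    for (i2 in seq_len(k)) {
      dp[i2] <- w[i2]; pred[i2] <- 0L
      for (j2 in seq_len(i2 - 1L)) {
        if (hi[j2] < lo[i2] && dp[j2] + w[i2] > dp[i2]) {
          dp[i2] <- dp[j2] + w[i2]; pred[i2] <- j2
        }
      }
    }
    best <- which.max(dp)  # first maximum: leftmost tie-break
    chain <- integer(0); cur <- best
    while (cur > 0L) { chain <- c(cur, chain); cur <- pred[cur] }
    cls <- rep("core_translocated", L)
    for (e in chain) {
      cls[elem[[e]]$members] <-
        if (elem[[e]]$inv) "core_inverted" else "core_collinear"
    }
    list(cls = cls, weight = dp[best])
  }
  fwd <- run_one(r, o)
  bwd <- run_one(rev(r), -rev(o))
  if (bwd$weight > fwd$weight) rev(bwd$cls) else fwd$cls
}

#' Classify the rendering color of each core block per genome
#'
#' For each genome (per chromosome), the longest order-preserving chain
#' against the consensus ranks is computed, with contiguous
#' reversed-orientation, rank-decreasing runs allowed on the chain as
#' inverted segments. Blocks on the chain with matching orientation are
#' collinear (light blue); on-chain blocks in inverted segments are
#' inverted (pink); blocks off the chain, including cross-chromosome
#' placements, are translocated (dark blue). A chromosome that aligns
#' better globally reversed is classified in that direction.
#'
#' @param consensus a \code{\linkS4class{ConsensusOrdering}}.
#' @return \code{data.frame} with \code{genome_id}, \code{seq_name},
#'   \code{block_id}, \code{color_class}.
#' @export
classifyCoreRendering <- function(consensus) {
  pr <- projections(consensus)
  if (nrow(pr) == 0L)
    return(data.frame(genome_id = character(), seq_name = character(),
                      block_id = integer(), color_class = character()))
  out <- list()
  for (g in unique(pr$genome_id)) {
    for (sq in unique(pr$seq_name[pr$genome_id == g])) {
      sub <- pr[pr$genome_id == g & pr$seq_name == sq, , drop = FALSE]
      sub <- sub[order(sub$start), , drop = FALSE]
      o <- ifelse(sub$strand == "-", -1L, 1L) * sub$consensus_orientation
      cls <- .chainClassify(sub$consensus_rank, o)
      out[[length(out) + 1L]] <- data.frame(
        genome_id = g, seq_name = sq, block_id = sub$block_id,
        color_class = cls, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Dot-plot point set: genomes against the consensus ordering
#'
#' One point per (genome, core block): x is the block midpoint on the
#' consensus axis, y its midpoint in the genome, staggered by a
#' per-genome offset to avoid overplotting. Points carry the rendering
#' mark (collinear / inverted / translocated), so planted inversions
#' appear as anti-diagonal runs and translocations as isolated
#' off-diagonal points.
#'
#' @param consensus a \code{\linkS4class{ConsensusOrdering}}.
#' @param rendering optional precomputed \code{\link{classifyCoreRendering}}
#'   table.
#' @param stagger per-genome y offset in bp; default 2\% of the
#'   consensus span per genome index.
#' @return \code{data.frame} with \code{genome_id}, \code{block_id},
#'   \code{consensus_x}, \code{genome_y}, \code{mark}.
#' @export
dotplotPoints <- function(consensus, rendering = classifyCoreRendering(consensus),
                          stagger = NULL) {
  pr <- projections(consensus)
  if (nrow(pr) == 0L)
    return(data.frame(genome_id = character(), block_id = integer(),
                      consensus_x = numeric(), genome_y = numeric(),
                      mark = character()))
  if (is.null(stagger)) stagger <- 0.02 * max(pr$consensus_end)
  genomes <- unique(pr$genome_id)
  gi <- stats::setNames(seq_along(genomes) - 1L, genomes)
  mk <- stats::setNames(sub("^core_", "", rendering$color_class),
                        paste(rendering$genome_id, rendering$block_id))
  data.frame(
    genome_id = pr$genome_id,
    block_id = pr$block_id,
    consensus_x = (pr$consensus_start + pr$consensus_end) / 2,
    genome_y = (pr$start + pr$end) / 2 + gi[pr$genome_id] * stagger,
    mark = unname(mk[paste(pr$genome_id, pr$block_id)]),
    stringsAsFactors = FALSE)
}

#' Render a dot-plot
#' @param points output of \code{\link{dotplotPoints}}.
#' @param file optional output image path (png/pdf via \code{ggsave}).
#' @return the ggplot object, invisibly.
#' @export
plotDotplot <- function(points, file = NULL) {
  p <- ggplot2::ggplot(points,
         ggplot2::aes(x = consensus_x, y = genome_y,
                      colour = genome_id, shape = mark)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_shape_manual(values = c(collinear = 16, inverted = 17,
                                           translocated = 4)) +
    ggplot2::labs(x = "consensus ordering (bp)", y = "genome coordinate (bp)",
                  colour = "genome", shape = "block") +
    ggplot2::theme_bw()
  if (!is.null(file)) ggplot2::ggsave(file, p, width = 8, height = 5, dpi = 150)
  invisible(p)
}

# Build BED6+1 records for all tracks in plain (native-coordinate) mode.
.plainRecords <- function(consensus, blockset, rendering,
                          colors = trackColors()) {
  seqs <- genomeBlockSequences(blockset)
  cons <- consensusBlocks(consensus)
  btab <- blockTable(blockset)
  lab <- stats::setNames(btab$class_label[!duplicated(btab$block_id)],
                         btab$block_id[!duplicated(btab$block_id)])
  rkey <- stats::setNames(rendering$color_class,
                          paste(rendering$genome_id, rendering$block_id))
  tracks <- list()
  for (g in names(seqs)) {
    sub <- seqs[[g]]
    cc <- ifelse(sub$block_class == "DISPENSABLE", "dispensable",
          ifelse(sub$block_class == "UNIQUE", "unique",
                 rkey[paste(g, sub$block_id)]))
    cc[is.na(cc)] <- "core_translocated"  # core block on an unplaced path
    tracks[[g]] <- data.frame(
      chrom = sub$seq_name, start = sub$start, end = sub$end,
      name = sub$class_label, score = 0L, strand = sub$strand,
      rgb = unname(colors[cc]), color_class = unname(cc),
      stringsAsFactors = FALSE)
  }
  tracks[["consensus"]] <- data.frame(
    chrom = "consensus", start = cons$consensus_start,
    end = cons$consensus_end,
    name = unname(lab[as.character(cons$block_id)]), score = 0L,
    strand = ifelse(cons$orientation < 0, "-", "+"),
    rgb = unname(colors["core_collinear"]), color_class = "core_collinear",
    stringsAsFactors = FALSE)
  tracks
}

# Gap-aligned records: every core block occupies the same interval on a
# common virtual axis in every track; the stretch after each core block
# holds each genome's D/U blocks packed left-to-right, sized to the
# maximum requirement across genomes.
.gapAlignedRecords <- function(consensus, blockset, rendering,
                               colors = trackColors()) {
  seqs <- genomeBlockSequences(blockset)
  cons <- consensusBlocks(consensus)
  if (length(consensusPaths(consensus)) > 1L)
    warning("gap-aligned tracks: consensus has multiple paths; emitting on one concatenated axis")
  m <- nrow(cons)
  rank_of <- stats::setNames(cons$rank, cons$block_id)
  len_of <- stats::setNames(cons$length, cons$rank)
  rkey <- stats::setNames(rendering$color_class,
                          paste(rendering$genome_id, rendering$block_id))
  # slot j (0..m) holds D/U content following core rank j (0 = before any)
  per_genome_slots <- list()
  gap <- numeric(m + 1L)
  for (g in names(seqs)) {
    sub <- seqs[[g]]
    slot <- list()
    for (sq in unique(sub$seq_name)) {
      ssub <- sub[sub$seq_name == sq, , drop = FALSE]
      cur <- 0L
      for (i in seq_len(nrow(ssub))) {
        if (ssub$block_class[i] == "CORE") {
          r <- rank_of[as.character(ssub$block_id[i])]
          cur <- if (is.na(r)) cur else as.integer(r)
        } else {
          key <- as.character(cur)
          slot[[key]] <- rbind(slot[[key]], ssub[i, , drop = FALSE])
        }
      }
    }
    per_genome_slots[[g]] <- slot
    for (key in names(slot)) {
      j <- as.integer(key)
      need <- sum(slot[[key]]$end - slot[[key]]$start)
      gap[j + 1L] <- max(gap[j + 1L], need)
    }
  }
  # virtual offsets: gap0, core1, gap1, core2, ...
  core_v <- numeric(m)
  off <- gap[1L]
  for (r in seq_len(m)) {
    core_v[r] <- off
    off <- off + len_of[[as.character(r)]] + gap[r + 1L]
  }
  tracks <- list()
  for (g in names(seqs)) {
    sub <- seqs[[g]]
    rows <- list()
    core_sub <- sub[sub$block_class == "CORE", , drop = FALSE]
    rr <- rank_of[as.character(core_sub$block_id)]
    keep <- !is.na(rr)
    if (any(keep)) {
      cc <- rkey[paste(g, core_sub$block_id[keep])]
      cc[is.na(cc)] <- "core_translocated"
      rows[[1L]] <- data.frame(
        chrom = "pan", start = core_v[rr[keep]],
        end = core_v[rr[keep]] + as.numeric(len_of[as.character(rr[keep])]),
        name = core_sub$class_label[keep], score = 0L,
        strand = core_sub$strand[keep], rgb = unname(colors[cc]),
        color_class = unname(cc), stringsAsFactors = FALSE)
    }
    slot <- per_genome_slots[[g]]
    for (key in names(slot)) {
      j <- as.integer(key)
      at <- if (j == 0L) 0 else core_v[j] + len_of[[as.character(j)]]
      ssub <- slot[[key]]
      for (i in seq_len(nrow(ssub))) {
        w <- ssub$end[i] - ssub$start[i]
        cc <- if (ssub$block_class[i] == "UNIQUE") "unique" else "dispensable"
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = "pan", start = at, end = at + w,
          name = ssub$class_label[i], score = 0L, strand = ssub$strand[i],
          rgb = unname(colors[cc]), color_class = cc, stringsAsFactors = FALSE)
        at <- at + w
      }
    }
    df <- do.call(rbind, rows)
    tracks[[g]] <- df[order(df$start, df$end), , drop = FALSE]
  }
  tracks[["consensus"]] <- data.frame(
    chrom = "pan", start = core_v,
    end = core_v + as.numeric(len_of[as.character(seq_len(m))]),
    name = vapply(cons$block_id, function(b) {
      btab <- blockTable(blockset)
      btab$class_label[match(b, btab$block_id)]
    }, character(1)),
    score = 0L, strand = ifelse(cons$orientation < 0, "-", "+"),
    rgb = unname(colors["core_collinear"]), color_class = "core_collinear",
    stringsAsFactors = FALSE)
  tracks
}

#' Write BED tracks for every genome plus the consensus
#'
#' Emits BED6+1 (chrom, start, end, name = class label, score, strand,
#' RGB color string) files, one per track. In \code{plain} mode
#' coordinates are each genome's native coordinates; in
#' \code{gap_aligned} mode all tracks share a virtual axis on which
#' every core block occupies the same interval in every genome
#' (vertical alignment), with the stretches between core blocks sized to
#' the largest D/U content across genomes.
#'
#' @param consensus a \code{\linkS4class{ConsensusOrdering}}.
#' @param blockset the classified \code{\linkS4class{PanBlockSet}}.
#' @param dir output directory (created if needed).
#' @param mode \code{"plain"} or \code{"gap_aligned"}.
#' @param rendering optional precomputed rendering table.
#' @param colors named RGB strings, see \code{\link{trackColors}}.
#' @return named character vector of written file paths, invisibly.
#' @export
writeBedTracks <- function(consensus, blockset, dir,
                           mode = c("plain", "gap_aligned"),
                           rendering = classifyCoreRendering(consensus),
                           colors = trackColors()) {
  mode <- match.arg(mode)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tracks <- if (mode == "plain")
    .plainRecords(consensus, blockset, rendering, colors)
  else .gapAlignedRecords(consensus, blockset, rendering, colors)
  paths <- character(0)
  for (tr in names(tracks)) {
    f <- file.path(dir, paste0(tr, ".bed"))
    df <- tracks[[tr]][, c("chrom", "start", "end", "name", "score",
                           "strand", "rgb")]
    df$start <- format(df$start, scientific = FALSE, trim = TRUE)
    df$end <- format(df$end, scientific = FALSE, trim = TRUE)
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    paths[tr] <- f
  }
  invisible(paths)
}

#' Read a BED6+1 track written by \code{\link{writeBedTracks}}
#' @param path BED file path
#' @return \code{data.frame} with the seven columns.
#' @export
readBedTrack <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand", "rgb"))
  df$start <- as.numeric(df$start); df$end <- as.numeric(df$end)
  df
}

#' Pass a GFF3 annotation through as a grey track (plain mode)
#'
#' Validates the GFF3 with rtracklayer and emits its features for one
#' genome as a grey BED6+1 track in native coordinates.
#'
#' @param gff_path GFF3 file.
#' @param genome_id the genome the annotation belongs to.
#' @param out BED output path.
#' @return \code{out}, invisibly.
#' @export
gffToGreyTrack <- function(gff_path, genome_id, out) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required for GFF3 pass-through")
  gr <- rtracklayer::import(gff_path, format = "gff3")
  nm <- S4Vectors::mcols(gr)$ID
  if (is.null(nm)) nm <- as.character(S4Vectors::mcols(gr)$type)
  nm[is.na(nm)] <- "feature"
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1L,
                   end = BiocGenerics::end(gr),
                   name = nm, score = 0L,
                   strand = sub("\\*", "+", as.character(BiocGenerics::strand(gr))),
                   rgb = trackColors()[["annotation"]],
                   stringsAsFactors = FALSE)
  utils::write.table(df, out, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(out)
}
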