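#' Run the full pan-genome pipeline
#'
#' Executes read, classify, genome block sequences, core permutations,
#' greedy consensus, refinement and track generation in one call, and
#' optionally writes the artifact directory: class summary TSV,
#' consensus TSV, BED track sets (plain, and gap-aligned on request),
#' dot-plot TSV and image, and a run log recording every resolved
#' parameter. Outputs are deterministic: running twice on the same
#' input yields byte-identical TSV/BED files.
#'
#' @param input path to the alignment (XMFA or backbone), or a
#'   \code{\linkS4class{PanBlockSet}}.
#' @param format \code{"xmfa"} or \code{"backbone"} (ignored when
#'   \code{input} is already a block set).
#' @param catalog a \code{\linkS4class{GenomeCatalog}} or a catalog file
#'   path (required when \code{input} is a file).
#' @param outdir optional output directory.
#' @param threshold_frac mis-join threshold in (0, 1], default 0.8.
#' @param signed signed symbol comparison in alignments/distances.
#' @param gap_aligned also emit gap-aligned BED tracks.
#' @param gff3 optional named character vector of GFF3 annotation files
#'   (names = genome ids) passed through as grey tracks.
#' @param dotplot_image emit a dot-plot image (\code{dotplot.png}) in
#'   \code{outdir}.
#' @return list with \code{blockset} (classified), \code{summary},
#'   \code{core_fraction}, \code{sequences}, \code{permutations},
#'   \code{consensus}, \code{rendering}, \code{dotplot} and
#'   \code{files} (written paths, if any).
#' @export
runPanGenome <- function(input, format = c("xmfa", "backbone"),
                         catalog = NULL, outdir = NULL, threshold_frac = 0.8,
                         signed = FALSE, gap_aligned = FALSE, gff3 = NULL,
                         dotplot_image = FALSE) {
  if (!is.numeric(threshold_frac) || threshold_frac <= 0 || threshold_frac > 1)
    stop("config error: threshold_frac must be in (0, 1]")
  if (is(input, "PanBlockSet")) {
    blockset <- input
  } else {
    format <- match.arg(format)
    if (is.character(catalog)) catalog <- readGenomeCatalog(catalog)
    if (is.null(catalog)) stop("config error: a genome catalog is required")
    blockset <- switch(format,
                       xmfa = readXMFA(input, catalog),
                       backbone = readBackbone(input, catalog))
  }
  blockset <- classifyBlocks(blockset)
  summary <- blockSummary(blockset)
  cf <- coreFraction(blockset)
  seqs <- genomeBlockSequences(blockset)
  perms <- corePermutations(seqs)
  consensus <- consensusOrdering(perms, threshold_frac = threshold_frac,
                                 signed = signed)
  rendering <- classifyCoreRendering(consensus)
  dots <- dotplotPoints(consensus, rendering)

  files <- character(0)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    f_sum <- file.path(outdir, "summary.tsv")
    sm <- summary
    sm$core_fraction_overall <- cf$overall
    utils::write.table(sm, f_sum, sep = "\t", quote = FALSE, row.names = FALSE)
    f_cons <- file.path(outdir, "consensus.tsv")
    writeConsensusTSV(consensus, f_cons)
    bed_plain <- writeBedTracks(consensus, blockset,
                                file.path(outdir, "bed_plain"), "plain",
                                rendering)
    files <- c(summary = f_sum, consensus = f_cons, bed_plain)
    if (gap_aligned) {
      bed_ga <- writeBedTracks(consensus, blockset,
                               file.path(outdir, "bed_gap_aligned"),
                               "gap_aligned", rendering)
      files <- c(files, bed_ga)
    }
    f_dots <- file.path(outdir, "dotplot.tsv")
    utils::write.table(dots, f_dots, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, dotplot = f_dots)
    if (dotplot_image) {
      f_img <- file.path(outdir, "dotplot.png")
      plotDotplot(dots, f_img)
      files <- c(files, dotplot_image = f_img)
    }
    if (!is.null(gff3)) {
      for (g in names(gff3)) {
        f_gff <- file.path(outdir, paste0(g, "_annotation.bed"))
        gffToGreyTrack(gff3[[g]], g, f_gff)
        files <- c(files, f_gff)
      }
    }
    f_log <- file.path(outdir, "run_log.txt")
    writeLines(c(
      sprintf("pancora %s", as.character(utils::packageVersion("pancora"))),
      sprintf("genomes: %d", nGenomes(blockset)),
      sprintf("blocks: %d", nBlocks(blockset)),
      sprintf("threshold_frac: %g", threshold_frac),
      sprintf("signed_edit: %s", signed),
      sprintf("gap_aligned: %s", gap_aligned),
      "seed_rule: lowest unassigned block id",
      "tie_rule: frequency ties broken by lower block id; orientation ties keep forward",
      "anchor_rule: median of per-genome best-alignment starts"),
      f_log)
    files <- c(files, log = f_log)
  }
  list(blockset = blockset, summary = summary, core_fraction = cf,
       sequences = seqs, permutations = perms, consensus = consensus,
       rendering = rendering, dotplot = dots, files = files)
}
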