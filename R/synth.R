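# Run code under a fixed seed without disturbing the caller's RNG state.
.withSeed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Configure a synthetic pan-genome scenario
#'
#' Describes a pan-genome with known truth: an ancestral ordering of
#' core and dispensable blocks, per-genome unique blocks, and planted
#' rearrangement events. Dispensable presence patterns are sampled
#' uniformly over subsets of 2..n-1 genomes; block lengths are uniform
#' in \code{block_length_range}. A fixed seed yields byte-identical
#' serialized fixtures.
#'
#' @param n_genomes number of genomes (>= 2; >= 3 if dispensable blocks
#'   are requested).
#' @param n_core number of core blocks.
#' @param n_dispensable number of dispensable blocks.
#' @param n_unique_per_genome unique blocks per genome.
#' @param block_length_range bp length range blocks are drawn from.
#' @param inversions list of \code{list(genome =, start_rank =, k =)}:
#'   reverse (and strand-flip) the span covering core consensus ranks
#'   \code{start_rank .. start_rank + k - 1} in that genome.
#' @param translocations list of \code{list(genome =, rank =, dest_rank =)}:
#'   move the core block of consensus rank \code{rank} next to the block
#'   of rank \code{dest_rank} in that genome (optionally
#'   \code{dest_seq =} for a cross-chromosome move).
#' @param shuffles list of \code{list(genomes =, start_rank =, k =)}:
#'   independently permute the core blocks of ranks
#'   \code{start_rank .. start_rank + k - 1} in the given genomes
#'   (\code{"all"} for every genome) - a planted highly variable region.
#' @param n_seqs chromosomes per genome (the ancestor is cut into
#'   contiguous chunks).
#' @param divergent \code{NULL}, or a list
#'   (\code{missing_core_frac}, \code{split_frac}, \code{extra_unique},
#'   \code{n_shuffle}) describing an added heavily diverged genome:
#'   it lacks a fraction of core blocks (demoting them), carries extra
#'   unique content and a heavily shuffled order, and a fraction of
#'   blocks is split in two in all genomes (alignment fragmentation).
#' @param seed RNG seed.
#' @return a \code{ScenarioConfig} (validated list).
#' @export
scenarioConfig <- function(n_genomes, n_core, n_dispensable = 0L,
                           n_unique_per_genome = 0L,
                           block_length_range = c(500L, 2000L),
                           inversions = list(), translocations = list(),
                           shuffles = list(), n_seqs = 1L, divergent = NULL,
                           seed = 1L) {
  cfg <- list(n_genomes = as.integer(n_genomes), n_core = as.integer(n_core),
              n_dispensable = as.integer(n_dispensable),
              n_unique_per_genome = as.integer(n_unique_per_genome),
              block_length_range = as.integer(block_length_range),
              inversions = inversions, translocations = translocations,
              shuffles = shuffles, n_seqs = as.integer(n_seqs),
              divergent = divergent, seed = as.integer(seed))
  if (cfg$n_genomes < 2L) stop("config error: need at least 2 genomes")
  if (cfg$n_dispensable > 0L && cfg$n_genomes < 3L)
    stop("config error: dispensable blocks need n >= 3")
  if (cfg$n_core < 1L) stop("config error: need at least 1 core block")
  if (cfg$n_seqs < 1L || cfg$n_seqs > cfg$n_core)
    stop("config error: n_seqs out of range")
  for (ev in cfg$inversions) {
    if (ev$genome < 1L || ev$genome > cfg$n_genomes ||
        ev$start_rank < 1L || ev$start_rank + ev$k - 1L > cfg$n_core)
      stop("config error: inversion event out of bounds")
  }
  for (ev in cfg$translocations) {
    if (ev$genome < 1L || ev$genome > cfg$n_genomes ||
        ev$rank < 1L || ev$rank > cfg$n_core ||
        ev$dest_rank < 1L || ev$dest_rank > cfg$n_core)
      stop("config error: translocation event out of bounds")
  }
  for (ev in cfg$shuffles) {
    if (ev$start_rank < 1L || ev$start_rank + ev$k - 1L > cfg$n_core)
      stop("config error: shuffle span out of bounds")
  }
  class(cfg) <- "ScenarioConfig"
  cfg
}

#' Generate a synthetic pan-genome with known truth
#'
#' Builds the ancestor block sequence, samples presence patterns
#' honoring the core/dispensable/unique definitions, applies the planted
#' events per genome, lays out non-overlapping bp coordinates, and
#' returns the block set together with a truth table.
#'
#' @param config a \code{\link{scenarioConfig}}.
#' @return a \code{PanScenario}: list with \code{blockset} (an
#'   unclassified \code{\linkS4class{PanBlockSet}}), \code{catalog},
#'   \code{truth} (list: \code{blocks} with true classes and lengths,
#'   \code{ranks} with per-genome core order and strand,
#'   \code{consensus} = planted signed core ordering, \code{events}) and
#'   \code{config}.
#' @examples
#' scn <- generateScenario(scenarioConfig(4, 10, 3, 1, seed = 7))
#' table(scn$truth$blocks$class)
#' @export
generateScenario <- function(config) {
  stopifnot(inherits(config, "ScenarioConfig"))
  .withSeed(config$seed, .generateScenario(config))
}

.generateScenario <- function(cfg) {
  n <- cfg$n_genomes
  core_ids <- seq_len(cfg$n_core)
  anc_core <- sample(core_ids)            # planted consensus ordering
  disp_ids <- if (cfg$n_dispensable) cfg$n_core + seq_len(cfg$n_dispensable)
              else integer(0)
  next_id <- cfg$n_core + cfg$n_dispensable

  # ancestor: core blocks in consensus order, dispensables interleaved
  anc <- anc_core
  for (d in disp_ids) {
    pos <- sample(0:length(anc), 1L)
    anc <- append(anc, d, after = pos)
  }
  presence <- list()
  for (b in core_ids) presence[[b]] <- seq_len(n)
  for (d in disp_ids)
    presence[[d]] <- sort(sample(seq_len(n), sample(2:(n - 1L), 1L)))

  # chromosome assignment: contiguous ancestor chunks
  chunk <- if (cfg$n_seqs == 1L) rep(1L, length(anc))
           else as.integer(cut(seq_along(anc), breaks = cfg$n_seqs,
                               labels = FALSE))
  chrom_of <- integer(next_id)
  chrom_of[anc] <- chunk

  # per genome, per chromosome: ordered data.frame(block_id, strand)
  genomes <- vector("list", n)
  uniq_of <- list()
  for (g in seq_len(n)) {
    chroms <- vector("list", cfg$n_seqs)
    for (cix in seq_len(cfg$n_seqs)) {
      ids <- anc[chunk == cix]
      ids <- ids[vapply(ids, function(b) g %in% presence[[b]], logical(1))]
      chroms[[cix]] <- data.frame(block_id = ids, strand = "+",
                                  stringsAsFactors = FALSE)
    }
    # unique blocks
    uq <- integer(0)
    for (u in seq_len(cfg$n_unique_per_genome)) {
      next_id <- next_id + 1L
      uq <- c(uq, next_id)
      presence[[next_id]] <- g
      cix <- sample(cfg$n_seqs, 1L)
      chrom_of[next_id] <- cix
      df <- chroms[[cix]]
      pos <- sample(0:nrow(df), 1L)
      chroms[[cix]] <- rbind(df[seq_len(pos), , drop = FALSE],
                             data.frame(block_id = next_id, strand = "+"),
                             df[seq_len(nrow(df)) > pos, , drop = FALSE])
    }
    uniq_of[[g]] <- uq
    genomes[[g]] <- chroms
  }

  rank_block <- function(r) anc_core[r]
  # planted events
  for (ev in cfg$inversions) {
    g <- ev$genome
    ids <- rank_block(ev$start_rank:(ev$start_rank + ev$k - 1L))
    cix <- chrom_of[ids[1L]]
    if (any(chrom_of[ids] != cix)) stop("config error: inversion spans chromosomes")
    df <- genomes[[g]][[cix]]
    p <- which(df$block_id %in% ids)
    span <- min(p):max(p)
    seg <- df[rev(span), , drop = FALSE]
    seg$strand <- ifelse(seg$strand == "+", "-", "+")
    df[span, ] <- seg
    genomes[[g]][[cix]] <- df
  }
  for (ev in cfg$translocations) {
    g <- ev$genome
    b <- rank_block(ev$rank); dest <- rank_block(ev$dest_rank)
    src_c <- chrom_of[b]
    dst_c <- if (!is.null(ev$dest_seq)) as.integer(ev$dest_seq) else chrom_of[dest]
    df <- genomes[[g]][[src_c]]
    row <- df[df$block_id == b, , drop = FALSE]
    genomes[[g]][[src_c]] <- df[df$block_id != b, , drop = FALSE]
    dd <- genomes[[g]][[dst_c]]
    pos <- which(dd$block_id == dest)
    if (length(pos) == 0L) pos <- nrow(dd)
    genomes[[g]][[dst_c]] <- rbind(dd[seq_len(pos), , drop = FALSE], row,
                                   dd[seq_len(nrow(dd)) > pos, , drop = FALSE])
  }
  for (ev in cfg$shuffles) {
    gs <- if (identical(ev$genomes, "all")) seq_len(n) else ev$genomes
    ids <- rank_block(ev$start_rank:(ev$start_rank + ev$k - 1L))
    for (g in gs) {
      cix <- chrom_of[ids[1L]]
      df <- genomes[[g]][[cix]]
      p <- which(df$block_id %in% ids)
      df[p, ] <- df[p[sample(length(p))], , drop = FALSE]
      genomes[[g]][[cix]] <- df
    }
  }

  # block lengths (shared across genomes)
  lens <- integer(next_id)
  lens[seq_len(next_id)] <- sample(cfg$block_length_range[1]:cfg$block_length_range[2],
                                   next_id, replace = TRUE)

  # optional divergent added genome + alignment fragmentation
  split_twin <- integer(0)
  if (!is.null(cfg$divergent)) {
    dv <- cfg$divergent
    n <- n + 1L
    # the new genome misses part of the core (demoting those blocks)
    missing <- sort(sample(core_ids, max(1L, round(dv$missing_core_frac *
                                                   cfg$n_core))))
    keep_core <- setdiff(core_ids, missing)
    for (b in keep_core) presence[[b]] <- c(presence[[b]], n)
    disp_in <- disp_ids[stats::runif(length(disp_ids)) < 0.4]
    for (d in disp_in) presence[[d]] <- sort(c(presence[[d]], n))
    chroms <- vector("list", cfg$n_seqs)
    for (cix in seq_len(cfg$n_seqs)) {
      ids <- anc[chunk == cix]
      ids <- ids[vapply(ids, function(b) n %in% presence[[b]], logical(1))]
      chroms[[cix]] <- data.frame(block_id = ids, strand = "+",
                                  stringsAsFactors = FALSE)
    }
    for (u in seq_len(dv$extra_unique)) {
      next_id <- next_id + 1L
      presence[[next_id]] <- n
      lens[next_id] <- sample(cfg$block_length_range[1]:cfg$block_length_range[2], 1L)
      cix <- sample(cfg$n_seqs, 1L)
      chrom_of[next_id] <- cix
      df <- chroms[[cix]]
      pos <- sample(0:nrow(df), 1L)
      chroms[[cix]] <- rbind(df[seq_len(pos), , drop = FALSE],
                             data.frame(block_id = next_id, strand = "+"),
                             df[seq_len(nrow(df)) > pos, , drop = FALSE])
    }
    # heavy shuffling of the new genome
    for (s in seq_len(dv$n_shuffle)) {
      cix <- sample(cfg$n_seqs, 1L)
      df <- chroms[[cix]]
      if (nrow(df) >= 6L) {
        w <- sample(4:min(10L, nrow(df)), 1L)
        at <- sample(nrow(df) - w + 1L, 1L)
        p <- at:(at + w - 1L)
        df[p, ] <- df[p[sample(w)], , drop = FALSE]
        chroms[[cix]] <- df
      }
    }
    genomes[[n]] <- chroms
    uniq_of[[n]] <- integer(0)
    # fragmentation: split a fraction of blocks in two, in every genome
    to_split <- sort(sample(c(core_ids, disp_ids),
                            max(1L, round(dv$split_frac *
                                          (cfg$n_core + cfg$n_dispensable)))))
    for (b in to_split) {
      next_id <- next_id + 1L
      twin <- next_id
      split_twin[as.character(b)] <- twin
      presence[[twin]] <- presence[[b]]
      chrom_of[twin] <- chrom_of[b]
      l1 <- lens[b] %/% 2L
      lens[twin] <- lens[b] - l1
      lens[b] <- l1
      for (g in seq_len(n)) {
        for (cix in seq_along(genomes[[g]])) {
          df <- genomes[[g]][[cix]]
          p <- which(df$block_id == b)
          if (length(p)) {
            tw <- data.frame(block_id = twin, strand = df$strand[p],
                             stringsAsFactors = FALSE)
            at <- if (df$strand[p] == "+") p else p - 1L
            genomes[[g]][[cix]] <- rbind(df[seq_len(at), , drop = FALSE], tw,
                                         df[seq_len(nrow(df)) > at, , drop = FALSE])
          }
        }
      }
    }
  }

  # bp layout, catalog, intervals
  gids <- paste0("g", seq_len(n))
  cat_rows <- list(); iv_rows <- list()
  for (g in seq_len(n)) {
    for (cix in seq_len(cfg$n_seqs)) {
      df <- genomes[[g]][[cix]]
      gaps <- sample(20:100, nrow(df) + 1L, replace = TRUE)
      off <- gaps[1L]
      if (nrow(df)) {
        bl <- lens[df$block_id]
        starts <- gaps[1L] + c(0L, cumsum(bl + gaps[2:(nrow(df) + 1L)]))[seq_len(nrow(df))]
        ends <- starts + bl
        off <- ends[nrow(df)] + gaps[nrow(df) + 1L]
        iv_rows[[length(iv_rows) + 1L]] <- data.frame(
          block_id = df$block_id, genome_id = gids[g],
          seq_name = paste0("chr", cix), start = starts, end = ends,
          strand = df$strand, stringsAsFactors = FALSE)
      }
      cat_rows[[length(cat_rows) + 1L]] <- data.frame(
        genome_id = gids[g], seq_name = paste0("chr", cix),
        seq_length = off + 50L, stringsAsFactors = FALSE)
    }
  }
  cat_df <- do.call(rbind, cat_rows)
  catalog <- GenomeCatalog(cat_df$genome_id, cat_df$seq_name, cat_df$seq_length)
  iv <- do.call(rbind, iv_rows)
  blockset <- PanBlockSet(iv, catalog)

  # truth
  all_ids <- seq_len(next_id)
  pres_n <- vapply(all_ids, function(b) length(presence[[b]]), integer(1))
  true_class <- ifelse(pres_n == n, "CORE",
                       ifelse(pres_n == 1L, "UNIQUE", "DISPENSABLE"))
  truth_blocks <- data.frame(block_id = all_ids, class = true_class,
                             length = lens[all_ids], n_present = pres_n,
                             stringsAsFactors = FALSE)
  final_core <- all_ids[true_class == "CORE"]
  consensus <- integer(0)
  for (b in anc_core) {
    if (b %in% final_core) consensus <- c(consensus, b)
    tw <- split_twin[as.character(b)]
    if (!is.na(tw) && length(tw) && tw %in% final_core)
      consensus <- c(consensus, tw)
  }
  rank_rows <- list()
  for (g in seq_len(n)) {
    ord <- do.call(rbind, genomes[[g]])
    ord <- ord[ord$block_id %in% final_core, , drop = FALSE]
    if (nrow(ord))
      rank_rows[[g]] <- data.frame(genome_id = gids[g],
                                   block_id = ord$block_id,
                                   rank = seq_len(nrow(ord)),
                                   strand = ord$strand,
                                   stringsAsFactors = FALSE)
  }
  truth <- list(blocks = truth_blocks,
                ranks = do.call(rbind, rank_rows),
                consensus = consensus,
                events = list(inversions = cfg$inversions,
                              translocations = cfg$translocations,
                              shuffles = cfg$shuffles),
                consensus_rank_blocks = anc_core)
  out <- list(config = cfg, catalog = catalog, blockset = blockset,
              truth = truth)
  class(out) <- "PanScenario"
  out
}

#' Named preset scenario configurations
#'
#' Desk-scale presets reproducing the qualitative regimes seen in real
#' pan-genomes: \code{"collinear"} (closely related assemblies, a single
#' consistent consensus), \code{"inversion"} (one large planted
#' inversion in one genome), \code{"translocation"} (several isolated
#' core-block moves), \code{"variable"} (a highly variable region that
#' fragments the greedy ordering).
#'
#' @param name preset name.
#' @param seed RNG seed.
#' @return a \code{\link{scenarioConfig}}.
#' @export
presetScenario <- function(name = c("collinear", "inversion", "translocation",
                                    "variable"),
                           seed = 1L) {
  name <- match.arg(name)
  base <- list(n_genomes = 4L, n_core = 40L, n_dispensable = 12L,
               n_unique_per_genome = 4L, seed = seed)
  args <- switch(name,
    collinear = base,
    inversion = c(base, list(inversions = list(list(genome = 2L,
                                                    start_rank = 12L, k = 6L)))),
    translocation = c(base, list(translocations = list(
      list(genome = 3L, rank = 5L, dest_rank = 25L),
      list(genome = 3L, rank = 12L, dest_rank = 36L)))),
    variable = c(base, list(shuffles = list(list(genomes = "all",
                                                 start_rank = 15L, k = 8L)))))
  do.call(scenarioConfig, args)
}

#' Generate a preset scenario with and without a divergent genome
#'
#' Returns the same base pan-genome twice: once as-is and once with a
#' heavily diverged extra genome added (missing core content, extra
#' unique blocks, shuffled order) and the accompanying alignment
#' fragmentation (block splits). Mirrors the effect of introducing a
#' wild relative into a cultivated panel: more blocks of every type,
#' smaller core fraction.
#'
#' @param seed RNG seed.
#' @param n_genomes,n_core,n_dispensable,n_unique_per_genome base panel
#'   dimensions.
#' @return list with \code{base} and \code{extended} \code{PanScenario}s.
#' @export
divergentPair <- function(seed = 1L, n_genomes = 4L, n_core = 40L,
                          n_dispensable = 12L, n_unique_per_genome = 4L) {
  cfg <- scenarioConfig(n_genomes, n_core, n_dispensable,
                        n_unique_per_genome, seed = seed)
  dv <- list(missing_core_frac = 0.25, split_frac = 0.25,
             extra_unique = 3L * n_unique_per_genome, n_shuffle = 3L)
  cfg2 <- scenarioConfig(n_genomes, n_core, n_dispensable,
                         n_unique_per_genome, divergent = dv, seed = seed)
  list(base = generateScenario(cfg), extended = generateScenario(cfg2))
}

#' Serialize a scenario as fixture files
#'
#' Writes the XMFA alignment, the backbone table (single-chromosome
#' catalogs only), the genome catalog (TSV) and the truth tables into a
#' directory.
#'
#' @param scenario a \code{PanScenario}.
#' @param dir output directory.
#' @return named vector of file paths, invisibly.
#' @export
writeScenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(xmfa = file.path(dir, "alignment.xmfa"),
             catalog = file.path(dir, "catalog.tsv"),
             truth_blocks = file.path(dir, "truth_blocks.tsv"),
             truth_ranks = file.path(dir, "truth_ranks.tsv"))
  writeXMFA(scenario$blockset, paths["xmfa"])
  writeGenomeCatalog(scenario$catalog, paths["catalog"])
  utils::write.table(scenario$truth$blocks, paths["truth_blocks"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(scenario$truth$ranks, paths["truth_ranks"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (scenario$config$n_seqs == 1L) {
    paths["backbone"] <- file.path(dir, "alignment.backbone")
    writeBackbone(scenario$blockset, paths["backbone"])
  }
  invisible(paths)
}
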