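test_that("a genome identical to the consensus renders fully collinear", {
  scn <- generateScenario(presetScenario("collinear", seed = 14L))
  res <- runPanGenome(scn$blockset)
  expect_true(all(res$rendering$color_class == "core_collinear"))
  # color partition: exactly one class per (genome, core block)
  expect_equal(nrow(res$rendering),
               nrow(unique(res$rendering[c("genome_id", "block_id")])))
  expect_equal(nrow(res$rendering), 4L * 40L)
})

test_that("a planted inversion renders exactly its k blocks as inverted", {
  scn <- generateScenario(presetScenario("inversion", seed = 5L))
  res <- runPanGenome(scn$blockset)
  rend <- res$rendering
  inv <- rend[rend$color_class == "core_inverted", ]
  expect_equal(unique(inv$genome_id), "g2")
  expect_equal(nrow(inv), 6L)
  planted <- scn$truth$consensus_rank_blocks[12:17]
  expect_setequal(inv$block_id, planted)
  # dot-plot: the inverted blocks form an anti-diagonal run
  d <- res$dotplot[res$dotplot$genome_id == "g2", ]
  d <- d[order(d$consensus_x), ]
  run <- which(d$mark == "inverted")
  expect_equal(run, seq(min(run), max(run)))     # contiguous in x
  expect_true(all(diff(d$genome_y[run]) < 0))    # decreasing in y
})

test_that("planted translocations render as isolated translocated blocks", {
  scn <- generateScenario(presetScenario("translocation", seed = 6L))
  res <- runPanGenome(scn$blockset)
  rend <- res$rendering
  tra <- rend[rend$color_class == "core_translocated", ]
  expect_equal(unique(tra$genome_id), "g3")
  planted <- scn$truth$consensus_rank_blocks[c(5L, 12L)]
  expect_setequal(tra$block_id, planted)
  expect_true(all(rend$color_class[rend$genome_id != "g3"] ==
                    "core_collinear"))
})

test_that("a cross-chromosome move renders as a translocation", {
  cfg <- scenarioConfig(4L, 30L, 0L, 0L, n_seqs = 2L,
                        translocations = list(list(genome = 2L, rank = 3L,
                                                   dest_rank = 25L,
                                                   dest_seq = 2L)),
                        seed = 13L)
  scn <- generateScenario(cfg)
  res <- runPanGenome(scn$blockset)
  moved <- scn$truth$consensus_rank_blocks[3L]
  rend <- res$rendering
  hit <- rend[rend$block_id == moved & rend$genome_id == "g2", ]
  expect_equal(hit$color_class, "core_translocated")
  expect_true(all(rend$color_class[rend$genome_id != "g2"] ==
                    "core_collinear"))
})

test_that("plain BED tracks round-trip and carry the legend colors", {
  scn <- generateScenario(presetScenario("inversion", seed = 5L))
  res <- runPanGenome(scn$blockset)
  d <- withr::local_tempdir()
  paths <- writeBedTracks(res$consensus, res$blockset, d, "plain",
                          res$rendering)
  expect_true(all(file.exists(paths)))
  g2 <- readBedTrack(paths[["g2"]])
  expect_equal(sum(g2$rgb == trackColors()[["core_inverted"]]), 6L)
  expect_equal(sum(grepl("^D", g2$name)),
               sum(g2$rgb == trackColors()[["dispensable"]]))
  expect_equal(sum(grepl("^U", g2$name)),
               sum(g2$rgb == trackColors()[["unique"]]))
  # round-trip: coordinates and fields survive a parse
  tab <- genomeBlockSequences(res$blockset)$g2
  expect_equal(g2$start, tab$start)
  expect_equal(g2$end, tab$end)
  expect_equal(g2$strand, tab$strand)
})

test_that("gap-aligned tracks align every core block vertically", {
  for (preset in c("collinear", "inversion")) {
    scn <- generateScenario(presetScenario(preset, seed = 22L))
    res <- runPanGenome(scn$blockset)
    d <- withr::local_tempdir()
    paths <- writeBedTracks(res$consensus, res$blockset, d, "gap_aligned",
                            res$rendering)
    tracks <- lapply(paths, readBedTrack)
    cons <- tracks[["consensus"]]
    for (g in setdiff(names(tracks), "consensus")) {
      core <- tracks[[g]][grepl("^C", tracks[[g]]$name), ]
      m <- merge(cons, core, by = "name")
      expect_equal(nrow(m), nrow(cons))         # every core block present
      expect_equal(m$start.x, m$start.y)        # identical span everywhere
      expect_equal(m$end.x, m$end.y)
    }
    # D/U records never overlap core slots within a track
    for (g in setdiff(names(tracks), "consensus")) {
      tr <- tracks[[g]][order(tracks[[g]]$start), ]
      expect_true(all(tr$start[-1L] >= tr$end[-nrow(tr)] - 1e-9))
    }
  }
})

test_that("dot-plot has one point per (genome, core block) with stagger", {
  scn <- generateScenario(presetScenario("collinear", seed = 2L))
  res <- runPanGenome(scn$blockset)
  dots <- res$dotplot
  expect_equal(nrow(dots), 4L * 40L)
  expect_equal(nrow(unique(dots[c("genome_id", "block_id")])), 4L * 40L)
  p <- plotDotplot(dots)
  expect_s3_class(p, "ggplot")
})
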