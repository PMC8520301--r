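test_that("XMFA headers convert 1-based inclusive to 0-based half-open", {
  cat2 <- GenomeCatalog(c("gA", "gB"), c("chr1", "chr1"), c(1000L, 1000L))
  f <- withr::local_tempfile(fileext = ".xmfa")
  writeLines(c(">1:101-200 +", strrep("A", 100), ">2:51-60 -",
               strrep("A", 10), "="), f)
  bs <- readXMFA(f, cat2)
  tab <- blockTable(bs)
  expect_equal(nrow(tab), 2L)
  a <- tab[tab$genome_id == "gA", ]
  expect_equal(c(a$start, a$end), c(100, 200))
  expect_equal(a$strand, "+")
  b <- tab[tab$genome_id == "gB", ]
  expect_equal(c(b$start, b$end), c(50, 60))
  expect_equal(b$strand, "-")
  # length preserved: 1-based [101,200] has 100 bp, as does [100,200)
  expect_equal(a$end - a$start, 100)
})

test_that("an XMFA group yields one block with one interval per present genome", {
  cat4 <- tinyCatalog(4L)
  f <- withr::local_tempfile(fileext = ".xmfa")
  writeLines(c(">1:1-10 +", "AAAAAAAAAA", ">2:1-10 +", "AAAAAAAAAA",
               ">4:21-30 -", "AAAAAAAAAA", "=",
               ">3:1-5 +", "AAAAA", ">1:101-105 +", "AAAAA", "="), f)
  bs <- readXMFA(f, cat4)
  tab <- blockTable(bs)
  expect_equal(sum(tab$block_id == 1L), 3L)
  expect_equal(sum(tab$block_id == 2L), 2L)
  # zero-length absent-genome entries are dropped
  f2 <- withr::local_tempfile(fileext = ".xmfa")
  writeLines(c(">1:1-10 +", "AAAAAAAAAA", ">2:0-0 +", "-", "="), f2)
  expect_equal(nrow(blockTable(readXMFA(f2, cat4))), 1L)
})

test_that("XMFA reader rejects malformed input with informative errors", {
  cat2 <- tinyCatalog(2L)
  f <- withr::local_tempfile(fileext = ".xmfa")
  writeLines(c(">not a header", "AAAA", "="), f)
  expect_error(readXMFA(f, cat2), "parse error.*line 1")
  writeLines(c(">7:1-10 +", "AAAAAAAAAA", "="), f)
  expect_error(readXMFA(f, cat2), "catalog error")
  writeLines(c(">1:20-10 +", "AAAA", "="), f)
  expect_error(readXMFA(f, cat2), "coordinate error")
})

test_that("writeXMFA emits placeholder payload of the ungapped length", {
  cat1 <- GenomeCatalog("gA", "chr1", 1000L)
  bs <- PanBlockSet(ivRow(1L, "gA", 10L, 15L), cat1)
  f <- withr::local_tempfile(fileext = ".xmfa")
  writeXMFA(bs, f)
  lines <- readLines(f)
  hdr <- grep("^>", lines)
  expect_length(hdr, 1L)
  expect_match(lines[hdr], "^>1:11-15 \\+$")
  expect_equal(nchar(lines[hdr + 1L]), 5L)
  # empty block set round-trips to an empty set
  bs0 <- PanBlockSet(ivRow(1L, "gA", 10L, 15L)[0, ], cat1)
  writeXMFA(bs0, f)
  expect_equal(nBlocks(readXMFA(f, cat1)), 0L)
  # out-of-bounds interval is refused at the constructor
  expect_error(PanBlockSet(ivRow(1L, "gA", 990L, 1200L), cat1), "bounds")
})

test_that("XMFA write -> read is the identity on block sets", {
  for (s in c(2L, 11L, 23L)) {
    scn <- generateScenario(scenarioConfig(4L, 15L, 8L, 2L,
                                           n_seqs = if (s %% 2) 1L else 2L,
                                           seed = s))
    f <- withr::local_tempfile(fileext = ".xmfa")
    writeXMFA(scn$blockset, f)
    expect_identical(blockKey(readXMFA(f, scn$catalog)),
                     blockKey(scn$blockset))
  }
})

test_that("backbone rows follow the sign and absence conventions", {
  cat3 <- tinyCatalog(3L)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("seq0_leftend", "seq0_rightend", "seq1_leftend",
                       "seq1_rightend", "seq2_leftend", "seq2_rightend"),
                     collapse = "\t"),
               "500\t700\t-900\t-800\t0\t0"), f)
  bs <- readBackbone(f, cat3)
  tab <- blockTable(bs)
  expect_equal(nrow(tab), 2L)
  g1 <- tab[tab$genome_id == "g1", ]
  expect_equal(c(g1$start, g1$end), c(499, 700))
  expect_equal(g1$strand, "+")
  g2 <- tab[tab$genome_id == "g2", ]
  expect_equal(c(g2$start, g2$end), c(799, 900))
  expect_equal(g2$strand, "-")
})

test_that("backbone reader rejects degenerate rows and bad shapes", {
  cat3 <- tinyCatalog(3L)
  f <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste(c("seq0_leftend", "seq0_rightend", "seq1_leftend",
                 "seq1_rightend", "seq2_leftend", "seq2_rightend"),
               collapse = "\t")
  writeLines(c(hdr, "0\t0\t0\t0\t0\t0"), f)
  expect_error(readBackbone(f, cat3), "all-zero")
  writeLines(c(hdr, "700\t500\t0\t0\t0\t0"), f)
  expect_error(readBackbone(f, cat3), "coordinate error")
  writeLines(c("seq0_leftend\tseq0_rightend", "1\t10"), f)
  expect_error(readBackbone(f, cat3), "format error")
})

test_that("backbone write -> read reproduces the generated truth", {
  for (s in c(3L, 17L)) {
    scn <- generateScenario(scenarioConfig(4L, 20L, 10L, 2L, seed = s))
    f <- withr::local_tempfile(fileext = ".tsv")
    writeBackbone(scn$blockset, f)
    bs <- readBackbone(f, scn$catalog)
    expect_identical(blockKey(bs), blockKey(scn$blockset))
    # and classification of the re-parsed set matches the planted truth
    expect_equal(unname(table(blockClasses(classifyBlocks(bs)))[
                   c("CORE", "DISPENSABLE", "UNIQUE")]),
                 unname(table(scn$truth$blocks$class)[
                   c("CORE", "DISPENSABLE", "UNIQUE")]))
  }
})

test_that("a block listing the same genome twice is rejected", {
  cat2 <- tinyCatalog(2L)
  df <- rbind(ivRow(1L, "g1", 0L, 10L), ivRow(1L, "g1", 20L, 30L))
  expect_error(PanBlockSet(df, cat2), "more than once")
})

test_that("genome catalogs round-trip through TSV and load from YAML", {
  cat3 <- GenomeCatalog(c("gA", "gA", "gB"), c("chr1", "chr2", "chr1"),
                        c(5000L, 4000L, 6000L))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeGenomeCatalog(cat3, f)
  cat3b <- readGenomeCatalog(f)
  expect_equal(genomeIds(cat3b), c("gA", "gB"))
  expect_equal(seqLengths(cat3b, "gA"), c(chr1 = 5000L, chr2 = 4000L))
  fy <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("- genome_id: gA", "  sequences:", "    chr1: 5000",
               "    chr2: 4000", "- genome_id: gB", "  sequences:",
               "    chr1: 6000"), fy)
  expect_equal(seqLengths(readGenomeCatalog(fy), "gA"),
               c(chr1 = 5000L, chr2 = 4000L))
})
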