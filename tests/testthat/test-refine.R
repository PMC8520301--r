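test_that("local alignment scores +1 per match and -1 per gap or mismatch", {
  expect_equal(localAlignBlocks(c(1, 2, 3), c(1, 2, 3))$score, 3L)
  expect_equal(localAlignBlocks(c(1, 2, 3), c(3, 2, 1))$score, 1L)
  al <- localAlignBlocks(integer(0), c(1, 2))
  expect_equal(al$score, 0L)
  expect_equal(al$path_span, c(0L, 0L))
  # spans bracket the aligned region
  al2 <- localAlignBlocks(c(9, 1, 2, 3, 8), c(7, 7, 1, 2, 3))
  expect_equal(al2$score, 3L)
  expect_equal(al2$path_span, c(2L, 4L))
  expect_equal(al2$perm_span, c(3L, 5L))
})

test_that("local alignment agrees with the exhaustive oracle on short pairs", {
  set.seed(77)
  for (i in 1:200) {
    a <- sample(1:4, sample(1:6, 1), replace = TRUE)
    b <- sample(1:4, sample(1:6, 1), replace = TRUE)
    expect_equal(localAlignBlocks(a, b)$score, exhaustiveLocalAlign(a, b))
  }
})

test_that("path orientation follows the higher summed score and is idempotent", {
  perms <- corePermutationList(list(1:5, 1:5, 1:5))
  o <- orientPath(-(5:1), perms)
  expect_true(o$reversed)
  expect_equal(o$ids, 1:5)
  # tie on a palindromic single block keeps forward
  o1 <- orientPath(1L, perms)
  expect_false(o1$reversed)
  # idempotence over random paths
  set.seed(5)
  for (i in 1:20) {
    p <- sample(5) * sample(c(-1L, 1L), 5, replace = TRUE)
    once <- orientPath(p, perms)$ids
    expect_equal(orientPath(once, perms)$ids, once)
  }
})

test_that("planted path orientations are recovered on collinear inputs", {
  set.seed(11)
  for (i in 1:25) {
    base <- sample(40L)
    perms <- corePermutationList(lapply(1:4, function(g) base))
    at <- sample(30L, 1); len <- sample(3:8, 1)
    sub <- base[at:(at + len - 1L)]
    flip <- stats::runif(1) < 0.5
    p <- if (flip) -rev(sub) else sub
    o <- orientPath(p, perms)
    expect_equal(o$ids, sub)
    expect_equal(o$reversed, flip)
  }
})

test_that("collinear paths pass the score threshold untouched", {
  perms <- corePermutationList(list(1:6, 1:6, 1:6))
  expect_identical(splitMisjoins(1:6, perms), list(1:6))
  expect_error(splitMisjoins(1:6, perms, threshold_frac = 1.5), "config error")
  expect_error(splitMisjoins(1:6, perms, threshold_frac = 0), "config error")
})

test_that("chimeric paths are cut at the planted junction and conserve blocks", {
  set.seed(99)
  for (s in 1:20) {
    inst <- chimericInstance(s + 400L)
    pieces <- splitMisjoins(inst$path, inst$perms)
    expect_equal(sort(unlist(pieces)), sort(inst$path))  # conservation
    expect_length(pieces, 2L)
    expect_equal(pieces[[1L]], inst$run_a)
    expect_equal(pieces[[2L]], inst$run_b)
  }
})

test_that("a full-span central region is finalized rather than looping", {
  # path matching one genome exactly but scoring badly overall
  perms <- corePermutationList(list(c(5, 4, 3, 2, 1), 1:5, 1:5, 1:5))
  p <- splitMisjoins(c(5L, 4L, 3L, 2L, 1L), perms)
  expect_equal(sort(unlist(p)), 1:5)
})

test_that("paths are ordered by their majority-vote anchors", {
  perms <- corePermutationList(list(1:6, 1:6, 1:6))
  co <- assignCoordinates(list(c(4L, 5L, 6L), c(1L, 2L, 3L)), perms)
  expect_equal(consensusBlocks(co)$block_id, 1:6)
  expect_true(all(diff(consensusBlocks(co)$consensus_start) > 0))
  # median anchor is robust to a single outlier placement
  p3 <- list(
    list(genome = "g1", seq = "chr1", ids = c(7L, 1L, 2L),
         start = c(100, 200, 300), end = c(150, 250, 350)),
    list(genome = "g2", seq = "chr1", ids = c(7L, 1L, 2L),
         start = c(100, 200, 300), end = c(150, 250, 350)),
    list(genome = "g3", seq = "chr1", ids = c(1L, 2L, 7L),
         start = c(900, 1000, 1100), end = c(950, 1050, 1150)))
  class(p3) <- "CorePermutationList"
  co2 <- assignCoordinates(list(c(1L, 2L), 7L), p3)
  # anchors: path [1,2] -> median(200, 200, 900) = 200; path [7] ->
  # median(100, 100, 1100) = 100, so [7] comes first
  expect_equal(consensusBlocks(co2)$block_id, c(7L, 1L, 2L))
})

test_that("consensus block lengths are the median occurrence lengths", {
  p <- lapply(1:3, function(g)
    list(genome = paste0("g", g), seq = "chr1", ids = c(1L, 2L),
         start = c(0, 5000), end = c(0 + 100 * g, 5000 + 400)))
  class(p) <- "CorePermutationList"
  co <- assignCoordinates(list(c(1L, 2L)), p)
  b <- consensusBlocks(co)
  expect_equal(b$length[b$block_id == 1L], 200)  # median(100, 200, 300)
  expect_equal(b$length[b$block_id == 2L], 400)
})

test_that("rearrangement-free pan-genomes collapse to the shared permutation", {
  for (s in c(7L, 19L)) {
    scn <- generateScenario(presetScenario("collinear", seed = s))
    perms <- corePermutations(classifyBlocks(scn$blockset))
    co <- consensusOrdering(perms)
    expect_length(consensusPaths(co), 1L)
    ids <- unlist(consensusPaths(co))
    expect_equal(sumEditDistance(ids, perms), 0L)
    expect_true(identical(abs(ids), scn$truth$consensus) ||
                  identical(rev(abs(ids)), scn$truth$consensus))
    # every genome's dot-plot is its own monotone diagonal
    dots <- dotplotPoints(co)
    for (g in unique(dots$genome_id)) {
      d <- dots[dots$genome_id == g, ]
      d <- d[order(d$consensus_x), ]
      expect_true(all(diff(d$genome_y) > 0) || all(diff(d$genome_y) < 0))
    }
  }
})
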