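test_that("blocks partition into core, dispensable and unique by genome count", {
  n <- 5L
  cat5 <- tinyCatalog(n)
  mk <- function(block, genomes, at) {
    do.call(rbind, lapply(seq_along(genomes), function(i)
      ivRow(block, genomes[i], at, at + 50L)))
  }
  df <- rbind(mk(1L, paste0("g", 1:5), 0L),     # all n -> CORE
              mk(2L, "g1", 100L),               # exactly 1 -> UNIQUE
              mk(3L, paste0("g", 1:2), 200L),   # 2 -> DISPENSABLE
              mk(4L, paste0("g", 1:3), 300L),   # 3 -> DISPENSABLE
              mk(5L, paste0("g", 1:4), 400L))   # n-1 -> DISPENSABLE
  bs <- classifyBlocks(PanBlockSet(df, cat5))
  cl <- blockClasses(bs)
  expect_equal(unname(cl[as.character(1:5)]),
               c("CORE", "UNIQUE", "DISPENSABLE", "DISPENSABLE", "DISPENSABLE"))
  tab <- blockTable(bs)
  lab <- tab$class_label[!duplicated(tab$block_id)][order(tab$block_id[!duplicated(tab$block_id)])]
  expect_equal(lab, c("C1", "U1", "D1", "D2", "D3"))
})

test_that("class partition matches a brute-force recount on random scenarios", {
  for (s in c(5L, 31L)) {
    scn <- generateScenario(scenarioConfig(5L, 25L, 15L, 3L, seed = s))
    bs <- classifyBlocks(scn$blockset)
    tab <- blockTable(bs)
    mult <- table(tab$block_id)
    brute <- as.vector(ifelse(mult == 5L, "CORE",
                              ifelse(mult == 1L, "UNIQUE", "DISPENSABLE")))
    cl <- blockClasses(bs)
    expect_equal(unname(cl[names(mult)]), brute)
    expect_equal(sum(cl == "CORE") + sum(cl == "DISPENSABLE") +
                   sum(cl == "UNIQUE"), nBlocks(bs))
    # every core block occurs in exactly n genome sequences/permutations
    perms <- corePermutations(bs)
    occ <- table(abs(unlist(lapply(perms, `[[`, "ids"))))
    expect_true(all(occ == 5L))
  }
})

test_that("genome block sequences are sorted and project to signed core permutations", {
  cat3 <- tinyCatalog(3L)
  df <- rbind(
    do.call(rbind, lapply(1:3, function(i) ivRow(1L, paste0("g", i), 0L, 10L))),
    ivRow(3L, "g1", 20L, 30L),
    do.call(rbind, lapply(1:3, function(i)
      ivRow(2L, paste0("g", i), 30L, 40L, "-"))))
  bs <- classifyBlocks(PanBlockSet(df, cat3))
  seqs <- genomeBlockSequences(bs)
  expect_equal(seqs$g1$class_label, c("C1", "U1", "C2"))
  expect_equal(seqs$g1$strand, c("+", "+", "-"))
  perms <- corePermutations(seqs)
  g1 <- perms[[which(vapply(perms, `[[`, "", "genome") == "g1")]]
  expect_equal(g1$ids, c(1L, -2L))
})

test_that("a genome absent from all blocks yields an empty sequence with a warning", {
  cat3 <- tinyCatalog(3L)
  df <- rbind(ivRow(1L, "g1", 0L, 10L), ivRow(1L, "g2", 0L, 10L))
  bs <- classifyBlocks(PanBlockSet(df, cat3))
  expect_warning(seqs <- genomeBlockSequences(bs), "g3")
  expect_equal(nrow(seqs$g3), 0L)
})

test_that("core fraction spans its closed-form limits", {
  cat2 <- GenomeCatalog(c("gA", "gB"), c("chr1", "chr1"), c(100L, 100L))
  # single core block covering both genomes end-to-end -> 1.0
  full <- rbind(ivRow(1L, "gA", 0L, 100L), ivRow(1L, "gB", 0L, 100L))
  expect_equal(coreFraction(classifyBlocks(PanBlockSet(full, cat2)))$overall, 1)
  # only unique blocks -> 0.0
  uniq <- rbind(ivRow(1L, "gA", 0L, 50L), ivRow(2L, "gB", 0L, 50L))
  cf <- coreFraction(classifyBlocks(PanBlockSet(uniq, cat2)))
  expect_equal(cf$overall, 0)
  expect_equal(unname(cf$per_genome), c(0, 0))
})

test_that("core fraction equals the planted value in exact arithmetic", {
  scn <- generateScenario(scenarioConfig(4L, 20L, 10L, 2L, seed = 8L))
  bs <- classifyBlocks(scn$blockset)
  tb <- scn$truth$blocks
  core_bp <- sum(tb$length[tb$class == "CORE"])
  expected <- 4 * core_bp / sum(scn$catalog@seqs$seq_length)
  expect_equal(coreFraction(bs)$overall, expected)
})

test_that("the unique class can be folded into dispensable for reporting", {
  scn <- generateScenario(scenarioConfig(4L, 10L, 5L, 2L, seed = 3L))
  bs <- classifyBlocks(scn$blockset)
  s3 <- blockSummary(bs)
  s2 <- blockSummary(bs, mergeUnique = TRUE)
  expect_equal(nrow(s2), 2L)
  expect_equal(s2$count[s2$class == "DISPENSABLE"],
               sum(s3$count[s3$class %in% c("DISPENSABLE", "UNIQUE")]))
  expect_equal(sum(s2$bp), sum(s3$bp))
})
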