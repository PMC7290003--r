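test_that("simulateGenome bookkeeping, determinism and GC boundary", {
  g <- simulateGenome(2, c(100000, 50000), 0.48, seed = 7)
  expect_equal(length(g), 2L)
  expect_equal(sum(Biostrings::width(g)), 150000)
  expect_equal(names(g), c("chr1", "chr2"))

  g2 <- simulateGenome(2, c(100000, 50000), 0.48, seed = 7)
  expect_identical(as.character(g), as.character(g2))

  noGC <- simulateGenome(1, 1000, 0.0, seed = 1)
  expect_false(grepl("[GC]", as.character(noGC[[1]])))

  comp <- Biostrings::letterFrequency(g[[1]], c("G", "C"))
  expect_equal(sum(comp) / 100000, 0.48, tolerance = 0.02)

  expect_error(simulateGenome(1, -5, 0.5, 1), "positive")
  expect_error(simulateGenome(2, c(100), 0.5, 1), "one entry")
})

test_that("buildConstruct copies native segments verbatim and keeps the rest novel", {
  g <- simulateGenome(2, c(60000, 40000), 0.48, seed = 3)
  ns <- data.frame(chromosome = c("chr1", "chr2"),
                   start = c(10000, 5000), end = c(10500, 5500),
                   label = c("promoter", "terminator"))
  con <- buildConstruct(g, backboneLength = 3500, cdsLength = 2000,
                        nativeSegments = ns, seed = 11)
  expect_s4_class(con, "ConstructMap")
  expect_equal(constructLength(con), 3500 + 2000 + 1000)
  sn <- sharedNativeTruth(con)
  expect_equal(sum(sn$end - sn$start), 1000)
  # verbatim copies
  cs <- constructSeq(con)
  for (i in seq_len(nrow(sn))) {
    expect_identical(
      substr(cs, sn$start[i] + 1, sn$end[i]),
      as.character(Biostrings::subseq(g[[sn$chromosome[i]]],
                                      sn$genome_start[i] + 1,
                                      sn$genome_end[i])))
  }
  # novel remainder: sampled 50-mers from the backbone are absent from the
  # genome
  for (off in c(0, 1000, 2000, 3000)) {
    kmer <- substr(cs, off + 1, off + 50)
    n <- sum(vapply(seq_along(g), function(i)
      Biostrings::countPattern(kmer, g[[i]]), integer(1)))
    expect_equal(n, 0L)
  }

  con0 <- buildConstruct(g, 2000, 1000, data.frame(), seed = 1)
  expect_equal(nrow(sharedNativeTruth(con0)), 0L)
  expect_equal(constructLength(con0), 3000)

  nsBad <- data.frame(chromosome = c("chr1", "chr1"),
                      start = c(100, 300), end = c(400, 600),
                      label = c("promoter", "terminator"))
  expect_error(buildConstruct(g, 1000, 500, nsBad, seed = 1), "overlap")
  nsOut <- data.frame(chromosome = "chr2", start = 39000, end = 41000,
                      label = "promoter")
  expect_error(buildConstruct(g, 1000, 500, nsOut, seed = 1), "within")
})

test_that("makeConcatemer respects orientation, length and fragment count contracts", {
  g <- simulateGenome(1, 50000, 0.5, seed = 5)
  con <- buildConstruct(g, 4500, 2000, data.frame(), seed = 6)
  L <- constructLength(con) # 6500

  # all-sense island
  sp <- islandSpec("chr1", 0, 20000, antisenseProb = 0)
  cc <- makeConcatemer(con, sp, seed = 1)
  expect_true(all(cc$structure$orientation == "sense"))
  expect_equal(nchar(cc$sequence), sum(cc$structure$island_end -
                                       cc$structure$island_start))

  # degenerate full-length fragments: target = L gives exactly one copy
  sp1 <- islandSpec("chr1", 0, L, fragFamily = "constant", fragParams = L,
                    antisenseProb = 0)
  cc1 <- makeConcatemer(con, sp1, seed = 2)
  expect_equal(nrow(cc1$structure), 1L)
  expect_equal(nchar(cc1$sequence), L)

  # 250 kbp of full-length copies: 38 full copies plus a remainder of at
  # most one fragment
  sp38 <- islandSpec("chr1", 0, 250000, fragFamily = "constant",
                     fragParams = L, antisenseProb = 0)
  cc38 <- makeConcatemer(con, sp38, seed = 3)
  expect_equal(sum((cc38$structure$island_end -
                    cc38$structure$island_start) == L), 39L)
  expect_true(nchar(cc38$sequence) - 250000 < L)
  expect_gte(nchar(cc38$sequence), 250000)
  expect_equal(floor(250000 / L), 38)

  # island sequence reconstructs from the structure
  spMix <- islandSpec("chr1", 0, 15000, antisenseProb = 0.5)
  ccM <- makeConcatemer(con, spMix, seed = 9)
  doubled <- paste0(constructSeq(con), constructSeq(con))
  rebuilt <- paste(vapply(seq_len(nrow(ccM$structure)), function(i) {
    st <- ccM$structure[i, ]
    frag <- substr(doubled, st$construct_start + 1, st$construct_end)
    if (st$orientation == "antisense")
      frag <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(frag)))
    frag
  }, character(1)), collapse = "")
  expect_identical(rebuilt, ccM$sequence)

  spBad <- islandSpec("chr1", 0, 1000, fragFamily = "constant",
                      fragParams = 0)
  expect_error(makeConcatemer(con, spBad, seed = 1), "degenerate")
})

test_that("plantIslands conserves length and records exact truth", {
  g <- simulateGenome(2, c(80000, 60000), 0.5, seed = 8)
  con <- buildConstruct(g, 4500, 2000, data.frame(), seed = 9)
  specs <- list(
    islandSpec("chr1", 30000, 10000, fragFamily = "constant",
               fragParams = 2000, antisenseProb = 0.3),
    islandSpec("chr2", 20000, 40000, antisenseProb = 0.5))
  pl <- plantIslands(g, con, specs, seed = 10)
  expect_equal(sum(Biostrings::width(pl$genome)),
               140000 + sum(pl$islands$true_length))
  expect_gte(pl$islands$true_length[1], 10000)
  expect_equal(pl$islands$insertion_point, c(30000, 20000))
  expect_equal(pl$islands$true_length,
               vapply(pl$islands$structure, function(s)
                 sum(s$island_end - s$island_start), numeric(1)))
  # planted sequence is flank + island + flank
  tg <- as.character(pl$genome[["chr1"]])
  wt <- as.character(g[["chr1"]])
  expect_identical(substr(tg, 1, 30000), substr(wt, 1, 30000))
  expect_identical(substr(tg, 30001 + pl$islands$true_length[1], nchar(tg)),
                   substr(wt, 30001, nchar(wt)))

  none <- plantIslands(g, con, list(), seed = 1)
  expect_identical(as.character(none$genome), as.character(g))
  expect_equal(nrow(none$islands), 0L)

  expect_error(plantIslands(g, con, list(islandSpec("chr1", 90000, 1000)),
                            seed = 1), "outside")
})

test_that("simulateReads honours coverage, the error-free limit and determinism", {
  g <- simulateGenome(1, 100000, 0.5, seed = 12)
  sim <- simulateReads(g, coverage = 5,
                       lengthDist = readLengthDist(meanLength = 2000,
                                                   sigma = 0.5),
                       errModel = perfectReads(), seed = 99)
  total <- sum(Biostrings::width(sim$reads))
  expect_gte(total, 0.95 * 5 * 100000)
  expect_lte(total, 1.05 * 5 * 100000)
  # every error-free read is an exact substring of the source or its
  # reverse complement
  src <- as.character(g[[1]])
  for (i in seq_len(min(25, length(sim$reads)))) {
    r <- sim$reads[[i]]
    fwd <- as.character(r)
    rc <- as.character(Biostrings::reverseComplement(r))
    expect_true(grepl(fwd, src, fixed = TRUE) ||
                grepl(rc, src, fixed = TRUE))
  }
  # truth intervals are exact
  i <- 3L
  tr <- sim$truth[i, ]
  sub <- substr(src, tr$source_start + 1, tr$source_end)
  if (tr$strand == "-")
    sub <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(sub)))
  expect_identical(as.character(sim$reads[[i]]), sub)

  # identical seeds give identical FASTQ bytes
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  sim2 <- simulateReads(g, coverage = 5,
                        lengthDist = readLengthDist(meanLength = 2000,
                                                    sigma = 0.5),
                        errModel = perfectReads(), seed = 99)
  writeFastq(sim$reads, f1); writeFastq(sim2$reads, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(simulateReads(Biostrings::DNAStringSet(), 5), "empty")
  expect_error(simulateReads(g, 0), "coverage")
})

test_that("circular molecules are read across the origin but never beyond one turn", {
  g <- simulateGenome(1, 5000, 0.5, seed = 13)
  names(g) <- "episome"
  sim <- simulateReads(g, coverage = 3,
                       lengthDist = readLengthDist("constant",
                                                   meanLength = 8000),
                       errModel = perfectReads(), seed = 5,
                       circular = TRUE)
  expect_true(all(Biostrings::width(sim$reads) <= 5000))
  doubled <- paste0(as.character(g[[1]]), as.character(g[[1]]))
  wrapped <- sim$truth$source_end > 5000
  expect_true(any(wrapped)) # origin-crossing reads exist
  for (i in which(wrapped)[1]) {
    r <- as.character(sim$reads[[i]])
    rc <- as.character(Biostrings::reverseComplement(sim$reads[[i]]))
    expect_true(grepl(r, doubled, fixed = TRUE) ||
                grepl(rc, doubled, fixed = TRUE))
  }
})

test_that("episome reads never produce construct-plus-chromosome truth", {
  ee <- simulateEpisomeLine(seed = 4, genomeLengths = c(60000, 40000),
                            coverage = 4, errModel = perfectReads())
  epi <- ee$truth$source_molecule == "episome"
  expect_true(all(ee$truth$true_class[epi] == "construct_only"))
  expect_true(all(ee$truth$true_class[!epi] == "genome_only"))
})
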