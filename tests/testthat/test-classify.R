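test_that("the shared-native mask recovers the genome-copied construct segments", {
  line <- smallLineErrorFree()
  con <- line$construct
  mask <- computeSharedNativeMask(con, line$wildtype, padding = 10)
  mk <- maskIntervals(mask)
  sn <- sharedNativeTruth(con)
  expect_equal(nrow(mk), nrow(sn))
  for (i in seq_len(nrow(sn))) {
    j <- which(mk$start <= sn$start[i] & mk$end >= sn$end[i])
    expect_equal(length(j), 1L)
    # padding-tight: within 10 bp + padding of the true segment
    expect_lte(sn$start[i] - mk$start[j], 20)
    expect_lte(mk$end[j] - sn$end[i], 20)
  }

  # fully synthetic construct: empty mask
  conNovel <- buildConstruct(line$wildtype, 3000, 2000, data.frame(),
                             seed = 5)
  m0 <- computeSharedNativeMask(conNovel, line$wildtype)
  expect_equal(nrow(maskIntervals(m0)), 0L)

  # abutting segments merge into one mask interval
  m2 <- sharedNativeMask(c(100, 600), c(600, 900), 6500, padding = 0)
  expect_equal(nrow(maskIntervals(m2)), 1L)
  expect_equal(maskIntervals(m2)$start, 100)
  expect_equal(maskIntervals(m2)$end, 900)
})

test_that("unmasked extent subtracts the mask per base without double counting", {
  mask <- sharedNativeMask(0, 1000, 6500, padding = 0)
  h <- hitRow("r", 0, 800, "p", 100, 900, kind = "construct")
  expect_equal(unmaskedExtent(h, mask), 0)

  empty <- sharedNativeMask(numeric(0), numeric(0), 6500)
  expect_equal(unmaskedExtent(h, empty), 800)

  mask100 <- sharedNativeMask(0, 100, 6500, padding = 0)
  two <- rbind(hitRow("r", 0, 600, "p", 0, 600, kind = "construct"),
               hitRow("r", 500, 1100, "p", 400, 1000, kind = "construct"))
  expect_equal(unmaskedExtent(two, mask100), 900) # union 1000 minus 100

  # wrap-around hit on a circular construct folds before masking
  wrap <- hitRow("r", 0, 1000, "p", 6000, 7000, kind = "construct")
  expect_equal(unmaskedExtent(wrap, mask100), 900)

  expect_error(unmaskedExtent(rbind(hitRow("a", 0, 10, "p", 0, 10),
                                    hitRow("b", 0, 10, "p", 0, 10)),
                              empty), "single read")
})

test_that("classifyRead implements the border-read taxonomy", {
  mask <- sharedNativeMask(numeric(0), numeric(0), 6500)
  par <- classifyParams()

  # genome hits only
  expect_equal(classifyRead(5000, emptyHits(),
                            hitRow("r", 0, 5000, "chr1", 10000, 15000),
                            mask, par)$class, "genome_only")
  # no hits at all
  expect_equal(classifyRead(5000, emptyHits(), emptyHits(), mask,
                            par)$class, "unmapped")

  # spanning: 4 kbp flank + ~10 kbp construct block + 14 kbp flank at the
  # adjacent locus
  ch <- hitRow("r", 4000, 14000, "p", 0, 6500, kind = "construct")
  gh <- rbind(hitRow("r", 0, 4000, "chr1", 96000, 100000),
              hitRow("r", 14000, 28000, "chr1", 100000, 114000))
  res <- classifyRead(28000, ch, gh, mask, par)
  expect_equal(res$class, "spanning")
  expect_equal(res$anchor$junction_left, 100000)
  expect_equal(res$anchor$junction_right, 100000)
  expect_equal(res$anchor$span_size, 10000)

  # left border: 3 kbp flank then ~42 kbp construct-aligned to the read end
  ch2 <- hitRow("r", 3000, 45000, "p", 0, 6500, kind = "construct")
  gh2 <- hitRow("r", 0, 3000, "chr9", 862083, 865083)
  res2 <- classifyRead(45000, ch2, gh2, mask, par)
  expect_equal(res2$class, "left_border")
  expect_equal(res2$anchor$junction_left, 865083)
  expect_equal(res2$anchor$construct_extent, 42000)

  # reverse-complemented read: read-5' flank on the minus strand anchors the
  # genomic right side
  res3 <- classifyRead(45000, ch2,
                       hitRow("r", 0, 3000, "chr9", 865119, 868119,
                              strand = "-"),
                       mask, par)
  expect_equal(res3$class, "right_border")
  expect_equal(res3$anchor$junction_right, 865119)

  # construct hits entirely within the mask, no genome hits: false positive
  maskAll <- sharedNativeMask(0, 6500, 6500, padding = 0)
  res4 <- classifyRead(2000, hitRow("r", 0, 800, "p", 100, 900,
                                    kind = "construct"),
                       emptyHits(), maskAll, par)
  expect_equal(res4$class, "false_positive")
  # same but with genome hits: the read is genomic
  res5 <- classifyRead(2000, hitRow("r", 0, 800, "p", 100, 900,
                                    kind = "construct"),
                       hitRow("r", 0, 2000, "chr1", 500, 2500),
                       maskAll, par)
  expect_equal(res5$class, "genome_only")

  # flanks on two chromosomes: ambiguous (possible chimera)
  gh6 <- rbind(hitRow("r", 0, 4000, "chr1", 96000, 100000),
               hitRow("r", 14000, 28000, "chr2", 50000, 64000))
  expect_equal(classifyRead(28000, ch, gh6, mask, par)$class, "ambiguous")

  expect_error(classifyRead(100, hitRow("a", 0, 50, "p", 0, 50),
                            hitRow("b", 0, 50, "c", 0, 50), mask, par),
               "multiple")
})

test_that("tabulate partitions reads and derives coverage", {
  cls <- data.frame(
    read_id = paste0("r", 1:10),
    class = c(rep("genome_only", 6), rep("construct_only", 3), "spanning"),
    stringsAsFactors = FALSE)
  rl <- setNames(rep(1000L, 10), paste0("r", 1:10))
  tab <- tabulateClasses(cls, rl, genomeSize = 5000)
  expect_equal(tab$total_reads, 10L)
  expect_equal(tab$total_nucleotides, 10000)
  expect_equal(tab$estimated_coverage, 2)
  expect_equal(tab$genome_only, 6L)
  expect_equal(tab$total_aligning_construct, 4L)
  classCounts <- unlist(tab[islandseq:::READ_CLASSES])
  expect_equal(sum(classCounts), tab$total_reads)

  empty <- tabulateClasses(cls[0, ], rl[0], genomeSize = 5000)
  expect_equal(empty$total_reads, 0L)
  expect_equal(empty$total_nucleotides, 0)
})

test_that("false-positive filter: wild-type reads never become construct-positive", {
  # reads from a wild-type genome; the construct shares only its
  # promoter/terminator with that genome
  for (sd in c(1, 2)) {
    g <- simulateGenome(2, c(150000, 100000), 0.48, seed = sd)
    con <- buildConstruct(
      g, 3500, 2000,
      data.frame(chromosome = c("chr1", "chr2"),
                 start = c(50000, 30000), end = c(50500, 30500),
                 label = c("promoter", "terminator")), seed = sd + 50)
    sim <- simulateReads(g, coverage = 6, errModel = perfectReads(),
                         seed = sd + 100)
    res <- detectIntegration(sim$reads, g, con)
    bad <- res$summary$construct_only + res$summary$left_border +
      res$summary$right_border + res$summary$spanning
    expect_equal(bad, 0L)
  }
})

test_that("error-free classification recovers simulator truth classes", {
  line <- smallLineErrorFree()
  res <- detectFor(line)
  merged <- merge(line$truth[, c("read_id", "true_class")], res$classes,
                  by = "read_id")
  agree <- mean(merged$true_class == merged$class)
  expect_gte(agree, 0.99)
  # disagreements only at reads with short flanks or tiny construct overlap
  dis <- merged[merged$true_class != merged$class, ]
  expect_true(all(dis$true_class %in%
                  c("left_border", "right_border", "spanning",
                    "construct_only", "false_positive", "genome_only")))
})
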