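anchorRow <- function(read_id, class, chrom, jl = NA, jr = NA,
                      extent = 1000, span = NA) {
  data.frame(read_id = read_id, class = class, chromosome = chrom,
             junction_left = jl, junction_right = jr,
             construct_extent = extent, span_size = span,
             stringsAsFactors = FALSE)
}

test_that("border anchors cluster by locus", {
  a <- rbind(anchorRow("r1", "left_border", "chr1", jl = 1000),
             anchorRow("r2", "left_border", "chr1", jl = 1020),
             anchorRow("r3", "right_border", "chr1", jr = 1060))
  cands <- clusterBorderAnchors(a, 10000)
  expect_equal(length(cands), 1L)
  expect_equal(nrow(cands[[1]]), 3L)

  b <- rbind(anchorRow("r1", "left_border", "chr1", jl = 1000),
             anchorRow("r2", "left_border", "chr2", jl = 1000))
  expect_equal(length(clusterBorderAnchors(b, 10000)), 2L)

  c3 <- rbind(anchorRow("r1", "left_border", "chr1", jl = 1000),
              anchorRow("r2", "right_border", "chr1", jr = 500000))
  expect_equal(length(clusterBorderAnchors(c3, 10000)), 2L)

  expect_equal(length(clusterBorderAnchors(a[0, ], 10000)), 0L)
})

test_that("insertion sites resolve to the inter-flank gap in report coordinates", {
  # left flank reaching 0-based 316958, right flank starting at 0-based
  # 317016: reported 1-based site 316,959-317,016, resolution 58 bp
  cand <- rbind(anchorRow("r1", "left_border", "chr11", jl = 316958),
                anchorRow("r2", "right_border", "chr11", jr = 317016))
  site <- resolveSite(cand)
  expect_equal(site$site_start, 316959)
  expect_equal(site$site_end, 317016)
  expect_equal(site$resolution, 58)
  expect_false(site$one_sided)

  # abutting flanks: zero-width site
  ab <- rbind(anchorRow("r1", "left_border", "chr1", jl = 5000),
              anchorRow("r2", "right_border", "chr1", jr = 5000))
  s2 <- resolveSite(ab)
  expect_equal(s2$resolution, 0)

  # flank overlap (microhomology) collapses to a midpoint
  ov <- rbind(anchorRow("r1", "left_border", "chr1", jl = 5010),
              anchorRow("r2", "right_border", "chr1", jr = 5000))
  s3 <- resolveSite(ov)
  expect_equal(s3$resolution, 0)
  expect_equal(s3$left_end, 5005)

  # one-sided candidate is flagged
  one <- anchorRow("r1", "left_border", "chr1", jl = 7000)
  s4 <- resolveSite(one)
  expect_true(s4$one_sided)
  expect_true(is.na(s4$resolution))
})

test_that("island size is exact with a spanning read, else a lower bound", {
  # longest left (42 kbp) and right (82 kbp) border extents: minimum 124 kbp
  cand <- rbind(
    anchorRow("r1", "left_border", "chr9", jl = 865083, extent = 42000),
    anchorRow("r2", "left_border", "chr9", jl = 865090, extent = 12000),
    anchorRow("r3", "right_border", "chr9", jr = 865119, extent = 82000))
  sz <- islandSize(cand)
  expect_equal(sz$size_bp, 124000)
  expect_false(sz$complete)
  expect_true(sz$size_is_lower_bound)

  sp <- rbind(cand,
              anchorRow("r4", "spanning", "chr9", jl = 865083, jr = 865119,
                        extent = 9800, span = 10050))
  sz2 <- islandSize(sp)
  expect_true(sz2$complete)
  expect_false(sz2$size_is_lower_bound)
  expect_equal(sz2$size_bp, 10050)

  one <- anchorRow("r1", "left_border", "chr1", jl = 100, extent = 5000)
  sz3 <- islandSize(one)
  expect_equal(sz3$size_bp, 5000)
  expect_true(sz3$size_is_lower_bound)
})

test_that("concatemer segmentation orders fragments and respects strand symmetry", {
  g <- simulateGenome(1, 50000, 0.5, seed = 61)
  con <- buildConstruct(g, 4500, 2000, data.frame(), seed = 62)
  L <- constructLength(con)
  cs <- constructSeq(con)
  rcL <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))

  # [full sense, full antisense] reconstructs exactly
  read <- paste0(cs, rcL(cs))
  hits <- mergeColinearHits(
    mapHits(Biostrings::DNAStringSet(c(r = read)), con,
            targetKind = "construct"), 200)
  st <- segmentConcatemer(hits, L)
  expect_equal(nrow(st), 2L)
  expect_equal(st$orientation, c("sense", "antisense"))
  expect_equal(st$read_start, c(0L, L))
  expect_equal(st$read_end, c(L, 2L * L))

  # single match: single fragment
  read1 <- substr(cs, 1001, 4000)
  h1 <- mapHits(Biostrings::DNAStringSet(c(r = read1)), con,
                targetKind = "construct")
  st1 <- segmentConcatemer(h1, L)
  expect_equal(nrow(st1), 1L)
  expect_equal(st1$construct_start, 1000L)
  expect_equal(st1$construct_end, 4000L)

  # reverse complement of a read: order reversed, orientations flipped
  spec <- islandSpec("chr1", 0, 20000, antisenseProb = 0.4)
  cc <- makeConcatemer(con, spec, seed = 63)
  fwd <- Biostrings::DNAStringSet(c(r = cc$sequence))
  rev <- Biostrings::reverseComplement(fwd)
  names(rev) <- "r"
  stF <- segmentConcatemer(mergeColinearHits(
    mapHits(fwd, con, targetKind = "construct"), 200), L)
  stR <- segmentConcatemer(mergeColinearHits(
    mapHits(rev, con, targetKind = "construct"), 200), L)
  expect_equal(nrow(stF), nrow(stR))
  expect_equal(stR$orientation,
               rev(ifelse(stF$orientation == "sense", "antisense", "sense")))
  expect_equal(stR$construct_start, rev(stF$construct_start))
  n <- nchar(cc$sequence)
  expect_equal(stR$read_start, n - rev(stF$read_end))
})

test_that("error-free segmentation reproduces the simulator's true structure", {
  for (sd in 1:4) {
    g <- simulateGenome(1, 200000, 0.5, seed = sd)
    con <- buildConstruct(
      g, 3500, 2000,
      data.frame(chromosome = "chr1", start = c(100000, 150000),
                 end = c(100500, 150500),
                 label = c("promoter", "terminator")), seed = sd + 1)
    cc <- makeConcatemer(con, islandSpec("chr1", 0, 30000,
                                         antisenseProb = 0.5),
                         seed = sd + 2)
    hits <- mergeColinearHits(
      mapHits(Biostrings::DNAStringSet(c(r = cc$sequence)), con,
              targetKind = "construct"), 200)
    st <- segmentConcatemer(hits, constructLength(con))
    tr <- canonicalStructure(cc$structure, constructLength(con))
    expectStructuresMatch(st, tr)
  }
})

test_that("intact cassette counting handles orientation and wrap-around", {
  st <- data.frame(construct_start = c(0, 6500, 500),
                   construct_end = c(6500, 13000, 2000),
                   orientation = c("sense", "antisense", "sense"))
  # full-construct fragments contain any cassette
  expect_equal(countIntactCassettes(st[1:2, ], c(4000, 6000), 6500), 2L)
  expect_equal(countIntactCassettes(st, c(600, 1800), 6500), 3L)
  # truncated fragments miss the cassette
  expect_equal(countIntactCassettes(st[3, , drop = FALSE], c(1500, 3000),
                                    6500), 0L)
  # wrap-around fragment spanning the origin
  wrap <- data.frame(construct_start = 6000, construct_end = 8000,
                     orientation = "sense")
  expect_equal(countIntactCassettes(wrap, c(0, 1400), 6500), 1L)
  expect_error(countIntactCassettes(st, c(-1, 10), 6500), "within")
})

test_that("feature context reports containing and nearby features", {
  features <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr1", "chr2"),
    IRanges::IRanges(start = c(2470000, 2477740, 2490000, 100),
                     end = c(2477060, 2480000, 2491000, 200)),
    ID = c("geneA", "geneB", "geneC", "geneD"),
    type = c("gene", "gene", "gene", "gene"))

  # intergenic site 199 bp from the upstream gene end and 479 bp from the
  # downstream gene start
  fc <- annotateIsland("chr1", 2477260, 2477260, features)
  expect_true(is.na(fc$within_feature))
  expect_equal(fc$upstream_feature, "geneA")
  expect_equal(fc$upstream_distance, 199)
  expect_equal(fc$downstream_feature, "geneB")
  expect_equal(fc$downstream_distance, 479)

  # site inside a gene
  fc2 <- annotateIsland("chr1", 2478000, 2478050, features)
  expect_equal(fc2$within_feature, "geneB")

  # everything further than 1 kbp: empty context
  fc3 <- annotateIsland("chr1", 2485000, 2485000, features)
  expect_true(is.na(fc3$within_feature))
  expect_true(is.na(fc3$upstream_feature))
  expect_true(is.na(fc3$downstream_feature))

  expect_error(annotateIsland("chrX", 100, 100, features), "chrX")
})

test_that("feature context works from a GFF3 file", {
  gff <- c("##gff-version 3",
           paste("chr1", "test", "gene", "1000", "2000", ".", "+", ".",
                 "ID=gene1;Name=gene1", sep = "\t"),
           paste("chr1", "test", "gene", "2500", "3500", ".", "-", ".",
                 "ID=gene2;Name=gene2", sep = "\t"))
  f <- tempfile(fileext = ".gff3")
  writeLines(gff, f)
  features <- rtracklayer::import(f)
  fc <- annotateIsland("chr1", 2200, 2210, features)
  expect_equal(fc$upstream_feature, "gene1")
  expect_equal(fc$upstream_distance, 199)
  expect_equal(fc$downstream_feature, "gene2")
  expect_equal(fc$downstream_distance, 289)
})
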