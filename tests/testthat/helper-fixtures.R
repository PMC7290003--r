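# Shared fixtures: built once per test run, in code, at small scale.

.fixtures <- new.env(parent = emptyenv())

# A small transgenic line (500 kbp genome, two islands, default 15% error)
# shared by classification/pipeline tests.
smallLine <- function() {
  if (is.null(.fixtures$line)) {
    .fixtures$line <- simulateIntegrationLine(
      seed = 2024, genomeLengths = c(300000, 200000),
      islandLengths = c(15000, 30000), coverage = 8)
  }
  .fixtures$line
}

# The same line, error-free (classification oracle).
smallLineErrorFree <- function() {
  if (is.null(.fixtures$lineEF)) {
    .fixtures$lineEF <- simulateIntegrationLine(
      seed = 2024, genomeLengths = c(300000, 200000),
      islandLengths = c(15000, 30000), coverage = 8,
      errModel = perfectReads())
  }
  .fixtures$lineEF
}

detectFor <- function(line) {
  detectIntegration(line$reads, line$wildtype, line$construct)
}

# Hit-frame row constructor for synthetic classification scenarios.
hitRow <- function(read_id, rs, re, target_id, ts, te, strand = "+",
                   identity = 0.9, kind = "genome", read_length = NA) {
  data.frame(read_id = read_id, read_length = read_length,
             read_start = rs, read_end = re, target_id = target_id,
             target_start = ts, target_end = te, strand = strand,
             identity = identity, n_seeds = 10L, target_kind = kind,
             stringsAsFactors = FALSE)
}

emptyHits <- function() {
  hitRow("x", 0, 1, "y", 0, 1)[0, ]
}

# Structures equal up to small boundary jitter (junction microhomology at
# fragment joints shifts maximal-hit boundaries by a few bases).
expectStructuresMatch <- function(called, truth, tol = 15) {
  expect_equal(nrow(called), nrow(truth))
  expect_equal(called$orientation, truth$orientation)
  expect_true(all(abs(called$read_start - truth$read_start) <= tol))
  expect_true(all(abs(called$read_end - truth$read_end) <= tol))
  expect_true(all(abs(called$construct_start - truth$construct_start) <= tol))
  expect_true(all(abs(called$construct_end - truth$construct_end) <= tol))
}
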