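# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed without disturbing the caller's RNG
# state (so simulator calls are reproducible and composable).
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Total width of the per-base union of 0-based half-open intervals
# (empty or inverted intervals are ignored).
unionWidth <- function(starts, ends) {
  if (length(starts) == 0L) return(0L)
  sum(width(reduce(asRanges0(starts, ends))))
}

# 0-based half-open intervals as an IRanges (1-based closed internally).
asRanges0 <- function(starts, ends) {
  keep <- ends > starts
  IRanges(starts[keep] + 1L, ends[keep])
}

# Back to a 0-based data.frame.
ranges0 <- function(ir) {
  data.frame(start = start(ir) - 1L, end = end(ir))
}

emptyHitFrame <- function() {
  data.frame(
    read_id = character(0), read_length = integer(0),
    read_start = integer(0), read_end = integer(0),
    target_id = character(0), target_start = integer(0),
    target_end = integer(0), strand = character(0),
    identity = numeric(0), n_seeds = integer(0),
    target_kind = character(0), stringsAsFactors = FALSE)
}

READ_CLASSES <- c("unmapped", "genome_only", "construct_only", "left_border",
                  "right_border", "spanning", "false_positive", "ambiguous")

randomDna <- function(n, gcFraction = 0.5) {
  p <- c((1 - gcFraction) / 2, gcFraction / 2, gcFraction / 2,
         (1 - gcFraction) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

revcompChar <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}
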