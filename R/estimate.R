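# Coverage arithmetic: fold coverage, Clarke-Carbon genome-coverage
# probability, the read-budget estimator for unresolved island size, and
# full plasmid-copy equivalents.

#' Estimate fold coverage
#'
#' @param totalNucleotides total sequenced nucleotides (bp).
#' @param genomeSize genome size in bp (> 0).
#' @return fold coverage `totalNucleotides / genomeSize`.
#' @examples
#' estimateCoverage(1e6, 5e5) # 2
#' @export
estimateCoverage <- function(totalNucleotides, genomeSize) {
  if (genomeSize <= 0) stop("genomeSize must be > 0")
  totalNucleotides / genomeSize
}

#' Clarke-Carbon probability that a genomic base is covered
#'
#' At random `c`-fold coverage the probability that any given base of the
#' genome is sequenced at least once is `1 - exp(-c)`.
#'
#' @param c fold coverage (>= 0).
#' @return probability in `[0, 1)`.
#' @examples
#' clarkeCarbonProbability(5.8) # > 0.99
#' @export
clarkeCarbonProbability <- function(c) {
  if (any(c < 0)) stop("coverage must be >= 0")
  1 - exp(-c)
}

#' Read-budget estimate of an unresolved island's size
#'
#' Reads aligning only to the construct are drawn from the integrated
#' islands (and, in episome lines, from free episomes). If their nucleotide
#' total is `ni`, the fold coverage `c`, and the summed length of the
#' already-sized islands `sum(knownIslandLengths)`, then the remaining
#' unresolved island length is estimated by
#' `ni / c - sum(knownIslandLengths)`: the construct-only read budget,
#' converted to sequence length at the observed coverage, minus the islands
#' already accounted for.
#'
#' @param ni total nucleotides in construct-only reads (bp).
#' @param knownIslandLengths lengths (bp) of islands of known size.
#' @param c fold coverage (> 0).
#' @return estimated length in bp; a negative estimate (budget already
#'   exhausted by the known islands) is unphysical and returns 0 with a
#'   warning.
#' @examples
#' unresolvedIslandSize(7 * 20000, numeric(0), 7) # 20000
#' @export
unresolvedIslandSize <- function(ni, knownIslandLengths = numeric(0), c) {
  if (c <= 0) stop("coverage must be > 0")
  if (ni < 0) stop("ni must be >= 0")
  est <- ni / c - sum(knownIslandLengths)
  if (est < 0) {
    warning("construct-only read budget is exhausted by the known islands; ",
            "returning 0")
    return(0)
  }
  est
}

#' Full construct-copy equivalents of an island
#'
#' @param islandLength island length in bp.
#' @param constructLength construct length in bp (> 0).
#' @return `islandLength / constructLength` rounded to the nearest integer:
#'   the number of hypothetical back-to-back full-construct integrations the
#'   island corresponds to.
#' @examples
#' fullCopyEquivalents(250000, 6500) # 38
#' @export
fullCopyEquivalents <- function(islandLength, constructLength) {
  if (constructLength <= 0) stop("constructLength must be > 0")
  round(islandLength / constructLength)
}

#' Total nucleotides in construct-only reads
#'
#' Computes `ni` for [unresolvedIslandSize()] from a classification result.
#' By default whole read lengths are summed (matching the convention that
#' the nucleotides "in" construct-only reads are counted); `aligned = TRUE`
#' restricts to construct-aligned bases.
#'
#' @param classes data.frame (`read_id`, `class`).
#' @param readLengths named integer vector of read lengths.
#' @param aligned if `TRUE`, sum construct-aligned bases instead of read
#'   lengths (requires `constructHits`).
#' @param constructHits construct hit data.frame (for `aligned = TRUE`).
#' @return total nucleotides (bp).
#' @export
constructOnlyNucleotides <- function(classes, readLengths, aligned = FALSE,
                                     constructHits = NULL) {
  ids <- classes$read_id[classes$class == "construct_only"]
  if (!aligned)
    return(sum(as.numeric(readLengths[ids])))
  if (is.null(constructHits))
    stop("constructHits required when aligned = TRUE")
  h <- constructHits[constructHits$read_id %in% ids, , drop = FALSE]
  sum(vapply(split(seq_len(nrow(h)), h$read_id), function(idx)
    unionWidth(h$read_start[idx], h$read_end[idx]), numeric(1)))
}
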