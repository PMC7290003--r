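#' ConstructMap: an exogenous construct with element annotations
#'
#' Holds the (usually circular) delivered DNA molecule -- an integration
#' plasmid or an episome -- together with its functional element intervals
#' and the intervals that were copied verbatim from the host genome
#' (shared-native segments such as promoters and terminators). All intervals
#' are 0-based half-open on the construct; on a circular construct interval
#' arithmetic is modulo the construct length.
#'
#' @slot id single identifier string.
#' @slot sequence a [Biostrings::DNAString] with the construct sequence.
#' @slot circular logical flag; `TRUE` for plasmids/episomes.
#' @slot elements data.frame with columns `label`
#'   (promoter/cds/terminator/selection_cassette/backbone), `start`, `end`.
#' @slot sharedNative data.frame with columns `start`, `end` (and optionally
#'   `chromosome`, `genome_start`, `genome_end`) recording segments copied
#'   verbatim from a host genome.
#' @exportClass ConstructMap
setClass("ConstructMap",
  representation(id = "character", sequence = "DNAString",
                 circular = "logical", elements = "data.frame",
                 sharedNative = "data.frame"),
  validity = function(object) {
    L <- length(object@sequence)
    msg <- character(0)
    if (length(object@id) != 1L) msg <- c(msg, "id must be a single string")
    el <- object@elements
    if (nrow(el) && (any(el$start < 0) || any(el$end > L) ||
                     any(el$start >= el$end)))
      msg <- c(msg, "element intervals must lie within [0, length)")
    sn <- object@sharedNative
    if (nrow(sn)) {
      if (any(sn$start < 0) || any(sn$end > L) || any(sn$start >= sn$end))
        msg <- c(msg, "shared-native intervals must lie within [0, length)")
      ir <- asRanges0(sn$start, sn$end)
      if (sum(width(reduce(ir))) != sum(width(ir)))
        msg <- c(msg, "shared-native intervals must not overlap")
    }
    if (length(msg)) msg else TRUE
  })

#' @describeIn ConstructMap constructor.
#' @param id,sequence,circular,elements,sharedNative see slots.
#' @return a `ConstructMap`.
#' @export
ConstructMap <- function(id, sequence, circular = TRUE,
                         elements = data.frame(label = character(0),
                                               start = integer(0),
                                               end = integer(0)),
                         sharedNative = data.frame(start = integer(0),
                                                   end = integer(0))) {
  if (is.character(sequence)) sequence <- DNAString(sequence)
  new("ConstructMap", id = id, sequence = sequence,
      circular = isTRUE(circular), elements = elements,
      sharedNative = sharedNative)
}

#' @describeIn ConstructMap construct length in bp.
#' @param x a `ConstructMap`.
#' @export
constructLength <- function(x) length(x@sequence)

#' @describeIn ConstructMap construct sequence as a character string.
#' @export
constructSeq <- function(x) as.character(x@sequence)

#' @describeIn ConstructMap element interval table.
#' @export
constructElements <- function(x) x@elements

#' @describeIn ConstructMap shared-native (genome-copied) interval table.
#' @export
sharedNativeTruth <- function(x) x@sharedNative

setMethod("show", "ConstructMap", function(object) {
  cat("ConstructMap '", object@id, "': ", length(object@sequence), " bp, ",
      if (object@circular) "circular" else "linear", "\n", sep = "")
  if (nrow(object@elements))
    cat("  elements: ",
        paste(sprintf("%s[%d,%d)", object@elements$label,
                      object@elements$start, object@elements$end),
              collapse = " "), "\n", sep = "")
  if (nrow(object@sharedNative))
    cat("  shared-native: ", nrow(object@sharedNative), " segment(s), ",
        sum(object@sharedNative$end - object@sharedNative$start),
        " bp\n", sep = "")
})

#' IslandSpec: plan for one synthetic integration island
#'
#' Describes a concatemer integration island to be planted in a host
#' chromosome: where it goes, how long it should be, and how its construct
#' fragments are drawn (length distribution, antisense probability, optional
#' junction micro-indels that blur the genome/island borders).
#'
#' @slot chromosome target chromosome id.
#' @slot position 0-based insertion point on the wild-type chromosome.
#' @slot targetLength desired island length in bp.
#' @slot fragFamily fragment length family, `"uniform"` or `"constant"`.
#' @slot fragParams numeric parameters: `c(min, max)` for uniform, `c(length)`
#'   for constant.
#' @slot antisenseProb probability that a fragment is inserted antisense.
#' @slot junctionIndelMax maximum size (bp) of deletions/insertions applied at
#'   the genome/island junctions (0 = clean junctions).
#' @exportClass IslandSpec
setClass("IslandSpec",
  representation(chromosome = "character", position = "numeric",
                 targetLength = "numeric", fragFamily = "character",
                 fragParams = "numeric", antisenseProb = "numeric",
                 junctionIndelMax = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (object@targetLength <= 0) msg <- c(msg, "targetLength must be > 0")
    if (object@antisenseProb < 0 || object@antisenseProb > 1)
      msg <- c(msg, "antisenseProb must be in [0, 1]")
    if (object@position < 0) msg <- c(msg, "position must be >= 0")
    if (!object@fragFamily %in% c("uniform", "constant"))
      msg <- c(msg, "fragFamily must be 'uniform' or 'constant'")
    if (length(msg)) msg else TRUE
  })

#' @describeIn IslandSpec constructor.
#' @param chromosome,position,targetLength,antisenseProb,junctionIndelMax see
#'   slots.
#' @param fragFamily,fragParams fragment length distribution; default uniform
#'   over `[500, construct length]` is applied by [makeConcatemer()] when
#'   `fragParams` is `NA`.
#' @return an `IslandSpec`.
#' @export
islandSpec <- function(chromosome, position, targetLength,
                       fragFamily = "uniform", fragParams = NA_real_,
                       antisenseProb = 0.5, junctionIndelMax = 0) {
  new("IslandSpec", chromosome = as.character(chromosome),
      position = as.numeric(position), targetLength = as.numeric(targetLength),
      fragFamily = fragFamily, fragParams = as.numeric(fragParams),
      antisenseProb = antisenseProb,
      junctionIndelMax = as.numeric(junctionIndelMax))
}

#' ErrorModel: per-base read error rates
#'
#' Substitution, insertion and deletion rates applied independently per base
#' when simulating reads. The defaults sum to the ~15% aggregate error
#' typical of the nanopore long-read regime this package targets.
#'
#' @slot substitution,insertion,deletion per-base rates in `[0, 1)`.
#' @exportClass ErrorModel
setClass("ErrorModel",
  representation(substitution = "numeric", insertion = "numeric",
                 deletion = "numeric"),
  validity = function(object) {
    r <- c(object@substitution, object@insertion, object@deletion)
    if (any(r < 0) || any(r >= 1)) "rates must be in [0, 1)" else TRUE
  })

#' @describeIn ErrorModel constructor; defaults 0.05/0.05/0.05 (0.15 total).
#' @param substitution,insertion,deletion per-base rates.
#' @return an `ErrorModel`.
#' @export
errorModel <- function(substitution = 0.05, insertion = 0.05,
                       deletion = 0.05) {
  new("ErrorModel", substitution = substitution, insertion = insertion,
      deletion = deletion)
}

#' @describeIn ErrorModel an error-free model (all rates zero).
#' @export
perfectReads <- function() errorModel(0, 0, 0)

#' HitParams: alignment hit acceptance thresholds
#'
#' @slot minHitLength minimum hit length in bp (on both axes).
#' @slot minIdentity minimum alignment identity in (0, 1].
#' @slot mergeGap maximum gap (bp, both axes) across which colinear hits are
#'   fused, and the maximum within-chain gap of the internal mapper.
#' @exportClass HitParams
setClass("HitParams",
  representation(minHitLength = "numeric", minIdentity = "numeric",
                 mergeGap = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (object@minHitLength < 1) msg <- c(msg, "minHitLength must be >= 1")
    if (object@minIdentity <= 0 || object@minIdentity > 1)
      msg <- c(msg, "minIdentity must be in (0, 1]")
    if (length(msg)) msg else TRUE
  })

#' @describeIn HitParams constructor. Defaults (100 bp, 0.70, 200 bp) are
#'   tolerant of the ~15% long-read error regime while excluding spurious
#'   seeds.
#' @param minHitLength,minIdentity,mergeGap see slots.
#' @return a `HitParams`.
#' @export
hitParams <- function(minHitLength = 100, minIdentity = 0.70,
                      mergeGap = 200) {
  new("HitParams", minHitLength = minHitLength, minIdentity = minIdentity,
      mergeGap = mergeGap)
}

#' ClassifyParams: read classification thresholds
#'
#' @slot minConstructExtent minimum unmasked construct-aligned extent (bp)
#'   for a read to count as construct-positive.
#' @slot minFlank minimum genomic flank length (bp) outside the construct
#'   block for a border call.
#' @slot clusterDistance maximum distance (bp) between genomic junction
#'   estimates anchored to the same locus.
#' @slot maskPadding padding (bp) added around shared-native mask intervals.
#' @exportClass ClassifyParams
setClass("ClassifyParams",
  representation(minConstructExtent = "numeric", minFlank = "numeric",
                 clusterDistance = "numeric", maskPadding = "numeric"))

#' @describeIn ClassifyParams constructor (defaults 100 bp / 200 bp /
#'   10 kbp / 10 bp).
#' @param minConstructExtent,minFlank,clusterDistance,maskPadding see slots.
#' @return a `ClassifyParams`.
#' @export
classifyParams <- function(minConstructExtent = 100, minFlank = 200,
                           clusterDistance = 10000, maskPadding = 10) {
  new("ClassifyParams", minConstructExtent = minConstructExtent,
      minFlank = minFlank, clusterDistance = clusterDistance,
      maskPadding = maskPadding)
}

#' SharedNativeMask: construct intervals shared with the host genome
#'
#' Sorted, disjoint 0-based half-open intervals on the construct marking
#' content copied from (or highly similar to) the host genome. Construct
#' alignment falling entirely inside the mask is discounted when classifying
#' reads, which implements the false-positive filter.
#'
#' @slot intervals data.frame with columns `start`, `end` (0-based half-open,
#'   sorted, disjoint).
#' @slot constructLength construct length in bp.
#' @slot padding padding (bp) that was applied around raw intervals.
#' @exportClass SharedNativeMask
setClass("SharedNativeMask",
  representation(intervals = "data.frame", constructLength = "numeric",
                 padding = "numeric"),
  validity = function(object) {
    iv <- object@intervals
    if (!nrow(iv)) return(TRUE)
    if (any(iv$start < 0) || any(iv$end > object@constructLength))
      return("mask intervals must lie within the construct")
    if (is.unsorted(iv$start)) return("mask intervals must be sorted")
    if (any(utils::head(iv$end, -1) > utils::tail(iv$start, -1)))
      return("mask intervals must be disjoint")
    TRUE
  })

#' @describeIn SharedNativeMask constructor; merges and sorts raw intervals
#'   after applying `padding`.
#' @param starts,ends 0-based half-open raw intervals.
#' @param constructLength,padding see slots.
#' @return a `SharedNativeMask`.
#' @export
sharedNativeMask <- function(starts, ends, constructLength, padding = 0) {
  if (length(starts)) {
    ir <- reduce(IRanges(pmax(0, starts - padding) + 1L,
                         pmin(constructLength, ends + padding)))
    iv <- ranges0(ir)
  } else {
    iv <- data.frame(start = integer(0), end = integer(0))
  }
  new("SharedNativeMask", intervals = iv,
      constructLength = as.numeric(constructLength),
      padding = as.numeric(padding))
}

#' @describeIn SharedNativeMask mask intervals as a data.frame
#'   (0-based half-open).
#' @param x a `SharedNativeMask`.
#' @export
maskIntervals <- function(x) x@intervals

setMethod("show", "SharedNativeMask", function(object) {
  cat("SharedNativeMask: ", nrow(object@intervals), " interval(s), ",
      sum(object@intervals$end - object@intervals$start), " of ",
      object@constructLength, " bp masked (padding ", object@padding,
      " bp)\n", sep = "")
})
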