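# Read classification: the false-positive filter (masking construct regions
# shared with the host genome) and the per-read taxonomy
# (unmapped / genome_only / construct_only / left_border / right_border /
# spanning / false_positive / ambiguous).

#' Compute the shared-native mask by aligning the construct to the genome
#'
#' Aligns the construct sequence against the host genome and takes the union
#' of the construct-side intervals of all passing hits, padded and merged.
#' Construct alignment of a read that falls entirely inside this mask is
#' evidence only of host sequence (promoters/terminators copied into the
#' construct), not of the construct itself, and is filtered as false
#' positive.
#'
#' @param construct a [ConstructMap].
#' @param genome host genome [Biostrings::DNAStringSet].
#' @param params a [hitParams()].
#' @param padding bp added around each masked interval (default 10).
#' @return a [SharedNativeMask].
#' @export
computeSharedNativeMask <- function(construct, genome,
                                    params = hitParams(), padding = 10) {
  if (length(genome) == 0L || constructLength(construct) == 0L)
    stop("construct and genome must be non-empty")
  hits <- mapHits(DNAStringSet(setNames(constructSeq(construct),
                                        construct@id)),
                  genome, params, circular = FALSE, targetKind = "genome")
  sharedNativeMask(hits$read_start, hits$read_end,
                   constructLength(construct), padding = padding)
}

# Construct-axis footprint of hits as an IRanges, folding circular wrap-around
# (target_end beyond the construct length) back onto [0, L).
constructFootprint <- function(targetStarts, targetEnds, L) {
  wrap <- targetEnds > L
  s <- c(targetStarts, rep(0L, sum(wrap)))
  e <- c(pmin(targetEnds, L), targetEnds[wrap] - L)
  asRanges0(s, e)
}

#' Unmasked construct-aligned extent of one read
#'
#' Projects the construct hits of a read onto the construct axis, subtracts
#' the shared-native mask, and returns the per-base union width (overlapping
#' hits are not double-counted). This is the quantity thresholded by the
#' false-positive filter.
#'
#' @param hits construct hits of a single read (hit data.frame).
#' @param mask a [SharedNativeMask].
#' @return unmasked extent in bp.
#' @export
unmaskedExtent <- function(hits, mask) {
  if (nrow(hits) == 0L) return(0)
  if (length(unique(hits$read_id)) > 1L)
    stop("hits must belong to a single read")
  fp <- reduce(constructFootprint(hits$target_start, hits$target_end,
                                  mask@constructLength))
  mk <- maskIntervals(mask)
  if (nrow(mk)) fp <- setdiff(fp, asRanges0(mk$start, mk$end))
  sum(width(fp))
}

#' Classify one read from its construct and genome hits
#'
#' Implements the read taxonomy. A read is `unmapped` with no passing hits;
#' `genome_only` if its construct evidence (if any) has zero unmasked
#' extent and genome hits exist; `false_positive` if construct hits exist but
#' their unmasked extent is below `minConstructExtent`; otherwise the read is
#' construct-positive and the genomic flanks outside its construct block
#' decide between `construct_only` (no flank of at least `minFlank` bp),
#' `left_border`/`right_border` (one flank; sides named on the genome axis,
#' left = flank reaching the smaller genomic coordinate at the junction),
#' `spanning` (two flanks anchored compatibly to one locus) and `ambiguous`
#' (flanks anchored to different chromosomes or loci further apart than
#' `clusterDistance` -- possible chimeras, logged but excluded from island
#' calling). Genome hits overlapping the construct block (mask leak-through)
#' contribute no flank.
#'
#' @param readLength read length in bp.
#' @param constructHits,genomeHits hit data.frames for this read.
#' @param mask a [SharedNativeMask].
#' @param params a [ClassifyParams].
#' @return list with `class` and, for border/spanning reads, `anchor`: a
#'   one-row data.frame with the chromosome, flank intervals, genomic
#'   junction estimates per side, the read-axis construct extent, and (for
#'   spanning reads) the read-space island size between the junctions.
#' @export
classifyRead <- function(readLength, constructHits, genomeHits, mask,
                         params = classifyParams()) {
  ids <- unique(c(constructHits$read_id, genomeHits$read_id))
  if (length(ids) > 1L) stop("hits from multiple reads supplied")
  nC <- nrow(constructHits); nG <- nrow(genomeHits)
  if (nC + nG == 0L) return(list(class = "unmapped", anchor = NULL))
  extent <- if (nC) unmaskedExtent(constructHits, mask) else 0
  if (extent < params@minConstructExtent) {
    if (extent == 0) {
      if (nG > 0L) return(list(class = "genome_only", anchor = NULL))
      return(list(class = "false_positive", anchor = NULL))
    }
    return(list(class = "false_positive", anchor = NULL))
  }
  # Construct block on the read: span of all construct hits. Masked hits
  # still demonstrate construct-compatible sequence (the mask only gates the
  # extent threshold above), so they belong to the block -- otherwise the
  # genomic alignment of a shared-native segment inside an island read would
  # masquerade as a genomic flank.
  blockStart <- min(constructHits$read_start)
  blockEnd <- max(constructHits$read_end)
  if (nG == 0L)
    return(list(class = "construct_only", anchor = NULL))
  flank5 <- pmax(0, pmin(genomeHits$read_end, blockStart) -
                      genomeHits$read_start)
  flank3 <- pmax(0, genomeHits$read_end -
                      pmax(genomeHits$read_start, blockEnd))
  i5 <- if (any(flank5 >= params@minFlank)) which.max(flank5) else NA
  i3 <- if (any(flank3 >= params@minFlank)) which.max(flank3) else NA
  if (is.na(i5) && is.na(i3))
    return(list(class = "construct_only", anchor = NULL))
  # junction positions on the read: the inner boundaries of the flank hits;
  # construct extent is measured on the island side of the junction(s) only
  innerL <- if (!is.na(i5)) genomeHits$read_end[i5] else 0L
  innerR <- if (!is.na(i3)) genomeHits$read_start[i3] else readLength
  readExtent <- unionWidth(pmax(constructHits$read_start, innerL),
                           pmin(constructHits$read_end, innerR))

  side_of <- function(i, readFive) {
    plus <- genomeHits$strand[i] == "+"
    if (readFive == plus) "left" else "right"
  }
  junction_of <- function(i, side)
    if (side == "left") genomeHits$target_end[i] else
      genomeHits$target_start[i]

  mkAnchor <- function(cls, chrom, jl, jr, spanSize) {
    data.frame(read_id = ids, class = cls, chromosome = chrom,
               junction_left = jl, junction_right = jr,
               construct_extent = readExtent, span_size = spanSize,
               stringsAsFactors = FALSE)
  }

  if (!is.na(i5) && !is.na(i3)) {
    s5 <- side_of(i5, TRUE); s3 <- side_of(i3, FALSE)
    chrom5 <- genomeHits$target_id[i5]; chrom3 <- genomeHits$target_id[i3]
    j5 <- junction_of(i5, s5); j3 <- junction_of(i3, s3)
    compatible <- chrom5 == chrom3 && s5 != s3
    if (compatible) {
      jl <- if (s5 == "left") j5 else j3
      jr <- if (s5 == "left") j3 else j5
      if (jr - jl >= -1000 && jr - jl <= params@clusterDistance) {
        # read-space island size between the inner flank boundaries
        spanSize <- innerR - innerL
        return(list(class = "spanning",
                    anchor = mkAnchor("spanning", chrom5, jl, jr, spanSize)))
      }
    }
    return(list(class = "ambiguous", anchor = NULL))
  }
  i <- if (!is.na(i5)) i5 else i3
  side <- side_of(i, !is.na(i5))
  j <- junction_of(i, side)
  cls <- if (side == "left") "left_border" else "right_border"
  anchor <- mkAnchor(cls, genomeHits$target_id[i],
                     if (side == "left") j else NA_real_,
                     if (side == "right") j else NA_real_, NA_real_)
  list(class = cls, anchor = anchor)
}

#' Classify every read of a sequencing run
#'
#' Driver applying [classifyRead()] to each read in the universe defined by
#' `readLengths` (reads with no hits are `unmapped`).
#'
#' @param constructHits,genomeHits hit data.frames for all reads.
#' @param readLengths named integer vector of read lengths (defines the read
#'   universe).
#' @param mask a [SharedNativeMask].
#' @param params a [ClassifyParams].
#' @return list with `classes` (data.frame `read_id`, `class`) and `anchors`
#'   (data.frame of border/spanning anchors, zero rows when none).
#' @export
classifyReads <- function(constructHits, genomeHits, readLengths, mask,
                          params = classifyParams()) {
  ids <- names(readLengths)
  cIdx <- split(seq_len(nrow(constructHits)), constructHits$read_id)
  gIdx <- split(seq_len(nrow(genomeHits)), genomeHits$read_id)
  cls <- character(length(ids))
  anchors <- vector("list", length(ids))
  hasC <- ids %in% names(cIdx)
  hasG <- ids %in% names(gIdx)
  # fast paths: the bulk of any run is reads with hits to one target only
  cls[!hasC & hasG] <- "genome_only"
  cls[!hasC & !hasG] <- "unmapped"
  for (i in which(hasC)) {
    id <- ids[i]
    ch <- constructHits[cIdx[[id]], , drop = FALSE]
    gh <- if (hasG[i]) genomeHits[gIdx[[id]], , drop = FALSE] else
      emptyHitFrame()
    res <- classifyRead(readLengths[[i]], ch, gh, mask, params)
    cls[i] <- res$class
    anchors[[i]] <- res$anchor
  }
  anchors <- anchors[!vapply(anchors, is.null, logical(1))]
  anchors <- if (length(anchors)) do.call(rbind, anchors) else
    data.frame(read_id = character(0), class = character(0),
               chromosome = character(0), junction_left = numeric(0),
               junction_right = numeric(0), construct_extent = numeric(0),
               span_size = numeric(0), stringsAsFactors = FALSE)
  list(classes = data.frame(read_id = ids, class = cls,
                            stringsAsFactors = FALSE),
       anchors = anchors)
}

#' Summarise read classes into run-level counts
#'
#' Produces the per-line summary: totals, mean read length, estimated fold
#' coverage (total nucleotides / genome size), one count per class, and the
#' number of reads aligning to the construct in any way (construct_only +
#' borders + spanning + false_positive).
#'
#' @param classes data.frame (`read_id`, `class`) from [classifyReads()].
#' @param readLengths named integer vector of read lengths.
#' @param genomeSize genome size in bp used for the coverage estimate.
#' @return a one-row data.frame of summary counts.
#' @export
tabulateClasses <- function(classes, readLengths, genomeSize) {
  stopifnot(genomeSize > 0)
  n <- nrow(classes)
  totalNt <- sum(as.numeric(readLengths[classes$read_id]))
  counts <- table(factor(classes$class, levels = READ_CLASSES))
  out <- data.frame(
    total_reads = n, total_nucleotides = totalNt,
    mean_read_length = if (n) totalNt / n else 0,
    estimated_coverage = totalNt / genomeSize,
    stringsAsFactors = FALSE)
  for (cl in READ_CLASSES) out[[cl]] <- as.integer(counts[[cl]])
  out$total_aligning_construct <- out$construct_only + out$left_border +
    out$right_border + out$spanning + out$false_positive
  out
}
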