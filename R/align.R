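# Local alignment hits via the internal k-mer seed-and-chain mapper.
#
# A hit is one local alignment between a read interval and a target
# interval, 0-based half-open on both axes, with the read interval always on
# the forward-oriented read. Hits are plain data.frames with columns
# read_id, read_length, read_start, read_end, target_id, target_start,
# target_end, strand, identity, n_seeds, target_kind.

#' Map reads against a target with the internal seed-and-chain mapper
#'
#' Seeds exact 13-mers, groups them per strand into diagonal bands, chains
#' colinear seeds along the read, and reports one hit per chain. Hit
#' boundaries are those of the terminal seeds (exact on error-free input,
#' conservatively inside the true aligned interval under sequencing error);
#' identity is estimated from the chained seed density as
#' `(m / windows)^(1/k)`, which is exact (1.0) for error-free hits and
#' tracks the per-base accuracy of noisy ones. Hits to a circular target
#' that cross the origin are reported as a single hit whose `target_end`
#' exceeds the target length (coordinates modulo length).
#'
#' @param reads a named [Biostrings::DNAStringSet] (or named character
#'   vector).
#' @param target a [Biostrings::DNAStringSet] (one entry per target
#'   sequence), a single sequence, or a [ConstructMap] (circularity is then
#'   taken from the map).
#' @param params a [hitParams()].
#' @param circular logical; single-sequence targets only.
#' @param targetKind label stored in the `target_kind` column, conventionally
#'   `"construct"` or `"genome"`.
#' @param chainGap maximum seed-free stretch (bp, both axes) bridged within
#'   one chain. At ~15% error the gaps between error-free 13-mers form
#'   runs that regularly exceed 200 bp, so this is deliberately much larger
#'   than `mergeGap`; it must stay below the smallest structural distance of
#'   interest.
#' @return a hit data.frame (zero rows if nothing aligns).
#' @export
mapHits <- function(reads, target, params = hitParams(), circular = FALSE,
                    targetKind = "genome", chainGap = 1000) {
  if (is(target, "ConstructMap")) {
    circular <- target@circular
    target <- DNAStringSet(setNames(constructSeq(target), target@id))
  }
  if (is.character(target)) target <- DNAStringSet(target)
  if (is.null(names(target)))
    names(target) <- paste0("target", seq_along(target))
  if (is.character(reads)) reads <- DNAStringSet(reads)
  if (length(reads) == 0L) return(emptyHitFrame())
  if (is.null(names(reads)))
    names(reads) <- paste0("read", seq_along(reads))
  if (circular && length(target) != 1L)
    stop("circular mapping requires a single target sequence")
  L <- width(target)
  tseq <- as.character(target)
  if (circular) tseq <- paste0(tseq, tseq)
  hits <- .cpp_kmer_map(as.character(reads), tseq, 13L,
                        as.integer(params@minHitLength), params@minIdentity,
                        as.integer(max(chainGap, params@mergeGap)), 60L, 256L)
  if (nrow(hits) == 0L) return(emptyHitFrame())
  out <- data.frame(
    read_id = names(reads)[hits$read],
    read_length = width(reads)[hits$read],
    read_start = hits$read_start, read_end = hits$read_end,
    target_id = names(target)[hits$target + 1L],
    target_start = hits$target_start, target_end = hits$target_end,
    strand = ifelse(hits$minus == 1L, "-", "+"),
    identity = hits$identity, n_seeds = hits$n_seeds,
    target_kind = targetKind, stringsAsFactors = FALSE)
  if (circular) out <- foldCircularHits(out, L)
  out[order(out$read_id, out$read_start, out$target_start), , drop = FALSE]
}

# Fold hits found on a doubled circular target back to [0, L): hits lying
# fully in the second copy are shifted by -L; duplicates and truncated
# artefacts of origin-crossing hits (hits whose read interval is contained
# in another hit's) are dropped. Origin-crossing hits keep target_end > L.
foldCircularHits <- function(hits, L) {
  shift <- hits$target_start >= L
  hits$target_start[shift] <- hits$target_start[shift] - L
  hits$target_end[shift] <- hits$target_end[shift] - L
  key <- paste(hits$read_id, hits$read_start, hits$read_end,
               hits$target_start, hits$target_end, hits$strand)
  hits <- hits[!duplicated(key), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (id in unique(hits$read_id)) {
    idx <- which(hits$read_id == id)
    if (length(idx) < 2L) next
    for (a in idx) for (b in idx) {
      if (a == b || !keep[a]) next
      if (hits$strand[a] == hits$strand[b] &&
          hits$read_start[a] >= hits$read_start[b] &&
          hits$read_end[a] <= hits$read_end[b] &&
          (hits$read_end[a] - hits$read_start[a]) <
            (hits$read_end[b] - hits$read_start[b]) && keep[b])
        keep[a] <- FALSE
    }
  }
  hits[keep, , drop = FALSE]
}

#' Fuse colinear hits separated by small gaps
#'
#' Hits of one read that lie on the same target and strand, progress
#' consistently on both axes, and are separated by at most `mergeGap` bp on
#' both axes are fused into one hit whose identity is the length-weighted
#' mean. High-error reads fragment alignments; fusing them restores the
#' underlying contiguous aligned block.
#'
#' @param hits a hit data.frame (any mix of reads/targets).
#' @param mergeGap maximum gap in bp on both axes.
#' @return a hit data.frame.
#' @export
mergeColinearHits <- function(hits, mergeGap = 200) {
  if (nrow(hits) < 2L) return(hits)
  grp <- paste(hits$read_id, hits$target_id, hits$strand, hits$target_kind)
  pieces <- lapply(split(seq_len(nrow(hits)), grp), function(idx) {
    sub <- hits[idx[order(hits$read_start[idx])], , drop = FALSE]
    if (nrow(sub) == 1L) return(sub)
    minus <- sub$strand[1] == "-"
    out <- sub[1, , drop = FALSE]
    for (i in 2:nrow(sub)) {
      cur <- sub[i, ]
      last <- out[nrow(out), ]
      rgap <- cur$read_start - last$read_end
      tgap <- if (!minus) cur$target_start - last$target_end
              else last$target_start - cur$target_end
      if (rgap >= -30 && rgap <= mergeGap && tgap >= -30 && tgap <= mergeGap) {
        w1 <- last$read_end - last$read_start
        w2 <- cur$read_end - cur$read_start
        last$identity <- (last$identity * w1 + cur$identity * w2) / (w1 + w2)
        last$n_seeds <- last$n_seeds + cur$n_seeds
        last$read_end <- max(last$read_end, cur$read_end)
        last$read_start <- min(last$read_start, cur$read_start)
        last$target_start <- min(last$target_start, cur$target_start)
        last$target_end <- max(last$target_end, cur$target_end)
        out[nrow(out), ] <- last
      } else {
        out <- rbind(out, cur)
      }
    }
    out
  })
  res <- do.call(rbind, pieces)
  rownames(res) <- NULL
  res[order(res$read_id, res$read_start, res$target_start), , drop = FALSE]
}
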