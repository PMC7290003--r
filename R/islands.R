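# Island calling: cluster border anchors into integration islands, resolve
# insertion sites, size islands (exactly when a spanning read exists,
# otherwise as a lower bound), reconstruct concatemer structure, and
# annotate genomic feature context.

#' Cluster border anchors into island candidates
#'
#' Anchors on the same chromosome whose genomic junction estimates lie
#' within `clusterDistance` of each other (single linkage) support one
#' integration locus. Spanning anchors contribute both junctions.
#'
#' @param anchors anchor data.frame from [classifyReads()].
#' @param clusterDistance linkage distance in bp (default 10 kbp).
#' @return list of candidate anchor data.frames (possibly empty).
#' @export
clusterBorderAnchors <- function(anchors, clusterDistance = 10000) {
  if (is.null(anchors) || nrow(anchors) == 0L) return(list())
  j <- ifelse(is.na(anchors$junction_left), anchors$junction_right,
              anchors$junction_left)
  gr <- GRanges(anchors$chromosome, IRanges(round(j) + 1L, round(j) + 1L))
  red <- reduce(gr, min.gapwidth = clusterDistance)
  grp <- GenomicRanges::findOverlaps(gr, red, select = "first")
  lapply(split(seq_len(nrow(anchors)), grp),
         function(idx) anchors[idx, , drop = FALSE])
}

#' Resolve the insertion site of an island candidate
#'
#' The left boundary is the maximum genomic coordinate reached by left-flank
#' alignments and the right boundary the minimum reached by right-flank
#' alignments; the gap between them is the insertion site interval and its
#' width the resolution. Flank overlap (junction microhomology) collapses to
#' a zero-width point at the midpoint. One-sided candidates get a one-sided
#' breakpoint with undefined resolution.
#'
#' @param candidate anchor data.frame of one candidate.
#' @return list with `chromosome`, `left_end`, `right_start` (0-based),
#'   `site_start`, `site_end` (1-based inclusive report frame),
#'   `resolution` (bp, `NA` if one-sided) and `one_sided`.
#' @export
resolveSite <- function(candidate) {
  chrom <- candidate$chromosome[1]
  jl <- candidate$junction_left[!is.na(candidate$junction_left)]
  jr <- candidate$junction_right[!is.na(candidate$junction_right)]
  if (length(jl) == 0L && length(jr) == 0L)
    stop("candidate carries no junction estimates")
  if (length(jl) == 0L || length(jr) == 0L) {
    b <- if (length(jl)) max(jl) else min(jr)
    return(list(chromosome = chrom, left_end = if (length(jl)) b else NA,
                right_start = if (length(jr)) b else NA,
                site_start = b + as.integer(length(jl) > 0),
                site_end = b + as.integer(length(jl) > 0),
                resolution = NA_real_, one_sided = TRUE))
  }
  leftEnd <- max(jl); rightStart <- min(jr)
  if (rightStart < leftEnd) {
    mid <- floor((leftEnd + rightStart) / 2)
    leftEnd <- rightStart <- mid
  }
  list(chromosome = chrom, left_end = leftEnd, right_start = rightStart,
       site_start = leftEnd + 1, site_end = rightStart,
       resolution = rightStart - leftEnd, one_sided = FALSE)
}

#' Size an island candidate
#'
#' With a spanning anchor the island is complete and its size is the
#' read-space extent between the two junctions of that read (robust to
#' intra-read deletions); otherwise the size is a lower bound: the largest
#' left-anchor construct extent plus the largest right-anchor construct
#' extent.
#'
#' @param candidate anchor data.frame of one candidate.
#' @return list with `size_bp`, `complete`, `size_is_lower_bound`,
#'   `left_extent`, `right_extent`.
#' @export
islandSize <- function(candidate) {
  sp <- candidate[candidate$class == "spanning", , drop = FALSE]
  lb <- candidate[candidate$class == "left_border", , drop = FALSE]
  rb <- candidate[candidate$class == "right_border", , drop = FALSE]
  leftExtent <- if (nrow(lb)) max(lb$construct_extent) else 0
  rightExtent <- if (nrow(rb)) max(rb$construct_extent) else 0
  if (nrow(sp)) {
    return(list(size_bp = max(sp$span_size), complete = TRUE,
                size_is_lower_bound = FALSE,
                left_extent = leftExtent, right_extent = rightExtent))
  }
  list(size_bp = leftExtent + rightExtent, complete = FALSE,
       size_is_lower_bound = TRUE,
       left_extent = leftExtent, right_extent = rightExtent)
}

#' Segment the construct-aligned portion of a read into ordered fragments
#'
#' Orders the (merged) construct hits of one read by read coordinate,
#' resolves overlaps by keeping the longer hit (ties: higher identity, then
#' leftmost), and reports the resulting concatemer structure: one row per
#' fragment with its read interval, construct interval and orientation.
#'
#' @param constructHits construct hits of one read.
#' @param constructLength construct length in bp (for wrap-around
#'   bookkeeping; optional).
#' @return data.frame with columns `index`, `read_start`, `read_end`,
#'   `construct_start`, `construct_end`, `orientation`.
#' @export
segmentConcatemer <- function(constructHits, constructLength = NA) {
  if (nrow(constructHits) == 0L)
    return(data.frame(index = integer(0), read_start = integer(0),
                      read_end = integer(0), construct_start = integer(0),
                      construct_end = integer(0), orientation = character(0),
                      stringsAsFactors = FALSE))
  if (length(unique(constructHits$read_id)) > 1L)
    stop("hits must belong to a single read")
  h <- constructHits
  span <- h$read_end - h$read_start
  ord <- order(-span, -h$identity, h$read_start)
  keep <- logical(nrow(h))
  accS <- integer(0); accE <- integer(0)
  for (i in ord) {
    ov <- sum(pmax(0, pmin(h$read_end[i], accE) -
                        pmax(h$read_start[i], accS)))
    if (ov <= 30) {
      keep[i] <- TRUE
      accS <- c(accS, h$read_start[i]); accE <- c(accE, h$read_end[i])
    }
  }
  h <- h[keep, , drop = FALSE]
  h <- h[order(h$read_start), , drop = FALSE]
  data.frame(index = seq_len(nrow(h)), read_start = h$read_start,
             read_end = h$read_end, construct_start = h$target_start,
             construct_end = h$target_end,
             orientation = ifelse(h$strand == "+", "sense", "antisense"),
             stringsAsFactors = FALSE)
}

#' Canonicalise a concatemer structure
#'
#' Merges consecutive same-orientation fragments that continue each other in
#' construct coordinates within `tol` bp (modulo the construct length for
#' circular constructs). Such junctions are invisible in sequence, so the
#' canonical (maximal-fragment) form is the structure any aligner can
#' recover; the simulator avoids generating them, but truth structures are
#' canonicalised before comparison for safety.
#'
#' @param structure a structure data.frame (from [segmentConcatemer()] or
#'   the simulator truth).
#' @param constructLength construct length in bp.
#' @param tol continuation tolerance in bp.
#' @return a structure data.frame.
#' @export
canonicalStructure <- function(structure, constructLength, tol = 30) {
  st <- structure
  names(st)[names(st) == "island_start"] <- "read_start"
  names(st)[names(st) == "island_end"] <- "read_end"
  if (nrow(st) < 2L) {
    st$index <- seq_len(nrow(st))
    return(st[, c("index", "read_start", "read_end", "construct_start",
                  "construct_end", "orientation")])
  }
  out <- st[1, , drop = FALSE]
  L <- constructLength
  for (i in 2:nrow(st)) {
    cur <- st[i, ]; last <- out[nrow(out), ]
    cont <- FALSE
    if (cur$orientation == last$orientation) {
      gap <- if (cur$orientation == "sense")
        (cur$construct_start - last$construct_end) %% L
      else (last$construct_start %% L - cur$construct_end) %% L
      cont <- min(gap, L - gap) <= tol
    }
    if (cont) {
      last$read_end <- cur$read_end
      if (cur$orientation == "sense") {
        last$construct_end <- last$construct_end +
          (cur$construct_end - cur$construct_start)
      } else {
        last$construct_start <- last$construct_start -
          (cur$construct_end - cur$construct_start)
      }
      out[nrow(out), ] <- last
    } else {
      out <- rbind(out, cur)
    }
  }
  neg <- out$construct_start < 0
  out$construct_start[neg] <- out$construct_start[neg] + L
  out$construct_end[neg] <- out$construct_end[neg] + L
  out$index <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("index", "read_start", "read_end", "construct_start",
          "construct_end", "orientation")]
}

#' Count intact expression cassettes in a concatemer structure
#'
#' A fragment carries an intact cassette when its construct interval fully
#' contains the cassette interval, in either orientation (wrap-around on
#' circular constructs is handled).
#'
#' @param structure a structure data.frame.
#' @param cassetteInterval numeric `c(start, end)`, 0-based half-open on the
#'   construct.
#' @param constructLength construct length in bp.
#' @return integer count.
#' @export
countIntactCassettes <- function(structure, cassetteInterval,
                                 constructLength) {
  cs <- cassetteInterval[1]; ce <- cassetteInterval[2]
  if (cs < 0 || ce > constructLength || cs >= ce)
    stop("cassette interval must lie within the construct")
  s <- structure$construct_start; e <- structure$construct_end
  sum((s <= cs & ce <= e) | (s <= cs + constructLength &
                             ce + constructLength <= e))
}

#' Annotate an island's genomic feature context
#'
#' Reports the feature containing the insertion site (if any) and the
#' nearest features upstream and downstream within 1 kbp. Upstream and
#' downstream are defined on the genome coordinate axis; distances are the
#' gap in bp between the closest boundaries (0 if touching).
#'
#' @param chromosome,siteStart,siteEnd the insertion site (1-based
#'   inclusive).
#' @param features a [GenomicRanges::GRanges] of annotation features (e.g.
#'   from [rtracklayer::import()] of a GFF3), with feature ids in the `ID`
#'   or `Name` metadata column.
#' @param maxDistance report flanking features within this distance
#'   (default 1000 bp).
#' @return list with `within_feature` (id or `NA`), `within_type`,
#'   `upstream_feature`, `upstream_distance`, `downstream_feature`,
#'   `downstream_distance`.
#' @export
annotateIsland <- function(chromosome, siteStart, siteEnd, features,
                           maxDistance = 1000) {
  if (!chromosome %in% as.character(GenomeInfoDb::seqlevels(features)))
    stop("chromosome '", chromosome, "' not present in the annotation")
  feat <- features[as.character(seqnames(features)) == chromosome]
  fid <- featureIds(feat)
  ftype <- if (!is.null(feat$type)) as.character(feat$type) else
    rep(NA_character_, length(feat))
  s <- start(feat); e <- end(feat)
  siteEnd <- max(siteEnd, siteStart)
  within <- which(s <= siteEnd & e >= siteStart)
  up <- which(e < siteStart)
  dn <- which(s > siteEnd)
  upD <- if (length(up)) siteStart - e[up] - 1 else numeric(0)
  dnD <- if (length(dn)) s[dn] - siteEnd - 1 else numeric(0)
  ui <- if (length(up) && min(upD) <= maxDistance) up[which.min(upD)] else NA
  di <- if (length(dn) && min(dnD) <= maxDistance) dn[which.min(dnD)] else NA
  list(
    within_feature = if (length(within)) fid[within[1]] else NA_character_,
    within_type = if (length(within)) ftype[within[1]] else NA_character_,
    upstream_feature = if (!is.na(ui)) fid[ui] else NA_character_,
    upstream_distance = if (!is.na(ui)) min(upD) else NA_real_,
    downstream_feature = if (!is.na(di)) fid[di] else NA_character_,
    downstream_distance = if (!is.na(di)) min(dnD) else NA_real_)
}

featureIds <- function(feat) {
  m <- mcols(feat)
  if ("ID" %in% names(m) && any(!is.na(m$ID))) as.character(m$ID)
  else if ("Name" %in% names(m)) as.character(m$Name)
  else paste0("feature", seq_along(feat))
}

#' Call integration islands from border anchors
#'
#' Clusters anchors, resolves each candidate's insertion site, sizes it, and
#' (optionally) attaches feature context and per-read concatemer structures.
#'
#' @param anchors anchor data.frame from [classifyReads()].
#' @param params a [ClassifyParams] (for `clusterDistance`).
#' @param constructHits construct hits of all reads (for structures;
#'   optional).
#' @param features optional annotation [GenomicRanges::GRanges].
#' @return data.frame catalogue: one row per island with site, resolution,
#'   completeness, size (and whether it is a lower bound), supporting read
#'   counts, extents, one-sided flag, feature context columns, and a
#'   `structures` list column of per-read structure data.frames keyed by
#'   read id.
#' @export
callIslands <- function(anchors, params = classifyParams(),
                        constructHits = NULL, features = NULL) {
  cands <- clusterBorderAnchors(anchors, params@clusterDistance)
  rows <- lapply(seq_along(cands), function(i) {
    cand <- cands[[i]]
    site <- resolveSite(cand)
    size <- islandSize(cand)
    row <- data.frame(
      island_id = paste0(site$chromosome, ":", site$site_start),
      chromosome = site$chromosome,
      site_start = site$site_start, site_end = site$site_end,
      resolution = site$resolution, one_sided = site$one_sided,
      complete = size$complete,
      size_bp = size$size_bp, size_is_lower_bound = size$size_is_lower_bound,
      left_extent = size$left_extent, right_extent = size$right_extent,
      n_left = sum(cand$class == "left_border"),
      n_right = sum(cand$class == "right_border"),
      n_spanning = sum(cand$class == "spanning"),
      supporting_reads = paste(cand$read_id, collapse = ","),
      stringsAsFactors = FALSE)
    if (!is.null(features)) {
      fc <- annotateIsland(site$chromosome, site$site_start, site$site_end,
                           features)
      row <- cbind(row, as.data.frame(fc, stringsAsFactors = FALSE))
    }
    row
  })
  cat <- if (length(rows)) do.call(rbind, rows) else
    data.frame(island_id = character(0), chromosome = character(0),
               site_start = numeric(0), site_end = numeric(0),
               resolution = numeric(0), one_sided = logical(0),
               complete = logical(0), size_bp = numeric(0),
               size_is_lower_bound = logical(0), left_extent = numeric(0),
               right_extent = numeric(0), n_left = integer(0),
               n_right = integer(0), n_spanning = integer(0),
               supporting_reads = character(0), stringsAsFactors = FALSE)
  if (!is.null(constructHits) && nrow(cat)) {
    cat$structures <- lapply(seq_len(nrow(cat)), function(i) {
      ids <- strsplit(cat$supporting_reads[i], ",", fixed = TRUE)[[1]]
      structs <- lapply(ids, function(id)
        segmentConcatemer(
          constructHits[constructHits$read_id == id, , drop = FALSE]))
      setNames(structs, ids)
    })
  }
  rownames(cat) <- NULL
  cat
}
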