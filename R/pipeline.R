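# Pipeline orchestration: end-to-end detection, configuration files, report
# outputs mirroring the per-line summary and island catalogue tables, and a
# simulation benchmark closing the loop against generator truth.

#' Run the integration detection pipeline on in-memory objects
#'
#' Maps reads against construct and genome, computes the shared-native
#' mask, classifies every read, tabulates summary counts, calls islands and
#' computes size estimates. This is the computational core behind
#' [runDetect()].
#'
#' @param reads named [Biostrings::DNAStringSet] of reads.
#' @param genome host reference [Biostrings::DNAStringSet].
#' @param construct a [ConstructMap].
#' @param hitPar a [hitParams()].
#' @param classPar a [classifyParams()].
#' @param genomeSize genome size used for coverage estimation (defaults to
#'   the reference length; on real data the effective genome size may
#'   differ from the assembly and should be supplied explicitly).
#' @param features optional annotation [GenomicRanges::GRanges].
#' @param constructHits,genomeHits optional precomputed hit frames (e.g.
#'   from [parseAlignments()]); when supplied the internal mapper is not
#'   run for that target.
#' @return list with `construct_hits`, `genome_hits`, `mask`, `classes`,
#'   `anchors`, `summary`, `islands`, `estimates`.
#' @export
detectIntegration <- function(reads, genome, construct,
                              hitPar = hitParams(),
                              classPar = classifyParams(),
                              genomeSize = NULL, features = NULL,
                              constructHits = NULL, genomeHits = NULL) {
  if (is.null(genomeSize)) genomeSize <- sum(as.numeric(width(genome)))
  readLengths <- setNames(width(reads), names(reads))
  if (is.null(constructHits))
    constructHits <- mapHits(reads, construct, hitPar,
                             targetKind = "construct")
  constructHits <- mergeColinearHits(constructHits, hitPar@mergeGap)
  if (is.null(genomeHits))
    genomeHits <- mapHits(reads, genome, hitPar, targetKind = "genome")
  genomeHits <- mergeColinearHits(genomeHits, hitPar@mergeGap)
  mask <- computeSharedNativeMask(construct, genome, hitPar,
                                  classPar@maskPadding)
  cls <- classifyReads(constructHits, genomeHits, readLengths, mask,
                       classPar)
  summary <- tabulateClasses(cls$classes, readLengths, genomeSize)
  islands <- callIslands(cls$anchors, classPar, constructHits, features)
  coverage <- summary$estimated_coverage
  ni <- constructOnlyNucleotides(cls$classes, readLengths)
  known <- islands$size_bp[islands$complete]
  # Depth for the read-budget formula: host-genome coverage. The
  # construct-only nucleotides are the budget being converted to length, so
  # including them in the depth estimate would count the islands twice; at
  # whole-genome scale the difference is negligible (ni << total), but it
  # matters when the transgene fraction is appreciable.
  hostCoverage <- (summary$total_nucleotides - ni) / genomeSize
  estimates <- list(
    genome_size = genomeSize, coverage = coverage,
    host_coverage = hostCoverage,
    genome_covered_probability = clarkeCarbonProbability(coverage),
    construct_only_nucleotides = ni,
    known_island_lengths = known,
    unresolved_island_size =
      if (hostCoverage > 0) unresolvedIslandSize(ni, known, hostCoverage)
      else NA,
    construct_length = constructLength(construct))
  estimates$full_copy_equivalents <-
    if (!is.na(estimates$unresolved_island_size))
      fullCopyEquivalents(estimates$unresolved_island_size,
                          constructLength(construct)) else NA
  list(construct_hits = constructHits, genome_hits = genomeHits,
       mask = mask, classes = cls$classes, anchors = cls$anchors,
       summary = summary, islands = islands, estimates = estimates)
}

#' Read a plain-text key=value pipeline configuration
#'
#' Lines of the form `key = value`; `#` starts a comment. Recognised keys:
#' paths (`reads`, `genome`, `construct_fasta`, `construct_elements`,
#' `annotation`, `alignments_construct`, `alignments_genome`,
#' `alignment_dialect`, `out_dir`), numeric parameters (`seed`,
#' `genome_size`, `min_hit_length`, `min_identity`, `merge_gap`,
#' `min_construct_extent`, `min_flank`, `cluster_distance`, `mask_padding`,
#' `cassette_start`, `cassette_end`) and `circular` (true/false).
#'
#' @param path configuration file.
#' @return named list of configuration values (numbers parsed).
#' @export
readPipelineConfig <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  bad <- which(vapply(kv, length, integer(1)) != 3L)
  if (length(bad)) stop("malformed config line: ", lines[bad[1]])
  keys <- vapply(kv, `[[`, character(1), 2)
  vals <- trimws(vapply(kv, `[[`, character(1), 3))
  out <- lapply(vals, function(v) {
    if (tolower(v) %in% c("true", "false")) return(tolower(v) == "true")
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  setNames(out, keys)
}

configParams <- function(config) {
  gv <- function(key, default) {
    if (!is.null(config[[key]])) config[[key]] else default
  }
  list(
    hit = hitParams(
      minHitLength = gv("min_hit_length", 100),
      minIdentity = gv("min_identity", 0.70),
      mergeGap = gv("merge_gap", 200)),
    classify = classifyParams(
      minConstructExtent = gv("min_construct_extent", 100),
      minFlank = gv("min_flank", 200),
      clusterDistance = gv("cluster_distance", 10000),
      maskPadding = gv("mask_padding", 10)))
}

#' Build a [ConstructMap] from a FASTA and an optional element table
#'
#' @param fasta construct FASTA (single record).
#' @param elementsTsv optional TSV with columns `label`, `start`, `end`
#'   (0-based half-open).
#' @param circular logical.
#' @return a [ConstructMap].
#' @export
constructMapFromFiles <- function(fasta, elementsTsv = NULL,
                                  circular = TRUE) {
  seqs <- readSequences(fasta)
  if (length(seqs) != 1L) stop("construct FASTA must hold a single record")
  elements <- if (!is.null(elementsTsv) && nzchar(elementsTsv))
    readTsv(elementsTsv) else
    data.frame(label = character(0), start = integer(0), end = integer(0))
  ConstructMap(id = names(seqs), sequence = as.character(seqs[[1]]),
               circular = circular, elements = elements)
}

#' Run the detection pipeline from a configuration file
#'
#' Reads the configured inputs, runs [detectIntegration()], and writes the
#' report files into the output directory: per-read classes
#' (`read_classes.tsv`), summary counts (`summary.tsv`), the island
#' catalogue (`islands.tsv`, `islands.bed`), per-island concatemer
#' structures (`concatemers.tsv`), the shared-native mask (`mask.bed`), size
#' estimates (`estimates.json`) and a parameter log (`run_log.txt`).
#' Re-running on identical inputs and configuration is deterministic.
#'
#' @param config path to a configuration file or a list from
#'   [readPipelineConfig()].
#' @return (invisibly) the [detectIntegration()] result.
#' @export
runDetect <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  for (key in c("reads", "genome", "construct_fasta", "out_dir"))
    if (is.null(config[[key]])) stop("config key '", key, "' is required")
  for (key in c("reads", "genome", "construct_fasta")) {
    if (!file.exists(config[[key]]))
      stop("input does not exist: ", config[[key]])
  }
  outDir <- config$out_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  reads <- readSequences(config$reads)
  names(reads) <- sub("\\s.*$", "", names(reads))
  genome <- readSequences(config$genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  construct <- constructMapFromFiles(config$construct_fasta,
                                     config$construct_elements,
                                     circular = is.null(config$circular) ||
                                       isTRUE(config$circular))
  features <- if (!is.null(config$annotation))
    rtracklayer::import(config$annotation) else NULL
  dialect <- if (!is.null(config$alignment_dialect))
    config$alignment_dialect else "paf"
  constructHits <- if (!is.null(config$alignments_construct))
    parseAlignments(config$alignments_construct, dialect, "construct") else
    NULL
  genomeHits <- if (!is.null(config$alignments_genome))
    parseAlignments(config$alignments_genome, dialect, "genome") else NULL
  pars <- configParams(config)
  res <- detectIntegration(reads, genome, construct,
                           hitPar = pars$hit, classPar = pars$classify,
                           genomeSize = config$genome_size,
                           features = features,
                           constructHits = constructHits,
                           genomeHits = genomeHits)

  writeTsv(res$classes, file.path(outDir, "read_classes.tsv"))
  writeTsv(res$summary, file.path(outDir, "summary.tsv"))
  islandCols <- setdiff(names(res$islands), "structures")
  writeTsv(res$islands[, islandCols, drop = FALSE],
           file.path(outDir, "islands.tsv"))
  if (nrow(res$islands)) {
    writeRegionsBed(data.frame(
      chromosome = res$islands$chromosome,
      start = pmax(0, res$islands$site_start - 1),
      end = pmax(res$islands$site_end, res$islands$site_start),
      name = res$islands$island_id), file.path(outDir, "islands.bed"))
  } else {
    file.create(file.path(outDir, "islands.bed"))
  }
  conc <- concatemerTable(res$islands)
  writeTsv(conc, file.path(outDir, "concatemers.tsv"))
  mk <- maskIntervals(res$mask)
  writeRegionsBed(data.frame(
    chromosome = rep(construct@id, nrow(mk)), start = mk$start,
    end = mk$end, name = paste0("mask", seq_len(nrow(mk)))),
    file.path(outDir, "mask.bed"))
  jsonlite::write_json(res$estimates,
                       file.path(outDir, "estimates.json"),
                       auto_unbox = TRUE, digits = NA)
  logLines <- c(
    paste0("islandseq detect"),
    paste0("reads = ", config$reads),
    paste0("genome = ", config$genome),
    paste0("construct = ", config$construct_fasta),
    paste0("seed = ", if (is.null(config$seed)) NA else config$seed),
    paste0("min_hit_length = ", pars$hit@minHitLength),
    paste0("min_identity = ", pars$hit@minIdentity),
    paste0("merge_gap = ", pars$hit@mergeGap),
    paste0("min_construct_extent = ", pars$classify@minConstructExtent),
    paste0("min_flank = ", pars$classify@minFlank),
    paste0("cluster_distance = ", pars$classify@clusterDistance),
    paste0("mask_padding = ", pars$classify@maskPadding),
    paste0("genome_size = ", res$estimates$genome_size),
    paste0("n_reads = ", res$summary$total_reads),
    paste0("n_islands = ", nrow(res$islands)))
  writeLines(logLines, file.path(outDir, "run_log.txt"))
  invisible(res)
}

# Equivalence interval of an insertion point under junction microhomology:
# 0-based insertion points q in [lo, hi] for which some island sequence
# reproduces the observed transgenic chromosome. p is the planted point on
# the wild-type chromosome, [a, b) the island interval on the transgenic one.
insertionEquivalence <- function(wtChrom, tgChrom, p, a, b, maxH = 200) {
  wt <- as.character(wtChrom); tg <- as.character(tgChrom)
  hL <- 0L
  while (hL < maxH && p + hL < nchar(wt) && a + hL < b &&
         substr(tg, a + hL + 1L, a + hL + 1L) ==
           substr(wt, p + hL + 1L, p + hL + 1L)) hL <- hL + 1L
  hR <- 0L
  while (hR < maxH && p - hR > 0L && b - hR > a &&
         substr(tg, b - hR, b - hR) == substr(wt, p - hR, p - hR)) hR <- hR + 1L
  c(p - hR, p + hL)
}

# Flatten per-island structures into one table.
concatemerTable <- function(islands) {
  if (!nrow(islands) || is.null(islands$structures))
    return(data.frame(island_id = character(0), read_id = character(0),
                      index = integer(0), read_start = integer(0),
                      read_end = integer(0), construct_start = integer(0),
                      construct_end = integer(0), orientation = character(0),
                      stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(islands)), function(i) {
    structs <- islands$structures[[i]]
    pieces <- lapply(names(structs), function(id) {
      st <- structs[[id]]
      if (!nrow(st)) return(NULL)
      cbind(data.frame(island_id = islands$island_id[i], read_id = id,
                       stringsAsFactors = FALSE), st)
    })
    do.call(rbind, pieces)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  out
}

#' Benchmark a detection result against simulation ground truth
#'
#' @param result a [detectIntegration()] result.
#' @param islandTruth island truth data.frame from [plantIslands()].
#' @param readTruth read truth data.frame with a `true_class` column.
#' @param matchDistance maximum distance (bp) between a called site and the
#'   true insertion point for the pair to be matched.
#' @param wildtype,transgenic optional wild-type and transgenic genomes
#'   ([Biostrings::DNAStringSet]). When supplied, site containment is
#'   evaluated against the *equivalence interval* of the true insertion
#'   point: when the island sequence shares its first/last bases with the
#'   genomic sequence flanking the junction (junction microhomology), every
#'   insertion point within the homology tract produces the identical
#'   transgenic sequence, so no aligner can distinguish them and containment
#'   of any equivalent point is correct recovery.
#' @return list with `island_recall`, `island_precision` (1 by convention
#'   when nothing was planted and nothing called), `site_containment_rate`,
#'   `resolutions`, `size_relative_errors` (complete islands),
#'   `lower_bound_violations`, and `confusion` (truth class x called class
#'   table).
#' @export
runBenchmark <- function(result, islandTruth, readTruth,
                         matchDistance = 50000, wildtype = NULL,
                         transgenic = NULL) {
  islands <- result$islands
  nTruth <- if (is.null(islandTruth)) 0L else nrow(islandTruth)
  nCalled <- nrow(islands)
  matchedTruth <- logical(nTruth)
  matchedCall <- logical(nCalled)
  contain <- logical(0)
  sizeRel <- numeric(0)
  lbViol <- logical(0)
  if (nTruth && nCalled) {
    if (!all(islands$chromosome %in% c(islandTruth$chromosome,
                                       readTruth$source_molecule)))
      stop("called island chromosome absent from truth")
    for (i in seq_len(nTruth)) {
      p <- islandTruth$insertion_point[i]
      dist <- abs((islands$site_start + islands$site_end) / 2 - p)
      cand <- which(islands$chromosome == islandTruth$chromosome[i] &
                    dist <= matchDistance)
      if (length(cand)) {
        j <- cand[which.min(dist[cand])]
        matchedTruth[i] <- TRUE
        matchedCall[cand] <- TRUE
        eq <- c(p, p)
        if (!is.null(wildtype) && !is.null(transgenic))
          eq <- insertionEquivalence(
            wildtype[[islandTruth$chromosome[i]]],
            transgenic[[islandTruth$chromosome[i]]], p,
            islandTruth$tg_start[i], islandTruth$tg_end[i])
        contain <- c(contain,
                     islands$site_start[j] - 1 <= eq[2] &
                       eq[1] <= islands$site_end[j])
        if (islands$complete[j]) {
          sizeRel <- c(sizeRel, (islands$size_bp[j] -
                                 islandTruth$true_length[i]) /
                                islandTruth$true_length[i])
        } else {
          lbViol <- c(lbViol,
                      islands$size_bp[j] > islandTruth$true_length[i])
        }
      }
    }
  }
  recall <- if (nTruth) mean(matchedTruth) else 1
  precision <- if (nCalled) mean(matchedCall) else 1
  confusion <- NULL
  if (!is.null(readTruth) && !is.null(readTruth$true_class)) {
    merged <- merge(readTruth[, c("read_id", "true_class")],
                    result$classes, by = "read_id")
    confusion <- table(truth = factor(merged$true_class,
                                      levels = READ_CLASSES),
                       called = factor(merged$class, levels = READ_CLASSES))
  }
  list(island_recall = recall, island_precision = precision,
       n_called = nCalled, n_truth = nTruth,
       site_containment_rate = if (length(contain)) mean(contain) else NA,
       resolutions = islands$resolution,
       size_relative_errors = sizeRel,
       lower_bound_violations = lbViol,
       confusion = confusion)
}
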