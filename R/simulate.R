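# Synthetic-data generator: host genomes, constructs, concatemer integration
# islands, episome pools and noisy long reads, each with ground truth.

#' Simulate a multi-chromosome host genome
#'
#' Generates i.i.d. random chromosome sequences at a given GC fraction. The
#' result stands in for a wild-type host reference genome; it reproduces the
#' composition, not the repeat structure, of real genomes.
#'
#' @param nChromosomes number of chromosomes (>= 1).
#' @param lengths integer vector of chromosome lengths (bp), length
#'   `nChromosomes`.
#' @param gcFraction target GC content in `[0, 1]`.
#' @param seed RNG seed; identical seeds give byte-identical genomes.
#' @return a named [Biostrings::DNAStringSet] (`chr1`, `chr2`, ...).
#' @examples
#' g <- simulateGenome(2, c(10000, 5000), 0.48, seed = 7)
#' sum(Biostrings::width(g))
#' @export
simulateGenome <- function(nChromosomes, lengths, gcFraction = 0.48,
                           seed = 1) {
  if (nChromosomes < 1) stop("nChromosomes must be >= 1")
  if (length(lengths) != nChromosomes)
    stop("'lengths' must have one entry per chromosome")
  if (any(lengths <= 0)) stop("chromosome lengths must be positive")
  if (gcFraction < 0 || gcFraction > 1) stop("gcFraction must be in [0, 1]")
  withSeed(seed, {
    seqs <- vapply(lengths, randomDna, character(1), gcFraction = gcFraction)
    DNAStringSet(setNames(seqs, paste0("chr", seq_len(nChromosomes))))
  })
}

#' Build a construct whose promoter/terminator segments are copied from the
#' host genome
#'
#' Assembles an exogenous construct from a novel random backbone, a novel
#' coding sequence, and native segments copied verbatim from the supplied
#' genome (emulating host-derived promoters and terminators). The copied
#' intervals are recorded as the shared-native truth: on real data these are
#' exactly the regions that make purely genomic reads produce false-positive
#' construct hits.
#'
#' @param genome a named [Biostrings::DNAStringSet] host genome.
#' @param backboneLength,cdsLength lengths (bp) of the novel vector backbone
#'   and coding sequence.
#' @param nativeSegments data.frame with columns `chromosome`, `start`, `end`
#'   (0-based half-open on the genome) and `label`; may have zero rows.
#' @param seed RNG seed for the novel sequence.
#' @param id construct identifier.
#' @param circular logical; constructs are circular plasmids by default.
#' @return a [ConstructMap].
#' @export
buildConstruct <- function(genome, backboneLength, cdsLength,
                           nativeSegments = data.frame(), seed = 1,
                           id = "construct", circular = TRUE) {
  ns <- nativeSegments
  if (is.null(ns) || nrow(ns) == 0L)
    ns <- data.frame(chromosome = character(0), start = integer(0),
                     end = integer(0), label = character(0))
  for (i in seq_len(nrow(ns))) {
    chrom <- as.character(ns$chromosome[i])
    if (!chrom %in% names(genome))
      stop("native segment chromosome '", chrom, "' not in genome")
    if (ns$start[i] < 0 || ns$end[i] > length(genome[[chrom]]) ||
        ns$start[i] >= ns$end[i])
      stop("native segment ", i, " does not lie within its chromosome")
  }
  if (nrow(ns) > 1L) {
    for (chrom in unique(ns$chromosome)) {
      sub <- ns[ns$chromosome == chrom, , drop = FALSE]
      ir <- asRanges0(sub$start, sub$end)
      if (sum(width(reduce(ir))) != sum(width(ir)))
        stop("native segments overlap on ", chrom)
    }
  }
  withSeed(seed, {
    backbone <- randomDna(backboneLength, 0.5)
    cds <- randomDna(cdsLength, 0.5)
    segSeq <- vapply(seq_len(nrow(ns)), function(i) {
      as.character(subseq(genome[[as.character(ns$chromosome[i])]],
                          ns$start[i] + 1L, ns$end[i]))
    }, character(1))
    # layout: backbone | native[1] | cds | native[2..]
    parts <- c(backbone, if (nrow(ns) >= 1) segSeq[1], cds,
               if (nrow(ns) >= 2) segSeq[-1])
    labels <- c("backbone", if (nrow(ns) >= 1) as.character(ns$label[1]),
                "cds", if (nrow(ns) >= 2) as.character(ns$label[-1]))
    lens <- nchar(parts)
    ends <- cumsum(lens)
    starts <- ends - lens
    isNative <- labels %in% as.character(ns$label) & labels != "backbone" &
      labels != "cds"
    nsOrder <- c(if (nrow(ns) >= 1) 1L, if (nrow(ns) >= 2) 2:nrow(ns))
    shared <- if (nrow(ns)) {
      idx <- which(isNative)
      data.frame(start = starts[idx], end = ends[idx],
                 chromosome = as.character(ns$chromosome[nsOrder]),
                 genome_start = ns$start[nsOrder],
                 genome_end = ns$end[nsOrder],
                 stringsAsFactors = FALSE)
    } else data.frame(start = integer(0), end = integer(0))
    ConstructMap(id = id, sequence = paste(parts, collapse = ""),
                 circular = circular,
                 elements = data.frame(label = labels, start = starts,
                                       end = ends, stringsAsFactors = FALSE),
                 sharedNative = shared)
  })
}

# Fragment length draw for makeConcatemer.
drawFragLength <- function(family, params, L) {
  len <- switch(family,
    uniform = round(runif(1, params[1], params[2])),
    constant = params[1],
    stop("unknown fragment length family: ", family))
  max(1L, min(as.integer(len), L))
}

#' Generate one concatemer island sequence and its true structure
#'
#' Draws construct fragments (length distribution and sense/antisense
#' orientation per the [IslandSpec]) and concatenates them until the target
#' length is reached; the total overshoots the target by less than one
#' fragment. Fragments whose construct coordinates would resume a nearby
#' same-orientation fragment's alignment diagonal within 300 bp (a
#' near-seamless junction, or a same-diagonal continuation within chaining
#' range) are redrawn, so the returned structure is the unique
#' maximal-fragment decomposition recoverable by alignment and downstream
#' structure recovery is well-defined.
#'
#' @param construct a [ConstructMap].
#' @param spec an [IslandSpec].
#' @param seed RNG seed.
#' @return list with `sequence` (character) and `structure`, a data.frame
#'   with one row per fragment: `index`, `island_start`, `island_end`
#'   (0-based on the island), `construct_start` (0-based, `< L`),
#'   `construct_end` (may exceed the construct length `L` when a fragment of
#'   a circular construct wraps the origin), `orientation`
#'   (`sense`/`antisense`).
#' @export
makeConcatemer <- function(construct, spec, seed = 1) {
  L <- constructLength(construct)
  params <- spec@fragParams
  if (all(is.na(params)))
    params <- if (spec@fragFamily == "uniform") c(min(500, L), L) else L
  if (spec@fragFamily == "constant" && params[1] <= 0)
    stop("degenerate fragment length distribution (all mass at 0)")
  if (spec@fragFamily == "uniform" && params[2] <= 0)
    stop("degenerate fragment length distribution (all mass at 0)")
  if (spec@targetLength < 1) stop("targetLength must be >= 1")
  doubled <- paste0(constructSeq(construct), constructSeq(construct))
  margin <- 300L
  withSeed(seed, {
    starts <- ends <- cs <- ce <- integer(0)
    ori <- character(0)
    seqs <- character(0)
    total <- 0L
    # A candidate fragment is rejected when a same-orientation fragment
    # within chaining range (1.2 kbp back along the island) shares its
    # alignment diagonal to within `margin` bp: such pairs would be fused by
    # any chaining aligner, making the planted structure unrecoverable.
    # Diagonal invariants: sense, construct_start - island_start; antisense,
    # construct_start + island_end (both modulo L).
    circDist <- function(g) pmin(g %% L, L - g %% L)
    while (total < spec@targetLength) {
      for (try in 1:50) {
        len <- drawFragLength(spec@fragFamily, params, L)
        anti <- runif(1) < spec@antisenseProb
        if (construct@circular) {
          s <- sample.int(L, 1L) - 1L
        } else {
          s <- sample.int(L - len + 1L, 1L) - 1L
        }
        e <- s + len
        ok <- TRUE
        if (L > 2L * margin && length(starts)) {
          near <- which(ends >= total - 1200L &
                        ori == (if (anti) "antisense" else "sense"))
          if (length(near)) {
            inv <- if (!anti) s - total else s + total + len
            invPrev <- if (!anti) cs[near] - starts[near] else
              cs[near] + ends[near]
            if (any(circDist(inv - invPrev) < margin)) ok <- FALSE
          }
        }
        if (ok) break
      }
      frag <- substr(doubled, s + 1L, e)
      if (anti) frag <- revcompChar(frag)
      starts <- c(starts, total)
      total <- total + len
      ends <- c(ends, total)
      cs <- c(cs, s); ce <- c(ce, e)
      ori <- c(ori, if (anti) "antisense" else "sense")
      seqs <- c(seqs, frag)
    }
    structure_df <- data.frame(
      index = seq_along(starts), island_start = starts, island_end = ends,
      construct_start = cs, construct_end = ce, orientation = ori,
      stringsAsFactors = FALSE)
    list(sequence = paste(seqs, collapse = ""), structure = structure_df)
  })
}

#' Plant concatemer islands into a wild-type genome
#'
#' Inserts one island per [IslandSpec] at its 0-based insertion point and
#' returns the transgenic genome together with exact ground truth. With
#' `junctionIndelMax = 0` (the default) junctions are clean and the
#' transgenic genome length equals the wild-type length plus the summed true
#' island lengths, exactly; with micro-indels enabled, up to that many host
#' bases are deleted and/or random bases inserted at each junction (recorded
#' in the truth table), emulating borders that cannot be resolved to the
#' base.
#'
#' @param genome wild-type [Biostrings::DNAStringSet].
#' @param construct a [ConstructMap].
#' @param specs list of [IslandSpec] (insertion points must be distinct and
#'   well separated).
#' @param seed RNG seed.
#' @return list with `genome` (transgenic `DNAStringSet`) and `islands`, a
#'   data.frame with one row per island: `island_id`, `chromosome`,
#'   `insertion_point` (0-based, wild-type frame), `true_length`, `tg_start`,
#'   `tg_end` (0-based island interval in the transgenic frame), junction
#'   indel sizes, and a `structure` list column of true
#'   concatemer structures.
#' @export
plantIslands <- function(genome, construct, specs, seed = 1) {
  if (length(specs) == 0L)
    return(list(genome = genome,
                islands = data.frame(island_id = character(0),
                                     chromosome = character(0),
                                     insertion_point = numeric(0),
                                     true_length = numeric(0),
                                     tg_start = numeric(0),
                                     tg_end = numeric(0))))
  chroms <- vapply(specs, function(s) s@chromosome, character(1))
  pos <- vapply(specs, function(s) s@position, numeric(1))
  for (i in seq_along(specs)) {
    if (!chroms[i] %in% names(genome))
      stop("island chromosome '", chroms[i], "' not in genome")
    if (pos[i] < 0 || pos[i] > length(genome[[chroms[i]]]))
      stop("insertion point outside chromosome for island ", i)
  }
  if (anyDuplicated(paste(chroms, pos)))
    stop("insertion points must be distinct")
  withSeed(seed, {
    conc <- lapply(seq_along(specs), function(i)
      makeConcatemer(construct, specs[[i]],
                     seed = sample.int(.Machine$integer.max, 1L)))
    out <- as.list(as.character(genome))
    truth <- vector("list", length(specs))
    ord <- order(chroms, pos)
    shift <- setNames(rep(0, length(genome)), names(genome))
    for (j in ord) {
      chrom <- chroms[j]
      p <- pos[j]
      isl <- conc[[j]]$sequence
      maxIndel <- specs[[j]]@junctionIndelMax
      dL <- if (maxIndel > 0) sample.int(maxIndel + 1L, 1L) - 1L else 0L
      dR <- if (maxIndel > 0) sample.int(maxIndel + 1L, 1L) - 1L else 0L
      nIL <- if (maxIndel > 0) sample.int(maxIndel + 1L, 1L) - 1L else 0L
      nIR <- if (maxIndel > 0) sample.int(maxIndel + 1L, 1L) - 1L else 0L
      insL <- if (nIL > 0) randomDna(nIL) else ""
      insR <- if (nIR > 0) randomDna(nIR) else ""
      s <- out[[chrom]]
      pAdj <- p + shift[chrom]
      left <- substr(s, 1L, pAdj - dL)
      right <- substr(s, pAdj + dR + 1L, nchar(s))
      tgStart <- (pAdj - dL) + nchar(insL)
      out[[chrom]] <- paste0(left, insL, isl, insR, right)
      truth[[j]] <- data.frame(
        island_id = paste0("island_", j), chromosome = chrom,
        insertion_point = p, true_length = nchar(isl),
        tg_start = tgStart, tg_end = tgStart + nchar(isl),
        del_left = dL, del_right = dR, ins_left = nIL, ins_right = nIR,
        stringsAsFactors = FALSE)
      shift[chrom] <- shift[chrom] + nchar(isl) + nIL + nIR - dL - dR
    }
    islands <- do.call(rbind, truth)
    islands$structure <- I(lapply(conc, `[[`, "structure"))
    list(genome = DNAStringSet(setNames(unlist(out), names(genome))),
         islands = islands)
  })
}

#' Read length distribution for the simulator
#'
#' @param family `"lognormal"` (default) or `"constant"`.
#' @param meanLength mean read length in bp (log-normal parameterised by its
#'   arithmetic mean).
#' @param sigma log-scale standard deviation (heavy tail; the default regime
#'   has a tail reaching ~190 kbp).
#' @param minLength minimum emitted read length.
#' @return a list describing the distribution.
#' @export
readLengthDist <- function(family = "lognormal", meanLength = 7000,
                           sigma = 0.9, minLength = 200) {
  list(family = family, meanLength = meanLength, sigma = sigma,
       minLength = minLength)
}

drawReadLengths <- function(n, dist) {
  switch(dist$family,
    lognormal = {
      meanlog <- log(dist$meanLength) - dist$sigma^2 / 2
      pmax(dist$minLength, round(rlnorm(n, meanlog, dist$sigma)))
    },
    constant = rep(as.integer(dist$meanLength), n),
    stop("unknown read length family: ", dist$family))
}

#' Simulate noisy long reads from a pool of molecules
#'
#' Draws reads from the weighted molecule pool until the requested fold
#' coverage of the pool is reached (the emitted nucleotide total is trimmed
#' to match the target exactly before errors are applied), then applies
#' per-base substitution/insertion/deletion errors. Circular molecules are
#' read from a doubled sequence; no read exceeds one full circumference.
#' With all error rates zero every read is an exact substring of its source
#' molecule or of its reverse complement.
#'
#' @param molecules named [Biostrings::DNAStringSet] of source molecules
#'   (chromosomes, episomes, ...).
#' @param coverage target fold coverage of the weighted pool (> 0).
#' @param lengthDist a [readLengthDist()].
#' @param errModel an [ErrorModel].
#' @param seed RNG seed; identical seeds give identical reads.
#' @param weights per-molecule copy weights (default 1).
#' @param circular logical per molecule (default all linear).
#' @return list with `reads` (named `DNAStringSet`) and `truth`, a data.frame
#'   with `read_id`, `source_molecule`, `source_start`, `source_end` (0-based
#'   half-open, pre-error; on circular molecules `source_end` may exceed the
#'   molecule length, meaning the read wraps the origin), `strand`, and
#'   `read_length` (post-error).
#' @export
simulateReads <- function(molecules, coverage, lengthDist = readLengthDist(),
                          errModel = errorModel(), seed = 1,
                          weights = rep(1, length(molecules)),
                          circular = rep(FALSE, length(molecules))) {
  if (length(molecules) == 0L) stop("molecule set must not be empty")
  if (coverage <= 0) stop("coverage must be > 0")
  lens <- width(molecules)
  target <- coverage * sum(weights * lens)
  withSeed(seed, {
    rl <- integer(0); mol <- integer(0)
    repeat {
      need <- target - sum(rl)
      if (need <= 0) break
      n <- max(10L, ceiling(need / lengthDist$meanLength * 1.3))
      newl <- drawReadLengths(n, lengthDist)
      newm <- sample.int(length(molecules), n, replace = TRUE,
                         prob = weights * lens)
      newl <- pmin(newl, lens[newm])
      rl <- c(rl, newl); mol <- c(mol, newm)
      cum <- cumsum(as.numeric(rl))
      if (cum[length(cum)] >= target) {
        k <- which(cum >= target)[1]
        rl <- rl[seq_len(k)]; mol <- mol[seq_len(k)]
        excess <- cum[k] - target
        rl[k] <- max(lengthDist$minLength, rl[k] - round(excess))
        break
      }
    }
    n <- length(rl)
    starts <- integer(n)
    for (i in seq_len(n)) {
      Lm <- lens[mol[i]]
      starts[i] <- if (circular[mol[i]]) sample.int(Lm, 1L) - 1L
                   else sample.int(Lm - rl[i] + 1L, 1L) - 1L
    }
    strand <- sample(c("+", "-"), n, replace = TRUE)
    seqs <- character(n)
    molChar <- as.character(molecules)
    for (m in unique(mol)) {
      idx <- which(mol == m)
      src <- if (circular[m]) paste0(molChar[m], molChar[m]) else molChar[m]
      seqs[idx] <- substring(src, starts[idx] + 1L, starts[idx] + rl[idx])
    }
    minus <- strand == "-"
    if (any(minus))
      seqs[minus] <- as.character(reverseComplement(DNAStringSet(seqs[minus])))
    if (errModel@substitution > 0 || errModel@insertion > 0 ||
        errModel@deletion > 0)
      seqs <- .cpp_mutate(seqs, errModel@substitution, errModel@insertion,
                          errModel@deletion)
    ids <- sprintf("read%06d", seq_len(n))
    truth <- data.frame(
      read_id = ids, source_molecule = names(molecules)[mol],
      source_start = starts, source_end = starts + rl, strand = strand,
      read_length = nchar(seqs), stringsAsFactors = FALSE)
    list(reads = DNAStringSet(setNames(seqs, ids)), truth = truth)
  })
}

#' True read classes from simulation ground truth
#'
#' Assigns each simulated read the class an ideal classifier (operating at
#' the same thresholds) would give it, from its source interval and the
#' planted island intervals. This is the oracle used to test classification.
#'
#' @param truth read truth from [simulateReads()].
#' @param islands island truth from [plantIslands()] (may have zero rows).
#' @param constructMolecules names of molecules that are pure construct
#'   (e.g. `"episome"`); their reads are `construct_only`.
#' @param params a [ClassifyParams].
#' @return character vector of classes, one per truth row.
#' @export
trueReadClasses <- function(truth, islands,
                            constructMolecules = character(0),
                            params = classifyParams()) {
  cls <- rep("genome_only", nrow(truth))
  cls[truth$source_molecule %in% constructMolecules] <- "construct_only"
  if (!is.null(islands) && nrow(islands)) {
    for (i in seq_len(nrow(islands))) {
      isl <- islands[i, ]
      on <- truth$source_molecule == isl$chromosome
      s <- truth$source_start; e <- truth$source_end
      o <- pmin(e, isl$tg_end) - pmax(s, isl$tg_start)
      idx <- which(on & o > 0)
      for (j in idx) {
        f5 <- max(0, isl$tg_start - s[j])
        f3 <- max(0, e[j] - isl$tg_end)
        if (o[j] < params@minConstructExtent) {
          cls[j] <- "false_positive"
        } else if (f5 >= params@minFlank && f3 >= params@minFlank) {
          cls[j] <- "spanning"
        } else if (f5 >= params@minFlank) {
          cls[j] <- "left_border"
        } else if (f3 >= params@minFlank) {
          cls[j] <- "right_border"
        } else {
          cls[j] <- "construct_only"
        }
      }
    }
  }
  cls
}

# Where the wrappers copy the construct's promoter/terminator from: 500 bp
# at one third of chr1 and one quarter of the last chromosome.
nativeSegmentPlan <- function(genome) {
  c2 <- names(genome)[min(2, length(genome))]
  p1 <- round(length(genome[["chr1"]]) / 3)
  p2 <- round(length(genome[[c2]]) / 4)
  data.frame(chromosome = c("chr1", c2),
             start = c(p1, p2), end = c(p1 + 500, p2 + 500),
             label = c("promoter", "terminator"),
             stringsAsFactors = FALSE)
}

#' Simulate a transgenic line with planted integration islands
#'
#' High-level wrapper reproducing the biolistic-integration study design at
#' desk scale: a 2-chromosome host genome, a 6.5 kbp construct whose
#' promoter and terminator are copied from the host, islands planted at
#' well-separated loci, and noisy long reads at the requested coverage.
#'
#' @param seed RNG seed driving every stage.
#' @param genomeLengths chromosome lengths (default 1.2 Mbp + 0.8 Mbp).
#' @param islandLengths island lengths in bp (default two islands drawn
#'   uniformly from 10-50 kbp).
#' @param coverage fold coverage (default 8).
#' @param errModel an [ErrorModel] (default ~15% total error).
#' @param lengthDist a [readLengthDist()].
#' @param junctionIndelMax junction micro-indel bound passed to the island
#'   specs.
#' @param antisenseProb fragment antisense probability.
#' @return list with `wildtype`, `genome` (transgenic), `construct`,
#'   `islands` (truth), `reads`, `truth` (read truth with a `true_class`
#'   column).
#' @export
simulateIntegrationLine <- function(seed = 1,
                                    genomeLengths = c(1200000, 800000),
                                    islandLengths = NULL, coverage = 8,
                                    errModel = errorModel(),
                                    lengthDist = readLengthDist(),
                                    junctionIndelMax = 0,
                                    antisenseProb = 0.5) {
  wt <- simulateGenome(length(genomeLengths), genomeLengths, 0.48,
                       seed = seed)
  construct <- buildConstruct(
    wt, backboneLength = 3500, cdsLength = 2000,
    nativeSegments = nativeSegmentPlan(wt),
    seed = seed + 101L, id = "plasmid")
  if (is.null(islandLengths))
    islandLengths <- withSeed(seed + 7L, round(runif(2, 10000, 50000)))
  nIsl <- length(islandLengths)
  chromFor <- rep(names(wt), length.out = nIsl)
  pos <- withSeed(seed + 11L, vapply(seq_len(nIsl), function(i) {
    Lc <- length(wt[[chromFor[i]]])
    round(runif(1, 0.25 * Lc, 0.75 * Lc))
  }, numeric(1)))
  specs <- lapply(seq_len(nIsl), function(i)
    islandSpec(chromFor[i], pos[i], islandLengths[i],
               antisenseProb = antisenseProb,
               junctionIndelMax = junctionIndelMax))
  planted <- plantIslands(wt, construct, specs, seed = seed + 23L)
  sim <- simulateReads(planted$genome, coverage, lengthDist, errModel,
                       seed = seed + 31L)
  sim$truth$true_class <- trueReadClasses(sim$truth, planted$islands)
  list(wildtype = wt, genome = planted$genome, construct = construct,
       islands = planted$islands, reads = sim$reads, truth = sim$truth)
}

#' Simulate an episome-carrying (non-integrated) line
#'
#' Emulates an exconjugant: the wild-type genome plus free circular episome
#' molecules whose promoter/terminator are copied from the host. No island
#' is planted, so a correct caller must report zero integration islands at
#' any error rate.
#'
#' @inheritParams simulateIntegrationLine
#' @param episomeCopies copy weight of the episome in the read pool.
#' @return list with `genome` (wild type), `episome` ([ConstructMap]),
#'   `reads`, `truth` (read truth with `true_class`).
#' @export
simulateEpisomeLine <- function(seed = 1, genomeLengths = c(1200000, 800000),
                                coverage = 8, errModel = errorModel(),
                                lengthDist = readLengthDist(),
                                episomeCopies = 20) {
  wt <- simulateGenome(length(genomeLengths), genomeLengths, 0.48,
                       seed = seed)
  episome <- buildConstruct(
    wt, backboneLength = 7849, cdsLength = 2000,
    nativeSegments = nativeSegmentPlan(wt),
    seed = seed + 101L, id = "episome")
  pool <- c(wt, DNAStringSet(setNames(constructSeq(episome), "episome")))
  sim <- simulateReads(pool, coverage, lengthDist, errModel,
                       seed = seed + 31L,
                       weights = c(rep(1, length(wt)), episomeCopies),
                       circular = c(rep(FALSE, length(wt)), TRUE))
  sim$truth$true_class <- trueReadClasses(
    sim$truth, islands = NULL, constructMolecules = "episome")
  list(genome = wt, episome = episome, reads = sim$reads, truth = sim$truth)
}
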