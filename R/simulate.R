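#' Build a simulation configuration
#'
#' Defaults encode the study conditions the cohort emulates: a
#' ((Lowland, Guatemalan), Mexican) topology with splits at 44,000 years
#' and 1.3 million years (6,286 and 185,714 generations at 7 years per
#' generation); per-site diversity theta = 4*Ne*mu = 0.0035 via
#' Ne = 23,148 and mu = 3.78e-8 per generation (5.4e-9 per site per year
#' at 7-year generations); 3 Mexican, 5 Lowland and 10 Guatemalan
#' diploids; a desk-scale genome of 12 chromosomes of 1 Mb tiled into
#' independent 1-kb segments.
#'
#' @param chromLengths named numeric, chromosome lengths in bp.
#' @param segmentLength independent-genealogy unit in bp.
#' @param nDiploid named integer diploid sample sizes
#'   (`Mexican`, `Lowland`, `Guatemalan`; zeros allowed).
#' @param ne effective size, either a single number used for every
#'   population (including the `LG` and `ANC` ancestors) or a fully named
#'   vector.
#' @param tRecent,tDeep split times in generations.
#' @param mu per-site per-generation mutation rate.
#' @param sweeps data.frame with columns `population`, `chrom`, `center`,
#'   `radius`, `s` (zero rows: neutral).
#' @param hybrids data.frame with columns `id`, `qMexican`, `qLowland`,
#'   `qGuatemalan` (zero rows: none).
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(chromLengths = stats::setNames(rep(1e6, 12),
                                                            paste0("chr", 1:12)),
                             segmentLength = 1000L,
                             nDiploid = c(Mexican = 3L, Lowland = 5L,
                                          Guatemalan = 10L),
                             ne = 23148,
                             tRecent = 6286,
                             tDeep = 185714,
                             mu = 3.78e-8,
                             sweeps = NULL,
                             hybrids = NULL) {
  if (length(ne) == 1L)
    ne <- c(Mexican = ne, Lowland = ne, Guatemalan = ne, LG = ne, ANC = ne)
  if (is.null(sweeps))
    sweeps <- data.frame(population = character(), chrom = character(),
                         center = numeric(), radius = numeric(),
                         s = numeric())
  if (is.null(hybrids))
    hybrids <- data.frame(id = character(), qMexican = numeric(),
                          qLowland = numeric(), qGuatemalan = numeric())
  new("SimulationConfig", chromLengths = chromLengths,
      segmentLength = as.integer(segmentLength),
      nDiploid = stats::setNames(as.integer(nDiploid), names(nDiploid)),
      ne = ne, tRecent = tRecent, tDeep = tDeep, mu = mu,
      sweeps = sweeps, hybrids = hybrids)
}

#' Hard-sweep distortion factor at a distance from the sweep center
#'
#' `f(d) = s + (1 - s) * min(1, d / r)`: full distortion (factor `s`) at
#' the center, linear recovery to neutral (factor 1) at the footprint
#' radius `r`. The simulator uses `f(d)` as the per-lineage escape
#' probability of the hard-sweep star approximation: at the sweep time
#' each sampled lineage of the swept population escapes independently
#' with probability `f(d)`, and all non-escapees coalesce instantly into
#' a single lineage. This collapses most lineages at the center into a
#' star-like genealogy and produces both the diversity trough and the
#' high-frequency-derived / singleton excess the CLR scan detects, with
#' exact ground truth.
#'
#' @param d distance(s) from the sweep center in bp.
#' @param s sweep intensity in (0, 1\]; smaller is stronger.
#' @param r footprint radius in bp.
#' @return numeric factor(s) in \[s, 1\].
#' @examples
#' sweepDistortionFactor(c(0, 25000, 50000, 80000), s = 0.05, r = 50000)
#' @export
sweepDistortionFactor <- function(d, s, r) {
  s + (1 - s) * pmin(1, d / r)
}

#' Simulate one structured-coalescent genealogy
#'
#' Standard structured coalescent without migration: within a population
#' of diploid size `N`, `k` lineages coalesce at rate `k (k - 1) / 2 / (2N)`
#' per generation; at `tRecent` the Lowland and Guatemalan lineage pools
#' merge (into the `LG` ancestor), at `tDeep` the merged pool joins
#' Mexican (`ANC`). An optional hard sweep at the sampling time applies
#' the star approximation: each lineage of the swept population escapes
#' with probability `escapeProb`, and all non-escapees coalesce
#' instantly into one lineage before the neutral process starts.
#'
#' Uses the current RNG stream; seed with [set.seed()] for
#' reproducibility.
#'
#' @param pop character vector: population label per lineage (haplotype).
#' @param ne named effective sizes (`Mexican`, `Lowland`, `Guatemalan`,
#'   `LG`, `ANC`).
#' @param tRecent,tDeep split times in generations.
#' @param sweepPop,escapeProb star-approximation sweep at time 0:
#'   population label and per-lineage escape probability
#'   (`escapeProb = 1` disables; see [sweepDistortionFactor()]).
#' @return list with `tmrca`, `totalLength` (sum of branch lengths in
#'   generations) and `edges` (`length` vector and `members` list of
#'   haplotype-index vectors, one per branch below the root).
#' @export
simulateGenealogy <- function(pop, ne, tRecent = Inf, tDeep = Inf,
                              sweepPop = NA_character_, escapeProb = 1) {
  nl <- length(pop)
  members <- as.list(seq_len(nl))
  birth <- numeric(nl)
  popCur <- pop
  t <- 0
  edgeLen <- numeric(2L * nl)
  edgeMem <- vector("list", 2L * nl)
  nEdge <- 0L
  if (!is.na(sweepPop) && escapeProb < 1) {
    inPop <- which(popCur == sweepPop)
    swept <- inPop[stats::runif(length(inPop)) >= escapeProb]
    if (length(swept) >= 2L) {
      # instantaneous multi-merger at t = 0: zero-length branches carry
      # no mutations, the merged clade shares its stem
      members[[swept[1]]] <- unlist(members[swept], use.names = FALSE)
      drop <- swept[-1]
      members <- members[-drop]
      birth <- birth[-drop]
      popCur <- popCur[-drop]
    }
  }
  breaks <- sort(unique(c(tRecent, tDeep, Inf)))
  while (length(members) > 1L) {
    pops <- unique(popCur)
    rates <- vapply(pops, function(p) {
      k <- sum(popCur == p)
      if (k < 2L) return(0)
      N <- ne[[p]]
      k * (k - 1) / 2 / (2 * N)
    }, numeric(1))
    tot <- sum(rates)
    nextBreak <- breaks[breaks > t][1]
    dt <- if (tot > 0) stats::rexp(1, tot) else Inf
    if (t + dt >= nextBreak) {
      t <- nextBreak
      if (t >= tDeep) {
        popCur[] <- "ANC"
      } else if (t >= tRecent) {
        popCur[popCur %in% c("Lowland", "Guatemalan")] <- "LG"
      }
      next
    }
    t <- t + dt
    p <- if (length(pops) == 1L) pops else
      sample(pops, 1L, prob = rates / tot)
    inPop <- which(popCur == p)
    pair <- if (length(inPop) == 2L) inPop else sample(inPop, 2L)
    for (li in pair) {
      nEdge <- nEdge + 1L
      edgeLen[nEdge] <- t - birth[li]
      edgeMem[[nEdge]] <- members[[li]]
    }
    members[[pair[1]]] <- c(members[[pair[1]]], members[[pair[2]]])
    birth[pair[1]] <- t
    members[[pair[2]]] <- NULL
    birth <- birth[-pair[2]]
    popCur <- popCur[-pair[2]]
  }
  len <- edgeLen[seq_len(nEdge)]
  list(tmrca = t, totalLength = sum(len),
       edges = list(length = len, members = edgeMem[seq_len(nEdge)]))
}

#' Drop infinite-sites mutations on a genealogy
#'
#' Poisson-distributed mutation count with mean
#' `totalLength * mu * segmentLength`; each mutation lands on a branch
#' with probability proportional to its length and at a distinct uniform
#' position within the segment. Carriers of the derived allele are the
#' branch's descendant haplotypes; the ancestral allele is the reference
#' (0).
#'
#' @param tree genealogy from [simulateGenealogy()].
#' @param segmentLength segment length in bp.
#' @param mu per-site per-generation mutation rate.
#' @return list with `pos` (1-based positions within the segment, sorted)
#'   and `carriers` (list of haplotype-index vectors).
#' @export
dropMutations <- function(tree, segmentLength, mu) {
  nMut <- stats::rpois(1, tree$totalLength * mu * segmentLength)
  nMut <- min(nMut, segmentLength)   # infinite sites at finite resolution
  if (nMut == 0L)
    return(list(pos = integer(), carriers = list()))
  lens <- tree$edges$length
  branch <- sample.int(length(lens), nMut, replace = TRUE, prob = lens)
  pos <- sort(sample.int(segmentLength, nMut))
  list(pos = pos, carriers = tree$edges$members[branch])
}

# sweep escape probability affecting one segment (smallest f wins)
.segmentSweep <- function(chrom, segMid, sweeps) {
  if (!nrow(sweeps)) return(NULL)
  rows <- which(sweeps$chrom == chrom)
  if (!length(rows)) return(NULL)
  f <- sweepDistortionFactor(abs(segMid - sweeps$center[rows]),
                             sweeps$s[rows], sweeps$radius[rows])
  best <- rows[which.min(f)]
  if (min(f) >= 1) return(NULL)
  list(pop = sweeps$population[best], escapeProb = min(f))
}

#' Simulate a three-population cohort with ground truth
#'
#' Simulates every segment of the configured genome as an independent
#' structured-coalescent genealogy (free recombination between segments,
#' none within), drops infinite-sites mutations, applies any configured
#' sweep footprints, and builds hybrid accessions by copying per-segment
#' haplotypes from the pure pools with the configured proportions. The
#' reference allele is always ancestral, enabling unfolded-SFS analyses.
#'
#' @param config a [SimulationConfig-class].
#' @param seed integer seed; the run is fully deterministic given the
#'   seed (byte-identical emitted files).
#' @return list with
#'   * `genotypes`: a [GenotypeMatrix-class] (pure samples then hybrids);
#'   * `truth`: list with the sweep table, the per-segment hybrid copy
#'     sources (`data.frame`), and the per-population haplotype indices.
#' @export
simulateCohort <- function(config, seed = 1L) {
  set.seed(seed)
  pops <- c("Mexican", "Lowland", "Guatemalan")
  nDip <- config@nDiploid[pops]
  sampleIds <- unlist(lapply(pops, function(p) {
    n <- nDip[[p]]
    if (n > 0L) paste0(substr(p, 1, 1), seq_len(n)) else character()
  }), use.names = FALSE)
  popOfSample <- rep(pops, nDip)
  hapPop <- rep(popOfSample, each = 2L)
  nHap <- length(hapPop)
  if (nHap < 2L) stop("need at least one diploid sample")
  segLen <- config@segmentLength
  chromNames <- names(config@chromLengths)
  posList <- list(); chromList <- list(); carrierList <- list()
  segTable <- list()
  segIdx <- 0L
  for (ch in chromNames) {
    L <- config@chromLengths[[ch]]
    starts <- seq(1, L, by = segLen)
    for (s0 in starts) {
      segIdx <- segIdx + 1L
      thisLen <- min(segLen, L - s0 + 1)
      sw <- .segmentSweep(ch, s0 + thisLen / 2, config@sweeps)
      tree <- if (is.null(sw))
        simulateGenealogy(hapPop, config@ne, config@tRecent, config@tDeep)
      else
        simulateGenealogy(hapPop, config@ne, config@tRecent, config@tDeep,
                          sweepPop = sw$pop, escapeProb = sw$escapeProb)
      mut <- dropMutations(tree, thisLen, config@mu)
      if (length(mut$pos)) {
        posList[[segIdx]] <- s0 + mut$pos - 1L
        chromList[[segIdx]] <- rep(ch, length(mut$pos))
        carrierList[[segIdx]] <- mut$carriers
      }
      segTable[[segIdx]] <- c(chrom = ch, start = s0)
    }
  }
  pos <- unlist(posList, use.names = FALSE)
  chrom <- unlist(chromList, use.names = FALSE)
  carriers <- do.call(c, carrierList)
  nSnp <- length(pos)
  g <- matrix(0L, nrow = nHap, ncol = nSnp)
  for (i in seq_len(nSnp)) g[carriers[[i]], i] <- 1L
  # hybrids: per-segment copying from the pure pools
  hyb <- config@hybrids
  truthHyb <- NULL
  if (nrow(hyb)) {
    segOf <- (pos - 1L) %/% segLen   # segment index within chromosome
    segKey <- paste(chrom, segOf)
    segLevels <- unique(segKey)
    hapIdxByPop <- lapply(pops, function(p) which(hapPop == p))
    names(hapIdxByPop) <- pops
    qMat <- as.matrix(hyb[, c("qMexican", "qLowland", "qGuatemalan")])
    rows <- list(); truthRows <- list()
    for (h in seq_len(nrow(hyb))) {
      for (hapNo in 1:2) {
        srcPop <- pops[sample.int(3L, length(segLevels), replace = TRUE,
                                  prob = qMat[h, ])]
        srcHap <- vapply(srcPop, function(p) {
          idx <- hapIdxByPop[[p]]
          idx[sample.int(length(idx), 1L)]
        }, integer(1))
        newRow <- integer(nSnp)
        segI <- match(segKey, segLevels)
        newRow <- g[cbind(srcHap[segI], seq_len(nSnp))]
        rows[[length(rows) + 1L]] <- newRow
        truthRows[[length(truthRows) + 1L]] <-
          data.frame(hybrid = hyb$id[h], haplotype = hapNo,
                     segment = segLevels, source_pop = srcPop,
                     source_hap = srcHap, row.names = NULL)
      }
    }
    g <- rbind(g, do.call(rbind, rows))
    hapPop <- c(hapPop, rep("admixed", 2L * nrow(hyb)))
    sampleIds <- c(sampleIds, hyb$id)
    popOfSample <- c(popOfSample, rep("admixed", nrow(hyb)))
    truthHyb <- do.call(rbind, truthRows)
  }
  sitesGr <- GRanges(chrom, IRanges(pos, width = 1L))
  GenomeInfoDb::seqlevels(sitesGr) <- chromNames
  GenomeInfoDb::seqlengths(sitesGr) <- config@chromLengths
  mcols(sitesGr) <- DataFrame(
    ref = rep("A", nSnp), alt = rep("T", nSnp),
    qual = rep(60, nSnp), depth = rep(20, nSnp),
    filter = rep("PASS", nSnp), biallelic = rep(TRUE, nSnp))
  gm <- GenotypeMatrix(g, sitesGr, sampleIds = sampleIds,
                       population = popOfSample)
  list(genotypes = gm,
       truth = list(sweeps = config@sweeps, hybridSources = truthHyb,
                    nSegments = segIdx))
}

#' Simulate synthetic gene models
#'
#' Random non-overlapping genes, each with 1-4 CDS exons, for exercising
#' gene-assignment and hemizygosity machinery. Deterministic given the
#' seed.
#'
#' @param chromLengths named numeric chromosome lengths.
#' @param nGenes number of genes to place.
#' @param meanSpan mean gene span in bp.
#' @param seed integer seed.
#' @return a [GeneModelSet-class].
#' @export
simulateGeneModels <- function(chromLengths, nGenes = 100,
                               meanSpan = 4000, seed = 1L) {
  set.seed(seed)
  chroms <- sample(names(chromLengths), nGenes, replace = TRUE,
                   prob = chromLengths / sum(chromLengths))
  spans <- pmax(600L, stats::rpois(nGenes, meanSpan))
  starts <- vapply(seq_len(nGenes), function(i)
    sample.int(max(1L, chromLengths[[chroms[i]]] - spans[i]), 1L),
    integer(1))
  gr <- GRanges(chroms, IRanges(starts, width = spans))
  # drop overlaps to keep gene spans disjoint
  keep <- !logical(nGenes)
  ov <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                    drop.redundant = TRUE)
  keep[S4Vectors::subjectHits(ov)] <- FALSE
  gr <- gr[keep]
  ids <- sprintf("gene%04d", seq_along(gr))
  cdsList <- vector("list", length(gr))
  for (i in seq_along(gr)) {
    nEx <- sample.int(4L, 1L)
    span <- width(gr)[i]
    bounds <- sort(sample.int(span - 1L, 2L * nEx))
    st <- start(gr)[i] + bounds[seq(1, 2 * nEx, by = 2)] - 1L
    en <- start(gr)[i] + bounds[seq(2, 2 * nEx, by = 2)] - 1L
    cdsList[[i]] <- GenomicRanges::reduce(
      GRanges(as.character(GenomeInfoDb::seqnames(gr))[i],
              IRanges(st, en)))
  }
  names(cdsList) <- ids
  cds <- GenomicRanges::GRangesList(cdsList)
  mcols(gr) <- DataFrame(gene_id = ids,
                         cds_length = vapply(cdsList, function(x)
                           sum(width(x)), numeric(1)))
  names(gr) <- ids
  new("GeneModelSet", genes = gr, cds = cds)
}

#' Write a GeneModelSet as GFF3
#'
#' Emits `gene`, `mRNA` and `CDS` features with ID/Parent attributes;
#' round-trips through [readGffGenes()].
#'
#' @param genes a [GeneModelSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGff3 <- function(genes, path) {
  gr <- geneRanges(genes)
  cds <- cdsRanges(genes)
  lines <- "##gff-version 3"
  for (i in seq_along(gr)) {
    id <- mcols(gr)$gene_id[i]
    ch <- as.character(GenomeInfoDb::seqnames(gr))[i]
    lines <- c(lines,
      sprintf("%s\tdomscan\tgene\t%d\t%d\t.\t+\t.\tID=%s",
              ch, start(gr)[i], end(gr)[i], id),
      sprintf("%s\tdomscan\tmRNA\t%d\t%d\t.\t+\t.\tID=%s.t1;Parent=%s",
              ch, start(gr)[i], end(gr)[i], id, id))
    ex <- cds[[i]]
    if (length(ex))
      lines <- c(lines,
        sprintf("%s\tdomscan\tCDS\t%d\t%d\t.\t+\t0\tID=%s.cds;Parent=%s.t1",
                ch, start(ex), end(ex), id, id))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a structural-variant set with planted hemizygosity truth
#'
#' Places one deletion per chosen gene, engineered to cover a target
#' fraction of the gene's merged CDS (walking the CDS intervals from the
#' gene start so introns are spanned as needed), with a configured read
#' support. The truth flag for a gene is
#' `achieved fraction >= 0.20 AND support >= 4`, matching the caller's
#' rules under noiseless supports.
#'
#' @param genes a [GeneModelSet-class].
#' @param fractions target CDS fractions, recycled over chosen genes.
#' @param supports read supports, recycled over chosen genes.
#' @param nEvents number of genes to hit (default: all with CDS).
#' @param seed integer seed.
#' @return list with `svs` (data.frame for [filterSv()]/[callHemizygous()])
#'   and `truth` (a [GeneSet-class] of genes that should be flagged).
#' @export
simulateSvSet <- function(genes, fractions = c(0.1, 0.19, 0.2, 0.3, 0.5),
                          supports = c(2, 3, 4, 6, 10),
                          nEvents = NULL, seed = 1L) {
  set.seed(seed)
  gr <- geneRanges(genes)
  cds <- cdsRanges(genes)
  withCds <- which(mcols(gr)$cds_length > 0)
  if (is.null(nEvents)) nEvents <- length(withCds)
  chosen <- sample(withCds, min(nEvents, length(withCds)))
  fractions <- rep_len(fractions, length(chosen))
  supports <- rep_len(supports, length(chosen))
  rows <- vector("list", length(chosen))
  truthIds <- character()
  for (i in seq_along(chosen)) {
    gi <- chosen[i]
    ex <- cds[[gi]]
    len <- mcols(gr)$cds_length[gi]
    target <- max(1L, round(fractions[i] * len))
    # walk merged CDS intervals until `target` coding bases are covered
    covered <- 0L
    endPos <- start(ex)[1]
    for (e in seq_along(ex)) {
      w <- width(ex)[e]
      if (covered + w >= target) {
        endPos <- start(ex)[e] + (target - covered) - 1L
        covered <- target
        break
      }
      covered <- covered + w
      endPos <- end(ex)[e]
    }
    delStart <- start(ex)[1]
    rows[[i]] <- data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(gr))[gi],
      start = delStart, svtype = "DEL",
      length = endPos - delStart + 1L, read_support = supports[i])
    if (covered / len >= 0.20 && supports[i] >= 4)
      truthIds <- c(truthIds, mcols(gr)$gene_id[gi])
  }
  list(svs = do.call(rbind, rows),
       truth = GeneSet(mcols(gr)$gene_id, truthIds, "planted hemizygous"))
}

#' Write a structural-variant set as a SNIFFLES-style VCF
#'
#' @param svs data.frame as produced by [simulateSvSet()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSvVcf <- function(svs, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=domscan-simulator",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
           "##INFO=<ID=RE,Number=1,Type=Integer,Description=\"Read support\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "sample", sep = "\t"))
  svlen <- ifelse(svs$svtype == "DEL", -svs$length, svs$length)
  recs <- sprintf("%s\t%d\t.\tN\t<%s>\t.\tPASS\tSVTYPE=%s;SVLEN=%d;RE=%d\tGT\t0/1",
                  svs$chrom, svs$start, svs$svtype, svs$svtype,
                  svlen, svs$read_support)
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Simulate MSMC2-style rate curves with a planted split
#'
#' Clean mode: piecewise-constant `lambda00 = lambda11 = 1/(2 Ne mu_gen)`
#' with `lambda01 = 0` for epochs younger than the split and `= lambda00`
#' for older epochs — a sharp rCCR step from 0 to 1 with the split exactly
#' at an epoch boundary, so midpoint interpolation of the crossing
#' recovers it exactly. Noisy mode multiplies every rate by independent
#' lognormal(0, sigma) noise.
#'
#' @param splitYears planted split time in years (default 44,000).
#' @param ne diploid effective size.
#' @param muPerYear,genYears scaling constants (defaults 5.4e-9 and 7).
#' @param nEpochs even number of epochs; the split sits at the boundary
#'   after epoch `nEpochs / 2`.
#' @param noiseSigma lognormal sigma (0 = clean).
#' @param seed integer seed (used only when `noiseSigma > 0`).
#' @return list with `curve` (a [RateCurve-class]), `truthScaled` and
#'   `truthYears`.
#' @export
simulateRateCurves <- function(splitYears = 44000, ne = 23148,
                               muPerYear = 5.4e-9, genYears = 7,
                               nEpochs = 32L, noiseSigma = 0,
                               seed = 1L) {
  stopifnot(nEpochs %% 2 == 0)
  muGen <- muPerYear * genYears
  splitScaled <- splitYears * muPerYear
  half <- nEpochs / 2
  w <- splitScaled / half
  left <- (seq_len(nEpochs) - 1) * w
  right <- left + w
  lamWithin <- rep(1 / (2 * ne * muGen), nEpochs)
  lamCross <- ifelse(left >= splitScaled, lamWithin, 0)
  if (noiseSigma > 0) {
    set.seed(seed)
    noise <- function(x) x * stats::rlnorm(length(x), 0, noiseSigma)
    lam00 <- noise(lamWithin); lam11 <- noise(lamWithin)
    lamCross <- noise(lamCross)
  } else {
    lam00 <- lamWithin; lam11 <- lamWithin
  }
  list(curve = RateCurve(left, right, lam00, lamCross, lam11,
                         labels = c("popA", "popB")),
       truthScaled = splitScaled, truthYears = splitYears)
}

#' Assembly N50
#'
#' Length `x` such that contigs of length `>= x` cover at least half the
#' assembly; the standard contiguity summary. Scaffolding the study
#' assembly improved N50 from 3.37 Mb to 61.9 Mb, an ~18-fold change.
#'
#' @param lengths numeric contig/scaffold lengths.
#' @return the N50 length.
#' @examples
#' n50(c(10, 20, 30, 40))   # 30
#' @export
n50 <- function(lengths) {
  lengths <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(lengths)
  lengths[which(cum >= sum(lengths) / 2)[1]]
}
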