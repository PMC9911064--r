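#' Genes near sweep locations
#'
#' A gene is included iff the minimum distance between its span and a sweep
#' test position is at most `flank` bp (default 5 kb on either side of the
#' location; a position inside the gene span counts as distance 0;
#' inclusive boundary, so an edge exactly `flank` bp away is in and
#' `flank + 1` is out).
#'
#' @param sweepPositions `GRanges` of sweep test positions (width-1 ranges,
#'   e.g. midpoints of top-1% CLR windows), or a data.frame with `chrom`
#'   and `pos` columns.
#' @param genes a [GeneModelSet-class].
#' @param flank inclusive distance bound in bp.
#' @param label label for the resulting set.
#' @return a [GeneSet-class] whose universe is all genes in `genes`.
#' @export
genesNearSweeps <- function(sweepPositions, genes, flank = 5000,
                            label = "CLR genes") {
  if (is.data.frame(sweepPositions))
    sweepPositions <- GRanges(sweepPositions$chrom,
                              IRanges(sweepPositions$pos, width = 1L))
  gr <- geneRanges(genes)
  grown <- suppressWarnings(
    GenomicRanges::resize(sweepPositions,
                          width = width(sweepPositions) + 2L * flank,
                          fix = "center"))
  grown <- GenomicRanges::trim(grown)
  hits <- GenomicRanges::findOverlaps(gr, grown)
  GeneSet(universe = mcols(gr)$gene_id,
          members = mcols(gr)$gene_id[unique(S4Vectors::queryHits(hits))],
          label = label)
}

#' Genes overlapping selected windows
#'
#' A gene is included iff its span overlaps any selected window by at least
#' one base (half-open window semantics: a gene starting exactly at a
#' window's end coordinate does not overlap it).
#'
#' @param windows `GRanges` of selected (e.g. top-1% Fst) windows.
#' @param genes a [GeneModelSet-class].
#' @param label label for the resulting set.
#' @return a [GeneSet-class] whose universe is all genes in `genes`.
#' @export
genesInWindows <- function(windows, genes, label = "Fst genes") {
  gr <- geneRanges(genes)
  hits <- GenomicRanges::findOverlaps(gr, windows, minoverlap = 1L)
  GeneSet(universe = mcols(gr)$gene_id,
          members = mcols(gr)$gene_id[unique(S4Vectors::queryHits(hits))],
          label = label)
}

#' Permutation test for the overlap of two gene sets
#'
#' Tests whether two flagged gene sets within the same universe share more
#' members than expected at random. Each permutation independently redraws
#' both sets as uniform random subsets of the universe with their sizes
#' fixed (equivalent to shuffling the flag labels on genes) and recomputes
#' the overlap. The p-value is `(b + 1) / (N + 1)` where `b` counts
#' permutations with overlap at least the observed value, so the smallest
#' reportable p at `N = 10000` is just under 1e-4. Under label shuffling
#' with fixed sizes the null overlap is hypergeometric, which serves as an
#' exact cross-check.
#'
#' This is the machinery both for shared sweep genes between two
#' populations and for the CLR-vs-Fst shared-gene test; the two flagged
#' sets differ only in provenance.
#'
#' @param setA,setB [GeneSet-class] objects over the same universe.
#' @param nPerm number of permutations (default 10,000).
#' @param seed integer seed for reproducibility.
#' @return a [PermutationResult-class].
#' @examples
#' u <- paste0("g", 1:10)
#' a <- GeneSet(u, u[1:3]); b <- GeneSet(u, u[1:4])
#' sharedGenePermutationTest(a, b, nPerm = 1000, seed = 1)
#' @export
sharedGenePermutationTest <- function(setA, setB, nPerm = 10000, seed = 1L) {
  if (!setequal(universe(setA), universe(setB)))
    stop("gene sets must share the same universe")
  u <- universe(setA)
  nU <- length(u)
  nA <- length(members(setA))
  nB <- length(members(setB))
  observed <- length(intersect(members(setA), members(setB)))
  exceed <- 0L
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  for (i in seq_len(nPerm)) {
    a <- sample.int(nU, nA)
    b <- sample.int(nU, nB)
    if (length(intersect(a, b)) >= observed) exceed <- exceed + 1L
  }
  new("PermutationResult", observed = as.integer(observed),
      nPerm = as.integer(nPerm), exceed = exceed,
      pValue = (exceed + 1) / (nPerm + 1), seed = as.integer(seed))
}

#' @rdname sharedGenePermutationTest
#' @param clrSet,fstSet the CLR-derived and Fst-derived [GeneSet-class]
#'   objects.
#' @export
clrFstSharedTest <- function(clrSet, fstSet, nPerm = 10000, seed = 1L) {
  sharedGenePermutationTest(clrSet, fstSet, nPerm = nPerm, seed = seed)
}
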