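#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom IRanges IRanges
#' @import GenomicRanges
NULL

#' GenotypeMatrix: phased-style haplotype-by-site allele matrix
#'
#' The central container for cohort genotypes: a `2 x samples` haplotype by
#' site matrix of 0 (reference/ancestral), 1 (alternate/derived) and `NA`
#' (missing) calls, together with the site annotations (a [GenomicRanges::GRanges]
#' carrying REF/ALT alleles, site QUAL, INFO/DP and the QC filter flag) and
#' per-sample population labels. Haplotypes `2i - 1` and `2i` belong to
#' diploid sample `i`.
#'
#' Genotypes read from unphased VCF GT fields are stored with the two alleles
#' of a genotype in an arbitrary but fixed order; every statistic in the
#' package (allele counts, heterozygosity, the SFS) is invariant to the
#' within-sample ordering.
#'
#' @slot genotypes integer matrix, haplotypes in rows, sites in columns.
#' @slot sites `GRanges` of the site coordinates with metadata columns
#'   `ref`, `alt`, `qual`, `depth`, `filter`, `biallelic`.
#' @slot sampleIds character vector of sample names.
#' @slot population character vector of per-sample population labels
#'   (e.g. `"Mexican"`, `"Lowland"`, `"Guatemalan"`, `"outgroup"`).
#'
#' @seealso [readVcfGenotypes()], [simulateCohort()]
#' @export
setClass("GenotypeMatrix",
  representation(
    genotypes  = "matrix",
    sites      = "GRanges",
    sampleIds  = "character",
    population = "character"
  )
)

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  if (nrow(object@genotypes) != 2L * length(object@sampleIds))
    msg <- c(msg, "haplotype rows must equal 2 x number of samples")
  if (ncol(object@genotypes) != length(object@sites))
    msg <- c(msg, "site columns must match length(sites)")
  if (length(object@population) != length(object@sampleIds))
    msg <- c(msg, "one population label per sample required")
  vals <- object@genotypes
  if (length(vals) && !all(vals %in% c(0L, 1L, NA_integer_)))
    msg <- c(msg, "genotype values must be 0, 1 or NA")
  need <- c("ref", "alt", "qual", "depth", "filter", "biallelic")
  if (!all(need %in% colnames(mcols(object@sites))))
    msg <- c(msg, paste("sites must carry metadata columns:",
                        paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' SweepModel: background spectrum and escape-distance model for the CLR scan
#'
#' Holds the ingredients of the composite-likelihood sweep scan: the
#' background site-frequency spectrum conditioned on polymorphism, the sample
#' size in haplotypes, and the grid of sweep intensities `alpha` over which
#' the composite likelihood is maximised. The probability that a lineage
#' escapes the sweep at physical distance `d` is `p_e = 1 - exp(-alpha * d)`;
#' `alpha = Inf` is the null sentinel under which the sweep spectrum equals
#' the background.
#'
#' @slot n integer, haplotype sample size.
#' @slot sfs numeric of length `n - 1`; `sfs[j]` is the probability of
#'   derived-allele count `j` given polymorphism. Sums to 1.
#' @slot folded logical; `TRUE` if the spectrum is folded (minor-allele).
#' @slot alphaGrid numeric vector of positive sweep intensities, plus `Inf`.
#'
#' @seealso [backgroundSfs()], [sweepModel()], [scanGenome()]
#' @export
setClass("SweepModel",
  representation(
    n         = "integer",
    sfs       = "numeric",
    folded    = "logical",
    alphaGrid = "numeric"
  )
)

setValidity("SweepModel", function(object) {
  msg <- character()
  if (object@n < 2L) msg <- c(msg, "n must be >= 2")
  if (length(object@sfs) != object@n - 1L)
    msg <- c(msg, "sfs must have n - 1 classes")
  if (any(object@sfs < 0)) msg <- c(msg, "sfs classes must be >= 0")
  if (abs(sum(object@sfs) - 1) > 1e-9)
    msg <- c(msg, "sfs must sum to 1 (tolerance 1e-9)")
  if (any(object@alphaGrid <= 0)) msg <- c(msg, "alpha grid must be positive")
  if (length(msg)) msg else TRUE
})

#' GeneModelSet: gene spans with merged CDS intervals
#'
#' Gene models as used by the sweep/Fst gene assignment and the hemizygosity
#' caller: one range per gene plus the merged (disjoint) CDS intervals of
#' each gene. CDS intervals are merged at construction so that the total CDS
#' length equals the number of distinct coding bases.
#'
#' @slot genes `GRanges`, one range per gene, metadata columns `gene_id` and
#'   `cds_length`.
#' @slot cds `GRangesList` of merged CDS intervals, named by `gene_id`,
#'   parallel to `genes`.
#'
#' @seealso [readGffGenes()], [callHemizygous()]
#' @export
setClass("GeneModelSet",
  representation(
    genes = "GRanges",
    cds   = "GRangesList"
  )
)

setValidity("GeneModelSet", function(object) {
  msg <- character()
  if (length(object@genes) != length(object@cds))
    msg <- c(msg, "genes and cds must be parallel")
  if (!all(c("gene_id", "cds_length") %in% colnames(mcols(object@genes))))
    msg <- c(msg, "genes must carry gene_id and cds_length")
  if (length(object@genes) &&
      !identical(names(object@cds), as.character(mcols(object@genes)$gene_id)))
    msg <- c(msg, "cds must be named by gene_id in gene order")
  if (length(msg)) msg else TRUE
})

#' GeneSet: a flagged subset of a gene universe
#'
#' A labelled subset of genes (e.g. "genes within 5 kb of a top-1% CLR sweep
#' location") within an explicit universe. Permutation tests for set overlap
#' operate on pairs of `GeneSet` objects sharing a universe.
#'
#' @slot universe character vector of all gene ids considered.
#' @slot members character vector, subset of `universe`.
#' @slot label single character description of the set.
#'
#' @seealso [genesNearSweeps()], [genesInWindows()],
#'   [sharedGenePermutationTest()]
#' @export
setClass("GeneSet",
  representation(
    universe = "character",
    members  = "character",
    label    = "character"
  )
)

setValidity("GeneSet", function(object) {
  msg <- character()
  if (anyDuplicated(object@universe)) msg <- c(msg, "universe has duplicates")
  if (!all(object@members %in% object@universe))
    msg <- c(msg, "members must be a subset of the universe")
  if (length(msg)) msg else TRUE
})

#' PermutationResult: outcome of a gene-set overlap permutation test
#'
#' @slot observed integer, observed overlap count.
#' @slot nPerm integer, number of permutations.
#' @slot exceed integer, permutations with overlap >= observed.
#' @slot pValue numeric, `(exceed + 1) / (nPerm + 1)`.
#' @slot seed integer seed used for the permutation stream.
#'
#' @seealso [sharedGenePermutationTest()]
#' @export
setClass("PermutationResult",
  representation(
    observed = "integer",
    nPerm    = "integer",
    exceed   = "integer",
    pValue   = "numeric",
    seed     = "integer"
  )
)

setValidity("PermutationResult", function(object) {
  msg <- character()
  if (object@exceed < 0L || object@exceed > object@nPerm)
    msg <- c(msg, "exceed must lie in [0, nPerm]")
  if (object@pValue <= 0 || object@pValue > 1)
    msg <- c(msg, "p-value must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' RateCurve: piecewise-constant coalescence-rate curves (MSMC2 dialect)
#'
#' Per-epoch coalescence rates in mutation-scaled units as emitted by MSMC2:
#' within-population rates `lambda00` and `lambda11` and the
#' cross-population rate `lambda01`. Within-only curves carry `lambda00`
#' alone (`lambda01`/`lambda11` of length 0); cross-population operations
#' reject such curves.
#'
#' @slot leftTime,rightTime numeric epoch boundaries, mutation-scaled,
#'   non-decreasing; the last `rightTime` may be `Inf`.
#' @slot lambda00,lambda01,lambda11 numeric per-epoch rates (>= 0).
#' @slot labels character of length 2 (or 1 for within-only curves).
#'
#' @seealso [readMsmcOutput()], [computeRccr()], [findCrossing()]
#' @export
setClass("RateCurve",
  representation(
    leftTime  = "numeric",
    rightTime = "numeric",
    lambda00  = "numeric",
    lambda01  = "numeric",
    lambda11  = "numeric",
    labels    = "character"
  )
)

setValidity("RateCurve", function(object) {
  msg <- character()
  ne <- length(object@leftTime)
  if (length(object@rightTime) != ne)
    msg <- c(msg, "left and right boundaries must be parallel")
  if (ne && any(object@rightTime < object@leftTime))
    msg <- c(msg, "epoch right boundaries must be >= left boundaries")
  if (ne > 1L && any(diff(object@leftTime) < 0))
    msg <- c(msg, "epoch boundaries must be non-decreasing")
  if (length(object@lambda00) != ne)
    msg <- c(msg, "lambda00 must have one value per epoch")
  cl <- length(object@lambda01)
  if (cl != 0L && cl != ne)
    msg <- c(msg, "lambda01 must be empty or one value per epoch")
  if (length(object@lambda11) != cl)
    msg <- c(msg, "lambda01 and lambda11 must be parallel")
  rates <- c(object@lambda00, object@lambda01, object@lambda11)
  if (length(rates) && any(rates < 0)) msg <- c(msg, "rates must be >= 0")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: study-condition parameters for the cohort simulator
#'
#' Fixes the conditions the simulator emulates: a three-population cohort
#' with nested splits `((Lowland, Guatemalan), Mexican)`, neutral diversity
#' near 0.0035 per site, optional hard-sweep footprints, admixed accessions
#' and SV sets. Defaults follow the study design: 3 Mexican, 5 Lowland and
#' 10 Guatemalan diploids; per-site theta = 4*Ne*mu = 0.0035; a mutation
#' rate of 5.4e-9 per site per year at 7-year generations
#' (mu = 3.78e-8 per generation); splits at 1.3 Mya and 44 kya
#' (185,714 and 6,286 generations).
#'
#' @slot chromLengths named numeric, chromosome lengths in bp.
#' @slot segmentLength integer, independent-genealogy unit in bp.
#' @slot nDiploid named integer, diploid sample sizes per population.
#' @slot ne named numeric, effective sizes: one per sampled population plus
#'   `"LG"` (Lowland+Guatemalan ancestor) and `"ANC"` (root).
#' @slot tRecent,tDeep numeric split times in generations, `tRecent < tDeep`.
#' @slot mu numeric, per-site per-generation mutation rate.
#' @slot sweeps data.frame with columns `population`, `chrom`, `center`,
#'   `radius`, `s` (intensity in (0, 1]); zero rows for neutral genomes.
#' @slot hybrids data.frame with columns `id`, `qMexican`, `qLowland`,
#'   `qGuatemalan` (rows sum to 1); zero rows for none.
#'
#' @seealso [simulationConfig()], [simulateCohort()]
#' @export
setClass("SimulationConfig",
  representation(
    chromLengths  = "numeric",
    segmentLength = "integer",
    nDiploid      = "integer",
    ne            = "numeric",
    tRecent       = "numeric",
    tDeep         = "numeric",
    mu            = "numeric",
    sweeps        = "data.frame",
    hybrids       = "data.frame"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (is.null(names(object@chromLengths)) || any(object@chromLengths <= 0))
    msg <- c(msg, "chromLengths must be named and positive")
  if (object@segmentLength < 1L) msg <- c(msg, "segmentLength must be >= 1")
  pops <- c("Mexican", "Lowland", "Guatemalan")
  if (!all(pops %in% names(object@nDiploid)))
    msg <- c(msg, "nDiploid must name Mexican, Lowland and Guatemalan")
  if (!all(c(pops, "LG", "ANC") %in% names(object@ne)))
    msg <- c(msg, "ne must name the three populations plus LG and ANC")
  if (!(object@tRecent < object@tDeep))
    msg <- c(msg, "tRecent must be < tDeep")
  if (object@mu < 0) msg <- c(msg, "mu must be >= 0")
  if (nrow(object@sweeps) &&
      (any(object@sweeps$s <= 0) || any(object@sweeps$s > 1)))
    msg <- c(msg, "sweep intensity s must lie in (0, 1]")
  if (nrow(object@hybrids)) {
    qs <- rowSums(object@hybrids[, c("qMexican", "qLowland", "qGuatemalan")])
    if (any(abs(qs - 1) > 1e-6))
      msg <- c(msg, "hybrid proportions must sum to 1")
  }
  if (length(msg)) msg else TRUE
})
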