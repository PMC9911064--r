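#' @describeIn GenotypeMatrix-accessors haplotype-by-site allele matrix
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @describeIn GenotypeMatrix-accessors site annotations as a `GRanges`
#' @export
setGeneric("sites", function(x) standardGeneric("sites"))

#' @describeIn GenotypeMatrix-accessors sample identifiers
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @describeIn GenotypeMatrix-accessors per-sample population labels
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @describeIn GenotypeMatrix-accessors number of diploid samples
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @describeIn GenotypeMatrix-accessors number of sampled haplotypes
#'   (chromosomes), `2 * nSamples(x)`
#' @export
setGeneric("nHaplotypes", function(x) standardGeneric("nHaplotypes"))

#' Accessors for GenotypeMatrix objects
#'
#' Small read-only accessors; slots are never reached into directly. A cohort
#' of 3 diploid individuals has `nHaplotypes(x) == 6` sampled chromosomes.
#'
#' @param x a [GenotypeMatrix-class] object.
#' @return the corresponding slot content.
#' @name GenotypeMatrix-accessors
#' @aliases genotypes sites sampleIds populations nSamples nHaplotypes
#' @examples
#' gm <- exampleGenotypeMatrix()
#' nSamples(gm)
#' nHaplotypes(gm)
NULL

#' @rdname GenotypeMatrix-accessors
setMethod("genotypes", "GenotypeMatrix", function(x) x@genotypes)

#' @rdname GenotypeMatrix-accessors
setMethod("sites", "GenotypeMatrix", function(x) x@sites)

#' @rdname GenotypeMatrix-accessors
setMethod("sampleIds", "GenotypeMatrix", function(x) x@sampleIds)

#' @rdname GenotypeMatrix-accessors
setMethod("populations", "GenotypeMatrix", function(x) {
  stats::setNames(x@population, x@sampleIds)
})

#' @rdname GenotypeMatrix-accessors
setMethod("nSamples", "GenotypeMatrix", function(x) length(x@sampleIds))

#' @rdname GenotypeMatrix-accessors
setMethod("nHaplotypes", "GenotypeMatrix", function(x) 2L * length(x@sampleIds))

setMethod("show", "GenotypeMatrix", function(object) {
  pops <- table(object@population)
  cat("GenotypeMatrix:", nrow(object@genotypes), "haplotypes x",
      ncol(object@genotypes), "sites\n")
  cat("  samples:", length(object@sampleIds), "(",
      paste(names(pops), pops, sep = "=", collapse = ", "), ")\n")
  nmiss <- sum(is.na(object@genotypes))
  cat("  missing calls:",
      sprintf("%.2f%%", 100 * nmiss / max(1, length(object@genotypes))), "\n")
})

#' Subset a GenotypeMatrix by samples and/or sites
#'
#' `x[i, j]` keeps samples `i` (by index or id) and site columns `j`.
#' Haplotype rows follow the sample subset.
#'
#' @param x a [GenotypeMatrix-class].
#' @param i sample indices or sample ids.
#' @param j site column indices (logical or integer).
#' @param ... ignored.
#' @param drop ignored (always `FALSE` semantics).
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_along(x@sampleIds)
  if (is.character(i)) {
    idx <- match(i, x@sampleIds)
    if (anyNA(idx))
      stop("unknown sample id(s): ", paste(i[is.na(idx)], collapse = ", "))
    i <- idx
  }
  if (is.logical(i)) i <- which(i)
  if (missing(j)) j <- seq_len(ncol(x@genotypes))
  hapRows <- as.vector(rbind(2L * i - 1L, 2L * i))
  new("GenotypeMatrix",
      genotypes  = x@genotypes[hapRows, j, drop = FALSE],
      sites      = x@sites[j],
      sampleIds  = x@sampleIds[i],
      population = x@population[i])
})

#' Construct a GenotypeMatrix from components
#'
#' @param genotypes integer matrix of 0/1/NA, haplotypes in rows (two
#'   consecutive rows per sample), sites in columns.
#' @param sites `GRanges` of site coordinates; missing metadata columns among
#'   `ref`, `alt`, `qual`, `depth`, `filter`, `biallelic` are filled with
#'   defaults.
#' @param sampleIds character sample names.
#' @param population per-sample population labels (recycled if length 1).
#' @return a [GenotypeMatrix-class].
#' @export
GenotypeMatrix <- function(genotypes, sites, sampleIds,
                           population = "unassigned") {
  storage.mode(genotypes) <- "integer"
  population <- rep_len(population, length(sampleIds))
  mc <- mcols(sites)
  if (is.null(mc$ref))    mc$ref    <- rep("A", length(sites))
  if (is.null(mc$alt))    mc$alt    <- rep("T", length(sites))
  if (is.null(mc$qual))   mc$qual   <- rep(NA_real_, length(sites))
  if (is.null(mc$depth))  mc$depth  <- rep(NA_real_, length(sites))
  if (is.null(mc$filter)) mc$filter <- rep("PASS", length(sites))
  if (is.null(mc$biallelic)) mc$biallelic <- rep(TRUE, length(sites))
  mcols(sites) <- mc
  new("GenotypeMatrix", genotypes = genotypes, sites = sites,
      sampleIds = sampleIds, population = population)
}

#' A small example GenotypeMatrix
#'
#' Three diploid samples over five sites; used in documentation examples.
#' @return a [GenotypeMatrix-class].
#' @export
exampleGenotypeMatrix <- function() {
  g <- matrix(c(0L, 1L, 0L, 0L, 1L,
                0L, 0L, 1L, 0L, 0L,
                1L, 0L, 0L, 0L, 1L,
                0L, 0L, 1L, 0L, 0L,
                0L, 1L, 0L, NA, 1L,
                0L, 0L, 0L, NA, 0L),
              nrow = 6, byrow = TRUE)
  sites <- GRanges("chr1", IRanges(c(101, 205, 340, 488, 602), width = 1))
  GenotypeMatrix(g, sites, sampleIds = c("s1", "s2", "s3"),
                 population = c("Mexican", "Mexican", "Lowland"))
}

setMethod("show", "SweepModel", function(object) {
  cat("SweepModel: n =", object@n, "haplotypes,",
      if (object@folded) "folded" else "unfolded", "spectrum\n")
  cat("  alpha grid:", sum(is.finite(object@alphaGrid)), "finite points",
      if (any(is.infinite(object@alphaGrid))) "+ null sentinel (Inf)" else "",
      "\n")
})

setMethod("show", "GeneSet", function(object) {
  cat("GeneSet", sQuote(object@label), ":", length(object@members),
      "of", length(object@universe), "genes flagged\n")
})

setMethod("show", "PermutationResult", function(object) {
  cat("PermutationResult: observed overlap =", object@observed,
      "| permutations =", object@nPerm, "\n")
  cat(sprintf("  P = %.4g  (%d of %d permutations >= observed; seed %d)\n",
              object@pValue, object@exceed, object@nPerm, object@seed))
})

setMethod("show", "RateCurve", function(object) {
  cat("RateCurve:", length(object@leftTime), "epochs,",
      if (length(object@lambda01)) "within + cross rates"
      else "within-population only", "\n")
  if (length(object@labels))
    cat("  populations:", paste(object@labels, collapse = " / "), "\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", length(object@chromLengths), "chromosomes,",
      sprintf("%.1f Mb total", sum(object@chromLengths) / 1e6), "\n")
  cat("  diploids:", paste(names(object@nDiploid), object@nDiploid,
                           sep = "=", collapse = ", "), "\n")
  cat("  splits (generations): recent =", object@tRecent,
      "deep =", object@tDeep, "\n")
  cat("  sweeps:", nrow(object@sweeps), "| hybrids:",
      nrow(object@hybrids), "\n")
})

#' Accessors for GeneSet, GeneModelSet, PermutationResult and RateCurve
#'
#' @param x the object.
#' @return the corresponding component.
#' @name misc-accessors
NULL

#' @rdname misc-accessors
#' @export
setGeneric("universe", function(x) standardGeneric("universe"))

#' @rdname misc-accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname misc-accessors
setMethod("universe", "GeneSet", function(x) x@universe)

#' @rdname misc-accessors
setMethod("members", "GeneSet", function(x) x@members)

#' @rdname misc-accessors
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname misc-accessors
#' @export
setGeneric("cdsRanges", function(x) standardGeneric("cdsRanges"))

#' @rdname misc-accessors
setMethod("geneRanges", "GeneModelSet", function(x) x@genes)

#' @rdname misc-accessors
setMethod("cdsRanges", "GeneModelSet", function(x) x@cds)

setMethod("show", "GeneModelSet", function(object) {
  cat("GeneModelSet:", length(object@genes), "genes,",
      sum(mcols(object@genes)$cds_length), "merged CDS bases\n")
})

#' @rdname misc-accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname misc-accessors
setMethod("pValue", "PermutationResult", function(x) x@pValue)

#' @rdname misc-accessors
#' @export
setGeneric("epochTimes", function(x) standardGeneric("epochTimes"))

#' @rdname misc-accessors
setMethod("epochTimes", "RateCurve", function(x) {
  data.frame(left = x@leftTime, right = x@rightTime)
})

#' @rdname misc-accessors
#' @export
setGeneric("lambdas", function(x) standardGeneric("lambdas"))

#' @rdname misc-accessors
setMethod("lambdas", "RateCurve", function(x) {
  out <- data.frame(lambda00 = x@lambda00)
  if (length(x@lambda01)) {
    out$lambda01 <- x@lambda01
    out$lambda11 <- x@lambda11
  }
  out
})

#' Construct a GeneSet
#'
#' @param universe character vector of gene ids (duplicates dropped).
#' @param members character vector, subset of `universe`.
#' @param label description of the set.
#' @return a [GeneSet-class].
#' @export
GeneSet <- function(universe, members = character(), label = "gene set") {
  new("GeneSet", universe = unique(as.character(universe)),
      members = unique(as.character(members)), label = label)
}

#' Construct a RateCurve
#'
#' @param leftTime,rightTime epoch boundaries (mutation-scaled).
#' @param lambda00 within-population rate for the first population.
#' @param lambda01,lambda11 cross- and second within-population rates;
#'   omit both for a within-only curve.
#' @param labels population label(s).
#' @return a [RateCurve-class].
#' @export
RateCurve <- function(leftTime, rightTime, lambda00,
                      lambda01 = numeric(), lambda11 = numeric(),
                      labels = c("pop1", "pop2")) {
  if (length(lambda01) == 0L) labels <- labels[1]
  new("RateCurve", leftTime = as.numeric(leftTime),
      rightTime = as.numeric(rightTime),
      lambda00 = as.numeric(lambda00), lambda01 = as.numeric(lambda01),
      lambda11 = as.numeric(lambda11), labels = labels)
}
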