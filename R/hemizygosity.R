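#' Read structural-variant calls (SNIFFLES-style VCF or BED)
#'
#' Accepts a VCF with `SVTYPE`/`SVLEN` INFO keys and read support in `RE`
#' or `SUPPORT` (SNIFFLES dialect), or a BED-like TSV with columns
#' `chrom`, `start` (0-based), `svtype`, `length`, `read_support`.
#'
#' @param path file path.
#' @return data.frame with columns `chrom`, `start` (1-based first
#'   affected base), `svtype`, `length`, `read_support`.
#' @export
readSvCalls <- function(path) {
  first <- readLines(path, n = 1)
  if (startsWith(first, "##fileformat=VCF")) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v, getINFO = TRUE)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    info <- fix[, "INFO"]
    grab <- function(key) {
      val <- sub(paste0("^.*(?:^|;)", key, "=([^;]+).*$"), "\\1",
                 info, perl = TRUE)
      val[!grepl(paste0("(^|;)", key, "="), info)] <- NA
      val
    }
    data.frame(chrom = fix[, "CHROM"],
               start = as.integer(fix[, "POS"]),
               svtype = grab("SVTYPE"),
               length = abs(as.numeric(grab("SVLEN"))),
               read_support = {
                 re <- suppressWarnings(as.numeric(grab("RE")))
                 sup <- suppressWarnings(as.numeric(grab("SUPPORT")))
                 ifelse(is.na(re), sup, re)
               },
               stringsAsFactors = FALSE)
  } else {
    sv <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    need <- c("chrom", "start", "svtype", "length", "read_support")
    if (!all(need %in% names(sv)))
      stop("BED-style SV table must have columns: ",
           paste(need, collapse = ", "))
    sv$start <- sv$start + 1L   # 0-based BED -> 1-based internal
    sv[, need]
  }
}

#' Filter structural variants by read support and type
#'
#' Keeps insertion/deletion events substantiated by at least `minSupport`
#' supporting reads (inclusive, "at least 4" semantics). Records of other
#' types (inversions, duplications, translocations) are skipped with a
#' warning.
#'
#' @param svs data.frame as from [readSvCalls()].
#' @param minSupport minimum read support (default 4).
#' @return the filtered data.frame.
#' @examples
#' svs <- data.frame(chrom = "chr1", start = c(10, 20, 30),
#'                   svtype = c("DEL", "DEL", "INV"),
#'                   length = 100, read_support = c(3, 4, 10))
#' filterSv(svs)   # only the support-4 deletion survives
#' @export
filterSv <- function(svs, minSupport = 4) {
  if (is.null(svs$read_support)) stop("read_support column required")
  known <- svs$svtype %in% c("DEL", "INS")
  if (any(!known))
    warning(sum(!known), " SV record(s) of unsupported type skipped: ",
            paste(unique(svs$svtype[!known]), collapse = ", "))
  svs[known & !is.na(svs$read_support) & svs$read_support >= minSupport, ,
      drop = FALSE]
}

#' Call genic hemizygosity from filtered structural variants
#'
#' A gene is flagged hemizygous when a single insertion/deletion event
#' affects at least `minCdsFraction` (default 20%, inclusive) of its
#' merged coding region:
#' * deletions: bases of overlap between the deletion span and the gene's
#'   merged CDS intervals, divided by total CDS length;
#' * insertions (point events that cannot "overlap" coding sequence): the
#'   breakpoint must fall inside a CDS interval and the inserted length
#'   must reach the same fraction of the CDS length. This reading of the
#'   rule for insertions is an interpretation; see the package vignette.
#'
#' With several SVs per gene the maximum single-event fraction decides
#' (per-event, not cumulative). Genes with zero CDS length are never
#' flagged.
#'
#' @param genes a [GeneModelSet-class].
#' @param svs data.frame of SVs, already passed through [filterSv()].
#' @param minCdsFraction inclusive coding-overlap fraction (default 0.20).
#' @param label label for the resulting set.
#' @return a [GeneSet-class] over all genes in `genes`, with a
#'   `fractions` attribute giving each gene's maximum single-event CDS
#'   fraction.
#' @export
callHemizygous <- function(genes, svs, minCdsFraction = 0.20,
                           label = "hemizygous genes") {
  gr <- geneRanges(genes)
  cds <- cdsRanges(genes)
  cdsLen <- mcols(gr)$cds_length
  ids <- mcols(gr)$gene_id
  best <- stats::setNames(numeric(length(ids)), ids)
  if (nrow(svs)) {
    del <- svs[svs$svtype == "DEL", , drop = FALSE]
    ins <- svs[svs$svtype == "INS", , drop = FALSE]
    cdsUl <- unlist(cds, use.names = FALSE)
    cdsGene <- rep(seq_along(cds), lengths(cds))
    if (nrow(del)) {
      delGr <- GRanges(del$chrom,
                       IRanges(del$start, width = pmax(1, del$length)))
      hits <- GenomicRanges::findOverlaps(delGr, cdsUl)
      if (length(hits)) {
        ovw <- width(GenomicRanges::pintersect(
          delGr[S4Vectors::queryHits(hits)],
          cdsUl[S4Vectors::subjectHits(hits)]))
        gIdx <- cdsGene[S4Vectors::subjectHits(hits)]
        # per (event, gene) total CDS overlap, then best event per gene
        key <- paste(S4Vectors::queryHits(hits), gIdx)
        perEvent <- tapply(ovw, key, sum)
        geneOf <- as.integer(sub("^\\S+ ", "", names(perEvent)))
        frac <- as.numeric(perEvent) / cdsLen[geneOf]
        frac[cdsLen[geneOf] == 0] <- 0
        for (gi in unique(geneOf)) {
          m <- max(frac[geneOf == gi])
          if (m > best[gi]) best[gi] <- m
        }
      }
    }
    if (nrow(ins)) {
      insGr <- GRanges(ins$chrom, IRanges(ins$start, width = 1L))
      hits <- GenomicRanges::findOverlaps(insGr, cdsUl)
      if (length(hits)) {
        gIdx <- cdsGene[S4Vectors::subjectHits(hits)]
        frac <- ins$length[S4Vectors::queryHits(hits)] / cdsLen[gIdx]
        frac[cdsLen[gIdx] == 0] <- 0
        for (h in seq_along(hits)) {
          gi <- gIdx[h]
          if (frac[h] > best[gi]) best[gi] <- frac[h]
        }
      }
    }
  }
  zero <- cdsLen == 0
  if (any(best[zero] > 0)) best[zero] <- 0
  flagged <- ids[best >= minCdsFraction & !zero]
  out <- GeneSet(universe = ids, members = flagged, label = label)
  attr(out, "fractions") <- best
  out
}

#' Genic hemizygosity rate
#'
#' The fraction of flagged genes in the universe, with the percent value
#' rounded to one decimal as conventionally reported (17 flagged of 466
#' genes is 3.6%).
#'
#' @param geneset a [GeneSet-class] (e.g. from [callHemizygous()]).
#' @return list with `fraction`, `percent` (rounded to one decimal),
#'   `flagged` and `total`.
#' @examples
#' gs <- GeneSet(paste0("g", 1:466), paste0("g", 1:17))
#' hemizygosityRate(gs)$percent   # 3.6
#' @export
hemizygosityRate <- function(geneset) {
  total <- length(universe(geneset))
  if (total == 0L) stop("empty gene universe")
  flagged <- length(members(geneset))
  frac <- flagged / total
  list(fraction = frac, percent = round(100 * frac, 1),
       flagged = flagged, total = total)
}
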