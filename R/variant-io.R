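#' Read a VCF into a GenotypeMatrix
#'
#' Reads a VCF 4.x file (plain or gzipped; parsing via [vcfR::read.vcfR])
#' into a [GenotypeMatrix-class]. Every record becomes one site column.
#' Multiallelic and non-SNP records are retained but flagged
#' `biallelic = FALSE` so that [selectBiallelicSnps()] can drop them later.
#' Missing genotypes (`./.`) yield `NA` for both haplotypes; any non-zero
#' allele index is coded 1 (only biallelic records are used by downstream
#' statistics). Site depth is taken from `INFO/DP` when present.
#'
#' @param path VCF file path.
#' @param sampleSubset optional character vector of sample names to keep;
#'   unknown names are an error.
#' @param population optional per-sample population labels, parallel to the
#'   retained samples.
#' @return a [GenotypeMatrix-class].
#' @seealso [writeVcfGenotypes()], [selectBiallelicSnps()]
#' @export
readVcfGenotypes <- function(path, sampleSubset = NULL, population = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  pos <- suppressWarnings(as.numeric(fix[, "POS"]))
  if (anyNA(pos))
    stop("malformed VCF record at data line ", which(is.na(pos))[1],
         ": non-numeric POS")
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2L)
    stop("VCF has no genotype (GT) columns: ", path)
  samples <- colnames(gt)[-1]
  if (!is.null(sampleSubset)) {
    missing <- setdiff(sampleSubset, samples)
    if (length(missing))
      stop("unknown sample(s) in subset: ", paste(missing, collapse = ", "))
    samples <- sampleSubset
  }
  gtField <- sub(":.*$", "", gt[, samples, drop = FALSE])
  nSite <- length(pos)
  hap <- matrix(NA_integer_, nrow = 2L * length(samples), ncol = nSite)
  for (k in seq_along(samples)) {
    calls <- gtField[, k]
    a1 <- sub("^([^/|]*)[/|].*$", "\\1", calls)
    a2 <- sub("^[^/|]*[/|](.*)$", "\\1", calls)
    haploid <- !grepl("[/|]", calls)
    a2[haploid] <- a1[haploid]
    code <- function(a) {
      out <- rep(NA_integer_, length(a))
      out[a == "0"] <- 0L
      num <- suppressWarnings(as.integer(a))
      out[!is.na(num) & num > 0L] <- 1L
      out
    }
    hap[2L * k - 1L, ] <- code(a1)
    hap[2L * k, ]      <- code(a2)
  }
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  alt[is.na(alt)] <- "."
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  info <- fix[, "INFO"]
  dp <- suppressWarnings(as.numeric(sub("^.*?\\bDP=([0-9.]+).*$", "\\1",
                                        paste0(";", info))))
  dp[!grepl("\\bDP=", info)] <- NA_real_
  filt <- fix[, "FILTER"]
  filt[is.na(filt) | filt == "."] <- "PASS"
  biallelic <- !grepl(",", alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    alt != "."
  sitesGr <- GRanges(fix[, "CHROM"], IRanges(pos, width = 1L))
  mcols(sitesGr) <- DataFrame(ref = ref, alt = alt, qual = qual, depth = dp,
                              filter = filt, biallelic = biallelic)
  if (is.null(population)) population <- "unassigned"
  GenotypeMatrix(hap, sitesGr, sampleIds = samples, population = population)
}

#' Write a GenotypeMatrix as a plain-text VCF 4.2 file
#'
#' Emits one record per site column with phased-style `a|b` GT fields
#' (missing calls as `.`), QUAL, the QC filter flag, and `DP` in INFO when
#' depth is known. `CHROM`/`POS`/`REF`/`ALT`/`GT` round-trip exactly through
#' [readVcfGenotypes()].
#'
#' @param x a [GenotypeMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeVcfGenotypes <- function(x, path) {
  s <- sites(x)
  g <- genotypes(x)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=domscan",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Site depth\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  sl <- GenomeInfoDb::seqlengths(s)
  for (ch in GenomeInfoDb::seqlevels(s)) {
    hdr <- c(hdr, if (!is.na(sl[ch]))
      sprintf("##contig=<ID=%s,length=%d>", ch, sl[ch])
      else sprintf("##contig=<ID=%s>", ch))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", sampleIds(x)),
                      collapse = "\t"))
  mc <- mcols(s)
  qual <- ifelse(is.na(mc$qual), ".", formatC(mc$qual, format = "g"))
  info <- ifelse(is.na(mc$depth), ".",
                 paste0("DP=", formatC(mc$depth, format = "d")))
  gtChar <- matrix(".", nrow = nrow(g), ncol = ncol(g))
  gtChar[!is.na(g)] <- as.character(g[!is.na(g)])
  odd <- seq(1L, nrow(g), by = 2L)
  gtCols <- matrix(paste(gtChar[odd, , drop = FALSE],
                         gtChar[odd + 1L, , drop = FALSE], sep = "|"),
                   nrow = length(odd))
  recs <- paste(as.character(GenomeInfoDb::seqnames(s)), start(s), ".",
                mc$ref, mc$alt, qual, mc$filter, info, "GT", sep = "\t")
  if (length(recs))
    recs <- paste(recs, apply(gtCols, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Site-level QC flag: %QUAL < 20 || DP > 32
#'
#' The per-site filter applied before biallelic SNP selection: a site is
#' `LowQual` when its quality is below `qualMin` *or* its depth exceeds
#' `dpMax` (strict inequalities, matching the bcftools expression
#' `-e "%QUAL < 20 || DP > 32"`); otherwise `PASS`. A missing depth (or
#' quality) cannot trigger its clause and passes it.
#'
#' @param qual numeric site quality score(s).
#' @param depth numeric site depth(s) (`INFO/DP`); `NA` passes the clause.
#' @param qualMin,dpMax thresholds (defaults 20 and 32).
#' @return character vector `"PASS"`/`"LowQual"`.
#' @examples
#' siteQcFlag(qual = c(19, 20, 50), depth = c(10, 32, 33))
#' @export
siteQcFlag <- function(qual, depth, qualMin = 20, dpMax = 32) {
  n <- max(length(qual), length(depth))
  qual <- rep_len(qual, n)
  depth <- rep_len(depth, n)
  if (any(depth < 0, na.rm = TRUE)) stop("negative site depth")
  low <- (!is.na(qual) & qual < qualMin) | (!is.na(depth) & depth > dpMax)
  ifelse(low, "LowQual", "PASS")
}

#' Apply the site QC flag to every site of a GenotypeMatrix
#'
#' @param x a [GenotypeMatrix-class].
#' @inheritParams siteQcFlag
#' @return `x` with the `filter` site metadata column rewritten.
#' @export
flagSites <- function(x, qualMin = 20, dpMax = 32) {
  s <- sites(x)
  mcols(s)$filter <- siteQcFlag(mcols(s)$qual, mcols(s)$depth,
                                qualMin, dpMax)
  methods::initialize(x, sites = s)
}

#' Keep PASS biallelic SNPs only
#'
#' Retains, in original order, sites that pass QC (`filter == "PASS"`), have
#' exactly one alternate allele, and are single-nucleotide for both REF and
#' ALT. Idempotent.
#'
#' @param x a [GenotypeMatrix-class] (typically after [flagSites()]).
#' @return the filtered [GenotypeMatrix-class].
#' @export
selectBiallelicSnps <- function(x) {
  mc <- mcols(sites(x))
  keep <- mc$filter == "PASS" & mc$biallelic
  x[, keep]
}

#' Remove samples with excessive missing data
#'
#' Per-sample missingness is the fraction of missing haplotype calls across
#' all site columns. Ingroup samples are kept iff their fraction is strictly
#' below `maxMissingIngroup` (default 50%), outgroup samples iff strictly
#' below `maxMissingOutgroup` (default 75%).
#'
#' @param x a [GenotypeMatrix-class] with population labels set.
#' @param maxMissingIngroup,maxMissingOutgroup strict upper bounds on the
#'   missing fraction.
#' @param outgroupLabels population labels treated as outgroup.
#' @return the filtered [GenotypeMatrix-class].
#' @export
missingnessFilter <- function(x, maxMissingIngroup = 0.50,
                              maxMissingOutgroup = 0.75,
                              outgroupLabels = "outgroup") {
  if (ncol(genotypes(x)) == 0L || nSamples(x) == 0L)
    stop("empty genotype matrix")
  g <- genotypes(x)
  idx <- seq_len(nSamples(x))
  frac <- vapply(idx, function(i) {
    rows <- c(2L * i - 1L, 2L * i)
    mean(is.na(g[rows, ]))
  }, numeric(1))
  thr <- ifelse(populations(x) %in% outgroupLabels,
                maxMissingOutgroup, maxMissingIngroup)
  x[which(frac < thr), ]
}

#' Tile chromosomes into non-overlapping windows
#'
#' Tiles each chromosome into consecutive `width`-bp windows, keeping the
#' final partial window. Windows lying entirely inside assembly gaps (runs
#' of N) are removed; remaining windows carry their gap-overlap fraction in
#' the `gap_fraction` metadata column, so density statistics can normalise
#' by non-gap width. Overlapping gap intervals are merged, not errored.
#'
#' @param chromLengths named numeric vector of chromosome lengths (bp).
#' @param gaps `GRanges` of assembly gaps (may be empty).
#' @param width window width in bp (> 0).
#' @return a `GRanges` of windows, sorted, with `gap_fraction` metadata.
#' @examples
#' tileWindows(c(chr1 = 25000), width = 10000)
#' @export
tileWindows <- function(chromLengths, gaps = GRanges(), width) {
  stopifnot(width > 0)
  if (is.null(names(chromLengths)))
    stop("chromLengths must be named by chromosome")
  wins <- lapply(names(chromLengths), function(ch) {
    len <- chromLengths[[ch]]
    starts <- seq(1L, len, by = width)
    GRanges(ch, IRanges(starts, end = pmin(starts + width - 1L, len)))
  })
  wins <- suppressWarnings(do.call(c, wins))
  GenomeInfoDb::seqlengths(wins) <-
    chromLengths[GenomeInfoDb::seqlevels(wins)]
  gaps <- GenomicRanges::reduce(gaps)
  ov <- rep(0, length(wins))
  if (length(gaps)) {
    hits <- GenomicRanges::findOverlaps(wins, gaps)
    if (length(hits)) {
      w <- width(GenomicRanges::pintersect(
        wins[S4Vectors::queryHits(hits)], gaps[S4Vectors::subjectHits(hits)]))
      ov <- ov + as.numeric(
        tapply(w, factor(S4Vectors::queryHits(hits),
                         levels = seq_along(wins)), sum, default = 0))
      ov[is.na(ov)] <- 0
    }
  }
  mcols(wins)$gap_fraction <- ov / width(wins)
  wins[mcols(wins)$gap_fraction < 1]
}

#' Read an admixture Q-matrix table
#'
#' Whitespace-delimited table, one row per accession: an accession id column
#' followed by K ancestry-proportion columns (fractions or percentages).
#' A header row is detected when the proportion columns are non-numeric on
#' the first line.
#'
#' @param path file path.
#' @param groups column names to use when the file has no header.
#' @return data.frame with `accession` plus one column per group.
#' @export
readQMatrix <- function(path, groups = NULL) {
  first <- strsplit(trimws(readLines(path, n = 1)), "\\s+")[[1]]
  hasHeader <- length(first) > 1 &&
    all(is.na(suppressWarnings(as.numeric(first[-1]))))
  q <- utils::read.table(path, header = hasHeader,
                         stringsAsFactors = FALSE, check.names = FALSE)
  names(q)[1] <- "accession"
  if (!hasHeader && !is.null(groups)) names(q)[-1] <- groups
  q
}

#' Classify accessions into genetic groups from ancestry proportions
#'
#' An accession is assigned to the group with its maximum ancestry
#' proportion iff that proportion strictly exceeds `threshold` (default
#' Qi > 0.80) and the accession is not on the exclusion list; otherwise it
#' is labelled `"admixed"` (or `"excluded"`). Each row is normalised before
#' testing: rows summing to ~1 are taken as fractions, rows summing to ~100
#' as percentages; anything else is an error.
#'
#' @param q data.frame as from [readQMatrix()]: `accession` column plus one
#'   numeric column per group.
#' @param threshold strict lower bound for single-group assignment.
#' @param exclusions accession ids to mark `"excluded"` regardless of
#'   proportions (e.g. close relatives of an over-sampled cultivar).
#' @return `q` with added columns `assigned_group` and `max_q` (normalised
#'   maximum proportion); proportion columns rescaled to fractions.
#' @examples
#' q <- data.frame(accession = c("Lyon", "Bacon"),
#'                 Guatemalan = c(83.78, 37.69),
#'                 Mexican = c(16.22, 62.31), Lowland = c(0, 0))
#' classifyAccessions(q)$assigned_group
#' @export
classifyAccessions <- function(q, threshold = 0.80, exclusions = character()) {
  propCols <- setdiff(names(q), "accession")
  mat <- as.matrix(q[, propCols, drop = FALSE])
  sums <- rowSums(mat)
  isFrac <- sums >= 0.99 & sums <= 1.01
  isPct  <- sums >= 99   & sums <= 101
  if (any(!isFrac & !isPct))
    stop("ancestry proportions for ",
         paste(q$accession[!isFrac & !isPct], collapse = ", "),
         " sum to neither ~1 nor ~100")
  mat[isPct, ] <- mat[isPct, , drop = FALSE] / 100
  mat <- mat / rowSums(mat)
  best <- propCols[max.col(mat, ties.method = "first")]
  maxQ <- mat[cbind(seq_len(nrow(mat)), max.col(mat, ties.method = "first"))]
  assigned <- ifelse(maxQ > threshold, best, "admixed")
  assigned[q$accession %in% exclusions] <- "excluded"
  q[, propCols] <- mat
  q$max_q <- maxQ
  q$assigned_group <- assigned
  q
}

#' Read gene models (gene spans + merged CDS) from a GFF3 file
#'
#' Parses `gene` and `CDS` features via `rtracklayer::import()`. CDS
#' intervals are attached to their gene through the `Parent` chain (either
#' directly or via an mRNA), merged per gene, and summed into the total CDS
#' length. CDS features whose parent gene cannot be resolved are skipped
#' with a warning.
#'
#' @param path GFF3 file path.
#' @return a [GeneModelSet-class].
#' @export
readGffGenes <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  type <- as.character(mcols(gff)$type)
  genes <- gff[type == "gene"]
  geneIds <- as.character(mcols(genes)$ID)
  if (anyNA(geneIds) || any(geneIds == ""))
    stop("gene features without ID attribute in ", path)
  mrna <- gff[type %in% c("mRNA", "transcript")]
  mrnaParent <- stats::setNames(
    vapply(mcols(mrna)$Parent, function(p)
      if (length(p)) as.character(p[1]) else NA_character_, character(1)),
    as.character(mcols(mrna)$ID))
  cds <- gff[type == "CDS"]
  cdsParent <- vapply(mcols(cds)$Parent, function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1))
  # resolve through mRNA level where needed
  viaMrna <- cdsParent %in% names(mrnaParent)
  cdsGene <- cdsParent
  cdsGene[viaMrna] <- mrnaParent[cdsParent[viaMrna]]
  orphan <- !(cdsGene %in% geneIds)
  if (any(orphan)) {
    warning(sum(orphan), " CDS feature(s) without a parent gene skipped")
    cds <- cds[!orphan]
    cdsGene <- cdsGene[!orphan]
  }
  mcols(cds) <- NULL
  cdsList <- GenomicRanges::reduce(
    GenomicRanges::split(cds, factor(cdsGene, levels = geneIds)))
  lens <- vapply(cdsList, function(gr) sum(width(gr)), numeric(1))
  out <- granges(genes)
  mcols(out) <- DataFrame(gene_id = geneIds, cds_length = as.integer(lens))
  names(out) <- geneIds
  new("GeneModelSet", genes = out, cds = cdsList)
}

#' Export a window track as BED
#'
#' Writes `chrom`, 0-based half-open `start`/`end`, and one value column
#' (BED4-style TSV). `NA`-valued windows are omitted.
#'
#' @param track `GRanges` with the statistic in a metadata column.
#' @param path output path.
#' @param valueCol metadata column to export.
#' @return `path`, invisibly.
#' @export
exportTrackBed <- function(track, path, valueCol = "value") {
  val <- mcols(track)[[valueCol]]
  if (is.null(val)) stop("no metadata column ", sQuote(valueCol))
  keep <- !is.na(val)
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(track))[keep],
                   start = start(track)[keep] - 1L,
                   end = end(track)[keep],
                   value = val[keep])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
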