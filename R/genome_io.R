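#' @include accessors.R
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   reduce mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame SimpleList queryHits subjectHits
NULL

#' Read phased haplotypes from a VCF
#'
#' Reads a VCF with phased diploid genotypes into one [HaplotypeSet-class]
#' per chromosome. Only biallelic SNP records with fully phased (or
#' missing) genotypes are kept; multiallelic, non-SNP and unphased
#' records are skipped with a logged count. The REF allele is taken as
#' ancestral unless the INFO field `AA` is present, in which case sites
#' whose ancestral allele equals ALT are flipped (a logged message states
#' which convention applied). VCF positions (1-based) are converted to
#' the package's 0-based convention.
#'
#' @param path VCF file.
#' @param seqLengths optional named vector of chromosome lengths used when
#'   the VCF header carries none.
#' @param verbose log skipped-record counts and the polarization
#'   convention (default TRUE).
#' @return named list of [HaplotypeSet-class], one per chromosome.
#' @export
readPhasedVcf <- function(path, seqLengths = NULL, verbose = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  # suppressWarnings: simulator VCFs may carry a record at POS 0
  # (0-based engines); it is dropped below with the other skipped records
  vcf <- suppressWarnings(
    VariantAnnotation::readVcf(path, genome = "unknown"))
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field: no phased records")
  rr <- SummarizedExperiment::rowRanges(vcf)
  nrec <- length(rr)
  if (nrec == 0L) {
    samples <- colnames(gt)
    return(list())
  }
  altList <- VariantAnnotation::alt(vcf)
  refs <- as.character(VariantAnnotation::ref(vcf))
  biallelic <- S4Vectors::elementNROWS(altList) == 1L
  alts <- rep(NA_character_, nrec)
  alts[biallelic] <- as.character(unlist(altList[biallelic]))
  snp <- biallelic & nchar(refs) == 1L & !is.na(alts) & nchar(alts) == 1L &
    alts %in% c("A", "C", "G", "T")
  phased <- rowSums(matrix(grepl("/", gt, fixed = TRUE),
                           nrow = nrow(gt))) == 0L
  keep <- snp & phased & start(rr) >= 1L
  if (!any(keep))
    stop("no phased biallelic SNP records in ", path)
  nskip <- sum(!keep)
  if (verbose && nskip > 0)
    message(nskip, " multiallelic/non-SNP/unphased record(s) skipped")

  aa <- NULL
  infoDf <- VariantAnnotation::info(vcf)
  if ("AA" %in% names(infoDf)) {
    aa <- toupper(as.character(infoDf$AA))
    if (verbose) message("polarizing by the AA (ancestral allele) INFO tag")
  } else if (verbose) {
    message("no AA tag present; treating REF as the ancestral allele")
  }

  chroms <- as.character(seqnames(rr))
  pos0 <- start(rr) - 1
  hdrLen <- GenomeInfoDb::seqlengths(rr)
  samples <- colnames(gt)
  nHap <- 2L * length(samples)
  hapIds <- as.vector(rbind(paste0(samples, "_h1"), paste0(samples, "_h2")))

  out <- list()
  for (ch in unique(chroms)) {
    idx <- which(keep & chroms == ch)
    idx <- idx[order(pos0[idx])]
    dup <- duplicated(pos0[idx])
    if (any(dup)) {
      if (verbose)
        message(sum(dup), " duplicate-position record(s) dropped on chrom ", ch)
      idx <- idx[!dup]
    }
    L <- hdrLen[ch]
    if (is.na(L)) L <- if (!is.null(seqLengths) && ch %in% names(seqLengths))
      seqLengths[[ch]] else if (length(idx)) max(pos0[idx]) + 1 else 1
    g <- gt[idx, , drop = FALSE]
    a1 <- substr(g, 1L, 1L)
    a2 <- substr(g, 3L, 3L)
    toInt <- function(x) {
      v <- rep(NA_integer_, length(x))
      v[x == "0"] <- 0L
      v[x == "1"] <- 1L
      v
    }
    # rows: sample1_h1, sample1_h2, sample2_h1, ... ; columns: sites
    m <- matrix(NA_integer_, nrow = nHap, ncol = length(idx))
    m[seq(1L, nHap, by = 2L), ] <- toInt(t(a1))
    m[seq(2L, nHap, by = 2L), ] <- toInt(t(a2))
    if (!is.null(aa)) {
      flip <- which(aa[idx] == alts[idx])
      if (length(flip)) m[, flip] <- 1L - m[, flip]
    }
    out[[ch]] <- HaplotypeSet(m, positions = pos0[idx], chrom = ch,
                              hapIds = hapIds, seqLength = L)
  }
  out
}

#' Write a HaplotypeSet as a phased VCF
#'
#' Inverse of [readPhasedVcf()]: sites become biallelic A/T records
#' (REF = ancestral), haplotype pairs become phased diploid genotypes,
#' missing entries become `.` alleles.
#'
#' @param haps a [HaplotypeSet-class] with an even number of haplotypes.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writePhasedVcf <- function(haps, path) {
  stopifnot(is(haps, "HaplotypeSet"))
  if (nHap(haps) %% 2 != 0)
    stop("need an even number of haplotypes to form diploid genotypes")
  n <- nSite(haps)
  nInd <- nHap(haps) / 2
  samples <- sub("_h1$", "", hapIds(haps)[seq(1, nHap(haps), by = 2)])
  if (anyDuplicated(samples)) samples <- paste0("ind_", seq_len(nInd))
  gr <- GRanges(rep(chromName(haps), n),
                IRanges(start = positions(haps) + 1, width = 1))
  GenomeInfoDb::seqinfo(gr) <- GenomeInfoDb::Seqinfo(
    chromName(haps), seqLength(haps))
  if (n > 0) names(gr) <- paste0("s", seq_len(n))
  a <- alleleMatrix(haps)
  ch <- matrix(as.character(a), nrow = nrow(a))
  ch[is.na(ch)] <- "."
  gtm <- matrix("", nrow = n, ncol = nInd,
                dimnames = list(names(gr), samples))
  rownames(gtm) <- names(gr)
  for (k in seq_len(nInd))
    gtm[, k] <- paste0(ch[2 * k - 1, ], "|", ch[2 * k, ])
  fixed <- DataFrame(
    REF = Biostrings::DNAStringSet(rep("A", n)),
    ALT = do.call(Biostrings::DNAStringSetList, as.list(rep("T", n))),
    QUAL = rep(NA_real_, n), FILTER = rep("PASS", n))
  vcf <- VariantAnnotation::VCF(
    rowRanges = gr, fixed = fixed, geno = SimpleList(GT = gtm),
    colData = DataFrame(Samples = seq_len(nInd), row.names = samples),
    collapsed = TRUE)
  hdr <- VariantAnnotation::VCFHeader(samples = samples)
  VariantAnnotation::geno(hdr) <- DataFrame(
    Number = "1", Type = "String", Description = "Genotype",
    row.names = "GT")
  VariantAnnotation::meta(hdr) <- IRanges::DataFrameList(
    fileformat = DataFrame(Value = "VCFv4.2", row.names = "fileformat"))
  VariantAnnotation::header(vcf) <- hdr
  VariantAnnotation::writeVcf(vcf, path)
  invisible(path)
}

#' Build sliding windows along a chromosome
#'
#' Windows of `size` bp are laid down every `step` bp starting at 0
#' (defaults: 30 kb windows every 25 kb, i.e. adjacent windows share
#' 5 kb). Only complete windows with `start + size <= chromLength` are
#' emitted, so all windows share a common length.
#'
#' @param chromLength chromosome length in bp.
#' @param size window size in bp.
#' @param step distance between window starts in bp (0 < step <= size).
#' @param chrom chromosome label.
#' @return a [GenomicRanges::GRanges] of windows (1-based closed
#'   representation of the 0-based half-open windows \[start, start+size)).
#' @examples
#' makeWindows(100000)  # [0,30000) [25000,55000) [50000,80000)
#' @export
makeWindows <- function(chromLength, size = 30000, step = 25000,
                        chrom = "1") {
  if (chromLength <= 0) stop("chromLength must be > 0")
  if (size <= 0 || step <= 0 || step > size)
    stop("need size > 0 and 0 < step <= size")
  starts0 <- seq(0, chromLength, by = step)
  starts0 <- starts0[starts0 + size <= chromLength]
  if (!length(starts0)) return(GRanges())
  gr <- GRanges(chrom, IRanges(start = starts0 + 1, width = size))
  if (length(gr)) mcols(gr)$wid <- sprintf("%s:%d-%d", chrom, starts0,
                                           starts0 + size)
  gr
}

#' Filter sites by minor allele frequency
#'
#' Retains sites with `min(p, 1-p) > threshold`, where `p` is the derived
#' allele frequency over non-missing entries. Monomorphic sites are
#' always removed (for `threshold = 0` only those are removed). The
#' filter is idempotent.
#'
#' @param haps a [HaplotypeSet-class].
#' @param threshold MAF threshold in \[0, 0.5\].
#' @return the filtered [HaplotypeSet-class].
#' @export
mafFilter <- function(haps, threshold = 0.05) {
  stopifnot(is(haps, "HaplotypeSet"))
  if (threshold < 0 || threshold > 0.5)
    stop("threshold must lie in [0, 0.5]")
  p <- derivedFreq(haps)
  maf <- pmin(p, 1 - p)
  keep <- which(!is.nan(maf) & maf > threshold)
  haps[, keep]
}

#' Intersect windows with gene annotations
#'
#' A gene is listed for a window iff its interval overlaps the window by
#' at least 1 bp under half-open semantics (a gene starting exactly at a
#' window's end is not listed). Equivalent to a bedtools-style intersect.
#'
#' @param windows [GenomicRanges::GRanges] of windows (see [makeWindows()]).
#' @param genes [GenomicRanges::GRanges] with a `name` metadata column, or
#'   a data.frame with columns `chrom`, `start`, `end` (0-based half-open)
#'   and `name`.
#' @return list of character vectors of gene names, one per window.
#' @export
intersectGenes <- function(windows, genes) {
  if (is.data.frame(genes))
    genes <- GRanges(genes$chrom,
                     IRanges(start = genes$start + 1, end = genes$end),
                     name = genes$name)
  hits <- findOverlaps(windows, genes)
  out <- rep(list(character()), length(windows))
  if (length(hits)) {
    sp <- split(mcols(genes)$name[subjectHits(hits)],
                factor(queryHits(hits), levels = seq_along(windows)))
    out <- lapply(sp, function(x) unique(as.character(x)))
  }
  names(out) <- if (!is.null(mcols(windows)$wid)) mcols(windows)$wid else NULL
  out
}

#' Read a BED file of intervals
#'
#' @param path BED file (chrom, start, end and optionally name), 0-based
#'   half-open.
#' @return a [GenomicRanges::GRanges] (with a `name` column if present).
#' @export
readBed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  gr <- GRanges(df[[1]], IRanges(start = df[[2]] + 1, end = df[[3]]))
  if (ncol(df) >= 4) mcols(gr)$name <- df[[4]]
  gr
}

#' Write intervals as BED (0-based half-open)
#'
#' @param gr a [GenomicRanges::GRanges]; a `name` or `wid` metadata column
#'   becomes the 4th BED column, a `score` column the 5th.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeBed <- function(gr, path) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1, end = end(gr))
  mc <- mcols(gr)
  nameCol <- if ("name" %in% names(mc)) mc$name
             else if ("wid" %in% names(mc)) mc$wid
  if (!is.null(nameCol)) {
    df$name <- nameCol
    if ("score" %in% names(mc)) df$score <- mc$score
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write ancestry tract files
#'
#' Tab-separated sidecar format: `chrom start end haplotype ancestry`
#' with a header line; 0-based half-open intervals.
#'
#' @param x an [AncestryTracts-class].
#' @param path file path.
#' @param chrom chromosome label to write.
#' @return `readTracts`: an [AncestryTracts-class]; `writeTracts`: the
#'   path, invisibly.
#' @export
writeTracts <- function(x, path, chrom = "1") {
  stopifnot(is(x, "AncestryTracts"))
  df <- x@tracts
  out <- data.frame(chrom = chrom, start = df$start, end = df$end,
                    haplotype = df$haplotype, ancestry = df$ancestry)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname writeTracts
#' @param hapIds,seqLength optional overrides when reading (defaults:
#'   haplotypes present in the file; max tract end).
#' @export
readTracts <- function(path, hapIds = NULL, seqLength = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(hapIds)) hapIds <- unique(df$haplotype)
  if (is.null(seqLength)) seqLength <- max(df$end)
  AncestryTracts(df[, c("start", "end", "haplotype", "ancestry")],
                 hapIds = hapIds, seqLength = seqLength)
}
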