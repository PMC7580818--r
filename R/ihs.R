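#' @include genome_io.R
#' @useDynLib admixScan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.ehhReason <- c("below-cutoff", "gap", "chrom-end")

#' Extended haplotype homozygosity around a core site
#'
#' EHH at distance d from the core, for haplotypes carrying a given core
#' allele, is the probability that two randomly chosen carriers are
#' identical over the whole interval from the core out to d:
#' `sum_g C(n_g, 2) / C(n_c, 2)` over groups `g` of identical extended
#' haplotypes among the `n_c` carriers. The curve starts at 1 and is
#' computed cumulatively outward on each side until it falls below
#' `minEhh`, a gap larger than `maxGap` separates consecutive sites
#' (the side is then flagged and the core is discarded from iHS), or the
#' chromosome end is reached. Haplotypes with a missing allele in the
#' extension are dropped from the pair count at and beyond that site
#' (the denominator stays fixed at the core, so the curve remains
#' non-increasing).
#'
#' @param haps a [HaplotypeSet-class].
#' @param core site index (1-based column of the allele matrix).
#' @param allele core allele, 0 (ancestral) or 1 (derived).
#' @param maxGap maximum tolerated gap between consecutive sites in bp.
#' @param minEhh stop once EHH drops below this value.
#' @return list with elements `left` and `right`, each a data.frame with
#'   columns `offset` (bp from the core) and `ehh`, carrying attributes
#'   `reason` (`"below-cutoff"`, `"gap"` or `"chrom-end"`) and
#'   `integral` (the trapezoid integral of that side in bp).
#' @seealso [ihh()], [ihsScan()]
#' @export
ehh <- function(haps, core, allele, maxGap = 20000, minEhh = 0.05) {
  stopifnot(is(haps, "HaplotypeSet"), allele %in% c(0, 1))
  if (core < 1 || core > nSite(haps)) stop("core out of range")
  a <- alleleMatrix(haps)[, core]
  if (sum(!is.na(a) & a == allele) < 2)
    stop("EHH undefined: fewer than 2 carriers of allele ", allele,
         " at core ", core)
  one <- function(dir) {
    r <- .ehh_side_cpp(alleleMatrix(haps), positions(haps), as.integer(core),
                       as.integer(allele), as.integer(dir), maxGap, minEhh)
    df <- data.frame(offset = r$offset, ehh = r$ehh)
    attr(df, "reason") <- .ehhReason[r$reason + 1L]
    attr(df, "integral") <- r$integral
    df
  }
  list(left = one(-1L), right = one(+1L))
}

#' Integrated EHH (iHH)
#'
#' Trapezoid integral of the EHH decay curve against physical distance,
#' summed over the two sides of the core. A side truncated at the core
#' (no extension) contributes 0.
#'
#' @param left,right per-side curves as returned by [ehh()] (data.frames
#'   with `offset` and `ehh` columns).
#' @return the integral in bp * EHH units.
#' @examples
#' side <- data.frame(offset = c(0, 1000), ehh = c(1, 0.5))
#' ihh(side, side)  # 2 * 750
#' @export
ihh <- function(left, right) {
  trap <- function(df) {
    if (nrow(df) < 2) return(0)
    sum(diff(df$offset) * (utils::head(df$ehh, -1) + df$ehh[-1]) / 2)
  }
  trap(left) + trap(right)
}

#' Unstandardized iHS at one core site
#'
#' `uiHS = ln(iHH_A / iHH_D)` where the integrals are over the EHH curves
#' of the ancestral and derived core alleles. The site is flagged
#' (uiHS = NA, with a reason) when a gap rule fired on either allele or
#' either integral is 0.
#'
#' @inheritParams ehh
#' @return list with `uihs`, `ihhA`, `ihhD`, `ok` and `reason`.
#' @export
unstandardizedIhs <- function(haps, core, maxGap = 20000, minEhh = 0.05) {
  stopifnot(is(haps, "HaplotypeSet"))
  r <- .ihs_scan_cpp(alleleMatrix(haps), positions(haps),
                     as.integer(core), maxGap, minEhh)
  .finishIhsRecord(r)
}

.finishIhsRecord <- function(r) {
  gap <- r$gapA | r$gapD
  zero <- r$ihhA <= 0 | r$ihhD <= 0
  few <- r$nAnc < 2 | r$nDer < 2
  uihs <- ifelse(gap | zero | few, NA_real_, log(r$ihhA / r$ihhD))
  reason <- rep(NA_character_, length(uihs))
  reason[zero] <- "zero-integral"
  reason[few] <- "too-few-carriers"
  reason[gap] <- "gap"
  if (length(uihs) == 1L)
    list(uihs = uihs, ihhA = r$ihhA, ihhD = r$ihhD, ok = is.na(reason),
         reason = reason)
  else
    data.frame(uihs = uihs, ihhA = r$ihhA, ihhD = r$ihhD,
               ok = is.na(reason), reason = reason,
               stringsAsFactors = FALSE)
}

#' Genome scan of unstandardized iHS
#'
#' Computes per-SNP iHH integrals and unstandardized iHS for every site
#' that passes the MAF filter, has at least 2 carriers of each allele and
#' at least `minHap` non-missing haplotypes. Sites where a gap > `maxGap`
#' fired or an integral is 0 are kept in the table but flagged
#' (`ok = FALSE`) and excluded from standardization.
#'
#' @param haps a [HaplotypeSet-class].
#' @param mafThreshold minor-allele-frequency filter applied to candidate
#'   cores (the full site set still supports the EHH extension).
#' @param maxGap,minEhh see [ehh()].
#' @param minHap minimum number of non-missing haplotypes at the core
#'   (guards heavily masked sites).
#' @return data.frame with one row per scored SNP: `position` (0-based
#'   bp), `freq` (derived allele frequency), `ihhA`, `ihhD`, `uihs`,
#'   `ok`, `reason`.
#' @export
ihsScan <- function(haps, mafThreshold = 0.05, maxGap = 20000,
                    minEhh = 0.05, minHap = 20) {
  stopifnot(is(haps, "HaplotypeSet"))
  a <- alleleMatrix(haps)
  nDer <- colSums(a == 1L, na.rm = TRUE)
  nOk <- colSums(!is.na(a))
  p <- ifelse(nOk > 0, nDer / nOk, NaN)
  maf <- pmin(p, 1 - p)
  cores <- which(!is.nan(maf) & maf > mafThreshold & nOk >= minHap &
                   nDer >= 2 & (nOk - nDer) >= 2)
  if (!length(cores))
    return(data.frame(position = numeric(), freq = numeric(),
                      ihhA = numeric(), ihhD = numeric(),
                      uihs = numeric(), ok = logical(),
                      reason = character(), stringsAsFactors = FALSE))
  r <- .ihs_scan_cpp(a, positions(haps), as.integer(cores), maxGap, minEhh)
  rec <- .finishIhsRecord(r)
  data.frame(position = positions(haps)[cores], freq = p[cores],
             ihhA = rec$ihhA, ihhD = rec$ihhD, uihs = rec$uihs,
             ok = rec$ok, reason = rec$reason, stringsAsFactors = FALSE)
}

#' Standardize iHS within derived-allele-frequency bins
#'
#' Standardizes unstandardized iHS scores to mean 0 and SD 1 within bins
#' of derived allele frequency (`nBins` equal-width bins over (0, 1);
#' bins with fewer than `minPerBin` scored SNPs are merged with their
#' nearest occupied neighbour). Records in a bin with zero SD are
#' flagged and excluded. Two-sided Gaussian p-values are attached.
#'
#' @param records data.frame from [ihsScan()] (or pooled over
#'   chromosomes/replicates): needs columns `freq`, `uihs`, `ok`.
#' @param nBins number of frequency bins.
#' @param minPerBin minimum scored SNPs per bin before merging.
#' @return the input with columns `bin`, `ihs`, `pvalue` and `negLogP`
#'   added; per-bin means/SDs are attached as `attr(x, "binStats")`.
#' @export
standardizeIhs <- function(records, nBins = 50, minPerBin = 10) {
  stopifnot(all(c("freq", "uihs", "ok") %in% names(records)))
  use <- records$ok & is.finite(records$uihs)
  bin <- rep(NA_integer_, nrow(records))
  edges <- seq(0, 1, length.out = nBins + 1)
  bin[use] <- pmin(pmax(findInterval(records$freq[use], edges,
                                     rightmost.closed = TRUE), 1L), nBins)
  if (sum(use) < 2) stop("need at least 2 scored records to standardize")
  # merge under-filled bins into their nearest occupied neighbour
  merged <- sort(unique(bin[use]))
  counts <- table(factor(bin[use], levels = merged))
  group <- stats::setNames(merged, merged)
  while (length(merged) > 1 && any(counts < minPerBin)) {
    i <- which.min(counts)
    j <- if (i == 1) 2 else if (i == length(merged)) i - 1 else
      if (counts[i - 1] <= counts[i + 1]) i - 1 else i + 1
    group[as.character(merged[i])] <- merged[j]
    group[group == merged[i]] <- merged[j]
    counts[j] <- counts[j] + counts[i]
    counts <- counts[-i]
    merged <- merged[-i]
  }
  # resolve chains
  resolve <- function(b) {
    while (group[as.character(b)] != b) b <- group[as.character(b)]
    b
  }
  gbin <- bin
  gbin[use] <- vapply(bin[use], resolve, numeric(1))
  ihs <- rep(NA_real_, nrow(records))
  stats <- list()
  for (b in unique(gbin[use])) {
    idx <- which(use & gbin == b)
    m <- mean(records$uihs[idx])
    # population (1/n) SD, so a two-point bin {a, -a} maps to {+1, -1}
    s <- sqrt(mean((records$uihs[idx] - m)^2))
    stats[[as.character(b)]] <- c(bin = b, n = length(idx), mean = m, sd = s)
    if (!is.finite(s) || s == 0) next  # degenerate bin: flagged, excluded
    ihs[idx] <- (records$uihs[idx] - m) / s
  }
  records$bin <- gbin
  records$ihs <- ihs
  pv <- ihsPvalue(ihs)
  records$pvalue <- pv$pvalue
  records$negLogP <- pv$negLogP
  attr(records, "binStats") <- do.call(rbind, stats)
  records
}

#' Two-sided Gaussian p-value for a standardized iHS
#'
#' `p = 2 * Phi(-|iHS|)`; the -log10 p is computed on the log scale so it
#' stays finite for extreme scores.
#'
#' @param ihs standardized score(s); NA gives NA.
#' @return data.frame with `pvalue` and `negLogP`.
#' @examples
#' ihsPvalue(0)       # p = 1
#' ihsPvalue(3.8906)  # p ~ 1e-4
#' @export
ihsPvalue <- function(ihs) {
  stopifnot(all(is.finite(ihs) | is.na(ihs)))
  lp <- stats::pnorm(-abs(ihs), log.p = TRUE) + log(2)
  data.frame(pvalue = pmin(exp(lp), 1), negLogP = pmax(-lp / log(10), 0))
}

#' Summarize standardized iHS in windows
#'
#' For each window, the mean and maximum of |iHS| over scored SNPs whose
#' position falls inside the (half-open) window, plus the maximum
#' -log10(p). SNPs in the overlap of two windows contribute to both.
#' Windows with no scored SNP are emitted with `nSnps = 0` and NA
#' summaries.
#'
#' @param records standardized records from [standardizeIhs()].
#' @param windows [GenomicRanges::GRanges] from [makeWindows()].
#' @return the windows with metadata columns `nSnps`, `meanAbsIhs`,
#'   `maxAbsIhs`, `maxNegLogP`.
#' @export
windowIhs <- function(records, windows) {
  stopifnot(all(c("position", "ihs") %in% names(records)))
  ok <- is.finite(records$ihs)
  pos <- records$position[ok]
  absIhs <- abs(records$ihs[ok])
  nlp <- records$negLogP[ok]
  n <- length(windows)
  nSnps <- integer(n); meanA <- maxA <- maxP <- rep(NA_real_, n)
  if (length(pos)) {
    snps <- GRanges(as.character(seqnames(windows))[1],
                    IRanges(start = pos + 1, width = 1))
    hits <- findOverlaps(windows, snps)
    if (length(hits)) {
      byWin <- split(subjectHits(hits), queryHits(hits))
      for (w in names(byWin)) {
        i <- as.integer(w); j <- byWin[[w]]
        nSnps[i] <- length(j)
        meanA[i] <- mean(absIhs[j])
        maxA[i] <- max(absIhs[j])
        maxP[i] <- max(nlp[j])
      }
    }
  }
  mcols(windows)$nSnps <- nSnps
  mcols(windows)$meanAbsIhs <- meanA
  mcols(windows)$maxAbsIhs <- maxA
  mcols(windows)$maxNegLogP <- maxP
  windows
}
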