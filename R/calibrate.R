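#' @include simulate.R ihs.R
NULL

#' Empirical null sample of a statistic under neutral simulation
#'
#' Repeatedly simulates neutral replicates of a demographic model and
#' applies `statistic` (a function taking a [HaplotypeSet-class] and
#' returning a numeric vector of per-unit values — per SNP or per
#' window), pooling the values until at least `nUnits` are collected
#' (then trimmed to exactly `nUnits`). Deterministic given the seed.
#'
#' Note: statistics that require pooled post-processing across
#' replicates (such as iHS standardization) should use
#' [ihsNeutralNull()], which standardizes over the pooled records.
#'
#' @param statistic function `HaplotypeSet -> numeric`.
#' @param model a [DemographicModel-class].
#' @param nUnits number of null values to collect.
#' @param seed root seed.
#' @param nHap,L,mu,r simulation parameters per replicate.
#' @param maxReplicates safety cap on the number of replicates.
#' @return numeric vector of length `nUnits`.
#' @export
neutralNull <- function(statistic, model, nUnits, seed = 1, nHap = NULL,
                        L = 1e6, mu = 1.25e-8, r = 1e-8,
                        maxReplicates = 1000) {
  stopifnot(is.function(statistic), nUnits > 0)
  vals <- numeric()
  i <- 0L
  while (length(vals) < nUnits) {
    i <- i + 1L
    if (i > maxReplicates)
      stop("needed more than ", maxReplicates, " replicates to collect ",
           nUnits, " null values")
    sim <- simulateNeutral(model, nHap = nHap, L = L, mu = mu, r = r,
                           seed = childSeed(seed, i), tracts = FALSE)
    vals <- c(vals, as.numeric(statistic(sim$haps)))
  }
  vals[seq_len(nUnits)]
}

#' Neutral null distributions for iHS (per SNP and per window)
#'
#' Simulates `nRep` neutral replicates, pools the unstandardized iHS
#' records across replicates, standardizes once over the pooled set
#' (frequency-bin standardization), and returns both the per-SNP
#' standardized |iHS| pool and the 30 kb-window mean |iHS| pool.
#'
#' @param model a [DemographicModel-class].
#' @param nRep number of replicate chromosomes.
#' @param L replicate length in bp.
#' @param nHap haplotypes sampled from the target population.
#' @param mu,r mutation/recombination rates.
#' @param seed root seed.
#' @param mafThreshold,maxGap,minEhh,minHap see [ihsScan()].
#' @param windowSize,windowStep see [makeWindows()].
#' @param nBins,minPerBin see [standardizeIhs()].
#' @param verbose print progress messages.
#' @return list with `snpAbsIhs` (numeric), `windowMeanAbsIhs` (numeric),
#'   `records` (pooled standardized data.frame with a `replicate`
#'   column) and `nSnps`.
#' @export
ihsNeutralNull <- function(model, nRep = 10, L = 1e7, nHap = NULL,
                           mu = 1.25e-8, r = 1e-8, seed = 1,
                           mafThreshold = 0.05, maxGap = 20000,
                           minEhh = 0.05, minHap = 20,
                           windowSize = 30000, windowStep = 25000,
                           nBins = 50, minPerBin = 10, verbose = FALSE) {
  recs <- vector("list", nRep)
  for (i in seq_len(nRep)) {
    sim <- simulateNeutral(model, nHap = nHap, L = L, mu = mu, r = r,
                           seed = childSeed(seed, i), tracts = FALSE)
    ri <- ihsScan(sim$haps, mafThreshold = mafThreshold, maxGap = maxGap,
                  minEhh = minEhh, minHap = minHap)
    ri$replicate <- i
    recs[[i]] <- ri
    if (verbose)
      message("replicate ", i, "/", nRep, ": ", nrow(ri), " scored SNPs")
  }
  pooled <- do.call(rbind, recs)
  pooled <- standardizeIhs(pooled, nBins = nBins, minPerBin = minPerBin)
  windows <- makeWindows(L, size = windowSize, step = windowStep)
  winMeans <- unlist(lapply(seq_len(nRep), function(i) {
    w <- windowIhs(pooled[pooled$replicate == i, ], windows)
    mcols(w)$meanAbsIhs[mcols(w)$nSnps > 0]
  }))
  list(snpAbsIhs = abs(pooled$ihs[is.finite(pooled$ihs)]),
       windowMeanAbsIhs = as.numeric(winMeans),
       records = pooled,
       nSnps = sum(is.finite(pooled$ihs)))
}

#' Percentile critical value from a null sample
#'
#' Linear-interpolation percentile (the standard order-statistic
#' interpolation of [stats::quantile()] type 7) of an empirical null
#' sample, returned with provenance.
#'
#' @param null numeric null sample.
#' @param q percentile in (0, 100), default 99.99.
#' @param statistic,popClass optional labels stored with the threshold.
#' @return one-row data.frame with columns `statistic`, `popClass`, `q`,
#'   `value`, `n`.
#' @export
percentileThreshold <- function(null, q = 99.99, statistic = NA_character_,
                                popClass = NA_character_) {
  null <- null[is.finite(null)]
  if (!length(null)) stop("empty null sample")
  if (q <= 0 || q >= 100) stop("q must lie in (0, 100)")
  need <- 100 / (100 - q)
  if (length(null) < need)
    warning("null sample of size ", length(null), " is small for the ",
            q, "th percentile (recommended >= ", ceiling(need), ")")
  data.frame(statistic = statistic, popClass = popClass, q = q,
             value = stats::quantile(null, q / 100, type = 7,
                                     names = FALSE),
             n = length(null), stringsAsFactors = FALSE)
}

#' Call candidate windows or SNPs above a critical value
#'
#' Strict `>` comparison against the threshold value; the surviving units
#' are returned sorted by decreasing score.
#'
#' @param scores numeric vector, data.frame, or [GenomicRanges::GRanges]
#'   with the score in `scoreCol`.
#' @param threshold a threshold row from [percentileThreshold()] (or a
#'   bare number).
#' @param scoreCol column holding the score.
#' @param statistic if given and the threshold carries a statistic label,
#'   the two must match.
#' @return the significant subset, sorted by decreasing score.
#' @export
callCandidates <- function(scores, threshold, scoreCol = "score",
                           statistic = NULL) {
  thr <- if (is.data.frame(threshold)) {
    if (!is.null(statistic) && !is.na(threshold$statistic[1]) &&
        !identical(statistic, threshold$statistic[1]))
      stop("threshold is for statistic ", threshold$statistic[1],
           ", not ", statistic)
    threshold$value[1]
  } else as.numeric(threshold)
  if (is(scores, "GRanges")) {
    v <- mcols(scores)[[scoreCol]]
    keep <- which(!is.na(v) & v > thr)
    scores[keep][order(v[keep], decreasing = TRUE)]
  } else if (is.data.frame(scores)) {
    v <- scores[[scoreCol]]
    keep <- which(!is.na(v) & v > thr)
    scores[keep[order(v[keep], decreasing = TRUE)], , drop = FALSE]
  } else {
    v <- as.numeric(scores)
    sort(v[!is.na(v) & v > thr], decreasing = TRUE)
  }
}

#' Relative derived site frequency spectrum
#'
#' Proportion of segregating sites at each derived allele count
#' `1 .. n-1`, computed over sites with complete data (no missing
#' entries).
#'
#' @param haps a [HaplotypeSet-class].
#' @return numeric vector of length `nHap - 1` summing to 1 (all zero if
#'   no segregating complete site exists).
#' @export
relativeSfs <- function(haps) {
  stopifnot(is(haps, "HaplotypeSet"))
  a <- alleleMatrix(haps)
  n <- nrow(a)
  complete <- colSums(is.na(a)) == 0
  cnt <- colSums(a[, complete, drop = FALSE])
  cnt <- cnt[cnt >= 1 & cnt <= n - 1]
  tab <- tabulate(cnt, nbins = n - 1)
  if (sum(tab) == 0) return(rep(0, n - 1))
  tab / sum(tab)
}

#' Compare two relative SFS vectors
#'
#' L1 distance between two relative derived-SFS vectors (e.g. real vs
#' simulated data), with the per-class differences retained so excesses
#' or deficits (such as missing singletons) can be localized.
#'
#' @param a,b [HaplotypeSet-class] objects with equal haplotype counts,
#'   or bare relative-SFS proportion vectors of equal length.
#' @return list with `sfs1`, `sfs2`, `diff` (`sfs1 - sfs2`) and `l1`.
#' @export
compareSfs <- function(a, b) {
  toSfs <- function(x) if (is(x, "HaplotypeSet")) relativeSfs(x) else
    as.numeric(x)
  s1 <- toSfs(a); s2 <- toSfs(b)
  if (length(s1) != length(s2))
    stop("SFS lengths differ (", length(s1), " vs ", length(s2),
         "); projection to a common sample size is not supported")
  list(sfs1 = s1, sfs2 = s2, diff = s1 - s2, l1 = sum(abs(s1 - s2)))
}
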