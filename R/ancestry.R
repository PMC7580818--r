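#' @include genome_io.R
NULL

# block boundaries over the site index range; a short terminal block is
# merged into its predecessor
.makeBlocks <- function(nSite, blockSize = 20) {
  if (nSite < 1) stop("no sites to block")
  starts <- seq(1L, nSite, by = blockSize)
  ends <- pmin(starts + blockSize - 1L, nSite)
  if (length(starts) > 1 && (ends[length(ends)] - starts[length(starts)] +
                             1L) < blockSize) {
    ends[length(ends) - 1L] <- nSite
    starts <- starts[-length(starts)]
    ends <- ends[-length(ends)]
  }
  list(start = as.integer(starts), end = as.integer(ends))
}

#' Assign local ancestry on SNP blocks by PCA projection
#'
#' Simplified PCAdmix-style deconvolution: the site range is cut into
#' consecutive blocks of `blockSize` SNPs; within each block the
#' reference panels define a discriminant axis (the centroid difference,
#' standardized by the pooled per-site variance — the principal axis of
#' between-panel variation, which at 20-SNP scale separates ancestries
#' far more reliably than the leading PC of the pooled panels, dominated
#' by within-panel linkage structure) and each query haplotype is
#' classified to the nearer reference centroid in the projected space.
#' Confidence is the relative projection margin
#' `|d_far - d_near| / (d_near + d_far)`: 0 at the midpoint (or when the
#' panels do not separate), approaching 1 on or beyond a centroid.
#'
#' Because ancestry tracts from a single admixture pulse ~100
#' generations ago extend over hundreds of kb (dozens of blocks) while a
#' 20-SNP block alone carries limited information against small
#' reference panels, labels are smoothed by summing the signed,
#' separation-normalized block margins (clipped to +/-3) over `smoothK`
#' adjacent blocks and taking the sign — a soft majority vote weighted
#' by how confidently each block votes. `smoothK = 1` disables
#' smoothing. Reference panels should be given on common variants
#' (apply [mafFilter()] jointly to query and panels first); rare
#' variants carry almost no ancestry information and dilute the blocks.
#'
#' @param query [HaplotypeSet-class] of haplotypes to deconvolute.
#' @param refA,refB reference panels ([HaplotypeSet-class]) sharing the
#'   query's site set, each with >= 10 haplotypes.
#' @param labels length-2 character: labels for `refA` and `refB`
#'   carriers (default `c("AFR", "WEA")`).
#' @param blockSize SNPs per block (terminal remainder merged into the
#'   last full block).
#' @param smoothK odd number of adjacent blocks over which the signed
#'   block margins are summed (1 = no smoothing). The default spans
#'   ~1/3 of a typical tract from a 104-generation-old pulse.
#' @return an [AncestryAssignment-class].
#' @export
assignLocalAncestry <- function(query, refA, refB,
                                labels = c("AFR", "WEA"),
                                blockSize = 20, smoothK = 21) {
  stopifnot(is(query, "HaplotypeSet"), is(refA, "HaplotypeSet"),
            is(refB, "HaplotypeSet"), length(labels) == 2)
  if (!identical(positions(query), positions(refA)) ||
      !identical(positions(query), positions(refB)))
    stop("query and reference panels must share the same site set")
  if (nHap(refA) < 10 || nHap(refB) < 10)
    stop("each reference panel needs at least 10 haplotypes")
  if (smoothK %% 2 != 1) stop("smoothK must be odd")
  blocks <- .makeBlocks(nSite(query), blockSize)
  nb <- length(blocks$start)
  nq <- nHap(query)
  lab <- matrix(NA_character_, nq, nb)
  conf <- matrix(NA_real_, nq, nb)
  qa <- alleleMatrix(query)
  ra <- alleleMatrix(refA)
  rb <- alleleMatrix(refB)
  margin <- matrix(0, nq, nb)  # signed: positive leans towards labels[2]
  for (k in seq_len(nb)) {
    j <- blocks$start[k]:blocks$end[k]
    mA <- colMeans(ra[, j, drop = FALSE], na.rm = TRUE)
    mB <- colMeans(rb[, j, drop = FALSE], na.rm = TRUE)
    mu <- (mA + mB) / 2
    v <- mu * (1 - mu) + 0.01   # regularized pooled variance
    ax <- (mB - mA) / v
    proj <- function(m) {
      X <- sweep(m[, j, drop = FALSE], 2, mu)
      X[is.na(X)] <- 0
      drop(X %*% ax)
    }
    cA <- mean(proj(ra)); cB <- mean(proj(rb))
    pq <- proj(qa)
    dA <- abs(pq - cA); dB <- abs(pq - cB)
    lab[, k] <- ifelse(dA <= dB, labels[1], labels[2])
    conf[, k] <- ifelse(dA + dB > 0, abs(dA - dB) / (dA + dB), 0)
    sep <- cB - cA
    margin[, k] <- if (abs(sep) > 1e-12)
      pmin(pmax((pq - (cA + cB) / 2) / abs(sep) * sign(sep), -3), 3)
    else 0
  }
  if (smoothK > 1 && nb > 1) {
    hw <- (smoothK - 1) / 2
    for (k in seq_len(nb)) {
      win <- max(1, k - hw):min(nb, k + hw)
      s <- rowSums(margin[, win, drop = FALSE])
      lab[, k] <- ifelse(s > 0, labels[2],
                         ifelse(s < 0, labels[1], lab[, k]))
    }
  }
  pos <- positions(query)
  new("AncestryAssignment", labels = lab, confidence = conf,
      blockStart = blocks$start, blockEnd = blocks$end,
      blockBp = cbind(pos[blocks$start], pos[blocks$end]),
      hapIds = hapIds(query))
}

#' Block ancestry labels from true simulated tracts
#'
#' Converts ground-truth [AncestryTracts-class] into a block-level
#' [AncestryAssignment-class] (each block labelled by the ancestry
#' covering the majority of its bp span on that haplotype, confidence =
#' covered fraction). Used to evaluate [assignLocalAncestry()] and to
#' compute truth-based ancestry proportions.
#'
#' @param tractSet an [AncestryTracts-class].
#' @param haps the corresponding [HaplotypeSet-class].
#' @param blockSize SNPs per block.
#' @return an [AncestryAssignment-class].
#' @export
assignmentFromTracts <- function(tractSet, haps, blockSize = 20) {
  stopifnot(is(tractSet, "AncestryTracts"), is(haps, "HaplotypeSet"))
  blocks <- .makeBlocks(nSite(haps), blockSize)
  nb <- length(blocks$start)
  pos <- positions(haps)
  ids <- hapIds(haps)
  df <- tracts(tractSet)
  lab <- matrix(NA_character_, nHap(haps), nb)
  conf <- matrix(NA_real_, nHap(haps), nb)
  for (h in seq_along(ids)) {
    d <- df[df$haplotype == ids[h], , drop = FALSE]
    if (!nrow(d)) stop("no tracts for haplotype ", ids[h])
    d <- d[order(d$start), , drop = FALSE]
    for (k in seq_len(nb)) {
      b0 <- pos[blocks$start[k]]
      b1 <- pos[blocks$end[k]] + 1
      ov <- pmin(d$end, b1) - pmax(d$start, b0)
      ov[ov < 0] <- 0
      byAnc <- tapply(ov, d$ancestry, sum)
      lab[h, k] <- names(byAnc)[which.max(byAnc)]
      conf[h, k] <- max(byAnc) / (b1 - b0)
    }
  }
  new("AncestryAssignment", labels = lab, confidence = conf,
      blockStart = blocks$start, blockEnd = blocks$end,
      blockBp = cbind(pos[blocks$start], pos[blocks$end]),
      hapIds = ids)
}

#' Per-block accuracy of an assignment against the truth
#'
#' @param assignment an [AncestryAssignment-class] (estimated).
#' @param truth an [AncestryAssignment-class] on the same blocks
#'   (e.g. from [assignmentFromTracts()]).
#' @return fraction of (haplotype, block) cells with matching labels.
#' @export
assignmentAccuracy <- function(assignment, truth) {
  stopifnot(identical(assignment@blockStart, truth@blockStart))
  mean(assignment@labels == truth@labels)
}

#' Mask one ancestry component
#'
#' Sets to missing every allele falling in a block assigned to the
#' target ancestry, and records the per-SNP masked fraction (the share
#' of haplotypes whose containing block carries the target label).
#'
#' @param haps a [HaplotypeSet-class].
#' @param assignment an [AncestryAssignment-class] covering `haps`.
#' @param target ancestry label to mask (default `"WEA"`).
#' @return a [MaskedHaplotypeSet-class].
#' @export
maskAncestry <- function(haps, assignment, target = "WEA") {
  stopifnot(is(haps, "HaplotypeSet"), is(assignment, "AncestryAssignment"))
  if (nHap(haps) != nrow(assignment@labels) ||
      nSite(haps) != assignment@blockEnd[length(assignment@blockEnd)])
    stop("assignment does not cover the haplotype set")
  a <- alleleMatrix(haps)
  frac <- numeric(nSite(haps))
  for (k in seq_along(assignment@blockStart)) {
    j <- assignment@blockStart[k]:assignment@blockEnd[k]
    hit <- assignment@labels[, k] == target
    if (any(hit)) a[hit, j] <- NA_integer_
    frac[j] <- mean(hit)
  }
  new("MaskedHaplotypeSet", chrom = chromName(haps),
      positions = positions(haps), alleles = a, hapIds = hapIds(haps),
      seqLength = seqLength(haps), maskedFraction = frac,
      maskedLabel = target)
}

#' Masked-ancestry proportion of a region
#'
#' Mean over the SNPs of a region of the per-SNP masked fraction: the
#' genome-wide value estimates the admixture proportion of the masked
#' component; per 30 kb window it gives the local ancestry track.
#'
#' @param masked a [MaskedHaplotypeSet-class].
#' @param region optional [GenomicRanges::GRanges] (one range) or
#'   half-open `c(start0, end0)`; default whole genome.
#' @return a fraction in \[0, 1\], or NA (with a warning) for a region
#'   containing no SNP.
#' @export
ancestryProportion <- function(masked, region = NULL) {
  stopifnot(is(masked, "MaskedHaplotypeSet"))
  f <- maskedFraction(masked)
  if (is.null(region)) sel <- rep(TRUE, length(f))
  else {
    if (is(region, "GRanges")) {
      s0 <- start(region)[1] - 1; e0 <- end(region)[1]
    } else { s0 <- region[1]; e0 <- region[2] }
    sel <- positions(masked) >= s0 & positions(masked) < e0
  }
  if (!any(sel)) {
    warning("region contains no SNP; ancestry proportion undefined")
    return(NA_real_)
  }
  mean(f[sel])
}

#' Per-window masked-ancestry track
#'
#' @param masked a [MaskedHaplotypeSet-class].
#' @param windows [GenomicRanges::GRanges] from [makeWindows()].
#' @return the windows with metadata columns `fraction` (per-window
#'   masked-ancestry proportion; NA where no SNP falls in the window)
#'   and `nSnps`.
#' @export
ancestryTrack <- function(masked, windows) {
  stopifnot(is(masked, "MaskedHaplotypeSet"))
  f <- maskedFraction(masked)
  pos <- positions(masked)
  frac <- rep(NA_real_, length(windows))
  n <- integer(length(windows))
  for (i in seq_along(windows)) {
    sel <- pos >= (start(windows)[i] - 1) & pos < end(windows)[i]
    n[i] <- sum(sel)
    if (n[i] > 0) frac[i] <- mean(f[sel])
  }
  mcols(windows)$fraction <- frac
  mcols(windows)$nSnps <- n
  windows
}

#' Merge selected windows into maximal intervals
#'
#' Overlapping or book-ended candidate windows are merged (interval
#' union), e.g. \[0,30000) and \[25000,55000) become \[0,55000).
#'
#' @param windows [GenomicRanges::GRanges] of candidate windows.
#' @return merged [GenomicRanges::GRanges].
#' @export
mergeSelected <- function(windows) {
  reduce(windows)
}

#' EnrichmentResult: resampling test for ancestry enrichment
#'
#' @slot observed observed mean masked-ancestry fraction of the selected
#'   windows.
#' @slot nSelected number of selected windows.
#' @slot nResamples number of resamples.
#' @slot nullMean,nullSd moments of the resampled null distribution.
#' @slot p one-sided empirical p-value with the (+1)/(n+1) correction.
#' @export
setClass("EnrichmentResult", representation(
  observed = "numeric", nSelected = "integer", nResamples = "integer",
  nullMean = "numeric", nullSd = "numeric", p = "numeric"
))

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf(paste0(
    "EnrichmentResult: observed mean fraction %.4f over %d windows\n",
    "  null %.4f +/- %.4f (%d resamples), one-sided p = %.3g\n"),
    object@observed, object@nSelected, object@nullMean, object@nullSd,
    object@nResamples, object@p))
})

#' Resampling test for ancestry enrichment in selected windows
#'
#' Draws `|selected|` windows from the genome-wide window set `n` times
#' (without replacement by default), computes the mean masked-ancestry
#' fraction of each draw, and compares the observed mean of the selected
#' windows against this null distribution of means. The one-sided
#' empirical p-value uses the (#null >= observed + 1)/(n + 1)
#' correction, so `1/(n+1) <= p <= 1`.
#'
#' @param fractions per-window masked-ancestry fractions (genome-wide);
#'   NA windows are dropped.
#' @param selected indices (into `fractions`) of the selected windows.
#' @param n number of resamples (default 1e5).
#' @param seed integer seed; the test is deterministic given it.
#' @param replace draw with replacement instead (default FALSE).
#' @return an [EnrichmentResult-class].
#' @export
enrichmentResampling <- function(fractions, selected, n = 100000,
                                 seed = 1, replace = FALSE) {
  if (!length(selected)) stop("empty selected set")
  obs <- mean(fractions[selected])
  pool <- fractions[!is.na(fractions)]
  k <- length(selected)
  if (k > length(pool)) stop("more selected windows than available windows")
  rng <- .seededRng(seed)
  nullMeans <- vapply(seq_len(n), function(i)
    mean(pool[sample.int(length(pool), k, replace = replace)]),
    numeric(1))
  .restoreRng(rng)
  p <- (sum(nullMeans >= obs) + 1) / (n + 1)
  new("EnrichmentResult", observed = obs, nSelected = as.integer(k),
      nResamples = as.integer(n), nullMean = mean(nullMeans),
      nullSd = stats::sd(nullMeans), p = p)
}

.seededRng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

.restoreRng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Regions of unbalanced local ancestry
#'
#' Under neutrality the masked-ancestry fraction is expected to be evenly
#' distributed along the genome; this reports maximal runs of
#' consecutive windows whose fraction falls outside a central `bandQ`%
#' null band around the genome-wide level (two-sided), on the same side
#' throughout, provided the run spans at least `minSpan` bp. The band is
#' `median +/- z * MAD` of the per-window fractions (the Gaussian
#' quantile `z` holding `bandQ`% of mass): a robust version of the
#' per-window null so that a genuinely unbalanced region cannot widen
#' the band that is supposed to flag it.
#'
#' @param track windows with a `fraction` metadata column, from
#'   [ancestryTrack()].
#' @param minSpan minimum bp span of a reported region (default 0.5 Mb).
#' @param bandQ central band mass in percent (default 99.9).
#' @return [GenomicRanges::GRanges] of regions with metadata columns
#'   `meanFraction`, `genomeMean`, `direction` (`"high"`/`"low"`),
#'   `nWindows` and `span`.
#' @export
unbalancedRegions <- function(track, minSpan = 500000, bandQ = 99.9) {
  f <- mcols(track)$fraction
  if (is.null(f)) stop("track needs a 'fraction' metadata column")
  usable <- !is.na(f)
  if (sum(width(reduce(track[usable]))) < minSpan)
    stop("track covers less than minSpan")
  alpha <- (1 - bandQ / 100) / 2
  z <- stats::qnorm(1 - alpha)
  ctr <- stats::median(f[usable])
  spread <- stats::mad(f[usable])
  lo <- ctr - z * spread
  hi <- ctr + z * spread
  gMean <- mean(f[usable])
  state <- ifelse(!usable, 0L, ifelse(f > hi, 1L, ifelse(f < lo, -1L, 0L)))
  out <- GRanges()
  r <- rle(state)
  endIdx <- cumsum(r$lengths)
  startIdx <- endIdx - r$lengths + 1
  for (i in seq_along(r$values)) {
    if (r$values[i] == 0L) next
    idx <- startIdx[i]:endIdx[i]
    s0 <- min(start(track)[idx]) - 1
    e0 <- max(end(track)[idx])
    if (e0 - s0 < minSpan) next
    g <- GRanges(as.character(seqnames(track))[1],
                 IRanges(start = s0 + 1, end = e0))
    mcols(g)$meanFraction <- mean(f[idx])
    mcols(g)$genomeMean <- gMean
    mcols(g)$direction <- if (r$values[i] > 0) "high" else "low"
    mcols(g)$nWindows <- length(idx)
    mcols(g)$span <- e0 - s0
    out <- c(out, g)
  }
  out
}
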