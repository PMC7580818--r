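#' @import methods
#' @importFrom GenomicRanges GRanges
NULL

MISSING_ALLELE <- NA_integer_

#' HaplotypeSet: phased haplotypes over biallelic sites
#'
#' Container for a phased 0/1 haplotype-by-site allele matrix on one
#' chromosome. Rows are haplotypes (two per diploid individual), columns
#' are segregating sites in strictly increasing base-pair order. Allele 0
#' is ancestral, 1 is derived; `NA` marks missing (e.g. ancestry-masked)
#' entries. Positions are 0-based.
#'
#' @slot chrom single chromosome label.
#' @slot positions numeric vector of strictly increasing 0-based bp positions.
#' @slot alleles integer matrix, `nHap x nSite`, entries in \{0, 1, NA\}.
#' @slot hapIds character vector of haplotype identifiers (rows).
#' @slot seqLength total sequence length in bp (>= max position + 1).
#'
#' @examples
#' hs <- HaplotypeSet(matrix(c(0L,1L,1L,0L), 2), positions = c(100, 200))
#' nHap(hs); nSite(hs)
#' @export
setClass("HaplotypeSet", representation(
  chrom = "character",
  positions = "numeric",
  alleles = "matrix",
  hapIds = "character",
  seqLength = "numeric"
))

setValidity("HaplotypeSet", function(object) {
  msg <- character()
  if (length(object@chrom) != 1L)
    msg <- c(msg, "chrom must be a single label")
  p <- object@positions
  if (ncol(object@alleles) != length(p))
    msg <- c(msg, "ncol(alleles) must equal length(positions)")
  if (length(p) > 1L && any(diff(p) <= 0))
    msg <- c(msg, "positions must be strictly increasing")
  if (length(p) && any(p < 0))
    msg <- c(msg, "positions must be non-negative")
  if (nrow(object@alleles) != length(object@hapIds))
    msg <- c(msg, "nrow(alleles) must equal length(hapIds)")
  a <- object@alleles
  if (length(a) && !all(a[!is.na(a)] %in% c(0L, 1L)))
    msg <- c(msg, "alleles must be 0, 1 or NA")
  if (object@seqLength <= 0 || (length(p) && object@seqLength <= max(p)))
    msg <- c(msg, "seqLength must exceed the largest position")
  if (length(msg)) msg else TRUE
})

#' MaskedHaplotypeSet: haplotypes with one ancestry component masked
#'
#' A [HaplotypeSet] whose entries falling in blocks assigned to the masked
#' ancestry have been set to `NA`, plus the per-site masked fraction.
#'
#' @slot maskedFraction numeric vector, per site, fraction of haplotypes
#'   whose containing ancestry block carries the masked label.
#' @slot maskedLabel the ancestry label that was masked (e.g. `"WEA"`).
#' @export
setClass("MaskedHaplotypeSet", contains = "HaplotypeSet", representation(
  maskedFraction = "numeric",
  maskedLabel = "character"
))

setValidity("MaskedHaplotypeSet", function(object) {
  msg <- character()
  if (length(object@maskedFraction) != length(object@positions))
    msg <- c(msg, "maskedFraction must have one entry per site")
  f <- object@maskedFraction
  if (length(f) && (any(f < 0) || any(f > 1)))
    msg <- c(msg, "maskedFraction must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' AncestryTracts: true local-ancestry intervals per haplotype
#'
#' Ground-truth local ancestry from an admixture simulation: for every
#' haplotype, an ordered set of half-open bp intervals labelled by source
#' ancestry. Per haplotype the tracts tile `[0, seqLength)` exactly.
#'
#' @slot tracts data.frame with columns `start`, `end` (0-based half-open
#'   bp), `haplotype` and `ancestry`.
#' @slot hapIds haplotype identifiers covered by the tract set.
#' @slot seqLength sequence length in bp.
#' @export
setClass("AncestryTracts", representation(
  tracts = "data.frame",
  hapIds = "character",
  seqLength = "numeric"
))

setValidity("AncestryTracts", function(object) {
  df <- object@tracts
  need <- c("start", "end", "haplotype", "ancestry")
  if (!all(need %in% names(df)))
    return("tracts must have columns start, end, haplotype, ancestry")
  msg <- character()
  if (!all(df$haplotype %in% object@hapIds))
    msg <- c(msg, "tract haplotypes must be among hapIds")
  for (h in object@hapIds) {
    d <- df[df$haplotype == h, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (!nrow(d)) { msg <- c(msg, paste0("no tracts for ", h)); break }
    ok <- d$start[1] == 0 &&
      d$end[nrow(d)] == object@seqLength &&
      all(d$end > d$start) &&
      (nrow(d) == 1 || all(d$start[-1] == d$end[-nrow(d)]))
    if (!ok) { msg <- c(msg, paste0("tracts for ", h, " do not tile [0, L)")); break }
  }
  if (length(msg)) msg else TRUE
})

#' DemographicModel: populations, events and an optional admixture pulse
#'
#' Declarative description of a multi-population demography, mirrored into
#' the msprime backend: populations with sizes and growth rates,
#' population splits, size changes, symmetric migration, and
#' single-generation admixture pulses. Times are generations before
#' present; sizes are diploid effective sizes.
#'
#' @slot populations data.frame with columns `name`, `size`, `growth`.
#' @slot events data.frame of demographic events (see [buildDemography]).
#' @slot migrations data.frame with columns `a`, `b`, `rate`.
#' @slot pulses data.frame with columns `time`, `source`, `dest`, `fraction`
#'   (forward-time: `dest` receives `fraction` of its ancestry from `source`).
#' @slot ancestryLabels named character vector mapping population names to
#'   ancestry labels (e.g. `c(EUR = "WEA")`) for tract recording.
#' @slot samplePops default populations to sample, named integer vector of
#'   diploid counts.
#' @slot name preset name, for provenance.
#' @export
setClass("DemographicModel", representation(
  populations = "data.frame",
  events = "data.frame",
  migrations = "data.frame",
  pulses = "data.frame",
  ancestryLabels = "character",
  samplePops = "integer",
  name = "character"
))

setValidity("DemographicModel", function(object) {
  msg <- character()
  pop <- object@populations
  if (!all(c("name", "size", "growth") %in% names(pop)))
    return("populations needs columns name, size, growth")
  if (any(pop$size <= 0)) msg <- c(msg, "population sizes must be > 0")
  if (any(!is.finite(pop$growth))) msg <- c(msg, "growth rates must be finite")
  pu <- object@pulses
  if (nrow(pu)) {
    if (any(pu$fraction < 0 | pu$fraction > 1))
      msg <- c(msg, "pulse fractions must lie in [0,1]")
    if (any(pu$time <= 0)) msg <- c(msg, "pulse times must be > 0")
    if (!all(c(pu$source, pu$dest) %in% pop$name))
      msg <- c(msg, "pulse populations must be defined")
  }
  ev <- object@events
  if (nrow(ev) && any(ev$time <= 0)) msg <- c(msg, "event times must be > 0")
  if (length(msg)) msg else TRUE
})

#' SweepParams: a hard selective sweep
#'
#' Parameters of a hard sweep at a single site: `s` is the per-copy
#' (additive) selective advantage of the derived allele per generation,
#' `tau` the number of generations the allele has been under selection,
#' `position` the selected site in bp, and `condition` how the simulation
#' is conditioned: `"frequency"` (present-day frequency set by the
#' deterministic logistic trajectory after `tau` generations) or
#' `"fixation"` (sweep completed; any surplus of `tau` over the
#' deterministic fixation time becomes post-fixation neutral drift).
#'
#' @slot s selection coefficient (>= 0).
#' @slot tau generations under selection (>= 0).
#' @slot position bp position of the selected site.
#' @slot dominance dominance coefficient (0.5 = additive; informational).
#' @slot condition `"frequency"` or `"fixation"`.
#' @export
setClass("SweepParams", representation(
  s = "numeric", tau = "numeric", position = "numeric",
  dominance = "numeric", condition = "character"
))

setValidity("SweepParams", function(object) {
  msg <- character()
  if (object@s < 0) msg <- c(msg, "s must be >= 0")
  if (object@tau < 0) msg <- c(msg, "tau must be >= 0")
  if (object@position < 0) msg <- c(msg, "position must be >= 0")
  if (!object@condition %in% c("frequency", "fixation"))
    msg <- c(msg, "condition must be 'frequency' or 'fixation'")
  if (length(msg)) msg else TRUE
})

#' SfselectModel: linear support-vector classifier over windowed SFS features
#'
#' A soft-margin linear SVM trained to separate neutral from swept
#' windows, represented by its weight vector over derived-allele-frequency
#' bins and bias. Scores are `w . x + b`; they are comparable only within
#' one trained model.
#'
#' @slot w numeric weight vector, one entry per frequency bin.
#' @slot b numeric bias.
#' @slot cost soft-margin regularization strength used in training.
#' @slot bins number of equal-width frequency bins over (0, 1).
#' @slot metadata list with the training grid (`s`, `tau` combinations),
#'   replicate counts and seed.
#' @export
setClass("SfselectModel", representation(
  w = "numeric", b = "numeric", cost = "numeric", bins = "integer",
  metadata = "list"
))

setValidity("SfselectModel", function(object) {
  msg <- character()
  if (length(object@w) != object@bins)
    msg <- c(msg, "length(w) must equal bins")
  if (!all(is.finite(object@w)) || !is.finite(object@b))
    msg <- c(msg, "w and b must be finite")
  if (length(msg)) msg else TRUE
})

#' AncestryAssignment: per-haplotype, per-block local ancestry labels
#'
#' Result of block-wise local ancestry assignment: the genome is cut into
#' consecutive blocks of (by default) 20 SNPs; every haplotype gets one
#' label per block plus a confidence in [0, 1] (normalized projection
#' margin). Blocks partition the site index range; a short terminal block
#' is merged into its predecessor.
#'
#' @slot labels character matrix, `nHap x nBlock`, entries are ancestry labels.
#' @slot confidence numeric matrix, same shape, in [0, 1].
#' @slot blockStart integer vector of first site indices (1-based) per block.
#' @slot blockEnd integer vector of last site indices per block.
#' @slot blockBp numeric 2-column matrix of bp ranges per block.
#' @slot hapIds haplotype identifiers (rows).
#' @export
setClass("AncestryAssignment", representation(
  labels = "matrix", confidence = "matrix",
  blockStart = "integer", blockEnd = "integer", blockBp = "matrix",
  hapIds = "character"
))

setValidity("AncestryAssignment", function(object) {
  msg <- character()
  nb <- length(object@blockStart)
  if (ncol(object@labels) != nb || ncol(object@confidence) != nb)
    msg <- c(msg, "label/confidence columns must match block count")
  if (nrow(object@labels) != length(object@hapIds))
    msg <- c(msg, "label rows must match hapIds")
  if (nb) {
    if (object@blockStart[1] != 1L)
      msg <- c(msg, "blocks must start at site 1")
    if (any(object@blockEnd < object@blockStart))
      msg <- c(msg, "blocks must be non-empty")
    if (nb > 1 && any(object@blockStart[-1] != object@blockEnd[-nb] + 1L))
      msg <- c(msg, "blocks must partition the site range")
  }
  cf <- object@confidence
  if (length(cf) && (any(cf < 0, na.rm = TRUE) || any(cf > 1, na.rm = TRUE)))
    msg <- c(msg, "confidence must lie in [0,1]")
  if (length(msg)) msg else TRUE
})
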