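#' @include AllClasses.R
NULL

#' Construct a HaplotypeSet
#'
#' @param alleles integer matrix, haplotypes in rows, sites in columns,
#'   entries 0 (ancestral), 1 (derived) or NA (missing).
#' @param positions 0-based bp positions, strictly increasing.
#' @param chrom chromosome label.
#' @param hapIds haplotype identifiers; defaults to `hap_1 ...`.
#' @param seqLength sequence length in bp; defaults to the last position + 1.
#' @return a [HaplotypeSet-class] object.
#' @export
HaplotypeSet <- function(alleles, positions, chrom = "1", hapIds = NULL,
                         seqLength = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (is.null(hapIds)) hapIds <- paste0("hap_", seq_len(nrow(alleles)))
  if (is.null(seqLength))
    seqLength <- if (length(positions)) max(positions) + 1 else 1
  new("HaplotypeSet", chrom = chrom, positions = as.numeric(positions),
      alleles = alleles, hapIds = hapIds, seqLength = as.numeric(seqLength))
}

#' @rdname HaplotypeSet
#' @param object,x a HaplotypeSet.
#' @export
setGeneric("nHap", function(x) standardGeneric("nHap"))
#' @rdname HaplotypeSet
#' @export
setGeneric("nSite", function(x) standardGeneric("nSite"))
#' @rdname HaplotypeSet
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))
#' @rdname HaplotypeSet
#' @export
setGeneric("alleleMatrix", function(x) standardGeneric("alleleMatrix"))
#' @rdname HaplotypeSet
#' @export
setGeneric("hapIds", function(x) standardGeneric("hapIds"))
#' @rdname HaplotypeSet
#' @export
setGeneric("chromName", function(x) standardGeneric("chromName"))
#' @rdname HaplotypeSet
#' @export
setGeneric("seqLength", function(x) standardGeneric("seqLength"))
#' Derived allele frequency per site
#'
#' Frequencies are computed over non-missing entries; sites with no
#' non-missing entry give NaN.
#' @param x a HaplotypeSet.
#' @return numeric vector of derived allele frequencies.
#' @export
setGeneric("derivedFreq", function(x) standardGeneric("derivedFreq"))

#' @rdname HaplotypeSet
setMethod("nHap", "HaplotypeSet", function(x) nrow(x@alleles))
#' @rdname HaplotypeSet
setMethod("nSite", "HaplotypeSet", function(x) ncol(x@alleles))
#' @rdname HaplotypeSet
setMethod("positions", "HaplotypeSet", function(x) x@positions)
#' @rdname HaplotypeSet
setMethod("alleleMatrix", "HaplotypeSet", function(x) x@alleles)
#' @rdname HaplotypeSet
setMethod("hapIds", "HaplotypeSet", function(x) x@hapIds)
#' @rdname HaplotypeSet
setMethod("chromName", "HaplotypeSet", function(x) x@chrom)
#' @rdname HaplotypeSet
setMethod("seqLength", "HaplotypeSet", function(x) x@seqLength)
#' @rdname derivedFreq
setMethod("derivedFreq", "HaplotypeSet", function(x) {
  a <- x@alleles
  colMeans(a, na.rm = TRUE)
})

#' Subset a HaplotypeSet by haplotype (i) and/or site (j) index
#' @param x a HaplotypeSet.
#' @param i haplotype indices.
#' @param j site indices.
#' @param ... ignored.
#' @param drop ignored (always FALSE).
#' @export
setMethod("[", "HaplotypeSet", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nHap(x))
  if (missing(j)) j <- seq_len(nSite(x))
  initialize(x, alleles = x@alleles[i, j, drop = FALSE],
             positions = x@positions[j], hapIds = x@hapIds[i])
})

setMethod("show", "HaplotypeSet", function(object) {
  cat(class(object), "with", nHap(object), "haplotypes x",
      nSite(object), "sites on chrom", object@chrom,
      sprintf("[0, %g)\n", object@seqLength))
  if (is(object, "MaskedHaplotypeSet"))
    cat("  masked label:", object@maskedLabel,
        sprintf("(mean masked fraction %.3f)\n",
                mean(object@maskedFraction)))
})

#' @rdname MaskedHaplotypeSet-class
#' @param x a MaskedHaplotypeSet.
#' @export
setGeneric("maskedFraction", function(x) standardGeneric("maskedFraction"))
#' @rdname MaskedHaplotypeSet-class
setMethod("maskedFraction", "MaskedHaplotypeSet", function(x) x@maskedFraction)

#' Construct an AncestryTracts object
#' @param tracts data.frame with columns start, end, haplotype, ancestry
#'   (0-based half-open bp intervals).
#' @param hapIds haplotype identifiers.
#' @param seqLength sequence length in bp.
#' @export
AncestryTracts <- function(tracts, hapIds, seqLength) {
  new("AncestryTracts", tracts = as.data.frame(tracts),
      hapIds = as.character(hapIds), seqLength = as.numeric(seqLength))
}

#' @rdname AncestryTracts
#' @param x an AncestryTracts object.
#' @export
setGeneric("tracts", function(x) standardGeneric("tracts"))
#' @rdname AncestryTracts
setMethod("tracts", "AncestryTracts", function(x) x@tracts)
#' @rdname AncestryTracts
setMethod("hapIds", "AncestryTracts", function(x) x@hapIds)
#' @rdname AncestryTracts
setMethod("seqLength", "AncestryTracts", function(x) x@seqLength)

setMethod("show", "AncestryTracts", function(object) {
  cat("AncestryTracts:", length(object@hapIds), "haplotypes,",
      nrow(object@tracts), "tracts, labels:",
      paste(sort(unique(object@tracts$ancestry)), collapse = ", "), "\n")
})

#' Fraction of sequence covered by an ancestry label
#'
#' Mean over haplotypes of the bp fraction of tracts carrying `label`.
#' @param x an AncestryTracts object.
#' @param label ancestry label, default `"WEA"`.
#' @return a single fraction in [0, 1].
#' @export
tractCoverage <- function(x, label = "WEA") {
  stopifnot(is(x, "AncestryTracts"))
  df <- x@tracts
  sum((df$end - df$start)[df$ancestry == label]) /
    (length(x@hapIds) * x@seqLength)
}

#' @rdname SweepParams-class
#' @param s selection coefficient (per-copy additive advantage).
#' @param tau generations under selection.
#' @param position bp position of the selected site.
#' @param dominance dominance coefficient (informational; additive model).
#' @param condition `"frequency"` or `"fixation"` (see class docs).
#' @export
SweepParams <- function(s, tau, position, dominance = 0.5,
                        condition = c("frequency", "fixation")) {
  condition <- match.arg(condition)
  new("SweepParams", s = as.numeric(s), tau = as.numeric(tau),
      position = as.numeric(position), dominance = as.numeric(dominance),
      condition = condition)
}

setMethod("show", "SweepParams", function(object) {
  cat(sprintf("SweepParams: s = %g, tau = %g, position = %g (%s)\n",
              object@s, object@tau, object@position, object@condition))
})

setMethod("show", "DemographicModel", function(object) {
  cat("DemographicModel", sQuote(object@name), "with",
      nrow(object@populations), "populations")
  if (nrow(object@pulses))
    cat(sprintf("; pulse %s -> %s (f = %g) at %g generations",
                object@pulses$source[1], object@pulses$dest[1],
                object@pulses$fraction[1], object@pulses$time[1]))
  cat("\n")
})

setMethod("show", "SfselectModel", function(object) {
  cat(sprintf(
    "SfselectModel: %d frequency bins, C = %g, |w| = %.3f, b = %.3f\n",
    object@bins, object@cost, sqrt(sum(object@w^2)), object@b))
})

#' @rdname AncestryAssignment-class
#' @param x an AncestryAssignment.
#' @export
setGeneric("blockLabels", function(x) standardGeneric("blockLabels"))
#' @rdname AncestryAssignment-class
setMethod("blockLabels", "AncestryAssignment", function(x) x@labels)
#' @rdname AncestryAssignment-class
#' @export
setGeneric("blockConfidence", function(x) standardGeneric("blockConfidence"))
#' @rdname AncestryAssignment-class
setMethod("blockConfidence", "AncestryAssignment", function(x) x@confidence)
#' @rdname AncestryAssignment-class
#' @export
setGeneric("nBlock", function(x) standardGeneric("nBlock"))
#' @rdname AncestryAssignment-class
setMethod("nBlock", "AncestryAssignment", function(x) length(x@blockStart))

setMethod("show", "AncestryAssignment", function(object) {
  tab <- table(object@labels)
  cat("AncestryAssignment:", nrow(object@labels), "haplotypes x",
      nBlock(object), "blocks;",
      paste(sprintf("%s: %.1f%%", names(tab), 100 * tab / sum(tab)),
            collapse = ", "), "\n")
})
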