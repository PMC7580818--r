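#' Re-exported generics
#'
#' Commonly needed accessors for the GRanges objects this package
#' returns, re-exported from GenomicRanges so users need not attach it.
#' @name reexports
#' @keywords internal
NULL

#' @importFrom GenomicRanges mcols
#' @export
GenomicRanges::mcols

#' @importFrom GenomicRanges start
#' @export
GenomicRanges::start

#' @importFrom GenomicRanges end
#' @export
GenomicRanges::end

#' @importFrom GenomicRanges seqnames
#' @export
GenomicRanges::seqnames

#' @importFrom GenomicRanges width
#' @export
GenomicRanges::width

#' @importFrom GenomicRanges GRanges
#' @export
GenomicRanges::GRanges
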