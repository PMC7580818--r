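#' @include demography.R genome_io.R
NULL

.pythonBin <- function() {
  p <- getOption("admixScan.python", "")
  if (!nzchar(p)) p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p))
    stop("no python interpreter found; the simulation module needs ",
         "python with msprime (set options(admixScan.python = ...))")
  p
}

.simScript <- function() {
  s <- system.file("python", "msprime_sim.py", package = "admixScan")
  if (!nzchar(s)) stop("msprime_sim.py not found in the installed package")
  s
}

# run the msprime backend on a config list; returns invisibly
.runBackend <- function(cfg) {
  cfgFile <- tempfile(fileext = ".json")
  on.exit(unlink(cfgFile))
  jsonlite::write_json(cfg, cfgFile, auto_unbox = TRUE, digits = NA,
                       null = "null")
  out <- suppressWarnings(system2(.pythonBin(), c(.simScript(), cfgFile),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("msprime backend failed:\n", paste(out, collapse = "\n"))
  invisible(out)
}

.readSimOutputs <- function(vcfPath, tractPath, metaPath, L, chrom) {
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  hapsList <- readPhasedVcf(vcfPath, seqLengths = stats::setNames(L, chrom),
                            verbose = FALSE)
  haps <- if (length(hapsList)) hapsList[[1]] else
    HaplotypeSet(matrix(integer(), length(meta$hap_names), 0), numeric(),
                 chrom = chrom, seqLength = L)
  # VCF sample order matches the backend's haplotype naming
  if (nHap(haps) == length(meta$hap_names))
    haps@hapIds <- meta$hap_names
  info <- data.frame(hapId = meta$hap_names, population = meta$populations,
                     stringsAsFactors = FALSE)
  tractSet <- NULL
  if (!is.null(tractPath) && file.exists(tractPath)) {
    df <- utils::read.delim(tractPath, stringsAsFactors = FALSE)
    tractSet <- AncestryTracts(df[, c("start", "end", "haplotype",
                                      "ancestry")],
                               hapIds = meta$hap_names, seqLength = L)
  }
  list(haps = haps, sampleInfo = info, tracts = tractSet, meta = meta)
}

#' Simulate neutral haplotypes under a demographic model
#'
#' Runs a coalescent simulation (msprime backend) of `model`, returning
#' phased haplotypes and, for admixed models, the true local-ancestry
#' tracts obtained from a census placed one generation older than the
#' admixture pulse. Output is deterministic given `(model, arguments,
#' seed)`.
#'
#' @param model a [DemographicModel-class].
#' @param nHap number of haplotypes to sample from the model's default
#'   target population (must be even); ignored when `samples` is given.
#' @param L sequence length in bp.
#' @param mu per-bp per-generation mutation rate.
#' @param r per-bp per-generation recombination rate.
#' @param seed integer random seed.
#' @param samples named integer vector of *diploid* counts per population;
#'   defaults to the preset's sampling scheme (or `nHap/2` for its target
#'   population).
#' @param tracts record true local-ancestry tracts (default: yes when the
#'   model has an admixture pulse).
#' @param chrom chromosome label for the output.
#' @return list with elements `haps` ([HaplotypeSet-class]), `sampleInfo`
#'   (data.frame of haplotype id and source population), `tracts`
#'   ([AncestryTracts-class] or NULL) and `meta` (backend metadata).
#' @examples
#' \donttest{
#' sim <- simulateNeutral(buildDemography("constant"), nHap = 10,
#'                        L = 1e5, seed = 1)
#' sim$haps
#' }
#' @export
simulateNeutral <- function(model, nHap = NULL, L = 1e6, mu = 1.25e-8,
                            r = 1e-8, seed = 1, samples = NULL,
                            tracts = nrow(model@pulses) > 0, chrom = "1") {
  stopifnot(is(model, "DemographicModel"))
  validObject(model)
  if (L <= 0) stop("L must be > 0")
  if (is.null(samples)) {
    samples <- model@samplePops
    if (!is.null(nHap)) {
      if (nHap %% 2 != 0) stop("nHap must be even (phased diploids)")
      samples[1] <- as.integer(nHap / 2)
    }
  }
  census <- if (tracts) {
    if (!nrow(model@pulses))
      stop("tracts requested but the model has no admixture pulse")
    max(model@pulses$time) + 1
  } else NULL
  vcfPath <- tempfile(fileext = ".vcf")
  tractPath <- if (tracts) tempfile(fileext = ".tsv") else NULL
  metaPath <- tempfile(fileext = ".json")
  on.exit(unlink(c(vcfPath, tractPath, metaPath)))
  cfg <- list(mode = "neutral", seed = seed, chrom = chrom, L = L, mu = mu,
              r = r, out_vcf = vcfPath, out_meta = metaPath,
              samples = as.list(samples),
              demography = .demographyToList(model, census = census))
  if (tracts) cfg$out_tracts <- tractPath
  .runBackend(cfg)
  .readSimOutputs(vcfPath, tractPath, metaPath, L, chrom)
}

#' Simulate a hard selective sweep
#'
#' Structured-coalescent simulation of a single-population hard sweep
#' with per-copy advantage `s` after `tau` generations of selection
#' (see [SweepParams()] for the conditioning modes). The deterministic
#' logistic trajectory maps `(s, tau)` to the present-day frequency of
#' the selected allele.
#'
#' @param model a single-population [DemographicModel-class] (e.g.
#'   `buildDemography("constant", Ne = ...)`).
#' @param sweep a [SweepParams-class].
#' @param nHap number of haplotypes (even).
#' @param L sequence length in bp.
#' @param mu,r mutation and recombination rates per bp per generation.
#' @param seed integer random seed.
#' @param maxRetries maximum number of trajectory retries before erroring.
#' @param chrom chromosome label.
#' @return a [HaplotypeSet-class]; the conditioning mode, realized end
#'   frequency and retry count are attached as `attr(x, "sweepMeta")`.
#' @export
simulateSweep <- function(model, sweep, nHap = 46, L = 1e5, mu = 1.25e-8,
                          r = 1e-8, seed = 1, maxRetries = 50, chrom = "1") {
  stopifnot(is(model, "DemographicModel"), is(sweep, "SweepParams"))
  validObject(model); validObject(sweep)
  if (nrow(model@populations) != 1)
    stop("sweep simulation requires a single-population model")
  if (sweep@position < 0 || sweep@position >= L)
    stop("selected site must lie inside [0, L)")
  if (nHap %% 2 != 0) stop("nHap must be even (phased diploids)")
  if (sweep@s == 0) {
    # neutral identity case
    sim <- simulateNeutral(model, nHap = nHap, L = L, mu = mu, r = r,
                           seed = seed, tracts = FALSE, chrom = chrom)
    haps <- sim$haps
    attr(haps, "sweepMeta") <- list(condition = "neutral", s = 0,
                                    tau = sweep@tau)
    return(haps)
  }
  vcfPath <- tempfile(fileext = ".vcf")
  metaPath <- tempfile(fileext = ".json")
  on.exit(unlink(c(vcfPath, metaPath)))
  samples <- stats::setNames(as.integer(nHap / 2), model@populations$name[1])
  cfg <- list(mode = "sweep", seed = seed, chrom = chrom, L = L, mu = mu,
              r = r, out_vcf = vcfPath, out_meta = metaPath,
              samples = as.list(samples),
              demography = .demographyToList(model),
              sweep = list(s = sweep@s, tau = sweep@tau,
                           position = sweep@position,
                           condition = sweep@condition,
                           max_retries = maxRetries))
  .runBackend(cfg)
  out <- .readSimOutputs(vcfPath, NULL, metaPath, L, chrom)
  haps <- out$haps
  attr(haps, "sweepMeta") <- out$meta[c("condition", "end_frequency",
                                        "generations_since_fixation",
                                        "retries")]
  haps
}

#' Is the msprime backend available?
#'
#' @return TRUE if a python interpreter with msprime importable is found.
#' @export
msprimeAvailable <- function() {
  ok <- tryCatch({
    p <- .pythonBin()
    status <- suppressWarnings(
      system2(p, c("-c", shQuote("import msprime")), stdout = FALSE,
              stderr = FALSE))
    status == 0
  }, error = function(e) FALSE)
  isTRUE(ok)
}
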