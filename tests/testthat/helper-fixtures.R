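# deterministic synthetic fixtures and independent reference
# implementations used as oracles across the suite

# random phased haplotype fixture (no linkage structure; for exactness
# oracles, not for realism)
makeRandomHaps <- function(nHap = 10, nSite = 50, seed = 1, missing = 0,
                           L = NULL, minSpacing = 50, maxSpacing = 500) {
  set.seed(seed)
  pos <- cumsum(sample(minSpacing:maxSpacing, nSite, replace = TRUE))
  m <- matrix(rbinom(nHap * nSite, 1, runif(nSite, 0.1, 0.9)[
    rep(seq_len(nSite), each = nHap)]), nrow = nHap)
  if (missing > 0) m[sample(length(m), round(missing * length(m)))] <- NA
  HaplotypeSet(m, positions = pos, seqLength = max(pos) + 1000)
}

# reference EHH walk: direct definition via string-keyed grouping,
# independent of the C++ kernel
refEhh <- function(haps, core, allele, dir, maxGap = 20000,
                   minEhh = 0.05) {
  mat <- alleleMatrix(haps)
  pos <- positions(haps)
  carriers <- which(!is.na(mat[, core]) & mat[, core] == allele)
  denom <- choose(length(carriers), 2)
  off <- 0; eh <- 1; reason <- "chrom-end"
  active <- carriers
  key <- rep("", length(active))
  prev <- pos[core]
  j <- core + dir
  while (j >= 1 && j <= ncol(mat) && denom > 0) {
    if (abs(pos[j] - prev) > maxGap) { reason <- "gap"; break }
    a <- mat[active, j]
    keepIdx <- !is.na(a)
    active <- active[keepIdx]
    key <- paste(key[keepIdx], a[keepIdx])
    e <- sum(choose(table(key), 2)) / denom
    off <- c(off, abs(pos[j] - pos[core]))
    eh <- c(eh, e)
    prev <- pos[j]
    if (e < minEhh) { reason <- "below-cutoff"; break }
    j <- j + dir
  }
  list(offset = off, ehh = eh, reason = reason)
}

refTrapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

# nucleotide diversity per site (mean pairwise differences / L)
pairwiseDiversity <- function(haps) {
  a <- alleleMatrix(haps)
  n <- nrow(a)
  p <- colMeans(a, na.rm = TRUE)
  sum(2 * p * (1 - p) * n / (n - 1)) / seqLength(haps)
}

tajimasD <- function(haps) {
  a <- alleleMatrix(haps)
  n <- nrow(a)
  p <- colMeans(a)
  seg <- p > 0 & p < 1
  S <- sum(seg)
  if (S < 3) return(NA_real_)
  k <- sum(2 * p[seg] * (1 - p[seg]) * n / (n - 1))
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# shared simulation cache so expensive msprime runs are reused across
# test files within one test_dir() run
.simCache <- new.env(parent = emptyenv())

cachedSim <- function(key, fn) {
  if (is.null(.simCache[[key]])) assign(key, fn(), envir = .simCache)
  .simCache[[key]]
}

# admixed target + reference panels with truth tracts (5 Mb)
admixedPanelSim <- function() {
  cachedSim("admixedPanel", function() {
    dem <- buildDemography("afroasiatic")
    simulateNeutral(dem, L = 5e6, seed = 20260918,
                    samples = c(EAFR = 24L, AFR = 12L, EUR = 12L),
                    tracts = TRUE)
  })
}

constantSim <- function() {
  cachedSim("constant10", function() {
    simulateNeutral(buildDemography("constant", Ne = 10000), nHap = 20,
                    L = 5e6, seed = 424242)
  })
}
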