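# simulation-backed tests; each test uses modest region sizes so the
# whole file stays within a few minutes

test_that("simulation is deterministic given the seed", {
  dem <- buildDemography("constant", Ne = 5000)
  a <- simulateNeutral(dem, nHap = 8, L = 2e5, seed = 99)
  b <- simulateNeutral(dem, nHap = 8, L = 2e5, seed = 99)
  c <- simulateNeutral(dem, nHap = 8, L = 2e5, seed = 100)
  expect_identical(alleleMatrix(a$haps), alleleMatrix(b$haps))
  expect_identical(positions(a$haps), positions(b$haps))
  expect_false(identical(positions(a$haps), positions(c$haps)))
})

test_that("zero mutation rate yields zero sites; odd nHap errors", {
  dem <- buildDemography("constant", Ne = 5000)
  sim <- simulateNeutral(dem, nHap = 6, L = 1e5, mu = 0, seed = 5)
  expect_equal(nSite(sim$haps), 0)
  expect_equal(nHap(sim$haps), 6)
  expect_error(simulateNeutral(dem, nHap = 7, L = 1e5, seed = 5), "even")
})

test_that("constant-size diversity matches the coalescent expectation 4*N*mu", {
  # E[pi] per site = 4 N mu; one long chromosome stands in for replicates
  Ne <- 10000; mu <- 1.25e-8
  sim <- constantSim()  # 20 haplotypes, 5 Mb, Ne 10000
  piHat <- pairwiseDiversity(sim$haps)
  expect_equal(piHat, 4 * Ne * mu, tolerance = 0.15)
})

test_that("neutral equilibrium gives Tajima's D near 0 and a 1/i SFS", {
  sim <- constantSim()
  haps <- sim$haps
  # mean D over 100 kb chunks ~ 0 (chunks are weakly correlated)
  starts <- seq(0, 4.9e6, by = 1e5)
  ds <- vapply(starts, function(s0) {
    idx <- which(positions(haps) >= s0 & positions(haps) < s0 + 1e5)
    if (length(idx) < 10) return(NA_real_)
    tajimasD(haps[, idx])
  }, numeric(1))
  expect_lt(abs(mean(ds, na.rm = TRUE)), 0.35)

  # relative SFS proportional to 1/i (Watterson expectation): per-class
  # t statistics across independent replicates (linkage inflates a
  # naive single-run chi-square, so the variance is estimated
  # empirically across replicates)
  dem <- buildDemography("constant", Ne = 10000)
  R <- 20
  sfsMat <- vapply(1:R, function(i) {
    s <- simulateNeutral(dem, nHap = 20, L = 2e5,
                         seed = childSeed(31415, i))$haps
    relativeSfs(s)
  }, numeric(19))
  expected <- (1 / 1:19) / sum(1 / 1:19)
  m <- rowMeans(sfsMat)
  se <- apply(sfsMat, 1, sd) / sqrt(R)
  expect_lt(max(abs((m - expected) / se)), 4.5)
})

test_that("ancestry tracts tile the genome and recover the pulse fraction", {
  sim <- admixedPanelSim()
  expect_s4_class(sim$tracts, "AncestryTracts")  # validity enforces tiling
  # West-Eurasian coverage of the target haplotypes fluctuates around
  # f = 0.54 on a single 5 Mb replicate (few long tracts per haplotype)
  targetIds <- sim$sampleInfo$hapId[sim$sampleInfo$population == "EAFR"]
  df <- tracts(sim$tracts)
  df <- df[df$haplotype %in% targetIds, ]
  cov <- sum((df$end - df$start)[df$ancestry == "WEA"]) /
    (length(targetIds) * seqLength(sim$haps))
  expect_lt(abs(cov - 0.54), 0.15)
  # across 50 replicates the mean coverage is within +/- 0.03 of f
  dem <- buildDemography("afroasiatic")
  covs <- vapply(1:50, function(i) {
    s <- simulateNeutral(dem, L = 2e6, seed = childSeed(4242, i),
                         tracts = TRUE)
    tractCoverage(s$tracts, "WEA")
  }, numeric(1))
  expect_lt(abs(mean(covs) - 0.54), 0.03)
})

test_that("logistic trajectory helper solves the selection ODE", {
  # numeric forward-Euler integration of dx/dt = s x (1 - x) as oracle
  s <- 0.03; Ne <- 10000
  x <- 1 / (2 * Ne); dt <- 0.01
  for (t in seq(dt, 500, by = dt)) x <- x + dt * s * x * (1 - x)
  expect_equal(logisticFrequency(s, 500, Ne), x, tolerance = 1e-3)
  # fixation time is consistent with the trajectory
  tf <- fixationTime(s, Ne)
  expect_equal(logisticFrequency(s, tf, Ne), 1 - 1 / (2 * Ne),
               tolerance = 1e-6)
})

test_that("sweeps reduce diversity near the selected site", {
  dem <- buildDemography("constant", Ne = 10000)
  sp <- SweepParams(s = 0.05, tau = fixationTime(0.05, 10000),
                    position = 5e4, condition = "fixation")
  wins <- 0
  reps <- 8
  for (i in seq_len(reps)) {
    sw <- simulateSweep(dem, sp, nHap = 20, L = 1e5,
                        seed = childSeed(777, i))
    nt <- simulateNeutral(dem, nHap = 20, L = 1e5,
                          seed = childSeed(777, i))$haps
    mid <- function(h) {
      idx <- which(positions(h) >= 4e4 & positions(h) < 6e4)
      p <- derivedFreq(h[, idx])
      sum(2 * p * (1 - p) * 20 / 19)
    }
    wins <- wins + (mid(sw) < mid(nt))
  }
  # sign test: diversity within 10 kb of the site is lower in most pairs
  expect_gte(wins, 7)
  meta <- attr(sw, "sweepMeta")
  expect_equal(meta$condition, "fixation")
})

test_that("an s = 0 sweep falls back to the neutral engine", {
  dem <- buildDemography("constant", Ne = 5000)
  sp <- SweepParams(s = 0, tau = 100, position = 5e4)
  sw <- simulateSweep(dem, sp, nHap = 10, L = 1e5, seed = 31)
  nt <- simulateNeutral(dem, nHap = 10, L = 1e5, seed = 31)$haps
  expect_identical(alleleMatrix(sw), alleleMatrix(nt))
  expect_error(simulateSweep(dem, SweepParams(0.05, 100, 2e5), nHap = 10,
                             L = 1e5, seed = 1), "inside")
})
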