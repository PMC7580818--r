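test_that("blocks partition the site range with terminal merging", {
  b <- admixScan:::.makeBlocks(100, 20)
  expect_equal(b$start, c(1, 21, 41, 61, 81))
  expect_equal(b$end, c(20, 40, 60, 80, 100))
  # 7 leftover sites merge into the previous block
  b2 <- admixScan:::.makeBlocks(107, 20)
  expect_equal(b2$end[length(b2$end)], 107)
  expect_equal(length(b2$start), 5)
})

test_that("a query identical to a reference haplotype gets that label", {
  set.seed(61)
  nSnp <- 100
  pA <- runif(nSnp, 0.05, 0.5)
  pB <- pmin(pA + 0.45, 0.95)  # well-diverged allele frequencies
  draw <- function(p, n) t(replicate(n, rbinom(nSnp, 1, p)))
  pos <- sort(sample(1:300000, nSnp))
  refA <- HaplotypeSet(draw(pA, 12), pos, seqLength = 3e5 + 1)
  refB <- HaplotypeSet(draw(pB, 12), pos, seqLength = 3e5 + 1)
  query <- HaplotypeSet(rbind(alleleMatrix(refA)[1, ],
                              alleleMatrix(refB)[5, ]), pos,
                        seqLength = 3e5 + 1)
  asg <- assignLocalAncestry(query, refA, refB, smoothK = 1)
  expect_true(all(blockLabels(asg)[1, ] == "AFR"))
  expect_true(all(blockLabels(asg)[2, ] == "WEA"))
  expect_error(assignLocalAncestry(query, refA[1:5, ], refB),
               "at least 10")
})

test_that("identical reference panels give ~50/50 labels at low confidence", {
  set.seed(62)
  nSnp <- 400
  p <- runif(nSnp, 0.2, 0.8)
  draw <- function(n) t(replicate(n, rbinom(nSnp, 1, p)))
  pos <- sort(sample(1:1000000, nSnp))
  refA <- HaplotypeSet(draw(12), pos)
  refB <- HaplotypeSet(draw(12), pos)   # same distribution: no signal
  query <- HaplotypeSet(draw(30), pos)
  asg <- assignLocalAncestry(query, refA, refB, smoothK = 1)
  fracA <- mean(blockLabels(asg) == "AFR")
  expect_gt(fracA, 0.3); expect_lt(fracA, 0.7)
  # diverged panels give much higher confidence than identical ones
  pB <- pmin(p + 0.4, 0.95)
  refBdiv <- HaplotypeSet(t(replicate(12, rbinom(nSnp, 1, pB))), pos)
  asgDiv <- assignLocalAncestry(query, refA, refBdiv, smoothK = 1)
  expect_gt(mean(blockConfidence(asgDiv)), mean(blockConfidence(asg)))
})

test_that("simulated admixed haplotypes are deconvoluted at >= 0.90 accuracy", {
  sim <- admixedPanelSim()
  info <- sim$sampleInfo
  # ancestry assignment runs on common variants (array-like density)
  haps <- mafFilter(sim$haps, 0.05)
  tIdx <- which(info$population == "EAFR")
  query <- haps[tIdx, ]
  refA <- haps[which(info$population == "AFR"), ]
  refB <- haps[which(info$population == "EUR"), ]
  asg <- assignLocalAncestry(query, refA, refB)
  truthAll <- assignmentFromTracts(sim$tracts, haps)
  truth <- new("AncestryAssignment",
               labels = blockLabels(truthAll)[tIdx, , drop = FALSE],
               confidence = blockConfidence(truthAll)[tIdx, , drop = FALSE],
               blockStart = truthAll@blockStart,
               blockEnd = truthAll@blockEnd, blockBp = truthAll@blockBp,
               hapIds = hapIds(query))
  acc <- assignmentAccuracy(asg, truth)
  expect_gte(acc, 0.90)
})

test_that("masking matches a direct per-entry recomputation", {
  hs <- makeRandomHaps(8, 60, seed = 71)
  blocks <- admixScan:::.makeBlocks(60, 20)
  set.seed(72)
  lab <- matrix(sample(c("AFR", "WEA"), 8 * 3, replace = TRUE), 8, 3)
  asg <- new("AncestryAssignment", labels = lab,
             confidence = matrix(1, 8, 3), blockStart = blocks$start,
             blockEnd = blocks$end,
             blockBp = cbind(positions(hs)[blocks$start],
                             positions(hs)[blocks$end]),
             hapIds = hapIds(hs))
  masked <- maskAncestry(hs, asg, "WEA")
  # direct recomputation
  for (k in 1:3) {
    j <- blocks$start[k]:blocks$end[k]
    for (h in 1:8) {
      if (lab[h, k] == "WEA")
        expect_true(all(is.na(alleleMatrix(masked)[h, j])))
      else
        expect_identical(alleleMatrix(masked)[h, j],
                         alleleMatrix(hs)[h, j])
    }
    expect_equal(unique(maskedFraction(masked)[j]),
                 mean(lab[, k] == "WEA"))
  }
  # all-AFR assignment leaves data untouched
  asg0 <- new("AncestryAssignment", labels = matrix("AFR", 8, 3),
              confidence = matrix(1, 8, 3), blockStart = blocks$start,
              blockEnd = blocks$end, blockBp = asg@blockBp,
              hapIds = hapIds(hs))
  m0 <- maskAncestry(hs, asg0, "WEA")
  expect_identical(alleleMatrix(m0), alleleMatrix(hs))
  expect_true(all(maskedFraction(m0) == 0))
  expect_equal(ancestryProportion(m0), 0)
  # all-WEA masks everything
  asg1 <- new("AncestryAssignment", labels = matrix("WEA", 8, 3),
              confidence = matrix(1, 8, 3), blockStart = blocks$start,
              blockEnd = blocks$end, blockBp = asg@blockBp,
              hapIds = hapIds(hs))
  m1 <- maskAncestry(hs, asg1, "WEA")
  expect_true(all(is.na(alleleMatrix(m1))))
  expect_equal(ancestryProportion(m1), 1)
})

test_that("genome-wide proportion equals the SNP-weighted block average", {
  hs <- makeRandomHaps(10, 100, seed = 81)
  blocks <- admixScan:::.makeBlocks(100, 20)
  set.seed(82)
  lab <- matrix(sample(c("AFR", "WEA"), 10 * 5, replace = TRUE,
                       prob = c(0.6, 0.4)), 10, 5)
  asg <- new("AncestryAssignment", labels = lab,
             confidence = matrix(1, 10, 5), blockStart = blocks$start,
             blockEnd = blocks$end,
             blockBp = cbind(positions(hs)[blocks$start],
                             positions(hs)[blocks$end]),
             hapIds = hapIds(hs))
  masked <- maskAncestry(hs, asg, "WEA")
  snpsPerBlock <- blocks$end - blocks$start + 1
  want <- sum((colMeans(lab == "WEA")) * snpsPerBlock) / 100
  expect_equal(ancestryProportion(masked), want, tolerance = 1e-12)
  expect_warning(p <- ancestryProportion(masked, c(1e7, 2e7)), "no SNP")
  expect_true(is.na(p))
})

test_that("window merging is an interval union", {
  w <- makeWindows(100000)
  merged <- mergeSelected(w[1:2])
  expect_equal(c(start(merged) - 1, end(merged)), c(0, 55000))
  # disjoint windows unchanged
  far <- c(w[1], GRanges("1", IRanges(start = 90001, width = 30000)))
  m2 <- mergeSelected(far)
  expect_length(m2, 2)
  # randomized vs an independent bp-level union oracle
  set.seed(91)
  for (rep in 1:5) {
    sel <- sort(sample(seq_along(makeWindows(5e5)), 8))
    ws <- makeWindows(5e5)[sel]
    got <- mergeSelected(ws)
    covered <- rep(FALSE, 5e5)
    for (i in seq_along(ws))
      covered[(start(ws)[i]):(end(ws)[i])] <- TRUE
    runs <- rle(covered)
    nRuns <- sum(runs$values)
    expect_equal(length(got), nRuns)
    expect_equal(sum(width(got)), sum(covered))
  }
})

test_that("enrichment p-value matches exact enumeration on the 4-window fixture", {
  # windows {0.1, 0.2, 0.3, 0.4}, selected = the {0.3, 0.4} pair:
  # observed mean 0.35; 1 of the C(4,2) = 6 subsets has mean >= 0.35
  fr <- c(0.1, 0.2, 0.3, 0.4)
  res <- enrichmentResampling(fr, selected = c(3, 4), n = 60000, seed = 3)
  expect_equal(res@observed, 0.35)
  se <- sqrt((1 / 6) * (5 / 6) / 60000)
  expect_lt(abs(res@p - 1 / 6), 4 * se + 2 / 60000)
  # extreme case: selected = the k largest fractions -> p = 1/(n+1)
  set.seed(4)
  fr2 <- runif(50)
  top <- order(fr2, decreasing = TRUE)[1:5]
  res2 <- enrichmentResampling(fr2, top, n = 2000, seed = 5)
  expect_equal(res2@p, 1 / 2001)
  # determinism and bounds
  res3 <- enrichmentResampling(fr2, top, n = 2000, seed = 5)
  expect_identical(res2@p, res3@p)
  expect_error(enrichmentResampling(fr2, integer(0)), "empty")
})

test_that("enrichment p is approximately uniform under a random selection", {
  set.seed(101)
  fr <- runif(120)
  ps <- vapply(1:500, function(i) {
    sel <- sample(120, 10)
    enrichmentResampling(fr, sel, n = 400, seed = i)@p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, punif))
  expect_gt(ks$p.value, 0.01)
})

test_that("unbalanced regions obey the span rule", {
  wins <- makeWindows(5e6)
  n <- length(wins)
  set.seed(111)
  base <- 0.5 + rnorm(n, 0, 0.01)
  # a 0.6 Mb dip to 0.05 -> one region; uniform track -> none
  dipIdx <- which(start(wins) - 1 >= 2e6 & end(wins) <= 2.6e6)
  f <- base; f[dipIdx] <- 0.05
  mcols(wins)$fraction <- f
  got <- unbalancedRegions(wins, minSpan = 5e5, bandQ = 99)
  expect_length(got, 1)
  expect_equal(mcols(got)$direction, "low")
  expect_gte(mcols(got)$span, 5e5)
  expect_true(start(got) - 1 <= min(start(wins)[dipIdx]) &&
                end(got) >= max(end(wins)[dipIdx]))
  # same dip spanning only ~0.2 Mb -> filtered by the span rule
  dip2 <- which(start(wins) - 1 >= 2e6 & end(wins) <= 2.2e6)
  f2 <- base; f2[dip2] <- 0.05
  mcols(wins)$fraction <- f2
  expect_length(unbalancedRegions(wins, minSpan = 5e5, bandQ = 99), 0)
  # uniform track at the genome-wide mean -> empty
  mcols(wins)$fraction <- rep(0.5, n)
  expect_length(unbalancedRegions(wins, minSpan = 5e5, bandQ = 99), 0)
})

test_that("pulse-fraction recovery via truth tracts across fractions", {
  # estimated genome-wide proportions within +/-0.05 of f
  for (f in c(0.07, 0.43)) {
    dem <- buildDemography("afroasiatic", pulseFraction = f)
    sim <- simulateNeutral(dem, L = 4e6, seed = 9000 + round(100 * f),
                           tracts = TRUE)
    asg <- assignmentFromTracts(sim$tracts, sim$haps)
    masked <- maskAncestry(sim$haps, asg, "WEA")
    expect_equal(ancestryProportion(masked), f, tolerance = 0.05 / f)
  }
})
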