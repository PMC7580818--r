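test_that("EHH at the core is 1 and the pair-counting example holds", {
  # 4 haplotypes, 3 carry the derived core allele; at the next site the
  # carriers split {0,1,1}: EHH = C(2,2)/C(3,2) = 1/3
  m <- rbind(c(1L, 0L), c(1L, 1L), c(1L, 1L), c(0L, 0L))
  hs <- HaplotypeSet(m, positions = c(100, 600))
  cv <- ehh(hs, core = 1, allele = 1)
  expect_equal(cv$right$ehh[1], 1)
  expect_equal(cv$right$ehh[2], 1 / 3)
  expect_equal(cv$right$offset, c(0, 500))
  # all carriers identical over the region -> EHH stays 1 to the end
  m2 <- cbind(rep(1L, 4), rep(0L, 4), rep(1L, 4))
  hs2 <- HaplotypeSet(m2, positions = c(0, 400, 900))
  cv2 <- ehh(hs2, core = 1, allele = 1)
  expect_true(all(cv2$right$ehh == 1))
  expect_equal(attr(cv2$right, "reason"), "chrom-end")
})

test_that("EHH requires at least two carriers", {
  m <- rbind(c(1L, 0L), c(0L, 1L), c(0L, 0L))
  hs <- HaplotypeSet(m, positions = c(10, 500))
  expect_error(ehh(hs, core = 1, allele = 1), "fewer than 2 carriers")
})

test_that("EHH matches the reference implementation on random fixtures", {
  for (seed in 1:5) {
    hs <- makeRandomHaps(14, 80, seed = seed,
                         missing = ifelse(seed > 3, 0.05, 0))
    core <- 40
    for (allele in 0:1) {
      cnt <- sum(alleleMatrix(hs)[, core] == allele, na.rm = TRUE)
      if (cnt < 2) next
      got <- ehh(hs, core, allele, maxGap = 5000, minEhh = 0.05)
      for (dir in c(-1, 1)) {
        want <- refEhh(hs, core, allele, dir, maxGap = 5000, minEhh = 0.05)
        side <- if (dir < 0) got$left else got$right
        expect_equal(side$offset, want$offset)
        expect_equal(side$ehh, want$ehh)
        expect_equal(attr(side, "reason"), want$reason)
        # monotone non-increasing in [0, 1], starting at 1
        expect_equal(side$ehh[1], 1)
        expect_true(all(diff(side$ehh) <= 1e-12))
        expect_true(all(side$ehh >= 0 & side$ehh <= 1))
      }
    }
  }
})

test_that("gap rule truncates and flags a side", {
  m <- rbind(c(1L, 1L, 0L), c(1L, 1L, 1L), c(1L, 0L, 1L), c(0L, 0L, 0L))
  hs <- HaplotypeSet(m, positions = c(0, 1000, 30000))
  cv <- ehh(hs, core = 1, allele = 1, maxGap = 20000)
  expect_equal(attr(cv$right, "reason"), "gap")
  expect_equal(length(cv$right$ehh), 2)  # stopped before the far site
})

test_that("iHH trapezoid integration matches closed form and quadrature", {
  side <- data.frame(offset = c(0, 1000), ehh = c(1, 0.5))
  expect_equal(ihh(side, side[0, ]), 750)
  expect_equal(ihh(side, side), 1500)  # mirror symmetry doubles
  # piecewise-linear curve vs fine-grid numerical integration
  set.seed(7)
  off <- c(0, sort(sample(1:20000, 30)))
  vals <- c(1, sort(runif(30, 0, 1), decreasing = TRUE))
  curve <- data.frame(offset = off, ehh = vals)
  fine <- approx(off, vals, xout = seq(0, max(off), by = 0.5))
  quad <- refTrapz(fine$x, fine$y)
  expect_equal(ihh(curve, curve[0, ]), quad, tolerance = 1e-9)
})

test_that("uiHS is antisymmetric under allele relabeling and 0 for symmetric data", {
  hs <- makeRandomHaps(16, 60, seed = 21)
  rec <- ihsScan(hs, mafThreshold = 0.1, minHap = 5)
  flipped <- HaplotypeSet(1L - alleleMatrix(hs), positions = positions(hs),
                          seqLength = seqLength(hs))
  rec2 <- ihsScan(flipped, mafThreshold = 0.1, minHap = 5)
  expect_equal(rec$position, rec2$position)
  expect_equal(rec$uihs, -rec2$uihs)
  expect_equal(rec$ihhA, rec2$ihhD)

  # configuration symmetric under allele relabeling: uiHS = 0
  m <- rbind(c(1L, 1L, 0L), c(1L, 1L, 1L), c(0L, 0L, 1L), c(0L, 0L, 0L))
  hs3 <- HaplotypeSet(m, positions = c(0, 500, 1000))
  r <- unstandardizedIhs(hs3, core = 2)
  expect_equal(r$uihs, 0)
})

test_that("a 6-haplotype case equals the step-by-step reference computation", {
  set.seed(33)
  m <- matrix(rbinom(6 * 30, 1, 0.5), nrow = 6)
  m[, 15] <- c(1L, 1L, 1L, 0L, 0L, 0L)
  hs <- HaplotypeSet(m, positions = sort(sample(0:8000, 30)))
  for (allele in 0:1) {
    l <- refEhh(hs, 15, allele, -1); r <- refEhh(hs, 15, allele, +1)
    want <- refTrapz(l$offset, l$ehh) + refTrapz(r$offset, r$ehh)
    got <- ehh(hs, 15, allele)
    expect_equal(ihh(got$left, got$right), want)
  }
  rec <- unstandardizedIhs(hs, 15)
  expect_equal(rec$uihs, log(rec$ihhA / rec$ihhD))
})

test_that("standardization gives per-bin mean 0 / SD 1 and handles degenerate bins", {
  # one bin containing {a, -a} -> standardized {+1, -1}
  rec <- data.frame(freq = c(0.5, 0.5), uihs = c(2, -2), ok = TRUE)
  out <- standardizeIhs(rec, nBins = 5, minPerBin = 2)
  expect_equal(sort(out$ihs), c(-1, 1))
  # all-equal scores in a bin -> flagged NA
  recd <- data.frame(freq = rep(0.5, 5), uihs = rep(1.3, 5), ok = TRUE)
  outd <- standardizeIhs(recd, nBins = 5, minPerBin = 2)
  expect_true(all(is.na(outd$ihs)))
  # frequency-dependent Gaussian uiHS: pooled standardized scores are N(0,1)
  set.seed(101)
  n <- 10000
  freq <- runif(n, 0.05, 0.95)
  bin <- findInterval(freq, seq(0, 1, length.out = 51))
  mu <- 0.5 * sin(bin / 8); sdv <- 0.5 + bin / 50
  recs <- data.frame(freq = freq, uihs = rnorm(n, mu, sdv), ok = TRUE)
  std <- standardizeIhs(recs, nBins = 50, minPerBin = 10)
  for (b in unique(std$bin)) {
    v <- std$ihs[std$bin == b]
    expect_lt(abs(mean(v)), 1e-10)
    expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-10)
  }
  ks <- suppressWarnings(ks.test(std$ihs, pnorm))
  expect_gt(ks$p.value, 0.01)
})

test_that("Gaussian p-values behave", {
  expect_equal(ihsPvalue(0)$pvalue, 1)
  expect_equal(ihsPvalue(0)$negLogP, 0)
  expect_equal(ihsPvalue(3.8906)$pvalue, 1e-4, tolerance = 1e-3)
  x <- seq(0, 6, by = 0.25)
  expect_true(all(diff(ihsPvalue(x)$pvalue) < 0))
})

test_that("window summaries match brute-force aggregation", {
  # |iHS| {1,2,3} in one window -> mean 2, max 3
  rec <- data.frame(position = c(1000, 2000, 3000),
                    ihs = c(-1, 2, -3),
                    negLogP = ihsPvalue(c(-1, 2, -3))$negLogP)
  w <- windowIhs(rec, makeWindows(30000))
  expect_equal(mcols(w)$meanAbsIhs, 2)
  expect_equal(mcols(w)$maxAbsIhs, 3)
  expect_equal(mcols(w)$nSnps, 3L)

  # randomized check incl. window overlap and empty windows
  set.seed(55)
  recs <- data.frame(position = sort(sample(0:200000, 300)),
                     ihs = rnorm(300))
  recs$negLogP <- ihsPvalue(recs$ihs)$negLogP
  recs$ihs[sample(300, 20)] <- NA
  wins <- makeWindows(2e5)
  got <- windowIhs(recs, wins)
  for (i in seq_along(wins)) {
    s0 <- start(wins)[i] - 1; e0 <- end(wins)[i]
    inw <- recs$position >= s0 & recs$position < e0 & is.finite(recs$ihs)
    expect_equal(mcols(got)$nSnps[i], sum(inw))
    if (any(inw)) {
      expect_equal(mcols(got)$meanAbsIhs[i], mean(abs(recs$ihs[inw])))
      expect_equal(mcols(got)$maxAbsIhs[i], max(abs(recs$ihs[inw])))
      expect_equal(mcols(got)$maxNegLogP[i], max(recs$negLogP[inw]))
    } else {
      expect_true(is.na(mcols(got)$meanAbsIhs[i]))
    }
  }
})

test_that("masked haplotypes drop out of pair counts without breaking bounds", {
  hs <- makeRandomHaps(20, 80, seed = 77, missing = 0.15)
  rec <- ihsScan(hs, mafThreshold = 0.05, minHap = 10)
  expect_true(all(rec$ihhA >= 0 & rec$ihhD >= 0))
  expect_true(all(is.finite(rec$uihs[rec$ok])))
})
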