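test_that("SFS features match a brute-force histogram", {
  hs <- makeRandomHaps(46, 200, seed = 13)
  w <- c(positions(hs)[20], positions(hs)[120])
  x <- windowSfsFeature(hs, w, bins = 20)
  expect_equal(sum(x), 1)
  # brute force
  p <- derivedFreq(hs)
  pos <- positions(hs)
  sel <- pos >= w[1] & pos < w[2] & p > 0 & p < 1
  # right-open bins, matching the documented convention
  brute <- table(cut(p[sel], seq(0, 1, length.out = 21), right = FALSE))
  expect_equal(as.numeric(x), as.numeric(brute) / sum(brute))
  expect_equal(attr(x, "nSnps"), sum(sel))
})

test_that("empty windows are flagged and singletons land in one bin", {
  hs <- makeRandomHaps(10, 20, seed = 3)
  x <- windowSfsFeature(hs, c(1e7, 2e7), bins = 20)
  expect_true(attr(x, "empty"))
  expect_equal(as.numeric(x), rep(0, 20))
  # all sites singletons in 46 haplotypes: all mass where 1/46 falls
  m <- matrix(0L, 46, 5)
  m[1, ] <- 1L
  hss <- HaplotypeSet(m, positions = seq(100, 500, by = 100))
  xs <- windowSfsFeature(hss, c(0, 1000), bins = 20)
  expect_equal(xs[ceiling((1 / 46) * 20)], 1)
  expect_equal(sum(xs), 1)
})

test_that("the linear SVM separates a separable toy set exactly", {
  set.seed(1)
  # neutral mass in low-frequency bins, swept mass in high-frequency bins
  lowBins <- t(replicate(30, { v <- c(runif(10, 1, 2), runif(10, 0, 0.1))
                               v / sum(v) }))
  highBins <- t(replicate(30, { v <- c(runif(10, 0, 0.1), runif(10, 1, 2))
                                v / sum(v) }))
  model <- trainSfselect(lowBins, highBins, C = 10)
  sc <- scoreWindows(rbind(lowBins, highBins), model)
  pred <- sc$score > 0
  expect_equal(pred, rep(c(FALSE, TRUE), each = 30))
  # label swap flips every decision value
  swapped <- trainSfselect(highBins, lowBins, C = 10)
  sc2 <- scoreWindows(rbind(lowBins, highBins), swapped)
  expect_equal(sc2$score, -sc$score, tolerance = 1e-5)
  # determinism
  again <- trainSfselect(lowBins, highBins, C = 10)
  expect_identical(again@w, model@w)
  expect_identical(again@b, model@b)
  expect_error(trainSfselect(lowBins[0, , drop = FALSE], highBins),
               "non-empty")
})

test_that("scoring is the exact linear decision value", {
  set.seed(8)
  model <- new("SfselectModel", w = rnorm(20), b = 0.3, cost = 1,
               bins = 20L, metadata = list())
  X <- matrix(runif(100), 5, 20)
  sc <- scoreWindows(X, model)
  expect_equal(sc$score, as.numeric(X %*% model@w + model@b),
               tolerance = 1e-12)
  # w = 0 -> every score equals b; flagged empty windows keep score b
  m0 <- new("SfselectModel", w = rep(0, 20), b = 0.7, cost = 1, bins = 20L,
            metadata = list())
  z <- matrix(0, 2, 20)
  attr(z, "empty") <- c(TRUE, TRUE)
  sc0 <- scoreWindows(z, m0)
  expect_equal(sc0$score, c(0.7, 0.7))
  expect_true(all(sc0$empty))
  expect_error(scoreWindows(matrix(0, 1, 5), m0), "does not match")
  # affine consistency along segments between two features
  x1 <- X[1, ]; x2 <- X[2, ]
  for (alpha in c(0.25, 0.5, 0.8)) {
    mix <- scoreWindows(alpha * x1 + (1 - alpha) * x2, model)$score
    expect_equal(mix, alpha * sc$score[1] + (1 - alpha) * sc$score[2],
                 tolerance = 1e-10)
  }
})

test_that("the SVM agrees with an independent reference implementation", {
  set.seed(42)
  X <- rbind(matrix(rnorm(200, -0.4), 20, 10),
             matrix(rnorm(200, 0.4), 20, 10))
  model <- trainSfselect(X[1:20, ], X[21:40, ], C = 1)
  ours <- scoreWindows(X, model)$score
  dir <- tempfile(); dir.create(dir)
  write.csv(X, file.path(dir, "X.csv"), row.names = FALSE)
  script <- file.path(dir, "svm.py")
  writeLines(c(
    "import numpy as np, sys",
    "from sklearn.svm import LinearSVC",
    sprintf("X = np.loadtxt('%s/X.csv', delimiter=',', skiprows=1)", dir),
    "y = np.r_[np.zeros(20), np.ones(20)]",
    "m = LinearSVC(C=1.0, loss='squared_hinge').fit(X, y)",
    "np.savetxt(sys.argv[1], m.decision_function(X))"), script)
  out <- file.path(dir, "dec.txt")
  status <- system2(Sys.which("python"), c(script, out), stdout = FALSE,
                    stderr = FALSE)
  expect_equal(status, 0L)
  ref <- scan(out, quiet = TRUE)
  # same decision rule (regularization details differ slightly)
  expect_equal(sign(ours), sign(ref))
  expect_gt(cor(ours, ref), 0.98)
})

test_that("classifier model round-trips through JSON", {
  model <- new("SfselectModel", w = rnorm(20), b = -0.2, cost = 2, bins = 20L,
               metadata = list(seed = 5, note = "fixture"))
  p <- tempfile(fileext = ".json")
  writeSfselectModel(model, p)
  back <- readSfselectModel(p)
  expect_equal(back@w, model@w)
  expect_equal(back@b, model@b)
  expect_equal(back@metadata$seed, 5)
})

test_that("training on simulated sweeps ranks held-out sweeps above neutral", {
  # scaled-down grid; AUC on held-out windows must exceed 0.9
  tr <- sfsTrainingSim()
  model <- trainSfselect(tr$neutral, tr$swept, C = 1,
                         metadata = tr$metadata)
  dem <- buildDemography("constant", Ne = 10000)
  heldS <- t(vapply(1:12, function(i) {
    sp <- SweepParams(0.02, fixationTime(0.02, 10000), 5e4)
    h <- simulateSweep(dem, sp, nHap = 46, L = 1e5,
                       seed = childSeed(555, i))
    as.numeric(windowSfsFeature(h, c(35000, 65000)))
  }, numeric(20)))
  heldN <- t(vapply(1:12, function(i) {
    h <- simulateNeutral(dem, nHap = 46, L = 1e5,
                         seed = childSeed(556, i))$haps
    as.numeric(windowSfsFeature(h, c(35000, 65000)))
  }, numeric(20)))
  sS <- scoreWindows(heldS, model)$score
  sN <- scoreWindows(heldN, model)$score
  auc <- mean(outer(sS, sN, ">") + 0.5 * outer(sS, sN, "=="))
  expect_gt(auc, 0.9)
  # monotone enrichment: swept windows score higher on average
  expect_gt(mean(sS), mean(sN))
})
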