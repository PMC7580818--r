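#' @include genome_io.R
NULL

#' Windowed site-frequency-spectrum feature
#'
#' Histogram of derived allele frequencies of the segregating sites in a
#' window, over `bins` equal-width bins spanning (0, 1), normalized to
#' sum to 1. Windows without segregating sites yield a flagged zero
#' vector (`empty = TRUE`).
#'
#' @param haps a [HaplotypeSet-class].
#' @param window a single window from [makeWindows()] (or a length-2
#'   numeric `c(start0, end0)`, half-open bp).
#' @param bins number of frequency bins.
#' @return numeric feature vector of length `bins`, with attributes
#'   `nSnps` and `empty`.
#' @export
windowSfsFeature <- function(haps, window, bins = 20) {
  if (is(window, "GRanges")) {
    start0 <- start(window)[1] - 1; end0 <- end(window)[1]
  } else {
    start0 <- window[1]; end0 <- window[2]
  }
  p <- derivedFreq(haps)
  pos <- positions(haps)
  sel <- pos >= start0 & pos < end0 & !is.nan(p) & p > 0 & p < 1
  .sfsHist(p[sel], bins)
}

.sfsHist <- function(p, bins) {
  edges <- seq(0, 1, length.out = bins + 1)
  cnt <- tabulate(pmin(pmax(findInterval(p, edges, rightmost.closed = TRUE),
                            1L), bins), nbins = bins)
  n <- length(p)
  x <- if (n > 0) cnt / n else rep(0, bins)
  attr(x, "nSnps") <- n
  attr(x, "empty") <- n == 0
  x
}

#' SFS feature matrix for a set of windows
#'
#' @inheritParams windowSfsFeature
#' @param windows [GenomicRanges::GRanges] of windows.
#' @return matrix `length(windows) x bins`; attributes `nSnps` (integer
#'   vector) and `empty` (logical vector).
#' @export
sfsFeatureMatrix <- function(haps, windows, bins = 20) {
  p <- derivedFreq(haps)
  pos <- positions(haps)
  seg <- !is.nan(p) & p > 0 & p < 1
  X <- matrix(0, nrow = length(windows), ncol = bins)
  nSnps <- integer(length(windows))
  for (i in seq_along(windows)) {
    sel <- seg & pos >= (start(windows)[i] - 1) & pos < end(windows)[i]
    f <- .sfsHist(p[sel], bins)
    X[i, ] <- f
    nSnps[i] <- attr(f, "nSnps")
  }
  attr(X, "nSnps") <- nSnps
  attr(X, "empty") <- nSnps == 0
  X
}

# soft-margin linear SVM via smoothed (squared) hinge loss:
#   min_w,b 0.5 ||w||^2 + C sum_i max(0, 1 - y_i (w.x_i + b))^2
# deterministic, solved with BFGS from the origin
.svmFit <- function(X, y, C) {
  d <- ncol(X)
  obj <- function(th) {
    w <- th[seq_len(d)]; b <- th[d + 1]
    m <- pmax(0, 1 - y * (drop(X %*% w) + b))
    0.5 * sum(w^2) + C * sum(m^2)
  }
  grad <- function(th) {
    w <- th[seq_len(d)]; b <- th[d + 1]
    m <- pmax(0, 1 - y * (drop(X %*% w) + b))
    gw <- w - 2 * C * drop(crossprod(X, y * m))
    gb <- -2 * C * sum(y * m)
    c(gw, gb)
  }
  fit <- stats::optim(rep(0, d + 1), obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  list(w = fit$par[seq_len(d)], b = fit$par[d + 1])
}

#' Train an SFselect-style window classifier
#'
#' Fits a soft-margin linear support-vector classifier separating
#' neutral-simulation window SFS features from selected-simulation
#' features (all sweep grid points pooled into one class). The decision
#' value `w.x + b` is the window selection score; positive scores lean
#' "swept". Training is deterministic given its inputs.
#'
#' @param neutral,swept feature matrices (rows = windows) from
#'   [sfsFeatureMatrix()]; both classes must be non-empty and share the
#'   bin count.
#' @param C soft-margin regularization strength.
#' @param metadata optional list recording the training grid
#'   (`s`/`tau` combinations, replicate counts, seed) for provenance.
#' @return an [SfselectModel-class].
#' @export
trainSfselect <- function(neutral, swept, C = 1, metadata = list()) {
  neutral <- as.matrix(neutral); swept <- as.matrix(swept)
  if (nrow(neutral) == 0 || nrow(swept) == 0)
    stop("both classes must be non-empty")
  if (ncol(neutral) != ncol(swept))
    stop("feature dimensions differ between classes")
  X <- rbind(neutral, swept)
  y <- c(rep(-1, nrow(neutral)), rep(1, nrow(swept)))
  fit <- .svmFit(X, y, C)
  md <- utils::modifyList(
    list(nNeutral = nrow(neutral), nSwept = nrow(swept), C = C),
    metadata)
  new("SfselectModel", w = fit$w, b = fit$b, cost = as.numeric(C),
      bins = ncol(X), metadata = md)
}

#' Score windows with a trained classifier
#'
#' Exact linear decision values `w.x + b` for each feature row.
#'
#' @param features feature matrix (or single feature vector) whose
#'   column count matches the model's bin count.
#' @param model an [SfselectModel-class].
#' @return data.frame with columns `score` and `empty` (windows whose
#'   feature was a flagged zero vector; their score equals the bias `b`).
#' @export
scoreWindows <- function(features, model) {
  stopifnot(is(model, "SfselectModel"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (ncol(features) != model@bins)
    stop("feature length ", ncol(features), " does not match model bins ",
         model@bins)
  empty <- attr(features, "empty")
  if (is.null(empty)) empty <- rowSums(features != 0) == 0
  data.frame(score = drop(features %*% model@w) + model@b, empty = empty)
}

#' Save / load a classifier as JSON
#'
#' Plain-text serialization of weights, bias and training metadata.
#' @param model an [SfselectModel-class].
#' @param path file path.
#' @return `readSfselectModel`: the model; `writeSfselectModel`: the
#'   path, invisibly.
#' @export
writeSfselectModel <- function(model, path) {
  stopifnot(is(model, "SfselectModel"))
  jsonlite::write_json(
    list(w = model@w, b = model@b, C = model@cost, bins = model@bins,
         metadata = model@metadata),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeSfselectModel
#' @export
readSfselectModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("SfselectModel", w = as.numeric(x$w), b = as.numeric(x$b),
      cost = as.numeric(x$C), bins = as.integer(x$bins),
      metadata = as.list(x$metadata))
}

#' Simulate a training set for the window classifier
#'
#' Simulates neutral and hard-sweep windows under a constant-size
#' demography and extracts the central 30 kb SFS feature of each
#' replicate. The sweep grid is a scaled-down stand-in for an extensive
#' (s, tau) grid: by default 4 selection coefficients crossed with 5
#' times-under-selection expressed as fractions of the deterministic
#' fixation time.
#'
#' @param Ne diploid effective size of the training demography.
#' @param nHap haplotypes per replicate.
#' @param sGrid selection coefficients.
#' @param tauFrac times under selection, as fractions of the
#'   deterministic fixation time for each `s`.
#' @param repsPerCombo sweep replicates per (s, tau) grid point.
#' @param nNeutral neutral replicates.
#' @param L replicate region length in bp (feature taken from the central
#'   30 kb window).
#' @param bins SFS feature bins.
#' @param mu,r mutation/recombination rates.
#' @param seed root seed; per-replicate seeds are derived from it.
#' @return list with feature matrices `neutral` and `swept`, plus
#'   `metadata` describing the grid.
#' @export
simulateSfselectTraining <- function(Ne = 14474, nHap = 46,
                                     sGrid = c(0.01, 0.02, 0.05, 0.1),
                                     tauFrac = c(0.25, 0.5, 0.75, 1, 1.25),
                                     repsPerCombo = 3, nNeutral = 60,
                                     L = 1e5, bins = 20, mu = 1.25e-8,
                                     r = 1e-8, seed = 1) {
  model <- buildDemography("constant", Ne = Ne)
  mid <- c(L / 2 - 15000, L / 2 + 15000)
  feat <- function(haps) as.numeric(windowSfsFeature(haps, mid, bins))
  neutral <- matrix(0, nNeutral, bins)
  k <- 0L
  for (i in seq_len(nNeutral)) {
    sim <- simulateNeutral(model, nHap = nHap, L = L, mu = mu, r = r,
                           seed = childSeed(seed, i), tracts = FALSE)
    neutral[i, ] <- feat(sim$haps)
  }
  grid <- expand.grid(s = sGrid, tauFrac = tauFrac)
  grid$tau <- grid$tauFrac * fixationTime(grid$s, Ne)
  swept <- matrix(0, nrow(grid) * repsPerCombo, bins)
  row <- 0L
  for (g in seq_len(nrow(grid))) {
    for (rep in seq_len(repsPerCombo)) {
      row <- row + 1L
      sp <- SweepParams(s = grid$s[g], tau = grid$tau[g], position = L / 2)
      haps <- simulateSweep(model, sp, nHap = nHap, L = L, mu = mu, r = r,
                            seed = childSeed(seed, 10000 + row))
      swept[row, ] <- feat(haps)
    }
  }
  list(neutral = neutral, swept = swept,
       metadata = list(Ne = Ne, nHap = nHap, grid = grid,
                       repsPerCombo = repsPerCombo, nNeutral = nNeutral,
                       L = L, bins = bins, seed = seed))
}
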