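#' @include calibrate.R sfs.R ancestry.R
NULL

#' Shared-signal matrix across populations
#'
#' Counts, for every pair of populations, the candidate 30 kb windows
#' shared between their scans; the diagonal holds each population's own
#' candidate count. Windows are compared by exact identity
#' (chrom, start, end), so all scans must use the same window grid.
#'
#' @param candidates named list of [GenomicRanges::GRanges] candidate
#'   window sets (one per population), all built from the same
#'   [makeWindows()] grid.
#' @return symmetric integer matrix with population names as dimnames.
#' @export
sharedSignalMatrix <- function(candidates) {
  stopifnot(is.list(candidates), length(candidates) >= 1)
  pops <- names(candidates)
  if (is.null(pops)) pops <- paste0("pop", seq_along(candidates))
  key <- function(gr) {
    if (!length(gr)) return(character())
    if (length(unique(width(gr))) > 1)
      stop("candidate sets use different window grids (mixed widths)")
    sprintf("%s:%d-%d", as.character(seqnames(gr)), start(gr), end(gr))
  }
  keys <- lapply(candidates, key)
  n <- length(keys)
  m <- matrix(0L, n, n, dimnames = list(pops, pops))
  for (i in seq_len(n)) for (j in i:n) {
    m[i, j] <- m[j, i] <-
      if (i == j) length(keys[[i]])
      else length(intersect(keys[[i]], keys[[j]]))
  }
  m
}

.defaultPipelineConfig <- function() {
  list(
    populations = list(
      list(name = "admixed_demo", preset = "afroasiatic"),
      list(name = "unadmixed_demo", preset = "gumuz")
    ),
    L = 4e6, nRepScan = 1, nRepNull = 2, mu = 1.25e-8, r = 1e-8,
    windowSize = 30000, windowStep = 25000,
    mafThreshold = 0.05, maxGap = 20000, minEhh = 0.05,
    q = 99.9, sfsBins = 20,
    training = list(nNeutral = 12, repsPerCombo = 1,
                    sGrid = c(0.02, 0.05), tauFrac = c(0.5, 1)),
    refDiploids = 12, blockSize = 20, smoothK = 21,
    enrichResamples = 10000
  )
}

#' Run the full scan pipeline on simulated populations
#'
#' Orchestrates, for each configured population: neutral-simulation
#' calibration of the class thresholds (admixed vs unadmixed; cached as
#' JSON in `outDir`), data simulation, SFS-classifier and iHS window
#' scans, candidate calling, and — for admixed populations — local
#' ancestry assignment against simulated reference panels, masking,
#' the ancestry-enrichment resampling test and unbalanced-ancestry
#' regions. Writes scores (TSV), candidates (BED), thresholds and
#' enrichment (JSON), the shared-signal matrix (TSV) and a run log.
#' Deterministic given `(config, seed)`; all stage seeds derive from the
#' root seed via [childSeed()].
#'
#' @param config list overriding entries of the default demo
#'   configuration (see Details in the vignette); `NULL` for defaults.
#' @param outDir output directory (created if needed).
#' @param seed root seed.
#' @param verbose log progress to the console as well as the log file.
#' @return invisibly, a list with per-population results, thresholds and
#'   the shared-signal matrices.
#' @export
runPipeline <- function(config = NULL, outDir = tempfile("admixscan_run"),
                        seed = 1, verbose = FALSE) {
  cfg <- .defaultPipelineConfig()
  if (!is.null(config)) {
    # the populations entry is an unnamed list, which modifyList would
    # silently ignore: replace it wholesale
    if (!is.null(config$populations)) {
      cfg$populations <- config$populations
      config$populations <- NULL
    }
    cfg <- utils::modifyList(cfg, config)
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(outDir, "run.log")
  logLines <- character()
  say <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    logLines <<- c(logLines, line)
    if (verbose) message(line)
  }
  say("pipeline start: seed=%d L=%g q=%g", seed, cfg$L, cfg$q)

  classes <- unique(vapply(cfg$populations, function(p)
    if (p$preset == "afroasiatic") "admixed" else "unadmixed", ""))

  # --- classifier (shared across classes) -------------------------------
  modelPath <- file.path(outDir, "sfselect_model.json")
  if (file.exists(modelPath)) {
    svm <- readSfselectModel(modelPath)
    say("sfselect model loaded from cache")
  } else {
    tr <- do.call(simulateSfselectTraining, c(
      cfg$training,
      list(bins = cfg$sfsBins, seed = childSeed(seed, 101))))
    svm <- trainSfselect(tr$neutral, tr$swept, C = 1,
                         metadata = tr$metadata)
    writeSfselectModel(svm, modelPath)
    say("sfselect model trained: %d neutral / %d swept windows",
        nrow(tr$neutral), nrow(tr$swept))
  }

  # --- per-class neutral thresholds (cached) ----------------------------
  thrPath <- file.path(outDir, "thresholds.json")
  if (file.exists(thrPath)) {
    thresholds <- jsonlite::read_json(thrPath, simplifyVector = TRUE)$thresholds
    say("thresholds loaded from cache")
  } else {
    thresholds <- do.call(rbind, lapply(classes, function(cl) {
      dem <- buildDemography(if (cl == "admixed") "afroasiatic" else "gumuz")
      say("calibrating class '%s' (%d x %g bp)", cl, cfg$nRepNull, cfg$L)
      null <- ihsNeutralNull(dem, nRep = cfg$nRepNull, L = cfg$L,
                             mu = cfg$mu, r = cfg$r,
                             seed = childSeed(seed, 201 + match(cl, classes)),
                             mafThreshold = cfg$mafThreshold,
                             maxGap = cfg$maxGap, minEhh = cfg$minEhh,
                             windowSize = cfg$windowSize,
                             windowStep = cfg$windowStep)
      wins <- makeWindows(cfg$L, cfg$windowSize, cfg$windowStep)
      sfsScores <- unlist(lapply(seq_len(cfg$nRepNull), function(i) {
        sim <- simulateNeutral(dem, L = cfg$L, mu = cfg$mu, r = cfg$r,
                               seed = childSeed(seed, 301 + i +
                                                  10 * match(cl, classes)),
                               tracts = FALSE)
        X <- sfsFeatureMatrix(sim$haps, wins, cfg$sfsBins)
        sc <- scoreWindows(X, svm)
        sc$score[!sc$empty]
      }))
      rbind(
        percentileThreshold(null$snpAbsIhs, cfg$q, "ihs_snp", cl),
        percentileThreshold(null$windowMeanAbsIhs, cfg$q, "ihs_window", cl),
        percentileThreshold(sfsScores, cfg$q, "sfselect", cl))
    }))
    jsonlite::write_json(
      list(thresholds = thresholds,
           provenance = list(seed = seed, L = cfg$L, nRep = cfg$nRepNull,
                             q = cfg$q,
                             percentile = "linear interpolation (type 7)")),
      thrPath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("thresholds written to %s", thrPath)
  }

  # --- per-population scans --------------------------------------------
  wins <- makeWindows(cfg$L, cfg$windowSize, cfg$windowStep)
  results <- list()
  for (pi in seq_along(cfg$populations)) {
    p <- cfg$populations[[pi]]
    cl <- if (p$preset == "afroasiatic") "admixed" else "unadmixed"
    dem <- buildDemography(p$preset)
    admixed <- nrow(dem@pulses) > 0
    say("scanning population '%s' (%s, class %s)", p$name, p$preset, cl)
    samples <- NULL
    if (admixed) {
      samples <- c(dem@samplePops,
                   stats::setNames(rep(cfg$refDiploids, 2), c("AFR", "EUR")))
    }
    sim <- simulateNeutral(dem, L = cfg$L, mu = cfg$mu, r = cfg$r,
                           seed = childSeed(seed, 401 + pi),
                           samples = samples, tracts = admixed)
    haps <- sim$haps
    targetPop <- names(dem@samplePops)[1]
    target <- if (admixed)
      haps[which(sim$sampleInfo$population == targetPop), ] else haps

    # SFS scan
    X <- sfsFeatureMatrix(target, wins, cfg$sfsBins)
    sfs <- scoreWindows(X, svm)
    sfsWins <- wins
    mcols(sfsWins)$score <- ifelse(sfs$empty, NA, sfs$score)

    # iHS scan
    rec <- ihsScan(target, cfg$mafThreshold, cfg$maxGap, cfg$minEhh)
    rec <- standardizeIhs(rec)
    ihsWins <- windowIhs(rec, wins)

    thr <- as.data.frame(thresholds)
    getThr <- function(stat) thr[thr$statistic == stat &
                                   thr$popClass == cl, , drop = FALSE]
    candSfs <- callCandidates(sfsWins, getThr("sfselect"), "score")
    candIhs <- callCandidates(ihsWins, getThr("ihs_window"), "meanAbsIhs")
    say("  %d sfselect and %d iHS candidate windows (class %s thresholds)",
        length(candSfs), length(candIhs), cl)

    base <- file.path(outDir, p$name)
    utils::write.table(rec, paste0(base, "_ihs_records.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(wid = mcols(wins)$wid, sfselect = mcols(sfsWins)$score,
                 meanAbsIhs = mcols(ihsWins)$meanAbsIhs,
                 maxAbsIhs = mcols(ihsWins)$maxAbsIhs,
                 maxNegLogP = mcols(ihsWins)$maxNegLogP,
                 nSnps = mcols(ihsWins)$nSnps),
      paste0(base, "_window_scores.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    writeBed(candSfs, paste0(base, "_candidates_sfselect.bed"))
    writeBed(candIhs, paste0(base, "_candidates_ihs.bed"))

    res <- list(name = p$name, class = cl, windows = wins,
                sfsWindows = sfsWins, ihsWindows = ihsWins,
                candidates = list(sfselect = candSfs, ihs = candIhs),
                records = rec)

    # ancestry analyses for admixed populations
    if (admixed) {
      # local ancestry runs on common variants across target + panels
      common <- mafFilter(haps, cfg$mafThreshold)
      targetC <- common[which(sim$sampleInfo$population == targetPop), ]
      refA <- common[which(sim$sampleInfo$population == "AFR"), ]
      refB <- common[which(sim$sampleInfo$population == "EUR"), ]
      asg <- assignLocalAncestry(targetC, refA, refB,
                                 blockSize = cfg$blockSize,
                                 smoothK = cfg$smoothK)
      masked <- maskAncestry(targetC, asg, "WEA")
      track <- ancestryTrack(masked, wins)
      gw <- ancestryProportion(masked)
      say("  genome-wide West-Eurasian fraction: %.3f", gw)
      enr <- list()
      for (statName in names(res$candidates)) {
        cand <- res$candidates[[statName]]
        selIdx <- which(!is.na(S4Vectors::match(wins, cand)))
        if (length(selIdx) && sum(!is.na(mcols(track)$fraction)) >
              length(selIdx)) {
          enr[[statName]] <- enrichmentResampling(
            mcols(track)$fraction, selIdx, n = cfg$enrichResamples,
            seed = childSeed(seed, 501 + pi))
        }
      }
      regions <- tryCatch(unbalancedRegions(track), error = function(e) {
        say("  unbalanced-region call skipped: %s", conditionMessage(e))
        GRanges()
      })
      utils::write.table(
        data.frame(wid = mcols(wins)$wid,
                   fraction = mcols(track)$fraction),
        paste0(base, "_ancestry_track.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      if (length(regions)) writeBed(regions,
                                    paste0(base, "_unbalanced.bed"))
      jsonlite::write_json(
        list(genomeWide = gw,
             enrichment = lapply(enr, function(e) list(
               observed = e@observed, nullMean = e@nullMean,
               nullSd = e@nullSd, p = e@p, n = e@nResamples))),
        paste0(base, "_ancestry.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
      res$ancestry <- list(assignment = asg, masked = masked,
                           track = track, genomeWide = gw,
                           enrichment = enr, unbalanced = regions)
    }
    results[[p$name]] <- res
  }

  shared <- lapply(c(sfselect = "sfselect", ihs = "ihs"), function(st)
    sharedSignalMatrix(lapply(results, function(r) r$candidates[[st]])))
  for (st in names(shared))
    utils::write.table(shared[[st]],
                       file.path(outDir, paste0("shared_", st, ".tsv")),
                       sep = "\t", quote = FALSE)
  say("pipeline done")
  writeLines(logLines, logFile)
  invisible(list(results = results, thresholds = thresholds,
                 shared = shared, outDir = outDir,
                 classifier = svm))
}
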