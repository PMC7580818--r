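#' @include AllClasses.R
NULL

# Three-population out-of-Africa parameter set (Gravel et al. 2011 values,
# generation time 25 y): ancestral expansion, out-of-Africa bottleneck,
# European/Asian split with exponential growth, continuous migration.
.gravelPopulations <- function(eastAfricanBranch = FALSE) {
  pops <- data.frame(
    name = c("AFR", "EUR", "ASN", "OOA"),
    size = c(14474, 1032 * exp(0.0038 * 920), 554 * exp(0.0048 * 920), 1861),
    growth = c(0, 0.0038, 0.0048, 0),
    active = c(TRUE, TRUE, TRUE, FALSE),  # OOA exists only as an ancestor
    stringsAsFactors = FALSE
  )
  if (eastAfricanBranch)
    pops <- rbind(data.frame(name = "EAFR", size = 14474, growth = 0,
                             active = TRUE), pops)
  pops
}

.gravelEvents <- function(eastAfricanBranch = FALSE, splitTime = 300) {
  ev <- data.frame(
    type = c("split", "migration_change", "split", "size_change"),
    time = c(920, 920, 2040, 5920),
    pop1 = c("EUR,ASN", "AFR", "OOA", "AFR"),
    pop2 = c("OOA", "OOA", "AFR", ""),
    rate = c(NA, 15e-5, NA, NA),
    size = c(NA, NA, NA, 7310),
    growth = c(NA, NA, NA, 0),
    stringsAsFactors = FALSE
  )
  if (eastAfricanBranch)
    ev <- rbind(data.frame(type = "split", time = splitTime, pop1 = "EAFR",
                           pop2 = "AFR", rate = NA, size = NA, growth = NA),
                ev)
  ev[order(ev$time), ]
}

.gravelMigrations <- function() {
  data.frame(a = c("AFR", "AFR", "EUR"),
             b = c("EUR", "ASN", "ASN"),
             rate = c(2.5e-5, 0.78e-5, 3.11e-5),
             stringsAsFactors = FALSE)
}

.ancestryLabels <- c(AFR = "AFR", EAFR = "AFR", EUR = "WEA", ASN = "WEA",
                     OOA = "WEA")

#' Describe a single-generation admixture pulse
#'
#' Forward-time convention: at `time` generations before present, the
#' `dest` population receives a fraction `fraction` of its ancestry from
#' `source` in a single generation.
#'
#' @param fraction admixture fraction in \[0, 1\].
#' @param time generations before present (> 0).
#' @param source,dest population names.
#' @return one-row data.frame usable as the `pulses` slot.
#' @export
admixturePulse <- function(fraction, time = 104, source = "EUR",
                           dest = "EAFR") {
  if (fraction < 0 || fraction > 1)
    stop("admixture fraction must lie in [0, 1]")
  if (time <= 0) stop("pulse time must be > 0")
  data.frame(time = time, source = source, dest = dest, fraction = fraction,
             stringsAsFactors = FALSE)
}

#' Build a demographic model
#'
#' Resolves a named preset into a full [DemographicModel-class]:
#'
#' * `"gumuz"` — unadmixed East African population: the three-population
#'   out-of-Africa demography, sampling the African population
#'   (no admixture pulse).
#' * `"afroasiatic"` — admixed East African population: the same
#'   demography plus an East African branch that receives a single
#'   West-Eurasian pulse (default fraction 0.54) 2,600 years ago,
#'   i.e. 104 generations at 25 years per generation.
#' * `"constant"` — a single constant-size population (for sweep
#'   simulation, classifier training and oracle tests).
#'
#' @param preset preset name.
#' @param pulseFraction West-Eurasian admixture fraction for the
#'   `"afroasiatic"` preset (0 drops the pulse entirely).
#' @param admixtureYears age of the pulse in years.
#' @param generationTime years per generation used to convert to
#'   generations (default 25, giving 104 generations).
#' @param Ne diploid size for the `"constant"` preset.
#' @param splitTime generations before present at which the admixed East
#'   African branch splits from the African population.
#' @return a [DemographicModel-class].
#' @examples
#' buildDemography("afroasiatic")  # pulse f = 0.54 at 104 generations
#' buildDemography("gumuz")
#' @export
buildDemography <- function(preset = c("gumuz", "afroasiatic", "constant"),
                            pulseFraction = 0.54, admixtureYears = 2600,
                            generationTime = 25, Ne = 10000,
                            splitTime = 300) {
  preset <- match.arg(preset)
  emptyEvents <- .gravelEvents()[0, ]
  if (preset == "constant") {
    if (Ne <= 0) stop("Ne must be > 0")
    return(new("DemographicModel",
               populations = data.frame(name = "POP", size = Ne, growth = 0,
                                        active = TRUE,
                                        stringsAsFactors = FALSE),
               events = emptyEvents,
               migrations = .gravelMigrations()[0, ],
               pulses = admixturePulse(1, 1)[0, ],
               ancestryLabels = c(POP = "AFR"),
               samplePops = c(POP = 23L),
               name = "constant"))
  }
  admixed <- preset == "afroasiatic"
  tAdm <- round(admixtureYears / generationTime)
  if (admixed && (pulseFraction < 0 || pulseFraction > 1))
    stop("pulseFraction must lie in [0, 1]")
  # a zero-fraction pulse is dropped outright so the model (and the RNG
  # stream of the backend) is identical to the no-pulse model
  pulses <- if (admixed && pulseFraction > 0)
    admixturePulse(pulseFraction, tAdm) else admixturePulse(1, 1)[0, ]
  new("DemographicModel",
      populations = .gravelPopulations(eastAfricanBranch = admixed),
      events = .gravelEvents(eastAfricanBranch = admixed,
                             splitTime = splitTime),
      migrations = .gravelMigrations(),
      pulses = pulses,
      ancestryLabels = .ancestryLabels,
      samplePops = if (admixed) c(EAFR = 24L) else c(AFR = 23L),
      name = preset)
}

# serialize a DemographicModel into the JSON structure the msprime
# backend script understands
.demographyToList <- function(model, census = NULL) {
  ev <- model@events
  events <- lapply(seq_len(nrow(ev)), function(i) {
    e <- ev[i, ]
    switch(e$type,
      split = list(type = "split", time = e$time,
                   derived = as.list(strsplit(e$pop1, ",")[[1]]),
                   ancestral = e$pop2),
      migration_change = list(type = "migration_change", time = e$time,
                              a = e$pop1, b = e$pop2, rate = e$rate),
      size_change = list(type = "size_change", time = e$time,
                         population = e$pop1, size = e$size,
                         growth = e$growth),
      stop("unknown event type ", e$type))
  })
  pu <- model@pulses
  events <- c(events, lapply(seq_len(nrow(pu)), function(i) {
    list(type = "pulse", time = pu$time[i], source = pu$source[i],
         dest = pu$dest[i], fraction = pu$fraction[i])
  }))
  migrations <- lapply(seq_len(nrow(model@migrations)), function(i) {
    m <- model@migrations[i, ]
    list(a = m$a, b = m$b, rate = m$rate)
  })
  pops <- lapply(seq_len(nrow(model@populations)), function(i) {
    p <- model@populations[i, ]
    out <- list(name = p$name, size = p$size, growth = p$growth)
    if ("active" %in% names(p)) out$active <- p$active
    out
  })
  out <- list(populations = pops, migrations = migrations, events = events,
              ancestry_labels = as.list(model@ancestryLabels))
  if (!is.null(census)) out$census_time <- census
  out
}

#' Deterministic selection trajectory helpers
#'
#' `logisticFrequency()` gives the derived-allele frequency after `tau`
#' generations of additive selection with per-copy advantage `s`, starting
#' from a single copy (frequency 1/(2N)); it is the closed-form solution
#' of dx/dt = s x (1 - x). `fixationTime()` gives the time for that
#' trajectory to reach 1 - 1/(2N).
#'
#' @param s selection coefficient (per-copy advantage).
#' @param tau generations under selection.
#' @param Ne diploid effective size.
#' @return a frequency in (0, 1), or a time in generations.
#' @export
logisticFrequency <- function(s, tau, Ne) {
  x0 <- 1 / (2 * Ne)
  if (s <= 0 || tau <= 0) return(x0)
  odds <- x0 / (1 - x0) * exp(s * tau)
  odds / (1 + odds)
}

#' @rdname logisticFrequency
#' @export
fixationTime <- function(s, Ne) 2 * log(2 * Ne - 1) / s
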