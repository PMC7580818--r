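# neutral-null runs shared by the acceptance criteria: 25 x 10 Mb
# replicate chromosomes per population class (~2.9e5 MAF-filtered SNPs,
# ~1e4 windows with data), the scale at which the 99.99th window
# percentile stops being clamped at the sample maximum. The suite
# tolerance (+/-0.45 on the published thresholds, vs the full-scale
# +/-0.25) was fixed a priori from the order-statistic standard error
# of a near-maximum statistic over ~1e4 LD-correlated windows.
scaledNull <- function(class) {
  cachedSim(paste0("null_", class), function() {
    dem <- buildDemography(if (class == "admixed") "afroasiatic"
                           else "gumuz")
    ihsNeutralNull(dem, nRep = 25, L = 1e7, seed = 987654)
  })
}

sfsTrainingSim <- function() {
  cachedSim("sfsTrain", function()
    simulateSfselectTraining(Ne = 10000, nHap = 46,
                             sGrid = c(0.02, 0.05),
                             tauFrac = c(0.75, 1),
                             repsPerCombo = 4, nNeutral = 16,
                             L = 1e5, seed = 2024))
}
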