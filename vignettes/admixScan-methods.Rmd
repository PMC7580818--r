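---
title: "Simulation-calibrated selection scans in admixed populations"
author: "admixScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation-calibrated selection scans in admixed populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Genome scans for recent positive selection compare a statistic computed
along the genome with the range of values that neutral evolution alone
would produce. In admixed populations — here, East African populations
that received a large West-Eurasian ancestry pulse roughly 2,600 years
ago — this comparison is treacherous twice over: admixture itself
distorts haplotype structure and the site frequency spectrum (inflating
false positives if the null model ignores it), and post-admixture
selection can act on the introduced ancestry itself, which a
haplotype-based scan will not see as a classic sweep. admixScan
implements the full workflow for this setting:

1. **Two windowed scan statistics** — an SFselect-style linear
   support-vector score on the windowed site frequency spectrum (old,
   near-complete sweeps) and the integrated haplotype score iHS
   (recent, incomplete sweeps) — on 30 kb windows laid every 25 kb, so
   adjacent windows share 5 kb.
2. **Simulation-calibrated critical values**: the 99.99th percentile of
   each statistic under a neutral coalescent model of the population's
   own demography, with *separate thresholds for admixed and unadmixed
   population classes*.
3. **Local-ancestry masking**: block-wise assignment of each haplotype
   segment to African or West-Eurasian ancestry against surrogate
   reference panels, masking of the West-Eurasian component,
   ancestry-proportion tracks, a resampling test for ancestry
   enrichment among selected windows, and detection of regions whose
   local ancestry is unbalanced relative to the genome-wide admixture
   fraction.

Everything is exercised end-to-end on synthetic data; the package
contains no real genotypes.

# The iHS statistic

For a biallelic core SNP, the extended haplotype homozygosity at
distance $d$, for carriers of one core allele, is the probability that
two randomly drawn carriers are identical over the whole interval from
the core to $d$:
$$\mathrm{EHH}(d) = \frac{\sum_g \binom{n_g}{2}}{\binom{n_c}{2}},$$
where the $n_g$ count carriers sharing the same extended haplotype and
$n_c$ is the carrier count at the core. Integrating the EHH decay curve
against *physical* distance (no genetic map is assumed) on both sides
gives iHH for the ancestral and derived allele, and
$\mathrm{uiHS} = \ln(\mathrm{iHH}_A / \mathrm{iHH}_D)$. Scores are
standardized to mean 0, SD 1 within derived-allele-frequency bins, so
extreme values flag cores whose haplotypes are unusually long for their
frequency. Two-sided Gaussian p-values $p = 2\Phi(-|\mathrm{iHS}|)$ are
attached as a convention (standardized scores are close to Gaussian
under neutrality).

Numerical and procedural choices:

* **EHH cutoff 0.05, gap rule 20 kb.** The curve stops once EHH falls
  below 0.05 (the crossing point is kept as the final trapezoid
  segment). If two consecutive sites during the extension are more than
  20 kb apart the side is flagged and the core is excluded from the
  statistic entirely; truncation at the chromosome end keeps the
  accumulated integral.
* **MAF filter 0.05** on cores (strictly greater), computed over
  non-missing haplotypes; the full site set still supports the
  extension.
* **Missing data** (which here means ancestry-masked data): haplotypes
  leave the numerator groups at the first missing call and stay out; the
  denominator stays fixed at the core, which keeps every EHH curve
  monotone non-increasing and biases masked-data iHH downward rather
  than upward. Cores with fewer than 20 non-missing haplotypes, or
  fewer than 2 carriers of either allele, are skipped.
* **Standardization bins**: 50 equal-width frequency bins over (0, 1),
  merged with their nearest occupied neighbour until every bin holds at
  least 10 scored SNPs; bins with zero SD are flagged and excluded. The
  population (1/n) SD is used, so a two-point bin $\{a, -a\}$
  standardizes to $\{+1, -1\}$.
* **Window summaries**: mean |iHS|, max |iHS| and max $-\log_{10} p$
  over the scored SNPs inside each 30 kb window (a SNP in the 5 kb
  overlap contributes to both windows); windows without scored SNPs are
  reported with `nSnps = 0` and NA summaries and are excluded from
  percentile computations. The window mean uses *absolute* scores; a
  signed mean would cancel opposing sweep signals.

# The SFS classifier

Each 30 kb window is summarized by the histogram of derived allele
frequencies of its segregating sites over $B = 20$ equal-width bins on
(0, 1), normalized to sum to one. A soft-margin linear support-vector
classifier is trained to separate neutral windows from windows
simulated under hard sweeps across a grid of selection coefficients $s$
and times under selection $\tau$ (all grid points pooled into one
"selected" class); the window score is the signed decision value
$w \cdot x + b$. Because no SVM solver ships with the R stack used
here, the classifier is fit in-package as L2-regularized squared-hinge
loss minimized with BFGS — deterministic given its inputs — and is
cross-checked in the test suite against an external reference SVM on a
fixture. Scores are comparable only within one trained model; for that
reason the original tool's published thresholds are *not* reproduction
targets, and the package derives its own thresholds from its own
model's neutral score distribution.

The default training grid is a scaled-down stand-in (4 values of
$s \in \{0.01, 0.02, 0.05, 0.1\}$ crossed with 5 values of $\tau$
expressed as $\{0.25, 0.5, 0.75, 1, 1.25\}$ of the deterministic
fixation time) for the original tool's much larger grid; it is
configurable and recorded in the model metadata. No MAF filter is
applied to SFS features by default (the low-frequency bins *are* the
signal); `mafFilter()` can be applied first where array-like input is
being emulated.

# The synthetic world

The simulation module stands in for controlled-access genotype data and
is first-class, tested code. It delegates coalescence to msprime
through the system Python interpreter (the engine is irrelevant to the
contract, which is on output statistics) behind a declarative
`DemographicModel`.

* **Demography**: the three-population out-of-Africa model of Gravel et
  al. (2011) — ancestral expansion 5,920 generations ago, out-of-Africa
  bottleneck 2,040 generations ago, European/Asian split 920
  generations ago with exponential growth and continuous migration —
  with times converted at 25 years per generation. The paper the
  package follows states the admixture age only as "2,600 years"; at
  25 y/gen this is the 104-generation pulse used throughout.
* **Presets**: `"gumuz"` samples 46 haplotypes from the (unadmixed)
  African population. `"afroasiatic"` adds an East African branch that
  splits from the African population 300 generations ago and receives a
  single pulse of fraction $f = 0.54$ from the European branch at 104
  generations; 48 haplotypes are sampled from it. $f$, the pulse age
  and the branch split time are configurable ($f$ spans 0.43–0.54
  across the populations being emulated); a fraction of 0 drops the
  pulse, making the model bit-identical to the unadmixed one.
* **Mutation and recombination**: $\mu = 1.25\times10^{-8}$ and
  $r = 1\times10^{-8}$ per bp per generation (the source publication is
  silent; these are standard human values), configurable.
* **Truth tracts**: a census one generation older than the pulse
  records, for every sampled haplotype, which census-time population
  each genomic segment descends from; segments tracing to the
  out-of-Africa side are labelled `WEA`, the rest `AFR`. Tract sets
  provably tile the genome and are the ground truth for the ancestry
  module's tests.
* **Sweeps**: single-population structured-coalescent sweeps
  (msprime's sweep model). Our $s$ is the per-copy (additive) fitness
  advantage; $(s, \tau)$ is mapped to the present-day allele frequency
  by the deterministic logistic trajectory
  $\dot x = s x (1 - x)$ from $x_0 = 1/2N$. Two conditioning modes are
  provided because the source publication states neither: `"frequency"`
  (the allele has reached the logistic frequency at sampling) and
  `"fixation"` (surplus time beyond the deterministic fixation time
  becomes post-fixation neutral drift). The mode and realized end
  frequency are recorded in the output metadata.

What a green test on this world does and does not establish: the
generator reproduces neutral coalescent expectations (diversity,
Tajima's D, 1/i SFS), realistic LD decay, and exact admixture ground
truth, but it has no genotyping error, no low-coverage singleton
deficit (the source data visibly had one), no phasing switch errors, a
uniform recombination map, and sequence-like rather than
array-ascertained site density. Threshold values transfer to real data
only to the extent the demographic model does.

# Calibration

Critical values are the 99.99th percentile (linear interpolation
between order statistics, `stats::quantile` type 7 — the convention is
recorded in the threshold provenance) of the statistic pooled over
neutral replicate chromosomes, separately for the admixed and unadmixed
class. iHS standardization is performed once over the pooled records of
all replicates, not per replicate. A scaled-down mode (fewer/shorter
replicates, optionally the 99.9th percentile) exists for test suites;
the widened test tolerance that goes with it (±0.45 on the published
per-SNP and window thresholds) was fixed a priori from the
order-statistic standard error at roughly $10^5$ LD-correlated SNPs.
The model-fit check compares relative derived SFS vectors (proportion
of segregating sites at each derived count) by L1 distance with
per-class differences retained, which localizes, e.g., singleton
deficits.

# Local ancestry and masking

The deconvolution is a deliberately simplified PCAdmix-style
classifier; the contract is tract-recovery accuracy on synthetic data,
not algorithmic identity with the original tool.

* The site range is cut into consecutive **20-SNP blocks** (a short
  terminal block merges into its predecessor). Within each block the
  two reference panels define a discriminant axis — the centroid
  difference standardized by the pooled per-site variance
  (regularized by +0.01). This is the principal axis *of between-panel
  variation*: the leading PC of the pooled panels, tried first, is
  dominated by within-panel linkage structure at 20-SNP scale and
  separated ancestries poorly.
* Each query haplotype projects onto the axis and takes the label of
  the nearer reference centroid; confidence is the relative margin
  $|d_{far} - d_{near}|/(d_{near} + d_{far})$, which is 0 when the
  panels do not separate (two halves of one panel behave this way) and
  approaches 1 on or beyond a centroid.
* **Smoothing**: ancestry tracts from a 104-generation-old pulse are
  hundreds of kb long (dozens of blocks), while a single 20-SNP block
  against 24-haplotype panels is individually weak. Labels are
  therefore smoothed by summing the signed, separation-normalized block
  margins (clipped to ±3) over 21 adjacent blocks and taking the sign —
  a soft, confidence-weighted majority vote. 21 blocks of common SNPs
  span roughly a third of a typical tract. A hard 3-block majority vote
  was tried first and plateaued near 74% block accuracy; the soft
  21-block vote exceeds 90%, which is the module's acceptance bar.
* **Common variants only**: assignment should run on jointly
  MAF-filtered (> 0.05) data. Rare variants — the majority of
  sequence-simulated sites — carry almost no ancestry information and
  dilute the blocks; the original workflow ran on genotyping-array
  sites, which are ascertained common.

Masking sets every allele in a `WEA`-labelled block to missing and
records the per-SNP masked fraction; the ancestry proportion of any
region is the mean per-SNP masked fraction over the SNPs in it. The
enrichment test draws `|selected|` windows from the genome-wide window
set $10^5$ times **without replacement** (with-replacement is available
behind a flag; the source publication is silent), and reports the
one-sided empirical p-value with the $(+1)/(n+1)$ correction, so
$p \in [1/(n+1), 1]$.

**Unbalanced-ancestry regions**: the source publication reports
"significant deviations" without defining them. Here a window is
extreme when its ancestry fraction leaves the central 99.9% band
`median ± z·MAD` of the genome-wide per-window fractions. The robust
band is essential: an empirical-quantile band would be widened by
exactly the anomalous regions it is meant to flag (a 0.6 Mb run of
near-zero West-Eurasian ancestry is >10% of a short test track).
Maximal same-side runs of extreme windows are reported only when they
span at least 0.5 Mb — the scale of the chromosome-17 example that
motivates the operation.

# The pipeline

`runPipeline()` wires the stages together for a configured set of
simulated populations: classifier training and per-class threshold
calibration (both cached as JSON in the output directory — deleting the
cache forces recalibration with bit-identical results under the same
seed), per-population SFS and iHS window scans, candidate calling with
the class-appropriate thresholds, ancestry masking/enrichment for
admixed populations, and the cross-population shared-window matrix
(exact window identity). All randomness derives from one root seed via
`childSeed()`, and every stage parameter lands in the run log. The
package exposes this as R functions rather than a shell dispatcher;
the functions and this vignette are the orchestration interface.

# Known limitations

* Thresholds are as good as the demographic model; none of the
  parameters are re-inferred from data.
* The sweep simulator is single-population; swept training windows do
  not model admixture or migration (their SFS signature, not their
  demographic context, is what the classifier consumes).
* The ancestry classifier is two-way, assumes phased error-free
  haplotypes, and leaves no blocks unassigned (the original tool's
  posterior threshold could), so masked fractions estimate the pulse
  fraction, not a lower bound on it.
* p-values for iHS are a Gaussian convention, not a calibrated error
  rate; the simulation-derived percentile thresholds are the inferential
  instrument.
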