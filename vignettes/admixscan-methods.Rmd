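---
title: "Methods: admixture inference and post-admixture selection scans"
author: "admixscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: admixture inference and post-admixture selection scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixscan)
```

# Scope and model

`admixscan` analyses a two-way admixed population — the motivating system is
an Austronesian-speaking population of the Solomon Islands whose genomes mix
a Papuan-related and an Asian-related ancestry — through five connected
stages: (i) detecting admixture with f-statistics, (ii) estimating the
mixture proportion with an F4 ratio, (iii) dating the pulse from the decay
of ancestry-weighted LD, (iv) scanning the genome for local-ancestry excess
against a neutral coalescent null, and (v) scanning phased haplotypes for
recent positive selection with EHH/iHS.  A built-in
coalescent-with-recombination engine and a tract-copying admixture generator
provide synthetic data with known truth for every stage.

Throughout, coordinates are 1-based inclusive and region length is
`end − start` bp; missing genotypes are `NA`, never 0, because a dosage of 0
is informative.  Where no genetic map is supplied, 1 cM = 1 Mb.

# f-statistics (`f3Test`, `f4Test`, `f4Ratio`)

For populations with sample alt-allele frequencies $a, b, c$ the
three-population statistic is the mean over usable variants of

$$ (c-a)(c-b) \;-\; \frac{\hat c(1-\hat c)}{n_C - 1}, $$

with $n_C$ the target's non-missing allele count; the subtracted term
removes the bias contributed by sampling noise in $\hat c$.  A population
formed by mixing groups related to A and B carries frequencies pulled
between $a$ and $b$, which makes the product negative in expectation; the
one-tailed rule flags $Z < -2.33$ (1% level).  f4 is the mean of
$(a-b)(c-d)$ and needs no correction because each frequency enters once.
Standard errors are leave-one-block-out jackknives over contiguous 5 Mb
blocks (5 cM under the default map) — wider than the LD scale of array
data, which is the requirement for the jackknife to be honest; the paperless
choice of block size is a convention, not a tuned constant.  Variants with
any undefined frequency among the populations of a statistic, or
monomorphic across them pooled, are skipped per statistic, so SNP counts
differ between statistics computed on the same matrix.

The F4 ratio is exact only under its assumed phylogeny: the source proxy
(e.g. an Aboriginal Taiwanese panel standing in for the Lapita source) must
branch off the admixed population's Asian source lineage at (or before) the
pulse.  Using a present-day sample of the Asian panel itself as the proxy
contaminates the denominator with the panel's post-pulse drift and biases
the proportion — which is why the simulator offers a dedicated sister deme
(`asian_proxy_chroms` in `demographyConfig`) splitting at the pulse time
for validating the estimator.

The F4 ratio estimates the Asian-related fraction as
$\alpha = f4(\mathrm{asian}, \mathrm{outgroup}; \mathrm{admixed},
\mathrm{papuan}) / f4(\mathrm{asian}, \mathrm{outgroup};
\mathrm{asianSource}, \mathrm{papuan})$.  The jackknife resamples the ratio
itself (both sums recomputed per deleted block).  A denominator within 3 SE
of zero means the assumed phylogeny carries no information about the
proportion and is reported as an error rather than an unstable number.

# Admixture dating (`weightedLDCurve`, `fitDecay`)

A single admixture pulse $n$ generations ago leaves LD between variants at
genetic distance $d$ Morgans that decays as $e^{-nd}$.  The curve statistic
weights each intra-chromosome pair by the product of source-panel frequency
differences $w_i w_j$ (so pairs that distinguish the ancestries dominate)
and averages the dosage correlation $\rho_{ij}$:
$A(d) = \sum w_i w_j \rho_{ij} / \sum |w_i w_j|$ in 0.1 cM bins up to
20 cM.  Swapping the panels negates every weight pairwise and leaves the
curve unchanged.  `fitDecay` fits $A_0 e^{-nd/100} + c$ (d in cM) by
Levenberg–Marquardt least squares, starting the fit at 0.5 cM: background
LD contaminates shorter distances, and the exclusion is the standard
weighted-LD convention rather than a fitted choice.  The decay constant per
Morgan is the admixture age in generations; 30 years/generation converts to
years.  A flat or non-decaying optimum is a fit failure, not a date.

# Local ancestry (`laiModel`, `fitDosage`)

The observation unit is the unphased genotype dosage of an admixed
individual, matching SNP-array reality.  The hidden state at a site is the
unordered ancestry pair of the two chromosomes, {PP, PA, AA}, with initial
distribution $(m^2, 2m(1-m), (1-m)^2)$.  Over a gap of $d$ Morgans each
chromosome independently retains its ancestry with probability $e^{-Td}$
and otherwise redraws from $(m, 1-m)$; the diploid transition is the
product of the two haploid kernels.  Genotype emissions convolve two
Bernoulli draws from the local ancestry's panel frequency, smoothed as
$(x + 0.5)/(n + 1)$ per panel (a Jeffreys-style pseudocount that keeps
likelihoods finite at panel-fixed sites); missing genotypes emit likelihood
1.  Posterior dosages come from scaled forward–backward per chromosome;
after each full pass the mixture proportion is re-estimated as the mean
posterior dosage / 2, for 20 EM passes.  $T$ is a user setting (77 for the
headline analysis; 50/100/150 probe sensitivity) and is deliberately not
EM-updated — the admixture date comes from the weighted-LD stage, and
fixing $T$ mirrors how local-ancestry tools are run in practice.

This three-state panel-frequency HMM deliberately replaces the two-layer
haplotype-cluster model of ELAI-style tools.  The estimand — per-site
posterior Papuan dosage — is the same, and on tract-simulated truth the
implementation recovers it essentially unbiasedly (dosage–truth correlation
above 0.9, genome-wide mean within 0.03 of the true proportion; see the
test suite).  What the simplification changes is the *noise profile*: a
cluster model pools linkage information along haplotypes, producing
spatially smoother dosage estimates.  The consequences for the outlier
scan are discussed under Limitations.

# Ancestry-excess scan (`summarizeTrack`, `callRegions`, `grubbsTest`)

The population mean track (per-site mean of dosage/2) is summarised by its
genome-wide mean and population SD (denominator $N$; at array scale the
choice versus $N-1$ is immaterial but must be fixed).  Positions are
flagged by strict inequality beyond mean ± 2 SD and ± 3 SD, and excess
regions are maximal runs of consecutive same-chromosome positions beyond
the ± 3 SD threshold, gap tolerance 0; singleton runs are retained as
zero-length regions.  Grubbs' test for a single outlier uses
$G = \max|x_i - \bar x| / s$ and the t-quantile relation
$\tau = \sqrt{N(N-2)G^2 / ((N-1)^2 - NG^2)}$,
$p = \min(1, 2N\,P(t_{N-2} \ge \tau))$.  On a strongly autocorrelated
ancestry track this nominal p-value ignores the autocorrelation entirely;
it is reported because it is the field's customary headline number, but the
calibrated test is the simulation null below.

# The neutral coalescent null (`simulateWindows`, `ascertainVariants`)

The null asks: how much local-ancestry excess does genetic drift alone
produce?  The demography is a three-population history — one ancestral
population of diploid size 1000 splits 1667 generations ago (50,000 years
at 30 years/generation) into a Papuan-side and an Asian-side population
(sizes 1000), and an admixed deme forms by a single pulse 77 generations
ago with Papuan fraction 0.5137, the genome-wide proportion estimated in
the admixed samples.  1500 independent 2 Mb windows (3 Gb total) are
simulated with mutation rate 1.2e-8 and recombination rate 1.3e-8 per base
per generation — 8.5e-9 for the variant mimicking the reduced
recombination of the HLA region — sampling 48, 40 and 90 chromosomes from
the Papuan-side, admixed and Asian-side demes.  The engine is an
event-driven ancestral-recombination-graph simulator written for this
package (Hudson's algorithm with ancestral-material tracking and on-the-fly
mutation dropping), validated distributionally against Watterson's formula
and the neutral frequency spectrum.  The true ancestry of every admixed
chromosome is recorded at the pulse, giving an exact per-site dosage oracle
(`trueAncestryDosage`).

SNP-array ascertainment is emulated by sampling sites without replacement
so the pooled-sample folded MAF histogram matches a target (0.01-wide bins,
largest-remainder rounding) at the genome-wide density of 146,090 sites per
3 Gb.  The shipped default target is flat above MAF 0.05 with a linear
taper below — a generic array-like spectrum standing in for a measured
one, replaceable by the user.  Folding is over the pooled sample (sources
plus admixed), the natural reading of matching "the real data" whose
genotypes span all three groups.  Undersupplied bins yield what they have
and the shortfall is redistributed proportionally with a warning.

The pipeline then mirrors the real analysis end to end: diploid genotypes,
panel frequencies from the simulated source samples (not the truth), HMM
dosages for the 20 admixed individuals, the mean track, ± 3 SD thresholds
computed from the simulated track itself, and per-window region calling
(windows are independent, so regions never span windows).

# Selection scan (`ehh`, `ihh`, `ihsScan`)

EHH around a core allele is the probability that two random carrier
haplotypes are identical over the interval from the core to a flank,
computed from distinct-prefix counts; it starts at 1 and is non-increasing
outward.  iHH integrates EHH trapezoidally over Morgans, stopping at the
first tabulated point below the 0.05 cutoff (no interpolation at the
crossing — the convention is documented rather than guessed); cores whose
curve reaches a chromosome edge while still above the cutoff are flagged
and excluded from standardisation.  The unstandardised score
$\ln(iHH_A/iHH_D)$ is standardised within 2% derived-allele-frequency bins
(bins with fewer than 10 cores merged), and the reported p-value is the
two-sided Gaussian tail $2\Phi(-|iHS|)$ — the choice of a two-sided test is
a package decision, made because both unusually long ancestral and derived
haplotypes are of interest.  Haplotypes with a missing call in the
extending window are dropped from the homozygosity count from that flank on.

# What the generators do and do not emulate

The coalescent engine reproduces the drift, recombination and sampling
structure of the stated demography exactly, including the clustering of
the 40 admixed chromosomes into a smaller number of founder lineages at
the pulse (about 23 effective founders after 77 generations at size 1000),
which dominates the between-window variance of the true ancestry track.
It does not model selection (the null is explicitly neutral), gene
conversion, mutation-rate or recombination-rate heterogeneity within a
window, genotyping error, or phasing error.  The tract-copying generator
(`simulateTractAdmixture`) draws ancestry switch points as a Poisson
process at rate $T$ per Morgan and alleles as independent Bernoulli draws
from the local ancestry's panel frequency — linkage equilibrium within
ancestry, which is ideal for oracle tests of the HMM (whose emission model
matches that assumption) but understates the background LD of real
genomes.  Passing tests on these generators therefore demonstrate correct
recovery of the estimand under the model's own assumptions, not robustness
to model violations.

# Problem sizes and numerical choices

The test suite exercises reduced problem sizes chosen so each property is
measured well inside its Monte-Carlo tolerance: Watterson checks at 400
small windows; ascertainment histogram matching at 160 windows; dating
recovery on a 3 Gb-equivalent map (30 chromosomes × 100 Mb at 50 kb
spacing, 20 individuals); HMM oracle runs on 4,000–10,000 variants; iHS
normality on pooled scans of 8–12 neutral 2 Mb windows.  The acceptance
script runs both neutral-null presets at the full 1500-window scale.
Forward–backward uses per-site scaling (no log-sum-exp needed at these
lengths); zero genetic distance between consecutive sites gives a switch
probability of 0 and is not an error; EM estimates of $m$ are clamped to
(1e-6, 1-1e-6); the decay fit seeds its optimiser from a log-linear
regression and treats a non-positive amplitude at the optimum as failure.

# Limitations

* **Region-length null versus estimator smoothness.**  The contiguous
  excess-region statistic is extremely sensitive to the spatial smoothness
  of the dosage estimator.  With the ancestry truth recorded at the pulse,
  the simulations show the mean track's dispersion is dominated by true
  founder-level variance (the true track's SD is ~12.5–13% under the
  standard preset conditions), and threshold excursions of the *true*
  track beyond its own +3 SD are short (tens of kb), because tract
  turnover chops them.  Cluster-based local-ancestry tools smooth dosages
  over longer ranges, which both shrinks the reported track SD and fuses
  threshold crossings into much longer runs.  Consequently the
  region-length calibration produced by this package's HMM is not
  interchangeable with one produced by a cluster-model estimator, and
  comparisons of observed regions to a null must use the same estimator on
  both sides — which is what `runNeutralNullStudy` does.
* **Grubbs' p-values** ignore track autocorrelation (see above).
* The f-statistics follow their textbook definitions; exact numeric parity
  with any specific toolkit's finite-sample conventions is not claimed.
* The weighted-LD statistic uses the normalised-correlation form; single
  admixture pulse only, no two-reference background-LD correction.
* Palindromic (A/T, C/G) variants are dropped at dataset merge rather than
  strand-corrected by frequency matching — the conservative array-era rule.
* The iHS scan requires externally phased haplotypes and known ancestral
  alleles; cores without polarity are skipped.
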