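---
title: "Haplotype features of bottlenecked, admixed populations: models and methods"
author: "hapscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype features of bottlenecked, admixed populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`hapscan` measures the haplotype footprints that recent demography leaves in
phased diploid genotype panels — linkage-disequilibrium (LD) decay,
identity-by-descent (IBD) sharing, runs of homozygosity (ROH), haplotype
diversity — and runs an EHH/iHS selection scan whose significance thresholds
are calibrated against a built-in neutral forward simulator of a
colonisation-bottleneck-plus-admixture history, the demographic setting of
Latin American populations. Candidate alleles can then be dated with the
haplotype-decay TMRCA clock. This vignette records the models, the tunable
parameters, and the design decisions a maintainer would want explained.

# The demographic null model

`colonizationModel()` returns the neutral history the scan is calibrated
against, for a 10 Mb chromosome with uniform crossover rate
$r = 10^{-8}$ and mutation rate $\mu = 1.5\times10^{-8}$ per bp per
generation (30-year generations):

* ancestral diploid size $N_e = 10{,}000$, burned to mutation–drift
  equilibrium;
* out-of-Africa contraction to $N_e = 2{,}000$ at 50 kya, recovery to
  10,000 at 5 kya;
* a colonisation bottleneck of $N_e = 100$ lasting from 500 to 90 years
  ago, opened by a one-generation admixture pulse in which a European-like
  lineage contributes 70% of parent draws, with a 70% inbreeding
  probability (implemented as selfing) throughout the bottleneck window;
* recovery to $N_e = 10{,}000$ at 90 years ago.

Two structural choices were genuinely open:

* **Where the admixture pulse comes from.** A single-population history has
  no European donors, so the simulator maintains a second, European-like
  deme from the out-of-Africa split onward. It follows the same size
  trajectory as the colonised deme until the pulse and then holds its
  pre-pulse size; only the colonised deme is ever sampled. This is the
  smallest amount of structure that makes the stated pulse executable.
* **What "inbreeding probability of 70%" means mechanistically.** It is
  implemented as selfing: during the bottleneck window each offspring's two
  parents are the same individual with probability 0.7. Selfing is the
  simplest Wright–Fisher mechanism governed by a single probability;
  sib-mating or other schemes would need extra state. The choice is
  isolated in one branch of the parent-drawing code and is swappable.

`constantModel()` is the matched control: identical rates and schedule
length, constant size, no events. It shares the burn-in state with the
bottleneck model, so control/bottleneck replicate pairs can be forked from
one equilibrium population — the batch design used by the calibration
suite and the acceptance script.

## Rescaling (the `q` knob)

Running $N_e = 10{,}000$ forward in time is not a desk-scale computation,
so `rescaleModel(model, q)` applies standard population rescaling: sizes
and times in generations are divided by $q$ and per-generation rates are
multiplied by $q$, preserving $\theta = 4N_e\mu$ and $\rho = 4N_e r$ and
hence the sample statistics they govern. The desk preset used throughout
the tests and the acceptance script is $q = 20$ ($N_e$ 500, burn-in
$10\,N_e$ = 5,000 generations, about half a minute on one CPU).

Two consequences are worth stating plainly:

* Event times are rounded to whole scaled generations with a floor of one
  generation per epoch. At $q = 20$ the 500–90 ya colonisation window
  collapses to a *single* scaled generation at $N_e = 5$ with selfing and
  the pulse stacked on it. The bottleneck's haplotype footprint is
  therefore somewhat stronger than a literal-time simulation would give;
  all directional comparisons (bottleneck vs control) are unaffected, which
  is what the calibration asserts.
* Genetic distances are always expressed on the *real* map (1 cM/Mb for
  the simulated chromosome, matching $r = 10^{-8}$), not the inflated
  scaled map, so segment lengths and EHH integrals are comparable across
  `q`.

## What the simulator does and does not emulate

It is a neutral, discrete-generation, single-chromosome Wright–Fisher
model with infinite-sites mutation (real-valued positions mapped to unique
integer bp on output) and Poisson crossovers. Panels retain sites with
derived frequency above 0.05 (the pipeline's marker filter) — except where
a statistic's closed form refers to the full site-frequency spectrum: mean
pairwise diversity loses about 10% of its mass below a 0.05 frequency
floor under the neutral SFS, so the diversity calibration samples with
`minFreq = 0`. The simulator does not emulate array ascertainment, genotype
or phasing error, gene conversion, multiple chromosomes, or selection;
passing calibration therefore says the *statistics* behave correctly under
the stated demography, not that real array data would be free of those
artefacts.

# Statistics

## EHH and iHS

EHH for a core allele at distance $x$ is the probability that two random
carriers are identical at every marker between the core and $x$,
$\mathrm{EHH} = \sum_h \binom{c_h}{2} / \binom{n_c}{2}$, evaluated at
marker positions and equal to 1 at the core. The iHS integrals
$iHH_A, iHH_D$ accumulate EHH over genetic distance by the trapezoid rule,
with one linearly interpolated final point where EHH crosses 0.05; cores
whose EHH is still above the cutoff at a chromosome end are skipped. The
unstandardised score is $\ln(iHH_D/iHH_A)$ — the selscan sign convention,
under which scores above +2 suggest selection on the derived allele — and
standardisation subtracts the mean and divides by the SD (denominator $n$)
within 2% derived-allele-frequency bins.

Numerical choices:

* **Extension bound.** EHH walks are truncated 1 Mb from the core
  (`maxExtendBp`), selscan's `--max-extend` behaviour. On post-bottleneck
  panels EHH commonly never reaches 0.05 — without the bound the scan's
  cost grows with the square of the marker count, and a 160-haplotype,
  ~13k-marker group takes hours instead of ~14 s. Truncation, not
  skipping: integration simply stops at the bound. Set `maxExtendBp = 0`
  to remove it.
* **Frequency filter.** Cores need a derived frequency in [0.05, 0.95] and
  at least two carriers of each allele.
* **Gaps.** No gap penalty is applied; a warning is emitted when an
  adjacent-marker gap exceeds 200 kb, where linear interpolation of EHH
  becomes coarse.

## LD decay

$r^2$ is the squared Pearson correlation of 0/1/2 genotype dosages (the
PLINK convention), computed for every marker pair within 100 kb and
averaged in 1 kb distance bins. Pairs involving a zero-variance marker are
excluded rather than scored 0. Under free recombination the finite-sample
null expectation of $r^2$ for $n$ individuals is $\approx 1/(n-1)$, which
the property suite checks.

## IBD detection and the IBD score

The detector is GERMLINE-style seed-and-extend: haplotypes are hashed over
consecutive 64-marker slices; exact slice matches seed candidate pairs;
seed runs are merged across gaps while accumulated mismatches stay within
per-segment allowances (a mismatch where both individuals are homozygous
counts against the homozygous allowance, default 1, any other mismatch
against the heterozygous allowance, default 1); merged matches are then
extended marker-by-marker to the first mismatching marker. Segments are
reported at `minCm = 2` and scored in the 3–20 cM band: the IBD score is
the summed genetic length of in-band segments divided by
$\binom{2n}{2} - n$, the number of between-individual haplotype pairs for
$n$ diploids — the only reading of the "normalised by sample size" pair
count that excludes an individual's two own haplotypes. Standard errors
come from a delete-one-block weighted jackknife (Busing-type, weights
proportional to block length) over 10 Mb blocks, segments assigned to the
block holding their midpoint, with the 95% CI at $\pm 1.96$ SE.

## ROH calling

`callROH()` reproduces the PLINK `--homozyg` algorithm: 50-SNP windows
sliding one SNP at a time, a window "homozygous" when it has at most
`windowHet` heterozygous (0 for array data, 3 for WGS) and at most 5
missing calls; a SNP qualifies when at least 5% of the windows overlapping
it are homozygous (truncated window ranges near chromosome ends use the
reduced overlap count); qualifying runs are reported at $\ge$ 50 SNPs,
$\ge$ 1 Mb, no internal gap above 1 Mb. Density (50 kb/SNP) follows the
PLINK default and no heterozygote end-trimming is applied; both are
documented constants of `rohParams()`.

## Diversity

Nei's unbiased haplotype diversity $H = \frac{n}{n-1}(1 - \sum p_i^2)$ is
computed in non-overlapping 10-marker windows (overlap is not used; with
abutting windows every marker still contributes exactly once) and averaged;
expected heterozygosity is $2p(1-p)$ averaged over sites.

## Simulation-derived cutoffs and the TMRCA clock

`deriveCutoffs()` matches a population's test count $n_\mathrm{tests}$
against pooled standardised scores from the neutral groups: the lower and
upper cutoffs are the expected minimum and maximum of a without-replacement
draw of size $n_\mathrm{tests}$, averaged over $B = 1000$ seeded draws.
This reproduces the qualitative behaviour that fewer tests earn less
extreme thresholds, and is deterministic under a seed; a plain tail
quantile at $1/n_\mathrm{tests}$ per tail is available behind
`method = "quantile"`. Filtering is strict at the boundaries (a score equal
to a cutoff does not pass).

The TMRCA clock assumes a star genealogy of the favoured-allele carriers:
the probability a chromosome keeps its ancestral haplotype intact to
recombination distance $r$ Morgans after $T$ generations is $e^{-2rT}$
(two meiosis paths between two carriers). Breakpoints are placed where the
favoured allele's EHH decays to 0.25; $r$ is half the genetic span between
the two interpolated crossings, $T = \ln 4 / (2r)$, and years $= 30\,T$.
Spans above 1.1 cM are skipped (an allele that young would need an
implausibly large selection coefficient); cores whose EHH never reaches
0.25 inside the panel are reported `unresolved` instead. Note the
dimensional reading: $T$ is in generations and the generation time enters
only in the final conversion to years — at the 1.1 cM skip boundary the
clock gives $\ln 4/0.011 \approx 126$ generations, about 3,800 years.

# Problem sizes used by the test and acceptance suites

One shared burn-in at $q = 20$; ten seeded control/bottleneck replicate
pairs of 50 diploids for the directional calibration; five pooled
80-individual groups (~10–13k scored markers each, matching the scale of
the study's simulated groups) plus one independent test group for the
null calibration of the scan; 100 random instances for each detector vs
its exhaustive oracle. These sizes keep the full suite within tens of
minutes on one CPU while leaving every Monte-Carlo comparison at least
3 SEs of headroom.

# Known limitations

* The scaled colonisation window is a single generation at the default
  `q = 20`; choose a smaller `q` for finer time resolution at higher cost.
* The IBD detector processes candidate pairs in R; panels beyond a few
  hundred haplotypes are better partitioned into groups first (as the
  pipeline does anyway).
* TMRCA estimates inherit the star-genealogy assumption and are expected
  to be biased low (roughly a factor of two) for alleles with structured
  genealogies; the parameter-recovery property in the test suite asserts
  only factor-of-two agreement.
* The `simulate`/`ihs`/`ibd`/`roh`/`ld`/`diversity`/`cutoffs`/`tmrca`
  command-line entry points (`inst/exec/hapscan.R`) are thin wrappers over
  the exported functions; programmatic use via the package API is the
  primary interface.
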