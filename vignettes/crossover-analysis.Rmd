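---
title: "Measuring crossover frequency and interference with fluorescent reporters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring crossover frequency and interference with fluorescent reporters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftlrec)
```

## The measurement problem

Fluorescent tagged lines (FTLs) carry linked transgenes expressing distinct
fluorescent proteins from pollen- or seed-specific promoters. In a plant
hemizygous for the construct, a meiotic crossover between the two transgenes
separates them, so the fluorescence classes of the gametes (or of selfed
progeny) report the recombination frequency of the interval. `ftlrec`
implements the estimators, interference statistics, group comparisons, and
marker-association scans used with such data, together with a four-strand
meiosis simulator that generates every count modality the estimators
consume. The package's particular concern is how juxtaposing heterozygous
and homozygous chromosome regions remodels crossovers — the experimental
design behind the F2 association scans and the interference comparisons.

## Estimators

Four scoring modalities are supported. Throughout, cM denotes 100 times the
recombinant gamete fraction, matching how the tables these estimators are
validated against report distance; no mapping-function correction
(e.g. Kosambi) is applied.

**Two-colour pollen** (`pollen2_cm`). Flow cytometry of pollen from a plant
carrying linked green- and red-channel transgenes yields four classes. The
estimate conditions on pollen carrying the green transgene:
`cM = 100 R5/(R3 + R5)`, where `R3` counts green+red (parental) and `R5`
green-alone (recombinant) pollen. Conditioning matters because non-hydrated
pollen inflates the red-alone class; the red-alone and colourless counts are
deliberately excluded, and the total recombinant count is reported as
`2 R5`. The standard error is binomial on `R3 + R5`.

**Selfed seed** (`seed_cm`). Seed from a self-fertilized `GR/++` plant
unite two independent gametes, so single-colour seed arise at combined
frequency `(N_G + N_R)/N_T = (1 - (1 - r)^2)/2`. Inverting,
`cM = 100 (1 - sqrt(1 - 2 (N_G + N_R)/N_T))`. This inversion is exact: the
package asserts `seed_cm(expected counts under r) = 100 r` across the whole
admissible range. Estimates above 50 cM trigger a warning (the model
saturates as double crossovers within the interval go uncounted); a negative
radicand is an error naming the offending counts. The SE propagates the
binomial variance of the single-colour proportion through the square root.

**Tetrads** (`tetrad_cm`). In the *qrt1* background, the four pollen of one
meiosis stay attached, and two-marker co-segregation classifies each tetrad
as parental ditype, non-parental ditype, or tetratype. The Perkins estimate
`cM = 100 (T/2 + 3 NPD)/n` weights NPDs — which require a four-strand double
crossover — to recover the doubles the tetratype count misses. Its standard
error uses the multinomial delta method,
`se = (100/sqrt(n)) sqrt(t(1 - t)/4 + 9 d(1 - d) - 3 t d)` with `t = T/n`,
`d = NPD/n`; the package checks this against a parametric bootstrap.

**Three-colour pollen** (`threecolour_cms`). With transgenes B–Y–R defining
two adjacent intervals, each of the eight fluorescence classes is assigned
to the recombinant set of interval b (B/Y discordant) or interval c
(Y/R discordant); each interval's cM is the discordant fraction times 100.
The class formulas are dimensionless fractions; the package reports them
scaled by 100 so that the three-colour estimates share units with every
other modality.

`classify_seed_objects` turns per-seed red/green intensity tables into the
four seed classes. In automatic mode each channel's cut sits at the deepest
valley of a kernel-smoothed log-intensity histogram; a unimodal histogram is
refused with advice to supply explicit cuts, since silently placing a
threshold inside a single mode would fabricate classes.
`call_configuration` distinguishes coupling (cis) from repulsion (trans)
linkage of the two reporters in segregating progeny by comparing multinomial
likelihoods of the four classes under the two configurations at a reference
recombinant fraction (default 0.15, typical of the intervals these reporters
span); below a configurable log-likelihood margin the call is `ambiguous`.
Trans-configured plants matter because their parental and crossover seed
classes are exactly reversed, which would corrupt a pooled estimate.

## Interference statistics

For a three-colour interval pair, the observed double crossovers are the two
classes recombinant in both intervals (`N_-Y- + N_B-R`); the expectation
under independence is `(cM_b/100)(cM_c/100) N_total`. The coefficient of
coincidence is observed/expected, interference is `1 - CoC`, and the
significance of the deficit is a binomial test of the observed count at the
expected proportion (`coc_threecolour`).

For tetrads scored over two adjacent intervals,
`tetrad_adjacent_interference` computes the focal interval's Perkins
estimate separately in tetrads with and without a crossover in the adjacent
interval. Positive interference shortens the with-crossover stratum, making
the without/with ratio exceed 1. The contrast is tested with a two-sided
z-test on the two Perkins estimates with their delta-method SEs; the
original analyses mark significance without naming a test, and the z-test is
this package's choice, consistent with the large per-stratum counts.

Per-interval interference contrasts are combined across intervals with
Fisher's combined probability test, `chi2 = -2 sum(log p)` on `2k` df
(`fisher_combined`); `fisher_critical` exposes the reference critical value.
Group differences in interference are tested by a binomial GLM on DCO
counts with an offset at the log-odds of each replicate's own
no-interference expectation (`compare_interference`); modelling counts
rather than the CoC ratio keeps the inference in the same binomial framework
as the recombinant-fraction comparisons.

## Group comparisons

`fit_binomial_glm` fits `cbind(Y, n - Y) ~ replicate + genotype` with a
logit link and tests the genotype term by likelihood ratio rather than Wald,
which behaves better with few replicates; residual degrees of freedom are
reported alongside. Dispersion is fixed at 1 (binomial); overdispersion, when
present, shows up in the residual deviance, which is returned for
diagnosis but not modelled. Complete separation is flagged with clamped
coefficients rather than silently huge estimates, and a rank-deficient
design is an error naming the aliased columns. Whether replicate enters as a
covariate is switchable (`include_replicate`), since some comparisons pool
replicates and some stratify by them.

`variance_f_test` compares the dispersion of per-individual cM between
populations (an F ratio with two-sided p). `merged_chisq` handles count
distributions with sparse tails — per-nucleus chiasmata counts — by pooling
adjacent categories from the tails inward until every expected cell reaches
5 (configurable), then applying the ordinary chi-square; degrees of freedom
follow the merged table. `yates_chisq_2x2` and `bh_fdr` are thin, validated
wrappers (continuity-corrected chi-square; Benjamini–Hochberg step-up) that
exist so the association pipeline has one canonical, tested path.
`windowed_spearman` correlates two windowed genomic tracks by rank, with
pairwise deletion of missing windows and optional re-binning to coarser
physical scales.

## Marker association in F2 populations

`quartile_association` ranks individuals by measured cM (ties broken by id
so reruns are identical), takes the hottest and coldest `floor(n/4)`
individuals, and tests each marker's heterozygous vs homozygous composition
between the two quartiles in a Yates-corrected 2×2 chi-square, followed by
BH adjustment across markers. Both homozygous classes are pooled: the
biological contrast of interest is heterozygosity vs homozygosity, not
allele identity. Rank-based selection makes the procedure invariant to
monotone transformations of the phenotype. A marker where every scored
individual falls in one class is untestable and reported with statistic 0,
p 1 rather than an error, matching how such rows appear in practice.

`lod_scan` is a deliberately simple single-marker scan: cM regressed on
genotype class means, `LOD = (n/2) log10(RSS0/RSS1)`, with a genome-wide
threshold from the `1 - alpha` quantile of max-LOD over seeded permutations
of the phenotype. It is not interval mapping — markers in these designs are
dense and the claims at stake are about where the signal lies, not about
centimorgan-resolution QTL placement.

One point worth stating about calibration expectations: with a genuine cis
effect present, the quartile scan typically makes several true discoveries,
and BH then tolerates false discoveries at the FDR level — so an occasional
significant marker on an unlinked chromosome in some runs is correct
behaviour of the procedure, not a failure of localisation. The package's
tests therefore require the *top* signal to sit on the reporter chromosome
and bound the stray-discovery fraction, while the FWER-controlled LOD scan
is held to strict per-run confinement.

## The synthetic-data generator

`sim_model` + `simulate_meioses` place crossovers on a bivalent along the
genetic scale: a stationary gamma renewal process with shape `nu` and mean
inter-event distance 0.5 Morgan (so expected crossovers per meiosis equal
twice the map length in Morgans), optionally mixed with a Poisson "escape"
stream carrying `escape_fraction` of events. `nu = 1` recovers
interference-free Poisson placement; `nu ≈ 5–10` produces the strong
positive interference typical of the ZMM pathway; the escape stream stands
in for the non-interfering minority pathway (and lets one emulate
*fancm*-like genotypes where that pathway dominates). Stationarity is
achieved by starting the renewal process 10 mean spacings upstream of the
region, which is indistinguishable from an exact equilibrium start at the
scales simulated. Each crossover involves one randomly chosen chromatid of
each homolog. Gamete haplotypes are traced with the standard strand walk — a
molecule switches to the partner strand at each exchange involving the
strand it currently follows — which realises "no chromatid interference":
each crossover involves the followed strand with probability 1/2, so
recombination events in disjoint intervals are independently thinned and the
coefficient of coincidence is exactly 1 under Poisson placement. This is a
statistical generator chosen for being the simplest mechanism consistent
with the statistics computed, not a mechanical model of interference;
`nu` has no externally calibrated value. There is no obligate-crossover
enforcement. Regional `region_modifiers` rescale local map density
multiplicatively — a phenomenological stand-in for rate modification, not a
model of its cause.

From the same machinery the generator emits every count modality: tetrad
PD/NPD/T (`simulate_tetrad_counts`, plus per-tetrad calls over two adjacent
intervals for the interference analysis), two-colour pollen with an
`artifact_fraction` of spurious red-alone objects emulating non-hydrated
pollen, three-colour pollen classes, selfed-seed classes from the exact
segregation algebra, and whole F2 populations
(`simulate_f2_population`) in which individuals are formed from two
independent simulated gametes, only reporter-heterozygous (coupling)
individuals are retained, and a user-supplied `cis_effect` maps each
individual's genotype pattern to a multiplicative factor on the reporter
interval's genetic length. Seed intensities, when requested, are lognormal
with brightness proportional to transgene copy number: the 1- and 2-copy
groups overlap substantially while both sit far above autofluorescence,
which is the regime in which fluorescent-vs-non-fluorescent thresholding
(rather than copy-number calling) is the right analysis.

What the generator does not emulate: sequence-level polymorphism and
heteroduplex effects (the cis effect is injected as a rate factor, not
derived from a mechanism), obligate crossover assurance, chromatid
interference, scoring error beyond the red-alone artifact, and linkage
between markers on *different* non-reporter chromosomes is simplified to a
uniform 4 cM/Mb map per chromosome. Passing calibration tests on these
simulations therefore demonstrates that the estimators and scans are
correct and well-calibrated under the stated model — not that real data obey
that model.

## Numerical and interface choices

* Map ↔ recombinant-fraction conversions use Haldane's function where
  Poisson placement makes them differ; `haldane_d`/`haldane_r` are exported
  because round-trip tests need the exact expectation.
* Reported tables round cM and SE to 2 decimals (the `cM_2dp` column of
  `write_report`) while retaining full precision in the primary columns.
* Coordinates: marker and T-DNA positions are 1-based bp; BED-like track
  inputs for the windowed correlation are 0-based half-open and converted at
  the boundary.
* Degenerate inputs fail loudly and specifically: zero informative counts,
  negative radicand (with the counts named), empty strata, zero margins,
  unimodal intensity histograms, constant phenotypes, rank-deficient
  designs.
* All randomness flows from explicit seeds (`rng_seed` in the model, `seed`
  arguments, `--seed` in the CLI); identical seeds give bit-identical
  outputs.
* Test problem sizes: calibration suites use 10^5 gametes/tetrads for
  round-trips and coincidence, 10^4 replicates for GLM type-I error, and 20
  replicate F2 populations (n = 139, 2000 seeds each, 27 markers) for the
  association calibrations — sizes at which Monte-Carlo error is a small
  fraction of the tolerances asserted.

## Known limitations

The seed estimator is single-interval and saturates near 50 cM. The
configuration caller assumes the reference recombinant fraction is roughly
right; grossly different true rates shrink its margin. The LOD scan does not
model genotyping error or segregation distortion. The adjacent-interval
z-test assumes approximate normality of the Perkins estimates, which is
comfortable at thousands of tetrads but optimistic below a few hundred. The
gamma-renewal model cannot reproduce interference that varies along the
chromosome, and `region_modifiers` change rate but not interference
structure.
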