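---
title: "Models and methods behind domscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind domscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

domscan implements the population-genomic analysis chain of a small
domestication resequencing study: cohort QC and ancestry purification,
windowed diversity and divergence, a composite-likelihood selective-sweep
scan, permutation tests for shared gene sets, genic hemizygosity calling
from structural variants, and cross-coalescence split-time estimation,
together with a cohort simulator that makes every stage verifiable against
known truth. This vignette describes the models, their assumptions, the
tunable parameters, and the numerical and design choices.

## Cohort QC and ancestry classification

Site-level QC follows the bcftools expression `%QUAL < 20 || DP > 32`:
a site is `LowQual` when its quality is strictly below 20 **or** its
`INFO/DP` strictly exceeds 32. Both inequalities are strict, mirroring the
filter expression. A record without a depth annotation cannot trigger the
DP clause and therefore passes it; the same holds for a missing QUAL. The
depth consulted is site-level `INFO/DP` (summed sample depth is not used).
Downstream statistics operate on PASS, single-ALT, single-nucleotide
records only (`selectBiallelicSnps()`).

Sample-level missingness is the fraction of missing haplotype calls; a
sample is kept iff its fraction is strictly below 50% (ingroup) or 75%
(outgroup). Ancestry classification assigns an accession to its
maximum-proportion group only when that proportion strictly exceeds
`threshold = 0.80`; otherwise it is `admixed`. Published ancestry tables
sometimes mix scales within one table (a row `1.00 / 0.00 / 0.00`
alongside `83.78 / 16.22 / 0.00`), so each row is interpreted by its sum:
in `[0.99, 1.01]` as fractions, in `[99, 101]` as percentages, anything
else is an error rather than a guess. Exclusion lists (e.g. to thin
near-relatives of an over-sampled cultivar) are a user-supplied parameter
because no objective rule defines them.

Coordinates are handled in the Bioconductor convention: every interval in
R is a 1-based closed `GRanges`; VCF and GFF3 are read in their native
1-based conventions, and BED export converts to 0-based half-open at the
boundary. Window tiling keeps the final partial window of each chromosome
(bedtools-compatible) and records each window's assembly-gap overlap
fraction so density statistics can renormalise; only windows lying
entirely inside gaps are removed.

## Diversity and divergence

Per-site diversity is `pi = k (n - k) / C(n, 2)` for derived count `k`
among `n` haplotypes; windowed `pi` divides the per-site sum by the full
window width. The full-width denominator matches VCFtools-style windowed
diversity when no callable-site mask exists; with a mask the values would
shrink toward it, which is a known, documented bias shared with the
original analyses.

Per-site Fst is the Weir & Cockerham (1984) two-population estimator
`theta = a / (a + b + c)` computed from sample sizes, allele frequencies
and observed heterozygosity. Window values are the arithmetic mean of the
defined per-site `theta` over SNPs in the window — the PLINK convention
the original windowed analysis used — with negative per-site values
retained, not truncated. The mean-of-sites statistic sits systematically
below the ratio-of-sums estimator because low-frequency SNPs (the bulk of
all SNPs) carry small `theta`; comparisons should therefore stay within
one convention. Sites where `a + b + c = 0` are undefined and excluded;
windows with no defined site carry no value and do not enter quantiles.
Quantile cutoffs (`empiricalTopCutoff()`) select the `ceiling(q W)`
highest-valued windows genome-wide, including all ties at the threshold.

## The sweep scan

The scan is the SweepFinder/SweeD composite-likelihood model. Conditioned
on a background site-frequency spectrum `p` (estimated genome-wide,
conditioned on polymorphism), a sweep at distance `d` with intensity
`alpha` lets each lineage escape with probability
`p_e = 1 - exp(-alpha d)`. With `b` escapees, the pre-sweep sample is the
`b` escapee lineages plus the single ancestor of the swept lineages; its
derived count is drawn from the background projected to `b + 1` samples by
the hypergeometric projection
`q_m(i) = sum_j p(j) C(j,i) C(n-j, m-i) / C(n,m)`. If the swept lineage is
derived (probability `i/(b+1)`), the post-sweep count is `n - b + i - 1`,
else `i`. The resulting spectrum is renormalised over polymorphic classes.
The composite likelihood ratio at test position `x` is
`Lambda(x) = 2 [max_alpha sum_s ln P(j_s | d_s, alpha) - sum_s ln p(j_s)]`,
clamped at zero because the grid contains the null sentinel
`alpha = Inf`.

Numerical choices:

* The `alpha` grid has 40 log-spaced points spanning escape
  half-distances from 100 bp to 10 Mb, plus the null sentinel — footprints
  from negligible to chromosome scale.
* Spectra are precomputed on a 2049-point `p_e` grid and the scan looks up
  the nearest grid point. The last grid row (`p_e = 1`) *is* the
  background, so SNPs far enough that `p_e` rounds to 1 contribute exactly
  the null term; the compiled scan kernel skips them (identical result,
  faster). At `p_e = 0` every lineage is swept and the site is
  monomorphic, making the polymorphism-conditioned spectrum 0/0; that grid
  column is evaluated at the small-`p_e` limit instead, where escapee
  singletons and `n - 1` classes dominate.
* One CLR evaluation per 10-kb window at the window midpoint, matching a
  windowed reporting of the statistic.
* The spectrum is unfolded by default (the simulator guarantees the
  reference allele is ancestral); a folded mode is provided for data
  without trustworthy polarisation, implemented by symmetrising the
  background before projection and folding observation classes in the
  likelihood.
* With missing data, observed counts are mapped to the cohort's common
  haplotype number (the median per-site non-missing count) — expectation
  projection when estimating the background, a hypergeometric subsample
  draw in the scan — and sites with fewer than half the common number are
  dropped.

Smoothing for genome-wide display assigns zero to unvalued windows and
fits `stats::loess` (tricube-weighted local quadratic regression, the same
routine ggplot2's `geom_smooth(method = "loess")` calls) with span 0.5 per
chromosome, evaluated at window midpoints. Chromosomes with fewer than
five windows are returned unsmoothed with a warning.

## Gene sets and permutation tests

Sweep locations recruit genes whose span lies within 5 kb (inclusive) of
the test position; Fst outlier windows recruit genes overlapping a
selected window by at least one base. Both rules are deliberately simple
interval geometry with explicit boundary conventions (an edge exactly
5,000 bp away is in; a gene abutting a half-open window end is out).

The shared-gene test shuffles flag labels: each permutation redraws both
sets as uniform random subsets of the common universe with sizes fixed and
recounts the overlap. This is distributionally identical to hypergeometric
sampling of the overlap, which the test suite uses as an exact oracle. The
p-value is `(b + 1) / (N + 1)`, which cannot be zero and at `N = 10000`
bottoms out just under 1e-4 — consistent with reporting "P < 0.0001". The
default universe is every gene in the supplied annotation; because the
expected overlap scales with `|A||B|/U`, the universe choice materially
changes p-values and is exposed as a parameter rather than hidden.

## Genic hemizygosity

Insertion/deletion calls (SNIFFLES-style VCF or BED-like tables) are kept
when supported by at least 4 reads (inclusive). A gene is called
hemizygous when a *single* event affects at least 20% (inclusive) of its
merged coding sequence: for deletions, the overlap between the deletion
span and the merged CDS intervals; for insertions — point events that
cannot "overlap" a fraction of anything — the breakpoint must fall inside
a CDS interval and the inserted length must reach the same 20% of CDS
length. The insertion rule is an interpretation (the natural reading of an
overlap criterion for a point event); both the per-event-vs-cumulative
choice and the fraction are exposed as parameters, with per-event maximum
as the default since the rule speaks of *events that overlapped*. Genes
with zero CDS length are never flagged.

## Cross-coalescence split times

Given MSMC2-style per-epoch rates, the relative cross-coalescence rate is
`rCCR = 2 lambda01 / (lambda00 + lambda11)`: about 1 while the two
populations still coalesce as one pool (deep past), falling toward 0 after
a clean split. The split time is the rCCR = 0.5 crossing, located by
scanning epochs from the present backwards and linearly interpolating
between epoch *midpoints* (epochs are half-open intervals; midpoints are
the natural representative under the MSMC convention; an infinite last
boundary falls back to its left edge). Non-monotone (noisy) curves use the
first crossing and warn. Scaled times convert to years as
`years = t / mu_per_year` with `mu = 5.4e-9` per site per year and 7-year
generations (so generations = years / 7), and rates convert to effective
sizes as `Ne = 1 / (2 lambda mu_gen)`. Whether a published crossing used
first-vs-last crossing or midpoint-vs-boundary interpolation is generally
not stated; the midpoint/first-crossing choice here is documented, not
asserted as anyone else's.

## The cohort simulator

The simulator defines the study conditions under which everything is
tested:

* topology `((Lowland, Guatemalan), Mexican)` with splits at 44,000 years
  and 1.3 million years — 6,286 and 185,714 generations at 7 years per
  generation;
* per-site diversity `theta = 4 Ne mu = 0.0035` via `Ne = 23,148` and
  `mu = 3.78e-8` per generation (5.4e-9 per site per year × 7);
* 3 Mexican, 5 Lowland and 10 Guatemalan diploids by default;
* a desk-scale genome of 12 × 1 Mb tiled into independent 1-kb segments.

Each segment is an independent structured-coalescent genealogy (`k`
lineages in a population of size `N` coalesce at rate `k(k-1)/2/(2N)`;
pools merge at the split times; no migration), onto which infinite-sites
mutations fall as a Poisson process proportional to branch length. The
segment construction approximates recombination as free between segments
and absent within them — fast, with exact ground truth, and sufficient for
window statistics, but it does not reproduce continuous linkage decay,
so haplotype-based statistics (iHS-like) should not be validated against
it. Other simplifications relative to real data: no sequencing error, no
missingness, no reference bias, and the reference allele is always
ancestral (which is what makes unfolded-SFS tests meaningful). Passing
tests therefore demonstrate correctness of the estimators under the
model's assumptions, not robustness to artefacts of real resequencing.

Hard sweeps use the star approximation directly: at the sampling time,
each lineage of the swept population escapes with probability
`f(d) = s + (1 - s) min(1, d/r)` and all non-escapees coalesce instantly
into one lineage, after which the neutral process runs. This was a
genuinely open design point. A time-constant rescaling of `Ne` by `f(d)`
leaves the SFS shape exactly neutral (a uniformly scaled Kingman tree has
the neutral spectrum), and a time-limited rescaling phase produces a
bottleneck signature — an intermediate-frequency excess that the sweep
model actively penalises; both were tried and neither yields a detectable
CLR signal. The escape/star construction is the generative model the CLR
itself assumes, produces the diversity trough and the
singleton-plus-high-frequency excess, and gives exact per-segment truth.
With `s = 0.05` and `r = 50 kb`, planted centers score CLR in the hundreds
against a background 99th percentile around ten.

Hybrid accessions copy, per segment and per haplotype independently, a
random haplotype from a source population drawn with the configured
proportions; the per-segment source is recorded as truth. Simulated SV
sets place one deletion per chosen gene covering an exact target fraction
of its merged CDS (walking CDS intervals from the gene start, spanning
introns as needed) with configured read support, so the hemizygosity
caller can be checked against planted flags exactly. Rate curves are
piecewise-constant with `lambda = 1/(2 Ne mu_gen)` within populations and
a sharp cross-rate step at the split; the split sits exactly on an epoch
boundary with equal-width neighbours, so midpoint interpolation recovers
it exactly in clean mode, and lognormal noise (`sigma = 0.1`) exercises
the noisy path. All generators are deterministic given a seed, to the
byte, in their emitted files.

One testing subtlety is worth recording: chi-square tests of the neutral
SFS against the `1/j` expectation assume independent draws, but SNPs
within a segment share one genealogy and their class counts are
overdispersed. The suite therefore rejection-samples segments with
probability proportional to their SNP count and takes one uniform SNP per
accepted segment — independent draws with exactly the SNP-weighted
marginal the `1/j` expectation describes. (Choosing one SNP per segment
*uniformly* is subtly wrong: it reweights toward short genealogies and
inflates singletons.)

## Problem sizes used in the checks

The test and acceptance workloads were sized for a single CPU: sweep-power
replicates use a 12 × 1 Mb genome with 10 diploids and 5 planted sweeps
(20 replicates in the test suite, 5 in the acceptance script); diversity
calibration uses 2 Mb; the SFS chi-square uses 24 Mb to collect over 5,000
independent draws after rejection sampling; permutation tests run at
N = 10,000 with the study's set sizes (436/638 with 18 shared, 396/436
with 10 shared) over a 49,450-gene universe. These sizes keep every
stochastic check comfortably inside its tolerance; scaling the genome up
only tightens them.

## Known limitations

* The composite likelihood treats SNPs as independent; as in SweepFinder,
  Λ values are an ordering statistic, not calibrated significance.
* Physical distance stands in for recombination distance in `p_e`.
* The windowed Fst convention (mean of per-site `theta`) is not
  comparable to ratio-of-sums values without conversion.
* The hemizygosity insertion rule is an interpretation of an
  overlap-fraction criterion for point events.
* The simulator's segment independence understates linkage; its sweep
  model is the same family the scanner assumes, which makes power
  estimates optimistic relative to sweeps with recombination during the
  fixation trajectory.
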