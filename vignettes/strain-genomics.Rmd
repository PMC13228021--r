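---
title: "Strain-comparative yeast genomics with strainvar: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain-comparative yeast genomics with strainvar: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainvar)
```

# Scope

`strainvar` analyzes collections of *Saccharomyces cerevisiae* strains from
short-read derived summaries — per-site allele depths, windowed coverage,
assembled ORFs — rather than raw reads. It answers six questions per
strain: what is the ploidy; which chromosomes are aneuploid and which
segments are duplicated or deleted; where has heterozygosity been lost and
by what mechanism class; how far apart are two strains in time; which
predicted genes are foreign to the reference gene set; and how does stress
tolerance relate to fermentation performance. A simulator with full ground
truth generates every input the pipeline consumes, so each caller is
testable by parameter recovery without sequencing data.

This vignette documents the models, the tunable parameters with their
defaults and rationale, the numerical choices, and the limits of what the
simulation-based tests demonstrate.

# The heterozygous-site sampling model

Everything upstream of the callers reduces to one observation model. At a
biallelic site carrying $a$ alternate copies among $c$ homologs, sequenced
to depth $d$, the alternate read count is

$$ k \sim \mathrm{Binomial}(d,\; a/c), $$

and the read support is $k/d$. A diploid heterozygote ($a/c = 1/2$)
centers at 50% support; a triploid at 1/3 or 2/3; a tetraploid at 1/4,
1/2, 3/4. Per-site depth is $d \sim
\mathrm{Poisson}(\bar d \cdot \mathrm{CN} / p)$ where $\bar d$ is the mean
depth at baseline ploidy $p$ and CN the local copy number, so aneuploid
and CNV regions carry proportionally more or fewer reads.

Homozygous sites are not sampled at support exactly 0 or 1: a residual
error rate (default 0.005) is kept so support concentrates at 0.995/0.005.
Real data never shows perfectly clean homozygous support, and a simulator
that did would leave the homozygosity threshold untested at its working
point.

# Ploidy inference

`fit_ploidy()` models in-band heterozygous alternate counts as a
uniform-weight mixture over dosage states: for candidate ploidy $c \in
\{2,3,4\}$,

$$ \mathcal{L}_c = \sum_i \log \frac{1}{c-1} \sum_{a=1}^{c-1}
   \mathrm{Binomial}(k_i \mid d_i, a/c), $$

scored as $\mathcal{L}_c - (c-1)\log n$ and maximized, ties toward smaller
$c$. Choices worth stating:

* **Candidate set {2,3,4}.** These are the ploidies observed in the strain
  collections this pipeline targets; higher candidates add overlapping
  mixture components ($a/c$ grids interleave) with little identifiability.
* **Penalty $(c-1)\log n$.** A BIC-style complexity term in the number of
  mixture components. The underlying study determined ploidy by flow
  cytometry, so no published computational rule exists to match; the
  penalty is standard model-selection practice.
* **Band 0.10–0.90 (config).** Sites outside the band are homozygous under
  the 90% rule (below) and carry no dosage information; including them
  would let LOH regions distort the fit.
* **Known tetraploid/diploid overlap.** The $a=2$ tetraploid component
  coincides with the diploid mode; discrimination rests on the 25%/75%
  components. Per-candidate scores are returned so a borderline fit is
  visible rather than silent.
* **Minimum 200 usable sites** (config), below which the call is
  `undetermined` rather than a guess.
* When a prior copy-number analysis is available, its aneuploid
  chromosomes can be excluded (`exclude_chroms`), since a trisomic
  chromosome in a diploid mimics triploid dosage locally.

# Aneuploidy and segmental CNV

Coverage windows (default 1 kb at the simulator's 1/10 genome scale, i.e.
10 kb at real scale) are normalized by the genome-wide median depth.
Per chromosome, the copy number estimate is
$\mathrm{round}(\tilde r \cdot p)$ with $\tilde r$ the median window
ratio — the median, not the mean, so a segmental CNV cannot drag a
whole-chromosome call. An aneuploidy is called only when at least 80% of
windows (config) individually round to the same non-baseline copy number;
otherwise the chromosome is reported euploid with its (low) support
fraction, which is how mixed or subclonal states surface. Rounding is
half-up at exactly $x.5$, a fixed convention so ties cannot flip between
runs; the support gate then decides whether such a marginal level is
called at all.

Segmental events are maximal runs of at least 3 consecutive windows
(config) deviating from the chromosome's called level by at least
`ratio_margin / ploidy` (default margin 0.3, i.e. 30% of one copy) in a
consistent direction. Runs become segments with copy number
$\mathrm{round}(\text{run median} \times p)$ and a positional class:
**terminal** when the segment comes within `terminal_margin` (default two
windows) of a chromosome end, **interstitial** otherwise, crossed with
gain/loss into four classes. Breakpoints are annotated with any repeat
feature (LTR, Ty, mating locus) within one window, reflecting the
association of rearrangement breakpoints with repetitive DNA.

rDNA and mitochondrial contigs can be excluded via a deny-list: their
depth artifacts would otherwise produce spurious calls.

# LOH segmentation and positional classes

Zygosity uses the 90% read-support rule, inclusive at the boundary, and
applied **two-sidedly**: a site with support $\ge 0.90$ *or* $\le 0.10$ is
homozygous. The one-sided rule describes alternate-homozygous sites;
reference-homozygous sites sit near support 0 and are equally homozygous.
Numerically the rule is evaluated as $\max(s, 1-s) \ge 0.90$ — computing
$1 - 0.90$ as a second threshold would put the inclusive boundary on the
wrong side of floating-point rounding.

Runs of homozygous calls become segments under an explicit tolerant-run
definition (the source study segments "regions" without stating a rule):
an interval of calls is a tolerant run iff its endpoints are homozygous,
no two adjacent heterozygous calls occur inside, and the heterozygous
count is at most `max_het_rate` (default 1/50) of the interval's sites.
Segments are the maximal tolerant runs with at least `min_sites` (default
10) members. The definition is deliberately simple enough to brute-force:
the test suite checks the implementation against an interval enumerator.

Classification is positional, in assessed-site units rather than base
pairs (variant density, not chromosome length, is the data's resolution):

* **UPD** — the segment covers ≥ 95% of the chromosome's assessed sites
  (whole-chromosome homozygosity from a segregation error);
* **terminal** — the segment reaches within 3 assessed sites (config) of
  the first or last assessed site on the chromosome (single-crossover
  signature);
* **interstitial** — anything else (gene conversion / double crossover).

The genome homozygosity fraction is length-weighted: total segment span
over total assessed span, where the assessed span is first-to-last
assessed SNV per chromosome. Using chromosome length as denominator would
make the fraction undefined policy in SNV deserts; this interpretation is
config-visible rather than silent.

## Mitotic vs meiotic positional statistic

Mitotic LOH concentrates near telomeres; meiotic LOH distributes more
evenly. The statistic is the fraction of total LOH length inside the
terminal 20% (config) of each chromosome arm, arms defined by the
centromere. The null re-places each segment uniformly along its own
chromosome, length preserved (default 1,000 draws, seeded). Patterns:
`fully-homozygous` at genome homozygosity ≥ 0.99 (checked first — a
genome-wide LOH pattern has no positional signal left); otherwise
`mitotic-dominated` above the null's 95th percentile, `meiotic-dominated`
within the central 90%, `undetermined` below the 5th percentile or with
fewer than 3 segments. The 20% arm fraction separates telomere-proximal
events cleanly at the simulator's scale and is exposed, not hard-coded.

# Divergence time and variant tallies

Two strains differing by $\Delta$ SNVs, with an accumulation rate $\mu$
(default $5 \times 10^{-3}$ SNVs per genome per division) and generation
time $g$ (default 2 h), diverged approximately

$$ T = \frac{\Delta}{\mu} \cdot \frac{g}{8760} \ \text{years} $$

with 8,760 h per 365-day year. $\Delta$ is the symmetric difference of
(chrom, pos, alt) SNV records — zygosity ignored, InDels excluded, and a
shared position with two different alternate alleles counts twice. No
factor of two for the two lineages is applied: the worked endpoints
(3,671 SNVs → 168 years; 86,949 → 3,970) reproduce only under total-count
scaling, so that is the definition used and stated.

InDel repeat context follows the replication-slippage taxonomy: an event
lying in a single-base run of length ≥ 4 (counting its own bases) is
`mononucleotide_repeat`; in ≥ 3 tandem units of a 2–6 bp motif,
`microsatellite`; else `non_repeat`, with mononucleotide precedence.
Frameshift InDels are computed natively from allele lengths
($|\,|\mathrm{ref}| - |\mathrm{alt}|\,| \bmod 3 \ne 0$ in coding
features); codon-level consequence calling is deliberately out of scope —
the module consumes upstream effect labels.

# Additional-gene (HGT) detection

A query ORF is "additional" when its best identity against the reference
ORF set is **at or below 85%** (inclusive), or when no reference shares
enough k-mers to be a candidate (identity recorded as 0). Identity is
global Needleman–Wunsch (match +1, mismatch −1, gap −2, end gaps
penalized), matches over all alignment columns including gaps. This is
stricter and more deterministic than the BLAST-style local identity used
by the original annotation tooling — a stated substitute, not a
reproduction. Traceback ties resolve diagonal, then gap-in-reference,
then gap-in-query; the tie-break is part of the definition so that the
test suite's independent plain-R implementation can agree exactly rather
than approximately. The comparison is nucleotide-level, matching how the
reference ORF sets are distributed. The k-mer prefilter (15-mers, ≥ 5
shared) keeps the all-vs-all DP desk-scale; at very low identities
(≲ 65%) the prefilter itself rejects the pair, which is the correct
outcome since such genes are additional either way.

Telomeric contig ends are detected as ≥ 8 tandem motif copies (≥ 90%
conserved) within a terminal 500 bp window; a contig carrying them was
chromosome-end located. A fragment bounded on both sides by
non-additional matches to the *same* native gene is flagged as a
flanking-duplication integration.

# Phenotype–fermentation analysis

Stress tolerance is relative biomass: OD under stress over OD under
control (endpoint OD; the readout time is config-exposed since the source
assay monitors growth without stating one). Condition clustering uses
correlation distance and average linkage by default (`stats::hclust`,
deterministic with column order as tie-break). The fermentation period is
the time to CO₂-loss plateau — the first 8-h increment below 0.05 g/100 mL
(config) — falling back to the full sampled range; the fermentation-rate
proxy is the ethanol titer linearly interpolated at the period midpoint.
Tolerance–fermentation association is raw Pearson $r$ per condition, as
in the source figures; permutation p-values (and Benjamini–Hochberg
adjustment) are optional and off by default.

# The simulator: what it emulates and what it does not

`simulate_strain()` draws a 16-chromosome genome with real *S. cerevisiae*
relative chromosome lengths and centromere positions at 1/10 linear scale
(~1.2 Mb), so that whole-pipeline tests run in seconds while
size-dependent phenomena (small chromosomes most often aneuploid,
arm-length asymmetry) stay representable. Defaults: one heterozygous SNV
per 300 bp, mean depth 80, 1 kb windows, Poisson depths, binomial allele
counts, residual homozygous error 0.005. LOH tracts are defined on truth
coordinates and convert contained sites to homozygous before sampling;
class placement follows the tract (interstitial internal, terminal
abutting an end, UPD whole-chromosome). HGT contigs carry reference ORFs
mutated to a requested identity by uniform substitutions (realized
identity within one percentage point), optional telomere-repeat tails and
optional native flanking duplications. InDels are planted with a
deterministic repeat-context count (default fraction 0.82) inside
regex-located mononucleotide runs and dinucleotide microsatellites;
non-repeat placements are screened by a conservative window test (no run
≥ 3, no tandem of any 2–6 bp unit) so truth labels cannot be accidentally
repetitive — the screen is intentionally stricter than the classifier so
the two stay independent.

What the simulator does **not** model: read-level artifacts (mappability,
GC bias, duplicates, quality), recombination as a forward process,
subclonality, reference bias, assembly errors, and real InDel length
spectra. Passing recovery tests therefore demonstrates that the callers
invert the stated generative model at realistic depths and densities —
not that they are robust to every artifact of real short-read data. The
thresholds most sensitive to such artifacts (support band, window
agreement fraction, ratio margin) are all config keys for exactly that
reason.

Depth is sampled per window as a Poisson read count
(`depth × width / read_length`) rather than per base; at 80× and 1 kb
windows the relative noise (~3.5%) is comparable to well-behaved real
coverage.

# Problem sizes and determinism

The test suite and the bundled acceptance script use: 10,000 sites for
read-support summaries; 30 simulated strains (10 per ploidy) for ploidy
recovery; 20 strains with 0–3 aneuploidies for copy-number
precision/recall; 20 strains × 3 tract classes for LOH recovery; planted
identities {0.60, 0.80, 0.95} for additional-gene flags; 150 InDels per
repeat fraction in {0, 0.5, 0.82, 1}; 200 random pairs (length ≤ 200 bp)
for alignment-oracle equivalence; and 100 random call sequences for the
segmentation enumerator. These sizes make the whole suite run in well
under a minute on one core while leaving the statistical assertions
comfortably powered. Every stochastic operation takes a seed; with a
fixed seed, simulation output is bit-reproducible.

# Known limitations

* Ploidies above 4 are out of scope; a pentaploid strain would be forced
  into the candidate set.
* Tetraploid/diploid discrimination weakens at low depth, where 1/4 and
  1/2 binomial modes blur.
* The CNV caller reports window-resolution breakpoints only; split-read
  or discordant-pair evidence is out of scope.
* LOH classes are positional; individual-event mechanism (gene conversion
  vs double crossover) is not inferred.
* Global-alignment identity diverges from BLAST local identity for genes
  with large unalignable regions; near the 85% boundary the two can
  disagree on real data.
* The divergence clock assumes constant $\mu$ and generation time and
  ignores LOH/CNV contributions to divergence.
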