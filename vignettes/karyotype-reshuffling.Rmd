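---
title: "Recombination landscapes and genome-wide reshuffling across divergent karyotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recombination landscapes and genome-wide reshuffling across divergent karyotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reshufflr)
library(dplyr)
```

## The problem

Chromosomal fissions and fusions change two things at once: the number of
independently assorting linkage groups, and the physical span over which
crossovers can shuffle alleles. In taxa with extreme intraspecific karyotype
variation — the motivating system is the wood white butterfly *Leptidea
sinapis*, whose populations range from 2n ≈ 56 to 2n ≈ 106 chromosomes, with
holocentric chromosomes and achiasmatic (non-recombining) female meiosis —
those two forces can be separated quantitatively. `reshufflr` implements the
quantities needed to do that from linkage-map (Marey map) tables, karyotype
tables, allele-count data with invariant sites, and homology block tables:

* windowed recombination-rate landscapes and per-chromosome map statistics,
* the genome-wide probability of pairwise reshuffling $\bar r$, decomposed
  into interchromosomal (independent assortment) and intrachromosomal
  (crossover) components,
* pixy-style windowed nucleotide diversity by site class, and
* permutation-tested regressions of between-population diversity ratios on
  recombination-rate ratios over ancestral chromosome blocks.

A seeded synthetic-data generator (karyotype rearrangement, interfering
crossovers, pedigree gametes, diversity landscapes with planted effects)
backs every estimator with an independent oracle, so the whole pipeline is
testable without pedigree or resequencing data.

## Marey maps and the recombination landscape

A Marey map is the ordered set of (physical bp, cumulative cM) marker pairs
of one chromosome; its local slope is the recombination rate. On reading
(`read_map_table()`), markers are sorted by physical position, co-located
markers are merged to their mean genetic position (RAD markers frequently
co-locate), and the first marker is normalized to 0 cM — maps are relative
distances. Genetic positions must be non-decreasing along the physical
order; violations are hard errors because they indicate a broken marker
order rather than noise.

Two numerical conventions matter downstream:

* **Coordinates** are 0-based with half-open windows `[start, end)`,
  matching BED conventions.
* **Interpolation** (`genetic_position_at()`) is linear between markers and
  *clamps* outside the marker span. There is no crossover information
  beyond the terminal markers, so unmapped terminal sequence is treated as
  fully linked to the nearest mapped marker. The alternative —
  extrapolating the terminal slope — fabricates recombination where nothing
  was observed.

Window rates (`windowed_rates()`, default 2 Mb) are the
physical-overlap-weighted mean of marker-interval rates. Two invariants pin
the estimator down and are enforced in the test suite: the covered-bp
weighted mean of window rates equals the chromosome mean rate exactly, and
the sum of rate × covered Mb over windows equals the map length
(conservation of centimorgans). Terminal partial windows are retained with
their true `covered_bp`; windows with zero coverage carry an `NA` rate and
are excluded from downstream statistics rather than imputed.

Map distance and recombination fraction are interconverted with Kosambi's
map function, the convention under which such maps are usually built:

$$d = 25 \ln\frac{1 + 2r}{1 - 2r} \qquad r = \tfrac12\tanh(d/50).$$

`excess_map_length()` subtracts the 50 cM contributed by the obligate
crossover of each bivalent; chromosomes below 50 cM (negative excess) are
expected and preserved. `expected_rate()` gives the $k \cdot 50\,\mathrm{cM}$
expectations used to compare chromosomes against exactly-one and
exactly-two crossover regimes; the ~18 Mb size threshold above which a
second crossover becomes common is a configuration constant
(`size_threshold_bp`), not a hard-coded magic number, because it is an
empirical, approximate boundary.

## Pairwise reshuffling

$\bar r$ is the probability that two loci drawn uniformly at random from
the genome derive from different grandparental haplotypes in a gamete. It
decomposes exactly:

* **Interchromosomal** (`inter_reshuffling()`): loci on different
  chromosomes reshuffle with probability 1/2 under independent assortment,
  giving $\bar r_\mathrm{inter} = \tfrac12\left(1 - \sum_i (\ell_i/L)^2\right)$
  for chromosome lengths $\ell_i$ and assembly length $L$. For $n$ equal
  chromosomes this is $\tfrac12(1 - 1/n)$ (`equal_size_expectation()`).
* **Intrachromosomal** (`intra_reshuffling_chrom()`): 1,000 pseudomarkers
  are placed evenly over the *physical* chromosome $[0, \ell]$, their
  genetic positions read off the Marey map (clamped at the ends), and the
  inverse Kosambi recombination fraction averaged over all
  $\binom{1000}{2}$ pairs — exact enumeration, not sampling; half a million
  pairs is cheap. Pseudomarkers span the full chromosome rather than just
  the marker span because reshuffling is defined over physical loci;
  clamping makes unmapped terminal sequence fully linked, which is the
  conservative choice.
* **Genome total** (`genome_intra()`, `totals()`): per-chromosome intra
  values are weighted by the probability $(\ell_c/L)^2$ that both loci land
  on that chromosome; the male total is inter + intra, the female total is
  the inter term alone (achiasmatic females), and the sex average is their
  mean. Chromosomes without markers must be declared achiasmatic explicitly
  — silently treating a missing map as zero would understate the total.

No additional chromatid factor is applied anywhere: inverse map functions
already return gamete-level recombination fractions $r \le 1/2$.

`reshuffling_from_crossovers()` handles the deterministic-placement case:
for chiasmata at fixed relative positions, two loci differ in origin with
probability 1/2 × P(odd number of intervening chiasmata) — the parity
decides whether the recombinant product switches origin and the sampled
chromatid carries it with probability 1/2. This reproduces the equality
that a single central chiasma and a quartile pair both give $\bar r = 0.25$.

Full precision is kept in memory and in JSON artifacts; the
table-shaped TSV report rounds to 3 decimals at serialization only
(`write_reports()`), so derived ratios should always be computed from the
unrounded report.

## Nucleotide diversity

`pi_windows()` implements the ratio-of-sums estimator: per site with $k \ge
2$ called haplotypes and alternate count $a$, differences $a(k-a)$ and
comparisons $\binom{k}{2}$ are accumulated, and window $\pi$ is
$\sum\mathrm{diff}/\sum\mathrm{comp}$ — never a mean of per-site ratios.
This matches the missing-data behaviour of the pixy estimator: invariant
sites must be present (they contribute comparisons), fully missing sites
contribute nothing, and $\pi$ is invariant to adding non-callable sites and
to relabelling alleles or individuals. Aggregation to larger bins
(`join_to_recombination()`, default 2 Mb) re-sums the counts, which is
identical to recomputing from sites when counts are complete.

`classify_degeneracy()` assigns 0-fold/4-fold classes per CDS position
under the standard genetic code: a position is 0-fold when every base
change alters the encoded amino acid (changes to a stop count as altering),
4-fold when none does; 2- and 3-fold positions, and positions whose class
conflicts across overlapping transcripts, are excluded so that only sites
with an unambiguous selective regime enter the $\pi_0/\pi_4$ contrast.
Upstream genotype filtering (depth bounds, repeat masking) is deliberately
out of scope: the input contract is a per-site called-haplotype count that
already reflects whatever masking was applied.

Association statistics follow the field's standard choices: Spearman
correlations and Wilcoxon rank-sum tests (`spearman_assoc()`,
`wilcoxon_compare()`), OLS with permutation p-values
(`ols_permutation()`: $p = (1 + \#\{|b^\ast| \ge |b|\})/(1 + n_\mathrm{perm})$,
two-sided, seed-deterministic), a 2 cM/Mb stratification
(`threshold_split()`) reflecting the observed saturation of the
diversity–recombination relationship, and Holm correction across site
classes (chosen because it is uniformly valid without independence
assumptions; the multiple-testing method was an open choice).

## Ancestral blocks and the diversity-ratio regression

Ancestral chromosomal units — segments left intact by the fissions and
fusions distinguishing two karyotypes — allow a within-segment contrast
that cancels shared genomic covariates (base composition, gene density,
demography). `block_summaries()` computes, per block and population, the
recombination rate (cM spanned by the block over its Mb length,
interpolating at block edges) and ratio-of-sums diversity over the windows
clipped to the block, then forms $X = \rho_2/\rho_1$ and $Y = \pi_2/\pi_1$.
Both $X$ and $Y$ are invariant to the window partition inside a block.

Because both axes carry sampling error, the slope is read as a model II
problem: `model2_regression()` fits OLS and assesses the slope by raw-data
permutation of $Y$ against $X$ (two-sided on $|b|$), not by OLS standard
errors. Blocks are unweighted by default — block length is available as an
optional weight column, but the reference analysis did not weight.
`excess_at_unity()` evaluates the fit at $X = 1$: the residual diversity
excess once recombination-rate differences are cancelled out, reported as a
percentage.

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions under
which every estimator is verified.

* **Karyotypes** (`simulate_karyotype_pair()`): fissions split at a uniform
  internal point in one lineage, fusions concatenate random chromosomes in
  the other; base pairs are conserved by construction and a homology block
  table is emitted. This mirrors a system where one lineage is fragmented
  and the other fused relative to the common ancestor.
* **Crossovers** (`simulate_meiosis()`): chiasmata are simulated on the
  bivalent, on the genetic scale. The default is a stationary gamma renewal
  process with mean spacing 50 cM; the shape $\nu$ sets interference
  strength ($\nu = 1$ is the no-interference Poisson case). The default
  $\nu = 5$ reflects the strong interference implied by bimodal
  large-chromosome landscapes, with the value left configurable because no
  empirical interference estimate exists for the system. The simpler
  `obligate_plus_poisson` model (one uniform obligate chiasma plus
  Poisson extras) is retained as a fallback and for analytic checks.
  Both models return bivalent chiasma counts (mean $G/50$ over a map of
  length $G$); thinning to chromatid crossovers — probability 1/2 each, no
  chromatid interference, the standard assumption — happens at gamete
  formation, keeping the two models interchangeable downstream.
* **Gametes** (`simulate_pedigree_gametes()`): grandparental origin at each
  marker is the parity of crossovers to its left from a random phase;
  female meioses are achiasmatic, making the female total reshuffling
  exactly the interchromosomal term — an invariant the tests exploit.
* **Maps from gametes** (`estimate_map_from_gametes()`): adjacent-marker
  recombinant fractions through Kosambi, cumulated; $\hat r$ is capped at
  0.49 with a warning because the map function diverges at 0.5.
* **Diversity** (`simulate_diversity()`): windowed $\pi$ follows a
  saturating curve $\pi = s \cdot \pi_\max \, \rho/(\rho + \rho_{50}) \cdot
  e^\varepsilon$ with lognormal noise, emitted as difference/comparison
  counts so the ratio-of-sums machinery is exercised end to end. Sequence-
  level coalescent simulation is deliberately avoided: window-level
  summaries keep the tests deterministic and fast while exercising exactly
  the statistics the analysis consumes.

Where simulated gametes are compared against Kosambi-based map arithmetic,
the tests use $\nu = 2.63$, the classical gamma shape whose renewal process
best matches Kosambi's map function; even so the match is approximate, so
those comparisons allow a small documented model term (0.004 on a genome
intra value of ~0.07) on top of Monte-Carlo error. This is a property of
the map-function/process pair, not an estimator defect.

## What the tests do and do not show

The generator emulates: ~50 cM chromosomes with an obligate crossover,
more-than-one crossover above ~18 Mb, achiasmatic females, independent
assortment, and a saturating diversity–recombination relationship with a
multiplicative population effect. It does not emulate: non-uniform marker
informativeness, genotyping error, segregation distortion, repeat-driven
masking structure, selection (Hill–Robertson dynamics), or sequence-level
coalescent noise. Green tests therefore certify the estimators and their
algebra under the stated generative conditions, not robustness of the
upstream data production that is outside this package's scope
(linkage-map construction, variant calling).

Problem sizes in the default suite were chosen to make Monte-Carlo error
small relative to the asserted tolerances: 2 × 10⁵ assortments for the
interchromosomal oracle, 2–4 × 10⁴ meioses for gamete-based $\bar r$,
500 gametes for map-length recovery (matching a realistic pedigree scale),
and 200 replicates for the planted 8% diversity-excess recovery.

## Reproducible summary quantities

`scripts/acceptance.R` recomputes, from a fresh seed, the desk-level
contrasts between the two study populations (from the published estimates
shipped in `extdata`) and the simulation-based oracle checks above, and
writes them as JSON. See the README for how to run it.

## Known limitations

* Recombination outside the marker span is undefined by design; analyses of
  chromosomes with sparse terminal markers will under-cover terminal
  windows.
* The intrachromosomal estimator inherits the map function's interference
  assumption; maps built under a different mapping function should set
  `map_fun` accordingly (Haldane is provided).
* The block regression treats blocks as exchangeable; spatial
  autocorrelation between adjacent blocks is not modelled, which makes the
  permutation p-value slightly liberal if many blocks derive from one
  chromosome.
* History-class filtering of blocks is configurable but the package cannot
  reconstruct block inclusion decisions made upstream of its inputs.
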