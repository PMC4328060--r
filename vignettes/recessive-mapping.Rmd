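---
title: "Mapping recessive disease alleles in inbred pedigrees: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping recessive disease alleles in inbred pedigrees: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recmapper)
```

recmapper implements the classical positional-cloning strategy for a rare
monogenic recessive disorder segregating in an inbred family: infer the
inheritance model from the pedigree, map the mutation by autozygosity,
filter case variants against unrelated controls, call structural variants
from read pairs, and classify the functional consequence of whatever
survives. This vignette is the package's account of the underlying models,
the tunable parameters, and the design decisions taken where more than one
reasonable choice existed.

## The pedigree model

A pedigree is a directed acyclic sire/dam graph. Kinship is computed by the
tabular (Emik–Terrill) method in topological order,

$$ f(x,x) = \tfrac12\,(1 + f(s_x, d_x)), \qquad
   f(x,y) = \tfrac12\,(f(s_x,y) + f(d_x,y)), $$

with founders mutually unrelated and an unknown parent contributing zero.
The inbreeding coefficient is $F(x) = f(s_x, d_x)$, exactly zero when
either parent is unknown. **Unknown parents are modelled as unique,
unrelated founders.** Field pedigrees are almost always incomplete; treating
missing ancestry as unrelated gives a conservative *lower bound* on F and
kinship, which is the safe direction for declaring obligate carriers and
expected autozygosity. The test suite checks the recursion against an
independent Wright path-counting oracle
$\sum (\tfrac12)^{n_1+n_2+1}(1+F_A)$ over all common ancestors $A$ and
node-disjoint path pairs, exhaustively on pedigrees up to 12 individuals.

Obligate carriers under an autosomal recessive model are reported as the
unaffected parents of affected individuals — the only individuals whose
carrier status is a logical certainty. Carrier status of remoter relatives
(for instance, exactly one of the two parents of a known carrier must
carry, but which one is undecidable) is deliberately not guessed; on the
bundled study pedigree this yields IV/A, III/A, III/B and II/C, while the
unknown-descent cow III/C, historically drawn as a carrier on the published
family diagram, is *not* derivable by this rule and is not returned.

### Gene dropping

`gene_drop()` transmits uniquely labelled founder haplotypes down the
pedigree. Recombination follows the Haldane model: crossovers are a Poisson
process at a per-bp rate (default in examples $10^{-8}$, i.e. 1 cM/Mb)
with no interference, and the starting phase of each gamete is a fair coin.
Autozygosity at a point is the event that both haplotype labels descend
from the same founder haplotype; its genome average converges to F, which
the tests verify at three Monte-Carlo standard errors with 1,000
replicates. Sex chromosomes are not modelled — the recessive mapping this
package supports is autosomal, and all simulated chromosomes are treated as
autosomes of equal length (29 × 90 Mb by default, a deliberately round
bovine-like genome).

## The synthetic cohort

`simulate_cohort()` generates every input the pipeline consumes under a
single seed. It emulates the study conditions end to end: the
four-generation inbred pedigree with two parent–offspring matings, a dense
biallelic SNP array (2,000 markers per chromosome by default — a desk-scale
stand-in for a 777k chip, evenly spaced with ±30% jitter), a recessive
2,433 bp deletion at chr16:65,704,617–65,707,049 carried by founder IV/A,
18 candidate genes of which one hosts the deletion over its first exon,
40 unrelated control genomes, and a 300 bp-insert 2 × 100 bp paired-end
library at 20× depth over the deletion locus ± 15 kb.

Design choices worth knowing about:

* **Founder allele frequencies** are drawn from a symmetric Beta(1.5, 1.5),
  giving array-like expected heterozygosity (~0.37). This produces enough
  background homozygosity-by-state that run detection and
  parental-exclusion filtering have real work to do, rather than trivially
  recovering only the identical-by-descent tracts.
* **Affected individuals are guaranteed del/del by conditioning, not
  rejection.** Transmissions on the founder-to-affected paths are
  phase-forced at the deletion midpoint. Under Haldane recombination the
  crossover positions are independent of the starting phase, so fixing the
  phase of the segment covering one point is exact conditional sampling;
  unconditioned rejection would accept on the order of 1 in 10⁴ replicates.
* **Array behaviour over deleted DNA.** Markers inside a homozygous
  deletion are emitted as missing calls (no DNA to hybridise); in carriers
  they are emitted hemizygous-as-homozygous. The latter reproduces a known
  array artifact: such markers can look Mendelian-inconsistent in trios,
  which is why the simulator's consistency guarantee (and its test) applies
  to markers outside the deletion.
* **Controls are unrelated founders**, not pedigree members: control
  genomes in such studies come from other projects and breeds. The control
  VCF is written as one multi-sample file; the privacy filter accepts
  either that or per-control files. Every shared site is forced to carry
  the alternate allele in at least one control, so "private" is never an
  artifact of sampling noise; the deletion locus window is kept
  variant-free in controls.
* **A second, non-causal deletion** (1.5 kb, 8 kb downstream of the causal
  one) is planted in the case and in ten controls so the reciprocal-overlap
  privacy filter is exercised by default.
* **Read pairs** are a flat mapping-record table (fragment, mates,
  orientation, mapq — SAM-subset semantics): the caller consumes positions
  and orientations only, so no sequences, base qualities or errors are
  simulated. Fragments are placed uniformly on each haplotype's contracted
  coordinate space; a read that would cross a breakpoint junction is
  dropped as unmappable (real pipelines would soft-clip or split-map it,
  and split-read evidence is out of scope here).

What the simulator does **not** emulate: linkage disequilibrium beyond
pedigree descent, genotyping error, population demography, sequencing error
and coverage biases. Passing tests therefore demonstrate correctness of the
algorithms under clean Mendelian descent, not robustness to every artifact
of real array or sequencing data.

## Homozygosity mapping

`detect_roh()` is an exact, run-based scanner, deliberately *not* a
sliding-window heuristic: a run is a maximal stretch of consecutive markers
that begins and ends with a homozygous call, contains at most
`max_het_per_run` heterozygous and `max_missing_per_run` missing calls, and
never jumps an inter-marker gap above `max_gap_bp`; runs shorter than
`min_markers` markers or `min_length_bp` bp are discarded. Runs are chosen
greedily left to right (leftmost start, longest admissible extension), so
reported segments never overlap and the output is deterministic and
checkable: the tests compare it against a brute-force quadratic window
enumeration on matrices up to 500 markers. Defaults
(50 markers, 1 Mb, 1 het, 2 missing, 1 Mb gap) follow common dense-chip
homozygosity-mapping practice; the 1 Mb length floor is the conventional
threshold separating autozygosity from background homozygosity-by-state.

`exclude_parental()` subtracts, from each case segment, every interval
where either parent also runs homozygous, keeping novel pieces above a
length floor. Interval subtraction (rather than discarding any overlapping
case segment wholesale) retains genuinely novel sub-regions; the stricter
whole-segment behaviour is available via `mode = "drop"`. The pipeline runs
trio-style — detect in the case, exclude regions seen in either genotyped
parent, then intersect with candidate genes — and `shared_homozygosity()`
additionally intersects segments across multiple cases, keeping only
intersections where all cases are homozygous for the *same* allele at every
genotyped marker (a heterozygous or discordant call rejects the interval;
missing calls are skipped).

On the default cohort the detected ROH genome fraction of the affected
case comes out above the pedigree expectation of 25% (31% at the default
seed) because homozygosity-by-state extends and adds to the
identical-by-descent tracts — the same qualitative gap the trio design
anticipates between expected autozygosity and observed array
homozygosity. Note the realized IBD fraction of a single simulated
individual is itself random with a standard deviation of roughly 0.07
around F, so individual replicates can fall below 25%.

## Private-variant filtering

The three small-variant filters are pure set operations and therefore
commute (a property the tests check on random tables): homozygous-alternate
with FILTER `PASS`/`.` in the case; alternate allele unobserved in every
control at any zygosity (missing control genotypes do not count as
observations — absence of evidence is not evidence of absence, and
counting `./.` as REF would manufacture false "observations"); and position
inside a mapped region. Multi-allelic records are decomposed to biallelic
ones first so privacy is per-allele. Each surviving record carries its
accumulated `reasons` string as an audit trail, and region restriction
annotates the overlapped candidate gene and CDS status.

## Deletion calling from read pairs

The caller uses insert-size discordance only:

1. `fit_insert_model()`: location = median apparent span (outer distance)
   of FR pairs, scale = 1.4826 × MAD. Median/MAD make the fit robust to a
   contaminating discordant fraction of ~10%; at least 50 FR pairs are
   required and a zero MAD is rejected as degenerate.
2. `find_discordant()`: FR pairs with span strictly greater than
   location + k·scale (default k = 3) and mapq ≥ 20. Non-FR orientations
   carry no deletion signal.
3. `cluster_discordant()`: each discordant pair implies a candidate deleted
   interval — its unread inner gap. Single-linkage clustering joins
   overlapping implied intervals; clusters are then *span-consistency
   trimmed*: all pairs from one deletion share span ≈ insert + size, so
   members deviating more than k robust SDs from the cluster's median span
   are insert-tail contaminants and are removed before breakpoints are
   computed. A cluster whose implied intervals have an empty common
   intersection is split greedily along start-sorted pairs. The breakpoint
   interval is the intersection of the implied intervals (it provably
   contains the true breakpoints when all members stem from one event), and
   the size estimate is mean span − location. Defaults: minimum support 3
   pairs; minimum estimated size 300 bp — a conventional minimum SV length
   that keeps chance clusters of insert-tail pairs (estimated sizes
   ~3 robust SDs) out of the call set. Size estimation carries a small
   positive length-bias (longer fragments span a junction more often,
   ~+9 bp at the default library), comfortably within the ±2 bp·scale/√n
   band the tests assert.
4. `genotype_deletion()`: the support ratio is r = D / (D + C), D the
   discordant pairs whose implied interval contains the call and C the
   *mean over the two breakpoints* of concordant pairs whose inner gap
   crosses that breakpoint. Counting inner-gap crossings gives concordant
   and discordant evidence the same per-junction detection window, and
   averaging the two breakpoints recognises that one discordant pair spans
   the single junction while each concordant pair crosses one breakpoint;
   a naive "concordant crossing either breakpoint" denominator would
   double-count reference evidence for deletions longer than the insert and
   pin heterozygous calls at r ≈ 1/3, on the decision boundary. With the
   averaged denominator, expectations are r ≈ 1 (hom), ≈ 0.5 (het). Depth
   corroboration d compares coverage inside the call with the flank mean.
   Thresholds (hom: r ≥ 0.8 and d ≤ 0.2; het: 0.3 ≤ r < 0.8 and
   0.3 ≤ d ≤ 0.7) are config-exposed constants; anything else is reported
   `ambiguous` with its numbers, never silently forced into a genotype.
5. `private_deletions()`: a case call is non-private when some control call
   matches it at ≥ 50% reciprocal overlap — the community-standard SV
   equivalence rule; reciprocality stops a large control CNV from erasing a
   small nested case call.

Every call retains its supporting fragment ids (`supporting_pairs()`), the
programmatic analogue of eyeballing the alignment in a genome browser, and
calls export as VCF symbolic `<DEL>` records (POS = start − 1 anchor-base
convention, INFO END/SVLEN/PE).

## Consequence classification

Coordinates are 1-based inclusive throughout (HGVS g. convention);
BED input/output converts at the boundary, centrally and tested both ways.
`deletion_length(start, end) = end − start + 1`. Classification is
strand-aware: the translation start is the first three *coding* bases in
translation order (walking exons, which handles codons split across exons),
and `start_lost` requires only that the deletion intersect any of those
three bases — disrupting one base of the codon is as disruptive as removing
all three. Class priority is start_lost > exon_loss (a whole exon
contained) > cds_truncation (any coding overlap) > intronic > upstream
(within 2 kb 5′ of the transcript, config-exposed) > intergenic; a
chromosome mismatch warns and returns intergenic. Deletions overlapping
only non-coding exon sequence without containing the exon are reported
intronic — a vocabulary simplification, documented here. Deleted coding
bases are counted inclusive of the start codon.

`downstream_start_rescue()` scans the remaining coding sequence 5′→3′ for
the first ATG in the *original* reading frame and reports its offset from
the lost start plus the fraction of wildtype CDS removed up to it; with no
in-frame ATG left it reports total loss. The bundled synthetic transcript
places the second in-frame ATG at offset 900 of a 3,600 nt CDS, so the
rescue analysis reports a truncated protein lacking 25% of the wildtype —
mirroring the geometry of the motivating study.

`predict_genotyping_bands()` models the three-primer diagnostic PCR: each
wildtype allele yields F+Rev1 (Rev1 sits inside the deletion; the F+Rev2
wildtype product is too long by design), each deleted allele F+Rev2, and a
diploid genotype shows the union — one band for wt/wt, one for del/del, two
for carriers. All six ordered allele pairs are tested exhaustively.

## Problem sizes and determinism

Default analysis sizes were chosen so a full cohort simulation plus
pipeline runs in seconds and the complete test suite in about a minute:
58,000 markers, 417 case small variants, ~140,000 read pairs across 44
genomes, 1,000 gene-drop replicates, 100 seeded caller replicates. Every
stochastic component takes an explicit seed and is bit-reproducible; the
cohort writer's outputs hash identically across runs of the same
configuration.

## Known limitations

* Kinship is pedigree-based only; genomic relationship matrices and
  likelihood-based segregation analysis are out of scope.
* ROH detection is not a bit-for-bit reimplementation of the windowed
  heuristics of common association toolkits; it is an exact run definition
  chosen for oracle-checkability, and parameter choices (not published for
  the motivating analysis) are conventions.
* Only deletions are called — no duplications, inversions, translocations,
  split-read refinement or depth-only CNV segmentation; breakpoints are
  reported as intervals, not base-pair exact.
* The X chromosome, imprinting and compound heterozygosity are not
  modelled.
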