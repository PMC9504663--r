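---
title: "Methods: probe specificity screening and map-order concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probe specificity screening and map-order concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tyrfish)
```

This vignette documents the models, parameter choices and numerical
conventions behind `tyrfish`, in the order the pipeline runs them. It states
design rationale only; every empirical number it mentions is computed by the
test suite or by `scripts/acceptance.R`, not asserted here.

## Coordinates

All intervals are 0-based, half-open, on a named sequence — the BED
convention. One internal convention avoids off-by-one drift between the
FASTA, BED and report layers; 1-based closed coordinates appear only in
human-readable output. Sequence case is meaningful end to end: lowercase is
soft-masked repeat, `N`/`n` hard-masked, and both survive file round-trips
byte-for-byte (which is why ingestion uses a case-preserving FASTA reader).

## Transcript placement

Markers on a transcriptome linkage map are transcript sequences; the probe
is designed on the *genomic* gene sequence so there is room for a 1–4 kb
product. `place_transcript()` is a deliberately small spliced-alignment
stand-in: exact k-mer seeds (default `k = 13`, non-overlapping on the query)
are chained colinearly by dynamic programming, allowing a genomic gap of up
to `max_intron` (default 5,000 bp — generous for typical plant introns)
between consecutive seeds and only 50 bp of query-side slack. The chain
score is `k` times the number of chained seeds; the locus is the chain's
genomic span extended to the full query footprint. A production pipeline
would use a dedicated spliced aligner; the contract here (best locus,
second-best score, ambiguity flag) is what the rest of the pipeline
consumes, and an external placement can be substituted at that interface.

A placement is **ambiguous** when the second-best locus (another sequence,
the other strand, or a non-overlapping region of the same sequence, found by
peeling the best chain's seeds and re-chaining) scores at least
`ambiguity_ratio` (default 0.95) of the best. The threshold is a
reconstruction choice: "mapped ambiguously" is not quantified in the
methodology this package implements, and 0.95 is conservative — an exact
duplicate always trips it, a 5 %-diverged paralog usually does at this seed
size. It is exposed in `tyr_config()`.

Markers are then partitioned by three exclusion filters, each with a
machine-readable reason: `no_protein_annotation` (protein-coding evidence is
carried as an input flag; this package does not run a protein-database
search), `ambiguous`/`unplaced`, and `wrong_chromosome` (best placement not
on the expected chromosome's sequences). Partitions are exhaustive and
disjoint, which the tests assert as a conservation property.

## Hard-mask screening and primer design

A gene sequence containing a run of at least `max_N_run = 10` consecutive
`N` is discarded: long `N` runs are collapsed repeats or assembly gaps,
while isolated ambiguities are tolerated. The run-length threshold is this
package's operationalisation of "hardly masked" — the source methodology
does not quantify it.

`propose_primer_pairs()` is a transparent, dependency-free ranking model
standing where a dedicated primer-design tool would sit. Primers are 18–27
nt (optimum 20), hard-constrained to 40–60 % GC and to contain no masked
base; Tm uses the long-oligo rule `Tm = 64.9 + 41·(GC − 16.4)/L` (°C).
A primer's penalty is `|Tm − 60| + 0.5·|GC − 50| + |L − 20|`; a pair adds
`|product − 2500|/500`, centring products in the 1,000–4,000 bp window. The
weights make 1 °C of Tm deviation, 2 GC points, 1 nt of length and 500 bp of
product deviation equally costly — a plain, documented trade-off rather than
a thermodynamic model (no duplex/hairpin screening; see Limitations).
Candidates are evaluated on a 25 bp anchor grid, which keeps the search
deterministic and O(grid²); the best `n_pairs = 5` pairs with distinct
anchors are returned in penalty order. Products containing *any* masked base
(soft or hard) are extracted but flagged `discarded_masked`: with
signal amplification of up to a thousandfold, even a short repeat tract in
the probe can light up the whole genome.

## The specificity screen and the dangerous-hit rule

`scan_genome()` is an internal seed-and-extend local aligner (exact 13-mer
seeds → positional clustering → full Smith–Waterman extension of each
cluster window, implemented in C++ with unit match/mismatch and a linear −2
gap). Reporting floors (`min_report_len = 50` aligned columns) replace
E-value statistics: the downstream rule consumes only identity and aligned
length, so those are reported explicitly. A window extends 200 bp beyond a
cluster's outermost seeds; any alignment worth reporting at the thresholds
below contains intact 13-mers every few tens of bases in expectation, so the
margin costs nothing in sensitivity while keeping extensions small. Users
with an established search engine can skip `scan_genome()` entirely and feed
tabular hits straight to `classify_dangerous()`.

A hit is **dangerous** when it lies outside the probe's own product interval
(≥ 1 bp overlap defines "own locus") and *strictly* exceeds 80 % identity
and 100 bp aligned length. The identity cutoff equals the hybridization and
washing stringency used for single-copy visualisation (80–82 %): a duplex
below the stringency's stability threshold washes off, so only alignments
above it can generate signal. `stringency_identity_threshold()` documents
that pass-through. Per gene, candidates are ranked ascending by
`(dangerous_count, total off-target aligned bases, primer penalty)` — the
first key is the published selection rule; the two tie-breaks are this
package's choice, preferring the probe with less total off-target homology
and then the better primer pair. A gene whose only candidate still has
dangerous hits is selected with an explicit warning flag rather than
silently dropped.

## Cytogenetic positions

RPHC (relative position of the hybridization site on the chromosome arm) is
`100·d/arm_length`, 0 at the centromere and 100 at the telomere; positions
aggregate as the sample mean and sample SD (n − 1) over non-overlapping
measured chromosomes. A single measurement reports SD 0.0 with a low-n
warning, matching how position tables always print an SD. Detection
frequency is `100·detected/analyzed`, rounded to one decimal in reports
(full precision is kept internally; RPHC/FL round to one decimal only in
report output, matching table precision).

The detection-frequency **denominator is configurable** (`metaphases`,
default; `chromosomes` = 2 per metaphase; `sites` = 4 chromatids): published
frequencies are not always expressible as k/metaphases for integer k, so the
package exposes the convention instead of guessing it.

FL (fractional length) places a signal on the whole chromosome, measured
from the short-arm telomere: `FL = f_s·(100 − RPHC)` on the short arm and
`FL = 100·f_s + (1 − f_s)·RPHC` on the long arm, with `f_s` the short-arm
fraction. FL is strictly decreasing in RPHC on the short arm and strictly
increasing on the long arm, and `fl_to_rphc()` inverts it exactly (the
centromere maps to `arm = "centromere"`, RPHC 0). Arm fractions are inputs
(`karyotype` table); the packaged values — 0.335 for chromosome 2 and 0.40
for chromosome 6 — are reconstruction choices, flagged as such in the
fixture: they are not published values, but 0.335 reproduces the published
FL of 13.4 % for a short-arm marker at RPHC 60.0, and the *orders* the
concordance metrics consume are invariant to `f_s` within an arm.

## Map integration and the two discordance metrics

`physical_order()` sorts by ascending FL (idiograms are drawn short arm up);
ties break by marker id with a warning. `detect_orientation()` compares a
linkage group's cM against the physical FL by Kendall rank correlation over
shared markers (≥ 3 required; fewer is reported `undetermined`): negative
correlation means the published linkage-group orientation is upended and it
is reversed before comparison. Kendall is used because marker sets are small
(~10–20) and it depends only on ranks.

Discordance is quantified two ways, and `build_report()` always prints both:

* **rank mismatch** — markers whose ordinal rank differs between the orders;
* **minimal removal** — the fewest markers to delete so the remaining orders
  are identical, computed as n minus the longest strictly increasing
  subsequence (LIS) of one order's ranks along the other.

Minimal removal never exceeds rank mismatch (deleting all rank-mismatched
markers trivially reconciles the orders), both are zero exactly for
identical orders, and both are invariant under simultaneous reversal and
relabeling — all property-tested, with the LIS route verified against
brute-force subset enumeration (exhaustively for all permutations to n = 8,
and on 200 random permutations to n = 12). Two metrics are first-class
because published "wrong position" counts are reproduced by *different*
rules on the two packaged chromosomes: rank mismatch yields chromosome 2's
3/12 and 3/13, minimal removal yields chromosome 6's 4/11 and 3/11, and
neither rule reproduces the other chromosome's counts. Reporting both,
labelled, avoids silently picking one and misreporting the other case.

Pseudochromosome positions are consumed as 1-Mbp bin numbers; markers
sharing a bin keep input order and are flagged as ties. Per map pair,
markers missing either coordinate are excluded from that pair only (the
mlh1 gene, absent from the genetic map, drops out of genetic comparisons but
not pseudochromosome ones) and listed in the report.

## Packaged tables

The `load_paper_fixture()` tables transcribe the published onion chromosome
2/6 results: every printed cell is carried verbatim, and cells the source
does not print (most cM values and Mbp bins, which appear only as figure
orders) are monotone interpolations that preserve the stated orders, each
flagged `interpolated` in a `*_source` column. One marker's genetic rank is
taken from the published figure order since its cM value is not printed, and
the mlh1 gene's pseudochromosome bin is placed concordantly between its
physical neighbours, consistent with the published discordance count. Only
the identical-sequence rows of the probe length/identity table are
recomputable here (the diverged identities come from chromatograms that are
not published); `percent_identity()` — global alignment, +1/−1/−2 linear
gaps, identity over all aligned columns including gaps — reproduces the
100 % rows and is oracle-checked against an independent implementation for
the rest of its range.

## The synthetic-data generators

`generate_genome()` emulates the features the pipeline must survive in a
real plant genome, at toy scale: multi-exon genes (placement must chain
across introns), soft-masked tandem and dispersed repeat families (masking
filters must fire), and diverged paralogs (the screen must flag them). The
default scale — 2 chromosomes × 200 kb, 20 genes, 2 repeat families, 10 %
paralog rate at 5 % divergence — exercises seeding, masking and screening
while keeping a full design run at seconds-to-a-minute scale; unit tests use
1 × 30 kb genomes. `generate_genetic_map()` integrates a recombination-rate
profile along the physical axis (rate × factor inside suppressed zones, so a
factor-0 zone collapses its markers to one cM), adds Gaussian cM noise, and
can emit the map upended or with planted marker swaps.
`simulate_signals()` draws per-metaphase detection (probability
`detection_p`) and per-homolog RPHC measurements (truth + Gaussian noise,
clipped to [0, 100] with clip events counted). All generators are
deterministic functions of their seed and emit truth tables sufficient to
score every downstream module.

What the generators do **not** emulate: real repeat families (specific
retrotransposon or satellite structure), indel divergence between paralogs
(substitutions only), strand-asymmetric gene placement, chimeric or
misassembled scaffolds, and measurement error structure beyond i.i.d.
Gaussian noise. Passing tests therefore show the machinery is correct on
data matching its assumptions, not that the biological thresholds (80 %,
100 bp) are optimal for any particular genome.

## Numerical conventions and degenerate inputs

* Alignment scores are unit match/mismatch with linear gap −2 throughout;
  identity is always `100·matches/aligned columns` including gap columns.
* Co-optimal alignments may differ in match count at equal score; tests
  therefore pin scores exactly and identities to a small band.
* `N` never matches anything, including another `N`.
* Empty inputs: a transcript with no seed hits is an "unplaced" result, not
  an error; a probe with no seeds returns an empty hit table; a gene below
  the minimum product returns an empty pair table with a reason attribute.
* Percentages print to one decimal; internal values are full precision.
* Seeds: every stochastic generator takes an explicit integer seed and
  restores the RNG state afterwards; pipeline outputs embed the package
  version, a config hash and the seed, so reruns are byte-identical.

## Limitations

The placement and screening stages are honest small-genome implementations:
quadratic seed chaining and full window Smith–Waterman are fine at the tens
of megabases this package targets for validation work, but a gigabase
genome calls for an external aligner and search engine behind the same
interfaces (both accept external results). Primer ranking ignores duplex
thermodynamics, hairpins and primer-dimer interactions. Orientation
detection assumes a mostly monotone relationship between maps; a linkage
group scrambled beyond recognition returns a low-confidence flip decision
with no significance statement, and the package deliberately offers no
statistical test of discordance. Scaffold re-ordering — feeding the
discordance evidence back into an assembly — is out of scope.
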