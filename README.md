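# tyrfish

Design genome-wide specific Tyr-FISH probes and integrate the resulting
cytogenetic positions with genetic and pseudochromosome maps.

## The problem

Chromosome-scale assemblies of large, repeat-rich plant genomes (onion's is
~16 Gb) are anchored into pseudomolecules with genetic linkage maps. Linkage
maps order markers by recombination frequency, so in regions where crossing
over is suppressed — pericentromeric and subtelomeric heterochromatin — the
genetic order can be compressed or scrambled relative to the physical
chromosome, and the pseudochromosome inherits those errors. Tyramide signal
amplification FISH (Tyr-FISH) can visualise a ~1 kb single-copy sequence
directly on a metaphase chromosome, giving an independent physical order of
markers that can verify (or correct) the assembly.

`tyrfish` is for researchers doing exactly that: it covers the dry-lab side
of the workflow end to end —

1. **Probe design** (`place_transcript()`, `filter_markers()`,
   `propose_primer_pairs()`, `extract_candidates()`): place a transcript on
   the genome by chained exact k-mer seeds (intron-tolerant), drop markers
   without protein annotation, with ambiguous placements, or on the wrong
   chromosome, design primer pairs for 1–4 kb products, and discard
   candidates touching repeat-masked sequence.
2. **Specificity screening** (`scan_genome()`, `classify_dangerous()`,
   `rank_candidates()`): an internal seed-and-extend Smith–Waterman screen
   of every candidate against the whole genome. An off-target hit with
   identity > 80 % and aligned length > 100 bp is *dangerous* — at the
   80–82 % washing stringency used for single-copy Tyr-FISH it can produce
   non-specific signal. The probe with none, or the fewest, dangerous hits
   is selected per gene.
3. **Cytogenetic positions** (`compute_rphc()`, `aggregate_position()`,
   `rphc_to_fl()`): turn per-metaphase signal measurements into table rows.
   RPHC is the centromere-to-signal distance as a percentage of the arm
   (mean ± SD over non-overlapping chromosomes, plus detection frequency);
   FL (fractional length) converts RPHC to a whole-chromosome coordinate
   measured from the short-arm telomere, with short-arm fraction *f*ₛ:

   - short arm: FL = *f*ₛ · (100 − RPHC)
   - long arm: FL = 100 · *f*ₛ + (1 − *f*ₛ) · RPHC
4. **Map integration** (`physical_order()`, `detect_orientation()`,
   `build_report()`): align the genetic (cM), physical (FL) and
   pseudochromosome (Mbp bin) orders, detect upended linkage groups by
   Kendall rank correlation, and quantify discordance with two metrics —
   the number of markers whose ordinal **rank differs**, and the **minimal
   removal** count (markers to delete so the orders agree; n minus the
   longest increasing subsequence). Both are reported because neither is
   canonical.
5. **Synthetic data** (`generate_genome()`, `generate_genetic_map()`,
   `simulate_signals()`): seeded generators for toy genomes with introns,
   soft-masked repeat families and diverged paralogs, genetic maps with
   recombination-suppressed zones, and noisy signal measurements, so the
   whole pipeline is testable offline.

The package also ships transcriptions of the published onion chromosome 2/6
Tyr-FISH tables (`load_paper_fixture()`), used below and by the test suite.

## Worked example

Integrate the packaged chromosome 6 tables:

```r
library(tyrfish)

entries <- fixture_map_entries(6)   # marker_id, cM, FL, arm, Mbp bin
report  <- build_report(entries)
report
#> Map-order concordance report (11 markers)
#>
#> # A tibble: 3 × 8
#>   map_pair            comparable n_shared orientation_flipped rank_mismatch_count
#>   <chr>               <lgl>         <int> <lgl>                             <int>
#> 1 genetic_vs_physical TRUE             11 TRUE                                  6
#> 2 genetic_vs_pseudo   TRUE             11 TRUE                                  2
#> 3 pseudo_vs_physical  TRUE             11 FALSE                                 7
#> # ℹ 3 more variables: rank_mismatch_pct <dbl>, min_removal_count <int>,
#> #   min_removal_pct <dbl>
```

`orientation_flipped = TRUE` for the genetic map: linkage group 6 was
published upended (its distal-cM markers sit on the physical short arm), so
it is reversed before comparison. After the flip, 4 of 11 markers
(`min_removal_count`, 36.4 %) must be removed to reconcile the genetic order
with the physical chromosome, and 3 of 11 (27.3 %) to reconcile the
pseudochromosome — about a quarter of the tested scaffolds sit in the wrong
place. `tidy(report)` returns the table, `glance(report)` a one-row summary,
`discordant_markers(report)` per-marker flags, `autoplot(report)` the
three-column map-alignment figure.

The physical order itself comes from sorting by FL, e.g. for chromosome 2
(short-arm fraction 0.335):

```r
pos2 <- load_paper_fixture("positions_chr2")
head(physical_order(pos2, 0.335)[, c("probe_id", "arm", "rphc_mean", "fl")], 5)
#> # A tibble: 5 × 4
#>   probe_id       arm   rphc_mean    fl
#> 1 Unigene23526   short      79.6  6.83
#> 2 Unigene10061   short      67.7 10.8
#> 3 CL5148.Contig1 short      67.3 11.0
#> 4 Unigene572     short      60.6 13.2
#> 5 Unigene28076   short      60   13.4
```

Unigene28076 sits first on the genetic map (5.9 cM) but only fifth on the
chromosome (FL 13.4 %) — the short-arm subtelomeric discordance that motivates
the whole exercise.

A shell front-end wrapping the same functions lives at
`inst/cli/tyrfish.R` (subcommands `design`, `positions`, `integrate`,
`simulate`, `fixtures`).

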