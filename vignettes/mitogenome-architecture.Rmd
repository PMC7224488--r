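---
title: "Methods: composition, codon usage and architecture of insect mitogenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composition, codon usage and architecture of insect mitogenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoarch)
```

## Scope and model

When a new insect mitochondrial genome is sequenced, the descriptive
analysis that accompanies it is highly standardized: nucleotide composition
and strand skews, codon usage and relative synonymous codon usage (RSCU),
start/stop codon tables, the profile of gene overlaps and intergenic
spacers, gene-order comparison against relatives, the motif structure of the
A+T-rich control region, and a multi-gene phylogeny. `mitoarch` implements
this battery as testable, reusable functions over a single container, the
`annotated_genome`: an ordered table of features on a circular molecule,
with or without its sequence.

Conventions every module relies on:

* **Coordinates** are 1-based and fully inclusive; a feature spanning
  `start..end` has length `end - start + 1`. Origin-spanning (wrap-around)
  features are rejected — they do not occur in the compact lepidopteran
  layouts this package targets, and allowing them would make junction
  arithmetic ambiguous.
* **Strands** use the mitochondrial J/N vocabulary (majority / minority
  coding strand), with F/R and +/− accepted as aliases on input.
* **Gene names** are resolved against a controlled vocabulary (13 PCGs, 22
  tRNAs with trnL1/trnL2 and trnS1/trnS2 distinguished, rrnL, rrnS, control
  region) through an editable synonym table, because GenBank records are
  heterogeneous ("COX1", "CO1", "l-rRNA", "tRNA-Leu(CUN)", ...). Unknown
  names are kept with a warning rather than dropped, so imperfect
  annotations remain visible.

## Junction accounting

With inclusive coordinates the signed gap at a junction is

```
gap = downstream$start - upstream$end - 1
```

positive for an intergenic spacer, negative for an overlap, zero for
abutting genes. Accounting is **linear from the first feature**: the
wrap-around junction closing the circle is computed and reported, but
excluded from the summary tallies. This is the only reading under which the
junction counts of published organization tables (whose first feature
starts at base 1 and whose control region ends at the genome's last base)
are reproducible. Overlap totals sum magnitudes; ties for "longest spacer"
are broken by genome position, and the full ranked list is exposed so ties
are visible.

Published tables carry their own parenthesized gap column; the readers keep
it as `printed_gap`, and `summarize_adjacencies(..., source = "printed")`
reproduces the published accounting while `cross_validate_gaps()` lists
junctions where the printed value and the coordinates disagree. The bundled
*Dendrolimus houi* table contains exactly one such junction (rrnL→trnV:
coordinates give −1 where the table prints 1), so its text-level tallies
(7 overlaps / 25 bp, 23 spacers / 372 bp) are reproducible only from the
printed column, while recomputation gives 8 / 26. Both views are reported
deliberately; neither is "corrected".

## Composition and skews

Strand asymmetry is measured by the standard skews

```
AT-skew = (A - T) / (A + T),   GC-skew = (G - C) / (G + C)
```

computed on the stored J-strand orientation by default (the convention
under which whole-genome values are reported in the literature; the skew of
a reverse complement flips sign). A skew with a zero denominator is NA, not
an error. Ambiguity codes are counted in `n_other`, included in the
percentage denominator, and excluded from skew denominators. For reports,
percentages are conventionally rounded to 2 decimals and skews to 4; the
objects always carry full doubles.

One numerical note: for the bundled published counts (G = 1175, C = 1923),
(G−C)/(G+C) evaluates to −0.2414 at four decimals. The source text prints
−0.2417, which is not reproducible from its own counts; the package reports
the recomputed value.

Codon-position A+T content pools codons across all coding sequences
(not per-gene averaging), takes each CDS in reading orientation, and drops
incomplete trailing codons.

## Codon usage and RSCU

The single source of truth for codon semantics is NCBI translation table 5
(invertebrate mitochondrial): AGA/AGG encode Ser, ATA Met, TGA Trp, leaving
TAA/TAG as the only stops and 62 sense codons.

* **Start codons** are simply the first annotated triplet — annotation
  boundaries are trusted, with no ORF re-scanning.
* **Stop classification**: a CDS whose length mod 3 is 1 (resp. 2) ending
  in `T` (resp. `TA`) has an *incomplete* stop, completed to UAA by
  polyadenylation in vivo. Otherwise the final in-frame triplet must be
  TAA/TAG; anything else is flagged `nonstandard_stop` rather than raising
  an error, since published tables show such heterogeneity is tolerated and
  worth surfacing.
* **RSCU** follows the Sharp & Li convention: a codon's count divided by
  the mean count of its full synonymous family (6 leucine codons, 8 serine
  codons under table 5). Family sums therefore equal the degeneracy exactly
  for observed families. The reporting labels Leu1 (CUN), Leu2 (UUR),
  Ser1 (AGN), Ser2 (UCN) are kept because RSCU tables in the mitogenome
  literature use them, but they do not define separate families.
* Codons containing ambiguity codes are excluded from usage and RSCU and
  tallied separately.

A known annotation pathology is handled explicitly: a CDS whose length is
divisible by 3 cannot end in a single-T stop, whatever a published table
says. The implementation trusts the coordinates, reports the derived
classification, and leaves the conflict visible instead of forcing either
reading.

## Gene order comparison

A genome's signed order is rotated to start at trnM (the conventional first
gene in these genomes; absence yields a warning, not an error) and compared
via circular adjacency signatures in which strand is part of the signature
— an inversion between the same neighbors is a change. Comparison is
duplicate-aware: genes duplicated or missing on either side are reported as
such and removed before breakpoints are counted, so a tRNA duplication
(e.g. the second trnR known from *Kunugia undans*, bundled as a fixture) is
reported as a duplication, not as spurious breakpoints. This gene-level
comparison stands in for sequence-level collinear-block analysis: "no
rearrangement" means zero breakpoints here.

## Control-region scanning

`scan_control_region()` reports exact motif hits (default `ATAGA`, the
conserved element preceding the origin of replication in lepidopteran
control regions), maximal poly-T runs of at least `min_polyT` bp, and
maximal tandem arrays of given units (default AT and AAT, the
microsatellite-like repeats typical of this region) with at least
`min_repeat_copies` copies. The literature highlights runs of ~14 bp but
states no threshold, so the default `min_polyT = 10` is an exposed
parameter, not a claim. Runs and arrays are maximal by construction
(regex-greedy / run-length encoding), and a property test verifies no
reported poly-T run is extendable.

## The distance phylogeny stand-in

Full ML/BI inference (alignment, trimming, model selection, RAxML/MrBayes)
is out of scope. The module instead exercises the supermatrix plumbing and
provides a falsifiable topology check:

* `build_supermatrix()` concatenates pre-aligned per-gene blocks in the
  canonical genome order of the 13 PCGs from trnM, recording partitions;
  `drop_gapped = TRUE` removes every column containing a gap — a
  transparent complete-deletion stand-in for alignment trimming, with
  partitions remapped so they still tile.
* `k2p_distance()` implements the Kimura 2-parameter closed form over
  pairwise-complete unambiguous sites; saturation returns Inf with a
  warning instead of silently clamping.
* `nj_tree()` is canonical Saitou–Nei neighbor joining with deterministic
  tie-breaking (lowest index pair) and negative branch lengths clamped to
  zero with a warning, so runs are bit-reproducible.
* `rf_distance()` is the Robinson–Foulds symmetric difference; it is backed
  by `phangorn::RF.dist` behind the package surface, and the test suite
  checks it against an independent bipartition-enumeration oracle.

NJ correctness is tested two ways: against a brute-force oracle that
enumerates all unrooted topologies (n ≤ 6) and picks the least-squares-fit
winner on additive matrices, and by topology recovery on sequences
simulated along a fixed 7-taxon reference tree (six ingroup taxa plus a
distant outgroup; internal branches 0.02–0.05, tips up to 0.15
substitutions/site, 2,000 bp, K2P with kappa 2, 100 seeded replicates,
pass mark ≥ 95% RF = 0). The 2,000 bp length was fixed in advance as a
desk-scale surrogate for a trimmed PCG concatenation.

## The synthetic genome generator

`generate_mitogenome()` realizes a `sim_spec()` exactly and returns the
genome together with truth metadata, making every analysis stage testable
offline. The default spec is the stated world the analyses assume:

* the 37-gene arrangement from trnM with the conserved lepidopteran strand
  pattern, ~15.4 kb;
* a junction plan with 8 overlapping junctions (deepest 8 bp) and a 60 bp
  spacer ahead of COI, mirroring a real compact layout;
* per-gene start/stop codons including CGA for COI and incomplete T / TA
  stops, with gene lengths arithmetically consistent with their stop
  (`length mod 3 = 1` for single-T stops) — inconsistent specs are rejected
  at construction;
* A+T target 0.80. Non-coding filler and RNA genes are i.i.d. at the
  target; PCG bodies are drawn from a codon-weight vector. Because the
  AT-richest codons (TAA/TAG) are excluded from the sense pool, a naive
  independent-base weighting would undershoot the target by ~0.7 points, so
  the default weights tilt the per-base probability (one `uniroot` call at
  spec build) until the sense-codon mixture's expected A+T equals the
  target. Realized A+T is then within ±0.01 of the target at full length;
* a control region carrying an ATAGA motif, a 14 bp poly-T run, and four
  AT/AAT tandem arrays. Single non-extending guard bases flank planted
  elements so they stay maximal, and filler is deterministically scrubbed
  of spurious motif hits, ≥10 bp T-runs and ≥3-copy arrays, so the scanner's
  output equals the planted truth exactly.

**Overlap semantics.** In overlapped bases the downstream gene's sequence
takes precedence; the upstream gene's final bases are whatever the overlap
imposes. This mirrors biology (overlapping genes share sequence; stops
truncated by a neighbor are completed post-transcriptionally) and
deliberately exercises the incomplete/nonstandard stop detector. A planted
stop under a 3' overlap can therefore be rewritten: the truth metadata
records both the planned and the realized codons, exact planned-codon
recovery is asserted on overlap-free plans, and realized-codon recovery on
the default plan.

`evolve_sequences()` simulates per-site substitution along a tree under K2P
(closed-form transition probabilities) or an equal-rates model with
arbitrary base frequencies ("jc"; AT-biased frequencies mimic mitochondrial
composition). All randomness flows through one seed; identical seeds give
byte-identical output.

**What the generator does not emulate** — and hence what a green test does
not establish: real strand-specific skew structure (filler is A/T- and
G/C-symmetric, so simulated genomes have near-zero skews, unlike the strong
negative GC-skew of real J-strands); selection-driven codon bias beyond a
composition target; tRNA/rRNA secondary structure; indel evolution,
recombination and heteroplasmy; and annotation error, since the generator's
annotation is true by construction. Green acceptance on synthetic data
establishes internal consistency of the pipeline, while the bundled
published coordinate tables anchor the junction, length and composition
statistics to real printed values.

## Degenerate inputs and numerical choices

Empty sequences, empty usage tables, empty junction sets and CDSs shorter
than 6 nt raise errors (an all-zero junction summary is available behind
`allow_empty`). Unsorted feature tables are auto-sorted with a warning.
Zero-denominator skews are NA; saturated K2P distances are Inf; NJ clamps
negative branch lengths to zero; all report rounding (2 dp percentages,
4 dp skews) happens only at the formatting layer.

## Known limitations

* The GenBank reader targets single-record mitogenome flat files; `join`
  locations are collapsed to their covering span with strand preserved.
* One bundled organization table is internally inconsistent at one junction
  (see above), and its published tRNA total length (1,475 bp) disagrees
  with the sum of its tRNA feature lengths (1,477 bp); neither is
  reconciled — the package computes from coordinates and keeps the printed
  column visible.
* The phylogeny module is a sanity check, not an inference engine; with
  real, strongly heterogeneous data NJ on K2P distances can differ from
  model-based trees.
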