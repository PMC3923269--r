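---
title: "Methods: analysing sequential-enrichment SynE screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing sequential-enrichment SynE screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synescreen)
```

## The screen and its data

A synthetic-element (SynE) library embeds two independent 12-nt random
cores in fixed flanks (`TCC…GAA`, `ATG…ACT`) separated by a constant
20-bp spacer, upstream of a minimal promoter and reporter. Sequential
rounds of transfection, Pol II ChIP (targeting the Ser-5-phosphorylated
CTD of initiating polymerase) and re-cloning enrich the library for
elements that support transcription. Samples taken before and after
enrichment are barcoded and sequenced as short paired-end reads: the
forward mate covers the left arm, the reverse mate the right arm, and the
spacer is never read. `synescreen` turns these reads into candidate
cis-regulatory elements through five analysis stages plus a simulator.

## Pre-processing

Demultiplexing requires an **exact** match between a sample barcode and
the first bases of the forward mate. No single-mismatch rescue is
attempted: with short (default 4-nt) barcodes, rescue would trade a small
gain in yield for cross-sample contamination, and an exact rule is
deterministic. Unassigned pairs are counted and dropped.

Core extraction is positional: after barcode trimming, the left window is
the *last* 18 nt of the forward mate and must match `TCC[ACGT]{12}GAA`;
the right window is the *first* 18 nt of the reverse-complemented reverse
mate and must match `ATG[ACGT]{12}ACT`. Fixing the flanks at fixed
positions rejects shifted or chimeric reads; requiring `[ACGT]` in the
cores rejects ambiguous base calls. Rejections are classified in a fixed
order — `too_short`, `flank_left`, `flank_right`, `ambiguous_base` — so
that accounting is deterministic; an N falling in a flank therefore
reports as a flank failure, an N in a core as `ambiguous_base`. The
package records, per sample, the raw assigned count, the extracted count
and the non-redundant (unique-key) count, and derives
`% unique = 100 · n_unique / n_filtered`.

Percentages are rounded **half-up to one decimal** (`round_half_up()`),
not banker's rounding, matching how such summary tables are customarily
printed.

## Frequency-guided Hamming-1 clustering

Sequencing errors scatter a truly abundant element into a halo of
low-count variants at Hamming distance 1. The clustering stage reassigns
such variants to their source using frequencies only — no base-quality
model — which is appropriate here because every library molecule is by
construction a legitimate sequence: a quality-based test cannot
distinguish a rare true element from an error, but a large count
imbalance between single-mismatch neighbours can.

The rule is deliberately fully deterministic. Unique keys are processed
in descending count, ties broken lexicographically. Each key's parent is
the Hamming-1 neighbour present in the table with **strictly greater**
count, choosing the neighbour of maximal count and, among equals, the
lexicographically smallest. Keys with no such neighbour are cluster
roots. Children can themselves be parents, so clusters are trees, not
stars; counts increase strictly along every child-to-parent edge, so the
root is the unique maximum of its cluster and acts as its
*representative*. The *cumulative frequency* is the sum of member counts.
Equal-count neighbours never merge: with no quality information, there is
no evidence for choosing a direction, and a strict inequality keeps the
output independent of input order.

`% clustered = 100 · (n_unique − n_clusters) / n_unique` summarises how
much of the unique-sequence set was absorbed: near zero for a random
library, rising steeply under selection. Representatives are compared
across samples by exact 24-nt identity as a full Venn partition
(`common_representatives()`).

Neighbour lookup hashes all 72 single-base variants of each key
(24 positions × 3 alternatives) against the key table, giving O(72·U)
work; the test suite checks this implementation against a quadratic
all-pairs oracle on tables of up to 500 keys.

## k-mer enrichment

All length-k windows (k = 5–7 by default) **within** each 12-nt core are
counted; windows never span the core–flank junction or the two cores,
because flanks and spacer are constant in every element and would
dominate any ranking (`include_flanks = TRUE` exposes the alternative).
Counting is over the non-redundant sequence set by default — each unique
element votes once, so a single hyper-abundant element cannot masquerade
as a motif — with read-count weighting available as an option.

For k-mer *m*, with pseudocount α,

  f(m) = (count(m) + α) / (total + α·4^k),  ratio(m) = f_sample(m) / f_reference(m),

where the reference is the source sub-library the enriched sample
originated from (declared explicitly in the pipeline configuration, never
inferred). The default α = 1 keeps all ratios finite without materially
disturbing the ranking; α = 0 gives exact ratios for testing, with
reference-absent k-mers reported separately rather than as infinities.
Ties are broken by sample count, then lexicographically. No p-values are
attached: the analysis ranks ratios, and validation of candidates is
experimental.

## Coupled cores and MEME export

Because the two cores of an element are physically linked, a functional
core can be interrogated by the company it keeps:
`coupled_partners()` collects, for an anchor core on one side, every
partner core observed on the other side with summed counts, and
`export_meme_fasta()` writes the partners as 12-nt FASTA records for
external motif discovery with MEME. The package prepares MEME's input but
does not re-implement it.

## Known-motif annotation

Motif tables are two-column TSVs of named IUPAC patterns (a PLACE-style
layout; the bundled demo table carries the W-box `TTGACY`, GCC-box
`GCCGCC` and as-1 `TGACG`). Loading applies the database filter: patterns
longer than 14 nt are dropped and exact-duplicate patterns collapsed.
Scanning works on the 18-nt arms with flanks included — the real
construct contains the flanks, and motifs overlapping a flank boundary
are biologically real — with a cores-only mode available; arms are never
concatenated, since the spacer separates them in the construct. Both
strands are scanned by default (cis-elements act in either orientation);
minus-strand hits are located by matching the reverse-complemented
pattern, so they are reported at the plus-strand coordinate of the
leftmost matched base. Representatives with no database hit are labelled
`novel`.

## The simulator

`simulate_screen()` generates the data the analysis assumes, with the
truth recorded: a library of `n_elements` i.i.d. uniform core pairs;
per-element sampling weights equal to the product of the folds of planted
IUPAC motifs matching either core (plus strand), raised to the per-sample
number of enrichment rounds; a multinomial draw of `depth` reads per
sample; reads laid out in the construct geometry with the barcode at the
5' end of both mates; then independent per-base substitution (uniform
over the three alternatives) and N-conversion. Truth counts are recorded
before noise, so a zero-noise run must round-trip exactly through
demultiplex → extract → tally — the suite asserts equality to the read.

Default parameters, chosen once as a desktop-scale rendition of the
screened libraries:

| parameter | default | rationale |
|---|---|---|
| `n_elements` | 200,000 | the screen's ~10^6 elements, scaled down but kept well above `depth`, so sampling is sparse — the regime in which enrichment is visible in the non-redundant set |
| `depth` | 50,000 reads/sample | scaled from the 2–10 × 10^5 raw reads per sample |
| `read_length` | 36 nt | the screen's paired-end read length |
| barcode | 4 nt, both mates | the original barcode design is not public; this convention makes demultiplexing testable |
| `error_rate` | 0.01/base | typical substitution rate of that sequencing era; 12 fixed flank bases imply a pass rate of (1−e)^12 ≈ 0.886 at e = 0.01, which the suite verifies |
| `n_rate` | 0.001/base | occasional no-calls |
| planted motif | W-box `TTGACY`, fold 10 | the canonical defense-responsive element such screens recover |
| spacer/filler | `ACGT` cycled | extraction never reads it; any fixed sequence works |

What the simulator does **not** emulate: PCR duplicates and amplification
bias, indels, position- or quality-dependent error profiles, cross-sample
barcode hopping, and biological correlation between cores. Passing tests
on simulated data therefore demonstrate the correctness of the
arithmetic and the recoverability of planted structure under i.i.d.
substitution noise — not robustness to every artefact of real libraries.

## Problem sizes and determinism

The shipped tests and the acceptance script run simulations of
2×10^4–2×10^5 elements at depths of 4,000–50,000 reads, sizes chosen so
the whole suite completes in well under a minute on one core while
leaving the stochastic checks (pass-rate, planted-motif recovery) with
comfortable margins — the planted-6-mer check, for instance, expects the
motif in the top 3 of 4,096 ratios and in practice finds it at rank 1
with a ratio near 4.

Every random step is driven by one integer seed: the library from
`seed`, each sample's reads from a seed derived from `seed` and the
sample's position in the barcode table. Identical configurations produce
byte-identical files; the pipeline writes no timestamps into its outputs
so whole runs are reproducible byte-for-byte, which the suite checks with
checksums.

## Known limitations

* Clustering merges only at Hamming distance 1, as a single-pass
  frequency rule; a variant two errors away joins its cluster only via an
  intermediate one-error variant present in the table.
* The published screen's own rounding of its summary table is internally
  inconsistent in one cell; this package always rounds half-up to one
  decimal and does not attempt to reproduce that cell.
* Exact-match demultiplexing discards every barcode-mutated read
  (≈ 4% at 1% error with 4-nt barcodes); acceptable at these depths,
  conservative by design.
* `% unique` and k-mer frequencies depend on sequencing depth relative to
  library complexity; comparisons are meaningful between samples of
  similar depth, which the screen design provides.
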