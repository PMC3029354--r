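---
title: "Mapping intron insertion sites, hot spots and similar intron pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping intron insertion sites, hot spots and similar intron pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Spliceosomal introns in a gene family can be compared across species only
after their positions are expressed in a coordinate system that survives
sequence divergence. The standard device is the protein multiple alignment:
an intron interrupting a coding sequence after `cds_offset` coding
nucleotides has codon **phase** `cds_offset mod 3` and an **anchor
residue** `floor(cds_offset / 3)` (0-based) — the first residue any of
whose codon nucleotides lie downstream of the intron. The alignment column
of the anchor residue is the intron's **insertion site**, comparable across
species and paralogs. This package implements that mapping end to end for
multi-copy gene families (its defaults are tuned to the four core histone
families H2A, H2B, H3 and H4 in fungi, where two yeast lineages are
essentially intronless while filamentous ascomycetes and basidiomycetes are
intron-rich), plus two downstream analyses:

* **Hot spots.** Within a clade and a family, an insertion site is a hot
  spot when it carries at least one third of that clade's introns in the
  family. The fraction is compared with exact integer arithmetic
  (`3 * n_at_site >= n_total`), so a site holding exactly one third counts;
  floating-point comparison would misjudge the boundary. The denominator is
  all introns of that clade in that family — not per species and not pooled
  across families — because hot-spot counts are reported per family per
  clade.
* **Sequence-similar intron pairs.** Every unordered pair of introns is
  scored by Smith–Waterman local alignment with affine gaps; significance
  comes from re-scoring against shuffles of one sequence and fitting a
  Gumbel (extreme-value) distribution to the shuffled scores, in the manner
  of the classic PRSS procedure. Pairs below the E-value cutoff are
  classified as same site/same family, different site/same family, or
  different families, and tallied per species pair.

## The anchor convention

One uniform formula, `anchor = floor(cds_offset / 3)`, gives every intron
exactly one residue: a phase-0 intron anchors to the residue following the
junction, phase-1 and phase-2 introns to the residue they interrupt. Every
intron therefore maps to exactly one alignment column, which is what lets
site matrices and annotated alignments mark a site with a single `I`
character. Introns whose anchor falls on the stop codon (anchor equal to
the protein length) have no alignment column; they stay in the gene
reports but are excluded from projection, hot spots and pair
classification, with a warning.

Site identity defaults to the alignment column alone: phase is recorded but
does not split sites, matching the granularity of an amino-acid-level site
comparison. `site_identity = "column+phase"` switches to the stricter
definition. Anchors that land in different columns because of adjacent gap
runs are *not* merged; we take the alignment at face value.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `hotspot_num/hotspot_den` | 1/3 | exact hot-spot fraction |
| `n_shuffles` | 200 | shuffled replicates per pair |
| `evalue_cutoff` | 0.02 | pair selection threshold |
| `match/mismatch` | +5/−4 | DNA substitution scores |
| `gap_open/gap_extend` | −16/−4 | affine gap scores (open includes the first position) |
| `shuffle` | mono | mononucleotide permutation; `window:<k>` preserves local composition |

The scoring values are the classic FASTA/PRSS DNA defaults; the similarity
procedure that motivated them names the tool but not its parameters, so all
four are exposed. The E-value is `n_shuffles` times the fitted Gumbel tail
probability at the observed score — the expected number of shuffled
comparisons reaching it. When the Gumbel fit fails (a flat or degenerate
score distribution, e.g. homopolymer introns) the empirical p-value
`(r + 1) / (n + 1)` is reported as the E-value instead; it is bounded below
by `1 / (n_shuffles + 1)` ≈ 0.005, which still lets unambiguous identities
pass the 0.02 cutoff while never manufacturing significance from a
degenerate null. The shorter sequence of a pair is always the one shuffled,
which reduces the variance of the null scores. No multiple-testing
correction is applied across pairs — the selection is per pair by design,
and the manifest records a note to that effect.

Per-pair shuffle seeds are derived from the master seed and the sorted pair
of intron ids through a 31-bit polynomial hash, so the pair list is
bit-identical across runs and independent of enumeration order.

## The synthetic-data generator

`simulate_dataset()` produces a desk-scale dataset with the statistical
structure the analysis assumes, plus complete truth tables. Its defaults
describe a 24-genome, 4-clade fungal survey: clade sizes 1/8/11/4, the four
histone families, 1–4 paralogs per species and family, proteins of 100–140
residues, and two intron-rich clades. Real fungal histone gene sets reach
higher paralog counts (around a dozen in extreme cases), but the median is
small; 1–4 keeps the gene count near the real one. Per intron-rich clade
and family, three sites are planted, one of them at a column shared across
the rich clades; the first (dominant) site has occupancy 0.8 per gene,
minor sites a third of that, and every gene in every clade may acquire a
private one-off intron with probability 0.05 — the intron-poor clades
therefore carry only those rare introns. Intron lengths are log-normal
(median 70 nt, log-sd 0.5) truncated to 20–250 nt; homologous introns at a
planted site descend from one ancestral sequence per clade and site,
mutated at 0.05 per position with the GT..AG dinucleotides preserved.
Protein divergence is 0.15 between the family ancestor and each clade and
0.03 at the species and paralog level. Sites sharing a column across clades
deliberately get *independent* ancestral intron sequences, so a shared site
does not imply sequence-similar introns.

Two design choices keep the truth exact. Protein evolution is
substitution-only, so the true alignment is gap-free and emitted directly —
site projection and hot-spot recovery are tested without conflating aligner
error; indel-tolerant simulation is a non-goal. And intron gain/loss is
Bernoulli occupancy per gene and site rather than an explicit branching
process on a tree; a branch-wise loss model would add realism (correlated
absences within subclades) but no additional coverage of the code paths
under test. Configurations whose expected dominant-site share
`p / (p + (k−1)q + r)` falls below the hot-spot fraction are rejected at
validation time, since they cannot plant a hot spot even in expectation.

Truth tables (site counts, hot spots, shared hot spots, homologous pairs)
are computed directly from the planted intron table by applying the
definitions — not by running the pipeline — so recovery tests compare two
independent routes to the same answer. What passing recovery shows about
real data is limited accordingly: it validates the coordinate arithmetic,
the projection, the rule and the significance machinery, not robustness to
alignment error, annotation noise, or non-canonical gene structures.

The seed is recorded in a `# seed:` header comment of the GFF3, the clade
table and every truth TSV. FASTA has no portable comment syntax, so the
sequence files rely on the manifest and the sibling files for provenance.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive on disk (GFF3) and in all reports;
  internal arithmetic uses 0-based offsets.
* Copy labels (`H2A_1`, `H2A_2`, ...) number paralogs by ascending genomic
  position, ties broken by contig name; the label is cosmetic and never
  used in computation.
* A CDS whose length is not a multiple of 3, or with an internal stop, is
  excluded with a warning; a missing sequence region is a hard error naming
  the gene. Non-GT..AG intron boundaries are accepted with a warning.
  Only CDS-interrupting introns are counted; UTR introns are ignored.
* Gene/intron counts per species count CDS introns only.
* `smith_waterman` returns 0 (the empty alignment) when nothing scores
  positively; `N` scores as a mismatch even against `N`.
* The Gumbel fit uses the standard ML fixed-point iteration for the scale
  with a mean-shifted exponential to avoid overflow; samples with zero
  variance or fewer than five values fail the fit and fall back to the
  empirical p-value.
* Hot-spot detection on a clade with zero introns in a family returns an
  empty result rather than dividing by zero.

## Problem sizes

The test suite and the acceptance script use a paper-scale synthetic run
(24 species, 4 families, roughly 150–200 genes and 200–250 introns, about
20,000–30,000 intron pairs at 200 shuffles each) for planted-truth
recovery, and smaller 2-clade configurations for round-trip, consistency
and determinism checks. The shuffle-calibration check uses 500 unrelated
60-nt pairs. These sizes exercise every code path at full statistical
structure while keeping a complete run in the minutes range on one core.

## Known limitations

* The protein alignments are consumed, not computed; alignment quality is
  the caller's responsibility, and sites split by alignment error are not
  re-merged.
* No ancestral-state reconstruction and no significance test for hot spots
  themselves — the 1/3 rule is a definition, not a test.
* The generator does not emulate indels, splice-site motifs beyond GT..AG,
  codon usage bias, or selection.
* Trans-splicing, programmed frameshifts and annotation lifting are out of
  scope for the GFF3 reader.
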