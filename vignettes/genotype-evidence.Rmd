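---
title: "Genotype reports and novel-allele evidence for AIRR-seq repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype reports and novel-allele evidence for AIRR-seq repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airrgenotype)
library(dplyr)
```

## The problem

Immunoglobulin (IG) germline reference sets are incomplete: AIRR-seq
repertoires routinely contain expressed alleles that are absent from the
curated references, and tools such as TIgGER or IgDiscover infer these novel
alleles from the repertoire itself. Before a novel allele can be accepted
into a reference set, reviewers need standardized, quantitative evidence:
how heavily the allele is used, how many reads match it *exactly* (i.e.
carry no somatic hypermutation over the covered region), how it differs from
its closest known relatives, and whether its pattern of association with a
heterozygous anchor gene is consistent with a real germline allele on one
chromosome rather than a hypermutation artifact.

This package computes that evidence from two inputs a submitter already has:
a germline reference set (gapped FASTA, optionally extended with candidate
novel alleles under submitter names such as `IGHV_S1`) and an annotated
AIRR rearrangement TSV. It also ships a seedable repertoire simulator with
exact ground truth, so every statistic can be validated end to end.

## The genotype report

The genotype is the set of alleles of one locus that lead to expressed
productive sequences in the subject's repertoire; non-productive reads are
excluded everywhere (including the diagnostics — the package takes the view
that evidence for a germline allele should come only from sequences under
selection as functional rearrangements). For the segment under study
(usually V), each observed allele gets one report row. The central
quantities, writing $u_a$ for the number of reads exactly matching allele
$a$ and $s_a$ for the number assigned to it:

* `assigned_unmutated_frequency` $= 100\, u_a / s_a$
* `allelic_percentage` $= 100\, u_a / \sum_{b \in \text{gene}(a)} u_b$
* `unmutated_frequency` $= 100\, u_a / \sum_b u_b$

plus co-occurrence diversity (distinct V/D/J partners and CDR3s, overall and
among exact matches) and UMI-deduplicated exact-match counts when a UMI
column is present.

**Assignment.** A read is assigned to the first allele of its
(possibly comma-separated) call string. Ambiguous calls count toward
`sequences` but never toward exact-match statistics: an exact match credited
to several alleles at once would double-count the strongest evidence there
is. This is a documented package convention; the report format itself does
not prescribe it.

**Exact matching.** "Exactly matching" is evaluated over the read's covered
extent of the studied segment only. For V, that is IMGT-gapped columns 1 to
`v_germline_end`; columns where both read and germline carry the gap
character `.` are ignored, a base against a gap (either direction) is a
mismatch, and any `N` in the read is a mismatch. 3′ bases trimmed by the
recombination junction are simply not covered and are not penalized. For J,
the read's J region is compared anchored at the germline 3′ end, because
junctional trimming removes 5′ J bases. D segments have no fixed comparison
extent, so exact-match status is undefined for them and the corresponding
fields stay empty. Where the input lacks `v_germline_end`, the covered
extent defaults to the shorter of read and germline frame — correct for
reads that simply end early, and conservative otherwise.

**Coordinates.** All coordinates are 1-based and inclusive. V positions are
IMGT-gapped positions; amino-acid positions are IMGT codon numbers (codon
$i$ = gapped columns $3i-2 \ldots 3i$). D and J positions count from the
start of the coding sequence. Substitutions are formatted
`<ref><position><alt>`, e.g. `G112A` for nucleotides, `A96N` for amino
acids. Codons containing a gap or `N` translate to `X` and are excluded from
amino-acid substitution lists — a gap column is an alignment artifact, not
evidence of a protein change. Novel V alleles must arrive pre-gapped on the
IMGT frame; computing IMGT gaps de novo is out of scope.

**Closest references.** For each candidate novel allele the report gives the
closest reference allele overall and the closest present in the subject's
own genotype, by positional (Hamming) distance on the shared gap frame, over
the overlapping 3′ extent only (novel inferences are often 3′-truncated
because the final nucleotides cannot be inferred reliably under junction
trimming). Ties break to the lexicographically smallest name, so results
are deterministic. Since the host set is a subset of the reference set,
`nt_diff_host >= nt_diff` always holds.

## Haplotype-anchor evidence

When a subject is heterozygous at a J gene (e.g. IGHJ6 carrying `*02` and
`*03`), each read's J allele labels the chromosome it came from. A genuine
novel V allele lies on one chromosome and should therefore associate with
exactly one anchor allele; a hypermutation artifact arising on reads of many
clones should not. The package:

1. tabulates J-allele usage per gene on **unmutated** reads only
   (`allele_usage`) — hypermutation would otherwise distort allele ratios;
2. calls a gene a candidate anchor when exactly two alleles each hold at
   least `min_minor_fraction` (default 0.2) of the gene's reads and the gene
   has at least `min_total` (default 100) reads (`detect_anchor`). The
   defaults are package choices — tolerant of moderately unbalanced
   heterozygotes while robust to noise alleles — and are configurable;
3. splits **all** assigned reads of each studied-segment allele by anchor
   allele (`haplotype_counts`): the split is about read counts per
   haplotype, and restricting it to unmutated reads would discard most of
   the signal;
4. flags exclusivity (`exclusivity_score`) strictly: zero reads on the minor
   haplotype and at least `min_reads` (default 10) on the major. The
   min/max ratio is reported so near-exclusive cases remain visible.

Multiple qualifying anchors are all reported; the genotype's
`haplotyping_gene` field joins their names with commas.

## Diagnostics

Five panel types support visual review, each available as a table (what the
tests assert on) and a ggplot2 figure (`autoplot()` / `render()`):

* **alignment panel** — every read assigned to an allele, projected on the
  germline gap frame; gaps as `.`, bases under the quality threshold
  (default Q20, configurable) as `-`, uncovered tail columns as `.`;
* **end zoom** — the final 8 (configurable) non-gap columns of the V frame,
  or the first 8 for J: the junction-adjacent bases whose inference is
  least certain;
* **mutation histogram** — reads binned by nucleotide distance to the
  (possibly inferred) allele sequence over the covered extent. For novel
  alleles the comparison is against the inferred sequence itself, so bin 0
  is the exact-match count; reads with ambiguous calls are skipped and
  counted, keeping bin 0 equal to `unmutated_sequences` by construction;
* **allele usage** and **haplotype split** — the anchor-evidence views
  described above.

## The simulator

`simulate_repertoire()` emulates exactly the structure the statistics
assume, with the emitted calls equal to the true alleles — it validates the
evidence computations, not an annotator. Default conditions: 10,000 reads;
a two-allele-per-gene V genotype plus the novel candidate `IGHV_S1`
(defined as IGHV1-69\*01 with the single substitution G112A); per-base V
substitution rate 0.01 placed uniformly over covered non-gap positions;
3′ V trims of 0–3 nt (probabilities 0.55/0.2/0.15/0.1); random in-frame
CDR3s of 10–16 amino acids; J usage over six genes with IGHJ6 at 30% split
50/50 between `*02` and `*03`; `IGHV_S1` exclusively linked to `IGHJ6*03`;
5% non-productive molecules; 12-mer UMIs with a 15% resequencing-duplicate
rate (duplicates share UMI and mutation pattern); and a two-level quality
string with 2% of bases at Q11. Rates and sizes without an external
prescription were chosen once as typical of a deeply sequenced IgM
repertoire study.

What it deliberately does not model: annotation errors, clonal lineage
structure, D/J trimming realism, N-region composition, indel hypermutation,
or sequencing error beyond the flat quality mask. Passing tests therefore
show the statistics are computed correctly given correct annotations — not
that any upstream annotator is reliable.

The reference set behind the defaults (`synthetic_reference_set()`) is
itself synthetic: pseudo-random sequences with a fixed internal seed,
IMGT-style gap blocks in the CDR1/CDR2 regions, and engineered allele
distances so that closest-reference relationships are unambiguous.

## Numerical choices and degenerate inputs

* Internal computation is in full precision; percentages are rounded
  half-up to 2 decimals only at CSV serialization.
* Percentages with an empty denominator (a gene with no exact matches; no
  exact matches anywhere) are rendered as empty cells, never `0/0`.
* An empty productive repertoire is an error; an empty simulated TSV, an
  empty FASTA and zero-read panels are all valid degenerate outputs.
* `-` gap characters in input FASTA are normalized to `.` (logged);
  duplicate names and non-nucleotide characters are errors naming the
  offending record and position.
* Unknown allele calls still produce report rows (with empty difference
  fields) and are listed as discrepancies rather than dropped: reviewers
  should see them.
* Problem sizes in the test suite: unit tests run on hand-built
  10-column fixtures and repertoires of 120–2,000 reads; the end-to-end
  validation uses one 10,000-read repertoire, the scale at which all
  acceptance-level properties are exercised.

## Limitations

* Only positional comparison on a shared gap frame; no edit-distance
  alignment, so indel-carrying novel alleles are only marked (`ins`/`del`
  entries), not aligned.
* Exact-match statistics for D genes are undefined (empty), as discussed.
* Haplotype analysis uses a single anchor gene at a time; full chromosomal
  haplotype reconstruction and locus deletion inference are out of scope.
* IMGT gap computation for ungapped novel V sequences is not performed;
  inputs must be pre-gapped.
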