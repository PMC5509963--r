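---
title: "Calling and annotating retrocopies: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and annotating retrocopies: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrofinder)
```

## The model

Retroposition copies a spliced mRNA back into the genome, so a retrocopy is
an intronless image of its parental gene's coding sequence. retrofinder
operationalizes this as a decision rule on protein-to-genome alignment
chains: a chain of a multi-exon gene's protein against a locus elsewhere in
the genome is a retrocopy call when the alignment is long enough (≥ 150 bp),
similar enough (identity and coverage ≥ 50% of the parental protein), and —
the actual signature — at least two parental introns have been lost at the
aligned locus.

Intron loss is tested in protein coordinates. Every CDS exon junction of
the parental transcript maps to an amino-acid offset
(`floor(cumulative CDS bp / 3)`, with a phase); a junction is *informative*
("spanned") only when that offset lies strictly inside the aligned query
span, since a junction at the alignment edge cannot distinguish loss from
truncation. A spanned intron is *lost* when the target-side gap at that
protein position — in excess of 3 bp per unaligned query residue — is
smaller than `retained_intron_min_gap`.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `min_aln_bp` | 150 | bp | below this, spurious protein hits dominate |
| `min_identity` | 0.50 | fraction | ancient retrocopies decay; 50% keeps them |
| `min_coverage` | 0.50 | fraction | guards against domain-level matches |
| `min_lost_introns` | 2 | count | one junction can be lost to chance gaps |
| `retained_intron_min_gap` | 30 | bp | shortest credible spliceosomal intron; a smaller target gap cannot be a retained intron, so the junction counts as lost |
| `pseudo_overlap` | 0.50 | fraction | of the *retrocopy's* length, inclusive |
| `mammal_flag_count` / `other_flag_count` | 50 / 5 | count | parent-flagging cut-offs |
| `polII_upstream` / `tss_upstream` | 1000 / 500 | bp | promoter search upstream of the 5' end |
| `body_fraction` | 0.30 | fraction | how far into the body a promoter signal may reach |

The `retained_intron_min_gap` rule is this package's own formalization:
the defining criterion is stated as intron loss, and some explicit gap rule
is needed to separate "intron still there" from "alignment artifact". 30 bp
sits below essentially all known spliceosomal introns, and the value is
exposed in `retro_thresholds()`.

Two further interpretation choices are exposed as switches rather than
hard-coded:

- `use-all-isoforms vs canonical`: retrocopy calling uses whichever protein
  the chain's query names; for building query sets, `canonical_protein()`
  picks the longest protein (ties: lexicographically smallest transcript
  id). Isoform choice is the caller's, since chains are inputs.
- `trim_mode` in `call_retrogenes()`: the 10-aa terminal exclusion defaults
  to trimming the parent-side *aligned span* ("aligned_span"); trimming the
  parent protein's absolute termini is available as "absolute". The aligned
  span reading is the stricter and more local one: terminal alignment
  wobble is a property of the alignment, not of the protein.

Similarly, "aligned coding length ≥ 150 bp" in the retrogene caller is
tested on the aligned portion (50 aa), consistent with the retrocopy
filter; testing the whole candidate CDS instead would only loosen the rule
for long genes with short homologous cores.

## Resolution, tie-breaks and determinism

Overlapping surviving chains at one locus (≥ 1 bp overlap, same strand) are
resolved to a single call by best score, then highest identity, then
highest coverage, then lexicographically smallest parental gene id — a
total order, so the output is invariant to input-file order. Retrocopy ids
are assigned by genomic sort. Chains overlapping the parental gene's own
annotated span are removed before resolution; without this the parent
trivially aligns to itself. Where two retrocopies of the same parent
overlap each other only the best-scoring one is kept.

Local alignments of one query fragmented by hard-masking are re-chained
when co-linear and separated by ≤ 1000 bp (`chain_colinear()`); the gap
bound is a package choice, exposed as `chain_gap` in the pipeline config.

## ORF conservation

The ORF report counts frameshifts (inter-block indels with net length not
divisible by 3) and premature stops (aligned codons translating to `*`,
with the frame re-anchored after every indel). Conservation is defined as
zero of both, inside the aligned region. Two compensating frameshifts count
as two events: frame restoration does not undo the lesions. Alternative
conservation definitions (longest-ORF fractions, start-codon context) are
out of scope; the counts themselves are reported so users can apply their
own rule.

## Expression evidence

Uniqueness of RNA-Seq reads is NH = 1 when the tag is present, else
MAPQ ≥ 30 — retrocopy/parent similarity makes multi-mappers uninformative,
and the strict rule deliberately underestimates expression rather than
inflate it. RPM uses the library's total mapped reads as denominator;
"expressed" is RPM ≥ 1.0, inclusive, in *any* library (the per-library OR
matches how per-tissue values are badged). One aligned base suffices for
read-to-locus overlap; uniqueness already provides specificity.

EST validation requires the retrocopy hit to be strictly better in both
score and identity than every other genomic hit of the same EST; ties
reject, because an EST matching parent and retrocopy equally well carries
no positional information.

Promoter-signal windows are strand-aware, clipped at contig boundaries, and
associate on ≥ 1 bp overlap. Sources never supplied are reported `NA`
("not assessed"), distinct from a negative.

## Orthology

Reciprocal overlap is measured in alignment-column space: each retrocopy is
projected through the gapped rows of the blocks it overlaps, columns
accumulate across blocks, and two retrocopies of different species are
linked when the shared columns are ≥ 50% (inclusive) of each one's column
set. A genomic-bp denominator mode is available (`space = "bp"`). Groups
are single-linkage connected components (no clustering method is implied by
the 50% rule itself); species sets for clade-restricted runs are simply the
names of the supplied call tables.

## The synthetic-fixture generator

`generate_genome()` builds genes of 2–8 CDS exons (25–90 codons each,
introns 60–400 bp with GT..AG ends, ~25% on the minus strand, ATG start, no
internal stops) in random intergenic background. Exon lengths are multiples
of 3 (phase-0 junctions), which keeps truth alignment blocks exact in
protein coordinates; phase-1/2 junction arithmetic is covered by dedicated
loader tests instead. `implant_retrocopies()` inserts spliced CDS copies —
with controllable substitution load (default 5%, roughly the divergence of
a moderately old retrocopy), 3'-truncation, 1-bp frameshift insertions and
stop substitutions — plus intron-retaining duplicates and single-exon
fragments as negative controls. Processed implants are drawn from parents
with ≥ 2 introns, because a copy of a one-intron gene cannot exhibit the
two-intron-loss signature at all. Implants are appended into fresh
intergenic sequence beyond the gene array: positions are still intergenic,
and existing coordinates stay stable as implants accumulate.

What the fixtures do *not* emulate: LINE-mediated target-site duplications
and polyA tails, sequencing error in reads, alignment-method noise (truth
chains are exact), overlapping genes, and isoform diversity (one transcript
per generated gene; multi-isoform behaviour is tested with hand-built
models). Passing tests therefore demonstrate the correctness of the
decision rules and their boundary behaviour, not robustness to aligner
artifacts on real genomes.

All randomness flows from one seed through labelled substreams, so adding a
generator never perturbs another's draws and every output is bit-identical
under a fixed seed.

## Numerical and degenerate-input choices

- Coordinates are 1-based closed inside R (GenomicRanges convention);
  PSL/BED (0-based half-open) and GFF3 (1-based closed) are converted at
  I/O boundaries. Chain blocks are kept in the alignment's native
  orientation so block lists ascend on both sides.
- Plain LAST tabular output carries no mismatch count; an optional
  `matches=` field is honored, else matches default to the aligned length.
  PSL input carries matches natively.
- All "at least" thresholds are inclusive (150 bp, 50%, 1 RPM, 100 nt,
  90%, 50% reciprocal overlap); "better than" in the EST rule is strict.
- Empty inputs yield empty outputs; a single-exon transcript passed to
  intron-position derivation, an empty intron list in loss detection, a
  zero-length library, and an unindexed BAM are errors.
- CDS features are taken to exclude the stop codon; a terminal stop in the
  translation is stripped defensively. Transcripts whose phase-adjusted CDS
  length is not a codon multiple are skipped with a warning.

## Problem sizes

The shipped tests and the acceptance script run on 20-gene genomes
(≈ 50 kb) with 15 implants and 8 negative controls, 1000-case random
window-association sweeps, and 200-vertex random graphs for the orthology
oracle — sizes at which every brute-force oracle is exact and the whole
suite completes in about two minutes. These are the package's validation
conditions; real genomes differ in scale, not in the rules applied.

## Known limitations

- Parental-gene assignment is purely best-alignment; paralog families with
  near-identical proteins can swap parents within a family.
- The ORF rule ignores the start codon and Kozak context.
- Expression badges are per-source booleans; no quantitative integration.
- The orthology stage trusts the whole-genome alignment; mis-aligned blocks
  propagate.
- Chimeric retrogenes and retrogene-derived fusions are not distinguished.
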