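---
title: "Descriptive profiling of insect mitochondrial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Descriptive profiling of insect mitochondrial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoprofile)
```

## Scope and model

Insect mitochondrial genomes are compact circular molecules of 14–20 kb
carrying a nearly invariant complement of 37 genes — 13 protein-coding genes
(PCGs), 22 tRNAs, 2 rRNAs — plus one A+T-rich control region. The first
descriptive pass over a newly assembled mitogenome is highly stereotyped:
tabulate the gene arrangement (sizes, overlaps, intergenic nucleotides),
summarize base composition and strand skews, profile codon usage, inventory
the control region's repeat structure, check conserved junction motifs, and
assess whether each tRNA folds into the canonical cloverleaf. `mitoprofile`
implements that pass as a tested, reusable pipeline, together with a seeded
synthetic-mitogenome generator so that every stage can be validated without
downloading any data.

Coordinates are 1-based inclusive throughout, matching how mitogenome
annotation tables are published. A feature wrapping the circular origin is
encoded with `start > end`; wrap arithmetic always takes the genome length
explicitly.

## Arrangement accounting

The intergenic-nucleotide (IGN) value of an adjacency is defined strictly as
`next.start - prev.end - 1` on the circle: zero for abutting genes, negative
values are overlap lengths negated. Published arrangement tables do not
always satisfy this identity against their own printed coordinates, so every
report carries both the values **computed** from coordinates and, where
available, the **printed** column retained verbatim
(`ign_source`/`size_source` in `summarize_arrangement()`). This reproduces a
published table's own summary statistics without silently endorsing
arithmetic that its coordinates contradict. The computed values obey
conservation of circumference — over a full circular arrangement,
`sum(size + ign) == genome_length` — which the test suite checks both on
fixtures and on generated genomes.

Gene order is compared through a canonical signature: the ordered
`name(strand)` token list rotated to a fixed anchor gene (`trnI` by default,
the gene conventionally printed first in insect mitogenome tables), falling
back to the lexicographically minimal rotation when the anchor is absent.
Two genomes share an arrangement exactly when their signatures are equal; no
rearrangement distance is computed.

## Composition and skews

Strand asymmetry is summarized by the classical skew statistics

$$\mathrm{AT\ skew} = \frac{A - T}{A + T}, \qquad
  \mathrm{GC\ skew} = \frac{G - C}{G + C},$$

computed identically from counts or percentages (the denominator cancels).
Two choices deserve note:

* **Skew orientation.** Some published composition tables print a "G+C
  skew" column that is arithmetically $(C-G)/(C+G)$, the negation of the
  formula those papers state. `gc_skew()` therefore takes an `orientation`
  argument: the default `g_minus_c` is the stated formula; the `c_minus_g`
  preset reproduces such tables. The package does not guess which the
  original authors intended.
* **Class rows.** Per-class composition (PCG, rRNA, tRNA, control region)
  is computed over the concatenation of *reading-strand* feature sequences,
  because skew is strand-dependent and class-level skews are only meaningful
  on the strand the genes are read from. The whole-genome row uses the plus
  strand.

`N` never counts toward the A/C/G/T denominator, so composition stays
well-defined on draft sequences. Percentages are rounded to 2 decimals and
skews to 3, half-up (so `-0.2347` prints as `-0.235`), and only at the
report edge; unrounded values are carried internally.

## Codon usage

Relative synonymous codon usage is
$$\mathrm{RSCU}(c) = \frac{n_c \cdot d_f}{\sum_{c' \in f} n_{c'}},$$
the observed count of codon $c$ divided by its expected count under uniform
use within its synonymous family $f$ of size $d_f$. The family partition is
configurable (`genetic_code_partition()`): the `standard` partition keeps
Leu/Ser/Arg six-fold, Ile three-fold and a `{UAA, UAG, UGA}` stop family;
`invertebrate_mito` moves AUA to Met, UGA to Trp and AGA/AGG to Ser.

The default for reproducing published mitogenome RSCU tables is the
**standard** partition. This is deliberate: the printed RSCU columns of the
codon-usage table this package mirrors are arithmetically consistent only
with standard-code families (e.g. AGA $= 38 \times 6 / 108 = 2.11$ with
six-fold Arg; UGA $= 32 \times 3 / 376 = 0.26$ with a three-codon stop
family), even though the row labels follow the invertebrate mitochondrial
code. Both partitions ship and every report names the partition used. Stop
codons are counted in the usage table, as published tables do; they can be
excluded by zeroing their counts.

Codons-per-thousand (CDspT) is $1000 \cdot n_g / N$ for a codon, family or
named group; the named groups are the conventional two-fold splits Leu2
(UUR) vs Leu1 (CUN), Ser1 (AGN) vs Ser2 (UCN), and Arg1 (CGN) vs Arg2
(AGR). RSCU is reported to 2 decimals and CDspT to 1, half-up, at the edge.

Incomplete stop codons — a trailing T or TA completed to UAA by transcript
polyadenylation, common in mitochondrial PCGs — are recorded by
`extract_codons()` as a trailing remainder, never counted as a codon, and
surfaced by `classify_terminals()` as partial stops.

## Control-region features

Three detectors run over the control region, each reporting **maximal**
features only:

* homopolymer runs (default minimum 10 bp, comfortably above the ~6 bp
  runs random A+T-rich sequence produces, below the ~19 bp poly-T tracts of
  interest);
* short-unit tandem arrays (default unit 2 bp, at least 5 copies); an
  array whose unit is a single repeated base is a homopolymer, not a
  microsatellite, and is excluded. The canonical unit is the
  lexicographically least rotation, resolving the (TA)n/(AT)n ambiguity
  deterministically;
* long direct repeats (default minimum 30 bp, same strand), substrings
  occurring at two or more positions, each distinct repeated segment
  reported once with all its occurrence starts, with segments wholly
  contained in a longer reported repeat suppressed. Inverted repeats are
  out of scope. The search enumerates substrings longest-first with
  explicit string comparison — collision-free by construction; at
  control-region scale (a few kb) correctness is worth far more than
  asymptotics, and a diagonal self-comparison pass caps the enumeration.

All three are checked against independent brute-force oracles in the test
suite (exhaustive scans on strings up to ~2 kb).

## Junction windows and motifs

Conserved motifs at gene junctions (e.g. the ATGATAA element across the
atp8/atp6 overlap) are examined in fixed windows anchored on annotation
coordinates, not on sequence alignment: the window spans the last `flank_a`
bases of the upstream gene through the first `flank_b` bases of the
downstream gene (defaults 15/15), extracted once from the genome so an
overlap is never duplicated, and returned on the upstream gene's reading
strand. Whether published junction figures used the reading strand or the
plus strand is usually unstated; the reading-strand contract here is
declared, not inferred. Motif hits allow a configurable mismatch budget
(exact matching by default, equivalent to naive substring search), and
motifs are configuration values rather than constants because the
literature itself is inconsistent about their exact spelling.

## tRNA cloverleaf folding

The folding heuristic is anchored rather than thermodynamic: the claims it
must support are arm presence (e.g. mitochondrial tRNAs missing the TΨC
arm) and a Watson-Crick / G·U wobble / mismatch inventory of stem pairs,
not free energies. The search (1) enumerates candidate anticodon arms —
stems of 4–5 pairs around a 7-nt loop, with the annotated anticodon
required at loop positions 3–5 when available; (2) fixes the acceptor stem
as the best 7-pair register of positions 1–7 against the 3′ end, with or
without a discriminator base, tolerating at most 2 non-pairs; (3) searches
the DHU arm (stem 3–4, loop 4–12 nt) between acceptor and anticodon arm and
the TΨC arm (stem 4–5, loop 3–9 nt) after it; and (4) scores
$3\,\mathrm{WC} + 2\,\mathrm{GU} - 1\,\mathrm{mismatch}$ over all stems,
returning the best non-crossing assembly. Ties break leftmost-then-longest,
which together with the fixed enumeration order makes folding fully
deterministic. The weights and arm ranges are this package's choices — the
descriptive literature states none — and are exposed in
`trna_fold_config()`.

## The synthetic generator

`generate_mitogenome()` is first-class, tested code and the package's test
substrate. Its defaults are the study conditions the package targets: the
ancestral insect gene order (37 genes plus control region, ~16.2 kb in
total), PCG sizes near the published arrangement table adjusted to codon
frame, codon usage sampled from the published codon-count column (internal
UAA/UAG zeroed), a 1,465 bp control region at 87% A+T target carrying a
19 bp poly-T, (TA)10, a terminal 12 bp poly-A and two >30 bp repeat
segments each planted twice, ATGATAA realized structurally across a −7 bp
atp8/atp6 overlap, TTAACTA in a 7 bp trnS2/nad1 spacer, and trnH/trnM/trnF
built without TΨC arms. Two PCGs printed with partial stops in the source
table are generated with complete TAA stops because their printed sizes are
exact codon multiples; partial stops are retained wherever the size ends in
a +1 frame remainder.

The generator lays out the annotation skeleton first and fills in sequence
second, so the manifest is exact by construction. Overlapping genes share
sequence, with the downstream gene owning the shared bases (mirroring real
atp8/atp6 overlaps); configuration validation rejects overlap motifs that
would contradict the upstream gene's stop codon. Random filler caps
homopolymer runs at 6 bp and period-2 arrays at 8 bp so planted features
are uniquely maximal, single-character boundary repairs prevent a plant
from extending into its flanks, and the generator then *verifies its own
manifest* by running the analysis modules on the emitted genome —
resampling filler deterministically (bounded retries) until recovery is
exact. tRNAs are likewise built with complementary stems and accepted only
if the folder recovers exactly the planted arms. This verify-by-recompute
design is what makes the round-trip tests exact rather than approximate.

What the generator does **not** emulate: mutation/selection processes, codon
autocorrelation along genes (filler is i.i.d. per class; nothing in the
descriptive statistics requires Markov structure), sequencing error, or
length variation of the control region. Passing round-trip tests therefore
demonstrates correctness of the accounting, not robustness to annotation
error in real data.

## Problem sizes and determinism

The test suite generates full ~16.2 kb genomes for seeds 1–5 (shared across
test files via a memoized helper) plus seeds 6–10 for the arm-recovery
property (220 tRNAs in total), runs detector-vs-oracle comparisons on
strings up to ~1.5 kb, and checks RSCU against explicit family enumeration
on 250 random count tables; the full suite completes in well under a
minute. All randomness flows through R's RNG under fixed seeds; generation
is byte-deterministic given a configuration, and the report pipeline writes
byte-identical outputs on reruns (timings go to stderr, not into files).

## Known limitations

* The GenBank reader/writer covers the flat-file subset this domain needs
  (LOCUS, CDS/tRNA/rRNA/misc_feature/D-loop features, `complement()`, one
  origin-spanning `join()`, ORIGIN); it is not a general GenBank parser.
* The folding heuristic assumes a cloverleaf topology; it cannot represent
  pseudoknots or severely degenerate mitochondrial tRNAs beyond whole-arm
  absence, and stems containing more than one mismatch are rejected as
  candidates by default.
* Direct-repeat detection is quadratic in region length and intended for
  control regions, not whole chromosomes.
* Printed-column reproduction modes necessarily inherit any internal
  inconsistencies of the published table they mirror; the computed columns
  are always reported alongside.
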