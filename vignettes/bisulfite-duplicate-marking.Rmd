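---
title: "Bisulfite-aware duplicate marking: model, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bisulfite-aware duplicate marking: model, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(bsmarkdup)
```

## Why bisulfite libraries need their own duplicate marker

PCR amplification during library preparation produces duplicate
fragments: multiple sequenced copies of one original molecule. Leaving
them unmarked biases any analysis that counts reads. For ordinary whole
genome sequencing (WGS), each genomic fragment yields one distinct
template, so duplicate marking reduces to finding reads with identical
coordinates and orientation.

Whole genome bisulfite sequencing (WGBS) breaks that assumption. Before
amplification the DNA is denatured and treated with sodium bisulfite,
which converts unmethylated cytosines to uracil (read as thymine). The
two denatured strands are no longer complementary, so a single genomic
locus gives rise to **two distinct template molecules**: one derived
from the original top strand (OT, with its PCR complement CTOT) and one
from the original bottom strand (OB/CTOB). Two reads at identical
coordinates but from opposite strand classes are *different molecules*,
not duplicates. A WGS-style marker merges them and discards real data;
a bisulfite-aware marker must keep them apart.

Only the two-way distinction matters for duplicate detection. Because
SAM stores `SEQ` in reference-forward orientation, reads from OT and
CTOT both show C→T mismatches against the reference, and reads from
OB/CTOB both show G→A; the four chemical strands collapse into two
observable classes, called `TOP` and `BOTTOM` throughout this package.

## The duplicate decision

Processing is per *template* — all SAM records sharing one QNAME. Input
must be name-grouped (aligner output order or a queryname sort); the
engine sits naturally between the aligner and the coordinate sorter.
Coordinate-sorted input is rejected with an explicit error rather than
mishandled, because the signature needs both primary mates of a
template at once.

For each template with at least one mapped primary record:

1. **Strand class** — from aligner auxiliary tags when present (`YD`
   from BISCUIT/bwa-meth, `XG` from Bismark, `XB` from gemBS, in that
   priority; the order is configurable). Otherwise, by summing C→T
   versus G→A conversion counts over the mapped primary records against
   an indexed reference FASTA. In WGS mode every template is assigned a
   single class.
2. **Signature** — the tuple that PCR copies of one molecule must
   share: supercontig bin and within-bin position of the unclipped 5′
   end of read 1 and read 2, whether read 1 lies left of read 2, the
   orientation pair, pairedness, and an optional cell barcode.
3. **Decision** — the pair (signature, strand class) is looked up in a
   per-class store. The first occurrence is the nonduplicate; every
   later occurrence is a duplicate. Only primary records contribute to
   the decision, but the verdict is applied to all of the template's
   records (primary, secondary, supplementary) via FLAG bit 0x400.

Templates with no mapped primary record — both-unmapped pairs, unmapped
single-end reads — pass through untouched and are counted separately.
Pre-existing 0x400 flags on processed templates are cleared and
recomputed, which makes the operation idempotent and aligner-agnostic.
All duplicates are treated generically; no attempt is made to
distinguish optical from PCR duplicates.

## The supercontig coordinate system

Rather than keying signatures on (contig, position) pairs, all contigs
are concatenated — in header `@SQ` order — into one *supercontig*, and
positions are encoded as (bin, offset) under a fixed bin width. Each
contig sits inside a padded slot: `floor(padding/2)` bp reserved before
it and the remainder after, so a clip-corrected 5′ position that
overhangs a contig edge still maps to a unique non-negative coordinate.
The map costs O(number of contigs) memory regardless of genome size,
which matters for fragmented plant-scale assemblies.

Two tunables, both exposed on the CLI:

* `bin_width` (default 2^26 bp). Only affects how the coordinate is
  split into (bin, offset) — correctness is unaffected since the
  signature keeps both numbers. The default yields a handful of bins
  for a mammalian genome.
* `padding` (default 10 000 bp per contig). Must exceed the largest
  plausible clip overhang; 10 kb is far beyond any short-read clip. The
  constraint `bin_width > padding` is enforced so an overhang cannot
  underflow ambiguously into the previous contig's final bin.

## Unclipped 5′ positions

Aligners soft- or hard-clip read ends, so the leftmost mapped position
(POS) of two copies of one fragment can differ. Signatures therefore
use the clip-corrected biological 5′ end: `POS − leading clip` on the
forward strand, and `POS + reference-consumed length + trailing clip −
1` (0-based inclusive) on the reverse strand — the standard
duplicate-marker convention.

## Edge cases and tie-breaks

* **Conversion-count tie** (including 0–0): resolved to `TOP`,
  deterministically. A tie carries no strand information; any fixed
  choice merely files the ambiguous template consistently into one
  class. Tag-free templates with no reference available default to
  `TOP` and are counted in `strand_unknown_fallbacks`.
* **Mate tag disagreement**: a fragment has one strand of origin, so
  conflicting mate tags signal aligner inconsistency; the template
  falls through to conversion counting.
* **One mate unmapped**: the template is keyed on the mapped mate like
  a single-end read but keeps `is_paired = TRUE` in the signature, so
  it deduplicates against other half-mapped pairs yet never collides
  with true single-end reads.
* **Mate order**: read 1 and read 2 are not canonicalized. A fragment
  re-sequenced with its mates swapped produces a different signature
  (`r1_left` and the orientation pair flip). The signature follows the
  field list literally; the consequence — R1/R2-swapped copies are not
  merged — is documented rather than hidden.
* **Barcodes**: by default a fixed sentinel (all templates comparable).
  With barcoding on, the barcode joins the signature, so identical
  coordinates from different cells are *not* duplicates. Priority when
  `auto`: `CB` tag, then `CR` tag, then the final `:`-separated field
  of the read name (the delimiter and field are configurable).

## What the synthetic generator emulates

`simulate_alignments()` generates name-grouped SAM with ground truth:
unique fragments drawn uniformly from a random reference, assigned a
strand class (default mix 50/50), sequenced single- or paired-end
(default 80% paired, inserts 150–400 bp, 100 bp reads), with bisulfite
conversion applied site-wise (default conversion 0.98 at unmethylated
sites, methylation 0.75 — typical of a well-converted mammalian
library), 5′ clips (20% of read ends, up to 10 bp, soft or hard),
aligner strand tags (YD/XG/XB mixed 60/25/15), optional cell barcodes,
occasional secondary/supplementary records (5%), and unmapped mates
(2% one-sided, 2% both-unmapped). PCR copies are planted per fragment
with truncated-geometric multiplicity and are byte-identical to their
original except for QNAME — amplification copies the molecule, clips
and all.

Two generator properties keep the truth table exact rather than
approximate:

* Distinct fragments are guaranteed distinct signatures by rejection
  resampling at generation time. Without this, two independent
  fragments could land on the same coordinates by chance and the
  planted truth would be ill-posed. The biologically meaningful
  collision — co-located opposite-strand fragments — is generated
  deliberately by `simulate_strand_pairs()` instead.
* Both-unmapped fragments receive no planted copies, since a
  pass-through template cannot carry a recoverable duplicate relation.

What the generator does **not** emulate: sequencing errors (they cannot
change a signature), base-quality structure, chimeric fragments,
optical duplicate geometry, and reference bias. Passing tests therefore
demonstrate the correctness of the decision logic under the library
model above, not robustness to aligner quirks on real data.

## Validation strategy

The package validates itself along two independent routes:

* `oracle_mark()` — a deliberately separate brute-force restatement of
  the rule: it recomputes every template's signature fields from the
  raw SAM fields with its own clip and layout arithmetic and performs
  an all-pairs comparison, marking all but the first of each
  equivalence class. The test suite asserts exact agreement with the
  streaming engine across randomized configurations (paired/single mix,
  clips, barcodes, tag-free fractions, both modes).
* The generator's truth table — with strand tags present, the engine's
  marked set must equal the planted duplicate set exactly, at planted
  rates from 0 to 0.6.

Further property checks: bisulfite-mode marks are always a subset of
WGS-mode marks on the same input; marking is idempotent; the marked
*count* is invariant under permuting template order (only the identity
of the surviving copy may change); co-located TOP/BOTTOM pairs are
never merged in bisulfite mode and merged exactly once per pair in WGS
mode; conversion-count strand inference on tag-free reads (conversion
rate 0.5, ≥20 informative sites — a deliberately hard setting, real
libraries convert at ≥98%) recovers the true class in >99.9% of
10 000 reads, as a binomial argument predicts; and marking changes FLAG
bit 0x400 and nothing else, field by field.

Problem sizes used by the test suite and the acceptance script — up to
10 000 templates per library, 100–200 randomized configurations, 1 000
co-located pairs — were chosen so the whole validation runs comfortably
on a laptop while keeping every binomial bound sharp.

## Numerical and implementation notes

* Coordinates are 0-based half-open internally; SAM's 1-based POS is
  converted at parse time. Supercontig coordinates are R doubles (exact
  up to 2^53, far beyond any genome).
* Records round-trip byte-identically: fields the engine never edits
  are kept as uninterpreted strings, auxiliary tags verbatim.
* This implementation reads the whole name-grouped stream into memory
  and processes it vectorised, rather than record-at-a-time as a C
  implementation would; `"-"` still supports stdin/stdout pipelines.
  The algorithmic contract (signatures from primaries only, first
  occurrence wins, verdict propagated to the whole template) is
  unchanged.
* BAM is decoded/encoded by piping through `samtools view`; SAM text is
  handled natively. CRAM is out of scope.
* The reference is only touched for tag-free templates; contigs are
  fetched lazily through the `.fai` index and cached.

## Known limitations

* Memory scales with the input SAM, not with the unique-signature count
  as in a streaming C implementation.
* No UMI support and no positional-tolerance ("fuzzy") matching.
* No optical-duplicate subclassification and no best-quality
  representative selection: the first occurrence wins, always.
* Hemi-methylation inference from strand-resolved duplicates is out of
  scope.

## A worked example

```{r example}
sam <- read_sam(system.file("extdata", "toy.sam", package = "bsmarkdup"))
res <- mark_duplicates(sam, bin_width = 1000, padding = 100)
glance(res)
tidy(res)
```

Template `t02` (identical coordinates and strand as `t01`) is marked;
`t03` sits at the same coordinates but on the bottom strand and
survives; the both-unmapped pair `t05` passes through untouched.
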