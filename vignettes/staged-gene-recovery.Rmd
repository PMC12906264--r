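---
title: "Staged cross-domain gene recovery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staged cross-domain gene recovery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossmask)
```

## The procedure and its assumptions

`crossmask` operationalises a simple observation about domain-specialised
metagenome gene callers: a homology-based eukaryotic predictor run first
produces reliable eukaryotic gene models plus a small, accurate set of
prokaryotic calls, and everything it finds can be *removed from play* before
an ab initio prokaryotic predictor sees the assembly. Removal is hard
masking: every base inside a first-pass gene region is replaced with `N`,
so a downstream predictor — which cannot call genes through runs of unknown
bases — is confined to the remaining sequence. The final gene set is the
union of both passes.

The approach assumes that (i) first-pass predictions are trustworthy enough
that masking them loses nothing (conflicts are therefore always resolved in
favor of the first pass), and (ii) the second-pass tool treats `N` as
uncallable, which holds for the standard prokaryotic predictors and is true
by construction for the built-in ORF caller. It does not assume contigs are
domain-homogeneous: masking operates per interval, so chimeric
eukaryotic–prokaryotic contigs are handled naturally.

## Coordinates and containers

All internal coordinates are 0-based half-open `[start, end)`; GFF3 I/O
converts to and from 1-based inclusive at the boundary. Half-open
arithmetic makes interval union and masking free of off-by-one cases:
interval length is `end - start`, touching means `end == next_start`, and
the union of touching intervals is their concatenation. Exon lists are
stored in ascending forward-strand order for every call regardless of
strand; strand is consulted only at translation time, because masking is
strand-agnostic (`N` destroys both strands). Sequence case is preserved
end to end so upstream soft-masking is not destroyed; all comparisons are
case-insensitive.

## Masking

`mask_metagenome()` composes three operations per contig: collect intervals
from calls, merge them, substitute the mask character.

* **`mode = "span"` (default)** masks each call's whole genomic span,
  introns included. The alternative reading — mask only coding exons
  (`mode = "exons"`) — is provided, but span masking is the safer default:
  an unmasked intron inside a eukaryotic gene is exactly the kind of
  sequence on which a prokaryotic predictor hallucinates ORF fragments.
* **Merging** delegates to `IRanges::reduce` with
  `min.gapwidth = merge_gap + 1`, so intervals separated by at most
  `merge_gap` fuse and touching intervals (`merge_gap = 0`) always fuse.
  Fusing changes nothing about the masked sequence; it only makes interval
  counts in reports deterministic and substitution passes fewer.
* **Substitution** is in-place per contig; only one contig's sequence is
  resident at a time, so memory is bounded by the largest contig, which is
  what makes direct coordinate substitution viable for assemblies far
  larger than memory-hungry alignment-based masking.

Masked-base accounting (`mask_report`) is defined on the *merged* union, so
nested, duplicated or overlapping first-pass predictions — common in
homology predictors' raw output — are counted once. This is also why no
deduplication step precedes masking: the interval union makes it
unnecessary.

## Parsers

MetaEuk-style headers are pipe-delimited with nine positional roles; since
layouts differ between predictor versions, the `header_dialect()` object
makes separator, coordinate base (0- or 1-based inclusive) and field order
configurable, with colon-separated `low-high` exon blocks. Bit scores and
E-values are carried through but never used for filtering — no E-value
threshold is applied anywhere in the pipeline. Records that extend past
their contig's end (dialect drift, truncated assemblies) are clipped to the
contig end with a counted warning; clipping is conservative for masking.
Prokaryotic GFF parsing enforces the single-CDS contract of that tool
family and errors on grouped multi-CDS records.

## The built-in second pass

`find_orfs()` is a deliberately naive six-frame scanner, present so the
pipeline is executable and testable with no external binaries: for each
in-frame stop codon the candidate ORF runs from the furthest-upstream
in-frame start codon after the previous in-frame stop, through the stop
inclusive (the prokaryotic-predictor convention of counting the stop in the
CDS). Defaults: `min_len_nt = 300` (100 codons — a classic, conservative
naive-ORF threshold chosen so the surrogate under-calls rather than
over-calls relative to real predictors), bacterial starts `ATG/GTG/TTG`,
stops `TAA/TAG/TGA`, both strands, minus-strand hits reflected onto forward
coordinates.

Two deliberate simplifications: no partial (edge-truncated) ORFs are
reported, and a candidate containing *any* non-ACGT character is
disqualified outright — there is no fallback to a later, cleaner start for
the same stop. The second rule is the mechanism that keeps the second pass
out of hard-masked regions (an ORF overlapping a masked interval
necessarily contains an `N` codon); dropping the whole candidate rather
than rescuing a shorter one occasionally under-calls next to mask
boundaries, which is the conservative direction for a surrogate. The
statistical machinery of real prokaryotic predictors (codon usage, RBS
models, dynamic programming) is explicitly out of scope.

## Consolidation

Second-pass calls whose span overlaps a first-pass masked region by one or
more bases are dropped and counted. With span masking and the built-in
caller this cannot happen (the tests assert it); the rule is a safety net
for exon-mode masking and for external predictors that may call through
short `N` runs. Identifier collisions are resolved by prefixing second-pass
ids with `sp.` until unique; output ordering (contig, span start, pass) is
deterministic, and the count identity
`|combined| = n_first + n_second − dropped` is asserted on every run.

## Evaluation metrics

* Gene length is **coding length** (sum of exon widths), not span length —
  this matches how predictors report lengths and makes intron-containing
  and single-CDS genes comparable.
* A truth gene is **detected** when same-contig (by default same-strand)
  predicted exons cover at least `overlap_frac` of its coding length.
  The default 0.5 is the conventional coverage criterion; it is a parameter
  because no single value is canonical.
* **Fragmentation** is the mean number of distinct predicted calls with at
  least one coding-base overlap per detected truth gene; 1 means intact
  recovery, values above 1 quantify splitting.
* **Percent identity** is defined over a Needleman–Wunsch global alignment
  with linear gap scoring (defaults +1/−1/−2): identity =
  100 × matches / alignment columns, gap columns included in the
  denominator. Among equal-score alignments the one with fewest gap columns
  is used; since score and gap count jointly determine the match count,
  this tie-break fully determines the reported identity. The definition is
  stated because "similarity" is ambiguous across annotation tools;
  reports from this package always mean identity over global-alignment
  columns.
* The median uses the lower-middle element for even counts, for
  determinism.

## The synthetic-data generator

`simulate_metagenome()` emulates the features of real mixed-community
assemblies that the workflow's correctness depends on — and nothing more:

* contigs of i.i.d. composition at a configurable GC (default 0.5), with
  intergenic DNA between genes;
* prokaryote-like and viral genes as single-CDS ORFs: `ATG`, random
  non-stop codons, terminal stop; lengths 300–1800 nt (multiples of 3),
  i.e. the typical bacterial gene-length range with a floor at the ORF
  caller's default threshold;
* eukaryote-like genes with 2–4 exons of 250–600 nt and `GT...AG` introns
  of 60–150 nt, the compact gene architecture of microbial eukaryotes
  (fungi, protists) rather than the long-intron architecture of metazoan
  genomes;
* default scale 20 contigs of 20–100 kb with 200/60/20
  prokaryote/eukaryote/virus genes — large enough for stable proportions,
  small enough that an end-to-end run takes seconds.

Placement is rejection sampling of non-overlapping positions
(strand chosen per gene), erroring after bounded attempts if the
configuration cannot pack. One derived random stream drives contig
composition and an independent one drives gene content, so changing gene
parameters does not perturb the contig sequences at the same seed. Viral
genes are generated exactly like prokaryotic ones and differ only in label;
the distinction exists to exercise per-category reporting.

`degrade_predictions()` turns truth into a mock first pass: per-category
recall (the profile used throughout the tests is 0.95 for eukaryotes and
0.25 for prokaryotes/viruses — near-complete eukaryote recovery, a minority
of prokaryotes, matching how eukaryote-oriented homology predictors behave),
optional fragmentation of kept genes into 2–3 disjoint pieces within the
original exons, and bounded boundary jitter clamped to contig limits.

What the simulator deliberately does *not* model: repeat families, codon
usage and GC bias inside genes, phylogenetically realistic divergence,
sequencing error, or mis-assembly. Tests passing on this generator
therefore demonstrate the correctness of the *mechanics* — parsing,
masking, staging, consolidation, accounting — and the qualitative behavior
of naive calling on intron-containing genes; they do not certify accuracy
of any external predictor on real data.

## Numerical and degenerate-input choices

Empty inputs are valid everywhere: an empty FASTA yields an empty contig
set, an empty first-pass file leaves contigs unmasked, a fully masked
contig yields an empty second pass, and empty gene sets summarise to a
zero row with undefined (NA) means. Interval validity (`0 <= start < end`),
exon containment/sortedness/disjointness, unique identifiers and strand
symbols are enforced at container construction, so every downstream
operation can assume them. All randomness flows through explicit integer
seeds; identical inputs and seeds give byte-identical output files.

## Problem sizes used by the test suite

The suite verifies the masking engine against a position-by-position
boolean oracle on 200 randomized interval sets (including nested, duplicate
and touching intervals), the ORF caller against an exhaustive
(frame, start, stop) enumeration on 100 random 2-kb contigs, the aligner
against exhaustive enumeration of all alignment outcomes for 200 random
pairs of length ≤ 8, and the degrader's keep-counts against central 99.9%
binomial intervals computed with `qbinom`. End-to-end properties (count
identity, cross-pass non-redundancy, byte-level determinism, and the
fragmentation/recovery contrasts between naive and staged calling) run on
seeded simulations at the default scale. These sizes were chosen so the
whole suite completes in about a minute while leaving each property
statistically meaningful.

## Known limitations

* The built-in caller is a surrogate, not a replacement, for real
  prokaryotic predictors; its minimal-ORF convention shortens second-pass
  mean lengths relative to full gene models.
* Category assignment for real (non-simulated) second-pass calls is out of
  scope — on real data that information comes from downstream taxonomic
  annotation of the emitted proteins; the simulator provides ground-truth
  categories instead.
* The GFF3 support is the narrow gene/CDS dialect the workflow touches,
  not a general-purpose GFF3 parser; FASTQ, alignment formats and
  compressed streams are likewise out of scope.
* Masking irreversibly discards first-pass regions for the second pass; a
  first pass with poor specificity would propagate its false positives
  into lost second-pass sensitivity. The trust ordering is a modelling
  choice, not a guarantee.
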