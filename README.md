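# crossmask

Staged recovery of **both eukaryotic and prokaryotic protein-coding genes**
from assembled metagenomes, by coordinate-based hard masking.

## The problem

Metagenome gene callers are domain-specialised. Ab initio prokaryotic
predictors (MetaGeneMark, Prodigal-style) are accurate on bacterial and
archaeal sequence but shred intron-containing eukaryotic genes into short
spurious fragments; homology-based eukaryotic predictors (MetaEuk-style)
recover eukaryotic gene models well and also find a small, accurate subset
of prokaryotic genes, but miss most of the prokaryotic complement. On
assemblies with substantial eukaryotic content, neither tool alone yields a
usable cross-domain gene set.

`crossmask` implements the staged workflow that resolves this:

1. **First pass** — import eukaryote-oriented predictions (MetaEuk-style GFF3
   or pipe-delimited FASTA headers).
2. **Hard-mask** — merge the predicted gene regions per contig into a
   disjoint interval union and replace the covered bases with `N` by direct
   coordinate substitution (alignment-free, so it scales to multi-GB
   assemblies).
3. **Second pass** — run a prokaryotic predictor on the masked contigs:
   any external tool via a `{input}`/`{output}` command template, or the
   built-in six-frame ORF caller when no external binary is available.
   `N` codons disqualify candidate ORFs, so the second pass cannot re-call
   first-pass regions.
4. **Consolidate** — union both gene sets with globally unique identifiers;
   conflicts resolve in favor of the first pass. The count identity
   `|combined| = n_first + n_second − dropped` always holds.

Evaluation utilities quantify what the staging buys: per-category gene
counts and coding-length summaries, reference-based sensitivity, a
**fragmentation index** (mean number of distinct calls overlapping one true
gene; > 1 means genes were split), and global-alignment percent identity
(Needleman–Wunsch, linear gaps, identity = matches / alignment columns).
A seeded synthetic-metagenome generator plants single-CDS prokaryote-like
genes and multi-exon `GT...AG`-intron eukaryote-like genes with exact
ground-truth coordinates, and a mock-predictor degrader (per-category
recall, fragmentation, boundary jitter) emulates first-pass behavior — so
the whole pipeline is testable end to end without external binaries or
downloads.

## Worked example

Simulate a mixed community (20 contigs, 20–100 kb; 200 prokaryotic, 60
eukaryotic, 20 viral genes), degrade the truth into a realistic first pass
(recall 0.95 for eukaryotes, 0.25 for prokaryotes/viruses), then run the
staged workflow with the built-in second pass:

```r
library(crossmask)

sim  <- simulate_metagenome(sim_config(seed = 7))
mock <- degrade_predictions(
  sim$truth,
  mock_predictor_profile(c(eukaryote = 0.95, prokaryote = 0.25, virus = 0.25),
                         seed = 7),
  sim$contigs)

write_fasta(sim$contigs, "contigs.fa")
write_gff(mock, "first_pass.gff")
res <- run_workflow("contigs.fa", "first_pass.gff", workflow_config(),
                    outdir = "run1")
res
#> <workflow_result>
#>   first pass : 91 call(s)
#>   masked     : 124,510 bases (11.21%)
#>   second pass: 591 call(s), 0 dropped as overlaps
#>   combined   : 682 call(s)
```

91 first-pass calls mask 11.2% of the assembly; the second pass finds 591
ORFs in the remainder, none overlapping a masked region. How much did the
second pass recover? Evaluate both gene sets against the prokaryote+virus
truth:

```r
pv <- gene_set(sim$truth$calls[sim$truth$calls$category != "eukaryote", ])
compare_to_truth(mock, pv)          # first pass alone
#> <evaluation_report> 38/220 truth genes detected (sensitivity 0.173)
#>   predictions: 91; fragmentation 1.00; mean length ratio 1.140
compare_to_truth(res$combined, pv)  # staged workflow
#> <evaluation_report> 220/220 truth genes detected (sensitivity 1.000)
#>   predictions: 682; fragmentation 1.12; mean length ratio 0.630
```

The first pass alone detects 17% of the prokaryotic/viral genes; the
consolidated set detects all of them, while the workflow's eukaryotic calls
(and their mean length) are exactly those of the first pass — staging adds
prokaryotic yield without touching the eukaryotic models. The mean length
ratio drops below 1 because the naive built-in caller reports minimal ORFs;
an external predictor plugged into `workflow_config(external_cmd = ...)`
replaces it transparently.

A thin CLI wraps the same functions (`inst/scripts/crossmask.R`):

```sh
Rscript inst/scripts/crossmask.R run --contigs asm.fa --first-pass metaeuk.gff \
    --mode span --outdir run1
Rscript inst/scripts/crossmask.R mask --fasta asm.fa --calls metaeuk.gff --out masked.fa
Rscript inst/scripts/crossmask.R orfs --fasta masked.fa --min-len 300 --out orfs.gff
```

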