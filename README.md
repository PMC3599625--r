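# regap — reference-guided re-assembly of repeat-broken genomes

`regap` is an R package for closing the repeat-induced gaps that
mapping-based (re-sequencing) genome assembly leaves behind.  When reads
from a new strain are assembled against a reference, repeats longer than
the read length collapse: the mapper piles all copies' reads onto one
locus, the other copies lose coverage, and the consensus fragments into
many small contigs.  `regap` takes the raw reads and the reference, finds
those breaks, re-assembles every broken region locally, and stitches the
pieces back into gap-closed contigs.  It is aimed at small-to-medium
re-sequencing targets — organelle genomes with their large inverted
repeats, bacterial genomes, single chromosomes — and at method work that
needs a fully controllable, truth-tracked test bed.

## Method

1. **Map** all reads to the reference (built-in seed-and-extend mapper
   with banded local alignment; external SAM or a 6-column mapping table
   is accepted instead).
2. **Anchor calling** — maximal reference intervals with pileup depth ≥
   `minDepth` become contigs; each column takes the majority base.
3. **Gap-size filter** — contigs shorter than `gapSize` (default 500 bases,
   the platform read length) are discarded and their footprints, merged
   with uncovered intervals, become *repeat regions*.
4. **Iterative local re-assembly** — each region is rebuilt by a greedy
   overlap-layout-consensus walk seeded at its flanking anchors, which
   recruits reads from the whole mapped set while preferring the region's
   own bin; drafts are polished by insertion-aware majority consensus.
5. **Stitching** — anchors and region contigs are spliced by end-overlap
   consensus into final contigs (`final_1`, `final_2`, ...).
6. **Metrics** — total length, contig number, NG50/LG50 (NG(X): the contig
   length at which the descending cumulative length first reaches X% of
   the genome size; LG(X): how many contigs that takes), and gap-filling
   count/length (pre-existing inter-anchor gaps completely covered by a
   final contig).

A simulation module generates planted-repeat genomes (dispersed, tandem
and inverted families) and pyrosequencing-like reads (454/IonTorrent:
~200–500 bases, homopolymer-biased indels) with full ground truth.

## Worked example

```r
library(regap)

## a 50 kb genome with a dispersed 1.5 kb x 3 repeat family
tr <- makeGenome(50000, list(RepeatSpec("dispersed", 1500, copies = 3)),
                 seed = 1)
rs <- simulateReads(tr, ReadSimConfig(coverage = 15, seed = 2))
res <- runPipeline(rs$reads, truthGenome(tr), verbose = FALSE)
res
#> ReassemblyResult
#>   mapped reads: 1875
#>   anchors:      3
#>   repeat regions: 4
#>   final contigs:  1
#> AssemblyMetrics
#>   genome_size      50000
#>   total_length     49933
#>   contig_number    1
#>   ng50             49933
#>   lg50             1
#>   gap_fill_number  2
#>   gap_fill_length  1590
```

Anchor calling found 3 trustworthy contigs separated by repeat-broken
gaps; the pipeline re-assembled the repeat regions and merged everything
into a single 49,933-base contig, closing both inter-anchor gaps (1,590
bases).  Accuracy against the known truth:

```r
globalIdentity(as.character(contigSeqs(finalContigs(res)))[1],
               as.character(truthGenome(tr)[[1]]))$identity
#> [1] 0.9996
```

A command-line front end over the same functions is installed at
`inst/scripts/regap` (subcommands `run`, `sweep-gap`, `sweep-coverage`,
`sim-genome`, `sim-reads`, `metrics`).

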