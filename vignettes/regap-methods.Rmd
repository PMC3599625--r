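---
title: "Reference-guided re-assembly of repeat-broken genomes with regap"
author: "regap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-guided re-assembly of repeat-broken genomes with regap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regap)
```

## The problem

In a re-sequencing project, reads from a new individual or strain are
assembled against an existing reference genome rather than de novo.
Mapping-based consensus works well in unique sequence, but repeats longer
than the read length defeat it: reads sampled from different repeat copies
are interchangeable, mappers place them at one arbitrary copy, and the
other copies lose their coverage.  The resulting assembly fragments into
many small contigs separated at the repeat loci — the classic failure mode
of pyrosequencing (Roche 454 / IonTorrent) re-sequencing pipelines, where
chloroplast-type large inverted repeats and dispersed nuclear repeats break
otherwise contiguous assemblies.

`regap` closes those breaks.  The key observation is that although repeat
reads are globally ambiguous, each repeat *locus* is locally unambiguous:
its flanking unique sequence anchors it, and the pooled reads from all
copies of the family are enough to rebuild the repeat unit.  The pipeline
therefore:

1. maps all reads to the reference (built-in seed-and-extend mapper, or an
   external SAM / mapping table);
2. calls **anchor contigs** as maximal reference intervals with pileup
   depth at least `minDepth`, taking the column-majority base;
3. discards contigs shorter than the **gap size** and merges their
   footprints with uncovered intervals into **repeat regions**;
4. re-assembles every repeat region iteratively from its locally mapped
   reads, recruiting additional reads from the whole mapped set as the
   contig grows;
5. stitches anchors and repeat-resolved contigs into final contigs by
   end-overlap consensus, and
6. reports totals, NG50/LG50 and gap-filling counts.

A synthetic-data module (`makeGenome`, `simulateReads`) generates
planted-repeat genomes and pyrosequencing-like reads with full ground
truth, so every stage of the method is testable without any external
dataset.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `gapSize` | 500 bases | contigs shorter than this are treated as repeat-broken and re-assembled. The default follows the read-length argument: repeats shorter than a read are resolved by mapping alone, so the threshold sits at the platform read length (~500 bases for 454, ~200 for IonTorrent). |
| `minDepth` | 3x | minimum pileup depth for anchor calling; below this a column is considered uncovered. |
| `flank` | mean read length | bases added around a repeat region when binning reads, so that boundary-spanning reads that tie the repeat to its locus are always recruited. |
| `minOverlap` | 40 bases | minimum end overlap for any merge (read extension, region stitching). |
| `maxMergeMismatchFrac` | 0.02 | maximum mismatch (or edit) fraction inside an accepted overlap. |
| `maxIters` | 10 | cap on assemble/recruit passes per repeat region. |
| mapper `k` | 15 | seed k-mer length; `minIdentity` 0.9 and `minAlignedFraction` 0.9 gate reported placements. |

Increasing `gapSize` marks more of the reference as repeat region — the
repeat-region footprint is monotone non-decreasing in `gapSize` (a property
the test suite checks) — at the cost of re-assembling more sequence.

## Region re-assembly: anchored walks

The local assembler is a greedy overlap-layout-consensus procedure over
suffix/prefix overlaps (substitution-tolerant scans by default).  Plain
greedy assembly of a repeat bin, however, cannot tell the copies of an
identical family apart: boundary reads from *different* copies both overlap
the repeat unit, and an unseeded merge order happily builds chimeras that
join the left flank of one copy to the right flank of another.  Those
chimeras fail to stitch and leave the assembly broken.

`resolveRegion` therefore anchors the walk at the locus: it starts from the
flanking anchors' end windows, extends read by read towards the middle, and
at every step recruits candidates from the entire mapped read set while
*preferring reads binned to this region* — the locus-specific boundary
reads — over reads recruited from other copies.  Extension from both sides
continues until the two walks close on each other (or on the opposite
anchor), no qualifying read remains, or a length cap is hit.  Regions
touching a reference end extend from their single anchor; a region with no
anchors at all falls back to plain `greedyAssemble` of its bin with
iterative end-overlap recruitment, which is also the exported general-purpose
assembler.  The iteration contract is checked at a fixed point: the
procedure repeats until the contig multiset is unchanged between passes or
`maxIters` is reached.

With noisy reads the growing contig tail carries the chosen reads' errors,
including homopolymer indels, which the strict substitution-only overlap
scan cannot align across.  Extension therefore falls back to a banded
edit-tolerant overlap (alignment anchored at the contig's 3' end and the
read's 5' start) on a bounded, deterministically chosen candidate subset
whenever the strict scan finds nothing.

Every region contig is then **polished**: its supporting reads are
re-mapped onto the draft with the built-in local aligner, and each column
is replaced by the majority vote over bases, deletions, and — where more
than half of the covering reads insert the same sequence between two
columns — insertions.  Insertion-aware voting matters: a draft base dropped
by a read deletion error can only be restored by an insertion column.
After polishing, two partial walk contigs that over-ran each other in the
middle of a region are merged if they now share a qualifying (possibly
edit-tolerant, up to 4.5 kb deep) overlap.

## Stitching and junction policy

`stitchContigs` walks the reference left to right.  At each junction it
splices the current contig to the next piece when a qualifying end overlap
exists (strict scan first, edit-tolerant fallback on capped end windows
second); inside an overlap the higher-mean-depth side contributes the
bases.  Region contigs may chain across a junction, and a region contig
that only reaches one anchor extends that side alone.  On junction failure
the contig is closed and a new one starts — contigs, never N-gapped
scaffolds.  Region contigs that merge nowhere are emitted unchanged, since
they still represent assembled sequence.  An optional `circular` flag
attempts one extra end-to-end overlap (first vs. last contig, or the two
ends of a single contig) to linearise circular genomes such as organelles.

## Metrics

NG(X) is the contig length at which the descending cumulative contig
length first reaches X% of the genome size; LG(X) is the number of contigs
needed to get there.  Both are `NA` — a distinguished marker, never 0 —
when the assembly is too small to reach the threshold.  **Gap filling** is
defined operationally: a pre-existing inter-anchor gap counts as filled
when some final contig's reference projection covers it entirely; the
count and the total gap bases are reported.  Whole-assembly accuracy is
measured by `globalIdentity`, a banded alignment (match +1, mismatch −2,
gap −3) with free end gaps, reporting matches over aligned columns;
free end gaps mean unassembled termini reduce completeness (total length)
rather than identity, which is the conventional separation.

## The read simulator

`makeGenome` draws an i.i.d. uniform ACGT background and plants repeat
families: `dispersed` copies scattered with a minimum spacing (default
2 kb, so each copy keeps unique flanks), `tandem` blocks, and `inverted`
pairs whose second copy is the reverse complement of the first — the
structure of the chloroplast large inverted repeat.  Per-copy divergence
applies substitutions to copies after the first.

`simulateReads` draws `round(coverage * L / meanLen)` reads with uniform
start positions and strands and truncated-normal lengths (minimum 30
bases).  The error model is per-base: substitutions at `subRate`,
insertions and deletions at `insRate`/`delRate`, with indel rates
multiplied by `homopolymerMultiplier` inside homopolymer runs of length at
least 3.  Defaults — 0.1% substitutions, 0.5% insertions, 0.5% deletions,
multiplier 3 — caricature pyrosequencing chemistry, whose dominant error
mode is homopolymer-length miscalls.  The simulator does not model
flowgram-level signal, quality-score calibration, coverage biases (GC,
chimeras) or paired ends; passing tests demonstrate repeat resolution under
idealised uniform sampling with a realistic error *composition*, not
performance on any particular instrument's artefacts.  In a coverage
sweep, the levels are nested random subsamples of one read set simulated
at the highest requested coverage (per replicate seed) — the in-silico
analogue of subsampling a real sequencing run, which keeps the coverage
response curve free of between-dataset sampling noise.

Circularity is emulated, not modelled: an optional flag appends the first
`meanLen` bases to the template before sampling so reads span the origin.

## Numerical and determinism choices

* Coordinates are 1-based closed in memory (the `GRanges` convention);
  BED, the mapping TSV dialect and FASTA headers use 0-based half-open
  on disk.
* Consensus ties break towards the reference (or draft) base, then
  alphabetically; deletion ranks last.
* Greedy merge ties break by longer combined length, then lexicographic
  id pair.  Mapper placement ties break towards the smallest reference
  coordinate, then the `+` strand — so reads from identical repeat copies
  pile onto the leftmost copy deterministically, which is exactly the
  collapse the repeat regions are designed to absorb.
* "Shorter than the gap size" is a strict inequality: a contig of exactly
  `gapSize` bases survives as an anchor.
* All simulation randomness flows from explicit seeds; the pipeline itself
  contains no randomness, and identical inputs give byte-identical
  outputs.

## Scale of the validation experiments

The packaged experiments run on a 100 kb genome carrying a dispersed
2 kb x 3 family plus a 3 kb inverted repeat (anchor calling leaves at
least three repeat-broken gaps), with 15x exact reads and 20x reads under
the default error model, and on a 30 kb organelle-like inverted-repeat
fixture for the coverage (1-20x) and gap-size (30-10,000) sweeps.  The
coverage sweep uses noise-free reads so the measured response isolates the
coverage variable: with the default error model the curve is the same
except for base-scale consensus jitter at saturation, and noise tolerance
is already established by the noisy full-pipeline experiment.  These
sizes exercise every code path — ambiguous mapping, anchored walks through
identical copies, inverted-orientation recruitment, polishing, stitching —
while keeping a full run in tens of seconds on one core.

## Known limitations

* Repeat copies of a family are resolved per locus only where unique
  flanks anchor them; a tandem array longer than the recruitment horizon
  collapses to its unit consensus, and the log notes the region as
  unclosed.
* Substitution divergence between copies up to the overlap mismatch
  tolerance (2%) is absorbed; beyond that, copy-specific variants are
  reported as the recruited majority.
* The mapper reports one placement per read (no split or chimeric
  alignments) and assumes reads are contained in the reference, as in
  re-sequencing.
* Structural variation between sample and reference other than the
  repeat-induced gaps (large insertions, rearrangements) is out of scope;
  novel sequence absent from the reference cannot be anchored.
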