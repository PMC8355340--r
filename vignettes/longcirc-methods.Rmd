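---
title: "Calling and characterizing circRNAs from long-read split alignments"
author: "longcirc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and characterizing circRNAs from long-read split alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longcirc)
```

## The problem and the model

Circular RNAs are covalently closed transcripts produced when a splice
donor joins an upstream splice acceptor (back-splicing). Because their
exons overlap the linear mRNA of the host gene almost entirely, the only
sequence evidence unique to a circRNA is its back-splice junction (BSJ).
A long nanopore read made from a nicked circular molecule crosses that
junction: a split aligner cannot represent the coordinate wrap-around in
one alignment, so the read splits into two genomic segments that appear
in *reversed* order along the read — the read-5' segment maps
transcript-downstream of the read-3' segment. That reversed geometry is
the calling signal this package is built around.

The pipeline has four stages.

**Read filtering.** Reads enter the analysis when their length is at
least 250 bases and their mean base quality is at least Phred 7 (both
inclusive). Per-base qualities relate to error probabilities through
$Q = -10\log_{10}(\mathrm{err})$; for example $Q = 11.95$ corresponds to
an error rate of $10^{-11.95/10} = 0.064$. The mean read quality is, by
default, the Phred value of the *mean error probability* rather than the
arithmetic mean of Phred values: averaging Phred values directly
overweights high-quality bases, and long-read QC tools average on the
error scale. Since the two conventions differ, `meanQuality()` and
`filterReads()` expose a `method` switch (`"error"`, the default, or
`"phred"`).

**BSJ calling.** Per-read alignments arrive as 21-column PSL. Each hit
gets a Blat-style score

$$\mathrm{score} = \mathrm{matches} - \mathrm{mismatches} -
  \mathrm{qGapCount} - \mathrm{tGapCount},$$

i.e. one penalty per gap *opening* on either axis, the published UCSC
PSL score convention (the score definition we build on names only
"gap penalties"; this is BLAT's own). Two hits from one read form a BSJ
candidate iff they

1. share the chromosome and genomic strand,
2. span at most 1 Mb together (measured on the combined genomic span,
   which *is* the putative circRNA region),
3. overlap genomically by fewer than 50 bp,
4. are in reverse order relative to the read, and
5. each reach a score of 30.

A single read passing all criteria suffices to call a circRNA; the score
requirement is what makes that acceptable.

**End correction and collapsing.** Nanopore 1D reads have heterogeneous
ends, so raw candidate boundaries scatter around the true BSJ. If both
ends lie within 30 bp of an annotated exon boundary on the candidate
strand — an exon start for the circRNA start, an exon end for the
circRNA end, which is the genomic phrasing of "acceptor side" and
"donor side" on either strand — each end snaps to its nearest such
boundary. Ties are broken toward the boundary yielding the longer
circRNA, then the smaller coordinate, so output is deterministic.
Candidates failing the exon rule are compared with known circRNA
catalogs (circBase / circAtlas / CIRCpedia-style tables); a span Jaccard
of at least 0.95 with a record snaps the ends to that record. Jaccard
(intersection over union) was chosen over one-sided coverage because it
penalizes overhang and underhang symmetrically; the denominator
convention is not fixed by the method description we follow, so it is
exposed as `knownJaccard`. Candidates failing both rules are excluded.
Reads on mitochondrial chromosomes or overlapping rRNA gene models are
removed (the rRNA flag lives in the gene-model input rather than being
inferred from gene names, which would be fragile), and the survivors
collapse to one record per unique (chromosome, strand, start, end) with
read counts, mean annotation overlaps (gene/exon/intron/EST bp per
read), and the minimum/maximum/mean of the per-read total end adjustment
(the sum of bp moved at both ends).

**Multi-round (concatemeric) reads.** Strand-displacing reverse
transcription can run several times around the circle, producing reads
with three or more alignment segments tiling one locus. A read is
classified `multi_round` when it has at least three hits on one
(chromosome, strand) locus within the span limit and at least two
read-adjacent segment pairs are BSJ-consistent — the later segment
restarts at or upstream (in transcript sense) of the earlier segment's
start. Such reads are counted separately and do **not** contribute to
circRNA support: counting every pass would inflate quantification. The
adjacency test uses all hits of the read, not only score-passing ones,
because the terminal partial pass of a concatemer is often short yet
still marks another round.

## circRNA-internal splicing

All feature analyses run on the BSJ-supporting reads of each circRNA,
using their raw mapped blocks (not the corrected ends): splice evidence
must come from the alignment itself.

**Novel and cryptic exons.** Within one read, mapped blocks separated by
at most 10 bp (an internal-deletion allowance for noisy reads) merge
into segments. A segment is an exon candidate iff the genome carries the
splicing signature immediately around it: `AG` at its transcript-5'
flank and `GT` at its transcript-3' flank (on the minus strand this is
genomic `AC` left of the segment and `CT` right of it). Candidates with
identical (start, end) coordinates in at least two reads are kept —
exact identity after the merge, because corroboration means agreeing on
the exon definition; fuzzier clustering would conflate neighboring
variants. Kept exons with at least 95% coordinate Jaccard to an
annotated exon are "known"; those with no overlap are "unique novel";
partial overlap (sharing one splice site) makes them "cryptic".
Single-exon circRNAs are excluded: their reads assemble one exon from
two mapping locations across the BSJ and carry no internal splice
evidence. Microexons are novel exons of 3–29 nt, subclassed 3–15 and
16–29 nt.

One interplay needs an explicit rule: a read that retains an intron maps
exon–intron–exon as one contiguous segment, which is itself AG…GT
flanked (by the *neighboring* introns' signals). Treating it as a novel
exon would both mislabel retention evidence and veto every retained
intron through the "no novel exon inside" gate below. Segments that
fully span an annotated intron are therefore excluded from exon
candidacy — they are retention evidence and are consumed by the intron
analysis instead. This is the only reading under which the retention and
novel-exon criteria can both fire on the same data.

**Intron retention.** For every annotated intron inside a circRNA span,
the analysis records how many supporting reads span the intron position
and what fraction of the intron length their blocks cover (union
coverage). At the circRNA level the *intronic fraction* is the mean
intron-mapping bp of the supporting reads divided by their mean
gene-mapping bp. An intron is called retained iff it is spanned by at
least 20 reads, covered over at least 90% of its length, the circRNA's
intronic fraction exceeds 3% (strictly), and no novel exon was detected
inside it. The read-count and coverage gates are per intron while the 3%
gate is per circRNA; that split follows the most literal reading of the
criteria this package implements.

**Exon usage.** For each exon inside a circRNA, usage is the number of
supporting reads with sequence mapped to the exon divided by the number
whose corrected span covers the exon's position — reads that do not span
the position cannot witness exclusion. Constitutive exons score 1,
unused exons 0. Records used by fewer than 10 reads (nick mode) or 50
reads (panel mode, which sequences targeted loci much deeper) are
flagged suppressed. `linearInclusion()` computes the matching fraction
for linear-transcript reads so circRNA and host mRNA usage can be
compared.

**Reading frames.** Gene models carry per-exon coding phases (codon
offset 0/1/2 at the exon 5' end, GFF3 convention). The phase dictated to
an inserted exon continues the frame of the immediate upstream annotated
exon. An exon is in frame iff its length is divisible by 3; stop codons
(TAA/TAG/TGA) are scanned only over codons fully inside the exon, in
that single dictated phase — junction-spanning codons are ignored
because the analysis is per exon. With no coding upstream exon all three
phases are scanned and the result flagged `phase_unknown`.

## Conservation

A circRNA's identity across assemblies is its BSJ, so conservation is
scored on BSJ coordinates alone, ignoring internal splice structure: the
20 bp at each end of the circRNA are lifted through a chain map,
recombined into a BSJ, and compared for an *exact*
(chromosome, start, end, strand) match in the other set; the match must
also reproduce the original coordinates when lifted back. The lift is
strict: an anchor maps only when all 20 bases fall inside one ungapped
block of a single chain (among covering chains the highest-scoring one
wins, ties by file order, mirroring best-chain liftover behavior).
Partial anchor mapping is not tolerated — with exact matching required
downstream, a partially mapped anchor could only produce a wrong
coordinate.

## The simulator

`makeReference()` and `simulateCircReads()` generate everything the
pipeline consumes: a toy genome (two chromosomes, a dozen multi-exon
genes with canonical GT…AG introns and per-exon phases), one circRNA per
gene, known-catalog entries for half of them, a coordinate-shifted
second assembly with chains in both directions, and reads with full
ground truth. Molecules are opened by exactly one nick at a uniform
position (the library design the once-nicked read model emulates cuts
predominantly once; multi-nick molecules are out of scope), or run 2–3
rounds around the circle when simulating concatemers. The PSL an ideal
split aligner would emit is written directly rather than running an
aligner: the testbed stays offline and the calling logic is isolated
from aligner idiosyncrasies. An optional end-noise mode trims the
BSJ-adjacent alignment ends by up to 15 bp to exercise the 30-bp snap;
optional per-base mismatch/insertion/deletion rates perturb reads and
their alignment records coherently. Qualities are drawn from a normal
distribution (mean 12, sd 2) truncated to [2, 40].

Defaults are the study conditions used throughout the test suite:
12 loci, depth 30 per circRNA, error-free reads, no concatemers, and one
planted instance each of a fully retained intron, a partially retained
intron (40% of reads), a unique novel exon (60 nt), a cryptic exon
extending an annotated exon 25 nt at its 5' side, microexons of 12 and
20 nt, and a 9-nt exon carrying a stop codon in its dictated phase.
Depth 30 keeps every retention gate testable (≥ 20 spanning reads) while
the whole suite stays fast; feature isoforms at 50% frequency give ~15
supporting reads, far above the 2-read corroboration gate.

Simulated genes all sit on the plus strand; minus-strand code paths
(flank signatures, end snapping, strand-flipping liftover, PSL
coordinate normalization) are exercised by hand-constructed fixtures in
the unit tests instead, which keeps the read-to-alignment bookkeeping in
the simulator simple and auditable.

What passing tests therefore show: the calling geometry, thresholds,
collapsing arithmetic, feature gates and conservation logic are
implemented exactly as specified, and the whole pipeline inverts the
generative model perfectly when alignments are ideal. What they do not
show: robustness to real aligner behavior (soft-clipping heuristics,
repeat-induced multi-mapping), realistic nanopore error structure
(homopolymer deletions, quality–error correlation), rRNA/mitochondrial
contamination patterns, or organism-scale annotation complexity
(overlapping genes, transcript-level exon conflicts).

## Worked example

```{r example, eval = FALSE}
ref <- makeReference(simConfig(seed = 1))
sim <- simulateCircReads(ref)
dir <- tempfile()
writeSimulation(ref, sim, dir)

cfg <- pipelineConfig(
  fastq = file.path(dir, "reads.fastq"),
  psl = file.path(dir, "truth.psl"),
  genome = file.path(dir, "genome.fa"),
  genes = file.path(dir, "genes.tsv"),
  known = file.path(dir, "known.tsv"),
  out_dir = file.path(dir, "out"))
res <- runPipeline(cfg)
res$summary$unique_circRNAs     # 12
as.data.frame(res$retained_introns)
```

## Numerical and degenerate-input choices

* All on-disk formats are 0-based half-open (PSL/BED convention);
  GRanges-backed objects are 1-based closed as usual in Bioconductor,
  and readers/writers convert at the boundary.
* Minus-strand PSL block coordinates are normalized to the forward read
  axis at parse time, so reverse-order logic sees one read axis.
* Boundary-snap ties and best-chain ties are broken deterministically
  (see above); identical runs produce identical outputs, and
  `runPipeline()` is a no-op when outputs for the same resolved config
  already exist.
* Empty inputs degrade cleanly: an empty PSL yields a zero summary and
  success; a circRNA with no supporting reads yields empty feature
  tables; zero filtered reads flags percentages as undefined rather than
  dividing by zero.
* `N` bases never extend a poly(A) run in `polyAStretch()` (k = 7 by
  default), the conservative reading of "7 or more A residues".

## Known limitations

* EST annotation is supported as an overlap layer but empty by default;
  no downloader is provided.
* Reads with more than two score-passing hits that are not concatemers
  are classified `linear_like` and never salvaged into candidate pairs;
  whether partial salvage is worthwhile is an open question the package
  resolves conservatively.
* The conservation module lifts only BSJ end anchors; it does not align
  circRNA bodies or infer synteny.
* Quantification is read-count based; no attempt is made to model
  nick-position or length biases in capture efficiency (a
  size-proportional sampling weight exists in the simulator's design
  space but is off by default).
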