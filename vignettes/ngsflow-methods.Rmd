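---
title: "ngsflow: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ngsflow: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Most NGS experiments — RNA-Seq, ChIP-Seq, Ribo-Seq, variant calling — share
the same skeleton: a set of FASTQ files per sample is pushed through a chain
of external command-line tools (trimmer, aligner, caller) and then analysed
inside R. The fragile parts are rarely the tools themselves but the glue:
keeping per-sample file paths consistent across steps, rerunning only what
failed, capturing logs, and regenerating a report when anything upstream
changes. `ngsflow` packages that glue as a small, testable core plus the
analysis utilities that typical transcriptomics workflows need downstream.

## Workflow model

A workflow is driven by exactly one user file, the **targets** sample sheet:
a TSV with columns `FileName1`, optional `FileName2` (paired-end mate),
`SampleName`, `Factor` and arbitrary extras. Comment lines of the form

```
# <CMP> CMPset1: A-B, A-C
```

declare named comparison sets as hyphen-separated factor pairs — the
contrasts later consumed by DEG filtering. Sample names and factor labels
are restricted to `[A-Za-z0-9_.]`: they end up inside file names, rendered
command lines and the `A-B` pair syntax, so whitespace and shell
metacharacters are rejected outright, and the hyphen is excluded because it
is the pair separator itself.

Each step is described by a **param** template (TSV: `slot_type`, `prefix`,
`value`) naming one executable and its argument slots in order. Values may
use five placeholder tokens — `<FileName1>`, `<FileName2>`, `<SampleName>`,
`<OutFile>`, `<Reference>` — and nothing else; an unknown token is a parse
error, never emitted literally. Fixing the vocabulary in code rather than in
data files means a sample sheet can never smuggle arbitrary shell text into
a command.

`build_sysargs()` instantiates a step over all samples: every placeholder is
substituted, giving one command per sample with registered inputs and
expected outputs. Commands are stored as argument token vectors; the display
string is just their join, and at execution time each token is individually
quoted, so no unquoted shell text ever derives from data. `chain_targets()`
rewrites `FileName1` to the step's first registered output (dropping
`FileName2`, since a step output is a single file), which is how downstream
sample sheets are derived automatically instead of being written by hand.

## Runner semantics

A sample counts as *completed* when all its expected outputs exist with size
greater than zero. This is deliberately minimal: output content is
tool-specific, but a zero-byte file is the universal signature of an
interrupted tool. `run_serial()` skips completed samples (unless
`force = TRUE`), launches the rest in row order, captures each job's
stdout/stderr to `<logdir>/<step>/<sample>.log`, and appends one JSON line
per result to an append-only `status.jsonl` registry — after every sample,
so a crash loses at most the in-flight record. Failed jobs have their
partial outputs renamed with a `.failed` suffix; completion can therefore
never be faked by debris. There are no automatic retries: a rerun of the
same call is the restart mechanism, and it executes exactly the missing
samples.

`run_parallel()` runs the same per-sample job through a local fork-based
process pool (`parallel::mclapply`, unprescheduled so each sample is an
independent job). Results are reported in targets row order regardless of
completion order, and a worker crash marks only its own sample failed.
Registry appends are single short `O_APPEND` writes, which POSIX keeps
atomic at these sizes. Cluster schedulers are intentionally out of scope;
the parallel map is the extension point.

## FASTQ statistics

`fastq_quality_summary()` accumulates all eight QC panels in one streaming
pass over batches of at most `batch_size` reads: (1) per-cycle quality
min/Q1/median/Q3/max and mean, kept exactly via a 94-level quality-count
matrix per cycle rather than approximate quantile sketches; (2) per-cycle
base proportions over A/C/G/T/N, with denominators counting only reads that
reach the cycle, so columns always sum to 1; (3) a histogram of
`floor(mean quality)` per read; (4) read lengths; (5) exact full-sequence
duplication multiplicities (a hash of distinct sequences — the one
accumulator whose memory scales with distinct reads rather than batch
size); (6) distinct k-mers ending at each cycle (default k = 4); (7) GC
fraction per read in twenty 0.05-wide bins; (8) N proportion per cycle.
Because every accumulator is a count, the summary is bitwise identical for
any batch size and any record order, which the tests assert.

Quality encoding is declared, not sniffed: Phred+33 only, with characters
below `!` rejected. Subsampling uses reservoir sampling under a caller seed;
`subsample = Inf` is deterministic.

`preprocess_reads()` streams reads through a composable transform.
Adaptor trimming is exact suffix overlap (the longest read suffix of at
least `min_overlap` bases equal to an adaptor prefix is removed);
error-tolerant matching is out of scope and better served by dedicated
trimmers. Quality trimming truncates after the last cycle reaching the
threshold; `bases_removed` counts trimming losses on reads that stay in the
output, while discarded reads are accounted by `dropped` alone.

## Counting and coverage

SAM text is parsed directly; CIGAR-to-reference-block arithmetic is
delegated to `GenomicAlignments::extractAlignmentRangesOnReference`
(M/`=`/X/D consume reference contiguously, N splits blocks, I/S/H consume
none), with adjacent D-joined ranges merged and zero-width artefacts of
N-only gaps dropped. The test suite cross-checks this against a
hand-walked CIGAR oracle.

`featuretype_counts()` counts a read once per feature *type* it overlaps by
at least one base (type-level, not per-feature, counting), split by read
strand, with only primary aligned records considered and zero rows emitted
for unseen types. Overlap detection is `GenomicRanges::findOverlaps` over
the block ranges; strand modes `sense`/`antisense` compare feature strand
with read strand, with unstranded (`*`) features matching any read.

`feature_coverage()` anchors profiles at the CDS of each transcript: U
upstream and D downstream nucleotides at single-base resolution, the two
codons themselves, and the spliced CDS compressed into B bins with
boundaries at `floor(i*L/B)` (the last bin absorbs the remainder). All
vectors are 5'→3' in transcript orientation; minus-strand transcripts are
flipped. Depth is the number of primary alignment blocks covering a
position, taken from `GenomicRanges::coverage`. The stop codon is assumed
included in the CDS span, and start/stop positions are the CDS extremes in
transcript orientation. Transcripts without CDS or with a spliced CDS
shorter than B bases are skipped with a warning rather than producing
degenerate bins.

## ORF prediction

An ORF is maximal: ATG to the first in-frame stop, stop included. After a
stop, scanning resumes beyond it, so internal ATGs sharing a stop are
suppressed — the 5'-most variant is the reported one, and suppressed
variants are recoverable by rescanning subsequences. Codons containing N
neither start nor stop scanning. Minus-strand ORFs are found on the reverse
complement and mapped back by `start' = L − end + 1`. Ranking is by
descending length, then ascending forward start, then `+` before `-`;
`longest_disjoint` greedily keeps top-ranked ORFs whose forward-coordinate
ranges do not overlap already kept ones. The default `min_length` of 30 nt
targets the short-ORF regime while suppressing the flood of spurious
9–21 nt hits in random sequence. Frame is `((start − 1) mod 3) + 1` in
scanning orientation.

## Venn intersects and DEG filtering

`overlapper()` assigns each element of the union to the region keyed by the
full subset of sets containing it — disjoint by construction, so region
counts always sum to the union size. Full region enumeration is capped at
20 sets (2^20 − 1 regions); beyond that the error advises pairwise
analysis. Diagrams are drawn for 2–5 sets; rather than hard-coding label
coordinates for up to 31 regions, the plot rasterises the circle/ellipse
layout on a grid, classifies each grid point by its membership bitmask, and
places each region's count at the centroid of its points — which also lets
a test assert that every region of every layout has drawable area.

`filter_degs()` consumes `<comparison>_logFC`/`<comparison>_FDR` column
pairs; FDR is consumed, never computed — multiple-testing correction
belongs to the upstream DE tool. Positive log-fold-change means higher in
the first-named factor of the `A-B` comparison pair, matching the targets
file ordering. Missing values never pass the cutoffs.

## Reporting

`build_report()` is a deterministic template filler: `{{field}}`
placeholders resolve against a named section list (data frames become
Markdown tables), the only timestamp is the caller-supplied `report_date`,
and a sidecar digest cache skips rewriting when no section changed —
regenerating from unchanged state is byte-identical. Literate code-chunk
evaluation is out of scope; the report is data-driven Markdown.

`gen_workenvir("rnaseq-mini", dir)` emits a self-contained demo: synthetic
genome/annotation/reads, a targets file with two comparison sets, param
files whose two command steps use `cp` as a portable stand-in for trimmer
and aligner, and a report template. `run_workflow()` (or the
`inst/scripts/run-workflow.R` CLI) runs it end to end in a few seconds on
one CPU, exercising the full chain: build → run → chain → align stats →
FASTQ QC → DEG filter → Venn → report.

## The synthetic-data generator

`make_genome()` draws i.i.d. bases at a target GC. `make_annotation()`
places non-overlapping genes and *writes the coding sequence into the
genome*: ATG, random sense codons, a stop — plus an in-frame stop
immediately 5' of the ATG, so the maximal ORF found by `pred_orf` is
exactly the CDS (otherwise a chance upstream in-frame ATG would extend it).
The CDS is kept contiguous within one exon so the unspliced genome scan can
recover it; when a second exon is drawn it is a UTR exon across an intron.
`simulate_reads()` samples read positions from CDS regions (sense strand)
or the background (random strand), applies i.i.d. substitution errors, and
assigns qualities from a linear decay model `Q(c) = 40 − 0.3(c−1)` with
Gaussian noise (sd 2) clipped to [2, 40] — a caricature of Illumina decay
sufficient for exercising the QC panels. The emitted SAM encodes the true
alignments (`<len>M`, flags 0/16), so alignment statistics on error-free
simulations are 100.0 % by construction and serve as a ground-truth check,
not a benchmark.

What the generator does *not* emulate: indels and clipping in reads,
spliced alignments, quality-dependent error profiles, duplicate/PCR
structure, paired-end fragments, multi-mapping. Tests passing on this
generator therefore validate the bookkeeping and arithmetic of the
operations, not robustness to real-data pathologies.

Default problem sizes in the tests and demo (genomes of 10–25 kb, 5–10
genes, hundreds of reads, 8-sample toy steps, 50–100 oracle instances) were
chosen so the whole suite exercises every code path in about two minutes on
a single core while keeping every oracle comparison exact.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere externally (GFF3/SAM
  native); Bioconductor containers carry them unchanged.
* Quality percentiles are exact order statistics over integer Phred counts;
  no interpolation, so `type`-dependent quantile differences cannot arise.
* Empty FASTQ batches, zero-read simulations, empty SAM bodies and absent
  status registries all return empty-but-well-typed objects rather than
  errors; zero-byte outputs are never completion.
* Ties in ORF ranking and bin boundaries are fixed by the documented rules
  (ascending start, `+` first; `floor(i*L/B)`), so all results are
  deterministic.

## Known limitations

Paired-end mates are counted independently (no fragment model); HPC
scheduler backends are not included; the FASTQ duplication accumulator
holds one entry per distinct sequence, so its memory is not bounded by
`batch_size` on extremely diverse libraries; GFF3 parsing keeps attributes
as verbatim strings (sufficient for `ID`/`Parent` linkage and round-trip
fidelity, but no escaping-aware attribute editing); encoding detection is
deliberately absent — Phred+33 is a declared input property.
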