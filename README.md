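# ngsflow

Sample-sheet driven NGS workflow execution and analysis utilities for R.

`ngsflow` is for scientists who run multi-step sequencing analyses —
trimming, alignment, counting, differential expression — where the actual
work is done by external command-line tools and R analysis functions, and
the pain is the glue: keeping per-sample paths consistent across steps,
rerunning only what failed, capturing logs, and regenerating reports. The
whole workflow is driven by one tab-delimited **targets** sample sheet

```
# <CMP> CMPset1: A-B
FileName1   SampleName  Factor
data/A1.fastq   A1  A
data/B1.fastq   B1  B
```

plus one **param** command template per step

```
software        bowtie2
option  -p      4
reference       -x      <Reference>
infile          <FileName1>
outfile -S      <SampleName>.sam
```

`build_sysargs(targets, param, ...)` renders one fully substituted command
per sample with registered inputs and expected outputs; `run_serial()` /
`run_parallel()` execute them with per-job logs, an append-only JSON status
registry, and restart/skip semantics (a sample is skipped when all its
outputs exist non-empty; failed partial outputs are quarantined with a
`.failed` suffix); `chain_targets()` derives the next step's sample sheet
from the registered outputs automatically.

Around the engine sit the analysis operators a transcriptomics workflow
needs, all testable offline against a built-in synthetic-data generator:

* `fastq_quality_summary()` / `render_fastq_report()` — eight QC panels
  (per-cycle quality and base composition, mean-quality / length /
  duplication / GC histograms, k-mer diversity, N rate) in one streaming,
  bounded-memory pass; `preprocess_reads()` with composable trim/filter
  transforms.
* `read_sam()`, `align_stats()` — SAM parsing with CIGAR-derived reference
  blocks, primary-record alignment statistics.
* `featuretype_counts()` — strand-specific read counts for *every* feature
  type in a GFF3 annotation; `feature_coverage()` — metagene coverage at
  nucleotide resolution around start/stop codons with binned CDS profiles.
* `pred_orf()` — maximal open reading frames on both strands.
* `overlapper()` / `venn_counts_plot()` — n-way disjoint Venn intersects
  (2–20 sets; diagrams for 2–5); `filter_degs()` — up/down enumeration from
  logFC/FDR tables under user cutoffs.
* `build_report()` — deterministic Markdown report assembly;
  `gen_workenvir()` — a runnable self-contained demo workflow.
* `make_genome()`, `make_annotation()`, `simulate_reads()` — seeded
  synthetic genome/annotation/reads with exact ground truth.

## Worked example

```r
library(ngsflow)
d <- tempfile()
gen_workenvir("rnaseq-mini", d)   # synthetic genome, reads, targets, params
res <- run_workflow(d)            # or: Rscript inst/scripts/run-workflow.R <d>
res$launched
#> [1] 8
res$align_stats
#>   label total_reads aligned align_pct secondary
#> 1    A1         300     300       100         0
#> 2    A2         300     300       100         0
#> 3    B1         300     300       100         0
#> 4    B2         300     300       100         0
res$deg
#> DEG filtering at |logFC| >= 1, FDR <= 0.05
#>  comparison n_up n_down n_total
#>         A.B    3      2       5
#>         B.A    1      3       4
run_workflow(d)$launched          # restart: everything already complete
#> [1] 0
```

The demo runs two command steps (portable `cp` stand-ins for trimmer and
aligner) over four samples — eight processes — then computes alignment
statistics (100 % by construction, since the simulated SAM encodes the true
alignments), FASTQ QC, DEG filtering of a simulated result table under
|log2FC| ≥ 1 and FDR ≤ 0.05, Venn intersects of the DEG sets, and writes
`results/report.md`. Rerunning launches zero processes; deleting one
sample's output and rerunning launches exactly one.

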