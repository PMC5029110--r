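#' Render a data.frame as a Markdown table
#' @param df a data.frame.
#' @return Character vector of Markdown lines.
#' @export
markdown_table <- function(df) {
  df <- as.data.frame(df)
  cells <- vapply(df, function(col) format(col, trim = TRUE),
                  character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  c(paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    apply(cells, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
}

.md5_of <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(x, tf)
  unname(tools::md5sum(tf))
}

#' Assemble a Markdown analysis report from workflow results
#'
#' Substitutes \code{\{\{field\}\}} placeholders in a Markdown template with
#' the corresponding entries of \code{sections}: character entries verbatim,
#' data.frames as Markdown tables. Rendering is deterministic — timestamps
#' come only from the \code{report_date} parameter — so regenerating from
#' unchanged state is byte-identical. A sidecar \code{<out>.cache.json}
#' records an MD5 digest per section; unchanged sections are detected there
#' and the file is not rewritten when nothing changed.
#'
#' @param sections named list of character vectors and/or data.frames.
#' @param template path to the Markdown template, or a character vector of
#'   template lines.
#' @param out output Markdown path.
#' @param report_date date string embedded wherever the template uses
#'   \code{\{\{report_date\}\}}.
#' @return \code{out}, invisibly.
#' @export
build_report <- function(sections, template, out, report_date = "unset") {
  tpl <- if (length(template) == 1L && file.exists(template))
    readLines(template, warn = FALSE) else template
  sections$report_date <- report_date
  text <- paste(tpl, collapse = "\n")
  fields <- unique(regmatches(text,
                              gregexpr("\\{\\{[A-Za-z0-9_.]+\\}\\}", text))[[1]])
  for (f in fields) {
    nm <- gsub("[{}]", "", f)
    if (is.null(sections[[nm]]))
      stop("unresolvable template field: ", nm, call. = FALSE)
    val <- sections[[nm]]
    if (is.data.frame(val)) val <- markdown_table(val)
    text <- gsub(f, paste(as.character(val), collapse = "\n"), text,
                 fixed = TRUE)
  }
  digests <- vapply(sections, function(v)
    .md5_of(if (is.data.frame(v))
      utils::capture.output(print(v)) else as.character(v)), "")
  cache <- paste0(out, ".cache.json")
  if (file.exists(out) && file.exists(cache)) {
    prev <- tryCatch(jsonlite::fromJSON(cache), error = function(e) NULL)
    if (identical(unlist(prev), digests)) return(invisible(out))
  }
  writeLines(text, out)
  jsonlite::write_json(as.list(digests), cache, auto_unbox = TRUE)
  invisible(out)
}

#' Generate a runnable demo workflow environment
#'
#' Populates \code{dest} with everything needed to run a miniature RNA-Seq
#' style workflow offline: a synthetic genome and annotation, simulated
#' FASTQ/SAM sample data, a targets file with two comparison sets, param
#' files whose steps use only the portable \code{cp} command as stand-ins
#' for the trimmer and aligner, a simulated DEG table and a report
#' template. Run it end to end with \code{\link{run_workflow}} or the
#' \code{run-workflow.R} script under \code{inst/scripts}.
#'
#' @param template_name the only built-in template is \code{"rnaseq-mini"}.
#' @param dest destination directory; must not exist or be empty.
#' @return \code{dest}, invisibly.
#' @export
gen_workenvir <- function(template_name = "rnaseq-mini", dest) {
  if (!identical(template_name, "rnaseq-mini"))
    stop("unknown workflow template '", template_name,
         "'; available: rnaseq-mini", call. = FALSE)
  if (dir.exists(dest) && length(list.files(dest, all.files = TRUE,
                                            no.. = TRUE)))
    stop("destination exists and is not empty: ", dest, call. = FALSE)
  dir.create(file.path(dest, "data"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dest, "param"), showWarnings = FALSE)
  genome <- file.path(dest, "data", "genome.fa")
  gff <- file.path(dest, "data", "annotation.gff3")
  make_genome(1L, 20000L, 0.45, seed = 101L, path = genome)
  make_annotation(genome, n_genes = 8L, seed = 102L, path = gff)
  samples <- c("A1", "A2", "B1", "B2")
  factors <- c("A", "A", "B", "B")
  for (i in seq_along(samples))
    simulate_reads(genome, gff, n_reads = 300L, read_len = 50L,
                   error_rate = 0.002, seed = 200L + i,
                   out_prefix = file.path(dest, "data", samples[i]))
  tdf <- data.frame(FileName1 = file.path("data",
                                          paste0(samples, ".fastq")),
                    SampleName = samples, Factor = factors,
                    SamPath = file.path("data", paste0(samples, ".sam")),
                    stringsAsFactors = FALSE)
  write_targets(targets_table(tdf, comparisons = list(
    CMPset1 = list(c("A", "B")), CMPset2 = list(c("B", "A")))),
    file.path(dest, "targets.txt"))
  writeLines(c("software\t\tcp",
               "infile\t\t<FileName1>",
               "outfile\t\t<SampleName>_trimmed.fastq"),
             file.path(dest, "param", "trim.param"))
  writeLines(c("software\t\tcp",
               "infile\t\t<FileName1>",
               "outfile\t\t<SampleName>.sam"),
             file.path(dest, "param", "align.param"))
  deg <- simulate_deg_table(sprintf("g%02d", 1:8),
                            c("A-B", "B-A"), frac_de = 0.4, seed = 103L)
  write.table(deg, file.path(dest, "data", "deg_table.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(c("# Mini RNA-Seq workflow report",
               "",
               "Date: {{report_date}}",
               "",
               "## Step status", "", "### Read preprocessing", "",
               "{{trim_status}}", "", "### Alignment", "", "{{align_status}}",
               "", "## Alignment statistics", "", "{{align_stats}}",
               "", "## FASTQ quality", "",
               "See `results/fastq_report.pdf` ({{n_fastq}} files).",
               "", "## DEG summary", "", "{{deg_summary}}",
               "", "## Venn intersects of DEG sets", "", "{{venn_counts}}"),
             file.path(dest, "report_template.md"))
  invisible(dest)
}

#' Run the demo workflow end to end
#'
#' Executes the \code{rnaseq-mini} environment created by
#' \code{\link{gen_workenvir}}: preprocessing and alignment steps through
#' the runner (with restart/skip semantics), then alignment statistics,
#' FASTQ quality summaries, DEG filtering, Venn intersects and the Markdown
#' report under \code{<dir>/results}.
#'
#' @param dir the workflow directory.
#' @param force rerun command steps even when their outputs are complete.
#' @param workers worker processes for the command steps.
#' @return Invisibly, a list: \code{steps} (run-result data.frames per
#'   step), \code{launched} (number of processes launched),
#'   \code{align_stats}, \code{deg}, \code{venn}, \code{report} (path).
#' @export
run_workflow <- function(dir, force = FALSE, workers = 1L) {
  owd <- setwd(dir)
  on.exit(setwd(owd))
  tgt <- read_targets("targets.txt")
  results <- "results"
  dir.create(results, showWarnings = FALSE)
  run <- function(step) if (workers > 1L)
    run_parallel(step, workers = workers, force = force)
  else run_serial(step, force = force)

  trim <- build_sysargs(tgt, read_param("param/trim.param"), "trim",
                        outdir = results)
  trim_res <- run(trim)
  tgt2 <- chain_targets(trim)
  # the alignment stand-in copies the pre-computed SAM registered in the
  # targets extras; real deployments would point this param at an aligner
  tgt2$df$FileName1 <- tgt$df$SamPath
  align <- build_sysargs(tgt2, read_param("param/align.param"), "align",
                         outdir = results)
  align_res <- run(align)

  sams <- vapply(align$outfiles, `[[`, "", 1L)
  ok <- file.exists(sams) & file.info(sams)$size > 0
  astats <- align_stats(sams[ok], sample_names(align)[ok])
  sums <- lapply(stats::setNames(tgt$df$FileName1, tgt$df$SampleName),
                 fastq_quality_summary)
  render_fastq_report(sums, file.path(results, "fastq_report.pdf"))
  deg_tab <- read.delim("data/deg_table.tsv", stringsAsFactors = FALSE)
  deg <- filter_degs(deg_tab, lfc_min = 1, fdr_max = 0.05)
  venn <- overlapper(list("A-B_up" = deg$up[["A.B"]],
                          "A-B_down" = deg$down[["A.B"]],
                          "B-A_up" = deg$up[["B.A"]]))
  venn_counts_plot(venn, file.path(results, "venn.pdf"))
  report <- build_report(
    sections = list(
      trim_status = trim_res[, c("sample_name", "state")],
      align_status = align_res[, c("sample_name", "state")],
      align_stats = astats,
      n_fastq = as.character(length(sums)),
      deg_summary = deg$summary,
      venn_counts = data.frame(region = names(venn_counts(venn)),
                               count = as.integer(venn_counts(venn)))),
    template = "report_template.md",
    out = file.path(results, "report.md"),
    report_date = "workflow-run")
  invisible(list(steps = list(trim = trim_res, align = align_res),
                 launched = sum(trim_res$state != "skipped") +
                   sum(align_res$state != "skipped"),
                 align_stats = astats, deg = deg, venn = venn,
                 report = report))
}
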