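#' Build a workflow step control object
#'
#' Instantiates one workflow step over all samples of a targets table: every
#' placeholder in the param template is substituted per sample, yielding one
#' rendered command per sample together with its registered input files and
#' expected output files. Commands are kept as argument token vectors and are
#' executed without a shell, so sample names and paths can never inject shell
#' syntax.
#'
#' @param targets a \code{\link{targets_table}}.
#' @param param a \code{\link{param_spec}}.
#' @param step_name short step identifier (used for log/status directories).
#' @param reference path substituted for \code{<Reference>}; required iff the
#'   template uses that token.
#' @param outdir directory receiving the step's outputs; created on demand by
#'   the runner. Outfile templates carrying a relative directory are placed
#'   under it.
#' @return An object of class \code{sysargs} with fields \code{step_name},
#'   \code{software}, \code{targets}, \code{commands} (display strings),
#'   \code{args} (token vectors), \code{infiles}, \code{outfiles} and
#'   \code{outdir}.
#' @examples
#' tf <- targets_table(data.frame(FileName1 = c("s1.fq", "s2.fq"),
#'                                SampleName = c("S1", "S2"),
#'                                Factor = c("A", "B")))
#' ps <- param_spec("cp", data.frame(slot_type = c("infile", "outfile"),
#'                                   prefix = c("", ""),
#'                                   value = c("<FileName1>", "<SampleName>.fq")))
#' step <- build_sysargs(tf, ps, "copy", outdir = tempdir())
#' step$commands
#' @export
build_sysargs <- function(targets, param, step_name,
                          reference = NULL, outdir = ".") {
  stopifnot(inherits(targets, "targets"), inherits(param, "param_spec"))
  .check_label(step_name, "step name")
  df <- targets$df
  all_vals <- c(param$slots$value, param$outfile_template)
  uses <- function(tok) any(grepl(tok, all_vals, fixed = TRUE))
  if (uses("<Reference>") && is.null(reference))
    stop("param template uses <Reference> but no reference was provided",
         call. = FALSE)
  if (uses("<FileName2>")) {
    if (!("FileName2" %in% names(df)) || any(df$FileName2 == "")) {
      off <- if ("FileName2" %in% names(df))
        df$SampleName[df$FileName2 == ""][1] else df$SampleName[[1]]
      stop("param template uses <FileName2> but sample ", off,
           " has no second input file", call. = FALSE)
    }
  }
  n <- nrow(df)
  args <- vector("list", n); infiles <- vector("list", n)
  outfiles <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- df[i, , drop = FALSE]
    subst <- c("<FileName1>" = rec$FileName1,
               "<FileName2>" = if ("FileName2" %in% names(rec)) rec$FileName2 else NA,
               "<SampleName>" = rec$SampleName,
               "<Reference>" = if (is.null(reference)) NA else reference)
    render <- function(v, extra = character()) {
      s <- c(subst, extra)
      for (tok in names(s)) if (!is.na(s[[tok]]))
        v <- gsub(tok, s[[tok]], v, fixed = TRUE)
      if (grepl("<", v, fixed = TRUE))
        stop("unresolved placeholder in '", v, "' for sample ",
             rec$SampleName, call. = FALSE)
      v
    }
    outs <- vapply(param$outfile_template,
                   function(tpl) file.path(outdir, render(tpl)), "",
                   USE.NAMES = FALSE)
    of <- c("<OutFile>" = if (length(outs)) outs[[1]] else NA)
    toks <- param$software
    ins <- character()
    for (j in seq_len(nrow(param$slots))) {
      slot <- param$slots[j, ]
      if (nzchar(slot$prefix)) toks <- c(toks, slot$prefix)
      if (nzchar(slot$value)) {
        v <- if (slot$slot_type == "outfile")
          file.path(outdir, render(slot$value)) else render(slot$value, of)
        toks <- c(toks, v)
        if (slot$slot_type == "infile") ins <- c(ins, v)
      }
    }
    args[[i]] <- toks
    infiles[[i]] <- ins
    outfiles[[i]] <- outs
  }
  structure(list(step_name = step_name, software = param$software,
                 targets = targets,
                 commands = vapply(args, paste, "", collapse = " "),
                 args = args, infiles = infiles, outfiles = outfiles,
                 outdir = outdir),
            class = "sysargs")
}

#' @export
print.sysargs <- function(x, ...) {
  cat(sprintf("workflow step '%s' [%s]: %d sample(s), outdir %s\n",
              x$step_name, x$software, length(x$args), x$outdir))
  done <- completed(x)
  for (i in seq_along(x$args))
    cat(sprintf("  %s %s: %s\n", if (done[i]) "[done]" else "[    ]",
                sample_names(x)[i], x$commands[i]))
  invisible(x)
}

#' @export
sample_names.sysargs <- function(x) x$targets$df$SampleName

#' @export
length.sysargs <- function(x) length(x$args)

#' Per-sample completion status of a step
#'
#' A sample counts as completed when every expected output file exists with
#' size greater than zero; empty files (e.g. left by an interrupted tool) are
#' not completion. The runner uses this to skip finished samples on restart.
#'
#' @param step a \code{sysargs} object.
#' @return Logical vector, one flag per sample in targets row order.
#' @export
completed <- function(step) {
  stopifnot(inherits(step, "sysargs"))
  vapply(step$outfiles, function(fs) {
    length(fs) > 0L && all(file.exists(fs)) &&
      all(file.info(fs)$size > 0)
  }, NA)
}

#' Derive the next step's targets table from a step's outputs
#'
#' The returned table has each sample's \code{FileName1} replaced by the
#' step's (first) expected output file, preserving sample names, factors,
#' extra columns and comparison sets — it is the input to the next workflow
#' step. Any \code{FileName2} column is dropped, since step outputs are
#' single files.
#'
#' @param step a \code{sysargs} object.
#' @return A \code{targets} object.
#' @export
chain_targets <- function(step) {
  stopifnot(inherits(step, "sysargs"))
  df <- step$targets$df
  df$FileName1 <- vapply(step$outfiles, `[[`, "", 1L)
  df$FileName2 <- NULL
  targets_table(df, step$targets$comparisons)
}
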