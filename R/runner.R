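#' Execute workflow steps with restart/skip semantics
#'
#' \code{run_serial} launches the rendered command of every sample whose
#' outputs are not yet complete, in targets row order; \code{run_parallel}
#' does the same through a local process pool. Each job's stdout/stderr is
#' captured to \code{<logdir>/<step>/<sample>.log} and an append-only
#' line-delimited JSON registry (\code{status.jsonl}) is updated after every
#' sample, so an interrupted run can be diagnosed and resumed: on restart,
#' already-completed samples are skipped unless \code{force = TRUE}. A failed
#' job's partial outputs are renamed with a \code{.failed} suffix so they are
#' never mistaken for completed results. Failures do not abort the run; the
#' remaining samples still execute, and no automatic retry is attempted.
#'
#' @param step a \code{\link{build_sysargs}} object.
#' @param force rerun samples even if their outputs are complete.
#' @param logdir log/status root; defaults to \code{<outdir>/.logs}.
#' @param workers number of concurrent worker processes.
#' @return A data.frame of run results with one row per sample, in targets
#'   row order: \code{sample_name}, \code{state} (\code{done}, \code{skipped}
#'   or \code{failed}), \code{exit_code} (NA when skipped), \code{log_path},
#'   \code{started}, \code{finished} (fractional epoch seconds).
#' @examples
#' tf <- targets_table(data.frame(FileName1 = "in.txt", SampleName = "S1"))
#' dir <- tempfile(); dir.create(dir)
#' writeLines("x", file.path(dir, "in.txt"))
#' ps <- param_spec("cp", data.frame(
#'   slot_type = c("infile", "outfile"), prefix = "",
#'   value = c("<FileName1>", "<SampleName>.txt")))
#' tf$df$FileName1 <- file.path(dir, "in.txt")
#' step <- build_sysargs(tf, ps, "copy", outdir = file.path(dir, "results"))
#' run_serial(step)$state
#' run_serial(step)$state  # skipped on rerun
#' @export
run_serial <- function(step, force = FALSE, logdir = NULL) {
  .run_step(step, force = force, logdir = logdir, workers = 1L)
}

#' @rdname run_serial
#' @export
run_parallel <- function(step, workers = 2L, force = FALSE, logdir = NULL) {
  stopifnot(workers >= 1L)
  .run_step(step, force = force, logdir = logdir, workers = as.integer(workers))
}

.step_logdir <- function(step, logdir) {
  if (is.null(logdir)) logdir <- file.path(step$outdir, ".logs")
  file.path(logdir, step$step_name)
}

.append_status <- function(status_file, rec) {
  line <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, na = "null")
  # single short line through an O_APPEND handle: atomic on POSIX
  con <- file(status_file, "a")
  on.exit(close(con))
  writeLines(line, con)
}

.run_one <- function(step, i, sldir, status_file) {
  sn <- sample_names(step)[i]
  log <- file.path(sldir, paste0(sn, ".log"))
  started <- as.numeric(Sys.time())
  toks <- step$args[[i]]
  code <- tryCatch(
    suppressWarnings(system2(toks[[1]], shQuote(toks[-1]),
                             stdout = log, stderr = log)),
    error = function(e) { cat(conditionMessage(e), "\n", file = log); 127L })
  ok <- code == 0L && all(file.exists(step$outfiles[[i]])) &&
    all(file.info(step$outfiles[[i]])$size > 0)
  if (!ok) {
    for (f in step$outfiles[[i]])
      if (file.exists(f)) file.rename(f, paste0(f, ".failed"))
  }
  rec <- list(sample_name = sn, state = if (ok) "done" else "failed",
              exit_code = as.integer(code), log_path = log,
              started = started, finished = as.numeric(Sys.time()))
  .append_status(status_file, rec)
  rec
}

.run_step <- function(step, force, logdir, workers) {
  stopifnot(inherits(step, "sysargs"))
  sldir <- .step_logdir(step, logdir)
  dir.create(sldir, recursive = TRUE, showWarnings = FALSE)
  dir.create(step$outdir, recursive = TRUE, showWarnings = FALSE)
  exe <- step$software
  if (Sys.which(exe) == "" && !file.exists(exe))
    stop("software not found on PATH: ", exe, call. = FALSE)
  status_file <- file.path(sldir, "status.jsonl")
  skip <- completed(step) & !force
  todo <- which(!skip)
  now <- as.numeric(Sys.time())
  res <- vector("list", length(step))
  for (i in which(skip)) {
    res[[i]] <- list(sample_name = sample_names(step)[i], state = "skipped",
                     exit_code = NA_integer_,
                     log_path = file.path(sldir, paste0(sample_names(step)[i], ".log")),
                     started = now, finished = now)
    .append_status(status_file, res[[i]])
  }
  if (length(todo)) {
    if (workers == 1L) {
      for (i in todo) res[[i]] <- .run_one(step, i, sldir, status_file)
    } else {
      out <- parallel::mclapply(todo, function(i)
        .run_one(step, i, sldir, status_file),
        mc.cores = workers, mc.preschedule = FALSE)
      for (k in seq_along(todo)) {
        i <- todo[[k]]
        if (inherits(out[[k]], "try-error") || is.null(out[[k]])) {
          # worker crashed before reporting: mark this sample failed
          rec <- list(sample_name = sample_names(step)[i], state = "failed",
                      exit_code = NA_integer_,
                      log_path = file.path(sldir, paste0(sample_names(step)[i], ".log")),
                      started = now, finished = as.numeric(Sys.time()))
          .append_status(status_file, rec)
          res[[i]] <- rec
        } else res[[i]] <- out[[k]]
      }
    }
  }
  .results_df(res)
}

.results_df <- function(res) {
  data.frame(sample_name = vapply(res, `[[`, "", "sample_name"),
             state = vapply(res, `[[`, "", "state"),
             exit_code = vapply(res, function(r)
               as.integer(r$exit_code %||% NA_integer_), 1L),
             log_path = vapply(res, `[[`, "", "log_path"),
             started = vapply(res, `[[`, 1, "started"),
             finished = vapply(res, `[[`, 1, "finished"),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Query the status registry of a step
#'
#' Reads the append-only \code{status.jsonl} registry written by the runner
#' and returns the last recorded result per sample. Corrupted registry lines
#' are skipped with a warning; an absent registry yields an empty result.
#'
#' @param logdir the log root passed to the runner (the directory containing
#'   one subdirectory per step).
#' @param step_name the step identifier.
#' @return A data.frame in the \code{\link{run_serial}} result layout, with
#'   zero rows if nothing has been recorded.
#' @export
status <- function(logdir, step_name) {
  status_file <- file.path(logdir, step_name, "status.jsonl")
  empty <- .results_df(list())
  if (!file.exists(status_file)) return(empty)
  lines <- readLines(status_file, warn = FALSE)
  recs <- list()
  for (k in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[k]]), error = function(e) NULL)
    if (is.null(rec) || is.null(rec$sample_name)) {
      warning("skipping corrupted registry line ", k, " in ", status_file,
              call. = FALSE)
      next
    }
    recs[[rec$sample_name]] <- rec  # later lines overwrite: last result wins
  }
  if (!length(recs)) return(empty)
  .results_df(unname(recs))
}
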