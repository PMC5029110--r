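#' @importFrom utils write.table read.delim head tail combn capture.output
NULL

# Characters allowed in sample names and factor labels: they end up inside
# file names, rendered commands and "A-B" comparison syntax, so whitespace
# and shell metacharacters are rejected at parse time.
.name_rx <- "^[A-Za-z0-9_.]+$"

.check_label <- function(x, what) {
  bad <- x[!grepl(.name_rx, x)]
  if (length(bad))
    stop(sprintf("invalid %s '%s': only [A-Za-z0-9_.] characters are allowed",
                 what, bad[[1]]), call. = FALSE)
  invisible(x)
}

#' Targets table: the workflow sample sheet
#'
#' A targets table maps each sample to its input file(s), a unique sample
#' name, a condition (factor) label and arbitrary extra annotation columns.
#' Comment header lines of the form \code{# <CMP> SETNAME: A-B, A-C} declare
#' named comparison (contrast) sets as hyphen-separated factor pairs. The
#' targets file is the sole user-provided input of a workflow; downstream
#' tables are derived automatically from step outputs (see
#' \code{\link{chain_targets}}).
#'
#' @param df data.frame with at least \code{FileName1} and \code{SampleName}
#'   columns; \code{FileName2} (paired-end mate) and \code{Factor} are
#'   recognised, all other columns are carried as extras.
#' @param comparisons named list; each element is a list of length-2 character
#'   vectors \code{c(factorA, factorB)}.
#' @param source_path path the table was read from, or \code{NA}.
#' @return An object of class \code{targets}.
#' @export
targets_table <- function(df, comparisons = list(), source_path = NA_character_) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (j in seq_along(df)) df[[j]] <- as.character(df[[j]])
  need <- setdiff(c("FileName1", "SampleName"), names(df))
  if (length(need))
    stop("missing mandatory column: ", paste(need, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L)
    stop("targets table has no samples", call. = FALSE)
  dup <- df$SampleName[duplicated(df$SampleName)]
  if (length(dup))
    stop("duplicate sample name ", dup[[1]], call. = FALSE)
  .check_label(df$SampleName, "sample name")
  if ("Factor" %in% names(df)) .check_label(df$Factor, "factor")
  if (length(comparisons)) {
    if (!("Factor" %in% names(df)))
      stop("comparisons declared but table has no Factor column", call. = FALSE)
    if (is.null(names(comparisons)) || any(names(comparisons) == ""))
      stop("comparison sets must be named", call. = FALSE)
    fac <- unique(df$Factor)
    for (nm in names(comparisons)) {
      prs <- comparisons[[nm]]
      for (p in prs) {
        if (length(p) != 2L)
          stop("comparison pairs must have exactly two factors (set ", nm, ")",
               call. = FALSE)
        miss <- setdiff(p, fac)
        if (length(miss))
          stop(sprintf("comparison set %s references unknown factor '%s'",
                       nm, miss[[1]]), call. = FALSE)
      }
    }
  }
  # canonical column order: FileName1 [FileName2] SampleName [Factor] extras
  lead <- intersect(c("FileName1", "FileName2", "SampleName", "Factor"), names(df))
  df <- df[, c(lead, setdiff(names(df), lead)), drop = FALSE]
  rownames(df) <- NULL
  structure(list(df = df, comparisons = comparisons, source_path = source_path),
            class = "targets")
}

#' @export
print.targets <- function(x, ...) {
  cat(sprintf("targets table: %d samples, %d comparison set(s)\n",
              nrow(x$df), length(x$comparisons)))
  print(x$df, ...)
  for (nm in names(x$comparisons)) {
    prs <- vapply(x$comparisons[[nm]], paste, "", collapse = "-")
    cat(sprintf("  <CMP> %s: %s\n", nm, paste(prs, collapse = ", ")))
  }
  invisible(x)
}

#' @export
length.targets <- function(x) nrow(x$df)

#' Sample names of a targets table or workflow step
#' @param x a \code{targets} or \code{sysargs} object.
#' @return Character vector of sample names, in row order.
#' @export
sample_names <- function(x) UseMethod("sample_names")

#' @export
sample_names.targets <- function(x) x$df$SampleName

.parse_cmp_line <- function(line, lineno) {
  body <- sub("^#[ \t]*<CMP>[ \t]*", "", line)
  m <- regmatches(body, regexec("^([A-Za-z0-9_.]+)[ \t]*:[ \t]*(.+)$", body))[[1]]
  if (length(m) != 3L)
    stop(sprintf("malformed <CMP> line %d: '%s'", lineno, line), call. = FALSE)
  pairs <- trimws(strsplit(m[[3]], ",")[[1]])
  prs <- lapply(pairs, function(p) {
    ab <- strsplit(p, "-", fixed = TRUE)[[1]]
    if (length(ab) != 2L || any(ab == ""))
      stop(sprintf("malformed comparison pair '%s' on <CMP> line %d", p, lineno),
           call. = FALSE)
    ab
  })
  list(name = m[[2]], pairs = prs)
}

#' Read a targets file
#'
#' Parses the tab-delimited sample sheet. Lines starting with \code{#} are
#' comments; among them, \code{# <CMP> SETNAME: A-B, A-C} lines define named
#' comparison sets. The first non-comment line is the header and must name at
#' least \code{FileName1} and \code{SampleName}.
#'
#' @param path path to the targets file.
#' @return A \code{\link{targets_table}} object.
#' @examples
#' tf <- tempfile(fileext = ".txt")
#' writeLines(c("# <CMP> CMPset1: A-B",
#'              "FileName1\tSampleName\tFactor",
#'              "s1.fq\tS1\tA", "s2.fq\tS2\tB"), tf)
#' read_targets(tf)
#' @export
read_targets <- function(path) {
  if (!file.exists(path)) stop("targets file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  is_comment <- startsWith(lines, "#")
  comparisons <- list()
  for (i in which(is_comment)) {
    if (grepl("^#[ \t]*<CMP>", lines[[i]])) {
      cmp <- .parse_cmp_line(lines[[i]], i)
      comparisons[[cmp$name]] <- cmp$pairs
    }
  }
  body <- lines[!is_comment]
  if (length(body) < 2L)
    stop("targets file needs a header line and at least one sample row",
         call. = FALSE)
  cells <- strsplit(body, "\t", fixed = TRUE)
  header <- trimws(cells[[1]])
  rows <- lapply(cells[-1], function(x) {
    length(x) <- length(header)
    x[is.na(x)] <- ""
    trimws(x)
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- header
  # a blank FileName2 column means single-end throughout
  if ("FileName2" %in% names(df) && all(df$FileName2 == ""))
    df$FileName2 <- NULL
  targets_table(df, comparisons, source_path = path)
}

#' Write a targets file
#'
#' Emits the table so that \code{read_targets(write_targets(x))} reproduces
#' the same samples and comparison sets. Comparison sets are written first,
#' one \code{# <CMP>} header line per set.
#'
#' @param x a \code{targets} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_targets <- function(x, path) {
  stopifnot(inherits(x, "targets"))
  if (nrow(x$df) == 0L) stop("targets table has no samples", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(x$comparisons)) {
    prs <- vapply(x$comparisons[[nm]], paste, "", collapse = "-")
    writeLines(sprintf("# <CMP> %s: %s", nm, paste(prs, collapse = ", ")), con)
  }
  write.table(x$df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
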