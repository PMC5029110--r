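#' Param files: declarative command-line templates
#'
#' A param file describes one external command as a tab-delimited table with
#' three columns: \code{slot_type}, \code{prefix}, \code{value}. Exactly one
#' \code{software} row names the executable; \code{option}, \code{reference},
#' \code{infile} and \code{outfile} rows are rendered in file order into the
#' argument list. Values may contain the placeholder tokens
#' \code{<FileName1>}, \code{<FileName2>}, \code{<SampleName>},
#' \code{<OutFile>} and \code{<Reference>}, substituted per sample when a
#' workflow step is built (see \code{\link{build_sysargs}}). The placeholder
#' vocabulary is fixed: data files cannot inject arbitrary shell text.
#'
#' @name param
NULL

.placeholders <- c("<FileName1>", "<FileName2>", "<SampleName>",
                   "<OutFile>", "<Reference>")
.slot_types <- c("software", "option", "infile", "outfile", "reference")

.check_placeholders <- function(value, lineno = NA) {
  toks <- regmatches(value, gregexpr("<[^<>]*>", value))[[1]]
  bad <- setdiff(toks, .placeholders)
  if (length(bad))
    stop(sprintf("unknown placeholder %s%s", bad[[1]],
                 if (is.na(lineno)) "" else sprintf(" on line %d", lineno)),
         call. = FALSE)
  toks
}

#' Construct a param spec in code
#'
#' @param software executable name.
#' @param slots data.frame with columns \code{slot_type}, \code{prefix},
#'   \code{value} (excluding the software row).
#' @return An object of class \code{param_spec} with fields \code{software},
#'   \code{slots}, \code{outfile_template} (character, possibly several
#'   templates) and \code{outdir} (relative directory taken from the first
#'   outfile template, \code{"."} if none).
#' @export
param_spec <- function(software, slots) {
  stopifnot(is.character(software), length(software) == 1L, nzchar(software))
  slots <- as.data.frame(slots, stringsAsFactors = FALSE)
  stopifnot(all(c("slot_type", "prefix", "value") %in% names(slots)))
  bad <- setdiff(slots$slot_type, setdiff(.slot_types, "software"))
  if (length(bad)) stop("unknown slot_type: ", bad[[1]], call. = FALSE)
  for (v in slots$value) .check_placeholders(v)
  out_rows <- slots$value[slots$slot_type == "outfile"]
  outdir <- if (length(out_rows)) {
    d <- dirname(out_rows[[1]])
    if (d == "") "." else d
  } else "."
  structure(list(software = software, slots = slots,
                 outfile_template = out_rows, outdir = outdir),
            class = "param_spec")
}

#' @export
print.param_spec <- function(x, ...) {
  cat(sprintf("param spec: software '%s', %d argument slot(s)\n",
              x$software, nrow(x$slots)))
  print(x$slots, ...)
  invisible(x)
}

#' Read a param file
#'
#' @param path path to the tab-delimited param file. Lines starting with
#'   \code{#} and an optional \code{slot_type} header line are skipped.
#' @return A \code{\link{param_spec}}.
#' @examples
#' pf <- tempfile(fileext = ".param")
#' writeLines(c("software\t\tbowtie2",
#'              "option\t-p\t4",
#'              "reference\t-x\t<Reference>",
#'              "infile\t\t<FileName1>",
#'              "outfile\t-S\t<SampleName>.sam"), pf)
#' read_param(pf)
#' @export
read_param <- function(path) {
  if (!file.exists(path)) stop("param file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  rows <- list(); lineno <- integer()
  for (i in which(keep)) {
    x <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    length(x) <- 3L
    x[is.na(x)] <- ""
    x <- trimws(x)
    if (i == which(keep)[1] && identical(x[[1]], "slot_type")) next  # header
    rows[[length(rows) + 1L]] <- x
    lineno[[length(lineno) + 1L]] <- i
  }
  if (!length(rows)) stop("param file is empty: ", path, call. = FALSE)
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("slot_type", "prefix", "value")
  bad <- which(!(df$slot_type %in% .slot_types))
  if (length(bad))
    stop(sprintf("unknown slot_type '%s' on line %d",
                 df$slot_type[bad[[1]]], lineno[bad[[1]]]), call. = FALSE)
  for (i in seq_len(nrow(df))) .check_placeholders(df$value[[i]], lineno[[i]])
  sw <- which(df$slot_type == "software")
  if (length(sw) != 1L)
    stop(sprintf("param file must contain exactly one software row (found %d)",
                 length(sw)), call. = FALSE)
  param_spec(df$value[[sw]], df[-sw, , drop = FALSE])
}

#' Write a param file
#' @param x a \code{param_spec}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_param <- function(x, path) {
  stopifnot(inherits(x, "param_spec"))
  df <- rbind(data.frame(slot_type = "software", prefix = "",
                         value = x$software, stringsAsFactors = FALSE),
              x$slots[, c("slot_type", "prefix", "value")])
  con <- file(path, "w")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
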