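#' Predict open reading frames in DNA sequences
#'
#' Scans the three reading frames of one or both strands for maximal ORFs:
#' an ORF runs from an ATG to the first in-frame stop codon (TAA, TAG or
#' TGA), stop included. After an ORF terminates, scanning resumes beyond its
#' stop, so internal ATGs sharing the same stop are suppressed — only the
#' 5'-most (longest) variant is reported. Codons containing N neither start
#' nor stop an ORF. Minus-strand ORFs are found on the reverse complement
#' and reported in forward-strand coordinates. Results are ranked by
#' descending length, ties broken by ascending forward start, then plus
#' before minus strand.
#'
#' @param seq a DNA string, named character vector or
#'   \code{\link[Biostrings]{DNAStringSet}}; alphabet A, C, G, T, N.
#' @param n \code{"all"}, \code{"longest"}, or a positive integer: how many
#'   top-ranked ORFs to return per sequence.
#' @param strand \code{"+"}, \code{"-"} or \code{"both"}.
#' @param min_length minimum ORF length in nucleotides (including the stop
#'   codon).
#' @param require_stop if \code{FALSE}, an ATG run reaching the end of the
#'   sequence without a stop is reported as an open-ended ORF (trimmed to
#'   full codons).
#' @param longest_disjoint greedily keep only top-ranked ORFs that do not
#'   overlap an already kept one (forward coordinates, either strand).
#' @return data.frame \code{seq_id}, \code{start}, \code{end} (1-based
#'   inclusive, forward strand), \code{strand}, \code{frame} (1-3 in
#'   scanning orientation), \code{length_nt}, \code{rank}.
#' @examples
#' pred_orf("ATGAAATAG", min_length = 9)
#' @export
pred_orf <- function(seq, n = "all", strand = c("both", "+", "-"),
                     min_length = 30L, require_stop = TRUE,
                     longest_disjoint = FALSE) {
  strand <- match.arg(strand)
  if (inherits(seq, "DNAStringSet")) seq <- as.character(seq)
  if (is.null(names(seq)))
    names(seq) <- if (length(seq) == 1L) "seq1" else paste0("seq", seq_along(seq))
  out <- lapply(names(seq), function(id)
    .pred_orf_one(id, seq[[id]], n, strand, min_length, require_stop,
                  longest_disjoint))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.orf_cols <- function() data.frame(
  seq_id = character(), start = integer(), end = integer(),
  strand = character(), frame = integer(), length_nt = integer(),
  rank = integer(), stringsAsFactors = FALSE)

.pred_orf_one <- function(id, s, n, strand, min_length, require_stop,
                          longest_disjoint) {
  s <- toupper(s)
  if (nchar(s) == 0L) return(.orf_cols())
  if (grepl("[^ACGTN]", s))
    stop("non-DNA character in sequence ", id, call. = FALSE)
  L <- nchar(s)
  scan <- function(x) {
    # returns ORFs as (start, end, frame) in the scanned orientation
    hits <- list()
    for (fr in 1:3) {
      ncod <- (nchar(x) - fr + 1L) %/% 3L
      if (ncod < 1L) next
      starts <- fr + 3L * (seq_len(ncod) - 1L)
      codons <- substring(x, starts, starts + 2L)
      is_atg <- codons == "ATG"
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      j <- 1L
      while (j <= ncod) {
        if (is_atg[j]) {
          stop_j <- j + which(is_stop[j:ncod])[1] - 1L
          if (!is.na(stop_j)) {
            hits[[length(hits) + 1L]] <-
              c(starts[j], starts[stop_j] + 2L, fr)
            j <- stop_j + 1L
          } else {
            if (!require_stop)
              hits[[length(hits) + 1L]] <-
                c(starts[j], starts[ncod] + 2L, fr)
            break
          }
        } else j <- j + 1L
      }
    }
    hits
  }
  rows <- list()
  if (strand %in% c("+", "both")) {
    for (h in scan(s))
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = id, start = h[1], end = h[2], strand = "+", frame = h[3],
        length_nt = h[2] - h[1] + 1L, stringsAsFactors = FALSE)
  }
  if (strand %in% c("-", "both")) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    for (h in scan(rc))
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = id, start = L - h[2] + 1L, end = L - h[1] + 1L,
        strand = "-", frame = h[3], length_nt = h[2] - h[1] + 1L,
        stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(.orf_cols())
  res <- do.call(rbind, rows)
  res <- res[res$length_nt >= min_length, , drop = FALSE]
  if (!nrow(res)) return(.orf_cols())
  res <- res[order(-res$length_nt, res$start, res$strand), , drop = FALSE]
  if (longest_disjoint) {
    keep <- logical(nrow(res))
    for (i in seq_len(nrow(res))) {
      ov <- keep & (res$start <= res$end[i]) & (res$end >= res$start[i])
      keep[i] <- !any(ov)
    }
    res <- res[keep, , drop = FALSE]
  }
  res$rank <- seq_len(nrow(res))
  if (identical(n, "longest")) n <- 1L
  if (!identical(n, "all")) res <- head(res, as.integer(n))
  rownames(res) <- NULL
  res
}
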