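#' Read a GFF3 annotation into a GRanges
#'
#' Parses the nine-column GFF3 format (1-based inclusive coordinates,
#' \code{##} directive lines skipped) into a
#' \code{\link[GenomicRanges]{GRanges}} with metadata columns \code{source},
#' \code{type}, \code{score}, \code{phase}, \code{ID}, \code{Parent} and the
#' verbatim \code{attributes} string, so the record round-trips through
#' \code{\link{write_gff3}} unchanged.
#'
#' @param path GFF3 path.
#' @return A \code{GRanges}.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  if (!length(keep))
    return(GenomicRanges::GRanges(
      seqnames = character(), ranges = IRanges::IRanges(), strand = character(),
      source = character(), type = character(), score = character(),
      phase = character(), ID = character(), Parent = character(),
      attributes = character()))
  cells <- strsplit(lines[keep], "\t", fixed = TRUE)
  nc <- lengths(cells)
  if (any(nc != 9L))
    stop(sprintf("GFF3 line %d does not have 9 columns",
                 keep[which(nc != 9L)[1]]), call. = FALSE)
  m <- do.call(rbind, cells)
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(start) | is.na(end) |
                 m[, 4] != as.character(start) | m[, 5] != as.character(end))
  if (length(bad))
    stop(sprintf("non-integer coordinates on GFF3 line %d", keep[bad[[1]]]),
         call. = FALSE)
  bad <- which(start > end)
  if (length(bad))
    stop(sprintf("start > end on GFF3 line %d", keep[bad[[1]]]), call. = FALSE)
  strand <- m[, 7]
  strand[!(strand %in% c("+", "-"))] <- "*"  # GFF '.' -> GRanges '*'
  attr_field <- function(attrs, field) {
    mm <- regmatches(attrs, regexec(paste0("(^|;)", field, "=([^;]*)"), attrs))
    vapply(mm, function(x) if (length(x) >= 3L) x[[3]] else NA_character_, "")
  }
  GenomicRanges::GRanges(
    seqnames = m[, 1],
    ranges = IRanges::IRanges(start = start, end = end),
    strand = strand,
    source = m[, 2], type = m[, 3], score = m[, 6], phase = m[, 8],
    ID = attr_field(m[, 9], "ID"), Parent = attr_field(m[, 9], "Parent"),
    attributes = m[, 9])
}

#' Write a GRanges annotation as GFF3
#'
#' The inverse of \code{\link{read_gff3}}: the verbatim \code{attributes}
#' column is emitted when present, otherwise one is assembled from \code{ID}
#' and \code{Parent}.
#'
#' @param gr a \code{GRanges} with at least a \code{type} metadata column.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gff3 <- function(gr, path) {
  mc <- S4Vectors::mcols(gr)
  col <- function(nm, default) {
    v <- if (nm %in% names(mc)) as.character(mc[[nm]]) else
      rep(default, length(gr))
    v[is.na(v)] <- default
    v
  }
  attrs <- if ("attributes" %in% names(mc)) as.character(mc$attributes) else {
    id <- col("ID", NA); pa <- col("Parent", NA)
    vapply(seq_along(gr), function(i) {
      parts <- c(if (!is.na(id[i]) && id[i] != ".") paste0("ID=", id[i]),
                 if (!is.na(pa[i]) && pa[i] != ".") paste0("Parent=", pa[i]))
      if (length(parts)) paste(parts, collapse = ";") else "."
    }, "")
  }
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  lines <- paste(as.character(GenomicRanges::seqnames(gr)),
                 col("source", "."), col("type", "."),
                 BiocGenerics::start(gr), BiocGenerics::end(gr),
                 col("score", "."), strand, col("phase", "."), attrs,
                 sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read SAM alignments
#'
#' Parses the text SAM format and derives each record's reference blocks
#' from its CIGAR string: M, =, X and D operations consume the reference
#' contiguously, N splits a block (spliced alignment), and I, S, H consume
#' none. Flag bit 0x4 marks a record unmapped (no blocks), 0x10 the minus
#' strand, 0x100/0x800 secondary/supplementary alignments.
#'
#' @param path SAM path.
#' @return A list of class \code{sam_alignments}: vectors \code{qname},
#'   \code{flag}, \code{rname}, \code{pos}, \code{mapq}, \code{cigar},
#'   \code{strand}, logicals \code{unmapped}, \code{secondary}, and
#'   \code{blocks}, an \code{IRangesList} (one element per record, empty for
#'   unmapped records).
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("SAM file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  body <- lines[nzchar(lines) & !startsWith(lines, "@")]
  if (!length(body)) {
    out <- list(qname = character(), flag = integer(), rname = character(),
                pos = integer(), mapq = integer(), cigar = character(),
                strand = character(), unmapped = logical(),
                secondary = logical(),
                blocks = IRanges::IRangesList())
    class(out) <- "sam_alignments"
    return(out)
  }
  cells <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(cells) < 11L))
    stop("SAM record with fewer than 11 fields", call. = FALSE)
  f <- function(j) vapply(cells, `[[`, "", j)
  flag <- as.integer(f(2))
  cigar <- f(6)
  unmapped <- bitwAnd(flag, 4L) != 0L
  bad <- grepl("[^0-9MIDNSHP=X*]", cigar)
  if (any(bad))
    stop("unknown CIGAR operation in '", cigar[bad][1], "'", call. = FALSE)
  if (any(grepl("P", cigar, fixed = TRUE)))
    stop("unknown CIGAR operation in '",
         cigar[grepl("P", cigar, fixed = TRUE)][1], "'", call. = FALSE)
  pos <- as.integer(f(4))
  blocks <- IRanges::IRangesList(lapply(seq_along(cells), function(i)
    IRanges::IRanges()))
  mapped <- which(!unmapped & cigar != "*")
  if (length(mapped)) {
    bl <- GenomicAlignments::extractAlignmentRangesOnReference(
      cigar[mapped], pos = pos[mapped], drop.D.ranges = FALSE)
    # D consumes the reference within a block; merge D-adjacent ranges and
    # drop zero-width artefacts of N-only gaps
    bl <- IRanges::reduce(bl, min.gapwidth = 0L)
    bl <- bl[IRanges::width(bl) > 0L]
    blocks[mapped] <- bl
  }
  out <- list(qname = f(1), flag = flag, rname = f(3), pos = pos,
              mapq = as.integer(f(5)), cigar = cigar,
              strand = ifelse(bitwAnd(flag, 16L) != 0L, "-", "+"),
              unmapped = unmapped,
              secondary = bitwAnd(flag, 256L) != 0L | bitwAnd(flag, 2048L) != 0L,
              blocks = blocks)
  class(out) <- "sam_alignments"
  out
}

#' @export
print.sam_alignments <- function(x, ...) {
  cat(sprintf("SAM alignments: %d records (%d mapped, %d secondary/suppl.)\n",
              length(x$flag), sum(!x$unmapped), sum(x$secondary)))
  invisible(x)
}

# GRanges of reference blocks of primary aligned records, with read index
# and read strand carried along.
.primary_block_granges <- function(aln) {
  keep <- which(!aln$unmapped & !aln$secondary)
  bl <- aln$blocks[keep]
  n <- S4Vectors::elementNROWS(bl)
  GenomicRanges::GRanges(
    seqnames = rep(aln$rname[keep], n),
    ranges = unlist(bl, use.names = FALSE),
    strand = "*",
    read = rep(keep, n),
    read_strand = rep(aln$strand[keep], n))
}

#' Alignment statistics across SAM files
#'
#' Counts primary records only (secondary/supplementary flags 0x100/0x800
#' are excluded from the total and reported separately); the alignment
#' percentage is rounded to one decimal.
#'
#' @param paths character vector of SAM paths.
#' @param labels one label per file (defaults to file base names).
#' @return data.frame with columns \code{label}, \code{total_reads},
#'   \code{aligned}, \code{align_pct}, \code{secondary}.
#' @export
align_stats <- function(paths, labels = basename(paths)) {
  stopifnot(length(paths) == length(labels))
  rows <- lapply(seq_along(paths), function(i) {
    aln <- read_sam(paths[[i]])
    prim <- !aln$secondary
    total <- sum(prim)
    aligned <- sum(prim & !aln$unmapped)
    if (total == 0L) {
      warning("no alignment records in ", paths[[i]], call. = FALSE)
      return(data.frame(label = labels[[i]], total_reads = 0L, aligned = 0L,
                        align_pct = 0, secondary = sum(aln$secondary)))
    }
    data.frame(label = labels[[i]], total_reads = total, aligned = aligned,
               align_pct = round(100 * aligned / total, 1),
               secondary = sum(aln$secondary))
  })
  do.call(rbind, rows)
}

#' Strand-specific read counts per annotation feature type
#'
#' Counts, for every feature type present in the annotation, the reads whose
#' reference blocks overlap (by at least one base) any record of that type.
#' A read is counted once per feature type regardless of how many features
#' of the type it touches; counts are split by read strand. Only primary
#' aligned records are counted. Under \code{strand_mode = "sense"} only
#' features on the read's strand are considered, under \code{"antisense"}
#' only features on the opposite strand; unstranded features (\code{*})
#' match any read in both modes.
#'
#' @param sam SAM path or a \code{\link{read_sam}} result.
#' @param annotation a \code{GRanges} with a \code{type} metadata column.
#' @param strand_mode one of \code{"both"}, \code{"sense"},
#'   \code{"antisense"}.
#' @return data.frame \code{feature_type}, \code{strand} (read strand),
#'   \code{count}, with zero rows included for every annotation type.
#' @export
featuretype_counts <- function(sam, annotation,
                               strand_mode = c("both", "sense", "antisense")) {
  strand_mode <- match.arg(strand_mode)
  aln <- if (inherits(sam, "sam_alignments")) sam else read_sam(sam)
  types <- sort(unique(as.character(S4Vectors::mcols(annotation)$type)))
  bg <- .primary_block_granges(aln)
  out <- expand.grid(feature_type = types, strand = c("+", "-"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$feature_type, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out$count <- 0L
  for (t in types) {
    feats <- annotation[S4Vectors::mcols(annotation)$type == t]
    hits <- GenomicRanges::findOverlaps(bg, feats, ignore.strand = TRUE)
    if (!length(hits)) next
    rs <- bg$read_strand[S4Vectors::queryHits(hits)]
    fs <- as.character(BiocGenerics::strand(feats))[S4Vectors::subjectHits(hits)]
    keep <- switch(strand_mode,
                   both = rep(TRUE, length(hits)),
                   sense = fs == "*" | fs == rs,
                   antisense = fs == "*" | (fs != rs))
    if (!any(keep)) next
    reads <- bg$read[S4Vectors::queryHits(hits)][keep]
    rs <- rs[keep]
    for (s in c("+", "-")) {
      n <- length(unique(reads[rs == s]))
      out$count[out$feature_type == t & out$strand == s] <- n
    }
  }
  out
}

# per-position depth lookup over an Rle coverage list; positions outside the
# covered range report depth 0
.depth_at <- function(cov, seqid, positions) {
  if (!(seqid %in% names(cov))) return(numeric(length(positions)))
  r <- cov[[seqid]]
  d <- numeric(length(positions))
  inside <- positions >= 1L & positions <= length(r)
  if (any(inside)) d[inside] <- as.numeric(r[positions[inside]])
  d
}

#' Metagene coverage around start and stop codons
#'
#' Computes per-transcript read-depth profiles anchored at the CDS: the
#' \code{U} nucleotides upstream of the start codon and \code{D} downstream
#' of the stop codon at single-base resolution, the 3-base start and stop
#' codons themselves, and the spliced CDS compressed into \code{B} contiguous
#' bins of mean depth (bin boundaries at \code{floor(i*L/B)}, the last bin
#' absorbing the remainder). All vectors are oriented 5' to 3' in transcript
#' orientation; minus-strand transcripts are flipped accordingly. Depth at a
#' position is the number of primary alignment blocks covering it. The stop
#' codon is taken to be included in the CDS span. Transcripts without CDS
#' records, or with a spliced CDS shorter than \code{B} bases, are skipped
#' with a warning.
#'
#' @param sam SAM path or \code{\link{read_sam}} result.
#' @param annotation \code{GRanges} from \code{\link{read_gff3}} containing
#'   mRNA and CDS records linked by \code{Parent}.
#' @param transcript_ids transcripts to profile, or \code{"all"}.
#' @param U,D upstream/downstream window sizes in nucleotides.
#' @param B number of CDS bins.
#' @param aggregate if \code{TRUE}, sum the profiles over transcripts and
#'   return a single profile.
#' @return A \code{coverage_profile} (aggregate) or named list of them:
#'   fields \code{transcript_id}, \code{upstream} (length \code{U}),
#'   \code{start_codon}, \code{stop_codon} (length 3), \code{cds_binned}
#'   (length \code{B}), \code{downstream} (length \code{D}),
#'   \code{n_transcripts_aggregated}.
#' @export
feature_coverage <- function(sam, annotation, transcript_ids = "all",
                             U = 50L, D = 50L, B = 20L, aggregate = TRUE) {
  aln <- if (inherits(sam, "sam_alignments")) sam else read_sam(sam)
  bg <- .primary_block_granges(aln)
  cov <- GenomicRanges::coverage(bg)
  mc <- S4Vectors::mcols(annotation)
  tx <- annotation[mc$type == "mRNA"]
  tids <- as.character(S4Vectors::mcols(tx)$ID)
  if (!identical(transcript_ids, "all")) {
    keep <- tids %in% transcript_ids
    tx <- tx[keep]; tids <- tids[keep]
  }
  profiles <- list()
  for (i in seq_along(tx)) {
    tid <- tids[[i]]
    cds <- annotation[mc$type == "CDS" & !is.na(mc$Parent) & mc$Parent == tid]
    if (!length(cds)) {
      warning("transcript ", tid, " has no CDS records; skipped",
              call. = FALSE)
      next
    }
    strand <- as.character(BiocGenerics::strand(cds))[1]
    seqid <- as.character(GenomicRanges::seqnames(cds))[1]
    cds <- cds[order(BiocGenerics::start(cds))]
    # spliced CDS positions in 5'->3' transcript orientation
    gpos <- unlist(lapply(seq_along(cds), function(j)
      BiocGenerics::start(cds)[j]:BiocGenerics::end(cds)[j]))
    if (strand == "-") gpos <- rev(gpos)
    L <- length(gpos)
    if (L < B || L < 3L) {
      warning("transcript ", tid, " CDS (", L, " nt) shorter than B = ", B,
              "; skipped", call. = FALSE)
      next
    }
    win <- function(from, by, n) if (n < 1L) integer() else from + by * seq_len(n)
    if (strand == "-") {
      up_pos <- rev(win(gpos[1], 1L, U))       # 5' window, transcript-oriented
      down_pos <- win(gpos[L], -1L, D)
    } else {
      up_pos <- rev(win(gpos[1], -1L, U))
      down_pos <- win(gpos[L], 1L, D)
    }
    depth <- function(p) .depth_at(cov, seqid, p)
    cdsd <- depth(gpos)
    bnd <- floor((0:B) * L / B)
    binned <- vapply(seq_len(B), function(b)
      mean(cdsd[(bnd[b] + 1L):bnd[b + 1L]]), 1)
    profiles[[tid]] <- structure(
      list(transcript_id = tid, upstream = depth(up_pos),
           start_codon = cdsd[1:3], stop_codon = cdsd[(L - 2L):L],
           cds_binned = binned, downstream = depth(down_pos),
           n_transcripts_aggregated = 1L),
      class = "coverage_profile")
  }
  if (!aggregate) return(profiles)
  if (!length(profiles))
    return(structure(list(transcript_id = NA_character_,
                          upstream = numeric(U), start_codon = numeric(3),
                          stop_codon = numeric(3), cds_binned = numeric(B),
                          downstream = numeric(D),
                          n_transcripts_aggregated = 0L),
                     class = "coverage_profile"))
  agg <- profiles[[1]]
  agg$transcript_id <- NA_character_
  for (p in profiles[-1])
    for (f in c("upstream", "start_codon", "stop_codon", "cds_binned",
                "downstream"))
      agg[[f]] <- agg[[f]] + p[[f]]
  agg$n_transcripts_aggregated <- length(profiles)
  agg
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf(
    "coverage profile (%s): U=%d, B=%d bins, D=%d; mean CDS bin depth %.2f\n",
    if (is.na(x$transcript_id))
      sprintf("%d transcripts aggregated", x$n_transcripts_aggregated)
    else x$transcript_id,
    length(x$upstream), length(x$cds_binned), length(x$downstream),
    mean(x$cds_binned)))
  invisible(x)
}
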