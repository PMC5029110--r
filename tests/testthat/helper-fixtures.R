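# Shared fixture builders and independent oracles used across the suite.

write_toy_targets <- function(dir = tempfile(), n = 2L, cmp = TRUE,
                              factors = rep(c("A", "B"), length.out = n)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "targets.txt")
  sn <- paste0("S", seq_len(n))
  lines <- c(if (cmp) "# <CMP> CMPset1: A-B",
             "FileName1\tSampleName\tFactor",
             paste(paste0("s", seq_len(n), ".fq"), sn, factors, sep = "\t"))
  writeLines(lines, path)
  path
}

write_toy_param <- function(path = tempfile(fileext = ".param"),
                            software = "bowtie2") {
  writeLines(c(paste0("software\t\t", software),
               "option\t-p\t4",
               "reference\t-x\t<Reference>",
               "infile\t\t<FileName1>",
               "outfile\t-S\t<SampleName>.sam"), path)
  path
}

# a runnable cp step over n real input files; returns the sysargs object
make_cp_step <- function(n = 2L, dir = tempfile(), content = "payload") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ins <- file.path(dir, paste0("in", seq_len(n), ".txt"))
  for (f in ins) writeLines(c(content, basename(f)), f)
  tgt <- targets_table(data.frame(
    FileName1 = ins, SampleName = paste0("S", seq_len(n)),
    Factor = rep(c("A", "B"), length.out = n), stringsAsFactors = FALSE))
  pf <- file.path(dir, "cp.param")
  writeLines(c("software\t\tcp", "infile\t\t<FileName1>",
               "outfile\t\t<SampleName>.out"), pf)
  build_sysargs(tgt, read_param(pf), "copy", outdir = file.path(dir, "results"))
}

write_fastq <- function(seqs, quals, path = tempfile(fileext = ".fastq"),
                        ids = sprintf("r%03d", seq_along(seqs))) {
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), path)
  path
}

random_reads <- function(n, len, seed) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""), "")
  quals <- vapply(seq_len(n), function(i)
    intToUtf8(sample(33:73, len, replace = TRUE)), "")
  list(seq = seqs, qual = quals)
}

write_toy_sam <- function(records, path = tempfile(fileext = ".sam"),
                          sq = c(chr1 = 10000L)) {
  writeLines(c("@HD\tVN:1.6",
               sprintf("@SQ\tSN:%s\tLN:%d", names(sq), sq),
               records), path)
  path
}

sam_record <- function(qname, flag, rname, pos, cigar, len = NULL) {
  if (is.null(len)) {
    n <- sum(as.integer(regmatches(cigar,
      gregexpr("[0-9]+(?=[MIS=X])", cigar, perl = TRUE))[[1]]))
    len <- max(n, 1L)
  }
  paste(qname, flag, rname, pos, 60, cigar, "*", 0, 0,
        paste(rep("A", len), collapse = ""),
        paste(rep("I", len), collapse = ""), sep = "\t")
}

# ---- independent oracles ---------------------------------------------------

# CIGAR -> reference blocks, computed by walking the string op by op
oracle_cigar_blocks <- function(cigar, pos) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  cur <- pos
  blocks <- list()
  open_s <- NA
  for (o in ops) {
    n <- as.integer(sub("[A-Z=]", "", o))
    op <- sub("[0-9]+", "", o)
    if (op %in% c("M", "=", "X", "D")) {
      if (is.na(open_s)) open_s <- cur
      cur <- cur + n
    } else if (op == "N") {
      if (!is.na(open_s)) blocks[[length(blocks) + 1L]] <- c(open_s, cur - 1L)
      open_s <- NA
      cur <- cur + n
    }  # I/S/H consume nothing on the reference
  }
  if (!is.na(open_s)) blocks[[length(blocks) + 1L]] <- c(open_s, cur - 1L)
  do.call(rbind, blocks)
}

# exhaustive ORF enumeration: every (position, frame, strand) independently
oracle_orfs <- function(s, min_length, require_stop = TRUE) {
  s <- toupper(s)
  L <- nchar(s)
  revcomp <- function(x) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  }
  scan1 <- function(x) {
    res <- list()
    stops_used <- c()
    for (fr in 1:3) {
      p <- fr
      while (p + 2L <= nchar(x)) {
        if (substr(x, p, p + 2L) == "ATG") {
          q <- p
          ok <- FALSE
          while (q + 2L <= nchar(x)) {
            cod <- substr(x, q, q + 2L)
            if (cod %in% c("TAA", "TAG", "TGA")) { ok <- TRUE; break }
            q <- q + 3L
          }
          if (ok) {
            res[[length(res) + 1L]] <- c(p, q + 2L, fr)
            p <- q + 3L
            next
          } else {
            if (!require_stop) {
              last <- p + 3L * ((nchar(x) - p + 1L) %/% 3L) - 1L
              res[[length(res) + 1L]] <- c(p, last, fr)
            }
            break
          }
        }
        p <- p + 3L
      }
    }
    res
  }
  rows <- list()
  for (h in scan1(s))
    rows[[length(rows) + 1L]] <- data.frame(start = h[1], end = h[2],
                                            strand = "+", frame = h[3])
  for (h in scan1(revcomp(s)))
    rows[[length(rows) + 1L]] <- data.frame(start = L - h[2] + 1L,
                                            end = L - h[1] + 1L,
                                            strand = "-", frame = h[3])
  if (!length(rows))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), frame = integer()))
  out <- do.call(rbind, rows)
  out <- out[(out$end - out$start + 1L) >= min_length, , drop = FALSE]
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

# per-element membership-bitmask Venn oracle
oracle_venn <- function(sets) {
  sets <- lapply(sets, function(s) unique(as.character(s)))
  u <- unique(unlist(sets))
  counts <- list()
  for (el in u) {
    key <- paste(sort(names(sets)[vapply(sets, function(s) el %in% s, NA)]),
                 collapse = "&")
    counts[[key]] <- (counts[[key]] %||% 0L) + 1L
  }
  unlist(counts)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# quadratic all-pairs overlap oracle for feature-type counting
oracle_featuretype_counts <- function(aln, annotation, strand_mode = "both") {
  ann <- data.frame(seqid = as.character(GenomicRanges::seqnames(annotation)),
                    start = BiocGenerics::start(annotation),
                    end = BiocGenerics::end(annotation),
                    strand = as.character(BiocGenerics::strand(annotation)),
                    type = S4Vectors::mcols(annotation)$type)
  types <- sort(unique(ann$type))
  out <- expand.grid(feature_type = types, strand = c("+", "-"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$feature_type, out$strand), ]
  rownames(out) <- NULL
  out$count <- 0L
  prim <- which(!aln$unmapped & !aln$secondary)
  for (i in prim) {
    bl <- aln$blocks[[i]]
    if (!length(bl)) next
    rs <- aln$strand[[i]]
    for (t in types) {
      feats <- ann[ann$type == t, ]
      hit <- FALSE
      for (j in seq_len(nrow(feats))) {
        if (feats$seqid[j] != aln$rname[[i]]) next
        fs <- feats$strand[j]
        oks <- switch(strand_mode, both = TRUE,
                      sense = fs == "*" || fs == rs,
                      antisense = fs == "*" || fs != rs)
        if (!oks) next
        for (b in seq_along(bl)) {
          if (BiocGenerics::start(bl)[b] <= feats$end[j] &&
              BiocGenerics::end(bl)[b] >= feats$start[j]) { hit <- TRUE; break }
        }
        if (hit) break
      }
      if (hit)
        out$count[out$feature_type == t & out$strand == rs] <-
          out$count[out$feature_type == t & out$strand == rs] + 1L
    }
  }
  out
}
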