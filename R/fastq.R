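#' Stream a FASTQ file in bounded-memory batches
#'
#' Opens a plain or gzip FASTQ file and returns a stream object from which
#' batches of at most \code{batch_size} reads are pulled with
#' \code{\link{next_batch}}. Only one batch is held in memory at a time.
#' Record structure is validated as it is read: a truncated 4-line record or
#' a sequence/quality length mismatch raises a format error naming the
#' record index.
#'
#' @param path FASTQ path (\code{.gz} accepted).
#' @param batch_size maximum reads per batch.
#' @return An object of class \code{fastq_stream}; close it with
#'   \code{close()} (done automatically at end of file).
#' @export
stream_fastq <- function(path, batch_size = 10000L) {
  stopifnot(batch_size >= 1L)
  if (!file.exists(path)) stop("FASTQ file not found: ", path, call. = FALSE)
  con <- gzfile(path, "r")  # reads plain files too
  env <- new.env(parent = emptyenv())
  env$con <- con; env$open <- TRUE; env$nseen <- 0L
  env$batch_size <- as.integer(batch_size); env$path <- path
  structure(list(env = env), class = "fastq_stream")
}

#' Pull the next batch from a FASTQ stream
#' @param stream a \code{\link{stream_fastq}} object.
#' @return A list with character vectors \code{id}, \code{seq}, \code{qual}
#'   (equal lengths, at most \code{batch_size}), or \code{NULL} at end of
#'   file.
#' @export
next_batch <- function(stream) {
  env <- stream$env
  if (!env$open) return(NULL)
  lines <- readLines(env$con, n = 4L * env$batch_size, warn = FALSE)
  if (!length(lines)) { close(stream); return(NULL) }
  if (length(lines) %% 4L != 0L) {
    close(stream)
    stop(sprintf("truncated FASTQ record at record index %d in %s",
                 env$nseen + length(lines) %/% 4L + 1L, env$path),
         call. = FALSE)
  }
  idx <- seq(1L, length(lines), by = 4L)
  id <- lines[idx]; seq <- lines[idx + 1L]
  plus <- lines[idx + 2L]; qual <- lines[idx + 3L]
  bad <- which(!startsWith(id, "@") | !startsWith(plus, "+"))
  if (length(bad)) {
    close(stream)
    stop(sprintf("malformed FASTQ record at record index %d in %s",
                 env$nseen + bad[[1]], env$path), call. = FALSE)
  }
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad)) {
    close(stream)
    stop(sprintf(
      "sequence/quality length mismatch at record index %d in %s",
      env$nseen + bad[[1]], env$path), call. = FALSE)
  }
  env$nseen <- env$nseen + length(idx)
  list(id = sub("^@", "", id), seq = seq, qual = qual)
}

#' @export
close.fastq_stream <- function(con, ...) {
  env <- con$env
  if (env$open) { close(env$con); env$open <- FALSE }
  invisible(NULL)
}

# ---- read transforms -------------------------------------------------------
# A read transform is a function(seq, qual) -> list(seq=, qual=) of the same
# length; NA marks a dropped read. Built-ins below; combine with
# compose_filters().

#' Built-in read transforms for preprocess_reads
#'
#' \code{adaptor_trim} removes a 3' adaptor by exact suffix overlap: the
#' longest read suffix (of at least \code{min_overlap} bases) equal to a
#' prefix of the adaptor is cut off; mismatches are not tolerated.
#' \code{quality_trim} truncates a read after the last cycle whose Phred+33
#' quality reaches \code{threshold} (3' trimming). \code{min_length} drops
#' reads shorter than \code{L} bases. \code{mean_quality_filter} drops reads
#' whose mean quality is below \code{Q}. \code{compose_filters} chains
#' transforms left to right; a read dropped by any stage stays dropped.
#'
#' @param adaptor adaptor sequence (5'->3').
#' @param min_overlap minimum read-suffix/adaptor-prefix overlap to trim.
#' @param threshold,Q Phred quality cutoffs.
#' @param from_3prime trim from the 3' end (the only supported direction).
#' @param L minimum retained read length in bases.
#' @param ... transforms to chain.
#' @return A read-transform function.
#' @name read_transforms
NULL

#' @rdname read_transforms
#' @export
adaptor_trim <- function(adaptor, min_overlap = 6L) {
  stopifnot(nchar(adaptor) >= 1L, min_overlap >= 1L)
  function(seq, qual) {
    keep <- !is.na(seq)
    for (i in which(keep)) {
      L <- nchar(seq[[i]])
      for (o in seq(min(L, nchar(adaptor)), min_overlap)) {
        if (o < min_overlap) break
        if (substr(seq[[i]], L - o + 1L, L) == substr(adaptor, 1L, o)) {
          seq[[i]] <- substr(seq[[i]], 1L, L - o)
          qual[[i]] <- substr(qual[[i]], 1L, L - o)
          break
        }
      }
    }
    list(seq = seq, qual = qual)
  }
}

#' @rdname read_transforms
#' @export
quality_trim <- function(threshold, from_3prime = TRUE) {
  stopifnot(isTRUE(from_3prime))
  function(seq, qual) {
    for (i in which(!is.na(seq))) {
      q <- utf8ToInt(qual[[i]]) - 33L
      last <- if (length(q)) max(c(0L, which(q >= threshold))) else 0L
      seq[[i]] <- substr(seq[[i]], 1L, last)
      qual[[i]] <- substr(qual[[i]], 1L, last)
    }
    list(seq = seq, qual = qual)
  }
}

#' @rdname read_transforms
#' @export
min_length <- function(L) {
  function(seq, qual) {
    drop <- !is.na(seq) & nchar(seq) < L
    seq[drop] <- NA_character_; qual[drop] <- NA_character_
    list(seq = seq, qual = qual)
  }
}

#' @rdname read_transforms
#' @export
mean_quality_filter <- function(Q) {
  function(seq, qual) {
    for (i in which(!is.na(seq))) {
      q <- utf8ToInt(qual[[i]]) - 33L
      if (!length(q) || mean(q) < Q) {
        seq[[i]] <- NA_character_; qual[[i]] <- NA_character_
      }
    }
    list(seq = seq, qual = qual)
  }
}

#' @rdname read_transforms
#' @export
compose_filters <- function(...) {
  fs <- list(...)
  function(seq, qual) {
    for (f in fs) {
      r <- f(seq, qual); seq <- r$seq; qual <- r$qual
    }
    list(seq = seq, qual = qual)
  }
}

#' Filter and/or trim a FASTQ file
#'
#' Streams \code{infile} through a read transform and writes the kept reads,
#' in input order, to \code{outfile} (gzip if the path ends in \code{.gz}).
#' Trimming never lengthens a read and \code{kept + dropped} equals the
#' input read count.
#'
#' @param infile,outfile FASTQ paths.
#' @param filter a read transform, e.g. from \code{\link{read_transforms}} or
#'   \code{compose_filters()}.
#' @param batch_size reads held in memory at a time.
#' @return A list: \code{kept}, \code{dropped}, \code{bases_removed} (bases
#'   trimmed from reads that remain in the output).
#' @export
preprocess_reads <- function(infile, outfile, filter, batch_size = 10000L) {
  st <- stream_fastq(infile, batch_size)
  out <- if (grepl("\\.gz$", outfile)) gzfile(outfile, "w") else file(outfile, "w")
  on.exit({ close(st); close(out) })
  kept <- 0L; dropped <- 0L; bases_removed <- 0
  repeat {
    b <- next_batch(st)
    if (is.null(b)) break
    r <- filter(b$seq, b$qual)
    keep <- !is.na(r$seq)
    dropped <- dropped + sum(!keep)
    kept <- kept + sum(keep)
    bases_removed <- bases_removed +
      sum(nchar(b$seq[keep]) - nchar(r$seq[keep]))
    if (any(keep)) {
      rec <- rbind(paste0("@", b$id[keep]), r$seq[keep], "+", r$qual[keep])
      writeLines(as.vector(rec), out)
    }
  }
  list(kept = kept, dropped = dropped, bases_removed = bases_removed)
}

# ---- quality summary -------------------------------------------------------

.QMAX <- 93L  # Phred+33 scores 0..93 ('!' .. '~')

#' Streaming FASTQ quality and diversity summary
#'
#' Accumulates, in a single pass with bounded memory, the statistics behind
#' the eight QC panels: per-cycle quality distribution (min/Q1/median/Q3/max
#' and mean), per-cycle base proportions over A/C/G/T/N, per-read
#' mean-quality histogram, read-length histogram, exact-sequence duplication
#' histogram, per-cycle distinct k-mer diversity, per-read GC-fraction
#' histogram, and per-cycle N proportion. Qualities must be Phred+33.
#'
#' @param path FASTQ path.
#' @param k k-mer length for the diversity panel.
#' @param batch_size reads per streaming batch.
#' @param subsample number of reads to subsample (reservoir sampling with
#'   \code{seed}), or \code{Inf} for all reads (deterministic).
#' @param seed RNG seed used only when subsampling.
#' @return An object of class \code{fastq_summary}; see Details for fields.
#' @details Fields: \code{n_reads}; \code{cycle_quality} (data.frame cycle,
#'   min, q1, median, q3, max, mean, n); \code{cycle_base_freq} (matrix
#'   5 x cycles of proportions); \code{read_meanq_hist} (counts over
#'   \code{floor(mean quality)} 0..93); \code{length_hist} (named counts);
#'   \code{duplication_hist} (named counts: multiplicity -> number of
#'   distinct sequences); \code{kmer_diversity} (per cycle >= k, distinct
#'   k-mers ending at that cycle); \code{gc_hist} (20 bins over [0,1]);
#'   \code{n_per_cycle} (proportion of N calls per cycle).
#' @export
fastq_quality_summary <- function(path, k = 4L, batch_size = 10000L,
                                  subsample = Inf, seed = 1L) {
  if (is.finite(subsample)) {
    reads <- .reservoir_reads(path, as.integer(subsample), batch_size, seed)
    return(.summarize_reads(reads$seq, reads$qual, k, path))
  }
  st <- stream_fastq(path, batch_size)
  on.exit(close(st))
  acc <- NULL
  repeat {
    b <- next_batch(st)
    if (is.null(b)) break
    acc <- .accumulate_summary(acc, b$seq, b$qual, k)
  }
  .finalize_summary(acc, k, path)
}

.reservoir_reads <- function(path, n, batch_size, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  st <- stream_fastq(path, batch_size)
  on.exit(close(st), add = TRUE)
  seqs <- character(n); quals <- character(n); seen <- 0L; filled <- 0L
  repeat {
    b <- next_batch(st)
    if (is.null(b)) break
    for (i in seq_along(b$seq)) {
      seen <- seen + 1L
      if (filled < n) {
        filled <- filled + 1L
        seqs[filled] <- b$seq[i]; quals[filled] <- b$qual[i]
      } else {
        j <- sample.int(seen, 1L)
        if (j <= n) { seqs[j] <- b$seq[i]; quals[j] <- b$qual[i] }
      }
    }
  }
  list(seq = seqs[seq_len(filled)], qual = quals[seq_len(filled)])
}

.new_acc <- function() {
  e <- new.env(parent = emptyenv())
  e$n_reads <- 0L
  e$maxlen <- 0L
  e$qcounts <- NULL            # (QMAX+1) x cycles matrix of quality counts
  e$bcounts <- NULL            # 5 x cycles matrix of base counts (A,C,G,T,N)
  e$meanq <- integer(.QMAX + 1L)
  e$lengths <- new.env(parent = emptyenv())
  e$dups <- new.env(parent = emptyenv())
  e$kmers <- list()            # per cycle: environment used as string set
  e$gc <- integer(20L)
  e
}

.grow <- function(m, nrow_, cycles) {
  if (is.null(m)) return(matrix(0L, nrow_, cycles))
  if (ncol(m) >= cycles) return(m)
  cbind(m, matrix(0L, nrow_, cycles - ncol(m)))
}

.accumulate_summary <- function(acc, seqs, quals, k) {
  if (is.null(acc)) acc <- .new_acc()
  if (!length(seqs)) return(acc)
  lens <- nchar(seqs)
  maxlen <- max(acc$maxlen, max(lens))
  acc$qcounts <- .grow(acc$qcounts, .QMAX + 1L, maxlen)
  acc$bcounts <- .grow(acc$bcounts, 5L, maxlen)
  if (length(acc$kmers) < maxlen)
    for (c in (length(acc$kmers) + 1L):maxlen)
      acc$kmers[[c]] <- new.env(parent = emptyenv())
  acc$maxlen <- maxlen
  acc$n_reads <- acc$n_reads + length(seqs)
  base_code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  for (i in seq_along(seqs)) {
    s <- toupper(seqs[[i]]); L <- lens[[i]]
    q <- utf8ToInt(quals[[i]]) - 33L
    if (any(q < 0L)) stop("quality character below '!': not Phred+33",
                          call. = FALSE)
    if (any(q > .QMAX)) stop("quality score above 93: not Phred+33",
                             call. = FALSE)
    if (L > 0L) {
      cyc <- seq_len(L)
      idx <- (cyc - 1L) * (.QMAX + 1L) + q + 1L
      acc$qcounts[idx] <- acc$qcounts[idx] + 1L
      bchar <- strsplit(s, "", fixed = TRUE)[[1]]
      bc <- base_code[bchar]; bc[is.na(bc)] <- 5L
      bidx <- (cyc - 1L) * 5L + bc
      acc$bcounts[bidx] <- acc$bcounts[bidx] + 1L
      mq <- floor(mean(q)) + 1L
      acc$meanq[mq] <- acc$meanq[mq] + 1L
      gcf <- sum(bchar %in% c("G", "C")) / L
      gbin <- min(20L, floor(gcf * 20) + 1L)
      acc$gc[gbin] <- acc$gc[gbin] + 1L
      if (L >= k) {
        for (c in k:L) {
          km <- substr(s, c - k + 1L, c)
          assign(km, TRUE, envir = acc$kmers[[c]])
        }
      }
    } else {
      acc$meanq[1L] <- acc$meanq[1L] + 1L
      acc$gc[1L] <- acc$gc[1L] + 1L
    }
    lk <- paste0("L", L)           # prefixed keys: "" is not a legal env name
    acc$lengths[[lk]] <- (acc$lengths[[lk]] %||% 0L) + 1L
    sk <- paste0("s", s)
    acc$dups[[sk]] <- (acc$dups[[sk]] %||% 0L) + 1L
  }
  acc
}

.env_table <- function(e) {
  ks <- ls(e, all.names = TRUE)
  v <- vapply(ks, function(k) e[[k]], 1L)
  names(v) <- sub("^L", "", ks)
  v[order(as.numeric(names(v)))]
}

.finalize_summary <- function(acc, k, path) {
  if (is.null(acc)) acc <- .new_acc()
  ncyc <- acc$maxlen
  qstats <- data.frame(cycle = integer(), min = integer(), q1 = numeric(),
                       median = numeric(), q3 = numeric(), max = integer(),
                       mean = numeric(), n = integer())
  n_per_cycle <- numeric(ncyc)
  bfreq <- matrix(numeric(), 5L, 0L, dimnames = list(c("A","C","G","T","N"), NULL))
  if (ncyc > 0L) {
    qlev <- 0:.QMAX
    cstat <- function(cnt) {
      n <- sum(cnt)
      cum <- cumsum(cnt)
      qat <- function(p) qlev[which(cum >= p * n)[1]]
      c(min = qlev[which(cnt > 0)[1]], q1 = qat(0.25), median = qat(0.5),
        q3 = qat(0.75), max = qlev[tail(which(cnt > 0), 1)],
        mean = sum(qlev * cnt) / n, n = n)
    }
    st <- vapply(seq_len(ncyc), function(c) cstat(acc$qcounts[, c]), numeric(7))
    qstats <- data.frame(cycle = seq_len(ncyc), t(st))
    btot <- colSums(acc$bcounts)
    bfreq <- sweep(acc$bcounts, 2L, btot, "/")
    rownames(bfreq) <- c("A", "C", "G", "T", "N")
    n_per_cycle <- acc$bcounts[5L, ] / btot
  }
  mult <- vapply(ls(acc$dups, all.names = TRUE), function(s) acc$dups[[s]], 1L)
  dup_hist <- if (length(mult)) table(mult) else table(integer())
  dup <- as.integer(dup_hist)
  names(dup) <- names(dup_hist)
  kdiv <- if (ncyc >= k)
    vapply(k:ncyc, function(c) length(ls(acc$kmers[[c]], all.names = TRUE)), 1L)
  else integer()
  if (length(kdiv)) names(kdiv) <- as.character(k:ncyc)
  gc_hist <- acc$gc
  names(gc_hist) <- sprintf("(%.2f,%.2f]", (0:19) / 20, (1:20) / 20)
  names(gc_hist)[1] <- "[0.00,0.05]"
  structure(list(path = path, n_reads = acc$n_reads, k = k,
                 cycle_quality = qstats,
                 cycle_base_freq = bfreq,
                 read_meanq_hist = stats::setNames(acc$meanq, 0:.QMAX),
                 length_hist = .env_table(acc$lengths),
                 duplication_hist = dup,
                 kmer_diversity = kdiv,
                 gc_hist = gc_hist,
                 n_per_cycle = n_per_cycle),
            class = "fastq_summary")
}

.summarize_reads <- function(seqs, quals, k, path) {
  .finalize_summary(.accumulate_summary(NULL, seqs, quals, k), k, path)
}

#' @export
print.fastq_summary <- function(x, ...) {
  cat(sprintf("FASTQ summary: %s\n  %d reads, %d cycles, k=%d\n",
              x$path, x$n_reads, nrow(x$cycle_quality), x$k))
  if (nrow(x$cycle_quality)) {
    cat(sprintf("  mean quality cycle 1: %.1f, last cycle: %.1f\n",
                x$cycle_quality$mean[1],
                x$cycle_quality$mean[nrow(x$cycle_quality)]))
    cat(sprintf("  distinct sequences: %d\n", sum(x$duplication_hist)))
  }
  invisible(x)
}

#' Render the multi-file FASTQ QC report
#'
#' Draws the eight QC panels, one column per FASTQ summary, into a single
#' figure (PDF or PNG by file extension) and writes the underlying numbers
#' as a long-format TSV (\code{file}, \code{panel}, \code{x}, \code{stat},
#' \code{value}) next to it. The TSV is written deterministically, so
#' re-rendering unchanged summaries is byte-identical.
#'
#' @param summaries named list of \code{\link{fastq_quality_summary}}
#'   results.
#' @param out figure path (\code{.pdf} or \code{.png}).
#' @return \code{out}, invisibly, with attribute \code{tsv} giving the
#'   table's path.
#' @export
render_fastq_report <- function(summaries, out) {
  if (!length(summaries)) stop("no FASTQ summaries to render", call. = FALSE)
  if (is.null(names(summaries)) || any(names(summaries) == ""))
    names(summaries) <- paste0("file", seq_along(summaries))
  tsv <- paste0(tools::file_path_sans_ext(out), ".tsv")
  tab <- do.call(rbind, lapply(names(summaries), function(nm)
    .summary_long(summaries[[nm]], nm)))
  write.table(format(tab, digits = 15, trim = TRUE, scientific = FALSE),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  nf <- length(summaries)
  if (grepl("\\.png$", out)) {
    grDevices::png(out, width = 300 * nf + 200, height = 1800, res = 100)
  } else grDevices::pdf(out, width = 3 * nf + 2, height = 18)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(8, nf), mar = c(2.5, 3, 2, 0.5), mgp = c(1.6, 0.5, 0))
  panels <- c("per-cycle quality", "base proportions", "mean quality",
              "read length", "duplication", "k-mer diversity",
              "GC content", "N per cycle")
  for (p in seq_along(panels)) for (nm in names(summaries))
    .draw_panel(summaries[[nm]], p, paste(panels[p], "-", nm))
  invisible(structure(out, tsv = tsv))
}

.summary_long <- function(s, nm) {
  rws <- list()
  add <- function(panel, x, stat, value)
    rws[[length(rws) + 1L]] <<- data.frame(
      file = nm, panel = panel, x = as.character(x), stat = stat,
      value = as.numeric(value), stringsAsFactors = FALSE)
  add("n_reads", 0, "count", s$n_reads)
  cq <- s$cycle_quality
  for (col in c("min", "q1", "median", "q3", "max", "mean"))
    if (nrow(cq)) add("cycle_quality", cq$cycle, col, cq[[col]])
  if (ncol(s$cycle_base_freq))
    for (b in rownames(s$cycle_base_freq))
      add("cycle_base_freq", seq_len(ncol(s$cycle_base_freq)), b,
          s$cycle_base_freq[b, ])
  add("read_meanq_hist", names(s$read_meanq_hist), "count", s$read_meanq_hist)
  if (length(s$length_hist))
    add("length_hist", names(s$length_hist), "count", s$length_hist)
  if (length(s$duplication_hist))
    add("duplication_hist", names(s$duplication_hist), "count",
        s$duplication_hist)
  if (length(s$kmer_diversity))
    add("kmer_diversity", names(s$kmer_diversity), "distinct",
        s$kmer_diversity)
  add("gc_hist", names(s$gc_hist), "count", s$gc_hist)
  if (length(s$n_per_cycle))
    add("n_per_cycle", seq_along(s$n_per_cycle), "prop", s$n_per_cycle)
  do.call(rbind, rws)
}

.draw_panel <- function(s, p, title) {
  cq <- s$cycle_quality
  switch(p,
    { # per-cycle quality ribbon
      if (nrow(cq)) {
        graphics::plot(cq$cycle, cq$median, type = "n", ylim = c(0, .QMAX / 2),
                       xlab = "cycle", ylab = "Phred", main = title,
                       cex.main = 0.8)
        graphics::polygon(c(cq$cycle, rev(cq$cycle)), c(cq$q1, rev(cq$q3)),
                          col = "grey80", border = NA)
        graphics::lines(cq$cycle, cq$median, lwd = 2)
        graphics::lines(cq$cycle, cq$mean, col = "red3")
      } else graphics::plot.new()
    },
    { if (ncol(s$cycle_base_freq)) {
        graphics::matplot(t(s$cycle_base_freq), type = "l", lty = 1,
                          xlab = "cycle", ylab = "prop", main = title,
                          cex.main = 0.8)
        graphics::legend("topright", rownames(s$cycle_base_freq),
                         col = 1:5, lty = 1, cex = 0.5, bty = "n")
      } else graphics::plot.new()
    },
    graphics::barplot(s$read_meanq_hist, main = title, cex.main = 0.8,
                      xlab = "mean Phred", border = NA),
    graphics::barplot(s$length_hist, main = title, cex.main = 0.8,
                      xlab = "length", border = NA),
    graphics::barplot(s$duplication_hist, main = title, cex.main = 0.8,
                      xlab = "multiplicity", border = NA),
    { if (length(s$kmer_diversity))
        graphics::plot(as.integer(names(s$kmer_diversity)), s$kmer_diversity,
                       type = "l", xlab = "cycle", ylab = "distinct k-mers",
                       main = title, cex.main = 0.8)
      else graphics::plot.new()
    },
    graphics::barplot(s$gc_hist, main = title, cex.main = 0.8,
                      xlab = "GC fraction", border = NA, names.arg = NULL),
    { if (length(s$n_per_cycle))
        graphics::plot(seq_along(s$n_per_cycle), s$n_per_cycle, type = "h",
                       xlab = "cycle", ylab = "N prop", main = title,
                       cex.main = 0.8, ylim = c(0, max(s$n_per_cycle, 0.01)))
      else graphics::plot.new()
    })
}
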