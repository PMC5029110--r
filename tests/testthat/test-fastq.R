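test_that("stream_fastq yields bounded batches, plain or gzipped", {
  r <- random_reads(10L, 20L, seed = 1)
  fq <- write_fastq(r$seq, r$qual)
  st <- stream_fastq(fq, batch_size = 4L)
  sizes <- integer()
  repeat {
    b <- next_batch(st)
    if (is.null(b)) break
    sizes <- c(sizes, length(b$seq))
  }
  expect_equal(sizes, c(4L, 4L, 2L))

  gz <- paste0(fq, ".gz")
  con <- gzfile(gz, "w"); writeLines(readLines(fq), con); close(con)
  st2 <- stream_fastq(gz, batch_size = 100L)
  b2 <- next_batch(st2)
  expect_equal(b2$seq, r$seq)
  expect_equal(b2$qual, r$qual)
  expect_null(next_batch(st2))
})

test_that("malformed FASTQ records raise errors naming the record index", {
  fq <- tempfile()
  writeLines(c("@r1", "ACGTA", "+", "IIII"), fq)  # 5 bases, 4 quals
  st <- stream_fastq(fq)
  expect_error(next_batch(st), "length mismatch at record index 1")

  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), fq)
  st <- stream_fastq(fq)
  expect_error(next_batch(st), "truncated FASTQ record at record index 2")
})

test_that("built-in read transforms match their definitions", {
  tr <- adaptor_trim("AAAA", min_overlap = 4L)
  r <- tr("ACGTACGTAAAA", "IIIIIIIIIIII")
  expect_equal(r$seq, "ACGTACGT")
  expect_equal(r$qual, "IIIIIIII")
  # partial 3' overlap shorter than min_overlap is left alone
  r2 <- tr("ACGTACGTAAA", "IIIIIIIIIII")
  expect_equal(r2$seq, "ACGTACGTAAA")
  # min_length drops the trimmed 8-mer
  r3 <- min_length(10L)(r$seq, r$qual)
  expect_true(is.na(r3$seq))
  # quality_trim chops low-quality 3' tail ('#' = Q2)
  r4 <- quality_trim(20L)("ACGTACGT", "IIIII###")
  expect_equal(r4$seq, "ACGTA")
})

test_that("preprocess_reads keeps order, conserves counts, never lengthens", {
  r <- random_reads(100L, 30L, seed = 42)
  fq <- write_fastq(r$seq, r$qual)
  out <- tempfile(fileext = ".fastq")
  stats <- preprocess_reads(fq, out, mean_quality_filter(20), batch_size = 7L)
  expect_equal(stats$kept + stats$dropped, 100L)
  # brute-force oracle: per-read mean quality computed directly
  meanq <- vapply(r$qual, function(q) mean(utf8ToInt(q) - 33), 1,
                  USE.NAMES = FALSE)
  keep_oracle <- meanq >= 20
  expect_equal(stats$kept, sum(keep_oracle))
  st <- stream_fastq(out, 1000L); b <- next_batch(st); close(st)
  if (is.null(b)) b <- list(seq = character())
  expect_equal(b$seq, r$seq[keep_oracle])  # order preserved, untrimmed
  expect_equal(stats$bases_removed, 0)

  # trimming never lengthens: adaptor + length filter chained
  stats2 <- preprocess_reads(fq, out, compose_filters(
    adaptor_trim("ACG", min_overlap = 2L), min_length(5L)))
  st3 <- stream_fastq(out, 1000L); b3 <- next_batch(st3); close(st3)
  expect_true(all(nchar(b3$seq) <= 30L))
  expect_true(all(nchar(b3$seq) >= 5L))
})

test_that("quality summary reproduces the worked Phred example", {
  fq <- write_fastq(c("AC", "AG"), c("II", "I5"))
  s <- fastq_quality_summary(fq, k = 1L)
  expect_equal(s$cycle_quality$mean, c(40, 30))  # 'I'=40, '5'=20
  expect_equal(unname(s$cycle_base_freq["A", 1]), 1.0)
  expect_equal(unname(s$cycle_base_freq["C", 2]), 0.5)
  expect_equal(unname(s$cycle_base_freq["G", 2]), 0.5)
  # quality below '!' is an encoding error
  fq2 <- write_fastq("AC", "I ")
  expect_error(fastq_quality_summary(fq2), "Phred")
})

test_that("summary invariants: duplication, lengths, base proportions", {
  fq <- write_fastq(rep("ACGTACGT", 5L), rep("IIIIIIII", 5L))
  s <- fastq_quality_summary(fq)
  expect_equal(s$duplication_hist, c("5" = 1L))  # one sequence, seen 5 times
  expect_equal(sum(as.integer(names(s$duplication_hist)) *
                     s$duplication_hist), s$n_reads)
  r <- random_reads(200L, 25L, seed = 3)
  fq2 <- write_fastq(r$seq, r$qual)
  s2 <- fastq_quality_summary(fq2, k = 4L)
  expect_equal(sum(s2$length_hist), s2$n_reads)
  expect_equal(sum(as.integer(names(s2$duplication_hist)) *
                     s2$duplication_hist), s2$n_reads)
  expect_true(all(abs(colSums(s2$cycle_base_freq) - 1) < 1e-9))
  # k-mer diversity bounded by possibilities and read count
  expect_true(all(s2$kmer_diversity <= pmin(4^4, 200L)))
  # exact distinct-count oracle at cycle 4
  expect_equal(unname(s2$kmer_diversity["4"]),
               length(unique(substr(r$seq, 1, 4))))
})

test_that("summary is identical across batch sizes and record order", {
  r <- random_reads(300L, 30L, seed = 11)
  fq <- write_fastq(r$seq, r$qual)
  s1 <- fastq_quality_summary(fq, batch_size = 1L)
  s2 <- fastq_quality_summary(fq, batch_size = 1000000L)
  s1$path <- s2$path <- NULL
  expect_identical(s1, s2)
  set.seed(99)
  p <- sample(300L)
  fq_sh <- write_fastq(r$seq[p], r$qual[p])
  s3 <- fastq_quality_summary(fq_sh)
  s3$path <- NULL
  expect_identical(s3, s1)
  # subsampling with a fixed seed is reproducible
  a <- fastq_quality_summary(fq, subsample = 50L, seed = 5L)
  b <- fastq_quality_summary(fq, subsample = 50L, seed = 5L)
  expect_identical(a, b)
  expect_equal(a$n_reads, 50L)
})

test_that("summary agrees with an independent ShortRead computation", {
  r <- random_reads(80L, 40L, seed = 21)
  fq <- write_fastq(r$seq, r$qual)
  s <- fastq_quality_summary(fq)
  sr <- ShortRead::readFastq(fq)
  q <- methods::as(Biostrings::quality(sr), "matrix")
  expect_equal(s$cycle_quality$mean, unname(colMeans(q)))
  ab <- Biostrings::alphabetFrequency(ShortRead::sread(sr))
  expect_equal(unname(s$cycle_base_freq["G", ] * 80),
               unname(Biostrings::consensusMatrix(ShortRead::sread(sr))["G", ]))
})

test_that("render_fastq_report writes the figure and a deterministic TSV", {
  r <- random_reads(50L, 20L, seed = 2)
  fq <- write_fastq(r$seq, r$qual)
  sums <- list(one = fastq_quality_summary(fq),
               two = fastq_quality_summary(fq),
               three = fastq_quality_summary(fq))
  out <- tempfile(fileext = ".pdf")
  res <- render_fastq_report(sums, out)
  tsv <- attr(res, "tsv")
  expect_true(file.exists(out))
  tab <- read.delim(tsv, stringsAsFactors = FALSE)
  expect_equal(sort(unique(tab$file)), c("one", "three", "two"))
  # TSV values exactly equal the in-memory summary
  m <- tab[tab$file == "one" & tab$panel == "cycle_quality" &
             tab$stat == "mean", ]
  expect_equal(m$value[order(as.integer(m$x))], sums$one$cycle_quality$mean)
  bytes1 <- readBin(tsv, "raw", file.info(tsv)$size)
  render_fastq_report(sums, out)
  bytes2 <- readBin(tsv, "raw", file.info(tsv)$size)
  expect_identical(bytes1, bytes2)
  expect_error(render_fastq_report(list(), out), "no FASTQ summaries")
})
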