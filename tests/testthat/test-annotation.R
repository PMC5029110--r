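test_that("read_gff3 preserves coordinates and links, rejects bad lines", {
  gff <- tempfile()
  writeLines(c("##gff-version 3",
               "chr1\tsrc\texon\t11\t20\t.\t+\t.\tID=e1;Parent=t1",
               "###",
               "chr1\tsrc\tgene\t5\t100\t.\t-\t.\tID=g1"), gff)
  gr <- read_gff3(gff)
  expect_equal(length(gr), 2L)
  expect_equal(BiocGenerics::start(gr), c(11L, 5L))
  expect_equal(BiocGenerics::end(gr), c(20L, 100L))
  expect_equal(S4Vectors::mcols(gr)$type, c("exon", "gene"))
  expect_equal(S4Vectors::mcols(gr)$ID, c("e1", "g1"))
  expect_equal(S4Vectors::mcols(gr)$Parent, c("t1", NA))

  writeLines("chr1\tsrc\texon\t30\t20\t.\t+\t.\tID=e1", gff)
  expect_error(read_gff3(gff), "start > end on GFF3 line 1")
  writeLines("chr1\tsrc\texon\txx\t20\t.\t+\t.\tID=e1", gff)
  expect_error(read_gff3(gff), "non-integer coordinates")
})

test_that("GFF3 write -> read is the identity on fixture annotations", {
  g <- make_genome(1L, 15000L, 0.5, seed = 31)
  gff <- make_annotation(g, n_genes = 6L, seed = 32)
  gr1 <- read_gff3(gff)
  out <- tempfile(fileext = ".gff3")
  write_gff3(gr1, out)
  gr2 <- read_gff3(out)
  expect_identical(as.character(GenomicRanges::seqnames(gr1)),
                   as.character(GenomicRanges::seqnames(gr2)))
  expect_identical(BiocGenerics::start(gr1), BiocGenerics::start(gr2))
  expect_identical(BiocGenerics::end(gr1), BiocGenerics::end(gr2))
  expect_identical(as.character(BiocGenerics::strand(gr1)),
                   as.character(BiocGenerics::strand(gr2)))
  expect_identical(S4Vectors::mcols(gr1)$attributes,
                   S4Vectors::mcols(gr2)$attributes)
  # independent parser agrees on coordinates and types
  rt <- rtracklayer::import(out)
  expect_equal(BiocGenerics::start(rt), BiocGenerics::start(gr1))
  expect_equal(as.character(rt$type), S4Vectors::mcols(gr1)$type)
})

test_that("read_sam derives reference blocks from CIGAR correctly", {
  sam <- write_toy_sam(c(
    sam_record("r1", 0, "chr1", 100, "10M"),
    sam_record("r2", 0, "chr1", 100, "5M20N5M"),
    sam_record("r3", 4, "*", 0, "*"),
    sam_record("r4", 16, "chr1", 200, "3S7M2I5M"),
    sam_record("r5", 0, "chr1", 300, "4M2D4M")))
  aln <- read_sam(sam)
  expect_equal(length(aln$flag), 5L)
  b1 <- aln$blocks[[1]]
  expect_equal(BiocGenerics::start(b1), 100L)
  expect_equal(BiocGenerics::end(b1), 109L)
  b2 <- aln$blocks[[2]]
  expect_equal(BiocGenerics::start(b2), c(100L, 125L))
  expect_equal(BiocGenerics::end(b2), c(104L, 129L))
  expect_true(aln$unmapped[3])
  expect_equal(length(aln$blocks[[3]]), 0L)
  expect_equal(aln$strand[4], "-")
  # I and S consume no reference: M runs around an insertion stay contiguous
  expect_equal(BiocGenerics::start(aln$blocks[[4]]), 200L)
  expect_equal(BiocGenerics::end(aln$blocks[[4]]), 211L)
  b5 <- aln$blocks[[5]]
  expect_equal(BiocGenerics::start(b5), 300L)
  expect_equal(BiocGenerics::end(b5), 309L)

  bad <- write_toy_sam(sam_record("r1", 0, "chr1", 1, "5Q"))
  expect_error(read_sam(bad), "unknown CIGAR")
})

test_that("CIGAR blocks match a hand-walked oracle on random records", {
  set.seed(7)
  ops <- c("M", "I", "D", "N", "S")
  for (trial in 1:50) {
    n_ops <- sample(1:6, 1)
    cig <- character()
    has_m <- FALSE
    for (k in seq_len(n_ops)) {
      op <- sample(ops, 1)
      if (k == 1 || k == n_ops) op <- "M"  # keep CIGAR well-formed
      if (op == "M") has_m <- TRUE
      cig <- c(cig, paste0(sample(1:9, 1), op))
    }
    cigar <- paste(cig, collapse = "")
    pos <- sample(1:1000, 1)
    sam <- write_toy_sam(sam_record("r", 0, "chr1", pos, cigar))
    aln <- read_sam(sam)
    got <- cbind(BiocGenerics::start(aln$blocks[[1]]),
                 BiocGenerics::end(aln$blocks[[1]]))
    expect_equal(unname(got), unname(oracle_cigar_blocks(cigar, pos)),
                 info = cigar)
  }
})

test_that("align_stats counts primary records and rounds percentages", {
  sam <- write_toy_sam(c(
    sam_record("r1", 0, "chr1", 100, "10M"),
    sam_record("r2", 0, "chr1", 150, "10M"),
    sam_record("r3", 4, "*", 0, "*")))
  st <- align_stats(sam, "three")
  expect_equal(st$total_reads, 3L)
  expect_equal(st$aligned, 2L)
  expect_equal(st$align_pct, 66.7)
  # a secondary record among four leaves total at 3
  sam2 <- write_toy_sam(c(
    sam_record("r1", 0, "chr1", 100, "10M"),
    sam_record("r1", 256, "chr1", 500, "10M"),
    sam_record("r2", 0, "chr1", 150, "10M"),
    sam_record("r3", 0, "chr1", 180, "10M")))
  st2 <- align_stats(sam2, "four")
  expect_equal(st2$total_reads, 3L)
  expect_equal(st2$align_pct, 100.0)
  expect_equal(st2$secondary, 1L)
  empty <- write_toy_sam(character())
  expect_warning(st3 <- align_stats(empty, "empty"), "no alignment records")
  expect_equal(st3$total_reads, 0L)
})

test_that("featuretype_counts handles strandedness and zero rows", {
  gff <- tempfile()
  writeLines(c("chr1\tsrc\texon\t105\t120\t.\t+\t.\tID=e1",
               "chr1\tsrc\tgene\t50\t200\t.\t+\t.\tID=g1",
               "chr1\tsrc\tintron\t300\t400\t.\t+\t.\tID=i1"), gff)
  ann <- read_gff3(gff)
  sam <- write_toy_sam(sam_record("r1", 0, "chr1", 100, "10M"))
  fc <- featuretype_counts(sam, ann)
  get <- function(t, s) fc$count[fc$feature_type == t & fc$strand == s]
  expect_equal(get("exon", "+"), 1L)
  expect_equal(get("gene", "+"), 1L)
  expect_equal(get("intron", "+"), 0L)
  expect_equal(get("exon", "-"), 0L)
  # sense mode: a minus-strand feature no longer matches the plus read
  gff2 <- tempfile()
  writeLines("chr1\tsrc\texon\t105\t120\t.\t-\t.\tID=e1", gff2)
  fc2 <- featuretype_counts(sam, read_gff3(gff2), strand_mode = "sense")
  expect_equal(sum(fc2$count), 0L)
  fc3 <- featuretype_counts(sam, read_gff3(gff2), strand_mode = "antisense")
  expect_equal(fc3$count[fc3$feature_type == "exon" & fc3$strand == "+"], 1L)
})

test_that("featuretype_counts equals the quadratic overlap oracle", {
  g <- make_genome(1L, 20000L, 0.5, seed = 41)
  gff <- make_annotation(g, n_genes = 8L, seed = 42)
  ann <- read_gff3(gff)
  sim <- simulate_reads(g, gff, n_reads = 400L, read_len = 40L,
                        error_rate = 0, seed = 43)
  aln <- read_sam(sim$sam)
  for (mode in c("both", "sense", "antisense")) {
    expect_equal(featuretype_counts(aln, ann, strand_mode = mode),
                 oracle_featuretype_counts(aln, ann, strand_mode = mode),
                 info = mode)
  }
})

test_that("feature_coverage resolves bins and orientation", {
  # single + transcript, CDS 101-160, one read covering 101-110, B=6
  gff <- tempfile()
  writeLines(c("chr1\tsrc\tgene\t81\t180\t.\t+\t.\tID=g1",
               "chr1\tsrc\tmRNA\t81\t180\t.\t+\t.\tID=t1;Parent=g1",
               "chr1\tsrc\texon\t81\t180\t.\t+\t.\tParent=t1",
               "chr1\tsrc\tCDS\t101\t160\t.\t+\t.\tParent=t1"), gff)
  ann <- read_gff3(gff)
  sam <- write_toy_sam(sam_record("r1", 0, "chr1", 101, "10M"))
  cov <- feature_coverage(sam, ann, U = 10L, D = 10L, B = 6L)
  expect_equal(cov$upstream, rep(0, 10))
  expect_equal(cov$cds_binned, c(1, 0, 0, 0, 0, 0))
  expect_equal(cov$start_codon, c(1, 1, 1))
  expect_equal(cov$downstream, rep(0, 10))
  # same geometry on the minus strand: read over the CDS's last genomic
  # 10 nt is the transcript's 5'-most bin
  gff2 <- tempfile()
  writeLines(c("chr1\tsrc\tgene\t81\t180\t.\t-\t.\tID=g1",
               "chr1\tsrc\tmRNA\t81\t180\t.\t-\t.\tID=t1;Parent=g1",
               "chr1\tsrc\texon\t81\t180\t.\t-\t.\tParent=t1",
               "chr1\tsrc\tCDS\t101\t160\t.\t-\t.\tParent=t1"), gff2)
  sam2 <- write_toy_sam(sam_record("r1", 16, "chr1", 151, "10M"))
  cov2 <- feature_coverage(sam2, read_gff3(gff2), U = 10L, D = 10L, B = 6L)
  expect_equal(cov2$cds_binned, c(1, 0, 0, 0, 0, 0))
  # transcript without CDS is skipped with a warning
  gff3 <- tempfile()
  writeLines(c("chr1\tsrc\tmRNA\t81\t180\t.\t+\t.\tID=t9"), gff3)
  expect_warning(feature_coverage(sam, read_gff3(gff3), B = 6L), "no CDS")
})

test_that("genome-wide coverage conserves aligned bases", {
  g <- make_genome(2L, 8000L, 0.5, seed = 51)
  gff <- make_annotation(g, n_genes = 4L, seed = 52)
  sim <- simulate_reads(g, gff, n_reads = 300L, read_len = 36L,
                        error_rate = 0, seed = 53)
  aln <- read_sam(sim$sam)
  bg <- ngsflow:::.primary_block_granges(aln)
  cov <- GenomicRanges::coverage(bg)
  total_depth <- sum(vapply(cov, function(r) sum(as.numeric(r)), 1))
  total_bases <- sum(vapply(seq_along(aln$flag), function(i)
    sum(BiocGenerics::width(aln$blocks[[i]])), 1))
  expect_equal(total_depth, total_bases)
})
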