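test_that("pred_orf finds the canonical toy ORFs on both strands", {
  res <- pred_orf("ATGAAATAG", min_length = 9L)
  expect_equal(nrow(res), 1L)
  expect_equal(res$start, 1L)
  expect_equal(res$end, 9L)
  expect_equal(res$strand, "+")
  expect_equal(res$frame, 1L)
  expect_equal(res$length_nt, 9L)
  # reverse complement: same ORF reported on the minus strand
  res2 <- pred_orf("CTATTTCAT", strand = "-", min_length = 9L)
  expect_equal(nrow(res2), 1L)
  expect_equal(c(res2$start, res2$end), c(1L, 9L))
  expect_equal(res2$strand, "-")
  expect_equal(res2$frame, 1L)
  # no stop: empty with require_stop, open-ended without
  expect_equal(nrow(pred_orf("ATGAAA", min_length = 6L)), 0L)
  res3 <- pred_orf("ATGAAA", min_length = 6L, require_stop = FALSE,
                   strand = "+")
  expect_equal(c(res3$start, res3$end), c(1L, 6L))
  expect_equal(nrow(pred_orf("", min_length = 3L)), 0L)
  expect_error(pred_orf("ATGQAA"), "non-DNA")
})

test_that("internal ATGs sharing a stop are suppressed; N blocks codons", {
  # two in-frame ATGs, one stop: only the maximal 5' ORF
  res <- pred_orf("ATGATGAAATAA", strand = "+", min_length = 3L)
  expect_equal(nrow(res), 1L)
  expect_equal(res$start, 1L)
  expect_equal(res$length_nt, 12L)
  # scanning resumes after the stop: a second ORF downstream is found
  res2 <- pred_orf("ATGTAAATGTAG", strand = "+", min_length = 3L)
  expect_equal(nrow(res2), 2L)
  expect_equal(sort(res2$start), c(1L, 7L))
  # N-containing codons neither start nor stop
  expect_equal(nrow(pred_orf("ATNAAATAG", strand = "+", min_length = 3L)), 0L)
  # an N inside a sense codon does not terminate scanning
  res3 <- pred_orf("ATGANATAGTAA", strand = "+", min_length = 3L)
  expect_equal(res3$end, 9L)  # ATG ANA TAG: N codon passed through, TAG stops
})

test_that("pred_orf matches the exhaustive oracle on random sequences", {
  set.seed(17)
  for (trial in 1:20) {
    L <- 2000L
    s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                      prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
    got <- pred_orf(s, min_length = 30L)
    got <- got[order(got$start, got$end, got$strand), ]
    want <- oracle_orfs(s, min_length = 30L)
    expect_equal(got$start, want$start, info = trial)
    expect_equal(got$end, want$end, info = trial)
    expect_equal(got$strand, want$strand, info = trial)
    expect_equal(got$frame, want$frame, info = trial)
  }
})

test_that("reported ORFs start with ATG, end with a stop, length %% 3 == 0", {
  set.seed(23)
  s <- paste(sample(c("A", "C", "G", "T", "N"), 3000L, replace = TRUE,
                    prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
  res <- pred_orf(s, min_length = 30L)
  expect_gt(nrow(res), 0L)
  expect_true(all(res$length_nt %% 3L == 0L))
  expect_true(all(res$end - res$start + 1L == res$length_nt))
  for (i in seq_len(nrow(res))) {
    sub <- substr(s, res$start[i], res$end[i])
    if (res$strand[i] == "-")
      sub <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(sub)))
    expect_equal(substr(sub, 1, 3), "ATG")
    expect_true(substr(sub, nchar(sub) - 2, nchar(sub)) %in%
                  c("TAA", "TAG", "TGA"))
  }
  # frame matches its definition in scanning orientation
  plus <- res[res$strand == "+", ]
  expect_equal(plus$frame, ((plus$start - 1L) %% 3L) + 1L)
})

test_that("strand symmetry, ranking, subsetting and monotonicity hold", {
  set.seed(29)
  s <- paste(sample(c("A", "C", "G", "T"), 1500L, replace = TRUE),
             collapse = "")
  L <- nchar(s)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  plus_on_rc <- pred_orf(rc, strand = "+", min_length = 30L)
  minus_on_s <- pred_orf(s, strand = "-", min_length = 30L)
  mapped <- data.frame(start = L - plus_on_rc$end + 1L,
                       end = L - plus_on_rc$start + 1L)
  mapped <- mapped[order(mapped$start), ]
  ms <- minus_on_s[order(minus_on_s$start), ]
  expect_equal(ms$start, mapped$start)
  expect_equal(ms$end, mapped$end)

  all_orfs <- pred_orf(s, min_length = 30L)
  expect_equal(all_orfs$rank, seq_len(nrow(all_orfs)))
  expect_true(all(diff(all_orfs$length_nt) <= 0L))
  expect_equal(nrow(pred_orf(s, n = "longest", min_length = 30L)), 1L)
  expect_equal(nrow(pred_orf(s, n = 3L, min_length = 30L)), 3L)
  # raising min_length never adds ORFs
  lo <- pred_orf(s, min_length = 30L)
  hi <- pred_orf(s, min_length = 60L)
  expect_true(nrow(hi) <= nrow(lo))
  key <- function(d) paste(d$start, d$end, d$strand)
  expect_true(all(key(hi) %in% key(lo)))
  # longest_disjoint keeps a non-overlapping subset led by rank 1
  dj <- pred_orf(s, min_length = 30L, longest_disjoint = TRUE)
  if (nrow(dj) > 1L) {
    o <- dj[order(dj$start), ]
    expect_true(all(o$start[-1] > o$end[-nrow(o)]))
  }
  expect_equal(dj$length_nt[1], all_orfs$length_nt[1])
})
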