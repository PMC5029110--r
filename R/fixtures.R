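# Synthetic-data generators: a random genome, a ground-truth annotation and
# simulated reads (FASTQ + SAM + truth table), so that every analysis
# operation is testable offline against known answers.

# run expr with a given seed, restoring the caller's RNG state afterwards
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

.STOPS <- c("TAA", "TAG", "TGA")
.CODONS64 <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                               c("A","C","G","T")), 1L, paste, collapse = "")
.SENSE_CODONS <- setdiff(.CODONS64, .STOPS)

#' Generate a random genome FASTA
#'
#' Bases are drawn i.i.d. with G and C probability \code{gc/2} each;
#' deterministic for a given seed.
#'
#' @param n_chroms number of chromosomes.
#' @param length chromosome length in nucleotides (recycled per chromosome).
#' @param gc target GC fraction, in (0, 1).
#' @param seed RNG seed.
#' @param path output FASTA path.
#' @return \code{path}, invisibly.
#' @export
make_genome <- function(n_chroms = 1L, length = 10000L, gc = 0.5,
                        seed = 1L, path = tempfile(fileext = ".fa")) {
  stopifnot(length >= 1L, n_chroms >= 1L)
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)", call. = FALSE)
  length <- rep_len(as.integer(length), n_chroms)
  seqs <- .with_seed(seed, lapply(seq_len(n_chroms), function(i)
    paste(sample(c("A", "T", "G", "C"), length[i], replace = TRUE,
                 prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
          collapse = "")))
  dss <- Biostrings::DNAStringSet(unlist(seqs))
  names(dss) <- paste0("chr", seq_len(n_chroms))
  Biostrings::writeXStringSet(dss, path, width = 80L)
  invisible(path)
}

.revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

#' Generate a ground-truth gene annotation
#'
#' Places non-overlapping genes on random strands and writes a GFF3 with
#' gene, mRNA, exon and CDS records linked by Parent attributes. The CDS is
#' kept contiguous inside one exon; additional exons, when drawn, are UTR
#' exons separated by introns. Each CDS sequence is written into the genome
#' FASTA (which is rewritten in place): an ATG start, random sense codons,
#' and a stop codon — plus an in-frame stop immediately 5' of the ATG — so
#' the maximal ORF found by \code{\link{pred_orf}} spans the CDS exactly and
#' coverage tools have exact ground truth.
#'
#' @param genome path to a FASTA from \code{\link{make_genome}}; modified in
#'   place.
#' @param n_genes number of genes to place.
#' @param exons_per_gene integer range \code{c(min, max)} of exons per gene.
#' @param cds_length range of CDS lengths in nt (rounded to codons).
#' @param seed RNG seed.
#' @param path output GFF3 path.
#' @return \code{path}, invisibly; the truth is recoverable from the GFF3.
#' @export
make_annotation <- function(genome, n_genes = 10L, exons_per_gene = c(1L, 2L),
                            cds_length = c(90L, 300L), seed = 1L,
                            path = tempfile(fileext = ".gff3")) {
  dss <- Biostrings::readDNAStringSet(genome)
  chrs <- as.character(dss)
  chr_names <- names(dss)
  .with_seed(seed, {
    used <- lapply(chrs, function(x) integer())  # occupied intervals per chrom
    recs <- list()
    for (g in seq_len(n_genes)) {
      cds_len <- (sample(cds_length[1]:cds_length[2], 1L) %/% 3L) * 3L
      n_ex <- min(sample(exons_per_gene[1]:exons_per_gene[2], 1L), 2L)
      utr5 <- sample(10:40, 1L); utr3 <- sample(10:40, 1L)
      intron <- if (n_ex > 1L) sample(30:80, n_ex - 1L) else integer()
      gene_len <- utr5 + cds_len + utr3 + sum(intron) + 6L
      placed <- FALSE
      for (try in 1:200) {
        ci <- sample(seq_along(chrs), 1L)
        if (nchar(chrs[[ci]]) < gene_len + 20L) next
        gs <- sample(10:(nchar(chrs[[ci]]) - gene_len - 10L), 1L)
        ge <- gs + gene_len - 1L
        ints <- used[[ci]]
        clash <- FALSE
        if (length(ints)) {
          m <- matrix(ints, ncol = 2L, byrow = TRUE)
          clash <- any(gs <= m[, 2] & ge >= m[, 1])
        }
        if (!clash) { placed <- TRUE; break }
      }
      if (!placed)
        stop("could not place ", n_genes, " non-overlapping genes; ",
             "reduce n_genes or enlarge the genome", call. = FALSE)
      used[[ci]] <- c(used[[ci]], gs, ge)
      strand <- sample(c("+", "-"), 1L)
      # layout in transcript orientation: [UTR exons/introns] utr5' guard
      # stop . CDS . utr3'; the guard stop sits in-frame just 5' of the ATG.
      cds_seq <- paste0("ATG",
                        paste(sample(.SENSE_CODONS, cds_len / 3L - 2L,
                                     replace = TRUE), collapse = ""),
                        sample(.STOPS, 1L))
      guard <- sample(.STOPS, 1L)
      if (strand == "+") {
        cs <- gs + utr5 + 3L                     # 3 nt guard before CDS
        ce <- cs + cds_len - 1L
        emb_start <- cs - 3L
        emb <- paste0(guard, cds_seq)
      } else {
        ce <- ge - utr5 - 3L
        cs <- ce - cds_len + 1L
        emb_start <- cs
        emb <- .revcomp(paste0(guard, cds_seq))  # guard lands 5' on - strand
      }
      substr(chrs[[ci]], emb_start, emb_start + nchar(emb) - 1L) <- emb
      gid <- sprintf("g%02d", g); tid <- sprintf("t%02d", g)
      add <- function(type, s, e, id = NULL, parent = NULL) {
        recs[[length(recs) + 1L]] <<- data.frame(
          seqid = chr_names[[ci]], type = type, start = s, end = e,
          strand = strand,
          attrs = paste(c(if (!is.null(id)) paste0("ID=", id),
                          if (!is.null(parent)) paste0("Parent=", parent)),
                        collapse = ";"),
          stringsAsFactors = FALSE)
      }
      add("gene", gs, ge, id = gid)
      add("mRNA", gs, ge, id = tid, parent = gid)
      # one exon contains the whole CDS; any extra exon is a short UTR exon
      # split off by an intron at the genomic end away from the CDS
      if (n_ex == 1L) {
        add("exon", gs, ge, parent = tid)
      } else if (strand == "+") {
        add("exon", gs, ge - intron[[1]] - 10L, parent = tid)
        add("exon", ge - 9L, ge, parent = tid)
      } else {
        add("exon", gs, gs + 9L, parent = tid)
        add("exon", gs + 10L + intron[[1]], ge, parent = tid)
      }
      add("CDS", cs, ce, id = paste0(tid, ".cds"), parent = tid)
    }
    dss2 <- Biostrings::DNAStringSet(chrs)
    names(dss2) <- chr_names
    Biostrings::writeXStringSet(dss2, genome, width = 80L)
    df <- do.call(rbind, recs)
    gr <- GenomicRanges::GRanges(
      seqnames = df$seqid,
      ranges = IRanges::IRanges(df$start, df$end),
      strand = df$strand, source = "ngsflow", type = df$type,
      score = ".", phase = ifelse(df$type == "CDS", "0", "."),
      attributes = df$attrs)
    write_gff3(gr, path)
  })
  invisible(path)
}

#' Simulate reads from a genome and annotation
#'
#' Draws reads either from within gene CDS regions (sense strand, fraction
#' \code{transcript_frac}) or uniformly from the genomic background (random
#' strand). Sequencing errors are i.i.d. substitutions at \code{error_rate};
#' base qualities follow a linear per-cycle decay
#' \code{Q(c) = 40 - 0.3 (c - 1)} plus Gaussian noise (sd 2), clipped to
#' [2, 40]. Writes a FASTQ, a SAM encoding the true alignments (CIGAR
#' \code{<len>M}, flag 0/16) and returns the truth table of read origins.
#'
#' @param genome FASTA path.
#' @param annotation GFF3 path from \code{\link{make_annotation}} (may be
#'   \code{NULL} for background-only reads).
#' @param n_reads number of reads.
#' @param read_len read length in nt.
#' @param error_rate substitution error probability per base.
#' @param seed RNG seed.
#' @param transcript_frac fraction of reads drawn from CDS regions.
#' @param out_prefix path prefix for \code{<prefix>.fastq},
#'   \code{<prefix>.sam} and \code{<prefix>.truth.tsv}.
#' @return list: \code{fastq}, \code{sam}, \code{truth} (data.frame
#'   \code{read_id}, \code{seqid}, \code{pos}, \code{strand}, \code{origin},
#'   \code{gene}) and \code{truth_path}.
#' @export
simulate_reads <- function(genome, annotation, n_reads = 1000L,
                           read_len = 50L, error_rate = 0, seed = 1L,
                           transcript_frac = 0.7,
                           out_prefix = tempfile()) {
  dss <- Biostrings::readDNAStringSet(genome)
  chrs <- as.character(dss)
  if (read_len > min(nchar(chrs)))
    stop("read_len exceeds the shortest chromosome", call. = FALSE)
  cds <- NULL
  if (!is.null(annotation)) {
    ann <- read_gff3(annotation)
    cds <- ann[S4Vectors::mcols(ann)$type == "CDS"]
    if (!length(cds)) cds <- NULL
  }
  fq <- paste0(out_prefix, ".fastq")
  sam <- paste0(out_prefix, ".sam")
  tt <- paste0(out_prefix, ".truth.tsv")
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrs), nchar(chrs)))
  if (n_reads == 0L) {
    writeLines(character(), fq)
    writeLines(header, sam)
    truth <- data.frame(read_id = character(), seqid = character(),
                        pos = integer(), strand = character(),
                        origin = character(), gene = character())
    write.table(truth, tt, sep = "\t", quote = FALSE, row.names = FALSE)
    return(list(fastq = fq, sam = sam, truth = truth, truth_path = tt))
  }
  res <- .with_seed(seed, {
    origin <- if (is.null(cds)) rep("background", n_reads) else
      ifelse(stats::runif(n_reads) < transcript_frac, "transcript",
             "background")
    seqid <- character(n_reads); pos <- integer(n_reads)
    strand <- character(n_reads); gene <- rep(NA_character_, n_reads)
    for (i in seq_len(n_reads)) {
      if (origin[i] == "transcript") {
        j <- sample(length(cds), 1L)
        cs <- BiocGenerics::start(cds)[j]; ce <- BiocGenerics::end(cds)[j]
        if (ce - cs + 1L < read_len) { origin[i] <- "background" }
        else {
          seqid[i] <- as.character(GenomicRanges::seqnames(cds))[j]
          pos[i] <- sample(cs:(ce - read_len + 1L), 1L)
          strand[i] <- as.character(BiocGenerics::strand(cds))[j]
          gene[i] <- S4Vectors::mcols(cds)$Parent[j]
        }
      }
      if (origin[i] == "background") {
        ci <- sample(length(chrs), 1L)
        seqid[i] <- names(chrs)[[ci]]
        pos[i] <- sample(nchar(chrs[[ci]]) - read_len + 1L, 1L)
        strand[i] <- sample(c("+", "-"), 1L)
      }
    }
    fwd <- substring(chrs[seqid], pos, pos + read_len - 1L)
    if (error_rate > 0) {
      fwd <- vapply(fwd, function(s) {
        b <- strsplit(s, "")[[1]]
        hit <- stats::runif(length(b)) < error_rate
        b[hit] <- vapply(b[hit], function(x)
          sample(setdiff(c("A", "C", "G", "T"), x), 1L), "")
        paste(b, collapse = "")
      }, "", USE.NAMES = FALSE)
    }
    read_seq <- ifelse(strand == "-", vapply(fwd, .revcomp, "",
                                             USE.NAMES = FALSE), fwd)
    q <- matrix(pmin(40, pmax(2, round(
      matrix(40 - 0.3 * (seq_len(read_len) - 1L), n_reads, read_len,
             byrow = TRUE) + stats::rnorm(n_reads * read_len, 0, 2)))),
      n_reads, read_len)
    quals <- apply(q, 1L, function(x) intToUtf8(x + 33L))
    list(origin = origin, seqid = seqid, pos = pos, strand = strand,
         gene = gene, fwd = fwd, read_seq = read_seq, quals = quals)
  })
  ids <- sprintf("read%06d", seq_len(n_reads))
  writeLines(as.vector(rbind(paste0("@", ids), res$read_seq, "+", res$quals)),
             fq)
  flag <- ifelse(res$strand == "-", 16L, 0L)
  # SAM stores SEQ/QUAL in reference-forward orientation
  sam_qual <- ifelse(res$strand == "-",
                     vapply(strsplit(res$quals, ""), function(x)
                       paste(rev(x), collapse = ""), ""), res$quals)
  writeLines(c(header,
               paste(ids, flag, res$seqid, res$pos, 60L,
                     paste0(read_len, "M"), "*", 0L, 0L, res$fwd, sam_qual,
                     sep = "\t")), sam)
  truth <- data.frame(read_id = ids, seqid = res$seqid, pos = res$pos,
                      strand = res$strand, origin = res$origin,
                      gene = res$gene, stringsAsFactors = FALSE)
  write.table(truth, tt, sep = "\t", quote = FALSE, row.names = FALSE)
  list(fastq = fq, sam = sam, truth = truth, truth_path = tt)
}

#' Simulate a differential-expression result table
#'
#' Produces per-gene logFC/FDR column pairs for each comparison, with a
#' configurable fraction of clearly regulated genes, for exercising
#' \code{\link{filter_degs}} and \code{\link{overlapper}}.
#'
#' @param genes gene identifiers.
#' @param comparisons character vector of comparison names (e.g.
#'   \code{"A-B"}; the hyphen is replaced by \code{"."} in column names).
#' @param frac_de fraction of genes regulated per comparison.
#' @param seed RNG seed.
#' @return data.frame with a \code{gene} column and one
#'   \code{<cmp>_logFC}/\code{<cmp>_FDR} pair per comparison.
#' @export
simulate_deg_table <- function(genes, comparisons, frac_de = 0.2, seed = 1L) {
  .with_seed(seed, {
    df <- data.frame(gene = genes, stringsAsFactors = FALSE)
    for (cmp in comparisons) {
      cname <- gsub("-", ".", cmp, fixed = TRUE)
      de <- stats::runif(length(genes)) < frac_de
      lfc <- stats::rnorm(length(genes), 0, 0.3)
      lfc[de] <- sample(c(-1, 1), sum(de), replace = TRUE) *
        stats::runif(sum(de), 1.5, 4)
      fdr <- stats::runif(length(genes), 0.05, 1)
      fdr[de] <- stats::runif(sum(de), 0, 0.01)
      df[[paste0(cname, "_logFC")]] <- round(lfc, 3)
      df[[paste0(cname, "_FDR")]] <- signif(fdr, 3)
    }
    df
  })
}
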