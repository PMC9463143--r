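#' @import GenomicRanges
#' @import IRanges
NULL

DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A", U = "A", N = "N")

comp_base <- function(x) unname(DNA_COMP[x])

normalize_base <- function(x) {
  x <- toupper(x)
  x[x == "U"] <- "T"
  x
}

#' Construct an alignment table
#'
#' One row per reported alignment of a small-RNA read. Coordinates are
#' 0-based half-open genomic positions of the (ungapped) alignment;
#' `five_prime_nt` is the nucleotide at the read's 5' end in read
#' orientation (U is stored as T), and `n_loci` is the number of
#' equally-best loci the read aligns to.
#'
#' @param read_id,chrom,start,end,strand,five_prime_nt,n_loci Per-alignment
#'   vectors (recycled where scalar).
#' @return data.frame of class `g22_alignments`.
#' @export
alignment_table <- function(read_id, chrom, start, end, strand,
                            five_prime_nt, n_loci = 1L) {
  df <- data.frame(read_id = as.character(read_id),
                   chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   five_prime_nt = normalize_base(as.character(five_prime_nt)),
                   n_loci = as.integer(n_loci),
                   stringsAsFactors = FALSE)
  df$length <- df$end - df$start
  if (nrow(df)) {
    stopifnot(all(df$start >= 0L), all(df$end > df$start),
              all(df$strand %in% c("+", "-")), all(df$n_loci >= 1L))
    bad <- tapply(df$n_loci, df$read_id, function(x) length(unique(x)) > 1L)
    if (any(bad))
      stop("inconsistent n_loci within read(s): ",
           paste(names(bad)[bad], collapse = ", "))
  }
  class(df) <- c("g22_alignments", "data.frame")
  df
}

#' Read aligned small-RNA reads (SAM/BAM or BED)
#'
#' SAM/BAM input is read through Rsamtools (`.sam` files are converted with
#' `asBam` on the fly); the 5' nucleotide is taken from the stored sequence,
#' reverse-complemented for minus-strand alignments so it always refers to
#' the read's own 5' end, and the multi-hit count comes from the `NH` tag
#' when present, otherwise from grouping alignments by read name.
#'
#' BED input is the package's BED6+2 dialect (columns 7 and 8 carry
#' `n_loci` and `five_prime_nt`); plain BED6 has no 5'-nt source and is
#' rejected.
#'
#' @param path `.sam`, `.bam` or `.bed` file.
#' @return A `g22_alignments` table (possibly 0-row for an empty file).
#' @export
read_alignments <- function(path) {
  fmt <- tolower(tools::file_ext(path))
  if (fmt == "bed") return(read_alignments_bed(path))
  if (!fmt %in% c("sam", "bam")) stop("unrecognized alignment format: ", path)
  bam <- path
  if (fmt == "sam")
    bam <- suppressMessages(Rsamtools::asBam(
      path, tempfile(), overwrite = TRUE, indexDestination = FALSE))
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "qwidth", "strand", "seq"),
    tag = "NH",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(x$qname)
  if (n == 0L)
    return(alignment_table(character(0), character(0), integer(0),
                           integer(0), character(0), character(0), integer(0)))
  seqs <- as.character(x$seq)
  if (any(!nzchar(seqs)) || any(seqs == "*"))
    stop("SAM/BAM records without sequence: no 5'-nt source")
  strand <- as.character(x$strand)
  fp <- ifelse(strand == "+",
               substr(seqs, 1L, 1L),
               comp_base(normalize_base(substr(seqs, nchar(seqs), nchar(seqs)))))
  nh <- x$tag$NH
  if (is.null(nh) || all(is.na(nh))) {
    nh <- as.integer(table(x$qname)[x$qname])
  } else if (anyNA(nh)) {
    stop("NH tag present but missing for some alignments")
  }
  alignment_table(x$qname, as.character(x$rname), x$pos - 1L,
                  x$pos - 1L + x$qwidth, strand, fp, nh)
}

read_alignments_bed <- function(path) {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0)
    return(alignment_table(character(0), character(0), integer(0),
                           integer(0), character(0), character(0), integer(0)))
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 8L)
    stop("alignment BED must be BED6+2 (n_loci, five_prime_nt): ",
         "no 5'-nt source in ", ncol(df), " columns")
  alignment_table(df[[4]], df[[1]], df[[2]], df[[3]], df[[6]], df[[8]], df[[7]])
}

#' Write alignments in the BED6+2 dialect
#'
#' @param aln A `g22_alignments` table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_alignments_bed <- function(aln, path) {
  bed <- data.frame(aln$chrom, aln$start, aln$end, aln$read_id, 0L,
                    aln$strand, aln$n_loci, aln$five_prime_nt)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write alignments as SAM
#'
#' Emits a minimal valid SAM file. Read sequences are reconstructed as the
#' 5' nucleotide followed by `A` filler (the generator does not model full
#' sequence content), stored in reference orientation, with the multi-hit
#' count in the `NH` tag.
#'
#' @param aln A `g22_alignments` table.
#' @param path Output file.
#' @param seqlengths Named integer vector of chromosome lengths for the
#'   `@SQ` header; inferred from alignment extents when omitted.
#' @return `path`, invisibly.
#' @export
write_alignments_sam <- function(aln, path, seqlengths = NULL) {
  if (is.null(seqlengths)) {
    if (nrow(aln)) {
      seqlengths <- tapply(aln$end, aln$chrom, max)
    } else seqlengths <- integer(0)
  }
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                   as.integer(seqlengths)))
  if (nrow(aln) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  len <- aln$end - aln$start
  read_seq <- paste0(aln$five_prime_nt, strrep("A", pmax(len - 1L, 0L)))
  stored <- ifelse(aln$strand == "+", read_seq, revcomp(read_seq))
  flag <- ifelse(aln$strand == "+", 0L, 16L)
  rec <- paste(aln$read_id, flag, aln$chrom, aln$start + 1L, 255L,
               paste0(len, "M"), "*", 0L, 0L, stored,
               strrep("I", len), paste0("NH:i:", aln$n_loci), sep = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(unname(DNA_COMP[strsplit(s, "", fixed = TRUE)[[1]]])),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
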