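#' Length-filter alignments and attach multimapper weights
#'
#' Keeps alignments of reads 17-40 nt long and attaches the weight
#' `1/n_loci`, so a read reported at several equally-best loci contributes
#' a total weight of at most one.
#'
#' @param aln A `g22_alignments` table.
#' @param min_len,max_len Length filter bounds (inclusive).
#' @return The filtered table with columns `aln_id` and `weight` added.
#' @export
filter_and_weight <- function(aln, min_len = 17L, max_len = 40L) {
  stopifnot(all(aln$n_loci >= 1L))
  out <- aln[aln$length >= min_len & aln$length <= max_len, , drop = FALSE]
  out$aln_id <- seq_len(nrow(out))
  out$weight <- 1 / out$n_loci
  rownames(out) <- NULL
  out
}

READ_CLASSES <- c("structural_sense", "mature_miRNA", "mature_piRNA",
                  "g22_antisense", "sense_feature", "other")

features_exon_granges <- function(features) {
  n_ex <- vapply(features$exon_starts, length, integer(1))
  GenomicRanges::GRanges(
    seqnames = rep(features$chrom, n_ex),
    ranges = IRanges::IRanges(
      start = unlist(features$exon_starts) + 1L,
      end = unlist(features$exon_ends)),
    strand = rep(features$strand, n_ex),
    feature_idx = rep(seq_len(nrow(features)), n_ex))
}

#' Classify weighted alignments against feature annotations
#'
#' Applies the class rules in fixed precedence order:
#' structural-RNA sense fragments, then mature miRNA / piRNA (sense reads
#' fully contained in the annotated locus, i.e. no overhang), then 22G-RNAs
#' (21-23 nt, 5' G, antisense to a protein-coding gene, pseudogene or
#' transposon), then generic sense overlap, then `other`. A read
#' contributes to every feature satisfying its winning rule. Antisense
#' requires at least 1 nt of overlap on the opposite strand; no minimum
#' overlap fraction is imposed.
#'
#' @param aln Output of [filter_and_weight()].
#' @param features A `g22_features` table.
#' @return data.frame of class `g22_classified`, one row per
#'   (alignment, assigned feature); unassigned alignments appear once with
#'   `feature_id = NA` and class `other`. Carries `features` as an
#'   attribute for downstream steps.
#' @export
classify_reads <- function(aln, features) {
  if (is.null(aln$aln_id)) aln <- filter_and_weight(aln)
  if (nrow(aln) == 0L) {
    out <- data.frame(aln_id = integer(0), read_id = character(0),
                      length = integer(0), five_prime_nt = character(0),
                      strand = character(0), weight = numeric(0),
                      read_class = character(0), feature_id = character(0),
                      orientation = character(0), start = integer(0),
                      end = integer(0), chrom = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("g22_classified", "data.frame")
    attr(out, "features") <- features
    return(out)
  }
  exon_gr <- features_exon_granges(features)
  aln_gr <- GenomicRanges::GRanges(
    aln$chrom, IRanges::IRanges(aln$start + 1L, aln$end), strand = aln$strand)
  hits <- GenomicRanges::findOverlaps(aln_gr, exon_gr, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  fi <- exon_gr$feature_idx[S4Vectors::subjectHits(hits)]
  # collapse multi-exon hits of the same (alignment, feature) pair
  key <- paste(qi, fi)
  dup <- duplicated(key)
  qi <- qi[!dup]; fi <- fi[!dup]

  f_bt <- features$biotype[fi]
  f_strand <- features$strand[fi]
  f_start <- features$start[fi]
  f_end <- features$end[fi]
  sense <- aln$strand[qi] == f_strand
  within <- aln$start[qi] >= f_start & aln$end[qi] <= f_end
  len <- aln$length[qi]
  fp <- aln$five_prime_nt[qi]

  prio <- rep(Inf, length(qi))
  prio[sense & f_bt %in% STRUCTURAL_BIOTYPES] <- 1
  prio[sense & within & f_bt == "miRNA"] <- 2
  prio[sense & within & f_bt == "piRNA"] <- 3
  prio[!sense & f_bt %in% G22_TARGET_BIOTYPES &
         len >= 21L & len <= 23L & fp == "G"] <- 4
  prio[is.infinite(prio) & sense] <- 5

  best <- rep(Inf, nrow(aln))
  agg <- tapply(prio, qi, min)
  best[as.integer(names(agg))] <- agg
  keep <- is.finite(prio) & prio == best[qi]

  cls_of_prio <- c("structural_sense", "mature_miRNA", "mature_piRNA",
                   "g22_antisense", "sense_feature")
  assigned <- data.frame(
    aln_id = aln$aln_id[qi[keep]],
    read_class = cls_of_prio[prio[keep]],
    feature_id = features$feature_id[fi[keep]],
    orientation = ifelse(sense[keep], "sense", "antisense"),
    stringsAsFactors = FALSE)
  un <- setdiff(aln$aln_id, assigned$aln_id)
  if (length(un))
    assigned <- rbind(assigned, data.frame(
      aln_id = un, read_class = "other", feature_id = NA_character_,
      orientation = NA_character_, stringsAsFactors = FALSE))
  cols <- c("aln_id", "read_id", "chrom", "start", "end", "strand",
            "length", "five_prime_nt", "weight")
  out <- cbind(aln[match(assigned$aln_id, aln$aln_id), cols, drop = FALSE],
               assigned[c("read_class", "feature_id", "orientation")])
  out <- out[order(out$aln_id, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("g22_classified", "data.frame")
  attr(out, "features") <- features
  out
}

#' Aggregate classified reads into a weighted count table
#'
#' Each read contributes its weight to every feature it was assigned under
#' its winning class, split by orientation. Library totals follow the
#' normalization frame of the study: `total_mapped` is the weighted number
#' of distinct mapped reads, `structural_sense` the weighted reads
#' classified as structural-RNA fragments, and `denominator` their
#' difference (the RPM denominator). `protein_coding_total` is the weighted
#' sense read count on protein-coding genes, the RPKM denominator for
#' poly(A)-selected mRNA libraries.
#'
#' @param classified Output of [classify_reads()].
#' @param features `g22_features` table (defaults to the attribute stored
#'   on `classified`).
#' @param sample Sample label stored on the result.
#' @return data.frame of class `g22_count_table` with columns
#'   `feature_id`, `read_class`, `orientation`, `count`, and attributes
#'   `totals` (list) and `sample`.
#' @export
build_count_table <- function(classified, features = attr(classified, "features"),
                              sample = "") {
  if (!is.null(classified$feature_id)) {
    unknown <- stats::na.omit(setdiff(classified$feature_id, features$feature_id))
    if (length(unknown))
      stop("classified reads reference unknown feature(s): ",
           paste(utils::head(unknown, 5), collapse = ", "))
  }
  dt <- data.table::as.data.table(classified)
  per_aln <- dt[!duplicated(aln_id)]
  total_mapped <- sum(per_aln$weight)
  structural <- sum(per_aln$weight[per_aln$read_class == "structural_sense"])
  denom <- total_mapped - structural
  assigned <- dt[!is.na(feature_id),
                 .(count = sum(weight)),
                 by = .(feature_id, read_class, orientation)]
  pc <- features$feature_id[features$biotype == "protein_coding"]
  pc_total <- sum(assigned$count[assigned$feature_id %in% pc &
                                   assigned$orientation == "sense"])
  out <- as.data.frame(assigned)
  out <- out[order(out$feature_id, out$read_class, out$orientation), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("g22_count_table", "data.frame")
  attr(out, "totals") <- list(total_mapped = total_mapped,
                              structural_sense = structural,
                              denominator = denom,
                              protein_coding_total = pc_total,
                              degenerate = denom <= 0)
  attr(out, "sample") <- sample
  attr(out, "features") <- features
  if (denom <= 0 && total_mapped > 0)
    warning("degenerate library: all mapped reads are structural")
  out
}

#' Construct a count table directly from per-gene counts
#'
#' Builds a `g22_count_table` from already-aggregated per-feature weighted
#' counts (one class/orientation), with explicit library totals. Used by the
#' count-level simulation path and by table readers.
#'
#' @param feature_id,count Per-feature ids and weighted counts.
#' @param totals List with `total_mapped`, `structural_sense`; the RPM
#'   `denominator` is derived. `protein_coding_total` optional.
#' @param read_class,orientation Class/orientation labels for all rows.
#' @param sample Sample label.
#' @return `g22_count_table`.
#' @export
count_table <- function(feature_id, count, totals,
                        read_class = "g22_antisense",
                        orientation = "antisense", sample = "") {
  out <- data.frame(feature_id = as.character(feature_id),
                    read_class = read_class, orientation = orientation,
                    count = as.numeric(count), stringsAsFactors = FALSE)
  totals$denominator <- totals$total_mapped - totals$structural_sense
  if (is.null(totals$protein_coding_total))
    totals$protein_coding_total <- NA_real_
  totals$degenerate <- totals$denominator <= 0
  class(out) <- c("g22_count_table", "data.frame")
  attr(out, "totals") <- totals
  attr(out, "sample") <- sample
  out
}

#' Normalize a count table (RPM or RPKM)
#'
#' Small-RNA mode divides weighted counts by the library total minus
#' structural-RNA sense reads, times 1e6 (RPM). mRNA mode computes RPKM:
#' count * 1e6 / (kb spliced length * protein-coding-mapped total).
#'
#' @param table A `g22_count_table`.
#' @param mode `"srna_rpm"` or `"mrna_rpkm"`.
#' @param features Feature table (needed for RPKM lengths; defaults to the
#'   attribute on `table`).
#' @return data.frame of class `g22_normalized_table`: the count table with
#'   an `rpm` (or `rpkm`) column; denominators recorded in the `totals`
#'   attribute.
#' @export
normalize_counts <- function(table, mode = c("srna_rpm", "mrna_rpkm"),
                             features = attr(table, "features")) {
  mode <- match.arg(mode)
  totals <- attr(table, "totals")
  out <- as.data.frame(table)
  if (mode == "srna_rpm") {
    if (is.null(totals$denominator) || totals$denominator <= 0)
      stop("zero RPM denominator (library degenerate)")
    out$rpm <- out$count * 1e6 / totals$denominator
  } else {
    if (is.null(totals$protein_coding_total) ||
        is.na(totals$protein_coding_total) || totals$protein_coding_total <= 0)
      stop("zero protein-coding total: cannot compute RPKM")
    if (is.null(features)) stop("features required for RPKM lengths")
    len <- features$spliced_length[match(out$feature_id, features$feature_id)]
    if (anyNA(len)) stop("missing spliced length for some features")
    out$rpkm <- out$count * 1e6 / ((len / 1000) * totals$protein_coding_total)
  }
  class(out) <- c("g22_normalized_table", "g22_count_table", "data.frame")
  attr(out, "totals") <- totals
  attr(out, "sample") <- attr(table, "sample")
  attr(out, "mode") <- mode
  out
}

#' Extract a named per-gene value vector from a table
#'
#' Convenience accessor: per-gene weighted count or RPM of one read class /
#' orientation, zero-filled over `gene_set`.
#'
#' @param table A `g22_count_table` or `g22_normalized_table`.
#' @param gene_set Character vector of feature ids.
#' @param value `"count"`, `"rpm"` or `"rpkm"`.
#' @param read_class,orientation Class/orientation selector.
#' @return Named numeric vector over `gene_set`.
#' @export
gene_values <- function(table, gene_set, value = "count",
                        read_class = "g22_antisense",
                        orientation = "antisense") {
  sel <- table$read_class == read_class &
    (is.na(orientation) | table$orientation == orientation)
  sub <- table[sel, , drop = FALSE]
  v <- stats::setNames(rep(0, length(gene_set)), gene_set)
  idx <- match(sub$feature_id, gene_set)
  ok <- !is.na(idx)
  v[idx[ok]] <- sub[[value]][ok]
  v
}

#' Weighted read-length histogram
#'
#' Weighted counts of reads per length 17..40 for one read class (or all
#' classes). Each distinct alignment contributes once with its weight, so
#' the histogram total equals the weighted read total of the class.
#'
#' @param classified Output of [classify_reads()].
#' @param read_class Class filter; `NULL` for all reads.
#' @param lengths Histogram support.
#' @return Named numeric vector over `lengths`.
#' @export
length_histogram <- function(classified, read_class = NULL,
                             lengths = 17:40) {
  dt <- classified[!duplicated(classified$aln_id), , drop = FALSE]
  if (!is.null(read_class)) dt <- dt[dt$read_class == read_class, , drop = FALSE]
  h <- stats::setNames(rep(0, length(lengths)), lengths)
  if (nrow(dt)) {
    agg <- tapply(dt$weight, factor(dt$length, levels = lengths), sum)
    agg[is.na(agg)] <- 0
    h[] <- agg
  }
  h
}
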