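#' Controlled biotype vocabulary
#'
#' The set of feature biotypes the pipeline understands. Reads are classified
#' against these: rRNA/tRNA/snoRNA are structural, miRNA/piRNA loci define
#' mature small-RNA boundaries, and protein-coding genes, pseudogenes and
#' transposons are the substrates of antisense 22G-RNA targeting.
#'
#' @return Character vector of valid biotype tokens.
#' @export
g22_biotypes <- function() {
  c("protein_coding", "pseudogene", "transposon", "rRNA", "tRNA",
    "snoRNA", "miRNA", "piRNA", "simple_repeat", "satellite")
}

STRUCTURAL_BIOTYPES <- c("rRNA", "tRNA", "snoRNA")
G22_TARGET_BIOTYPES <- c("protein_coding", "pseudogene", "transposon")

#' Default GFF3 type/biotype token map
#'
#' Maps tokens found in the GFF3 `type` column or `biotype` attribute to the
#' controlled vocabulary of [g22_biotypes()]. Identity mappings for the
#' vocabulary itself plus a few common aliases.
#'
#' @return Named character vector (token -> biotype).
#' @export
default_biotype_map <- function() {
  v <- g22_biotypes()
  c(stats::setNames(v, v),
    protein_coding_gene = "protein_coding",
    mRNA = "protein_coding",
    transposable_element = "transposon",
    piRNA_gene = "piRNA",
    miRNA_gene = "miRNA")
}

#' Construct a feature table
#'
#' Internal constructor/validator for the exon-resolved feature table used
#' throughout the pipeline. All coordinates are 0-based half-open; exon
#' intervals of one feature must be sorted, disjoint and on one chromosome
#' and strand.
#'
#' @param feature_id Unique feature names.
#' @param chrom Chromosome per feature.
#' @param strand "+" or "-" per feature.
#' @param biotype Biotype per feature (see [g22_biotypes()]).
#' @param exon_starts,exon_ends Lists of integer vectors (0-based half-open).
#' @return A `data.frame` of class `g22_features` with one row per feature
#'   and list-columns `exon_starts`/`exon_ends`, plus `start`, `end` (the
#'   genomic span) and `spliced_length`.
#' @export
feature_table <- function(feature_id, chrom, strand, biotype,
                          exon_starts, exon_ends) {
  stopifnot(length(feature_id) == length(chrom),
            length(chrom) == length(strand),
            length(strand) == length(biotype),
            length(exon_starts) == length(feature_id),
            length(exon_ends) == length(feature_id))
  if (anyDuplicated(feature_id))
    stop("duplicate feature_id: ",
         paste(unique(feature_id[duplicated(feature_id)]), collapse = ", "))
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  bad <- !biotype %in% g22_biotypes()
  if (any(bad))
    stop("unknown biotype: ", paste(unique(biotype[bad]), collapse = ", "))
  exon_starts <- lapply(exon_starts, as.integer)
  exon_ends <- lapply(exon_ends, as.integer)
  for (i in seq_along(feature_id)) {
    s <- exon_starts[[i]]; e <- exon_ends[[i]]
    if (length(s) == 0L || length(s) != length(e))
      stop("feature ", feature_id[i], ": malformed exon structure")
    if (any(s >= e) || any(s < 0L))
      stop("feature ", feature_id[i], ": invalid exon interval")
    if (is.unsorted(s, strictly = TRUE) && length(s) > 1L)
      stop("feature ", feature_id[i], ": exons not sorted")
    if (length(s) > 1L && any(s[-1L] < e[-length(e)]))
      stop("feature ", feature_id[i], ": overlapping exons")
  }
  df <- data.frame(
    feature_id = as.character(feature_id),
    chrom = as.character(chrom),
    strand = as.character(strand),
    biotype = as.character(biotype),
    start = vapply(exon_starts, function(x) x[1L], integer(1)),
    end = vapply(exon_ends, function(x) x[length(x)], integer(1)),
    spliced_length = vapply(seq_along(exon_starts), function(i)
      sum(exon_ends[[i]] - exon_starts[[i]]), integer(1)),
    stringsAsFactors = FALSE)
  df$exon_starts <- exon_starts
  df$exon_ends <- exon_ends
  class(df) <- c("g22_features", "data.frame")
  df
}

#' Read genome feature annotations (GFF3 or BED12)
#'
#' Parses feature annotations into the internal exon-resolved feature table.
#' GFF3 1-based inclusive coordinates are converted to 0-based half-open at
#' this boundary; BED coordinates are already 0-based half-open. For GFF3,
#' the biotype is taken from the `biotype` attribute when present, otherwise
#' from the `type` column, and resolved through `biotype_map`; exon child
#' records (`type == "exon"` with a `Parent`) refine the parent's intervals.
#' BED12 block structure gives the exon intervals; since BED carries no
#' biotype, `biotype_map` may name feature ids directly, with
#' `default_biotype` as fallback.
#'
#' Records whose biotype token cannot be resolved are skipped and reported in
#' the `skipped` attribute of the result.
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED (`.bed`) file.
#' @param biotype_map Named character vector mapping tokens (GFF3) or
#'   feature ids (BED12) to biotypes.
#' @param default_biotype Fallback biotype for BED records absent from
#'   `biotype_map` (default `NA` = skip such records).
#' @return A `g22_features` table; attribute `skipped` holds the ids of
#'   records dropped for unknown biotype.
#' @export
read_annotations <- function(path, biotype_map = default_biotype_map(),
                             default_biotype = NA_character_) {
  fmt <- tolower(tools::file_ext(path))
  if (fmt %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "gff3")
    read_annotations_gff(gr, biotype_map)
  } else if (fmt == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    read_annotations_bed12(gr, biotype_map, default_biotype)
  } else {
    stop("unrecognized annotation format: ", path)
  }
}

read_annotations_gff <- function(gr, biotype_map) {
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  parent <- if ("Parent" %in% names(meta))
    vapply(meta$Parent, function(p) if (length(p)) as.character(p[1]) else NA_character_,
           character(1)) else rep(NA_character_, length(gr))
  is_exon <- type == "exon" & !is.na(parent)
  feat <- gr[!is_exon]
  fmeta <- S4Vectors::mcols(feat)
  ids <- if ("ID" %in% names(fmeta)) as.character(fmeta$ID) else fmeta$Name
  if (is.null(ids) || anyNA(ids)) stop("GFF3 feature records must carry an ID")
  if (anyDuplicated(ids))
    stop("duplicate feature_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  token <- if ("biotype" %in% names(fmeta) )
    ifelse(is.na(fmeta$biotype), as.character(fmeta$type), as.character(fmeta$biotype))
  else as.character(fmeta$type)
  biotype <- unname(biotype_map[token])
  keep <- !is.na(biotype)
  skipped <- ids[!keep]
  if (length(skipped))
    message(length(skipped), " annotation record(s) skipped (unknown biotype)")
  feat <- feat[keep]; ids <- ids[keep]; biotype <- biotype[keep]
  # GFF3 (1-based inclusive) -> 0-based half-open
  f_start <- GenomicRanges::start(feat) - 1L
  f_end <- GenomicRanges::end(feat)
  exon_starts <- as.list(f_start)
  exon_ends <- as.list(f_end)
  if (any(is_exon)) {
    ex <- gr[is_exon]
    ep <- parent[is_exon]
    idx <- match(ep, ids)
    for (i in which(!is.na(idx))) {
      j <- idx[i]
      exon_starts[[j]] <- c(exon_starts[[j]], GenomicRanges::start(ex)[i] - 1L)
      exon_ends[[j]] <- c(exon_ends[[j]], GenomicRanges::end(ex)[i])
    }
    # features with exon children: drop the span placeholder, keep sorted exons
    has_kids <- ids %in% ep
    for (j in which(has_kids)) {
      s <- exon_starts[[j]][-1L]; e <- exon_ends[[j]][-1L]
      o <- order(s)
      exon_starts[[j]] <- s[o]; exon_ends[[j]] <- e[o]
    }
  }
  out <- feature_table(ids, as.character(GenomicRanges::seqnames(feat)),
                       as.character(GenomicRanges::strand(feat)),
                       biotype, exon_starts, exon_ends)
  attr(out, "skipped") <- skipped
  out
}

read_annotations_bed12 <- function(gr, biotype_map, default_biotype) {
  ids <- S4Vectors::mcols(gr)$name
  if (is.null(ids)) stop("BED annotation must carry feature names")
  if (anyDuplicated(ids))
    stop("duplicate feature_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  biotype <- unname(biotype_map[ids])
  biotype[is.na(biotype)] <- default_biotype
  keep <- !is.na(biotype)
  skipped <- ids[!keep]
  if (length(skipped))
    message(length(skipped), " annotation record(s) skipped (unknown biotype)")
  gr2 <- gr[keep]; ids <- ids[keep]; biotype <- biotype[keep]
  blocks <- S4Vectors::mcols(gr2)$blocks
  exon_starts <- vector("list", length(gr2))
  exon_ends <- vector("list", length(gr2))
  for (i in seq_along(gr2)) {
    if (!is.null(blocks) && length(blocks[[i]])) {
      b <- blocks[[i]]  # block coords relative, 1-based within feature
      exon_starts[[i]] <- GenomicRanges::start(gr2)[i] - 1L + (IRanges::start(b) - 1L)
      exon_ends[[i]] <- GenomicRanges::start(gr2)[i] - 1L + IRanges::end(b)
    } else {
      exon_starts[[i]] <- GenomicRanges::start(gr2)[i] - 1L
      exon_ends[[i]] <- GenomicRanges::end(gr2)[i]
    }
  }
  out <- feature_table(ids, as.character(GenomicRanges::seqnames(gr2)),
                       as.character(GenomicRanges::strand(gr2)),
                       biotype, exon_starts, exon_ends)
  attr(out, "skipped") <- skipped
  out
}

#' Write annotations as GFF3
#'
#' Inverse of [read_annotations()] for the GFF3 dialect: one record per
#' feature with `ID` and `biotype` attributes, plus `exon` child records for
#' multi-exon features. Internal 0-based half-open coordinates are converted
#' back to 1-based inclusive.
#'
#' @param features A `g22_features` table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_annotations_gff <- function(features, path) {
  lines <- character(0)
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    lines <- c(lines, paste(f$chrom, "g22pipe", "gene", f$start + 1L, f$end,
                            ".", f$strand, ".",
                            sprintf("ID=%s;biotype=%s", f$feature_id, f$biotype),
                            sep = "\t"))
    es <- f$exon_starts[[1]]; ee <- f$exon_ends[[1]]
    if (length(es) > 1L) {
      for (j in seq_along(es)) {
        lines <- c(lines, paste(f$chrom, "g22pipe", "exon", es[j] + 1L, ee[j],
                                ".", f$strand, ".",
                                sprintf("ID=%s.e%d;Parent=%s", f$feature_id, j,
                                        f$feature_id),
                                sep = "\t"))
      }
    }
  }
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read piRNA target sites
#'
#' Sites are carried as a BED6 file of genomic site locations (name =
#' piRNA id) paired with a TSV giving, per site, the targeted feature and
#' the transcript-coordinate anchor (the position paired to piRNA
#' nucleotide 10). The TSV is the coordinate authority used by profile
#' windows; the BED is genomic bookkeeping.
#'
#' @param tsv_path TSV with columns `piRNA_id`, `target_feature_id`, `anchor`.
#' @param features Optional `g22_features` table for anchor validation.
#' @return data.frame with columns `piRNA_id`, `target_feature_id`, `anchor`.
#' @export
read_target_sites <- function(tsv_path, features = NULL) {
  df <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  need <- c("piRNA_id", "target_feature_id", "anchor")
  if (!all(need %in% names(df)))
    stop("target-site TSV must have columns: ", paste(need, collapse = ", "))
  df$anchor <- as.integer(df$anchor)
  if (!is.null(features)) {
    len <- features$spliced_length[match(df$target_feature_id, features$feature_id)]
    bad <- is.na(len) | df$anchor < 0L | df$anchor >= len
    if (any(bad))
      stop("invalid target-site anchors for: ",
           paste(df$piRNA_id[bad], collapse = ", "))
  }
  df[need]
}

#' Write piRNA target sites (TSV + BED6)
#'
#' @param sites data.frame with `piRNA_id`, `target_feature_id`, `anchor`
#'   (and optionally genomic columns `chrom`, `start`, `end`, `strand`).
#' @param tsv_path Output TSV path.
#' @param bed_path Optional output BED6 path (requires genomic columns).
#' @return `tsv_path`, invisibly.
#' @export
write_target_sites <- function(sites, tsv_path, bed_path = NULL) {
  utils::write.table(sites[c("piRNA_id", "target_feature_id", "anchor")],
                     tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bed_path)) {
    stopifnot(all(c("chrom", "start", "end", "strand") %in% names(sites)))
    bed <- data.frame(sites$chrom, sites$start, sites$end, sites$piRNA_id,
                      0L, sites$strand)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(tsv_path)
}
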