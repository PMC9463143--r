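#' Map genomic alignment intervals to spliced transcript intervals
#'
#' Internal: given reads overlapping one feature, returns the covered
#' transcript-coordinate intervals (0-based half-open, 5'->3' of the
#' annotated mRNA; minus-strand features are flipped). Read portions
#' falling into introns or outside the feature are clipped away.
#' @noRd
transcript_intervals <- function(starts, ends, feature) {
  es <- feature$exon_starts[[1]]; ee <- feature$exon_ends[[1]]
  L <- feature$spliced_length
  offs <- cumsum(c(0L, (ee - es)[-length(es)]))
  out_s <- integer(0); out_e <- integer(0); out_i <- integer(0)
  for (j in seq_along(es)) {
    ov_s <- pmax(starts, es[j]); ov_e <- pmin(ends, ee[j])
    hit <- which(ov_s < ov_e)
    if (!length(hit)) next
    ts <- offs[j] + (ov_s[hit] - es[j])
    te <- offs[j] + (ov_e[hit] - es[j])
    if (feature$strand == "-") {
      tmp <- L - te
      te <- L - ts
      ts <- tmp
    }
    out_s <- c(out_s, ts); out_e <- c(out_e, te); out_i <- c(out_i, hit)
  }
  list(start = out_s, end = out_e, read = out_i)
}

#' Per-base normalized 22G depth along one transcript
#'
#' Builds the depth track of a feature from its classified antisense
#' 22G-RNA reads: every spliced transcript position covered by a read
#' receives that read's RPM-normalized weight (coverage counting, not
#' 5'-end counting). Positions run 5'->3' of the annotated mRNA.
#'
#' @param classified Output of [classify_reads()] (rows assigned to the
#'   feature with class `g22_antisense` are used).
#' @param feature One-row subset of a `g22_features` table.
#' @param denominator RPM denominator of the library (weighted mapped reads
#'   minus structural).
#' @return Numeric vector of length `spliced_length` (class `g22_depth`),
#'   with the feature id and total mass as attributes.
#' @export
per_base_depth <- function(classified, feature, denominator) {
  stopifnot(nrow(feature) == 1L, denominator > 0)
  sel <- !is.na(classified$feature_id) &
    classified$feature_id == feature$feature_id &
    classified$read_class == "g22_antisense"
  sub <- classified[sel, , drop = FALSE]
  L <- feature$spliced_length
  track <- numeric(L)
  if (nrow(sub)) {
    ti <- transcript_intervals(sub$start, sub$end, feature)
    w <- sub$weight[ti$read] * 1e6 / denominator
    # difference-array accumulation
    d <- numeric(L + 1L)
    for (i in seq_along(ti$start)) {
      d[ti$start[i] + 1L] <- d[ti$start[i] + 1L] + w[i]
      d[ti$end[i] + 1L] <- d[ti$end[i] + 1L] - w[i]
    }
    track <- cumsum(d[seq_len(L)])
  }
  structure(track, class = "g22_depth",
            feature_id = feature$feature_id, total = sum(track))
}

#' Depth tracks for a set of genes
#'
#' @param classified Output of [classify_reads()].
#' @param features `g22_features` table.
#' @param gene_set Feature ids to profile.
#' @param denominator RPM denominator of the library.
#' @return Named list of depth tracks.
#' @export
depth_tracks <- function(classified, features, gene_set, denominator) {
  idx <- match(gene_set, features$feature_id)
  if (anyNA(idx)) stop("unknown gene(s) in gene_set")
  out <- lapply(idx, function(i)
    per_base_depth(classified, features[i, , drop = FALSE], denominator))
  stats::setNames(out, gene_set)
}

#' 100-bin metagene profile
#'
#' Rescales every transcript to `n_bins` bins by assigning position p of a
#' length-L transcript to bin `floor(p * n_bins / L)` and summing depth
#' within bins, then sums bins across genes. The floor rule conserves mass
#' exactly for any transcript length.
#'
#' @param tracks Named list of depth tracks (from [depth_tracks()]).
#' @param n_bins Number of bins (default 100).
#' @return list of class `g22_metagene`: `profile` (length `n_bins`),
#'   `n_features`, `total`.
#' @export
metagene_profile <- function(tracks, n_bins = 100L) {
  if (length(tracks) == 0L) stop("empty gene set")
  prof <- numeric(n_bins)
  for (tr in tracks) {
    L <- length(tr)
    stopifnot(L >= 1L)
    bins <- floor((seq_len(L) - 1L) * n_bins / L)
    agg <- rowsum(as.numeric(tr), bins)
    part <- numeric(n_bins)
    part[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
    prof <- prof + part
  }
  structure(list(profile = prof, n_features = length(tracks),
                 total = sum(vapply(tracks, sum, numeric(1)))),
            class = "g22_metagene")
}

#' 3'-end targeting enrichment of one transcript
#'
#' Fraction of a transcript's 22G depth mass falling in its last 15%
#' (`ceiling(0.15 * L)` positions), classified as `non_enriched`
#' (<= 0.15), `medium` ((0.15, 0.30]) or `high` (> 0.30). The class
#' boundaries follow the published 15% / 16-30% / >30% anchors, closed so
#' that classification is total.
#'
#' @param track A depth track.
#' @param tail_fraction_cutoff Tail length as a fraction of the transcript
#'   (default 0.15).
#' @return list: `feature_id`, `tail_fraction`, `class`; `NA` fraction and
#'   class `"missing"` for a zero-mass track.
#' @export
tail_enrichment <- function(track, tail_fraction_cutoff = 0.15) {
  L <- length(track)
  total <- sum(track)
  if (total <= 0)
    return(list(feature_id = attr(track, "feature_id"),
                tail_fraction = NA_real_, class = "missing"))
  tail_len <- ceiling(tail_fraction_cutoff * L)
  frac <- sum(track[(L - tail_len + 1L):L]) / total
  cls <- if (frac <= 0.15) "non_enriched" else if (frac <= 0.30) "medium" else "high"
  list(feature_id = attr(track, "feature_id"), tail_fraction = frac,
       class = cls)
}

#' 3'-end enrichment table for a set of tracks
#'
#' @param tracks Named list of depth tracks.
#' @inheritParams tail_enrichment
#' @return data.frame with `feature_id`, `tail_fraction`, `class`.
#' @export
tail_enrichment_table <- function(tracks, tail_fraction_cutoff = 0.15) {
  rows <- lapply(tracks, tail_enrichment, tail_fraction_cutoff)
  data.frame(feature_id = vapply(rows, `[[`, character(1), "feature_id"),
             tail_fraction = vapply(rows, `[[`, numeric(1), "tail_fraction"),
             class = vapply(rows, `[[`, character(1), "class"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' piRNA-target-site-centered density window
#'
#' For each target site, takes the 100-nt window of transcript positions
#' anchor-`halfwidth` .. anchor+`halfwidth`-1 around the position paired to
#' piRNA nucleotide 10, and averages the normalized depth per relative
#' position over all sites. Window positions falling outside a transcript
#' are excluded from that position's mean (not zero-filled).
#'
#' @param tracks Named list of depth tracks (names = feature ids).
#' @param sites data.frame with `piRNA_id`, `target_feature_id`, `anchor`.
#' @param halfwidth Window half-width (default 50 -> 100 positions).
#' @return list of class `g22_site_profile`: `position` (-halfwidth ..
#'   halfwidth-1), `mean_depth`, `n_sites`, `n_at_position`.
#' @export
site_window_profile <- function(tracks, sites, halfwidth = 50L) {
  sites <- sites[sites$target_feature_id %in% names(tracks), , drop = FALSE]
  if (nrow(sites) == 0L) stop("no usable target sites")
  offs <- seq(-halfwidth, halfwidth - 1L)
  acc <- numeric(length(offs))
  cnt <- integer(length(offs))
  for (i in seq_len(nrow(sites))) {
    tr <- tracks[[sites$target_feature_id[i]]]
    pos <- sites$anchor[i] + offs
    ok <- pos >= 0L & pos < length(tr)
    acc[ok] <- acc[ok] + tr[pos[ok] + 1L]
    cnt[ok] <- cnt[ok] + 1L
  }
  mean_depth <- ifelse(cnt > 0L, acc / cnt, NA_real_)
  structure(list(position = offs, mean_depth = mean_depth,
                 n_sites = nrow(sites), n_at_position = cnt),
            class = "g22_site_profile")
}
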