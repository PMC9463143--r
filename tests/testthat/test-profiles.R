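make_track <- function(values, id = "g") {
  structure(as.numeric(values), class = "g22_depth", feature_id = id,
            total = sum(values))
}

test_that("per-base depth adds read coverage in transcript coordinates", {
  f <- feature_table("g", "chr1", "+", "protein_coding",
                     list(0L), list(100L))
  aln <- alignment_table(c("r1", "r2"), "chr1", c(10L, 20L), c(32L, 42L),
                         "-", "G", 1L)
  cls <- classify_reads(filter_and_weight(aln), f)
  tr <- per_base_depth(cls, f, denominator = 1e6)
  expect_equal(sum(tr > 0), length(union(11:32, 21:42)))
  expect_equal(unname(tr[11]), 1)      # single read coverage, RPM weight 1
  expect_equal(unname(tr[25]), 2)      # overlap of both reads adds
  expect_equal(length(tr), 100L)
  # no reads -> all-zero track
  f2 <- feature_table("h", "chr9", "+", "protein_coding",
                      list(0L), list(50L))
  tr0 <- per_base_depth(cls, f2, 1e6)
  expect_equal(sum(tr0), 0)
})

test_that("minus-strand and spliced features map depth 5'->3' of the mRNA", {
  # two-exon minus-strand gene: transcript position 0 is the rightmost base
  f <- feature_table("g", "chr1", "-", "protein_coding",
                     list(c(100L, 300L)), list(c(200L, 400L)))
  aln <- alignment_table("r1", "chr1", 378L, 400L, "+", "G", 1L)
  cls <- classify_reads(filter_and_weight(aln), f)
  tr <- per_base_depth(cls, f, 1e6)
  expect_equal(which(tr > 0), 1:22)  # 5' end of the transcript
  # intron-spanning portions are clipped
  aln2 <- alignment_table("r2", "chr1", 190L, 212L, "+", "G", 1L)
  cls2 <- classify_reads(filter_and_weight(aln2), f)
  tr2 <- per_base_depth(cls2, f, 1e6)
  expect_equal(sum(tr2 > 0), 10L)  # only the 10 exonic bases count
})

test_that("metagene binning is exact for divisible lengths", {
  mg <- metagene_profile(list(make_track(rep(1, 1000))))
  expect_equal(mg$profile, rep(10, 100))
  expect_error(metagene_profile(list()), "empty")
})

test_that("metagene conserves mass and matches the brute-force oracle", {
  set.seed(42)
  for (L in c(1L, 7L, 99L, 100L, 150L, 1001L, sample(1:5000, 6))) {
    tr <- make_track(stats::rpois(L, 3) * 0.37)
    mg <- metagene_profile(list(tr))
    expect_equal(sum(mg$profile), sum(tr), tolerance = 1e-9)
    expect_equal(mg$profile, oracle_metagene(as.numeric(tr)))
  }
  # multi-gene aggregation sums per-gene profiles
  t1 <- make_track(stats::rpois(150, 2)); t2 <- make_track(stats::rpois(77, 2))
  mg <- metagene_profile(list(t1, t2))
  expect_equal(mg$profile, oracle_metagene(as.numeric(t1)) +
                 oracle_metagene(as.numeric(t2)))
  expect_equal(mg$n_features, 2L)
})

test_that("depth concentrated in the last 10% lands in bins 90-99", {
  v <- numeric(730); v[658:730] <- 1  # last 10% of a 730-nt transcript
  mg <- metagene_profile(list(make_track(v)))
  expect_gte(sum(mg$profile[91:100]) / sum(mg$profile), 0.99)
})

test_that("3'-tail classes follow the published boundaries", {
  mk <- function(frac, L = 1000L) {
    tailL <- ceiling(0.15 * L)
    v <- numeric(L)
    v[seq_len(L - tailL)] <- (1 - frac) / (L - tailL)
    v[(L - tailL + 1):L] <- frac / tailL
    make_track(v)
  }
  expect_equal(tail_enrichment(mk(0.10))$class, "non_enriched")
  expect_equal(tail_enrichment(mk(0.20))$class, "medium")
  expect_equal(tail_enrichment(mk(0.35))$class, "high")
  # uniform depth gives tail fraction == ceil(0.15 L)/L -> non_enriched
  u <- tail_enrichment(make_track(rep(1, 1000)))
  expect_equal(u$tail_fraction, 0.15)
  expect_equal(u$class, "non_enriched")
  z <- tail_enrichment(make_track(numeric(10)))
  expect_equal(z$class, "missing")
  expect_true(is.na(z$tail_fraction))
})

test_that("tail classifier recovers planted tail weights", {
  truth <- build_truth(sim_config(tau_csr = 0.40, tau_default = 0.10,
                                  tau_enhanced = 0.40, bump_beta = 0,
                                  n_duplicated_pairs = 0L), seed = 19)
  spec <- sample_spec("wildtype", "total", 3e5, 91)
  aln <- simulate_srna_library(truth, spec)
  cls <- classify_reads(filter_and_weight(aln), truth$features)
  denom <- attr(build_count_table(cls, truth$features), "totals")$denominator
  mu <- expected_counts(truth, spec)
  cm <- truth$classmap
  csr <- cm$feature_id[cm$target_class == "CSR1"]
  other <- cm$feature_id[cm$target_class == "none"]
  hi <- intersect(csr, names(mu)[mu >= 100])
  lo <- intersect(other, names(mu)[mu >= 100])
  te <- tail_enrichment_table(
    depth_tracks(cls, truth$features, c(hi, lo), denom))
  expect_gte(mean(te$class[te$feature_id %in% hi] == "high"), 0.95)
  expect_gte(mean(te$class[te$feature_id %in% lo] == "non_enriched"), 0.95)
})

test_that("site windows center on the anchor and exclude out-of-range", {
  tr <- make_track(numeric(200)); tr[101] <- 1  # delta at position 100
  sites <- data.frame(piRNA_id = "p1", target_feature_id = "g",
                      anchor = 100L, stringsAsFactors = FALSE)
  sp <- site_window_profile(list(g = tr), sites)
  expect_equal(sp$mean_depth[sp$position == 0], 1)
  expect_equal(sum(sp$mean_depth), 1)
  # anchor near the transcript start: left positions have no coverage count
  s2 <- data.frame(piRNA_id = "p2", target_feature_id = "g", anchor = 10L,
                   stringsAsFactors = FALSE)
  sp2 <- site_window_profile(list(g = tr), s2)
  expect_equal(sp2$n_at_position[sp2$position == -20], 0L)
  expect_true(is.na(sp2$mean_depth[sp2$position == -20]))
  expect_error(site_window_profile(list(g = tr),
                                   s2[s2$piRNA_id == "none", ]), "no usable")
})

test_that("site profiles are order-invariant and localize planted bumps", {
  truth <- build_truth(sim_config(n_duplicated_pairs = 0L), seed = 23)
  spec <- sample_spec("wildtype", "total", 3e5, 61)
  aln <- simulate_srna_library(truth, spec)
  cls <- classify_reads(filter_and_weight(aln), truth$features)
  denom <- attr(build_count_table(cls, truth$features), "totals")$denominator
  genes <- unique(truth$sites$target_feature_id)
  tracks <- depth_tracks(cls, truth$features, genes, denom)
  sp <- site_window_profile(tracks, truth$sites)
  expect_lte(abs(sp$position[which.max(sp$mean_depth)]), 3)
  perm <- sample(nrow(truth$sites))
  sp2 <- site_window_profile(tracks, truth$sites[perm, ])
  expect_equal(sp$mean_depth, sp2$mean_depth)
})
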