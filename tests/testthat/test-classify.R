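test_that("length filter drops <17 and >40 nt reads and attaches weights", {
  aln <- alignment_table(c("a", "b", "c", "d"), "chr1",
                         c(0L, 0L, 0L, 0L), c(16L, 17L, 40L, 41L),
                         "+", "G", c(1L, 4L, 1L, 1L))
  fw <- filter_and_weight(aln)
  expect_equal(fw$read_id, c("b", "c"))
  expect_equal(fw$weight, c(0.25, 1))
})

test_that("class rules and precedence follow the 22G definition", {
  f <- tiny_features()
  cases <- list(
    # 22 nt, 5'G, antisense to a protein-coding gene -> 22G
    list(aln1(start = 200L, strand = "-", fp = "G"), "g22_antisense"),
    # same but 5'A -> not a 22G; no sense overlap -> other
    list(aln1(start = 200L, strand = "-", fp = "A"), "other"),
    # 24 nt 5'G antisense -> too long for 22G -> other
    list(aln1(start = 200L, len = 24L, strand = "-", fp = "G"), "other"),
    # sense read inside an rRNA, even 22 nt 5'G -> structural fragment
    list(aln1(chrom = "chr2", start = 1200L, strand = "+", fp = "G"),
         "structural_sense"),
    # exact sense match of the piRNA locus -> mature piRNA
    list(aln1(start = 3000L, len = 21L, strand = "+", fp = "T"),
         "mature_piRNA"),
    # 1-nt overhang -> not mature, just a sense read
    list(aln1(start = 2999L, len = 21L, strand = "+", fp = "T"),
         "sense_feature"),
    # antisense 5'G 22-mer on the minus-strand transposon (read on +)
    list(aln1(chrom = "chr2", start = 4100L, strand = "+", fp = "G"),
         "g22_antisense"))
  for (cs in cases) {
    cls <- classify_reads(filter_and_weight(cs[[1]]), f)
    expect_equal(unique(cls$read_class), cs[[2]])
  }
})

test_that("classification is independent of read order", {
  truth <- small_truth(seed = 4)
  aln <- simulate_srna_library(truth, sample_spec("wildtype", "total",
                                                  5e3, 9))
  fw <- filter_and_weight(aln)
  c1 <- classify_reads(fw, truth$features)
  perm <- sample(nrow(aln))
  fw2 <- filter_and_weight(aln[perm, ])
  c2 <- classify_reads(fw2, truth$features)
  k1 <- c1[order(c1$read_id, c1$start, c1$feature_id),
           c("read_id", "read_class", "feature_id")]
  k2 <- c2[order(c2$read_id, c2$start, c2$feature_id),
           c("read_id", "read_class", "feature_id")]
  rownames(k1) <- rownames(k2) <- NULL
  expect_equal(k1, k2)
})

test_that("count table totals follow the structural-excluded RPM frame", {
  f <- tiny_features()
  aln <- rbind(
    aln1("g1", start = 200L), aln1("g2", start = 300L),
    aln1("s1", chrom = "chr2", start = 1100L, strand = "+", fp = "A",
         len = 20L))
  cls <- classify_reads(filter_and_weight(aln), f)
  ct <- build_count_table(cls, f)
  tot <- attr(ct, "totals")
  expect_equal(tot$total_mapped, 3)
  expect_equal(tot$structural_sense, 1)
  expect_equal(tot$denominator, 2)
  expect_equal(ct$count[ct$feature_id == "geneA" &
                          ct$read_class == "g22_antisense"], 2)
  rpm <- normalize_counts(ct, "srna_rpm")
  expect_equal(rpm$rpm[rpm$feature_id == "geneA"], 2 * 1e6 / 2)
})

test_that("a two-locus read contributes half to each duplicated copy", {
  f <- feature_table(c("dupA", "dupB"), c("chr1", "chr1"), c("+", "+"),
                     c("transposon", "transposon"),
                     list(0L, 5000L), list(1000L, 6000L))
  aln <- alignment_table(c("r1", "r1"), "chr1", c(100L, 5100L),
                         c(122L, 5122L), "-", "G", 2L)
  cls <- classify_reads(filter_and_weight(aln), f)
  ct <- build_count_table(cls, f)
  expect_equal(sort(ct$count[ct$read_class == "g22_antisense"]), c(0.5, 0.5))
  expect_equal(attr(ct, "totals")$total_mapped, 1)
})

test_that("structural-only libraries are flagged degenerate", {
  f <- tiny_features()
  aln <- aln1("s1", chrom = "chr2", start = 1100L, strand = "+", fp = "A",
              len = 20L)
  cls <- classify_reads(filter_and_weight(aln), f)
  expect_warning(ct <- build_count_table(cls, f), "degenerate")
  expect_true(attr(ct, "totals")$degenerate)
  expect_error(normalize_counts(ct, "srna_rpm"), "denominator")
})

test_that("RPM and RPKM formulas are exact", {
  tab <- count_table("g1", 15,
                     totals = list(total_mapped = 1.5e6 + 3,
                                   structural_sense = 3))
  rpm <- normalize_counts(tab, "srna_rpm")
  expect_equal(rpm$rpm, 10)
  f <- feature_table("g1", "chr1", "+", "protein_coding",
                     list(0L), list(2000L))
  mt <- count_table("g1", 100,
                    totals = list(total_mapped = 1e6, structural_sense = 0,
                                  protein_coding_total = 1e6),
                    read_class = "sense_feature", orientation = "sense")
  attr(mt, "features") <- f
  rpkm <- normalize_counts(mt, "mrna_rpkm")
  expect_equal(rpkm$rpkm, 50)
  # zero-count gene queried through gene_values -> 0 RPM
  expect_equal(unname(gene_values(rpm, c("g1", "gX"), "rpm")), c(10, 0))
})

test_that("length histogram conserves class totals", {
  truth <- small_truth(seed = 6)
  aln <- simulate_srna_library(truth, sample_spec("wildtype", "total",
                                                  8e3, 3))
  cls <- classify_reads(filter_and_weight(aln), truth$features)
  per_aln <- cls[!duplicated(cls$aln_id), ]
  for (rc in c("g22_antisense", "mature_piRNA", "structural_sense")) {
    h <- length_histogram(cls, rc)
    expect_equal(sum(h), sum(per_aln$weight[per_aln$read_class == rc]))
  }
  expect_equal(sum(length_histogram(cls, "nonexistent_class")), 0)
  # mature piRNAs are all 21 nt
  hp <- length_histogram(cls, "mature_piRNA")
  expect_equal(sum(hp[names(hp) != "21"]), 0)
})

test_that("per-gene 22G RPM tracks the generating abundances", {
  truth <- build_truth(sim_config(n_duplicated_pairs = 0L), seed = 11)
  spec <- sample_spec("wildtype", "total", 1e5, 21)
  aln <- simulate_srna_library(truth, spec)
  cls <- classify_reads(filter_and_weight(aln), truth$features)
  ct <- build_count_table(cls, truth$features)
  rpm <- normalize_counts(ct, "srna_rpm")
  mu <- expected_counts(truth, spec)
  genes <- intersect(truth$classmap$feature_id, names(mu))
  v <- gene_values(rpm, genes, "rpm")
  expect_gte(cor(v, mu[genes], method = "spearman"), 0.95)
})
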