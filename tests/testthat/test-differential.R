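test_that("evidence limits: no data, identical data, clear difference", {
  ev0 <- bb_evidence(0, 0, 0, 0)
  expect_equal(ev0$log_evidence_shared, 0)
  expect_equal(ev0$log_evidence_independent, 0)
  ev <- bb_evidence(0, 1000, 0, 1000)
  expect_gt(ev$log_evidence_shared, ev$log_evidence_independent)
  expect_gt(same_probability(0, 1000, 0, 1000), 0.5)
  expect_lt(same_probability(100, 1000, 10, 1000), 0.5)
  expect_error(bb_evidence(5, 3, 0, 10), "exceeds")
  expect_error(bb_evidence(-1, 3, 0, 10), "non-negative")
})

test_that("closed-form evidences match adaptive quadrature", {
  for (case in list(c(100, 1000, 10, 1000), c(0, 7, 3, 9), c(20, 50, 20, 50),
                    c(1, 1, 0, 50))) {
    ev <- bb_evidence(case[1], case[2], case[3], case[4])
    expect_lt(abs(ev$log_evidence_shared -
                    oracle_log_shared(case[1], case[2], case[3], case[4])),
              1e-6)
    expect_lt(abs(ev$log_evidence_independent -
                    (oracle_log_marginal(case[1], case[2]) +
                       oracle_log_marginal(case[3], case[4]))), 1e-6)
  }
})

test_that("p_same is symmetric and favors the shared model on equal data", {
  grid <- expand.grid(k1 = c(0, 3, 17), N1 = c(40, 200),
                      k2 = c(1, 9, 30), N2 = c(60, 200))
  p12 <- same_probability(grid$k1, grid$N1, grid$k2, grid$N2)
  p21 <- same_probability(grid$k2, grid$N2, grid$k1, grid$N1)
  expect_equal(p12, p21)
  for (N in c(50, 200)) {
    k <- 0:N
    expect_true(all(same_probability(k, N, k, N) > 0.5))
  }
})

test_that("p_same peaks near k2 = k1 and decays as counts diverge", {
  for (N in c(100, 200)) for (k1 in c(10, 50)) {
    p <- same_probability(rep(k1, N + 1), N, 0:N, N)
    peak <- which.max(p) - 1
    expect_lte(abs(peak - k1), 2)
    # monotone decrease away from the peak
    expect_true(all(diff(p[(peak + 3):(N + 1)]) < 0))
    if (peak > 3) expect_true(all(diff(p[1:(peak - 1)]) > 0))
  }
})

test_that("fold-change direction uses pseudocounted RPM with A as reference", {
  mk <- function(counts, denom) {
    count_table(names(counts), counts,
                totals = list(total_mapped = denom, structural_sense = 0))
  }
  ta <- mk(c(g1 = 10, g2 = 10, g3 = 0), 1e6)
  tb <- mk(c(g1 = 4, g2 = 10, g3 = 0), 1e6)
  d <- call_differential(ta, tb, c("g1", "g2", "g3"))
  expect_equal(d$direction[d$feature_id == "g1"], "decreased_2fold")
  expect_equal(d$direction[d$feature_id == "g2"], "unchanged")
  expect_equal(d$direction[d$feature_id == "g3"], "unchanged")
  expect_equal(d$log2_fold_change[d$feature_id == "g1"], log2(5 / 11))
  expect_error(call_differential(ta, tb, character(0)), "empty gene_set")
})

test_that("weighted counts are rounded half-to-even for the test only", {
  mk <- function(counts, denom) {
    count_table(names(counts), counts,
                totals = list(total_mapped = denom, structural_sense = 0))
  }
  ta <- mk(c(g1 = 2.5, g2 = 3.5), 1e5)
  tb <- mk(c(g1 = 2.5, g2 = 3.5), 1e5)
  d <- call_differential(ta, tb, c("g1", "g2"))
  expect_equal(d$k1, c(2, 4))  # banker's rounding
  expect_equal(d$rpm_a, c(25, 35))  # RPM stays fractional
})

test_that("planted effects are recovered as significant directional calls", {
  truth <- build_truth(sim_config(n_protein_coding = 1000L,
                                  n_duplicated_pairs = 0L), seed = 31)
  cm <- truth$classmap
  genes <- cm$feature_id[cm$target_class != "none"]
  prg1 <- cm$feature_id[cm$prg1_dependent]
  enh <- cm$feature_id[cm$enhanced_hrde1]
  ta <- simulate_count_table(truth, sample_spec("wildtype", "total", 1e6, 41))
  tb <- simulate_count_table(truth, sample_spec("mutant", "total", 1e6, 42))
  d <- call_differential(ta, tb, genes)
  mu <- expected_counts(truth, sample_spec("wildtype", "total", 1e6, 41))
  sel <- intersect(prg1, names(mu)[mu >= 50])
  dd <- d[match(sel, d$feature_id), ]
  expect_gte(mean(dd$significant & dd$direction == "decreased_2fold"), 0.9)
  de <- d[match(enh, d$feature_id), ]
  expect_gte(mean(de$significant & de$direction == "increased_2fold"), 0.9)
})

test_that("quadrant analysis partitions genes and recovers planted fractions", {
  m <- c(a = 1, b = -1, c = 0.5, d = -2)
  s <- c(a = -1, b = 1, c = 0.5, d = -0.1)
  qa <- quadrant_analysis(m, s, names(m))
  expect_equal(unname(qa$quadrant),
               c("upper_left", "lower_right", "upper_right", "lower_left"))
  expect_equal(sum(qa$proportions), 1)
  qa0 <- quadrant_analysis(c(x = 0, y = 0), c(x = 0, y = 1), c("x", "y"))
  expect_equal(unname(qa0$counts["boundary"]), 2L)
  expect_equal(sum(qa0$proportions), 1)
  expect_error(quadrant_analysis(m, s, c("a", "zz")), "missing")
  # 60% planted activated genes land upper-left within +/- 0.05
  truth <- build_truth(sim_config(n_protein_coding = 1000L,
                                  prg1_frac = 0.5, enhanced_frac = 0.15,
                                  n_duplicated_pairs = 0L), seed = 77)
  cm <- truth$classmap
  prg1 <- cm$feature_id[cm$prg1_dependent]
  enh <- cm$feature_id[cm$enhanced_hrde1]
  n_act <- length(prg1)
  gene_set <- c(prg1, enh[seq_len(min(length(enh), round(n_act * 2 / 3)))])
  frac_act <- n_act / length(gene_set)
  ta <- simulate_count_table(truth, sample_spec("wildtype", "total", 1e6, 81))
  tb <- simulate_count_table(truth, sample_spec("mutant", "total", 1e6, 82))
  d <- call_differential(ta, tb, gene_set)
  s_lfc <- stats::setNames(d$log2_fold_change, d$feature_id)
  mw <- simulate_mrna_counts(truth, sample_spec("wildtype", "mRNA", 1e6, 83))
  mm <- simulate_mrna_counts(truth, sample_spec("mutant", "mRNA", 1e6, 84))
  kw <- gene_values(mw, gene_set, "count", "sense_feature", "sense")
  km <- gene_values(mm, gene_set, "count", "sense_feature", "sense")
  m_lfc <- log2((km + 1) / (kw + 1))
  qa2 <- quadrant_analysis(m_lfc, s_lfc, gene_set)
  expect_lt(abs(qa2$proportions[["upper_left"]] - frac_act), 0.05)
})
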