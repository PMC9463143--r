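#' Beta prior specification for the read-accumulation probability
#'
#' Conjugate Beta(a, b) prior on a gene's probability of accumulating a
#' read, plus the prior odds of the shared model over the independent
#' model. The default is the uniform prior a = b = 1 with equal model odds.
#'
#' @param a,b Positive shape parameters.
#' @param prior_odds Prior odds P(shared)/P(independent).
#' @return list of class `prior_spec`.
#' @export
prior_spec <- function(a = 1, b = 1, prior_odds = 1) {
  stopifnot(a > 0, b > 0, prior_odds > 0)
  structure(list(a = a, b = b, prior_odds = prior_odds),
            class = "prior_spec")
}

check_counts <- function(k1, N1, k2, N2) {
  if (any(k1 < 0 | k2 < 0 | N1 < 0 | N2 < 0))
    stop("counts must be non-negative")
  if (any(k1 > N1 | k2 > N2))
    stop("gene count k exceeds library total N")
}

#' Log evidence of the shared- and independent-rate models
#'
#' For gene counts k out of library totals N in two libraries, computes the
#' log marginal likelihood of (i) the shared model, one binomial
#' probability common to both libraries integrated over the Beta prior,
#' and (ii) the independent model, the product of the two per-library
#' Beta-binomial marginals. All terms are evaluated in log space
#' (log-Beta / log-binomial), finite for all valid inputs.
#'
#' @param k1,N1,k2,N2 Integer counts (vectorized); 0 <= k_i <= N_i.
#' @param prior A [prior_spec()].
#' @return data.frame with columns `log_evidence_shared`,
#'   `log_evidence_independent`.
#' @export
bb_evidence <- function(k1, N1, k2, N2, prior = prior_spec()) {
  check_counts(k1, N1, k2, N2)
  a <- prior$a; b <- prior$b
  lc <- lchoose(N1, k1) + lchoose(N2, k2)
  sh <- lc + lbeta(k1 + k2 + a, N1 + N2 - k1 - k2 + b) - lbeta(a, b)
  ind <- lc + lbeta(k1 + a, N1 - k1 + b) + lbeta(k2 + a, N2 - k2 + b) -
    2 * lbeta(a, b)
  data.frame(log_evidence_shared = sh, log_evidence_independent = ind)
}

#' Posterior probability that two libraries share one accumulation rate
#'
#' The posterior probability of the shared model given the two observed
#' counts, under the model prior odds in `prior`. This is the quantity the
#' analysis uses as its per-gene "p value"; it is a posterior model
#' probability, not a frequentist tail probability.
#'
#' @inheritParams bb_evidence
#' @return Numeric vector in (0, 1).
#' @export
same_probability <- function(k1, N1, k2, N2, prior = prior_spec()) {
  ev <- bb_evidence(k1, N1, k2, N2, prior)
  d <- ev$log_evidence_independent - ev$log_evidence_shared -
    log(prior$prior_odds)
  1 / (1 + exp(d))
}

#' Per-gene Bayesian differential 22G-RNA test between two libraries
#'
#' For each gene in `gene_set`, compares its weighted antisense 22G count
#' (rounded half-to-even to an integer) against the library totals of the
#' two samples with the shared/independent beta-binomial model comparison,
#' applies Bonferroni control over `length(gene_set)` tests, and assigns a
#' fold-change direction from pseudocounted RPM. A gene is significant when
#' its shared-model posterior falls below `alpha / n` AND its absolute log2
#' fold change reaches `log2(fold_threshold)`.
#'
#' @param table_a,table_b `g22_count_table`s of the reference (A) and
#'   comparison (B) libraries.
#' @param gene_set Character vector of gene ids to test.
#' @param prior A [prior_spec()].
#' @param alpha Family-wise error target (Bonferroni).
#' @param fold_threshold Fold-change threshold (default 2).
#' @param pseudocount RPM pseudocount added to both sides of the ratio.
#' @param read_class,orientation Which counts to test.
#' @return data.frame of class `g22_differential`, one row per gene, with
#'   counts, evidences, `p_same`, `significant`, `log2_fold_change` and
#'   `direction`; test metadata in attributes.
#' @export
call_differential <- function(table_a, table_b, gene_set,
                              prior = prior_spec(), alpha = 0.05,
                              fold_threshold = 2, pseudocount = 1,
                              read_class = "g22_antisense",
                              orientation = "antisense") {
  if (length(gene_set) == 0L) stop("empty gene_set")
  ta <- attr(table_a, "totals"); tb <- attr(table_b, "totals")
  if (is.null(ta$denominator) || is.null(tb$denominator) ||
      ta$denominator <= 0 || tb$denominator <= 0)
    stop("zero library totals")
  ca <- gene_values(table_a, gene_set, "count", read_class, orientation)
  cb <- gene_values(table_b, gene_set, "count", read_class, orientation)
  N1 <- round(ta$denominator); N2 <- round(tb$denominator)
  k1 <- round(ca); k2 <- round(cb)   # round() is half-to-even
  ev <- bb_evidence(k1, N1, k2, N2, prior)
  p <- same_probability(k1, N1, k2, N2, prior)
  rpm_a <- ca * 1e6 / ta$denominator
  rpm_b <- cb * 1e6 / tb$denominator
  lfc <- log2((rpm_b + pseudocount) / (rpm_a + pseudocount))
  n <- length(gene_set)
  thr <- alpha / n
  lf <- log2(fold_threshold)
  sig <- p < thr & abs(lfc) >= lf
  dir <- ifelse(lfc <= -lf, "decreased_2fold",
                ifelse(lfc >= lf, "increased_2fold", "unchanged"))
  out <- data.frame(feature_id = gene_set, k1 = k1, N1 = N1, k2 = k2, N2 = N2,
                    log_evidence_shared = ev$log_evidence_shared,
                    log_evidence_independent = ev$log_evidence_independent,
                    p_same = p, significant = sig,
                    rpm_a = rpm_a, rpm_b = rpm_b,
                    log2_fold_change = lfc, direction = dir,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("g22_differential", "data.frame")
  attr(out, "bonferroni_alpha") <- alpha
  attr(out, "n_tested") <- n
  attr(out, "prior") <- prior
  attr(out, "pseudocount") <- pseudocount
  attr(out, "fold_threshold") <- fold_threshold
  attr(out, "percent") <- c(
    decreased_2fold = 100 * mean(dir == "decreased_2fold"),
    increased_2fold = 100 * mean(dir == "increased_2fold"),
    unchanged = 100 * mean(dir == "unchanged"),
    significant_decreased = 100 * mean(sig & dir == "decreased_2fold"),
    significant_increased = 100 * mean(sig & dir == "increased_2fold"))
  out
}

#' mRNA versus 22G-RNA fold-change quadrant analysis
#'
#' Partitions genes by the signs of their mRNA and small-RNA log2 fold
#' changes. The upper-left quadrant (mRNA up, 22G down) corresponds to
#' silencing targets activated in the mutant; the lower-right (mRNA down,
#' 22G up) to genes aberrantly silenced. Genes with an exactly-zero fold
#' change on either axis are assigned to a separate `boundary` category so
#' that proportions always sum to one.
#'
#' @param mrna_log2fc,srna_log2fc Named numeric vectors of log2 fold
#'   changes (mutant over wild type).
#' @param gene_set Genes to partition; every gene must be present in both
#'   vectors.
#' @return list with `proportions` (named numeric summing to 1 over
#'   `upper_left`, `upper_right`, `lower_left`, `lower_right`, `boundary`),
#'   `counts`, and per-gene `quadrant` assignments.
#' @export
quadrant_analysis <- function(mrna_log2fc, srna_log2fc, gene_set) {
  missing <- union(setdiff(gene_set, names(mrna_log2fc)),
                   setdiff(gene_set, names(srna_log2fc)))
  if (length(missing))
    stop("genes missing fold changes: ", paste(missing, collapse = ", "))
  m <- mrna_log2fc[gene_set]; s <- srna_log2fc[gene_set]
  q <- rep("boundary", length(gene_set))
  q[m > 0 & s < 0] <- "upper_left"
  q[m > 0 & s > 0] <- "upper_right"
  q[m < 0 & s < 0] <- "lower_left"
  q[m < 0 & s > 0] <- "lower_right"
  lev <- c("upper_left", "upper_right", "lower_left", "lower_right",
           "boundary")
  counts <- table(factor(q, levels = lev))
  list(proportions = stats::setNames(as.numeric(counts) / length(gene_set),
                                     lev),
       counts = stats::setNames(as.integer(counts), lev),
       quadrant = stats::setNames(q, gene_set))
}
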