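#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed`, restoring the caller's RNG
#' state afterwards, so generator calls are pure functions of their seed.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Parameters of the synthetic genome and read generator. Defaults encode
#' the study conditions the pipeline is validated under: 22G abundances are
#' lognormal with WAGO/CSR-1 targets carrying a `target_abund_mult`-fold
#' higher baseline; in the mutant condition, piRNA-dependent WAGO targets
#' lose 22G-RNAs fourfold (`phi_prg1_mutant`) while enhanced-HRDE-1 CSR-1
#' targets gain them fourfold (`phi_enhanced_mutant`), with anticorrelated
#' mRNA effects (`psi_*`); CSR-1 targets concentrate 40% of their 22G
#' density in the last 15% of the transcript while other genes are uniform
#' (tail weight 0.15); piRNA target sites on WAGO genes add localized
#' density bumps of half-width 10 nt; HRDE-1/CSR-1 IP enrichment factors
#' are 4:1 for WAGO targets and 1:4 for CSR-1 targets (2:4 for the
#' enhanced subset); counts are negative-binomial with one global size
#' parameter of 100 (mild extra-Poisson spread between single libraries).
#' Unknown keys are rejected.
#'
#' @param ... Overrides of the defaults listed above.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_protein_coding = 300L, n_pseudogene = 20L, n_transposon = 30L,
    n_duplicated_pairs = 5L,
    n_pirna = 50L, n_mirna = 10L,
    n_rrna = 5L, n_trna = 15L, n_snorna = 10L,
    n_chrom = 3L, chrom_gap = 200L,
    gene_len_meanlog = log(1500), gene_len_sdlog = 0.35, gene_len_min = 300L,
    wago_frac = 0.3, csr_frac = 0.3,
    prg1_frac = 0.5, enhanced_frac = 0.15,
    abund_meanlog = log(40), abund_sdlog = 0.6, target_abund_mult = 3,
    phi_prg1_mutant = 0.25, phi_enhanced_mutant = 4,
    psi_prg1_mutant = 2, psi_enhanced_mutant = 0.5,
    mrna_meanlog = log(100), mrna_sdlog = 0.8,
    tau_default = 0.15, tau_csr = 0.40, tau_enhanced = 0.15,
    sites_per_wago_gene = 2L, bump_beta = 0.15, bump_halfwidth = 10,
    eps_hrde1_wago = 4, eps_hrde1_csr = 1, eps_hrde1_enhanced = 2,
    eps_csr1_wago = 1, eps_csr1_csr = 4,
    nb_size = 100,
    structural_frac = 0.08, pirna_frac = 0.10, mirna_frac = 0.02)
  ov <- list(...)
  if (length(ov)) {
    unknown <- setdiff(names(ov), names(cfg))
    if (length(unknown) || is.null(names(ov)) || any(names(ov) == ""))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(ov)] <- ov
  }
  with(cfg, {
    if (wago_frac < 0 || csr_frac < 0 || wago_frac + csr_frac > 1 + 1e-9)
      stop("target class fractions must be in [0,1] and sum to at most 1")
    if (prg1_frac < 0 || prg1_frac > 1 || enhanced_frac < 0 || enhanced_frac > 1)
      stop("subset fractions must lie in [0,1]")
    fr <- structural_frac + pirna_frac + mirna_frac
    if (fr < 0 || fr >= 1)
      stop("library composition fractions must sum below 1")
    if (tau_default < 0 || tau_default > 1 || tau_csr < 0 || tau_csr > 1)
      stop("tail weights must lie in [0,1]")
    if (tau_default + sites_per_wago_gene * bump_beta >= 1)
      stop("tail weight plus site bump weights must stay below 1")
  })
  structure(cfg, class = c("sim_config", "list"))
}

#' Library sample specification
#'
#' @param condition `"wildtype"` or `"mutant"`.
#' @param kind Library kind: `"total"` small RNA, `"IP_HRDE1"`,
#'   `"IP_CSR1"`, or `"mRNA"`.
#' @param depth Target sequencing depth (expected reads).
#' @param seed RNG seed for this library.
#' @return list of class `sample_spec`.
#' @export
sample_spec <- function(condition = c("wildtype", "mutant"),
                        kind = c("total", "IP_HRDE1", "IP_CSR1", "mRNA"),
                        depth = 1e5, seed = 1L) {
  condition <- match.arg(condition)
  kind <- match.arg(kind)
  stopifnot(depth > 0)
  structure(list(condition = condition, kind = kind, depth = depth,
                 seed = as.integer(seed)),
            class = c("sample_spec", "list"))
}

#' Build a synthetic genome, target classes, piRNA sites and ground truth
#'
#' Lays out single-exon features (protein-coding genes, pseudogenes,
#' transposons including duplicated pairs, piRNA/miRNA loci, structural
#' RNAs) non-overlapping on synthetic chromosomes, assigns WAGO/CSR-1
#' target classes and their subsets, plants piRNA target sites on WAGO
#' genes, and draws all generative parameters (baseline abundances, fold
#' effects, tail weights, IP enrichments). Duplicated transposon pairs have
#' identical length and shared abundance; reads simulated from them are
#' reported at both loci with `n_loci = 2`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the whole truth bundle is a pure function of
#'   (config, seed).
#' @return list of class `sim_truth`: `features`, `classmap`, `sites`,
#'   `lambda`, `tau`, `phi`, `psi`, `eps`, `mrna_mu`, `dup_groups`,
#'   `nb_size`, `ref_total`, `config`, `seed`.
#' @export
build_truth <- function(config = sim_config(), seed = 1L) {
  with_seed(seed, {
    cfg <- config
    glen <- function(n) pmax(cfg$gene_len_min,
                             round(stats::rlnorm(n, cfg$gene_len_meanlog,
                                                 cfg$gene_len_sdlog)))
    n_dup <- 2L * cfg$n_duplicated_pairs
    ids <- character(0); lens <- integer(0); bts <- character(0)
    add <- function(n, prefix, bt, len_fun) {
      if (n == 0L) return(invisible())
      ids <<- c(ids, sprintf("%s%04d", prefix, seq_len(n)))
      lens <<- c(lens, len_fun(n))
      bts <<- c(bts, rep(bt, n))
      invisible()
    }
    add(cfg$n_protein_coding, "gene", "protein_coding", glen)
    add(cfg$n_pseudogene, "pseudo", "pseudogene", glen)
    add(cfg$n_transposon, "tn", "transposon", glen)
    # duplicated pairs: identical lengths within a pair
    if (cfg$n_duplicated_pairs > 0L) {
      dlen <- glen(cfg$n_duplicated_pairs)
      ids <- c(ids, sprintf("dup%04d%s", rep(seq_len(cfg$n_duplicated_pairs), each = 2),
                            rep(c("a", "b"), cfg$n_duplicated_pairs)))
      lens <- c(lens, rep(dlen, each = 2))
      bts <- c(bts, rep("transposon", n_dup))
    }
    add(cfg$n_pirna, "pirna", "piRNA", function(n) rep(21L, n))
    add(cfg$n_mirna, "mirna", "miRNA", function(n) rep(22L, n))
    add(cfg$n_rrna, "rrna", "rRNA", function(n) rep(1500L, n))
    add(cfg$n_trna, "trna", "tRNA", function(n) rep(75L, n))
    add(cfg$n_snorna, "snorna", "snoRNA", function(n) rep(120L, n))
    n_feat <- length(ids)
    strand <- sample(c("+", "-"), n_feat, replace = TRUE)
    chrom <- paste0("simchr", 1L + (seq_len(n_feat) - 1L) %% cfg$n_chrom)
    # sequential placement per chromosome with fixed gaps
    start <- integer(n_feat)
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      start[i] <- cumsum(c(0L, (lens[i] + cfg$chrom_gap)[-length(i)])) +
        cfg$chrom_gap
    }
    features <- feature_table(ids, chrom, strand, bts,
                              as.list(start), as.list(start + lens))

    is_gene_like <- bts %in% G22_TARGET_BIOTYPES
    pc_ids <- ids[bts == "protein_coding"]
    n_wago <- round(cfg$n_protein_coding * cfg$wago_frac)
    n_csr <- round(cfg$n_protein_coding * cfg$csr_frac)
    cls_pick <- sample(pc_ids, n_wago + n_csr)
    wago <- cls_pick[seq_len(n_wago)]
    csr <- cls_pick[n_wago + seq_len(n_csr)]
    prg1 <- if (n_wago) sample(wago, round(n_wago * cfg$prg1_frac)) else character(0)
    enh <- if (n_csr) sample(csr, round(n_csr * cfg$enhanced_frac)) else character(0)
    classmap <- data.frame(
      feature_id = ids[is_gene_like],
      target_class = "none", stringsAsFactors = FALSE)
    classmap$target_class[classmap$feature_id %in% wago] <- "WAGO"
    classmap$target_class[classmap$feature_id %in% csr] <- "CSR1"
    classmap$prg1_dependent <- classmap$feature_id %in% prg1
    classmap$reduced_hrde1 <- classmap$prg1_dependent  # one planted mechanism
    classmap$enhanced_hrde1 <- classmap$feature_id %in% enh

    # baseline antisense abundance; targets carry more 22G reads
    lam_g <- stats::rlnorm(sum(is_gene_like), cfg$abund_meanlog, cfg$abund_sdlog)
    names(lam_g) <- ids[is_gene_like]
    tgt <- classmap$feature_id[classmap$target_class != "none"]
    lam_g[tgt] <- lam_g[tgt] * cfg$target_abund_mult
    # duplicated pair members share one abundance (drawn for member a)
    dup_groups <- NULL
    if (cfg$n_duplicated_pairs > 0L) {
      a <- sprintf("dup%04da", seq_len(cfg$n_duplicated_pairs))
      b <- sprintf("dup%04db", seq_len(cfg$n_duplicated_pairs))
      lam_g[b] <- lam_g[a]
      dup_groups <- data.frame(group = seq_len(cfg$n_duplicated_pairs),
                               member_a = a, member_b = b,
                               stringsAsFactors = FALSE)
    }
    gene_sum <- sum(lam_g[setdiff(names(lam_g),
                                  if (is.null(dup_groups)) character(0)
                                  else dup_groups$member_b)])
    g_share <- 1 - cfg$structural_frac - cfg$pirna_frac - cfg$mirna_frac
    share_total <- function(frac, idv) {
      if (!length(idv)) return(numeric(0))
      w <- stats::rlnorm(length(idv), 0, 1)
      stats::setNames(w / sum(w) * gene_sum * frac / g_share, idv)
    }
    lam_struct <- share_total(cfg$structural_frac,
                              ids[bts %in% STRUCTURAL_BIOTYPES])
    lam_pirna <- share_total(cfg$pirna_frac, ids[bts == "piRNA"])
    lam_mirna <- share_total(cfg$mirna_frac, ids[bts == "miRNA"])
    lambda <- c(lam_g, lam_struct, lam_pirna, lam_mirna)

    tau <- stats::setNames(rep(cfg$tau_default, sum(is_gene_like)),
                           ids[is_gene_like])
    tau[csr] <- cfg$tau_csr
    tau[enh] <- cfg$tau_enhanced

    # piRNA target sites on WAGO genes, anchored away from ends so the
    # 100-nt window and the 3' tail stay clean
    sites <- NULL
    if (length(wago) && cfg$sites_per_wago_gene > 0L) {
      rows <- list()
      for (g in sort(wago)) {
        fi <- features[features$feature_id == g, ]
        L <- fi$spliced_length
        H <- L - ceiling(0.15 * L)
        lo <- 80L; hi <- H - 80L
        if (hi <= lo) next
        anch <- sort(sample(lo:hi, cfg$sites_per_wago_gene))
        gpos <- if (fi$strand == "+") fi$start + anch else fi$end - 1L - anch
        rows[[g]] <- data.frame(
          piRNA_id = sprintf("pi_%s_%d", g, seq_along(anch)),
          target_feature_id = g, anchor = anch,
          beta = cfg$bump_beta, halfwidth = cfg$bump_halfwidth,
          chrom = fi$chrom, start = gpos, end = gpos + 1L,
          strand = fi$strand, stringsAsFactors = FALSE)
      }
      sites <- do.call(rbind, rows)
      rownames(sites) <- NULL
    }

    ones <- stats::setNames(rep(1, length(lambda)), names(lambda))
    phi_mut <- ones
    phi_mut[prg1] <- cfg$phi_prg1_mutant
    phi_mut[enh] <- cfg$phi_enhanced_mutant
    eps_h <- ones
    eps_h[wago] <- cfg$eps_hrde1_wago
    eps_h[csr] <- cfg$eps_hrde1_csr
    eps_h[enh] <- cfg$eps_hrde1_enhanced
    eps_c <- ones
    eps_c[wago] <- cfg$eps_csr1_wago
    eps_c[csr] <- cfg$eps_csr1_csr

    mrna_mu <- stats::setNames(
      stats::rlnorm(length(pc_ids), cfg$mrna_meanlog, cfg$mrna_sdlog), pc_ids)
    psi_mut <- stats::setNames(rep(1, length(pc_ids)), pc_ids)
    psi_mut[intersect(prg1, pc_ids)] <- cfg$psi_prg1_mutant
    psi_mut[intersect(enh, pc_ids)] <- cfg$psi_enhanced_mutant

    structure(list(
      features = features, classmap = classmap, sites = sites,
      lambda = lambda, tau = tau,
      phi = list(wildtype = ones, mutant = phi_mut),
      psi = list(wildtype = stats::setNames(rep(1, length(pc_ids)), pc_ids),
                 mutant = psi_mut),
      eps = list(total = ones, IP_HRDE1 = eps_h, IP_CSR1 = eps_c),
      mrna_mu = mrna_mu, dup_groups = dup_groups,
      nb_size = cfg$nb_size, ref_total = sum(lambda) -
        (if (is.null(dup_groups)) 0 else sum(lambda[dup_groups$member_b])),
      config = cfg, seed = as.integer(seed)),
      class = c("sim_truth", "list"))
  })
}

gene_like_ids <- function(truth) {
  f <- truth$features
  f$feature_id[f$biotype %in% G22_TARGET_BIOTYPES]
}

#' Expected per-feature read counts for a library
#'
#' The generator's first moment: lambda * phi(condition) * eps(kind),
#' scaled so a wild-type total library has expected size `depth`.
#'
#' @param truth A [build_truth()] result.
#' @param spec A [sample_spec()].
#' @return Named numeric vector over read-generating features (duplicated
#'   pair members `b` are excluded; their reads are mirrored from `a`).
#' @export
expected_counts <- function(truth, spec) {
  if (!spec$condition %in% names(truth$phi))
    stop("unknown condition: ", spec$condition)
  scale <- spec$depth / truth$ref_total
  mu <- truth$lambda * truth$phi[[spec$condition]] * truth$eps[[spec$kind]] *
    scale
  if (!is.null(truth$dup_groups))
    mu <- mu[setdiff(names(mu), truth$dup_groups$member_b)]
  mu
}

#' Simulate an aligned small-RNA library
#'
#' Draws per-feature read counts from the negative-binomial model and
#' places reads positionally: antisense 22G reads (21-23 nt, 5' G) on
#' protein-coding genes, pseudogenes and transposons from the
#' head/tail/site-bump mixture; sense 21-nt 5' U reads spanning piRNA loci
#' exactly; sense 22-nt reads at miRNA loci; sense fragments of 17-30 nt on
#' structural RNAs. Reads from duplicated transposon pairs are reported at
#' both loci with `n_loci = 2`.
#'
#' @param truth A [build_truth()] result.
#' @param spec A [sample_spec()] (kind `"total"`, `"IP_HRDE1"` or
#'   `"IP_CSR1"`).
#' @return A `g22_alignments` table.
#' @export
simulate_srna_library <- function(truth, spec) {
  stopifnot(spec$kind != "mRNA")
  mu <- expected_counts(truth, spec)
  with_seed(spec$seed, {
    f <- truth$features
    fi <- match(names(mu), f$feature_id)
    n_reads <- stats::rnbinom(length(mu), mu = mu, size = truth$nb_size)
    dup_b <- if (is.null(truth$dup_groups)) character(0) else
      stats::setNames(truth$dup_groups$member_b, truth$dup_groups$member_a)
    recs <- vector("list", length(mu))
    rid0 <- 0L
    for (i in seq_along(mu)) {
      n <- n_reads[i]
      if (n == 0L) next
      id <- names(mu)[i]
      row <- f[fi[i], ]
      bt <- row$biotype
      L <- row$spliced_length
      if (bt %in% G22_TARGET_BIOTYPES) {
        len <- sample(21:23, n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
        st <- if (is.null(truth$sites)) NULL
        else truth$sites[truth$sites$target_feature_id == id, , drop = FALSE]
        s <- draw_positions(n, len, L, truth$tau[[id]], st)
        gstart <- if (row$strand == "+") row$start + s else row$end - s - len
        strand <- if (row$strand == "+") "-" else "+"
        fp <- "G"
      } else if (bt == "piRNA") {
        len <- rep(21L, n); gstart <- rep(row$start, n)
        strand <- row$strand; fp <- "T"
      } else if (bt == "miRNA") {
        len <- rep(22L, n); gstart <- rep(row$start, n)
        strand <- row$strand; fp <- "T"
      } else {  # structural
        len <- sample(17:30, n, replace = TRUE)
        s <- floor(stats::runif(n) * (L - len + 1))
        gstart <- row$start + s
        strand <- row$strand
        fp <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
      }
      read_id <- sprintf("r%08d", rid0 + seq_len(n))
      rid0 <- rid0 + n
      rec <- data.frame(read_id = read_id, chrom = row$chrom,
                        start = as.integer(gstart),
                        end = as.integer(gstart + len),
                        strand = strand, five_prime_nt = fp,
                        n_loci = 1L, stringsAsFactors = FALSE)
      if (id %in% names(dup_b)) {
        # mirror every read onto the duplicated copy at the same offset
        rowb <- f[f$feature_id == dup_b[[id]], ]
        off <- if (row$strand == "+") as.integer(gstart) - row$start
        else row$end - as.integer(gstart + len)
        gstart_b <- if (rowb$strand == "+") rowb$start + off
        else rowb$end - off - len
        strand_b <- if (identical(rowb$strand, row$strand)) strand
        else chartr("+-", "-+", strand)
        recb <- rec
        recb$chrom <- rowb$chrom
        recb$start <- as.integer(gstart_b)
        recb$end <- as.integer(gstart_b + len)
        recb$strand <- strand_b
        rec$n_loci <- 2L
        recb$n_loci <- 2L
        rec <- rbind(rec, recb)
      }
      recs[[i]] <- rec
    }
    all <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
    if (is.null(all))
      return(alignment_table(character(0), character(0), integer(0),
                             integer(0), character(0), character(0),
                             integer(0)))
    alignment_table(all$read_id, all$chrom, all$start, all$end, all$strand,
                    all$five_prime_nt, all$n_loci)
  })
}

# position mixture: uniform head, 3' tail with weight tau, per-site bumps
draw_positions <- function(n, len, L, tau, sites) {
  tailL <- ceiling(0.15 * L)
  H <- L - tailL
  nb <- if (is.null(sites) || nrow(sites) == 0L) 0L else nrow(sites)
  betas <- if (nb) sites$beta else numeric(0)
  p <- c(max(0, 1 - tau - sum(betas)), tau, betas)
  comp <- sample.int(2L + nb, n, replace = TRUE, prob = p)
  s <- integer(n)
  head_i <- comp == 1L
  s[head_i] <- floor(stats::runif(sum(head_i)) * (H - len[head_i] + 1))
  tail_i <- comp == 2L
  s[tail_i] <- (L - tailL) +
    floor(stats::runif(sum(tail_i)) * (tailL - len[tail_i] + 1))
  if (nb) for (b in seq_len(nb)) {
    bi <- comp == 2L + b
    if (!any(bi)) next
    ctr <- sites$anchor[b] +
      round(stats::rnorm(sum(bi), 0, sites$halfwidth[b] / 2))
    s[bi] <- pmin(pmax(ctr - floor(len[bi] / 2), 0L), L - len[bi])
  }
  s
}

#' Simulate a per-gene mRNA count table
#'
#' Poly(A) mRNA counts for protein-coding genes, negative-binomial around
#' `mrna_mu * psi(condition)` scaled to the target depth. The mRNA-side
#' fold effects are anticorrelated with the 22G effects: activated WAGO
#' targets gain mRNA, aberrantly silenced CSR-1 targets lose it.
#'
#' @param truth A [build_truth()] result.
#' @param spec A [sample_spec()] with kind `"mRNA"`.
#' @return `g22_count_table` (sense counts on protein-coding genes) with
#'   `protein_coding_total` set; the truth features attached for RPKM.
#' @export
simulate_mrna_counts <- function(truth, spec) {
  stopifnot(spec$kind == "mRNA")
  if (!spec$condition %in% names(truth$psi))
    stop("unknown condition: ", spec$condition)
  mu0 <- truth$mrna_mu * truth$psi[[spec$condition]][names(truth$mrna_mu)]
  scale <- spec$depth / sum(truth$mrna_mu)
  with_seed(spec$seed, {
    k <- stats::rnbinom(length(mu0), mu = mu0 * scale, size = truth$nb_size)
    tab <- count_table(names(mu0), k,
                       totals = list(total_mapped = sum(k),
                                     structural_sense = 0,
                                     protein_coding_total = sum(k)),
                       read_class = "sense_feature", orientation = "sense",
                       sample = paste(spec$condition, "mRNA", sep = "_"))
    attr(tab, "features") <- truth$features
    tab
  })
}

#' Simulate a library at the count level
#'
#' Draws per-gene weighted antisense 22G counts and the structural /
#' piRNA / miRNA library components from the same negative-binomial model
#' as [simulate_srna_library()], skipping read placement. Produces a
#' `g22_count_table` with the same totals frame, for validations that only
#' exercise counting-level statistics.
#'
#' @inheritParams simulate_srna_library
#' @return `g22_count_table` of antisense 22G counts with library totals.
#' @export
simulate_count_table <- function(truth, spec) {
  stopifnot(spec$kind != "mRNA")
  mu <- expected_counts(truth, spec)
  with_seed(spec$seed, {
    k <- stats::rnbinom(length(mu), mu = mu, size = truth$nb_size)
    names(k) <- names(mu)
    f <- truth$features
    bt <- f$biotype[match(names(k), f$feature_id)]
    gene <- bt %in% G22_TARGET_BIOTYPES
    struct <- bt %in% STRUCTURAL_BIOTYPES
    kt <- k
    if (!is.null(truth$dup_groups)) {
      # duplicated copies: counts mirrored, each alignment weighted 1/2
      kb <- kt[truth$dup_groups$member_a]
      names(kb) <- truth$dup_groups$member_b
      kt[truth$dup_groups$member_a] <- kb / 2
      kt <- c(kt, kb / 2)
      gene <- c(gene, rep(TRUE, length(kb)))
    }
    total <- sum(k)
    count_table(names(kt)[gene], kt[gene],
                totals = list(total_mapped = total,
                              structural_sense = sum(k[struct])),
                sample = paste(spec$condition, spec$kind, sep = "_"))
  })
}

#' Serialize a truth bundle to plain-text files
#'
#' Writes the annotation (GFF3), target classes, sites, generative
#' parameters and config into a directory so downstream recovery tests can
#' read truth only from this artifact. [read_truth()] restores it.
#'
#' @param truth A [build_truth()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_annotations_gff(truth$features, file.path(dir, "annotation.gff3"))
  write_tsv_table(truth$classmap, file.path(dir, "classmap.tsv"))
  if (!is.null(truth$sites))
    write_tsv_table(truth$sites, file.path(dir, "sites.tsv"))
  par <- data.frame(feature_id = names(truth$lambda),
                    lambda = as.numeric(truth$lambda),
                    stringsAsFactors = FALSE)
  par$tau <- truth$tau[par$feature_id]
  par$phi_mutant <- truth$phi$mutant[par$feature_id]
  par$eps_hrde1 <- truth$eps$IP_HRDE1[par$feature_id]
  par$eps_csr1 <- truth$eps$IP_CSR1[par$feature_id]
  par$mrna_mu <- truth$mrna_mu[par$feature_id]
  par$psi_mutant <- truth$psi$mutant[par$feature_id]
  write_tsv_table(par, file.path(dir, "params.tsv"))
  if (!is.null(truth$dup_groups))
    write_tsv_table(truth$dup_groups, file.path(dir, "dup_groups.tsv"))
  yaml::write_yaml(list(seed = truth$seed, nb_size = truth$nb_size,
                        ref_total = truth$ref_total,
                        config = lapply(unclass(truth$config), identity)),
                   file.path(dir, "config.yaml"), precision = 17L)
  invisible(dir)
}

#' Restore a truth bundle written by [write_truth()]
#'
#' @param dir Directory written by [write_truth()].
#' @return A `sim_truth` list (regenerated via [build_truth()] from the
#'   serialized config and seed, then checked against the serialized
#'   parameter table).
#' @export
read_truth <- function(dir) {
  y <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg <- do.call(sim_config, y$config)
  truth <- build_truth(cfg, y$seed)
  par <- read_tsv_table(file.path(dir, "params.tsv"))
  if (max(abs(truth$lambda[par$feature_id] - as.numeric(par$lambda))) > 1e-9)
    stop("serialized truth does not match regenerated truth")
  truth
}
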