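#' Pipeline run configuration
#'
#' Validated configuration for [run_pipeline()]: the simulation config, the
#' seed, library depths, and the analysis parameters of every stage.
#' Unknown keys are rejected before any stage runs.
#'
#' @param ... Overrides; `sim` takes [sim_config()] arguments as a list.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    sim = list(),
    depth_srna = 1e5, depth_mrna = 1e5, depth_ip = 1e5,
    stages = c("simulate", "classify", "diff", "metagene", "tail3p",
               "sitemap", "ratio"),
    alpha = 0.05, fold_threshold = 2, prior_a = 1, prior_b = 1,
    diff_pseudocount = 1, ratio_pseudocount = 0.1,
    n_bins = 100L, site_halfwidth = 50L)
  ov <- list(...)
  if (length(ov)) {
    unknown <- setdiff(names(ov), names(cfg))
    if (length(unknown) || is.null(names(ov)) || any(names(ov) == ""))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(ov)] <- ov
  }
  if (length(cfg$sim)) {
    unknown <- setdiff(names(cfg$sim), names(sim_config()))
    if (length(unknown))
      stop("unknown config key(s): ",
           paste(paste0("sim.", unknown), collapse = ", "))
  }
  known <- c("simulate", "classify", "diff", "metagene", "tail3p",
             "sitemap", "ratio")
  bad <- setdiff(cfg$stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(cfg, class = c("run_config", "list"))
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose top-level keys are [run_config()] arguments.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

classify_library <- function(aln, features, sample) {
  cls <- classify_reads(filter_and_weight(aln), features)
  list(classified = cls,
       counts = build_count_table(cls, features, sample = sample))
}

#' Run the simulation-to-tables pipeline
#'
#' Executes the requested stages on one synthetic experiment: builds truth,
#' simulates wild-type and mutant total sRNA libraries, mRNA counts and the
#' two IP libraries, classifies and normalizes them, then produces the
#' differential table (mutant vs wild type over WAGO and CSR-1 targets),
#' metagene / 3'-tail / site-window profiles, and the HRDE-1:CSR-1 ratio
#' table. All outputs are TSV files in `outdir`; `manifest.yaml` records
#' the full configuration, the seed, and the MD5 of every produced file.
#' Reruns with an identical configuration reproduce byte-identical tables.
#'
#' @param config A [run_config()] (or path to a YAML file).
#' @param outdir Output directory.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  produced <- character(0)
  emit <- function(df, name) {
    p <- file.path(outdir, name)
    write_tsv_table(df, p)
    produced <<- c(produced, name)
  }
  stage <- "simulate"
  res <- tryCatch({
    truth <- build_truth(do.call(sim_config, config$sim), config$seed)
    write_truth(truth, file.path(outdir, "truth"))
    produced <- c(produced, file.path("truth", list.files(file.path(outdir, "truth"))))
    cm <- truth$classmap
    wago <- cm$feature_id[cm$target_class == "WAGO"]
    csr <- cm$feature_id[cm$target_class == "CSR1"]

    libs <- list(
      wt = sample_spec("wildtype", "total", config$depth_srna, config$seed + 11L),
      mut = sample_spec("mutant", "total", config$depth_srna, config$seed + 12L),
      hrde = sample_spec("wildtype", "IP_HRDE1", config$depth_ip, config$seed + 13L),
      csr = sample_spec("wildtype", "IP_CSR1", config$depth_ip, config$seed + 14L))
    cl <- list()
    if ("classify" %in% config$stages ||
        any(c("diff", "metagene", "tail3p", "sitemap", "ratio") %in%
              config$stages)) {
      stage <- "classify"
      for (nm in names(libs)) {
        aln <- simulate_srna_library(truth, libs[[nm]])
        write_alignments_bed(aln, file.path(outdir, paste0("reads_", nm, ".bed")))
        produced <- c(produced, paste0("reads_", nm, ".bed"))
        cl[[nm]] <- classify_library(aln, truth$features, nm)
        rpm <- normalize_counts(cl[[nm]]$counts, "srna_rpm")
        emit(rpm, paste0("rpm_", nm, ".tsv"))
      }
    }
    if ("diff" %in% config$stages) {
      stage <- "diff"
      prior <- prior_spec(config$prior_a, config$prior_b)
      dw <- call_differential(cl$wt$counts, cl$mut$counts, wago,
                              prior = prior, alpha = config$alpha,
                              fold_threshold = config$fold_threshold,
                              pseudocount = config$diff_pseudocount)
      emit(dw, "diff_wago.tsv")
      dc <- call_differential(cl$wt$counts, cl$mut$counts, csr,
                              prior = prior, alpha = config$alpha,
                              fold_threshold = config$fold_threshold,
                              pseudocount = config$diff_pseudocount)
      emit(dc, "diff_csr1.tsv")
      mw <- simulate_mrna_counts(truth, sample_spec(
        "wildtype", "mRNA", config$depth_mrna, config$seed + 15L))
      mm <- simulate_mrna_counts(truth, sample_spec(
        "mutant", "mRNA", config$depth_mrna, config$seed + 16L))
      rw <- normalize_counts(mw, "mrna_rpkm", truth$features)
      rm_ <- normalize_counts(mm, "mrna_rpkm", truth$features)
      pc_wago <- intersect(wago, rw$feature_id)
      mr_lfc <- log2((gene_values(rm_, pc_wago, "rpkm", "sense_feature", "sense") + 1) /
                       (gene_values(rw, pc_wago, "rpkm", "sense_feature", "sense") + 1))
      sr_lfc <- stats::setNames(dw$log2_fold_change, dw$feature_id)[pc_wago]
      qa <- quadrant_analysis(mr_lfc, sr_lfc, pc_wago)
      emit(data.frame(quadrant = names(qa$proportions),
                      proportion = as.numeric(qa$proportions),
                      count = as.integer(qa$counts)),
           "quadrants_wago.tsv")
    }
    if (any(c("metagene", "tail3p", "sitemap") %in% config$stages)) {
      stage <- "profiles"
      denom <- attr(cl$wt$counts, "totals")$denominator
      gene_set <- union(wago, csr)
      tracks <- depth_tracks(cl$wt$classified, truth$features, gene_set, denom)
      if ("metagene" %in% config$stages) {
        mg <- metagene_profile(tracks[wago], config$n_bins)
        emit(data.frame(bin = seq_len(config$n_bins) - 1L,
                        depth = mg$profile), "metagene_wago.tsv")
      }
      if ("tail3p" %in% config$stages)
        emit(tail_enrichment_table(tracks), "tail3p.tsv")
      if ("sitemap" %in% config$stages && !is.null(truth$sites)) {
        sp <- site_window_profile(tracks, truth$sites, config$site_halfwidth)
        emit(data.frame(position = sp$position, mean_depth = sp$mean_depth,
                        n_sites = sp$n_at_position), "sitemap.tsv")
      }
    }
    if ("ratio" %in% config$stages) {
      stage <- "ratio"
      hr <- normalize_counts(cl$hrde$counts, "srna_rpm")
      cr <- normalize_counts(cl$csr$counts, "srna_rpm")
      emit(compute_ratio(hr, cr, csr, config$ratio_pseudocount), "ratio_csr1.tsv")
    }
    TRUE
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  manifest <- list(
    config = unclass(config),
    config_hash = digest_config(config),
    produced = lapply(stats::setNames(produced, produced), function(p)
      unname(tools::md5sum(file.path(outdir, p)))))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(manifest)
}

digest_config <- function(config) {
  # stable content hash of the configuration (md5 of its serialized form)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}
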