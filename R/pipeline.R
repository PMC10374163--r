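#' Build a pipeline run configuration
#'
#' Assembles, validates and seed-derives the configuration for
#' [run_pipeline()]. Every stochastic stage receives a seed derived
#' deterministically from the global seed, so a rerun with the same
#' configuration is bit-identical for deterministic stages. Configurations
#' round-trip losslessly through YAML via [read_config()]/[write_config()].
#'
#' @param seed Global integer seed.
#' @param n_outlines Number of synthetic hip outlines to measure.
#' @param n_subjects Subjects in the observational phenotype table.
#' @param departure_tol,cam_threshold_deg Alpha-angle measurement settings.
#' @param maf_min,info_min Summary-statistics QC thresholds.
#' @param clump_r2,clump_kb,p_threshold LD clumping settings.
#' @param forward_sim,reverse_sim `gwas_sim_spec` objects for the two MR
#'   directions (defaults: a weak forward causal effect of shape on disease
#'   and a stronger reverse effect, echoing the bidirectional design).
#' @param n_boot Bootstrap replicates for median/mode estimators.
#' @param coloc_priors Named list with `p1`, `p2`, `p12`.
#' @param stages Character vector of stages to run (subset of the default).
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1, n_outlines = 25, n_subjects = 4000,
                       departure_tol = 0.02, cam_threshold_deg = 60,
                       maf_min = 0.01, info_min = 0.4,
                       clump_r2 = 0.001, clump_kb = 10000,
                       p_threshold = 5e-8,
                       forward_sim = NULL, reverse_sim = NULL,
                       n_boot = 500,
                       coloc_priors = list(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5),
                       stages = c("simulate", "alpha", "epi", "meta",
                                  "clump", "mr", "coloc")) {
  check_num(seed, "seed", len = 1, integerish = TRUE)
  check_num(n_outlines, "n_outlines", lower = 1, len = 1, integerish = TRUE)
  check_num(n_subjects, "n_subjects", lower = 10, len = 1, integerish = TRUE)
  forward_sim <- forward_sim %||%
    gwas_sim_spec(causal_beta = 0.1, seed = derive_seed(seed, 11L))
  reverse_sim <- reverse_sim %||%
    gwas_sim_spec(n_snps = 34, causal_beta = 0.09, n_exposure = 323948,
                  n_outcome = 44214, outcome_type = "quantitative",
                  seed = derive_seed(seed, 12L))
  structure(list(seed = as.integer(seed), n_outlines = n_outlines,
                 n_subjects = n_subjects, departure_tol = departure_tol,
                 cam_threshold_deg = cam_threshold_deg, maf_min = maf_min,
                 info_min = info_min, clump_r2 = clump_r2,
                 clump_kb = clump_kb, p_threshold = p_threshold,
                 forward_sim = forward_sim, reverse_sim = reverse_sim,
                 n_boot = n_boot, coloc_priors = coloc_priors,
                 stages = stages),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  plain <- config_as_plain(config)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  fw <- raw$forward_sim
  rv <- raw$reverse_sim
  raw$forward_sim <- NULL
  raw$reverse_sim <- NULL
  cfg <- do.call(run_config, raw)
  if (!is.null(fw)) cfg$forward_sim <- do.call(gwas_sim_spec, fw)
  if (!is.null(rv)) cfg$reverse_sim <- do.call(gwas_sim_spec, rv)
  cfg
}

# Strip S3 classes recursively so configs serialize cleanly to YAML/JSON.
config_as_plain <- function(x) {
  if (is.list(x)) lapply(unclass(x), config_as_plain) else x
}

log_line <- function(log_path, fmt, ...) {
  cat(sprintf(paste0(fmt, "\n"), ...), file = log_path, append = TRUE)
}

run_stage <- function(name, log_path, expr) {
  log_line(log_path, "[stage %s] start", name)
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis chain
#'
#' Orchestrates simulate -> alpha angle -> observational -> meta-analysis ->
#' clumping -> bidirectional MR -> colocalization on synthetic inputs,
#' writing delimited tables, a stage-count log (the record funnel), and a
#' JSON manifest (configuration, derived seeds, file checksums) into a new
#' run directory. A stage failure halts the run with a stage-named error;
#' partial outputs are retained.
#'
#' @param config A [run_config()].
#' @param out_dir Parent directory for the run directory (created if
#'   needed); the run directory itself is timestamped and never overwritten.
#' @return Path of the run directory, invisibly; the manifest lists every
#'   stage output.
#' @export
run_pipeline <- function(config, out_dir = tempfile("camMR_run_")) {
  if (!inherits(config, "run_config")) {
    stop("config must be created by run_config()", call. = FALSE)
  }
  run_dir <- file.path(out_dir,
                       format(Sys.time(), "run_%Y%m%d_%H%M%OS3"))
  dir.create(run_dir, recursive = TRUE)
  log_path <- file.path(run_dir, "log.txt")
  file.create(log_path)
  outputs <- character(0)
  emit <- function(df, name) {
    p <- file.path(run_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <<- c(outputs, name)
    p
  }
  stages <- config$stages

  outlines <- pheno <- sim_fwd <- sim_rev <- NULL
  if ("simulate" %in% stages) {
    run_stage("simulate", log_path, {
      aa <- aa_population(config$n_outlines,
                          seed = derive_seed(config$seed, 1L))
      outlines <- lapply(seq_len(config$n_outlines), function(i) {
        generate_hip_outline(
          shape_spec(cam_onset_angle = min(max(aa[i], 35), 140),
                     cam_amplitude = 0.15, noise_sd = 0.005,
                     seed = derive_seed(config$seed, 100L + i)),
          subject_id = sprintf("subj_%04d", i))
      })
      pheno <- simulate_phenotype_table(config$n_subjects,
                                         seed = derive_seed(config$seed, 2L))
      sim_fwd <- simulate_summary_stats(config$forward_sim)
      sim_rev <- simulate_summary_stats(config$reverse_sim)
      log_line(log_path,
               "[stage simulate] outlines=%d subjects=%d fwd_snps=%d rev_snps=%d",
               length(outlines), nrow(pheno), config$forward_sim$n_snps,
               config$reverse_sim$n_snps)
    })
  }
  if ("alpha" %in% stages) {
    run_stage("alpha", log_path, {
      res <- batch_alpha(outlines, config$departure_tol,
                         config$cam_threshold_deg)
      emit(res, "alpha_angles.tsv")
      log_line(log_path, "[stage alpha] in=%d measured=%d failed=%d",
               nrow(res), sum(!is.na(res$alpha_deg)),
               sum(!is.na(res$error)))
    })
  }
  if ("epi" %in% stages) {
    run_stage("epi", log_path, {
      tab <- observational_table(pheno)
      emit(tab, "observational_associations.tsv")
      log_line(log_path, "[stage epi] subjects=%d rows=%d", nrow(pheno),
               nrow(tab))
    })
  }
  meta_fwd <- NULL
  if ("meta" %in% stages) {
    run_stage("meta", log_path, {
      qc <- qc_filter(sim_fwd$exposure, config$maf_min, config$info_min)
      meta_fwd <- fixed_effects_meta(qc$kept)
      emit(meta_fwd, "meta_exposure.tsv")
      log_line(log_path, "[stage meta] in=%d qc_dropped=%d pooled=%d",
               nrow(sim_fwd$exposure), nrow(qc$dropped), nrow(meta_fwd))
    })
  }
  clumped <- NULL
  if ("clump" %in% stages) {
    run_stage("clump", log_path, {
      ld <- simulate_ld_matrix(rep(1, nrow(meta_fwd)), 0,
                               seed = derive_seed(config$seed, 3L))
      dimnames(ld) <- list(meta_fwd$SNP, meta_fwd$SNP)
      clumped <- ld_clump(meta_fwd, ld, config$p_threshold,
                           config$clump_r2, config$clump_kb)
      emit(clumped, "clumped_instruments.tsv")
      log_line(log_path, "[stage clump] candidates=%d indices=%d",
               sum(meta_fwd$P < config$p_threshold), nrow(clumped))
    })
  }
  if ("mr" %in% stages) {
    run_stage("mr", log_path, {
      keep <- clumped$SNP
      fwd_exp <- meta_fwd[meta_fwd$SNP %in% keep, , drop = FALSE]
      fwd_out <- qc_filter(
        fixed_effects_meta(sim_fwd$outcome), config$maf_min,
        config$info_min)$kept
      h_fwd <- harmonize_instruments(fwd_exp, fwd_out)
      rev_exp <- fixed_effects_meta(sim_rev$exposure)
      rev_exp <- rev_exp[rev_exp$P < config$p_threshold, , drop = FALSE]
      rev_out <- fixed_effects_meta(sim_rev$outcome)
      h_rev <- harmonize_instruments(rev_exp, rev_out)
      bi <- bidirectional_mr(h_fwd, h_rev, n_boot = config$n_boot,
                             seed = derive_seed(config$seed, 4L))
      emit(bi$report, "mr_estimates.tsv")
      scan <- sensitivity_scan(h_fwd)
      emit(scan$leave_one_out, "mr_leave_one_out.tsv")
      emit(scan$single_snp, "mr_single_snp.tsv")
      log_line(log_path, "[stage mr] fwd_snps=%d rev_snps=%d excluded=%d",
               nrow(h_fwd), nrow(h_rev),
               nrow(attr(h_fwd, "exclusions")) +
                 nrow(attr(h_rev, "exclusions")))
    })
  }
  if ("coloc" %in% stages) {
    run_stage("coloc", log_path, {
      locus <- simulate_locus_pair(seed = derive_seed(config$seed, 5L))
      cres <- coloc_pp(locus$trait1, locus$trait2,
                       p1 = config$coloc_priors$p1,
                       p2 = config$coloc_priors$p2,
                       p12 = config$coloc_priors$p12)
      emit(data.frame(locus = cres$locus, t(cres$pp),
                      n_variants = cres$n_variants, call = cres$call),
           "coloc_results.tsv")
      log_line(log_path, "[stage coloc] variants=%d call=%s",
               cres$n_variants, cres$call)
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("camMR")),
    seed = config$seed,
    derived_seeds = list(outlines = derive_seed(config$seed, 1L),
                         phenotypes = derive_seed(config$seed, 2L),
                         clump_ld = derive_seed(config$seed, 3L),
                         mr_boot = derive_seed(config$seed, 4L),
                         coloc = derive_seed(config$seed, 5L)),
    config = config_as_plain(config),
    stage_outputs = outputs,
    checksums = as.list(tools::md5sum(file.path(run_dir, outputs))))
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(run_dir)
}

#' Validate pipeline input files
#'
#' Schema checks with line-level diagnostics for outline and
#' summary-statistics files; inputs are never mutated and failures are
#' findings, not errors.
#'
#' @param paths Character vector of file paths.
#' @return Data frame of findings: `file`, `line` (NA for file-level
#'   findings), `issue`. Zero rows means all files passed.
#' @export
validate_inputs <- function(paths) {
  findings <- list()
  add <- function(file, line, issue) {
    findings[[length(findings) + 1]] <<-
      data.frame(file = file, line = line, issue = issue,
                 stringsAsFactors = FALSE)
  }
  for (p in paths) {
    if (!file.exists(p)) {
      add(p, NA_integer_, "file not found")
      next
    }
    header <- tryCatch(names(utils::read.delim(p, nrows = 1)),
                       error = function(e) NULL)
    if (is.null(header)) {
      add(p, NA_integer_, "unreadable or empty file")
      next
    }
    if (all(c("SNP", "BETA", "SE", "P") %in% header)) {
      df <- utils::read.delim(p, stringsAsFactors = FALSE, na.strings = "NA")
      ln <- seq_len(nrow(df)) + 1L  # header is line 1
      bad <- which(!is.na(df$SE) & df$SE <= 0)
      for (i in bad) add(p, ln[i], "SE must be positive")
      if ("P" %in% names(df)) {
        bad <- which(!is.na(df$P) & (df$P <= 0 | df$P > 1))
        for (i in bad) add(p, ln[i], "P outside (0, 1]")
      }
      for (col in intersect(c("EA", "NEA"), names(df))) {
        bad <- which(!df[[col]] %in% c("A", "C", "G", "T"))
        for (i in bad) add(p, ln[i], sprintf("invalid allele in %s", col))
      }
      if ("EAF" %in% names(df)) {
        bad <- which(!is.na(df$EAF) & (df$EAF <= 0 | df$EAF >= 1))
        for (i in bad) add(p, ln[i], "EAF outside (0, 1)")
      }
    } else if (all(c("point_index", "x", "y", "landmark_role") %in% header)) {
      df <- utils::read.delim(p, stringsAsFactors = FALSE)
      ln <- seq_len(nrow(df)) + 1L
      bad <- which(!df$landmark_role %in%
                     c("head", "neck_superior", "neck_inferior", "apex"))
      for (i in bad) add(p, ln[i], "invalid landmark_role")
      bad <- which(!df$osteophyte_flag %in% c(0, 1))
      for (i in bad) add(p, ln[i], "invalid osteophyte_flag")
    } else {
      add(p, NA_integer_, "unrecognized file schema")
    }
  }
  if (length(findings)) do.call(rbind, findings) else
    data.frame(file = character(0), line = integer(0), issue = character(0),
               stringsAsFactors = FALSE)
}
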