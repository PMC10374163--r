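#' Specify a two-sample GWAS simulation
#'
#' Parameters for [simulate_summary_stats()]: a multi-cohort exposure GWAS of
#' a standardized trait and an independent outcome GWAS whose per-SNP effects
#' are `causal_beta` times the exposure effects plus configurable pleiotropy.
#' Setting every pleiotropy control to zero yields a valid-instrument
#' scenario.
#'
#' When `exposure_betas` is `NULL` the instrument follows an equal-z design:
#' each SNP's effect is `z_target` times its standard error at `n_exposure`,
#' so rarer variants get larger effects (as observed for selected
#' genome-wide-significant instruments) and every SNP has the same analytic
#' power. The default `z_target = 7` gives per-SNP power above 0.9 at the
#' genome-wide threshold of 5e-8.
#'
#' @param n_snps Number of instrument SNPs.
#' @param eaf_range Interval in (0,1) from which effect-allele frequencies
#'   are drawn uniformly.
#' @param exposure_betas Optional per-SNP true effects on the standardized
#'   exposure; `NULL` uses the equal-z design.
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param causal_beta True causal effect of the exposure on the outcome.
#' @param uncorrelated_pleiotropy_sd SD of random direct SNP-outcome effects
#'   (InSIDE-satisfying horizontal pleiotropy).
#' @param pleiotropy_mean Mean of the direct effects (directional
#'   pleiotropy; a nonzero value is what the Egger intercept estimates).
#' @param correlated_pleiotropy_frac Fraction of SNPs acting through a
#'   shared confounder of exposure and outcome (violates InSIDE).
#' @param direct_effects Optional explicit per-SNP direct outcome effects,
#'   added on top of the random pleiotropy terms.
#' @param n_cohorts Number of exposure/outcome cohorts.
#' @param cohort_fracs Sample-size fractions per cohort; defaults to
#'   (0.863, 0.137) for two cohorts (one large biobank plus a smaller
#'   replication cohort) and equal shares otherwise.
#' @param between_cohort_sd SD of cohort-level deviations of the true effect
#'   (heterogeneity scale).
#' @param outcome_type `"binary"` (effects on the log-odds scale, standard
#'   errors reflecting `case_fraction`) or `"quantitative"`.
#' @param case_fraction Outcome case fraction when `outcome_type="binary"`.
#' @param z_target Design z-score of the equal-z instrument.
#' @param palindromic_frac Fraction of SNPs given palindromic (A/T or C/G)
#'   allele codes; default 0.
#' @param seed Integer seed.
#' @return Object of class `gwas_sim_spec`.
#' @export
gwas_sim_spec <- function(n_snps = 8, eaf_range = c(0.05, 0.95),
                          exposure_betas = NULL, n_exposure = 44214,
                          n_outcome = 323948, causal_beta = 0,
                          uncorrelated_pleiotropy_sd = 0,
                          pleiotropy_mean = 0,
                          correlated_pleiotropy_frac = 0,
                          direct_effects = NULL,
                          n_cohorts = 2, cohort_fracs = NULL,
                          between_cohort_sd = 0,
                          outcome_type = c("binary", "quantitative"),
                          case_fraction = 0.03, z_target = 7,
                          palindromic_frac = 0, seed = 1) {
  outcome_type <- match.arg(outcome_type)
  check_num(n_snps, "n_snps", lower = 1, len = 1, integerish = TRUE)
  check_num(eaf_range, "eaf_range", lower = 0, upper = 1, len = 2,
            strict_lower = TRUE, strict_upper = TRUE)
  if (eaf_range[2] <= eaf_range[1]) {
    stop_field("eaf_range", "must be an increasing interval")
  }
  if (!is.null(exposure_betas)) {
    check_num(exposure_betas, "exposure_betas", len = n_snps)
  }
  check_num(n_exposure, "n_exposure", lower = 1, len = 1)
  check_num(n_outcome, "n_outcome", lower = 1, len = 1)
  check_num(causal_beta, "causal_beta", len = 1)
  check_num(uncorrelated_pleiotropy_sd, "uncorrelated_pleiotropy_sd",
            lower = 0, len = 1)
  check_num(pleiotropy_mean, "pleiotropy_mean", len = 1)
  check_num(correlated_pleiotropy_frac, "correlated_pleiotropy_frac",
            lower = 0, upper = 1, len = 1)
  if (!is.null(direct_effects)) {
    check_num(direct_effects, "direct_effects", len = n_snps)
  }
  check_num(n_cohorts, "n_cohorts", lower = 1, len = 1, integerish = TRUE)
  if (is.null(cohort_fracs)) {
    cohort_fracs <- if (n_cohorts == 2) c(0.863, 0.137) else
      rep(1 / n_cohorts, n_cohorts)
  }
  check_num(cohort_fracs, "cohort_fracs", lower = 0, upper = 1,
            strict_lower = TRUE, len = n_cohorts)
  cohort_fracs <- cohort_fracs / sum(cohort_fracs)
  check_num(between_cohort_sd, "between_cohort_sd", lower = 0, len = 1)
  check_num(case_fraction, "case_fraction", lower = 0, upper = 1,
            strict_lower = TRUE, strict_upper = TRUE, len = 1)
  check_num(z_target, "z_target", lower = 0, strict_lower = TRUE, len = 1)
  check_num(palindromic_frac, "palindromic_frac", lower = 0, upper = 1,
            len = 1)
  check_num(seed, "seed", len = 1, integerish = TRUE)
  structure(list(n_snps = as.integer(n_snps), eaf_range = eaf_range,
                 exposure_betas = exposure_betas, n_exposure = n_exposure,
                 n_outcome = n_outcome, causal_beta = causal_beta,
                 uncorrelated_pleiotropy_sd = uncorrelated_pleiotropy_sd,
                 pleiotropy_mean = pleiotropy_mean,
                 correlated_pleiotropy_frac = correlated_pleiotropy_frac,
                 direct_effects = direct_effects,
                 n_cohorts = as.integer(n_cohorts),
                 cohort_fracs = cohort_fracs,
                 between_cohort_sd = between_cohort_sd,
                 outcome_type = outcome_type, case_fraction = case_fraction,
                 z_target = z_target, palindromic_frac = palindromic_frac,
                 seed = as.integer(seed)),
            class = "gwas_sim_spec")
}

# Non-palindromic and palindromic allele pairs for synthetic variants.
ALLELE_PAIRS <- list(np = list(c("A", "G"), c("A", "C"), c("T", "G"),
                               c("T", "C"), c("G", "A"), c("C", "A"),
                               c("G", "T"), c("C", "T")),
                     pal = list(c("A", "T"), c("T", "A"),
                                c("C", "G"), c("G", "C")))

se_from_eaf_n <- function(eaf, n, case_fraction = NULL) {
  denom <- 2 * eaf * (1 - eaf) * n
  if (!is.null(case_fraction)) {
    denom <- denom * case_fraction * (1 - case_fraction)
  }
  1 / sqrt(denom)
}

p_from_z <- function(z) 2 * stats::pnorm(abs(z), lower.tail = FALSE)

#' Simulate multi-cohort exposure and outcome summary statistics
#'
#' Draws the two-sample architecture described in [gwas_sim_spec()]: per-SNP
#' exposure effect estimates are normal around the (possibly cohort-shifted)
#' true effects with standard errors from the cohort sample size and allele
#' frequency; outcome estimates are centred on
#' `causal_beta * exposure_effect + direct_effect` and drawn independently of
#' the exposure estimates (two-sample regime).
#'
#' @param spec A [gwas_sim_spec()].
#' @return List with elements `exposure` and `outcome` (long data frames,
#'   one row per SNP x cohort, columns `SNP CHR BP EA NEA EAF BETA SE P N
#'   INFO COHORT`) and `truth` (the drawn true effects and pleiotropy
#'   terms).
#' @export
simulate_summary_stats <- function(spec) {
  if (!inherits(spec, "gwas_sim_spec")) {
    stop("spec must be created by gwas_sim_spec()", call. = FALSE)
  }
  set.seed(spec$seed)
  m <- spec$n_snps
  eaf <- stats::runif(m, spec$eaf_range[1], spec$eaf_range[2])

  se_x_total <- se_from_eaf_n(eaf, spec$n_exposure)
  beta_x <- spec$exposure_betas %||% (spec$z_target * se_x_total)

  # Confounder-mediated (correlated) pleiotropy: selected SNPs gain an
  # effect on a shared confounder that feeds both traits.
  gamma <- numeric(m)
  n_cor <- round(spec$correlated_pleiotropy_frac * m)
  if (n_cor > 0) {
    idx <- seq_len(n_cor)
    gamma[idx] <- stats::rnorm(n_cor, 0, 0.3 * mean(abs(beta_x)))
  }
  beta_x_tot <- beta_x + gamma

  alpha <- stats::rnorm(m, spec$pleiotropy_mean,
                        spec$uncorrelated_pleiotropy_sd) + gamma
  if (!is.null(spec$direct_effects)) alpha <- alpha + spec$direct_effects
  beta_y_true <- spec$causal_beta * beta_x_tot + alpha

  n_pal <- round(spec$palindromic_frac * m)
  pal <- c(rep(TRUE, n_pal), rep(FALSE, m - n_pal))
  alleles <- t(vapply(seq_len(m), function(j) {
    pool <- if (pal[j]) ALLELE_PAIRS$pal else ALLELE_PAIRS$np
    unlist(pool[[sample.int(length(pool), 1)]])
  }, character(2)))

  snp <- sprintf("rs%06d", seq_len(m))
  chr <- ((seq_len(m) - 1L) %% 22L) + 1L
  # positions restart per chromosome (kept as double: large panels would
  # overflow integer arithmetic)
  bp <- 1e6 + 2e6 * ((seq_len(m) - 1) %/% 22)

  draw_cohorts <- function(n_total, true_beta, case_fraction = NULL,
                           label_prefix) {
    out <- vector("list", spec$n_cohorts)
    for (cc in seq_len(spec$n_cohorts)) {
      n_c <- max(2, round(n_total * spec$cohort_fracs[cc]))
      beta_c <- true_beta + if (spec$between_cohort_sd > 0) {
        stats::rnorm(m, 0, spec$between_cohort_sd)
      } else 0
      se_c <- se_from_eaf_n(eaf, n_c, case_fraction)
      bhat <- stats::rnorm(m, beta_c, se_c)
      eaf_hat <- pmin(pmax(
        eaf + stats::rnorm(m, 0, sqrt(eaf * (1 - eaf) / (2 * n_c))),
        1e-4), 1 - 1e-4)
      out[[cc]] <- data.frame(
        SNP = snp, CHR = chr, BP = bp, EA = alleles[, 1], NEA = alleles[, 2],
        EAF = eaf_hat, BETA = bhat, SE = se_c, P = p_from_z(bhat / se_c),
        N = n_c, INFO = stats::runif(m, 0.85, 1),
        COHORT = sprintf("%s%d", label_prefix, cc),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }

  exposure <- draw_cohorts(spec$n_exposure, beta_x_tot, NULL, "exp_cohort")
  case_fr <- if (spec$outcome_type == "binary") spec$case_fraction else NULL
  outcome <- draw_cohorts(spec$n_outcome, beta_y_true, case_fr, "out_cohort")

  list(exposure = exposure, outcome = outcome,
       truth = list(eaf = eaf, beta_exposure = beta_x_tot,
                    direct_effects = alpha, beta_outcome = beta_y_true,
                    causal_beta = spec$causal_beta, palindromic = pal,
                    snp = snp))
}

#' Simulate an individual-level toy cohort
#'
#' Genotypes are Binomial(2, maf); the phenotype is the genetic score plus
#' optional covariate effects plus Gaussian noise, with the residual variance
#' chosen so the phenotype variance is approximately 1.
#'
#' @param n Number of individuals (>= 1).
#' @param m Number of variants (>= 1).
#' @param maf Per-variant minor (effect) allele frequency in (0,1), recycled
#'   to length `m`.
#' @param beta Per-variant phenotype effects, recycled to length `m`.
#' @param covariate_effects Optional named numeric vector; one standard
#'   normal covariate is generated per entry with the given effect.
#' @param seed Integer seed.
#' @return List with `genotypes` (n x m matrix), `phenotype`, `covariates`
#'   (data frame, possibly zero-column), `maf`, `beta`.
#' @export
simulate_cohort <- function(n, m, maf = 0.3, beta = 0,
                            covariate_effects = NULL, seed = 1) {
  check_num(n, "n", lower = 1, len = 1, integerish = TRUE)
  check_num(m, "m", lower = 1, len = 1, integerish = TRUE)
  check_num(maf, "maf", lower = 0, upper = 1, strict_lower = TRUE,
            strict_upper = TRUE)
  check_num(beta, "beta")
  if (!is.null(covariate_effects)) {
    check_num(covariate_effects, "covariate_effects")
    if (is.null(names(covariate_effects))) {
      names(covariate_effects) <- sprintf("cov%d", seq_along(covariate_effects))
    }
  }
  set.seed(seed)
  maf <- rep_len(maf, m)
  beta <- rep_len(beta, m)
  G <- matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), nrow = n)
  colnames(G) <- sprintf("snp_%05d", seq_len(m))
  covs <- data.frame(row.names = seq_len(n))
  cov_term <- 0
  if (!is.null(covariate_effects)) {
    for (nm in names(covariate_effects)) {
      covs[[nm]] <- stats::rnorm(n)
      cov_term <- cov_term + covariate_effects[[nm]] * covs[[nm]]
    }
  }
  var_g <- sum(beta^2 * 2 * maf * (1 - maf))
  var_c <- sum(unlist(covariate_effects)^2)
  resid_sd <- sqrt(max(0.05, 1 - var_g - var_c))
  y <- as.vector(G %*% beta) + cov_term + stats::rnorm(n, 0, resid_sd)
  list(genotypes = G, phenotype = y, covariates = covs, maf = maf,
       beta = beta)
}

#' Simulate a block-structured LD matrix
#'
#' Block-diagonal symmetric r-squared matrix with unit diagonal: within a
#' block every pair has `within_r2`; across blocks r-squared is 0.
#'
#' @param block_sizes Positive integer sizes of the disjoint LD blocks.
#' @param within_r2 Within-block r-squared in \[0, 1\].
#' @param seed Integer seed (reserved for future stochastic variants; the
#'   construction is deterministic).
#' @return Square matrix with variant labels `snp_000001`, ... as dimnames.
#' @export
simulate_ld_matrix <- function(block_sizes, within_r2 = 0.9, seed = 1) {
  check_num(block_sizes, "block_sizes", lower = 1, integerish = TRUE)
  check_num(within_r2, "within_r2", lower = 0, upper = 1, len = 1)
  m <- sum(block_sizes)
  R <- matrix(0, m, m)
  at <- 0L
  for (b in block_sizes) {
    idx <- at + seq_len(b)
    R[idx, idx] <- within_r2
    at <- at + b
  }
  diag(R) <- 1
  labels <- sprintf("snp_%06d", seq_len(m))
  dimnames(R) <- list(labels, labels)
  R
}

#' Simulate a locus pair for colocalization
#'
#' Region-level per-variant summary statistics for two traits with a single
#' causal variant each. With `shared = TRUE` both traits load on the same
#' variant (the colocalization alternative); otherwise trait 2 uses its own
#' causal variant, or none when `z2 = 0`.
#'
#' @param n_variants Number of variants in the region.
#' @param z1,z2 Causal-variant z-scores for trait 1 and trait 2 (0 = null
#'   trait).
#' @param se1,se2 Per-variant standard errors.
#' @param shared Do the traits share the causal variant?
#' @param seed Integer seed.
#' @return List of two data frames (`trait1`, `trait2`) with columns
#'   `SNP BETA SE P`, plus `causal1`/`causal2` indices.
#' @export
simulate_locus_pair <- function(n_variants = 100, z1 = 8, z2 = 8,
                                se1 = 0.05, se2 = 0.05, shared = TRUE,
                                seed = 1) {
  check_num(n_variants, "n_variants", lower = 2, len = 1, integerish = TRUE)
  set.seed(seed)
  snp <- sprintf("rs%06d", seq_len(n_variants))
  c1 <- ceiling(n_variants / 2)
  c2 <- if (shared) c1 else max(1L, c1 - ceiling(n_variants / 4))
  mk <- function(z, se, causal) {
    mu <- numeric(n_variants)
    if (z != 0) mu[causal] <- z * se
    beta <- stats::rnorm(n_variants, mu, se)
    data.frame(SNP = snp, BETA = beta, SE = se,
               P = p_from_z(beta / se), stringsAsFactors = FALSE)
  }
  list(trait1 = mk(z1, se1, c1), trait2 = mk(z2, se2, c2),
       causal1 = c1, causal2 = if (z2 != 0) c2 else NA_integer_)
}

#' Simulate a phenotype table for the observational stage
#'
#' Alpha angles follow the shifted log-normal population model of
#' [aa_population()]; binary hip-OA outcomes follow logistic models with the
#' configured odds ratios per SD of alpha angle, and total hip replacement
#' follows an exponential time-to-event model with the configured hazard
#' ratio and uniform administrative censoring. Covariates (age, sex, height,
#' weight) carry modest effects of their own.
#'
#' @param n Number of subjects.
#' @param or_hip_pain,or_rhoa,or_hoa Odds ratios per SD of alpha angle for
#'   hip pain, radiographic hip OA (grade >= 2) and hospital-diagnosed OA.
#' @param hr_thr Hazard ratio per SD for total hip replacement.
#' @param mean_aa Population mean alpha angle in degrees.
#' @param seed Integer seed.
#' @return Data frame with columns `alpha_deg`, `z_alpha`, `hip_pain`,
#'   `rhoa`, `hoa`, `fu_time`, `thr_event`, `age`, `sex`, `height`,
#'   `weight`.
#' @export
simulate_phenotype_table <- function(n = 10000, or_hip_pain = 1.15,
                                     or_rhoa = 1.63, or_hoa = 1.44,
                                     hr_thr = 1.45, mean_aa = 47.8,
                                     seed = 1) {
  check_num(n, "n", lower = 10, len = 1, integerish = TRUE)
  aa <- aa_population(n, mean_aa = mean_aa, seed = seed)
  set.seed(derive_seed(seed, 7L))
  z <- standardize(aa)
  age <- stats::rnorm(n, 63, 7.5)
  sex <- stats::rbinom(n, 1, 0.48)
  height <- stats::rnorm(n, 168 + 8 * sex, 7)
  weight <- stats::rnorm(n, 72 + 8 * sex, 12)
  zage <- (age - mean(age)) / stats::sd(age)
  lin <- function(base_logit, or) {
    base_logit + log(or) * z + 0.3 * zage + 0.1 * sex
  }
  draw <- function(eta) stats::rbinom(n, 1, stats::plogis(eta))
  hip_pain <- draw(lin(stats::qlogis(0.20), or_hip_pain))
  rhoa <- draw(lin(stats::qlogis(0.10), or_rhoa))
  hoa <- draw(lin(stats::qlogis(0.02), or_hoa))
  haz <- 0.003 * exp(log(hr_thr) * z + 0.3 * zage)
  event_t <- stats::rexp(n, haz)
  censor_t <- stats::runif(n, 5, 10)
  data.frame(alpha_deg = aa, z_alpha = z,
             hip_pain = hip_pain, rhoa = rhoa, hoa = hoa,
             fu_time = pmin(event_t, censor_t),
             thr_event = as.integer(event_t <= censor_t),
             age = age, sex = sex, height = height, weight = weight)
}

#' Write / read GWAS summary statistics
#'
#' Tab-delimited dialect with header `SNP CHR BP EA NEA EAF BETA SE P N
#' INFO` (a trailing `COHORT` column is preserved when present); missing
#' values are written as `NA`.
#'
#' @param stats Summary-statistics data frame.
#' @param path File path.
#' @export
write_sumstats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("summary statistics file not found: %s", path),
         call. = FALSE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  need <- c("SNP", "CHR", "BP", "EA", "NEA", "EAF", "BETA", "SE", "P", "N",
            "INFO")
  if (!all(need %in% names(df))) {
    stop(sprintf("summary statistics file %s missing columns: %s", path,
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  }
  df
}

#' Estimator-validation simulation spec
#'
#' The canonical scenario used to validate the MR estimator panel: an 8-SNP
#' instrument with exposure effects spread over 0.06--0.20 per SD (so Egger
#' regression's requirement of variation in instrument strength is met and
#' regression dilution is an order of magnitude below the estimator bias of
#' interest), an exposure GWAS of 44,214 individuals, and an independent
#' quantitative outcome GWAS of 11,000 (so outcome-side noise dominates the
#' error model that inverse-variance weights assume). Pleiotropy controls
#' default to zero (valid instruments) and can be planted via `...`.
#'
#' @param seed Integer seed for this replicate.
#' @param causal_beta True causal effect (default 0.3).
#' @param ... Further overrides passed to [gwas_sim_spec()] (for example
#'   `pleiotropy_mean`, `uncorrelated_pleiotropy_sd`, `direct_effects`).
#' @return A [gwas_sim_spec()].
#' @export
mr_validation_spec <- function(seed, causal_beta = 0.3, ...) {
  gwas_sim_spec(n_snps = 8, eaf_range = c(0.1, 0.9),
                exposure_betas = seq(0.06, 0.20, length.out = 8),
                n_exposure = 44214, n_outcome = 11000,
                outcome_type = "quantitative", n_cohorts = 1,
                causal_beta = causal_beta, seed = seed, ...)
}

#' Harmonized instruments from one simulated replicate
#'
#' Convenience wrapper: simulate one two-sample replicate, meta-analyse each
#' side (a no-op pool for single-cohort specs) and harmonize, yielding the
#' instrument set the estimators consume.
#'
#' @param spec A [gwas_sim_spec()].
#' @return A `harmonized_instruments` data frame.
#' @export
simulate_instruments <- function(spec) {
  sim <- simulate_summary_stats(spec)
  harmonize_instruments(fixed_effects_meta(sim$exposure),
                        fixed_effects_meta(sim$outcome))
}
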