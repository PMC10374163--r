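test_that("shape specs validate their fields by name", {
  expect_error(shape_spec(head_radius = -1), "head_radius")
  expect_error(shape_spec(cam_onset_angle = 0), "cam_onset_angle")
  expect_error(shape_spec(cam_onset_angle = 180), "cam_onset_angle")
  expect_error(shape_spec(n_points = 10), "n_points")
  expect_error(shape_spec(neck_half_width = 2), "neck_half_width")
  expect_error(shape_spec(osteophyte_arc = list(start = 10, end = 5,
                                                amplitude = 0.1)),
               "osteophyte_arc")
})

test_that("outline generation is deterministic and ordered with the neck last", {
  sp <- shape_spec(cam_onset_angle = 65, cam_amplitude = 0.2,
                   noise_sd = 0.01, seed = 9)
  o1 <- generate_hip_outline(sp)
  o2 <- generate_hip_outline(sp)
  expect_identical(o1, o2)
  expect_identical(tail(o1$landmark_role, 1), "neck_inferior")
  expect_true(all(c("head", "neck_superior", "neck_inferior", "apex") %in%
                    o1$landmark_role))
  expect_gte(sum(o1$landmark_role == "head"), 3)
})

test_that("outline files round-trip and reads are validated", {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  ol <- cam_outline(angle = 55, seed = 2)
  write_outline(ol, tmp)
  back <- read_outline(tmp)
  expect_equal(back$x, ol$x, tolerance = 1e-12)
  expect_equal(back$landmark_role, ol$landmark_role)

  bad <- tempfile(fileext = ".tsv")
  on.exit(unlink(bad), add = TRUE)
  writeLines(c("point_index\tx\ty\tlandmark_role\tosteophyte_flag",
               "1\t0\t0\televator\t0"), bad)
  expect_error(read_outline(bad), "landmark_role")
  expect_error(read_outline(tempfile()), "not found")
})

test_that("population alpha angles are positively skewed with the configured mean", {
  aa <- aa_population(20000, mean_aa = 47.8, seed = 4)
  expect_lt(abs(mean(aa) - 47.8), 0.5)
  expect_gt(camMR:::sample_skewness(aa), 0)
  aa2 <- aa_population(20000, mean_aa = 52, seed = 4)
  expect_lt(abs(mean(aa2) - 52), 0.5)
})

test_that("toy cohorts recover planted effects within the closed-form OLS error", {
  co <- simulate_cohort(20000, 1, maf = 0.5, beta = 0.2, seed = 7)
  pv <- per_variant_association(co$genotypes, standardize(co$phenotype))
  se_closed <- 1 / sqrt(2 * 0.5 * 0.5 * 20000)
  expect_lt(abs(pv$BETA - 0.2), 3 * se_closed)
  expect_lt(abs(stats::var(co$phenotype) - 1), 0.1)
})

test_that("null cohorts give uniform association P values", {
  co <- simulate_cohort(5000, 2000, maf = 0.3, beta = 0, seed = 8)
  pv <- per_variant_association(co$genotypes, standardize(co$phenotype))
  expect_lt(abs(mean(pv$P < 0.05) - 0.05), 0.015)
})

test_that("degenerate cohort parameters are rejected", {
  expect_error(simulate_cohort(10, 0), "m")
  expect_error(simulate_cohort(0, 5), "n")
  expect_error(simulate_cohort(10, 2, maf = NaN), "maf")
  expect_error(simulate_cohort(10, 2, beta = Inf), "beta")
})

test_that("summary-statistic simulation is deterministic and two-sample", {
  sp <- gwas_sim_spec(causal_beta = 0.2, seed = 21)
  s1 <- simulate_summary_stats(sp)
  s2 <- simulate_summary_stats(sp)
  expect_identical(s1, s2)
  expect_equal(sort(unique(s1$exposure$COHORT)),
               c("exp_cohort1", "exp_cohort2"))
  expect_true(all(s1$exposure$SE > 0))
  expect_true(all(s1$exposure$EAF > 0 & s1$exposure$EAF < 1))
})

test_that("pleiotropy-free defaults give a strong valid instrument", {
  sp <- gwas_sim_spec(seed = 22)
  s <- simulate_summary_stats(sp)
  expect_true(all(s$truth$direct_effects == 0))
  # Expectation check: analytic per-SNP power at the pooled sample size
  # exceeds 0.9 at the genome-wide threshold.
  se_pooled <- camMR:::se_from_eaf_n(s$truth$eaf, sp$n_exposure)
  power <- pnorm(abs(s$truth$beta_exposure) / se_pooled -
                   qnorm(1 - 2.5e-8))
  expect_true(all(power > 0.9))
})

test_that("between-cohort heterogeneity inflates the meta-analysis Q", {
  qs <- vapply(1:40, function(s) {
    sim <- simulate_summary_stats(gwas_sim_spec(
      n_snps = 4, between_cohort_sd = 0.02, seed = s))
    mean(fixed_effects_meta(sim$exposure)$Q)
  }, numeric(1))
  expect_gt(mean(qs), 1)  # null expectation for Q with df = 1
})

test_that("invalid simulation fields are rejected by name", {
  expect_error(gwas_sim_spec(correlated_pleiotropy_frac = 1.2),
               "correlated_pleiotropy_frac")
  expect_error(gwas_sim_spec(eaf_range = c(0.9, 0.1)), "eaf_range")
  expect_error(gwas_sim_spec(n_exposure = NaN), "n_exposure")
})

test_that("LD matrices are block-diagonal, symmetric, unit-diagonal", {
  R <- simulate_ld_matrix(c(3, 3), 0.9)
  expect_equal(dim(R), c(6, 6))
  expect_true(isSymmetric(R))
  expect_equal(unname(diag(R)), rep(1, 6))
  expect_equal(unname(R[1, 2]), 0.9)
  expect_equal(unname(R[1, 4]), 0)
  expect_error(simulate_ld_matrix(c(3, 0)), "block_sizes")
})

test_that("phenotype tables carry coherent outcomes and follow-up", {
  ph <- simulate_phenotype_table(3000, seed = 30)
  expect_equal(mean(ph$z_alpha), 0, tolerance = 1e-10)
  expect_equal(sd(ph$z_alpha), 1, tolerance = 1e-10)
  expect_true(all(ph$fu_time >= 0))
  expect_true(all(ph$thr_event %in% 0:1))
  expect_gt(sum(ph$thr_event), 0)
})
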