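test_that("harmonization aligns outcome effects to the exposure coding", {
  ex <- data.frame(SNP = "rs1", EA = "A", NEA = "G", EAF = 0.3,
                   BETA = 0.1, SE = 0.02, stringsAsFactors = FALSE)
  out <- data.frame(SNP = "rs1", EA = "G", NEA = "A", EAF = 0.7,
                    BETA = 0.05, SE = 0.04, stringsAsFactors = FALSE)
  h <- harmonize_instruments(ex, out)
  expect_equal(h$beta_outcome, -0.05)
  expect_equal(h$eaf_outcome, 0.3)
  expect_equal(h$wald_ratio, -0.5)
})

test_that("palindromic SNPs follow the stated policy", {
  ex <- data.frame(SNP = c("rs1", "rs2"), EA = c("A", "A"),
                   NEA = c("T", "T"), EAF = c(0.5, 0.2), BETA = 0.1,
                   SE = 0.02, stringsAsFactors = FALSE)
  out <- data.frame(SNP = c("rs1", "rs2"), EA = c("A", "A"),
                    NEA = c("T", "T"), EAF = c(0.5, 0.81), BETA = 0.05,
                    SE = 0.04, stringsAsFactors = FALSE)
  # default policy: all palindromic SNPs dropped -> nothing survives rs1/rs2
  expect_error(harmonize_instruments(ex, out), "no SNPs survived")
  # infer policy: ambiguous 0.5 still dropped; rs2 resolved by frequency
  # (opposite sides of 0.5 implies opposite strand reading)
  h <- harmonize_instruments(ex, out, palindrome_policy = "infer")
  expect_equal(h$SNP, "rs2")
  expect_equal(h$beta_outcome, -0.05)
  excl <- attr(h, "exclusions")
  expect_identical(excl$reason[excl$SNP == "rs1"],
                   "palindromic_ambiguous_eaf")
})

test_that("missing outcome SNPs are rescued by a valid proxy with provenance", {
  sim <- simulate_summary_stats(gwas_sim_spec(n_snps = 8, n_cohorts = 1,
                                              causal_beta = 0.2, seed = 31))
  ex <- fixed_effects_meta(sim$exposure)
  out <- fixed_effects_meta(sim$outcome)
  # replace one outcome SNP with a proxy id linked through the LD matrix
  out$SNP[3] <- "rs_proxy"
  ld <- matrix(c(1, 0.77, 0.77, 1), 2,
               dimnames = list(c(ex$SNP[3], "rs_proxy"),
                               c(ex$SNP[3], "rs_proxy")))
  h <- harmonize_instruments(ex, out, ld = ld)
  expect_equal(nrow(h), 8)
  expect_identical(h$proxy_snp[h$SNP == ex$SNP[3]], "rs_proxy")
  expect_equal(h$proxy_r2[h$SNP == ex$SNP[3]], 0.77)
  # without the proxy the SNP is excluded with a reason
  h2 <- harmonize_instruments(ex, out)
  expect_equal(nrow(h2), 7)
  expect_identical(attr(h2, "exclusions")$reason, "missing_in_outcome")
})

test_that("IVW reduces to the Wald ratio for one SNP and is exact on proportional effects", {
  one <- instruments_from(0.2, 0.1)
  est <- mr_ivw(one)
  expect_equal(est$estimate, 0.5)
  expect_equal(est$se, 0.05 / 0.2)
  expect_error(mr_ivw(instruments_from(0, 0.1)), "zero exposure")

  bx <- c(0.1, 0.15, 0.2, 0.3)
  prop <- instruments_from(bx, 2 * bx)
  est2 <- mr_ivw(prop)
  expect_equal(est2$estimate, 2, tolerance = 1e-12)
  expect_equal(est2$Q, 0, tolerance = 1e-20)
})

test_that("Egger regression recovers an exact affine relationship", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  h <- instruments_from(bx, 0.05 + 1.5 * bx)
  est <- mr_egger(h)
  expect_equal(est$estimate, 1.5, tolerance = 1e-10)
  expect_equal(est$egger_intercept, 0.05, tolerance = 1e-10)
  expect_error(mr_egger(instruments_from(c(0.1, 0.2), c(0.1, 0.2))), "3")
})

test_that("Egger regression is invariant to the reported orientation of SNPs", {
  set.seed(32)
  h <- simulate_instruments(mr_validation_spec(101, causal_beta = 0.3,
                                               pleiotropy_mean = 0.02,
                                               uncorrelated_pleiotropy_sd = 0.01))
  flip <- rep(c(1, -1), length.out = nrow(h))
  h_flip <- h
  h_flip$beta_exposure <- h$beta_exposure * flip
  h_flip$beta_outcome <- h$beta_outcome * flip
  e1 <- mr_egger(h)
  e2 <- mr_egger(h_flip)
  expect_equal(e1$estimate, e2$estimate, tolerance = 1e-12)
  expect_equal(e1$egger_intercept, e2$egger_intercept, tolerance = 1e-12)
})

test_that("all estimators agree when every Wald ratio is identical", {
  bx <- c(0.1, 0.2, 0.25, 0.3, 0.4)
  h <- instruments_from(bx, 0.4 * bx)
  expect_equal(mr_ivw(h)$estimate, 0.4, tolerance = 1e-10)
  expect_equal(mr_egger(h)$estimate, 0.4, tolerance = 1e-6)
  expect_equal(mr_weighted_median(h, n_boot = 100, seed = 1)$estimate, 0.4,
               tolerance = 1e-10)
  modes <- mr_mode(h, n_boot = 100, seed = 1)
  expect_equal(modes$estimate, c(0.4, 0.4), tolerance = 1e-6)
})

test_that("bootstrap standard errors are reproducible given the seed", {
  h <- simulate_instruments(mr_validation_spec(77, causal_beta = 0.3))
  a <- mr_weighted_median(h, n_boot = 200, seed = 5)
  b <- mr_weighted_median(h, n_boot = 200, seed = 5)
  expect_identical(a$se, b$se)
  expect_message(mr_weighted_median(h, n_boot = 50, seed = 5), "n_boot")
  m1 <- mr_mode(h, n_boot = 150, seed = 9)
  m2 <- mr_mode(h, n_boot = 150, seed = 9)
  expect_identical(m1$se, m2$se)
})

test_that("mode estimators land in the majority cluster of a bimodal ratio set", {
  bx <- rep(0.2, 10)
  ratios <- c(rep(0.3, 6), rep(0.9, 4)) + seq(-0.01, 0.01, length.out = 10)
  h <- instruments_from(bx, ratios * bx, se_y = 0.02)
  modes <- mr_mode(h, n_boot = 100, seed = 2)
  expect_true(all(abs(modes$estimate - 0.3) < 0.1))
  expect_error(mr_mode(h, phi = 0), "phi")
  # doubling the bandwidth moves the mode only within the cluster spread
  wide <- mr_mode(h, phi = 2, n_boot = 100, seed = 2)
  expect_true(all(abs(wide$estimate - modes$estimate) < 0.6))
})

test_that("instrument strength matches closed forms and a quantile-function oracle", {
  expect_equal(instrument_strength(instruments_from(0.1, 0, se_x = 0.05)), 4)
  # SE recovered from a printed P value: F must equal the squared normal
  # quantile of that P, independent of the effect size
  p <- 7.52e-9
  z <- qnorm(1 - p / 2)
  inst <- data.frame(beta_exposure = 0.04, se_exposure = 0.04 / z)
  expect_equal(instrument_strength(inst), z^2, tolerance = 1e-10)
  tab <- aa_instrument()
  expect_equal(tab$F[tab$SNP == "rs7571789"], z^2, tolerance = 1e-10)
  expect_error(instrument_strength(instruments_from(numeric(0), numeric(0))),
               "empty")
})

test_that("heterogeneity Q is zero for proportional instruments and chi-square under validity", {
  bx <- c(0.1, 0.2, 0.3)
  expect_equal(heterogeneity_q(instruments_from(bx, 3 * bx), "ivw")$Q, 0,
               tolerance = 1e-20)
  qs <- vapply(1:200, function(s) {
    h <- simulate_instruments(mr_validation_spec(4000 + s, causal_beta = 0.3))
    heterogeneity_q(h, "ivw")$Q
  }, numeric(1))
  ks <- suppressWarnings(ks.test(qs, pchisq, df = 7))
  expect_gt(ks$p.value, 0.01)
  expect_error(heterogeneity_q(instruments_from(0.1, 0.2), "ivw"), "2")
})

test_that("leave-one-out analysis isolates a planted outlier SNP", {
  h <- simulate_instruments(mr_validation_spec(55, causal_beta = 0.3))
  h$beta_outcome[4] <- h$beta_outcome[4] + 0.1  # planted driver
  scan <- sensitivity_scan(h)
  expect_equal(nrow(scan$leave_one_out), nrow(h))
  expect_equal(nrow(scan$single_snp), nrow(h))
  full <- mr_ivw(h, method = "fe")$estimate
  shift <- abs(scan$leave_one_out$estimate - full)
  expect_equal(which.max(shift), 4L)
  # dropping the outlier reduces Q more than dropping any other SNP
  q_drop <- vapply(seq_len(nrow(h)), function(i) {
    heterogeneity_q(h[-i, ], "ivw")$Q
  }, numeric(1))
  expect_equal(which.min(q_drop), 4L)
})

test_that("two-SNP leave-one-out rows are single-SNP Wald ratios", {
  h <- instruments_from(c(0.2, 0.4), c(0.1, 0.3))
  scan <- sensitivity_scan(h)
  expect_equal(scan$leave_one_out$estimate, c(0.3 / 0.4, 0.1 / 0.2))
})

test_that("homogeneous instruments keep leave-one-out estimates near the full estimate", {
  h <- simulate_instruments(mr_validation_spec(66, causal_beta = 0.3))
  full <- mr_ivw(h, method = "fe")
  scan <- sensitivity_scan(h, method = "fe")
  expect_true(all(abs(scan$leave_one_out$estimate - full$estimate) <
                    2 * full$se))
})

test_that("the bidirectional report scales the reverse direction per doubling of odds", {
  fwd <- simulate_instruments(mr_validation_spec(88, causal_beta = 0.3))
  rev_h <- simulate_instruments(mr_validation_spec(89, causal_beta = 0.1))
  bi <- bidirectional_mr(fwd, rev_h, n_boot = 100, seed = 3)
  expect_setequal(unique(bi$report$direction), c("forward", "reverse"))
  # doubling all reverse exposure betas halves the reverse estimate
  rev2 <- rev_h
  rev2$beta_exposure <- 2 * rev2$beta_exposure
  rev2$se_exposure <- 2 * rev2$se_exposure
  bi2 <- bidirectional_mr(NULL, rev2, n_boot = 100, seed = 3)
  ivw1 <- bi$reverse$estimate[bi$reverse$method == "IVW"]
  ivw2 <- bi2$reverse$estimate[bi2$reverse$method == "IVW"]
  expect_equal(ivw2, ivw1 / 2, tolerance = 1e-10)
  expect_match(attr(bi2$report, "gap"), "forward")
  expect_error(bidirectional_mr(NULL, NULL), "at least one")
})

test_that("an asymmetric causal architecture yields a one-way signal", {
  fwd <- simulate_instruments(mr_validation_spec(90, causal_beta = 0.3))
  rev_h <- simulate_instruments(mr_validation_spec(91, causal_beta = 0))
  bi <- bidirectional_mr(fwd, rev_h, n_boot = 100, seed = 4)
  ivw_f <- bi$forward[bi$forward$method == "IVW", ]
  ivw_r <- bi$reverse[bi$reverse$method == "IVW", ]
  expect_lt(ivw_f$p, 0.001)
  expect_gt(ivw_r$p, 0.01)
  expect_true(ivw_r$ci_low <= 0 && 0 <= ivw_r$ci_high)
})
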