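test_that("QC keeps boundary values and enumerates drop reasons", {
  rec <- meta_records(rep(0.1, 5), 0.02, snp = sprintf("rs%d", 1:5))
  rec$EAF <- c(0.009, 0.010, 0.5, 0.990, 0.5)
  rec$INFO <- c(1, 1, 0.39, 0.40, 0.40)
  out <- qc_filter(rec)
  expect_equal(out$kept$SNP, c("rs2", "rs4", "rs5"))
  expect_equal(out$dropped$reason, c("maf", "info"))

  both <- rec[1, ]
  both$EAF <- 0.001
  both$INFO <- 0.1
  expect_equal(qc_filter(both)$dropped$reason, "maf;info")

  empty <- qc_filter(rec[0, ])
  expect_equal(nrow(empty$kept), 0)
})

test_that("allele alignment matches an independent truth table over all pairings", {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  bases <- names(comp)
  ref <- data.frame(SNP = "rs1", EA = "A", NEA = "G", BETA = 0.1, EAF = 0.3)
  pairs <- expand.grid(ea = bases, nea = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ea != pairs$nea, ]
  # Independent oracle: compare the record's two strand readings with the
  # reference pair as ordered tuples.
  oracle <- function(ea, nea) {
    if (comp[[ea]] == nea) return(list(status = "palindromic"))
    fwd <- c(ea, nea)
    rev_strand <- c(comp[[ea]], comp[[nea]])
    tgt <- c(ref$EA, ref$NEA)
    if (identical(fwd, tgt)) list(status = "ok", sign = +1)
    else if (identical(rev(fwd), tgt)) list(status = "swapped", sign = -1)
    else if (identical(rev_strand, tgt)) list(status = "strand_flipped",
                                              sign = +1)
    else if (identical(rev(rev_strand), tgt)) list(status = "strand_swapped",
                                                   sign = -1)
    else list(status = "incompatible")
  }
  for (i in seq_len(nrow(pairs))) {
    rec <- data.frame(SNP = "rs1", EA = pairs$ea[i], NEA = pairs$nea[i],
                      BETA = 0.04, EAF = 0.2, stringsAsFactors = FALSE)
    got <- align_alleles(rec, ref)
    want <- oracle(pairs$ea[i], pairs$nea[i])
    expect_identical(got$align_status, want$status,
                     label = sprintf("%s/%s status", pairs$ea[i], pairs$nea[i]))
    if (!is.null(want$sign)) {
      expect_equal(got$BETA, want$sign * 0.04)
      expect_equal(got$EAF, if (want$sign > 0) 0.2 else 0.8)
    }
  }
})

test_that("alignment flags records missing from the reference and foreign alleles", {
  ref <- data.frame(SNP = "rs1", EA = "A", NEA = "G", BETA = 0.1, EAF = 0.3)
  rec <- data.frame(SNP = c("rs1", "rs2"), EA = c("N", "A"),
                    NEA = c("G", "G"), BETA = 0.1, EAF = 0.3,
                    stringsAsFactors = FALSE)
  got <- align_alleles(rec, ref)
  expect_identical(got$align_status, c("incompatible", "missing_reference"))
})

test_that("fixed-effects pooling matches closed forms and an independent meta-analysis fit", {
  m <- fixed_effects_meta(meta_records(c(0.4, 0.2), 0.2))
  expect_equal(m$BETA, 0.3, tolerance = 1e-12)
  expect_equal(m$SE, sqrt(1 / (2 / 0.04)), tolerance = 1e-12)  # 0.1414...
  expect_equal(m$Q, 0.5, tolerance = 1e-12)
  expect_equal(m$I2, 0)
  expect_identical(m$DIRECTION, "++")

  skip_if_not_installed("metafor")
  set.seed(23)
  beta <- rnorm(5, 0.1, 0.05)
  se <- runif(5, 0.02, 0.1)
  ours <- fixed_effects_meta(meta_records(beta, se))
  ref <- metafor::rma(yi = beta, sei = se, method = "FE")
  expect_equal(ours$BETA, as.numeric(ref$beta), tolerance = 1e-8)
  expect_equal(ours$SE, ref$se, tolerance = 1e-8)
  expect_equal(ours$Q, ref$QE, tolerance = 1e-8)
})

test_that("pooling is permutation-invariant, bounded by the inputs, and exact for k = 1", {
  rec <- meta_records(c(0.1, -0.3, 0.25), c(0.05, 0.2, 0.1))
  m1 <- fixed_effects_meta(rec)
  m2 <- fixed_effects_meta(rec[c(3, 1, 2), ])
  expect_equal(m1$BETA, m2$BETA, tolerance = 1e-12)
  expect_equal(m1$Q, m2$Q, tolerance = 1e-12)
  expect_true(m1$BETA >= min(rec$BETA) && m1$BETA <= max(rec$BETA))
  expect_lte(m1$SE, min(rec$SE))

  single <- fixed_effects_meta(meta_records(0.12, 0.03))
  expect_equal(single$BETA, 0.12)
  expect_equal(single$SE, 0.03)
  expect_equal(single$Q, 0)

  k <- 4
  ident <- fixed_effects_meta(meta_records(rep(0.1, k), 0.08))
  expect_equal(ident$SE, 0.08 / sqrt(k), tolerance = 1e-12)
  expect_error(fixed_effects_meta(meta_records(0.1, 0.1)[0, ]),
               "zero cohorts")
})

test_that("genomic inflation is calibrated and tracks constructed inflation", {
  set.seed(24)
  p <- runif(1e5)
  expect_lt(abs(genomic_lambda(p) - 1), 0.02)
  chisq <- qchisq(p, 1, lower.tail = FALSE)
  p_infl <- pchisq(1.1 * chisq, 1, lower.tail = FALSE)
  expect_equal(genomic_lambda(p_infl), 1.1 * genomic_lambda(p),
               tolerance = 1e-6)
  expect_error(genomic_lambda(runif(50)), "100")
  expect_error(genomic_lambda(c(runif(200), 0)), "0, 1")
})

test_that("clumping selects block-minimum-P indices, matching a brute-force oracle", {
  R <- simulate_ld_matrix(c(3, 3), 0.9)
  meta <- data.frame(SNP = rownames(R), CHR = 1L,
                     BP = seq(1e6, by = 1e4, length.out = 6),
                     BETA = 0.1, P = c(1e-9, 1e-12, 1e-10,
                                       1e-15, 1e-9, 1e-11))
  idx <- ld_clump(meta, R, r2_threshold = 0.1)
  block <- rep(1:2, each = 3)
  oracle <- vapply(split(seq_len(6), block), function(ii) {
    meta$SNP[ii][which.min(meta$P[ii])]
  }, character(1))
  expect_setequal(idx$SNP, oracle)
  expect_equal(nrow(idx), 2)

  # no LD at all: every significant variant is its own index
  R0 <- simulate_ld_matrix(c(3, 3), 0)
  idx0 <- ld_clump(meta, R0, r2_threshold = 0.1)
  expect_equal(nrow(idx0), 6)

  none <- ld_clump(transform(meta, P = 0.5), R)
  expect_equal(nrow(none), 0)

  # variants missing from the LD matrix are treated as unlinked and logged
  meta2 <- rbind(meta, data.frame(SNP = "rs_orphan", CHR = 1L, BP = 2e6,
                                  BETA = 0.1, P = 1e-9))
  idx2 <- ld_clump(meta2, R, r2_threshold = 0.1)
  expect_true("rs_orphan" %in% idx2$SNP)
  expect_identical(attr(idx2, "unlinked"), "rs_orphan")
})

test_that("clumping ties break deterministically by position then id", {
  R <- simulate_ld_matrix(c(2), 0.95)
  meta <- data.frame(SNP = rownames(R), CHR = 1L, BP = c(200L, 100L),
                     BETA = 0.1, P = c(1e-10, 1e-10))
  idx <- ld_clump(meta, R, r2_threshold = 0.1)
  expect_identical(idx$SNP, "snp_000002")  # smaller position wins the tie
})

test_that("proxy lookup returns the highest-LD proxy above threshold, else nothing", {
  R <- matrix(c(1, 0.77, 0.65,
                0.77, 1, 0.5,
                0.65, 0.5, 1), 3, 3,
              dimnames = list(c("t", "p1", "p2"), c("t", "p1", "p2")))
  got <- proxy_substitute("t", c("p1", "p2"), R)
  expect_identical(got$snp, "p1")
  expect_equal(got$r2, 0.77)
  expect_null(proxy_substitute("t", "p2", R))
  self <- proxy_substitute("t", c("t", "p1"), R)
  expect_identical(self$snp, "t")
  expect_equal(self$r2, 1)
  expect_error(proxy_substitute("nope", "p1", R), "no LD row")
})

test_that("association scans handle monomorphic variants and covariate overload", {
  co <- simulate_cohort(400, 5, maf = 0.3, beta = 0, seed = 25)
  co$genotypes[, 3] <- 0
  pv <- per_variant_association(co$genotypes, standardize(co$phenotype))
  expect_true(is.na(pv$BETA[3]))
  expect_identical(pv$reason[3], "monomorphic")
  expect_true(all(is.finite(pv$P[-3])))
  expect_error(per_variant_association(co$genotypes[1:4, ],
                                       standardize(co$phenotype)[1:4],
                                       data.frame(a = 1:4, b = 4:1, c = 1:4)),
               "covariates")
})

test_that("covariate adjustment matches per-variant lm fits", {
  co <- simulate_cohort(500, 3, maf = 0.4, beta = c(0.1, 0, -0.1),
                        covariate_effects = c(age = 0.2), seed = 26)
  y <- standardize(co$phenotype)
  pv <- per_variant_association(co$genotypes, y, co$covariates)
  for (j in 1:3) {
    ref <- summary(lm(y ~ co$genotypes[, j] + co$covariates$age))
    expect_equal(pv$BETA[j], ref$coefficients[2, 1], tolerance = 1e-10)
    expect_equal(pv$SE[j], ref$coefficients[2, 2], tolerance = 1e-10)
    expect_equal(pv$P[j], ref$coefficients[2, 4], tolerance = 1e-10)
  }
})

test_that("cross-cohort allele frequencies are guarded", {
  a <- meta_records(0.1, 0.05, snp = "rs1")
  b <- meta_records(0.1, 0.05, snp = "rs1")
  b$EAF <- 0.85
  expect_identical(eaf_consistency_flags(a, b), "rs1")
  expect_length(eaf_consistency_flags(a, a), 0)
})
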