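#' Quality-control filter for summary statistics
#'
#' Removes variants with minor allele frequency below `maf_min` or imputation
#' info below `info_min`; the boundary values themselves are kept. Dropped
#' records carry an enumerated reason.
#'
#' @param records Summary-statistics data frame (`EAF`, `INFO` columns).
#' @param maf_min Minimum minor allele frequency (default 0.01).
#' @param info_min Minimum imputation info score (default 0.4).
#' @return List with `kept` and `dropped` (the latter with a `reason`
#'   column).
#' @export
qc_filter <- function(records, maf_min = 0.01, info_min = 0.4) {
  if (nrow(records) == 0) {
    return(list(kept = records,
                dropped = cbind(records, reason = character(0))))
  }
  if (anyNA(records$EAF) || anyNA(records$INFO)) {
    stop("qc_filter: EAF/INFO contain missing values", call. = FALSE)
  }
  maf <- pmin(records$EAF, 1 - records$EAF)
  bad_maf <- maf < maf_min
  bad_info <- records$INFO < info_min
  reason <- ifelse(bad_maf & bad_info, "maf;info",
                   ifelse(bad_maf, "maf", ifelse(bad_info, "info", "")))
  keep <- !(bad_maf | bad_info)
  dropped <- records[!keep, , drop = FALSE]
  dropped$reason <- reason[!keep]
  list(kept = records[keep, , drop = FALSE], dropped = dropped)
}

ALLELE_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Align a record's alleles to a reference record
#'
#' Harmonizes effect/non-effect allele coding against a reference: swapped
#' alleles flip the sign of `BETA` and the frequency; strand-flipped
#' (complementary) codings are resolved without a sign change;
#' strand-flipped *and* swapped codings get both. Palindromic variants
#' (A/T, C/G) cannot be strand-resolved and are flagged for the MR-stage
#' policy; irreconcilable pairs are flagged incompatible.
#'
#' @param record Data frame of records to align (columns `SNP EA NEA BETA
#'   EAF`).
#' @param reference Data frame with the reference coding (matched by `SNP`).
#' @return `record` with `EA/NEA/BETA/EAF` harmonized and an added
#'   `align_status` column, one of `ok`, `swapped`, `strand_flipped`,
#'   `strand_swapped`, `palindromic`, `incompatible`, `missing_reference`.
#' @export
align_alleles <- function(record, reference) {
  idx <- match(record$SNP, reference$SNP)
  status <- character(nrow(record))
  for (i in seq_len(nrow(record))) {
    if (is.na(idx[i])) {
      status[i] <- "missing_reference"
      next
    }
    ea <- record$EA[i]; nea <- record$NEA[i]
    rea <- reference$EA[idx[i]]; rnea <- reference$NEA[idx[i]]
    if (!all(c(ea, nea, rea, rnea) %in% names(ALLELE_COMPLEMENT))) {
      status[i] <- "incompatible"
      next
    }
    if (ea == ALLELE_COMPLEMENT[[nea]]) {
      # A/T or C/G: strand orientation is unidentifiable from alleles alone.
      status[i] <- "palindromic"
      if (identical(c(ea, nea), c(rnea, rea))) {
        record$BETA[i] <- -record$BETA[i]
        record$EAF[i] <- 1 - record$EAF[i]
        record$EA[i] <- rea; record$NEA[i] <- rnea
      }
      next
    }
    cea <- ALLELE_COMPLEMENT[[ea]]; cnea <- ALLELE_COMPLEMENT[[nea]]
    if (ea == rea && nea == rnea) {
      status[i] <- "ok"
    } else if (ea == rnea && nea == rea) {
      status[i] <- "swapped"
      record$BETA[i] <- -record$BETA[i]
      record$EAF[i] <- 1 - record$EAF[i]
      record$EA[i] <- rea; record$NEA[i] <- rnea
    } else if (cea == rea && cnea == rnea) {
      status[i] <- "strand_flipped"
      record$EA[i] <- rea; record$NEA[i] <- rnea
    } else if (cea == rnea && cnea == rea) {
      status[i] <- "strand_swapped"
      record$BETA[i] <- -record$BETA[i]
      record$EAF[i] <- 1 - record$EAF[i]
      record$EA[i] <- rea; record$NEA[i] <- rnea
    } else {
      status[i] <- "incompatible"
    }
  }
  record$align_status <- status
  record
}

#' Per-variant association scan
#'
#' Linear model of a standardized trait on allele count, residualizing both
#' the trait and the genotypes on the covariates first (equivalent to
#' including them in the model), vectorized across variants and processed in
#' chunks so genome-sized scans stay in memory. Monomorphic variants are
#' emitted with `NA` results and a reason rather than dropped.
#'
#' @param genotypes n x m matrix of allele counts.
#' @param phenotype Standardized phenotype vector.
#' @param covariates Optional data frame of covariates.
#' @param n_label Sample size recorded in the output (defaults to the row
#'   count).
#' @return Summary-statistics data frame: `SNP EAF BETA SE P N INFO reason`.
#' @export
per_variant_association <- function(genotypes, phenotype, covariates = NULL,
                                    n_label = NULL) {
  G <- as.matrix(genotypes)
  n <- nrow(G)
  m <- ncol(G)
  q <- if (is.null(covariates)) 0L else ncol(covariates)
  if (n <= q + 2) {
    stop("per_variant_association: more covariates than informative samples",
         call. = FALSE)
  }
  y <- phenotype
  X0 <- cbind(rep(1, n), if (q > 0) as.matrix(covariates))
  qr0 <- qr(X0)
  y_r <- qr.resid(qr0, y)
  df_resid <- n - q - 2L

  snp <- colnames(G) %||% sprintf("snp_%05d", seq_len(m))
  beta <- se <- p <- rep(NA_real_, m)
  reason <- rep(NA_character_, m)
  chunk <- 10000L
  for (start in seq(1L, m, by = chunk)) {
    idx <- start:min(start + chunk - 1L, m)
    Gc <- qr.resid(qr0, G[, idx, drop = FALSE])
    sxx <- colSums(Gc^2)
    mono <- sxx < 1e-12
    sxy <- colSums(Gc * y_r)
    b <- ifelse(mono, NA_real_, sxy / sxx)
    rss <- sum(y_r^2) - b^2 * sxx
    s2 <- pmax(rss, 0) / df_resid
    se_c <- sqrt(s2 / sxx)
    tstat <- b / se_c
    beta[idx] <- b
    se[idx] <- ifelse(mono, NA_real_, se_c)
    p[idx] <- ifelse(mono, NA_real_,
                     2 * stats::pt(abs(tstat), df_resid, lower.tail = FALSE))
    reason[idx] <- ifelse(mono, "monomorphic", NA_character_)
  }
  data.frame(SNP = snp, EAF = colMeans(G) / 2, BETA = beta, SE = se, P = p,
             N = n_label %||% n, INFO = 1, reason = reason,
             stringsAsFactors = FALSE)
}

#' Fixed-effects inverse-variance meta-analysis
#'
#' Pools per-cohort effect estimates with weights `1/SE^2`. Heterogeneity is
#' summarized by Cochran's Q (with `df = k - 1`) and
#' `I2 = max(0, (Q - df)/Q) * 100`. A per-cohort direction string (`"+-"`
#' style) is recorded. Extreme pooled P values are additionally stored as
#' `log10(P)` to avoid underflow.
#'
#' @param records Long summary-statistics data frame across cohorts (one row
#'   per SNP x cohort, allele codings already aligned).
#' @return Data frame with one row per SNP: pooled `BETA`, `SE`, `P`,
#'   `LOG10P`, `Q`, `DF`, `Q_P`, `I2`, `DIRECTION`, `N`, plus pass-through
#'   `CHR BP EA NEA EAF INFO` from the first cohort seen.
#' @export
fixed_effects_meta <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    stop("fixed_effects_meta: zero cohorts supplied", call. = FALSE)
  }
  check_num(records$SE, "SE", lower = 0, strict_lower = TRUE)
  split_idx <- split(seq_len(nrow(records)), records$SNP)
  # Preserve first-appearance SNP order rather than alphabetical.
  split_idx <- split_idx[unique(records$SNP)]
  rows <- lapply(split_idx, function(ii) {
    sub <- records[ii, , drop = FALSE]
    w <- 1 / sub$SE^2
    pooled <- sum(w * sub$BETA) / sum(w)
    se <- 1 / sqrt(sum(w))
    k <- nrow(sub)
    q <- sum(w * (sub$BETA - pooled)^2)
    df <- k - 1L
    z <- pooled / se
    log10p <- (log(2) + stats::pnorm(abs(z), lower.tail = FALSE,
                                     log.p = TRUE)) / log(10)
    data.frame(
      SNP = sub$SNP[1],
      CHR = sub$CHR[1] %||% NA, BP = sub$BP[1] %||% NA,
      EA = sub$EA[1] %||% NA, NEA = sub$NEA[1] %||% NA,
      EAF = sum(w * sub$EAF) / sum(w),
      BETA = pooled, SE = se, P = p_from_z(z), LOG10P = log10p,
      Q = q, DF = df,
      Q_P = if (df > 0) stats::pchisq(q, df, lower.tail = FALSE) else NA_real_,
      I2 = if (q > 0) max(0, (q - df) / q) * 100 else 0,
      DIRECTION = paste(ifelse(sub$BETA >= 0, "+", "-"), collapse = ""),
      N = sum(sub$N), INFO = min(sub$INFO %||% 1),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genomic inflation factor
#'
#' Lambda is the median association chi-square statistic divided by the
#' median of the null chi-square(1) distribution (0.4549...): values above 1
#' indicate test-statistic inflation from confounding or polygenicity.
#'
#' @param p_values At least 100 P values in (0, 1\].
#' @return Lambda (scalar).
#' @export
genomic_lambda <- function(p_values) {
  if (length(p_values) < 100) {
    stop("genomic_lambda: need at least 100 P values", call. = FALSE)
  }
  if (anyNA(p_values) || any(p_values <= 0 | p_values > 1)) {
    stop("genomic_lambda: P values must lie in (0, 1]", call. = FALSE)
  }
  chisq <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Greedy LD clumping
#'
#' Repeatedly takes the smallest-P unclaimed variant below `p_threshold` as
#' an index SNP and claims every variant within `window_kb` of it whose LD
#' r-squared with the index is at least `r2_threshold`. Ties on P are broken
#' by position, then lexicographic id, so the result is deterministic.
#' Variants absent from the LD matrix are treated as unlinked and logged in
#' the `unlinked` attribute.
#'
#' @param meta Meta-analysis results (`SNP CHR BP P` columns).
#' @param ld Symmetric r-squared matrix with variant ids as dimnames.
#' @param p_threshold Significance threshold for index SNPs (default 5e-8).
#' @param r2_threshold r-squared above which variants are claimed (default
#'   0.001, the conventional instrument-selection setting).
#' @param window_kb Claim window around the index in kilobases (default
#'   10000).
#' @return The index-SNP rows of `meta`, in selection order.
#' @export
ld_clump <- function(meta, ld, p_threshold = 5e-8, r2_threshold = 0.001,
                     window_kb = 10000) {
  cand <- meta[is.finite(meta$P) & meta$P < p_threshold, , drop = FALSE]
  if (nrow(cand) == 0) return(cand)
  ord <- order(cand$P, cand$BP, cand$SNP)
  cand <- cand[ord, , drop = FALSE]
  in_ld_matrix <- cand$SNP %in% rownames(ld)
  unlinked <- cand$SNP[!in_ld_matrix]
  claimed <- rep(FALSE, nrow(cand))
  keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (claimed[i]) next
    keep <- c(keep, i)
    claimed[i] <- TRUE
    if (!in_ld_matrix[i]) next
    same_chr <- cand$CHR == cand$CHR[i]
    in_window <- same_chr & abs(cand$BP - cand$BP[i]) <= window_kb * 1000
    for (j in seq_len(nrow(cand))) {
      if (claimed[j] || !in_window[j] || !in_ld_matrix[j]) next
      if (ld[cand$SNP[i], cand$SNP[j]] >= r2_threshold) claimed[j] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unlinked") <- unlinked
  out
}

#' Proxy substitution by LD
#'
#' Returns the available variant in highest LD with the target, provided its
#' r-squared reaches `min_r2`; otherwise `NULL` (absence is a valid
#' outcome). The target itself, when available, is its own proxy (r2 = 1).
#'
#' @param target Variant id.
#' @param available Character vector of variant ids present in the other
#'   data set.
#' @param ld Symmetric r-squared matrix with variant ids as dimnames.
#' @param min_r2 Minimum acceptable r-squared (default 0.7).
#' @return List `(snp, r2)` or `NULL`.
#' @export
proxy_substitute <- function(target, available, ld, min_r2 = 0.7) {
  if (!target %in% rownames(ld)) {
    stop(sprintf("proxy_substitute: no LD row for target %s", target),
         call. = FALSE)
  }
  if (target %in% available) return(list(snp = target, r2 = 1))
  avail <- intersect(available, colnames(ld))
  if (!length(avail)) return(NULL)
  r2 <- ld[target, avail]
  best <- which.max(r2)
  if (r2[best] < min_r2) return(NULL)
  list(snp = avail[best], r2 = unname(r2[best]))
}

#' Cross-cohort allele-frequency consistency check
#'
#' Flags SNPs whose effect-allele frequency differs between two cohorts by
#' more than `tol` after alignment, a light-weight harmonization guard.
#'
#' @param a,b Aligned summary-statistics data frames.
#' @param tol Maximum tolerated absolute EAF difference (default 0.2).
#' @return Character vector of flagged SNP ids.
#' @export
eaf_consistency_flags <- function(a, b, tol = 0.2) {
  common <- intersect(a$SNP, b$SNP)
  da <- a$EAF[match(common, a$SNP)]
  db <- b$EAF[match(common, b$SNP)]
  common[abs(da - db) > tol]
}
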