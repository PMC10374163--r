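#' Harmonize exposure and outcome summary statistics into MR instruments
#'
#' Matches each exposure instrument SNP to the outcome GWAS, aligns the
#' outcome allele coding to the exposure coding via [align_alleles()], and
#' applies the palindromic-SNP policy. SNPs absent from the outcome data can
#' be rescued by an LD proxy via [proxy_substitute()]; proxy provenance is
#' recorded. Every exclusion carries a reason code in the `exclusions`
#' attribute; nothing is silently dropped.
#'
#' @param exposure Exposure summary statistics (the instrument SNPs).
#' @param outcome Outcome summary statistics.
#' @param palindrome_policy `"drop"` removes palindromic SNPs (default);
#'   `"infer"` keeps them when both allele frequencies are far from 0.5
#'   (outside 0.42--0.58) and resolves strand by frequency.
#' @param ld Optional LD r-squared matrix for proxy lookup.
#' @param min_proxy_r2 Minimum proxy r-squared (default 0.7).
#' @return Data frame of class `harmonized_instruments`: `SNP`,
#'   `beta_exposure`, `se_exposure`, `eaf_exposure`, `beta_outcome`,
#'   `se_outcome`, `eaf_outcome`, `wald_ratio`, `palindromic`, `proxy_snp`,
#'   `proxy_r2`; attribute `exclusions`.
#' @export
harmonize_instruments <- function(exposure, outcome,
                                  palindrome_policy = c("drop", "infer"),
                                  ld = NULL, min_proxy_r2 = 0.7) {
  palindrome_policy <- match.arg(palindrome_policy)
  excl <- list()
  rows <- list()
  for (i in seq_len(nrow(exposure))) {
    ex <- exposure[i, ]
    proxy_snp <- NA_character_
    proxy_r2 <- NA_real_
    j <- match(ex$SNP, outcome$SNP)
    if (is.na(j) && !is.null(ld) && ex$SNP %in% rownames(ld)) {
      pr <- proxy_substitute(ex$SNP, outcome$SNP, ld, min_proxy_r2)
      if (!is.null(pr)) {
        j <- match(pr$snp, outcome$SNP)
        proxy_snp <- pr$snp
        proxy_r2 <- pr$r2
      }
    }
    if (is.na(j)) {
      excl[[length(excl) + 1]] <-
        data.frame(SNP = ex$SNP, reason = "missing_in_outcome")
      next
    }
    out <- outcome[j, ]
    if (is.na(proxy_snp)) {
      al <- align_alleles(out, ex)
      status <- al$align_status
      if (status == "incompatible" || status == "missing_reference") {
        excl[[length(excl) + 1]] <-
          data.frame(SNP = ex$SNP, reason = "incompatible_alleles")
        next
      }
      out <- al
    } else {
      status <- "proxy"
    }
    palindromic <- identical(status, "palindromic")
    if (palindromic) {
      if (palindrome_policy == "drop") {
        excl[[length(excl) + 1]] <-
          data.frame(SNP = ex$SNP, reason = "palindromic")
        next
      }
      ambiguous <- function(f) f > 0.42 & f < 0.58
      if (ambiguous(ex$EAF) || ambiguous(out$EAF)) {
        excl[[length(excl) + 1]] <-
          data.frame(SNP = ex$SNP, reason = "palindromic_ambiguous_eaf")
        next
      }
      if ((ex$EAF < 0.5) != (out$EAF < 0.5)) {
        # Frequencies on opposite sides of 0.5: opposite strand reading.
        out$BETA <- -out$BETA
        out$EAF <- 1 - out$EAF
      }
    }
    rows[[length(rows) + 1]] <- data.frame(
      SNP = ex$SNP,
      beta_exposure = ex$BETA, se_exposure = ex$SE, eaf_exposure = ex$EAF,
      beta_outcome = out$BETA, se_outcome = out$SE, eaf_outcome = out$EAF,
      wald_ratio = out$BETA / ex$BETA,
      palindromic = palindromic, proxy_snp = proxy_snp, proxy_r2 = proxy_r2,
      stringsAsFactors = FALSE)
  }
  h <- if (length(rows)) do.call(rbind, rows) else NULL
  if (is.null(h) || nrow(h) == 0) {
    stop("harmonize_instruments: no SNPs survived harmonization",
         call. = FALSE)
  }
  check_num(h$se_exposure, "se_exposure", lower = 0, strict_lower = TRUE)
  check_num(h$se_outcome, "se_outcome", lower = 0, strict_lower = TRUE)
  attr(h, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(SNP = character(0), reason = character(0))
  class(h) <- c("harmonized_instruments", "data.frame")
  h
}

mr_estimate_row <- function(method, est, se, p, n_snps, diagnostics = list()) {
  row <- data.frame(method = method, estimate = est, se = se,
                    ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
                    p = p, or = exp(est), n_snps = n_snps,
                    stringsAsFactors = FALSE)
  for (nm in names(diagnostics)) row[[nm]] <- diagnostics[[nm]]
  class(row) <- c("mr_estimate", "data.frame")
  row
}

#' Inverse-variance weighted MR estimate
#'
#' Slope of the outcome effects on the exposure effects through the origin
#' with weights `1/se_outcome^2`. With a single SNP this reduces exactly to
#' the Wald ratio. The default flavour inflates the fixed-effect standard
#' error by `sqrt(Q/df)` when Cochran's Q exceeds its degrees of freedom
#' (multiplicative random effects); `method = "fe"` keeps the fixed-effect
#' SE, `method = "re"` always inflates.
#'
#' @param instruments A `harmonized_instruments` data frame (or anything
#'   with `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`).
#' @param method `"re_switch"` (default), `"fe"`, or `"re"`.
#' @return One-row `mr_estimate` data frame with diagnostics `Q`, `Q_df`,
#'   `Q_p`, `mean_F`.
#' @export
mr_ivw <- function(instruments, method = c("re_switch", "fe", "re")) {
  method <- match.arg(method)
  h <- instruments
  n <- nrow(h)
  if (n < 1) stop("mr_ivw: need at least 1 SNP", call. = FALSE)
  if (n == 1 && h$beta_exposure[1] == 0) {
    stop("mr_ivw: single SNP with zero exposure effect", call. = FALSE)
  }
  w <- 1 / h$se_outcome^2
  bx <- h$beta_exposure; by <- h$beta_outcome
  b <- sum(w * bx * by) / sum(w * bx^2)
  se_fe <- 1 / sqrt(sum(w * bx^2))
  q <- sum(w * (by - b * bx)^2)
  df <- n - 1L
  infl <- if (df > 0) sqrt(q / df) else 1
  se <- switch(method,
               fe = se_fe,
               re = se_fe * max(infl, 1e-12),
               re_switch = se_fe * max(1, infl))
  mr_estimate_row("IVW", b, se, p_from_z(b / se), n,
                  list(Q = q, Q_df = df,
                       Q_p = if (df > 0) stats::pchisq(q, df, lower.tail = FALSE)
                             else NA_real_,
                       mean_F = instrument_strength(h)))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome effects on exposure effects with a free
#' intercept (weights `1/se_outcome^2`). Exposure effects are oriented
#' positive first (flipping the paired outcome effect), since Egger
#' regression is not orientation-invariant. The intercept estimates the
#' average directional pleiotropy; its test is reported alongside the slope.
#' Standard errors use the multiplicative random-effects model with the
#' residual dispersion floored at 1; P values use the t distribution with
#' `n - 2` df. Rucker's Q about the Egger fit is reported.
#'
#' @param instruments A `harmonized_instruments` data frame with >= 3 SNPs.
#' @return One-row `mr_estimate` with diagnostics `egger_intercept`,
#'   `intercept_se`, `intercept_p`, `Q` (Rucker), `Q_df`, `Q_p`, `mean_F`.
#' @export
mr_egger <- function(instruments) {
  h <- instruments
  n <- nrow(h)
  if (n < 3) stop("mr_egger: need at least 3 SNPs", call. = FALSE)
  flip <- sign(h$beta_exposure)
  flip[flip == 0] <- 1
  bx <- h$beta_exposure * flip
  by <- h$beta_outcome * flip
  w <- 1 / h$se_outcome^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  sigma <- sm$sigma
  adj <- max(1, sigma) / sigma   # multiplicative RE with dispersion floor 1
  slope <- sm$coefficients["bx", 1]
  slope_se <- sm$coefficients["bx", 2] * adj
  inter <- sm$coefficients["(Intercept)", 1]
  inter_se <- sm$coefficients["(Intercept)", 2] * adj
  df <- n - 2L
  q <- sum(w * stats::residuals(fit)^2)
  pt2 <- function(t) 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  mr_estimate_row("MR-Egger", slope, slope_se, pt2(slope / slope_se), n,
                  list(egger_intercept = inter, intercept_se = inter_se,
                       intercept_p = pt2(inter / inter_se),
                       Q = q, Q_df = df,
                       Q_p = stats::pchisq(q, df, lower.tail = FALSE),
                       mean_F = instrument_strength(h)))
}

weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(r)])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

boot_instruments <- function(h) {
  data.frame(beta_exposure = stats::rnorm(nrow(h), h$beta_exposure,
                                          h$se_exposure),
             se_exposure = h$se_exposure,
             beta_outcome = stats::rnorm(nrow(h), h$beta_outcome,
                                         h$se_outcome),
             se_outcome = h$se_outcome)
}

#' Weighted median MR estimate
#'
#' Weighted median of the per-SNP Wald ratios with inverse-variance weights:
#' consistent as long as valid instruments contribute more than half of the
#' total weight. The standard error comes from a seeded parametric
#' bootstrap.
#'
#' @param instruments A `harmonized_instruments` data frame with >= 3 SNPs.
#' @param n_boot Bootstrap replicates (default 1000; values below 100 are
#'   accepted with a logged note).
#' @param seed Integer seed for the bootstrap.
#' @return One-row `mr_estimate`.
#' @export
mr_weighted_median <- function(instruments, n_boot = 1000, seed = 1) {
  h <- instruments
  n <- nrow(h)
  if (n < 3) stop("mr_weighted_median: need at least 3 SNPs", call. = FALSE)
  if (n_boot < 100) {
    message("mr_weighted_median: n_boot < 100 gives unstable standard errors")
  }
  ratios <- h$beta_outcome / h$beta_exposure
  w <- (h$beta_exposure / h$se_outcome)^2
  est <- weighted_median_point(ratios, w)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    hb <- boot_instruments(h)
    rb <- hb$beta_outcome / hb$beta_exposure
    wb <- (hb$beta_exposure / hb$se_outcome)^2
    weighted_median_point(rb, wb)
  }, numeric(1))
  se <- stats::sd(boots)
  mr_estimate_row("Weighted median", est, se, p_from_z(est / se), n,
                  list(mean_F = instrument_strength(h)))
}

kernel_mode <- function(ratios, weights, bw) {
  if (stats::sd(ratios) == 0) return(ratios[1])
  w <- weights / sum(weights)
  d <- stats::density(ratios, weights = w, bw = bw, n = 2048,
                      from = min(ratios) - 3 * bw, to = max(ratios) + 3 * bw)
  d$x[which.max(d$y)]
}

#' Simple and weighted mode MR estimates
#'
#' Mode of the smoothed empirical density of the per-SNP Wald ratios,
#' unweighted (simple mode) and inverse-variance weighted (weighted mode),
#' with a normal kernel whose bandwidth is `phi` times the modified Silverman
#' rule `0.9 min(sd, mad) n^(-1/5)`. Consistent when the largest cluster of
#' ratios comes from valid instruments. Bootstrap standard errors are
#' seeded.
#'
#' @param instruments A `harmonized_instruments` data frame with >= 3 SNPs.
#' @param phi Bandwidth scale factor (> 0, default 1).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return Two-row `mr_estimate` data frame (simple mode, weighted mode).
#' @export
mr_mode <- function(instruments, phi = 1, n_boot = 1000, seed = 1) {
  h <- instruments
  n <- nrow(h)
  if (n < 3) stop("mr_mode: need at least 3 SNPs", call. = FALSE)
  check_num(phi, "phi", lower = 0, strict_lower = TRUE, len = 1)
  ratios <- h$beta_outcome / h$beta_exposure
  se_r <- abs(h$se_outcome / h$beta_exposure)
  w_inv <- 1 / se_r^2
  bw_of <- function(r) {
    s <- 0.9 * min(stats::sd(r), stats::mad(r)) * length(r)^(-1 / 5)
    if (s == 0) s <- 1e-8
    phi * s
  }
  est_simple <- kernel_mode(ratios, rep(1, n), bw_of(ratios))
  est_weighted <- kernel_mode(ratios, w_inv, bw_of(ratios))
  set.seed(seed)
  boots <- matrix(NA_real_, n_boot, 2)
  for (b in seq_len(n_boot)) {
    hb <- boot_instruments(h)
    rb <- hb$beta_outcome / hb$beta_exposure
    wb <- 1 / (hb$se_outcome / hb$beta_exposure)^2
    bwb <- bw_of(rb)
    boots[b, 1] <- kernel_mode(rb, rep(1, n), bwb)
    boots[b, 2] <- kernel_mode(rb, wb, bwb)
  }
  se_s <- stats::sd(boots[, 1])
  se_w <- stats::sd(boots[, 2])
  rbind(
    mr_estimate_row("Simple mode", est_simple, se_s,
                    p_from_z(est_simple / se_s), n,
                    list(mean_F = instrument_strength(h))),
    mr_estimate_row("Weighted mode", est_weighted, se_w,
                    p_from_z(est_weighted / se_w), n,
                    list(mean_F = instrument_strength(h))))
}

#' Mean instrument-strength F statistic
#'
#' Per-SNP `F = (beta_exposure / se_exposure)^2`, averaged; mean F below ~10
#' signals weak-instrument bias.
#'
#' @param instruments A `harmonized_instruments` data frame.
#' @return Scalar mean F.
#' @export
instrument_strength <- function(instruments) {
  if (nrow(instruments) < 1) {
    stop("instrument_strength: empty instrument", call. = FALSE)
  }
  mean((instruments$beta_exposure / instruments$se_exposure)^2)
}

#' Heterogeneity Q statistics
#'
#' Cochran's Q about the fixed-effect IVW slope (`df = n - 1`) or Rucker's Q
#' about the MR-Egger fit (`df = n - 2`), with the chi-square P value.
#'
#' @param instruments A `harmonized_instruments` data frame.
#' @param method `"ivw"` or `"egger"`.
#' @return List `(Q, df, p)`.
#' @export
heterogeneity_q <- function(instruments, method = c("ivw", "egger")) {
  method <- match.arg(method)
  n <- nrow(instruments)
  if (method == "ivw") {
    if (n < 2) stop("heterogeneity_q: IVW Q needs >= 2 SNPs", call. = FALSE)
    est <- mr_ivw(instruments, method = "fe")
    list(Q = est$Q, df = est$Q_df, p = est$Q_p)
  } else {
    if (n < 3) stop("heterogeneity_q: Egger Q needs >= 3 SNPs", call. = FALSE)
    est <- mr_egger(instruments)
    list(Q = est$Q, df = est$Q_df, p = est$Q_p)
  }
}

#' Leave-one-out and single-SNP sensitivity analyses
#'
#' Re-estimates the causal effect with each SNP left out in turn, and
#' reports each SNP's own Wald ratio with its first-order standard error;
#' both tables are suitable for forest plotting.
#'
#' @param instruments A `harmonized_instruments` data frame with >= 2 SNPs.
#' @param method IVW flavour passed to [mr_ivw()].
#' @return List with `leave_one_out` and `single_snp` data frames.
#' @export
sensitivity_scan <- function(instruments, method = "re_switch") {
  h <- instruments
  n <- nrow(h)
  if (n < 2) stop("sensitivity_scan: need >= 2 SNPs", call. = FALSE)
  loo <- do.call(rbind, lapply(seq_len(n), function(i) {
    est <- mr_ivw(h[-i, , drop = FALSE], method = method)
    data.frame(excluded = h$SNP[i] %||% as.character(i),
               estimate = est$estimate, se = est$se, p = est$p,
               stringsAsFactors = FALSE)
  }))
  single <- data.frame(SNP = h$SNP %||% as.character(seq_len(n)),
                       estimate = h$beta_outcome / h$beta_exposure,
                       se = abs(h$se_outcome / h$beta_exposure),
                       stringsAsFactors = FALSE)
  single$p <- p_from_z(single$estimate / single$se)
  list(leave_one_out = loo, single_snp = single)
}

#' Run the full MR estimator panel
#'
#' IVW, MR-Egger, weighted median, simple mode and weighted mode on one
#' harmonized instrument set, in the layout of a bidirectional MR results
#' table.
#'
#' @param instruments A `harmonized_instruments` data frame.
#' @param ivw_method IVW flavour (see [mr_ivw()]).
#' @param n_boot,seed Bootstrap settings for median/mode estimators.
#' @return `mr_estimate` data frame with one row per method.
#' @export
mr_all <- function(instruments, ivw_method = "re_switch", n_boot = 1000,
                   seed = 1) {
  rows <- list(mr_ivw(instruments, method = ivw_method))
  if (nrow(instruments) >= 3) {
    rows <- c(rows, list(mr_egger(instruments),
                         mr_weighted_median(instruments, n_boot, seed),
                         mr_mode(instruments, 1, n_boot, seed)))
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(c("egger_intercept", "intercept_se", "intercept_p",
                      "Q", "Q_df", "Q_p", "mean_F"), names(r))
    for (nm in miss) r[[nm]] <- NA_real_
    r
  }))
  rownames(out) <- NULL
  out
}

#' Bidirectional two-sample MR
#'
#' Runs the estimator panel in both directions. The forward direction
#' (shape trait to disease) is reported as an odds ratio per SD of the
#' exposure. In the reverse direction the binary-disease instrument effects
#' are log odds; they are rescaled by `ln 2` so estimates read "SD change in
#' the quantitative trait per doubling in odds of the disease".
#'
#' @param forward Harmonized instruments for the forward direction (or
#'   `NULL` if that direction is unavailable).
#' @param reverse Harmonized instruments for the reverse direction (binary
#'   exposure on the log-odds scale), or `NULL`.
#' @param ivw_method,n_boot,seed Passed to [mr_all()].
#' @return List with `forward`, `reverse` estimate tables (either may be
#'   `NULL`, in which case the gap is stated in `report`) and a combined
#'   `report` data frame.
#' @export
bidirectional_mr <- function(forward = NULL, reverse = NULL,
                             ivw_method = "re_switch", n_boot = 1000,
                             seed = 1) {
  if (is.null(forward) && is.null(reverse)) {
    stop("bidirectional_mr: at least one direction is required",
         call. = FALSE)
  }
  fwd <- rev_tab <- NULL
  if (!is.null(forward)) {
    fwd <- mr_all(forward, ivw_method, n_boot, seed)
    fwd$direction <- "forward"
    fwd$scale <- "OR per SD of exposure"
  }
  if (!is.null(reverse)) {
    rv <- reverse
    # Log-odds exposure effects expressed per doubling in odds (ln 2).
    rv$beta_exposure <- rv$beta_exposure / log(2)
    rv$se_exposure <- rv$se_exposure / log(2)
    rv$wald_ratio <- rv$beta_outcome / rv$beta_exposure
    rev_tab <- mr_all(rv, ivw_method, n_boot, seed)
    rev_tab$direction <- "reverse"
    rev_tab$scale <- "SD of outcome per doubling in odds of exposure"
  }
  report <- rbind(fwd, rev_tab)
  if (is.null(fwd)) attr(report, "gap") <- "forward direction unavailable"
  if (is.null(rev_tab)) attr(report, "gap") <- "reverse direction unavailable"
  list(forward = fwd, reverse = rev_tab, report = report)
}
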