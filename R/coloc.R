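#' Approximate Bayes factor for one association
#'
#' Wakefield-style log approximate Bayes factor comparing an association
#' with prior effect SD `prior_sd` against the null:
#' `log ABF = 0.5 * (log(se^2/(se^2+W^2)) + z^2 * W^2/(se^2+W^2))` with
#' `z = beta/se` and `W = prior_sd`. Evaluated in log space so it is stable
#' for very large z.
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s) (> 0).
#' @param prior_sd Prior effect SD (> 0); conventional values are 0.15 for
#'   quantitative traits and 0.2 for binary-trait log odds.
#' @return Log ABF (vectorized).
#' @export
approx_bayes_factor <- function(beta, se, prior_sd) {
  check_num(beta, "beta")
  check_num(se, "se", lower = 0, strict_lower = TRUE)
  check_num(prior_sd, "prior_sd", lower = 0, strict_lower = TRUE)
  z <- beta / se
  r <- prior_sd^2 / (se^2 + prior_sd^2)
  0.5 * (log(se^2 / (se^2 + prior_sd^2)) + z^2 * r)
}

#' Colocalization posterior probabilities for a locus pair
#'
#' Single-causal-variant colocalization of two traits from per-variant
#' summary statistics: per-variant log ABFs are combined over the five
#' hypotheses (H0 no association; H1/H2 one trait only; H3 two distinct
#' causal variants; H4 one shared causal variant) with prior probabilities
#' `p1`, `p2`, `p12`, using log-sum-exp throughout. The call is
#' `"colocalized"` when PP4 exceeds 0.80, `"suggestive"` when it exceeds
#' 0.60, otherwise `"none"` (strict inequalities).
#'
#' @param trait1,trait2 Data frames with `SNP`, `BETA`, `SE` for the same
#'   locus.
#' @param p1,p2 Prior probability that a variant is causal for trait 1 /
#'   trait 2 only (defaults 1e-4).
#' @param p12 Prior probability that a variant is causal for both (default
#'   1e-5).
#' @param prior_sd1,prior_sd2 ABF prior SDs per trait (defaults 0.15).
#' @param locus Locus label.
#' @return List of class `coloc_result`: `locus`, `pp` (named PP0..PP4),
#'   `n_variants`, `call`, and the per-variant log ABFs.
#' @export
coloc_pp <- function(trait1, trait2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                     prior_sd1 = 0.15, prior_sd2 = 0.15, locus = "locus") {
  common <- intersect(trait1$SNP, trait2$SNP)
  if (length(common) == 0) {
    stop("coloc_pp: traits share no variants", call. = FALSE)
  }
  if (length(common) < 10) {
    message(sprintf("coloc_pp: only %d shared variants; posterior may be unstable",
                    length(common)))
  }
  t1 <- trait1[match(common, trait1$SNP), ]
  t2 <- trait2[match(common, trait2$SNP), ]
  l1 <- approx_bayes_factor(t1$BETA, t1$SE, prior_sd1)
  l2 <- approx_bayes_factor(t2$BETA, t2$SE, prior_sd2)

  s1 <- logsumexp(l1)
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)
  lH0 <- 0
  lH1 <- log(p1) + s1
  lH2 <- log(p2) + s2
  # Sum over ordered pairs (i, j), i != j: full product minus the diagonal.
  lH3 <- log(p1) + log(p2) + logdiffexp(s1 + s2, s12)
  lH4 <- log(p12) + s12
  lall <- c(lH0, lH1, lH2, lH3, lH4)
  denom <- logsumexp(lall)
  pp <- exp(lall - denom)
  names(pp) <- paste0("PP", 0:4)
  call <- if (pp[5] > 0.80) "colocalized" else if (pp[5] > 0.60) "suggestive"
          else "none"
  structure(list(locus = locus, pp = pp, n_variants = length(common),
                 call = call,
                 per_variant = data.frame(SNP = common, log_abf1 = l1,
                                          log_abf2 = l2,
                                          stringsAsFactors = FALSE)),
            class = "coloc_result")
}
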