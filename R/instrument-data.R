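#' Published alpha-angle genetic instrument
#'
#' The eight independent genome-wide-significant loci for the DXA-derived
#' alpha angle from the published UK Biobank + Rotterdam Study GWAS
#' meta-analysis (N = 44,214), as printed: effect/non-effect alleles,
#' effect-allele frequency, per-SD effect size and P value, with the closest
#' gene label. Standard errors are not printed at the source, so they are
#' recovered from the effect size and P value as
#' `SE = |beta| / qnorm(1 - P/2)`; this is a standard reconstruction but is
#' sensitive to P-value rounding. Per-SNP F statistics use the recovered SE.
#'
#' The corresponding per-SNP hip-osteoarthritis outcome effects are not
#' printed at the source and are not distributed with this package, so the
#' published forward MR cannot be recomputed from packaged data alone; the
#' estimators are validated on simulated architectures instead.
#'
#' @return Data frame with columns `SNP CHR BP EA NEA EAF BETA P SE F
#'   gene`.
#' @export
aa_instrument <- function() {
  d <- data.frame(
    SNP = c("rs7571789", "rs10478422", "rs1048584", "rs62578126",
            "rs10787959", "rs561578905", "rs146939415", "rs4911180"),
    CHR = c(2L, 5L, 6L, 9L, 10L, 12L, 15L, 20L),
    BP = c(70714793L, 118747441L, 155578599L, 129375338L, 121131313L,
           24206118L, 51522210L, 33972948L),
    EA = c("T", "T", "A", "T", "A", "A", "C", "A"),
    NEA = c("C", "C", "T", "C", "G", "C", "G", "G"),
    EAF = c(0.48, 0.30, 0.39, 0.37, 0.28, 0.27, 0.01, 0.63),
    BETA = c(0.04, 0.04, -0.04, -0.04, -0.04, 0.05, 0.17, -0.04),
    P = c(7.52e-09, 9.64e-10, 7.67e-09, 9.00e-09, 1.08e-08, 3.37e-08,
          2.47e-08, 1.25e-11),
    gene = c("TGFA", "TNFAIP8", "TFB1M", "LMX1B", "GRK5", "SOX5",
             "CYP19A1", "UQCC1"),
    stringsAsFactors = FALSE)
  z <- stats::qnorm(1 - d$P / 2)
  d$SE <- abs(d$BETA) / z
  d$F <- z^2
  d
}
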