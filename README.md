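# camMR

Cam-type hip morphology — an aspherical femoral head, summarized by the
**alpha angle (AA)** — is strongly associated with hip osteoarthritis (OA),
and that association has motivated corrective surgery. Whether the shape
*causes* the disease, or develops as part of it, is a causal question that
observational data cannot settle. camMR implements the full analysis chain
used to attack it with genetics: geometric AA measurement from hip outline
points, observational association models, GWAS summary-statistic
meta-analysis with QC and LD clumping, Bayesian colocalization, and
bidirectional two-sample Mendelian randomization (MR) between AA and hip
OA. It is written for biostatisticians and genetic epidemiologists who want
a tested, self-contained reimplementation of each stage, with a
synthetic-data module that generates every input (outlines, toy cohorts,
multi-cohort summary statistics, LD matrices) with known ground truth, so
the whole chain runs and validates without access-restricted cohort data.

## The statistics at the core

**Alpha angle.** With a circle of best fit (algebraic least squares on
x² + y² + Dx + Ey + F = 0) through the osteophyte-excluding femoral-head
points, AA is the angle at the circle centre between the ray to the femoral
neck midpoint and the ray to the point where the contour departs the
circle. Cam morphology is AA ≥ 60°.

**Fixed-effects meta-analysis.** Cohort effects pool with weights
wᵢ = 1/SEᵢ²: β̂ = Σwᵢβᵢ/Σwᵢ, SE = (Σwᵢ)^(−1/2), Cochran's
Q = Σwᵢ(βᵢ − β̂)², I² = max(0, (Q − df)/Q)·100. Genomic inflation λ is the
median association χ²₁ over 0.4549. Instruments are selected by greedy LD
clumping (P < 5×10⁻⁸; r² 0.001 within 10,000 kb by default) with proxy
substitution at r² ≥ 0.7.

**Two-sample MR.** For harmonized per-SNP effect pairs, the package
provides inverse-variance weighted (through-origin weighted slope;
multiplicative random-effects SE when Q/df > 1), MR-Egger (free intercept =
directional-pleiotropy test, Rücker's Q), weighted median (bootstrap SE),
simple/weighted mode (kernel-smoothed Wald-ratio density), per-SNP
F = (β/SE)², and leave-one-out / single-SNP sensitivity scans. The reverse
(disease → shape) direction is rescaled by ln 2 to read "SD change per
doubling in odds".

**Colocalization.** Wakefield log approximate Bayes factors,
log ABF = ½[log(se²/(se² + W²)) + z²·W²/(se² + W²)], combined over the five
single-causal-variant hypotheses (priors p1 = p2 = 1e-4, p12 = 1e-5) in log
space; a locus is called colocalized when PP4 > 0.80, suggestive when
PP4 > 0.60.

## Worked example

Measure a synthetic hip with a cam bump constructed at 68°, then run the MR
estimator panel on a simulated 8-SNP instrument with a true causal effect
of 0.3:

```r
library(camMR)

ol  <- generate_hip_outline(shape_spec(cam_onset_angle = 68,
                                       cam_amplitude = 0.2, seed = 1))
res <- compute_alpha_angle(ol)
sprintf("alpha = %.2f deg, cam = %s", res$alpha_deg, res$is_cam)
#> "alpha = 67.94 deg, cam = TRUE"

h     <- simulate_instruments(mr_validation_spec(seed = 42, causal_beta = 0.3))
panel <- mr_all(h, n_boot = 1000, seed = 1)
panel[, c("method", "estimate", "se", "ci_low", "ci_high", "p")]
#>            method estimate     se  ci_low ci_high        p
#> 1             IVW    0.289 0.0378  0.2149   0.363 2.09e-14
#> 2        MR-Egger    0.174 0.1394 -0.0986   0.448 2.57e-01
#> 3 Weighted median    0.335 0.0515  0.2341   0.436 7.53e-11
#> 4     Simple mode    0.338 0.0797  0.1820   0.494 2.20e-05
#> 5   Weighted mode    0.338 0.0748  0.1918   0.485 6.07e-06
```

The measured angle sits within 0.1° of the 68° construction; the IVW
estimate 0.289 (95% CI 0.215–0.363) recovers the planted effect 0.3, and
the wider, null-consistent Egger interval is the expected behaviour of
pleiotropy-robust estimators on a valid instrument of this size.

The numbered scripts in `analysis/` run the whole chain as a narrative —
`01_simulate.R` through `06_coloc.R` — writing tables to `results/`
(simulation inputs land in `scratch/`). `run_pipeline(run_config(seed = 1))`
does the same in one call with a manifest and stage-count log.
`aa_instrument()` ships the published eight-locus AA instrument
(exposure-side effects with SEs recovered from printed P values).

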