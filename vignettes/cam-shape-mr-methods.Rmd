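---
title: "Methods: alpha-angle morphometry, GWAS meta-analysis and bidirectional MR"
author: "camMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alpha-angle morphometry, GWAS meta-analysis and bidirectional MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

camMR implements an analysis chain that asks whether cam-type femoral head
shape, summarized by the alpha angle (AA), is a cause or a consequence of hip
osteoarthritis (OA). The chain runs from raw hip outline points to causal
estimates: geometric AA measurement, observational association models, GWAS
summary-statistic meta-analysis with quality control and LD clumping,
Bayesian colocalization, and bidirectional two-sample Mendelian
randomization (MR). Because the individual-level cohort data behind such
studies are access-restricted, a first-class synthetic-data module generates
every input with known ground truth; this vignette records the models, the
parameter choices, and what the synthetic validation does and does not show.

## Alpha-angle geometry

The alpha angle quantifies femoral head asphericity: with a circle of best
fit through the (osteophyte-excluding) femoral head points, it is the angle
at the circle centre between the ray to the femoral neck midpoint and the
ray to the point where the head contour first leaves the circle toward the
neck. Cam morphology is operationalized as AA >= 60 degrees (inclusive).

`fit_circle()` uses the algebraic (Kasa) least-squares fit: linear least
squares on \(x^2+y^2+Dx+Ey+F=0\). It is closed-form and deterministic, exact
on noiseless circles, and for the dense head arcs produced here its known
small-arc bias is negligible; the RMS radial residual is reported so callers
can detect degenerate fits. The neck midpoint is the midpoint of the
minimum-width chord between the superior and inferior neck margins, found by
brute force over margin point pairs.

`compute_alpha_angle()` walks the contour from the head apex toward the neck
on the measurement (superior) side and declares departure at the first point
whose distance from the fitted centre exceeds `radius * (1 + departure_tol)`
with `departure_tol = 0.02` by default, linearly interpolated between the
bracketing contour points. Two numerical choices matter:

* **Persistence guard.** A departure must open a run of at least three
  consecutive supra-threshold points. With point jitter of about 1% of the
  radius (and a 2% threshold), isolated noise spikes would otherwise trigger
  early departures on most noisy contours and bias AA upward by degrees; a
  three-point run makes that probability negligible while a genuine cam
  plateau always satisfies it. Triggered decisions are recorded in
  `method_flags`.
* **Fallback crossing.** If no point exceeds the tolerance (a spherical
  head), the departure point falls back to the contour/circle crossing
  nearest the neck, which lands at the head-neck junction.

Rigid motions and uniform scaling leave the measurement unchanged (all
quantities are relative to the fitted circle), verified to below 1e-6
degrees in the tests.

## The outline generator

`generate_hip_outline()` constructs a counter-clockwise contour — superior
neck margin, cam bump, spherical head arc, inferior neck margin — with the
neck closing the sequence. The cam bump is a radial excess that returns to
the circle exactly at `cam_onset_angle` (measured from the neck axis), so
the ground-truth AA is a construction parameter. Two deliberate choices:

* The bump's onset breakpoint and a steep rise point (0.5 degrees wide) are
  emitted as actual contour samples, so the interpolated threshold crossing
  lands within 0.1 degrees of the construction angle regardless of the
  sampling grid.
* Bump points are labelled `neck_superior`, not `head`: the aspherical
  excess sits at the head-neck junction, and only spherical-head points
  should inform the circle of best fit. Osteophytes are modelled as an
  outward radial displacement over a configurable arc, flagged, and excluded
  from both the fit and the walk, mirroring osteophyte-excluding measurement
  practice.

Population AAs follow a shifted log-normal, the simplest two-parameter
positively skewed family: `aa_population()` defaults to mean 47.8 degrees
with lower shift 31.8 and log-SD 0.35, matching the skewed population
distribution reported for imaging cohorts of older adults. A limitation to
keep in mind: the generator produces idealized projections with exact
landmark roles; it does not emulate image segmentation error, out-of-plane
projection of the cam lesion, or modality differences between DXA and
radiographs, so passing the geometric oracle says nothing about those
error sources.

## Observational stage

`standardize()` converts AA to a Z score (mean 0, SD 1), the scale used
throughout. Binary outcomes (hip pain, radiographic OA grade thresholds,
hospital-diagnosed OA) use logistic regression; total hip replacement uses a
Cox proportional hazards model with Efron tie handling. Both report Wald
95% CIs per SD of AA, unadjusted and adjusted for age, sex, height and
weight. Missing covariates are handled by complete-case analysis with a
logged count; separation is detected and flagged rather than silently
returned. The synthetic phenotype generator plants odds ratios 1.15 / 1.63 /
1.44 and hazard ratio 1.45 per SD — the magnitudes reported for DXA-derived
AA in a large biobank — so the observational stage can be checked for
parameter recovery.

## GWAS, meta-analysis and instrument selection

Per-cohort records are filtered on minor allele frequency (< 0.01 removed)
and imputation info (< 0.4 removed), with boundary values kept and drop
reasons enumerated. Allele harmonization resolves effect-allele swaps (sign
and frequency flip), strand flips (complement codes), and their
combination; palindromic A/T and C/G variants are unresolvable from allele
codes alone and are flagged for the MR-stage policy (drop by default, or
frequency-resolve when both EAFs lie outside 0.42--0.58).

Cohorts are pooled by fixed-effects inverse-variance weighting: weights
\(w_i = 1/\mathrm{SE}_i^2\), pooled beta \(\sum w_i\beta_i/\sum w_i\),
pooled SE \((\sum w_i)^{-1/2}\), Cochran's \(Q=\sum w_i(\beta_i-\hat\beta)^2\)
with df \(k-1\) and \(I^2=\max(0,(Q-\mathrm{df})/Q)\cdot100\), plus a
per-cohort direction string. Extreme pooled P values are also stored as
log10(P) to avoid underflow. Genomic inflation is the median association
chi-square over the null median (0.4549).

LD clumping is greedy: the smallest-P unclaimed variant below 5e-8 becomes
an index and claims variants with r^2 >= `clump_r2` within `clump_kb`.
The r^2 = 0.001 / 10,000 kb defaults are the conventional
instrument-selection settings for two-sample MR; ties break by position then
id so selection is deterministic. `proxy_substitute()` returns the
highest-r^2 available proxy at r^2 >= 0.7, the threshold at which published
analyses accept a substitute instrument SNP.

## MR estimators

All estimators consume harmonized per-SNP pairs (beta_exposure,
beta_outcome, SEs). IVW is the weighted through-origin slope with weights
1/se_outcome^2; with one SNP it reduces exactly to the Wald ratio. The
default flavour inflates the fixed-effect SE by sqrt(Q/df) when Q/df > 1
(multiplicative random effects), a common two-sample default; it is
switchable because the flavour is rarely stated in publications. MR-Egger
adds a free intercept after orienting exposure betas positive (Egger is not
orientation-invariant); the intercept estimates average directional
pleiotropy, SEs use the multiplicative model with dispersion floored at 1,
P values use t with n-2 df, and Rucker's Q is reported. The weighted median
interpolates the inverse-variance-weighted cumulative distribution of Wald
ratios at 50% and is consistent while valid instruments carry more than
half the weight; its SE comes from a seeded parametric bootstrap (default
1,000 replicates). The mode estimators smooth the Wald-ratio density with a
normal kernel (bandwidth phi times the modified Silverman rule
0.9 min(sd, mad) n^(-1/5)) and take the argmax, unweighted and
inverse-variance weighted. Instrument strength is the mean of
(beta_exposure/se_exposure)^2; when a source prints only beta and P, the SE
is recovered as |beta|/qnorm(1-P/2), a standard reconstruction that is
sensitive to P rounding. Leave-one-out and single-SNP scans re-estimate the
effect with each variant excluded and report per-SNP Wald ratios.

In the reverse direction (disease to shape) the binary-exposure instrument
effects are log odds; they are rescaled by ln 2 so estimates read "SD change
per doubling in odds", making the two directions comparable in a single
report.

## Estimator validation scenario and calibration choices

`mr_validation_spec()` fixes the scenario used to validate the panel: 8
SNPs with exposure effects spread evenly over 0.06--0.20 per SD at an
exposure GWAS of 44,214 (EAFs uniform on 0.1--0.9), and an independent
quantitative outcome GWAS of 11,000, true causal effect 0.3 where planted.
The design is chosen so the estimator property under test is not confounded
by known finite-sample artefacts:

* The spread in exposure effects gives Egger regression the
  instrument-strength variation it assumes; with near-constant effects the
  slope suffers regression dilution and the intercept absorbs the bias,
  which is a property of the scenario, not the estimator.
* The effect sizes put per-SNP F statistics high enough (roughly 60--800)
  that weak-instrument attenuation (about beta/F-bar) sits an order of
  magnitude below the 0.01 bias tolerance being checked.
* The outcome sample size makes outcome-side noise dominate, matching the
  error model whose inverse-variance weights IVW uses, so nominal CI
  coverage is a fair check.

Null-calibration and recovery checks use the fixed-effect IVW flavour: the
homogeneous valid-instrument generator *is* the fixed-effect model, and the
random-effects switch is deliberately conservative under the null (its SE
inflation can only widen CIs, deflating type-I error to about 0.03), which
would make a nominal-level check test the switch rather than the estimator.
The default generator instrument (`gwas_sim_spec()` with `z_target = 7`)
uses an equal-z design in which rarer variants carry larger effects, as
selected genome-wide-significant instruments do, giving per-SNP power above
0.9 at the 5e-8 threshold.

The weighted-median breakdown check uses 20 near-equal-weight SNPs at very
large sample sizes with 8 or 12 of them given a direct outcome shift of
0.5 times their exposure effect: below half the weight the estimate stays
within 0.05 of the true 0.3; above it the estimate migrates to the invalid
cluster.

## Colocalization

`approx_bayes_factor()` computes the Wakefield-style log approximate Bayes
factor `0.5 [log(se^2/(se^2+W^2)) + z^2 W^2/(se^2+W^2)]`; prior effect SDs
default to 0.15 for quantitative traits and 0.2 for binary log odds.
`coloc_pp()` combines per-variant log ABFs over the five
single-causal-variant hypotheses with priors p1 = p2 = 1e-4, p12 = 1e-5
(the field-standard defaults; the source publications rarely state them),
entirely in log space via log-sum-exp so z scores of 40 or more remain
finite. Calls follow strict thresholds: colocalized when PP4 > 0.80,
suggestive when PP4 > 0.60. Fewer than 10 shared variants triggers a logged
warning. Multi-causal-variant colocalization and fine-mapping are out of
scope.

## Orchestration, determinism and problem sizes

`run_pipeline()` chains the stages on synthetic inputs, writing delimited
tables, a stage-count log (the record funnel: counts in = counts out plus
enumerated exclusions), and a JSON manifest with the configuration, derived
seeds and file checksums into a timestamped, never-overwritten run
directory. Every stochastic stage receives a seed derived deterministically
from the global seed, so deterministic outputs are bit-identical across
reruns; configurations round-trip through YAML. `validate_inputs()` checks
file schemas with line-level findings and never mutates inputs.

Validation problem sizes are chosen to estimate each property to well
within its tolerance while keeping the full suite in the minutes range: 500
replicates for estimator bias, coverage, intercept recovery and type-I
error; 100,000 null variants (300 subjects) for the genomic-inflation
check; a 2,008-variant panel with 8 planted signals for end-to-end signal
recovery; 51 noiseless shapes for the geometric oracle sweep; 200 noisy
shapes for the measurement-noise check.

## Known limitations

The published forward-direction MR of this design cannot be recomputed from
distributable inputs: the per-SNP disease outcome effects for the published
8-SNP shape instrument live in access-restricted supplementary material, so
the packaged published instrument (`aa_instrument()`) carries exposure-side
values only and the forward reproduction check states that gap explicitly
rather than substituting tuned numbers. The generators draw effect
estimates directly at the summary level (no LD between panel variants, no
sample overlap between exposure and outcome GWAS, no imputation error
beyond the info score), so agreement on synthetic data validates the
estimators and plumbing — not robustness to those real-data features.
Correlated-pleiotropy models that use full summary statistics are out of
scope; the report notes the caveat instead.
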