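# Shared fixture builders; everything is generated in code at test time.

cam_outline <- function(angle = 60, amplitude = 0.2, noise = 0, seed = 1,
                        ...) {
  generate_hip_outline(shape_spec(cam_onset_angle = angle,
                                  cam_amplitude = amplitude,
                                  noise_sd = noise, seed = seed, ...))
}

# Minimal harmonized-instrument table built directly from effect vectors.
instruments_from <- function(bx, by, se_x = 0.01, se_y = 0.05) {
  n <- length(bx)
  data.frame(SNP = sprintf("rs%03d", seq_len(n)),
             beta_exposure = bx, se_exposure = rep_len(se_x, n),
             beta_outcome = by, se_outcome = rep_len(se_y, n),
             stringsAsFactors = FALSE)
}

# One-row-per-cohort summary statistics for a single variant.
meta_records <- function(beta, se, snp = "rs1") {
  k <- length(beta)
  data.frame(SNP = snp, CHR = 1L, BP = 100L, EA = "A", NEA = "G",
             EAF = 0.5, BETA = beta, SE = rep_len(se, k), P = 0.5,
             N = 1000L, INFO = 1, stringsAsFactors = FALSE)
}

rotate_translate <- function(outline, theta, shift) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  xy <- as.matrix(outline[, c("x", "y")]) %*% t(R)
  out <- outline
  out$x <- xy[, 1] + shift[1]
  out$y <- xy[, 2] + shift[2]
  out
}
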