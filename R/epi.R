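#' Standardize to a Z score
#'
#' Centres and scales to sample mean 0 and SD 1, the scale on which the
#' alpha-angle GWAS and observational models operate.
#'
#' @param values Numeric vector with at least 2 distinct finite values.
#' @return Numeric vector of z-scores.
#' @export
standardize <- function(values) {
  if (!is.numeric(values) || sum(is.finite(values)) < 2) {
    stop("standardize: need at least 2 finite values", call. = FALSE)
  }
  s <- stats::sd(values, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    stop("standardize: input is constant", call. = FALSE)
  }
  (values - mean(values, na.rm = TRUE)) / s
}

assoc_row <- function(outcome_label, measure, est, se, p, adjusted, n,
                      flag = NA_character_) {
  data.frame(outcome = outcome_label, measure = measure,
             estimate = exp(est),
             ci_low = exp(est - 1.96 * se), ci_high = exp(est + 1.96 * se),
             p = p, adjusted = adjusted, n = n, flag = flag,
             stringsAsFactors = FALSE)
}

complete_cases_or_log <- function(df) {
  keep <- stats::complete.cases(df)
  if (any(!keep)) {
    message(sprintf("complete-case analysis: dropped %d of %d rows with missing values",
                    sum(!keep), nrow(df)))
  }
  df[keep, , drop = FALSE]
}

#' Odds ratio for a binary outcome per SD of exposure
#'
#' Logistic regression of the outcome on the standardized exposure, with
#' optional covariate adjustment and Wald confidence intervals. Quasi- or
#' complete separation is detected (non-converged fit or exploding
#' coefficient) and flagged rather than returned silently.
#'
#' @param z_exposure Standardized exposure.
#' @param outcome Binary 0/1 outcome with both classes present.
#' @param covariates Optional data frame of adjustment covariates.
#' @param outcome_label Label carried into the result row.
#' @return One-row data frame: `outcome`, `measure` ("OR"), `estimate`,
#'   `ci_low`, `ci_high`, `p`, `adjusted`, `n`, `flag`.
#' @export
logistic_association <- function(z_exposure, outcome, covariates = NULL,
                                 outcome_label = "outcome") {
  if (length(unique(stats::na.omit(outcome))) < 2) {
    stop("logistic_association: outcome must have both classes present",
         call. = FALSE)
  }
  dat <- data.frame(.y = outcome, .x = z_exposure)
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  dat <- complete_cases_or_log(dat)
  fit <- stats::glm(.y ~ ., data = dat, family = stats::binomial())
  sm <- summary(fit)$coefficients[".x", ]
  flag <- NA_character_
  if (!fit$converged || abs(sm[1]) > 10 || sm[2] > 5) {
    flag <- "possible_separation"
  }
  assoc_row(outcome_label, "OR", sm[1], sm[2], sm[4],
            adjusted = !is.null(covariates), n = nrow(dat), flag = flag)
}

#' Hazard ratio for a time-to-event outcome per SD of exposure
#'
#' Cox proportional hazards model (Efron tie handling) of event time on the
#' standardized exposure, optionally covariate-adjusted, with Wald CIs.
#'
#' @param z_exposure Standardized exposure.
#' @param time Non-negative follow-up time.
#' @param event Event indicator (1 = event, 0 = censored); at least one
#'   event required.
#' @param covariates Optional data frame of adjustment covariates.
#' @param outcome_label Label carried into the result row.
#' @return One-row data frame as [logistic_association()], with `measure`
#'   "HR".
#' @export
cox_association <- function(z_exposure, time, event, covariates = NULL,
                            outcome_label = "outcome") {
  check_num(time, "time", lower = 0)
  if (sum(event, na.rm = TRUE) < 1) {
    stop("cox_association: no events observed", call. = FALSE)
  }
  dat <- data.frame(.time = time, .event = event, .x = z_exposure)
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  dat <- complete_cases_or_log(dat)
  fit <- survival::coxph(survival::Surv(.time, .event) ~ ., data = dat,
                         ties = "efron")
  sm <- summary(fit)$coefficients[".x", ]
  assoc_row(outcome_label, "HR", sm["coef"], sm["se(coef)"],
            sm["Pr(>|z|)"], adjusted = !is.null(covariates), n = nrow(dat))
}

#' Observational association table
#'
#' Runs the observational stage on a phenotype table: odds ratios for each
#' binary hip-OA outcome and a hazard ratio for total hip replacement, both
#' unadjusted and adjusted for age, sex, height and weight.
#'
#' @param pheno Phenotype table as produced by
#'   [simulate_phenotype_table()].
#' @return Data frame with one row per outcome x adjustment combination.
#' @export
observational_table <- function(pheno) {
  covs <- pheno[, c("age", "sex", "height", "weight")]
  z <- pheno$z_alpha
  binary <- c(hip_pain = "hip pain", rhoa = "radiographic hip OA grade >=2",
              hoa = "hospital-diagnosed OA")
  rows <- list()
  for (col in names(binary)) {
    rows[[length(rows) + 1]] <-
      logistic_association(z, pheno[[col]], NULL, binary[[col]])
    rows[[length(rows) + 1]] <-
      logistic_association(z, pheno[[col]], covs, binary[[col]])
  }
  rows[[length(rows) + 1]] <-
    cox_association(z, pheno$fu_time, pheno$thr_event, NULL,
                    "total hip replacement")
  rows[[length(rows) + 1]] <-
    cox_association(z, pheno$fu_time, pheno$thr_event, covs,
                    "total hip replacement")
  do.call(rbind, rows)
}
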