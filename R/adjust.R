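#' Estimated glomerular filtration rate (CKD-EPI 2009, Japanese coefficient)
#'
#' CKD-EPI 2009 creatinine equation:
#' `141 * min(Scr/k, 1)^a * max(Scr/k, 1)^-1.209 * 0.993^age * 1.018[female]`
#' with `k = 0.7` (female) / `0.9` (male) and `a = -0.329` (female) /
#' `-0.411` (male), multiplied by the Japanese coefficient 0.908 by default.
#' The equation is isolated behind this one function so an alternative
#' formula can be swapped in.
#'
#' @param serum_creatinine serum creatinine, mg/dl (> 0).
#' @param age years (> 0).
#' @param sex `"male"` or `"female"` (vectorized).
#' @param japanese_coef multiplier applied to the CKD-EPI value; set to 1 to
#'   disable the ethnicity adjustment.
#' @return eGFR in mL/min/1.73 m^2.
#' @export
egfr <- function(serum_creatinine, age, sex, japanese_coef = 0.908) {
  if (any(!sex %in% c("male", "female")))
    stopf("sex must be 'male' or 'female'")
  if (any(serum_creatinine <= 0) || any(age <= 0))
    stopf("serum_creatinine and age must be positive")
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  r <- serum_creatinine / kappa
  141 * pmin(r, 1)^alpha * pmax(r, 1)^(-1.209) * 0.993^age *
    ifelse(female, 1.018, 1) * japanese_coef
}

#' Invert the eGFR equation for simulation
#'
#' Solves for the serum creatinine that yields a target eGFR at a given age
#' and sex (the equation is strictly decreasing in creatinine). Used by the
#' generator's creatinine-first mode.
#'
#' @param target_egfr target eGFR values (mL/min/1.73 m^2, > 0).
#' @inheritParams egfr
#' @return serum creatinine, mg/dl.
#' @export
creatinine_for_egfr <- function(target_egfr, age, sex, japanese_coef = 0.908) {
  if (any(target_egfr <= 0)) stopf("target eGFR must be positive")
  mapply(function(g, a, s) {
    stats::uniroot(function(scr) egfr(scr, a, s, japanese_coef) - g,
                   interval = c(1e-4, 50), tol = 1e-10)$root
  }, target_egfr, age, sex)
}

#' Fit the sex-stratified covariate adjustment model
#'
#' Ordinary least squares of serum urate on the covariates (default age,
#' BMI, eGFR, HbA1c) within one sex stratum, with classical coefficient SEs
#' and two-sided p-values (equivalent to a Gaussian-identity `glm`).
#' Missing covariates must have been handled upstream (listwise exclusion);
#' any NA in the design is an error here.
#'
#' @param participants one stratum's participant data.frame.
#' @param covariates covariate column names.
#' @param response response column name (default `"urate"`).
#' @return object of class `"adjustment_model"`: the `lm` fit, a coefficient
#'   table (estimate, se, t, p), `n_used`, `stratum`.
#' @export
fit_adjustment_model <- function(participants,
                                 covariates = c("age", "bmi", "egfr", "hba1c"),
                                 response = "urate") {
  miss <- setdiff(c(response, covariates), names(participants))
  if (length(miss))
    stopf("missing column(s): %s", paste(miss, collapse = ", "))
  d <- participants[, c(response, covariates), drop = FALSE]
  if (anyNA(d))
    stopf("NA in response or covariates; exclude incomplete records upstream")
  if (nrow(d) <= length(covariates) + 1L)
    stopf("need more observations (%d) than coefficients (%d)",
          nrow(d), length(covariates) + 1L)
  form <- stats::reformulate(covariates, response = response)
  fit <- stats::lm(form, data = d)
  if (fit$rank < length(covariates) + 1L) {
    al <- stats::alias(fit)$Complete
    stopf("rank-deficient design; collinear column(s): %s",
          paste(rownames(al) %||% "unknown", collapse = ", "))
  }
  ct <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(ct), estimate = ct[, 1L],
                      se = ct[, 2L], t = ct[, 3L], p = ct[, 4L],
                      row.names = NULL, stringsAsFactors = FALSE)
  stratum <- unique(participants$sex)
  structure(list(fit = fit, coefficients = coefs,
                 n_used = nrow(d), covariates = covariates,
                 response = response,
                 stratum = if (length(stratum) == 1L) stratum else "mixed"),
            class = "adjustment_model")
}

#' @export
print.adjustment_model <- function(x, ...) {
  cat(sprintf("Covariate adjustment model (%s, n = %d)\n", x$stratum, x$n_used))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' @export
coef.adjustment_model <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Adjusted serum urate and the variance it removes
#'
#' Adjusted urate is the raw OLS residual (observed minus fitted, mg/dl;
#' mean zero by construction, not standardized). Variances use divisor `n`,
#' under which the additivity `V(U) = V(E_known) + V(U_adjusted)` holds
#' exactly, with `V(E_known)` the variance of the fitted values.
#'
#' @param model an [fit_adjustment_model()] result.
#' @param participants optional data.frame to adjust (defaults to the
#'   fitting data); must contain the model's response and covariates, and
#'   optionally `id` used to name the residuals.
#' @return object of class `"adjusted_phenotype"`: `values` (residuals),
#'   `v_u`, `v_u_adjusted`, `v_e_known`, `n`.
#' @export
adjusted_urate <- function(model, participants = NULL) {
  stopifnot(inherits(model, "adjustment_model"))
  if (is.null(participants)) {
    res <- stats::residuals(model$fit)
    y <- stats::fitted(model$fit) + res
  } else {
    y <- participants[[model$response]]
    res <- y - stats::predict(model$fit, newdata = participants)
    if (!is.null(participants$id)) names(res) <- participants$id
  }
  v_u <- var_n(y)
  v_adj <- var_n(res)
  structure(list(values = res, v_u = v_u, v_u_adjusted = v_adj,
                 v_e_known = v_u - v_adj, n = length(res)),
            class = "adjusted_phenotype")
}

#' @export
print.adjusted_phenotype <- function(x, ...) {
  cat(sprintf("Adjusted urate: n = %d, V(U) = %.4f, V(E_known) = %.4f, V(U_adj) = %.4f\n",
              x$n, x$v_u, x$v_e_known, x$v_u_adjusted))
  invisible(x)
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS statistic of the standardized values against the standard
#' normal, with the asymptotic p-value. Because mean and SD are estimated
#' from the same data, the p-value is conservative (the Lilliefors
#' correction, available via `lilliefors = TRUE` when the `nortest` package
#' is installed, accounts for the estimation).
#'
#' @param values numeric vector, `n >= 5`, nonzero variance.
#' @param lilliefors use the Lilliefors-corrected test instead.
#' @return list with `D`, `p.value`, and `note` stating the caveat.
#' @export
ks_normality <- function(values, lilliefors = FALSE) {
  values <- values[!is.na(values)]
  if (length(values) < 5L) stopf("need at least 5 values")
  if (stats::sd(values) == 0) stopf("zero-variance input")
  if (lilliefors) {
    if (!requireNamespace("nortest", quietly = TRUE))
      stopf("lilliefors = TRUE requires the nortest package")
    ht <- nortest::lillie.test(values)
    return(list(D = unname(ht$statistic), p.value = ht$p.value,
                note = "Lilliefors-corrected for estimated parameters"))
  }
  z <- (values - mean(values)) / stats::sd(values)
  ht <- suppressWarnings(stats::ks.test(z, "pnorm"))
  list(D = unname(ht$statistic), p.value = ht$p.value,
       note = "parameters estimated from the data; p-value conservative")
}
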