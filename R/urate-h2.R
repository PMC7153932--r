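#' Carrier-grouped heritability of serum urate within one stratum
#'
#' Fits the full estimator for one sex stratum in a single call: ordinary
#' least squares of the trait on the covariates (the "known environment"),
#' adjusted urate as the raw residuals, carrier-group statistics, the
#' carrier-collapsing burden test, and the carrier-grouped variance
#' decomposition giving the additive variance of the gene and its
#' heritability share `h2 = 100 V(A_gene)/V(U)`.
#'
#' @param formula model formula for the covariate adjustment, e.g.
#'   `urate ~ age + bmi + egfr + hba1c`.
#' @param data data.frame with the trait, covariates, and (optionally) an
#'   `id` column.
#' @param carrier carrier indicator: a logical vector, or an (unquoted or
#'   quoted) column name in `data`. NA carriers are dropped from the
#'   grouped analysis (counted in `n_dropped`), not from the adjustment.
#' @param var_equal pooled-variance (Student) burden test instead of Welch.
#' @param unbiased bias-corrected additive variance (default off).
#' @return object of class `"urate_h2"` with components `call`, `model`
#'   (the `lm` fit), `adjustment` (coefficient table), `adjusted`
#'   ([adjusted_urate()] result), `carrier`, `group_stats`, `burden`,
#'   `decomposition`, `n`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_men = 300, n_women = 300, seed = 7))
#' men <- cohort$participants[cohort$participants$sex == "male", ]
#' fit <- urate_h2(urate ~ age + bmi + egfr + hba1c, data = men,
#'                 carrier = cohort$carrier[men$id])
#' summary(fit)
#' @export
urate_h2 <- function(formula, data, carrier, var_equal = FALSE,
                     unbiased = FALSE) {
  cl <- match.call()
  carrier_expr <- substitute(carrier)
  carrier <- tryCatch(eval(carrier_expr, data, parent.frame()),
                      error = function(e) eval(carrier_expr, parent.frame()))
  if (is.character(carrier) && length(carrier) == 1L &&
      carrier %in% names(data))
    carrier <- data[[carrier]]
  carrier <- as.logical(carrier)
  if (length(carrier) != nrow(data))
    stopf("carrier must have one entry per row of data (%d vs %d)",
          length(carrier), nrow(data))
  vars <- all.vars(formula)
  response <- vars[1L]
  covariates <- vars[-1L]
  model <- fit_adjustment_model(data, covariates = covariates,
                                response = response)
  adjusted <- adjusted_urate(model)
  if (!is.null(data$id)) names(adjusted$values) <- data$id
  dec <- decompose_variance(adjusted, carrier, var_equal = var_equal,
                            unbiased = unbiased)
  structure(list(call = cl, formula = formula, model = model$fit,
                 adjustment = model, adjusted = adjusted,
                 carrier = carrier, group_stats = dec$group_stats,
                 burden = dec$burden, decomposition = dec,
                 n = nrow(data)),
            class = "urate_h2")
}

#' @export
print.urate_h2 <- function(x, ...) {
  cat("Carrier-grouped urate heritability fit\n")
  cat("Call: ")
  print(x$call)
  st <- x$group_stats
  cat(sprintf("n = %d (%d wild type, %d carriers", x$n, st$n1, st$n2))
  if (st$n_dropped > 0) cat(sprintf(", %d undetermined", st$n_dropped))
  cat(")\n")
  d <- x$decomposition
  if (!d$degenerate) {
    cat(sprintf("V(A_gene) = %.3f (mg/dl)^2; h2_gene = %.1f%% of V(U) = %.3f\n",
                d$v_a_gene, d$h2_gene, d$v_u))
  } else {
    cat("No carriers: gene components undefined\n")
  }
  invisible(x)
}

#' @export
summary.urate_h2 <- function(object, ...) {
  structure(list(call = object$call,
                 adjustment = object$adjustment,
                 group_stats = object$group_stats,
                 decomposition = object$decomposition,
                 burden = object$burden),
            class = "summary.urate_h2")
}

#' @export
print.summary.urate_h2 <- function(x, ...) {
  cat("Carrier-grouped urate heritability\n\nCovariate adjustment:\n")
  print(x$adjustment$coefficients, digits = 4)
  cat("\n")
  print(x$group_stats)
  cat("\n")
  print(x$decomposition)
  invisible(x)
}

#' @export
coef.urate_h2 <- function(object, ...) coef(object$adjustment)

#' @export
residuals.urate_h2 <- function(object, ...) object$adjusted$values

#' @export
fitted.urate_h2 <- function(object, ...) stats::fitted(object$model)

#' Predict serum urate for new participants
#'
#' Covariate expectation from the fitted adjustment model plus, for
#' carriers, the estimated carrier contrast (carrier group mean minus
#' wild-type group mean of adjusted urate).
#'
#' @param object a [urate_h2()] fit.
#' @param newdata data.frame with the model covariates.
#' @param carrier logical carrier indicator for the new participants
#'   (default all non-carriers).
#' @param ... unused.
#' @return numeric vector of expected urate (mg/dl).
#' @export
predict.urate_h2 <- function(object, newdata,
                             carrier = rep(FALSE, nrow(newdata)), ...) {
  st <- object$group_stats
  delta <- if (st$degenerate) 0 else st$mean2 - st$mean1
  stats::predict(object$model, newdata = newdata) +
    delta * as.numeric(carrier)
}

#' Simulate trait values from a fitted decomposition
#'
#' Parametric resimulation: fitted covariate expectation, plus the
#' estimated carrier contrast for carriers, plus normal noise with the
#' pooled within-group SD of the adjusted values.
#'
#' @param object a [urate_h2()] fit.
#' @param nsim number of simulated replicates.
#' @param seed optional seed.
#' @param ... unused.
#' @return data.frame with `nsim` columns (`sim_1`, ...), one row per
#'   participant used in the fit.
#' @export
simulate.urate_h2 <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  st <- object$group_stats
  delta <- if (st$degenerate) 0 else st$mean2 - st$mean1
  n_tot <- st$n1 + st$n2
  sd_within <- sqrt((st$n1 * st$v1 + st$n2 * st$v2) / n_tot)
  mu <- stats::fitted(object$model) + delta * as.numeric(object$carrier)
  out <- as.data.frame(
    vapply(seq_len(nsim),
           function(i) mu + stats::rnorm(length(mu), sd = sd_within),
           numeric(length(mu))))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Histogram of adjusted urate by carrier status
#'
#' Distribution of the adjusted trait with the carrier subgroup overlaid,
#' showing the downward carrier shift the decomposition quantifies.
#'
#' @param x a [urate_h2()] fit.
#' @param breaks passed to [graphics::hist()].
#' @param ... further arguments to [graphics::hist()].
#' @return invisibly, the histogram of all values.
#' @export
plot.urate_h2 <- function(x, breaks = 30, ...) {
  vals <- x$adjusted$values
  keep <- !is.na(x$carrier)
  h <- graphics::hist(vals[keep], breaks = breaks,
                      col = "grey85", border = "grey40",
                      main = "Adjusted serum urate",
                      xlab = "Adjusted urate (mg/dl)", ...)
  graphics::hist(vals[keep & x$carrier[keep]], breaks = h$breaks,
                 col = grDevices::adjustcolor("black", 0.7), add = TRUE)
  graphics::legend("topright", fill = c("grey85", "black"),
                   legend = c("wild type", "carriers"), bty = "n")
  invisible(h)
}
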