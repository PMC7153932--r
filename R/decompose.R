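#' Carrier-group summary statistics of adjusted urate
#'
#' Group sizes, means, and divisor-n variances for wild-type homozygotes
#' (group 1) and carriers (group 2), plus the grand mean. Participants with
#' undetermined (NA) carrier status are dropped with a message and the count
#' recorded. An empty group yields an explicit degenerate result (not zero).
#'
#' @param adjusted an [adjusted_urate()] result or a numeric vector of
#'   adjusted values.
#' @param carriers logical vector aligned with the values (NA =
#'   undetermined).
#' @return object of class `"group_stats"`: `n1`, `n2`, `mean1`, `mean2`,
#'   `v1`, `v2` (divisor n), `sd1`, `sd2` (divisor n-1, descriptive),
#'   `grand_mean`, `n_dropped`, `degenerate`.
#' @export
group_variance_stats <- function(adjusted, carriers) {
  x <- if (inherits(adjusted, "adjusted_phenotype")) adjusted$values
       else as.numeric(adjusted)
  if (length(x) != length(carriers))
    stopf("carriers must align with the adjusted values (%d vs %d)",
          length(carriers), length(x))
  drop <- is.na(carriers)
  if (any(drop)) {
    message(sprintf("dropping %d participant(s) with undetermined carrier status",
                    sum(drop)))
    x <- x[!drop]
    carriers <- carriers[!drop]
  }
  x1 <- x[!carriers]
  x2 <- x[carriers]
  sdesc <- function(v) if (length(v) >= 2L) stats::sd(v) else NA_real_
  st <- list(n1 = length(x1), n2 = length(x2),
             mean1 = if (length(x1)) mean(x1) else NA_real_,
             mean2 = if (length(x2)) mean(x2) else NA_real_,
             v1 = if (length(x1)) var_n(x1) else NA_real_,
             v2 = if (length(x2)) var_n(x2) else NA_real_,
             sd1 = sdesc(x1), sd2 = sdesc(x2),
             grand_mean = mean(x), n_dropped = sum(drop),
             degenerate = length(x1) == 0L || length(x2) == 0L)
  structure(st, class = "group_stats")
}

#' Carrier-group statistics from published summaries
#'
#' Builds a [group_variance_stats()]-shaped object from printed group sizes,
#' means, and SDs (taken as sample SDs, divisor n-1). Only the sizes and
#' means enter [additive_variance()]; the SDs feed the burden test.
#'
#' @param n1,mean1,sd1 wild-type homozygote group size, mean, SD.
#' @param n2,mean2,sd2 carrier group size, mean, SD.
#' @return object of class `"group_stats"`.
#' @export
group_stats_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  if (n1 < 0 || n2 < 0) stopf("group sizes must be nonnegative")
  structure(list(n1 = n1, n2 = n2, mean1 = mean1, mean2 = mean2,
                 v1 = sd1^2 * (n1 - 1) / n1, v2 = sd2^2 * (n2 - 1) / n2,
                 sd1 = sd1, sd2 = sd2,
                 grand_mean = (n1 * mean1 + n2 * mean2) / (n1 + n2),
                 n_dropped = 0L, degenerate = n1 == 0L || n2 == 0L),
            class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat("Carrier-group statistics (adjusted urate)\n")
  cat(sprintf("  wild type: n = %d, mean = %.3f, SD = %.3f\n",
              x$n1, x$mean1, x$sd1))
  cat(sprintf("  carriers : n = %d, mean = %.3f, SD = %.3f\n",
              x$n2, x$mean2, x$sd2))
  cat(sprintf("  grand mean = %.4f\n", x$grand_mean))
  if (x$degenerate) cat("  NOTE: one group is empty; estimator undefined\n")
  invisible(x)
}

#' Additive variance explained by the carrier grouping
#'
#' The between-group component of the law of total variance:
#' `V(A) = [n1 (mean1 - grand)^2 + n2 (mean2 - grand)^2] / (n1 + n2)`.
#' Under divisor-n variances this satisfies exactly
#' `V(total) = pooled within-group variance + V(A)`. No small-sample bias
#' correction is applied by default (the estimator has a small positive
#' bias of order `V/n` under the null); `unbiased = TRUE` subtracts the
#' ANOVA-based expectation of that bias,
#' `MS_within * (k - 1) / n` with `k = 2` groups.
#'
#' @param stats a `group_stats` object.
#' @param unbiased apply the ANOVA-style bias correction (default off,
#'   matching the uncorrected published estimator).
#' @return nonnegative between-group variance ((mg/dl)^2); `NA` with a
#'   warning when a group is empty.
#' @export
additive_variance <- function(stats, unbiased = FALSE) {
  stopifnot(inherits(stats, "group_stats"))
  if (stats$degenerate) {
    warning("a carrier group is empty; additive variance undefined")
    return(NA_real_)
  }
  n <- stats$n1 + stats$n2
  g <- (stats$n1 * stats$mean1 + stats$n2 * stats$mean2) / n
  v_a <- (stats$n1 * (stats$mean1 - g)^2 + stats$n2 * (stats$mean2 - g)^2) / n
  if (unbiased) {
    if (n <= 2) stopf("bias correction needs n1 + n2 > 2")
    ms_within <- (stats$n1 * stats$v1 + stats$n2 * stats$v2) / (n - 2)
    v_a <- max(0, v_a - ms_within / n)
  }
  v_a
}

#' Heritability share of the gene (percent)
#'
#' `100 * V(A_gene) / V(U)`: the additive variance attributable to the
#' gene's qualifying variants as a percent of the total trait variance.
#'
#' @param v_a_gene additive variance ((mg/dl)^2, >= 0).
#' @param v_u total trait variance ((mg/dl)^2, > 0).
#' @return percent.
#' @export
heritability_share <- function(v_a_gene, v_u) {
  if (any(v_u <= 0)) stopf("v_u must be positive")
  if (any(v_a_gene < 0)) stopf("v_a_gene must be nonnegative")
  100 * v_a_gene / v_u
}

#' Carrier-collapsing burden test
#'
#' Two-sample t-test of adjusted urate, carriers versus wild-type
#' homozygotes, with equal weight for all qualifying variants (collapsing).
#' Welch's form is the default because the two groups' variances typically
#' differ; the pooled Student form is available via `var_equal`. Also
#' computable directly from a `group_stats` summary.
#'
#' @param adjusted an [adjusted_urate()] result, numeric vector, or a
#'   `group_stats` object (in which case `carriers` is ignored).
#' @param carriers logical carrier vector (NA dropped with the same rule as
#'   [group_variance_stats()]).
#' @param var_equal use the pooled-variance form.
#' @return list with `t`, `df`, `p.value` (two-sided); both groups must
#'   have n >= 2.
#' @export
burden_test <- function(adjusted, carriers = NULL, var_equal = FALSE) {
  st <- if (inherits(adjusted, "group_stats")) adjusted
        else group_variance_stats(adjusted, carriers)
  if (st$n1 < 2 || st$n2 < 2)
    stopf("both carrier groups need n >= 2 (got %d and %d)", st$n1, st$n2)
  w <- welch_test(list(mean = st$mean1, sd = st$sd1, n = st$n1),
                  list(mean = st$mean2, sd = st$sd2, n = st$n2),
                  var_equal = var_equal)
  list(t = w$t, df = w$df, p.value = w$p.value)
}

#' Full variance decomposition for one sex stratum
#'
#' Chains the adjustment-step variances with the carrier grouping:
#' total variance V(U), known-environment variance V(E_known) (removed by
#' the covariate adjustment), adjusted variance V(U_adjusted), the gene's
#' additive variance V(A_gene) (between-carrier-group component), its
#' heritability share h2 = 100 V(A_gene)/V(U), and percent portions of
#' V(U). The recomputed total variance of the adjusted values (pooled
#' within + between) is reported alongside V(U_adjusted); published-style
#' totals can disagree with their own subgroup summaries, so both are kept.
#'
#' @param adjusted an [adjusted_urate()] result.
#' @param carriers logical carrier vector.
#' @param var_equal pooled-variance burden test.
#' @param unbiased bias-corrected additive variance (default off).
#' @return object of class `"variance_decomposition"` with fields `v_u`,
#'   `v_e_known`, `v_u_adjusted`, `v_a_gene`, `h2_gene` (percent),
#'   `portions` (percent of V(U)), `group_stats`, `burden`,
#'   `v_u_adjusted_recomputed`.
#' @export
decompose_variance <- function(adjusted, carriers, var_equal = FALSE,
                               unbiased = FALSE) {
  stopifnot(inherits(adjusted, "adjusted_phenotype"))
  st <- group_variance_stats(adjusted, carriers)
  v_a <- additive_variance(st, unbiased = unbiased)
  degenerate <- st$degenerate
  n <- st$n1 + st$n2
  within <- if (degenerate) NA_real_ else (st$n1 * st$v1 + st$n2 * st$v2) / n
  burden <- if (!degenerate && st$n1 >= 2 && st$n2 >= 2)
    burden_test(st, var_equal = var_equal) else NULL
  h2 <- if (degenerate) NA_real_ else heritability_share(v_a, adjusted$v_u)
  portions <- c(
    v_u = 100,
    v_e_known = 100 * adjusted$v_e_known / adjusted$v_u,
    v_a_gene = h2,
    unexplained = if (degenerate) NA_real_ else
      100 * (adjusted$v_u_adjusted - v_a) / adjusted$v_u
  )
  structure(list(v_u = adjusted$v_u, v_e_known = adjusted$v_e_known,
                 v_u_adjusted = adjusted$v_u_adjusted,
                 v_u_adjusted_recomputed = if (degenerate) NA_real_ else
                   within + v_a,
                 v_a_gene = v_a, h2_gene = h2, portions = portions,
                 group_stats = st, burden = burden, n = adjusted$n,
                 degenerate = degenerate),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, digits = 2, ...) {
  cat("Variance decomposition of serum urate\n")
  tab <- decomposition_table(x)
  tab$variance <- round(tab$variance, digits)
  tab$portion_pct <- round(tab$portion_pct, 1)
  print(tab, row.names = FALSE)
  if (!is.null(x$burden))
    cat(sprintf("Burden test (carriers vs wild type): t = %.2f, df = %.1f, p = %.3g\n",
                x$burden$t, x$burden$df, x$burden$p.value))
  if (x$degenerate)
    cat("NOTE: no carriers in this stratum; gene components undefined\n")
  invisible(x)
}

#' Decomposition report table
#'
#' @param x a `variance_decomposition`.
#' @return data.frame with rows V(U), V(E_known), V(A_gene) and columns
#'   `component`, `variance`, `portion_pct`.
#' @export
decomposition_table <- function(x) {
  stopifnot(inherits(x, "variance_decomposition"))
  data.frame(component = c("V(U)", "V(E_known)", "V(A_gene)"),
             variance = c(x$v_u, x$v_e_known, x$v_a_gene),
             portion_pct = c(100, unname(x$portions["v_e_known"]),
                             x$h2_gene),
             stringsAsFactors = FALSE)
}
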