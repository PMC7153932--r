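as_group_summary <- function(x, what = "group") {
  if (is.numeric(x) && length(x) > 1L) {
    n <- length(x)
    return(list(mean = mean(x), se = stats::sd(x) / sqrt(n), n = n))
  }
  if (is.data.frame(x)) x <- as.list(x)
  if (is.list(x)) {
    n <- x$n
    if (is.null(n) || n < 2) stopf("%s needs n >= 2", what)
    m <- x$mean
    se <- x$se %||% (if (!is.null(x$sd)) x$sd / sqrt(n) else NULL)
    if (!is.null(x$uptake)) {  # raw-mode assay record
      v <- x$uptake
      return(list(mean = mean(v), se = stats::sd(v) / sqrt(length(v)),
                  n = length(v)))
    }
    if (is.null(m) || is.null(se))
      stopf("%s needs mean and se (or sd and n), or a raw vector", what)
    if (se < 0) stopf("%s SE must be nonnegative", what)
    return(list(mean = m, se = se, n = n))
  }
  stopf("%s must be a raw numeric vector or a list with mean/se (or sd)/n",
        what)
}

#' Welch two-sample t-test from raw values or summary statistics
#'
#' The test statistic is `t = (m_a - m_b) / sqrt(se_a^2 + se_b^2)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value from the t
#' distribution. Summary-statistic mode is first-class because published
#' assay tables report only (mean, SE, n); raw numeric vectors are reduced
#' to their summaries first. With `var_equal = TRUE` the pooled (Student)
#' form with `n_a + n_b - 2` df is used instead.
#'
#' Degenerate inputs: if both SEs are zero the test is decided by the means
#' alone (equal means: p = 1; unequal: p = 0 with a warning).
#'
#' @param a,b each either a raw numeric vector (length >= 2) or a list /
#'   one-row data.frame with `mean`, `se` (or `sd`), `n`.
#' @param var_equal use the pooled-variance Student form.
#' @return list with `t`, `df`, `p.value`, `mean_a`, `mean_b`.
#' @export
welch_test <- function(a, b, var_equal = FALSE) {
  ga <- as_group_summary(a, "group a")
  gb <- as_group_summary(b, "group b")
  dm <- ga$mean - gb$mean
  if (ga$se == 0 && gb$se == 0) {
    if (isTRUE(all.equal(ga$mean, gb$mean))) {
      return(list(t = 0, df = Inf, p.value = 1,
                  mean_a = ga$mean, mean_b = gb$mean))
    }
    warning("both groups have zero SE with unequal means; p = 0 by convention")
    return(list(t = sign(dm) * Inf, df = Inf, p.value = 0,
                mean_a = ga$mean, mean_b = gb$mean))
  }
  if (var_equal) {
    s2a <- ga$se^2 * ga$n
    s2b <- gb$se^2 * gb$n
    df <- ga$n + gb$n - 2
    sp2 <- ((ga$n - 1) * s2a + (gb$n - 1) * s2b) / df
    se <- sqrt(sp2 * (1 / ga$n + 1 / gb$n))
  } else {
    se <- sqrt(ga$se^2 + gb$se^2)
    df <- (ga$se^2 + gb$se^2)^2 /
      (ga$se^4 / (ga$n - 1) + gb$se^4 / (gb$n - 1))
  }
  t <- dm / se
  list(t = t, df = df, p.value = 2 * stats::pt(-abs(t), df),
       mean_a = ga$mean, mean_b = gb$mean)
}

#' Classify a variant's effect on transporter function
#'
#' A variant is called `function_affecting` when its uptake is significantly
#' *lower* than wild type (two-sided Welch p below `alpha` and variant mean
#' below the wild-type mean); the direction guard ensures an uptake increase
#' is never called function-affecting. Stop-gain and validated
#' splice-disrupting variants without assay data are classified
#' `loss_of_function_annotation` from the annotation alone; a variant with
#' neither assay nor loss-of-function annotation is `untested`.
#'
#' @param assay the variant's uptake assay (raw vector or mean/se/n list),
#'   or `NULL` if unassayed.
#' @param wildtype the wild-type assay in the same form.
#' @param annotation consequence class: one of `missense`, `stop_gain`,
#'   `splice` (validated splice-disrupting), `splice_region`, `synonymous`;
#'   may be `NA`.
#' @param alpha significance threshold, default 0.01.
#' @return list (class `"functional_call"`) with `status`, `t`, `df`,
#'   `p.value`, `direction` (`lower`/`higher`/`none`).
#' @export
classify_variant <- function(assay, wildtype,
                             annotation = NA_character_, alpha = 0.01) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stopf("alpha must lie in (0, 1)")
  if (!is.null(assay)) {
    w <- welch_test(assay, wildtype)
    direction <- if (w$mean_a < w$mean_b) "lower"
                 else if (w$mean_a > w$mean_b) "higher" else "none"
    status <- if (w$p.value < alpha && direction == "lower")
      "function_affecting" else "neutral"
    out <- list(status = status, t = w$t, df = w$df, p.value = w$p.value,
                direction = direction)
  } else if (!is.na(annotation) && annotation %in% c("stop_gain", "splice")) {
    out <- list(status = "loss_of_function_annotation", t = NA_real_,
                df = NA_real_, p.value = NA_real_, direction = "lower")
  } else {
    out <- list(status = "untested", t = NA_real_, df = NA_real_,
                p.value = NA_real_, direction = "none")
  }
  structure(out, class = "functional_call")
}

#' Classify a panel of variants against wild type
#'
#' @param assay_summary data.frame with columns `variant_id`, `mean`, `se`,
#'   `n` (one row may be `wildtype` and is used as the reference unless
#'   `wildtype` is supplied); variants absent from the table fall back to
#'   annotation-driven classification.
#' @param annotations data.frame with `variant_id` and `consequence`.
#' @param alpha significance threshold.
#' @param wildtype optional explicit wild-type summary (list mean/se/n).
#' @return data.frame with one row per annotated variant: `variant_id`,
#'   `status`, `t`, `df`, `p.value`, `direction`.
#' @export
classify_variants <- function(assay_summary, annotations, alpha = 0.01,
                              wildtype = NULL) {
  if (is.null(wildtype)) {
    wt_row <- assay_summary$variant_id %in% c("wildtype", "Wildtype", "WT")
    if (!any(wt_row))
      stopf("assay table has no wildtype row and no explicit wildtype given")
    wildtype <- as.list(assay_summary[which(wt_row)[1L],
                                      c("mean", "se", "n")])
  }
  rows <- lapply(seq_len(nrow(annotations)), function(i) {
    vid <- annotations$variant_id[i]
    hit <- assay_summary$variant_id == vid
    assay <- if (any(hit))
      as.list(assay_summary[which(hit)[1L], c("mean", "se", "n")]) else NULL
    fc <- classify_variant(assay, wildtype, annotations$consequence[i], alpha)
    data.frame(variant_id = vid, status = fc$status, t = fc$t, df = fc$df,
               p.value = fc$p.value, direction = fc$direction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Qualifying variant set from functional calls
#'
#' The default carrier-grouping set: assay-classified function-affecting
#' variants plus annotation-driven loss-of-function variants.
#'
#' @param calls data.frame from [classify_variants()].
#' @return character vector of variant ids.
#' @export
qualifying_variants <- function(calls) {
  calls$variant_id[calls$status %in%
                     c("function_affecting", "loss_of_function_annotation")]
}

#' Per-variant alternative-allele frequency (percent)
#'
#' `100 * (alternative allele count) / (2 * non-missing genotyped
#' participants)` within a stratum. A variant with all calls missing in the
#' stratum gets `NA`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param stratum participant subset: logical vector, indices, or ids;
#'   default all participants. Must be nonempty.
#' @return named numeric vector of percents in `[0, 100]`.
#' @export
allele_frequency <- function(genotypes, stratum = NULL) {
  counts <- genotypes$counts
  if (!is.null(stratum)) {
    counts <- counts[stratum, , drop = FALSE]
  }
  if (nrow(counts) == 0L) stopf("stratum is empty")
  alt <- colSums(counts, na.rm = TRUE)
  denom <- 2 * colSums(!is.na(counts))
  out <- ifelse(denom > 0, 100 * alt / denom, NA_real_)
  stats::setNames(out, colnames(counts))
}

#' Per-participant carrier status
#'
#' A participant is a carrier when they hold at least one alternative allele
#' at at least one qualifying variant; compound heterozygotes count once.
#' A participant whose genotypes are missing at *all* qualifying sites gets
#' `NA` (and should be dropped from grouped analyses); observed homozygous
#' reference at any site with the rest missing counts as non-carrier.
#'
#' @param genotypes a [genotype_matrix()].
#' @param qualifying character vector of qualifying variant ids (must all be
#'   present); an empty set yields all-FALSE.
#' @return logical vector, one element per participant (NA = undetermined).
#' @export
carrier_status <- function(genotypes, qualifying) {
  missing_ids <- setdiff(qualifying, colnames(genotypes$counts))
  if (length(missing_ids))
    stopf("qualifying variant(s) not in genotype matrix: %s",
          paste(missing_ids, collapse = ", "))
  n <- nrow(genotypes$counts)
  if (length(qualifying) == 0L)
    return(stats::setNames(rep(FALSE, n), rownames(genotypes$counts)))
  q <- genotypes$counts[, qualifying, drop = FALSE]
  any_alt <- rowSums(q > 0, na.rm = TRUE) > 0
  all_missing <- rowSums(!is.na(q)) == 0
  out <- any_alt
  out[all_missing] <- NA
  stats::setNames(out, rownames(genotypes$counts))
}
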