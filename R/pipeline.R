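#' Pipeline configuration
#'
#' Exactly one input mode must be active: file paths (`phenotypes`, `vcf`,
#' `assay`, `annotations`) or a `simulate` block (a [sim_config()]).
#'
#' @param phenotypes phenotype TSV path (see [read_phenotypes()]).
#' @param vcf genotype VCF path (see [read_vcf()]).
#' @param assay uptake assay TSV path: columns `variant_id`, `mean`, `se`,
#'   `n` (a `wildtype` row required), or long raw format `variant_id`,
#'   `oocyte`, `uptake`.
#' @param annotations variant annotation TSV path: columns `variant_id`,
#'   `consequence`.
#' @param qualifying optional path to a plain-text qualifying-variant list
#'   (one id per line) overriding the classification-derived set.
#' @param simulate a [sim_config()]; mutually exclusive with the paths.
#' @param alpha classification significance threshold.
#' @param var_equal pooled-variance burden test.
#' @param divisor variance divisor for descriptive SD columns in reports
#'   (`"n-1"` or `"n"`); decomposition variances always use divisor n.
#' @param seed seed recorded and used for any simulation.
#' @return object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(phenotypes = NULL, vcf = NULL, assay = NULL,
                            annotations = NULL, qualifying = NULL,
                            simulate = NULL, alpha = 0.01,
                            var_equal = FALSE, divisor = c("n-1", "n"),
                            seed = 1L) {
  divisor <- match.arg(divisor)
  have_paths <- !is.null(phenotypes) || !is.null(vcf) || !is.null(assay)
  if (have_paths && !is.null(simulate))
    stopf("give either input paths or a simulate block, not both")
  if (!have_paths && is.null(simulate))
    stopf("give input paths (phenotypes, vcf, assay) or a simulate block")
  if (have_paths && (is.null(phenotypes) || is.null(vcf)))
    stopf("path mode needs both phenotypes and vcf")
  if (have_paths && is.null(assay) && is.null(annotations) &&
      is.null(qualifying))
    stopf("path mode needs an assay or annotations table, or a qualifying list")
  if (!is.null(simulate) && !inherits(simulate, "sim_config"))
    stopf("simulate must be a sim_config object")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  structure(list(phenotypes = phenotypes, vcf = vcf, assay = assay,
                 annotations = annotations, qualifying = qualifying,
                 simulate = simulate, alpha = alpha, var_equal = var_equal,
                 divisor = divisor, seed = as.integer(seed)),
            class = "pipeline_config")
}

read_assay_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (all(c("variant_id", "oocyte", "uptake") %in% names(d))) {
    summ <- do.call(rbind, lapply(split(d, d$variant_id), function(g) {
      data.frame(variant_id = g$variant_id[1L], mean = mean(g$uptake),
                 se = stats::sd(g$uptake) / sqrt(nrow(g)), n = nrow(g),
                 stringsAsFactors = FALSE)
    }))
    rownames(summ) <- NULL
    return(summ)
  }
  need <- c("variant_id", "mean", "se", "n")
  if (!all(need %in% names(d)))
    stopf("assay table needs columns %s (summary) or variant_id/oocyte/uptake (raw)",
          paste(need, collapse = ", "))
  d[, need]
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (optional) -> filter -> classify -> adjust ->
#' decompose, per sex stratum, writing report tables (functional calls,
#' regression, carrier-group statistics, decomposition), an exclusion
#' tally, a JSON summary (additive variance, heritability share, burden p
#' per stratum), and a stage log. Re-running with the same config and seed
#' is byte-identical. Any stage error aborts with the stage name and
#' removes partial outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with per-stratum `urate_h2` fits, the
#'   functional call table, the exclusion tally, and the summary list.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  emit <- function(obj, file) {
    path <- file.path(out_dir, file)
    utils::write.table(obj, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    written <<- c(written, path)
    path
  }
  stage <- "setup"
  result <- tryCatch({
    if (!is.null(config$simulate)) {
      stage <- "simulate"
      cohort <- simulate_cohort(config$simulate)
      phen_path <- file.path(out_dir, "phenotypes.tsv")
      write_phenotypes(cohort$participants, phen_path)
      vcf_path <- file.path(out_dir, "genotypes.vcf")
      write_vcf(cohort$genotypes, vcf_path)
      written <- c(written, phen_path, vcf_path)
      assay_means <- stats::setNames(uptake_reference()$mean,
                                     uptake_reference()$variant_id)
      assay_sds <- stats::setNames(uptake_reference()$se * sqrt(10),
                                   uptake_reference()$variant_id)
      assay <- simulate_uptake_assay(assay_means, n_oocytes = 10L,
                                     noise_sd = assay_sds,
                                     seed = config$simulate$seed)$summary
      ann <- cohort$genotypes$variants[, c("variant_id", "consequence")]
      participants <- cohort$participants
      genotypes <- cohort$genotypes
      true_path <- file.path(out_dir, "true_parameters.json")
      jsonlite::write_json(cohort$true, true_path, auto_unbox = TRUE,
                           digits = NA)
      written <- c(written, true_path)
      note("simulate: %d participants, %d variants",
           nrow(participants), nrow(genotypes$variants))
    } else {
      stage <- "read"
      participants <- read_phenotypes(config$phenotypes)
      genotypes <- read_vcf(config$vcf)
      assay <- if (!is.null(config$assay)) read_assay_table(config$assay)
               else NULL
      ann <- if (!is.null(config$annotations))
        utils::read.delim(config$annotations, stringsAsFactors = FALSE)
      else NULL
      note("read: %d participants, %d variants",
           nrow(participants), nrow(genotypes$variants))
    }

    stage <- "filter"
    filt <- apply_exclusions(participants)
    tally <- filt$tally
    emit(data.frame(category = c(names(tally$per_flag),
                                 "excluded_union", "input", "retained"),
                    n = c(unname(tally$per_flag), tally$n_excluded,
                          tally$n_input, tally$n_retained)),
         "exclusion_tally.tsv")
    note("filter: %d in, %d excluded (union; per-category counts overlap), %d retained",
         tally$n_input, tally$n_excluded, tally$n_retained)
    strata <- stratify_by_sex(filt$retained)
    note("stratify: %d men, %d women",
         nrow(strata$male), nrow(strata$female))

    stage <- "classify"
    if (!is.null(config$qualifying)) {
      qualifying <- readLines(config$qualifying)
      qualifying <- qualifying[nzchar(trimws(qualifying))]
      calls <- NULL
      note("classify: qualifying set of %d variant(s) supplied by user",
           length(qualifying))
    } else {
      if (is.null(ann)) stopf("no annotations available for classification")
      calls <- classify_variants(assay, ann, alpha = config$alpha)
      qualifying <- qualifying_variants(calls)
      emit(calls, "functional_calls.tsv")
      note("classify: %d of %d variants qualify (alpha = %g)",
           length(qualifying), nrow(calls), config$alpha)
    }
    qualifying <- intersect(qualifying, colnames(genotypes$counts))

    stage <- "adjust/decompose"
    fits <- list()
    summary_list <- list(seed = config$seed, alpha = config$alpha,
                         t_test = if (config$var_equal) "student" else "welch",
                         egfr_coefficient = 0.908)
    freq_rows <- list()
    for (s in c("male", "female")) {
      d <- strata[[s]]
      if (nrow(d) == 0L) { note("%s: empty stratum, skipped", s); next }
      if (all(is.na(d$egfr)) && !all(is.na(d$serum_creatinine)))
        d$egfr <- egfr(d$serum_creatinine, d$age, d$sex)
      carrier <- carrier_status(genotypes, qualifying)[d$id]
      fit <- urate_h2(urate ~ age + bmi + egfr + hba1c, data = d,
                      carrier = carrier, var_equal = config$var_equal)
      fits[[s]] <- fit
      freq_rows[[s]] <- data.frame(
        sex = s, variant_id = colnames(genotypes$counts),
        af_pct = unname(allele_frequency(genotypes, d$id)),
        stringsAsFactors = FALSE)
      emit(fit$adjustment$coefficients, sprintf("regression_%s.tsv", s))
      st <- fit$group_stats
      emit(data.frame(group = c("all", "carriers", "wildtype"),
                      n = c(st$n1 + st$n2, st$n2, st$n1),
                      mean = c(st$grand_mean, st$mean2, st$mean1),
                      sd = c(stats::sd(fit$adjusted$values[!is.na(fit$carrier)]),
                             st$sd2, st$sd1)),
           sprintf("group_stats_%s.tsv", s))
      emit(decomposition_table(fit$decomposition),
           sprintf("decomposition_%s.tsv", s))
      dct <- fit$decomposition
      summary_list[[s]] <- list(
        n = fit$n, n_carriers = st$n2, n_wildtype = st$n1,
        v_u = dct$v_u, v_e_known = dct$v_e_known,
        v_u_adjusted = dct$v_u_adjusted, v_a_gene = dct$v_a_gene,
        h2_gene_pct = dct$h2_gene,
        burden_t = if (!is.null(dct$burden)) dct$burden$t else NA,
        burden_df = if (!is.null(dct$burden)) dct$burden$df else NA,
        burden_p = if (!is.null(dct$burden)) dct$burden$p.value else NA)
      note("%s: n = %d, carriers = %d, V(A) = %.4f, h2 = %.2f%%, burden p = %.3g",
           s, fit$n, st$n2, dct$v_a_gene, dct$h2_gene,
           if (!is.null(dct$burden)) dct$burden$p.value else NA)
    }
    emit(do.call(rbind, freq_rows), "allele_frequencies.tsv")

    stage <- "report"
    json_path <- file.path(out_dir, "summary.json")
    jsonlite::write_json(summary_list, json_path, auto_unbox = TRUE,
                         digits = NA)
    written <- c(written, json_path)
    log_path <- file.path(out_dir, "pipeline.log")
    writeLines(log_lines, log_path)
    list(fits = fits, functional_calls = calls, tally = tally,
         summary = summary_list, qualifying = qualifying)
  }, error = function(e) {
    unlink(written)
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  invisible(result)
}
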