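EXCLUSION_FLAGS <- c("withdrew_consent", "missing_data", "ovariectomy",
                     "diabetes", "urate_lowering_drug")

#' Genotype matrix container
#'
#' Diploid alternative-allele counts (0/1/2, NA = missing call) for
#' participants (rows) by variants (columns), with variant metadata.
#'
#' @param counts integer matrix, participants x variants, with dimnames.
#' @param variants data.frame with at least `variant_id` matching the
#'   column names of `counts`; typically also `chrom`, `pos`, `ref`, `alt`,
#'   `consequence`, `functional`.
#' @return object of class `"genotype_matrix"`.
#' @export
genotype_matrix <- function(counts, variants) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must have participant row names and variant column names")
  if (!identical(colnames(counts), variants$variant_id))
    stopf("variants$variant_id must match counts column names in order")
  bad <- counts[!is.na(counts) & !(counts %in% 0:2)]
  if (length(bad)) stopf("allele counts must be 0, 1, 2, or NA")
  structure(list(counts = counts, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d participants x %d variants (%d missing calls)\n",
              nrow(x$counts), ncol(x$counts), sum(is.na(x$counts))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$counts)

#' Read a phenotype table
#'
#' Reads a tab-separated phenotype table with columns `id`, `sex`, `age`,
#' `bmi`, `hba1c`, `urate`, at least one of `serum_creatinine` / `egfr`, and
#' an optional `flags` column (comma-separated exclusion flags among
#' withdrew_consent, missing_data, ovariectomy, diabetes,
#' urate_lowering_drug). Rows whose required numeric fields are empty or
#' unparseable are retained with the `missing_data` flag added rather than
#' aborting; structurally invalid values (nonpositive age/BMI, negative
#' urate, ovariectomy flag on a male) are hard errors listing the row ids.
#'
#' @param path file path.
#' @return data.frame of typed participant records.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stopf("phenotype file not found: %s", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("id", "sex", "age", "bmi", "hba1c", "urate")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stopf("phenotype table is missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  if (!any(c("serum_creatinine", "egfr") %in% names(raw)))
    stopf("phenotype table needs at least one of: serum_creatinine, egfr")
  if (!"flags" %in% names(raw)) raw$flags <- ""
  if (!"serum_creatinine" %in% names(raw)) raw$serum_creatinine <- ""
  if (!"egfr" %in% names(raw)) raw$egfr <- ""
  num <- function(x) suppressWarnings(as.numeric(x))
  out <- data.frame(id = raw$id, sex = normalize_sex(raw$sex),
                    age = num(raw$age), bmi = num(raw$bmi),
                    serum_creatinine = num(raw$serum_creatinine),
                    egfr = num(raw$egfr), hba1c = num(raw$hba1c),
                    urate = num(raw$urate),
                    flags = gsub("[[:space:]]", "", raw$flags),
                    stringsAsFactors = FALSE)
  known <- c(EXCLUSION_FLAGS, "")
  toks <- unique(unlist(strsplit(out$flags, "[,;]")))
  if (length(setdiff(toks, known)))
    stopf("unknown exclusion flag(s): %s",
          paste(setdiff(toks, known), collapse = ", "))
  incomplete <- is.na(out$age) | is.na(out$bmi) | is.na(out$hba1c) |
    is.na(out$urate) | is.na(out$sex) |
    (is.na(out$serum_creatinine) & is.na(out$egfr))
  out$flags[incomplete] <- ifelse(nzchar(out$flags[incomplete]),
                                  paste0(out$flags[incomplete], ",missing_data"),
                                  "missing_data")
  validate_participants(out)
  out
}

normalize_sex <- function(x) {
  s <- tolower(trimws(x))
  s[s %in% c("m", "male", "man", "men", "1")] <- "male"
  s[s %in% c("f", "female", "woman", "women", "2")] <- "female"
  s[!s %in% c("male", "female")] <- NA_character_
  s
}

validate_participants <- function(p) {
  chk <- function(bad, what) {
    bad <- bad & !has_flag(p$flags, "missing_data")
    if (any(bad, na.rm = TRUE))
      stopf("invalid %s for participant(s): %s", what,
            paste(p$id[which(bad)], collapse = ", "))
  }
  chk(!is.na(p$age) & p$age <= 0, "age (must be > 0)")
  chk(!is.na(p$bmi) & p$bmi <= 0, "BMI (must be > 0)")
  chk(!is.na(p$urate) & p$urate < 0, "urate (must be >= 0)")
  chk(!is.na(p$hba1c) & p$hba1c <= 0, "HbA1c (must be > 0)")
  ovx <- has_flag(p$flags, "ovariectomy") & !is.na(p$sex) & p$sex == "male"
  if (any(ovx))
    stopf("ovariectomy flag set for male participant(s): %s",
          paste(p$id[ovx], collapse = ", "))
  invisible(p)
}

has_flag <- function(flags, flag) {
  vapply(strsplit(flags, "[,;]"), function(f) flag %in% f, logical(1L))
}

#' Write a phenotype table
#'
#' Inverse of [read_phenotypes()]: tab-separated, one row per participant.
#'
#' @param participants participant data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(participants, path) {
  utils::write.table(participants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read genotypes from a minimal VCF
#'
#' Parses a VCFv4.2 file with diploid GT calls (via `vcfR`) into a
#' [genotype_matrix()]. Only the GT field is used; positions are 1-based.
#' Multi-allelic rows must be pre-split (a comma in ALT is an error naming
#' the site), and any non-diploid or malformed GT is an error naming the
#' site. Missing calls (`./.` or `.`) become `NA` counts, not 0.
#'
#' @param path VCF path.
#' @return a [genotype_matrix()]; variant ids are the VCF ID column, or
#'   `chrom:pos` where ID is `.`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stopf("VCF file not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix_mat <- vcfR::getFIX(v)
  if (is.null(dim(fix_mat))) fix_mat <- t(fix_mat)  # single-record VCF
  fix <- as.data.frame(fix_mat, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stopf("VCF contains no variant records: %s", path)
  site <- paste0(fix$CHROM, ":", fix$POS)
  if (any(grepl(",", fix$ALT, fixed = TRUE)))
    stopf("multi-allelic site(s) must be pre-split: %s",
          paste(site[grepl(",", fix$ALT, fixed = TRUE)], collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stopf("VCF has no GT format field: %s", path)
  parse_col <- function(calls, where) {
    calls[is.na(calls)] <- "."
    counts <- rep(NA_integer_, length(calls))
    ok_missing <- calls %in% c(".", "./.", ".|.")
    alleles <- strsplit(calls, "[/|]")
    diploid <- lengths(alleles) == 2L
    valid <- diploid & vapply(alleles, function(a) all(a %in% c("0", "1")),
                              logical(1L))
    bad <- !ok_missing & !valid
    if (any(bad))
      stopf("malformed or non-diploid GT at %s: %s", where,
            paste(unique(calls[bad]), collapse = ", "))
    counts[valid] <- vapply(alleles[valid], function(a) sum(a == "1"),
                            integer(1L))
    counts
  }
  counts <- vapply(seq_len(nrow(gt)),
                   function(i) parse_col(gt[i, ], site[i]),
                   integer(ncol(gt)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = ncol(gt))
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".", site, fix$ID)
  dimnames(counts) <- list(colnames(gt), ids)
  variants <- data.frame(variant_id = ids, chrom = fix$CHROM,
                         pos = as.integer(fix$POS), ref = fix$REF,
                         alt = fix$ALT, stringsAsFactors = FALSE)
  genotype_matrix(counts, variants)
}

#' Write genotypes as a minimal VCF
#'
#' Emits a plain-text VCFv4.2 file with one sample column per participant
#' and GT-only genotypes (missing counts as `./.`). Round-trips through
#' [read_vcf()].
#'
#' @param genotypes a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  v <- genotypes$variants
  chrom <- v$chrom %||% rep("11", nrow(v))
  pos <- v$pos %||% seq_len(nrow(v))
  ref <- v$ref %||% rep("A", nrow(v))
  alt <- v$alt %||% rep("T", nrow(v))
  gt_str <- c("0/0", "0/1", "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(genotypes$counts)),
                   collapse = "\t"))
  for (j in seq_len(nrow(v))) {
    calls <- ifelse(is.na(genotypes$counts[, j]), "./.",
                    gt_str[genotypes$counts[, j] + 1L])
    lines <- c(lines, paste(c(chrom[j], pos[j], v$variant_id[j], ref[j],
                              alt[j], ".", "PASS", ".", "GT", calls),
                            collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Apply participant exclusion rules
#'
#' Removes the union of participants carrying any exclusion flag
#' (withdrew_consent, missing_data, ovariectomy, diabetes,
#' urate_lowering_drug). Flags may overlap, so per-category counts can sum
#' to more than the union; the tally reports both.
#'
#' @param participants participant data.frame (as from [read_phenotypes()]).
#' @return list with `retained` (flag-free participants) and `tally`
#'   (class `"exclusion_tally"`): per-category counts, `n_input`,
#'   `n_excluded` (union size), `n_retained`.
#' @export
apply_exclusions <- function(participants) {
  flag_mat <- vapply(EXCLUSION_FLAGS,
                     function(f) has_flag(participants$flags, f),
                     logical(nrow(participants)))
  if (is.null(dim(flag_mat)))
    flag_mat <- matrix(flag_mat, nrow = nrow(participants),
                       dimnames = list(NULL, EXCLUSION_FLAGS))
  excluded <- rowSums(flag_mat) > 0
  tally <- structure(list(per_flag = colSums(flag_mat),
                          n_input = nrow(participants),
                          n_excluded = sum(excluded),
                          n_retained = sum(!excluded)),
                     class = "exclusion_tally")
  list(retained = participants[!excluded, , drop = FALSE], tally = tally)
}

#' @export
print.exclusion_tally <- function(x, ...) {
  cat(sprintf("Participants: %d in, %d excluded (union), %d retained\n",
              x$n_input, x$n_excluded, x$n_retained))
  for (f in names(x$per_flag))
    cat(sprintf("  %-20s %d\n", f, x$per_flag[[f]]))
  cat("  (categories may overlap; union <= sum of categories)\n")
  invisible(x)
}

#' Stratify participants by sex
#'
#' @param participants participant data.frame with a `sex` column coded
#'   `male`/`female`; anything else is an error listing the offending ids.
#' @return list with `male` and `female` data.frames (disjoint, exhaustive).
#' @export
stratify_by_sex <- function(participants) {
  bad <- is.na(participants$sex) | !participants$sex %in% c("male", "female")
  if (any(bad))
    stopf("unknown sex code for participant(s): %s",
          paste(participants$id[bad], collapse = ", "))
  list(male = participants[participants$sex == "male", , drop = FALSE],
       female = participants[participants$sex == "female", , drop = FALSE])
}
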