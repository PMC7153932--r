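# Shared fixture builders; everything is generated in code at test time.

# numeric vector with exactly the requested mean and sample SD (divisor n-1)
vector_with_moments <- function(n, mean, sd, seed = 1) {
  set.seed(seed)
  z <- stats::rnorm(n)
  z <- (z - base::mean(z)) / stats::sd(z)
  mean + sd * z
}

# small sim config that runs fast
tiny_config <- function(seed = 1, ...) {
  sim_config(n_men = 120, n_women = 120, seed = seed, ...)
}

# published carrier-group summaries as group_stats objects
table4_stats <- function(sex = "male") {
  g <- group_reference()[[sex]]
  group_stats_from_summary(g$n_wt, g$mean_wt, g$sd_wt,
                           g$n_carrier, g$mean_carrier, g$sd_carrier)
}

# phenotype table fixture
phenotype_fixture <- function() {
  data.frame(
    id = c("P1", "P2", "P3", "P4", "P5", "P6"),
    sex = c("male", "female", "male", "female", "male", "female"),
    age = c(60, 55, 70, 48, 62, 51),
    bmi = c(24.1, 22.0, 26.3, 21.5, 25.0, 23.3),
    serum_creatinine = c(0.9, 0.7, 1.1, 0.6, 0.95, 0.75),
    egfr = c(85, 95, 70, 102, 80, 92),
    hba1c = c(5.4, 5.2, 5.8, 5.1, 5.5, 5.3),
    urate = c(6.2, 4.5, 7.1, 3.9, 5.8, 4.8),
    flags = c("", "", "", "", "", ""),
    stringsAsFactors = FALSE
  )
}

# tiny genotype matrix: 4 participants x 3 variants
genotype_fixture <- function() {
  counts <- matrix(c(0L, 1L, 0L, 2L,
                     0L, 0L, NA, 1L,
                     0L, 1L, 0L, 0L),
                   nrow = 4,
                   dimnames = list(c("P1", "P2", "P3", "P4"),
                                   c("v1", "v2", "v3")))
  variants <- data.frame(variant_id = c("v1", "v2", "v3"),
                         chrom = "11", pos = c(100L, 200L, 300L),
                         ref = c("G", "C", "A"), alt = c("A", "T", "G"),
                         consequence = c("missense", "stop_gain", "missense"),
                         functional = c(TRUE, TRUE, FALSE),
                         stringsAsFactors = FALSE)
  genotype_matrix(counts, variants)
}

# exact two-sided permutation p for a difference in group means
permutation_p <- function(x, y, n_perm = 1e5, seed = 42) {
  set.seed(seed)
  pooled <- c(x, y)
  n1 <- length(x)
  obs <- abs(mean(x) - mean(y))
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pooled), n1)
    d <- abs(mean(pooled[idx]) - mean(pooled[-idx]))
    if (d >= obs - 1e-12) hits <- hits + 1L
  }
  hits / n_perm
}
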