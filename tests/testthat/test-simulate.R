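test_that("identical seed and config give bit-identical cohorts", {
  a <- simulate_cohort(tiny_config(seed = 5))
  b <- simulate_cohort(tiny_config(seed = 5))
  expect_identical(a$genotypes$counts, b$genotypes$counts)
  expect_identical(a$participants, b$participants)
  expect_identical(a$true, b$true)
  d <- simulate_cohort(tiny_config(seed = 6))
  expect_false(identical(a$participants$urate, d$participants$urate))
})

test_that("config validation rejects out-of-range parameters", {
  v <- default_variant_table()
  v$freq_male[1] <- 0.6
  expect_error(sim_config(variants = v), "\\[0, 0.5\\]")
  expect_error(sim_config(n_men = 0), "positive")
  expect_error(sim_config(residual_sd = c(male = 0, female = 0.5)),
               "residual_sd")
})

test_that("genotypes follow the configured frequencies under HWE", {
  v <- data.frame(variant_id = c("a", "b"), functional = c(TRUE, FALSE),
                  freq_male = c(0, 0), freq_female = c(0, 0),
                  consequence = "missense", stringsAsFactors = FALSE)
  g0 <- simulate_genotypes(sim_config(n_men = 50, n_women = 50,
                                      variants = v, seed = 1))
  expect_true(all(g0$counts == 0L))

  v$freq_male <- v$freq_female <- c(0.5, 0.5)
  het_frac <- vapply(1:5, function(s) {
    g5 <- simulate_genotypes(sim_config(n_men = 3000, n_women = 3000,
                                        variants = v, seed = s))
    mean(g5$counts[, "a"] == 1L)
  }, numeric(1))
  expect_lt(abs(mean(het_frac) - 0.5), 3 * sqrt(0.25 / 6000) / sqrt(5))
})

test_that("realized allele frequency is binomially unbiased at a published rate", {
  # oracle: allele count ~ Binomial(2n, f); mean frequency over replicates = f
  f <- 0.046
  n <- 631
  v <- data.frame(variant_id = "w258x", functional = TRUE, freq_male = f,
                  freq_female = f, consequence = "stop_gain",
                  stringsAsFactors = FALSE)
  reps <- vapply(seq_len(2000), function(r) {
    g <- simulate_genotypes(sim_config(n_men = n, n_women = 1, variants = v,
                                       residual_sd = c(male = 1, female = 1),
                                       seed = r))
    sum(g$counts[seq_len(n), 1]) / (2 * n)
  }, numeric(1))
  mc_se <- sqrt(f * (1 - f) / (2 * n)) / sqrt(2000)
  expect_lt(abs(mean(reps) - f), 3 * mc_se)
})

test_that("degenerate phenotype model collapses to the intercept", {
  v <- data.frame(variant_id = "a", functional = TRUE, freq_male = 0.1,
                  freq_female = 0.1, consequence = "missense",
                  stringsAsFactors = FALSE)
  beta0 <- lapply(default_beta(), function(b) b * 0)
  cfg <- sim_config(n_men = 40, n_women = 40, beta = beta0,
                    intercept = c(male = 6, female = 4.5),
                    carrier_delta = 0,
                    residual_sd = c(male = 1e-9, female = 1e-9),
                    variants = v, seed = 3)
  ph <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
  expect_equal(ph$participants$urate[ph$participants$sex == "male"],
               rep(6, 40), tolerance = 1e-6)
  expect_equal(ph$participants$urate[ph$participants$sex == "female"],
               rep(4.5, 40), tolerance = 1e-6)
})

test_that("simulated stratum mean matches the model-implied expectation", {
  # oracle: E[urate] = intercept + sum(beta * covariate mean) (delta = 0)
  cfg <- sim_config(carrier_delta = 0, seed = 11)
  ph <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
  women <- ph$participants[ph$participants$sex == "female", ]
  implied <- cfg$intercept[["female"]] +
    sum(cfg$beta$female[cfg$covariate_params$female$variable] *
          cfg$covariate_params$female$mean)
  expect_equal(implied, 4.57, tolerance = 1e-8)  # intercept back-computed
  expect_lt(abs(mean(women$urate) - implied), 0.12)  # ~3 SD of the mean
  expect_equal(nrow(women), 647L)
})

test_that("adding a variant leaves phenotype draws unchanged (seed hierarchy)", {
  cfg1 <- tiny_config(seed = 9)
  extra <- cfg1$variants[1, ]
  extra$variant_id <- "extra_neutral"
  extra$functional <- FALSE
  extra$freq_male <- extra$freq_female <- 0.01
  cfg2 <- tiny_config(seed = 9, variants = rbind(cfg1$variants, extra))
  a <- simulate_cohort(cfg1)
  b <- simulate_cohort(cfg2)
  expect_identical(a$participants, b$participants)
  expect_identical(a$genotypes$counts,
                   b$genotypes$counts[, colnames(a$genotypes$counts)])
})

test_that("carrier-free model yields near-zero downstream additive variance", {
  h2 <- vapply(1:30, function(s) {
    cfg <- sim_config(n_men = 400, n_women = 2, carrier_delta = 0, seed = s)
    co <- simulate_cohort(cfg)
    men <- co$participants[co$participants$sex == "male", ]
    fit <- urate_h2(urate ~ age + bmi + egfr + hba1c, data = men,
                    carrier = co$carrier[men$id])
    fit$decomposition$v_a_gene
  }, numeric(1))
  expect_lt(mean(h2, na.rm = TRUE), 0.05)  # bias is O(V/n), ~0.005
})

test_that("uptake assay reproduces configured means and the SE = SD/sqrt(n) law", {
  a <- simulate_uptake_assay(c(wt = 8.202), n_oocytes = 10,
                             noise_sd = 1e-9, seed = 1)
  expect_equal(a$raw$uptake, rep(8.202, 10), tolerance = 1e-6)
  expect_lt(a$summary$se, 1e-9)

  ses <- vapply(seq_len(200), function(s) {
    simulate_uptake_assay(c(wt = 8.202), n_oocytes = 10,
                          noise_sd = 0.412 * sqrt(10),
                          seed = s)$summary$se
  }, numeric(1))
  expect_lt(abs(mean(ses) - 0.412), 0.03)

  expect_error(simulate_uptake_assay(c(a = 1), noise_sd = 0), "positive")
  expect_error(simulate_uptake_assay(c(a = 1), n_oocytes = 1, noise_sd = 1),
               "at least 2")
})

test_that("a strongly reduced simulated uptake is classified function-affecting", {
  wt_sd <- 0.412 * sqrt(10)
  hits <- vapply(seq_len(40), function(s) {
    a <- simulate_uptake_assay(c(wildtype = 8.202, mut = 0.215),
                               n_oocytes = 10, noise_sd = wt_sd, seed = s)
    wt <- as.list(a$summary[a$summary$variant_id == "wildtype",
                            c("mean", "se", "n")])
    mu <- as.list(a$summary[a$summary$variant_id == "mut",
                            c("mean", "se", "n")])
    classify_variant(mu, wt)$status == "function_affecting"
  }, logical(1))
  expect_gt(mean(hits), 0.95)
})

test_that("theoretical_h2 matches hand arithmetic and handles edge cases", {
  expect_equal(theoretical_h2(0.5, 0, 1), 0)
  expect_equal(theoretical_h2(1, -2, 1.5), 0)
  # hand evaluation: q(1-q) delta^2 / V at the published scale
  expect_equal(theoretical_h2(0.06, -2.04, 1.73),
               0.06 * 0.94 * 2.04^2 / 1.73)
  expect_equal(round(theoretical_h2(0.06, -2.04, 1.73), 4), 0.1357)
  expect_error(theoretical_h2(0.06, -2.04, 0), "positive")
  expect_error(theoretical_h2(1.2, 1, 1), "\\[0, 1\\]")
})

test_that("true parameters follow their defining identity", {
  co <- simulate_cohort(tiny_config(seed = 21))
  q <- co$true$male$carrier_freq_realized
  expect_equal(co$true$male$v_a_true,
               q * (1 - q) * co$config$carrier_delta^2)
  expect_gte(co$true$male$h2_true, 0)
  expect_lte(co$true$male$h2_true, 1)
})
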