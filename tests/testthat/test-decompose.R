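test_that("group statistics reproduce an engineered published-scale fixture", {
  # affine-transformed base vectors with exact means and sample SDs
  x1 <- vector_with_moments(596, 0.12, 1.25, seed = 1)
  x2 <- vector_with_moments(38, -1.92, 0.87, seed = 2)
  st <- group_variance_stats(c(x1, x2), c(rep(FALSE, 596), rep(TRUE, 38)))
  expect_equal(st$n1, 596)
  expect_equal(st$n2, 38)
  expect_equal(st$mean1, 0.12, tolerance = 1e-12)
  expect_equal(st$mean2, -1.92, tolerance = 1e-12)
  expect_equal(st$sd1, 1.25, tolerance = 1e-12)
  expect_equal(st$sd2, 0.87, tolerance = 1e-12)
  expect_equal(st$grand_mean, (596 * 0.12 - 38 * 1.92) / 634,
               tolerance = 1e-12)
  # divisor-n within-group variances
  expect_equal(st$v1, var_n(x1), tolerance = 1e-12)
})

test_that("degenerate groupings return explicit results, not zeros", {
  st <- group_variance_stats(rnorm(10), rep(FALSE, 10))
  expect_true(st$degenerate)
  expect_warning(va <- additive_variance(st), "empty")
  expect_true(is.na(va))

  two <- group_variance_stats(c(1.5, -0.5), c(FALSE, TRUE))
  expect_equal(two$v1, 0)
  expect_equal(two$v2, 0)
  expect_equal(two$mean1, 1.5)
  expect_equal(two$mean2, -0.5)
})

test_that("undetermined carriers are dropped and counted", {
  x <- rnorm(10)
  carr <- c(rep(FALSE, 6), rep(TRUE, 3), NA)
  expect_message(st <- group_variance_stats(x, carr), "undetermined")
  expect_equal(st$n1 + st$n2, 9)
  expect_equal(st$n_dropped, 1)
})

test_that("additive variance equals the ANOVA between-group oracle", {
  set.seed(91)
  for (i in 1:50) {
    n <- sample(6:40, 1)
    y <- rnorm(n)
    g <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(g)) < 2) next
    st <- group_variance_stats(y, g)
    # oracle: between-group sum of squares from one-way ANOVA, divided by n
    ss_between <- anova(lm(y ~ factor(g)))[["Sum Sq"]][1]
    expect_equal(additive_variance(st), ss_between / n, tolerance = 1e-10)
  }
})

test_that("law of total variance holds exactly under divisor n", {
  set.seed(17)
  for (i in 1:200) {
    n <- sample(4:60, 1)
    y <- rnorm(n, sd = runif(1, 0.1, 3))
    g <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(g)) < 2) next
    st <- group_variance_stats(y, g)
    within <- (st$n1 * st$v1 + st$n2 * st$v2) / (st$n1 + st$n2)
    expect_equal(var_n(y), within + additive_variance(st),
                 tolerance = 1e-12)
  }
})

test_that("additive variance is shift-invariant and scales quadratically", {
  y <- rnorm(30)
  g <- rep(c(TRUE, FALSE), 15)
  v0 <- additive_variance(group_variance_stats(y, g))
  expect_equal(additive_variance(group_variance_stats(y + 5, g)), v0,
               tolerance = 1e-12)
  expect_equal(additive_variance(group_variance_stats(3 * y, g)), 9 * v0,
               tolerance = 1e-12)
})

test_that("permuted labels show the documented positive O(V/n) null bias", {
  set.seed(5)
  n <- 60
  y <- rnorm(n)
  s2 <- var(y)  # sample variance, divisor n-1
  vals <- vapply(1:2000, function(i) {
    g <- sample(rep(c(TRUE, FALSE), c(6, 54)))
    additive_variance(group_variance_stats(y, g))
  }, numeric(1))
  # permutation-null expectation of the between component is s^2 (k-1)/n
  expect_equal(mean(vals), s2 / n, tolerance = 0.15)
  expect_gt(mean(vals), 0)
})

test_that("bias-corrected estimator is centered at zero under the null", {
  set.seed(6)
  vals <- vapply(1:500, function(i) {
    y <- rnorm(80)
    g <- sample(rep(c(TRUE, FALSE), c(8, 72)))
    additive_variance(group_variance_stats(y, g), unbiased = TRUE)
  }, numeric(1))
  # truncation at zero leaves a small positive mean; far below the raw bias 1/80
  expect_lt(mean(vals), 1 / 80)
})

test_that("heritability share behaves and flags the published rounding gap", {
  expect_equal(heritability_share(0, 1.73), 0)
  expect_error(heritability_share(0.2, 0), "positive")
  expect_error(heritability_share(-0.1, 1), "nonnegative")
  # direct arithmetic on the published women's values gives ~10.9%,
  # not the printed 10.5% (unprinted-precision rounding upstream)
  expect_equal(round(heritability_share(0.10, 0.92), 1), 10.9)
  expect_gt(heritability_share(0.10, 0.92), 10.5)
})

test_that("burden test matches t.test on raw data and errors on tiny groups", {
  set.seed(23)
  y <- rnorm(40)
  g <- rep(c(TRUE, FALSE), c(8, 32))
  ours <- burden_test(y, g)
  ref <- t.test(y[!g], y[g])
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
  pooled <- burden_test(y, g, var_equal = TRUE)
  refp <- t.test(y[!g], y[g], var.equal = TRUE)
  expect_equal(pooled$p.value, refp$p.value, tolerance = 1e-10)
  expect_error(burden_test(y, c(rep(FALSE, 39), TRUE)), "n >= 2")
})

test_that("burden p approximates a permutation reference on small samples", {
  set.seed(29)
  y <- c(rnorm(6, 0.7), rnorm(6))
  g <- rep(c(TRUE, FALSE), each = 6)
  p_perm <- permutation_p(y[g], y[!g], n_perm = 1e5)
  expect_lt(abs(burden_test(y, g)$p.value - p_perm), 0.05)
})

test_that("identical group summaries give p = 1", {
  st <- group_stats_from_summary(20, 0.5, 1.1, 20, 0.5, 1.1)
  expect_equal(burden_test(st)$p.value, 1)
  expect_equal(additive_variance(st), 0)
})

test_that("full decomposition satisfies its internal identities", {
  co <- simulate_cohort(tiny_config(seed = 31))
  men <- co$participants[co$participants$sex == "male", ]
  m <- fit_adjustment_model(men)
  a <- adjusted_urate(m, men)
  d <- decompose_variance(a, unname(co$carrier[men$id]))
  expect_equal(d$v_u, d$v_e_known + d$v_u_adjusted, tolerance = 1e-12)
  # law of total variance: recomputed total equals the adjusted variance
  expect_equal(d$v_u_adjusted_recomputed, d$v_u_adjusted, tolerance = 1e-12)
  expect_gte(d$v_a_gene, 0)
  expect_lte(d$v_a_gene, d$v_u_adjusted + 1e-12)
  expect_lte(d$h2_gene, 100 * d$v_u_adjusted / d$v_u + 1e-9)
  expect_true(all(d$portions >= -1e-9))
  expect_equal(sum(d$portions[c("v_e_known", "v_a_gene", "unexplained")]),
               100, tolerance = 1e-9)
  tab <- decomposition_table(d)
  expect_equal(tab$variance, c(d$v_u, d$v_e_known, d$v_a_gene))
})
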