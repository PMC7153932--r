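wt <- list(mean = 8.202, se = 0.412, n = 10)

test_that("welch_test is antisymmetric in t and symmetric in p", {
  a <- list(mean = 5.659, se = 0.181, n = 10)
  ab <- welch_test(a, wt)
  ba <- welch_test(wt, a)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p.value, ba$p.value)
  expect_equal(ab$df, ba$df)
})

test_that("welch_test on raw vectors agrees with stats::t.test", {
  set.seed(71)
  for (i in 1:20) {
    x <- rnorm(sample(3:12, 1), mean = 1)
    y <- rnorm(sample(3:12, 1), sd = 2)
    ours <- welch_test(x, y)
    ref <- t.test(x, y)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
    pooled <- welch_test(x, y, var_equal = TRUE)
    refp <- t.test(x, y, var.equal = TRUE)
    expect_equal(pooled$t, unname(refp$statistic), tolerance = 1e-12)
    expect_equal(pooled$p.value, refp$p.value, tolerance = 1e-12)
  }
})

test_that("welch_test handles degenerate zero-SE inputs by convention", {
  same <- welch_test(list(mean = 2, se = 0, n = 5), list(mean = 2, se = 0, n = 5))
  expect_equal(same$p.value, 1)
  expect_equal(same$t, 0)
  expect_warning(
    diffr <- welch_test(list(mean = 2, se = 0, n = 5),
                        list(mean = 3, se = 0, n = 5)),
    "zero SE")
  expect_equal(diffr$p.value, 0)
  ident <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t, 0)
  expect_equal(ident$p.value, 1)
})

test_that("welch p approximates an exact permutation reference on small samples", {
  set.seed(33)
  x <- rnorm(6, mean = 0.8)
  y <- rnorm(6)
  w <- welch_test(x, y)
  p_perm <- permutation_p(x, y, n_perm = 1e5)
  expect_lt(abs(w$p.value - p_perm), 0.05)
})

test_that("classification calls published variants as the assay dictates", {
  his540 <- list(mean = 0.175, se = 0.039, n = 10)
  expect_equal(classify_variant(his540, wt)$status, "function_affecting")
  expect_equal(classify_variant(his540, wt)$direction, "lower")

  gln533 <- list(mean = 7.898, se = 0.298, n = 10)
  call533 <- classify_variant(gln533, wt)
  expect_equal(call533$status, "neutral")
  expect_equal(round(call533$p.value, 2), 0.56)
})

test_that("an uptake increase is never function-affecting (direction guard)", {
  up <- list(mean = 20, se = 0.05, n = 10)
  call <- classify_variant(up, wt)
  expect_lt(call$p.value, 0.01)
  expect_equal(call$status, "neutral")
  expect_equal(call$direction, "higher")
})

test_that("annotation-driven and untested classifications work without assay", {
  expect_equal(classify_variant(NULL, wt, "stop_gain")$status,
               "loss_of_function_annotation")
  expect_equal(classify_variant(NULL, wt, "splice")$status,
               "loss_of_function_annotation")
  expect_equal(classify_variant(NULL, wt, "missense")$status, "untested")
  expect_equal(classify_variant(NULL, wt, NA)$status, "untested")
})

test_that("lowering alpha never converts neutral to function-affecting", {
  assays <- list(list(mean = 5.659, se = 0.181, n = 10),
                 list(mean = 7.898, se = 0.298, n = 10),
                 list(mean = 8.960, se = 0.469, n = 10))
  for (a in assays) {
    alphas <- c(0.2, 0.1, 0.05, 0.01, 0.001)
    st <- vapply(alphas,
                 function(al) classify_variant(a, wt, alpha = al)$status,
                 character(1))
    affecting <- st == "function_affecting"
    # monotone: once neutral at some alpha, neutral at every smaller alpha
    expect_true(all(diff(as.integer(affecting)) <= 0))
  }
})

test_that("classify_variants builds the published qualifying set", {
  ref <- uptake_reference()
  assay <- ref[ref$variant_id != "water", c("variant_id", "mean", "se", "n")]
  ann <- variant_reference()[, c("variant_id", "consequence")]
  calls <- classify_variants(assay, ann)
  q <- qualifying_variants(calls)
  # assay-significant reductions + stop gains + validated splice variant
  expect_setequal(q, c("rs552232030", "rs145738825", "rs201136391",
                       "chr11:64366046", "chr11:64368979",  # assay
                       "rs121907892",                        # stop gain
                       "rs58174038"))                        # splice
  expect_equal(calls$status[calls$variant_id == "rs144325235"], "untested")
})

test_that("allele frequency counts alleles over non-missing genotypes", {
  g <- genotype_fixture()
  af <- allele_frequency(g)
  expect_equal(unname(af["v1"]), 100 * 3 / 8)
  expect_equal(unname(af["v2"]), 100 * 1 / 6)  # P3 missing excluded
  expect_true(all(af >= 0 & af <= 100))
  expect_error(allele_frequency(g, stratum = character(0)), "empty")

  # single het among 631 men and the published 58/1262 case
  counts <- matrix(0L, nrow = 631, ncol = 2,
                   dimnames = list(sprintf("M%03d", 1:631), c("a", "b")))
  counts[1, "a"] <- 1L
  counts[1:29, "b"] <- 2L  # 58 alternative alleles
  gg <- genotype_matrix(counts, data.frame(variant_id = c("a", "b"),
                                           stringsAsFactors = FALSE))
  af2 <- allele_frequency(gg)
  expect_equal(unname(af2["a"]), 100 / 1262)
  expect_equal(round(unname(af2["b"]), 2), 4.60)
})

test_that("duplicating the stratum leaves allele frequency unchanged", {
  g <- genotype_fixture()
  doubled <- genotype_matrix(rbind(g$counts,
                                   `rownames<-`(g$counts,
                                                paste0(rownames(g$counts), "b"))),
                             g$variants)
  expect_equal(unname(allele_frequency(doubled)), unname(allele_frequency(g)))
})

test_that("carrier status collapses qualifying variants correctly", {
  g <- genotype_fixture()
  expect_equal(unname(carrier_status(g, character(0))), rep(FALSE, 4))
  cs <- carrier_status(g, c("v1", "v2"))
  # P2 carries v1 only; P4 carries both (compound) yet counts once
  expect_identical(unname(cs), c(FALSE, TRUE, FALSE, TRUE))
  # P3: v1 observed 0, v2 missing -> determined non-carrier by observed site
  expect_false(cs[["P3"]])
  # all qualifying sites missing -> undetermined
  counts <- g$counts
  counts["P3", c("v1", "v2")] <- NA
  g2 <- genotype_matrix(counts, g$variants)
  expect_true(is.na(carrier_status(g2, c("v1", "v2"))[["P3"]]))
  expect_error(carrier_status(g, "nope"), "not in genotype matrix")
})

test_that("an engineered cohort yields the published carrier count", {
  counts <- matrix(0L, nrow = 634, ncol = 1,
                   dimnames = list(sprintf("M%03d", 1:634), "q"))
  counts[1:38, 1] <- 1L
  g <- genotype_matrix(counts, data.frame(variant_id = "q",
                                          stringsAsFactors = FALSE))
  expect_equal(sum(carrier_status(g, "q")), 38)
})
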