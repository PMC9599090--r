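test_that("region t-tests match stats::t.test and handle degeneracy", {
  set.seed(20)
  a <- matrix(rnorm(40), 8, 5)
  b <- matrix(rnorm(30, mean = 0.5), 6, 5)
  res <- region_ttest(a, b)
  for (j in 1:5) {
    ref <- t.test(a[, j], b[, j], var.equal = TRUE)
    expect_equal(res$t[j], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p[j], ref$p.value, tolerance = 1e-10)
  }
  welch <- region_ttest(a, b, var_equal = FALSE)
  for (j in 1:5) {
    ref <- t.test(a[, j], b[, j], var.equal = FALSE)
    expect_equal(welch$t[j], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(welch$p[j], ref$p.value, tolerance = 1e-10)
  }

  # identical groups: t = 0, p = 1
  same <- region_ttest(a, a)
  expect_true(all(same$t == 0))
  expect_true(all(same$p == 1))
  expect_false(any(same$significant))
  fixed <- matrix(rep(c(1, 2, 3), 2), 3, 2)
  expect_true(all(region_ttest(fixed, fixed)$t == 0))

  # swapping groups flips t, preserves p
  swap <- region_ttest(b, a)
  expect_equal(swap$t, -res$t)
  expect_equal(swap$p, res$p)

  # zero pooled variance with differing means: explicit degenerate marker
  ca <- matrix(1, 3, 2); cb <- matrix(c(1, 2), 3, 2, byrow = TRUE)
  dg <- region_ttest(ca, cb)
  expect_equal(dg$degenerate, c(FALSE, TRUE))
  expect_true(is.na(dg$p[2]))
  expect_equal(dg$p[1], 1)

  expect_error(region_ttest(a[1, , drop = FALSE], b), "2 subjects")
})

test_that("permutation p-values are exact on enumerable instances", {
  # a = (10, 11) vs b = (0, 1): only the observed split and its mirror
  # reach |delta mean| >= 10 among the C(4, 2) = 6 relabelings
  res <- region_permutation_test(matrix(c(10, 11), 2, 1),
                                 matrix(c(0, 1), 2, 1),
                                 n_permutations = 1000)
  expect_true(res$exhaustive)
  expect_equal(res$permutation_p, 2 / 6)

  # identical multisets: observed delta = 0 never strictly exceeded
  x <- matrix(c(1, 2, 3), 3, 1)
  expect_equal(region_permutation_test(x, x,
                                       n_permutations = 1000)$permutation_p,
               1)

  # small instances enumerate all splits regardless of the requested count
  set.seed(5)
  a4 <- matrix(rnorm(12), 4, 3); b4 <- matrix(rnorm(12, 1), 4, 3)
  exact4 <- region_permutation_test(a4, b4, n_permutations = 10000)
  expect_true(all(exact4$exhaustive))
  expect_equal(exact4$n_permutations[1], choose(8, 4))

  # Monte-Carlo agrees with exhaustive enumeration on an 8-vs-8 toy
  a <- matrix(rnorm(24), 8, 3); b <- matrix(rnorm(24, 1), 8, 3)
  exact <- region_permutation_test(a, b, n_permutations = 20000)
  expect_true(exact$exhaustive[1])  # choose(16, 8) = 12870 splits
  mc <- region_permutation_test(a, b, n_permutations = 10000, seed = 9)
  expect_false(mc$exhaustive[1])
  expect_lt(max(abs(mc$permutation_p - exact$permutation_p)), 0.02)

  expect_error(region_permutation_test(a, b, n_permutations = 10), ">= 100")
  expect_error(region_permutation_test(a[1, , drop = FALSE], b,
                                       n_permutations = 100), "2 subjects")
})

test_that("permutation test is calibrated under the null", {
  # 1000 independent null regions, n = 10 + 10, 1000 label shuffles
  set.seed(101)
  a <- matrix(rnorm(10 * 1000), 10, 1000)
  b <- matrix(rnorm(10 * 1000), 10, 1000)
  res <- region_permutation_test(a, b, n_permutations = 1000, seed = 202)
  rate <- mean(res$permutation_p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("cross-modal correlation matches the closed-form oracle", {
  set.seed(3)
  m <- matrix(rnorm(25), 5, 5,
              dimnames = list(NULL, as.character(1:5)))
  s <- matrix(rnorm(25), 5, 5,
              dimnames = list(NULL, as.character(1:5)))
  res <- crossmodal_correlation(m, s, group = "AD")
  for (j in 1:5) {
    x <- m[, j]; y <- s[, j]
    r_oracle <- cov(x, y) / (sd(x) * sd(y))
    expect_equal(res$r[j], r_oracle, tolerance = 1e-12)
    expect_equal(res$p[j], cor.test(x, y)$p.value, tolerance = 1e-12)
  }

  # perfect linear coupling
  lin <- crossmodal_correlation(m, 2 * m + 1)
  expect_equal(lin$r, rep(1, 5), tolerance = 1e-12)
  neg <- crossmodal_correlation(m, -m)
  expect_equal(neg$r, rep(-1, 5), tolerance = 1e-12)

  # zero variance marked degenerate, never silent NaN
  s2 <- s; s2[, 2] <- 1
  dg <- crossmodal_correlation(m, s2)
  expect_true(dg$degenerate[2])
  expect_true(is.na(dg$r[2]))
  expect_error(crossmodal_correlation(m, s, regions = "99"), "regions")
})

test_that("hub vulnerability recovers designed and null associations", {
  nc <- toy_strength(runif(30, 1, 5), level = "group_mean",
                     scale = "pearson_r")
  mk_loss <- function(values) {
    sig <- baseline_sigma(nc, "per_node")
    structure(list(values = setNames(values, names(nc$values)),
                   level = "group_mean", subject_id = "AD",
                   baseline = sig, sign = "printed",
                   region_labels = nc$region_labels),
              class = "plfcs_vector")
  }
  # exact linear construction -> r = -1
  hv <- hub_vulnerability(nc, mk_loss(-0.2 * nc$values + 0.1))
  expect_equal(hv$r, -1, tolerance = 1e-12)
  expect_lt(hv$p, 1e-10)

  # independent noise: |r| small over many draws
  set.seed(8)
  rs <- replicate(50, hub_vulnerability(nc, mk_loss(rnorm(30)))$r)
  expect_lt(abs(mean(rs)), 0.1)
  expect_gt(mean(abs(rs) < 0.4), 0.8)

  bad <- toy_strength(runif(10), level = "group_mean", scale = "pearson_r")
  expect_error(hub_vulnerability(bad, mk_loss(rnorm(30))), "labels")
})

test_that("clinical correlations are exact and guard degenerate scores", {
  set.seed(6)
  metric <- data.frame(global_plfcs = rnorm(10))
  scores <- data.frame(mmse = 3 * metric$global_plfcs + 5,
                       cdr_sb = rnorm(10))
  res <- clinical_correlation(metric, scores, group = "MCI")
  expect_equal(res$r[res$score == "mmse"], 1, tolerance = 1e-12)
  ref <- cor.test(metric$global_plfcs, scores$cdr_sb)
  expect_equal(res$r[res$score == "cdr_sb"], unname(ref$estimate),
               tolerance = 1e-12)
  expect_equal(res$p[res$score == "cdr_sb"], ref$p.value,
               tolerance = 1e-12)

  const <- data.frame(mmse = rep(30, 10))
  dg <- clinical_correlation(metric, const)
  expect_true(dg$degenerate[1])
  expect_error(clinical_correlation(metric, data.frame(mmse = c(rep(1, 9),
                                                                NA))),
               "finite")
})

test_that("three-group ANOVA with Bonferroni post hoc behaves correctly", {
  # separated third group
  set.seed(12)
  vals <- c(rnorm(4, 0, 0.01), rnorm(4, 0, 0.01), rnorm(4, 10, 0.01))
  grp <- rep(c("NC", "MCI", "AD"), each = 4)
  res <- global_group_comparison(vals, grp)
  expect_lt(res$p, 0.001)
  ph <- res$posthoc
  vs_ad <- grepl("AD", ph$pair)
  expect_true(all(ph$p_bonferroni[vs_ad] < 0.001))
  expect_gt(ph$p_bonferroni[!vs_ad], 0.05)
  # Bonferroni arithmetic: capped at 1, factor 3 otherwise
  expect_equal(ph$p_bonferroni, pmin(1, 3 * ph$p_raw))

  # null: p roughly uniform over seeds
  ps <- sapply(1:60, function(s) {
    set.seed(s)
    global_group_comparison(rnorm(18), rep(c("a", "b", "c"), 6))$p
  })
  expect_gt(mean(ps < 0.05), 0.0)  # sanity: some variation
  expect_lt(mean(ps < 0.05), 0.2)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)

  expect_error(global_group_comparison(rnorm(5),
                                       c("a", "a", "b", "b", "c")),
               "at least 2")
})
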