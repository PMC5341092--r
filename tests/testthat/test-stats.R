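test_that("spearman matches hand ranking and the rank-formula oracle", {
  # monotone, no ties
  expect_equal(spearman(1:10, (1:10)^3)$statistic, 1)
  # hand-ranked example: d = (-1, 1, -1, 1), rho = 1 - 6*4/(4*15) = 0.6
  res <- spearman(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(res$statistic, 0.6)
  # oracle: classic no-ties formula 1 - 6*sum(d^2)/(n(n^2-1)), plus cor()
  set.seed(41)
  for (i in 1:5) {
    x <- rnorm(30); y <- rnorm(30)
    d <- rank(x) - rank(y)
    expect_equal(spearman(x, y)$statistic,
                 1 - 6 * sum(d^2) / (30 * (30^2 - 1)), tolerance = 1e-12)
    expect_equal(spearman(x, y)$statistic,
                 cor(x, y, method = "spearman"), tolerance = 1e-12)
  }
  # invariance under strictly monotone transforms
  x <- rexp(50); y <- rnorm(50)
  expect_equal(spearman(exp(x), y)$statistic, spearman(x, y)$statistic)
  expect_error(spearman(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("partial spearman equals the residual-regression-on-ranks oracle", {
  set.seed(42)
  n <- 8
  x <- rnorm(n); y <- x + rnorm(n); z1 <- rnorm(n); z2 <- x + rnorm(n)
  ctrl <- cbind(z1, z2)
  res <- partial_spearman(x, y, ctrl)
  # oracle: Pearson correlation of OLS residuals of the ranks
  rx <- rank(x); ry <- rank(y); rc <- apply(ctrl, 2, rank)
  ex <- residuals(lm(rx ~ rc))
  ey <- residuals(lm(ry ~ rc))
  expect_equal(res$statistic, cor(ex, ey), tolerance = 1e-10)
  expect_equal(res$df, n - 2 - 2)
  # empty control set reduces to the zero-order correlation
  expect_equal(partial_spearman(x, y)$statistic, spearman(x, y)$statistic)
  # y monotone in x with an independent control: partial correlation
  # stays near 1 (exactly tied ranks would make the matrix singular)
  big <- rnorm(50)
  expect_gt(partial_spearman(big, big + 0.05 * rnorm(50),
                             cbind(rnorm(50)))$statistic, 0.95)
  expect_error(partial_spearman(big, big^3, cbind(rnorm(50))), "singular")
})

test_that("kruskal-wallis matches hand computation and kruskal.test with ties", {
  res <- kruskal_wallis(list(c(1, 2), c(3, 4)))
  expect_equal(res$statistic, 2.4)
  expect_equal(res$df, 1)
  # identical groups: H = 0 after tie handling
  expect_equal(kruskal_wallis(list(c(5, 5, 7), c(5, 7, 5)))$statistic, 0,
               tolerance = 1e-12)
  # oracle: stats::kruskal.test on tied data
  set.seed(43)
  g <- list(sample(1:5, 20, TRUE), sample(2:6, 15, TRUE), sample(1:6, 25, TRUE))
  ref <- kruskal.test(g)
  mine <- kruskal_wallis(g)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p_raw, ref$p.value, tolerance = 1e-12)
  expect_error(kruskal_wallis(list(c(1, 1), c(1, 1))), "identical")
})

test_that("two-group kruskal-wallis equals squared tie-corrected MWU z", {
  set.seed(44)
  a <- sample(1:8, 30, TRUE); b <- sample(3:10, 20, TRUE)
  h <- kruskal_wallis(list(a, b))$statistic
  z <- testevol:::mwu_z_no_cc(a, b)
  expect_equal(h, z^2, tolerance = 1e-10)
})

test_that("mann-whitney exact enumeration matches combinatorics and wilcox.test", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_raw, 1 / 3)
  # identical samples under forced exact mode: p = 1
  expect_equal(mann_whitney_u(c(2, 2, 2), c(2, 2, 2), mode = "exact")$p_raw, 1)
  # oracle: wilcox.test exact p on no-ties samples
  set.seed(45)
  for (i in 1:5) {
    a <- rnorm(8); b <- rnorm(11)
    mine <- mann_whitney_u(a, b)
    ref <- wilcox.test(a, b, exact = TRUE, correct = FALSE)
    expect_equal(mine$statistic, unname(ref$statistic))
    expect_equal(mine$p_raw, ref$p.value, tolerance = 1e-12)
  }
  # normal mode matches wilcox.test's tie-corrected continuity-corrected p
  a <- sample(1:20, 40, TRUE); b <- sample(5:25, 35, TRUE)
  mine <- mann_whitney_u(a, b, mode = "normal")
  ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(mine$p_raw, ref$p.value, tolerance = 1e-10)
})

test_that("exact and normal-approximation MWU p agree asymptotically", {
  set.seed(46)
  a <- rnorm(50); b <- rnorm(50)
  p_exact <- mann_whitney_u(a, b, mode = "exact")$p_raw
  p_norm <- mann_whitney_u(a, b, mode = "normal")$p_raw
  expect_lt(abs(p_exact - p_norm), 0.01)
})

test_that("pearson chi-squared matches the expected-count oracle", {
  # observed composition table: immunity across the three categories
  tab <- rbind(yes = c(130, 11, 140), no = c(276, 46, 362))
  res <- pearson_chi2(tab)
  expect_equal(res$statistic, 4.687, tolerance = 5e-4)
  expect_equal(res$df, 2)
  # independence: proportional table gives exactly 0
  prop <- outer(c(30, 70), c(10, 20, 40)) / 100
  expect_equal(pearson_chi2(prop * 10)$statistic, 0, tolerance = 1e-12)
  # oracle: explicit double loop over cells
  set.seed(47)
  t2 <- matrix(rpois(6, 30) + 1, 2, 3)
  e <- outer(rowSums(t2), colSums(t2)) / sum(t2)
  x2 <- 0
  for (i in 1:2) for (j in 1:3) x2 <- x2 + (t2[i, j] - e[i, j])^2 / e[i, j]
  expect_equal(pearson_chi2(t2)$statistic, x2, tolerance = 1e-12)
  expect_equal(pearson_chi2(t2)$statistic,
               unname(chisq.test(t2, correct = FALSE)$statistic),
               tolerance = 1e-12)
  expect_error(pearson_chi2(rbind(c(0, 0), c(3, 4))), "margin")
})

test_that("fisher exact p matches full hypergeometric enumeration", {
  res <- fisher_exact(rbind(c(3, 1), c(1, 3)))
  expect_equal(res$p_raw, 34 / 70, tolerance = 1e-12)
  # oracle: stats::fisher.test (independent enumeration) on random tables
  set.seed(48)
  for (i in 1:5) {
    t22 <- matrix(rpois(4, 5) + 1, 2, 2)
    expect_equal(fisher_exact(t22)$p_raw, fisher.test(t22)$p.value,
                 tolerance = 1e-8)
    t23 <- matrix(rpois(6, 4) + 1, 2, 3)
    expect_equal(fisher_exact(t23)$p_raw, fisher.test(t23)$p.value,
                 tolerance = 1e-8)
  }
  # 2x2 treated as an r x c Freeman-Halton table gives the identical p
  t22 <- rbind(c(7, 2), c(3, 8))
  expect_equal(fisher_exact(t22)$p_raw, fisher.test(t22)$p.value,
               tolerance = 1e-10)
  expect_error(fisher_exact(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("test selection follows the expected-count rule", {
  # X-chromosome composition: smallest expected cell 2.36, needs Fisher
  x_tab <- rbind(yes = c(27, 5, 8), no = c(379, 52, 494))
  expect_equal(choose_test(x_tab), "fisher")
  # immunity composition: all expected counts comfortably over 5
  imm <- rbind(yes = c(130, 11, 140), no = c(276, 46, 362))
  expect_equal(choose_test(imm), "chi2")
  expect_equal(choose_test(matrix(100, 2, 3)), "chi2")
})

test_that("holm adjustment matches the hand step-down and p.adjust", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2, m = 1), 0.2)
  expect_equal(holm_adjust(rep(1, 4)), rep(1, 4))
  # family larger than the vector: first factor is m
  expect_equal(holm_adjust(c(0.01, 0.02), m = 6), c(0.06, 0.1))
  expect_error(holm_adjust(c(0.1, 0.2), m = 1), "family size")
  set.seed(49)
  p <- runif(12)
  expect_equal(holm_adjust(p), p.adjust(p, "holm"), tolerance = 1e-12)
  # bounds: at least raw p, at most Bonferroni
  expect_true(all(holm_adjust(p) >= p))
  expect_true(all(holm_adjust(p) <= pmin(1, length(p) * p)))
})

test_that("bootstrap median CI behaves as a percentile interval", {
  expect_equal(bootstrap_median_ci(rep(3.5, 20), B = 200, seed = 1),
               c(3.5, 3.5))
  ci <- bootstrap_median_ci(1:9, B = 5000, seed = 2)
  expect_lte(ci[1], 5)
  expect_gte(ci[2], 5)
  # interval width shrinks with sample size
  set.seed(50)
  small <- rnorm(20); large <- rnorm(2000)
  w_small <- diff(bootstrap_median_ci(small, B = 3000, seed = 3))
  w_large <- diff(bootstrap_median_ci(large, B = 3000, seed = 3))
  expect_lt(w_large, w_small)
  # reproducible from seed, caller's RNG stream untouched
  set.seed(99); before <- rnorm(1)
  c1 <- bootstrap_median_ci(rnorm(50), B = 500, seed = 7)
  set.seed(99); invisible(rnorm(1))
  c2 <- bootstrap_median_ci(rnorm(50), B = 500, seed = 7)
  expect_equal(c1, c2)
})
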