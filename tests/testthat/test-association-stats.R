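test_that("pearson chi-square matches the direct summation oracle", {
  set.seed(41)
  for (i in 1:20) {
    tab <- matrix(rpois(12, 20) + 1, 3, 4)
    res <- pearson_chi2(tab)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    x2 <- 0
    for (r in 1:3) for (c in 1:4) x2 <- x2 + (tab[r, c] - E[r, c])^2 / E[r, c]
    expect_equal(res$statistic, x2, tolerance = 1e-10)
    expect_equal(res$df, 6)
  }
  # perfect independence
  res0 <- pearson_chi2(matrix(10, 2, 2))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)
  expect_error(pearson_chi2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "zero margin")
})

test_that("contingency statistics are invariant to row/column permutation", {
  set.seed(42)
  tab <- matrix(rpois(6, 30) + 1, 3, 2)
  p1 <- pearson_chi2(tab)$statistic
  p2 <- pearson_chi2(tab[c(3, 1, 2), c(2, 1)])$statistic
  expect_equal(p1, p2, tolerance = 1e-12)
  f1 <- fisher_exact(matrix(c(3, 1, 1, 3), 2))$p
  f2 <- fisher_exact(matrix(c(3, 1, 1, 3), 2)[2:1, 2:1])$p
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("trend statistic equals (n-1) r^2 on expanded subject vectors", {
  set.seed(43)
  for (i in 1:10) {
    tab <- matrix(rpois(6, 25) + 1, 3, 2)
    res <- trend_chi2(tab)
    x <- rep(rep(1:3, 2), as.vector(tab))
    y <- rep(rep(0:1, each = 3), as.vector(tab))
    expect_equal(res$statistic, (sum(tab) - 1) * cor(x, y)^2,
                 tolerance = 1e-10)
  }
  # identical column proportions per row -> M^2 = 0, p = 1
  flat <- matrix(c(10, 10, 20, 20, 5, 5), 3, 2, byrow = TRUE)
  expect_equal(trend_chi2(flat)$statistic, 0, tolerance = 1e-12)
  expect_equal(trend_chi2(flat)$p, 1)
  expect_error(trend_chi2(matrix(c(5, 5, 5, 5), 2)), ">= 3 ordered")
})

test_that("trend test on a linear-in-score table beats Pearson's df=2 p", {
  # reference grade tables: the df=1 trend p is smaller than Pearson's df=2
  tabs <- reference_association_tables()
  for (id in c("grade_tcd163", "grade_dist_scd163")) {
    tab <- tabs[[id]]$counts
    expect_lt(trend_chi2(tab)$p, pearson_chi2(tab)$p)
  }
})

test_that("fisher two-sided p equals full hypergeometric enumeration", {
  tab <- matrix(c(3, 1, 1, 3), 2)
  res <- fisher_exact(tab)
  # margins 4/4, 4/4: a ranges 0..4
  probs <- vapply(0:4, function(a) dhyper(a, 4, 4, 4), numeric(1))
  p_enum <- sum(probs[probs <= dhyper(3, 4, 4, 4) + 1e-12])
  expect_equal(res$p, p_enum, tolerance = 1e-7)
  # zero margin -> p = 1
  expect_equal(fisher_exact(matrix(c(0, 0, 4, 6), 2, byrow = TRUE))$p, 1)
})

test_that("the test-choice rule is deterministic and matches expected counts", {
  tabs <- reference_association_tables()
  expect_equal(choose_test(tabs$grade_tcd163$counts, row_ordered = TRUE),
               "trend_chi2")
  # 2x2 with min expected >= 5 -> pearson
  expect_equal(choose_test(matrix(c(20, 25, 30, 25), 2)), "pearson_chi2")
  # 2x2 with a small expected count -> fisher
  small <- matrix(c(2, 8, 9, 1), 2)
  expect_lt(min(expected_counts(small)), 5)
  expect_equal(choose_test(small), "fisher_exact")
  # unordered 3x2 stays pearson
  expect_equal(choose_test(tabs$grade_tcd163$counts, row_ordered = FALSE),
               "pearson_chi2")
})

test_that("spearman rs equals correlation of mid-ranks and is rank invariant", {
  set.seed(44)
  x <- rnorm(40)
  y <- 0.6 * x + rnorm(40)
  res <- spearman_rho(x, y)
  expect_equal(res$effect$rs, cor(rank(x), rank(y)), tolerance = 1e-12)
  # invariance under strictly monotone transforms of x
  expect_equal(spearman_rho(exp(x), y)$effect$rs, res$effect$rs,
               tolerance = 1e-12)
  expect_equal(spearman_rho(x, y^3 + 2 * y)$effect$rs,
               spearman_rho(x, y)$effect$rs, tolerance = 1e-12)
  expect_equal(spearman_rho(x, x)$effect$rs, 1)
  expect_error(spearman_rho(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("mann-whitney handles separation and matches a permutation oracle", {
  a <- 1:5
  b <- 11:16
  res <- mann_whitney(a, b)
  expect_true(res$statistic %in% c(0, length(a) * length(b)))
  expect_lt(res$p, 0.01)
  # identical samples: U at its null mean
  res0 <- mann_whitney(1:9, 1:9)
  expect_equal(unname(res0$statistic), 9 * 9 / 2)
  expect_gt(res0$p, 0.95)
  # moderate-n permutation oracle within 0.01 (absolute)
  set.seed(45)
  x <- rnorm(30, 0.4)
  y <- rnorm(30)
  r <- rank(c(x, y))
  uobs <- sum(r[1:30]) - 30 * 31 / 2
  mu <- 30 * 30 / 2
  perm <- replicate(40000, sum(r[sample(60, 30)]) - 30 * 31 / 2)
  p_perm <- mean(abs(perm - mu) >= abs(uobs - mu) - 1e-9)
  expect_lt(abs(mann_whitney(x, y)$p - p_perm), 0.01)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("wilcoxon signed-rank: sign saturation, errors, sign-flip oracle", {
  a <- rnorm(10)
  expect_error(wilcoxon_signed_rank(a, a), "zero")
  expect_lt(wilcoxon_signed_rank(a, a + 3)$p, 0.05)
  # Monte-Carlo sign-flip oracle at n = 40 (normal approximation regime)
  set.seed(46)
  d <- rnorm(40, 0.15, 1)
  r <- rank(abs(d))
  wobs <- sum(r[d > 0])
  mu <- 40 * 41 / 4
  flips <- matrix(sample(c(0, 1), 200000 * 40, TRUE), ncol = 40)
  wall <- flips %*% r
  p_mc <- mean(abs(wall - mu) >= abs(wobs - mu) - 1e-9)
  expect_lt(abs(wilcoxon_signed_rank(d + 1, rep(1, 40))$p - p_mc), 0.01)
})

test_that("every validated reference table reproduces its reported p", {
  rec <- recompute_reference_tables()
  val <- rec[rec$validated, ]
  expect_true(all(val$agrees))
  # the two flagged-ambiguous tables are genuinely not reproduced
  expect_true(all(!rec$agrees[!rec$validated]))
})

test_that("the association battery returns tidy rows with chosen tests", {
  set.seed(47)
  coh <- generate_cohort(sim_config(n_cases = 60, seed = 47), level = "case")
  data <- merge(coh$clinical, coh$metrics, by = "case_id")
  res <- association_battery(
    data,
    features = list(grade = list(var = "grade", type = "ordered"),
                    ki67 = list(var = "ki67_high", type = "binary"),
                    age = list(var = "age", type = "continuous")),
    groups = c("sCD163_high", "tCD206_high"))
  expect_equal(nrow(res), 6)
  expect_setequal(unique(res$feature), c("grade", "ki67", "age"))
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_equal(res$test[res$feature == "grade"],
               rep("trend_chi2", 2))
  expect_equal(res$test[res$feature == "age"], rep("mann_whitney", 2))
})

test_that("paired flag shift equals the McNemar discordant-pair statistic", {
  # 30 stromal-high/tumoral-low discordants vs 10 of the converse
  s_high <- c(rep(TRUE, 70), rep(FALSE, 50))
  t_high <- c(rep(TRUE, 40), rep(FALSE, 30), rep(TRUE, 10), rep(FALSE, 40))
  res <- paired_flag_shift(s_high, t_high)
  expect_equal(res$test, "mcnemar")
  expect_equal(res$statistic, (30 - 10)^2 / (30 + 10), tolerance = 1e-12)
  expect_lt(res$p, 0.01)
})
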