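test_that("Mann-Whitney exact p matches permutation oracle and base R", {
  set.seed(11)
  for (rep in 1:30) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    # half the cases with heavy ties
    pool <- if (rep %% 2) rnorm(n1 + n2) else sample(1:4, n1 + n2, TRUE)
    x <- pool[seq_len(n1)]; y <- pool[-seq_len(n1)]
    got <- mann_whitney_test(x, y)
    want <- oracle_mw(x, y)
    expect_true(got$exact)
    expect_equal(got$statistic, want$u, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-9)
    if (!anyDuplicated(pool)) {
      # independent cross-check: base R's exact two-sided p
      expect_equal(got$p, wilcox.test(x, y, exact = TRUE)$p.value,
                   tolerance = 1e-9)
    }
  }
  # spec worked example: complete separation of {1,2} and {3,4}
  res <- mann_whitney_test(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 2 / 6)
})

test_that("Wilcoxon signed ranks exact p matches sign-flip oracle", {
  set.seed(12)
  for (rep in 1:20) {
    m <- sample(3:8, 1)
    x <- rnorm(m); y <- if (rep %% 2) rnorm(m) else x + sample(-2:2, m, TRUE)
    got <- wilcoxon_signed_rank_test(x, y)
    want <- oracle_wsr(x, y)
    expect_equal(got$statistic, want$v, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-9)
    d <- x - y
    if (!anyDuplicated(abs(d[d != 0])) && all(d != 0)) {
      expect_equal(got$p, wilcox.test(x, y, paired = TRUE,
                                      exact = TRUE)$p.value,
                   tolerance = 1e-9)
    }
  }
  expect_true(wilcoxon_signed_rank_test(1:4, 1:4)$degenerate)
  expect_equal(wilcoxon_signed_rank_test(1:4, 1:4)$p, 1)
})

test_that("Kruskal-Wallis exact p matches the all-permutations oracle", {
  cases <- list(
    list(c(1, 2), c(3, 4), c(5, 6)),
    list(c(2, 2), c(3, 1), c(5, 4)),         # with ties
    list(c(1.2, 0.1), c(2.3, 1.9, 0.7), c(4, 2))
  )
  for (samples in cases) {
    got <- kruskal_wallis_test(samples)
    want <- oracle_kw(samples)
    expect_true(got$exact)
    expect_equal(got$statistic, want$h, tolerance = 1e-9)
    expect_equal(got$p, want$p, tolerance = 1e-9)
  }
  # frozen example: three separated groups of two -> H = 4.571, exact p
  res <- kruskal_wallis_test(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(res$statistic, 32 / 7, tolerance = 1e-9)
  # large samples fall back to the chi-square approximation
  big <- lapply(1:3, function(i) rnorm(30, i))
  approx <- kruskal_wallis_test(big)
  expect_false(approx$exact)
  expect_equal(approx$p,
               kruskal.test(unlist(big),
                            rep(1:3, each = 30))$p.value,
               tolerance = 1e-9)
})

test_that("Friedman exact p matches the per-block permutation oracle", {
  set.seed(13)
  y <- matrix(rnorm(12), nrow = 4, ncol = 3)
  got <- friedman_test(y)
  want <- oracle_friedman(y)
  expect_true(got$exact)
  expect_equal(got$statistic, want$f, tolerance = 1e-9)
  expect_equal(got$p, want$p, tolerance = 1e-9)
  # chi-square fallback agrees with base R (no ties)
  y_big <- matrix(rnorm(40), nrow = 10, ncol = 4)
  approx <- friedman_test(y_big, exact_limit = 10)
  expect_false(approx$exact)
  expect_equal(approx$statistic,
               unname(friedman.test(y_big)$statistic), tolerance = 1e-9)
  expect_equal(approx$p, friedman.test(y_big)$p.value, tolerance = 1e-9)
})

test_that("omnibus dispatch follows the two-by-two design rule", {
  v <- c(1, 2, 3, 4, 5, 6)
  g2 <- rep(c("a", "b"), each = 3)
  g3 <- rep(c("a", "b", "c"), each = 2)
  blocks2 <- rep(1:3, times = 2)
  blocks3 <- rep(1:2, times = 3)
  expect_equal(omnibus_test(v, g2, "unrelated")$name, "Mann-Whitney U")
  expect_equal(omnibus_test(v, g3, "unrelated")$name, "Kruskal-Wallis H")
  expect_equal(omnibus_test(v, g2, "related", blocks2)$name,
               "Wilcoxon signed ranks")
  expect_equal(omnibus_test(v, g3, "related", blocks3)$name, "Friedman")
  expect_error(omnibus_test(v, rep("a", 6), "unrelated"), "at least 2")
  expect_error(omnibus_test(v[-1], g3[-1], "related", blocks3[-1]),
               "aligned units")
  # identical groups sit at the null centre
  same <- omnibus_test(rep(1:3, 2), g2, "unrelated")
  expect_equal(same$p, 1)
})

test_that("Bonferroni contrasts divide alpha by the contrasts performed", {
  set.seed(14)
  v <- c(rnorm(4, 0), rnorm(4, 10), rnorm(4, 20), rnorm(4, 30))
  g <- rep(letters[1:4], each = 4)
  ctr <- bonferroni_contrasts(v, g, "unrelated", alpha = 0.05)
  expect_equal(nrow(ctr), 6)
  expect_equal(attr(ctr, "alpha_adjusted"), 0.05 / 6, tolerance = 1e-12)
  expect_equal(unique(ctr$alpha_adjusted), 0.05 / 6)
  ctr2 <- bonferroni_contrasts(v[1:8], g[1:8], "unrelated")
  expect_equal(attr(ctr2, "alpha_adjusted"), 0.05)
  # degenerate pair: identical values on both sides -> p = 1, flagged
  ctr3 <- bonferroni_contrasts(rep(1, 8), rep(c("a", "b"), 4), "unrelated")
  expect_true(all(ctr3$degenerate))
  expect_equal(ctr3$p, 1)
})

test_that("clearly separated treatments earn all-distinct letters", {
  set.seed(15)
  v <- c(rnorm(8, 0, 0.1), rnorm(8, 10, 0.1), rnorm(8, 20, 0.1),
         rnorm(8, 30, 0.1))
  g <- rep(c("t1", "t2", "t3", "t4"), each = 8)
  cmp <- compare_groups(v, g, "unrelated", alpha = 0.05)
  expect_true(all(cmp$contrasts$significant))
  expect_equal(unname(cmp$letters), c("a", "b", "c", "d"))
  expect_lt(cmp$omnibus$p, 0.05)
})

test_that("Kendall trend reports tau-b and flags constant series", {
  expect_equal(kendall_trend(1:5, 2 * (1:5))$tau, 1)
  expect_equal(kendall_trend(1:5, -(1:5))$tau, -1)
  # hand count over the 3 pairs of {(1,3),(2,1),(3,2)}: 1 concordant,
  # 2 discordant -> tau = -1/3
  res <- kendall_trend(c(1, 2, 3), c(3, 1, 2))
  expect_equal(res$tau, -1 / 3, tolerance = 1e-12)
  expect_true(res$exact)
  expect_warning(out <- kendall_trend(1:5, rep(2, 5)), "constant")
  expect_true(out$degenerate)
  expect_error(kendall_trend(1:2, 1:2), "at least 3")
  # tie-corrected tau-b agrees with base R
  set.seed(16)
  x <- sample(1:5, 12, TRUE); y <- sample(1:5, 12, TRUE)
  expect_equal(kendall_trend(x, y)$tau,
               unname(suppressWarnings(
                 cor.test(x, y, method = "kendall")$estimate)),
               tolerance = 1e-12)
})
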